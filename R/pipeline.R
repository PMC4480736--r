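#' Configuration of a full pipeline run
#'
#' A run is fully described by one config object: either a simulation
#' block ([sim_config()]) or a directory of input files (the TSV dialects
#' written by [emit_inputs()]), never both, plus the binning, smoothing,
#' cutoff, holdout and hub settings. The master `seed` is fanned out into
#' independent per-stage streams (world generation, gold-standard holdout
#' split, SAM permutations).
#'
#' @param simulation A [sim_config()], or `NULL` when reading inputs.
#' @param input_dir Directory containing the input TSVs, or `NULL`.
#' @param n_coexpr_bins Equal-width correlation bins.
#' @param pseudocount Likelihood-table smoothing pseudocount.
#' @param lr_cutoff Numeric LR cutoff (default 117) or `"auto"` to choose
#'   the F1-maximizing cutoff on the validation split.
#' @param holdout_fraction Fraction of each gold-standard set held out
#'   from likelihood estimation for evaluation and cutoff selection.
#' @param criteria Hub-calling [hub_criteria()].
#' @param top_k Novel hubs paired in the dual-target analysis.
#' @param apoptotic_term BP term identifier defining the apoptotic
#'   annotation set.
#' @param prior_odds Prior odds reported alongside composite LRs.
#' @param outdir Output directory for stage artifacts and the report, or
#'   `NULL` to run in memory.
#' @param write_evidence Also write the (large) per-pair evidence tables
#'   when `outdir` is set.
#' @param seed Master seed of the run.
#' @return A validated `ppi_run_config` list.
#' @export
run_config <- function(simulation = NULL, input_dir = NULL,
                       n_coexpr_bins = 10, pseudocount = 0.5,
                       lr_cutoff = 117, holdout_fraction = 0.3,
                       criteria = hub_criteria(), top_k = 5,
                       apoptotic_term = "apoptotic_process",
                       prior_odds = 1, outdir = NULL,
                       write_evidence = FALSE, seed = 1L) {
  if (is.null(simulation) == is.null(input_dir)) {
    stop("exactly one of `simulation` and `input_dir` must be given",
      call. = FALSE
    )
  }
  if (!is.null(simulation) && !inherits(simulation, "ppi_sim_config")) {
    stop("`simulation` must be a sim_config()", call. = FALSE)
  }
  if (!is.null(input_dir)) {
    required <- c(
      "annotation.tsv", "expression.tsv", "orthologs.tsv",
      "domains.tsv", "ddi.tsv"
    )
    missing <- required[!file.exists(file.path(input_dir, required))]
    if (length(missing) > 0) {
      stop("missing input files in ", input_dir, ": ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    if (length(Sys.glob(file.path(input_dir, "interactions_*.tsv"))) == 0) {
      stop("no interactions_*.tsv files in ", input_dir, call. = FALSE)
    }
  }
  if (!identical(lr_cutoff, "auto") &&
    (!is.numeric(lr_cutoff) || lr_cutoff <= 0)) {
    stop("`lr_cutoff` must be positive or 'auto'", call. = FALSE)
  }
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("`holdout_fraction` must be in (0, 1)", call. = FALSE)
  }
  stopifnot(inherits(criteria, "ppi_hub_criteria"))
  structure(
    list(
      simulation = simulation, input_dir = input_dir,
      n_coexpr_bins = n_coexpr_bins, pseudocount = pseudocount,
      lr_cutoff = lr_cutoff, holdout_fraction = holdout_fraction,
      criteria = criteria, top_k = top_k,
      apoptotic_term = apoptotic_term, prior_odds = prior_odds,
      outdir = outdir, write_evidence = write_evidence,
      seed = as.integer(seed)
    ),
    class = "ppi_run_config"
  )
}

read_input_bundle <- function(input_dir) {
  src_files <- sort(Sys.glob(file.path(input_dir, "interactions_*.tsv")))
  model_files <- sort(Sys.glob(file.path(input_dir, "model_ppi_*.tsv")))
  list(
    interaction_sources = bind_rows(lapply(src_files, read_interactions)),
    annotation = read_annotation(file.path(input_dir, "annotation.tsv")),
    expression = read_expression(file.path(input_dir, "expression.tsv")),
    orthologs = read_orthologs(file.path(input_dir, "orthologs.tsv")),
    model_interactions = bind_rows(
      lapply(model_files, read_interactions)
    ),
    domains = read_domains(file.path(input_dir, "domains.tsv")),
    ddi = read_ddi(file.path(input_dir, "ddi.tsv"))
  )
}

#' Run the full discovery pipeline
#'
#' Executes simulate (or read) -> gold standards -> evidence scoring and
#' binning -> likelihood-ratio estimation -> naive-Bayes combination ->
#' holdout evaluation -> network assembly -> hub identification ->
#' dual-target prioritization, writes stage artifacts and a JSON report
#' when an output directory is configured, and returns everything for
#' programmatic use. Identical config and seed give an identical report.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A `ppi_run` list: `report` (the deterministic run summary) and
#'   `objects` (world/bundle, gold standards, scores, ROC, network, hub
#'   report, subnetwork, dual-target candidates).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "ppi_run_config"))
  log_lines <- character(0)
  t0 <- Sys.time()
  say <- function(...) {
    line <- sprintf(
      "[%7.2fs] %s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")),
      paste0(...)
    )
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    say("stage ", name, " started")
    res <- tryCatch(expr, error = function(e) {
      if (!is.null(config$outdir)) {
        dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
        writeLines(
          c(paste("FAILED at stage:", name), conditionMessage(e)),
          file.path(config$outdir, "FAILED")
        )
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
    say("stage ", name, " done")
    res
  }

  ## inputs -------------------------------------------------------------
  inputs <- stage("inputs", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      sim$seed <- sub_seed(config$seed, 101)
      w <- simulate_world(sim)
      if (!is.null(config$outdir)) {
        emit_inputs(w, file.path(config$outdir, "inputs"))
      }
      list(world = w, bundle = w[c(
        "interaction_sources", "annotation", "expression", "orthologs",
        "model_interactions", "domains", "ddi"
      )])
    } else {
      list(world = NULL, bundle = read_input_bundle(config$input_dir))
    }
  })
  world <- inputs$world
  bundle <- inputs$bundle
  roster <- sort(unique(c(
    bundle$expression$gene_id,
    bundle$annotation$protein_id,
    bundle$domains$protein_id,
    bundle$interaction_sources$protein_a,
    bundle$interaction_sources$protein_b
  )))

  ## gold standards ------------------------------------------------------
  gold <- stage("standards", {
    build_gold_standards(bundle$interaction_sources, bundle$annotation)
  })

  ## evidence ------------------------------------------------------------
  evidence <- stage("evidence", {
    universe <- all_pairs(roster)
    evidence_table(
      universe, bundle$expression, bundle$domains, bundle$ddi,
      bundle$orthologs, bundle$model_interactions, bundle$annotation
    )
  })
  binned <- stage("binning", {
    bin_evidence(evidence, n_coexpr_bins = config$n_coexpr_bins)
  })

  ## gold-standard holdout split -----------------------------------------
  set.seed(sub_seed(config$seed, 102))
  split_set <- function(pairs) {
    n <- nrow(pairs)
    if (n < 2) {
      return(list(train = pairs[0, ], val = pairs))
    }
    val <- sort(sample.int(n, size = max(1, round(config$holdout_fraction * n))))
    list(train = pairs[-val, ], val = pairs[val, ])
  }
  gsp_split <- split_set(gold$gsp)
  gsn_split <- split_set(gold$gsn)

  ## likelihood-ratio estimation and combination -------------------------
  lr_table <- stage("integrate", {
    estimate_lr_table(
      binned$binned, gsp_split$train, gsn_split$train,
      binned$schemes,
      pseudocount = config$pseudocount
    )
  })
  scores <- stage("combine", {
    combine_lr(
      evidence[c("protein_a", "protein_b")], binned$binned, lr_table,
      prior_odds = config$prior_odds
    )
  })

  ## holdout evaluation and cutoff ---------------------------------------
  val_set <- bind_rows(
    mutate(as_tibble(gsp_split$val), label = "pos"),
    mutate(as_tibble(gsn_split$val), label = "neg")
  )
  evaluation <- stage("evaluate", {
    holdout_evaluate(
      scores, val_set,
      list(gsp_split$train, gsn_split$train)
    )
  })
  cutoff_used <- if (identical(config$lr_cutoff, "auto")) {
    choose_cutoff(val_set, scores)$cutoff
  } else {
    config$lr_cutoff
  }
  say("LR cutoff used: ", format(cutoff_used, digits = 6))

  ## network, hubs, prioritization ---------------------------------------
  network <- stage("network", {
    predict_network(scores, gold$gsp, lr_cutoff = cutoff_used)
  })
  apoptotic_set <- bundle$annotation %>%
    filter(aspect == "BP", term_id == config$apoptotic_term) %>%
    pull(protein_id) %>%
    unique()
  criteria <- config$criteria
  criteria$seed <- sub_seed(config$seed, 103)
  hub_report <- stage("hubs", {
    identify_hubs(network, apoptotic_set, bundle$expression, criteria)
  })
  subnetwork <- stage("prioritize-subnetwork", {
    extract_core_subnetwork(network, hub_report)
  })
  candidates <- stage("prioritize-targets", {
    dual_target_candidates(subnetwork, hub_report, top_k = config$top_k)
  })

  ## report ---------------------------------------------------------------
  lr_summary <- as_tibble(lr_table) %>%
    group_by(evidence) %>%
    summarise(
      n_bins = dplyr::n(), min_lr = min(lr), max_lr = max(lr),
      .groups = "drop"
    )
  top_pairs <- head(as_tibble(candidates), 3)
  report <- list(
    package = "apoppi",
    version = as.character(packageVersion("apoppi")),
    seed = config$seed,
    config = list(
      mode = if (is.null(config$simulation)) "files" else "simulation",
      n_coexpr_bins = config$n_coexpr_bins,
      pseudocount = config$pseudocount,
      lr_cutoff = config$lr_cutoff,
      holdout_fraction = config$holdout_fraction,
      hub_criteria = config$criteria[c(
        "min_degree", "min_apoptotic_links_classical",
        "min_apoptotic_links_novel", "k_core_min", "sam_fdr",
        "sam_permutations", "scale_thresholds", "reference_n"
      )],
      top_k = config$top_k,
      apoptotic_term = config$apoptotic_term,
      simulation = if (is.null(config$simulation)) {
        NULL
      } else {
        unclass(config$simulation)
      }
    ),
    counts = list(
      n_proteins = length(roster),
      n_source_records = nrow(bundle$interaction_sources),
      n_gsp = nrow(gold$gsp),
      n_gsn = nrow(gold$gsn),
      gsn_overlap_removed = gold$overlap_removed,
      n_universe_pairs = nrow(evidence),
      n_scored_pairs = nrow(scores),
      n_validation_pairs = nrow(val_set),
      n_network_edges = nrow(network),
      n_network_nodes = length(attr(network, "nodes")),
      n_edges_predicted = sum(network$provenance == "predicted"),
      n_edges_gold_only = sum(network$provenance == "gold_positive"),
      n_edges_both = sum(network$provenance == "both"),
      n_apoptotic = length(apoptotic_set),
      n_hubs_classical = sum(hub_report$hub_class == "classical"),
      n_hubs_novel = sum(hub_report$hub_class == "novel"),
      n_subnetwork_edges = nrow(subnetwork),
      n_sam_significant = if (is.null(attr(hub_report, "sam"))) {
        NA_integer_
      } else {
        sum(attr(hub_report, "sam")$genes$significant)
      }
    ),
    likelihood_table = lapply(
      split(lr_summary, lr_summary$evidence),
      function(r) as.list(r[-1])
    ),
    evaluation = list(
      auc = evaluation$roc$auc,
      n_validation_pos = evaluation$roc$n_pos,
      n_validation_neg = evaluation$roc$n_neg,
      lr_cutoff_used = cutoff_used
    ),
    hub_thresholds_applied = attr(hub_report, "thresholds"),
    top_dual_targets = lapply(
      seq_len(nrow(top_pairs)),
      function(i) as.list(top_pairs[i, ])
    ),
    conservation = list(
      gsp_edges_all_in_network = all(
        pair_keys(gold$gsp) %in% pair_keys(network)
      ),
      network_nodes_in_roster = all(attr(network, "nodes") %in% roster),
      subnetwork_edges_in_network = all(
        pair_keys(subnetwork) %in% pair_keys(network)
      )
    )
  )

  if (!is.null(config$outdir)) {
    stage("write-artifacts", {
      out <- config$outdir
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_ppi_table(gold$gsp, file.path(out, "gsp.tsv"))
      write_ppi_table(gold$gsn, file.path(out, "gsn.tsv"))
      jsonlite::write_json(
        list(
          n_gsp = nrow(gold$gsp), n_gsn = nrow(gold$gsn),
          overlap_removed = gold$overlap_removed
        ),
        file.path(out, "gold_standard_counts.json"),
        auto_unbox = TRUE
      )
      write_ppi_table(
        as_tibble(lr_table), file.path(out, "lr_table.tsv")
      )
      write_ppi_table(
        as_tibble(network), file.path(out, "network.tsv")
      )
      write_sif(network, file.path(out, "network.sif"))
      write_ppi_table(
        evaluation$roc$points, file.path(out, "roc.tsv")
      )
      write_ppi_table(
        as_tibble(hub_report), file.path(out, "hub_report.tsv")
      )
      write_ppi_table(
        as_tibble(subnetwork), file.path(out, "subnetwork.tsv")
      )
      write_sif(subnetwork, file.path(out, "subnetwork.sif"))
      write_ppi_table(
        attr(candidates, "ranking"), file.path(out, "novel_hub_ranking.tsv")
      )
      if (nrow(candidates) > 0) {
        write_ppi_table(
          as_tibble(candidates), file.path(out, "dual_targets.tsv")
        )
      }
      if (config$write_evidence) {
        write_ppi_table(evidence, file.path(out, "evidence.tsv"))
        write_ppi_table(
          binned$binned, file.path(out, "evidence_bins.tsv")
        )
      }
      con <- file(file.path(out, "report.json"), open = "wb")
      writeLines(
        jsonlite::toJSON(
          report,
          auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
        ),
        con
      )
      close(con)
      TRUE
    })
    writeLines(log_lines, file.path(config$outdir, "run.log"))
  }
  say("pipeline complete")

  structure(
    list(
      report = report,
      objects = list(
        world = world, bundle = bundle, gold = gold,
        evidence = evidence, binned = binned, lr_table = lr_table,
        scores = scores, evaluation = evaluation, network = network,
        hub_report = hub_report, subnetwork = subnetwork,
        candidates = candidates, cutoff_used = cutoff_used,
        validation_set = val_set
      )
    ),
    class = "ppi_run"
  )
}

#' @export
print.ppi_run <- function(x, ...) {
  r <- x$report
  cat(
    "Pipeline run (seed ", r$seed, "): ",
    r$counts$n_network_edges, " network edges over ",
    r$counts$n_network_nodes, " proteins; validation AUC ",
    format(r$evaluation$auc, digits = 4), "; ",
    r$counts$n_hubs_classical, " classical / ",
    r$counts$n_hubs_novel, " novel hubs\n",
    sep = ""
  )
  invisible(x)
}
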