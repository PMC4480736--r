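#' Configuration for the synthetic interactome world
#'
#' Defines the ground-truth generative model behind every synthetic input
#' bundle: a scale-free true interactome with planted apoptotic hubs, plus
#' four evidence channels (co-expression, domain-domain interaction,
#' cross-species interologs, shared biological-process annotation) whose
#' emission is conditional on true edge status with configurable effect
#' sizes. Each channel draws from its own pseudo-random stream derived from
#' the master seed, so changing one effect size leaves the other channels'
#' draws untouched.
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: 500 proteins of which ~12% are apoptotic (the prevalence of
#' apoptosis annotation in a 13k-protein proteome), three classical and two
#' novel planted hubs, six model organisms, and informative but noisy
#' evidence channels. See the methods vignette for the rationale behind each
#' value.
#'
#' @param n_proteins Number of proteins (genes share the same identifiers).
#' @param n_apoptotic Size of the apoptotic annotation set.
#' @param n_planted_classical_hubs Planted hubs inside the apoptotic set.
#' @param n_planted_novel_hubs Planted hubs outside the apoptotic set.
#' @param attachment_edges_per_node Edges added per node during
#'   preferential-attachment growth of the true interactome.
#' @param hub_extra_degree Extra edges attached to each planted hub.
#' @param hub_apoptotic_bias Probability that a planted hub's extra edge
#'   targets the apoptotic set.
#' @param n_samples_per_condition Microarray samples per condition (two
#'   conditions are emitted).
#' @param coexpr_effect Weight in `[0,1]` of the shared latent factor mixed
#'   into the expression profiles of interacting pairs.
#' @param ddi_tpr,ddi_fpr Probability that a true (resp. false) pair is
#'   backed by a compatible domain pair in the DDI table.
#' @param n_species Number of model organisms (max 6).
#' @param interolog_tpr_per_species,interolog_fpr_per_species Per-species
#'   probability that a mappable true (resp. false) pair has an interacting
#'   ortholog pair.
#' @param ortholog_coverage Per-species probability that a protein has an
#'   ortholog.
#' @param n_bp_terms Number of background biological-process terms.
#' @param bp_term_size_range Integer `[min, max]` of background term sizes.
#' @param ssbp_coannotation_boost Probability that a true pair is
#'   co-annotated to a dedicated small (2-protein) process term.
#' @param de_fraction Fraction of genes differentially expressed between
#'   conditions (planted hubs are always included).
#' @param de_effect Standardized mean shift of differentially expressed
#'   genes in condition 2.
#' @param localization_probs Named probabilities over
#'   `membrane`, `nucleus`, `cytoplasm`, `secreted`, `multiple`
#'   (must sum to 1; `multiple` proteins are annotated to both the
#'   plasma-membrane and nuclear compartments).
#' @param n_sources Number of curated interaction source tables emitted.
#' @param source_coverage Fraction of true edges each source reports.
#' @param seed Master seed (integer).
#' @return A validated `ppi_sim_config` list.
#' @export
sim_config <- function(n_proteins = 500,
                       n_apoptotic = 60,
                       n_planted_classical_hubs = 3,
                       n_planted_novel_hubs = 2,
                       attachment_edges_per_node = 3,
                       hub_extra_degree = 80,
                       hub_apoptotic_bias = 0.8,
                       n_samples_per_condition = 10,
                       coexpr_effect = 0.8,
                       ddi_tpr = 0.7,
                       ddi_fpr = 0.02,
                       n_species = 6,
                       interolog_tpr_per_species = 0.5,
                       interolog_fpr_per_species = 0.01,
                       ortholog_coverage = 0.8,
                       n_bp_terms = 60,
                       bp_term_size_range = c(5, 40),
                       ssbp_coannotation_boost = 0.6,
                       de_fraction = 0.1,
                       de_effect = 2,
                       localization_probs = c(
                         membrane = 0.25, nucleus = 0.25, cytoplasm = 0.3,
                         secreted = 0.1, multiple = 0.1
                       ),
                       n_sources = 3,
                       source_coverage = 0.45,
                       seed = 1L) {
  config <- list(
    n_proteins = n_proteins, n_apoptotic = n_apoptotic,
    n_planted_classical_hubs = n_planted_classical_hubs,
    n_planted_novel_hubs = n_planted_novel_hubs,
    attachment_edges_per_node = attachment_edges_per_node,
    hub_extra_degree = hub_extra_degree,
    hub_apoptotic_bias = hub_apoptotic_bias,
    n_samples_per_condition = n_samples_per_condition,
    coexpr_effect = coexpr_effect,
    ddi_tpr = ddi_tpr, ddi_fpr = ddi_fpr,
    n_species = n_species,
    interolog_tpr_per_species = interolog_tpr_per_species,
    interolog_fpr_per_species = interolog_fpr_per_species,
    ortholog_coverage = ortholog_coverage,
    n_bp_terms = n_bp_terms,
    bp_term_size_range = bp_term_size_range,
    ssbp_coannotation_boost = ssbp_coannotation_boost,
    de_fraction = de_fraction, de_effect = de_effect,
    localization_probs = localization_probs,
    n_sources = n_sources, source_coverage = source_coverage,
    seed = as.integer(seed)
  )
  validate_sim_config(config)
  structure(config, class = "ppi_sim_config")
}

validate_sim_config <- function(config) {
  check_prob <- function(field) {
    v <- config[[field]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v > 1)) {
      stop("invalid simulation config: `", field,
        "` must be a probability in [0, 1]",
        call. = FALSE
      )
    }
  }
  check_count <- function(field, minimum = 1) {
    v <- config[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < minimum ||
      v != floor(v)) {
      stop("invalid simulation config: `", field,
        "` must be an integer >= ", minimum,
        call. = FALSE
      )
    }
  }
  for (f in c(
    "coexpr_effect", "ddi_tpr", "ddi_fpr", "interolog_tpr_per_species",
    "interolog_fpr_per_species", "ortholog_coverage",
    "ssbp_coannotation_boost", "de_fraction", "hub_apoptotic_bias",
    "source_coverage", "localization_probs"
  )) {
    check_prob(f)
  }
  for (f in c(
    "n_proteins", "n_apoptotic", "attachment_edges_per_node",
    "n_samples_per_condition", "n_species", "n_bp_terms", "n_sources"
  )) {
    check_count(f)
  }
  for (f in c("n_planted_classical_hubs", "n_planted_novel_hubs")) {
    check_count(f, minimum = 0)
  }
  if (config$n_apoptotic > config$n_proteins) {
    stop("invalid simulation config: `n_apoptotic` exceeds `n_proteins`",
      call. = FALSE
    )
  }
  if (config$n_planted_classical_hubs > config$n_apoptotic) {
    stop("invalid simulation config: `n_planted_classical_hubs` exceeds ",
      "`n_apoptotic`",
      call. = FALSE
    )
  }
  if (config$n_planted_novel_hubs >
    config$n_proteins - config$n_apoptotic) {
    stop("invalid simulation config: `n_planted_novel_hubs` exceeds the ",
      "non-apoptotic protein count",
      call. = FALSE
    )
  }
  lp <- config$localization_probs
  wanted <- c("membrane", "nucleus", "cytoplasm", "secreted", "multiple")
  if (!setequal(names(lp), wanted)) {
    stop("invalid simulation config: `localization_probs` must be named ",
      paste(wanted, collapse = ", "),
      call. = FALSE
    )
  }
  if (abs(sum(lp) - 1) > 1e-9) {
    stop("invalid simulation config: `localization_probs` must sum to 1",
      call. = FALSE
    )
  }
  if (length(config$bp_term_size_range) != 2 ||
    config$bp_term_size_range[[1]] < 2 ||
    config$bp_term_size_range[[2]] < config$bp_term_size_range[[1]]) {
    stop("invalid simulation config: `bp_term_size_range` must be ",
      "[min, max] with 2 <= min <= max",
      call. = FALSE
    )
  }
  if (config$n_species > 6) {
    stop("invalid simulation config: `n_species` must be <= 6", call. = FALSE)
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1 ||
    is.na(config$seed)) {
    stop("invalid simulation config: `seed` must be a single integer",
      call. = FALSE
    )
  }
  invisible(config)
}

# Deterministic sub-stream seed for evidence channel k; arithmetic stays
# below 2^53 so it is exact in doubles and the result fits a 32-bit int.
sub_seed <- function(seed, k) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 1103 + k * 524287) %% 2147483629)
}

model_species_names <- function(n_species) {
  c(
    "cerevisiae", "melanogaster", "elegans",
    "musculus", "norvegicus", "coli"
  )[seq_len(n_species)]
}

# Sample k distinct canonical non-edge pairs from `ids`, rejecting pairs in
# `edge_keys`. Returns a tibble of canonical pairs (possibly fewer than k if
# the non-edge space is nearly exhausted).
sample_nonedge_pairs <- function(ids, edge_keys, k) {
  out_a <- character(0)
  out_b <- character(0)
  seen <- character(0)
  n <- length(ids)
  if (k <= 0 || n < 2) {
    return(tibble(protein_a = character(), protein_b = character()))
  }
  tries <- 0
  while (length(out_a) < k && tries < 50) {
    m <- max(2L * (k - length(out_a)), 16L)
    i <- sample.int(n, m, replace = TRUE)
    j <- sample.int(n, m, replace = TRUE)
    ok <- i != j
    a <- pmin(ids[i[ok]], ids[j[ok]])
    b <- pmax(ids[i[ok]], ids[j[ok]])
    key <- paste(a, b, sep = "\x1f")
    keep <- !key %in% edge_keys & !key %in% seen & !duplicated(key)
    out_a <- c(out_a, a[keep])
    out_b <- c(out_b, b[keep])
    seen <- c(seen, key[keep])
    tries <- tries + 1
  }
  tibble(
    protein_a = out_a[seq_len(min(k, length(out_a)))],
    protein_b = out_b[seq_len(min(k, length(out_b)))]
  )
}

#' Simulate a synthetic interactome world
#'
#' Builds a scale-free true interactome by preferential attachment, plants
#' classical (apoptotic) and novel (non-apoptotic) hub proteins with extra
#' edges biased into the apoptotic set, and emits the four evidence channels
#' conditional on true edge status. The ground truth (true edges, apoptotic
#' set, planted hubs, differentially expressed genes) is carried alongside
#' the input tables but is only ever written to a sidecar file that the
#' analysis pipeline never reads.
#'
#' @param config A [sim_config()].
#' @return A `ppi_world` list with the in-memory input tables
#'   (`interaction_sources`, `annotation`, `expression`, `orthologs`,
#'   `model_interactions`, `domains`, `ddi`) and the ground truth
#'   (`true_interactome`, `apoptotic_set`, `planted_hubs`, `de_genes`).
#' @examples
#' world <- simulate_world(sim_config(n_proteins = 60, n_apoptotic = 12,
#'   hub_extra_degree = 15, seed = 7))
#' world$planted_hubs
#' @export
simulate_world <- function(config) {
  if (!inherits(config, "ppi_sim_config")) {
    config <- do.call(sim_config, config)
  }
  validate_sim_config(config)
  proteins <- sprintf("P%04d", seq_len(config$n_proteins))

  ## --- true interactome with planted hubs (stream 1) ---
  set.seed(sub_seed(config$seed, 1))
  g <- igraph::sample_pa(
    config$n_proteins,
    m = config$attachment_edges_per_node,
    directed = FALSE
  )
  el <- igraph::as_edgelist(g, names = FALSE)
  base_edges <- canonical_pairs(proteins[el[, 1]], proteins[el[, 2]])

  apoptotic_set <- sort(sample(proteins, config$n_apoptotic))
  classical <- sort(sample(apoptotic_set, config$n_planted_classical_hubs))
  novel <- sort(sample(
    setdiff(proteins, apoptotic_set),
    config$n_planted_novel_hubs
  ))
  hubs <- c(classical, novel)

  hub_edges <- list()
  if (length(hubs) >= 2) {
    idx <- combn(length(hubs), 2)
    hub_edges[["clique"]] <- canonical_pairs(
      hubs[idx[1, ]], hubs[idx[2, ]]
    )
  }
  for (h in hubs) {
    k <- config$hub_extra_degree
    n_apop <- rbinom(1, k, config$hub_apoptotic_bias)
    apop_pool <- setdiff(apoptotic_set, h)
    other_pool <- setdiff(proteins, c(h, apoptotic_set))
    targets <- c(
      sample(apop_pool, min(n_apop, length(apop_pool))),
      sample(other_pool, min(k - n_apop, length(other_pool)))
    )
    hub_edges[[h]] <- canonical_pairs(rep(h, length(targets)), targets)
  }
  true_interactome <- bind_rows(c(list(base_edges), hub_edges)) %>%
    distinct(protein_a, protein_b) %>%
    arrange(protein_a, protein_b)
  edge_key <- pair_keys(true_interactome)
  n_edges <- nrow(true_interactome)
  deg_tab <- table(c(true_interactome$protein_a, true_interactome$protein_b))
  degree_of <- setNames(rep(0, length(proteins)), proteins)
  degree_of[names(deg_tab)] <- as.numeric(deg_tab)

  ## --- localization / CC annotation (stream 2) ---
  set.seed(sub_seed(config$seed, 2))
  loc <- sample(
    names(config$localization_probs),
    config$n_proteins,
    replace = TRUE,
    prob = config$localization_probs
  )
  cc_term <- list(
    membrane = "plasma_membrane", nucleus = "nucleus",
    cytoplasm = "cytoplasm", secreted = "extracellular",
    # dual-localized proteins carry both compartment annotations
    multiple = c("plasma_membrane", "nucleus")
  )
  cc_annotation <- tibble(
    protein_id = rep(proteins, lengths(cc_term[loc])),
    aspect = "CC",
    term_id = unlist(cc_term[loc], use.names = FALSE)
  )

  ## --- expression with per-edge latent factors and DE shift ---
  set.seed(sub_seed(config$seed, 7)) # DE gene selection (stream 7)
  n_de <- round(config$de_fraction * config$n_proteins)
  de_pool <- setdiff(proteins, hubs)
  de_genes <- sort(c(
    hubs,
    sample(de_pool, max(0, min(n_de - length(hubs), length(de_pool))))
  ))

  set.seed(sub_seed(config$seed, 3)) # expression noise + latents (stream 3)
  n_samples <- 2L * config$n_samples_per_condition
  w <- config$coexpr_effect
  eps <- matrix(rnorm(config$n_proteins * n_samples),
    nrow = config$n_proteins
  )
  rownames(eps) <- proteins
  x <- sqrt(1 - w^2) * eps
  if (w > 0 && n_edges > 0) {
    z <- matrix(rnorm(n_edges * n_samples), nrow = n_edges)
    latent_sum <- rowsum(
      rbind(z, z),
      group = c(true_interactome$protein_a, true_interactome$protein_b)
    )
    scale_by <- sqrt(pmax(degree_of[rownames(latent_sum)], 1))
    x[rownames(latent_sum), ] <- x[rownames(latent_sum), ] +
      w * latent_sum / scale_by
  }
  cond2_cols <- config$n_samples_per_condition + seq_len(
    config$n_samples_per_condition
  )
  x[de_genes, cond2_cols] <- x[de_genes, cond2_cols] + config$de_effect
  colnames(x) <- c(
    sprintf("cond1_%d", seq_len(config$n_samples_per_condition)),
    sprintf("cond2_%d", seq_len(config$n_samples_per_condition))
  )
  expression <- as_tibble(x) %>% mutate(gene_id = proteins, .before = 1)

  ## --- domains and DDI table (stream 4) ---
  set.seed(sub_seed(config$seed, 4))
  n_dom <- sample(1:3, config$n_proteins, replace = TRUE)
  domains <- tibble(
    protein_id = rep(proteins, n_dom),
    domain_id = sprintf("DM%05d", seq_len(sum(n_dom)))
  )
  dom_of <- split(domains$domain_id, domains$protein_id)
  pick_domain <- function(ps) {
    unname(vapply(
      dom_of[ps], function(d) d[[sample.int(length(d), 1)]], character(1)
    ))
  }
  # the confidence grade reflects curation quality of the entry, not edge
  # status: with ddi_tpr == ddi_fpr the channel is fully uninformative
  true_hit <- runif(n_edges) < config$ddi_tpr
  ddi_true <- tibble(
    domain_a = pick_domain(true_interactome$protein_a[true_hit]),
    domain_b = pick_domain(true_interactome$protein_b[true_hit]),
    confidence_level = sample(1:4, sum(true_hit), replace = TRUE)
  )
  n_nonedge <- choose(config$n_proteins, 2) - n_edges
  k_false <- rbinom(1, n_nonedge, config$ddi_fpr)
  false_pairs <- sample_nonedge_pairs(proteins, edge_key, k_false)
  ddi_false <- tibble(
    domain_a = pick_domain(false_pairs$protein_a),
    domain_b = pick_domain(false_pairs$protein_b),
    confidence_level = sample(1:4, nrow(false_pairs), replace = TRUE)
  )
  ddi <- bind_rows(ddi_true, ddi_false)
  ddi <- tibble(
    domain_a = pmin(ddi$domain_a, ddi$domain_b),
    domain_b = pmax(ddi$domain_a, ddi$domain_b),
    confidence_level = ddi$confidence_level
  ) %>%
    distinct(domain_a, domain_b, .keep_all = TRUE) %>%
    arrange(domain_a, domain_b)

  ## --- orthologs and model-organism interactions (stream 5) ---
  set.seed(sub_seed(config$seed, 5))
  species_names <- model_species_names(config$n_species)
  ortho_list <- list()
  model_list <- list()
  for (s in species_names) {
    mapped <- proteins[runif(config$n_proteins) < config$ortholog_coverage]
    model_id <- setNames(
      paste0(substr(s, 1, 3), "_", mapped),
      mapped
    )
    ortho_list[[s]] <- tibble(
      species = s,
      model_protein_id = unname(model_id),
      human_protein_id = mapped,
      group_id = paste0("OG_", mapped)
    )
    both_mapped <- true_interactome$protein_a %in% mapped &
      true_interactome$protein_b %in% mapped
    supported <- both_mapped & runif(n_edges) < config$interolog_tpr_per_species
    true_rows <- tibble(
      protein_a = unname(model_id[true_interactome$protein_a[supported]]),
      protein_b = unname(model_id[true_interactome$protein_b[supported]]),
      source = s
    )
    n_map_nonedge <- max(
      0,
      choose(length(mapped), 2) - sum(both_mapped)
    )
    k_sp <- rbinom(1, n_map_nonedge, config$interolog_fpr_per_species)
    sp_false <- sample_nonedge_pairs(mapped, edge_key, k_sp)
    false_rows <- tibble(
      protein_a = unname(model_id[sp_false$protein_a]),
      protein_b = unname(model_id[sp_false$protein_b]),
      source = s
    )
    rows <- bind_rows(true_rows, false_rows)
    cleaned <- canonicalize_pairs(rows, dedupe = TRUE) %>%
      arrange(protein_a, protein_b)
    attr(cleaned, "n_self_dropped") <- NULL
    model_list[[s]] <- cleaned
  }
  orthologs <- bind_rows(ortho_list)
  model_interactions <- bind_rows(model_list)

  ## --- biological-process annotation (stream 6) ---
  set.seed(sub_seed(config$seed, 6))
  sizes <- sample(
    config$bp_term_size_range[[1]]:config$bp_term_size_range[[2]],
    config$n_bp_terms,
    replace = TRUE
  )
  bp_bg <- tibble(
    protein_id = unlist(lapply(sizes, function(k) sample(proteins, k))),
    aspect = "BP",
    term_id = rep(sprintf("BP%04d", seq_len(config$n_bp_terms)), sizes)
  )
  bp_apop <- tibble(
    protein_id = apoptotic_set,
    aspect = "BP",
    term_id = "apoptotic_process"
  )
  boosted <- which(runif(n_edges) < config$ssbp_coannotation_boost)
  bp_boost <- tibble(
    protein_id = c(
      true_interactome$protein_a[boosted],
      true_interactome$protein_b[boosted]
    ),
    aspect = "BP",
    term_id = rep(sprintf("BPpair%05d", seq_along(boosted)), 2)
  )
  bp_annotation <- bind_rows(bp_bg, bp_apop, bp_boost) %>%
    distinct(protein_id, aspect, term_id)

  ## --- curated interaction sources (stream 8) ---
  set.seed(sub_seed(config$seed, 8))
  src_list <- lapply(seq_len(config$n_sources), function(i) {
    keep <- runif(n_edges) < config$source_coverage
    true_interactome[keep, ] %>%
      mutate(source = sprintf("source_%02d", i))
  })
  interaction_sources <- bind_rows(src_list)

  annotation <- bind_rows(cc_annotation, bp_annotation) %>%
    arrange(aspect, protein_id, term_id)

  structure(
    list(
      config = config,
      proteins = proteins,
      true_interactome = true_interactome,
      apoptotic_set = apoptotic_set,
      planted_hubs = tibble(
        protein = hubs,
        hub_class = rep(
          c("classical", "novel"),
          c(length(classical), length(novel))
        )
      ),
      de_genes = de_genes,
      interaction_sources = interaction_sources,
      annotation = annotation,
      expression = expression,
      orthologs = orthologs,
      model_interactions = model_interactions,
      domains = domains,
      ddi = ddi
    ),
    class = "ppi_world"
  )
}

#' @export
print.ppi_world <- function(x, ...) {
  cat(
    "Synthetic interactome world:",
    length(x$proteins), "proteins,",
    nrow(x$true_interactome), "true edges,",
    length(x$apoptotic_set), "apoptotic proteins,",
    nrow(x$planted_hubs), "planted hubs\n"
  )
  invisible(x)
}

#' Write a world's input bundle to disk
#'
#' Emits every input table the analysis pipeline consumes (curated
#' interaction sources, combined CC/BP annotation, expression matrix,
#' ortholog table, per-species model-organism interaction lists, domain
#' assignments and the DDI table) plus a ground-truth sidecar that only the
#' test suite reads. All files are TSV with a `#`-prefixed header.
#'
#' @param world A `ppi_world` from [simulate_world()].
#' @param directory Output directory (created if absent).
#' @return A tibble manifest (`name`, `path`, `n_rows`), invisibly ordered
#'   by file name.
#' @export
emit_inputs <- function(world, directory) {
  stopifnot(inherits(world, "ppi_world"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory) || file.access(directory, mode = 2) != 0) {
    stop("cannot write to directory: ", directory, call. = FALSE)
  }
  manifest <- list()
  emit <- function(name, table) {
    path <- file.path(directory, paste0(name, ".tsv"))
    write_ppi_table(table, path)
    manifest[[name]] <<- tibble(
      name = name, path = path, n_rows = nrow(table)
    )
  }
  for (src in unique(world$interaction_sources$source)) {
    emit(
      paste0("interactions_", src),
      filter(world$interaction_sources, source == src)
    )
  }
  emit("annotation", world$annotation)
  emit("expression", world$expression)
  emit("orthologs", world$orthologs)
  for (s in unique(world$model_interactions$source)) {
    emit(
      paste0("model_ppi_", s),
      filter(world$model_interactions, source == s)
    )
  }
  emit("domains", world$domains)
  emit("ddi", world$ddi)
  emit("ground_truth_edges", world$true_interactome)
  emit("ground_truth_proteins", tibble(
    protein_id = world$proteins,
    apoptotic = as.integer(world$proteins %in% world$apoptotic_set),
    planted_hub_class = {
      cls <- setNames(
        world$planted_hubs$hub_class, world$planted_hubs$protein
      )
      out <- rep("none", length(world$proteins))
      out[match(names(cls), world$proteins)] <- cls
      out
    },
    de_gene = as.integer(world$proteins %in% world$de_genes)
  ))
  out <- bind_rows(manifest) %>% arrange(name)
  invisible(out)
}
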