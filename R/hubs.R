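#' Hub-calling criteria
#'
#' The four golden standards for apoptotic hub proteins: (1) degree at
#' least `min_degree`; (2) links to known apoptotic proteins at least
#' `min_apoptotic_links_classical` for proteins inside the apoptotic
#' annotation set, or `min_apoptotic_links_novel` for proteins outside it;
#' (3) membership in the dense area of the network, operationalized as
#' k-core index at least `k_core_min`; (4) divergent expression by SAM.
#' The defaults (300 / 300 / 200) are the operating thresholds used on the
#' full 13,128-protein interactome; with `scale_thresholds = TRUE` the
#' count thresholds are scaled by `|nodes| / reference_n` so that hubs can
#' exist in smaller networks.
#'
#' @param min_degree Minimum degree.
#' @param min_apoptotic_links_classical,min_apoptotic_links_novel Minimum
#'   apoptotic-neighbor counts for the two hub classes (novel must not
#'   exceed classical).
#' @param k_core_min Minimum core index, or `"auto"` (75th percentile of
#'   the network's core indices).
#' @param sam_fdr Target FDR for the SAM criterion.
#' @param sam_permutations Label permutations for SAM.
#' @param seed Seed for the SAM permutation stream.
#' @param scale_thresholds Scale the count thresholds to the network size.
#' @param reference_n Node count of the reference interactome the default
#'   thresholds refer to.
#' @param enabled Named logical vector switching individual criteria on or
#'   off (`degree`, `links`, `core`, `sam`).
#' @return A `ppi_hub_criteria` list.
#' @export
hub_criteria <- function(min_degree = 300,
                         min_apoptotic_links_classical = 300,
                         min_apoptotic_links_novel = 200,
                         k_core_min = "auto",
                         sam_fdr = 0.1,
                         sam_permutations = 100,
                         seed = 1,
                         scale_thresholds = TRUE,
                         reference_n = 13128,
                         enabled = c(
                           degree = TRUE, links = TRUE,
                           core = TRUE, sam = TRUE
                         )) {
  if (min_degree < 1 || min_apoptotic_links_classical < 1 ||
    min_apoptotic_links_novel < 1) {
    stop("hub thresholds must be positive counts", call. = FALSE)
  }
  if (min_apoptotic_links_novel > min_apoptotic_links_classical) {
    stop("`min_apoptotic_links_novel` must not exceed ",
      "`min_apoptotic_links_classical`",
      call. = FALSE
    )
  }
  if (!identical(k_core_min, "auto") &&
    (!is.numeric(k_core_min) || k_core_min < 1)) {
    stop("`k_core_min` must be 'auto' or a positive count", call. = FALSE)
  }
  stopifnot(
    setequal(names(enabled), c("degree", "links", "core", "sam")),
    is.logical(enabled)
  )
  structure(
    list(
      min_degree = min_degree,
      min_apoptotic_links_classical = min_apoptotic_links_classical,
      min_apoptotic_links_novel = min_apoptotic_links_novel,
      k_core_min = k_core_min,
      sam_fdr = sam_fdr,
      sam_permutations = sam_permutations,
      seed = seed,
      scale_thresholds = scale_thresholds,
      reference_n = reference_n,
      enabled = enabled[c("degree", "links", "core", "sam")]
    ),
    class = "ppi_hub_criteria"
  )
}

network_graph <- function(network) {
  igraph::graph_from_data_frame(
    as_tibble(network)[c("protein_a", "protein_b")],
    directed = FALSE
  )
}

#' Degree and apoptotic-link counts per protein
#'
#' @param network A `ppi_network` (or any canonical edge list).
#' @param apoptotic_set Character vector of apoptotic protein ids.
#' @return Tibble: `protein`, `degree`, `apoptotic_links` for every node
#'   of the network.
#' @export
degree_and_links <- function(network, apoptotic_set) {
  edges <- as_tibble(network)[c("protein_a", "protein_b")]
  if (nrow(edges) == 0) {
    stop("network is empty", call. = FALSE)
  }
  ends <- c(edges$protein_a, edges$protein_b)
  other <- c(edges$protein_b, edges$protein_a)
  tibble(protein = ends, neighbor = other) %>%
    group_by(protein) %>%
    summarise(
      degree = dplyr::n(),
      apoptotic_links = sum(.data$neighbor %in% apoptotic_set),
      .groups = "drop"
    ) %>%
    arrange(protein)
}

#' Dense-area filter by k-core index
#'
#' A protein's core index is the largest `k` such that it survives
#' iterative removal of all nodes of degree below `k`. Hub proteins enrich
#' in the dense area of the interactome, so the filter passes proteins
#' whose core index meets `k_core_min`; in auto mode the threshold is the
#' 75th percentile of the network's core indices.
#'
#' @param network A `ppi_network` (or canonical edge list).
#' @param k_core_min Minimum core index or `"auto"`.
#' @return Tibble `protein`, `core_index`, `core_pass`; the threshold used
#'   is attached as attribute `k_core_min`.
#' @export
dense_area_filter <- function(network, k_core_min = "auto") {
  g <- network_graph(network)
  if (igraph::vcount(g) == 0) {
    stop("network is empty", call. = FALSE)
  }
  core <- igraph::coreness(g)
  threshold <- if (identical(k_core_min, "auto")) {
    as.numeric(stats::quantile(core, 0.75))
  } else {
    k_core_min
  }
  out <- tibble(
    protein = names(core),
    core_index = as.integer(core),
    core_pass = core >= threshold
  ) %>% arrange(protein)
  attr(out, "k_core_min") <- threshold
  out
}

#' Identify apoptotic hub proteins by the four golden standards
#'
#' A protein is a hub iff it passes every enabled criterion: degree,
#' apoptotic links (with the class-specific threshold), dense-area (k-core)
#' and SAM differential expression. Hubs inside the apoptotic annotation
#' set are classical; hubs outside it are novel (proteins of unexpectedly
#' high apoptotic connectivity that are not themselves annotated
#' apoptotic). Proteins absent from the expression matrix cannot be
#' evaluated by SAM and fail that criterion unless it is disabled.
#'
#' @param network A `ppi_network`.
#' @param apoptotic_set Character vector of apoptotic protein ids.
#' @param expr Expression table or matrix (two conditions).
#' @param criteria A [hub_criteria()].
#' @return A `ppi_hub_report` tibble: `protein`, `degree`,
#'   `apoptotic_links`, `core_index`, `sam_significant`,
#'   `in_apoptotic_set`, per-criterion `pass_*` flags and `hub_class`
#'   (`classical` / `novel` / `none`). Attributes: `criteria` (the input),
#'   `thresholds` (the possibly scaled values applied), `sam` (the fitted
#'   `ppi_sam`, when the criterion ran).
#' @export
identify_hubs <- function(network, apoptotic_set, expr,
                          criteria = hub_criteria()) {
  stopifnot(inherits(criteria, "ppi_hub_criteria"))
  conn <- degree_and_links(network, apoptotic_set)
  cores <- dense_area_filter(network, criteria$k_core_min)
  n_nodes <- nrow(conn)

  scale <- if (isTRUE(criteria$scale_thresholds)) {
    n_nodes / criteria$reference_n
  } else {
    1
  }
  thr <- list(
    degree = max(1, ceiling(criteria$min_degree * scale)),
    links_classical = max(
      1, ceiling(criteria$min_apoptotic_links_classical * scale)
    ),
    links_novel = max(
      1, ceiling(criteria$min_apoptotic_links_novel * scale)
    ),
    k_core_min = attr(cores, "k_core_min")
  )

  sam <- NULL
  sam_flags <- rep(NA, n_nodes)
  if (criteria$enabled[["sam"]]) {
    sam <- sam_de(
      expr,
      fdr = criteria$sam_fdr,
      n_permutations = criteria$sam_permutations,
      seed = criteria$seed
    )
    sig <- sam$genes$gene_id[sam$genes$significant]
    measured <- conn$protein %in% sam$genes$gene_id
    sam_flags <- ifelse(measured, conn$protein %in% sig, NA)
  }

  report <- conn %>%
    left_join(select(cores, protein, core_index), by = "protein") %>%
    mutate(
      in_apoptotic_set = protein %in% apoptotic_set,
      sam_significant = sam_flags,
      link_threshold = if_else(
        in_apoptotic_set, thr$links_classical, thr$links_novel
      ),
      pass_degree = !criteria$enabled[["degree"]] | degree >= thr$degree,
      pass_links = !criteria$enabled[["links"]] |
        apoptotic_links >= link_threshold,
      pass_core = !criteria$enabled[["core"]] |
        core_index >= thr$k_core_min,
      pass_sam = !criteria$enabled[["sam"]] |
        (!is.na(sam_significant) & sam_significant),
      hub_class = dplyr::case_when(
        pass_degree & pass_links & pass_core & pass_sam &
          in_apoptotic_set ~ "classical",
        pass_degree & pass_links & pass_core & pass_sam ~ "novel",
        TRUE ~ "none"
      )
    )
  structure(
    report,
    class = c("ppi_hub_report", class(report)),
    criteria = criteria,
    thresholds = thr,
    sam = sam
  )
}

#' @export
print.ppi_hub_report <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat(
    "Hub report:", nrow(x), "proteins;",
    sum(x$hub_class == "classical"), "classical and",
    sum(x$hub_class == "novel"), "novel hubs\n",
    "applied thresholds: degree >=", thr$degree,
    ", apoptotic links >=", thr$links_classical, "(classical) /",
    thr$links_novel, "(novel), core index >=", thr$k_core_min, "\n"
  )
  invisible(x)
}
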