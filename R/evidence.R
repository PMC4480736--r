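#' Pearson correlation of two expression profiles
#'
#' The co-expression evidence is the Pearson correlation coefficient
#' `rho = sum((x_i - xbar)(y_i - ybar)) / ((n - 1) s_x s_y)` with `s` the
#' sample standard deviation, i.e. the standard product-moment estimator.
#' A zero-variance profile has no defined correlation and is signalled as
#' `NA`, which upstream scorers treat as missing evidence.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return A single correlation in `[-1, 1]`, or `NA` for zero variance.
#' @examples
#' pearson_correlation(c(1, 2, 3), c(1, 2, 4))
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (length(x) < 3) {
    stop("at least 3 paired samples are required", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("expression profiles must not contain missing values", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(NA_real_)
  }
  cor(x, y)
}

#' Score co-expression evidence for protein pairs
#'
#' Computes the Pearson correlation over all samples pooled (both
#' conditions together) for every requested pair. Pairs with a gene absent
#' from the matrix, or with a zero-variance profile, are recorded as
#' missing.
#'
#' @param pairs Canonical pair data frame (`protein_a`, `protein_b`).
#' @param expr Expression table (`gene_id` + sample columns) or matrix with
#'   gene row names.
#' @return The pair tibble with a `coexpr_rho` column (`NA` = missing).
#' @export
score_coexpression <- function(pairs, expr) {
  m <- if (is.matrix(expr)) expr else expression_matrix(expr)
  pairs <- as_tibble(pairs[c("protein_a", "protein_b")])
  present <- pairs$protein_a %in% rownames(m) &
    pairs$protein_b %in% rownames(m)
  rho <- rep(NA_real_, nrow(pairs))
  if (any(present)) {
    used <- unique(c(
      pairs$protein_a[present], pairs$protein_b[present]
    ))
    sub <- m[used, , drop = FALSE]
    keep <- apply(sub, 1, sd) > 0
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) > 0) {
      cmat <- suppressWarnings(cor(t(sub)))
      ia <- match(pairs$protein_a, rownames(sub))
      ib <- match(pairs$protein_b, rownames(sub))
      ok <- !is.na(ia) & !is.na(ib)
      rho[ok] <- cmat[cbind(ia[ok], ib[ok])]
    }
  }
  mutate(pairs, coexpr_rho = rho)
}

#' Score domain-domain interaction evidence
#'
#' For each pair, the maximum confidence level over all cross-products of
#' the two proteins' domain sets that have an entry in the DDI table.
#' Missing when either protein has no domain annotation; explicit level 0
#' when both have domains but no domain pair matches (the informative
#' absence of curated domain support).
#'
#' @param pairs Canonical pair data frame.
#' @param domains Protein-to-domain table (`protein_id`, `domain_id`).
#' @param ddi DDI table (`domain_a`, `domain_b`, `confidence_level`);
#'   domain pairs are matched symmetrically.
#' @return The pair tibble with a `ddi_level` column.
#' @export
score_ddi <- function(pairs, domains, ddi) {
  pairs <- as_tibble(pairs[c("protein_a", "protein_b")])
  # both orientations of each DDI entry so either protein can match either
  ddi_sym <- bind_rows(
    select(ddi, domain_a, domain_b, confidence_level),
    tibble(
      domain_a = ddi$domain_b, domain_b = ddi$domain_a,
      confidence_level = ddi$confidence_level
    )
  ) %>% distinct()
  hits <- ddi_sym %>%
    inner_join(domains, by = c(domain_a = "domain_id"),
      relationship = "many-to-many"
    ) %>%
    rename(pa = protein_id) %>%
    inner_join(domains, by = c(domain_b = "domain_id"),
      relationship = "many-to-many"
    ) %>%
    rename(pb = protein_id) %>%
    filter(.data$pa != .data$pb)
  if (nrow(hits) > 0) {
    hit_pairs <- canonical_pairs(hits$pa, hits$pb) %>%
      mutate(confidence_level = hits$confidence_level) %>%
      group_by(protein_a, protein_b) %>%
      summarise(ddi_level = max(confidence_level), .groups = "drop")
  } else {
    hit_pairs <- tibble(
      protein_a = character(), protein_b = character(),
      ddi_level = integer()
    )
  }
  has_domain <- unique(domains$protein_id)
  out <- left_join(pairs, hit_pairs, by = c("protein_a", "protein_b"))
  measurable <- out$protein_a %in% has_domain & out$protein_b %in% has_domain
  out$ddi_level[measurable & is.na(out$ddi_level)] <- 0L
  out$ddi_level[!measurable] <- NA_integer_
  out
}

#' Score cross-species interolog evidence
#'
#' A pair's support is the number of distinct model organisms in which at
#' least one interacting model-protein pair maps (via the ortholog table,
#' many-to-many allowed) onto the two human proteins. Support 0 means the
#' pair is mappable but unsupported; the value is missing only when neither
#' protein has an ortholog in any species.
#'
#' @param pairs Canonical pair data frame.
#' @param orthologs Ortholog table (`species`, `model_protein_id`,
#'   `human_protein_id`, `group_id`).
#' @param model_interactions Model-organism edge list (`protein_a`,
#'   `protein_b` in model identifiers, `source` = species).
#' @return The pair tibble with an `interolog_support` column.
#' @export
score_interolog <- function(pairs, orthologs, model_interactions) {
  pairs <- as_tibble(pairs[c("protein_a", "protein_b")])
  mapped <- model_interactions %>%
    inner_join(
      select(orthologs, species, model_protein_id, human_protein_id),
      by = c(protein_a = "model_protein_id", source = "species"),
      relationship = "many-to-many"
    ) %>%
    rename(ha = human_protein_id) %>%
    inner_join(
      select(orthologs, species, model_protein_id, human_protein_id),
      by = c(protein_b = "model_protein_id", source = "species"),
      relationship = "many-to-many"
    ) %>%
    rename(hb = human_protein_id) %>%
    filter(.data$ha != .data$hb)
  if (nrow(mapped) > 0) {
    support <- canonical_pairs(mapped$ha, mapped$hb) %>%
      mutate(species = mapped$source) %>%
      distinct(protein_a, protein_b, species) %>%
      count(protein_a, protein_b, name = "interolog_support")
  } else {
    support <- tibble(
      protein_a = character(), protein_b = character(),
      interolog_support = integer()
    )
  }
  has_ortholog <- unique(orthologs$human_protein_id)
  out <- left_join(pairs, support, by = c("protein_a", "protein_b"))
  mappable <- out$protein_a %in% has_ortholog |
    out$protein_b %in% has_ortholog
  out$interolog_support[mappable & is.na(out$interolog_support)] <- 0L
  out$interolog_support[!mappable] <- NA_integer_
  out
}

#' Score smallest-shared-biological-process evidence
#'
#' For each pair: over all biological-process terms annotating both
#' proteins, the minimum of the term's total assigned-protein count. Small,
#' specific shared processes are stronger evidence of functional linkage
#' than large, general ones. Pairs that are both annotated but share no
#' term receive the `Inf` sentinel ("no shared term"); pairs where either
#' protein has no BP annotation at all are missing.
#'
#' @param pairs Canonical pair data frame.
#' @param bp_annotation Annotation table (`protein_id`, `aspect`,
#'   `term_id`); only `BP` rows are used.
#' @return The pair tibble with an `ssbp_size` column (`Inf` = no shared
#'   term, `NA` = missing).
#' @export
score_ssbp <- function(pairs, bp_annotation) {
  pairs <- as_tibble(pairs[c("protein_a", "protein_b")])
  bp <- bp_annotation %>%
    filter(aspect == "BP") %>%
    distinct(protein_id, term_id)
  term_sizes <- count(bp, term_id, name = "size")
  shared <- bp %>%
    inner_join(bp, by = "term_id", relationship = "many-to-many") %>%
    filter(.data$protein_id.x < .data$protein_id.y) %>%
    inner_join(term_sizes, by = "term_id") %>%
    group_by(
      protein_a = .data$protein_id.x,
      protein_b = .data$protein_id.y
    ) %>%
    summarise(ssbp_size = min(size), .groups = "drop")
  annotated <- unique(bp$protein_id)
  out <- left_join(pairs, shared, by = c("protein_a", "protein_b"))
  measurable <- out$protein_a %in% annotated & out$protein_b %in% annotated
  out$ssbp_size[measurable & is.na(out$ssbp_size)] <- Inf
  out$ssbp_size[!measurable] <- NA_real_
  mutate(out, ssbp_size = as.numeric(.data$ssbp_size))
}

#' Compute all four evidence values for a pair universe
#'
#' Convenience wrapper running the four scorers and joining their outputs
#' into one evidence table.
#'
#' @param pairs Canonical pair data frame.
#' @param expr Expression table or matrix.
#' @param domains,ddi Domain assignment and DDI tables.
#' @param orthologs,model_interactions Ortholog table and model-organism
#'   edge list.
#' @param bp_annotation Annotation table (BP rows used).
#' @return Tibble with pair columns plus `coexpr_rho`, `ddi_level`,
#'   `interolog_support`, `ssbp_size`.
#' @export
evidence_table <- function(pairs, expr, domains, ddi, orthologs,
                           model_interactions, bp_annotation) {
  pairs <- as_tibble(pairs[c("protein_a", "protein_b")])
  score_coexpression(pairs, expr) %>%
    left_join(
      score_ddi(pairs, domains, ddi),
      by = c("protein_a", "protein_b")
    ) %>%
    left_join(
      score_interolog(pairs, orthologs, model_interactions),
      by = c("protein_a", "protein_b")
    ) %>%
    left_join(
      score_ssbp(pairs, bp_annotation),
      by = c("protein_a", "protein_b")
    )
}
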