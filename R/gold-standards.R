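#' Build the Gold Standard Positive set
#'
#' Unions curated interaction records from several source tables into a
#' single canonical, deduplicated positive pair set. Records are symmetric
#' (`(A,B)` equals `(B,A)`), self-pairs are dropped, and per-source totals
#' are reported so multi-source overlap is auditable.
#'
#' @param sources A list of interaction data frames (columns `protein_a`,
#'   `protein_b`, optionally `source`), or a single data frame with a
#'   `source` column.
#' @return A tibble of canonical pairs (class `ppi_gsp`) with attributes
#'   `per_source_counts` (tibble) and `n_self_dropped`.
#' @export
build_gsp <- function(sources) {
  if (is.data.frame(sources)) {
    sources <- if ("source" %in% names(sources)) {
      split(sources, sources$source)
    } else {
      list(sources)
    }
  }
  if (length(sources) == 0) {
    stop("no interaction sources supplied", call. = FALSE)
  }
  names(sources) <- names(sources) %||%
    sprintf("source_%02d", seq_along(sources))
  cleaned <- lapply(sources, function(tab) {
    stopifnot(all(c("protein_a", "protein_b") %in% names(tab)))
    if (any(is.na(tab$protein_a) | is.na(tab$protein_b) |
      tab$protein_a == "" | tab$protein_b == "")) {
      stop("interaction records must have two non-empty ids", call. = FALSE)
    }
    canonicalize_pairs(
      tab[c("protein_a", "protein_b")],
      drop_self = TRUE, dedupe = TRUE
    )
  })
  per_source <- tibble(
    source = names(cleaned),
    n_records = vapply(sources, nrow, integer(1)),
    n_unique = vapply(cleaned, nrow, integer(1))
  )
  gsp <- bind_rows(cleaned) %>%
    distinct(protein_a, protein_b) %>%
    arrange(protein_a, protein_b)
  if (nrow(gsp) == 0) {
    warning("empty gold-standard positive set: likelihood-ratio ",
      "estimation downstream is impossible",
      call. = FALSE
    )
  }
  structure(
    gsp,
    class = c("ppi_gsp", class(gsp)),
    per_source_counts = per_source,
    n_self_dropped = sum(
      vapply(cleaned, function(x) attr(x, "n_self_dropped"), integer(1))
    )
  )
}

#' Build the Gold Standard Negative set
#'
#' Negative pairs are all canonical combinations of a plasma-membrane
#' protein with a nuclear protein, on the rationale that non-co-localized
#' proteins cannot physically interact. Proteins annotated to both
#' compartments violate that rationale and are excluded from both sides.
#' Pairs already present in the positive set are removed and counted.
#'
#' @param cc_annotation Annotation data frame (`protein_id`, `aspect`,
#'   `term_id`); only `CC` rows are used.
#' @param gsp Gold-standard positive pairs (canonical edge list).
#' @param membrane_term,nucleus_term Term identifiers of the two
#'   compartments.
#' @return A tibble of canonical negative pairs (class `ppi_gsn`) with
#'   attributes `overlap_removed`, `n_membrane_only`, `n_nucleus_only`.
#' @export
build_gsn <- function(cc_annotation, gsp,
                      membrane_term = "plasma_membrane",
                      nucleus_term = "nucleus") {
  cc <- filter(cc_annotation, aspect == "CC")
  membrane <- unique(cc$protein_id[cc$term_id == membrane_term])
  nucleus <- unique(cc$protein_id[cc$term_id == nucleus_term])
  dual <- intersect(membrane, nucleus)
  membrane <- sort(setdiff(membrane, dual))
  nucleus <- sort(setdiff(nucleus, dual))
  if (length(membrane) == 0 || length(nucleus) == 0) {
    warning("no single-compartment membrane or nucleus proteins: ",
      "gold-standard negative set is empty",
      call. = FALSE
    )
    raw <- tibble(protein_a = character(), protein_b = character())
  } else {
    grid <- expand.grid(
      m = membrane, n = nucleus,
      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
    )
    raw <- canonical_pairs(grid$m, grid$n) %>%
      distinct(protein_a, protein_b)
  }
  in_gsp <- pair_keys(raw) %in% pair_keys(gsp)
  gsn <- raw[!in_gsp, ] %>% arrange(protein_a, protein_b)
  structure(
    gsn,
    class = c("ppi_gsn", class(gsn)),
    overlap_removed = sum(in_gsp),
    n_membrane_only = length(membrane),
    n_nucleus_only = length(nucleus)
  )
}

#' Assemble both gold-standard sets
#'
#' Convenience wrapper returning the positive set, the negative set and the
#' bookkeeping counts in one object.
#'
#' @inheritParams build_gsp
#' @inheritParams build_gsn
#' @return A list (class `ppi_gold_standards`) with elements `gsp`, `gsn`,
#'   `overlap_removed`.
#' @export
build_gold_standards <- function(sources, cc_annotation,
                                 membrane_term = "plasma_membrane",
                                 nucleus_term = "nucleus") {
  gsp <- build_gsp(sources)
  gsn <- build_gsn(cc_annotation, gsp, membrane_term, nucleus_term)
  structure(
    list(
      gsp = gsp,
      gsn = gsn,
      overlap_removed = attr(gsn, "overlap_removed")
    ),
    class = "ppi_gold_standards"
  )
}

#' @export
print.ppi_gold_standards <- function(x, ...) {
  cat(
    "Gold standards:", nrow(x$gsp), "positive pairs,",
    nrow(x$gsn), "negative pairs (", x$overlap_removed,
    "overlapping pairs removed from the negatives)\n"
  )
  invisible(x)
}
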