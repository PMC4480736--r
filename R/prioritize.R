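#' Extract the core hub subnetwork
#'
#' The induced subgraph of the predicted network on all proteins called
#' hubs (classical or novel): an edge survives iff both endpoints are
#' hubs. Per-node counts of links to other hubs are recorded; they drive
#' the dual-target ranking.
#'
#' @param network A `ppi_network` (or canonical edge list).
#' @param hub_report A `ppi_hub_report` computed on the same network.
#' @return A `ppi_subnetwork` tibble of induced edges, with attributes
#'   `hubs` (node ids) and `hub_links` (tibble `protein`, `hub_links`,
#'   including isolated hubs with zero links).
#' @export
extract_core_subnetwork <- function(network, hub_report) {
  hubs <- hub_report$protein[hub_report$hub_class != "none"]
  if (length(hubs) == 0) {
    warning("no hubs were called: core subnetwork is empty", call. = FALSE)
  }
  edges <- as_tibble(network) %>%
    filter(protein_a %in% hubs & protein_b %in% hubs)
  counts <- tibble(
    protein = c(edges$protein_a, edges$protein_b)
  ) %>%
    count(protein, name = "hub_links")
  hub_links <- tibble(protein = sort(hubs)) %>%
    left_join(counts, by = "protein") %>%
    mutate(hub_links = dplyr::coalesce(hub_links, 0L))
  structure(
    edges,
    class = c("ppi_subnetwork", class(edges)),
    hubs = sort(hubs),
    hub_links = hub_links
  )
}

#' Rank proteins by links to other hub proteins
#'
#' Descending by hub-link count; ties are broken lexicographically by
#' identifier and flagged, so a downstream reader can see that the order
#' within a tie group is arbitrary.
#'
#' @param subnetwork A `ppi_subnetwork`.
#' @param proteins Optional subset of proteins to rank (default: all hubs
#'   in the subnetwork).
#' @return Tibble: `protein`, `hub_links`, `rank_links`, `tied`.
#' @export
rank_by_hub_links <- function(subnetwork, proteins = NULL) {
  hub_links <- attr(subnetwork, "hub_links")
  if (is.null(hub_links) || nrow(hub_links) == 0) {
    stop("subnetwork has no hubs to rank", call. = FALSE)
  }
  if (!is.null(proteins)) {
    hub_links <- filter(hub_links, protein %in% proteins)
  }
  hub_links %>%
    arrange(desc(hub_links), protein) %>%
    mutate(
      rank_links = row_number(),
      tied = duplicated(hub_links) | duplicated(hub_links, fromLast = TRUE)
    )
}

#' Overlap statistics for a dual-target pair
#'
#' Set arithmetic over the hub interactors of two candidate targets: the
#' two targets are first excluded from each other's interactor sets
#' (links to *other* hub proteins), then the intersection and union counts
#' and the derived fractions are computed exactly.
#'
#' @param interactors_a,interactors_b Character vectors of hub interactors
#'   of the two targets (subsets of `hub_universe`).
#' @param hub_universe Character vector of all hub proteins.
#' @param target_a,target_b Identifiers of the two targets.
#' @return One-row tibble: `target_a`, `target_b`, `n_a`, `n_b`,
#'   `n_common`, `n_union`, `frac_common_of_union` (shared interactors
#'   over all interactors of either target), `frac_union_of_hubs` (their
#'   joint reach over the remaining hub universe).
#' @export
overlap_stats <- function(interactors_a, interactors_b, hub_universe,
                          target_a = NA_character_,
                          target_b = NA_character_) {
  if (length(hub_universe) == 0) {
    stop("hub universe is empty", call. = FALSE)
  }
  a <- setdiff(unique(interactors_a), c(target_a, target_b))
  b <- setdiff(unique(interactors_b), c(target_a, target_b))
  extra <- setdiff(c(a, b), hub_universe)
  if (length(extra) > 0) {
    stop("interactors outside the hub universe: ",
      paste(head(extra, 3), collapse = ", "),
      call. = FALSE
    )
  }
  common <- intersect(a, b)
  uni <- union(a, b)
  universe_other <- setdiff(hub_universe, c(target_a, target_b))
  tibble(
    target_a = target_a, target_b = target_b,
    n_a = length(a), n_b = length(b),
    n_common = length(common), n_union = length(uni),
    frac_common_of_union = if (length(uni) == 0) {
      0
    } else {
      length(common) / length(uni)
    },
    frac_union_of_hubs = if (length(universe_other) == 0) {
      0
    } else {
      length(uni) / length(universe_other)
    }
  )
}

#' Enumerate and score dual-target candidate pairs
#'
#' Generalizes the dual-kinase analysis: take the top `top_k` novel hubs
#' by links to other hub proteins, form all pairs among them, and report
#' [overlap_stats()] for each, ordered by the number of common hub
#' interactors (then union size, then identifiers).
#'
#' @param subnetwork A `ppi_subnetwork`.
#' @param hub_report The `ppi_hub_report` behind it.
#' @param top_k Number of top-ranked novel hubs to pair (default 5).
#' @return Tibble of overlap statistics, one row per candidate pair,
#'   best-supported pair first; the novel-hub ranking is attached as
#'   attribute `ranking`.
#' @export
dual_target_candidates <- function(subnetwork, hub_report, top_k = 5) {
  novel <- hub_report$protein[hub_report$hub_class == "novel"]
  if (length(novel) < 2) {
    warning("fewer than two novel hubs: no dual-target candidates",
      call. = FALSE
    )
    empty_ranking <- tibble(
      protein = character(), hub_links = integer(),
      rank_links = integer(), tied = logical()
    )
    ranking <- if (length(novel) > 0 &&
      nrow(attr(subnetwork, "hub_links") %||% tibble()) > 0) {
      rank_by_hub_links(subnetwork, novel)
    } else {
      empty_ranking
    }
    return(structure(tibble(), ranking = ranking))
  }
  ranking <- rank_by_hub_links(subnetwork, novel)
  top <- head(ranking$protein, top_k)
  hubs <- attr(subnetwork, "hubs")
  edges <- as_tibble(subnetwork)
  neighbors_of <- function(p) {
    unique(c(
      edges$protein_b[edges$protein_a == p],
      edges$protein_a[edges$protein_b == p]
    ))
  }
  idx <- combn(length(top), 2)
  stats <- purrr::map_dfr(seq_len(ncol(idx)), function(j) {
    a <- top[idx[1, j]]
    b <- top[idx[2, j]]
    overlap_stats(
      neighbors_of(a), neighbors_of(b), hubs,
      target_a = min(a, b), target_b = max(a, b)
    )
  }) %>%
    arrange(desc(n_common), desc(n_union), target_a, target_b)
  attr(stats, "ranking") <- ranking
  stats
}
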