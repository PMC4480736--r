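# Independent brute-force oracles. Deliberately naive (loops, string sets):
# they share no code with the package implementation they check.

okey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Set-union over sources, dropping self pairs, as a sorted key vector.
oracle_gsp_keys <- function(sources) {
  keys <- character(0)
  for (tab in sources) {
    for (i in seq_len(nrow(tab))) {
      a <- tab$protein_a[[i]]
      b <- tab$protein_b[[i]]
      if (a != b) keys <- c(keys, okey(a, b))
    }
  }
  sort(unique(keys))
}

# Membrane-only x nucleus-only cross product minus gsp, as sorted keys.
oracle_gsn_keys <- function(membrane, nucleus, gsp_keys) {
  dual <- intersect(membrane, nucleus)
  membrane <- setdiff(membrane, dual)
  nucleus <- setdiff(nucleus, dual)
  keys <- character(0)
  for (m in membrane) {
    for (n in nucleus) {
      keys <- c(keys, okey(m, n))
    }
  }
  sort(setdiff(unique(keys), gsp_keys))
}

# Pearson correlation by the printed formula with (n-1) sample SDs.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  num / ((n - 1) * sd(x) * sd(y))
}

# Max DDI confidence level over domain cross products; NA when either
# protein has no domains, 0 when domains exist but nothing matches.
oracle_ddi_level <- function(a, b, domains, ddi) {
  da <- domains$domain_id[domains$protein_id == a]
  db <- domains$domain_id[domains$protein_id == b]
  if (length(da) == 0 || length(db) == 0) {
    return(NA_integer_)
  }
  best <- 0L
  for (x in da) {
    for (y in db) {
      hit <- ddi$confidence_level[
        (ddi$domain_a == x & ddi$domain_b == y) |
          (ddi$domain_a == y & ddi$domain_b == x)
      ]
      if (length(hit) > 0) best <- max(best, hit)
    }
  }
  best
}

# Distinct species with an interacting ortholog pair mapping to (a, b).
oracle_interolog <- function(a, b, orthologs, model_int) {
  if (!a %in% orthologs$human_protein_id &&
    !b %in% orthologs$human_protein_id) {
    return(NA_integer_)
  }
  n_support <- 0L
  for (s in unique(orthologs$species)) {
    os <- orthologs[orthologs$species == s, ]
    ma <- os$model_protein_id[os$human_protein_id == a]
    mb <- os$model_protein_id[os$human_protein_id == b]
    mi <- model_int[model_int$source == s, ]
    found <- FALSE
    for (i in seq_len(nrow(mi))) {
      p <- mi$protein_a[[i]]
      q <- mi$protein_b[[i]]
      if ((p %in% ma && q %in% mb) || (p %in% mb && q %in% ma)) {
        found <- TRUE
        break
      }
    }
    if (found) n_support <- n_support + 1L
  }
  n_support
}

# Smallest shared BP term size; Inf when no shared term, NA when either
# protein is unannotated.
oracle_ssbp <- function(a, b, bp) {
  bp <- bp[bp$aspect == "BP", ]
  ta <- unique(bp$term_id[bp$protein_id == a])
  tb <- unique(bp$term_id[bp$protein_id == b])
  if (length(ta) == 0 || length(tb) == 0) {
    return(NA_real_)
  }
  shared <- intersect(ta, tb)
  if (length(shared) == 0) {
    return(Inf)
  }
  min(vapply(
    shared,
    function(t) length(unique(bp$protein_id[bp$term_id == t])),
    numeric(1)
  ))
}

# Smoothed per-bin likelihood ratios from raw bin label vectors.
oracle_lr <- function(pos_bins, neg_bins, labels, pseudocount) {
  p_pos <- numeric(length(labels))
  p_neg <- numeric(length(labels))
  for (i in seq_along(labels)) {
    p_pos[[i]] <- (sum(pos_bins == labels[[i]]) + pseudocount) /
      (length(pos_bins) + length(labels) * pseudocount)
    p_neg[[i]] <- (sum(neg_bins == labels[[i]]) + pseudocount) /
      (length(neg_bins) + length(labels) * pseudocount)
  }
  setNames(p_pos / p_neg, labels)
}

# Mann-Whitney AUC with ties counting one half.
oracle_auc <- function(pos_scores, neg_scores) {
  total <- 0
  for (p in pos_scores) {
    for (q in neg_scores) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos_scores) * length(neg_scores))
}

# k-core indices by iterative peeling on an adjacency list.
oracle_coreness <- function(edges) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  core <- setNames(rep(0L, length(nodes)), nodes)
  alive <- setNames(rep(TRUE, length(nodes)), nodes)
  deg_of <- function() {
    d <- setNames(rep(0L, length(nodes)), nodes)
    for (i in seq_len(nrow(edges))) {
      a <- edges$protein_a[[i]]
      b <- edges$protein_b[[i]]
      if (alive[[a]] && alive[[b]]) {
        d[[a]] <- d[[a]] + 1L
        d[[b]] <- d[[b]] + 1L
      }
    }
    d
  }
  k <- 0L
  while (any(alive)) {
    repeat {
      d <- deg_of()
      victims <- names(alive)[alive & d < k]
      if (length(victims) == 0) break
      alive[victims] <- FALSE
    }
    core[names(alive)[alive]] <- k
    k <- k + 1L
  }
  core
}

# Induced-subgraph edge filter.
oracle_induced_keys <- function(edges, keep) {
  keys <- character(0)
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[[i]]
    b <- edges$protein_b[[i]]
    if (a %in% keep && b %in% keep) keys <- c(keys, okey(a, b))
  }
  sort(unique(keys))
}
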