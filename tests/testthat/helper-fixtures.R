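# Small random instances for oracle-equivalence and property tests.
# Everything is generated in code under an explicit seed; no stored data.

random_edges <- function(proteins, n_edges) {
  pool <- t(combn(proteins, 2))
  take <- sample.int(nrow(pool), min(n_edges, nrow(pool)))
  tibble::tibble(
    protein_a = pmin(pool[take, 1], pool[take, 2]),
    protein_b = pmax(pool[take, 1], pool[take, 2])
  )
}

# A complete random micro-instance exercising every scorer at once.
random_instance <- function(seed, n_proteins = 10) {
  set.seed(seed)
  proteins <- sprintf("Q%02d", seq_len(n_proteins))

  sources <- lapply(seq_len(sample(2:3, 1)), function(i) {
    n <- sample(4:12, 1)
    tibble::tibble(
      protein_a = sample(proteins, n, replace = TRUE),
      protein_b = sample(proteins, n, replace = TRUE),
      source = paste0("s", i)
    )
  })

  membrane <- sample(proteins, sample(2:4, 1))
  nucleus <- sample(proteins, sample(2:4, 1))
  cc <- tibble::tibble(
    protein_id = c(membrane, nucleus),
    aspect = "CC",
    term_id = rep(
      c("plasma_membrane", "nucleus"),
      c(length(membrane), length(nucleus))
    )
  )

  n_samples <- 8
  expr <- matrix(rnorm(n_proteins * n_samples), nrow = n_proteins,
    dimnames = list(proteins, c(
      sprintf("cond1_%d", 1:4), sprintf("cond2_%d", 1:4)
    ))
  )

  with_domains <- sample(proteins, n_proteins - 2)
  n_dom <- sample(1:2, length(with_domains), replace = TRUE)
  domains <- tibble::tibble(
    protein_id = rep(with_domains, n_dom),
    domain_id = sprintf("d%03d", seq_len(sum(n_dom)))
  )
  all_dom <- domains$domain_id
  n_ddi <- sample(3:8, 1)
  ddi <- tibble::tibble(
    domain_a = sample(all_dom, n_ddi, replace = TRUE),
    domain_b = sample(all_dom, n_ddi, replace = TRUE),
    confidence_level = sample(1:4, n_ddi, replace = TRUE)
  )
  ddi <- ddi[ddi$domain_a != ddi$domain_b, ]

  species <- c("yeastx", "flyx")
  orthologs <- dplyr::bind_rows(lapply(species, function(s) {
    mapped <- sample(proteins, sample(5:n_proteins, 1))
    tibble::tibble(
      species = s,
      model_protein_id = paste0(s, "_", mapped),
      human_protein_id = mapped,
      group_id = paste0("og_", mapped)
    )
  }))
  model_int <- dplyr::bind_rows(lapply(species, function(s) {
    os <- orthologs[orthologs$species == s, ]
    if (nrow(os) < 2) {
      return(NULL)
    }
    n <- sample(2:6, 1)
    tibble::tibble(
      protein_a = sample(os$model_protein_id, n, replace = TRUE),
      protein_b = sample(os$model_protein_id, n, replace = TRUE),
      source = s
    )
  }))
  model_int <- model_int[model_int$protein_a != model_int$protein_b, ]

  n_terms <- sample(3:6, 1)
  bp <- dplyr::bind_rows(lapply(seq_len(n_terms), function(i) {
    tibble::tibble(
      protein_id = sample(proteins, sample(2:6, 1)),
      aspect = "BP",
      term_id = sprintf("t%02d", i)
    )
  }))

  list(
    proteins = proteins, sources = sources, cc = cc, expr = expr,
    domains = domains, ddi = ddi, orthologs = orthologs,
    model_int = model_int, bp = bp,
    pairs = all_pairs(proteins)
  )
}

# Labeled random scores for ROC fixtures.
random_labeled_scores <- function(seed, n_pos = 8, n_neg = 12) {
  set.seed(seed)
  n <- n_pos + n_neg
  pairs <- tibble::tibble(
    protein_a = sprintf("A%03d", seq_len(n)),
    protein_b = sprintf("B%03d", seq_len(n))
  )
  labels <- dplyr::mutate(
    pairs,
    label = rep(c("pos", "neg"), c(n_pos, n_neg))
  )
  scores <- dplyr::mutate(
    pairs,
    score = sample(seq_len(6), n, replace = TRUE) + rnorm(n, sd = 0.01)
  )
  list(labels = labels, scores = scores)
}

# Tiny informative world for end-to-end tests at modest cost.
small_world_config <- function(n_proteins = 150, seed = 1, ...) {
  sim_config(
    n_proteins = n_proteins,
    n_apoptotic = max(10, round(0.12 * n_proteins)),
    n_planted_classical_hubs = 2,
    n_planted_novel_hubs = 2,
    hub_extra_degree = max(15, round(n_proteins / 8)),
    seed = seed,
    ...
  )
}

# Random non-edges of a world's true interactome (test-side helper).
sample_nonedge_pairs_for_test <- function(world, k) {
  truth <- paste(
    world$true_interactome$protein_a,
    world$true_interactome$protein_b
  )
  univ <- all_pairs(world$proteins)
  keys <- paste(univ$protein_a, univ$protein_b)
  univ <- univ[!keys %in% truth, ]
  univ[sample.int(nrow(univ), min(k, nrow(univ))), ]
}
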