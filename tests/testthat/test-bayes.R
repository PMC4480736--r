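# Minimal binned-evidence fixture: one evidence type, two bins.
two_bin_fixture <- function(pos_counts, neg_counts) {
  gsp <- tibble::tibble(
    protein_a = sprintf("P%02d", seq_len(sum(pos_counts))),
    protein_b = sprintf("Q%02d", seq_len(sum(pos_counts)))
  )
  gsn <- tibble::tibble(
    protein_a = sprintf("R%02d", seq_len(sum(neg_counts))),
    protein_b = sprintf("S%02d", seq_len(sum(neg_counts)))
  )
  bins <- dplyr::bind_rows(
    dplyr::mutate(gsp,
      evidence = "ddi",
      bin = rep(c("L0", "L1"), pos_counts)
    ),
    dplyr::mutate(gsn,
      evidence = "ddi",
      bin = rep(c("L0", "L1"), neg_counts)
    )
  )
  scheme <- make_bins(c(0L, 1L), "ddi")$scheme
  list(gsp = gsp, gsn = gsn, bins = bins, schemes = list(ddi = scheme))
}

test_that("likelihood ratios equal the frequency ratios on the two-bin fixture", {
  fx <- two_bin_fixture(c(8, 2), c(2, 8))
  tab <- estimate_lr_table(fx$bins, fx$gsp, fx$gsn, fx$schemes,
    pseudocount = 0
  )
  expect_equal(tab$lr, c(4.0, 0.25))
  expect_equal(tab$pos_count, c(8L, 2L))
  expect_equal(tab$neg_count, c(2L, 8L))
})

test_that("identically distributed gold standards give LR 1 everywhere", {
  fx <- two_bin_fixture(c(6, 4), c(6, 4))
  tab <- estimate_lr_table(fx$bins, fx$gsp, fx$gsn, fx$schemes,
    pseudocount = 0
  )
  expect_equal(tab$lr, c(1, 1))
})

test_that("smoothing keeps zero-count bins finite and class probabilities normalized", {
  fx <- two_bin_fixture(c(5, 0), c(0, 5))
  tab <- estimate_lr_table(fx$bins, fx$gsp, fx$gsn, fx$schemes,
    pseudocount = 0.5
  )
  expect_true(all(is.finite(tab$lr) & tab$lr > 0))
  expect_gt(tab$lr[[1]], 1)
  expect_lt(tab$lr[[2]], 1)
  sums <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(tab), evidence),
    sp = sum(p_pos), sn = sum(p_neg)
  )
  expect_equal(sums$sp, 1, tolerance = 1e-9)
  expect_equal(sums$sn, 1, tolerance = 1e-9)

  expect_error(
    estimate_lr_table(fx$bins, fx$gsp, fx$gsn, fx$schemes, pseudocount = 0),
    "positive"
  )
})

test_that("overlapping or empty gold standards are rejected", {
  fx <- two_bin_fixture(c(2, 2), c(2, 2))
  expect_error(
    estimate_lr_table(fx$bins, fx$gsp, fx$gsp, fx$schemes),
    "overlap"
  )
  empty <- fx$gsp[0, ]
  expect_error(
    estimate_lr_table(fx$bins, empty, fx$gsn, fx$schemes),
    "non-empty"
  )
})

test_that("naive-Bayes combination multiplies factors and treats missing as 1", {
  tab <- structure(
    tibble::tibble(
      evidence = c("ddi", "ddi", "coexpr", "coexpr", "ssbp", "ssbp"),
      bin = c("L0", "L1", "low", "high", "small", "none"),
      pos_count = 1L, neg_count = 1L, p_pos = 0.5, p_neg = 0.5,
      lr = c(2, 3, 4, 0.5, 6, 1)
    ),
    class = c("ppi_lr_table", "tbl_df", "tbl", "data.frame")
  )
  pairs <- tibble::tibble(
    protein_a = c("A", "C", "E"), protein_b = c("B", "D", "F")
  )
  bins <- tibble::tibble(
    protein_a = c("A", "A", "A", "C"),
    protein_b = c("B", "B", "B", "D"),
    evidence = c("ddi", "coexpr", "ssbp", "ddi"),
    bin = c("L1", "low", "small", "L0")
  )
  out <- combine_lr(pairs, bins, tab)
  expect_equal(out$lr_combined, c(3 * 4 * 6, 2, 1))
  expect_equal(out$n_evidence_used, c(3L, 1L, 0L))
  expect_equal(out$posterior_odds, out$lr_combined)
  out10 <- combine_lr(pairs, bins, tab, prior_odds = 0.1)
  expect_equal(out10$posterior_odds, 0.1 * out10$lr_combined)

  bad_bins <- tibble::tibble(
    protein_a = "A", protein_b = "B", evidence = "ddi", bin = "L9"
  )
  expect_error(combine_lr(pairs, bad_bins, tab), "L9")
})

test_that("combination matches the lookup-and-multiply oracle on random fixtures", {
  for (seed in 1:20) {
    set.seed(seed)
    evs <- c("coexpr", "ddi", "interolog", "ssbp")
    tab <- dplyr::bind_rows(lapply(evs, function(e) {
      tibble::tibble(
        evidence = e, bin = paste0(e, "_b", 1:4),
        pos_count = 1L, neg_count = 1L, p_pos = 0.25, p_neg = 0.25,
        lr = exp(rnorm(4))
      )
    }))
    class(tab) <- c("ppi_lr_table", class(tab))
    n <- 15
    pairs <- tibble::tibble(
      protein_a = sprintf("A%02d", 1:n), protein_b = sprintf("B%02d", 1:n)
    )
    bins <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      use <- evs[runif(4) < 0.6]
      if (length(use) == 0) {
        return(NULL)
      }
      tibble::tibble(
        protein_a = pairs$protein_a[[i]], protein_b = pairs$protein_b[[i]],
        evidence = use,
        bin = paste0(use, "_b", sample(1:4, length(use), replace = TRUE))
      )
    }))
    out <- combine_lr(pairs, bins, tab)
    for (i in seq_len(n)) {
      rows <- bins[bins$protein_a == pairs$protein_a[[i]], ]
      expected <- 1
      for (j in seq_len(nrow(rows))) {
        expected <- expected *
          tab$lr[tab$evidence == rows$evidence[[j]] &
            tab$bin == rows$bin[[j]]]
      }
      expect_equal(out$lr_combined[[i]], expected,
        tolerance = 1e-9, info = sprintf("seed %d pair %d", seed, i)
      )
      expect_equal(out$n_evidence_used[[i]], nrow(rows))
    }
  }
})

test_that("an extra factor moves the combined LR in its own direction", {
  tab <- structure(
    tibble::tibble(
      evidence = c("ddi", "ddi"), bin = c("up", "down"),
      pos_count = 1L, neg_count = 1L, p_pos = 0.5, p_neg = 0.5,
      lr = c(2.5, 0.4)
    ),
    class = c("ppi_lr_table", "tbl_df", "tbl", "data.frame")
  )
  pairs <- tibble::tibble(protein_a = "A", protein_b = "B")
  base <- combine_lr(pairs, tibble::tibble(
    protein_a = character(), protein_b = character(),
    evidence = character(), bin = character()
  ), tab)$lr_combined
  up <- combine_lr(pairs, tibble::tibble(
    protein_a = "A", protein_b = "B", evidence = "ddi", bin = "up"
  ), tab)$lr_combined
  down <- combine_lr(pairs, tibble::tibble(
    protein_a = "A", protein_b = "B", evidence = "ddi", bin = "down"
  ), tab)$lr_combined
  expect_gt(up, base)
  expect_lt(down, base)
})

test_that("network assembly applies the cutoff and marks provenance", {
  scores <- structure(
    tibble::tibble(
      protein_a = c("A", "C"), protein_b = c("B", "D"),
      lr_combined = c(120, 50)
    ),
    class = c("ppi_scores", "tbl_df", "tbl", "data.frame")
  )
  gsp <- tibble::tibble(protein_a = "C", protein_b = "D")
  net <- predict_network(scores, gsp, lr_cutoff = 117)
  expect_equal(nrow(net), 2)
  expect_equal(
    net$provenance[net$protein_a == "A"], "predicted"
  )
  expect_equal(
    net$provenance[net$protein_a == "C"], "gold_positive"
  )
  expect_equal(attr(net, "lr_cutoff"), 117)

  # cutoff below everything predicts all scored pairs
  net_all <- predict_network(scores, gsp[0, ], lr_cutoff = 1e-6)
  expect_equal(nrow(net_all), 2)
  expect_true(all(net_all$provenance == "predicted"))

  # a gold pair at or above the cutoff appears once, as "both"
  net_both <- predict_network(scores, tibble::tibble(
    protein_a = "A", protein_b = "B"
  ), lr_cutoff = 117)
  expect_equal(sum(net_both$protein_a == "A"), 1)
  expect_equal(net_both$provenance[net_both$protein_a == "A"], "both")
})

test_that("raising the cutoff never adds a predicted edge", {
  set.seed(5)
  scores <- structure(
    tibble::tibble(
      protein_a = sprintf("A%03d", 1:200),
      protein_b = sprintf("B%03d", 1:200),
      lr_combined = exp(rnorm(200, sd = 3))
    ),
    class = c("ppi_scores", "tbl_df", "tbl", "data.frame")
  )
  gsp <- tibble::tibble(protein_a = character(), protein_b = character())
  cutoffs <- sort(exp(rnorm(8, sd = 3)))
  prev <- NULL
  for (ct in cutoffs) {
    keys <- apoppi:::pair_keys(predict_network(scores, gsp, ct))
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})
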