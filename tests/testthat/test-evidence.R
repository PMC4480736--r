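test_that("pearson_correlation matches hand-computed and boundary cases", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1)), -1.0)
  # hand evaluation of the (n-1) formula: 3 / (2 * sqrt(7/3))
  expect_equal(
    pearson_correlation(c(1, 2, 3), c(1, 2, 4)),
    3 / (2 * sqrt(7 / 3))
  )
  expect_equal(
    round(pearson_correlation(c(1, 2, 3), c(1, 2, 4)), 4), 0.9820
  )
  expect_true(is.na(pearson_correlation(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("pearson_correlation is symmetric, affine-invariant and bounded", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(10)
    y <- rnorm(10)
    r <- pearson_correlation(x, y)
    expect_equal(r, pearson_correlation(y, x))
    expect_equal(r, pearson_correlation(2.5 * x + 3, y))
    expect_true(abs(r) <= 1 + 1e-12)
    expect_equal(r, oracle_pearson(x, y))
  }
})

test_that("co-expression scoring composes per-pair correlation with missingness", {
  set.seed(3)
  expr <- matrix(rnorm(20 * 8), nrow = 20,
    dimnames = list(sprintf("G%02d", 1:20), c(
      sprintf("cond1_%d", 1:4), sprintf("cond2_%d", 1:4)
    ))
  )
  pairs <- all_pairs(rownames(expr))
  out <- score_coexpression(pairs, expr)
  for (i in sample.int(nrow(out), 30)) {
    expect_equal(
      out$coexpr_rho[[i]],
      pearson_correlation(
        expr[out$protein_a[[i]], ], expr[out$protein_b[[i]], ]
      )
    )
  }
  # absent gene and zero-variance gene are missing
  expr2 <- rbind(expr, FLAT = rep(1, 8))
  pairs2 <- tibble::tibble(
    protein_a = c("G01", "G01"), protein_b = c("ZZZ", "FLAT")
  )
  expect_true(all(is.na(score_coexpression(pairs2, expr2)$coexpr_rho)))
})

test_that("DDI scoring takes the max level over domain cross-products", {
  domains <- tibble::tibble(
    protein_id = c("P1", "P1", "P2", "P4"),
    domain_id = c("D1", "D3", "D2", "D9")
  )
  ddi <- tibble::tibble(
    domain_a = c("D1", "D2"), domain_b = c("D2", "D3"),
    confidence_level = c(1L, 4L)
  )
  pairs <- tibble::tibble(
    protein_a = c("P1", "P1", "P2", "P2"),
    protein_b = c("P2", "P3", "P3", "P4")
  )
  out <- score_ddi(pairs, domains, ddi)
  expect_equal(out$ddi_level, c(4L, NA, NA, 0L))

  single <- score_ddi(
    tibble::tibble(protein_a = "P1", protein_b = "P2"),
    tibble::tibble(protein_id = c("P1", "P2"), domain_id = c("D1", "D2")),
    tibble::tibble(domain_a = "D1", domain_b = "D2", confidence_level = 3L)
  )
  expect_equal(single$ddi_level, 3L)
})

test_that("interolog support counts distinct supporting species", {
  orthologs <- tibble::tibble(
    species = c("yeastx", "yeastx", "flyx", "flyx", "wormx"),
    model_protein_id = c("y_A", "y_B", "f_A", "f_B", "w_C"),
    human_protein_id = c("A", "B", "A", "B", "C"),
    group_id = paste0("og", 1:5)
  )
  model_int <- tibble::tibble(
    protein_a = c("y_A", "f_A"), protein_b = c("y_B", "f_B"),
    source = c("yeastx", "flyx")
  )
  pairs <- tibble::tibble(
    protein_a = c("A", "A", "D"), protein_b = c("B", "C", "E")
  )
  out <- score_interolog(pairs, orthologs, model_int)
  expect_equal(out$interolog_support, c(2L, 0L, NA))
})

test_that("SSBP finds the smallest shared process and flags absences", {
  bp <- tibble::tibble(
    protein_id = c(
      "P1", "P2", "P3",
      sprintf("X%02d", 1:8), "P1", "P2",
      "P9"
    ),
    aspect = "BP",
    term_id = c(rep("T1", 3), rep("T2", 10), "T3")
  )
  pairs <- tibble::tibble(
    protein_a = c("P1", "P1", "P1"), protein_b = c("P2", "P9", "ZZ")
  )
  out <- score_ssbp(pairs, bp)
  expect_equal(out$ssbp_size, c(3, Inf, NA))

  tiny <- score_ssbp(
    tibble::tibble(protein_a = "P1", protein_b = "P2"),
    tibble::tibble(
      protein_id = c("P1", "P2"), aspect = "BP", term_id = "T1"
    )
  )
  expect_equal(tiny$ssbp_size, 2)
})

test_that("all four scorers agree with brute-force recomputation on random instances", {
  for (seed in 1:25) {
    inst <- random_instance(seed, n_proteins = 10)
    pairs <- inst$pairs
    ev <- evidence_table(
      pairs, inst$expr, inst$domains, inst$ddi,
      inst$orthologs, inst$model_int, inst$bp
    )
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$protein_a[[i]]
      b <- pairs$protein_b[[i]]
      expect_equal(
        ev$ddi_level[[i]],
        oracle_ddi_level(a, b, inst$domains, inst$ddi),
        info = sprintf("ddi seed %d pair %s-%s", seed, a, b)
      )
      expect_equal(
        ev$interolog_support[[i]],
        oracle_interolog(a, b, inst$orthologs, inst$model_int),
        info = sprintf("interolog seed %d pair %s-%s", seed, a, b)
      )
      expect_equal(
        ev$ssbp_size[[i]],
        oracle_ssbp(a, b, inst$bp),
        info = sprintf("ssbp seed %d pair %s-%s", seed, a, b)
      )
      expect_equal(
        ev$coexpr_rho[[i]],
        oracle_pearson(inst$expr[a, ], inst$expr[b, ]),
        info = sprintf("coexpr seed %d pair %s-%s", seed, a, b)
      )
    }
  }
})

test_that("binning partitions each evidence range with the stated schemes", {
  mb <- make_bins(c(0.95, -1, 0.8, NA), "coexpr")
  expect_equal(mb$bins[[1]], "(0.80,1.00]")
  expect_equal(mb$bins[[2]], "(-1.00,-0.80]")
  expect_equal(mb$bins[[3]], "(0.60,0.80]")
  expect_true(is.na(mb$bins[[4]]))

  expect_equal(make_bins(c(0, 2, 1), "interolog")$bins, c("S0", "S2", "S1"))
  expect_equal(make_bins(c(0L, 3L), "ddi")$bins, c("L0", "L3"))

  sb <- make_bins(c(2, 3, 4, 7, 40, Inf, NA), "ssbp")
  expect_equal(
    sb$bins,
    c("[2]", "[3,4]", "[3,4]", "[5,8]", "[33,Inf)", "none", NA)
  )

  expect_error(make_bins(c(NA_real_, NA_real_), "coexpr"), "missing")
})

test_that("every non-missing value lands in exactly one bin and counts are conserved", {
  set.seed(11)
  vals <- c(runif(1000, -1, 1), rep(NA, 17))
  mb <- make_bins(vals, "coexpr")
  expect_equal(sum(!is.na(mb$bins)), 1000)
  expect_true(all(mb$bins[!is.na(vals)] %in% mb$scheme$labels))
  expect_equal(sum(table(mb$bins)), 1000)

  # re-applying the scheme to subsets is consistent
  sub <- sample(vals, 100)
  expect_equal(bin_values(sub, mb$scheme), mb$bins[match(sub, vals)])
})
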