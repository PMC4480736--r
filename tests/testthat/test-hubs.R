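star_network <- function(n_leaves = 5) {
  tibble::tibble(
    protein_a = pmin("C0", sprintf("L%d", seq_len(n_leaves))),
    protein_b = pmax("C0", sprintf("L%d", seq_len(n_leaves)))
  )
}

test_that("degree and apoptotic links count incident edges and annotated neighbors", {
  net <- star_network(5)
  out <- degree_and_links(net, apoptotic_set = c("L1", "L2", "L3"))
  centre <- out[out$protein == "C0", ]
  expect_equal(centre$degree, 5L)
  expect_equal(centre$apoptotic_links, 3L)
  leaf <- out[out$protein == "L4", ]
  expect_equal(leaf$degree, 1L)
  expect_equal(leaf$apoptotic_links, 0L)
  # handshake lemma
  expect_equal(sum(out$degree), 2 * nrow(net))
  expect_error(degree_and_links(net[0, ], "L1"), "empty")
})

test_that("k-core indices match hand-peeled values on canonical graphs", {
  triangle <- tibble::tibble(
    protein_a = c("A", "A", "B"), protein_b = c("B", "C", "C")
  )
  out <- dense_area_filter(triangle, k_core_min = 2)
  expect_true(all(out$core_index == 2))
  expect_true(all(out$core_pass))

  tree <- tibble::tibble(
    protein_a = c("A", "A", "B", "B"), protein_b = c("B", "C", "D", "E")
  )
  expect_true(all(dense_area_filter(tree, 1)$core_index == 1))

  clique6 <- all_pairs(sprintf("K%d", 1:6))
  expect_true(all(dense_area_filter(clique6, 5)$core_index == 5))
})

test_that("k-core equals the brute-force peeling oracle on random graphs", {
  for (seed in 1:30) {
    set.seed(seed)
    edges <- random_edges(sprintf("V%02d", 1:12), sample(8:25, 1))
    out <- dense_area_filter(edges, 1)
    oracle <- oracle_coreness(edges)
    expect_equal(
      setNames(out$core_index, out$protein)[names(oracle)],
      oracle,
      info = paste("seed", seed)
    )
    expect_true(all(
      out$core_index <=
        degree_and_links(edges, character(0))$degree[
          match(out$protein, degree_and_links(edges, character(0))$protein)
        ]
    ))
  }
})

test_that("hub criteria validate their thresholds and echo the defaults", {
  crit <- hub_criteria()
  expect_equal(crit$min_degree, 300)
  expect_equal(crit$min_apoptotic_links_classical, 300)
  expect_equal(crit$min_apoptotic_links_novel, 200)
  expect_error(
    hub_criteria(min_apoptotic_links_novel = 400), "must not exceed"
  )
  expect_error(hub_criteria(min_degree = 0), "positive")
})

test_that("hub calling is the conjunction of the enabled criteria", {
  # two dense communities so the 75th-percentile core rule is non-trivial
  world <- simulate_world(small_world_config(n_proteins = 120, seed = 9))
  net <- structure(world$true_interactome,
    class = c("ppi_network", class(world$true_interactome)),
    nodes = world$proteins
  )
  crit <- hub_criteria(sam_permutations = 40, seed = 2)
  report <- identify_hubs(net, world$apoptotic_set, world$expression, crit)

  hubs <- report[report$hub_class != "none", ]
  expect_true(all(
    hubs$pass_degree & hubs$pass_links & hubs$pass_core & hubs$pass_sam
  ))
  # classical hubs are annotated apoptotic, novel hubs are not
  expect_true(all(hubs$in_apoptotic_set[hubs$hub_class == "classical"]))
  expect_true(!any(hubs$in_apoptotic_set[hubs$hub_class == "novel"]))
  # any failed criterion blocks hubhood
  non_hubs <- report[report$hub_class == "none", ]
  expect_true(all(
    !non_hubs$pass_degree | !non_hubs$pass_links |
      !non_hubs$pass_core | !non_hubs$pass_sam
  ))

  # disabling the SAM criterion can only grow the hub set
  crit_nosam <- hub_criteria(
    sam_permutations = 40, seed = 2,
    enabled = c(degree = TRUE, links = TRUE, core = TRUE, sam = FALSE)
  )
  report2 <- identify_hubs(net, world$apoptotic_set, world$expression,
    crit_nosam
  )
  expect_true(all(
    report$protein[report$hub_class != "none"] %in%
      report2$protein[report2$hub_class != "none"]
  ))
})

test_that("planted hubs are recovered and thresholds echo the reference values", {
  world <- simulate_world(small_world_config(n_proteins = 150, seed = 4))
  net <- structure(world$true_interactome,
    class = c("ppi_network", class(world$true_interactome)),
    nodes = world$proteins
  )
  crit <- hub_criteria(sam_permutations = 50, seed = 7)
  report <- identify_hubs(net, world$apoptotic_set, world$expression, crit)
  called <- report$protein[report$hub_class != "none"]
  planted <- world$planted_hubs$protein
  # every planted hub is recovered; at this small scale the auto-scaled
  # thresholds are permissive, so a few extra calls are tolerated (the
  # tight Jaccard bound is asserted at the default simulation scale)
  expect_true(all(planted %in% called))
  expect_lte(length(setdiff(called, planted)), 2)

  echoed <- attr(report, "criteria")
  expect_equal(echoed$min_degree, 300)
  expect_equal(echoed$min_apoptotic_links_classical, 300)
  expect_equal(echoed$min_apoptotic_links_novel, 200)
  thr <- attr(report, "thresholds")
  expect_equal(thr$degree, ceiling(300 * nrow(report) / 13128))
})

test_that("raising any threshold never adds a hub", {
  world <- simulate_world(small_world_config(n_proteins = 120, seed = 6))
  net <- structure(world$true_interactome,
    class = c("ppi_network", class(world$true_interactome)),
    nodes = world$proteins
  )
  base_crit <- hub_criteria(
    min_degree = 100, min_apoptotic_links_classical = 100,
    min_apoptotic_links_novel = 60, sam_permutations = 40, seed = 5
  )
  base <- identify_hubs(net, world$apoptotic_set, world$expression, base_crit)
  base_hubs <- base$protein[base$hub_class != "none"]
  variants <- list(
    hub_criteria(
      min_degree = 150, min_apoptotic_links_classical = 100,
      min_apoptotic_links_novel = 60, sam_permutations = 40, seed = 5
    ),
    hub_criteria(
      min_degree = 100, min_apoptotic_links_classical = 150,
      min_apoptotic_links_novel = 90, sam_permutations = 40, seed = 5
    ),
    hub_criteria(
      min_degree = 100, min_apoptotic_links_classical = 100,
      min_apoptotic_links_novel = 100, sam_permutations = 40, seed = 5
    )
  )
  for (crit in variants) {
    rep_v <- identify_hubs(net, world$apoptotic_set, world$expression, crit)
    expect_true(all(
      rep_v$protein[rep_v$hub_class != "none"] %in% base_hubs
    ))
  }
})
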