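test_that("shortest paths use inverse-weight lengths", {
  single <- sym_from_edges(2, list(c(1, 2)), 2)
  expect_equal(shortest_path_distances(single)[1, 2], 0.5)

  # direct edge 0.4 (length 2.5) loses to a two-hop route of unit weights
  w <- sym_from_edges(3, list(c(1, 3), c(1, 2), c(2, 3)), c(0.4, 1, 1))
  expect_equal(shortest_path_distances(w)[1, 3], 2)

  iso <- matrix(0, 2, 2)
  expect_equal(shortest_path_distances(iso)[1, 2], Inf)
})

test_that("distances and efficiencies match a Floyd-Warshall oracle on random graphs", {
  for (seed in 1:50) {
    n <- sample(4:12, 1)
    w <- rand_weighted(n, stats::runif(1, 0.2, 0.8), seed)
    d <- shortest_path_distances(w)
    d_oracle <- fw_distances_oracle(w)
    expect_equal(d, d_oracle, tolerance = 1e-12, ignore_attr = TRUE)
    eff <- eff_from_distances(d_oracle)
    expect_equal(global_efficiency(w), eff$e_glob, tolerance = 1e-12)
    expect_equal(unname(nodal_efficiency(w)), eff$e_nodal, tolerance = 1e-12)
  }
})

test_that("total strength implements the mean-nodal-strength formula", {
  expect_equal(total_strength(unit_triangle()), 2)       # 6 / 3
  expect_equal(total_strength(matrix(0, 4, 4)), 0)
  one <- sym_from_edges(5, list(c(2, 4)), 0.7)
  expect_equal(total_strength(one), 2 * 0.7 / 5)
  # alternative reading: mean over existing edges
  w <- sym_from_edges(4, list(c(1, 2), c(3, 4)), c(1, 3))
  expect_equal(total_strength(w, per = "edge"), 2)
})

test_that("Onnela clustering is max-scaled and handles degenerate nodes", {
  expect_equal(weighted_clustering(unit_triangle())$mean, 1)
  expect_equal(weighted_clustering(unit_star())$mean, 0)
  expect_equal(weighted_clustering(unit_path3())$mean, 0)
  # scale invariance through max-normalization
  w <- rand_weighted(10, 0.5, 5)
  expect_equal(weighted_clustering(3.7 * w)$per_node,
               weighted_clustering(w)$per_node, tolerance = 1e-12)
  # a weighted triangle: intensity is the geometric mean of scaled weights
  tw <- sym_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)), c(1, 2, 4))
  expect_equal(weighted_clustering(tw)$per_node[1],
               ((1 / 4) * (2 / 4) * (4 / 4))^(1 / 3), ignore_attr = TRUE)
})

test_that("efficiency closed forms hold", {
  expect_equal(global_efficiency(unit_path3()), 5 / 6)
  expect_equal(char_path_length(unit_path3()), 1.2)
  expect_equal(global_efficiency(unit_k4()), 1)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  expect_error(char_path_length(matrix(0, 4, 4)), "path")

  expect_equal(local_efficiency(unit_k4()), 1)
  expect_equal(local_efficiency(unit_star()), 0)
  expect_equal(local_efficiency(unit_triangle()), 1)

  expect_equal(unname(nodal_efficiency(unit_path3())), c(0.75, 1, 0.75))
  expect_equal(unname(nodal_efficiency(unit_k4())), rep(1, 4))
})

test_that("efficiency scales linearly with weights and L inversely", {
  w <- rand_weighted(10, 0.6, 9)
  for (c_scale in c(0.5, 3)) {
    expect_equal(global_efficiency(c_scale * w),
                 c_scale * global_efficiency(w), tolerance = 1e-12)
    expect_equal(unname(nodal_efficiency(c_scale * w)),
                 unname(c_scale * nodal_efficiency(w)), tolerance = 1e-12)
    expect_equal(char_path_length(c_scale * w),
                 char_path_length(w) / c_scale, tolerance = 1e-12)
  }
})

test_that("efficiency identities and monotonicity hold on random graphs", {
  for (seed in 1:15) {
    w <- rand_weighted(10, 0.5, 100 + seed)
    eg <- global_efficiency(w)
    expect_equal(mean(nodal_efficiency(w)), eg, tolerance = 1e-12)
    if (eg > 0)
      expect_equal(char_path_length(w) * eg, 1, tolerance = 1e-12)
    # deleting any edge never raises global efficiency
    idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    pick <- idx[sample(nrow(idx), 1), ]
    w2 <- w
    w2[pick[1], pick[2]] <- w2[pick[2], pick[1]] <- 0
    expect_lte(global_efficiency(w2), eg + 1e-12)
  }
})

test_that("hub rule keeps nodes one sample SD above the mean", {
  v <- c(1, 1, 1, 5)   # mean 2, sd 2, threshold 4
  expect_equal(identify_hubs(v), 4L)
  expect_length(identify_hubs(rep(0.3, 10)), 0)
  lin <- seq_len(78)
  hubs <- identify_hubs(lin)
  expect_true(all(hubs > 39))
  expect_lt(length(hubs), 39)
})

test_that("metric tables carry one row per subject and per node", {
  G <- normalize_by_mean_weight(rand_weighted(20, 0.35, 17))
  gm <- global_metrics(G)
  expect_named(gm, c("S", "CC", "L", "E_glob", "E_loc", "Q"))
  expect_equal(gm$L * gm$E_glob, 1, tolerance = 1e-12)
  nm <- nodal_metrics(G)
  expect_equal(nrow(nm), 20L)
  expect_true(all(nm$PC >= 0 & nm$PC <= 1))
  expect_equal(mean(nm$E_nodal), gm$E_glob, tolerance = 1e-12)
})
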