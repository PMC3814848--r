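test_that("the planted partition splits regions into near-equal deterministic blocks", {
  expect_equal(tabulate(planted_partition(78, 6)), rep(13, 6))
  expect_equal(tabulate(planted_partition(7, 2)), c(4, 3))
  expect_identical(planted_partition(7, 2), planted_partition(7, 2))
  expect_equal(partition_nmi(planted_partition(78, 6),
                             planted_partition(78, 6)), 1)
  expect_error(planted_partition(5, 6), "more modules")
})

test_that("cohort specs validate their parameters", {
  expect_error(cohort_spec(n_per_group = 0), "positive")
  expect_error(cohort_spec(fa_young = 1.2), "FA")
  expect_error(cohort_spec(fn_span_factor = 0.8), "factors")
  expect_warning(cohort_spec(p_in = 0.03, p_out = 0.05), "not be recoverable")
  expect_error(cohort_spec(n_groups = 3, age_ranges = list(c(6, 10))),
               "age range")
})

test_that("generation is bitwise reproducible from the seed", {
  spec <- small_cohort_spec(seed = 99)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$demographics, b$demographics)
  c2 <- generate_cohort(small_cohort_spec(seed = 100))
  expect_false(identical(a$subjects, c2$subjects))
})

test_that("every generated subject satisfies the connectivity invariants", {
  n_checked <- 0
  for (seed in 1:3) {
    coh <- generate_cohort(cohort_spec(n_groups = 3, n_per_group = 12,
                                       n_regions = 40, n_modules = 4,
                                       seed = seed))
    for (s in coh$subjects) {
      expect_identical(s$FN, t(s$FN))
      expect_identical(s$FA, t(s$FA))
      expect_equal(diag(s$FN), rep(0L, 40), ignore_attr = TRUE)
      expect_equal(diag(s$FA), rep(0, 40), ignore_attr = TRUE)
      expect_identical(s$FA > 0, s$FN > 0)
      expect_true(all(s$FA[s$FN > 0] >= 0.2 & s$FA[s$FN > 0] <= 0.9))
      expect_true(all(s$volumes > 0))
      expect_true(all(s$FN >= 0) && all(s$FN == round(s$FN)))
      n_checked <- n_checked + 1
    }
    # ages stay inside their group's range
    for (g in seq_len(3)) {
      ages <- coh$demographics$age[coh$demographics$group ==
                                     coh$group_order[g]]
      rng <- coh$spec$age_ranges[[g]]
      expect_true(all(ages >= rng[1] & ages <= rng[2]))
    }
  }
  expect_gte(n_checked, 100)
})

test_that("total fiber count rises by about the programmed span factor", {
  ratios <- vapply(1:10, function(seed) {
    coh <- generate_cohort(cohort_spec(seed = seed))
    fn <- vapply(coh$subjects, function(s) sum(s$FN) / 2, numeric(1))
    means <- tapply(fn, coh$demographics$group, mean)[coh$group_order]
    unname(means[5] / means[1])
  }, numeric(1))
  expect_gte(mean(ratios), 1.45)
  expect_lte(mean(ratios), 1.75)
})

test_that("group mean sparsity is non-decreasing when a sparsity span is programmed", {
  for (seed in 1:5) {
    coh <- generate_cohort(cohort_spec(n_groups = 4, n_per_group = 10,
                                       n_regions = 50, n_modules = 5,
                                       seed = 50 + seed))
    sp <- vapply(coh$subjects, function(s) sparsity(build_network(s)),
                 numeric(1))
    means <- tapply(sp, coh$demographics$group, mean)[coh$group_order]
    expect_true(all(diff(means) > -0.002))
  }
})

test_that("planted modules are recovered through the full backbone route", {
  spec <- cohort_spec(n_per_group = 18, n_groups = 1, p_in = 0.9,
                      p_out = 0.05, seed = 8,
                      age_ranges = list(c(6, 30)))
  coh <- generate_cohort(spec)
  nets <- lapply(coh$subjects, function(s)
    normalize_by_mean_weight(build_network(s)))
  bb <- build_backbone(nets)
  part <- greedy_modularity(bb$network)
  expect_gte(partition_nmi(part, coh$planted), 0.9)
})

test_that("region labels mirror the 78-region cortical parcellation", {
  tab <- cortical_region_table()
  expect_equal(nrow(tab), 78)
  expect_equal(sum(tab$hemisphere == "L"), 39)
  expect_equal(tab$abbreviation[tab$index == 21], "PCUN")
  expect_equal(tab$abbreviation[tab$index == 60], "PCUN")
  labs <- region_labels(78)
  expect_equal(labs[7], "SFGdor.L")
  expect_equal(anyDuplicated(labs), 0L)
  expect_equal(length(region_labels(30)), 30)
})

test_that("cohorts survive a disk round trip", {
  coh <- generate_cohort(cohort_spec(n_groups = 2, n_per_group = 3,
                                     n_regions = 20, n_modules = 2, seed = 4))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$subjects), 6)
  expect_equal(back$subjects[[1]]$FN, coh$subjects[[1]]$FN,
               ignore_attr = TRUE)
  expect_equal(back$subjects[[1]]$volumes, coh$subjects[[1]]$volumes,
               tolerance = 1e-12)
  expect_equal(back$demographics$age, coh$demographics$age, tolerance = 1e-12)
  js <- jsonlite::read_json(file.path(dir, "cohort_spec.json"))
  expect_equal(js$seed, 4)
})
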