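test_that("with covariates balanced across groups the group effect is the raw mean difference", {
  set.seed(10)
  n <- 36
  age <- rep(stats::runif(n, 8, 12), 2)     # identical age pattern per group
  sex <- rep(rep(0:1, length.out = n), 2)
  grp <- rep(0:1, each = n)
  y <- stats::rnorm(2 * n) + 0.4 * grp
  fit <- glm_group_effect(y, grp, age, sex)
  # identical covariate patterns make the group column orthogonal to them,
  # so the adjusted coefficient collapses to the two-sample mean difference
  expect_equal(fit$coefficient, mean(y[grp == 1]) - mean(y[grp == 0]),
               tolerance = 1e-10)
  # and the t statistic matches an explicit normal-equations oracle
  X <- cbind(1, grp, age, sex)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  rss <- sum((y - X %*% beta)^2)
  se <- sqrt(rss / (2 * n - 4) * solve(t(X) %*% X)[2, 2])
  expect_equal(fit$t_stat, beta[2] / se, tolerance = 1e-10)
  expect_equal(fit$df, 2 * n - 4)
})

test_that("the group estimate is invariant to centering age and recoding sex", {
  set.seed(11)
  n <- 30
  grp <- rep(0:1, each = n)
  age <- stats::runif(2 * n, 6, 30)
  sex <- stats::rbinom(2 * n, 1, 0.5)
  y <- stats::rnorm(2 * n) + 0.02 * age + 0.3 * grp
  f1 <- glm_group_effect(y, grp, age, sex)
  f2 <- glm_group_effect(y, grp, age - mean(age), sex)
  f3 <- glm_group_effect(y, grp, age, 1 - sex)
  expect_equal(f1$coefficient, f2$coefficient, tolerance = 1e-10)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-10)
  expect_equal(f1$coefficient, f3$coefficient, tolerance = 1e-10)
  # and matches lm() as an independent fitting route
  lm_fit <- summary(stats::lm(y ~ grp + age + sex))
  expect_equal(f1$t_stat, lm_fit$coefficients["grp", "t value"],
               tolerance = 1e-10)
})

test_that("rank-deficient designs fail loudly with the collinear column named", {
  n <- 20
  grp <- rep(0:1, each = n)
  age <- 10 + 5 * grp                       # age perfectly separates groups
  y <- stats::rnorm(2 * n)
  expect_error(glm_group_effect(y, grp, age, stats::rbinom(2 * n, 1, 0.5)),
               "collinear")
  expect_error(glm_group_effect(y, grp, stats::runif(2 * n, 6, 30),
                                rep(1, 2 * n)), "collinear")
  expect_error(glm_group_effect(y[1:3], c(0, 1, 1), c(1, 2, 3), c(0, 1, 0)),
               "two subjects")
})

test_that("the BH mask matches hand application and a step-up oracle", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.2), 0.05), c(TRUE, TRUE, FALSE))
  expect_equal(fdr_bh(rep(0.001, 10), 0.05), rep(TRUE, 10))
  expect_identical(fdr_bh(numeric(0)), logical(0))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
  set.seed(12)
  for (rep in 1:200) {
    m <- sample(1:40, 1)
    p <- stats::runif(m)^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(fdr_bh(p, q), bh_oracle(p, q))
  }
})

test_that("lowering one p-value never shrinks the BH rejection set", {
  set.seed(13)
  for (rep in 1:30) {
    p <- stats::runif(15)
    base <- fdr_bh(p, 0.05)
    i <- sample(15, 1)
    p2 <- p
    p2[i] <- p[i] / 2
    expect_true(all(base[-i] <= fdr_bh(p2, 0.05)[-i]))
  }
})

test_that("adjacent-group comparison walks each transition once and corrects nodal maps per cell", {
  set.seed(14)
  groups <- paste0("g", 1:5)
  demo <- data.frame(
    subject_id = sprintf("s%03d", 1:100),
    group = rep(groups, each = 20),
    age = stats::runif(100, 6, 30),
    sex = stats::rbinom(100, 1, 0.5))
  gm <- cbind(demo, m1 = stats::rnorm(100), m2 = stats::rnorm(100))
  nodal <- do.call(rbind, lapply(1:5, function(r)
    data.frame(demo, region = paste0("r", r), metric = "E_nodal",
               value = stats::rnorm(100))))
  res <- compare_adjacent_groups(gm, nodal, groups)
  glob <- res[is.na(res$region), ]
  expect_equal(nrow(glob), 2 * 4)           # 2 metrics x 4 transitions
  expect_setequal(unique(glob$transition),
                  paste0(groups[1:4], "->", groups[2:5]))
  nod <- res[!is.na(res$region), ]
  expect_equal(nrow(nod), 5 * 4)            # 5 regions x 4 transitions
  # per-cell FDR: the mask within one (metric, transition) cell matches fdr_bh
  cell <- nod[nod$transition == "g1->g2", ]
  expect_equal(cell$significant, fdr_bh(cell$p_value, 0.05))
  expect_error(compare_adjacent_groups(gm, NULL, "g1"), "two ordered")
})

test_that("shuffled group labels are flagged at close to the nominal rate", {
  set.seed(15)
  rates <- replicate(200, {
    demo <- data.frame(
      subject_id = sprintf("s%02d", 1:72),
      group = sample(rep(c("a", "b"), each = 36)),
      age = stats::runif(72, 8, 13),
      sex = stats::rbinom(72, 1, 0.5))
    gm <- cbind(demo, m = stats::rnorm(72))
    res <- compare_adjacent_groups(gm, NULL, c("a", "b"))
    res$p_value < 0.05
  })
  expect_gt(mean(rates), 0.01)
  expect_lt(mean(rates), 0.10)
})
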