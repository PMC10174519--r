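gamma36 <- function(g) gxl_factor(g, n_labs = 3, n_genotypes = 6)

test_that("pooled SD matches hand arithmetic", {
  gs <- function(n, s) group_stats(n, 0, s)
  expect_equal(pooled_sd(gs(5, 1), gs(9, 1)), 1)
  expect_equal(pooled_sd(gs(2, 0), gs(2, 2)), sqrt(2))
  expect_equal(pooled_sd(gs(3, 1), gs(5, 2)), sqrt((2 * 1 + 4 * 4) / 6))
  expect_error(pooled_sd(gs(1, 0), gs(5, 1)), "n >= 2")
})

test_that("Satterthwaite df match the printed-formula evaluation", {
  expect_equal(satterthwaite_df(10, 10, 0, NULL, NULL), 18)
  expect_equal(satterthwaite_df(10, 10, 0.5, 3, 6),
               0.49 / (0.04 / 18 + 0.25 / 10))
  expect_equal(round(satterthwaite_df(10, 10, 0.5, 3, 6), 3), 18.000)
  expect_equal(satterthwaite_df(10, 10, 2, 3, 6),
               (0.2 + 8)^2 / (0.04 / 18 + 4 * 16 / 10))
  expect_equal(round(satterthwaite_df(10, 10, 2, 3, 6), 2), 10.50)
  expect_error(satterthwaite_df(10, 10, 0.5), "n_labs")
})

test_that("df formula agrees with an independent evaluation over a grid", {
  # independent oracle retains the s_p^4 factor that the implementation cancels
  direct_nu <- function(n1, n2, g, nL, nS, sp) {
    num <- sp^4 * (1 / n1 + 1 / n2 + 2 * g^2)^2
    den <- sp^4 * (1 / n1 + 1 / n2)^2 / (n1 + n2 - 2) +
      4 * sp^4 * g^4 / ((nL - 1) * (nS - 1))
    min(num / den, n1 + n2 - 2)  # capped at the pooled df
  }
  set.seed(4)
  grid <- expand.grid(n1 = c(2, 5, 10, 40), n2 = c(3, 10, 25),
                      g = c(0.1, 0.5, 1, 2), nL = c(2, 3, 11), nS = c(2, 6))
  for (i in seq_len(nrow(grid))) {
    r <- grid[i, ]
    sp <- runif(1, 0.2, 5)
    expect_equal(satterthwaite_df(r$n1, r$n2, r$g, r$nL, r$nS),
                 direct_nu(r$n1, r$n2, r$g, r$nL, r$nS, sp),
                 tolerance = 1e-12)
  }
})

test_that("worked adjusted-test values match the closed formulas", {
  gx <- group_stats(10, 1, 1, genotype = "a")
  gy <- group_stats(10, 0, 1, genotype = "b")

  naive <- adjusted_t_test(gx, gy, gamma36(0))
  expect_equal(naive$t_stat, 1 / sqrt(0.2), tolerance = 1e-12)
  expect_equal(naive$df, 18)
  expect_equal(round(naive$p_value, 4), 0.0382)
  expect_false(naive$adjusted)

  adj <- adjusted_t_test(gx, gy, gamma36(0.5))
  expect_equal(adj$se, sqrt(0.7), tolerance = 1e-12)
  expect_equal(round(adj$se, 4), 0.8367)
  expect_equal(round(adj$t_stat, 4), 1.1952)
  expect_equal(adj$df, 18, tolerance = 1e-12)
  expect_equal(round(adj$p_value, 4), 0.2475)
})

test_that("gamma = 0 reproduces the classical pooled t test exactly", {
  set.seed(92)
  for (rep in 1:25) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    x <- rnorm(n1, runif(1, -2, 2), runif(1, 0.3, 3))
    y <- rnorm(n2, runif(1, -2, 2), runif(1, 0.3, 3))
    ours <- adjusted_t_test(stats_of(x, "a"), stats_of(y, "b"), gamma36(0))
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(c(ours$ci_low, ours$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-12)
  }
})

test_that("adjustment can only increase the p-value", {
  set.seed(31)
  for (rep in 1:40) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    gx <- group_stats(n1, rnorm(1), runif(1, 0.1, 4), genotype = "a")
    gy <- group_stats(n2, rnorm(1), runif(1, 0.1, 4), genotype = "b")
    g <- runif(1, 0, 2)
    p_adj <- adjusted_t_test(gx, gy, gamma36(g))$p_value
    p_naive <- adjusted_t_test(gx, gy, gamma36(0))$p_value
    expect_gte(p_adj, p_naive)
  }
})

test_that("group compatibility is enforced", {
  a <- group_stats(10, 1, 1, lab = "lab1", genotype = "a")
  b_other_lab <- group_stats(10, 0, 1, lab = "lab2", genotype = "b")
  b_other_sex <- group_stats(10, 0, 1, sex = "male", genotype = "b")
  expect_error(adjusted_t_test(a, b_other_lab, gamma36(0.5)), "same lab")
  expect_error(adjusted_t_test(a, b_other_sex, gamma36(0.5)), "stratum")
  f_t <- gxl_factor(0.3, kind = "txgxl", n_labs = 3, n_genotypes = 6)
  expect_error(adjusted_t_test(a, group_stats(10, 0, 1, genotype = "b"), f_t),
               "kind 'gxl'")
})

test_that("treatment contrast matches its closed formulas", {
  mk <- function(mean, treatment, genotype) {
    group_stats(10, mean, 1, genotype = genotype, treatment = treatment,
                sex = "male")
  }
  f0 <- gxl_factor(0, kind = "txgxl", n_labs = 3, n_genotypes = 6)
  f3 <- gxl_factor(0.3, kind = "txgxl", n_labs = 3, n_genotypes = 6)

  flat <- adjusted_treatment_contrast(mk(1, "treated", "a"), mk(1, "control", "a"),
                                      mk(1, "treated", "b"), mk(1, "control", "b"),
                                      f3)
  expect_equal(flat$estimate, 0)
  expect_equal(flat$p_value, 1)

  res0 <- adjusted_treatment_contrast(mk(1, "treated", "a"), mk(0, "control", "a"),
                                      mk(0, "treated", "b"), mk(0, "control", "b"),
                                      f0)
  expect_equal(res0$t_stat, 1 / sqrt(0.4), tolerance = 1e-12)
  expect_equal(round(res0$t_stat, 4), 1.5811)
  expect_equal(res0$df, 36)

  res3 <- adjusted_treatment_contrast(mk(1, "treated", "a"), mk(0, "control", "a"),
                                      mk(0, "treated", "b"), mk(0, "control", "b"),
                                      f3)
  expect_equal(res3$se, sqrt(0.4 + 0.36), tolerance = 1e-12)
  expect_equal(round(res3$se, 4), 0.8718)
  expect_equal(round(res3$t_stat, 4), 1.1471)

  expect_error(adjusted_treatment_contrast(
    mk(1, "treated", "a"), mk(0, "control", "a"),
    mk(0, "treated", "b"), mk(0, "control", "b"), gamma36(0.3)), "txgxl")
})

test_that("adjusted CIs cover the across-lab difference; naive CIs undercover", {
  set.seed(2024)
  gamma <- 0.8; sigma <- 1; n <- 10; true_diff <- 0.5
  n_rep <- 2000
  cover_adj <- logical(n_rep); cover_naive <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- draw_single_lab_pair(n, sigma, gamma, effect = true_diff)
    gx <- stats_of(d$x, "a"); gy <- stats_of(d$y, "b")
    adj <- adjusted_t_test(gx, gy, gamma36(gamma))
    nai <- adjusted_t_test(gx, gy, gamma36(0))
    cover_adj[i] <- adj$ci_low <= true_diff && true_diff <= adj$ci_high
    cover_naive[i] <- nai$ci_low <= true_diff && true_diff <= nai$ci_high
  }
  expect_gte(mean(cover_adj), 0.90)
  expect_lt(mean(cover_naive), 0.70)
})
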