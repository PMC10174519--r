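# sqrt of interaction-to-error variance ratio from any fit-like object
fake_fit <- function(s2, s2_gxl, n_labs = 3L, n_genotypes = 6L) {
  structure(list(sigma2_within = s2, sigma2_lab = 0, sigma2_gxl = s2_gxl,
                 n_labs = n_labs, n_genotypes = n_genotypes,
                 phenotype = "bw", subpopulation = NULL, method = "moments",
                 truncated = character()),
            class = "random_lab_fit")
}

test_that("the GxL factor is the interaction-to-error SD ratio", {
  expect_equal(gxl_factor(fake_fit(1.4^2, 0.8^2))$gamma, 0.8 / 1.4)
  expect_equal(round(gxl_factor(fake_fit(1.4^2, 0.8^2))$gamma, 2), 0.57)
  expect_equal(gxl_factor(fake_fit(2.3, 0))$gamma, 0)
  expect_equal(gxl_factor(fake_fit(1.7, 1.7))$gamma, 1)
  expect_error(gxl_factor(fake_fit(0, 1)), "degenerate")
  expect_error(gxl_factor(fake_fit(1, 1), kind = "txgxl"), "three-way")
})

test_that("moments estimator matches a from-scratch EMS computation", {
  tab <- simulate_multilab(sim_config(seed = 21, sigma_gxl = 0.6,
                                      sigma_lab = 0.8))
  fit <- fit_random_lab_model(tab, "sim", method = "moments")

  # independent oracle: mean squares from cell/lab/grand means by hand
  d <- as.data.frame(tab)
  n <- 10; L <- 3; G <- 6
  cell <- tapply(d$value, list(d$genotype, d$lab), mean)
  geno <- rowMeans(cell); lab <- colMeans(cell); grand <- mean(cell)
  ms_err <- sum((d$value - cell[cbind(d$genotype, d$lab)])^2) / (L * G * (n - 1))
  ms_int <- n * sum((sweep(sweep(cell, 1, geno), 2, lab) + grand)^2) /
    ((L - 1) * (G - 1))
  ms_lab <- n * G * sum((lab - grand)^2) / (L - 1)
  expect_equal(fit$sigma2_within, ms_err, tolerance = 1e-10)
  expect_equal(fit$sigma2_gxl, (ms_int - ms_err) / n, tolerance = 1e-10)
  expect_equal(fit$sigma2_lab, (ms_lab - ms_int) / (n * G), tolerance = 1e-10)
})

test_that("REML and moments agree on balanced data in the interior", {
  for (seed in c(5, 17, 29)) {
    tab <- simulate_multilab(sim_config(seed = seed, sigma_gxl = 0.7,
                                        sigma_lab = 0.6))
    r <- coef(fit_random_lab_model(tab, "sim", method = "reml"))
    m <- coef(fit_random_lab_model(tab, "sim", method = "moments"))
    expect_equal(r, m, tolerance = 1e-4)
  }
})

test_that("null interaction yields a near-zero estimated factor", {
  tab <- simulate_multilab(sim_config(seed = 101, n_per_group = 200,
                                      sigma_gxl = 0, sigma_lab = 0))
  fit <- fit_random_lab_model(tab, "sim")
  expect_lt(gxl_factor(fit)$gamma, 0.1)
})

test_that("the estimated factor recovers the generating ratio", {
  gammas <- vapply(1:400, function(seed) {
    tab <- simulate_multilab(sim_config(seed = seed, sigma_gxl = 0.57))
    gxl_factor(fit_random_lab_model(tab, "sim", method = "moments"))$gamma
  }, 0)
  expect_lt(abs(median(gammas) - 0.57), 0.15)
})

test_that("gamma is invariant to measurement scale and lab shifts", {
  tab <- simulate_multilab(sim_config(seed = 33, sigma_gxl = 0.5))
  base_m <- fit_random_lab_model(tab, "sim", method = "moments")
  base_r <- fit_random_lab_model(tab, "sim", method = "reml")

  scaled <- tab; scaled$value <- scaled$value * 37.2
  sc_m <- fit_random_lab_model(scaled, "sim", method = "moments")
  sc_r <- fit_random_lab_model(scaled, "sim", method = "reml")
  expect_equal(gxl_factor(sc_m)$gamma, gxl_factor(base_m)$gamma,
               tolerance = 1e-8)
  expect_equal(gxl_factor(sc_r)$gamma, gxl_factor(base_r)$gamma,
               tolerance = 1e-6)

  shifted <- tab
  shifted$value <- shifted$value + c(lab1 = 5, lab2 = -3, lab3 = 11)[shifted$lab]
  sh <- fit_random_lab_model(shifted, "sim", method = "moments")
  expect_equal(sh$sigma2_within, base_m$sigma2_within, tolerance = 1e-8)
  expect_equal(sh$sigma2_gxl, base_m$sigma2_gxl, tolerance = 1e-8)
  expect_gt(sh$sigma2_lab, base_m$sigma2_lab)
})

test_that("degenerate designs are refused", {
  tab <- as.data.frame(tiny_table())
  one_lab <- tab[tab$lab == "labA", ]
  expect_error(fit_random_lab_model(as_measurement_table(one_lab), "bw"),
               "2 labs")
  one_geno <- tab[tab$genotype == "g1", ]
  expect_error(fit_random_lab_model(as_measurement_table(one_geno), "bw"),
               "2 genotypes")
  singleton <- tab[!duplicated(paste(tab$lab, tab$genotype)), ]
  expect_error(fit_random_lab_model(as_measurement_table(singleton), "bw"),
               "one animal per cell")
})

test_that("three-way fit estimates the TxGxL component", {
  cfg <- sim_config(seed = 55, with_treatment = TRUE, sigma_txgxl = 0.3,
                    sigma_txl = 0.2, sigma_gxl = 0.5)
  tab <- simulate_multilab(cfg)
  r <- coef(fit_treatment_model(tab, "sim", method = "reml"))
  m <- coef(fit_treatment_model(tab, "sim", method = "moments"))
  expect_equal(r, m, tolerance = 1e-3)

  # recovery of the three-way ratio over replicates
  g3 <- vapply(1:200, function(seed) {
    tab <- simulate_multilab(sim_config(seed = seed, with_treatment = TRUE,
                                        sigma_txgxl = 0.3))
    gxl_factor(fit_treatment_model(tab, "sim", method = "moments"),
               kind = "txgxl")$gamma
  }, 0)
  expect_lt(abs(median(g3) - 0.3), 0.15)

  # null three-way interaction
  g0 <- vapply(1:150, function(seed) {
    tab <- simulate_multilab(sim_config(seed = 1000 + seed,
                                        with_treatment = TRUE,
                                        sigma_txgxl = 0))
    gxl_factor(fit_treatment_model(tab, "sim", method = "moments"),
               kind = "txgxl")$gamma
  }, 0)
  expect_lt(median(g0), 0.1)
})

test_that("treatment confined to one lab is a design error naming the lab", {
  cfg <- sim_config(seed = 9, with_treatment = TRUE)
  tab <- as.data.frame(simulate_multilab(cfg))
  tab <- tab[!(tab$treatment == "treated" & tab$lab != "lab1"), ]
  expect_error(fit_treatment_model(as_measurement_table(tab), "sim"),
               "lab2")
})

test_that("negative moment estimates are truncated at zero and flagged", {
  # interaction-free data with tiny n makes negative EMS differences likely
  found <- FALSE
  for (seed in 1:20) {
    tab <- simulate_multilab(sim_config(seed = seed, n_per_group = 3,
                                        sigma_gxl = 0, sigma_lab = 0))
    fit <- fit_random_lab_model(tab, "sim", method = "moments")
    expect_gte(fit$sigma2_gxl, 0)
    expect_gte(fit$sigma2_lab, 0)
    if (length(fit$truncated)) found <- TRUE
  }
  expect_true(found)
})

test_that("REML handles unbalanced data after random drop-out", {
  tab <- simulate_dropout(simulate_multilab(sim_config(seed = 77)),
                          rate = 0.2, seed = 3)
  fit <- fit_random_lab_model(tab, "sim", method = "reml")
  expect_true(all(coef(fit) >= 0))
  expect_error(fit_random_lab_model(tab, "sim", method = "moments"),
               "balanced")
})
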