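#' Configuration for the Random Lab Model data generator
#'
#' Defines a fully crossed, balanced multi-lab phenotyping design generated
#' under the Random Lab Model: additive fixed genotype means, an additive
#' Gaussian lab effect, a Gaussian genotype-by-lab interaction, and Gaussian
#' within-group noise, all on the (possibly transformed) analysis scale.
#' With `with_treatment = TRUE` a fixed treatment effect plus random TxL and
#' TxGxL interactions are added, emulating a treated-males arm.
#'
#' Defaults mirror a typical multi-lab mouse phenotyping stratum: 3 labs,
#' 6 genotypes, 10 animals per group, unit within-group SD, a lab shift of
#' half an SD, and an interaction-to-error ratio of 0.57.
#'
#' @param n_labs,n_genotypes,n_per_group Design dimensions.
#' @param genotype_effects Fixed genotype means (length `n_genotypes`);
#'   default all zero (null configuration).
#' @param sigma_within Within-group error SD.
#' @param sigma_lab SD of the additive lab effect.
#' @param sigma_gxl SD of the genotype-by-lab interaction.
#' @param with_treatment Add a crossed control/treated arm?
#' @param treatment_effect Fixed treatment effect.
#' @param sigma_txl,sigma_txgxl SDs of the treatment-by-lab and
#'   treatment-by-genotype-by-lab interactions (used when
#'   `with_treatment = TRUE`).
#' @param sex Sex label stamped on the generated animals; the generator
#'   produces one sex stratum per call (bind several calls with different
#'   seeds for a multi-stratum study).
#' @param phenotype Phenotype label stamped on the records.
#' @param seed Integer seed; fully determines the generated table.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_labs = 3L, n_genotypes = 6L, n_per_group = 10L,
                       genotype_effects = rep(0, n_genotypes),
                       sigma_within = 1, sigma_lab = 0.5, sigma_gxl = 0.57,
                       with_treatment = FALSE, treatment_effect = 0,
                       sigma_txl = 0.3, sigma_txgxl = 0.3,
                       sex = if (with_treatment) "male" else "female",
                       phenotype = "sim", seed = 1L) {
  stopifnot(n_labs >= 1, n_genotypes >= 1, n_per_group >= 1,
            length(genotype_effects) == n_genotypes,
            sigma_within >= 0, sigma_lab >= 0, sigma_gxl >= 0,
            sigma_txl >= 0, sigma_txgxl >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(n_labs = as.integer(n_labs),
                 n_genotypes = as.integer(n_genotypes),
                 n_per_group = as.integer(n_per_group),
                 genotype_effects = as.numeric(genotype_effects),
                 sigma_within = sigma_within, sigma_lab = sigma_lab,
                 sigma_gxl = sigma_gxl, with_treatment = with_treatment,
                 treatment_effect = treatment_effect, sigma_txl = sigma_txl,
                 sigma_txgxl = sigma_txgxl, sex = sex, phenotype = phenotype,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-lab phenotyping dataset
#'
#' Draws one realisation of the Random Lab Model under `cfg`:
#' `value = mu_g (+ tau for treated) + L_l + GL_gl (+ TL_tl + TGL_tgl) + eps`,
#' every random term i.i.d. Gaussian at its configured SD. The design is
#' fully crossed and balanced; cell-level random effects are drawn before the
#' animal-level noise, in a fixed order, so the same seed yields the same
#' cell effects regardless of group size.
#'
#' @param cfg A [sim_config()].
#' @return A `measurement_table` with `n_labs * n_genotypes * n_per_group`
#'   rows (doubled when `with_treatment`).
#' @export
simulate_multilab <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  labs <- sprintf("lab%d", seq_len(cfg$n_labs))
  genos <- sprintf("g%02d", seq_len(cfg$n_genotypes))
  treatments <- if (cfg$with_treatment) c("control", "treated") else "control"

  L <- stats::rnorm(cfg$n_labs, 0, cfg$sigma_lab)
  GL <- matrix(stats::rnorm(cfg$n_genotypes * cfg$n_labs, 0, cfg$sigma_gxl),
               nrow = cfg$n_genotypes)
  if (cfg$with_treatment) {
    TL <- matrix(stats::rnorm(2 * cfg$n_labs, 0, cfg$sigma_txl), nrow = 2)
    TGL <- array(stats::rnorm(2 * cfg$n_genotypes * cfg$n_labs, 0,
                              cfg$sigma_txgxl),
                 dim = c(2, cfg$n_genotypes, cfg$n_labs))
  }

  grid <- expand.grid(animal = seq_len(cfg$n_per_group),
                      treatment = treatments, genotype = seq_len(cfg$n_genotypes),
                      lab = seq_len(cfg$n_labs), stringsAsFactors = FALSE)
  g <- grid$genotype; l <- grid$lab
  ti <- match(grid$treatment, c("control", "treated"))
  mu <- cfg$genotype_effects[g] + L[l] + GL[cbind(g, l)]
  if (cfg$with_treatment) {
    mu <- mu + (ti == 2L) * cfg$treatment_effect + TL[cbind(ti, l)] +
      TGL[cbind(ti, g, l)]
  }
  value <- mu + stats::rnorm(nrow(grid), 0, cfg$sigma_within)

  out <- data.frame(
    animal_id = sprintf("%s_%s_%s_%02d", labs[l], genos[g],
                        substr(grid$treatment, 1, 1), grid$animal),
    lab = labs[l], genotype = genos[g], sex = cfg$sex,
    treatment = grid$treatment, phenotype = cfg$phenotype, value = value,
    stringsAsFactors = FALSE)
  as_measurement_table(out)
}

#' Extract one lab's slice of a simulated multi-lab study
#'
#' Regenerates the multi-lab draw for `cfg` (same seed) and returns the
#' chosen lab's rows, emulating a single-lab study whose across-lab "truth"
#' is known to the harness: the union of all lab slices is exactly the
#' multi-lab table.
#'
#' @param cfg A [sim_config()].
#' @param lab_index Lab to extract, in `1..n_labs`.
#' @export
simulate_single_lab <- function(cfg, lab_index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (lab_index < 1L || lab_index > cfg$n_labs) {
    stop("lab_index must be in 1..", cfg$n_labs)
  }
  full <- simulate_multilab(cfg)
  lab <- sprintf("lab%d", as.integer(lab_index))
  out <- full[full$lab == lab, , drop = FALSE]
  class(out) <- class(full)
  out
}

#' Random animal drop-out
#'
#' Deletes each row independently with probability `rate`, to turn the
#' generator's balanced designs into unbalanced ones (e.g. for exercising
#' REML on ragged cells).
#'
#' @param table A measurement table.
#' @param rate Per-animal deletion probability in `[0, 1)`.
#' @param seed Integer seed.
#' @export
simulate_dropout <- function(table, rate, seed = 1L) {
  table <- as_measurement_table(table)
  stopifnot(rate >= 0, rate < 1)
  set.seed(seed)
  keep <- stats::runif(nrow(table)) >= rate
  out <- table[keep, , drop = FALSE]
  class(out) <- class(table)
  out
}
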