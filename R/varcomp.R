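#' Fit the Random Lab Model to multi-lab phenotyping data
#'
#' The Random Lab Model treats the genotype effect as fixed and both the lab
#' effect and the genotype-by-lab (GxL) interaction as independent Gaussian
#' random components:
#' \deqn{y_{gli} = \mu + \beta_g + L_l + (GL)_{gl} + \varepsilon_{gli},}
#' with \eqn{L_l \sim N(0, \sigma^2_L)}, \eqn{(GL)_{gl} \sim N(0,
#' \sigma^2_{GxL})} and \eqn{\varepsilon \sim N(0, \sigma^2)}. Under this
#' model the variance of a within-lab genotype mean difference picks up an
#' extra \eqn{2\sigma^2_{GxL}} that does not shrink with group size, which is
#' the quantity the GxL adjustment transfers to single-lab studies.
#'
#' @param table A measurement table covering at least 2 labs and 2 genotypes.
#' @param phenotype Phenotype label to analyse.
#' @param subpop Optional [subpopulation()] stratum; components are estimated
#'   separately per phenotype and stratum.
#' @param transform [transform_spec()] applied to the values before fitting.
#' @param method `"reml"` (default; via [lme4::lmer()]) or `"moments"`, the
#'   balanced-design expected-mean-squares ANOVA estimator, kept as an
#'   independent cross-check. The moments estimator refuses unbalanced
#'   designs.
#' @return An object of class `"random_lab_fit"`: a list with elements
#'   `sigma2_within`, `sigma2_lab`, `sigma2_gxl`, `n_labs`, `n_genotypes`,
#'   `n_total`, `phenotype`, `subpopulation`, `method`, and `truncated`
#'   (names of components estimated at the zero boundary).
#' @seealso [gxl_factor()], [fit_treatment_model()]
#' @examples
#' cfg <- sim_config(seed = 42, sigma_gxl = 0.5)
#' fit <- fit_random_lab_model(simulate_multilab(cfg), phenotype = "sim")
#' gxl_factor(fit)
#' @export
fit_random_lab_model <- function(table, phenotype, subpop = NULL,
                                 transform = transform_spec("identity"),
                                 method = c("reml", "moments")) {
  method <- match.arg(method)
  dat <- .filter_measurements(table, phenotype, subpop)
  dat$value <- apply_transform(dat$value, transform)
  dat$lab <- factor(dat$lab)
  dat$genotype <- factor(dat$genotype)
  .check_crossed_design(dat)

  est <- if (method == "reml") .reml_two_way(dat) else .moments_two_way(dat)
  structure(c(est, list(
    n_labs = nlevels(dat$lab), n_genotypes = nlevels(dat$genotype),
    n_total = nrow(dat), phenotype = phenotype,
    subpopulation = subpop, method = method
  )), class = "random_lab_fit")
}

.check_crossed_design <- function(dat, treatment = FALSE) {
  if (nlevels(dat$lab) < 2L) stop("design error: need at least 2 labs")
  if (nlevels(dat$genotype) < 2L) stop("design error: need at least 2 genotypes")
  tab <- table(dat$genotype, dat$lab)
  seen_in <- rowSums(tab > 0)
  if (sum(seen_in >= 2L) < 2L) {
    stop("design error: need at least 2 genotypes observed in at least 2 labs")
  }
  if (all(tab <= 1L)) {
    stop("design error: one animal per cell everywhere; ",
         "within-group variance is not identifiable")
  }
  if (treatment) {
    tt <- table(dat$treatment, dat$lab)
    missing_lab <- colnames(tt)[colSums(tt > 0) < 2L]
    if (length(missing_lab)) {
      stop("design error: treatment level missing entirely in lab(s): ",
           paste(missing_lab, collapse = ", "))
    }
    tg <- table(dat$treatment, dat$genotype)
    if (any(colSums(tg > 0) < 2L)) {
      stop("design error: both treatment levels must appear in at least 2 genotypes")
    }
  }
  invisible(TRUE)
}

.reml_two_way <- function(dat) {
  fit <- suppressMessages(lme4::lmer(
    value ~ genotype + (1 | lab) + (1 | lab:genotype),
    data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v[1L] else 0
  }
  out <- list(sigma2_within = pick("Residual"),
              sigma2_lab = pick("lab"),
              sigma2_gxl = pick("lab:genotype"))
  out$truncated <- names(out)[vapply(out, function(v) isTRUE(v <= 1e-10), TRUE)]
  out$truncated <- setdiff(out$truncated, "sigma2_within")
  out
}

# Balanced two-way mixed ANOVA estimator from expected mean squares:
#   E(MS_err) = s2;  E(MS_GxL) = s2 + n s2_GxL;  E(MS_L) = s2 + n s2_GxL + nG s2_L
.moments_two_way <- function(dat) {
  .check_balanced(dat, c("lab", "genotype"))
  n <- nrow(dat) / (nlevels(dat$lab) * nlevels(dat$genotype))
  G <- nlevels(dat$genotype)
  ms <- .mean_squares(dat, value ~ genotype + lab + lab:genotype)
  s2 <- ms["Residuals"]
  s2_gxl <- (ms["genotype:lab"] - s2) / n
  s2_lab <- (ms["lab"] - ms["genotype:lab"]) / (n * G)
  raw <- c(sigma2_within = unname(s2), sigma2_lab = unname(s2_lab),
           sigma2_gxl = unname(s2_gxl))
  truncated <- names(raw)[raw < 0]
  raw[raw < 0] <- 0
  c(as.list(raw), list(truncated = truncated))
}

.check_balanced <- function(dat, cols) {
  counts <- table(dat[cols])
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0)) {
    stop("the moments estimator requires a fully crossed balanced design; ",
         "use method = 'reml' for unbalanced data")
  }
  invisible(TRUE)
}

.mean_squares <- function(dat, formula) {
  a <- stats::anova(stats::lm(formula, data = dat))
  stats::setNames(a[["Mean Sq"]], rownames(a))
}

#' Fit the three-way Random Lab Model with a treatment arm
#'
#' Extends [fit_random_lab_model()] with a fixed treatment effect (and fixed
#' genotype-by-treatment interaction) and random interactions of all orders
#' that involve the lab: treatment-by-lab (TxL), genotype-by-lab (GxL) and
#' treatment-by-genotype-by-lab (TxGxL). The TxGxL component is the one that
#' survives in the treatment-difference contrast between genotypes and drives
#' its adjustment.
#'
#' @inheritParams fit_random_lab_model
#' @param sex Optional sex label restricting the analysis stratum (both
#'   treatment levels of that sex are used).
#' @return An object of class `c("random_lab_fit3", "random_lab_fit")` with
#'   the additional elements `sigma2_txl` and `sigma2_txgxl`.
#' @export
fit_treatment_model <- function(table, phenotype, sex = NULL,
                                transform = transform_spec("identity"),
                                method = c("reml", "moments")) {
  method <- match.arg(method)
  dat <- .filter_measurements(table, phenotype)
  if (!is.null(sex)) {
    dat <- dat[dat$sex == sex, , drop = FALSE]
    if (!nrow(dat)) stop("no rows for sex '", sex, "'")
  }
  dat$value <- apply_transform(dat$value, transform)
  dat$lab <- factor(dat$lab)
  dat$genotype <- factor(dat$genotype)
  dat$treatment <- factor(dat$treatment)
  if (nlevels(dat$treatment) < 2L) {
    stop("design error: both treatment levels must be present")
  }
  .check_crossed_design(dat, treatment = TRUE)

  est <- if (method == "reml") .reml_three_way(dat) else .moments_three_way(dat)
  structure(c(est, list(
    n_labs = nlevels(dat$lab), n_genotypes = nlevels(dat$genotype),
    n_total = nrow(dat), phenotype = phenotype,
    subpopulation = if (is.null(sex)) NULL else subpopulation(sex, "both"),
    method = method
  )), class = c("random_lab_fit3", "random_lab_fit"))
}

.reml_three_way <- function(dat) {
  fit <- suppressMessages(lme4::lmer(
    value ~ genotype * treatment + (1 | lab) + (1 | lab:genotype) +
      (1 | lab:treatment) + (1 | lab:genotype:treatment),
    data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v[1L] else 0
  }
  out <- list(sigma2_within = pick("Residual"),
              sigma2_lab = pick("lab"),
              sigma2_gxl = pick("lab:genotype"),
              sigma2_txl = pick("lab:treatment"),
              sigma2_txgxl = pick("lab:genotype:treatment"))
  out$truncated <- setdiff(
    names(out)[vapply(out, function(v) isTRUE(v <= 1e-10), TRUE)],
    "sigma2_within")
  out
}

# Balanced three-way EMS (unconstrained random components; genotype and
# treatment fixed). With n per cell, G genotypes, T=2 treatments:
#   E(MS_err)   = s2
#   E(MS_TGL)   = s2 + n s2_TGL
#   E(MS_GL)    = s2 + n s2_TGL + nT s2_GL
#   E(MS_TL)    = s2 + n s2_TGL + nG s2_TL
#   E(MS_L)     = s2 + n s2_TGL + nT s2_GL + nG s2_TL + nGT s2_L
.moments_three_way <- function(dat) {
  .check_balanced(dat, c("lab", "genotype", "treatment"))
  G <- nlevels(dat$genotype)
  Tt <- nlevels(dat$treatment)
  n <- nrow(dat) / (nlevels(dat$lab) * G * Tt)
  ms <- .mean_squares(dat,
    value ~ genotype * treatment + lab + lab:genotype + lab:treatment +
      lab:genotype:treatment)
  s2 <- ms[["Residuals"]]
  s2_tgl <- (ms[["genotype:treatment:lab"]] - s2) / n
  s2_gl <- (ms[["genotype:lab"]] - ms[["genotype:treatment:lab"]]) / (n * Tt)
  s2_tl <- (ms[["treatment:lab"]] - ms[["genotype:treatment:lab"]]) / (n * G)
  s2_l <- (ms[["lab"]] - ms[["genotype:lab"]] - ms[["treatment:lab"]] +
             ms[["genotype:treatment:lab"]]) / (n * G * Tt)
  raw <- c(sigma2_within = s2, sigma2_lab = s2_l, sigma2_gxl = s2_gl,
           sigma2_txl = s2_tl, sigma2_txgxl = s2_tgl)
  truncated <- names(raw)[raw < 0]
  raw[raw < 0] <- 0
  c(as.list(raw), list(truncated = truncated))
}

#' @export
print.random_lab_fit <- function(x, ...) {
  three <- inherits(x, "random_lab_fit3")
  cat(if (three) "Three-way Random Lab Model fit" else "Random Lab Model fit",
      sprintf("(%s)\n", toupper(x$method)))
  cat(sprintf("  phenotype: %s   labs: %d   genotypes: %d   animals: %d\n",
              x$phenotype, x$n_labs, x$n_genotypes, x$n_total))
  if (!is.null(x$subpopulation)) {
    cat("  stratum:", format(x$subpopulation), "\n")
  }
  comp <- coef(x)
  cat("  variance components:\n")
  for (nm in names(comp)) {
    cat(sprintf("    %-14s %10.5f%s\n", nm, comp[[nm]],
                if (nm %in% x$truncated) "  (truncated at 0)" else ""))
  }
  g <- tryCatch(gxl_factor(x), error = function(e) NULL)
  if (!is.null(g)) cat(sprintf("  GxL factor gamma: %.4f\n", g$gamma))
  invisible(x)
}

#' @export
coef.random_lab_fit <- function(object, ...) {
  nms <- intersect(c("sigma2_within", "sigma2_lab", "sigma2_gxl",
                     "sigma2_txl", "sigma2_txgxl"), names(object))
  unlist(object[nms])
}

#' @export
summary.random_lab_fit <- function(object, ...) {
  out <- list(components = coef(object),
              gamma = tryCatch(gxl_factor(object)$gamma,
                               error = function(e) NA_real_),
              fit = object)
  if (inherits(object, "random_lab_fit3")) {
    out$gamma_txgxl <- tryCatch(gxl_factor(object, "txgxl")$gamma,
                                error = function(e) NA_real_)
  }
  class(out) <- "summary.random_lab_fit"
  out
}

#' @export
print.summary.random_lab_fit <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' The dimensionless GxL factor
#'
#' The GxL factor \eqn{\gamma = \sqrt{\sigma^2_{GxL} / \sigma^2}} is the ratio
#' of the interaction SD to the within-group SD. Being a ratio of SDs on the
#' same scale it is dimensionless, so a value estimated in one set of labs can
#' be transferred to a study measured on a different multiplicative scale.
#' For treatment-difference contrasts the relevant factor uses the three-way
#' TxGxL component instead.
#'
#' @param x Either a [fit_random_lab_model()] / [fit_treatment_model()] fit, or
#'   a plain numeric `gamma` value (e.g. taken from a published database), in
#'   which case `n_labs` and `n_genotypes` of the source design are required.
#' @param kind `"gxl"` (genotype comparisons) or `"txgxl"`
#'   (treatment-difference contrasts; requires a three-way fit).
#' @param n_labs,n_genotypes Source design dimensions (numeric method only);
#'   they enter the Satterthwaite degrees of freedom of the adjusted test.
#' @param source Provenance string carried along for reporting.
#' @param ... Unused.
#' @return An object of class `"gxl_factor"` with elements `gamma`, `kind`,
#'   `n_labs`, `n_genotypes`, `source`, `phenotype`, `subpopulation`.
#' @examples
#' gxl_factor(sqrt(0.8^2 / 1.4^2), n_labs = 3, n_genotypes = 6)  # gamma = 0.57
#' @export
gxl_factor <- function(x, ...) UseMethod("gxl_factor")

#' @rdname gxl_factor
#' @export
gxl_factor.random_lab_fit <- function(x, kind = c("gxl", "txgxl"), ...) {
  kind <- match.arg(kind)
  if (x$sigma2_within <= 0) {
    stop("degenerate scale: within-group variance is zero; gamma undefined")
  }
  s2_int <- switch(kind,
    gxl = x$sigma2_gxl,
    txgxl = {
      if (is.null(x$sigma2_txgxl)) {
        stop("kind 'txgxl' requires a three-way treatment fit")
      }
      x$sigma2_txgxl
    })
  .new_gxl_factor(sqrt(s2_int / x$sigma2_within), kind,
                  x$n_labs, x$n_genotypes,
                  source = sprintf("%d-lab %s fit", x$n_labs, x$method),
                  phenotype = x$phenotype, subpopulation = x$subpopulation)
}

#' @rdname gxl_factor
#' @export
gxl_factor.numeric <- function(x, kind = c("gxl", "txgxl"), n_labs, n_genotypes,
                               source = "user-supplied", ...) {
  kind <- match.arg(kind)
  stopifnot(length(x) == 1L, is.finite(x), x >= 0)
  .new_gxl_factor(x, kind, n_labs, n_genotypes, source = source,
                  phenotype = NA_character_, subpopulation = NULL)
}

.new_gxl_factor <- function(gamma, kind, n_labs, n_genotypes, source,
                            phenotype, subpopulation) {
  stopifnot(n_labs >= 2L, n_genotypes >= 2L)
  structure(list(gamma = gamma, kind = kind,
                 n_labs = as.integer(n_labs),
                 n_genotypes = as.integer(n_genotypes),
                 source = source, phenotype = phenotype,
                 subpopulation = subpopulation),
            class = "gxl_factor")
}

#' @export
print.gxl_factor <- function(x, ...) {
  cat(sprintf("GxL factor (%s): gamma = %.4f\n", x$kind, x$gamma))
  cat(sprintf("  source: %s (%d labs x %d genotypes)\n",
              x$source, x$n_labs, x$n_genotypes))
  if (!is.na(x$phenotype)) cat("  phenotype:", x$phenotype, "\n")
  invisible(x)
}
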