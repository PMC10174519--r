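# GxL-aware power and sample size for two-group single-lab designs.
#
# Under the Random Lab Model the variance of a single-lab mean difference is
# sigma^2 (2/n) + 2 sigma^2 gamma^2; the interaction term does not shrink with
# n, so power has a gamma-imposed ceiling.

#' Specify a two-group design for power analysis
#'
#' @param effect Mean difference to detect, on the analysis scale.
#' @param sigma Within-group SD on the analysis scale (> 0).
#' @param gamma Plug-in GxL factor (>= 0).
#' @param n_per_group Animals per group (equal allocation).
#' @param alpha Two-sided level, default 0.05.
#' @param n_labs,n_genotypes Source design of `gamma` (df term); required
#'   when `gamma > 0`.
#' @export
power_design <- function(effect, sigma, gamma = 0, n_per_group,
                         alpha = 0.05, n_labs = NULL, n_genotypes = NULL) {
  stopifnot(is.finite(effect), sigma > 0, gamma >= 0,
            n_per_group >= 2, alpha > 0, alpha < 1)
  if (gamma > 0 && (is.null(n_labs) || is.null(n_genotypes))) {
    stop("gamma > 0 requires n_labs and n_genotypes of the source design")
  }
  structure(list(effect = effect, sigma = sigma, gamma = gamma,
                 n_per_group = as.integer(n_per_group), alpha = alpha,
                 n_labs = n_labs, n_genotypes = n_genotypes),
            class = "power_design")
}

#' Power of the GxL-adjusted two-group t test
#'
#' Noncentral-t power of the two-sided adjusted test: the noncentrality is
#' `effect / (sigma * sqrt(2/n + 2 gamma^2))` and the df come from
#' [satterthwaite_df()]. With `gamma = 0` this is the classical two-sample
#' power. Power is nonincreasing in `gamma` and, for `gamma > 0`, bounded
#' above by [power_limit()].
#'
#' @param d A [power_design()].
#' @return Power in (0, 1).
#' @examples
#' power_of_design(power_design(effect = 1, sigma = 1, n_per_group = 17))
#' @export
power_of_design <- function(d) {
  stopifnot(inherits(d, "power_design"))
  n <- d$n_per_group
  se_scale <- sqrt(2 / n + 2 * d$gamma^2)
  ncp <- d$effect / (d$sigma * se_scale)
  df <- satterthwaite_df(n, n, d$gamma, d$n_labs, d$n_genotypes)
  .t_power(ncp, df, d$alpha)
}

.t_power <- function(ncp, df, alpha) {
  crit <- stats::qt(1 - alpha / 2, df = df)
  stats::pt(-crit, df = df, ncp = ncp) +
    stats::pt(crit, df = df, ncp = ncp, lower.tail = FALSE)
}

#' Asymptotic power ceiling imposed by the GxL interaction
#'
#' As the group size grows, `2/n` vanishes but the `2 gamma^2` interaction
#' term does not: the noncentrality converges to
#' `effect / (sigma * sqrt(2) * gamma)` and the Satterthwaite df converge to
#' the interaction df `(n_labs - 1)(n_genotypes - 1)`. The resulting power is
#' the ceiling no sample size can exceed.
#'
#' @inheritParams power_design
#' @return Limiting power. Conventions: `effect = 0` returns `alpha`;
#'   `gamma = 0` with a nonzero effect returns 1.
#' @export
power_limit <- function(effect, sigma, gamma, alpha = 0.05,
                        n_labs = NULL, n_genotypes = NULL) {
  stopifnot(sigma > 0, gamma >= 0)
  if (gamma == 0) return(if (effect == 0) alpha else 1.0)
  stopifnot(!is.null(n_labs), !is.null(n_genotypes),
            n_labs >= 2, n_genotypes >= 2)
  ncp <- effect / (sigma * sqrt(2) * gamma)
  df <- (n_labs - 1) * (n_genotypes - 1)
  .t_power(ncp, df, alpha)
}

#' Required sample size under GxL-inflated variance
#'
#' Iterative scheme on top of the classical sample-size computation: start
#' from the classical per-group `n` at SD `sigma`; inflate the SD to
#' `sigma_1 = sigma * sqrt(1 + n * gamma^2)` (so that the classical variance
#' `sigma_1^2 * 2/n` reproduces the Random Lab Model variance
#' `sigma^2 (2/n) + 2 sigma^2 gamma^2`); recompute `n`; repeat to a fixed
#' point. The converged `n` is then polished against [power_of_design()] so
#' that `n` is the smallest integer whose adjusted power meets the target.
#' When the target exceeds the [power_limit()] ceiling the request is
#' unattainable and the ceiling is reported instead.
#'
#' @inheritParams power_design
#' @param target_power Desired power in (0, 1).
#' @param inflation `"relative"` (default) uses
#'   `sigma_1 = sigma * sqrt(1 + n gamma^2)`; `"absolute"` uses the literal
#'   recipe `sigma_1 = sqrt(sigma^2 + n gamma^2)`, which coincides with the
#'   former only when `sigma = 1` and is provided for compatibility.
#' @param max_iter Iteration cap.
#' @return Object of class `"required_n"`: list with `n` (integer, or `NA`
#'   if unattainable), `attainable`, `asymptotic_power`, `achieved_power`,
#'   `iterations`, `oscillated`.
#' @export
required_n <- function(effect, sigma, gamma = 0, alpha = 0.05,
                       target_power = 0.8, n_labs = NULL, n_genotypes = NULL,
                       inflation = c("relative", "absolute"),
                       max_iter = 100L) {
  inflation <- match.arg(inflation)
  stopifnot(target_power > 0, target_power < 1, effect != 0)
  limit <- power_limit(effect, sigma, gamma, alpha, n_labs, n_genotypes)
  if (gamma > 0 && target_power >= limit) {
    return(structure(list(n = NA_integer_, attainable = FALSE,
                          asymptotic_power = limit,
                          achieved_power = NA_real_, iterations = 0L,
                          oscillated = FALSE, target_power = target_power),
                     class = "required_n"))
  }
  classical_n <- function(sd) {
    ceiling(stats::power.t.test(delta = abs(effect), sd = sd,
                                sig.level = alpha,
                                power = target_power)$n)
  }
  n <- classical_n(sigma)
  seen <- integer()
  oscillated <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sigma1 <- switch(inflation,
      relative = sigma * sqrt(1 + n * gamma^2),
      absolute = sqrt(sigma^2 + n * gamma^2))
    n_new <- classical_n(sigma1)
    if (n_new == n) break
    if (n_new %in% seen) {  # 2-cycle: keep the larger fixed point
      oscillated <- TRUE
      n <- max(n, n_new)
      break
    }
    seen <- c(seen, n)
    n <- n_new
    if (iter >= max_iter) { oscillated <- TRUE; break }
  }
  pow <- function(k) {
    power_of_design(power_design(effect, sigma, gamma, k, alpha,
                                 n_labs, n_genotypes))
  }
  # polish: smallest integer n whose adjusted power meets the target
  n <- max(n, 2)
  hi <- as.numeric(n)
  while (pow(hi) < target_power) hi <- hi * 2
  lo <- 2
  while (lo < hi) {
    mid <- floor((lo + hi) / 2)
    if (pow(mid) >= target_power) hi <- mid else lo <- mid + 1
  }
  n <- hi
  structure(list(n = as.integer(n), attainable = TRUE,
                 asymptotic_power = limit, achieved_power = pow(n),
                 iterations = iter, oscillated = oscillated,
                 target_power = target_power),
            class = "required_n")
}

#' @export
print.required_n <- function(x, ...) {
  if (!x$attainable) {
    cat(sprintf(
      "target power %.2f is unattainable: the GxL interaction caps power at %.3f\n",
      x$target_power, x$asymptotic_power))
  } else {
    cat(sprintf("required n per group: %d  (achieved power %.3f, ceiling %.3f)\n",
                x$n, x$achieved_power, x$asymptotic_power))
    if (x$oscillated) cat("  note: iteration oscillated; larger fixed point taken\n")
  }
  invisible(x)
}
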