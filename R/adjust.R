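#' Pooled within-group standard deviation
#'
#' @param gx,gy Group summaries ([group_stats()] or one-row summaries) with
#'   `n >= 2` each.
#' @return `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' @export
pooled_sd <- function(gx, gy) {
  gx <- .as_group_stats(gx); gy <- .as_group_stats(gy)
  if (gx$n < 2L || gy$n < 2L) stop("pooled SD requires n >= 2 in both groups")
  sqrt(((gx$n - 1) * gx$sd^2 + (gy$n - 1) * gy$sd^2) / (gx$n + gy$n - 2))
}

# Pool any number of groups (used by the four-group treatment contrast).
.pooled_sd_multi <- function(groups) {
  ns <- vapply(groups, `[[`, 0, "n")
  sds <- vapply(groups, `[[`, 0, "sd")
  if (any(ns < 2)) stop("pooled SD requires n >= 2 in every group")
  sqrt(sum((ns - 1) * sds^2) / (sum(ns) - length(ns)))
}

#' Satterthwaite degrees of freedom for the GxL-adjusted t statistic
#'
#' The adjusted standard error mixes two independently estimated variances:
#' the single-lab pooled variance (with `n1 + n2 - 2` df) and the database
#' interaction variance (with `(n_L - 1)(n_S - 1)` df from its source
#' design). The effective df are
#' \deqn{\nu = \frac{(1/n_1 + 1/n_2 + 2\gamma^2)^2}
#'   {(1/n_1 + 1/n_2)^2/(n_1+n_2-2) + 4\gamma^4/((n_L-1)(n_S-1))},}
#' the common \eqn{s_p^4} factor cancelling. With `gamma = 0` this collapses
#' exactly to the pooled-t df `n1 + n2 - 2`.
#'
#' The approximation is capped at the pooled df `n1 + n2 - 2`: for small
#' `gamma` the raw ratio can exceed it, and an adjusted test must never gain
#' degrees of freedom over the classical one. Together with the inflated
#' standard error, the cap guarantees that adjustment can only increase the
#' p-value, for every input.
#'
#' @param n1,n2 Single-lab group sizes (>= 2).
#' @param gamma Plug-in GxL factor (>= 0).
#' @param n_labs,n_genotypes Dimensions of the multi-lab design from which
#'   `gamma` was estimated; required when `gamma > 0`.
#' @param contrast_scale `2` for a two-group genotype comparison (variance
#'   inflation `2 gamma^2`), `4` for the four-group treatment-difference
#'   contrast (inflation `4 gamma^2`; `n1`, `n2` are then effective sizes,
#'   see [adjusted_treatment_contrast()]).
#' @param df_error Error degrees of freedom; defaults to `n1 + n2 - 2`.
#' @return Effective degrees of freedom (positive, noninteger in general).
#' @export
satterthwaite_df <- function(n1, n2, gamma, n_labs = NULL, n_genotypes = NULL,
                             contrast_scale = 2, df_error = n1 + n2 - 2) {
  stopifnot(n1 >= 2, n2 >= 2, gamma >= 0, contrast_scale %in% c(2, 4),
            df_error >= 1)
  a <- 1 / n1 + 1 / n2
  if (gamma == 0) return(df_error)
  if (is.null(n_labs) || is.null(n_genotypes) || n_labs < 2 || n_genotypes < 2) {
    stop("gamma > 0 requires n_labs >= 2 and n_genotypes >= 2 ",
         "(interaction df undefined otherwise)")
  }
  df_int <- (n_labs - 1) * (n_genotypes - 1)
  infl <- contrast_scale * gamma^2
  min((a + infl)^2 / (a^2 / df_error + infl^2 / df_int), df_error)
}

.new_adjusted_result <- function(estimate, se, df, alpha, gamma, kind, adjusted,
                                 label) {
  t_stat <- estimate / se
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  p <- min(max(p, .Machine$double.xmin), 1)
  crit <- stats::qt(1 - alpha / 2, df = df)
  structure(list(estimate = estimate, se = se, t_stat = t_stat, df = df,
                 p_value = p, ci_low = estimate - crit * se,
                 ci_high = estimate + crit * se, alpha = alpha,
                 gamma_used = gamma, adjusted = adjusted, kind = kind,
                 label = label),
            class = "gxl_test")
}

#' @export
print.gxl_test <- function(x, digits = 4, ...) {
  cat(if (x$adjusted) "GxL-adjusted" else "Unadjusted (classical)",
      if (x$kind == "txgxl") "treatment-difference contrast\n" else "two-group t test\n")
  if (!is.null(x$label)) cat("  comparison:", x$label, "\n")
  cat(sprintf("  estimate = %.*f,  se = %.*f\n", digits, x$estimate, digits, x$se))
  cat(sprintf("  T = %.*f on %.2f df,  two-sided p = %.4g\n",
              digits, x$t_stat, x$df, x$p_value))
  cat(sprintf("  %d%% CI: [%.*f, %.*f]", round(100 * (1 - x$alpha)),
              digits, x$ci_low, digits, x$ci_high))
  if (x$adjusted) cat(sprintf("   (gamma = %.3f)", x$gamma_used))
  cat("\n")
  invisible(x)
}

#' GxL-adjusted t test for a single-lab genotype comparison
#'
#' Tests a genotype mean difference observed in one lab while accounting for
#' the genotype-by-lab interaction that would be seen across labs:
#' \deqn{T = \frac{\bar x - \bar y}{s_p\sqrt{1/n_1 + 1/n_2 + 2\gamma^2}},}
#' referred to Student's t with Satterthwaite df ([satterthwaite_df()]).
#' Because the interaction term is expressed through the dimensionless
#' \eqn{\gamma} and the lab's own \eqn{s_p}, the adjustment transfers across
#' measurement scales. With `gamma = 0` the result is exactly the classical
#' pooled two-sample t test. The adjusted standard error is never smaller
#' than the unadjusted one, so a nonsignificant single-lab result can never
#' become significant after adjustment.
#'
#' @param gx,gy Group summaries for the two genotypes, same lab and stratum.
#' @param factor A [gxl_factor()] with `kind = "gxl"` (a bare nonnegative
#'   number is rejected: the source design dimensions are needed for the df).
#' @param alpha Two-sided level, default 0.05.
#' @return An object of class `"gxl_test"` with elements `estimate`, `se`,
#'   `t_stat`, `df`, `p_value`, `ci_low`, `ci_high`, `alpha`, `gamma_used`,
#'   `adjusted`.
#' @examples
#' gx <- group_stats(10, 21.3, 1.4, genotype = "A")
#' gy <- group_stats(10, 20.0, 1.4, genotype = "B")
#' f <- gxl_factor(0.57, n_labs = 3, n_genotypes = 6)
#' adjusted_t_test(gx, gy, f)
#' @export
adjusted_t_test <- function(gx, gy, factor, alpha = 0.05) {
  gx <- .as_group_stats(gx); gy <- .as_group_stats(gy)
  stopifnot(inherits(factor, "gxl_factor"))
  if (factor$kind != "gxl") {
    stop("adjusted_t_test requires a factor of kind 'gxl'; ",
         "use adjusted_treatment_contrast for 'txgxl'")
  }
  if (factor$gamma < 0) stop("gamma must be nonnegative")
  if (gx$lab != gy$lab) stop("groups must come from the same lab")
  if (gx$sex != gy$sex || gx$treatment != gy$treatment) {
    stop("stratum mismatch: groups must share sex and treatment")
  }
  g <- factor$gamma
  sp <- pooled_sd(gx, gy)
  se <- sp * sqrt(1 / gx$n + 1 / gy$n + 2 * g^2)
  df <- satterthwaite_df(gx$n, gy$n, g, factor$n_labs, factor$n_genotypes)
  .new_adjusted_result(gx$mean - gy$mean, se, df, alpha, g, "gxl",
                       adjusted = g > 0,
                       label = paste(gx$genotype, "-", gy$genotype))
}

#' GxL-adjusted treatment-difference contrast between two genotypes
#'
#' Tests whether a treatment effect differs between two genotypes in one lab:
#' the contrast \eqn{(\bar x_T - \bar x_C) - (\bar y_T - \bar y_C)}. In the
#' three-way Random Lab Model the lab main effect, TxL and GxL interactions
#' all cancel in this contrast; the four independent TxGxL terms remain and
#' inflate its variance by \eqn{4 s_p^2 \gamma^2_{TxGxL}}:
#' \deqn{T = \frac{(\bar x_T-\bar x_C)-(\bar y_T-\bar y_C)}
#'   {s_p\sqrt{1/n_{1T}+1/n_{1C}+1/n_{2T}+1/n_{2C}+4\gamma^2_{TxGxL}}}.}
#' Degrees of freedom follow the analogous Satterthwaite form with the
#' `4 gamma^2` inflation, `16 gamma^4` in the interaction term, and pooled
#' error df `n1T + n1C + n2T + n2C - 4`.
#'
#' @param x_t,x_c Treated and control group summaries for the first genotype.
#' @param y_t,y_c Treated and control group summaries for the second genotype.
#' @param factor A [gxl_factor()] with `kind = "txgxl"`.
#' @param alpha Two-sided level, default 0.05.
#' @return A `"gxl_test"` object; see [adjusted_t_test()].
#' @export
adjusted_treatment_contrast <- function(x_t, x_c, y_t, y_c, factor,
                                        alpha = 0.05) {
  groups <- lapply(list(x_t = x_t, x_c = x_c, y_t = y_t, y_c = y_c),
                   .as_group_stats)
  stopifnot(inherits(factor, "gxl_factor"))
  if (factor$kind != "txgxl") {
    stop("adjusted_treatment_contrast requires a factor of kind 'txgxl'")
  }
  labs <- unique(vapply(groups, `[[`, "", "lab"))
  if (length(labs) != 1L) stop("all four groups must come from the same lab")
  g <- factor$gamma
  sp <- .pooled_sd_multi(groups)
  a <- sum(vapply(groups, function(x) 1 / x$n, 0))
  est <- (groups$x_t$mean - groups$x_c$mean) -
    (groups$y_t$mean - groups$y_c$mean)
  se <- sp * sqrt(a + 4 * g^2)
  N <- sum(vapply(groups, `[[`, 0L, "n"))
  # reuse the df kernel with the contrast's 1/n sum and 4*gamma^2 inflation
  df <- if (g == 0) N - 4 else {
    df_int <- (factor$n_labs - 1) * (factor$n_genotypes - 1)
    min((a + 4 * g^2)^2 / (a^2 / (N - 4) + 16 * g^4 / df_int), N - 4)
  }
  .new_adjusted_result(est, se, df, alpha, g, "txgxl", adjusted = g > 0,
                       label = paste0("(", groups$x_t$genotype, ": T-C) - (",
                                      groups$y_t$genotype, ": T-C)"))
}
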