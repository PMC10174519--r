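# Multi-lab "replicable / non-replicable" calls, A-F classification of
# single-lab comparisons, and type-I replicability error / power summaries.

#' Replicability calls for genotype pairs from a multi-lab study
#'
#' Declares a genotype difference "replicable" when it is statistically
#' significant in a multi-lab experiment analysed under the Random Lab Model:
#' the fixed genotype contrast is tested against a variance that includes the
#' GxL interaction, \eqn{se^2 = \hat\sigma^2 (1/\tilde n_1 + 1/\tilde n_2) +
#' 2\hat\sigma^2_{GxL}/L} (with the per-lab cell-mean average as the
#' estimate, so additive lab effects cancel), using Satterthwaite df that
#' combine the residual df with the `(L-1)(G-1)` interaction df.
#'
#' @param table Multi-lab measurement table (>= 2 labs).
#' @param phenotype Phenotype label.
#' @param subpop Optional [subpopulation()] stratum.
#' @param transform [transform_spec()] applied before analysis.
#' @param alpha Significance level for the replicability call, default 0.05.
#' @param method Variance-component estimator passed to
#'   [fit_random_lab_model()].
#' @param multiplicity `"none"` (default; each pair at level `alpha`) or
#'   `"tukey"` (studentized-range adjustment over all genotype pairs).
#' @return A data frame of class `"replicability_calls"` with one row per
#'   genotype pair present in every lab: `genotype_pair`, `estimate`, `se`,
#'   `df`, `p_value`, `replicable`. Pairs with a genotype absent from some
#'   lab are skipped with a warning.
#' @export
replicability_calls <- function(table, phenotype, subpop = NULL,
                                transform = transform_spec("identity"),
                                alpha = 0.05,
                                method = c("reml", "moments"),
                                multiplicity = c("none", "tukey")) {
  method <- match.arg(method)
  multiplicity <- match.arg(multiplicity)
  fit <- fit_random_lab_model(table, phenotype, subpop, transform, method)
  dat <- .filter_measurements(table, phenotype, subpop)
  dat$value <- apply_transform(dat$value, transform)

  labs <- sort(unique(dat$lab))
  genos <- sort(unique(dat$genotype))
  L <- length(labs)
  cell_n <- base::table(dat$genotype, dat$lab)
  cell_mean <- tapply(dat$value, list(dat$genotype, dat$lab), mean)

  df_err <- nrow(dat) - sum(cell_n > 0)
  df_int <- (fit$n_labs - 1) * (fit$n_genotypes - 1)
  s2 <- fit$sigma2_within
  s2_gxl <- fit$sigma2_gxl
  nbar <- nrow(dat) / sum(cell_n > 0)  # average animals per cell

  pairs <- utils::combn(genos, 2, simplify = FALSE)
  rows <- list()
  skipped <- character()
  for (pr in pairs) {
    n1 <- cell_n[pr[1L], ]; n2 <- cell_n[pr[2L], ]
    if (any(n1 == 0) || any(n2 == 0)) {
      skipped <- c(skipped, paste(pr, collapse = " - "))
      next
    }
    est <- mean(cell_mean[pr[1L], ]) - mean(cell_mean[pr[2L], ])
    # se^2 = sigma^2 sum(1/n1l + 1/n2l)/L^2 + 2 sigma^2_GxL / L, decomposed
    # as a*MSE-like + b*(sigma^2 + nbar sigma^2_GxL)-like pieces so the df
    # reflect the underlying mean squares: on balanced data a = 0 and the
    # test is an exact t with (L-1)(G-1) df, the classical balanced
    # mixed-model comparison.
    a_tot <- sum(1 / n1 + 1 / n2) / L^2
    b <- 2 / (nbar * L)
    a <- max(a_tot - b, 0)
    v_ms_int <- b * (s2 + nbar * s2_gxl)
    v_err <- a * s2
    se <- sqrt(v_err + v_ms_int)
    df <- if (v_err > 1e-12 * se^2) {
      (v_err + v_ms_int)^2 / (v_err^2 / df_err + v_ms_int^2 / df_int)
    } else df_int
    tval <- est / se
    p <- if (multiplicity == "tukey") {
      stats::ptukey(abs(tval) * sqrt(2), nmeans = length(genos),
                    df = df, lower.tail = FALSE)
    } else {
      2 * stats::pt(-abs(tval), df = df)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      genotype_pair = paste(pr, collapse = " - "),
      estimate = est, se = se, df = df, p_value = p,
      replicable = p <= alpha, stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning("skipping pair(s) with a genotype absent from some lab: ",
            paste(skipped, collapse = "; "))
  }
  if (!length(rows)) stop("no genotype pair is observed in every lab")
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  attr(out, "alpha") <- alpha
  class(out) <- c("replicability_calls", "data.frame")
  out
}

.category_levels <- c("A", "B", "C", "D", "E", "F")

#' Classify comparisons into the six replicability categories
#'
#' Each comparison is cross-classified by its multi-lab replicability call,
#' its original single-lab significance, and its GxL-adjusted significance:
#' \itemize{
#'   \item A: replicable, significant, adjusted significant
#'   \item B: replicable, significant, adjusted nonsignificant
#'   \item C: replicable, nonsignificant (missed by both)
#'   \item D: non-replicable, significant, adjusted significant
#'   \item E: non-replicable, significant, adjusted nonsignificant
#'   \item F: non-replicable, nonsignificant
#' }
#' The combination (single-lab nonsignificant, adjusted significant) is
#' impossible because the adjustment can only increase the p-value; it raises
#' an integrity error.
#'
#' @param replicable Logical vector of multi-lab calls.
#' @param single_lab_p Original single-lab p-values.
#' @param adjusted_p GxL-adjusted p-values (elementwise `>= single_lab_p`).
#' @param alpha Significance level, default 0.05.
#' @return Factor with levels A-F, one per comparison.
#' @export
classify_comparisons <- function(replicable, single_lab_p, adjusted_p,
                                 alpha = 0.05) {
  stopifnot(is.logical(replicable),
            length(single_lab_p) == length(replicable),
            length(adjusted_p) == length(replicable))
  if (any(single_lab_p <= 0 | single_lab_p > 1) ||
      any(adjusted_p <= 0 | adjusted_p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  sig1 <- single_lab_p <= alpha
  sig2 <- adjusted_p <= alpha
  if (any(!sig1 & sig2)) {
    stop("integrity error: adjusted p significant where single-lab p is not ",
         "(adjustment cannot decrease a p-value)")
  }
  cat_rep <- ifelse(sig1 & sig2, "A", ifelse(sig1, "B", "C"))
  cat_non <- ifelse(sig1 & sig2, "D", ifelse(sig1, "E", "F"))
  factor(ifelse(replicable, cat_rep, cat_non), levels = .category_levels)
}

#' Tabulate category counts
#'
#' @param categories Factor (or character) of categories A-F, e.g. from
#'   [classify_comparisons()]; alternatively a named numeric vector of counts.
#' @param alpha Level at which the classification was made (metadata).
#' @return Object of class `"replicability_table"`: named integer counts
#'   A-F plus the `alpha` attribute.
#' @export
category_table <- function(categories, alpha = 0.05) {
  if (is.numeric(categories)) {
    stopifnot(!is.null(names(categories)),
              setequal(names(categories), .category_levels))
    counts <- as.integer(categories[.category_levels])
    stopifnot(all(counts >= 0))
    counts <- stats::setNames(counts, .category_levels)
  } else {
    if (!length(categories)) stop("empty input: no comparisons to tabulate")
    categories <- factor(as.character(categories), levels = .category_levels)
    if (anyNA(categories)) stop("categories must all be in A..F")
    counts <- table(categories)
    counts <- stats::setNames(as.integer(counts), .category_levels)
  }
  structure(counts, alpha = alpha, class = "replicability_table")
}

#' @export
print.replicability_table <- function(x, ...) {
  cat("Replicability categories (alpha =", attr(x, "alpha"), ")\n")
  lab <- c(A = "replicable, approved by adjustment",
           B = "replicable, missed by adjustment",
           C = "replicable, missed by both",
           D = "non-replicable, insufficient adjustment",
           E = "non-replicable, prevented by adjustment",
           F = "non-replicable, prevented by both")
  for (k in .category_levels) {
    cat(sprintf("  %s  %-42s %4d\n", k, lab[[k]], x[[k]]))
  }
  invisible(x)
}

# Exact binomial proportion with Clopper-Pearson CI, on the percent scale.
.prop_ci <- function(k, n, conf = 0.95) {
  if (n == 0) {
    return(list(k = k, n = n, pct = NA_real_, lo = NA_real_, hi = NA_real_))
  }
  ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
  list(k = k, n = n, pct = 100 * k / n, lo = 100 * ci[1L], hi = 100 * ci[2L])
}

#' Summarise type-I replicability error and power
#'
#' From the category counts, the proportion of non-replicable comparisons
#' that were declared significant estimates the "type I replicability error"
#' of a single-lab discovery: `(D+E)/(D+E+F)` unadjusted and `D/(D+E+F)`
#' after GxL adjustment. The power to detect a replicable difference is
#' `(A+B)/(A+B+C)` unadjusted and `A/(A+B+C)` adjusted. Each proportion is
#' reported as a percentage with an exact (Clopper-Pearson) 95% CI; the CIs
#' are approximate in that they treat the individual decisions as
#' independent. A zero denominator leaves the corresponding entries
#' undefined (`NA`) rather than raising an error.
#'
#' @param table A [category_table()].
#' @param conf Confidence level for the exact binomial CIs, default 0.95.
#' @return Object of class `"replicability_summary"`: a list of four
#'   proportion records (`typeI_unadjusted`, `typeI_adjusted`,
#'   `power_unadjusted`, `power_adjusted`), each with `k`, `n`, `pct`, `lo`,
#'   `hi` on the percent scale.
#' @export
replicability_summary <- function(table, conf = 0.95) {
  stopifnot(inherits(table, "replicability_table"))
  n_non <- table[["D"]] + table[["E"]] + table[["F"]]
  n_rep <- table[["A"]] + table[["B"]] + table[["C"]]
  out <- list(
    typeI_unadjusted = .prop_ci(table[["D"]] + table[["E"]], n_non, conf),
    typeI_adjusted = .prop_ci(table[["D"]], n_non, conf),
    power_unadjusted = .prop_ci(table[["A"]] + table[["B"]], n_rep, conf),
    power_adjusted = .prop_ci(table[["A"]], n_rep, conf)
  )
  structure(out, conf = conf, alpha = attr(table, "alpha"),
            class = "replicability_summary")
}

#' Format a percentage for display
#'
#' Percentages are displayed rounded to one decimal and CI bounds to integers,
#' the package's table convention.
#'
#' @param pct Percentage value(s).
#' @param digits Decimal places (default 1).
#' @export
format_percent <- function(pct, digits = 1) {
  ifelse(is.na(pct), "-", sprintf(paste0("%.", digits, "f%%"), round(pct, digits)))
}

#' @export
print.replicability_summary <- function(x, ...) {
  lab <- c(typeI_unadjusted = "type I replicability error, single-lab",
           typeI_adjusted = "type I replicability error, GxL-adjusted",
           power_unadjusted = "power for replicable discoveries, single-lab",
           power_adjusted = "power for replicable discoveries, GxL-adjusted")
  cat("Replicability summary (", round(100 * attr(x, "conf")), "% exact CIs)\n",
      sep = "")
  for (nm in names(lab)) {
    e <- x[[nm]]
    if (is.na(e$pct)) {
      cat(sprintf("  %-46s undefined (0 denominator)\n", lab[[nm]]))
    } else {
      cat(sprintf("  %-46s %3d/%-3d = %6s  (%d-%d)\n", lab[[nm]], e$k, e$n,
                  format_percent(e$pct), round(e$lo), round(e$hi)))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.replicability_summary <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(nm) {
    e <- x[[nm]]
    data.frame(measure = nm, k = e$k, n = e$n, pct = e$pct,
               ci_low = e$lo, ci_high = e$hi, stringsAsFactors = FALSE)
  }))
}
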