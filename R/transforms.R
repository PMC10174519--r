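#' Phenotype scale transforms
#'
#' Many phenotypes are analysed on a transformed scale on which the additive
#' Gaussian assumptions of the Random Lab Model are more plausible: percent
#' phenotypes (e.g. center time, tail-suspension immobility) are logit
#' transformed, grip strength is taken to the 1/3 power, and skewed positive
#' measures may be logged. A `transform_spec` records the transform name and,
#' for the percent logit, the boundary clip `epsilon` applied on the
#' proportion scale.
#'
#' @param name One of `"identity"`, `"logit_percent"`, `"cube_root"`, `"log"`.
#' @param epsilon Boundary clip for `logit_percent`: percent values are mapped
#'   to proportions and clipped into `[epsilon, 1 - epsilon]` before the
#'   logit, so exact 0 or 100 remain finite. Default `1e-3`.
#' @return An object of class `"transform_spec"`.
#' @examples
#' tr <- transform_spec("logit_percent")
#' apply_transform(50, tr)  # 0 by symmetry
#' @export
transform_spec <- function(name = c("identity", "logit_percent", "cube_root", "log"),
                           epsilon = 1e-3) {
  name <- match.arg(name)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0, epsilon < 0.5)
  structure(list(name = name, epsilon = epsilon), class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("phenotype transform:", x$name)
  if (x$name == "logit_percent") cat("  (epsilon =", format(x$epsilon), "on proportion scale)")
  cat("\n")
  invisible(x)
}

#' Apply a scale transform elementwise
#'
#' @param values Numeric vector on the native measurement scale.
#' @param t A [transform_spec()]. A character name is accepted and promoted.
#' @return Numeric vector on the transformed scale.
#' @details `logit_percent` maps `v` to `log(p / (1 - p))` with
#'   `p = clip(v / 100, epsilon, 1 - epsilon)`; its domain is `[0, 100]`.
#'   `cube_root` requires nonnegative values; `log` requires positive values.
#'   All transforms are strictly monotone on their domain.
#' @export
apply_transform <- function(values, t = transform_spec("identity")) {
  if (is.character(t)) t <- transform_spec(t)
  stopifnot(inherits(t, "transform_spec"))
  values <- as.numeric(values)
  if (anyNA(values)) stop("transform input contains missing values")
  switch(t$name,
    identity = values,
    logit_percent = {
      if (any(values < 0 | values > 100)) {
        stop("logit_percent requires values in [0, 100]; offending value: ",
             format(values[which(values < 0 | values > 100)[1L]]))
      }
      p <- pmin(pmax(values / 100, t$epsilon), 1 - t$epsilon)
      log(p / (1 - p))
    },
    cube_root = {
      if (any(values < 0)) {
        stop("cube_root requires nonnegative values; offending value: ",
             format(values[which(values < 0)[1L]]))
      }
      values^(1 / 3)
    },
    log = {
      if (any(values <= 0)) {
        stop("log requires strictly positive values; offending value: ",
             format(values[which(values <= 0)[1L]]))
      }
      log(values)
    }
  )
}

#' Invert a scale transform
#'
#' Inverse of [apply_transform()] on the open interior of each transform's
#' domain (for `logit_percent`, the clipped boundary cannot be inverted).
#'
#' @inheritParams apply_transform
#' @export
invert_transform <- function(values, t = transform_spec("identity")) {
  if (is.character(t)) t <- transform_spec(t)
  stopifnot(inherits(t, "transform_spec"))
  values <- as.numeric(values)
  switch(t$name,
    identity = values,
    logit_percent = 100 * stats::plogis(values),
    cube_root = values^3,
    log = exp(values)
  )
}
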