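# Tidy per-animal measurement records: the universal input of the toolkit.
# Canonical columns: animal_id, lab, genotype, sex, treatment, phenotype, value.

.canonical_cols <- c("animal_id", "lab", "genotype", "sex", "treatment",
                     "phenotype", "value")

#' Validate a measurement table
#'
#' Checks an in-memory data frame against the measurement-table contract:
#' canonical columns present, no missing lab/genotype/phenotype/value, finite
#' numeric values, and unique (animal_id, phenotype) pairs.
#'
#' @param df A data frame with the canonical columns.
#' @return The validated data frame, with `value` numeric and the categorical
#'   columns as character, invisibly classed `"measurement_table"`.
#' @export
as_measurement_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.canonical_cols, names(df))
  if (length(missing_cols)) {
    stop("measurement table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, .canonical_cols]
  for (col in setdiff(.canonical_cols, "value")) {
    df[[col]] <- as.character(df[[col]])
  }
  if (!is.numeric(df$value)) {
    suppressWarnings(v <- as.numeric(df$value))
    bad <- which(is.na(v) & !is.na(df$value))
    if (length(bad)) {
      stop("non-numeric phenotype value at row ", bad[1L], ": '",
           df$value[bad[1L]], "'")
    }
    df$value <- v
  }
  for (col in c("lab", "genotype", "phenotype")) {
    if (anyNA(df[[col]]) || any(!nzchar(df[[col]]))) {
      stop("missing values in required column '", col, "'")
    }
  }
  if (anyNA(df$value) || any(!is.finite(df$value))) {
    stop("missing or non-finite phenotype value at row ",
         which(!is.finite(df$value))[1L])
  }
  dup <- duplicated(df[, c("animal_id", "phenotype")])
  if (any(dup)) {
    stop("duplicate (animal_id, phenotype) pair at row ", which(dup)[1L],
         ": animal '", df$animal_id[which(dup)[1L]], "'")
  }
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Read per-animal phenotype measurements from CSV
#'
#' Reads a long-format CSV (one row per animal and phenotype) and validates it
#' as a measurement table. Column names in the file may differ from the
#' canonical names; supply `schema` to map them.
#'
#' @param path Path to a comma-separated, UTF-8, headered CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(animal_id = "mouse", value = "measurement")`. Unmapped canonical
#'   columns are taken verbatim from the file.
#' @return A validated `measurement_table` data frame.
#' @seealso [write_measurements()], [as_measurement_table()]
#' @export
read_measurements <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  wanted <- stats::setNames(.canonical_cols, .canonical_cols)
  if (!is.null(schema)) {
    stopifnot(is.character(schema), !is.null(names(schema)))
    unknown <- setdiff(names(schema), .canonical_cols)
    if (length(unknown)) stop("schema maps unknown column(s): ",
                              paste(unknown, collapse = ", "))
    wanted[names(schema)] <- schema
  }
  absent <- wanted[!wanted %in% names(raw)]
  if (length(absent)) {
    stop("input file lacks required column(s): ",
         paste(sprintf("%s (expected as '%s')", names(absent), absent),
               collapse = ", "))
  }
  df <- stats::setNames(raw[, wanted, drop = FALSE], names(wanted))
  as_measurement_table(df)
}

#' Write a measurement table to CSV
#'
#' @param table A `measurement_table` (or coercible data frame).
#' @param path Output file path.
#' @export
write_measurements <- function(table, path) {
  table <- as_measurement_table(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Define an analysis stratum (subpopulation)
#'
#' Multi-lab phenotyping designs are analysed within strata defined by sex and
#' treatment; the canonical three are untreated females, untreated males, and
#' treated males.
#'
#' @param sex `"female"` or `"male"` (any label is allowed).
#' @param treatment `"control"` or `"treated"` (any label is allowed).
#' @export
subpopulation <- function(sex, treatment = "control") {
  stopifnot(is.character(sex), length(sex) == 1L,
            is.character(treatment), length(treatment) == 1L)
  structure(list(sex = sex, treatment = treatment), class = "subpopulation")
}

#' @export
print.subpopulation <- function(x, ...) {
  cat("subpopulation: sex =", x$sex, ", treatment =", x$treatment, "\n")
  invisible(x)
}

#' @export
format.subpopulation <- function(x, ...) paste0(x$sex, "/", x$treatment)

# Subset a measurement table to one phenotype (and optionally one stratum).
.filter_measurements <- function(table, phenotype, subpop = NULL) {
  table <- as_measurement_table(table)
  keep <- table$phenotype == phenotype
  if (!any(keep)) stop("no rows for phenotype '", phenotype, "'")
  out <- table[keep, , drop = FALSE]
  if (!is.null(subpop)) {
    stopifnot(inherits(subpop, "subpopulation"))
    keep <- out$sex == subpop$sex & out$treatment == subpop$treatment
    if (!any(keep)) {
      stop("no rows for phenotype '", phenotype, "' in subpopulation ",
           format(subpop))
    }
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Per-group summary statistics
#'
#' Summarises a measurement table into one record per
#' (lab, genotype, sex, treatment) cell: group size `n`, mean and SD on the
#' transformed scale. These are the sufficient statistics consumed by the
#' adjusted tests. Groups with fewer than 2 animals cannot contribute a
#' within-group variance; they are dropped with a warning and listed in the
#' `"excluded"` attribute.
#'
#' @param table A measurement table.
#' @param phenotype Phenotype label to summarise.
#' @param transform A [transform_spec()] (or its name) applied before
#'   summarising.
#' @param subpop Optional [subpopulation()] restriction.
#' @return A data frame of class `"group_stats_table"` with columns
#'   `lab, genotype, sex, treatment, n, mean, sd` (SD uses the n-1
#'   denominator).
#' @export
group_summaries <- function(table, phenotype,
                            transform = transform_spec("identity"),
                            subpop = NULL) {
  dat <- .filter_measurements(table, phenotype, subpop)
  dat$value <- apply_transform(dat$value, transform)
  key <- interaction(dat$lab, dat$genotype, dat$sex, dat$treatment, drop = TRUE)
  pieces <- split(dat, key)
  out <- do.call(rbind, lapply(pieces, function(g) {
    data.frame(lab = g$lab[1L], genotype = g$genotype[1L], sex = g$sex[1L],
               treatment = g$treatment[1L], n = nrow(g),
               mean = mean(g$value),
               sd = if (nrow(g) >= 2L) stats::sd(g$value) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  small <- out$n < 2L
  if (any(small)) {
    cells <- paste(out$lab[small], out$genotype[small],
                   paste0(out$sex[small], "/", out$treatment[small]),
                   sep = ":")
    warning("excluding ", sum(small), " group(s) with fewer than 2 animals: ",
            paste(cells, collapse = "; "))
  }
  excluded <- out[small, , drop = FALSE]
  out <- out[!small, , drop = FALSE]
  attr(out, "excluded") <- excluded
  attr(out, "phenotype") <- phenotype
  class(out) <- c("group_stats_table", "data.frame")
  out
}

#' Construct a single group's summary statistics
#'
#' Convenience constructor for feeding the adjusted tests directly from
#' published summary statistics rather than raw data.
#'
#' @param n Group size (>= 2 when `sd` is used for inference).
#' @param mean,sd Group mean and SD on the analysis (transformed) scale; the
#'   SD uses the n-1 denominator.
#' @param lab,genotype,sex,treatment Optional labels.
#' @export
group_stats <- function(n, mean, sd, lab = "lab1", genotype = "g",
                        sex = "female", treatment = "control") {
  stopifnot(n >= 1, is.finite(mean), is.finite(sd), sd >= 0)
  structure(list(lab = lab, genotype = genotype, sex = sex,
                 treatment = treatment, n = as.integer(n),
                 mean = mean, sd = sd),
            class = "group_stats")
}

# Accept either a group_stats object or a single row of a group_stats_table.
.as_group_stats <- function(g) {
  if (inherits(g, "group_stats")) return(g)
  if (is.data.frame(g) && nrow(g) == 1L) {
    return(group_stats(g$n, g$mean, g$sd, lab = g$lab, genotype = g$genotype,
                       sex = g$sex, treatment = g$treatment))
  }
  if (is.list(g) && all(c("n", "mean", "sd") %in% names(g))) {
    return(group_stats(g$n, g$mean, g$sd,
                       lab = if (is.null(g$lab)) "lab1" else g$lab,
                       genotype = if (is.null(g$genotype)) "g" else g$genotype,
                       sex = if (is.null(g$sex)) "female" else g$sex,
                       treatment = if (is.null(g$treatment)) "control" else g$treatment))
  }
  stop("cannot interpret group statistics; supply group_stats() or a one-row summary")
}
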