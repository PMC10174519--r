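# Shared fixtures and small generators used across the test files.

# Category counts from the published multi-lab replication analyses, bundled
# as a plain-text fixture (the raw animal-level data are not redistributed).
published_counts <- function(analysis) {
  path <- system.file("extdata", "category_counts.csv", package = "gxladjust")
  df <- read.csv(path, stringsAsFactors = FALSE)
  row <- df[df$analysis == analysis, , drop = FALSE]
  stopifnot(nrow(row) == 1L)
  unlist(row[, c("A", "B", "C", "D", "E", "F")])
}

# A tiny deterministic measurement table for I/O and summary tests.
tiny_table <- function() {
  as_measurement_table(data.frame(
    animal_id = sprintf("a%02d", 1:12),
    lab = rep(c("labA", "labB"), each = 6),
    genotype = rep(rep(c("g1", "g2"), each = 3), 2),
    sex = "female", treatment = "control", phenotype = "bw",
    value = c(1, 2, 3, 4, 5, 6, 2, 3, 4, 5, 6, 7),
    stringsAsFactors = FALSE))
}

# Draw a single lab's two-genotype experiment directly under the Random Lab
# Model (zero fixed difference unless stated): independent of the package's
# simulate module, for use as a cross-checking generator.
draw_single_lab_pair <- function(n, sigma, gamma, effect = 0) {
  gl <- rnorm(2, 0, gamma * sigma)
  x <- effect + gl[1] + rnorm(n, 0, sigma)
  y <- gl[2] + rnorm(n, 0, sigma)
  list(x = x, y = y)
}

stats_of <- function(v, genotype = "g", lab = "lab1") {
  group_stats(length(v), mean(v), sd(v), lab = lab, genotype = genotype)
}
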