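#' Published reference PRD tables
#'
#' Mean test PRD (percent) reported for two reconstructors — a plain
#' convolutional network and the residual CS-ResNet — trained on the
#' original motor-imagery EEG dataset ("none") and on the dataset
#' augmented with 25-100% of the adversarially generated frames, across
#' compression ratios 10-90%. Shipped as input for the delta-arithmetic
#' routines that summarize the augmentation benefit.
#'
#' @return list of two numeric matrices (`cnn`, `cs_resnet`), rows =
#'   compression ratio (90% down to 10%), columns = augmentation
#'   fraction.
#' @export
reference_prd_tables <- function() {
  cols <- c("none", "add25", "add50", "add75", "add100")
  rows <- paste0(seq(90, 10, by = -10), "%")
  cnn <- matrix(c(
    0.9728, 0.9291, 0.8852, 0.8477, 0.8212,
    1.0507, 0.9913, 0.9343, 0.9064, 0.8796,
    1.2605, 1.1954, 1.1436, 1.1108, 1.0954,
    1.3053, 1.2589, 1.1997, 1.1539, 1.1297,
    1.5008, 1.4321, 1.3847, 1.3583, 1.3178,
    2.2074, 2.1282, 2.0693, 2.0165, 1.9855,
    6.2556, 5.9215, 5.7764, 5.3842, 5.0331,
    25.7751, 24.8785, 24.0494, 22.7955, 21.9786,
    44.2411, 42.7291, 41.2338, 39.8773, 38.6593),
    nrow = 9, byrow = TRUE, dimnames = list(rows, cols))
  cs_resnet <- matrix(c(
    0.5485, 0.4889, 0.4465, 0.4178, 0.3966,
    0.5976, 0.5447, 0.4979, 0.4766, 0.4498,
    0.6198, 0.5623, 0.5244, 0.4981, 0.4763,
    0.6506, 0.5991, 0.5493, 0.5212, 0.5049,
    0.7996, 0.7268, 0.6881, 0.6549, 0.6411,
    1.0016, 0.9546, 0.9173, 0.8896, 0.8588,
    3.9906, 3.6824, 3.4564, 3.3151, 3.1890,
    20.1886, 19.2756, 18.2276, 17.3934, 16.4784,
    30.2299, 29.3579, 27.9547, 26.6872, 25.5369),
    nrow = 9, byrow = TRUE, dimnames = list(rows, cols))
  list(cnn = cnn, cs_resnet = cs_resnet)
}

#' Improvement deltas of a PRD table
#'
#' `delta(fraction) = PRD(none) - PRD(fraction)`, truncated (not
#' rounded) to 2 decimals — the convention relating the reference
#' tables' cells to the prose range statements.
#'
#' @param tab PRD matrix with a "none" column (e.g. one element of
#'   [reference_prd_tables()], or `$prd` of a
#'   [augmentation_benchmark()] result).
#' @return matrix of truncated deltas, one column per fraction.
#' @export
prd_deltas <- function(tab) {
  if (inherits(tab, "prd_table")) tab <- tab$prd
  if (!("none" %in% colnames(tab))) stop("table needs a 'none' column")
  prd_delta_matrix(tab)
}

#' Summarize the augmentation benefit of a PRD table
#'
#' Reproduces the standard presentation of the reference results: the
#' per-fraction delta averaged over compression ratios 40-90% (then
#' truncated), plus the per-row deltas at CR = 30%, 20% and 10%; each
#' group is reported as the min-max range across augmentation
#' fractions.
#'
#' @param tab PRD matrix with rownames "10%".."90%" and a "none" column.
#' @return data.frame with columns `group`, `min_delta`, `max_delta`.
#' @export
improvement_summary <- function(tab) {
  if (inherits(tab, "prd_table")) tab <- tab$prd
  base <- tab[, "none"]
  fr_cols <- setdiff(colnames(tab), "none")
  raw <- base - tab[, fr_cols, drop = FALSE]
  hi <- paste0(seq(40, 90, by = 10), "%")
  hi <- intersect(hi, rownames(tab))
  rows <- list()
  if (length(hi) > 0) {
    avg <- trunc2(colMeans(raw[hi, , drop = FALSE]))
    rows[["40-90%"]] <- range(avg)
  }
  for (cr in c("30%", "20%", "10%")) {
    if (cr %in% rownames(tab)) {
      rows[[cr]] <- range(trunc2(raw[cr, ]))
    }
  }
  data.frame(group = names(rows),
             min_delta = vapply(rows, `[`, numeric(1L), 1L),
             max_delta = vapply(rows, `[`, numeric(1L), 2L),
             row.names = NULL)
}
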