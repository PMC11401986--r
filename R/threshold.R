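#' No-call genotype calls below a score threshold
#'
#' Records whose score is strictly below the threshold have their genotype
#' replaced by NC; everything else is untouched. The original genotype is
#' retained in a `gtype_orig` shadow column (created on first application,
#' never overwritten), and records that were already NC stay NC. The
#' inequality is strict, so threshold 0 is a no-op.
#'
#' @param t Genotype table.
#' @param score_col Name of the score column to threshold (e.g. `"score"`
#'   for the vendor GenCall score or `"rfgda_score"`).
#' @param threshold Value in `[0, 1]`.
#' @return The table with `gtype` updated and `gtype_orig` present.
#' @export
#' @examples
#' t <- data.frame(gtype = c("AA", "AB"), score = c(0.4, 0.6))
#' set_threshold(t, "score", 0.5)$gtype   # "NC" "AB"
set_threshold <- function(t, score_col = "rfgda_score", threshold = 0.5) {
  if (!score_col %in% names(t))
    abort_parameter("no such score column: %s", score_col)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    abort_parameter("threshold must be a single value in [0, 1]")
  if (!"gtype_orig" %in% names(t)) t$gtype_orig <- t$gtype
  t$gtype[t[[score_col]] < threshold] <- "NC"
  t
}

#' Sweep score thresholds and tabulate call rates
#'
#' For each score column ("algorithm") and each threshold of the grid:
#' apply [set_threshold()], compute per-individual genotype-class
#' proportions ([callrate()]), pivot the classes to columns and derive
#' `callrate = AA + AB + BB`. Each threshold is applied to the original
#' table, so rows are directly comparable across the grid. This is the
#' computation behind score-threshold performance curves comparing the
#' two-layer score against the vendor GenCall score.
#'
#' @param t Genotype table with `individual`, `gtype` and the score columns.
#' @param score_cols Character vector of score columns to sweep.
#' @param grid Numeric vector of thresholds in `[0, 1]`.
#' @return Long data frame keyed (`individual`, `thr`, `alg`) with columns
#'   `AA`, `AB`, `BB`, `NC`, `callrate`.
#' @export
threshold_sweep <- function(t, score_cols = c("rfgda_score", "score"),
                            grid = seq(0, 0.96, by = 0.01)) {
  if (!length(grid)) abort_parameter("threshold grid must be non-empty")
  if (!is.numeric(grid) || any(grid < 0) || any(grid > 1))
    abort_parameter("threshold grid values must lie in [0, 1]")
  miss <- setdiff(score_cols, names(t))
  if (length(miss))
    abort_parameter("no such score column(s): %s", paste(miss, collapse = ", "))
  rows <- vector("list", length(score_cols) * length(grid))
  k <- 0L
  for (alg in score_cols) {
    for (thr in grid) {
      cr <- callrate(set_threshold(t, alg, thr), group_by = "individual")
      wide <- stats::reshape(cr, idvar = "individual", timevar = "gtype",
                             direction = "wide")
      names(wide) <- sub("^Callrate\\.", "", names(wide))
      wide$callrate <- wide$AA + wide$AB + wide$BB
      wide$thr <- thr
      wide$alg <- alg
      k <- k + 1L
      rows[[k]] <- wide
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[c("individual", "thr", "alg", "AA", "AB", "BB", "NC", "callrate")]
}

#' Mean and standard error of sweep curves across individuals
#'
#' Collapses a [threshold_sweep()] table to one row per (threshold,
#' algorithm): mean and standard error of the mean (sample SD / sqrt(n)) of
#' the call rate and of the AB proportion across individuals. With a single
#' individual the SEM is undefined and reported as `NA`.
#'
#' @param s Sweep table from [threshold_sweep()].
#' @return Data frame with columns `thr`, `alg`, `n`, `mean_callrate`,
#'   `sem_callrate`, `mean_AB`, `sem_AB`.
#' @export
summarize_sweep <- function(s) {
  need <- c("individual", "thr", "alg", "AB", "callrate")
  miss <- setdiff(need, names(s))
  if (length(miss))
    abort_parameter("sweep table is missing column(s): %s",
                    paste(miss, collapse = ", "))
  key <- paste(s$alg, format(s$thr, digits = 15), sep = "\r")
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  sem <- function(v) if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
  first <- !duplicated(key)
  out <- data.frame(thr = s$thr[first], alg = s$alg[first])
  ord_key <- key[first]
  out$n <- as.integer(tapply(s$callrate, key, length)[ord_key])
  out$mean_callrate <- tapply(s$callrate, key, mean)[ord_key]
  out$sem_callrate <- tapply(s$callrate, key, sem)[ord_key]
  out$mean_AB <- tapply(s$AB, key, mean)[ord_key]
  out$sem_AB <- tapply(s$AB, key, sem)[ord_key]
  rownames(out) <- NULL
  out[order(out$alg, out$thr), ]
}
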