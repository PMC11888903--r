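# Rank-based comparison of classifiers: Friedman omnibus test over blocks
# (by default the five metric values of one trial, treatments = the
# classifiers), Nemenyi post-hoc pairwise p-values from the Studentized
# range distribution, and the critical difference
#   CD = q_alpha * sqrt(k (k + 1) / (6 N)),
# q_alpha the Studentized range quantile divided by sqrt(2). Ranks are
# computed with "higher metric is better" (rank 1 = best); ties share the
# mean rank.

.blockRanks <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 classifiers (columns)")
  if (nrow(mat) < 2L) stop("need at least 2 blocks (rows)")
  if (any(!is.finite(mat))) stop("block matrix must be complete")
  t(apply(-mat, 1L, rank))
}

#' Friedman rank test over a block matrix
#'
#' Within-block average ranks (ties share the mean rank) with the
#' chi-square approximation, including the standard tie correction. When
#' every block is completely tied the statistic is 0 and the p-value 1.
#'
#' @param mat numeric matrix, blocks in rows, classifiers in columns.
#' @return list with `statistic`, `pValue`, `df`, and `avgRanks` (named if
#'   `mat` has column names).
#' @export
friedmanRankTest <- function(mat) {
  R <- .blockRanks(mat)
  N <- nrow(R)
  k <- ncol(R)
  Rsum <- colSums(R)
  stat <- 12 / (N * k * (k + 1)) * sum(Rsum^2) - 3 * N * (k + 1)
  ties <- sum(apply(R, 1L, function(r) {
    tab <- table(r)
    sum(tab^3 - tab)
  }))
  corr <- 1 - ties / (N * k * (k^2 - 1))
  if (corr <= 0) {
    stat <- 0
    p <- 1
  } else {
    stat <- stat / corr
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  list(statistic = stat, pValue = p, df = k - 1,
       avgRanks = colMeans(R))
}

#' Nemenyi pairwise post-hoc p-values
#'
#' For every classifier pair, the p-value of the average-rank difference
#' under the Studentized range distribution with infinite degrees of
#' freedom. Off-diagonal values are reported capped to the 0.001-0.900
#' range of the standard tabulations; the diagonal is 1.
#'
#' @param mat numeric block matrix (blocks x classifiers).
#' @param cap logical; cap off-diagonal p-values to 0.001-0.900
#'   (default TRUE).
#' @return Symmetric k x k matrix of p-values.
#' @export
nemenyiPairwise <- function(mat, cap = TRUE) {
  R <- .blockRanks(mat)
  N <- nrow(R)
  k <- ncol(R)
  avg <- colMeans(R)
  se <- sqrt(k * (k + 1) / (6 * N))
  p <- matrix(1, k, k, dimnames = list(colnames(R), colnames(R)))
  for (i in seq_len(k - 1L))
    for (j in seq(i + 1L, k)) {
      q <- abs(avg[i] - avg[j]) / se
      pij <- stats::ptukey(q * sqrt(2), nmeans = k, df = Inf,
                           lower.tail = FALSE)
      if (cap) pij <- min(max(pij, 0.001), 0.900)
      p[i, j] <- p[j, i] <- pij
    }
  p
}

#' Critical difference for average ranks
#'
#' `CD = q_alpha * sqrt(k (k + 1) / (6 N))`, with `q_alpha` the upper
#' Studentized range quantile (infinite df) divided by sqrt(2). Two
#' classifiers differ significantly when their average ranks differ by at
#' least CD.
#'
#' @param k number of classifiers (>= 2).
#' @param N number of blocks/datasets (>= 1).
#' @param alpha significance level, 0.05 or 0.10.
#' @return numeric scalar.
#' @examples
#' criticalDifference(6, 5) # 3.372 at alpha = 0.05
#' @export
criticalDifference <- function(k, N, alpha = 0.05) {
  stopifnot(k >= 2, N >= 1)
  if (!alpha %in% c(0.05, 0.10)) stop("alpha must be 0.05 or 0.10")
  qAlpha <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  qAlpha * sqrt(k * (k + 1) / (6 * N))
}

#' Full rank comparison of one block matrix
#'
#' Convenience wrapper: Friedman omnibus, Nemenyi pairwise matrix, average
#' ranks and the critical difference at `alpha`.
#'
#' @param mat block matrix (blocks x classifiers).
#' @param alpha significance level (0.05 or 0.10).
#' @return list with `friedman`, `nemenyi`, `avgRanks`, `cd`, `alpha`.
#' @export
compareClassifiers <- function(mat, alpha = 0.05) {
  fr <- friedmanRankTest(mat)
  list(friedman = fr, nemenyi = nemenyiPairwise(mat),
       avgRanks = fr$avgRanks,
       cd = criticalDifference(ncol(as.matrix(mat)), nrow(as.matrix(mat)),
                               alpha),
       alpha = alpha)
}

#' Per-trial significance table against a focal classifier
#'
#' For each trial's block matrix, the row of Nemenyi p-values comparing the
#' focal classifier (PHCA by default) with every other roster member, with
#' a flag per pair: `p > alpha` means no significant difference under the
#' standard reading (small p rejects equality).
#'
#' @param blockMatrices list of block matrices (one per trial, 5 metrics x
#'   k classifiers), e.g. `runTrials(...)$blockMatrices`.
#' @param focal focal classifier column name (default "PHCA").
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with one row per trial: `trial`, one p-value column
#'   `<focal>-<other>` per comparison, and matching `sig.<other>` logical
#'   columns (TRUE = significantly different).
#' @export
significanceTable <- function(blockMatrices, focal = "PHCA", alpha = 0.05) {
  stopifnot(length(blockMatrices) >= 1L)
  others <- setdiff(colnames(as.matrix(blockMatrices[[1L]])), focal)
  if (!focal %in% colnames(as.matrix(blockMatrices[[1L]])))
    stop("focal classifier '", focal, "' not in the roster")
  rows <- lapply(seq_along(blockMatrices), function(t) {
    pm <- nemenyiPairwise(blockMatrices[[t]])
    out <- data.frame(trial = t)
    for (o in others) out[[paste0(focal, "-", o)]] <- pm[focal, o]
    for (o in others) out[[paste0("sig.", o)]] <- pm[focal, o] <= alpha
    out
  })
  do.call(rbind, rows)
}

#' Write per-trial Nemenyi tables and a comparison summary
#'
#' One `nemenyi_trial<t>.csv` per trial (the full pairwise p-value matrix)
#' plus `comparison_summary.json` holding the Friedman p-value per trial,
#' the critical difference, and the focal significance flags.
#'
#' @param blockMatrices list of per-trial block matrices.
#' @param dir output directory.
#' @param focal focal classifier (default "PHCA").
#' @param alpha significance threshold.
#' @return `dir`, invisibly.
#' @export
writeComparisonOutputs <- function(blockMatrices, dir, focal = "PHCA",
                                   alpha = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fried <- numeric(length(blockMatrices))
  for (t in seq_along(blockMatrices)) {
    nem <- nemenyiPairwise(blockMatrices[[t]])
    utils::write.csv(round(nem, 4),
                     file.path(dir, sprintf("nemenyi_trial%d.csv", t)),
                     quote = FALSE)
    fried[t] <- friedmanRankTest(blockMatrices[[t]])$pValue
  }
  sig <- significanceTable(blockMatrices, focal = focal, alpha = alpha)
  k <- ncol(as.matrix(blockMatrices[[1L]]))
  N <- nrow(as.matrix(blockMatrices[[1L]]))
  jsonlite::write_json(
    list(friedmanP = fried, alpha = alpha,
         criticalDifference = criticalDifference(k, N, alpha),
         significance = sig),
    file.path(dir, "comparison_summary.json"), auto_unbox = TRUE,
    digits = NA, dataframe = "rows")
  invisible(dir)
}
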