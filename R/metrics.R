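#' Matthews correlation coefficient from confusion counts
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the
#' convention that the value is 0 whenever any marginal of the confusion
#' matrix is zero (e.g. all samples predicted positive). Invariant under the
#' simultaneous swap tp<->tn, fp<->fn.
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return MCC in \[-1, 1\].
#' @examples
#' mccScore(50, 40, 10, 0)
#' @export
mccScore <- function(tp, tn, fp, fn) {
  if (min(tp, tn, fp, fn) < 0) stop("counts must be non-negative")
  if (tp + tn + fp + fn < 1) stop("at least one observation required")
  denom <- as.double(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (as.double(tp) * tn - as.double(fp) * fn) / sqrt(denom)
}

#' Area under the ROC curve (tie-aware Mann-Whitney form)
#'
#' `P(score+ > score-) + 0.5 P(score+ = score-)` over all positive-negative
#' sample pairs, computed from average ranks. Satisfies
#' `aucScore(s, y) == 1 - aucScore(s, 1 - y)`.
#'
#' @param scores numeric score per sample (higher = more positive).
#' @param y binary 0/1 decision vector; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
aucScore <- function(scores, y) {
  y <- stopIfNot01(as.integer(y))
  checkBothClasses(y, "AUC computation")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusionAt <- function(scores, y, cutoff) {
  pred <- as.integer(scores > cutoff)
  c(tp = sum(pred == 1L & y == 1L), tn = sum(pred == 0L & y == 0L),
    fp = sum(pred == 1L & y == 0L), fn = sum(pred == 0L & y == 1L))
}

#' Tune the vote cutoff to maximise MCC
#'
#' Evaluates MCC (predicting positive when score > cutoff) on the grid of
#' midpoints between consecutive distinct sorted scores, plus 0.5, and
#' returns the maximiser. Ties are broken toward the cutoff closest to 0.5
#' (then toward the smaller cutoff). With constant scores the grid is
#' \{0.5\} and the MCC of the induced majority assignment is returned.
#'
#' @param scores per-sample scores in \[0,1\] (e.g. OOB vote fractions).
#' @param y binary 0/1 decision vector.
#' @return A list with `cutoff` and `mcc`.
#' @export
tuneVoteCutoff <- function(scores, y) {
  y <- stopIfNot01(as.integer(y))
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0,1]")
  s <- sort(unique(scores))
  grid <- if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  grid <- sort(unique(c(grid, 0.5)))
  # cumulative-count evaluation of the confusion matrix along the grid
  n <- length(scores)
  pos <- sum(y == 1L); neg <- n - pos
  ordDesc <- order(scores, decreasing = TRUE)
  cumTP <- c(0, cumsum(y[ordDesc] == 1L))
  m <- n - findInterval(grid, sort(scores))  # predicted positives per cutoff
  tp <- cumTP[m + 1L]; fp <- m - tp; fn <- pos - tp; tn <- neg - fp
  denom <- as.double(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mccs <- ifelse(denom == 0, 0,
                 (as.double(tp) * tn - as.double(fp) * fn) / sqrt(denom))
  # tolerance so exactly-tied MCC values rounded differently still tie
  best <- which(mccs >= max(mccs) - 1e-9)
  if (length(best) > 1L) {
    d <- abs(grid[best] - 0.5)
    best <- best[d == min(d)]
    best <- best[1L]
  }
  list(cutoff = grid[best], mcc = mccs[best])
}
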