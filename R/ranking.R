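orderRanking <- function(df) {
  df <- df[order(df$p.value, -df$score, df$feature), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Rank features by the Mann-Whitney U test
#'
#' Computes a two-sided Mann-Whitney p-value per feature comparing the two
#' decision classes. The exact null distribution is used when the total
#' sample size is at most 20 and the feature has no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. Constant features get p = 1 by convention.
#'
#' @param X numeric matrix, samples in rows.
#' @param y binary 0/1 decision vector.
#' @return A `FeatureRanking`: data.frame (feature, p.value, score) sorted by
#'   ascending p-value, ties broken by descending score (|U - n1 n2 / 2|)
#'   then feature name, with attribute `method = "utest"`.
#' @export
uTestRank <- function(X, y) {
  X <- asFeatureMatrix(X)
  y <- stopIfNot01(as.integer(y))
  checkBothClasses(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L); n <- n1 + n0
  R <- apply(X, 2, rank)
  U <- colSums(R[y == 1L, , drop = FALSE]) - n1 * (n1 + 1) / 2
  dev <- abs(U - n1 * n0 / 2)
  # sum(t^3 - t) over tie groups recovered from the rank variance:
  # sum (r - (n+1)/2)^2 = (n^3 - n)/12 - tieSum/12 under average ranks
  tieSum <- pmax(0, (n^3 - n) - 12 * colSums((R - (n + 1) / 2)^2))
  sigma2 <- n1 * n0 / 12 * ((n + 1) - tieSum / (n * (n - 1)))
  z <- pmax(0, dev - 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- pmin(1, 2 * stats::pnorm(-z))
  p[sigma2 <= 1e-8] <- 1  # constant feature: no information
  if (n <= 20L) {
    exact <- tieSum < 1e-8 & sigma2 > 1e-8
    for (j in which(exact))
      p[j] <- min(1, 2 * min(pwilcox(U[j], n1, n0),
                             1 - pwilcox(U[j] - 1, n1, n0)))
  }
  dev[sigma2 <= 1e-8] <- 0
  out <- orderRanking(data.frame(feature = colnames(X), p.value = p,
                                 score = dev, stringsAsFactors = FALSE))
  attr(out, "method") <- "utest"
  out
}

entropyNats <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

# Conditional entropy H(Y | B) in nats for every column of a binned code
# matrix (codes 1..K), vectorised over features.
condEntropyCols <- function(B, y, K) {
  n <- nrow(B)
  h <- numeric(ncol(B))
  for (k in seq_len(K)) {
    ind <- B == k
    n1 <- colSums(ind & y == 1L)
    nk <- colSums(ind)
    n0 <- nk - n1
    term <- function(cnt, tot) ifelse(cnt > 0, cnt * log(cnt / tot), 0)
    h <- h + -(term(n1, nk) + term(n0, nk)) / n
  }
  h
}

# Random-threshold binning of all columns at once: thresholds drawn
# uniformly from the central `rangeParam` fraction of each feature's value
# range. Returns codes 1..nBins.
randomBinning <- function(X, nBins, rangeParam) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  pad <- (1 - rangeParam) / 2 * (hi - lo)
  B <- matrix(1L, nrow(X), ncol(X))
  for (s in seq_len(nBins - 1L)) {
    thr <- lo + pad + runif(ncol(X)) * pmax(hi - lo - 2 * pad, 0)
    B <- B + (X > rep(thr, each = nrow(X)))
  }
  # collapse code gaps so codes stay in 1..nBins
  B
}

#' Rank features by multidimensional information-gain filtering
#'
#' Scores each feature by the decrease in entropy of the decision variable
#' given discretized feature tuples. For `dimension = 1` the score is the
#' best information gain IG(f) = H(Y) - H(Y | disc(f)) over
#' `nDiscretizations` random binnings; for `dimension = 2` it is the best
#' conditional gain H(Y | disc(g)) - H(Y | disc(f), disc(g)) over partner
#' features g and binnings, which detects pairwise interactions (e.g. XOR)
#' invisible to univariate filters. P-values come from the asymptotic
#' chi-square distribution of the likelihood-ratio statistic 2 N IG (nats),
#' with df = nBins - 1 for D = 1 and (nBins - 1) * nBins for D = 2, Sidak
#' corrected for the maximisation over the random binnings so that p-values
#' stay near-uniform under independence (the residual maximisation over
#' partner features in D = 2 is not corrected; p-values are approximate and
#' honest only asymptotically). Features with at most `nBins` distinct
#' values are used as-is without random binning. Scores are reported in
#' bits.
#'
#' @param X numeric matrix, samples in rows.
#' @param y binary 0/1 decision vector.
#' @param dimension 1 or 2.
#' @param nBins number of bins per feature (default 2).
#' @param nDiscretizations number of random binnings per feature.
#' @param rangeParam central fraction of each feature's value range from
#'   which thresholds are drawn (1 = full range).
#' @param seed integer seed for the random binnings.
#' @return A `FeatureRanking` data.frame as in [uTestRank()], with attribute
#'   `method` = `"mdfs1d"` or `"mdfs2d"`.
#' @export
mdfsRank <- function(X, y, dimension = 1L, nBins = 2L, nDiscretizations = 30L,
                     rangeParam = 1, seed = 1L) {
  X <- asFeatureMatrix(X)
  y <- stopIfNot01(as.integer(y))
  checkBothClasses(y)
  if (!dimension %in% c(1L, 2L)) stop("dimension must be 1 or 2")
  if (dimension == 2L && ncol(X) < 2L)
    stop("dimension 2 requires at least 2 features")
  n <- nrow(X); p <- ncol(X)
  hy <- entropyNats(table(y))

  nDistinct <- apply(X, 2, function(v) length(unique(v)))
  fixed <- nDistinct <= nBins
  fixedCodes <- X
  for (j in which(fixed))
    fixedCodes[, j] <- as.integer(factor(X[, j]))

  withSeed(seed, {
    binnings <- lapply(seq_len(nDiscretizations), function(d) {
      B <- randomBinning(X, nBins, rangeParam)
      if (any(fixed)) B[, fixed] <- fixedCodes[, fixed]
      storage.mode(B) <- "integer"
      B
    })

    if (dimension == 1L) {
      igBest <- rep(-Inf, p)
      for (B in binnings)
        igBest <- pmax(igBest, hy - condEntropyCols(B, y, nBins))
      igBest <- pmax(igBest, 0)
      df <- nBins - 1L
    } else {
      igBest <- rep(-Inf, p)
      for (B in binnings) {
        hYgivenG <- condEntropyCols(B, y, nBins)
        for (g in seq_len(p)) {
          # H(Y | f, g) for all f at once: condition on the cells of g
          hfg <- numeric(p)
          for (b in seq_len(nBins)) {
            rows <- B[, g] == b
            if (!any(rows)) next
            hfg <- hfg + condEntropyCols(B[rows, , drop = FALSE],
                                         y[rows], nBins) * sum(rows) / n
          }
          ig <- hYgivenG[g] - hfg
          ig[g] <- -Inf
          igBest <- pmax(igBest, ig)
        }
      }
      igBest <- pmax(igBest, 0)
      df <- (nBins - 1L) * nBins
    }
    pv <- pchisq(2 * n * igBest, df = df, lower.tail = FALSE)
    # Sidak correction for taking the best of nDiscretizations random
    # binnings; features used as-is (<= nBins distinct values) need none.
    nEff <- ifelse(fixed, 1L, nDiscretizations)
    pv <- 1 - (1 - pv)^nEff
    out <- orderRanking(data.frame(feature = colnames(X), p.value = pv,
                                   score = igBest / log(2),
                                   stringsAsFactors = FALSE))
    attr(out, "method") <- if (dimension == 1L) "mdfs1d" else "mdfs2d"
    out
  })
}
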