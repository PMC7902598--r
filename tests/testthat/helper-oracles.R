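# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the code paths of the implementation.

# Two-sided Mann-Whitney p-value by exhaustive enumeration of all
# rank assignments of the pooled sample (tie-free inputs only).
oracleUTestExact <- function(x0, x1) {
  n0 <- length(x0); n1 <- length(x1); n <- n0 + n1
  pooled <- c(x0, x1)
  robs <- rank(pooled)
  uObs <- sum(robs[(n0 + 1):n]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  pLow <- mean(us <= uObs)
  pHigh <- mean(us >= uObs)
  min(1, 2 * min(pLow, pHigh))
}

# MCC via the phi coefficient: Pearson correlation of the binary
# predicted/true label vectors (0 when undefined).
oracleMCC <- function(pred, truth) {
  if (length(unique(pred)) < 2L || length(unique(truth)) < 2L) return(0)
  suppressWarnings(stats::cor(pred, truth))
}

# AUC by explicit enumeration of positive-negative pairs.
oracleAUC <- function(scores, y) {
  sp <- scores[y == 1]; sn <- scores[y == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Exhaustive cutoff search replicating the stated grid and tie rules.
oracleCutoff <- function(scores, y) {
  s <- sort(unique(scores))
  grid <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  grid <- sort(unique(c(grid, 0.5)))
  mccs <- sapply(grid, function(ct) oracleMCC(as.integer(scores > ct), y))
  # distinct confusion matrices differ in MCC by far more than 1e-9, so a
  # tolerance here recovers the mathematically exact tie set despite the
  # different floating-point route (cor vs closed form)
  best <- which(mccs >= max(mccs) - 1e-9)
  if (length(best) > 1) {
    d <- abs(grid[best] - 0.5)
    best <- best[d == min(d)][1]
  }
  list(cutoff = grid[best], mcc = mccs[best])
}

# Iterative binomial SGoF with a hand-summed binomial tail.
oracleSGoF <- function(p, gamma = 0.05, alpha = 0.05) {
  n <- length(p)
  f <- sum(p <= gamma)
  tail <- function(k) sum(sapply(k:n, function(i)
    choose(n, i) * gamma^i * (1 - gamma)^(n - i)))
  r <- 0L
  while (f > 0 && tail(f) <= alpha) {
    r <- r + 1L
    f <- f - 1L
  }
  r
}

# Direct application of the greedy redundancy rule with cor().
oracleGreedy <- function(feats, X, rhoMax, nKeepMax = Inf) {
  kept <- character(0)
  for (f in feats) {
    if (length(kept) >= nKeepMax) break
    ok <- TRUE
    for (g in kept) {
      rho <- suppressWarnings(
        stats::cor(X[, f], X[, g], method = "spearman"))
      if (is.na(rho)) rho <- 0
      if (abs(rho) >= rhoMax) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, f)
  }
  kept
}

# Plug-in conditional information gain (bits) from a contingency table of
# already-discrete feature codes.
oracleIGBits <- function(f, y) {
  h <- function(tab) {
    p <- tab[tab > 0] / sum(tab)
    -sum(p * log2(p))
  }
  hy <- h(table(y))
  hcond <- 0
  for (v in unique(f)) {
    idx <- f == v
    hcond <- hcond + mean(idx) * h(table(y[idx]))
  }
  hy - hcond
}

# Small cohort builders shared across tests -------------------------------

nullCohort <- function(n = 300, p = 200, seed = 1) {
  cfg <- cohortConfig(n, positiveFraction = 0.4,
    clinical = list(clinicalFeature("c1", effect = 0)),
    nClinicalNoise = 9,
    omics = list(omicsLayerSpec("mol", p, 0, 0, p, 0)),
    seed = seed)
  simulateCohort(cfg)$bundle
}
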