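test_that("sgofSelect matches the hand-summed binomial oracle", {
  expect_equal(sgofSelect(rep(0.9, 100)), 0L)
  p1 <- c(rep(0.001, 20), rep(0.5, 80))
  r1 <- sgofSelect(p1)
  expect_equal(r1, oracleSGoF(p1))
  expect_gt(r1, 0)
  p2 <- rep(0.04, 10)
  r2 <- sgofSelect(p2)
  expect_equal(r2, oracleSGoF(p2))
  expect_lte(r2, 10)
  expect_error(sgofSelect(numeric(0)), "empty")
  expect_error(sgofSelect(c(0.5, 1.2)), "0,1")
  # randomized instances against the oracle; R never exceeds #{p <= gamma}
  set.seed(19)
  for (i in 1:100) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    r <- sgofSelect(p)
    expect_equal(r, oracleSGoF(p))
    expect_lte(r, sum(p <= 0.05))
  }
})

test_that("sgofSelect keeps the null false-positive fraction modest", {
  set.seed(77)
  fracs <- replicate(50, sgofSelect(runif(300)) / 300)
  expect_lt(mean(fracs), 0.10)
})

test_that("greedy redundancy removal applies the blocking rule in ranking order", {
  # f2 blocked by f1 (rho ~ 0.97), f3 kept (low rho with f1)
  set.seed(2)
  n <- 60
  f1 <- rnorm(n)
  f2 <- f1 + rnorm(n, sd = 0.15)
  f3 <- 0.3 * scale(f2)[, 1] + rnorm(n)
  X <- cbind(f1 = f1, f2 = f2, f3 = f3)
  sp <- function(a, b) abs(cor(X[, a], X[, b], method = "spearman"))
  expect_gt(sp("f1", "f2"), 0.7); expect_lt(sp("f1", "f3"), 0.7)
  kept <- greedyRedundancyFilter(c("f1", "f2", "f3"), X, rhoMax = 0.7)
  expect_identical(kept, c("f1", "f3"))
  # a duplicated feature (rho = 1) is always removed at the 0.7 threshold
  X2 <- cbind(a = rnorm(30), b = rnorm(30))
  X2 <- cbind(X2, a_copy = X2[, "a"])
  expect_identical(greedyRedundancyFilter(c("a", "a_copy", "b"), X2, 0.7),
                   c("a", "b"))
  # mutually independent features all kept up to the cap
  set.seed(3)
  X3 <- matrix(rnorm(200 * 6), 200, 6,
               dimnames = list(NULL, paste0("g", 1:6)))
  expect_identical(greedyRedundancyFilter(paste0("g", 1:6), X3, 0.7, 4),
                   paste0("g", 1:4))
  expect_error(greedyRedundancyFilter("a", X2, rhoMax = 0), "positive")
})

test_that("greedy filter matches the direct-rule oracle on random instances", {
  set.seed(23)
  for (i in 1:30) {
    n <- 40; p <- sample(4:10, 1)
    base <- matrix(rnorm(n * p), n, p)
    # random mixing induces a spread of pairwise correlations
    mix <- matrix(rnorm(p * p, sd = 0.6), p, p); diag(mix) <- 1
    X <- base %*% mix
    colnames(X) <- paste0("v", seq_len(p))
    ord <- sample(colnames(X))
    rho <- runif(1, 0.3, 0.95)
    cap <- sample(2:p, 1)
    expect_identical(greedyRedundancyFilter(ord, X, rho, cap),
                     oracleGreedy(ord, X, rho, cap))
  }
})

test_that("greedy output ignores shuffles below the last kept feature", {
  set.seed(31)
  X <- matrix(rnorm(80 * 8), 80, 8, dimnames = list(NULL, paste0("v", 1:8)))
  kept <- greedyRedundancyFilter(paste0("v", 1:8), X, 0.7, 3)
  tailFeats <- setdiff(paste0("v", 1:8), kept)
  ord2 <- c(kept, sample(tailFeats))
  expect_identical(greedyRedundancyFilter(ord2, X, 0.7, 3), kept)
})

test_that("selectFeatures composes rank -> SGoF -> redundancy -> cap and records counts", {
  # correlated triples: roughly one representative kept per cluster
  cfg <- cohortConfig(400, positiveFraction = 0.5,
    clinical = list(clinicalFeature("c", effect = 0)),
    omics = list(omicsLayerSpec("mol", 60, 30, 0.8, 20, 0.9)),
    seed = 5)
  sim <- simulateCohort(cfg)
  X <- omicsLayer(sim$bundle, "mol")
  y <- decision(sim$bundle)
  sel <- selectFeatures(X, y, selectionConfig("utest", mCap = 50))
  expect_s4_class(sel, "SelectedFeatureSet")
  expect_false(sel@empty)
  expect_lte(sel@nFinal, min(sel@nAfterRedundancy, sel@nSignificant))
  # brute-force composition oracle
  rk <- uTestRank(X, y)
  nSig <- oracleSGoF(rk$p.value)
  keptOracle <- oracleGreedy(rk$feature[seq_len(nSig)], X, 0.7, 50)
  expect_identical(sel@features, head(keptOracle, 50))
  # informative features live in the first 10 clusters (3 features each);
  # redundancy removal should leave about one representative per cluster
  clusters <- sim$truth@omics$mol$cluster[match(sel@features,
                                                sim$truth@omics$mol$feature)]
  expect_gte(length(unique(clusters)), 8)
  expect_lte(max(table(clusters)), 2)
  # kept set is pairwise below the Spearman threshold
  rhos <- cor(X[, sel@features], method = "spearman")
  expect_lt(max(abs(rhos[upper.tri(rhos)])), 0.7)
})

test_that("selectFeatures caps at mCap with the top-ranked survivors", {
  set.seed(41)
  y <- rep(0:1, each = 150)
  X <- sapply(seq_len(40), function(j) y * runif(1, 0.8, 1.6) + rnorm(300))
  colnames(X) <- sprintf("f%02d", seq_len(40))
  sel <- selectFeatures(X, y, selectionConfig("utest", mCap = 10))
  expect_equal(sel@nFinal, 10L)
  rk <- uTestRank(X, y)
  nSig <- sgofSelect(rk$p.value)
  kept <- greedyRedundancyFilter(rk$feature[seq_len(nSig)], X, 0.7, Inf)
  expect_identical(sel@features, head(kept, 10))
})

test_that("selectFeatures returns an empty flagged set on a null cohort", {
  b <- nullCohort(n = 200, p = 300, seed = 9)
  expect_warning(
    sel <- selectFeatures(omicsLayer(b, "mol"), decision(b),
                          selectionConfig("utest")),
    "empty")
  expect_true(sel@empty)
  expect_equal(sel@nFinal, 0L)
})

test_that("shadow selection confirms a leaked copy of y and rejects pure noise", {
  set.seed(55)
  n <- 250
  y <- rbinom(n, 1, 0.5); y[1:2] <- 0:1
  X <- cbind(leak = y + rnorm(n, sd = 0.05),
             matrix(rnorm(n * 15), n, 15,
                    dimnames = list(NULL, paste0("noise", 1:15))))
  for (s in 1:3) {
    res <- shadowSelectClinical(X, y, nIterations = 15, alpha = 0.01,
                                nTrees = 100, seed = s)
    expect_identical(res$confirmed, "leak")
  }
})

test_that("shadow selection separates strong from noise clinical features", {
  cfg <- cohortConfig(300, positiveFraction = 0.4,
    clinical = list(clinicalFeature("a", effect = 1.2),
                    clinicalFeature("b", "ordinal", 1.0, 4),
                    clinicalFeature("c", effect = 0.9)),
    nClinicalNoise = 5, seed = 3)
  b <- simulateCohort(cfg)$bundle
  res <- shadowSelectClinical(clinical(b), decision(b), nIterations = 25,
                              alpha = 0.05, nTrees = 150, seed = 8)
  expect_true(all(c("a", "b", "c") %in% res$confirmed))
  expect_false(any(grepl("^noise", res$confirmed)))
  expect_error(shadowSelectClinical(clinical(b), decision(b),
                                    nIterations = 3), ">= 5")
})
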