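mkBundle <- function(n = 120, seed = 5, omicsEffect = 0.8, nInf = 10) {
  cfg <- cohortConfig(n, positiveFraction = 0.4,
    clinical = list(clinicalFeature("a", effect = 1.2),
                    clinicalFeature("b", "ordinal", 0.7, 4)),
    nClinicalNoise = 3,
    omics = list(omicsLayerSpec("mol", 60, nInf, omicsEffect, 20, 0.4)),
    seed = seed)
  simulateCohort(cfg)$bundle
}

test_that("earlyMerge concatenates columns with ID alignment and collision suffixes", {
  clin <- matrix(1:6, 3, 2, dimnames = list(c("s1", "s2", "s3"), c("a", "b")))
  mol <- matrix(7:12, 3, 2, dimnames = list(c("s3", "s1", "s2"), c("g1", "a")))
  m <- earlyMerge(clin, mol)
  expect_equal(ncol(m), 4)
  expect_identical(colnames(m), c("a", "b", "g1", "a_mol"))
  # realignment: row s3 of mol must land in row s3 of the merge
  expect_equal(m["s3", "g1"], mol["s3", "g1"])
  expect_equal(m["s1", "a_mol"], mol["s1", "a"])
  # empty molecular table: identity
  expect_identical(earlyMerge(clin, clin[, 0]), clin)
  bad <- matrix(1:4, 2, 2, dimnames = list(c("s1", "zz"), c("x", "y")))
  expect_error(earlyMerge(clin, bad), "mismatch")
})

test_that("hybridFit builds one synthetic variable per usable layer", {
  b <- mkBundle()
  hm <- hybridFit(b, selection = selectionConfig("utest"), nTrees = 80,
                  seed = 3)
  expect_s4_class(hm, "HybridModel")
  expect_identical(syntheticNames(hm), "synthetic_mol")
  expect_identical(hm@finalModel@features,
                   c(colnames(clinical(b)), "synthetic_mol"))
  v <- hm@layers$mol$forest@oobVotes
  expect_true(all(v >= 0 & v <= 1))
  p <- hybridPredict(hm, b)
  expect_length(p, nSamples(b))
  expect_true(all(p >= 0 & p <= 1))
  # permutation equivariance of prediction
  idx <- sample(nSamples(b))
  expect_equal(hybridPredict(hm, b[idx]), p[idx], tolerance = 1e-12)
})

test_that("hybrid with no molecular layer reduces exactly to the clinical model", {
  b <- mkBundle()
  hm <- hybridFit(b, layers = character(0), nTrees = 80, seed = 3)
  expect_length(syntheticNames(hm), 0)
  direct <- trainForest(clinical(b), decision(b), nTrees = 80,
                        seed = hybridRF:::deriveSeed(3, 0L, 3L))
  expect_identical(oobVotes(hm@finalModel), oobVotes(direct))
  expect_identical(hybridPredict(hm, b), unname(predict(direct, clinical(b))))
})

test_that("an all-noise layer is skipped with a warning and does not change the model", {
  b <- nullCohort(n = 150, p = 100, seed = 31)
  w <- capture_warnings(hm <- hybridFit(b, selection = selectionConfig("utest"),
                                        nTrees = 60, seed = 2))
  expect_true(any(grepl("skipped", w)))
  expect_identical(hm@skipped, "mol")
  expect_length(syntheticNames(hm), 0)
})

test_that("NNLS combiner recovers exact and degenerate weight structure", {
  set.seed(9)
  y <- rbinom(100, 1, 0.5); y[1:2] <- 0:1
  meta <- cbind(good = y, bad = 1 - y)
  cb <- fitCombiner(meta, y, "nnls")
  expect_equal(unname(cb$weights), c(1, 0), tolerance = 1e-8)
  expect_equal(predictCombiner(cb, meta), as.numeric(y), tolerance = 1e-8)
  # duplicated base model: weights may split but prediction is invariant
  meta2 <- cbind(a = y * 0.8 + 0.1, a2 = y * 0.8 + 0.1, n = runif(100))
  cb2 <- fitCombiner(meta2, y, "nnls")
  expect_true(all(cb2$weights >= 0))
  single <- fitCombiner(meta2[, c(1, 3)], y, "nnls")
  expect_equal(predictCombiner(cb2, meta2),
               predictCombiner(single, meta2[, c(1, 3)]), tolerance = 1e-6)
  # noise base model gets (near) zero weight
  expect_lt(cb2$weights[["n"]], 0.05)
})

test_that("best-k combiner picks the top-AUC columns and reduces to the mean", {
  set.seed(10)
  y <- rbinom(120, 1, 0.5); y[1:2] <- 0:1
  meta <- cbind(m1 = runif(120), m2 = y * 0.6 + runif(120) * 0.4,
                m3 = runif(120))
  cb <- fitCombiner(meta, y, "best_k", k = 1)
  aucs <- apply(meta, 2, aucScore, y = y)
  expect_identical(cb$cols, names(which.max(aucs)))
  cbAll <- fitCombiner(meta, y, "best_k", k = 3)
  expect_equal(predictCombiner(cbAll, meta), rowMeans(meta), tolerance = 1e-12)
  expect_error(fitCombiner(meta, y, "best_k", k = 4), "exceeds")
})

test_that("super learner with one base model reproduces the base model", {
  b <- mkBundle(n = 150)
  base <- clinicalStrategy(nTrees = 80, name = "cd")
  slm <- superLearnerFit(b, list(base), loops = 2, innerK = 5,
                         combiner = "nnls", seed = 6)
  expect_equal(unname(slm@combiners[[1]]$weights), 1)
  pSL <- superLearnerPredict(slm, b)
  pBase <- base$predict(slm@baseModels[[1]], b)
  expect_equal(pSL, unname(pBase), tolerance = 1e-10)
})

test_that("super learner down-weights a pure-noise base model", {
  b <- mkBundle(n = 150)
  noiseBase <- structure(list(
    name = "noise",
    fit = function(bundle, seed) seed,
    predict = function(model, bundle)
      withSeed(model, runif(nSamples(bundle))),
    cutoff = function(model) 0.5), class = "cvStrategy")
  slm <- superLearnerFit(
    b, list(clinicalStrategy(nTrees = 80, name = "cd"), noiseBase),
    loops = 3, innerK = 5, combiner = "nnls", seed = 8)
  w <- sapply(slm@combiners, function(cb) cb$weights[["noise"]])
  expect_lt(mean(w), 0.15)
  # median aggregation is also available
  pm <- superLearnerPredict(slm, b, aggregate = "median")
  expect_true(all(pm >= 0 & pm <= 1))
})

test_that("bootstrap bias correction brackets simple oracle cases", {
  set.seed(14)
  y <- rbinom(200, 1, 0.4); y[1:2] <- 0:1
  # constant meta-feature: combiner output constant, AUC exactly 0.5
  metaC <- cbind(c1 = rep(0.5, 200))
  expect_equal(bbcEstimate(metaC, y, B = 10)$auc, 0.5)
  # oracle meta-feature: near-perfect corrected AUC
  metaY <- cbind(o = y, n = runif(200))
  expect_gt(bbcEstimate(metaY, y, B = 20)$auc, 0.99)
  expect_error(bbcEstimate(metaY, y, B = 5), ">= 10")
})

test_that("BBC estimate agrees with external cross-validation of the combiner", {
  # simulated meta-features with realistic signal
  diffs <- sapply(1:12, function(s) {
    set.seed(s + 100)
    n <- 240
    y <- rbinom(n, 1, 0.45); y[1:2] <- 0:1
    meta <- cbind(a = pmin(1, pmax(0, 0.4 * y + runif(n) * 0.6)),
                  b = pmin(1, pmax(0, 0.25 * y + runif(n) * 0.75)),
                  c = runif(n))
    bbc <- bbcEstimate(meta, y, B = 30, seed = s)$auc
    folds <- cvFolds(y, 5, seed = s)
    aucs <- sapply(folds, function(te) {
      cb <- fitCombiner(meta[-te, , drop = FALSE], y[-te], "nnls")
      aucScore(predictCombiner(cb, meta[te, , drop = FALSE]), y[te])
    })
    bbc - mean(aucs)
  })
  expect_lt(abs(mean(diffs)), 0.02)
})
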