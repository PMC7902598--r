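test_that("cohort generation is exactly reproducible under a fixed seed", {
  cfg <- cohortConfig(150, positiveFraction = 0.35,
    clinical = list(clinicalFeature("a", effect = 1),
                    clinicalFeature("o", "ordinal", 0.5, 4),
                    clinicalFeature("k", "categorical", 0.5, 3)),
    nClinicalNoise = 2,
    redundantPairs = list(list(source = "a", correlation = 0.8)),
    omics = list(omicsLayerSpec("mol", 50, 5, 0.5, 10, 0.4,
                                missingRate = 0.05)))
  s1 <- simulateCohort(cfg, seed = 42)
  s2 <- simulateCohort(cfg, seed = 42)
  expect_identical(s1$bundle, s2$bundle)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateCohort(cfg, seed = 43)
  expect_false(identical(s1$bundle, s3$bundle))
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(0), "positive count")
  expect_error(cohortConfig(10, positiveFraction = 1), "strictly in")
  expect_error(omicsLayerSpec("m", 10, nClusters = 11), "cluster count")
  expect_error(omicsLayerSpec("m", 10, nInformative = 11), "nInformative")
  expect_error(omicsLayerSpec("m", 10, withinCor = 1.2), "withinCor")
  expect_error(clinicalFeature("a", effect = Inf), "finite")
})

test_that("class fraction, missingness and structure match the configuration", {
  cfg <- cohortConfig(1200, positiveFraction = 0.4,
    clinical = list(clinicalFeature("a", effect = 1)),
    omics = list(omicsLayerSpec("mol", 80, 10, 0.4, 20, 0.5,
                                missingRate = 0.03)),
    seed = 2)
  sim <- simulateCohort(cfg)
  y <- decision(sim$bundle)
  se <- sqrt(0.4 * 0.6 / 1200)
  expect_lt(abs(mean(y) - 0.4), 3 * se)
  X <- omicsLayer(sim$bundle, "mol")
  expect_lt(abs(mean(is.na(X)) - 0.03), 0.01)
  expect_equal(dim(X), c(1200, 80))
  expect_equal(sum(sim$truth@omics$mol$relevant), 10)
})

test_that("within-cluster correlation is close to the configured value", {
  cfg <- cohortConfig(1500, positiveFraction = 0.5,
    clinical = list(clinicalFeature("a", effect = 0)),
    omics = list(omicsLayerSpec("mol", 40, 0, 0, 8, 0.5)), seed = 7)
  sim <- simulateCohort(cfg)
  X <- omicsLayer(sim$bundle, "mol")
  cl <- sim$truth@omics$mol$cluster
  rhos <- c()
  for (g in unique(cl)) {
    idx <- which(cl == g)
    cm <- cor(X[, idx])
    rhos <- c(rhos, cm[upper.tri(cm)])
  }
  expect_lt(abs(mean(rhos) - 0.5), 0.05)
  # features in different clusters are uncorrelated
  expect_lt(abs(mean(cor(X[, cl == 1], X[, cl == 2]))), 0.05)
})

test_that("irrelevant features show no class separation", {
  cfg <- cohortConfig(1000, positiveFraction = 0.4,
    clinical = list(clinicalFeature("a", effect = 1)),
    nClinicalNoise = 5,
    omics = list(omicsLayerSpec("mol", 30, 5, 0.8, 10, 0.6)), seed = 11)
  sim <- simulateCohort(cfg)
  X <- omicsLayer(sim$bundle, "mol")
  y <- decision(sim$bundle)
  tr <- sim$truth@omics$mol
  for (f in tr$feature[!tr$relevant]) {
    d <- mean(X[y == 1, f]) - mean(X[y == 0, f])
    se <- sqrt(var(X[y == 1, f]) / sum(y) + var(X[y == 0, f]) / sum(1 - y))
    expect_lt(abs(d) / se, 3.5)
  }
})

test_that("a strong single clinical feature separates classes as the closed form predicts", {
  # AUC for a Gaussian shift delta is Phi(delta / sqrt(2)); delta = 3 gives 0.983
  cfg <- cohortConfig(2000, positiveFraction = 0.5,
    clinical = list(clinicalFeature("s", effect = 3)), seed = 5)
  sim <- simulateCohort(cfg)
  auc <- aucScore(clinical(sim$bundle)[, "s"], decision(sim$bundle))
  expect_gt(auc, 0.95)
  expect_lt(abs(auc - pnorm(3 / sqrt(2))), 0.02)
})

test_that("redundant pairs hit the target Spearman correlation", {
  cfg <- cohortConfig(1500, positiveFraction = 0.4,
    clinical = list(clinicalFeature("er_status", effect = 1.2)),
    redundantPairs = list(list(source = "er_status", correlation = 0.82,
                               name = "er_ihc")),
    seed = 13)
  b <- simulateCohort(cfg)$bundle
  rho <- cor(clinical(b)[, "er_status"], clinical(b)[, "er_ihc"],
             method = "spearman")
  expect_lt(abs(rho - 0.82), 0.05)
})

test_that("null cohorts give uniform U-test p-values", {
  b <- nullCohort(n = 500, p = 150, seed = 17)
  p <- uTestRank(omicsLayer(b, "mol"), decision(b))$p.value
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ordinal and categorical clinical features come out as integer codes", {
  cfg <- cohortConfig(300, clinical = list(
    clinicalFeature("o", "ordinal", 0.8, 4),
    clinicalFeature("k", "categorical", 0.8, 5)), seed = 3)
  b <- simulateCohort(cfg)$bundle
  o <- clinical(b)[, "o"]; k <- clinical(b)[, "k"]
  expect_true(all(o == round(o)) && all(o %in% 1:4))
  expect_true(all(k == round(k)) && all(k %in% 1:5))
  # ordinal codes are monotone in risk; categorical codes need not be
  expect_gt(cor(o, decision(b)), 0.2)
})
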