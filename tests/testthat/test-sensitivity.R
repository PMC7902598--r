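# Cohorts here keep the signal entirely in the clinical block so the
# combined model is cheap to refit many times.

test_that("single-feature removal flags the only signal carrier and spares noise", {
  cfg <- cohortConfig(250, positiveFraction = 0.4,
    clinical = list(clinicalFeature("signal", effect = 2)),
    nClinicalNoise = 4, seed = 6)
  b <- simulateCohort(cfg)$bundle
  rep_ <- looSensitivity(b, layers = character(0), r = 4, k = 5,
                         nTrees = 80, seed = 2)
  tab <- rep_$table
  expect_identical(tab$feature[1], "signal")
  # removing the only carrier costs roughly all the skill of the model
  dSignal <- tab$deltaAUC[tab$feature == "signal"]
  expect_gt(dSignal, 0.8 * (rep_$fullMean - 0.5))
  # pure-noise columns sit within two standard deviations of zero
  noise <- tab[tab$feature != "signal", ]
  expect_true(all(abs(noise$deltaAUC) <= 2 * noise$sd))
  # sanity envelope: no removal changes AUC by more than the model's skill
  expect_true(all(noise$deltaAUC <= rep_$fullMean - 0.5 + 3 * noise$sd))
})

test_that("perfectly redundant features mask each other in removal analysis", {
  cfg <- cohortConfig(250, positiveFraction = 0.4,
    clinical = list(clinicalFeature("sig", effect = 1.8)),
    nClinicalNoise = 2,
    redundantPairs = list(list(source = "sig", correlation = 0.995,
                               name = "sig_twin")),
    seed = 8)
  b <- simulateCohort(cfg)$bundle
  rep_ <- looSensitivity(b, layers = character(0), r = 4, k = 5,
                         nTrees = 80, seed = 3)
  tab <- rep_$table
  for (f in c("sig", "sig_twin")) {
    row <- tab[tab$feature == f, ]
    expect_lt(abs(row$deltaAUC), 2 * row$sd + 0.02)
  }
})

test_that("RFE eliminates one redundant copy before performance drops", {
  cfg <- cohortConfig(250, positiveFraction = 0.4,
    clinical = list(clinicalFeature("sig", effect = 1.8)),
    nClinicalNoise = 2,
    redundantPairs = list(list(source = "sig", correlation = 0.995,
                               name = "sig_twin")),
    seed = 8)
  b <- simulateCohort(cfg)$bundle
  tr <- rfe(b, layers = character(0), r = 3, k = 5, nTrees = 80, seed = 4)
  trace <- tr$trace
  # trace covers every size down to 1
  expect_identical(trace$size, seq(nrow(trace), 1))
  remSig <- which(trace$removed %in% c("sig", "sig_twin"))
  # the two copies are not eliminated back to back at full strength:
  # exactly one leaves while the model is still within one sd of full
  firstOut <- trace$removed[trace$size > tr$recommendedSize]
  expect_equal(sum(c("sig", "sig_twin") %in% firstOut), 1)
  expect_true(any(c("sig", "sig_twin") %in% tr$recommendedFeatures))
})

test_that("RFE trace on two features has length two", {
  cfg <- cohortConfig(150, positiveFraction = 0.4,
    clinical = list(clinicalFeature("a", effect = 1.5),
                    clinicalFeature("b", effect = 0)), seed = 9)
  b <- simulateCohort(cfg)$bundle
  tr <- rfe(b, layers = character(0), r = 3, k = 5, nTrees = 60, seed = 1)
  expect_equal(nrow(tr$trace), 2)
  expect_identical(tr$trace$size, c(2L, 1L))
  expect_true(is.na(tr$trace$removed[2]))
})

test_that("RFE removes noise before signal and recommends a compact informative model", {
  cfg <- cohortConfig(220, positiveFraction = 0.4,
    clinical = list(clinicalFeature("s1", effect = 1.4),
                    clinicalFeature("s2", effect = 1.1),
                    clinicalFeature("s3", "ordinal", 0.9, 4)),
    nClinicalNoise = 7, seed = 12)
  b <- simulateCohort(cfg)$bundle
  tr <- rfe(b, layers = character(0), r = 3, k = 5, nTrees = 60, seed = 2)
  sig <- c("s1", "s2", "s3")
  elimOrder <- tr$trace$removed[!is.na(tr$trace$removed)]
  lastNoise <- max(which(grepl("^noise", elimOrder)))
  firstSig <- which(elimOrder %in% sig)
  if (length(firstSig)) expect_gt(min(firstSig), lastNoise - 1)
  expect_true(all(tr$recommendedFeatures %in% sig))
  # cheap mode agrees on the trace structure and runs the same sizes
  trc <- rfe(b, layers = character(0), r = 2, k = 5, nTrees = 60, seed = 2,
             recompute = FALSE)
  expect_identical(trc$trace$size, tr$trace$size)
})

test_that("synthetic layer variables take part in removal analysis", {
  cfg <- cohortConfig(220, positiveFraction = 0.4,
    clinical = list(clinicalFeature("weak", effect = 0.4)),
    nClinicalNoise = 1,
    omics = list(omicsLayerSpec("mol", 60, 25, 0.7, 30, 0.3)), seed = 15)
  b <- simulateCohort(cfg)$bundle
  rep_ <- looSensitivity(b, selection = selectionConfig("utest"),
                         r = 3, k = 5, nTrees = 80, seed = 5)
  expect_true("synthetic_mol" %in% rep_$table$feature)
  # the molecular layer carries most of the signal here
  expect_identical(rep_$table$feature[1], "synthetic_mol")
})
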