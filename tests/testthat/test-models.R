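## small clean dataset reused within this file
cleanParams <- fragmentationParams("methodA", noiseSigma = 0, dropout = 0,
                                   decoyRate = 0)

test_that("training sets pair every cleavage site with its four ion targets", {
  peps <- genPeptides(10, sharedReg, lengthRange = c(8L, 8L), ptmRate = 0,
                      seed = 5L)
  psms <- lapply(seq_along(peps), function(i)
    simulatePsm(peps[[i]], 2L, cleanParams, sharedReg, seed = i))
  sets <- buildTrainingSet(psms, "methodA", sharedReg)
  expect_named(sets, "2")
  ts <- sets[["2"]]
  expect_equal(nrow(ts@features), 10L * 7L)
  expect_equal(fragMethod(ts), "methodA")
  expect_equal(precursorCharge(ts), 2L)

  ## targets equal the annotation output entry-wise, with site i paired to
  ## b_i and y_(L-i)
  tv <- annotateSpectrum(psms[[1]]$peptide, psms[[1]]$spectrum, sharedReg)
  t <- intensityTargets(tv)
  L1 <- nrow(t)
  block <- ts@targets[1:L1, ]
  expect_equal(block[, "b"], t[, "b"], ignore_attr = TRUE)
  expect_equal(block[, "b2"], t[, "b2"], ignore_attr = TRUE)
  expect_equal(block[, "y"], t[L1:1, "y"], ignore_attr = TRUE)
  expect_equal(block[, "y2"], t[L1:1, "y2"], ignore_attr = TRUE)

  ## identical PSMs contribute identical examples
  sets2 <- buildTrainingSet(c(psms[1], psms[1]), "methodA", sharedReg)
  expect_equal(sets2[["2"]]@features[1:L1, ],
               sets2[["2"]]@features[L1 + 1:L1, ])
  expect_error(buildTrainingSet(list(), "methodA", sharedReg), "empty")
})

test_that("PSMs are partitioned by precursor charge", {
  peps <- genPeptides(6, sharedReg, lengthRange = c(9L, 9L), ptmRate = 0,
                      seed = 6L)
  psms <- lapply(seq_along(peps), function(i)
    simulatePsm(peps[[i]], if (i %% 2) 2L else 3L, cleanParams, sharedReg,
                seed = i))
  sets <- buildTrainingSet(psms, "methodA", sharedReg)
  expect_named(sets, c("2", "3"))
  expect_equal(nrow(sets[["2"]]@features), 3L * 8L)
  expect_equal(precursorCharge(sets[["3"]]), 3L)
})

test_that("training is reproducible given the seed", {
  psms <- simulateDataset(40, 2L, cleanParams, sharedReg, seed = 17L,
                          lengthRange = c(8L, 10L))
  ts <- buildTrainingSet(psms, "methodA", sharedReg)[["2"]]
  m1 <- trainModel(ts, numTrees = 15L, seed = 4L)
  m2 <- trainModel(ts, numTrees = 15L, seed = 4L)
  probe <- parsePeptide("H-ELVISLIVESK-OH", sharedReg)
  p1 <- predictSpectrum(m1, probe, sharedReg, 2L)
  p2 <- predictSpectrum(m2, probe, sharedReg, 2L)
  expect_identical(p1$intensity, p2$intensity)
  ## and prediction itself is deterministic
  expect_identical(p1$intensity,
                   predictSpectrum(m1, probe, sharedReg, 2L)$intensity)
})

test_that("predictions cover the full theoretical ion set at any length", {
  for (txt in c("H-PEPTIDEPEPTIDEPEPTIDEPEPTIDEKGR-OH",  # 31-mer
                "H-GAVLK-OH")) {                        # 5-mer
    p <- parsePeptide(txt, sharedReg)
    ions <- predictSpectrum(sharedModel, p, sharedReg, 2L)
    expect_equal(nrow(ions), 4L * (peptideLength(p) - 1L))
    expect_true(all(ions$intensity >= 0))
    theo <- theoreticalSpectrum(p, sharedReg)
    expect_equal(ions$mz, theo$mz)
    expect_equal(ions[, c("series", "ionCharge", "index")],
                 theo[, c("series", "ionCharge", "index")])
  }
  expect_error(predictSpectrum(sharedModel, parsePeptide("H-GAVLK-OH",
                                                         sharedReg),
                               sharedReg, 3L), "charge")
})

test_that("model bundles survive a save/load round trip and refuse bad schemas", {
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(sharedModel, path)
  m <- loadModel(path)
  probe <- parsePeptide("H-SAoxMPLEK-OH", sharedReg)
  expect_identical(predictSpectrum(m, probe, sharedReg, 2L)$intensity,
                   predictSpectrum(sharedModel, probe, sharedReg,
                                   2L)$intensity)
  expect_equal(fragMethod(m), "methodA")
  cfg <- trainingConfig(m)
  expect_equal(cfg$seed, 1L)
  expect_equal(cfg$num.trees, 30L)

  ## tampered schema version is refused with an explicit message
  x <- readRDS(path)
  x$schema_version <- "v0"
  saveRDS(x, path)
  expect_error(loadModel(path), "schema version 'v0'")

  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(hello = 1), bad)
  expect_error(loadModel(bad), "corrupt")
})

test_that("redundancy filter keeps the highest-TIC PSM per precursor", {
  p <- parsePeptide("H-PEPTIDEK-OH", sharedReg)
  mk <- function(scale) {
    ions <- theoreticalSpectrum(p, sharedReg)
    list(peptide = p,
         spectrum = ObservedSpectrum("x", 2L, 450,
                                     cbind(ions$mz, scale * seq_len(28))))
  }
  kept <- dedupePsms(list(mk(1), mk(5), mk(2)))
  expect_length(kept, 1L)
  expect_equal(max(peakMatrix(kept[[1]]$spectrum)[, 2]), 5 * 28)
})

test_that("more training data does not hurt held-out accuracy", {
  big <- simulateDataset(200, 2L, cleanParams, sharedReg, seed = 71L,
                         lengthRange = c(9L, 12L))
  ev <- simulateDataset(60, 2L, cleanParams, sharedReg, seed = 72L,
                        lengthRange = c(9L, 12L))
  mSmall <- trainModel(buildTrainingSet(big[1:100], "methodA",
                                        sharedReg)[["2"]],
                       numTrees = 30L, seed = 1L)
  mBig <- trainModel(buildTrainingSet(big, "methodA", sharedReg)[["2"]],
                     numTrees = 30L, seed = 1L)
  medSmall <- median(evaluateModel(mSmall, ev, sharedReg)$r, na.rm = TRUE)
  medBig <- median(evaluateModel(mBig, ev, sharedReg)$r, na.rm = TRUE)
  expect_gte(medBig, medSmall - 0.02)
})
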