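## helper: a predictions list with deterministic fake intensities
fakePredictions <- function(texts, charge = 2L) {
  lapply(texts, function(txt) {
    p <- parsePeptide(txt, sharedReg)
    ions <- theoreticalSpectrum(p, sharedReg)
    ions$intensity <- seq_len(nrow(ions)) / nrow(ions)
    list(peptide = p, charge = charge, ions = ions)
  })
}

test_that("MGF write -> read round-trips spectra and honours the header contract", {
  preds <- fakePredictions(c("H-SAMPLE-OH", "H-SAoxMPLE-OH", "ace-PEPTIDEK-OH"))
  path <- withr::local_tempfile(fileext = ".mgf")
  writeMGF(preds, path, sharedReg)
  txt <- readLines(path)
  expect_true("TITLE=H-SAMPLE-OH" %in% txt)
  expect_true("TITLE=H-SAoxMPLE-OH" %in% txt)
  expect_true(any(grepl("^CHARGE=2\\+$", txt)))

  spectra <- readMGF(path)
  expect_length(spectra, 3L)
  for (i in seq_along(preds)) {
    s <- spectra[[i]]
    expect_equal(spectrumTitle(s), renderPeptide(preds[[i]]$peptide))
    expect_equal(precursorCharge(s), 2L)
    ions <- preds[[i]]$ions[order(preds[[i]]$ions$mz), ]
    expect_equal(peakMatrix(s)[, "mz"], ions$mz, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(peakMatrix(s)[, "intensity"], ions$intensity,
                 tolerance = 1e-7, ignore_attr = TRUE)
    z <- 2L
    expect_equal(s@pepmass,
                 (peptideMass(preds[[i]]$peptide, sharedReg) +
                    z * massConstants()$proton) / z,
                 tolerance = 1e-6)
  }
})

test_that("zero-intensity pruning and empty blocks are handled", {
  preds <- fakePredictions("H-SAMPLE-OH")
  preds[[1]]$ions$intensity[1:5] <- 0
  path <- withr::local_tempfile(fileext = ".mgf")
  writeMGF(preds, path, sharedReg, keepZeros = FALSE)
  expect_equal(nrow(peakMatrix(readMGF(path)[[1]])), 15L)
  writeMGF(preds, path, sharedReg, keepZeros = TRUE)
  expect_equal(nrow(peakMatrix(readMGF(path)[[1]])), 20L)

  ## block with an empty peak list parses to a zero-peak spectrum
  path2 <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=empty", "PEPMASS=500.0", "CHARGE=2+",
               "END IONS"), path2)
  s <- readMGF(path2)
  expect_length(s, 1L)
  expect_equal(nrow(peakMatrix(s[[1]])), 0L)
})

test_that("malformed MGF input errors name the line; odd charges are skipped", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "CHARGE=oops+", "END IONS"), path)
  expect_error(readMGF(path), "line 3")

  writeLines(c("BEGIN IONS", "TITLE=x", "CHARGE=2+", "100.0 banana 1",
               "END IONS"), path)
  expect_error(readMGF(path), "line 4")

  writeLines(c("BEGIN IONS", "TITLE=x", "CHARGE=2+", "100.0 5.0"), path)
  expect_error(readMGF(path), "END IONS")

  writeLines(c("BEGIN IONS", "TITLE=a", "CHARGE=4+", "100.0 5.0", "END IONS",
               "", "BEGIN IONS", "TITLE=b", "CHARGE=2+", "100.0 5.0",
               "END IONS"), path)
  expect_warning(s <- readMGF(path), "skipped 1")
  expect_length(s, 1L)
  expect_equal(spectrumTitle(s[[1]]), "b")
})

test_that("annotation matches peaks within tolerance and normalizes them", {
  p <- parsePeptide("H-SAMPLE-OH", sharedReg)
  ions <- theoreticalSpectrum(p, sharedReg)

  ## all 20 theoretical peaks present at equal intensity: every target equal
  s <- ObservedSpectrum("t", 2L, 400, cbind(ions$mz, rep(5, 20)))
  tv <- annotateSpectrum(p, s, sharedReg, tol = 0.02)
  expect_true(all(matchedFlags(tv)))
  expect_equal(length(unique(round(as.vector(intensityTargets(tv)), 12))), 1L)

  ## no peak near any ion: all entries at the baseline, zero matches
  s0 <- ObservedSpectrum("t", 2L, 400, cbind(ions$mz + 5, rep(5, 20)))
  tv0 <- annotateSpectrum(p, s0, sharedReg, tol = 0.02)
  expect_false(any(matchedFlags(tv0)))
  expect_equal(unique(as.vector(intensityTargets(tv0))), log2(tv0@epsilon))

  ## two peaks inside the window: the more intense one wins (exhaustive
  ## check on a 5-peak toy spectrum)
  b1 <- fragmentMz(p, sharedReg, "b", 1, 1)
  toy <- ObservedSpectrum("t", 2L, 400,
                          cbind(c(b1 - 0.015, b1 + 0.01, 200, 300, 400),
                                c(10, 40, 7, 8, 9)))
  tvToy <- annotateSpectrum(p, toy, sharedReg, tol = 0.02)
  tic <- sum(c(10, 40, 7, 8, 9))
  expect_equal(intensityTargets(tvToy)[1, "b"],
               log2(40 / tic + tvToy@epsilon), ignore_attr = TRUE)

  expect_error(annotateSpectrum(p, s, sharedReg, tol = 0), "tol")
})

test_that("annotation is deterministic and preserves intensity rank order", {
  p <- parsePeptide("H-PEPTIDEK-OH", sharedReg)
  psm <- simulatePsm(p, 2L, fragmentationParams("methodA"), sharedReg,
                     seed = 9L)
  tv1 <- annotateSpectrum(p, psm$spectrum, sharedReg)
  tv2 <- annotateSpectrum(p, psm$spectrum, sharedReg)
  expect_identical(intensityTargets(tv1), intensityTargets(tv2))

  ## the log2(TIC-normalized + eps) transform is strictly monotone
  ions <- theoreticalSpectrum(p, sharedReg)
  raw <- withr::with_seed(3, runif(nrow(ions), 1, 100))
  s <- ObservedSpectrum("t", 2L, 400, cbind(ions$mz, raw))
  tv <- annotateSpectrum(p, s, sharedReg)
  col <- ifelse(ions$ionCharge == 1L, ions$series, paste0(ions$series, "2"))
  got <- intensityTargets(tv)[cbind(ions$index, match(col, c("b", "y", "b2", "y2")))]
  expect_equal(order(got), order(raw))
})

test_that("prediction CSV has one row per ion and matches the MGF title", {
  preds <- fakePredictions("H-SAMPLE-OH")
  csv <- withr::local_tempfile(fileext = ".csv")
  writePredictionsCSV(preds, csv)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 20L)
  expect_equal(unique(tab$peptide), "H-SAMPLE-OH")
  expect_equal(unique(tab$precursor_charge), 2L)
  expect_equal(sort(tab$mz), sort(preds[[1]]$ions$mz), tolerance = 1e-12)
  expect_equal(tab$intensity[order(tab$mz)],
               preds[[1]]$ions$intensity[order(preds[[1]]$ions$mz)],
               tolerance = 1e-12)
})
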