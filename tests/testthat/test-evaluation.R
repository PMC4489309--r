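test_that("pearsonR reproduces textbook values and flags degenerate input", {
  expect_equal(pearsonR(1:5, 1:5), 1.0)
  expect_equal(pearsonR(1:5, -(1:5) + 10), -1.0)
  expect_equal(pearsonR(c(1, 2, 3), c(1, 2, 4)), 0.98198, tolerance = 1e-5)
  expect_equal(pearsonR(c(1, 2, 3), c(1, 2, 4)),
               oraclePearson(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)
  expect_true(is.na(pearsonR(c(2, 2, 2), 1:3)))
  expect_error(pearsonR(1:4, 1:5), "length mismatch")
  expect_error(pearsonR(1:2, 1:2), "at least 3")
})

test_that("pearsonR is invariant under positive affine transforms", {
  withr::with_seed(31, {
    for (i in 1:20) {
      x <- rnorm(25); y <- rnorm(25)
      r <- pearsonR(x, y)
      a <- runif(1, 0.1, 5); b <- rnorm(1)
      expect_equal(pearsonR(a * x + b, y), r, tolerance = 1e-12)
      expect_equal(pearsonR(x, a * y + b), r, tolerance = 1e-12)
    }
  })
})

test_that("evaluation produces one labelled record per PSM", {
  psms <- simulateDataset(12, 2L, fragmentationParams("methodA"), sharedReg,
                          seed = 41L, lengthRange = c(9L, 12L))
  rec <- evaluateModel(sharedModel, psms, sharedReg)
  expect_equal(nrow(rec), 12L)
  expect_equal(rec$model_method, rep("methodA", 12L))
  expect_equal(rec$spectrum_method, rep("methodA", 12L))
  expect_equal(rec$precursor_charge, rep(2L, 12L))
  expect_true(all(rec$r[!rec$degenerate] >= -1 & rec$r[!rec$degenerate] <= 1))

  ## per-series correlations on request
  recS <- evaluateModel(sharedModel, psms[1:3], sharedReg, perSeries = TRUE)
  expect_true(all(c("r_b", "r_y", "r_b2", "r_y2") %in% names(recS)))

  ## a charge-3 PSM is refused by a charge-2 model
  psm3 <- simulateDataset(1, 3L, fragmentationParams("methodA"), sharedReg,
                          seed = 42L)
  expect_error(evaluateModel(sharedModel, psm3, sharedReg), "charge")
})

test_that("matched-method evaluation is accurate at sigma = 0.2", {
  sig <- fragmentationParams("methodA", dropout = 0, decoyRate = 0)
  tr <- simulateDataset(400, 2L, sig, sharedReg, seed = 51L)
  ev <- simulateDataset(100, 2L, sig, sharedReg, seed = 52L)
  m <- trainModel(buildTrainingSet(tr, "methodA", sharedReg)[["2"]],
                  seed = 1L)
  rec <- evaluateModel(m, ev, sharedReg)
  expect_gte(median(rec$r, na.rm = TRUE), 0.9)
})

test_that("PTM classes are assigned from the peptide's modifications", {
  cls <- function(p) ms2forest:::.ptmClass(p, sharedReg)
  expect_equal(cls(Peptide("SAMPLEK", registry = sharedReg)), "no_ptm")
  expect_equal(cls(Peptide("SAMPLEK", c("3" = "ox"), registry = sharedReg)),
               "mox")
  expect_equal(cls(Peptide("SACPLEK", c("3" = "cmm"), registry = sharedReg)),
               "cmm")
  expect_equal(cls(Peptide("SACPLEN", c("3" = "cmm", "7" = "deam"),
                           registry = sharedReg)), "other")
  expect_equal(cls(Peptide("SAMPLEK", nTerm = "ace-", registry = sharedReg)),
               "other")
})

test_that("distribution summaries follow quartile and whisker conventions", {
  rec <- data.frame(r = 1:5, model_method = "m")
  s <- summarizeRecords(rec)
  expect_equal(s$q1, 2); expect_equal(s$median, 3); expect_equal(s$q3, 4)
  expect_equal(s$n, 5L)
  expect_equal(s$whisker_low, 1); expect_equal(s$whisker_high, 5)

  ## identical values: zero-width box, whiskers on the box
  s2 <- summarizeRecords(data.frame(r = rep(0.7, 8)))
  expect_equal(s2$q1, s2$q3)
  expect_equal(s2$whisker_low, 0.7); expect_equal(s2$whisker_high, 0.7)

  ## whiskers stop at the most extreme datum within 1.5 IQR
  v <- c(1, 2, 3, 4, 100)
  s3 <- summarizeRecords(data.frame(r = v))
  expect_equal(s3$whisker_high, 4)

  ## grouped summary reproduces a charge x method grid
  rec4 <- expand.grid(precursor_charge = c(2L, 3L),
                      model_method = c("A", "B"))
  rec4 <- rec4[rep(1:4, each = 5), ]
  rec4$r <- withr::with_seed(1, runif(20))
  s4 <- summarizeRecords(rec4, c("precursor_charge", "model_method"))
  expect_equal(nrow(s4), 4L)
  expect_true(all(s4$q1 <= s4$median & s4$median <= s4$q3))

  ## permutation invariance in input order
  perm <- withr::with_seed(2, sample(nrow(rec4)))
  s5 <- summarizeRecords(rec4[perm, ], c("precursor_charge", "model_method"))
  expect_equal(s4[order(s4$precursor_charge, s4$model_method), ],
               s5[order(s5$precursor_charge, s5$model_method), ],
               ignore_attr = TRUE)

  ## degenerate records are excluded and counted
  s6 <- summarizeRecords(data.frame(r = c(1, 2, 3, NA)))
  expect_equal(s6$n, 3L); expect_equal(s6$n_degenerate, 1L)
  expect_error(summarizeRecords(data.frame(r = numeric(0))), "no records")
})
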