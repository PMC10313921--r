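test_that("tumor survival normalizes per-focus ratios against untreated controls", {
  ## treated ratio mean 0.5 at one dose vs untreated mean 1.0 -> s = 0.5
  raw <- rawTumorTable(c(1, 1, 10, 10), c(0.4, 0.6, 1.3, 1.5),
                       ctrlRatios = c(0.9, 1.1))
  s <- normalizeTumorSurvival(raw)
  expect_s4_class(s, "DoseResponseCurve")
  expect_equal(curveKind(s), "tumor_survival")
  expect_equal(doses(s), c(1, 10))
  expect_equal(respValues(s)[1], 0.5, tolerance = 1e-12,
               ignore_attr = TRUE)
  ## growth preserved, not clipped: 1.4x untreated stays 1.4
  expect_equal(respValues(s)[2], 1.4, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(s@replicateN), c(2L, 2L))

  ## treated identical to controls -> s = 1 at every dose
  raw2 <- rawTumorTable(c(1, 10, 100), c(1, 1, 1), ctrlRatios = c(1, 1))
  expect_equal(respValues(normalizeTumorSurvival(raw2)), rep(1, 3))
})

test_that("tumor normalization is scale-invariant and validates inputs", {
  raw <- rawTumorTable(c(1, 1, 10, 10), c(0.4, 0.6, 0.2, 0.3),
                       ctrlRatios = c(0.9, 1.1))
  scaled <- raw
  scaled$bli_end <- scaled$bli_end * 1234.5
  expect_equal(respValues(normalizeTumorSurvival(raw)),
               respValues(normalizeTumorSurvival(scaled)))

  noCtrl <- raw[!raw$is_untreated_control, ]
  expect_error(normalizeTumorSurvival(noCtrl), "untreated control")
  onlyCtrl <- raw[raw$is_untreated_control, ]
  expect_error(normalizeTumorSurvival(onlyCtrl), "no treated")
})

test_that("toxicity rescales PI between healthy and dead anchors, clamped to [0,1]", {
  ## healthy -> 0, dead level -> 1, halfway -> 0.5, below-healthy clamps
  raw <- rawSliceTable(c(1, 10, 100, 1000), c(100, 600, 1100, 50))
  tox <- normalizeToxicity(raw)
  expect_equal(curveKind(tox), "slice_toxicity")
  expect_equal(unname(respValues(tox)), c(0, 0.5, 1, 0))

  ## above-dead clamps to 1
  hot <- rawSliceTable(1, 5000)
  expect_equal(unname(respValues(normalizeToxicity(hot))), 1)

  ## inverted anchors are a hard error
  bad <- rawSliceTable(1, 500, healthy = 1100, dead = 100)
  expect_error(normalizeToxicity(bad), "degenerate anchors")
  expect_error(normalizeToxicity(raw[raw$role == "treated", ]),
               "healthy_baseline")
})

test_that("toxicity is monotone in the PI signal for fixed anchors", {
  pi1 <- c(150, 400, 800)
  pi2 <- pi1 + c(50, 100, 200)
  t1 <- respValues(normalizeToxicity(rawSliceTable(c(1, 10, 100), pi1)))
  t2 <- respValues(normalizeToxicity(rawSliceTable(c(1, 10, 100), pi2)))
  expect_true(all(t2 >= t1))
})

test_that("kill fraction complements survival and round-trips exactly", {
  s <- survCurve(c(1, 0.5, 0))
  k <- killFraction(s)
  expect_equal(unname(respValues(k)), c(0, 0.5, 1))
  expect_equal(curveKind(k), "tumor_kill")
  ## growth survives as negative kill
  expect_equal(unname(respValues(killFraction(survCurve(c(1.6, 1, 0.2))))),
               c(-0.6, 0, 0.8))
  ## exact round trip
  expect_identical(respValues(survivalFromKill(k)), respValues(s))
  expect_error(killFraction(k), "tumor_survival")
  expect_error(survivalFromKill(s), "tumor_kill")
})

test_that("curve validity enforces the domain invariants", {
  ## the constructor sorts; duplicated doses violate strict monotonicity
  sorted <- DoseResponseCurve(c(10, 1), c(0.1, 0.2), "slice_toxicity")
  expect_equal(doses(sorted), c(1, 10))
  expect_equal(unname(respValues(sorted)), c(0.2, 0.1))
  expect_error(DoseResponseCurve(c(1, 1, 10), c(0.1, 0.2, 0.3),
                                 "slice_toxicity"), "strictly increasing")
  expect_error(DoseResponseCurve(c(1, 10), c(-0.1, 0.2), "slice_toxicity"),
               "\\[0, 1\\]")
  expect_error(DoseResponseCurve(c(1, 10), c(-0.1, 0.2), "tumor_survival"),
               ">= 0")
  expect_error(DoseResponseCurve(c(0, 10), c(0.1, 0.2), "slice_toxicity"),
               "positive")
  ## survival above 1 is legal (treatment-accelerated growth)
  expect_s4_class(survCurve(c(1.6, 0.5)), "DoseResponseCurve")
})

test_that("CSV readers validate the dialect and name offending rows", {
  td <- withr::local_tempdir()
  raw <- rawTumorTable(c(1, 10), c(0.5, 0.4), ctrlRatios = 1)
  fp <- file.path(td, "tumor_raw.csv")
  write.csv(raw, fp, row.names = FALSE)
  back <- readTumorRaw(fp)
  expect_equal(back$bli_end, raw$bli_end)
  expect_type(back$is_untreated_control, "logical")

  bad <- raw
  bad$dose[2] <- -5
  write.csv(bad, fp, row.names = FALSE)
  expect_error(readTumorRaw(fp), "row\\(s\\) 2")

  ctrlDosed <- raw
  ctrlDosed$dose[ctrlDosed$is_untreated_control][1] <- 3
  write.csv(ctrlDosed, fp, row.names = FALSE)
  expect_error(readTumorRaw(fp), "untreated controls must have dose = 0")

  write.csv(raw[, -3], fp, row.names = FALSE)
  expect_error(readTumorRaw(fp), "missing required column")

  sp <- file.path(td, "slice_raw.csv")
  sraw <- rawSliceTable(c(1, 10), c(200, 600))
  sraw$role[1] <- "mystery"
  write.csv(sraw, sp, row.names = FALSE)
  expect_error(readSliceRaw(sp), "role")
})
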