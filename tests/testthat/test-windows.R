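test_that("ECx windows compare kill and toxicity at the crossing dose", {
  ## EC50 reached where tox = 0 -> +0.5
  k <- killCurve(c(0.2, 0.5, 0.9))
  z <- toxCurve(c(0, 0, 0))
  expect_equal(ecxWindow(k, z, 50), 0.5)

  ## tumor kill identical to tox -> 0 for every reached level
  v <- c(0.15, 0.3, 0.55, 0.8, 0.95)
  k2 <- killCurve(v)
  t2 <- toxCurve(v)
  for (x in c(10, 25, 50, 75, 90))
    expect_equal(ecxWindow(k2, t2, x), 0, tolerance = 1e-12)

  ## NR fallback: shortfall + top-dose tox, clamped
  expect_equal(ecxWindow(killCurve(c(0.1, 0.15, 0.2)),
                         toxCurve(c(0.5, 0.7, 0.9)), 90), -1)

  ## below-range crossing evaluates observed kill and tox at the lowest
  ## dose
  expect_equal(ecxWindow(killCurve(c(0.9, 0.95, 1)),
                         toxCurve(c(0.1, 0.5, 0.8)), 50), 0.8)

  expect_error(
    ecxWindow(killCurve(c(0.2, 0.6)),
              DoseResponseCurve(c(1, 10), c(0.1, 0.2), "slice_toxicity",
                                unit = "Gy"), 50),
    "unit mismatch")
})

test_that("max-kill window is kill minus toxicity at the top dose", {
  expect_equal(maxKillWindow(killCurve(c(0.5, 1)), toxCurve(c(0, 0))), 1)
  expect_equal(maxKillWindow(killCurve(c(0, 0)), toxCurve(c(0.5, 1))), -1)
  expect_equal(maxKillWindow(killCurve(c(0.2, 0.8)), toxCurve(c(0.1, 0.3))),
               0.5)
  ## clamped when growth meets full toxicity
  expect_equal(maxKillWindow(killCurve(c(0, -0.6)), toxCurve(c(0.5, 1))), -1)
})

test_that("slope window is the bounded slope ratio with EC50-attainment tie-break", {
  ## equal slopes -> 0
  k <- killCurve(c(0.2, 0.6, 0.9))
  t <- toxCurve(c(0.2, 0.6, 0.9))
  expect_equal(slopeWindow(k, t), 0)
  ## m_T = 0.4, m_O = 0 (flat toxicity above its EC50) -> +1
  expect_equal(slopeWindow(killCurve(c(0.2, 0.6)), toxCurve(c(0.6, 0.6))), 1)
  ## m_T = 0 (flat kill above EC50), m_O = 0.3 -> -1
  expect_equal(slopeWindow(killCurve(c(0.7, 0.7)), toxCurve(c(0.2, 0.5))), -1)
  ## general ratio
  expect_equal(slopeWindow(killCurve(c(0.2, 0.6)), toxCurve(c(0.3, 0.5))),
               (0.4 - 0.2) / (0.4 + 0.2))
  ## both slopes zero: attainment breaks the tie
  expect_equal(slopeWindow(killCurve(c(1, 1)), toxCurve(c(0, 0))), 1)
  expect_equal(slopeWindow(killCurve(c(0, 0)), toxCurve(c(1, 1))), -1)
  expect_equal(slopeWindow(killCurve(c(0.3, 0.3)), toxCurve(c(0.3, 0.3))), 0)
  expect_equal(slopeWindow(killCurve(c(0.8, 0.8)), toxCurve(c(0.9, 0.9))), 0)
})

test_that("AUC window is the clamped difference of normalized areas", {
  v <- c(0.1, 0.4, 0.7)
  expect_equal(aucWindow(killCurve(v), toxCurve(v)), 0)
  expect_equal(aucWindow(killCurve(c(1, 1, 1)), toxCurve(c(0, 0, 0))), 1)
  ## uniform growth against toxicity clamps at -1
  expect_equal(aucWindow(killCurve(c(-0.5, -0.5)), toxCurve(c(0.6, 0.6))),
               -1)
})

test_that("behavioral windows apply the published thresholds", {
  growthAt <- function(pct)
    growthWindow(detectShape(survCurve(c(pct / 100, 1, 0.9, 0.8, 0.7, 0.6))))
  expect_equal(growthAt(120), 1)
  expect_equal(growthAt(140), 0)
  expect_equal(growthAt(160), -1)
  expect_equal(growthAt(125), 1)   # boundary: up to 125% keeps +1
  expect_equal(growthAt(150), 0)   # boundary: 150% still 0

  remainAt <- function(pct)
    incompleteKillWindow(detectShape(
      survCurve(c(1, 0.9, 0.8, 0.7, 0.5, pct / 100))))
  expect_equal(remainAt(5), 1)
  expect_equal(remainAt(15), 0)
  expect_equal(remainAt(30), -1)
  expect_equal(remainAt(10), 0)    # boundary: 10% enters the 0 band
  expect_equal(remainAt(25), 0)    # boundary: 25% still 0

  ## biphasic: plateaued kill with residual tumor is penalized
  expect_equal(biphasicWindow(detectShape(
    survCurve(1 - c(0.55, 0.60, 0.62, 0.63, 0.63, 0.64)))), -1)
  ## monotone complete kill is not
  expect_equal(biphasicWindow(detectShape(
    survCurve(1 - c(0.1, 0.3, 0.6, 0.8, 0.9, 0.97)))), 1)
  ## flat zero-kill curve has no rapid low-dose killing
  expect_equal(biphasicWindow(detectShape(survCurve(rep(1, 6)))), 1)
})

test_that("the full window panel reproduces the canonical end-member cases", {
  d <- DOSES6
  ## tumor identical to tox, monotone complete kill
  tox <- c(0.05, 0.2, 0.5, 0.8, 0.93, 0.98)
  w1 <- computeAllWindows(DoseResponseCurve(d, 1 - tox, "tumor_survival"),
                          DoseResponseCurve(d, tox, "slice_toxicity"))
  v1 <- windowValues(w1)
  expect_equal(unname(v1[1:8]), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(v1[9:11]), rep(1, 3))

  ## full kill at all doses, zero tox -> all eleven +1
  w2 <- computeAllWindows(DoseResponseCurve(d, rep(0, 6), "tumor_survival"),
                          DoseResponseCurve(d, rep(0, 6), "slice_toxicity"))
  expect_equal(unname(windowValues(w2)), rep(1, 11))

  ## zero kill, full tox, 100% remaining, no growth
  w3 <- computeAllWindows(DoseResponseCurve(d, rep(1, 6), "tumor_survival"),
                          DoseResponseCurve(d, rep(1, 6), "slice_toxicity"))
  v3 <- windowValues(w3)
  expect_equal(unname(v3[1:8]), rep(-1, 8))
  expect_equal(unname(v3[c("growth", "biphasic")]), c(1, 1))
  expect_equal(unname(v3["incomplete"]), -1)
  expect_true(all(nrFlags(w3)))
})

test_that("all windows stay in [-1, +1] for arbitrary valid curve pairs", {
  set.seed(99)
  for (rep in 1:50) {
    p <- randomCurvePair()
    w <- windowValues(computeAllWindows(p$surv, p$tox))
    expect_true(all(w >= -1 - 1e-12 & w <= 1 + 1e-12))
    expect_true(all(w[c("growth", "biphasic", "incomplete")] %in%
                      c(-1, 0, 1)))
  }
})

test_that("windows respond monotonically to kill and toxicity shifts", {
  set.seed(123)
  cmp <- c("max_kill", "ec10", "ec25", "ec50", "ec75", "ec90", "auc")
  for (rep in 1:30) {
    d <- DOSES6
    tox <- sort(runif(6, 0, 0.9))
    s <- runif(6, 0.05, 1.2)
    bump <- runif(6, 0, 0.4)
    toxC <- DoseResponseCurve(d, tox, "slice_toxicity")
    wLo <- windowValues(computeAllWindows(
      DoseResponseCurve(d, s, "tumor_survival"), toxC))
    wHi <- windowValues(computeAllWindows(
      DoseResponseCurve(d, pmax(s - bump, 0), "tumor_survival"), toxC))
    ## pointwise-higher kill with fixed monotone tox never lowers 1-6, 8
    expect_true(all(wHi[cmp] >= wLo[cmp] - 1e-9))

    ## pointwise-higher tox with fixed tumor never raises 1-6, 8
    sFix <- runif(6, 0, 1.2)
    t1 <- sort(runif(6, 0, 0.6))
    t2 <- pmin(t1 + runif(6, 0, 0.35), 1)
    wt1 <- windowValues(computeAllWindows(
      DoseResponseCurve(d, sFix, "tumor_survival"),
      DoseResponseCurve(d, t1, "slice_toxicity")))
    wt2 <- windowValues(computeAllWindows(
      DoseResponseCurve(d, sFix, "tumor_survival"),
      DoseResponseCurve(d, t2, "slice_toxicity")))
    expect_true(all(wt2[cmp] <= wt1[cmp] + 1e-9))
  }
})
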