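test_that("interpolation is piecewise-linear on the configured axis", {
  k <- killCurve(c(0.2, 0.6), doses = c(1, 10))
  ## node identity
  expect_equal(interpolateResponse(k, 1), 0.2)
  expect_equal(interpolateResponse(k, 10), 0.6)
  ## midpoint on the log10 axis
  expect_equal(interpolateResponse(k, 10^0.5), 0.4)
  ## constant curve
  flat <- killCurve(c(0.3, 0.3, 0.3))
  for (d in c(1, 7, 42, 100))
    expect_equal(interpolateResponse(flat, d), 0.3)
  ## no extrapolation
  expect_error(interpolateResponse(k, 0.5), "outside the tested range")
  expect_error(interpolateResponse(k, 11), "outside the tested range")
  ## Gy curves interpolate on the linear axis
  gy <- DoseResponseCurve(c(2, 10), c(0.2, 0.6), "tumor_kill", unit = "Gy")
  expect_equal(interpolationAxis(gy), "linear")
  expect_equal(interpolateResponse(gy, 6), 0.4)
})

test_that("ECx finds the first upward crossing with NR and below-range semantics", {
  k <- killCurve(c(0.2, 0.6, 0.9), doses = c(1, 10, 100))
  r <- computeEcx(k, 50)
  expect_true(r@reached)
  expect_false(r@belowRange)
  ## (0.5-0.2)/(0.6-0.2) = 0.75 of the log10 decade
  expect_equal(r@dose, 10^0.75, tolerance = 1e-12)

  ## max kill 0.4 -> NR
  nr <- computeEcx(killCurve(c(0.1, 0.3, 0.4)), 50)
  expect_false(nr@reached)
  expect_true(is.na(nr@dose))

  ## crossing precedes the grid
  br <- computeEcx(killCurve(c(0.8, 0.9, 0.95)), 50)
  expect_true(br@reached)
  expect_true(br@belowRange)
  expect_equal(br@dose, 1)

  ## node-exact crossing reports the node; flat segment reports its
  ## lowest dose
  expect_equal(computeEcx(killCurve(c(0.2, 0.5, 0.9)), 50)@dose, 10)
  expect_equal(computeEcx(killCurve(c(0.2, 0.5, 0.5, 0.9)), 50)@dose, 10)

  ## non-monotone curves use the first upward crossing
  wob <- killCurve(c(0.1, 0.6, 0.3, 0.8), doses = c(1, 10, 100, 1000))
  expect_equal(computeEcx(wob, 50)@dose, 10^0.8, tolerance = 1e-12)

  expect_error(computeEcx(killCurve(c(0.4, 0.6)), 33), "10, 25, 50, 75, 90")
  expect_error(computeEcx(killCurve(0.9, doses = 1), 50), "at least 2")
})

test_that("ICx applies the same machinery to kill = 1 - survival", {
  s <- survCurve(c(0.9, 0.4, 0.1), doses = c(1, 10, 100))
  r <- computeIcx(s, 50)
  expect_true(r@reached)
  expect_gt(r@dose, 1)
  expect_lt(r@dose, 10)

  ## <50% death at the highest dose -> NR
  expect_false(computeIcx(survCurve(c(1, 0.8, 0.6)), 50)@reached)

  ## exact node crossing
  expect_equal(computeIcx(survCurve(c(0.9, 0.5, 0.1)), 50)@dose, 10)
  expect_error(computeIcx(killCurve(c(0.2, 0.6)), 50), "tumor_survival")
})

test_that("ECx matches a 1e4-point dense brute-force scan on the same curve", {
  set.seed(42)
  for (rep in 1:25) {
    k <- killCurve(runif(6, -0.3, 1), doses = DOSES6)
    for (x in c(10, 25, 50, 75, 90)) {
      mine <- computeEcx(k, x)
      brute <- bruteEcx(k, x)
      expect_identical(mine@reached, brute$reached)
      if (brute$reached) {
        expect_identical(mine@belowRange, brute$belowRange)
        expect_lt(abs(log10(mine@dose) - log10(brute$dose)),
                  2 * brute$step)
      }
    }
  }
})

test_that("reached ECx doses are ordered on a monotone kill curve", {
  set.seed(7)
  for (rep in 1:20) {
    k <- killCurve(sort(runif(6, 0, 1)), doses = DOSES6)
    dd <- sapply(c(10, 25, 50, 75, 90), function(x) {
      r <- computeEcx(k, x)
      if (r@reached) r@dose else NA_real_
    })
    dd <- dd[!is.na(dd)]
    expect_true(all(diff(dd) >= -1e-12))
  }
})

test_that("normalized AUC is the axis-mean response and ignores collinear points", {
  expect_equal(computeNormalizedAuc(killCurve(c(0.5, 0.5, 0.5))), 0.5)
  expect_equal(computeNormalizedAuc(killCurve(c(1, 1, 1, 1))), 1)
  expect_equal(computeNormalizedAuc(toxCurve(c(0, 0, 0))), 0)
  ## uniform growth stays negative
  expect_equal(computeNormalizedAuc(killCurve(c(-0.2, -0.2))), -0.2)

  ## inserting a redundant collinear dose point changes nothing
  k <- killCurve(c(0.2, 0.6), doses = c(1, 100))
  k2 <- killCurve(c(0.2, 0.4, 0.6), doses = c(1, 10, 100))
  expect_equal(computeNormalizedAuc(k), computeNormalizedAuc(k2))

  expect_error(computeNormalizedAuc(killCurve(0.5, doses = 3)),
               "at least 2")
})

test_that("slope through the EC50 uses the crossing segment with a steepest-segment fallback", {
  ## rise/run over one decade
  expect_equal(computeSlopeAtEc50(killCurve(c(0.2, 0.6), doses = c(1, 10))),
               0.4)
  ## flat curve -> 0
  expect_equal(computeSlopeAtEc50(killCurve(c(0.2, 0.2, 0.2))), 0)
  ## EC50 NR -> steepest segment slope
  expect_equal(computeSlopeAtEc50(killCurve(c(0.1, 0.2, 0.3))), 0.1)
  ## crossing in the second segment
  expect_equal(computeSlopeAtEc50(killCurve(c(0.1, 0.3, 0.9))), 0.6)
  ## below-range crossing uses the first segment
  expect_equal(computeSlopeAtEc50(killCurve(c(0.7, 0.8, 0.9))), 0.1)
})

test_that("shape detection reads growth, residual tumor and the biphasic rule", {
  sh <- detectShape(survCurve(c(1.4, 1.2, 1.0, 0.8, 0.6, 0.5)))
  expect_equal(sh@maxGrowthPercent, 140)
  expect_equal(sh@remainingAtMax, 50)
  expect_false(sh@biphasic)

  ## low-half kill >= 0.25, tail gain <= 0.10, remaining > 10%
  sh2 <- detectShape(survCurve(1 - c(0.55, 0.60, 0.62, 0.63, 0.63, 0.64)))
  expect_true(sh2@biphasic)

  ## near-complete kill is excluded (remaining <= 10%)
  sh3 <- detectShape(survCurve(1 - c(0.3, 0.5, 0.7, 0.85, 0.92, 0.95)))
  expect_false(sh3@biphasic)

  ## flat zero-kill curve: no rapid low-dose killing
  expect_false(detectShape(survCurve(rep(1, 6)))@biphasic)
})

test_that("pointwise-higher kill never lowers max kill, AUC, or reached ECx doses", {
  set.seed(11)
  for (rep in 1:20) {
    v <- runif(6, -0.2, 0.95)
    up <- pmin(v + runif(6, 0, 0.3), 1)
    k1 <- killCurve(v, doses = DOSES6)
    k2 <- killCurve(up, doses = DOSES6)
    expect_gte(max(respValues(k2)), max(respValues(k1)))
    expect_gte(computeNormalizedAuc(k2), computeNormalizedAuc(k1))
    for (x in c(25, 50, 75)) {
      r1 <- computeEcx(k1, x)
      r2 <- computeEcx(k2, x)
      if (r1@reached) {
        expect_true(r2@reached)
        expect_lte(r2@dose, r1@dose + 1e-9)
      }
    }
  }
})

test_that("the ICx table reports NR as empty dose cells", {
  curves <- list("T1|drugA" = survCurve(c(0.9, 0.4, 0.1)),
                 "T1|drugB" = survCurve(c(1, 0.9, 0.8)))
  tab <- icxTable(curves, x = 50)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$tumor_id, c("T1", "T1"))
  expect_equal(tab$drug_id, c("drugA", "drugB"))
  expect_true(tab$reached[1])
  expect_false(tab$reached[2])
  expect_true(is.na(tab$dose_at_x[2]))
})
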