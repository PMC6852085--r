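test_that("body-weight indexing arithmetic", {
  expect_equal(cardiac_index(co = 10, bw = 50), 200)
  expect_equal(stroke_volume_index(ci = 200, hr = 200), 1)
  # resting control magnitudes: SVi 1.28 at HR 136 implies CI 174.1
  expect_equal(1.28 * 136, 174.08)
  expect_equal(stroke_volume_index(174.08, 136), 1.28)
  expect_error(cardiac_index(0, 50))
})

test_that("vascular resistance indices and their round-trip identity", {
  expect_equal(vascular_resistance_indices(mpap = 20, maop = 90, ci = 0.2)$tpvri,
               100)
  r <- vascular_resistance_indices(mpap = 24, maop = 91, ci = 0.162)
  expect_equal(r$tpvri * 0.162, 24)
  expect_equal(r$svri * 0.162, 91)
  # homogeneity: doubling CI halves both indices exactly
  r2 <- vascular_resistance_indices(24, 91, 2 * 0.162)
  expect_equal(r2$tpvri, r$tpvri / 2)
  expect_equal(r2$svri, r$svri / 2)
})

test_that("stroke work convention", {
  expect_equal(stroke_work(mpap = 20, sv = 60), 1200)
  expect_equal(stroke_work(20, 0), 0)
  sc <- default_scenario(n_beats = 6)
  sv <- median(sc$truth$sv)
  expect_equal(stroke_work(mean(sc$pap$y), sv), mean(sc$pap$y) * sv)
})

test_that("gravimetric hypertrophy ratios", {
  f <- fulton_index(rvw = 60, lvw = 180, bw = 60)
  expect_equal(f$rv_lv, 1 / 3)
  expect_equal(f$rvw_bw, 1)
  expect_equal(fulton_index(100, 100, 50)$rv_lv, 1)
  # scale invariance of the Fulton index
  expect_equal(fulton_index(2 * 60, 2 * 180, 60)$rv_lv, f$rv_lv)
})

test_that("capillary morphometry", {
  m <- capillary_metrics(3000, field_area = 1, myocyte_count = 100)
  expect_equal(m$density_per_mm2, 3000)
  expect_equal(capillary_metrics(200, 1, 100)$capillary_fiber_ratio, 2)
  expect_warning(m0 <- capillary_metrics(10, 1, 0), "undefined")
  expect_true(is.na(m0$capillary_fiber_ratio))
  # pooled fields equal the count-weighted combination
  pooled <- capillary_metrics(400, 1.5, 150)
  expect_equal(pooled$density_per_mm2,
               sum(c(100, 300)) / sum(c(0.5, 1)))
  expect_equal(pooled$capillary_fiber_ratio, 400 / 150)
})

test_that("microsphere dose arithmetic matches the protocol approximations", {
  m <- microsphere_count(0.5)
  expect_equal(m$rounded, 2500)
  expect_equal(m$raw, 2463.76, tolerance = 1e-4)
  expect_equal(microsphere_count(3)$rounded, 15000)
  # linearity
  expect_equal(microsphere_count(1)$raw, 2 * m$raw)
})

test_that("embolization decision rules match a brute-force restatement", {
  expect_equal(embolization_decision(20, 80, week_index = 2, phase = "weekly"),
               "schedule_reembolization")
  expect_equal(embolization_decision(62, 80, phase = "session"),
               "stop_session")
  expect_equal(embolization_decision(24, 65, week_index = 2, phase = "weekly"),
               "no_action")
  expect_error(embolization_decision(30, 80, cumulative_today_g = 3.5),
               "inconsistent")

  # exhaustive decision table vs an independent restatement of the rules
  brute <- function(mpap, pao2, cum, week, phase) {
    if (phase == "session") {
      if (mpap >= 60) return("stop_session")
      if (pao2 <= 40) return("stop_session")
      if (cum >= 3) return("stop_session")
      return("infuse")
    }
    if (week > 4) return("no_action")
    if (mpap < 25 && pao2 > 70) return("schedule_reembolization")
    "no_action"
  }
  for (mpap in c(15, 24, 25, 59, 60, 70))
    for (pao2 in c(35, 40, 41, 70, 71, 90))
      for (cum in c(0, 1.5, 2.9, 3))
        for (week in c(1, 4, 5, 8))
          for (ph in c("session", "weekly"))
            expect_equal(
              embolization_decision(mpap, pao2, cum, week, ph),
              brute(mpap, pao2, cum, week, ph),
              info = sprintf("mpap=%g pao2=%g cum=%g week=%d %s",
                             mpap, pao2, cum, week, ph))
})
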