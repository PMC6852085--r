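test_that("sine fit recovers an exact sine to high precision", {
  w <- pure_sine_wave(offset = 40, amp = 30, omega = 8, phase = 0.4)
  fs <- w$fs
  # rising limb before the crest (t = 0.146 s), falling limb after it
  ivc <- c(1, round(0.06 * fs))
  ivr <- c(round(0.17 * fs), round(0.44 * fs))
  for (scaled in c(TRUE, FALSE)) {
    f <- fit_sine(w, ivc, ivr, scaled = scaled)
    expect_true(f$ok)
    expect_equal(f$offset, 40, tolerance = 1e-6)
    expect_equal(f$amplitude, 30, tolerance = 1e-6)
    expect_equal(f$pmax, 70, tolerance = 1e-6)
    expect_equal(f$omega, 8, tolerance = 1e-4)
  }
})

test_that("flat windows are flagged degenerate, not fitted", {
  flat <- waveform(rep(25, 500), 250, "rvp", "mmHg")
  f <- fit_sine(flat, c(10, 30), c(60, 90))
  expect_false(f$ok)
  expect_true(is.na(f$pmax))
})

test_that("windows from a single phase are an explicit failure", {
  w <- pure_sine_wave()
  expect_error(fit_sine(w, c(10, 5), c(40, 60)), "non-empty")
})

test_that("noiseless ejecting-beat Pmax approximates the clamped oracle", {
  par <- elastance_params(emax = 1.5, hr = 150)
  sc <- simulate_beats(par, afterload_params(rp = 0.6),
                       sim_config(n_beats = 12, seed = 2))
  est <- estimate_pmax(sc$rvp, sc$flow)
  expect_gte(length(est$pmax), 10)
  err <- abs(median(est$pmax) - clamp_isovolumic(par)) / clamp_isovolumic(par)
  expect_lt(err, 0.10)
})

test_that("per-beat coupling follows the single-beat identities", {
  b <- single_beat_coupling(60, mpap = 30, svi = 1.2)
  expect_equal(b$ees, 25)
  expect_equal(b$ea, 25)
  expect_equal(b$ratio, 1)
  # algebraic identity for arbitrary valid inputs
  set.seed(1)
  for (i in 1:20) {
    mpap <- runif(1, 10, 60); svi <- runif(1, 0.5, 2)
    pmax <- mpap * runif(1, 1.1, 3)
    b <- single_beat_coupling(pmax, mpap, svi)
    expect_equal(b$ratio, pmax / mpap - 1, tolerance = 1e-12)
    expect_equal(b$ees * b$svi + b$pes, pmax, tolerance = 1e-12)
  }
  # resting-swine magnitudes: SVi 1.28 mL/kg, Pmax = 2.5 x mPAP
  b <- single_beat_coupling(2.5 * 20.5, mpap = 20.5, svi = 1.28)
  expect_equal(b$ea, 16.0, tolerance = 0.01)
  expect_equal(b$ratio, 1.5, tolerance = 1e-12)
})

test_that("a fit whose apex does not clear mPAP is excluded", {
  b <- single_beat_coupling(25, mpap = 30, svi = 1)
  expect_false(b$ok)
  expect_true(is.na(b$ratio))
})

test_that("coupling summary medians behave", {
  ratios <- seq(0.5, 1.5, length.out = 11)
  beats <- do.call(rbind, lapply(ratios, function(r)
    single_beat_coupling(30 * (1 + r), mpap = 30, svi = 1)))
  s <- summarize_coupling(beats)
  expect_equal(s$median_ratio, 1)
  expect_equal(s$n_beats_used, 11)
  # order invariance
  s2 <- summarize_coupling(beats[sample(nrow(beats)), ])
  expect_equal(s2$median_ratio, s$median_ratio)
  expect_equal(s2$median_pmax, s$median_pmax)
  # floor is enforced and names the count
  expect_error(summarize_coupling(beats[1:4, ]), "4 usable beats")
  expect_silent(summarize_coupling(beats[1:4, ], allow_fewer = TRUE))
})

test_that("one wild outlier beat moves the median by at most 2%", {
  beats <- do.call(rbind, lapply(seq(0.9, 1.1, length.out = 10), function(r)
    single_beat_coupling(30 * (1 + r), mpap = 30, svi = 1)))
  clean <- summarize_coupling(beats)
  outlier <- single_beat_coupling(300 * 2, mpap = 30, svi = 1)
  both <- summarize_coupling(rbind(beats, outlier))
  expect_lt(abs(both$median_ratio - clean$median_ratio) / clean$median_ratio,
            0.02)
})

test_that("full recording analysis returns a coherent summary", {
  sc <- default_scenario(emax = 1, hr = 136, n_beats = 15)
  cs <- analyze_coupling(sc$rvp, sc$pap, sc$flow, bw = 61)
  expect_s3_class(cs, "coupling_summary")
  expect_gte(cs$n_beats_used, 10)
  ok <- cs$per_beat[cs$per_beat$ok, ]
  expect_true(cs$median_ratio >= min(ok$ratio) &&
                cs$median_ratio <= max(ok$ratio))
  # mismatched channels fail loudly
  expect_error(analyze_coupling(sc$rvp, sc$pap,
                                waveform(sc$flow$y[-1], sc$flow$fs),
                                bw = 61),
               "share sampling rate")
})

test_that("median Ees tracks simulated contractility with perfect rank order", {
  emaxes <- c(0.5, 1, 2, 3)
  ees <- vapply(emaxes, function(e) {
    sc <- default_scenario(emax = e, hr = 136, rp = 0.6, n_beats = 12)
    analyze_coupling(sc$rvp, sc$pap, sc$flow, bw = 61)$median_ees
  }, numeric(1))
  expect_equal(cor(ees, emaxes, method = "spearman"), 1)
})
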