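#' Sine-wave fit over the isovolumic phases of one beat
#'
#' Fits a sine wave by least squares to the isovolumic contraction and
#' relaxation samples of an RV pressure beat and reads the maximal
#' isovolumic pressure (Pmax) off its apex.
#'
#' Two fit modes are available. The default (`scaled = TRUE`) models
#' the two limbs as scaled copies of one sine,
#' `P(t) = k_limb (B + C sin(omega t + phase))`, sharing the carrier
#' (omega, phase) between limbs but giving each its own offset and
#' amplitude, and takes `pmax` from the apex of the contraction limb.
#' Rationale: in a ventricle whose pressure is generated by a
#' time-varying elastance, pressures during isovolumic relaxation are
#' scaled by the smaller end-systolic volume, so a common amplitude
#' biases the apex low, while the contraction limb carries the
#' end-diastolic volume scale that a clamped (non-ejecting) beat would
#' retain. The carrier is profiled on an omega grid spanning
#' `omega_bounds` times pi / (window span) crossed with a fine phase
#' grid, then refined numerically; candidate carriers are restricted to
#' those whose crest falls inside the inter-window (ejection) gap and
#' whose preceding trough does not postdate the contraction-window
#' start, which pins the physically meaningful basin. `scaled = FALSE`
#' gives the classic single sine
#' `P(t) = offset + amplitude * sin(omega t + phase)` over the
#' concatenated samples with equal weights.
#'
#' @param rvp RV pressure [waveform()].
#' @param ivc integer pair, start/end indices of the isovolumic
#'   contraction window.
#' @param ivr integer pair, start/end indices of the isovolumic
#'   relaxation window.
#' @param omega_bounds multiplicative bounds on omega around its
#'   initial value pi / (window span).
#' @param n_grid number of omega grid points profiled.
#' @param scaled use the scaled two-limb model (default) or a single
#'   common sine.
#' @return object of class `sine_fit`: `offset`, `amplitude`
#'   (contraction-limb values in scaled mode), `omega`, `phase`,
#'   `pmax`, `rmse`, `n`, `ok` (FALSE for degenerate fits whose apex
#'   does not exceed the observed window pressures).
#' @export
fit_sine <- function(rvp, ivc, ivr, omega_bounds = c(0.9, 3),
                     n_grid = 60, scaled = TRUE) {
  stopifnot(inherits(rvp, "waveform"), length(ivc) == 2, length(ivr) == 2)
  if (ivc[1] > ivc[2] || ivr[1] > ivr[2])
    stop("isovolumic windows must be non-empty index ranges")
  i1 <- ivc[1]:ivc[2]; i2 <- ivr[1]:ivr[2]
  fs <- rvp$fs
  t1 <- rvp$t[i1] - rvp$t[i1[1]]; y1 <- rvp$y[i1]
  t2 <- rvp$t[i2] - rvp$t[i1[1]]; y2 <- rvp$y[i2]
  n <- length(i1) + length(i2)
  fail <- structure(list(offset = NA_real_, amplitude = NA_real_,
                         omega = NA_real_, phase = NA_real_,
                         pmax = NA_real_, rmse = NA_real_, n = n,
                         ok = FALSE), class = "sine_fit")
  if (n < 8) return(fail)
  if (stats::sd(c(y1, y2)) < 1e-8) return(fail)

  omega0 <- pi / (t2[length(t2)] - t1[1])
  wgrid <- exp(seq(log(omega_bounds[1] * omega0),
                   log(omega_bounds[2] * omega0), length.out = n_grid))

  if (scaled) {
    # crest inside the inter-window gap; trough at/before the
    # contraction-window start
    t_gap_hi <- t2[1]
    crest_ok <- function(w, phi) {
      tc <- ((pi / 2 - phi) / w) %% (2 * pi / w)
      (tc > t1[length(t1)] - 2 / fs) &&
        (tc < t_gap_hi + 2 / fs) &&
        (tc - pi / w <= 2 / fs)
    }
    pgrid <- seq(0, 2 * pi, length.out = 181)[-181]
    best <- NULL; brss <- Inf
    for (w in wgrid) {
      rr <- vapply(pgrid, function(phi)
        scaled_limb_rss(w, phi, t1, y1, t2, y2), numeric(1))
      ok <- vapply(pgrid, function(phi) crest_ok(w, phi), logical(1))
      rr[!ok] <- Inf
      j <- which.min(rr)
      if (rr[j] < brss) { brss <- rr[j]; best <- c(w, pgrid[j]) }
    }
    if (is.null(best) || !is.finite(brss)) return(fail)
    pen <- function(p) scaled_limb_rss(p[1], p[2], t1, y1, t2, y2) +
      if (crest_ok(p[1], p[2])) 0 else 1e9
    opt <- stats::optim(best, pen, method = "Nelder-Mead",
                        control = list(reltol = 1e-12))
    opt <- stats::optim(opt$par, pen, method = "Nelder-Mead",
                        control = list(reltol = 1e-12))  # restart polish
    w <- opt$par[1]; phi <- opt$par[2] %% (2 * pi)
    u1 <- sin(w * t1 + phi)
    cf <- stats::lm.fit(cbind(1, u1), y1)$coefficients
    cf[is.na(cf)] <- 0
    if (cf[[2]] < 0) {               # canonicalize: carrier crest = apex
      phi <- (phi + pi) %% (2 * pi)
      cf[[2]] <- -cf[[2]]
    }
    offset <- cf[[1]]; amp <- cf[[2]]
    rss <- scaled_limb_rss(w, phi, t1, y1, t2, y2)
  } else {
    rss_of <- function(w) common_sine_fit(w, c(t1, t2), c(y1, y2))$rss
    rs <- vapply(wgrid, rss_of, numeric(1))
    k <- which.min(rs)
    opt <- stats::optimize(rss_of, c(wgrid[max(1, k - 1)],
                                     wgrid[min(n_grid, k + 1)]))
    opt <- stats::optimize(rss_of, opt$minimum * c(0.99, 1.01),
                           tol = 1e-12)   # polish
    sol <- common_sine_fit(opt$minimum, c(t1, t2), c(y1, y2))
    w <- opt$minimum; phi <- sol$phase %% (2 * pi)
    offset <- sol$c0; amp <- sol$amp; rss <- sol$rss
  }

  structure(list(
    offset = offset, amplitude = amp, omega = w, phase = phi,
    pmax = offset + amp, rmse = sqrt(rss / n), n = n,
    ok = amp > 0 && (offset + amp) > max(y1, y2)
  ), class = "sine_fit")
}

# sum over both limbs of the 2-parameter (offset + amplitude on the
# shared carrier) least-squares residual, closed form
scaled_limb_rss <- function(w, phi, t1, y1, t2, y2) {
  one <- function(tt, yy) {
    u <- sin(w * tt + phi)
    n <- length(yy)
    su <- sum(u); suu <- sum(u * u); sy <- sum(yy); suy <- sum(u * yy)
    det <- n * suu - su * su
    if (abs(det) < 1e-12) return(sum((yy - mean(yy))^2))
    b <- (suu * sy - su * suy) / det
    cc <- (n * suy - su * sy) / det
    sum((yy - b - cc * u)^2)
  }
  one(t1, y1) + one(t2, y2)
}

#' @export
print.sine_fit <- function(x, ...) {
  if (!x$ok) cat("<sine_fit> degenerate (flagged unusable)\n")
  else cat(sprintf(
    "<sine_fit> Pmax %.1f mmHg (offset %.1f + amp %.1f), omega %.2f rad/s, rmse %.3f, n %d\n",
    x$pmax, x$offset, x$amplitude, x$omega, x$rmse, x$n))
  invisible(x)
}

# classic single sine, linear in offset + sin/cos pair at fixed omega
common_sine_fit <- function(w, tt, yy) {
  X <- cbind(1, sin(w * tt), cos(w * tt))
  fit <- stats::lm.fit(X, yy)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(c0 = cf[[1]], amp = sqrt(cf[[2]]^2 + cf[[3]]^2),
       phase = atan2(cf[[3]], cf[[2]]), rss = sum(fit$residuals^2))
}

#' Recording-level Pmax estimation over consecutive beats
#'
#' Estimates the maximal isovolumic pressure for every usable beat of a
#' recording. Because all beats of a recording share their systolic
#' timing, the sine carrier (frequency and phase) is estimated once, on
#' a noise-reduced ensemble beat built by averaging the beats aligned
#' at their valve-opening sample, with the valve-delimited isovolumic
#' windows of [isovolumic_windows()]; each beat then contributes a
#' single amplitude scale fitted to the ensemble template over its own
#' contraction window, so per-beat Pmax values remain beat-specific
#' while the ill-conditioned shape parameters are shared.
#'
#' @param rvp RV pressure [waveform()].
#' @param flow matched arterial flow [waveform()] (marks valve events).
#' @param segs optional precomputed [segment_beats()] result.
#' @param ... passed to [segment_beats()].
#' @return list: `pmax` (per usable beat), `beat_rows` (row indices of
#'   `segs` used), `fit` (the ensemble `sine_fit`), `segs`.
#' @export
estimate_pmax <- function(rvp, flow, segs = NULL, ...) {
  stopifnot(inherits(rvp, "waveform"), inherits(flow, "waveform"))
  if (is.null(segs)) segs <- segment_beats(rvp, ...)
  if (nrow(segs) == 0)
    return(list(pmax = numeric(0), beat_rows = integer(0),
                fit = NULL, segs = segs))
  wins <- lapply(seq_len(nrow(segs)), function(k)
    isovolumic_windows(segs[k, ], rvp, flow = flow))
  ok <- vapply(wins, function(x)
    x$usable && !is.na(x$open_idx), logical(1))
  rows <- which(ok)
  if (length(rows) < 2)
    return(list(pmax = numeric(0), beat_rows = integer(0),
                fit = NULL, segs = segs))
  wins <- wins[rows]
  fs <- rvp$fs
  opens <- vapply(wins, `[[`, 1L, "open_idx")

  # ensemble beat aligned at valve opening
  pre <- min(opens - 1,
             max(opens - vapply(wins, function(x) x$ivc[1], 1L)) + 3)
  post <- min(length(rvp$y) - opens,
              max(vapply(wins, function(x) x$ivr[2], 1L) - opens) + 3)
  M <- vapply(opens, function(o) rvp$y[(o - pre):(o + post)],
              numeric(pre + post + 1))
  ens_y <- rowMeans(M)
  ens <- waveform(ens_y, fs, "rvp_ensemble", rvp$units)

  # ensemble windows from the median per-beat offsets around opening
  i1s <- round(stats::median(opens - vapply(wins, function(x) x$ivc[1], 1L)))
  co <- round(stats::median(vapply(wins, `[[`, 1L, "close_idx") - opens))
  i2e <- round(stats::median(vapply(wins, function(x) x$ivr[2], 1L) - opens))
  j1 <- c(max(1, pre + 1 - i1s), pre)
  j2 <- c(pre + 1 + co + 1, min(pre + 1 + i2e, length(ens_y)))
  if (j1[2] - j1[1] < 3 || j2[2] - j2[1] < 5 || j2[1] >= length(ens_y))
    return(list(pmax = numeric(0), beat_rows = integer(0),
                fit = NULL, segs = segs))
  fit <- fit_sine(ens, j1, j2)
  if (!fit$ok)
    return(list(pmax = numeric(0), beat_rows = integer(0),
                fit = fit, segs = segs))

  # per-beat amplitude scale on the ensemble template
  off1 <- (j1[1]:j1[2]) - (pre + 1)
  tb <- (off1 - off1[1]) / fs
  f <- fit$offset + fit$amplitude * sin(fit$omega * tb + fit$phase)
  pm <- vapply(seq_along(wins), function(k) {
    i1b <- opens[k] + off1
    if (min(i1b) < 1 || max(i1b) > length(rvp$y)) return(NA_real_)
    s_b <- sum(rvp$y[i1b] * f) / sum(f * f)
    s_b * fit$pmax
  }, numeric(1))
  keep <- is.finite(pm)
  list(pmax = pm[keep], beat_rows = rows[keep], fit = fit, segs = segs)
}

#' Per-beat single-beat coupling indices
#'
#' Computes the single-beat coupling triplet for one cardiac cycle:
#' end-systolic elastance Ees = (Pmax - mPAP) / SVi, arterial elastance
#' Ea = mPAP / SVi, and their ratio (RV-PA coupling), taking
#' end-systolic PA pressure equal to mPAP. The ratio satisfies
#' Ees/Ea = Pmax/mPAP - 1 identically.
#'
#' @param pmax sine-fit maximal isovolumic pressure, mmHg (or a
#'   `sine_fit` object).
#' @param mpap mean pulmonary artery pressure over the beat, mmHg.
#' @param svi stroke volume index, mL/kg.
#' @return one-row data frame: `pmax`, `pes`, `svi`, `ees`, `ea`,
#'   `ratio`, `ok`. A fit whose Pmax does not exceed mPAP is flagged
#'   non-physiological (`ok = FALSE`, indices NA).
#' @export
single_beat_coupling <- function(pmax, mpap, svi) {
  if (inherits(pmax, "sine_fit")) {
    if (!pmax$ok) pmax <- NA_real_ else pmax <- pmax$pmax
  }
  stopifnot(is.numeric(mpap), mpap > 0, is.numeric(svi), svi > 0)
  if (!is.finite(pmax) || pmax <= mpap) {
    return(data.frame(pmax = pmax, pes = mpap, svi = svi,
                      ees = NA_real_, ea = NA_real_, ratio = NA_real_,
                      ok = FALSE))
  }
  ees <- (pmax - mpap) / svi
  ea <- mpap / svi
  data.frame(pmax = pmax, pes = mpap, svi = svi,
             ees = ees, ea = ea, ratio = ees / ea, ok = TRUE)
}

#' Median summary of per-beat coupling over consecutive beats
#'
#' The single-beat method reports the median of each index over at
#' least `min_beats` consecutive usable beats; the floor can be
#' overridden explicitly for short recordings.
#'
#' @param beats data frame of [single_beat_coupling()] rows.
#' @param min_beats required number of usable beats (default 10).
#' @param allow_fewer set TRUE to override the floor.
#' @return object of class `coupling_summary`: `n_beats_used`,
#'   `n_excluded`, medians of pmax/ees/ea/ratio, and the per-beat table.
#' @export
summarize_coupling <- function(beats, min_beats = 10,
                               allow_fewer = FALSE) {
  stopifnot(is.data.frame(beats), min_beats >= 1)
  usable <- beats[!is.na(beats$ok) & beats$ok, , drop = FALSE]
  if (nrow(usable) < min_beats && !allow_fewer)
    stop(sprintf(
      "only %d usable beats; the single-beat summary requires at least %d (set allow_fewer = TRUE to override)",
      nrow(usable), min_beats))
  if (nrow(usable) == 0)
    stop("no usable beats to summarize")
  structure(list(
    n_beats_used = nrow(usable),
    n_excluded = nrow(beats) - nrow(usable),
    median_pmax = stats::median(usable$pmax),
    median_ees = stats::median(usable$ees),
    median_ea = stats::median(usable$ea),
    median_ratio = stats::median(usable$ratio),
    per_beat = beats
  ), class = "coupling_summary")
}

#' @export
print.coupling_summary <- function(x, ...) {
  cat(sprintf(
    "<coupling_summary> %d beats (%d excluded): Pmax %.1f mmHg, Ees %.2f, Ea %.2f mmHg/mL/kg, Ees/Ea %.2f\n",
    x$n_beats_used, x$n_excluded, x$median_pmax, x$median_ees,
    x$median_ea, x$median_ratio))
  invisible(x)
}

#' Full single-beat coupling analysis of one recording
#'
#' Runs the complete per-recording pipeline: segments the RV pressure
#' trace into beats, estimates the per-beat maximal isovolumic pressure
#' by the recording-level sine method of [estimate_pmax()], pairs each
#' beat with its own mean PA pressure and flow-integral stroke volume
#' (indexed to body weight), and returns the median coupling summary.
#'
#' @param rvp,pap,flow [waveform()]s sharing fs and length: RV pressure
#'   (mmHg), PA pressure (mmHg), proximal arterial flow (mL/s).
#' @param bw body weight, kg.
#' @param min_beats usable-beat floor for the summary.
#' @param allow_fewer override the floor.
#' @param ... passed to [segment_beats()].
#' @return a `coupling_summary`; its `per_beat` table carries one row
#'   per detected beat with the exclusion flag.
#' @export
analyze_coupling <- function(rvp, pap, flow, bw, min_beats = 10,
                             allow_fewer = FALSE, ...) {
  stopifnot(inherits(rvp, "waveform"), inherits(pap, "waveform"),
            inherits(flow, "waveform"), bw > 0)
  if (length(rvp$y) != length(pap$y) || length(rvp$y) != length(flow$y) ||
      rvp$fs != pap$fs || rvp$fs != flow$fs)
    stop("rvp, pap and flow must share sampling rate and length")
  est <- estimate_pmax(rvp, flow, ...)
  segs <- est$segs
  pmax_by_row <- rep(NA_real_, nrow(segs))
  pmax_by_row[est$beat_rows] <- est$pmax
  rows <- lapply(seq_len(nrow(segs)), function(k) {
    s <- segs[k, ]
    rng <- s$onset_idx:s$end_idx
    mpap <- mean(pap$y[rng])
    sv <- wf_integrate(flow, rng)
    pm <- pmax_by_row[k]
    if (!is.finite(pm) || mpap <= 0 || sv <= 0)
      return(data.frame(pmax = pm, pes = mpap, svi = sv / bw,
                        ees = NA_real_, ea = NA_real_, ratio = NA_real_,
                        ok = FALSE))
    single_beat_coupling(pm, mpap, sv / bw)
  })
  beats <- do.call(rbind, rows)
  summarize_coupling(beats, min_beats = min_beats,
                     allow_fewer = allow_fewer)
}
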