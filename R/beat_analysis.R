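#' Smoothed time derivative of a waveform
#'
#' Local-polynomial (Savitzky-Golay) differentiation: a quadratic is fit
#' over a sliding window and its analytic slope taken at the centre. The
#' window length defaults to 11 samples at 250 Hz and scales with the
#' sampling rate (always odd, at least 5). Edges use the one-sided
#' polynomial fits, so a pure linear ramp differentiates exactly
#' everywhere including the edges.
#'
#' @param w a [waveform()].
#' @param order polynomial order of the local fit.
#' @param window window length in samples (odd); default scales
#'   `11 * fs / 250`.
#' @return a [waveform()] of the derivative, same length and fs, units
#'   `<units>/s`.
#' @export
differentiate <- function(w, order = 2, window = NULL) {
  stopifnot(inherits(w, "waveform"))
  if (is.null(window)) window <- round(11 * w$fs / 250)
  window <- max(5, window)
  if (window %% 2 == 0) window <- window + 1
  if (length(w$y) < window)
    stop(sprintf("waveform has %d samples, fewer than the %d-sample smoothing window",
                 length(w$y), window))
  dy <- signal::sgolayfilt(w$y, p = order, n = window, m = 1, ts = 1 / w$fs)
  waveform(dy, w$fs, paste0("d", w$label, "/dt"),
           paste0(w$units, "/s"), t0 = w$t[1])
}

#' Segment an RV pressure trace into beats
#'
#' Beat onsets are detected as upstroke crossings of a threshold
#' fraction of the local cycle's maximal dP/dt, requiring the
#' derivative to stay above threshold for a short persistence span, and
#' separated by a refractory period; partial cycles at the trace edges
#' are discarded. Requiring the derivative to hold above threshold for
#' a few consecutive samples keeps onset detection stable under
#' measurement noise. Detection works entirely on the derivative, so
#' results are invariant to a constant pressure offset.
#'
#' @param rvp RV pressure [waveform()], mmHg.
#' @param threshold_frac onset threshold as a fraction of the cycle
#'   dP/dt maximum.
#' @param refractory_s minimum spacing between onsets, s.
#' @param min_dpdt minimum dP/dt maximum (mmHg/s) for a trace to be
#'   considered pulsatile; flat or monotone traces yield an empty
#'   result with a warning.
#' @param smooth_window Savitzky-Golay window (samples) used for onset
#'   detection; default scales `11 * fs / 250` (as [differentiate()]).
#' @return data frame of class `beat_segments`, one row per complete
#'   beat: `onset_idx`, `dpdt_max_idx`, `dpdt_max`, `dpdt_min_idx`,
#'   `dpdt_min`, `end_idx`, `ivc_start`, `ivc_end`, `ivr_start`,
#'   `ivr_end`, `usable`.
#' @export
segment_beats <- function(rvp, threshold_frac = 0.2,
                          refractory_s = 0.150, min_dpdt = 25,
                          smooth_window = NULL) {
  stopifnot(inherits(rvp, "waveform"), threshold_frac > 0,
            threshold_frac < 1)
  if (is.null(smooth_window)) smooth_window <- round(11 * rvp$fs / 250)
  dp <- differentiate(rvp, window = smooth_window)$y  # onset detection
  dpl <- differentiate(rvp)$y                         # landmark placement
  n <- length(dp)
  persist <- max(3L, round(0.012 * rvp$fs))
  empty <- data.frame(onset_idx = integer(0), dpdt_max_idx = integer(0),
                      dpdt_max = numeric(0), dpdt_min_idx = integer(0),
                      dpdt_min = numeric(0), end_idx = integer(0),
                      ivc_start = integer(0), ivc_end = integer(0),
                      ivr_start = integer(0), ivr_end = integer(0),
                      usable = logical(0))
  class(empty) <- c("beat_segments", "data.frame")
  if (max(dp) < min_dpdt) {
    warning("no beats found: trace is flat or lacks a pressure upstroke")
    return(empty)
  }

  # pass 1: candidate onsets against the global dP/dt maximum
  onsets <- upstroke_crossings(dp, threshold_frac * max(dp),
                               round(refractory_s * rvp$fs), persist)
  if (length(onsets) < 2) {
    warning("no complete beats found: fewer than two upstrokes detected")
    return(empty)
  }

  # pass 2: re-locate each onset against its own cycle's dP/dt maximum
  bounds <- c(onsets, n + 1L)
  for (k in seq_along(onsets)) {
    lo <- max(1, onsets[k] - round(0.5 * refractory_s * rvp$fs))
    hi <- bounds[k + 1] - 1L
    thr <- threshold_frac * max(dp[onsets[k]:hi])
    i_max <- onsets[k] - 1L + which.max(dp[onsets[k]:hi])
    cand <- upstroke_crossings(dp[lo:i_max], thr, 1L, persist)
    if (length(cand)) onsets[k] <- lo + cand[length(cand)] - 1L
  }
  onsets <- sort(unique(onsets))

  period <- stats::median(diff(onsets))
  ends <- c(onsets[-1] - 1L,
            if (n - onsets[length(onsets)] + 1 >= 0.7 * period) n)
  onsets <- onsets[seq_along(ends)]

  segs <- lapply(seq_along(ends), function(k) {
    o <- onsets[k]; e <- ends[k]
    rng <- o:e
    i_max <- o - 1L + which.max(dpl[rng])
    i_min <- o - 1L + which.min(dpl[rng])
    ok <- (o < i_max) && (i_max < i_min) && (i_min < e) &&
      dpl[i_max] > 0 && dpl[i_min] < 0
    data.frame(onset_idx = o, dpdt_max_idx = i_max, dpdt_max = dpl[i_max],
               dpdt_min_idx = i_min, dpdt_min = dpl[i_min], end_idx = e,
               usable = ok)
  })
  segs <- do.call(rbind, segs)
  segs <- segs[segs$usable, , drop = FALSE]
  if (nrow(segs) == 0) {
    warning("no beats with valid landmark ordering")
    return(empty)
  }

  win <- lapply(seq_len(nrow(segs)), function(k)
    isovolumic_windows(segs[k, ], rvp))
  segs$ivc_start <- vapply(win, function(x) x$ivc[1], integer(1))
  segs$ivc_end   <- vapply(win, function(x) x$ivc[2], integer(1))
  segs$ivr_start <- vapply(win, function(x) x$ivr[1], integer(1))
  segs$ivr_end   <- vapply(win, function(x) x$ivr[2], integer(1))
  segs$usable    <- vapply(win, function(x) x$usable, logical(1))
  rownames(segs) <- NULL
  class(segs) <- c("beat_segments", "data.frame")
  segs
}

# indices where x crosses thr upward and stays above it for `persist`
# samples, separated by >= refractory samples
upstroke_crossings <- function(x, thr, refractory, persist = 3L) {
  n <- length(x)
  above <- x >= thr
  ok <- above
  if (persist > 1) for (j in seq_len(persist - 1))
    ok <- ok & c(above[-seq_len(j)], rep(FALSE, j))
  idx <- which(ok & !c(FALSE, above[-n]))
  if (!length(idx)) return(integer(0))
  keep <- idx[1]
  for (i in idx[-1]) if (i - keep[length(keep)] >= refractory)
    keep <- c(keep, i)
  keep
}

#' Isovolumic contraction and relaxation windows of one beat
#'
#' By the dP/dt convention (default), the isovolumic contraction window
#' runs from the beat onset to the time of maximal dP/dt, and the
#' isovolumic relaxation window from the time of minimal dP/dt to the
#' first sample where pressure falls back below its value at onset,
#' capped at the beat end. When the matched arterial `flow` trace is
#' supplied, the windows are instead delimited by the valve events it
#' marks - contraction from onset to the last zero-flow sample before
#' ejection, relaxation from the first zero-flow sample after ejection
#' to pressure recovery - which is the physiological definition of the
#' isovolumic phases and excludes early-ejection samples from the sine
#' fit. A beat whose pressure never recovers below the onset value
#' before the beat end (e.g. truncated at the trace edge), or whose
#' windows hold fewer than 4 samples, is flagged unusable.
#'
#' @param beat one row of the [segment_beats()] result (landmarks).
#' @param rvp the RV pressure [waveform()] the landmarks index into.
#' @param flow optional matched flow [waveform()]; when given, windows
#'   are clipped to the zero-flow (closed-valve) spans.
#' @param persist number of consecutive sub-threshold samples required
#'   to declare pressure recovery (guards against noise dips).
#' @return list with `ivc` and `ivr` (integer start/end index pairs),
#'   `open_idx`/`close_idx` (valve events, NA without `flow`), and
#'   `usable`.
#' @export
isovolumic_windows <- function(beat, rvp, flow = NULL, persist = 3L) {
  stopifnot(inherits(rvp, "waveform"))
  o <- beat$onset_idx; e <- beat$end_idx
  open_idx <- NA_integer_; close_idx <- NA_integer_
  ivc_end <- beat$dpdt_max_idx
  ivr_start <- beat$dpdt_min_idx
  if (!is.null(flow)) {
    stopifnot(inherits(flow, "waveform"))
    fl <- which(flow$y[o:e] > 1e-9)
    if (length(fl)) {
      open_idx <- as.integer(o - 1L + fl[1])
      close_idx <- as.integer(o - 1L + max(fl))
      ivc_end <- open_idx - 1L
      ivr_start <- close_idx + 1L
    }
  }
  ivc <- c(o, ivc_end)
  p_on <- rvp$y[o]
  after <- ivr_start:e
  # recovery = pressure below onset value, sustained for `persist`
  # samples so that a single noise dip does not truncate the window
  bel <- rvp$y[after] < p_on
  run <- bel
  if (persist > 1) for (j in seq_len(persist - 1))
    run <- run & c(bel[-seq_len(j)], rep(FALSE, j))
  recovered <- any(run)
  ivr_end <- if (recovered) after[which(run)[1]] else e
  ivr <- c(ivr_start, ivr_end)
  usable <- recovered &&
    (ivc[2] - ivc[1] + 1 >= 4) && (ivr[2] - ivr[1] + 1 >= 4)
  list(ivc = as.integer(ivc), ivr = as.integer(ivr),
       open_idx = open_idx, close_idx = close_idx, usable = usable)
}
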