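#' Uniformly sampled physiological waveform
#'
#' Container for a uniformly sampled signal (pressure in mmHg, flow in
#' mL/s, volume in mL) with its sampling rate and unit label. All analysis
#' functions in the package accept and return this class.
#'
#' @param y numeric vector of samples; must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param label signal name, e.g. "rvp".
#' @param units unit string, e.g. "mmHg" or "mL/s".
#' @param t0 time of the first sample in seconds.
#' @return An object of class `waveform`: a list with elements `t`, `y`,
#'   `fs`, `label`, `units`.
#' @examples
#' w <- waveform(sin(2 * pi * seq(0, 1, by = 1 / 250)), fs = 250,
#'               label = "demo", units = "mmHg")
#' @export
waveform <- function(y, fs, label = "signal", units = "", t0 = 0) {
  stopifnot(is.numeric(y), length(y) >= 1, is.numeric(fs), fs > 0)
  if (!all(is.finite(y))) stop("waveform samples must be finite")
  structure(
    list(t = t0 + (seq_along(y) - 1) / fs, y = as.numeric(y),
         fs = fs, label = label, units = units),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform '%s'> %d samples @ %g Hz (%.3f s), units %s\n",
              x$label, length(x$y), x$fs,
              length(x$y) / x$fs, x$units))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$y)

#' Trapezoidal integral of a waveform over an index range
#'
#' Used for per-beat stroke volume as the time-integral of flow.
#'
#' @param w a [waveform()].
#' @param idx integer index range to integrate over (default: all).
#' @return the integral of `y` over time, in `units * s`.
#' @export
wf_integrate <- function(w, idx = seq_along(w$y)) {
  y <- w$y[idx]
  if (length(y) < 2) return(0)
  sum((y[-1] + y[-length(y)]) / 2) / w$fs
}

# run code with a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
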