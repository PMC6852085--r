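#' Ventricular time-varying elastance parameters
#'
#' Parameters of the time-varying elastance ventricle
#' P(t) = E(t) (V(t) - V0), with E(t) moving between `emin` and `emax`
#' under a raised-cosine activation that peaks (value 1) at `t_peak`.
#'
#' @param emax end-systolic (peak) elastance, mmHg/mL.
#' @param emin diastolic elastance, mmHg/mL.
#' @param v0 unstressed volume, mL.
#' @param ved end-diastolic volume, mL; the ventricle refills to `ved`
#'   over the final part of each cycle (smooth late-diastolic ramp).
#' @param hr heart rate in beats/min; sets the period `t_beat = 60/hr`.
#' @param t_peak time of peak activation within the beat, s. Default 26%
#'   of the period.
#' @param rise_w,fall_w raised-cosine activation rise and fall widths, s.
#'   Both default to 21% of the period, giving a systolic fraction of
#'   about 40% of the cycle; with equal widths the whole activation is
#'   one half-cosine, so isovolumic pressure segments are exactly
#'   sinusoidal in time.
#' @return object of class `elastance_params`.
#' @export
elastance_params <- function(emax, emin = 0.05, v0 = 10, ved = 60,
                             hr = 120, t_peak = NULL,
                             rise_w = NULL, fall_w = NULL) {
  t_beat <- 60 / hr
  if (is.null(t_peak)) t_peak <- 0.26 * t_beat
  if (is.null(rise_w)) rise_w <- 0.21 * t_beat
  if (is.null(fall_w)) fall_w <- 0.21 * t_beat
  stopifnot(emax > emin, emin > 0, ved > v0, v0 >= 0,
            t_peak > 0, t_peak < t_beat, rise_w > 0, fall_w > 0,
            rise_w <= t_peak, t_peak + fall_w <= t_beat)
  structure(list(emax = emax, emin = emin, v0 = v0, ved = ved,
                 t_beat = t_beat, hr = hr, t_peak = t_peak,
                 rise_w = rise_w, fall_w = fall_w),
            class = "elastance_params")
}

#' Three-element windkessel afterload parameters
#'
#' @param zc characteristic impedance, mmHg s/mL.
#' @param rp peripheral resistance, mmHg s/mL.
#' @param c_art arterial compliance, mL/mmHg.
#' @param pd0 initial downstream (compliance) pressure, mmHg.
#' @param p_out outflow (venous/atrial) pressure the peripheral
#'   resistance drains into, mmHg; sets the diastolic floor of the
#'   arterial pressure.
#' @return object of class `afterload_params`.
#' @export
afterload_params <- function(zc = 0.035, rp = 0.6, c_art = 2.0, pd0 = 15,
                             p_out = 5) {
  stopifnot(zc > 0, rp > 0, c_art > 0, pd0 > 0, p_out >= 0, pd0 > p_out)
  structure(list(zc = zc, rp = rp, c_art = c_art, pd0 = pd0,
                 p_out = p_out),
            class = "afterload_params")
}

#' Simulation configuration
#'
#' @param fs output sampling rate, Hz (>= 100). Default 250.
#' @param n_beats number of steady-state beats to emit.
#' @param noise_sd additive white-noise SD on the pressure channels, mmHg.
#' @param resp_amp amplitude of a sinusoidal respiratory baseline
#'   modulation added to pressures, mmHg.
#' @param resp_rate respiratory rate, Hz.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @param oversample internal fixed-step integration runs at
#'   `oversample * fs`; emitted samples are taken on the output grid.
#' @param n_transient minimum number of charging beats discarded before
#'   emitting; the simulator keeps discarding beats until the
#'   beat-boundary state is periodic (relative change below `tol_periodic`),
#'   up to `max_transient`.
#' @param tol_periodic relative tolerance on the beat-boundary windkessel
#'   pressure for declaring a periodic steady state.
#' @param max_transient maximum charging beats; exceeding it is an error
#'   (non-convergent periodic state).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(fs = 250, n_beats = 15, noise_sd = 0,
                       resp_amp = 0, resp_rate = 0.25, seed = 1L,
                       oversample = 10L, n_transient = 5L,
                       tol_periodic = 1e-10, max_transient = 500L) {
  stopifnot(fs >= 100, n_beats >= 1, noise_sd >= 0, resp_amp >= 0,
            oversample >= 2, n_transient >= 0, tol_periodic > 0,
            max_transient >= n_transient)
  structure(list(fs = fs, n_beats = n_beats, noise_sd = noise_sd,
                 resp_amp = resp_amp, resp_rate = resp_rate,
                 seed = as.integer(seed),
                 oversample = as.integer(oversample),
                 n_transient = as.integer(n_transient),
                 tol_periodic = tol_periodic,
                 max_transient = as.integer(max_transient)),
            class = "sim_config")
}

# raised-cosine activation, a(t_peak) = 1, zero outside the rise/fall span
activation <- function(s, p) {
  a <- numeric(length(s))
  rise <- s >= (p$t_peak - p$rise_w) & s <= p$t_peak
  fall <- s > p$t_peak & s <= (p$t_peak + p$fall_w)
  a[rise] <- 0.5 * (1 - cos(pi * (s[rise] - p$t_peak + p$rise_w) / p$rise_w))
  a[fall] <- 0.5 * (1 + cos(pi * (s[fall] - p$t_peak) / p$fall_w))
  a
}

#' Simulate RV/PA pressure and flow beats
#'
#' Integrates a time-varying elastance ventricle ejecting through a
#' diode valve into a three-element windkessel. The ventricle refills to
#' `ved` over the last 12% of each cycle along a smooth raised-cosine
#' volume ramp (the valve is closed by then, so outflow conservation per
#' beat is unaffected and the pressure trace stays continuous).
#' Fixed-step explicit Euler at `oversample * fs`. Charging beats are
#' discarded until the beat-boundary state is periodic (at least
#' `n_transient`, at most `max_transient`, tolerance `tol_periodic`);
#' emitted traces are the internal solution on the output grid. Ground truth (isovolumic peak pressure
#' and per-beat stroke volume) is stored alongside the traces.
#'
#' @param params [elastance_params()].
#' @param afterload [afterload_params()].
#' @param config [sim_config()].
#' @param clamp_valve if TRUE the valve is held shut (isovolumic beats).
#' @return object of class `elastance_scenario`: waveforms `rvp`, `pap`,
#'   `flow`, `volume`, a `truth` data frame (one row per emitted beat:
#'   `pmax`, `sv`, `ves`, `onset_t`), the input parameter objects, and a
#'   `non_ejecting` flag.
#' @export
simulate_beats <- function(params, afterload, config,
                           clamp_valve = FALSE) {
  stopifnot(inherits(params, "elastance_params"),
            inherits(afterload, "afterload_params"),
            inherits(config, "sim_config"))
  p <- params; a <- afterload; cf <- config
  fs_in <- cf$fs * cf$oversample
  dt <- 1 / fs_in
  steps_per_beat <- round(p$t_beat * fs_in)

  s_in_beat <- (seq_len(steps_per_beat) - 1) * dt
  act <- activation(s_in_beat, p)
  e_of_s <- p$emin + (p$emax - p$emin) * act
  fill_start <- steps_per_beat - round(0.12 * steps_per_beat)
  fill_frac <- 0.5 * (1 - cos(pi * (fill_start:steps_per_beat - fill_start) /
                                (steps_per_beat - fill_start)))

  # advance one beat from state (v = ved at boundary, pd); optionally
  # record the internal traces
  one_beat <- function(pd, record = FALSE) {
    v <- p$ved
    if (record) plv <- pdv <- qv <- vv <- numeric(steps_per_beat)
    v_fill <- NA_real_; sv <- NA_real_; ves <- NA_real_
    for (i in seq_len(steps_per_beat)) {
      if (i == fill_start) {
        v_fill <- v; ves <- v; sv <- p$ved - v
      }
      if (i >= fill_start)           # raised-cosine refill to ved
        v <- v_fill + (p$ved - v_fill) * fill_frac[i - fill_start + 1]
      pv <- e_of_s[i] * (v - p$v0)
      q <- if (!clamp_valve && pv > pd) (pv - pd) / a$zc else 0
      if (record) { plv[i] <- pv; pdv[i] <- pd; qv[i] <- q; vv[i] <- v }
      v <- v - q * dt
      pd <- pd + (q - (pd - a$p_out) / a$rp) / a$c_art * dt
    }
    out <- list(pd = pd, sv = sv, ves = ves)
    if (record) { out$plv <- plv; out$pdv <- pdv; out$qv <- qv; out$vv <- vv }
    out
  }

  # charging phase: discard beats until the boundary state is periodic
  pd <- a$pd0
  n_tr <- 0L
  repeat {
    pd_prev <- pd
    st <- one_beat(pd)
    pd <- st$pd
    n_tr <- n_tr + 1L
    if (n_tr >= cf$n_transient &&
        abs(pd - pd_prev) <= cf$tol_periodic * max(1, abs(pd))) break
    if (n_tr >= cf$max_transient)
      stop(sprintf(
        "non-convergent periodic state after %d charging beats (boundary pressure still changing by %.3g mmHg)",
        n_tr, abs(pd - pd_prev)))
  }

  n_steps <- steps_per_beat * cf$n_beats
  plv <- pd_tr <- q_tr <- v_tr <- numeric(n_steps)
  sv_acc <- ves_acc <- numeric(cf$n_beats)
  for (b in seq_len(cf$n_beats)) {
    st <- one_beat(pd, record = TRUE)
    idx <- (b - 1) * steps_per_beat + seq_len(steps_per_beat)
    plv[idx] <- st$plv; pd_tr[idx] <- st$pdv
    q_tr[idx] <- st$qv; v_tr[idx] <- st$vv
    sv_acc[b] <- st$sv; ves_acc[b] <- st$ves
    pd <- st$pd
  }

  pap_in <- pd_tr + a$zc * q_tr      # proximal PA pressure

  # decimate: internal grid contains the output grid exactly
  keep <- seq(1, n_steps, by = cf$oversample)
  t_out <- (seq_along(keep) - 1) / cf$fs
  rvp_y <- plv[keep]; pap_y <- pap_in[keep]
  flow_y <- q_tr[keep]; vol_y <- v_tr[keep]

  if (cf$noise_sd > 0 || cf$resp_amp > 0) {
    with_seed(cf$seed, {
      resp <- cf$resp_amp * sin(2 * pi * cf$resp_rate * t_out)
      rvp_y <- rvp_y + resp + stats::rnorm(length(t_out), 0, cf$noise_sd)
      pap_y <- pap_y + resp + stats::rnorm(length(t_out), 0, cf$noise_sd)
    })
  }

  truth <- data.frame(
    beat = seq_len(cf$n_beats),
    pmax = p$emax * (p$ved - p$v0),
    sv = sv_acc,
    ves = ves_acc,
    onset_t = (seq_len(cf$n_beats) - 1) * p$t_beat
  )

  structure(list(
    params = p, afterload = a, config = cf,
    rvp = waveform(rvp_y, cf$fs, "rvp", "mmHg"),
    pap = waveform(pap_y, cf$fs, "pap", "mmHg"),
    flow = waveform(flow_y, cf$fs, "aof", "mL/s"),
    volume = waveform(vol_y, cf$fs, "vol", "mL"),
    truth = truth,
    clamp_valve = clamp_valve,
    non_ejecting = all(sv_acc < 1e-9)
  ), class = "elastance_scenario")
}

#' @export
print.elastance_scenario <- function(x, ...) {
  cat(sprintf(
    "<elastance_scenario> %d beats @ %g Hz, Emax %.2f mmHg/mL, HR %.0f%s\n",
    nrow(x$truth), x$config$fs, x$params$emax, x$params$hr,
    if (x$non_ejecting) " [non-ejecting]" else ""))
  invisible(x)
}

#' Isovolumic (clamped-valve) peak pressure oracle
#'
#' Peak pressure of a non-ejecting beat. Because activation peaks at 1
#' and the volume never changes in a clamped beat, this equals
#' `emax * (ved - v0)` in closed form. It is the ground-truth quantity
#' that the sine-fit Pmax of an ejecting beat approximates.
#'
#' @param params [elastance_params()].
#' @return peak isovolumic pressure, mmHg.
#' @export
clamp_isovolumic <- function(params) {
  stopifnot(inherits(params, "elastance_params"))
  params$emax * (params$ved - params$v0)
}

#' Design of a synthetic qPCR Ct table
#'
#' @param fold named numeric vector of true fold-changes (CTEPH vs
#'   control) per target gene; all > 0.
#' @param ref_genes names of the reference panel (true fold 1); default
#'   the three-gene panel actb/gapdh/ppia.
#' @param n_control,n_cteph samples per group (>= 2).
#' @param ct_base mean target Ct in the control group, cycles.
#' @param ct_sd replicate noise SD, cycles.
#' @param load_sd SD of the per-sample loading shift (added to every gene
#'   of a sample; removed by reference normalization), cycles.
#' @param seed integer seed.
#' @return object of class `ct_design`.
#' @export
ct_design <- function(fold, ref_genes = c("actb", "gapdh", "ppia"),
                      n_control = 9, n_cteph = 5, ct_base = 22,
                      ct_sd = 0.3, load_sd = 0.5, seed = 1L) {
  stopifnot(all(fold > 0), length(ref_genes) >= 1,
            n_control >= 2, n_cteph >= 2, ct_sd >= 0, load_sd >= 0)
  if (is.null(names(fold)))
    names(fold) <- paste0("gene", seq_along(fold))
  if (any(ref_genes %in% names(fold)))
    stop("reference genes must not appear among target genes")
  structure(list(fold = fold, ref_genes = ref_genes,
                 n_control = n_control, n_cteph = n_cteph,
                 ct_base = ct_base, ct_sd = ct_sd, load_sd = load_sd,
                 seed = as.integer(seed)),
            class = "ct_design")
}

#' Generate a synthetic qPCR Ct table with known fold-changes
#'
#' Ct values follow `ct = ct_base - log2(expression) + loading + noise`:
#' a gene with true fold-change f has Ct lower by log2(f) in the CTEPH
#' group; reference genes carry only the per-sample loading shift, so
#' delta-delta-Ct normalization removes it.
#'
#' @param design [ct_design()].
#' @return data frame of Ct records: `sample_id`, `group`, `gene`, `ct`.
#' @export
generate_ct_table <- function(design) {
  stopifnot(inherits(design, "ct_design"))
  d <- design
  groups <- c(rep("control", d$n_control), rep("CTEPH", d$n_cteph))
  ids <- sprintf("s%02d", seq_along(groups))
  genes <- c(d$ref_genes, names(d$fold))
  with_seed(d$seed, {
    load <- stats::rnorm(length(ids), 0, d$load_sd)
    recs <- expand.grid(sample_id = ids, gene = genes,
                        stringsAsFactors = FALSE)
    recs$group <- groups[match(recs$sample_id, ids)]
    f <- ifelse(recs$gene %in% d$ref_genes, 1,
                ifelse(recs$group == "CTEPH",
                       d$fold[recs$gene], 1))
    recs$ct <- d$ct_base - log2(f) + load[match(recs$sample_id, ids)] +
      stats::rnorm(nrow(recs), 0, d$ct_sd)
    recs[order(recs$sample_id, recs$gene),
         c("sample_id", "group", "gene", "ct")]
  })
}

#' Generate a synthetic rest/exercise cohort with ground truth
#'
#' Builds paired rest and exercise elastance scenarios per animal. The
#' control arm responds to exercise with a large rise in heart rate and
#' contractility (Emax) and a modest fall in peripheral resistance, so
#' simulated RV-PA coupling rises. The CTEPH arm has elevated peripheral
#' resistance at rest and a blunted contractility reserve, so coupling is
#' lower at rest and falls or stays flat with exercise.
#'
#' @param n_control,n_cteph animals per group (>= 1).
#' @param seed integer seed; per-animal parameter jitter and scenario
#'   seeds derive from it.
#' @param noise_sd pressure noise SD passed to each scenario, mmHg.
#' @param n_beats emitted beats per recording.
#' @param fs output sampling rate, Hz.
#' @return list with `meta` (data frame: `id`, `group`, `sex`, `bw`) and
#'   `scenarios` (named list; `scenarios[[id]]$rest` / `$exercise` are
#'   `elastance_scenario` objects), plus `truth` (data frame of the
#'   generative parameters per animal x condition).
#' @export
generate_cohort <- function(n_control = 7, n_cteph = 7, seed = 1L,
                            noise_sd = 0.5, n_beats = 15, fs = 250) {
  stopifnot(n_control >= 1, n_cteph >= 1)
  base <- list(
    control = list(
      rest     = list(hr = 136, emax = 0.60, rp = 0.45),
      exercise = list(hr = 235, emax = 1.10, rp = 0.38)
    ),
    CTEPH = list(
      rest     = list(hr = 131, emax = 0.95, rp = 1.15),
      exercise = list(hr = 211, emax = 1.10, rp = 1.10)
    )
  )
  groups <- c(rep("control", n_control), rep("CTEPH", n_cteph))
  ids <- sprintf("%s%02d", ifelse(groups == "control", "C", "P"),
                 unlist(lapply(c(n_control, n_cteph), seq_len)))
  with_seed(seed, {
    sex <- sample(c("M", "F"), length(ids), replace = TRUE)
    bw <- round(stats::rnorm(length(ids), 61, 3), 1)
    jit <- stats::rlnorm(length(ids) * 3, 0, 0.06)
    scen_seeds <- sample.int(.Machine$integer.max - 1L,
                             length(ids) * 2)
    meta <- data.frame(id = ids, group = groups, sex = sex, bw = bw,
                       stringsAsFactors = FALSE)
    scenarios <- list()
    truth <- NULL
    for (i in seq_along(ids)) {
      g <- groups[i]
      jhr <- jit[3 * i - 2]; jem <- jit[3 * i - 1]; jrp <- jit[3 * i]
      pair <- list()
      for (k in c(1, 2)) {
        cond <- c("rest", "exercise")[k]
        b <- base[[g]][[cond]]
        hr <- b$hr * jhr; emax <- b$emax * jem; rp <- b$rp * jrp
        par <- elastance_params(emax = emax, hr = hr)
        aft <- afterload_params(rp = rp)
        cfg <- sim_config(fs = fs, n_beats = n_beats,
                          noise_sd = noise_sd,
                          seed = scen_seeds[2 * (i - 1) + k])
        pair[[cond]] <- simulate_beats(par, aft, cfg)
        truth <- rbind(truth, data.frame(
          id = ids[i], group = g, condition = cond, hr = hr,
          emax = emax, rp = rp,
          pmax = clamp_isovolumic(par)))
      }
      scenarios[[ids[i]]] <- pair
    }
    list(meta = meta, scenarios = scenarios, truth = truth)
  })
}
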