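#' Body-weight indexed cardiac output and stroke volume
#'
#' Cardiac index corrects cardiac output for body weight:
#' `ci = 1000 * co / bw` (mL/min/kg); stroke volume index is
#' `svi = ci / hr` (mL/kg).
#'
#' @param co cardiac output, L/min.
#' @param bw body weight, kg.
#' @return cardiac index, mL/min/kg.
#' @export
cardiac_index <- function(co, bw) {
  stopifnot(all(co > 0), all(bw > 0))
  1000 * co / bw
}

#' @rdname cardiac_index
#' @param ci cardiac index, mL/min/kg.
#' @param hr heart rate, beats/min.
#' @return stroke volume index, mL/kg.
#' @export
stroke_volume_index <- function(ci, hr) {
  stopifnot(all(ci > 0), all(hr > 0))
  ci / hr
}

#' Total pulmonary and systemic vascular resistance indices
#'
#' `tpvri = mpap / ci` and `svri = maop / ci`, with `ci` expressed in
#' L/min/kg so that the indices come out in mmHg/(L/min/kg), the
#' convention under which a resting systemic value is of order 500-900.
#'
#' @param mpap mean pulmonary artery pressure, mmHg.
#' @param maop mean aortic pressure, mmHg.
#' @param ci cardiac index, L/min/kg.
#' @return data frame with `tpvri` and `svri`, mmHg/(L/min/kg).
#' @export
vascular_resistance_indices <- function(mpap, maop, ci) {
  stopifnot(all(ci > 0))
  data.frame(tpvri = mpap / ci, svri = maop / ci)
}

#' Stroke work
#'
#' Convention: `sw = mpap * sv` (mmHg mL). Mean PA pressure times
#' stroke volume; no right-atrial pressure term is subtracted (none is
#' measured by the pipeline), which is a declared convention rather
#' than a universal definition.
#'
#' @param mpap mean pulmonary artery pressure, mmHg.
#' @param sv stroke volume, mL.
#' @return stroke work, mmHg mL.
#' @export
stroke_work <- function(mpap, sv) {
  stopifnot(all(mpap > 0), all(sv >= 0))
  mpap * sv
}

#' Fulton index and weight-indexed ventricular masses
#'
#' Gravimetric hypertrophy metrics from necropsy weights: the Fulton
#' index RV/LV (g/g, LV including septum) plus RV and LV weights
#' indexed to body weight (g/kg).
#'
#' @param rvw RV free wall weight, g.
#' @param lvw LV + septum weight, g.
#' @param bw body weight, kg.
#' @return data frame with `rv_lv`, `rvw_bw`, `lvw_bw`.
#' @export
fulton_index <- function(rvw, lvw, bw) {
  stopifnot(all(rvw > 0), all(lvw > 0), all(bw > 0))
  data.frame(rv_lv = rvw / lvw, rvw_bw = rvw / bw, lvw_bw = lvw / bw)
}

#' Capillary density metrics
#'
#' Capillary density per unit area and the capillary-to-myocyte ratio
#' from morphometric counts.
#'
#' @param capillary_count capillaries counted in the field.
#' @param field_area field area, mm^2.
#' @param myocyte_count cardiomyocytes counted in the field; 0 yields an
#'   NA ratio with a warning.
#' @return data frame with `density_per_mm2` and
#'   `capillary_fiber_ratio`.
#' @export
capillary_metrics <- function(capillary_count, field_area,
                              myocyte_count) {
  stopifnot(all(capillary_count >= 0), all(field_area > 0),
            all(myocyte_count >= 0))
  ratio <- ifelse(myocyte_count > 0, capillary_count / myocyte_count,
                  NA_real_)
  if (any(myocyte_count == 0))
    warning("capillary/fiber ratio undefined for fields with zero myocytes")
  data.frame(density_per_mm2 = capillary_count / field_area,
             capillary_fiber_ratio = ratio)
}

#' Microsphere count from infused mass
#'
#' Number of embolization microspheres corresponding to a given mass,
#' `count = mass / (density * (4/3) pi (d/2)^3)`. Reported both raw and
#' rounded to the nearest 500, the granularity at which protocol doses
#' are quoted. Defaults: polyethylene spheres of density 1.13 g/cm^3
#' and nominal diameter 700 um (within the 600-710 um product band).
#'
#' @param mass_g infused mass, g.
#' @param density_g_cm3 sphere density, g/cm^3.
#' @param diameter_um sphere diameter, um.
#' @return data frame with `raw` and `rounded` counts.
#' @export
microsphere_count <- function(mass_g, density_g_cm3 = 1.13,
                              diameter_um = 700) {
  stopifnot(all(mass_g > 0), density_g_cm3 > 0, diameter_um > 0)
  r_cm <- diameter_um / 2 * 1e-4
  sphere_mass <- density_g_cm3 * (4 / 3) * pi * r_cm^3
  raw <- mass_g / sphere_mass
  data.frame(raw = raw, rounded = 500 * round(raw / 500))
}

#' Embolization protocol decision
#'
#' Encodes the induction protocol's decision rules. Within an infusion
#' session: stop when mPAP has reached 60 mmHg, or PaO2 has dropped to
#' 40 mmHg, or the 3 g daily microsphere maximum has been reached;
#' otherwise infuse again. At the weekly haemodynamic checks during the
#' four weeks after induction: re-embolization is scheduled only when
#' both mPAP < 25 mmHg and PaO2 > 70 mmHg; no infusions are scheduled
#' during the final five follow-up weeks (week index > 4).
#'
#' @param mpap mean pulmonary artery pressure, mmHg.
#' @param pao2 arterial PaO2, mmHg.
#' @param cumulative_today_g microspheres already infused today, g.
#' @param week_index week since induction (weekly-check phase only).
#' @param phase `"session"` (during an infusion session) or `"weekly"`
#'   (scheduled haemodynamic check).
#' @return one of `"infuse"`, `"stop_session"`,
#'   `"schedule_reembolization"`, `"no_action"`.
#' @export
embolization_decision <- function(mpap, pao2, cumulative_today_g = 0,
                                  week_index = 1,
                                  phase = c("session", "weekly")) {
  phase <- match.arg(phase)
  stopifnot(mpap > 0, pao2 > 0, cumulative_today_g >= 0)
  if (cumulative_today_g > 3)
    stop("inconsistent state: cumulative dose exceeds the 3 g daily maximum")
  if (phase == "session") {
    if (mpap >= 60 || pao2 <= 40 || cumulative_today_g >= 3)
      return("stop_session")
    return("infuse")
  }
  if (week_index > 4) return("no_action")
  if (mpap < 25 && pao2 > 70) return("schedule_reembolization")
  "no_action"
}
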