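# Indirect calorimetry (Brouwer stoichiometry), guarded ratios, efficiency,
# mood-state indices and pacing.

#' Substrate oxidation from gas exchange (Brouwer stoichiometry)
#'
#' Fat and carbohydrate oxidation rates from whole-body VO2 and VCO2 using
#' the Brouwer stoichiometric coefficients
#' `fat = 1.695 * VO2 - 1.701 * VCO2` and
#' `cho = 4.170 * VCO2 - 2.965 * VO2` (g/min, gas volumes in L/min).
#' Negative rates, which arise when the respiratory exchange ratio (RER =
#' VCO2/VO2) falls outside the physiological 0.7-1.0 substrate range, are
#' clipped to zero; the unclipped values and an out-of-range note are
#' retained. Energy expenditure uses caloric equivalents per litre of O2
#' and CO2 (defaults 3.820 and 1.150 kcal/L).
#'
#' @param vo2 Oxygen uptake, L/min (> 0).
#' @param vco2 Carbon-dioxide output, L/min (>= 0).
#' @param fat_o2,fat_co2,cho_co2,cho_o2 Stoichiometric coefficients.
#' @param kcal_o2,kcal_co2 Caloric equivalents, kcal per L.
#' @return A list: `fat_gmin`, `cho_gmin` (clipped at 0), `fat_raw`,
#'   `cho_raw`, `rer` (unclipped), `ee_kcal_min`, `ee_watt`,
#'   `rer_out_of_range` (logical).
#' @examples
#' brouwer_substrates(2.0, 2.0)   # RER 1.0: pure carbohydrate
#' brouwer_substrates(2.0, 1.4)   # RER 0.7: pure fat
#' @export
brouwer_substrates <- function(vo2, vco2,
                               fat_o2 = 1.695, fat_co2 = 1.701,
                               cho_co2 = 4.170, cho_o2 = 2.965,
                               kcal_o2 = 3.820, kcal_co2 = 1.150) {
  if (any(vo2 <= 0)) stop("vo2 must be > 0", call. = FALSE)
  if (any(vco2 < 0)) stop("vco2 must be >= 0", call. = FALSE)
  fat_raw <- fat_o2 * vo2 - fat_co2 * vco2
  cho_raw <- cho_co2 * vco2 - cho_o2 * vo2
  rer <- vco2 / vo2
  ee_kcal_min <- kcal_o2 * vo2 + kcal_co2 * vco2
  list(fat_gmin = pmax(fat_raw, 0), cho_gmin = pmax(cho_raw, 0),
       fat_raw = fat_raw, cho_raw = cho_raw, rer = rer,
       ee_kcal_min = ee_kcal_min,
       ee_watt = ee_kcal_min * 4184 / 60,
       rer_out_of_range = rer < 0.7 | rer > 1.0)
}

#' Guarded ratio
#'
#' Division that never emits a silent infinity: a non-positive or missing
#' denominator yields `NA` plus a flag.
#'
#' @param num,den Numerics (recycled).
#' @return list with `value` and `invalid` (logical).
#' @export
guarded_ratio <- function(num, den) {
  bad <- is.na(den) | den <= 0
  value <- ifelse(bad, NA_real_, num / den)
  list(value = value, invalid = bad)
}

#' Derived efficiency and exertion ratios
#'
#' Session-level exploratory ratios: oxygen cost of power (VO2/W) and its
#' inverse (`economy_w_per_lmin`, both emitted since "cycling economy" is
#' used with either orientation in the field), power per heart beat, and
#' power, heart rate and lactate per unit RPE. All divisions are guarded;
#' an invalid denominator yields `NA` with a flag.
#'
#' @param power_w Mean power, W.
#' @param hr_bpm Mean heart rate, bpm.
#' @param vo2_lmin Mean oxygen uptake, L/min.
#' @param rpe Borg 6-20 rating.
#' @param lactate Blood lactate, mmol/L.
#' @return data.frame of ratios with a parallel `<name>_invalid` flag for
#'   each.
#' @export
efficiency_ratios <- function(power_w = NA_real_, hr_bpm = NA_real_,
                              vo2_lmin = NA_real_, rpe = NA_real_,
                              lactate = NA_real_) {
  parts <- list(
    vo2_per_w = guarded_ratio(vo2_lmin, power_w),
    economy_w_per_lmin = guarded_ratio(power_w, vo2_lmin),
    w_per_hr = guarded_ratio(power_w, hr_bpm),
    w_per_rpe = guarded_ratio(power_w, rpe),
    hr_per_rpe = guarded_ratio(hr_bpm, rpe),
    lactate_per_rpe = guarded_ratio(lactate, rpe)
  )
  cols <- list()
  for (nm in names(parts)) {
    cols[[nm]] <- parts[[nm]]$value
    cols[[paste0(nm, "_invalid")]] <- parts[[nm]]$invalid
  }
  as.data.frame(cols)
}

#' Gross efficiency
#'
#' Mechanical power divided by metabolic power (from gas exchange via
#' [brouwer_substrates()] energy expenditure converted to W), as a
#' percentage.
#'
#' @param power_w Mechanical power, W.
#' @param vo2,vco2 Gas exchange, L/min.
#' @param ... Passed to [brouwer_substrates()] (coefficient overrides).
#' @return Gross efficiency in percent (`NA` with a warning if metabolic
#'   power is non-positive).
#' @export
gross_efficiency <- function(power_w, vo2, vco2, ...) {
  met <- brouwer_substrates(vo2, vco2, ...)$ee_watt
  g <- guarded_ratio(power_w, met)
  100 * g$value
}

#' POMS-derived mood indices
#'
#' Total Mood Disturbance
#' `TMD = tension + depression + anger + fatigue + confusion - vigor`
#' and the Energy Index `EI = vigor - fatigue` from the six POMS subscale
#' scores.
#'
#' @param tension,depression,anger,fatigue,confusion,vigor Subscale scores.
#' @return list with `tmd` and `ei`.
#' @examples
#' poms_derived(10, 10, 10, 10, 10, 10)   # tmd 40, ei 0
#' @export
poms_derived <- function(tension, depression, anger, fatigue, confusion,
                         vigor) {
  vals <- list(tension = tension, depression = depression, anger = anger,
               fatigue = fatigue, confusion = confusion, vigor = vigor)
  for (nm in names(vals))
    if (is.null(vals[[nm]]) || length(vals[[nm]]) == 0L || is.na(vals[[nm]]))
      stop("missing POMS subscale: ", nm, call. = FALSE)
  list(tmd = tension + depression + anger + fatigue + confusion - vigor,
       ei = vigor - fatigue)
}

#' Initial pacing target for the first HIIT interval
#'
#' The first interval of the first session is paced at 117% of the power
#' at the individually determined lactate threshold; afterwards pacing is
#' free with the best previous mean power as target.
#'
#' @param lactate_threshold_power_w Lactate-threshold power, W (> 0).
#' @return Target power, W.
#' @examples
#' initial_pacing_target(100) # 117
#' @export
initial_pacing_target <- function(lactate_threshold_power_w) {
  if (any(lactate_threshold_power_w <= 0))
    stop("lactate threshold power must be > 0", call. = FALSE)
  1.17 * lactate_threshold_power_w
}
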