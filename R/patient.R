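#' Create a patient record
#'
#' A patient record holds the routine clinical measures needed to
#' personalize an aortic pressure waveform: demographics, brachial
#' pressures, heart rate and the imaging-derived left-ventricular mass.
#'
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @param height Height in cm.
#' @param weight Weight in kg.
#' @param hr Heart rate in beats/min.
#' @param p_sys Brachial systolic pressure in mmHg.
#' @param p_dia Brachial diastolic pressure in mmHg.
#' @param lv_mass Left-ventricular mass in grams.
#' @param state Physiological state, `"rest"` or `"stress"`.
#' @param id Optional patient identifier.
#'
#' @return A one-row tibble with the validated record.
#' @examples
#' patient_record(age = 60, sex = "male", height = 175, weight = 75,
#'                hr = 70, p_sys = 120, p_dia = 80, lv_mass = 160)
#' @export
patient_record <- function(age, sex, height, weight, hr, p_sys, p_dia,
                           lv_mass, state = "rest", id = "P1") {
  rec <- tibble(
    id = as.character(id), age = as.numeric(age), sex = as.character(sex),
    height = as.numeric(height), weight = as.numeric(weight),
    hr = as.numeric(hr), p_sys = as.numeric(p_sys),
    p_dia = as.numeric(p_dia), lv_mass = as.numeric(lv_mass),
    state = as.character(state)
  )
  validate_patients(rec)
}

#' Validate a tibble of patient records
#'
#' Checks field presence, ranges and pressure ordering for every row.
#'
#' @param patients A data frame with the columns of [patient_record()].
#' @return The input as a tibble, invisibly validated.
#' @export
validate_patients <- function(patients) {
  patients <- as_tibble(patients)
  required <- c("age", "sex", "height", "weight", "hr", "p_sys", "p_dia",
                "lv_mass", "state")
  missing <- setdiff(required, names(patients))
  if (length(missing) > 0) {
    stop_validation(paste0("patient record is missing field(s): ",
                           paste(missing, collapse = ", ")))
  }
  if (!"id" %in% names(patients)) {
    patients$id <- paste0("P", seq_len(nrow(patients)))
  }
  with(patients, {
    if (!all(sex %in% c("male", "female"))) {
      stop_validation("sex must be 'male' or 'female'")
    }
    if (!all(state %in% c("rest", "stress"))) {
      stop_validation("state must be 'rest' or 'stress'")
    }
    if (!all(is.finite(age) & age > 0)) stop_validation("age must be > 0")
    if (!all(is.finite(hr) & hr > 20 & hr < 250)) {
      stop_validation("hr must lie in (20, 250) beats/min")
    }
    if (!all(is.finite(p_sys) & is.finite(p_dia) & p_dia > 0 &
               p_sys > p_dia)) {
      stop_validation("pressures must satisfy p_sys > p_dia > 0")
    }
    for (f in c("height", "weight", "lv_mass")) {
      v <- get(f)
      if (!all(is.finite(v) & v > 0)) {
        stop_validation(paste0(f, " must be positive"))
      }
    }
  })
  patients
}

#' Diastolic/systolic time ratio from heart rate
#'
#' Quadratic regression of the diastolic-to-systolic duration ratio on
#' heart rate, fitted to stress-echo timing data.
#'
#' @param hr Heart rate in beats/min, in (20, 250). Vectorized.
#' @return The dimensionless ratio of diastolic to systolic duration.
#' @examples
#' diastolic_systolic_ratio(60) # 1.79332
#' @export
diastolic_systolic_ratio <- function(hr) {
  if (!all(is.finite(hr) & hr > 20 & hr < 250)) {
    stop_validation("hr must lie in (20, 250) beats/min")
  }
  2.537e-4 * hr^2 - 0.057 * hr + 4.3
}

#' Systolic duration (time of the dicrotic notch)
#'
#' The heartbeat period T = 60/HR is split into systole and diastole by the
#' ratio of [diastolic_systolic_ratio()]: T_notch = T / (1 + R_ds). Systole
#' is taken to start at t = 0, so T_notch is also the notch time.
#'
#' @inheritParams diastolic_systolic_ratio
#' @return Systolic duration in seconds. Vectorized.
#' @export
systolic_duration <- function(hr) {
  (60 / hr) / (1 + diastolic_systolic_ratio(hr))
}

#' Body surface area (Du Bois)
#'
#' @param height Height in cm.
#' @param weight Weight in kg.
#' @return Body surface area in m^2.
#' @export
du_bois_bsa <- function(height, weight) {
  if (!all(is.finite(height) & height > 0 & is.finite(weight) & weight > 0)) {
    stop_validation("height and weight must be positive")
  }
  0.007184 * height^0.725 * weight^0.425
}

#' Left-ventricular mass indexed to body surface area
#'
#' @param lv_mass Left-ventricular mass in grams.
#' @inheritParams du_bois_bsa
#' @return Indexed mass in g/m^2.
#' @export
lv_indexed_mass <- function(lv_mass, height, weight) {
  if (!all(is.finite(lv_mass) & lv_mass > 0)) {
    stop_validation("lv_mass must be positive")
  }
  lv_mass / du_bois_bsa(height, weight)
}

#' Isovolumic relaxation time
#'
#' Double regression: IVRT at the reference age of 54 years is linear in
#' left-ventricular indexed mass, then shifted by 0.412 ms per year of age
#' away from 54 (the slope of the healthy-population IVRT-vs-age line).
#'
#' @param age Age in years.
#' @param lvim Left-ventricular indexed mass in g/m^2.
#' @return IVRT in seconds. Vectorized.
#' @examples
#' ivrt(54, 100) # 78.15 ms
#' @export
ivrt <- function(age, lvim) {
  if (!all(is.finite(age) & age > 0 & is.finite(lvim) & lvim > 0)) {
    stop_validation("age and lvim must be positive")
  }
  (0.267 * lvim + 51.45 + 0.412 * (age - 54)) / 1000
}

#' Augmentation index from demographics
#'
#' Sex-specific polynomial in age, heart rate and height giving the
#' augmentation index, i.e. the augmentation pressure as a percentage of
#' central pulse pressure.
#'
#' @param sex `"male"` or `"female"`. Vectorized with the other arguments.
#' @param age Age in years.
#' @param hr Heart rate in beats/min.
#' @param height Height in cm.
#' @return Augmentation index in percent (may be negative for young, tall
#'   subjects; see [augmentation_pressure()]).
#' @export
augmentation_index <- function(sex, age, hr, height) {
  if (!all(sex %in% c("male", "female"))) {
    stop_validation("sex must be 'male' or 'female'")
  }
  ifelse(sex == "male",
         79.70 + 0.63 * age - 0.002 * age^2 - 0.28 * hr - 0.39 * height,
         56.28 + 0.90 * age - 0.005 * age^2 - 0.34 * hr - 0.24 * height)
}

#' Augmentation pressure
#'
#' The late-systolic pressure boost contributed by the reflected arterial
#' wave: the augmentation index applied to the central pulse pressure
#' `p_peak - p_min`. A negative index is clamped to zero with a warning.
#'
#' @inheritParams augmentation_index
#' @param p_peak Aortic peak systolic pressure in mmHg.
#' @param p_min Aortic minimum diastolic pressure in mmHg.
#' @return Augmentation pressure in mmHg (non-negative).
#' @export
augmentation_pressure <- function(sex, age, hr, height, p_peak, p_min) {
  if (!all(p_peak > p_min)) stop_validation("p_peak must exceed p_min")
  aix <- augmentation_index(sex, age, hr, height)
  if (any(aix < 0)) {
    warn("negative augmentation index clamped to 0")
    aix <- pmax(aix, 0)
  }
  (aix / 100) * (p_peak - p_min)
}

#' Dicrotic notch pressure from mean pressure
#'
#' Linear regression of the notch pressure on the simplified mean aortic
#' pressure `0.5 * (p_peak + p_min)`.
#'
#' @inheritParams augmentation_pressure
#' @return Notch pressure in mmHg.
#' @examples
#' notch_pressure(110, 80) # 98.2075
#' @export
notch_pressure <- function(p_peak, p_min) {
  if (!all(p_peak > p_min)) stop_validation("p_peak must exceed p_min")
  1.1667 * 0.5 * (p_peak + p_min) - 12.629
}

#' Derive all waveform timing and pressure parameters
#'
#' Computes, for each patient record, every key instant and pressure value
#' of the four-phase aortic waveform: period, shoulder/peak/incisura/notch
#' times, IVRT, IVCT (fixed at 0.05 s), and the corresponding pressures.
#' The brachial-to-aortic transfer uses `p_peak = p_sys - 10` mmHg for men
#' and `- 8` mmHg for women; `p_min = p_dia`.
#'
#' @param patients A tibble of patient records (see [patient_record()]).
#' @return A tibble with one row per patient: the input columns plus
#'   `t_period`, `t_sh`, `t_peak`, `t_i`, `t_notch`, `ivrt`, `ivct` (s) and
#'   `p_min`, `p_peak`, `delta_p`, `p_sh`, `p_i`, `p_notch`, `p_mean` (mmHg).
#' @examples
#' patient_record(60, "male", 175, 75, 70, 120, 80, 160) |>
#'   derive_waveform_params()
#' @export
derive_waveform_params <- function(patients) {
  patients <- validate_patients(patients)
  out <- dplyr::mutate(
    patients,
    t_period = 60 / .data$hr,
    t_notch = systolic_duration(.data$hr),
    t_sh = .data$t_notch / 3,
    t_peak = .data$t_notch / 2,
    ivrt = ivrt(.data$age,
                lv_indexed_mass(.data$lv_mass, .data$height, .data$weight)),
    ivct = 0.05,
    t_i = .data$t_notch - .data$ivrt,
    p_min = .data$p_dia,
    p_peak = .data$p_sys - ifelse(.data$sex == "male", 10, 8),
    delta_p = augmentation_pressure(.data$sex, .data$age, .data$hr,
                                    .data$height, .data$p_peak, .data$p_min),
    p_sh = .data$p_peak - .data$delta_p,
    p_mean = 0.5 * (.data$p_peak + .data$p_min),
    p_notch = notch_pressure(.data$p_peak, .data$p_min)
  )
  # incisura pressure from the phase-II parabola evaluated at t_i
  a2 <- (out$p_sh - out$p_peak) / (out$t_sh - out$t_peak)^2
  out$p_i <- a2 * (out$t_i - out$t_peak)^2 + out$p_peak
  check_timing_order(out)
  out
}

# Assert the timing chain 0 < t_sh < t_peak < t_i < t_notch < T - ivct < T
check_timing_order <- function(wp) {
  for (i in seq_len(nrow(wp))) {
    r <- wp[i, ]
    if (r$ivrt >= r$t_notch / 2) {
      stop_validation(sprintf(
        "IVRT (%.4f s) must be < t_notch/2 (%.4f s): timings would be non-ordered (t_i <= t_peak)",
        r$ivrt, r$t_notch / 2))
    }
    chain <- c(0, r$t_sh, r$t_peak, r$t_i, r$t_notch,
               r$t_period - r$ivct, r$t_period)
    names(chain) <- c("0", "t_sh", "t_peak", "t_i", "t_notch",
                      "T - ivct", "T")
    bad <- which(diff(chain) <= 0)
    if (length(bad) > 0) {
      stop_validation(sprintf(
        "timing order violated for patient %s: %s >= %s",
        r$id, names(chain)[bad[1]], names(chain)[bad[1] + 1]))
    }
    if (!(r$p_min < r$p_sh && r$p_sh <= r$p_peak)) {
      stop_validation(sprintf(
        "pressure order violated for patient %s: need p_min < p_sh <= p_peak",
        r$id))
    }
  }
  invisible(wp)
}
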