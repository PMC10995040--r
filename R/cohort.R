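# Reproducible synthetic inputs: paired rest/stress measure sets with
# planted gross outliers, and plausible patient records spanning the
# target population (adults over 40 undergoing functional CAD testing).
# All randomness flows from the single seed in the cohort spec.

#' Specification for a synthetic cohort
#'
#' Defines the study conditions for generated data: the true rest-to-stress
#' mapping, per-quantity measurement-noise standard deviations, the rate
#' and magnitude of gross outliers, and the resting ranges from which
#' patient covariates are drawn.
#'
#' @param n Number of paired records per quantity.
#' @param seed Integer seed; the only source of randomness.
#' @param truth True mapping coefficients (default: the shipped clinical
#'   coefficients).
#' @param noise_sd Named numeric: measurement-noise SD per quantity, in the
#'   quantity's units.
#' @param outlier_rate Fraction of records planted as gross outliers.
#' @param outlier_magnitude Outlier shift, in multiples of the noise SD.
#' @param ranges Named list of `c(min, max)` resting ranges per patient
#'   field.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 75, seed = 1,
                        truth = default_stress_map(),
                        noise_sd = c(hr = 8, p_sys = 9, p_dia = 7),
                        outlier_rate = 0.1, outlier_magnitude = 20,
                        ranges = list(
                          age = c(40, 80), hr = c(55, 90),
                          p_sys = c(100, 160), p_dia = c(60, 100),
                          height = c(150, 195), weight = c(50, 110),
                          lv_mass = c(100, 220)
                        )) {
  if (n < 4) stop_validation("n must be >= 4")
  if (outlier_rate < 0 || outlier_rate > 0.3) {
    stop_validation("outlier_rate must lie in [0, 0.3]")
  }
  if (any(vapply(ranges, function(r) r[1] >= r[2] || r[1] <= 0,
                 logical(1)))) {
    stop_validation("ranges must be positive with min < max")
  }
  structure(list(n = n, seed = as.integer(seed), truth = truth,
                 noise_sd = noise_sd, outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude, ranges = ranges),
            class = "cohort_spec")
}

# deterministic sub-seed per task, kept within 32-bit integer range
sub_seed <- function(seed, offset) (seed * 7919L + offset) %% 2147483647L

#' Generate paired rest/stress measures for one quantity
#'
#' Resting values are sampled uniformly over the range in `spec`; stress values
#' follow the true linear mapping plus Gaussian noise; a Bernoulli subset
#' is additionally shifted by `+/- outlier_magnitude * noise_sd` to emulate
#' unreliable clinical records.
#'
#' @param spec A [cohort_spec()].
#' @param quantity One of `"hr"`, `"p_sys"`, `"p_dia"`.
#' @return A tibble with columns `quantity`, `x_rest`, `x_stress`,
#'   `is_outlier`.
#' @export
generate_paired_measures <- function(spec, quantity = c("hr", "p_sys", "p_dia")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(spec, "cohort_spec"))
  qoff <- c(hr = 1L, p_sys = 2L, p_dia = 3L)[[quantity]]
  tr <- spec$truth[spec$truth$quantity == quantity, ]
  sd_q <- spec$noise_sd[[quantity]]
  rng <- spec$ranges[[quantity]]
  with_local_seed(sub_seed(spec$seed, qoff), {
    x_rest <- stats::runif(spec$n, rng[1], rng[2])
    x_stress <- tr$alpha * x_rest + tr$beta + stats::rnorm(spec$n, 0, sd_q)
    is_out <- stats::runif(spec$n) < spec$outlier_rate
    shift_sign <- sample(c(-1, 1), spec$n, replace = TRUE)
    x_stress <- x_stress +
      is_out * shift_sign * spec$outlier_magnitude * sd_q
    tibble(quantity = quantity, x_rest = x_rest, x_stress = x_stress,
           is_outlier = is_out)
  })
}

#' Generate paired measures for all three quantities
#'
#' @inheritParams generate_paired_measures
#' @return A tibble stacking [generate_paired_measures()] for `hr`,
#'   `p_sys`, `p_dia`.
#' @export
generate_paired_dataset <- function(spec) {
  dplyr::bind_rows(lapply(c("hr", "p_sys", "p_dia"),
                          function(q) generate_paired_measures(spec, q)))
}

#' Generate one synthetic patient record
#'
#' Fields are sampled uniformly within the ranges in `spec`; the record is
#' validated and its waveform parameters are derived once to guarantee the
#' timing-order invariants hold.
#'
#' @inheritParams generate_paired_measures
#' @param index Patient index; together with the seed it fully determines
#'   the record.
#' @return A one-row patient tibble (state `"rest"`).
#' @export
generate_patient <- function(spec, index = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  r <- spec$ranges
  rec <- with_local_seed(sub_seed(spec$seed, 1000L + as.integer(index)), {
    repeat_draw <- function() {
      p_dia <- stats::runif(1, r$p_dia[1], r$p_dia[2])
      p_sys <- stats::runif(1, max(r$p_sys[1], p_dia + 20), r$p_sys[2])
      patient_record(
        age = stats::runif(1, r$age[1], r$age[2]),
        sex = sample(c("male", "female"), 1),
        height = stats::runif(1, r$height[1], r$height[2]),
        weight = stats::runif(1, r$weight[1], r$weight[2]),
        hr = stats::runif(1, r$hr[1], r$hr[2]),
        p_sys = p_sys, p_dia = p_dia,
        lv_mass = stats::runif(1, r$lv_mass[1], r$lv_mass[2]),
        id = paste0("S", index)
      )
    }
    repeat_draw()
  })
  wp <- tryCatch(derive_waveform_params(rec), error = function(e) {
    stop_validation(paste0("generated record ", rec$id,
                           " violates waveform timing invariants: ",
                           conditionMessage(e)))
  })
  rec
}

#' Generate a cohort of synthetic patients
#'
#' @inheritParams generate_paired_measures
#' @param n Number of patients.
#' @return A tibble with one row per patient.
#' @export
generate_cohort <- function(spec, n = spec$n) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) generate_patient(spec, i)))
}
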