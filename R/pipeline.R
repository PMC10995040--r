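# Configuration, file I/O and the end-to-end pipeline:
# patient -> waveforms -> stress mapping -> dilation -> resting calibration
# -> stress conductances -> beat simulation -> FFR/MBF report.

#' Read / write a patient record as JSON
#'
#' Field names and units are exactly those of [patient_record()]; no unit
#' inference is performed.
#'
#' @param path File path.
#' @return `read_patient_json()` returns a validated one-row tibble.
#' @export
read_patient_json <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("age", "sex", "height", "weight", "hr", "p_sys", "p_dia",
                "lv_mass")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop_validation(paste0("patient JSON ", path, " is missing field(s): ",
                           paste(missing, collapse = ", ")))
  }
  patient_record(age = x$age, sex = x$sex, height = x$height,
                 weight = x$weight, hr = x$hr, p_sys = x$p_sys,
                 p_dia = x$p_dia, lv_mass = x$lv_mass,
                 state = x$state %||% "rest", id = x$id %||% "P1")
}

#' @rdname read_patient_json
#' @param patient A one-row patient tibble.
#' @export
write_patient_json <- function(patient, path) {
  patient <- validate_patients(patient)
  jsonlite::write_json(as.list(patient[1, ]), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write paired rest-stress measures as CSV
#'
#' Columns: `quantity`, `x_rest`, `x_stress`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_pairs_csv <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("quantity", "x_rest", "x_stress")
  if (!all(req %in% names(df))) {
    stop_validation(paste0("pairs CSV ", path, " must have header columns: ",
                           paste(req, collapse = ", ")))
  }
  as_tibble(df)
}

#' @rdname read_pairs_csv
#' @param pairs A tibble of paired measures.
#' @export
write_pairs_csv <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sampled pressure waveform as CSV
#'
#' Two columns `time_s,pressure_mmHg`, header row, full double precision,
#' POSIX newlines.
#'
#' @param curve A `piecewise_pressure`.
#' @param path Output path.
#' @param dt Sampling step in seconds.
#' @export
write_waveform_csv <- function(curve, path, dt = 1e-3) {
  df <- sample_pressure(curve, dt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("time_s,pressure_mmHg", con, sep = "\n")
  writeLines(paste(format(df$time_s, digits = 17, trim = TRUE),
                   format(df$pressure_mmHg, digits = 17, trim = TRUE),
                   sep = ","), con, sep = "\n")
  invisible(path)
}

#' @rdname write_waveform_csv
#' @return `read_waveform_csv()` returns the sampled tibble.
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df), c("time_s", "pressure_mmHg"))) {
    stop_validation(paste0("waveform CSV ", path,
                           " must have header time_s,pressure_mmHg"))
  }
  as_tibble(df)
}

#' Read / write a coronary tree as CSV
#'
#' Segments CSV columns: `segment_id,parent_id,length_m,radius_m,territory`
#' (empty `parent_id` for a root). Stenoses CSV columns:
#' `segment_id,radius_reduction_frac,length_frac`.
#'
#' @param path Segments CSV path.
#' @param stenoses_path Optional stenoses CSV path.
#' @return A [coronary_tree()].
#' @export
read_tree_csv <- function(path, stenoses_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  st <- if (!is.null(stenoses_path)) {
    utils::read.csv(stenoses_path, stringsAsFactors = FALSE)
  } else NULL
  coronary_tree(df, stenoses = st)
}

#' @rdname read_tree_csv
#' @param tree A `coronary_tree`.
#' @export
write_tree_csv <- function(tree, path, stenoses_path = NULL) {
  utils::write.csv(tree$segments, path, row.names = FALSE, quote = FALSE)
  if (!is.null(stenoses_path) && !is.null(tree$stenoses)) {
    utils::write.csv(tree$stenoses, stenoses_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

# metadata block attached to every written report
run_metadata <- function(config, seed) {
  # no timestamp: identical config + seed must reproduce byte-identical output
  list(package = "coroflow",
       version = as.character(utils::packageVersion("coroflow")),
       config_hash = rlang::hash(config),
       seed = seed)
}

#' Run the full prediction pipeline for one patient
#'
#' Executes, in order: waveform-parameter derivation at rest, rest-to-
#' stress mapping, hyperemic waveform construction (aortic + effective),
#' epicardial dilation, blinded resting calibration of the microvascular
#' conductances against the resting inflow target, stress scaling of the
#' conductances, one coupled cardiac cycle under the hyperemic effective
#' pressure, and FFR/MBF reporting.
#'
#' @param patient A one-row resting patient tibble (or a path to a patient
#'   JSON file).
#' @param tree A [coronary_tree()]; default healthy surrogate.
#' @param grid A [darcy_grid()]; default 20 x 20 x 10 slab of 2 mm voxels.
#' @param params Base [darcy_params()].
#' @param coeffs Stress-mapping coefficients.
#' @param dt Beat time step, s.
#' @param target_inflow Resting calibration target, mL min^-1 g^-1.
#' @param dilation_factor Hyperemic radial dilation of the tree.
#' @param stress_conductance_factor Hyperemic multiplier of the
#'   microvascular conductances.
#' @param out_dir Optional directory: if given, all intermediate artifacts
#'   (waveform CSVs, stress record JSON, summary JSON) are written there.
#' @param seed Seed recorded in the metadata (the pipeline itself is
#'   deterministic).
#' @return A list of class `coroflow_run`: the summary (landmark FFR, mean
#'   MBF, per-beat inflow, calibration lambda), all intermediate objects,
#'   and run metadata.
#' @export
run_pipeline <- function(patient, tree = default_coronary_tree(),
                         grid = darcy_grid(20, 20, 10, h = 2e-3),
                         params = darcy_params(),
                         coeffs = default_stress_map(), dt = 1e-3,
                         target_inflow = 1.0, dilation_factor = 1.225,
                         stress_conductance_factor = 4,
                         out_dir = NULL, seed = 1L) {
  if (is.character(patient)) patient <- read_patient_json(patient)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }
  config <- list(patient = as.list(patient[1, ]), dt = dt,
                 target_inflow = target_inflow,
                 dilation_factor = dilation_factor,
                 stress_conductance_factor = stress_conductance_factor,
                 grid = unclass(grid), params = unclass(params))

  wp_rest <- stage("derive_waveform_params", derive_waveform_params(patient))
  par_rest <- stage("build_aortic_waveform", build_aortic_waveform(wp_rest))
  peff_rest <- stage("build_effective_waveform",
                     build_effective_waveform(par_rest))
  stress <- stage("rest_to_stress", rest_to_stress(patient, coeffs))
  wp_stress <- stage("derive_waveform_params", derive_waveform_params(stress))
  par_stress <- stage("build_aortic_waveform", build_aortic_waveform(wp_stress))
  peff_stress <- stage("build_effective_waveform",
                       build_effective_waveform(par_stress))

  # resting driving pressure: time-average of the resting effective curve
  rest_drive <- mean(sample_pressure(peff_rest, 1e-3)$pressure_mmHg)
  cal <- stage("calibrate_rest",
               calibrate_rest(grid, params, tree, rest_drive,
                              target_inflow = target_inflow))
  tree_stress <- stage("dilate", dilate(tree, dilation_factor))
  params_stress <- stage("scale_to_stress",
                         scale_to_stress(cal$params,
                                         stress_conductance_factor))
  beat <- stage("run_beat",
                run_beat(tree_stress, peff_stress, grid, params_stress,
                         dt = dt))
  ffr <- stage("compute_ffr", compute_ffr(beat))
  mbf_mean <- beat$mean_mbf

  summary <- list(
    patient_id = patient$id,
    ffr_landmarks = as.list(ffr$landmarks),
    mean_mbf_ml_min_100g = mbf_mean,
    total_inflow_ml_beat = beat$total_inflow_ml_beat,
    diastolic_flow_fraction = diastolic_flow_fraction(beat),
    calibration_lambda = cal$lambda,
    rest_inflow_per_g_ml_min = cal$inflow_per_g_ml_min,
    metadata = run_metadata(config, seed)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_waveform_csv(par_stress, file.path(out_dir, "par_stress.csv"), dt)
    write_waveform_csv(peff_stress, file.path(out_dir, "peff_stress.csv"), dt)
    write_patient_json(stress, file.path(out_dir, "patient_stress.json"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(summary = summary, patient = patient, stress = stress,
                 waveforms = list(par_rest = par_rest, peff_rest = peff_rest,
                                  par_stress = par_stress,
                                  peff_stress = peff_stress),
                 calibration = cal, beat = beat, ffr = ffr,
                 tree = tree_stress, grid = grid,
                 params_stress = params_stress),
            class = "coroflow_run")
}

#' @export
print.coroflow_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<coroflow_run> patient %s\n", s$patient_id))
  cat(sprintf("  FFR landmarks: LAD %.3f, LCX %.3f, RCA %.3f\n",
              s$ffr_landmarks$LAD, s$ffr_landmarks$LCX, s$ffr_landmarks$RCA))
  cat(sprintf("  mean MBF %.1f mL/min/100g, inflow %.3f mL/beat, diastolic fraction %.2f\n",
              s$mean_mbf_ml_min_100g, s$total_inflow_ml_beat,
              s$diastolic_flow_fraction))
  cat(sprintf("  calibration lambda %.4f (rest inflow %.4f mL/min/g)\n",
              s$calibration_lambda, s$rest_inflow_per_g_ml_min))
  invisible(x)
}

#' @export
glance.coroflow_run <- function(x, ...) {
  s <- x$summary
  tibble(patient_id = s$patient_id,
         ffr_lad = s$ffr_landmarks$LAD, ffr_lcx = s$ffr_landmarks$LCX,
         ffr_rca = s$ffr_landmarks$RCA,
         mean_mbf_ml_min_100g = s$mean_mbf_ml_min_100g,
         total_inflow_ml_beat = s$total_inflow_ml_beat,
         diastolic_flow_fraction = s$diastolic_flow_fraction,
         calibration_lambda = s$calibration_lambda)
}
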