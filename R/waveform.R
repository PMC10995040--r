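# Piecewise polynomial pressure curves over one cardiac cycle.
#
# A piecewise_pressure object stores ordered breakpoints covering [0, T]
# and, for each interval, polynomial coefficients in local time
# P(t) = sum_j c_j (t - t_start)^j (degree <= 3). Curves are periodic with
# period T.

new_piecewise_pressure <- function(breakpoints, coefs, phases, label,
                                   params = NULL) {
  stopifnot(length(coefs) == length(breakpoints) - 1,
            all(diff(breakpoints) > 0))
  structure(
    list(breakpoints = breakpoints, coefs = coefs, phases = phases,
         period = breakpoints[length(breakpoints)], label = label,
         params = params),
    class = "piecewise_pressure"
  )
}

#' @export
print.piecewise_pressure <- function(x, ...) {
  cat(sprintf("<piecewise_pressure: %s>\n", x$label))
  cat(sprintf("  period: %.4f s, %d phases (%s)\n", x$period,
              length(x$coefs), paste(x$phases, collapse = ", ")))
  rng <- range(eval_pressure(x, seq(0, x$period, length.out = 512)))
  cat(sprintf("  range: %.1f - %.1f mmHg\n", rng[1], rng[2]))
  invisible(x)
}

#' Build the four-phase aortic pressure waveform
#'
#' Constructs the aortic-root pressure over one heartbeat as a continuous
#' piecewise polynomial: a cubic systolic upstroke (zero slope at t = 0,
#' prescribed slope `k` at the shoulder), a downward parabola for the
#' augmentation region with vertex at the systolic peak, a parabola for the
#' dicrotic-notch region with vertex at the notch, and a linear diastolic
#' decay back to `p_min`. Value continuity holds at every joint; derivative
#' continuity is deliberately not enforced, allowing the sharp incisura
#' seen in invasive recordings.
#'
#' @param wp A one-row tibble from [derive_waveform_params()] (a multi-row
#'   tibble is accepted by [aortic_waveform()]).
#' @param k Slope of the upstroke at the shoulder time, in mmHg/s.
#' @return A `piecewise_pressure` object labelled `"aortic"`.
#' @examples
#' patient_record(60, "male", 175, 75, 70, 120, 80, 160) |>
#'   derive_waveform_params() |>
#'   build_aortic_waveform()
#' @export
build_aortic_waveform <- function(wp, k = 75) {
  wp <- as_tibble(wp)
  if (nrow(wp) != 1) {
    stop_validation("build_aortic_waveform() expects exactly one patient row; use aortic_waveform() for cohorts")
  }
  check_timing_order(wp)
  if (wp$delta_p > 0 && wp$p_sh >= wp$p_peak) {
    stop_validation("p_sh must be < p_peak when delta_p > 0")
  }
  t_sh <- wp$t_sh; t_peak <- wp$t_peak; t_i <- wp$t_i
  t_notch <- wp$t_notch; t_end <- wp$t_period

  # Phase I cubic on [0, t_sh], local time from 0:
  # P(0) = p_min, P'(0) = 0, P(t_sh) = p_sh, P'(t_sh) = k
  A <- rbind(c(t_sh^3, t_sh^2), c(3 * t_sh^2, 2 * t_sh))
  ab <- solve(A, c(wp$p_sh - wp$p_min, k))
  c1 <- c(wp$p_min, 0, ab[2], ab[1])

  # Phase II parabola, vertex (t_peak, p_peak), through (t_sh, p_sh);
  # local time from t_sh
  a2 <- (wp$p_sh - wp$p_peak) / (t_sh - t_peak)^2
  d2 <- t_sh - t_peak
  c2 <- c(a2 * d2^2 + wp$p_peak, 2 * a2 * d2, a2, 0)

  # Phase III parabola, vertex (t_notch, p_notch), through (t_i, p_i)
  a3 <- (wp$p_i - wp$p_notch) / (t_i - t_notch)^2
  d3 <- t_i - t_notch
  c3 <- c(a3 * d3^2 + wp$p_notch, 2 * a3 * d3, a3, 0)

  # Phase IV line through (t_notch, p_notch) and (T, p_min)
  slope4 <- (wp$p_min - wp$p_notch) / (t_end - t_notch)
  c4 <- c(wp$p_notch, slope4, 0, 0)

  new_piecewise_pressure(
    breakpoints = c(0, t_sh, t_i, t_notch, t_end),
    coefs = list(c1, c2, c3, c4),
    phases = c("I_upstroke", "II_augmentation", "III_notch", "IV_diastole"),
    label = "aortic", params = wp
  )
}

#' Build aortic (and optionally effective) waveforms for a cohort
#'
#' Convenience wrapper mapping [build_aortic_waveform()] (and
#' [build_effective_waveform()]) over the rows of a patient table.
#'
#' @param patients A tibble of patient records or of rows already processed
#'   by [derive_waveform_params()].
#' @param effective Also build the effective-pressure curve per patient?
#' @param k Upstroke shoulder slope, mmHg/s.
#' @return The parameter tibble with list-columns `aortic` (and `effective`).
#' @export
aortic_waveform <- function(patients, effective = FALSE, k = 75) {
  wp <- if (!"t_notch" %in% names(patients)) {
    derive_waveform_params(patients)
  } else {
    as_tibble(patients)
  }
  wp$aortic <- purrr::map(seq_len(nrow(wp)),
                          function(i) build_aortic_waveform(wp[i, ], k = k))
  if (effective) {
    wp$effective <- purrr::map(wp$aortic, build_effective_waveform)
  }
  wp
}

#' Build the effective coronary driving pressure
#'
#' In models that do not resolve cardiac contraction, the prescribed inlet
#' pressure is corrected by a surrogate of left-ventricular chamber
#' pressure, which compresses the microvasculature during systole. During
#' ejection (up to the incisura) the chamber surrogate is 70% of the aortic
#' pressure, so the effective pressure is `0.3 * P_ar`; during mid-diastole
#' the chamber pressure is negligible and `P_eff = P_ar`; the isovolumic
#' relaxation and contraction intervals are bridged with parabolas that
#' keep the curve continuous and periodic.
#'
#' @param par A `piecewise_pressure` built by [build_aortic_waveform()].
#' @return A `piecewise_pressure` labelled `"effective"`.
#' @export
build_effective_waveform <- function(par) {
  if (!inherits(par, "piecewise_pressure") || par$label != "aortic") {
    stop_validation("par must be an aortic piecewise_pressure")
  }
  wp <- par$params
  if (is.null(wp)) stop_validation("aortic curve carries no parameter row")
  t_i <- wp$t_i; t_notch <- wp$t_notch; t_end <- wp$t_period
  t_ic <- t_end - wp$ivct

  # 0.3 * P_ar on [0, t_i]: scale phase I and the part of phase II up to t_i
  c1 <- par$coefs[[1]] * 0.3
  c2 <- par$coefs[[2]] * 0.3

  # IR parabola on [t_i, t_notch]: vertex (t_notch, p_notch),
  # through (t_i, 0.3 * P_ar(t_i))
  p_eff_ti <- 0.3 * eval_pressure(par, t_i)
  a_ir <- (p_eff_ti - wp$p_notch) / (t_i - t_notch)^2
  d_ir <- t_i - t_notch
  c_ir <- c(a_ir * d_ir^2 + wp$p_notch, 2 * a_ir * d_ir, a_ir, 0)

  # P_eff = P_ar on [t_notch, T - ivct]: phase IV line
  c4 <- par$coefs[[4]]

  # IC parabola on [T - ivct, T]: vertex (t_ic, P_ar(t_ic)),
  # ending at 0.3 * P_ar(T) = 0.3 * p_min
  p_ic0 <- eval_pressure(par, t_ic)
  a_ic <- (0.3 * wp$p_min - p_ic0) / wp$ivct^2
  c_ic <- c(p_ic0, 0, a_ic, 0)

  new_piecewise_pressure(
    breakpoints = c(0, wp$t_sh, t_i, t_notch, t_ic, t_end),
    coefs = list(c1, c2, c_ir, c4, c_ic),
    phases = c("I_scaled", "II_scaled", "IR", "IV_diastole", "IC"),
    label = "effective", params = wp
  )
}

# locate the segment index owning each (period-reduced) time
segment_index <- function(curve, t) {
  tr <- t %% curve$period
  idx <- findInterval(tr, curve$breakpoints, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  n <- length(curve$coefs)
  idx[idx > n] <- n
  list(idx = idx, tr = tr)
}

#' Evaluate a piecewise pressure curve
#'
#' @param curve A `piecewise_pressure` object.
#' @param t Times in seconds (any real; reduced modulo the period).
#' @return Pressure in mmHg, vectorized over `t`.
#' @export
eval_pressure <- function(curve, t) {
  s <- segment_index(curve, t)
  out <- numeric(length(t))
  for (j in unique(s$idx)) {
    sel <- s$idx == j
    dt <- s$tr[sel] - curve$breakpoints[j]
    cf <- curve$coefs[[j]]
    out[sel] <- cf[1] + dt * (cf[2] + dt * (cf[3] + dt * cf[4]))
  }
  out
}

#' Analytic time derivative of a piecewise pressure curve
#'
#' Uses the polynomial coefficients directly (no finite differencing). At a
#' breakpoint the derivative of the segment starting there is returned.
#'
#' @inheritParams eval_pressure
#' @param side `"right"` (default) or `"left"`: which one-sided derivative
#'   to report at an interior breakpoint.
#' @return Derivative in mmHg/s, vectorized over `t`.
#' @export
deriv_pressure <- function(curve, t, side = c("right", "left")) {
  side <- match.arg(side)
  s <- segment_index(curve, t)
  if (side == "left") {
    # times exactly at an interior breakpoint belong to the previous segment
    exact <- which(abs(s$tr - curve$breakpoints[s$idx]) < .Machine$double.eps * 8 &
                     s$idx > 1)
    s$idx[exact] <- s$idx[exact] - 1L
  }
  out <- numeric(length(t))
  for (j in unique(s$idx)) {
    sel <- s$idx == j
    dt <- s$tr[sel] - curve$breakpoints[j]
    cf <- curve$coefs[[j]]
    out[sel] <- cf[2] + dt * (2 * cf[3] + dt * 3 * cf[4])
  }
  out
}

#' Sample a pressure curve on a uniform grid
#'
#' @inheritParams eval_pressure
#' @param dt Sampling step in seconds, 0 < dt < period.
#' @return A tibble with columns `time_s` and `pressure_mmHg`;
#'   `floor(T/dt) + 1` rows starting at t = 0 (the endpoint T is included
#'   whenever `dt` divides the period).
#' @export
sample_pressure <- function(curve, dt) {
  if (!(is.finite(dt) && dt > 0 && dt <= curve$period)) {
    stop_validation("dt must satisfy 0 < dt <= period")
  }
  n <- floor(curve$period / dt + 1e-9) + 1
  tt <- (seq_len(n) - 1) * dt
  tibble(time_s = tt, pressure_mmHg = eval_pressure(curve, tt))
}

#' Peak diastolic pressure time
#'
#' The instant of maximal effective pressure within diastole
#' (`[t_notch, T]`), at which FFR is evaluated. The diastolic branch of the
#' constructed curve is a decaying line followed by the isovolumic
#' contraction parabola, so the maximum sits at the notch; the search is
#' nonetheless performed numerically over the whole interval.
#'
#' @param curve A `piecewise_pressure` (typically the effective pressure).
#' @param n Number of grid points for the search.
#' @return Time in seconds within `[t_notch, T]`.
#' @export
find_peak_diastolic_time <- function(curve, n = 2048) {
  wp <- curve$params
  if (is.null(wp)) stop_validation("curve carries no parameter row")
  tt <- seq(wp$t_notch, wp$t_period, length.out = n)
  tt[which.max(eval_pressure(curve, tt))]
}

#' @export
tidy.piecewise_pressure <- function(x, ...) {
  tibble(
    phase = x$phases,
    t_start = head(x$breakpoints, -1),
    t_end = tail(x$breakpoints, -1),
    c0 = purrr::map_dbl(x$coefs, 1),
    c1 = purrr::map_dbl(x$coefs, 2),
    c2 = purrr::map_dbl(x$coefs, 3),
    c3 = purrr::map_dbl(x$coefs, 4)
  )
}

#' @export
glance.piecewise_pressure <- function(x, ...) {
  p <- eval_pressure(x, seq(0, x$period, length.out = 4096))
  tibble(label = x$label, period_s = x$period, n_phases = length(x$coefs),
         p_min_mmHg = min(p), p_max_mmHg = max(p),
         p_mean_mmHg = mean(p))
}

#' @export
autoplot.piecewise_pressure <- function(object, dt = 1e-3, ...) {
  df <- sample_pressure(object, dt)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$pressure_mmHg)) +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::geom_vline(xintercept = object$breakpoints, linetype = 3,
                        colour = "grey50") +
    ggplot2::labs(x = "time (s)", y = "pressure (mmHg)",
                  title = paste0(object$label, " pressure waveform")) +
    ggplot2::theme_minimal()
}

#' Plot aortic and effective pressure together
#'
#' @param par,peff Aortic and effective `piecewise_pressure` curves.
#' @param dt Sampling step in seconds.
#' @return A ggplot object.
#' @export
plot_waveforms <- function(par, peff, dt = 1e-3) {
  df <- dplyr::bind_rows(
    dplyr::mutate(sample_pressure(par, dt), curve = "aortic"),
    dplyr::mutate(sample_pressure(peff, dt), curve = "effective")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$pressure_mmHg,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "pressure (mmHg)") +
    ggplot2::theme_minimal()
}
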