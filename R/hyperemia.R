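# Rest-to-hyperemia mapping: linear regressions of stress HR and brachial
# pressures on their resting counterparts, with interquartile-range
# cleaning of paired clinical measures before fitting.

#' Default rest-to-stress mapping coefficients
#'
#' Linear coefficients `x_stress = alpha * x_rest + beta` for heart rate
#' and brachial systolic/diastolic pressure under exogenous adenosine,
#' with the Pearson correlation of the underlying clinical regression as
#' metadata. They encode the expected hemodynamic response: a relevant
#' increase in heart rate and a slight decrease in both pressures for
#' typical resting values.
#'
#' @return A tibble with columns `quantity` (`"hr"`, `"p_sys"`, `"p_dia"`),
#'   `alpha` (dimensionless), `beta` (units of the quantity), `r`.
#' @export
default_stress_map <- function() {
  tibble(
    quantity = c("hr", "p_sys", "p_dia"),
    alpha = c(0.92, 0.73, 0.73),
    beta = c(26.00, 31.10, 21.25),
    r = c(0.89, 0.78, 0.70)
  )
}

#' Map resting records to the hyperemic state
#'
#' Applies the linear stress mapping to heart rate and systolic/diastolic
#' pressure of each resting record; all other fields are copied and the
#' state is set to `"stress"`.
#'
#' @param patients A tibble of resting patient records.
#' @param coeffs Mapping coefficients as from [default_stress_map()] or
#'   [fit_stress_mapping()].
#' @return A tibble of stress-state records passing the usual invariants.
#' @examples
#' patient_record(60, "male", 175, 75, 70, 120, 80, 160) |> rest_to_stress()
#' @export
rest_to_stress <- function(patients, coeffs = default_stress_map()) {
  patients <- validate_patients(patients)
  if (!all(patients$state == "rest")) {
    stop_validation("rest_to_stress() expects records with state = 'rest'")
  }
  cf <- function(q, col) coeffs[[col]][coeffs$quantity == q]
  out <- dplyr::mutate(
    patients,
    hr = cf("hr", "alpha") * .data$hr + cf("hr", "beta"),
    p_sys = cf("p_sys", "alpha") * .data$p_sys + cf("p_sys", "beta"),
    p_dia = cf("p_dia", "alpha") * .data$p_dia + cf("p_dia", "beta"),
    state = "stress"
  )
  if (any(out$p_sys <= out$p_dia)) {
    stop_validation("stress mapping produced degenerate pressures (p_sys <= p_dia)")
  }
  validate_patients(out)
}

#' Interquartile-range cleaning of paired rest/stress measures
#'
#' For each record the rest-stress difference `dx = x_rest - x_stress` is
#' computed; a record is kept iff `Q1 - f*IQR < dx < Q3 + f*IQR` with
#' strict inequalities, where Q1/Q3 are the quartiles of the dx
#' distribution and `f` defaults to the unusually strict 0.5 used to clean
#' the adenosine dataset. Quartiles use the median-unbiased estimator
#' (`stats::quantile(type = 8)`). If the IQR is zero the strict fences
#' collapse to a point; records sitting exactly at the common quartile
#' value are then kept, so a zero-spread dataset survives cleaning intact.
#'
#' @param pairs A tibble with numeric columns `x_rest` and `x_stress`
#'   (optionally a `quantity` column naming the measure).
#' @param fence_factor Multiple of the IQR added beyond the quartiles.
#' @return An object of class `iqr_clean`: the annotated data (logical
#'   `kept` column) plus the quartiles and fences. `tidy()` returns the
#'   annotated tibble, `glance()` the summary row.
#' @export
iqr_clean <- function(pairs, fence_factor = 0.5) {
  pairs <- as_tibble(pairs)
  if (!all(c("x_rest", "x_stress") %in% names(pairs))) {
    stop_validation("pairs must have columns x_rest and x_stress")
  }
  if (nrow(pairs) < 4) {
    stop_validation("at least 4 records are required to estimate quartiles")
  }
  dx <- pairs$x_rest - pairs$x_stress
  if (!all(is.finite(dx))) stop_validation("non-finite paired measures")
  q <- quantile(dx, c(0.25, 0.75), type = 8, names = FALSE)
  iqr <- q[2] - q[1]
  kept <- dx > (q[1] - fence_factor * iqr) & dx < (q[2] + fence_factor * iqr)
  if (iqr == 0) {
    # degenerate spread: the strict fences collapse to a point, so records
    # sitting exactly at the common quartile value are retained
    kept <- kept | dx == q[1]
  }
  structure(
    list(data = dplyr::mutate(pairs, dx = dx, kept = kept),
         q1 = q[1], q3 = q[2], iqr = iqr, fence_factor = fence_factor,
         lower = q[1] - fence_factor * iqr,
         upper = q[2] + fence_factor * iqr,
         kept_idx = which(kept), removed_idx = which(!kept)),
    class = "iqr_clean"
  )
}

#' @export
print.iqr_clean <- function(x, ...) {
  cat(sprintf(
    "<iqr_clean> n = %d, kept %d, removed %d (fences %.3f .. %.3f, factor %.2f)\n",
    nrow(x$data), length(x$kept_idx), length(x$removed_idx),
    x$lower, x$upper, x$fence_factor))
  invisible(x)
}

#' @export
tidy.iqr_clean <- function(x, ...) x$data

#' @export
glance.iqr_clean <- function(x, ...) {
  tibble(n = nrow(x$data), n_kept = length(x$kept_idx),
         n_removed = length(x$removed_idx), q1 = x$q1, q3 = x$q3,
         iqr = x$iqr, lower_fence = x$lower, upper_fence = x$upper)
}

#' @export
autoplot.iqr_clean <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$x_rest, y = .data$x_stress,
                               colour = .data$kept)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "#b2182b")) +
    ggplot2::labs(x = "rest", y = "stress", colour = "kept") +
    ggplot2::theme_minimal()
}

#' Ordinary least squares rest-to-stress line
#'
#' Fits `x_stress = alpha * x_rest + beta` by least squares and reports the
#' Pearson correlation.
#'
#' @inheritParams iqr_clean
#' @return A one-row tibble with `alpha`, `beta`, `r`, `n`.
#' @export
fit_linear <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) < 2) stop_validation("need at least 2 points to fit a line")
  if (stats::var(pairs$x_rest) == 0) {
    stop_validation("zero variance in x_rest: regression undefined")
  }
  fit <- lm(x_stress ~ x_rest, data = pairs)
  tibble(alpha = unname(coef(fit)[2]), beta = unname(coef(fit)[1]),
         r = cor(pairs$x_rest, pairs$x_stress), n = nrow(pairs))
}

#' Fit the full stress mapping from paired datasets
#'
#' Per quantity (`hr`, `p_sys`, `p_dia`): IQR-clean the paired measures,
#' then fit the regression line on the kept records. The result is
#' directly usable by [rest_to_stress()].
#'
#' @param pairs A tibble with columns `quantity`, `x_rest`, `x_stress`
#'   covering the three quantities.
#' @param fence_factor Passed to [iqr_clean()].
#' @return A coefficients tibble (`quantity`, `alpha`, `beta`, `r`, `n`)
#'   with the per-quantity cleaning reports in attribute `"cleaning"`.
#' @export
fit_stress_mapping <- function(pairs, fence_factor = 0.5) {
  pairs <- as_tibble(pairs)
  if (!"quantity" %in% names(pairs)) {
    stop_validation("pairs must have a quantity column")
  }
  qs <- unique(pairs$quantity)
  reports <- list()
  rows <- purrr::map(qs, function(q) {
    sub <- dplyr::filter(pairs, .data$quantity == q)
    cl <- iqr_clean(sub, fence_factor = fence_factor)
    reports[[q]] <<- cl
    kept <- dplyr::filter(cl$data, .data$kept)
    dplyr::mutate(fit_linear(kept), quantity = q, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "cleaning") <- reports
  out
}
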