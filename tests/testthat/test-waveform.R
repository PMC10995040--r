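wp1 <- derive_waveform_params(test_patient())
par1 <- build_aortic_waveform(wp1)
peff1 <- build_effective_waveform(par1)

test_that("aortic waveform satisfies its boundary and matching conditions", {
  expect_equal(eval_pressure(par1, 0), wp1$p_min)
  expect_equal(eval_pressure(par1, wp1$t_sh), wp1$p_sh)
  expect_equal(eval_pressure(par1, wp1$t_peak), wp1$p_peak)
  expect_equal(eval_pressure(par1, wp1$t_notch), wp1$p_notch)
  # prescribed shoulder slope from the upstroke side
  expect_equal(deriv_pressure(par1, wp1$t_sh, side = "left"), 75)
  # zero-slope closure at the cycle seam
  expect_equal(deriv_pressure(par1, 0, side = "right"), 0)
  # phase II and III agree at the incisura by construction
  expect_equal(eval_pressure(par1, wp1$t_i), wp1$p_i, tolerance = 1e-12)
})

# exact one-sided limit of segment j at its right end (local polynomial)
segment_end_value <- function(curve, j) {
  tau <- curve$breakpoints[j + 1] - curve$breakpoints[j]
  cf <- curve$coefs[[j]]
  cf[1] + cf[2] * tau + cf[3] * tau^2 + cf[4] * tau^3
}

test_that("curves are continuous and periodic to 1e-9 mmHg", {
  for (curve in list(par1, peff1)) {
    n_seg <- length(curve$coefs)
    for (j in seq_len(n_seg - 1)) {
      gap <- abs(segment_end_value(curve, j) - curve$coefs[[j + 1]][1])
      expect_lte(gap, 1e-9)
    }
    expect_lt(abs(eval_pressure(curve, 0) -
                    eval_pressure(curve, curve$period)), 1e-9)
  }
})

test_that("the global maximum is the systolic peak at t_peak", {
  tt <- seq(0, par1$period, length.out = 20001)
  pp <- eval_pressure(par1, tt)
  expect_lte(max(pp), wp1$p_peak + 1e-9)
  expect_equal(tt[which.max(pp)], wp1$t_peak, tolerance = 1e-3)
})

test_that("upstroke is monotone under the Hermite slope condition", {
  # k <= 3 (p_sh - p_min) / t_sh guarantees a non-decreasing cubic
  expect_lte(75, 3 * (wp1$p_sh - wp1$p_min) / wp1$t_sh)
  tt <- seq(0, wp1$t_sh, length.out = 2000)
  expect_true(all(diff(eval_pressure(par1, tt)) >= -1e-12))
})

test_that("effective pressure scales ejection and matches diastole exactly", {
  # 30% of aortic pressure throughout ejection
  tt_ej <- seq(1e-6, wp1$t_i - 1e-6, length.out = 500)
  expect_equal(eval_pressure(peff1, tt_ej),
               0.3 * eval_pressure(par1, tt_ej), tolerance = 1e-12)
  # identical to the aortic curve in mid-diastole
  tt_d <- seq(wp1$t_notch, wp1$t_period - wp1$ivct, length.out = 500)
  expect_equal(eval_pressure(peff1, tt_d), eval_pressure(par1, tt_d),
               tolerance = 1e-12)
  # periodic end conditions through the isovolumic contraction parabola
  expect_equal(eval_pressure(peff1, wp1$t_period), 0.3 * wp1$p_min)
  expect_equal(eval_pressure(peff1, 0), 0.3 * wp1$p_min)
  # never exceeds the aortic curve up to the isovolumic contraction (the
  # flat-vertex IC parabola can sit marginally above the declining aortic
  # line during the final 0.05 s by construction)
  tt <- seq(0, wp1$t_period - wp1$ivct, length.out = 5000)
  expect_true(all(eval_pressure(peff1, tt) <=
                    eval_pressure(par1, tt) + 1e-9))
})

test_that("evaluation is periodic and breakpoint-consistent", {
  expect_equal(eval_pressure(par1, par1$period + 0.1),
               eval_pressure(par1, 0.1))
  expect_equal(eval_pressure(par1, -0.1),
               eval_pressure(par1, par1$period - 0.1))
})

test_that("uniform sampling has the declared length and captures the peak", {
  T <- par1$period
  s_full <- sample_pressure(par1, T)
  expect_identical(nrow(s_full), 2L)
  expect_equal(s_full$pressure_mmHg[1], s_full$pressure_mmHg[2])
  dt <- 1e-3
  s <- sample_pressure(par1, dt)
  expect_identical(nrow(s), as.integer(floor(T / dt + 1e-9)) + 1L)
  # peak recovery within the phase-II curvature bound a_II dt^2 / 4
  a2 <- (wp1$p_sh - wp1$p_peak) / (wp1$t_sh - wp1$t_peak)^2
  expect_lte(wp1$p_peak - max(s$pressure_mmHg), abs(a2) * dt^2 / 4 + 1e-12)
})

test_that("generated-cohort curves stay within physiologic bounds", {
  spec <- cohort_spec(seed = 7)
  for (i in 1:20) {
    wp <- derive_waveform_params(generate_patient(spec, i))
    curve <- build_aortic_waveform(wp)
    p <- eval_pressure(curve, seq(0, curve$period, length.out = 2000))
    expect_true(all(p > 40 & p < 200))
  }
})

test_that("peak diastolic time sits at the notch for the constructed curve", {
  t_star <- find_peak_diastolic_time(peff1)
  expect_equal(t_star, wp1$t_notch, tolerance = 1e-3)
  expect_gte(t_star, wp1$t_notch)
  expect_lte(t_star, wp1$t_period)
  # invariant under uniform pressure rescaling
  scaled <- peff1
  scaled$coefs <- lapply(scaled$coefs, function(cf) cf * 3.7)
  expect_equal(find_peak_diastolic_time(scaled), t_star)
})

test_that("mismatched or degenerate inputs are rejected", {
  expect_error(build_aortic_waveform(dplyr::bind_rows(wp1, wp1)),
               class = "coroflow_validation_error")
  bad <- wp1
  bad$t_i <- bad$t_peak - 0.01   # breaks t_peak < t_i
  expect_error(build_aortic_waveform(bad), class = "coroflow_validation_error")
  expect_error(build_effective_waveform(peff1),
               class = "coroflow_validation_error")
  expect_error(sample_pressure(par1, 0), class = "coroflow_validation_error")
})
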