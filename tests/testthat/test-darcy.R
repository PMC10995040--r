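test_that("zero source gives the homogeneous venous solution", {
  g <- darcy_grid(4, 3, 3)
  st <- solve_darcy(g, darcy_params(), g = 0)
  expect_equal(st$p1, rep(5, g$n), tolerance = 1e-10)
  expect_equal(st$p2, rep(5, g$n), tolerance = 1e-10)
  expect_equal(st$p3, rep(5, g$n), tolerance = 1e-10)
  expect_equal(compute_mbf(st)$mean, 0, tolerance = 1e-10)
})

test_that("uniform source reproduces the closed-form pressure chain", {
  pp <- darcy_params()
  g0 <- 0.02625
  for (dims in list(c(2, 2, 2), c(5, 4, 3), c(8, 8, 4))) {
    g <- darcy_grid(dims[1], dims[2], dims[3])
    st <- solve_darcy(g, pp, g = g0)
    p3_exp <- 5 + (g0 / pp$gamma) / 133.322
    p2_exp <- p3_exp + (g0 / pp$beta23) / 133.322
    p1_exp <- p2_exp + (g0 / pp$beta12) / 133.322
    expect_equal(st$p3, rep(p3_exp, g$n), tolerance = 1e-10)
    expect_equal(st$p2, rep(p2_exp, g$n), tolerance = 1e-10)
    expect_equal(st$p1, rep(p1_exp, g$n), tolerance = 1e-10)
    # unit conversion: 0.02625 / s * 6000 / 1.05 = 150 mL/min/100g
    expect_equal(compute_mbf(st)$mean, 150, tolerance = 1e-10)
  }
})

test_that("sparse solution matches the independent dense oracle", {
  pp <- darcy_params()
  for (seed in 1:3) {
    set.seed(seed)
    g <- darcy_grid(3, 3, 3)
    src <- runif(g$n, 0, 0.05)
    st <- solve_darcy(g, pp, src)
    oracle <- dense_darcy_solve(g, pp, src)
    expect_equal(st$p1, oracle$p1, tolerance = 1e-10)
    expect_equal(st$p2, oracle$p2, tolerance = 1e-10)
    expect_equal(st$p3, oracle$p3, tolerance = 1e-10)
  }
  # also on an anisotropic 4x4x4 with distinct conductivities
  pp2 <- darcy_params(k1 = 3e-9, k2 = 1e-9, k3 = 2e-9)
  g4 <- darcy_grid(4, 4, 4)
  set.seed(4); src <- runif(g4$n, 0, 0.05)
  st4 <- solve_darcy(g4, pp2, src)
  or4 <- dense_darcy_solve(g4, pp2, src)
  expect_equal(st4$p1, or4$p1, tolerance = 1e-10)
})

test_that("mass is conserved and the maximum principle holds", {
  pp <- darcy_params()
  g <- darcy_grid(6, 6, 4)
  set.seed(8); src <- runif(g$n, 0, 0.06)
  st <- solve_darcy(g, pp, src)
  expect_lt(abs(st$total_inflow_ml_min - st$total_drain_ml_min) /
              st$total_inflow_ml_min, 1e-8)
  # mean MBF times mass equals total inflow (conservation identity)
  expect_equal(compute_mbf(st)$mean * g$mass_g / 100,
               st$total_inflow_ml_min, tolerance = 1e-8)
  # non-negative source keeps every compartment above venous pressure
  expect_true(all(st$p3 >= pp$p_veins - 1e-10))
  expect_true(all(st$p1 >= st$p2 & st$p2 >= st$p3))
})

test_that("compartment-1 pressure responds monotonically to the source", {
  pp <- darcy_params()
  g <- darcy_grid(4, 4, 3)
  set.seed(12); src <- runif(g$n, 0, 0.05)
  st <- solve_darcy(g, pp, src)
  for (r in 1:3) {
    bump <- src
    j <- sample.int(g$n, 1)
    bump[j] <- bump[j] + 0.02
    st2 <- solve_darcy(g, pp, bump)
    expect_true(all(st2$p1 >= st$p1 - 1e-12))
  }
})

test_that("total series conductance follows the harmonic rule", {
  pp <- darcy_params()
  expect_equal(total_conductance(pp),
               1 / (1 / 2.5e-5 + 1 / 1.25e-5 + 1 / 3e-5), tolerance = 1e-12)
  expect_equal(total_conductance(pp), 6.5217e-6, tolerance = 1e-4)
  eq <- darcy_params(beta12 = 2e-5, beta23 = 2e-5, gamma = 2e-5)
  expect_equal(total_conductance(eq), 2e-5 / 3, tolerance = 1e-12)
  sc <- scale_to_stress(pp, 3.5)
  expect_equal(total_conductance(sc) / total_conductance(pp), 3.5,
               tolerance = 1e-12)
})

test_that("stress scaling multiplies conductances only", {
  pp <- darcy_params()
  st <- scale_to_stress(pp)
  expect_equal(total_conductance(st) / total_conductance(pp), 4,
               tolerance = 1e-12)
  expect_equal(total_conductance(scale_to_stress(st)) /
                 total_conductance(pp), 16, tolerance = 1e-12)
  expect_identical(st$p_veins, 5)
  expect_identical(st$k1, pp$k1)
})

test_that("resting calibration hits and reproduces the inflow target", {
  grid <- darcy_grid(8, 8, 4, h = 2e-3)
  tree <- default_coronary_tree()
  pp <- darcy_params()
  drive <- 60
  # target set to the lambda = 1 inflow: calibration returns ~1
  base <- coroflow:::steady_coupled_state(tree, grid, pp, drive)
  f1 <- base$darcy$total_inflow_ml_min / grid$mass_g
  cal0 <- calibrate_rest(grid, pp, tree, drive, target_inflow = f1)
  expect_equal(cal0$lambda, 1, tolerance = 0.05)
  # standard 1 mL/min/g target
  cal <- calibrate_rest(grid, pp, tree, drive, target_inflow = 1.0)
  expect_lt(abs(cal$inflow_per_g_ml_min - 1.0), 0.005)
  # re-simulation with the calibrated parameters reproduces the target
  st <- coroflow:::steady_coupled_state(tree, grid, cal$params, drive)
  expect_equal(st$darcy$total_inflow_ml_min / grid$mass_g,
               cal$inflow_per_g_ml_min, tolerance = 1e-10)
  # doubling the target strictly increases lambda
  cal2 <- calibrate_rest(grid, pp, tree, drive, target_inflow = 2.0)
  expect_gt(cal2$lambda, cal$lambda)
  # unreachable target errors
  expect_error(calibrate_rest(grid, pp, tree, drive, target_inflow = 1e6),
               class = "coroflow_numerical_error")
})
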