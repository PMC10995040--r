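test_that("Poiseuille segment resistance follows the r^4 law", {
  expect_equal(segment_resistance(0.03, 1.5e-3, 3.5e-3), 5.2816e7,
               tolerance = 1e-4)
  expect_equal(segment_resistance(0.03, 0.75e-3) /
                 segment_resistance(0.03, 1.5e-3), 16, tolerance = 1e-12)
  expect_equal(segment_resistance(0.06, 1.5e-3) /
                 segment_resistance(0.03, 1.5e-3), 2, tolerance = 1e-12)
  expect_error(segment_resistance(0, 1e-3), class = "coroflow_validation_error")
})

test_that("hyperemic dilation scales radii and resistances as expected", {
  tree <- default_coronary_tree(
    stenoses = tibble::tibble(segment_id = "LAD2",
                              radius_reduction_frac = 0.5,
                              length_frac = 0.25))
  d <- dilate(tree)
  expect_equal(d$segments$radius_m / tree$segments$radius_m,
               rep(1.225, nrow(tree$segments)))
  expect_identical(d$stenoses, tree$stenoses)
  expect_identical(d$segments$length_m, tree$segments$length_m)
  expect_equal(dilate(tree, 1)$segments$radius_m, tree$segments$radius_m)
  # resistance drops by 1.225^-4 per segment (stenosed segments included)
  expect_equal(coroflow:::tree_resistances(d) /
                 coroflow:::tree_resistances(tree),
               setNames(rep(1.225^-4, 7), tree$segments$segment_id),
               tolerance = 1e-12)
  expect_error(dilate(tree, 0), class = "coroflow_validation_error")
})

test_that("network solve is exact: trivial cases and Kirchhoff balance", {
  tree <- default_coronary_tree()
  # equal boundary pressures: no flow anywhere
  sol0 <- solve_network(tree, 50, c(LAD = 50, LCX = 50, RCA = 50))
  expect_equal(sol0$segments$flow_ml_s, rep(0, 7), tolerance = 1e-12)
  # single segment obeys Q = dP / R
  one <- coronary_tree(tibble::tibble(segment_id = "A", parent_id = NA,
                                      length_m = 0.03, radius_m = 1.5e-3,
                                      territory = "LAD"))
  sol1 <- solve_network(one, 90, c(LAD = 20))
  expect_equal(sol1$segments$flow_m3_s,
               (70 * 133.322) / segment_resistance(0.03, 1.5e-3),
               tolerance = 1e-12)
  expect_lt(kirchhoff_residual(solve_network(tree, 90,
                                             c(LAD = 20, LCX = 30, RCA = 25))),
            1e-10)
})

test_that("network pressures match the dense nodal oracle", {
  terminal <- c(LAD = 18, LCX = 22, RCA = 25)
  for (seed in 1:4) {
    tree <- random_test_tree(n_segments = sample(c(7, 10, 15), 1), seed = seed)
    sol <- solve_network(tree, 85, terminal)
    oracle <- dense_network_solve(tree, 85, terminal)
    got <- setNames(sol$nodes$pressure_mmHg, sol$nodes$node)
    expect_equal(got[names(oracle)], oracle, tolerance = 1e-12)
    expect_lt(kirchhoff_residual(sol), 1e-10)
  }
  # stenosed tree against the oracle too
  tr <- default_coronary_tree(
    stenoses = tibble::tibble(segment_id = "LAD1",
                              radius_reduction_frac = 0.6,
                              length_frac = 0.3))
  sol <- solve_network(tr, 85, terminal)
  oracle <- dense_network_solve(tr, 85, terminal)
  got <- setNames(sol$nodes$pressure_mmHg, sol$nodes$node)
  expect_equal(got[names(oracle)], oracle, tolerance = 1e-12)
})

test_that("tree validation catches malformed topologies", {
  segs <- default_coronary_tree()$segments
  bad <- segs; bad$parent_id[1] <- "LAD2"   # LM <- LAD2 <- LAD1 <- LM cycle
  expect_error(coronary_tree(bad), class = "coroflow_validation_error")
  bad2 <- segs; bad2$radius_m[3] <- 0
  expect_error(coronary_tree(bad2), class = "coroflow_validation_error")
  expect_error(coronary_tree(segs, stenoses = tibble::tibble(
    segment_id = "LAD2", radius_reduction_frac = 1.2, length_frac = 0.5)),
    class = "coroflow_validation_error")
})

# shared small configuration for the coupled-beat tests
beat_fixture <- local({
  wp <- derive_waveform_params(rest_to_stress(test_patient()))
  peff <- build_effective_waveform(build_aortic_waveform(wp))
  grid <- darcy_grid(8, 8, 4, h = 2e-3)
  params <- scale_to_stress(darcy_params(), 4)
  list(wp = wp, peff = peff, grid = grid, params = params)
})

test_that("coupled beat conserves mass and is mostly diastolic", {
  fx <- beat_fixture
  beat <- run_beat(dilate(default_coronary_tree()), fx$peff, fx$grid,
                   fx$params, dt = 1e-3)
  # per-beat inflow equals per-beat Darcy drainage (quasi-static coupling)
  expect_lt(abs(beat$total_inflow_ml_beat - beat$total_drain_ml_beat) /
              beat$total_inflow_ml_beat, 0.005)
  # diastolic fraction of left-inlet flow above one half
  expect_gt(diastolic_flow_fraction(beat), 0.5)
  # dilation increases per-beat inflow, all else equal
  beat0 <- run_beat(default_coronary_tree(), fx$peff, fx$grid, fx$params,
                    dt = 1e-3)
  expect_gt(beat$total_inflow_ml_beat, beat0$total_inflow_ml_beat)
})

test_that("FFR field is unity at the inlet and monotone along paths", {
  fx <- beat_fixture
  tree <- dilate(default_coronary_tree())
  beat <- run_beat(tree, fx$peff, fx$grid, fx$params, dt = 1e-3)
  ffr <- compute_ffr(beat)
  nodes <- setNames(ffr$nodes$ffr, ffr$nodes$node)
  expect_equal(unname(nodes["inlet:LM"]), 1, tolerance = 1e-12)
  expect_equal(unname(nodes["inlet:RCA1"]), 1, tolerance = 1e-12)
  expect_true(all(ffr$nodes$ffr > 0 & ffr$nodes$ffr <= 1 + 1e-12))
  # non-increasing from root to leaf under positive flow
  for (path in list(c("inlet:LM", "LM", "LAD1", "LAD2"),
                    c("inlet:LM", "LM", "LCX1", "LCX2"),
                    c("inlet:RCA1", "RCA1", "RCA2"))) {
    expect_true(all(diff(nodes[path]) <= 1e-12))
  }
  # healthy landmark values stay high
  expect_true(all(ffr$landmarks > 0.9))
})

test_that("a stenosis strictly lowers FFR at every distal node", {
  fx <- beat_fixture
  sten <- tibble::tibble(segment_id = "LAD1", radius_reduction_frac = 0.6,
                         length_frac = 0.5)
  tree_h <- dilate(default_coronary_tree())
  tree_s <- dilate(default_coronary_tree(stenoses = sten))
  ffr_h <- compute_ffr(run_beat(tree_h, fx$peff, fx$grid, fx$params,
                                dt = 2e-3))
  ffr_s <- compute_ffr(run_beat(tree_s, fx$peff, fx$grid, fx$params,
                                dt = 2e-3))
  h <- setNames(ffr_h$nodes$ffr, ffr_h$nodes$node)
  s <- setNames(ffr_s$nodes$ffr, ffr_s$nodes$node)
  for (nd in c("LAD1", "LAD2")) expect_lt(s[[nd]], h[[nd]])
  expect_lt(ffr_s$landmarks[["LAD"]], ffr_h$landmarks[["LAD"]])
})
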