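# Quasi-static Poiseuille resistive surrogate of the epicardial coronary
# tree, one-way coupled to the Darcy slab. This deliberately replaces a 3D
# Navier-Stokes arterial model: FFR values are method-consistent within
# the surrogate, not reproductions of patient-specific 3D results.
#
# Topology: each segment is an edge from its parent's distal node to its
# own distal node; a root segment (parent NA) starts at an inlet node held
# at the prescribed inlet pressure. Terminal (leaf) distal nodes are held
# at the territory pressure supplied by the perfusion model.

#' Construct a coronary tree surrogate
#'
#' @param segments Tibble with columns `segment_id`, `parent_id` (NA for a
#'   root), `length_m`, `radius_m`, `territory` (`"LAD"`, `"LCX"`,
#'   `"RCA"`).
#' @param stenoses Optional tibble with columns `segment_id`,
#'   `radius_reduction_frac` in (0,1) and `length_frac` in (0,1]: the
#'   fraction of the segment length narrowed and by how much.
#' @param viscosity Blood dynamic viscosity, Pa s.
#' @return A list of class `coronary_tree`.
#' @examples
#' default_coronary_tree()
#' @export
coronary_tree <- function(segments, stenoses = NULL, viscosity = 3.5e-3) {
  segments <- as_tibble(segments)
  req <- c("segment_id", "parent_id", "length_m", "radius_m", "territory")
  if (!all(req %in% names(segments))) {
    stop_validation(paste0("segments must have columns: ",
                           paste(req, collapse = ", ")))
  }
  if (anyDuplicated(segments$segment_id)) {
    stop_validation("duplicate segment_id")
  }
  if (!all(is.na(segments$parent_id) |
             segments$parent_id %in% segments$segment_id)) {
    stop_validation("parent_id must be NA or an existing segment_id")
  }
  if (!all(segments$territory %in% c("LAD", "LCX", "RCA"))) {
    stop_validation("territory must be LAD, LCX or RCA")
  }
  if (!all(segments$radius_m > 0 & segments$length_m > 0)) {
    stop_validation("radii and lengths must be positive")
  }
  # acyclicity/connectivity: walking parents must reach a root
  for (s in segments$segment_id) {
    seen <- character(0); cur <- s
    repeat {
      p <- segments$parent_id[segments$segment_id == cur]
      if (is.na(p)) break
      if (p %in% seen) stop_validation("cycle detected in parent links")
      seen <- c(seen, cur); cur <- p
    }
  }
  if (!is.null(stenoses)) {
    stenoses <- as_tibble(stenoses)
    if (!all(stenoses$segment_id %in% segments$segment_id)) {
      stop_validation("stenosis refers to unknown segment")
    }
    if (!all(stenoses$radius_reduction_frac > 0 &
               stenoses$radius_reduction_frac < 1)) {
      stop_validation("radius_reduction_frac must lie in (0, 1)")
    }
    if (!all(stenoses$length_frac > 0 & stenoses$length_frac <= 1)) {
      stop_validation("length_frac must lie in (0, 1]")
    }
  }
  structure(list(segments = segments, stenoses = stenoses,
                 viscosity = viscosity),
            class = "coronary_tree")
}

#' @export
print.coronary_tree <- function(x, ...) {
  ns <- if (is.null(x$stenoses)) 0 else nrow(x$stenoses)
  cat(sprintf("<coronary_tree> %d segments, %d root(s), %d stenosis(es)\n",
              nrow(x$segments), sum(is.na(x$segments$parent_id)), ns))
  invisible(x)
}

#' Default healthy two-inlet coronary tree
#'
#' A seven-segment surrogate: left main bifurcating into two-segment LAD
#' and LCX branches, and a two-segment RCA from its own inlet. Dimensions
#' are typical adult epicardial values.
#'
#' @param stenoses Optional stenosis table (see [coronary_tree()]).
#' @return A `coronary_tree`.
#' @export
default_coronary_tree <- function(stenoses = NULL) {
  segs <- tibble(
    segment_id = c("LM", "LAD1", "LAD2", "LCX1", "LCX2", "RCA1", "RCA2"),
    parent_id = c(NA, "LM", "LAD1", "LM", "LCX1", NA, "RCA1"),
    length_m = c(0.010, 0.040, 0.040, 0.030, 0.035, 0.040, 0.040),
    radius_m = c(2.25e-3, 1.8e-3, 1.4e-3, 1.7e-3, 1.3e-3, 1.7e-3, 1.3e-3),
    territory = c("LAD", "LAD", "LAD", "LCX", "LCX", "RCA", "RCA")
  )
  coronary_tree(segs, stenoses = stenoses)
}

#' Poiseuille resistance of a cylindrical segment
#'
#' @param length Segment length, m.
#' @param radius Lumen radius, m.
#' @param viscosity Dynamic viscosity, Pa s.
#' @return Resistance in Pa s m^-3. Vectorized.
#' @examples
#' segment_resistance(0.03, 1.5e-3, 3.5e-3) # ~5.28e7
#' @export
segment_resistance <- function(length, radius, viscosity = 3.5e-3) {
  if (!all(length > 0 & radius > 0 & viscosity > 0)) {
    stop_validation("length, radius, viscosity must be positive")
  }
  8 * viscosity * length / (pi * radius^4)
}

# per-segment resistance, stenosed portion in series with the rest
tree_resistances <- function(tree) {
  segs <- tree$segments
  R <- segment_resistance(segs$length_m, segs$radius_m, tree$viscosity)
  if (!is.null(tree$stenoses)) {
    for (i in seq_len(nrow(tree$stenoses))) {
      st <- tree$stenoses[i, ]
      j <- which(segs$segment_id == st$segment_id)
      r_st <- segs$radius_m[j] * (1 - st$radius_reduction_frac)
      l_st <- segs$length_m[j] * st$length_frac
      l_rest <- segs$length_m[j] - l_st
      R[j] <- segment_resistance(l_st, r_st, tree$viscosity) +
        if (l_rest > 0) {
          segment_resistance(l_rest, segs$radius_m[j], tree$viscosity)
        } else 0
    }
  }
  setNames(R, segs$segment_id)
}

#' Uniform hyperemic dilation of the epicardial tree
#'
#' Multiplies every segment radius by `factor` (default 1.225, the mean
#' stress/rest distal-RCA diameter ratio), leaving lengths and fractional
#' stenosis descriptions unchanged. Per-segment Poiseuille resistance
#' scales by `factor^-4`.
#'
#' @param tree A [coronary_tree()].
#' @param factor Radial dilation factor, > 0.
#' @return The dilated tree.
#' @export
dilate <- function(tree, factor = 1.225) {
  if (!is.numeric(factor) || factor <= 0) {
    stop_validation("dilation factor must be positive")
  }
  segs <- tree$segments
  segs$radius_m <- segs$radius_m * factor
  coronary_tree(segs, stenoses = tree$stenoses, viscosity = tree$viscosity)
}

# node bookkeeping: inlets, internal, terminal
tree_nodes <- function(tree) {
  segs <- tree$segments
  roots <- segs$segment_id[is.na(segs$parent_id)]
  leaves <- setdiff(segs$segment_id, segs$parent_id[!is.na(segs$parent_id)])
  inlet_nodes <- paste0("inlet:", roots)
  from <- ifelse(is.na(segs$parent_id), paste0("inlet:", segs$segment_id),
                 segs$parent_id)
  list(nodes = c(inlet_nodes, segs$segment_id),
       inlet_nodes = inlet_nodes, roots = roots, leaves = leaves,
       terminal_nodes = leaves, from = from, to = segs$segment_id)
}

#' Solve the resistive network for given boundary pressures
#'
#' Dirichlet conditions: every inlet node at `inlet_pressure`, every
#' terminal node at its territory's entry in `terminal_pressures`. The
#' internal nodal system is solved exactly (direct dense solve; the
#' network is small), so Kirchhoff balance holds to machine precision.
#'
#' @param tree A [coronary_tree()].
#' @param inlet_pressure Inlet pressure, mmHg.
#' @param terminal_pressures Named numeric: pressure (mmHg) per territory
#'   (`LAD`, `LCX`, `RCA`) or per terminal segment id.
#' @return A list of class `network_solution`: `nodes` tibble (node,
#'   pressure_mmHg, type), `segments` tibble (segment_id, from, to,
#'   resistance_pa_s_m3, flow_ml_s), and per-territory/inlet flow
#'   summaries.
#' @export
solve_network <- function(tree, inlet_pressure, terminal_pressures) {
  nb <- tree_nodes(tree)
  segs <- tree$segments
  R <- tree_resistances(tree)
  G <- 1 / R                                   # m^3 s^-1 Pa^-1
  nodes <- nb$nodes
  n <- length(nodes)
  # Dirichlet values in Pa
  p_fix <- setNames(rep(NA_real_, n), nodes)
  p_fix[nb$inlet_nodes] <- mmhg_to_pa(inlet_pressure)
  for (leaf in nb$leaves) {
    terr <- segs$territory[segs$segment_id == leaf]
    val <- if (leaf %in% names(terminal_pressures)) {
      terminal_pressures[[leaf]]
    } else if (terr %in% names(terminal_pressures)) {
      terminal_pressures[[terr]]
    } else {
      stop_validation(paste0("no terminal pressure for leaf ", leaf,
                             " (territory ", terr, ")"))
    }
    p_fix[leaf] <- mmhg_to_pa(val)
  }
  # weighted graph Laplacian
  L <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(segs))) {
    a <- nb$from[e]; b <- nb$to[e]; g <- G[e]
    L[a, a] <- L[a, a] + g; L[b, b] <- L[b, b] + g
    L[a, b] <- L[a, b] - g; L[b, a] <- L[b, a] - g
  }
  free <- is.na(p_fix)
  p <- p_fix
  if (any(free)) {
    rhs <- -L[free, !free, drop = FALSE] %*% p_fix[!free]
    p[free] <- solve(L[free, free, drop = FALSE], rhs)
  }
  q <- G * (p[nb$from] - p[nb$to])             # m^3/s, parent -> distal
  seg_tbl <- tibble(segment_id = segs$segment_id, from = nb$from,
                    to = nb$to, territory = segs$territory,
                    resistance_pa_s_m3 = unname(R),
                    flow_m3_s = unname(q), flow_ml_s = unname(q) * 1e6)
  node_tbl <- tibble(
    node = nodes, pressure_mmHg = pa_to_mmhg(unname(p)),
    type = dplyr::case_when(nodes %in% nb$inlet_nodes ~ "inlet",
                            nodes %in% nb$terminal_nodes ~ "terminal",
                            TRUE ~ "internal"))
  terr_flow <- seg_tbl |>
    dplyr::filter(.data$segment_id %in% nb$leaves) |>
    dplyr::group_by(.data$territory) |>
    dplyr::summarise(flow_m3_s = sum(.data$flow_m3_s), .groups = "drop")
  inlet_flow <- seg_tbl |>
    dplyr::filter(.data$from %in% nb$inlet_nodes) |>
    dplyr::select(inlet = "from", "flow_m3_s")
  structure(list(nodes = node_tbl, segments = seg_tbl,
                 territory_flow = terr_flow, inlet_flow = inlet_flow,
                 tree = tree),
            class = "network_solution")
}

#' @export
print.network_solution <- function(x, ...) {
  cat("<network_solution>\n")
  print(x$nodes, n = 5)
  invisible(x)
}

#' Kirchhoff residual of a network solution
#'
#' Maximum relative flow imbalance over internal junctions.
#'
#' @param sol A `network_solution`.
#' @return A non-negative scalar.
#' @export
kirchhoff_residual <- function(sol) {
  internal <- sol$nodes$node[sol$nodes$type == "internal"]
  if (length(internal) == 0) return(0)
  res <- vapply(internal, function(nd) {
    q_in <- sum(sol$segments$flow_m3_s[sol$segments$to == nd])
    q_out <- sum(sol$segments$flow_m3_s[sol$segments$from == nd])
    abs(q_in - q_out) / max(abs(q_in), abs(q_out), 1e-300)
  }, numeric(1))
  max(res)
}

# --- one-way coupling to the Darcy slab -----------------------------------

#' Map slab voxels to coronary perfusion territories
#'
#' Splits the slab into contiguous blocks along x, with fractions roughly
#' matching the myocardial share of each artery.
#'
#' @param grid A [darcy_grid()].
#' @param fractions Named fractions summing to 1.
#' @return A character vector of length `grid$n` (x-fastest ordering).
#' @export
territory_map <- function(grid, fractions = c(LAD = 0.4, LCX = 0.3, RCA = 0.3)) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  cuts <- round(cumsum(fractions) * grid$nx)
  ivals <- findInterval(seq_len(grid$nx), c(0, head(cuts, -1)) + 1L)
  lab_x <- names(fractions)[pmin(ivals, length(fractions))]
  ijk_i <- rep(seq_len(grid$nx), times = grid$ny * grid$nz)
  lab_x[ijk_i]
}

# Affine coupling operator on the territory-pressure interface.
#
# Both sub-models are linear, so the coupled quasi-static state at a given
# inlet pressure solves a 3x3 linear interface problem exactly:
#   network:  Q = a * P_in + B * p_term      (probed)
#   darcy:    mean-p1 per territory = p_veins + D * Q   (probed, g >= 0 basis)
# giving (I - D B) p_term = p_veins + D a P_in. The probe Darcy solves also
# yield per-territory unit-flow response fields reused to reconstruct
# pressure/MBF fields at any time without further elliptic solves.
coupling_operator <- function(tree, grid, params,
                              fractions = c(LAD = 0.4, LCX = 0.3, RCA = 0.3)) {
  terr <- territory_map(grid, fractions)
  terrs <- names(fractions)
  nvox <- vapply(terrs, function(tt) sum(terr == tt), numeric(1))
  op <- darcy_operator(grid, params)

  # network probes: territory flows and node pressures, affine in (P_in, p_term)
  probe_net <- function(p_in, p_term) {
    sol <- solve_network(tree, p_in, setNames(p_term, terrs))
    qf <- setNames(rep(0, length(terrs)), terrs)
    qf[sol$territory_flow$territory] <- sol$territory_flow$flow_m3_s
    list(q = qf, p_nodes = setNames(sol$nodes$pressure_mmHg, sol$nodes$node),
         sol = sol)
  }
  base <- probe_net(0, rep(0, length(terrs)))
  a_q <- probe_net(1, rep(0, length(terrs)))$q - base$q
  B <- matrix(0, length(terrs), length(terrs),
              dimnames = list(terrs, terrs))
  for (j in seq_along(terrs)) {
    e <- rep(0, length(terrs)); e[j] <- 1
    B[, j] <- probe_net(0, e)$q - base$q
  }
  # node-pressure responses (for FFR over time)
  nodes <- names(base$p_nodes)
  a_p <- probe_net(1, rep(0, length(terrs)))$p_nodes - base$p_nodes
  P_B <- matrix(0, length(nodes), length(terrs),
                dimnames = list(nodes, terrs))
  for (j in seq_along(terrs)) {
    e <- rep(0, length(terrs)); e[j] <- 1
    P_B[, j] <- probe_net(0, e)$p_nodes - base$p_nodes
  }

  # darcy probes: unit territory inflow (1 m^3/s spread over the territory)
  D <- matrix(0, length(terrs), length(terrs),
              dimnames = list(terrs, terrs))
  p3_resp <- matrix(0, grid$n, length(terrs), dimnames = list(NULL, terrs))
  p1_resp <- matrix(0, grid$n, length(terrs), dimnames = list(NULL, terrs))
  for (j in seq_along(terrs)) {
    g <- ifelse(terr == terrs[j],
                1 / (nvox[j] * grid$voxel_volume_m3), 0)
    st <- solve_darcy(grid, params, g, op = op)
    for (i in seq_along(terrs)) {
      D[i, j] <- mean(st$p1[terr == terrs[i]]) - params$p_veins
    }
    p1_resp[, j] <- st$p1 - params$p_veins
    p3_resp[, j] <- st$p3 - params$p_veins
  }

  list(tree = tree, grid = grid, params = params, fractions = fractions,
       terr = terr, terrs = terrs, nvox = nvox, op = op,
       a_q = a_q, B = B, D = D, a_p = a_p, P_B = P_B, nodes = nodes,
       p1_resp = p1_resp, p3_resp = p3_resp,
       M = diag(length(terrs)) - D %*% B)
}

# interface solve at one inlet pressure: territory pressures and flows
coupling_solve <- function(cop, p_in) {
  rhs <- cop$params$p_veins + cop$D %*% (cop$a_q * p_in)
  p_term <- as.numeric(solve(cop$M, rhs))
  q <- cop$a_q * p_in + as.numeric(cop$B %*% p_term)
  list(p_term = setNames(p_term, cop$terrs), q = setNames(q, cop$terrs))
}

# full coupled steady state (network solution + darcy state) at one P_in
steady_coupled_state <- function(tree, grid, params, inlet_pressure_mmHg,
                                 fractions = c(LAD = 0.4, LCX = 0.3, RCA = 0.3),
                                 cop = NULL) {
  cop <- cop %||% coupling_operator(tree, grid, params, fractions)
  cs <- coupling_solve(cop, inlet_pressure_mmHg)
  net <- solve_network(tree, inlet_pressure_mmHg,
                       setNames(cs$p_term, cop$terrs))
  g <- rep(0, grid$n)
  for (j in seq_along(cop$terrs)) {
    tt <- cop$terrs[j]
    g[cop$terr == tt] <- cs$q[[tt]] / (cop$nvox[[tt]] * grid$voxel_volume_m3)
  }
  darcy <- solve_darcy(grid, params, g, op = cop$op)
  list(network = net, darcy = darcy, p_term = cs$p_term, q = cs$q,
       cop = cop)
}

#' Simulate one cardiac cycle of coupled coronary and myocardial flow
#'
#' Quasi-static sweep over one period of the effective inlet pressure: at
#' each instant the Poiseuille network is in equilibrium with the
#' territory-mean compartment-1 pressure of the Darcy slab, and the
#' territory outlet flows feed back uniformly as the slab source. Both
#' sub-models are linear, so the interface equilibrium is computed exactly
#' at every step via precomputed affine response operators.
#'
#' @param tree A [coronary_tree()] (already dilated for hyperemia if
#'   simulating stress).
#' @param peff The effective-pressure `piecewise_pressure` driving the
#'   inlets.
#' @param grid A [darcy_grid()].
#' @param params Calibrated [darcy_params()].
#' @param dt Time step, s (<= 1e-3 recommended for waveform fidelity).
#' @param fractions Territory share of the slab.
#' @return An object of class `beat_solution`: time grid, inlet pressure
#'   trace, per-inlet and per-territory flows over time, per-node pressure
#'   matrix, per-beat totals, time-averaged MBF field, and the components
#'   used.
#' @export
run_beat <- function(tree, peff, grid, params, dt = 1e-3,
                     fractions = c(LAD = 0.4, LCX = 0.3, RCA = 0.3)) {
  if (!inherits(peff, "piecewise_pressure")) {
    stop_validation("peff must be a piecewise_pressure")
  }
  cop <- coupling_operator(tree, grid, params, fractions)
  Tper <- peff$period
  n <- floor(Tper / dt + 1e-9)
  times <- (seq_len(n) - 1) * dt                # [0, T), step dt
  p_in <- eval_pressure(peff, times)

  # affine-in-P_in responses: precompute at P_in = 0 and slope
  c0 <- coupling_solve(cop, 0); c1 <- coupling_solve(cop, 1)
  q_t <- outer(c1$q - c0$q, p_in) + c0$q         # terrs x n
  p_term_t <- outer(c1$p_term - c0$p_term, p_in) + c0$p_term
  # node pressures: p_nodes = a_p * P_in + P_B %*% p_term  (+0 base)
  p_nodes_t <- cop$a_p %o% p_in + cop$P_B %*% p_term_t

  # inlet flows: root segment flow = G_root * (P_in - p_distal(root))
  segs <- tree$segments
  roots <- segs$segment_id[is.na(segs$parent_id)]
  R <- tree_resistances(tree)
  inlet_flow_t <- vapply(roots, function(rt) {
    (mmhg_to_pa(p_in) - mmhg_to_pa(p_nodes_t[rt, ])) / R[[rt]]
  }, numeric(n))                                 # n x roots, m^3/s
  inlet_flow_t <- t(inlet_flow_t)

  # time-averaged capillary overpressure field -> mean MBF field
  q_mean <- rowMeans(q_t)
  p3_over_mean <- as.numeric(cop$p3_resp %*% q_mean)   # mmHg above veins
  mbf_mean_field <- params$gamma * mmhg_to_pa(p3_over_mean) *
    6000 / grid$density

  total_inflow_ml <- sum(colSums(inlet_flow_t) * dt) * 1e6  # mL per beat
  total_drain_ml <- params$gamma * sum(mmhg_to_pa(p3_over_mean)) *
    grid$voxel_volume_m3 * Tper * 1e6

  structure(
    list(times = times, dt = dt, period = Tper, p_in = p_in,
         roots = roots, inlet_flow_m3_s = inlet_flow_t,
         territory_flow_m3_s = q_t, p_term_mmHg = p_term_t,
         node_pressure_mmHg = p_nodes_t,
         mbf_mean_field = mbf_mean_field,
         mean_mbf = mean(mbf_mean_field),
         total_inflow_ml_beat = total_inflow_ml,
         total_drain_ml_beat = total_drain_ml,
         tree = tree, grid = grid, params = params, peff = peff,
         cop = cop),
    class = "beat_solution"
  )
}

#' @export
print.beat_solution <- function(x, ...) {
  cat(sprintf("<beat_solution> T = %.3f s, dt = %.4g s, inflow %.3f mL/beat, mean MBF %.1f mL/min/100g\n",
              x$period, x$dt, x$total_inflow_ml_beat, x$mean_mbf))
  invisible(x)
}

#' @export
tidy.beat_solution <- function(x, ...) {
  flows <- as_tibble(t(x$inlet_flow_m3_s) * 1e6)
  names(flows) <- paste0("inlet_", x$roots, "_ml_s")
  dplyr::bind_cols(tibble(time_s = x$times, p_in_mmHg = x$p_in), flows)
}

#' @export
glance.beat_solution <- function(x, ...) {
  tibble(period_s = x$period, dt_s = x$dt,
         total_inflow_ml_beat = x$total_inflow_ml_beat,
         mean_mbf_ml_min_100g = x$mean_mbf,
         diastolic_flow_fraction = diastolic_flow_fraction(x))
}

#' @export
autoplot.beat_solution <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(dplyr::starts_with("inlet_"),
                        names_to = "inlet", values_to = "flow_ml_s")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$flow_ml_s,
                                   colour = .data$inlet)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peff$params$t_notch,
                        linetype = 3) +
    ggplot2::labs(x = "time (s)", y = "inlet flow (mL/s)") +
    ggplot2::theme_minimal()
}

#' Diastolic fraction of left-inlet flow over the beat
#'
#' Fraction of per-beat inflow at the left coronary inlet delivered during
#' diastole (`t >= t_notch`). The effective-pressure correction should
#' make coronary flow mostly diastolic.
#'
#' @param beat A [run_beat()] solution.
#' @param inlet Root segment id; defaults to the first (left) root.
#' @return A number in `[0, 1]`.
#' @export
diastolic_flow_fraction <- function(beat, inlet = beat$roots[1]) {
  i <- which(beat$roots == inlet)
  q <- beat$inlet_flow_m3_s[i, ]
  t_notch <- beat$peff$params$t_notch
  dia <- beat$times >= t_notch
  sum(q[dia]) / sum(q)
}

#' Compute the FFR field at an evaluation instant
#'
#' FFR at each network node is the nodal pressure divided by the inlet
#' pressure at `t_eval` (by default the peak-diastolic instant of the
#' driving effective pressure). Landmark values per major artery are read
#' at the most distal node of each territory, matching invasive practice
#' (distal LAD at the apex; distal LCX before the posterior descent in
#' left-dominant trees, else end of LCX; distal RCA before its terminal
#' bifurcation).
#'
#' @param beat A [run_beat()] solution.
#' @param t_eval Evaluation time in seconds; defaults to the peak
#'   diastolic pressure time.
#' @return An object of class `ffr_field`: per-node tibble and named
#'   landmark values.
#' @export
compute_ffr <- function(beat, t_eval = NULL) {
  t_eval <- t_eval %||% find_peak_diastolic_time(beat$peff)
  idx <- which.min(abs(beat$times - (t_eval %% beat$period)))
  p_inlet <- beat$p_in[idx]
  if (p_inlet <= 0) stop_numerical("inlet pressure non-positive at t_eval")
  pn <- beat$node_pressure_mmHg[, idx]
  ffr <- pn / p_inlet
  segs <- beat$tree$segments
  nodes_tbl <- tibble(node = rownames(beat$node_pressure_mmHg),
                      pressure_mmHg = unname(pn), ffr = unname(ffr))
  # landmark: deepest distal node per territory (cumulative path length)
  depth <- setNames(rep(0, nrow(segs)), segs$segment_id)
  for (s in segs$segment_id) {
    cur <- s; d <- 0
    repeat {
      j <- which(segs$segment_id == cur)
      d <- d + segs$length_m[j]
      if (is.na(segs$parent_id[j])) break
      cur <- segs$parent_id[j]
    }
    depth[s] <- d
  }
  leaves <- setdiff(segs$segment_id, segs$parent_id[!is.na(segs$parent_id)])
  landmarks <- vapply(c("LAD", "LCX", "RCA"), function(tt) {
    cand <- intersect(leaves, segs$segment_id[segs$territory == tt])
    if (length(cand) == 0) return(NA_real_)
    nd <- cand[which.max(depth[cand])]
    ffr[[nd]]
  }, numeric(1))
  structure(list(nodes = nodes_tbl, landmarks = landmarks,
                 t_eval = beat$times[idx], p_inlet_mmHg = p_inlet),
            class = "ffr_field")
}

#' @export
print.ffr_field <- function(x, ...) {
  cat(sprintf("<ffr_field> at t = %.3f s (P_inlet %.1f mmHg)\n",
              x$t_eval, x$p_inlet_mmHg))
  cat(sprintf("  landmarks: LAD %.3f, LCX %.3f, RCA %.3f\n",
              x$landmarks[["LAD"]], x$landmarks[["LCX"]],
              x$landmarks[["RCA"]]))
  invisible(x)
}

#' @export
tidy.ffr_field <- function(x, ...) x$nodes

#' @export
glance.ffr_field <- function(x, ...) {
  tibble(t_eval_s = x$t_eval, p_inlet_mmHg = x$p_inlet_mmHg,
         ffr_lad = x$landmarks[["LAD"]], ffr_lcx = x$landmarks[["LCX"]],
         ffr_rca = x$landmarks[["RCA"]])
}

#' @export
autoplot.ffr_field <- function(object, ...) {
  df <- tibble(artery = names(object$landmarks),
               ffr = unname(object$landmarks))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$artery, y = .data$ffr)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2, colour = "#b2182b") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(y = "FFR (landmark)", x = NULL) +
    ggplot2::theme_minimal()
}
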