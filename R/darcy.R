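# Three-compartment Darcy perfusion on a voxelized myocardial slab.
#
# Compartments: 1 small arteries, 2 arterioles, 3 capillaries. In each
# voxel, with conductivity K_i (m^2 Pa^-1 s^-1), exchange conductances
# beta12, beta23 and venous drain gamma (Pa^-1 s^-1):
#
#   -div(K1 grad p1) = g - beta12 (p1 - p2)
#   -div(K2 grad p2) = beta12 (p1 - p2) - beta23 (p2 - p3)
#   -div(K3 grad p3) = beta23 (p2 - p3) - gamma (p3 - p_veins)
#
# discretized with cell-centered finite volumes on a uniform grid with
# zero-flux boundary conditions on every external face. Pressures are Pa
# internally, mmHg at all interfaces; the source g is volumetric inflow
# per tissue volume (s^-1).

#' Voxelized myocardial slab
#'
#' @param nx,ny,nz Voxel counts per axis (>= 2).
#' @param h Voxel edge length in metres.
#' @param density Tissue density in g/mL.
#' @return A list of class `darcy_grid` with derived totals: voxel count
#'   `n`, `volume_ml`, `mass_g`.
#' @examples
#' darcy_grid(20, 20, 10, h = 2e-3)
#' @export
darcy_grid <- function(nx, ny, nz, h = 2e-3, density = 1.05) {
  if (any(c(nx, ny, nz) < 2)) stop_validation("nx, ny, nz must be >= 2")
  if (h <= 0 || density <= 0) stop_validation("h and density must be positive")
  n <- nx * ny * nz
  vol_m3 <- n * h^3
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz), h = h, density = density, n = n,
                 voxel_volume_m3 = h^3, volume_ml = vol_m3 * 1e6,
                 mass_g = vol_m3 * 1e6 * density),
            class = "darcy_grid")
}

#' @export
print.darcy_grid <- function(x, ...) {
  cat(sprintf("<darcy_grid> %d x %d x %d voxels, h = %.3g m (%.1f mL, %.1f g)\n",
              x$nx, x$ny, x$nz, x$h, x$volume_ml, x$mass_g))
  invisible(x)
}

#' Darcy model parameters
#'
#' Defaults are the literature values used for every simulated patient:
#' conductivities `K_i = 2e-9` m^2 Pa^-1 s^-1, exchange conductances
#' `beta12 = 2.5e-5`, `beta23 = 1.25e-5` Pa^-1 s^-1, venous drain
#' `gamma = 3e-5` Pa^-1 s^-1 and venous pressure 5 mmHg.
#'
#' @param k1,k2,k3 Compartment hydraulic conductivities, m^2 Pa^-1 s^-1.
#' @param beta12,beta23 Inter-compartment conductances, Pa^-1 s^-1.
#' @param gamma Venous drain conductance, Pa^-1 s^-1.
#' @param p_veins Venous pressure, mmHg.
#' @return A list of class `darcy_params`.
#' @export
darcy_params <- function(k1 = 2e-9, k2 = 2e-9, k3 = 2e-9,
                         beta12 = 2.5e-5, beta23 = 1.25e-5,
                         gamma = 3e-5, p_veins = 5) {
  vals <- c(k1, k2, k3, beta12, beta23, gamma)
  if (any(!is.finite(vals) | vals <= 0)) {
    stop_validation("all Darcy coefficients must be positive")
  }
  structure(list(k1 = k1, k2 = k2, k3 = k3, beta12 = beta12,
                 beta23 = beta23, gamma = gamma, p_veins = p_veins),
            class = "darcy_params")
}

#' @export
print.darcy_params <- function(x, ...) {
  cat(sprintf(paste0("<darcy_params> K = (%.3g, %.3g, %.3g) m^2/Pa/s, ",
                     "beta12 = %.3g, beta23 = %.3g, gamma = %.3g /Pa/s, ",
                     "p_veins = %.3g mmHg\n"),
              x$k1, x$k2, x$k3, x$beta12, x$beta23, x$gamma, x$p_veins))
  invisible(x)
}

#' Total series microvascular conductance
#'
#' The harmonic (series) combination of the two exchange conductances and
#' the venous drain, `1 / (1/beta12 + 1/beta23 + 1/gamma)`: the overall
#' conductance a uniform pressure head sees through the compartment chain.
#'
#' @param params A [darcy_params()].
#' @return Conductance in Pa^-1 s^-1.
#' @export
total_conductance <- function(params) {
  1 / (1 / params$beta12 + 1 / params$beta23 + 1 / params$gamma)
}

# 7-point graph Laplacian of the structured grid (N x N, unscaled)
grid_laplacian <- function(grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  idx <- function(i, j, k) i + (j - 1) * nx + (k - 1) * nx * ny
  from <- integer(0); to <- integer(0)
  # x-faces
  if (nx > 1) {
    g <- expand.grid(i = 1:(nx - 1), j = 1:ny, k = 1:nz)
    from <- c(from, idx(g$i, g$j, g$k)); to <- c(to, idx(g$i + 1, g$j, g$k))
  }
  if (ny > 1) {
    g <- expand.grid(i = 1:nx, j = 1:(ny - 1), k = 1:nz)
    from <- c(from, idx(g$i, g$j, g$k)); to <- c(to, idx(g$i, g$j + 1, g$k))
  }
  if (nz > 1) {
    g <- expand.grid(i = 1:nx, j = 1:ny, k = 1:(nz - 1))
    from <- c(from, idx(g$i, g$j, g$k)); to <- c(to, idx(g$i, g$j, g$k + 1))
  }
  n <- grid$n
  A <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from),
                            x = -1, dims = c(n, n))
  deg <- -Matrix::rowSums(A)
  A + Matrix::Diagonal(n, deg)
}

#' Assemble and factorize the Darcy operator
#'
#' Builds the symmetric positive-definite 3N x 3N system matrix and its
#' sparse Cholesky factorization, reusable across right-hand sides (the
#' matrix depends on the grid and parameters only, not on the source).
#'
#' @param grid A [darcy_grid()].
#' @param params A [darcy_params()].
#' @return A list of class `darcy_operator` holding the factorization.
#' @export
darcy_operator <- function(grid, params) {
  n <- grid$n
  L <- grid_laplacian(grid) / grid$h^2
  I <- Matrix::Diagonal(n)
  Z <- Matrix::Matrix(0, n, n, sparse = TRUE)
  b12 <- params$beta12; b23 <- params$beta23; gam <- params$gamma
  A <- rbind(
    cbind(params$k1 * L + b12 * I, -b12 * I, Z),
    cbind(-b12 * I, params$k2 * L + (b12 + b23) * I, -b23 * I),
    cbind(Z, -b23 * I, params$k3 * L + (b23 + gam) * I)
  )
  A <- Matrix::forceSymmetric(A)
  structure(list(grid = grid, params = params, A = A,
                 norm_A = Matrix::norm(A, "F"),
                 chol = Matrix::Cholesky(A, LDL = FALSE)),
            class = "darcy_operator")
}

#' Solve the three-compartment Darcy system
#'
#' @param grid A [darcy_grid()].
#' @param params A [darcy_params()].
#' @param g Source field in s^-1: scalar (uniform) or a vector of length
#'   `grid$n`, ordered x-fastest. Volumetric inflow into compartment 1 per
#'   tissue volume.
#' @param op Optional precomputed [darcy_operator()] (must match `grid` and
#'   `params`); avoids refactorizing in loops.
#' @return An object of class `darcy_state` with pressure fields `p1`,
#'   `p2`, `p3` (mmHg, length-`n` vectors), the source, the relative
#'   residual, total inflow (mL/min) and the MBF field (mL/min/100 g).
#' @examples
#' g <- darcy_grid(4, 4, 4)
#' st <- solve_darcy(g, darcy_params(), g = 0.0175)
#' glance(st)
#' @export
solve_darcy <- function(grid, params, g, op = NULL) {
  n <- grid$n
  if (length(g) == 1) g <- rep(g, n)
  if (length(g) != n || !all(is.finite(g))) {
    stop_validation("g must be finite, scalar or length grid$n")
  }
  if (is.null(op)) op <- darcy_operator(grid, params)
  pv_pa <- mmhg_to_pa(params$p_veins)
  rhs <- c(g, rep(0, n), rep(params$gamma * pv_pa, n))
  x <- as.numeric(Matrix::solve(op$chol, rhs))
  rhs_norm <- max(sqrt(sum(rhs^2)), .Machine$double.eps)
  res <- NA_real_
  # iterative refinement; convergence measured by the normwise backward
  # error, which stays meaningful when the conductances are scaled far
  # below the diffusion terms and ||A|| ||x|| >> ||b||
  for (pass in 1:5) {
    r <- rhs - as.numeric(op$A %*% x)
    res <- sqrt(sum(r^2)) /
      (op$norm_A * sqrt(sum(x^2)) + rhs_norm)
    if (res <= 1e-12) break
    x <- x + as.numeric(Matrix::solve(op$chol, r))
  }
  if (!is.finite(res) || res > 1e-10) {
    stop_numerical(sprintf("Darcy solve did not converge: relative residual %.3g", res))
  }
  p1 <- x[1:n]; p2 <- x[(n + 1):(2 * n)]; p3 <- x[(2 * n + 1):(3 * n)]
  drain <- params$gamma * (p3 - pv_pa)              # s^-1 per voxel
  mbf <- drain * 6000 / grid$density                # mL/min/100 g
  structure(
    list(grid = grid, params = params, g = g,
         p1 = pa_to_mmhg(p1), p2 = pa_to_mmhg(p2), p3 = pa_to_mmhg(p3),
         residual = res,
         total_inflow_ml_min = sum(g) * grid$voxel_volume_m3 * 1e6 * 60,
         total_drain_ml_min = sum(drain) * grid$voxel_volume_m3 * 1e6 * 60,
         mbf = mbf),
    class = "darcy_state"
  )
}

#' @export
print.darcy_state <- function(x, ...) {
  cat(sprintf("<darcy_state> inflow %.2f mL/min, mean MBF %.1f mL/min/100g, residual %.2g\n",
              x$total_inflow_ml_min, mean(x$mbf), x$residual))
  invisible(x)
}

#' Myocardial blood flow field
#'
#' MBF is defined as the venous drainage per tissue volume,
#' `gamma * (p3 - p_veins)` (s^-1), converted to mL/min per 100 g through
#' the tissue density.
#'
#' @param state A solved [solve_darcy()] state.
#' @return A list with the voxel `field` (mL/min/100 g) and its spatial
#'   `mean`.
#' @export
compute_mbf <- function(state) {
  list(field = state$mbf, mean = mean(state$mbf))
}

#' @export
tidy.darcy_state <- function(x, ...) {
  grid <- x$grid
  ijk <- expand.grid(i = seq_len(grid$nx), j = seq_len(grid$ny),
                     k = seq_len(grid$nz))
  tibble(i = ijk$i, j = ijk$j, k = ijk$k,
         p1_mmHg = x$p1, p2_mmHg = x$p2, p3_mmHg = x$p3,
         g_per_s = x$g, mbf_ml_min_100g = x$mbf)
}

#' @export
glance.darcy_state <- function(x, ...) {
  tibble(total_inflow_ml_min = x$total_inflow_ml_min,
         total_drain_ml_min = x$total_drain_ml_min,
         inflow_per_g_ml_min = x$total_inflow_ml_min / x$grid$mass_g,
         mean_mbf_ml_min_100g = mean(x$mbf),
         mean_p1_mmHg = mean(x$p1), mean_p2_mmHg = mean(x$p2),
         mean_p3_mmHg = mean(x$p3), residual = x$residual)
}

#' @export
autoplot.darcy_state <- function(object, slice = NULL, ...) {
  df <- tidy(object)
  slice <- slice %||% ceiling(object$grid$nz / 2)
  df <- dplyr::filter(df, .data$k == slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$mbf_ml_min_100g)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "MBF\n(mL/min/100g)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("MBF, slice k = %d", slice)) +
    ggplot2::theme_minimal()
}

#' Pressure-drop distribution across compartments
#'
#' Diagnostic report of how the total head from mean compartment-1
#' pressure down to the veins splits across the two exchanges and the
#' venous drain.
#'
#' @param state A solved `darcy_state`.
#' @return A tibble with per-stage mean pressure drops (mmHg) and their
#'   fractions of the total.
#' @export
pressure_drop_report <- function(state) {
  d12 <- mean(state$p1 - state$p2)
  d23 <- mean(state$p2 - state$p3)
  d3v <- mean(state$p3 - state$params$p_veins)
  tot <- d12 + d23 + d3v
  tibble(stage = c("arteries->arterioles", "arterioles->capillaries",
                   "capillaries->veins"),
         drop_mmHg = c(d12, d23, d3v),
         fraction = c(d12, d23, d3v) / tot)
}

#' Scale calibrated resting conductances to hyperemia
#'
#' Multiplies `beta12`, `beta23` and `gamma` by `factor` (default 4), so
#' that by homogeneity the total series conductance is `factor` times its
#' resting value, emulating maximal microvascular vasodilation.
#' Conductivities and venous pressure are unchanged.
#'
#' @param params Calibrated resting [darcy_params()].
#' @param factor Conductance multiplier.
#' @return New `darcy_params`.
#' @export
scale_to_stress <- function(params, factor = 4) {
  if (factor <= 0) stop_validation("factor must be positive")
  darcy_params(k1 = params$k1, k2 = params$k2, k3 = params$k3,
               beta12 = params$beta12 * factor,
               beta23 = params$beta23 * factor,
               gamma = params$gamma * factor,
               p_veins = params$p_veins)
}

# scale the three conductances by lambda
scale_conductances <- function(params, lambda) scale_to_stress(params, lambda)

#' Blinded resting calibration of the microvascular conductances
#'
#' Finds a single multiplicative factor lambda on (`beta12`, `beta23`,
#' `gamma`) such that the coupled coronary-tree/Darcy steady state at the
#' resting driving pressure delivers the target arterial inflow per gram
#' of tissue (default 1 mL/min/g, the angiographically-normal resting
#' value). Only this population target is used - no stress-perfusion data.
#'
#' @param grid A [darcy_grid()].
#' @param params Base [darcy_params()].
#' @param tree A [coronary_tree()] supplying the slab.
#' @param inlet_pressure_mmHg Steady resting driving pressure at the
#'   coronary ostia (typically the time-average of the resting effective
#'   pressure).
#' @param target_inflow Target inflow, mL min^-1 g^-1.
#' @param tol Relative tolerance on the achieved inflow.
#' @param lambda_range Bracket for the bisection.
#' @return A list: calibrated `params`, `lambda`, achieved
#'   `inflow_per_g_ml_min`, the final coupled `state`, and the bisection
#'   `trace` tibble.
#' @export
calibrate_rest <- function(grid, params, tree, inlet_pressure_mmHg,
                           target_inflow = 1.0, tol = 0.005,
                           lambda_range = c(1e-4, 1e4)) {
  inflow_at <- function(lambda) {
    p <- scale_conductances(params, lambda)
    st <- steady_coupled_state(tree, grid, p, inlet_pressure_mmHg)
    st$darcy$total_inflow_ml_min / grid$mass_g
  }
  lo <- lambda_range[1]; hi <- lambda_range[2]
  f_lo <- inflow_at(lo); f_hi <- inflow_at(hi)
  if ((f_lo - target_inflow) * (f_hi - target_inflow) > 0) {
    stop_numerical(sprintf(
      "target inflow %.3g mL/min/g unreachable for lambda in [%g, %g] (attainable range %.3g-%.3g)",
      target_inflow, lo, hi, f_lo, f_hi))
  }
  trace <- tibble(iteration = integer(), lambda = numeric(),
                  inflow_per_g_ml_min = numeric())
  lambda <- NA_real_; f_mid <- NA_real_
  for (it in 1:80) {
    lambda <- sqrt(lo * hi)       # bisection in log space (inflow is monotone)
    f_mid <- inflow_at(lambda)
    trace <- dplyr::bind_rows(trace, tibble(iteration = it, lambda = lambda,
                                            inflow_per_g_ml_min = f_mid))
    if (abs(f_mid - target_inflow) <= tol * target_inflow) break
    if ((f_mid - target_inflow) * (f_lo - target_inflow) > 0) {
      lo <- lambda; f_lo <- f_mid
    } else {
      hi <- lambda
    }
  }
  if (abs(f_mid - target_inflow) > tol * target_inflow) {
    stop_numerical("resting calibration did not converge in 80 bisection steps")
  }
  cal <- scale_conductances(params, lambda)
  st <- steady_coupled_state(tree, grid, cal, inlet_pressure_mmHg)
  list(params = cal, lambda = lambda,
       inflow_per_g_ml_min = st$darcy$total_inflow_ml_min / grid$mass_g,
       state = st, trace = trace)
}
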