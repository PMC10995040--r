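# Shared fixtures: a reference synthetic patient, small grids, and
# independent dense oracles for the Darcy and network solvers.

test_patient <- function(sex = "male") {
  patient_record(age = 60, sex = sex, height = if (sex == "male") 175 else 165,
                 weight = 75, hr = 70, p_sys = 120, p_dia = 80,
                 lv_mass = 160)
}

# Independent dense assembly of the three-compartment finite-volume system:
# explicit voxel loops, no shared code with the package's sparse assembler.
dense_darcy_solve <- function(grid, params, g) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz; h <- grid$h
  n <- nx * ny * nz
  idx <- function(i, j, k) i + (j - 1) * nx + (k - 1) * nx * ny
  ks <- c(params$k1, params$k2, params$k3)
  A <- matrix(0, 3 * n, 3 * n)
  for (k in 1:nz) for (j in 1:ny) for (i in 1:nx) {
    v <- idx(i, j, k)
    nbrs <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                 c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (comp in 1:3) {
      row <- (comp - 1) * n + v
      for (nb in nbrs) {
        if (nb[1] >= 1 && nb[1] <= nx && nb[2] >= 1 && nb[2] <= ny &&
              nb[3] >= 1 && nb[3] <= nz) {
          w <- idx(nb[1], nb[2], nb[3])
          col <- (comp - 1) * n + w
          A[row, row] <- A[row, row] + ks[comp] / h^2
          A[row, col] <- A[row, col] - ks[comp] / h^2
        }
      }
    }
    # exchange terms
    A[v, v] <- A[v, v] + params$beta12
    A[v, n + v] <- A[v, n + v] - params$beta12
    A[n + v, n + v] <- A[n + v, n + v] + params$beta12 + params$beta23
    A[n + v, v] <- A[n + v, v] - params$beta12
    A[n + v, 2 * n + v] <- A[n + v, 2 * n + v] - params$beta23
    A[2 * n + v, 2 * n + v] <- A[2 * n + v, 2 * n + v] +
      params$beta23 + params$gamma
    A[2 * n + v, n + v] <- A[2 * n + v, n + v] - params$beta23
  }
  pv_pa <- params$p_veins * 133.322
  rhs <- c(g, rep(0, n), rep(params$gamma * pv_pa, n))
  x <- solve(A, rhs)
  list(p1 = x[1:n] / 133.322, p2 = x[(n + 1):(2 * n)] / 133.322,
       p3 = x[(2 * n + 1):(3 * n)] / 133.322)
}

# Independent dense nodal oracle for the resistive network: assembles the
# full (Dirichlet rows included) linear system node by node and solves it.
dense_network_solve <- function(tree, inlet_pressure, terminal_pressures) {
  segs <- tree$segments
  roots <- segs$segment_id[is.na(segs$parent_id)]
  leaves <- setdiff(segs$segment_id, segs$parent_id[!is.na(segs$parent_id)])
  nodes <- c(paste0("inlet:", roots), segs$segment_id)
  n <- length(nodes)
  # per-segment resistance with stenoses, recomputed independently
  res <- numeric(nrow(segs))
  for (e in seq_len(nrow(segs))) {
    L <- segs$length_m[e]; r <- segs$radius_m[e]
    Rfun <- function(l, rr) 8 * tree$viscosity * l / (pi * rr^4)
    if (!is.null(tree$stenoses) &&
          segs$segment_id[e] %in% tree$stenoses$segment_id) {
      st <- tree$stenoses[tree$stenoses$segment_id == segs$segment_id[e], ]
      res[e] <- Rfun(L * st$length_frac, r * (1 - st$radius_reduction_frac)) +
        Rfun(L * (1 - st$length_frac) + 1e-300, r)
    } else {
      res[e] <- Rfun(L, r)
    }
  }
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  b <- setNames(rep(0, n), nodes)
  for (nd in nodes) {
    if (nd %in% paste0("inlet:", roots)) {
      M[nd, nd] <- 1; b[nd] <- inlet_pressure * 133.322
    } else if (nd %in% leaves) {
      terr <- segs$territory[segs$segment_id == nd]
      val <- if (nd %in% names(terminal_pressures)) {
        terminal_pressures[[nd]]
      } else terminal_pressures[[terr]]
      M[nd, nd] <- 1; b[nd] <- val * 133.322
    } else {
      # Kirchhoff current balance
      for (e in seq_len(nrow(segs))) {
        from <- if (is.na(segs$parent_id[e])) {
          paste0("inlet:", segs$segment_id[e])
        } else segs$parent_id[e]
        to <- segs$segment_id[e]
        gcond <- 1 / res[e]
        if (from == nd) {
          M[nd, nd] <- M[nd, nd] + gcond; M[nd, to] <- M[nd, to] - gcond
        }
        if (to == nd) {
          M[nd, nd] <- M[nd, nd] + gcond; M[nd, from] <- M[nd, from] - gcond
        }
      }
    }
  }
  p <- solve(M, b)
  setNames(p / 133.322, nodes)
}

# random small tree for oracle comparison: a chain/branching topology with
# physiologic-ish dimensions, fully determined by the seed
random_test_tree <- function(n_segments = 10, seed = 1) {
  stopifnot(n_segments >= 3)
  set.seed(seed)
  ids <- paste0("S", seq_len(n_segments))
  parent <- c(NA, vapply(2:n_segments, function(i) {
    ids[sample.int(i - 1, 1)]
  }, character(1)))
  terr <- sample(c("LAD", "LCX", "RCA"), n_segments, replace = TRUE)
  segs <- tibble::tibble(
    segment_id = ids, parent_id = parent,
    length_m = runif(n_segments, 0.01, 0.05),
    radius_m = runif(n_segments, 1e-3, 2.5e-3),
    territory = terr
  )
  coronary_tree(segs)
}
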