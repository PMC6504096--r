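#' Poisson-Boltzmann grid configuration
#'
#' @param grid_spacing lattice spacing, Angstrom.
#' @param padding clearance between the solute extent and the box faces,
#'   Angstrom (at least 5).
#' @param epsilon_in,epsilon_out solute and solvent dielectric constants.
#' @param sor_tolerance convergence threshold on the maximum potential
#'   update per sweep (e/Angstrom units).
#' @param max_iterations sweep budget before the solver errors out.
#' @param omega over-relaxation factor; chosen from the grid dimension
#'   when `NULL`.
#' @return list of class `pb_config`.
#' @export
pb_config <- function(grid_spacing = 0.4, padding = 8, epsilon_in = 1,
                      epsilon_out = 80, sor_tolerance = 1e-6,
                      max_iterations = 5000, omega = NULL) {
  if (grid_spacing <= 0) abort("grid_spacing must be > 0")
  if (padding < 5) abort("padding must be >= 5 Angstrom")
  if (sor_tolerance <= 0) abort("sor_tolerance must be > 0")
  structure(list(grid_spacing = grid_spacing, padding = padding,
                 epsilon_in = epsilon_in, epsilon_out = epsilon_out,
                 sor_tolerance = sor_tolerance,
                 max_iterations = max_iterations, omega = omega),
            class = "pb_config")
}

#' Finite-difference Poisson-Boltzmann polar solvation energy
#'
#' Solves the linearized Poisson-Boltzmann equation at zero ionic
#' strength (i.e. the Poisson equation with a two-dielectric map) on a
#' cubic lattice: the dielectric boundary is the van der Waals surface
#' (edge values are fractionally harmonic-averaged where an atom sphere
#' cuts an edge), charges are spread to the eight surrounding nodes by
#' trilinear weighting, boundary potentials are Coulombic in the outer
#' dielectric, and the interior is relaxed by red-black successive
#' over-relaxation. The reaction energy is the two-solve difference
#' `G_pol = 1/2 sum_i q_i (phi_solvated - phi_uniform)(x_i)`, which
#' cancels the grid self-energy artifact.
#'
#' @param atoms atom tibble (single model).
#' @param config a [pb_config()].
#' @return polar solvation energy, kcal/mol.
#' @export
pb_polar <- function(atoms, config = pb_config()) {
  .assert_atoms(atoms)
  if (all(atoms$charge == 0)) return(0)
  phi_solv <- .pb_solve(atoms, config, uniform = FALSE)
  phi_vac <- .pb_solve(atoms, config, uniform = TRUE)
  0.5 * K_COULOMB * sum(atoms$charge * (phi_solv - phi_vac))
}

# one FD solve; returns potential interpolated at the atom positions
.pb_solve <- function(atoms, config, uniform) {
  h <- config$grid_spacing
  eps_in <- config$epsilon_in
  eps_out <- if (uniform) eps_in else config$epsilon_out
  xyz <- .xyz(atoms)
  ctr <- (apply(xyz, 2, max) + apply(xyz, 2, min)) / 2
  half <- max(.dist_inf(xyz, ctr) + atoms$radius) + config$padding
  m <- ceiling(half / h)
  n <- 2L * m + 1L
  ax <- (seq_len(n) - m - 1) * h    # grid axis, centred on the solute

  # edge dielectric maps (harmonic mixing by inside fraction)
  eps <- .pb_dielectric(atoms, ctr, ax, h, eps_in, eps_out, uniform)

  # node charges by trilinear spreading
  qn <- .pb_spread_charges(atoms, ctr, ax, h, n)

  # Coulomb boundary condition in the outer dielectric
  phi <- .pb_boundary(atoms, ctr, ax, n, eps_out)

  phi <- .pb_sor(phi, eps, qn, h, config)

  # trilinear interpolation back to atom positions
  .pb_interp(phi, atoms, ctr, ax, h)
}

.dist_inf <- function(xyz, ctr) {
  apply(abs(sweep(xyz, 2, ctr)), 1, max)
}

# fraction of each lattice edge inside the solute, turned into a
# harmonically mixed edge dielectric; returns list(x, y, z) arrays
.pb_dielectric <- function(atoms, ctr, ax, h, eps_in, eps_out, uniform) {
  n <- length(ax)
  if (uniform) {
    e <- array(eps_in, dim = c(n, n, n))
    return(list(x = e, y = e, z = e))
  }
  fx <- array(0, dim = c(n, n, n))   # inside fraction of edge (i,i+1)
  fy <- fx; fz <- fx
  rel <- sweep(.xyz(atoms), 2, ctr)
  for (a in seq_len(nrow(rel))) {
    R <- atoms$radius[a]
    if (R <= 0) next
    p <- rel[a, ]
    ir <- lapply(1:3, function(k) {
      which(ax >= p[k] - R - h & ax <= p[k] + R + h)
    })
    if (any(lengths(ir) == 0)) next
    dx <- ax[ir[[1]]] - p[1]; dy <- ax[ir[[2]]] - p[2]; dz <- ax[ir[[3]]] - p[3]
    # node distances within the bounding sub-box
    d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
    dn <- sqrt(d2)
    # edge inside-fractions from node distances (linear interpolation of
    # the crossing point; edges clipped without containing a node are
    # neglected, a documented vdW-surface discretisation)
    fx[ir[[1]][-length(ir[[1]])], ir[[2]], ir[[3]]] <-
      pmax(fx[ir[[1]][-length(ir[[1]])], ir[[2]], ir[[3]]],
           .edge_frac(dn[-dim(dn)[1], , , drop = FALSE],
                      dn[-1, , , drop = FALSE], R))
    fy[ir[[1]], ir[[2]][-length(ir[[2]])], ir[[3]]] <-
      pmax(fy[ir[[1]], ir[[2]][-length(ir[[2]])], ir[[3]]],
           .edge_frac(dn[, -dim(dn)[2], , drop = FALSE],
                      dn[, -1, , drop = FALSE], R))
    fz[ir[[1]], ir[[2]], ir[[3]][-length(ir[[3]])]] <-
      pmax(fz[ir[[1]], ir[[2]], ir[[3]][-length(ir[[3]])]],
           .edge_frac(dn[, , -dim(dn)[3], drop = FALSE],
                      dn[, , -1, drop = FALSE], R))
  }
  mix <- function(f) 1 / (f / eps_in + (1 - f) / eps_out)
  list(x = mix(fx), y = mix(fy), z = mix(fz))
}

# inside fraction of an edge given the sphere-centre distances of its
# two end nodes
.edge_frac <- function(d1, d2, R) {
  lo <- pmin(d1, d2); hi <- pmax(d1, d2)
  f <- (R - lo) / pmax(hi - lo, 1e-12)
  pmin(pmax(f, 0), 1)
}

.pb_spread_charges <- function(atoms, ctr, ax, h, n) {
  qn <- array(0, dim = c(n, n, n))
  rel <- sweep(.xyz(atoms), 2, ctr)
  for (a in seq_len(nrow(rel))) {
    q <- atoms$charge[a]
    if (q == 0) next
    t0 <- (rel[a, ] - ax[1]) / h
    i0 <- pmin(pmax(floor(t0) + 1L, 1L), n - 1L)
    w <- t0 - (i0 - 1L)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
      ii <- i0 + c(dx, dy, dz)
      qn[ii[1], ii[2], ii[3]] <- qn[ii[1], ii[2], ii[3]] + q * wt
    }
  }
  qn
}

.pb_boundary <- function(atoms, ctr, ax, n, eps_ref) {
  phi <- array(0, dim = c(n, n, n))
  rel <- sweep(.xyz(atoms), 2, ctr)
  q <- atoms$charge
  face <- function(ix, iy, iz) {
    g <- expand.grid(x = ax[ix], y = ax[iy], z = ax[iz])
    v <- numeric(nrow(g))
    for (a in seq_len(nrow(rel))) {
      r <- sqrt((g$x - rel[a, 1])^2 + (g$y - rel[a, 2])^2 +
                  (g$z - rel[a, 3])^2)
      v <- v + q[a] / (eps_ref * pmax(r, 1e-6))
    }
    array(v, dim = c(length(ix), length(iy), length(iz)))
  }
  all_i <- seq_len(n)
  phi[1, , ] <- face(1L, all_i, all_i)[1, , ]
  phi[n, , ] <- face(n, all_i, all_i)[1, , ]
  phi[, 1, ] <- face(all_i, 1L, all_i)[, 1, ]
  phi[, n, ] <- face(all_i, n, all_i)[, 1, ]
  phi[, , 1] <- face(all_i, all_i, 1L)[, , 1]
  phi[, , n] <- face(all_i, all_i, n)[, , 1]
  phi
}

# red-black SOR on the 7-point stencil of div(eps grad phi) = -4 pi rho
.pb_sor <- function(phi, eps, qn, h, config) {
  n <- dim(phi)[1]
  int <- 2:(n - 1)
  src <- 4 * pi * qn[int, int, int] / h
  ex_m <- eps$x[int - 1, int, int]; ex_p <- eps$x[int, int, int]
  ey_m <- eps$y[int, int - 1, int]; ey_p <- eps$y[int, int, int]
  ez_m <- eps$z[int, int, int - 1]; ez_p <- eps$z[int, int, int]
  diag_e <- ex_m + ex_p + ey_m + ey_p + ez_m + ez_p
  idx <- expand.grid(i = int, j = int, k = int)
  red <- array((idx$i + idx$j + idx$k) %% 2 == 0, dim = rep(n - 2, 3))
  omega <- config$omega %||% (2 / (1 + sin(pi / n)))
  nb_sum <- function(p) {
    ex_m * p[int - 1, int, int] + ex_p * p[int + 1, int, int] +
      ey_m * p[int, int - 1, int] + ey_p * p[int, int + 1, int] +
      ez_m * p[int, int, int - 1] + ez_p * p[int, int, int + 1]
  }
  for (it in seq_len(config$max_iterations)) {
    delta <- 0
    for (mask in list(red, !red)) {
      new_int <- (nb_sum(phi) + src) / diag_e
      cur <- phi[int, int, int]
      upd <- cur + omega * (new_int - cur)
      delta <- max(delta, max(abs(upd[mask] - cur[mask])))
      cur[mask] <- upd[mask]
      phi[int, int, int] <- cur
    }
    if (delta < config$sor_tolerance) return(phi)
  }
  res <- max(abs(nb_sum(phi) + src - diag_e * phi[int, int, int]))
  abort(sprintf("PB solver did not converge in %d iterations (residual %.3e)",
                config$max_iterations, res))
}

.pb_interp <- function(phi, atoms, ctr, ax, h) {
  n <- dim(phi)[1]
  rel <- sweep(.xyz(atoms), 2, ctr)
  out <- numeric(nrow(rel))
  for (a in seq_len(nrow(rel))) {
    t0 <- (rel[a, ] - ax[1]) / h
    i0 <- pmin(pmax(floor(t0) + 1L, 1L), n - 1L)
    w <- t0 - (i0 - 1L)
    v <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
      ii <- i0 + c(dx, dy, dz)
      v <- v + wt * phi[ii[1], ii[2], ii[3]]
    }
    out[a] <- v
  }
  out
}
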