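#' Generalized Born model configuration
#'
#' Parameters of the effective-radius calculation. The OBC defaults are
#' the model-II tanh coefficients (alpha 1.0, beta 0.8, gamma 4.85) with
#' a 0.09 A radius offset and the classic per-element descreening
#' scaling factors. The GBn defaults use that model's published tanh
#' coefficients, offset, neck scaling and element screens; its neck
#' correction parameters (position and height of the interatomic neck
#' integral) are computed numerically on first use and memoised (see
#' the methods vignette).
#'
#' @param model `"OBC"` or `"GBn"`.
#' @param radius_offset intrinsic-radius reduction, Angstrom.
#' @param alpha,beta,gamma tanh rescaling coefficients.
#' @param screen named vector of per-element descreening scale factors;
#'   the `default` entry covers unlisted elements.
#' @param s_neck neck-correction scaling (GBn only).
#' @param probe_radius water probe radius used by the neck integral, A.
#' @return list of class `gb_config`.
#' @export
gb_config <- function(model = c("OBC", "GBn"), radius_offset = NULL,
                      alpha = NULL, beta = NULL, gamma = NULL,
                      screen = NULL, s_neck = NULL, probe_radius = 1.4) {
  model <- match.arg(model)
  def <- if (model == "OBC") {
    list(radius_offset = 0.09, alpha = 1.0, beta = 0.8, gamma = 4.85,
         screen = c(H = 0.85, C = 0.72, N = 0.79, O = 0.85, S = 0.96,
                    P = 0.86, default = 0.80),
         s_neck = 0)
  } else {
    list(radius_offset = 0.0195141, alpha = 1.09511284, beta = 1.90792938,
         gamma = 2.50798245,
         screen = c(H = 1.09085413633, C = 0.48435382330, N = 0.700147318409,
                    O = 1.06557401132, S = 0.602256336067, default = 0.5),
         s_neck = 0.361825)
  }
  out <- list(model = model,
              radius_offset = radius_offset %||% def$radius_offset,
              alpha = alpha %||% def$alpha,
              beta = beta %||% def$beta,
              gamma = gamma %||% def$gamma,
              screen = screen %||% def$screen,
              s_neck = s_neck %||% def$s_neck,
              probe_radius = probe_radius)
  if (out$radius_offset < 0) abort("radius_offset must be >= 0")
  structure(out, class = "gb_config")
}

.screen_factors <- function(atoms, config) {
  elem <- element_of(atoms$atom_name)
  s <- config$screen[elem]
  s[is.na(s)] <- config$screen[["default"]]
  unname(s)
}

#' Effective Born radii
#'
#' Per-atom burial measure entering the GB pairwise energy. The
#' descreening integral `I_i` is the standard pairwise analytic overlap
#' (Hawkins-Cramer-Truhlar) sum over neighbours with scaled reduced
#' radii; the OBC model then rescales through
#' `R_i^-1 = rho_i'^-1 - rho_i^-1 tanh(alpha Psi - beta Psi^2 + gamma
#' Psi^3)` with `rho_i' = rho_i - offset` and `Psi = I_i rho_i'`. The
#' GBn model adds the interatomic neck contribution to `I_i` before the
#' tanh rescaling. An isolated atom recovers `R = rho - offset`.
#'
#' @param atoms atom tibble (single model); all radii must be > offset.
#' @param config a [gb_config()].
#' @return numeric vector of effective radii, Angstrom.
#' @export
effective_born_radii <- function(atoms, config = gb_config("OBC")) {
  .assert_atoms(atoms)
  n <- nrow(atoms)
  rho_full <- atoms$radius
  rho <- rho_full - config$radius_offset
  if (any(rho <= 0)) abort("non-positive intrinsic radius after offset")
  if (n == 1) {
    psi <- 0
  } else {
    xyz <- .xyz(atoms)
    d <- .dist_mat(xyz, xyz)
    s <- .screen_factors(atoms, config)
    sr <- matrix(s * rho, n, n, byrow = TRUE)   # scaled reduced radius of j
    rho_i <- matrix(rho, n, n)                  # reduced radius of i (rows)
    U <- d + sr
    L <- pmax(abs(d - sr), rho_i)
    dd <- d; diag(dd) <- 1                      # avoid 0/0 on the diagonal
    h <- 0.5 * (1 / L - 1 / U +
                  0.25 * (dd - sr^2 / dd) * (1 / U^2 - 1 / L^2) +
                  0.5 * log(L / U) / dd)
    # engulfed case: atom i centre buried inside neighbour's scaled sphere
    engulf <- sr - d - rho_i > 0
    h[engulf] <- h[engulf] + (1 / rho_i[engulf] - 1 / L[engulf])
    h[rho_i >= U] <- 0                          # neighbour inside atom i
    diag(h) <- 0
    I <- rowSums(h)
    if (config$model == "GBn" && config$s_neck > 0) {
      I <- I + config$s_neck * .neck_sum(d, rho_full, config$probe_radius)
    }
    psi <- I * rho
  }
  r_inv <- 1 / rho - tanh(config$alpha * psi - config$beta * psi^2 +
                            config$gamma * psi^3) / rho_full
  r_inv <- pmax(r_inv, 1e-6)                    # guard extreme burial
  1 / r_inv
}

# sum of neck-correction contributions to the descreening integral of
# each atom; d is the full distance matrix, radii the intrinsic radii
.neck_sum <- function(d, radii, probe_radius) {
  n <- nrow(d)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (d[i, j] >= radii[i] + radii[j] + 2 * probe_radius) next
      p <- .neck_params(radii[i], radii[j], probe_radius)
      dd <- d[i, j] - p["d0"]
      out[i] <- out[i] + p["m0"] / (1 + 100 * dd^2 + 3e5 * dd^6)
    }
  }
  out
}

# position (d0) and height (m0) of the neck integral for a radius pair,
# from direct numerical quadrature of the defining integral; memoised
.neck_params <- function(ri, rj, rw = 1.4) {
  key <- sprintf("neck_%.3f_%.3f_%.2f", ri, rj, rw)
  hit <- .rr_cache[[key]]
  if (!is.null(hit)) return(hit)
  ds <- seq(max(ri, rj) + 0.1, ri + rj + 2 * rw - 0.05, by = 0.05)
  vals <- vapply(ds, function(d) .neck_integral(d, ri, rj, rw), numeric(1))
  k <- which.max(vals)
  # quadratic refinement around the grid maximum
  if (k > 1 && k < length(vals)) {
    y1 <- vals[k - 1]; y2 <- vals[k]; y3 <- vals[k + 1]
    denom <- y1 - 2 * y2 + y3
    shift <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    d0 <- ds[k] + shift * 0.05
    m0 <- .neck_integral(d0, ri, rj, rw)
  } else {
    d0 <- ds[k]; m0 <- vals[k]
  }
  out <- c(d0 = d0, m0 = m0)
  .rr_cache[[key]] <- out
  out
}

# exact neck integral: integral of 1/r^4 (r measured from atom i) over
# the solvent-excluded neck between two spheres, by midpoint quadrature
# in cylindrical coordinates (axis through both centres)
.neck_integral <- function(d, ri, rj, rw, h = 0.04) {
  Ri <- ri + rw; Rj <- rj + rw
  if (d >= ri + rj + 2 * rw) return(0)
  zs <- seq(-rw, d + rw, by = h)
  smax <- max(Ri, Rj)
  ss <- seq(h / 2, smax, by = h)
  g <- expand.grid(z = zs, s = ss)
  z <- g$z; s <- g$s
  di2 <- z^2 + s^2
  dj2 <- (z - d)^2 + s^2
  outside_atoms <- di2 > ri^2 & dj2 > rj^2
  # probe-centre exclusion: nearest allowed centre (outside both
  # inflated spheres) must be farther than rw for the point to be in
  # the solvent-excluded neck
  di <- sqrt(di2); dj <- sqrt(dj2)
  inside_both <- di < Ri & dj < Rj
  cand1 <- Ri - di                       # radial escape from sphere i
  p1x <- z * Ri / pmax(di, 1e-12); p1s <- s * Ri / pmax(di, 1e-12)
  ok1 <- (p1x - d)^2 + p1s^2 >= Rj^2
  cand2 <- Rj - dj
  p2x <- d + (z - d) * Rj / pmax(dj, 1e-12); p2s <- s * Rj / pmax(dj, 1e-12)
  ok2 <- p2x^2 + p2s^2 >= Ri^2
  # intersection circle of the two inflated spheres
  xc <- (d^2 + Ri^2 - Rj^2) / (2 * d)
  sc2 <- Ri^2 - xc^2
  dist_int <- if (sc2 > 0) {
    sc <- sqrt(sc2)
    sqrt((z - xc)^2 + (s - sc)^2)
  } else rep(Inf, length(z))
  dmin <- pmin(ifelse(ok1, cand1, Inf), ifelse(ok2, cand2, Inf), dist_int)
  in_neck <- outside_atoms & inside_both & (dmin > rw)
  if (!any(in_neck)) return(0)
  sum(2 * pi * s[in_neck] / di2[in_neck]^2) * h * h
}

#' Generalized Born polar solvation energy
#'
#' The Still pairwise expression
#' `-(k_C / 2) (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB` with
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`, including the
#' `i = j` Born self terms. For a single ion it reduces exactly to the
#' Born formula.
#'
#' @param atoms atom tibble.
#' @param radii effective Born radii; computed with
#'   [effective_born_radii()] when `NULL`.
#' @param epsilon_in,epsilon_out solute and solvent dielectric constants.
#' @param config [gb_config()] used when `radii` is `NULL`.
#' @return polar solvation energy, kcal/mol.
#' @export
gb_polar <- function(atoms, radii = NULL, epsilon_in = 1, epsilon_out = 80,
                     config = gb_config("OBC")) {
  .assert_atoms(atoms)
  if (is.null(radii)) radii <- effective_born_radii(atoms, config)
  if (length(radii) != nrow(atoms)) {
    abort("length of `radii` does not match the number of atoms")
  }
  if (all(atoms$charge == 0)) return(0)
  pref <- -0.5 * K_COULOMB * (1 / epsilon_in - 1 / epsilon_out)
  pref * sum(outer(atoms$charge, atoms$charge) / .fgb_mat(atoms, radii))
}

.fgb_mat <- function(atoms, radii) {
  xyz <- .xyz(atoms)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * tcrossprod(xyz)
  d2 <- pmax(d2, 0)
  rr <- outer(radii, radii)
  sqrt(d2 + rr * exp(-d2 / (4 * rr)))
}

#' Electrostatic size of a molecule
#'
#' Global size parameter `A` of the ALPB model. The default
#' bounding-sphere rule takes the radius of a sphere centred on the
#' centroid of the charged atoms that encloses them (including their
#' intrinsic radii). The structural-moments rule estimates `A` from the
#' second moment of the charged-atom positions (exact for a uniform
#' ball) plus the mean intrinsic radius.
#'
#' @param atoms atom tibble.
#' @param rule `"bounding-sphere"` or `"structural-moments"`.
#' @return electrostatic size in Angstrom.
#' @export
electrostatic_size <- function(atoms,
                               rule = c("bounding-sphere",
                                        "structural-moments")) {
  rule <- match.arg(rule)
  .assert_atoms(atoms)
  sel <- atoms$charge != 0
  if (!any(sel)) sel <- rep(TRUE, nrow(atoms))
  xyz <- .xyz(atoms[sel, , drop = FALSE])
  ctr <- colMeans(xyz)
  r2 <- rowSums(sweep(xyz, 2, ctr)^2)
  if (rule == "bounding-sphere") {
    max(sqrt(r2) + atoms$radius[sel])
  } else {
    sqrt(5 / 3 * mean(r2)) + mean(atoms$radius[sel])
  }
}

#' ALPB polar solvation energy
#'
#' The analytical linearized Poisson-Boltzmann correction to the GB
#' energy: with `beta = eps_in / eps_out` and electrostatic size `A`,
#' `G = -(k_C / 2) (1/eps_in - 1/eps_out) / (1 + alpha beta) *
#' sum_ij q_i q_j (1 / f_GB + alpha beta / A)`. In the `A -> Inf` limit
#' this tends to the plain GB energy divided by `(1 + alpha beta)`, and
#' for a Born ion with `A = R` it reproduces the Born energy exactly.
#'
#' @inheritParams gb_polar
#' @param alpha_alpb the ALPB constant (default 0.571412).
#' @param size_rule rule for the electrostatic size when `A` is `NULL`,
#'   see [electrostatic_size()].
#' @param A electrostatic size, Angstrom; must be > 0.
#' @return polar solvation energy, kcal/mol.
#' @export
alpb_polar <- function(atoms, radii = NULL, epsilon_in = 1,
                       epsilon_out = 80, alpha_alpb = 0.571412,
                       size_rule = c("bounding-sphere",
                                     "structural-moments"),
                       A = NULL, config = gb_config("OBC")) {
  .assert_atoms(atoms)
  if (alpha_alpb <= 0) abort("alpha_alpb must be > 0")
  if (is.null(radii)) radii <- effective_born_radii(atoms, config)
  if (length(radii) != nrow(atoms)) {
    abort("length of `radii` does not match the number of atoms")
  }
  if (is.null(A)) A <- electrostatic_size(atoms, match.arg(size_rule))
  if (!is.finite(A) && A > 0) A <- Inf
  if (A <= 0) abort("electrostatic size A must be > 0")
  if (all(atoms$charge == 0)) return(0)
  b <- epsilon_in / epsilon_out
  pref <- -0.5 * K_COULOMB * (1 / epsilon_in - 1 / epsilon_out) /
    (1 + alpha_alpb * b)
  qq <- outer(atoms$charge, atoms$charge)
  extra <- if (is.finite(A)) alpha_alpb * b / A else 0
  pref * sum(qq * (1 / .fgb_mat(atoms, radii) + extra))
}
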