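#' Solvent accessible surface area
#'
#' Sphere-point (Shrake-Rupley style) SASA with probe-inflated radii and
#' a deterministic golden-spiral point set: for each atom, the fraction
#' of points on its inflated sphere lying outside every neighbour's
#' inflated sphere times the sphere area. An isolated atom recovers
#' `4 pi (r + probe)^2` exactly up to point-count resolution.
#'
#' @param atoms atom tibble (single model), all radii > 0.
#' @param probe_radius probe radius, Angstrom (default water, 1.4).
#' @param n_points sphere points per atom (>= 32; default 960).
#' @return list with `per_atom` (numeric vector, Angstrom^2) and
#'   `total` (their sum).
#' @export
sasa <- function(atoms, probe_radius = 1.4, n_points = 960) {
  .assert_atoms(atoms)
  if (probe_radius < 0) abort("probe_radius must be >= 0")
  if (n_points < 32) abort("n_points must be >= 32")
  if (any(atoms$radius <= 0)) abort("all radii must be > 0 for SASA")
  pts <- .sphere_points(n_points)
  xyz <- .xyz(atoms)
  ri <- atoms$radius + probe_radius
  n <- nrow(atoms)
  d <- if (n > 1) .dist_mat(xyz, xyz) else matrix(0, 1, 1)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < ri[i] + ri & seq_len(n) != i)
    area_i <- 4 * pi * ri[i]^2
    if (length(nb) == 0) {
      per_atom[i] <- area_i
      next
    }
    p <- sweep(pts * ri[i], 2, xyz[i, ], `+`)
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      buried <- buried | dj2 < ri[j]^2
      if (all(buried)) break
    }
    per_atom[i] <- area_i * mean(!buried)
  }
  list(per_atom = per_atom, total = sum(per_atom))
}

#' Nonpolar solvation term from a surface area
#'
#' The linear surface-tension model `gamma * SASA + beta` with the Amber
#' convention defaults `gamma = 0.0072 kcal/(mol A^2)`, `beta = 0`.
#'
#' @param total_sasa surface area, Angstrom^2 (>= 0).
#' @param gamma surface tension coefficient, kcal/(mol Angstrom^2).
#' @param beta constant offset, kcal/mol.
#' @return nonpolar solvation energy, kcal/mol.
#' @export
nonpolar_term <- function(total_sasa, gamma = 0.0072, beta = 0) {
  if (any(total_sasa < 0)) abort("total_sasa must be >= 0")
  gamma * total_sasa + beta
}
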