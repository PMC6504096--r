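# Coulomb constant, kcal * Angstrom / (mol * e^2)
K_COULOMB <- 332.0637

# Bondi van der Waals radii by element (Angstrom); X = generic halogen
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                 X = 1.75)

# package-level cache (memoised templates, LJ table, neck parameters)
.rr_cache <- new.env(parent = emptyenv())

#' Infer the element of an atom from its name
#'
#' Strips digits and primes and takes the leading character, which is the
#' element for standard amino-acid heavy-atom names (`CA`, `OD1`, `NZ`,
#' `SG`, ...). Halogen two-letter names (`CL`, `BR`, `F`, `I`) map to the
#' generic halogen class `"X"`.
#'
#' @param atom_name character vector of atom names.
#' @return character vector of element symbols.
#' @export
element_of <- function(atom_name) {
  nm <- toupper(gsub("[0-9']", "", atom_name))
  out <- substr(nm, 1, 1)
  out[nm %in% c("CL", "BR", "F", "I")] <- "X"
  out
}

# squared distance matrix between two coordinate sets (n x 3 each)
.dist_mat <- function(xyz_a, xyz_b) {
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), `+`) -
    2 * tcrossprod(xyz_a, xyz_b)
  sqrt(pmax(d2, 0))
}

.xyz <- function(atoms) cbind(atoms$x, atoms$y, atoms$z)

# deterministic unit-sphere points on a golden spiral
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# rotation matrix about unit axis u by angle theta (Rodrigues)
.rot_axis <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * tcrossprod(u)
}

.assert_atoms <- function(atoms, arg = "atoms") {
  need <- c("atom_name", "x", "y", "z", "charge", "radius")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing atom columns: %s", arg,
                  paste(miss, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort(sprintf("`%s` contains no atoms", arg))
  invisible(atoms)
}
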