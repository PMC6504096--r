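#' Pairwise Coulomb energy between two atom sets
#'
#' Full pairwise sum (no cutoff) of the screened Coulomb interaction
#' between every atom of `atoms_a` and every atom of `atoms_b`:
#' `k_C * sum(q_i q_j / (eps_in * r_ij))` with
#' `k_C = 332.0637 kcal A / (mol e^2)`.
#'
#' @param atoms_a,atoms_b disjoint atom tibbles.
#' @param epsilon_in internal (solute) dielectric constant, > 0.
#' @return energy in kcal/mol.
#' @export
pairwise_electrostatic <- function(atoms_a, atoms_b, epsilon_in = 1) {
  .assert_atoms(atoms_a, "atoms_a"); .assert_atoms(atoms_b, "atoms_b")
  if (epsilon_in <= 0) abort("epsilon_in must be > 0")
  d <- .dist_mat(.xyz(atoms_a), .xyz(atoms_b))
  if (any(d < 1e-9)) abort("coincident atom pair (r = 0) in electrostatic sum")
  K_COULOMB * sum(outer(atoms_a$charge, atoms_b$charge) / d) / epsilon_in
}

#' Pairwise Lennard-Jones energy between two atom sets
#'
#' 12-6 potential with Lorentz-Berthelot combination
#' (`r_min = r_min_half_i + r_min_half_j`, `eps = sqrt(eps_i eps_j)`),
#' summed over all cross pairs with no cutoff.
#'
#' @inheritParams pairwise_electrostatic
#' @param lj_table parameter table (see [lj_default()]); every atom class
#'   present must be covered or an error names the missing class.
#' @return energy in kcal/mol.
#' @export
pairwise_vdw <- function(atoms_a, atoms_b, lj_table = lj_default()) {
  .assert_atoms(atoms_a, "atoms_a"); .assert_atoms(atoms_b, "atoms_b")
  pa <- .lj_params(atoms_a, lj_table)
  pb <- .lj_params(atoms_b, lj_table)
  d <- .dist_mat(.xyz(atoms_a), .xyz(atoms_b))
  r_min <- outer(pa$r_min_half, pb$r_min_half, `+`)
  eps <- sqrt(outer(pa$epsilon, pb$epsilon))
  s6 <- (r_min / d)^6
  sum(eps * (s6^2 - 2 * s6))
}

# internal nonbonded energy that tolerates near-coincident atoms
# (used by the minimiser and rotamer search, where clashes are expected)
.nb_energy <- function(xyz_a, q_a, lj_a, xyz_b, q_b, lj_b, epsilon_in) {
  d <- pmax(.dist_mat(xyz_a, xyz_b), 1e-6)
  e_ele <- K_COULOMB * sum(outer(q_a, q_b) / d) / epsilon_in
  r_min <- outer(lj_a$r_min_half, lj_b$r_min_half, `+`)
  eps <- sqrt(outer(lj_a$epsilon, lj_b$epsilon))
  s6 <- (r_min / d)^6
  e_ele + sum(eps * (s6^2 - 2 * s6))
}

#' Receptor-ligand gas-phase interaction energy
#'
#' Electrostatic and van der Waals terms of the binding free energy in
#' the single-trajectory convention. Because receptor and ligand
#' coordinates are sub-coordinates of the complex, intra-component terms
#' cancel in the complex-minus-parts difference and the result equals
#' the sum over receptor-by-ligand cross pairs only, which is what is
#' computed.
#'
#' @param complex atom tibble with a `component` column (or taggable by
#'   [tag_components()]).
#' @param split optional precomputed [split_complex()] result.
#' @param epsilon_in internal dielectric constant.
#' @param lj_table Lennard-Jones parameter table.
#' @return one-row tibble with columns `e_ele` and `e_vdw` (kcal/mol).
#' @export
interaction_energy <- function(complex, split = NULL, epsilon_in = 1,
                               lj_table = lj_default()) {
  if (is.null(split)) split <- split_complex(complex)
  tibble(
    e_ele = pairwise_electrostatic(split$receptor, split$ligand, epsilon_in),
    e_vdw = pairwise_vdw(split$receptor, split$ligand, lj_table)
  )
}
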