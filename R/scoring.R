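#' Binding free energy method specification
#'
#' Bundles the choices that define one end-state scoring method: the
#' polar solvation model (finite-difference PB, generalized Born OBC or
#' GBn, or ALPB), the internal dielectric (2 or 4 are the conventional
#' settings; 4 is the default), the nonpolar surface coefficients, and
#' the sampling tag. Entropy is always dropped and internal
#' (bond/angle/dihedral) terms cancel identically in the
#' single-trajectory scheme, so both are fixed at zero in every score.
#'
#' @param polar_method one of `"GB-OBC"`, `"PB"`, `"GBn"`, `"ALPB"`.
#' @param epsilon_in internal dielectric constant.
#' @param epsilon_out solvent dielectric constant.
#' @param gamma,beta nonpolar SASA coefficients, kcal/(mol A^2) and
#'   kcal/mol.
#' @param probe_radius,n_points SASA settings.
#' @param sampling `"single_structure"` or `"ensemble"` tag recorded in
#'   the output.
#' @param pb [pb_config()] used when `polar_method = "PB"` (its
#'   dielectrics are overridden by `epsilon_in`/`epsilon_out`).
#' @param gb [gb_config()] for the GB-based methods (`"GBn"` switches
#'   the default model).
#' @param alpha_alpb,size_rule ALPB parameters, see [alpb_polar()].
#' @return list of class `method_spec`.
#' @export
method_spec <- function(polar_method = c("GB-OBC", "PB", "GBn", "ALPB"),
                        epsilon_in = 4, epsilon_out = 80, gamma = 0.0072,
                        beta = 0, probe_radius = 1.4, n_points = 960,
                        sampling = c("single_structure", "ensemble"),
                        pb = NULL, gb = NULL, alpha_alpb = 0.571412,
                        size_rule = "bounding-sphere") {
  polar_method <- match.arg(polar_method)
  sampling <- match.arg(sampling)
  if (epsilon_in <= 0 || epsilon_out <= epsilon_in) {
    abort("need epsilon_out > epsilon_in > 0")
  }
  if (is.null(gb)) {
    gb <- gb_config(if (polar_method == "GBn") "GBn" else "OBC")
  }
  if (is.null(pb)) pb <- pb_config()
  pb$epsilon_in <- epsilon_in
  pb$epsilon_out <- epsilon_out
  structure(list(polar_method = polar_method, epsilon_in = epsilon_in,
                 epsilon_out = epsilon_out, gamma = gamma, beta = beta,
                 probe_radius = probe_radius, n_points = n_points,
                 sampling = sampling, pb = pb, gb = gb,
                 alpha_alpb = alpha_alpb, size_rule = size_rule),
            class = "method_spec")
}

# polar solvation energy of one molecule under a method spec
.polar_energy <- function(atoms, method) {
  switch(method$polar_method,
    "PB" = pb_polar(atoms, method$pb),
    "GB-OBC" = ,
    "GBn" = gb_polar(atoms, epsilon_in = method$epsilon_in,
                     epsilon_out = method$epsilon_out, config = method$gb),
    "ALPB" = alpb_polar(atoms, epsilon_in = method$epsilon_in,
                        epsilon_out = method$epsilon_out,
                        alpha_alpb = method$alpha_alpb,
                        size_rule = method$size_rule, config = method$gb)
  )
}

#' Single-structure binding free energy
#'
#' End-state estimate `dG_bind = G(complex) - G(receptor) - G(ligand)`
#' in the single-trajectory approximation: receptor and ligand
#' coordinates are taken from the complex, so the gas-phase interaction
#' reduces to the receptor-ligand cross terms, internal molecular
#' mechanics terms cancel exactly, and the entropy term is dropped. The
#' polar and nonpolar solvation differences are computed
#' complex-minus-parts with the chosen polar model and SASA.
#'
#' @param complex atom tibble with receptor/ligand tags (see
#'   [tag_components()]); a single model.
#' @param method a [method_spec()].
#' @param lj_table Lennard-Jones parameter table.
#' @return one-row tibble of class `binding_score` with `dg` and the
#'   breakdown `e_ele`, `e_vdw`, `e_internal` (0), `g_pol`, `g_np`,
#'   `entropy_term` (0); `dg` equals the row sum.
#' @export
binding_free_energy <- function(complex, method = method_spec(),
                                lj_table = lj_default()) {
  if (!"component" %in% names(complex)) complex <- tag_components(complex)
  if ("model" %in% names(complex) && length(unique(complex$model)) > 1) {
    abort("binding_free_energy() scores one model; see ensemble_binding_free_energy()")
  }
  parts <- split_complex(complex)
  mm <- interaction_energy(complex, parts, method$epsilon_in, lj_table)
  g_pol <- .polar_energy(complex, method) -
    .polar_energy(parts$receptor, method) -
    .polar_energy(parts$ligand, method)
  np <- function(a) nonpolar_term(sasa(a, method$probe_radius,
                                       method$n_points)$total,
                                  method$gamma, method$beta)
  g_np <- np(complex) - np(parts$receptor) - np(parts$ligand)
  out <- tibble(dg = mm$e_ele + mm$e_vdw + g_pol + g_np,
                e_ele = mm$e_ele, e_vdw = mm$e_vdw, e_internal = 0,
                g_pol = g_pol, g_np = g_np, entropy_term = 0)
  class(out) <- c("binding_score", class(out))
  attr(out, "method") <- method
  out
}

#' Ensemble (frame-averaged) binding free energy
#'
#' Arithmetic mean of the per-frame single-structure scores over the
#' models of a multi-model structure (e.g. the last frames of an
#' externally produced trajectory written as a multi-model PQR). The
#' breakdown is averaged componentwise.
#'
#' @param complex atom tibble with a `model` column; every model must
#'   contain the same atoms (name/chain/residue sequence).
#' @inheritParams binding_free_energy
#' @return one-row `binding_score` tibble; attribute `n_models` records
#'   the number of frames averaged.
#' @export
ensemble_binding_free_energy <- function(complex, method = method_spec(),
                                         lj_table = lj_default()) {
  if (!"component" %in% names(complex)) complex <- tag_components(complex)
  frames <- pqr_models(complex)
  key <- function(a) paste(a$chain_id, a$residue_number, a$atom_name,
                           collapse = "|")
  keys <- vapply(frames, key, character(1))
  if (length(unique(keys)) != 1) {
    abort("models differ in atom identity; cannot frame-average")
  }
  scores <- lapply(frames, binding_free_energy, method = method,
                   lj_table = lj_table)
  out <- dplyr::bind_rows(scores) %>%
    summarise(across(dplyr::everything(), mean))
  class(out) <- c("binding_score", class(out))
  attr(out, "method") <- method
  attr(out, "n_models") <- length(frames)
  out
}

#' Score a mutation panel against a wild-type complex
#'
#' Builds each variant by grafting its substitutions onto the wild-type
#' complex ([graft_mutation()], with rotamer selection and clash
#' relief) and scores every structure, wild type included, with
#' [binding_free_energy()]. Panel positions may be expressed in a
#' reference numbering convention; supply `map` to translate them to
#' the structure's own numbering. A mutation site is grafted at every
#' receptor residue matching its (translated) number and source
#' residue, so multimers with repeated chains are handled naturally.
#'
#' @param complex wild-type atom tibble with component tags.
#' @param panel tibble with columns `variant_id` and `mutations`
#'   (strings like `"P197A"`, `"P197A+W574L"`, `"WT"`); an optional
#'   `label` column is carried through.
#' @param method a [method_spec()].
#' @param map optional [numbering_map()] translating panel positions
#'   (reference) to structure positions (target).
#' @param scheme numbering scheme of the panel positions.
#' @param templates residue template library.
#' @param lj_table Lennard-Jones parameters.
#' @param ligand_id identifier recorded in the output rows.
#' @param ... passed to [graft_mutation()].
#' @return tibble with one row per variant (wild type first): ids,
#'   method fields and the energy breakdown.
#' @export
score_panel <- function(complex, panel, method = method_spec(), map = NULL,
                        scheme = c("reference", "target"),
                        templates = residue_templates(),
                        lj_table = lj_default(), ligand_id = "LIG", ...) {
  scheme <- match.arg(scheme)
  if (!"component" %in% names(complex)) complex <- tag_components(complex)
  if (!all(c("variant_id", "mutations") %in% names(panel))) {
    abort("panel needs columns `variant_id` and `mutations`")
  }
  wt_ids <- toupper(panel$mutations) %in% c("WT", "NONE", "")
  variants <- panel[!wt_ids, , drop = FALSE]

  score_one <- function(variant_id, mutations) {
    atoms <- complex
    muts <- parse_mutations(mutations, scheme)
    for (i in seq_len(nrow(muts))) {
      pos <- muts$residue_number[i]
      if (scheme == "reference" && !is.null(map)) {
        pos <- map_residue_number(map, pos, "reference_to_target")
      }
      hit <- atoms$component == "receptor" &
        atoms$residue_number == pos &
        atoms$residue_name == muts$from_aa[i]
      chains <- unique(atoms$chain_id[hit])
      if (length(chains) == 0) {
        abort(sprintf("variant %s: no receptor residue %s%d to mutate",
                      variant_id, muts$from_aa[i], pos))
      }
      for (ch in chains) {
        atoms <- graft_mutation(atoms, ch, pos, muts$to_aa[i],
                                from_aa = muts$from_aa[i],
                                templates = templates, lj_table = lj_table,
                                epsilon_in = method$epsilon_in, ...)
      }
    }
    bfe <- binding_free_energy(atoms, method, lj_table)
    dplyr::bind_cols(tibble(variant_id = variant_id, ligand_id = ligand_id,
                            polar_method = method$polar_method,
                            epsilon_in = method$epsilon_in,
                            sampling = method$sampling),
                     as_tibble(bfe))
  }

  rows <- c(
    list(score_one("WT", "WT")),
    purrr::map2(variants$variant_id, variants$mutations, score_one)
  )
  out <- dplyr::bind_rows(rows)
  if ("label" %in% names(panel)) {
    lab <- panel[, c("variant_id", "label")]
    if (!any(wt_ids)) lab <- dplyr::bind_rows(tibble(variant_id = "WT",
                                                     label = "S"), lab)
    lab$variant_id[toupper(lab$variant_id) == "WT"] <- "WT"
    out <- left_join(out, distinct(lab), by = "variant_id")
  }
  out
}
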