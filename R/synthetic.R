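# Desk-scale synthetic inputs: a toy pocket-ligand complex family whose
# designated "mutations" perturb contact residues, and Gaussian affinity
# tables with a stated resistant/susceptible mean shift. Both are pure
# functions of their arguments (seed included).

#' Generate a toy pocket-ligand complex family
#'
#' Builds a wild-type complex - a ring of rigid 4-atom pseudo-residues
#' (chain A) around a small charged ligand (chain L) with complementary
#' contact charges and favourable contact distances - plus one variant
#' per requested mutation effect:
#'
#' * `charge_flip`: the contact atom's charge is negated (loses the
#'   salt-bridge-like attraction; resistant-like, binding weakens),
#' * `bulky`: atom radii of the site grow and the contact atom protrudes
#'   toward the ligand (steric clash; resistant-like),
#' * `shrink`: the two outermost atoms of the site are deleted
#'   (binding-irrelevant bulk; susceptible-like),
#' * `neutral`: only the outermost atom's small charge is flipped, far
#'   from the ligand (susceptible-like).
#'
#' Pseudo-residues are rigid atom groups, not real amino acids: they
#' exercise splitting, scoring and ranking, while real-residue grafting
#' is covered by [residue_templates()] and [gen_toy_peptide()].
#'
#' @param n_pocket_residues pocket size (default 8).
#' @param ligand_atom_count ligand size (default 12).
#' @param mutation_effects named list or vector mapping pocket site
#'   (1-based index as character) to effect; defaults to one variant of
#'   each effect on sites 1-4.
#' @param seed integer seed for the coordinate jitter.
#' @return list of class `toy_complex_set`: `$structures` (named list of
#'   tagged atom tibbles, `WT` first), `$labels` (tibble `variant_id`,
#'   `label`), `$manifest` (per-variant site, effect and atom counts).
#' @export
gen_toy_complex <- function(n_pocket_residues = 8, ligand_atom_count = 12,
                            mutation_effects = NULL, seed = 1) {
  if (n_pocket_residues < 1 || ligand_atom_count < 1) {
    abort("counts must be >= 1")
  }
  if (is.null(mutation_effects)) {
    mutation_effects <- as.list(setNames(
      c("charge_flip", "bulky", "shrink", "neutral"),
      as.character(seq_len(min(4, n_pocket_residues)))
    ))
  }
  sites <- as.integer(names(mutation_effects))
  if (any(is.na(sites)) || any(sites < 1) ||
      any(sites > n_pocket_residues)) {
    abort("mutation effect site outside the pocket")
  }
  effects <- unlist(mutation_effects, use.names = FALSE)
  known <- c("charge_flip", "bulky", "shrink", "neutral")
  if (!all(effects %in% known)) {
    abort(sprintf("unknown mutation effect: %s",
                  paste(setdiff(effects, known), collapse = ", ")))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  # ligand: compact shell of atoms, alternating small charges, net anionic
  pts <- .sphere_points(ligand_atom_count) * 1.8
  lig_q <- rep(c(0.3, -0.3), length.out = ligand_atom_count)
  lig_q[1] <- -0.5
  elem_cycle <- rep(c("C", "C", "N", "O"), length.out = ligand_atom_count)
  ligand <- tibble(
    model = 1L, record = "HETATM",
    serial = seq_len(ligand_atom_count),
    atom_name = paste0(elem_cycle, seq_len(ligand_atom_count)),
    residue_name = "LIG", chain_id = "L", residue_number = 1L,
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    charge = lig_q, radius = unname(BONDI_RADII[elem_cycle])
  )

  # pocket: radial 4-atom pseudo-residues with complementary contacts
  radial <- c(5.4, 6.6, 7.8, 9.0)
  res_rows <- lapply(seq_len(n_pocket_residues), function(r) {
    ang <- 2 * pi * (r - 1) / n_pocket_residues
    zoff <- ifelse(r %% 2 == 0, 0.8, -0.8)
    dirv <- c(cos(ang), sin(ang), 0)
    xyz <- t(vapply(radial, function(d) dirv * d + c(0, 0, zoff),
                    numeric(3)))
    xyz <- xyz + matrix(runif(12, -0.15, 0.15), 4, 3)
    # contact charge complements the nearest ligand atom
    contact <- xyz[1, ]
    near <- which.min((pts[, 1] - contact[1])^2 + (pts[, 2] - contact[2])^2 +
                        (pts[, 3] - contact[3])^2)
    qc <- -sign(lig_q[near]) * 0.4
    tibble(
      model = 1L, record = "ATOM", serial = 0L,
      atom_name = paste0("C", 1:4), residue_name = "PSD",
      chain_id = "A", residue_number = as.integer(r),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      charge = c(qc, -qc * 0.25, 0, 0.1),
      radius = BONDI_RADII[["C"]]
    )
  })
  receptor <- dplyr::bind_rows(res_rows)
  wt <- dplyr::bind_rows(receptor, ligand)
  wt$serial <- seq_len(nrow(wt))
  wt <- tag_components(wt, ligand_chains = "L")

  apply_effect <- function(atoms, site, effect) {
    rows <- which(atoms$chain_id == "A" & atoms$residue_number == site)
    stopifnot(length(rows) >= 1)
    if (effect == "charge_flip") {
      atoms$charge[rows[1]] <- -atoms$charge[rows[1]]
    } else if (effect == "bulky") {
      atoms$radius[rows] <- atoms$radius[rows] + 0.5
      # bulkier side chain protrudes into the pocket
      p <- c(atoms$x[rows[1]], atoms$y[rows[1]], atoms$z[rows[1]])
      p <- p * (1 - 0.9 / sqrt(sum(p^2)))
      atoms$x[rows[1]] <- p[1]; atoms$y[rows[1]] <- p[2]
      atoms$z[rows[1]] <- p[3]
    } else if (effect == "shrink") {
      atoms <- atoms[-rows[3:4], , drop = FALSE]
    } else if (effect == "neutral") {
      atoms$charge[rows[4]] <- -atoms$charge[rows[4]]
    }
    atoms
  }

  variant_ids <- sprintf("S%d_%s", sites, effects)
  structures <- c(list(WT = wt),
                  setNames(purrr::map2(sites, effects,
                                       ~ apply_effect(wt, .x, .y)),
                           variant_ids))
  labels <- tibble(
    variant_id = c("WT", variant_ids),
    label = c("S", ifelse(effects %in% c("charge_flip", "bulky"),
                          "R", "S"))
  )
  manifest <- tibble(
    variant_id = c("WT", variant_ids),
    site = c(NA_integer_, sites),
    effect = c("none", effects),
    n_atoms = unname(vapply(structures, nrow, integer(1))),
    n_receptor = unname(vapply(structures,
                               function(a) sum(a$component == "receptor"),
                               integer(1))),
    n_ligand = unname(vapply(structures,
                             function(a) sum(a$component == "ligand"),
                             integer(1)))
  )
  structure(list(structures = structures, labels = labels,
                 manifest = manifest, seed = seed),
            class = "toy_complex_set")
}

#' Generate a small real-residue pocket for grafting tests
#'
#' Arranges real amino-acid residues (built from [residue_templates()])
#' in an arc with their side chains pointing at a small charged ligand,
#' so that side-chain grafting, panel scoring and numbering-map
#' translation can be exercised end to end on a structure with genuine
#' N/CA/C backbones.
#'
#' @param residues character vector of three-letter codes placed on the
#'   arc, in order; residue numbers are `101, 102, ...`.
#' @param ligand_atom_count ligand size.
#' @param ring_radius distance of the CA atoms from the ligand centre.
#' @param seed jitter seed.
#' @return a tagged atom tibble (chain A receptor, chain L ligand).
#' @export
gen_toy_peptide <- function(residues = c("LEU", "SER", "VAL", "THR"),
                            ligand_atom_count = 8, ring_radius = 9,
                            seed = 1) {
  templates <- residue_templates()
  bad <- setdiff(toupper(residues), names(templates))
  if (length(bad) > 0) abort(sprintf("unknown residue: %s",
                                     paste(bad, collapse = ", ")))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  pts <- .sphere_points(ligand_atom_count) * 1.6
  lig_q <- rep(c(0.35, -0.35), length.out = ligand_atom_count)
  ligand <- tibble(
    model = 1L, record = "HETATM", serial = 0L,
    atom_name = paste0("C", seq_len(ligand_atom_count)),
    residue_name = "LIG", chain_id = "L", residue_number = 1L,
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    charge = lig_q, radius = BONDI_RADII[["C"]]
  )

  n <- length(residues)
  res_rows <- lapply(seq_len(n), function(i) {
    tpl <- templates[[toupper(residues[i])]]
    ang <- 2 * pi * (i - 1) / max(n, 2)
    # rotate the template so the CA->CB direction (~ -y in the local
    # frame) points at the ligand, then place CA on the ring
    ca_pos <- c(ring_radius * cos(ang), ring_radius * sin(ang), 0)
    inward <- -ca_pos / sqrt(sum(ca_pos^2))
    local_cb <- c(-0.55, -1.20, -0.76)          # CB direction in frame
    local_cb <- local_cb / sqrt(sum(local_cb^2))
    axis <- c(local_cb[2] * inward[3] - local_cb[3] * inward[2],
              local_cb[3] * inward[1] - local_cb[1] * inward[3],
              local_cb[1] * inward[2] - local_cb[2] * inward[1])
    cosang <- sum(local_cb * inward)
    rot <- if (sqrt(sum(axis^2)) < 1e-8) {
      diag(3) * sign(cosang)
    } else {
      .rot_axis(axis, acos(pmin(pmax(cosang, -1), 1)))
    }
    xyz <- cbind(tpl$x, tpl$y, tpl$z) %*% t(rot)
    xyz <- sweep(xyz, 2, ca_pos, `+`) +
      matrix(runif(3, -0.1, 0.1), nrow(tpl), 3, byrow = TRUE)
    tibble(
      model = 1L, record = "ATOM", serial = 0L,
      atom_name = tpl$atom_name, residue_name = tpl$residue_name,
      chain_id = "A", residue_number = 100L + i,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      charge = tpl$charge, radius = tpl$radius
    )
  })
  out <- dplyr::bind_rows(c(res_rows, list(ligand)))
  out$serial <- seq_len(nrow(out))
  tag_components(out, ligand_chains = "L")
}

#' Generate a synthetic affinity table
#'
#' Emulates a table of estimated binding free energies for a labelled
#' variant panel under one or more scoring methods: per variant and
#' method, `dG = base + delta * [resistant] + sqrt(rho) * Z_v +
#' sqrt(1 - rho) * E_vm`, where `Z_v` is a shared per-variant effect
#' (making methods correlate with coefficient `rho`) and `E_vm`
#' independent noise, both with standard deviation `sigma`. Resistant
#' variants are shifted `delta` kcal/mol above (weaker than) the
#' susceptible group, which includes the wild type.
#'
#' @param n_R,n_S numbers of resistant and susceptible mutants (the wild
#'   type is always added to the susceptible side).
#' @param delta resistant-vs-susceptible mean shift, kcal/mol.
#' @param sigma noise standard deviation, kcal/mol (>= 0).
#' @param n_methods number of scoring methods emulated.
#' @param rho inter-method correlation, in `[0, 1)`.
#' @param base susceptible-group mean, kcal/mol.
#' @param seed integer seed.
#' @return list with `scores` (tibble `variant_id`, `ligand_id`,
#'   `method`, `sampling`, `dg`) and `labels` (tibble `variant_id`,
#'   `label`).
#' @export
gen_affinity_table <- function(n_R = 25, n_S = 3, delta = 2, sigma = 0.5,
                               n_methods = 1, rho = 0.5, base = -40,
                               seed = 1) {
  if (n_R < 1 || n_S < 1) abort("n_R and n_S must be >= 1")
  if (sigma < 0) abort("sigma must be >= 0")
  if (rho < 0 || rho >= 1) abort("rho must be in [0, 1)")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  ids <- c(sprintf("R%02d", seq_len(n_R)), sprintf("S%02d", seq_len(n_S)),
           "WT")
  lab <- c(rep("R", n_R), rep("S", n_S + 1))
  n_var <- length(ids)
  z <- rnorm(n_var, 0, sigma)
  scores <- purrr::map_dfr(seq_len(n_methods), function(m) {
    e <- rnorm(n_var, 0, sigma)
    tibble(variant_id = ids, ligand_id = "LIG",
           method = sprintf("M%02d", m), sampling = "single_structure",
           dg = base + delta * (lab == "R") + sqrt(rho) * z +
             sqrt(1 - rho) * e)
  })
  list(scores = scores, labels = tibble(variant_id = ids, label = lab))
}

#' Load the packaged Kochia scoparia AHAS mutation panel
#'
#' The curated panel of field-reported acetohydroxyacid synthase (AHAS)
#' substitutions in *Kochia scoparia* with their experimentally
#' determined resistance to the sulfonylurea herbicides tribenuron
#' methyl and thifensulfuron methyl: the wild type plus 28 variants (17
#' single and 11 double substitutions; 25 resistant, 3 susceptible),
#' with positions in the Arabidopsis (reference) numbering convention.
#' The bundled file is checksum-verified on load.
#'
#' @return tibble with columns `variant_id`, `mutation_type`,
#'   `mutations`, `label`, `source_refs`.
#' @seealso [ahas_numbering_map()] for the reference-to-Kochia position
#'   map.
#' @export
load_kochia_panel <- function() {
  path <- system.file("extdata", "kochia_panel.csv", package = "resistrank")
  sum_got <- unname(tools::md5sum(path))
  if (!identical(sum_got, KOCHIA_PANEL_MD5)) {
    abort("kochia_panel.csv fixture is corrupted (checksum mismatch)")
  }
  out <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character"))
  out
}

# md5 of inst/extdata/kochia_panel.csv as shipped
KOCHIA_PANEL_MD5 <- "d61c0e0409fb3ae835f3cb9aa80c4329"

#' Reference-to-Kochia AHAS residue numbering map
#'
#' The seven mutation sites of the panel in Arabidopsis AHAS (reference)
#' numbering and their Kochia AHAS (target) counterparts. The offset is
#' not constant, which is why [map_residue_number()] refuses to
#' extrapolate.
#'
#' @return a [numbering_map()].
#' @export
ahas_numbering_map <- function() {
  path <- system.file("extdata", "ahas_numbering.tsv",
                      package = "resistrank")
  read_numbering_map(path)
}
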