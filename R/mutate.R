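#' Relieve clashes by rigid-fragment minimisation
#'
#' Moves the mobile atom selection as one rigid fragment (translation
#' plus rotation about its centroid; pure translation for a single atom)
#' downhill on the nonbonded potential (screened Coulomb plus 12-6
#' Lennard-Jones) against all other atoms, mirroring a
#' steepest-descent-then-conjugate-gradient minimisation policy at desk
#' scale. Steps are accepted only if they lower the energy (backtracking
#' line search), so the energy trace is monotone non-increasing and the
#' result is deterministic.
#'
#' @param atoms atom tibble (single model).
#' @param mobile integer or logical index of the mobile atoms.
#' @param sd_steps,cg_steps maximum steepest-descent and
#'   conjugate-gradient iterations (>= 0).
#' @param step_size initial line-search step, Angstrom.
#' @param epsilon_in dielectric used in the Coulomb term.
#' @param lj_table Lennard-Jones parameters.
#' @param tol gradient-norm convergence threshold.
#' @param exclude optional index of atoms ignored by the potential
#'   (covalent neighbours of a grafted fragment, which would otherwise
#'   dominate a nonbonded-only energy).
#' @return the atom tibble with updated mobile coordinates; attribute
#'   `relax` holds the initial/final energies and iteration count.
#' @export
relax_mutant <- function(atoms, mobile, sd_steps = 200, cg_steps = 500,
                         step_size = 0.05, epsilon_in = 4,
                         lj_table = lj_default(), tol = 1e-6,
                         exclude = NULL) {
  .assert_atoms(atoms)
  if (sd_steps < 0 || cg_steps < 0) abort("step counts must be >= 0")
  if (is.logical(mobile)) mobile <- which(mobile)
  if (is.logical(exclude)) exclude <- which(exclude)
  if (length(mobile) == 0) abort("mobile selection is empty")
  static <- setdiff(seq_len(nrow(atoms)), c(mobile, exclude))
  if (length(static) == 0) abort("no static atoms to relax against")

  mob <- atoms[mobile, , drop = FALSE]
  sta <- atoms[static, , drop = FALSE]
  xyz_m0 <- .xyz(mob); xyz_s <- .xyz(sta)
  lj_m <- .lj_params(mob, lj_table); lj_s <- .lj_params(sta, lj_table)
  centroid <- colMeans(xyz_m0)
  single <- nrow(mob) == 1
  n_par <- if (single) 3L else 6L

  place <- function(p) {
    out <- sweep(xyz_m0, 2, centroid)
    if (!single && any(p[4:6] != 0)) {
      th <- sqrt(sum(p[4:6]^2))
      if (th > 0) out <- out %*% t(.rot_axis(p[4:6] / th, th))
    }
    sweep(out, 2, centroid + p[1:3], `+`)
  }
  efun <- function(p) {
    .nb_energy(place(p), mob$charge, lj_m, xyz_s, sta$charge, lj_s,
               epsilon_in)
  }
  gfun <- function(p, hstep = 1e-4) {
    g <- numeric(n_par)
    for (k in seq_len(n_par)) {
      pp <- p; pm <- p
      pp[k] <- pp[k] + hstep; pm[k] <- pm[k] - hstep
      g[k] <- (efun(pp) - efun(pm)) / (2 * hstep)
    }
    g
  }
  line_search <- function(p, dir, e0, alpha) {
    for (k in 1:30) {
      cand <- p + alpha * dir
      e1 <- efun(cand)
      if (is.finite(e1) && e1 < e0) return(list(p = cand, e = e1))
      alpha <- alpha / 2
    }
    NULL
  }

  p <- numeric(n_par)
  e <- efun(p)
  e_start <- e
  iters <- 0L

  # steepest descent
  for (it in seq_len(sd_steps)) {
    g <- gfun(p)
    gn <- sqrt(sum(g^2))
    if (gn < tol) break
    step <- line_search(p, -g / gn, e, step_size)
    if (is.null(step)) break
    p <- step$p; e <- step$e; iters <- iters + 1L
  }
  # Polak-Ribiere conjugate gradient
  if (cg_steps > 0) {
    g_prev <- gfun(p)
    dir <- -g_prev
    for (it in seq_len(cg_steps)) {
      gn <- sqrt(sum(g_prev^2))
      if (gn < tol) break
      dn <- sqrt(sum(dir^2))
      if (dn < 1e-12) break
      step <- line_search(p, dir / dn, e, step_size)
      if (is.null(step)) break
      p <- step$p; e <- step$e; iters <- iters + 1L
      g_new <- gfun(p)
      beta_pr <- max(0, sum(g_new * (g_new - g_prev)) / max(sum(g_prev^2),
                                                            1e-12))
      dir <- -g_new + beta_pr * dir
      g_prev <- g_new
    }
  }

  xyz_new <- place(p)
  atoms$x[mobile] <- xyz_new[, 1]
  atoms$y[mobile] <- xyz_new[, 2]
  atoms$z[mobile] <- xyz_new[, 3]
  attr(atoms, "relax") <- list(energy_start = e_start, energy_end = e,
                               iterations = iters)
  atoms
}

#' Graft a point mutation onto a structure
#'
#' Replaces the side chain of the target residue with the idealized
#' template of the new residue, placed through the backbone N-CA-C
#' frame. The new side chain is spun through `rotations` trial positions
#' about the CA-CB axis, the lowest-nonbonded-energy rotamer is kept,
#' and (optionally) rigid-fragment clash relief ([relax_mutant()]) is
#' applied to the grafted atoms. Backbone atoms (N, CA, C, O, OXT) and
#' every other residue are left bit-identical; grafting a residue onto
#' itself is a no-op. Template charges and radii replace those of the
#' old side chain.
#'
#' @param atoms atom tibble (single model).
#' @param chain_id,residue_number location of the site in the
#'   structure's own numbering.
#' @param to_aa three-letter code of the replacement residue.
#' @param from_aa optional three-letter code asserted against the
#'   current residue name.
#' @param templates template library, see [residue_templates()].
#' @param rotations number of trial rotations about the CA-CB axis.
#' @param relax apply [relax_mutant()] to the new side chain (excluding
#'   the site's own backbone from the potential, the bonded-exclusion
#'   convention).
#' @param epsilon_in,lj_table nonbonded parameters for rotamer selection
#'   and relaxation.
#' @param sd_steps,cg_steps,step_size minimisation policy forwarded to
#'   [relax_mutant()].
#' @return the mutated atom tibble.
#' @export
graft_mutation <- function(atoms, chain_id, residue_number, to_aa,
                           from_aa = NULL, templates = residue_templates(),
                           rotations = 12, relax = TRUE, epsilon_in = 4,
                           lj_table = lj_default(), sd_steps = 50,
                           cg_steps = 100, step_size = 0.02) {
  .assert_atoms(atoms)
  if ("model" %in% names(atoms) && length(unique(atoms$model)) > 1) {
    abort("graft_mutation() operates on a single model")
  }
  to_aa <- toupper(to_aa)
  if (!to_aa %in% names(templates)) {
    abort(sprintf("unknown replacement residue '%s'", to_aa))
  }
  site <- which(atoms$chain_id == chain_id &
                  atoms$residue_number == residue_number)
  if (length(site) == 0) {
    abort(sprintf("residue %s%d not found", chain_id, residue_number))
  }
  res_name <- atoms$residue_name[site[1]]
  if (!is.null(from_aa) && toupper(from_aa) != res_name) {
    abort(sprintf("residue %s%d is %s, not %s", chain_id, residue_number,
                  res_name, toupper(from_aa)))
  }
  if (res_name == to_aa) return(atoms)   # explicit no-op

  backbone_names <- c("N", "CA", "C", "O", "OXT")
  bb <- site[atoms$atom_name[site] %in% backbone_names]
  need <- c("N", "CA", "C")
  have <- atoms$atom_name[bb]
  if (!all(need %in% have)) {
    abort(sprintf("residue %s%d is missing backbone atoms: %s", chain_id,
                  residue_number, paste(setdiff(need, have), collapse = ", ")))
  }
  old_side <- setdiff(site, bb)

  pos_of <- function(nm) {
    i <- bb[atoms$atom_name[bb] == nm][1]
    c(atoms$x[i], atoms$y[i], atoms$z[i])
  }
  frame <- .backbone_frame(pos_of("N"), pos_of("CA"), pos_of("C"))
  ca <- pos_of("CA")

  tpl <- templates[[to_aa]]
  sc <- tpl[!tpl$backbone, , drop = FALSE]
  new_rows <- NULL
  if (nrow(sc) > 0) {
    local <- cbind(sc$x, sc$y, sc$z)
    global <- sweep(local %*% frame, 2, ca, `+`)
    # rotamer scan about the CA-CB axis (CB is on the axis, so only
    # atoms beyond CB move)
    if (nrow(sc) > 1 && rotations > 1) {
      cb <- global[which(sc$atom_name == "CB")[1], ]
      axis <- cb - ca
      rest <- atoms[-site, , drop = FALSE]
      bbres <- atoms[bb, , drop = FALSE]
      env <- dplyr::bind_rows(rest, bbres)
      lj_env <- .lj_params(env, lj_table)
      lj_sc <- lj_default_lookup(sc, lj_table)
      best <- NULL; best_e <- Inf
      beyond <- sc$atom_name != "CB"
      for (k in seq_len(rotations)) {
        theta <- 2 * pi * (k - 1) / rotations
        g <- global
        if (theta != 0) {
          rot <- .rot_axis(axis, theta)
          g[beyond, ] <- sweep(sweep(g[beyond, , drop = FALSE], 2, cb) %*%
                                 t(rot), 2, cb, `+`)
        }
        e <- .nb_energy(g, sc$charge, lj_sc, .xyz(env), env$charge, lj_env,
                        epsilon_in)
        if (e < best_e) { best_e <- e; best <- g }
      }
      global <- best
    }
    # inherit residue-level metadata (model, record, component, ...)
    # from the site's CA row so extra columns survive the graft
    proto <- atoms[rep(bb[atoms$atom_name[bb] == "CA"][1], nrow(sc)), ,
                   drop = FALSE]
    proto$serial <- max(atoms$serial %||% 0L) + seq_len(nrow(sc))
    proto$atom_name <- sc$atom_name
    proto$residue_name <- to_aa
    proto$x <- global[, 1]; proto$y <- global[, 2]; proto$z <- global[, 3]
    proto$charge <- sc$charge
    proto$radius <- sc$radius
    new_rows <- proto
  }

  out <- atoms
  out$residue_name[site] <- to_aa
  keep <- setdiff(seq_len(nrow(out)), old_side)
  insert_after <- max(match(bb, keep))
  out <- out[keep, , drop = FALSE]
  out <- dplyr::bind_rows(
    out[seq_len(insert_after), , drop = FALSE],
    new_rows,
    if (insert_after < nrow(out)) out[(insert_after + 1):nrow(out), ,
                                      drop = FALSE]
  )
  if (relax && !is.null(new_rows) && nrow(new_rows) > 0) {
    in_site <- out$chain_id == chain_id & out$residue_number == residue_number
    mob <- which(in_site & !out$atom_name %in% backbone_names)
    own_bb <- which(in_site & out$atom_name %in% backbone_names)
    out <- relax_mutant(out, mob, sd_steps = sd_steps, cg_steps = cg_steps,
                        step_size = step_size, epsilon_in = epsilon_in,
                        lj_table = lj_table, exclude = own_bb)
  }
  out
}

# LJ lookup for template tibbles (they carry `element`, not atom_class)
lj_default_lookup <- function(tpl, lj_table) {
  idx <- match(tpl$element, lj_table$class)
  if (anyNA(idx)) {
    abort(sprintf("template element not in LJ table: %s",
                  paste(unique(tpl$element[is.na(idx)]), collapse = ", ")))
  }
  list(r_min_half = lj_table$r_min_half[idx], epsilon = lj_table$epsilon[idx])
}
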