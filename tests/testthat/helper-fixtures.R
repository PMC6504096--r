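# shared fixture builders; everything is generated in code

mk_atoms <- function(pos, charge = 0, radius = 1.7, atom_name = NULL,
                     chain_id = "A", residue_number = NULL,
                     residue_name = "UNK", record = "ATOM") {
  pos <- matrix(pos, ncol = 3)
  n <- nrow(pos)
  tibble::tibble(
    model = 1L, record = rep_len(record, n), serial = seq_len(n),
    atom_name = atom_name %||% paste0("C", seq_len(n)),
    residue_name = rep_len(residue_name, n),
    chain_id = rep_len(chain_id, n),
    residue_number = residue_number %||% seq_len(n),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    charge = rep_len(charge, n), radius = rep_len(radius, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random valid structure on the write_pqr precision grid
random_structure <- function(n = 12, n_models = 1, seed = 1) {
  withr::with_seed(seed, {
    one <- function(m) {
      tibble::tibble(
        model = m, record = sample(c("ATOM", "HETATM"), n, replace = TRUE),
        serial = seq_len(n),
        atom_name = paste0(sample(c("C", "N", "O", "S"), n, replace = TRUE),
                           seq_len(n)),
        residue_name = sample(c("ALA", "LIG", "GLY"), n, replace = TRUE),
        chain_id = sample(c("A", "B"), n, replace = TRUE),
        residue_number = sample.int(50, n),
        x = round(runif(n, -20, 20), 3), y = round(runif(n, -20, 20), 3),
        z = round(runif(n, -20, 20), 3),
        charge = round(runif(n, -1, 1), 4),
        radius = round(runif(n, 1, 2), 4)
      )
    }
    dplyr::bind_rows(lapply(seq_len(n_models), one))
  })
}

# small random two-component complex with well-separated atoms
random_complex <- function(n_rec = 8, n_lig = 4, seed = 1, spread = 6) {
  withr::with_seed(seed, {
    rec <- mk_atoms(cbind(runif(n_rec, -spread, spread),
                          runif(n_rec, -spread, spread),
                          runif(n_rec, 3.5, spread + 4)),
                    charge = round(runif(n_rec, -0.5, 0.5), 3),
                    radius = 1.7, chain_id = "A")
    lig <- mk_atoms(cbind(runif(n_lig, -2, 2), runif(n_lig, -2, 2),
                          runif(n_lig, -2, 0)),
                    charge = round(runif(n_lig, -0.5, 0.5), 3),
                    radius = 1.7, chain_id = "L", record = "HETATM",
                    residue_name = "LIG")
    lig$residue_number <- 1L
    lig$atom_name <- paste0("C", seq_len(n_lig))
    out <- dplyr::bind_rows(rec, lig)
    out$serial <- seq_len(nrow(out))
    tag_components(out, ligand_chains = "L")
  })
}

# naive O(n^2) nonbonded oracle over two atom sets
naive_cross_energy <- function(a, b, epsilon_in, lj_table) {
  e_ele <- 0; e_vdw <- 0
  pa <- resistrank:::.lj_params(a, lj_table)
  pb <- resistrank:::.lj_params(b, lj_table)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      r <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      e_ele <- e_ele + 332.0637 * a$charge[i] * b$charge[j] /
        (epsilon_in * r)
      rm <- pa$r_min_half[i] + pb$r_min_half[j]
      ep <- sqrt(pa$epsilon[i] * pb$epsilon[j])
      e_vdw <- e_vdw + ep * ((rm / r)^12 - 2 * (rm / r)^6)
    }
  }
  c(e_ele = e_ele, e_vdw = e_vdw)
}

# exhaustive pair-counting AUC oracle (concordant + half ties)
pair_count_auc <- function(dg, label) {
  r <- dg[label == "R"]; s <- dg[label == "S"]
  tot <- 0
  for (x in r) for (y in s) {
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  tot / (length(r) * length(s))
}

# ranked panel built directly from an ordered label sequence
ranked_from_labels <- function(labels_in_rank_order) {
  n <- length(labels_in_rank_order)
  scores <- tibble::tibble(
    variant_id = sprintf("V%02d", seq_len(n)),
    dg = seq(0, by = -1, length.out = n)
  )
  labels <- tibble::tibble(variant_id = scores$variant_id,
                           label = labels_in_rank_order)
  rank_panel(scores, labels)
}

rigid_transform <- function(atoms, axis = c(1, 1, 0), angle = 0.7,
                            shift = c(3, -2, 5)) {
  rot <- resistrank:::.rot_axis(axis, angle)
  xyz <- cbind(atoms$x, atoms$y, atoms$z) %*% t(rot)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}
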