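# canonical heavy-atom side-chain sizes (CB included; GLY has none)
CANONICAL_SIDECHAIN <- c(ALA = 1, ARG = 7, ASN = 4, ASP = 4, CYS = 2,
                         GLN = 5, GLU = 5, GLY = 0, HIS = 6, ILE = 4,
                         LEU = 4, LYS = 5, MET = 4, PHE = 7, PRO = 3,
                         SER = 2, THR = 3, TRP = 10, TYR = 8, VAL = 3)

test_that("templates carry the canonical heavy-atom composition", {
  tpl <- residue_templates()
  expect_setequal(names(tpl), names(CANONICAL_SIDECHAIN))
  for (res in names(tpl)) {
    t <- tpl[[res]]
    expect_equal(sum(!t$backbone), unname(CANONICAL_SIDECHAIN[res]),
                 info = res)
    expect_setequal(t$atom_name[t$backbone], c("N", "CA", "C", "O"))
    # bonded geometry is physically plausible: CB sits ~1.53 A from CA
    if (res != "GLY") {
      cb <- t[t$atom_name == "CB", ]
      expect_equal(sqrt(cb$x^2 + cb$y^2 + cb$z^2), 1.53, tolerance = 0.01)
    }
    expect_true(all(t$radius > 0))
  }
})

test_that("backbone frames are orthonormal", {
  f <- resistrank:::.backbone_frame(c(1.4, 0, 0), c(0, 0, 0),
                                    c(-0.5, 1.4, 0))
  expect_equal(unname(f %*% t(f)), diag(3), tolerance = 1e-12)
})

test_that("grafting a residue onto itself is a no-op", {
  pep <- gen_toy_peptide(seed = 5)
  expect_identical(graft_mutation(pep, "A", 102, "SER"), pep)
})

test_that("grafting to glycine leaves no side-chain atoms", {
  pep <- gen_toy_peptide(seed = 5)
  g <- graft_mutation(pep, "A", 101, "GLY", from_aa = "LEU")
  site <- g[g$residue_number == 101, ]
  expect_setequal(site$atom_name, c("N", "CA", "C", "O"))
  expect_true(all(site$residue_name == "GLY"))
})

test_that("grafting never moves atoms outside the target site", {
  pep <- gen_toy_peptide(seed = 5)
  for (to in c("TRP", "ALA", "GLU")) {
    mut <- graft_mutation(pep, "A", 103, to, from_aa = "VAL")
    other_new <- mut[mut$residue_number != 103, ]
    other_old <- pep[pep$residue_number != 103, ]
    expect_equal(max(abs(other_new$x - other_old$x)), 0)
    expect_equal(max(abs(other_new$y - other_old$y)), 0)
    expect_equal(max(abs(other_new$z - other_old$z)), 0)
    # backbone of the site itself is also untouched
    bb_new <- mut[mut$residue_number == 103 &
                    mut$atom_name %in% c("N", "CA", "C", "O"), ]
    bb_old <- pep[pep$residue_number == 103 &
                    pep$atom_name %in% c("N", "CA", "C", "O"), ]
    expect_equal(bb_new$x, bb_old$x)
  }
})

test_that("grafted side chains take template charges, radii and size", {
  pep <- gen_toy_peptide(seed = 5)
  mut <- graft_mutation(pep, "A", 102, "ASP", from_aa = "SER",
                        relax = FALSE)
  side <- mut[mut$residue_number == 102 &
                !mut$atom_name %in% c("N", "CA", "C", "O"), ]
  tpl <- residue_templates()$ASP
  tside <- tpl[!tpl$backbone, ]
  expect_equal(side$atom_name, tside$atom_name)
  expect_equal(side$charge, tside$charge)
  expect_equal(side$radius, tside$radius)
  # anionic side chain carries its formal charge
  expect_equal(sum(side$charge), -1)
})

test_that("graft errors are informative", {
  pep <- gen_toy_peptide(seed = 5)
  expect_error(graft_mutation(pep, "A", 102, "XYZ"), "unknown")
  expect_error(graft_mutation(pep, "A", 999, "ALA"), "not found")
  expect_error(graft_mutation(pep, "A", 102, "ALA", from_aa = "LEU"),
               "is SER")
  broken <- pep[!(pep$residue_number == 102 & pep$atom_name == "CA"), ]
  expect_error(graft_mutation(broken, "A", 102, "ALA"), "backbone")
})

test_that("relaxation with zero steps returns the input unchanged", {
  a <- mk_atoms(rbind(c(0, 0, 0), c(1, 0, 0)), charge = 0.2)
  r <- relax_mutant(a, mobile = 2, sd_steps = 0, cg_steps = 0)
  expect_equal(r$x, a$x)
  expect_error(relax_mutant(a, mobile = 2, sd_steps = -1), ">= 0")
  expect_error(relax_mutant(a, mobile = integer()), "empty")
})

test_that("an overlapping neutral pair relaxes to the pair-potential minimum", {
  # 1-D oracle: grid line search on the isolated pair potential
  lj <- lj_default()
  pair_e <- function(r) {
    pairwise_vdw(mk_atoms(c(0, 0, 0)), mk_atoms(c(r, 0, 0)), lj)
  }
  grid <- seq(2.5, 6, by = 1e-4)
  oracle_r <- grid[which.min(vapply(grid, pair_e, numeric(1)))]

  a <- mk_atoms(rbind(c(0, 0, 0), c(0.8, 0, 0)), charge = 0)
  r <- relax_mutant(a, mobile = 2, sd_steps = 300, cg_steps = 300,
                    step_size = 0.2)
  info <- attr(r, "relax")
  sep <- abs(r$x[2] - r$x[1])
  expect_gt(sep, 2 * 1.908 * 0.95)          # at least contact distance
  expect_lt(info$energy_end, info$energy_start)
  expect_equal(sep, oracle_r, tolerance = 1e-2)
  expect_equal(info$energy_end, pair_e(oracle_r), tolerance = 1e-4)
})

test_that("a pair at its minimum does not move", {
  r0 <- 2 * 1.908
  a <- mk_atoms(rbind(c(0, 0, 0), c(r0, 0, 0)), charge = 0)
  r <- relax_mutant(a, mobile = 2, sd_steps = 100, cg_steps = 100)
  expect_equal(abs(r$x[2] - r$x[1]), r0, tolerance = 1e-3)
})

test_that("relaxation is deterministic and monotone in energy", {
  pep <- gen_toy_peptide(seed = 7)
  mob <- which(pep$residue_number == 101 &
                 !pep$atom_name %in% c("N", "CA", "C", "O"))
  r1 <- relax_mutant(pep, mob, sd_steps = 30, cg_steps = 30)
  r2 <- relax_mutant(pep, mob, sd_steps = 30, cg_steps = 30)
  expect_identical(r1, r2)
  info <- attr(r1, "relax")
  expect_lte(info$energy_end, info$energy_start)
})
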