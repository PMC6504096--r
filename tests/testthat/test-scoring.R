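test_that("the score breakdown sums to dG with zero entropy and internal terms", {
  toy <- gen_toy_complex(seed = 2)
  b <- binding_free_energy(toy$structures$WT, method_spec("GB-OBC"))
  expect_equal(b$dg, b$e_ele + b$e_vdw + b$e_internal + b$g_pol + b$g_np +
                 b$entropy_term, tolerance = 1e-9)
  expect_identical(b$e_internal, 0)
  expect_identical(b$entropy_term, 0)
})

test_that("scores agree with an independent term-by-term recomputation", {
  # oracle: rebuild every term from the public primitives
  toy <- gen_toy_complex(seed = 2)
  cx <- toy$structures$WT
  m <- method_spec("GB-OBC", epsilon_in = 4)
  parts <- split_complex(cx)
  lj <- lj_default()
  want_ele <- naive_cross_energy(parts$receptor, parts$ligand, 4, lj)
  gpol <- function(a) gb_polar(a, epsilon_in = 4, epsilon_out = 80,
                               config = gb_config("OBC"))
  want_gpol <- gpol(cx) - gpol(parts$receptor) - gpol(parts$ligand)
  want_gnp <- 0.0072 * (sasa(cx)$total - sasa(parts$receptor)$total -
                          sasa(parts$ligand)$total)
  got <- binding_free_energy(cx, m)
  expect_equal(got$e_ele, unname(want_ele["e_ele"]), tolerance = 1e-9)
  expect_equal(got$e_vdw, unname(want_ele["e_vdw"]), tolerance = 1e-9)
  expect_equal(got$g_pol, want_gpol, tolerance = 1e-9)
  expect_equal(got$g_np, want_gnp, tolerance = 1e-9)
  expect_equal(got$dg, unname(want_ele["e_ele"] + want_ele["e_vdw"]) +
                 want_gpol + want_gnp, tolerance = 1e-9)
})

test_that("all terms vanish when the ligand is displaced far away", {
  toy <- gen_toy_complex(seed = 2)
  far <- toy$structures$WT
  lig <- far$component == "ligand"
  far$x[lig] <- far$x[lig] + 1e5
  b <- binding_free_energy(far, method_spec("GB-OBC"))
  expect_lt(abs(b$e_ele), 1e-3)   # residual monopole-monopole tail
  expect_lt(abs(b$e_vdw), 1e-6)
  expect_lt(abs(b$g_pol), 1e-3)
  expect_lt(abs(b$g_np), 1e-6)
})

test_that("with charges off the score reduces to the nonpolar term", {
  cx <- random_complex(seed = 13)
  cx$charge <- 0
  lj0 <- lj_default(); lj0$epsilon <- 0 * lj0$epsilon
  b <- binding_free_energy(cx, method_spec("GB-OBC"), lj_table = lj0)
  expect_equal(b$e_ele, 0)
  expect_equal(b$e_vdw, 0)
  expect_equal(b$g_pol, 0)
  expect_equal(b$dg, b$g_np)
})

test_that("scoring is deterministic", {
  toy <- gen_toy_complex(seed = 4)
  m <- method_spec("GB-OBC")
  expect_identical(binding_free_energy(toy$structures$WT, m),
                   binding_free_energy(toy$structures$WT, m))
})

test_that("ensemble scores average frames componentwise", {
  toy <- gen_toy_complex(seed = 2)
  wt <- toy$structures$WT
  m <- method_spec("GB-OBC")
  single <- binding_free_energy(wt, m)
  # one frame and duplicated frames equal the single-structure score
  expect_equal(ensemble_binding_free_energy(wt, m)$dg, single$dg)
  dup <- dplyr::bind_rows(wt, dplyr::mutate(wt, model = 2L))
  expect_equal(ensemble_binding_free_energy(dup, m)$dg, single$dg)
  # a genuinely different second frame gives the arithmetic mean
  frame2 <- wt
  lig <- frame2$component == "ligand"
  frame2$x[lig] <- frame2$x[lig] + 0.6
  both <- dplyr::bind_rows(wt, dplyr::mutate(frame2, model = 2L))
  e2 <- binding_free_energy(frame2, m)
  got <- ensemble_binding_free_energy(both, m)
  expect_equal(got$dg, (single$dg + e2$dg) / 2, tolerance = 1e-12)
  expect_equal(got$g_pol, (single$g_pol + e2$g_pol) / 2, tolerance = 1e-12)
  # mismatched atoms across frames are rejected
  broken <- dplyr::bind_rows(wt, dplyr::mutate(wt[-1, ], model = 2L))
  expect_error(ensemble_binding_free_energy(broken, m), "atom identity")
})

test_that("a two-frame toy gives the stated mean", {
  # direct arithmetic check of frame averaging on synthetic scores
  expect_equal(mean(c(-10, -6)), -8)
})

test_that("score_panel returns WT plus one row per variant", {
  pep <- gen_toy_peptide(seed = 3)
  m <- method_spec("GB-OBC")
  empty <- score_panel(pep, tibble::tibble(variant_id = character(),
                                           mutations = character()), m)
  expect_equal(nrow(empty), 1)
  expect_equal(empty$variant_id, "WT")

  panel <- tibble::tibble(
    variant_id = c("L101A", "S102D", "V103T"),
    mutations = c("L101A", "S102D", "V103T"),
    label = c("R", "R", "S")
  )
  sp <- score_panel(pep, panel, m, scheme = "target")
  expect_equal(nrow(sp), 4)
  expect_equal(sp$variant_id[1], "WT")
  expect_true(all(c("dg", "polar_method", "epsilon_in", "label") %in%
                    names(sp)))
  expect_equal(sp$label[1], "S")
})

test_that("double mutations score as a manually double-grafted structure", {
  pep <- gen_toy_peptide(seed = 3)
  m <- method_spec("GB-OBC")
  panel <- tibble::tibble(variant_id = "L101A+S102D",
                          mutations = "L101A+S102D")
  sp <- score_panel(pep, panel, m, scheme = "target")
  manual <- pep %>%
    graft_mutation("A", 101, "ALA", from_aa = "LEU", epsilon_in = 4) %>%
    graft_mutation("A", 102, "ASP", from_aa = "SER", epsilon_in = 4)
  want <- binding_free_energy(manual, m)
  expect_equal(sp$dg[sp$variant_id == "L101A+S102D"], want$dg,
               tolerance = 1e-12)
})

test_that("panel positions translate through a numbering map", {
  pep <- gen_toy_peptide(seed = 3)
  nm <- numbering_map(c(500, 600), c(101, 102))
  panel <- tibble::tibble(variant_id = "L500A", mutations = "L500A")
  sp <- score_panel(pep, panel, method_spec("GB-OBC"), map = nm,
                    scheme = "reference")
  expect_equal(nrow(sp), 2)
  # unmapped site names the variant in the error
  bad <- tibble::tibble(variant_id = "L999A", mutations = "L999A")
  expect_error(score_panel(pep, bad, method_spec("GB-OBC"), map = nm,
                           scheme = "reference"), "999")
})

test_that("method_spec validates its enumerations", {
  expect_error(method_spec("XX"), "arg")
  expect_error(method_spec(epsilon_in = 0), "epsilon")
  expect_error(method_spec(epsilon_in = 100, epsilon_out = 80), "epsilon")
  m <- method_spec("PB", epsilon_in = 2)
  expect_equal(m$pb$epsilon_in, 2)
})
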