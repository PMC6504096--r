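test_that("an isolated atom has effective radius rho - offset", {
  a <- mk_atoms(c(0, 0, 0), charge = 0.5, radius = 1.5)
  expect_equal(effective_born_radii(a, gb_config("OBC")), 1.41)
  expect_error(effective_born_radii(mk_atoms(c(0, 0, 0), radius = 0.05)),
               "non-positive")
})

test_that("a neighbour at 50 A leaves the radius essentially isolated", {
  a <- mk_atoms(rbind(c(0, 0, 0), c(50, 0, 0)), charge = 0, radius = 1.5)
  r <- effective_born_radii(a, gb_config("OBC"))
  expect_lt(abs(r[1] - 1.41), 1e-3)
})

test_that("the buried centre of a cluster has the largest effective radius", {
  # 12 neighbours around a central atom; oracle = direct comparison of
  # the descreening integrals (centre sees every neighbour up close)
  shell <- resistrank:::.sphere_points(12) * 3.4
  a <- mk_atoms(rbind(c(0, 0, 0), shell), charge = 0, radius = 1.7)
  r <- effective_born_radii(a, gb_config("OBC"))
  expect_true(all(r[1] > r[-1]))
})

test_that("GB reproduces the Born formula for a single ion", {
  ion <- mk_atoms(c(0, 0, 0), charge = 1, radius = 3.09)
  born <- -0.5 * 332.0637 * (1 - 1 / 80) / 3
  expect_equal(gb_polar(ion, radii = 3, epsilon_in = 1, epsilon_out = 80),
               born, tolerance = 1e-12)
  expect_equal(gb_polar(ion, radii = 3, epsilon_in = 1, epsilon_out = 1), 0)
  expect_equal(gb_polar(mk_atoms(c(0, 0, 0), charge = 0, radius = 2)), 0)
  expect_error(gb_polar(ion, radii = c(1, 2)), "match")
})

test_that("GB energy scales quadratically with total charge scaling", {
  cx <- random_complex(seed = 8)
  r <- effective_born_radii(cx)
  e1 <- gb_polar(cx, r, epsilon_in = 1)
  scaled <- cx; scaled$charge <- 3 * scaled$charge
  expect_equal(gb_polar(scaled, r, epsilon_in = 1), 9 * e1,
               tolerance = 1e-9)
})

test_that("GB polar energy is invariant under rigid motion", {
  cx <- random_complex(seed = 12)
  moved <- rigid_transform(cx)
  expect_equal(gb_polar(moved, epsilon_in = 4), gb_polar(cx, epsilon_in = 4),
               tolerance = 1e-8)
})

test_that("single-charge systems have non-positive GB energy", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      a <- mk_atoms(cbind(runif(6, -4, 4), runif(6, -4, 4),
                          runif(6, -4, 4)), radius = 1.6)
      a$charge <- c(1, rep(0, 5))
    })
    expect_lte(gb_polar(a, epsilon_in = 1), 0)
  }
})

test_that("ALPB tends to GB/(1+alpha*beta) as A grows and is exact for Born", {
  ion <- mk_atoms(c(0, 0, 0), charge = 1, radius = 3.09)
  ab <- 0.571412 * (1 / 80)
  gb <- gb_polar(ion, radii = 3, epsilon_in = 1, epsilon_out = 80)
  expect_equal(alpb_polar(ion, radii = 3, epsilon_in = 1, epsilon_out = 80,
                          A = Inf),
               gb / (1 + ab), tolerance = 1e-12)
  # with A equal to the Born radius the ALPB correction cancels exactly
  expect_equal(alpb_polar(ion, radii = 3, epsilon_in = 1, epsilon_out = 80,
                          A = 3),
               gb, tolerance = 1e-12)
  expect_equal(alpb_polar(mk_atoms(c(0, 0, 0), charge = 0, radius = 2)), 0)
  expect_error(alpb_polar(ion, radii = 3, A = -1), "A must be > 0")
})

test_that("the multi-atom ALPB limit matches GB elementwise", {
  cx <- random_complex(seed = 5)
  r <- effective_born_radii(cx)
  ab <- 0.571412 * (4 / 80)
  expect_equal(alpb_polar(cx, r, epsilon_in = 4, A = Inf),
               gb_polar(cx, r, epsilon_in = 4) / (1 + ab),
               tolerance = 1e-10)
})

test_that("electrostatic size rules behave sensibly", {
  ion <- mk_atoms(c(0, 0, 0), charge = 1, radius = 2.5)
  expect_equal(electrostatic_size(ion, "bounding-sphere"), 2.5)
  ball <- mk_atoms(resistrank:::.sphere_points(30) * 5, charge = 0.1,
                   radius = 1.5)
  a_bs <- electrostatic_size(ball, "bounding-sphere")
  a_sm <- electrostatic_size(ball, "structural-moments")
  expect_gt(a_bs, 5)
  expect_gt(a_sm, 5)
})

test_that("GBn neck parameters are physically placed", {
  p <- resistrank:::.neck_params(1.7, 1.7, 1.4)
  expect_gt(p[["m0"]], 0)
  expect_gt(p[["d0"]], 2 * 1.7)          # beyond atom contact
  expect_lt(p[["d0"]], 2 * 1.7 + 2 * 1.4) # before the neck vanishes
  # neck vanishes once a probe fits between the spheres
  expect_equal(resistrank:::.neck_integral(1.7 + 1.7 + 2 * 1.4 + 0.1,
                                           1.7, 1.7, 1.4), 0)
})

test_that("the GBn neck deepens burial relative to plain descreening", {
  pair <- mk_atoms(rbind(c(0, 0, 0), c(4, 0, 0)), charge = 0, radius = 1.7)
  cfg <- gb_config("GBn")
  cfg_noneck <- gb_config("GBn", s_neck = 0)
  r_neck <- effective_born_radii(pair, cfg)
  r_none <- effective_born_radii(pair, cfg_noneck)
  expect_true(all(r_neck > r_none))
})
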