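# Parameter lookups, the class-specific correction term, and the solvent
# registry.

test_that("parameter lookups return the shipped table values", {
  p <- default_parameters()
  expect_equal(lookup_params(p, "A", "H"), list(kappa = 0.124, g = 10.0))
  expect_equal(lookup_params(p, "B", "Br")$g, 23.3)
  expect_equal(lookup_params(p, "D", "I"), list(kappa = 0.052, g = -29.3))
  expect_equal(vdw_radius(p, "S"), 2.34)
  # unparameterized pairs fail loudly, naming class and element
  expect_error(lookup_params(p, "C", "I"), "'I' in solvent class C")
  expect_error(lookup_params(p, "A", "P"), "'P'")
  expect_error(vdw_radius(p, "P"), "'P'")
})

test_that("parameter table survives a write/read round trip", {
  p <- default_parameters()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_parameters(p, f)
  q <- read_parameters(f)
  expect_equal(q$radii, p$radii)
  expect_equal(q$zeta, p$zeta)
  expect_equal(q$kappa, p$kappa)
  expect_equal(q$g, p$g)
})

test_that("a chargeless H atom in water keeps only the area term", {
  r <- solvation_free_energy(make_born_ion("H", 0), "water")
  expect_equal(r$e_elst, 0)
  expect_equal(r$terms[["zeta_v"]], 0)   # zeta fixed at 0 for water
  expect_equal(r$terms[["g_q"]], 0)
  expect_equal(r$terms[["xi_s"]], 0)
  expect_equal(r$dg_solv, 0.124 * 4 * pi * 0.90^2, tolerance = 1e-10)
})

test_that("the proton correction combines area and induced-charge terms", {
  ion <- make_born_ion("H", 1)
  cav <- build_cavity(ion)
  sys <- build_system(ion, cav)
  sol <- solve_surface_charges(sys, ion, 78.36, cav$owner)
  corr <- correction_energy(default_parameters(), solvent_spec("water"),
                            cav, sol, ion)
  # hand-assembled: kappa_H * S_H + g_H * q_H, nothing else
  expect_equal(corr$dg_corr,
               0.124 * cav$total_area + 10.0 * sol$q_atom[1],
               tolerance = 1e-12)
  # induced charge on the dielectric side is ~ -(1 - 1/eps) * Q
  expect_equal(sol$q_atom[1], -(1 - 1 / 78.36), tolerance = 0.02)
})

test_that("the xi shift acts linearly through the total area, classes C/D only", {
  s <- make_random_solute(4, 17)
  base <- solvent_spec("acetone-like", eps = 20, cls = "C", xi = 0)
  shift <- solvent_spec("acetone-like", eps = 20, cls = "C", xi = 0.1)
  r0 <- solvation_free_energy(s, base)
  r1 <- solvation_free_energy(s, shift)
  expect_equal(r1$dg_solv - r0$dg_solv, 0.1 * r0$total_area,
               tolerance = 1e-10)
  # class B ignores xi entirely
  b0 <- solvation_free_energy(s, solvent_spec("b", eps = 20, cls = "B"))
  b1 <- solvation_free_energy(s, solvent_spec("b", eps = 20, cls = "B",
                                              xi = 0.1))
  expect_equal(b0$dg_solv, b1$dg_solv)
})

test_that("correction terms are size consistent for separated solutes", {
  p <- default_parameters()
  # chargeless dimer: every term is a pure atom-sum, additive to 1e-6
  s <- strip_charges(make_random_solute(4, 23))
  d <- make_dimer(s)
  for (spec in list(solvent_spec("water"), solvent_spec("methanol"),
                    solvent_spec("dimethyl sulfoxide"),
                    solvent_spec("hexane"))) {
    one <- solvation_free_energy(s, spec)
    two <- solvation_free_energy(d, spec)
    expect_lt(abs(two$dg_corr - 2 * one$dg_corr), 1e-6)
    expect_lt(abs(two$dg_solv - 2 * one$dg_solv), 1e-6)
  }
  # with charges, the induced-charge term keeps a genuine electrostatic
  # coupling between the monomers' COSMO solves that decays with distance
  sq <- make_random_solute(4, 23)
  one <- solvation_free_energy(sq, "methanol")
  dev <- vapply(c(50, 150), function(h) {
    two <- solvation_free_energy(make_dimer(sq, h), "methanol")
    abs(two$dg_corr - 2 * one$dg_corr)
  }, 0)
  expect_lt(dev[1], 2e-3)
  expect_lt(dev[2], dev[1])
})

test_that("solvent registry covers the four classes and validates entries", {
  reg <- solvent_registry()
  w <- solvent_spec("water")
  expect_equal(w$cls, "A"); expect_equal(w$xi, 0)
  expect_equal(solvent_spec("dimethyl sulfoxide")$cls, "C")
  expect_equal(solvent_spec("hexadecane")$cls, "D")
  expect_equal(solvent_spec("Methanol")$cls, "B")  # case-insensitive
  expect_true(all(reg$eps[reg$cls == "D"] < 9))
  expect_true(all(reg$eps > 1))
  expect_error(solvent_spec("wafer"), "nearest matches.*water")
  # explicit specs are validated
  expect_error(solvent_spec("oil", eps = 20, cls = "D"), "below 9")
  expect_error(solvent_spec("notwater", eps = 78, cls = "A"),
               "reserved for water")
  expect_error(solvent_spec("x", eps = 0.5, cls = "B"), "exceed 1")
})

test_that("a config file can add and override registry entries", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# overrides", "cyclopentane : 1.96 D",
               "methanol : 32.61 B -0.012"), f)
  reg <- solvent_registry(config = f)
  cp <- solvent_spec("cyclopentane", registry = reg)
  expect_equal(cp$cls, "D"); expect_equal(cp$eps, 1.96)
  me <- solvent_spec("methanol", registry = reg)
  expect_equal(me$xi, -0.012)
  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("methanol 32 B", bad)
  expect_error(solvent_registry(config = bad), "bad solvent config")
})
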