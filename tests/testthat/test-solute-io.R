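# Solute construction, validation, and the three input formats.

test_that("solute validation catches inconsistent inputs", {
  expect_error(solute(c("H", "O"), matrix(0, 1, 3), c(0, 0)),
               "equal length")
  expect_error(solute("H", matrix(0, 1, 3), 0.5, total_charge = 0),
               "sum to")
  expect_error(solute(c("H", "H"),
                      rbind(c(0, 0, 0), c(0.05, 0, 0)), c(0, 0)),
               "closer than 0.1")
  expect_error(solute("Xx", matrix(0, 1, 3), 0), "unknown element")
  expect_error(solute("D1", matrix(0, 1, 3), 0), "invalid element")
  # case normalization
  s <- solute("cl", matrix(0, 1, 3), -1, -1L)
  expect_identical(s$elements, "Cl")
})

test_that("XYZQ parses the documented dialect and round-trips losslessly", {
  s <- parse_xyzq(c("1", "Hplus 1", "H 0 0 0 1.0"))
  expect_identical(length(s$elements), 1L)
  expect_identical(s$total_charge, 1L)
  expect_identical(s$name, "Hplus")

  for (seed in 1:10) {
    orig <- make_random_solute(sample(1:6, 1), seed,
                               total_charge = sample(-1:1, 1))
    back <- parse_xyzq(write_xyzq(orig))
    expect_lt(max(abs(back$coords - orig$coords)), 1e-6)
    expect_lt(max(abs(back$charges - orig$charges)), 1e-6)
    expect_identical(back$elements, orig$elements)
    expect_identical(back$total_charge, orig$total_charge)
  }
})

test_that("XYZQ rejects malformed input", {
  expect_error(parse_xyzq(c("2", "two 0", "H 0 0 0 0")), "2 atoms but 1")
  expect_error(parse_xyzq(c("1", "bad 0", "H 0 0 zzz 0")), "non-numeric")
  expect_error(parse_xyzq(c("1", "bad 0", "Qq 0 0 0 0")), "unknown element")
  expect_error(parse_xyzq(c("1", "short 0")), "too short")
})

test_that("MOPAC outputs parse to the exact embedded structure", {
  h <- make_born_ion("H", 0, name = "hatom")
  s <- parse_mopac_output(make_mopac_text(h))
  expect_identical(s$elements, "H")
  expect_identical(s$charges, 0)
  expect_identical(s$total_charge, 0L)

  for (seed in 11:25) {
    orig <- make_random_solute(sample(2:6, 1), seed,
                               total_charge = sample(-1:1, 1))
    got <- parse_mopac_output(make_mopac_text(orig))
    expect_lt(max(abs(got$coords - orig$coords)), 1e-6)
    expect_lt(max(abs(got$charges - orig$charges)), 1e-6)
    expect_identical(got$elements, orig$elements)
    expect_identical(got$total_charge, orig$total_charge)
  }
})

test_that("MOPAC parser takes the last charge table and flags mismatches", {
  s <- make_random_solute(3, 3)
  txt <- make_mopac_text(s)
  # append a second, shifted charge table: the last one must win
  s2 <- s
  s2$charges <- s$charges + c(0.1, -0.1, 0)
  m2 <- make_mopac_text(s2)
  txt2 <- c(txt, m2[grep("NET ATOMIC CHARGES", m2):length(m2)])
  got <- parse_mopac_output(txt2)
  expect_lt(max(abs(got$charges - s2$charges)), 1e-6)

  # geometry of 3 atoms, charge table truncated to 2 rows
  bad <- txt[-(length(txt) - 2)]
  expect_error(parse_mopac_output(bad), "3 atoms but the charge table has 2")
  expect_error(
    parse_mopac_output(txt[1:(grep("NET ATOMIC", txt) - 1)]),
    "NET ATOMIC CHARGES")
  expect_error(parse_mopac_output("no geometry here"),
               "CARTESIAN COORDINATES")
})

test_that("MOPAC output without a charge record warns and assumes neutral", {
  s <- make_random_solute(2, 5)
  txt <- make_mopac_text(s)[-4]
  expect_warning(got <- parse_mopac_output(txt), "assuming a neutral")
  expect_identical(got$total_charge, 0L)
})

test_that("Gaussian outputs parse geometry, charges and total charge", {
  water <- solute(c("O", "H", "H"),
                  rbind(c(0, 0, 0.117), c(0, 0.757, -0.467),
                        c(0, -0.757, -0.467)),
                  c(-0.64, 0.32, 0.32), 0L, name = "water")
  got <- parse_gaussian_output(make_gaussian_text(water))
  expect_identical(got$elements, c("O", "H", "H"))
  expect_equal(sum(got$charges), 0, tolerance = 1e-10)
  expect_lt(max(abs(got$coords - water$coords)), 1e-6)

  for (seed in 31:45) {
    orig <- make_random_solute(sample(2:6, 1), seed,
                               total_charge = sample(-1:1, 1))
    got <- parse_gaussian_output(make_gaussian_text(orig))
    expect_lt(max(abs(got$coords - orig$coords)), 1e-6)
    expect_lt(max(abs(got$charges - orig$charges)), 1e-6)
    expect_identical(got$total_charge, orig$total_charge)
  }
})

test_that("truncated Gaussian files raise parse errors", {
  s <- make_random_solute(3, 7)
  txt <- make_gaussian_text(s)
  cut <- txt[1:grep("Mulliken charges:", txt, fixed = TRUE)[1]]
  expect_error(parse_gaussian_output(cut), "empty or truncated")
  expect_error(parse_gaussian_output(txt[1:2]), "no orientation block")
})

test_that("read_solute auto-detects all three formats", {
  s <- make_random_solute(3, 9, total_charge = 1L)
  d <- withr::local_tempdir()
  fm <- file.path(d, "a.out"); writeLines(make_mopac_text(s), fm)
  fg <- file.path(d, "b.log"); writeLines(make_gaussian_text(s), fg)
  fx <- file.path(d, "c.xyzq"); writeLines(write_xyzq(s), fx)
  for (f in c(fm, fg, fx)) {
    got <- read_solute(f)
    expect_lt(max(abs(got$coords - s$coords)), 1e-6)
    expect_identical(got$total_charge, s$total_charge)
  }
})
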