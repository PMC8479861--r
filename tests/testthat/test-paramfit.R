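# Weighted least-squares parameterization, the solvent-shift fit, and the
# error statistics.

test_that("design matrix has the documented shape and column content", {
  p <- default_parameters()
  tr <- make_synthetic_training(p, n = 8, noise_sd = 0, seed = 2,
                                elements = "C")
  d <- assemble_design_matrix(tr)
  expect_identical(colnames(d$X), c("kappa_C", "g_C", "zeta"))
  expect_identical(dim(d$X), c(8L, 3L))
  expect_equal(d$y, tr$dg_ref - tr$e_elst)
  # feature columns agree with directly recomputed pipeline sums
  s <- make_random_solute(3, 31, elements = c("C", "O"))
  cav <- build_cavity(s, p)
  sys <- build_system(s, cav)
  sol <- solve_surface_charges(sys, s, 20, cav$owner)
  row <- data.frame(dg_ref = 0, e_elst = electrostatic_energy(sys, sol, s, 20),
                    volume = cav$volume)
  for (el in c("C", "O")) {
    sel <- s$elements == el
    row[[paste0("S_", el)]] <- sum(cav$per_atom_area[sel])
    row[[paste0("q_", el)]] <- sum(sol$q_atom[sel])
  }
  d2 <- assemble_design_matrix(row)
  expect_equal(unname(d2$X[1, "kappa_C"]),
               sum(cav$per_atom_area[s$elements == "C"]))
  expect_equal(unname(d2$X[1, "g_O"]), sum(sol$q_atom[s$elements == "O"]))
  expect_equal(unname(d2$X[1, "zeta"]), cav$volume)
})

test_that("degenerate designs raise rank-deficiency errors naming columns", {
  one <- data.frame(dg_ref = 1, e_elst = 0, volume = 2, S_C = 3, q_C = 0.1)
  same <- one[rep(1, 5), ]
  same$dg_ref <- 1:5
  expect_error(solv_fit(same), "rank deficient")
  expect_error(solv_fit(one), "at least as many rows")
  expect_error(assemble_design_matrix(data.frame(dg_ref = 1, e_elst = 0)),
               "required columns|area columns")
})

test_that("noise-free synthetic fits recover the planted parameters exactly", {
  p <- default_parameters()
  for (seed in c(1, 12, 123)) {
    tr <- make_synthetic_training(p, n = 30, noise_sd = 0, seed = seed)
    fit <- solv_fit(tr)
    expect_equal(coef(fit), attr(tr, "true"), tolerance = 1e-8)
    expect_lt(max(abs(residuals(fit))), 1e-8)
  }
})

test_that("estimates are invariant to uniform weight rescaling", {
  tr <- make_synthetic_training(default_parameters(), n = 40,
                                noise_sd = 0.3, seed = 5)
  f1 <- solv_fit(tr)
  tr2 <- tr; tr2$weight <- tr$weight * 2
  f2 <- solv_fit(tr2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  # but non-uniform weights change the fit
  tr3 <- tr; tr3$weight <- seq_len(nrow(tr))
  expect_gt(max(abs(coef(solv_fit(tr3)) - coef(f1))), 1e-6)
})

test_that("weighted estimates agree with the reference linear-model fit", {
  tr <- make_synthetic_training(default_parameters(), n = 50,
                                noise_sd = 0.3, seed = 9)
  tr$weight <- rep(c(1, 2.5), length.out = nrow(tr))
  d <- assemble_design_matrix(tr)
  fit <- solv_fit(tr)
  ref <- lm(d$y ~ 0 + d$X, weights = d$w)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-8)
})

test_that("noisy fits recover parameters within statistical error", {
  p <- default_parameters()
  tr <- make_synthetic_training(p, n = 200, noise_sd = 0.3, seed = 31)
  fit <- solv_fit(tr)
  z <- (coef(fit) - attr(tr, "true")) / fit$se
  expect_lt(max(abs(z)), 3)
  # fitted predictions reproduce the references at the noise level
  pred <- predict(fit, tr)
  expect_lt(sqrt(mean((pred - tr$dg_ref)^2)), 2 * 0.3)
})

test_that("the solvent shift has its closed-form solution", {
  S <- c(80, 120, 150, 210)
  expect_equal(fit_xi_solv(0.07 * S, S), 0.07, tolerance = 1e-12)
  # residuals orthogonal to the areas give a zero shift
  r <- c(1, -1, 1, -1)
  r <- r - S * sum(r * S) / sum(S^2)
  expect_equal(fit_xi_solv(r, S), 0, tolerance = 1e-12)
  expect_error(fit_xi_solv(1, 80), "at least two")

  # planted shift with noise is recovered within 3 standard errors
  withr::local_seed(42)
  S <- runif(40, 60, 250)
  resid <- -0.05 * S + rnorm(40, 0, 0.3)
  xi <- fit_xi_solv(resid, S)
  se <- 0.3 / sqrt(sum(S^2))
  expect_lt(abs(xi - (-0.05)) / se, 3)
})

test_that("error statistics implement signed mean, absolute mean and RMSE", {
  expect_equal(solv_stats(c(1, -1)), c(mse = 0, mae = 1, sd = 1))
  expect_equal(solv_stats(c(0, 0, 0)), c(mse = 0, mae = 0, sd = 0))
  expect_equal(solv_stats(3), c(mse = 3, mae = 3, sd = 3))
  withr::local_seed(1)
  e <- rnorm(25)
  st <- solv_stats(e)
  expect_equal(st[["sd"]], sqrt(mean(e^2)))
  expect_equal(st[["mse"]], mean(e))
  expect_equal(st[["mae"]], mean(abs(e)))
  expect_error(solv_stats(numeric(0)), "empty")
})

test_that("training tables survive the CSV round trip", {
  tr <- make_synthetic_training(default_parameters(), n = 12,
                                noise_sd = 0.1, seed = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_training(tr, f)
  back <- read_training(f)
  expect_equal(back$dg_ref, tr$dg_ref, tolerance = 1e-12)
  expect_equal(coef(solv_fit(back)), coef(solv_fit(tr)), tolerance = 1e-10)
})
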