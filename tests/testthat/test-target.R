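# compact two-compartment fixture shared by several tests
make_target_data <- function(noise = 0, seed = 1, k_AB = 800, k_A = 100,
                             k_B = 40, n_wl = 30) {
  irf <- irf_model(0, 0.051)
  sc <- kinetic_scheme(c("A", "B"),
                       data.frame(from = c("A", "A", "B"),
                                  to = c("B", "GS", "GS"),
                                  rate = c(k_AB, k_A, k_B),
                                  id = c("k_AB", "k_A", "k_B")),
                       c(A = 1), irf = irf)
  shapes <- list(A = band_shape(c(510, 590), c(-1, 1.2), c(12, 20)),
                 B = band_shape(c(540, 620), c(0.8, -0.9), c(15, 14)))
  d <- generate_dataset(sc, shapes, irf = irf,
                        wavelengths = seq(480, 640, length.out = n_wl),
                        noise_sigma = noise, seed = seed)
  list(dataset = d, scheme = sc, shapes = shapes)
}

test_that("projection collapses to C^T Psi for orthonormal concentration columns", {
  set.seed(41)
  nt <- 80; nl <- 12
  Q <- qr.Q(qr(matrix(rnorm(nt * 3), nt, 3)))
  colnames(Q) <- c("A", "B", "C")
  Psi <- matrix(rnorm(nt * nl), nt, nl)
  d <- ta_dataset(seq_len(nt), seq(500, 610, length.out = nl), Psi)
  S <- project_spectra(Q, d)
  expect_equal(unname(S$spectra), unname(t(crossprod(Q, Psi))),
               tolerance = 1e-12)
})

test_that("noiseless projection with the true kinetics recovers the spectra exactly", {
  td <- make_target_data(noise = 0)
  C <- concentrations(td$scheme, td$scheme$irf, td$dataset$times)
  S <- project_spectra(C, td$dataset)
  S_true <- eval_band_spectra(td$shapes, td$dataset$wavelengths)
  expect_equal(unname(S$spectra), unname(S_true), tolerance = 1e-10)
})

test_that("zero-regions zero the spectrum and leave the banded residual unchanged", {
  td <- make_target_data(noise = 0.01, seed = 2)
  C <- concentrations(td$scheme, td$scheme$irf, td$dataset$times)
  cons <- constraint_set(zero = data.frame(compartment = "B",
                                           lo = 630, hi = 720))
  S <- project_spectra(C, td$dataset, cons)
  wl <- td$dataset$wavelengths
  expect_true(all(S$spectra[wl >= 630, "B"] == 0))
  expect_false(all(S$spectra[wl < 630, "B"] == 0))
  # inside the zero band the solve is identical to simply dropping B
  Cm <- C$C
  sub <- wl >= 630
  S_drop <- qr.coef(qr(Cm[, "A", drop = FALSE]), td$dataset$dA[, sub])
  expect_equal(unname(S$spectra[sub, "A"]), as.numeric(S_drop),
               tolerance = 1e-12)
})

test_that("rank-deficient designs name the collinear compartments", {
  td <- make_target_data(noise = 0)
  C <- concentrations(td$scheme, td$scheme$irf, td$dataset$times)$C
  C2 <- cbind(C, C[, "B", drop = FALSE])
  colnames(C2) <- c("A", "B", "Bcopy")
  expect_error(project_spectra(C2, td$dataset), "collinear")
})

test_that("variable projection is optimal: perturbing spectra raises the cost", {
  td <- make_target_data(noise = 0.02, seed = 3)
  C <- concentrations(td$scheme, td$scheme$irf, td$dataset$times)
  S <- project_spectra(C, td$dataset)
  cost0 <- sum(attr(S, "residuals")^2)
  set.seed(44)
  for (i in 1:5) {
    S_pert <- S$spectra + matrix(rnorm(length(S$spectra), 0, 0.01),
                                 nrow(S$spectra))
    cost_p <- sum((td$dataset$dA - C$C %*% t(S_pert))^2)
    expect_gt(cost_p, cost0)
  }
  # and the reported cost equals the recomputed reconstruction error
  cost_re <- sum((td$dataset$dA - C$C %*% t(S$spectra))^2)
  expect_equal(cost0, cost_re, tolerance = 1e-9)
})

test_that("zero free parameters reduces fit_target to per-dataset projection", {
  td <- make_target_data(noise = 0.01, seed = 4)
  fit <- fit_target(list(td$dataset), list(td$scheme))
  C <- concentrations(td$scheme, td$scheme$irf, td$dataset$times)
  S <- project_spectra(C, td$dataset)
  expect_equal(fit$sads[[1]]$spectra, S$spectra)
  expect_equal(fit$cost, sum(attr(S, "residuals")^2), tolerance = 1e-9)
})

test_that("noiseless target data return the generating rates to 1e-4 relative", {
  # k_AB and k_B are identified through the scheme eigenvalues; the
  # A -> GS loss is held fixed (with every spectrum free, only total decay
  # rates are identifiable -- branching splits need spectral assumptions)
  td <- make_target_data(noise = 0)
  start <- set_rates(td$scheme, c(k_AB = 500, k_B = 70))
  fit <- fit_target(list(td$dataset), list(start),
                    free = c("k_AB", "k_B"), seed = 1, n_starts = 1,
                    maxiter = 400, ftol = 1e-14, ptol = 1e-12)
  est <- setNames(fit$rates_table$rate, fit$rates_table$id)
  expect_equal(est[["k_AB"]], 800, tolerance = 1e-4)
  expect_equal(est[["k_B"]], 40, tolerance = 1e-4)
})

test_that("estimator bias of a free rate vanishes as noise goes to zero", {
  errs <- sapply(c(0.05, 0.01, 0.002), function(ns) {
    est <- sapply(1:20, function(r) {
      td <- make_target_data(noise = ns, seed = 100 * r)
      fit <- fit_target(list(td$dataset), list(td$scheme), free = "k_B",
                        seed = r, n_starts = 1)
      fit$rates_table$rate
    })
    abs(mean(est) - 40) / 40
  })
  expect_lt(errs[3], errs[1] + 0.01)
  expect_lt(errs[3], 0.01)
})

test_that("linked spectra are bit-identical and the link never lowers the cost", {
  irf <- irf_model(0, 0.051)
  sch <- load_scheme("fig3d_690")
  shapes <- tafit:::bands_690()
  zero <- scheme_constraints("fig3d_690")$zero
  wl <- ta_window("qy")
  mk <- function(seed) generate_dataset(sch, shapes, irf = irf,
                                        wavelengths = wl, noise_sigma = 0.02,
                                        seed = seed, zero = zero)
  d1 <- mk(11); d2 <- mk(12)
  cons_link <- constraint_set(zero = zero,
                              links = list(data.frame(dataset = c(1, 2),
                                                      compartment = "Sq")))
  cons_free <- constraint_set(zero = zero)
  f_link <- fit_target(list(d1, d2), list(sch, sch), constraints = cons_link)
  f_free <- fit_target(list(d1, d2), list(sch, sch), constraints = cons_free)
  expect_identical(f_link$sads[[1]]$spectra[, "Sq"],
                   f_link$sads[[2]]$spectra[, "Sq"])
  expect_gte(f_link$cost, f_free$cost - 1e-9)
  # zero-regions hold exactly in the fitted SADS
  expect_true(all(f_link$sads[[1]]$spectra[wl >= 630, "ChlT"] == 0))
  expect_true(all(f_link$sads[[1]]$spectra[wl <= 630, "CarT"] == 0))
})

test_that("correctly specified fits leave residuals without structure", {
  td <- make_target_data(noise = 0.02, seed = 6)
  fit <- fit_target(list(td$dataset), list(td$scheme), free = "k_AB",
                    seed = 1, n_starts = 1)
  frac_large <- mean(abs(fit$residuals[[1]]) > 3 * 0.02)
  expect_lt(frac_large, 0.01)
})

test_that("branching fractions and pathway yields follow the rate arithmetic", {
  one <- kinetic_scheme("A", data.frame(from = "A", to = "GS", rate = 5),
                        c(A = 1))
  by1 <- branching_yields(one)
  expect_equal(by1$fraction, 1)
  expect_equal(by1$yield, 1)
  two <- kinetic_scheme(c("A", "B"),
                        data.frame(from = c("A", "A", "B"),
                                   to = c("B", "GS", "GS"),
                                   rate = c(3000, 1000, 10)),
                        c(A = 1))
  by2 <- branching_yields(two)
  expect_equal(by2$fraction[1:2], c(0.75, 0.25))
  expect_equal(by2$yield[by2$to == "B"], 0.75)
  # reversible (cyclic) scheme handled exactly by the linear-system route
  cyc <- kinetic_scheme(c("A", "B"),
                        data.frame(from = c("A", "B", "B"),
                                   to = c("B", "A", "GS"),
                                   rate = c(2, 1, 1)), c(A = 1))
  byc <- branching_yields(cyc)
  expect_equal(sum(byc$yield[byc$to == "GS"]), 1, tolerance = 1e-12)
  # walker arithmetic: every pass through B splits 50/50 back to A vs GS
  expect_equal(byc$yield[byc$from == "B" & byc$to == "A"], 1)
  zero_tot <- kinetic_scheme(c("A", "B"),
                             data.frame(from = "A", to = "B", rate = 2),
                             c(A = 1))
  expect_error(branching_yields(zero_tot), "zero total")
})

test_that("target-scheme yields match the stochastic walker oracle within 3 sigma", {
  sc <- load_scheme("fig3b_508")
  exact <- branching_yields(sc)
  mc <- gillespie_yields(sc, n_walkers = 1e6, seed = 99)
  for (i in seq_len(nrow(exact))) {
    p <- exact$yield[i]
    se <- sqrt(p * (1 - p) / 1e6)
    expect_lt(abs(mc$yield[i] - p), max(3 * se, 1e-6))
  }
  # all excitation eventually reaches the ground state
  expect_equal(sum(exact$yield[exact$to == "GS"]), 1, tolerance = 1e-12)
})
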