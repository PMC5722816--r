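test_that("IRF-convolved exponential matches its closed-form limits", {
  # step centered at mu: half the amplitude for k = 0
  expect_equal(exp_conv_gauss(0, 0, mu = 0, sigma = 0.05), 0.5)
  expect_equal(exp_conv_gauss(0, 5, mu = 5, sigma = 1.3), 0.5)
  # delta-IRF limit reduces to the plain exponential
  expect_equal(exp_conv_gauss(0.1, 10, mu = 0, sigma = 1e-6), exp(-1),
               tolerance = 1e-9)
  # overflow-safe for large k * sigma products
  big <- exp_conv_gauss(1e4, c(0, 1, 10), mu = 0, sigma = 0.05)
  expect_true(all(is.finite(big)) && all(big >= 0))
  expect_error(exp_conv_gauss(0.1, Inf, 0, 0.05))
  expect_error(exp_conv_gauss(-1, 0, 0, 0.05))
  expect_error(exp_conv_gauss(0.1, 0, 0, 0))
})

test_that("IRF-convolved exponential agrees with quadrature of the convolution integral", {
  k <- 0.185  # the 6-ps carotenoid decay in ps^-1
  tt <- seq(-0.5, 20, length.out = 60)
  ours <- exp_conv_gauss(k, tt, mu = 0, sigma = 0.05)
  orac <- conv_quadrature(k, tt, mu = 0, sigma = 0.05)
  expect_equal(ours, orac, tolerance = 1e-6)
})

test_that("amplitude is monotone decreasing past the IRF-shifted peak", {
  # past t = mu + k sigma^2 the profile decays whenever the pulse is slower
  # than the instantaneous loss there, i.e. k sigma sqrt(2 pi) > 1; below
  # that the mode of the exponentially modified Gaussian sits later
  for (par in list(c(k = 2, sigma = 0.5), c(k = 30, sigma = 0.05),
                   c(k = 1, sigma = 1))) {
    k <- par[["k"]]; sigma <- par[["sigma"]]; mu <- 0.1
    tt <- seq(mu + k * sigma^2 + 1e-9, mu + k * sigma^2 + 12 / k,
              length.out = 400)
    g <- exp_conv_gauss(k, tt, mu, sigma)
    expect_true(all(diff(g) < 0))
  }
})

test_that("scheme validator enforces the structural invariants", {
  ok <- kinetic_scheme(c("A", "B"),
                       data.frame(from = c("A", "B"), to = c("B", "GS"),
                                  rate = c(2, 1)),
                       c(A = 1))
  expect_silent(validate_scheme(ok))
  K <- scheme_matrix(ok)
  # column j: off-diagonal nonnegative, diagonal covers the column outflow
  expect_true(all(K[row(K) != col(K)] >= 0))
  expect_true(all(-diag(K) - (colSums(K) - diag(K)) >= -1e-12))
  expect_equal(K["B", "A"], 2)
  expect_equal(K["A", "A"], -2)
  expect_error(kinetic_scheme(c("A", "A"), ok$rates, c(A = 1)), "unique")
  expect_error(kinetic_scheme("A", data.frame(from = "A", to = "GS", rate = -1),
                              c(A = 1)), "nonnegative")
  expect_error(kinetic_scheme("A", data.frame(from = "A", to = "GS", rate = 1),
                              c(A = 0.5)), "sum to 1")
  expect_error(kinetic_scheme("A", data.frame(from = "A", to = "B", rate = 1),
                              c(A = 1)), "not among")
})

test_that("single-compartment concentrations give the printed 183 ns^-1 lifetime", {
  # a 183 ns^-1 total decay corresponds to a 1000/183 ~ 5.46 ps lifetime
  sc <- kinetic_scheme("S1", data.frame(from = "S1", to = "GS", rate = 183),
                       c(S1 = 1))
  irf <- irf_model(0, 1e-4)
  tt <- c(1, 2, 5, 10, 20)
  C <- concentrations(sc, irf, tt)$C
  expect_equal(as.numeric(C), exp(-tt / (1000 / 183)), tolerance = 1e-7)
  tau <- 1000 / 183
  expect_equal(tau, 5.46, tolerance = 0.01)
})

test_that("analytic concentrations match the matrix-exponential oracle", {
  sc <- kinetic_scheme(c("A", "B"),
                       data.frame(from = c("A", "A", "B"),
                                  to = c("B", "GS", "GS"),
                                  rate = c(1500, 500, 300)),
                       c(A = 0.8, B = 0.2))
  irf <- irf_model(mu = 0.05, sigma = 0.04)
  tt <- c(-0.2, 0, 0.1, 0.5, 1, 3, 10)
  C <- concentrations(sc, irf, tt)$C
  orac <- expm_concentrations(scheme_matrix(sc) / 1000, sc$input,
                              0.05, 0.04, tt)
  expect_equal(unname(C), orac, tolerance = 1e-6)
})

test_that("analytic solution equals stiff ODE integration for random schemes", {
  for (s in 1:12) {
    n <- sample(2:6, 1)
    sc <- random_scheme(n, seed = 1000 + s)
    irf <- irf_model(0, 0.051)
    tt <- ta_time_grid()
    Ca <- concentrations(sc, irf, tt, method = "eigen")$C
    Co <- concentrations(sc, irf, tt, method = "ode")$C
    expect_lt(max(abs(Ca - Co)) / max(Ca), 1e-6)
  }
})

test_that("complex-eigenvalue (cyclic) schemes still match the ODE route", {
  # a directed 3-cycle with unequal rates has a complex eigenpair
  sc <- kinetic_scheme(c("A", "B", "C"),
                       data.frame(from = c("A", "B", "C", "A", "B", "C"),
                                  to = c("B", "C", "A", "GS", "GS", "GS"),
                                  rate = c(4000, 2500, 1500, 100, 150, 200)),
                       c(A = 1))
  ev <- eigen(scheme_matrix(sc))$values
  expect_true(any(abs(Im(ev)) > 1e-9))
  irf <- irf_model(0, 0.051)
  tt <- ta_time_grid()
  Ca <- concentrations(sc, irf, tt, method = "eigen")$C
  Co <- concentrations(sc, irf, tt, method = "ode")$C
  expect_lt(max(abs(Ca - Co)) / max(Ca), 1e-6)
})

test_that("degenerate rates trigger the ODE fallback and stay accurate", {
  sc <- kinetic_scheme(c("A", "B"),
                       data.frame(from = c("A", "B"), to = c("B", "GS"),
                                  rate = c(200, 200)),
                       c(A = 1))
  irf <- irf_model(0, 1e-4)
  tt <- c(1, 5, 10, 25)
  expect_error(concentrations(sc, irf, tt, method = "eigen"), "degenerate")
  C <- concentrations(sc, irf, tt)$C   # auto falls back
  k <- 0.2
  expect_equal(C[, "B"], k * tt * exp(-k * tt), tolerance = 1e-6)
})

test_that("population is conserved: closed scheme and ground-state bookkeeping", {
  closed <- kinetic_scheme(c("A", "B"),
                           data.frame(from = c("A", "B"), to = c("B", "A"),
                                      rate = c(900, 400)),
                           c(A = 1))
  irf <- irf_model(0, 0.03)
  tt <- seq(0.5, 3000, length.out = 40)
  C <- concentrations(closed, irf, tt)$C
  expect_equal(rowSums(C), rep(1, length(tt)), tolerance = 1e-9)

  # open scheme: compartments + integrated ground-state flux = 1 after pulse
  sc <- random_scheme(4, seed = 7)
  K <- scheme_matrix(sc) / 1000
  loss <- -colSums(K)   # ps^-1 loss to ground per compartment
  tfine <- seq(-0.3, 200, length.out = 20001)
  Cf <- concentrations(sc, irf, tfine)$C
  gs_flux <- as.numeric(Cf %*% loss)
  total_end <- sum(Cf[length(tfine), ]) +
    sum((gs_flux[-1] + gs_flux[-length(tfine)]) / 2 * diff(tfine))
  expect_equal(total_end, 1, tolerance = 1e-6)
})

test_that("sequential amplitude matrix reproduces chain populations", {
  expect_equal(sequential_amplitudes(2.5), matrix(1, 1, 1))
  B <- sequential_amplitudes(c(1, 0.5, 0.1))
  expect_equal(B[1, 1], 1)
  # populations via b against the matrix-exponential oracle (delta pulse)
  rates <- c(1, 0.5, 0.1)
  sc <- sequential_scheme(1 / rates * 1000 / 1000)  # lifetimes in ps = 1/rate
  K <- scheme_matrix(sc) / 1000
  tt <- seq(0.2, 30, length.out = 25)
  orac <- expm_delta(K, sc$input, tt)
  G <- sapply(rates, function(k) exp(-k * tt))
  expect_equal(unname(G %*% B), orac, tolerance = 1e-8)
  expect_error(sequential_amplitudes(c(1, 1 + 1e-12)), "concentrations")
  expect_error(sequential_amplitudes(c(1, -2)), "positive")
})

test_that("sequential amplitudes agree with the general path on a chain", {
  tau <- c(0.17, 2.7, 7.8)  # ps
  irf <- irf_model(0.02, 0.051)
  tt <- ta_time_grid()
  sc <- sequential_scheme(tau, irf = irf)
  C_general <- concentrations(sc, irf, tt)$C
  B <- sequential_amplitudes(1 / tau)
  G <- sapply(1 / tau, function(k) exp_conv_gauss(k, tt, irf$mu, irf$sigma))
  expect_equal(unname(C_general), G %*% B, tolerance = 1e-9)
})

test_that("chain ordering shows the printed carotenoid components peaking in order", {
  # the six-component carotenoid-excitation chain, including the printed
  # 2.7 ps (1000/2.7 ns^-1) and 7.8 ps components
  tau <- c(0.03, 0.17, 2.7, 7.8, 300, 3000)
  sc <- sequential_scheme(tau)
  irf <- irf_model(0, 0.051)
  tt <- sort(unique(c(ta_time_grid(), seq(0.5, 40, by = 0.05))))
  C <- concentrations(sc, irf, tt)$C
  peaks <- tt[apply(C, 2, which.max)]
  expect_true(all(diff(peaks) > 0))
})
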