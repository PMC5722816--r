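#' Scaled complementary error function
#'
#' Computes `exp(x^2) * erfc(x)` without overflow for large positive `x`,
#' using the log-scale normal tail probability. For real input only.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @keywords internal
#' @noRd
erfcx <- function(x) {
  exp(x^2 + log(2) + stats::pnorm(-x * sqrt(2), log.p = TRUE))
}

#' Exponential decay convolved with a Gaussian instrument response
#'
#' Closed form of the convolution of `exp(-k t)` for `t >= 0` with a
#' unit-area Gaussian of center `mu` and standard deviation `sigma`:
#' \deqn{g(t) = \tfrac12 \exp(k^2\sigma^2/2 - k(t-\mu))\,
#'   \mathrm{erfc}\!\left(\frac{\mu + k\sigma^2 - t}{\sigma\sqrt2}\right).}
#' Evaluated through the scaled complementary error function so that large
#' `k * sigma` products do not overflow. This is the elementary response of
#' every IRF-convolved kinetic model in the package.
#'
#' @param k decay rate in 1/ps, `k >= 0`. May be a complex scalar (used for
#'   oscillatory eigenmodes of cyclic schemes), in which case the real part
#'   of the decay must be nonnegative.
#' @param t time axis in ps (vector).
#' @param mu IRF center in ps.
#' @param sigma IRF standard deviation in ps, `> 0`.
#' @return amplitude at each `t` (dimensionless); complex if `k` is complex.
#' @examples
#' exp_conv_gauss(0, 0, mu = 0, sigma = 0.05)  # 0.5 at the step center
#' @export
exp_conv_gauss <- function(k, t, mu = 0, sigma) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a positive finite scalar")
  if (length(mu) != 1L || !is.finite(mu))
    stop("`mu` must be a finite scalar")
  if (any(!is.finite(t)))
    stop("`t` must be finite")
  u <- t - mu
  if (is.complex(k)) {
    if (any(!is.finite(k)) || any(Re(k) < 0))
      stop("complex `k` must be finite with nonnegative real part")
    x <- (k * sigma^2 - u) / (sigma * sqrt(2))
    return(0.5 * exp(0.5 * k^2 * sigma^2 - k * u) * (1 - pracma::erfz(x)))
  }
  if (any(!is.finite(k)) || any(k < 0))
    stop("`k` must be finite and nonnegative")
  x <- (k * sigma^2 - u) / (sigma * sqrt(2))
  out <- numeric(length(x))
  pos <- x > 0
  # x > 0: exp(a) erfc(x) = erfcx(x) exp(a - x^2), and a - x^2 = -u^2/(2 sigma^2)
  if (any(pos))
    out[pos] <- 0.5 * exp(-(u[pos]^2) / (2 * sigma^2)) * erfcx(x[pos])
  if (any(!pos)) {
    # x <= 0 implies k*u > k^2 sigma^2, so the exponent is <= 0: safe directly
    out[!pos] <- 0.5 * exp(0.5 * k^2 * sigma^2 - (if (length(k) > 1) k[!pos] else k) * u[!pos]) *
      (2 * stats::pnorm(-x[!pos] * sqrt(2)))
  }
  out
}

#' Gaussian instrument-response model
#'
#' @param mu center of the instrument response in ps.
#' @param sigma Gaussian standard deviation in ps (`> 0`). Alternatively give
#'   `fwhm`.
#' @param fwhm full width at half maximum in ps; converted to `sigma` via
#'   `fwhm / (2 sqrt(2 log 2))`.
#' @return an object of class `irf_model` with fields `mu` and `sigma`.
#' @export
irf_model <- function(mu = 0, sigma = NULL, fwhm = NULL) {
  if (is.null(sigma)) {
    if (is.null(fwhm)) stop("give either `sigma` or `fwhm`")
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
  }
  if (!is.finite(sigma) || sigma <= 0) stop("IRF sigma must be > 0")
  structure(list(mu = mu, sigma = sigma), class = "irf_model")
}

#' First-order compartmental kinetic scheme
#'
#' Builds and validates a compartmental scheme. Rates are stored in ns^-1
#' (the convention used for the printed rate constants on kinetic-scheme
#' figures); times everywhere else in the package are in ps, and the unit
#' conversion happens in exactly one place, [concentrations()].
#'
#' The transfer matrix `K` is column-stochastic-oriented: `K[i, j]` with
#' `i != j` is the rate from compartment `j` into compartment `i`, and the
#' diagonal `K[j, j]` is minus the total decay rate of `j` (transfers plus
#' loss to the ground state).
#'
#' @param compartments character vector of unique compartment labels.
#' @param rates data frame with columns `from`, `to`, `rate` (ns^-1) and
#'   optionally `id` (parameter identifier, used for cross-scheme linking)
#'   and `provenance`. `to = "GS"` denotes loss to the ground state.
#' @param input named numeric vector of excitation fractions (entries >= 0,
#'   summing to 1); names must be compartment labels. Compartments absent
#'   from `input` receive 0.
#' @param name optional scheme name.
#' @param irf optional [irf_model()] associated with the scheme file.
#' @return an object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(compartments, rates, input, name = NULL, irf = NULL) {
  rates <- as.data.frame(rates, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "rate") %in% names(rates)))
    stop("`rates` needs columns from, to, rate")
  if (is.null(rates$id))
    rates$id <- paste0(rates$from, "_to_", rates$to)
  if (is.null(rates$provenance)) rates$provenance <- "free"
  j <- rep(0, length(compartments))
  names(j) <- compartments
  j[names(input)] <- input
  scheme <- structure(
    list(compartments = compartments, rates = rates, input = j,
         name = name, irf = irf),
    class = "kinetic_scheme")
  validate_scheme(scheme)
  scheme
}

#' Validate a kinetic scheme
#'
#' Checks the structural invariants: unique labels, nonnegative rates with
#' known endpoints, nonnegative ground-state outflow for every compartment
#' (the diagonal dominates the off-diagonal column sum by construction), and
#' an input vector with nonnegative entries summing to 1.
#'
#' @param scheme a `kinetic_scheme`.
#' @return the scheme, invisibly; errors describe the violated invariant.
#' @export
validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  cmp <- scheme$compartments
  if (anyDuplicated(cmp)) stop("compartment labels must be unique")
  r <- scheme$rates
  bad <- !(r$from %in% cmp) | !(r$to %in% c(cmp, "GS"))
  if (any(bad))
    stop("rate endpoints not among compartments: ",
         paste(unique(c(r$from[bad], r$to[bad])), collapse = ", "))
  if (any(r$from == r$to)) stop("self-transfer rates are not allowed")
  if (any(!is.finite(r$rate)) || any(r$rate < 0))
    stop("rates must be finite and nonnegative")
  if (anyDuplicated(r[c("from", "to")]))
    stop("duplicate rate entries for the same edge")
  dup <- tapply(r$rate, r$id, function(v) length(unique(v)) > 1)
  if (any(dup))
    stop("rate id used with conflicting values: ",
         paste(names(dup)[dup], collapse = ", "))
  j <- scheme$input
  if (any(j < 0) || abs(sum(j) - 1) > 1e-8)
    stop("input fractions must be >= 0 and sum to 1")
  invisible(scheme)
}

#' Transfer-rate matrix of a scheme
#'
#' @param scheme a `kinetic_scheme`.
#' @return square matrix `K` in ns^-1, `K[i, j]` = rate j -> i for `i != j`,
#'   diagonal = minus total decay rate (see [kinetic_scheme()]).
#' @export
scheme_matrix <- function(scheme) {
  cmp <- scheme$compartments
  n <- length(cmp)
  K <- matrix(0, n, n, dimnames = list(cmp, cmp))
  for (e in seq_len(nrow(scheme$rates))) {
    from <- scheme$rates$from[e]; to <- scheme$rates$to[e]
    k <- scheme$rates$rate[e]
    K[from, from] <- K[from, from] - k
    if (to != "GS") K[to, from] <- K[to, from] + k
  }
  K
}

#' Set rate values by parameter id
#' @param scheme a `kinetic_scheme`.
#' @param values named numeric vector; names are rate `id`s.
#' @return the updated scheme.
#' @export
set_rates <- function(scheme, values) {
  idx <- match(scheme$rates$id, names(values))
  hit <- !is.na(idx)
  scheme$rates$rate[hit] <- unname(values[idx[hit]])
  scheme
}

#' IRF-driven concentrations of a compartmental scheme
#'
#' Solves `dc/dt = K c + j g(t)` with `g` the unit-area Gaussian IRF,
#' analytically via eigendecomposition of `K`, each eigenmode rendered by
#' [exp_conv_gauss()]. Rates are stored in ns^-1 and converted to ps^-1
#' (divided by 1000) here, the single place where units change. If the
#' eigenvalues are degenerate within a relative tolerance of 1e-9 the closed
#' form is singular and the function falls back to a stiff numerical
#' integration of the driven system.
#'
#' @param scheme a `kinetic_scheme`.
#' @param irf an [irf_model()]; defaults to the scheme's own.
#' @param times delay axis in ps, sorted ascending.
#' @param method `"auto"` (eigendecomposition with ODE fallback),
#'   `"eigen"`, or `"ode"`.
#' @return object of class `concentration_matrix`: list with `times` and
#'   matrix `C` (one column per compartment).
#' @export
concentrations <- function(scheme, irf = scheme$irf, times,
                           method = c("auto", "eigen", "ode")) {
  method <- match.arg(method)
  validate_scheme(scheme)
  if (is.null(irf)) stop("no IRF given and the scheme carries none")
  if (is.unsorted(times)) stop("`times` must be sorted ascending")
  K <- scheme_matrix(scheme) / 1000  # ns^-1 -> ps^-1, the only conversion
  j <- scheme$input
  n <- length(j)
  degenerate <- FALSE
  if (method != "ode") {
    eig <- eigen(K)
    lam <- eig$values
    scale <- max(abs(lam), 1e-300)
    d <- abs(outer(lam, lam, "-")) / scale
    degenerate <- any(d[upper.tri(d)] < 1e-9)
    if (!degenerate) {
      # clamp roundoff-positive real parts (e.g. the zero mode of a closed
      # scheme) so the decay rates passed on are nonnegative
      rp <- Re(lam)
      rp[rp > 0 & rp < 1e-10 * scale] <- 0
      lam <- if (is.complex(lam)) complex(real = rp, imaginary = Im(lam)) else rp
      V <- eig$vectors
      w <- if (is.complex(V)) solve(V, as.complex(j)) else solve(V, j)
      G <- sapply(seq_len(n), function(m)
        exp_conv_gauss(-lam[m], times, irf$mu, irf$sigma))
      if (!is.matrix(G)) G <- matrix(G, nrow = length(times))
      # c(t) = sum_m g_m(t) w_m V[, m]
      C <- Re(G %*% t(V * matrix(w, n, n, byrow = TRUE)))
      colnames(C) <- scheme$compartments
      return(structure(list(times = times, C = C),
                       class = "concentration_matrix"))
    }
    if (method == "eigen")
      stop("degenerate eigenvalues (relative gap < 1e-9); use method = \"ode\"")
  }
  C <- ode_concentrations(K, j, irf$mu, irf$sigma, times)
  colnames(C) <- scheme$compartments
  structure(list(times = times, C = C), class = "concentration_matrix")
}

# Stiff numerical integration of dc/dt = K c + j g(t). The Gaussian pulse is
# narrow relative to the full delay range, so the integration is split at
# mu + 8 sigma: before the split the maximum step is capped at sigma/3 so the
# solver cannot step over the pulse, afterwards the driving term is zero.
ode_concentrations <- function(K_ps, input, mu, sigma, times) {
  n <- length(input)
  rhs_pulse <- function(t, y, p)
    list(as.vector(K_ps %*% y) + input * stats::dnorm(t, mu, sigma))
  rhs_free <- function(t, y, p) list(as.vector(K_ps %*% y))
  split <- mu + 8 * sigma
  t0 <- min(times[1], mu - 8 * sigma)
  C <- matrix(0, length(times), n)
  early <- times <= split
  y <- rep(0, n)
  if (any(early)) {
    tt <- unique(c(t0, times[early], split))
    sol <- deSolve::ode(y = y, times = tt, func = rhs_pulse, parms = NULL,
                        method = "lsoda", hmax = sigma / 3,
                        rtol = 1e-10, atol = 1e-12)
    keep <- match(times[early], tt)
    C[early, ] <- sol[keep, -1, drop = FALSE]
    y <- as.numeric(sol[nrow(sol), -1])
  } else {
    tt <- unique(c(t0, split))
    sol <- deSolve::ode(y = y, times = tt, func = rhs_pulse, parms = NULL,
                        method = "lsoda", hmax = sigma / 3,
                        rtol = 1e-10, atol = 1e-12)
    y <- as.numeric(sol[nrow(sol), -1])
  }
  if (any(!early)) {
    tt <- c(split, times[!early])
    sol <- deSolve::ode(y = y, times = tt, func = rhs_free, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    C[!early, ] <- sol[-1, -1, drop = FALSE]
  }
  C
}

#' Amplitude matrix of a sequential (unbranched) kinetic chain
#'
#' For a chain in which every compartment decays with total rate `k_l` into
#' the next, the population of compartment `l` is
#' `sum_{j<=l} b[j, l] g(k_j, t)` with `g` the IRF-convolved exponential
#' ([exp_conv_gauss()]) and
#' \deqn{b_{jl} = \frac{\prod_{m=1}^{l-1} k_m}{\prod_{m=1,m\neq j}^{l} (k_m - k_j)}.}
#' The closed form is singular at equal rates, hence the distinctness
#' precondition; near-degenerate chains should go through the general
#' [concentrations()] path.
#'
#' @param rates positive decay rates of the chain, in chain order (any time
#'   unit; the result is dimensionless).
#' @return upper-triangular matrix `b` with `b[1, 1] = 1`.
#' @export
sequential_amplitudes <- function(rates) {
  n <- length(rates)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("rates must be positive and finite")
  if (n > 1) {
    rel <- abs(outer(rates, rates, "-")) / max(rates)
    if (any(rel[upper.tri(rel)] < 1e-9))
      stop("near-degenerate rates: use the general concentrations() path")
  }
  B <- matrix(0, n, n)
  for (l in seq_len(n)) {
    num <- prod(rates[seq_len(l - 1)])
    for (j in seq_len(l)) {
      den <- prod(rates[setdiff(seq_len(l), j)] - rates[j])
      B[j, l] <- num / den
    }
  }
  B
}

#' Build a sequential chain scheme from lifetimes
#'
#' Convenience constructor for global analysis and the synthetic generator:
#' `n` compartments, each decaying entirely into the next (the last into the
#' ground state), with total rates `1000 / lifetimes` ns^-1 and all input in
#' the first compartment.
#'
#' @param lifetimes_ps positive lifetimes in ps, one per compartment.
#' @param labels optional compartment labels (default `S1..Sn`).
#' @param irf optional [irf_model()].
#' @return a `kinetic_scheme`.
#' @export
sequential_scheme <- function(lifetimes_ps, labels = NULL, irf = NULL) {
  n <- length(lifetimes_ps)
  if (is.null(labels)) labels <- paste0("comp", seq_len(n))
  to <- c(labels[-1], "GS")
  rates <- data.frame(from = labels, to = to, rate = 1000 / lifetimes_ps,
                      stringsAsFactors = FALSE)
  input <- stats::setNames(c(1, rep(0, n - 1)), labels)[1]
  kinetic_scheme(labels, rates, input, irf = irf)
}

# IRF-convolved decay profiles of a sequential chain on a time grid:
# columns are compartment populations, computed from the amplitude matrix.
# Rates in ps^-1. Near-degenerate rates are nudged apart by 1e-7 relative so
# optimizers crossing a degeneracy keep a finite, continuous-enough surface.
chain_profiles <- function(rates_ps, times, mu, sigma) {
  n <- length(rates_ps)
  if (n > 1) {
    o <- order(rates_ps)
    repeat {
      s <- sort(rates_ps)
      rel <- diff(s) / max(s)
      if (all(rel >= 1e-8)) break
      i <- which(rel < 1e-8)[1]
      bump <- s[i + 1] * 1e-7 + 1e-300
      rates_ps[o[i + 1]] <- rates_ps[o[i + 1]] + bump
    }
  }
  B <- sequential_amplitudes(rates_ps)
  G <- vapply(rates_ps, function(k) exp_conv_gauss(k, times, mu, sigma),
              numeric(length(times)))
  G %*% B
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme", if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat("  compartments:", paste(x$compartments, collapse = ", "), "\n")
  cat("  input:", paste(sprintf("%s=%.3g", names(x$input)[x$input > 0],
                                x$input[x$input > 0]), collapse = ", "), "\n")
  r <- x$rates
  cat(sprintf("  %-10s -> %-10s %10s ns^-1  [%s]\n",
              r$from, r$to, format(r$rate, digits = 6), r$provenance), sep = "")
  invisible(x)
}
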