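#' Set of associated difference spectra
#'
#' One difference spectrum per kinetic component or compartment: EADS for a
#' sequential chain, DADS for the equivalent parallel model, SADS for a
#' general target scheme.
#'
#' @param kind `"EADS"`, `"DADS"` or `"SADS"`.
#' @param wavelengths shared wavelength axis in nm.
#' @param spectra matrix, `length(wavelengths)` rows, one column per
#'   component (mOD).
#' @param labels component labels.
#' @param constraints optional annotations (zero-regions, link ids).
#' @return object of class `spectrum_set`.
#' @export
spectrum_set <- function(kind = c("EADS", "DADS", "SADS"), wavelengths,
                         spectra, labels = NULL, constraints = NULL) {
  kind <- match.arg(kind)
  spectra <- as.matrix(spectra)
  if (nrow(spectra) != length(wavelengths))
    stop("spectra must have one row per wavelength")
  if (is.null(labels)) labels <- paste0("comp", seq_len(ncol(spectra)))
  colnames(spectra) <- labels
  structure(list(kind = kind, wavelengths = wavelengths, spectra = spectra,
                 labels = labels, constraints = constraints),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("%s: %d spectra on %d channels (%.4g-%.4g nm)\n", x$kind,
              ncol(x$spectra), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Decay-associated from evolution-associated difference spectra
#'
#' The sequential chain and the parallel sum-of-exponentials model span the
#' same function space; the exact linear transform between their amplitude
#' spectra is \eqn{DADS_j = \sum_l b_{jl}\, EADS_l} with `b` from
#' [sequential_amplitudes()]. The transform is invertible
#' (see [eads_from_dads()]).
#'
#' @param eads a `spectrum_set` of kind EADS.
#' @param rates total decay rates of the chain, in chain order (one per
#'   spectrum; any consistent time unit).
#' @return a `spectrum_set` of kind DADS.
#' @export
dads_from_eads <- function(eads, rates) {
  stopifnot(inherits(eads, "spectrum_set"))
  if (length(rates) != ncol(eads$spectra))
    stop("need one rate per EADS")
  B <- sequential_amplitudes(rates)
  spectrum_set("DADS", eads$wavelengths, eads$spectra %*% t(B), eads$labels)
}

#' Evolution-associated from decay-associated difference spectra
#' @param dads a `spectrum_set` of kind DADS.
#' @param rates as in [dads_from_eads()].
#' @return a `spectrum_set` of kind EADS.
#' @export
eads_from_dads <- function(dads, rates) {
  stopifnot(inherits(dads, "spectrum_set"))
  if (length(rates) != ncol(dads$spectra))
    stop("need one rate per DADS")
  B <- sequential_amplitudes(rates)
  spectrum_set("EADS", dads$wavelengths,
               t(solve(B, t(dads$spectra))), dads$labels)
}

#' Global analysis: sequential-scheme fit of one TA dataset
#'
#' Fits \eqn{\Delta A(t,\lambda)} with an `n_components` sequential chain in
#' which every compartment decays into the next, all convolved with a
#' Gaussian IRF. The spectra (EADS) are eliminated at every step by variable
#' projection (per-wavelength linear least squares against the chain's
#' concentration matrix), so the nonlinear search runs only over the
#' lifetimes and, optionally, the IRF center and width. The optimizer is
#' seeded multi-start Levenberg-Marquardt with lifetimes log-parametrized to
#' stay positive. Components are returned in ascending lifetime order (ties
#' broken by EADS norm); the DADS of the numerically equivalent parallel
#' model are included.
#'
#' @param dataset a [ta_dataset()].
#' @param n_components number of sequential compartments (>= 1, at most the
#'   numerical rank of the data matrix).
#' @param irf an [irf_model()] giving the starting IRF.
#' @param init_lifetimes optional positive, increasing starting lifetimes in
#'   ps; defaults to a log-spaced ladder across the measured delay range.
#' @param seed integer seed for the multi-start jitter.
#' @param n_starts number of optimizer starts (first start unjittered).
#' @param fit_irf also fit the IRF center and width (default `TRUE`).
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return object of class `ta_fit` with elements `lifetimes` (ps), `irf`,
#'   `eads`, `dads`, `residuals`, `rss`, `singular_values`, `convergence`.
#' @export
fit_sequential <- function(dataset, n_components, irf,
                           init_lifetimes = NULL, seed = 1L, n_starts = 8L,
                           fit_irf = TRUE, maxiter = 50L) {
  stopifnot(inherits(dataset, "ta_dataset"), n_components >= 1)
  Psi <- dataset$dA
  times <- dataset$times
  sv <- svd(Psi, nu = 0, nv = 0)$d
  rank <- sum(sv > sv[1] * 1e-10)
  if (n_components > rank)
    stop("n_components (", n_components, ") exceeds data rank (", rank, ")")
  lo <- max(2 * irf$sigma, 1e-3)
  hi <- max(times) / 3
  if (is.null(init_lifetimes))
    init_lifetimes <- exp(seq(log(lo), log(hi), length.out = n_components))
  if (length(init_lifetimes) != n_components || any(init_lifetimes <= 0))
    stop("init_lifetimes must be ", n_components, " positive values")

  resid_fn <- function(p) {
    tau <- exp(p[seq_len(n_components)])
    mu <- if (fit_irf) p[n_components + 1] else irf$mu
    sig <- if (fit_irf) exp(p[n_components + 2]) else irf$sigma
    C <- chain_profiles(1 / tau, times, mu, sig)
    qrC <- qr(C)
    as.vector(qr.resid(qrC, Psi))
  }

  p0 <- c(log(init_lifetimes),
          if (fit_irf) c(irf$mu, log(irf$sigma)))
  set.seed(seed)
  best <- NULL
  conv_any <- FALSE
  for (s in seq_len(n_starts)) {
    p <- p0
    if (s > 1) {
      # alternate between jittering the supplied ladder and jittered
      # ladders with a raised floor: multi-exponential surfaces have local
      # minima that park one component at an unsupported ultrafast lifetime
      if (s %% 3 == 0) {
        lo_s <- lo * 5^(1 + (s %/% 3) %% 2)
        p[seq_len(n_components)] <-
          seq(log(lo_s), log(hi), length.out = n_components)
      }
      p[seq_len(n_components)] <- p[seq_len(n_components)] +
        stats::rnorm(n_components, 0, 0.3)
      if (fit_irf) p[n_components + 1] <- p[n_components + 1] +
          stats::rnorm(1, 0, irf$sigma / 2)
    }
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = p, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, nprint = 0))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$info %in% 1:4) conv_any <- TRUE
    if (is.null(best) || fit$deviance < best$deviance * (1 - 5e-3)) {
      best <- fit
      best$start <- s
      best$hits <- 1L
    } else if (fit$deviance < best$deviance * (1 + 5e-3)) {
      # another start reached the same basin
      best$hits <- best$hits + 1L
    }
    # stop exploring once two independent starts agree on the best minimum
    if (s >= 3 && conv_any && best$hits >= 2L) break
  }
  if (is.null(best))
    stop("sequential fit failed in all ", n_starts, " starts")
  if (!conv_any)
    stop("sequential fit did not converge in any start; best residual sum ",
         "of squares ", format(best$deviance))

  p <- best$par
  tau <- exp(p[seq_len(n_components)])
  mu <- if (fit_irf) p[n_components + 1] else irf$mu
  sig <- if (fit_irf) exp(p[n_components + 2]) else irf$sigma
  # the projection residual depends only on the span of the exponentials,
  # so the chain may be reordered to ascending lifetime and re-solved
  C0 <- chain_profiles(1 / tau, times, mu, sig)
  S0 <- qr.coef(qr(C0), Psi)
  norms <- sqrt(rowSums(S0^2))
  o <- order(tau, norms)
  tau <- tau[o]
  C <- chain_profiles(1 / tau, times, mu, sig)
  qrC <- qr(C)
  S <- qr.coef(qrC, Psi)               # n x n_lambda
  R <- qr.resid(qrC, Psi)
  labels <- paste0("EADS", seq_len(n_components))
  eads <- spectrum_set("EADS", dataset$wavelengths, t(S), labels)
  dads <- dads_from_eads(eads, 1 / tau)
  dads$kind <- "DADS"
  structure(list(
    kind = "sequential",
    lifetimes = tau,
    rates = 1000 / tau,  # ns^-1
    irf = irf_model(mu = mu, sigma = sig),
    eads = eads, dads = dads,
    residuals = R, rss = sum(R^2),
    singular_values = sv[seq_len(min(10, length(sv)))],
    convergence = list(info = best$info, iterations = best$niter,
                       start = best$start, seed = seed,
                       message = best$message)),
    class = "ta_fit")
}

#' @export
print.ta_fit <- function(x, ...) {
  cat("TA fit (", x$kind, ")\n", sep = "")
  if (!is.null(x$lifetimes))
    cat("  lifetimes (ps):", paste(signif(x$lifetimes, 4), collapse = ", "), "\n")
  if (!is.null(x$rates_table)) {
    cat("  rates (ns^-1):\n")
    print(x$rates_table, row.names = FALSE)
  }
  cat("  rss:", format(x$rss %||% x$cost), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
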