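#' Gaussian band-shape set for a compartment
#'
#' Stylized difference spectrum built from signed Gaussian bands (negative =
#' ground-state bleach, positive = excited-state absorption).
#'
#' @param center band centers in nm.
#' @param amplitude signed amplitudes in mOD.
#' @param width Gaussian standard deviations in nm (> 0).
#' @return object of class `band_shape` (a data frame).
#' @export
band_shape <- function(center, amplitude, width) {
  if (any(width <= 0)) stop("band widths must be > 0")
  structure(data.frame(center = center, amplitude = amplitude, width = width),
            class = c("band_shape", "data.frame"))
}

#' Evaluate band shapes on a wavelength axis
#'
#' @param shapes named list of [band_shape()]s, one per compartment.
#' @param wavelengths axis in nm.
#' @param zero optional zero-region data frame (`compartment`, `lo`, `hi`)
#'   clipped to exactly zero, so generated truth honors the same constraints
#'   used at fit time.
#' @return matrix, `length(wavelengths)` rows, one column per compartment.
#' @export
eval_band_spectra <- function(shapes, wavelengths, zero = NULL) {
  S <- vapply(names(shapes), function(nm) {
    b <- shapes[[nm]]
    y <- rep(0, length(wavelengths))
    for (i in seq_len(nrow(b)))
      y <- y + b$amplitude[i] * exp(-0.5 * ((wavelengths - b$center[i]) / b$width[i])^2)
    y
  }, numeric(length(wavelengths)))
  colnames(S) <- names(shapes)
  if (!is.null(zero)) for (r in seq_len(nrow(zero))) {
    i <- which(colnames(S) == zero$compartment[r])
    if (length(i))
      S[wavelengths >= zero$lo[r] & wavelengths <= zero$hi[r], i] <- 0
  }
  S
}

#' Default delay grid of the emulated pump-probe instrument
#'
#' 50 linear points in \[-0.5, 2\] ps (resolving the fs instrument response)
#' followed by 70 log-spaced points out to 3500 ps (the delay-line maximum of
#' 3.5 ns).
#'
#' @return numeric vector of delays in ps.
#' @export
ta_time_grid <- function() {
  lin <- seq(-0.5, 2, length.out = 50)
  log <- exp(seq(log(2), log(3500), length.out = 71))[-1]
  c(lin, log)
}

#' Detection window axes of the emulated instrument
#'
#' Two 76-channel windows of about 130 nm each: the Soret/carotenoid window
#' (480-610 nm) and the Chl Q_x/Q_y window (590-720 nm).
#'
#' @param which `"soret"` or `"qy"`.
#' @return wavelength axis in nm (length 76).
#' @export
ta_window <- function(which = c("soret", "qy")) {
  which <- match.arg(which)
  if (which == "soret") seq(480, 610, length.out = 76)
  else seq(590, 720, length.out = 76)
}

#' Generate a synthetic TA dataset from a kinetic scheme
#'
#' \eqn{\Delta A = C\,S^T + \varepsilon} with `C` the IRF-convolved
#' concentrations of the scheme, `S` the band-shape spectra, and
#' \eqn{\varepsilon} i.i.d. Gaussian noise. The generating truth is stored
#' on the dataset.
#'
#' @param scheme a `kinetic_scheme`.
#' @param shapes named list of [band_shape()]s covering every compartment.
#' @param irf an [irf_model()] (defaults to the scheme's).
#' @param times delay axis in ps (default [ta_time_grid()]).
#' @param wavelengths detection axis in nm (default Soret [ta_window()]).
#' @param noise_sigma additive noise standard deviation in mOD.
#' @param seed integer seed (required: synthetic data are reproducible).
#' @param excitation pump wavelength to record, nm.
#' @param zero optional zero-region data frame applied to the truth spectra.
#' @return a [ta_dataset()] with `truth` attached.
#' @export
generate_dataset <- function(scheme, shapes, irf = scheme$irf,
                             times = ta_time_grid(),
                             wavelengths = ta_window("soret"),
                             noise_sigma = 0, seed,
                             excitation = NA_real_, zero = NULL) {
  missing_sh <- setdiff(scheme$compartments, names(shapes))
  if (length(missing_sh))
    stop("no band shape for compartment: ", paste(missing_sh, collapse = ", "))
  if (missing(seed)) stop("a seed is required")
  C <- concentrations(scheme, irf, times)$C
  S <- eval_band_spectra(shapes[scheme$compartments], wavelengths, zero)
  clean <- C %*% t(S)
  set.seed(seed)
  dA <- clean + matrix(stats::rnorm(length(clean), 0, noise_sigma),
                       nrow(clean), ncol(clean))
  ta_dataset(times, wavelengths, dA, excitation = excitation,
             noise_sigma = noise_sigma,
             truth = list(scheme = scheme, shapes = shapes, irf = irf,
                          spectra = S, clean = clean, seed = seed))
}

# stylized band shapes for the 508-nm target scheme compartments
bands_508 <- function() {
  list(
    S2    = band_shape(c(500, 570), c(-1.0, 0.9), c(14, 28)),
    hotS1 = band_shape(c(500, 645), c(-1.0, 1.2), c(14, 38)),
    S1    = band_shape(c(500, 595, 630), c(-1.0, 1.5, 1.2), c(14, 12, 12)),
    Sstar = band_shape(c(498, 592, 558), c(-1.0, 1.6, 0.5), c(14, 14, 20)),
    Sq    = band_shape(c(500, 590), c(-0.3, 1.0), c(14, 45)),
    Chl   = band_shape(c(680, 550), c(-2.0, 0.25), c(9, 70)),
    S1u   = band_shape(c(492, 605, 640), c(-0.9, 1.3, 0.9), c(13, 16, 14)))
}

# stylized band shapes for the 690-nm target scheme compartments; the
# triplet shapes are clipped by the same zero regions the fit assumes
bands_690 <- function() {
  list(
    Chla1p = band_shape(c(682, 560), c(-2.0, 0.15), c(8.5, 70)),
    Chla2p = band_shape(c(676, 560), c(-1.9, 0.15), c(8.5, 70)),
    Chla3p = band_shape(c(670, 560), c(-1.8, 0.15), c(8.5, 70)),
    Sq     = band_shape(c(500, 590), c(-0.3, 1.0), c(14, 45)),
    ChlT   = band_shape(c(520, 600), c(0.8, 0.4), c(28, 18)),
    CarT   = band_shape(c(662), c(1.0), c(16)))
}

# printed global-analysis component sets used by the sequential generator:
# 508 nm: <100 fs, 170 fs, 2.7 ps, 7.8 ps published; 300 ps quenched-Chl
# stand-in and a >ns long-lived component complete the six.
# 690 nm: 2.2 ps published equilibration; the rest are stand-ins.
seq_lifetimes_508 <- function() c(0.03, 0.17, 2.7, 7.8, 300, 3000)
seq_lifetimes_690 <- function() c(2.2, 30, 350, 3200)

seq_bands_508 <- function() {
  list(
    comp1 = band_shape(c(508, 495), c(1.5, -1.2), c(8, 8)),
    comp2 = band_shape(c(500, 645), c(-1.0, 1.2), c(14, 38)),
    comp3 = band_shape(c(500, 595, 630), c(-1.0, 1.5, 1.2), c(14, 12, 12)),
    comp4 = band_shape(c(498, 592, 558), c(-1.0, 1.6, 0.5), c(14, 14, 20)),
    comp5 = band_shape(c(680, 590), c(-1.5, 0.5), c(9, 45)),
    comp6 = band_shape(c(680), c(-0.15), c(9)))
}

seq_bands_690 <- function() {
  list(
    comp1 = band_shape(c(686, 560), c(-2.0, 0.1), c(8, 70)),
    comp2 = band_shape(c(680, 590), c(-1.8, 0.3), c(8.5, 45)),
    comp3 = band_shape(c(678, 590), c(-1.5, 0.6), c(9, 45)),
    comp4 = band_shape(c(678), c(-0.12), c(9)))
}

#' Generate a synthetic paired-window pump-probe experiment
#'
#' Emulates one pump-probe measurement of the astaxanthin-binding LHC: two
#' 76-channel spectral windows (Soret 480-610 nm and Chl Q_x/Q_y 590-720 nm)
#' on the default delay grid, 120-fs-FWHM Gaussian IRF, additive white noise
#' of 2% of the peak signal. With `model = "target"` the kinetics come from
#' the shipped target scheme for the chosen excitation ([load_scheme()]);
#' with `model = "sequential"` from an unbranched chain with the
#' global-analysis component lifetimes (six components at 508 nm, four at
#' 690 nm). Band-shape spectra are arbitrary stylizations; only the kinetic
#' parameters carry meaning.
#'
#' @param excitation 508 or 690 (nm).
#' @param seed integer seed.
#' @param model `"target"` or `"sequential"`.
#' @param noise_frac noise sigma as a fraction of the peak absolute clean
#'   signal over both windows (default 0.02).
#' @return list with elements `soret` and `qy`, each a [ta_dataset()] with
#'   ground truth attached.
#' @export
generate_paper_like <- function(excitation, seed,
                                model = c("target", "sequential"),
                                noise_frac = 0.02) {
  model <- match.arg(model)
  if (!excitation %in% c(508, 690))
    stop("excitation must be 508 or 690 (nm)")
  irf <- irf_model(mu = 0, fwhm = 0.120)
  zero <- NULL
  if (model == "target") {
    name <- if (excitation == 508) "fig3b_508" else "fig3d_690"
    scheme <- load_scheme(name)
    shapes <- if (excitation == 508) bands_508() else bands_690()
    cz <- scheme_constraints(name)$zero
    zero <- cz
  } else {
    tau <- if (excitation == 508) seq_lifetimes_508() else seq_lifetimes_690()
    scheme <- sequential_scheme(tau, irf = irf)
    shapes <- if (excitation == 508) seq_bands_508() else seq_bands_690()
  }
  times <- ta_time_grid()
  C <- concentrations(scheme, irf, times)$C
  wl_s <- ta_window("soret"); wl_q <- ta_window("qy")
  Ss <- eval_band_spectra(shapes[scheme$compartments], wl_s, zero)
  Sq <- eval_band_spectra(shapes[scheme$compartments], wl_q, zero)
  clean_s <- C %*% t(Ss); clean_q <- C %*% t(Sq)
  set.seed(seed)
  # homoscedastic instrument noise: one sigma for both windows of the
  # experiment, scaled to the overall peak signal (the noise floor does not
  # drop in a window where the sample happens to absorb little)
  peak <- max(abs(clean_s), abs(clean_q))
  mk <- function(clean, wl) {
    noise_sigma <- noise_frac * peak
    dA <- clean + matrix(stats::rnorm(length(clean), 0, noise_sigma),
                         nrow(clean), ncol(clean))
    ta_dataset(times, wl, dA, excitation = excitation,
               noise_sigma = noise_sigma,
               truth = list(scheme = scheme, shapes = shapes, irf = irf,
                            model = model, clean = clean, seed = seed,
                            zero = zero))
  }
  list(soret = mk(clean_s, wl_s), qy = mk(clean_q, wl_q))
}
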