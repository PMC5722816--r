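#' Transient-absorption dataset
#'
#' Container for a difference-absorption matrix \eqn{\Delta A(t, \lambda)}.
#'
#' @param times delay axis in ps, strictly increasing.
#' @param wavelengths detection axis in nm, strictly increasing.
#' @param dA matrix of difference absorption in mOD, `length(times)` rows by
#'   `length(wavelengths)` columns.
#' @param excitation pump wavelength in nm (optional).
#' @param window spectral window `c(min, max)` nm; defaults to the range of
#'   `wavelengths`.
#' @param noise_sigma additive noise standard deviation in mOD, if known.
#' @param truth for synthetic data, a list tagging the generating ground
#'   truth (scheme, spectra, irf, seed).
#' @return object of class `ta_dataset`.
#' @export
ta_dataset <- function(times, wavelengths, dA, excitation = NA_real_,
                       window = range(wavelengths), noise_sigma = NA_real_,
                       truth = NULL) {
  dA <- as.matrix(dA)
  if (nrow(dA) != length(times) || ncol(dA) != length(wavelengths))
    stop("dA must be length(times) x length(wavelengths)")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(times = times, wavelengths = wavelengths, dA = dA,
                 excitation = excitation, window = window,
                 noise_sigma = noise_sigma, truth = truth),
            class = "ta_dataset")
}

#' @export
print.ta_dataset <- function(x, ...) {
  cat(sprintf("TA dataset: %d delays (%.3g to %.4g ps) x %d channels (%.4g-%.4g nm)\n",
              length(x$times), min(x$times), max(x$times),
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  if (is.finite(x$excitation)) cat("  excitation:", x$excitation, "nm\n")
  if (is.finite(x$noise_sigma)) cat("  noise sigma:", x$noise_sigma, "mOD\n")
  if (!is.null(x$truth)) cat("  synthetic (ground truth attached)\n")
  invisible(x)
}

# split a delimited line, auto-detecting the delimiter among tab/comma/semicolon
detect_delim <- function(line) {
  counts <- vapply(c("\t", ",", ";"), function(d)
    length(gregexpr(d, line, fixed = TRUE)[[1]][gregexpr(d, line, fixed = TRUE)[[1]] > 0]),
    integer(1))
  if (all(counts == 0)) " " else names(which.max(counts))
}

#' Read a transient-absorption matrix file
#'
#' File dialect: first row holds the wavelength axis in nm (its first cell is
#' a corner label or empty), first column the delay axis in ps, and the body
#' the \eqn{\Delta A} values in mOD. Delimiter is auto-detected among tab,
#' comma and semicolon (fields may also be space-separated). Unsorted delay
#' rows are sorted with a warning; ragged rows, non-numeric cells and
#' duplicated axis values are parse errors reporting the line number.
#'
#' @param path file path.
#' @param excitation optional pump wavelength in nm to record.
#' @return a [ta_dataset()].
#' @export
read_ta_matrix <- function(path, excitation = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("TA matrix needs a header row and data rows")
  delim <- detect_delim(lines[1])
  split1 <- function(x) {
    f <- if (delim == " ") strsplit(trimws(x), "[ \t]+")[[1]]
         else strsplit(x, delim, fixed = TRUE)[[1]]
    trimws(f)
  }
  head_f <- split1(lines[1])
  # the corner cell may be an arbitrary label; drop it
  wl <- suppressWarnings(as.numeric(head_f[-1]))
  if (anyNA(wl)) stop("line 1: non-numeric wavelength cell")
  ncol_expect <- length(head_f)
  nr <- length(lines) - 1L
  times <- numeric(nr)
  dA <- matrix(NA_real_, nr, length(wl))
  for (i in seq_len(nr)) {
    f <- split1(lines[i + 1])
    if (length(f) != ncol_expect)
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, ncol_expect, length(f)))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric cell", i + 1L))
    times[i] <- v[1]
    dA[i, ] <- v[-1]
  }
  if (anyDuplicated(times)) stop("duplicate delay values in first column")
  if (anyDuplicated(wl)) stop("duplicate wavelength values in header")
  if (is.unsorted(times)) {
    warning("delay axis not sorted; sorting rows")
    o <- order(times)
    times <- times[o]; dA <- dA[o, , drop = FALSE]
  }
  if (is.unsorted(wl)) {
    warning("wavelength axis not sorted; sorting columns")
    o <- order(wl)
    wl <- wl[o]; dA <- dA[, o, drop = FALSE]
  }
  ta_dataset(times, wl, dA, excitation = excitation)
}

#' Write a transient-absorption matrix file
#'
#' Inverse of [read_ta_matrix()]: tab-delimited, full double precision
#' (`%.17g`), first row wavelengths, first column delays.
#'
#' @param dataset a [ta_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ta_matrix <- function(dataset, path) {
  fmt <- function(x) sprintf("%.17g", x)
  head <- paste(c("time_ps", fmt(dataset$wavelengths)), collapse = "\t")
  rows <- vapply(seq_along(dataset$times), function(i)
    paste(c(fmt(dataset$times[i]), fmt(dataset$dA[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(head, rows), path)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records package version, R version, seed and any configuration values
#' next to a run's outputs, so the run can be repeated bit-for-bit on the
#' same platform.
#'
#' @param path output file path (YAML).
#' @param seed integer seed that drove the run.
#' @param config named list of run settings.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, config = list()) {
  m <- list(
    package = "tafit",
    version = as.character(utils::packageVersion("tafit")),
    r_version = R.version.string,
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = seed,
    config = config)
  yaml::write_yaml(m, path)
  invisible(path)
}
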