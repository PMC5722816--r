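#' Read a kinetic-scheme file
#'
#' Scheme files are declarative YAML with sections `compartments`, `rates`
#' (entries `from`, `to`, `rate` in ns^-1, optional `id` and `provenance`),
#' `input` (excitation fractions) and optional `irf` (`mu`, `sigma` in ps)
#' and `constraints` (per-compartment `zero` wavelength intervals in nm).
#'
#' @param path YAML file path.
#' @return a `kinetic_scheme`; any constraints appear as attribute
#'   `"constraints"`.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("no such scheme file: ", path)
  y <- yaml::read_yaml(path)
  rates <- do.call(rbind, lapply(y$rates, function(r)
    data.frame(from = r$from, to = r$to, rate = as.numeric(r$rate),
               id = if (is.null(r$id)) paste0(r$from, "_to_", r$to) else r$id,
               provenance = if (is.null(r$provenance)) "free" else r$provenance,
               stringsAsFactors = FALSE)))
  irf <- if (!is.null(y$irf)) irf_model(mu = y$irf$mu, sigma = y$irf$sigma)
  scheme <- kinetic_scheme(unlist(y$compartments), rates,
                           unlist(y$input), name = y$name, irf = irf)
  if (!is.null(y$excitation)) scheme$excitation <- y$excitation
  if (!is.null(y$constraints))
    attr(scheme, "constraints") <- y$constraints
  scheme
}

#' Write a kinetic-scheme file
#'
#' Inverse of [read_scheme()]; numeric values are serialized with enough
#' digits that read -> write -> read is value-identical.
#'
#' @param scheme a `kinetic_scheme`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  r <- scheme$rates
  y <- list(
    name = scheme$name,
    excitation = scheme$excitation,
    compartments = as.list(scheme$compartments),
    rates = lapply(seq_len(nrow(r)), function(i)
      list(from = r$from[i], to = r$to[i], rate = r$rate[i],
           id = r$id[i], provenance = r$provenance[i])),
    input = as.list(scheme$input[scheme$input > 0]),
    irf = if (!is.null(scheme$irf))
      list(mu = scheme$irf$mu, sigma = scheme$irf$sigma),
    constraints = attr(scheme, "constraints"))
  y <- y[!vapply(y, is.null, logical(1))]
  writeLines(yaml::as.yaml(y, precision = 15), path)
  invisible(path)
}

#' Load a shipped kinetic scheme by name
#'
#' The package ships the two target models for the astaxanthin-binding LHC:
#' `fig3b_508` (carotenoid excitation at 508 nm: S2 branching into hot S1 and
#' S*, relaxation to S1, energy transfer to the Chl pool, quenching by S_q,
#' and a parallel branch for astaxanthin unconnected to the Chls) and
#' `fig3d_690` (Chl excitation at 690 nm: uphill equilibration over three
#' Chl a pools, quenching of each pool by S_q at heterogeneous rates, and
#' minor Chl/Car triplet formation). Rates carry provenance `printed` when
#' the value is a published rate constant and `free` when it is a
#' package-chosen default meant to be refined by fitting. The S_q decay
#' carries the same parameter id (`Sq_decay`) in both schemes, so fitting
#' them simultaneously links that rate.
#'
#' @param name one of `"fig3b_508"`, `"fig3d_690"`.
#' @return a validated `kinetic_scheme` (round-trips through
#'   [write_scheme()]/[read_scheme()] value-exactly).
#' @export
load_scheme <- function(name) {
  avail <- list_schemes()
  if (!name %in% avail)
    stop("unknown scheme '", name, "'; available: ",
         paste(avail, collapse = ", "))
  read_scheme(system.file("extdata", "schemes", paste0(name, ".yaml"),
                          package = "tafit", mustWork = TRUE))
}

#' List shipped scheme names
#' @return character vector of names usable with [load_scheme()].
#' @export
list_schemes <- function() {
  files <- list.files(system.file("extdata", "schemes", package = "tafit"),
                      pattern = "\\.yaml$")
  sort(sub("\\.yaml$", "", files))
}

#' Spectral constraints of a shipped scheme
#'
#' Returns the zero-region constraint set declared in a shipped scheme file
#' (e.g. the triplet SADS of `fig3d_690`: Chl T zero above 630 nm and Car T
#' zero below 630 nm) as a [constraint_set()].
#'
#' @param name scheme name as in [load_scheme()].
#' @return a `constraint_set` (empty if the scheme declares none).
#' @export
scheme_constraints <- function(name) {
  sc <- load_scheme(name)
  cz <- attr(sc, "constraints")$zero
  if (is.null(cz)) return(constraint_set())
  zero <- do.call(rbind, lapply(cz, function(z)
    data.frame(compartment = z$compartment, lo = z$lo, hi = z$hi,
               stringsAsFactors = FALSE)))
  constraint_set(zero = zero)
}

#' Functionally unconnected carotenoids per complex
#'
#' Pigment-stoichiometry arithmetic: with `chl_per_monomer` chlorophylls and
#' a measured Chl/Car molar ratio, the complex carries
#' `round(chl_per_monomer / chl_car_ratio)` carotenoids in total; whatever
#' exceeds the number of carotenoid binding sites cannot be coupled to the
#' chlorophylls. Rounding to the nearest integer reflects that measured
#' stoichiometries are per-complex averages.
#'
#' @param chl_per_monomer chlorophylls per monomeric complex (positive).
#' @param chl_car_ratio measured Chl/Car molar ratio (positive).
#' @param n_binding_sites carotenoid binding sites per monomer (positive).
#' @return integer count of unconnected carotenoids (floored at 0).
#' @examples
#' unconnected_carotenoids(14, 2.37, 3)  # 3
#' @export
unconnected_carotenoids <- function(chl_per_monomer, chl_car_ratio,
                                    n_binding_sites) {
  if (!all(is.finite(c(chl_per_monomer, chl_car_ratio, n_binding_sites))) ||
      chl_per_monomer <= 0 || chl_car_ratio <= 0 || n_binding_sites <= 0)
    stop("all stoichiometry inputs must be positive")
  max(0L, as.integer(round(chl_per_monomer / chl_car_ratio) - n_binding_sites))
}
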