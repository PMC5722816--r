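#' Signed torsion (dihedral) angle of four points
#'
#' IUPAC convention: the angle between the plane (p1, p2, p3) and the plane
#' (p2, p3, p4), signed, with 0 for the eclipsed (cis) arrangement and 180
#' for anti (trans). Computed with the atan2 formulation, which is
#' numerically stable near +/- 90 degrees.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) == 0 || sum(b2^2) == 0 || sum(b3^2) == 0)
    stop("consecutive points coincide")
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  if (sum(n1^2) < 1e-24 * sum(b1^2) * sum(b2^2) ||
      sum(n2^2) < 1e-24 * sum(b2^2) * sum(b3^2))
    stop("three consecutive points are collinear")
  m <- cross(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
  # cis is 0 when p1 and p4 eclipse: the above yields 0 there and pi for anti
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Dihedral atom selector
#'
#' Names the four atoms defining a ring-chain torsion by chain, residue
#' number and atom name, with side and site labels for reporting. The exact
#' atom quadruple per carotenoid end ring is an editable assumption; see the
#' mapping file in `system.file("extdata", "dihedral_specs", package =
#' "tafit")`.
#'
#' @param chain chain identifiers (length 4 or recycled scalar).
#' @param resid residue numbers (length 4 or recycled scalar).
#' @param atoms four distinct atom names.
#' @param side `"stromal"` or `"lumenal"` (optional label).
#' @param site `"L1"`, `"L2"` or `"N1"` (optional label).
#' @return object of class `dihedral_spec`.
#' @export
dihedral_spec <- function(chain, resid, atoms, side = NA_character_,
                          site = NA_character_) {
  chain <- rep_len(as.character(chain), 4)
  resid <- rep_len(as.integer(resid), 4)
  if (length(atoms) != 4 ||
      anyDuplicated(paste(chain, resid, atoms)))
    stop("a dihedral needs four distinct atoms")
  structure(list(chain = chain, resid = resid, atoms = as.character(atoms),
                 side = side, site = site), class = "dihedral_spec")
}

#' Read a multi-frame PDB coordinate ensemble
#'
#' Reads a (possibly multi-MODEL) PDB file into an atom table plus a frames
#' by 3*natoms coordinate matrix. Binary trajectory formats are out of
#' scope; convert upstream.
#'
#' @param path PDB file path.
#' @return object of class `coord_ensemble`: list with `atom` (data frame)
#'   and `xyz` (matrix, one row per frame).
#' @export
read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  structure(list(atom = pdb$atom, xyz = unclass(xyz)),
            class = "coord_ensemble")
}

# resolve a dihedral_spec to the 4 atom row indices of an ensemble
resolve_spec <- function(ensemble, spec) {
  at <- ensemble$atom
  idx <- integer(4)
  for (i in 1:4) {
    hit <- which(at$elety == spec$atoms[i] &
                 at$resno == spec$resid[i] &
                 (is.na(spec$chain[i]) | at$chain == spec$chain[i]))
    if (length(hit) != 1)
      stop("atom selector (", spec$chain[i], " ", spec$resid[i], " ",
           spec$atoms[i], ") matched ", length(hit), " atoms")
    idx[i] <- hit
  }
  idx
}

circular_mean <- function(deg) {
  r <- deg * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

circular_variance <- function(deg) {
  r <- deg * pi / 180
  1 - sqrt(mean(sin(r))^2 + mean(cos(r))^2)
}

#' Dihedral-angle distribution over a coordinate ensemble
#'
#' Computes the torsion for every frame (after discarding leading
#' equilibration frames), wraps angles to (-180, 180], bins them on a fixed
#' circular grid and reports circular statistics. Distributions from
#' different ensembles are meant to be reported side by side (see
#' [angle_distribution_table()]); they are never pooled silently.
#'
#' @param ensemble a [read_pdb_frames()] ensemble (a single-frame structure
#'   reduces to one marker value, as for crystal structures).
#' @param spec a [dihedral_spec()].
#' @param bin_width histogram bin width in degrees (default 5; must divide
#'   360).
#' @param discard number of leading frames to drop.
#' @return object of class `angle_distribution`: `angles` (degrees),
#'   `breaks`, `counts`, `mean` (circular), `variance` (circular, in
#'   \[0, 1\]), `n`.
#' @export
angle_distribution <- function(ensemble, spec, bin_width = 5, discard = 0) {
  stopifnot(inherits(ensemble, "coord_ensemble"))
  nf <- nrow(ensemble$xyz)
  if (discard >= nf) stop("no frames left after discarding ", discard)
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  idx <- resolve_spec(ensemble, spec)
  cols <- function(i) (3 * (idx[i] - 1) + 1):(3 * idx[i])
  frames <- (discard + 1):nf
  ang <- vapply(frames, function(f) {
    x <- ensemble$xyz[f, ]
    dihedral(x[cols(1)], x[cols(2)], x[cols(3)], x[cols(4)])
  }, numeric(1))
  ang <- ((ang + 180) %% 360) - 180
  ang[ang == -180] <- 180
  breaks <- seq(-180, 180, by = bin_width)
  counts <- as.integer(table(cut(ang, breaks, right = TRUE,
                                 include.lowest = TRUE)))
  structure(list(angles = ang, breaks = breaks, counts = counts,
                 mean = circular_mean(ang),
                 variance = circular_variance(ang),
                 n = length(ang), spec = spec),
            class = "angle_distribution")
}

#' Side-by-side dihedral distributions for several ensembles
#'
#' @param ensembles named list of `coord_ensemble`s (e.g. independent
#'   simulation runs or crystal structures).
#' @param spec a [dihedral_spec()].
#' @param bin_width,discard as in [angle_distribution()].
#' @return long data frame: `ensemble`, `bin_mid` (degrees), `count`, plus
#'   per-ensemble circular `mean`, `variance` and `n` repeated on each row.
#' @export
angle_distribution_table <- function(ensembles, spec, bin_width = 5,
                                     discard = 0) {
  stopifnot(length(names(ensembles)) == length(ensembles))
  do.call(rbind, lapply(names(ensembles), function(nm) {
    d <- angle_distribution(ensembles[[nm]], spec, bin_width, discard)
    mid <- (d$breaks[-1] + d$breaks[-length(d$breaks)]) / 2
    data.frame(ensemble = nm, bin_mid = mid, count = d$counts,
               mean = d$mean, variance = d$variance, n = d$n,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat(sprintf("Dihedral distribution: n = %d, circular mean = %.2f deg, circular variance = %.4f\n",
              x$n, x$mean, x$variance))
  invisible(x)
}

#' Read dihedral specs from a mapping file
#'
#' The mapping file is tab-separated with columns `species`, `site`, `side`,
#' `chain`, `resid`, `a1`..`a4`. The package ships a default mapping for the
#' lutein and astaxanthin end-ring torsions
#' (`extdata/dihedral_specs/carotenoid_end_rings.tsv`); the atom quadruples
#' there are documented assumptions and the file is meant to be edited for
#' other naming conventions.
#'
#' @param path mapping file; default the shipped one.
#' @return named list of [dihedral_spec()]s (names `species_site_side`).
#' @export
read_dihedral_specs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dihedral_specs",
                        "carotenoid_end_rings.tsv", package = "tafit",
                        mustWork = TRUE)
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tb)), function(i)
    dihedral_spec(tb$chain[i], tb$resid[i],
                  c(tb$a1[i], tb$a2[i], tb$a3[i], tb$a4[i]),
                  side = tb$side[i], site = tb$site[i]))
  names(out) <- paste(tb$species, tb$site, tb$side, sep = "_")
  out
}
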