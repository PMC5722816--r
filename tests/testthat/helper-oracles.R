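# Independent oracles used across the suite. Each implements the quantity
# under test by a different route than the package code.

# numerical convolution of exp(-k t) * theta(t) with a unit-area Gaussian,
# by adaptive quadrature
conv_quadrature <- function(k, t, mu, sigma) {
  vapply(t, function(ti) {
    stats::integrate(function(s) exp(-k * (ti - s)) * stats::dnorm(s, mu, sigma),
                     lower = mu - 10 * sigma, upper = ti,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, numeric(1))
}

# matrix-exponential propagation of dc/dt = K c + j g(t): adaptive
# quadrature of expm(K (t - s)) j g(s) per compartment and time point
expm_concentrations <- function(K_ps, input, mu, sigma, times) {
  n <- length(input)
  out <- matrix(0, length(times), n)
  for (ti in seq_along(times)) {
    tt <- times[ti]
    if (tt <= mu - 8 * sigma) next
    for (i in seq_len(n)) {
      f <- function(s) vapply(s, function(ss)
        as.numeric((as.matrix(Matrix::expm(K_ps * (tt - ss))) %*% input)[i]) *
          stats::dnorm(ss, mu, sigma), numeric(1))
      out[ti, i] <- stats::integrate(f, lower = mu - 8 * sigma, upper = tt,
                                     rel.tol = 1e-10, abs.tol = 1e-13)$value
    }
  }
  out
}

# exact matrix-exponential solution for a delta-function pulse at t = 0
expm_delta <- function(K_ps, input, times) {
  t(vapply(times, function(tt) {
    if (tt < 0) return(numeric(length(input)))
    as.numeric(as.matrix(Matrix::expm(K_ps * tt)) %*% input)
  }, numeric(length(input))))
}

# second, independent dihedral formula: project the outer bonds onto the
# plane perpendicular to the central bond and take the signed angle
dihedral_projection <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b2 <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  u <- (p1 - p2) - sum((p1 - p2) * b2) * b2
  v <- (p4 - p3) - sum((p4 - p3) * b2) * b2
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi
  if (sum(cross(u, v) * b2) < 0) ang <- -ang
  # match the IUPAC sign convention of the implementation under test
  -ang
}

# stochastic pathway-yield oracle: propagate walker counts through the
# embedded jump chain with multinomial draws until all are absorbed
gillespie_yields <- function(scheme, n_walkers = 1e6, seed = 1) {
  set.seed(seed)
  K <- scheme_matrix(scheme)
  tot <- -diag(K)
  r <- scheme$rates
  edge_counts <- stats::setNames(rep(0, nrow(r)), paste(r$from, r$to))
  pop <- stats::rmultinom(1, n_walkers, scheme$input)[, 1]
  names(pop) <- scheme$compartments
  for (step in 1:10000) {
    if (all(pop == 0)) break
    newpop <- stats::setNames(rep(0, length(pop)), names(pop))
    for (cmp in names(pop)[pop > 0]) {
      out_edges <- which(r$from == cmp)
      probs <- r$rate[out_edges] / tot[cmp]
      draws <- stats::rmultinom(1, pop[cmp], probs)[, 1]
      edge_counts[out_edges] <- edge_counts[out_edges] + draws
      dest <- r$to[out_edges]
      for (ei in seq_along(out_edges)) {
        if (dest[ei] != "GS")
          newpop[dest[ei]] <- newpop[dest[ei]] + draws[ei]
      }
    }
    pop <- newpop
  }
  data.frame(from = r$from, to = r$to,
             yield = as.numeric(edge_counts) / n_walkers,
             n = n_walkers, stringsAsFactors = FALSE)
}

# random DAG-structured valid scheme: rates log-uniform in [1, 1e4] ns^-1,
# every compartment keeps a positive ground-state loss
random_scheme <- function(n, seed) {
  set.seed(seed)
  labels <- paste0("X", seq_len(n))
  rows <- list()
  for (j in seq_len(n)) {
    pool <- if (j < n) (j + 1):n else integer(0)
    n_tg <- if (length(pool)) sample(0:min(2, length(pool)), 1) else 0L
    # sample() from a length-one pool would draw from 1:pool
    targets <- if (n_tg > 0) sample(c(pool, pool), n_tg) else integer(0)
    targets <- unique(targets)
    for (tg in targets)
      rows[[length(rows) + 1]] <- data.frame(from = labels[j], to = labels[tg],
                                             rate = 10^stats::runif(1, 0, 4))
    rows[[length(rows) + 1]] <- data.frame(from = labels[j], to = "GS",
                                           rate = 10^stats::runif(1, 0, 4))
  }
  input <- stats::runif(n)
  input <- input / sum(input)
  names(input) <- labels
  kinetic_scheme(labels, do.call(rbind, rows), input)
}

# write a small multi-MODEL PDB file of one 4-atom chain per frame
write_frames_pdb <- function(coords_list, path) {
  lines <- character(0)
  for (f in seq_along(coords_list)) {
    xyz <- coords_list[[f]]
    lines <- c(lines, sprintf("MODEL     %4d", f))
    for (a in seq_len(nrow(xyz))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  C%-2d LIG A 620    %8.3f%8.3f%8.3f  1.00  0.00           C",
        a, a, xyz[a, 1], xyz[a, 2], xyz[a, 3]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# four points with a prescribed torsion angle (degrees): p1 along +x, the
# central bond along z; rotating p4 by -a about z yields torsion +a
points_with_torsion <- function(angle_deg) {
  a <- -angle_deg * pi / 180
  rbind(c(1, 0, 0),
        c(0, 0, 0),
        c(0, 0, 1.5),
        c(cos(a), sin(a), 1.5))
}

# random rigid transform applied to an n x 3 coordinate block
rigid_transform <- function(xyz, seed) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  shift <- matrix(stats::runif(3, -50, 50), nrow(xyz), 3, byrow = TRUE)
  xyz %*% t(Rz %*% Ry %*% Rx) + shift
}
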