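#' Spectral constraint set for target analysis
#'
#' @param zero data frame with columns `compartment`, `lo`, `hi`: wavelength
#'   intervals (nm, inclusive) on which that compartment's spectrum is forced
#'   to exactly zero.
#' @param links list of spectrum-link groups; each group is a data frame with
#'   columns `dataset` (index into the dataset list) and `compartment`. All
#'   members of a group share one spectrum, solved jointly by stacking the
#'   linked datasets' design matrices (the datasets must share a wavelength
#'   axis). Rates are linked independently, through shared rate `id`s in the
#'   schemes.
#' @return object of class `constraint_set`.
#' @export
constraint_set <- function(zero = NULL, links = NULL) {
  if (!is.null(zero)) {
    zero <- as.data.frame(zero, stringsAsFactors = FALSE)
    stopifnot(all(c("compartment", "lo", "hi") %in% names(zero)))
  }
  if (!is.null(links))
    links <- lapply(links, function(g) as.data.frame(g, stringsAsFactors = FALSE))
  structure(list(zero = zero, links = links), class = "constraint_set")
}

# active-compartment mask for one dataset: TRUE where the spectrum is free
zero_mask <- function(wavelengths, labels, zero) {
  M <- matrix(TRUE, length(wavelengths), length(labels),
              dimnames = list(NULL, labels))
  if (is.null(zero)) return(M)
  for (r in seq_len(nrow(zero))) {
    i <- which(labels == zero$compartment[r])
    if (length(i))
      M[wavelengths >= zero$lo[r] & wavelengths <= zero$hi[r], i] <- FALSE
  }
  M
}

# Joint variable-projection linear solve over one or more datasets.
# C_list: concentration matrices (colnames = compartments); Psi_list: data
# matrices; wl_list: wavelength axes. Returns per-dataset spectra (ncomp x
# nlambda), per-dataset residual matrices, and the design condition number.
project_spectra_multi <- function(C_list, Psi_list, wl_list, constraints = NULL) {
  nd <- length(C_list)
  zero <- constraints$zero
  links <- constraints$links
  # cluster datasets connected through spectrum links
  cluster <- seq_len(nd)
  if (!is.null(links)) for (g in links) {
    ds <- unique(g$dataset)
    cluster[cluster %in% cluster[ds]] <- min(cluster[ds])
  }
  S_out <- vector("list", nd)
  R_out <- vector("list", nd)
  cond <- NA_real_
  for (cl in unique(cluster)) {
    ds <- which(cluster == cl)
    wl <- wl_list[[ds[1]]]
    if (length(ds) > 1) {
      for (d in ds[-1]) if (!isTRUE(all.equal(wl_list[[d]], wl)))
        stop("spectrum-linked datasets must share a wavelength axis")
    }
    nlam <- length(wl)
    # column plan: linked groups first, then per-dataset unlinked compartments
    plan <- list()
    linked_members <- matrix(character(0), 0, 2)
    if (!is.null(links)) for (g in links) {
      if (!any(g$dataset %in% ds)) next
      plan[[length(plan) + 1]] <- data.frame(dataset = g$dataset,
                                             compartment = g$compartment,
                                             stringsAsFactors = FALSE)
      linked_members <- rbind(linked_members,
                              cbind(as.character(g$dataset), g$compartment))
    }
    for (d in ds) for (comp in colnames(C_list[[d]])) {
      if (nrow(linked_members) &&
          any(linked_members[, 1] == as.character(d) &
              linked_members[, 2] == comp)) next
      plan[[length(plan) + 1]] <- data.frame(dataset = d, compartment = comp,
                                             stringsAsFactors = FALSE)
    }
    ncols <- length(plan)
    col_name <- vapply(plan, function(p)
      paste(paste0(p$compartment, "@", p$dataset), collapse = "+"), character(1))
    # per-column activity mask (zero-region on any member zeroes the column)
    A <- matrix(TRUE, nlam, ncols)
    for (ci in seq_len(ncols)) {
      for (m in seq_len(nrow(plan[[ci]]))) {
        d <- plan[[ci]]$dataset[m]
        comp <- plan[[ci]]$compartment[m]
        A[, ci] <- A[, ci] & zero_mask(wl, comp, zero)[, 1]
      }
    }
    nt <- vapply(ds, function(d) nrow(C_list[[d]]), integer(1))
    row_off <- c(0, cumsum(nt))
    X_full <- matrix(0, sum(nt), ncols, dimnames = list(NULL, col_name))
    for (ci in seq_len(ncols)) for (m in seq_len(nrow(plan[[ci]]))) {
      d <- plan[[ci]]$dataset[m]
      di <- match(d, ds)
      rows <- (row_off[di] + 1):row_off[di + 1]
      X_full[rows, ci] <- X_full[rows, ci] +
        C_list[[d]][, plan[[ci]]$compartment[m]]
    }
    for (d in ds) {
      S_out[[d]] <- matrix(0, ncol(C_list[[d]]), nlam,
                           dimnames = list(colnames(C_list[[d]]), NULL))
      R_out[[d]] <- matrix(0, nrow(C_list[[d]]), nlam)
    }
    Psi_stack <- do.call(rbind, lapply(ds, function(d) Psi_list[[d]]))
    patt <- apply(A, 1, paste, collapse = "")
    for (pt in unique(patt)) {
      lam <- which(patt == pt)
      act <- A[lam[1], ]
      X <- X_full[, act, drop = FALSE]
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) {
        bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
        stop("collinear concentration profiles: ", paste(bad, collapse = ", "))
      }
      if (is.na(cond) && all(act)) cond <- kappa(X, exact = FALSE)
      B <- qr.coef(qrX, Psi_stack[, lam, drop = FALSE])
      Rs <- qr.resid(qrX, Psi_stack[, lam, drop = FALSE])
      act_idx <- which(act)
      for (k in seq_along(act_idx)) {
        ci <- act_idx[k]
        for (m in seq_len(nrow(plan[[ci]]))) {
          d <- plan[[ci]]$dataset[m]
          S_out[[d]][plan[[ci]]$compartment[m], lam] <- B[k, ]
        }
      }
      for (di in seq_along(ds)) {
        rows <- (row_off[di] + 1):row_off[di + 1]
        R_out[[ds[di]]][, lam] <- Rs[rows, , drop = FALSE]
      }
    }
  }
  list(S = S_out, resid = R_out, condition = cond)
}

#' Variable-projection spectra for one dataset
#'
#' The linear step of target analysis: per-wavelength least squares
#' \eqn{\Psi(\cdot,\lambda) \approx C\, S(\lambda)} given the IRF-convolved
#' concentration matrix. Inside a compartment's zero-region its column is
#' removed from the design before solving and the spectrum entry is exactly
#' 0; among all spectra honoring the constraints, the returned ones minimize
#' the residual.
#'
#' @param C a `concentration_matrix` (or plain matrix with compartment
#'   column names) on the dataset's delay axis.
#' @param dataset a [ta_dataset()].
#' @param constraints optional [constraint_set()] (zero regions only; links
#'   are a multi-dataset concept handled by [fit_target()]).
#' @return a `spectrum_set` of kind SADS with attributes `"residuals"`
#'   (matrix) and `"condition"` (design condition number on the
#'   unconstrained set).
#' @export
project_spectra <- function(C, dataset, constraints = NULL) {
  Cm <- if (inherits(C, "concentration_matrix")) C$C else as.matrix(C)
  if (nrow(Cm) != length(dataset$times))
    stop("concentration matrix does not match the dataset delay axis")
  pr <- project_spectra_multi(list(Cm), list(dataset$dA),
                              list(dataset$wavelengths), constraints)
  out <- spectrum_set("SADS", dataset$wavelengths, t(pr$S[[1]]),
                      colnames(Cm), constraints = constraints)
  attr(out, "residuals") <- pr$resid[[1]]
  attr(out, "condition") <- pr$condition
  out
}

# map free parameter ids to a transformed vector and back
free_par_init <- function(schemes, free) {
  vals <- numeric(0)
  for (id in free) {
    if (startsWith(id, "input_frac:")) {
      comp <- sub("^input_frac:", "", id)
      f <- NA_real_
      for (sc in schemes) if (comp %in% sc$compartments && sc$input[comp] > 0)
        f <- sc$input[comp]
      if (is.na(f)) stop("free input fraction refers to unknown compartment: ", comp)
      vals[id] <- stats::qlogis(f)
    } else {
      v <- NA_real_
      for (sc in schemes) {
        hit <- sc$rates$id == id
        if (any(hit)) {
          vv <- unique(sc$rates$rate[hit])
          if (!is.na(v) && abs(vv - v) > 1e-12 * max(vv, v))
            stop("linked rate id '", id, "' has conflicting values across schemes")
          v <- vv
        }
      }
      if (is.na(v)) stop("free parameter not found in any scheme: ", id)
      if (v <= 0) stop("free rate '", id, "' must start positive")
      vals[id] <- log(v)
    }
  }
  vals
}

apply_free_pars <- function(scheme, free, p) {
  rate_ids <- free[!startsWith(free, "input_frac:")]
  if (length(rate_ids))
    scheme <- set_rates(scheme, stats::setNames(exp(p[rate_ids]), rate_ids))
  for (id in free[startsWith(free, "input_frac:")]) {
    comp <- sub("^input_frac:", "", id)
    if (comp %in% names(scheme$input) && scheme$input[comp] > 0) {
      f <- stats::plogis(p[id])
      others <- setdiff(names(scheme$input)[scheme$input > 0], comp)
      scheme$input[comp] <- f
      scheme$input[others] <- scheme$input[others] *
        (1 - f) / sum(scheme$input[others])
    }
  }
  scheme
}

#' Target analysis: simultaneous compartmental fit of several datasets
#'
#' Minimizes the pooled residual of all datasets over the selected free
#' parameters by seeded multi-start Levenberg-Marquardt. At every evaluation
#' the species-associated spectra are eliminated analytically by variable
#' projection ([project_spectra()]); spectra linked across datasets are
#' solved jointly by stacking the linked design matrices. Free rates are
#' log-parametrized; a rate `id` shared by several schemes is one parameter
#' (rate linking). A free parameter `"input_frac:<compartment>"` fits that
#' compartment's share of the excitation vector (logit-parametrized, the
#' remaining shares rescaled).
#'
#' @param datasets list of [ta_dataset()] objects.
#' @param schemes list of `kinetic_scheme`s, one per dataset (the same
#'   scheme object may serve several windows of one experiment).
#' @param free character vector of free parameter ids.
#' @param constraints optional [constraint_set()].
#' @param irfs list of [irf_model()] per dataset; defaults to each scheme's.
#' @param seed integer seed for multi-start jitter.
#' @param n_starts optimizer starts (first start from the schemes' values).
#' @param jitter_sd lognormal jitter (sd of log) for starts beyond the first.
#' @param maxiter iteration cap per start.
#' @param ftol,ptol Levenberg-Marquardt stopping tolerances (relative cost
#'   and parameter change).
#' @return object of class `ta_fit` with `rates_table` (id, rate in ns^-1,
#'   standard error from the Gauss-Newton Jacobian at the optimum),
#'   `input_fracs`, `sads` (list of `spectrum_set`), `residuals`, `cost`,
#'   `schemes` (updated), and `convergence` metadata. Linked spectra are
#'   bit-identical across datasets and zero-regions are exactly zero.
#' @export
fit_target <- function(datasets, schemes, free = character(),
                       constraints = NULL, irfs = NULL, seed = 1L,
                       n_starts = 3L, jitter_sd = 0.3, maxiter = 100L,
                       ftol = 1.49e-8, ptol = 1.49e-8) {
  nd <- length(datasets)
  if (length(schemes) != nd)
    stop("need one scheme per dataset")
  if (is.null(irfs)) irfs <- lapply(schemes, `[[`, "irf")
  if (any(vapply(irfs, is.null, logical(1))))
    stop("every dataset needs an IRF (from its scheme or `irfs`)")
  lapply(schemes, validate_scheme)

  eval_model <- function(p) {
    sch <- lapply(schemes, apply_free_pars, free = free, p = p)
    C_list <- lapply(seq_len(nd), function(d)
      concentrations(sch[[d]], irfs[[d]], datasets[[d]]$times)$C)
    pr <- project_spectra_multi(C_list,
                                lapply(datasets, `[[`, "dA"),
                                lapply(datasets, `[[`, "wavelengths"),
                                constraints)
    pr$schemes <- sch
    pr$C_list <- C_list
    pr
  }
  n_resid <- sum(vapply(datasets, function(d) length(d$dA), integer(1)))
  resid_fn <- function(p) {
    names(p) <- names(p0)
    # a step into a degenerate region (collinear profiles) is rejected by
    # returning a huge residual instead of aborting the whole start
    tryCatch(
      unlist(lapply(eval_model(p)$resid, as.vector), use.names = FALSE),
      error = function(e) rep(1e6, n_resid))
  }

  p0 <- free_par_init(schemes, free)
  if (length(free) == 0) {
    pr <- eval_model(p0)
    best <- NULL
  } else {
    set.seed(seed)
    best <- NULL
    conv_any <- FALSE
    for (s in seq_len(n_starts)) {
      p <- p0
      if (s > 1) p <- p + stats::rnorm(length(p), 0, jitter_sd)
      fit <- tryCatch(
        minpack.lm::nls.lm(par = p, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, ftol = ftol, ptol = ptol,
                             nprint = 0)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (fit$info %in% 1:4) conv_any <- TRUE
      if (is.null(best) || fit$deviance < best$deviance) {
        best <- fit; best$start <- s
      }
    }
    if (is.null(best)) stop("target fit failed in all starts")
    if (!conv_any)
      warning("target fit did not converge; returning best effort (rss ",
              format(best$deviance), ")")
    names(best$par) <- names(p0)
    pr <- eval_model(best$par)
  }
  p_hat <- if (is.null(best)) p0 else best$par

  # standard errors on the transformed scale from the LM Jacobian, mapped to
  # the rate scale by the delta method
  se <- rep(NA_real_, length(free))
  names(se) <- free
  if (!is.null(best)) {
    sm <- tryCatch(summary(best), error = function(e) NULL)
    if (!is.null(sm)) {
      se_t <- sm$coefficients[, "Std. Error"]
      se <- se_t
    } else {
      warning("singular Jacobian: parameter uncertainties unavailable (",
              paste(free, collapse = ", "), ")")
    }
  }
  rate_ids <- free[!startsWith(free, "input_frac:")]
  rates_table <- data.frame(
    id = rate_ids,
    rate = exp(unname(p_hat[rate_ids])),
    se = exp(unname(p_hat[rate_ids])) * unname(se[rate_ids]),
    stringsAsFactors = FALSE)
  frac_ids <- free[startsWith(free, "input_frac:")]
  input_fracs <- stats::setNames(stats::plogis(unname(p_hat[frac_ids])), frac_ids)

  sads <- lapply(seq_len(nd), function(d)
    spectrum_set("SADS", datasets[[d]]$wavelengths, t(pr$S[[d]]),
                 rownames(pr$S[[d]]), constraints = constraints))
  cost <- sum(vapply(pr$resid, function(r) sum(r^2), numeric(1)))
  structure(list(
    kind = "target",
    rates_table = rates_table,
    input_fracs = input_fracs,
    sads = sads,
    residuals = pr$resid,
    cost = cost,
    condition = pr$condition,
    schemes = pr$schemes,
    convergence = if (!is.null(best))
      list(info = best$info, iterations = best$niter, start = best$start,
           seed = seed) else list(info = 0L, iterations = 0L, start = 0L,
                                  seed = seed)),
    class = "ta_fit")
}

#' Branching yields of a kinetic scheme
#'
#' For each compartment the fraction of its decays through each outgoing
#' edge is `rate / total rate`. Cumulative pathway yields (the fraction of
#' the initial excitation that leaves through each edge) follow from the
#' expected visit counts of the embedded jump chain, obtained as the
#' solution of a linear system, which handles cyclic (reversible) schemes
#' exactly.
#'
#' @param scheme a `kinetic_scheme`; every compartment must have a positive
#'   total decay rate.
#' @return data frame with columns `from`, `to`, `fraction` (per-compartment
#'   branch fraction) and `yield` (fraction of total input through the
#'   edge). Yields over edges into `GS` sum to 1.
#' @export
branching_yields <- function(scheme) {
  validate_scheme(scheme)
  K <- scheme_matrix(scheme)
  tot <- -diag(K)
  if (any(tot <= 0))
    stop("compartment with zero total decay rate: ",
         paste(scheme$compartments[tot <= 0], collapse = ", "))
  n <- length(tot)
  P <- K
  diag(P) <- 0
  P <- sweep(P, 2, tot, "/")      # P[i, j] = prob j hops to i
  visits <- solve(diag(n) - P, scheme$input)
  names(visits) <- scheme$compartments
  r <- scheme$rates
  data.frame(from = r$from, to = r$to,
             fraction = r$rate / tot[r$from],
             yield = visits[r$from] * r$rate / tot[r$from],
             row.names = NULL, stringsAsFactors = FALSE)
}
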