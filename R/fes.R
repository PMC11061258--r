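# Well-tempered metadynamics post-processing: free-energy surface
# reconstruction from Gaussian deposition records, projection of 2D
# surfaces to 1D potentials of mean force, and the conversion of a PMF
# into a partition coefficient kappa, its standard-state form kappa0 and
# the adsorption free energy dG0 = -kT ln(kappa0).
#
# Quadrature: the stored grid is treated as a piecewise-linear function of
# the collective variables; Boltzmann integrals along z use the exact
# closed form of the exponential of a linear segment per grid cell (with a
# global exponent shift for numerical stability), and the bounded cosine
# axis uses the composite trapezoid.

#' Construct a free-energy-surface grid
#'
#' @param axes Named list of strictly increasing axis node vectors, e.g.
#'   `list(z = ..., cos_tilt = ...)`. One or two axes are supported.
#' @param values Free energy in kJ/mol: a vector (1 axis) or an
#'   `length(axes[[1]]) x length(axes[[2]])` matrix.
#' @param temperature Temperature in K, default 300.
#' @param bias_factor Well-tempered bias factor gamma (NA when the grid
#'   did not come from a deposition record).
#' @param periodic Named logical per axis (default all FALSE); a periodic
#'   axis additionally carries a `period` attribute taken from its span.
#' @return Object of class `fes_grid`.
#' @export
fes_grid <- function(axes, values, temperature = 300, bias_factor = NA_real_,
                     periodic = NULL) {
  stopifnot(is.list(axes), length(axes) %in% 1:2, !is.null(names(axes)))
  for (ax in axes) {
    stopifnot(is.numeric(ax), length(ax) >= 2L, !is.unsorted(ax, strictly = TRUE))
  }
  if (length(axes) == 1L) {
    values <- as.numeric(values)
    stopifnot(length(values) == length(axes[[1L]]))
  } else {
    values <- as.matrix(values)
    stopifnot(nrow(values) == length(axes[[1L]]),
              ncol(values) == length(axes[[2L]]))
  }
  if (!all(is.finite(values))) stop("FES values must be finite", call. = FALSE)
  if (is.null(periodic)) {
    periodic <- stats::setNames(rep(FALSE, length(axes)), names(axes))
  }
  structure(list(axes = axes, values = values,
                 temperature = temperature, bias_factor = bias_factor,
                 periodic = periodic),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  dims <- paste(vapply(x$axes, length, integer(1L)), collapse = " x ")
  cat(sprintf("FES grid over (%s): %s points, T = %g K, range %.3g..%.3g kJ/mol\n",
              paste(names(x$axes), collapse = ", "), dims,
              x$temperature, min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a Gaussian deposition (hills) record
#'
#' @param entries data.frame with columns `time` (ns), one centre column
#'   per collective variable, matching `sigma_<cv>` width columns, `height`
#'   (kJ/mol, stored as deposited, i.e. already tempered), `biasf` and
#'   `walker`.
#' @param cvs Character vector of collective-variable names.
#' @return Object of class `hills_record`.
#' @export
hills_record <- function(entries, cvs) {
  sig_cols <- paste0("sigma_", cvs, recycle0 = TRUE)
  needed <- c("time", cvs, sig_cols, "height", "biasf", "walker")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols) > 0L) {
    stop("hills entries lack columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(entries) > 0L) {
    if (any(entries[sig_cols] <= 0)) stop("Gaussian widths must be > 0",
                                          call. = FALSE)
    if (any(entries$height < 0)) stop("Gaussian heights must be >= 0",
                                      call. = FALSE)
    entries <- entries[order(entries$time), , drop = FALSE]
    rownames(entries) <- NULL
  }
  structure(list(entries = entries, cvs = cvs), class = "hills_record")
}

#' @export
print.hills_record <- function(x, ...) {
  cat(sprintf("Hills record: %d Gaussians over (%s), %d walker(s)\n",
              nrow(x$entries), paste(x$cvs, collapse = ", "),
              length(unique(x$entries$walker))))
  invisible(x)
}

#' Reconstruct a free-energy surface from deposited Gaussians
#'
#' Sums the deposited bias V(s) = sum_i h_i prod_cv exp(-(s - c_i)^2 /
#' (2 sigma_i^2)) over a rectangular grid (periodic axes include their
#' +-1 period images) and converts it into a free-energy estimate. With
#' `heights_tempered = TRUE` (the on-disk convention of well-tempered
#' records, whose stored heights already decay with the accumulated bias)
#' the surface is F = -gamma/(gamma - 1) V; with `FALSE` (plain
#' metadynamics) F = -V. The minimum is then shifted to zero.
#'
#' @param hills A [hills_record()].
#' @param axes Named list of grid node vectors, names matching the record's
#'   collective variables (1 or 2 of them).
#' @param temperature Temperature (K) carried into the grid.
#' @param bias_factor Bias factor gamma; defaults to the record's `biasf`.
#'   Must be > 1 for the well-tempered conversion.
#' @param periodic Named logical per axis; periodic axes use the axis span
#'   (node range plus one spacing) as the period.
#' @param heights_tempered See description.
#' @return A [fes_grid()] (attribute `truncated_hills` reports Gaussians
#'   whose +-4 sigma support is not fully covered by the grid).
#' @export
reconstruct_fes <- function(hills, axes, temperature = 300,
                            bias_factor = NULL, periodic = NULL,
                            heights_tempered = TRUE) {
  stopifnot(inherits(hills, "hills_record"))
  cvs <- names(axes)
  if (!setequal(cvs, hills$cvs) && nrow(hills$entries) > 0L) {
    stop("grid axes do not match the record's collective variables",
         call. = FALSE)
  }
  if (is.null(periodic)) {
    periodic <- stats::setNames(rep(FALSE, length(axes)), cvs)
  }
  ent <- hills$entries
  if (is.null(bias_factor)) {
    bias_factor <- if (nrow(ent) > 0L) ent$biasf[1L] else NA_real_
  }
  if (heights_tempered && nrow(ent) > 0L &&
      (!is.finite(bias_factor) || bias_factor <= 1)) {
    stop("bias factor must be > 1 for the well-tempered conversion",
         call. = FALSE)
  }
  n1 <- length(axes[[1L]])
  n2 <- if (length(axes) == 2L) length(axes[[2L]]) else 1L
  v <- matrix(0, n1, n2)
  truncated <- 0L
  if (nrow(ent) > 0L) {
    per <- vapply(cvs, function(cv) {
      if (isTRUE(periodic[[cv]])) {
        ax <- axes[[cv]]
        diff(range(ax)) + (ax[2L] - ax[1L])
      } else NA_real_
    }, numeric(1L))
    gauss_axis <- function(ax, c0, s0, period) {
      d <- ax - c0
      if (!is.na(period)) {
        g <- exp(-d^2 / (2 * s0^2))
        for (k in c(-1, 1)) g <- g + exp(-(d + k * period)^2 / (2 * s0^2))
        g
      } else {
        exp(-d^2 / (2 * s0^2))
      }
    }
    for (i in seq_len(nrow(ent))) {
      covered <- TRUE
      for (j in seq_along(cvs)) {
        cv <- cvs[j]
        if (is.na(per[j])) {
          lo <- ent[[cv]][i] - 4 * ent[[paste0("sigma_", cv)]][i]
          hi <- ent[[cv]][i] + 4 * ent[[paste0("sigma_", cv)]][i]
          if (lo < min(axes[[cv]]) || hi > max(axes[[cv]])) covered <- FALSE
        }
      }
      if (!covered) truncated <- truncated + 1L
      g1 <- gauss_axis(axes[[1L]], ent[[cvs[1L]]][i],
                       ent[[paste0("sigma_", cvs[1L])]][i], per[1L])
      if (length(axes) == 2L) {
        g2 <- gauss_axis(axes[[2L]], ent[[cvs[2L]]][i],
                         ent[[paste0("sigma_", cvs[2L])]][i], per[2L])
        v <- v + ent$height[i] * tcrossprod(g1, g2)
      } else {
        v[, 1L] <- v[, 1L] + ent$height[i] * g1
      }
    }
  }
  if (truncated > 0L) {
    warning(sprintf("%d Gaussian(s) extend beyond the grid and are truncated",
                    truncated), call. = FALSE)
  }
  scale <- if (heights_tempered && is.finite(bias_factor)) {
    bias_factor / (bias_factor - 1)
  } else 1
  f <- -scale * v
  f <- f - min(f)
  vals <- if (length(axes) == 2L) f else as.numeric(f[, 1L])
  out <- fes_grid(axes, vals, temperature = temperature,
                  bias_factor = bias_factor, periodic = periodic)
  attr(out, "truncated_hills") <- truncated
  out
}

#' Construct a 1D potential-of-mean-force profile
#'
#' @param axis_name Name of the collective variable.
#' @param axis Numeric node vector (strictly increasing).
#' @param values Free energy per node, kJ/mol.
#' @param uncertainty Optional per-node uncertainty (kJ/mol, >= 0).
#' @param reference_window Optional `(lo, hi)` range of the axis where the
#'   profile is anchored to zero.
#' @return Object of class `pmf_profile`.
#' @export
pmf_profile <- function(axis_name, axis, values, uncertainty = NULL,
                        reference_window = NULL) {
  stopifnot(length(axis) == length(values), !is.unsorted(axis, strictly = TRUE),
            all(is.finite(values)))
  if (!is.null(uncertainty)) {
    stopifnot(length(uncertainty) == length(values), all(uncertainty >= 0))
  }
  structure(list(axis_name = axis_name, axis = as.numeric(axis),
                 values = as.numeric(values), uncertainty = uncertainty,
                 reference_window = reference_window),
            class = "pmf_profile")
}

#' Anchor a PMF to zero over a reference window
#'
#' Subtracts the mean of the profile over `window` so the (far-field)
#' reference region sits at zero.
#'
#' @param pmf A [pmf_profile()].
#' @param window `(lo, hi)` axis range used as the reference.
#' @return The shifted [pmf_profile()] with `reference_window` recorded.
#' @export
anchor_pmf <- function(pmf, window) {
  stopifnot(inherits(pmf, "pmf_profile"), length(window) == 2L)
  sel <- pmf$axis >= window[1L] & pmf$axis <= window[2L]
  if (!any(sel)) stop("reference window contains no grid points",
                      call. = FALSE)
  pmf$values <- pmf$values - mean(pmf$values[sel])
  pmf$reference_window <- window
  pmf
}

#' Project a 2D free-energy surface onto one collective variable
#'
#' Boltzmann-weighted projection: the probability density is integrated
#' over the complementary variable and transformed back,
#' W1(s) = -(1/beta) ln Integral exp(-beta W(s, u)) du, evaluated with a
#' log-sum-exp stabilised composite trapezoid in u. The result is shifted
#' so its minimum is zero, or anchored over `reference_window` when given.
#'
#' @param fes A 2-axis [fes_grid()].
#' @param keep_axis Name of the axis to keep.
#' @param temperature Temperature in K; defaults to the grid's.
#' @param reference_window Optional anchoring range passed to
#'   [anchor_pmf()].
#' @return A [pmf_profile()] over `keep_axis`.
#' @export
project_to_1d <- function(fes, keep_axis, temperature = NULL,
                          reference_window = NULL) {
  stopifnot(inherits(fes, "fes_grid"))
  if (length(fes$axes) != 2L) stop("projection requires a 2-axis grid",
                                   call. = FALSE)
  if (!keep_axis %in% names(fes$axes)) {
    stop("unknown axis: ", keep_axis, call. = FALSE)
  }
  if (is.null(temperature)) temperature <- fes$temperature
  beta <- 1 / (kB_kJ_mol_K * temperature)
  keep_first <- names(fes$axes)[1L] == keep_axis
  w <- if (keep_first) fes$values else t(fes$values)
  u <- if (keep_first) fes$axes[[2L]] else fes$axes[[1L]]
  du <- diff(u)
  tw <- c(du[1L] / 2, (du[-1L] + du[-length(du)]) / 2,
          du[length(du)] / 2) # trapezoid weights
  lw <- log(tw)
  vals <- apply(w, 1L, function(row) {
    a <- -beta * row + lw
    m <- max(a)
    -(m + log(sum(exp(a - m)))) / beta
  })
  out <- pmf_profile(keep_axis, fes$axes[[if (keep_first) 1L else 2L]], vals)
  if (!is.null(reference_window)) {
    out <- anchor_pmf(out, reference_window)
  } else {
    out$values <- out$values - min(out$values)
  }
  out
}

# Exact Boltzmann integral of a piecewise-linear free energy along z over
# [lo, hi], with exponent shift `shift` (computes
# Integral exp(-beta W(z) - shift) dz). Endpoint values are obtained by
# linear interpolation when lo/hi fall between nodes.
.boltzmann_integral_pl <- function(z, w, beta, lo, hi, shift = 0) {
  stopifnot(lo >= min(z) - 1e-9, hi <= max(z) + 1e-9, hi > lo)
  interp <- stats::approx(z, w, xout = c(lo, hi), rule = 2)$y
  inner <- z > lo & z < hi
  zz <- c(lo, z[inner], hi)
  ww <- c(interp[1L], w[inner], interp[2L])
  a <- -beta * ww - shift
  a1 <- a[-length(a)]
  a2 <- a[-1L]
  h <- diff(zz)
  m <- pmax(a1, a2)
  d <- -abs(a1 - a2)
  seg <- ifelse(d > -1e-12,
                h * exp(m) * (1 + d / 2),
                h * exp(m) * expm1(d) / d)
  sum(seg)
}

.free_region_check <- function(w_free, beta, tol_kT = 0.25) {
  dev <- max(abs(w_free - mean(w_free)))
  if (dev > tol_kT / beta) {
    warning(sprintf(
      "free-region plateau not flat: max deviation %.3g kJ/mol (> %.2f kT); anchoring may be unreliable",
      dev, tol_kT), call. = FALSE)
  }
  mean(w_free)
}

.new_thermo_result <- function(kappa, lambda, temperature, method) {
  beta <- 1 / (kB_kJ_mol_K * temperature)
  structure(list(kappa = kappa, kappa0 = NA_real_, lambda = lambda,
                 V0 = NA_real_, dG = -log(kappa) / beta, dG0 = NA_real_,
                 temperature = temperature, beta = beta, method = method,
                 uncertainty = NA_real_),
            class = "thermo_result")
}

#' Partition coefficient from a 2D (z, cos tilt) free-energy surface
#'
#' kappa = 1/(2 lambda) Integral_0^lambda Integral_-1^1
#' exp(-beta W(z, cos phi)) dz dcos(phi): the ratio of bound to free
#' probability per unit volume, with the factor 2 the width of the cosine
#' measure. The surface is first anchored so the free region
#' (z > lambda) averages to zero (a flatness warning is raised when that
#' plateau deviates by more than 0.25 kT).
#'
#' @param fes A 2-axis [fes_grid()] whose z axis spans `[0, lambda]` (and
#'   beyond, for anchoring).
#' @param lambda Distance threshold (nm) beyond which the
#'   peptide-membrane interaction is negligible.
#' @param temperature Temperature in K; defaults to the grid's.
#' @param z_axis Name of the distance axis, default `"z"`.
#' @param anchor Anchor the energy origin on the free region (default
#'   TRUE). With `FALSE` the grid values are integrated as stored.
#' @return A `thermo_result` with `kappa` filled in (`method =
#'   "eq_2d"`); pass it to [standard_state()] for kappa0 and dG0.
#' @export
kappa_from_2d <- function(fes, lambda, temperature = NULL, z_axis = "z",
                          anchor = TRUE) {
  stopifnot(inherits(fes, "fes_grid"), length(fes$axes) == 2L, lambda > 0)
  if (!z_axis %in% names(fes$axes)) stop("no axis named ", z_axis,
                                         call. = FALSE)
  if (is.null(temperature)) temperature <- fes$temperature
  beta <- 1 / (kB_kJ_mol_K * temperature)
  z_first <- names(fes$axes)[1L] == z_axis
  z <- fes$axes[[if (z_first) 1L else 2L]]
  cc <- fes$axes[[if (z_first) 2L else 1L]]
  w <- if (z_first) fes$values else t(fes$values) # rows: z, cols: cos
  if (lambda > max(z) + 1e-9 || min(z) > 1e-9) {
    stop("z axis must span [0, lambda]", call. = FALSE)
  }
  if (anchor) {
    free <- z > lambda
    if (!any(free)) {
      stop("grid has no free region beyond lambda to anchor on",
           call. = FALSE)
    }
    w0 <- .free_region_check(as.numeric(w[free, ]), beta)
    w <- w - w0
  }
  shift <- max(-beta * w)
  inner <- vapply(seq_along(cc), function(j) {
    .boltzmann_integral_pl(z, w[, j], beta, 0, lambda, shift)
  }, numeric(1L))
  kappa <- exp(shift + log(pracma::trapz(cc, inner))) / (2 * lambda)
  .new_thermo_result(kappa, lambda, temperature, "eq_2d")
}

#' Partition coefficient from a 1D PMF over z
#'
#' kappa = 1/lambda Integral_0^lambda exp(-beta W(z)) dz, the
#' one-collective-variable counterpart of [kappa_from_2d()].
#'
#' @param pmf A [pmf_profile()] over the z distance (nm).
#' @param lambda Distance threshold (nm); the profile must reach it.
#' @param temperature Temperature in K, default 300.
#' @param anchor Anchor the profile to zero over the free region
#'   `[lambda, max(z)]` first (default TRUE).
#' @return A `thermo_result` (`method = "eq_1d"`).
#' @export
kappa_from_1d <- function(pmf, lambda, temperature = 300, anchor = TRUE) {
  stopifnot(inherits(pmf, "pmf_profile"), lambda > 0)
  z <- pmf$axis
  w <- pmf$values
  if (lambda > max(z) + 1e-9 || min(z) > 1e-9) {
    stop("profile must span [0, lambda]", call. = FALSE)
  }
  beta <- 1 / (kB_kJ_mol_K * temperature)
  if (anchor) {
    free <- z > lambda
    if (!any(free)) {
      stop("profile has no free region beyond lambda to anchor on",
           call. = FALSE)
    }
    w <- w - .free_region_check(w[free], beta)
  }
  shift <- max(-beta * w)
  kappa <- exp(shift +
                 log(.boltzmann_integral_pl(z, w, beta, 0, lambda, shift))) /
    lambda
  .new_thermo_result(kappa, lambda, temperature, "eq_1d")
}

#' Standard-state correction of a partition coefficient
#'
#' Rescales kappa to the 1 M reference state: kappa0 = kappa lambda /
#' V0^(1/3) and dG0 = -kT ln(kappa0), with V0 the volume per molecule at
#' 1 M (1.660 nm^3 by default).
#'
#' @param result A `thermo_result` from [kappa_from_2d()] /
#'   [kappa_from_1d()].
#' @param V0 Standard-state volume in nm^3, default [V0_nm3].
#' @return The `thermo_result` with `kappa0`, `V0` and `dG0` filled in.
#' @export
standard_state <- function(result, V0 = V0_nm3) {
  stopifnot(inherits(result, "thermo_result"))
  if (!is.finite(result$kappa) || result$kappa <= 0 || result$lambda <= 0 ||
      V0 <= 0) {
    stop("kappa, lambda and V0 must be positive", call. = FALSE)
  }
  result$V0 <- V0
  result$kappa0 <- result$kappa * result$lambda / V0^(1 / 3)
  result$dG0 <- -log(result$kappa0) / result$beta
  result
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("Thermo result (%s, T = %g K, lambda = %g nm):\n",
              x$method, x$temperature, x$lambda))
  cat(sprintf("  kappa  = %.6g   dG  = %.4g kJ/mol\n", x$kappa, x$dG))
  if (is.finite(x$kappa0)) {
    cat(sprintf("  kappa0 = %.6g   dG0 = %.4g kJ/mol (V0 = %.3f nm^3)\n",
                x$kappa0, x$dG0, x$V0))
  }
  invisible(x)
}

#' Membrane-to-membrane transfer free energy
#'
#' ddG0 = dG0(water -> C) - dG0(water -> M) = dG0(M -> C): the preference
#' of the peptide for membrane C over membrane M. Any common water-phase
#' offset cancels, so the result does not depend on the aqueous reference
#' state of the peptide.
#'
#' @param result_M,result_C `thermo_result`s for the two membranes, with
#'   [standard_state()] applied, at the same temperature and V0.
#' @param from,to Composition labels for bookkeeping.
#' @return List of class `transfer_result` with `ddG0` (kJ/mol),
#'   `from_membrane`, `to_membrane`.
#' @export
transfer_ddg <- function(result_M, result_C, from = "M", to = "C") {
  stopifnot(inherits(result_M, "thermo_result"),
            inherits(result_C, "thermo_result"))
  if (!is.finite(result_M$dG0) || !is.finite(result_C$dG0)) {
    stop("apply standard_state() to both results first", call. = FALSE)
  }
  if (abs(result_M$temperature - result_C$temperature) > 1e-9 ||
      abs(result_M$V0 - result_C$V0) > 1e-12) {
    stop("results must share temperature and V0", call. = FALSE)
  }
  structure(list(ddG0 = result_C$dG0 - result_M$dG0,
                 from_membrane = from, to_membrane = to),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("Transfer %s -> %s: ddG0 = %.4g kJ/mol\n",
              x$from_membrane, x$to_membrane, x$ddG0))
  invisible(x)
}

#' Pick the interaction-range threshold lambda from a PMF
#'
#' Returns the smallest axis value beyond which |W| stays below the
#' threshold (default half a kT) all the way to the far edge, i.e. the
#' distance where the peptide-membrane interaction becomes negligible. The
#' plateau must span at least two grid points.
#'
#' @param pmf A [pmf_profile()] over z, anchored near zero in the far
#'   field.
#' @param threshold Energy threshold in kJ/mol; default `0.5 * kT`.
#' @param temperature Temperature in K used for the default threshold.
#' @return lambda in nm.
#' @export
choose_lambda <- function(pmf, threshold = NULL, temperature = 300) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (is.null(threshold)) threshold <- 0.5 * kB_kJ_mol_K * temperature
  ok <- abs(pmf$values) < threshold
  n <- length(ok)
  tail_ok <- rev(cumprod(rev(ok))) == 1
  idx <- which(tail_ok)
  if (length(idx) < 2L) {
    stop(sprintf(
      "no far-field plateau below %.3g kJ/mol found (profile tail |W| = %.3g)",
      threshold, abs(pmf$values[n])), call. = FALSE)
  }
  pmf$axis[idx[1L]]
}

#' Block-based convergence uncertainty of PMF profiles
#'
#' Given a time-ordered sequence of PMF profiles (one per convergence
#' checkpoint), takes the trailing fraction (default last 30%), anchors
#' each profile over a common reference window, and returns the pointwise
#' standard deviation as the uncertainty estimate.
#'
#' @param profiles List of [pmf_profile()]s on a shared axis, time order.
#' @param trailing_fraction Fraction of profiles (from the end) to use,
#'   default 0.3.
#' @param reference_window Anchoring window; default the top 10% of the
#'   axis range.
#' @return A [pmf_profile()] whose `values` are the mean trailing profile
#'   and `uncertainty` the pointwise standard deviation.
#' @export
convergence_blocks <- function(profiles, trailing_fraction = 0.3,
                               reference_window = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            trailing_fraction > 0, trailing_fraction <= 1)
  n_keep <- ceiling(trailing_fraction * length(profiles))
  keep <- profiles[seq.int(length(profiles) - n_keep + 1L, length(profiles))]
  if (length(keep) < 3L) {
    stop("need at least 3 profiles in the trailing fraction", call. = FALSE)
  }
  ax <- keep[[1L]]$axis
  for (p in keep) {
    stopifnot(inherits(p, "pmf_profile"))
    if (length(p$axis) != length(ax) || any(abs(p$axis - ax) > 1e-9)) {
      stop("profiles must share a common axis", call. = FALSE)
    }
  }
  if (is.null(reference_window)) {
    reference_window <- c(max(ax) - 0.1 * diff(range(ax)), max(ax))
  }
  anchored <- lapply(keep, anchor_pmf, window = reference_window)
  m <- vapply(anchored, `[[`, numeric(length(ax)), "values")
  pmf_profile(keep[[1L]]$axis_name, ax, rowMeans(m),
              uncertainty = apply(m, 1L, stats::sd),
              reference_window = reference_window)
}

#' Standard-state free-energy uncertainty from convergence blocks
#'
#' Propagates PMF convergence scatter into dG0: kappa (1D route) and the
#' standard-state correction are recomputed on each trailing-block
#' profile, and the standard deviation of the resulting dG0 values is
#' returned.
#'
#' @param profiles Time-ordered list of z-axis [pmf_profile()]s.
#' @param lambda Interaction threshold (nm).
#' @param temperature Temperature (K).
#' @param V0 Standard-state volume (nm^3).
#' @param trailing_fraction Fraction of trailing profiles, default 0.3.
#' @return Standard deviation of dG0 (kJ/mol) across trailing blocks.
#' @export
dg0_uncertainty <- function(profiles, lambda, temperature = 300,
                            V0 = V0_nm3, trailing_fraction = 0.3) {
  n_keep <- ceiling(trailing_fraction * length(profiles))
  keep <- profiles[seq.int(length(profiles) - n_keep + 1L, length(profiles))]
  if (length(keep) < 3L) {
    stop("need at least 3 profiles in the trailing fraction", call. = FALSE)
  }
  dg0 <- vapply(keep, function(p) {
    r <- kappa_from_1d(p, lambda, temperature)
    standard_state(r, V0)$dG0
  }, numeric(1L))
  stats::sd(dg0)
}

#' Half-harmonic sampling-wall bias
#'
#' Restraining potential used to confine metadynamics sampling to
#' z in `[bounds[1], bounds[2]]`: zero inside the bounds (inclusive) and
#' 0.5 kappa_wall (z - bound)^2 outside. Used by the synthetic generators
#' to emulate restricted sampling, and to mask wall-contaminated grid
#' regions in post-processing.
#'
#' @param z Position(s) in nm.
#' @param bounds Length-2 ordered bounds in nm, default `c(0, 8)`.
#' @param kappa_wall Force constant in kJ/(mol nm^2), default 50000.
#' @return Bias energy in kJ/mol (vectorised over `z`).
#' @export
wall_bias <- function(z, bounds = c(0, 8), kappa_wall = 50000) {
  stopifnot(length(bounds) == 2L, bounds[1L] < bounds[2L], kappa_wall >= 0)
  lo <- pmin(z - bounds[1L], 0)
  hi <- pmax(z - bounds[2L], 0)
  0.5 * kappa_wall * (lo^2 + hi^2)
}
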