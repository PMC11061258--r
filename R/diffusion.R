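# Lateral (in-plane) diffusion of the peptide centre of mass.
#
# Displacement magnitudes over a time window Delta-t of a 2D Brownian
# walker follow the Rayleigh law
#   P(r, dt) = r / (2 D dt) * exp(-r^2 / (4 D dt)),
# whose maximum-likelihood estimator is the closed form
#   D_hat = <r^2> / (4 dt).
# Confidence intervals come from a moving-block bootstrap over start
# times, since overlapping windows are strongly autocorrelated.

#' In-plane COM displacement magnitudes over a time window
#'
#' Unwraps the peptide centre-of-mass xy track across periodic boundaries
#' (a per-frame jump larger than half the box is treated as a wrap event),
#' then collects r = |xy(t + dt) - xy(t)| for every start time on the
#' stride grid.
#'
#' @param traj A [cg_trajectory()]; frames must be evenly spaced in time.
#' @param window Time window dt in ns.
#' @param stride Spacing of start times in ns; default one frame
#'   (overlapping windows).
#' @return List of class `displacement_sample` with elements `window`
#'   (ns), `displacements` (nm), `n`, `stride_frames`, `window_frames`.
#' @export
lateral_displacements <- function(traj, window, stride = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"), window > 0)
  times <- traj$times
  if (length(times) < 2L) stop("trajectory too short", call. = FALSE)
  dtf <- diff(times)
  dt0 <- dtf[1L]
  if (any(abs(dtf - dt0) > 1e-9 * max(1, dt0))) {
    stop("frames must be evenly spaced in time", call. = FALSE)
  }
  if (window < dt0 - 1e-12) {
    stop("window shorter than the frame spacing", call. = FALSE)
  }
  if (window > (max(times) - min(times)) + 1e-12) {
    stop("window exceeds the trajectory span", call. = FALSE)
  }
  kw <- as.integer(round(window / dt0))
  if (abs(kw * dt0 - window) > 1e-6 * dt0) {
    stop("window must be a multiple of the frame spacing", call. = FALSE)
  }
  ks <- if (is.null(stride)) 1L else max(1L, as.integer(round(stride / dt0)))
  pidx <- .peptide_idx(traj)
  if (length(pidx) == 0L) stop("no peptide beads in trajectory",
                               call. = FALSE)
  nf <- length(times)
  com <- t(vapply(traj$frames,
                  function(f) colMeans(f[pidx, 1:2, drop = FALSE]),
                  numeric(2L)))
  # periodic unwrapping in x and y
  for (j in 1:2) {
    jump <- diff(com[, j])
    corr <- -traj$box[j] * cumsum(round(jump / traj$box[j]))
    com[, j] <- com[, j] + c(0, corr)
  }
  starts <- seq.int(1L, nf - kw, by = ks)
  dx <- com[starts + kw, 1L] - com[starts, 1L]
  dy <- com[starts + kw, 2L] - com[starts, 2L]
  structure(list(window = kw * dt0,
                 displacements = sqrt(dx * dx + dy * dy),
                 n = length(starts), stride_frames = ks,
                 window_frames = kw),
            class = "displacement_sample")
}

#' Fit the 2D random-walk (Rayleigh) law to displacement magnitudes
#'
#' Maximum-likelihood estimate D = <r^2> / (4 dt) of the lateral diffusion
#' coefficient, with a moving-block bootstrap confidence interval (block
#' length defaulting to the window length in samples, so overlapping-start
#' autocorrelation is respected) and a Kolmogorov-Smirnov distance to the
#' fitted Rayleigh law as goodness of fit.
#'
#' @param sample A `displacement_sample` from [lateral_displacements()],
#'   or a raw numeric vector of displacements when `window` is given.
#' @param window Time window in ns (when `sample` is a raw vector).
#' @param n_boot Bootstrap replicates, default 200.
#' @param conf Confidence level, default 0.95.
#' @param block_length Bootstrap block length in samples; default the
#'   number of strides spanned by one window (at least 1).
#' @param min_n Minimum sample size, default 50.
#' @return List of class `rayleigh_fit`: `D_nm2_ns`, `D_cm2_s`, `ci`
#'   (cm^2/s), `ci_nm2_ns`, `n`, `window_ns`, `gof` (KS statistic).
#' @export
rayleigh_fit <- function(sample, window = NULL, n_boot = 200, conf = 0.95,
                         block_length = NULL, min_n = 50) {
  if (inherits(sample, "displacement_sample")) {
    r <- sample$displacements
    window <- sample$window
    if (is.null(block_length)) {
      block_length <- max(1L,
        as.integer(ceiling(sample$window_frames / sample$stride_frames)))
    }
  } else {
    r <- as.numeric(sample)
    if (is.null(window) || window <= 0) {
      stop("window (ns) required for raw displacement input", call. = FALSE)
    }
    if (is.null(block_length)) block_length <- 1L
  }
  n <- length(r)
  if (n < min_n) {
    stop(sprintf("insufficient sample: n = %d < %d", n, min_n),
         call. = FALSE)
  }
  if (all(r == 0)) stop("degenerate fit: all displacements are zero",
                        call. = FALSE)
  est <- function(x) mean(x * x) / (4 * window)
  d_hat <- est(r)
  boot <- numeric(n_boot)
  n_blocks <- ceiling(n / block_length)
  for (b in seq_len(n_boot)) {
    starts <- sample.int(max(1L, n - block_length + 1L), n_blocks,
                         replace = TRUE)
    idx <- as.vector(outer(0:(block_length - 1L), starts, "+"))[seq_len(n)]
    boot[b] <- est(r[idx])
  }
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(a, 1 - a)))
  cdf <- function(x) 1 - exp(-x * x / (4 * d_hat * window))
  ks <- max(abs(cdf(sort(r)) - seq_len(n) / n),
            abs(cdf(sort(r)) - (seq_len(n) - 1L) / n))
  structure(list(D_nm2_ns = d_hat, D_cm2_s = nm2ns_to_cm2s(d_hat),
                 ci = nm2ns_to_cm2s(ci), ci_nm2_ns = ci, n = n,
                 window_ns = window, gof = ks, conf = conf),
            class = "rayleigh_fit")
}

#' @export
print.rayleigh_fit <- function(x, ...) {
  cat(sprintf(
    "Rayleigh fit (dt = %g ns, n = %d): D = %.4g cm^2/s [%.4g, %.4g], KS = %.3f\n",
    x$window_ns, x$n, x$D_cm2_s, x$ci[1], x$ci[2], x$gof))
  invisible(x)
}

#' Lateral diffusion coefficients at several time windows
#'
#' Runs [lateral_displacements()] + [rayleigh_fit()] for each window and
#' tabulates the results. A window whose preconditions fail yields a row
#' of `NA`s carrying the error message, and the rest of the table is still
#' produced.
#'
#' @param traj A [cg_trajectory()].
#' @param windows Numeric vector of window lengths in ns; default
#'   `c(0.2, 2, 100)`.
#' @param stride,n_boot,conf Passed through.
#' @return data.frame of class `diffusion_table` with columns `window_ns`,
#'   `D_cm2_per_s`, `ci_low`, `ci_high`, `n`, `error`.
#' @export
diffusion_table <- function(traj, windows = c(0.2, 2, 100), stride = NULL,
                            n_boot = 200, conf = 0.95) {
  stopifnot(length(windows) >= 1L)
  rows <- lapply(windows, function(w) {
    fit <- tryCatch({
      s <- lateral_displacements(traj, w, stride)
      rayleigh_fit(s, n_boot = n_boot, conf = conf)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(window_ns = w, D_cm2_per_s = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, n = NA_integer_,
                 error = conditionMessage(fit))
    } else {
      data.frame(window_ns = w, D_cm2_per_s = fit$D_cm2_s,
                 ci_low = fit$ci[1L], ci_high = fit$ci[2L], n = fit$n,
                 error = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diffusion_table", "data.frame")
  out
}
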