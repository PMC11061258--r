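# Deterministic synthetic-data generators: every input the analysis
# pipeline consumes, with known ground truth. The generators produce
# statistical structure only (ideal helices, lattice bilayers, scheduled
# rigid-body kinematics, Brownian walks, analytic free-energy surfaces and
# Gaussian deposition records); they do not attempt physically realistic
# packing or dynamics.

# Run expr under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards, so adding one generator call never shifts
# another generator's output.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Build an ideal helical coarse-grained peptide
#'
#' Places one backbone bead per residue on an ideal helix (default rise
#' 0.15 nm per residue, radius 0.23 nm, 100 degrees per turn — canonical
#' alpha-helix geometry), assigns residue classes, Fauchere-Pliska
#' hydrophobic weights and the net formal charge, and marks the termini.
#' The helix axis lies along z with the N-terminus (residue 1) at the
#' origin end.
#'
#' @param sequence One-letter residue string or vector.
#' @param rise Rise per residue along the axis, nm.
#' @param radius Helix radius, nm.
#' @param turn_deg Rotation per residue, degrees.
#' @param side_beads Integer extra (side-chain) beads per residue, default
#'   0; side beads are placed radially outward and count toward
#'   `bead_counts` for contact normalisation.
#' @param zwitterionic Terminal charge bookkeeping flag.
#' @param seed Unused randomness hook (construction is deterministic);
#'   kept for interface symmetry with the other generators.
#' @return A [peptide()].
#' @examples
#' make_helix("KWKLFKKIGAVLKVL")
#' @export
make_helix <- function(sequence, rise = 0.15, radius = 0.23,
                       turn_deg = 100, side_beads = 0L,
                       zwitterionic = TRUE, seed = NULL) {
  codes <- .split_sequence(sequence)
  n <- length(codes)
  if (n == 1L) {
    backbone <- matrix(0, 1L, 3L)
  } else {
    i <- seq_len(n) - 1L
    th <- .rad(turn_deg) * i
    backbone <- cbind(radius * cos(th), radius * sin(th), rise * i)
  }
  beads <- data.frame(residue = seq_len(n),
                      x = backbone[, 1L], y = backbone[, 2L],
                      z = backbone[, 3L], backbone = TRUE)
  if (side_beads > 0L) {
    for (k in seq_len(side_beads)) {
      r_out <- radius + 0.25 * k
      th <- if (n == 1L) 0 else .rad(turn_deg) * (seq_len(n) - 1L)
      beads <- rbind(beads, data.frame(
        residue = seq_len(n),
        x = r_out * cos(th), y = r_out * sin(th), z = backbone[, 3L],
        backbone = FALSE))
    }
  }
  peptide(codes, backbone,
          bead_counts = rep(1L + as.integer(side_beads), n),
          beads = beads, zwitterionic = zwitterionic)
}

# Named bilayer compositions (mole % per species).
.bilayer_compositions <- list(
  healthy_popc = c(POPC = 100),
  bacterial_pe_pg = c(POPE = 10, POPG = 90),
  cancer_5comp = c(CHOL = 28.4, DOPE = 20, DOPC = 20, DPSM = 18.4,
                   DOPS = 13.2)
)

#' Named model-membrane compositions
#'
#' The three packaged bilayer models: `healthy_popc` (POPC 100%),
#' `bacterial_pe_pg` (POPE 10%, POPG 90%) and `cancer_5comp`
#' (CHOL 28.4%, DOPE 20%, DOPC 20%, DPSM 18.4%, DOPS 13.2%).
#'
#' @return Named list of named percentage vectors.
#' @export
bilayer_compositions <- function() .bilayer_compositions

# Largest-remainder apportionment of percentages into n integer counts.
.largest_remainder <- function(pct, n) {
  exact <- pct * n / 100
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0L) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(base), names(pct))
}

#' Generate a planar two-leaflet model bilayer
#'
#' Lipids are apportioned to species by largest-remainder rounding of the
#' composition percentages, placed on a jittered square lattice in each
#' leaflet, and given a four-bead vertical profile (headgroup, linker, two
#' tail beads) with head planes separated by `head_separation`.
#'
#' @param composition A composition name (see [bilayer_compositions()]) or
#'   a named percentage vector summing to 100 (+-0.1).
#' @param lipids_per_leaflet Integer, default 250.
#' @param area_per_lipid nm^2 per lipid, default 0.64 (sets the box xy
#'   size).
#' @param head_separation Distance between the two headgroup planes, nm;
#'   default 4 (a typical bilayer thickness).
#' @param box_z Box height, nm; the bilayer is centred at `box_z / 2`.
#' @param jitter In-plane Gaussian jitter sd, nm.
#' @param seed Integer RNG seed for jitter and species placement.
#' @return Object of class `bilayer_model`: `atoms` data.frame (`lipid`,
#'   `leaflet`, `role`, `x`, `y`, `z`), `composition` (requested %),
#'   `counts` (realised per-leaflet counts), `membrane_center_z`, `box`.
#' @export
make_bilayer <- function(composition = "healthy_popc",
                         lipids_per_leaflet = 250,
                         area_per_lipid = 0.64, head_separation = 4,
                         box_z = 14, jitter = 0.05, seed = 1) {
  if (is.character(composition)) {
    if (!composition %in% names(.bilayer_compositions)) {
      stop("unknown composition label: ", composition, call. = FALSE)
    }
    label <- composition
    pct <- .bilayer_compositions[[composition]]
  } else {
    label <- "custom"
    pct <- composition
    stopifnot(is.numeric(pct), !is.null(names(pct)))
    if (abs(sum(pct) - 100) > 0.1) {
      stop("composition percentages must sum to 100 (+-0.1)", call. = FALSE)
    }
  }
  n <- as.integer(lipids_per_leaflet)
  counts <- .largest_remainder(pct, n)
  L <- sqrt(n * area_per_lipid)
  m <- ceiling(sqrt(n))
  sp <- L / m
  center_z <- box_z / 2
  half <- head_separation / 2
  # per-lipid bead z offsets from the membrane centre, outermost first
  roles <- c("headgroup", "linker", "tail", "tail")
  offsets <- c(half, half - 0.5, half - 1.1, half - 1.7)
  .with_seed(seed, {
    leaf_atoms <- function(leaflet_sign, leaflet_name) {
      site <- seq_len(n) - 1L
      gx <- (site %% m + 0.5) * sp
      gy <- (site %/% m + 0.5) * sp
      gx <- (gx + stats::rnorm(n, 0, jitter)) %% L
      gy <- (gy + stats::rnorm(n, 0, jitter)) %% L
      species <- sample(rep(names(counts), counts))
      do.call(rbind, lapply(seq_along(roles), function(k) {
        data.frame(lipid = species, leaflet = leaflet_name, role = roles[k],
                   x = gx, y = gy,
                   z = center_z + leaflet_sign * offsets[k])
      }))
    }
    atoms <- rbind(leaf_atoms(1, "upper"), leaf_atoms(-1, "lower"))
  })
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, composition = pct, counts = counts,
                 label = label, membrane_center_z = center_z,
                 box = c(L, L, box_z)),
            class = "bilayer_model")
}

#' @export
print.bilayer_model <- function(x, ...) {
  cat(sprintf("Bilayer model '%s': %d lipids/leaflet, box %.2f x %.2f x %.2f nm\n",
              x$label, sum(x$counts), x$box[1], x$box[2], x$box[3]))
  print(x$counts)
  invisible(x)
}

# Rodrigues rotation matrix for unit axis `u` and angle `th` (radians).
.rotation_matrix <- function(u, th) {
  u <- .normalize3(u)
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation taking unit vector a onto unit vector b.
.rotation_between <- function(a, b) {
  a <- .normalize3(a); b <- .normalize3(b)
  v <- .cross3(a, b)
  s <- sqrt(sum(v * v))
  c0 <- sum(a * b)
  if (s < 1e-12) {
    if (c0 > 0) return(diag(3L))
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- .normalize3(.cross3(a, p))
    return(.rotation_matrix(axis, pi))
  }
  .rotation_matrix(v / s, atan2(s, c0))
}

#' Generate a trajectory with a prescribed orientation schedule
#'
#' Rigidly places the peptide at each frame according to linearly
#' interpolated waypoints of z offset (from the membrane centre), tilt and
#' spin, over a static bilayer, optionally adding isotropic Gaussian
#' positional noise to the peptide beads. A zero-noise round trip through
#' [orientation_series()] recovers the schedule.
#'
#' @param pep A [peptide()].
#' @param bilayer A [make_bilayer()] model.
#' @param schedule data.frame with columns `time` (ns, increasing), `z`
#'   (signed COM offset from the membrane centre, nm; positive = upper
#'   side), `tilt_deg`, `spin_deg` (`NA` to leave the azimuth free).
#' @param dt Frame spacing in ns, default 1.
#' @param noise Gaussian positional noise sd (nm), default 0.
#' @param seed RNG seed for the noise stream.
#' @return A [cg_trajectory()].
#' @export
make_trajectory <- function(pep, bilayer, schedule, dt = 1, noise = 0,
                            seed = 1) {
  stopifnot(inherits(pep, "peptide"), inherits(bilayer, "bilayer_model"))
  needed <- c("time", "z", "tilt_deg", "spin_deg")
  stopifnot(all(needed %in% names(schedule)), nrow(schedule) >= 1L)
  if (is.unsorted(schedule$time)) {
    stop("schedule waypoints must be time-ordered", call. = FALSE)
  }
  box <- bilayer$box
  mem_z <- bilayer$membrane_center_z
  if (any(mem_z + schedule$z > box[3L]) || any(mem_z + schedule$z < 0)) {
    stop("schedule z offsets exceed the box", call. = FALSE)
  }
  times <- if (nrow(schedule) == 1L) schedule$time else {
    seq(min(schedule$time), max(schedule$time), by = dt)
  }
  sched_at <- function(col) {
    v <- schedule[[col]]
    ok <- !is.na(v)
    if (sum(ok) == 0L) return(rep(NA_real_, length(times)))
    if (nrow(schedule) == 1L || sum(ok) == 1L) {
      return(rep(v[ok][1L], length(times)))
    }
    stats::approx(schedule$time[ok], v[ok], xout = times, rule = 2)$y
  }
  z_t <- sched_at("z")
  tilt_t <- sched_at("tilt_deg")
  spin_t <- sched_at("spin_deg")

  bead_xyz <- as.matrix(pep$beads[, c("x", "y", "z")])
  bb_rows <- which(pep$beads$backbone)
  bb_res <- pep$beads$residue[bb_rows]
  bb_rows <- bb_rows[order(bb_res)]
  com0 <- colMeans(bead_xyz[bb_rows, , drop = FALSE])
  rel0 <- sweep(bead_xyz, 2L, com0)
  u0 <- .normalize3(bead_xyz[bb_rows[1L], ] -
                      bead_xyz[bb_rows[length(bb_rows)], ])
  mu0 <- as.numeric(crossprod(
    sweep(bead_xyz[bb_rows, , drop = FALSE], 2L, com0),
    pep$hydrophobic_weight))

  lip_xyz <- as.matrix(bilayer$atoms[, c("x", "y", "z")])
  n_pep <- nrow(bead_xyz)
  n_lip <- nrow(lip_xyz)
  atoms <- data.frame(
    bead_id = seq_len(n_pep + n_lip),
    group = c(rep("peptide", n_pep), rep("lipid", n_lip)),
    residue = c(pep$beads$residue, rep(NA_integer_, n_lip)),
    class = c(pep$residue_class[pep$beads$residue],
              rep(NA_character_, n_lip)),
    lipid = c(rep(NA_character_, n_pep), bilayer$atoms$lipid),
    role = c(rep(NA_character_, n_pep), bilayer$atoms$role),
    backbone = c(pep$beads$backbone, rep(FALSE, n_lip)))

  place <- function(z_off, tilt_deg, spin_deg) {
    upper <- z_off >= 0
    alpha <- if (upper) -1 else 1
    phi <- .rad(tilt_deg)
    # axis direction realising the requested tilt on this leaflet side
    u_t <- c(sin(phi), 0, alpha * cos(phi))
    R1 <- .rotation_between(u0, u_t)
    rel <- rel0 %*% t(R1)
    com <- c(box[1L] / 2, box[2L] / 2, mem_z + z_off)
    if (!is.na(spin_deg) && abs(sin(phi)) > 1e-9) {
      frame <- helix_frame(u_t, c(0, 0, 0), com[3L], mem_z,
                           box_z = box[3L])
      mu <- as.numeric(R1 %*% mu0)
      dec <- decompose_moment(mu, u_t)
      cur <- spin_angle(dec$transversal, frame)
      if (!is.na(cur)) {
        R2 <- .rotation_matrix(u_t, .rad(spin_deg - as.numeric(cur)))
        rel <- rel %*% t(R2)
      }
    }
    sweep(rel, 2L, com, "+")
  }

  frames <- .with_seed(seed, lapply(seq_along(times), function(i) {
    p <- place(z_t[i], tilt_t[i], spin_t[i])
    if (noise > 0) {
      p <- p + matrix(stats::rnorm(length(p), 0, noise), ncol = 3L)
    }
    unname(rbind(p, lip_xyz))
  }))
  cg_trajectory(times, frames, box, atoms)
}

#' Simulate a 2D Brownian (optionally tethered) in-plane walk
#'
#' Generates the xy track of a single-bead walker with i.i.d. Gaussian
#' increments of variance `2 D dt` per axis, wrapped into the periodic
#' box. With `tether_rate > 0` the walk is an Ornstein-Uhlenbeck process
#' relaxing toward the box centre at that rate (1/ns), which confines the
#' walker and makes windowed diffusion estimates decrease with the window
#' length.
#'
#' @param D Diffusion coefficient in nm^2/ns.
#' @param dt Time step, ns.
#' @param n_steps Number of steps (the trajectory has `n_steps + 1`
#'   frames).
#' @param box Length-3 box, nm.
#' @param tether_rate Harmonic relaxation rate theta in 1/ns, default 0
#'   (free diffusion).
#' @param seed Integer RNG seed.
#' @return A [cg_trajectory()] with one peptide bead.
#' @export
make_brownian_walk <- function(D, dt, n_steps, box = c(20, 20, 10),
                               tether_rate = 0, seed = 1) {
  stopifnot(D >= 0, dt > 0, n_steps >= 1L)
  sdd <- sqrt(2 * D * dt)
  xy <- .with_seed(seed, {
    steps <- matrix(stats::rnorm(2L * n_steps, 0, sdd), ncol = 2L)
    out <- matrix(0, nrow = n_steps + 1L, ncol = 2L)
    for (i in seq_len(n_steps)) {
      drift <- if (tether_rate > 0) -tether_rate * out[i, ] * dt else c(0, 0)
      out[i + 1L, ] <- out[i, ] + drift + steps[i, ]
    }
    out
  })
  center <- box[1:2] / 2
  wrapped <- cbind((xy[, 1L] + center[1L]) %% box[1L],
                   (xy[, 2L] + center[2L]) %% box[2L])
  frames <- lapply(seq_len(n_steps + 1L), function(i) {
    matrix(c(wrapped[i, 1L], wrapped[i, 2L], box[3L] / 2), 1L, 3L)
  })
  atoms <- data.frame(bead_id = 1L, group = "peptide", residue = 1L,
                      class = "hydrophobic", lipid = NA_character_,
                      role = NA_character_, backbone = TRUE)
  traj <- cg_trajectory(seq(0, by = dt, length.out = n_steps + 1L),
                        frames, box, atoms)
  attr(traj, "D_true_nm2_ns") <- D
  traj
}

#' Analytic free-energy surfaces with known partition coefficients
#'
#' Builds a 2D grid over (z, cos_tilt) of a named closed form and returns
#' it together with the partition coefficient kappa implied by the
#' generated surface for the given lambda and temperature.
#'
#' Forms (parameters in `params`):
#' \describe{
#'   \item{`flat`}{W = 0; kappa = 1.}
#'   \item{`square_well`}{depth `eps` over z in `[z1, z2]` (z-only).
#'     `z1`/`z2` are snapped to grid nodes; the grid representation ramps
#'     linearly over the single adjoining cell on each side, and
#'     `kappa_true` is the exact Boltzmann integral of that ramped
#'     piecewise-linear well. The idealised sharp-well value
#'     `((lambda - d) + d e^(beta eps)) / lambda` is attached as
#'     `kappa_sharp`.}
#'   \item{`harmonic_well`}{W = k/2 (z - z0)^2 - eps clipped to zero
#'     outside |z - z0| <= a = sqrt(2 eps / k); `kappa_true` is the
#'     error-function closed form of the smooth well.}
#'   \item{`tilted_well`}{W = -eps cos^2(phi) on z in `[z1, z2]` (ramped
#'     in z as for `square_well`); `kappa_true` combines the per-cosine
#'     closed form in z with a dense quadrature over the cosine.}
#'   \item{`gaussian_well`}{smooth W = -eps cos^2(phi)
#'     exp(-(z - z0)^2 / (2 w^2)); `kappa_true` by Gauss-Legendre x
#'     adaptive quadrature.}
#' }
#'
#' @param form One of the names above.
#' @param params Named list of parameters for the form.
#' @param lambda Interaction threshold (nm) used for `kappa_true`.
#' @param temperature Temperature, K.
#' @param z_max Upper edge of the z axis (>= lambda), nm.
#' @param nz,ncos Grid sizes.
#' @return List with `fes` (a [fes_grid()]), `kappa_true`, `lambda`,
#'   `temperature`, `form`, `params`.
#' @export
make_analytic_fes <- function(form = c("flat", "square_well",
                                       "harmonic_well", "tilted_well",
                                       "gaussian_well"),
                              params = list(), lambda = 3,
                              temperature = 300, z_max = 4, nz = 2001,
                              ncos = 41) {
  form <- match.arg(form)
  stopifnot(z_max >= lambda, lambda > 0)
  beta <- 1 / (kB_kJ_mol_K * temperature)
  z <- seq(0, z_max, length.out = nz)
  cc <- seq(-1, 1, length.out = ncos)
  h <- z[2L] - z[1L]
  snap <- function(x) z[which.min(abs(z - x))]
  wz <- NULL   # z-only profile when applicable
  wmat <- NULL # full matrix otherwise
  kappa_true <- NA_real_
  kappa_sharp <- NA_real_
  if (form == "flat") {
    wz <- rep(0, nz)
    kappa_true <- 1
  } else if (form %in% c("square_well", "tilted_well")) {
    eps <- params$eps %||% 10
    z1 <- snap(params$z1 %||% 1)
    z2 <- snap(params$z2 %||% 2)
    stopifnot(z1 > h, z2 > z1, z2 + h < lambda)
    d <- z2 - z1
    inside <- z >= z1 - 1e-12 & z <= z2 + 1e-12
    if (form == "square_well") {
      wz <- ifelse(inside, -eps, 0)
      E <- exp(beta * eps)
      ramps <- 2 * h * (E - 1) / (beta * eps)
      kappa_true <- ((z1 - h) + (lambda - z2 - h) + d * E + ramps) / lambda
      kappa_sharp <- ((lambda - d) + d * E) / lambda
    } else {
      wmat <- outer(ifelse(inside, 1, 0), -eps * cc^2)
      # per-cosine closed form in z (ramped well of depth eps c^2),
      # integrated over the cosine on a dense grid
      cfine <- seq(-1, 1, length.out = 200001L)
      a <- beta * eps * cfine^2
      Ec <- exp(a)
      ramp_c <- ifelse(a < 1e-12, 2 * h * (1 + a / 2),
                       2 * h * (Ec - 1) / a)
      integ <- (z1 - h) + (lambda - z2 - h) + d * Ec + ramp_c
      kappa_true <- pracma::trapz(cfine, integ) / (2 * lambda)
    }
  } else if (form == "harmonic_well") {
    eps <- params$eps %||% 10
    kk <- params$k %||% 100
    z0 <- params$z0 %||% 1.5
    a <- sqrt(2 * eps / kk)
    stopifnot(z0 - a > 0, z0 + a < lambda)
    wz <- pmin(0.5 * kk * (z - z0)^2 - eps, 0)
    erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
    well <- exp(beta * eps) * sqrt(2 * pi / (beta * kk)) *
      erf(a * sqrt(beta * kk / 2))
    kappa_true <- ((lambda - 2 * a) + well) / lambda
  } else { # gaussian_well
    eps <- params$eps %||% 10
    z0 <- params$z0 %||% 1.5
    w0 <- params$w %||% 0.4
    g <- exp(-(z - z0)^2 / (2 * w0^2))
    wmat <- outer(g, -eps * cc^2)
    gl <- pracma::gaussLegendre(201, -1, 1)
    inner <- vapply(gl$x, function(ci) {
      stats::integrate(function(zz) {
        exp(beta * eps * ci^2 * exp(-(zz - z0)^2 / (2 * w0^2)))
      }, 0, lambda, rel.tol = 1e-11)$value
    }, numeric(1L))
    kappa_true <- sum(gl$w * inner) / (2 * lambda)
  }
  if (is.null(wmat)) wmat <- matrix(wz, nrow = nz, ncol = ncos)
  fes <- fes_grid(list(z = z, cos_tilt = cc), wmat,
                  temperature = temperature)
  out <- list(fes = fes, kappa_true = kappa_true, lambda = lambda,
              temperature = temperature, form = form, params = params)
  if (is.finite(kappa_sharp)) out$kappa_sharp <- kappa_sharp
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesise a Gaussian deposition record reproducing a target FES
#'
#' Greedily deposits Gaussians of at most `height` kJ/mol at the grid
#' point of largest remaining deficit until the accumulated bias matches
#' (gamma - 1)/gamma times the inverted target within `tol`. Feeding the
#' record back through [reconstruct_fes()] recovers the target (shifted to
#' min zero) within about `gamma/(gamma - 1) * tol`.
#'
#' @param target A [fes_grid()] (1 or 2 axes) to emulate.
#' @param sigma Named numeric of Gaussian widths per axis; defaults to
#'   2.5 grid spacings per axis.
#' @param height Maximum Gaussian height (kJ/mol), default 2.2.
#' @param bias_factor Well-tempered bias factor gamma, default 50.
#' @param tol Deposition residual tolerance (kJ/mol), default 0.2.
#' @param pace Time between deposits, ns, default 1.
#' @param n_walkers Number of walkers the record is split across
#'   (round-robin), default 1.
#' @param max_hills Iteration budget; exceeding it aborts with the
#'   residual in the error message.
#' @param seed Unused randomness hook (deposition is deterministic).
#' @return A [hills_record()].
#' @export
make_hills <- function(target, sigma = NULL, height = 2.2,
                       bias_factor = 50, tol = 0.2, pace = 1,
                       n_walkers = 1L, max_hills = 100000L, seed = NULL) {
  stopifnot(inherits(target, "fes_grid"), bias_factor > 1, height > 0,
            tol > 0)
  axes <- target$axes
  cvs <- names(axes)
  if (is.null(sigma)) {
    sigma <- vapply(axes, function(ax) 2.5 * (ax[2L] - ax[1L]), numeric(1L))
    names(sigma) <- cvs
  }
  stopifnot(all(cvs %in% names(sigma)), all(sigma[cvs] > 0))
  t0 <- as.matrix(target$values)
  v_des <- (bias_factor - 1) / bias_factor * (max(t0) - t0)
  n1 <- nrow(v_des); n2 <- ncol(v_des)
  g1_tab <- outer(axes[[1L]], axes[[1L]],
                  function(a, b) exp(-(a - b)^2 / (2 * sigma[[cvs[1L]]]^2)))
  g2_tab <- if (length(axes) == 2L) {
    outer(axes[[2L]], axes[[2L]],
          function(a, b) exp(-(a - b)^2 / (2 * sigma[[cvs[2L]]]^2)))
  } else matrix(1, 1L, 1L)
  v <- matrix(0, n1, n2)
  rows <- vector("list", 0L)
  k <- 0L
  repeat {
    deficit <- v_des - v
    dmax <- max(deficit)
    if (dmax < tol) break
    if (k >= max_hills) {
      stop(sprintf(
        "deposition did not converge within %d hills (residual %.3g kJ/mol)",
        max_hills, dmax), call. = FALSE)
    }
    idx <- which.max(deficit)
    i1 <- (idx - 1L) %% n1 + 1L
    i2 <- (idx - 1L) %/% n1 + 1L
    hgt <- min(height, dmax)
    v <- v + hgt * tcrossprod(g1_tab[, i1], g2_tab[, i2])
    k <- k + 1L
    row <- list(time = k * pace)
    row[[cvs[1L]]] <- axes[[1L]][i1]
    if (length(axes) == 2L) row[[cvs[2L]]] <- axes[[2L]][i2]
    for (cv in cvs) row[[paste0("sigma_", cv)]] <- sigma[[cv]]
    row$height <- hgt
    row$biasf <- bias_factor
    row$walker <- (k - 1L) %% n_walkers + 1L
    rows[[k]] <- row
  }
  entries <- if (k == 0L) {
    cols <- c("time", cvs, paste0("sigma_", cvs), "height", "biasf",
              "walker")
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                  cols))
  } else {
    do.call(rbind, lapply(rows, as.data.frame))
  }
  rec <- hills_record(entries, cvs)
  attr(rec, "residual") <- max(abs(v_des - v))
  rec
}
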