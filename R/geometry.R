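# Orientation descriptors of a rigid helical peptide at a planar bilayer:
# tilt angle, hydrophobic dipole moment and its decomposition, spin angle.
#
# Conventions (pinned once, used everywhere):
#  * The helix axis vector runs from the C-terminus to the N-terminus,
#    NC = r_N - r_C.
#  * alpha = -1 when the peptide sits on the upper side of the bilayer
#    (peptide COM z above the membrane centre), +1 on the lower side.
#    With cos(phi) = NC_z / (|NC| alpha) this makes phi = 0 mean
#    "N-terminus approaching the membrane" on either leaflet.
#  * n_hat is the unit z vector pointing from the peptide toward the nearer
#    leaflet, i.e. (0, 0, alpha). The tilt-reference vector
#    t_hat = normalize(NC_hat x (NC_hat x n_hat)) lies in the plane spanned
#    by the axis and z, perpendicular to the axis; a spin angle of 180 deg
#    then means the transversal hydrophobic moment points at the membrane.

.normalize3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n == 0) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Build the orientation frame of a helical peptide at a bilayer
#'
#' Derives the helix-axis unit vector, the leaflet side, the sign factor
#' alpha, the membrane-pointing normal and the in-plane tilt-reference
#' vector from the two terminal backbone positions and the peptide/membrane
#' geometry.
#'
#' @param n_pos,c_pos Length-3 numeric, backbone positions of the N- and
#'   C-terminal residues (nm).
#' @param peptide_com_z z coordinate of the peptide centre of mass (nm).
#' @param membrane_center_z z of the bilayer centre (nm).
#' @param box_z Optional box height (nm) for minimum-image z offsets.
#' @param tol_parallel Tolerance on |sin(tilt)| below which the
#'   tilt-reference vector (and hence the spin angle) is undefined.
#' @return A list of class `helix_frame` with elements `nc`, `nc_unit`,
#'   `alpha`, `leaflet_side`, `n_hat`, `t_hat` (NULL when the axis is
#'   parallel to z) and `com_offset_z` (signed z offset, nm).
#' @export
helix_frame <- function(n_pos, c_pos, peptide_com_z, membrane_center_z,
                        box_z = NULL, tol_parallel = 1e-6) {
  stopifnot(length(n_pos) == 3L, length(c_pos) == 3L)
  nc <- as.numeric(n_pos) - as.numeric(c_pos)
  if (sqrt(sum(nc * nc)) < 1e-12) {
    stop("coincident termini: helix axis undefined", call. = FALSE)
  }
  nc_unit <- .normalize3(nc)
  dz <- peptide_com_z - membrane_center_z
  if (!is.null(box_z)) dz <- .min_image(dz, box_z)
  leaflet_side <- if (dz >= 0) "upper" else "lower"
  alpha <- if (leaflet_side == "upper") -1 else 1
  n_hat <- c(0, 0, alpha)
  t_raw <- .cross3(nc_unit, .cross3(nc_unit, n_hat))
  t_norm <- sqrt(sum(t_raw * t_raw)) # equals |sin(angle(axis, z))|
  t_hat <- if (t_norm < tol_parallel) NULL else t_raw / t_norm
  structure(list(nc = nc, nc_unit = nc_unit, alpha = alpha,
                 leaflet_side = leaflet_side, n_hat = n_hat, t_hat = t_hat,
                 com_offset_z = dz),
            class = "helix_frame")
}

#' Tilt angle of the helix axis relative to the membrane normal
#'
#' Angle phi between the C-to-N terminus vector and the z axis, signed by
#' the leaflet side so that phi = 0 deg always means the N-terminus points
#' toward the nearer leaflet and phi = 180 deg the C-terminus:
#' cos(phi) = NC_z / (|NC| alpha), alpha = -1 (upper side) or +1 (lower).
#'
#' @param frame A `helix_frame`, or the N-terminus position when `c_pos`
#'   etc. are supplied directly.
#' @param c_pos,peptide_com_z,membrane_center_z,box_z Passed to
#'   [helix_frame()] when `frame` is a raw N-terminus position.
#' @return Tilt angle in degrees, in `[0, 180]`.
#' @examples
#' tilt_angle(c(0, 0, 3), c(0, 0, 5), peptide_com_z = 4,
#'            membrane_center_z = 0) # 0: N-terminus toward the membrane
#' @export
tilt_angle <- function(frame, c_pos = NULL, peptide_com_z = NULL,
                       membrane_center_z = 0, box_z = NULL) {
  if (!inherits(frame, "helix_frame")) {
    n_pos <- frame
    if (is.null(peptide_com_z)) {
      peptide_com_z <- (n_pos[3L] + c_pos[3L]) / 2
    }
    frame <- helix_frame(n_pos, c_pos, peptide_com_z, membrane_center_z,
                         box_z)
  }
  cosphi <- frame$nc_unit[3L] / frame$alpha
  cosphi <- max(-1, min(1, cosphi))
  .deg(acos(cosphi))
}

#' Hydrophobic dipole moment of a peptide
#'
#' Sum of backbone bead positions relative to the backbone centre of mass,
#' weighted by the per-residue Fauchere-Pliska hydrophobicity:
#' mu = sum_i mu_i (r_i - r_com). Translation-invariant by construction.
#'
#' @param pep A [peptide()] object, or an n x 3 backbone matrix when
#'   `weights` is given.
#' @param weights Per-residue hydrophobic weights (only when `pep` is a raw
#'   coordinate matrix).
#' @return Length-3 numeric vector (dimensionless weight x nm).
#' @export
hydrophobic_moment <- function(pep, weights = NULL) {
  if (inherits(pep, "peptide")) {
    pos <- pep$backbone
    weights <- pep$hydrophobic_weight
  } else {
    pos <- as.matrix(pep)
  }
  stopifnot(ncol(pos) == 3L)
  if (is.null(weights) || length(weights) != nrow(pos) || anyNA(weights)) {
    stop("missing hydrophobic weight for a residue", call. = FALSE)
  }
  com <- colMeans(pos)
  rel <- sweep(pos, 2L, com)
  as.numeric(crossprod(rel, weights))
}

#' Decompose a hydrophobic moment along and across the helix axis
#'
#' Longitudinal part: projection of the moment on the axis unit vector,
#' mu_L = (mu . NC_hat) NC_hat; transversal part: mu_perp = mu - mu_L.
#'
#' @param moment Length-3 numeric vector.
#' @param nc_unit Unit helix-axis vector (C-terminus to N-terminus).
#' @return List of class `hydrophobic_moment` with elements `total`,
#'   `longitudinal`, `transversal`.
#' @export
decompose_moment <- function(moment, nc_unit) {
  stopifnot(length(moment) == 3L, length(nc_unit) == 3L)
  n2 <- sum(nc_unit * nc_unit)
  if (n2 < 1e-12) stop("zero axis vector", call. = FALSE)
  if (abs(n2 - 1) > 1e-6) nc_unit <- nc_unit / sqrt(n2)
  long <- sum(moment * nc_unit) * nc_unit
  structure(list(total = as.numeric(moment), longitudinal = long,
                 transversal = as.numeric(moment) - long),
            class = "hydrophobic_moment")
}

#' Spin angle: azimuthal rotation of the helix about its own axis
#'
#' Angle xi between the tilt-reference vector t_hat and the transversal
#' hydrophobic-moment component, xi = arccos(t_hat . mu_perp / |mu_perp|),
#' lifted from `[0, 180]` to `[0, 360)` by the sign of
#' NC_hat . (t_hat x mu_perp): positive for xi < 180, negative for
#' xi > 180. With the packaged conventions xi = 180 deg means the
#' transversal moment points toward the nearer leaflet (the membrane).
#'
#' Undefined configurations (transversal moment below tolerance, or helix
#' axis parallel to z so that t_hat does not exist) return `NA` with a
#' `"reason"` attribute instead of an arbitrary angle.
#'
#' @param transversal Length-3 numeric, transversal component of the
#'   hydrophobic moment.
#' @param frame A [helix_frame()].
#' @param tol Magnitude below which the transversal moment is considered
#'   degenerate.
#' @return Spin angle in degrees in `[0, 360)`, or `NA` for degenerate
#'   input.
#' @export
spin_angle <- function(transversal, frame, tol = 1e-8) {
  stopifnot(inherits(frame, "helix_frame"), length(transversal) == 3L)
  m <- sqrt(sum(transversal^2))
  if (m < tol) {
    return(structure(NA_real_, reason = "transversal moment ~ 0"))
  }
  if (is.null(frame$t_hat)) {
    return(structure(NA_real_, reason = "helix axis parallel to z"))
  }
  mu_hat <- transversal / m
  cosxi <- max(-1, min(1, sum(frame$t_hat * mu_hat)))
  xi <- .deg(acos(cosxi))
  s <- sum(frame$nc_unit * .cross3(frame$t_hat, mu_hat))
  if (s < 0) xi <- 360 - xi
  xi %% 360
}

#' Per-frame orientation descriptors along a trajectory
#'
#' Computes, for every frame, the signed z distance between the peptide
#' centre of mass and the bilayer centre (minimum image), the tilt angle
#' and the spin angle. The spin is reported as `NA` with
#' `spin_defined = FALSE` where its preconditions fail.
#'
#' @param traj A [cg_trajectory()] containing peptide and lipid beads.
#' @param pep The [peptide()] whose residues the peptide beads map to
#'   (supplies hydrophobic weights).
#' @return data.frame of class `orientation_series` with columns
#'   `time_ns`, `com_distance_nm`, `tilt_deg`, `spin_deg`, `spin_defined`.
#' @export
orientation_series <- function(traj, pep) {
  stopifnot(inherits(traj, "cg_trajectory"), inherits(pep, "peptide"))
  pidx <- .peptide_idx(traj)
  lidx <- .lipid_idx(traj)
  if (length(pidx) == 0L || length(lidx) == 0L) {
    stop("trajectory must contain both peptide and lipid beads",
         call. = FALSE)
  }
  bb <- pidx[traj$atoms$backbone[pidx]]
  res <- traj$atoms$residue[bb]
  ord <- order(res)
  bb <- bb[ord]
  res <- res[ord]
  if (!identical(as.integer(res), seq_along(pep$sequence))) {
    stop("trajectory backbone beads do not match the peptide residues",
         call. = FALSE)
  }
  nf <- length(traj$times)
  out <- data.frame(time_ns = traj$times,
                    com_distance_nm = NA_real_,
                    tilt_deg = NA_real_,
                    spin_deg = NA_real_,
                    spin_defined = FALSE)
  wts <- pep$hydrophobic_weight
  for (i in seq_len(nf)) {
    fr <- traj$frames[[i]]
    bpos <- fr[bb, , drop = FALSE]
    com <- colMeans(bpos)
    mem_z <- .membrane_center_z(fr, lidx)
    frame <- helix_frame(bpos[1L, ], bpos[nrow(bpos), ], com[3L], mem_z,
                         box_z = traj$box[3L])
    mu <- as.numeric(crossprod(sweep(bpos, 2L, com), wts))
    dec <- decompose_moment(mu, frame$nc_unit)
    sp <- spin_angle(dec$transversal, frame)
    out$com_distance_nm[i] <- frame$com_offset_z
    out$tilt_deg[i] <- tilt_angle(frame)
    out$spin_deg[i] <- as.numeric(sp)
    out$spin_defined[i] <- !is.na(sp)
  }
  class(out) <- c("orientation_series", "data.frame")
  out
}
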