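# Trajectory container: time-stamped frames of peptide + bilayer beads in an
# orthorhombic periodic box.

#' Construct a coarse-grained trajectory object
#'
#' @param times Numeric vector of frame times (ns), strictly increasing.
#' @param frames List of N x 3 coordinate matrices (nm), one per time.
#' @param box Length-3 numeric, orthorhombic box edge lengths (nm).
#' @param atoms data.frame describing the N beads, with columns
#'   `bead_id` (integer), `group` (`"peptide"` or `"lipid"`),
#'   `residue` (residue index for peptide beads, NA otherwise),
#'   `class` (residue class for peptide beads), `lipid` (lipid species name
#'   for lipid beads), `role` (`"headgroup"`, `"tail"` or `"linker"` for
#'   lipid beads), `backbone` (logical, peptide backbone bead flag).
#' @return An object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(times, frames, box, atoms) {
  stopifnot(is.numeric(times), length(times) >= 1L,
            is.list(frames), length(frames) == length(times),
            length(box) == 3L, all(box > 0))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  n <- nrow(frames[[1L]])
  ok <- vapply(frames, function(f) is.matrix(f) && ncol(f) == 3L &&
                 nrow(f) == n, logical(1L))
  if (!all(ok)) stop("all frames must be N x 3 matrices of equal N",
                     call. = FALSE)
  needed <- c("bead_id", "group", "residue", "class", "lipid", "role",
              "backbone")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(nrow(atoms) == n)
  structure(list(times = as.numeric(times), frames = frames,
                 box = as.numeric(box), atoms = atoms),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "CG trajectory: %d frames (%.3g..%.3g ns), %d beads (%d peptide, %d lipid), box %.2f x %.2f x %.2f nm\n",
    length(x$times), min(x$times), max(x$times), nrow(x$atoms),
    sum(x$atoms$group == "peptide"), sum(x$atoms$group == "lipid"),
    x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

# Minimum-image displacement for orthorhombic boxes (vectorised per axis).
.min_image <- function(d, box_len) d - box_len * round(d / box_len)

# Indices helpers
.peptide_idx <- function(traj) which(traj$atoms$group == "peptide")
.lipid_idx <- function(traj) which(traj$atoms$group == "lipid")

# z of the bilayer centre in one frame: mean z of lipid beads. Generated and
# typical simulation bilayers do not straddle the periodic z boundary.
.membrane_center_z <- function(frame, lipid_idx) {
  mean(frame[lipid_idx, 3L])
}

# Frames whose times fall inside [window[1], window[2]].
.frames_in_window <- function(traj, window) {
  sel <- which(traj$times >= window[1L] & traj$times <= window[2L])
  if (length(sel) == 0L) stop("no frames inside the requested time window",
                              call. = FALSE)
  sel
}
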