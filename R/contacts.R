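# Peptide-lipid contact fingerprints and z-density profiles.
#
# A contact is a peptide-bead / lipid-bead pair whose minimum-image
# distance is at most the cutoff (0.6 nm by default, the mindist-style
# criterion). Counts are aggregated by peptide residue class and lipid
# species, then normalised by the total number of peptide beads of each
# class so that amino acids of different sizes are comparable.

#' Count peptide-lipid contacts in one frame
#'
#' @param pep_pos m x 3 matrix of peptide bead positions (nm).
#' @param pep_class length-m residue-class label per peptide bead.
#' @param lip_pos k x 3 matrix of lipid bead positions (nm).
#' @param lip_name length-k lipid species name per lipid bead.
#' @param box Length-3 box (nm) for minimum-image distances.
#' @param cutoff Contact cutoff distance (nm), default 0.6.
#' @param method `"cell"` (cell-list accelerated, default) or `"brute"`
#'   (all-pairs scan); both give identical counts.
#' @return Numeric matrix, residue classes x lipid names, of raw pair
#'   counts (attribute `normalized = FALSE`).
#' @export
count_contacts <- function(pep_pos, pep_class, lip_pos, lip_name, box,
                           cutoff = 0.6, method = c("cell", "brute")) {
  method <- match.arg(method)
  pep_pos <- as.matrix(pep_pos)
  lip_pos <- as.matrix(lip_pos)
  if (nrow(pep_pos) == 0L || nrow(lip_pos) == 0L) {
    stop("empty peptide or lipid selection", call. = FALSE)
  }
  stopifnot(cutoff > 0, length(box) == 3L, all(box > 0),
            length(pep_class) == nrow(pep_pos),
            length(lip_name) == nrow(lip_pos),
            all(is.finite(pep_pos)), all(is.finite(lip_pos)))
  classes <- .class_levels[.class_levels %in% unique(pep_class)]
  lipids <- sort(unique(lip_name))
  mat <- matrix(0, nrow = length(classes), ncol = length(lipids),
                dimnames = list(classes, lipids))
  lip_fac <- factor(lip_name, levels = lipids)
  if (method == "brute") {
    for (i in seq_len(nrow(pep_pos))) {
      hits <- .within_cutoff(pep_pos[i, ], lip_pos, box, cutoff)
      if (any(hits)) {
        tab <- table(lip_fac[hits])
        mat[pep_class[i], ] <- mat[pep_class[i], ] + as.numeric(tab)
      }
    }
  } else {
    cl <- .build_cell_list(lip_pos, box, cutoff)
    for (i in seq_len(nrow(pep_pos))) {
      cand <- .cell_candidates(pep_pos[i, ], cl)
      if (length(cand) == 0L) next
      hits <- cand[.within_cutoff(pep_pos[i, ], lip_pos[cand, , drop = FALSE],
                                  box, cutoff)]
      if (length(hits) > 0L) {
        tab <- table(lip_fac[hits])
        mat[pep_class[i], ] <- mat[pep_class[i], ] + as.numeric(tab)
      }
    }
  }
  attr(mat, "normalized") <- FALSE
  attr(mat, "cutoff") <- cutoff
  mat
}

# minimum-image distance test of one point against a coordinate block
.within_cutoff <- function(p, coords, box, cutoff) {
  dx <- .min_image(coords[, 1L] - p[1L], box[1L])
  dy <- .min_image(coords[, 2L] - p[2L], box[2L])
  dz <- .min_image(coords[, 3L] - p[3L], box[3L])
  dx * dx + dy * dy + dz * dz <= cutoff * cutoff
}

# Cell list over the periodic box with cell edge >= cutoff.
.build_cell_list <- function(coords, box, cutoff) {
  ncell <- pmax(1L, floor(box / cutoff))
  edge <- box / ncell
  wrapped <- sweep(coords, 2L, box, "%%")
  idx <- floor(sweep(wrapped, 2L, edge, "/"))
  for (j in 1:3) idx[, j] <- pmin(idx[, j], ncell[j] - 1L) # guard box-edge rounding
  key <- idx[, 1L] + ncell[1L] * (idx[, 2L] + ncell[2L] * idx[, 3L])
  list(ncell = ncell, edge = edge, box = box,
       members = split(seq_len(nrow(coords)), key))
}

.cell_candidates <- function(p, cl) {
  ncell <- cl$ncell
  pw <- p %% cl$box
  c0 <- pmin(floor(pw / cl$edge), ncell - 1L)
  out <- integer(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    ix <- (c0[1L] + dx) %% ncell[1L]
    iy <- (c0[2L] + dy) %% ncell[2L]
    iz <- (c0[3L] + dz) %% ncell[3L]
    key <- as.character(ix + ncell[1L] * (iy + ncell[2L] * iz))
    m <- cl$members[[key]]
    if (!is.null(m)) out <- c(out, m)
  }
  unique(out)
}

#' Normalise a raw contact matrix per residue-class bead count
#'
#' Divides each residue-class row of a raw contact-count matrix by the
#' total number of peptide beads of that class, making counts comparable
#' across amino acids of different size. Normalisation is tracked by an
#' attribute and refuses to be applied twice.
#'
#' @param raw Matrix from [count_contacts()] (or an averaged one).
#' @param pep The [peptide()] providing per-residue bead counts.
#' @return A `contact_fingerprint` matrix (contacts per bead).
#' @export
normalize_fingerprint <- function(raw, pep) {
  if (isTRUE(attr(raw, "normalized"))) {
    stop("fingerprint is already normalised", call. = FALSE)
  }
  totals <- .class_bead_totals(pep)
  present <- rownames(raw)
  zero <- present[totals[present] == 0]
  if (length(zero) > 0L) {
    stop("contacts reported for residue class with zero beads: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  out <- sweep(raw, 1L, as.numeric(totals[present]), "/")
  attr(out, "normalized") <- TRUE
  attr(out, "cutoff") <- attr(raw, "cutoff")
  attr(out, "window") <- attr(raw, "window")
  class(out) <- c("contact_fingerprint", class(out))
  out
}

#' Time-averaged, normalised contact fingerprint over a trailing window
#'
#' Computes the per-frame raw contact matrix for every frame inside the
#' window, averages them, and normalises per residue-class bead count.
#'
#' @param traj A [cg_trajectory()].
#' @param pep The corresponding [peptide()].
#' @param cutoff Contact cutoff (nm), default 0.6.
#' @param window Length-2 numeric `(t_start, t_end)` in ns; default the
#'   trailing 1000 ns of the trajectory.
#' @param method Passed to [count_contacts()].
#' @return A `contact_fingerprint` matrix with `window` attribute.
#' @export
average_fingerprint <- function(traj, pep, cutoff = 0.6, window = NULL,
                                method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "cg_trajectory"), inherits(pep, "peptide"))
  if (is.null(window)) {
    window <- c(max(traj$times) - 1000, max(traj$times))
  }
  sel <- .frames_in_window(traj, window)
  pidx <- .peptide_idx(traj)
  lidx <- .lipid_idx(traj)
  pep_class <- traj$atoms$class[pidx]
  lip_name <- traj$atoms$lipid[lidx]
  acc <- NULL
  for (i in sel) {
    fr <- traj$frames[[i]]
    m <- count_contacts(fr[pidx, , drop = FALSE], pep_class,
                        fr[lidx, , drop = FALSE], lip_name,
                        traj$box, cutoff, method)
    acc <- if (is.null(acc)) m else acc + m
  }
  avg <- acc / length(sel)
  attr(avg, "normalized") <- FALSE
  attr(avg, "cutoff") <- cutoff
  attr(avg, "window") <- window
  normalize_fingerprint(avg, pep)
}

#' z-density profile of lipid heads, lipid tails and peptide beads
#'
#' Histograms bead z coordinates (wrapped into the primary box, then
#' recentred on the bilayer centre of mass) over the frames of a time
#' window. Counts are summed over frames, so each species' histogram total
#' equals its bead count times the number of frames.
#'
#' @param traj A [cg_trajectory()].
#' @param window Length-2 `(t_start, t_end)` ns; default trailing 1000 ns.
#' @param bin_width Bin width in nm, default 0.1.
#' @return data.frame of class `density_profile` with columns
#'   `z_center_nm`, `heads`, `tails`, `peptide`.
#' @export
density_profile <- function(traj, window = NULL, bin_width = 0.1) {
  stopifnot(inherits(traj, "cg_trajectory"), bin_width > 0)
  bz <- traj$box[3L]
  if (bz <= 0) stop("zero-thickness box", call. = FALSE)
  if (is.null(window)) window <- c(max(traj$times) - 1000, max(traj$times))
  sel <- .frames_in_window(traj, window)
  lidx <- .lipid_idx(traj)
  head_idx <- lidx[traj$atoms$role[lidx] == "headgroup"]
  tail_idx <- lidx[traj$atoms$role[lidx] == "tail"]
  pep_idx <- .peptide_idx(traj)
  nb <- max(2L, ceiling(bz / bin_width))
  edges <- seq(-bz / 2, bz / 2, length.out = nb + 1L)
  counts <- matrix(0, nrow = nb, ncol = 3L,
                   dimnames = list(NULL, c("heads", "tails", "peptide")))
  for (i in sel) {
    fr <- traj$frames[[i]]
    center <- .membrane_center_z(fr, lidx)
    zrel <- function(idx) {
      z <- (fr[idx, 3L] - center) %% bz
      ifelse(z >= bz / 2, z - bz, z)
    }
    for (sp in list(c("heads", 1L), c("tails", 2L), c("peptide", 3L))) {
      idx <- switch(sp[[1L]], heads = head_idx, tails = tail_idx,
                    peptide = pep_idx)
      if (length(idx) == 0L) next
      h <- findInterval(zrel(idx), edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
      tb <- tabulate(h, nbins = nb)
      counts[, as.integer(sp[[2L]])] <- counts[, as.integer(sp[[2L]])] + tb
    }
  }
  out <- data.frame(z_center_nm = (edges[-1L] + edges[-(nb + 1L)]) / 2,
                    heads = counts[, 1L], tails = counts[, 2L],
                    peptide = counts[, 3L])
  attr(out, "window") <- window
  class(out) <- c("density_profile", "data.frame")
  out
}
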