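# Peptide container and sequence-level fingerprints.

#' Classify residues into basic / acidic / polar / hydrophobic
#'
#' Maps each one-letter residue code onto exactly one of the four classes
#' used throughout the package: basic \{K, R, H\}, acidic \{D, E\}, polar
#' \{S, T, N, Q\} and hydrophobic \{G, A, V, L, I, P, F, M, W, C, Y\}.
#'
#' @param sequence A single string of one-letter codes, or a character
#'   vector of individual codes.
#' @return Character vector of class labels, one per residue.
#' @examples
#' classify_residues("KKKK")
#' classify_residues("GIGKFLHSAKKFGKAFVGEIMNS")
#' @export
classify_residues <- function(sequence) {
  codes <- .split_sequence(sequence)
  cls <- .residue_classes[codes]
  bad <- which(is.na(cls))
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue code '%s' at position %d",
                 codes[bad[1L]], bad[1L]), call. = FALSE)
  }
  unname(cls)
}

.split_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) >= 1L)
  codes <- if (length(sequence) == 1L && nchar(sequence) > 1L) {
    strsplit(sequence, "", fixed = TRUE)[[1L]]
  } else {
    sequence
  }
  codes <- toupper(codes)
  if (length(codes) < 1L || length(codes) > 1000L) {
    stop("sequence length must be in [1, 1000]", call. = FALSE)
  }
  codes
}

#' Residue-class composition percentages
#'
#' Aggregates per-residue class labels into the percentage of basic,
#' acidic, polar and hydrophobic residues (the pie-chart summary of a
#' peptide sequence). Percentages sum to 100.
#'
#' @param classes Character vector of class labels as produced by
#'   [classify_residues()] (a raw sequence string is also accepted and
#'   classified first).
#' @return An object of class `composition_fingerprint`: named numeric
#'   vector with entries `basic`, `acidic`, `polar`, `hydrophobic` (in %).
#' @examples
#' composition_fingerprint(classify_residues("KKDD"))
#' @export
composition_fingerprint <- function(classes) {
  if (length(classes) == 0L) stop("empty class list", call. = FALSE)
  if (!all(classes %in% .class_levels)) {
    classes <- classify_residues(classes)
  }
  counts <- table(factor(classes, levels = .class_levels))
  pct <- 100 * as.numeric(counts) / length(classes)
  names(pct) <- .class_levels
  structure(pct, class = "composition_fingerprint")
}

#' @export
print.composition_fingerprint <- function(x, ...) {
  cat("Residue-class composition (%):\n")
  print(round(unclass(x), 1))
  invisible(x)
}

#' Net formal charge of a peptide sequence
#'
#' Counts +1 per K/R and -1 per D/E; histidine is treated as neutral at
#' physiological pH. Zwitterionic termini (the default) contribute +1 and
#' -1 and therefore cancel; with `zwitterionic = FALSE` both termini are
#' uncharged, which gives the same net total.
#'
#' @param sequence One-letter sequence string or vector.
#' @param zwitterionic Logical; kept for bookkeeping of the terminal state.
#' @return Integer net charge in elementary units.
#' @export
peptide_net_charge <- function(sequence, zwitterionic = TRUE) {
  codes <- .split_sequence(sequence)
  chg <- .residue_charges[codes]
  chg[is.na(chg)] <- 0L
  as.integer(sum(chg))
}

#' Construct a coarse-grained peptide object
#'
#' Bundles the sequence, one backbone bead position per residue, per-residue
#' bead counts, residue classes, hydrophobic weights and net charge into a
#' `peptide` object consumed by the orientation and contact analyses.
#'
#' @param sequence One-letter residue string or vector (length n).
#' @param backbone n x 3 numeric matrix of backbone bead positions (nm).
#' @param bead_counts Integer vector, total CG beads per residue (default 1,
#'   i.e. backbone-only resolution). Used to normalise contact fingerprints.
#' @param beads Optional data.frame of all peptide beads with columns
#'   `residue`, `x`, `y`, `z` (nm). Defaults to the backbone beads.
#' @param zwitterionic Logical, terminal charge state bookkeeping.
#' @return An object of class `peptide`.
#' @examples
#' pep <- peptide("KALA", matrix(rnorm(12), ncol = 3))
#' pep$residue_class
#' @export
peptide <- function(sequence, backbone, bead_counts = NULL, beads = NULL,
                    zwitterionic = TRUE) {
  codes <- .split_sequence(sequence)
  n <- length(codes)
  backbone <- as.matrix(backbone)
  stopifnot(is.numeric(backbone), ncol(backbone) == 3L, nrow(backbone) == n)
  if (!all(is.finite(backbone))) stop("backbone positions must be finite",
                                      call. = FALSE)
  cls <- classify_residues(codes)
  wt <- fauchere_pliska[codes]
  if (anyNA(wt)) stop("missing hydrophobic weight for a residue",
                      call. = FALSE)
  if (is.null(bead_counts)) bead_counts <- rep(1L, n)
  stopifnot(length(bead_counts) == n, all(bead_counts >= 1L))
  if (is.null(beads)) {
    beads <- data.frame(residue = seq_len(n),
                        x = backbone[, 1], y = backbone[, 2],
                        z = backbone[, 3])
  }
  stopifnot(all(c("residue", "x", "y", "z") %in% names(beads)))
  structure(list(
    sequence = codes,
    backbone = unname(backbone),
    bead_counts = as.integer(bead_counts),
    residue_class = cls,
    hydrophobic_weight = unname(wt),
    net_charge = peptide_net_charge(codes, zwitterionic),
    zwitterionic = isTRUE(zwitterionic),
    n_term_index = 1L,
    c_term_index = n,
    beads = beads
  ), class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("Coarse-grained peptide: %d residues, net charge %+d\n",
              length(x$sequence), x$net_charge))
  cat(" sequence: ", paste(x$sequence, collapse = ""), "\n", sep = "")
  print(composition_fingerprint(x$residue_class))
  invisible(x)
}

# Total number of peptide beads per residue class (for contact
# normalisation).
.class_bead_totals <- function(pep) {
  tapply(pep$bead_counts, factor(pep$residue_class, levels = .class_levels),
         sum, default = 0L)
}
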