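# Shared fixtures: reference sequences and small synthetic systems.

# Reference AMP sequences (one-letter codes)
seq_ll37 <- "LLGDFFRKSKEKIGKEFKRIVQRIKDFLRNLVPRTES" # 37 res, +6
seq_magainin2 <- "GIGKFLHSAKKFGKAFVGEIMNS"            # 23 res
seq_cm15 <- "KWKLFKKIGAVLKVL"                        # 15 res, +5

# A small bilayer + scheduled trajectory for contact/density tests.
small_system <- function(n_lipids = 64, seed = 3, side_beads = 1L,
                         noise = 0.02) {
  pep <- make_helix(seq_cm15, side_beads = side_beads)
  bil <- make_bilayer("cancer_5comp", lipids_per_leaflet = n_lipids,
                      seed = seed)
  sched <- data.frame(time = c(0, 20), z = c(4, 2.2),
                      tilt_deg = c(0, 90), spin_deg = c(NA, 180))
  traj <- make_trajectory(pep, bil, sched, dt = 1, noise = noise,
                          seed = seed + 1)
  list(pep = pep, bil = bil, traj = traj)
}

# Independent all-pairs contact oracle: plain double loop over bead pairs
# with explicit minimum-image distances.
oracle_contacts <- function(pep_pos, pep_class, lip_pos, lip_name, box,
                            cutoff) {
  classes <- c("basic", "acidic", "polar", "hydrophobic")
  classes <- classes[classes %in% unique(pep_class)]
  lipids <- sort(unique(lip_name))
  mat <- matrix(0, length(classes), length(lipids),
                dimnames = list(classes, lipids))
  for (i in seq_len(nrow(pep_pos))) {
    for (j in seq_len(nrow(lip_pos))) {
      d <- pep_pos[i, ] - lip_pos[j, ]
      d <- d - box * round(d / box)
      if (sum(d^2) <= cutoff^2) {
        mat[pep_class[i], lip_name[j]] <- mat[pep_class[i], lip_name[j]] + 1
      }
    }
  }
  mat
}

# Independent Gaussian-summation oracle for FES reconstruction (double
# loop over hills x grid points, non-periodic axes).
oracle_fes_2d <- function(entries, z_axis, c_axis, bias_factor) {
  v <- matrix(0, length(z_axis), length(c_axis))
  for (r in seq_len(nrow(entries))) {
    for (i in seq_along(z_axis)) {
      v[i, ] <- v[i, ] + entries$height[r] *
        exp(-(z_axis[i] - entries$z[r])^2 / (2 * entries$sigma_z[r]^2) -
              (c_axis - entries$cos_tilt[r])^2 /
              (2 * entries$sigma_cos_tilt[r]^2))
    }
  }
  f <- -bias_factor / (bias_factor - 1) * v
  f - min(f)
}
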