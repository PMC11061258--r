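# Generators: helices, bilayers, walks, analytic surfaces, hills records.

test_that("ideal helices have the configured geometry and bookkeeping", {
  one <- make_helix("K")
  expect_equal(one$backbone, matrix(0, 1, 3))
  h <- make_helix("AAAAAAAAAAAAAAAAAA", rise = 0.15) # 18 residues
  expect_equal(diff(h$backbone[, 3]), rep(0.15, 17), tolerance = 1e-9)
  # all beads at the configured radius
  expect_equal(sqrt(h$backbone[, 1]^2 + h$backbone[, 2]^2), rep(0.23, 18),
               tolerance = 1e-9)
  ll37 <- make_helix(seq_ll37)
  expect_equal(nrow(ll37$backbone), 37L)
  expect_equal(ll37$net_charge, 6L)
  expect_error(make_helix("AZA"), "unknown residue")
  side <- make_helix("KAK", side_beads = 2L)
  expect_equal(side$bead_counts, rep(3L, 3))
  expect_equal(nrow(side$beads), 9L)
})

test_that("bilayer compositions follow largest-remainder apportionment", {
  popc <- make_bilayer("healthy_popc", lipids_per_leaflet = 250, seed = 1)
  expect_equal(unname(popc$counts["POPC"]), 250L)
  bact <- make_bilayer("bacterial_pe_pg", lipids_per_leaflet = 250,
                       seed = 1)
  expect_equal(unname(bact$counts[c("POPE", "POPG")]), c(25L, 225L))
  cancer <- make_bilayer("cancer_5comp", lipids_per_leaflet = 250,
                         seed = 1)
  expect_equal(sum(cancer$counts), 250L)
  realized <- 100 * cancer$counts / 250
  target <- bilayer_compositions()$cancer_5comp
  expect_true(all(abs(realized[names(target)] - target) < 0.4))
  # largest-remainder bound: < 100 / (2 n) percentage points at any n
  for (n in c(50, 137, 250)) {
    b <- make_bilayer("cancer_5comp", lipids_per_leaflet = n, seed = 2)
    realized <- 100 * b$counts / n
    expect_true(all(abs(realized[names(target)] - target) <= 100 / n))
  }
  expect_error(make_bilayer(c(POPC = 70, POPG = 20)), "sum to 100")
  expect_error(make_bilayer("unknown_label"), "unknown composition")
})

test_that("bilayers have two leaflets, in-box beads and seeded determinism", {
  b1 <- make_bilayer("bacterial_pe_pg", lipids_per_leaflet = 40, seed = 9)
  expect_setequal(unique(b1$atoms$leaflet), c("upper", "lower"))
  expect_true(all(b1$atoms$x >= 0 & b1$atoms$x <= b1$box[1]))
  expect_true(all(b1$atoms$z >= 0 & b1$atoms$z <= b1$box[3]))
  b2 <- make_bilayer("bacterial_pe_pg", lipids_per_leaflet = 40, seed = 9)
  expect_identical(b1$atoms, b2$atoms)
  b3 <- make_bilayer("bacterial_pe_pg", lipids_per_leaflet = 40, seed = 10)
  expect_false(identical(b1$atoms, b2$atoms) &&
                 identical(b1$atoms$x, b3$atoms$x))
})

test_that("generator RNG streams are isolated from the session stream", {
  set.seed(101)
  before <- .Random.seed
  invisible(make_bilayer("healthy_popc", lipids_per_leaflet = 20,
                         seed = 5))
  invisible(make_brownian_walk(0.1, 0.1, 50, seed = 6))
  expect_identical(.Random.seed, before)
})

test_that("scheduled trajectories respect box bounds and noise contracts", {
  pep <- make_helix(seq_cm15)
  bil <- make_bilayer("healthy_popc", lipids_per_leaflet = 25, seed = 2)
  sched_bad <- data.frame(time = 0, z = 50, tilt_deg = 90, spin_deg = NA)
  expect_error(make_trajectory(pep, bil, sched_bad), "exceed")
  sched <- data.frame(time = c(0, 4), z = c(4, 3), tilt_deg = c(90, 90),
                      spin_deg = c(180, 180))
  t1 <- make_trajectory(pep, bil, sched, dt = 1, noise = 0.05, seed = 11)
  t2 <- make_trajectory(pep, bil, sched, dt = 1, noise = 0.05, seed = 11)
  expect_identical(t1$frames, t2$frames)
  t3 <- make_trajectory(pep, bil, sched, dt = 1, noise = 0.05, seed = 12)
  expect_false(identical(t1$frames, t3$frames))
  # noise scatters descriptors at the propagated scale but not wildly
  os <- orientation_series(t1, pep)
  expect_true(all(abs(os$com_distance_nm - seq(4, 3, by = -0.25)) < 0.2))
})

test_that("Brownian walks reproduce their diffusion coefficient", {
  still <- make_brownian_walk(D = 0, dt = 0.1, n_steps = 100, seed = 3)
  com <- t(vapply(still$frames, function(f) f[1, 1:2], numeric(2)))
  expect_equal(max(apply(com, 2, stats::sd)), 0)
  w <- make_brownian_walk(D = 0.08, dt = 0.05, n_steps = 50000, seed = 13)
  s <- lateral_displacements(w, window = 0.05) # single-step displacements
  d_hat <- mean(s$displacements^2) / (4 * 0.05)
  se <- 0.08 / sqrt(s$n)
  expect_lt(abs(d_hat - 0.08), 3 * se)
  w2 <- make_brownian_walk(D = 0.08, dt = 0.05, n_steps = 100, seed = 13)
  w2b <- make_brownian_walk(D = 0.08, dt = 0.05, n_steps = 100, seed = 13)
  w3 <- make_brownian_walk(D = 0.08, dt = 0.05, n_steps = 100, seed = 14)
  expect_identical(w2$frames, w2b$frames)
  expect_false(identical(w2$frames[[50]], w3$frames[[50]]))
})

test_that("analytic surfaces carry correct closed-form kappas", {
  flat <- make_analytic_fes("flat", lambda = 2.5, z_max = 3, nz = 301)
  expect_equal(flat$kappa_true, 1)
  expect_true(all(flat$fes$values == 0))
  # harmonic well: erf closed form against an independent quadrature
  hw <- make_analytic_fes("harmonic_well",
                          params = list(eps = 12, k = 150, z0 = 1.4),
                          lambda = 3, z_max = 4, nz = 501)
  beta <- 1 / (kB_kJ_mol_K * 300)
  quad <- stats::integrate(function(z) {
    exp(-beta * pmin(0.5 * 150 * (z - 1.4)^2 - 12, 0))
  }, 0, 3, rel.tol = 1e-10)$value / 3
  expect_equal(hw$kappa_true, quad, tolerance = 1e-8)
  # square well: ramped closed form sits between sharp-well bounds
  sq <- make_analytic_fes("square_well",
                          params = list(eps = 8, z1 = 1, z2 = 2),
                          lambda = 3, z_max = 4, nz = 1001)
  expect_equal(sq$kappa_true, sq$kappa_sharp, tolerance = 1e-2)
  expect_error(make_analytic_fes("no_such_form"), "arg")
})

test_that("hills generation round-trips through reconstruction", {
  z <- seq(0, 4, length.out = 201)
  target <- fes_grid(list(z = z), -12 * exp(-(z - 1.5)^2 / (2 * 0.3^2)))
  rec <- make_hills(target, sigma = c(z = 0.06), height = 2.2,
                    bias_factor = 50, tol = 0.2)
  expect_gt(nrow(rec$entries), 10)
  expect_true(all(rec$entries$height <= 2.2 + 1e-12))
  back <- reconstruct_fes(rec, list(z = z))
  expect_lt(max(abs(back$values - (target$values - min(target$values)))),
            0.5)
  # flat target: nothing to deposit
  rec0 <- make_hills(fes_grid(list(z = z), rep(0, 201)), tol = 0.2)
  expect_equal(nrow(rec0$entries), 0L)
  # six-walker split reconstructs identically after merge
  rec6 <- make_hills(target, sigma = c(z = 0.06), height = 2.2,
                     bias_factor = 50, tol = 0.2, n_walkers = 6L)
  expect_setequal(unique(rec6$entries$walker), 1:6)
  back6 <- reconstruct_fes(rec6, list(z = z))
  expect_equal(back6$values, back$values, tolerance = 1e-12)
  # iteration budget failure carries the residual
  expect_error(make_hills(target, sigma = c(z = 0.06), height = 2.2,
                          tol = 0.2, max_hills = 3L), "residual")
})
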