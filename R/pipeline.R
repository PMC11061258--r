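# Orchestration of the two workflows: unbiased-trajectory descriptor
# analysis, and metadynamics FES thermodynamics. The exported functions
# are the programmatic entry points; scripts can wrap them trivially.

#' Resolve an analysis configuration
#'
#' Fills in the packaged defaults (contact cutoff 0.6 nm; diffusion
#' windows 0.2, 2 and 100 ns; trailing averaging window 1000 ns;
#' temperature 300 K; standard-state volume 1.660 nm^3; lambda policy
#' `"auto"`) and returns the fully resolved configuration together with a
#' stable fingerprint hash that every report embeds.
#'
#' @param ... Overrides of the defaults listed above (`cutoff`,
#'   `diffusion_windows`, `trailing_window`, `temperature`, `V0`,
#'   `lambda`, `bin_width`, `seed`, `out_dir`, plus free-form labels).
#' @return List of class `run_config` with a `hash` element.
#' @export
run_config <- function(...) {
  cfg <- list(cutoff = 0.6, diffusion_windows = c(0.2, 2, 100),
              trailing_window = 1000, temperature = 300, V0 = V0_nm3,
              lambda = "auto", bin_width = 0.1, seed = 1L,
              out_dir = ".", membrane = NA_character_)
  dots <- list(...)
  if (length(dots) > 0L) {
    stopifnot(!is.null(names(dots)), all(nzchar(names(dots))))
    cfg[names(dots)] <- dots
  }
  cfg$package_version <- as.character(utils::packageVersion("helimem"))
  cfg$hash <- .config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

# md5 of the canonical JSON serialisation (version field excluded from the
# hashed payload so the hash tracks scientific settings only).
.config_hash <- function(cfg) {
  payload <- cfg[setdiff(sort(names(cfg)), c("hash", "out_dir"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run the unbiased-trajectory descriptor workflow
#'
#' Computes the orientation series, the time-averaged contact
#' fingerprint, the z-density profile and the windowed diffusion table
#' for one trajectory, writes each as TSV plus a JSON summary into
#' `config$out_dir`, and returns the results.
#'
#' @param traj A [cg_trajectory()] (or a path readable by
#'   [read_frames_txt()] when `atoms` metadata is embedded in `pep`;
#'   passing the object is the normal route).
#' @param pep The matching [peptide()].
#' @param config A [run_config()]; defaults are used when omitted.
#' @param contacts,density,diffusion Logical toggles per analysis stage.
#' @return List with elements `orientation`, `contacts`, `density`,
#'   `diffusion`, `files`, `config` (invisibly writes the report bundle).
#' @export
run_descriptor_pipeline <- function(traj, pep, config = run_config(),
                                    contacts = TRUE, density = TRUE,
                                    diffusion = TRUE) {
  stopifnot(inherits(traj, "cg_trajectory"), inherits(pep, "peptide"),
            inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- c(sprintf("helimem %s", config$package_version),
             sprintf("config %s", config$hash))
  files <- character(0)
  window <- c(max(traj$times) - config$trailing_window, max(traj$times))

  orient <- orientation_series(traj, pep)
  f <- file.path(config$out_dir, "orientation.tsv")
  .write_tsv(orient, f, stamp)
  files <- c(files, f)

  fp <- NULL
  if (contacts) {
    fp <- average_fingerprint(traj, pep, cutoff = config$cutoff,
                              window = window)
    f <- file.path(config$out_dir, "contacts.tsv")
    .write_tsv(data.frame(residue_class = rownames(fp),
                          as.data.frame(unclass(fp)[, , drop = FALSE]),
                          check.names = FALSE),
               f, c(stamp, sprintf("cutoff_nm %g", config$cutoff)))
    files <- c(files, f)
  }

  dens <- NULL
  if (density) {
    dens <- density_profile(traj, window = window,
                            bin_width = config$bin_width)
    f <- file.path(config$out_dir, "density.tsv")
    .write_tsv(dens, f, stamp)
    files <- c(files, f)
  }

  diff_tab <- NULL
  if (diffusion) {
    diff_tab <- diffusion_table(traj, windows = config$diffusion_windows)
    f <- file.path(config$out_dir, "diffusion.tsv")
    .write_tsv(diff_tab, f, stamp)
    files <- c(files, f)
  }

  summary <- list(config = unclass(config)[setdiff(names(config),
                                                   c("hash", "out_dir"))],
                  config_hash = config$hash,
                  n_frames = length(traj$times),
                  final_com_distance_nm =
                    orient$com_distance_nm[nrow(orient)],
                  mean_tilt_deg_window =
                    mean(orient$tilt_deg[traj$times >= window[1L]]),
                  files = basename(files))
  f <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  invisible(list(orientation = orient, contacts = fp, density = dens,
                 diffusion = diff_tab, files = files, config = config))
}

#' Run the metadynamics thermodynamics workflow
#'
#' Starting from either a reconstructed FES grid or a hills record (which
#' is first reconstructed on the supplied axes), projects onto z, selects
#' lambda (automatically at the half-kT rule, or as fixed in the config),
#' computes the partition coefficient by both the 2D and the projected 1D
#' route, applies the standard-state correction and writes the PMF and a
#' JSON thermodynamic report.
#'
#' @param fes A [fes_grid()] over `(z, cos_tilt)`; alternatively `NULL`
#'   with `hills` given.
#' @param hills Optional [hills_record()]; used when `fes` is `NULL`.
#' @param axes Grid axes for the reconstruction when starting from hills.
#' @param config A [run_config()].
#' @param convergence Optional time-ordered list of z-PMFs for block
#'   uncertainty.
#' @return List with `pmf_z`, `lambda`, `thermo_2d`, `thermo_1d`,
#'   `uncertainty_dG0`, `files`, `config`.
#' @export
run_thermo_pipeline <- function(fes = NULL, hills = NULL, axes = NULL,
                                config = run_config(),
                                convergence = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(fes)) {
    if (is.null(hills)) stop("either a FES grid or a hills record is required",
                             call. = FALSE)
    stopifnot(!is.null(axes))
    fes <- reconstruct_fes(hills, axes, temperature = config$temperature)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- c(sprintf("helimem %s", config$package_version),
             sprintf("config %s", config$hash))
  pmf_z <- project_to_1d(fes, "z", temperature = config$temperature)
  zmax <- max(pmf_z$axis)
  # provisional far-field anchor for lambda selection
  probe <- anchor_pmf(pmf_z, c(zmax - 0.1 * diff(range(pmf_z$axis)), zmax))
  lambda <- if (identical(config$lambda, "auto")) {
    tryCatch(choose_lambda(probe, temperature = config$temperature),
             error = function(e) {
               stop("automatic lambda selection failed: ",
                    conditionMessage(e), call. = FALSE)
             })
  } else {
    as.numeric(config$lambda)
  }
  th2 <- standard_state(
    kappa_from_2d(fes, lambda, temperature = config$temperature),
    V0 = config$V0)
  pmf_anchored <- anchor_pmf(pmf_z, c(lambda, zmax))
  th1 <- standard_state(
    kappa_from_1d(pmf_anchored, lambda, temperature = config$temperature),
    V0 = config$V0)
  unc <- if (!is.null(convergence)) {
    tryCatch(dg0_uncertainty(convergence, lambda,
                             temperature = config$temperature,
                             V0 = config$V0),
             error = function(e) NA_real_)
  } else NA_real_
  th2$uncertainty <- unc
  th1$uncertainty <- unc

  f_pmf <- file.path(config$out_dir, "pmf_z.tsv")
  .write_tsv(data.frame(z_nm = pmf_anchored$axis,
                        pmf_kJ_mol = pmf_anchored$values),
             f_pmf, c(stamp, sprintf("lambda_nm %g", lambda)))
  report <- list(config_hash = config$hash,
                 package_version = config$package_version,
                 temperature_K = config$temperature,
                 lambda_nm = lambda, V0_nm3 = config$V0,
                 kappa_2d = th2$kappa, kappa0_2d = th2$kappa0,
                 dG0_2d_kJ_mol = th2$dG0,
                 kappa_1d = th1$kappa, kappa0_1d = th1$kappa0,
                 dG0_1d_kJ_mol = th1$dG0,
                 dG0_uncertainty_kJ_mol = unc)
  f_json <- file.path(config$out_dir, "thermo.json")
  jsonlite::write_json(report, f_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(pmf_z = pmf_anchored, lambda = lambda, thermo_2d = th2,
                 thermo_1d = th1, uncertainty_dG0 = unc,
                 files = c(f_pmf, f_json), config = config))
}
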