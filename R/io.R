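# Plain-text readers and writers: GRO and PDB coordinate dialects, a
# columnar text trajectory format for fixtures, PLUMED-style HILLS
# deposition records, gridded FES files and TSV report tables.

#' Read a GRO coordinate file
#'
#' Fixed-column GROMACS coordinate dialect (positions in nm).
#'
#' @param path File path.
#' @return data.frame with columns `resid`, `resname`, `atom`, `x`, `y`,
#'   `z` (nm) and a `box` attribute (length-3 nm).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a GRO file: ", path, call. = FALSE)
  natoms <- as.integer(trimws(lines[2L]))
  at <- lines[3L:(2L + natoms)]
  out <- data.frame(
    resid = as.integer(substr(at, 1L, 5L)),
    resname = trimws(substr(at, 6L, 10L)),
    atom = trimws(substr(at, 11L, 15L)),
    x = as.numeric(substr(at, 21L, 28L)),
    y = as.numeric(substr(at, 29L, 36L)),
    z = as.numeric(substr(at, 37L, 44L)))
  box <- as.numeric(strsplit(trimws(lines[3L + natoms]), "\\s+")[[1L]])[1:3]
  attr(out, "box") <- box
  out
}

#' Write a GRO coordinate file
#'
#' @param atoms data.frame with `resid`, `resname`, `atom`, `x`, `y`, `z`
#'   (nm).
#' @param box Length-3 box vector (nm).
#' @param path Output path.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(atoms, box, path, title = "helimem coordinates") {
  n <- nrow(atoms)
  lines <- c(title, sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     atoms$resid %% 100000L, substr(atoms$resname, 1L, 5L),
                     substr(atoms$atom, 1L, 5L), seq_len(n) %% 100000L,
                     atoms$x, atoms$y, atoms$z),
             sprintf("%10.5f%10.5f%10.5f", box[1L], box[2L], box[3L]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PDB coordinate file (positions converted to nm)
#'
#' Thin wrapper over `bio3d::read.pdb` that returns the same columns as
#' [read_gro()], with Angstrom coordinates converted to nm.
#'
#' @param path File path.
#' @return data.frame with `resid`, `resname`, `atom`, `x`, `y`, `z` (nm).
#' @export
read_pdb_nm <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB files requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  data.frame(resid = a$resno, resname = a$resid, atom = a$elety,
             x = a$x / 10, y = a$y / 10, z = a$z / 10)
}

#' Write a trajectory to the columnar text frame format
#'
#' One row per bead per frame: `time_ns bead_id x y z` (nm), with a
#' header comment. Bead metadata is not stored; supply the atoms table to
#' [read_frames_txt()] when reading back.
#'
#' @param traj A [cg_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frames_txt <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time_ns bead_id x y z", con)
  writeLines(sprintf("# box %.9g %.9g %.9g", traj$box[1L], traj$box[2L],
                     traj$box[3L]), con)
  n <- nrow(traj$atoms)
  for (i in seq_along(traj$times)) {
    f <- traj$frames[[i]]
    writeLines(sprintf("%.9g %d %.9g %.9g %.9g", traj$times[i],
                       seq_len(n), f[, 1L], f[, 2L], f[, 3L]), con)
  }
  invisible(path)
}

#' Read a columnar text trajectory
#'
#' @param path File written by [write_frames_txt()].
#' @param atoms Bead metadata table (see [cg_trajectory()]).
#' @param box Optional box override; defaults to the `# box` header.
#' @return A [cg_trajectory()].
#' @export
read_frames_txt <- function(path, atoms, box = NULL) {
  lines <- readLines(path)
  hdr <- grep("^# box ", lines, value = TRUE)
  if (is.null(box)) {
    if (length(hdr) == 0L) stop("no box header in ", path, call. = FALSE)
    box <- as.numeric(strsplit(sub("^# box ", "", hdr[1L]), "\\s+")[[1L]])
  }
  dat <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           col.names = c("time_ns", "bead_id", "x", "y",
                                         "z"))
  times <- unique(dat$time_ns)
  n <- nrow(atoms)
  frames <- lapply(times, function(t0) {
    d <- dat[dat$time_ns == t0, ]
    d <- d[order(d$bead_id), ]
    if (nrow(d) != n) stop("frame at t=", t0, " has wrong bead count",
                           call. = FALSE)
    unname(as.matrix(d[, c("x", "y", "z")]))
  })
  cg_trajectory(times, frames, box, atoms)
}

#' Write a hills record to PLUMED-dialect files, one per walker
#'
#' Header line `#! FIELDS time <cvs> sigma_<cvs> height biasf`, then
#' whitespace-separated columns.
#'
#' @param hills A [hills_record()].
#' @param paths Character vector of output paths, one per walker id
#'   present (in sorted walker order).
#' @return `paths`, invisibly.
#' @export
write_hills <- function(hills, paths) {
  stopifnot(inherits(hills, "hills_record"))
  walkers <- sort(unique(hills$entries$walker))
  if (length(walkers) == 0L) walkers <- 1L
  stopifnot(length(paths) == length(walkers))
  cols <- c("time", hills$cvs, paste0("sigma_", hills$cvs), "height",
            "biasf")
  for (i in seq_along(walkers)) {
    ent <- hills$entries[hills$entries$walker == walkers[i], cols,
                         drop = FALSE]
    con <- file(paths[i], "w")
    writeLines(paste("#! FIELDS", paste(cols, collapse = " ")), con)
    if (nrow(ent) > 0L) {
      writeLines(do.call(sprintf, c(
        list(paste(rep("%.12g", length(cols)), collapse = " ")),
        unname(as.list(ent)))), con)
    }
    close(con)
  }
  invisible(paths)
}

#' Read PLUMED-dialect hills files (one per walker) into a merged record
#'
#' @param paths One file per walker; entries are merged and sorted by
#'   time, with the walker id (file index) retained per entry.
#' @return A [hills_record()].
#' @export
read_hills <- function(paths) {
  if (length(paths) == 0L) {
    return(hills_record(data.frame(time = numeric(0), height = numeric(0),
                                   biasf = numeric(0),
                                   walker = integer(0)),
                        cvs = character(0)))
  }
  parse_one <- function(path, walker) {
    lines <- readLines(path)
    hl <- grep("^#! FIELDS", lines, value = TRUE)
    if (length(hl) == 0L) stop("no FIELDS header in ", path, call. = FALSE)
    fields <- strsplit(trimws(sub("^#! FIELDS", "", hl[1L])), "\\s+")[[1L]]
    body <- lines[!startsWith(lines, "#")]
    dat <- if (length(body) == 0L) {
      as.data.frame(stats::setNames(rep(list(numeric(0)), length(fields)),
                                    fields))
    } else {
      utils::read.table(text = body, col.names = fields)
    }
    cvs <- setdiff(fields[!startsWith(fields, "sigma_")],
                   c("time", "height", "biasf"))
    dat$walker <- walker
    list(dat = dat, cvs = cvs)
  }
  parsed <- lapply(seq_along(paths), function(i) parse_one(paths[i], i))
  cvs <- parsed[[1L]]$cvs
  for (p in parsed) {
    if (!identical(sort(p$cvs), sort(cvs))) {
      stop("inconsistent collective-variable sets across hills files",
           call. = FALSE)
    }
  }
  hills_record(do.call(rbind, lapply(parsed, `[[`, "dat")), cvs)
}

#' Write a FES grid to a commented-header text file
#'
#' Header lines name the axes, units and periodicity; the body has one
#' row per grid point (row-major over the first axis) with the axis
#' values followed by the free energy in kJ/mol.
#'
#' @param fes A [fes_grid()].
#' @param path Output path.
#' @param units Named character of axis units (defaults `z` = nm, others
#'   dimensionless).
#' @return `path`, invisibly.
#' @export
write_fes_grid <- function(fes, path, units = NULL) {
  stopifnot(inherits(fes, "fes_grid"))
  axn <- names(fes$axes)
  if (is.null(units)) {
    units <- stats::setNames(ifelse(axn == "z", "nm", "1"), axn)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in axn) {
    writeLines(sprintf("# axis %s unit %s periodic %s n %d", nm,
                       units[[nm]],
                       ifelse(isTRUE(fes$periodic[[nm]]), "true", "false"),
                       length(fes$axes[[nm]])), con)
  }
  writeLines(sprintf("# temperature_K %.9g bias_factor %.9g",
                     fes$temperature, fes$bias_factor), con)
  if (length(fes$axes) == 1L) {
    writeLines(sprintf("%.12g %.12g", fes$axes[[1L]], fes$values), con)
  } else {
    grid <- expand.grid(i = seq_along(fes$axes[[1L]]),
                        j = seq_along(fes$axes[[2L]]))
    grid <- grid[order(grid$i, grid$j), ]
    writeLines(sprintf("%.12g %.12g %.12g",
                       fes$axes[[1L]][grid$i], fes$axes[[2L]][grid$j],
                       fes$values[cbind(grid$i, grid$j)]), con)
  }
  invisible(path)
}

#' Read a FES grid file written by [write_fes_grid()]
#'
#' @param path File path.
#' @return A [fes_grid()].
#' @export
read_fes_grid <- function(path) {
  lines <- readLines(path)
  axl <- grep("^# axis ", lines, value = TRUE)
  if (length(axl) == 0L) stop("no axis headers in ", path, call. = FALSE)
  axes <- list()
  periodic <- logical(0)
  for (l in axl) {
    tk <- strsplit(trimws(sub("^# axis", "", l)), "\\s+")[[1L]]
    # tokens: name unit <u> periodic <p> n <n>
    axes[[tk[1L]]] <- as.integer(tk[which(tk == "n") + 1L])
    periodic[tk[1L]] <- identical(tk[which(tk == "periodic") + 1L], "true")
  }
  meta <- grep("^# temperature_K", lines, value = TRUE)
  temperature <- 300
  bias_factor <- NA_real_
  if (length(meta) > 0L) {
    tk <- strsplit(trimws(sub("^#", "", meta[1L])), "\\s+")[[1L]]
    temperature <- as.numeric(tk[2L])
    bf_tok <- tk[which(tk == "bias_factor") + 1L]
    bias_factor <- if (length(bf_tok) == 0L || bf_tok %in% c("NA", "nan")) {
      NA_real_
    } else as.numeric(bf_tok)
  }
  dat <- utils::read.table(text = lines[!startsWith(lines, "#")])
  axn <- names(axes)
  if (length(axes) == 1L) {
    fes_grid(stats::setNames(list(dat[[1L]]), axn), dat[[2L]],
             temperature = temperature, bias_factor = bias_factor,
             periodic = periodic)
  } else {
    n1 <- axes[[1L]]; n2 <- axes[[2L]]
    ax1 <- unique(dat[[1L]]); ax2 <- unique(dat[[2L]])
    stopifnot(length(ax1) == n1, length(ax2) == n2)
    vals <- matrix(dat[[3L]], nrow = n1, ncol = n2, byrow = TRUE)
    fes_grid(stats::setNames(list(sort(ax1), sort(ax2)), axn), vals,
             temperature = temperature, bias_factor = bias_factor,
             periodic = periodic)
  }
}

# TSV writer shared by the report functions: '.' decimal, tab separator,
# header row, optional leading comment lines.
.write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0L) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
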