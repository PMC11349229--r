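#' Coordinate trajectory container
#'
#' Frames by 3N coordinate matrix in nanometres (GROMACS convention;
#' PLUMED output is in nm as well) plus atom metadata.  PDB and DCD
#' files store angstroms; readers and writers convert at the boundary.
#'
#' @param xyz numeric T x 3N matrix (nm), columns x1,y1,z1,x2,...
#' @param atoms data frame with at least `elety` (atom name), `resid`
#'   (residue name) and `resno` (residue number); one row per atom.
#' @param dt_ps frame spacing in ps.
#' @param segments segment start rows (see [feature_series()]).
#' @return an object of class `coord_traj`.
#' @export
coord_traj <- function(xyz, atoms, dt_ps = 1, segments = 1L) {
  xyz <- as.matrix(xyz)
  atoms <- as.data.frame(atoms)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop(sprintf("trajectory has %d coordinates per frame but topology has %d atoms",
                 ncol(xyz), nrow(atoms)))
  if (!all(c("elety", "resid", "resno") %in% names(atoms)))
    stop("atoms needs columns elety, resid, resno")
  if (!is.numeric(dt_ps) || dt_ps <= 0) stop("dt_ps must be > 0")
  segments <- check_segments(segments, nrow(xyz))
  structure(list(xyz = xyz, atoms = atoms, dt_ps = dt_ps, segments = segments),
            class = "coord_traj")
}

#' @export
print.coord_traj <- function(x, ...) {
  cat(sprintf("coord_traj: %d frames, %d atoms, dt = %g ps\n",
              nrow(x$xyz), nrow(x$atoms), x$dt_ps))
  invisible(x)
}

#' Read a trajectory with its topology
#'
#' Supported inputs: a (multi-model) PDB used as both topology and
#' trajectory, or a PDB topology plus a DCD trajectory.  Parsing is done
#' by \pkg{bio3d}; coordinates are converted from angstrom to nm.
#'
#' @param trajfile trajectory file (`.pdb` or `.dcd`).
#' @param topfile PDB topology; defaults to `trajfile` when that is a PDB.
#' @param dt_ps frame spacing in ps.
#' @return a [coord_traj()].
#' @export
read_trajectory <- function(trajfile, topfile = NULL, dt_ps = 1) {
  if (!file.exists(trajfile)) stop(sprintf("trajectory file '%s' not found", trajfile))
  ext <- tolower(tools::file_ext(trajfile))
  if (is.null(topfile)) {
    if (ext != "pdb")
      stop("a PDB topology is required for non-PDB trajectories")
    topfile <- trajfile
  }
  if (!file.exists(topfile)) stop(sprintf("topology file '%s' not found", topfile))
  top <- bio3d::read.pdb(topfile, multi = TRUE)
  atoms <- top$atom[, c("elety", "resid", "resno", "chain")]
  natom <- nrow(atoms)
  xyz <- switch(ext,
    pdb = {
      m <- top$xyz
      if (!is.matrix(m)) m <- matrix(m, nrow = 1)
      m
    },
    dcd = bio3d::read.dcd(trajfile, verbose = FALSE),
    stop(sprintf("unsupported trajectory format '.%s' (use pdb or dcd)", ext)))
  if (ncol(xyz) != 3L * natom)
    stop(sprintf("atom-count mismatch: topology has %d atoms, trajectory frames have %d",
                 natom, ncol(xyz) %/% 3L))
  coord_traj(xyz / 10, atoms, dt_ps = dt_ps)   # angstrom -> nm
}

#' Write a trajectory as CHARMM-style DCD
#'
#' Minimal single-precision DCD writer (no unit cell), readable by
#' `bio3d::read.dcd` and standard MD tooling.  Input coordinates are in
#' nm and are written in angstrom.
#'
#' @param xyz T x 3N coordinate matrix in nm.
#' @param path output file.
#' @param dt_ps frame spacing stamped into the header.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(xyz, path, dt_ps = 1) {
  xyz <- as.matrix(xyz) * 10     # nm -> angstrom
  nframes <- nrow(xyz)
  natom <- ncol(xyz) %/% 3L
  con <- file(path, "wb")
  on.exit(close(con))
  put_int <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  put_f <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  # header block: 'CORD' + 20 control ints (delta stored as float in slot 10)
  put_int(84L)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nframes; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nframes
  icntrl[20] <- 24L    # CHARMM version flag
  put_int(icntrl[1:9]); put_f(dt_ps); put_int(icntrl[11:20])
  put_int(84L)
  # title block
  title <- formatC("Created by slowcv toy trajectory writer", width = -80)
  put_int(4L + 80L); put_int(1L)
  writeChar(title, con, nchars = 80, eos = NULL)
  put_int(4L + 80L)
  # natom block
  put_int(4L); put_int(natom); put_int(4L)
  ix <- seq(1L, 3L * natom, by = 3L)
  for (f in seq_len(nframes)) {
    for (off in 0:2) {
      put_int(4L * natom)
      put_f(xyz[f, ix + off])
      put_int(4L * natom)
    }
  }
  invisible(path)
}

#' Write a topology / trajectory as (multi-model) PDB
#'
#' @param traj a [coord_traj()].
#' @param path output file.
#' @param frames frame indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_pdb_traj <- function(traj, path, frames = seq_len(nrow(traj$xyz))) {
  stopifnot(inherits(traj, "coord_traj"))
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  chain <- if ("chain" %in% names(a) && !all(is.na(a$chain))) a$chain else
    rep("A", nrow(a))
  for (f in frames) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$xyz[f, ] * 10    # nm -> angstrom
    for (i in seq_len(nrow(a))) {
      writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                         i, a$elety[i], a$resid[i], chain[i], a$resno[i],
                         xyz[3 * i - 2], xyz[3 * i - 1], xyz[3 * i]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
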