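#' Time-ordered feature table with segment boundaries
#'
#' The container consumed by [sfa()].  `values` is a numeric T x J matrix
#' (frames by features), `segments` gives the 1-based row index at which
#' each independent trajectory starts (first always 1), and `dt_ps` is
#' the frame spacing in picoseconds.  Segment boundaries matter because
#' finite differences are never taken across them: concatenated
#' trajectories are independent realizations, and a difference spanning
#' the join would inject a spurious fast signal.
#'
#' @param values numeric matrix, frames in rows, features in columns.
#' @param names feature labels; defaults to `colnames(values)`.
#' @param segments integer vector of segment start rows (1-based,
#'   strictly increasing, first element 1).
#' @param dt_ps frame spacing in ps (> 0).
#' @return an object of class `feature_series`.
#' @export
feature_series <- function(values, names = colnames(values),
                           segments = 1L, dt_ps = 1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(names)) names <- paste0("f", seq_len(ncol(values)))
  names <- as.character(names)
  if (length(names) != ncol(values))
    stop("need one name per feature column")
  if (anyDuplicated(names)) stop("feature names must be unique")
  if (ncol(values) < 1L) stop("at least one feature is required")
  if (anyNA(values)) stop("feature values must not contain missing values")
  segments <- check_segments(segments, nrow(values), min_len = 2L)
  if (!is.numeric(dt_ps) || length(dt_ps) != 1L || dt_ps <= 0)
    stop("dt_ps must be a single positive number")
  colnames(values) <- names
  structure(list(values = values, segments = segments, dt_ps = dt_ps),
            class = "feature_series")
}

check_segments <- function(segments, n, min_len = 1L) {
  segments <- as.integer(segments)
  if (length(segments) < 1L || segments[1] != 1L)
    stop("segment starts must begin at 1")
  if (any(diff(segments) <= 0L)) stop("segment starts must be strictly increasing")
  if (any(segments > n)) stop("segment start beyond last frame")
  len <- diff(c(segments, n + 1L))
  if (any(len < min_len))
    stop(sprintf("every segment needs at least %d frames", min_len))
  segments
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("feature_series: %d frames x %d features, %d segment(s), dt = %g ps\n",
              nrow(x$values), ncol(x$values), length(x$segments), x$dt_ps))
  cat("  features:", paste(head(colnames(x$values), 6), collapse = ", "),
      if (ncol(x$values) > 6) "..." else "", "\n")
  invisible(x)
}

#' Dihedral-angle time series
#'
#' Angles in radians in (-pi, pi], one column per torsion.  `atoms` may
#' carry the 1-based atom serials of each torsion's defining quadruple
#' (a 4-column matrix with one row per torsion); it is carried through
#' [sincos_expand()] so that slow features can later be exported as
#' PLUMED `TORSION` actions.
#'
#' @param values numeric T x D matrix of angles (radians).
#' @param labels torsion labels, e.g. `"chi1_TRP41"`.
#' @param segments segment start rows as in [feature_series()].
#' @param dt_ps frame spacing in ps.
#' @param atoms optional D x 4 matrix of atom serials.
#' @return an object of class `dihedral_series`.
#' @export
dihedral_series <- function(values, labels = colnames(values),
                            segments = 1L, dt_ps = 1, atoms = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(labels)) stop("torsion labels are required")
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) stop("need one label per torsion")
  if (anyDuplicated(labels)) stop("torsion labels must be unique")
  if (anyNA(values)) stop("angles must not contain missing values")
  if (any(values <= -pi - 1e-12) || any(values > pi + 1e-12))
    stop("angles must lie in (-pi, pi]")
  segments <- check_segments(segments, nrow(values))
  if (!is.null(atoms)) {
    atoms <- as.matrix(atoms)
    if (nrow(atoms) != ncol(values) || ncol(atoms) != 4L)
      stop("atoms must be a D x 4 matrix of serials")
    rownames(atoms) <- labels
  }
  colnames(values) <- labels
  structure(list(values = values, segments = segments, dt_ps = dt_ps,
                 atoms = atoms),
            class = "dihedral_series")
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf("dihedral_series: %d frames x %d torsions, %d segment(s)\n",
              nrow(x$values), ncol(x$values), length(x$segments)))
  invisible(x)
}

#' Signed dihedral angle from four points
#'
#' IUPAC convention: the angle between the plane through (p1, p2, p3)
#' and the plane through (p2, p3, p4), measured looking from p2 towards
#' p3, clockwise positive; cis = 0, range (-pi, pi].  Computed from the
#' two plane normals with a two-argument arctangent, so it is exact for
#' planar inputs and invariant under rigid motion.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors or n x 3 matrices (one row per
#'   frame).
#' @return numeric vector of angles in radians.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  m1 <- cross(n1, n2)
  b2n <- b2 / sqrt(rowSums(b2^2))
  y <- rowSums(m1 * b2n)
  x <- rowSums(n1 * n2)
  ang <- atan2(y, x)
  ang[ang <= -pi] <- ang[ang <= -pi] + 2 * pi   # closed at +pi, open at -pi
  ang
}

# chi1: N-CA-CB-<G>; chi2: CA-CB-<G>-<D>, with the conventional
# heavy-atom choice per residue type.
.CHI1_G <- c(ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG",
             GLU = "CG", HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG",
             MET = "CG", PHE = "CG", PRO = "CG", SER = "OG", THR = "OG1",
             TRP = "CG", TYR = "CG", VAL = "CG1")
.CHI2_GD <- list(ARG = c("CG", "CD"),  GLN = c("CG", "CD"),
                 GLU = c("CG", "CD"),  LYS = c("CG", "CD"),
                 PRO = c("CG", "CD"),  ILE = c("CG1", "CD1"),
                 LEU = c("CG", "CD1"), PHE = c("CG", "CD1"),
                 TRP = c("CG", "CD1"), TYR = c("CG", "CD1"),
                 ASP = c("CG", "OD1"), ASN = c("CG", "OD1"),
                 HIS = c("CG", "ND1"), MET = c("CG", "SD"))

torsion_quadruple <- function(atoms, resno, kind) {
  res <- atoms[atoms$resno == resno, , drop = FALSE]
  if (nrow(res) == 0L)
    stop(sprintf("residue %d not found in topology", resno))
  resname <- res$resid[1]
  find_atom <- function(name, rn = resno) {
    hit <- which(atoms$resno == rn & atoms$elety == name)
    if (length(hit) == 0L)
      stop(sprintf("%s of %s%d: atom %s missing (angle undefined for this residue)",
                   kind, resname, resno, name))
    hit[1]
  }
  switch(kind,
    chi1 = {
      g <- .CHI1_G[resname]
      if (is.na(g))
        stop(sprintf("chi1 of %s%d: residue type has no chi1 angle", resname, resno))
      c(find_atom("N"), find_atom("CA"), find_atom("CB"), find_atom(g))
    },
    chi2 = {
      gd <- .CHI2_GD[[resname]]
      if (is.null(gd))
        stop(sprintf("chi2 of %s%d: residue type has no chi2 angle", resname, resno))
      c(find_atom("CA"), find_atom("CB"), find_atom(gd[1]), find_atom(gd[2]))
    },
    phi = c(find_atom("C", resno - 1L), find_atom("N"), find_atom("CA"),
            find_atom("C")),
    psi = c(find_atom("N"), find_atom("CA"), find_atom("C"),
            find_atom("N", resno + 1L)),
    stop(sprintf("unknown angle kind '%s'", kind)))
}

#' Compute selected dihedral angles from a trajectory
#'
#' @param traj a [coord_traj] object from [read_trajectory()].
#' @param selection data frame with columns `resno` and `kind`
#'   (kind in `chi1`, `chi2`, `phi`, `psi`); see [dihedral_selection()].
#' @return a [dihedral_series()] with one column per selection entry,
#'   labelled `<kind>_<RESNAME><resno>`, and the atom quadruples attached.
#'   A residue lacking the atoms for a requested angle raises an error
#'   naming the selection; nothing is skipped silently.
#' @export
compute_dihedrals <- function(traj, selection) {
  stopifnot(inherits(traj, "coord_traj"))
  selection <- as.data.frame(selection)
  if (!all(c("resno", "kind") %in% names(selection)))
    stop("selection needs columns 'resno' and 'kind'")
  atoms <- traj$atoms
  nsel <- nrow(selection)
  quad <- matrix(0L, nsel, 4)
  labels <- character(nsel)
  for (i in seq_len(nsel)) {
    rn <- selection$resno[i]; kd <- as.character(selection$kind[i])
    quad[i, ] <- torsion_quadruple(atoms, rn, kd)
    labels[i] <- sprintf("%s_%s%d", kd, atoms$resid[atoms$resno == rn][1], rn)
  }
  xyz <- traj$xyz
  vals <- matrix(0, nrow(xyz), nsel)
  at_xyz <- function(j) xyz[, c(3 * j - 2, 3 * j - 1, 3 * j), drop = FALSE]
  for (i in seq_len(nsel)) {
    q <- quad[i, ]
    vals[, i] <- dihedral_angle(at_xyz(q[1]), at_xyz(q[2]),
                                at_xyz(q[3]), at_xyz(q[4]))
  }
  dihedral_series(vals, labels = labels, segments = traj$segments,
                  dt_ps = traj$dt_ps, atoms = quad)
}

#' Build a dihedral selection table
#'
#' @param resno residue numbers.
#' @param kind angle kinds, recycled against `resno`.
#' @return data frame usable as the `selection` of [compute_dihedrals()].
#' @export
dihedral_selection <- function(resno, kind) {
  data.frame(resno = as.integer(resno), kind = as.character(kind))
}

#' Expand dihedrals into periodic sin/cos features
#'
#' Each angle column produces two features `sin_<label>`, `cos_<label>`,
#' interleaved per angle, so that periodicity is removed before SFA.
#'
#' @param d a [dihedral_series()].
#' @return a [feature_series()] with J = 2 D columns; segment starts,
#'   frame spacing and (when present) the torsion atom table are carried
#'   over as the attribute `torsion_atoms`.
#' @export
sincos_expand <- function(d) {
  stopifnot(inherits(d, "dihedral_series"))
  v <- d$values
  D <- ncol(v)
  out <- matrix(0, nrow(v), 2L * D)
  nm <- character(2L * D)
  for (j in seq_len(D)) {
    out[, 2L * j - 1L] <- sin(v[, j])
    out[, 2L * j] <- cos(v[, j])
    nm[2L * j - 1L] <- paste0("sin_", colnames(v)[j])
    nm[2L * j] <- paste0("cos_", colnames(v)[j])
  }
  fs <- feature_series(out, names = nm, segments = d$segments, dt_ps = d$dt_ps)
  if (!is.null(d$atoms)) attr(fs, "torsion_atoms") <- d$atoms
  fs
}

#' Concatenate independent feature series
#'
#' Rows are stacked in argument order and every original trajectory
#' start is recorded as a segment boundary, so later finite differences
#' never straddle a join.
#'
#' @param ... `feature_series` objects with identical feature names and
#'   frame spacing.
#' @return one `feature_series`.
#' @export
concat_segments <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "feature_series")) parts <- parts[[1]]
  stopifnot(length(parts) >= 1L)
  for (p in parts) stopifnot(inherits(p, "feature_series"))
  nm <- colnames(parts[[1]]$values)
  dt <- parts[[1]]$dt_ps
  for (p in parts[-1]) {
    if (!identical(colnames(p$values), nm))
      stop("feature names differ between series")
    if (!isTRUE(all.equal(p$dt_ps, dt)))
      stop("frame spacing differs between series")
  }
  values <- do.call(rbind, lapply(parts, function(p) p$values))
  offs <- cumsum(c(0L, vapply(parts, function(p) nrow(p$values), 0L)))
  segments <- unlist(lapply(seq_along(parts), function(i)
    parts[[i]]$segments + offs[i]))
  fs <- feature_series(values, names = nm, segments = segments, dt_ps = dt)
  ta <- attr(parts[[1]], "torsion_atoms")
  if (!is.null(ta)) attr(fs, "torsion_atoms") <- ta
  fs
}

#' Write / read a feature series as self-describing TSV
#'
#' Plain tab-separated text: comment header lines carry the frame
#' spacing and the 1-based segment starts, then a header row of feature
#' names and one row per frame at full double precision.
#'
#' @param x a `feature_series`.
#' @param path output file.
#' @return `write_feature_series` returns `path` invisibly;
#'   `read_feature_series` returns a `feature_series`.
#' @export
write_feature_series <- function(x, path) {
  stopifnot(inherits(x, "feature_series"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("# slowcv feature_series v1",
           paste("# dt_ps", fmt_full(x$dt_ps)),
           paste("# segments", paste(x$segments, collapse = " ")))
  ta <- attr(x, "torsion_atoms")
  if (!is.null(ta))
    hdr <- c(hdr, sprintf("# torsion %s %s", rownames(ta),
                          apply(ta, 1L, paste, collapse = " ")))
  writeLines(c(hdr, paste(colnames(x$values), collapse = "\t")), con)
  body <- apply(x$values, 1L, function(r) paste(fmt_full(r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_feature_series
#' @export
read_feature_series <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L || !startsWith(lines[1], "# slowcv feature_series"))
    stop("not a slowcv feature_series file")
  nhdr <- which(!startsWith(lines, "# "))[1] - 1L
  hdr <- lines[seq_len(nhdr)]
  grab <- function(key) grep(paste0("^# ", key, " "), hdr, value = TRUE)
  dt <- as.numeric(sub("^# dt_ps ", "", grab("dt_ps")))
  segments <- as.integer(strsplit(sub("^# segments ", "",
                                      grab("segments")), " ")[[1]])
  nm <- strsplit(lines[nhdr + 1L], "\t", fixed = TRUE)[[1]]
  dat <- utils::read.table(text = lines[-seq_len(nhdr + 1L)], sep = "\t",
                           colClasses = "numeric")
  fs <- feature_series(as.matrix(dat), names = nm, segments = segments,
                       dt_ps = dt)
  tor <- grab("torsion")
  if (length(tor) > 0) {
    parts <- strsplit(sub("^# torsion ", "", tor), " ")
    ta <- do.call(rbind, lapply(parts, function(p) as.integer(p[-1])))
    rownames(ta) <- vapply(parts, `[`, "", 1L)
    attr(fs, "torsion_atoms") <- ta
  }
  fs
}
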