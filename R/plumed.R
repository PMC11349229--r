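#' Flatten slow features to explicit affine collective variables
#'
#' A fitted order-1 model on sin/cos torsion features is an affine map
#' of the base features; this folds the input means/scales, the
#' expansion mean and the sphering matrix of each requested component
#' into a constant offset plus one coefficient per `sin_<torsion>` /
#' `cos_<torsion>` feature, ready for bit-exact PLUMED emission.
#'
#' @param model an order-1 `sfa_model` whose feature names all parse as
#'   `sin_<torsion>` or `cos_<torsion>`.
#' @param components component indices to export.
#' @param prefix CV name prefix; names are `<prefix>1`, `<prefix>2`, ...
#' @return list of `cv_spec` objects (name, offset, term table with
#'   columns `feature`, `kind`, `torsion`, `coef`).
#' @export
cv_from_model <- function(model, components = 1:2, prefix = "SF") {
  stopifnot(inherits(model, "sfa_model"))
  if (model$order != 1L)
    stop("PLUMED export supports order-1 (linear) models only")
  parsed <- regmatches(model$names,
                       regexec("^(sin|cos)_(.+)$", model$names))
  bad <- vapply(parsed, length, 0L) != 3L
  if (any(bad))
    stop(sprintf("non-torsion feature(s) cannot be exported: %s",
                 paste(model$names[bad], collapse = ", ")))
  kind <- vapply(parsed, `[`, "", 2L)
  torsion <- vapply(parsed, `[`, "", 3L)
  lapply(seq_along(components), function(i) {
    k <- components[i]
    af <- affine_form(model, k)
    if (all(af$coef == 0)) stop("slow feature has an all-zero weight vector")
    structure(list(name = paste0(prefix, k),
                   offset = af$offset,
                   terms = data.frame(feature = model$names, kind = kind,
                                      torsion = torsion,
                                      coef = unname(af$coef),
                                      stringsAsFactors = FALSE)),
              class = "cv_spec")
  })
}

#' @export
print.cv_spec <- function(x, ...) {
  cat(sprintf("cv_spec %s: offset %.6g + %d sin/cos torsion terms\n",
              x$name, x$offset, nrow(x$terms)))
  invisible(x)
}

#' Evaluate a CV specification on feature data
#'
#' @param cv a `cv_spec`.
#' @param x a [feature_series()] holding the base sin/cos features.
#' @return numeric vector, one value per frame.
#' @export
evaluate_cv <- function(cv, x) {
  stopifnot(inherits(cv, "cv_spec"), inherits(x, "feature_series"))
  missing <- setdiff(cv$terms$feature, colnames(x$values))
  if (length(missing) > 0)
    stop(sprintf("missing feature(s): %s", paste(missing, collapse = ", ")))
  drop(x$values[, cv$terms$feature, drop = FALSE] %*% cv$terms$coef) + cv$offset
}

#' Gaussian width heuristic for metadynamics
#'
#' One third of the population standard deviation of each slow feature
#' over the first `n_frames` frames of the (unbiased) training data.
#'
#' @param y a `slow_feature_series` or numeric matrix.
#' @param n_frames number of leading frames to use (default 10000).
#' @return numeric vector of per-CV Gaussian widths.
#' @export
gaussian_width_heuristic <- function(y, n_frames = 10000L) {
  if (inherits(y, "slow_feature_series")) y <- y$values
  y <- as.matrix(y)
  if (nrow(y) == 0L) stop("empty slow-feature series")
  n <- min(n_frames, nrow(y))
  if (nrow(y) < n_frames)
    warning(sprintf("only %d frames available (< %d); using all of them",
                    nrow(y), n_frames))
  head_y <- y[seq_len(n), , drop = FALSE]
  mu <- colMeans(head_y)
  sqrt(colMeans(sweep(head_y, 2, mu, "-")^2)) / 3
}

#' Well-tempered metadynamics parameters
#'
#' Defaults follow the standard protein parameterization: Gaussians of
#' height 1.5 kJ/mol deposited every 500 steps, bias factor 20, 300 K.
#'
#' @param height Gaussian height, kJ/mol (> 0).
#' @param pace deposition pace in MD steps (>= 1).
#' @param biasfactor well-tempered bias factor gamma (> 1).
#' @param widths per-CV Gaussian widths (> 0).
#' @param temp temperature in kelvin.
#' @return an object of class `metad_params`.
#' @export
metad_params <- function(height = 1.5, pace = 500L, biasfactor = 20,
                         widths, temp = 300) {
  stopifnot(height > 0, pace >= 1, biasfactor > 1, all(widths > 0), temp > 0)
  structure(list(height = height, pace = as.integer(pace),
                 biasfactor = biasfactor, widths = widths, temp = temp),
            class = "metad_params")
}

#' Funnel restraint parameters
#'
#' Funnel geometry for ligand-binding metadynamics: a cone of
#' half-angle `alpha` up to `zcc` along the binding axis, continuing as
#' a cylinder of radius `rcyl`, enforced by a harmonic upper wall of
#' spring constant `kappa` on the radial excess.  Defaults are the
#' common protein-ligand choice: zcc = 2.0 nm, rcyl = 0.1 nm,
#' alpha = 0.5 rad, kappa = 50000 kJ/mol/nm^2.
#'
#' @param zcc cone-cylinder switch distance (nm).
#' @param rcyl cylinder radius (nm).
#' @param alpha cone half-angle (rad).
#' @param kappa wall spring constant (kJ/mol/nm^2).
#' @param lig_atoms atom serials of the ligand (funnel-tip group COM).
#' @param anchor_atoms atom serials of the anchor group (e.g. catalytic
#'   dyad COM) defining the funnel origin.
#' @return an object of class `funnel_spec`.
#' @export
funnel_spec <- function(zcc = 2.0, rcyl = 0.1, alpha = 0.5, kappa = 50000,
                        lig_atoms, anchor_atoms) {
  stopifnot(zcc > 0, rcyl > 0, alpha > 0, kappa > 0,
            length(lig_atoms) >= 1, length(anchor_atoms) >= 1)
  structure(list(zcc = zcc, rcyl = rcyl, alpha = alpha, kappa = kappa,
                 lig_atoms = as.integer(lig_atoms),
                 anchor_atoms = as.integer(anchor_atoms)),
            class = "funnel_spec")
}

#' Emit a PLUMED 2.x input file for well-tempered metadynamics
#'
#' Writes one `TORSION` action per unique torsion (1-based atom
#' serials), `MATHEVAL` sin/cos helpers, one affine `MATHEVAL` action
#' per CV (`PERIODIC=NO`; sin/cos inputs make the combination aperiodic
#' by construction), a `METAD` action with HEIGHT/PACE/BIASFACTOR/
#' SIGMA/TEMP, a `PRINT` of CVs plus bias to COLVAR and, when a funnel
#' is given, a cone-plus-cylinder radial upper wall along the
#' anchor-ligand axis.  Output is byte-stable for identical inputs
#' (fixed 9-significant-digit formatting, no timestamps).
#'
#' @param cvs list of `cv_spec` objects from [cv_from_model()].
#' @param params a [metad_params()]; one width per CV.
#' @param torsion_atoms D x 4 matrix of 1-based atom serials with
#'   torsion labels as row names (as produced by [compute_dihedrals()]
#'   and carried on the model), covering every torsion used by the CVs.
#' @param funnel optional [funnel_spec()].
#' @param path output file, or `NULL` to only return the text.
#' @return the emitted text as a character vector of lines (invisibly
#'   when `path` is given).
#' @export
write_plumed_metad <- function(cvs, params, torsion_atoms, funnel = NULL,
                               path = NULL) {
  stopifnot(is.list(cvs), inherits(params, "metad_params"))
  for (cv in cvs) stopifnot(inherits(cv, "cv_spec"))
  cv_names <- vapply(cvs, function(cv) cv$name, "")
  if (anyDuplicated(cv_names)) stop("duplicate CV names")
  if (length(params$widths) != length(cvs))
    stop("need exactly one Gaussian width per CV")
  torsions <- unique(unlist(lapply(cvs, function(cv) cv$terms$torsion)))
  torsion_atoms <- as.matrix(torsion_atoms)
  missing <- setdiff(torsions, rownames(torsion_atoms))
  if (length(missing) > 0)
    stop(sprintf("no atom quadruple for torsion(s): %s",
                 paste(missing, collapse = ", ")))

  out <- c("# PLUMED input generated by slowcv",
           "# units: nm, kJ/mol, ps, rad", "")
  for (tor in torsions)
    out <- c(out, sprintf("t_%s: TORSION ATOMS=%s", tor,
                          paste(torsion_atoms[tor, ], collapse = ",")))
  out <- c(out, "")
  for (tor in torsions) {
    out <- c(out,
             sprintf("sin_%s: MATHEVAL ARG=t_%s FUNC=sin(x) PERIODIC=NO", tor, tor),
             sprintf("cos_%s: MATHEVAL ARG=t_%s FUNC=cos(x) PERIODIC=NO", tor, tor))
  }
  out <- c(out, "")
  for (cv in cvs) {
    n <- nrow(cv$terms)
    vars <- paste0("v", seq_len(n))
    co <- cv$terms$coef
    piece <- paste0(ifelse(co < 0, "-", "+"), fmt_num(abs(co)), "*", vars)
    piece[1] <- sub("^\\+", "", piece[1])
    func <- paste0(paste(piece, collapse = ""),
                   ifelse(cv$offset < 0, "-", "+"), fmt_num(abs(cv$offset)))
    out <- c(out, sprintf("%s: MATHEVAL ARG=%s VAR=%s FUNC=%s PERIODIC=NO",
                          cv$name, paste(cv$terms$feature, collapse = ","),
                          paste(vars, collapse = ","), func))
  }
  out <- c(out, "")
  if (!is.null(funnel)) {
    stopifnot(inherits(funnel, "funnel_spec"))
    out <- c(out,
      sprintf("lig: COM ATOMS=%s", paste(funnel$lig_atoms, collapse = ",")),
      sprintf("anchor: COM ATOMS=%s", paste(funnel$anchor_atoms, collapse = ",")),
      "fv: DISTANCE ATOMS=anchor,lig COMPONENTS NOPBC",
      "fz: MATHEVAL ARG=fv.z FUNC=x PERIODIC=NO",
      "frho: MATHEVAL ARG=fv.x,fv.y FUNC=sqrt(x*x+y*y) PERIODIC=NO",
      # radius profile R(z) = rcyl + (zcc - z) tan(alpha) in the cone,
      # rcyl in the cylinder (z > zcc); wall acts on rho - R(z)
      sprintf("fexcess: MATHEVAL ARG=fz,frho VAR=z,r FUNC=r-(%s+step(%s-z)*(%s-z)*%s) PERIODIC=NO",
              fmt_num(funnel$rcyl), fmt_num(funnel$zcc), fmt_num(funnel$zcc),
              fmt_num(tan(funnel$alpha))),
      sprintf("# funnel: ZCC=%s RCYL=%s ALPHA=%s", fmt_num(funnel$zcc),
              fmt_num(funnel$rcyl), fmt_num(funnel$alpha)),
      sprintf("funnel_wall: UPPER_WALLS ARG=fexcess AT=0.0 KAPPA=%s EXP=2 EPS=1 OFFSET=0",
              fmt_num(funnel$kappa)),
      "")
  }
  out <- c(out,
    sprintf("metad: METAD ARG=%s SIGMA=%s HEIGHT=%s PACE=%d BIASFACTOR=%s TEMP=%s FILE=HILLS",
            paste(cv_names, collapse = ","),
            paste(fmt_num(params$widths), collapse = ","),
            fmt_num(params$height), params$pace,
            fmt_num(params$biasfactor), fmt_num(params$temp)),
    "",
    sprintf("PRINT ARG=%s,metad.bias STRIDE=%d FILE=COLVAR",
            paste(cv_names, collapse = ","), params$pace))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

parse_plumed_header <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop(sprintf("'%s' is empty", path))
  if (!startsWith(lines[1], "#! FIELDS"))
    stop(sprintf("'%s' does not start with a '#! FIELDS' header", path))
  fields <- strsplit(trimws(sub("^#! FIELDS", "", lines[1])), "\\s+")[[1]]
  data_lines <- lines[!startsWith(lines, "#")]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) > 0) {
    nf <- lengths(strsplit(trimws(data_lines), "\\s+"))
    if (any(nf != length(fields)))
      stop(sprintf("'%s' has ragged rows (header has %d fields)", path,
                   length(fields)))
  }
  tab <- if (length(data_lines) == 0L) {
    as.data.frame(setNames(rep(list(numeric(0)), length(fields)), fields))
  } else {
    d <- utils::read.table(text = data_lines, col.names = fields,
                           check.names = FALSE)
    names(d) <- fields
    d
  }
  tab
}

#' Read a PLUMED HILLS file
#'
#' Columns are bound by the `#! FIELDS` header names: `time`, one
#' center column per CV, `sigma_<cv>` widths, `height`, and `biasf`
#' when the run was well-tempered.
#'
#' @param path HILLS file.
#' @return data frame of hill records, one per deposited Gaussian, with
#'   attribute `cv_names`.
#' @export
read_hills <- function(path) {
  tab <- parse_plumed_header(path)
  fields <- names(tab)
  if (!"time" %in% fields) stop("HILLS header lacks a 'time' column")
  if (!"height" %in% fields) stop("HILLS header lacks a 'height' column")
  sigma_cols <- grep("^sigma_", fields, value = TRUE)
  cv_names <- sub("^sigma_", "", sigma_cols)
  if (length(cv_names) == 0L) stop("HILLS header lacks sigma_<cv> columns")
  if (!all(cv_names %in% fields))
    stop("HILLS sigma columns do not match any CV center column")
  attr(tab, "cv_names") <- cv_names
  class(tab) <- c("hills", class(tab))
  tab
}

#' Read a PLUMED COLVAR file
#'
#' Columns are bound by the `#! FIELDS` header names.  Rows are
#' time-sorted and duplicate-time restart artifacts are removed keeping
#' the last occurrence.  A header-only file yields an empty table.
#'
#' @param path COLVAR file.
#' @return data frame with a `time` column and the CV/bias columns.
#' @export
read_colvar <- function(path) {
  tab <- parse_plumed_header(path)
  if (!"time" %in% names(tab)) stop("COLVAR header lacks a 'time' column")
  if (nrow(tab) > 0) {
    tab <- tab[!duplicated(tab$time, fromLast = TRUE), , drop = FALSE]
    tab <- tab[order(tab$time), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Write HILLS / COLVAR files in the PLUMED dialect
#'
#' Used by the toy metadynamics engine; the emitted files round-trip
#' through [read_hills()] / [read_colvar()].
#'
#' @param hills data frame with `time`, CV centers, `sigma_<cv>`,
#'   `height` and optionally `biasf` columns.
#' @param colvar data frame with `time`, CV and bias columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  write_plumed_table(as.data.frame(hills), path)
}

#' @rdname write_hills
#' @export
write_colvar <- function(colvar, path) {
  write_plumed_table(as.data.frame(colvar), path)
}

write_plumed_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(tab), collapse = " ")), con)
  if (nrow(tab) > 0) {
    body <- do.call(paste, c(lapply(tab, fmt_num), list(sep = " ")))
    writeLines(body, con)
  }
  invisible(path)
}
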