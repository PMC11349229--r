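resolve_kT <- function(temp, kT) {
  if (!is.null(kT)) return(kT)
  kT_kjmol(temp)
}

hills_matrices <- function(hills) {
  cv_names <- attr(hills, "cv_names")
  if (is.null(cv_names)) {
    sigma_cols <- grep("^sigma_", names(hills), value = TRUE)
    cv_names <- sub("^sigma_", "", sigma_cols)
  }
  if (length(cv_names) == 0L) stop("hills carry no CV columns")
  list(cv_names = cv_names,
       centers = as.matrix(hills[, cv_names, drop = FALSE]),
       sigmas = as.matrix(hills[, paste0("sigma_", cv_names), drop = FALSE]),
       heights = hills$height,
       times = hills$time)
}

# effective deposited heights under the chosen HILLS convention.
# "raw": heights in the file are the actual (already tempered) deposited
# heights — the convention of this package's toy engine.  "scaled":
# heights were rescaled by gamma/(gamma-1) on output (as PLUMED does for
# well-tempered runs) and are multiplied back by (gamma-1)/gamma.
effective_heights <- function(h, heights = c("raw", "scaled"), biasfactor = NULL) {
  heights <- match.arg(heights)
  if (heights == "raw") return(h$heights)
  gamma <- biasfactor
  if (is.null(gamma)) stop("heights = 'scaled' needs a bias factor")
  h$heights * (gamma - 1) / gamma
}

#' Metadynamics bias energy at a point
#'
#' Sum over all hills deposited strictly before time `t` of
#' `height_i * exp(-sum_d (s_d - center_id)^2 / (2 sigma_id^2))`.
#'
#' @param hills hill records from [read_hills()] or [wt_metad()].
#' @param point CV values (vector of the hills' CV dimension, or a
#'   matrix with one row per evaluation point).
#' @param t evaluation time; `Inf` (default) uses all hills.
#' @param heights `"raw"` when the file stores actual deposited heights
#'   (the toy-engine convention), `"scaled"` when they were rescaled by
#'   gamma/(gamma-1) as PLUMED does for well-tempered runs.  This is
#'   the single most dangerous silent-corruption point of metadynamics
#'   post-processing, hence an explicit flag.
#' @param biasfactor bias factor, needed for `heights = "scaled"`.
#' @return bias energy (kJ/mol), one value per evaluation point.
#' @export
bias_at <- function(hills, point, t = Inf, heights = "raw",
                    biasfactor = NULL) {
  h <- hills_matrices(hills)
  pts <- if (is.matrix(point)) point else matrix(point, nrow = 1)
  if (ncol(pts) != length(h$cv_names))
    stop(sprintf("point has %d dimensions but hills have %d CVs",
                 ncol(pts), length(h$cv_names)))
  eff <- effective_heights(h, heights, biasfactor)
  act <- h$times < t
  if (!any(act)) return(rep(0, nrow(pts)))
  centers <- h$centers[act, , drop = FALSE]
  sigmas <- h$sigmas[act, , drop = FALSE]
  eff <- eff[act]
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    ex <- 0
    for (d in seq_len(ncol(pts)))
      ex <- ex + (pts[i, d] - centers[, d])^2 / (2 * sigmas[, d]^2)
    out[i] <- sum(eff * exp(-ex))
  }
  out
}

# regular grid of cell centers covering the sampled CV range padded by
# pad_mult * max width in each dimension
default_rct_grid <- function(h, nbins, pad_mult) {
  lapply(seq_along(h$cv_names), function(d) {
    pad <- pad_mult * max(h$sigmas[, d])
    lo <- min(h$centers[, d]) - pad
    hi <- max(h$centers[, d]) + pad
    seq(lo, hi, length.out = nbins)
  })
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Tiwary-Parrinello reweighting factor c(t)
#'
#' At each hill-deposition time the accumulated bias V(s, t) on a CV
#' grid gives
#' `c(t) = (1/beta) ln [ sum exp(beta*gamma/(gamma-1) V) / sum exp(beta/(gamma-1) V) ]`.
#' For a converging well-tempered run c(t) is non-decreasing and
#' reaches an asymptotic plateau.  The bias is accumulated
#' incrementally on the grid, one Gaussian per deposition.
#'
#' @inheritParams bias_at
#' @param biasfactor well-tempered bias factor gamma (> 1); taken from
#'   the hills' `biasf` column when absent.
#' @param temp temperature in kelvin (kT via the molar gas constant).
#' @param kT thermal energy override in the energy units of the hills;
#'   set `kT = 1` for reduced-unit toy data.
#' @param nbins grid points per CV dimension.
#' @param pad_mult grid padding in units of the largest hill width.
#' @param grid optional list of grid-point vectors, one per CV.
#' @return data frame of class `rct_series` with columns `time` and
#'   `rct`; the series starts at c(0) = 0 and has one row per
#'   deposition.
#' @export
compute_rct <- function(hills, biasfactor = NULL, temp = 300, kT = NULL,
                        nbins = 100L, pad_mult = 3, grid = NULL,
                        heights = "raw") {
  h <- hills_matrices(hills)
  if (length(h$times) == 0L) stop("no hills to reweight")
  if (is.null(biasfactor)) {
    if (!"biasf" %in% names(hills))
      stop("bias factor not given and hills carry no 'biasf' column")
    biasfactor <- hills$biasf[1]
  }
  stopifnot(biasfactor > 1)
  kT <- resolve_kT(temp, kT)
  beta <- 1 / kT
  if (is.null(grid)) grid <- default_rct_grid(h, nbins, pad_mult)
  pts <- as.matrix(expand.grid(grid))
  eff <- effective_heights(h, heights, biasfactor)

  n <- length(h$times)
  V <- numeric(nrow(pts))
  rct <- numeric(n)
  f1 <- beta * biasfactor / (biasfactor - 1)
  f2 <- beta / (biasfactor - 1)
  for (i in seq_len(n)) {
    ex <- 0
    for (d in seq_len(ncol(pts)))
      ex <- ex + (pts[, d] - h$centers[i, d])^2 / (2 * h$sigmas[i, d]^2)
    V <- V + eff[i] * exp(-ex)
    rct[i] <- (logsumexp(f1 * V) - logsumexp(f2 * V)) / beta
  }
  out <- data.frame(time = c(0, h$times), rct = c(0, rct))
  class(out) <- c("rct_series", class(out))
  out
}

#' Unbiased frame weights from a biased run
#'
#' `weight_t` is proportional to `exp(beta * (V(s_t, t) - c(t)))` with
#' V the instantaneous bias recorded in the COLVAR table and c(t) the
#' reweighting factor, interpolated stepwise-constant
#' (right-continuous) between depositions — the bias only changes at
#' depositions.  Frames before the first deposition use c = 0.
#'
#' @param colvar COLVAR table from [read_colvar()] or [wt_metad()].
#' @param rct an `rct_series` from [compute_rct()].
#' @param temp temperature in kelvin.
#' @param kT thermal energy override (reduced units: `kT = 1`).
#' @param bias_col name of the bias column; by default the single
#'   column whose name contains "bias".
#' @return numeric weights summing to 1, one per COLVAR row.
#' @export
frame_weights <- function(colvar, rct, temp = 300, kT = NULL,
                          bias_col = NULL) {
  colvar <- as.data.frame(colvar)
  if (is.null(bias_col)) {
    cand <- grep("bias", names(colvar), value = TRUE)
    if (length(cand) != 1L)
      stop("cannot identify the bias column; pass bias_col explicitly")
    bias_col <- cand
  }
  if (!bias_col %in% names(colvar))
    stop(sprintf("COLVAR has no bias column '%s'", bias_col))
  kT <- resolve_kT(temp, kT)
  idx <- findInterval(colvar$time, rct$time)
  ct <- ifelse(idx >= 1L, rct$rct[pmax(idx, 1L)], 0)
  logw <- (colvar[[bias_col]] - ct) / kT
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' Project weighted samples onto a free-energy surface
#'
#' `F(bin) = -kT ln(sum of weights in bin)`, shifted so the minimum
#' over occupied bins is zero.  Empty bins carry an explicit `empty`
#' flag (and `NA` free energy) rather than an arbitrary cap.
#'
#' @param obs numeric vector (1-D) or 2-column matrix/data frame (2-D)
#'   of observable values, one row per frame.
#' @param weights normalized frame weights (uniform when `NULL`).
#' @param bins bins per dimension (scalar or length-2).
#' @param range optional list of c(lo, hi) per dimension; defaults to
#'   the sampled range.
#' @param temp temperature in kelvin.
#' @param kT thermal energy override (reduced units: `kT = 1`).
#' @return an object of class `fes_grid`: bin `edges` and `mids` per
#'   dimension, free energy `F` (vector or matrix, kJ/mol or kT units),
#'   logical `empty` flags, and `kT`.
#' @export
project_fes <- function(obs, weights = NULL, bins = 100L, range = NULL,
                        temp = 300, kT = NULL) {
  obs <- if (is.null(dim(obs))) matrix(obs, ncol = 1) else as.matrix(obs)
  ndim <- ncol(obs)
  if (!ndim %in% c(1L, 2L)) stop("only 1-D and 2-D projections are supported")
  n <- nrow(obs)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("one weight per observation row is required")
  if (sum(weights) <= 0) stop("total weight must be positive")
  weights <- weights / sum(weights)
  kT <- resolve_kT(temp, kT)
  bins <- rep(as.integer(bins), length.out = ndim)
  edges <- lapply(seq_len(ndim), function(d) {
    r <- if (is.null(range)) base::range(obs[, d]) else range[[d]]
    seq(r[1], r[2], length.out = bins[d] + 1L)
  })
  bin_of <- function(d) {
    i <- findInterval(obs[, d], edges[[d]], rightmost.closed = TRUE)
    pmin(pmax(i, 1L), bins[d])
  }
  if (ndim == 1L) {
    idx <- bin_of(1)
    mass <- vapply(seq_len(bins[1]), function(b) sum(weights[idx == b]), 0)
  } else {
    idx <- (bin_of(2) - 1L) * bins[1] + bin_of(1)
    mass <- vapply(seq_len(bins[1] * bins[2]),
                   function(b) sum(weights[idx == b]), 0)
    mass <- matrix(mass, bins[1], bins[2])
  }
  empty <- mass == 0
  F <- ifelse(empty, NA_real_, -kT * log(mass))
  F <- F - min(F, na.rm = TRUE)
  mids <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  structure(list(edges = edges, mids = mids, F = F, empty = empty, kT = kT),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  dims <- vapply(x$mids, length, 0L)
  cat(sprintf("fes_grid: %s bins, %d empty, kT = %g\n",
              paste(dims, collapse = " x "), sum(x$empty), x$kT))
  occ <- x$F[!x$empty]
  cat(sprintf("  free energy range: 0 .. %.4g\n", max(occ)))
  invisible(x)
}

#' Write a free-energy surface as plain text
#'
#' One row per bin: bin-center coordinates, free energy and the empty
#' flag; header comments record edges and kT.
#'
#' @param fes an `fes_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fes <- function(fes, path) {
  stopifnot(inherits(fes, "fes_grid"))
  ndim <- length(fes$mids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# slowcv fes_grid v1",
               paste("# kT", fmt_full(fes$kT)),
               paste("# bins", paste(vapply(fes$mids, length, 0L),
                                     collapse = " "))), con)
  if (ndim == 1L) {
    writeLines("x F empty", con)
    writeLines(paste(fmt_num(fes$mids[[1]]),
                     ifelse(fes$empty, "NA", fmt_num(fes$F)),
                     as.integer(fes$empty)), con)
  } else {
    writeLines("x y F empty", con)
    g <- expand.grid(x = fes$mids[[1]], y = fes$mids[[2]])
    writeLines(paste(fmt_num(g$x), fmt_num(g$y),
                     ifelse(as.vector(fes$empty), "NA",
                            fmt_num(as.vector(fes$F))),
                     as.integer(as.vector(fes$empty))), con)
  }
  invisible(path)
}
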