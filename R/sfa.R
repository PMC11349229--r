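# All moments in this file use population (1/T) normalization, matching
# the temporal-average reading of the angle brackets in the SFA
# definitions; sample (1/(T-1)) normalization changes nothing material
# but breaks the exact oracle identities the tests assert.

pop_mean_sd <- function(m) {
  mu <- colMeans(m)
  sigma <- sqrt(colMeans(sweep(m, 2, mu, "-")^2))
  list(mu = mu, sigma = sigma)
}

#' Normalize features to zero mean and unit variance
#'
#' Centers each column by its temporal mean and divides by its
#' population root-mean-square deviation, so that every feature enters
#' the analysis on the same scale.  Averages span all frames of all
#' segments.  Columns with zero variance (e.g. the sin of an angle
#' pinned at 0) are dropped with a warning rather than failing the fit.
#'
#' @param x a [feature_series()].
#' @return list with `series` (normalized `feature_series`), `mu`,
#'   `sigma` (named vectors over the kept columns) and `dropped`
#'   (names of zero-variance columns).
#' @export
normalize_features <- function(x) {
  stopifnot(inherits(x, "feature_series"))
  ms <- pop_mean_sd(x$values)
  keep <- ms$sigma > 0
  dropped <- colnames(x$values)[!keep]
  if (length(dropped) > 0)
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(dropped, collapse = ", ")))
  if (!any(keep)) stop("all features have zero variance")
  v <- x$values[, keep, drop = FALSE]
  v <- sweep(sweep(v, 2, ms$mu[keep], "-"), 2, ms$sigma[keep], "/")
  list(series = feature_series(v, names = colnames(x$values)[keep],
                               segments = x$segments, dt_ps = x$dt_ps),
       mu = ms$mu[keep], sigma = ms$sigma[keep], dropped = dropped)
}

expanded_names <- function(nm, order) {
  if (order == 1L) return(nm)
  J <- length(nm)
  quad <- character(J * (J + 1L) / 2L)
  k <- 1L
  for (i in seq_len(J)) for (j in i:J) {
    quad[k] <- paste0(nm[i], "*", nm[j]); k <- k + 1L
  }
  c(nm, quad)
}

#' Monomial expansion of a normalized signal
#'
#' Order 1 is the identity (linear SFA, the mode used for molecular
#' dynamics data).  Order 2 appends all degree-two monomials including
#' mixed terms, in the documented order c1..cJ, c1c1, c1c2, ..., cJcJ,
#' giving J + J(J+1)/2 columns.
#'
#' @param values numeric T x J matrix.
#' @param order 1 or 2.
#' @return numeric matrix of expanded features.
#' @export
expand_monomials <- function(values, order = 1L) {
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("expansion order must be 1 or 2")
  values <- as.matrix(values)
  if (order == 1L) return(values)
  J <- ncol(values)
  quad <- matrix(0, nrow(values), J * (J + 1L) / 2L)
  k <- 1L
  for (i in seq_len(J)) for (j in i:J) {
    quad[, k] <- values[, i] * values[, j]; k <- k + 1L
  }
  cbind(values, quad)
}

#' Whiten (sphere) a signal by PCA
#'
#' Centers the input and maps it through S = D^(-1/2) U^T, where
#' U D U^T is the eigendecomposition of the population covariance, so
#' that the output second moment is the identity on the retained rank.
#' Principal components whose eigenvalue falls below
#' `floor_rel * max(eigenvalue)` are discarded: near-null directions
#' explode under D^(-1/2) and would contaminate the slowest features.
#'
#' @param values numeric T x E matrix.
#' @param floor_rel relative variance floor for rank truncation.
#' @return list with `z` (whitened T x K matrix), `S` (K x E sphering
#'   matrix), `center` (column means) and `rank` (K).
#' @export
whiten_pca <- function(values, floor_rel = 1e-10) {
  values <- as.matrix(values)
  center <- colMeans(values)
  zc <- sweep(values, 2, center, "-")
  C <- crossprod(zc) / nrow(zc)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[1] <= 0) stop("input signal is identically zero")
  keep <- e$values >= floor_rel * e$values[1]
  d <- e$values[keep]
  U <- e$vectors[, keep, drop = FALSE]
  S <- sweep(t(U), 1, sqrt(d), "/")
  list(z = zc %*% t(S), S = S, center = center, rank = sum(keep))
}

#' Segment-aware forward differences
#'
#' Forward differences with unit frame spacing, taken within each
#' segment only; no difference straddles a segment boundary.  Output
#' has T minus (number of segments) rows.
#'
#' @param values numeric T x K matrix.
#' @param segments segment start rows (1-based).
#' @return numeric difference matrix.
#' @export
time_differences <- function(values, segments = 1L) {
  values <- as.matrix(values)
  segments <- check_segments(segments, nrow(values), min_len = 2L)
  ends <- c(segments[-1] - 1L, nrow(values))
  keep <- rep(TRUE, nrow(values) - 1L)
  keep[ends[-length(ends)]] <- FALSE   # rows whose forward diff crosses a join
  d <- values[-1L, , drop = FALSE] - values[-nrow(values), , drop = FALSE]
  d[keep, , drop = FALSE]
}

#' Fit a slow feature analysis model
#'
#' Composes normalization, optional quadratic expansion, PCA whitening
#' and an eigendecomposition of the second moment of the whitened
#' signal's forward differences.  The eigenvectors belonging to the
#' smallest eigenvalues are the slow features: unit-variance,
#' decorrelated output components ordered by slowness, where the
#' slowness Delta(y_k) (mean squared one-step difference) equals the
#' eigenvalue lambda_k.  No lag-time parameter exists anywhere — this
#' is what distinguishes SFA from tICA.
#'
#' Each weight vector's sign is fixed so that its largest-magnitude
#' pulled-back input coefficient is positive (slow features are
#' otherwise sign-indeterminate).
#'
#' @param x a [feature_series()] of training data.
#' @param order expansion order, 1 (linear, default) or 2 (quadratic).
#' @param n_components number of slow features to keep.
#' @param floor_rel whitening variance floor (relative to the largest
#'   covariance eigenvalue).
#' @return an object of class `sfa_model`.
#' @export
sfa <- function(x, order = 1L, n_components = 2L, floor_rel = 1e-10) {
  stopifnot(inherits(x, "feature_series"))
  order <- as.integer(order)
  nrm <- normalize_features(x)
  Z <- expand_monomials(nrm$series$values, order)
  wh <- whiten_pca(Z, floor_rel = floor_rel)
  if (n_components > wh$rank)
    stop(sprintf("n_components (%d) exceeds retained rank (%d)",
                 n_components, wh$rank))
  zdot <- time_differences(wh$z, x$segments)
  A <- crossprod(zdot) / nrow(zdot)    # raw second moment of differences
  e <- eigen(A, symmetric = TRUE)      # values descending
  idx <- rev(seq(wh$rank - n_components + 1L, wh$rank))
  lambda <- e$values[idx]
  W <- e$vectors[, idx, drop = FALSE]
  # sign convention: largest-magnitude pulled-back coefficient positive
  for (k in seq_len(ncol(W))) {
    gk <- drop(crossprod(wh$S, W[, k]))
    if (order == 1L) gk <- gk / nrm$sigma
    j <- which.max(abs(gk))
    if (gk[j] < 0) W[, k] <- -W[, k]
  }
  model <- list(mu = nrm$mu, sigma = nrm$sigma, dropped = nrm$dropped,
                names = names(nrm$mu), order = order,
                zmean = unname(wh$center), S = unname(wh$S), rank = wh$rank,
                W = W, lambda = pmax(lambda, 0),
                n_components = as.integer(n_components),
                expanded_names = expanded_names(names(nrm$mu), order))
  ta <- attr(x, "torsion_atoms")
  if (!is.null(ta)) model$torsion_atoms <- ta
  class(model) <- "sfa_model"
  model
}

#' @export
print.sfa_model <- function(x, ...) {
  cat(sprintf("sfa_model: order %d, %d input features, rank %d, %d slow feature(s)\n",
              x$order, length(x$names), x$rank, x$n_components))
  cat("  slowness eigenvalues:", paste(signif(x$lambda, 5), collapse = ", "), "\n")
  if (length(x$dropped)) cat("  dropped zero-variance:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Project data onto fitted slow features
#'
#' Evaluates y_k(t) = w_k . S (H(c(t)) - <Z>) with c the
#' model-normalized input.  Columns of `newdata` are matched to the
#' model's features by name, so column order is irrelevant; features
#' the model dropped as zero-variance are ignored.
#'
#' @param object a fitted `sfa_model`.
#' @param newdata a [feature_series()] containing at least the model's
#'   features.
#' @param ... unused.
#' @return a `slow_feature_series`: values (T x K'), segment starts,
#'   frame spacing and the model eigenvalues.
#' @export
predict.sfa_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "feature_series"))
  have <- colnames(newdata$values)
  missing <- setdiff(object$names, have)
  if (length(missing) > 0)
    stop(sprintf("missing feature(s): %s", paste(missing, collapse = ", ")))
  unknown <- setdiff(have, c(object$names, object$dropped))
  if (length(unknown) > 0)
    stop(sprintf("unknown feature(s): %s", paste(unknown, collapse = ", ")))
  v <- newdata$values[, object$names, drop = FALSE]
  cmat <- sweep(sweep(v, 2, object$mu, "-"), 2, object$sigma, "/")
  Z <- expand_monomials(cmat, object$order)
  z <- sweep(Z, 2, object$zmean, "-") %*% t(object$S)
  y <- z %*% object$W
  colnames(y) <- paste0("SF", seq_len(ncol(y)))
  structure(list(values = y, segments = newdata$segments,
                 dt_ps = newdata$dt_ps, lambda = object$lambda),
            class = "slow_feature_series")
}

#' @export
print.slow_feature_series <- function(x, ...) {
  cat(sprintf("slow_feature_series: %d frames x %d components, %d segment(s)\n",
              nrow(x$values), ncol(x$values), length(x$segments)))
  invisible(x)
}

#' Slowness of a signal
#'
#' Delta(y) = mean squared one-step forward difference, taken within
#' segments only.  On a model's own training output this equals the
#' slowness eigenvalue lambda_k of each component.
#'
#' @param y numeric vector/matrix or a `slow_feature_series`.
#' @param segments segment start rows (ignored when `y` carries its own).
#' @return numeric vector, one Delta per column.
#' @export
delta_value <- function(y, segments = 1L) {
  if (inherits(y, "slow_feature_series")) {
    segments <- y$segments
    y <- y$values
  }
  y <- as.matrix(y)
  d <- time_differences(y, segments)
  colMeans(d^2)
}

# affine form of one order-1 slow feature over the raw input features:
# y = sum_j coef_j * X_j + offset
affine_form <- function(model, k) {
  stopifnot(inherits(model, "sfa_model"))
  if (model$order != 1L)
    stop("affine pull-back is defined for order-1 (linear) models only")
  if (k < 1L || k > model$n_components) stop("component index out of range")
  g <- drop(crossprod(model$S, model$W[, k]))    # coefficients on c
  coef <- g / model$sigma
  offset <- -sum(coef * model$mu) - sum(g * model$zmean)
  list(coef = setNames(coef, model$names), offset = offset)
}

#' Feature-weight attribution of a slow feature
#'
#' Pulls a slow feature's weight vector back through the whitening map
#' and the input scaling to a coefficient per named input feature, the
#' quantity plotted as "SF weights" bar charts.  For order-2 models the
#' attribution is per expanded monomial instead.
#'
#' @param model a fitted `sfa_model`.
#' @param k component index.
#' @return data frame with columns `feature` and `coefficient`, sorted
#'   by absolute coefficient descending (ties broken by feature index);
#'   attribute `offset` completes the affine map so that
#'   `offset + sum(coefficient * feature)` reproduces [predict.sfa_model()]
#'   for order-1 models.
#' @export
rank_weights <- function(model, k = 1L) {
  stopifnot(inherits(model, "sfa_model"))
  if (k < 1L || k > model$n_components) stop("component index out of range")
  if (model$order == 1L) {
    af <- affine_form(model, k)
    coef <- af$coef
    offset <- af$offset
  } else {
    coef <- setNames(drop(crossprod(model$S, model$W[, k])),
                     model$expanded_names)
    offset <- -sum(coef * model$zmean)
  }
  ord <- order(-abs(coef), seq_along(coef))
  out <- data.frame(feature = names(coef)[ord], coefficient = unname(coef[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "offset") <- offset
  out
}

#' Save / load a fitted SFA model
#'
#' Single self-describing JSON file holding means, scales, expansion
#' order, expansion mean, sphering matrix, weight vectors, eigenvalues,
#' feature names and dropped columns.  Numbers are written with 17
#' significant digits so the round trip is bit-stable.
#'
#' @param model an `sfa_model`.
#' @param path file path.
#' @return `write_sfa_model` returns `path` invisibly; `read_sfa_model`
#'   returns the reconstructed `sfa_model`.
#' @export
write_sfa_model <- function(model, path) {
  stopifnot(inherits(model, "sfa_model"))
  ser <- list(
    format = "slowcv sfa_model v1",
    names = model$names, dropped = model$dropped, order = model$order,
    mu = unname(model$mu), sigma = unname(model$sigma),
    zmean = unname(model$zmean), rank = model$rank,
    n_components = model$n_components,
    lambda = unname(model$lambda),
    S = list(dim = dim(model$S), data = as.vector(model$S)),
    W = list(dim = dim(model$W), data = as.vector(model$W)),
    expanded_names = model$expanded_names)
  if (!is.null(model$torsion_atoms))
    ser$torsion_atoms <- list(dim = dim(model$torsion_atoms),
                              data = as.vector(model$torsion_atoms),
                              labels = rownames(model$torsion_atoms))
  json <- jsonlite::toJSON(ser, digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_sfa_model
#' @export
read_sfa_model <- function(path) {
  ser <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = TRUE)
  if (!identical(ser$format, "slowcv sfa_model v1"))
    stop("not a slowcv sfa_model file")
  model <- list(
    mu = setNames(as.numeric(ser$mu), ser$names),
    sigma = setNames(as.numeric(ser$sigma), ser$names),
    dropped = as.character(ser$dropped),
    names = as.character(ser$names),
    order = as.integer(ser$order),
    zmean = as.numeric(ser$zmean),
    S = matrix(ser$S$data, ser$S$dim[1], ser$S$dim[2]),
    rank = as.integer(ser$rank),
    W = matrix(ser$W$data, ser$W$dim[1], ser$W$dim[2]),
    lambda = as.numeric(ser$lambda),
    n_components = as.integer(ser$n_components),
    expanded_names = as.character(ser$expanded_names))
  if (!is.null(ser$torsion_atoms)) {
    ta <- matrix(ser$torsion_atoms$data, ser$torsion_atoms$dim[1],
                 ser$torsion_atoms$dim[2])
    rownames(ta) <- ser$torsion_atoms$labels
    model$torsion_atoms <- ta
  }
  class(model) <- "sfa_model"
  model
}
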