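# Independent oracles and fixture builders used across the test files.

# dihedral oracle: projection (praxeolitic) formulation, algebraically
# different from the package's cross-product-normal formulation
oracle_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2; b1 <- p3 - p2; b2 <- p4 - p3
  b1 <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  atan2(y, x)
}

# random rigid motion (rotation + translation) applied to an n x 3 matrix
random_rigid <- function(pts, seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- rnorm(3, sd = 5)
  sweep(pts %*% R, 2, tr, "+")
}

# population covariance (1/T)
pop_cov <- function(m) {
  mc <- sweep(m, 2, colMeans(m), "-")
  crossprod(mc) / nrow(mc)
}

# generalized-eigenproblem SFA oracle on normalized data:
# Cov(cdot) w = lambda Cov(c) w, solved via Cholesky reduction.
# Returns ascending eigenvalues and the weight vectors (columns) in the
# space of the normalized features c.
sfa_oracle <- function(x) {
  stopifnot(inherits(x, "feature_series"))
  v <- x$values
  mu <- colMeans(v)
  sg <- sqrt(colMeans(sweep(v, 2, mu, "-")^2))
  cmat <- sweep(sweep(v, 2, mu, "-"), 2, sg, "/")
  B <- crossprod(cmat) / nrow(cmat)              # Cov(c), population
  cd <- slowcv::time_differences(cmat, x$segments)
  A <- crossprod(cd) / nrow(cd)                  # raw 2nd moment of diffs
  R <- chol(B)
  Ri <- backsolve(R, diag(ncol(B)))
  M <- t(Ri) %*% A %*% Ri
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- rev(seq_along(e$values))                # ascending
  list(lambda = e$values[ord], W = Ri %*% e$vectors[, ord, drop = FALSE])
}

# principal angles (radians) between the column spans of two matrices
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1))
}

# mixed AR(1) sources with random loadings: a generic stationary
# multivariate series with distinct timescales
make_ar1_features <- function(n, j, seed) {
  set.seed(seed)
  phi <- seq(0.999, 0.2, length.out = j)
  src <- matrix(0, n, j)
  innov <- matrix(rnorm(n * j), n, j)
  for (t in 2:n)
    src[t, ] <- phi * src[t - 1, ] + sqrt(1 - phi^2) * innov[t, ]
  mix <- matrix(rnorm(j * j), j, j) + diag(j)
  slowcv::feature_series(src %*% mix,
                         names = sprintf("f%02d", seq_len(j)))
}

# hand-built CV spec over two torsions with exact decimal coefficients
# (independent of any fitted model, so the golden file is platform-stable)
fixed_cv_spec <- function() {
  structure(list(
    name = "SF1", offset = -0.125,
    terms = data.frame(
      feature = c("sin_chi1_TRP41", "cos_chi1_TRP41",
                  "sin_chi2_TYR77", "cos_chi2_TYR77"),
      kind = c("sin", "cos", "sin", "cos"),
      torsion = c("chi1_TRP41", "chi1_TRP41", "chi2_TYR77", "chi2_TYR77"),
      coef = c(0.75, -0.5, 0.25, 0.0625),
      stringsAsFactors = FALSE)),
    class = "cv_spec")
}

fixed_torsion_atoms <- function() {
  ta <- rbind(c(5L, 7L, 9L, 11L), c(21L, 23L, 25L, 27L))
  rownames(ta) <- c("chi1_TRP41", "chi2_TYR77")
  ta
}

# parse KEY=value tokens of a PLUMED action line into a named character
# vector (used to check the METAD stanza)
parse_plumed_line <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  kv <- grep("=", toks, value = TRUE)
  parts <- strsplit(kv, "=", fixed = TRUE)
  stats::setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
}
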