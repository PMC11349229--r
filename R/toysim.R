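#' Model potentials for the toy engine
#'
#' Energies are in kT = 1 reduced units.  Each potential carries an
#' integer code so the Langevin and metadynamics integrators run fully
#' in compiled code.
#'
#' @param k force constant (harmonic).
#' @param barrier barrier height in kT.
#' @param theta0 location of one well of the periodic double well; the
#'   second well sits at `theta0 + pi` (angles wrapped into (-pi, pi]).
#' @param ky transverse harmonic constant of the 2-D double well.
#' @return an object of class `model_potential` with fields `dim`,
#'   `U` (vectorized energy over rows), `code` and `params`.
#' @name model_potential
NULL

new_potential <- function(dim, code, params, periodic = FALSE) {
  structure(list(dim = dim, code = code, params = as.numeric(params),
                 periodic = periodic,
                 U = function(x) {
                   x <- if (is.null(dim(x))) matrix(x, ncol = dim) else as.matrix(x)
                   .pot_energy_cpp(code, as.numeric(params), x)
                 }),
            class = "model_potential")
}

#' @rdname model_potential
#' @export
harmonic_potential <- function(k = 1) new_potential(1L, 1L, k)

#' @rdname model_potential
#' @export
double_well_1d <- function(barrier = 4) new_potential(1L, 2L, barrier)

#' @rdname model_potential
#' @export
periodic_double_well <- function(barrier = 5, theta0 = -pi / 3)
  new_potential(1L, 3L, c(barrier, theta0), periodic = TRUE)

#' @rdname model_potential
#' @export
double_well_2d <- function(barrier = 4, ky = 2)
  new_potential(2L, 4L, c(barrier, ky))

#' @export
print.model_potential <- function(x, ...) {
  cat(sprintf("model_potential: code %d, dim %d, params (%s)\n",
              x$code, x$dim, paste(signif(x$params, 5), collapse = ", ")))
  invisible(x)
}

#' Toy run configuration
#'
#' All toy dynamics use kT = 1 reduced units and overdamped
#' Euler-Maruyama integration; the seed is mandatory — no implicit
#' randomness anywhere in the toy engine.
#'
#' @param seed RNG seed (mandatory).
#' @param n_steps number of integration steps.
#' @param dt step size (> 0).
#' @param friction friction coefficient of the overdamped dynamics.
#' @param x0 start coordinates (defaults to the origin).
#' @param stride record every `stride` steps.
#' @param pace metadynamics deposition pace in steps.
#' @param height initial Gaussian height (kT).
#' @param width per-CV Gaussian widths.
#' @param biasfactor well-tempered bias factor (> 1).
#' @param kT thermal energy in reduced units (default 1; 0 switches the
#'   noise off for deterministic-limit checks).
#' @param bound divergence guard: error when |x| exceeds it.
#' @return an object of class `toy_run_config`.
#' @export
toy_run_config <- function(seed, n_steps = 200000L, dt = 0.005, friction = 1,
                           x0 = NULL, stride = 10L, pace = 500L,
                           height = 0.5, width = 0.15, biasfactor = 10,
                           kT = 1, bound = 1e3) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(dt > 0, friction > 0, n_steps >= 1, stride >= 1, pace >= 1,
            height > 0, all(width > 0), biasfactor > 1, kT >= 0)
  structure(list(seed = as.integer(seed), n_steps = as.integer(n_steps),
                 dt = dt, friction = friction, x0 = x0,
                 stride = as.integer(stride), pace = as.integer(pace),
                 height = height, width = width, biasfactor = biasfactor,
                 kT = kT, bound = bound),
            class = "toy_run_config")
}

#' Canonical two-component SFA test signal
#'
#' x1(t) = sin(t) + cos^2(11 t), x2(t) = cos(11 t) on
#' t = 0, dt, ..., (n-1) dt.  The identity x1 - x2^2 = sin(t) means a
#' quadratic expansion contains a feature proportional to the slow
#' sin(t), which quadratic SFA must recover as its slowest component.
#'
#' @param n number of frames (>= 100).
#' @param dt time step (default 0.002 * 2 pi, ten sin periods at
#'   n = 5000).
#' @return a [feature_series()] with columns `x1`, `x2`.
#' @export
wiskott_signal <- function(n = 5000L, dt = 0.002 * 2 * pi) {
  stopifnot(n >= 100L)
  t <- (seq_len(n) - 1) * dt
  feature_series(cbind(x1 = sin(t) + cos(11 * t)^2, x2 = cos(11 * t)),
                 dt_ps = dt)
}

#' Two-state flipping dihedral with fast noise angles
#'
#' Emulates a rare side-chain flip: one angle alternates between wells
#' near -pi/3 and +2pi/3 via a symmetric telegraph process with
#' per-frame flip probability `flip_rate` plus small Gaussian jitter,
#' and `n_fast` additional angles are fast wrapped noise.  A telegraph
#' process (rather than Langevin on a periodic double well) makes the
#' flip rate exactly known for count tests.  Fixed seed implies
#' bit-identical output.
#'
#' @param n number of frames.
#' @param flip_rate per-frame flip probability (0 < rate < 0.5).
#' @param n_fast number of fast noise angles.
#' @param seed RNG seed (mandatory).
#' @param jitter within-well Gaussian jitter standard deviation (rad).
#' @param wells the two well centers (rad).
#' @return a [dihedral_series()]; the slow angle is labelled
#'   `chi1_TRP41`, the fast ones `chi1_PHE<i>`.  Synthetic atom
#'   quadruples (consecutive serials) are attached so the series can be
#'   carried all the way to PLUMED export.
#' @export
two_state_dihedral <- function(n = 100000L, flip_rate = 0.001, n_fast = 9L,
                               seed, jitter = 0.1,
                               wells = c(-pi / 3, 2 * pi / 3)) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(flip_rate > 0 || flip_rate == 0, flip_rate < 0.5, n_fast >= 0)
  with_seed(seed, {
    flips <- if (flip_rate > 0) runif(n - 1) < flip_rate else logical(n - 1)
    state <- 1L + (cumsum(c(0L, as.integer(flips))) %% 2L)
    slow <- wells[state] + rnorm(n, sd = jitter)
    fast <- if (n_fast > 0)
      matrix(runif(n * n_fast, -pi, pi), n, n_fast) else NULL
    vals <- cbind(slow, fast)
    vals <- ((vals + pi) %% (2 * pi)) - pi       # wrap into [-pi, pi)
    vals[vals <= -pi] <- pi
    labels <- c("chi1_TRP41",
                if (n_fast > 0) sprintf("chi1_PHE%d", seq_len(n_fast)))
    atoms <- matrix(seq_len(4L * (1L + n_fast)), ncol = 4L, byrow = TRUE)
    dihedral_series(vals, labels = labels, atoms = atoms)
  })
}

#' Overdamped Langevin dynamics on a model potential
#'
#' Euler-Maruyama in kT = 1 units:
#' `x' = x - grad U(x) dt / friction + sqrt(2 dt / friction) xi`.
#' Coordinates of periodic potentials are wrapped into (-pi, pi].
#'
#' @param potential a [model_potential].
#' @param cfg a [toy_run_config()].
#' @return data frame with `time` and one column per coordinate,
#'   recorded every `cfg$stride` steps (initial frame included); the
#'   seed is attached as attribute `seed`.
#' @export
langevin <- function(potential, cfg) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(cfg, "toy_run_config"))
  x0 <- if (is.null(cfg$x0)) numeric(potential$dim) else as.numeric(cfg$x0)
  stopifnot(length(x0) == potential$dim)
  m <- with_seed(cfg$seed,
    .langevin_cpp(potential$code, potential$params, x0, cfg$n_steps,
                  cfg$dt, cfg$friction, cfg$kT, cfg$stride, cfg$bound))
  out <- as.data.frame(m)
  names(out) <- c("time", paste0("x", seq_len(potential$dim)))
  attr(out, "seed") <- cfg$seed
  out
}

#' Toy CV definitions for the metadynamics integrator
#'
#' `toy_cv_coord(i)` biases coordinate i directly;
#' `toy_cv_sincos(offset, bsin, bcos)` biases the affine combination
#' `offset + sum_d bsin_d sin(x_d) + bcos_d cos(x_d)` — exactly the
#' form of an exported slow-feature CV over angles.
#'
#' @param i coordinate index (1-based).
#' @param offset constant term.
#' @param bsin,bcos coefficient vectors, one entry per coordinate.
#' @return a `toy_cv` list understood by [wt_metad()].
#' @export
toy_cv_coord <- function(i = 1L)
  structure(list(type = 0L, idx = as.integer(i)), class = "toy_cv")

#' @rdname toy_cv_coord
#' @export
toy_cv_sincos <- function(offset, bsin, bcos)
  structure(list(type = 1L, offset = as.numeric(offset),
                 bsin = as.numeric(bsin), bcos = as.numeric(bcos)),
            class = "toy_cv")

#' Convert an exported CV to a toy CV over angle coordinates
#'
#' Maps a `cv_spec` (affine in sin/cos of named torsions) onto the
#' coordinates of a toy angle system, given the torsion order of those
#' coordinates.
#'
#' @param cv a `cv_spec` from [cv_from_model()].
#' @param torsions character vector: torsion label of each toy
#'   coordinate, in coordinate order.
#' @return a `toy_cv`.
#' @export
toy_cv_from_spec <- function(cv, torsions) {
  stopifnot(inherits(cv, "cv_spec"))
  missing <- setdiff(cv$terms$torsion, torsions)
  if (length(missing) > 0)
    stop(sprintf("torsion(s) not in the toy system: %s",
                 paste(missing, collapse = ", ")))
  bsin <- bcos <- numeric(length(torsions))
  for (r in seq_len(nrow(cv$terms))) {
    d <- match(cv$terms$torsion[r], torsions)
    if (cv$terms$kind[r] == "sin") bsin[d] <- bsin[d] + cv$terms$coef[r]
    else bcos[d] <- bcos[d] + cv$terms$coef[r]
  }
  toy_cv_sincos(cv$offset, bsin, bcos)
}

#' Toy well-tempered metadynamics
#'
#' Overdamped Langevin dynamics with a history-dependent bias built
#' from Gaussians deposited along the given CVs every `cfg$pace` steps,
#' with deposited height `h exp(-V(s, t) / ((gamma - 1) kT))` (kT = 1).
#' Emits COLVAR and HILLS tables in exactly the layout
#' [read_colvar()] / [read_hills()] parse, with heights recorded as
#' actually deposited (`heights = "raw"` downstream).
#'
#' @param potential a [model_potential].
#' @param cvs list of `toy_cv` objects (or a single one).
#' @param cfg a [toy_run_config()]; `cfg$width` must have one entry per
#'   CV.
#' @param cv_names CV column names (default `cv1`, `cv2`, ...).
#' @return list with `colvar` (data frame: time, CVs, the raw
#'   coordinates `x1..xd` as extra observable columns, `metad.bias`) and
#'   `hills` (data frame: time, centers, `sigma_<cv>`, `height`,
#'   `biasf`), both carrying the seed as an attribute.
#' @export
wt_metad <- function(potential, cvs, cfg, cv_names = NULL) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(cfg, "toy_run_config"))
  if (inherits(cvs, "toy_cv")) cvs <- list(cvs)
  for (cv in cvs) stopifnot(inherits(cv, "toy_cv"))
  ncv <- length(cvs)
  widths <- rep(cfg$width, length.out = ncv)
  if (is.null(cv_names)) cv_names <- paste0("cv", seq_len(ncv))
  x0 <- if (is.null(cfg$x0)) numeric(potential$dim) else as.numeric(cfg$x0)
  stopifnot(length(x0) == potential$dim)
  res <- with_seed(cfg$seed,
    .wt_metad_cpp(potential$code, potential$params, x0, cfg$n_steps,
                  cfg$dt, cfg$friction, cfg$kT, cfg$stride, cfg$pace,
                  cfg$height, widths, cfg$biasfactor,
                  lapply(cvs, unclass), cfg$bound))
  colvar <- as.data.frame(res$colvar)
  names(colvar) <- c("time", cv_names, paste0("x", seq_len(potential$dim)),
                     "metad.bias")
  hills <- as.data.frame(res$hills)
  names(hills) <- c("time", cv_names, "height")
  for (k in seq_len(ncv)) hills[[paste0("sigma_", cv_names[k])]] <- widths[k]
  hills$biasf <- cfg$biasfactor
  hills <- hills[, c("time", cv_names, paste0("sigma_", cv_names),
                     "height", "biasf")]
  attr(colvar, "seed") <- cfg$seed
  attr(hills, "seed") <- cfg$seed
  attr(hills, "cv_names") <- cv_names
  class(hills) <- c("hills", class(hills))
  list(colvar = colvar, hills = hills)
}

#' Convert toy (kT = 1) metadynamics output to kJ/mol at a temperature
#'
#' The toy engine works in reduced units; PLUMED-side post-processing
#' works in kJ/mol.  This multiplies every energy-like column (bias,
#' hill heights) by kT(temp) so the standard reweighting path applies.
#'
#' @param run list with `colvar` and `hills` from [wt_metad()].
#' @param temp target temperature in kelvin.
#' @return the run with energies rescaled to kJ/mol.
#' @export
toy_to_kjmol <- function(run, temp = 300) {
  f <- kT_kjmol(temp)
  run$colvar[["metad.bias"]] <- run$colvar[["metad.bias"]] * f
  run$hills$height <- run$hills$height * f
  run
}

#' Analytic free-energy surface of a model potential
#'
#' `F = -kT ln integral exp(-U)` over the coordinates orthogonal to the
#' projection, evaluated at bin centers and shifted so the minimum is
#' zero.  For a 1-D potential this is exactly `U - min U`; for 2-D
#' potentials the orthogonal coordinate is integrated by the
#' trapezoidal rule on a dense grid.
#'
#' @param potential a [model_potential].
#' @param projection coordinate index to project on.
#' @param bins number of bins.
#' @param range c(lo, hi) of the projected coordinate.
#' @param orth_range integration range of the orthogonal coordinate
#'   (2-D potentials).
#' @param quad_n quadrature points for the orthogonal integral.
#' @return an `fes_grid` (kT = 1 units) with values at bin centers.
#' @export
analytic_fes <- function(potential, projection = 1L, bins = 100L,
                         range = c(-2, 2), orth_range = c(-6, 6),
                         quad_n = 801L) {
  stopifnot(inherits(potential, "model_potential"))
  edges <- seq(range[1], range[2], length.out = bins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  if (potential$dim == 1L) {
    F <- potential$U(matrix(mids, ncol = 1))
  } else if (potential$dim == 2L) {
    yg <- seq(orth_range[1], orth_range[2], length.out = quad_n)
    dy <- yg[2] - yg[1]
    other <- if (projection == 1L) 2L else 1L
    F <- vapply(mids, function(m) {
      pts <- matrix(0, quad_n, 2)
      pts[, projection] <- m
      pts[, other] <- yg
      u <- potential$U(pts)
      w <- rep(1, quad_n); w[c(1, quad_n)] <- 0.5   # trapezoid
      -log(sum(w * exp(-u)) * dy)
    }, 0)
  } else stop("analytic_fes supports 1-D and 2-D potentials")
  F <- F - min(F)
  structure(list(edges = list(edges), mids = list(mids), F = F,
                 empty = rep(FALSE, bins), kT = 1),
            class = "fes_grid")
}

#' Toy coordinate trajectory of a rotating dihedral
#'
#' Builds a 4-atom chain whose torsion follows the given angle series;
#' used for featurization round-trip tests (write as PDB or DCD, read
#' back, recover the angles).
#'
#' @param angles numeric vector of torsion angles (rad).
#' @return a [coord_traj()] with atoms N, CA, CB, CG of one TRP residue.
#' @export
toy_dihedral_traj <- function(angles) {
  n <- length(angles)
  xyz <- matrix(0, n, 12)
  # fixed frame: N at (-.1,.1,0), CA at origin, CB along x; CG rotated
  # about the CA-CB axis, dihedral measured from the N position
  for (i in seq_len(n)) {
    a <- angles[i]
    xyz[i, ] <- c(-0.10, 0.10, 0,
                  0, 0, 0,
                  0.15, 0, 0,
                  0.15, 0.10 * cos(a), 0.10 * sin(a))
  }
  atoms <- data.frame(elety = c("N", "CA", "CB", "CG"),
                      resid = "TRP", resno = 41L, chain = "A",
                      stringsAsFactors = FALSE)
  coord_traj(xyz, atoms)
}
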