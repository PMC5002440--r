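#' Two-manipulator co-registration
#'
#' Geometry of a dual-manipulator setup in which a reference manipulator (the
#' pipette holder, "PS") defines the stereotaxic frame and a second, tilted
#' three-axis manipulator ("IVM") carries the extracellular probe.  Readings of
#' the tilted manipulator are first rotated into the reference frame with the
#' tilt transform, and residual mechanical misalignment is then removed by a
#' least-squares affine correction fitted to paired calibration points.
#'
#' Coordinates are micrometres throughout: X medio-lateral, Y
#' anterior-posterior, Z dorso-ventral in the reference frame.
#'
#' @name coreg
NULL

DEFAULT_THETA_DEG <- 48.2

.check_xyz <- function(p, what = "coordinates") {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p)))
    stop("invalid ", what, ": need 3 finite values, got [",
         paste(format(p), collapse = ", "), "]")
  p
}

#' Manipulator reading in the tilted manipulator's native frame
#'
#' @param x,y,z axis readings in micrometres.
#' @param theta_deg tilt of the manipulator's approach axis from the
#'   horizontal, degrees; must lie in (-90, 90).  The probe manipulator in the
#'   reference setup is tilted 48.2 degrees.
#' @return an object of class `manipulator_reading`.
#' @export
manipulator_reading <- function(x, y, z, theta_deg = DEFAULT_THETA_DEG) {
  p <- .check_xyz(c(x, y, z), "manipulator reading")
  if (!is.finite(theta_deg) || theta_deg <= -90 || theta_deg >= 90)
    stop("theta_deg must be finite and in (-90, 90), got ", theta_deg)
  structure(list(xyz = p, theta_deg = as.numeric(theta_deg)),
            class = "manipulator_reading")
}

#' Tilt rotation matrix for a given approach angle
#'
#' The matrix is symmetric and orthogonal (an involution, determinant -1), so
#' it is its own inverse: applying it twice recovers the input.
#'
#' @param theta_deg tilt angle in degrees.
#' @return a 3x3 rotation/reflection matrix mapping native (x, y, z) readings
#'   into the reference frame.
#' @export
tilt_matrix <- function(theta_deg) {
  th <- theta_deg * pi / 180
  s <- sin(th); cth <- cos(th)
  # x' = cos(theta) z + sin(theta) x ; y' = y ; z' = -sin(theta) z + cos(theta) x
  matrix(c(s,   0, cth,
           0,   1, 0,
           cth, 0, -s), nrow = 3, byrow = TRUE)
}

#' Rotate a tilted-manipulator reading into the reference frame
#'
#' Applies the tilt transform x' = cos(theta) z + sin(theta) x, y' = y,
#' z' = -sin(theta) z + cos(theta) x.  The transform preserves Euclidean norms.
#' A negative theta transposes the rotation; the package convention stores the
#' probe manipulator's tilt as +48.2 degrees.
#'
#' @param reading a [manipulator_reading()] (or a length-3 numeric, in which
#'   case `theta_deg` must be supplied).
#' @param theta_deg tilt angle, used only when `reading` is a bare vector.
#' @return length-3 numeric position in the reference frame (micrometres).
#' @export
tilt_to_reference <- function(reading, theta_deg = NULL) {
  if (inherits(reading, "manipulator_reading")) {
    p <- reading$xyz
    theta_deg <- reading$theta_deg
  } else {
    p <- .check_xyz(reading, "manipulator reading")
    if (is.null(theta_deg)) stop("theta_deg required for a bare coordinate vector")
  }
  as.numeric(tilt_matrix(theta_deg) %*% p)
}

#' Paired calibration observations of one physical point
#'
#' @param reference length-3 position in the reference (PS) frame, micrometres.
#' @param moving a [manipulator_reading()] of the same physical point in the
#'   tilted manipulator's native frame.
#' @return an object of class `calibration_pair`.
#' @export
calibration_pair <- function(reference, moving) {
  if (!inherits(moving, "manipulator_reading"))
    stop("moving must be a manipulator_reading")
  structure(list(reference = .check_xyz(reference, "reference position"),
                 moving = moving),
            class = "calibration_pair")
}

.pairs_matrices <- function(pairs) {
  if (!length(pairs)) stop("empty calibration pair list")
  ok <- vapply(pairs, inherits, logical(1), what = "calibration_pair")
  if (!all(ok)) stop("all elements must be calibration_pair objects")
  ref <- t(vapply(pairs, function(p) p$reference, numeric(3)))
  mov <- t(vapply(pairs, function(p) tilt_to_reference(p$moving), numeric(3)))
  list(ref = ref, mov = mov)
}

#' Fit the affine software correction to calibration pairs
#'
#' Least-squares fit of `reference ~ linear %*% tilt(moving) + offset` over all
#' pairs: the linear misalignment map plus a translation offset that absorbs
#' zeroing errors.  The correction is fitted between tilt-transformed moving
#' coordinates and reference coordinates, i.e. the tilt transform is applied
#' first and the affine map removes only the residual misalignment.
#'
#' @param pairs list of [calibration_pair()] objects; at least 4, with moving
#'   points spanning 3D (not coplanar).
#' @return an object of class `affine_correction` with elements `linear`
#'   (3x3), `offset` (length 3, micrometres), `fit_residual_mean` and
#'   `fit_residual_sd` (micrometres, over per-point Euclidean residuals).
#' @export
fit_affine_correction <- function(pairs) {
  m <- .pairs_matrices(pairs)
  n <- nrow(m$mov)
  if (n < 4L)
    stop("degenerate fit: need at least 4 calibration pairs, got ", n)
  X <- cbind(m$mov, 1)
  qx <- qr(X)
  if (qx$rank < 4L)
    stop("degenerate fit: moving points are coplanar or collinear ",
         "(affine design rank ", qx$rank, " < 4)")
  beta <- qr.coef(qx, m$ref)            # 4 x 3; columns = output axes
  linear <- t(beta[1:3, , drop = FALSE])
  offset <- as.numeric(beta[4, ])
  pred <- m$mov %*% t(linear) + rep(offset, each = n)
  res <- sqrt(rowSums((m$ref - pred)^2))
  if (abs(det(linear)) < 1e-12)
    stop("degenerate fit: fitted linear map is singular")
  structure(list(linear = linear, offset = offset,
                 fit_residual_mean = mean(res),
                 fit_residual_sd = stats::sd(res),
                 n_pairs = n),
            class = "affine_correction")
}

#' Identity correction (no software adjustment)
#' @return an `affine_correction` that leaves positions unchanged.
#' @export
identity_correction <- function() {
  structure(list(linear = diag(3), offset = c(0, 0, 0),
                 fit_residual_mean = 0, fit_residual_sd = 0, n_pairs = 0L),
            class = "affine_correction")
}

#' Apply the fitted correction to a manipulator reading
#'
#' Composition order: the reading is first rotated into the reference frame
#' with the tilt transform, then the fitted affine map is applied.
#'
#' @param correction an [affine_correction].
#' @param reading a [manipulator_reading()], or a length-3 position already in
#'   the reference frame (skips the tilt step).
#' @return corrected length-3 position, micrometres.
#' @export
apply_correction <- function(correction, reading) {
  stopifnot(inherits(correction, "affine_correction"))
  p <- if (inherits(reading, "manipulator_reading"))
    tilt_to_reference(reading) else .check_xyz(reading, "position")
  as.numeric(correction$linear %*% p + correction$offset)
}

#' Distance-error summary over calibration pairs
#'
#' Per-point Euclidean distance between each reference position and the
#' predicted position of the moving manipulator: the raw tilt transform when
#' `correction` is `NULL` (the physical misalignment error), or the corrected
#' position otherwise (the post-software-alignment error).
#'
#' @param pairs list of [calibration_pair()] objects.
#' @param correction an [affine_correction], or `NULL` for no correction.
#' @return list with `per_point_um`, `mean_um`, `sd_um`, `n`.
#' @export
distance_errors <- function(pairs, correction = NULL) {
  m <- .pairs_matrices(pairs)
  if (is.null(correction)) correction <- identity_correction()
  stopifnot(inherits(correction, "affine_correction"))
  n <- nrow(m$mov)
  pred <- m$mov %*% t(correction$linear) + rep(correction$offset, each = n)
  d <- sqrt(rowSums((m$ref - pred)^2))
  list(per_point_um = d, mean_um = mean(d),
       sd_um = if (n > 1L) stats::sd(d) else 0, n = n)
}

#' Seeded subsample of a cubic calibration lattice
#'
#' Calibration positions are drawn from a regular lattice spanning the working
#' volume (reference setup: 5,000 x 5,000 x 5,000 um in 1,000-um steps).  The
#' subsample is deterministic given the seed and guaranteed to have full
#' affine design rank (4) whenever `n_points >= 4`, so it can always anchor an
#' affine fit.
#'
#' @param extent_um length-3 extent of the lattice per axis, micrometres.
#' @param step_um lattice step; must divide each extent.
#' @param n_points number of lattice points to return; `NULL` returns the full
#'   lattice.
#' @param seed integer seed for the subsample.
#' @return matrix `n_points` x 3 of positions (micrometres).
#' @export
calibration_grid <- function(extent_um = c(5000, 5000, 5000), step_um = 1000,
                             n_points = NULL, seed = 1L) {
  extent_um <- .check_xyz(extent_um, "extent")
  if (step_um <= 0 || any(abs(extent_um %% step_um) > 1e-9))
    stop("step_um must be positive and divide every extent")
  ax <- lapply(extent_um, function(e) seq(0, e, by = step_um))
  lattice <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  dimnames(lattice) <- list(NULL, c("x", "y", "z"))
  if (is.null(n_points)) return(lattice)
  if (n_points > nrow(lattice))
    stop("n_points (", n_points, ") exceeds lattice size (", nrow(lattice), ")")
  rng <- .local_rng(seed)
  for (attempt in 1:100) {
    idx <- rng(function() sample.int(nrow(lattice), n_points))
    sub <- lattice[idx, , drop = FALSE]
    if (n_points < 4L || qr(cbind(sub, 1))$rank == 4L) return(sub)
  }
  stop("could not draw a full-rank calibration subsample")  # nocov
}

# Run `expr()` under a private RNG stream without disturbing the caller's RNG.
.local_rng <- function(seed) {
  force(seed)
  first <- TRUE
  state <- NULL
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
            else assign(".Random.seed", old, envir = globalenv()))
    if (first) set.seed(seed) else assign(".Random.seed", state, envir = globalenv())
    out <- expr()
    state <<- get(".Random.seed", globalenv())
    first <<- FALSE
    out
  }
}

#' @export
print.affine_correction <- function(x, ...) {
  cat("Affine software correction (reference <- linear . tilt(moving) + offset)\n")
  cat("linear:\n"); print(round(x$linear, 6))
  cat("offset (um):", format(round(x$offset, 3)), "\n")
  cat(sprintf("fit residual: %.2f +/- %.2f um (n = %d)\n",
              x$fit_residual_mean, x$fit_residual_sd, x$n_pairs))
  invisible(x)
}

#' Read and write calibration pairs as CSV
#'
#' Column layout: `pair_index, ref_x_um, ref_y_um, ref_z_um, mov_x_um,
#' mov_y_um, mov_z_um, theta_deg`.
#'
#' @param pairs list of [calibration_pair()] objects.
#' @param path CSV file path.
#' @return `read_calibration_csv` returns a list of calibration pairs.
#' @export
write_calibration_csv <- function(pairs, path) {
  m <- .pairs_matrices(pairs)   # validates
  df <- data.frame(pair_index = seq_along(pairs),
                   ref_x_um = m$ref[, 1], ref_y_um = m$ref[, 2], ref_z_um = m$ref[, 3],
                   mov_x_um = vapply(pairs, function(p) p$moving$xyz[1], 0),
                   mov_y_um = vapply(pairs, function(p) p$moving$xyz[2], 0),
                   mov_z_um = vapply(pairs, function(p) p$moving$xyz[3], 0),
                   theta_deg = vapply(pairs, function(p) p$moving$theta_deg, 0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("ref_x_um", "ref_y_um", "ref_z_um",
            "mov_x_um", "mov_y_um", "mov_z_um", "theta_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("calibration CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    calibration_pair(c(df$ref_x_um[i], df$ref_y_um[i], df$ref_z_um[i]),
                     manipulator_reading(df$mov_x_um[i], df$mov_y_um[i],
                                         df$mov_z_um[i], df$theta_deg[i])))
}

#' Serialize an affine correction to JSON
#'
#' Flat record: row-major 3x3 linear coefficients, the 3-vector offset
#' (micrometres) and the residual statistics.
#'
#' @param correction an [affine_correction].
#' @param path JSON file path.
#' @export
write_correction_json <- function(correction, path) {
  stopifnot(inherits(correction, "affine_correction"))
  jsonlite::write_json(
    list(linear_row_major = as.numeric(t(correction$linear)),
         offset_um = correction$offset,
         fit_residual_mean_um = correction$fit_residual_mean,
         fit_residual_sd_um = correction$fit_residual_sd,
         n_pairs = correction$n_pairs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_correction_json
#' @export
read_correction_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(linear = matrix(j$linear_row_major, 3, 3, byrow = TRUE),
                 offset = as.numeric(j$offset_um),
                 fit_residual_mean = j$fit_residual_mean_um,
                 fit_residual_sd = j$fit_residual_sd_um,
                 n_pairs = as.integer(j$n_pairs)),
            class = "affine_correction")
}
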