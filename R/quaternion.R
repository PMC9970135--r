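#' Quaternion algebra for wearable orientation streams
#'
#' Quaternions are represented scalar-first as numeric vectors `c(w, x, y, z)`
#' or as n x 4 matrices (one quaternion per row) under the Hamilton product
#' convention. All public operations accept either form; matrix inputs are
#' processed row-wise.
#'
#' @name quaternion-algebra
NULL

as_quat_matrix <- function(q) {
  if (is.matrix(q)) {
    if (ncol(q) != 4L) stop("quaternion matrix must have 4 columns (w, x, y, z)")
    q
  } else {
    if (length(q) != 4L) stop("a quaternion has 4 components (w, x, y, z)")
    matrix(q, nrow = 1L)
  }
}

restore_quat_shape <- function(m, template) {
  if (is.matrix(template)) m else drop(m)
}

#' Quaternion norm
#'
#' @param q quaternion as length-4 vector `(w, x, y, z)` or n x 4 matrix.
#' @return Euclidean norm, one value per quaternion.
#' @export
quat_norm <- function(q) {
  m <- as_quat_matrix(q)
  sqrt(rowSums(m^2))
}

#' Normalize quaternions to unit norm
#'
#' @inheritParams quat_norm
#' @return Unit-norm quaternion(s) in the same shape as the input.
#' @export
quat_normalize <- function(q) {
  m <- as_quat_matrix(q)
  n <- sqrt(rowSums(m^2))
  if (any(n < .Machine$double.eps)) stop("cannot normalize a zero quaternion")
  restore_quat_shape(m / n, q)
}

#' Quaternion conjugate
#'
#' Negates the vector part: `(w, x, y, z) -> (w, -x, -y, -z)`. For a unit
#' quaternion the conjugate is the inverse rotation.
#'
#' @inheritParams quat_norm
#' @return Conjugated quaternion(s) in the same shape as the input.
#' @export
quat_conjugate <- function(q) {
  m <- as_quat_matrix(q)
  m[, 2:4] <- -m[, 2:4]
  restore_quat_shape(m, q)
}

#' Hamilton product of quaternions
#'
#' Row-wise Hamilton product `a %*% b` under the scalar-first (w, x, y, z)
#' convention, so `(0,1,0,0) x (0,0,1,0) = (0,0,0,1)` (i x j = k). Matrix
#' inputs must have equal row counts (or one of them a single quaternion,
#' which is recycled).
#'
#' @param a,b quaternions as length-4 vectors or n x 4 matrices.
#' @return The product, as a matrix if either input was a matrix with more
#'   than one row, otherwise a length-4 vector.
#' @export
quat_multiply <- function(a, b) {
  ma <- as_quat_matrix(a)
  mb <- as_quat_matrix(b)
  if (nrow(ma) != nrow(mb)) {
    if (nrow(ma) == 1L) ma <- ma[rep(1L, nrow(mb)), , drop = FALSE]
    else if (nrow(mb) == 1L) mb <- mb[rep(1L, nrow(ma)), , drop = FALSE]
    else stop("quaternion sequences have different lengths")
  }
  # grouped so that q (x) conj(q) cancels exactly in floating point
  w <- (ma[, 1] * mb[, 1] - ma[, 2] * mb[, 2]) - (ma[, 3] * mb[, 3] + ma[, 4] * mb[, 4])
  x <- (ma[, 1] * mb[, 2] + ma[, 2] * mb[, 1]) + (ma[, 3] * mb[, 4] - ma[, 4] * mb[, 3])
  y <- (ma[, 1] * mb[, 3] + ma[, 3] * mb[, 1]) + (ma[, 4] * mb[, 2] - ma[, 2] * mb[, 4])
  z <- (ma[, 1] * mb[, 4] + ma[, 4] * mb[, 1]) + (ma[, 2] * mb[, 3] - ma[, 3] * mb[, 2])
  out <- cbind(w, x, y, z, deparse.level = 0)
  colnames(out) <- c("w", "x", "y", "z")
  if (is.matrix(a) && nrow(as_quat_matrix(a)) > 1L ||
      is.matrix(b) && nrow(as_quat_matrix(b)) > 1L) out else drop(out)
}

#' Axis-angle rotation quaternion
#'
#' @param angle rotation angle(s) in radians (vectorized).
#' @param axis length-3 unit axis; normalized if it is not.
#' @return Unit quaternion(s): a length-4 vector, or an n x 4 matrix when
#'   `angle` has length > 1.
#' @export
quat_from_axis_angle <- function(angle, axis) {
  if (length(axis) != 3L) stop("axis must have 3 components")
  axis <- axis / sqrt(sum(axis^2))
  half <- angle / 2
  out <- cbind(w = cos(half),
               x = sin(half) * axis[1],
               y = sin(half) * axis[2],
               z = sin(half) * axis[3])
  if (length(angle) > 1L) out else drop(out)
}

#' Rotation angle of unit quaternions
#'
#' @inheritParams quat_norm
#' @return Rotation angle(s) in radians, in `[0, pi]`.
#' @export
quat_angle <- function(q) {
  m <- as_quat_matrix(q)
  2 * acos(pmin(1, abs(m[, 1])))
}

#' Construct a quaternion time series for one sensor unit
#'
#' Ingest normalizes every quaternion to unit norm (tolerance 1e-6 on the
#' incoming norm is asserted after normalization) and validates the timestamp
#' grid. Rows that are entirely `NA` are kept as gap placeholders for
#' [fill_missing()].
#'
#' @param t timestamps in seconds, strictly increasing.
#' @param q n x 4 matrix of quaternion components (w, x, y, z).
#' @param unit_id one of `"thorax"`, `"abdomen"`, `"reference"`.
#' @param fs nominal sampling rate in Hz (default 10).
#' @return A `quat_series` object: list with elements `t`, `q`, `unit_id`,
#'   `fs`.
#' @export
quat_series <- function(t, q, unit_id = c("thorax", "abdomen", "reference"),
                        fs = 10) {
  unit_id <- match.arg(unit_id)
  q <- as_quat_matrix(q)
  if (length(t) != nrow(q)) stop("timestamps and quaternions differ in length")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  missing_row <- rowSums(is.na(q)) > 0
  if (any(missing_row & rowSums(is.na(q)) != 4L))
    stop("partially missing quaternion rows are not allowed")
  if (any(!missing_row)) {
    q[!missing_row, ] <- as_quat_matrix(quat_normalize(q[!missing_row, , drop = FALSE]))
  }
  colnames(q) <- c("w", "x", "y", "z")
  structure(list(t = as.numeric(t), q = q, unit_id = unit_id, fs = fs),
            class = "quat_series")
}

#' @export
print.quat_series <- function(x, ...) {
  cat(sprintf("<quat_series> unit=%s  n=%d  fs=%g Hz  duration=%.1f s  missing=%d\n",
              x$unit_id, nrow(x$q), x$fs,
              if (nrow(x$q)) diff(range(x$t)) + 1 / x$fs else 0,
              sum(is.na(x$q[, 1]))))
  invisible(x)
}

#' @export
length.quat_series <- function(x) nrow(x$q)

#' Relative orientation of a sensor unit with respect to the reference unit
#'
#' Computes, sample by sample, `unit (x) conjugate(ref)`: the orientation of
#' the thoracic or abdominal unit expressed in the reference unit's frame.
#' When the reference carries exactly the shared trunk motion, the result is
#' the residual (breathing-related) rotation. The output is renormalized and
#' given a canonical sign (`w >= 0`) so that double-cover flips between `q`
#' and `-q` cannot inject artificial steps into the baseline.
#'
#' @param unit,ref `quat_series` objects of equal length with aligned
#'   timestamps; `ref` should be the reference unit.
#' @return A `quat_series` with the unit id of `unit`.
#' @export
relative_series <- function(unit, ref) {
  stopifnot(inherits(unit, "quat_series"), inherits(ref, "quat_series"))
  if (length(unit) != length(ref))
    stop("alignment error: series have different lengths")
  if (max(abs(unit$t - ref$t)) > 1e-9)
    stop("alignment error: timestamps do not match")
  q <- quat_multiply(unit$q, quat_conjugate(ref$q))
  q <- as_quat_matrix(quat_normalize(q))
  flip <- q[, 1] < 0
  q[flip, ] <- -q[flip, , drop = FALSE]
  quat_series(unit$t, q, unit$unit_id, fs = unit$fs)
}
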