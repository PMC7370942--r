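#' Cap/head transform: rotation, per-axis scaling and translation
#'
#' The transform family assumed by the registration model: the cap (or the
#' whole marked constellation) may rotate rigidly and scale along the
#' anterior-posterior and left-right axes; the vertical scale is fixed at 1
#' by default. Two compositions are supported, selected by `scale_in`:
#'
#' * `"subject"`: `x' = R %*% S %*% x + t` — scaling acts in the source
#'   (head) frame before rotation. This is the generator convention used by
#'   [simulate_subject()].
#' * `"reference"`: `x' = S %*% R %*% x + t` — scaling acts along the
#'   reference (MNI) axes after rotation, which is the natural model when
#'   the subject cloud has an arbitrary orientation. Used by
#'   [fit_head_transform()]. It is the exact inverse family of `"subject"`.
#'
#' `S = diag(scale_lr, scale_ap, scale_vert)` under the package axis
#' convention (x = left-right, y = anterior-posterior, z = vertical).
#'
#' @param rotation 3x3 rotation matrix (det +1, orthonormal).
#' @param scale_ap,scale_lr,scale_vert positive scale factors.
#' @param translation length-3 numeric, mm.
#' @param scale_in `"subject"` or `"reference"` (see above).
#' @return An object of class `cap_transform`.
#' @seealso [apply_transform()], [rotation_matrix()], [fit_head_transform()]
#' @export
cap_transform <- function(rotation = diag(3), scale_ap = 1, scale_lr = 1,
                          scale_vert = 1, translation = c(0, 0, 0),
                          scale_in = c("subject", "reference")) {
  scale_in <- match.arg(scale_in)
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      abs(det(rotation) - 1) > 1e-9 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop_capreg("invalid_parameter",
                "`rotation` must be a 3x3 rotation matrix with det +1")
  if (any(c(scale_ap, scale_lr, scale_vert) <= 0))
    stop_capreg("invalid_parameter", "scale factors must be positive")
  structure(list(rotation = rotation, scale_ap = scale_ap,
                 scale_lr = scale_lr, scale_vert = scale_vert,
                 translation = as.numeric(translation), scale_in = scale_in),
            class = "cap_transform")
}

#' @export
print.cap_transform <- function(x, ...) {
  cat("cap_transform (scale applied in", x$scale_in, "frame)\n")
  cat(sprintf("  scales  LR %.4f  AP %.4f  vert %.4f\n",
              x$scale_lr, x$scale_ap, x$scale_vert))
  cat(sprintf("  translation (%.3f, %.3f, %.3f) mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("  rotation angle %.3f deg\n", ang))
  invisible(x)
}

#' Rotation matrix from extrinsic XYZ Euler angles (degrees)
#'
#' `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)`, angles in degrees.
#'
#' @param angles_deg length-3 numeric: rotations about x, y, z in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(angles_deg) {
  a <- as.numeric(angles_deg) * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

transform_scale_matrix <- function(tf) {
  diag(c(tf$scale_lr, tf$scale_ap, tf$scale_vert))
}

transform_linear_part <- function(tf) {
  S <- transform_scale_matrix(tf)
  if (tf$scale_in == "subject") tf$rotation %*% S else S %*% tf$rotation
}

#' Apply a cap_transform to points
#'
#' @param transform a [cap_transform()].
#' @param points n x 3 numeric matrix (rows = points, mm), or a length-3
#'   vector.
#' @return Transformed points, same shape; row/entry names preserved.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "cap_transform"))
  A <- transform_linear_part(transform)
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, nrow = 1)
  out <- points %*% t(A) +
    matrix(transform$translation, nrow(points), 3, byrow = TRUE)
  rownames(out) <- rownames(points)
  colnames(out) <- c("x", "y", "z")
  if (vec) drop(out) else out
}

#' Invert a cap_transform
#'
#' The inverse of a `"subject"`-frame transform is a `"reference"`-frame
#' transform with reciprocal scales and transposed rotation, and vice versa.
#'
#' @param transform a [cap_transform()].
#' @return The inverse [cap_transform()].
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "cap_transform"))
  Rt <- t(transform$rotation)
  other <- if (transform$scale_in == "subject") "reference" else "subject"
  A <- transform_linear_part(transform)
  cap_transform(rotation = Rt,
                scale_ap = 1 / transform$scale_ap,
                scale_lr = 1 / transform$scale_lr,
                scale_vert = 1 / transform$scale_vert,
                translation = as.numeric(-solve(A, transform$translation)),
                scale_in = other)
}

# Closed-form similarity transform (rotation + uniform scale + translation)
# from rows of X onto rows of Y, least squares (Umeyama / Horn).
# Returns list(R, s, t) with y ~= s * R x + t, or NULL if degenerate.
fit_similarity <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  C <- crossprod(Yc, Xc) / n
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  varx <- sum(Xc^2) / n
  if (varx < 1e-12) return(NULL)
  s <- sum(sv$d * c(1, 1, d)) / varx
  if (!is.finite(s) || s <= 1e-12) return(NULL)
  t <- my - s * as.numeric(R %*% mx)
  list(R = R, s = s, t = t)
}

# rigid Kabsch (no scale); used for transform-fit initialisation
fit_rigid <- function(X, Y) {
  f <- fit_similarity(X, Y)
  if (is.null(f)) return(NULL)
  list(R = f$R, t = colMeans(Y) - as.numeric(f$R %*% colMeans(X)))
}
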