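#' Labeled fiducial set
#'
#' A set of named 3-D points (mm) drawn from the nine-label vocabulary
#' [FIDUCIAL_LABELS]: three head anatomical points (Nz, AL, AR) and six cap
#' sticker points (Cz, Pz, Iz, FRONT, LEFT, RIGHT). A full set has all nine;
#' a registration-grade subset needs at least five (the cap points carry
#' redundancy, so five cap points together with the head points suffice for
#' complete cap-head registration).
#'
#' @param points numeric matrix with 3 columns (x, y, z in mm) and rownames
#'   from [FIDUCIAL_LABELS], or a named list of length-3 vectors.
#' @return Object of class `fiducial_set`: a labeled n x 3 matrix.
#' @export
fiducial_set <- function(points) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop_capreg("invalid_parameter", "fiducial points must have 3 columns")
  labs <- rownames(points)
  if (is.null(labs) || anyNA(labs) || any(labs == ""))
    stop_capreg("invalid_parameter", "fiducial points must be labeled")
  bad <- setdiff(labs, FIDUCIAL_LABELS)
  if (length(bad))
    stop_capreg("invalid_parameter",
                paste0("unknown fiducial label(s): ",
                       paste(bad, collapse = ", ")))
  if (anyDuplicated(labs))
    stop_capreg("invalid_parameter", "fiducial labels must be unique")
  if (!all(is.finite(points)))
    stop_capreg("invalid_parameter", "fiducial coordinates must be finite")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  # canonical label order for the labels present
  points <- points[intersect(FIDUCIAL_LABELS, labs), , drop = FALSE]
  structure(points, class = c("fiducial_set", "matrix", "array"))
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat("fiducial_set:", nrow(x), "of 9 labels\n")
  print(format(round(unclass(x), 3)), quote = FALSE)
  invisible(x)
}

#' @export
`[.fiducial_set` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out) && identical(colnames(out), c("x", "y", "z")))
    class(out) <- c("fiducial_set", "matrix", "array")
  out
}

is_full_fiducial_set <- function(x) {
  inherits(x, "fiducial_set") && nrow(x) == 9L
}

#' Colored point cloud
#'
#' The stand-in for the structure-from-motion reconstruction: vertex
#' positions (mm) with per-vertex RGB colors (0-255 integers).
#'
#' @param positions n x 3 numeric matrix, mm.
#' @param colors n x 3 matrix of RGB values in 0..255.
#' @return Object of class `colored_point_cloud`.
#' @export
colored_point_cloud <- function(positions, colors) {
  positions <- as.matrix(positions)
  colors <- as.matrix(colors)
  if (ncol(positions) != 3L || ncol(colors) != 3L ||
      nrow(positions) != nrow(colors) || nrow(positions) < 1L)
    stop_capreg("invalid_parameter",
                "positions and colors must be matching n x 3 matrices, n >= 1")
  if (!all(is.finite(positions)))
    stop_capreg("invalid_parameter", "positions must be finite")
  if (any(colors < 0 | colors > 255))
    stop_capreg("invalid_parameter", "colors must lie in 0..255")
  storage.mode(positions) <- "double"
  colors <- round(colors)
  storage.mode(colors) <- "integer"
  colnames(positions) <- c("x", "y", "z")
  colnames(colors) <- c("red", "green", "blue")
  structure(list(positions = positions, colors = colors),
            class = "colored_point_cloud")
}

#' @export
print.colored_point_cloud <- function(x, ...) {
  cat("colored_point_cloud:", nrow(x$positions), "vertices\n")
  invisible(x)
}

# hue in [0,1) per color row; returns NA for pixels with zero
# saturation/value (hue undefined there)
rgb_to_hue <- function(colors) {
  m <- t(as.matrix(colors))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  h <- hsv[1L, ]
  h[hsv[2L, ] <= 0 | hsv[3L, ] <= 0] <- NA_real_
  h
}

# circular hue distance on the unit hue circle
hue_distance <- function(h, h0) {
  d <- abs(h - h0) %% 1
  pmin(d, 1 - d)
}
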