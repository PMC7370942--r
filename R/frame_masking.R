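# Frame masking: white balance, sticker-circle detection, cap segmentation,
# face polygon, mask composition and over-masked frame rejection.

#' Video frame container
#'
#' @param pixels H x W x 3 array of RGB values in 0..255 (H, W >= 16).
#' @param frame_index integer frame number.
#' @param timestamp_s acquisition time in seconds (frames are assumed to
#'   come from 240 fps slow-motion video; timestamps let the external SfM
#'   stage restrict correspondences to a two-second window).
#' @return Object of class `capreg_frame`.
#' @export
capreg_frame <- function(pixels, frame_index = 1L, timestamp_s = 0) {
  pixels <- as.array(pixels)
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L || d[1] < 16L || d[2] < 16L)
    stop_capreg("invalid_parameter",
                "`pixels` must be an H x W x 3 array with H, W >= 16")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_capreg("invalid_parameter", "pixel values must lie in 0..255")
  structure(list(pixels = pixels, frame_index = as.integer(frame_index),
                 timestamp_s = as.numeric(timestamp_s)),
            class = "capreg_frame")
}

#' @export
print.capreg_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("capreg_frame %d: %d x %d px, t = %.4f s\n",
              x$frame_index, d[1], d[2], x$timestamp_s))
  invisible(x)
}

frame_dim <- function(frame) dim(frame$pixels)[1:2]

#' Gray-world white balance
#'
#' Scales each channel so its mean equals the global gray mean, clipping to
#' 0..255. Idempotent up to clipping on already-balanced frames.
#'
#' @param frame a [capreg_frame()].
#' @return The balanced `capreg_frame`.
#' @export
white_balance <- function(frame) {
  stopifnot(inherits(frame, "capreg_frame"))
  px <- frame$pixels
  means <- c(mean(px[, , 1]), mean(px[, , 2]), mean(px[, , 3]))
  if (all(means == 0))
    stop_capreg("degenerate_input", "cannot white-balance an all-black frame")
  gray <- mean(means)
  gains <- ifelse(means > 0, gray / means, 1)
  for (ch in 1:3) px[, , ch] <- pmin(255, pmax(0, px[, , ch] * gains[ch]))
  frame$pixels <- px
  frame
}

# hue (in [0,1), NA where undefined) for every pixel of a frame
frame_hue <- function(frame) {
  px <- frame$pixels
  h <- rgb_to_hue(cbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                        as.vector(px[, , 3])))
  matrix(h, dim(px)[1], dim(px)[2])
}

# 8-connected component labeling of a logical matrix; returns integer
# matrix (0 = background)
connected_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  idx <- which(mask)
  stack <- integer(length(idx))
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- cur
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      r <- ((p - 1L) %% H) + 1L
      c <- ((p - 1L) %/% H) + 1L
      for (dc in -1:1) {
        cc <- c + dc
        if (cc < 1L || cc > W) next
        base <- (cc - 1L) * H
        for (dr in -1:1) {
          rr <- r + dr
          if (rr < 1L || rr > H) next
          q <- base + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            top <- top + 1L
            stack[top] <- q
          }
        }
      }
    }
  }
  lab
}

# exact minimum enclosing circle (Welzl, move-to-front) of (row,col) points
min_enclosing_circle <- function(pts) {
  circ2 <- function(a, b) {
    c((a + b) / 2, sqrt(sum((a - b)^2)) / 2)
  }
  circ3 <- function(a, b, c3) {
    d <- 2 * (a[1] * (b[2] - c3[2]) + b[1] * (c3[2] - a[2]) +
                c3[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) return(NULL)
    ux <- (sum(a^2) * (b[2] - c3[2]) + sum(b^2) * (c3[2] - a[2]) +
             sum(c3^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c3[1] - b[1]) + sum(b^2) * (a[1] - c3[1]) +
             sum(c3^2) * (b[1] - a[1])) / d
    cen <- c(ux, uy)
    c(cen, sqrt(sum((a - cen)^2)))
  }
  inside <- function(circ, p) sum((p - circ[1:2])^2) <= circ[3]^2 + 1e-9
  trivial <- function(S) {
    n <- nrow(S)
    if (n == 0L) return(c(0, 0, 0))
    if (n == 1L) return(c(S[1, ], 0))
    if (n == 2L) return(circ2(S[1, ], S[2, ]))
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      cc <- circ2(S[pair[1], ], S[pair[2], ])
      if (all(apply(S, 1, function(p) inside(cc, p)))) return(cc)
    }
    cc <- circ3(S[1, ], S[2, ], S[3, ])
    if (is.null(cc)) circ2(S[which.max(dist(S))[1], ], S[1, ]) else cc
  }
  welzl <- function(P, S) {
    if (nrow(P) == 0L || nrow(S) == 3L) return(trivial(S))
    p <- P[nrow(P), ]
    cc <- welzl(P[-nrow(P), , drop = FALSE], S)
    if (inside(cc, p)) return(cc)
    welzl(P[-nrow(P), , drop = FALSE], rbind(S, p))
  }
  pts <- unique(as.matrix(pts))
  # deterministic shuffle keeps expected-linear behaviour without RNG state
  o <- order((seq_len(nrow(pts)) * 2654435761) %% 4294967296)
  welzl(pts[o, , drop = FALSE], matrix(numeric(0), 0, 2))
}

#' Detect fiducial-sticker circles in a frame
#'
#' Classifies every 8-connected cluster of at least `min_pixels` pixels
#' whose hue lies within `hue_tol` of the sticker hue (wrapping around the
#' hue circle) as one sticker, and defines a circle around the cluster —
#' the exact minimum enclosing circle with an additional margin of 20% of
#' its radius. Pixels with undefined hue (zero saturation or value) never
#' match.
#'
#' @param frame a [capreg_frame()].
#' @param sticker_hue sticker hue in \[0, 1).
#' @param hue_tol tolerance as a fraction of the hue circle, in (0, 0.5);
#'   default 0.15.
#' @param min_pixels minimum cluster size (default 5).
#' @param margin circle margin as a fraction of the radius (default 0.2).
#' @return List of `sticker_detection` objects, each with `center_px`
#'   (row, col), `radius_px` (margin included), `pixel_count`, `mean_hue`.
#'   Empty list when nothing is detected.
#' @export
detect_stickers <- function(frame, sticker_hue, hue_tol = 0.15,
                            min_pixels = 5L, margin = 0.2) {
  stopifnot(inherits(frame, "capreg_frame"))
  if (!is.finite(hue_tol) || hue_tol <= 0 || hue_tol >= 0.5)
    stop_capreg("invalid_parameter", "`hue_tol` must lie in (0, 0.5)")
  if (!is.finite(sticker_hue) || sticker_hue < 0 || sticker_hue >= 1)
    stop_capreg("invalid_parameter", "`sticker_hue` must lie in [0, 1)")
  hmat <- frame_hue(frame)
  inhue <- !is.na(hmat) & hue_distance(hmat, sticker_hue) <= hue_tol
  if (!any(inhue)) return(list())
  lab <- connected_components(inhue)
  out <- list()
  for (k in seq_len(max(lab))) {
    pix <- which(lab == k)
    if (length(pix) < min_pixels) next
    H <- nrow(hmat)
    pts <- cbind(((pix - 1L) %% H) + 1L, ((pix - 1L) %/% H) + 1L)
    mec <- min_enclosing_circle(pts)
    out[[length(out) + 1L]] <- structure(
      list(center_px = c(row = mec[1], col = mec[2]),
           radius_px = mec[3] * (1 + margin),
           pixel_count = length(pix),
           mean_hue = mean(hmat[pix])),
      class = "sticker_detection")
  }
  out
}

#' @export
print.sticker_detection <- function(x, ...) {
  cat(sprintf("sticker_detection: center (%.2f, %.2f), radius %.2f px, %d px, hue %.3f\n",
              x$center_px[1], x$center_px[2], x$radius_px,
              x$pixel_count, x$mean_hue))
  invisible(x)
}

#' Segment the cap in a frame
#'
#' The trained segmentation network used in production is out of scope
#' here; any segmenter honouring the mask contract (function from frame to
#' H x W logical matrix) can be plugged in. The default fallback marks
#' pixels whose hue falls in either of the two configured cap-pattern hue
#' bands.
#'
#' @param frame a [capreg_frame()].
#' @param segmenter optional function `frame -> logical H x W matrix`.
#' @param cap_hues length-2 numeric, hue centers of the two pattern colors
#'   (defaults match the default synthetic pattern: red and blue).
#' @param hue_tol half-width of each hue band (fraction of hue circle).
#' @return Logical H x W cap mask.
#' @export
segment_cap <- function(frame, segmenter = NULL,
                        cap_hues = c(0, 2 / 3), hue_tol = 0.08) {
  stopifnot(inherits(frame, "capreg_frame"))
  d <- frame_dim(frame)
  if (!is.null(segmenter)) {
    mask <- segmenter(frame)
    if (!is.matrix(mask) || !all(dim(mask) == d))
      stop_capreg("contract_violation",
                  "segmenter must return a logical H x W matrix of frame size")
    return(matrix(as.logical(mask), d[1], d[2]))
  }
  hmat <- frame_hue(frame)
  mask <- matrix(FALSE, d[1], d[2])
  ok <- !is.na(hmat)
  for (h0 in cap_hues)
    mask[ok & hue_distance(hmat, h0) <= hue_tol] <- TRUE
  mask
}

#' Face polygon mask
#'
#' Fills the convex polygon connecting the nose, external eye edges and
#' forehead. Landmark acquisition (an external face detector) is pluggable
#' and out of scope; this takes the four landmark pixel positions directly.
#'
#' @param landmarks named list with entries `nose`, `left_eye`, `right_eye`,
#'   `forehead`, each a (row, col) pixel position.
#' @param height,width frame size in pixels.
#' @return Logical H x W mask.
#' @export
face_polygon <- function(landmarks, height, width) {
  need <- c("nose", "left_eye", "right_eye", "forehead")
  miss <- setdiff(need, names(landmarks))
  if (length(miss))
    stop_capreg("incomplete_landmarks",
                paste0("missing landmark(s): ", paste(miss, collapse = ", ")))
  pts <- do.call(rbind, landmarks[need])
  cen <- colMeans(pts)
  cpts <- sweep(pts, 2, cen)
  if (svd(cpts)$d[2] < 1e-9)
    stop_capreg("degenerate_polygon", "landmarks are collinear or coincident")
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  convex_polygon_mask(height, width, pts[hull, , drop = FALSE])
}

#' Compose the crop mask and blacken the rest of the frame
#'
#' The kept region is the union of the cap mask, the face mask and the
#' detected sticker circles; everything outside is set to black.
#'
#' @param frame a [capreg_frame()].
#' @param cap_mask,face_mask logical H x W matrices (either may be NULL).
#' @param stickers list of `sticker_detection` objects (may be empty).
#' @return List: `frame` (cropped) and `mask`, a `crop_mask` object with
#'   the logical mask and its `kept_fraction`.
#' @export
compose_and_apply <- function(frame, cap_mask = NULL, face_mask = NULL,
                              stickers = list()) {
  stopifnot(inherits(frame, "capreg_frame"))
  d <- frame_dim(frame)
  keep <- matrix(FALSE, d[1], d[2])
  for (m in list(cap_mask, face_mask)) {
    if (is.null(m)) next
    if (!is.matrix(m) || !all(dim(m) == d))
      stop_capreg("contract_violation", "mask size does not match frame")
    keep <- keep | m
  }
  for (s in stickers)
    keep <- keep | disk_mask(d[1], d[2], s$center_px[1], s$center_px[2],
                             s$radius_px)
  px <- frame$pixels
  for (ch in 1:3) {
    lay <- px[, , ch]
    lay[!keep] <- 0
    px[, , ch] <- lay
  }
  frame$pixels <- px
  mask <- structure(list(mask = keep, kept_fraction = mean(keep)),
                    class = "crop_mask")
  list(frame = frame, mask = mask)
}

#' @export
print.crop_mask <- function(x, ...) {
  cat(sprintf("crop_mask: %.1f%% kept\n", 100 * x$kept_fraction))
  invisible(x)
}

#' Reject an over-masked frame
#'
#' A frame is rejected when strictly more than `threshold` of it is
#' blackened (default 0.98); a frame with exactly 98% blackened is kept.
#'
#' @param mask a `crop_mask` from [compose_and_apply()].
#' @param threshold blackened-fraction threshold in (0, 1\].
#' @return `TRUE` if the frame should be rejected.
#' @export
reject_frame <- function(mask, threshold = 0.98) {
  stopifnot(inherits(mask, "crop_mask"))
  if (!is.finite(threshold) || threshold <= 0 || threshold > 1)
    stop_capreg("invalid_parameter", "`threshold` must lie in (0, 1]")
  (1 - mask$kept_fraction) > threshold
}
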