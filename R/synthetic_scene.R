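# Synthetic-scene generator: ground-truth heads, cap placements, colored
# point clouds, patterned cap textures and rendered frames, so every
# downstream stage is testable without real recordings.

# map a direction (any nonzero vector) onto the ellipsoid with the given
# semi-axes; scale-invariant in `d`
ellipsoid_point <- function(d, semi_axes) {
  d / sqrt(sum((d / semi_axes)^2))
}

canonical_fiducial_directions <- function() {
  path <- system.file("extdata", "fiducial_directions.csv", package = "capreg")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, c("dx", "dy", "dz")])
  rownames(m) <- tab$label
  m
}

# probe channels sit between these fiducial pairs, on the head surface
PROBE_PAIRS <- list(
  c("Cz", "FRONT"), c("Cz", "Pz"), c("Cz", "LEFT"), c("Cz", "RIGHT"),
  c("Pz", "Iz"), c("FRONT", "LEFT"), c("FRONT", "RIGHT"),
  c("Pz", "LEFT"), c("Pz", "RIGHT"), c("Cz", "Iz"))

#' Generate a ground-truth model head
#'
#' Builds the synthetic stand-in for the reference capture: an ellipsoidal
#' head point set with the nine fiducials placed at canonical 10-20-like
#' directions (Nz anterior, AL/AR lateral at ear height, Cz at the vertex,
#' Pz/Iz posterior, FRONT/LEFT/RIGHT at the cap edges; directions shipped in
#' `extdata/fiducial_directions.csv`) and ten probe channels placed on the
#' surface between fiducial pairs. Axis convention: x = left-right,
#' y = anterior-posterior, z = up; origin at the head center; mm.
#'
#' @param semi_axes length-3 positive numeric, ellipsoid semi-axes (mm)
#'   along (x, y, z). Default `c(80, 95, 90)` approximates an adult head.
#' @param n_surface_points number of random surface vertices (>= 100).
#' @param seed integer seed; the same seed reproduces identical coordinates.
#' @return Object of class `ground_truth_scene`: list with `head_vertices`
#'   (n x 3), `fiducials` ([fiducial_set()], 9 labels), `probes` (named
#'   matrix of channel positions), `applied_transform` (identity
#'   [cap_transform()]), `semi_axes`, `seed`.
#' @examples
#' scene <- make_model_head(seed = 1)
#' scene$fiducials
#' @export
make_model_head <- function(semi_axes = c(80, 95, 90),
                            n_surface_points = 2000, seed = 0) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) ||
      any(semi_axes <= 0))
    stop_capreg("invalid_parameter", "`semi_axes` must be 3 positive lengths")
  if (n_surface_points < 100)
    stop_capreg("invalid_parameter", "`n_surface_points` must be >= 100")

  dirs <- canonical_fiducial_directions()
  fid <- t(apply(dirs, 1, ellipsoid_point, semi_axes = semi_axes))
  fiducials <- fiducial_set(fid)

  probes <- t(vapply(PROBE_PAIRS, function(pr) {
    ellipsoid_point(colSums(fiducials[pr, , drop = FALSE]) / 2, semi_axes)
  }, numeric(3)))
  rownames(probes) <- sprintf("CH%02d", seq_along(PROBE_PAIRS))
  colnames(probes) <- c("x", "y", "z")

  head_vertices <- with_seed(seed, {
    d <- matrix(stats::rnorm(3 * n_surface_points), ncol = 3)
    t(apply(d, 1, ellipsoid_point, semi_axes = semi_axes))
  })
  colnames(head_vertices) <- c("x", "y", "z")

  structure(list(head_vertices = head_vertices, fiducials = fiducials,
                 probes = probes, applied_transform = cap_transform(),
                 semi_axes = semi_axes, seed = seed),
            class = "ground_truth_scene")
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat("ground_truth_scene:", nrow(x$head_vertices), "head vertices,",
      nrow(x$fiducials), "fiducials,", nrow(x$probes), "probes\n")
  print(x$applied_transform)
  invisible(x)
}

#' Simulate a subject capture as a colored point cloud
#'
#' Applies the assumed placement model to a ground-truth scene — a rigid
#' rotation (subject pose) composed with anterior-posterior and left-right
#' scaling about the head center (head-size accommodation of the cap) — and
#' emits the structure-from-motion stand-in: each fiducial becomes a
#' cluster of `points_per_sticker` sticker-colored vertices with isotropic
#' Gaussian noise, head vertices are colored with the two cap-pattern
#' colors, and the returned scene carries the transformed ground truth.
#'
#' @param scene a [make_model_head()] scene with all nine fiducials.
#' @param rotation_deg length-3 rotation angles about (x, y, z), degrees.
#' @param scale_ap,scale_lr scale factors along the anterior-posterior (y)
#'   and left-right (x) axes, applied before rotation.
#' @param noise_sd_mm isotropic Gaussian noise sd for every emitted vertex
#'   (>= 0).
#' @param points_per_sticker vertices per sticker cluster (>= 5).
#' @param seed integer seed.
#' @param sticker_color RGB 0..255; default saturated green.
#' @param cap_colors 2 x 3 RGB matrix for the two cap-pattern colors.
#' @return List with `cloud` ([colored_point_cloud()]) and `scene` (the
#'   transformed `ground_truth_scene`, `applied_transform` recording the
#'   transform).
#' @export
simulate_subject <- function(scene, rotation_deg = c(0, 0, 0),
                             scale_ap = 1, scale_lr = 1,
                             noise_sd_mm = 0.5, points_per_sticker = 200,
                             seed = 0,
                             sticker_color = c(0, 255, 0),
                             cap_colors = rbind(c(200, 40, 40),
                                                c(40, 40, 200))) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  if (!is_full_fiducial_set(scene$fiducials))
    stop_capreg("incomplete_scene",
                "input scene must contain all nine fiducials")
  if (noise_sd_mm < 0)
    stop_capreg("invalid_parameter", "`noise_sd_mm` must be >= 0")
  if (points_per_sticker < 5)
    stop_capreg("invalid_parameter", "`points_per_sticker` must be >= 5")

  tf <- cap_transform(rotation = rotation_matrix(rotation_deg),
                      scale_ap = scale_ap, scale_lr = scale_lr,
                      scale_vert = 1, scale_in = "subject")
  fid_t <- fiducial_set(apply_transform(tf, scene$fiducials))
  probes_t <- apply_transform(tf, scene$probes)
  head_t <- apply_transform(tf, scene$head_vertices)

  n_head <- nrow(head_t)
  n_stick <- 9L * points_per_sticker
  out <- with_seed(seed, {
    stick <- fid_t[rep(seq_len(9L), each = points_per_sticker), ,
                   drop = FALSE]
    if (noise_sd_mm > 0) {
      stick <- stick + matrix(stats::rnorm(3 * n_stick, sd = noise_sd_mm),
                              ncol = 3)
      head_n <- head_t + matrix(stats::rnorm(3 * n_head, sd = noise_sd_mm),
                                ncol = 3)
    } else head_n <- head_t
    list(stick = stick, head = head_n)
  })

  pos <- rbind(out$head, unclass(out$stick))
  cap_col <- cap_colors[rep_len(c(1L, 2L), n_head), , drop = FALSE]
  cols <- rbind(cap_col,
                matrix(sticker_color, n_stick, 3, byrow = TRUE))
  cloud <- colored_point_cloud(pos, cols)

  scene_t <- scene
  scene_t$head_vertices <- head_t
  scene_t$fiducials <- fid_t
  scene_t$probes <- probes_t
  scene_t$applied_transform <- tf
  scene_t$seed <- seed
  list(cloud = cloud, scene = scene_t)
}

# single octave of 2-D lattice gradient noise on a pixel grid
perlin_octave <- function(width, height, cell) {
  nx <- ceiling(width / cell) + 1L
  ny <- ceiling(height / cell) + 1L
  ang <- matrix(stats::runif(nx * ny, 0, 2 * pi), ny, nx)
  gx <- cos(ang); gy <- sin(ang)

  px <- (seq_len(width) - 0.5) / cell   # continuous lattice coords
  py <- (seq_len(height) - 0.5) / cell
  ix <- pmin(floor(px), nx - 2L); iy <- pmin(floor(py), ny - 2L)
  fx <- px - ix; fy <- py - iy
  fade <- function(u) u * u * u * (u * (u * 6 - 15) + 10)
  ux <- fade(fx); uy <- fade(fy)

  FX <- matrix(fx, height, width, byrow = TRUE)
  FY <- matrix(fy, height, width)
  UX <- matrix(ux, height, width, byrow = TRUE)
  UY <- matrix(uy, height, width)
  IX <- matrix(ix, height, width, byrow = TRUE)
  IY <- matrix(iy, height, width)

  corner <- function(dx, dy) {
    idx <- cbind(as.vector(IY + dy + 1L), as.vector(IX + dx + 1L))
    matrix(gx[idx], height, width) * (FX - dx) +
      matrix(gy[idx], height, width) * (FY - dy)
  }
  n00 <- corner(0L, 0L); n10 <- corner(1L, 0L)
  n01 <- corner(0L, 1L); n11 <- corner(1L, 1L)
  nx0 <- n00 + UX * (n10 - n00)
  nx1 <- n01 + UX * (n11 - n01)
  nx0 + UY * (nx1 - nx0)
}

#' Two-color Perlin cap pattern
#'
#' Generates the feature-rich two-color pattern printed on the cap to help
#' multi-view correspondence: multi-octave 2-D gradient (Perlin) noise,
#' min-max normalised to \[0, 1\] and thresholded into exactly two colors.
#'
#' @param width_px,height_px image size in pixels (>= 16).
#' @param threshold threshold on the normalised field, in (0, 1).
#' @param seed integer seed.
#' @param colors 2 x 3 RGB matrix (rows: below- and above-threshold color);
#'   default red and blue.
#' @param octaves number of octaves (default 4, persistence 0.5).
#' @return `height_px x width_px x 3` array of RGB values in 0..255, with
#'   attribute `"binary"` holding the logical above-threshold matrix.
#' @export
perlin_pattern <- function(width_px, height_px, threshold = 0.5, seed = 0,
                           colors = rbind(c(200, 40, 40), c(40, 40, 200)),
                           octaves = 4L) {
  if (width_px < 16 || height_px < 16)
    stop_capreg("invalid_parameter", "pattern dimensions must be >= 16 px")
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop_capreg("invalid_parameter", "`threshold` must lie strictly in (0,1)")

  field <- with_seed(seed, {
    base_cell <- max(width_px, height_px) / 8
    f <- matrix(0, height_px, width_px)
    amp <- 1
    for (o in seq_len(octaves)) {
      cell <- max(base_cell / 2^(o - 1), 2)
      f <- f + amp * perlin_octave(width_px, height_px, cell)
      amp <- amp / 2
    }
    f
  })
  rng <- range(field)
  field <- (field - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  binary <- field >= threshold
  img <- array(0, c(height_px, width_px, 3L))
  for (ch in 1:3)
    img[, , ch] <- ifelse(binary, colors[2L, ch], colors[1L, ch])
  attr(img, "binary") <- binary
  img
}

# camera basis: z = forward (towards origin), x = image right,
# y = image down; returns list(Rview rows = x,y,z axes)
camera_basis <- function(cam) {
  f <- -cam / sqrt(sum(cam^2))
  up <- if (abs(f[3]) > 0.999) c(0, 1, 0) else c(0, 0, 1)
  right <- c(f[2] * up[3] - f[3] * up[2],
             f[3] * up[1] - f[1] * up[3],
             f[1] * up[2] - f[2] * up[1])
  right <- right / sqrt(sum(right^2))
  upv <- c(right[2] * f[3] - right[3] * f[2],
           right[3] * f[1] - right[1] * f[3],
           right[1] * f[2] - right[2] * f[1])
  rbind(right, -upv, f)
}

project_points <- function(points, cam, f_px, image_size) {
  Rv <- camera_basis(cam)
  pc <- sweep(as.matrix(points), 2, cam) %*% t(Rv)
  z <- pc[, 3]
  cx <- (image_size + 1) / 2
  list(col = cx + f_px * pc[, 1] / z,
       row = cx + f_px * pc[, 2] / z,
       depth = z)
}

#' Render synthetic frames of a scene
#'
#' Pinhole projection of the scene from each camera: the head silhouette
#' (convex hull of projected surface vertices) is textured with the
#' two-color cap pattern, visible fiducials are drawn as filled
#' sticker-colored disks of at least 5 px radius, and the background uses a
#' distinct dark color. A fiducial is visible when its outward surface
#' direction faces the camera (exact for a convex head).
#'
#' @param scene a `ground_truth_scene`.
#' @param camera_positions list of length-3 vectors or n x 3 matrix (mm);
#'   every camera must lie outside the head's bounding sphere.
#' @param image_size square frame size in pixels.
#' @param sticker_color RGB 0..255 disk color.
#' @param sticker_diameter_mm physical sticker diameter (default 10 mm; the
#'   projected disk radius is floored at 5 px).
#' @param cap_colors 2 x 3 RGB pattern colors; `background` RGB 0..255.
#' @return List: `frames` (list of `capreg_frame`) and `truth`, a data frame
#'   with one row per fiducial per frame (`frame_index`, `label`, `row`,
#'   `col`, `visible`).
#' @export
render_frames <- function(scene, camera_positions, image_size = 256,
                          sticker_color = c(0, 255, 0),
                          sticker_diameter_mm = 10,
                          cap_colors = rbind(c(200, 40, 40), c(40, 40, 200)),
                          background = c(40, 40, 40)) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  if (is.list(camera_positions)) camera_positions <- do.call(rbind, camera_positions)
  camera_positions <- matrix(as.numeric(camera_positions), ncol = 3)
  if (nrow(camera_positions) < 1L)
    stop_capreg("invalid_parameter", "need at least one camera")
  all_pts <- rbind(scene$head_vertices, unclass(scene$fiducials))
  rad <- sqrt(max(rowSums(all_pts^2)))
  dists <- sqrt(rowSums(camera_positions^2))
  if (any(dists <= rad))
    stop_capreg("invalid_camera",
                "camera position(s) inside the head's bounding sphere")

  centroid <- colMeans(scene$head_vertices)
  frames <- vector("list", nrow(camera_positions))
  truth <- vector("list", nrow(camera_positions))
  for (i in seq_len(nrow(camera_positions))) {
    cam <- camera_positions[i, ]
    f_px <- 0.4 * image_size * dists[i] / rad
    img <- array(0, c(image_size, image_size, 3L))
    for (ch in 1:3) img[, , ch] <- background[ch]

    # cap/head silhouette: filled convex hull of front-facing projections
    ph <- project_points(scene$head_vertices, cam, f_px, image_size)
    keep <- ph$depth > 0
    sil <- NULL
    if (sum(keep) >= 3) {
      pts <- cbind(ph$row[keep], ph$col[keep])
      hull <- grDevices::chull(pts[, 2], pts[, 1])
      sil <- convex_polygon_mask(image_size, image_size,
                                 pts[hull, , drop = FALSE])
      pat <- perlin_pattern(image_size, image_size, 0.5,
                            seed = (scene$seed %% 100000L) + 7919L * i,
                            colors = cap_colors)
      bin <- attr(pat, "binary")
      for (ch in 1:3) {
        lay <- img[, , ch]
        lay[sil] <- ifelse(bin[sil], cap_colors[2L, ch], cap_colors[1L, ch])
        img[, , ch] <- lay
      }
    }

    # visible fiducials as filled disks
    pf <- project_points(scene$fiducials, cam, f_px, image_size)
    outward <- unclass(scene$fiducials) -
      matrix(centroid, 9, 3, byrow = TRUE)
    to_cam <- matrix(cam, 9, 3, byrow = TRUE) - unclass(scene$fiducials)
    visible <- rowSums(outward * to_cam) > 0 & pf$depth > 0
    r_px <- pmax(5, f_px * (sticker_diameter_mm / 2) / pf$depth)
    for (k in which(visible)) {
      dm <- disk_mask(image_size, image_size, pf$row[k], pf$col[k], r_px[k])
      for (ch in 1:3) {
        lay <- img[, , ch]
        lay[dm] <- sticker_color[ch]
        img[, , ch] <- lay
      }
    }
    frames[[i]] <- capreg_frame(img, frame_index = i,
                                timestamp_s = (i - 1) / 240)
    truth[[i]] <- data.frame(frame_index = i,
                             label = rownames(scene$fiducials),
                             row = pf$row, col = pf$col, visible = visible,
                             stringsAsFactors = FALSE)
  }
  list(frames = frames, truth = do.call(rbind, truth))
}

# logical H x W mask of pixels within `radius` of (row0, col0)
disk_mask <- function(H, W, row0, col0, radius) {
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  (rows - row0)^2 + (cols - col0)^2 <= radius^2
}

# filled convex polygon given vertex (row, col) matrix in hull order
convex_polygon_mask <- function(H, W, verts) {
  n <- nrow(verts)
  cen <- colMeans(verts)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  mask <- matrix(TRUE, H, W)
  for (k in seq_len(n)) {
    a <- verts[k, ]; b <- verts[if (k == n) 1L else k + 1L, ]
    e <- b - a
    s <- sign(e[1] * (cen[2] - a[2]) - e[2] * (cen[1] - a[1]))
    if (s == 0) next
    side <- e[1] * (cols - a[2]) - e[2] * (rows - a[1])
    mask <- mask & (s * side >= 0)
  }
  mask
}
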