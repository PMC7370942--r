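# Fiducial recovery from the reconstructed point cloud: hue clustering of
# sticker-colored vertices and RANSAC label assignment against the model
# cap.

#' Extract fiducial cluster centroids from a colored point cloud
#'
#' Single-linkage clusters of sticker-colored vertices: a vertex is in-hue
#' when its hue lies within `hue_tol` of `sticker_hue` (wrapping around the
#' hue circle; vertices with undefined hue never match), and clusters are
#' the connected groups at link distance `link_radius_mm`. Clusters smaller
#' than `min_cluster_size` are dropped.
#'
#' @param cloud a [colored_point_cloud()].
#' @param sticker_hue sticker hue in \[0, 1); default 1/3 (green).
#' @param hue_tol hue tolerance, fraction of the hue circle.
#' @param link_radius_mm single-linkage merge radius (> 0), default 10 mm.
#' @param min_cluster_size minimum vertices per kept cluster (>= 1).
#' @return k x 3 matrix of cluster centroids (mm), possibly 0 rows; cluster
#'   sizes in attribute `"sizes"`. Order unspecified.
#' @export
extract_fiducial_clusters <- function(cloud, sticker_hue = 1 / 3,
                                      hue_tol = 0.15, link_radius_mm = 10,
                                      min_cluster_size = 5L) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  if (link_radius_mm <= 0)
    stop_capreg("invalid_parameter", "`link_radius_mm` must be > 0")
  if (min_cluster_size < 1)
    stop_capreg("invalid_parameter", "`min_cluster_size` must be >= 1")
  h <- rgb_to_hue(cloud$colors)
  sel <- !is.na(h) & hue_distance(h, sticker_hue) <= hue_tol
  pts <- cloud$positions[sel, , drop = FALSE]
  empty <- matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(pts) == 0L) return(empty)
  if (nrow(pts) == 1L) {
    if (min_cluster_size > 1L) return(empty)
    out <- pts
    attr(out, "sizes") <- 1L
    return(out)
  }
  grp <- stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                       h = link_radius_mm)
  sizes <- tabulate(grp)
  keep <- which(sizes >= min_cluster_size)
  if (!length(keep)) return(empty)
  cent <- t(vapply(keep, function(g) colMeans(pts[grp == g, , drop = FALSE]),
                   numeric(3)))
  colnames(cent) <- c("x", "y", "z")
  attr(cent, "sizes") <- sizes[keep]
  cent
}

#' Label fiducial centroids by RANSAC against the model cap
#'
#' Every hypothesis maps an ordered triple of model labels onto a triple of
#' observed centroids, fits the closed-form three-point similarity
#' transform (rotation + uniform scale + translation), projects the
#' remaining model fiducials through it, and is scored by the summed
#' distances under the optimal one-to-one assignment of remaining model
#' points to remaining centroids (exact, never double-matching). The
#' minimum-score hypothesis determines the full labeling. All
#' `choose(n,3) * 504` hypotheses are enumerated when at most nine
#' centroids are given; with more, centroid triples are sampled (seeded,
#' deterministic). Degenerate (collinear) triples are skipped; equal costs
#' resolve to the lexicographically first label triple.
#'
#' @param centroids k x 3 matrix of cluster centroids (k >= 5).
#' @param model [fiducial_set()] with all nine labels.
#' @param max_iterations sampled centroid triples when k > 9.
#' @param seed integer seed (sampling only).
#' @return Object of class `labeling_result`: `fiducials`
#'   ([fiducial_set()] of labeled centroids), `fit_cost_mm`, `transform`
#'   (the winning similarity as a [cap_transform()]), `n_points_used`.
#' @export
label_fiducials <- function(centroids, model, max_iterations = 2000L,
                            seed = 0) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 5L)
    stop_capreg("insufficient_points",
                "at least five centroids are required for labeling")
  if (!is_full_fiducial_set(model))
    stop_capreg("incomplete_model", "model must contain all nine fiducials")

  n <- nrow(centroids)
  if (n <= 9L) {
    triples <- t(utils::combn(n, 3L))
  } else {
    triples <- with_seed(seed, {
      t(replicate(max_iterations, sort(sample.int(n, 3L))))
    })
    triples <- unique(triples)
  }
  storage.mode(triples) <- "integer"

  res <- .ransac_label_score(unclass(model), centroids[, 1:3, drop = FALSE],
                             triples)
  if (!isTRUE(res$ok))
    stop_capreg("labeling_failure",
                "all labeling hypotheses were degenerate")

  labs <- res$labels
  named <- which(labs > 0L)
  pts <- centroids[named, 1:3, drop = FALSE]
  rownames(pts) <- rownames(model)[labs[named]]
  tf <- cap_transform(rotation = res$rotation,
                      scale_ap = res$scale, scale_lr = res$scale,
                      scale_vert = res$scale,
                      translation = as.numeric(res$translation),
                      scale_in = "subject")
  structure(list(fiducials = fiducial_set(pts),
                 fit_cost_mm = res$cost,
                 transform = tf,
                 n_points_used = length(named)),
            class = "labeling_result")
}

#' @export
print.labeling_result <- function(x, ...) {
  cat(sprintf("labeling_result: %d labeled points, fit cost %.3f mm\n",
              x$n_points_used, x$fit_cost_mm))
  print(x$fiducials)
  invisible(x)
}
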