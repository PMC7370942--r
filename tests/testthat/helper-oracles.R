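# Shared fixtures and independent brute-force oracles used across tests.

# all permutations of 1..n as an (n!) x n matrix (recursive enumeration)
perms_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms_all(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

# brute-force single-linkage components: points are connected when within
# `radius`; returns integer component id per row
brute_link_components <- function(pts, radius) {
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(D[v, ] <= radius & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# exhaustive minimum enclosing circle over all pair- and triple-defined
# candidate circles (O(n^3) check; keep n small)
brute_mec <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  best <- c(0, 0, Inf)
  check <- function(cen, r) {
    if (r < best[3] &&
        all(sqrt(rowSums((pts - matrix(cen, n, 2, byrow = TRUE))^2)) <=
              r + 1e-9))
      best <<- c(cen, r)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cen <- (pts[i, ] + pts[j, ]) / 2
    check(cen, sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2)
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- pts[i, ]; b <- pts[j, ]; c3 <- pts[k, ]
      d <- 2 * (a[1] * (b[2] - c3[2]) + b[1] * (c3[2] - a[2]) +
                  c3[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(a^2) * (b[2] - c3[2]) + sum(b^2) * (c3[2] - a[2]) +
               sum(c3^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (c3[1] - b[1]) + sum(b^2) * (a[1] - c3[1]) +
               sum(c3^2) * (b[1] - a[1])) / d
      check(c(ux, uy), sqrt(sum((a - c(ux, uy))^2)))
    }
  }
  best
}

# frame with filled disks of `color` planted on a dark background
make_disk_frame <- function(H = 120, W = 120, centers = NULL, radius = 5,
                            color = c(0, 255, 0), background = c(30, 30, 30)) {
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- background[ch]
  if (!is.null(centers)) {
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (i in seq_len(nrow(centers))) {
      m <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <= radius^2
      for (ch in 1:3) {
        lay <- img[, , ch]
        lay[m] <- color[ch]
        img[, , ch] <- lay
      }
    }
  }
  capreg_frame(img)
}

# full-assignment labeling oracle: under the returned similarity transform,
# enumerate all 9! complete assignments of model fiducials to centroids and
# return the label (per centroid) of the minimum-cost one
oracle_full_assignment <- function(model, centroids, transform) {
  stopifnot(nrow(model) == 9L, nrow(centroids) == 9L)
  pred <- apply_transform(transform, unclass(model))
  D <- sqrt(pmax(outer(rowSums(pred^2), rowSums(centroids^2), `+`) -
                   2 * pred %*% t(centroids), 0))
  P <- perms_all(9L)
  costs <- rowSums(matrix(D[cbind(rep(1:9, each = nrow(P)),
                                  as.vector(P))],
                          nrow(P), 9L))
  best <- P[which.min(costs), ]
  labs <- character(9L)
  labs[best] <- rownames(model)   # centroid best[i] gets label i
  labs
}

# labels of centroids by nearest true (transformed) fiducial
true_labels_by_proximity <- function(true_fiducials, centroids) {
  vapply(seq_len(nrow(centroids)), function(i) {
    d <- sqrt(colSums((t(unclass(true_fiducials)) -
                         as.numeric(centroids[i, ]))^2))
    names(which.min(d))
  }, character(1))
}
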