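test_that("gray-world white balance equalises channel means and is idempotent", {
  gray <- capreg_frame(array(128, c(20, 20, 3)))
  expect_equal(white_balance(gray)$pixels, gray$pixels, tolerance = 1e-12)

  px <- array(0, c(32, 32, 3))
  px[, , 1] <- 100; px[, , 2] <- 50; px[, , 3] <- 25
  fr <- capreg_frame(px)
  out <- white_balance(fr)$pixels
  means <- c(mean(out[, , 1]), mean(out[, , 2]), mean(out[, , 3]))
  # gray-world oracle: every channel mean becomes (100+50+25)/3
  expect_true(all(abs(means - mean(c(100, 50, 25))) < 1))
  twice <- white_balance(white_balance(fr))$pixels
  expect_lte(max(abs(twice - out)), 1)

  expect_error(white_balance(capreg_frame(array(0, c(16, 16, 3)))),
               class = "degenerate_input")
})

test_that("sticker detection enforces the five-connected-pixel rule", {
  fr <- make_disk_frame(64, 64)            # no in-hue pixels at all
  expect_length(detect_stickers(fr, 1 / 3), 0)

  # exactly four connected green pixels: below the cluster-size floor
  px <- fr$pixels
  for (p in list(c(10, 10), c(10, 11), c(11, 10), c(11, 11)))
    px[p[1], p[2], ] <- c(0, 255, 0)
  expect_length(detect_stickers(capreg_frame(px), 1 / 3), 0)

  # a fifth pixel tips the cluster into a detection
  px[12, 11, ] <- c(0, 255, 0)
  det <- detect_stickers(capreg_frame(px), 1 / 3)
  expect_length(det, 1)
  expect_identical(det[[1]]$pixel_count, 5L)
})

test_that("planted disks are detected with enclosing-circle accuracy", {
  centers <- rbind(c(25, 30), c(25, 85), c(85, 55))
  fr <- make_disk_frame(120, 120, centers, radius = 5)
  det <- detect_stickers(fr, 1 / 3)
  expect_length(det, 3)
  got <- do.call(rbind, lapply(det, function(d) d$center_px))
  ord <- order(got[, 1], got[, 2])
  got <- got[ord, ]
  expect_true(all(abs(got - centers[order(centers[, 1], centers[, 2]), ]) <= 1))
  radii <- vapply(det, `[[`, numeric(1), "radius_px")
  expect_true(all(abs(radii - 1.2 * 5) / (1.2 * 5) <= 0.1))
})

test_that("detected circles equal the brute-force minimum enclosing circle", {
  centers <- rbind(c(20, 20), c(45, 50))
  fr <- make_disk_frame(70, 70, centers, radius = 3)
  det <- detect_stickers(fr, 1 / 3)
  expect_length(det, 2)
  px <- fr$pixels
  green <- px[, , 2] == 255
  comp <- brute_link_components(which(green, arr.ind = TRUE), 1.5)
  pts_all <- which(green, arr.ind = TRUE)
  for (d in det) {
    grp <- comp[which.min((pts_all[, 1] - d$center_px[1])^2 +
                            (pts_all[, 2] - d$center_px[2])^2)]
    mec <- brute_mec(pts_all[comp == grp, ])
    expect_equal(unname(d$center_px), unname(mec[1:2]), tolerance = 1e-6)
    expect_equal(d$radius_px, unname(1.2 * mec[3]), tolerance = 1e-6)
  }
})

test_that("sticker detection is exactly translation-equivariant", {
  centers <- rbind(c(20, 25), c(40, 60))
  f1 <- make_disk_frame(100, 100, centers, radius = 4)
  f2 <- make_disk_frame(100, 100, centers + 10, radius = 4)
  d1 <- do.call(rbind, lapply(detect_stickers(f1, 1 / 3),
                              function(d) d$center_px))
  d2 <- do.call(rbind, lapply(detect_stickers(f2, 1 / 3),
                              function(d) d$center_px))
  expect_equal(d2[order(d2[, 1]), ], d1[order(d1[, 1]), ] + 10,
               tolerance = 1e-12)
})

test_that("cap segmentation fallback recovers a planted two-hue silhouette", {
  H <- 80; W <- 80
  sil <- matrix(FALSE, H, W)
  sil[20:60, 15:65] <- TRUE
  pat <- perlin_pattern(W, H, 0.5, seed = 3)   # red/blue pattern
  px <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    lay <- matrix(30, H, W)                    # gray background, no hue
    lay[sil] <- pat[, , ch][sil]
    px[, , ch] <- lay
  }
  fr <- capreg_frame(px)
  mask <- segment_cap(fr)
  tp <- sum(mask & sil)
  expect_gte(tp / sum(sil), 0.99)              # recall
  expect_gte(tp / max(sum(mask), 1), 0.99)     # precision

  none <- make_disk_frame(32, 32)              # gray-only frame
  expect_false(any(segment_cap(none)))

  stub <- function(frame) matrix(TRUE, 32, 32)
  expect_true(all(segment_cap(none, segmenter = stub)))
  bad <- function(frame) matrix(TRUE, 16, 16)
  expect_error(segment_cap(none, segmenter = bad),
               class = "contract_violation")
})

test_that("face polygon mask matches analytic area and translates exactly", {
  lm <- list(nose = c(60, 40), left_eye = c(30, 20), right_eye = c(30, 60),
             forehead = c(15, 40))
  sq <- list(nose = c(50, 20), left_eye = c(20, 20), right_eye = c(20, 50),
             forehead = c(50, 50))
  m <- face_polygon(sq, 80, 80)
  expect_lt(abs(sum(m) - 31^2), 4 * 31 + 4)    # area +/- boundary pixels

  m1 <- face_polygon(lm, 100, 100)
  lm2 <- lapply(lm, function(p) p + c(10, 10))
  m2 <- face_polygon(lm2, 100, 100)
  expect_identical(m2[11:100, 11:100], m1[1:90, 1:90])

  expect_error(face_polygon(lm[-1], 80, 80), class = "incomplete_landmarks")
  same <- list(nose = c(5, 5), left_eye = c(5, 5), right_eye = c(5, 5),
               forehead = c(5, 5))
  expect_error(face_polygon(same, 80, 80), class = "degenerate_polygon")
})

test_that("mask composition keeps the union and reports the kept fraction", {
  fr <- make_disk_frame(50, 50, rbind(c(25, 25)), radius = 6)
  all_on <- matrix(TRUE, 50, 50)
  res <- compose_and_apply(fr, cap_mask = all_on)
  expect_identical(res$frame$pixels, fr$pixels)
  expect_identical(res$mask$kept_fraction, 1)

  res0 <- compose_and_apply(fr)
  expect_true(all(res0$frame$pixels == 0))
  expect_identical(res0$mask$kept_fraction, 0)
  expect_equal(mean(res0$mask$mask), res0$mask$kept_fraction,
               tolerance = 1e-12)

  det <- detect_stickers(fr, 1 / 3)
  expect_length(det, 1)
  res1 <- compose_and_apply(fr, stickers = det)
  expect_equal(res1$mask$kept_fraction,
               pi * det[[1]]$radius_px^2 / (50 * 50), tolerance = 0.1)
  # never enlarges beyond the union of its inputs
  circle <- disk_pixels <- res1$mask$mask
  nonblack <- apply(res1$frame$pixels, c(1, 2), max) > 0
  expect_true(all(!nonblack | circle))

  expect_error(compose_and_apply(fr, cap_mask = matrix(TRUE, 10, 10)),
               class = "contract_violation")
})

test_that("frames are rejected only when strictly more than 98% is blackened", {
  mk <- function(kept) structure(list(mask = NULL, kept_fraction = kept),
                                 class = "crop_mask")
  expect_true(reject_frame(mk(0.019)))     # 98.1% blackened
  expect_false(reject_frame(mk(0.020)))    # exactly 98%: kept
  expect_false(reject_frame(mk(1.0)))
  expect_error(reject_frame(mk(0.5), threshold = 0),
               class = "invalid_parameter")
})

test_that("detection pipeline recovers planted stickers in rendered frames", {
  scene <- make_model_head(n_surface_points = 800, seed = 21)
  cams <- list(c(0, 420, 160), c(0, -420, 160), c(420, 0, 120),
               c(-420, 0, 120))
  rf <- render_frames(scene, cams, image_size = 240)
  n_vis <- 0; n_found <- 0
  for (i in seq_along(rf$frames)) {
    tr <- rf$truth[rf$truth$frame_index == i & rf$truth$visible, ]
    # only score frames where planted stickers are >= 40 px apart
    if (nrow(tr) > 1 && min(dist(tr[, c("row", "col")])) < 40) next
    det <- detect_stickers(rf$frames[[i]], 1 / 3)
    centers <- do.call(rbind, lapply(det, function(d) d$center_px))
    for (j in seq_len(nrow(tr))) {
      n_vis <- n_vis + 1
      dmin <- min(sqrt((centers[, 1] - tr$row[j])^2 +
                         (centers[, 2] - tr$col[j])^2))
      if (dmin <= 3) n_found <- n_found + 1
    }
    # zero false positives: every detection sits on a planted sticker
    for (k in seq_len(nrow(centers))) {
      dmin <- min(sqrt((tr$row - centers[k, 1])^2 +
                         (tr$col - centers[k, 2])^2))
      expect_lte(dmin, 3)
    }
  }
  expect_gte(n_vis, 10)
  expect_gte(n_found / n_vis, 0.95)
})
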