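mk_meas <- function(pos, method = "video", id = "s1") {
  session_measurement(pos, method = method, session_id = id)
}

rand_channels <- function(n, seed) {
  set.seed(seed)
  m <- matrix(rnorm(3 * n, sd = 30), n)
  rownames(m) <- sprintf("CH%02d", seq_len(n))
  m
}

test_that("channel distances match the direct coordinate-wise oracle", {
  a <- rand_channels(10, 1)
  expect_true(all(channel_distances(mk_meas(a),
                                    mk_meas(a))$per_channel_mm[[1]] == 0))
  shifted <- a + matrix(c(3, 0, 0), 10, 3, byrow = TRUE)
  d <- channel_distances(mk_meas(a), mk_meas(shifted))
  expect_equal(unname(d$per_channel_mm[[1]]), rep(3, 10), tolerance = 1e-12)
  expect_equal(d$grand_mean_mm, 3, tolerance = 1e-12)

  b <- rand_channels(10, 2)
  d2 <- channel_distances(mk_meas(a), mk_meas(b))
  oracle <- sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2 +
                   (a[, 3] - b[, 3])^2)
  expect_equal(d2$per_channel_mm[[1]], oracle, tolerance = 1e-12)

  # non-overlapping channels are reported, never dropped silently
  b2 <- b
  rownames(b2)[1] <- "EXTRA"
  d3 <- channel_distances(mk_meas(a), mk_meas(b2))
  expect_identical(d3$missing[[1]]$only_a, "CH01")
  expect_identical(d3$missing[[1]]$only_b, "EXTRA")
  rownames(b2) <- paste0("X", seq_len(10))
  expect_error(channel_distances(mk_meas(a), mk_meas(b2)),
               class = "no_overlap")

  # grand mean is the mean of per-subject means
  subjA <- list(mk_meas(a), mk_meas(rand_channels(10, 3)))
  subjB <- list(mk_meas(rand_channels(10, 4)), mk_meas(rand_channels(10, 5)))
  dd <- channel_distances(subjA, subjB)
  expect_equal(dd$grand_mean_mm, mean(dd$per_subject_mean_mm),
               tolerance = 1e-12)
  expect_equal(dd$grand_sd_mm, sd(dd$per_subject_mean_mm), tolerance = 1e-12)
})

test_that("shift analysis reproduces canonical angles and flags zero shifts", {
  a1 <- rand_channels(5, 6)
  shift <- matrix(rnorm(15), 5)
  a2 <- a1 + shift

  same <- shift_analysis(list(mk_meas(a1), mk_meas(a2)),
                         list(mk_meas(a1), mk_meas(a2)))
  expect_true(all(abs(same$angle_deg) < 1e-4))

  opp <- shift_analysis(list(mk_meas(a1), mk_meas(a2)),
                        list(mk_meas(a1), mk_meas(a1 - shift)))
  expect_true(all(abs(opp$angle_deg - 180) < 1e-4))

  b2 <- a1
  b2[, ] <- a1 + matrix(c(0, 1, 0), 5, 3, byrow = TRUE)
  orth <- shift_analysis(list(mk_meas(a1),
                              mk_meas(a1 + matrix(c(1, 0, 0), 5, 3,
                                                  byrow = TRUE))),
                         list(mk_meas(a1), mk_meas(b2)))
  expect_true(all(abs(orth$angle_deg - 90) < 1e-9))

  zero <- shift_analysis(list(mk_meas(a1), mk_meas(a1)),
                         list(mk_meas(a1), mk_meas(a2)))
  expect_true(all(!zero$angle_defined))
  expect_true(all(is.na(zero$angle_deg)))
})

test_that("KS statistic against uniform angles matches the ECDF oracle", {
  expect_equal(ks_uniform_test(90)$K, 0.5, tolerance = 1e-12)

  n <- 20
  plotting <- (seq_len(n) - 0.5) / n * 180
  expect_equal(ks_uniform_test(plotting)$K, 1 / (2 * n), tolerance = 1e-12)

  set.seed(7)
  x <- runif(30, 0, 180)
  got <- ks_uniform_test(x)
  # brute-force sup over ECDF jump points
  xs <- sort(x)
  u <- xs / 180
  oracle <- max(pmax(abs(seq_len(30) / 30 - u), abs((seq_len(30) - 1) / 30 - u)))
  expect_equal(got$K, oracle, tolerance = 1e-12)
  expect_true(got$p > 0 && got$p <= 1)

  expect_error(ks_uniform_test(c(10, 200)), class = "domain_error")
  expect_error(ks_uniform_test(NA_real_), class = "insufficient_data")
})

test_that("paired t test matches the closed-form oracle and is antisymmetric", {
  x <- c(2, 1, 4, 3)
  y <- c(1, 2, 3, 4)                     # d = (1,-1,1,-1)
  expect_equal(paired_t_test(x, y)$t, 0, tolerance = 1e-12)

  y2 <- c(5, 4, 3, 2, 1)
  x2 <- y2 + c(1, 2, 3, 4, 5)
  got <- paired_t_test(x2, y2)
  d <- x2 - y2
  expect_equal(got$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(got$t, 3 * sqrt(5) / sqrt(2.5), tolerance = 1e-12)
  expect_identical(got$df, 4)
  expect_equal(paired_t_test(y2, x2)$t, -got$t, tolerance = 1e-12)

  expect_error(paired_t_test(1, 2), class = "insufficient_data")
  expect_error(paired_t_test(c(1, 2), c(0, 1)), class = "degenerate_test")
})

test_that("shift-size regression matches the normal-equations oracle", {
  a <- c(1, 2, 3, 4)
  perfect <- shift_size_regression(a, 2 * a)
  expect_equal(perfect$slope, 2, tolerance = 1e-12)
  expect_equal(perfect$intercept, 0, tolerance = 1e-12)
  resid <- 2 * a - (perfect$intercept + perfect$slope * a)
  expect_lt(sum(resid^2), 1e-20)
  expect_gt(perfect$F, 1e6)

  set.seed(11)
  x <- runif(100, 0, 10)
  y <- x + rnorm(100, sd = 0.5)
  got <- shift_size_regression(x, y)
  slope_o <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(got$slope, slope_o, tolerance = 1e-10)
  expect_equal(got$intercept, mean(y) - slope_o * mean(x), tolerance = 1e-10)
  # F oracle from sums of squares
  fitted <- got$intercept + got$slope * x
  Fo <- sum((fitted - mean(y))^2) / (sum((y - fitted)^2) / 98)
  expect_equal(got$F, Fo, tolerance = 1e-10)
  expect_identical(got$df, c(1L, 98L))

  expect_error(shift_size_regression(rep(1, 5), rnorm(5)),
               class = "degenerate_regression")
  expect_error(shift_size_regression(1:2, 1:2), class = "insufficient_data")
})

test_that("statistics are invariant under a common rigid transform", {
  a1 <- rand_channels(12, 21); a2 <- a1 + matrix(rnorm(36), 12)
  b1 <- a1 + matrix(rnorm(36, sd = 0.5), 12)
  b2 <- a2 + matrix(rnorm(36, sd = 0.5), 12)
  R <- rotation_matrix(c(20, -35, 60))
  t0 <- c(10, -4, 7)
  rig <- function(m) m %*% t(R) + matrix(t0, nrow(m), 3, byrow = TRUE)
  rep1 <- compare_sessions(mk_meas(a1), mk_meas(a2),
                           mk_meas(b1, "digitizer"), mk_meas(b2, "digitizer"))
  rep2 <- compare_sessions(mk_meas(rig(a1)), mk_meas(rig(a2)),
                           mk_meas(rig(b1), "digitizer"),
                           mk_meas(rig(b2), "digitizer"))
  expect_equal(rep1$validity$grand_mean_mm, rep2$validity$grand_mean_mm,
               tolerance = 1e-9)
  expect_equal(rep1$shifts$angle_deg, rep2$shifts$angle_deg,
               tolerance = 1e-9)
  expect_equal(rep1$ks$K, rep2$ks$K, tolerance = 1e-9)
  expect_equal(rep1$regression$slope, rep2$regression$slope,
               tolerance = 1e-9)
})

test_that("regression slope converges to 1 as method-B noise vanishes", {
  slopes <- vapply(c(2, 0.5, 0.01), function(sd0) {
    set.seed(31)
    a1 <- rand_channels(100, 31)
    shift <- matrix(rnorm(300, sd = 3), 100)
    a2 <- a1 + shift
    b1 <- a1
    b2 <- a1 + shift + matrix(rnorm(300, sd = sd0), 100)
    sh <- shift_analysis(list(mk_meas(a1), mk_meas(a2)),
                         list(mk_meas(b1, "digitizer"),
                              mk_meas(b2, "digitizer")))
    shift_size_regression(sh$size_a_mm, sh$size_b_mm)$slope
  }, numeric(1))
  expect_lt(abs(slopes[3] - 1), 0.01)
  expect_true(abs(slopes[3] - 1) < abs(slopes[1] - 1))
})
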