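# Validation analytics: per-channel distances between methods/sessions,
# shift magnitude and direction agreement, and the accompanying tests.

as_measurement_list <- function(x) {
  if (inherits(x, "session_measurement")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, TRUE, "session_measurement")))
    x
  else stop_capreg("invalid_parameter",
                   "expected a session_measurement or a list of them")
}

#' Per-channel distances between two sets of measurements
#'
#' Euclidean distance between the positions of the same channel in two
#' measurements (one pair per subject). Channels present on only one side
#' are reported, never silently dropped. The summary follows the
#' subjects-then-channels convention: per-subject means first, then their
#' mean and SD across subjects.
#'
#' @param a,b a [session_measurement()] or a list of them (paired by
#'   position; pairs are subjects).
#' @return Object of class `channel_distance_report`: `per_channel_mm`
#'   (list, one named vector per subject), `per_subject_mean_mm`,
#'   `grand_mean_mm`, `grand_sd_mm` (SD over subjects; `NA` for one
#'   subject), `missing` (per subject, channels absent from either side).
#' @export
channel_distances <- function(a, b) {
  a <- as_measurement_list(a)
  b <- as_measurement_list(b)
  if (length(a) != length(b))
    stop_capreg("invalid_parameter", "`a` and `b` must pair up by subject")
  per <- vector("list", length(a))
  missing <- vector("list", length(a))
  for (i in seq_along(a)) {
    pa <- a[[i]]$channel_positions
    pb <- b[[i]]$channel_positions
    shared <- intersect(rownames(pa), rownames(pb))
    if (!length(shared))
      stop_capreg("no_overlap",
                  sprintf("no shared channels for subject %d", i))
    d <- sqrt(rowSums((pa[shared, , drop = FALSE] -
                         pb[shared, , drop = FALSE])^2))
    names(d) <- shared
    per[[i]] <- d
    missing[[i]] <- list(only_a = setdiff(rownames(pa), shared),
                         only_b = setdiff(rownames(pb), shared))
  }
  subj_means <- vapply(per, mean, numeric(1))
  structure(list(per_channel_mm = per,
                 per_subject_mean_mm = subj_means,
                 grand_mean_mm = mean(subj_means),
                 grand_sd_mm = if (length(subj_means) > 1)
                   stats::sd(subj_means) else NA_real_,
                 missing = missing),
            class = "channel_distance_report")
}

#' @export
print.channel_distance_report <- function(x, ...) {
  cat(sprintf("channel_distance_report: %d subject(s), %.2f +/- %s mm\n",
              length(x$per_channel_mm), x$grand_mean_mm,
              if (is.na(x$grand_sd_mm)) "NA"
              else sprintf("%.2f", x$grand_sd_mm)))
  invisible(x)
}

#' Between-session shift vectors and their angular agreement
#'
#' For every channel shared by all four measurements, computes the shift
#' vector (session 2 minus session 1) under each method and the spatial
#' angle between the two shifts. Channels whose shift has zero length under
#' either method get an undefined angle (`NA`, `angle_defined = FALSE`) —
#' they are excluded from angle statistics but counted.
#'
#' @param method_a,method_b each a list of two [session_measurement()]s
#'   (sessions 1 and 2).
#' @return Data frame of class `shift_pairs`: channel, shift components and
#'   sizes per method (mm), `angle_deg` in \[0, 180\], `angle_defined`.
#' @export
shift_analysis <- function(method_a, method_b) {
  a <- as_measurement_list(method_a)
  b <- as_measurement_list(method_b)
  if (length(a) != 2L || length(b) != 2L)
    stop_capreg("invalid_parameter",
                "each method needs exactly two session measurements")
  ids <- Reduce(intersect, lapply(c(a, b),
                                  function(m) rownames(m$channel_positions)))
  if (!length(ids))
    stop_capreg("no_overlap", "no channels shared by all four measurements")
  sa <- a[[2]]$channel_positions[ids, , drop = FALSE] -
    a[[1]]$channel_positions[ids, , drop = FALSE]
  sb <- b[[2]]$channel_positions[ids, , drop = FALSE] -
    b[[1]]$channel_positions[ids, , drop = FALSE]
  na <- sqrt(rowSums(sa^2))
  nb <- sqrt(rowSums(sb^2))
  defined <- na > 0 & nb > 0
  cosang <- rowSums(sa * sb) / (na * nb)
  ang <- rep(NA_real_, length(ids))
  ang[defined] <- acos(pmin(1, pmax(-1, cosang[defined]))) * 180 / pi
  out <- data.frame(channel = ids,
                    ax = sa[, 1], ay = sa[, 2], az = sa[, 3],
                    bx = sb[, 1], by = sb[, 2], bz = sb[, 3],
                    size_a_mm = na, size_b_mm = nb,
                    angle_deg = ang, angle_defined = defined,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("shift_pairs", "data.frame")
  out
}

#' One-sample Kolmogorov-Smirnov test against uniform angles
#'
#' Tests whether shift angles are uniform on \[0, 180\] degrees; the
#' observed skew toward zero indicates the two methods agree on shift
#' direction. Statistic is the sup difference between the empirical CDF and
#' `x/180`; the p-value uses the asymptotic Kolmogorov distribution.
#'
#' @param angles_deg numeric sample in \[0, 180\], length >= 1 (`NA`s from
#'   undefined angles are removed).
#' @return List with `K` (statistic) and `p`.
#' @export
ks_uniform_test <- function(angles_deg) {
  x <- angles_deg[!is.na(angles_deg)]
  if (length(x) < 1L)
    stop_capreg("insufficient_data", "need at least one defined angle")
  if (any(x < 0 | x > 180))
    stop_capreg("domain_error", "angles must lie in [0, 180] degrees")
  kt <- suppressWarnings(
    stats::ks.test(x, stats::punif, min = 0, max = 180, exact = FALSE))
  list(K = unname(kt$statistic), p = unname(kt$p.value))
}

#' Paired t test
#'
#' Two-sided paired t test: `t = mean(d) / (sd(d)/sqrt(n))` with
#' `df = n - 1`, `d = x - y`.
#'
#' @param x,y equal-length numeric samples, n >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y))
    stop_capreg("invalid_parameter", "`x` and `y` must have equal length")
  n <- length(x)
  if (n < 2L)
    stop_capreg("insufficient_data", "paired t test needs n >= 2")
  d <- x - y
  if (stats::sd(d) == 0)
    stop_capreg("degenerate_test", "differences have zero variance")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Regression of shift sizes between methods
#'
#' Ordinary least squares of method-B shift sizes on method-A shift sizes,
#' pooled over channels, with the F test of the slope on (1, n-2) degrees
#' of freedom. This simplifies the mixed-effects model (random subject
#' effects) used in the original validation study; the simplification is
#' noted in the returned object.
#'
#' @param sizes_a,sizes_b equal-length numeric samples (mm), n >= 3.
#' @return List with `slope`, `intercept`, `F`, `df` (length 2), `p`, and
#'   `note` recording the OLS-for-LME simplification.
#' @export
shift_size_regression <- function(sizes_a, sizes_b) {
  if (length(sizes_a) != length(sizes_b))
    stop_capreg("invalid_parameter", "samples must have equal length")
  n <- length(sizes_a)
  if (n < 3L)
    stop_capreg("insufficient_data", "regression needs n >= 3")
  if (stats::var(sizes_a) == 0)
    stop_capreg("degenerate_regression", "predictor has zero variance")
  fit <- stats::lm(sizes_b ~ sizes_a)
  cf <- stats::coef(fit)
  sse <- sum(stats::residuals(fit)^2)
  ssr <- sum((stats::fitted(fit) - mean(sizes_b))^2)
  Fstat <- if (sse == 0) Inf else ssr / (sse / (n - 2))
  p <- if (is.infinite(Fstat)) 0
  else stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       F = Fstat, df = c(1L, n - 2L), p = p,
       note = "OLS pooled over channels (mixed-effects model simplified)")
}

#' Full two-method, two-session comparison report
#'
#' Convenience wrapper binding the validation analytics together:
#' inter-method validity (session-wise distances between methods),
#' intra-method reliability (between-session distances within each method),
#' shift pairs with the KS test of angle uniformity, and the shift-size
#' regression.
#'
#' @param a1,a2 method-A measurements for sessions 1 and 2.
#' @param b1,b2 method-B measurements for sessions 1 and 2.
#' @return List of class `session_report` with components `validity`,
#'   `reliability_a`, `reliability_b`, `shifts`, `ks`, `regression`.
#' @export
compare_sessions <- function(a1, a2, b1, b2) {
  shifts <- shift_analysis(list(a1, a2), list(b1, b2))
  ang <- shifts$angle_deg[shifts$angle_defined]
  structure(list(
    validity = channel_distances(list(a1, a2), list(b1, b2)),
    reliability_a = channel_distances(a1, a2),
    reliability_b = channel_distances(b1, b2),
    shifts = shifts,
    ks = if (length(ang)) ks_uniform_test(ang) else NULL,
    regression = shift_size_regression(shifts$size_a_mm, shifts$size_b_mm)),
    class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat("session_report\n")
  cat(sprintf("  inter-method validity: %.2f mm (mean over subjects)\n",
              x$validity$grand_mean_mm))
  cat(sprintf("  intra-method reliability A/B: %.2f / %.2f mm\n",
              x$reliability_a$grand_mean_mm, x$reliability_b$grand_mean_mm))
  if (!is.null(x$ks))
    cat(sprintf("  angle-vs-uniform KS: K = %.3f, p = %.3g\n",
                x$ks$K, x$ks$p))
  cat(sprintf("  shift-size regression: slope %.3f, F(%d,%d) = %.2f\n",
              x$regression$slope, x$regression$df[1], x$regression$df[2],
              x$regression$F))
  invisible(x)
}
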