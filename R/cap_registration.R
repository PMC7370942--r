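# Cap registration: barycentric model-cap weights, head-fiducial MNI
# transform, and channel interpolation.

# minimum-norm sum-to-one barycentric weights: rows of W express each probe
# as a weighted sum of the k fiducials, with each weight row summing to 1.
# The 4-equation system (3 coordinates + sum-to-one) in k unknowns is
# underdetermined for k > 4; the minimum-norm solution is unique and keeps
# the interpolation affinely equivariant.
solve_barycentric <- function(fiducials, probes) {
  Fm <- unclass(fiducials)
  P <- as.matrix(probes)
  k <- nrow(Fm)
  A <- rbind(t(Fm), rep(1, k))             # 4 x k
  if (qr(A)$rank < 4L)
    stop_capreg("degenerate_model",
                "fiducial configuration is affinely degenerate")
  B <- rbind(t(P), rep(1, nrow(P)))         # 4 x m
  W <- t(crossprod(A, solve(tcrossprod(A), B)))  # m x k, min-norm rows
  resid <- max(abs(W %*% Fm - P))
  if (resid > 1e-6)
    stop_capreg("degenerate_model",
                sprintf("barycentric residual %.3g mm exceeds 1e-6", resid))
  dimnames(W) <- list(rownames(P), rownames(Fm))
  W
}

#' Pre-register the model cap
#'
#' Builds the reference used by every later session: for each manually
#' marked probe `p_j` it solves for sum-to-one barycentric weights `w_ij`
#' such that `p_j = sum_i w_ij * f_i` over the nine fiducials `f_i`. The
#' system (three coordinates plus the sum-to-one constraint, nine unknowns)
#' is underdetermined; the minimum-norm solution is used, which is unique
#' and guarantees affine equivariance of the interpolation.
#'
#' @param fiducials [fiducial_set()] with all nine labels (mm).
#' @param probes named m x 3 matrix of probe/channel positions (m >= 1).
#' @return Object of class `model_cap`: `fiducials`, `probes`, `weights`
#'   (m x 9, rows summing to 1 within 1e-9).
#' @export
register_model_cap <- function(fiducials, probes) {
  if (!is_full_fiducial_set(fiducials))
    stop_capreg("incomplete_model",
                "model registration requires all nine fiducials")
  probes <- as.matrix(probes)
  if (nrow(probes) < 1L || ncol(probes) != 3L)
    stop_capreg("invalid_parameter", "`probes` must be an m x 3 matrix, m >= 1")
  if (is.null(rownames(probes)))
    rownames(probes) <- sprintf("CH%02d", seq_len(nrow(probes)))
  W <- solve_barycentric(fiducials, probes)
  structure(list(fiducials = fiducials, probes = probes, weights = W),
            class = "model_cap")
}

#' @export
print.model_cap <- function(x, ...) {
  cat("model_cap:", nrow(x$probes), "probes over",
      nrow(x$fiducials), "fiducials\n")
  cat(sprintf("  max |W %%*%% F - P| = %.2e mm\n",
              max(abs(x$weights %*% unclass(x$fiducials) - x$probes))))
  invisible(x)
}

rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-300) return(diag(3))
  k <- w / th
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Fit the head transform into reference (MNI) space
#'
#' Least-squares fit, over the four head-fiducial correspondences (Nz, AL,
#' AR, Cz), of the transform `y = S R x + t` with rotation `R`, translation
#' `t` and independent anterior-posterior / left-right scales applied along
#' the reference axes (`S = diag(s_lr, s_ap, s_vert)`); the vertical scale
#' is fixed at 1 unless `free_vertical`. Solved by Gauss-Newton from a
#' similarity-fit initialisation; with noiseless data from the same family
#' the planted parameters are recovered to machine precision.
#'
#' @param subject_head [fiducial_set()] containing Nz, AL, AR, Cz (subject
#'   space, mm).
#' @param reference_mni [fiducial_set()] with the same four labels in MNI
#'   space (mm).
#' @param free_vertical also fit the inferior-superior scale (default
#'   FALSE).
#' @return A [cap_transform()] with `scale_in = "reference"`; attribute
#'   `"residual_mm"` holds the root-mean-square fit residual.
#' @export
fit_head_transform <- function(subject_head, reference_mni,
                               free_vertical = FALSE) {
  need <- HEAD_FIDUCIAL_LABELS
  for (nm in list(subject_head, reference_mni)) {
    miss <- setdiff(need, rownames(nm))
    if (length(miss))
      stop_capreg("missing_fiducial",
                  paste0("missing head fiducial(s): ",
                         paste(miss, collapse = ", ")))
  }
  X <- unclass(subject_head)[need, , drop = FALSE]
  Y <- unclass(reference_mni)[need, , drop = FALSE]

  init <- fit_similarity(X, Y)
  if (is.null(init))
    stop_capreg("degenerate_model", "head fiducials are degenerate")
  R <- init$R
  s <- c(init$s, init$s, if (free_vertical) init$s else 1)
  t <- colMeans(Y) - s * as.numeric(R %*% colMeans(X))
  ns <- if (free_vertical) 3L else 2L

  for (iter in 1:200) {
    RX <- X %*% t(R)                       # n x 3, rows = R x_i
    pred <- sweep(RX, 2, s, `*`)
    pred <- sweep(pred, 2, t, `+`)
    r <- as.vector(t(Y - pred))            # stacked per point (x,y,z)
    J <- matrix(0, length(r), 3L + ns + 3L)
    for (i in seq_len(nrow(X))) {
      rows <- (i - 1) * 3 + 1:3
      xi <- X[i, ]
      Xx <- rbind(c(0, -xi[3], xi[2]), c(xi[3], 0, -xi[1]),
                  c(-xi[2], xi[1], 0))
      J[rows, 1:3] <- diag(s) %*% R %*% Xx        # d r / d omega
      for (k in seq_len(ns))
        J[rows[k], 3L + k] <- -RX[i, k]           # d r / d s_k
      J[rows, (3L + ns + 1):(3L + ns + 3)] <- -diag(3)
    }
    delta <- tryCatch(qr.solve(J, -r), error = function(e) NULL)
    if (is.null(delta)) break
    R <- R %*% rodrigues(delta[1:3])
    # re-orthonormalise against drift
    sv <- svd(R)
    R <- sv$u %*% t(sv$v)
    if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
    s[seq_len(ns)] <- pmax(s[seq_len(ns)] + delta[3L + seq_len(ns)], 1e-6)
    t <- t + delta[(3L + ns + 1):(3L + ns + 3)]
    if (max(abs(delta)) < 1e-13) break
  }

  out <- cap_transform(rotation = R, scale_ap = s[2], scale_lr = s[1],
                       scale_vert = s[3], translation = t,
                       scale_in = "reference")
  pred <- apply_transform(out, X)
  attr(out, "residual_mm") <- sqrt(mean(rowSums((Y - pred)^2)))
  out
}

#' Session measurement: per-channel positions from one method/session
#'
#' @param channels named m x 3 matrix of channel positions (MNI mm).
#' @param method `"video"` or `"digitizer"`.
#' @param session_id free-form session identifier.
#' @return Object of class `session_measurement`.
#' @export
session_measurement <- function(channels, method = c("video", "digitizer"),
                                session_id = "session1") {
  method <- match.arg(method)
  channels <- as.matrix(channels)
  if (ncol(channels) != 3L || is.null(rownames(channels)) ||
      anyDuplicated(rownames(channels)) || !all(is.finite(channels)))
    stop_capreg("invalid_parameter",
                "`channels` must be a finite m x 3 matrix with unique rownames")
  colnames(channels) <- c("x", "y", "z")
  structure(list(method = method, session_id = session_id,
                 channel_positions = channels),
            class = "session_measurement")
}

#' @export
print.session_measurement <- function(x, ...) {
  cat(sprintf("session_measurement [%s, %s]: %d channels\n",
              x$method, x$session_id, nrow(x$channel_positions)))
  invisible(x)
}

#' Interpolate channel positions in MNI space
#'
#' Maps the subject fiducials into MNI space through the fitted head
#' transform and evaluates each channel as the barycentric combination
#' `sum_i w_ij * f_i(MNI)` from the pre-registered model cap. When a
#' fiducial is missing (at least five of nine must be present — the cap
#' points carry redundancy), the weights are re-solved on the available
#' subset of the *model* fiducials and applied to the available subject
#' fiducials.
#'
#' @param model a [register_model_cap()] object.
#' @param subject_fiducials [fiducial_set()] measured on the subject
#'   (>= 5 of the model's nine labels).
#' @param head_transform [cap_transform()] from [fit_head_transform()]
#'   (identity by default, for measurements already in reference space).
#' @param session_id identifier stored in the output.
#' @return A [session_measurement()] with `method = "video"`.
#' @export
project_channels <- function(model, subject_fiducials,
                             head_transform = cap_transform(),
                             session_id = "session1") {
  stopifnot(inherits(model, "model_cap"))
  avail <- intersect(rownames(model$fiducials), rownames(subject_fiducials))
  if (length(avail) < 5L)
    stop_capreg("insufficient_fiducials",
                sprintf("only %d of 9 model fiducials present; need >= 5",
                        length(avail)))
  F_mni <- apply_transform(head_transform,
                           unclass(subject_fiducials)[avail, , drop = FALSE])
  W <- if (length(avail) == nrow(model$fiducials)) {
    model$weights[, avail, drop = FALSE]
  } else {
    solve_barycentric(model$fiducials[avail, , drop = FALSE], model$probes)
  }
  channels <- W %*% F_mni
  session_measurement(channels, method = "video", session_id = session_id)
}
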