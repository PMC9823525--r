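#' Model scaling from marker-pair distances
#'
#' Estimates per-body, per-axis scale factors by comparing observed
#' marker-pair distances against the same distances in the default model at
#' the neutral pose. For each configured `(marker_a, marker_b, axis)` record
#' the scale is `mean observed distance / default-model distance`, the mean
#' taken over calibration frames where both markers are present.
#' Unconfigured axes inherit the body's mean configured scale; bodies with
#' no configured pair keep scale 1.
#'
#' @param model A `skeletal_model`.
#' @param calibration A [marker_trajectory()] of calibration frames
#'   (neutral pose).
#' @param cfg Data frame with columns `body`, `marker_a`, `marker_b`,
#'   `axis` (`"x"`, `"y"` or `"z"`); defaults to [default_scale_pairs()].
#' @return 3 x n_body scale matrix with body column names.
#' @export
scale_from_markers <- function(model, calibration,
                               cfg = default_scale_pairs(model)) {
  cm <- compiled(model)
  stopifnot(all(c("body", "marker_a", "marker_b", "axis") %in% names(cfg)),
            all(cfg$axis %in% c("x", "y", "z")))
  neutral <- forward_kinematics(model, theta = neutral_pose(model))
  p0 <- neutral$marker_positions
  scales <- matrix(NA_real_, 3, cm$n_body,
                   dimnames = list(c("x", "y", "z"), cm$body_names))
  for (i in seq_len(nrow(cfg))) {
    ma <- match(cfg$marker_a[i], cm$marker_names)
    mb <- match(cfg$marker_b[i], cm$marker_names)
    if (is.na(ma) || is.na(mb))
      stop("scale pair refers to unknown marker: ",
           cfg$marker_a[i], " / ", cfg$marker_b[i])
    d0 <- sqrt(sum((p0[, ma] - p0[, mb])^2))
    if (d0 < 1e-9)
      stop("zero default-model distance for pair ", cfg$marker_a[i], " - ",
           cfg$marker_b[i])
    ok <- !calibration$missing[, ma] & !calibration$missing[, mb]
    if (!any(ok))
      stop("markers ", cfg$marker_a[i], " / ", cfg$marker_b[i],
           " are never simultaneously present in the calibration frames")
    d <- sqrt(rowSums((calibration$positions[ok, ma, , drop = FALSE] -
                       calibration$positions[ok, mb, , drop = FALSE])^2,
                      dims = 1))
    scales[cfg$axis[i], cfg$body[i]] <- mean(d) / d0
  }
  for (b in seq_len(ncol(scales))) {
    have <- !is.na(scales[, b])
    scales[!have, b] <- if (any(have)) mean(scales[have, b]) else 1
  }
  scales
}

#' Inverse-kinematics options
#'
#' @param max_iter Maximum damped Gauss-Newton iterations per frame.
#' @param tol Step-norm convergence tolerance (rad).
#' @param lambda_init Initial Levenberg-Marquardt damping.
#' @param reject_mm Per-segment marker RMS residual (mm) above which the
#'   adjacent coordinates of a frame are flagged invalid.
#' @return A list of class `"ik_config"`.
#' @export
ik_config <- function(max_iter = 100L, tol = 1e-8, lambda_init = 1e-3,
                      reject_mm = 20) {
  stopifnot(max_iter >= 1, tol > 0, lambda_init > 0, reject_mm > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 lambda_init = lambda_init, reject_mm = reject_mm),
            class = "ik_config")
}

# One damped Gauss-Newton (Levenberg-Marquardt) IK solve. Parameters are
# all model coordinates (the unbounded ground-joint angles carry the root
# rotation) plus a free root translation absorbing the global offset.
ik_frame_core <- function(cm, beta, obs, observed, weights, q_init, t_init,
                          cfg) {
  nq <- cm$n_coord
  oix <- which(observed & weights > 0)
  rows <- as.vector(t(outer(oix, 1:3, function(m, k) 3 * (m - 1) + k)))
  sw <- sqrt(weights[oix])
  obs_v <- as.vector(t(obs[oix, , drop = FALSE]))  # x,y,z per marker

  q <- q_init
  t3 <- t_init
  lambda <- cfg$lambda_init
  lo <- cm$coord_ranges[1, ]; hi <- cm$coord_ranges[2, ]
  clamp <- function(q) pmin(pmax(q, lo), hi)

  eval_at <- function(q, t3, want_jac) {
    if (want_jac) {
      jac <- fk_jacobian_cpp(cm, beta, q, matrix(0, 0, 0), FALSE)
      mp <- jac$marker_pos
      J <- jac$Jq[rows, , drop = FALSE]
    } else {
      mp <- fk_pose_cpp(cm, beta, q, matrix(0, 0, 0))$marker_pos
      J <- NULL
    }
    pred <- as.vector(mp[, oix]) + rep(t3, length(oix))
    r <- rep(sw, each = 3) * (pred - obs_v)
    list(r = r, f = sum(r^2), J = J, markers = mp)
  }

  cur <- eval_at(q, t3, TRUE)
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    J <- cur$J * rep(sw, each = 3)
    # translation block: identity per observed marker, weighted
    Jt <- matrix(0, length(cur$r), 3)
    Jt[seq(1, length(cur$r), by = 3), 1] <- sw
    Jt[seq(2, length(cur$r), by = 3), 2] <- sw
    Jt[seq(3, length(cur$r), by = 3), 3] <- sw
    J <- cbind(J, Jt)
    A <- crossprod(J)
    g <- crossprod(J, cur$r)
    improved <- FALSE
    while (!improved && lambda < 1e10) {
      step <- tryCatch(
        -solve(A + lambda * diag(nrow(A)), g),
        error = function(e) NULL)
      if (!is.null(step)) {
        q_new <- clamp(q + step[seq_len(nq)])
        t_new <- t3 + step[nq + 1:3]
        trial <- eval_at(q_new, t_new, FALSE)
        if (trial$f < cur$f) {
          moved <- sqrt(sum((q_new - q)^2) + sum((t_new - t3)^2))
          q <- q_new; t3 <- t_new
          cur <- eval_at(q, t3, TRUE)
          lambda <- max(lambda / 3, 1e-12)
          improved <- TRUE
          if (moved < cfg$tol) converged <- TRUE
        } else lambda <- lambda * 10
      } else lambda <- lambda * 10
    }
    if (!improved || converged) {
      # a stall with a (near-)zero gradient is a local minimum
      converged <- converged || (!improved && max(abs(g)) < 1e-6)
      break
    }
  }

  # unweighted per-segment RMS residual over observed markers
  seg_rms <- rep(NA_real_, cm$n_body)
  pred <- cur$markers
  for (b in seq_len(cm$n_body)) {
    mix <- which(cm$marker_body + 1L == b & observed)
    if (!length(mix)) next
    d2 <- colSums((pred[, mix, drop = FALSE] + t3 -
                   t(obs[mix, , drop = FALSE]))^2)
    seg_rms[b] <- sqrt(mean(d2))
  }
  list(theta = setNames(q, cm$coord_names), translation = t3,
       objective = cur$f, segment_rms = setNames(seg_rms, cm$body_names),
       iterations = iter, converged = converged)
}

#' Single-frame inverse kinematics
#'
#' Finds the joint angles (and a free root translation) minimising the sum
#' of weighted squared distances between the model's markers and one frame
#' of observations, by damped Gauss-Newton (Levenberg-Marquardt) steps with
#' the analytic forward-kinematics Jacobian. Missing markers are excluded;
#' joint-range bounds are enforced by projection after each step; the
#' unbounded ground-joint coordinates carry the root rotation.
#'
#' @param model A `skeletal_model` (or compiled model).
#' @param scales Body scales (see [forward_kinematics()]).
#' @param observations M x 3 matrix of observed marker positions (m), `NA`
#'   rows for missing markers, rows in model marker order.
#' @param weights Non-negative per-marker weights; default the model's
#'   `ik_weight`s.
#' @param theta_init Initial coordinate vector (default neutral pose).
#' @param cfg An [ik_config()].
#' @return List with `theta` (named angles, rad), `root_rotation` (3x3),
#'   `translation`, per-body `segment_rms` (m), `objective`, `iterations`
#'   and `converged`. Non-convergence returns the best iterate with
#'   `converged = FALSE`.
#' @export
solve_ik_frame <- function(model, scales = NULL, observations,
                           weights = NULL, theta_init = NULL,
                           cfg = ik_config()) {
  cm <- compiled(model)
  beta <- as_body_scales_cm(cm, scales)
  stopifnot(nrow(observations) == cm$n_marker, ncol(observations) == 3L)
  observed <- apply(is.finite(observations), 1, all)
  if (sum(observed) * 3 < 6)
    stop("too few observed markers to constrain the model")
  if (is.null(weights)) weights <- cm$marker_weights
  q0 <- if (is.null(theta_init)) numeric(cm$n_coord) else
    q_vector(cm, theta_init)
  t0 <- colMeans(observations[observed, , drop = FALSE]) -
    rowMeans(fk_pose_cpp(cm, beta, q0,
                         matrix(0, 0, 0))$marker_pos[, observed,
                                                     drop = FALSE])
  res <- ik_frame_core(cm, beta, observations, observed, weights, q0, t0,
                       cfg)
  res$root_rotation <- root_rotation_from_q(cm, res$theta)
  res
}

root_rotation_from_q <- function(cm, q) {
  if (cm$root_ndof == 0) return(diag(3))
  th <- q[cm$root_coordix + 1L]
  R <- diag(3)
  acc <- diag(3)
  for (i in seq_len(cm$root_ndof)) {
    a <- acc %*% cm$root_axes[, i]
    Ri <- axis_angle_matrix(as.numeric(a), th[i])
    R <- Ri %*% R
    acc <- R
  }
  R %*% t(cm$root_Fc)
}

#' Sequence inverse kinematics with residual rejection
#'
#' Runs [solve_ik_frame()] over a trajectory, initialising each frame from
#' the previous frame's solution (the first from the neutral pose). Any
#' coordinate adjacent to a segment whose marker RMS residual exceeds the
#' rejection threshold is flagged invalid for that frame, following the rule
#' that joint angles from segments fitting worse than 2 cm are disregarded.
#'
#' @param model A `skeletal_model`.
#' @param scales Body scales.
#' @param trajectory A [marker_trajectory()] with markers named as in the
#'   model (extra markers ignored).
#' @param weights Optional per-marker weights (model order).
#' @param cfg An [ik_config()].
#' @return List of class `"ik_result"`: `motion` (a [motion_sequence()]
#'   with rejection flags in `valid`), `segment_rms` (F x n_body matrix, m),
#'   `objective`, `converged` per frame, and the `reject_mm` threshold used.
#' @export
solve_ik_sequence <- function(model, scales = NULL, trajectory,
                              weights = NULL, cfg = ik_config()) {
  cm <- compiled(model)
  beta <- as_body_scales_cm(cm, scales)
  nf <- length(trajectory$timestamps)
  mix <- match(cm$marker_names, trajectory$marker_names)
  if (anyNA(mix))
    stop("trajectory is missing model marker: ",
         cm$marker_names[which(is.na(mix))[1]])
  if (is.null(weights)) weights <- cm$marker_weights

  angles <- matrix(NA_real_, nf, cm$n_coord,
                   dimnames = list(NULL, cm$coord_names))
  valid <- matrix(TRUE, nf, cm$n_coord)
  seg <- matrix(NA_real_, nf, cm$n_body,
                dimnames = list(NULL, cm$body_names))
  rots <- array(diag(3), c(3, 3, nf))
  objective <- converged <- rep(NA, nf)

  q_prev <- numeric(cm$n_coord)
  for (f in seq_len(nf)) {
    obs <- matrix(trajectory$positions[f, mix, ], ncol = 3)
    obs[trajectory$missing[f, mix], ] <- NA_real_
    observed <- apply(is.finite(obs), 1, all)
    if (sum(observed) * 3 < 6) {
      valid[f, ] <- FALSE
      next
    }
    t0 <- colMeans(obs[observed, , drop = FALSE]) -
      rowMeans(fk_pose_cpp(cm, beta, q_prev,
                           matrix(0, 0, 0))$marker_pos[, observed,
                                                       drop = FALSE])
    res <- ik_frame_core(cm, beta, obs, observed, weights, q_prev, t0, cfg)
    angles[f, ] <- res$theta
    rots[, , f] <- root_rotation_from_q(cm, res$theta)
    seg[f, ] <- res$segment_rms
    objective[f] <- res$objective
    converged[f] <- res$converged
    q_prev <- as.numeric(res$theta)
    bad_bodies <- which(is.finite(seg[f, ]) &
                          seg[f, ] > cfg$reject_mm / 1000)
    if (length(bad_bodies)) {
      bad_names <- cm$body_names[bad_bodies]
      for (ci in seq_len(cm$n_coord))
        if (any(cm$coord_joint_bodies[[ci]] %in% bad_names))
          valid[f, ci] <- FALSE
    }
  }
  angles[is.na(angles)] <- 0
  motion <- motion_sequence(cm$coord_names, trajectory$timestamps, angles,
                            rots, valid)
  structure(list(motion = motion, segment_rms = seg,
                 objective = objective, converged = converged,
                 reject_mm = cfg$reject_mm),
            class = "ik_result")
}

# Recompute rejection flags from a per-frame, per-body RMS residual matrix
# at a given threshold (mm); used to study threshold sensitivity.
recount_rejections <- function(segment_rms, model, reject_mm) {
  cm <- compiled(model)
  flags <- matrix(FALSE, nrow(segment_rms), cm$n_coord)
  for (f in seq_len(nrow(segment_rms))) {
    bad <- cm$body_names[which(is.finite(segment_rms[f, ]) &
                                 segment_rms[f, ] > reject_mm / 1000)]
    if (length(bad))
      for (ci in seq_len(cm$n_coord))
        if (any(cm$coord_joint_bodies[[ci]] %in% bad))
          flags[f, ci] <- TRUE
  }
  flags
}

#' Zero-phase low-pass filter
#'
#' Forward-backward fourth-order Butterworth low-pass smoothing, applied per
#' column. Constant signals pass unchanged; series shorter than the filter's
#' stable startup length are returned unfiltered.
#'
#' @param series Numeric vector or matrix (channels in columns).
#' @param cutoff Cut-off frequency, Hz; must be below `rate / 2`.
#' @param rate Sampling rate, Hz.
#' @return The smoothed series, same shape.
#' @export
lowpass_smooth <- function(series, cutoff, rate) {
  stopifnot(cutoff > 0, cutoff < rate / 2)
  vec <- is.null(dim(series))
  x <- if (vec) matrix(series, ncol = 1) else as.matrix(series)
  nf <- nrow(x)
  if (nf < 24) return(series)
  bf <- signal::butter(4, cutoff / (rate / 2), type = "low")
  pad <- min(nf - 1L, 3L * ceiling(rate / cutoff))
  out <- apply(x, 2, function(col) {
    # odd-reflection padding suppresses the forward-backward edge transient;
    # filtering the deviation from the mean keeps constants exact
    ext <- c(2 * col[1] - rev(col[2:(pad + 1)]), col,
             2 * col[nf] - rev(col[(nf - pad):(nf - 1)]))
    m <- mean(ext)
    signal::filtfilt(bf, ext - m)[pad + seq_len(nf)] + m
  })
  if (vec) as.numeric(out) else out
}
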