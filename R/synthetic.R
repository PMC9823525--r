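#' Noise specification for synthetic marker observations
#'
#' Emulates the error structure of image-based keypoint estimators: a
#' constant per-marker systematic bias (direction uniform on the sphere,
#' norm uniform in `bias_norm_range`), i.i.d. Gaussian jitter, and
#' contiguous occlusion gaps. The defaults (5 mm jitter, 30-50 mm bias)
#' mirror the reported magnitude of joint-center errors of pose-estimation
#' algorithms relative to optical motion capture.
#'
#' @param gaussian_sigma Jitter standard deviation per axis, metres.
#' @param bias_norm_range Length-2 `[lo, hi]`, metres; per-marker bias norm
#'   drawn uniformly, constant over time.
#' @param occlusion_rate Expected fraction of occluded frames per marker,
#'   in `[0, 1]`.
#' @param occlusion_window Length of each contiguous occlusion gap, frames.
#' @param seed Integer seed; all randomness is drawn from it.
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(gaussian_sigma = 0.005,
                       bias_norm_range = c(0.030, 0.050),
                       occlusion_rate = 0.02, occlusion_window = 10L,
                       seed = 1L) {
  stopifnot(gaussian_sigma >= 0, length(bias_norm_range) == 2L,
            0 <= bias_norm_range[1],
            bias_norm_range[1] <= bias_norm_range[2],
            occlusion_rate >= 0, occlusion_rate <= 1,
            occlusion_window >= 1)
  structure(list(gaussian_sigma = gaussian_sigma,
                 bias_norm_range = bias_norm_range,
                 occlusion_rate = occlusion_rate,
                 occlusion_window = as.integer(occlusion_window),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Trajectory specification for synthetic motions
#'
#' Smooth ground-truth joint-angle trajectories: each coordinate follows a
#' bank of sinusoids around its range midpoint, windowed in by a smooth ramp
#' after an initial neutral-pose calibration hold. Amplitudes are scaled so
#' every angle stays within its declared range; the sampling rate must
#' exceed twice the largest sinusoid frequency.
#'
#' @param duration Motion duration after the calibration hold, seconds.
#' @param rate Sampling rate, Hz.
#' @param n_harmonics Sinusoids per coordinate.
#' @param amp_frac Total amplitude as a fraction of each coordinate's
#'   half-range, in `(0, 1]`.
#' @param freq_range Length-2 `[lo, hi]` sinusoid frequency range, Hz.
#' @param root_amp Amplitude (rad) used for the unbounded root coordinates.
#' @param calibration_s Neutral-pose hold at the start, seconds.
#' @param seed Integer seed for the sinusoid bank.
#' @return A list of class `"trajectory_spec"`.
#' @export
trajectory_spec <- function(duration = 8, rate = 30, n_harmonics = 2L,
                            amp_frac = 0.4, freq_range = c(0.1, 0.8),
                            root_amp = 0.25, calibration_s = 1,
                            seed = 1L) {
  stopifnot(duration > 0, rate > 0, amp_frac >= 0, amp_frac <= 1,
            length(freq_range) == 2L, freq_range[1] <= freq_range[2],
            rate > 2 * freq_range[2], root_amp >= 0, calibration_s >= 0)
  structure(list(duration = duration, rate = rate,
                 n_harmonics = as.integer(n_harmonics),
                 amp_frac = amp_frac, freq_range = freq_range,
                 root_amp = root_amp, calibration_s = calibration_s,
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Body catalogue of the default humanoid: dims are the (x, y, z) extents in
# metres, sign the direction each extent runs from the body origin.
default_body_table <- function(spine_segments) {
  rows <- list(
    list("pelvis",    c(0.24, 0.12, 0.10), c(1, -1, 1)),
    list("head",      c(0.15, 0.22, 0.18), c(1, 1, 1)),
    list("l_upper_arm", c(0.08, 0.28, 0.08), c(1, -1, 1)),
    list("l_forearm", c(0.06, 0.26, 0.06), c(1, -1, 1)),
    list("l_hand",    c(0.08, 0.17, 0.03), c(1, -1, 1)),
    list("r_upper_arm", c(0.08, 0.28, 0.08), c(-1, -1, 1)),
    list("r_forearm", c(0.06, 0.26, 0.06), c(-1, -1, 1)),
    list("r_hand",    c(0.08, 0.17, 0.03), c(-1, -1, 1)),
    list("l_femur",   c(0.10, 0.40, 0.10), c(1, -1, 1)),
    list("l_tibia",   c(0.08, 0.38, 0.08), c(1, -1, 1)),
    list("l_foot",    c(0.08, 0.06, 0.24), c(1, -1, 1)),
    list("r_femur",   c(0.10, 0.40, 0.10), c(-1, -1, 1)),
    list("r_tibia",   c(0.08, 0.38, 0.08), c(-1, -1, 1)),
    list("r_foot",    c(0.08, 0.06, 0.24), c(-1, -1, 1)))
  spine <- lapply(seq_len(spine_segments), function(i)
    list(paste0("spine_", i), c(0.10, 0.15, 0.08), c(1, 1, 1)))
  c(rows[1], spine, rows[-1])
}

#' Default humanoid skeletal model
#'
#' A deterministic full-body fixture: pelvis root, a configurable spine
#' chain, head, and three-segment arms and legs. Every body carries four
#' markers -- one at the body origin and one at the end of each of its three
#' axis extents -- so each body axis is observable from a same-body marker
#' pair; the origin and length-axis markers are flagged bony landmarks. The
#' ground joint has three unbounded coordinates; all other coordinates carry
#' physiological-style ranges.
#'
#' @param spine_segments Number of lumped spine segments (default 3; the
#'   full thoracolumbar chain would use 9).
#' @return A validated `skeletal_model`.
#' @export
make_default_model <- function(spine_segments = 3L) {
  stopifnot(spine_segments >= 1)
  tab <- default_body_table(spine_segments)
  bodies <- lapply(tab, function(r)
    body_definition(r[[1]], 1000 * max(r[[2]])))
  dims <- setNames(lapply(tab, function(r) r[[2]] * r[[3]]),
                   vapply(tab, `[[`, "", 1))

  ax <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  top_spine <- paste0("spine_", spine_segments)
  j <- list()
  add <- function(name, parent, child, tp, dofs, tc = c(0, 0, 0)) {
    j[[length(j) + 1]] <<- joint_definition(
      name, parent, child, translation_in_parent = tp,
      translation_in_child = tc, dofs = dofs)
  }
  ball <- function(prefix, rz, rx, ry) list(
    dof_definition(paste0(prefix, "_flexion"), ax$z, c(-rz, rz)),
    dof_definition(paste0(prefix, "_adduction"), ax$x, c(-rx, rx)),
    dof_definition(paste0(prefix, "_rotation"), ax$y, c(-ry, ry)))

  add("ground_pelvis", "ground", "pelvis", c(0, 0, 0), list(
    dof_definition("pelvis_tilt", ax$z, c(-Inf, Inf)),
    dof_definition("pelvis_list", ax$x, c(-Inf, Inf)),
    dof_definition("pelvis_rotation", ax$y, c(-Inf, Inf))))

  spine_parent <- "pelvis"
  for (i in seq_len(spine_segments)) {
    seg <- paste0("spine_", i)
    tp <- if (i == 1) c(0, 0.05, 0) else c(0, 0.15, 0)
    add(paste0("lumbar_", i), spine_parent, seg, tp,
        ball(paste0("spine_", i), 0.35, 0.35, 0.35))
    spine_parent <- seg
  }
  add("neck", top_spine, "head", c(0, 0.17, 0),
      ball("neck", 0.7, 0.7, 0.7), tc = c(0, -0.02, 0))

  for (s in c("l", "r")) {
    sx <- if (s == "l") 1 else -1
    add(paste0(s, "_shoulder"), top_spine, paste0(s, "_upper_arm"),
        c(sx * 0.20, 0.12, 0), ball(paste0(s, "_shoulder"), 2.0, 1.5, 1.5))
    add(paste0(s, "_elbow"), paste0(s, "_upper_arm"), paste0(s, "_forearm"),
        c(0, -0.28, 0), list(
          dof_definition(paste0(s, "_elbow_flexion"), ax$z, c(0, 2.5))))
    add(paste0(s, "_wrist"), paste0(s, "_forearm"), paste0(s, "_hand"),
        c(0, -0.26, 0), list(
          dof_definition(paste0(s, "_wrist_flexion"), ax$z, c(-1, 1)),
          dof_definition(paste0(s, "_wrist_deviation"), ax$x,
                         c(-0.5, 0.5))))
    add(paste0(s, "_hip"), "pelvis", paste0(s, "_femur"),
        c(sx * 0.09, -0.05, 0), ball(paste0(s, "_hip"), 2.0, 0.7, 0.7))
    add(paste0(s, "_knee"), paste0(s, "_femur"), paste0(s, "_tibia"),
        c(0, -0.40, 0), list(
          dof_definition(paste0(s, "_knee_flexion"), ax$z, c(0, 2.3))))
    add(paste0(s, "_ankle"), paste0(s, "_tibia"), paste0(s, "_foot"),
        c(0, -0.38, 0), list(
          dof_definition(paste0(s, "_ankle_flexion"), ax$x, c(-0.8, 0.8)),
          dof_definition(paste0(s, "_ankle_inversion"), ax$z,
                         c(-0.6, 0.6))))
  }

  markers <- list()
  for (bname in names(dims)) {
    d <- dims[[bname]]
    offs <- list(o = c(0, 0, 0), x = c(d[1], 0, 0), y = c(0, d[2], 0),
                 z = c(0, 0, d[3]))
    for (suffix in names(offs)) {
      markers[[length(markers) + 1]] <- marker_definition(
        paste(bname, suffix, sep = "_"), bname, offs[[suffix]],
        is_bony_landmark = suffix %in% c("o", "y"))
    }
  }
  skeletal_model("pelvis", bodies, j, markers)
}

#' Longest-dimension axis per body
#'
#' Derives, for each body, the axis (1 = x, 2 = y, 3 = z) with the largest
#' marker-offset extent -- for the bundled fixture this is the body's longest
#' default dimension, the axis whose scale error is converted to mm.
#'
#' @param model A `skeletal_model`.
#' @return Named integer vector, one entry per body.
#' @export
body_long_axes <- function(model) {
  bn <- body_names(model)
  out <- setNames(rep(2L, length(bn)), bn)
  for (b in bn) {
    offs <- vapply(Filter(function(m) m$anchor_body == b, model$markers),
                   `[[`, numeric(3), "offset")
    if (length(offs)) out[b] <- which.max(apply(abs(offs), 1, max))
  }
  out
}

#' Default scale-pair configuration
#'
#' For every body of the bundled fixture, maps the observed distance between
#' the body-origin marker and each axis-end marker to that body axis.
#'
#' @param model A model built by [make_default_model()].
#' @return Data frame with columns `body`, `marker_a`, `marker_b`, `axis`.
#' @export
default_scale_pairs <- function(model) {
  bn <- body_names(model)
  mn <- marker_names(model)
  rows <- do.call(rbind, lapply(bn, function(b) {
    data.frame(body = b,
               marker_a = paste(b, "o", sep = "_"),
               marker_b = paste(b, c("x", "y", "z"), sep = "_"),
               axis = c("x", "y", "z"))
  }))
  rows[rows$marker_a %in% mn & rows$marker_b %in% mn, ]
}

#' Simulate a smooth ground-truth motion
#'
#' Each coordinate follows `theta(t) = ramp(t) * (mid + sum_k a_k
#' sin(2 pi f_k t + phi_k))` where `mid` is the coordinate's range midpoint
#' (0 for unbounded coordinates), the sinusoid bank is drawn from the spec's
#' seed, and `ramp` holds the neutral pose through the calibration window
#' then rises smoothly to 1 over half a second. Root rotations are built
#' from the ground-joint coordinates. Deterministic given the spec.
#'
#' @param model A `skeletal_model`.
#' @param spec A [trajectory_spec()].
#' @return A [motion_sequence()] covering calibration plus motion.
#' @export
simulate_motion <- function(model, spec = trajectory_spec()) {
  cm <- compiled(model)
  nf <- as.integer(round((spec$duration + spec$calibration_s) * spec$rate))
  ts <- (seq_len(nf) - 1) / spec$rate
  nc <- cm$n_coord
  ang <- matrix(0, nf, nc, dimnames = list(NULL, cm$coord_names))

  t0 <- spec$calibration_s
  ramp <- ifelse(ts < t0, 0,
                 ifelse(ts > t0 + 0.5, 1,
                        0.5 * (1 - cos(pi * (ts - t0) / 0.5))))
  with_seed(spec$seed, {
    for (ci in seq_len(nc)) {
      rg <- cm$coord_ranges[, ci]
      bounded <- all(is.finite(rg))
      mid <- if (bounded) mean(rg) else 0
      half <- if (bounded) (rg[2] - rg[1]) / 2 else spec$root_amp
      w <- runif(spec$n_harmonics)
      a <- w / sum(w) * spec$amp_frac * half
      f <- runif(spec$n_harmonics, spec$freq_range[1], spec$freq_range[2])
      phi <- runif(spec$n_harmonics, 0, 2 * pi)
      # a coordinate with no excitation holds the neutral pose
      if (sum(a) == 0) next
      wave <- rowSums(vapply(seq_len(spec$n_harmonics), function(k)
        a[k] * sin(2 * pi * f[k] * ts + phi[k]), numeric(nf)))
      ang[, ci] <- ramp * (mid + wave)
    }
  })

  root_joint <- Filter(function(j) j$parent_body == "ground",
                       model$joints)[[1]]
  ri <- match(vapply(root_joint$dofs, `[[`, "", "coordinate_name"),
              cm$coord_names)
  rr <- array(0, c(3, 3, nf))
  for (f in seq_len(nf))
    rr[, , f] <- root_transform_from_angles(root_joint,
                                            ang[f, ri])[1:3, 1:3]
  motion_sequence(cm$coord_names, ts, ang, rr)
}

#' Corrupt a marker trajectory
#'
#' Adds a constant per-marker systematic bias (direction uniform on the
#' sphere, norm uniform in the spec's range), i.i.d. Gaussian jitter, and
#' contiguous occlusion windows marked missing. Deterministic given the
#' spec's seed.
#'
#' @param traj The true [marker_trajectory()].
#' @param spec A [noise_spec()].
#' @return A corrupted [marker_trajectory()].
#' @export
corrupt_markers <- function(traj, spec = noise_spec()) {
  nf <- length(traj$timestamps)
  nm <- length(traj$marker_names)
  pos <- traj$positions
  missing <- traj$missing
  with_seed(spec$seed, {
    for (m in seq_len(nm)) {
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      bias <- dir * runif(1, spec$bias_norm_range[1],
                          spec$bias_norm_range[2])
      pos[, m, ] <- sweep(pos[, m, , drop = FALSE], 3, -bias)[, 1, ]
      if (spec$gaussian_sigma > 0)
        pos[, m, ] <- pos[, m, ] +
          matrix(rnorm(3 * nf, 0, spec$gaussian_sigma), nf, 3)
    }
    if (spec$occlusion_rate > 0 && nf > 0) {
      if (spec$occlusion_rate >= 1) {
        missing[] <- TRUE
      } else {
        n_win <- round(spec$occlusion_rate * nf / spec$occlusion_window)
        for (m in seq_len(nm)) {
          if (n_win < 1) next
          starts <- sample.int(max(1L, nf - spec$occlusion_window + 1L),
                               n_win, replace = TRUE)
          for (s in starts)
            missing[s:min(nf, s + spec$occlusion_window - 1L), m] <- TRUE
        }
      }
    }
  })
  pos[is.na(pos)] <- 0
  pos[array(missing, dim(pos))] <- NA_real_
  marker_trajectory(traj$marker_names, traj$timestamps, pos, missing)
}
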