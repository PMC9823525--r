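#' Motion transform of a joint
#'
#' Builds the rigid transform generated by a joint's ordered rotational
#' degrees of freedom. With axes `A1, A2, A3` (joint frame) and angles
#' `theta`, the rotation block is `R3 %*% R2 %*% R1` where
#' `R1 = G(A1, th1)`, `R2 = G(R1 A2, th2)`, `R3 = G(R2 R1 A3, th3)` and `G`
#' is the axis-angle rotation: each later axis is pre-rotated by the
#' accumulated earlier rotations. Absent degrees of freedom contribute the
#' identity; the translation is zero.
#'
#' @param dofs List of dof records (each with `axis` and `range`), at most 3.
#' @param theta Numeric vector of angles (rad), one per dof.
#' @return A 4x4 rigid transform. If any angle lies outside its dof's
#'   declared range the attribute `"range_warning"` on the result is `TRUE`
#'   (out-of-range angles are legal for the unbounded pelvis coordinates).
#' @export
motion_transform <- function(dofs, theta) {
  stopifnot(length(theta) == length(dofs), length(dofs) <= 3L)
  R <- diag(3)
  acc <- diag(3)
  warn <- FALSE
  for (i in seq_along(dofs)) {
    a <- acc %*% dofs[[i]]$axis
    Ri <- axis_angle_matrix(as.numeric(a), theta[i])
    R <- Ri %*% R
    acc <- R
    rg <- dofs[[i]]$range
    if (!is.null(rg) && (theta[i] < rg[1] || theta[i] > rg[2])) warn <- TRUE
  }
  out <- rigid_transform(R)
  attr(out, "range_warning") <- warn
  out
}

#' Joint-frame transform
#'
#' The constant transform from a joint frame into a body frame: rotation
#' `euler_to_matrix(o)`, translation `t_hat` (the scaled joint offset).
#'
#' @param o Euler 3-vector (rad).
#' @param t_hat Translation 3-vector (m), already scaled to the subject.
#' @return A 4x4 rigid transform.
#' @export
joint_frame_transform <- function(o, t_hat) {
  rigid_transform(euler_to_matrix(o), t_hat)
}

#' Parent-from-child transform of a joint
#'
#' Computes `R_parent<-child = R_parent<-joint %*% R_motion %*%
#' solve(R_child<-joint)` with the parent- and child-side joint offsets
#' scaled by the parent and child body's scale ratios respectively.
#'
#' @param joint A `joint_definition`.
#' @param theta Angles (rad), one per dof of the joint.
#' @param beta_hat_parent,beta_hat_child Positive 3-vectors of subject scale
#'   factors for the parent and child bodies.
#' @param beta_parent,beta_child Default scale factors (all ones by default).
#' @return A 4x4 rigid transform mapping child-frame points to the parent
#'   frame.
#' @export
parent_child_transform <- function(joint, theta,
                                   beta_hat_parent = c(1, 1, 1),
                                   beta_hat_child = c(1, 1, 1),
                                   beta_parent = c(1, 1, 1),
                                   beta_child = c(1, 1, 1)) {
  Tp <- scale_translation(joint$translation_in_parent, beta_hat_parent,
                          beta_parent)
  Tc <- scale_translation(joint$translation_in_child, beta_hat_child,
                          beta_child)
  P <- joint_frame_transform(joint$orientation_in_parent, Tp)
  C <- joint_frame_transform(joint$orientation_in_child, Tc)
  M <- motion_transform(joint$dofs, theta)
  out <- P %*% M %*% solve(C)
  attr(out, "range_warning") <- attr(M, "range_warning")
  out
}

#' Ground-from-root transform from pelvis angles
#'
#' Builds the root rotation `R_ground<-pelvis = R_motion %*%
#' solve(R_pelvis<-joint)` from the ground joint's angles. The translation
#' part is zero: the layer predicts root-relative positions.
#'
#' @param root_joint The `joint_definition` whose parent is `"ground"`.
#' @param theta_root Angles (rad), one per dof.
#' @return A 4x4 rigid transform with zero translation.
#' @export
root_transform_from_angles <- function(root_joint, theta_root) {
  M <- motion_transform(root_joint$dofs, theta_root)
  C <- euler_to_matrix(root_joint$orientation_in_child)
  rigid_transform(M[1:3, 1:3] %*% t(C))
}

q_vector <- function(cm, theta) {
  if (is.null(names(theta))) {
    stopifnot(length(theta) == cm$n_coord)
    return(as.numeric(theta))
  }
  missing <- setdiff(cm$coord_names, names(theta))
  if (length(missing))
    stop("missing coordinate value: ", missing[1])
  as.numeric(theta[cm$coord_names])
}

#' Forward kinematics of one frame
#'
#' Traverses the kinematic tree from the root in level order, composing the
#' scaled parent-from-child transforms, and returns world transforms of all
#' bodies, joint positions (world origin of each child body) and marker
#' positions, all root-relative (the root translation is zero unless a root
#' transform with non-zero translation is supplied).
#'
#' @param model A `skeletal_model` (or a pre-compiled model).
#' @param scales Body scales: `NULL` (default model), a scalar, or a
#'   3 x n_body matrix with body column names.
#' @param theta Named numeric vector of coordinate angles (rad) covering
#'   every coordinate, or an unnamed vector in [coordinate_names()] order.
#' @param root Either `NULL` (the root transform is built from the ground
#'   joint's coordinates in `theta`) or a 4x4 rigid transform / 3x3 rotation.
#' @return A list of class `"pose_frame"` with elements `world_transforms`
#'   (4 x 4 x n_body, body names on the third dimension), `joint_positions`
#'   (3 x n_joint) and `marker_positions` (3 x n_marker).
#' @examples
#' model <- make_default_model()
#' pose <- forward_kinematics(model, theta = neutral_pose(model))
#' @export
forward_kinematics <- function(model, scales = NULL, theta, root = NULL) {
  cm <- compiled(model)
  beta <- as_body_scales_cm(cm, scales)
  q <- q_vector(cm, theta)
  rootm <- root_matrix(root)
  res <- fk_pose_cpp(cm, beta, q, rootm)
  dimnames(res$world) <- list(NULL, NULL, cm$body_names)
  colnames(res$marker_pos) <- cm$marker_names
  structure(list(world_transforms = res$world,
                 joint_positions = res$joint_pos,
                 marker_positions = res$marker_pos),
            class = "pose_frame")
}

root_matrix <- function(root) {
  if (is.null(root)) return(matrix(0, 0, 0))
  if (is.matrix(root) && all(dim(root) == c(3L, 3L)))
    root <- rigid_transform(root)
  stopifnot(is.matrix(root), all(dim(root) == c(4L, 4L)))
  if (!is_rotation(root[1:3, 1:3]))
    stop("root rotation block is not orthonormal with det +1")
  root
}

as_body_scales_cm <- function(cm, scales) {
  if (is.null(scales))
    return(matrix(1, 3, cm$n_body, dimnames = list(NULL, cm$body_names)))
  if (is.numeric(scales) && length(scales) == 1L)
    return(matrix(scales, 3, cm$n_body,
                  dimnames = list(NULL, cm$body_names)))
  stopifnot(is.matrix(scales), nrow(scales) == 3L)
  if (!is.null(colnames(scales))) {
    missing <- setdiff(cm$body_names, colnames(scales))
    if (length(missing)) stop("unknown or missing body in scales: ",
                              missing[1])
    scales <- scales[, cm$body_names, drop = FALSE]
  } else stopifnot(ncol(scales) == cm$n_body)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("body scales must be positive and finite")
  scales
}

#' Forward kinematics over a sequence
#'
#' Batched frame-wise forward kinematics; identical to calling
#' [forward_kinematics()] per frame.
#'
#' @inheritParams forward_kinematics
#' @param angles F x n_coord matrix (column names = coordinate names).
#' @param roots Either `NULL` (roots from the ground-joint coordinates) or a
#'   3 x 3 x F array of root rotations.
#' @return List with `marker_positions` (3 x n_marker x F) and
#'   `joint_positions` (3 x n_joint x F).
#' @export
fk_sequence <- function(model, scales = NULL, angles, roots = NULL) {
  cm <- compiled(model)
  beta <- as_body_scales_cm(cm, scales)
  if (!is.null(colnames(angles)))
    angles <- angles[, cm$coord_names, drop = FALSE]
  stopifnot(ncol(angles) == cm$n_coord)
  Q <- t(angles)
  rc <- if (is.null(roots)) array(0, c(3, 3, 0)) else roots
  res <- fk_sequence_cpp(cm, beta, Q, rc)
  dimnames(res$marker_pos) <- list(NULL, cm$marker_names, NULL)
  list(marker_positions = res$marker_pos, joint_positions = res$joint_pos)
}

#' Jacobian of marker positions
#'
#' Analytic Jacobian of all marker coordinates with respect to the joint
#' angles and (optionally) the per-body scale factors, evaluated at one
#' configuration. Rows are ordered (x, y, z) per marker, markers stacked;
#' angle columns follow [coordinate_names()], scale columns are
#' (x, y, z) per body in body order.
#'
#' @inheritParams forward_kinematics
#' @param wrt `"theta"`, `"scales"` or `"both"`.
#' @return List with `marker_positions`, and `J_theta` and/or `J_scales`.
#' @export
fk_jacobian <- function(model, scales = NULL, theta, root = NULL,
                        wrt = c("both", "theta", "scales")) {
  wrt <- match.arg(wrt)
  cm <- compiled(model)
  beta <- as_body_scales_cm(cm, scales)
  q <- q_vector(cm, theta)
  res <- fk_jacobian_cpp(cm, beta, q, root_matrix(root),
                         wrt %in% c("both", "scales"))
  out <- list(marker_positions = res$marker_pos)
  if (wrt %in% c("both", "theta")) {
    colnames(res$Jq) <- cm$coord_names
    out$J_theta <- res$Jq
  }
  if (wrt %in% c("both", "scales")) {
    colnames(res$Jbeta) <- paste(rep(cm$body_names, each = 3),
                                 c("x", "y", "z"), sep = ".")
    out$J_scales <- res$Jbeta
  }
  out
}

#' Neutral pose
#'
#' A named all-zero coordinate vector for a model.
#'
#' @param model A `skeletal_model` or compiled model.
#' @return Named numeric vector of zeros.
#' @export
neutral_pose <- function(model) {
  cm <- compiled(model)
  setNames(numeric(cm$n_coord), cm$coord_names)
}
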