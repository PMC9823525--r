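# Independent oracles: literal transcriptions of the rotation and
# kinematic-chain equations, written without using the package's own
# primitives so they can cross-check them.

# Rodrigues, assembled term by term: cos(t) I + sin(t) K + (1 - cos(t)) a a^T
oracle_axang <- function(a, th) {
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  cos(th) * diag(3) + sin(th) * K + (1 - cos(th)) * (a %o% a)
}

oracle_euler <- function(o) {
  Rx <- matrix(c(1, 0, 0,
                 0, cos(o[1]), sin(o[1]),
                 0, -sin(o[1]), cos(o[1])), 3, 3)
  Ry <- matrix(c(cos(o[2]), 0, -sin(o[2]),
                 0, 1, 0,
                 sin(o[2]), 0, cos(o[2])), 3, 3)
  Rz <- matrix(c(cos(o[3]), sin(o[3]), 0,
                 -sin(o[3]), cos(o[3]), 0,
                 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

# motion rotation with each later axis pre-rotated by the accumulated
# earlier rotations: R1 = G(A1, t1), R2 = G(R1 A2, t2), R3 = G(R2 R1 A3, t3)
oracle_motion_rot <- function(axes, th) {
  n <- length(th)
  if (n == 0) return(diag(3))
  R1 <- oracle_axang(axes[[1]], th[1])
  if (n == 1) return(R1)
  R2 <- oracle_axang(as.numeric(R1 %*% axes[[2]]), th[2])
  if (n == 2) return(R2 %*% R1)
  R3 <- oracle_axang(as.numeric(R2 %*% R1 %*% axes[[3]]), th[3])
  R3 %*% R2 %*% R1
}

oracle_homog <- function(R, t) {
  H <- diag(4)
  H[1:3, 1:3] <- R
  H[1:3, 4] <- t
  H
}

# parent<-joint * motion * solve(child<-joint) with scaled translations
oracle_parent_child <- function(joint, th, beta_parent, beta_child) {
  axes <- lapply(joint$dofs, `[[`, "axis")
  P <- oracle_homog(oracle_euler(joint$orientation_in_parent),
                    joint$translation_in_parent * beta_parent)
  C <- oracle_homog(oracle_euler(joint$orientation_in_child),
                    joint$translation_in_child * beta_child)
  M <- oracle_homog(oracle_motion_rot(axes, th), c(0, 0, 0))
  P %*% M %*% solve(C)
}

oracle_root_transform <- function(root_joint, th) {
  axes <- lapply(root_joint$dofs, `[[`, "axis")
  M <- oracle_homog(oracle_motion_rot(axes, th), c(0, 0, 0))
  C <- oracle_homog(oracle_euler(root_joint$orientation_in_child),
                    root_joint$translation_in_child)
  H <- diag(4) %*% M %*% solve(C)
  H[1:3, 4] <- 0  # root-relative output: translation ignored
  H
}

# Path-product forward kinematics: for each marker, multiply the
# parent<-child transforms along the root -> anchor path and apply the
# scaled marker offset; also returns world child-origin positions.
oracle_fk <- function(model, beta, theta, root = NULL) {
  bn <- vapply(model$bodies, `[[`, "", "name")
  joint_of_child <- list()
  for (j in model$joints)
    if (j$parent_body != "ground") joint_of_child[[j$child_body]] <- j
  root_joint <- Filter(function(j) j$parent_body == "ground",
                       model$joints)[[1]]
  if (is.null(root)) {
    rth <- vapply(root_joint$dofs, function(d) theta[[d$coordinate_name]],
                  0)
    root <- oracle_root_transform(root_joint, rth)
  }
  world_of <- function(body) {
    chain <- list()
    b <- body
    while (!is.null(joint_of_child[[b]])) {
      chain <- c(list(joint_of_child[[b]]), chain)
      b <- joint_of_child[[b]]$parent_body
    }
    W <- root
    for (j in chain) {
      th <- vapply(j$dofs, function(d) theta[[d$coordinate_name]], 0)
      W <- W %*% oracle_parent_child(j, th, beta[, j$parent_body],
                                     beta[, j$child_body])
    }
    W
  }
  markers <- vapply(model$markers, function(m) {
    W <- world_of(m$anchor_body)
    as.numeric((W %*% c(m$offset * beta[, m$anchor_body], 1))[1:3])
  }, numeric(3))
  colnames(markers) <- vapply(model$markers, `[[`, "", "name")
  internal <- Filter(function(j) j$parent_body != "ground", model$joints)
  joints <- vapply(internal, function(j) {
    W <- world_of(j$child_body)
    W[1:3, 4]
  }, numeric(3))
  colnames(joints) <- vapply(internal, `[[`, "", "child_body")
  list(marker_positions = markers, joint_positions = joints)
}

# central finite differences of marker positions w.r.t. theta
numeric_fk_jacobian <- function(model, scales, theta, h = 1e-6) {
  q <- as.numeric(theta)
  nm <- names(theta)
  cols <- lapply(seq_along(q), function(i) {
    qp <- q; qm <- q
    qp[i] <- qp[i] + h
    qm[i] <- qm[i] - h
    (as.vector(forward_kinematics(model, scales,
                                  setNames(qp, nm))$marker_positions) -
       as.vector(forward_kinematics(model, scales,
                                    setNames(qm, nm))$marker_positions)) /
      (2 * h)
  })
  do.call(cbind, cols)
}

# sorting-based type-7 quantile, written out by hand
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
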