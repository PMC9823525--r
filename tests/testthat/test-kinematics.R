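test_that("axis-angle rotations match the Rodrigues formula", {
  expect_equal(axis_angle_matrix(c(1, 0, 0), 0), diag(3))
  expect_equal(axis_angle_matrix(c(0, 0, 1), pi / 2),
               matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3),
               tolerance = 1e-15)
  set.seed(42)
  for (i in 1:25) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    th <- runif(1, -2 * pi, 2 * pi)
    expect_equal(axis_angle_matrix(a, th), oracle_axang(a, th),
                 tolerance = 1e-13)
  }
  expect_error(axis_angle_matrix(c(0, 0, 0.5), 1), "unit")
})

test_that("Euler conversion composes X, Y, Z axis rotations in order", {
  expect_equal(euler_to_matrix(c(0, 0, 0)), diag(3))
  expect_equal(euler_to_matrix(c(0, 0, pi / 2)),
               axis_angle_matrix(c(0, 0, 1), pi / 2))
  set.seed(43)
  for (i in 1:25) {
    o <- runif(3, -pi, pi)
    composed <- axis_angle_matrix(c(1, 0, 0), o[1]) %*%
      axis_angle_matrix(c(0, 1, 0), o[2]) %*%
      axis_angle_matrix(c(0, 0, 1), o[3])
    expect_equal(euler_to_matrix(o), composed, tolerance = 1e-14)
    expect_equal(euler_to_matrix(o), oracle_euler(o), tolerance = 1e-14)
  }
})

test_that("translation scaling is elementwise in the scale ratio", {
  expect_equal(scale_translation(c(0, -0.4, 0), c(1, 1, 1)), c(0, -0.4, 0))
  expect_equal(scale_translation(c(0.1, 0.2, 0.3), c(2, 2, 2)),
               c(0.2, 0.4, 0.6))
  expect_equal(scale_translation(c(0.1, 0.2, 0.3), c(1.1, 0.9, 1.0)),
               c(0.11, 0.18, 0.30))
  expect_equal(scale_translation(c(0.1, 0.2, 0.3), c(1, 1, 1),
                                 beta = c(2, 2, 2)),
               c(0.05, 0.1, 0.15))
  expect_error(scale_translation(c(1, 1, 1), c(1, 1, 1), c(0, 1, 1)),
               "positive")
})

test_that("motion transforms pre-rotate later axes by earlier rotations", {
  expect_equal(motion_transform(list(), numeric(0)), diag(4),
               ignore_attr = TRUE)
  d1 <- dof_definition("a", c(0, 1, 0))
  expect_equal(motion_transform(list(d1), 0.7)[1:3, 1:3],
               axis_angle_matrix(c(0, 1, 0), 0.7))
  set.seed(44)
  for (i in 1:20) {
    dofs <- lapply(1:3, function(k) {
      a <- rnorm(3)
      dof_definition(paste0("c", k), a / sqrt(sum(a^2)), c(-2 * pi, 2 * pi))
    })
    th <- runif(3, -pi, pi)
    M <- motion_transform(dofs, th)
    expect_equal(M[1:3, 1:3],
                 oracle_motion_rot(lapply(dofs, `[[`, "axis"), th),
                 tolerance = 1e-13)
    expect_equal(M[1:3, 4], c(0, 0, 0))
  }
})

test_that("out-of-range angles raise the warning flag, not an error", {
  d <- dof_definition("a", c(0, 0, 1), c(-0.5, 0.5))
  expect_false(attr(motion_transform(list(d), 0.2), "range_warning"))
  expect_true(attr(motion_transform(list(d), 1.2), "range_warning"))
})

test_that("joint-frame transforms place the joint at the scaled offset", {
  expect_equal(joint_frame_transform(c(0, 0, 0), c(0, 0, 0)), diag(4))
  H <- joint_frame_transform(c(0, 0, 0), c(1, 2, 3))
  expect_equal(H[1:3, 1:3], diag(3))
  expect_equal(H[1:3, 4], c(1, 2, 3))
  set.seed(45)
  for (i in 1:10) {
    o <- runif(3, -pi, pi); t3 <- rnorm(3)
    expect_equal(as.numeric((joint_frame_transform(o, t3) %*%
                               c(0, 0, 0, 1))[1:3]), t3)
  }
})

test_that("parent-from-child transforms equal the literal three-factor product", {
  j0 <- joint_definition("j", "a", "b",
                         translation_in_parent = c(0.1, 0.2, 0.3),
                         translation_in_child = c(0.05, -0.1, 0))
  H <- parent_child_transform(j0, numeric(0))
  expect_equal(H[1:3, 1:3], diag(3), ignore_attr = TRUE)
  expect_equal(H[1:3, 4], c(0.1, 0.2, 0.3) - c(0.05, -0.1, 0))

  jz <- joint_definition("j", "a", "b",
                         dofs = list(dof_definition("q", c(0, 0, 1))))
  expect_equal(parent_child_transform(jz, pi / 2)[1:3, 1:3],
               axis_angle_matrix(c(0, 0, 1), pi / 2), ignore_attr = TRUE)

  set.seed(46)
  for (i in 1:20) {
    nd <- sample(0:3, 1)
    dofs <- lapply(seq_len(nd), function(k) {
      a <- rnorm(3)
      dof_definition(paste0("c", k), a / sqrt(sum(a^2)), c(-2 * pi, 2 * pi))
    })
    j <- joint_definition("j", "a", "b",
                          orientation_in_parent = runif(3, -pi, pi),
                          translation_in_parent = rnorm(3, sd = 0.3),
                          orientation_in_child = runif(3, -pi, pi),
                          translation_in_child = rnorm(3, sd = 0.3),
                          dofs = dofs)
    th <- runif(nd, -pi, pi)
    bp <- runif(3, 0.8, 1.2); bc <- runif(3, 0.8, 1.2)
    expect_equal(parent_child_transform(j, th, bp, bc),
                 oracle_parent_child(j, th, bp, bc),
                 tolerance = 1e-13, ignore_attr = TRUE)
  }
})

test_that("root transform follows the motion-times-inverse-joint product", {
  rj <- joint_definition("g", "ground", "pelvis",
                         orientation_in_child = c(0.1, -0.2, 0.3),
                         translation_in_child = c(0, 0.05, 0),
                         dofs = list(dof_definition("rx", c(1, 0, 0),
                                                    c(-Inf, Inf))))
  expect_equal(root_transform_from_angles(rj, 0)[1:3, 1:3],
               t(euler_to_matrix(c(0.1, -0.2, 0.3))), tolerance = 1e-14)
  expect_equal(root_transform_from_angles(rj, pi),
               oracle_root_transform(rj, pi), tolerance = 1e-13)
  set.seed(47)
  for (i in 1:10) {
    H <- root_transform_from_angles(rj, runif(1, -10, 10))
    R <- H[1:3, 1:3]
    expect_equal(crossprod(R), diag(3), tolerance = 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
    expect_equal(H[1:3, 4], c(0, 0, 0))
  }
})

test_that("rotation projection returns the nearest special-orthogonal matrix", {
  R <- axis_angle_matrix(c(0, 1, 0), 0.9)
  expect_equal(project_to_rotation(R), R, tolerance = 1e-10)
  expect_equal(project_to_rotation(2 * diag(3)), diag(3))
  set.seed(48)
  for (i in 1:20) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    truth <- oracle_axang(a, runif(1, -pi, pi))
    M <- truth + matrix(rnorm(9, 0, 0.05), 3, 3)
    P <- project_to_rotation(M)
    expect_equal(det(P), 1, tolerance = 1e-9)
    expect_lte(norm(P - truth, "F"), norm(M - truth, "F") + 1e-12)
  }
  expect_error(project_to_rotation(matrix(0, 3, 3)), "singular")
})

test_that("forward kinematics matches the path-product oracle", {
  model <- default_model_cached()
  cm <- compiled_default()
  bn <- cm$body_names
  for (s in 1:5) {
    cfgr <- random_configuration(model, 500 + s, root = (s %% 2 == 0))
    pose <- forward_kinematics(model, cfgr$beta, cfgr$theta, cfgr$root)
    ref <- oracle_fk(model, cfgr$beta, cfgr$theta, cfgr$root)
    expect_equal(pose$marker_positions, ref$marker_positions,
                 tolerance = 1e-11)
    level_children <- bn[cm$joint_child + 1L]
    expect_equal(pose$joint_positions,
                 ref$joint_positions[, level_children],
                 tolerance = 1e-11, ignore_attr = TRUE)
    for (b in seq_along(bn)) {
      R <- pose$world_transforms[1:3, 1:3, b]
      expect_equal(crossprod(R), diag(3), tolerance = 1e-8)
    }
  }
})

test_that("the two-link planar arm reaches its closed-form tip position", {
  m <- two_link_model()
  pose <- forward_kinematics(
    m, theta = c(q1 = pi / 2, q2 = pi / 2))
  expect_equal(pose$marker_positions[, "end"], c(-0.25, 0.3, 0),
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("positions are linear in a uniform scale factor", {
  model <- default_model_cached()
  cfgr <- random_configuration(model, 77)
  base <- forward_kinematics(model, 1, cfgr$theta)
  for (c in c(0.5, 1.1, 2.0)) {
    scaled <- forward_kinematics(model, c, cfgr$theta)
    expect_equal(scaled$marker_positions, c * base$marker_positions,
                 tolerance = 1e-12)
  }
})

test_that("forward kinematics is equivariant under root rotation", {
  model <- default_model_cached()
  cfgr <- random_configuration(model, 88, root = TRUE)
  R <- axis_angle_matrix(c(0, 1, 0), 1.1)
  p1 <- forward_kinematics(model, cfgr$beta, cfgr$theta,
                           rigid_transform(R) %*% cfgr$root)
  p0 <- forward_kinematics(model, cfgr$beta, cfgr$theta, cfgr$root)
  expect_equal(p1$marker_positions, R %*% p0$marker_positions,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("batched sequence evaluation equals per-frame calls", {
  model <- default_model_cached()
  mot <- simulate_motion(model, trajectory_spec(duration = 0.5, seed = 9))
  fk <- fk_sequence(model, angles = mot$angles,
                    roots = mot$root_rotation)
  for (f in c(1, 7, length(mot$timestamps))) {
    single <- forward_kinematics(
      model, theta = setNames(mot$angles[f, ], colnames(mot$angles)),
      root = mot$root_rotation[, , f])
    expect_equal(fk$marker_positions[, , f], single$marker_positions,
                 tolerance = 1e-14)
  }
})

test_that("the marker Jacobian obeys lever-arm and tree-locality structure", {
  m <- two_link_model()
  # single hinge: marker speed equals its radius about the joint axis
  J <- fk_jacobian(m, theta = c(q1 = 0.4, q2 = 0), wrt = "theta")
  tip_rows <- 7:9
  expect_equal(sqrt(sum(J$J_theta[tip_rows, "q1"]^2)), 0.55,
               tolerance = 1e-12)
  expect_equal(sqrt(sum(J$J_theta[tip_rows, "q2"]^2)), 0.25,
               tolerance = 1e-12)
  # joints not on the path to a marker have zero effect on it
  shoulder_rows <- 1:3
  expect_equal(J$J_theta[shoulder_rows, "q2"], rep(0, 3),
               ignore_attr = TRUE)
  expect_equal(J$J_theta[shoulder_rows, "q1"], rep(0, 3),
               ignore_attr = TRUE)
})

test_that("analytic Jacobians match central finite differences", {
  model <- default_model_cached()
  for (s in 1:3) {
    cfgr <- random_configuration(model, 900 + s)
    J <- fk_jacobian(model, cfgr$beta, cfgr$theta)
    fd <- numeric_fk_jacobian(model, cfgr$beta, cfgr$theta)
    scale <- max(abs(fd))
    expect_lt(max(abs(J$J_theta - fd)) / scale, 1e-6)
  }
})
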