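# Shared fixtures, built in code.

# Planar two-link arm: z-axis hinges, link lengths 0.3 m and 0.25 m, end
# marker at the tip of the distal link.
two_link_model <- function() {
  skeletal_model(
    root_body = "base",
    bodies = list(body_definition("base", 100),
                  body_definition("link1", 300),
                  body_definition("link2", 250)),
    joints = list(
      joint_definition("shoulder", "base", "link1",
                       dofs = list(dof_definition("q1", c(0, 0, 1),
                                                  c(-pi, pi)))),
      joint_definition("elbow", "link1", "link2",
                       translation_in_parent = c(0.3, 0, 0),
                       dofs = list(dof_definition("q2", c(0, 0, 1),
                                                  c(-pi, pi))))),
    markers = list(
      marker_definition("shoulder_m", "base", c(0, 0, 0),
                        is_bony_landmark = TRUE),
      marker_definition("elbow_m", "link2", c(0, 0, 0),
                        is_bony_landmark = TRUE),
      marker_definition("end", "link2", c(0.25, 0, 0),
                        is_bony_landmark = TRUE)))
}

# closed-form tip position of the two-link arm
two_link_tip <- function(q1, q2) {
  c(0.3 * cos(q1) + 0.25 * cos(q1 + q2),
    0.3 * sin(q1) + 0.25 * sin(q1 + q2), 0)
}

default_model_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- make_default_model()
    m
  }
})

compiled_default <- local({
  cm <- NULL
  function() {
    if (is.null(cm)) cm <<- skelkin:::compiled(default_model_cached())
    cm
  }
})

# random valid configuration of a model: angles within (finite) ranges,
# scales around 1, optional random root rotation
random_configuration <- function(model, seed, root = FALSE) {
  cm <- skelkin:::compiled(model)
  set.seed(seed)
  rg <- cm$coord_ranges
  lo <- ifelse(is.finite(rg[1, ]), rg[1, ], -pi / 2)
  hi <- ifelse(is.finite(rg[2, ]), rg[2, ], pi / 2)
  theta <- setNames(runif(cm$n_coord, lo, hi), cm$coord_names)
  beta <- matrix(runif(3 * cm$n_body, 0.8, 1.25), 3,
                 dimnames = list(NULL, cm$body_names))
  out <- list(theta = theta, beta = beta, root = NULL)
  if (root) {
    ax <- rnorm(3)
    out$root <- rigid_transform(
      axis_angle_matrix(ax / sqrt(sum(ax^2)), runif(1, -pi, pi)))
  }
  out
}

# FK-generated marker trajectory (the truth) for a simulated motion
fk_trajectory <- function(model, motion, beta = NULL) {
  fk <- fk_sequence(model, scales = beta, angles = motion$angles,
                    roots = motion$root_rotation)
  pos <- aperm(fk$marker_positions, c(3, 2, 1))
  marker_trajectory(dimnames(fk$marker_positions)[[2]],
                    motion$timestamps, pos)
}
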