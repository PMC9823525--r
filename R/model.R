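#' Skeletal model constructors
#'
#' A skeletal model is a tree of body segments connected by joints with up to
#' three rotational degrees of freedom each, plus markers rigidly attached to
#' bodies at fixed body-frame offsets.  All lengths are metres and all angles
#' radians; `reference_length` is the millimetre length of a body's longest
#' dimension in the default model and is used to convert scale errors to mm.
#'
#' The joint connecting the ground to the root body uses the reserved parent
#' name `"ground"`; its coordinates are unbounded (the pelvis is free to
#' rotate in all directions).
#'
#' @param name Identifier.
#' @param reference_length Positive length in mm of the body's longest
#'   dimension in the default model.
#' @return `body_definition` returns a named list describing one body.
#' @export
body_definition <- function(name, reference_length) {
  stopifnot(is.character(name), nzchar(name),
            is.numeric(reference_length), reference_length > 0)
  list(name = name, reference_length = as.numeric(reference_length))
}

#' @rdname body_definition
#' @param coordinate_name Globally unique coordinate identifier.
#' @param axis Unit 3-vector (joint frame).
#' @param range Length-2 numeric `[min, max]` in radians; may be infinite.
#' @export
dof_definition <- function(coordinate_name, axis, range = c(-pi, pi)) {
  axis <- as.numeric(axis)
  stopifnot(is.character(coordinate_name), nzchar(coordinate_name),
            length(axis) == 3L, length(range) == 2L, range[1] <= range[2])
  list(coordinate_name = coordinate_name, axis = axis,
       range = as.numeric(range))
}

#' @rdname body_definition
#' @param parent_body,child_body Body names (`"ground"` allowed as parent of
#'   the root joint only).
#' @param orientation_in_parent,orientation_in_child Euler 3-vectors (rad)
#'   fixing the joint frame in the parent/child body frame.
#' @param translation_in_parent,translation_in_child 3-vectors (m) from the
#'   parent/child body origin to the joint, default-model frame.
#' @param dofs List of `dof_definition` records, at most three.
#' @export
joint_definition <- function(name, parent_body, child_body,
                             orientation_in_parent = c(0, 0, 0),
                             translation_in_parent = c(0, 0, 0),
                             orientation_in_child = c(0, 0, 0),
                             translation_in_child = c(0, 0, 0),
                             dofs = list()) {
  stopifnot(is.character(name), is.character(parent_body),
            is.character(child_body), length(dofs) <= 3L)
  list(name = name, parent_body = parent_body, child_body = child_body,
       orientation_in_parent = as.numeric(orientation_in_parent),
       translation_in_parent = as.numeric(translation_in_parent),
       orientation_in_child = as.numeric(orientation_in_child),
       translation_in_child = as.numeric(translation_in_child),
       dofs = dofs)
}

#' @rdname body_definition
#' @param anchor_body Body the marker is attached to.
#' @param offset 3-vector (m) from the anchor-body origin, default model.
#' @param is_bony_landmark Logical; bony landmarks form the subset scored by
#'   [mpblpe()].
#' @param ik_weight Non-negative weight used by the inverse-kinematics fit.
#' @export
marker_definition <- function(name, anchor_body, offset,
                              is_bony_landmark = FALSE, ik_weight = 1.0) {
  offset <- as.numeric(offset)
  stopifnot(is.character(name), is.character(anchor_body),
            length(offset) == 3L, ik_weight >= 0)
  list(name = name, anchor_body = anchor_body, offset = offset,
       is_bony_landmark = isTRUE(is_bony_landmark),
       ik_weight = as.numeric(ik_weight))
}

#' @rdname body_definition
#' @param root_body Name of the root body (pelvis analogue).
#' @param bodies List of `body_definition` records.
#' @param joints List of `joint_definition` records.
#' @param markers List of `marker_definition` records.
#' @param validate Check all invariants (default `TRUE`).
#' @return `skeletal_model` returns a validated object of class
#'   `"skeletal_model"`.
#' @export
skeletal_model <- function(root_body, bodies, joints, markers = list(),
                           validate = TRUE) {
  model <- structure(
    list(root_body = root_body, bodies = bodies, joints = joints,
         markers = markers),
    class = "skeletal_model")
  if (validate) validate_model(model)
  model
}

body_names <- function(model) vapply(model$bodies, `[[`, "", "name")
marker_names <- function(model) vapply(model$markers, `[[`, "", "name")

#' Coordinate names of a model
#'
#' Returns all coordinate names in deterministic level order (the ground
#' joint's coordinates first, then each joint's coordinates breadth-first
#' from the root).
#'
#' @param model A `skeletal_model`.
#' @return Character vector of coordinate names.
#' @export
coordinate_names <- function(model) {
  ord <- level_order_joints(model)
  unlist(lapply(ord, function(j)
    vapply(j$dofs, `[[`, "", "coordinate_name")), use.names = FALSE)
}

# Joints sorted breadth-first from the root, ground joint (if any) first.
# Children at equal depth keep their definition order.
level_order_joints <- function(model) {
  jparent <- vapply(model$joints, `[[`, "", "parent_body")
  jchild <- vapply(model$joints, `[[`, "", "child_body")
  ground <- which(jparent == "ground")
  ord <- if (length(ground)) model$joints[ground] else list()
  frontier <- model$root_body
  seen_bodies <- model$root_body
  remaining <- setdiff(seq_along(model$joints), ground)
  while (length(frontier)) {
    nxt <- remaining[jparent[remaining] %in% frontier]
    nxt <- nxt[order(match(jparent[nxt], frontier), nxt)]
    ord <- c(ord, model$joints[nxt])
    frontier <- jchild[nxt]
    seen_bodies <- c(seen_bodies, frontier)
    remaining <- setdiff(remaining, nxt)
  }
  attr(ord, "reached_bodies") <- seen_bodies
  ord
}

#' Validate a skeletal model
#'
#' Checks every structural invariant: unique names, positive reference
#' lengths, unit dof axes (tolerance 1e-9), at most three dofs per joint,
#' globally unique coordinate names, the tree property (every non-root body
#' the child of exactly one joint, all bodies reachable from the root, no
#' cycles), and marker anchors/weights.
#'
#' @param model A `skeletal_model`.
#' @return The model, invisibly; signals an error describing the offending
#'   field otherwise.
#' @export
validate_model <- function(model) {
  bn <- body_names(model)
  if (anyDuplicated(bn)) stop("duplicate body name: ",
                              bn[duplicated(bn)][1])
  if ("ground" %in% bn) stop("'ground' is reserved and cannot be a body name")
  rl <- vapply(model$bodies, `[[`, 0, "reference_length")
  if (any(!is.finite(rl) | rl <= 0))
    stop("reference_length must be positive for body: ", bn[rl <= 0][1])
  if (!model$root_body %in% bn)
    stop("root_body '", model$root_body, "' is not a defined body")

  coords <- character()
  child_count <- setNames(integer(length(bn)), bn)
  for (j in model$joints) {
    for (nm in c("orientation_in_parent", "translation_in_parent",
                 "orientation_in_child", "translation_in_child")) {
      v <- j[[nm]]
      if (length(v) != 3L || any(!is.finite(v)))
        stop("joint '", j$name, "': ", nm, " must be a finite 3-vector")
    }
    if (!(j$parent_body %in% c(bn, "ground")))
      stop("joint '", j$name, "': unknown parent_body '", j$parent_body, "'")
    if (j$parent_body == "ground" && j$child_body != model$root_body)
      stop("joint '", j$name, "': ground joint must attach the root body")
    if (!j$child_body %in% bn)
      stop("joint '", j$name, "': unknown child_body '", j$child_body, "'")
    if (length(j$dofs) > 3L)
      stop("joint '", j$name, "': more than 3 dofs")
    for (d in j$dofs) {
      if (abs(sqrt(sum(d$axis^2)) - 1) > 1e-9)
        stop("joint '", j$name, "', coordinate '", d$coordinate_name,
             "': axis does not have unit norm")
      coords <- c(coords, d$coordinate_name)
    }
    if (j$parent_body != "ground")
      child_count[j$child_body] <- child_count[j$child_body] + 1L
  }
  if (anyDuplicated(coords))
    stop("duplicate coordinate_name: ", coords[duplicated(coords)][1])
  non_root <- setdiff(bn, model$root_body)
  bad <- non_root[child_count[non_root] != 1L]
  if (length(bad))
    stop("body '", bad[1], "' must be the child of exactly one joint ",
         "(found ", child_count[bad[1]], ")")
  if (child_count[model$root_body] != 0L)
    stop("root body cannot be the child of a non-ground joint (cycle)")

  ord <- level_order_joints(model)
  reached <- attr(ord, "reached_bodies")
  missing <- setdiff(bn, reached)
  if (length(missing))
    stop("body '", missing[1], "' is not reachable from the root ",
         "(disconnected or cyclic joint structure)")

  for (m in model$markers) {
    if (!m$anchor_body %in% bn)
      stop("marker '", m$name, "': unknown anchor_body '", m$anchor_body, "'")
    if (!is.finite(m$ik_weight) || m$ik_weight < 0)
      stop("marker '", m$name, "': ik_weight must be >= 0")
  }
  invisible(model)
}

#' @export
print.skeletal_model <- function(x, ...) {
  cat("Skeletal model: ", length(x$bodies), " bodies, ",
      length(x$joints), " joints, ", length(coordinate_names(x)),
      " coordinates, ", length(x$markers), " markers\n", sep = "")
  cat("Root body:", x$root_body, "\n")
  invisible(x)
}

#' Default body scales
#'
#' Returns the all-ones scale set for a model: a 3 x n_body matrix of
#' per-axis factors with bodies as column names.
#'
#' @param model A `skeletal_model`.
#' @return 3 x n_body numeric matrix.
#' @export
default_body_scales <- function(model) {
  bn <- body_names(model)
  matrix(1, 3, length(bn), dimnames = list(c("x", "y", "z"), bn))
}

as_body_scales <- function(model, scales) {
  bn <- body_names(model)
  if (is.null(scales)) return(default_body_scales(model))
  if (is.numeric(scales) && length(scales) == 1L) {
    out <- default_body_scales(model)
    out[] <- scales
    return(out)
  }
  stopifnot(is.matrix(scales), nrow(scales) == 3L)
  if (!is.null(colnames(scales))) {
    missing <- setdiff(bn, colnames(scales))
    if (length(missing)) stop("scales missing body: ", missing[1])
    scales <- scales[, bn, drop = FALSE]
  } else if (ncol(scales) != length(bn)) {
    stop("scales must cover every body")
  }
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("body scales must be positive and finite")
  scales
}

# Compile a model into the flat, 0-indexed arrays the C++ kernels consume.
# Level-ordered so a parent's transform precedes its children's.
compile_model <- function(model) {
  validate_model(model)
  bn <- body_names(model)
  ord <- level_order_joints(model)
  is_ground <- vapply(ord, function(j) j$parent_body == "ground", TRUE)
  internal <- ord[!is_ground]
  nj <- length(internal)

  Tp <- Tc <- matrix(0, 3, max(nj, 1L))
  Fp <- Fc <- array(0, c(3, 3, max(nj, 1L)))
  axes <- array(0, c(3, 3, max(nj, 1L)))
  coordix <- matrix(-1L, 3, max(nj, 1L))
  jparent <- jchild <- ndof <- integer(nj)

  coords <- coordinate_names(model)
  cix <- function(nm) match(nm, coords) - 1L

  for (k in seq_len(nj)) {
    j <- internal[[k]]
    jparent[k] <- match(j$parent_body, bn) - 1L
    jchild[k] <- match(j$child_body, bn) - 1L
    Tp[, k] <- j$translation_in_parent
    Tc[, k] <- j$translation_in_child
    Fp[, , k] <- euler_to_matrix(j$orientation_in_parent)
    Fc[, , k] <- euler_to_matrix(j$orientation_in_child)
    ndof[k] <- length(j$dofs)
    axes[, , k] <- diag(3)
    for (i in seq_along(j$dofs)) {
      axes[, i, k] <- j$dofs[[i]]$axis
      coordix[i, k] <- cix(j$dofs[[i]]$coordinate_name)
    }
  }

  root_ndof <- 0L
  root_axes <- diag(3)
  root_Fc <- diag(3)
  root_coordix <- integer(0)
  if (any(is_ground)) {
    g <- ord[[which(is_ground)[1]]]
    root_ndof <- length(g$dofs)
    for (i in seq_along(g$dofs)) root_axes[, i] <- g$dofs[[i]]$axis
    root_Fc <- euler_to_matrix(g$orientation_in_child)
    root_coordix <- vapply(g$dofs, function(d) cix(d$coordinate_name), 0L)
  }

  nm <- length(model$markers)
  mbody <- integer(nm)
  moff <- matrix(0, 3, max(nm, 1L))
  for (m in seq_len(nm)) {
    mbody[m] <- match(model$markers[[m]]$anchor_body, bn) - 1L
    moff[, m] <- model$markers[[m]]$offset
  }

  # joints on the path root -> anchor body, per marker (0-based indices)
  parent_of <- setNames(rep(NA_integer_, length(bn)), bn)
  for (k in seq_len(nj)) parent_of[jchild[k] + 1L] <- k
  mpath <- lapply(seq_len(nm), function(m) {
    path <- integer(0)
    b <- mbody[m] + 1L
    while (!is.na(parent_of[b])) {
      k <- parent_of[b]
      path <- c(k - 1L, path)
      b <- jparent[k] + 1L
    }
    path
  })

  # coordinate ranges and joint adjacency, used by IK
  ranges <- matrix(NA_real_, 2, length(coords))
  coord_joint_bodies <- vector("list", length(coords))
  for (j in ord) {
    adj <- if (j$parent_body == "ground") j$child_body else
      c(j$parent_body, j$child_body)
    for (d in j$dofs) {
      i <- match(d$coordinate_name, coords)
      ranges[, i] <- d$range
      coord_joint_bodies[[i]] <- adj
    }
  }

  list(n_body = length(bn), n_joint = nj, n_marker = nm,
       n_coord = length(coords),
       joint_parent = jparent, joint_child = jchild, joint_ndof = ndof,
       Tp = Tp, Tc = Tc, Fp = Fp, Fc = Fc, axes = axes, coordix = coordix,
       root_body = match(model$root_body, bn) - 1L,
       root_ndof = root_ndof, root_axes = root_axes, root_Fc = root_Fc,
       root_coordix = root_coordix,
       marker_body = mbody, marker_offset = moff, marker_path = mpath,
       body_names = bn, coord_names = coords,
       marker_names = marker_names(model),
       coord_ranges = ranges, coord_joint_bodies = coord_joint_bodies,
       marker_weights = vapply(model$markers, `[[`, 0, "ik_weight"),
       bony = vapply(model$markers, `[[`, TRUE, "is_bony_landmark"),
       reference_lengths = setNames(
         vapply(model$bodies, `[[`, 0, "reference_length"), bn))
}

compiled <- function(model) {
  if (inherits(model, "skelkin_compiled")) return(model)
  structure(compile_model(model), class = "skelkin_compiled")
}
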