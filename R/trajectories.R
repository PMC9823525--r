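#' Marker trajectory container
#'
#' Per-frame 3D marker observations with missing-data flags. Positions are
#' metres internally; timestamps are seconds with uniform spacing.
#'
#' @param marker_names Character vector, one per marker.
#' @param timestamps Numeric vector, strictly increasing, uniform within
#'   1e-6 s.
#' @param positions Numeric array F x M x 3 (metres).
#' @param missing Logical F x M matrix; positions must be finite wherever
#'   `missing` is `FALSE`.
#' @return An object of class `"marker_trajectory"`.
#' @export
marker_trajectory <- function(marker_names, timestamps, positions,
                              missing = NULL) {
  nf <- length(timestamps)
  nm <- length(marker_names)
  if (is.null(missing)) missing <- matrix(FALSE, nf, nm)
  stopifnot(is.array(positions), length(dim(positions)) == 3L,
            dim(positions)[1] == nf, dim(positions)[2] == nm,
            dim(positions)[3] == 3L,
            is.logical(missing), all(dim(missing) == c(nf, nm)))
  check_uniform_time(timestamps)
  obs <- !missing
  if (nf > 0 && nm > 0) {
    finite <- apply(is.finite(positions), c(1, 2), all)
    if (any(obs & !finite))
      stop("non-finite position at a frame/marker not flagged missing")
  }
  structure(list(marker_names = marker_names, timestamps = timestamps,
                 positions = positions, missing = missing),
            class = "marker_trajectory")
}

check_uniform_time <- function(ts) {
  if (length(ts) >= 2) {
    dt <- diff(ts)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6)
      stop("timestamps must be uniformly spaced within 1e-6 s")
  }
  invisible(ts)
}

frame_rate <- function(x) {
  ts <- x$timestamps
  if (length(ts) < 2) return(NA_real_)
  1 / mean(diff(ts))
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat("Marker trajectory: ", length(x$timestamps), " frames x ",
      length(x$marker_names), " markers",
      if (length(x$timestamps) > 1)
        sprintf(" @ %.6g Hz", frame_rate(x)) else "",
      ", ", sum(x$missing), " missing cells\n", sep = "")
  invisible(x)
}

#' Motion sequence container
#'
#' Uniformly sampled joint-angle frames (radians) plus a root rotation per
#' frame. The `valid` mask carries the inverse-kinematics rejection flags.
#'
#' @param coordinate_names Character vector of coordinate names.
#' @param timestamps Numeric vector (s), uniform spacing.
#' @param angles F x C numeric matrix (rad); finite wherever `valid`.
#' @param root_rotation 3 x 3 x F array of ground-from-root rotations, each
#'   orthonormal with determinant +1 (tolerance 1e-8). Defaults to identity.
#' @param valid Logical F x C matrix (default all `TRUE`).
#' @return An object of class `"motion_sequence"`.
#' @export
motion_sequence <- function(coordinate_names, timestamps, angles,
                            root_rotation = NULL, valid = NULL) {
  nf <- length(timestamps)
  nc <- length(coordinate_names)
  angles <- as.matrix(angles)
  stopifnot(nrow(angles) == nf, ncol(angles) == nc)
  colnames(angles) <- coordinate_names
  if (is.null(root_rotation))
    root_rotation <- array(diag(3), c(3, 3, nf))
  if (is.null(valid)) valid <- matrix(TRUE, nf, nc)
  stopifnot(all(dim(root_rotation) == c(3, 3, nf)),
            is.logical(valid), all(dim(valid) == c(nf, nc)))
  check_uniform_time(timestamps)
  for (f in seq_len(nf)) {
    if (!is_rotation(root_rotation[, , f]))
      stop("root rotation at frame ", f,
           " is not orthonormal with det +1 (tolerance 1e-8)")
  }
  if (any(valid & !is.finite(angles)))
    stop("non-finite angle at a frame/coordinate flagged valid")
  structure(list(coordinate_names = coordinate_names,
                 timestamps = timestamps, angles = angles,
                 root_rotation = root_rotation, valid = valid),
            class = "motion_sequence")
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat("Motion sequence: ", length(x$timestamps), " frames x ",
      length(x$coordinate_names), " coordinates",
      if (length(x$timestamps) > 1)
        sprintf(" @ %.6g Hz", 1 / mean(diff(x$timestamps))) else "",
      ", ", sum(!x$valid), " invalid entries\n", sep = "")
  invisible(x)
}
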