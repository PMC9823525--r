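#' Read and write skeletal model files
#'
#' The model schema is a structured YAML document whose keys mirror the
#' model's fields (`root_body`, `bodies`, `joints`, `markers`; see
#' [skeletal_model()]). Lengths are metres and angles radians in the file,
#' matching the in-memory convention; `reference_length` is millimetres.
#' Writing then reading a model is lossless (numbers are emitted with 17
#' significant digits).
#'
#' @param path File path.
#' @return `read_model` returns a validated `skeletal_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file does not exist: ", path)
  doc <- yaml::read_yaml(path)
  for (field in c("root_body", "bodies", "joints"))
    if (is.null(doc[[field]]))
      stop("model schema violation: missing field '", field, "'")
  bodies <- lapply(doc$bodies, function(b) {
    if (is.null(b$name) || is.null(b$reference_length))
      stop("model schema violation: body needs 'name' and ",
           "'reference_length'")
    body_definition(b$name, b$reference_length)
  })
  joints <- lapply(doc$joints, function(j) {
    if (is.null(j$name) || is.null(j$parent_body) || is.null(j$child_body))
      stop("model schema violation: joint needs 'name', 'parent_body' ",
           "and 'child_body'")
    dofs <- lapply(j$dofs, function(d) {
      if (is.null(d$coordinate_name) || is.null(d$axis))
        stop("model schema violation: dof needs 'coordinate_name' and ",
             "'axis' (joint '", j$name, "')")
      dof_definition(d$coordinate_name, unlist(d$axis),
                     if (is.null(d$range)) c(-pi, pi) else unlist(d$range))
    })
    joint_definition(
      j$name, j$parent_body, j$child_body,
      orientation_in_parent = null_default(j$orientation_in_parent),
      translation_in_parent = null_default(j$translation_in_parent),
      orientation_in_child = null_default(j$orientation_in_child),
      translation_in_child = null_default(j$translation_in_child),
      dofs = dofs)
  })
  markers <- lapply(doc$markers, function(m) {
    if (is.null(m$name) || is.null(m$anchor_body) || is.null(m$offset))
      stop("model schema violation: marker needs 'name', 'anchor_body' ",
           "and 'offset'")
    marker_definition(m$name, m$anchor_body, unlist(m$offset),
                      is_bony_landmark = isTRUE(m$is_bony_landmark),
                      ik_weight = if (is.null(m$ik_weight)) 1.0
                                  else m$ik_weight)
  })
  skeletal_model(doc$root_body, bodies, joints, markers)
}

null_default <- function(x, default = c(0, 0, 0)) {
  if (is.null(x)) default else as.numeric(unlist(x))
}

#' @rdname read_model
#' @param model A validated `skeletal_model`.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  doc <- list(
    root_body = model$root_body,
    bodies = model$bodies,
    joints = lapply(model$joints, function(j) {
      j$dofs <- lapply(j$dofs, function(d) d)
      j
    }),
    markers = model$markers)
  txt <- yaml::as.yaml(doc, precision = 17L)
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop("cannot write model file: ", path)
  invisible(path)
}

#' Read and write TRC marker files
#'
#' Tab-separated TRC marker trajectories per the de-facto motion-capture
#' interchange standard. Positions are converted to metres internally
#' regardless of the file units (`mm` or `m`); blank cells become missing
#' observations. `write_trc` emits millimetres with missing markers as empty
#' cells.
#'
#' @param path File path.
#' @return `read_trc` returns a [marker_trajectory()].
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5) stop("TRC file too short: ", path)
  keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  hdr <- setNames(as.list(vals[seq_along(keys)]), keys)
  units <- hdr$Units
  if (is.null(units) || !units %in% c("mm", "m"))
    stop("unsupported TRC units: ", if (is.null(units)) "<missing>"
         else units)
  to_m <- if (units == "mm") 1e-3 else 1
  n_markers <- as.integer(hdr$NumMarkers)
  name_cells <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  names_raw <- name_cells[-(1:2)]
  mnames <- names_raw[nzchar(names_raw)]
  if (length(mnames) != n_markers)
    stop("TRC header NumMarkers (", n_markers, ") does not match marker ",
         "name row (", length(mnames), ")")
  ncol_expected <- 2L + 3L * n_markers
  data_lines <- lines[-seq_len(5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  nf <- length(data_lines)
  pos <- array(NA_real_, c(nf, n_markers, 3))
  missing <- matrix(TRUE, nf, n_markers)
  ts <- numeric(nf)
  for (f in seq_len(nf)) {
    cells <- strsplit(data_lines[f], "\t", fixed = TRUE)[[1]]
    if (length(cells) > ncol_expected)
      stop("TRC row ", f, " has ", length(cells), " columns; expected at ",
           "most ", ncol_expected)
    cells <- c(cells, rep("", ncol_expected - length(cells)))
    ts[f] <- as.numeric(cells[2])
    for (m in seq_len(n_markers)) {
      xyz <- cells[2L + (3L * (m - 1L) + 1L):(3L * m)]
      if (all(nzchar(xyz))) {
        pos[f, m, ] <- as.numeric(xyz) * to_m
        missing[f, m] <- FALSE
      }
    }
  }
  marker_trajectory(mnames, ts, pos, missing)
}

#' @rdname read_trc
#' @param traj A [marker_trajectory()].
#' @export
write_trc <- function(traj, path) {
  nf <- length(traj$timestamps)
  nm <- length(traj$marker_names)
  rate <- if (nf > 1) 1 / mean(diff(traj$timestamps)) else 0
  l1 <- paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t")
  l2 <- paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
              "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames",
              sep = "\t")
  l3 <- paste(fmt(rate), fmt(rate), nf, nm, "mm", fmt(rate), 1, nf,
              sep = "\t")
  l4 <- paste(c("Frame#", "Time",
                as.vector(rbind(traj$marker_names, "", ""))), collapse = "\t")
  l5 <- paste(c("", "", paste0(rep(c("X", "Y", "Z"), nm),
                               rep(seq_len(nm), each = 3))), collapse = "\t")
  rows <- vapply(seq_len(nf), function(f) {
    cells <- character(3 * nm)
    for (m in seq_len(nm)) {
      ix <- (3 * (m - 1) + 1):(3 * m)
      cells[ix] <- if (traj$missing[f, m]) "" else
        fmt(traj$positions[f, m, ] * 1000)
    }
    paste(c(f, fmt(traj$timestamps[f]), cells), collapse = "\t")
  }, "")
  writeLines(c(l1, l2, l3, l4, l5, "", rows), path)
  invisible(path)
}

fmt <- function(x) sprintf("%.17g", x)

#' Read and write MOT joint-angle files
#'
#' MOT/STO joint-angle trajectories: degrees on disk, radians in memory.
#' The per-frame root rotation, which the standard format has no slot for,
#' is serialised as nine auxiliary columns `rot_00` ... `rot_22` (row-major);
#' files without these columns read back with identity root rotations.
#' Invalid angle entries are stored as `nan` and read back as invalid.
#'
#' @param path File path.
#' @return `read_mot` returns a [motion_sequence()].
#' @export
read_mot <- function(path) {
  lines <- readLines(path)
  end <- which(trimws(lines) == "endheader")
  if (!length(end)) stop("MOT file has no 'endheader' line: ", path)
  hdr <- lines[seq_len(end[1] - 1)]
  in_deg <- any(grepl("^\\s*inDegrees\\s*=\\s*yes\\s*$", hdr,
                      ignore.case = TRUE))
  body <- lines[-seq_len(end[1])]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("MOT file has no column header row: ", path)
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (cols[1] != "time") stop("MOT first column must be 'time'")
  rot_cols <- grep("^rot_[0-2][0-2]$", cols)
  coord_ix <- setdiff(seq_along(cols)[-1], rot_cols)
  cnames <- cols[coord_ix]
  data_lines <- body[-1]
  nf <- length(data_lines)
  vals <- matrix(NA_real_, nf, length(cols))
  for (f in seq_len(nf)) {
    cells <- strsplit(data_lines[f], "\t", fixed = TRUE)[[1]]
    if (length(cells) != length(cols))
      stop("MOT row ", f, " has ", length(cells), " columns; expected ",
           length(cols))
    vals[f, ] <- suppressWarnings(as.numeric(cells))
  }
  ts <- vals[, 1]
  ang <- vals[, coord_ix, drop = FALSE]
  if (in_deg) ang <- ang * pi / 180
  valid <- is.finite(ang)
  rr <- array(diag(3), c(3, 3, nf))
  if (length(rot_cols) == 9L) {
    ord <- order(cols[rot_cols])  # rot_00 .. rot_22 row-major
    rmat <- vals[, rot_cols[ord], drop = FALSE]
    for (f in seq_len(nf))
      rr[, , f] <- matrix(rmat[f, ], 3, 3, byrow = TRUE)
  }
  motion_sequence(cnames, ts, ang, rr, valid)
}

#' @rdname read_mot
#' @param seq A [motion_sequence()].
#' @export
write_mot <- function(seq, path) {
  nf <- length(seq$timestamps)
  rot_names <- paste0("rot_", as.vector(t(outer(0:2, 0:2, paste0))))
  cols <- c("time", seq$coordinate_names, rot_names)
  hdr <- c(basename(path), "version=1",
           paste0("nRows=", nf), paste0("nColumns=", length(cols)),
           "inDegrees=yes", "endheader")
  deg <- seq$angles * 180 / pi
  deg[!seq$valid] <- NaN
  rows <- vapply(seq_len(nf), function(f) {
    rr <- t(seq$root_rotation[, , f])  # row-major flatten
    paste(c(fmt(seq$timestamps[f]), fmt(deg[f, ]), fmt(as.vector(rr))),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, paste(cols, collapse = "\t"), rows), path)
  invisible(path)
}
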