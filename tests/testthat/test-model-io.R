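test_that("model files round-trip losslessly", {
  model <- default_model_cached()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back, model, tolerance = 1e-15)
  # writing the re-read model reproduces the same document
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_model(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("models with no markers and unicode names survive a round-trip", {
  m <- skeletal_model(
    "tørso",
    bodies = list(body_definition("tørso", 300),
                  body_definition("arm", 250)),
    joints = list(joint_definition(
      "j", "tørso", "arm",
      translation_in_parent = c(0, 0.1, 0),
      dofs = list(dof_definition("q", c(1, 0, 0))))),
    markers = list())
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(m, path)
  expect_equal(read_model(path), m, tolerance = 1e-15)
})

test_that("invalid models are rejected with structural errors", {
  model <- two_link_model()
  # non-unit joint axis
  bad <- model
  bad$joints[[1]]$dofs[[1]]$axis <- c(0, 0, 0.5)
  expect_error(validate_model(bad), "unit norm")
  # duplicate coordinate name
  bad <- model
  bad$joints[[2]]$dofs[[1]]$coordinate_name <- "q1"
  expect_error(validate_model(bad), "duplicate coordinate")
  # a body that is the child of two joints
  bad <- model
  bad$joints[[2]]$child_body <- "link1"
  expect_error(validate_model(bad), "exactly one joint")
  # cycle back into the root
  bad <- model
  bad$joints[[2]]$child_body <- "base"
  expect_error(validate_model(bad), "cycle|exactly one")
  # disconnected body
  bad <- model
  bad$joints[[2]]$parent_body <- "link2"
  expect_error(validate_model(bad), "reachable|exactly one")
  # duplicate body name
  bad <- model
  bad$bodies[[3]]$name <- "link1"
  expect_error(validate_model(bad), "duplicate body")
  # invalid files surface the same errors through read_model
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(model, path)
  doc <- yaml::read_yaml(path)
  doc$joints[[1]]$dofs[[1]]$axis <- c(0, 0, 0.5)
  yaml::write_yaml(doc, path)
  expect_error(read_model(path), "unit norm")
})

test_that("TRC files convert units and blank cells", {
  path <- withr::local_tempfile(fileext = ".trc")
  writeLines(c(
    "PathFileType\t4\t(X/Y/Z)\ttest.trc",
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames",
          sep = "\t"),
    "100\t100\t2\t3\tmm\t100\t1\t2",
    "Frame#\tTime\tA\t\t\tB\t\t\tC\t\t",
    "\t\tX1\tY1\tZ1\tX2\tY2\tZ2\tX3\tY3\tZ3",
    "",
    "1\t0\t1\t2\t3\t4\t5\t6\t7\t8\t9",
    "2\t0.01\t10\t20\t30\t\t\t\t70\t80\t90"), path)
  traj <- read_trc(path)
  expect_equal(traj$marker_names, c("A", "B", "C"))
  expect_equal(traj$positions[1, 1, ], c(1, 2, 3) / 1000)
  expect_equal(traj$positions[2, 3, ], c(70, 80, 90) / 1000)
  expect_true(traj$missing[2, 2])
  expect_false(any(traj$missing[1, ]))
})

test_that("TRC rejects unsupported units and ragged rows", {
  path <- withr::local_tempfile(fileext = ".trc")
  writeLines(c(
    "PathFileType\t4\t(X/Y/Z)\tt.trc",
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits",
    "100\t100\t1\t1\tfurlong",
    "Frame#\tTime\tA\t\t",
    "\t\tX1\tY1\tZ1",
    "",
    "1\t0\t1\t2\t3"), path)
  expect_error(read_trc(path), "units")
  writeLines(c(
    "PathFileType\t4\t(X/Y/Z)\tt.trc",
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits",
    "100\t100\t1\t1\tmm",
    "Frame#\tTime\tA\t\t",
    "\t\tX1\tY1\tZ1",
    "",
    "1\t0\t1\t2\t3\t4\t5"), path)
  expect_error(read_trc(path), "columns")
})

test_that("marker trajectories round-trip through TRC", {
  set.seed(10)
  for (rep in 1:3) {
    nf <- sample(2:6, 1); nm <- sample(1:4, 1)
    pos <- array(rnorm(nf * nm * 3), c(nf, nm, 3))
    miss <- matrix(runif(nf * nm) < 0.2, nf, nm)
    pos[array(miss, dim(pos))] <- NA_real_
    traj <- marker_trajectory(paste0("M", seq_len(nm)),
                              (seq_len(nf) - 1) / 100, pos, miss)
    path <- withr::local_tempfile(fileext = ".trc")
    write_trc(traj, path)
    back <- read_trc(path)
    expect_equal(back$marker_names, traj$marker_names)
    expect_equal(back$missing, traj$missing, ignore_attr = TRUE)
    expect_equal(back$positions[!is.na(traj$positions)],
                 traj$positions[!is.na(traj$positions)],
                 tolerance = 1e-9)
  }
})

test_that("MOT files store degrees on disk and radians in memory", {
  path <- withr::local_tempfile(fileext = ".mot")
  writeLines(c("test", "version=1", "nRows=1", "nColumns=2",
               "inDegrees=yes", "endheader",
               "time\tknee_flexion_l", "0\t90"), path)
  s <- read_mot(path)
  expect_equal(s$coordinate_names, "knee_flexion_l")
  expect_equal(unname(s$angles[1, 1]), pi / 2)
  expect_equal(s$root_rotation[, , 1], diag(3))
})

test_that("an empty MOT data section yields a zero-frame sequence", {
  path <- withr::local_tempfile(fileext = ".mot")
  writeLines(c("test", "version=1", "inDegrees=yes", "endheader",
               "time\ta\tb"), path)
  s <- read_mot(path)
  expect_equal(length(s$timestamps), 0L)
  expect_equal(s$coordinate_names, c("a", "b"))
})

test_that("motion sequences round-trip through MOT with root rotations", {
  set.seed(11)
  nf <- 4
  ang <- matrix(runif(nf * 3, -1, 1), nf, 3)
  valid <- matrix(TRUE, nf, 3)
  valid[2, 3] <- FALSE
  rr <- array(0, c(3, 3, nf))
  for (f in 1:nf) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    rr[, , f] <- axis_angle_matrix(a, runif(1, -pi, pi))
  }
  s <- motion_sequence(c("a", "b", "c"), (0:(nf - 1)) / 50, ang, rr, valid)
  path <- withr::local_tempfile(fileext = ".mot")
  write_mot(s, path)
  back <- read_mot(path)
  expect_equal(back$angles[valid], s$angles[valid], tolerance = 1e-9)
  expect_equal(back$valid, valid, ignore_attr = TRUE)
  expect_equal(back$root_rotation, s$root_rotation, tolerance = 1e-9)
  expect_equal(back$timestamps, s$timestamps, tolerance = 1e-12)
})
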