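#' Mean per-bony-landmark position error (mm)
#'
#' Aligns prediction and ground truth at the root position of every frame,
#' then averages the Euclidean distance over all frames and bony landmarks
#' (one pooled mean). Invariant to per-frame global translation of either
#' trajectory.
#'
#' @param pred,truth 3 x M x F arrays of marker positions (metres), or
#'   [marker_trajectory()] objects.
#' @param bony Logical or integer index selecting the bony-landmark subset
#'   (non-empty).
#' @param root_index Marker column used as the root for per-frame alignment;
#'   `NULL` uses the origin (positions already root-relative).
#' @return Scalar error in millimetres.
#' @export
mpblpe <- function(pred, truth, bony, root_index = NULL) {
  pred <- as_pos_array(pred); truth <- as_pos_array(truth)
  stopifnot(all(dim(pred) == dim(truth)))
  sel <- if (is.logical(bony)) which(bony) else as.integer(bony)
  if (!length(sel)) stop("bony landmark subset is empty")
  nf <- dim(pred)[3]
  if (nf == 0) return(NaN)
  total <- 0
  for (f in seq_len(nf)) {
    p <- pred[, , f]; y <- truth[, , f]
    if (!is.null(root_index)) {
      p <- p - p[, root_index]
      y <- y - y[, root_index]
    }
    d <- p[, sel, drop = FALSE] - y[, sel, drop = FALSE]
    total <- total + sum(sqrt(colSums(d^2)))
  }
  1000 * total / (nf * length(sel))
}

as_pos_array <- function(x) {
  if (inherits(x, "marker_trajectory")) x <- aperm(x$positions, c(3, 2, 1))
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[1] == 3L)
  x
}

#' Body-scale errors
#'
#' `rmse_body` is the root-mean-square error over all scale entries
#' (unitless). `mae_body` selects, per body, the axis along the body's
#' longest default dimension, converts that axis' scale error to millimetres
#' via the body's reference length, and averages over bodies and frames.
#'
#' @param pred_scales 3 x n_body matrix, or 3 x n_body x F array for
#'   per-frame estimates (body column names required).
#' @param true_scales 3 x n_body matrix with body column names.
#' @param reference_lengths Named vector, mm per body.
#' @param long_axis Named integer vector giving each body's longest-dimension
#'   axis (1 = x, 2 = y, 3 = z); defaults to axis 2 (the length axis of a
#'   segment) for every body.
#' @return List with `rmse_body` (unitless) and `mae_body` (mm).
#' @export
body_scale_errors <- function(pred_scales, true_scales, reference_lengths,
                              long_axis = NULL) {
  if (length(dim(pred_scales)) == 2L)
    pred_scales <- array(pred_scales, c(dim(pred_scales), 1),
                         dimnames = c(dimnames(pred_scales), list(NULL)))
  bn <- colnames(true_scales)
  if (is.null(bn)) bn <- names(reference_lengths)
  stopifnot(!is.null(bn), all(bn %in% names(reference_lengths)))
  if (is.null(long_axis)) long_axis <- setNames(rep(2L, length(bn)), bn)
  nf <- dim(pred_scales)[3]
  err <- pred_scales - array(true_scales, c(3, length(bn), nf))
  rmse <- sqrt(mean(err^2))
  mae_mm <- mean(vapply(seq_along(bn), function(b) {
    ax <- long_axis[[bn[b]]]
    mean(abs(err[ax, b, ])) * reference_lengths[[bn[b]]]
  }, 0))
  list(rmse_body = rmse, mae_body = mae_mm)
}

#' Joint-angle errors (degrees)
#'
#' Mean absolute error, standard deviation of the signed errors (population
#' convention, divide by n) and root-mean-square error, per coordinate and
#' pooled, computed over valid entries only and reported in degrees.
#'
#' @param pred,truth F x C angle matrices in radians (coordinate columns),
#'   or [motion_sequence()] objects.
#' @param valid Logical F x C mask; defaults to the intersection of the two
#'   sequences' masks (or all `TRUE` for plain matrices).
#' @return List with pooled `mae`, `sd`, `rmse` (deg) and a
#'   `per_coordinate` data frame.
#' @export
angle_errors <- function(pred, truth, valid = NULL) {
  if (inherits(pred, "motion_sequence")) {
    valid <- if (is.null(valid)) pred$valid else valid & pred$valid
    pred <- pred$angles
  }
  if (inherits(truth, "motion_sequence")) {
    valid <- if (is.null(valid)) truth$valid else valid & truth$valid
    truth <- truth$angles
  }
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  stopifnot(all(dim(pred) == dim(truth)))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(pred), ncol(pred))
  err <- (pred - truth) * 180 / pi
  err[!valid] <- NA
  pop_sd <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NaN)
    sqrt(mean((x - mean(x))^2))
  }
  per <- data.frame(
    coordinate = colnames(pred) %||% paste0("coord", seq_len(ncol(pred))),
    mae = apply(abs(err), 2, mean, na.rm = TRUE),
    sd = apply(err, 2, pop_sd),
    rmse = sqrt(apply(err^2, 2, mean, na.rm = TRUE)),
    row.names = NULL)
  e <- err[!is.na(err)]
  list(mae = mean(abs(e)), sd = pop_sd(e), rmse = sqrt(mean(e^2)),
       per_coordinate = per)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean velocity of a sampled signal
#'
#' The mean absolute first difference divided by the sampling interval:
#' `sum(|s_t - s_{t+1}|) / dt / n` with `n` the number of consecutive pairs
#' (`#samples - 1`). Exact (`= |slope|`) for affine signals.
#'
#' @param series Numeric vector, or a matrix with one channel per column.
#' @param dt Sampling interval in seconds.
#' @return Per-channel mean velocity in signal units per second.
#' @export
mean_velocity <- function(series, dt) {
  stopifnot(dt > 0)
  if (is.null(dim(series))) series <- matrix(series, ncol = 1)
  if (nrow(series) < 2) stop("mean velocity needs at least 2 samples")
  d <- abs(diff(series)) / dt
  colMeans(d)
}

#' Pearson correlation with agreement category
#'
#' Computes Pearson's correlation and maps its absolute value onto the four
#' agreement categories used for joint-angle time series: weak
#' (`|rho| <= 0.35`), moderate (`0.35 < |rho| <= 0.67`), strong
#' (`0.67 < |rho| <= 0.90`) and excellent (`0.90 < |rho|`).
#'
#' @param a,b Numeric vectors of equal length, at least 3 samples, neither
#'   constant.
#' @return List with `rho` and `category`.
#' @export
pearson_with_category <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3) stop("need at least 3 samples for a correlation")
  if (sd(a) == 0 || sd(b) == 0)
    stop("correlation undefined for a constant series")
  rho <- cor(a, b)
  list(rho = rho, category = rho_category(abs(rho)))
}

rho_category <- function(r) {
  if (r <= 0.35) "weak" else if (r <= 0.67) "moderate"
  else if (r <= 0.90) "strong" else "excellent"
}

#' Distribution summary
#'
#' Median, interquartile range (linear-interpolation quantiles, type 7),
#' mean and (sample) standard deviation, the central-tendency summary used
#' for per-joint error distributions.
#'
#' @param values Non-empty numeric vector.
#' @return Named list with `median`, `iqr`, `mean`, `sd`.
#' @export
summarize_distribution <- function(values) {
  stopifnot(length(values) >= 1)
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  list(median = median(values), iqr = q[2] - q[1],
       mean = mean(values), sd = if (length(values) > 1) sd(values) else 0)
}
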