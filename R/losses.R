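#' Loss configuration
#'
#' Non-negative weights of the composite training loss
#' `L = l1*L_joint + l2*L_marker + l3*L_body + l4*L_angle`. The defaults
#' (1.0, 2.0, 0.1, 0.06) are the weights under which the direct regressor is
#' trained.
#'
#' @param lambda_joint,lambda_marker,lambda_body,lambda_angle Non-negative
#'   finite weights.
#' @return A list of class `"loss_config"`.
#' @export
loss_config <- function(lambda_joint = 1.0, lambda_marker = 2.0,
                        lambda_body = 0.1, lambda_angle = 0.06) {
  w <- c(lambda_joint, lambda_marker, lambda_body, lambda_angle)
  stopifnot(all(is.finite(w)), all(w >= 0))
  structure(list(lambda_joint = lambda_joint,
                 lambda_marker = lambda_marker,
                 lambda_body = lambda_body,
                 lambda_angle = lambda_angle),
            class = "loss_config")
}

#' Root-relative L1 loss
#'
#' Subtracts each point set's root position, then sums the absolute
#' coordinate-wise differences: `sum(|(yhat - yhat_root) - (y - y_root)|)`.
#' Invariant to any global translation applied to either point set.
#'
#' @param pred,truth Point sets with points in columns: d x N matrices for
#'   d-dimensional points (N x 3 matrices are transposed for convenience), or
#'   plain vectors of one-dimensional points.
#' @param root_index Column index of the root point (default 1).
#' @return Non-negative scalar.
#' @export
root_relative_l1 <- function(pred, truth, root_index = 1L) {
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1)
  if (is.null(dim(truth))) truth <- matrix(truth, nrow = 1)
  stopifnot(all(dim(pred) == dim(truth)))
  if (nrow(pred) != 3L && ncol(pred) == 3L) {
    pred <- t(pred); truth <- t(truth)
  }
  stopifnot(root_index >= 1, root_index <= ncol(pred))
  p <- pred - pred[, root_index]
  y <- truth - truth[, root_index]
  sum(abs(p - y))
}

#' Composite training loss
#'
#' The weighted sum of root-relative L1 joint- and marker-position losses
#' and plain L1 body-scale and joint-angle losses. `pred` and `truth` are
#' lists with elements `theta` (angles, rad), `scales`, `joint_positions`
#' (3 x J) and `marker_positions` (3 x M); the first column of each position
#' block is taken as the root unless `root_index` says otherwise.
#'
#' @param pred,truth Lists as described above (shapes must agree).
#' @param cfg A [loss_config()].
#' @param root_index Root column for the root-relative terms.
#' @return Scalar total with attribute `"terms"`: the named unweighted
#'   per-term values.
#' @export
composite_loss <- function(pred, truth, cfg = loss_config(),
                           root_index = 1L) {
  l_joint <- root_relative_l1(pred$joint_positions, truth$joint_positions,
                              root_index)
  l_marker <- root_relative_l1(pred$marker_positions,
                               truth$marker_positions, root_index)
  l_body <- sum(abs(as.numeric(pred$scales) - as.numeric(truth$scales)))
  l_angle <- sum(abs(as.numeric(pred$theta) - as.numeric(truth$theta)))
  total <- cfg$lambda_joint * l_joint + cfg$lambda_marker * l_marker +
    cfg$lambda_body * l_body + cfg$lambda_angle * l_angle
  attr(total, "terms") <- c(joint = l_joint, marker = l_marker,
                            body = l_body, angle = l_angle)
  total
}
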