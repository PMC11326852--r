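#' Pearson map correlation with guarded denominator
#'
#' Correlation over all voxels of two maps, with a small epsilon inside
#' each root of the denominator to guard against constant maps:
#' `sum((x - xbar)(y - ybar)) / (sqrt(sum((x - xbar)^2) + eps) *
#' sqrt(sum((y - ybar)^2) + eps))`.
#'
#' @param e,e2 [volume_grid]s or numeric arrays of matching dimensions.
#' @param epsilon Guard constant (default 1e-8).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_map <- function(e, e2, epsilon = 1e-8) {
  x <- if (inherits(e, "volume_grid")) e$values else e
  y <- if (inherits(e2, "volume_grid")) e2$values else e2
  if (!all(dim(x) == dim(y)) && length(x) != length(y)) {
    stop("dimension mismatch between maps", call. = FALSE)
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / (sqrt(sum(xc^2) + epsilon) * sqrt(sum(yc^2) + epsilon))
}

#' Loss configuration
#'
#' @param w_mse MSE weight (default 0.9999).
#' @param w_pc Weight of the negated Pearson correlation (default 1e-4).
#' @param epsilon Guard constant inside the correlation roots.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(w_mse = 0.9999, w_pc = 1e-4, epsilon = 1e-8) {
  stopifnot(w_mse >= 0, w_pc >= 0, epsilon > 0)
  structure(list(w_mse = w_mse, w_pc = w_pc, epsilon = epsilon),
            class = "loss_config")
}

#' Training loss: weighted MSE minus weighted Pearson correlation
#'
#' `w_mse * mean((pred - target)^2) + w_pc * (-PC(pred, target))`. At
#' `pred == target` the loss equals `-w_pc` exactly.
#'
#' @param pred,target Numeric vectors/arrays or [volume_grid]s of matching
#'   size.
#' @param cfg A [loss_config].
#' @param gradient Also return the gradient w.r.t. `pred`.
#' @return The scalar loss, or a list `(loss, pc, grad)` when
#'   `gradient = TRUE`.
#' @export
map_loss <- function(pred, target, cfg = loss_config(), gradient = FALSE) {
  x <- if (inherits(pred, "volume_grid")) as.vector(pred$values) else
    as.vector(pred)
  y <- if (inherits(target, "volume_grid")) as.vector(target$values) else
    as.vector(target)
  if (length(x) != length(y)) {
    stop("dimension mismatch between prediction and target", call. = FALSE)
  }
  n <- length(x)
  diff <- x - y
  mse <- sum(diff^2) / n
  xc <- x - mean(x)
  yc <- y - mean(y)
  rx <- sqrt(sum(xc^2) + cfg$epsilon)
  ry <- sqrt(sum(yc^2) + cfg$epsilon)
  sxy <- sum(xc * yc)
  pc <- sxy / (rx * ry)
  loss <- cfg$w_mse * mse - cfg$w_pc * pc
  if (!gradient) return(loss)
  dpc <- yc / (rx * ry) - sxy * xc / (rx^3 * ry)
  grad <- cfg$w_mse * 2 * diff / n - cfg$w_pc * dpc
  list(loss = loss, pc = pc, grad = grad)
}
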