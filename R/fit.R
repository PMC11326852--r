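#' Fit a Patterson-to-density transformer
#'
#' The main modelling entry point: trains the hybrid 3D-CNN/transformer
#' regression network on a set of map examples (all from one tensor-size
#' bin) and returns a classed fit with the usual accessor methods
#' (`print`, `summary`, `predict`, `plot`, `residuals`).
#'
#' @param examples List of `example_record`s (see [build_example()] and
#'   [generate_dataset()]).
#' @param model A [model_config]; its `grid_dims` must match the
#'   examples' grids.
#' @param training A [train_config].
#' @param loss A [loss_config].
#' @param recycle If `TRUE`, after the base run a fresh two-channel model
#'   is retrained with the base predictions as an extra input channel and
#'   returned as the final model.
#' @param verbose Print per-epoch progress.
#' @return An object of class `xtalformer`.
#' @examples
#' \donttest{
#' set.seed(1)
#' ds <- generate_dataset(4, generator_config(n_residues = 2, seed = 7),
#'                        d_min = 2, oversampling = 2, mode = "fixed",
#'                        fixed_cell = unit_cell(14, 14, 14),
#'                        patch_dims = c(4, 4, 4))
#' fit <- xtalformer(ds$examples,
#'                   model = model_config(grid_dims = c(16, 16, 16)),
#'                   training = train_config(epochs = 3, batch_size = 4))
#' print(fit)
#' }
#' @export
xtalformer <- function(examples, model = model_config(),
                       training = train_config(), loss = loss_config(),
                       recycle = FALSE, verbose = FALSE) {
  base <- train_model(examples, model, training, loss, verbose = verbose)
  fit <- base
  if (recycle) {
    fit <- recycle_train(base, examples, train_cfg = training,
                         loss_cfg = loss)
  }
  structure(list(fit = fit, base_fit = if (recycle) base,
                 recycled = recycle,
                 n_examples = length(examples),
                 example_dims = examples[[1L]]$density$dims,
                 call = match.call()),
            class = "xtalformer")
}

#' @export
print.xtalformer <- function(x, ...) {
  cat("Patterson-to-density transformer fit\n")
  print(x$fit$config)
  h <- x$fit$history
  cat(sprintf("trained %d epochs on %d examples%s\n", nrow(h),
              x$n_examples, if (x$recycled) " (recycling run)" else ""))
  cat(sprintf("final train loss %.6f, mean PC %.4f\n",
              h$loss[nrow(h)], h$mean_pc[nrow(h)]))
  invisible(x)
}

#' @export
summary.xtalformer <- function(object, examples = NULL, n_shells = 10L,
                               ...) {
  if (is.null(examples)) {
    cat("(pass the evaluation examples: summary(fit, examples))\n")
    return(invisible(print(object)))
  }
  report <- evaluate_model(object, examples, n_shells = n_shells)
  print(report)
  invisible(report)
}

#' Predict density maps for new examples
#'
#' @param object An `xtalformer` fit.
#' @param newdata A single `example_record` or a list of them.
#' @param ... Unused.
#' @return A [volume_grid] prediction, or a list of them.
#' @export
predict.xtalformer <- function(object, newdata, ...) {
  fit <- object$fit
  idx <- model_indices(fit$config)
  one <- function(ex) {
    recycled <- NULL
    if (fit$config$in_channels == 2L) {
      # recycling model: second channel is the base model's prediction
      recycled <- predict_example(ex, object$base_fit$params,
                                  object$base_fit$config, idx)
    }
    predict_example(ex, fit$params, fit$config, idx, recycled = recycled)
  }
  if (inherits(newdata, "example_record")) return(one(newdata))
  lapply(newdata, one)
}

#' @export
plot.xtalformer <- function(x, ...) {
  h <- x$fit$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "train loss", main = "loss", ...)
  graphics::plot(h$epoch, h$mean_pc, type = "l", xlab = "epoch",
                 ylab = "mean Pearson correlation", main = "map PC",
                 ylim = c(-1, 1), ...)
  graphics::abline(h = 0.9, lty = 3)
  invisible(x)
}

#' Residual maps of a fit
#'
#' @param object An `xtalformer` fit.
#' @param examples Examples with ground-truth density.
#' @param ... Unused.
#' @return A list of [volume_grid]s holding prediction minus truth.
#' @export
residuals.xtalformer <- function(object, examples, ...) {
  preds <- predict(object, examples)
  if (inherits(examples, "example_record")) {
    examples <- list(examples)
    preds <- list(preds)
  }
  Map(function(ex, pr) {
    volume_grid(pr$values - ex$density$values, ex$cell,
                kind = "prediction", spacing = pr$spacing)
  }, examples, preds)
}

#' Save / load a model checkpoint
#'
#' Single-file container holding the model config and all named parameter
#' arrays (plus, for recycling fits, the base model).
#'
#' @param object An `xtalformer` fit or a raw fit list.
#' @param path Checkpoint file path.
#' @export
write_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)
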