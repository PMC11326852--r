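#' Evaluate predictions by map correlation and phase error
#'
#' For every example the model prediction is compared with the ground
#' truth density: the Pearson correlation over voxels, and the mean phase
#' error of the structure factors obtained from both maps by forward
#' transform to the example's build resolution (F(0,0,0) excluded),
#' binned into equal-count resolution shells. Because the dataset builder
#' centers every structure, maps share a common origin and no origin
#' search is needed or performed.
#'
#' @param fit A fit from [train_model()] / [recycle_train()] or an
#'   `xtalformer` object.
#' @param examples List of `example_record`s carrying ground truth.
#' @param n_shells Number of resolution shells (default 10).
#' @param recycled Optional named list of previous predictions (by id)
#'   for two-channel models; defaults to the fit's own `recycled_from`.
#' @return An object of class `evaluation_report`: per-example PC and
#'   mean phase error, their means, per-shell mean phase error across
#'   examples, per-shell fraction of examples with shell mean < 60
#'   degrees, and the overall fraction of examples with mean phase error
#'   < 60 degrees.
#' @export
evaluate_model <- function(fit, examples, n_shells = 10L, recycled = NULL) {
  if (inherits(fit, "xtalformer")) fit <- fit$fit
  if (is.null(recycled)) recycled <- fit$recycled_from
  idx <- model_indices(fit$config)
  n <- length(examples)
  pcs <- numeric(n)
  mean_err <- numeric(n)
  shell_tabs <- vector("list", n)
  ids <- character(n)
  for (i in seq_len(n)) {
    ex <- examples[[i]]
    ids[i] <- ex$id
    pred <- predict_example(ex, fit$params, fit$config, idx,
                            recycled = if (!is.null(recycled))
                              recycled[[ex$id]])
    pcs[i] <- pearson_map(ex$density, pred)
    sf_t <- sf_from_map(ex$density, ex$d_min)
    sf_p <- sf_from_map(pred, ex$d_min)
    pe <- phase_error(sf_p, sf_t, n_shells = n_shells)
    mean_err[i] <- pe$mean_error
    shell_tabs[[i]] <- pe$shells
  }
  n_sh <- nrow(shell_tabs[[1L]])
  shell_mat <- vapply(shell_tabs, function(t) t$mean_error, numeric(n_sh))
  shell_mat <- matrix(shell_mat, nrow = n_sh)
  shells <- data.frame(
    shell = shell_tabs[[1L]]$shell,
    d_max = rowMeans(vapply(shell_tabs, function(t) t$d_max,
                            numeric(n_sh))),
    d_min = rowMeans(vapply(shell_tabs, function(t) t$d_min,
                            numeric(n_sh))),
    mean_error = rowMeans(shell_mat),
    frac_examples_below_60 = rowMeans(shell_mat < 60))
  structure(list(ids = ids, per_example_pc = pcs,
                 per_example_phase_error = mean_err,
                 mean_pc = mean(pcs),
                 mean_phase_error = mean(mean_err),
                 frac_examples_below_60 = mean(mean_err < 60),
                 shells = shells, n_examples = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation over %d examples\n", x$n_examples))
  cat(sprintf("  mean PC:           %.4f\n", x$mean_pc))
  cat(sprintf("  mean phase error:  %.2f deg\n", x$mean_phase_error))
  cat(sprintf("  examples < 60 deg: %.1f%%\n",
              100 * x$frac_examples_below_60))
  cat("per-shell mean phase error (deg):\n")
  print(x$shells, row.names = FALSE, digits = 4)
  invisible(x)
}

report_to_json <- function(report, path) {
  out <- list(
    mean_pc = report$mean_pc,
    mean_phase_error = report$mean_phase_error,
    frac_examples_below_60 = report$frac_examples_below_60,
    per_example = data.frame(id = report$ids, pc = report$per_example_pc,
                             mean_phase_error =
                               report$per_example_phase_error),
    shells = report$shells)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
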