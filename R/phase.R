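#' Mean phase error between two reflection sets
#'
#' For every common reflection (excluding F(0,0,0)) the absolute wrapped
#' phase difference |wrap(phi_pred - phi_truth)| in [0, 180] degrees is
#' computed. Reflections are then partitioned into `n_shells` equal-count
#' resolution shells ordered from low resolution (large d) to high. The
#' primary statistic is the unweighted mean error; an amplitude-weighted
#' mean (weights = truth amplitudes) is reported alongside, since phase
#' agreement of strong reflections matters most for map quality.
#'
#' @param pred,truth `reflection_set`s sharing cell and (h,k,l) domain.
#' @param n_shells Number of equal-count resolution shells (default 10).
#' @return A list of class `phase_error` with `mean_error`,
#'   `weighted_mean_error`, `n_reflections`, `frac_below_60` (fraction of
#'   reflections with error < 60 degrees) and `shells`, a data.frame with
#'   per-shell d range, count, mean error, weighted mean error and fraction
#'   of reflections below 60 degrees.
#' @export
phase_error <- function(pred, truth, n_shells = 10L) {
  stopifnot(inherits(pred, "reflection_set"),
            inherits(truth, "reflection_set"))
  kp <- do.call(paste, pred$hkl[c("h", "k", "l")])
  kt <- do.call(paste, truth$hkl[c("h", "k", "l")])
  if (nrow(pred$hkl) != nrow(truth$hkl) || !all(kp == kt)) {
    stop("domain mismatch: reflection sets index different (h,k,l)",
         call. = FALSE)
  }
  keep <- !(truth$hkl$h == 0 & truth$hkl$k == 0 & truth$hkl$l == 0)
  dphi <- wrap_phase_diff(Arg(pred$F[keep]) * 180 / pi,
                          Arg(truth$F[keep]) * 180 / pi)
  d <- truth$hkl$d[keep]
  w <- Mod(truth$F[keep])
  if (sum(w) == 0) w <- rep(1, length(w))
  n_shells <- max(1L, min(as.integer(n_shells), length(dphi)))
  # equal-count shells from low resolution (large d) to high
  shell_id <- ceiling(rank(-d, ties.method = "first") / length(d) * n_shells)
  shells <- do.call(rbind, lapply(seq_len(n_shells), function(s) {
    i <- shell_id == s
    data.frame(shell = s,
               d_max = max(d[i]), d_min = min(d[i]), n = sum(i),
               mean_error = mean(dphi[i]),
               weighted_mean_error = sum(w[i] * dphi[i]) / sum(w[i]),
               frac_below_60 = mean(dphi[i] < 60))
  }))
  structure(list(mean_error = mean(dphi),
                 weighted_mean_error = sum(w * dphi) / sum(w),
                 n_reflections = length(dphi),
                 frac_below_60 = mean(dphi < 60),
                 shells = shells),
            class = "phase_error")
}

# absolute wrapped difference of two phase vectors (degrees) into [0, 180]
wrap_phase_diff <- function(phi1, phi2) {
  abs(((phi1 - phi2 + 180) %% 360) - 180)
}

#' @export
print.phase_error <- function(x, ...) {
  cat(sprintf("mean phase error: %.2f deg over %d reflections (%.1f%% < 60 deg)\n",
              x$mean_error, x$n_reflections, 100 * x$frac_below_60))
  print(x$shells, row.names = FALSE, digits = 4)
  invisible(x)
}
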