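#' Electron density map from structure factors
#'
#' Synthesizes rho(x) = (1/V) sum_hkl F(h,k,l) exp(-2 pi i (hx + ky + lz))
#' on a regular grid by placing the Friedel-expanded coefficients into a
#' complex frequency grid and applying a discrete Fourier transform (R's
#' forward `fft`, whose kernel is exp(-2 pi i h n / N), matching the
#' crystallographic synthesis convention with voxel n at fraction n/N).
#' The imaginary residue must vanish for Friedel-consistent input.
#'
#' @param refs A `reflection_set` (Friedel-unique half).
#' @param grid A list with `dims` (and optionally `spacing`), as returned
#'   by [build_grid()].
#' @return A [volume_grid] of kind "density".
#' @export
density_from_sf <- function(refs, grid) {
  stopifnot(inherits(refs, "reflection_set"))
  fgrid <- sf_to_frequency_grid(refs, grid$dims)
  cmplx <- stats::fft(fgrid) / refs$cell$V
  assert_real_map(cmplx)
  volume_grid(Re(cmplx), refs$cell, kind = "density",
              spacing = grid$spacing %||% NULL)
}

#' Patterson map from structure factors
#'
#' Synthesizes p(u) = (1/V) sum_hkl |F(h,k,l)|^2 exp(-2 pi i (hu + kv + lw)):
#' amplitudes squared, all phases set to zero. The result is real and
#' centrosymmetric, with its origin peak at voxel (0,0,0).
#'
#' @inheritParams density_from_sf
#' @return A [volume_grid] of kind "patterson".
#' @export
patterson_from_sf <- function(refs, grid) {
  stopifnot(inherits(refs, "reflection_set"))
  fgrid <- sf_to_frequency_grid(refs, grid$dims, values = Mod(refs$F)^2 + 0i)
  cmplx <- stats::fft(fgrid) / refs$cell$V
  assert_real_map(cmplx)
  volume_grid(Re(cmplx), refs$cell, kind = "patterson",
              spacing = grid$spacing %||% NULL)
}

#' Patterson map as the autocorrelation of a density map
#'
#' Computes p = Re(FT(|FTinv(e)|^2)) on the sampling grid of `e`: the
#' discrete counterpart of squaring amplitudes and dropping phases. The
#' "inverse-shifted" copy of the density in the autocorrelation appears as
#' complex conjugation in frequency space. Scaling matches
#' [patterson_from_sf()] exactly for band-limited maps.
#'
#' @param e A real-valued [volume_grid] of kind "density" (or any map).
#' @return A [volume_grid] of kind "patterson".
#' @export
patterson_from_density <- function(e) {
  stopifnot(inherits(e, "volume_grid"))
  Fgrid <- stats::fft(e$values, inverse = TRUE) * (e$cell$V / prod(e$dims))
  cmplx <- stats::fft(Mod(Fgrid)^2 + 0i) / e$cell$V
  volume_grid(Re(cmplx), e$cell, kind = "patterson", spacing = e$spacing)
}

assert_real_map <- function(cmplx) {
  re_peak <- max(abs(Re(cmplx)))
  im_peak <- max(abs(Im(cmplx)))
  if (re_peak > 0 && im_peak > 1e-6 * re_peak) {
    stop("non-real density: Friedel-inconsistent structure factors",
         call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct O(N_voxel * N_hkl) synthesis of the density equation; reference
# oracle for the FFT path on tiny grids.
density_direct_sum <- function(refs, dims) {
  hkl <- refs$hkl
  cell <- refs$cell
  out <- array(0, dims)
  fx <- (seq_len(dims[1L]) - 1L) / dims[1L]
  fy <- (seq_len(dims[2L]) - 1L) / dims[2L]
  fz <- (seq_len(dims[3L]) - 1L) / dims[3L]
  for (r in seq_len(nrow(hkl))) {
    ph <- 2 * pi * (outer(outer(hkl$h[r] * fx, hkl$k[r] * fy, "+"),
                          hkl$l[r] * fz, "+"))
    Fr <- refs$F[r]
    term <- Re(Fr) * cos(ph) + Im(Fr) * sin(ph) # Re(F exp(-i ph))
    mult <- if (hkl$h[r] == 0 && hkl$k[r] == 0 && hkl$l[r] == 0) 1 else 2
    out <- out + mult * term
  }
  out / cell$V
}
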