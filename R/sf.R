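#' @name reflection_set
#' @title Indexed structure factors to a resolution limit
#'
#' @description A `reflection_set` stores complex structure factors
#' F(h,k,l) of a P1 orthorhombic cell on a Friedel-unique half sphere
#' (h > 0, or h = 0 & k > 0, or h = k = 0 & l >= 0, which includes
#' F(0,0,0)) for all indices with resolution `d >= d_min`. For a real
#' density the other half follows from Friedel symmetry,
#' F(-h,-k,-l) = Conj(F(h,k,l)).
NULL

# Enumerate the Friedel-unique index half for a cell/resolution. Returns a
# data.frame h,k,l,d sorted by (h,k,l).
enumerate_hkl <- function(cell, d_min) {
  if (!is.numeric(d_min) || d_min <= 0) {
    stop("invalid resolution: d_min must be > 0", call. = FALSE)
  }
  hmax <- floor(cell$a / d_min)
  kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  inv_d2 <- (g$h / cell$a)^2 + (g$k / cell$b)^2 + (g$l / cell$c)^2
  keep <- inv_d2 <= 1 / d_min^2 + 1e-12
  half <- g$h > 0 | (g$h == 0 & g$k > 0) | (g$h == 0 & g$k == 0 & g$l >= 0)
  g <- g[keep & half, , drop = FALSE]
  inv_d2 <- inv_d2[keep & half]
  g$d <- ifelse(inv_d2 > 0, 1 / sqrt(inv_d2), Inf)
  g <- g[order(g$h, g$k, g$l), , drop = FALSE]
  rownames(g) <- NULL
  g
}

new_reflection_set <- function(hkl, F, cell, d_min) {
  structure(list(hkl = hkl[, c("h", "k", "l", "d")], F = F, cell = cell,
                 d_min = d_min),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf(
    "reflection set: %d unique reflections to d_min = %.3g A\n",
    nrow(x$hkl), x$d_min))
  print(x$cell)
  invisible(x)
}

#' Amplitudes and phases of a reflection set
#'
#' @param refs A `reflection_set`.
#' @return A data.frame with columns h, k, l, d, amplitude `Fabs` and phase
#'   `phi` in degrees in `[0, 360)`.
#' @export
amplitudes_phases <- function(refs) {
  stopifnot(inherits(refs, "reflection_set"))
  out <- refs$hkl
  out$Fabs <- Mod(refs$F)
  out$phi <- (Arg(refs$F) * 180 / pi) %% 360
  out
}

# Atomic scattering factor per reflection: point model uses the electron
# count (1 for unknown elements); the Gaussian model uses 4-term
# Cromer-Mann coefficients, defined only for H, C, N, O, S.
scattering_factors <- function(elements, s, model = c("point", "gaussian")) {
  model <- match.arg(model)
  n_ref <- length(s)
  f <- matrix(0, n_ref, length(elements))
  if (model == "point") {
    fe <- .electron_counts[elements]
    fe[is.na(fe)] <- 1
    f <- matrix(rep(fe, each = n_ref), n_ref, length(elements))
  } else {
    bad <- setdiff(unique(elements), names(.cromer_mann))
    if (length(bad) > 0) {
      stop("unsupported element(s) for gaussian scattering model: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    s2_4 <- (s / 2)^2 # (sin theta / lambda)^2
    for (el in unique(elements)) {
      cm <- .cromer_mann[[el]]
      fe <- cm$c + colSums(cm$a * exp(-outer(cm$b, s2_4)))
      f[, elements == el] <- fe
    }
  }
  f
}

#' Structure factors of a fragment by direct summation
#'
#' Computes F(h,k,l) = sum_j f_j(s) occ_j exp(-B_j s^2 / 4)
#' exp(2 pi i (h x_j/a + k y_j/b + l z_j/c)) with s = 1/d over the
#' Friedel-unique half sphere to `d_min`, including F(0,0,0).
#'
#' @param structure A [fragment_structure] with a cell.
#' @param d_min Resolution limit in Angstrom.
#' @param scattering "point" (f = electron count; analytically exact test
#'   oracles) or "gaussian" (Cromer-Mann form factors for H/C/N/O/S).
#' @return A `reflection_set`.
#' @export
calc_structure_factors <- function(structure, d_min,
                                   scattering = c("point", "gaussian")) {
  scattering <- match.arg(scattering)
  stopifnot(inherits(structure, "fragment_structure"))
  if (is.null(structure$cell)) stop("structure has no cell", call. = FALSE)
  if (nrow(structure$atoms) == 0L) {
    stop("empty structure: no atoms", call. = FALSE)
  }
  cell <- structure$cell
  hkl <- enumerate_hkl(cell, d_min)
  frac <- fractional_coords(structure)
  s <- ifelse(is.finite(hkl$d), 1 / hkl$d, 0)
  f <- scattering_factors(structure$atoms$element, s, scattering)
  occ <- structure$atoms$occ
  bfac <- structure$atoms$b
  damp <- exp(-outer(s^2 / 4, bfac)) # n_ref x n_atom
  weights <- f * damp * rep(occ, each = nrow(hkl))
  phase <- 2 * pi * (outer(hkl$h, frac[, 1L]) + outer(hkl$k, frac[, 2L]) +
                       outer(hkl$l, frac[, 3L]))
  F <- rowSums(weights * cos(phase)) + 1i * rowSums(weights * sin(phase))
  new_reflection_set(hkl, F, cell, d_min)
}

# Place a Friedel-unique half set onto a full complex frequency grid of the
# given dims (index (h mod N) + 1). `values` defaults to F; passing
# Mod(F)^2 yields the Patterson coefficient grid. Errors if any index pair
# (h, -h) would collide on the grid (grid too coarse for d_min).
sf_to_frequency_grid <- function(refs, dims, values = NULL) {
  hkl <- refs$hkl
  if (is.null(values)) values <- refs$F
  hm <- c(max(abs(hkl$h)), max(abs(hkl$k)), max(abs(hkl$l)))
  if (any(2L * hm + 1L > dims)) {
    stop("grid dims too small for the reflection set (index aliasing)",
         call. = FALSE)
  }
  grid <- array(0 + 0i, dims)
  idx <- cbind(hkl$h %% dims[1L], hkl$k %% dims[2L], hkl$l %% dims[3L]) + 1L
  grid[idx] <- values
  mate <- !(hkl$h == 0 & hkl$k == 0 & hkl$l == 0)
  midx <- cbind((-hkl$h[mate]) %% dims[1L], (-hkl$k[mate]) %% dims[2L],
                (-hkl$l[mate]) %% dims[3L]) + 1L
  grid[midx] <- Conj(values[mate])
  grid
}

#' Structure factors from a sampled map by forward transform
#'
#' Recovers F(h,k,l) = (V / N1 N2 N3) sum_n m_n exp(+2 pi i h.n/N) from a
#' real map sampled at fractional coordinates n/N, on the Friedel-unique
#' half sphere to `d_min`. For a band-limited map synthesized from a
#' reflection set this inverts [density_from_sf()] exactly.
#'
#' @param m A [volume_grid].
#' @param d_min Resolution limit in Angstrom; indices beyond the grid's
#'   alias-free range are dropped.
#' @return A `reflection_set`.
#' @export
sf_from_map <- function(m, d_min) {
  stopifnot(inherits(m, "volume_grid"))
  cell <- m$cell
  hkl <- enumerate_hkl(cell, d_min)
  ok <- 2L * abs(hkl$h) < m$dims[1L] & 2L * abs(hkl$k) < m$dims[2L] &
    2L * abs(hkl$l) < m$dims[3L]
  hkl <- hkl[ok, , drop = FALSE]
  Fgrid <- stats::fft(m$values, inverse = TRUE) * (cell$V / prod(m$dims))
  idx <- cbind(hkl$h %% m$dims[1L], hkl$k %% m$dims[2L],
               hkl$l %% m$dims[3L]) + 1L
  new_reflection_set(hkl, Fgrid[idx], cell, d_min)
}

#' Write a reflection set as plain text
#'
#' One line per reflection: `h k l |F| phi` with the phase in degrees.
#'
#' @param refs A `reflection_set`.
#' @param path Output file path.
#' @export
write_reflections <- function(refs, path) {
  ap <- amplitudes_phases(refs)
  lines <- sprintf("%d %d %d %.8g %.6f", ap$h, ap$k, ap$l, ap$Fabs, ap$phi)
  writeLines(c(sprintf("# cell %.6g %.6g %.6g d_min %.6g",
                       refs$cell$a, refs$cell$b, refs$cell$c, refs$d_min),
               lines), path)
  invisible(path)
}

#' Read a reflection set written by [write_reflections()]
#'
#' @param path Input file path.
#' @return A `reflection_set`.
#' @export
read_reflections <- function(path) {
  lines <- readLines(path)
  hdr <- as.numeric(strsplit(sub("^# cell ", "", lines[1L]), " ")[[1L]][c(1:3, 5)])
  cell <- unit_cell(hdr[1L], hdr[2L], hdr[3L])
  tab <- utils::read.table(text = lines[-1L],
                           col.names = c("h", "k", "l", "Fabs", "phi"))
  inv_d2 <- (tab$h / cell$a)^2 + (tab$k / cell$b)^2 + (tab$l / cell$c)^2
  tab$d <- ifelse(inv_d2 > 0, 1 / sqrt(inv_d2), Inf)
  F <- tab$Fabs * exp(1i * tab$phi * pi / 180)
  new_reflection_set(tab, F, cell, hdr[4L])
}
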