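#' Orthorhombic unit cell
#'
#' Constructs a P1 orthorhombic unit cell (all angles fixed at 90 degrees).
#'
#' @param a,b,c Cell edge lengths in Angstrom; all must be positive.
#' @return An object of class `unit_cell` with fields `a`, `b`, `c` and the
#'   derived volume `V = a*b*c` in cubic Angstrom.
#' @examples
#' unit_cell(41, 30, 24)
#' @export
unit_cell <- function(a, b, c) {
  edges <- c(a, b, c)
  if (!is.numeric(edges) || length(edges) != 3L || any(!is.finite(edges)) ||
      any(edges <= 0)) {
    stop("invalid cell: edges must be finite and positive", call. = FALSE)
  }
  structure(list(a = unname(a), b = unname(b), c = unname(c),
                 V = unname(a * b * c)),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("P1 orthorhombic cell: a=%.3f b=%.3f c=%.3f A, V=%.1f A^3\n",
              x$a, x$b, x$c, x$V))
  invisible(x)
}

cell_edges <- function(cell) c(cell$a, cell$b, cell$c)

# Electron counts used as point-scatterer form factors and for "center of
# mass" style bookkeeping of scattering power.
.electron_counts <- c(H = 1, C = 6, N = 7, O = 8, S = 16)

# Standard atomic masses (u) for the mass-weighted centroid.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

# 4-term Cromer-Mann coefficients (International Tables) for the supported
# elements; f(s) = sum_i a_i exp(-b_i (s/2)^2) + c with s = 1/d.
.cromer_mann <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

#' Peptide fragment in a unit cell
#'
#' Bundles an ordered atom table, its grouping into residues, and the unit
#' cell containing the fragment: the "molecule in a box" that every map in
#' this package is derived from.
#'
#' @param atoms A data.frame with columns `element` (character), `x`, `y`,
#'   `z` (Cartesian Angstrom), and optionally `occ` (occupancy in (0,1],
#'   default 1) and `b` (isotropic B-factor in A^2, default 0).
#' @param residues A data.frame with columns `type` (three-letter residue
#'   code), `first`, `last` (1-based atom index range). Ranges must
#'   partition the atom table in order.
#' @param cell A [unit_cell], or `NULL` if the cell is assigned later (e.g.
#'   by [expand_cell()]).
#' @return An object of class `fragment_structure`.
#' @export
fragment_structure <- function(atoms, residues = NULL, cell = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L,
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (any(atoms$occ <= 0 | atoms$occ > 1)) {
    stop("occupancy must lie in (0, 1]", call. = FALSE)
  }
  if (any(atoms$b < 0)) stop("B-factors must be >= 0", call. = FALSE)
  if (is.null(residues)) {
    residues <- data.frame(type = "UNK", first = 1L, last = nrow(atoms))
  }
  if (residues$first[1L] != 1L ||
      residues$last[nrow(residues)] != nrow(atoms) ||
      (nrow(residues) > 1L &&
       any(residues$first[-1L] != residues$last[-nrow(residues)] + 1L))) {
    stop("residue index ranges must partition the atom list", call. = FALSE)
  }
  if (!is.null(cell)) stopifnot(inherits(cell, "unit_cell"))
  structure(list(atoms = atoms, residues = residues, cell = cell),
            class = "fragment_structure")
}

#' @export
print.fragment_structure <- function(x, ...) {
  cat(sprintf("fragment: %d atoms in %d residues (%s)\n",
              nrow(x$atoms), nrow(x$residues),
              paste(x$residues$type, collapse = "-")))
  if (!is.null(x$cell)) print(x$cell) else cat("  (no cell assigned)\n")
  invisible(x)
}

n_residues <- function(structure) nrow(structure$residues)

atom_xyz <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

set_atom_xyz <- function(structure, xyz) {
  structure$atoms$x <- xyz[, 1L]
  structure$atoms$y <- xyz[, 2L]
  structure$atoms$z <- xyz[, 3L]
  structure
}

#' Wrap atoms into the unit cell
#'
#' Translates each atom by lattice vectors so its coordinates lie in
#' `[0,a) x [0,b) x [0,c)`. Structure-factor phases are periodic, so
#' wrapping never changes any derived map.
#'
#' @param structure A [fragment_structure] with a cell.
#' @return The structure with wrapped coordinates.
#' @export
wrap_into_cell <- function(structure) {
  stopifnot(!is.null(structure$cell))
  edges <- cell_edges(structure$cell)
  xyz <- atom_xyz(structure)
  for (i in 1:3) xyz[, i] <- xyz[, i] %% edges[i]
  set_atom_xyz(structure, xyz)
}

fractional_coords <- function(structure) {
  sweep(atom_xyz(structure), 2L, cell_edges(structure$cell), "/")
}

#' Mass-weighted centroid of a fragment
#'
#' @param structure A [fragment_structure].
#' @return Numeric length-3 Cartesian centroid (Angstrom). Unknown elements
#'   are assigned the mass of carbon.
#' @export
center_of_mass <- function(structure) {
  m <- .atomic_masses[structure$atoms$element]
  m[is.na(m)] <- .atomic_masses[["C"]]
  xyz <- atom_xyz(structure)
  colSums(xyz * m) / sum(m)
}
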