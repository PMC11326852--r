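#' Minimum intermolecular contact distance under lattice translations
#'
#' Minimum Euclidean distance between any atom of the central copy of the
#' fragment and any atom of its 26 neighboring periodic images. Self-image
#' pairs at zero lattice offset (i.e. intramolecular distances) are not
#' considered: the quantity audits crystal packing, not chain geometry.
#'
#' @param structure A [fragment_structure] with a cell.
#' @return Minimum contact distance in Angstrom.
#' @export
min_intermolecular_contact <- function(structure) {
  stopifnot(inherits(structure, "fragment_structure"),
            !is.null(structure$cell), nrow(structure$atoms) >= 1L)
  xyz <- atom_xyz(structure)
  edges <- cell_edges(structure$cell)
  offsets <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  best <- Inf
  for (r in seq_len(nrow(offsets))) {
    shift <- offsets[r, ] * edges
    sx <- sweep(xyz, 2L, shift, "+")
    # cross distances central copy vs shifted image
    d2 <- outer(rowSums(xyz^2), rowSums(sx^2), "+") - 2 * xyz %*% t(sx)
    best <- min(best, sqrt(max(0, min(d2))))
  }
  best
}

discard_signal <- function(reason) {
  structure(list(reason = reason), class = "discard_signal")
}

#' @export
print.discard_signal <- function(x, ...) {
  cat("example discarded:", x$reason, "\n")
  invisible(x)
}

#' Grow a unit cell until periodic images no longer clash
#'
#' Starting from the per-axis coordinate ranges (max - min) of the
#' fragment, grows all three cell edges by `step` per iteration until the
#' minimum intermolecular contact reaches `threshold`. Atoms keep their
#' Cartesian coordinates. If `max_iter` iterations do not suffice the
#' example is discarded.
#'
#' @param structure A [fragment_structure]; any existing cell is ignored.
#' @param threshold Required minimum contact in Angstrom (default 2.75).
#' @param step Per-iteration growth of each edge in Angstrom (default
#'   0.25; isotropic growth keeps fragment-to-cell proportions).
#' @param max_iter Iteration budget (default 100).
#' @return The structure with its new cell, or a `discard_signal`.
#' @export
expand_cell <- function(structure, threshold = 2.75, step = 0.25,
                        max_iter = 100L) {
  stopifnot(step > 0)
  xyz <- atom_xyz(structure)
  edges <- pmax(apply(xyz, 2L, function(v) diff(range(v))), step)
  # shift so the fragment starts at the cell origin
  structure <- set_atom_xyz(structure, sweep(xyz, 2L, apply(xyz, 2L, min)))
  for (iter in seq_len(max_iter + 1L)) {
    structure$cell <- unit_cell(edges[1L], edges[2L], edges[3L])
    if (min_intermolecular_contact(structure) >= threshold) {
      return(structure)
    }
    edges <- edges + step
  }
  discard_signal(sprintf(
    "clash: contact below %.3g A after %d expansion iterations",
    threshold, max_iter))
}

#' Center a fragment's center of mass in its cell
#'
#' Applies one common translation so the mass-weighted centroid sits at
#' (a/2, b/2, c/2); relative geometry is untouched. Centering removes the
#' translation ambiguity of the Patterson map, so predicted and true maps
#' can be compared without an origin search. Idempotent.
#'
#' @param structure A [fragment_structure] with a cell.
#' @return The centered structure.
#' @export
center_structure <- function(structure) {
  stopifnot(!is.null(structure$cell))
  com <- center_of_mass(structure)
  target <- cell_edges(structure$cell) / 2
  xyz <- sweep(atom_xyz(structure), 2L, target - com, "+")
  set_atom_xyz(structure, xyz)
}

#' Permute axes so a >= b >= c
#'
#' Reorients the structure by a reindexing operation so the first cell
#' axis is the longest and the third the shortest; coordinates and cell
#' edges are permuted consistently. Ties keep the original relative axis
#' order (stable sort).
#'
#' @param structure A [fragment_structure] with a cell.
#' @return The reindexed structure.
#' @export
reindex_axes <- function(structure) {
  stopifnot(!is.null(structure$cell))
  edges <- cell_edges(structure$cell)
  perm <- order(-edges) # stable for ties
  xyz <- atom_xyz(structure)[, perm, drop = FALSE]
  structure <- set_atom_xyz(structure, xyz)
  structure$cell <- unit_cell(edges[perm[1L]], edges[perm[2L]],
                              edges[perm[3L]])
  structure
}

#' Standardized per-residue partial-structure maps
#'
#' For each residue of the fragment (in chain order) the idealized
#' template of its residue type is placed in the cell and its standalone
#' density computed on the example's grid and normalized. Templates are
#' example-independent: two examples with the same residue type on the
#' same grid receive identical partial maps. By default the template is
#' centered at the cell center ("center"); `placement = "true"` instead
#' translates it to the residue's actual centroid.
#'
#' @param structure A [fragment_structure] with a cell.
#' @param grid Grid spec from [build_grid()].
#' @param d_min Resolution limit in Angstrom.
#' @param placement "center" (default) or "true".
#' @param scattering Scattering model, as in [calc_structure_factors()].
#' @param cache Optional environment used to reuse identical partial maps
#'   across examples sharing a cell and grid.
#' @return A list of class `partial_structure_set`: `grids` (list of
#'   [volume_grid] of kind "partial") and `residue_types`.
#' @export
make_partial_structures <- function(structure, grid, d_min,
                                    placement = c("center", "true"),
                                    scattering = "point", cache = NULL) {
  placement <- match.arg(placement)
  cell <- structure$cell
  grids <- vector("list", n_residues(structure))
  for (j in seq_len(n_residues(structure))) {
    type <- structure$residues$type[j]
    key <- paste(type, paste(grid$dims, collapse = "x"),
                 paste(signif(cell_edges(cell), 10), collapse = "x"),
                 scattering, sep = "|")
    if (placement == "center" && !is.null(cache) && !is.null(cache[[key]])) {
      grids[[j]] <- cache[[key]]
      next
    }
    tmpl <- residue_template(type)
    tmpl$cell <- cell
    target <- if (placement == "center") {
      cell_edges(cell) / 2
    } else {
      idx <- structure$residues$first[j]:structure$residues$last[j]
      colMeans(atom_xyz(structure)[idx, , drop = FALSE])
    }
    shift <- target - center_of_mass(tmpl)
    tmpl <- set_atom_xyz(tmpl, sweep(atom_xyz(tmpl), 2L, shift, "+"))
    refs <- calc_structure_factors(tmpl, d_min, scattering = scattering)
    g <- density_from_sf(refs, grid)
    g$kind <- "partial"
    g <- normalize_map(g)
    if (placement == "center" && !is.null(cache)) cache[[key]] <- g
    grids[[j]] <- g
  }
  structure(list(grids = grids, residue_types = structure$residues$type),
            class = "partial_structure_set")
}

#' Group examples into tensor-size bins and drop sparse bins
#'
#' Examples are grouped by their exact grid dimension triple; training
#' batches must be drawn within one bin, so bins holding fewer examples
#' than the minimum batch size are removed.
#'
#' @param examples List of example records from [build_example()].
#' @param min_batch Minimum bin occupancy to keep (>= 1).
#' @return A list with `bins` (named list of example lists, key
#'   "N1xN2xN3") and `report` (data.frame of bin sizes and kept flag).
#' @export
bin_and_filter <- function(examples, min_batch = 1L) {
  stopifnot(min_batch >= 1L)
  keys <- vapply(examples,
                 function(ex) paste(ex$density$dims, collapse = "x"),
                 character(1L))
  bins <- split(examples, keys)
  sizes <- vapply(bins, length, integer(1L))
  keep <- sizes >= min_batch
  report <- data.frame(dims = names(bins), n = as.integer(sizes),
                       kept = keep, row.names = NULL)
  list(bins = bins[keep], report = report)
}

#' Build one (Patterson, density, partials) training example
#'
#' Applies the dataset rules end to end: cell assignment (iterative
#' expansion in "variable" mode, a fixed cell otherwise), discard on
#' intermolecular clash, axis reindexing, center-of-mass centering,
#' structure factors to `d_min`, density and Patterson synthesis,
#' standardized partial structures, and max-abs normalization of every
#' map.
#'
#' @param structure A [fragment_structure].
#' @param d_min Resolution limit in Angstrom (default 1.5).
#' @param oversampling Grid oversampling factor (default 3.0, i.e. 0.5
#'   Angstrom spacing at 1.5 Angstrom resolution).
#' @param mode "variable" (expand a minimal cell per fragment) or "fixed"
#'   (place the fragment in `fixed_cell`; clashing fragments are
#'   discarded).
#' @param fixed_cell Cell used in fixed mode (default
#'   `unit_cell(41, 30, 24)`).
#' @param contact Minimum intermolecular contact in Angstrom (default
#'   2.75).
#' @param patch_dims Optional length-3 integer: round grid dims up to
#'   multiples of the model patch (denser sampling over the same cell).
#' @param id Example identifier string.
#' @param placement,scattering,cache Passed to
#'   [make_partial_structures()] / [calc_structure_factors()].
#' @param step,max_iter Expansion schedule for variable mode.
#' @return A list of class `example_record` with fields `id`, `patterson`,
#'   `density`, `partials`, `cell`, `n_residues`, `residue_types`,
#'   `d_min`, `oversampling` — or a `discard_signal` with a reason.
#' @export
build_example <- function(structure, d_min = 1.5, oversampling = 3.0,
                          mode = c("variable", "fixed"),
                          fixed_cell = unit_cell(41, 30, 24),
                          contact = 2.75, patch_dims = NULL,
                          id = "example", placement = "center",
                          scattering = "point", cache = NULL,
                          step = 0.25, max_iter = 100L) {
  mode <- match.arg(mode)
  if (mode == "variable") {
    structure <- expand_cell(structure, threshold = contact, step = step,
                             max_iter = max_iter)
    if (inherits(structure, "discard_signal")) return(structure)
  } else {
    structure$cell <- fixed_cell
    if (min_intermolecular_contact(structure) < contact) {
      return(discard_signal(sprintf(
        "clash: contact below %.3g A in the fixed cell", contact)))
    }
  }
  structure <- reindex_axes(structure)
  structure <- center_structure(structure)
  structure <- wrap_into_cell(structure)
  grid <- build_grid(structure$cell, d_min, oversampling,
                     multiple_of = patch_dims)
  refs <- calc_structure_factors(structure, d_min, scattering = scattering)
  density <- density_from_sf(refs, grid)
  patterson <- patterson_from_sf(refs, grid)
  partials <- make_partial_structures(structure, grid, d_min,
                                      placement = placement,
                                      scattering = scattering,
                                      cache = cache)
  structure(list(id = id,
                 patterson = normalize_map(patterson),
                 density = normalize_map(density),
                 partials = partials,
                 cell = structure$cell,
                 n_residues = n_residues(structure),
                 residue_types = structure$residues$type,
                 d_min = d_min, oversampling = oversampling,
                 structure = structure),
            class = "example_record")
}

#' @export
print.example_record <- function(x, ...) {
  cat(sprintf("example %s: %d residues (%s), grid %s, d_min %.3g A\n",
              x$id, x$n_residues, paste(x$residue_types, collapse = "-"),
              paste(x$density$dims, collapse = "x"), x$d_min))
  invisible(x)
}
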