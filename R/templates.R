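# Idealized residue geometry, defined by internal coordinates and realized
# by natural-extension (NeRF) placement. Bond lengths in Angstrom, angles
# and torsions in degrees. Side-chain torsions are fixed at a common
# conformer so that every occurrence of a residue type yields the identical
# standardized template ("partial structure").

# Place atom D given positions A, B, C and internal coordinates:
# |C-D| = bond, angle(B,C,D) = theta, torsion(A,B,C,D) = phi.
place_atom <- function(A, B, C, bond, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2L] * bc[3L] - ab[3L] * bc[2L],
         ab[3L] * bc[1L] - ab[1L] * bc[3L],
         ab[1L] * bc[2L] - ab[2L] * bc[1L])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2L] * bc[3L] - n[3L] * bc[2L],
         n[3L] * bc[1L] - n[1L] * bc[3L],
         n[1L] * bc[2L] - n[2L] * bc[1L])
  d <- c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + bond * (d[1L] * bc + d[2L] * m + d[3L] * n)
}

# Backbone ideal values shared by the chain builder and the templates.
.bb <- list(n_ca = 1.46, ca_c = 1.52, c_n = 1.33, c_o = 1.231,
            ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.8)

# Side-chain Z-matrix rows: name, element, refs (A, B, C) among already
# placed atoms of the residue, bond, angle, torsion. CB is placed off the
# backbone with the standard improper torsion giving an L-amino acid.
.sidechains <- list(
  GLY = list(),
  ALA = list(
    list("CB", "C", "C", "N", "CA", 1.53, 110.1, 122.6)),
  SER = list(
    list("CB", "C", "C", "N", "CA", 1.53, 110.1, 122.6),
    list("OG", "O", "N", "CA", "CB", 1.417, 110.8, -65)),
  CYS = list(
    list("CB", "C", "C", "N", "CA", 1.53, 110.1, 122.6),
    list("SG", "S", "N", "CA", "CB", 1.808, 113.8, -65)),
  VAL = list(
    list("CB", "C", "C", "N", "CA", 1.53, 110.1, 122.6),
    list("CG1", "C", "N", "CA", "CB", 1.521, 110.5, 175),
    list("CG2", "C", "N", "CA", "CB", 1.521, 110.5, 53)),
  THR = list(
    list("CB", "C", "C", "N", "CA", 1.53, 110.1, 122.6),
    list("OG1", "O", "N", "CA", "CB", 1.433, 109.6, -60),
    list("CG2", "C", "N", "CA", "CB", 1.521, 110.5, 60)),
  LEU = list(
    list("CB", "C", "C", "N", "CA", 1.53, 110.1, 122.6),
    list("CG", "C", "N", "CA", "CB", 1.53, 116.3, -65),
    list("CD1", "C", "CA", "CB", "CG", 1.524, 110.7, 175),
    list("CD2", "C", "CA", "CB", "CG", 1.524, 110.7, 53)),
  ASP = list(
    list("CB", "C", "C", "N", "CA", 1.53, 110.1, 122.6),
    list("CG", "C", "N", "CA", "CB", 1.516, 112.6, -65),
    list("OD1", "O", "CA", "CB", "CG", 1.249, 118.4, -15),
    list("OD2", "O", "CA", "CB", "CG", 1.249, 118.4, 165)),
  ASN = list(
    list("CB", "C", "C", "N", "CA", 1.53, 110.1, 122.6),
    list("CG", "C", "N", "CA", "CB", 1.516, 112.6, -65),
    list("OD1", "O", "CA", "CB", "CG", 1.231, 120.8, -58),
    list("ND2", "N", "CA", "CB", "CG", 1.328, 116.4, 122))
)

#' Residue types with built-in idealized templates
#' @return Character vector of three-letter codes.
#' @export
supported_residues <- function() names(.sidechains)

# Build the standalone atoms of one residue given placed backbone N/CA/C
# positions; returns data.frame(name, element, x, y, z). O is placed at the
# given psi-like torsion (N-CA-C-O = psi + 180).
build_residue_atoms <- function(type, N, CA, C, psi = 135) {
  if (!type %in% names(.sidechains)) {
    stop("unsupported residue type: ", type, call. = FALSE)
  }
  pos <- list(N = N, CA = CA, C = C)
  pos$O <- place_atom(pos$N, pos$CA, pos$C, .bb$c_o, .bb$ang_ca_c_o,
                      (psi + 180) %% 360)
  names_out <- c("N", "CA", "C", "O")
  elems_out <- c("N", "C", "C", "O")
  for (row in .sidechains[[type]]) {
    pos[[row[[1L]]]] <- place_atom(pos[[row[[3L]]]], pos[[row[[4L]]]],
                                   pos[[row[[5L]]]], row[[6L]], row[[7L]],
                                   row[[8L]])
    names_out <- c(names_out, row[[1L]])
    elems_out <- c(elems_out, row[[2L]])
  }
  xyz <- do.call(rbind, pos[names_out])
  data.frame(name = names_out, element = elems_out,
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
}

.template_cache <- new.env(parent = emptyenv())

#' Standalone idealized residue template
#'
#' Returns the standardized single-residue fragment used to build
#' partial-structure maps: idealized bond geometry in a fixed common
#' conformation and a fixed standard orientation, independent of any
#' example the residue occurs in.
#'
#' @param type Three-letter residue code (see [supported_residues()]).
#' @return A [fragment_structure] with one residue and no cell.
#' @export
residue_template <- function(type) {
  if (!is.null(.template_cache[[type]])) return(.template_cache[[type]])
  N <- c(0, 0, 0)
  CA <- c(.bb$n_ca, 0, 0)
  ang <- .bb$ang_n_ca_c * pi / 180
  C <- CA + .bb$ca_c * c(-cos(ang), sin(ang), 0)
  atoms <- build_residue_atoms(type, N, CA, C)
  out <- fragment_structure(
    atoms[, c("element", "x", "y", "z")],
    residues = data.frame(type = type, first = 1L, last = nrow(atoms)))
  out$atom_names <- atoms$name
  .template_cache[[type]] <- out
  out
}

#' Load a residue template from a plain-text file
#'
#' The format is one atom per line: `name element x y z`, with `#` comment
#' lines ignored; coordinates in Angstrom. This lets users supply templates
#' for residue types the built-in library does not cover.
#'
#' @param path File path.
#' @param type Three-letter code to label the residue with.
#' @return A [fragment_structure] with one residue and no cell.
#' @export
load_residue_template <- function(path, type) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("name", "element", "x", "y", "z"))
  out <- fragment_structure(
    tab[, c("element", "x", "y", "z")],
    residues = data.frame(type = type, first = 1L, last = nrow(tab)))
  out$atom_names <- tab$name
  out
}
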