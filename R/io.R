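#' Read a peptide fragment from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d when available, else a minimal
#' fixed-column reader), keeping elements, coordinates, occupancies and
#' B-factors, and grouping atoms into residues by chain/residue number
#' (1-based numbering preserved in the residue table).
#'
#' @param path PDB file path.
#' @param cell Optional [unit_cell]; if omitted and the file has a
#'   CRYST1 record, that cell is used.
#' @return A [fragment_structure].
#' @export
read_fragment_pdb <- function(path, cell = NULL) {
  lines <- readLines(path)
  if (is.null(cell)) {
    cr <- grep("^CRYST1", lines, value = TRUE)
    if (length(cr) > 0) {
      v <- as.numeric(c(substr(cr[1L], 7, 15), substr(cr[1L], 16, 24),
                        substr(cr[1L], 25, 33)))
      if (all(is.finite(v)) && all(v > 0)) cell <- unit_cell(v[1], v[2], v[3])
    }
  }
  rec <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  if (length(rec) == 0L) stop("no ATOM/HETATM records in ", path,
                              call. = FALSE)
  f <- function(a, b) substr(rec, a, b)
  elem <- trimws(f(77, 78))
  name <- trimws(f(13, 16))
  # fall back to the first letter of the atom name when the element
  # column is blank
  elem[elem == ""] <- substr(gsub("[0-9]", "", name[elem == ""]), 1, 1)
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[!is.finite(occ)] <- 1
  bfac <- suppressWarnings(as.numeric(f(61, 66)))
  bfac[!is.finite(bfac)] <- 0
  atoms <- data.frame(element = elem,
                      x = as.numeric(f(31, 38)),
                      y = as.numeric(f(39, 46)),
                      z = as.numeric(f(47, 54)),
                      occ = occ, b = bfac)
  resno <- as.integer(f(23, 26))
  restyp <- trimws(f(18, 20))
  chain <- f(22, 22)
  key <- paste(chain, resno)
  runs <- rle(key)
  last <- cumsum(runs$lengths)
  first <- c(1L, utils::head(last, -1L) + 1L)
  residues <- data.frame(type = restyp[first], first = first, last = last,
                         number = resno[first])
  out <- fragment_structure(atoms, residues, cell = cell)
  out$atom_names <- name
  out
}

#' Write a fragment as a PDB file
#'
#' @param structure A [fragment_structure].
#' @param path Output path; a CRYST1 record is written when the structure
#'   has a cell.
#' @export
write_fragment_pdb <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(structure$cell)) {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      structure$cell$a, structure$cell$b, structure$cell$c, 90, 90, 90),
      con)
  }
  nm <- structure$atom_names %||% structure$atoms$element
  res <- structure$residues
  resno <- integer(nrow(structure$atoms))
  restyp <- character(nrow(structure$atoms))
  for (i in seq_len(nrow(res))) {
    resno[res$first[i]:res$last[i]] <- i
    restyp[res$first[i]:res$last[i]] <- res$type[i]
  }
  a <- structure$atoms
  for (i in seq_len(nrow(a))) {
    an <- nm[i]
    an_fmt <- if (nchar(an) < 4L) sprintf(" %-3s", an) else an
    writeLines(sprintf(
      "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, an_fmt, restyp[i], resno[i], a$x[i], a$y[i], a$z[i], a$occ[i],
      a$b[i], a$element[i]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a map as a CCP4/MRC file (mode 2, float32)
#'
#' Minimal MRC2014 writer: axis order fastest-to-slowest matches the grid
#' dims, cell angles 90 degrees, space group P1.
#'
#' @param grid A [volume_grid].
#' @param path Output path.
#' @export
write_ccp4_map <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  con <- file(path, "wb")
  on.exit(close(con))
  d <- grid$dims
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(d)                # NX NY NZ
  wi(2L)               # MODE 2 = float32
  wi(c(0L, 0L, 0L))    # NXSTART..
  wi(d)                # MX MY MZ (sampling == dims)
  wf(cell_edges(grid$cell))
  wf(c(90, 90, 90))
  wi(c(1L, 2L, 3L))    # MAPC MAPR MAPS
  v <- as.vector(grid$values)
  wf(c(min(v), max(v), mean(v)))
  wi(1L)               # ISPG = P1
  wi(0L)               # NSYMBT
  wi(integer(25L))     # EXTRA
  wf(c(0, 0, 0))       # ORIGIN
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian stamp
  wf(stats::sd(v))
  wi(0L)               # NLABL
  writeBin(raw(800L), con)
  wf(v)
  invisible(path)
}

#' Read a CCP4/MRC map written by [write_ccp4_map()]
#'
#' Supports mode-2 little-endian maps with axis order 1,2,3.
#'
#' @param path Map file path.
#' @param kind Map kind to label the grid with.
#' @return A [volume_grid].
#' @export
read_ccp4_map <- function(path, kind = "density") {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L,
                            endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L,
                            endian = "little")
  d <- ri(3L)
  mode <- ri(1L)
  if (mode != 2L) stop("only mode 2 (float32) maps supported",
                       call. = FALSE)
  ri(3L)
  ri(3L)
  cell <- rf(3L)
  rf(3L)
  axes <- ri(3L)
  if (!all(axes == 1:3)) stop("only axis order 1,2,3 supported",
                              call. = FALSE)
  seek(con, 1024L)
  v <- rf(prod(d))
  volume_grid(array(v, d), unit_cell(cell[1L], cell[2L], cell[3L]),
              kind = kind)
}
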