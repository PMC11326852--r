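#' Configuration for the synthetic fragment generator
#'
#' @param n_residues Number of residues in each generated chain (>= 1).
#' @param residue_alphabet Residue types to sample from; must be a subset
#'   of [supported_residues()]. Default GLY/ALA/SER.
#' @param seed Integer seed; the generator is a pure function of it.
#' @param dihedral_distribution "uniform" backbone torsions, or
#'   "helix-biased" (phi ~ N(-60, 10), psi ~ N(-45, 10) degrees).
#' @param max_tries Rejection-sampling budget for clash-free chains.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_residues = 2L,
                             residue_alphabet = c("GLY", "ALA", "SER"),
                             seed = 1L,
                             dihedral_distribution = c("uniform",
                                                       "helix-biased"),
                             max_tries = 200L) {
  dihedral_distribution <- match.arg(dihedral_distribution)
  stopifnot(n_residues >= 1L, length(residue_alphabet) >= 1L)
  bad <- setdiff(residue_alphabet, supported_residues())
  if (length(bad) > 0) {
    stop("no template for residue type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_residues = as.integer(n_residues),
                 residue_alphabet = residue_alphabet,
                 seed = as.integer(seed),
                 dihedral_distribution = dihedral_distribution,
                 max_tries = as.integer(max_tries)),
            class = "generator_config")
}

sample_torsions <- function(n, distribution) {
  if (distribution == "uniform") {
    list(phi = stats::runif(n, -180, 180), psi = stats::runif(n, -180, 180))
  } else {
    list(phi = stats::rnorm(n, -60, 10), psi = stats::rnorm(n, -45, 10))
  }
}

# Build one chain attempt from a sampled sequence and torsions.
build_chain <- function(types, phi, psi) {
  n <- length(types)
  res_atoms <- vector("list", n)
  # backbone of residue 1 in the standard frame
  N <- c(0, 0, 0)
  CA <- c(.bb$n_ca, 0, 0)
  ang <- .bb$ang_n_ca_c * pi / 180
  C <- CA + .bb$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      Np <- N; CAp <- CA; Cp <- C
      N <- place_atom(Np, CAp, Cp, .bb$c_n, .bb$ang_ca_c_n, psi[i - 1L])
      CA <- place_atom(CAp, Cp, N, .bb$n_ca, .bb$ang_c_n_ca, 180)
      C <- place_atom(Cp, N, CA, .bb$ca_c, .bb$ang_n_ca_c, phi[i])
    }
    res_atoms[[i]] <- build_residue_atoms(types[i], N, CA, C, psi = psi[i])
  }
  counts <- vapply(res_atoms, nrow, integer(1L))
  atoms <- do.call(rbind, res_atoms)
  last <- cumsum(counts)
  residues <- data.frame(type = types,
                         first = c(1L, utils::head(last, -1L) + 1L),
                         last = last)
  frag <- fragment_structure(atoms[, c("element", "x", "y", "z")], residues)
  frag$atom_names <- atoms$name
  frag
}

# Intramolecular audit: every pair not directly bonded must be >= min_sep.
# Bonds: consecutive z-matrix placements within a residue plus the
# backbone and peptide bonds.
chain_min_nonbonded <- function(frag) {
  xyz <- atom_xyz(frag)
  nm <- frag$atom_names
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  res <- frag$residues
  for (i in seq_len(nrow(res))) {
    idx <- res$first[i]:res$last[i]
    names(idx) <- nm[idx]
    bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
    for (row in .sidechains[[res$type[i]]]) {
      bonds <- c(bonds, list(c(row[[5L]], row[[1L]])))
    }
    for (bnd in bonds) {
      a <- idx[[bnd[1L]]]; b <- idx[[bnd[2L]]]
      d[a, b] <- Inf; d[b, a] <- Inf
    }
    if (i > 1L) {
      a <- (res$first[i - 1L]:res$last[i - 1L])[nm[res$first[i - 1L]:res$last[i - 1L]] == "C"]
      b <- idx[["N"]]
      d[a, b] <- Inf; d[b, a] <- Inf
    }
  }
  min(d)
}

#' Generate one random peptide-like fragment
#'
#' Builds a chain of idealized residues joined by peptide bonds (C-N 1.33,
#' N-CA 1.46, CA-C 1.52 Angstrom) with backbone torsions drawn from the
#' configured distribution, rejection-resampled until no non-bonded atom
#' pair is closer than 1.8 Angstrom. A pure function of the seed.
#'
#' @param config A [generator_config].
#' @return A [fragment_structure] (no cell assigned yet).
#' @export
generate_fragment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  types <- sample(config$residue_alphabet, config$n_residues, replace = TRUE)
  for (try in seq_len(config$max_tries)) {
    tor <- sample_torsions(config$n_residues, config$dihedral_distribution)
    frag <- build_chain(types, tor$phi, tor$psi)
    if (chain_min_nonbonded(frag) >= 1.8) return(frag)
  }
  stop("generation failed: rejection budget exhausted", call. = FALSE)
}

#' Generate a serialized dataset of map examples
#'
#' Draws `n` random fragments, pushes each through [build_example()], bins
#' the survivors by grid dimensions with [bin_and_filter()], and writes a
#' container per bin plus a JSON manifest recording per-fragment seeds and
#' discard reasons. Per-fragment seeds are `seed + i`, so the dataset is a
#' pure function of the configuration.
#'
#' @param n Number of fragments to draw (>= 1).
#' @param config A [generator_config]; its `seed` anchors the per-fragment
#'   seeds.
#' @param out_dir Output directory (created if missing). `NULL` skips
#'   writing and returns the examples in memory.
#' @param min_batch Minimum examples a size bin must hold to be kept.
#' @param ... Passed to [build_example()] (d_min, oversampling, mode, ...).
#' @return Invisibly, a list with `examples` (kept), `bins`, `manifest`.
#' @export
generate_dataset <- function(n, config, out_dir = NULL, min_batch = 1L,
                             ...) {
  stopifnot(n >= 1L)
  examples <- list()
  discards <- list()
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    frag <- generate_fragment(cfg_i)
    ex <- build_example(frag, id = sprintf("frag%04d", i), ...)
    if (inherits(ex, "discard_signal")) {
      discards[[length(discards) + 1L]] <-
        list(id = sprintf("frag%04d", i), seed = cfg_i$seed,
             reason = ex$reason)
    } else {
      ex$seed <- cfg_i$seed
      examples[[length(examples) + 1L]] <- ex
    }
  }
  if (length(examples) == 0L) {
    stop("empty dataset: no fragment survived the builder", call. = FALSE)
  }
  binned <- bin_and_filter(examples, min_batch = min_batch)
  manifest <- list(
    n_requested = n, seed = config$seed,
    n_residues = config$n_residues,
    residue_alphabet = config$residue_alphabet,
    dihedral_distribution = config$dihedral_distribution,
    kept = lapply(unlist(binned$bins, recursive = FALSE), function(ex) {
      list(id = ex$id, seed = ex$seed, dims = ex$density$dims,
           cell = cell_edges(ex$cell), residues = ex$residue_types)
    }),
    discarded = discards,
    bin_report = binned$report
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(binned$bins)) {
      saveRDS(binned$bins[[key]],
              file.path(out_dir, paste0("bin_", gsub("x", "_", key), ".rds")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(examples = unlist(binned$bins, recursive = FALSE,
                                   use.names = FALSE),
                 bins = binned$bins, manifest = manifest))
}

#' Read a dataset written by [generate_dataset()]
#'
#' @param dir Dataset directory containing `bin_*.rds` and `manifest.json`.
#' @return A list with `examples` and `manifest`.
#' @export
read_dataset <- function(dir) {
  files <- list.files(dir, pattern = "^bin_.*\\.rds$", full.names = TRUE)
  examples <- unlist(lapply(sort(files), readRDS), recursive = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  list(examples = examples, manifest = manifest)
}
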