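# Shared fixture builders. Everything is generated in code; heavier shared
# objects are built once per test run and memoised here.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# random point-atom structure in a given cell
random_structure <- function(n_atoms, cell, seed,
                             elements = c("C", "N", "O")) {
  set.seed(seed)
  atoms <- data.frame(element = sample(elements, n_atoms, replace = TRUE),
                      x = runif(n_atoms, 0, cell$a),
                      y = runif(n_atoms, 0, cell$b),
                      z = runif(n_atoms, 0, cell$c))
  fragment_structure(atoms, cell = cell)
}

# brute-force structure-factor oracle: plain direct summation written
# independently of calc_structure_factors
sf_oracle <- function(structure, h, k, l) {
  cell <- structure$cell
  fe <- c(H = 1, C = 6, N = 7, O = 8, S = 16)[structure$atoms$element]
  fe[is.na(fe)] <- 1
  out <- complex(length(h))
  for (r in seq_along(h)) {
    ph <- 2 * pi * (h[r] * structure$atoms$x / cell$a +
                      k[r] * structure$atoms$y / cell$b +
                      l[r] * structure$atoms$z / cell$c)
    out[r] <- sum(fe * exp(1i * ph))
  }
  out
}

# brute-force minimum image contact over the 26 neighbour offsets
contact_oracle <- function(structure) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  edges <- c(structure$cell$a, structure$cell$b, structure$cell$c)
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    if (i == 0 && j == 0 && k == 0) next
    for (a in seq_len(nrow(xyz))) for (b in seq_len(nrow(xyz))) {
      best <- min(best,
                  sqrt(sum((xyz[a, ] - xyz[b, ] -
                              c(i, j, k) * edges)^2)))
    }
  }
  best
}

# a small bank of dipeptide map examples on a 16^3 grid (fixed 14 A cell),
# shared by the model / training / evaluation tests
toy_examples <- function(n = 8L) {
  memo("toy_examples", function() {
    gen <- generator_config(n_residues = 2L, seed = 11L)
    ds <- generate_dataset(10L, gen, d_min = 2.0, oversampling = 2.0,
                           mode = "fixed",
                           fixed_cell = unit_cell(14, 14, 14),
                           patch_dims = c(4L, 4L, 4L), min_batch = 1L)
    ds$examples
  })[seq_len(n)]
}

toy_model_config <- function(...) {
  args <- utils::modifyList(
    list(grid_dims = c(16L, 16L, 16L), patch_dims = c(4L, 4L, 4L)),
    list(...))
  do.call(model_config, args)
}

# minimal config for gradient checks and attention unit tests
tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(grid_dims = c(8L, 8L, 8L), patch_dims = c(4L, 4L, 4L), c = 2L,
         d_t = 8L, heads = 2L, d_h = 4L, layers = 1L, ff_width = 16L),
    list(...))
  do.call(model_config, args)
}
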