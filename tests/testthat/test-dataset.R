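test_that("intermolecular contact uses the 26 periodic images", {
  # single atom: nearest image along the shortest cell edge
  fr1 <- fragment_structure(data.frame(element = "C", x = 1, y = 1, z = 1),
                            cell = unit_cell(5, 5, 5))
  expect_equal(min_intermolecular_contact(fr1), 5)
  fr2 <- fragment_structure(data.frame(element = "C", x = 2, y = 3, z = 4),
                            cell = unit_cell(5, 7, 9))
  expect_equal(min_intermolecular_contact(fr2), 5)

  # two atoms near opposite walls touch through the boundary
  fr3 <- fragment_structure(
    data.frame(element = "C", x = c(1, 9), y = 2, z = 2),
    cell = unit_cell(10, 10, 10))
  expect_equal(min_intermolecular_contact(fr3), 2)
  # growing the violating axis to 11 A opens the contact to 3 A
  fr3$cell <- unit_cell(11, 10, 10)
  expect_equal(min_intermolecular_contact(fr3), 3)

  # agreement with a brute-force oracle on random structures
  for (seed in 1:5) {
    cell <- unit_cell(runif(1, 5, 9), runif(1, 5, 9), runif(1, 5, 9))
    fr <- random_structure(6, cell, seed = 300 + seed)
    expect_equal(min_intermolecular_contact(fr), contact_oracle(fr),
                 tolerance = 1e-9)
  }
})

test_that("cell expansion reaches the contact threshold or discards", {
  fr <- generate_fragment(generator_config(n_residues = 2L, seed = 8L))
  out <- expand_cell(fr, threshold = 2.75, step = 0.25)
  expect_s3_class(out, "fragment_structure")
  expect_gte(min_intermolecular_contact(out), 2.75)
  # initial edges from coordinate ranges: final edges >= ranges
  xyz <- as.matrix(fr$atoms[, c("x", "y", "z")])
  ranges <- apply(xyz, 2, function(v) diff(range(v)))
  expect_true(all(c(out$cell$a, out$cell$b, out$cell$c) >= ranges - 1e-9))

  # a cramped budget triggers the discard signal
  bad <- expand_cell(fr, threshold = 2.75, step = 0.01, max_iter = 2L)
  expect_s3_class(bad, "discard_signal")
  expect_match(bad$reason, "clash")

  # coincident atoms are an intramolecular matter: expansion still
  # terminates using image contacts only
  co <- fragment_structure(
    data.frame(element = "C", x = c(1, 1, 3), y = c(1, 1, 1),
               z = c(1, 1, 2)))
  outco <- expand_cell(co, threshold = 2.75, step = 0.5)
  expect_s3_class(outco, "fragment_structure")
  expect_gte(min_intermolecular_contact(outco), 2.75)
})

test_that("cell expansion stops at the first step meeting the threshold", {
  # four atoms on corners of a 4 A box: under the full-diagonal lattice
  # offset each corner lands on another, so the range-sized cell always
  # clashes and the cell must grow. The minimal passing cell is the
  # first 0.25 A step whose contact clears 2.75 A.
  fr <- fragment_structure(
    data.frame(element = "C",
               x = c(0, 4, 4, 0), y = c(0, 4, 0, 4), z = c(0, 0, 4, 4)))
  out <- expand_cell(fr, threshold = 2.75, step = 0.25)
  expect_gte(min_intermolecular_contact(out), 2.75)
  # one step smaller on every axis still violates the threshold
  smaller <- out
  smaller$cell <- unit_cell(out$cell$a - 0.25, out$cell$b - 0.25,
                            out$cell$c - 0.25)
  expect_lt(min_intermolecular_contact(smaller), 2.75)
})

test_that("centering puts the mass-weighted centroid at the cell center", {
  fr <- fragment_structure(
    data.frame(element = c("C", "O"), x = c(0, 2), y = 0, z = 0),
    cell = unit_cell(10, 10, 10))
  cen <- center_structure(fr)
  expect_equal(unname(center_of_mass(cen)), c(5, 5, 5), tolerance = 1e-12)
  # the common shift moved the mass centroid, not the midpoint: C ends
  # up left of center because O is heavier
  expect_lt(cen$atoms$x[1], 4.5)
  # idempotent
  expect_equal(center_structure(cen)$atoms, cen$atoms, tolerance = 1e-12)
  # single atom lands exactly at the center
  fr1 <- fragment_structure(data.frame(element = "N", x = 9, y = 1, z = 2),
                            cell = unit_cell(6, 8, 10))
  expect_equal(unname(center_of_mass(center_structure(fr1))), c(3, 4, 5))
})

test_that("axis reindexing sorts edges a >= b >= c with stable ties", {
  fr <- fragment_structure(
    data.frame(element = "C", x = 1, y = 2, z = 3),
    cell = unit_cell(24, 41, 30))
  out <- reindex_axes(fr)
  expect_equal(c(out$cell$a, out$cell$b, out$cell$c), c(41, 30, 24))
  # coordinates permute with the axes: new x is the old y, etc.
  expect_equal(c(out$atoms$x, out$atoms$y, out$atoms$z), c(2, 3, 1))

  sorted <- fragment_structure(
    data.frame(element = "C", x = 1, y = 2, z = 3),
    cell = unit_cell(41, 30, 24))
  expect_equal(reindex_axes(sorted)$atoms, sorted$atoms)

  tied <- fragment_structure(
    data.frame(element = "C", x = 1, y = 2, z = 3),
    cell = unit_cell(30, 30, 24))
  out2 <- reindex_axes(tied)
  expect_equal(c(out2$atoms$x, out2$atoms$y, out2$atoms$z), c(1, 2, 3))
})

test_that("partial structures are standardized and share the example grid", {
  gen <- generator_config(n_residues = 2L, seed = 13L)
  ex1 <- build_example(generate_fragment(gen), d_min = 2.0,
                       oversampling = 2.0, mode = "fixed",
                       fixed_cell = unit_cell(14, 14, 14),
                       patch_dims = c(4L, 4L, 4L), id = "a")
  expect_equal(length(ex1$partials$grids), 2L)
  for (g in ex1$partials$grids) {
    expect_identical(g$dims, ex1$density$dims)
    expect_identical(g$kind, "partial")
    expect_equal(max(abs(g$values)), 1)
  }
  # same residue type in a different example on the same grid gives an
  # identical partial map (templates are example-independent)
  gen2 <- generator_config(n_residues = 2L, seed = 17L)
  ex2 <- build_example(generate_fragment(gen2), d_min = 2.0,
                       oversampling = 2.0, mode = "fixed",
                       fixed_cell = unit_cell(14, 14, 14),
                       patch_dims = c(4L, 4L, 4L), id = "b")
  for (t in intersect(ex1$residue_types, ex2$residue_types)) {
    g1 <- ex1$partials$grids[[match(t, ex1$residue_types)]]
    g2 <- ex2$partials$grids[[match(t, ex2$residue_types)]]
    expect_equal(g1$values, g2$values, tolerance = 1e-12)
  }
})

test_that("partial map integrals track the template electron count", {
  cell <- unit_cell(14, 14, 14)
  fr <- generate_fragment(generator_config(
    n_residues = 2L, seed = 19L, residue_alphabet = "GLY"))
  fr$cell <- cell
  grid <- build_grid(cell, 2.0, 2.0, multiple_of = 4L)
  tmpl <- residue_template("GLY")
  tmpl$cell <- cell
  tmpl <- center_structure(tmpl)
  refs <- calc_structure_factors(tmpl, 2.0)
  den <- density_from_sf(refs, grid)
  # integral of the map = F(0,0,0) = total electron count (point model)
  integral <- sum(den$values) * cell$V / prod(den$dims)
  electrons <- sum(c(C = 6, N = 7, O = 8)[tmpl$atoms$element])
  expect_equal(integral, electrons, tolerance = 0.01 * electrons)
})

test_that("size-bin filtering keeps only well-populated bins", {
  fake <- function(dims, id) {
    structure(list(id = id,
                   density = list(dims = dims)),
              class = "example_record")
  }
  exs <- c(lapply(1:10, function(i) fake(c(16L, 16L, 16L), i)),
           lapply(11:12, function(i) fake(c(20L, 16L, 16L), i)))
  out <- bin_and_filter(exs, min_batch = 4L)
  expect_equal(names(out$bins), "16x16x16")
  expect_equal(out$report$kept, c(TRUE, FALSE))
  all_kept <- bin_and_filter(exs, min_batch = 1L)
  expect_equal(length(all_kept$bins), 2L)
  # post-condition on a generated set: every kept dims occurs >= min_batch
  gen <- generator_config(n_residues = 2L, seed = 23L)
  ds <- generate_dataset(12L, gen, d_min = 2.5, oversampling = 2.0,
                         mode = "variable", min_batch = 2L)
  counts <- table(vapply(ds$examples, function(e)
    paste(e$density$dims, collapse = "x"), character(1)))
  expect_true(all(counts >= 2L))
})

test_that("build_example applies every dataset rule end to end", {
  gen <- generator_config(n_residues = 2L, seed = 29L)
  fr <- generate_fragment(gen)
  ex <- build_example(fr, d_min = 2.0, oversampling = 2.0,
                      mode = "variable", patch_dims = c(4L, 4L, 4L),
                      id = "v1")
  expect_s3_class(ex, "example_record")
  st <- ex$structure
  expect_gte(min_intermolecular_contact(st), 2.75)
  expect_lt(max(abs(center_of_mass(st) -
                      c(st$cell$a, st$cell$b, st$cell$c) / 2)), 1e-6)
  expect_true(st$cell$a >= st$cell$b && st$cell$b >= st$cell$c)
  expect_true(all(ex$density$dims %% 4L == 0L))

  # normalized patterson equals the normalized autocorrelation of the
  # unnormalized density (route equivalence survives the pipeline)
  refs <- calc_structure_factors(st, 2.0)
  den <- density_from_sf(refs, list(dims = ex$density$dims))
  p2 <- normalize_map(patterson_from_density(den))
  expect_lt(max(abs(ex$patterson$values - p2$values)), 1e-5)

  # determinism: same input, same record
  ex2 <- build_example(fr, d_min = 2.0, oversampling = 2.0,
                       mode = "variable", patch_dims = c(4L, 4L, 4L),
                       id = "v1")
  expect_identical(ex, ex2)

  # a fragment that cannot fit the fixed cell is discarded with a reason
  big <- generate_fragment(generator_config(n_residues = 15L, seed = 3L))
  out <- build_example(big, d_min = 2.0, oversampling = 2.0,
                       mode = "fixed", fixed_cell = unit_cell(8, 8, 8),
                       id = "clash")
  expect_s3_class(out, "discard_signal")
  expect_match(out$reason, "clash")
})

test_that("the production-scale fixed cell yields the expected grid", {
  g <- build_grid(unit_cell(41, 30, 24), 1.5, 3.0)
  expect_identical(g$dims, c(82L, 60L, 48L))
  # one full-resolution build on the 41x30x24 cell
  fr <- generate_fragment(generator_config(n_residues = 2L, seed = 37L))
  ex <- build_example(fr, d_min = 1.5, oversampling = 3.0, mode = "fixed",
                      id = "full")
  expect_identical(ex$density$dims, c(82L, 60L, 48L))
  expect_equal(max(abs(ex$density$values)), 1)
})
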