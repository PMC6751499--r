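test_that("orthogonalization maps fractional corners of simple cells", {
  ct <- cell_transform(unit_cell(10, 10, 10))
  expect_equal(frac_to_cart(ct, c(0.5, 0.5, 0.5)), c(5, 5, 5))
  ct2 <- cell_transform(unit_cell(10, 20, 30))
  expect_equal(frac_to_cart(ct2, c(1, 1, 1)), c(10, 20, 30))
  expect_equal(ct2$deorth %*% ct2$orth, diag(3), tolerance = 1e-9)
  # |orth e1| = a
  expect_equal(sqrt(sum(frac_to_cart(ct2, c(1, 0, 0))^2)), 10)
})

test_that("skewed-cell Cartesian distances match the metric-tensor oracle", {
  cell <- unit_cell(10, 10, 10, beta = 120)
  ct <- cell_transform(cell)
  set.seed(42)
  for (i in 1:25) {
    f1 <- stats::runif(3); f2 <- stats::runif(3)
    d_cart <- sqrt(sum((frac_to_cart(ct, f1) - frac_to_cart(ct, f2))^2))
    expect_equal(d_cart, metric_distance(cell, f1, f2), tolerance = 1e-9)
  }
  expect_error(unit_cell(10, 10, 10, alpha = 170, beta = 170, gamma = 170),
               "invalid cell")
})

test_that("symmetry operators act as rotation %*% x + translation", {
  expect_equal(apply_sym_op(identity_op(), c(1, 2, 3)), c(1, 2, 3))
  two_fold <- sym_op(diag(c(-1, -1, 1)), c(0, 0, 5))
  expect_equal(apply_sym_op(two_fold, c(1, 1, 0)), c(-1, -1, 5))
  set.seed(7)
  for (i in 1:20) {
    # random signed permutation: orthogonal with |det| = 1
    R <- diag(sample(c(-1, 1), 3, TRUE))[, sample(3)]
    t <- stats::runif(3, -5, 5)
    p <- stats::rnorm(3)
    expect_equal(apply_sym_op(sym_op(R, t), p), drop(R %*% p) + t,
                 tolerance = 1e-12)
  }
  expect_error(sym_op(diag(c(2, 1, 1)), c(0, 0, 0)), "det")
})

test_that("a lattice-shift image across the cell boundary is found", {
  # P1 cubic a=10; atom at (5,5,5); center (5,5,14): image via shift (0,0,1)
  # lies at (5,5,15), distance 1.0
  spec <- fixture_spec(
    1, "P1AA", unit_cell(10, 10, 10), resolution = 2.0,
    metals = data.frame(element = "Zn", chain = "A", res_no = 1L,
                        x = 5, y = 5, z = 5, occupancy = 1,
                        stringsAsFactors = FALSE))
  ent <- parse_pdb_entry(build_entry_fixture(spec)$lines)
  hit <- nearest_symmetry_contact(ent, c(5, 5, 14), radius = 3.5)
  expect_equal(hit$distance, 1.0, tolerance = 1e-9)
  expect_equal(hit$lattice_shift, c(0L, 0L, 1L))
  # center far from every lattice image -> absent
  expect_null(nearest_symmetry_contact(ent, c(5, 5, 5) + 0.1, radius = 3.5))
})

test_that("a two-fold image planted at 3.2 A is recovered exactly", {
  spec <- fixture_spec(
    2, "P2AA", unit_cell(16, 16, 16),
    operators = list(sym_op(diag(c(-1, -1, 1)), c(7.2, 4, 0))),
    resolution = 2.0,
    metals = data.frame(element = "Mn", chain = "A", res_no = 1L,
                        x = 2, y = 2, z = 4, occupancy = 1,
                        stringsAsFactors = FALSE))
  ent <- parse_pdb_entry(build_entry_fixture(spec)$lines)
  hit <- nearest_symmetry_contact(ent, c(2, 2, 4), radius = 3.5)
  expect_equal(hit$distance, 3.2, tolerance = 1e-6)
  expect_equal(hit$distance,
               brute_min_symmetry(ent, c(2, 2, 4)), tolerance = 1e-9)
})

test_that("nearest contact equals exhaustive enumeration on random fixtures", {
  for (seed in 1:40) {
    fx <- random_symmetry_fixture(seed)
    ref <- brute_min_symmetry(fx$entry, fx$center)
    radius <- min(fx$entry$cell$a, fx$entry$cell$b, fx$entry$cell$c)
    hit <- nearest_symmetry_contact(fx$entry, fx$center, radius = radius,
                                    shells = 2)
    if (ref <= radius) {
      expect_false(is.null(hit))
      expect_equal(hit$distance, ref, tolerance = 1e-9)
    } else {
      expect_null(hit)
    }
  }
})

test_that("the identity zero-shift image of the metal itself never reports 0", {
  fx <- random_symmetry_fixture(99)
  hit <- nearest_symmetry_contact(fx$entry, fx$center, radius = 50,
                                  shells = 7)
  expect_true(is.null(hit) || hit$distance > 1e-6)
})

test_that("the search is invariant under a whole-lattice translation", {
  fx <- random_symmetry_fixture(5)
  ent <- fx$entry
  ct <- cell_transform(ent$cell)
  shift <- frac_to_cart(ct, c(1, -1, 1))
  ent2 <- ent
  ent2$atoms$x <- ent$atoms$x + shift[1]
  ent2$atoms$y <- ent$atoms$y + shift[2]
  ent2$atoms$z <- ent$atoms$z + shift[3]
  h1 <- nearest_symmetry_contact(ent, fx$center, radius = 8, shells = 3)
  h2 <- nearest_symmetry_contact(ent2, fx$center + shift, radius = 8,
                                 shells = 3)
  expect_equal(is.null(h1), is.null(h2))
  if (!is.null(h1)) expect_equal(h1$distance, h2$distance, tolerance = 1e-9)
})

test_that("explicitly undersized shell counts are rejected", {
  spec <- fixture_spec(
    3, "TINY", unit_cell(4.5, 4.5, 4.5), resolution = 2.0,
    metals = data.frame(element = "Zn", chain = "A", res_no = 1L,
                        x = 2, y = 2, z = 2, occupancy = 1,
                        stringsAsFactors = FALSE))
  ent <- parse_pdb_entry(build_entry_fixture(spec)$lines)
  expect_error(nearest_symmetry_contact(ent, c(2, 2, 2), radius = 8,
                                        shells = 1), "shells")
  # auto-escalation handles the same call without an explicit shell count
  expect_s3_class(nearest_symmetry_contact(ent, c(2, 2, 2), radius = 8),
                  "symmetry_contact")
})
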