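# 8^3 map, voxel volume 1 A^3: one hot voxel of value 1 at the center of a
# low-amplitude alternating background, so the hot voxel is the only
# significant one and contributes exactly |1| * 1 * scale electrons
hot_voxel_map <- function() {
  a <- array(c(0.1, -0.1), dim = c(8, 8, 8))
  a[4, 4, 4] <- 1
  make_map(a, unit_cell(8, 8, 8))
}

test_that("a single significant voxel contributes |value| x voxel volume", {
  m <- hot_voxel_map()
  center <- grid_to_cartesian(m, c(3, 3, 3))  # the hot voxel's position
  r <- regional_discrepancy(m, center, radius = 2, z_cut = 3)
  expect_equal(r$significant_voxel_count, 1L)
  expect_equal(r$discrepancy_sum, 1.0, tolerance = 1e-6)
  expect_true(r$covered)
  # linearity in the electron scale
  r3 <- regional_discrepancy(m, center, radius = 2, z_cut = 3,
                             electron_scale = 2.5)
  expect_equal(r3$discrepancy_sum, 2.5 * r$discrepancy_sum)
})

test_that("a region with no significant voxels sums to zero", {
  m <- hot_voxel_map()
  far <- grid_to_cartesian(m, c(0, 0, 0))
  r <- regional_discrepancy(m, far, radius = 1.5, z_cut = 3)
  expect_equal(r$discrepancy_sum, 0)
  expect_equal(r$significant_voxel_count, 0L)
})

test_that("constant maps raise a degenerate-map error", {
  m <- make_map(array(0, dim = c(6, 6, 6)), unit_cell(6, 6, 6))
  expect_error(regional_discrepancy(m, c(3, 3, 3)), "degenerate")
  expect_error(background_discrepancy(m), "degenerate")
})

test_that("regional sums equal a naive voxel loop on varied fixtures", {
  for (seed in c(2, 5, 8)) {
    ao <- list(1:3, c(3, 1, 2), c(2, 3, 1))[[(seed %% 3) + 1]]
    m <- random_noise_map(seed, cell_edge = 9, axis_order = ao)
    center <- c(4.5, 4.5, 4.5) + stats::runif(3, -2, 2)
    ref <- voxel_loop_regional(m, center)
    got <- regional_discrepancy(m, center)
    expect_equal(got$discrepancy_sum, ref$sum, tolerance = 1e-9)
    expect_equal(got$significant_voxel_count, ref$count)
  }
})

test_that("background discrepancy matches the closed form and the loop", {
  m <- hot_voxel_map()
  # exactly one significant voxel of |value| 1, voxel volume 1, map volume 512
  expect_equal(background_discrepancy(m, radius = 3.5),
               1 / 512 * (4 / 3) * pi * 3.5^3, tolerance = 1e-6)
  expect_equal(background_discrepancy(m, radius = 3.5),
               voxel_loop_background(m, radius = 3.5), tolerance = 1e-12)
  mr <- random_noise_map(17)
  expect_equal(background_discrepancy(mr), voxel_loop_background(mr),
               tolerance = 1e-9)
})

test_that("sums are monotone in radius and anti-monotone in z_cut", {
  m <- random_noise_map(23)
  center <- c(4.5, 4.5, 4.5)
  radii <- c(1, 2, 3, 4)
  sums_r <- vapply(radii, function(r)
    regional_discrepancy(m, center, radius = r)$discrepancy_sum, numeric(1))
  expect_true(all(diff(sums_r) >= 0))
  zs <- c(1, 2, 3, 5)
  sums_z <- vapply(zs, function(z)
    regional_discrepancy(m, center, radius = 4, z_cut = z)$discrepancy_sum,
    numeric(1))
  expect_true(all(diff(sums_z) <= 0))
})

test_that("spheres leaving a partial map are reported as uncovered", {
  set.seed(71)
  a <- array(stats::rnorm(8 * 16 * 16, 0, 0.1), dim = c(8, 16, 16))
  part <- make_map(a, unit_cell(8, 8, 8), grid = c(16, 16, 16))
  # covers x in [0, 3.5); a sphere at x = 3 extends past the stored slab
  inside <- regional_discrepancy(part, c(1.5, 4, 4), radius = 1)
  expect_true(inside$covered)
  outside <- regional_discrepancy(part, c(3, 4, 4), radius = 1.5)
  expect_false(outside$covered)
  # uncovered sums still equal the loop over stored voxels
  ref <- voxel_loop_regional(part, c(3, 4, 4), radius = 1.5)
  expect_equal(outside$discrepancy_sum, ref$sum, tolerance = 1e-9)
})

clean_pair <- function() {
  spec <- fixture_spec(
    4, "CLN1", unit_cell(16, 16, 16), resolution = 1.8,
    metals = data.frame(element = "Ca", chain = "F", res_no = 405L,
                        x = 8, y = 8, z = 8, occupancy = 1,
                        stringsAsFactors = FALSE),
    blobs = data.frame(x = 8, y = 8, z = 8, electrons = 5, width = 1.5))
  entry <- parse_pdb_entry(build_entry_fixture(spec)$lines)
  list(entry = entry, map = build_map_fixture(spec)$map,
       site = extract_metal_sites(entry)[1, ])
}

test_that("evaluate_site produces the documented flag logic", {
  p <- clean_pair()
  rec <- evaluate_site(p$entry, p$map, p$site, qc_config(),
                       discrepancy_cutoff = 19.3)
  expect_true(rec$pass_resolution && rec$pass_occupancy &&
                rec$pass_symmetry && rec$pass_discrepancy && rec$pass_all)
  expect_true(is.na(rec$min_symmetry_dist_A))

  # toggling exactly one input across its threshold flips exactly that flag
  ent7 <- p$entry; ent7$resolution <- 7.0
  r7 <- evaluate_site(ent7, p$map, p$site, qc_config(), 19.3)
  expect_false(r7$pass_resolution)
  expect_true(r7$pass_occupancy && r7$pass_symmetry && r7$pass_discrepancy)
  expect_false(r7$pass_all)

  s07 <- p$site; s07$occupancy <- 0.7
  r07 <- evaluate_site(p$entry, p$map, s07, qc_config(), 19.3)
  expect_false(r07$pass_occupancy)
  expect_true(r07$pass_resolution && r07$pass_symmetry && r07$pass_discrepancy)

  rtight <- evaluate_site(p$entry, p$map, p$site, qc_config(),
                          discrepancy_cutoff = 1e-9)
  expect_false(rtight$pass_discrepancy)
  expect_true(rtight$pass_resolution && rtight$pass_occupancy &&
                rtight$pass_symmetry)

  # without a cutoff the discrepancy and overall flags are deferred
  rna <- evaluate_site(p$entry, p$map, p$site, qc_config())
  expect_true(is.na(rna$pass_discrepancy) && is.na(rna$pass_all))
})

test_that("the discrepancy criterion boundary is strict", {
  p <- clean_pair()
  rec <- evaluate_site(p$entry, p$map, p$site, qc_config(),
                       discrepancy_cutoff = 19.3)
  at_boundary <- evaluate_site(p$entry, p$map, p$site, qc_config(),
                               discrepancy_cutoff = rec$discrepancy_e)
  expect_false(at_boundary$pass_discrepancy)
})

test_that("a mismatched map cell warns with the site identifier", {
  p <- clean_pair()
  bad_map <- p$map
  bad_map$cell <- unit_cell(17, 16, 16)
  expect_warning(evaluate_site(p$entry, bad_map, p$site, qc_config(), 19.3),
                 "cell differs")
})
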