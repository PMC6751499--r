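# Independent oracles and small builders used across the tests. These
# deliberately duplicate no package code paths: geometry goes through the
# metric tensor or an inline orthogonalization, sums through plain loops.

# squared distance between fractional points via the metric tensor
metric_distance <- function(cell, f1, f2) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  G <- matrix(c(cell$a^2, cell$a * cell$b * cg, cell$a * cell$c * cb,
                cell$a * cell$b * cg, cell$b^2, cell$b * cell$c * ca,
                cell$a * cell$c * cb, cell$b * cell$c * ca, cell$c^2), 3, 3)
  d <- f1 - f2
  sqrt(drop(t(d) %*% G %*% d))
}

orth_oracle <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0, cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0, 0, cell$c * v / sg), 3, 3, byrow = TRUE)
}

# exhaustive nearest symmetry image: operators x shifts in [-2,2]^3 x atoms
brute_min_symmetry <- function(entry, center, shells = 2) {
  M <- orth_oracle(entry$cell)
  best <- Inf
  X <- as.matrix(entry$atoms[, c("x", "y", "z")])
  for (k in seq_along(entry$operators)) {
    op <- entry$operators[[k]]
    ident <- max(abs(op$rotation - diag(3))) < 1e-9 &&
      max(abs(op$translation)) < 1e-9
    for (sx in -shells:shells) for (sy in -shells:shells)
      for (sz in -shells:shells) {
        if (ident && sx == 0 && sy == 0 && sz == 0) next
        sh <- drop(M %*% c(sx, sy, sz))
        for (i in seq_len(nrow(X))) {
          p <- drop(op$rotation %*% X[i, ]) + op$translation + sh
          d <- sqrt(sum((p - center)^2))
          if (d < best) best <- d
        }
      }
  }
  best
}

# plain voxel-loop regional sum (minimum-image iff the map spans the cell)
voxel_loop_regional <- function(map, center, radius = 3.5, z_cut = 3,
                                scale = 1) {
  M <- orth_oracle(map$cell)
  cf <- drop(solve(M) %*% center)
  v <- map$values; d <- dim(v); ao <- map$axis_order
  ext <- integer(3); ext[ao] <- d
  full <- all(ext == map$grid)
  m <- mean(v); sigma <- sqrt(mean((v - m)^2))
  voxvol <- cell_volume(map$cell) / prod(map$grid)
  total <- 0; count <- 0L; g <- numeric(3)
  for (i3 in seq_len(d[3])) for (i2 in seq_len(d[2])) for (i1 in seq_len(d[1])) {
    g[ao] <- map$start + c(i1, i2, i3) - 1
    df <- g / map$grid - cf
    if (full) df <- df - round(df)
    if (sum((M %*% df)^2) <= radius^2) {
      val <- v[i1, i2, i3]
      if (abs(val - m) >= z_cut * sigma) {
        total <- total + abs(val) * voxvol * scale
        count <- count + 1L
      }
    }
  }
  list(sum = total, count = count)
}

voxel_loop_background <- function(map, radius = 3.5, z_cut = 3, scale = 1) {
  v <- as.vector(map$values)
  m <- mean(v); sigma <- sqrt(mean((v - m)^2))
  voxvol <- cell_volume(map$cell) / prod(map$grid)
  total <- 0
  for (x in v) if (abs(x - m) >= z_cut * sigma) total <- total + abs(x)
  (total * voxvol * scale) / (length(v) * voxvol) * (4 / 3) * pi * radius^3
}

# independently coded single-pass trim-then-SD
trim_sd_oracle <- function(x, trim = 2, k = 1) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / n)
  kept <- if (s == 0) x else x[abs(x - m) < trim * s]
  mk <- sum(kept) / length(kept)
  k * sqrt(sum((kept - mk)^2) / length(kept))
}

# build a density_map object from a crystal-order array, optionally
# permuting to a different storage axis order
make_map <- function(values_crystal, cell, axis_order = 1:3,
                     start = c(0L, 0L, 0L), grid = NULL) {
  grid <- if (is.null(grid)) dim(values_crystal) else as.integer(grid)
  vals <- aperm(values_crystal, axis_order)
  raw <- write_ccp4_map(structure(list(
    values = vals, start = as.integer(start)[axis_order], grid = grid,
    axis_order = as.integer(axis_order), cell = cell,
    declared_mean = mean(vals), declared_rms = stats::sd(vals),
    ispg = 1L, endian = "little"), class = "density_map"))
  read_ccp4_map(raw)  # ensures float32 storage exactly as a real file
}

# a random toy entry built through the fixture generator
random_symmetry_fixture <- function(seed) {
  set.seed(seed)
  edges <- stats::runif(3, 8, 15)
  cell <- unit_cell(edges[1], edges[2], edges[3])
  # sign-flip rotations and the inversion: all map an orthorhombic lattice
  # onto itself, so the fixtures are crystallographically consistent
  rots <- list(diag(c(-1, -1, 1)), diag(c(1, -1, -1)), diag(c(-1, 1, -1)),
               -diag(3))
  nops <- sample(1:3, 1)
  ops <- lapply(sample(rots, nops), function(R)
    sym_op(R, stats::runif(3, 0, min(edges))))
  nat <- sample(4:19, 1)
  metal_pos <- stats::runif(3, 0.2, 0.8) * edges
  spec <- fixture_spec(
    seed, "RND1", cell, operators = ops, resolution = 2.0,
    metals = data.frame(element = "Zn", chain = "A", res_no = 1L,
                        x = metal_pos[1], y = metal_pos[2], z = metal_pos[3],
                        occupancy = 1, stringsAsFactors = FALSE),
    decoys = data.frame(element = sample(c("C", "N", "O"), nat, TRUE),
                        x = stats::runif(nat, 0, edges[1]),
                        y = stats::runif(nat, 0, edges[2]),
                        z = stats::runif(nat, 0, edges[3]),
                        stringsAsFactors = FALSE))
  list(entry = parse_pdb_entry(build_entry_fixture(spec)$lines),
       center = as.numeric(round(metal_pos, 3)))
}

# a small seeded noise map with a couple of hot voxels
random_noise_map <- function(seed, n = 12L, cell_edge = 9,
                             axis_order = 1:3) {
  set.seed(seed)
  a <- array(stats::rnorm(n^3, 0, 0.1), dim = rep(n, 3))
  hot <- matrix(sample(n, 9, TRUE), 3)
  for (j in 1:3) a[hot[1, j], hot[2, j], hot[3, j]] <- stats::rnorm(1, 0, 2)
  make_map(a, unit_cell(cell_edge, cell_edge, cell_edge),
           axis_order = axis_order)
}
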