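# Deterministic synthetic fixtures: paired toy PDB entries and CCP4 maps
# with ground truth computed by independent brute-force oracles (never by
# the analysis functions they are used to test).

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic structure/map fixture pair
#'
#' @param seed Integer seed; all randomness of the fixture (noise, jitter)
#'   derives from it.
#' @param pdb_id 4-character identifier for the toy entry.
#' @param cell A [unit_cell()].
#' @param operators List of [sym_op()] (the identity is prepended when
#'   absent).
#' @param resolution Declared resolution in Angstrom (`NA` for none).
#' @param metals Data frame: `element`, `chain`, `res_no`, `x`, `y`, `z`
#'   (Cartesian Angstrom), `occupancy`.
#' @param decoys Optional data frame of non-metal atoms: `element`, `x`,
#'   `y`, `z`.
#' @param blobs Optional data frame of planted density features: `x`, `y`,
#'   `z`, `electrons` (analytic integral of the Gaussian), `width`
#'   (Gaussian sigma, Angstrom).
#' @param noise_sigma Gaussian background noise level in map units.
#' @param grid Length-3 integer: full-cell sampling counts per crystal axis.
#' @param axis_order Permutation of 1:3 giving the crystal axis stored on
#'   each file axis (MAPC/MAPR/MAPS).
#' @param map_extent `NULL` for full-cell coverage, or
#'   `list(start =, count =)` in crystal-axis order for a partial map.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, pdb_id, cell, operators = list(),
                         resolution = 2.0, metals,
                         decoys = NULL, blobs = NULL,
                         noise_sigma = 0.01, grid = c(32L, 32L, 32L),
                         axis_order = 1:3, map_extent = NULL) {
  stopifnot(inherits(cell, "unit_cell"), is.data.frame(metals),
            nrow(metals) >= 1)
  if (length(operators) == 0 ||
      !any(vapply(operators, is_identity_op, logical(1))))
    operators <- c(list(identity_op()), operators)
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3, all(grid > 0),
            all(sort(as.integer(axis_order)) == 1:3))

  edges <- c(cell$a, cell$b, cell$c)
  pos <- rbind(as.matrix(metals[, c("x", "y", "z")]),
               if (!is.null(decoys)) as.matrix(decoys[, c("x", "y", "z")]))
  if (any(pos < 0) || any(t(t(pos) / (2 * edges)) >= 1))
    stop("fixture spec error: atom placements must lie in [0, 2 cells)")

  if (!is.null(blobs) && nrow(blobs) > 0) {
    if (any(blobs$width <= 0)) stop("fixture spec error: blob widths must be > 0")
    spacing <- edges / grid
    if (max(spacing) > min(blobs$width) / 3 + 1e-9)
      stop("fixture spec error: grid spacing must be <= 1/3 of the smallest blob width")
  }
  if (!is.null(map_extent)) {
    stopifnot(length(map_extent$start) == 3, length(map_extent$count) == 3)
    if (any(map_extent$start < 0) ||
        any(map_extent$start + map_extent$count > grid))
      stop("fixture spec error: partial-map extent exceeds the cell grid")
  }
  structure(list(
    seed = as.integer(seed), pdb_id = pdb_id, cell = cell,
    operators = operators, resolution = resolution, metals = metals,
    decoys = decoys, blobs = blobs, noise_sigma = noise_sigma,
    grid = grid, axis_order = as.integer(axis_order),
    map_extent = map_extent
  ), class = "fixture_spec")
}

# --- independent oracles ---------------------------------------------------

# standard orthogonalization, coded inline for the generator's own use
.oracle_orth <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0, cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0, 0, cell$c * v / sg), 3, 3, byrow = TRUE)
}

# exhaustive minimum symmetry-image distance: every operator x every lattice
# shift in [-shells, shells]^3 x every atom, excluding (identity, zero shift)
.oracle_min_sym_distance <- function(cell, operators, atoms_xyz, center,
                                     shells = 2) {
  M <- .oracle_orth(cell)
  best <- Inf
  for (k in seq_along(operators)) {
    op <- operators[[k]]
    ident <- max(abs(op$rotation - diag(3))) <= 1e-8 &&
      max(abs(op$translation)) <= 1e-8
    for (sx in -shells:shells) for (sy in -shells:shells)
      for (sz in -shells:shells) {
        if (ident && sx == 0 && sy == 0 && sz == 0) next
        shift <- M %*% c(sx, sy, sz)
        for (i in seq_len(nrow(atoms_xyz))) {
          p <- op$rotation %*% atoms_xyz[i, ] + op$translation + shift
          d <- sqrt(sum((p - center)^2))
          if (d < best) best <- d
        }
      }
  }
  best
}

# plain voxel-loop regional discrepancy sum (minimum image iff full cell)
.oracle_regional_sum <- function(map, center, radius = 3.5, z_cut = 3,
                                 electron_scale = 1.0) {
  M <- .oracle_orth(map$cell)
  Minv <- solve(M)
  v <- map$values
  d <- dim(v)
  ao <- map$axis_order
  ext <- integer(3); ext[ao] <- d
  full <- all(ext == map$grid)
  m <- mean(v)
  sigma <- sqrt(mean((v - m)^2))
  voxvol <- (map$cell$a * map$cell$b * map$cell$c *
               .oracle_vol_factor(map$cell)) / prod(map$grid)
  cf <- Minv %*% center
  total <- 0; count <- 0L
  g <- numeric(3)
  for (i3 in seq_len(d[3])) for (i2 in seq_len(d[2])) for (i1 in seq_len(d[1])) {
    g[ao[1]] <- map$start[1] + i1 - 1
    g[ao[2]] <- map$start[2] + i2 - 1
    g[ao[3]] <- map$start[3] + i3 - 1
    df <- g / map$grid - cf
    if (full) df <- df - round(df)
    cart <- M %*% df
    if (sum(cart^2) <= radius^2) {
      val <- v[i1, i2, i3]
      if (abs(val - m) >= z_cut * sigma) {
        total <- total + abs(val) * voxvol * electron_scale
        count <- count + 1L
      }
    }
  }
  list(sum = total, count = count)
}

.oracle_vol_factor <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

# plain voxel-loop background discrepancy
.oracle_background <- function(map, radius = 3.5, z_cut = 3,
                               electron_scale = 1.0) {
  v <- as.vector(map$values)
  m <- mean(v); sigma <- sqrt(mean((v - m)^2))
  voxvol <- (map$cell$a * map$cell$b * map$cell$c *
               .oracle_vol_factor(map$cell)) / prod(map$grid)
  total <- 0
  for (i in seq_along(v))
    if (abs(v[i] - m) >= z_cut * sigma) total <- total + abs(v[i])
  total * voxvol * electron_scale / (length(v) * voxvol) *
    (4 / 3) * pi * radius^3
}

# independently coded single-pass trim-then-SD (population SD, strict keep)
.oracle_trim_sd <- function(x, trim = 2, k = 1) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / length(x))
  kept <- if (s == 0) x else x[abs(x - m) < trim * s]
  mk <- sum(kept) / length(kept)
  k * sqrt(sum((kept - mk)^2) / length(kept))
}

# pairwise metal-metal cluster flags, brute force
.oracle_cluster_flags <- function(xyz, cluster_distance = 3.0) {
  n <- nrow(xyz)
  flags <- rep(FALSE, n)
  if (n < 2) return(flags)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cluster_distance) {
      flags[i] <- TRUE; flags[j] <- TRUE
    }
  }
  flags
}

# --- builders --------------------------------------------------------------

#' Build the PDB-text half of a fixture
#'
#' Emits HEADER, REMARK 2, REMARK 290 SMTRY, CRYST1 and HETATM/ATOM records
#' at fixed columns, with per-site ground truth (minimum symmetry-image
#' distance from 5^3-shift enumeration, cluster flags, expected
#' resolution/occupancy/symmetry criterion outcomes at the default
#' thresholds).
#'
#' @param spec A [fixture_spec()].
#' @return List with `lines` (PDB text) and `truth` (data frame, one row
#'   per metal site).
#' @export
build_entry_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  metals <- spec$metals
  metals[, c("x", "y", "z")] <- round(metals[, c("x", "y", "z")], 3)
  decoys <- spec$decoys
  if (!is.null(decoys))
    decoys[, c("x", "y", "z")] <- round(decoys[, c("x", "y", "z")], 3)

  out <- sprintf("%-62s%4s", "HEADER    SYNTHETIC METAL SITE FIXTURE", spec$pdb_id)
  out <- c(out, "EXPDTA    X-RAY DIFFRACTION")
  out <- c(out, if (is.na(spec$resolution))
    "REMARK   2 RESOLUTION. NOT APPLICABLE."
    else sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", spec$resolution))
  for (k in seq_along(spec$operators)) {
    op <- spec$operators[[k]]
    for (r in 1:3)
      out <- c(out, sprintf(
        "REMARK 290   SMTRY%d %3d%10.6f%10.6f%10.6f%15.5f",
        r, k, op$rotation[r, 1], op$rotation[r, 2], op$rotation[r, 3],
        op$translation[r]))
  }
  cl <- spec$cell
  out <- c(out, sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma))

  serial <- 0L
  atom_line <- function(record, name, res_name, chain, res_no, x, y, z,
                        occ, element) {
    serial <<- serial + 1L
    if (nchar(name) < 4 && nchar(element) < 2) name <- paste0(" ", name)
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, name, "", res_name, chain, res_no, "",
            x, y, z, occ, 20.0, toupper(element))
  }
  for (i in seq_len(nrow(metals)))
    out <- c(out, atom_line("HETATM", toupper(metals$element[i]),
                            toupper(metals$element[i]), metals$chain[i],
                            metals$res_no[i], metals$x[i], metals$y[i],
                            metals$z[i], metals$occupancy[i],
                            metals$element[i]))
  if (!is.null(decoys)) for (i in seq_len(nrow(decoys)))
    out <- c(out, atom_line("ATOM", toupper(decoys$element[i]), "GLY", "Z",
                            900L + i, decoys$x[i], decoys$y[i], decoys$z[i],
                            1.0, decoys$element[i]))
  out <- c(out, "END")

  all_xyz <- rbind(as.matrix(metals[, c("x", "y", "z")]),
                   if (!is.null(decoys)) as.matrix(decoys[, c("x", "y", "z")]))
  min_sym <- vapply(seq_len(nrow(metals)), function(i)
    .oracle_min_sym_distance(spec$cell, spec$operators, all_xyz,
                             as.numeric(metals[i, c("x", "y", "z")])),
    numeric(1))
  clusters <- .oracle_cluster_flags(as.matrix(metals[, c("x", "y", "z")]))

  truth <- data.frame(
    site_id = sprintf("%s.%s.%d.%s", spec$pdb_id, metals$chain,
                      metals$res_no, toupper(metals$element)),
    element = metals$element,
    x = metals$x, y = metals$y, z = metals$z,
    resolution = spec$resolution,
    occupancy = metals$occupancy,
    min_symmetry_distance = min_sym,
    cluster = clusters,
    pass_resolution = !is.na(spec$resolution) & spec$resolution <= 2.5,
    pass_occupancy = metals$occupancy >= 0.9,
    pass_symmetry = min_sym > 3.5,
    stringsAsFactors = FALSE)
  list(lines = out, truth = truth)
}

#' Build the density-map half of a fixture
#'
#' Seeded Gaussian background noise plus isotropic Gaussian blobs, each
#' normalized so its analytic integral equals the specified electron count
#' at electron scale 1. Blobs are planted with crystallographic periodicity
#' on the full cell; a partial map is then cropped to the requested extent.
#'
#' @param spec A [fixture_spec()].
#' @return List with `map` (a `density_map`) and `truth` (list:
#'   `planted_electrons` per blob, `noise_sigma`).
#' @export
build_map_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  g <- spec$grid
  M <- .oracle_orth(spec$cell)
  Minv <- solve(M)
  nvox <- prod(g)

  vals <- .with_seed(spec$seed,
                     array(stats::rnorm(nvox, 0, spec$noise_sigma), dim = g))

  if (!is.null(spec$blobs) && nrow(spec$blobs) > 0) {
    i1 <- rep.int(seq_len(g[1]) - 1L, g[2] * g[3])
    i2 <- rep.int(rep(seq_len(g[2]) - 1L, each = g[1]), g[3])
    i3 <- rep(seq_len(g[3]) - 1L, each = g[1] * g[2])
    Fr <- rbind(i1 / g[1], i2 / g[2], i3 / g[3])
    for (b in seq_len(nrow(spec$blobs))) {
      bb <- spec$blobs[b, ]
      amp <- bb$electrons / ((2 * pi)^1.5 * bb$width^3)
      D <- Fr - drop(Minv %*% c(bb$x, bb$y, bb$z))
      D <- D - round(D)
      C <- M %*% D
      vals <- vals + amp * exp(-colSums(C * C) / (2 * bb$width^2))
    }
  }

  start_crystal <- c(0L, 0L, 0L)
  if (!is.null(spec$map_extent)) {
    s <- as.integer(spec$map_extent$start)
    n <- as.integer(spec$map_extent$count)
    vals <- vals[s[1] + seq_len(n[1]), s[2] + seq_len(n[2]),
                 s[3] + seq_len(n[3]), drop = FALSE]
    start_crystal <- s
  }
  ao <- spec$axis_order
  vals <- aperm(vals, ao)

  v <- as.vector(vals)
  map <- structure(list(
    values = vals,
    start = start_crystal[ao],
    grid = g,
    axis_order = ao,
    cell = spec$cell,
    declared_mean = mean(v),
    declared_rms = sqrt(mean((v - mean(v))^2)),
    ispg = 1L,
    endian = "little"
  ), class = "density_map")

  list(map = map,
       truth = list(planted_electrons = spec$blobs$electrons,
                    noise_sigma = spec$noise_sigma))
}

#' Fixture suite spanning all criterion outcomes
#'
#' Builds a deterministic set of seven paired entry/map fixtures: a clean
#' pass-all site, a resolution failure (7 A), an occupancy failure (0.7), a
#' symmetry-contact failure (image at 3.2 A), a high-discrepancy site, a
#' two-metal cluster, and a partial-coverage map whose site has unusable
#' density. Ground truth (criterion flags, minimum symmetry distances,
#' voxel-loop discrepancy sums, the trimmed-SD cohort cutoff, cluster
#' flags) is computed entirely by brute-force oracles.
#'
#' @param seed Integer master seed; per-fixture seeds derive from it.
#' @param dir Optional directory: when given, `<id>.pdb` / `<id>.ccp4`
#'   files and a `manifest.tsv` of truth values are written there.
#' @return List of class `fixture_suite`: per-fixture elements (each with
#'   `spec`, `pdb_lines`, `map`, `truth`) plus attributes `truth` (combined
#'   per-site truth table with flags under the derived cutoff) and `cutoff`.
#' @export
fixture_suite <- function(seed = 1, dir = NULL) {
  seed <- as.integer(seed)
  cube16 <- unit_cell(16, 16, 16)
  met <- function(element, chain, res_no, x, y, z, occupancy = 1.0)
    data.frame(element = element, chain = chain, res_no = res_no,
               x = x, y = y, z = z, occupancy = occupancy,
               stringsAsFactors = FALSE)
  blob <- function(x, y, z, electrons, width = 1.5)
    data.frame(x = x, y = y, z = z, electrons = electrons, width = width)
  shell_o <- function(x, y, z)  # four oxygens ~2.3 A around a metal
    data.frame(element = "O",
               x = x + c(2.3, -2.3, 0, 0), y = y + c(0, 0, 2.3, -2.3),
               z = z + c(0.3, -0.3, 0.4, -0.4), stringsAsFactors = FALSE)

  specs <- list(
    clean = fixture_spec(seed + 11L, "SYN1", cube16, resolution = 1.8,
                         metals = met("Ca", "F", 405L, 8, 8, 8),
                         decoys = shell_o(8, 8, 8),
                         blobs = blob(8, 8, 8, 3)),
    resolution_fail = fixture_spec(seed + 12L, "SYN2", cube16,
                                   resolution = 7.0,
                                   metals = met("Mg", "C", 163L, 8, 8, 8),
                                   decoys = shell_o(8, 8, 8),
                                   blobs = blob(8, 8, 8, 5),
                                   axis_order = c(3L, 1L, 2L)),
    occupancy_fail = fixture_spec(seed + 13L, "SYN3", cube16,
                                  resolution = 2.0,
                                  metals = met("Zn", "B", 701L, 8, 8, 8,
                                               occupancy = 0.7),
                                  decoys = shell_o(8, 8, 8),
                                  blobs = blob(8, 8, 8, 5)),
    symmetry_fail = fixture_spec(
      seed + 14L, "SYN4", cube16, resolution = 2.0,
      operators = list(sym_op(diag(c(-1, -1, 1)), c(7.2, 4, 0))),
      metals = met("Mn", "A", 706L, 2, 2, 4),
      decoys = data.frame(element = "O", x = c(2, 2), y = c(2, 2),
                          z = c(6.1, 1.9), stringsAsFactors = FALSE),
      blobs = blob(2, 2, 4, 8)),
    discrepancy_fail = fixture_spec(seed + 15L, "SYN5", cube16,
                                    resolution = 1.9,
                                    metals = met("Cu", "A", 200L, 8, 8, 8),
                                    decoys = shell_o(8, 8, 8),
                                    blobs = blob(8, 8, 8, 60)),
    cluster = fixture_spec(seed + 16L, "SYN6", cube16, resolution = 2.1,
                           metals = rbind(met("Fe", "A", 501L, 7, 8, 8),
                                          met("Fe", "A", 502L, 9.5, 8, 8)),
                           blobs = rbind(blob(7, 8, 8, 12),
                                         blob(9.5, 8, 8, 16))),
    partial_coverage = fixture_spec(seed + 17L, "SYN7", cube16,
                                    resolution = 2.0,
                                    metals = met("Na", "A", 301L, 7.5, 8, 8),
                                    blobs = blob(7.5, 8, 8, 4),
                                    map_extent = list(start = c(0L, 0L, 0L),
                                                      count = c(16L, 32L, 32L)))
  )

  fixtures <- lapply(specs, function(sp) {
    ent <- build_entry_fixture(sp)
    mp <- build_map_fixture(sp)
    list(spec = sp, pdb_lines = ent$lines, map = mp$map,
         truth = ent$truth, map_truth = mp$truth)
  })

  # oracle discrepancy sums and coverage per site
  truth <- do.call(rbind, lapply(names(fixtures), function(nm) {
    fx <- fixtures[[nm]]
    tt <- fx$truth
    tt$fixture <- nm
    tt$discrepancy_e <- vapply(seq_len(nrow(tt)), function(i)
      .oracle_regional_sum(fx$map, c(tt$x[i], tt$y[i], tt$z[i]))$sum,
      numeric(1))
    ext <- integer(3); ext[fx$map$axis_order] <- dim(fx$map$values)
    tt$density_usable <- all(ext == fx$map$grid)  # by construction: the
    # only partial map leaves its site's sphere partly uncovered
    tt
  }))

  qualifying <- truth$pass_resolution & truth$pass_occupancy &
    truth$density_usable
  cutoff <- .oracle_trim_sd(truth$discrepancy_e[qualifying], trim = 2, k = 1)
  truth$pass_discrepancy <- truth$density_usable &
    truth$discrepancy_e < cutoff
  truth$pass_all <- truth$pass_resolution & truth$pass_occupancy &
    truth$pass_symmetry & truth$pass_discrepancy & truth$density_usable
  rownames(truth) <- NULL

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (fx in fixtures) {
      writeLines(fx$pdb_lines, file.path(dir, paste0(fx$spec$pdb_id, ".pdb")))
      write_ccp4_map(fx$map, file.path(dir, paste0(fx$spec$pdb_id, ".ccp4")))
    }
    utils::write.table(truth, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  structure(fixtures, class = "fixture_suite", truth = truth,
            cutoff = cutoff)
}

#' Planted-blob electron recovery fixture
#'
#' A finely sampled full-cell map with a single Gaussian blob of known
#' integrated electron content at one metal, and a second metal placed 8 A
#' from the blob whose sphere contains essentially no density. Used to
#' check that the regional discrepancy sum recovers the planted electron
#' count (up to significance clipping of the sub-threshold Gaussian tail
#' and grid discretization).
#'
#' @param seed Integer seed for the background noise.
#' @param electrons Planted electron count.
#' @return List with `spec`, `map`, `blob_center`, `displaced_center`
#'   (8 A away), `planted_electrons`.
#' @export
blob_recovery_fixture <- function(seed = 1, electrons = 25) {
  sp <- fixture_spec(
    as.integer(seed) + 101L, "SYNB", unit_cell(30, 30, 30),
    resolution = 1.8,
    metals = data.frame(element = c("Zn", "Zn"), chain = "A",
                        res_no = c(101L, 102L),
                        x = c(15, 23), y = 15, z = 15, occupancy = 1.0,
                        stringsAsFactors = FALSE),
    blobs = data.frame(x = 15, y = 15, z = 15, electrons = electrons,
                       width = 0.6),
    noise_sigma = 0.008, grid = c(150L, 150L, 150L))
  mp <- build_map_fixture(sp)
  list(spec = sp, map = mp$map,
       blob_center = c(15, 15, 15), displaced_center = c(23, 15, 15),
       planted_electrons = electrons)
}
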