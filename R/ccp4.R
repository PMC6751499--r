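#' Read a CCP4/MRC density map
#'
#' Decodes the 1024-byte CCP4/MRC header and the mode-2 (32-bit float) data
#' block. Endianness is auto-detected from the machine-stamp word; the
#' `"MAP "` magic is required. Axis order (MAPC/MAPR/MAPS) is preserved so
#' that values can be addressed by crystal-axis grid indices.
#'
#' @param src File path or a raw vector holding the map bytes.
#' @return An object of class `density_map`: a list with `values` (3-D array
#'   in file storage order, dim = column/row/section counts), `start`
#'   (NCSTART/NRSTART/NSSTART, file-axis order), `grid` (NX/NY/NZ, full-cell
#'   sampling intervals along the crystal axes), `axis_order` (MAPC/MAPR/MAPS:
#'   crystal axis stored on each file axis), `cell` ([unit_cell]),
#'   `declared_mean`, `declared_rms`, `ispg`, `endian`.
#' @export
read_ccp4_map <- function(src) {
  bytes <- if (is.raw(src)) src else readBin(src, "raw", file.info(src)$size)
  if (length(bytes) < 1024)
    stop("not a CCP4/MRC map: file shorter than the 1024-byte header")
  if (rawToChar(bytes[209:212]) != "MAP ")
    stop("not a CCP4/MRC map: missing 'MAP ' magic at header word 53")
  stamp <- as.integer(bytes[213])
  endian <- if (stamp == 0x11) "big" else "little"

  int_at <- function(word, n = 1)
    readBin(bytes[(4 * (word - 1) + 1):(4 * (word + n - 1))],
            "integer", n, 4, endian = endian)
  dbl_at <- function(word, n = 1)
    readBin(bytes[(4 * (word - 1) + 1):(4 * (word + n - 1))],
            "double", n, 4, endian = endian)

  extents <- int_at(1, 3)            # NC, NR, NS
  mode <- int_at(4)
  if (mode != 2)
    stop("unsupported map mode ", mode, " (only mode 2, 32-bit float)")
  start <- int_at(5, 3)              # NCSTART, NRSTART, NSSTART
  grid <- int_at(8, 3)               # NX, NY, NZ
  cellp <- dbl_at(11, 6)
  axis_order <- int_at(17, 3)        # MAPC, MAPR, MAPS
  amean <- dbl_at(22)
  ispg <- int_at(23)
  nsymbt <- int_at(24)
  arms <- dbl_at(55)
  if (!all(sort(axis_order) == 1:3))
    stop("corrupt map header: MAPC/MAPR/MAPS is not a permutation of 1:3")
  if (any(extents <= 0) || any(grid <= 0))
    stop("corrupt map header: non-positive extents or grid counts")

  nvox <- prod(extents)
  off <- 1024 + nsymbt
  if (length(bytes) < off + 4 * nvox)
    stop(sprintf("truncated map: expected %d voxels, data block too short", nvox))
  values <- readBin(bytes[(off + 1):(off + 4 * nvox)], "double", nvox, 4,
                    endian = endian)
  dim(values) <- extents

  # stale header statistics are a warning, never an error: analysis always
  # uses statistics computed from the voxels
  m <- mean(values)
  rms_c <- sqrt(mean((values - m)^2))
  if (is.finite(arms) && arms > 0 && rms_c > 0 &&
      (abs(arms - rms_c) / rms_c > 1e-3 || abs(amean - m) > 1e-3 * rms_c))
    warning("map header AMEAN/ARMS disagree with computed statistics; using computed values")

  structure(list(
    values = values,
    start = start,
    grid = grid,
    axis_order = axis_order,
    cell = unit_cell(cellp[1], cellp[2], cellp[3],
                     cellp[4], cellp[5], cellp[6]),
    declared_mean = amean,
    declared_rms = arms,
    ispg = ispg,
    endian = endian
  ), class = "density_map")
}

#' Write a density map in CCP4/MRC mode-2 format
#'
#' Min/max/mean and RMS header fields are recomputed from the values.
#'
#' @param map A `density_map`.
#' @param path Output path; if `NULL` the raw bytes are returned.
#' @param endian `"little"` (default) or `"big"`; the machine stamp is set
#'   accordingly.
#' @return The raw bytes, invisibly when written to `path`.
#' @export
write_ccp4_map <- function(map, path = NULL, endian = c("little", "big")) {
  stopifnot(inherits(map, "density_map"))
  endian <- match.arg(endian)
  v <- as.vector(map$values)
  n <- length(v)
  m <- mean(v)
  rms <- sqrt(mean((v - m)^2))

  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = endian)
  wd <- function(x) writeBin(as.numeric(x), con, size = 4, endian = endian)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)

  wi(dim(map$values))                         # 1-3   NC NR NS
  wi(2)                                       # 4     MODE
  wi(map$start)                               # 5-7
  wi(map$grid)                                # 8-10
  cl <- map$cell
  wd(c(cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma))  # 11-16
  wi(map$axis_order)                          # 17-19
  wd(c(min(v), max(v), m))                    # 20-22
  wi(if (is.null(map$ispg)) 1 else map$ispg)  # 23
  wi(0)                                       # 24    NSYMBT
  wi(rep(0L, 25))                             # 25-49
  wd(c(0, 0, 0))                              # 50-52 ORIGIN
  writeBin(charToRaw("MAP "), con)            # 53
  stamp <- if (endian == "little") as.raw(c(0x44, 0x44, 0x00, 0x00))
           else as.raw(c(0x11, 0x11, 0x00, 0x00))
  writeBin(stamp, con)                        # 54
  wd(rms)                                     # 55
  wi(1)                                       # 56    NLABL
  lab <- sprintf("%-80s", "Synthetic Fo-Fc difference map (metalsiteqc)")
  writeBin(charToRaw(paste(c(lab, rep(sprintf("%80s", ""), 9)),
                           collapse = "")), con)  # 57-256
  wd(v)

  bytes <- rawConnectionValue(con)
  if (!is.null(path)) {
    writeBin(bytes, path)
    return(invisible(bytes))
  }
  bytes
}

#' Map statistics
#'
#' Mean and population standard deviation over all stored voxels (computed,
#' not taken from the header), and the voxel volume.
#'
#' @param map A `density_map`.
#' @return A list of class `map_statistics` with `mean`, `sigma`,
#'   `voxel_volume` (cubic Angstrom, cell volume divided by the full-cell
#'   grid-point count), `n_voxels`.
#' @export
map_statistics <- function(map) {
  stopifnot(inherits(map, "density_map"))
  v <- as.vector(map$values)
  if (length(v) == 0) stop("empty map")
  m <- mean(v)
  structure(list(
    mean = m,
    sigma = sqrt(mean((v - m)^2)),
    voxel_volume = cell_volume(map$cell) / prod(map$grid),
    n_voxels = length(v)
  ), class = "map_statistics")
}

# extents and start indices reordered to crystal-axis order
.crystal_extent <- function(map) {
  e <- integer(3); e[map$axis_order] <- dim(map$values); e
}
.crystal_start <- function(map) {
  s <- integer(3); s[map$axis_order] <- map$start; s
}

#' Does the map cover a full unit cell?
#'
#' True when the stored extents equal the full-cell sampling counts along
#' every crystal axis, in which case crystallographic periodicity
#' (minimum-image wrapping) applies. Partial maps are never wrapped; sphere
#' regions extending beyond their extent are reported as uncovered.
#'
#' @param map A `density_map`.
#' @return Logical.
#' @export
map_covers_cell <- function(map) all(.crystal_extent(map) == map$grid)

# absolute crystal-axis grid coordinates of every stored voxel, 3 x nvox,
# in storage order
.crystal_grid_coords <- function(map) {
  d <- dim(map$values)
  ao <- map$axis_order
  i1 <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  i2 <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  i3 <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  G <- matrix(0, 3, prod(d))
  G[ao[1], ] <- map$start[1] + i1
  G[ao[2], ] <- map$start[2] + i2
  G[ao[3], ] <- map$start[3] + i3
  G
}

#' Grid index to Cartesian coordinates
#'
#' Converts a crystal-axis-order grid index, relative to the map start, to
#' Cartesian Angstrom: fractional coordinate `(index + start) / grid`
#' orthogonalized through the cell transform. Indices may exceed the stored
#' extents (positions are defined by the lattice, not the coverage).
#'
#' @param map A `density_map`.
#' @param index Length-3 vector (crystal-axis order, 0-based), or a 3-row
#'   matrix of such columns.
#' @return Cartesian coordinates, same shape as `index`.
#' @export
grid_to_cartesian <- function(map, index) {
  ct <- cell_transform(map$cell)
  frac <- (index + .crystal_start(map)) / map$grid
  drop(ct$orth %*% frac)
}

#' Cartesian coordinates to (real-valued) grid index
#'
#' Exact inverse of [grid_to_cartesian()] up to periodic wrapping.
#'
#' @param map A `density_map`.
#' @param point Cartesian length-3 vector or 3-row matrix of columns.
#' @return Real-valued grid coordinates (crystal-axis order, relative to the
#'   map start), same shape as `point`.
#' @export
cartesian_to_grid <- function(map, point) {
  ct <- cell_transform(map$cell)
  frac <- ct$deorth %*% point
  drop(frac * map$grid - .crystal_start(map))
}

#' @export
print.density_map <- function(x, ...) {
  st <- map_statistics(x)
  cat(sprintf(
    "CCP4/MRC map: extents %s, grid %s, axis order (%d,%d,%d)\n",
    paste(dim(x$values), collapse = "x"), paste(x$grid, collapse = "x"),
    x$axis_order[1], x$axis_order[2], x$axis_order[3]))
  cat(sprintf("  mean %.5g, sigma %.5g, voxel volume %.5g A^3, %s\n",
              st$mean, st$sigma, st$voxel_volume,
              if (map_covers_cell(x)) "full-cell coverage" else "partial coverage"))
  print(x$cell)
  invisible(x)
}
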