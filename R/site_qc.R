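#' Quality-control configuration
#'
#' All thresholds of the four-criterion regional QC method, with the
#' defaults used for the pan-PDB screen: resolution at or below 2.5 A,
#' occupancy at or above 0.9, no symmetry atom within 3.5 A, and a regional
#' discrepancy sum below a cohort-derived cutoff (significant voxels at 3
#' map standard deviations inside a 3.5 A sphere; cutoff = 1 SD of the
#' 2-SD-trimmed cohort distribution).
#'
#' @param resolution_max Maximum resolution in Angstrom (criterion 1).
#' @param occupancy_min Minimum occupancy fraction (criterion 2).
#' @param symmetry_radius Symmetry-contact exclusion radius, Angstrom
#'   (criterion 3; a contact at exactly this distance fails).
#' @param region_radius Radius of the regional discrepancy sphere, Angstrom.
#' @param z_cut Significance threshold in map standard deviations.
#' @param trim_sd Outlier trim width (standard deviations) for cutoff
#'   derivation.
#' @param cutoff_sd Multiple of the trimmed standard deviation used as the
#'   discrepancy cutoff.
#' @param cluster_distance Metal-metal distance (Angstrom) defining a metal
#'   ion cluster (strictly less than).
#' @param electron_scale Electrons per (map unit times cubic Angstrom);
#'   1.0 treats map values as electrons per cubic Angstrom. A per-entry
#'   calibration (e.g. a density-to-electron ratio derived externally) can
#'   be supplied here.
#' @param metal_elements Element symbols treated as metals.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(resolution_max = 2.5,
                      occupancy_min = 0.9,
                      symmetry_radius = 3.5,
                      region_radius = 3.5,
                      z_cut = 3,
                      trim_sd = 2,
                      cutoff_sd = 1,
                      cluster_distance = 3.0,
                      electron_scale = 1.0,
                      metal_elements = default_metal_elements()) {
  thr <- c(resolution_max, occupancy_min, symmetry_radius, region_radius,
           z_cut, trim_sd, cutoff_sd, cluster_distance, electron_scale)
  if (any(!is.finite(thr)) || any(thr <= 0))
    stop("all qc_config thresholds must be positive")
  if (occupancy_min > 1)
    stop("occupancy_min must lie in (0, 1]")
  structure(list(
    resolution_max = resolution_max, occupancy_min = occupancy_min,
    symmetry_radius = symmetry_radius, region_radius = region_radius,
    z_cut = z_cut, trim_sd = trim_sd, cutoff_sd = cutoff_sd,
    cluster_distance = cluster_distance, electron_scale = electron_scale,
    metal_elements = metal_elements
  ), class = "qc_config")
}

#' @export
print.qc_config <- function(x, ...) {
  cat("Metal-site QC configuration:\n")
  cat(sprintf("  resolution <= %.2f A | occupancy >= %.2f | no symmetry atom within %.2f A\n",
              x$resolution_max, x$occupancy_min, x$symmetry_radius))
  cat(sprintf("  region radius %.2f A | significance %g sigma | trim %g sd | cutoff %g sd\n",
              x$region_radius, x$z_cut, x$trim_sd, x$cutoff_sd))
  cat(sprintf("  cluster distance %.2f A | electron scale %g | %d metal elements\n",
              x$cluster_distance, x$electron_scale, length(x$metal_elements)))
  invisible(x)
}

#' Regional electron discrepancy around a point
#'
#' Sums the absolute significant difference-map density inside a sphere.
#' Every stored voxel whose center lies within `radius` of `center`
#' (minimum-image convention when the map covers a full cell) and whose
#' value deviates from the map mean by at least `z_cut` computed map
#' standard deviations contributes `|value| * voxel_volume * electron_scale`
#' electrons.
#'
#' @param map A `density_map`.
#' @param center Cartesian point (length 3), Angstrom.
#' @param radius Sphere radius, Angstrom.
#' @param z_cut Significance threshold in map standard deviations.
#' @param electron_scale Electrons per (map unit times cubic Angstrom).
#' @return List with `discrepancy_sum` (electrons),
#'   `significant_voxel_count`, and `covered` (`FALSE` when any sphere voxel
#'   falls outside a partial map's extent; the sum is then over covered
#'   voxels only).
#' @export
regional_discrepancy <- function(map, center, radius = 3.5, z_cut = 3,
                                 electron_scale = 1.0) {
  stopifnot(inherits(map, "density_map"), radius > 0, z_cut > 0)
  center <- as.numeric(center)
  st <- map_statistics(map)
  if (st$sigma <= 0)
    stop("degenerate map: zero standard deviation, significance undefined")
  ct <- cell_transform(map$cell)
  wrap <- map_covers_cell(map)

  Fr <- .crystal_grid_coords(map) / map$grid     # fractional, 3 x nvox
  cf <- drop(ct$deorth %*% center)
  D <- Fr - cf
  if (wrap) D <- D - round(D)                    # per-axis minimum image
  C <- ct$orth %*% D
  inside <- colSums(C * C) <= radius^2

  vals <- as.vector(map$values)[inside]
  sig <- abs(vals - st$mean) >= z_cut * st$sigma
  total <- sum(abs(vals[sig])) * st$voxel_volume * electron_scale

  covered <- if (wrap) TRUE else .sphere_covered(map, ct, center, radius)
  list(discrepancy_sum = total,
       significant_voxel_count = sum(sig),
       covered = covered)
}

# for partial maps: is every lattice voxel within the sphere stored?
.sphere_covered <- function(map, ct, center, radius) {
  grid <- map$grid
  start <- .crystal_start(map)
  ext <- .crystal_extent(map)
  cg <- drop(ct$deorth %*% center) * grid        # absolute grid coordinate
  halfw <- radius * grid * sqrt(rowSums(ct$deorth^2))
  rng <- lapply(1:3, function(j)
    seq.int(floor(cg[j] - halfw[j]), ceiling(cg[j] + halfw[j])))
  G <- t(as.matrix(expand.grid(rng)))
  D <- ct$orth %*% (G / grid - drop(ct$deorth %*% center))
  need <- colSums(D * D) <= radius^2
  Gn <- G[, need, drop = FALSE]
  all(Gn >= start & Gn <= start + ext - 1)
}

#' Whole-map background discrepancy
#'
#' The average absolute significant discrepancy per cubic Angstrom over the
#' whole map, scaled to the volume of a sphere of the given radius. Serves
#' as the baseline against which metal-centric regional discrepancies are
#' compared.
#'
#' @inheritParams regional_discrepancy
#' @return Electrons (per sphere volume).
#' @export
background_discrepancy <- function(map, radius = 3.5, z_cut = 3,
                                   electron_scale = 1.0) {
  stopifnot(inherits(map, "density_map"), radius > 0, z_cut > 0)
  st <- map_statistics(map)
  if (st$sigma <= 0)
    stop("degenerate map: zero standard deviation, significance undefined")
  v <- as.vector(map$values)
  sig <- abs(v - st$mean) >= z_cut * st$sigma
  total <- sum(abs(v[sig])) * st$voxel_volume * electron_scale
  map_volume <- st$n_voxels * st$voxel_volume
  total / map_volume * (4 / 3) * pi * radius^3
}

#' Evaluate one metal site against all four criteria
#'
#' @param entry A `structure_entry`.
#' @param map A `density_map` (its cell should match the entry's within
#'   0.1\% per edge; a warning is issued otherwise).
#' @param site One row of the data frame from [extract_metal_sites()].
#' @param config A [qc_config()].
#' @param discrepancy_cutoff Cohort-derived cutoff in electrons, or `NULL`
#'   when not yet known (two-phase workflow); the discrepancy and overall
#'   flags are then `NA`.
#' @return One-row data frame (a site QC record): `site_id`, `element`,
#'   `resolution_A`, `occupancy`, `min_symmetry_dist_A` (`NA` when no
#'   contact lies within the exclusion radius), `discrepancy_e`,
#'   `n_sig_voxels`, `density_usable`, `pass_resolution`, `pass_occupancy`,
#'   `pass_symmetry`, `pass_discrepancy`, `pass_all`.
#' @export
evaluate_site <- function(entry, map, site, config = qc_config(),
                          discrepancy_cutoff = NULL) {
  stopifnot(inherits(entry, "structure_entry"), inherits(map, "density_map"),
            inherits(config, "qc_config"))
  ec <- entry$cell; mc <- map$cell
  rel <- abs(c(ec$a - mc$a, ec$b - mc$b, ec$c - mc$c)) /
    c(ec$a, ec$b, ec$c)
  if (any(rel > 1e-3))
    warning(sprintf("%s: map cell differs from entry cell by more than 0.1%%",
                    site$site_id))

  center <- c(site$x, site$y, site$z)
  contact <- tryCatch(
    nearest_symmetry_contact(entry, center, radius = config$symmetry_radius),
    error = function(e) stop(sprintf("%s: %s", site$site_id, conditionMessage(e))))
  min_sym <- if (is.null(contact)) NA_real_ else contact$distance

  reg <- tryCatch(
    regional_discrepancy(map, center, radius = config$region_radius,
                         z_cut = config$z_cut,
                         electron_scale = config$electron_scale),
    error = function(e) stop(sprintf("%s: %s", site$site_id, conditionMessage(e))))

  pass_res <- !is.na(entry$resolution) && entry$resolution <= config$resolution_max
  pass_occ <- site$occupancy >= config$occupancy_min
  pass_sym <- is.null(contact)
  usable <- reg$covered
  if (is.null(discrepancy_cutoff) || is.na(discrepancy_cutoff)) {
    pass_disc <- NA
    pass_all <- NA
  } else {
    pass_disc <- usable && reg$discrepancy_sum < discrepancy_cutoff
    pass_all <- pass_res && pass_occ && pass_sym && pass_disc && usable
  }

  data.frame(
    site_id = site$site_id,
    element = site$element,
    resolution_A = if (is.na(entry$resolution)) NA_real_ else entry$resolution,
    occupancy = site$occupancy,
    min_symmetry_dist_A = min_sym,
    discrepancy_e = reg$discrepancy_sum,
    n_sig_voxels = reg$significant_voxel_count,
    density_usable = usable,
    pass_resolution = pass_res,
    pass_occupancy = pass_occ,
    pass_symmetry = pass_sym,
    pass_discrepancy = pass_disc,
    pass_all = pass_all,
    stringsAsFactors = FALSE)
}
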