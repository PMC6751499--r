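# Two-phase workflow: per-site evaluation (cutoff unknown), then cohort
# cutoff derivation and final flag setting.

#' Pair entry and map files by shared identifier
#'
#' Matches `<id>.pdb`/`<id>.ent` files against `<id>.ccp4`/`<id>.mrc`/
#' `<id>.map` files on the basename `<id>`.
#'
#' @param entries_dir Directory of PDB entries.
#' @param maps_dir Directory of density maps.
#' @return Data frame with columns `id`, `entry`, `map` (map path `NA` when
#'   unmatched), sorted by id.
#' @export
pair_inputs <- function(entries_dir, maps_dir) {
  ents <- list.files(entries_dir, pattern = "\\.(pdb|ent)$", full.names = TRUE)
  maps <- list.files(maps_dir, pattern = "\\.(ccp4|mrc|map)$", full.names = TRUE)
  base <- function(p) sub("\\.[^.]+$", "", basename(p))
  mids <- base(maps)
  ids <- base(ents)
  ord <- order(ids)
  data.frame(id = ids[ord], entry = ents[ord],
             map = maps[match(ids, mids)][ord],
             stringsAsFactors = FALSE)
}

#' Phase one: evaluate every metal site of every entry
#'
#' Parses each entry, reads its map, and scores every metal site on
#' resolution, occupancy, symmetry contacts and the regional discrepancy
#' sum. The discrepancy criterion flag is left `NA` (the cohort cutoff is
#' not yet known; see [run_finalize()]). Unreadable or unpaired inputs are
#' logged in the manifest and skipped; the run continues.
#'
#' @param pairs Data frame with columns `entry` and `map` (file paths; see
#'   [pair_inputs()]), or a list of `list(entry =, map =)` in-memory
#'   `structure_entry`/`density_map` pairs.
#' @param config A [qc_config()].
#' @param out Optional path for the tab-separated records file.
#' @return List of class `qc_evaluation`: `records` (one row per metal
#'   site, ordered by entry id then file order, with a `cluster_flag`
#'   column) and `manifest` (config snapshot, per-input status, counts).
#' @export
run_evaluate <- function(pairs, config = qc_config(), out = NULL) {
  stopifnot(inherits(config, "qc_config"))
  status <- data.frame(id = character(0), status = character(0),
                       reason = character(0), stringsAsFactors = FALSE)
  records <- list()

  load_pair <- function(p) {
    if (is.list(p) && inherits(p$entry, "structure_entry"))
      return(list(entry = p$entry, map = p$map))
    if (is.na(p$map) || !file.exists(p$map))
      stop("missing density map")
    list(entry = read_pdb_entry(p$entry), map = read_ccp4_map(p$map))
  }
  as_list <- if (is.data.frame(pairs))
    lapply(seq_len(nrow(pairs)), function(i) pairs[i, , drop = FALSE])
  else pairs

  for (p in as_list) {
    loaded <- tryCatch(load_pair(p), error = function(e) e)
    pid <- if (is.data.frame(p)) sub("\\.[^.]+$", "", basename(p$entry))
           else tryCatch(p$entry$pdb_id, error = function(e) "?")
    if (inherits(loaded, "error")) {
      status <- rbind(status, data.frame(
        id = pid, status = "skipped", reason = conditionMessage(loaded),
        stringsAsFactors = FALSE))
      next
    }
    entry <- loaded$entry
    sites <- extract_metal_sites(entry, config$metal_elements)
    if (nrow(sites) == 0) {
      status <- rbind(status, data.frame(
        id = entry$pdb_id, status = "parsed", reason = "no metal sites",
        stringsAsFactors = FALSE))
      next
    }
    clusters <- detect_metal_clusters(sites, config$cluster_distance)
    recs <- tryCatch(
      do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
        evaluate_site(entry, loaded$map, sites[i, , drop = FALSE], config))),
      error = function(e) e)
    if (inherits(recs, "error")) {
      status <- rbind(status, data.frame(
        id = entry$pdb_id, status = "skipped",
        reason = conditionMessage(recs), stringsAsFactors = FALSE))
      next
    }
    recs$cluster_flag <- clusters
    records[[length(records) + 1]] <- recs
    status <- rbind(status, data.frame(
      id = entry$pdb_id, status = "parsed",
      reason = sprintf("%d metal sites", nrow(sites)),
      stringsAsFactors = FALSE))
  }

  records <- if (length(records) > 0) do.call(rbind, records)
  else .empty_records()
  ord <- order(parse_site_id(records$site_id)$pdb_id,
               seq_len(nrow(records)))
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL

  manifest <- list(
    config = config,
    status = status,
    counts = c(inputs = length(as_list),
               parsed = sum(status$status == "parsed"),
               skipped = sum(status$status == "skipped"),
               sites = nrow(records)))
  res <- structure(list(records = records, manifest = manifest),
                   class = "qc_evaluation")
  if (!is.null(out)) {
    write_records(records, out)
    write_manifest(manifest, paste0(out, ".manifest"))
  }
  res
}

.empty_records <- function() {
  data.frame(site_id = character(0), element = character(0),
             resolution_A = numeric(0), occupancy = numeric(0),
             min_symmetry_dist_A = numeric(0), discrepancy_e = numeric(0),
             n_sig_voxels = integer(0), density_usable = logical(0),
             pass_resolution = logical(0), pass_occupancy = logical(0),
             pass_symmetry = logical(0), pass_discrepancy = logical(0),
             pass_all = logical(0), cluster_flag = logical(0),
             stringsAsFactors = FALSE)
}

#' Write / read a site records table
#'
#' Tab-separated, header row, fixed column order.
#' @param records Records data frame.
#' @param path File path.
#' @export
write_records <- function(records, path) {
  cols <- names(.empty_records())
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' Config snapshot, per-input status and stage counts as plain text
#' (reruns on identical inputs produce identical bytes).
#' @param manifest Manifest from [run_evaluate()].
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  cfg <- manifest$config
  scal <- vapply(cfg, function(x) length(x) == 1, logical(1))
  lines <- c("[config]",
             sprintf("%s = %s", names(cfg)[scal],
                     vapply(cfg[scal], as.character, "")),
             sprintf("metal_elements = %s",
                     paste(cfg$metal_elements, collapse = ",")),
             "[counts]",
             sprintf("%s = %d", names(manifest$counts), manifest$counts),
             "[inputs]",
             sprintf("%s\t%s\t%s", manifest$status$id,
                     manifest$status$status, manifest$status$reason))
  writeLines(lines, path)
}

#' Phase two: derive the cohort cutoff and set the final flags
#'
#' Derives the data-driven discrepancy cutoff from the sums of all sites
#' passing the resolution and occupancy criteria with usable density, sets
#' the discrepancy and pass-all flags, and produces the per-element
#' tabulation plus the high-quality site list.
#'
#' @param records Records data frame from [run_evaluate()], or a path to a
#'   records file.
#' @param config A [qc_config()].
#' @param out_dir Optional output directory: writes `records_final.tsv`,
#'   `element_table.tsv`, `cutoff_summary.tsv` and
#'   `high_quality_sites.tsv`.
#' @return List of class `qc_final`: `records` (flags filled in), `cutoff`
#'   (a `cutoff_result`), `table` (per-element tabulation), `passing`
#'   (records passing all four criteria).
#' @export
run_finalize <- function(records, config = qc_config(), out_dir = NULL) {
  stopifnot(inherits(config, "qc_config"))
  if (is.character(records)) records <- read_records(records)
  if (nrow(records) == 0)
    stop("insufficient data: no site records; run the evaluation phase on entries containing metal sites")

  qualifying <- records$pass_resolution & records$pass_occupancy &
    records$density_usable
  if (!any(qualifying)) {
    warning("insufficient data: no sites pass the resolution and occupancy criteria with usable density; no cutoff derived, discrepancy criterion fails for all sites (relax the thresholds or add entries)")
    cutoff <- NULL
    records$pass_discrepancy <- FALSE
  } else {
    cutoff <- derive_cutoff(records$discrepancy_e[qualifying], config)
    records$pass_discrepancy <- records$density_usable &
      records$discrepancy_e < cutoff$cutoff
  }
  records$pass_all <- records$pass_resolution & records$pass_occupancy &
    records$pass_symmetry & records$pass_discrepancy &
    records$density_usable

  tab <- tabulate_by_element(records)
  passing <- records[records$pass_all, , drop = FALSE]
  rownames(passing) <- NULL

  res <- structure(list(records = records, cutoff = cutoff, table = tab,
                        passing = passing), class = "qc_final")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_records(records, file.path(out_dir, "records_final.tsv"))
    writeLines(format_element_table(tab),
               file.path(out_dir, "element_table.tsv"))
    cuts <- if (is.null(cutoff))
      c("cutoff_e\tNA", "trimmed_sd_e\tNA", "untrimmed_mean_e\tNA",
        "untrimmed_sd_e\tNA", "n_input\t0", "n_trimmed_out\t0")
    else c(sprintf("cutoff_e\t%.10g", cutoff$cutoff),
           sprintf("trimmed_sd_e\t%.10g", cutoff$trimmed_sd),
           sprintf("untrimmed_mean_e\t%.10g", cutoff$untrimmed_mean),
           sprintf("untrimmed_sd_e\t%.10g", cutoff$untrimmed_sd),
           sprintf("n_input\t%d", cutoff$n_input),
           sprintf("n_trimmed_out\t%d", cutoff$n_trimmed_out))
    writeLines(c("key\tvalue", cuts),
               file.path(out_dir, "cutoff_summary.tsv"))
    write_records(passing, file.path(out_dir, "high_quality_sites.tsv"))
  }
  res
}

#' One-shot workflow: evaluate then finalize
#'
#' @inheritParams run_evaluate
#' @param out_dir Optional output directory (see [run_finalize()]; the
#'   phase-one records are written as `records.tsv`).
#' @return The [run_finalize()] result with the evaluation manifest
#'   attached as `manifest`.
#' @export
run_qc <- function(pairs, config = qc_config(), out_dir = NULL) {
  ev <- run_evaluate(pairs, config,
                     out = if (!is.null(out_dir)) {
                       dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
                       file.path(out_dir, "records.tsv")
                     })
  fin <- run_finalize(ev$records, config, out_dir)
  fin$manifest <- ev$manifest
  fin
}

#' @export
print.qc_final <- function(x, ...) {
  cat(sprintf("Metal-site QC: %d sites, %d pass all four criteria\n",
              nrow(x$records), nrow(x$passing)))
  if (!is.null(x$cutoff)) print(x$cutoff) else cat("  (no cutoff derivable)\n")
  invisible(x)
}

#' @export
print.qc_evaluation <- function(x, ...) {
  cat(sprintf("Metal-site QC evaluation: %d sites from %d parsed inputs (%d skipped)\n",
              nrow(x$records), x$manifest$counts[["parsed"]],
              x$manifest$counts[["skipped"]]))
  invisible(x)
}
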