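# population standard deviation (divide by n); the trim bound and the
# trimmed spread are both defined on it
.pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Derive the data-driven discrepancy cutoff
#'
#' From the cohort distribution of regional discrepancy sums (sites passing
#' the resolution and occupancy criteria, with usable density), outliers
#' beyond `trim_sd` population standard deviations of the untrimmed mean
#' are removed in a single pass, and the cutoff is set to `cutoff_sd` times
#' the population standard deviation of the surviving values. Values lying
#' exactly on the trim bound are removed; a zero-spread input keeps all
#' values.
#'
#' @param sums Numeric vector of discrepancy sums in electrons (all >= 0).
#' @param config A [qc_config()] supplying `trim_sd` and `cutoff_sd`.
#' @return An object of class `cutoff_result`: `cutoff`, `trimmed_sd`,
#'   `untrimmed_mean`, `untrimmed_sd` (all electrons), `n_input`,
#'   `n_trimmed_out`.
#' @export
derive_cutoff <- function(sums, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  sums <- as.numeric(sums)
  if (length(sums) == 0) stop("insufficient data: no discrepancy sums supplied")
  if (any(!is.finite(sums)) || any(sums < 0))
    stop("discrepancy sums must be finite and non-negative")
  m <- mean(sums)
  s <- .pop_sd(sums)
  keep <- if (s == 0) rep(TRUE, length(sums))
          else abs(sums - m) < config$trim_sd * s
  if (sum(keep) < 2)
    stop("insufficient data: fewer than 2 values survive the outlier trim")
  ts <- .pop_sd(sums[keep])
  structure(list(
    cutoff = config$cutoff_sd * ts,
    trimmed_sd = ts,
    untrimmed_mean = m,
    untrimmed_sd = s,
    n_input = length(sums),
    n_trimmed_out = sum(!keep)
  ), class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "Discrepancy cutoff: %.3f e (= cutoff_sd x trimmed SD %.3f e)\n",
    x$cutoff, x$trimmed_sd))
  cat(sprintf("  untrimmed: mean %.3f e, SD %.3f e; n = %d, trimmed out = %d\n",
              x$untrimmed_mean, x$untrimmed_sd, x$n_input, x$n_trimmed_out))
  invisible(x)
}

#' Detect metal ion clusters
#'
#' Flags every metal ion that has another metal ion of the same asymmetric
#' unit at a Euclidean distance strictly below `cluster_distance` (e.g. the
#' metals of an iron-sulfur cluster).
#'
#' @param sites Data frame of sites from one entry (needs columns `x`, `y`,
#'   `z`), as returned by [extract_metal_sites()].
#' @param cluster_distance Distance threshold in Angstrom.
#' @return Logical vector, one flag per site.
#' @export
detect_metal_clusters <- function(sites, cluster_distance = 3.0) {
  n <- nrow(sites)
  if (n < 2) return(rep(FALSE, n))
  d <- as.matrix(stats::dist(sites[, c("x", "y", "z")]))
  diag(d) <- Inf
  unname(apply(d < cluster_distance, 1, any))
}

#' Integer percentage with round-half-away-from-zero
#'
#' The rounding used in the per-element tabulation: e.g. 13,230 of 67,405
#' gives 20.
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`. Vectorized.
#' @return Integer percentage(s).
#' @export
integer_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("undefined percentage: zero denominator")
  if (any(numerator < 0) || any(numerator > denominator))
    stop("numerator must lie in [0, denominator]")
  as.integer(floor(100 * numerator / denominator + 0.5))
}

#' Tabulate site QC records by element
#'
#' Builds the per-element table: number of entries and sites per metal
#' element, marginal counts of sites passing each criterion independently
#' (so column counts can exceed the pass-all column), the pass-all count,
#' integer percentages of each count relative to the element's site total,
#' and a grand-total row. Rows are ordered by decreasing entry count.
#'
#' @param records Data frame of site QC records (from [evaluate_site()] /
#'   [run_finalize()]); entry ids are taken from an `entry_id` column or
#'   derived from `site_id`.
#' @return Data frame with one row per element plus a `Total` row: columns
#'   `element`, `n_entries`, `n_sites`, `n_pass_resolution`,
#'   `n_pass_occupancy`, `n_pass_symmetry`, `n_pass_discrepancy`,
#'   `n_pass_all` and matching `pct_*` integer percentages.
#' @export
tabulate_by_element <- function(records) {
  stopifnot(nrow(records) > 0)
  entry_id <- if ("entry_id" %in% names(records)) records$entry_id
              else parse_site_id(records$site_id)$pdb_id
  crits <- c("pass_resolution", "pass_occupancy", "pass_symmetry",
             "pass_discrepancy", "pass_all")
  one <- function(el) {
    r <- records[records$element == el, , drop = FALSE]
    counts <- vapply(crits, function(cn) sum(r[[cn]] %in% TRUE), integer(1))
    data.frame(
      element = el,
      n_entries = length(unique(entry_id[records$element == el])),
      n_sites = nrow(r),
      n_pass_resolution = counts[1], n_pass_occupancy = counts[2],
      n_pass_symmetry = counts[3], n_pass_discrepancy = counts[4],
      n_pass_all = counts[5],
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(unique(records$element), one))
  tab <- tab[order(-tab$n_entries, -tab$n_sites, tab$element), , drop = FALSE]
  total <- data.frame(
    element = "Total",
    n_entries = length(unique(entry_id)),
    n_sites = sum(tab$n_sites),
    n_pass_resolution = sum(tab$n_pass_resolution),
    n_pass_occupancy = sum(tab$n_pass_occupancy),
    n_pass_symmetry = sum(tab$n_pass_symmetry),
    n_pass_discrepancy = sum(tab$n_pass_discrepancy),
    n_pass_all = sum(tab$n_pass_all),
    stringsAsFactors = FALSE)
  tab <- rbind(tab, total)
  pct_cols <- c(pct_resolution = "n_pass_resolution",
                pct_occupancy = "n_pass_occupancy",
                pct_symmetry = "n_pass_symmetry",
                pct_discrepancy = "n_pass_discrepancy",
                pct_all = "n_pass_all")
  for (pn in names(pct_cols))
    tab[[pn]] <- integer_percent(tab[[pct_cols[[pn]]]], tab$n_sites)
  rownames(tab) <- NULL
  tab
}

#' Format the element table as tab-separated text
#'
#' Criterion cells are rendered as `count(pct%)`, mirroring the published
#' tabulation layout.
#'
#' @param tab Output of [tabulate_by_element()].
#' @return Character vector of TSV lines (header first).
#' @export
format_element_table <- function(tab) {
  cellify <- function(n, p) sprintf("%d(%d%%)", n, p)
  header <- paste(c("element", "n_entries", "n_sites", "resolution",
                    "occupancy", "symmetry", "discrepancy", "pass_all"),
                  collapse = "\t")
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    paste(c(tab$element[i], tab$n_entries[i], tab$n_sites[i],
            cellify(tab$n_pass_resolution[i], tab$pct_resolution[i]),
            cellify(tab$n_pass_occupancy[i], tab$pct_occupancy[i]),
            cellify(tab$n_pass_symmetry[i], tab$pct_symmetry[i]),
            cellify(tab$n_pass_discrepancy[i], tab$pct_discrepancy[i]),
            cellify(tab$n_pass_all[i], tab$pct_all[i])),
          collapse = "\t")
  }, "")
  c(header, rows)
}
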