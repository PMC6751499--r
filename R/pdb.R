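#' Parse a legacy PDB-format entry
#'
#' Reads the fixed-column records needed for regional metal-site quality
#' control: CRYST1 (unit cell), REMARK 2 (resolution), REMARK 290 SMTRY
#' (crystallographic symmetry operators, Cartesian convention), EXPDTA, and
#' ATOM/HETATM coordinates. Hydrogen atoms are dropped; only the first MODEL
#' is read; records after END are ignored.
#'
#' @param text The entry as a single string or a character vector of lines.
#' @return An object of class `structure_entry`: a list with `pdb_id`,
#'   `resolution` (Angstrom, `NA` if the entry declares none), `method`,
#'   `cell` ([unit_cell]), `operators` (list of [sym_op]; identity-only if
#'   the entry carries no SMTRY records), and `atoms` (data frame with
#'   columns serial, name, alt_loc, res_name, chain, res_no, i_code,
#'   x, y, z, occ, b, element, record).
#' @seealso [read_pdb_entry()] to read from a file, [write_pdb_entry()] for
#'   the round-trip writer, [extract_metal_sites()].
#' @export
parse_pdb_entry <- function(text) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("\r$", "", text)

  rec <- function(l) trimws(substr(l, 1, 6))
  recs <- vapply(lines, rec, "", USE.NAMES = FALSE)

  # records after END are ignored
  iend <- which(recs == "END")
  if (length(iend) > 0) {
    lines <- lines[seq_len(iend[1] - 1)]
    recs <- recs[seq_len(iend[1] - 1)]
  }

  pdb_id <- "XXXX"
  ih <- which(recs == "HEADER")
  if (length(ih) > 0) {
    id <- trimws(substr(lines[ih[1]], 63, 66))
    if (nchar(id) == 4) pdb_id <- id
  }

  method <- NA_character_
  ie <- which(recs == "EXPDTA")
  if (length(ie) > 0) method <- trimws(substr(lines[ie[1]], 11, 79))

  resolution <- NA_real_
  ir <- grep("^REMARK   2 RESOLUTION\\.", lines)
  if (length(ir) > 0) {
    m <- regmatches(lines[ir[1]],
                    regexpr("[0-9]+\\.?[0-9]*(?=[[:space:]]*ANGSTROM)",
                            lines[ir[1]], perl = TRUE))
    if (length(m) == 1) resolution <- as.numeric(m)
  }

  ic <- which(recs == "CRYST1")
  if (length(ic) == 0)
    stop("malformed entry: no CRYST1 record")
  cl <- lines[ic[1]]
  cell <- unit_cell(
    a = as.numeric(substr(cl, 7, 15)),
    b = as.numeric(substr(cl, 16, 24)),
    c = as.numeric(substr(cl, 25, 33)),
    alpha = as.numeric(substr(cl, 34, 40)),
    beta = as.numeric(substr(cl, 41, 47)),
    gamma = as.numeric(substr(cl, 48, 54))
  )

  operators <- .parse_smtry(lines)
  if (length(operators) == 0) operators <- list(identity_op())

  atoms <- .parse_atoms(lines, recs)

  structure(list(
    pdb_id = pdb_id,
    resolution = resolution,
    method = method,
    cell = cell,
    operators = operators,
    atoms = atoms
  ), class = "structure_entry")
}

# REMARK 290   SMTRY1   1  1.000000  0.000000  0.000000        0.00000
.parse_smtry <- function(lines) {
  sm <- grep("^REMARK 290[[:space:]]+SMTRY[123]", lines, value = TRUE)
  if (length(sm) == 0) return(list())
  row_no <- as.integer(substr(sm, 19, 19))
  fields <- lapply(strsplit(trimws(substring(sm, 20)), "[[:space:]]+"),
                   as.numeric)
  bad <- vapply(fields, function(f) length(f) != 5 || any(!is.finite(f)),
                logical(1))
  if (any(bad))
    stop("malformed symmetry: unparsable SMTRY row: ", sm[which(bad)[1]])
  op_no <- vapply(fields, function(f) as.integer(f[1]), integer(1))
  ops <- list()
  for (k in sort(unique(op_no))) {
    sel <- which(op_no == k)
    if (!setequal(row_no[sel], 1:3))
      stop(sprintf("malformed symmetry: SMTRY triplet for operator %d incomplete", k))
    R <- matrix(0, 3, 3)
    t <- numeric(3)
    for (i in sel) {
      r <- row_no[i]
      R[r, ] <- fields[[i]][2:4]
      t[r] <- fields[[i]][5]
    }
    ops[[length(ops) + 1]] <- sym_op(R, t)
  }
  ops
}

.parse_atoms <- function(lines, recs) {
  is_atom <- recs %in% c("ATOM", "HETATM")
  # only the first model: drop atom records after the first ENDMDL
  iem <- which(recs == "ENDMDL")
  if (length(iem) > 0) is_atom[seq_along(recs) > iem[1]] <- FALSE
  al <- lines[is_atom]
  n <- length(al)
  empty <- data.frame(
    serial = integer(0), name = character(0), alt_loc = character(0),
    res_name = character(0), chain = character(0), res_no = integer(0),
    i_code = character(0), x = numeric(0), y = numeric(0), z = numeric(0),
    occ = numeric(0), b = numeric(0), element = character(0),
    record = character(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)

  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(al, from, to)))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("malformed atom record (%s): %s", what, al[i]))
    }
    v
  }
  x <- num(31, 38, "x coordinate")
  y <- num(39, 46, "y coordinate")
  z <- num(47, 54, "z coordinate")
  occ <- suppressWarnings(as.numeric(substr(al, 55, 60)))
  occ[is.na(occ)] <- 1
  b <- suppressWarnings(as.numeric(substr(al, 61, 66)))
  b[is.na(b)] <- 0

  name <- trimws(substr(al, 13, 16))
  element <- .normalize_element(substr(al, 77, 78))
  # element column occasionally blank in older entries: fall back to the
  # atom-name field stripped of digits and primes
  blank <- element == ""
  if (any(blank))
    element[blank] <- .normalize_element(gsub("[0-9']", "", name[blank]))

  atoms <- data.frame(
    serial = as.integer(num(7, 11, "serial")),
    name = name,
    alt_loc = trimws(substr(al, 17, 17)),
    res_name = trimws(substr(al, 18, 20)),
    chain = trimws(substr(al, 22, 22)),
    res_no = as.integer(num(23, 26, "residue number")),
    i_code = trimws(substr(al, 27, 27)),
    x = x, y = y, z = z, occ = occ, b = b,
    element = element,
    record = trimws(substr(al, 1, 6)),
    stringsAsFactors = FALSE)
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Read a PDB entry from a file
#' @param path Path to a `.pdb`/`.ent` file.
#' @return A `structure_entry`; see [parse_pdb_entry()].
#' @export
read_pdb_entry <- function(path) parse_pdb_entry(readLines(path, warn = FALSE))

#' Write a structure entry back to PDB text
#'
#' Emits HEADER, EXPDTA, REMARK 2, REMARK 290 SMTRY, CRYST1 and
#' ATOM/HETATM records at fixed columns so that re-parsing yields identical
#' cell, operators and atom fields.
#'
#' @param entry A `structure_entry`.
#' @param path Optional file path; if `NULL`, the lines are returned.
#' @return Character vector of PDB lines, invisibly if written to `path`.
#' @export
write_pdb_entry <- function(entry, path = NULL) {
  stopifnot(inherits(entry, "structure_entry"))
  out <- character(0)
  out <- c(out, sprintf("%-62s%4s", "HEADER    METAL SITE QC", entry$pdb_id))
  if (!is.na(entry$method))
    out <- c(out, sprintf("EXPDTA    %s", entry$method))
  if (!is.na(entry$resolution))
    out <- c(out, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                          entry$resolution))
  else
    out <- c(out, "REMARK   2 RESOLUTION. NOT APPLICABLE.")
  for (k in seq_along(entry$operators)) {
    op <- entry$operators[[k]]
    for (r in 1:3)
      out <- c(out, sprintf(
        "REMARK 290   SMTRY%d %3d%10.6f%10.6f%10.6f%15.5f",
        r, k, op$rotation[r, 1], op$rotation[r, 2], op$rotation[r, 3],
        op$translation[r]))
  }
  cl <- entry$cell
  out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                        cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma))
  a <- entry$atoms
  for (i in seq_len(nrow(a))) {
    nm <- a$name[i]
    if (nchar(nm) < 4 && nchar(a$element[i]) < 2) nm <- paste0(" ", nm)
    out <- c(out, sprintf(
      "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$record[i], a$serial[i], nm, a$alt_loc[i], a$res_name[i], a$chain[i],
      a$res_no[i], a$i_code[i], a$x[i], a$y[i], a$z[i], a$occ[i], a$b[i],
      toupper(a$element[i])))
  }
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Identify metal ion sites in an entry
#'
#' Returns one site per ATOM/HETATM record whose element (column 77-78)
#' belongs to the metal set; alternate-location duplicates yield separate
#' sites. Discrimination is by element, so a calcium ion (element CA) is a
#' site while an alpha-carbon (atom name CA, element C) is not.
#'
#' @param entry A `structure_entry`.
#' @param metals Character vector of element symbols;
#'   defaults to [default_metal_elements()].
#' @return Data frame with one row per metal site: `site_id`, `element`,
#'   `chain`, `res_no`, `alt_loc`, `x`, `y`, `z`, `occupancy`, `atom_index`
#'   (row in `entry$atoms`), in file order.
#' @export
extract_metal_sites <- function(entry, metals = default_metal_elements()) {
  stopifnot(inherits(entry, "structure_entry"), length(metals) > 0)
  a <- entry$atoms
  sel <- which(a$element %in% metals)
  data.frame(
    site_id = site_id(entry$pdb_id, a$chain[sel], a$res_no[sel],
                      a$element[sel]),
    element = a$element[sel],
    chain = a$chain[sel],
    res_no = a$res_no[sel],
    alt_loc = a$alt_loc[sel],
    x = a$x[sel], y = a$y[sel], z = a$z[sel],
    occupancy = a$occ[sel],
    atom_index = sel,
    stringsAsFactors = FALSE)
}

#' Metal site identifier
#'
#' Builds the dotted identifier `PDBID.chain.residue_number.ELEMENT`
#' (element upper-cased), e.g. `"5FVN.F.405.CA"`.
#'
#' @param pdb_id Entry identifier.
#' @param chain Chain identifier.
#' @param res_no Residue number.
#' @param element Element symbol.
#' @return Character vector of identifiers.
#' @export
site_id <- function(pdb_id, chain, res_no, element) {
  if (length(chain) == 0) return(character(0))
  sprintf("%s.%s.%d.%s", pdb_id, chain, as.integer(res_no), toupper(element))
}

#' Parse a metal site identifier
#' @param id Identifier as produced by [site_id()].
#' @return Data frame with columns `pdb_id`, `chain`, `res_no`, `element`.
#' @export
parse_site_id <- function(id) {
  parts <- strsplit(id, ".", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 4
  if (any(bad)) stop("malformed site identifier: ", id[which(bad)[1]])
  data.frame(
    pdb_id = vapply(parts, `[`, "", 1),
    chain = vapply(parts, `[`, "", 2),
    res_no = as.integer(vapply(parts, `[`, "", 3)),
    element = .normalize_element(vapply(parts, `[`, "", 4)),
    stringsAsFactors = FALSE)
}

#' @export
print.structure_entry <- function(x, ...) {
  cat(sprintf("PDB entry %s: %d atoms, %d symmetry operators, resolution %s A\n",
              x$pdb_id, nrow(x$atoms), length(x$operators),
              ifelse(is.na(x$resolution), "n/a",
                     format(x$resolution, nsmall = 2))))
  print(x$cell)
  invisible(x)
}
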