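#' Read a PDB file into a structure
#'
#' Parses fixed-column ATOM (and optionally HETATM) records into an ordered
#' atom table.  Only the first MODEL of a multi-model file is read, and only
#' the first alternate-location conformer (altloc blank or `"A"`) is kept.
#' By default hydrogen/deuterium atoms and HETATM records are excluded, the
#' conventional setup for SASA calculations.
#'
#' Hydrogens are detected from the element columns (77-78) when present;
#' otherwise the first character of the atom name after stripping leading
#' digits is used, which handles legacy files such as names like `"1HB"`.
#'
#' @param input a file path, a connection (e.g. `stdin()`), or a character
#'   vector of PDB lines.
#' @param include_hydrogens keep hydrogen/deuterium atoms? Default `FALSE`.
#' @param include_hetatm keep HETATM records? Default `FALSE`.
#' @param source_label label recorded in the structure (defaults to the file
#'   name, or `"<text>"` for in-memory input).
#' @return An object of class `"sasa_structure"`: a list with
#'   \describe{
#'     \item{atoms}{data.frame with columns `serial`, `name`, `residue_name`,
#'       `residue_number`, `insertion_code`, `chain_id`, `element`, `x`, `y`,
#'       `z`, `is_hetatm`, `radius` (NA until assigned), `polarity` (NA until
#'       assigned), in file order.}
#'     \item{chain_ids}{distinct chain identifiers in first-appearance order.}
#'     \item{source_label}{provenance string.}
#'   }
#' @export
#' @examples
#' pdb <- c(
#'  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
#'  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C")
#' s <- read_pdb(pdb)
#' nrow(s$atoms)
read_pdb <- function(input, include_hydrogens = FALSE, include_hetatm = FALSE,
                     source_label = NULL) {
  if (inherits(input, "connection")) {
    lines <- readLines(input, warn = FALSE)
    if (is.null(source_label)) source_label <- "<connection>"
  } else if (is.character(input) && length(input) == 1L &&
             !grepl("\n", input, fixed = TRUE) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
    if (is.null(source_label)) source_label <- basename(input)
  } else if (is.character(input)) {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(source_label)) source_label <- "<text>"
  } else {
    stop("input must be a file path, connection, or character vector",
         call. = FALSE)
  }
  if (!length(lines))
    stop(no_atoms_error("empty PDB input"))

  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  "
  is_het <- rec == "HETATM"
  # first model only: drop records after the first ENDMDL or second MODEL
  model_starts <- which(rec == "MODEL ")
  endmdl <- which(rec == "ENDMDL")
  last <- length(lines)
  if (length(endmdl)) last <- min(last, endmdl[1] - 1L)
  if (length(model_starts) > 1L) last <- min(last, model_starts[2] - 1L)
  keep <- (is_atom | is_het) & seq_along(lines) <= last
  idx <- which(keep)
  if (!length(idx))
    stop(no_atoms_error(sprintf("no atoms read from %s", source_label)))

  ln <- lines[idx]
  field <- function(a, b) substr(ln, a, b)
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v))
    if (length(bad))
      stop(parse_error(sprintf("line %d: malformed %s field in PDB record",
                               idx[bad[1]], what)))
    v
  }
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(field(7, 11))),
    name = trimws(field(13, 16)),
    altloc = field(17, 17),
    residue_name = trimws(field(18, 20)),
    chain_id = field(22, 22),
    residue_number = suppressWarnings(as.integer(field(23, 26))),
    insertion_code = trimws(field(27, 27)),
    x = num(field(31, 38), "x-coordinate"),
    y = num(field(39, 46), "y-coordinate"),
    z = num(field(47, 54), "z-coordinate"),
    element = toupper(trimws(field(77, 78))),
    is_hetatm = is_het[idx],
    stringsAsFactors = FALSE
  )
  bad_res <- which(is.na(atoms$residue_number))[1]
  if (!is.na(bad_res))
    stop(parse_error(sprintf("line %d: malformed residue number", idx[bad_res])))
  atoms$serial[is.na(atoms$serial)] <- seq_len(nrow(atoms))[is.na(atoms$serial)]

  # element inference for legacy files lacking columns 77-78
  miss <- atoms$element == ""
  if (any(miss))
    atoms$element[miss] <- infer_element(atoms$name[miss])

  keep_row <- atoms$altloc %in% c(" ", "", "A")
  if (!include_hydrogens) keep_row <- keep_row & !(atoms$element %in% c("H", "D"))
  if (!include_hetatm) keep_row <- keep_row & !atoms$is_hetatm
  atoms <- atoms[keep_row, , drop = FALSE]
  if (!nrow(atoms))
    stop(no_atoms_error(sprintf("no atoms accepted from %s", source_label)))
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  atoms$radius <- NA_real_
  atoms$polarity <- NA_character_

  structure(list(atoms = atoms,
                 chain_ids = unique(atoms$chain_id),
                 source_label = source_label),
            class = "sasa_structure")
}

# leading-character heuristic: strip digits, first letter; two-letter
# element only when the full 4-char name starts at column 13 with a letter
# pair that is a known element (e.g. "FE", "SE") -- here kept simple:
# digit-stripped first character, with H/D recognized as hydrogen.
infer_element <- function(name) {
  stripped <- sub("^[0-9]+", "", name)
  first <- toupper(substr(stripped, 1, 1))
  two <- toupper(substr(stripped, 1, 2))
  ifelse(two %in% c("SE", "CL", "BR", "FE", "ZN", "MG", "NA", "MN") &
           nchar(name) >= 2 & !grepl("^[0-9]", name) & two != "CA",
         two, first)
}

no_atoms_error <- function(msg) {
  errorCondition(msg, class = c("sasar_no_atoms_error", "sasar_error"))
}
parse_error <- function(msg) {
  errorCondition(msg, class = c("sasar_parse_error", "sasar_error"))
}

#' Write a structure as PDB with SASA in the temperature-factor column
#'
#' Emits one ATOM/HETATM record per atom, preserving identity columns and
#' coordinates; the occupancy column carries the assigned atomic radius and
#' the temperature-factor (B) column the per-atom SASA, both in the standard
#' fixed-width `%6.2f` PDB format.
#'
#' @param structure a `"sasa_structure"`.
#' @param result the matching `"sasa_result"` from [calc_sasa()].
#' @param file a file path, connection, or `""` for standard output.
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_pdb_sasa <- function(structure, result, file = "") {
  a <- structure$atoms
  area <- result$per_atom_area
  if (length(area) != nrow(a))
    stop("result does not match structure: expected one area per atom",
         call. = FALSE)
  radius <- a$radius
  radius[is.na(radius)] <- 0
  lines <- sprintf("%-6s%5d %s %3s%2s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(a$is_hetatm, "HETATM", "ATOM"),
                   a$serial %% 100000L,
                   format_atom_name(a$name),
                   a$residue_name,
                   paste0(" ", a$chain_id),
                   a$residue_number %% 10000L,
                   a$insertion_code,
                   a$x, a$y, a$z,
                   radius, area,
                   a$element)
  if (is.character(file) && file == "") {
    cat(lines, sep = "\n")
  } else {
    writeLines(lines, file)
  }
  invisible(lines)
}

# PDB atom-name alignment: names of up to 3 characters start in column 14,
# 4-character names occupy columns 13-16
format_atom_name <- function(name) {
  ifelse(nchar(name) >= 4, sprintf("%-4s", name), sprintf(" %-3s", name))
}

#' @export
print.sasa_structure <- function(x, ...) {
  cat(sprintf("SASA structure '%s': %d atoms, chains %s\n",
              x$source_label, nrow(x$atoms), paste(x$chain_ids, collapse = "")))
  if (all(is.na(x$atoms$radius))) {
    cat("  radii: unassigned (run assign_radii())\n")
  } else {
    cat(sprintf("  radii: assigned, range [%.2f, %.2f] A\n",
                min(x$atoms$radius, na.rm = TRUE),
                max(x$atoms$radius, na.rm = TRUE)))
  }
  invisible(x)
}

#' Keep only the named chains of a structure
#'
#' @param structure a `"sasa_structure"`.
#' @param chains character vector of chain identifiers to keep.
#' @return A `"sasa_structure"` containing only atoms of those chains, in
#'   the original order.
#' @export
subset_chains <- function(structure, chains) {
  bad <- setdiff(chains, structure$chain_ids)
  if (length(bad))
    stop(sprintf("unknown chain(s) %s; structure has chains %s",
                 paste(bad, collapse = ","),
                 paste(structure$chain_ids, collapse = ",")), call. = FALSE)
  atoms <- structure$atoms[structure$atoms$chain_id %in% chains, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, chain_ids = unique(atoms$chain_id),
                 source_label = structure$source_label),
            class = "sasa_structure")
}
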