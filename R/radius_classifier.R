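# van der Waals radii of the main-group elements (Mantina et al. 2009),
# used as fallback for atoms not covered by a classifier's residue/atom map.
.vdw_main_group <- c(
  H = 1.10, D = 1.10, HE = 1.40,
  LI = 1.81, BE = 1.53, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  NE = 1.54, "NA" = 2.27, MG = 1.73, AL = 1.84, SI = 2.10, P = 1.80, S = 1.80,
  CL = 1.75, AR = 1.88, K = 2.75, CA = 2.31, GA = 1.87, GE = 2.11, AS = 1.85,
  SE = 1.90, BR = 1.83, KR = 2.02, RB = 3.03, SR = 2.49, IN = 1.93,
  SN = 2.17, SB = 2.06, TE = 2.06, I = 1.98, XE = 2.16, CS = 3.43,
  BA = 2.68, TL = 1.96, PB = 2.02, BI = 2.07, PO = 1.97, AT = 2.02,
  RN = 2.20, FR = 3.48, RA = 2.83)

.classifier_cache <- new.env(parent = emptyenv())

#' Parse a classifier configuration file
#'
#' The format has two sections.  `types:` declares atom classes, one per
#' line, as `class_name radius polarity` (radius in Angstrom, polarity
#' `polar` or `apolar`).  `atoms:` maps atoms to classes, one per line, as
#' `residue_name atom_name class_name`.  `#` starts a comment; blank lines
#' are ignored; residue and atom names are matched case-insensitively.
#' Duplicate (residue, atom) keys keep the last entry, with a warning.
#'
#' @param input a file path, connection, or character vector of config lines.
#' @param name label for the classifier (defaults to the file name).
#' @return An object of class `"sasa_classifier"`: a list with
#'   `residue_atom_map` (named list keyed `"RES|ATOM"`, each entry a list
#'   with `class_name`, `radius`, `polarity`), `element_fallback` (named
#'   numeric vector of vdW radii) and `name`.
#' @export
parse_classifier_config <- function(input, name = NULL) {
  if (inherits(input, "connection")) {
    lines <- readLines(input, warn = FALSE)
    if (is.null(name)) name <- "config"
  } else if (is.character(input) && length(input) == 1L &&
             !grepl("\n", input, fixed = TRUE) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
    if (is.null(name)) name <- sub("\\.config$", "", basename(input))
  } else {
    lines <- unlist(strsplit(as.character(input), "\n", fixed = TRUE))
    if (is.null(name)) name <- "config"
  }
  types <- list()
  map <- list()
  section <- ""
  for (k in seq_along(lines)) {
    line <- sub("#.*$", "", lines[k])
    line <- trimws(line)
    if (!nzchar(line)) next
    low <- tolower(line)
    if (low == "types:") { section <- "types"; next }
    if (low == "atoms:") { section <- "atoms"; next }
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (section == "types") {
      if (length(tok) != 3)
        stop(parse_error(sprintf(
          "line %d: expected 'class radius polarity', got '%s'", k, line)))
      r <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(r))
        stop(parse_error(sprintf("line %d: radius '%s' is not a number", k, tok[2])))
      if (r <= 0)
        stop(parse_error(sprintf("line %d: radius must be positive, got %s", k, tok[2])))
      pol <- tolower(tok[3])
      if (!pol %in% c("polar", "apolar"))
        stop(parse_error(sprintf(
          "line %d: polarity must be 'polar' or 'apolar', got '%s'", k, tok[3])))
      types[[toupper(tok[1])]] <- list(class_name = tok[1], radius = r,
                                       polarity = pol)
    } else if (section == "atoms") {
      if (length(tok) != 3)
        stop(parse_error(sprintf(
          "line %d: expected 'residue atom class', got '%s'", k, line)))
      cls <- types[[toupper(tok[3])]]
      if (is.null(cls))
        stop(parse_error(sprintf(
          "line %d: atom class '%s' has not been declared in the types section",
          k, tok[3])))
      key <- paste0(toupper(tok[1]), "|", toupper(tok[2]))
      if (!is.null(map[[key]]))
        warning(sprintf("duplicate entry for (%s, %s); last one wins",
                        tok[1], tok[2]), call. = FALSE)
      map[[key]] <- cls
    } else {
      stop(parse_error(sprintf(
        "line %d: content before a 'types:' or 'atoms:' section header", k)))
    }
  }
  structure(list(residue_atom_map = map,
                 element_fallback = .vdw_main_group,
                 name = name),
            class = "sasa_classifier")
}

#' Built-in ProtOr classifier
#'
#' Covers the 20 standard amino acids plus Sec (SEC), Pyl (PYL) and
#' selenomethionine (MSE), the standard ribo- and deoxyribonucleotides
#' (A, C, G, U, T, DA, DC, DG, DT), the acetyl and NH2 capping groups, and
#' water.  Carbon classes are 1.88/1.76/1.61 Angstrom (tetrahedral,
#' aromatic CH, trigonal bare), nitrogen 1.64, carbonyl/carboxyl oxygen
#' 1.42, hydroxyl oxygen 1.46, sulfur 1.77; phosphorus is assigned 1.8
#' Angstrom and selenium 1.9.  Atoms not covered fall back to the element's
#' van der Waals radius.
#'
#' @return A `"sasa_classifier"`.
#' @export
#' @examples
#' cl <- builtin_protor_classifier()
#' cl$residue_atom_map[["ALA|CA"]]$radius  # 1.88
builtin_protor_classifier <- function() {
  if (is.null(.classifier_cache$protor)) {
    path <- system.file("extdata", "protor.config", package = "sasar",
                        mustWork = TRUE)
    .classifier_cache$protor <- parse_classifier_config(path, name = "ProtOr")
  }
  .classifier_cache$protor
}

#' Built-in NACCESS-compatible classifier (protein subset)
#'
#' A protein-only radius set matching the NACCESS parameterization
#' (aliphatic C 1.87, aromatic/trigonal C 1.76, N 1.65, O 1.40, S 1.85).
#'
#' @return A `"sasa_classifier"`.
#' @export
builtin_naccess_classifier <- function() {
  if (is.null(.classifier_cache$naccess)) {
    path <- system.file("extdata", "naccess.config", package = "sasar",
                        mustWork = TRUE)
    .classifier_cache$naccess <- parse_classifier_config(path, name = "NACCESS")
  }
  .classifier_cache$naccess
}

# single (residue, atom) lookup; "*" in atom names is normalized to "'"
# so legacy nucleotide naming (C1*) matches
classifier_lookup <- function(classifier, residue_name, atom_name) {
  atom_name <- gsub("*", "'", toupper(atom_name), fixed = TRUE)
  classifier$residue_atom_map[[paste0(toupper(residue_name), "|", atom_name)]]
}

#' Assign radii and polarity classes to a structure's atoms
#'
#' Atoms found in the classifier's residue/atom map get that entry's radius
#' and polarity.  Unmatched atoms fall back to the van der Waals radius of
#' their element (carbon is counted apolar, all other elements polar) and
#' each fallback is reported through a warning.  Atoms whose element is not
#' in the fallback table either raise an error (default) or are dropped
#' with a warning (`unknown = "skip"`).
#'
#' @param structure a `"sasa_structure"` from [read_pdb()].
#' @param classifier a `"sasa_classifier"`; defaults to the ProtOr set.
#' @param unknown policy for atoms with unknown element: `"error"` or
#'   `"skip"`.
#' @return The structure with `radius` and `polarity` columns filled.
#' @export
assign_radii <- function(structure, classifier = builtin_protor_classifier(),
                         unknown = c("error", "skip")) {
  unknown <- match.arg(unknown)
  a <- structure$atoms
  n <- nrow(a)
  radius <- numeric(n)
  polarity <- character(n)
  drop <- logical(n)
  fallbacks <- character(0)
  for (i in seq_len(n)) {
    entry <- classifier_lookup(classifier, a$residue_name[i], a$name[i])
    if (!is.null(entry)) {
      radius[i] <- entry$radius
      polarity[i] <- entry$polarity
    } else {
      el <- toupper(a$element[i])
      r <- if (el %in% names(classifier$element_fallback))
        classifier$element_fallback[[el]] else NULL
      if (is.null(r) || is.na(r)) {
        msg <- sprintf("atom %s/%s %d/%s: element '%s' not in fallback table",
                       a$residue_name[i], a$name[i], a$residue_number[i],
                       a$chain_id[i], a$element[i])
        if (unknown == "error")
          stop(errorCondition(msg, class = c("sasar_unknown_element_error",
                                             "sasar_error")))
        warning(paste0(msg, "; atom skipped"), call. = FALSE)
        drop[i] <- TRUE
        next
      }
      radius[i] <- r
      polarity[i] <- if (el == "C") "apolar" else "polar"
      fallbacks <- c(fallbacks, sprintf("%s/%s (element %s, vdW %.2f A)",
                                        a$residue_name[i], a$name[i], el, r))
    }
  }
  if (length(fallbacks))
    warning(sprintf("%d atom(s) assigned element vdW fallback radii: %s",
                    length(fallbacks),
                    paste(unique(fallbacks), collapse = "; ")),
            call. = FALSE)
  a$radius <- radius
  a$polarity <- polarity
  if (any(drop)) {
    a <- a[!drop, , drop = FALSE]
    rownames(a) <- NULL
  }
  out <- structure
  out$atoms <- a
  out$chain_ids <- unique(a$chain_id)
  out
}

#' @export
print.sasa_classifier <- function(x, ...) {
  cat(sprintf("SASA classifier '%s': %d (residue, atom) entries, %d fallback elements\n",
              x$name, length(x$residue_atom_map), length(x$element_fallback)))
  invisible(x)
}
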