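#' Aggregate per-atom SASA into class, chain and residue totals
#'
#' Produces the totals a SASA log reports: overall, polar/apolar split (with
#' a separate `unknown` class for atoms whose polarity could not be
#' determined, so that the partition stays auditable), per chain, per
#' residue, and per residue type.  By construction
#' `polar + apolar + unknown = total` and chain/residue sums equal the
#' total up to floating-point accumulation.
#'
#' @param structure a `"sasa_structure"` with polarity assigned.
#' @param result the matching `"sasa_result"`.
#' @return An object of class `"sasa_report"`: a list with `total`,
#'   `polar`, `apolar`, `unknown`, `per_chain` (named numeric),
#'   `per_residue` (data.frame with `chain_id`, `residue_number`,
#'   `insertion_code`, `residue_name`, `area`), `per_residue_type` (named
#'   numeric), `parameters_used` and `source_label`.
#' @export
aggregate_sasa <- function(structure, result) {
  a <- structure$atoms
  area <- result$per_atom_area
  if (length(area) != nrow(a))
    stop("result does not match structure", call. = FALSE)
  pol <- a$polarity
  pol[is.na(pol) | !pol %in% c("polar", "apolar")] <- "unknown"
  per_chain <- vapply(structure$chain_ids,
                      function(ch) sum(area[a$chain_id == ch]), numeric(1))
  names(per_chain) <- structure$chain_ids
  key <- paste(a$chain_id, a$residue_number, a$insertion_code, sep = "|")
  first <- !duplicated(key)
  per_residue <- data.frame(
    chain_id = a$chain_id[first],
    residue_number = a$residue_number[first],
    insertion_code = a$insertion_code[first],
    residue_name = a$residue_name[first],
    area = as.numeric(tapply(area, factor(key, levels = key[first]), sum)),
    stringsAsFactors = FALSE)
  types <- sort(unique(a$residue_name))
  per_residue_type <- vapply(types,
                             function(t) sum(area[a$residue_name == t]),
                             numeric(1))
  structure(list(total = sum(area),
                 polar = sum(area[pol == "polar"]),
                 apolar = sum(area[pol == "apolar"]),
                 unknown = sum(area[pol == "unknown"]),
                 per_chain = per_chain,
                 per_residue = per_residue,
                 per_residue_type = per_residue_type,
                 parameters_used = result$parameters_used,
                 source_label = structure$source_label),
            class = "sasa_report")
}

#' Recalculate SASA for chain groups in isolation
#'
#' For each `+`-separated group of chain letters, a new structure containing
#' only those chains is built and the SASA fully recomputed (atoms of other
#' chains are removed, not merely hidden from reporting).  A chain's area in
#' isolation is at least its area within the full complex, so the difference
#' measures surface buried at the interface.
#'
#' @param structure a `"sasa_structure"` with radii assigned.
#' @param group_spec group specification such as `"ABCD+XY"`.
#' @param parameters a `"sasa_params"`.
#' @return Named list of `"sasa_report"` objects, one per group.
#' @export
chain_groups_sasa <- function(structure, group_spec,
                              parameters = sasa_params()) {
  groups <- strsplit(group_spec, "+", fixed = TRUE)[[1]]
  groups <- groups[nzchar(groups)]
  if (!length(groups)) stop("empty chain-group specification", call. = FALSE)
  letters_all <- unlist(strsplit(groups, ""))
  bad <- setdiff(letters_all, structure$chain_ids)
  if (length(bad))
    stop(sprintf("unknown chain(s) %s in group spec; valid chains: %s",
                 paste(bad, collapse = ","),
                 paste(structure$chain_ids, collapse = ",")), call. = FALSE)
  out <- lapply(groups, function(g) {
    sub <- subset_chains(structure, strsplit(g, "")[[1]])
    aggregate_sasa(sub, calc_sasa(sub, parameters))
  })
  names(out) <- groups
  out
}

#' @export
print.sasa_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

# RESULTS block in the classic log layout
format_report <- function(report, verbose = FALSE) {
  out <- c("RESULTS (A^2)",
           sprintf("Total   : %8.2f", report$total),
           sprintf("Apolar  : %8.2f", report$apolar),
           sprintf("Polar   : %8.2f", report$polar))
  if (report$unknown > 0)
    out <- c(out, sprintf("Unknown : %8.2f", report$unknown))
  if (length(report$per_chain) > 1)
    out <- c(out, sprintf("CHAIN %s : %8.2f", names(report$per_chain),
                          report$per_chain))
  if (verbose)
    out <- c(out, "", "RESIDUE TYPES (A^2)",
             sprintf("%-4s: %8.2f", names(report$per_residue_type),
                     report$per_residue_type))
  out
}

# full log: header, PARAMETERS, INPUT, RESULTS, optional SELECTIONS
format_log <- function(structure, report, selections = numeric(0),
                       verbose = FALSE) {
  p <- report$parameters_used
  out <- c(sprintf("## sasar %s ##",
                   as.character(utils::packageVersion("sasar"))),
           "",
           "PARAMETERS",
           sprintf("algorithm    : %s", algorithm_label(p$algorithm)),
           sprintf("probe-radius : %.3f", p$probe_radius),
           sprintf("threads      : %d", p$n_workers))
  out <- c(out,
           if (p$algorithm == "lee_richards")
             sprintf("slices       : %d", p$n_slices)
           else sprintf("points       : %d", p$n_points),
           "",
           "INPUT",
           sprintf("source  : %s", report$source_label),
           sprintf("chains  : %s", paste(structure$chain_ids, collapse = "")),
           sprintf("atoms   : %d", nrow(structure$atoms)),
           "",
           format_report(report, verbose = verbose))
  if (length(selections))
    out <- c(out, "", "SELECTIONS",
             sprintf("%s : %10.2f", names(selections), selections))
  out
}

#' Write per-residue areas as tab-separated values
#'
#' @param report a `"sasa_report"`.
#' @param file path, connection, or `""` for standard output.
#' @return Invisibly, the per-residue data.frame.
#' @export
write_residue_tsv <- function(report, file = "") {
  utils::write.table(report$per_residue, file = file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(report$per_residue)
}

#' One-call SASA pipeline for a PDB file
#'
#' Convenience wrapper: [read_pdb()], [assign_radii()], [calc_sasa()] and
#' [aggregate_sasa()] in sequence.
#'
#' @inheritParams read_pdb
#' @param parameters a `"sasa_params"`.
#' @param classifier a `"sasa_classifier"`.
#' @return A list with `structure`, `result` and `report`.
#' @export
sasa_pdb <- function(input, parameters = sasa_params(),
                     classifier = builtin_protor_classifier(),
                     include_hydrogens = FALSE, include_hetatm = FALSE) {
  s <- read_pdb(input, include_hydrogens = include_hydrogens,
                include_hetatm = include_hetatm)
  s <- assign_radii(s, classifier)
  r <- calc_sasa(s, parameters)
  list(structure = s, result = r, report = aggregate_sasa(s, r))
}
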