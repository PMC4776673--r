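#' Parse an atom selection
#'
#' Selections use a subset of the Pymol selection syntax:
#' `"<label>, <expression>"`.  Supported primitives are `resn` (residue
#' name), `resi` (residue number, with `-` ranges and optional insertion
#' codes, e.g. `1-10` or `10A`), `chain`, `name` (atom name) and `symbol`
#' (element).  Values can be `+`-separated lists, which bind tighter than
#' the boolean operators `not`, `and`, `or` (in decreasing precedence);
#' parentheses are allowed.  Keywords are case-insensitive.
#'
#' @param text a selection string, e.g. `"RNA, resn A+U+G+C"`.
#' @return An object of class `"selection_expr"`: a list with `name` (the
#'   label) and `tree` (the parsed boolean expression).
#' @export
#' @examples
#' sel <- parse_selection("RNA, resn A+U+G+C")
#' sel$name
parse_selection <- function(text) {
  if (length(text) != 1L || !is.character(text))
    stop(selection_error("selection must be a single string"))
  comma <- regexpr(",", text, fixed = TRUE)
  if (comma < 0)
    stop(selection_error(
      "selection must have the form '<label>, <expression>' (missing comma)"))
  label <- trimws(substr(text, 1, comma - 1))
  expr <- trimws(substr(text, comma + 1, nchar(text)))
  if (!nzchar(label)) stop(selection_error("empty selection label"))
  if (!nzchar(expr)) stop(selection_error("empty selection expression"))
  tokens <- tokenize_selection(expr)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$pos <- 1L
  tree <- parse_or(st)
  if (st$pos <= length(st$tokens))
    stop(selection_error(sprintf("unexpected token '%s'", st$tokens[st$pos])))
  structure(list(name = label, tree = tree), class = "selection_expr")
}

selection_error <- function(msg) {
  errorCondition(paste0("selection syntax error: ", msg),
                 class = c("sasar_selection_error", "sasar_error"))
}

tokenize_selection <- function(expr) {
  expr <- gsub("(", " ( ", expr, fixed = TRUE)
  expr <- gsub(")", " ) ", expr, fixed = TRUE)
  tok <- strsplit(trimws(expr), "[[:space:]]+")[[1]]
  tok[nzchar(tok)]
}

peek <- function(st) if (st$pos <= length(st$tokens)) st$tokens[st$pos] else NULL
advance <- function(st) { t <- peek(st); st$pos <- st$pos + 1L; t }

parse_or <- function(st) {
  left <- parse_and(st)
  while (!is.null(peek(st)) && tolower(peek(st)) == "or") {
    advance(st)
    left <- list(op = "or", left = left, right = parse_and(st))
  }
  left
}

parse_and <- function(st) {
  left <- parse_not(st)
  while (!is.null(peek(st)) && tolower(peek(st)) == "and") {
    advance(st)
    left <- list(op = "and", left = left, right = parse_not(st))
  }
  left
}

parse_not <- function(st) {
  if (!is.null(peek(st)) && tolower(peek(st)) == "not") {
    advance(st)
    return(list(op = "not", operand = parse_not(st)))
  }
  parse_primary(st)
}

parse_primary <- function(st) {
  t <- peek(st)
  if (is.null(t)) stop(selection_error("unexpected end of expression"))
  if (t == "(") {
    advance(st)
    inner <- parse_or(st)
    if (is.null(peek(st)) || peek(st) != ")")
      stop(selection_error("missing closing parenthesis"))
    advance(st)
    return(inner)
  }
  kw <- tolower(t)
  if (!kw %in% c("resn", "resi", "chain", "name", "symbol"))
    stop(selection_error(sprintf("unknown keyword '%s'", t)))
  advance(st)
  v <- peek(st)
  if (is.null(v) || v %in% c("(", ")") ||
      tolower(v) %in% c("and", "or", "not"))
    stop(selection_error(sprintf("keyword '%s' needs a value list", t)))
  advance(st)
  values <- toupper(strsplit(v, "+", fixed = TRUE)[[1]])
  values <- values[nzchar(values)]
  if (!length(values))
    stop(selection_error(sprintf("empty value list after '%s'", t)))
  list(op = "primitive", keyword = kw, values = values)
}

# logical mask of atoms matched by a parsed tree
selection_mask <- function(tree, atoms) {
  switch(tree$op,
    or = selection_mask(tree$left, atoms) | selection_mask(tree$right, atoms),
    and = selection_mask(tree$left, atoms) & selection_mask(tree$right, atoms),
    not = !selection_mask(tree$operand, atoms),
    primitive = primitive_mask(tree, atoms),
    stop("internal error: unknown selection node"))
}

primitive_mask <- function(tree, atoms) {
  switch(tree$keyword,
    resn = toupper(atoms$residue_name) %in% tree$values,
    chain = toupper(atoms$chain_id) %in% tree$values,
    name = toupper(atoms$name) %in% tree$values,
    symbol = toupper(atoms$element) %in% tree$values,
    resi = resi_mask(tree$values, atoms))
}

# resi values: "12" (any insertion code), "12A" (that insertion code),
# "3-17" (inclusive numeric range)
resi_mask <- function(values, atoms) {
  mask <- rep(FALSE, nrow(atoms))
  for (v in values) {
    if (grepl("^-?[0-9]+--?[0-9]+$", v) && !grepl("^-?[0-9]+$", v)) {
      parts <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
      lo <- as.integer(parts[2]); hi <- as.integer(parts[3])
      mask <- mask | (atoms$residue_number >= lo & atoms$residue_number <= hi)
    } else if (grepl("^-?[0-9]+$", v)) {
      mask <- mask | (atoms$residue_number == as.integer(v))
    } else if (grepl("^-?[0-9]+[A-Z]$", v)) {
      num <- as.integer(sub("[A-Z]$", "", v))
      ic <- sub("^-?[0-9]+", "", v)
      mask <- mask | (atoms$residue_number == num &
                        toupper(atoms$insertion_code) == ic)
    } else {
      stop(selection_error(sprintf("cannot parse resi value '%s'", v)))
    }
  }
  mask
}

#' Evaluate a selection against a SASA result
#'
#' Sums the per-atom SASA over the atoms matched by the selection tree.
#' An empty match returns 0 with a warning.
#'
#' @param expr a `"selection_expr"` from [parse_selection()], or a
#'   selection string.
#' @param structure the `"sasa_structure"` the result was computed from.
#' @param result the matching `"sasa_result"`.
#' @return Named numeric scalar: the selection's area in Angstrom^2, named
#'   by the selection label.
#' @export
#' @examples
#' s <- assign_radii(read_pdb(poly_ala_pdb(3)))
#' r <- calc_sasa(s)
#' evaluate_selection("bb, name N+CA+C+O", s, r)
evaluate_selection <- function(expr, structure, result) {
  if (is.character(expr)) expr <- parse_selection(expr)
  if (length(result$per_atom_area) != nrow(structure$atoms))
    stop("result does not match structure", call. = FALSE)
  mask <- selection_mask(expr$tree, structure$atoms)
  if (!any(mask))
    warning(sprintf("selection '%s' matches no atoms", expr$name),
            call. = FALSE)
  stats::setNames(sum(result$per_atom_area[mask]), expr$name)
}

#' @export
print.selection_expr <- function(x, ...) {
  cat(sprintf("Selection '%s': %s\n", x$name, deparse_tree(x$tree)))
  invisible(x)
}

deparse_tree <- function(tree) {
  switch(tree$op,
    or = sprintf("(%s or %s)", deparse_tree(tree$left), deparse_tree(tree$right)),
    and = sprintf("(%s and %s)", deparse_tree(tree$left), deparse_tree(tree$right)),
    not = sprintf("(not %s)", deparse_tree(tree$operand)),
    primitive = sprintf("%s %s", tree$keyword,
                        paste(tree$values, collapse = "+")))
}
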