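#' Tag chains as receptor or ligand
#'
#' Adds a `component` column assigning every chain to `"receptor"` or
#' `"ligand"`. By default chains consisting entirely of `HETATM` records
#' are taken as the ligand and all others as the receptor; explicit chain
#' sets override the default and must be disjoint.
#'
#' @param atoms atom tibble.
#' @param ligand_chains,receptor_chains optional character vectors of
#'   chain identifiers.
#' @return the atom tibble with a `component` column.
#' @export
tag_components <- function(atoms, ligand_chains = NULL,
                           receptor_chains = NULL) {
  .assert_atoms(atoms)
  chains <- unique(atoms$chain_id)
  if (is.null(ligand_chains)) {
    if (!"record" %in% names(atoms)) {
      abort("no `record` column: supply `ligand_chains` explicitly")
    }
    ligand_chains <- chains[vapply(chains, function(ch) {
      all(atoms$record[atoms$chain_id == ch] == "HETATM")
    }, logical(1))]
  }
  if (is.null(receptor_chains)) {
    receptor_chains <- setdiff(chains, ligand_chains)
  }
  if (length(intersect(ligand_chains, receptor_chains)) > 0) {
    abort("ligand and receptor chain sets must be disjoint")
  }
  untagged <- setdiff(chains, c(ligand_chains, receptor_chains))
  if (length(untagged) > 0) {
    abort(sprintf("chains not assigned to a component: %s",
                  paste(untagged, collapse = ", ")))
  }
  if (length(ligand_chains) == 0) abort("no chain tagged as ligand")
  if (length(receptor_chains) == 0) abort("no chain tagged as receptor")
  atoms$component <- ifelse(atoms$chain_id %in% ligand_chains,
                            "ligand", "receptor")
  atoms
}

#' Split a tagged complex into receptor and ligand
#'
#' Coordinates are left untouched (single-trajectory convention): the
#' receptor and ligand substructures are the rows of the complex, so the
#' union of the parts reproduces the complex atom-for-atom.
#'
#' @param atoms atom tibble with a `component` column (see
#'   [tag_components()]); if absent, default tagging is attempted.
#' @return named list with `receptor` and `ligand` atom tibbles.
#' @export
split_complex <- function(atoms) {
  if (!"component" %in% names(atoms)) atoms <- tag_components(atoms)
  lig <- atoms[atoms$component == "ligand", , drop = FALSE]
  rec <- atoms[atoms$component == "receptor", , drop = FALSE]
  if (nrow(lig) == 0) abort("no chain tagged as ligand")
  if (nrow(rec) == 0) abort("no chain tagged as receptor")
  list(receptor = rec, ligand = lig)
}

#' Construct a residue numbering map
#'
#' Holds the correspondence between a reference numbering convention
#' (e.g. the Arabidopsis AHAS sequence in which field mutations are
#' reported) and the target protein's own numbering. The offset between
#' conventions is not constant, so lookups never extrapolate.
#'
#' @param reference,target integer vectors of paired positions, both
#'   strictly increasing.
#' @return a tibble of class `numbering_map`.
#' @export
numbering_map <- function(reference, target) {
  reference <- as.integer(reference)
  target <- as.integer(target)
  if (length(reference) != length(target)) {
    abort("reference and target must have equal length")
  }
  if (length(reference) == 0) abort("numbering map must be non-empty")
  if (is.unsorted(reference, strictly = TRUE) ||
      is.unsorted(target, strictly = TRUE)) {
    abort("numbering map columns must be strictly increasing")
  }
  structure(tibble(reference = reference, target = target),
            class = c("numbering_map", class(tibble())))
}

#' Read a numbering map from two-column text
#'
#' @param path whitespace-separated file with reference and target
#'   columns; a header line is detected and skipped.
#' @return a [numbering_map()].
#' @export
read_numbering_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.integer(strsplit(trimws(first),
                                                           "\\s+")[[1]][1])))
  df <- read.table(path, header = has_header)
  numbering_map(df[[1]], df[[2]])
}

#' Translate a residue position between numbering conventions
#'
#' @param map a [numbering_map()].
#' @param position integer position(s) to translate.
#' @param direction `"reference_to_target"` or `"target_to_reference"`.
#' @return integer vector of paired positions; unmapped positions are an
#'   error (the offset between conventions is not constant, so
#'   extrapolation is never attempted).
#' @export
map_residue_number <- function(map, position,
                               direction = c("reference_to_target",
                                             "target_to_reference")) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "numbering_map"))
  from <- if (direction == "reference_to_target") map$reference else map$target
  to <- if (direction == "reference_to_target") map$target else map$reference
  idx <- match(as.integer(position), from)
  if (anyNA(idx)) {
    abort(sprintf("position(s) not in numbering map: %s",
                  paste(position[is.na(idx)], collapse = ", ")))
  }
  to[idx]
}

AA_ONE_TO_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                     Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                     L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                     S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Parse a mutation specification string
#'
#' Accepts the field-convention strings used in resistance panels:
#' `"P197A"` for a single substitution and `"P197A+W574L"` for a double;
#' `"WT"`, `"None"`, `""` and `NA` denote the unmutated protein and
#' yield zero rows.
#'
#' @param spec a single mutation string.
#' @param scheme numbering scheme the positions are expressed in.
#' @return tibble with columns `from_aa`, `residue_number`, `to_aa`
#'   (three-letter codes) and `scheme`.
#' @export
parse_mutations <- function(spec, scheme = c("reference", "target")) {
  scheme <- match.arg(scheme)
  if (length(spec) != 1) abort("parse_mutations() takes a single string")
  if (is.na(spec) || toupper(spec) %in% c("", "WT", "NONE")) {
    return(tibble(from_aa = character(), residue_number = integer(),
                  to_aa = character(), scheme = character()))
  }
  parts <- strsplit(spec, "+", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", parts))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) {
    abort(sprintf("cannot parse mutation '%s'", parts[bad][1]))
  }
  one_from <- toupper(vapply(m, `[[`, character(1), 2))
  one_to <- toupper(vapply(m, `[[`, character(1), 4))
  unknown <- setdiff(c(one_from, one_to), names(AA_ONE_TO_THREE))
  if (length(unknown) > 0) {
    abort(sprintf("unknown amino-acid code: %s", paste(unknown, collapse = ", ")))
  }
  tibble(from_aa = unname(AA_ONE_TO_THREE[one_from]),
         residue_number = as.integer(vapply(m, `[[`, character(1), 3)),
         to_aa = unname(AA_ONE_TO_THREE[one_to]),
         scheme = scheme)
}
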