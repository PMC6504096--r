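#' Read a Lennard-Jones parameter table
#'
#' Columnar whitespace-separated text with columns `class`,
#' `r_min_half` (Angstrom) and `epsilon` (kcal/mol). Atom classes are
#' element symbols by default (`C`, `N`, `O`, `S`, `H`, `P`, plus the
#' generic halogen `X`); a structure may carry an explicit `atom_class`
#' column to use bespoke types.
#'
#' @param path path to the table file.
#' @return tibble of class parameters.
#' @export
read_lj_table <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("class", "r_min_half", "epsilon")
  if (!all(need %in% names(df))) {
    abort("LJ table must have columns: class, r_min_half, epsilon")
  }
  if (any(df$epsilon < 0)) abort("LJ epsilon must be >= 0")
  if (any(df$r_min_half <= 0)) abort("LJ r_min_half must be > 0")
  if (anyDuplicated(df$class)) abort("duplicate atom class in LJ table")
  as_tibble(df[need])
}

#' Bundled element-keyed Lennard-Jones parameters
#'
#' A simplified table with literature-typical well depths and minimum
#' distances keyed by element. Scores built on it are meaningful
#' comparatively (wild type versus mutants under one parameter set), not
#' as absolute force-field energies.
#'
#' @return tibble with columns `class`, `r_min_half`, `epsilon`.
#' @export
lj_default <- function() {
  if (!is.null(.rr_cache$lj)) return(.rr_cache$lj)
  path <- system.file("extdata", "lj_elements.tsv", package = "resistrank")
  tab <- read_lj_table(path)
  .rr_cache$lj <- tab
  tab
}

# resolve per-atom LJ classes; error naming any missing class
.lj_params <- function(atoms, lj_table) {
  cls <- if ("atom_class" %in% names(atoms)) atoms$atom_class
         else element_of(atoms$atom_name)
  idx <- match(cls, lj_table$class)
  if (anyNA(idx)) {
    abort(sprintf("atom class not in LJ table: %s",
                  paste(unique(cls[is.na(idx)]), collapse = ", ")))
  }
  list(r_min_half = lj_table$r_min_half[idx], epsilon = lj_table$epsilon[idx])
}
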