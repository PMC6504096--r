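#' Read a PQR structure file
#'
#' Parses whitespace-separated `ATOM`/`HETATM` records in the APBS PQR
#' dialect: record name, serial, atom name, residue name, optional chain
#' identifier, residue number, x, y, z (Angstrom), partial charge
#' (elementary charges) and radius (Angstrom) as the final two numeric
#' fields. `MODEL`/`ENDMDL` lines delimit the frames of an ensemble;
#' frames are returned stacked in one tibble with a `model` column
#' (1-based, in file order). `TER`, `REMARK` and `END` lines are ignored.
#'
#' @param path path to a PQR file, or a character vector of lines.
#' @return A tibble with one row per atom and columns `model`, `record`,
#'   `serial`, `atom_name`, `residue_name`, `chain_id`, `residue_number`,
#'   `x`, `y`, `z`, `charge`, `radius`.
#' @seealso [write_pqr()], [tag_components()]
#' @export
read_pqr <- function(path) {
  lines <- if (length(path) == 1 && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (length(lines) == 0) abort("empty PQR input")

  model <- 1L
  seen_model_line <- FALSE
  rows <- vector("list", length(lines))
  n_atoms <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "") next
    key <- toupper(tok[1])
    if (key == "MODEL") {
      if (seen_model_line) model <- model + 1L
      seen_model_line <- TRUE
      next
    }
    if (key %in% c("ENDMDL", "TER", "END") || key == "REMARK") next
    if (!key %in% c("ATOM", "HETATM")) next

    if (!length(tok) %in% c(10L, 11L)) {
      abort(sprintf("malformed PQR record on line %d: expected 10 or 11 fields, got %d",
                    ln, length(tok)))
    }
    has_chain <- length(tok) == 11L
    chain <- if (has_chain) tok[5] else "A"
    num_at <- if (has_chain) 6L else 5L
    nums <- suppressWarnings(as.numeric(tok[num_at:length(tok)]))
    serial <- suppressWarnings(as.integer(tok[2]))
    if (anyNA(nums) || is.na(serial)) {
      abort(sprintf("malformed PQR record on line %d: non-numeric field", ln))
    }
    n_atoms <- n_atoms + 1L
    rows[[n_atoms]] <- list(model = model, record = key, serial = serial,
                            atom_name = tok[3], residue_name = tok[4],
                            chain_id = chain,
                            residue_number = as.integer(nums[1]),
                            x = nums[2], y = nums[3], z = nums[4],
                            charge = nums[5], radius = nums[6])
  }
  if (n_atoms == 0L) abort("no ATOM/HETMATM records found in PQR input")
  atoms <- dplyr::bind_rows(rows[seq_len(n_atoms)])
  validate_atoms(atoms)
  atoms
}

#' Validate an atom table
#'
#' Checks the structural invariants assumed throughout the package:
#' non-negative radii, finite coordinates, and unique
#' (chain, residue number, atom name) keys within each model.
#'
#' @param atoms an atom tibble as returned by [read_pqr()].
#' @return `atoms`, invisibly; errors if an invariant is violated.
#' @export
validate_atoms <- function(atoms) {
  .assert_atoms(atoms)
  if (any(atoms$radius < 0)) abort("atom radii must be >= 0")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort("atom coordinates must be finite")
  }
  if (all(c("model", "chain_id", "residue_number") %in% names(atoms))) {
    key <- paste(atoms$model, atoms$chain_id, atoms$residue_number,
                 atoms$atom_name)
    if (anyDuplicated(key)) {
      abort("duplicate (chain, residue, atom name) within a model")
    }
  }
  invisible(atoms)
}

#' Write atoms to PQR text
#'
#' Emits the same whitespace-separated dialect read by [read_pqr()]
#' (record name plus ten data fields per atom line). Ensembles (more than
#' one distinct `model`) are wrapped in `MODEL`/`ENDMDL` blocks.
#' Coordinates are written to 3 decimals and charge/radius to 4, so a
#' write/read cycle reproduces values on that grid exactly.
#'
#' @param atoms atom tibble (see [read_pqr()] for columns; `model`,
#'   `record` and `serial` are optional and defaulted).
#' @param path optional output file; when `NULL` the text is returned.
#' @return character vector of lines, invisibly when `path` is given.
#' @export
write_pqr <- function(atoms, path = NULL) {
  .assert_atoms(atoms)
  atoms <- .complete_atom_cols(atoms)
  too_long <- nchar(atoms$atom_name) > 4
  if (any(too_long)) {
    abort(sprintf("atom name exceeds 4-character field width: %s",
                  atoms$atom_name[which(too_long)[1]]))
  }
  fmt <- function(df) {
    sprintf("%-6s %5d %-4s %-4s %s %4d %11.3f %11.3f %11.3f %8.4f %8.4f",
            df$record, df$serial, df$atom_name, df$residue_name,
            df$chain_id, df$residue_number, df$x, df$y, df$z,
            df$charge, df$radius)
  }
  models <- unique(atoms$model)
  lines <- if (length(models) > 1) {
    unlist(lapply(seq_along(models), function(i) {
      c(sprintf("MODEL %8d", i),
        fmt(atoms[atoms$model == models[i], , drop = FALSE]),
        "ENDMDL")
    }), use.names = FALSE)
  } else {
    fmt(atoms)
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

# fill optional atom columns with defaults
.complete_atom_cols <- function(atoms) {
  atoms <- as_tibble(atoms)
  if (!"model" %in% names(atoms)) atoms$model <- 1L
  if (!"record" %in% names(atoms)) atoms$record <- "ATOM"
  if (!"chain_id" %in% names(atoms)) atoms$chain_id <- "A"
  if (!"residue_name" %in% names(atoms)) atoms$residue_name <- "UNK"
  if (!"residue_number" %in% names(atoms)) atoms$residue_number <- 1L
  if (!"serial" %in% names(atoms)) {
    atoms <- atoms %>%
      group_by(.data$model) %>%
      mutate(serial = row_number()) %>%
      ungroup()
  }
  atoms
}

#' Split an ensemble tibble into per-model structures
#'
#' @param atoms atom tibble with a `model` column.
#' @return named list of single-model atom tibbles, in model order.
#' @export
pqr_models <- function(atoms) {
  .assert_atoms(atoms)
  if (!"model" %in% names(atoms)) return(list(`1` = atoms))
  split(atoms, atoms$model)
}
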