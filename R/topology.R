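#' Build and validate a topology table
#'
#' A topology is the static per-atom record over which all analyses run: atom
#' identity, residue assignment, a group label marking each atom as part of
#' the protein or the ligand, a fixed partial charge, Lennard-Jones
#' parameters in the sigma/epsilon convention, and a mass.  Alternative
#' charge sets (e.g. additive force-field charges versus polarised
#' protein-specific charges) are simply different topology tables; the
#' analysis code is charge-set-agnostic.
#'
#' @param atoms data.frame with columns `atom_id` (consecutive integers from
#'   0), `atom_name`, `element`, `residue_index` (0-based), `residue_name`,
#'   `group` (`"protein"` or `"ligand"`), `charge` (e), `lj_sigma` (Angstrom,
#'   > 0), `lj_epsilon` (kcal/mol, >= 0), `mass` (amu, > 0).
#' @return data.frame of class `"topology"`.
#' @seealso [read_topology()], [write_topology()]
#' @export
topology <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  validate_topology(atoms)
  class(atoms) <- c("topology", "data.frame")
  atoms
}

TOPOLOGY_COLUMNS <- c("atom_id", "atom_name", "element", "residue_index",
                      "residue_name", "group", "charge", "lj_sigma",
                      "lj_epsilon", "mass")

validate_topology <- function(atoms) {
  missing_cols <- setdiff(TOPOLOGY_COLUMNS, names(atoms))
  if (length(missing_cols) > 0L)
    stop_iebind("topology is missing required column(s): %s",
                paste(missing_cols, collapse = ", "),
                class = "iebind_format_error")
  if (nrow(atoms) == 0L)
    stop_iebind("topology has no atoms", class = "iebind_empty_error")
  if (!identical(as.integer(atoms$atom_id), seq_len(nrow(atoms)) - 1L))
    stop_iebind("atom_id must be consecutive integers starting at 0",
                class = "iebind_invariant_error")
  bad_group <- setdiff(unique(atoms$group), c("protein", "ligand"))
  if (length(bad_group) > 0L)
    stop_iebind("group must be 'protein' or 'ligand'; found: %s",
                paste(bad_group, collapse = ", "),
                class = "iebind_invariant_error")
  for (col in c("charge", "lj_sigma", "lj_epsilon", "mass")) {
    if (!is.numeric(atoms[[col]]) || anyNA(atoms[[col]]))
      stop_iebind("topology column '%s' must be numeric and non-missing", col,
                  class = "iebind_parse_error")
  }
  if (any(atoms$lj_epsilon < 0))
    stop_iebind("lj_epsilon must be >= 0 (offending atom_id %d)",
                atoms$atom_id[which(atoms$lj_epsilon < 0)[1L]],
                class = "iebind_invariant_error")
  if (any(atoms$lj_sigma <= 0))
    stop_iebind("lj_sigma must be > 0 (offending atom_id %d)",
                atoms$atom_id[which(atoms$lj_sigma <= 0)[1L]],
                class = "iebind_invariant_error")
  if (any(atoms$mass <= 0))
    stop_iebind("mass must be > 0 (offending atom_id %d)",
                atoms$atom_id[which(atoms$mass <= 0)[1L]],
                class = "iebind_invariant_error")
  invisible(atoms)
}

#' Read a topology table from delimited text
#'
#' The on-disk dialect is a tab- or comma-separated table (auto-detected from
#' the header line) with header
#' `atom_id,atom_name,element,residue_index,residue_name,group,charge,lj_sigma,lj_epsilon,mass`.
#' Column order is irrelevant; extra columns are carried along untouched.
#'
#' @param path path to a topology file.
#' @return a [topology()] object.
#' @export
read_topology <- function(path) {
  if (!file.exists(path))
    stop_iebind("topology file not found: %s", path, class = "iebind_io_error")
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  missing_cols <- setdiff(TOPOLOGY_COLUMNS, names(raw))
  if (length(missing_cols) > 0L)
    stop_iebind("topology file %s is missing required column(s): %s",
                path, paste(missing_cols, collapse = ", "),
                class = "iebind_format_error")
  for (col in c("atom_id", "residue_index")) raw[[col]] <- as.integer(raw[[col]])
  for (col in c("charge", "lj_sigma", "lj_epsilon", "mass")) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(parsed)) {
      bad_row <- which(is.na(parsed))[1L]
      stop_iebind("non-numeric value in column '%s' at line %d of %s",
                  col, bad_row + 1L, path, class = "iebind_parse_error")
    }
    raw[[col]] <- parsed
  }
  topology(raw)
}

#' Write a topology table
#'
#' @param top a [topology()] object.
#' @param path output path; tab-separated with header.
#' @export
write_topology <- function(top, path) {
  validate_topology(top)
  utils::write.table(as.data.frame(top), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d residues (%d protein / %d ligand atoms)\n",
              nrow(x), length(unique(x$residue_index)),
              sum(x$group == "protein"), sum(x$group == "ligand")))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

group_index <- function(top, group) which(top$group == group)

require_both_groups <- function(top) {
  if (!any(top$group == "protein") || !any(top$group == "ligand"))
    stop_iebind("binding analyses need at least one protein and one ligand atom",
                class = "iebind_invariant_error")
  invisible(top)
}
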