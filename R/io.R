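# Readers and writers for the standard formats the pipeline touches.

#' Read a protein record from FASTA
#'
#' Multi-record files yield the first record with a warning (this is a
#' single-target tool).
#'
#' @param path FASTA file path.
#' @return A [protein_record()].
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  if (length(set) > 1L) {
    warning(sprintf("%s holds %d records; using the first", path,
                    length(set)))
  }
  id <- strsplit(names(set)[1], "[[:space:]]+")[[1]][1]
  protein_record(id, as.character(set[[1]]))
}

#' Write a protein record to FASTA
#' @param record A [protein_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(record, path) {
  set <- Biostrings::AAStringSet(record$sequence)
  names(set) <- record$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read ligand records from a CSV/TSV table
#'
#' Expects a header with `id` and `smiles` columns (comma or tab
#' separated).  Ids must be unique and non-empty.
#'
#' @param path File path.
#' @return List of [ligand_record()] objects.
#' @export
read_ligand_csv <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (!all(c("id", "smiles") %in% names(df))) {
    stop(path, " must have 'id' and 'smiles' columns", call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop(sprintf("%s: duplicate ligand id '%s'", path,
                 df$id[anyDuplicated(df$id)]), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) ligand_record(df$id[i], df$smiles[i]))
}

#' Write ligand records to CSV
#' @param records List of [ligand_record()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ligand_csv <- function(records, path) {
  df <- data.frame(id = vapply(records, `[[`, character(1), "id"),
                   smiles = vapply(records, `[[`, character(1), "smiles"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write label tables
#'
#' CSV with header `ligand_id,score_kcal_mol` and an optional `method`
#' column.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_label_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (!all(c("ligand_id", "score_kcal_mol") %in% names(df))) {
    stop(path, " must have 'ligand_id' and 'score_kcal_mol' columns",
         call. = FALSE)
  }
  df
}

#' @rdname read_label_csv
#' @param df data.frame with `ligand_id`, `score_kcal_mol` (and optionally
#'   `method`).
#' @export
write_label_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read C-alpha coordinates from a PDB file
#'
#' @param path PDB file path.
#' @param chain Optional chain identifier filter.
#' @return N x 3 matrix of C-alpha coordinates (Angstrom), one row per
#'   residue in file order.
#' @export
read_pdb_coords <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, elety = "CA",
                            chain = if (is.null(chain)) NULL else chain)
  xyz <- matrix(pdb$xyz[sel$xyz], ncol = 3L, byrow = TRUE)
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

#' Serialize a ligand graph bundle to JSON
#'
#' The bundle holds atoms, bonds, feature matrices, charges and (if
#' embedded) coordinates, and round-trips through [read_graph_bundle()].
#'
#' @param graph A `ligand_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_bundle <- function(graph, path) {
  obj <- list(id = graph$record$id, smiles = graph$record$smiles,
              atoms = graph$atoms, bonds = graph$bonds,
              coords = graph$coords,
              atom_features = graph$atom_features,
              bond_features = graph$bond_features,
              feature_scheme = graph$feature_scheme)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_graph_bundle
#' @export
read_graph_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bonds <- as.data.frame(obj$bonds, stringsAsFactors = FALSE)
  if (!nrow(bonds)) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = character(0),
                        in_ring = logical(0), stringsAsFactors = FALSE)
  }
  atoms <- as.data.frame(obj$atoms, stringsAsFactors = FALSE)
  atoms$partial_charge <- as.numeric(atoms$partial_charge)
  atoms$n_hydrogens <- suppressWarnings(as.integer(atoms$n_hydrogens))
  structure(list(record = ligand_record(obj$id, obj$smiles),
                 atoms = atoms, bonds = bonds,
                 coords = if (!is.null(obj$coords)) as.matrix(obj$coords),
                 atom_features = if (!is.null(obj$atom_features))
                   as.matrix(obj$atom_features),
                 bond_features = if (!is.null(obj$bond_features))
                   as.matrix(obj$bond_features),
                 feature_scheme = obj$feature_scheme),
            class = "ligand_graph")
}

#' Write a metrics report as JSON
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
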