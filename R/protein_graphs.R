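.aa_alphabet <- c("A","C","D","E","F","G","H","I","K","L",
                  "M","N","P","Q","R","S","T","V","W","Y")

# Kyte-Doolittle hydropathy index per residue.
.kyte_doolittle <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
                     G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
                     M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                     S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Integer side-chain charge class at physiological pH.
.aa_charge_class <- c(D = -1, E = -1, K = 1, R = 1)

#' Create a protein record
#'
#' @param id Character scalar.
#' @param sequence One-letter amino-acid string; the 20 canonical letters
#'   plus `X` (unknown) are accepted.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c(.aa_alphabet, "X"))
  if (length(bad)) {
    stop(sprintf("protein '%s': illegal residue character '%s' at position %d",
                 id, chars[bad[1]], bad[1]), call. = FALSE)
  }
  structure(list(id = id, sequence = paste(chars, collapse = "")),
            class = "protein_record")
}

#' Build the linear residue graph of a protein sequence
#'
#' Each residue becomes a node; consecutive residues are joined by a chain
#' edge reflecting the peptide-bond order, giving exactly `N - 1` edges for
#' `N` residues.  This sequence-only graph is the main protein
#' representation; 3D contact edges are an opt-in ablation
#' ([build_contact_graph()]).
#'
#' @param record A [protein_record()].
#' @return A `protein_graph`: list with `record`, `residues` (data.frame
#'   `index`, `aa`), `chain_edges` (two-column 0-based matrix), and
#'   `contact_edges` (`NULL` here).
#' @export
build_sequence_graph <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  residues <- data.frame(index = 0:(n - 1L), aa = chars,
                         stringsAsFactors = FALSE)
  chain <- if (n > 1L) cbind(i = 0:(n - 2L), j = 1:(n - 1L)) else
    matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j")))
  structure(list(record = record, residues = residues, chain_edges = chain,
                 contact_edges = NULL, residue_features = NULL,
                 feature_scheme = NULL),
            class = "protein_graph")
}

#' Build a distance-threshold contact graph (ablation mode)
#'
#' Adds contact edges between residue pairs (i, j) with `j > i + 1` whose
#' representative atoms (conventionally C-alpha) lie within `threshold`
#' Angstrom, on top of the chain edges.  Coordinates are user-supplied
#' (e.g. from a deposited or model structure); they are never fetched.
#'
#' @param record A [protein_record()].
#' @param coords N x 3 numeric matrix, one row per residue, Angstrom.
#' @param threshold Positive distance cutoff in Angstrom (default 8,
#'   matching the non-bonded physics cutoff).
#' @return A `protein_graph` with `contact_edges` (two-column 0-based
#'   matrix, possibly empty).
#' @export
build_contact_graph <- function(record, coords, threshold = 8) {
  g <- build_sequence_graph(record)
  coords <- as.matrix(coords)
  n <- nrow(g$residues)
  if (nrow(coords) != n || ncol(coords) != 3L) {
    stop(sprintf("protein '%s': coords must be %d x 3 (got %d x %d)",
                 record$id, n, nrow(coords), ncol(coords)), call. = FALSE)
  }
  stopifnot(threshold > 0)
  d <- as.matrix(stats::dist(coords))
  pairs <- which(upper.tri(d) & d <= threshold, arr.ind = TRUE)
  keep <- pairs[pairs[, 2] - pairs[, 1] > 1L, , drop = FALSE]
  g$contact_edges <- cbind(i = as.integer(keep[, 1]) - 1L,
                           j = as.integer(keep[, 2]) - 1L)
  g$contact_threshold <- threshold
  g
}

#' Available residue feature schemes
#' @return Character vector of scheme names for [featurize_residues()].
#' @export
residue_feature_schemes <- function() "default"

#' Compute residue feature vectors
#'
#' The `"default"` scheme is a 20-dimensional one-hot over the canonical
#' amino acids (all-zero for `X`) plus two physicochemical scalars:
#' Kyte-Doolittle hydropathy and an integer side-chain charge class
#' (+1 for K/R, -1 for D/E, 0 otherwise), 22 numbers per residue.
#'
#' @param graph A `protein_graph`.
#' @param scheme Scheme name; see [residue_feature_schemes()].
#' @return The graph with an N x 22 `residue_features` matrix.
#' @export
featurize_residues <- function(graph, scheme = "default") {
  stopifnot(inherits(graph, "protein_graph"))
  if (!scheme %in% residue_feature_schemes()) {
    stop(sprintf("unknown residue feature scheme '%s'; available: %s",
                 scheme, paste(residue_feature_schemes(), collapse = ", ")),
         call. = FALSE)
  }
  aa <- graph$residues$aa
  onehot <- matrix(0, length(aa), 20L)
  idx <- match(aa, .aa_alphabet)
  hit <- which(!is.na(idx))
  onehot[cbind(hit, idx[hit])] <- 1
  hydro <- unname(ifelse(is.na(idx), 0, .kyte_doolittle[aa]))
  hydro[is.na(hydro)] <- 0
  chg <- unname(.aa_charge_class[aa])
  chg[is.na(chg)] <- 0
  graph$residue_features <- cbind(onehot, hydro, chg)
  graph$feature_scheme <- scheme
  graph
}

#' @exportS3Method base::print
print.protein_graph <- function(x, ...) {
  cat(sprintf("<protein_graph> %s: %d residues, %d chain edges%s\n",
              x$record$id, nrow(x$residues), nrow(x$chain_edges),
              if (!is.null(x$contact_edges))
                sprintf(", %d contact edges", nrow(x$contact_edges)) else ""))
  invisible(x)
}
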