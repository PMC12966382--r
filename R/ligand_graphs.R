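#' Create a ligand record
#'
#' A ligand record pairs a short unique identifier with a SMILES string.
#' It is the unit of input for [parse_smiles()] and the dataset builders.
#'
#' @param id Non-empty character scalar naming the ligand.
#' @param smiles SMILES string for a single connected molecule.
#' @return An object of class `ligand_record` (a named list).
#' @examples
#' ligand_record("eth", "CCO")
#' @export
ligand_record <- function(id, smiles) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(smiles), length(smiles) == 1L)
  structure(list(id = id, smiles = smiles), class = "ligand_record")
}

#' Parse a SMILES string into a featurizable molecular graph
#'
#' Atoms become nodes and bonds become edges.  The graph is heavy-atom only:
#' hydrogens are treated implicitly here and added internally only where the
#' chemistry needs them (charge assignment, conformer embedding).  Aromaticity
#' is perceived by Open Babel; ring membership of bonds is derived from the
#' graph (a bond is in a ring iff it is not a bridge).
#'
#' @param record A [ligand_record()], or a bare SMILES string (an id is
#'   derived from it).
#' @return A `ligand_graph`: list with `record`, `atoms` (data.frame with
#'   `index`, `element`, `degree`, `formal_charge`, `is_aromatic`,
#'   `partial_charge`, `n_hydrogens`), `bonds` (data.frame with `i`, `j`,
#'   `order`, `in_ring`; 0-based endpoint indices, each bond stored once),
#'   and `coords` (`NULL` until [embed_conformer()]).
#' @details Multi-fragment SMILES (disconnected graphs, e.g. salts written
#'   with a `.`) are rejected with a distinct error rather than trimmed to
#'   the largest fragment, so bad input fails loudly.
#' @seealso [assign_gasteiger_charges()], [embed_conformer()],
#'   [featurize_atoms_bonds()]
#' @examples
#' \dontrun{
#' g <- parse_smiles(ligand_record("benzene", "c1ccccc1"))
#' nrow(g$atoms)  # 6
#' }
#' @export
parse_smiles <- function(record) {
  if (is.character(record)) record <- ligand_record(record, record)
  stopifnot(inherits(record, "ligand_record"))
  smiles_precheck(record$smiles, record$id)
  if (grepl(".", record$smiles, fixed = TRUE)) {
    stop(sprintf("record '%s': multi-fragment SMILES are not supported",
                 record$id), call. = FALSE)
  }
  m <- ob_read_mol2(ob_run(record$smiles, record$id, format = "mol2"))
  n <- nrow(m$atom)
  elements <- sub("\\..*$", "", m$atom$elety)
  is_aromatic <- grepl("\\.ar$", m$atom$elety)
  if (is.null(m$bond) || nrow(m$bond) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0),
                        order = character(0), in_ring = logical(0),
                        stringsAsFactors = FALSE)
  } else {
    ord <- vapply(m$bond$type, function(t) switch(t,
      "1" = "single", "2" = "double", "3" = "triple",
      "ar" = "aromatic", "am" = "single", t), character(1))
    bonds <- data.frame(i = as.integer(m$bond$origin) - 1L,
                        j = as.integer(m$bond$target) - 1L,
                        order = ord, stringsAsFactors = FALSE)
    g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j) + 1L,
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    if (igraph::components(g)$no > 1L) {
      stop(sprintf("record '%s': multi-fragment SMILES are not supported",
                   record$id), call. = FALSE)
    }
    br <- igraph::bridges(g)
    bonds$in_ring <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  deg <- integer(n)
  if (nrow(bonds)) {
    tab <- table(factor(c(bonds$i, bonds$j), levels = 0:(n - 1L)))
    deg <- as.integer(tab)
  }
  atoms <- data.frame(index = 0:(n - 1L), element = elements, degree = deg,
                      formal_charge = ob_formal_charges(record$smiles,
                                                        record$id, n),
                      is_aromatic = is_aromatic,
                      partial_charge = NA_real_,
                      n_hydrogens = NA_integer_,
                      stringsAsFactors = FALSE)
  structure(list(record = record, atoms = atoms, bonds = bonds,
                 coords = NULL, atom_features = NULL, bond_features = NULL,
                 feature_scheme = NULL),
            class = "ligand_graph")
}

#' Assign Gasteiger-Marsili partial charges
#'
#' Charges are computed by Open Babel on the fully protonated molecule;
#' each hydrogen's charge is then folded onto its heavy neighbor, so the
#' heavy-atom charges sum to the molecule's net formal charge.
#'
#' @param graph A `ligand_graph` from [parse_smiles()].
#' @return The graph with `atoms$partial_charge` and `atoms$n_hydrogens`
#'   populated.
#' @export
assign_gasteiger_charges <- function(graph) {
  stopifnot(inherits(graph, "ligand_graph"))
  m <- ob_read_mol2(ob_run(graph$record$smiles, graph$record$id,
                           format = "mol2", addh = TRUE, gasteiger = TRUE))
  n_heavy <- nrow(graph$atoms)
  el <- sub("\\..*$", "", m$atom$elety)
  if (sum(el != "H") != n_heavy) {
    stop(sprintf("record '%s': heavy-atom count changed during protonation",
                 graph$record$id), call. = FALSE)
  }
  q <- m$atom$charge
  if (any(!is.finite(q))) {
    bad <- which(!is.finite(q))
    stop(sprintf("record '%s': non-finite Gasteiger charge on atom(s) %s",
                 graph$record$id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  # obabel appends added hydrogens after the heavy atoms, preserving order
  folded <- q[seq_len(n_heavy)]
  nh <- integer(n_heavy)
  if (nrow(m$bond)) {
    for (b in seq_len(nrow(m$bond))) {
      o <- m$bond$origin[b]; t <- m$bond$target[b]
      if (el[o] == "H" && el[t] != "H") {
        folded[t] <- folded[t] + q[o]; nh[t] <- nh[t] + 1L
      } else if (el[t] == "H" && el[o] != "H") {
        folded[o] <- folded[o] + q[t]; nh[o] <- nh[o] + 1L
      }
    }
  }
  graph$atoms$partial_charge <- folded
  graph$atoms$n_hydrogens <- nh
  graph
}

#' Embed a deterministic 3D conformer
#'
#' Generates several seed-derived distance-geometry embeddings (ETKDG, 10
#' by default), relaxes each with a force field (MMFF94 where
#' parameterized, UFF otherwise), and keeps the lowest-energy conformer.
#' The whole procedure is driven by `seed`: repeated calls with the same
#' seed return bitwise-identical coordinates.
#'
#' @param graph A `ligand_graph`.
#' @param seed Integer seed controlling the embedding.
#' @param n_confs Number of seed-derived embeddings to relax and rank.
#' @return The graph with `coords` set to an N x 3 matrix (Angstrom, heavy
#'   atoms only, rows aligned with `atoms`) and `conformer_seed` recorded.
#' @export
embed_conformer <- function(graph, seed = 0L, n_confs = 10L) {
  stopifnot(inherits(graph, "ligand_graph"))
  res <- rdkit_embed_batch(graph$record$smiles, graph$record$id,
                           seed = seed, n_confs = n_confs)[[1]]
  attach_conformer(graph, res, seed)
}

#' @noRd
attach_conformer <- function(graph, res, seed) {
  if (length(res$elements) != nrow(graph$atoms) ||
      !identical(res$elements, graph$atoms$element)) {
    stop(sprintf("record '%s': conformer embedding failed (atom mismatch)",
                 graph$record$id), call. = FALSE)
  }
  xyz <- res$coords
  dimnames(xyz) <- NULL
  if (any(!is.finite(xyz))) {
    stop(sprintf("record '%s': conformer embedding produced non-finite coordinates",
                 graph$record$id), call. = FALSE)
  }
  graph$coords <- xyz
  graph$conformer_seed <- as.integer(seed)
  graph
}

.atom_feature_elements <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")
.bond_orders <- c("single", "double", "triple", "aromatic")

#' Available ligand feature schemes
#' @return Character vector of scheme names accepted by
#'   [featurize_atoms_bonds()].
#' @export
ligand_feature_schemes <- function() "default"

#' Compute fixed-length atom and bond feature vectors
#'
#' The `"default"` scheme encodes each atom as: element one-hot over
#' (C, N, O, S, F, Cl, Br, I, P, other), degree one-hot (0-5), formal
#' charge, aromatic flag, and the Gasteiger partial charge (19 numbers).
#' Bonds carry a bond-order one-hot (single, double, triple, aromatic)
#' plus a ring flag (5 numbers).
#'
#' @param graph A `ligand_graph` with charges assigned.
#' @param scheme Feature scheme name; see [ligand_feature_schemes()].
#' @return The graph with `atom_features` (N x 19) and `bond_features`
#'   (B x 5) matrices and `feature_scheme` recorded.
#' @export
featurize_atoms_bonds <- function(graph, scheme = "default") {
  stopifnot(inherits(graph, "ligand_graph"))
  if (!scheme %in% ligand_feature_schemes()) {
    stop(sprintf("unknown ligand feature scheme '%s'; available: %s",
                 scheme, paste(ligand_feature_schemes(), collapse = ", ")),
         call. = FALSE)
  }
  if (anyNA(graph$atoms$partial_charge)) {
    stop("assign_gasteiger_charges() must run before featurization",
         call. = FALSE)
  }
  a <- graph$atoms
  el <- match(a$element, .atom_feature_elements)
  el_onehot <- matrix(0, nrow(a), length(.atom_feature_elements) + 1L)
  el_onehot[cbind(seq_len(nrow(a)),
                  ifelse(is.na(el), length(.atom_feature_elements) + 1L, el))] <- 1
  deg <- pmin(a$degree, 5L)
  deg_onehot <- matrix(0, nrow(a), 6L)
  deg_onehot[cbind(seq_len(nrow(a)), deg + 1L)] <- 1
  graph$atom_features <- cbind(el_onehot, deg_onehot, a$formal_charge,
                               as.numeric(a$is_aromatic), a$partial_charge)
  b <- graph$bonds
  if (nrow(b)) {
    ord <- match(b$order, .bond_orders)
    ord_onehot <- matrix(0, nrow(b), length(.bond_orders))
    ord_onehot[cbind(which(!is.na(ord)), ord[!is.na(ord)])] <- 1
    graph$bond_features <- cbind(ord_onehot, as.numeric(b$in_ring))
  } else {
    graph$bond_features <- matrix(0, 0L, length(.bond_orders) + 1L)
  }
  graph$feature_scheme <- scheme
  graph
}

#' @exportS3Method base::print
print.ligand_graph <- function(x, ...) {
  cat(sprintf("<ligand_graph> %s: %d atoms, %d bonds%s%s\n",
              x$record$id, nrow(x$atoms), nrow(x$bonds),
              if (!anyNA(x$atoms$partial_charge)) ", charged" else "",
              if (!is.null(x$coords)) ", 3D" else ""))
  invisible(x)
}
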