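# Shared small fixtures, built once per test run (obabel conversions are
# cached inside the package for the session, so repeated parses are cheap).

ethanol_graph <- function() {
  assign_gasteiger_charges(parse_smiles(ligand_record("eth", "CCO")))
}

benzene_graph <- function() {
  assign_gasteiger_charges(parse_smiles(ligand_record("benzene", "c1ccccc1")))
}

small_protein <- function(seq = "ACDEFGHIK") {
  featurize_residues(build_sequence_graph(protein_record("prot", seq)))
}

# A tiny featurized ligand + protein + physics item set for model tests.
tiny_dataset <- function(ids = c("eth", "phenol", "pyridine"),
                         smiles = c("CCO", "c1ccccc1O", "c1ccncc1"),
                         labels = c(-7, -8, -9)) {
  recs <- Map(ligand_record, ids, smiles)
  graphs <- featurize_ligands(recs)
  prot <- small_protein()
  build_affinity_dataset(graphs, prot,
                         labels = stats::setNames(labels, ids))
}

tiny_model_config <- function(...) {
  physdual_config(drug_hidden_dims = c(8L, 8L), protein_hidden_dims = 6L,
                  fusion_dims = c(10L, 5L), ...)
}
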