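test_that("parse_smiles builds the expected graphs for known molecules", {
  eth <- parse_smiles(ligand_record("eth", "CCO"))
  expect_s3_class(eth, "ligand_graph")
  expect_equal(nrow(eth$atoms), 3L)
  expect_equal(nrow(eth$bonds), 2L)
  expect_false(any(eth$atoms$is_aromatic))
  expect_equal(sort(eth$atoms$element), c("C", "C", "O"))

  benzene <- parse_smiles(ligand_record("benzene", "c1ccccc1"))
  expect_equal(nrow(benzene$atoms), 6L)
  expect_equal(nrow(benzene$bonds), 6L)
  expect_true(all(benzene$atoms$is_aromatic))
  expect_true(all(benzene$bonds$order == "aromatic"))
  expect_true(all(benzene$bonds$in_ring))
})

test_that("malformed and multi-fragment SMILES fail loudly with the record id", {
  expect_error(parse_smiles(ligand_record("broken", "C(")),
               "broken.*unbalanced parentheses")
  expect_error(parse_smiles(ligand_record("ringbond", "C1CC")),
               "ringbond")
  expect_error(parse_smiles(ligand_record("salt", "CCO.CC")),
               "multi-fragment")
})

test_that("node and edge counts match an independent adjacency-matrix walk", {
  for (smi in c("CCO", "c1ccccc1O", "CC(=O)Nc1ccccc1", "C1CCNCC1")) {
    g <- parse_smiles(ligand_record("x", smi))
    n <- nrow(g$atoms)
    adj <- matrix(0L, n, n)
    adj[cbind(g$bonds$i + 1L, g$bonds$j + 1L)] <- 1L
    adj <- adj | t(adj)
    expect_equal(sum(adj) / 2, nrow(g$bonds))
    expect_equal(as.integer(rowSums(adj)), g$atoms$degree)
    # connected: power-iteration reachability from node 1
    reach <- rep(FALSE, n); reach[1] <- TRUE
    for (k in seq_len(n)) reach <- reach | (adj %*% reach > 0)
    expect_true(all(reach))
  }
})

test_that("Gasteiger charges conserve the net formal charge", {
  eth <- ethanol_graph()
  expect_true(all(is.finite(eth$atoms$partial_charge)))
  expect_lt(abs(sum(eth$atoms$partial_charge)), 1e-3)

  acetate <- assign_gasteiger_charges(
    parse_smiles(ligand_record("acetate", "CC(=O)[O-]")))
  expect_lt(abs(sum(acetate$atoms$partial_charge) - (-1)), 1e-3)
  expect_equal(sum(acetate$atoms$formal_charge), -1L)

  ammonium <- assign_gasteiger_charges(
    parse_smiles(ligand_record("tma", "C[N+](C)(C)C")))
  expect_lt(abs(sum(ammonium$atoms$partial_charge) - 1), 1e-3)
})

test_that("charge conservation holds across a random pool sample", {
  pool <- smiles_pool()
  set.seed(42)
  pick <- sample(names(pool), 50)
  for (nm in pick) {
    g <- assign_gasteiger_charges(parse_smiles(ligand_record(nm, pool[[nm]])))
    net <- sum(g$atoms$formal_charge)
    expect_lt(abs(sum(g$atoms$partial_charge) - net), 1e-3)
  }
})

test_that("conformer embedding is deterministic and physically sane", {
  g1 <- embed_conformer(ethanol_graph(), seed = 0)
  g2 <- embed_conformer(ethanol_graph(), seed = 0)
  expect_identical(g1$coords, g2$coords)
  expect_equal(dim(g1$coords), c(3L, 2L + 1L))
  d <- as.matrix(stats::dist(g1$coords))
  offdiag <- d[upper.tri(d)]
  expect_true(all(offdiag > 0.8 & offdiag < 5.0))
})

test_that("relaxed benzene ring bonds are equal within 0.05 Angstrom", {
  g <- embed_conformer(benzene_graph(), seed = 0)
  lens <- vapply(seq_len(nrow(g$bonds)), function(b) {
    sqrt(sum((g$coords[g$bonds$i[b] + 1L, ] - g$coords[g$bonds$j[b] + 1L, ])^2))
  }, numeric(1))
  expect_lt(max(lens) - min(lens), 0.05)
  expect_true(all(lens > 1.2 & lens < 1.6))
})

test_that("featurization obeys the shape and invariance contracts", {
  g <- featurize_atoms_bonds(ethanol_graph())
  expect_equal(ncol(g$atom_features), 19L)
  expect_equal(nrow(g$atom_features), nrow(g$atoms))
  expect_equal(ncol(g$bond_features), 5L)
  # carbon vs oxygen differ in the element one-hot block
  expect_false(isTRUE(all.equal(g$atom_features[1, 1:10],
                                g$atom_features[3, 1:10])))
  # feature multiset is invariant to atom input order: reversed SMILES
  g_rev <- featurize_atoms_bonds(assign_gasteiger_charges(
    parse_smiles(ligand_record("eth_rev", "OCC"))))
  sorted_rows <- function(m) m[do.call(order, as.data.frame(m)), ]
  expect_equal(sorted_rows(g_rev$atom_features), sorted_rows(g$atom_features),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(featurize_atoms_bonds(g, scheme = "nope"),
               "unknown ligand feature scheme")
  expect_error(featurize_atoms_bonds(parse_smiles(ligand_record("x", "CC"))),
               "assign_gasteiger_charges")
})

test_that("parse -> charge -> embed is reproducible end to end", {
  run <- function() {
    g <- embed_conformer(assign_gasteiger_charges(
      parse_smiles(ligand_record("phenol", "c1ccccc1O"))), seed = 1)
    featurize_atoms_bonds(g)
  }
  a <- run(); b <- run()
  expect_identical(a$coords, b$coords)
  expect_identical(a$atom_features, b$atom_features)
})
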