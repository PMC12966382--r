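test_that("embeddings have the configured lengths", {
  cfg <- tiny_model_config()
  g <- featurize_atoms_bonds(ethanol_graph())
  prot <- small_protein()
  m <- init_physdual_model(ncol(g$atom_features),
                           ncol(prot$residue_features), cfg, seed = 1)
  expect_length(encode_drug(m, g), cfg$drug_hidden_dims[2])
  expect_length(encode_protein(m, prot), cfg$protein_hidden_dims[1])
  expect_error(encode_drug(m, featurize_atoms_bonds(ethanol_graph())[
    c("record", "atoms", "bonds")]), class = "error")
})

test_that("drug embeddings are invariant to atom reordering", {
  cfg <- tiny_model_config()
  # same molecule written from different starting atoms
  g1 <- featurize_atoms_bonds(assign_gasteiger_charges(
    parse_smiles(ligand_record("a", "CC(=O)Nc1ccccc1"))))
  g2 <- featurize_atoms_bonds(assign_gasteiger_charges(
    parse_smiles(ligand_record("b", "c1ccccc1NC(C)=O"))))
  prot <- small_protein()
  m <- init_physdual_model(ncol(g1$atom_features),
                           ncol(prot$residue_features), cfg, seed = 5)
  e1 <- encode_drug(m, g1); e2 <- encode_drug(m, g2)
  expect_lt(max(abs(e1 - e2)), 1e-6)
  # different molecules embed differently
  g3 <- featurize_atoms_bonds(ethanol_graph())
  expect_gt(max(abs(encode_drug(m, g3) - e1)), 1e-4)
})

test_that("protein embeddings respect chain symmetry and degenerate inputs", {
  cfg <- tiny_model_config()
  pal <- small_protein("AKDKA")  # palindromic sequence
  rev <- small_protein("AKDKA")
  m <- init_physdual_model(18, ncol(pal$residue_features), cfg, seed = 2)
  expect_equal(encode_protein(m, pal), encode_protein(m, rev))
  single <- small_protein("W")   # 1 node, 0 edges
  emb <- encode_protein(m, single)
  expect_true(all(is.finite(emb)))
})

test_that("fusion consumes physics features and guards their scale", {
  cfg <- tiny_model_config()
  g <- featurize_atoms_bonds(ethanol_graph())
  prot <- small_protein()
  m <- init_physdual_model(ncol(g$atom_features),
                           ncol(prot$residue_features), cfg, seed = 7)
  d <- encode_drug(m, g); p <- encode_protein(m, prot)
  y1 <- fuse_and_predict(m, d, p, c(0.2, 0.9), "eth")
  expect_s3_class(y1, "affinity_prediction")
  expect_true(is.finite(y1$predicted_energy))
  # deterministic inference
  y2 <- fuse_and_predict(m, d, p, c(0.2, 0.9), "eth")
  expect_identical(y1$predicted_energy, y2$predicted_energy)
  # physics features actually reach the output
  y0 <- fuse_and_predict(m, d, p, c(0, 0), "eth")
  expect_gt(abs(y1$predicted_energy - y0$predicted_energy), 1e-8)
  # normalization contract is enforced
  expect_error(fuse_and_predict(m, d, p, c(1.4, 0.2)), "min-max normalized")
  expect_error(fuse_and_predict(m, d, p, c(0.5)), "expected 2")
})

test_that("end-to-end predictions are permutation invariant", {
  ds <- tiny_dataset()
  cfg <- tiny_model_config()
  fit <- train_physdual(ds$items, cfg,
                        train_config(max_epochs = 5, patience = 4), seed = 1)
  # re-parse each fixture ligand from a rotated SMILES spelling
  alt <- list(eth = "OCC", phenol = "Oc1ccccc1", pyridine = "n1ccccc1")
  for (id in names(alt)) {
    g_alt <- featurize_atoms_bonds(assign_gasteiger_charges(
      parse_smiles(ligand_record(id, alt[[id]]))))
    it <- ds$items[[id]]
    it_alt <- it; it_alt$drug <- g_alt
    p0 <- predict(fit, list(it))$predicted_energy
    p1 <- predict(fit, list(it_alt))$predicted_energy
    expect_lt(abs(p0 - p1), 1e-5)
  }
})

test_that("backprop gradients match central finite differences", {
  ds <- tiny_dataset()
  cfg <- tiny_model_config()
  inp <- build_model_input(ds$items[[1]]$drug, ds$items[[1]]$protein,
                           ds$items[[1]]$physics, ds$items[[1]]$label)
  m <- init_physdual_model(ncol(inp$Xd), ncol(inp$Xp), cfg, seed = 3)
  fw <- physdualgcn:::model_forward(m, inp)
  t_std <- -0.3
  grads <- physdualgcn:::model_backward(m, inp, fw, 2 * (fw$y_std - t_std))
  lossfun <- function(mm) {
    (physdualgcn:::model_forward(mm, inp)$y_std - t_std)^2
  }
  set.seed(4)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    idx <- if (length(p) > 4) sample(length(p), 4) else seq_along(p)
    for (k in idx) {
      h <- 1e-6
      up <- m; up$params[[nm]][k] <- up$params[[nm]][k] + h
      dn <- m; dn$params[[nm]][k] <- dn$params[[nm]][k] - h
      num <- (lossfun(up) - lossfun(dn)) / (2 * h)
      expect_lt(abs(num - grads[[nm]][k]) / max(1, abs(num)), 1e-5)
    }
  }
})

test_that("checkpoints round-trip through JSON", {
  ds <- tiny_dataset()
  cfg <- tiny_model_config()
  fit <- train_physdual(ds$items, cfg,
                        train_config(max_epochs = 3, patience = 2), seed = 2)
  fit$model$scalers <- ds$scalers
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit$model, path)
  m2 <- load_checkpoint(path)
  p1 <- predict(fit$model, ds$items)
  p2 <- predict(m2, ds$items)
  expect_equal(p2$predicted_energy, p1$predicted_energy, tolerance = 1e-12)
  expect_equal(m2$scalers$coul$lower, ds$scalers$coul$lower)
})
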