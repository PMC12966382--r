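test_that("training is reproducible and learns a trivial target", {
  ds <- tiny_dataset(labels = c(-5, -5, -5))
  cfg <- tiny_model_config()
  tc <- train_config(max_epochs = 40, patience = 10)
  f1 <- train_physdual(ds$items, cfg, tc, seed = 3)
  f2 <- train_physdual(ds$items, cfg, tc, seed = 3)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$loss_curve$train_loss, f2$loss_curve$train_loss)
  lc <- f1$loss_curve$train_loss
  expect_lt(min(lc), lc[1])
  expect_lt(min(lc), 1e-3)
})

test_that("early stopping obeys the patience rule exactly", {
  ds <- tiny_dataset()
  cfg <- tiny_model_config()
  # an aggressive learning rate converges fast and then plateaus under
  # dropout noise, so the patience rule must terminate the run early
  fit <- train_physdual(ds$items, cfg,
                        train_config(learning_rate = 5e-3, patience = 5,
                                     max_epochs = 200, dropout = 0.3),
                        seed = 1)
  lc <- fit$loss_curve$train_loss
  expect_equal(fit$best_epoch, which.min(lc))
  if (fit$stopped_epoch < 200L) {
    expect_equal(fit$stopped_epoch, fit$best_epoch + 5L)
  }
  # no epoch between best and stop improved on the best loss
  expect_true(all(lc[seq(fit$best_epoch, fit$stopped_epoch)] >=
                    lc[fit$best_epoch]))
  expect_lte(nrow(fit$loss_curve), 200L)
})

test_that("non-finite labels are rejected", {
  ds <- tiny_dataset()
  ds$items[[2]]$label <- NaN
  expect_error(train_physdual(ds$items, tiny_model_config()),
               "non-finite training label")
})

test_that("prediction is stateless, order independent, and composes fuse_and_predict", {
  ds <- tiny_dataset()
  fit <- train_physdual(ds$items, tiny_model_config(),
                        train_config(max_epochs = 5, patience = 4), seed = 2)
  p <- predict(fit, ds$items)
  p_rev <- predict(fit, rev(ds$items))
  expect_equal(p_rev$predicted_energy[match(p$ligand_id, p_rev$ligand_id)],
               p$predicted_energy)
  expect_equal(nrow(predict(fit, list())), 0L)
  # composition with the explicit encode/fuse path
  it <- ds$items[[1]]
  manual <- fuse_and_predict(fit$model,
                             encode_drug(fit$model, it$drug),
                             encode_protein(fit$model, it$protein),
                             it$physics, it$id)
  expect_equal(manual$predicted_energy, p$predicted_energy[p$ligand_id == it$id],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("seed averaging is the per-ligand arithmetic mean", {
  p1 <- data.frame(ligand_id = c("a", "b"), predicted_energy = c(-10, -11))
  p2 <- data.frame(ligand_id = c("b", "a"), predicted_energy = c(-11, -10))
  avg <- seed_average(list(p1, p2))
  expect_equal(avg$predicted_energy[avg$ligand_id == "a"], -10)
  p3 <- data.frame(ligand_id = c("a", "b"), predicted_energy = c(-10, -11))
  p4 <- data.frame(ligand_id = c("a", "b"), predicted_energy = c(-11, -11))
  expect_equal(seed_average(list(p3, p4))$predicted_energy, c(-10.5, -11))
  expect_equal(seed_average(list(p1)), p1[order(p1$ligand_id), ],
               ignore_attr = TRUE)
  expect_error(seed_average(list(p1, data.frame(ligand_id = "c",
                                                predicted_energy = 1))),
               "different ligands")
})

test_that("metrics match hand-computed references", {
  r <- suppressWarnings(compute_metrics(c(1, 2, 3), c(2, 2, 2)))
  expect_equal(r$mae, 2 / 3)
  expect_equal(r$mse, 2 / 3)
  expect_equal(r$rmse, sqrt(2 / 3))
  expect_equal(r$r2, 0)
  perfect <- suppressWarnings(compute_metrics(c(-3, -5, -9), c(-3, -5, -9)))
  expect_equal(c(perfect$mae, perfect$mse, perfect$rmse), c(0, 0, 0))
  expect_equal(perfect$r2, 1)
  expect_warning(compute_metrics(c(2, 2), c(1, 3)), "constant reference")
  expect_warning(compute_metrics(c(1, 2, 3), c(1, 2, 2.5)), "n = 3")
  expect_error(compute_metrics(1:3, 1:2), "length mismatch")
})

test_that("metric identities hold on random vectors", {
  set.seed(99)
  for (k in 1:1000) {
    n <- sample(2:30, 1)
    y <- stats::rnorm(n); yhat <- stats::rnorm(n)
    r <- suppressWarnings(compute_metrics(y, yhat))
    expect_equal(r$rmse^2, r$mse, tolerance = 1e-10)
    expect_gte(r$rmse + 1e-12, r$mae)
    expect_lte(r$r2, 1)
  }
})

test_that("comparison tables mark gaps and zero out the self-comparison", {
  scores <- data.frame(
    method = c("vina", "vina", "other", "other"),
    ligand_id = c("a", "b", "a", "b"),
    score_kcal_mol = c(-9.9, -10.6, -9.5, -10.0))
  ct <- comparison_table(scores, reference = "vina")
  self <- ct$metrics[ct$metrics$method == "vina", ]
  expect_equal(self$mae, 0)
  expect_equal(self$rmse, 0)
  # disjoint ligand sets leave explicit NA gap markers
  scores2 <- data.frame(method = c("m1", "m2"), ligand_id = c("a", "b"),
                        score_kcal_mol = c(-1, -2))
  ct2 <- comparison_table(scores2, reference = "m1")
  expect_true(is.na(ct2$table[ct2$table$method == "m1", "b"]))
  expect_true(is.na(ct2$table[ct2$table$method == "m2", "a"]))
  expect_error(comparison_table(scores, reference = "absent"),
               "not present")
})

test_that("the fixture reference table round-trips through the comparison", {
  fx <- load_paper_fixtures()
  ct <- comparison_table(fx$reference_scores, reference = "vina")
  panel <- c("brexpiprazole", "donepezil", "galantamine", "rivastigmine")
  vina_row <- as.numeric(ct$table[ct$table$method == "vina", panel])
  expect_equal(vina_row, c(-9.9, -10.6, -7.4, -7.0))
})
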