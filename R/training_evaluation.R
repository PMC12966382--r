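# Training protocol and evaluation metrics.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam, learning rate 5e-4,
#' weight decay 1e-5, dropout 0.2, batch size 1 ligand-protein pair, up to
#' 300 epochs with early stopping at a patience of 30 epochs, and five
#' random seeds for run-to-run averaging.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to gradients.
#' @param dropout Dropout probability during training.
#' @param batch_size Pairs per update (the protocol uses 1).
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in epochs.
#' @param seeds Integer vector of training seeds (default 5).
#' @param monitor `"auto"` monitors validation loss when a validation set
#'   is supplied and training loss otherwise; or force `"train"` /
#'   `"validation"`.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, weight_decay = 1e-5,
                         dropout = 0.2, batch_size = 1L, max_epochs = 300L,
                         patience = 30L, seeds = 1:5,
                         monitor = c("auto", "train", "validation")) {
  monitor <- match.arg(monitor)
  stopifnot(learning_rate > 0, weight_decay >= 0, dropout >= 0, dropout < 1,
            batch_size >= 1L, max_epochs >= 1L, patience >= 1L,
            patience < max_epochs, length(seeds) >= 1L)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 dropout = dropout, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seeds = as.integer(seeds),
                 monitor = monitor, loss = "mse"),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

dataset_inputs <- function(dataset, use_physics) {
  lapply(dataset, function(item) {
    phys <- if (use_physics) item$physics else NULL
    build_model_input(item$drug, item$protein, phys, item$label)
  })
}

eval_mse <- function(model, inputs) {
  err <- vapply(inputs, function(inp) {
    model_forward(model, inp)$y - inp$label
  }, numeric(1))
  mean(err^2)
}

#' Train the dual-branch model
#'
#' Minimizes the mean squared error between predictions and reference
#' scores with Adam, one ligand-protein pair per update.  Targets are
#' standardized internally (z-score of the training labels) for numerical
#' conditioning and the transform is inverted at prediction time; reported
#' losses are on the original kcal/mol scale.  Early stopping keeps the
#' weights of the best monitored epoch.  Every stochastic component (weight
#' initialization, epoch shuffling, dropout masks) is driven by `seed`, so
#' a rerun reproduces the result exactly.
#'
#' @param dataset List of items, each a list with `drug` (featurized
#'   `ligand_graph`), `protein` (featurized `protein_graph`), `physics`
#'   (normalized feature vector) and `label` (kcal/mol).  Ligand-level
#'   separation across dataset splits is the caller's responsibility.
#' @param model_config A [physdual_config()].
#' @param config A [train_config()].
#' @param seed Integer seed for this run.
#' @param validation Optional held-out item list monitored for early
#'   stopping.
#' @return A `physdual_fit`: list with `model`, `loss_curve` (data.frame
#'   `epoch`, `train_loss`, optionally `val_loss`, kcal/mol squared),
#'   `stopped_epoch`, `best_epoch`, and `seed`.
#' @export
train_physdual <- function(dataset, model_config = physdual_config(),
                           config = train_config(), seed = 1L,
                           validation = NULL) {
  stopifnot(length(dataset) >= 1L)
  labels <- vapply(dataset, `[[`, numeric(1), "label")
  if (any(!is.finite(labels))) stop("non-finite training label", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  inputs <- dataset_inputs(dataset, model_config$use_physics)
  val_inputs <- if (!is.null(validation))
    dataset_inputs(validation, model_config$use_physics)
  model <- init_physdual_model(ncol(inputs[[1]]$Xd), ncol(inputs[[1]]$Xp),
                               model_config, seed = seed)
  model$y_center <- mean(labels)
  model$y_scale <- if (length(labels) > 1L && stats::sd(labels) > 0)
    stats::sd(labels) else 1
  targets_std <- (labels - model$y_center) / model$y_scale

  monitor_val <- switch(config$monitor,
                        auto = !is.null(val_inputs),
                        validation = {
                          if (is.null(val_inputs)) {
                            stop("monitor = 'validation' needs a validation set",
                                 call. = FALSE)
                          }
                          TRUE
                        },
                        train = FALSE)
  p_drop <- config$dropout
  nhid <- length(model_config$fusion_dims)
  state <- adam_init(model$params)
  n <- length(inputs)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  curve_train <- numeric(0); curve_val <- numeric(0)
  epoch <- 0L
  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    order <- sample.int(n)
    ep_loss <- 0
    for (idx in order) {
      masks <- if (p_drop > 0) {
        # dropout after every graph-convolution layer (node states, both
        # branches) and on the head's hidden units, the usual placement
        # for this architecture family; the analytic physics features
        # reach the head unmasked
        draw <- function(n, d) {
          matrix((stats::runif(n * d) >= p_drop) / (1 - p_drop), n, d)
        }
        inp <- inputs[[idx]]
        list(drug = lapply(model_config$drug_hidden_dims, function(d) {
               draw(nrow(inp$Xd), d)
             }),
             protein = lapply(model_config$protein_hidden_dims, function(d) {
               draw(nrow(inp$Xp), d)
             }),
             hidden = lapply(model_config$fusion_dims, function(d) {
               (stats::runif(d) >= p_drop) / (1 - p_drop)
             }))
      } else NULL
      fw <- model_forward(model, inputs[[idx]], dropout_masks = masks)
      err <- fw$y_std - targets_std[idx]
      if (!is.finite(err)) {
        stop(sprintf("non-finite loss at epoch %d, item '%s'",
                     epoch, inputs[[idx]]$id), call. = FALSE)
      }
      ep_loss <- ep_loss + err^2
      grads <- model_backward(model, inputs[[idx]], fw, 2 * err)
      upd <- adam_step(model$params, grads, state,
                       config$learning_rate, config$weight_decay)
      model$params <- upd$params
      state <- upd$state
    }
    # The loss curve and the monitored quantity are the dropout-free MSE of
    # the current weights, so early stopping is not driven by mask noise.
    train_loss <- eval_mse(model, inputs)
    curve_train[epoch] <- train_loss
    monitored <- train_loss
    if (monitor_val) {
      val_loss <- eval_mse(model, val_inputs)
      curve_val[epoch] <- val_loss
      monitored <- val_loss
    }
    if (monitored < best$loss - 1e-12) {
      best <- list(loss = monitored, params = model$params, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  model$params <- best$params
  curve <- data.frame(epoch = seq_len(epoch), train_loss = curve_train)
  if (monitor_val) curve$val_loss <- curve_val
  structure(list(model = model,
                 loss_curve = structure(curve, class = c("loss_curve",
                                                         "data.frame")),
                 stopped_epoch = epoch, best_epoch = best$epoch,
                 seed = as.integer(seed), config = config),
            class = "physdual_fit")
}

#' Predict binding scores for ligand-protein pairs
#'
#' Deterministic, order-independent inference (dropout inactive).
#'
#' @param object A `physdual_fit` or `physdual_model`.
#' @param pairs List of items with `drug`, `protein`, and `physics` (as in
#'   [train_physdual()]); labels are ignored.
#' @param ... Unused.
#' @return data.frame with `ligand_id` and `predicted_energy` (kcal/mol).
#' @export
predict.physdual_fit <- function(object, pairs, ...) {
  predict(object$model, pairs, ...)
}

#' @rdname predict.physdual_fit
#' @export
predict.physdual_model <- function(object, pairs, ...) {
  if (!length(pairs)) {
    return(data.frame(ligand_id = character(0),
                      predicted_energy = numeric(0)))
  }
  inputs <- dataset_inputs(pairs, object$config$use_physics)
  data.frame(ligand_id = vapply(inputs, `[[`, character(1), "id"),
             predicted_energy = vapply(inputs, function(inp) {
               model_forward(object, inp)$y
             }, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Average predictions across seeds
#'
#' @param predictions List of prediction data.frames (one per seed), each
#'   covering the same ligand set.
#' @return data.frame with the per-ligand arithmetic mean prediction.
#' @export
seed_average <- function(predictions) {
  stopifnot(length(predictions) >= 1L)
  ids <- sort(predictions[[1]]$ligand_id)
  for (p in predictions) {
    if (!identical(sort(p$ligand_id), ids)) {
      stop("prediction sets cover different ligands", call. = FALSE)
    }
  }
  mat <- vapply(predictions, function(p) {
    p$predicted_energy[match(ids, p$ligand_id)]
  }, numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids))
  data.frame(ligand_id = ids, predicted_energy = rowMeans(mat),
             stringsAsFactors = FALSE)
}

#' Regression metrics for binding-score prediction
#'
#' MAE, MSE, RMSE (`sqrt(MSE)`), the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`, and the per-item percentage error
#' `100 |y - yhat| / |y|`.
#'
#' @param y Reference scores (kcal/mol).
#' @param yhat Predicted scores.
#' @param ids Optional item identifiers.
#' @return A `metrics_report`: list with `per_item` data.frame (`id`, `y`,
#'   `yhat`, `abs_error`, `pct_error`), `mae`, `mse`, `rmse`, `r2`, `n`.
#' @details `R^2` is `NaN` (with a warning) when all reference values are
#'   identical.  With fewer than 8 items a warning flags that `R^2`
#'   measures the fit to the reference scores only, not generalization.
#' @export
compute_metrics <- function(y, yhat, ids = NULL) {
  if (length(y) != length(yhat)) {
    stop(sprintf("length mismatch: %d reference vs %d predicted values",
                 length(y), length(yhat)), call. = FALSE)
  }
  stopifnot(length(y) >= 1L)
  if (is.null(ids)) ids <- as.character(seq_along(y))
  err <- y - yhat
  mae <- mean(abs(err))
  mse <- mean(err^2)
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) {
    warning("R^2 is undefined for constant reference values; reporting NaN")
    r2 <- NaN
  } else {
    r2 <- 1 - sum(err^2) / sstot
    if (length(y) < 8L) {
      warning(sprintf("R^2 on n = %d items reflects fit to the reference scores, not generalization",
                      length(y)))
    }
  }
  per_item <- data.frame(id = ids, y = y, yhat = yhat, abs_error = abs(err),
                         pct_error = 100 * abs(err) / abs(y),
                         stringsAsFactors = FALSE)
  structure(list(per_item = per_item, mae = mae, mse = mse,
                 rmse = sqrt(mse), r2 = r2, n = length(y)),
            class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d | MAE %.4f | MSE %.4f | RMSE %.4f | R2 %.4f\n",
              x$n, x$mae, x$mse, x$rmse, x$r2))
  print(x$per_item, row.names = FALSE)
  invisible(x)
}

#' Side-by-side comparison of per-ligand scores across methods
#'
#' Builds a method-by-ligand score matrix (missing entries stay `NA` as
#' explicit gap markers) and computes metrics for each method against a
#' chosen reference column.
#'
#' @param scores data.frame with columns `method`, `ligand_id`,
#'   `score_kcal_mol` (external docking scores are inputs, never computed
#'   here).
#' @param reference Method name used as the reference.
#' @return A `comparison_table`: list with `table` (wide data.frame,
#'   methods x ligands) and `metrics` (per-method MAE/MSE/RMSE/R2 versus
#'   the reference, over the ligands both methods cover).
#' @export
comparison_table <- function(scores, reference) {
  stopifnot(all(c("method", "ligand_id", "score_kcal_mol") %in% names(scores)))
  if (!reference %in% scores$method) {
    stop(sprintf("reference method '%s' is not present", reference),
         call. = FALSE)
  }
  ligands <- unique(scores$ligand_id)
  methods <- unique(scores$method)
  wide <- data.frame(method = methods, stringsAsFactors = FALSE)
  for (lg in ligands) {
    col <- rep(NA_real_, length(methods))
    sub <- scores[scores$ligand_id == lg, ]
    col[match(sub$method, methods)] <- sub$score_kcal_mol
    wide[[lg]] <- col
  }
  ref_row <- as.numeric(wide[wide$method == reference, ligands])
  metr <- do.call(rbind, lapply(methods, function(m) {
    row <- as.numeric(wide[wide$method == m, ligands])
    ok <- !is.na(row) & !is.na(ref_row)
    if (!any(ok)) {
      return(data.frame(method = m, n = 0L, mae = NA_real_, mse = NA_real_,
                        rmse = NA_real_, r2 = NA_real_))
    }
    rep <- suppressWarnings(compute_metrics(ref_row[ok], row[ok],
                                            ids = ligands[ok]))
    data.frame(method = m, n = rep$n, mae = rep$mae, mse = rep$mse,
               rmse = rep$rmse, r2 = rep$r2)
  }))
  structure(list(table = wide, metrics = metr, reference = reference),
            class = "comparison_table")
}

#' @exportS3Method base::print
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> reference: %s\n", x$reference))
  print(x$table, row.names = FALSE)
  invisible(x)
}
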