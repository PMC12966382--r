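# The dual-branch architecture: a two-layer graph-convolution encoder for
# the ligand graph, a one-layer graph-convolution encoder for the linear
# residue graph, mean-pooling readouts, and a dense head over the fused
# (drug, protein, normalized physics) vector that outputs kcal/mol.
#
# Layers use the symmetric-normalized convolution
#   H' = act( D^-1/2 (A + I) D^-1/2 H W + b ),
# which together with mean pooling makes the embeddings exactly invariant
# to node reordering.  Forward and backward passes are written out by hand
# (base R + Matrix); gradients are checked against finite differences in
# the test suite.

#' Model configuration
#'
#' @param drug_hidden_dims Two integers: widths of the two drug GCN layers
#'   (default `c(64, 64)`).
#' @param protein_hidden_dims Integer vector: widths of the protein GCN
#'   layers (default 64, one layer).
#' @param fusion_dims Integer vector: hidden widths of the dense head
#'   (default `c(128, 64)`), followed by the scalar output.
#' @param dropout Dropout probability on the head's hidden activations
#'   during training (default 0.2; inactive at inference).
#' @param activation `"relu"` (default) or `"tanh"`.
#' @param physics_feature_count Number of normalized physics features fused
#'   into the head (default 2: normalized E_Coul and E_LJ; E_phys is their
#'   sum and would be redundant).
#' @param use_physics If `FALSE`, the physics inputs are dropped entirely
#'   (the ablation model).
#' @return A `physdual_config` list.
#' @export
physdual_config <- function(drug_hidden_dims = c(64L, 64L),
                            protein_hidden_dims = 64L,
                            fusion_dims = c(128L, 64L),
                            dropout = 0.2, activation = c("relu", "tanh"),
                            physics_feature_count = 2L,
                            use_physics = TRUE) {
  activation <- match.arg(activation)
  stopifnot(length(drug_hidden_dims) == 2L, all(drug_hidden_dims >= 1L),
            all(protein_hidden_dims >= 1L), all(fusion_dims >= 1L),
            dropout >= 0, dropout < 1, physics_feature_count >= 0L)
  structure(list(drug_hidden_dims = as.integer(drug_hidden_dims),
                 protein_hidden_dims = as.integer(protein_hidden_dims),
                 fusion_dims = as.integer(fusion_dims),
                 dropout = dropout, activation = activation,
                 physics_feature_count =
                   if (use_physics) as.integer(physics_feature_count) else 0L,
                 use_physics = use_physics),
            class = "physdual_config")
}

act_fn <- function(x, activation) {
  if (activation == "relu") pmax(x, 0) else tanh(x)
}
act_grad <- function(pre, activation) {
  if (activation == "relu") (pre > 0) * 1 else 1 - tanh(pre)^2
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize a model with random weights
#'
#' @param drug_in_dim Atom feature length.
#' @param protein_in_dim Residue feature length.
#' @param config A [physdual_config()].
#' @param seed Integer seed controlling the weight draw.
#' @return A `physdual_model` (untrained; `y_center`/`y_scale` identity).
#' @export
init_physdual_model <- function(drug_in_dim, protein_in_dim,
                                config = physdual_config(), seed = 0L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  d <- config$drug_hidden_dims
  p <- config$protein_hidden_dims
  fuse_in <- d[2] + p[length(p)] + config$physics_feature_count
  dims <- c(fuse_in, config$fusion_dims, 1L)
  params <- list(Wd1 = glorot(drug_in_dim, d[1]), bd1 = numeric(d[1]),
                 Wd2 = glorot(d[1], d[2]), bd2 = numeric(d[2]))
  prev <- protein_in_dim
  for (k in seq_along(p)) {
    params[[paste0("Wp", k)]] <- glorot(prev, p[k])
    params[[paste0("bp", k)]] <- numeric(p[k])
    prev <- p[k]
  }
  for (k in seq_len(length(dims) - 1L)) {
    params[[paste0("Wf", k)]] <- glorot(dims[k], dims[k + 1])
    params[[paste0("bf", k)]] <- numeric(dims[k + 1])
  }
  structure(list(config = config, params = params,
                 drug_in_dim = drug_in_dim, protein_in_dim = protein_in_dim,
                 y_center = 0, y_scale = 1, scalers = NULL,
                 feature_schemes = list(ligand = "default",
                                        residue = "default"),
                 seed = as.integer(seed)),
            class = "physdual_model")
}

# Symmetric-normalized adjacency D^-1/2 (A + I) D^-1/2 as a sparse matrix.
#' @noRd
norm_adjacency <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  ii <- c(seq_len(n), edges[, 1], edges[, 2])
  jj <- c(seq_len(n), edges[, 2], edges[, 1])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  dinv <- 1 / sqrt(Matrix::rowSums(A))
  Matrix::Diagonal(x = dinv) %*% A %*% Matrix::Diagonal(x = dinv)
}

ligand_adjacency <- function(graph) {
  norm_adjacency(nrow(graph$atoms), cbind(graph$bonds$i, graph$bonds$j) + 1L)
}

protein_adjacency <- function(graph) {
  edges <- graph$chain_edges
  if (!is.null(graph$contact_edges) && nrow(graph$contact_edges)) {
    edges <- rbind(edges, graph$contact_edges)
  }
  norm_adjacency(nrow(graph$residues), edges + 1L)
}

# Forward through a stack of GCN layers with mean-pooling readout.
# `masks` (training only) holds one n x d dropout mask per layer, applied
# to the post-activation node states.  Returns the embedding plus caches
# for backprop.
gcn_forward <- function(X, Ahat, Ws, bs, activation, masks = NULL) {
  H <- X
  caches <- vector("list", length(Ws))
  for (k in seq_along(Ws)) {
    AX <- as.matrix(Ahat %*% H)
    Z <- AX %*% Ws[[k]] + matrix(bs[[k]], nrow(AX), length(bs[[k]]),
                                 byrow = TRUE)
    caches[[k]] <- list(AX = AX, Z = Z)
    H <- act_fn(Z, activation)
    if (!is.null(masks)) H <- H * masks[[k]]
  }
  list(emb = colMeans(H), H = H, caches = caches, masks = masks)
}

# Backprop d(loss)/d(embedding) through the GCN stack; returns weight/bias
# gradients (same order as Ws).
gcn_backward <- function(d_emb, X, Ahat, Ws, bs, activation, fw) {
  n <- nrow(fw$H)
  dH <- matrix(d_emb, n, length(d_emb), byrow = TRUE) / n
  gW <- vector("list", length(Ws)); gb <- vector("list", length(Ws))
  for (k in rev(seq_along(Ws))) {
    cache <- fw$caches[[k]]
    if (!is.null(fw$masks)) dH <- dH * fw$masks[[k]]
    dZ <- dH * act_grad(cache$Z, activation)
    gW[[k]] <- t(cache$AX) %*% dZ
    gb[[k]] <- colSums(dZ)
    if (k > 1L) {
      dAX <- dZ %*% t(Ws[[k]])
      dH <- as.matrix(Matrix::t(Ahat) %*% dAX)
    }
  }
  list(gW = gW, gb = gb)
}

drug_layer_names <- function() list(W = c("Wd1", "Wd2"), b = c("bd1", "bd2"))
protein_layer_names <- function(config) {
  k <- seq_along(config$protein_hidden_dims)
  list(W = paste0("Wp", k), b = paste0("bp", k))
}
head_layer_names <- function(config) {
  k <- seq_len(length(config$fusion_dims) + 1L)
  list(W = paste0("Wf", k), b = paste0("bf", k))
}

#' Precompute the model input for one ligand-protein pair
#'
#' Caches the feature matrices and normalized adjacencies so repeated
#' training passes do not rebuild them.
#'
#' @param ligand A featurized `ligand_graph`.
#' @param protein A featurized `protein_graph`.
#' @param physics Numeric vector of min-max normalized physics features
#'   (values in `[0, 1]`), or `NULL` for the ablation model.
#' @param label Optional reference score in kcal/mol.
#' @return A `physdual_input` list.
#' @export
build_model_input <- function(ligand, protein, physics = NULL,
                              label = NA_real_) {
  stopifnot(inherits(ligand, "ligand_graph"), inherits(protein, "protein_graph"))
  if (is.null(ligand$atom_features)) {
    stop("ligand graph is not featurized", call. = FALSE)
  }
  if (is.null(protein$residue_features)) {
    stop("protein graph is not featurized", call. = FALSE)
  }
  structure(list(id = ligand$record$id,
                 Xd = ligand$atom_features, Ad = ligand_adjacency(ligand),
                 Xp = protein$residue_features, Ap = protein_adjacency(protein),
                 physics = physics, label = label),
            class = "physdual_input")
}

check_physics_features <- function(model, physics) {
  k <- model$config$physics_feature_count
  if (k == 0L) return(numeric(0))
  if (is.null(physics) || length(physics) != k) {
    stop(sprintf("expected %d physics feature(s)", k), call. = FALSE)
  }
  if (any(physics < -1e-9 | physics > 1 + 1e-9)) {
    stop("physics features must be min-max normalized to [0, 1]",
         call. = FALSE)
  }
  pmin(1, pmax(0, physics))
}

# Full forward pass.  dropout_masks (training only) is a list with
# `drug` / `protein` (per-GCN-layer node-state masks) and `hidden` (one
# mask per hidden head layer), each already scaled by 1/(1-p) upstream.
model_forward <- function(model, input, dropout_masks = NULL) {
  cfg <- model$config
  p <- model$params
  if (ncol(input$Xd) != model$drug_in_dim) {
    stop(sprintf("atom feature length %d does not match the model input dim %d",
                 ncol(input$Xd), model$drug_in_dim), call. = FALSE)
  }
  if (ncol(input$Xp) != model$protein_in_dim) {
    stop(sprintf("residue feature length %d does not match the model input dim %d",
                 ncol(input$Xp), model$protein_in_dim), call. = FALSE)
  }
  dn <- drug_layer_names(); pn <- protein_layer_names(cfg)
  fw_d <- gcn_forward(input$Xd, input$Ad, p[dn$W], p[dn$b], cfg$activation,
                      masks = dropout_masks$drug)
  fw_p <- gcn_forward(input$Xp, input$Ap, p[pn$W], p[pn$b], cfg$activation,
                      masks = dropout_masks$protein)
  phys <- check_physics_features(model, input$physics)
  z <- c(fw_d$emb, fw_p$emb, phys)
  hn <- head_layer_names(cfg)
  nhid <- length(cfg$fusion_dims)
  acts <- list(); pres <- list()
  h <- z
  for (k in seq_len(nhid)) {
    a <- as.numeric(t(p[[hn$W[k]]]) %*% h) + p[[hn$b[k]]]
    pres[[k]] <- a
    h <- act_fn(a, cfg$activation)
    if (!is.null(dropout_masks)) h <- h * dropout_masks$hidden[[k]]
    acts[[k]] <- h
  }
  k_out <- nhid + 1L
  y_std <- as.numeric(t(p[[hn$W[k_out]]]) %*% h) + p[[hn$b[k_out]]]
  y <- model$y_center + model$y_scale * y_std
  list(y = y, y_std = y_std, z = z, fw_d = fw_d, fw_p = fw_p,
       pres = pres, acts = acts, phys = phys, dropout_masks = dropout_masks)
}

# Gradient of a squared-error loss in standardized space for one item.
model_backward <- function(model, input, fw, d_y_std) {
  cfg <- model$config; p <- model$params
  hn <- head_layer_names(cfg)
  nhid <- length(cfg$fusion_dims)
  grads <- list()
  h_last <- if (nhid) fw$acts[[nhid]] else fw$z
  k_out <- nhid + 1L
  grads[[hn$W[k_out]]] <- matrix(h_last * d_y_std, ncol = 1L)
  grads[[hn$b[k_out]]] <- d_y_std
  dh <- as.numeric(p[[hn$W[k_out]]]) * d_y_std
  for (k in rev(seq_len(nhid))) {
    # dropout mask is folded into acts; its scaling already entered forward
    if (!is.null(fw$dropout_masks)) dh <- dh * fw$dropout_masks$hidden[[k]]
    da <- dh * act_grad(fw$pres[[k]], cfg$activation)
    h_in <- if (k > 1L) fw$acts[[k - 1L]] else fw$z
    grads[[hn$W[k]]] <- outer(h_in, da)
    grads[[hn$b[k]]] <- da
    dh <- as.numeric(p[[hn$W[k]]] %*% da)
  }
  dz <- dh
  dcfg <- cfg$drug_hidden_dims
  d_demb <- dz[seq_len(dcfg[2])]
  off <- dcfg[2]
  pdim <- cfg$protein_hidden_dims[length(cfg$protein_hidden_dims)]
  d_pemb <- dz[off + seq_len(pdim)]
  dn <- drug_layer_names(); pn <- protein_layer_names(cfg)
  gd <- gcn_backward(d_demb, input$Xd, input$Ad, p[dn$W], p[dn$b],
                     cfg$activation, fw$fw_d)
  gp <- gcn_backward(d_pemb, input$Xp, input$Ap, p[pn$W], p[pn$b],
                     cfg$activation, fw$fw_p)
  for (k in seq_along(dn$W)) {
    grads[[dn$W[k]]] <- gd$gW[[k]]; grads[[dn$b[k]]] <- gd$gb[[k]]
  }
  for (k in seq_along(pn$W)) {
    grads[[pn$W[k]]] <- gp$gW[[k]]; grads[[pn$b[k]]] <- gp$gb[[k]]
  }
  grads
}

#' Encode a ligand graph into its learned embedding
#'
#' @param model A `physdual_model`.
#' @param graph A featurized `ligand_graph`.
#' @return Numeric embedding of length `drug_hidden_dims[2]`.
#' @export
encode_drug <- function(model, graph) {
  stopifnot(inherits(model, "physdual_model"), inherits(graph, "ligand_graph"))
  if (is.null(graph$atom_features)) {
    stop("ligand graph is not featurized", call. = FALSE)
  }
  if (ncol(graph$atom_features) != model$drug_in_dim) {
    stop(sprintf("atom feature length %d does not match the model input dim %d",
                 ncol(graph$atom_features), model$drug_in_dim), call. = FALSE)
  }
  dn <- drug_layer_names()
  gcn_forward(graph$atom_features, ligand_adjacency(graph),
              model$params[dn$W], model$params[dn$b],
              model$config$activation)$emb
}

#' Encode a protein graph into its learned embedding
#'
#' @param model A `physdual_model`.
#' @param graph A featurized `protein_graph`.
#' @return Numeric embedding of length `tail(protein_hidden_dims, 1)`.
#' @export
encode_protein <- function(model, graph) {
  stopifnot(inherits(model, "physdual_model"), inherits(graph, "protein_graph"))
  if (is.null(graph$residue_features)) {
    stop("protein graph is not featurized", call. = FALSE)
  }
  if (ncol(graph$residue_features) != model$protein_in_dim) {
    stop(sprintf("residue feature length %d does not match the model input dim %d",
                 ncol(graph$residue_features), model$protein_in_dim),
         call. = FALSE)
  }
  pn <- protein_layer_names(model$config)
  gcn_forward(graph$residue_features, protein_adjacency(graph),
              model$params[pn$W], model$params[pn$b],
              model$config$activation)$emb
}

#' Fuse embeddings with physics features and predict a binding score
#'
#' Concatenates the drug embedding, protein embedding and normalized
#' physics features and runs the dense head (dropout inactive).
#'
#' @param model A `physdual_model`.
#' @param drug_emb,protein_emb Embeddings from [encode_drug()] /
#'   [encode_protein()].
#' @param physics_features Min-max normalized vector in `[0, 1]` (length
#'   `physics_feature_count`), or `NULL` for an ablation model.
#' @param ligand_id Identifier carried into the result.
#' @return An `affinity_prediction`: list with `ligand_id` and
#'   `predicted_energy` (kcal/mol).
#' @export
fuse_and_predict <- function(model, drug_emb, protein_emb,
                             physics_features = NULL, ligand_id = NA_character_) {
  cfg <- model$config
  stopifnot(length(drug_emb) == cfg$drug_hidden_dims[2],
            length(protein_emb) ==
              cfg$protein_hidden_dims[length(cfg$protein_hidden_dims)])
  phys <- check_physics_features(model, physics_features)
  z <- c(drug_emb, protein_emb, phys)
  hn <- head_layer_names(cfg)
  h <- z
  for (k in seq_len(length(cfg$fusion_dims))) {
    h <- act_fn(as.numeric(t(model$params[[hn$W[k]]]) %*% h) +
                  model$params[[hn$b[k]]], cfg$activation)
  }
  k_out <- length(cfg$fusion_dims) + 1L
  y_std <- as.numeric(t(model$params[[hn$W[k_out]]]) %*% h) +
    model$params[[hn$b[k_out]]]
  y <- model$y_center + model$y_scale * y_std
  structure(list(ligand_id = ligand_id, predicted_energy = unname(y)),
            class = "affinity_prediction")
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON bundle holding the weights, the model
#' configuration, the feature scheme names, the target scaling, and the
#' fitted min-max scalers, so predictions are reproducible end to end.
#'
#' @param model A `physdual_model`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `physdual_model`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(config = unclass(model$config),
              params = lapply(model$params, function(m) {
                list(dim = if (is.matrix(m)) dim(m) else integer(0),
                     x = as.numeric(m))
              }),
              drug_in_dim = model$drug_in_dim,
              protein_in_dim = model$protein_in_dim,
              y_center = model$y_center, y_scale = model$y_scale,
              scalers = lapply(model$scalers, unclass),
              feature_schemes = model$feature_schemes,
              seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(pp) {
    d <- unlist(pp$dim)
    if (is.numeric(d) && length(d) == 2L) matrix(pp$x, d[1], d[2])
    else as.numeric(pp$x)
  })
  cfg <- do.call(physdual_config, obj$config[c("drug_hidden_dims",
                                               "protein_hidden_dims",
                                               "fusion_dims", "dropout",
                                               "activation",
                                               "physics_feature_count",
                                               "use_physics")])
  scalers <- lapply(obj$scalers, function(s) {
    structure(list(lower = s$lower, upper = s$upper), class = "minmax_scaler")
  })
  structure(list(config = cfg, params = params,
                 drug_in_dim = obj$drug_in_dim,
                 protein_in_dim = obj$protein_in_dim,
                 y_center = obj$y_center, y_scale = obj$y_scale,
                 scalers = scalers, feature_schemes = obj$feature_schemes,
                 seed = obj$seed),
            class = "physdual_model")
}

#' @exportS3Method base::print
print.physdual_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<physdual_model> drug GCN %s | protein GCN %s | head %s -> 1 | physics features: %d\n",
              paste(cfg$drug_hidden_dims, collapse = "-"),
              paste(cfg$protein_hidden_dims, collapse = "-"),
              paste(cfg$fusion_dims, collapse = "-"),
              cfg$physics_feature_count))
  invisible(x)
}
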