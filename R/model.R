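#' Combine propagated and gated raw features
#'
#' The anti-oversmoothing core of the model: the high-level representation
#' `G^L X0` obtained by decoupled propagation is summed with a per-node gated
#' copy of the raw (underlying) features,
#' `G^L X0 + diag(sigma2(R)) X0`,
#' where `R` is a learnable vector (the diagonal of the adaptive retention
#' matrix) and `sigma2` squashes it into `(0, 1)`. Each node thus keeps a
#' learned fraction of its own low-level features regardless of how strongly
#' propagation has mixed it with its hypergraph neighbourhood.
#'
#' @param op an `"hg_operator"` (see [spectral_operator()]).
#' @param X0 raw node-feature matrix, one row per node.
#' @param L nonnegative integer propagation depth.
#' @param R numeric gate parameter vector, one entry per node.
#' @param sigma2 squashing nonlinearity (default [sigmoid]).
#' @return Matrix of the same shape as `X0`.
#' @export
adaptive_combine <- function(op, X0, L, R, sigma2 = sigmoid) {
  X0 <- as.matrix(X0)
  if (length(R) != nrow(X0)) {
    stopf("R has length %d but X0 has %d rows", length(R), nrow(X0))
  }
  propagate(op, X0, L) + sigma2(R) * X0
}

#' Fit a hypergraph convolutional classifier
#'
#' Fits the full transductive pipeline on a multimodal cohort: z-score each
#' modality on training-split statistics, build one KNN hypergraph per
#' modality and fuse them, precompute the decoupled propagation `G^L X0`,
#' then train the adaptive-retention gate and a two-layer fully connected
#' head (`fused width -> hidden -> C`) by full-batch Adam on the
#' cross-entropy of the training nodes. The hypergraph spans *all* nodes
#' (transductive semi-supervised setting); labels of test/unlabeled nodes
#' never enter the loss.
#'
#' @param dataset a [multimodal_dataset()] whose `split` marks training
#'   nodes; at least two classes must be present among them.
#' @param Z KNN neighbour count(s), recycled per modality (each hyperedge
#'   has `Z + 1` members including its centroid).
#' @param propagation `"spectral"` (symmetric normalized aggregator),
#'   `"spatial"` (row-stochastic aggregator), or `"gcn_clique"` (clique-
#'   expand the fused hypergraph and use the symmetric degree-normalized
#'   adjacency with self-loops — the plain-GCN baseline).
#' @param L number of decoupled propagation layers.
#' @param hidden hidden layer width of the transformation head.
#' @param dropout dropout probability applied to the input of each fully
#'   connected layer during training.
#' @param epochs full-batch Adam steps.
#' @param lr,weight_decay,lr_decay,lr_decay_every Adam learning rate, L2
#'   coefficient (applied to the two weight matrices and the gate vector,
#'   not the biases), multiplicative learning-rate decay factor and its
#'   epoch period.
#' @param gate `"adaptive"` (learn the per-node retention vector `R`) or
#'   `"static"` (fix every gate at `static_gate` and exclude `R` from the
#'   optimizer — the uniform-weighting ablation).
#' @param static_gate constant gate value under `gate = "static"`.
#' @param standardize z-score modalities on training-split statistics before
#'   KNN construction.
#' @param seed integer; fixes parameter initialization and dropout, making
#'   the fit exactly reproducible.
#' @return An object of class `"hgcn"` with components `parameters` (`R`,
#'   `theta1`, `bias1`, `theta2`, `bias2`), `history` (per-epoch loss,
#'   final training accuracy), `config`, `operator`, `X0`, `GL_X0`,
#'   `class_levels`, and the dataset bookkeeping needed by [predict.hgcn()].
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_subjects = 30, seed = 7))
#' fit <- hgcn(sim$dataset, Z = 3, epochs = 50, seed = 1)
#' predict(fit, subset = "test")
#' @export
hgcn <- function(dataset, Z = 5,
                 propagation = c("spectral", "spatial", "gcn_clique"),
                 L = 2, hidden = 128, dropout = 0.5, epochs = 600,
                 lr = 1e-3, weight_decay = 5e-4, lr_decay = 0.7,
                 lr_decay_every = 200, gate = c("adaptive", "static"),
                 static_gate = 0.5, standardize = TRUE, seed = 1) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  propagation <- match.arg(propagation)
  gate <- match.arg(gate)
  if (epochs < 1) stopf("epochs must be >= 1")

  train_mask <- dataset$split == "train"
  train_labels <- dataset$labels[train_mask]
  class_levels <- sort(unique(dataset$labels[!is.na(dataset$labels)]))
  C <- length(class_levels)
  if (length(unique(train_labels)) < 2) {
    stopf("training split must contain at least two classes")
  }

  work <- if (standardize) standardize_dataset(dataset, train_mask) else dataset
  fused <- fuse_modalities(work, Z)
  op <- build_operator(fused$hypergraph, propagation)
  X0 <- fused$features
  GL_X0 <- propagate(op, X0, L)

  n <- nrow(X0)
  d <- ncol(X0)
  y <- match(dataset$labels, class_levels)      # 1..C, NA for unlabeled
  Y <- matrix(0, n, C)
  Y[cbind(which(train_mask), y[train_mask])] <- 1
  n_train <- sum(train_mask)

  config <- list(Z = Z, propagation = propagation, L = L, hidden = hidden,
                 dropout = dropout, epochs = epochs, lr = lr,
                 weight_decay = weight_decay, lr_decay = lr_decay,
                 lr_decay_every = lr_decay_every, gate = gate,
                 static_gate = static_gate, standardize = standardize,
                 seed = seed)

  fit <- with_seed(seed, {
    params <- init_params(n, d, hidden, C)
    train_loop(params, X0, GL_X0, Y, train_mask, n_train, config)
  })
  params <- fit$params

  scores <- forward_scores(params, X0, GL_X0, config)
  pred_train <- apply(scores[train_mask, , drop = FALSE], 1, which.max)
  train_acc <- mean(pred_train == y[train_mask])

  structure(
    list(parameters = list(R = params$R, theta1 = params$W1,
                           bias1 = params$b1, theta2 = params$W2,
                           bias2 = params$b2),
         history = list(loss = fit$loss, train_accuracy = train_acc),
         config = config, operator = op, X0 = X0, GL_X0 = GL_X0,
         scores = scores, class_levels = class_levels,
         node_ids = dataset$node_ids, labels = dataset$labels,
         split = dataset$split),
    class = "hgcn"
  )
}

build_operator <- function(h, propagation) {
  if (propagation == "spectral") return(spectral_operator(h))
  if (propagation == "spatial") return(spatial_operator(h))
  # plain-GCN baseline on the clique expansion: D^{-1/2} (A + I) D^{-1/2}
  A <- clique_expand(h)$adjacency
  Ahat <- A + diag(nrow(A))
  dis <- 1 / sqrt(rowSums(Ahat))
  G <- (dis * Ahat) * rep(dis, each = nrow(A))
  new_operator("spectral", (G + t(G)) / 2, h$node_ids)
}

# Glorot-uniform weights, zero biases, zero gate (sigmoid(0) = 0.5: the
# neutral half-and-half blend of propagated and raw features).
init_params <- function(n, d, hidden, C) {
  glorot <- function(fan_in, fan_out) {
    s <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(fan_in * fan_out, -s, s), fan_in, fan_out)
  }
  list(R = rep(0, n), W1 = glorot(d, hidden), b1 = rep(0, hidden),
       W2 = glorot(hidden, C), b2 = rep(0, C))
}

train_loop <- function(params, X0, GL_X0, Y, train_mask, n_train, config) {
  adaptive <- config$gate == "adaptive"
  p_drop <- config$dropout
  decayed <- if (adaptive) c("R", "W1", "W2") else c("W1", "W2")
  opt_names <- if (adaptive) c("R", "W1", "b1", "W2", "b2") else
    c("W1", "b1", "W2", "b2")
  m <- v <- lapply(params[opt_names], function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0
  loss_hist <- numeric(config$epochs)
  train_idx <- which(train_mask)
  train_lab <- max.col(Y[train_idx, , drop = FALSE], ties.method = "first")

  for (epoch in seq_len(config$epochs)) {
    lr_t <- config$lr *
      config$lr_decay^(floor((epoch - 1) / config$lr_decay_every))

    g <- if (adaptive) sigmoid(params$R) else
      rep(config$static_gate, nrow(X0))
    Xc <- GL_X0 + g * X0
    if (p_drop > 0) {
      mask1 <- matrix(runif(length(Xc)) >= p_drop, nrow(Xc), ncol(Xc))
      D1 <- Xc * mask1 / (1 - p_drop)
    } else D1 <- Xc
    A1 <- sweep(D1 %*% params$W1, 2, params$b1, `+`)
    H1 <- relu(A1)
    if (p_drop > 0) {
      mask2 <- matrix(runif(length(H1)) >= p_drop, nrow(H1), ncol(H1))
      D2 <- H1 * mask2 / (1 - p_drop)
    } else D2 <- H1
    S <- sweep(D2 %*% params$W2, 2, params$b2, `+`)
    P <- softmax_rows(S)

    loss <- -mean(log(pmax(P[cbind(train_idx, train_lab)], 1e-300)))
    if (!is.finite(loss)) stopf("training diverged: non-finite loss at epoch %d", epoch)
    loss_hist[epoch] <- loss

    dS <- matrix(0, nrow(P), ncol(P))
    dS[train_idx, ] <- (P[train_idx, , drop = FALSE] -
                        Y[train_idx, , drop = FALSE]) / n_train
    grads <- list()
    grads$W2 <- crossprod(D2, dS)
    grads$b2 <- colSums(dS)
    dD2 <- dS %*% t(params$W2)
    dH1 <- if (p_drop > 0) dD2 * mask2 / (1 - p_drop) else dD2
    dA1 <- dH1 * (A1 > 0)
    grads$W1 <- crossprod(D1, dA1)
    grads$b1 <- colSums(dA1)
    if (adaptive) {
      dD1 <- dA1 %*% t(params$W1)
      dXc <- if (p_drop > 0) dD1 * mask1 / (1 - p_drop) else dD1
      grads$R <- unname(rowSums(dXc * X0)) * g * (1 - g)
    }

    t_step <- t_step + 1
    for (nm in opt_names) {
      gr <- grads[[nm]]
      if (nm %in% decayed) gr <- gr + config$weight_decay * params[[nm]]
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * gr
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * gr^2
      mhat <- m[[nm]] / (1 - beta1^t_step)
      vhat <- v[[nm]] / (1 - beta2^t_step)
      params[[nm]] <- params[[nm]] - lr_t * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, loss = loss_hist)
}

# Deterministic evaluation-mode forward pass: no dropout.
forward_scores <- function(params, X0, GL_X0, config) {
  g <- if (config$gate == "adaptive") sigmoid(params$R) else
    rep(config$static_gate, nrow(X0))
  Xc <- GL_X0 + g * X0
  H1 <- relu(sweep(Xc %*% params$W1, 2, params$b1, `+`))
  S <- sweep(H1 %*% params$W2, 2, params$b2, `+`)
  rownames(S) <- rownames(X0)
  S
}

#' Forward pass of a fitted model
#'
#' Recomputes class scores for all nodes. In training mode a fresh dropout
#' mask is drawn under `seed`; in evaluation mode (the default) the pass is
#' deterministic and equals `fitted(model)`.
#'
#' @param model a fitted [hgcn()] object.
#' @param training logical; draw dropout masks?
#' @param seed RNG seed used when `training = TRUE`.
#' @return Numeric `|Q| x C` class-score matrix.
#' @export
hgcn_forward <- function(model, training = FALSE, seed = NULL) {
  stopifnot(inherits(model, "hgcn"))
  p <- model$parameters
  params <- list(R = p$R, W1 = p$theta1, b1 = p$bias1, W2 = p$theta2,
                 b2 = p$bias2)
  if (!training || model$config$dropout == 0) {
    return(forward_scores(params, model$X0, model$GL_X0, model$config))
  }
  with_seed(seed, {
    pd <- model$config$dropout
    g <- if (model$config$gate == "adaptive") sigmoid(params$R) else
      rep(model$config$static_gate, nrow(model$X0))
    Xc <- model$GL_X0 + g * model$X0
    D1 <- apply_dropout(Xc, pd)
    H1 <- relu(sweep(D1 %*% params$W1, 2, params$b1, `+`))
    D2 <- apply_dropout(H1, pd)
    S <- sweep(D2 %*% params$W2, 2, params$b2, `+`)
    rownames(S) <- rownames(model$X0)
    S
  })
}

#' Predict classes for nodes of the fitted cohort
#'
#' Transductive prediction: scores were computed over the fixed node set the
#' model was fitted on, so prediction selects rows rather than embedding new
#' data. The predicted class is the argmax of the class scores; ties break
#' toward the lowest class index.
#'
#' @param object a fitted [hgcn()].
#' @param subset `"test"`, `"train"`, `"all"`, or a vector of node ids.
#' @param type `"class"` for labels, `"scores"` for the raw score matrix.
#' @param ... unused.
#' @return For `type = "class"`, a named integer vector of class labels (on
#'   the original label coding); for `"scores"`, the score matrix rows.
#' @export
predict.hgcn <- function(object, subset = "test",
                         type = c("class", "scores"), ...) {
  type <- match.arg(type)
  idx <- if (length(subset) == 1 && subset %in% c("test", "train", "all")) {
    if (subset == "all") seq_along(object$node_ids) else
      which(object$split == subset)
  } else {
    i <- match(as.character(subset), object$node_ids)
    if (anyNA(i)) stopf("unknown node id(s): %s",
                        paste(subset[is.na(i)], collapse = ", "))
    i
  }
  S <- object$scores[idx, , drop = FALSE]
  if (type == "scores") return(S)
  cls <- object$class_levels[apply(S, 1, which.max)]
  names(cls) <- object$node_ids[idx]
  cls
}

#' @export
fitted.hgcn <- function(object, ...) object$scores

#' @export
print.hgcn <- function(x, ...) {
  cat("Hypergraph convolutional classifier (transductive)\n")
  cat(sprintf("  %d nodes, %d classes, fused width %d\n",
              nrow(x$X0), length(x$class_levels), ncol(x$X0)))
  cat(sprintf("  propagation: %s, L = %d, Z = %s, gate: %s\n",
              x$config$propagation, x$config$L,
              paste(x$config$Z, collapse = "/"), x$config$gate))
  cat(sprintf("  final loss %.4f, training accuracy %.3f\n",
              tail(x$history$loss, 1), x$history$train_accuracy))
  invisible(x)
}

#' @export
summary.hgcn <- function(object, ...) {
  gates <- sigmoid(object$parameters$R)
  out <- list(config = object$config,
              final_loss = tail(object$history$loss, 1),
              train_accuracy = object$history$train_accuracy,
              gate_quartiles = quantile(gates, c(0, 0.25, 0.5, 0.75, 1)))
  class(out) <- "summary.hgcn"
  out
}

#' @export
print.summary.hgcn <- function(x, ...) {
  cat("Hypergraph convolutional classifier\n")
  cat(sprintf("  epochs %d, final cross-entropy %.4f, train accuracy %.3f\n",
              x$config$epochs, x$final_loss, x$train_accuracy))
  cat("  retention gates sigma(R):\n")
  print(round(x$gate_quartiles, 3))
  invisible(x)
}

#' @export
coef.hgcn <- function(object, ...) {
  c(object$parameters, list(gate = sigmoid(object$parameters$R)))
}

#' @export
plot.hgcn <- function(x, ...) {
  plot(seq_along(x$history$loss), x$history$loss, type = "l",
       xlab = "epoch", ylab = "training cross-entropy",
       main = "hgcn training loss", ...)
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single JSON file holding the learned parameters
#' (gate vector `R`, both transformation matrices and biases), the training
#' configuration, the node-id order, and the class levels. The propagation
#' operator and features are not stored; `read_hgcn()` rebuilds them from
#' the dataset, which must be the cohort the model was fitted on.
#'
#' @param model a fitted [hgcn()].
#' @param path JSON file path.
#' @param dataset the [multimodal_dataset()] the model was fitted on.
#' @return `write_hgcn()` returns `path` invisibly; `read_hgcn()` an
#'   `"hgcn"` object.
#' @export
write_hgcn <- function(model, path) {
  stopifnot(inherits(model, "hgcn"))
  payload <- list(
    parameters = lapply(model$parameters, unclass),
    config = model$config,
    node_ids = model$node_ids,
    class_levels = model$class_levels,
    history = model$history
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_hgcn
#' @export
read_hgcn <- function(path, dataset) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(payload$node_ids), dataset$node_ids)) {
    stopf("checkpoint node ids do not match the dataset")
  }
  cfg <- payload$config
  train_mask <- dataset$split == "train"
  work <- if (isTRUE(cfg$standardize)) standardize_dataset(dataset, train_mask)
          else dataset
  fused <- fuse_modalities(work, cfg$Z)
  op <- build_operator(fused$hypergraph, cfg$propagation)
  X0 <- fused$features
  GL_X0 <- propagate(op, X0, cfg$L)
  pars <- payload$parameters
  params <- list(R = as.numeric(pars$R), W1 = as.matrix(pars$theta1),
                 b1 = as.numeric(pars$bias1), W2 = as.matrix(pars$theta2),
                 b2 = as.numeric(pars$bias2))
  scores <- forward_scores(params, X0, GL_X0, cfg)
  structure(
    list(parameters = list(R = params$R, theta1 = params$W1,
                           bias1 = params$b1, theta2 = params$W2,
                           bias2 = params$b2),
         history = payload$history, config = cfg, operator = op, X0 = X0,
         GL_X0 = GL_X0, scores = scores,
         class_levels = as.integer(payload$class_levels),
         node_ids = dataset$node_ids, labels = dataset$labels,
         split = dataset$split),
    class = "hgcn"
  )
}
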