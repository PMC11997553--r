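# ---------------------------------------------------------------------------
# Fitting interface: configuration, Adam training loop, S3 methods,
# cross-validated pretraining, frozen fine-tuning, checkpoints.
# ---------------------------------------------------------------------------

#' Model and optimizer configuration
#'
#' Architecture and training hyperparameters for the dual-graph GVP-GNN
#' classifier. Defaults follow the published training setup: 3 GVP-GNN
#' layers, 2 GVPs in the message function, 4 GVPs in the feedforward
#' function, hidden dimension 182, batch size 64, dropout 0.6, learning
#' rate 1e-4 and Adam weight decay 1e-3 for pretraining (the fine-tuning
#' stage uses learning rate 1e-3, weight decay 1e-6, dropout 0.4 — see
#' [stabgvp_finetune()]).
#'
#' @param n_gnn_layers Number of message-passing layers (3).
#' @param n_message_gvps GVPs chained in the message function (2).
#' @param n_feedforward_gvps GVPs chained in the feedforward function (4).
#' @param hidden_dim Hidden scalar-channel width (182).
#' @param hidden_vector_dim Hidden vector-channel multiplicity (16).
#' @param edge_hidden_dim Edge embedding scalar width (32).
#' @param attention_dim Attention token width; must be divisible by
#'   `n_attention_heads`.
#' @param n_attention_heads Multi-head attention heads (4).
#' @param jk_mode Jumping-knowledge aggregation: "concat" (default)
#'   concatenates all layer outputs before pooling; "last" uses only the
#'   final layer.
#' @param batch_size Minibatch size (64).
#' @param dropout Dropout rate on scalar channels (0.6).
#' @param lr Adam learning rate (1e-4).
#' @param weight_decay L2 weight decay (1e-3).
#' @param epochs Training epochs (100).
#' @param patience Early-stopping patience on validation loss (10); only
#'   active when a validation set is supplied.
#' @param seed Integer seed controlling initialization, batching and
#'   dropout.
#' @return A validated list of class `stabgvp_config`.
#' @export
stabgvp_config <- function(n_gnn_layers = 3, n_message_gvps = 2,
                           n_feedforward_gvps = 4, hidden_dim = 182,
                           hidden_vector_dim = 16, edge_hidden_dim = 32,
                           attention_dim = 128, n_attention_heads = 4,
                           jk_mode = c("concat", "last"),
                           batch_size = 64, dropout = 0.6, lr = 1e-4,
                           weight_decay = 1e-3, epochs = 100,
                           patience = 10, seed = 1) {
  jk_mode <- match.arg(jk_mode)
  cfg <- list(n_gnn_layers = n_gnn_layers, n_message_gvps = n_message_gvps,
              n_feedforward_gvps = n_feedforward_gvps,
              hidden_dim = hidden_dim,
              hidden_vector_dim = hidden_vector_dim,
              edge_hidden_dim = edge_hidden_dim,
              attention_dim = attention_dim,
              n_attention_heads = n_attention_heads, jk_mode = jk_mode,
              batch_size = batch_size, dropout = dropout, lr = lr,
              weight_decay = weight_decay, epochs = epochs,
              patience = patience, seed = as.integer(seed))
  num <- c("n_gnn_layers", "n_message_gvps", "n_feedforward_gvps",
           "hidden_dim", "hidden_vector_dim", "edge_hidden_dim",
           "attention_dim", "n_attention_heads", "batch_size", "lr",
           "epochs", "patience")
  for (f in num) if (cfg[[f]] <= 0) stop("config field '", f,
                                         "' must be positive")
  if (cfg$weight_decay < 0) stop("weight_decay must be non-negative")
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop("dropout must lie in [0, 1)")
  if (cfg$attention_dim %% cfg$n_attention_heads != 0)
    stop("attention_dim must be divisible by n_attention_heads")
  class(cfg) <- "stabgvp_config"
  cfg
}

# --- Adam ------------------------------------------------------------------

.adam_state <- function(flat) {
  list(m = lapply(flat, function(x) array(0, dim = dim(as.array(x)))),
       v = lapply(flat, function(x) array(0, dim = dim(as.array(x)))),
       t = 0)
}

.adam_step <- function(flat, grads, state, lr, wd, trainable,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(flat)) {
    if (!trainable[[nm]]) next
    g <- grads[[nm]] + wd * flat[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(flat = flat, state = state)
}

# --- fitting ---------------------------------------------------------------

#' Fit the dual-graph GVP-GNN stability classifier
#'
#' Trains the binary stabilizing/destabilizing classifier on labeled
#' (wild-type graph, mutant graph) pairs by minibatch Adam on binary
#' cross-entropy. Both graphs pass through a shared-weight GVP-GNN
#' encoder; jumping-knowledge node representations are mean-pooled per
#' graph, the two graph embeddings attend to each other through
#' multi-head attention, and an affine + sigmoid head emits the
#' stabilizing probability (1 = stabilizing, 0 = destabilizing,
#' thresholded at 0.5).
#'
#' @param x List of samples; each a list with elements `wt` and `mut`
#'   ([build_graph()] outputs featurized with the same encoder stack)
#'   and `label` (0/1).
#' @param config A [stabgvp_config()].
#' @param init Optional parameter list (e.g. from a pretrained model) to
#'   start from instead of random initialization.
#' @param trainable Optional character regex: only parameters whose name
#'   matches are updated; all others stay frozen bit-identically.
#' @param validation Optional held-out sample list for early stopping.
#' @return An object of class `stabgvp` with elements `params`,
#'   `config`, `history` (per-epoch loss/accuracy TSV-able data.frame),
#'   `fitted` (training-set probabilities), `labels`, `trainable`.
#' @export
stabgvp <- function(x, config = stabgvp_config(), init = NULL,
                    trainable = NULL, validation = NULL) {
  stopifnot(length(x) >= 1)
  labels <- vapply(x, function(s) as.numeric(s$label), 1)
  if (any(is.na(labels))) stop("all training samples need a 0/1 label")
  ds <- ncol(x[[1]]$wt$S)
  es <- ncol(x[[1]]$wt$Se)
  for (s in x)
    if (ncol(s$wt$S) != ds || ncol(s$mut$S) != ds)
      stop("encoder-stack mismatch: all graphs must share the same ",
           "scalar feature width")
  params <- if (is.null(init)) .init_params(config, ds, 3, es) else init
  flat <- .flatten_params(params)
  trainable_mask <- stats::setNames(rep(TRUE, length(flat)), names(flat))
  if (!is.null(trainable))
    trainable_mask[] <- grepl(trainable, names(flat))
  if (!any(trainable_mask)) stop("no trainable parameters selected")
  state <- .adam_state(flat)
  n <- length(x)
  set.seed(config$seed + 1L)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric(), val_loss = numeric())
  best_val <- Inf; best_flat <- flat; wait <- 0
  for (ep in seq_len(config$epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_correct <- 0
    for (b in batches) {
      params <- .unflatten_params(flat, params)
      batch <- .collate(x[b])
      fw <- .network_forward(params, batch, config, training = TRUE)
      loss <- ad_bce_logits(fw$tape, fw$logits, batch$labels)
      ad_backward(fw$tape, loss)
      grads <- .flatten_params(.read_grads(params, fw$reg))
      upd <- .adam_step(flat, grads, state, config$lr,
                        config$weight_decay, trainable_mask)
      flat <- upd$flat; state <- upd$state
      ep_loss <- ep_loss + loss$value * length(b)
      ep_correct <- ep_correct + sum((fw$prob > 0.5) == batch$labels)
    }
    val_loss <- NA_real_
    if (!is.null(validation)) {
      params <- .unflatten_params(flat, params)
      vb <- .collate(validation)
      vf <- .network_forward(params, vb, config, training = FALSE)
      eps <- 1e-12
      val_loss <- -mean(vb$labels * log(vf$prob + eps) +
                          (1 - vb$labels) * log(1 - vf$prob + eps))
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss; best_flat <- flat; wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= config$patience) {
          history <- rbind(history, data.frame(
            epoch = ep, loss = ep_loss / n, accuracy = ep_correct / n,
            val_loss = val_loss))
          flat <- best_flat
          break
        }
      }
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_loss / n, accuracy = ep_correct / n,
      val_loss = val_loss))
  }
  params <- .unflatten_params(flat, params)
  final <- .network_forward(params, .collate(x), config, training = FALSE)
  obj <- list(params = params, config = config, history = history,
              fitted = final$prob, labels = labels,
              trainable = trainable_mask,
              node_scalar_dim = ds, edge_scalar_dim = es,
              call = match.call())
  class(obj) <- "stabgvp"
  obj
}

#' @export
print.stabgvp <- function(x, ...) {
  np <- sum(vapply(.flatten_params(x$params), length, 1L))
  cat("Dual-graph GVP-GNN stability classifier\n")
  cat("  layers:", x$config$n_gnn_layers,
      " hidden:", x$config$hidden_dim,
      " parameters:", np, "\n")
  cat("  trained", nrow(x$history), "epochs on", length(x$labels),
      "samples; final loss",
      format(utils::tail(x$history$loss, 1), digits = 4),
      " train accuracy",
      format(utils::tail(x$history$accuracy, 1), digits = 3), "\n")
  invisible(x)
}

#' @export
summary.stabgvp <- function(object, ...) {
  pred <- as.integer(object$fitted > 0.5)
  out <- list(config = object$config,
              n_samples = length(object$labels),
              n_epochs = nrow(object$history),
              final_loss = utils::tail(object$history$loss, 1),
              train_metrics = compute_metrics(object$labels,
                                              object$fitted),
              n_trainable = sum(object$trainable),
              n_frozen = sum(!object$trainable))
  class(out) <- "summary.stabgvp"
  out
}

#' @export
print.summary.stabgvp <- function(x, ...) {
  cat("GVP-GNN stability classifier:", x$n_samples, "samples,",
      x$n_epochs, "epochs\n")
  cat("  trainable parameter arrays:", x$n_trainable,
      " frozen:", x$n_frozen, "\n")
  m <- x$train_metrics
  cat(sprintf("  training: accuracy %.3f precision %.3f recall %.3f auc %s\n",
              m$accuracy, m$precision, m$recall,
              ifelse(is.na(m$auc), "undefined", sprintf("%.3f", m$auc))))
  invisible(x)
}

#' Predict stabilization probabilities for graph pairs
#'
#' @param object A fitted `stabgvp` model.
#' @param newdata A list of samples (each with `wt` and `mut` graphs) or
#'   a single such sample.
#' @param type "prob" for probabilities, "class" for 0/1 calls at 0.5.
#' @param ... Unused.
#' @return Numeric (or integer) vector, one value per pair.
#' @export
predict.stabgvp <- function(object, newdata,
                            type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!is.null(newdata$wt)) newdata <- list(newdata)
  ds <- ncol(newdata[[1]]$wt$S)
  if (ds != object$node_scalar_dim)
    stop("encoder-stack mismatch: model expects scalar width ",
         object$node_scalar_dim, ", got ", ds)
  batch <- .collate(newdata)
  fw <- .network_forward(object$params, batch, object$config,
                         training = FALSE)
  if (type == "class") as.integer(fw$prob > 0.5) else fw$prob
}

#' @export
coef.stabgvp <- function(object, ...) .flatten_params(object$params)

#' @export
residuals.stabgvp <- function(object, ...) object$labels - object$fitted

#' @export
plot.stabgvp <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "binary cross-entropy",
                 main = "training loss", ...)
  invisible(x)
}

#' @export
simulate.stabgvp <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, stats::rbinom(
    length(object$fitted), 1, object$fitted)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

# --- cross-validated pretraining ------------------------------------------

#' Pretrain with k-fold cross-validation
#'
#' Runs the standard pretraining protocol: seeded k-fold (default 5)
#' cross-validation with binary cross-entropy, reporting per-fold and
#' mean/sd accuracy, precision, recall and AUC, then refits a final
#' model on all data. Folds that end up single-class in their validation
#' part are skipped with a report entry.
#'
#' @param x Labeled sample list (see [stabgvp()]).
#' @param config A [stabgvp_config()]; pretraining defaults are the
#'   published ones (lr 1e-4, weight decay 1e-3, dropout 0.6).
#' @param k Number of folds, default 5.
#' @return Object of class `stabgvp_pretrain`: `model` (fit on all
#'   data), `cv` (per-fold metric data.frame), `cv_summary` (mean/sd),
#'   `folds` (assignment vector).
#' @export
stabgvp_pretrain <- function(x, config = stabgvp_config(), k = 5) {
  n <- length(x)
  labels <- vapply(x, function(s) as.numeric(s$label), 1)
  set.seed(config$seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  rows <- list(); skipped <- character()
  for (f in seq_len(k)) {
    hold <- which(folds == f)
    if (length(unique(labels[hold])) < 2) {
      skipped <- c(skipped, sprintf("fold %d skipped: single-class validation part", f))
      rows[[f]] <- data.frame(fold = f, n_val = length(hold),
                              accuracy = NA, precision = NA, recall = NA,
                              auc = NA)
      next
    }
    fit <- stabgvp(x[-hold], config)
    p <- predict(fit, x[hold])
    m <- compute_metrics(labels[hold], p)
    rows[[f]] <- data.frame(fold = f, n_val = length(hold),
                            accuracy = m$accuracy, precision = m$precision,
                            recall = m$recall, auc = m$auc)
  }
  cv <- do.call(rbind, rows)
  met <- c("accuracy", "precision", "recall", "auc")
  cv_summary <- data.frame(
    metric = met,
    mean = vapply(met, function(m) mean(cv[[m]], na.rm = TRUE), 1),
    sd = vapply(met, function(m) stats::sd(cv[[m]], na.rm = TRUE), 1))
  model <- stabgvp(x, config)
  out <- list(model = model, cv = cv, cv_summary = cv_summary,
              folds = folds, skipped = skipped, seed = config$seed)
  class(out) <- "stabgvp_pretrain"
  out
}

#' @export
print.stabgvp_pretrain <- function(x, ...) {
  cat("Cross-validated pretraining (", max(x$folds), "folds )\n")
  print(x$cv, row.names = FALSE)
  if (length(x$skipped)) cat(paste(x$skipped, collapse = "\n"), "\n")
  invisible(x)
}

#' Fine-tune a pretrained model on multiple-point mutation data
#'
#' Updates only the GVP-GNN layer parameters (message and feedforward
#' chains); embeddings, attention and the classification head stay
#' frozen bit-identically, matching the published fine-tuning scope.
#' Fine-tuning hyperparameters default to the published values
#' (learning rate 1e-3, weight decay 1e-6, dropout 0.4). Set
#' `scope = "all"` to unfreeze everything.
#'
#' @param pretrained A `stabgvp` or `stabgvp_pretrain` object.
#' @param x Labeled multiple-point sample list.
#' @param lr,weight_decay,dropout,epochs Fine-tuning hyperparameters.
#' @param scope "gnn_only" (default) or "all".
#' @param validation Optional held-out samples for early stopping.
#' @return A fitted `stabgvp` with a `finetuned_from` attribute.
#' @export
stabgvp_finetune <- function(pretrained, x, lr = 1e-3,
                             weight_decay = 1e-6, dropout = 0.4,
                             epochs = NULL, scope = c("gnn_only", "all"),
                             validation = NULL) {
  scope <- match.arg(scope)
  if (inherits(pretrained, "stabgvp_pretrain")) pretrained <- pretrained$model
  stopifnot(inherits(pretrained, "stabgvp"))
  if (ncol(x[[1]]$wt$S) != pretrained$node_scalar_dim)
    stop("architecture mismatch: checkpoint expects scalar width ",
         pretrained$node_scalar_dim)
  cfg <- pretrained$config
  cfg$lr <- lr; cfg$weight_decay <- weight_decay; cfg$dropout <- dropout
  if (!is.null(epochs)) cfg$epochs <- epochs
  pat <- if (scope == "gnn_only") "^gnn" else "."
  fit <- stabgvp(x, cfg, init = pretrained$params, trainable = pat,
                 validation = validation)
  attr(fit, "finetuned_from") <- deparse(substitute(pretrained))
  fit
}

# --- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints are a single JSON archive holding every parameter array
#' (with dimensions), the configuration and the seed manifest; loading
#' reproduces identical outputs on fixed input.
#'
#' @param model A `stabgvp` object.
#' @param path Output path (.json).
#' @export
save_checkpoint <- function(model, path) {
  flat <- .flatten_params(model$params)
  obj <- list(
    package = "stabgvp", format = 1L,
    config = unclass(model$config),
    node_scalar_dim = model$node_scalar_dim,
    edge_scalar_dim = model$edge_scalar_dim,
    trainable = as.list(model$trainable),
    labels = model$labels,
    fitted = model$fitted,
    history = model$history,
    params = lapply(flat, function(x) {
      a <- as.array(x)
      list(dim = dim(a), data = as.vector(a))
    }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$package) || obj$package != "stabgvp")
    stop("not a stabgvp checkpoint: ", path)
  cfg <- do.call(stabgvp_config, obj$config)
  flat <- lapply(obj$params, function(p) {
    if (length(p$dim) <= 1) as.numeric(p$data)
    else array(p$data, dim = p$dim)
  })
  es <- if (is.null(obj$edge_scalar_dim)) 16L else obj$edge_scalar_dim
  template <- .init_params(cfg, obj$node_scalar_dim, 3, es)
  params <- .unflatten_params(flat, template)
  model <- list(params = params, config = cfg,
                history = as.data.frame(obj$history),
                fitted = obj$fitted, labels = obj$labels,
                trainable = unlist(obj$trainable),
                node_scalar_dim = obj$node_scalar_dim,
                edge_scalar_dim = es,
                call = NULL)
  class(model) <- "stabgvp"
  model
}
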