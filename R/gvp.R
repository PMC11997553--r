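# ---------------------------------------------------------------------------
# Geometric vector perceptron layers and the dual-graph network forward.
#
# A GVP jointly transforms a (scalar, vector) tuple: vectors are mixed by
# learned linear maps and gated by scalar-path activations, scalars mix
# the input scalars with norms of the transformed vectors. Scalar outputs
# are invariant and vector outputs equivariant under any orthogonal
# transform applied to the input vectors.
# ---------------------------------------------------------------------------

.glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

# parameter arrays for one GVP: (si, nu_in) -> (so, nu_out)
.gvp_params <- function(si, nu_in, so, nu_out) {
  h <- max(nu_in, nu_out, 1L)
  p <- list(Wh = .glorot(max(nu_in, 1L), h),
            Ws = .glorot(si + h, so),
            bs = numeric(so))
  if (nu_out > 0) {
    p$Wmu <- .glorot(h, nu_out)
    p$Wg <- .glorot(so, nu_out)
    p$bg <- numeric(nu_out)
  }
  p
}

# forward one GVP on tape nodes. s: (n, si); V: (n, nu_in, 3); pn: named
# list of parameter *nodes*. Returns list(s, V).
.gvp_forward <- function(tape, s, V, pn, nu_in, nu_out, activate = TRUE) {
  if (nu_in > 0) {
    Vh <- ad_vlinear(tape, V, pn$Wh)
    nrm <- ad_vnorm(tape, Vh)
    sm <- ad_linear(tape, ad_concat(tape, list(s, nrm)), pn$Ws, pn$bs)
  } else {
    sm <- ad_linear(tape, s, pn$Ws, pn$bs)
  }
  s_out <- if (activate) ad_relu(tape, sm) else sm
  V_out <- NULL
  if (nu_out > 0) {
    Vmu <- ad_vlinear(tape, Vh, pn$Wmu)
    gate <- ad_sigmoid(tape, ad_linear(tape, s_out, pn$Wg, pn$bg))
    V_out <- ad_vgate(tape, Vmu, gate)
  }
  list(s = s_out, V = V_out)
}

# chain of GVPs with fixed hidden dims; dims: list of c(si, vi, so, vo)
.gvp_chain_params <- function(dims) {
  out <- lapply(dims, function(d) .gvp_params(d[1], d[2], d[3], d[4]))
  names(out) <- paste0("gvp", seq_along(out))
  out
}

.gvp_chain_forward <- function(tape, s, V, pns, dims) {
  n <- length(pns)
  for (j in seq_len(n)) {
    out <- .gvp_forward(tape, s, V, pns[[j]], dims[[j]][2], dims[[j]][4],
                        activate = j < n)
    s <- out$s; V <- out$V
  }
  list(s = s, V = V)
}

# ---------------------------------------------------------------------------
# Model parameter construction
# ---------------------------------------------------------------------------

.message_dims <- function(cfg) {
  hs <- cfg$hidden_dim; hv <- cfg$hidden_vector_dim
  se <- cfg$edge_hidden_dim
  dims <- list(c(2 * hs + se, 2 * hv + 1, hs, hv))
  if (cfg$n_message_gvps > 1)
    dims <- c(dims, rep(list(c(hs, hv, hs, hv)), cfg$n_message_gvps - 1))
  dims
}

.ff_dims <- function(cfg) {
  hs <- cfg$hidden_dim; hv <- cfg$hidden_vector_dim
  rep(list(c(hs, hv, hs, hv)), cfg$n_feedforward_gvps)
}

# builds the full named parameter list; naming encodes the trainable
# grouping: "gnn..." parameters are the GVP-GNN layers (the fine-tuning
# scope), everything else is embedding/attention/head.
.init_params <- function(cfg, node_scalar_dim, node_vector_dim = 3,
                         edge_scalar_dim = 16) {
  set.seed(cfg$seed)
  hs <- cfg$hidden_dim; hv <- cfg$hidden_vector_dim
  p <- list()
  p$embed_node <- .gvp_params(node_scalar_dim, node_vector_dim, hs, hv)
  p$embed_edge <- .gvp_params(edge_scalar_dim, 1, cfg$edge_hidden_dim, 1)
  for (l in seq_len(cfg$n_gnn_layers)) {
    p[[paste0("gnn", l, "_msg")]] <- .gvp_chain_params(.message_dims(cfg))
    p[[paste0("gnn", l, "_ff")]] <- .gvp_chain_params(.ff_dims(cfg))
  }
  jk_dim <- if (cfg$jk_mode == "concat") cfg$n_gnn_layers * hs else hs
  d <- cfg$attention_dim
  p$attn_proj <- list(W = .glorot(jk_dim, d), b = numeric(d))
  p$attn <- list(Wq = .glorot(d, d), bq = numeric(d),
                 Wk = .glorot(d, d), bk = numeric(d),
                 Wv = .glorot(d, d), bv = numeric(d),
                 Wo = .glorot(d, d), bo = numeric(d))
  p$head <- list(W = .glorot(2 * d, 1), b = numeric(1))
  p
}

# wrap a (possibly nested) parameter list into tape leaves, returning a
# parallel structure of nodes plus a flat environment for gradient readout
.wrap_params <- function(tape, params, reg, prefix = "") {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) {
    x <- params[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(x)) {
      out[[nm]] <- .wrap_params(tape, x, reg, paste0(key, "."))
    } else {
      node <- ad_leaf(tape, x)
      assign(key, node, envir = reg)
      out[[nm]] <- node
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Batched forward pass
# ---------------------------------------------------------------------------

# Collate a list of samples (each: list(wt = protein_graph,
# mut = protein_graph, label)) into one disjoint-union graph.
.collate <- function(samples) {
  graphs <- unlist(lapply(samples, function(s) list(s$wt, s$mut)),
                   recursive = FALSE)
  nn <- vapply(graphs, `[[`, 1L, "n_nodes")
  offset <- cumsum(c(0L, nn[-length(nn)]))
  S <- do.call(rbind, lapply(graphs, `[[`, "S"))
  Vl <- lapply(graphs, `[[`, "V")
  N <- sum(nn)
  V <- array(0, dim = c(N, 3, 3))
  row <- 0L
  for (g in Vl) {
    V[row + seq_len(dim(g)[1]), , ] <- g
    row <- row + dim(g)[1]
  }
  for (g in graphs)
    if (length(g$edge_index) &&
        (max(g$edge_index) > g$n_nodes || min(g$edge_index) < 1))
      stop("dangling edge index: edge refers to a node outside the graph")
  ei <- do.call(cbind, lapply(seq_along(graphs), function(j)
    graphs[[j]]$edge_index + offset[j]))
  Se <- do.call(rbind, lapply(graphs, `[[`, "Se"))
  E <- ncol(ei)
  Ve <- array(0, dim = c(E, 1, 3))
  row <- 0L
  for (g in graphs) {
    e <- dim(g$Ve)[1]
    Ve[row + seq_len(e), , ] <- g$Ve
    row <- row + e
  }
  node_graph <- rep(seq_along(graphs), nn)
  list(S = S, V = V, edge_index = ei, Se = Se, Ve = Ve,
       node_graph = node_graph, n_graphs = length(graphs),
       labels = vapply(samples, function(s)
         if (is.null(s$label)) NA_real_ else as.numeric(s$label), 1))
}

.dropout_mask <- function(x_dim, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(prod(x_dim), 1, 1 - p) / (1 - p),
         x_dim[1], x_dim[2])
}

.apply_dropout <- function(tape, x, p, training) {
  if (!training || p <= 0) return(x)
  m <- .dropout_mask(dim(x$value), p)
  ad_mul(tape, x, ad_const(tape, m))
}

# Full network forward on a collated batch. Returns logits node plus the
# tape and parameter-node registry.
.network_forward <- function(params, batch, cfg, training = FALSE) {
  tape <- ad_tape()
  reg <- new.env(parent = emptyenv())
  pn <- .wrap_params(tape, params, reg)
  drop_p <- if (training) cfg$dropout else 0

  s <- ad_const(tape, batch$S)
  V <- ad_const(tape, batch$V)
  se <- ad_const(tape, batch$Se)
  ve <- ad_const(tape, batch$Ve)

  emb <- .gvp_forward(tape, s, V, pn$embed_node, 3, cfg$hidden_vector_dim)
  s <- emb$s; V <- emb$V
  eemb <- .gvp_forward(tape, se, ve, pn$embed_edge, 1, 1)
  se <- eemb$s; ve <- eemb$V

  src <- batch$edge_index[1, ]
  dst <- batch$edge_index[2, ]
  N <- nrow(batch$S)
  msg_dims <- .message_dims(cfg)
  ff_dims <- .ff_dims(cfg)
  layer_states <- list()
  for (l in seq_len(cfg$n_gnn_layers)) {
    s_msg_in <- ad_concat(tape, list(ad_rows(tape, s, src), se,
                                     ad_rows(tape, s, dst)))
    V_msg_in <- ad_vconcat(tape, list(ad_vrows(tape, V, src), ve,
                                      ad_vrows(tape, V, dst)))
    msg <- .gvp_chain_forward(tape, s_msg_in, V_msg_in,
                              pn[[paste0("gnn", l, "_msg")]], msg_dims)
    agg_s <- ad_scatter_mean(tape, msg$s, dst, N)
    agg_V <- ad_vscatter_mean(tape, msg$V, dst, N)
    s <- ad_layernorm(tape, ad_add(tape, s,
                                   .apply_dropout(tape, agg_s, drop_p,
                                                  training)))
    V <- ad_vrms(tape, ad_vadd(tape, V, agg_V))
    ff <- .gvp_chain_forward(tape, s, V, pn[[paste0("gnn", l, "_ff")]],
                             ff_dims)
    s <- ad_layernorm(tape, ad_add(tape, s,
                                   .apply_dropout(tape, ff$s, drop_p,
                                                  training)))
    V <- ad_vrms(tape, ad_vadd(tape, V, ff$V))
    layer_states[[l]] <- s
  }

  jk <- if (cfg$jk_mode == "concat") ad_concat(tape, layer_states) else s
  pooled <- ad_scatter_mean(tape, jk, batch$node_graph, batch$n_graphs)
  tok <- ad_relu(tape, ad_linear(tape, pooled, pn$attn_proj$W,
                                 pn$attn_proj$b))
  tok <- .apply_dropout(tape, tok, drop_p, training)

  B <- batch$n_graphs / 2
  wt_idx <- seq(1, batch$n_graphs, by = 2)
  mut_idx <- seq(2, batch$n_graphs, by = 2)
  Tw <- ad_rows(tape, tok, wt_idx)
  Tm <- ad_rows(tape, tok, mut_idx)

  att <- .pair_attention(tape, Tw, Tm, pn$attn, cfg)
  paired <- ad_concat(tape, list(att$w, att$m))
  paired <- .apply_dropout(tape, paired, drop_p, training)
  logits <- ad_linear(tape, paired, pn$head$W, pn$head$b)
  list(tape = tape, reg = reg, logits = logits,
       prob = 1 / (1 + exp(-as.vector(logits$value))))
}

# Two-token multi-head self-attention over the (wild-type, mutant)
# embedding pair. With two tokens the per-query softmax reduces exactly
# to a sigmoid of the score difference.
.pair_attention <- function(tape, Tw, Tm, pn, cfg) {
  d <- cfg$attention_dim
  H <- cfg$n_attention_heads
  dh <- d / H
  Qw <- ad_linear(tape, Tw, pn$Wq, pn$bq); Qm <- ad_linear(tape, Tm, pn$Wq, pn$bq)
  Kw <- ad_linear(tape, Tw, pn$Wk, pn$bk); Km <- ad_linear(tape, Tm, pn$Wk, pn$bk)
  Vw <- ad_linear(tape, Tw, pn$Wv, pn$bv); Vm <- ad_linear(tape, Tm, pn$Wv, pn$bv)
  one <- ad_const(tape, matrix(1, nrow(Tw$value), 1))
  outs_w <- list(); outs_m <- list()
  for (h in seq_len(H)) {
    idx <- (h - 1) * dh + seq_len(dh)
    qw <- ad_cols(tape, Qw, idx); qm <- ad_cols(tape, Qm, idx)
    kw <- ad_cols(tape, Kw, idx); km <- ad_cols(tape, Km, idx)
    vw <- ad_cols(tape, Vw, idx); vm <- ad_cols(tape, Vm, idx)
    sc <- 1 / sqrt(dh)
    att_out <- function(q) {
      s_w <- ad_smul(tape, ad_rowsum(tape, ad_mul(tape, q, kw)), sc)
      s_m <- ad_smul(tape, ad_rowsum(tape, ad_mul(tape, q, km)), sc)
      a_w <- ad_sigmoid(tape, ad_sub(tape, s_w, s_m))  # 2-way softmax
      a_m <- ad_sub(tape, one, a_w)
      ad_add(tape, ad_scale_cols(tape, vw, a_w),
             ad_scale_cols(tape, vm, a_m))
    }
    outs_w[[h]] <- att_out(qw)
    outs_m[[h]] <- att_out(qm)
  }
  ow <- ad_linear(tape, ad_concat(tape, outs_w), pn$Wo, pn$bo)
  om <- ad_linear(tape, ad_concat(tape, outs_m), pn$Wo, pn$bo)
  list(w = ad_add(tape, Tw, ow), m = ad_add(tape, Tm, om))  # residual
}

# read gradients for a nested parameter list from the registry
.read_grads <- function(params, reg, prefix = "") {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) {
    x <- params[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(x)) {
      out[[nm]] <- .read_grads(x, reg, paste0(key, "."))
    } else {
      node <- get(key, envir = reg)
      g <- node$grad
      out[[nm]] <- if (is.null(g)) array(0, dim = dim(as.array(x))) else g
    }
  }
  out
}

# flatten/unflatten nested parameter lists (used by the optimizer and
# checkpointing)
.flatten_params <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    x <- params[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(x)) out <- c(out, .flatten_params(x, paste0(key, ".")))
    else out[[key]] <- x
  }
  out
}

.unflatten_params <- function(flat, template) {
  fill <- function(tpl, prefix) {
    for (nm in names(tpl)) {
      key <- paste0(prefix, nm)
      if (is.list(tpl[[nm]])) tpl[[nm]] <- fill(tpl[[nm]], paste0(key, "."))
      else tpl[[nm]] <- flat[[key]]
    }
    tpl
  }
  fill(template, "")
}
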