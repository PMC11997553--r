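# Shared fixtures built in code: tiny model configs, toy datasets and
# geometric helpers used across test files.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(hidden_dim = 8, hidden_vector_dim = 3, edge_hidden_dim = 6,
         attention_dim = 8, n_attention_heads = 2, batch_size = 16,
         dropout = 0, lr = 5e-3, weight_decay = 0, epochs = 2, seed = 7),
    list(...))
  do.call(stabgvp_config, args)
}

tiny_samples <- function(n = 6, seed = 3) {
  gen_classification_fixture(n, n_residues = 8, k_neighbors = 4,
                             seed = seed)
}

toy_dataset <- function() {
  mutation_dataset(data.frame(
    record_id = c("r1", "r2", "r3"),
    wt_id = c("P1", "P1", "P2"),
    wt_sequence = c("ACDEFG", "ACDEFG", "MKLVWY"),
    mutations = c("C2W", "C2W;E4K", "K2R"),
    ddg = c(1.0, -0.5, 2.0),
    stringsAsFactors = FALSE))
}

# random proper rotation matrix (det +1)
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rigid-motion a backbone structure: x -> R x + t
transform_structure <- function(bb, R, t = c(0, 0, 0)) {
  tr <- function(m) sweep(m %*% t(R), 2, -t)
  backbone_structure(bb$sequence, tr(bb$N), tr(bb$CA), tr(bb$C),
                     if (is.null(bb$O)) NULL else tr(bb$O), bb$chain)
}

# apply an orthogonal transform directly to a graph's vector channels
transform_graph_vectors <- function(g, R) {
  for (j in seq_len(dim(g$V)[2]))
    g$V[, j, ] <- g$V[, j, , drop = TRUE] %*% t(R)
  g$Ve[, 1, ] <- matrix(g$Ve[, 1, ], ncol = 3) %*% t(R)
  g
}
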