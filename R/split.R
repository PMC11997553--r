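# ---------------------------------------------------------------------------
# Mutation-type clustering and leakage-free train/test allocation
# ---------------------------------------------------------------------------

#' Mutation-type vocabulary
#'
#' The ordered set of (from, to) residue substitution types observed in a
#' dataset, in lexicographic order. At most 380 (20 x 19) types exist.
#'
#' @param df Mutation dataset.
#' @return Character vector of types like "L>A", lexicographically sorted.
#' @export
mutation_type_vocabulary <- function(df) {
  types <- unlist(lapply(df$mutations, function(m) {
    p <- parse_mutations(m)
    paste0(p$from, ">", p$to)
  }), use.names = FALSE)
  sort(unique(types))
}

#' Multi-hot encode mutation-type combinations
#'
#' Each record's mutation combination is separated into its constituent
#' single substitution types and encoded as a binary vector over the
#' vocabulary: 1 wherever the record contains that type. Positions are
#' deliberately not encoded — two records with the same type set at
#' different positions map to the same vector.
#'
#' @param df Mutation dataset.
#' @param vocabulary From [mutation_type_vocabulary()].
#' @return Binary matrix, nrow(df) x length(vocabulary).
#' @export
encode_type_combination <- function(df, vocabulary) {
  m <- matrix(0L, nrow(df), length(vocabulary),
              dimnames = list(df$record_id, vocabulary))
  for (i in seq_len(nrow(df))) {
    p <- parse_mutations(df$mutations[i])
    tt <- unique(paste0(p$from, ">", p$to))
    unseen <- setdiff(tt, vocabulary)
    if (length(unseen))
      stop("mutation type(s) not in vocabulary: ",
           paste(unseen, collapse = ", "))
    m[i, tt] <- 1L
  }
  m
}

# --- exact t-SNE (small n) -------------------------------------------------

.tsne_p_matrix <- function(d2, perplexity) {
  n <- nrow(d2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p <- rep(1 / length(di), length(di)) else p <- p / sp
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Exact t-SNE embedding
#'
#' Plain (non-Barnes-Hut) t-distributed stochastic neighbor embedding for
#' the small point sets arising from unique mutation-type combinations:
#' Gaussian input affinities calibrated per point to a target perplexity,
#' Student-t output affinities, KL-divergence gradient descent with
#' momentum and early exaggeration. Deterministic under a fixed seed.
#'
#' @param x Numeric matrix (rows = points).
#' @param dims Output dimensionality, default 2.
#' @param perplexity Target perplexity; clamped to (n-1)/3 when the point
#'   set is too small for the default 30.
#' @param n_iter Gradient-descent iterations.
#' @param seed Integer seed for the random initialization.
#' @return n x dims embedding matrix.
#' @export
tsne_embed <- function(x, dims = 2, perplexity = 30, n_iter = 300,
                       seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("t-SNE needs at least 2 points")
  perplexity <- max(1, min(perplexity, (n - 1) / 3))
  d2 <- as.matrix(stats::dist(x))^2
  P <- .tsne_p_matrix(d2, perplexity)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  G <- matrix(0, n, dims)
  momentum <- 0.5
  for (it in seq_len(n_iter)) {
    Pit <- if (it <= 100) P * 4 else P       # early exaggeration
    dY2 <- as.matrix(stats::dist(Y))^2
    Qnum <- 1 / (1 + dY2); diag(Qnum) <- 0
    Q <- pmax(Qnum / sum(Qnum), 1e-12)
    W <- (Pit - Q) * Qnum
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    momentum <- if (it > 250) 0.8 else 0.5
    G <- momentum * G - 100 * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

# --- DBSCAN ---------------------------------------------------------------

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN on a Euclidean distance matrix: core points have at
#' least `min_samples` neighbours (self included) within `eps`; clusters
#' grow by density reachability; non-reachable points are labeled 0
#' (noise). When `eps` is NULL it is chosen from the k-distance curve
#' (k = `min_samples`): the value just before the largest gap in the
#' sorted k-th-neighbour distances.
#'
#' @param x Numeric matrix of points.
#' @param eps Neighbourhood radius, or NULL for the k-distance heuristic.
#' @param min_samples Core-point threshold, default 5.
#' @return Integer cluster labels (1..k; 0 = noise), with the chosen
#'   `eps` as attribute.
#' @export
dbscan_cluster <- function(x, eps = NULL, min_samples = 5) {
  x <- as.matrix(x)
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))
  if (is.null(eps)) {
    k <- min(min_samples, n - 1)
    kdist <- sort(apply(D, 1, function(r) sort(r)[k + 1]))
    if (n < 3 || max(kdist) == 0) {
      eps <- max(kdist, 1e-8)
    } else {
      gaps <- diff(kdist)
      j <- which.max(gaps)
      eps <- kdist[j] + 1e-8
      if (eps <= 0) eps <- max(kdist) / 2
    }
  }
  labels <- rep(NA_integer_, n)
  core <- vapply(seq_len(n), function(i) sum(D[i, ] <= eps) >= min_samples,
                 TRUE)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      nb <- which(D[p, ] <= eps)
      for (q in nb) {
        if (is.na(labels[q]) || labels[q] == 0L) {
          newly <- is.na(labels[q])
          labels[q] <- cl
          if (newly && core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels[is.na(labels)] <- 0L
  attr(labels, "eps") <- eps
  labels
}

# --- clustering front-end --------------------------------------------------

#' Cluster mutation-type combinations
#'
#' Embeds the multi-hot mutation-type vectors into 2 dimensions with
#' t-SNE (run on unique combinations, then mapped back to records) and
#' clusters the embedding with DBSCAN. Noise points keep the dedicated
#' label 0. Degenerate input (all vectors identical) yields a single
#' cluster without embedding.
#'
#' @param vectors Multi-hot matrix from [encode_type_combination()].
#' @param tsne_params List: perplexity (30), dims (2), n_iter (300).
#' @param dbscan_params List: eps (NULL = k-distance elbow),
#'   min_samples (5).
#' @param seed Integer seed.
#' @return Integer labels per row of `vectors` (0 = noise).
#' @export
cluster_types <- function(vectors, tsne_params = list(),
                          dbscan_params = list(), seed = 1) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2) stop("need at least 2 vectors to cluster")
  tp <- utils::modifyList(list(perplexity = 30, dims = 2, n_iter = 300),
                          tsne_params)
  dp <- utils::modifyList(list(eps = NULL, min_samples = 5), dbscan_params)
  key <- apply(vectors, 1, paste, collapse = "")
  uniq <- !duplicated(key)
  ux <- vectors[uniq, , drop = FALSE]
  map <- match(key, key[uniq])
  if (nrow(ux) == 1) return(rep(1L, nrow(vectors)))
  emb <- tsne_embed(ux, dims = tp$dims, perplexity = tp$perplexity,
                    n_iter = tp$n_iter, seed = seed)
  ms <- min(dp$min_samples, nrow(ux))
  ulab <- dbscan_cluster(emb, eps = dp$eps, min_samples = ms)
  out <- as.integer(ulab)[map]
  attr(out, "eps") <- attr(ulab, "eps")
  out
}

# --- allocation ------------------------------------------------------------

.round_half_up <- function(x) floor(x + 0.5)

#' Allocate a leakage-free train/test split
#'
#' Per-cluster quota sampling at the wild-type-protein level: each
#' cluster contributes `round(cluster size x test_fraction)` records to
#' the test set, but wild-type proteins always move whole — when a
#' protein is selected, all its records across all clusters go to test,
#' so no wild-type sequence ever appears in both partitions. Candidate
#' proteins are drawn in seeded random order; when every remaining
#' candidate would overshoot a cluster's quota, the smallest-data
#' candidate is taken provided the overshoot stays within one typical
#' wild type's worth of records (the dataset-wide mean per protein);
#' otherwise the cluster under-fills. Clusters whose records belong to
#' too few proteins
#' may under-fill; shortfalls are reported in the attached manifest, not
#' hidden. Noise points (cluster 0) are not quota'd and stay in train
#' unless their protein was selected via another cluster.
#'
#' @param df Mutation dataset.
#' @param cluster_labels Integer labels from [cluster_types()].
#' @param test_fraction Target test fraction in (0, 1).
#' @param seed Integer seed for the candidate shuffle.
#' @return Data.frame (record_id, cluster, partition) with a
#'   `"manifest"` attribute (seed, quotas, achieved counts, shortfalls).
#' @export
allocate_split <- function(df, cluster_labels, test_fraction = 0.2,
                           seed = 1) {
  stopifnot(length(cluster_labels) == nrow(df),
            test_fraction > 0, test_fraction < 1)
  wt <- df$wt_sequence
  clusters <- sort(setdiff(unique(cluster_labels), 0L))
  quota <- vapply(clusters, function(cl)
    .round_half_up(sum(cluster_labels == cl) * test_fraction), 1)
  names(quota) <- clusters
  in_test_wt <- character()
  test_count <- stats::setNames(numeric(length(clusters)), clusters)
  wt_sizes <- table(wt)
  avg_wt_size <- nrow(df) / length(wt_sizes)
  set.seed(seed)
  # process clusters largest-first so tight clusters see a full candidate pool
  for (cl in clusters[order(-quota)]) {
    key <- as.character(cl)
    # credit records already moved via proteins picked for other clusters
    test_count[key] <- sum(cluster_labels == cl & wt %in% in_test_wt)
    repeat {
      if (test_count[key] >= quota[key]) break
      cand <- unique(wt[cluster_labels == cl & !(wt %in% in_test_wt)])
      if (length(cand) == 0) break
      cand <- sample(cand)
      deficit <- quota[key] - test_count[key]
      contrib <- vapply(cand, function(w)
        sum(cluster_labels == cl & wt == w), 1)
      fits <- contrib <= deficit
      pick <- if (any(fits)) cand[fits][1] else
        cand[order(contrib)][1]  # smallest-data protein when tight
      if (!any(fits) && contrib[pick] - deficit > avg_wt_size)
        break  # overshoot beyond one wild type's worth: under-fill
      in_test_wt <- c(in_test_wt, pick)
      moved <- wt == pick
      for (c2 in clusters) {
        k2 <- as.character(c2)
        test_count[k2] <- test_count[k2] + sum(moved & cluster_labels == c2)
      }
      if (!any(fits)) break  # one overshooting protein at most
    }
  }
  partition <- ifelse(wt %in% in_test_wt, "test", "train")
  achieved <- vapply(as.character(clusters), function(k)
    sum(partition == "test" & cluster_labels == as.integer(k)), 1)
  shortfall <- pmax(quota - achieved, 0)
  if (any(shortfall > 0))
    message("cluster(s) under-filled: ",
            paste(sprintf("%s (short %d)", names(shortfall)[shortfall > 0],
                          as.integer(shortfall[shortfall > 0])),
                  collapse = ", "))
  out <- data.frame(record_id = df$record_id,
                    cluster = as.integer(cluster_labels),
                    partition = partition, stringsAsFactors = FALSE)
  attr(out, "manifest") <- list(
    seed = seed, test_fraction = test_fraction,
    quota = as.list(quota), achieved = as.list(achieved),
    shortfall = as.list(shortfall),
    achieved_fraction = mean(partition == "test"),
    test_wildtypes = in_test_wt)
  out
}

#' Write a split assignment and its manifest
#'
#' Writes the (record_id, partition) two-column TSV plus a JSON sidecar
#' carrying seed, parameters, per-cluster quotas and shortfalls.
#'
#' @param assignment Result of [allocate_split()].
#' @param path TSV output path; the sidecar gets ".json" appended.
#' @export
write_split_manifest <- function(assignment, path) {
  utils::write.table(assignment[, c("record_id", "partition")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(attr(assignment, "manifest"),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
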