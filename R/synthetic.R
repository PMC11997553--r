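# ---------------------------------------------------------------------------
# Synthetic fixtures: idealized backbones, mutation datasets with
# controlled thermodynamics, and encoder side-tables. All generators are
# deterministic under a fixed seed and emit the same formats the real
# pipeline reads.
# ---------------------------------------------------------------------------

# Place atom D given A, B, C with bond length |CD|, bond angle B-C-D and
# torsion A-B-C-D (natural extension reference frame).
.place_atom <- function(a, b, c, length, angle, torsion) {
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d2 <- length * c(-cos(angle), sin(angle) * cos(torsion),
                   sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Generate an ideal alpha-helical backbone
#'
#' Builds an N/CA/C/O backbone with standard bond geometry (N-CA 1.458,
#' CA-C 1.525, C-N 1.329, C-O 1.231 Angstroms) and helical torsions
#' phi = -57, psi = -47, omega = 180 degrees, via internal-coordinate
#' chain extension. Optional seeded Gaussian coordinate jitter (clamped
#' to 0.1 Angstroms) roughens the geometry without breaking the chain.
#'
#' @param n_residues Chain length (>= 2).
#' @param sequence Optional amino-acid string of that length; random
#'   uniform over the 20 canonical residues by default.
#' @param jitter Jitter standard deviation in Angstroms (<= 0.1).
#' @param seed Integer seed.
#' @return A [backbone_structure()].
#' @export
gen_helix_backbone <- function(n_residues, sequence = NULL, jitter = 0,
                               seed = 1) {
  if (n_residues < 2) stop("need at least 2 residues")
  stopifnot(jitter >= 0, jitter <= 0.1)
  set.seed(seed)
  if (is.null(sequence))
    sequence <- paste(sample(aa_alphabet(), n_residues, replace = TRUE),
                      collapse = "")
  stopifnot(nchar(sequence) == n_residues)
  deg <- pi / 180
  phi <- -57 * deg; psi <- -47 * deg; omg <- 180 * deg
  aNCAC <- 111.2 * deg; aCACN <- 116.2 * deg; aCNCA <- 121.7 * deg
  aCACO <- 120.8 * deg
  N <- CA <- C <- O <- matrix(0, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(aNCAC), sin(aNCAC), 0)
  for (i in 2:n_residues) {
    N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          1.329, aCACN, psi)
    CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                           1.458, aCNCA, omg)
    C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ],
                          1.525, aNCAC, phi)
  }
  for (i in seq_len(n_residues)) {
    tors_o <- if (i < n_residues) psi + pi else pi
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], 1.231, aCACO, tors_o)
  }
  if (jitter > 0) {
    jit <- function(m) m + matrix(pmin(pmax(stats::rnorm(length(m),
                                                         sd = jitter),
                                            -0.1), 0.1), nrow(m), 3)
    N <- jit(N); CA <- jit(CA); C <- jit(C); O <- jit(O)
  }
  backbone_structure(sequence, N, CA, C, O)
}

#' Generate a synthetic mutation dataset
#'
#' Emulates the statistical shape of curated thermostability data:
#' `n_wildtypes` random sequences, each with `variants_per_wt` variant
#' records sharing that wild type (so thermodynamic-looping pairs
#' exist). Measured ddg values are drawn from a two-component Gaussian
#' mixture: with probability `stabilizing_fraction` from
#' N(+ddg_mean, ddg_sd) truncated positive, otherwise from
#' N(-ddg_mean, ddg_sd) truncated negative, under the
#' stabilizing-positive convention.
#'
#' @param n_wildtypes Number of distinct wild-type proteins.
#' @param variants_per_wt Variant records per wild type.
#' @param chain_length Sequence length.
#' @param n_mutations Integer range (min, max) of point mutations per
#'   record; default c(1, 1) generates single-point data.
#' @param stabilizing_fraction Fraction of stabilizing records. Default
#'   0.3, mirroring the destabilizing-majority of experimental
#'   databases.
#' @param ddg_mean,ddg_sd Mixture component magnitude and spread
#'   (kcal/mol).
#' @param seed Integer seed.
#' @return A validated mutation dataset data.frame.
#' @export
gen_mutation_dataset <- function(n_wildtypes, variants_per_wt,
                                 chain_length = 30,
                                 n_mutations = c(1, 1),
                                 stabilizing_fraction = 0.3,
                                 ddg_mean = 1.5, ddg_sd = 0.8,
                                 seed = 1) {
  stopifnot(n_wildtypes > 0, variants_per_wt > 0, chain_length > 1,
            stabilizing_fraction >= 0, stabilizing_fraction <= 1)
  if (length(n_mutations) == 1) n_mutations <- rep(n_mutations, 2)
  set.seed(seed)
  aa <- aa_alphabet()
  rows <- vector("list", n_wildtypes * variants_per_wt)
  r <- 0L
  for (w in seq_len(n_wildtypes)) {
    wt_seq <- paste(sample(aa, chain_length, replace = TRUE),
                    collapse = "")
    wt_chars <- strsplit(wt_seq, "")[[1]]
    wt_id <- sprintf("SYN%04d", w)
    seen <- character()
    for (v in seq_len(variants_per_wt)) {
      repeat {
        k <- sample(n_mutations[1]:n_mutations[2], 1)
        pos <- sort(sample(chain_length, k))
        to <- vapply(pos, function(p)
          sample(setdiff(aa, wt_chars[p]), 1), "")
        mut <- paste0(wt_chars[pos], pos, to, collapse = ";")
        if (!mut %in% seen) break
      }
      seen <- c(seen, mut)
      stab <- stats::runif(1) < stabilizing_fraction
      ddg <- if (stab) abs(stats::rnorm(1, ddg_mean, ddg_sd))
      else -abs(stats::rnorm(1, ddg_mean, ddg_sd))
      r <- r + 1L
      rows[[r]] <- data.frame(
        record_id = sprintf("%s_v%03d", wt_id, v), wt_id = wt_id,
        wt_sequence = wt_seq, mutations = mut, ddg = ddg,
        dtm = NA_real_, label = as.integer(ddg > 0),
        direction = "direct", provenance = "experimental",
        stringsAsFactors = FALSE)
    }
  }
  mutation_dataset(do.call(rbind, rows), name = "synthetic")
}

#' Generate a synthetic per-residue evolutionary profile
#'
#' @param sequence Amino-acid string.
#' @param seed Integer seed.
#' @return L x 20 matrix of raw log-odds-like scores with residue-named
#'   columns, matching the [load_pssm()] schema.
#' @export
gen_pssm <- function(sequence, seed = 1) {
  L <- nchar(sequence)
  stopifnot(L > 0)
  set.seed(seed)
  m <- matrix(stats::rnorm(L * 20, 0, 2), L, 20,
              dimnames = list(NULL, aa_alphabet()))
  # bias toward the native residue, as real profiles are
  idx <- match(strsplit(sequence, "")[[1]], aa_alphabet())
  m[cbind(seq_len(L), idx)] <- m[cbind(seq_len(L), idx)] + 3
  m
}

#' Generate a synthetic per-residue score table
#'
#' @param sequence Amino-acid string.
#' @param seed Integer seed.
#' @return L x 20 data.frame with the [residue_score_schema()] columns.
#' @export
gen_residue_scores <- function(sequence, seed = 1) {
  L <- nchar(sequence)
  stopifnot(L > 0)
  set.seed(seed)
  m <- matrix(stats::rnorm(L * 20, 0, 1), L, 20)
  df <- as.data.frame(m)
  names(df) <- residue_score_schema()
  df$total <- rowSums(df[, 1:19])
  df
}

#' Generate a separable wild-type/mutant graph-pair classification set
#'
#' Builds labeled (wild-type graph, mutant graph) samples on jittered
#' helical backbones where the label is recoverable from the mutant's
#' residue composition: stabilizing samples mutate positions to alanine,
#' destabilizing ones to aspartate. Used for training sanity checks —
#' the task is solvable, not physically meaningful.
#'
#' @param n_samples Number of pairs (labels alternate, balanced).
#' @param n_residues Residues per backbone.
#' @param k_neighbors Graph connectivity.
#' @param seed Integer seed.
#' @param use Encoder families passed to [build_graph()].
#' @return List of samples: each has `wt`, `mut` (protein graphs) and
#'   `label`.
#' @export
gen_classification_fixture <- function(n_samples = 32, n_residues = 12,
                                       k_neighbors = 8, seed = 1,
                                       use = c("one_hot", "atchley",
                                               "potential", "dihedral")) {
  set.seed(seed)
  samples <- vector("list", n_samples)
  n_mut <- max(2, n_residues %/% 3)
  for (i in seq_len(n_samples)) {
    label <- i %% 2
    wt_seq <- paste(sample(setdiff(aa_alphabet(), c("A", "D")),
                           n_residues, replace = TRUE), collapse = "")
    bb <- gen_helix_backbone(n_residues, wt_seq, jitter = 0.05,
                             seed = seed * 1000 + i)
    pos <- sort(sample(n_residues, n_mut))
    chars <- strsplit(wt_seq, "")[[1]]
    to <- if (label == 1) "A" else "D"
    mut <- paste0(chars[pos], pos, to, collapse = ";")
    mut_seq <- apply_mutations(wt_seq, mut)
    mb <- backbone_structure(mut_seq, bb$N, bb$CA, bb$C, bb$O)
    samples[[i]] <- list(
      wt = build_graph(bb, k_neighbors = k_neighbors, use = use),
      mut = build_graph(mb, k_neighbors = k_neighbors, use = use),
      label = label, mutations = mut)
  }
  samples
}
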