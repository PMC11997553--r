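# ---------------------------------------------------------------------------
# Backbone structures, per-residue encoders and geometric protein graphs
# ---------------------------------------------------------------------------

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(c(0, 0, 0))
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Backbone structure container
#'
#' Holds per-residue N, CA, C (and optionally O) coordinates in
#' Angstroms plus residue identities for a single chain. Consecutive
#' residues whose CA-CA distance falls outside [2.5, 4.5] Angstroms are
#' flagged as chain breaks; features spanning a break are masked
#' downstream.
#'
#' @param sequence Amino-acid string (length L).
#' @param N,CA,C,O L x 3 coordinate matrices (O may be NULL; it is not
#'   used by dihedrals or graph building).
#' @param chain Chain identifier.
#' @return An object of class `backbone_structure`.
#' @export
backbone_structure <- function(sequence, N, CA, C, O = NULL, chain = "A") {
  L <- nchar(sequence)
  for (m in list(N, CA, C)) {
    stopifnot(is.matrix(m), nrow(m) == L, ncol(m) == 3)
    if (any(!is.finite(m))) stop("non-finite backbone coordinates")
  }
  if (!is.null(O)) stopifnot(nrow(O) == L, ncol(O) == 3)
  d <- sqrt(rowSums((CA[-1, , drop = FALSE] - CA[-L, , drop = FALSE])^2))
  breaks <- d < 2.5 | d > 4.5
  structure(list(sequence = sequence, N = N, CA = CA, C = C, O = O,
                 chain = chain, n_residues = L,
                 breaks = if (L > 1) breaks else logical(0)),
            class = "backbone_structure")
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat("Backbone structure: ", x$n_residues, " residues, chain ", x$chain,
      ", ", sum(x$breaks), " chain break(s)\n", sep = "")
  invisible(x)
}

#' Read a backbone structure from a PDB file
#'
#' Reads ATOM records for one chain (the first, unless given), keeping
#' N/CA/C/O atoms with blank or "A" altloc. Residues missing any of
#' N/CA/C are dropped and the gap is flagged as a chain break by the
#' CA-CA distance rule.
#'
#' @param path PDB file path.
#' @param chain Chain id or NULL for the first chain present.
#' @return A [backbone_structure()].
#' @export
read_backbone <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  at <- at[at$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  res_ids <- unique(at$resno)
  rows <- list()
  seq3 <- character()
  for (r in res_ids) {
    sub <- at[at$resno == r, , drop = FALSE]
    if (!all(c("N", "CA", "C") %in% sub$elety)) next
    get <- function(el) {
      i <- which(sub$elety == el)[1]
      c(sub$x[i], sub$y[i], sub$z[i])
    }
    rows[[length(rows) + 1L]] <- list(
      N = get("N"), CA = get("CA"), C = get("C"),
      O = if ("O" %in% sub$elety) get("O") else c(NA, NA, NA),
      aa = sub$resid[which(sub$elety == "CA")[1]])
  }
  if (length(rows) < 2) stop("fewer than 2 complete residues in ", path)
  aa1 <- bio3d::aa321(vapply(rows, `[[`, "", "aa"))
  N <- do.call(rbind, lapply(rows, `[[`, "N"))
  CA <- do.call(rbind, lapply(rows, `[[`, "CA"))
  C <- do.call(rbind, lapply(rows, `[[`, "C"))
  O <- do.call(rbind, lapply(rows, `[[`, "O"))
  if (any(is.na(O))) O <- NULL
  backbone_structure(paste(aa1, collapse = ""), N, CA, C, O, chain = chain)
}

#' Write a backbone structure to a PDB file
#'
#' @param x A [backbone_structure()].
#' @param path Output path.
#' @export
write_backbone_pdb <- function(x, path) {
  aa3 <- bio3d::aa123(strsplit(x$sequence, "")[[1]])
  ele <- c("N", "CA", "C", "O")
  has_o <- !is.null(x$O)
  if (!has_o) ele <- c("N", "CA", "C")
  xyz <- c()
  elety <- c(); resid <- c(); resno <- c()
  for (i in seq_len(x$n_residues)) {
    for (e in ele) {
      xyz <- c(xyz, x[[e]][i, ])
      elety <- c(elety, e); resid <- c(resid, aa3[i]); resno <- c(resno, i)
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, elety = elety, resid = resid,
                   resno = resno, chain = x$chain, type = "ATOM")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Per-residue encoders
# ---------------------------------------------------------------------------

#' One-hot residue encoding
#'
#' @param residues Character vector of one-letter codes (or a sequence
#'   string).
#' @return length(residues) x 20 binary matrix, columns in alphabetical
#'   residue order.
#' @export
one_hot_encode <- function(residues) {
  if (length(residues) == 1 && nchar(residues) > 1)
    residues <- strsplit(residues, "")[[1]]
  aa <- aa_alphabet()
  idx <- match(residues, aa)
  if (any(is.na(idx)))
    stop("non-canonical residue: ", residues[is.na(idx)][1])
  m <- matrix(0, length(residues), 20, dimnames = list(NULL, aa))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Atchley factor encoding
#'
#' @inheritParams one_hot_encode
#' @return length(residues) x 5 matrix of the published factor scores.
#' @export
atchley_encode <- function(residues) {
  if (length(residues) == 1 && nchar(residues) > 1)
    residues <- strsplit(residues, "")[[1]]
  tab <- atchley_table()
  idx <- match(residues, rownames(tab))
  if (any(is.na(idx)))
    stop("non-canonical residue: ", residues[is.na(idx)][1])
  tab[idx, , drop = FALSE]
}

#' Load a per-residue evolutionary profile (PSSM)
#'
#' Accepts a numeric L x 20 matrix or a headered TSV path. Raw log-odds
#' scores are passed through a monotone squashing transform to a bounded
#' range (logistic, default) so profile magnitudes are comparable across
#' proteins.
#'
#' @param x Matrix or TSV path with 20 residue-named columns.
#' @param sequence Reference sequence (row count must match).
#' @param transform "sigmoid" (default, maps to (0,1)) or "none".
#' @param scale Logistic scale (default 2): encoded = 1/(1+exp(-x/scale)).
#' @return L x 20 matrix.
#' @export
load_pssm <- function(x, sequence, transform = c("sigmoid", "none"),
                      scale = 2) {
  transform <- match.arg(transform)
  if (is.character(x))
    x <- as.matrix(utils::read.table(x, header = TRUE, sep = "\t",
                                     check.names = FALSE))
  x <- as.matrix(x)
  if (nrow(x) != nchar(sequence))
    stop("PSSM has ", nrow(x), " rows but sequence has ",
         nchar(sequence), " residues")
  if (ncol(x) != 20) stop("PSSM must have 20 columns, got ", ncol(x))
  if (!is.null(colnames(x)) && all(aa_alphabet() %in% colnames(x)))
    x <- x[, aa_alphabet(), drop = FALSE]
  if (transform == "sigmoid") x <- 1 / (1 + exp(-x / scale))
  unname(x)
}

# pluggable structure-based encoder registry
.structure_encoders <- new.env(parent = emptyenv())

#' Register a structure-based per-residue encoder
#'
#' The structure-based feature slot is pluggable: alternative potentials
#' can be registered by name and selected via
#' [structure_potential_encode()].
#'
#' @param name Encoder name.
#' @param fn function(structure, ...) -> numeric vector (one value per
#'   residue).
#' @export
register_structure_encoder <- function(name, fn) {
  assign(name, fn, envir = .structure_encoders)
  invisible(name)
}

#' Contact-based structure potential
#'
#' The default structure-based encoding: for each residue, the count of
#' other CA atoms within `cutoff` Angstroms, normalized by the
#' structure's maximum count to [0, 1]. A stand-in for residue-level
#' contact potentials; replaceable via [register_structure_encoder()].
#'
#' @param structure A [backbone_structure()].
#' @param cutoff Contact cutoff in Angstroms (default 10).
#' @param method Registered encoder name (default "contact_count").
#' @return Numeric vector in [0, 1], one value per residue.
#' @export
structure_potential_encode <- function(structure, cutoff = 10,
                                       method = "contact_count") {
  fn <- get0(method, envir = .structure_encoders)
  if (is.null(fn)) stop("unknown structure encoder: ", method)
  fn(structure, cutoff = cutoff)
}

.contact_count_encoder <- function(structure, cutoff = 10) {
  D <- as.matrix(stats::dist(structure$CA))
  counts <- rowSums(D <= cutoff) - 1
  unname(counts / max(1, max(counts)))
}

register_structure_encoder("contact_count", .contact_count_encoder)

#' Load a per-residue score table
#'
#' Accepts a numeric L x 20 table or headered TSV path with exactly the
#' columns of [residue_score_schema()] (any column order: matching is by
#' name, not position). These tables are produced externally by
#' all-atom scoring; the package only consumes them.
#'
#' @param x Data.frame/matrix or TSV path.
#' @param sequence Reference sequence (row count must match).
#' @return L x 20 matrix, columns in schema order.
#' @export
load_residue_scores <- function(x, sequence) {
  if (is.character(x))
    x <- utils::read.table(x, header = TRUE, sep = "\t",
                           check.names = FALSE)
  x <- as.data.frame(x)
  schema <- residue_score_schema()
  if (ncol(x) != 20)
    stop("residue score table must have 20 columns, got ", ncol(x))
  if (is.null(colnames(x)) || !all(schema %in% colnames(x)))
    stop("residue score table must carry the named schema columns: ",
         paste(setdiff(schema, colnames(x)), collapse = ", "))
  if (nrow(x) != nchar(sequence))
    stop("residue score table has ", nrow(x), " rows but sequence has ",
         nchar(sequence), " residues")
  as.matrix(x[, schema])
}

# ---------------------------------------------------------------------------
# Dihedrals
# ---------------------------------------------------------------------------

.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  atan2(sum(.cross3(n1, n2) * .unit(b2)), sum(n1 * n2))
}

#' Backbone dihedral angles
#'
#' Computes per-residue phi, psi, omega torsions and their (sin, cos)
#' encodings. Angles undefined at chain termini (phi of the first
#' residue; psi and omega bookkeeping at the last) or spanning a chain
#' break are encoded (0, 0) and flagged in the validity mask.
#'
#' @param structure A [backbone_structure()].
#' @return List: `angles` (L x 3, radians, NA where undefined),
#'   `encoded` (L x 6: sin/cos of phi, psi, omega), `mask` (L x 3
#'   logical, TRUE = defined).
#' @export
compute_dihedrals <- function(structure) {
  L <- structure$n_residues
  N <- structure$N; CA <- structure$CA; C <- structure$C
  brk <- structure$breaks
  ok_prev <- function(i) i > 1 && !brk[i - 1]     # i-1 -> i link intact
  ok_next <- function(i) i < L && !brk[i]
  ang <- matrix(NA_real_, L, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
  for (i in seq_len(L)) {
    if (ok_prev(i))
      ang[i, "phi"] <- .torsion(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (ok_next(i))
      ang[i, "psi"] <- .torsion(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
    if (ok_prev(i))
      ang[i, "omega"] <- .torsion(CA[i - 1, ], C[i - 1, ], N[i, ], CA[i, ])
  }
  mask <- !is.na(ang)
  enc <- matrix(0, L, 6, dimnames = list(NULL, c(
    "sin_phi", "cos_phi", "sin_psi", "cos_psi", "sin_omega", "cos_omega")))
  for (j in 1:3) {
    def <- mask[, j]
    enc[def, 2 * j - 1] <- sin(ang[def, j])
    enc[def, 2 * j] <- cos(ang[def, j])
  }
  list(angles = ang, encoded = enc, mask = mask)
}

# ---------------------------------------------------------------------------
# Encoder stack and graph construction
# ---------------------------------------------------------------------------

#' Concatenated node scalar features
#'
#' Builds the node scalar feature matrix by concatenating the selected
#' per-residue encoder families in fixed order: one-hot (20), Atchley
#' factors (5), PSSM (20), structure potential (1), residue scores (20),
#' dihedral sin/cos (6). Families whose side-tables are not supplied can
#' be dropped via `use`.
#'
#' @param structure A [backbone_structure()].
#' @param pssm Optional L x 20 matrix/path for [load_pssm()].
#' @param residue_scores Optional table/path for [load_residue_scores()].
#' @param use Character subset of
#'   c("one_hot","atchley","pssm","potential","scores","dihedral").
#' @return L x width matrix with a `"widths"` attribute naming each
#'   family's contribution.
#' @export
encode_residues <- function(structure, pssm = NULL, residue_scores = NULL,
                            use = c("one_hot", "atchley", "pssm",
                                    "potential", "scores", "dihedral")) {
  res <- strsplit(structure$sequence, "")[[1]]
  parts <- list(); widths <- integer()
  if ("one_hot" %in% use) {
    parts$one_hot <- one_hot_encode(res); widths["one_hot"] <- 20L
  }
  if ("atchley" %in% use) {
    parts$atchley <- atchley_encode(res); widths["atchley"] <- 5L
  }
  if ("pssm" %in% use) {
    if (is.null(pssm)) stop("encoder family 'pssm' selected but no PSSM given")
    parts$pssm <- load_pssm(pssm, structure$sequence); widths["pssm"] <- 20L
  }
  if ("potential" %in% use) {
    parts$potential <- matrix(structure_potential_encode(structure), ncol = 1)
    widths["potential"] <- 1L
  }
  if ("scores" %in% use) {
    if (is.null(residue_scores))
      stop("encoder family 'scores' selected but no residue score table given")
    parts$scores <- load_residue_scores(residue_scores, structure$sequence)
    widths["scores"] <- 20L
  }
  if ("dihedral" %in% use) {
    parts$dihedral <- compute_dihedrals(structure)$encoded
    widths["dihedral"] <- 6L
  }
  out <- do.call(cbind, parts)
  attr(out, "widths") <- widths
  out
}

#' Radial basis expansion of a distance
#'
#' Gaussian kernels at `n_centers` evenly spaced centers over `range`,
#' width equal to the center spacing: a distance exactly at a center
#' activates that component to 1.
#'
#' @param d Numeric vector of distances (Angstroms).
#' @param n_centers Number of basis functions (default 16).
#' @param range Two-element range in Angstroms (default c(0, 20)).
#' @return length(d) x n_centers matrix with entries in (0, 1].
#' @export
rbf_expand <- function(d, n_centers = 16, range = c(0, 20)) {
  centers <- seq(range[1], range[2], length.out = n_centers)
  sigma <- centers[2] - centers[1]
  out <- exp(-((outer(d, centers, "-")) / sigma)^2)
  attr(out, "centers") <- centers
  out
}

.node_vectors <- function(structure) {
  L <- structure$n_residues
  CA <- structure$CA; N <- structure$N; C <- structure$C
  brk <- structure$breaks
  V <- array(0, dim = c(L, 3, 3))  # (residue, {forward, backward, sidechain}, xyz)
  for (i in seq_len(L)) {
    if (i < L && !brk[i]) V[i, 1, ] <- .unit(CA[i + 1, ] - CA[i, ])
    if (i > 1 && !brk[i - 1]) V[i, 2, ] <- .unit(CA[i - 1, ] - CA[i, ])
    cv <- .unit(C[i, ] - CA[i, ]); nv <- .unit(N[i, ] - CA[i, ])
    bis <- .unit(cv + nv); perp <- .unit(.cross3(cv, nv))
    V[i, 3, ] <- -bis * sqrt(1 / 3) - perp * sqrt(2 / 3)  # imputed side-chain
  }
  V
}

#' Build a geometric protein graph
#'
#' Converts a backbone structure into the graph consumed by the model:
#' residues as nodes, directed edges from each residue's k nearest CA
#' neighbours (ties broken by residue index; k truncated to n-1 for
#' short chains). Node scalars are the encoder-stack concatenation; node
#' vectors are the forward/backward CA unit vectors plus an imputed
#' side-chain direction from idealized backbone geometry; edge scalars
#' are the RBF-expanded CA-CA distance; edge vectors the unit
#' displacement from the receiving residue to its neighbour.
#'
#' @param structure A [backbone_structure()] with >= 2 residues.
#' @param k_neighbors Number of nearest neighbours (default 30).
#' @param rbf List: n_centers (16), range (c(0, 20)).
#' @param ... Passed to [encode_residues()] (pssm, residue_scores, use).
#' @return An object of class `protein_graph`: S (node scalars), V (node
#'   vectors, L x 3 x 3), edge_index (2 x E matrix, row 1 = source, row
#'   2 = destination), Se (E x n_centers), Ve (E x 1 x 3).
#' @export
build_graph <- function(structure, k_neighbors = 30,
                        rbf = list(n_centers = 16, range = c(0, 20)),
                        ...) {
  L <- structure$n_residues
  if (L < 2) stop("graph building needs at least 2 residues")
  stopifnot(k_neighbors >= 1)
  S <- encode_residues(structure, ...)
  widths <- attr(S, "widths")
  attributes(S) <- list(dim = dim(S))
  V <- .node_vectors(structure)
  D <- as.matrix(stats::dist(structure$CA))
  k <- min(k_neighbors, L - 1)
  src <- integer(0); dst <- integer(0)
  for (i in seq_len(L)) {
    # quantize before ordering so distance ties (and sub-1e-6 numeric
    # noise from rigid motions) break deterministically by residue index
    ord <- order(round(D[i, ] * 1e6), seq_len(L))
    ord <- ord[ord != i][seq_len(k)]
    src <- c(src, ord); dst <- c(dst, rep(i, k))
  }
  d <- D[cbind(src, dst)]
  Se <- rbf_expand(d, rbf$n_centers, rbf$range)
  rbf$centers <- attr(Se, "centers")
  attributes(Se) <- list(dim = dim(Se))
  Ve <- array(0, dim = c(length(src), 1, 3))
  disp <- structure$CA[src, , drop = FALSE] - structure$CA[dst, , drop = FALSE]
  nrm <- sqrt(rowSums(disp^2))
  Ve[, 1, ] <- disp / pmax(nrm, 1e-12)
  g <- list(S = unname(S), V = V,
            edge_index = rbind(src = src, dst = dst),
            Se = unname(Se), Ve = Ve,
            distances = d, n_nodes = L,
            meta = list(k_neighbors = k_neighbors,
                        rbf = rbf,
                        widths = widths,
                        sequence = structure$sequence))
  class(g) <- "protein_graph"
  g
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("Protein graph: ", x$n_nodes, " nodes, ", ncol(x$edge_index),
      " edges, scalar width ", ncol(x$S), ", ", dim(x$V)[2],
      " node vectors\n", sep = "")
  invisible(x)
}

#' Serialize / load a protein graph
#'
#' Graphs are archived as a single JSON document carrying the arrays
#' plus metadata (k, RBF configuration, encoder widths, sequence).
#'
#' @param graph A `protein_graph`.
#' @param path Output path (.json).
#' @return `load_graph()` returns the reconstructed `protein_graph`.
#' @export
save_graph <- function(graph, path) {
  obj <- list(S = graph$S, V = as.vector(graph$V), V_dim = dim(graph$V),
              edge_index = graph$edge_index, Se = graph$Se,
              Ve = as.vector(graph$Ve), Ve_dim = dim(graph$Ve),
              distances = graph$distances, n_nodes = graph$n_nodes,
              meta = graph$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- list(S = as.matrix(obj$S),
            V = array(obj$V, dim = obj$V_dim),
            edge_index = matrix(as.integer(obj$edge_index), nrow = 2,
                                dimnames = list(c("src", "dst"), NULL)),
            Se = as.matrix(obj$Se),
            Ve = array(obj$Ve, dim = obj$Ve_dim),
            distances = obj$distances,
            n_nodes = obj$n_nodes,
            meta = obj$meta)
  rownames(g$edge_index) <- c("src", "dst")
  class(g) <- "protein_graph"
  g
}
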