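test_that("one-hot encoding is exact and rejects non-canonical residues", {
  m <- one_hot_encode("A")
  expect_equal(which(m[1, ] == 1), c(A = 1L))
  m <- one_hot_encode("ACDW")
  expect_equal(rowSums(m), rep(1, 4))
  expect_error(one_hot_encode("X"), "non-canonical")
})

test_that("Atchley encoding is the bundled standardized table", {
  tab <- atchley_table()
  expect_equal(dim(tab), c(20, 5))
  # factor scores are centered over the 20 residues
  expect_true(all(abs(colMeans(tab)) < 0.005))
  m <- atchley_encode("AR")
  expect_equal(unname(m[1, ]), unname(tab["A", ]))
  expect_equal(unname(m[2, ]), unname(tab["R", ]))
  expect_error(atchley_encode("B"), "non-canonical")
})

test_that("PSSM loading enforces shape and squashes monotonically", {
  seqn <- "ACDEFGHIKLMN"
  p <- gen_pssm(seqn, seed = 2)
  enc <- load_pssm(p, seqn)
  expect_equal(dim(enc), c(12, 20))
  expect_true(all(enc > 0 & enc < 1))
  expect_error(load_pssm(p[1:5, ], seqn), "rows")
  # monotone: larger raw score -> larger encoded value
  set.seed(3)
  for (i in 1:10) {
    a <- stats::rnorm(1); b <- a + abs(stats::rnorm(1)) + 1e-6
    m <- matrix(c(a, b, rep(0, 38)), 2, 20)
    e <- load_pssm(m, "AC")
    expect_lt(e[1, 1], e[2, 1])
  }
  raw <- load_pssm(p, seqn, transform = "none")
  expect_equal(raw, unname(p))
})

test_that("contact potential matches brute force and ranks core above termini", {
  bb <- gen_helix_backbone(25, seed = 3)
  pot <- structure_potential_encode(bb, cutoff = 10)
  expect_true(all(pot >= 0 & pot <= 1))
  # brute-force contact count oracle
  counts <- vapply(1:25, function(i) {
    sum(sqrt(rowSums((bb$CA - matrix(bb$CA[i, ], 25, 3,
                                     byrow = TRUE))^2)) <= 10) - 1
  }, 1)
  expect_equal(pot, counts / max(counts))
  # interior residue denser than the terminus
  expect_gt(pot[13], pot[1])
  # a fully extended chain has near-minimal interior contact
  ext <- backbone_structure(
    paste(rep("A", 10), collapse = ""),
    N = cbind(seq(0, 9) * 3.8 - 0.5, 0, 0),
    CA = cbind(seq(0, 9) * 3.8, 0, 0),
    C = cbind(seq(0, 9) * 3.8 + 0.5, 0, 0))
  pe <- structure_potential_encode(ext, cutoff = 10)
  counts_e <- vapply(1:10, function(i)
    sum(abs(seq(0, 9) * 3.8 - (i - 1) * 3.8) <= 10) - 1, 1)
  expect_equal(pe, counts_e / max(counts_e))
})

test_that("residue score tables are schema-driven, not positional", {
  seqn <- "ACDEFG"
  tab <- gen_residue_scores(seqn, seed = 4)
  m1 <- load_residue_scores(tab, seqn)
  expect_equal(dim(m1), c(6, 20))
  # shuffled columns with headers reproduce identical output
  perm <- sample(ncol(tab))
  m2 <- load_residue_scores(tab[, perm], seqn)
  expect_identical(m1, m2)
  expect_error(load_residue_scores(tab[, 1:19], seqn), "20 columns")
  expect_error(load_residue_scores(tab[1:3, ], seqn), "rows")
  bad <- tab; names(bad)[1] <- "mystery"
  expect_error(load_residue_scores(bad, seqn), "schema")
})

test_that("dihedrals match an independent torsion oracle on ideal helices", {
  bb <- gen_helix_backbone(12, seed = 5)
  dh <- compute_dihedrals(bb)
  interior <- 2:11
  expect_true(all(abs(dh$angles[interior, "phi"] * 180 / pi - (-57)) < 2))
  expect_true(all(abs(dh$angles[interior, "psi"] * 180 / pi - (-47)) < 2))
  # trans peptide omega: (sin, cos) = (0, -1)
  expect_equal(unname(dh$encoded[2, c("sin_omega", "cos_omega")]),
               c(0, -1), tolerance = 1e-6)
  # independent four-atom torsion oracle (bio3d)
  for (i in interior) {
    oracle <- bio3d::torsion.xyz(c(bb$C[i - 1, ], bb$N[i, ],
                                   bb$CA[i, ], bb$C[i, ]))
    expect_equal(unname(dh$angles[i, "phi"] * 180 / pi), unname(oracle),
                 tolerance = 1e-6)
  }
  # termini masked
  expect_false(dh$mask[1, "phi"])
  expect_false(dh$mask[12, "psi"])
  expect_equal(unname(dh$encoded[1, c("sin_phi", "cos_phi")]), c(0, 0))
})

test_that("chain breaks mask spanning dihedrals", {
  bb <- gen_helix_backbone(10, seed = 6)
  shifted <- bb
  gap <- function(m) rbind(m[1:5, ], sweep(m[6:10, ], 2, c(40, 0, 0), "+"))
  broken <- backbone_structure(bb$sequence, gap(bb$N), gap(bb$CA),
                               gap(bb$C))
  expect_true(broken$breaks[5])
  dh <- compute_dihedrals(broken)
  expect_false(dh$mask[6, "phi"])    # spans the break
  expect_false(dh$mask[5, "psi"])
  expect_false(dh$mask[6, "omega"])
  expect_true(dh$mask[7, "phi"])
})

test_that("k-NN graph edges match an exhaustive distance scan", {
  bb <- gen_helix_backbone(20, jitter = 0.05, seed = 7)
  g <- build_graph(bb, k_neighbors = 5,
                   use = c("one_hot", "dihedral"))
  D <- as.matrix(dist(bb$CA))
  for (i in 1:20) {
    nb <- g$edge_index["src", g$edge_index["dst", ] == i]
    ord <- order(D[i, ], seq_len(20))
    oracle <- setdiff(ord, i)[1:5]
    expect_setequal(nb, oracle)
  }
  # collinear chain, k = 2: neighbors are the adjacent residues
  lin <- backbone_structure(
    "AAAA", N = cbind(0:3 * 3.8 - 0.5, 0, 0),
    CA = cbind(0:3 * 3.8, 0, 0), C = cbind(0:3 * 3.8 + 0.5, 0, 0))
  gl <- build_graph(lin, k_neighbors = 2, use = "one_hot")
  expect_setequal(gl$edge_index["src", gl$edge_index["dst", ] == 1],
                  c(2, 3))
  expect_setequal(gl$edge_index["src", gl$edge_index["dst", ] == 2],
                  c(1, 3))
  # k truncation: n = 2, k = 30 -> one edge per node
  two <- backbone_structure(
    "AA", N = cbind(c(0, 3.8) - 0.5, 0, 0),
    CA = cbind(c(0, 3.8), 0, 0), C = cbind(c(0, 3.8) + 0.5, 0, 0))
  g2 <- build_graph(two, k_neighbors = 30, use = "one_hot")
  expect_equal(ncol(g2$edge_index), 2)
  expect_error(build_graph(two, k_neighbors = 0), "k_neighbors")
})

test_that("RBF expansion peaks at its centers and brackets distances", {
  r <- rbf_expand(c(0, 20), n_centers = 16, range = c(0, 20))
  centers <- attr(r, "centers")
  expect_equal(r[1, 1], 1)       # distance exactly at the first center
  expect_equal(r[2, 16], 1)
  expect_true(all(r > 0 & r <= 1))
  # argmax center recovers the distance within one bin width
  d <- runif(20, 0, 20)
  rr <- rbf_expand(d)
  dec <- centers[apply(rr, 1, which.max)]
  expect_true(all(abs(dec - d) <= centers[2] - centers[1]))
})

test_that("scalar features are rigid-motion invariant, vectors equivariant", {
  bb <- gen_helix_backbone(15, jitter = 0.03, seed = 8)
  g0 <- build_graph(bb, k_neighbors = 6,
                    use = c("one_hot", "potential", "dihedral"))
  for (s in 1:5) {
    R <- random_rotation(seed = 100 + s)
    t <- stats::rnorm(3, sd = 10)
    gt <- build_graph(transform_structure(bb, R, t), k_neighbors = 6,
                      use = c("one_hot", "potential", "dihedral"))
    expect_equal(gt$S, g0$S, tolerance = 1e-6)
    expect_equal(gt$Se, g0$Se, tolerance = 1e-6)
    expect_identical(gt$edge_index, g0$edge_index)
    for (j in 1:3)
      expect_equal(gt$V[, j, ], g0$V[, j, ] %*% t(R), tolerance = 1e-9)
    expect_equal(matrix(gt$Ve[, 1, ], ncol = 3),
                 matrix(g0$Ve[, 1, ], ncol = 3) %*% t(R),
                 tolerance = 1e-9)
  }
  # determinism: same structure + config -> identical graph
  g1 <- build_graph(bb, k_neighbors = 6,
                    use = c("one_hot", "potential", "dihedral"))
  expect_identical(g0[c("S", "V", "edge_index", "Se", "Ve")],
                   g1[c("S", "V", "edge_index", "Se", "Ve")])
})

test_that("node vectors have unit norm except where undefined", {
  bb <- gen_helix_backbone(10, seed = 9)
  g <- build_graph(bb, k_neighbors = 4, use = "one_hot")
  nrm <- sqrt(apply(g$V^2, c(1, 2), sum))
  expect_equal(nrm[1, 2], 0)            # no backward vector at N-terminus
  expect_equal(nrm[10, 1], 0)           # no forward vector at C-terminus
  defined <- nrm[nrm > 0]
  expect_equal(defined, rep(1, length(defined)), tolerance = 1e-9)
  env <- sqrt(rowSums(matrix(g$Ve[, 1, ], ncol = 3)^2))
  expect_equal(env, rep(1, length(env)), tolerance = 1e-9)
})

test_that("graphs and PDB files round-trip through their archives", {
  bb <- gen_helix_backbone(10, seed = 10)
  pdb <- file.path(tempdir(), "helix.pdb")
  write_backbone_pdb(bb, pdb)
  back <- read_backbone(pdb)
  expect_equal(back$sequence, bb$sequence)
  expect_equal(back$CA, bb$CA, tolerance = 1e-3)  # PDB has 3 decimals
  g <- build_graph(bb, k_neighbors = 4,
                   pssm = gen_pssm(bb$sequence, 1),
                   residue_scores = gen_residue_scores(bb$sequence, 1))
  gp <- file.path(tempdir(), "graph.json")
  save_graph(g, gp)
  g2 <- load_graph(gp)
  expect_equal(g2$S, g$S)
  expect_equal(g2$V, g$V)
  expect_equal(unname(g2$edge_index), unname(g$edge_index))
  expect_equal(g2$Se, g$Se)
  expect_equal(g2$Ve, g$Ve)
})

test_that("the encoder stack concatenates declared widths in order", {
  bb <- gen_helix_backbone(8, seed = 11)
  S <- encode_residues(bb, pssm = gen_pssm(bb$sequence, 1),
                       residue_scores = gen_residue_scores(bb$sequence, 1))
  w <- attr(S, "widths")
  expect_equal(unname(w), c(20L, 5L, 20L, 1L, 20L, 6L))
  expect_equal(ncol(S), 72)
  expect_error(encode_residues(bb, use = c("one_hot", "pssm")), "no PSSM")
  S2 <- encode_residues(bb, use = c("one_hot", "dihedral"))
  expect_equal(ncol(S2), 26)
})
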