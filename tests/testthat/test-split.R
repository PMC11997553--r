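test_that("mutation-type vocabulary and multi-hot encoding", {
  df <- mutation_dataset(data.frame(
    record_id = c("r1", "r2", "r3"),
    wt_id = "P", wt_sequence = "LKLKLK",
    mutations = c("L1A;K2R", "L3A", "L1A;L3A"),
    ddg = 1, stringsAsFactors = FALSE))
  vocab <- mutation_type_vocabulary(df)
  expect_equal(vocab, c("K>R", "L>A"))  # lexicographic, deduplicated
  v <- encode_type_combination(df, vocab)
  expect_equal(unname(v[1, ]), c(1L, 1L))
  expect_equal(unname(v[2, ]), c(0L, 1L))   # single type: exactly one 1
  # same type set at different positions -> identical vectors
  expect_equal(unname(v[2, ]), unname(v[3, ]))
  bad <- df; bad$mutations[1] <- "K2C"
  expect_error(encode_type_combination(bad, vocab), "K>C")
})

test_that("clustering separates disjoint type blocs and is deterministic", {
  set.seed(1)
  typesA <- c("A>C", "A>D", "C>E", "D>F", "E>G",
              "F>H", "G>I", "H>K", "I>L", "K>M")
  typesB <- c("L>N", "L>P", "N>Q", "P>R", "Q>S",
              "R>T", "S>V", "T>W", "V>Y", "W>A")
  vocab <- sort(c(typesA, typesB))
  mkvec <- function(types) t(vapply(1:50, function(i) {
    v <- integer(20); names(v) <- vocab
    v[sample(types, 2)] <- 1L
    v
  }, integer(20)))
  vec <- rbind(mkvec(typesA), mkvec(typesB))
  # exact multi-hot distance oracle: the blocs share no type, so every
  # cross-bloc squared distance (4) exceeds every within-bloc one (<= 4
  # only when disjoint pairs within a bloc... check the margin directly)
  D2 <- as.matrix(dist(vec))^2
  expect_true(min(D2[1:50, 51:100]) >= 2)
  lab <- cluster_types(vec, seed = 42)
  found <- setdiff(unique(lab), 0L)
  expect_equal(length(found), 2)
  # bloc purity: each bloc maps into a single cluster
  expect_equal(length(unique(lab[1:50])), 1)
  expect_equal(length(unique(lab[51:100])), 1)
  expect_identical(lab, cluster_types(vec, seed = 42))  # determinism
  # degenerate input: all identical vectors -> one cluster, no failure
  same <- vec[rep(1, 10), ]
  expect_equal(unique(cluster_types(same, seed = 1)), 1L)
})

test_that("quota allocation moves wild types whole", {
  # 10 wild types x 10 records, one cluster, fraction 0.2 -> exactly
  # 2 wild types (20 records) in test
  df <- gen_mutation_dataset(10, 10, chain_length = 10, seed = 4)
  lab <- rep(1L, nrow(df))
  split <- allocate_split(df, lab, 0.2, seed = 1)
  expect_equal(sum(split$partition == "test"), 20)
  test_wt <- unique(df$wt_sequence[split$partition == "test"])
  expect_equal(length(test_wt), 2)
  # partition property
  expect_setequal(split$partition, c("train", "test"))
  expect_equal(nrow(split), nrow(df))
  # no wild-type sequence in both partitions
  expect_length(intersect(df$wt_sequence[split$partition == "test"],
                          df$wt_sequence[split$partition == "train"]), 0)
})

test_that("oversized single-owner clusters under-fill and report shortfall", {
  # one wild type owns cluster 2 entirely, holding half of all records
  df <- gen_mutation_dataset(11, 2, chain_length = 10, seed = 6)
  big <- df[rep(which(df$wt_id == "SYN0011"), 10), ]
  big$record_id <- sprintf("big%03d", seq_len(nrow(big)))
  df <- mutation_dataset(rbind(df[df$wt_id != "SYN0011", ], big))
  lab <- ifelse(df$wt_id == "SYN0011", 2L, 1L)
  expect_message(split <- allocate_split(df, lab, 0.2, seed = 3),
                 "under-filled")
  man <- attr(split, "manifest")
  expect_gt(man$shortfall[["2"]], 0)
  # the dominant wild type stayed in train rather than flooding test
  expect_true(all(split$partition[lab == 2L] == "train"))
})

test_that("split assignment is deterministic and leakage-free over seeds", {
  ds <- gen_mutation_dataset(20, 6, chain_length = 12,
                             n_mutations = c(1, 3), seed = 2)
  vocab <- mutation_type_vocabulary(ds)
  vec <- encode_type_combination(ds, vocab)
  lab <- cluster_types(vec, seed = 1)
  s1 <- allocate_split(ds, lab, 0.2, seed = 5)
  s2 <- allocate_split(ds, lab, 0.2, seed = 5)
  expect_identical(s1, s2)
  for (seed in 1:5) {
    s <- allocate_split(ds, lab, 0.2, seed = seed)
    expect_length(intersect(ds$wt_sequence[s$partition == "test"],
                            ds$wt_sequence[s$partition == "train"]), 0)
    frac <- mean(s$partition == "test")
    expect_gte(frac, 0.15); expect_lte(frac, 0.25)
  }
})

test_that("split manifests serialize assignment, quotas and seed", {
  ds <- gen_mutation_dataset(6, 4, chain_length = 10, seed = 3)
  split <- allocate_split(ds, rep(1L, nrow(ds)), 0.25, seed = 9)
  path <- file.path(tempdir(), "split.tsv")
  write_split_manifest(split, path)
  back <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expect_equal(back$record_id, split$record_id)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$seed, 9)
  expect_equal(side$test_fraction, 0.25)
  expect_true(!is.null(side$quota))
})
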