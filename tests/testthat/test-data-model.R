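test_that("mutation notation parses, formats and rejects malformed tokens", {
  p <- parse_mutations("L10A;K20R")
  expect_equal(p$from, c("L", "K"))
  expect_equal(p$pos, c(10L, 20L))
  expect_equal(p$to, c("A", "R"))
  expect_equal(format_mutations(p), "L10A;K20R")
  # ordering is canonical by position
  expect_equal(format_mutations(parse_mutations("K20R;L10A")), "L10A;K20R")
  expect_error(parse_mutations("L10"), "malformed")
  expect_error(parse_mutations("X10A"), "non-canonical")
  expect_error(parse_mutations("L10L"), "identical")
  expect_error(parse_mutations("L10A;L10C"), "duplicate")
  expect_equal(nrow(parse_mutations("")), 0)
})

test_that("stability labeling follows the sign convention and flags zeros", {
  expect_identical(classify_label(1.0, "stabilizing_positive"), 1L)
  expect_identical(classify_label(-1.0, "stabilizing_positive"), 0L)
  expect_identical(classify_label(1.0, "stabilizing_negative"), 0L)
  expect_identical(classify_label(-1.0, "stabilizing_negative"), 1L)
  expect_warning(z <- classify_label(0.0, "stabilizing_positive"),
                 "exactly 0")
  expect_identical(z, 0L)
  expect_error(classify_label(NaN), "non-finite")
  # antisymmetry about zero under a fixed convention
  set.seed(1)
  for (x in stats::rnorm(25)) {
    if (x == 0) next
    expect_true(classify_label(x) != classify_label(-x))
  }
})

test_that("apply_mutations and diff_sequences are mutually inverse", {
  expect_equal(apply_mutations("ACDEFG", "C2W"), "AWDEFG")
  expect_equal(apply_mutations("ACDEFG", ""), "ACDEFG")
  expect_equal(apply_mutations("ACDEFG", "A1C;C2A"), "CADEFG")
  expect_error(apply_mutations("ACDEFG", "W2C"), "mismatch")
  expect_error(apply_mutations("ACD", "C9A"), "beyond")
  expect_equal(diff_sequences("AWDEFG", "ACDEFG"), "W2C")
  expect_equal(diff_sequences("ACDEFG", "ACDEFG"), "")
  expect_error(diff_sequences("ACD", "ACDE"), "length mismatch")
  # round-trip property against a brute-force position scan
  set.seed(42)
  aa <- aa_alphabet()
  for (rep in 1:20) {
    L <- sample(5:30, 1)
    s <- paste(sample(aa, L, replace = TRUE), collapse = "")
    k <- sample(0:min(4, L), 1)
    pos <- sort(sample(L, k))
    sc <- strsplit(s, "")[[1]]
    to <- vapply(pos, function(p) sample(setdiff(aa, sc[p]), 1), "")
    m <- if (k == 0) "" else paste0(sc[pos], pos, to, collapse = ";")
    s2 <- apply_mutations(s, m)
    # brute-force scan oracle
    sc2 <- strsplit(s2, "")[[1]]
    oracle <- which(sc != sc2)
    expect_equal(diff_sequences(s, s2), if (length(oracle) == 0) "" else
      paste0(sc[oracle], oracle, sc2[oracle], collapse = ";"))
    expect_equal(apply_mutations(s, diff_sequences(s, s2)), s2)
  }
})

test_that("deduplication keeps first occurrence, logs conflicts, is idempotent", {
  df <- mutation_dataset(data.frame(
    record_id = c("a", "b", "c", "d"),
    wt_id = c("P1", "P1", "P2", "P1"),
    wt_sequence = c("ACDEFG", "ACDEFG", "MKLVWY", "ACDEFG"),
    mutations = c("C2W", "C2W", "K2R", "C2W"),
    ddg = c(1.0, 1.0, 1.0, -2.0), stringsAsFactors = FALSE))
  expect_message(out <- dedup_records(df), "conflicting ddg")
  expect_equal(nrow(out), 2)
  expect_equal(out$record_id, c("a", "c"))  # first occurrence wins
  expect_equal(out$ddg[out$record_id == "a"], 1.0)
  expect_length(attr(out, "conflicts"), 1)
  # same mutation on different wild types stays distinct
  expect_equal(sum(out$wt_sequence == "MKLVWY"), 1)
  # idempotence
  out2 <- dedup_records(out)
  expect_equal(out2[, names(out2)], out[, names(out2)],
               ignore_attr = TRUE)
})

test_that("measurement selection drops empty records and derives labels", {
  df <- mutation_dataset(data.frame(
    record_id = c("g1", "g2", "t1"),
    wt_id = "P1", wt_sequence = "ACDEFG",
    mutations = c("C2W", "D3E", "E4K"),
    ddg = c(1.5, NA, NA), dtm = c(NA, NA, 3.0),
    label = c(NA, 0L, NA), stringsAsFactors = FALSE))
  out <- select_measurement(df)
  expect_equal(out$label[out$record_id == "g1"], 1L)   # from ddg
  expect_equal(out$label[out$record_id == "t1"], 1L)   # from dtm sign
  # record with neither measurement nor label never validates at intake
  expect_error(mutation_dataset(data.frame(
    record_id = "x", wt_id = "P", wt_sequence = "ACD",
    mutations = "C2W", stringsAsFactors = FALSE)), "none of")
})

test_that("homology filtering removes oracle-flagged proteins only", {
  set.seed(9)
  aa <- aa_alphabet()
  seqs <- vapply(1:5, function(i)
    paste(sample(aa, 40, replace = TRUE), collapse = ""), "")
  # protein 4 is a near-copy of protein 1 (>= 90% identity)
  s4 <- strsplit(seqs[1], "")[[1]]
  s4[1:3] <- ifelse(s4[1:3] == "A", "C", "A")
  seqs[4] <- paste(s4, collapse = "")
  df <- mutation_dataset(data.frame(
    record_id = paste0("r", 1:5), wt_id = paste0("P", 1:5),
    wt_sequence = seqs,
    mutations = vapply(seqs, function(s)
      paste0(substr(s, 1, 1), 1,
             setdiff(aa, substr(s, 1, 1))[1]), ""),
    ddg = 1, stringsAsFactors = FALSE))
  expect_error(homology_filter(df, seqs[1]), "backend")
  expect_identical(homology_filter(df, character(0)), df)
  out <- homology_filter(df, seqs[1], backend = identity_backend(0.9))
  # brute-force pairwise identity oracle
  ident <- vapply(seqs, function(q) mean(strsplit(q, "")[[1]] ==
                                           strsplit(seqs[1], "")[[1]]), 1)
  expect_setequal(out$wt_sequence, seqs[ident < 0.9])
  expect_true(all(out$record_id %in% df$record_id))  # subset of input
})

test_that("the blastp backend flags a self-hit", {
  set.seed(5)
  q <- paste(sample(aa_alphabet(), 60, replace = TRUE), collapse = "")
  other <- paste(sample(aa_alphabet(), 60, replace = TRUE), collapse = "")
  flagged <- blastp_backend()(c(q, other), q, 0.001)
  expect_true(flagged[1])
})

test_that("mutation tables round-trip through CSV and TSV", {
  df <- toy_dataset()
  for (ext in c("csv", "tsv")) {
    path <- file.path(tempdir(), paste0("muts.", ext))
    write_mutation_table(df, path)
    back <- read_mutation_table(path)
    expect_equal(back$record_id, df$record_id)
    expect_equal(back$mutations, df$mutations)
    expect_equal(back$ddg, df$ddg)
  }
})
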