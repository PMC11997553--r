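# ---------------------------------------------------------------------------
# Mutation notation
# ---------------------------------------------------------------------------

#' Parse point-mutation tokens
#'
#' Parses mutation tokens in the standard "L10A" notation (wild-type
#' residue, 1-based position, mutant residue). Multiple mutations are
#' given as a character vector or a single semicolon-joined string.
#'
#' @param x Character vector of tokens, or one string like "L10A;K20R".
#' @return A data.frame with columns `from`, `pos` (integer), `to`,
#'   one row per mutation, ordered by position.
#' @export
parse_mutations <- function(x) {
  if (length(x) == 1 && grepl(";", x, fixed = TRUE))
    x <- strsplit(x, ";", fixed = TRUE)[[1]]
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (length(x) == 0)
    return(data.frame(from = character(), pos = integer(), to = character(),
                      stringsAsFactors = FALSE))
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed mutation token(s): ", paste(x[bad], collapse = ", "))
  from <- vapply(m, `[`, "", 2L)
  pos  <- as.integer(vapply(m, `[`, "", 3L))
  to   <- vapply(m, `[`, "", 4L)
  aa <- aa_alphabet()
  if (!all(from %in% aa) || !all(to %in% aa))
    stop("non-canonical residue in mutation token(s): ",
         paste(x[!(from %in% aa & to %in% aa)], collapse = ", "))
  if (any(from == to))
    stop("mutation token(s) with identical from/to residue: ",
         paste(x[from == to], collapse = ", "))
  if (any(pos < 1)) stop("mutation positions must be >= 1")
  if (anyDuplicated(pos))
    stop("duplicate mutated position: ", pos[duplicated(pos)][1])
  o <- order(pos)
  data.frame(from = from[o], pos = pos[o], to = to[o],
             stringsAsFactors = FALSE)
}

#' Format a mutation table back to token notation
#'
#' Inverse of [parse_mutations()]: returns the canonical semicolon-joined
#' string, mutations ordered by position.
#'
#' @param mut Data.frame with columns `from`, `pos`, `to`.
#' @return A single string ("" for no mutations).
#' @export
format_mutations <- function(mut) {
  if (nrow(mut) == 0) return("")
  mut <- mut[order(mut$pos), , drop = FALSE]
  paste0(mut$from, mut$pos, mut$to, collapse = ";")
}

#' Apply point mutations to a sequence
#'
#' @param wt_sequence Amino-acid string.
#' @param mutations Tokens accepted by [parse_mutations()].
#' @return The mutated sequence.
#' @examples
#' apply_mutations("ACDEFG", "C2W")   # "AWDEFG"
#' @export
apply_mutations <- function(wt_sequence, mutations) {
  mut <- if (is.data.frame(mutations)) mutations else parse_mutations(mutations)
  s <- strsplit(wt_sequence, "")[[1]]
  if (nrow(mut) == 0) return(wt_sequence)
  if (any(mut$pos > length(s)))
    stop("mutation position ", max(mut$pos), " beyond sequence length ",
         length(s))
  mismatch <- s[mut$pos] != mut$from
  if (any(mismatch))
    stop("wild-type residue mismatch at position ",
         mut$pos[mismatch][1], ": sequence has '", s[mut$pos[mismatch][1]],
         "', mutation expects '", mut$from[mismatch][1], "'")
  s[mut$pos] <- mut$to
  paste(s, collapse = "")
}

#' Diff two equal-length sequences into point mutations
#'
#' Returns the minimal mutation set carrying `seq_a` to `seq_b`, i.e.
#' `apply_mutations(seq_a, diff_sequences(seq_a, seq_b)) == seq_b`.
#'
#' @param seq_a,seq_b Equal-length amino-acid strings.
#' @return Semicolon-joined mutation string ("" if identical).
#' @export
diff_sequences <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  if (length(a) != length(b))
    stop("sequence length mismatch: ", length(a), " vs ", length(b))
  pos <- which(a != b)
  if (length(pos) == 0) return("")
  paste0(a[pos], pos, b[pos], collapse = ";")
}

# ---------------------------------------------------------------------------
# Records and labeling
# ---------------------------------------------------------------------------

.dataset_columns <- c("record_id", "wt_id", "wt_sequence", "mutations",
                      "ddg", "dtm", "label", "direction", "provenance")

#' Assemble a mutation dataset
#'
#' Builds the package's tabular mutation-record container: one row per
#' labeled mutation event with reference protein, mutation list, measured
#' stability change(s), optional binary label, direction flag and
#' provenance. Missing optional columns are filled with NA defaults and
#' the result is validated.
#'
#' @param df Data.frame with at least `record_id`, `wt_id`, `wt_sequence`,
#'   `mutations`; optional `ddg` (kcal/mol), `dtm` (degrees C), `label`
#'   (0/1), `direction` ("direct"/"reverse"), `provenance`
#'   ("experimental"/"TL"/"TR").
#' @param name Optional dataset name, stored as an attribute.
#' @return Validated data.frame with the canonical column set.
#' @export
mutation_dataset <- function(df, name = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("record_id", "wt_id", "wt_sequence", "mutations")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (!"ddg" %in% names(df)) df$ddg <- NA_real_
  if (!"dtm" %in% names(df)) df$dtm <- NA_real_
  if (!"label" %in% names(df)) df$label <- NA_integer_
  if (!"direction" %in% names(df)) df$direction <- "direct"
  if (!"provenance" %in% names(df)) df$provenance <- "experimental"
  df <- df[, .dataset_columns]
  df$ddg <- as.numeric(df$ddg)
  df$dtm <- as.numeric(df$dtm)
  df$label <- as.integer(df$label)
  validate_mutation_data(df)
  if (!is.null(name)) attr(df, "dataset_name") <- name
  df
}

#' Validate mutation-record invariants
#'
#' Checks: unique record ids; every mutation's wild-type residue matches
#' the reference sequence at its position; no two mutations of a record
#' share a position; each record carries at least one of ddg/dtm/label;
#' direction and provenance take known values.
#'
#' @param df A mutation dataset data.frame.
#' @return Invisibly `df`; errors name the offending record.
#' @export
validate_mutation_data <- function(df) {
  if (anyDuplicated(df$record_id))
    stop("duplicate record_id: ", df$record_id[duplicated(df$record_id)][1])
  if (!all(df$direction %in% c("direct", "reverse")))
    stop("direction must be 'direct' or 'reverse'")
  if (!all(df$provenance %in% c("experimental", "TL", "TR")))
    stop("provenance must be one of experimental/TL/TR")
  no_measure <- is.na(df$ddg) & is.na(df$dtm) & is.na(df$label)
  if (any(no_measure))
    stop("record '", df$record_id[no_measure][1],
         "' has none of ddg, dtm or label")
  for (i in seq_len(nrow(df))) {
    mut <- tryCatch(parse_mutations(df$mutations[i]), error = function(e)
      stop("record '", df$record_id[i], "': ", conditionMessage(e)))
    if (nrow(mut) > 0) {
      s <- strsplit(df$wt_sequence[i], "")[[1]]
      if (max(mut$pos) > length(s))
        stop("record '", df$record_id[i], "': mutation position beyond sequence")
      bad <- which(s[mut$pos] != mut$from)
      if (length(bad))
        stop("record '", df$record_id[i], "': wild-type residue mismatch at ",
             mut$pos[bad[1]])
    }
  }
  invisible(df)
}

#' Label a stability change from its sign
#'
#' Maps a measured stability change to the binary stabilizing (1) /
#' destabilizing (0) label. The sign convention is an explicit argument
#' and never inferred: under `"stabilizing_positive"` a positive change
#' means stabilizing; under `"stabilizing_negative"` (the folding-energy
#' reading, where a stabilized fold sits at lower energy) the mapping is
#' mirrored. An exact zero is labeled 0 with a warning.
#'
#' @param ddg Numeric vector of stability changes (kcal/mol, or degrees C
#'   when labeling from melting-temperature shifts).
#' @param convention "stabilizing_positive" or "stabilizing_negative".
#' @return Integer vector of 0/1 labels.
#' @export
classify_label <- function(ddg,
                           convention = c("stabilizing_positive",
                                          "stabilizing_negative")) {
  convention <- match.arg(convention)
  if (any(!is.finite(ddg)))
    stop("non-finite stability change at index ",
         which(!is.finite(ddg))[1])
  if (any(ddg == 0))
    warning("stability change of exactly 0 labeled destabilizing (0)")
  lab <- as.integer(ddg > 0)
  if (convention == "stabilizing_negative") lab <- as.integer(ddg < 0)
  lab[ddg == 0] <- 0L
  lab
}

# ---------------------------------------------------------------------------
# Curation
# ---------------------------------------------------------------------------

.record_key <- function(df) {
  key_mut <- vapply(df$mutations, function(m) {
    p <- parse_mutations(m)
    format_mutations(p)
  }, "", USE.NAMES = FALSE)
  paste(df$wt_sequence, key_mut, df$direction, sep = "|")
}

#' Remove duplicate mutation records
#'
#' One record is kept per (wild-type sequence, mutation set, direction)
#' key, the first occurrence winning. Duplicates whose measurements
#' disagree with the retained record are logged on the returned
#' `"conflicts"` attribute (and a message is emitted), never silently
#' merged.
#'
#' @param df Mutation dataset.
#' @return Deduplicated data.frame with a `"conflicts"` attribute.
#' @export
dedup_records <- function(df) {
  key <- .record_key(df)
  keep <- !duplicated(key)
  out <- df[keep, , drop = FALSE]
  conflicts <- character()
  if (any(!keep)) {
    first_of <- match(key[!keep], key)
    dup_idx <- which(!keep)
    for (j in seq_along(dup_idx)) {
      i <- dup_idx[j]; f <- first_of[j]
      same <- isTRUE(all.equal(df$ddg[i], df$ddg[f])) ||
        (is.na(df$ddg[i]) && is.na(df$ddg[f]))
      if (!same)
        conflicts <- c(conflicts, sprintf(
          "record '%s' duplicates '%s' with conflicting ddg (%s vs %s); first kept",
          df$record_id[i], df$record_id[f],
          format(df$ddg[i]), format(df$ddg[f])))
    }
  }
  if (length(conflicts)) message(paste(conflicts, collapse = "\n"))
  attr(out, "conflicts") <- conflicts
  rownames(out) <- NULL
  out
}

#' Select usable measurements and derive labels
#'
#' Drops records carrying neither a free-energy change nor a
#' melting-temperature shift nor a label. Where a label is absent it is
#' derived from ddg when available, otherwise from the sign of dtm, both
#' under the supplied convention.
#'
#' @param df Mutation dataset.
#' @param convention Sign convention passed to [classify_label()].
#' @return Filtered, labeled data.frame.
#' @export
select_measurement <- function(df, convention = "stabilizing_positive") {
  keep <- !(is.na(df$ddg) & is.na(df$dtm))
  keep <- keep | !is.na(df$label)
  out <- df[keep, , drop = FALSE]
  need <- is.na(out$label)
  from_ddg <- need & !is.na(out$ddg)
  if (any(from_ddg))
    out$label[from_ddg] <- classify_label(out$ddg[from_ddg], convention)
  from_dtm <- is.na(out$label) & !is.na(out$dtm)
  if (any(from_dtm))
    out$label[from_dtm] <- classify_label(out$dtm[from_dtm], convention)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Homology filtering
# ---------------------------------------------------------------------------

#' Sequence-identity homology oracle
#'
#' A simple injected backend for [homology_filter()]: flags a query as
#' homologous when its global fractional identity to any reference
#' sequence (equal lengths; shorter overlap for unequal lengths) reaches
#' `min_identity`.
#'
#' @param min_identity Fraction in (0, 1]; default 0.9.
#' @return A backend function(query_seqs, reference_seqs, evalue_threshold).
#' @export
identity_backend <- function(min_identity = 0.9) {
  force(min_identity)
  function(query_seqs, reference_seqs, evalue_threshold) {
    vapply(query_seqs, function(q) {
      qs <- strsplit(q, "")[[1]]
      any(vapply(reference_seqs, function(r) {
        rs <- strsplit(r, "")[[1]]
        n <- min(length(qs), length(rs))
        if (n == 0) return(FALSE)
        mean(qs[seq_len(n)] == rs[seq_len(n)]) >= min_identity
      }, TRUE))
    }, TRUE, USE.NAMES = FALSE)
  }
}

#' blastp homology backend
#'
#' Wraps the NCBI `blastp` binary: builds a reference database on the
#' fly, searches each query and flags those with any hit below the
#' e-value threshold. Requires `blastp` and `makeblastdb` on the PATH.
#'
#' @return A backend function for [homology_filter()].
#' @export
blastp_backend <- function() {
  function(query_seqs, reference_seqs, evalue_threshold) {
    if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "")
      stop("blastp/makeblastdb not found on PATH; inject a similarity ",
           "oracle backend instead (e.g. identity_backend())")
    dir <- tempfile("blastdb"); dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    ref_fa <- file.path(dir, "ref.fa")
    writeLines(paste0(">ref", seq_along(reference_seqs), "\n",
                      reference_seqs), ref_fa)
    qry_fa <- file.path(dir, "qry.fa")
    writeLines(paste0(">qry", seq_along(query_seqs), "\n", query_seqs),
               qry_fa)
    db <- file.path(dir, "refdb")
    system2("makeblastdb", c("-in", ref_fa, "-dbtype", "prot",
                             "-out", db), stdout = FALSE, stderr = FALSE)
    out <- file.path(dir, "hits.tsv")
    system2("blastp", c("-query", qry_fa, "-db", db,
                        "-evalue", format(evalue_threshold),
                        "-outfmt", "6", "-out", out),
            stdout = FALSE, stderr = FALSE)
    hits <- tryCatch(utils::read.table(out, sep = "\t",
                                       stringsAsFactors = FALSE),
                     error = function(e) NULL)
    flagged <- rep(FALSE, length(query_seqs))
    if (!is.null(hits) && nrow(hits) > 0) {
      qi <- as.integer(sub("^qry", "", hits[[1]]))
      ev <- as.numeric(hits[[11]])
      flagged[unique(qi[ev < evalue_threshold])] <- TRUE
    }
    flagged
  }
}

#' Exclude records homologous to a reference set
#'
#' Removes every record whose wild-type sequence the search backend flags
#' as homologous (e-value below threshold, or oracle-flagged) to any
#' sequence of the reference set. Used to keep held-out benchmark
#' proteins out of the training data.
#'
#' @param df Mutation dataset.
#' @param reference_seqs Character vector of reference sequences.
#' @param evalue_threshold Default 0.001.
#' @param backend A function(query_seqs, reference_seqs, evalue_threshold)
#'   returning a logical flag per query, e.g. [blastp_backend()] or
#'   [identity_backend()]. Required: there is no silent pass-through.
#' @return Filtered data.frame (subset of the input rows).
#' @export
homology_filter <- function(df, reference_seqs, evalue_threshold = 0.001,
                            backend = NULL) {
  if (length(reference_seqs) == 0) return(df)
  if (is.null(backend))
    stop("no search backend supplied; pass blastp_backend() or an ",
         "injected similarity oracle such as identity_backend()")
  qry <- unique(df$wt_sequence)
  flagged <- backend(qry, reference_seqs, evalue_threshold)
  stopifnot(is.logical(flagged), length(flagged) == length(qry))
  drop_seqs <- qry[flagged]
  out <- df[!(df$wt_sequence %in% drop_seqs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Table IO
# ---------------------------------------------------------------------------

#' Read / write mutation tables
#'
#' Mutation datasets are exchanged as CSV or TSV (chosen by file
#' extension) with the canonical columns: record_id, wt_id, wt_sequence,
#' mutations (semicolon-joined tokens), ddg, dtm, label, direction,
#' provenance.
#'
#' @param path File path; ".tsv"/".txt" is tab-separated, otherwise CSV.
#' @return `read_mutation_table()` returns a validated data.frame.
#' @export
read_mutation_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          na.strings = c("NA", ""))
  df$mutations[is.na(df$mutations)] <- ""
  mutation_dataset(df)
}

#' @rdname read_mutation_table
#' @param df Mutation dataset to write.
#' @export
write_mutation_table <- function(df, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
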