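# ---------------------------------------------------------------------------
# Thermodynamic-cycle data augmentation: looping (TL) and reversibility (TR)
# ---------------------------------------------------------------------------

#' Cycle-closure stability change between two variants
#'
#' For variants A and B sharing the same wild type W, energy conservation
#' around the closed thermodynamic cycle W -> A -> B -> W fixes the
#' variant-to-variant change as
#' \deqn{\Delta\Delta G(A \to B) = \Delta\Delta G(W \to B) - \Delta\Delta G(W \to A).}
#' In particular, when A sits at higher energy than the wild type
#' (\eqn{\Delta\Delta G(W \to A) > 0} under the folding-energy convention)
#' and B at lower energy (\eqn{\Delta\Delta G(W \to B) < 0}), the derived
#' value is necessarily negative.
#'
#' @param ddg_wa Stability change W -> A (kcal/mol).
#' @param ddg_wb Stability change W -> B (kcal/mol), same convention.
#' @return \eqn{\Delta\Delta G(A \to B)} in kcal/mol (vectorized).
#' @export
tl_ddg <- function(ddg_wa, ddg_wb) {
  if (any(!is.finite(ddg_wa)) || any(!is.finite(ddg_wb)))
    stop("tl_ddg requires finite stability changes")
  ddg_wb - ddg_wa
}

#' Thermodynamic-looping augmentation
#'
#' Derives variant-to-variant mutation records from pairs of variants
#' sharing the same wild-type sequence. For each ordered pair (A, B) of
#' distinct variants with numeric ddg, a record is emitted whose
#' reference is A's mutant sequence, whose mutation set is the sequence
#' diff from A's to B's mutant sequence, and whose ddg is
#' [tl_ddg()]`(ddg_A, ddg_B)`. Derived records whose diff contains
#' exactly one mutation are returned separately (`derived_single`) so
#' they can be merged into a single-point training set; the rest join
#' the originals in `augmented_multi`. Pairs whose derived |ddg| falls
#' below `zero_tol` are skipped (their stabilizing/destabilizing sign is
#' undefined), as are variants without a usable ddg.
#'
#' @param df Mutation dataset (direct records with ddg).
#' @param convention Sign convention used to label derived records.
#' @param zero_tol Skip threshold on |derived ddg|, kcal/mol.
#' @return List with elements `augmented_multi` (originals + multi-point
#'   TL records), `derived_single` (single-point TL records) and
#'   `skipped` (log of unusable variants/pairs).
#' @export
tl_augment <- function(df, convention = "stabilizing_positive",
                       zero_tol = 1e-9) {
  skipped <- character()
  usable <- is.finite(df$ddg)
  if (any(!usable))
    skipped <- c(skipped, sprintf("record '%s' skipped: no numeric ddg",
                                  df$record_id[!usable]))
  use <- df[usable, , drop = FALSE]
  new_rows <- list()
  groups <- split(seq_len(nrow(use)), use$wt_sequence)
  for (g in groups) {
    if (length(g) < 2) next
    mut_seq <- vapply(g, function(i)
      apply_mutations(use$wt_sequence[i], use$mutations[i]), "")
    for (a in seq_along(g)) for (b in seq_along(g)) {
      if (a == b) next
      ia <- g[a]; ib <- g[b]
      d <- tl_ddg(use$ddg[ia], use$ddg[ib])
      if (abs(d) < zero_tol) {
        skipped <- c(skipped, sprintf(
          "pair '%s'->'%s' skipped: derived ddg within zero tolerance",
          use$record_id[ia], use$record_id[ib]))
        next
      }
      mut <- diff_sequences(mut_seq[a], mut_seq[b])
      if (!nzchar(mut)) next  # identical mutant sequences
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        record_id = paste0("TL:", use$record_id[ia], ">", use$record_id[ib]),
        wt_id = paste0(use$wt_id[ia], ":", use$mutations[ia]),
        wt_sequence = mut_seq[a],
        mutations = mut,
        ddg = d, dtm = NA_real_,
        label = classify_label(d, convention),
        direction = "direct", provenance = "TL",
        stringsAsFactors = FALSE)
    }
  }
  derived <- if (length(new_rows)) do.call(rbind, new_rows) else
    df[0, .dataset_columns]
  if (nrow(derived)) derived <- dedup_records(derived)
  n_mut <- vapply(derived$mutations, function(m) nrow(parse_mutations(m)),
                  1L, USE.NAMES = FALSE)
  single <- derived[n_mut == 1L, , drop = FALSE]
  multi <- derived[n_mut != 1L, , drop = FALSE]
  augmented <- rbind(df, multi)
  rownames(augmented) <- NULL; rownames(single) <- NULL
  if (length(skipped)) message(length(skipped), " TL candidate(s) skipped")
  list(augmented_multi = augmented, derived_single = single,
       skipped = skipped)
}

#' Thermodynamic-reversibility augmentation
#'
#' Anti-symmetry augmentation: for every direct record X -> Y a reverse
#' record Y -> X is added with the mutant sequence as reference, each
#' mutation inverted (to/from swapped), ddg negated, label flipped,
#' direction "reverse" and provenance "TR". On a deduplicated input of n
#' records the output has exactly 2n rows, the originals preserved
#' verbatim.
#'
#' @param df Mutation dataset; every record needs a ddg or a label.
#' @return Data.frame of 2 x nrow(df) records.
#' @export
tr_augment <- function(df) {
  no_basis <- is.na(df$ddg) & is.na(df$label)
  if (any(no_basis))
    stop("record '", df$record_id[no_basis][1],
         "' has neither ddg nor label; cannot reverse")
  rev <- df
  for (i in seq_len(nrow(df))) {
    mut <- parse_mutations(df$mutations[i])
    rev$wt_sequence[i] <- apply_mutations(df$wt_sequence[i], mut)
    inv <- mut; inv$from <- mut$to; inv$to <- mut$from
    rev$mutations[i] <- format_mutations(inv)
  }
  rev$record_id <- paste0("TR:", df$record_id)
  rev$wt_id <- paste0(df$wt_id, ":rev")
  rev$ddg <- -df$ddg
  rev$dtm <- -df$dtm
  rev$label <- ifelse(is.na(df$label), NA_integer_, 1L - df$label)
  rev$direction <- ifelse(df$direction == "direct", "reverse", "direct")
  rev$provenance <- "TR"
  out <- rbind(df, rev)
  rownames(out) <- NULL
  out
}
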