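#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in fixed alphabetical
#' order. This ordering defines the index convention for one-hot
#' encodings, PSSM columns and mutation-type vocabularies throughout the
#' package.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Atchley's five-factor solution for the 20 amino acids (factor scores are
# standardized over residues: each column has mean ~0, sd ~1).
.atchley <- matrix(c(
  # FI      FII     FIII    FIV     FV
  -0.591, -1.302, -0.733,  1.570, -0.146,  # A
  -1.343,  0.465, -0.862, -1.020, -0.255,  # C
   1.050,  0.302, -3.656, -0.259, -3.242,  # D
   1.357, -1.453,  1.477,  0.113, -0.837,  # E
  -1.006, -0.590,  1.891, -0.397,  0.412,  # F
  -0.384,  1.652,  1.330,  1.045,  2.064,  # G
   0.336, -0.417, -1.673, -1.474, -0.078,  # H
  -1.239, -0.547,  2.131,  0.393,  0.816,  # I
   1.831, -0.561,  0.533, -0.277,  1.648,  # K
  -1.019, -0.987, -1.505,  1.266, -0.912,  # L
  -0.663, -1.524,  2.219, -1.005,  1.212,  # M
   0.945,  0.828,  1.299, -0.169,  0.933,  # N
   0.189,  2.081, -1.628,  0.421, -1.392,  # P
   0.931, -0.179, -3.005, -0.503, -1.853,  # Q
   1.538, -0.055,  1.502,  0.440,  2.897,  # R
  -0.228,  1.399, -4.760,  0.670, -2.647,  # S
  -0.032,  0.326,  2.213,  0.908,  1.313,  # T
  -1.337, -0.279, -0.544,  1.242, -1.262,  # V
  -0.595,  0.009,  0.672, -2.128, -0.184,  # W
   0.260,  0.830,  3.097, -0.838,  1.512   # Y
), nrow = 20, ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  paste0("F", 1:5)))

#' Atchley factor table
#'
#' The published five-factor summary of amino-acid physicochemical
#' variation (polarity/accessibility, secondary-structure propensity,
#' molecular size, codon composition, electrostatic charge). Factor
#' scores are standardized across the 20 residues.
#'
#' @return A 20 x 5 numeric matrix with residue rownames.
#' @export
atchley_table <- function() .atchley

#' Per-residue score table schema
#'
#' Column names expected in per-residue scoring tables: the 19 weighted
#' terms of the Rosetta ref2015 all-atom energy function plus the total.
#' The package consumes such tables (produced externally or by
#' [gen_residue_scores()]); it never computes the energies itself.
#'
#' @return Character vector of 20 column names.
#' @export
residue_score_schema <- function() {
  c("fa_atr", "fa_rep", "fa_sol", "fa_intra_rep", "fa_intra_sol_xover4",
    "lk_ball_wtd", "fa_elec", "pro_close", "hbond_sr_bb", "hbond_lr_bb",
    "hbond_bb_sc", "hbond_sc", "dslf_fa13", "omega", "fa_dun",
    "p_aa_pp", "yhh_planarity", "ref", "rama_prepro", "total")
}
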