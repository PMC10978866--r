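# Preferred human codon per amino acid: for each amino acid the codon with
# the highest usage fraction in the human transcriptome; '*' (nonsense) is
# written as TGA. One designated codon per substitution keeps the designed
# library one-variant-per-entry, mirroring synthesis-vendor practice.
.CODON_PREF <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
  G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
  M = "ATG", N = "AAC", P = "CCC", Q = "CAG", R = "AGA",
  S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC",
  `*` = "TGA"
)

#' Embedded human codon-preference table
#'
#' One designated codon per amino acid (plus `*` for nonsense), used when
#' enumerating the designed library. The same table ships as a plain-text
#' fixture at `inst/extdata/human_codon_preference.tsv`.
#'
#' @return A data frame with columns `aa` and `codon` (21 rows).
#' @export
codon_preference <- function() {
  data.frame(aa = names(.CODON_PREF), codon = unname(.CODON_PREF),
             stringsAsFactors = FALSE)
}

#' Designated codon for a designed substitution
#'
#' Returns the single codon used to encode `alt_aa` in the designed
#' library, from the embedded human codon-preference table. The reference
#' codon is accepted for interface stability but does not influence the
#' choice (each substitution uses one fixed codon).
#'
#' @param alt_aa Amino acid (one-letter code) or `"*"` for nonsense.
#'   Vectorized.
#' @param ref_codon Optional reference codon(s); ignored.
#' @return Codon string(s).
#' @examples
#' choose_codon("M")  # "ATG"
#' choose_codon("W")  # "TGG"
#' @export
choose_codon <- function(alt_aa, ref_codon = NULL) {
  codon <- .CODON_PREF[alt_aa]
  if (anyNA(codon)) {
    stop("unknown amino acid(s): ",
         paste(unique(alt_aa[is.na(codon)]), collapse = ", "), call. = FALSE)
  }
  unname(codon)
}
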