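#' Translate an open reading frame
#'
#' Standard-genetic-code translation of a coding nucleotide sequence. A
#' terminal stop codon, if present, is stripped from the returned protein;
#' an internal stop codon is an error (the sequence would not encode a
#' single contiguous protein).
#'
#' @param nt_seq Nucleotide string (A/C/G/T), length divisible by 3.
#' @return Single amino-acid string (one-letter code, no terminal `*`).
#' @examples
#' translate_orf("ATGGCTAAATAA")  # "MAK"
#' translate_orf("ATGTAA")        # "M"
#' @export
translate_orf <- function(nt_seq) {
  stopifnot(is.character(nt_seq), length(nt_seq) == 1L)
  nt_seq <- toupper(nt_seq)
  n <- nchar(nt_seq)
  if (n == 0L || n %% 3L != 0L) {
    stop("sequence length (", n, ") is not a positive multiple of 3",
         call. = FALSE)
  }
  if (grepl("[^ACGT]", nt_seq)) {
    stop("sequence contains characters outside A/C/G/T", call. = FALSE)
  }
  codons <- substring(nt_seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- codons_to_aa(codons)
  stops <- which(aa == "*")
  if (length(stops) > 0L && any(stops != length(aa))) {
    stop("internal stop codon at codon ",
         paste(stops[stops != length(aa)], collapse = ", "), call. = FALSE)
  }
  paste(aa[aa != "*"], collapse = "")
}

#' Reference ORF object
#'
#' Container for a coding sequence: the nucleotide string, its codon grid
#' and the translated protein. The ORF must start with ATG, end with a stop
#' codon (TAA/TAG/TGA), and contain no internal stop; the protein length is
#' `L = nchar(nt_seq)/3 - 1`.
#'
#' @param nt_seq Coding nucleotide string including the terminal stop codon.
#' @param name Sequence identifier.
#' @return An object of class `reference_orf`: a list with elements `name`,
#'   `nt_seq`, `codons` (character vector of `L + 1` codons, the last being
#'   the terminator), `protein` (amino-acid string of length `L`) and
#'   `length` (`L`).
#' @examples
#' orf <- reference_orf("ATGGCTAAATAA", "toy")
#' orf$protein  # "MAK"
#' @export
reference_orf <- function(nt_seq, name = "orf") {
  protein <- translate_orf(nt_seq)  # validates alphabet/frame/internal stops
  nt_seq <- toupper(nt_seq)
  n <- nchar(nt_seq)
  codons <- substring(nt_seq, seq(1L, n, 3L), seq(3L, n, 3L))
  if (codons[1L] != "ATG") {
    stop("first codon is ", codons[1L], ", not ATG", call. = FALSE)
  }
  if (!codons[length(codons)] %in% c("TAA", "TAG", "TGA")) {
    stop("last codon (", codons[length(codons)], ") is not a stop codon",
         call. = FALSE)
  }
  structure(
    list(name = as.character(name), nt_seq = nt_seq, codons = codons,
         protein = protein, length = nchar(protein)),
    class = "reference_orf"
  )
}

#' @export
print.reference_orf <- function(x, ...) {
  cat("reference_orf '", x$name, "': ", nchar(x$nt_seq), " nt, ",
      x$length, " aa\n", sep = "")
  invisible(x)
}

#' Read a reference ORF from a single-record FASTA file
#'
#' @param path Path to a FASTA file holding exactly one coding sequence.
#' @return A [reference_orf()] object.
#' @export
read_orf <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L) {
    stop("expected exactly 1 FASTA record, found ", length(seqs),
         call. = FALSE)
  }
  nm <- sub("\\s.*$", "", names(seqs)[1L])
  reference_orf(as.character(seqs[[1L]]), name = nm)
}

#' Write one or more sequences as FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Residues of the synthetic EGFR-like ORF pinned to their published
# identities (1-based protein positions). Covers the initiator, the
# screen's control and validation variants, the cysteine-rich positions of
# the dimerization domains, and the depleted truncations.
.EGFR_PINNED <- c(
  `1` = "M", `108` = "R", `222` = "R", `229` = "S", `237` = "A",
  `277` = "M", `289` = "A", `302` = "T", `311` = "C", `333` = "C",
  `447` = "S", `582` = "C", `595` = "C", `598` = "G", `620` = "C",
  `624` = "C", `628` = "C", `644` = "P", `675` = "R", `677` = "R",
  `709` = "E", `718` = "L", `719` = "G", `725` = "T", `747` = "L",
  `768` = "S", `769` = "V", `773` = "H", `774` = "V", `779` = "G",
  `790` = "T", `797` = "C", `858` = "L", `861` = "L"
)

#' Synthetic EGFR-like reference ORF
#'
#' Deterministically constructs a 1210-residue ORF (3,633 nt including the
#' terminator) that serves as a stand-in for the EGFR coding sequence,
#' which is not redistributable with this package. Residues at positions of
#' biological interest (e.g. T790, L858, A289, C311, G598, R675, the
#' cysteines of the dimerization domains) carry their published identities;
#' all remaining residues are filled from a fixed-seed random draw over the
#' 20 amino acids. Codons are the preferred human codons from
#' [codon_preference()], so the sequence is fully reproducible. The same
#' sequence ships as `inst/extdata/egfr_synthetic_orf.fa`.
#'
#' @return A [reference_orf()] of length 1210 aa named
#'   `"EGFR_synthetic"`.
#' @export
synthetic_egfr_orf <- function() {
  L <- 1210L
  aa <- with_seed(20240328L, sample(AA20, L, replace = TRUE))
  pinned_pos <- as.integer(names(.EGFR_PINNED))
  aa[pinned_pos] <- unname(.EGFR_PINNED)
  codons <- unname(.CODON_PREF[aa])
  nt <- paste0(paste(codons, collapse = ""), "TGA")
  reference_orf(nt, name = "EGFR_synthetic")
}
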