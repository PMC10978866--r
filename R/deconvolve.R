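#' End-trim a read by base quality
#'
#' Removes terminal bases with quality below `quality_floor` from both
#' ends (end-trimming only: interior low-quality bases are retained), and
#' adjusts the 1-based reference start accordingly. May return an empty
#' read, which downstream classification treats as contributing nothing.
#'
#' @param seq Aligned read sequence.
#' @param qual Integer base qualities, or a Phred+33 string.
#' @param pos 1-based reference start of the read.
#' @param quality_floor Minimum terminal base quality (default 10).
#' @return A list with elements `seq`, `qual` (integer vector), `pos`.
#' @export
trim_read <- function(seq, qual, pos, quality_floor = 10) {
  if (is.character(qual)) qual <- decode_qual(qual)
  stopifnot(nchar(seq) == length(qual))
  ok <- which(qual >= quality_floor)
  if (length(ok) == 0L) {
    return(list(seq = "", qual = integer(0), pos = as.integer(pos)))
  }
  i1 <- min(ok)
  i2 <- max(ok)
  list(seq = substr(seq, i1, i2), qual = qual[i1:i2],
       pos = as.integer(pos) + i1 - 1L)
}

#' Call codon-level variants on one aligned read pair
#'
#' After quality end-trimming of both mates, only codons whose three bases
#' are all covered (by either mate) with base quality at or above
#' `min_base_quality` are evaluated against the reference codon grid.
#' Classification rules:
#' \itemize{
#'   \item mates disagreeing at an overlapping base: `discarded`;
#'   \item no fully covered codon: `discarded`;
#'   \item no mismatched fully covered codon: `wildtype_supporting`;
#'   \item a mismatched codon translating to the \emph{same} amino acid
#'     (silent) is recorded but ignored for classification;
#'   \item exactly one mismatched codon translating to a different amino
#'     acid or stop: `single_variant`, carrying that `(aa_pos, alt_aa)`;
#'   \item two or more such codons: `multi_variant`.
#' }
#' Only codons `1..L` (protein positions) are evaluated; the terminator
#' codon is ignored. A trimmed mate extending beyond the ORF is an error.
#'
#' @param pair One-row `read_pairs` data frame, or a list with elements
#'   `pos1`, `seq1`, `qual1`, `pos2`, `seq2`, `qual2`.
#' @param orf A [reference_orf()].
#' @param quality_floor End-trimming quality floor (default 10).
#' @param min_base_quality Minimum base quality for codon evaluation
#'   (default 20).
#' @return A list of class `variant_call` with elements `classification`
#'   (one of `wildtype_supporting`, `single_variant`, `multi_variant`,
#'   `discarded`), `variant` (`NULL`, or list with `aa_pos`, `ref_aa`,
#'   `alt_aa`, `alt_codon`), `covered_codons` (integer vector of fully
#'   covered protein positions) and `silent_codons`.
#' @export
call_codon_variants <- function(pair, orf, quality_floor = 10,
                                min_base_quality = 20) {
  stopifnot(inherits(orf, "reference_orf"))
  nt_len <- nchar(orf$nt_seq)
  L <- orf$length

  base <- rep(NA_character_, nt_len)
  bq <- rep(-1L, nt_len)
  for (mate in list(list(pair$pos1, pair$seq1, pair$qual1),
                    list(pair$pos2, pair$seq2, pair$qual2))) {
    tr <- trim_read(mate[[2L]], mate[[3L]], mate[[1L]], quality_floor)
    len <- nchar(tr$seq)
    if (len == 0L) next
    if (tr$pos < 1L || tr$pos + len - 1L > nt_len) {
      stop("read pair extends beyond ORF bounds", call. = FALSE)
    }
    idx <- tr$pos:(tr$pos + len - 1L)
    bases <- strsplit(tr$seq, "")[[1L]]
    overlap <- !is.na(base[idx])
    if (any(overlap & base[idx] != bases)) {
      return(variant_call("discarded"))
    }
    base[idx] <- bases
    bq[idx] <- pmax(bq[idx], tr$qual)
  }

  usable <- !is.na(base) & bq >= min_base_quality
  if (!any(usable)) return(variant_call("discarded"))

  # Protein codons fully covered by usable bases.
  cod_start <- 3L * (seq_len(L) - 1L) + 1L
  fully <- usable[cod_start] & usable[cod_start + 1L] & usable[cod_start + 2L]
  covered <- which(fully)
  if (length(covered) == 0L) return(variant_call("discarded"))

  obs <- vapply(covered, function(i) {
    paste(base[(3L * (i - 1L) + 1L):(3L * i)], collapse = "")
  }, character(1L))
  ref <- orf$codons[covered]
  mism <- which(obs != ref)
  if (length(mism) == 0L) {
    return(variant_call("wildtype_supporting", covered = covered))
  }
  obs_aa <- codons_to_aa(obs[mism])
  ref_aa <- codons_to_aa(ref[mism])
  silent <- obs_aa == ref_aa
  silent_pos <- covered[mism[silent]]
  var_idx <- mism[!silent]
  if (length(var_idx) == 0L) {
    return(variant_call("wildtype_supporting", covered = covered,
                        silent = silent_pos))
  }
  if (length(var_idx) > 1L) {
    return(variant_call("multi_variant", covered = covered,
                        silent = silent_pos))
  }
  variant_call(
    "single_variant",
    variant = list(aa_pos = covered[var_idx],
                   ref_aa = ref_aa[!silent][1L],
                   alt_aa = obs_aa[!silent][1L],
                   alt_codon = obs[var_idx]),
    covered = covered, silent = silent_pos
  )
}

variant_call <- function(classification, variant = NULL,
                         covered = integer(0), silent = integer(0)) {
  structure(
    list(classification = classification, variant = variant,
         covered_codons = as.integer(covered),
         silent_codons = as.integer(silent)),
    class = "variant_call"
  )
}

#' Tally per-variant molecule counts from a stream of read pairs
#'
#' Applies [call_codon_variants()] to each pair of one sample and
#' aggregates: per designed variant, the number of `single_variant` calls
#' matching its `(aa_pos, alt_aa)`; per position, the wildtype depth (the
#' number of pairs fully covering that codon with the reference codon
#' there -- `wildtype_supporting` pairs at all their covered codons, and
#' `single_variant` pairs at their non-variant covered codons). Calls to
#' substitutions outside the designed library are tallied separately as
#' undesigned; `multi_variant` and `discarded` pairs enter only the QC
#' totals.
#'
#' @param pairs A `read_pairs` data frame (from [simulate_reads()] or
#'   [read_sam()]).
#' @param orf A [reference_orf()].
#' @param library The designed `variant_library`.
#' @param quality_floor,min_base_quality Thresholds passed to
#'   [call_codon_variants()].
#' @param sample Sample label for the returned count table.
#' @return A list of class `tally` with elements:
#'   \describe{
#'     \item{counts}{[screen_counts()] over all designed variants (zeros
#'       included).}
#'     \item{wildtype_depth}{data frame `aa_pos`, `sample`, `depth`.}
#'     \item{undesigned}{data frame `name`, `count` of called variants not
#'       in the design.}
#'     \item{qc}{data frame `classification`, `n` (the four classes plus
#'       `total`; the four classes sum to `total`).}
#'   }
#' @export
tally_counts <- function(pairs, orf, library, quality_floor = 10,
                         min_base_quality = 20, sample = "sample") {
  stopifnot(inherits(orf, "reference_orf"),
            inherits(library, "variant_library"))
  L <- orf$length
  designed <- setNames(numeric(nrow(library)), library$name)
  undesigned <- numeric(0)
  wt_depth <- integer(L)
  cls <- c(wildtype_supporting = 0L, single_variant = 0L,
           multi_variant = 0L, discarded = 0L)

  for (i in seq_len(nrow(pairs))) {
    call <- call_codon_variants(pairs[i, ], orf, quality_floor,
                                min_base_quality)
    cls[call$classification] <- cls[call$classification] + 1L
    if (call$classification %in% c("wildtype_supporting", "single_variant")) {
      wt_pos <- setdiff(call$covered_codons, call$silent_codons)
      if (call$classification == "single_variant") {
        v <- call$variant
        wt_pos <- setdiff(wt_pos, v$aa_pos)
        nm <- variant_name(v$ref_aa, v$aa_pos, v$alt_aa)
        if (nm %in% names(designed)) {
          designed[nm] <- designed[nm] + 1
        } else {
          undesigned[nm] <- if (nm %in% names(undesigned))
            undesigned[nm] + 1 else 1
        }
      }
      wt_depth[wt_pos] <- wt_depth[wt_pos] + 1L
    }
  }

  structure(
    list(
      counts = screen_counts(names(designed), sample, unname(designed)),
      wildtype_depth = data.frame(aa_pos = seq_len(L), sample = sample,
                                  depth = wt_depth,
                                  stringsAsFactors = FALSE),
      undesigned = data.frame(name = names(undesigned),
                              count = unname(undesigned),
                              stringsAsFactors = FALSE),
      qc = data.frame(classification = c(names(cls), "total"),
                      n = c(unname(cls), nrow(pairs)),
                      stringsAsFactors = FALSE)
    ),
    class = "tally"
  )
}
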