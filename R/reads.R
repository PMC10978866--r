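#' Shotgun read-pair simulation configuration
#'
#' Geometry and error model for simulated paired-end shotgun reads over
#' the ORF: normal fragment lengths, fixed read length, independent
#' per-base substitution errors, constant base quality.
#'
#' @param frag_mean,frag_sd Fragment length mean and sd (nt). Defaults
#'   350 / 60.
#' @param read_len Read length (nt), must not exceed `frag_mean`. Default
#'   150.
#' @param error_rate Per-base substitution error probability. Default
#'   1e-3.
#' @param base_quality Phred quality assigned to every simulated base.
#'   Default 37.
#' @return An object of class `read_config`.
#' @export
read_config <- function(frag_mean = 350, frag_sd = 60, read_len = 150,
                        error_rate = 1e-3, base_quality = 37L) {
  stopifnot(frag_mean > 0, frag_sd >= 0, read_len > 0,
            error_rate >= 0, error_rate <= 1,
            base_quality >= 0, base_quality <= 41)
  if (read_len > frag_mean) {
    stop("read length (", read_len, ") exceeds mean fragment length (",
         frag_mean, ")", call. = FALSE)
  }
  structure(
    list(frag_mean = frag_mean, frag_sd = frag_sd,
         read_len = as.integer(read_len), error_rate = error_rate,
         base_quality = as.integer(base_quality)),
    class = "read_config"
  )
}

# Inject independent per-base substitution errors into a character vector
# of equal-length sequences.
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  len <- nchar(seqs[1L])
  n_err <- rbinom(length(seqs), size = len, prob = rate)
  todo <- which(n_err > 0L)
  for (i in todo) {
    chars <- strsplit(seqs[i], "")[[1L]]
    pos <- sample.int(len, n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate aligned shotgun read pairs from a counted variant pool
#'
#' For each counted molecule, a fragment start is drawn uniformly over the
#' ORF (the fragment always lies inside the ORF), the molecule's variant
#' codon is substituted into the reference before read extraction, the two
#' reads are taken from the fragment ends, and independent per-base
#' substitution errors are applied. Reads are emitted as match-only
#' alignments with true 1-based reference positions. Fragment lengths are
#' drawn Normal(`frag_mean`, `frag_sd`), rounded, and clamped to
#' `[read_len, ORF length]`. Reproducible from `seed`.
#'
#' @param orf A [reference_orf()].
#' @param library A `variant_library`; molecule names in `counts` must be
#'   library variant names or `"WT"` (reference molecules).
#' @param counts A [screen_counts()] table (one sample, or use `sample` to
#'   select one).
#' @param read_cfg A [read_config()].
#' @param seed Integer seed.
#' @param sample Sample label to draw molecules from; defaults to the
#'   single sample present.
#' @return A data frame of class `read_pairs` with columns `qname`,
#'   `variant`, `frag_start`, `frag_end`, `pos1`, `seq1`, `qual1`, `pos2`,
#'   `seq2`, `qual2` (qualities as Phred+33 strings).
#' @export
simulate_reads <- function(orf, library, counts, read_cfg, seed,
                           sample = NULL) {
  stopifnot(inherits(orf, "reference_orf"),
            inherits(library, "variant_library"),
            inherits(counts, "screen_counts"),
            inherits(read_cfg, "read_config"))
  if (is.null(sample)) {
    smp <- unique(counts$sample)
    if (length(smp) != 1L) {
      stop("counts hold ", length(smp),
           " samples; pick one with `sample`", call. = FALSE)
    }
    sample <- smp
  }
  cts <- sample_counts(counts, sample)
  known <- c(library$name, "WT")
  if (length(bad <- setdiff(names(cts)[cts > 0], known)) > 0L) {
    stop("counts refer to unknown variants: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  orf_len <- nchar(orf$nt_seq)
  rl <- read_cfg$read_len
  if (rl > orf_len) {
    stop("read length exceeds ORF length", call. = FALSE)
  }

  molecules <- rep(names(cts), cts)
  n <- length(molecules)
  if (n == 0L) {
    return(empty_read_pairs())
  }

  # Mutant full-length sequence per distinct variant present.
  mut_seq <- setNames(character(0), character(0))
  for (v in unique(molecules)) {
    if (v == "WT") {
      mut_seq[v] <- orf$nt_seq
    } else {
      row <- match(v, library$name)
      mut_seq[v] <- variant_orf_seq(orf, library$aa_pos[row],
                                    library$alt_codon[row])
    }
  }

  with_seed(seed, {
    frag_len <- pmin(orf_len,
                     pmax(rl, round(rnorm(n, read_cfg$frag_mean,
                                          read_cfg$frag_sd))))
    start <- 1L + floor(runif(n) * (orf_len - frag_len + 1))
    end <- start + frag_len - 1L
    full <- mut_seq[molecules]
    seq1 <- substr(full, start, start + rl - 1L)
    seq2 <- substr(full, end - rl + 1L, end)
    seq1 <- inject_errors(seq1, read_cfg$error_rate)
    seq2 <- inject_errors(seq2, read_cfg$error_rate)
    qual <- strrep(rawToChar(as.raw(read_cfg$base_quality + 33L)), rl)
    structure(
      data.frame(
        qname = sprintf("%s_%06d", sample, seq_len(n)),
        variant = molecules,
        frag_start = as.integer(start), frag_end = as.integer(end),
        pos1 = as.integer(start), seq1 = unname(seq1), qual1 = qual,
        pos2 = as.integer(end - rl + 1L), seq2 = unname(seq2), qual2 = qual,
        stringsAsFactors = FALSE
      ),
      class = c("read_pairs", "data.frame")
    )
  })
}

empty_read_pairs <- function() {
  structure(
    data.frame(qname = character(), variant = character(),
               frag_start = integer(), frag_end = integer(),
               pos1 = integer(), seq1 = character(), qual1 = character(),
               pos2 = integer(), seq2 = character(), qual2 = character(),
               stringsAsFactors = FALSE),
    class = c("read_pairs", "data.frame")
  )
}

#' Write read pairs as a SAM file
#'
#' Emits proper-pair, match-only alignments (CIGAR `<len>M`) against the
#' ORF with 1-based positions: flag 99 for the first mate (forward) and
#' 147 for the second (reverse-strand mate), both mapped.
#'
#' @param pairs A `read_pairs` data frame.
#' @param orf The [reference_orf()] the pairs are aligned to.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pairs, orf, path) {
  stopifnot(inherits(pairs, "read_pairs"), inherits(orf, "reference_orf"))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", orf$name, "\tLN:", nchar(orf$nt_seq)))
  if (nrow(pairs) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  tlen <- pairs$frag_end - pairs$frag_start + 1L
  cig1 <- paste0(nchar(pairs$seq1), "M")
  cig2 <- paste0(nchar(pairs$seq2), "M")
  l1 <- paste(pairs$qname, 99L, orf$name, pairs$pos1, 60L, cig1, "=",
              pairs$pos2, tlen, pairs$seq1, pairs$qual1, sep = "\t")
  l2 <- paste(pairs$qname, 147L, orf$name, pairs$pos2, 60L, cig2, "=",
              pairs$pos1, -tlen, pairs$seq2, pairs$qual2, sep = "\t")
  body <- as.vector(rbind(l1, l2))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read aligned read pairs from a SAM file
#'
#' Imports a SAM file (via Rsamtools) and assembles mates into the
#' package's `read_pairs` layout. Alignments are expected to be
#' substitution-only: CIGAR operations other than `M` and terminal `S`
#' (soft clip) cause the pair to be dropped with a warning; soft-clipped
#' bases are removed before assembly. Unpaired reads are dropped with a
#' warning.
#'
#' @param path SAM file path.
#' @return A `read_pairs` data frame (column `variant` is `NA`; ground
#'   truth is unknown for external alignments).
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "seq", "qual", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(rec$qname)
  if (n == 0L) return(empty_read_pairs())
  seqs <- as.character(rec$seq)
  quals <- as.character(rec$qual)
  pos <- rec$pos
  keep <- rep(TRUE, n)

  bad_cigar <- grepl("[^0-9MS]", rec$cigar)
  if (any(bad_cigar)) {
    warning(sum(bad_cigar), " alignment(s) with indel/complex CIGAR dropped",
            call. = FALSE)
    keep[bad_cigar] <- FALSE
  }
  # Strip terminal soft clips; POS already refers to the first aligned base.
  lead <- regmatches(rec$cigar, regexpr("^[0-9]+(?=S)", rec$cigar,
                                        perl = TRUE))
  has_lead <- grepl("^[0-9]+S", rec$cigar)
  trail <- grepl("[0-9]+S$", rec$cigar)
  for (i in which((has_lead | trail) & keep)) {
    s <- seqs[i]; q <- quals[i]
    if (has_lead[i]) {
      k <- as.integer(sub("S.*$", "", rec$cigar[i]))
      s <- substr(s, k + 1L, nchar(s)); q <- substr(q, k + 1L, nchar(q))
    }
    if (trail[i]) {
      k <- as.integer(sub("^.*?([0-9]+)S$", "\\1", rec$cigar[i]))
      s <- substr(s, 1L, nchar(s) - k); q <- substr(q, 1L, nchar(q) - k)
    }
    seqs[i] <- s; quals[i] <- q
  }

  first <- bitwAnd(rec$flag, 64L) > 0L
  idx1 <- which(keep & first)
  idx2 <- which(keep & !first)
  m <- match(rec$qname[idx1], rec$qname[idx2])
  lost <- sum(is.na(m)) + sum(!seq_along(idx2) %in% m)
  if (lost > 0L) {
    warning(lost, " unpaired alignment(s) dropped", call. = FALSE)
  }
  ok <- !is.na(m)
  i1 <- idx1[ok]
  i2 <- idx2[m[ok]]
  structure(
    data.frame(
      qname = rec$qname[i1], variant = NA_character_,
      frag_start = pmin(pos[i1], pos[i2]),
      frag_end = pmax(pos[i1] + nchar(seqs[i1]) - 1L,
                      pos[i2] + nchar(seqs[i2]) - 1L),
      pos1 = pos[i1], seq1 = seqs[i1], qual1 = quals[i1],
      pos2 = pos[i2], seq2 = seqs[i2], qual2 = quals[i2],
      stringsAsFactors = FALSE
    ),
    class = c("read_pairs", "data.frame")
  )
}

# Decode a Phred+33 quality string to integer qualities.
decode_qual <- function(qual) {
  if (nchar(qual) == 0L) return(integer(0))
  utf8ToInt(qual) - 33L
}
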