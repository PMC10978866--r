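# Shared fixtures: toy ORFs, hand-built read pairs, and an independent
# brute-force codon-variant caller used as an oracle against the
# pipeline's deconvolution stage.

toy_orf <- function() reference_orf("ATGGCTAAATAA", "toy")  # M A K stop

# ORF from an amino-acid vector (first element must be "M"); codons taken
# from the package's preference table, TGA terminator appended.
mk_orf <- function(aa, name = "mk") {
  reference_orf(paste0(paste(choose_codon(aa), collapse = ""), "TGA"), name)
}

random_orf <- function(L, seed, name = "rand") {
  set.seed(seed)
  aas <- c("M", sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                         "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                       L - 1, replace = TRUE))
  mk_orf(aas, name)
}

phred_str <- function(q, len = 1L) {
  if (length(q) == 1L) q <- rep(q, len)
  rawToChar(as.raw(q + 33L))
}

# One read pair as a one-row data frame in the read_pairs layout. When the
# second mate is omitted it duplicates the first (fully overlapping,
# agreeing mates).
mk_pair <- function(pos1, seq1, qual1 = NULL, pos2 = NULL, seq2 = NULL,
                    qual2 = NULL, q = 40L) {
  if (is.null(qual1)) qual1 <- phred_str(q, nchar(seq1))
  if (is.null(pos2)) { pos2 <- pos1; seq2 <- seq1; qual2 <- qual1 }
  if (is.null(qual2)) qual2 <- phred_str(q, nchar(seq2))
  structure(
    data.frame(qname = "p1", variant = NA_character_,
               frag_start = min(pos1, pos2),
               frag_end = max(pos1 + nchar(seq1) - 1L,
                              pos2 + nchar(seq2) - 1L),
               pos1 = pos1, seq1 = seq1, qual1 = qual1,
               pos2 = pos2, seq2 = seq2, qual2 = qual2,
               stringsAsFactors = FALSE),
    class = c("read_pairs", "data.frame")
  )
}

# ---- independent brute-force oracle -----------------------------------

# End-trimming re-derived with an explicit while loop.
oracle_trim <- function(seq, qual_str, pos, floor) {
  q <- if (nchar(qual_str)) utf8ToInt(qual_str) - 33L else integer(0)
  b <- strsplit(seq, "")[[1]]
  while (length(q) > 0 && q[1] < floor) {
    q <- q[-1]; b <- b[-1]; pos <- pos + 1L
  }
  while (length(q) > 0 && q[length(q)] < floor) {
    q <- q[-length(q)]; b <- b[-length(b)]
  }
  list(base = b, qual = q, pos = pos)
}

# Re-derives one pair's call by direct string comparison, written
# independently of the package implementation (per-position association
# lists rather than reference-length vectors).
oracle_call <- function(pair, orf, floor = 10, minq = 20) {
  gc <- Biostrings::GENETIC_CODE
  m1 <- oracle_trim(pair$seq1, pair$qual1, pair$pos1, floor)
  m2 <- oracle_trim(pair$seq2, pair$qual2, pair$pos2, floor)
  seen_base <- list()
  seen_qual <- list()
  for (m in list(m1, m2)) {
    if (length(m$base) == 0) next
    for (j in seq_along(m$base)) {
      key <- as.character(m$pos + j - 1L)
      if (!is.null(seen_base[[key]]) && seen_base[[key]] != m$base[j]) {
        return(list(classification = "discarded", variant = NA))
      }
      seen_base[[key]] <- m$base[j]
      seen_qual[[key]] <- max(seen_qual[[key]], m$qual[j])
    }
  }
  L <- orf$length
  variants <- character(0)
  covered <- integer(0)
  silent <- integer(0)
  for (cpos in seq_len(L)) {
    keys <- as.character((3 * (cpos - 1) + 1):(3 * cpos))
    if (any(vapply(keys, function(k) is.null(seen_base[[k]]) ||
                     seen_qual[[k]] < minq, logical(1)))) next
    covered <- c(covered, cpos)
    obs <- paste(vapply(keys, function(k) seen_base[[k]], character(1)),
                 collapse = "")
    ref <- substr(orf$nt_seq, 3 * (cpos - 1) + 1, 3 * cpos)
    if (obs == ref) next
    if (gc[[obs]] == gc[[ref]]) {
      silent <- c(silent, cpos)
    } else {
      variants <- c(variants, paste0(gc[[ref]], cpos, gc[[obs]]))
    }
  }
  if (length(covered) == 0) {
    return(list(classification = "discarded", variant = NA))
  }
  if (length(variants) == 0) {
    return(list(classification = "wildtype_supporting", variant = NA,
                covered = covered, silent = silent))
  }
  if (length(variants) > 1) {
    return(list(classification = "multi_variant", variant = NA,
                covered = covered, silent = silent))
  }
  list(classification = "single_variant", variant = variants,
       covered = covered, silent = silent)
}

# Brute-force tally over a read_pairs data frame.
oracle_tally <- function(pairs, orf, library, floor = 10, minq = 20) {
  counts <- setNames(numeric(nrow(library)), library$name)
  undesigned <- list()
  wt <- integer(orf$length)
  cls <- c(wildtype_supporting = 0, single_variant = 0,
           multi_variant = 0, discarded = 0)
  for (i in seq_len(nrow(pairs))) {
    res <- oracle_call(pairs[i, ], orf, floor, minq)
    cls[res$classification] <- cls[res$classification] + 1
    if (res$classification %in% c("wildtype_supporting", "single_variant")) {
      wt_pos <- setdiff(res$covered, res$silent)
      if (res$classification == "single_variant") {
        vpos <- as.integer(gsub("[^0-9]", "", res$variant))
        wt_pos <- setdiff(wt_pos, vpos)
        if (res$variant %in% names(counts)) {
          counts[res$variant] <- counts[res$variant] + 1
        } else {
          undesigned[[res$variant]] <-
            max(0, undesigned[[res$variant]]) + 1
        }
      }
      wt[wt_pos] <- wt[wt_pos] + 1L
    }
  }
  list(counts = counts, wildtype_depth = wt, cls = cls,
       undesigned = undesigned)
}
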