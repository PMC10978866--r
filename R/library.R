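#' Protein-change variant names
#'
#' `variant_name()` builds names of the form `"T790M"` / `"R675*"` from the
#' reference amino acid, 1-based protein position, and alternate amino acid
#' (or `*` for nonsense). `parse_variant_name()` is its exact inverse.
#'
#' @param ref_aa,alt_aa One-letter amino-acid codes (`alt_aa` may be `"*"`).
#' @param aa_pos 1-based protein position(s).
#' @return `variant_name()`: character vector. `parse_variant_name()`: data
#'   frame with columns `ref_aa`, `aa_pos`, `alt_aa`.
#' @examples
#' variant_name("T", 790, "M")               # "T790M"
#' parse_variant_name("R675*")
#' @export
variant_name <- function(ref_aa, aa_pos, alt_aa) {
  stopifnot(all(ref_aa %in% AA20), all(alt_aa %in% c(AA20, "*")),
            all(aa_pos == as.integer(aa_pos)), all(aa_pos >= 1))
  paste0(ref_aa, as.integer(aa_pos), alt_aa)
}

#' @rdname variant_name
#' @param name Character vector of variant names such as `"T790M"`.
#' @export
parse_variant_name <- function(name) {
  m <- regexec("^([A-Y])([0-9]+)([A-Y*])$", name)
  parts <- regmatches(name, m)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("unparseable variant name(s): ",
         paste(unique(name[bad]), collapse = ", "), call. = FALSE)
  }
  parts <- do.call(rbind, parts)
  out <- data.frame(ref_aa = parts[, 2L],
                    aa_pos = as.integer(parts[, 3L]),
                    alt_aa = parts[, 4L],
                    stringsAsFactors = FALSE)
  ok <- out$ref_aa %in% AA20 & out$alt_aa %in% c(AA20, "*")
  if (!all(ok)) {
    stop("unparseable variant name(s): ",
         paste(unique(name[!ok]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Enumerate the designed saturation-mutagenesis library
#'
#' For every mutagenized protein position, designs one codon variant for
#' each of the 19 missense substitutions plus 1 nonsense substitution (the
#' reference amino acid is excluded). The initiator methionine (position 1)
#' and the terminator codon are never mutagenized, so the default position
#' set is `2..L`. Alternate codons come from the embedded codon-preference
#' table via [choose_codon()]. Ordering is deterministic: by position, then
#' alternate amino acid alphabetically with `*` last.
#'
#' @param orf A [reference_orf()].
#' @param positions Integer vector of protein positions to mutagenize;
#'   default `2:L`. Must lie within `2..L`.
#' @return A data frame of class `variant_library` with columns
#'   `variant_id`, `aa_pos`, `ref_aa`, `alt_aa`, `ref_codon`, `alt_codon`,
#'   `name`, and `20 * length(positions)` rows.
#' @examples
#' orf <- reference_orf("ATGGCTAAATAA")
#' lib <- enumerate_saturation_library(orf)  # 2 positions x 20 variants
#' nrow(lib)
#' @export
enumerate_saturation_library <- function(orf, positions = NULL) {
  stopifnot(inherits(orf, "reference_orf"))
  L <- orf$length
  if (is.null(positions)) {
    positions <- seq(2L, L)
  }
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) == 0L || any(positions < 2L) || any(positions > L)) {
    stop("positions must lie within 2..", L,
         " (the initiator and terminator are never mutagenized)",
         call. = FALSE)
  }
  ref_aa_all <- strsplit(orf$protein, "")[[1L]]

  per_pos <- lapply(positions, function(pos) {
    ref <- ref_aa_all[pos]
    alts <- c(sort(setdiff(AA20, ref)), "*")  # 19 missense + 1 nonsense
    data.frame(aa_pos = pos, ref_aa = ref, alt_aa = alts,
               stringsAsFactors = FALSE)
  })
  lib <- do.call(rbind, per_pos)
  lib$ref_codon <- orf$codons[lib$aa_pos]
  lib$alt_codon <- choose_codon(lib$alt_aa, lib$ref_codon)
  lib$name <- variant_name(lib$ref_aa, lib$aa_pos, lib$alt_aa)
  lib <- cbind(variant_id = sprintf("v%05d", seq_len(nrow(lib))), lib,
               stringsAsFactors = FALSE)
  rownames(lib) <- NULL
  structure(lib, class = c("variant_library", "data.frame"),
            orf_name = orf$name, protein_length = L)
}

#' Full-length mutant ORF sequence for one variant
#'
#' Substitutes the variant's alternate codon into the reference nucleotide
#' sequence.
#'
#' @param orf A [reference_orf()].
#' @param aa_pos 1-based protein position.
#' @param alt_codon Codon to place at that position.
#' @return Nucleotide string of the mutant ORF.
#' @export
variant_orf_seq <- function(orf, aa_pos, alt_codon) {
  stopifnot(inherits(orf, "reference_orf"), length(aa_pos) == 1L,
            aa_pos >= 1L, aa_pos <= orf$length, nchar(alt_codon) == 3L)
  nt <- orf$nt_seq
  start <- 3L * (aa_pos - 1L) + 1L
  paste0(substr(nt, 1L, start - 1L), alt_codon,
         substr(nt, start + 3L, nchar(nt)))
}

#' Read/write a designed variant library as TSV
#'
#' The TSV carries the columns `variant_id`, `aa_pos`, `ref_aa`, `alt_aa`,
#' `ref_codon`, `alt_codon`, `name`.
#'
#' @param lib A `variant_library` data frame.
#' @param path File path.
#' @return `write_library()`: `path`, invisibly. `read_library()`: a
#'   `variant_library` data frame.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "variant_library"))
  write.table(as.data.frame(lib), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lib <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(aa_pos = "integer"))
  need <- c("variant_id", "aa_pos", "ref_aa", "alt_aa", "ref_codon",
            "alt_codon", "name")
  if (!all(need %in% names(lib))) {
    stop("library TSV is missing column(s): ",
         paste(setdiff(need, names(lib)), collapse = ", "), call. = FALSE)
  }
  structure(lib[need], class = c("variant_library", "data.frame"))
}
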