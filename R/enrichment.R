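#' Per-variant log2 fold change between treated and reference samples
#'
#' `LFC_v = log2((c_trt,v + p) / N_trt) - log2((c_ref,v + p) / N_ref)`.
#' By default `N` is the sample's total count. When per-position wildtype
#' depths from deconvolution are supplied, the denominator for variant `v`
#' is instead the number of molecules interrogating `v`'s codon (all
#' variant counts at that position plus the wildtype depth there), which
#' removes fragment-coverage bias along the ORF.
#'
#' With `pseudocount = 0` a zero count yields an infinite LFC; such
#' variants are reported and should be treated as uncovered (as
#' [score_screen()] does).
#'
#' @param counts A [screen_counts()] table holding both samples.
#' @param reference,treated Sample labels.
#' @param pseudocount Nonnegative pseudocount `p` added to every count
#'   (default 0.5; 0 reproduces the pure frequency ratio).
#' @param wildtype_depth Optional data frame `aa_pos`, `sample`, `depth`
#'   (from [tally_counts()]) switching on per-position denominators;
#'   requires parseable variant names.
#' @return A data frame with columns `name`, `lfc`.
#' @examples
#' cts <- screen_counts(c("A2D", "A2E", "A2D", "A2E"),
#'                      rep(c("ref", "trt"), each = 2),
#'                      c(100, 100, 400, 100))
#' compute_lfc(cts, "ref", "trt", pseudocount = 0)  # log2(1.6), 0- shifted
#' @export
compute_lfc <- function(counts, reference, treated, pseudocount = 0.5,
                        wildtype_depth = NULL) {
  stopifnot(pseudocount >= 0)
  c_ref <- sample_counts(counts, reference)
  c_trt <- sample_counts(counts, treated)
  if (!identical(sort(names(c_ref)), sort(names(c_trt)))) {
    stop("reference and treated samples cover different variant sets",
         call. = FALSE)
  }
  c_trt <- c_trt[names(c_ref)]

  if (is.null(wildtype_depth)) {
    n_ref <- rep(sum(c_ref), length(c_ref))
    n_trt <- rep(sum(c_trt), length(c_trt))
  } else {
    pos <- parse_variant_name(names(c_ref))$aa_pos
    per_pos <- function(cts, smp) {
      tot <- tapply(cts, pos, sum)
      depth <- wildtype_depth[wildtype_depth$sample == smp, ]
      if (nrow(depth) == 0L) {
        stop("no wildtype depths for sample '", smp, "'", call. = FALSE)
      }
      wt <- setNames(depth$depth, depth$aa_pos)
      unname(tot[as.character(pos)] + wt[as.character(pos)])
    }
    n_ref <- per_pos(c_ref, reference)
    n_trt <- per_pos(c_trt, treated)
  }
  if (any(n_ref <= 0) || any(n_trt <= 0)) {
    stop("zero denominator in LFC computation", call. = FALSE)
  }
  lfc <- log2((c_trt + pseudocount) / n_trt) -
    log2((c_ref + pseudocount) / n_ref)
  data.frame(name = names(c_ref), lfc = unname(lfc),
             stringsAsFactors = FALSE)
}

#' Standardize LFCs to z-scores over covered variants
#'
#' `z_v = (LFC_v - mean) / sd`, with mean and sample standard deviation
#' (denominator `n - 1`) taken over covered variants only. Uncovered
#' variants receive `NA`. By construction the covered z-scores have mean 0
#' and sample SD 1 exactly. A robust variant (median/MAD) is available but
#' off by default.
#'
#' @param lfc Numeric LFC vector (optionally named), or the data frame
#'   from [compute_lfc()].
#' @param covered Logical mask of covered variants (default: all finite
#'   LFCs).
#' @param robust If `TRUE`, center by median and scale by MAD instead.
#' @return Numeric vector of z-scores, `NA` where uncovered.
#' @export
compute_zscores <- function(lfc, covered = NULL, robust = FALSE) {
  if (is.data.frame(lfc)) {
    lfc <- setNames(lfc$lfc, lfc$name)
  }
  if (is.null(covered)) covered <- is.finite(lfc)
  stopifnot(length(covered) == length(lfc))
  x <- lfc[covered]
  if (length(x) < 2L) {
    stop("need at least 2 covered variants with finite LFC", call. = FALSE)
  }
  center <- if (robust) stats::median(x) else mean(x)
  scale <- if (robust) stats::mad(x) else sd(x)
  if (!is.finite(scale) || scale == 0) {
    stop("LFC standard deviation is zero; z-scores undefined", call. = FALSE)
  }
  z <- rep(NA_real_, length(lfc))
  z[covered] <- (x - center) / scale
  names(z) <- names(lfc)
  z
}

#' Call significantly enriched variants
#'
#' A variant is significant if its enrichment z-score is at or above the
#' threshold (default 1.5).
#'
#' @param z Named numeric z-score vector (`NA` allowed), or an
#'   `enrichment_table`.
#' @param threshold Significance threshold (default 1.5).
#' @return Character vector of significant variant names.
#' @export
call_significant <- function(z, threshold = 1.5) {
  if (inherits(z, "enrichment_table")) z <- setNames(z$z, z$name)
  names(z)[!is.na(z) & z >= threshold]
}

#' Library coverage of a screen
#'
#' A designed variant is covered when its count in the reference sample
#' reaches `min_count`.
#'
#' @param counts A [screen_counts()] table.
#' @param library The designed `variant_library`.
#' @param min_count Minimum reference count (default 1).
#' @param sample Reference sample label (default `"reference"`).
#' @return A list with `n_covered` and `coverage_fraction`.
#' @export
coverage_stats <- function(counts, library, min_count = 1,
                           sample = "reference") {
  stopifnot(inherits(library, "variant_library"))
  if (nrow(library) == 0L) stop("library is empty", call. = FALSE)
  cts <- sample_counts(counts, sample)
  cts <- cts[names(cts) %in% library$name]
  n_cov <- sum(cts >= min_count)
  list(n_covered = n_cov, coverage_fraction = n_cov / nrow(library))
}

#' Tail summary of the z-score distribution
#'
#' Counts of variants above each enrichment threshold and fractions with
#' |z| below each absolute threshold, over variants with a z-score.
#'
#' @param z Numeric z-score vector (`NA` ignored) or an
#'   `enrichment_table`.
#' @param enrich_thresholds Upper-tail thresholds (default `c(2, 3, 4)`).
#' @param abs_thresholds Absolute-value thresholds (default `c(2, 3)`).
#' @return A list with `n_above` (named counts) and `frac_abs_below`
#'   (named fractions), plus `n` (number of scored variants).
#' @examples
#' tail_summary(c(-3.5, -1, 0, 1, 2.5))
#' @export
tail_summary <- function(z, enrich_thresholds = c(2, 3, 4),
                         abs_thresholds = c(2, 3)) {
  if (inherits(z, "enrichment_table")) z <- z$z
  z <- z[!is.na(z)]
  n_above <- vapply(enrich_thresholds, function(t) sum(z > t), numeric(1))
  frac_below <- vapply(abs_thresholds, function(t) mean(abs(z) < t),
                       numeric(1))
  list(n_above = setNames(n_above, paste0("z_gt_", enrich_thresholds)),
       frac_abs_below = setNames(frac_below,
                                 paste0("abs_z_lt_", abs_thresholds)),
       n = length(z))
}

#' Score a screen: counts to enrichment table
#'
#' Orchestrates [compute_lfc()], coverage masking, [compute_zscores()] and
#' [call_significant()] into the per-variant enrichment table. Covered
#' variants are designed variants with reference count at or above
#' `min_count` and finite LFC; z-scores are computed over covered variants
#' only (nonsense variants included in the normalization set).
#'
#' @inheritParams compute_lfc
#' @param library The designed `variant_library`.
#' @param z_threshold Significance threshold on z (default 1.5).
#' @param min_count Reference-count coverage threshold (default 1).
#' @param robust Use median/MAD standardization (default `FALSE`).
#' @return A data frame of class `enrichment_table` with columns `name`,
#'   `aa_pos`, `ref_aa`, `alt_aa`, `lfc`, `z`, `covered`, `significant`,
#'   ordered as the library.
#' @export
score_screen <- function(counts, library, reference = "reference",
                         treated = "treated", pseudocount = 0.5,
                         z_threshold = 1.5, min_count = 1,
                         wildtype_depth = NULL, robust = FALSE) {
  stopifnot(inherits(library, "variant_library"))
  lfc_df <- compute_lfc(counts, reference, treated, pseudocount,
                        wildtype_depth)
  lfc <- setNames(lfc_df$lfc, lfc_df$name)
  lfc <- lfc[library$name]
  if (anyNA(names(lfc))) {
    stop("counts are missing designed variants", call. = FALSE)
  }
  c_ref <- sample_counts(counts, reference)[library$name]
  covered <- !is.na(lfc) & is.finite(lfc) & c_ref >= min_count
  z <- compute_zscores(lfc, covered, robust = robust)
  structure(
    data.frame(
      name = library$name, aa_pos = library$aa_pos,
      ref_aa = library$ref_aa, alt_aa = library$alt_aa,
      lfc = unname(lfc), z = unname(z), covered = unname(covered),
      significant = !is.na(z) & z >= z_threshold,
      stringsAsFactors = FALSE
    ),
    class = c("enrichment_table", "data.frame"),
    z_threshold = z_threshold, pseudocount = pseudocount,
    denominator = if (is.null(wildtype_depth)) "sample_total"
      else "per_position"
  )
}

#' Read/write an enrichment table as TSV
#'
#' Columns `name  aa_pos  ref_aa  alt_aa  lfc  z  covered  significant`;
#' missing z-scores are written as empty fields.
#'
#' @param x An `enrichment_table`.
#' @param path File path.
#' @return `write_enrichment()`: `path` invisibly; `read_enrichment()`:
#'   an `enrichment_table`.
#' @export
write_enrichment <- function(x, path) {
  stopifnot(inherits(x, "enrichment_table"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_enrichment
#' @export
read_enrichment <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$covered <- as.logical(df$covered)
  df$significant <- as.logical(df$significant)
  structure(df, class = c("enrichment_table", "data.frame"))
}
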