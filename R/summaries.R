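#' Position-by-substitution z-score matrix
#'
#' Rows are protein positions `1..L`, columns the 20 amino acids plus
#' `*`; each covered variant's z-score is placed at
#' `(aa_pos, alt_aa)`. Cells for uncovered/undesigned substitutions, and
#' the reference-identity cell of every row, are `NA` (missing is
#' distinguished from zero everywhere).
#'
#' @param enrichment An `enrichment_table` from [score_screen()].
#' @param orf The [reference_orf()] (fixes `L`).
#' @return Numeric `L x 21` matrix with dimnames (positions,
#'   substitutions).
#' @export
substitution_matrix <- function(enrichment, orf) {
  stopifnot(inherits(enrichment, "enrichment_table"),
            inherits(orf, "reference_orf"))
  L <- orf$length
  if (nrow(enrichment) > 0L && any(enrichment$aa_pos > L)) {
    stop("variant position exceeds protein length ", L, call. = FALSE)
  }
  cols <- c(AA20, "*")
  mat <- matrix(NA_real_, nrow = L, ncol = length(cols),
                dimnames = list(seq_len(L), cols))
  keep <- enrichment$covered & !is.na(enrichment$z)
  mat[cbind(enrichment$aa_pos[keep],
            match(enrichment$alt_aa[keep], cols))] <- enrichment$z[keep]
  mat
}

#' Per-position average z-score
#'
#' Mean over the populated cells of each row of a substitution matrix;
#' rows with no populated cell are `NA`.
#'
#' @param mat Matrix from [substitution_matrix()].
#' @return Named numeric vector (one entry per position).
#' @export
position_average <- function(mat) {
  out <- rowMeans(mat, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Per-domain average z-score
#'
#' Mean z over covered variants whose position lies inside each region
#' (1-based closed intervals), with the number of contributing variants.
#'
#' @param enrichment An `enrichment_table`.
#' @param domains A [domain_map()].
#' @return Data frame `region`, `start`, `end`, `n`, `mean_z` (`NA` where
#'   a region contains no covered variant).
#' @export
domain_average <- function(enrichment, domains) {
  stopifnot(inherits(enrichment, "enrichment_table"),
            inherits(domains, "domain_map"))
  keep <- enrichment$covered & !is.na(enrichment$z)
  res <- lapply(seq_len(nrow(domains)), function(i) {
    inside <- keep & enrichment$aa_pos >= domains$start[i] &
      enrichment$aa_pos <= domains$end[i]
    data.frame(region = domains$region[i], start = domains$start[i],
               end = domains$end[i], n = sum(inside),
               mean_z = if (any(inside)) mean(enrichment$z[inside])
                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cysteine-substitution enrichment by region
#'
#' Within each region, partitions covered variants into substitutions to
#' cysteine (X->C) versus all other substitutions and reports the group
#' mean z-scores, their difference, and group sizes. Emulates the
#' observation that cysteine gains are preferentially enriched in
#' cysteine-rich dimerization domains. The difference is `NA` when either
#' group is empty.
#'
#' @param enrichment An `enrichment_table`.
#' @param domains A [domain_map()] restricted to the regions of interest.
#' @return Data frame `region`, `n_cys`, `n_other`, `mean_z_cys`,
#'   `mean_z_other`, `difference`.
#' @export
cysteine_enrichment <- function(enrichment, domains) {
  stopifnot(inherits(enrichment, "enrichment_table"),
            inherits(domains, "domain_map"))
  keep <- enrichment$covered & !is.na(enrichment$z)
  res <- lapply(seq_len(nrow(domains)), function(i) {
    inside <- keep & enrichment$aa_pos >= domains$start[i] &
      enrichment$aa_pos <= domains$end[i]
    cys <- inside & enrichment$alt_aa == "C"
    oth <- inside & enrichment$alt_aa != "C"
    m_c <- if (any(cys)) mean(enrichment$z[cys]) else NA_real_
    m_o <- if (any(oth)) mean(enrichment$z[oth]) else NA_real_
    data.frame(region = domains$region[i], n_cys = sum(cys),
               n_other = sum(oth), mean_z_cys = m_c, mean_z_other = m_o,
               difference = m_c - m_o, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Overlap between screen hits and a patient-mutation catalog
#'
#' Joins the significant variant set against a catalog of
#' patient-observed protein changes (e.g. an export from a clinical
#' sequencing registry), keeping catalog entries observed at least
#' `min_observations` times. Catalog names are normalized (whitespace
#' trimmed, a leading `p.` stripped) and must parse as protein changes;
#' unparseable rows are skipped with a warning. Output is independent of
#' the row order of either input.
#'
#' @param significant Character vector of significant variant names, or
#'   an `enrichment_table` (its `significant` rows are used).
#' @param catalog Data frame with columns `name`, `count` (and optionally
#'   `cohort`).
#' @param min_observations Minimum catalog observation count (default 2).
#' @return A list with data frame `overlap` (columns `name`, `count`,
#'   and `cohort` if present) and character vectors
#'   `significant_not_observed`, `observed_not_significant` (all sorted).
#' @export
catalog_overlap <- function(significant, catalog, min_observations = 2) {
  if (inherits(significant, "enrichment_table")) {
    significant <- significant$name[significant$significant]
  }
  stopifnot(is.character(significant),
            all(c("name", "count") %in% names(catalog)))
  if (nrow(catalog) > 0L && any(catalog$count < 1)) {
    stop("catalog counts must be >= 1", call. = FALSE)
  }
  nm <- sub("^p\\.", "", trimws(catalog$name))
  ok <- vapply(nm, function(x) {
    !inherits(try(parse_variant_name(x), silent = TRUE), "try-error")
  }, logical(1L))
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " unparseable catalog name(s): ",
            paste(unique(nm[!ok]), collapse = ", "), call. = FALSE)
  }
  catalog <- catalog[ok, , drop = FALSE]
  catalog$name <- nm[ok]
  # Collapse duplicate names (e.g. same change in several cohorts).
  if (nrow(catalog) > 0L) {
    obs_counts <- tapply(catalog$count, catalog$name, sum)
    observed <- names(obs_counts)[obs_counts >= min_observations]
  } else {
    obs_counts <- numeric(0)
    observed <- character(0)
  }

  hit <- sort(intersect(significant, observed))
  overlap <- data.frame(name = hit, count = unname(obs_counts[hit]),
                        stringsAsFactors = FALSE)
  if ("cohort" %in% names(catalog) && nrow(overlap) > 0L) {
    overlap$cohort <- vapply(hit, function(x) {
      paste(sort(unique(catalog$cohort[catalog$name == x])), collapse = ",")
    }, character(1L))
  }
  list(overlap = overlap,
       significant_not_observed = sort(setdiff(significant, observed)),
       observed_not_significant = sort(setdiff(observed, significant)))
}

#' Read a patient-mutation catalog from TSV
#'
#' Expects columns `name`, `count`, optionally `cohort`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "count") %in% names(df))) {
    stop("catalog TSV needs columns `name` and `count`", call. = FALSE)
  }
  df
}

#' Write a substitution matrix as TSV
#'
#' One row per position (`L` rows), a leading `aa_pos` column and 21
#' substitution columns; missing cells are empty fields, never zero.
#'
#' @param mat Matrix from [substitution_matrix()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(aa_pos = as.integer(rownames(mat)), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
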