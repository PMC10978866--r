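#' Effect-assignment configuration for a synthetic screen
#'
#' Describes how true drug-sensitivity effects are distributed across a
#' designed variant library. A minority of variants are drug-insensitive
#' (growth-advantaged under drug); their probability varies by protein
#' region, with an optional extra probability for substitutions to
#' cysteine inside listed regions (emulating disulfide-mediated activation
#' in cysteine-rich dimerization domains).
#'
#' @param background_rate Net growth rate of drug-sensitive cells under
#'   drug, in doublings/day (typically negative). Default -0.35.
#' @param insensitive_rate_range Length-2 numeric `c(low, high)`: growth
#'   rates of insensitive variants are drawn uniformly from this range
#'   (doublings/day). `low` must exceed `background_rate`. Default
#'   `c(-0.2, 0.6)`.
#' @param region_effect_probs Named numeric vector mapping region names
#'   (from the [domain_map()]; `"background"` covers unlisted positions) to
#'   the probability that a substitution there is insensitive. Regions not
#'   named get probability 0.
#' @param cysteine_boost Additional insensitivity probability for X->C
#'   substitutions inside `cysteine_regions` (capped at 1). Default 0.
#' @param cysteine_regions Character vector of region names receiving the
#'   cysteine boost.
#' @param representation_dispersion Lognormal sigma of pre-selection
#'   variant abundances. Default 0.5.
#' @param seed Mandatory integer seed; effect assignment is fully
#'   reproducible from it.
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(background_rate = -0.35,
                          insensitive_rate_range = c(-0.2, 0.6),
                          region_effect_probs = c(background = 0),
                          cysteine_boost = 0,
                          cysteine_regions = character(),
                          representation_dispersion = 0.5,
                          seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(length(insensitive_rate_range) == 2L,
            insensitive_rate_range[1L] <= insensitive_rate_range[2L],
            representation_dispersion >= 0,
            cysteine_boost >= 0, cysteine_boost <= 1)
  if (background_rate >= insensitive_rate_range[1L]) {
    stop("background_rate must be below insensitive_rate_range[1] ",
         "(the insensitive/sensitive classification cutoff)", call. = FALSE)
  }
  if (is.null(names(region_effect_probs)) ||
      any(!nzchar(names(region_effect_probs)))) {
    stop("region_effect_probs must be a fully named numeric vector",
         call. = FALSE)
  }
  if (any(region_effect_probs < 0) || any(region_effect_probs > 1)) {
    stop("region probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(background_rate = background_rate,
         insensitive_rate_range = as.numeric(insensitive_rate_range),
         region_effect_probs = region_effect_probs,
         cysteine_boost = cysteine_boost,
         cysteine_regions = cysteine_regions,
         representation_dispersion = representation_dispersion,
         seed = as.integer(seed)),
    class = "effect_config"
  )
}

#' EGFR-like default effect configuration
#'
#' Region insensitivity probabilities concentrated in the dimerization
#' domains (II and IV), the transmembrane helix and the kinase domain,
#' with a cysteine boost in domains II/IV, so that roughly 2-3% of the
#' 24,180 designed variants are drug-insensitive -- the enrichment
#' structure observed in a full-length receptor-kinase resistance screen.
#'
#' @inheritParams effect_config
#' @return An `effect_config`.
#' @export
egfr_effect_config <- function(seed) {
  effect_config(
    background_rate = -0.35,
    insensitive_rate_range = c(-0.2, 0.6),
    region_effect_probs = c(background = 0.004,
                            domain_I = 0.004, domain_II = 0.055,
                            domain_III = 0.004, domain_IV = 0.045,
                            TM = 0.15, JM = 0.004,
                            kinase = 0.03, C_terminal = 0.01),
    cysteine_boost = 0.05,
    cysteine_regions = c("domain_II", "domain_IV"),
    representation_dispersion = 0.5,
    seed = seed
  )
}

#' Screen selection design
#'
#' @param days Duration of drug selection in days (default 10).
#' @param drug_label Free-text drug description (default
#'   `"erlotinib 200 nM"`).
#' @param depth_ref,depth_treated Total molecule/read-pair tallies to
#'   sample for the reference and treated samples.
#' @param reference Which population the reference sample represents:
#'   `"pdna"` (the plasmid pool used to generate virus) or `"early_split"`
#'   (the infected pool at the treatment split). Under the package's
#'   minimal growth model the two share the same pre-selection weights and
#'   therefore coincide; the knob is kept for interface completeness.
#' @param reference_label,treated_label Sample names used in count tables.
#' @return An object of class `screen_design`.
#' @export
screen_design <- function(days = 10, drug_label = "erlotinib 200 nM",
                          depth_ref = 5e6, depth_treated = 5e6,
                          reference = c("pdna", "early_split"),
                          reference_label = "reference",
                          treated_label = "treated") {
  reference <- match.arg(reference)
  stopifnot(days > 0, depth_ref > 0, depth_treated > 0)
  structure(
    list(days = days, drug_label = drug_label,
         depth_ref = as.numeric(depth_ref),
         depth_treated = as.numeric(depth_treated),
         reference = reference,
         reference_label = reference_label, treated_label = treated_label),
    class = "screen_design"
  )
}

#' Construct a truth table directly
#'
#' Ground-truth container for simulator output: one row per variant with
#' its true growth rate under drug, effect class and relative pre-selection
#' abundance. The class is derived from the stored classification cutoff:
#' `insensitive` iff `growth_rate >= cutoff`.
#'
#' @param name Variant names.
#' @param growth_rate True growth rates (doublings/day).
#' @param initial_weight Relative pre-selection abundances (> 0).
#' @param cutoff Classification cutoff separating insensitive from
#'   sensitive rates.
#' @param aa_pos,ref_aa,alt_aa Optional per-variant annotation.
#' @return A data frame of class `truth_table` with attribute `cutoff`.
#' @export
truth_table <- function(name, growth_rate, initial_weight = 1, cutoff,
                        aa_pos = NA_integer_, ref_aa = NA_character_,
                        alt_aa = NA_character_) {
  n <- length(name)
  initial_weight <- rep_len(initial_weight, n)
  stopifnot(length(growth_rate) == n, all(initial_weight > 0),
            length(cutoff) == 1L)
  out <- data.frame(
    name = as.character(name),
    aa_pos = rep_len(as.integer(aa_pos), n),
    ref_aa = rep_len(as.character(ref_aa), n),
    alt_aa = rep_len(as.character(alt_aa), n),
    growth_rate = as.numeric(growth_rate),
    effect_class = ifelse(growth_rate >= cutoff, "insensitive", "sensitive"),
    initial_weight = as.numeric(initial_weight),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("truth_table", "data.frame"), cutoff = cutoff)
}

#' Assign ground-truth drug-sensitivity effects to a designed library
#'
#' Each variant is declared drug-insensitive by an independent Bernoulli
#' draw whose probability is the effect probability of the region
#' containing its position (plus `cysteine_boost` for X->C substitutions in
#' the configured regions, capped at 1). Insensitive variants receive a
#' growth rate drawn uniformly from `insensitive_rate_range`; sensitive
#' variants grow at `background_rate`. Pre-selection abundances are
#' lognormal(0, `representation_dispersion`). Fully reproducible from
#' `cfg$seed`.
#'
#' @param library A `variant_library` from
#'   [enumerate_saturation_library()].
#' @param cfg An [effect_config()].
#' @param domains A [domain_map()] naming the regions referenced by `cfg`.
#' @return A [truth_table()] with an extra `region` column; attribute
#'   `cutoff` is `cfg$insensitive_rate_range[1]`.
#' @export
assign_true_effects <- function(library, cfg, domains) {
  stopifnot(inherits(library, "variant_library"),
            inherits(cfg, "effect_config"), inherits(domains, "domain_map"))
  known <- c(domains$region, "background")
  unknown <- setdiff(names(cfg$region_effect_probs), known)
  if (length(unknown) > 0L) {
    stop("unknown region name(s) in region_effect_probs: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(bad <- setdiff(cfg$cysteine_regions, known)) > 0L) {
    stop("unknown region name(s) in cysteine_regions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  region <- region_of_position(library$aa_pos, domains)
  prob <- cfg$region_effect_probs[region]
  prob[is.na(prob)] <- 0
  boost <- cfg$cysteine_boost *
    (library$alt_aa == "C" & region %in% cfg$cysteine_regions)
  prob <- pmin(unname(prob) + boost, 1)

  n <- nrow(library)
  lo <- cfg$insensitive_rate_range[1L]
  hi <- cfg$insensitive_rate_range[2L]
  draws <- with_seed(cfg$seed, {
    insensitive <- runif(n) < prob
    rate <- ifelse(insensitive, runif(n, lo, hi), cfg$background_rate)
    w0 <- rlnorm(n, meanlog = 0, sdlog = cfg$representation_dispersion)
    list(rate = rate, w0 = w0)
  })
  out <- truth_table(
    name = library$name, growth_rate = draws$rate,
    initial_weight = draws$w0, cutoff = lo,
    aa_pos = library$aa_pos, ref_aa = library$ref_aa,
    alt_aa = library$alt_aa
  )
  out$region <- region
  out
}

#' Simulate sequencing counts for a selection screen
#'
#' Deterministic exponential growth followed by multinomial sequencing
#' sampling. Treated weights are
#' `w_v = initial_weight_v * 2^(growth_rate_v * days)`; reference counts
#' are Multinomial(`depth_ref`, normalized initial weights) and treated
#' counts Multinomial(`depth_treated`, normalized treated weights). The
#' reference and treated samples share the pre-selection weights (the
#' split-the-infected-cells design). An optional negative-binomial-style
#' overdispersion multiplies each variant's weight by an independent
#' Gamma(size, size) factor per sample before sampling; it is off by
#' default.
#'
#' @param truth A [truth_table()].
#' @param design A [screen_design()].
#' @param seed Integer seed; counts are reproducible from it.
#' @param overdispersion Optional positive Gamma shape (`NULL` = pure
#'   multinomial; smaller values mean more extra-multinomial noise).
#' @return A data frame of class `screen_counts` in long form with columns
#'   `name`, `sample`, `count`.
#' @export
simulate_counts <- function(truth, design, seed, overdispersion = NULL) {
  stopifnot(inherits(truth, "truth_table"), inherits(design, "screen_design"))
  if (nrow(truth) == 0L) stop("truth table is empty", call. = FALSE)
  w0 <- truth$initial_weight
  wt <- w0 * 2^(truth$growth_rate * design$days)
  if (sum(w0) <= 0 || sum(wt) <= 0) {
    stop("all weights are zero", call. = FALSE)
  }
  counts <- with_seed(seed, {
    if (!is.null(overdispersion)) {
      stopifnot(overdispersion > 0)
      w0 <- w0 * stats::rgamma(length(w0), shape = overdispersion,
                               rate = overdispersion)
      wt <- wt * stats::rgamma(length(wt), shape = overdispersion,
                               rate = overdispersion)
    }
    ref <- as.vector(rmultinom(1L, design$depth_ref, w0 / sum(w0)))
    trt <- as.vector(rmultinom(1L, design$depth_treated, wt / sum(wt)))
    list(ref = ref, trt = trt)
  })
  screen_counts(
    name = c(truth$name, truth$name),
    sample = rep(c(design$reference_label, design$treated_label),
                 each = nrow(truth)),
    count = c(counts$ref, counts$trt)
  )
}

#' Screen-count table
#'
#' Long-form per-variant, per-sample molecule tallies (the `name  sample
#' count` layout used on disk).
#'
#' @param name Variant names.
#' @param sample Sample labels.
#' @param count Nonnegative integer counts.
#' @return A data frame of class `screen_counts`.
#' @export
screen_counts <- function(name, sample, count) {
  sample <- rep_len(sample, length(name))
  stopifnot(length(name) == length(count), all(count >= 0))
  structure(
    data.frame(name = as.character(name), sample = as.character(sample),
               count = as.numeric(count), stringsAsFactors = FALSE),
    class = c("screen_counts", "data.frame")
  )
}

# Named count vector for one sample of a screen_counts table.
sample_counts <- function(counts, sample) {
  stopifnot(inherits(counts, "screen_counts"))
  rows <- counts$sample == sample
  if (!any(rows)) {
    stop("sample '", sample, "' not present in counts", call. = FALSE)
  }
  setNames(counts$count[rows], counts$name[rows])
}

#' Sequencing depth achieving a target dropout rate
#'
#' Solves for the total sampling depth `D` at which the expected fraction
#' of variants receiving zero reads equals `dropout`, for the given
#' pre-selection weights (Poisson approximation to the multinomial:
#' `mean(exp(-D * p_v)) = dropout`). Used to emulate a screen with a known
#' library coverage rate.
#'
#' @param weights Positive pre-selection weights (e.g.
#'   `truth$initial_weight`).
#' @param dropout Target expected dropout fraction in (0, 1).
#' @return Total depth (numeric).
#' @export
depth_for_dropout <- function(weights, dropout) {
  stopifnot(all(weights > 0), dropout > 0, dropout < 1)
  p <- weights / sum(weights)
  f <- function(log_d) mean(exp(-exp(log_d) * p)) - dropout
  exp(uniroot(f, lower = 0, upper = log(1e15), tol = 1e-10)$root)
}

#' Read/write screen counts and truth tables as TSV
#'
#' Counts use the long layout `name  sample  count`; truth tables use
#' `name  growth_rate  effect_class  initial_weight` (plus any annotation
#' columns present).
#'
#' @param x Object to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the object.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "screen_counts"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  screen_counts(df$name, df$sample, df$count)
}

#' @rdname write_counts
#' @export
write_truth <- function(x, path) {
  stopifnot(inherits(x, "truth_table"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param cutoff Classification cutoff to attach when reading a truth
#'   table.
#' @export
read_truth <- function(path, cutoff) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- truth_table(df$name, df$growth_rate, df$initial_weight, cutoff,
                     aa_pos = if ("aa_pos" %in% names(df)) df$aa_pos else NA,
                     ref_aa = if ("ref_aa" %in% names(df)) df$ref_aa else NA,
                     alt_aa = if ("alt_aa" %in% names(df)) df$alt_aa else NA)
  if ("region" %in% names(df)) out$region <- df$region
  out
}
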