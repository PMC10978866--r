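---
title: "Methods: saturation-mutagenesis screen simulation and scoring"
author: "satmut authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saturation-mutagenesis screen simulation and scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satmut)
```

# The assay being modeled

satmut analyzes pooled saturation-mutagenesis ("deep mutational scanning")
drug-resistance screens over a single open reading frame. The archetype is
a full-length receptor tyrosine kinase scan in a drug-addicted cancer cell
line: a library of single-codon variants (19 missense + 1 nonsense change
at every protein position except the initiator and terminator) is
expressed in a pool, the pool is split into a reference arm and a
drug-treated arm, and after about ten days of selection the surviving
variant composition is read out by shotgun sequencing of the integrated
ORF. Drug-insensitive variants keep growing under drug and enrich; the
great majority of variants deplete with the background.

For a 1210-residue protein this design yields
`1209 x 20 = 24,180` variants. The package enumerates exactly this set
([`enumerate_saturation_library()`]); positions are 1-based protein
coordinates and all region arithmetic uses 1-based closed intervals.

# Library design choices

* **One codon per substitution.** Each designed substitution is encoded by
  a single fixed codon taken from an embedded human codon-preference table
  (the most-used human codon per amino acid; nonsense = TGA). This mirrors
  synthesis-vendor practice and keeps the library one-variant-per-entry.
  The table ships as `inst/extdata/human_codon_preference.tsv`.
* **Positions 2..L.** The initiator methionine and the terminator codon
  are never mutagenized. Designed variants are named
  `ref_aa` + position + `alt_aa` (`T790M`, `R675*`), and
  `parse_variant_name()` is the exact inverse of `variant_name()`.
* **Silent variants are not designed**, but the variant caller still
  recognizes silent codon changes in reads and records them without
  counting them against any designed variant.

# The synthetic-screen generator

The generator exists so that every downstream stage can be exercised,
end to end, on data with known ground truth. It models:

1. **Effect assignment** (`assign_true_effects()`). Each variant is
   drug-insensitive with a probability set per protein region, plus an
   optional extra probability for substitutions *to cysteine* in listed
   regions — emulating the concentration of resistance variants in
   dimerization/transmembrane/kinase regions and the cysteine-gain
   enrichment seen in cysteine-rich dimerization domains. Insensitive
   variants draw a growth rate uniformly from a configured range;
   sensitive variants grow at the background rate. Pre-selection
   abundances are lognormal.
2. **Selection** (`simulate_counts()`). Growth is deterministic
   exponential: after `d` days a variant with rate `r` (doublings/day)
   changes weight by `2^(r d)`. Biological noise enters through the
   lognormal representation dispersion and the sampling step, not through
   growth-rate noise; this is the minimal model sufficient to exercise
   the scoring statistics. An optional Gamma-multiplier overdispersion
   knob (negative-binomial-style) exists but is off by default, since the
   assay provides no replicate structure from which to fit a dispersion.
3. **Sequencing** — multinomial sampling of both arms at configured
   depths. The reference arm and treated arm share the same pre-selection
   weights (the split-pool design). The `reference = "pdna" |
   "early_split"` switch is retained on `screen_design()`, but under this
   minimal model (no infection bottleneck between plasmid pool and
   split) both choices sample the same weights and coincide.
4. **Shotgun read pairs** (`simulate_reads()`). Each counted molecule
   yields one fragment placed uniformly inside the ORF with
   Normal(mean, sd) length, paired reads taken from the fragment ends,
   the molecule's variant codon substituted before read extraction, and
   independent per-base substitution errors. Reads are emitted as
   match-only alignments with true 1-based positions (SAM via
   `write_sam()`). Fragment lengths are clamped up to the read length so
   the normal tail cannot produce an impossible geometry; a read length
   exceeding the *mean* fragment length is rejected at configuration
   time.

Every stochastic operation takes an explicit integer seed and restores
the caller's RNG state; there is no hidden global randomness.

## Default parameter values

| Parameter | Default | Units | Why |
|---|---|---|---|
| `days` | 10 | days | standard selection window for this assay class |
| `background_rate` | -0.35 | doublings/day | net regression of drug-sensitive cells under an effective TKI dose (about 11-fold depletion over 10 d) |
| `insensitive_rate_range` | (-0.2, 0.6) | doublings/day | a continuum from partial to near-full resistance; drawn uniformly |
| `representation_dispersion` | 0.5 | lognormal sigma | typical spread of synthesis/cloning representation in large ORF libraries |
| `region_effect_probs` (EGFR preset) | 0.004 background; 0.055 / 0.045 domains II/IV; 0.15 TM; 0.03 kinase; 0.01 C-terminal | probability | places roughly 2-3% of the library in the insensitive class, concentrated where resistance variants cluster |
| `cysteine_boost` (EGFR preset) | 0.05 in domains II/IV | probability | cysteine-gain enrichment in cysteine-rich dimerization domains |
| fragment length | 350 +/- 60, reads 2 x 150 | nt | tagmentation-style shotgun geometry |
| `error_rate` | 1e-3 | per base | short-read substitution error scale |

The insensitive/sensitive classification cutoff stored in the truth table
is the lower end of the insensitive rate range, so class and rate are
always consistent.

## What the generator does *not* emulate

Infection multiplicity, antibiotic selection of infected cells, PCR
amplification bias, tagmentation insertion-site bias, growth-rate noise,
and replicate structure. Consequently, passing tests demonstrate that the
*analysis* is correct under the stated statistical model — multinomial
sampling around exponential selection — not that real screens are free of
extra-multinomial noise. On real data the z-score tails will be heavier
than the simulator's.

# Deconvolution: reads to counts

`call_codon_variants()` re-implements the codon-level variant-calling
role of a shotgun-screen deconvolution stage as an explicit, auditable
rule set:

* **End trimming** (`trim_read()`): terminal bases with quality below
  `quality_floor` (default 10) are clipped from both read ends; interior
  low-quality bases are retained (end-trimming only).
* **Codon evaluation**: only codons whose three bases are all covered, by
  either mate, at base quality >= `min_base_quality` (default 20) are
  compared with the reference. Codons partially covered are ignored; a
  pair covering no full codon is discarded.
* **Mate overlap**: where trimmed mates overlap, any base disagreement
  discards the whole pair. This is the simplest auditable rule; no
  quality arbitration is attempted.
* **Classification**: 0 mismatched codons = wildtype-supporting; exactly
  1 mismatched codon changing the amino acid (or creating a stop) =
  single-variant; >= 2 = multi-variant. Silent codon mismatches are
  recorded but never classified as variants (none are designed).
  Indel-containing alignments are outside scope and dropped with a
  warning at SAM import.

`tally_counts()` then counts single-variant calls per designed variant
and, per position, the wildtype depth: the number of pairs whose fully
covered codon at that position matches the reference (wildtype-supporting
pairs at all their covered codons; single-variant pairs at their other
covered codons). Because a read pair interrogates only the codons it
covers, per-position denominators (variant counts at the codon plus
wildtype depth there) remove fragment-coverage bias along the ORF;
`compute_lfc()` uses them whenever wildtype depths are supplied, and
total-count denominators otherwise.

# Enrichment scoring

For variant $v$ with counts $c_{t,v}$ (treated) and $c_{r,v}$
(reference) and denominators $N_t, N_r$:

$$\mathrm{LFC}_v = \log_2 \frac{c_{t,v} + p}{N_t} - \log_2 \frac{c_{r,v} + p}{N_r},
\qquad z_v = \frac{\mathrm{LFC}_v - \overline{\mathrm{LFC}}}{s_{\mathrm{LFC}}}$$

with mean and *sample* standard deviation taken over covered variants
only, and significance called at $z \ge 1.5$ (configurable). Choices
worth stating:

* **Pseudocount** $p = 0.5$ by default: keeps dropouts finite without
  dominating well-covered variants; $p = 0$ reproduces the pure
  frequency ratio, with zero counts yielding infinite LFC and the
  variant marked uncovered.
* **Coverage**: a designed variant is covered when its reference-sample
  count reaches `min_count` (default 1). z-scores exist only for covered
  variants; by construction their mean is exactly 0 and sample SD
  exactly 1 on every run.
* **Nonsense variants** stay in the normalization set (truncations carry
  informative depletion scores).
* **Plain mean/SD**, matching the assay's conventional z statistic; a
  robust median/MAD alternative is available via `robust = TRUE` but off
  by default.

`tail_summary()` reports counts above enrichment thresholds (2, 3, 4)
and fractions with $|z|$ below absolute thresholds (2, 3);
`coverage_stats()` reports detected-variant counts and fractions, and
`depth_for_dropout()` inverts the Poisson dropout approximation
$\mathbb{E}[e^{-D p_v}] = \text{dropout}$ to choose a depth that emulates
an observed coverage rate.

# Summaries

`substitution_matrix()` arranges z-scores as positions x (20 amino acids
+ `*`), with missing cells (uncovered, undesigned, reference identity)
kept as missing — never zero-filled, and written as empty fields in TSV.
`position_average()` and `domain_average()` average over populated cells
and closed intervals respectively; `cysteine_enrichment()` contrasts
X->C substitutions against all others per region; `catalog_overlap()`
joins the significant set against a patient-mutation catalog (names
normalized by trimming whitespace and a leading `p.`; entries must be
observed at least twice by default). Transcript-isoform reconciliation is
out of scope — matching is by exact normalized protein-change string.

# The packaged reference ORF

No real receptor CDS is redistributable with the package, so
`synthetic_egfr_orf()` builds a synthetic 1210-residue stand-in
deterministically: residues at positions of interest (T790, L858, R675,
A289, C311, C333, the domain-IV cysteines, G598, the kinase-domain
validation positions, ...) carry their published identities and the rest
are a fixed-seed random fill, encoded with the preferred-codon table. The
FASTA under `inst/extdata/` is byte-identical to the constructor's
output (a test asserts this). Analyses of real screens should supply the
true CDS via `read_orf()`.

# Numerical and degenerate-input conventions

* Ties/ordering: library rows are ordered by position, then alternate
  amino acid alphabetically with `*` last; all scoring is order
  independent (tested under permutation).
* Degenerate inputs: empty read streams tally to zeros; an all-equal LFC
  vector has no defined z (error, not NaN); regions without covered
  variants report `NA` means with `n = 0`; an empty cysteine group
  yields a missing difference.
* Reproducibility: seeds are explicit everywhere; identical seeds give
  identical tables byte-for-byte.

# Problem sizes used in the shipped checks

The packaged tests and the results-reproduction script run entirely on
synthetic data: the full 24,180-variant library at 200x depth for null
calibration and tail statistics, a dropout-tuned depth for the coverage
emulation, 1,000-variant screens for planted-signal recovery, and
read-level checks on ORFs of 50-100 codons with around 1,000 read pairs
— sizes chosen so the whole suite completes in a few minutes on one CPU
while still exercising every stage at realistic per-variant depths.

# Known limitations

* Single-variant-per-molecule assumption: multi-variant pairs are
  excluded from tallies (conservative for a single-codon library).
* No replicate-aware variance model, shrinkage, or FDR control — the
  single z threshold mirrors the assay's convention; these are natural
  extension points.
* The simulator's multinomial noise floor understates real biological
  variability; calibration claims transfer to real data only insofar as
  the multinomial model holds.
* Indels, complex variants and UMI handling are out of scope.
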