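# toy ORF "ATGGCTAAATAA": codons ATG | GCT | AAA | TAA  (M A K stop)

test_that("quality end-trimming clips terminal low-quality bases only", {
  # all qualities at/above the floor: identity
  tr <- trim_read("ACGT", c(30, 30, 30, 30), pos = 5, quality_floor = 10)
  expect_identical(tr, list(seq = "ACGT", qual = c(30, 30, 30, 30),
                            pos = 5L))
  # all below: empty read
  tr <- trim_read("ACGT", c(2, 2, 2, 2), pos = 5)
  expect_identical(tr$seq, "")
  expect_length(tr$qual, 0)
  # interior low-quality base retained (end rule only)
  tr <- trim_read("ACGT", c(40, 40, 2, 40), pos = 5)
  expect_identical(tr$seq, "ACGT")
  # leading clip adjusts the reference start
  tr <- trim_read("ACGT", c(2, 2, 40, 40), pos = 5)
  expect_identical(tr, list(seq = "GT", qual = c(40, 40), pos = 7L))
  # Phred+33 string qualities accepted
  tr <- trim_read("ACGT", phred_str(c(2, 40, 40, 2)), pos = 1)
  expect_identical(tr$seq, "CG")
})

test_that("codon calls follow the coverage and mismatch rules", {
  orf <- toy_orf()
  # codon 2 read as GAT (A->D): single variant
  call <- call_codon_variants(mk_pair(4, "GATAAA"), orf)
  expect_identical(call$classification, "single_variant")
  expect_identical(call$variant$aa_pos, 2L)
  expect_identical(call$variant$alt_aa, "D")
  expect_identical(variant_name(call$variant$ref_aa, call$variant$aa_pos,
                                call$variant$alt_aa), "A2D")
  expect_identical(call$covered_codons, 2:3)

  # same span matching the reference: wildtype-supporting
  call <- call_codon_variants(mk_pair(4, "GCTAAA"), orf)
  expect_identical(call$classification, "wildtype_supporting")
  expect_identical(call$covered_codons, 2:3)

  # only bases 4-5 (partial codon 2): no fully covered codon
  call <- call_codon_variants(mk_pair(4, "GC"), orf)
  expect_identical(call$classification, "discarded")

  # two mismatched codons: multi-variant
  call <- call_codon_variants(mk_pair(4, "GATCAA"), orf)
  expect_identical(call$classification, "multi_variant")
})

test_that("silent codon changes are recorded but never called as variants", {
  orf <- toy_orf()
  # codon 3 AAA -> AAG is still K: silent, pair supports wild type
  call <- call_codon_variants(mk_pair(4, "GCTAAG"), orf)
  expect_identical(call$classification, "wildtype_supporting")
  expect_identical(call$silent_codons, 3L)
  # silent at 3 plus real variant at 2: still a single variant call
  call <- call_codon_variants(mk_pair(4, "GATAAG"), orf)
  expect_identical(call$classification, "single_variant")
  expect_identical(call$variant$aa_pos, 2L)
  expect_identical(call$silent_codons, 3L)
})

test_that("disagreeing mate overlap discards the pair", {
  orf <- toy_orf()
  pair <- mk_pair(4, "GCTAAA", pos2 = 4, seq2 = "GCTAAG")
  expect_identical(call_codon_variants(pair, orf)$classification,
                   "discarded")
  # agreeing overlap is fine and merges coverage
  pair <- mk_pair(4, "GCT", pos2 = 7, seq2 = "AAA")
  call <- call_codon_variants(pair, orf)
  expect_identical(call$classification, "wildtype_supporting")
  expect_identical(call$covered_codons, 2:3)
})

test_that("base-quality masking removes codons from evaluation", {
  orf <- toy_orf()
  # middle base of codon 2 at Q15 (>= floor 10, < min 20): codon 2 not
  # evaluated, codon 3 still wild-type supporting
  pair <- mk_pair(4, "GATAAA", qual1 = phred_str(c(40, 15, 40, 40, 40, 40)))
  call <- call_codon_variants(pair, orf)
  expect_identical(call$classification, "wildtype_supporting")
  expect_identical(call$covered_codons, 3L)
  # lowering the evaluation threshold restores the variant call
  call <- call_codon_variants(pair, orf, min_base_quality = 10)
  expect_identical(call$classification, "single_variant")
})

test_that("terminator codon and ORF bounds are handled", {
  orf <- toy_orf()
  # read over the stop codon only: terminator is not a protein position
  call <- call_codon_variants(mk_pair(10, "TAA"), orf)
  expect_identical(call$classification, "discarded")
  expect_error(call_codon_variants(mk_pair(11, "AAA"), orf),
               "beyond ORF")
})

test_that("calls are equivariant under codon shifts", {
  aa <- c("M", rep(c("A", "K", "P", "G", "T", "L", "S", "V", "D"), 3))
  orf <- mk_orf(aa)
  for (k in 0:5) {
    # inject GAT at codon (2 + k); GAT encodes D
    start <- 3 * (2 + k - 1) + 1
    call <- call_codon_variants(mk_pair(start, "GAT"), orf)
    if (aa[2 + k] == "D") {
      expect_identical(call$classification, "wildtype_supporting")
    } else {
      expect_identical(call$classification, "single_variant")
      expect_identical(call$variant$aa_pos, 2L + k)
      expect_identical(call$variant$alt_aa, "D")
    }
  }
})

test_that("tallies recover a known error-free composition exactly", {
  orf <- toy_orf()
  lib <- enumerate_saturation_library(orf)
  pairs <- do.call(rbind, c(
    replicate(30, mk_pair(4, "GATAAA"), simplify = FALSE),  # A2D
    replicate(70, mk_pair(4, "GCTAAA"), simplify = FALSE)   # WT
  ))
  tal <- tally_counts(pairs, orf, lib, sample = "s")
  cts <- setNames(tal$counts$count, tal$counts$name)
  expect_identical(unname(cts["A2D"]), 30)
  expect_identical(sum(cts), 30)
  expect_identical(tal$wildtype_depth$depth[2], 70L)
  # the variant pairs support wild type at codon 3
  expect_identical(tal$wildtype_depth$depth[3], 100L)
  expect_identical(tal$qc$n[tal$qc$classification == "single_variant"], 30L)
  expect_identical(tal$qc$n[tal$qc$classification == "total"], 100L)
})

test_that("an empty stream tallies to all zeros", {
  orf <- toy_orf()
  lib <- enumerate_saturation_library(orf)
  tal <- tally_counts(pairs = mk_pair(4, "GCT")[0, ], orf, lib)
  expect_true(all(tal$counts$count == 0))
  expect_true(all(tal$wildtype_depth$depth == 0))
  expect_identical(tal$qc$n[tal$qc$classification == "total"], 0L)
})

test_that("classification counts are conserved on random simulated reads", {
  orf <- random_orf(60, 13)
  lib <- enumerate_saturation_library(orf)
  cfg <- read_config(frag_mean = 100, frag_sd = 20, read_len = 60,
                     error_rate = 0.01, base_quality = 30)
  cts <- screen_counts(c("WT", sample(lib$name, 20)), "s",
                       c(60, rep(7, 20)))
  pr <- simulate_reads(orf, lib, cts, cfg, seed = 17)
  tal <- tally_counts(pr, orf, lib, sample = "s")
  qc <- setNames(tal$qc$n, tal$qc$classification)
  expect_identical(sum(qc[c("wildtype_supporting", "single_variant",
                            "multi_variant", "discarded")]),
                   qc[["total"]])
  expect_identical(qc[["total"]], nrow(pr))
})

test_that("error-free tallies equal the emitted fragment coverage", {
  orf <- random_orf(50, 19)
  lib <- enumerate_saturation_library(orf)
  cfg <- read_config(frag_mean = 90, frag_sd = 15, read_len = 45,
                     error_rate = 0)
  picked <- lib$name[c(10, 200, 500)]
  cts <- screen_counts(c("WT", picked), "s", c(40, 25, 25, 25))
  pr <- simulate_reads(orf, lib, cts, cfg, seed = 23)
  tal <- tally_counts(pr, orf, lib, sample = "s")
  got <- setNames(tal$counts$count, tal$counts$name)
  pos <- parse_variant_name(picked)$aa_pos
  for (i in seq_along(picked)) {
    nt_lo <- 3 * (pos[i] - 1) + 1
    nt_hi <- 3 * pos[i]
    emitted <- sum(pr$variant == picked[i] &
                     pr$frag_start <= nt_lo & pr$frag_end >= nt_hi &
                     # codon must be fully inside one of the two reads
                     ((pr$pos1 <= nt_lo & pr$pos1 + 44 >= nt_hi) |
                        (pr$pos2 <= nt_lo & pr$pos2 + 44 >= nt_hi)))
    expect_identical(unname(got[picked[i]]), as.numeric(emitted))
  }
})

test_that("tallies match an independent brute-force caller on 1000 pairs", {
  orf <- random_orf(80, 29)
  lib <- enumerate_saturation_library(orf)
  cfg <- read_config(frag_mean = 120, frag_sd = 30, read_len = 70,
                     error_rate = 0.005, base_quality = 30)
  cts <- screen_counts(c("WT", sample(lib$name, 50)), "s",
                       c(500, rep(10, 50)))
  pr <- simulate_reads(orf, lib, cts, cfg, seed = 31)
  expect_identical(nrow(pr), 1000L)
  tal <- tally_counts(pr, orf, lib, sample = "s")
  ora <- oracle_tally(pr, orf, lib)
  expect_identical(setNames(tal$counts$count, tal$counts$name), ora$counts)
  expect_identical(tal$wildtype_depth$depth, ora$wildtype_depth)
  expect_identical(setNames(as.numeric(tal$qc$n[1:4]),
                            tal$qc$classification[1:4]), ora$cls)
})

test_that("tallies are identical whether pairs come direct or via SAM", {
  orf <- random_orf(40, 37)
  lib <- enumerate_saturation_library(orf)
  cfg <- read_config(frag_mean = 80, frag_sd = 10, read_len = 40,
                     error_rate = 0.01)
  cts <- screen_counts(c("WT", lib$name[100]), "s", c(30, 15))
  pr <- simulate_reads(orf, lib, cts, cfg, seed = 41)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(pr, orf, sam)
  tal1 <- tally_counts(pr, orf, lib, sample = "s")
  tal2 <- tally_counts(read_sam(sam), orf, lib, sample = "s")
  expect_identical(tal1$counts, tal2$counts)
  expect_identical(tal1$wildtype_depth, tal2$wildtype_depth)
  expect_identical(tal1$qc, tal2$qc)
})
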