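# minimal eccs-format row for align_eccs
as_eccs <- function(seqs, amplicon = "ampA", start = 0L) {
  tibble::tibble(family = seq_along(seqs), amplicon = amplicon,
                 umi_key = paste0("u", seq_along(seqs)),
                 size = 3L, eccs = seqs, start = start,
                 length = nchar(seqs),
                 n_N = nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE)),
                 frac_N = 0, n_reads_used = 6L, n_outliers = 0L)
}

test_that("an ECCS identical to the amplicon reports reference everywhere", {
  amp <- fixture_amp()
  obs <- align_eccs(as_eccs(amp$sequence), amp)
  expect_equal(obs$status, "aligned")
  expect_equal(obs$ref_start, 1L)
  expect_equal(obs$ref_end, 60L)
  expect_equal(obs$aligned, amp$sequence)
  expect_equal(obs$identity, 1)
})

test_that("substitutions and deletions land on the right reference position", {
  amp <- fixture_amp()
  mut <- amp$sequence
  ref40 <- substr(mut, 40, 40)
  substr(mut, 40, 40) <- setdiff(c("A", "C", "G", "T"), ref40)[1]
  obs <- align_eccs(as_eccs(mut), amp)
  expect_equal(substr(obs$aligned, 40, 40), substr(mut, 40, 40))
  expect_equal(substr(obs$aligned, 1, 39), substr(amp$sequence, 1, 39))

  # 1-base deletion: gap at the deleted position, flanks intact; checked
  # against an independent global aligner on a short amplicon
  toy <- toy_amplicons(c(toyA = "ACGTACGGTCAGATCCGATTGACGCATGAC"))
  del <- paste0(substr(toy$sequence, 1, 11), substr(toy$sequence, 13, 30))
  obs2 <- align_eccs(as_eccs(del, "toyA"), toy)
  expect_equal(substr(obs2$aligned, 12, 12), "-")
  expect_equal(gsub("-", "", obs2$aligned), del)
  oracle <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(del), Biostrings::DNAString(toy$sequence),
    type = "global", gapOpening = 0, gapExtension = 1)
  expect_equal(Biostrings::nindel(oracle)@deletion[1, ], c(1L, 1L),
               ignore_attr = TRUE)
  expect_equal(as.character(Biostrings::alignedPattern(oracle)),
               obs2$aligned, ignore_attr = TRUE)
})

test_that("gaps left-normalise to one canonical position in homopolymers", {
  toy <- toy_amplicons(c(hp = "ATTCGGGGGACTTACGATCA"))
  # deleting any G of the homopolymer gives the same sequence; the alignment
  # must always report the gap at the leftmost G (position 5)
  del <- paste0(substr(toy$sequence, 1, 7), substr(toy$sequence, 9, 20))
  obs <- align_eccs(as_eccs(del, "hp"), toy)
  expect_equal(substr(obs$aligned, 5, 5), "-")
  expect_equal(gsub("-", "", obs$aligned), del)
  # insertion of a G anchors after position 4 (left of the run)
  ins <- paste0(substr(toy$sequence, 1, 7), "G", substr(toy$sequence, 8, 20))
  obs2 <- align_eccs(as_eccs(ins, "hp"), toy)
  expect_equal(obs2$insertions[[1]]$pos, 4L)
  expect_equal(obs2$insertions[[1]]$seq, "G")
})

test_that("degenerate consensi are discarded as unalignable", {
  amp <- fixture_amp()
  withr::with_seed(9, junk <- random_dna(1, 60, gc = 0.5))
  obs <- align_eccs(as_eccs(c(amp$sequence, junk)), amp)
  expect_equal(obs$status, c("aligned", "unalignable"))
})

test_that("allele counting reproduces published VAFs from family counts", {
  # worked rows: counts in, VAF out
  expect_equal(round(compute_vaf(61238, 156986), 4), 0.2806)
  expect_equal(round(compute_vaf(220551, 110047), 4), 0.6671)
  expect_equal(compute_vaf(0, 4187), 0)
  expect_true(is.na(compute_vaf(0, 0)))
  # every published row reproduces under the reporting rounding rule
  tb <- read_patient_calls()
  expect_equal(format_vaf(compute_vaf(tb$variant_rfs, tb$reference_rfs)),
               tb$vaf_printed)
})

test_that("families split into variant, reference and other at an SNV", {
  amp <- fixture_amp()
  off <- 25L
  ref <- substr(amp$sequence, off, off)
  others <- setdiff(c("A", "C", "G", "T"), ref)
  alt <- others[1]
  target <- toy_target(amp, off, ref, alt)
  mk <- function(base) {
    s <- amp$sequence
    substr(s, off, off) <- base
    s
  }
  third <- mk(others[2])
  ncase <- mk(ref)
  substr(ncase, off, off) <- "N"
  obs <- align_eccs(as_eccs(c(amp$sequence, mk(alt), mk(alt), third, ncase)),
                    amp)
  cnt <- count_alleles(obs, target)
  expect_equal(cnt$variant_rfs, 2L)
  expect_equal(cnt$reference_rfs, 1L)
  expect_equal(cnt$other_rfs, 2L)  # third allele + N at the locus
  expect_equal(cnt$spanning, 5L)
  expect_equal(cnt$vaf, 2 / 3)
  # conservation: every spanning family is counted exactly once
  expect_equal(cnt$variant_rfs + cnt$reference_rfs + cnt$other_rfs,
               cnt$spanning)
})

test_that("indel targets require the exact anchored replacement", {
  toy <- toy_amplicons(c(toyA = "ACGTACGGTCAGATCCGATTGACGCATGACCGTTAGCATT"))
  # del of CT at 14-15, anchored at 13 ("ATC" -> "A")
  tg <- toy_target(toy, 13L, substr(toy$sequence, 13, 15),
                   substr(toy$sequence, 13, 13), label = "delCT")
  exact <- paste0(substr(toy$sequence, 1, 13), substr(toy$sequence, 16, 40))
  partial <- paste0(substr(toy$sequence, 1, 13), substr(toy$sequence, 15, 40))
  obs <- align_eccs(as_eccs(c(toy$sequence, exact, partial), "toyA"), toy)
  cnt <- count_alleles(obs, tg)
  expect_equal(cnt$variant_rfs, 1L)
  expect_equal(cnt$reference_rfs, 1L)
  expect_equal(cnt$other_rfs, 1L)  # 1-base deletion is not the 2-base one
  # insertion target: ins GG after position 20
  tg_ins <- toy_target(toy, 20L, substr(toy$sequence, 20, 20),
                       paste0(substr(toy$sequence, 20, 20), "GG"),
                       label = "insGG")
  with_ins <- paste0(substr(toy$sequence, 1, 20), "GG",
                     substr(toy$sequence, 21, 40))
  obs2 <- align_eccs(as_eccs(c(toy$sequence, with_ins), "toyA"), toy)
  cnt2 <- count_alleles(obs2, tg_ins)
  expect_equal(cnt2$variant_rfs, 1L)
  expect_equal(cnt2$reference_rfs, 1L)
})

test_that("an indel molecule is recovered through the full family path", {
  amp <- fixture_amp()
  off <- 30L
  tg <- toy_target(amp, off - 1L, substr(amp$sequence, off - 1L, off),
                   substr(amp$sequence, off - 1L, off - 1L), label = "del1")
  tg2 <- umiecs::normalize_variant(amp$sequence, tg$offset, tg$ref, tg$alt)
  tg$offset <- tg2$offset; tg$ref <- tg2$ref; tg$alt <- tg2$alt
  tg$position <- amp$start + tg$offset - 1L
  del_tmpl <- paste0(substr(amp$sequence, 1, off - 1L),
                     substr(amp$sequence, off + 1L, 60))
  pairs <- dplyr::bind_rows(
    toy_family(del_tmpl, 3, u1 = strrep("G", 16), tmpl_len = 40,
               name_prefix = "var"),
    toy_family(amp$sequence, 3, u1 = strrep("T", 16), tmpl_len = 40,
               name_prefix = "ref"))
  eccs <- call_consensus(toy_grouped(pairs, amp), amp)
  obs <- align_eccs(eccs, amp)
  cnt <- count_alleles(obs, tg)
  expect_equal(cnt$variant_rfs, 1L)
  expect_equal(cnt$reference_rfs, 1L)
  expect_equal(cnt$vaf, 0.5)
})

test_that("detection uses class-specific thresholds and indel counts", {
  amp <- fixture_amp()
  profile <- structure(list(
    thresholds = tibble::tibble(
      group = c("G>T(C>A)", "C>T(G>A)", "other", "global"),
      n_records = c(100L, 100L, 100L, 300L),
      threshold = c(0.0034, 0.0002, 0.000079, 0.0016)),
    classes = tibble::tibble(), specificity = 0.99,
    records = tibble::tibble(vaf = numeric())),
    class = "ecs_error_profile")
  counts <- dplyr::bind_rows(
    dplyr::mutate(toy_target(amp, 25L, "T", "G", label = "TtoG"),
                  ref = "T", alt = "G", type = "snv",
                  variant_rfs = 42L, reference_rfs = 9958L, other_rfs = 0L,
                  spanning = 10000L, vaf = 0.0042),
    dplyr::mutate(toy_target(amp, 30L, "G", "T", label = "GtoT"),
                  ref = "G", alt = "T", type = "snv",
                  variant_rfs = 2L, reference_rfs = 9998L, other_rfs = 0L,
                  spanning = 10000L, vaf = 0.0002),
    dplyr::mutate(toy_target(amp, 40L, "AG", "A", label = "del"),
                  ref = "AG", alt = "A", type = "del",
                  variant_rfs = 3L, reference_rfs = 997L, other_rfs = 0L,
                  spanning = 1000L, vaf = 0.003),
    dplyr::mutate(toy_target(amp, 45L, "C", "A", label = "zero"),
                  ref = "C", alt = "A", type = "snv",
                  variant_rfs = 0L, reference_rfs = 1000L, other_rfs = 0L,
                  spanning = 1000L, vaf = 0))
  calls <- call_variants(counts, profile)
  # 0.0042 T>G clears the other-eight threshold 0.000079
  expect_true(calls$detected[calls$label == "TtoG"])
  expect_equal(calls$threshold[calls$label == "TtoG"], 0.000079)
  # 0.0002 G>T stays under the oxidative-class threshold 0.0034
  expect_false(calls$detected[calls$label == "GtoT"])
  # indel detection is count-based
  expect_true(calls$detected[calls$label == "del"])
  expect_false(call_variants(counts, profile,
                             min_indel_rfs = 4)$detected[3])
  # VAF 0 is never detected for a positive threshold
  expect_false(calls$detected[calls$label == "zero"])
})

test_that("a missing class threshold falls back to global with a warning", {
  amp <- fixture_amp()
  profile <- structure(list(
    thresholds = tibble::tibble(group = c("G>T(C>A)", "global"),
                                n_records = c(10L, 10L),
                                threshold = c(0.003, 0.001)),
    classes = tibble::tibble(), specificity = 0.99,
    records = tibble::tibble(vaf = numeric())),
    class = "ecs_error_profile")
  counts <- dplyr::mutate(toy_target(amp, 25L, "T", "G", label = "x"),
                          ref = "T", alt = "G", type = "snv",
                          variant_rfs = 50L, reference_rfs = 9950L,
                          other_rfs = 0L, spanning = 10000L, vaf = 0.005)
  expect_warning(calls <- call_variants(counts, profile), "global")
  expect_equal(calls$threshold, 0.001)
  expect_true(calls$detected)
})
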