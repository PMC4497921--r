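test_that("wild-type site records count alt families over covering families", {
  amp <- fixture_amp()
  off <- 25L
  ref <- substr(amp$sequence, off, off)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  mut <- amp$sequence
  substr(mut, off, off) <- alt
  seqs <- c(rep(amp$sequence, 998), rep(mut, 2))
  obs <- tibble::tibble(family = seq_along(seqs), amplicon = "ampA",
                        umi_key = "u", size = 3L, status = "aligned",
                        ref_start = 1L, ref_end = 60L, aligned = seqs,
                        insertions = vector("list", length(seqs)),
                        identity = 1)
  # no targets: every position is wild-type
  no_targets <- toy_target(amp, 40L, substr(amp$sequence, 40, 40), "A")[0, ]
  recs <- wildtype_site_vafs(obs, amp, no_targets)
  r <- recs[recs$pos == off & recs$alt_base == alt, ]
  expect_equal(r$n_alt, 2)
  expect_equal(r$n_cover, 1000)
  expect_equal(r$vaf, 0.002)
  expect_equal(r$ref_base, ref)
  # all other sites are clean
  expect_equal(sum(recs$n_alt), 2)
  # 3 alt records per covered position
  expect_equal(nrow(recs), 3L * 60L)

  # positions covered by a target's reference allele are excluded
  tg <- toy_target(amp, off, ref, alt)
  recs2 <- wildtype_site_vafs(obs, amp, tg)
  expect_false(any(recs2$pos == off))
  expect_equal(nrow(recs2), 3L * 59L)
})

test_that("specificity thresholds follow the strict-quantile definition", {
  # all-zero records: any positive VAF clears background
  expect_equal(specificity_threshold(rep(0, 200), 0.99), 0)
  # 99 zeros and one 0.5: the smallest t with 99% of records below it
  expect_equal(specificity_threshold(c(rep(0, 99), 0.5), 0.99), 0.5)
  # too few records to resolve the tail -> warning
  expect_warning(specificity_threshold(c(rep(0, 9), 0.5), 0.99), "records")
})

test_that("thresholds match a sort-based oracle and are monotone", {
  brute_threshold <- function(v, s) {
    for (t in sort(unique(v))) {
      if (sum(v < t) >= s * length(v)) return(t)
    }
    max(v)
  }
  withr::with_seed(77, {
    v <- c(rbinom(10000, 50, 2e-3) / 50)  # lumpy small-count VAFs
  })
  for (s in c(0.95, 0.99, 0.999)) {
    expect_equal(specificity_threshold(v, s), brute_threshold(v, s))
  }
  expect_true(specificity_threshold(v, 0.999) >=
                specificity_threshold(v, 0.99))
  expect_true(specificity_threshold(v, 0.99) >=
                specificity_threshold(v, 0.95))
})

test_that("strand collapse is a reverse-complement involution", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  expect_equal(length(unique(collapse_class(combos$ref, combos$alt))), 6L)
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(collapse_class(unname(rc[combos$ref]), unname(rc[combos$alt])),
               collapse_class(combos$ref, combos$alt))
  # groups: the oxidative and deamination pairs, 8 remaining
  expect_equal(substitution_group("G", "T"), "G>T(C>A)")
  expect_equal(substitution_group("C", "A"), "G>T(C>A)")
  expect_equal(substitution_group("C", "T"), "C>T(G>A)")
  expect_equal(substitution_group("G", "A"), "C>T(G>A)")
  expect_equal(sum(substitution_group(combos$ref, combos$alt) == "other"), 8L)
})

test_that("class profile partitions records and conserves counts", {
  withr::with_seed(5, {
    bases <- c("A", "C", "G", "T")
    n <- 600
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    recs <- tibble::tibble(
      amplicon = "a", pos = seq_len(n), ref_base = ref, alt_base = unname(alt),
      n_alt = rbinom(n, 10, 0.05), n_cover = 1000)
  })
  recs$vaf <- recs$n_alt / recs$n_cover
  recs$class <- paste0(recs$ref_base, ">", recs$alt_base)
  recs$class6 <- collapse_class(recs$ref_base, recs$alt_base)
  recs$group <- substitution_group(recs$ref_base, recs$alt_base)
  prof <- class_profile(recs, 0.95)
  # 12 raw classes collapse onto 6 with conserved record counts
  expect_equal(sum(prof$classes$n_records), nrow(recs))
  expect_equal(nrow(prof$classes), 6L)
  expect_equal(sum(prof$classes$alt_families), sum(recs$n_alt))
  expect_equal(prof$thresholds$n_records[4], nrow(recs))
  # an empty group warns and yields NA
  sub <- recs[recs$group != "C>T(G>A)", ]
  expect_warning(p2 <- class_profile(sub, 0.95), "C>T")
  expect_true(is.na(p2$thresholds$threshold[p2$thresholds$group == "C>T(G>A)"]))
})

test_that("oxidative damage shifts the G>T(C>A) threshold by its rate ratio", {
  # damage knobs scaled up so the per-class thresholds are resolved on a
  # small library; the G>T excess over the PCR-error background must track
  # the simulated rate ratio within 3x
  oxo <- 1.2e-3
  pcr <- 3 * 4e-4 / 2  # per-class background 2e-4 per alt base
  withr::with_seed(31, {
    cfg <- sim_config(n_molecules = 2.5e4, true_vaf = 0,
                      oxo_g_rate = oxo, ct_error_rate = 0, pcr_error = pcr,
                      per_read_error = 0.003)
    lib <- simulate_library(cfg, seed = 13)
  })
  run <- run_pipeline(lib$reads, cfg$amplicons, cfg$targets,
                      compute_profile = TRUE)
  th <- run$profile$thresholds
  t_oxo <- th$threshold[th$group == "G>T(C>A)"]
  t_other <- th$threshold[th$group == "other"]
  rate_ratio <- oxo / (pcr / 3)
  expect_gt(t_oxo / t_other, rate_ratio / 3)
  expect_lt(t_oxo / t_other, rate_ratio * 3)
})

test_that("identical inputs give identical CDFs and empty inputs error", {
  v <- c(0, 0, 1e-4, 2e-3)
  cdf <- raw_vs_corrected_cdf(v, v)
  expect_equal(cdf$F_raw, cdf$F_eccs)
  expect_true(all(diff(cdf$F_raw) >= 0))
  expect_error(raw_vs_corrected_cdf(v, numeric()), "error-corrected")
  expect_error(raw_vs_corrected_cdf(numeric(), v), "raw")
})

test_that("consensus correction dominates the raw CDF and shrinks its tail", {
  withr::with_seed(71, {
    cfg <- sim_config(n_molecules = 2000, true_vaf = 0, lambda = 8,
                      per_read_error = 0.003)
    lib <- simulate_library(cfg, seed = 41)
  })
  grouped <- filter_families(
    toy_grouped(lib$reads, cfg$amplicons, min_insert = 30), 3)
  eccs <- consensus_quality_filter(call_consensus(grouped, cfg$amplicons))
  obs <- align_eccs(eccs, cfg$amplicons)
  eccs_sites <- wildtype_site_vafs(obs, cfg$amplicons, cfg$targets)
  raw_sites <- raw_site_vafs(grouped, cfg$amplicons, cfg$targets)
  cdf <- raw_vs_corrected_cdf(raw_sites, eccs_sites)
  # error correction never worsens the distribution, at any grid point
  expect_true(all(cdf$F_eccs >= cdf$F_raw))
  # and the 99% quantile shrinks at least tenfold
  q_raw <- specificity_threshold(raw_sites, 0.99)
  q_eccs <- specificity_threshold(eccs_sites, 0.99)
  expect_lt(q_eccs, q_raw / 10)
})
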