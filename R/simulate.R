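#' Simulation configuration for indexed amplicon libraries
#'
#' Describes one sequencing library of molecularly indexed amplicons with
#' known truth. The defaults mirror a typical targeted ECS library: ~2.5
#' million tagged molecules loaded for sequencing, 150 bp paired-end reads
#' carrying a 16 bp random index on each mate, family sizes around 8 read
#' pairs (qPCR-controlled loading), an Illumina-like per-read substitution
#' rate of 0.3%, and rare molecule-level damage: oxidative G>T (C>A)
#' conversion, deamination-style C>T (G>A) conversion, and early-cycle PCR
#' errors, all of which are inherited by every read of the affected family
#' and therefore survive consensus correction (the residual error floor).
#'
#' @param amplicons amplicon table; `NULL` generates one random amplicon of
#'   `amplicon_length` bases (deterministically from `ref_seed`).
#' @param targets targets tibble with an extra `true_vaf` column; `NULL`
#'   places one transversion SNV in the middle of the generated amplicon at
#'   `true_vaf`.
#' @param true_vaf variant allele fraction used when `targets` is `NULL`.
#' @param n_molecules number of tagged molecules in the library.
#' @param family_size `"poisson"` (truncated at >= 1) or `"fixed"`.
#' @param lambda mean of the Poisson family-size distribution.
#' @param fixed_size family size when `family_size = "fixed"`.
#' @param per_read_error per-base substitution probability per read.
#' @param oxo_g_rate per-site probability that a molecule's G (either
#'   strand) is oxidatively converted before amplification, yielding a
#'   strand-consistent G>T (C>A) family.
#' @param ct_error_rate per-site probability of a deamination-style C>T
#'   (G>A) conversion before amplification.
#' @param pcr_error per-base probability of an early-cycle PCR substitution
#'   inherited by the whole family.
#' @param read_length read length in bases (index included).
#' @param index_length molecular index length per mate.
#' @param amplicon_length length of the auto-generated amplicon.
#' @param gc GC content of the auto-generated amplicon.
#' @param phred flat Phred quality written to simulated reads.
#' @param ref_seed seed for the deterministic auto-generation of the
#'   amplicon and target (kept separate from the library seed so one
#'   reference serves a whole dilution series).
#' @return an `ecs_sim_config` list.
#' @export
sim_config <- function(amplicons = NULL, targets = NULL, true_vaf = 0.05,
                       n_molecules = 2.5e6, family_size = c("poisson", "fixed"),
                       lambda = 8, fixed_size = 8,
                       per_read_error = 0.003, oxo_g_rate = 1e-5,
                       ct_error_rate = 2e-6, pcr_error = 1e-6,
                       read_length = 150, index_length = 16,
                       amplicon_length = 150, gc = 0.5, phred = 30,
                       ref_seed = 42) {
  family_size <- match.arg(family_size)
  if (is.null(amplicons)) {
    amplicons <- withr::with_seed(ref_seed, tibble(
      name = "amp1", contig = "sim1", start = 1001L,
      end = 1000L + as.integer(amplicon_length),
      sequence = random_dna(1L, amplicon_length, gc)
    ))
  }
  validate_amplicons(amplicons)
  if (is.null(targets)) {
    off <- as.integer(ceiling(nchar(amplicons$sequence[1]) / 2))
    ref <- substr(amplicons$sequence[1], off, off)
    alt <- unname(c(A = "T", C = "G", G = "C", T = "A")[ref])
    targets <- tibble(
      label = "simSNV", contig = amplicons$contig[1],
      position = amplicons$start[1] + off - 1L,
      ref = ref, alt = alt, type = "snv",
      amplicon = amplicons$name[1], offset = off, true_vaf = true_vaf
    )
  }
  if (!"true_vaf" %in% names(targets)) {
    abort("simulation targets need a true_vaf column")
  }
  cfg <- structure(list(
    amplicons = amplicons, targets = targets, n_molecules = n_molecules,
    family_size = family_size, lambda = lambda, fixed_size = fixed_size,
    per_read_error = per_read_error, oxo_g_rate = oxo_g_rate,
    ct_error_rate = ct_error_rate, pcr_error = pcr_error,
    read_length = read_length, index_length = index_length,
    phred = phred
  ), class = "ecs_sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param config an `ecs_sim_config`.
#' @return the config, invisibly, after validation.
#' @export
validate_sim_config <- function(config) {
  probs <- c(config$per_read_error, config$oxo_g_rate, config$ct_error_rate,
             config$pcr_error, config$targets$true_vaf)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities (error rates, true VAFs) must lie in [0, 1]")
  }
  if (config$n_molecules < 1) abort("n_molecules must be >= 1")
  if (config$family_size == "poisson" && config$lambda <= 0) {
    abort("lambda must be > 0")
  }
  if (config$family_size == "fixed" && config$fixed_size < 1) {
    abort("fixed_size must be >= 1")
  }
  if (config$read_length <= config$index_length) {
    abort("read_length must exceed index_length")
  }
  tmpl_len <- config$read_length - config$index_length
  if (any(nchar(config$amplicons$sequence) < tmpl_len)) {
    abort("amplicons must be at least read_length - index_length long")
  }
  validate_amplicons(config$amplicons)
  validate_targets(config$targets, config$amplicons)
  invisible(config)
}

# apply anchored ref -> alt replacements to one amplicon sequence; offsets
# refer to the unedited sequence, so edits are applied right to left
apply_variants <- function(sequence, offsets, refs, alts) {
  o <- order(offsets, decreasing = TRUE)
  for (i in o) {
    stopifnot(substr(sequence, offsets[i], offsets[i] + nchar(refs[i]) - 1L)
              == refs[i])
    sequence <- paste0(substr(sequence, 1L, offsets[i] - 1L), alts[i],
                       substr(sequence, offsets[i] + nchar(refs[i]),
                              nchar(sequence)))
  }
  sequence
}

# molecule-level damage: convert single sites of `templates` (at positions
# where the current base is in `from`) with per-site probability `rate`
apply_site_damage <- function(templates, rate, from, to) {
  if (rate <= 0) return(templates)
  n_sites <- nchar(templates) # upper bound; thinning below corrects per base
  n_hit <- rbinom(length(templates), n_sites, rate)
  hit <- which(n_hit > 0L)
  for (i in hit) {
    pos <- sample.int(nchar(templates[i]), n_hit[i])
    for (p in pos) {
      b <- substr(templates[i], p, p)
      j <- match(b, from)
      if (!is.na(j)) substr(templates[i], p, p) <- to[j]
    }
  }
  templates
}

rtrunc_pois <- function(n, lambda) {
  p0 <- stats::dpois(0, lambda)
  stats::qpois(runif(n, p0, 1), lambda)
}

random_indexes <- function(n, length) {
  if (length == 0L) return(rep("", n))
  m <- matrix(sample(c("A", "C", "G", "T"), n * length, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate one indexed amplicon library
#'
#' For every molecule: the haplotype is drawn per target
#' (`Bernoulli(true_vaf)`), molecule-level damage (oxidative G>T/C>A,
#' deamination C>T/G>A, early-cycle PCR substitutions) is applied to the
#' template, a fresh random index pair is attached, a family size is drawn,
#' and that many read pairs are emitted in random orientation with
#' independent per-read sequencing errors. The truth table records each
#' molecule's haplotype, indexes and family size.
#'
#' @param config an [sim_config()] object.
#' @param seed integer seed; identical config and seed give byte-identical
#'   output.
#' @param dir optional output directory; when given, FASTQ pairs
#'   (`<prefix>_R1.fastq`, `<prefix>_R2.fastq`) and a truth TSV are written.
#' @param prefix file and read-name prefix.
#' @return list with elements `reads` (tibble `name`, `seq1`, `qual1`,
#'   `seq2`, `qual2`), `truth` (tibble `molecule`, `amplicon`, `haplotype`,
#'   `umi1`, `umi2`, `n_pairs`), `config`, `seed`, and (with `dir`) `paths`.
#' @export
simulate_library <- function(config, seed = 1, dir = NULL, prefix = "sim") {
  validate_sim_config(config)
  withr::with_seed(seed, {
    amp <- config$amplicons
    n <- as.integer(config$n_molecules)
    amp_idx <- if (nrow(amp) == 1L) rep(1L, n)
               else sample.int(nrow(amp), n, replace = TRUE)

    templates <- amp$sequence[amp_idx]
    haplotype <- rep("ref", n)
    tg <- config$targets
    for (k in seq_len(nrow(tg))) {
      on_amp <- which(amp$name[amp_idx] == tg$amplicon[k])
      var <- on_amp[runif(length(on_amp)) < tg$true_vaf[k]]
      if (length(var) == 0L) next
      # apply this target's edit once per distinct template
      uq <- unique(templates[var])
      edited <- vapply(uq, function(s)
        apply_variants(s, tg$offset[k], tg$ref[k], tg$alt[k]), "")
      templates[var] <- unname(edited[templates[var]])
      haplotype[var] <- ifelse(haplotype[var] == "ref", tg$label[k],
                               paste0(haplotype[var], ";", tg$label[k]))
    }
    templates <- apply_site_damage(templates, config$oxo_g_rate,
                                   c("G", "C"), c("T", "A"))
    templates <- apply_site_damage(templates, config$ct_error_rate,
                                   c("C", "G"), c("T", "A"))
    if (config$pcr_error > 0) {
      n_hit <- rbinom(n, nchar(templates), config$pcr_error)
      hit <- which(n_hit > 0L)
      if (length(hit) > 0L) {
        rows <- rep(hit, n_hit[hit])
        pos <- ceiling(runif(length(rows)) * nchar(templates)[rows])
        rot <- sample.int(3L, length(rows), replace = TRUE)
        templates[unique(rows)] <-
          cpp_inject_errors(templates, rows, as.integer(pos), rot)[unique(rows)]
      }
    }

    sizes <- switch(config$family_size,
                    poisson = rtrunc_pois(n, config$lambda),
                    fixed = rep(as.integer(config$fixed_size), n))
    umi1 <- random_indexes(n, config$index_length)
    umi2 <- random_indexes(n, config$index_length)

    tmpl_len <- config$read_length - config$index_length
    left_part <- substr(templates, 1L, tmpl_len)
    right_part <- substr(revcomp(templates), 1L, tmpl_len)
    left_read <- paste0(umi1, left_part)
    right_read <- paste0(umi2, right_part)

    mol <- rep(seq_len(n), sizes)
    npairs <- length(mol)
    fwd <- runif(npairs) < 0.5
    seq1 <- left_read[mol]; seq1[!fwd] <- right_read[mol[!fwd]]
    seq2 <- right_read[mol]; seq2[!fwd] <- left_read[mol[!fwd]]

    if (config$per_read_error > 0) {
      for (nm in c("seq1", "seq2")) {
        s <- get(nm)
        nerr <- rbinom(npairs, nchar(s), config$per_read_error)
        idx <- which(nerr > 0L)
        if (length(idx) > 0L) {
          rows <- rep(idx, nerr[idx])
          pos <- ceiling(runif(length(rows)) * nchar(s)[rows])
          rot <- sample.int(3L, length(rows), replace = TRUE)
          s <- cpp_inject_errors(s, rows, as.integer(pos), rot)
        }
        assign(nm, s)
      }
    }

    qch <- intToUtf8(config$phred + 33L)
    flat_qual <- function(s) {
      len <- nchar(s)
      ul <- unique(len)
      strrep(qch, ul)[match(len, ul)]
    }
    reads <- tibble(
      name = cpp_int_names(prefix, npairs),
      seq1 = seq1, qual1 = flat_qual(seq1),
      seq2 = seq2, qual2 = flat_qual(seq2)
    )
    truth <- tibble(molecule = seq_len(n), amplicon = amp$name[amp_idx],
                    haplotype = haplotype, umi1 = umi1, umi2 = umi2,
                    n_pairs = sizes)
    out <- list(reads = reads, truth = truth, config = config, seed = seed)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      r1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
      r2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
      write_fastq_pairs(reads, r1, r2)
      tr <- file.path(dir, paste0(prefix, "_truth.tsv"))
      readr::write_tsv(truth, tr, progress = FALSE)
      out$paths <- c(r1 = r1, r2 = r2, truth = tr)
    }
    out
  })
}

#' Design a spike-in dilution series
#'
#' One library per (dilution, replicate), with the target's true VAF set to
#' `tumor_vaf * dilution` — tumor DNA carrying the variant serially diluted
#' into normal DNA. Library seeds are derived deterministically from `seed`,
#' so the whole series (and any later regeneration of a single library) is
#' reproducible.
#'
#' @param config base [sim_config()]; its first target is diluted.
#' @param dilutions positive dilution fractions, e.g. `10^-(1:5)`.
#' @param replicates libraries per dilution.
#' @param tumor_vaf VAF of the variant in the undiluted tumor sample
#'   (0.5 for a clonal heterozygous SNV).
#' @param seed master seed for the series.
#' @param dir optional directory: every library's FASTQ pair and truth
#'   table are written there.
#' @return the design: a tibble with columns `library`, `dilution`,
#'   `replicate`, `expected_vaf`, `seed` (per-library), `n_molecules`.
#' @export
simulate_dilution_series <- function(config, dilutions = 10^-(1:5),
                                     replicates = 2, tumor_vaf = 0.5,
                                     seed = 1, dir = NULL) {
  if (length(dilutions) == 0L) abort("dilutions must be non-empty")
  if (any(dilutions <= 0)) abort("dilutions must be positive")
  if (any(tumor_vaf * dilutions > 1)) abort("expected VAF exceeds 1")
  grid <- expand.grid(replicate = seq_len(replicates), dilution = dilutions)
  lib_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max - 1L,
                                           nrow(grid)))
  design <- tibble(
    library = sprintf("d%g_r%d", grid$dilution, grid$replicate),
    dilution = grid$dilution,
    replicate = grid$replicate,
    expected_vaf = tumor_vaf * grid$dilution,
    seed = lib_seeds,
    n_molecules = config$n_molecules
  )
  if (!is.null(dir)) {
    for (i in seq_len(nrow(design))) {
      cfg <- dilution_config(config, design$expected_vaf[i])
      simulate_library(cfg, seed = design$seed[i], dir = dir,
                       prefix = design$library[i])
    }
  }
  design
}

# base config with the first target's true VAF replaced
dilution_config <- function(config, expected_vaf) {
  cfg <- config
  cfg$targets$true_vaf[1] <- expected_vaf
  cfg
}

#' Run the full pipeline over a dilution-series design
#'
#' Each library is regenerated from its design seed, pushed through the
#' complete ECS pipeline (index extraction, amplicon assignment, family
#' grouping and filtering, consensus, alignment, allele counting) and the
#' first target's estimated VAF recorded. Libraries are processed one at a
#' time so memory stays bounded.
#'
#' @param design tibble from [simulate_dilution_series()].
#' @param config the same base [sim_config()] used for the design.
#' @param ... pipeline parameters passed to [run_pipeline()].
#' @param quiet suppress per-library progress messages.
#' @return `design` with columns `estimated_vaf`, `variant_rfs`,
#'   `reference_rfs` appended.
#' @export
run_dilution_series <- function(design, config, ..., quiet = FALSE) {
  res <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
    cfg <- dilution_config(config, design$expected_vaf[i])
    lib <- simulate_library(cfg, seed = design$seed[i])
    run <- run_pipeline(lib$reads, cfg$amplicons, cfg$targets,
                        compute_profile = FALSE, ...)
    rm(lib)
    cc <- run$counts[1, ]
    if (!quiet) {
      inform(sprintf("%s: expected %.3g, estimated %.3g (%d/%d RFs)",
                     design$library[i], design$expected_vaf[i],
                     ifelse(is.na(cc$vaf), 0, cc$vaf),
                     cc$variant_rfs, cc$reference_rfs))
    }
    tibble(estimated_vaf = cc$vaf, variant_rfs = cc$variant_rfs,
           reference_rfs = cc$reference_rfs)
  })
  dplyr::bind_cols(design, res)
}

#' Fit the dilution-series calibration
#'
#' Ordinary least squares of estimated on expected VAF over the series; the
#' coefficient of determination summarises how quantitatively the pipeline
#' reads out tumor DNA prevalence.
#'
#' @param results tibble from [run_dilution_series()] (columns
#'   `expected_vaf`, `estimated_vaf`; `NA` estimates are treated as 0).
#' @return an `ecs_dilution_fit` with [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods.
#' @export
fit_dilution <- function(results) {
  stopifnot(all(c("expected_vaf", "estimated_vaf") %in% names(results)))
  dat <- tibble(expected_vaf = results$expected_vaf,
                estimated_vaf = ifelse(is.na(results$estimated_vaf), 0,
                                       results$estimated_vaf))
  fit <- stats::lm(estimated_vaf ~ expected_vaf, data = dat)
  structure(list(fit = fit, data = dat,
                 r_squared = summary(fit)$r.squared),
            class = "ecs_dilution_fit")
}

#' @export
print.ecs_dilution_fit <- function(x, ...) {
  cat(sprintf("Dilution-series fit over %d libraries: r^2 = %.6f\n",
              nrow(x$data), x$r_squared))
  invisible(x)
}
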