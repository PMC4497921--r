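#' Validate targets against an amplicon set
#'
#' @param targets targets tibble (see [read_targets()]).
#' @param amplicons amplicon table.
#' @return the targets, invisibly, after validation.
#' @export
validate_targets <- function(targets, amplicons) {
  req <- c("label", "contig", "position", "ref", "alt", "type", "amplicon",
           "offset")
  if (!all(req %in% names(targets))) {
    abort(paste("targets table must have columns:", paste(req, collapse = ", ")))
  }
  if (nrow(targets) == 0L) return(invisible(targets))
  m <- match(targets$amplicon, amplicons$name)
  if (anyNA(m)) {
    abort(paste0("target amplicon not in the amplicon set: ",
                 targets$amplicon[which(is.na(m))[1]]))
  }
  obs <- substr(amplicons$sequence[m], targets$offset,
                targets$offset + nchar(targets$ref) - 1L)
  bad <- obs != targets$ref
  if (any(bad)) {
    abort(sprintf("target %s: ref allele %s does not match amplicon sequence (%s)",
                  targets$label[which(bad)[1]], targets$ref[which(bad)[1]],
                  obs[which(bad)[1]]))
  }
  if (any(targets$ref == targets$alt)) abort("target ref and alt are identical")
  pos_ok <- targets$position == amplicons$start[m] + targets$offset - 1L
  if (!all(pos_ok)) abort("target position and amplicon offset disagree")
  invisible(targets)
}

#' Run the complete ECS pipeline
#'
#' Executes index extraction, amplicon assignment, family grouping and size
#' filtering, consensus building, quality filtering, alignment, allele
#' counting and (optionally) residual error profiling, in one call. Input is
#' either an in-memory read-pair tibble or a pair of FASTQ paths.
#'
#' @param reads read-pair tibble (`name`, `seq1`, `qual1`, `seq2`, `qual2`),
#'   or `NULL` when `r1`/`r2` are given.
#' @param amplicons amplicon table ([read_amplicons()]).
#' @param targets targets tibble ([read_targets()]).
#' @param r1,r2 FASTQ paths, used when `reads` is `NULL`.
#' @param index_length,min_insert see [extract_index()].
#' @param anchor_k,anchor_max_edits see [assign_amplicon()].
#' @param umi_collapse apply [collapse_indexes()] after grouping.
#' @param min_family_size see [filter_families()].
#' @param min_agreement,min_depth,max_member_edits see [call_consensus()].
#' @param max_n_fraction see [consensus_quality_filter()].
#' @param min_identity see [align_eccs()].
#' @param compute_profile compute the wild-type error profile and
#'   class-group thresholds, and flag detected targets.
#' @param raw_profile also compute the uncorrected (per-read) site VAFs and
#'   the raw-versus-corrected CDF table (costly on large libraries).
#' @param specificity specificity for the error-profile thresholds.
#' @param min_indel_rfs see [call_variants()].
#' @param out_dir optional directory for report files (calls table,
#'   per-target JSON, thresholds, family-size histogram, manifest).
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return an `ecs_run` object: list with `calls` (per-target tibble;
#'   includes `threshold`/`detected` when profiled), `counts` (the same
#'   without detection columns), `profile` (an `ecs_error_profile` or
#'   `NULL`), `cdf`, `observations`, `manifest`, `params`.
#' @export
run_pipeline <- function(reads = NULL, amplicons, targets,
                         r1 = NULL, r2 = NULL,
                         index_length = 16, min_insert = 30,
                         anchor_k = 20, anchor_max_edits = 2,
                         umi_collapse = FALSE, min_family_size = 3,
                         min_agreement = 0.9, min_depth = 3,
                         max_member_edits = 5, max_n_fraction = 0.2,
                         min_identity = 0.8, compute_profile = TRUE,
                         raw_profile = FALSE, specificity = 0.99,
                         min_indel_rfs = 3, out_dir = NULL, seed = NULL) {
  validate_amplicons(amplicons)
  validate_targets(targets, amplicons)
  checksums <- NULL
  if (is.null(reads)) {
    if (is.null(r1) || is.null(r2)) abort("supply reads or both r1 and r2")
    if (!file.exists(r1) || !file.exists(r2)) abort("FASTQ input not found")
    checksums <- tools::md5sum(c(r1, r2))
    reads <- read_fastq_pairs(r1, r2)
  }
  params <- list(index_length = index_length, min_insert = min_insert,
                 anchor_k = anchor_k, anchor_max_edits = anchor_max_edits,
                 umi_collapse = umi_collapse,
                 min_family_size = min_family_size,
                 min_agreement = min_agreement, min_depth = min_depth,
                 max_member_edits = max_member_edits,
                 max_n_fraction = max_n_fraction,
                 min_identity = min_identity, specificity = specificity,
                 min_indel_rfs = min_indel_rfs)

  tagged <- extract_index(reads, index_length, min_insert,
                          keep_qualities = FALSE)
  n_pairs <- nrow(reads)
  rm(reads)
  tagged <- assign_amplicon(tagged, amplicons, anchor_k, anchor_max_edits)
  fates <- pair_fates(tagged)

  grouped <- group_families(tagged)
  rm(tagged)
  if (umi_collapse) grouped <- collapse_indexes(grouped)
  n_families <- if (nrow(grouped)) max(grouped$family) else 0L
  kept <- filter_families(grouped, min_family_size)
  n_kept_fam <- length(unique(kept$family))
  size_hist <- family_size_histogram(grouped)
  rm(grouped)

  eccs <- call_consensus(kept, amplicons, min_agreement, min_depth,
                         max_member_edits)
  eccs_kept <- consensus_quality_filter(eccs, max_n_fraction)
  n_eccs_dropped <- attr(eccs_kept, "dropped_eccs")

  obs <- align_eccs(eccs_kept, amplicons, min_identity)
  n_unalignable <- sum(obs$status != "aligned")
  counts <- count_alleles(obs, targets)

  profile <- NULL
  cdf <- NULL
  calls <- counts
  if (compute_profile) {
    sites <- wildtype_site_vafs(obs, amplicons, targets)
    profile <- class_profile(sites, specificity)
    calls <- call_variants(counts, profile, specificity, min_indel_rfs)
    if (raw_profile) {
      raw_sites <- raw_site_vafs(kept, amplicons, targets, min_identity)
      cdf <- raw_vs_corrected_cdf(raw_sites, sites)
    }
  }
  rm(kept)

  manifest <- list(
    tool = paste0("umiecs ", as.character(utils::packageVersion("umiecs"))),
    params = params,
    seed = seed,
    input_checksums = as.list(checksums),
    counts = list(
      input_pairs = n_pairs,
      assigned_pairs = fates$n[fates$fate == "assigned"],
      too_short = fates$n[fates$fate == "too_short"],
      unassigned = fates$n[fates$fate == "unassigned"],
      ambiguous = fates$n[fates$fate == "ambiguous"],
      families = n_families,
      families_kept = n_kept_fam,
      eccs = nrow(eccs),
      eccs_dropped_by_n_fraction = n_eccs_dropped,
      eccs_unalignable = n_unalignable,
      eccs_counted = nrow(obs) - n_unalignable
    )
  )
  run <- structure(list(calls = calls, counts = counts, profile = profile,
                        cdf = cdf, observations = obs,
                        family_sizes = size_hist,
                        manifest = manifest, params = params),
                   class = "ecs_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

write_run_outputs <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_calls_table(run$calls, file.path(out_dir, "calls.tsv"))
  jsonlite::write_json(
    purrr::transpose(as.list(run$calls[, setdiff(names(run$calls),
                                                 c("insertions"))])),
    file.path(out_dir, "calls.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  readr::write_tsv(run$family_sizes, file.path(out_dir, "family_sizes.tsv"),
                   progress = FALSE)
  if (!is.null(run$profile)) {
    readr::write_tsv(run$profile$thresholds,
                     file.path(out_dir, "thresholds.tsv"), progress = FALSE)
    readr::write_tsv(run$profile$classes,
                     file.path(out_dir, "class_spectrum.tsv"),
                     progress = FALSE)
  }
  if (!is.null(run$cdf)) {
    readr::write_tsv(run$cdf, file.path(out_dir, "vaf_cdf.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' @export
print.ecs_run <- function(x, ...) {
  cn <- x$manifest$counts
  cat(sprintf("ECS run: %d read pairs, %d families (%d kept), %d ECCS counted\n",
              cn$input_pairs, cn$families, cn$families_kept, cn$eccs_counted))
  print(x$calls)
  invisible(x)
}

#' Tidy an ECS run
#'
#' @param x an `ecs_run`.
#' @param ... unused.
#' @return the per-target calls tibble.
#' @export
tidy.ecs_run <- function(x, ...) as_tibble(x$calls)

#' One-row summary of an ECS run
#'
#' @param x an `ecs_run`.
#' @param ... unused.
#' @return tibble with pipeline stage counts and detection tally.
#' @export
glance.ecs_run <- function(x, ...) {
  cn <- x$manifest$counts
  tibble(input_pairs = cn$input_pairs, assigned_pairs = cn$assigned_pairs,
         families = cn$families, families_kept = cn$families_kept,
         eccs_counted = cn$eccs_counted,
         n_targets = nrow(x$calls),
         n_detected = if ("detected" %in% names(x$calls))
           sum(x$calls$detected) else NA_integer_)
}

#' Tidy a dilution fit
#'
#' @param x an `ecs_dilution_fit`.
#' @param ... unused.
#' @return per-coefficient tibble of the underlying linear model.
#' @export
tidy.ecs_dilution_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(term = rownames(co), estimate = co[, 1], std.error = co[, 2],
         statistic = co[, 3], p.value = co[, 4])
}

#' One-row summary of a dilution fit
#'
#' @param x an `ecs_dilution_fit`.
#' @param ... unused.
#' @return tibble with `r.squared`, `slope`, `intercept`, `n_libraries`.
#' @export
glance.ecs_dilution_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared,
         slope = unname(stats::coef(x$fit)[2]),
         intercept = unname(stats::coef(x$fit)[1]),
         n_libraries = nrow(x$data))
}

#' Longitudinal per-target VAF report
#'
#' Combines per-timepoint call tables into one table with a VAF column per
#' sample, ordered by years before diagnosis (most remote first), the layout
#' used to follow pre-leukemic clones across banked samples.
#'
#' @param call_tables named list of call tibbles (from [count_alleles()] or
#'   [run_pipeline()]`$calls`); names are sample identifiers.
#' @param metadata tibble with columns `sample_id` (matching the list
#'   names) and `years_before`.
#' @return tibble with one row per target (`label`, `contig`, `position`,
#'   `mut`) and one `vaf_<sample_id>` column per timepoint; `NA` where a
#'   target was not queried at a timepoint.
#' @export
longitudinal_report <- function(call_tables, metadata) {
  stopifnot(length(call_tables) >= 1, !is.null(names(call_tables)))
  if (!all(names(call_tables) %in% metadata$sample_id)) {
    abort("every call table needs a metadata row (sample_id)")
  }
  ord <- metadata[radix_order(-metadata$years_before), , drop = FALSE]
  ord <- ord[ord$sample_id %in% names(call_tables), , drop = FALSE]
  all_targets <- dplyr::distinct(
    dplyr::bind_rows(lapply(call_tables, function(x)
      x[, c("label", "contig", "position", "ref", "alt")])))
  out <- tibble(label = all_targets$label, contig = all_targets$contig,
                position = all_targets$position,
                mut = mut_label(all_targets$ref, all_targets$alt))
  for (sid in ord$sample_id) {
    ct <- call_tables[[sid]]
    m <- match(paste(out$label, out$contig, out$position),
               paste(ct$label, ct$contig, ct$position))
    out[[paste0("vaf_", sid)]] <- ct$vaf[m]
  }
  out
}
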