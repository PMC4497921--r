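#' Align consensus sequences to their amplicon references
#'
#' Each ECCS is aligned to its amplicon by a fitting (glocal) alignment under
#' unit edit costs, with reference overhangs free so the consensus finds its
#' best placement. Gaps are left-normalised so an indel in repeat context has
#' one canonical reference position. Per reference position the family's
#' observation is recorded: a base, `N` (no call), or `-` (deleted);
#' insertions are recorded against the reference position they follow
#' (left-anchored). An ECCS whose alignment identity (matches over aligned
#' non-`N` columns) falls below `min_identity` is discarded as unalignable.
#'
#' Identical consensus strings are aligned once and the result shared, which
#' makes the per-family cost of deep libraries small. Equal-length consensus
#' sequences that differ from the reference window by at most a few
#' substitutions skip the dynamic program entirely.
#'
#' @param eccs tibble from [call_consensus()] (after
#'   [consensus_quality_filter()]).
#' @param amplicons amplicon table.
#' @param min_identity minimum alignment identity.
#' @return tibble with one row per family: `family`, `amplicon`, `umi_key`,
#'   `size`, `status` (`"aligned"`/`"unalignable"`), `ref_start`, `ref_end`
#'   (1-based amplicon coordinates covered), `aligned` (one character per
#'   covered reference position), `insertions` (list column of
#'   `list(pos, seq)` or `NULL`), `identity`.
#' @export
align_eccs <- function(eccs, amplicons, min_identity = 0.8) {
  if (nrow(eccs) == 0L) {
    return(tibble(family = integer(), amplicon = character(),
                  umi_key = character(), size = integer(), status = character(),
                  ref_start = integer(), ref_end = integer(),
                  aligned = character(), insertions = list(),
                  identity = double()))
  }
  pieces <- lapply(split(seq_len(nrow(eccs)), eccs$amplicon), function(ix) {
    ref <- amplicons$sequence[match(eccs$amplicon[ix[1]], amplicons$name)]
    amp_len <- nchar(ref)
    sub <- eccs[ix, ]
    key <- paste0(sub$start, "\r", sub$eccs)
    ui <- which(!duplicated(key))
    uq <- sub[ui, ]
    map <- match(key, key[ui])

    status <- rep("unalignable", length(ui))
    ref_start <- rep(NA_integer_, length(ui))
    ref_end <- rep(NA_integer_, length(ui))
    aligned <- rep(NA_character_, length(ui))
    ins <- vector("list", length(ui))
    ident <- rep(NA_real_, length(ui))

    # fast path: full-length, start-anchored, nearly identical consensus
    fast <- which(nchar(uq$eccs) == amp_len & uq$start == 0L)
    if (length(fast) > 0L) {
      hm <- cpp_hamming_to_ref(uq$eccs[fast], ref, rep(0L, length(fast)))
      ok <- hm[, 1] <= 3L & (amp_len - hm[, 2]) > 0 &
        (amp_len - hm[, 2] - hm[, 1]) / pmax(amp_len - hm[, 2], 1L) >= min_identity
      sel <- fast[ok]
      status[sel] <- "aligned"
      ref_start[sel] <- 1L
      ref_end[sel] <- amp_len
      aligned[sel] <- uq$eccs[sel]
      ident[sel] <- (amp_len - hm[ok, 2] - hm[ok, 1]) /
        pmax(amp_len - hm[ok, 2], 1L)
    }
    slow <- setdiff(seq_along(ui), which(status == "aligned"))
    if (length(slow) > 0L) {
      res <- cpp_align_batch(uq$eccs[slow], ref, min_identity)
      okc <- res$status == 0L
      status[slow[okc]] <- "aligned"
      ref_start[slow] <- res$ref_start
      ref_end[slow] <- res$ref_end
      aligned[slow[okc]] <- res$aligned[okc]
      ins[slow] <- res$insertions
      n_N <- nchar(res$aligned) -
        nchar(gsub("N", "", res$aligned, fixed = TRUE))
      ident[slow] <- ifelse(res$n_col > 0,
                            res$n_match / pmax(res$n_col - n_N, 1), NA_real_)
    }
    tibble(family = sub$family, amplicon = sub$amplicon,
           umi_key = sub$umi_key, size = sub$size,
           status = status[map], ref_start = ref_start[map],
           ref_end = ref_end[map], aligned = aligned[map],
           insertions = ins[map], identity = ident[map])
  })
  out <- dplyr::bind_rows(pieces)
  out[radix_order(out$family), , drop = FALSE]
}

# observation of one family inside a target window, from its aligned string
window_obs <- function(obs, offset, width) {
  substr(obs$aligned, offset - obs$ref_start + 1L,
         offset - obs$ref_start + width)
}

has_insertion_at <- function(insertions, pos, seq) {
  vapply(insertions, function(x) {
    if (is.null(x)) return(FALSE)
    any(x$pos == pos & x$seq == seq)
  }, logical(1))
}

has_any_insertion_at <- function(insertions, pos) {
  vapply(insertions, function(x) {
    if (is.null(x)) return(FALSE)
    any(x$pos == pos)
  }, logical(1))
}

#' Count variant- and reference-supporting read families at target loci
#'
#' Each aligned family contributes exactly once per target: to
#' `variant_rfs` when its observation matches the alternate allele (for
#' indels, the exact anchored replacement), to `reference_rfs` when it
#' matches the reference allele, and to `other_rfs` otherwise (third
#' alleles, `N` no-calls, partial or shifted indels). Families whose
#' alignment does not span the target are not counted. The variant allele
#' fraction is `variant_rfs / (variant_rfs + reference_rfs)`, undefined
#' (`NA`) when the denominator is zero; `other_rfs` never enters the
#' denominator.
#'
#' @param observations tibble from [align_eccs()].
#' @param targets targets tibble from [read_targets()].
#' @return `targets` with columns `variant_rfs`, `reference_rfs`,
#'   `other_rfs`, `spanning` (total families counted) and `vaf`.
#' @export
count_alleles <- function(observations, targets) {
  if (nrow(targets) == 0L) {
    return(dplyr::mutate(targets, variant_rfs = integer(),
                         reference_rfs = integer(), other_rfs = integer(),
                         spanning = integer(), vaf = double()))
  }
  res <- purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    obs <- observations[observations$amplicon == tg$amplicon &
                          observations$status == "aligned", , drop = FALSE]
    width <- nchar(tg$ref)
    span_end <- tg$offset + width - 1L
    if (tg$type == "ins") span_end <- tg$offset + 1L
    obs <- obs[!is.na(obs$ref_start) & obs$ref_start <= tg$offset &
                 obs$ref_end >= span_end, , drop = FALSE]
    n_span <- nrow(obs)
    if (n_span == 0L) {
      return(tibble(variant_rfs = 0L, reference_rfs = 0L, other_rfs = 0L,
                    spanning = 0L, vaf = NA_real_))
    }
    if (tg$type == "snv") {
      ch <- window_obs(obs, tg$offset, 1L)
      v <- sum(ch == tg$alt)
      r <- sum(ch == tg$ref)
    } else if (tg$type == "del") {
      win <- window_obs(obs, tg$offset, width)
      gap_pattern <- paste0(tg$alt, strrep("-", width - nchar(tg$alt)))
      no_ins <- !has_any_insertion_at(obs$insertions, tg$offset)
      v <- sum(win == gap_pattern & no_ins)
      r <- sum(win == tg$ref & no_ins)
    } else if (tg$type == "ins") {
      anchor <- window_obs(obs, tg$offset, 1L)
      ins_seq <- substr(tg$alt, nchar(tg$ref) + 1L, nchar(tg$alt))
      hit <- has_insertion_at(obs$insertions, tg$offset, ins_seq)
      any_ins <- has_any_insertion_at(obs$insertions, tg$offset)
      v <- sum(anchor == tg$ref & hit)
      r <- sum(anchor == tg$ref & !any_ins)
    } else {  # multi-nucleotide substitution
      win <- window_obs(obs, tg$offset, width)
      v <- sum(win == tg$alt)
      r <- sum(win == tg$ref)
    }
    tibble(variant_rfs = as.integer(v), reference_rfs = as.integer(r),
           other_rfs = as.integer(n_span - v - r), spanning = n_span,
           vaf = compute_vaf(v, r))
  })
  dplyr::bind_cols(targets, res)
}

#' Variant allele fraction from read-family counts
#'
#' @param variant_rfs,reference_rfs family counts.
#' @return `variant_rfs / (variant_rfs + reference_rfs)`, `NA` when the
#'   denominator is zero.
#' @export
#' @examples
#' compute_vaf(61238, 156986)  # 0.2806...
compute_vaf <- function(variant_rfs, reference_rfs) {
  denom <- variant_rfs + reference_rfs
  ifelse(denom > 0, variant_rfs / denom, NA_real_)
}

#' Decide which targets are detected
#'
#' A substitution is detected when its VAF exceeds the substitution-class
#' threshold of the residual error profile at the requested specificity
#' (class groups: G>T(C>A), C>T(G>A), and the other eight substitutions).
#' Indels, which the sequencing process only rarely generates erroneously,
#' are detected on a minimum variant-family count instead.
#'
#' @param allele_counts tibble from [count_alleles()].
#' @param error_profile an `ecs_error_profile` from [class_profile()], or
#'   `NULL` to use only a global threshold of 0 (every positive VAF called).
#' @param specificity requested specificity; must match the profile's.
#' @param min_indel_rfs minimum variant families for an indel call.
#' @return `allele_counts` with columns `class_group`, `threshold` and
#'   `detected`.
#' @export
call_variants <- function(allele_counts, error_profile,
                          specificity = 0.99, min_indel_rfs = 3) {
  grp <- ifelse(allele_counts$type == "snv",
                substitution_group(allele_counts$ref, allele_counts$alt),
                "indel")
  thr <- rep(NA_real_, nrow(allele_counts))
  if (is.null(error_profile)) {
    glob <- 0
  } else {
    stopifnot(inherits(error_profile, "ecs_error_profile"))
    if (!isTRUE(all.equal(error_profile$specificity, specificity))) {
      warn("specificity differs from the error profile's; profile thresholds used as-is")
    }
    th <- error_profile$thresholds
    glob <- th$threshold[th$group == "global"]
    m <- match(grp, th$group)
    thr <- th$threshold[m]
  }
  miss <- allele_counts$type == "snv" & is.na(thr)
  if (any(miss)) {
    warn(paste0("no class threshold for ",
                paste(unique(grp[miss]), collapse = ", "),
                "; falling back to the global threshold"))
    thr[miss] <- glob
  }
  snv <- allele_counts$type == "snv"
  detected <- logical(nrow(allele_counts))
  detected[snv] <- !is.na(allele_counts$vaf[snv]) &
    allele_counts$vaf[snv] > thr[snv]
  detected[!snv] <- allele_counts$variant_rfs[!snv] >= min_indel_rfs
  dplyr::mutate(allele_counts, class_group = grp, threshold = thr,
                detected = detected)
}
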