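comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Substitution class helpers
#'
#' Twelve raw substitution classes (`ref>alt`) collapse to six strand
#' classes by merging each class with its reverse complement, written
#' pyrimidine-first (`"C>A(G>T)"` merges C>A with G>T). For thresholding,
#' classes form three groups: `"G>T(C>A)"` (the 8-oxo-guanine signature),
#' `"C>T(G>A)"` (deamination-type), and `"other"` (the remaining eight
#' substitutions).
#'
#' @param ref,alt single reference and alternate bases (vectorised).
#' @return character vector of class labels.
#' @export
collapse_class <- function(ref, alt) {
  pyr <- ref %in% c("C", "T")
  r <- ifelse(pyr, ref, unname(comp_base(ref)))
  a <- ifelse(pyr, alt, unname(comp_base(alt)))
  paste0(r, ">", a, "(", unname(comp_base(r)), ">", unname(comp_base(a)), ")")
}

#' @rdname collapse_class
#' @export
substitution_group <- function(ref, alt) {
  dplyr::case_when(
    (ref == "G" & alt == "T") | (ref == "C" & alt == "A") ~ "G>T(C>A)",
    (ref == "C" & alt == "T") | (ref == "G" & alt == "A") ~ "C>T(G>A)",
    TRUE ~ "other"
  )
}

# weighted per-position base counts from an observation table, one matrix
# (rows A,C,G,T,N,-) per amplicon; identical aligned strings counted once
position_counts <- function(observations, amplicons) {
  obs <- observations[observations$status == "aligned", , drop = FALSE]
  out <- list()
  for (amp in unique(obs$amplicon)) {
    sub <- obs[obs$amplicon == amp, , drop = FALSE]
    amp_len <- nchar(amplicons$sequence[match(amp, amplicons$name)])
    key <- paste0(sub$ref_start, "\r", sub$aligned)
    tb <- table(key)
    first <- sub[match(names(tb), key), , drop = FALSE]
    m <- cpp_column_counts(first$aligned, first$ref_start,
                           as.numeric(tb), amp_len)
    rownames(m) <- c("A", "C", "G", "T", "N", "-")
    out[[amp]] <- m
  }
  out
}

# amplicon positions masked because a target's reference allele covers them
target_mask <- function(targets, amplicon) {
  tg <- targets[targets$amplicon == amplicon, , drop = FALSE]
  if (nrow(tg) == 0L) return(integer())
  unique(unlist(lapply(seq_len(nrow(tg)), function(i) {
    seq(tg$offset[i], tg$offset[i] + nchar(tg$ref[i]) - 1L)
  })))
}

site_records_from_counts <- function(counts_by_amp, amplicons, targets) {
  pieces <- lapply(names(counts_by_amp), function(amp) {
    m <- counts_by_amp[[amp]]
    ref_seq <- amplicons$sequence[match(amp, amplicons$name)]
    ref_base <- strsplit(ref_seq, "")[[1]]
    keep <- setdiff(seq_len(ncol(m)), target_mask(targets, amp))
    cover <- colSums(m[c("A", "C", "G", "T"), , drop = FALSE])
    keep <- keep[cover[keep] > 0]
    if (length(keep) == 0L) return(NULL)
    recs <- lapply(keep, function(p) {
      rb <- ref_base[p]
      ab <- setdiff(c("A", "C", "G", "T"), rb)
      tibble(amplicon = amp, pos = p, ref_base = rb, alt_base = ab,
             n_alt = unname(m[ab, p]), n_cover = unname(cover[p]))
    })
    dplyr::bind_rows(recs)
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0L) {
    return(tibble(amplicon = character(), pos = integer(),
                  ref_base = character(), alt_base = character(),
                  n_alt = double(), n_cover = double(), vaf = double(),
                  class = character(), class6 = character(),
                  group = character()))
  }
  out$vaf <- out$n_alt / out$n_cover
  out$class <- paste0(out$ref_base, ">", out$alt_base)
  out$class6 <- collapse_class(out$ref_base, out$alt_base)
  out$group <- substitution_group(out$ref_base, out$alt_base)
  out
}

#' Per-site VAF records at wild-type positions
#'
#' For every amplicon position not covered by a queried target allele and
#' every alternate base, the fraction of aligned families showing that base
#' over families covering the position (with a called base). These records
#' characterise the residual error that survives consensus correction and
#' are the input to [specificity_threshold()] and [class_profile()].
#'
#' @param observations tibble from [align_eccs()] (or any table in that
#'   format, e.g. per-read observations for the uncorrected comparator).
#' @param amplicons amplicon table.
#' @param targets targets tibble; their reference-allele positions are
#'   excluded.
#' @return tibble with columns `amplicon`, `pos`, `ref_base`, `alt_base`,
#'   `n_alt`, `n_cover`, `vaf`, `class`, `class6`, `group`; zero-coverage
#'   sites are omitted.
#' @export
wildtype_site_vafs <- function(observations, amplicons, targets) {
  cnt <- position_counts(observations, amplicons)
  site_records_from_counts(cnt, amplicons, targets)
}

#' Uncorrected per-site VAF records
#'
#' The conventional deep-sequencing comparator: every read is treated as its
#' own size-1 family (no within-family correction), then per-site VAF records
#' are computed exactly as in [wildtype_site_vafs()].
#'
#' @param grouped tibble from [group_families()] (family structure is
#'   ignored; all assigned reads are used).
#' @param amplicons amplicon table.
#' @param targets targets tibble.
#' @param min_identity alignment identity threshold per read.
#' @return per-site VAF records, as in [wildtype_site_vafs()].
#' @export
raw_site_vafs <- function(grouped, amplicons, targets, min_identity = 0.8) {
  members <- member_reads(grouped)
  amp_len <- nchar(amplicons$sequence[match(members$amplicon,
                                            amplicons$name)])
  pseudo <- tibble(
    family = seq_len(nrow(members)),
    amplicon = members$amplicon,
    umi_key = NA_character_,
    size = 1L,
    eccs = members$seq,
    start = ifelse(members$side == 0L, 0L,
                   pmax(amp_len - nchar(members$seq), 0L))
  )
  obs <- align_eccs(pseudo, amplicons, min_identity)
  wildtype_site_vafs(obs, amplicons, targets)
}

#' Specificity threshold from wild-type site VAFs
#'
#' The smallest observed VAF `t` such that at least a `specificity` fraction
#' of wild-type site records fall strictly below `t`; calling only variants
#' with VAF above `t` is then false-positive at rate at most
#' `1 - specificity` on this record set. When no observed value qualifies
#' the maximum observed VAF is returned (for a degenerate all-zero record
#' set this is 0: any positive VAF clears background).
#'
#' @param vaf_records tibble with a `vaf` column, or a numeric vector.
#' @param specificity requested specificity in (0, 1).
#' @return a single VAF threshold.
#' @export
specificity_threshold <- function(vaf_records, specificity = 0.99) {
  v <- if (is.numeric(vaf_records)) vaf_records else vaf_records$vaf
  stopifnot(specificity > 0, specificity < 1)
  n <- length(v)
  if (n == 0L) abort("no VAF records")
  if (n < 1 / (1 - specificity)) {
    warn(sprintf(paste0("only %d records; the %.4g quantile is not resolved ",
                        "and the threshold falls back toward the maximum"),
                 n, specificity))
  }
  sv <- sort(v)
  u <- unique(sv)
  below <- match(u, sv) - 1L  # records strictly below each candidate
  ok <- which(below >= specificity * n - 1e-9)
  if (length(ok) == 0L) return(max(v)) else u[ok[1]]
}

#' Residual error profile by substitution class
#'
#' Partitions wild-type site records into the three threshold groups
#' (G>T(C>A), C>T(G>A), other eight), applies [specificity_threshold()] to
#' each and to the pooled records, and tabulates the six strand-collapsed
#' substitution classes.
#'
#' @param vaf_records tibble from [wildtype_site_vafs()].
#' @param specificity requested specificity.
#' @return an `ecs_error_profile`: list with `thresholds` (tibble: `group`,
#'   `n_records`, `threshold`), `classes` (tibble: `class6`, `n_records`,
#'   `alt_families`, `mean_vaf`), `specificity`, and the input `records`.
#' @export
class_profile <- function(vaf_records, specificity = 0.99) {
  groups <- c("G>T(C>A)", "C>T(G>A)", "other")
  thr <- purrr::map_dfr(groups, function(g) {
    recs <- vaf_records[vaf_records$group == g, , drop = FALSE]
    if (nrow(recs) == 0L) {
      warn(paste0("no wild-type records in class group ", g,
                  "; its threshold is undefined"))
      return(tibble(group = g, n_records = 0L, threshold = NA_real_))
    }
    tibble(group = g, n_records = nrow(recs),
           threshold = suppressWarnings(specificity_threshold(recs, specificity)))
  })
  thr <- dplyr::bind_rows(
    thr,
    tibble(group = "global", n_records = nrow(vaf_records),
           threshold = if (nrow(vaf_records) > 0)
             suppressWarnings(specificity_threshold(vaf_records, specificity))
           else NA_real_))
  cls <- vaf_records |>
    dplyr::group_by(class6 = .data$class6) |>
    dplyr::summarise(n_records = dplyr::n(),
                     alt_families = sum(.data$n_alt),
                     mean_vaf = mean(.data$vaf), .groups = "drop") |>
    dplyr::arrange(.data$class6)
  structure(list(thresholds = thr, classes = cls,
                 specificity = specificity, records = vaf_records),
            class = "ecs_error_profile")
}

#' @export
print.ecs_error_profile <- function(x, ...) {
  cat(sprintf("ECS residual error profile (%d wild-type site records, %.4g specificity)\n",
              nrow(x$records), x$specificity))
  print(x$thresholds)
  invisible(x)
}

#' Cumulative VAF distributions, raw versus error-corrected
#'
#' Empirical CDFs of per-site VAF records from the uncorrected (per-read)
#' and the consensus-corrected pipeline, evaluated on a shared grid. A lower
#' error floor shows as the corrected CDF dominating the raw one (reaching
#' any quantile at a smaller VAF).
#'
#' @param raw_site_vafs records from [raw_site_vafs()] (tibble or numeric).
#' @param eccs_site_vafs records from [wildtype_site_vafs()].
#' @param grid VAF grid; defaults to all VAFs observed in either set.
#' @return tibble with columns `vaf`, `F_raw`, `F_eccs`, non-decreasing in
#'   `vaf`.
#' @export
raw_vs_corrected_cdf <- function(raw_site_vafs, eccs_site_vafs, grid = NULL) {
  vr <- if (is.numeric(raw_site_vafs)) raw_site_vafs else raw_site_vafs$vaf
  ve <- if (is.numeric(eccs_site_vafs)) eccs_site_vafs else eccs_site_vafs$vaf
  if (length(ve) == 0L) abort("no error-corrected VAF records")
  if (length(vr) == 0L) abort("no raw VAF records")
  if (is.null(grid)) grid <- sort(unique(c(0, vr, ve)))
  tibble(vaf = grid,
         F_raw = vapply(grid, function(t) mean(vr <= t), 0.0),
         F_eccs = vapply(grid, function(t) mean(ve <= t), 0.0))
}
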