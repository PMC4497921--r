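# orient every member read to the amplicon top strand and tag which molecule
# end anchors it: side 0 starts at the template's first base, side 1 ends at
# its last base. Forward pairs: mate1 is left-anchored, mate2 (reverse
# complemented) right-anchored; reverse pairs swap roles.
member_reads <- function(grouped) {
  rev <- which(grouped$orientation == "reverse")
  left_seq <- grouped$tmpl1
  right_raw <- grouped$tmpl2
  left_seq[rev] <- grouped$tmpl2[rev]
  right_raw[rev] <- grouped$tmpl1[rev]
  tibble(
    family = rep(grouped$family, 2L),
    amplicon = rep(grouped$amplicon, 2L),
    seq = c(left_seq, revcomp(right_raw)),
    side = rep(c(0L, 1L), each = nrow(grouped))
  )
}

#' Build error-corrected consensus sequences
#'
#' One consensus (ECCS) is built per read family by a per-position vote over
#' its member reads, both mates voting independently. At each position the
#' modal base is kept when it is unique, covered by at least `min_depth`
#' reads, and supported by at least a `min_agreement` fraction of the reads
#' covering that position; every other position - disagreements, ties, thin
#' coverage - becomes `N`, which excludes it from variant calling without
#' discarding the family.
#'
#' Members are end-anchored: each read either starts at the molecule's first
#' template base or ends at its last one, so no gapped alignment is needed
#' within a family. When a family carries both blocks, their relative offset
#' is reconciled by a bounded shift scan (up to `max_shift` positions around
#' the reference spacing) that maximises agreement between the modal left and
#' modal right member, which keeps indel-bearing molecules internally
#' consistent. A member whose anchored mismatch count against its block's
#' modal read exceeds `max_member_edits` is excluded from the vote and
#' counted as an outlier.
#'
#' @param grouped tibble from [group_families()] / [filter_families()],
#'   containing at least one read pair per family.
#' @param amplicons amplicon table.
#' @param min_agreement minimum fraction of covering reads that must carry
#'   the modal base.
#' @param min_depth minimum reads covering a position.
#' @param max_member_edits member discordance budget against the modal read.
#' @param max_shift bound on the left/right block offset scan.
#' @param collect_support return per-position `support` and `depth` integer
#'   vectors as list columns (memory-heavy on large runs).
#' @return tibble with one row per family: `family`, `amplicon`, `umi_key`,
#'   `size` (read pairs), `eccs`, `start` (0-based template offset of the
#'   consensus string), `n_N`, `frac_N`, `n_reads_used`, `n_outliers`, and
#'   optionally `support`/`depth`.
#' @export
call_consensus <- function(grouped, amplicons,
                           min_agreement = 0.9, min_depth = 3,
                           max_member_edits = 5, max_shift = 10,
                           collect_support = FALSE) {
  if (nrow(grouped) == 0L) {
    out <- tibble(family = integer(), amplicon = character(),
                  umi_key = character(), size = integer(), eccs = character(),
                  start = integer(), length = integer(), n_N = integer(),
                  frac_N = double(), n_reads_used = integer(),
                  n_outliers = integer())
    if (collect_support) { out$support <- list(); out$depth <- list() }
    return(out)
  }
  if (anyNA(grouped$family)) abort("grouped reads contain unassigned rows")
  ft <- family_table(grouped)
  members <- member_reads(grouped)
  members <- members[radix_order(members$family), , drop = FALSE]
  pieces <- lapply(split(seq_len(nrow(members)), members$amplicon), function(ix) {
    amp_len <- nchar(amplicons$sequence[match(members$amplicon[ix[1]],
                                              amplicons$name)])
    res <- cpp_consensus(members$seq[ix], members$side[ix],
                         members$family[ix], amp_len,
                         min_agreement, as.integer(min_depth),
                         as.integer(max_member_edits), as.integer(max_shift),
                         collect_support)
    out <- tibble(family = res$fam, eccs = res$consensus, start = res$start,
                  length = res$length, n_N = res$n_N,
                  n_reads_used = res$n_used, n_outliers = res$n_outliers)
    if (collect_support) { out$support <- res$support; out$depth <- res$depth }
    out
  })
  out <- dplyr::bind_rows(pieces)
  out <- out[radix_order(out$family), , drop = FALSE]
  out$frac_N <- out$n_N / out$length
  m <- match(out$family, ft$family)
  out$amplicon <- ft$amplicon[m]
  out$umi_key <- ft$umi_key[m]
  out$size <- ft$size[m]
  cols <- c("family", "amplicon", "umi_key", "size", "eccs", "start",
            "length", "n_N", "frac_N", "n_reads_used", "n_outliers")
  if (collect_support) cols <- c(cols, "support", "depth")
  out[, cols]
}

#' Filter consensus sequences by no-call fraction
#'
#' An ECCS dominated by `N` positions carries little usable evidence and is
#' removed before calling.
#'
#' @param eccs tibble from [call_consensus()].
#' @param max_n_fraction drop an ECCS whose fraction of `N` positions
#'   exceeds this value (1.0 never drops).
#' @return the filtered tibble, with attribute `"dropped_eccs"` counting
#'   removals.
#' @export
consensus_quality_filter <- function(eccs, max_n_fraction = 0.2) {
  keep <- eccs$frac_N <= max_n_fraction
  out <- eccs[keep, , drop = FALSE]
  attr(out, "dropped_eccs") <- sum(!keep)
  out
}
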