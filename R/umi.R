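#' Extract molecular indexes from read pairs
#'
#' Each mate begins with a random molecular index of `index_length` bases
#' (16 by default, per adapter end); the index is removed and recorded, and
#' the remainder forms the template sequence. Pairs whose post-trim template
#' would be shorter than `min_insert` on either mate are rejected with reason
#' `"too_short"` and carried through in the output so that downstream counts
#' always reconcile with the input.
#'
#' @param pairs tibble of read pairs with columns `name`, `seq1`, `qual1`,
#'   `seq2`, `qual2` (see [read_fastq_pairs()]).
#' @param index_length index length per mate; 0 is a degenerate mode in which
#'   the index is empty and the template is the full read.
#' @param min_insert minimum template length after index removal.
#' @param keep_qualities keep per-template quality strings (`tqual1`,
#'   `tqual2`). Dropping them roughly halves memory on large libraries; the
#'   consensus vote never uses them.
#' @return the input tibble with columns `umi1`, `umi2`, `tmpl1`, `tmpl2`
#'   (and `tqual1`/`tqual2` unless dropped) plus `reject` (`NA` for kept
#'   pairs, otherwise the rejection reason). Original `seq*`/`qual*` columns
#'   are dropped.
#' @export
extract_index <- function(pairs, index_length = 16, min_insert = 30,
                          keep_qualities = TRUE) {
  stopifnot(index_length >= 0, min_insert >= 0)
  l1 <- nchar(pairs$seq1)
  l2 <- nchar(pairs$seq2)
  too_short <- l1 < index_length + min_insert | l2 < index_length + min_insert
  out <- tibble(
    name = pairs$name,
    umi1 = substr(pairs$seq1, 1L, index_length),
    umi2 = substr(pairs$seq2, 1L, index_length),
    tmpl1 = substr(pairs$seq1, index_length + 1L, l1),
    tmpl2 = substr(pairs$seq2, index_length + 1L, l2)
  )
  if (keep_qualities) {
    out$tqual1 <- substr(pairs$qual1, index_length + 1L, l1)
    out$tqual2 <- substr(pairs$qual2, index_length + 1L, l2)
  }
  out$reject <- ifelse(too_short, "too_short", NA_character_)
  out
}

# per-amplicon anchor k-mers: the first k bases (forward strand entry) and
# the reverse complement of the last k bases (reverse strand entry)
amplicon_anchors <- function(amplicons, anchor_k) {
  if (any(nchar(amplicons$sequence) < anchor_k)) {
    abort("anchor_k exceeds the length of an amplicon")
  }
  len <- nchar(amplicons$sequence)
  tibble(
    anchor = c(substr(amplicons$sequence, 1L, anchor_k),
               revcomp(substr(amplicons$sequence, len - anchor_k + 1L, len))),
    amplicon = rep(amplicons$name, 2L),
    orientation = rep(c("forward", "reverse"), each = nrow(amplicons))
  )
}

#' Assign read pairs to amplicons
#'
#' The start of the mate-1 template is compared with each amplicon's two
#' entry k-mers: its first `anchor_k` bases (a forward-orientation pair) and
#' the reverse complement of its last `anchor_k` bases (a reverse-orientation
#' pair). The closest anchor within `anchor_max_edits` edits wins; exact
#' matches use a hash lookup and only the remainder pays for edit distances
#' (computed on deduplicated k-mers). No match within the edit budget rejects
#' the pair as `"unassigned"`; a tie between amplicons or orientations
#' rejects it as `"ambiguous"`.
#'
#' @param tagged tibble from [extract_index()].
#' @param amplicons amplicon table ([read_amplicons()]).
#' @param anchor_k anchor k-mer length.
#' @param anchor_max_edits maximum edit distance to an anchor.
#' @return `tagged` with columns `amplicon`, `orientation`, and `umi_key`
#'   (the orientation-normalised concatenated index: reverse-orientation
#'   pairs swap mates first so both read directions of one molecule yield
#'   the same key); `reject` gains `"unassigned"`/`"ambiguous"`.
#' @export
assign_amplicon <- function(tagged, amplicons, anchor_k = 20,
                            anchor_max_edits = 2) {
  anchors <- amplicon_anchors(amplicons, anchor_k)
  n <- nrow(tagged)
  amplicon <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  reject <- tagged$reject
  live <- which(is.na(reject))
  head1 <- substr(tagged$tmpl1[live], 1L, anchor_k)

  dup_anchor <- anchors$anchor[duplicated(anchors$anchor)]
  hit <- match(head1, anchors$anchor)
  exact <- !is.na(hit)
  amb_exact <- exact & head1 %in% dup_anchor
  ok <- exact & !amb_exact
  amplicon[live[ok]] <- anchors$amplicon[hit[ok]]
  orientation[live[ok]] <- anchors$orientation[hit[ok]]
  reject[live[amb_exact]] <- "ambiguous"

  todo <- which(!exact)
  if (length(todo) > 0L) {
    uh <- unique(head1[todo])
    d <- utils::adist(uh, anchors$anchor)
    best <- do.call(pmin, lapply(seq_len(ncol(d)), function(j) d[, j]))
    # ties at the minimum leave the pair ambiguous; one winner assigns it
    n_best <- rowSums(d == best)
    win <- max.col(-d, ties.method = "first")
    status <- ifelse(best > anchor_max_edits, "unassigned",
                     ifelse(n_best > 1L, "ambiguous", "ok"))
    m <- match(head1[todo], uh)
    st <- status[m]
    sel <- todo[st == "ok"]
    amplicon[live[sel]] <- anchors$amplicon[win[m][st == "ok"]]
    orientation[live[sel]] <- anchors$orientation[win[m][st == "ok"]]
    reject[live[todo[st != "ok"]]] <- st[st != "ok"]
  }

  out <- tagged
  out$amplicon <- amplicon
  out$orientation <- orientation
  out$reject <- reject
  key <- paste0(out$umi1, out$umi2)
  rev <- which(!is.na(out$orientation) & out$orientation == "reverse")
  key[rev] <- paste0(out$umi2[rev], out$umi1[rev])
  key[is.na(out$orientation)] <- NA_character_
  out$umi_key <- key
  out
}

#' Tally pair fates after tagging and assignment
#'
#' @param tagged tibble from [assign_amplicon()] (or [extract_index()]).
#' @return tibble with columns `fate` (`assigned`, `too_short`, `unassigned`,
#'   `ambiguous`) and `n`; the column sums to the number of input pairs.
#' @export
pair_fates <- function(tagged) {
  fate <- ifelse(is.na(tagged$reject), "assigned", tagged$reject)
  fate <- factor(fate, levels = c("assigned", "too_short", "unassigned",
                                  "ambiguous"))
  counts <- as.integer(table(fate))
  tibble(fate = levels(fate), n = counts)
}
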