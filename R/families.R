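#' Group tagged reads into read families
#'
#' Reads carrying the same molecular index on the same amplicon descend from
#' one tagged molecule and form a read family, the unit of error correction.
#' The family key is `(amplicon, umi_key)`; identical indexes on different
#' amplicons are distinct molecules. Rejected pairs (see [assign_amplicon()])
#' are dropped here.
#'
#' @param tagged tibble from [assign_amplicon()].
#' @return a tibble of the kept pairs, sorted by amplicon then index (radix
#'   order, locale-independent), with an integer `family` column numbering
#'   families in that order. Summarise with [family_table()].
#' @export
group_families <- function(tagged) {
  kept <- tagged[is.na(tagged$reject), , drop = FALSE]
  if (nrow(kept) == 0L) {
    kept$family <- integer()
    return(as_tibble(kept))
  }
  o <- radix_order(kept$amplicon, kept$umi_key)
  kept <- kept[o, , drop = FALSE]
  new_fam <- c(TRUE, kept$amplicon[-1] != kept$amplicon[-nrow(kept)] |
                 kept$umi_key[-1] != kept$umi_key[-nrow(kept)])
  kept$family <- cumsum(new_fam)
  as_tibble(kept)
}

#' Summarise read families
#'
#' @param grouped tibble from [group_families()].
#' @return tibble with one row per family: `family`, `amplicon`, `umi_key`,
#'   `size` (number of read pairs).
#' @export
family_table <- function(grouped) {
  if (nrow(grouped) == 0L) {
    return(tibble(family = integer(), amplicon = character(),
                  umi_key = character(), size = integer()))
  }
  idx <- which(c(TRUE, grouped$family[-1] != grouped$family[-nrow(grouped)]))
  tibble(family = grouped$family[idx],
         amplicon = grouped$amplicon[idx],
         umi_key = grouped$umi_key[idx],
         size = as.integer(tabulate(grouped$family)[grouped$family[idx]]))
}

#' Filter read families by size
#'
#' Families below `min_size` read pairs cannot support a consensus in which
#' a majority outvotes a single error, and are removed before consensus
#' building.
#'
#' @param grouped tibble from [group_families()].
#' @param min_size minimum number of read pairs per family (default 3, the
#'   smallest size with majority semantics).
#' @return the filtered tibble; the number of families removed is attached
#'   as attribute `"discarded_families"` and the number of read pairs removed
#'   as `"discarded_pairs"`.
#' @export
filter_families <- function(grouped, min_size = 3) {
  if (min_size < 1) abort("min_size must be >= 1")
  if (nrow(grouped) == 0L) {
    attr(grouped, "discarded_families") <- 0L
    attr(grouped, "discarded_pairs") <- 0L
    return(grouped)
  }
  sizes <- tabulate(grouped$family)
  keep <- sizes[grouped$family] >= min_size
  out <- grouped[keep, , drop = FALSE]
  attr(out, "discarded_families") <- sum(sizes >= 1L & sizes < min_size)
  attr(out, "discarded_pairs") <- sum(!keep)
  out
}

#' Family-size histogram
#'
#' @param grouped tibble from [group_families()].
#' @return tibble with columns `size` and `n_families`.
#' @export
family_size_histogram <- function(grouped) {
  ft <- family_table(grouped)
  if (nrow(ft) == 0L) return(tibble(size = integer(), n_families = integer()))
  tb <- table(ft$size)
  tibble(size = as.integer(names(tb)), n_families = as.integer(tb))
}

#' Directional collapse of molecular indexes
#'
#' Optional salvage of index sequencing errors: within each amplicon, a
#' family whose index is within `max_mismatch` mismatches of a family with at
#' least `ratio` times as many read pairs is merged into that neighbour
#' (largest neighbour wins; processed in decreasing size order). Off by
#' default in the pipeline; exact index matching is the baseline behaviour.
#'
#' @param grouped tibble from [group_families()].
#' @param ratio minimum size ratio of absorber to absorbed.
#' @param max_mismatch maximum mismatches between indexes (1 supported).
#' @return a regrouped tibble in the format of [group_families()].
#' @export
collapse_indexes <- function(grouped, ratio = 10, max_mismatch = 1) {
  if (max_mismatch != 1L) abort("only max_mismatch = 1 is supported")
  if (nrow(grouped) == 0L) return(grouped)
  ft <- family_table(grouped)
  remap <- setNames(ft$umi_key, paste0(ft$amplicon, "\r", ft$umi_key))
  neighbours1 <- function(key) {
    L <- nchar(key)
    pos <- rep(seq_len(L), each = 3L)
    alt <- unlist(lapply(strsplit(key, "")[[1]],
                         function(b) setdiff(c("A", "C", "G", "T"), b)),
                  use.names = FALSE)
    out <- rep(key, length(pos))
    substr(out, pos, pos) <- alt
    out
  }
  for (amp in unique(ft$amplicon)) {
    sub <- ft[ft$amplicon == amp, , drop = FALSE]
    sub <- sub[radix_order(-sub$size, sub$umi_key), , drop = FALSE]
    size_of <- setNames(sub$size, sub$umi_key)
    canon <- setNames(sub$umi_key, sub$umi_key)
    for (i in seq_len(nrow(sub))) {
      key <- sub$umi_key[i]
      if (canon[[key]] != key) next
      nb <- neighbours1(key)
      nb <- nb[nb %in% names(size_of)]
      nb <- nb[size_of[nb] >= ratio * size_of[[key]]]
      if (length(nb) > 0L) {
        # absorb into the largest qualifying neighbour (ties: smallest key)
        o <- radix_order(-size_of[nb], nb)
        target <- canon[[nb[o[1]]]]
        canon[names(canon)[canon == key]] <- target
      }
    }
    remap[paste0(amp, "\r", names(canon))] <- unname(canon)
  }
  out <- grouped
  out$umi_key <- unname(remap[paste0(out$amplicon, "\r", out$umi_key)])
  group_families(out)
}
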