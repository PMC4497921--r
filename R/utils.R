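#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `A`, `C`, `G`, `T`; any other character
#' becomes `N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGTA"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

#' Random DNA sequences
#'
#' @param n number of sequences.
#' @param length sequence length.
#' @param gc GC content.
#' @return character vector of `n` sequences.
#' @export
random_dna <- function(n, length, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  m <- matrix(sample(names(p), n * length, replace = TRUE, prob = p),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

is_dna <- function(x) {
  grepl("^[ACGT]+$", x)
}

# locale-independent ordering for reproducible outputs
radix_order <- function(...) {
  order(..., method = "radix")
}

#' Classify a target as SNV, deletion or insertion
#'
#' Alleles follow VCF anchoring: a deletion has `nchar(ref) > nchar(alt)`,
#' an insertion the reverse, and an SNV has both of length 1.
#'
#' @param ref,alt reference and alternate allele strings.
#' @return character vector in `c("snv", "del", "ins", "mnv")`.
#' @export
variant_type <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "snv",
    nchar(ref) > nchar(alt) ~ "del",
    nchar(alt) > nchar(ref) ~ "ins",
    TRUE ~ "mnv"
  )
}

# "T to G", "del G", "ins AC" style labels from anchored alleles
mut_label <- function(ref, alt) {
  type <- variant_type(ref, alt)
  out <- character(length(ref))
  out[type == "snv"] <- paste(ref[type == "snv"], "to", alt[type == "snv"])
  out[type == "del"] <- paste("del", substr(ref[type == "del"],
                                            nchar(alt[type == "del"]) + 1L,
                                            nchar(ref[type == "del"])))
  out[type == "ins"] <- paste("ins", substr(alt[type == "ins"],
                                            nchar(ref[type == "ins"]) + 1L,
                                            nchar(alt[type == "ins"])))
  out[type == "mnv"] <- paste(ref[type == "mnv"], "to", alt[type == "mnv"])
  out
}
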