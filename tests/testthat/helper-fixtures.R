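# Deterministic toy fixtures built in code.

# amplicon table from named sequences, spaced out on one contig
toy_amplicons <- function(seqs, contig = "chr1", gap = 50L) {
  starts <- integer(length(seqs))
  pos <- 101L
  for (i in seq_along(seqs)) {
    starts[i] <- pos
    pos <- pos + nchar(seqs[i]) + gap
  }
  tibble::tibble(
    name = names(seqs),
    contig = contig,
    start = starts,
    end = starts + nchar(seqs) - 1L,
    sequence = unname(seqs)
  )
}

# read pair for one molecule: each mate = index + template part read inward
# from its end; tmpl_len defaults to the full template so toy reads cover it
toy_pair <- function(template, u1 = strrep("A", 16), u2 = strrep("C", 16),
                     fwd = TRUE, tmpl_len = nchar(template), qchar = "I",
                     name = "r1") {
  left <- substr(template, 1L, tmpl_len)
  right <- substr(umiecs::revcomp(template), 1L, tmpl_len)
  s1 <- if (fwd) paste0(u1, left) else paste0(u2, right)
  s2 <- if (fwd) paste0(u2, right) else paste0(u1, left)
  tibble::tibble(name = name, seq1 = s1, qual1 = strrep(qchar, nchar(s1)),
                 seq2 = s2, qual2 = strrep(qchar, nchar(s2)))
}

# n identical read pairs for one molecule (a clean read family)
toy_family <- function(template, n, u1 = strrep("A", 16),
                       u2 = strrep("C", 16), fwd = NULL,
                       tmpl_len = nchar(template), name_prefix = "fam") {
  if (is.null(fwd)) fwd <- rep(TRUE, n)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    toy_pair(template, u1, u2, fwd = fwd[i], tmpl_len = tmpl_len,
             name = paste0(name_prefix, ":", i))
  }))
}

# run extraction + assignment + grouping on a pair tibble
toy_grouped <- function(pairs, amplicons, index_length = 16,
                        min_insert = 10) {
  tagged <- umiecs::extract_index(pairs, index_length, min_insert)
  tagged <- umiecs::assign_amplicon(tagged, amplicons)
  umiecs::group_families(tagged)
}

# a fixed 60 bp amplicon used across tests (all four bases, no repeats at
# the anchor ends)
fixture_amp <- function() {
  seq <- paste0("ACGTTGCAGGTCAGATCCGA", "TTGACGCATGACCGTTAGCA",
                "GGATCCGTTACAGCTAAGTC")
  toy_amplicons(c(ampA = seq))
}

# targets tibble built directly (already anchored/validated form)
toy_target <- function(amplicons, offset, ref, alt, label = "t1",
                       amp = 1L) {
  tibble::tibble(
    label = label, contig = amplicons$contig[amp],
    position = amplicons$start[amp] + offset - 1L,
    ref = ref, alt = alt, type = umiecs::variant_type(ref, alt),
    amplicon = amplicons$name[amp], offset = as.integer(offset)
  )
}

patient_calls_path <- function() {
  system.file("extdata", "patient_calls.tsv", package = "umiecs")
}

read_patient_calls <- function() {
  readr::read_tsv(patient_calls_path(),
                  col_types = readr::cols(years_prior = "c",
                                          vaf_printed = "c"),
                  progress = FALSE)
}
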