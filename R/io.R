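#' Read amplicon reference sequences
#'
#' Amplicon sequences come from a FASTA file; genomic placement comes either
#' from FASTA headers of the form `name contig:start-end` (1-based inclusive)
#' or from a BED-like companion file with columns contig, start (0-based),
#' end, name. Amplicons on the same contig must not overlap, so every genomic
#' position maps to at most one amplicon.
#'
#' @param fasta path to a FASTA file of amplicon sequences.
#' @param bed optional path to a BED-like companion file; when given, FASTA
#'   record names are matched against its `name` column.
#' @return a tibble with columns `name`, `contig`, `start`, `end`,
#'   `sequence` (uppercase DNA), one row per amplicon.
#' @export
read_amplicons <- function(fasta, bed = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  headers <- names(seqs)
  sequence <- toupper(as.character(seqs))
  if (is.null(bed)) {
    m <- regmatches(headers,
                    regexec("^(\\S+)\\s+(\\S+):(\\d+)-(\\d+)\\s*$", headers))
    bad <- vapply(m, length, 1L) == 0L
    if (any(bad)) {
      abort(paste0("FASTA header not in 'name contig:start-end' form: ",
                   headers[which(bad)[1]],
                   " (supply a BED companion file instead)"))
    }
    amp <- tibble(
      name = vapply(m, `[`, "", 2L),
      contig = vapply(m, `[`, "", 3L),
      start = as.integer(vapply(m, `[`, "", 4L)),
      end = as.integer(vapply(m, `[`, "", 5L)),
      sequence = unname(sequence)
    )
  } else {
    bedtbl <- readr::read_tsv(bed, col_names = c("contig", "start", "end", "name"),
                              col_types = "ciic", progress = FALSE)
    nm <- sub("\\s.*$", "", headers)
    idx <- match(nm, bedtbl$name)
    if (anyNA(idx)) {
      abort(paste0("FASTA record '", nm[which(is.na(idx))[1]],
                   "' has no row in the BED companion file"))
    }
    amp <- tibble(
      name = nm,
      contig = bedtbl$contig[idx],
      start = bedtbl$start[idx] + 1L,  # BED is 0-based half-open
      end = bedtbl$end[idx],
      sequence = unname(sequence)
    )
  }
  validate_amplicons(amp)
  amp
}

#' Validate an amplicon table
#'
#' Checks the invariants assumed throughout the pipeline: coordinates are
#' 1-based inclusive and consistent with sequence length, sequences are
#' uppercase ACGT, and amplicons never overlap on a contig.
#'
#' @param amplicons a tibble as returned by [read_amplicons()].
#' @return the input, invisibly, after validation.
#' @export
validate_amplicons <- function(amplicons) {
  req <- c("name", "contig", "start", "end", "sequence")
  if (!all(req %in% names(amplicons))) {
    abort(paste("amplicon table must have columns:", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(amplicons$name)) abort("duplicate amplicon names")
  if (!all(is_dna(amplicons$sequence))) {
    abort("amplicon sequences must be uppercase ACGT")
  }
  if (!all(amplicons$end - amplicons$start + 1L == nchar(amplicons$sequence))) {
    abort("amplicon end - start + 1 must equal sequence length")
  }
  by_contig <- split(amplicons, amplicons$contig)
  for (grp in by_contig) {
    if (nrow(grp) < 2L) next
    o <- radix_order(grp$start)
    if (any(grp$start[o][-1] <= grp$end[o][-nrow(grp)])) {
      abort(paste0("overlapping amplicons on contig ", grp$contig[1]))
    }
  }
  invisible(amplicons)
}

# map genomic (contig, position) to (amplicon, offset); NA when outside all
locate_in_amplicons <- function(contig, position, amplicons) {
  idx <- rep(NA_integer_, length(contig))
  for (i in seq_along(contig)) {
    hit <- which(amplicons$contig == contig[i] &
                   amplicons$start <= position[i] &
                   amplicons$end >= position[i])
    if (length(hit) == 1L) idx[i] <- hit
  }
  tibble(amplicon = amplicons$name[idx],
         offset = position - amplicons$start[idx] + 1L,
         amp_idx = idx)
}

#' Read a targets file
#'
#' Targets are tab-separated with a header. Two dialects are accepted:
#'
#' * VCF-style: columns `contig`, `position`, `ref`, `alt`, `label`, with
#'   indels anchored on the preceding reference base (`ref = "AG"`,
#'   `alt = "A"` for a G deletion).
#' * shorthand: columns `contig`, `position`, `mut`, `label`, where `mut` is
#'   `"X to Y"`, `"del X"` or `"ins X"` and `position` is the first affected
#'   reference base. Shorthand rows are normalised to the anchored form.
#'
#' After parsing, every locus is validated against the amplicon set: the
#' position must fall inside exactly one amplicon and the reference allele
#' must match the amplicon sequence. Indels are left-normalised so that a
#' deletion inside a homopolymer has one canonical position.
#'
#' @param path targets file path.
#' @param amplicons amplicon table from [read_amplicons()].
#' @return a tibble with columns `label`, `contig`, `position`, `ref`, `alt`,
#'   `type`, `amplicon`, `offset` (1-based offset of `position` within the
#'   amplicon), in file order.
#' @export
read_targets <- function(path, amplicons) {
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) == 0L) abort("targets file is empty (no header)")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  vcf_cols <- c("contig", "position", "ref", "alt", "label")
  mut_cols <- c("contig", "position", "mut", "label")
  dialect <- if (all(vcf_cols %in% header)) "vcf"
             else if (all(mut_cols %in% header)) "mut"
             else abort(paste0("targets header must contain columns ",
                               paste(vcf_cols, collapse = "/"), " or ",
                               paste(mut_cols, collapse = "/")))
  if (length(body) == 0L) {
    return(tibble(label = character(), contig = character(),
                  position = integer(), ref = character(), alt = character(),
                  type = character(), amplicon = character(),
                  offset = integer()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  parse_error <- function(i, msg) {
    abort(sprintf("targets file line %d: %s", i + 1L, msg))
  }
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- setNames(fields[[i]][seq_along(header)], header)
    if (anyNA(f) || length(fields[[i]]) < length(header)) {
      parse_error(i, "wrong number of fields")
    }
    pos <- suppressWarnings(as.integer(gsub("[ ,]", "", f[["position"]])))
    if (is.na(pos)) parse_error(i, "position is not an integer")
    if (pos < 1L) parse_error(i, "position must be >= 1 (1-based coordinates)")
    if (dialect == "vcf") {
      ref <- toupper(f[["ref"]]); alt <- toupper(f[["alt"]])
      if (!is_dna(ref)) parse_error(i, "ref allele must be non-empty ACGT")
      if (!is_dna(alt)) {
        parse_error(i, "alt allele must be non-empty ACGT (anchor deletions per VCF)")
      }
    } else {
      mut <- trimws(f[["mut"]])
      if (grepl("^[ACGTacgt] to [ACGTacgt]$", mut)) {
        ref <- toupper(substr(mut, 1L, 1L))
        alt <- toupper(substr(mut, nchar(mut), nchar(mut)))
      } else if (grepl("^del [ACGTacgt]+$", mut)) {
        if (pos < 2L) parse_error(i, "deletion needs an anchor base before it")
        ref <- toupper(sub("^del ", "", mut))  # deleted bases; anchored below
        alt <- ""
        attr(ref, "needs_anchor") <- TRUE
      } else if (grepl("^ins [ACGTacgt]+$", mut)) {
        ref <- ""
        alt <- toupper(sub("^ins ", "", mut))
        attr(alt, "needs_anchor") <- TRUE
      } else {
        parse_error(i, paste0("cannot parse mut '", mut,
                              "' (expected 'X to Y', 'del X' or 'ins X')"))
      }
    }
    rows[[i]] <- list(label = f[["label"]], contig = f[["contig"]],
                      position = pos, ref = ref, alt = alt, line = i + 1L)
  }
  out <- purrr::map_dfr(rows, function(r) {
    pos <- r$position; ref <- r$ref; alt <- r$alt
    if (nchar(ref) == 0L || nchar(alt) == 0L) {
      # shorthand indel: anchor on the preceding reference base
      anchor_pos <- if (nchar(alt) == 0L) pos - 1L else pos
      loc <- locate_in_amplicons(r$contig, anchor_pos, amplicons)
      if (is.na(loc$amp_idx)) {
        abort(sprintf(
          "targets file line %d: locus %s:%d falls outside all amplicons",
          r$line, r$contig, anchor_pos))
      }
      anchor <- substr(amplicons$sequence[loc$amp_idx], loc$offset, loc$offset)
      if (nchar(alt) == 0L) { ref <- paste0(anchor, ref); alt <- anchor; pos <- anchor_pos }
      else { alt <- paste0(anchor, alt); ref <- anchor }
    }
    loc <- locate_in_amplicons(r$contig, pos, amplicons)
    if (is.na(loc$amp_idx)) {
      abort(sprintf(
        "targets file line %d: locus %s:%d falls outside all amplicons",
        r$line, r$contig, pos))
    }
    amp <- amplicons[loc$amp_idx, ]
    norm <- normalize_variant(amp$sequence, pos - amp$start + 1L, ref, alt)
    pos <- amp$start + norm$offset - 1L
    ref <- norm$ref; alt <- norm$alt
    if (ref == alt) {
      abort(sprintf("targets file line %d: ref and alt alleles are identical",
                    r$line))
    }
    ref_obs <- substr(amp$sequence, norm$offset,
                      norm$offset + nchar(ref) - 1L)
    if (ref_obs != ref) {
      abort(sprintf(
        "targets file line %d: ref allele %s does not match amplicon %s (%s at %s:%d)",
        r$line, ref, amp$name, ref_obs, r$contig, pos))
    }
    if (pos + nchar(ref) - 1L > amp$end) {
      abort(sprintf("targets file line %d: ref allele runs past amplicon end",
                    r$line))
    }
    tibble(label = r$label, contig = r$contig, position = pos,
           ref = ref, alt = alt, type = variant_type(ref, alt),
           amplicon = amp$name, offset = norm$offset)
  })
  out
}

#' Left-normalise a variant within an amplicon
#'
#' Shifts an anchored indel to its leftmost equivalent placement (shared
#' trailing bases are traded for preceding reference bases) and trims shared
#' leading bases down to a single anchor, the standard VCF normalisation.
#' SNVs pass through unchanged.
#'
#' @param sequence amplicon sequence.
#' @param offset 1-based offset of the first reference base of `ref`.
#' @param ref,alt anchored alleles.
#' @return list with elements `offset`, `ref`, `alt`.
#' @export
normalize_variant <- function(sequence, offset, ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    return(list(offset = offset, ref = ref, alt = alt))
  }
  last_ch <- function(x) substr(x, nchar(x), nchar(x))
  repeat {
    if (nchar(ref) > 0L && nchar(alt) > 0L && last_ch(ref) == last_ch(alt)) {
      if (nchar(ref) > 1L && nchar(alt) > 1L) {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
      } else if (offset > 1L) {
        prev <- substr(sequence, offset - 1L, offset - 1L)
        ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
        alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
        offset <- offset - 1L
      } else break
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    offset <- offset + 1L
  }
  list(offset = offset, ref = ref, alt = alt)
}

#' Write a targets file
#'
#' Writes the VCF-style dialect accepted by [read_targets()]; reading the
#' result back reproduces the input loci.
#'
#' @param targets a targets tibble from [read_targets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  readr::write_tsv(targets[, c("contig", "position", "ref", "alt", "label")],
                   path, progress = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTQ
# ---------------------------------------------------------------------------

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

parse_fastq_lines <- function(lines, path) {
  n <- length(lines)
  if (n %% 4L != 0L) {
    abort(paste0("truncated FASTQ record in ", path,
                 " (line count not a multiple of 4)"))
  }
  if (n == 0L) {
    return(tibble(name = character(), seq = character(), qual = character()))
  }
  at <- seq(1L, n, by = 4L)
  hdr <- lines[at]
  if (!all(startsWith(hdr, "@"))) {
    abort(paste0("malformed FASTQ record in ", path, " (header must start with @)"))
  }
  plus <- lines[at + 2L]
  if (!all(startsWith(plus, "+"))) {
    abort(paste0("malformed FASTQ record in ", path, " (separator must start with +)"))
  }
  seq <- lines[at + 1L]
  qual <- lines[at + 3L]
  if (!all(nchar(seq) == nchar(qual))) {
    abort(paste0("malformed FASTQ record in ", path,
                 " (sequence and quality lengths differ)"))
  }
  name <- sub("[/ \t].*$", "", substring(hdr, 2L))
  tibble(name = name, seq = seq, qual = qual)
}

#' Stream read pairs from a pair of FASTQ files
#'
#' Returns a generator function that yields successive chunks of read pairs
#' as tibbles, so arbitrarily large files can be processed without loading
#' them whole. Files may be plain or gzip-compressed. Read names (before any
#' whitespace or `/1`/`/2` suffix) must match between the two files, record
#' by record.
#'
#' @param path_r1,path_r2 FASTQ paths for mate 1 and mate 2.
#' @param chunk_size number of read pairs per chunk.
#' @return a function; each call returns a tibble with columns `name`,
#'   `seq1`, `qual1`, `seq2`, `qual2`, or `NULL` once the files are
#'   exhausted.
#' @export
fastq_pair_reader <- function(path_r1, path_r2, chunk_size = 1e6) {
  con1 <- open_maybe_gz(path_r1)
  con2 <- open_maybe_gz(path_r2)
  done <- FALSE
  function() {
    if (done) return(NULL)
    l1 <- readLines(con1, n = 4L * chunk_size)
    l2 <- readLines(con2, n = 4L * chunk_size)
    if (length(l1) < 4L * chunk_size) {
      done <<- TRUE
      close(con1); close(con2)
    }
    r1 <- parse_fastq_lines(l1, path_r1)
    r2 <- parse_fastq_lines(l2, path_r2)
    if (nrow(r1) != nrow(r2)) {
      abort(sprintf("read pairing error: %s and %s differ in record count",
                    path_r1, path_r2))
    }
    if (nrow(r1) == 0L) return(NULL)
    bad <- which(r1$name != r2$name)
    if (length(bad) > 0L) {
      abort(sprintf("read pairing error: record %d names differ ('%s' vs '%s')",
                    bad[1], r1$name[bad[1]], r2$name[bad[1]]))
    }
    tibble(name = r1$name, seq1 = r1$seq, qual1 = r1$qual,
           seq2 = r2$seq, qual2 = r2$qual)
  }
}

#' Read a pair of FASTQ files completely
#'
#' Convenience wrapper around [fastq_pair_reader()] that collects all chunks.
#'
#' @inheritParams fastq_pair_reader
#' @return a tibble with columns `name`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path_r1, path_r2, chunk_size = 1e6) {
  reader <- fastq_pair_reader(path_r1, path_r2, chunk_size)
  chunks <- list()
  repeat {
    ch <- reader()
    if (is.null(ch)) break
    chunks[[length(chunks) + 1L]] <- ch
  }
  if (length(chunks) == 0L) {
    return(tibble(name = character(), seq1 = character(), qual1 = character(),
                  seq2 = character(), qual2 = character()))
  }
  dplyr::bind_rows(chunks)
}

#' Write read pairs to FASTQ files
#'
#' @param reads a tibble with columns `name`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (as produced by [read_fastq_pairs()] or [simulate_library()]).
#' @param path_r1,path_r2 output paths; a `.gz` suffix triggers gzip.
#' @return invisibly, `c(path_r1, path_r2)`.
#' @export
write_fastq_pairs <- function(reads, path_r1, path_r2) {
  write_one <- function(seq, qual, path) {
    lines <- if (nrow(reads) == 0L) character(0) else
      as.vector(rbind(paste0("@", reads$name), seq,
                      rep("+", nrow(reads)), qual))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    writeLines(lines, con)
    close(con)
  }
  write_one(reads$seq1, reads$qual1, path_r1)
  write_one(reads$seq2, reads$qual2, path_r2)
  invisible(c(path_r1, path_r2))
}

# ---------------------------------------------------------------------------
# Calls table
# ---------------------------------------------------------------------------

#' Format a variant allele fraction for reporting
#'
#' VAFs are rounded half-up to four decimal places and printed with trailing
#' zeros trimmed, so 7/199945 prints as `"0"` and 10/135861 as `"0.0001"`.
#' Undefined VAFs (no variant and no reference families) print `"NA"`.
#'
#' @param vaf numeric vector of fractions (may contain `NA`).
#' @param digits decimal places to round to.
#' @return character vector.
#' @export
#' @examples
#' format_vaf(c(7 / 199945, 10 / 135861, 2898 / (2898 + 82245), NA))
format_vaf <- function(vaf, digits = 4) {
  scale <- 10^digits
  # half-up rounding; the epsilon guards exact-boundary rationals against
  # binary representation error (e.g. 1/20000 * 1e4 landing just below 0.5)
  r <- floor(vaf * scale + 0.5 + 1e-9) / scale
  out <- format(r, scientific = FALSE, trim = TRUE)
  dec <- grepl(".", out, fixed = TRUE)
  out[dec] <- sub("\\.?0+$", "", out[dec])
  out[is.na(vaf)] <- "NA"
  out
}

#' Write the per-target calls table
#'
#' Tab-separated table with one row per queried locus: `label`, `contig`,
#' `position`, `mut`, `variant_RFs`, `reference_RFs`, `VAF`, where VAF is
#' formatted by [format_vaf()]. Loci with no variant and no reference
#' families print `NA` for VAF to distinguish absent coverage from an
#' observed VAF of zero.
#'
#' @param allele_counts tibble from [count_alleles()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_table <- function(allele_counts, path) {
  out <- tibble(
    label = allele_counts$label,
    contig = allele_counts$contig,
    position = allele_counts$position,
    mut = mut_label(allele_counts$ref, allele_counts$alt),
    variant_RFs = allele_counts$variant_rfs,
    reference_RFs = allele_counts$reference_rfs,
    VAF = format_vaf(allele_counts$vaf)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
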