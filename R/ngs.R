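# Raw FASTQ -> per-sample variant count tables: quality filter, barcode
# demultiplexing, constant-region trimming at a maximum error rate, frame +1
# translation, exact-sequence counting.

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (Phred+33)
#' @return data.frame of class `fc_reads`: `id`, `seq`, `qual`
#' @export
read_fastq <- function(path) {
  # readQualityScaledDNAStringSet warns about dropping FASTQ metadata
  # columns it never uses; that is expected here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  out <- data.frame(id = names(x), seq = as.character(x),
                    qual = as.character(Biostrings::quality(x)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fc_reads", "data.frame")
  out
}

#' Write a read table to FASTQ
#'
#' @param reads an `fc_reads` data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual)
  )
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Filter reads on mean quality and ambiguous-base count
#'
#' A read is kept iff its mean Phred quality is at least `min_mean_q` and it
#' contains at most `max_n` N bases (the spirit of fastp's default
#' filtering).
#'
#' @param reads an `fc_reads` data.frame
#' @param min_mean_q minimum mean Phred score (default 15)
#' @param max_n maximum N count (default 5)
#' @return the kept reads, with attribute `n_rejected`
#' @export
quality_filter <- function(reads, min_mean_q = 15, max_n = 5) {
  if (nrow(reads) == 0L) {
    attr(reads, "n_rejected") <- 0L
    return(reads)
  }
  nc <- nchar(reads$qual)
  ints <- utf8ToInt(paste(reads$qual, collapse = "")) - 33L
  grp <- rep.int(seq_len(nrow(reads)), nc)
  meanq <- as.vector(rowsum(ints, grp)) / nc
  n_count <- nchar(reads$seq) - nchar(gsub("N", "", reads$seq, fixed = TRUE))
  keep <- meanq >= min_mean_q & n_count <= max_n
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!keep)
  class(out) <- c("fc_reads", "data.frame")
  out
}

#' Assign reads to samples by barcode prefix
#'
#' Each read is assigned to the unique sample whose forward barcode matches
#' the read prefix with at most `max_mismatch` substitutions; reads matching
#' no barcode or more than one go to the unassigned bin.
#'
#' @param reads an `fc_reads` data.frame
#' @param barcode_table data.frame with columns `sample` and `barcode`
#' @param max_mismatch allowed substitutions in the barcode (default 0)
#' @return named list of `fc_reads` (one per sample) plus `unassigned`
#' @export
demultiplex <- function(reads, barcode_table, max_mismatch = 0L) {
  stopifnot(is.data.frame(barcode_table),
            all(c("sample", "barcode") %in% names(barcode_table)))
  bcs <- toupper(barcode_table$barcode)
  if (anyDuplicated(barcode_table$sample)) stop("duplicated sample names")
  # prefix-uniqueness at the mismatch radius: a barcode reachable from
  # another by <= max_mismatch substitutions cannot be told apart at all
  # (reads merely *near* two barcodes are handled by the unassigned bin)
  for (i in seq_along(bcs)) for (j in seq_len(i - 1L)) {
    n <- min(nchar(bcs[i]), nchar(bcs[j]))
    d <- hamming_to(substr(bcs[i], 1L, n), substr(bcs[j], 1L, n))
    if (d <= max_mismatch)
      stop("barcode collision at mismatch radius ", max_mismatch, ": ",
           bcs[i], " vs ", bcs[j])
  }
  n_reads <- nrow(reads)
  mism <- vapply(bcs, function(b)
    hamming_to(substr(reads$seq, 1L, nchar(b)), b), numeric(n_reads))
  mism <- matrix(mism, nrow = n_reads)
  hits <- mism <= max_mismatch
  n_hits <- rowSums(hits)
  assign_to <- ifelse(n_hits == 1L, max.col(hits, ties.method = "first"), NA)
  out <- lapply(seq_along(bcs), function(k) {
    r <- reads[!is.na(assign_to) & assign_to == k, , drop = FALSE]
    rownames(r) <- NULL
    class(r) <- c("fc_reads", "data.frame")
    r
  })
  names(out) <- barcode_table$sample
  un <- reads[is.na(assign_to), , drop = FALSE]
  rownames(un) <- NULL
  class(un) <- c("fc_reads", "data.frame")
  out$unassigned <- un
  out
}

# Locate `pattern` in each unique sequence with at most `budget` mismatches
# (substitutions only), preferring windows with fewer mismatches;
# `side = "left"` takes the leftmost such window, `side = "right"` the
# rightmost. Returns the start position or NA.
locate_flank <- function(seqs, pattern, budget, side = c("left", "right")) {
  side <- match.arg(side)
  start <- rep(NA_integer_, length(seqs))
  plen <- nchar(pattern)
  feasible <- nchar(seqs) >= plen
  unresolved <- which(feasible)
  for (k in 0:budget) {
    if (length(unresolved) == 0L) break
    m <- Biostrings::vmatchPattern(pattern,
                                   Biostrings::DNAStringSet(seqs[unresolved]),
                                   max.mismatch = k, with.indels = FALSE,
                                   fixed = TRUE)
    st <- Biostrings::startIndex(m)
    found <- lengths(st) > 0L
    if (any(found)) {
      pick <- vapply(st[found], if (side == "left") min else max, 1L)
      start[unresolved[found]] <- pick
      unresolved <- unresolved[!found]
    }
  }
  start
}

#' Trim constant flanking regions from reads
#'
#' Locates the upstream flank as the window minimising Hamming mismatches
#' (leftmost on ties) with at most `floor(max_error_rate * flank length)`
#' mismatches, then the downstream flank likewise (rightmost on ties) in the
#' remainder of the read, and returns the enclosed variable region. Reads in
#' which either flank is not found within tolerance, or whose enclosed
#' region is empty, are rejected (`NA`).
#'
#' @param seqs character vector of read sequences (any leading barcode may be
#'   left in place; the flank search scans the whole read)
#' @param up_flank,down_flank constant sequences bounding the variable region
#' @param max_error_rate maximum per-flank mismatch rate (default 0.1)
#' @return character vector of variable regions, `NA` where rejected
#' @export
trim_flanks <- function(seqs, up_flank, down_flank, max_error_rate = 0.1) {
  stopifnot(nzchar(up_flank), nzchar(down_flank))
  if (length(seqs) == 0L) return(character(0))
  up_flank <- toupper(up_flank); down_flank <- toupper(down_flank)
  budget_up <- floor(max_error_rate * nchar(up_flank))
  budget_dn <- floor(max_error_rate * nchar(down_flank))

  uniq <- unique(seqs)
  up_start <- locate_flank(uniq, up_flank, budget_up, side = "left")
  region <- rep(NA_character_, length(uniq))
  ok <- !is.na(up_start)
  if (any(ok)) {
    var_from <- up_start[ok] + nchar(up_flank)
    tails <- substr(uniq[ok], var_from, nchar(uniq[ok]))
    dn_start <- locate_flank(tails, down_flank, budget_dn, side = "right")
    ok2 <- !is.na(dn_start) & dn_start > 1L
    region[which(ok)[ok2]] <- substr(tails[ok2], 1L, dn_start[ok2] - 1L)
  }
  region[match(seqs, uniq)]
}

#' Translate variable regions in reading frame +1 with rejection
#'
#' Standard genetic code from base 1. Sequences whose length is not
#' divisible by 3, or that contain an internal stop codon, are rejected
#' (`NA`); the attribute `reason` records `"ok"`, `"length"` or `"stop"`
#' per sequence.
#'
#' @param dna character vector of DNA sequences
#' @return character vector of amino-acid sequences with `NA` for rejects
#'   and a `reason` attribute
#' @export
translate_frame1 <- function(dna) {
  out <- rep(NA_character_, length(dna))
  reason <- rep("ok", length(dna))
  bad_len <- is.na(dna) | nchar(dna) %% 3L != 0L | nchar(dna) == 0L
  reason[bad_len] <- "length"
  if (any(!bad_len)) {
    aa <- translate_dna(dna[!bad_len])
    has_stop <- grepl("*", aa, fixed = TRUE)
    out[!bad_len][!has_stop] <- aa[!has_stop]
    reason[which(!bad_len)[has_stop]] <- "stop"
  }
  attr(out, "reason") <- reason
  out
}

#' Count exact variant sequences in a sample
#'
#' Groups identical sequences, reporting copy numbers and within-sample
#' frequencies, sorted by copies descending (ties broken lexicographically
#' by sequence).
#'
#' @param seqs character vector of accepted sequences (DNA or amino acid)
#' @param level `"dna"` or `"aa"` (metadata recorded on the table)
#' @param sample_id sample name recorded on the table
#' @return data.frame of class `fc_counts`: `sequence`, `copies`,
#'   `frequency`; attributes `sample` and `level`
#' @export
count_variants <- function(seqs, level = c("dna", "aa"), sample_id = "sample") {
  level <- match.arg(level)
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) == 0L) stop("no sequences to count")
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab), copies = as.integer(tab),
                    frequency = as.integer(tab) / length(seqs),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$copies, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample") <- sample_id
  attr(out, "level") <- level
  class(out) <- c("fc_counts", "data.frame")
  out
}

#' Run the full read-processing chain on one demultiplexed sample
#'
#' Quality filter, flank trimming, frame +1 translation, and DNA- and
#' amino-acid-level counting, with per-reason rejection counters. The
#' conservation identity `accepted_aa + quality + flank + length + stop =
#' input reads` holds on every run.
#'
#' @param reads the sample's `fc_reads`
#' @param lib the `fc_library` (provides flanks)
#' @param sample_id sample name for the output tables
#' @param min_mean_q,max_n see [quality_filter()]
#' @param max_error_rate see [trim_flanks()]
#' @return list: `dna_table`, `aa_table` (both `fc_counts`) and `counters`
#'   (named integer vector: input, quality, flank, length, stop,
#'   accepted_dna, accepted_aa)
#' @export
process_sample <- function(reads, lib, sample_id = "sample",
                           min_mean_q = 15, max_n = 5, max_error_rate = 0.1) {
  n_input <- nrow(reads)
  kept <- quality_filter(reads, min_mean_q = min_mean_q, max_n = max_n)
  n_quality <- attr(kept, "n_rejected")
  region <- trim_flanks(kept$seq, lib$up_flank, lib$down_flank,
                        max_error_rate = max_error_rate)
  n_flank <- sum(is.na(region))
  dna_ok <- region[!is.na(region)]
  aa <- translate_frame1(dna_ok)
  reason <- attr(aa, "reason")
  n_length <- sum(reason == "length")
  n_stop <- sum(reason == "stop")
  counters <- c(input = n_input, quality = n_quality, flank = n_flank,
                length = n_length, stop = n_stop,
                accepted_dna = length(dna_ok), accepted_aa = sum(!is.na(aa)))
  list(
    dna_table = count_variants(dna_ok, "dna", sample_id),
    aa_table = count_variants(aa[!is.na(aa)], "aa", sample_id),
    counters = counters
  )
}

#' Write a count table to a delimited file
#'
#' @param table an `fc_counts` table
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_count_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
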