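# Selection analytics on count tables: enrichment scores, cumulative
# frequency curves, copy-threshold beneficial-variant calls, position
# probability matrices with sequence-logo color classes, and combination
# variants.

#' Enrichment of variants between two samples
#'
#' For each sequence in the union of two count tables, computes the
#' pseudocounted frequency ratio
#' \deqn{score = \frac{(c_{after}+\pi)/N_{after}}{(c_{before}+\pi)/N_{before}}}
#' where \eqn{\pi} is a pseudocount in read units (default 0.5), so
#' sequences absent from one table still get a finite positive score. With
#' `pseudocount = 0` on tables without zero counts this is the plain
#' frequency ratio.
#'
#' @param before,after `fc_counts` tables at the same level
#' @param pseudocount pseudocount in read-equivalents per table (default 0.5)
#' @return data.frame sorted by `score` descending (ties: copies after,
#'   then sequence): `sequence`, `copies_before`, `copies_after`,
#'   `freq_before`, `freq_after`, `score`, `log2_score`
#' @export
enrichment_table <- function(before, after, pseudocount = 0.5) {
  if (!identical(attr(before, "level"), attr(after, "level")))
    stop("count tables are at different levels (",
         attr(before, "level"), " vs ", attr(after, "level"), ")")
  stopifnot(pseudocount >= 0)
  seqs <- union(before$sequence, after$sequence)
  cb <- before$copies[match(seqs, before$sequence)]; cb[is.na(cb)] <- 0L
  ca <- after$copies[match(seqs, after$sequence)]; ca[is.na(ca)] <- 0L
  nb <- sum(before$copies); na <- sum(after$copies)
  score <- ((ca + pseudocount) / na) / ((cb + pseudocount) / nb)
  out <- data.frame(
    sequence = seqs, copies_before = cb, copies_after = ca,
    freq_before = cb / nb, freq_after = ca / na,
    score = score, log2_score = log2(score),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score, -out$copies_after, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ranked cumulative-frequency curve of a count table
#'
#' Variants are ranked by copy number (descending, ties lexicographic); the
#' cumulative frequency at rank k is the summed frequency of the top k
#' variants, reaching 1 at the last rank. Diversity loss across selection
#' shows as the curve rising faster after sorting.
#'
#' @param table an `fc_counts` table
#' @return data.frame: `rank`, `sequence`, `copies`, `cumulative_frequency`
#' @export
cumulative_curve <- function(table) {
  if (nrow(table) == 0L) stop("empty count table")
  t2 <- table[order(-table$copies, table$sequence), , drop = FALSE]
  data.frame(
    rank = seq_len(nrow(t2)), sequence = t2$sequence, copies = t2$copies,
    cumulative_frequency = cumsum(t2$frequency),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Variants above a copy-number threshold and their pooled frequency
#'
#' Identifies the variants with more than `min_copies` copies (the
#' "beneficial" calls of an enriched pool) and the fraction of all
#' sequences they jointly account for.
#'
#' @param table an `fc_counts` table
#' @param min_copies copy threshold; variants with copies strictly greater
#'   are reported (default 1000)
#' @return list: `variants` (rows of `table`) and `pooled_fraction`
#' @export
top_variants <- function(table, min_copies = 1000) {
  if (nrow(table) == 0L) stop("empty count table")
  sel <- table[table$copies > min_copies, , drop = FALSE]
  rownames(sel) <- NULL
  list(variants = sel, pooled_fraction = sum(sel$frequency))
}

#' Per-position amino-acid probability matrix (sequence-logo input)
#'
#' Copy-weighted amino-acid frequencies at each variable position, with the
#' standard logo color classes (hydrophobic G,A,V,L,I,M,P,F,Y,W; positive
#' R,K,H; negative D,E; polar uncharged C,S,T,N,Q). Sequences must all share
#' one length: either the loop length itself, or the full variable-region
#' peptide when `lib` is supplied (loop columns are then extracted through
#' the library's EU/codon map). Sequences containing letters outside the 20
#' standard amino acids are excluded and counted.
#'
#' @param table an amino-acid-level `fc_counts` table
#' @param lib optional `fc_library` for extracting loop positions from
#'   full-region peptides
#' @return object of class `fc_ppm`: list with `probs` (positions x 20
#'   matrix, rows labelled by EU number when available), `classes` (color
#'   class per amino acid) and `n_excluded`
#' @export
position_probabilities <- function(table, lib = NULL) {
  if (!identical(attr(table, "level"), "aa") && !is.null(attr(table, "level")))
    stop("position probabilities require an amino-acid-level table")
  lens <- unique(nchar(table$sequence))
  if (length(lens) != 1L)
    stop("sequences must all have the same length")
  seqs <- table$sequence
  copies <- table$copies
  labels <- as.character(seq_len(lens))
  if (!is.null(lib)) {
    n_loop <- nrow(lib$positions)
    n_pep <- nchar(lib$ref_dna) / 3L
    if (lens == n_pep && lens != n_loop) {
      idx <- lib$positions$codon_index
      seqs <- vapply(strsplit(seqs, "", fixed = TRUE),
                     function(ch) paste0(ch[idx], collapse = ""), "")
      lens <- n_loop
    } else if (lens != n_loop) {
      stop("sequence length matches neither the loop nor the variable region")
    }
    labels <- as.character(lib$positions$eu)
  }
  standard <- !grepl(paste0("[^", paste0(AA20, collapse = ""), "]"), seqs)
  n_excluded <- sum(copies[!standard])
  seqs <- seqs[standard]; copies <- copies[standard]
  if (length(seqs) == 0L) stop("no sequences over the standard amino acids")
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), ncol = lens, byrow = TRUE)
  probs <- vapply(seq_len(lens), function(p) {
    cnt <- tapply(copies, factor(mat[, p], levels = AA20), sum)
    cnt[is.na(cnt)] <- 0
    as.numeric(cnt / sum(cnt))
  }, numeric(length(AA20)))
  probs <- t(probs)
  colnames(probs) <- AA20
  rownames(probs) <- labels[seq_len(lens)]
  structure(list(probs = probs, classes = AA_CLASS, n_excluded = n_excluded),
            class = "fc_ppm")
}

#' @export
print.fc_ppm <- function(x, ...) {
  cat("fc_ppm:", nrow(x$probs), "positions x 20 amino acids\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' Bar-style sequence logo of a probability matrix
#'
#' Stacked per-position probability bars, colored by amino-acid class
#' (orange hydrophobic, red positive, green negative, blue polar uncharged).
#'
#' @param x an `fc_ppm`
#' @param ... passed to [graphics::barplot()]
#' @return invisibly, the bar midpoints
#' @export
plot.fc_ppm <- function(x, ...) {
  cls_col <- c(hydrophobic = "orange", positive = "red",
               negative = "green3", `polar-uncharged` = "blue")
  cols <- cls_col[x$classes[colnames(x$probs)]]
  mids <- graphics::barplot(t(x$probs), col = cols, border = NA,
                            xlab = "position", ylab = "probability", ...)
  invisible(mids)
}

#' Combine two sets of variant specs
#'
#' Cartesian combination of substitution lists (e.g. combining a lead single
#' mutant with double-mutant partners). Pairs that assign different target
#' residues to the same position conflict and are excluded (reported in the
#' `conflicts` attribute); a substitution shared by both parents is kept
#' once.
#'
#' @param a,b character vectors of variant display strings
#' @return character vector of combined display strings, with attribute
#'   `conflicts` (data.frame of the excluded pairs)
#' @export
combine_mutations <- function(a, b) {
  grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
  out <- character(0)
  conflicts <- grid[0, , drop = FALSE]
  for (i in seq_len(nrow(grid))) {
    sa <- parse_variant_spec(grid$a[i])
    sb <- parse_variant_spec(grid$b[i])
    merged <- rbind(sa, sb)
    merged <- merged[!duplicated(merged), , drop = FALSE]
    if (anyDuplicated(merged$eu)) {
      conflicts <- rbind(conflicts, grid[i, , drop = FALSE])
    } else {
      out <- c(out, format_variant_spec(merged))
    }
  }
  out <- unique(out)
  rownames(conflicts) <- NULL
  attr(out, "conflicts") <- conflicts
  out
}
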