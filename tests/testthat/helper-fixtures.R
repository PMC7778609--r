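# Fixtures built in code: small libraries, synthetic PDB files, and
# independent brute-force oracles used across test files.

# Two-position library over "EPK" (diversify codons 1 and 3).
tiny_library <- function() {
  fc_library(
    name = "tiny",
    positions = data.frame(eu = c(268L, 270L), wt_aa = c("E", "K"),
                           codon_index = c(1L, 3L)),
    ref_dna = "GAGCCCAAA",
    up_flank = "ACGTACGTAC", down_flank = "GGCCGGCCGG",
    barcode_fwd = "AAGG"
  )
}

# Six-position CH2-loop library used by the simulator tests.
loop_library <- function() {
  read_library_config(system.file("extdata", "example_library.yaml",
                                  package = "fcsortseq"))
}

# Eight-position library: variant space > 1e4, for distribution tests.
wide_library <- function() {
  fc_library(
    name = "wide",
    positions = data.frame(eu = 296:303,
                           wt_aa = c("Y", "N", "S", "T", "Y", "R", "V", "V"),
                           codon_index = 1:8),
    ref_dna = "TACAACAGCACCTACCGGGTGGTG",
    up_flank = "ACCTGCGTGGTG", down_flank = "AAGTTCAACTGG",
    barcode_fwd = "CCTTAA"
  )
}

# Write a synthetic PDB file from an atom table (chain, resno, resid, name,
# x, y, z, and optionally altloc/occ/element).
write_synthetic_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  n <- nrow(atoms)
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$element)) atoms$element <- substr(atoms$name, 1L, 1L)
  lines <- vapply(seq_len(n), function(i) {
    paste0(
      "ATOM  ", sprintf("%5d", i), " ",
      sprintf(" %-3s", atoms$name[i]),
      sprintf("%1s", substr(paste0(atoms$altloc[i], " "), 1L, 1L)),
      sprintf("%3s", atoms$resid[i]), " ",
      atoms$chain[i], sprintf("%4d", atoms$resno[i]), "    ",
      sprintf("%8.3f%8.3f%8.3f", atoms$x[i], atoms$y[i], atoms$z[i]),
      sprintf("%6.2f", atoms$occ[i]), sprintf("%6.2f", 0),
      "          ", sprintf("%2s", atoms$element[i])
    )
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

# Random 30-residue two-chain complex with a handful of genuine contacts.
random_complex_atoms <- function(seed = 42L) {
  set.seed(seed)
  res <- data.frame(
    chain = rep(c("A", "B"), c(20L, 10L)),
    resno = c(1:20, 1:10),
    resid = "GLY", stringsAsFactors = FALSE
  )
  # chain A spread over a 25 A box, chain B shifted so some atoms approach A
  atoms <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
    base <- if (res$chain[i] == "A") c(0, 0, 0) else c(12, 0, 0)
    k <- sample(1:3, 1L)
    data.frame(
      chain = res$chain[i], resno = res$resno[i], resid = res$resid[i],
      name = c("CA", "CB", "CG")[seq_len(k)],
      # 3 decimals: lossless through the fixed-column PDB coordinate fields
      x = round(base[1L] + runif(k, 0, 25), 3L),
      y = round(base[2L] + runif(k, 0, 25), 3L),
      z = round(base[3L] + runif(k, 0, 25), 3L), stringsAsFactors = FALSE
    )
  }))
  atoms
}

# O(N^2) brute-force contact oracle over an atom table.
oracle_interface <- function(atoms, query_chains, partner_chains, cutoff) {
  q <- atoms[atoms$chain %in% query_chains, ]
  p <- atoms[atoms$chain %in% partner_chains, ]
  keys <- unique(paste(q$chain, q$resno))
  out <- lapply(keys, function(k) {
    qa <- q[paste(q$chain, q$resno) == k, ]
    dmin <- Inf
    for (i in seq_len(nrow(qa))) for (j in seq_len(nrow(p))) {
      d <- sqrt((qa$x[i] - p$x[j])^2 + (qa$y[i] - p$y[j])^2 +
                  (qa$z[i] - p$z[j])^2)
      if (d < dmin) dmin <- d
    }
    data.frame(chain = qa$chain[1L], resno = qa$resno[1L], dmin = dmin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$dmin <= cutoff, ]
  out[order(out$chain, out$resno), ]
}

# Exhaustive per-read Hamming demultiplexer (the oracle for demultiplex()).
oracle_demux <- function(seqs, barcodes, max_mismatch) {
  vapply(seqs, function(s) {
    d <- vapply(barcodes, function(b) {
      pre <- substr(s, 1L, nchar(b))
      sum(strsplit(pre, "")[[1L]] != strsplit(b, "")[[1L]])
    }, 0)
    hit <- which(d <= max_mismatch)
    if (length(hit) == 1L) hit else NA_integer_
  }, 1L, USE.NAMES = FALSE)
}

# fc_reads constructor for hand-built tests.
make_reads <- function(seqs, quals = NULL, phred = 30L) {
  if (is.null(quals)) quals <- strrep(intToUtf8(phred + 33L), nchar(seqs))
  r <- data.frame(id = sprintf("r%04d", seq_along(seqs)), seq = seqs,
                  qual = quals, stringsAsFactors = FALSE)
  class(r) <- c("fc_reads", "data.frame")
  r
}
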