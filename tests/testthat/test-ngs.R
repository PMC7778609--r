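test_that("quality filtering applies the per-read mean-Q and N rules", {
  q30 <- strrep(intToUtf8(30L + 33L), 9L)
  q2 <- strrep(intToUtf8(2L + 33L), 9L)
  reads <- make_reads(c("ACGTACGTA", "ACGTACGTA", "ACGNNNNNN"),
                      quals = c(q30, q2, q30))
  kept <- quality_filter(reads, min_mean_q = 15, max_n = 5)
  expect_equal(kept$id, "r0001")  # q2 fails quality, 6 Ns fail max_n
  expect_equal(attr(kept, "n_rejected"), 2L)

  # mixed random set agrees with a per-read recomputation oracle
  set.seed(1)
  n <- 200L
  seqs <- vapply(1:n, function(i)
    paste0(sample(c("A", "C", "G", "T", "N"), 30, replace = TRUE,
                  prob = c(.23, .23, .23, .23, .08)), collapse = ""), "")
  quals <- vapply(1:n, function(i)
    intToUtf8(sample(2:40, 30, replace = TRUE) + 33L), "")
  reads <- make_reads(seqs, quals)
  kept <- quality_filter(reads)
  oracle <- vapply(1:n, function(i) {
    mq <- mean(utf8ToInt(quals[i]) - 33L)
    nn <- sum(strsplit(seqs[i], "")[[1L]] == "N")
    mq >= 15 && nn <= 5
  }, TRUE)
  expect_identical(kept$id, reads$id[oracle])
})

test_that("demultiplexing matches the exhaustive Hamming oracle on 1e4 simulated reads", {
  set.seed(2)
  barcodes <- c("AAGGCC", "TTCCGG", "CATGCA")
  n <- 10000L
  pick <- sample(1:4, n, replace = TRUE)  # 4 = junk prefix
  prefix <- character(n)
  for (i in 1:n) {
    if (pick[i] <= 3) {
      b <- strsplit(barcodes[pick[i]], "")[[1L]]
      nmut <- sample(0:2, 1L, prob = c(.7, .2, .1))
      if (nmut > 0) {
        at <- sample(6L, nmut)
        b[at] <- vapply(b[at], function(x)
          sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
      }
      prefix[i] <- paste0(b, collapse = "")
    } else {
      prefix[i] <- paste0(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                          collapse = "")
    }
  }
  seqs <- paste0(prefix, strrep("ACGT", 5))
  reads <- make_reads(seqs)
  tab <- data.frame(sample = c("s1", "s2", "s3"), barcode = barcodes)
  for (mm in 0:1) {
    got <- demultiplex(reads, tab, max_mismatch = mm)
    want <- oracle_demux(seqs, barcodes, mm)
    for (k in 1:3)
      expect_identical(got[[paste0("s", k)]]$id,
                       reads$id[!is.na(want) & want == k])
    expect_identical(got$unassigned$id, reads$id[is.na(want)])
    # conservation: every read lands in exactly one bin
    expect_equal(sum(vapply(got, nrow, 0L)), n)
  }
})

test_that("ambiguous and colliding barcodes are handled per the radius rules", {
  # AAGC is one substitution from both AAGG and AACC: ambiguous at radius 1
  reads <- make_reads(c("AAGGTTTTTTTT", "AAGCTTTTTTTT"))
  tab <- data.frame(sample = c("x", "y"), barcode = c("AAGG", "AACC"))
  got1 <- demultiplex(reads, tab, max_mismatch = 1L)
  expect_equal(got1$x$id, "r0001")
  expect_equal(got1$unassigned$id, "r0002")
  got0 <- demultiplex(reads, tab, max_mismatch = 0L)
  expect_equal(got0$x$id, "r0001")
  expect_equal(nrow(got0$unassigned), 1L)
  # barcodes within the radius of each other are a configuration error
  bad <- data.frame(sample = c("x", "y"), barcode = c("AAGG", "AAGC"))
  expect_error(demultiplex(reads, bad, max_mismatch = 1L), "collision")
})

test_that("flank trimming finds minimum-mismatch windows within the error budget", {
  up <- "ACGTACGTAC"; down <- "GGCCGGCCGG"
  region <- "GAGCCCAAA"
  exact <- paste0("TT", up, region, down, "AA")
  expect_equal(trim_flanks(exact, up, down), region)

  # one substitution in a 10-base flank is within rate 0.1; two are not
  up1 <- up; substr(up1, 3, 3) <- "T"
  expect_equal(trim_flanks(paste0(up1, region, down), up, down), region)
  up2 <- up1; substr(up2, 7, 7) <- "A"
  expect_true(is.na(trim_flanks(paste0(up2, region, down), up, down)))

  # empty enclosed region rejects
  expect_true(is.na(trim_flanks(paste0(up, down), up, down)))
  # vectorised over a mixed set
  out <- trim_flanks(c(exact, paste0(up2, region, down)), up, down)
  expect_identical(is.na(out), c(FALSE, TRUE))
})

test_that("frame +1 translation applies the genetic code and rejection rules", {
  out <- translate_frame1(c("GAGCCCAAA", "GAGCC", "TAAGAG", "GAGTAG"))
  expect_identical(unclass(out)[1:4],
                   c("EPK", NA_character_, NA_character_, NA_character_))
  expect_identical(attr(out, "reason"), c("ok", "length", "stop", "stop"))
})

test_that("variant counting groups exactly with deterministic ordering", {
  tab <- count_variants(c("E", "E", "K"), level = "aa", sample_id = "s")
  expect_equal(tab$sequence, c("E", "K"))
  expect_equal(tab$copies, c(2L, 1L))
  expect_equal(tab$frequency, c(2 / 3, 1 / 3))
  expect_equal(sum(tab$frequency), 1)

  one <- count_variants("ACG", level = "dna")
  expect_equal(one$frequency, 1)
  expect_error(count_variants(character(0), "dna"), "no sequences")

  # ties in copies break lexicographically
  t2 <- count_variants(c("B", "A", "C", "A", "C"), level = "aa")
  expect_equal(t2$sequence, c("A", "C", "B"))
})

test_that("the amino-acid table marginalises the DNA table (regrouping oracle)", {
  lib <- loop_library()
  camp <- run_campaign(lib, 50, n_rounds = 1, cells_assayed = 5e4,
                       expansion = 5e4, reads_per_sample = 2e4,
                       error_rate = 0.005, sequence_rounds = 0L, seed = 14)
  s <- process_sample(camp$reads$round0, lib, "r0")
  # oracle: translate each DNA row, drop rejects, regroup copies
  aa <- translate_frame1(s$dna_table$sequence)
  keep <- !is.na(aa)
  agg <- tapply(s$dna_table$copies[keep], unclass(aa)[keep], sum)
  oracle <- data.frame(sequence = names(agg), copies = as.integer(agg),
                       stringsAsFactors = FALSE)
  oracle <- oracle[order(-oracle$copies, oracle$sequence), ]
  expect_equal(s$aa_table$sequence, oracle$sequence)
  expect_equal(s$aa_table$copies, oracle$copies)
  expect_equal(sum(s$aa_table$frequency), 1, tolerance = 1e-9)
})

test_that("read accounting is conserved through the pipeline and error-free reads count exactly", {
  lib <- loop_library()
  camp <- run_campaign(lib, 40, n_rounds = 1, cells_assayed = 5e4,
                       expansion = 5e4, reads_per_sample = 1e4,
                       error_rate = 0.002, sequence_rounds = 0L, seed = 8)
  s <- process_sample(camp$reads$round0, lib, "r0")
  ct <- s$counters
  expect_equal(ct[["input"]],
               ct[["quality"]] + ct[["flank"]] + ct[["length"]] +
                 ct[["stop"]] + ct[["accepted_aa"]])
  expect_equal(ct[["accepted_dna"]],
               ct[["input"]] - ct[["quality"]] - ct[["flank"]])

  # with no sequencing errors the DNA table equals the template tally
  clean <- run_campaign(lib, 40, n_rounds = 1, cells_assayed = 5e4,
                        expansion = 5e4, reads_per_sample = 1e4,
                        error_rate = 0, sequence_rounds = 0L, seed = 8)
  s0 <- process_sample(clean$reads$round0, lib, "r0")
  bc_up <- nchar(lib$barcode_fwd) + nchar(lib$up_flank)
  dna_len <- nchar(lib$ref_dna)
  tmpl <- substr(clean$reads$round0$seq, bc_up + 1L, bc_up + dna_len)
  tally <- table(tmpl)
  expect_equal(s0$counters[["accepted_dna"]], nrow(clean$reads$round0))
  got <- setNames(s0$dna_table$copies, s0$dna_table$sequence)
  expect_equal(got[names(tally)], setNames(as.integer(tally), names(tally)))
})

test_that("FASTQ writing and reading round-trip read tables", {
  reads <- make_reads(c("ACGTACGTAA", "TTGGCCAATT"))
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$qual, reads$qual)
  expect_equal(back$id, reads$id)
})
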