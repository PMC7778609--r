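test_that("library simulation is reproducible and respects the KD range", {
  lib <- loop_library()
  a <- simulate_library(lib, 25, seed = 5)
  b <- simulate_library(lib, 25, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, simulate_library(lib, 25, seed = 6)))

  v <- simulate_library(lib, 500, kd_log10_range = c(-9, -5), wt_kd = 1e-6,
                        seed = 2)
  expect_true(all(v$kd >= 1e-9 & v$kd <= 1e-5))
  expect_equal(v$spec[1L], "WT")
  expect_equal(v$kd[1L], 1e-6)
  # every DNA translates to the variant's loop amino acids
  pep <- translate_dna(v$dna)
  loops <- vapply(strsplit(pep, ""), function(ch)
    paste0(ch[lib$positions$codon_index], collapse = ""), "")
  expect_identical(loops, v$loop_aa)
  expect_error(simulate_library(lib, 1e6, seed = 1), "exceeds")
})

test_that("simulated log10 KD is uniform over its range (KS test)", {
  v <- simulate_library(wide_library(), 10000, kd_log10_range = c(-9, -5),
                        seed = 17)
  ks <- suppressWarnings(stats::ks.test(log10(v$kd[-1L]), "punif", -9, -5))
  expect_gt(ks$p.value, 0.01)
})

test_that("staining follows single-site occupancy with log-normal noise", {
  # half saturation at C = KD, saturation to display level as C -> infinity
  expect_equal(staining_signal(250e-9, 250), 0.5)
  expect_equal(staining_signal(250e-9, 1e9, display = 2.5), 2.5,
               tolerance = 1e-3)
  # Monte-Carlo mean over noise draws equals occupancy x exp(sigma^2/2)
  set.seed(8)
  cv <- 0.3
  draws <- staining_signal(rep(1e-7, 1e5), 250, noise_cv = cv)
  sdlog <- sqrt(log1p(cv^2))
  expected <- (250e-9 / (250e-9 + 1e-7)) * exp(sdlog^2 / 2)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("a sorting round enriches the high-affinity variant", {
  lib <- tiny_library()
  ev <- enumerate_variants(lib, dedup = TRUE)
  variants <- data.frame(
    spec = c("WT", ev$spec[ev$spec != "WT"][1L]),
    loop_aa = c(ev$loop_aa[ev$spec == "WT"], ev$loop_aa[ev$spec != "WT"][1L]),
    dna = c(lib$ref_dna, lib$ref_dna),
    kd = c(1e-9, 1e-5), display = c(1, 1), stringsAsFactors = FALSE
  )
  class(variants) <- c("fc_sim_variants", "data.frame")
  pop <- initial_population(variants, total_cells = 2e4)
  cfg <- sort_round_config(250, gate_fraction = 0.1, cells_assayed = 2e4,
                           expansion = 2e4, noise_cv = 0.3, seed = 4)
  out <- run_sort_round(pop, variants, cfg)
  expect_gt(out$count[1L] / sum(out$count), pop$count[1L] / sum(pop$count))
  expect_identical(run_sort_round(pop, variants, cfg), out)
  expect_equal(attr(out, "round"), 1L)
})

test_that("a fully open gate preserves abundance proportions in expectation", {
  lib <- tiny_library()
  variants <- simulate_library(lib, 3, seed = 9)
  pop <- initial_population(variants, total_cells = 1e4)
  pop$count <- c(5000L, 3000L, 2000L)
  props <- replicate(100, {
    cfg <- sort_round_config(250, gate_fraction = 1.0, cells_assayed = 1e4,
                             expansion = 1e4, noise_cv = 0.3,
                             seed = sample.int(1e6, 1L))
    out <- run_sort_round(pop, variants, cfg)
    out$count / sum(out$count)
  })
  p0 <- pop$count / sum(pop$count)
  for (i in 1:3) {
    se <- stats::sd(props[i, ]) / sqrt(ncol(props))
    expect_lt(abs(mean(props[i, ]) - p0[i]), 3 * se + 1e-3)
  }
})

test_that("error-free sequencing reconstructs templates; reads have the amplicon layout", {
  lib <- loop_library()
  variants <- simulate_library(lib, 20, seed = 3)
  pop <- initial_population(variants, total_cells = 1e4)
  cfg <- seq_run_config(reads_per_sample = 2000, error_rate = 0, seed = 6)
  reads <- sequence_reads(pop, lib, cfg)
  expect_equal(nrow(reads), 2000L)
  amplicons <- paste0(lib$barcode_fwd, lib$up_flank, variants$dna,
                      lib$down_flank)
  expect_true(all(reads$seq %in% amplicons))
  expect_true(all(nchar(reads$seq) ==
                    nchar(lib$barcode_fwd) + nchar(lib$up_flank) +
                    nchar(variants$dna[1L]) + nchar(lib$down_flank)))
  expect_true(all(reads$qual == strrep(intToUtf8(30L + 33L),
                                       nchar(reads$seq[1L]))))
})

test_that("the observed substitution rate matches the configured error rate", {
  lib <- loop_library()
  variants <- simulate_library(lib, 5, seed = 3)
  pop <- initial_population(variants, total_cells = 1e4)
  eps <- 0.01
  cfg <- seq_run_config(reads_per_sample = 2e4, error_rate = eps, seed = 12)
  reads <- sequence_reads(pop, lib, cfg)
  clean <- sequence_reads(pop, lib,
                          seq_run_config(reads_per_sample = 2e4,
                                         error_rate = 0, seed = 12))
  n_bases <- sum(nchar(reads$seq))
  mism <- sum(vapply(seq_len(nrow(reads)), function(i)
    sum(strsplit(reads$seq[i], "")[[1L]] != strsplit(clean$seq[i], "")[[1L]]),
    0L))
  se <- sqrt(n_bases * eps * (1 - eps))
  expect_lt(abs(mism - n_bases * eps), 3 * se)
})

test_that("ground truth carries one row per variant with exact abundances", {
  lib <- loop_library()
  camp <- run_campaign(lib, 30, n_rounds = 2, cells_assayed = 2e4,
                       expansion = 2e4, reads_per_sample = 1000, seed = 21)
  tr <- camp$truth
  expect_equal(nrow(tr), 30L)
  expect_identical(tr$round0,
                   camp$populations$round0$count[match(tr$spec,
                                                       camp$populations$round0$spec)])
  expect_identical(tr$round2,
                   camp$populations$round2$count[match(tr$spec,
                                                       camp$populations$round2$spec)])
  expect_identical(tr$kd, camp$variants$kd)
})

test_that("a full campaign is byte-identical under a fixed seed", {
  lib <- loop_library()
  run <- function() run_campaign(lib, 40, n_rounds = 2, cells_assayed = 5e4,
                                 expansion = 5e4, reads_per_sample = 5000,
                                 seed = 33)
  a <- run(); b <- run()
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(a$reads$round2, f1)
  write_fastq(b$reads$round2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("mean log enrichment decreases with KD across deciles of a sorted campaign", {
  lib <- loop_library()
  scores <- NULL; kds <- NULL
  for (seed in 1:10) {
    camp <- run_campaign(lib, 300, n_rounds = 2, cells_assayed = 3e5,
                         expansion = 3e5, reads_per_sample = 1000,
                         seed = seed)
    tr <- camp$truth
    scores <- c(scores, log((tr$round2 + 0.5) / (tr$round0 + 0.5)))
    kds <- c(kds, log10(tr$kd))
  }
  dec <- cut(kds, stats::quantile(kds, probs = seq(0, 1, 0.1)),
             include.lowest = TRUE, labels = FALSE)
  means <- tapply(scores, dec, mean)
  # weakly decreasing; small slack for near-saturated adjacent deciles
  expect_true(all(diff(means) <= 0.05))
  expect_lt(means[10L], means[1L])
})
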