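# Synthetic-data generator: multi-round FACS selection of a displayed Fc
# variant library, followed by amplicon sequencing with substitution errors.
#
# The selection acts on a latent equilibrium dissociation constant KD per
# variant through a single-site occupancy staining model; the default
# campaign stains at 250 nM in round 1 and 125 nM in later rounds.

#' Draw a simulated variant library
#'
#' Samples variants without replacement from the deduplicated design space of
#' the library. Each variant receives a latent KD log-uniform over the given
#' log10 range and a log-normal relative display level; the wild type is
#' always included, with its own KD.
#'
#' @param lib an `fc_library`
#' @param n_variants number of variants including wild type
#' @param kd_log10_range `c(lo, hi)` of log10 KD in mol/L (default
#'   `c(-9, -5)`, i.e. 1 nM to 10 uM)
#' @param wt_kd wild-type KD in mol/L (default 1e-6)
#' @param display_sigma sdlog of the log-normal display level (default 0.3)
#' @param seed integer seed; the draw is reproducible
#' @return data.frame of class `fc_sim_variants`: `spec`, `loop_aa`, `dna`
#'   (variable-region DNA), `kd` (mol/L), `display`
#' @export
simulate_library <- function(lib, n_variants, kd_log10_range = c(-9, -5),
                             wt_kd = 1e-6, display_sigma = 0.3, seed = 1L) {
  stopifnot(inherits(lib, "fc_library"), n_variants >= 1L,
            kd_log10_range[1L] < kd_log10_range[2L])
  space <- enumerate_variants(lib, dedup = TRUE)
  if (n_variants > nrow(space))
    stop("n_variants (", n_variants, ") exceeds the variant space (",
         nrow(space), ")")
  with_seed(stage_seed(seed, 1L), {
    others <- space[space$spec != "WT", , drop = FALSE]
    pick <- others[sample.int(nrow(others), n_variants - 1L), , drop = FALSE]
    sel <- rbind(space[space$spec == "WT", , drop = FALSE], pick)
    kd <- 10^stats::runif(nrow(sel), kd_log10_range[1L], kd_log10_range[2L])
    kd[1L] <- wt_kd
    display <- stats::rlnorm(nrow(sel), meanlog = 0, sdlog = display_sigma)
    out <- data.frame(
      spec = sel$spec, loop_aa = sel$loop_aa,
      dna = variant_dna(lib, sel$loop_aa),
      kd = kd, display = display, stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    class(out) <- c("fc_sim_variants", "data.frame")
    out
  })
}

# Build variable-region DNA for loop amino-acid assignments: reference codons
# everywhere, one fixed NNK codon per substituted amino acid.
variant_dna <- function(lib, loop_aa) {
  codons <- substring(lib$ref_dna,
                      seq(1L, nchar(lib$ref_dna), by = 3L),
                      seq(3L, nchar(lib$ref_dna), by = 3L))
  aa2codon <- nnk_codon_for_aa()
  vapply(loop_aa, function(s) {
    cod <- codons
    aa <- strsplit(s, "")[[1L]]
    sub <- which(aa != lib$positions$wt_aa)
    cod[lib$positions$codon_index[sub]] <- aa2codon[aa[sub]]
    paste0(cod, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Staining signal under the single-site occupancy model
#'
#' Signal = display level x C/(C + KD) x multiplicative log-normal noise.
#' The occupancy term is fractional receptor binding at stain concentration C
#' in equilibrium; at C = KD it equals 0.5 and it saturates to 1 as C grows.
#'
#' @param kd dissociation constant(s), mol/L
#' @param stain_nM stain concentration in nM
#' @param display display level(s) (default 1)
#' @param noise_cv coefficient of variation of the log-normal noise
#'   (default 0, i.e. deterministic); noise has meanlog 0, so its mean is
#'   `exp(sdlog^2/2)`
#' @param n number of signal draws (default: length of `kd`)
#' @return numeric vector of signals
#' @export
staining_signal <- function(kd, stain_nM, display = 1, noise_cv = 0,
                            n = length(kd)) {
  stopifnot(stain_nM > 0, all(kd > 0))
  conc <- stain_nM * 1e-9
  occ <- conc / (conc + kd)
  base <- rep_len(display * occ, n)
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    base <- base * stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
  }
  base
}

#' Configuration of one sorting round
#'
#' @param stain_nM stain concentration in nM (the reference campaign uses
#'   250 nM in round 1, 125 nM in rounds 2 and 3)
#' @param gate_fraction fraction of assayed cells retained by the sort gate
#'   (top fraction by signal; default 0.01)
#' @param cells_assayed cells passed through the sorter (default 5e5)
#' @param expansion post-sort culture size (default 5e5)
#' @param noise_cv log-normal signal noise CV (default 0.3)
#' @param seed integer seed for the round
#' @return list of class `fc_sort_config`
#' @export
sort_round_config <- function(stain_nM, gate_fraction = 0.01,
                              cells_assayed = 5e5, expansion = 5e5,
                              noise_cv = 0.3, seed = 1L) {
  stopifnot(stain_nM > 0, gate_fraction > 0, gate_fraction <= 1,
            cells_assayed >= 1, expansion >= 1)
  structure(list(stain_nM = stain_nM, gate_fraction = gate_fraction,
                 cells_assayed = as.integer(cells_assayed),
                 expansion = as.integer(expansion),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "fc_sort_config")
}

#' Initial (round-0) population of a simulated campaign
#'
#' Every library variant starts at equal abundance, emulating a transformant
#' pool expanded without selection.
#'
#' @param variants an `fc_sim_variants` table
#' @param total_cells total population size (default 5e5)
#' @return data.frame of class `fc_population` (`spec`, `dna`, `count`) with
#'   attribute `round = 0`
#' @export
initial_population <- function(variants, total_cells = 5e5) {
  n <- nrow(variants)
  base <- rep(floor(total_cells / n), n)
  base[seq_len(total_cells - sum(base))] <- base[seq_len(total_cells - sum(base))] + 1L
  pop <- data.frame(spec = variants$spec, dna = variants$dna,
                    count = as.integer(base), stringsAsFactors = FALSE)
  attr(pop, "round") <- 0L
  class(pop) <- c("fc_population", "data.frame")
  pop
}

#' Run one FACS sorting round
#'
#' Cells are sampled multinomially from the population to the assayed count,
#' each cell draws a noisy staining signal, the top `gate_fraction` of cells
#' by signal is retained, and the retained cells are resampled with
#' replacement to the expansion size.
#'
#' @param pop an `fc_population`
#' @param variants the `fc_sim_variants` table (provides KD and display)
#' @param cfg an `fc_sort_config`
#' @return the post-round `fc_population` (round index incremented)
#' @export
run_sort_round <- function(pop, variants, cfg) {
  stopifnot(inherits(pop, "fc_population"), inherits(cfg, "fc_sort_config"))
  if (sum(pop$count) == 0L) stop("population is empty")
  idx <- match(pop$spec, variants$spec)
  if (anyNA(idx)) stop("population contains variants absent from the library")
  with_seed(cfg$seed, {
    assayed <- as.vector(stats::rmultinom(1L, cfg$cells_assayed,
                                          prob = pop$count))
    cell_var <- rep.int(seq_len(nrow(pop)), assayed)
    sig <- staining_signal(
      kd = variants$kd[idx][cell_var], stain_nM = cfg$stain_nM,
      display = variants$display[idx][cell_var], noise_cv = cfg$noise_cv,
      n = length(cell_var)
    )
    k <- as.integer(ceiling(cfg$gate_fraction * length(cell_var)))
    if (k < 1L) stop("sort gate retains zero cells")
    keep <- cell_var[order(sig, decreasing = TRUE)[seq_len(k)]]
    retained <- tabulate(keep, nbins = nrow(pop))
    if (sum(retained) == 0L) stop("sort gate retains zero cells")
    expanded <- as.vector(stats::rmultinom(1L, cfg$expansion, prob = retained))
    out <- data.frame(spec = pop$spec, dna = pop$dna,
                      count = as.integer(expanded), stringsAsFactors = FALSE)
    attr(out, "round") <- attr(pop, "round") + 1L
    class(out) <- c("fc_population", "data.frame")
    out
  })
}

#' Sequencing-run configuration
#'
#' @param reads_per_sample reads emitted per sample (default 1e5)
#' @param error_rate per-base substitution probability (default 0.001; must
#'   be below 0.25)
#' @param phred constant Phred quality assigned to every base (default 30)
#' @param seed integer seed
#' @return list of class `fc_seq_config`
#' @export
seq_run_config <- function(reads_per_sample = 1e5, error_rate = 0.001,
                           phred = 30L, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 0.25, reads_per_sample >= 1)
  structure(list(reads_per_sample = as.integer(reads_per_sample),
                 error_rate = error_rate, phred = as.integer(phred),
                 seed = as.integer(seed)),
            class = "fc_seq_config")
}

#' Emit amplicon reads from a population
#'
#' Each read is `forward barcode + upstream flank + variant DNA + downstream
#' flank`; templates are drawn multinomially in proportion to abundance and
#' each base is substituted independently with probability `error_rate` to a
#' uniformly chosen other base. Qualities are a constant Phred string.
#'
#' @param pop an `fc_population`
#' @param lib the `fc_library` (provides barcode and flanks)
#' @param cfg an `fc_seq_config`
#' @return data.frame of class `fc_reads` with columns `id`, `seq`, `qual`
#' @export
sequence_reads <- function(pop, lib, cfg) {
  stopifnot(inherits(pop, "fc_population"), inherits(lib, "fc_library"),
            inherits(cfg, "fc_seq_config"))
  if (sum(pop$count) == 0L) stop("population is empty")
  templates <- paste0(lib$barcode_fwd, lib$up_flank, pop$dna, lib$down_flank)
  L <- unique(nchar(templates))
  if (length(L) != 1L) stop("variable regions must share one length")
  with_seed(cfg$seed, {
    draws <- as.vector(stats::rmultinom(1L, cfg$reads_per_sample,
                                        prob = pop$count))
    tmpl_idx <- rep.int(seq_along(templates), draws)
    tmpl_mat <- matrix(unlist(strsplit(templates, "", fixed = TRUE),
                              use.names = FALSE),
                       nrow = length(templates), ncol = L, byrow = TRUE)
    reads_mat <- tmpl_mat[tmpl_idx, , drop = FALSE]
    n <- nrow(reads_mat)
    if (cfg$error_rate > 0) {
      hit <- which(stats::runif(n * L) < cfg$error_rate)
      if (length(hit) > 0L) {
        bases <- c("A", "C", "G", "T")
        alt <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                     c("A", "C", "T"), c("A", "C", "G"))
        cur <- match(reads_mat[hit], bases)
        pickn <- sample.int(3L, length(hit), replace = TRUE)
        ok <- !is.na(cur)  # leave non-ACGT template chars untouched
        reads_mat[hit[ok]] <- alt[cbind(cur[ok], pickn[ok])]
      }
    }
    seqs <- do.call(paste0, as.data.frame(reads_mat, stringsAsFactors = FALSE))
    rd <- attr(pop, "round")
    out <- data.frame(
      id = sprintf("%s_r%d_%06d", lib$name, rd, seq_len(n)),
      seq = seqs,
      qual = strrep(intToUtf8(cfg$phred + 33L), L),
      stringsAsFactors = FALSE
    )
    attr(out, "round") <- rd
    class(out) <- c("fc_reads", "data.frame")
    out
  })
}

#' Ground-truth table of a simulated campaign
#'
#' @param variants the `fc_sim_variants` table
#' @param pops list of `fc_population`s (one per round, any order)
#' @return data.frame: `spec`, `kd`, `display`, one `round<k>` abundance
#'   column per population
#' @export
ground_truth <- function(variants, pops) {
  out <- data.frame(spec = variants$spec, kd = variants$kd,
                    display = variants$display, stringsAsFactors = FALSE)
  for (p in pops) {
    cnt <- p$count[match(out$spec, p$spec)]
    cnt[is.na(cnt)] <- 0L
    out[[paste0("round", attr(p, "round"))]] <- cnt
  }
  out
}

#' Simulate a complete selection campaign
#'
#' Library draw, round-0 population, the given number of sorting rounds
#' (stain 250 nM in round 1 and 125 nM afterwards unless overridden), and
#' sequencing of the requested rounds. Every stage draws from its own
#' seed stream derived from `seed`, so the campaign is reproducible
#' end to end.
#'
#' @param lib an `fc_library`
#' @param n_variants library size (including wild type)
#' @param n_rounds number of sorting rounds (default 2)
#' @param stain_nM per-round stain concentrations; default
#'   `c(250, 125, 125, ...)`
#' @param kd_log10_range,wt_kd,display_sigma passed to [simulate_library()]
#' @param gate_fraction,cells_assayed,expansion,noise_cv per-round sorting
#'   parameters (see [sort_round_config()])
#' @param reads_per_sample,error_rate,phred sequencing parameters (see
#'   [seq_run_config()])
#' @param sequence_rounds which rounds to sequence (default round 0 and the
#'   final round)
#' @param seed master integer seed
#' @return list with `variants`, `populations` (rounds 0..n), `reads` (named
#'   `round<k>`), and `truth` (the [ground_truth()] table)
#' @export
run_campaign <- function(lib, n_variants, n_rounds = 2L,
                         stain_nM = NULL,
                         kd_log10_range = c(-9, -5), wt_kd = 1e-6,
                         display_sigma = 0.3,
                         gate_fraction = 0.01, cells_assayed = 5e5,
                         expansion = 5e5, noise_cv = 0.3,
                         reads_per_sample = 1e5, error_rate = 0.001,
                         phred = 30L,
                         sequence_rounds = c(0L, n_rounds), seed = 1L) {
  if (is.null(stain_nM)) stain_nM <- c(250, rep(125, max(0L, n_rounds - 1L)))
  stopifnot(length(stain_nM) == n_rounds)
  variants <- simulate_library(lib, n_variants, kd_log10_range, wt_kd,
                               display_sigma, seed = seed)
  pops <- vector("list", n_rounds + 1L)
  pops[[1L]] <- initial_population(variants, total_cells = expansion)
  for (r in seq_len(n_rounds)) {
    cfg <- sort_round_config(stain_nM[r], gate_fraction, cells_assayed,
                             expansion, noise_cv,
                             seed = stage_seed(seed, 100L + r))
    pops[[r + 1L]] <- run_sort_round(pops[[r]], variants, cfg)
  }
  names(pops) <- paste0("round", 0:n_rounds)
  reads <- lapply(sequence_rounds, function(r) {
    cfg <- seq_run_config(reads_per_sample, error_rate, phred,
                          seed = stage_seed(seed, 200L + r))
    sequence_reads(pops[[r + 1L]], lib, cfg)
  })
  names(reads) <- paste0("round", sequence_rounds)
  list(variants = variants, populations = pops, reads = reads,
       truth = ground_truth(variants, pops))
}
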