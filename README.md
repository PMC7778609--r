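# fcsortseq

Sort-seq analytics for mammalian-display Fc engineering.

Antibody effector functions are governed by how the IgG Fc engages the Fcγ
receptor family — activating FcγRI/FcγRIIa/FcγRIIIa versus inhibitory
FcγRIIb. Campaigns that re-tune this balance diversify Fc loops at the
Fc/FcγR interface, display the library on mammalian cells, enrich binders
over repeated FACS sorts against a biotinylated receptor, and deep-sequence
the enriched pools to identify beneficial substitutions. `fcsortseq`
implements the computational side of such a campaign for the engineer
running or analysing one:

* **Interface positions** — parse a PDB complex and report the query-chain
  residues with any heavy atom within a cutoff (default 5 Å) of the partner
  chains, grouped into contiguous loops.
* **Library design** — two-position degenerate (NNK) libraries over a loop:
  variant-space enumeration, theoretical diversity
  (raw C(L,2)·20² and deduplicated), degenerate oligos, and
  transformant-coverage arithmetic `cov(D,T) = 1 − (1 − 1/D)^T` with its
  inverse.
* **Selection simulator** — ground-truthed synthetic campaigns: latent
  log-uniform K_D per variant, single-site occupancy staining
  `S = display · C/(C + K_D) · lognormal noise`, hard top-fraction FACS
  gates with multinomial resampling (defaults: stain 250 nM then 125 nM,
  gate 1%, 10⁷ cells), and barcoded amplicon FASTQ with substitution
  errors.
* **Read processing** — quality filter, barcode demultiplexing, Hamming
  flank trimming at max error rate 0.1, frame +1 translation, DNA- and
  AA-level count tables with full rejection accounting.
* **Selection analytics** — pseudocounted enrichment scores
  `((c_a+π)/N_a)/((c_b+π)/N_b)`, ranked cumulative-frequency curves,
  copy-threshold beneficial-variant calls, per-position amino-acid
  probability matrices with the standard logo color classes, and
  combination-variant generation.
* **Assay arithmetic** — LDH `% cytotoxicity` and receptor-selectivity
  KD/EC50 ratio tables with NB/WB sentinel handling (undefined ratios
  rendered `/`), rounded half-up at printed precision.

## Worked example

```r
library(fcsortseq)

lib <- read_library_config(system.file("extdata", "example_library.yaml",
                                       package = "fcsortseq"))
lib
#> fc_library 'loop2': 6 loop positions (EU 265, 266, 267, 268, 269, 270), scheme NNK

theoretical_diversity(lib)                      # raw design count
#> [1] 6000
theoretical_diversity(lib, dedup = TRUE)        # distinct AA sequences
#> [1] 5530
expected_coverage(6000, 10 * 6000)              # 10x transformant excess
#> [1] 0.9999546
transformants_for_coverage(6000, 0.95)
#> [1] 17973
```

A simulated two-round campaign, processed back to enrichment calls:

```r
camp <- run_campaign(lib, n_variants = 200, n_rounds = 2,
                     cells_assayed = 1e6, expansion = 1e6,
                     reads_per_sample = 2e4, seed = 42)
s0 <- process_sample(camp$reads$round0, lib, "round0")
s2 <- process_sample(camp$reads$round2, lib, "round2")
s2$counters
#>        input      quality        flank       length         stop accepted_dna
#>        20000            0            6            0           18        19994
#>  accepted_aa
#>        19976

et <- enrichment_table(s0$aa_table, s2$aa_table)
head(et[, c("sequence", "copies_before", "copies_after", "score")], 3)
#>     sequence copies_before copies_after score
#> 1 VDVSVQDPEV            83         7069  84.7
#> 2 VDPSHADPEV            96         4936  51.2
#> 3 VDVQHLDPEV           105         4301  40.8
```

The three dominant variants after two sorts carry true affinity ranks 46, 3
and 31 of 200 (display-level variation deliberately confounds the gate, as
it does on a sorter). Rejection counters always satisfy
`input = quality + flank + length + stop + accepted_aa`.

Selectivity ratios reproduce printed KD tables cellwise from the bundled
panels:

```r
panel <- read_affinity_panel(system.file("extdata", "rituximab_kd_panel.tsv",
                                         package = "fcsortseq"))
ratio_table(panel, list(c("FcgRIIIa-F158", "FcgRIIb")))
#>             variant FcgRIIIa-F158/FcgRIIb
#> 1                WT                  0.39
#> 2 H268E/K326M/I332E                  0.15
#> 3 H268E/K326S/I332E                  0.13
#> 4 H268E/K326I/I332E                  0.18
#> 5 H268E/A330Y/I332D                  0.06
#> 6 H268E/A330T/I332E                  0.17

percent_cytotoxicity(50, 10, 5, 105)   # LDH signals
#> [1] 35
```

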