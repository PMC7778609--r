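---
title: "Methods: sort-seq analytics for Fc-engineering screens"
author: "fcsortseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sort-seq analytics for Fc-engineering screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcsortseq)
```

## The problem

Antibody effector functions are set by the balance of IgG Fc binding across
the Fcγ receptor family — activating FcγRI, FcγRIIa and FcγRIIIa versus the
inhibitory FcγRIIb. Engineering campaigns that re-tune this balance screen
large Fc variant libraries displayed on mammalian cells: candidate positions
are read off an Fc/FcγR co-crystal structure, loops at the interface are
diversified two positions at a time with degenerate codons, the displayed
library is stained with a biotinylated receptor and enriched over repeated
FACS sorts, and the enriched pools are deep-sequenced to find recurrent
beneficial substitutions. Hits are then characterised by SPR affinity panels
(selectivity ratios across receptors) and cytotoxicity assays.

`fcsortseq` implements the desk side of that campaign: interface-residue
identification, library design and coverage arithmetic, a selection
simulator that provides ground-truthed synthetic sequencing data, the read
processing and enrichment analytics, and the assay arithmetic used to
interpret screened variants.

## Interface positions

A residue of the query chains (the Fc) is a candidate mutagenesis position
iff any of its heavy atoms lies within a distance cutoff — 5 Å by default —
of any heavy atom of the partner chains (the receptor). Distances are exact
Euclidean distances on the parsed coordinates; no solvent accessibility or
energy term enters. Hydrogens are excluded by default because the crystal
structures this criterion is normally applied to do not resolve them.
Alternate-location records are resolved to the highest-occupancy conformer
before any distance is measured (ties keep the first conformer encountered,
making parsing deterministic). HETATM records (waters, glycans) are excluded
from the search by default since the criterion concerns protein residues.

Author residue numbering is reported untranslated. For the Fc chains of the
commonly used complex entries the author numbering already follows the EU
convention, but that is a property of those entries, not of PDB files in
general, so any EU mapping is supplied explicitly in the library
configuration rather than inferred.

Contiguous candidate residues are grouped into loops with
`group_loops()`: runs of residue numbers whose gaps do not exceed
`max_gap` (default 1) form one loop. The grouping rule is a package
convention — loop boundaries are ultimately a design choice made on the
structure.

## Library design and coverage

A library diversifies every unordered pair of positions within one loop,
each position receiving all 20 amino acids. Two diversity conventions are
exposed, because "theoretical diversity" is used loosely in the field:

* the **raw design count** $\binom{L}{2} \cdot 20^2$ for loop length $L$ —
  one cell per (pair, assignment); and
* the **deduplicated count** of distinct amino-acid sequences, in which
  assignments matching wild type collapse across pairs
  ($1 + 19L + \binom{L}{2}19^2$).

Both are computed; the coverage arithmetic deliberately takes the diversity
$D$ as an argument so either convention (or a DNA-level count) can be used.

Coverage of $D$ equally likely variants by $T$ independent transformants is
the occupancy expectation
$$\mathrm{cov}(D, T) = 1 - \left(1 - \tfrac{1}{D}\right)^T,$$
evaluated in log space for numerical stability. Its inverse,
`transformants_for_coverage()`, is $\lceil \ln(1-p) / \ln(1 - 1/D)\rceil$.
A 10-fold transformant excess ($T = 10D$) gives
$1 - (1-1/D)^{10D} \ge 1 - e^{-10+}$, i.e. above 99.99% for every $D \ge 2$ —
comfortably clearing the 95% design target quoted for such libraries.

The degenerate codon defaults to NNK (N = A/C/G/T, K = G/T): 32 codons
covering all 20 amino acids with a single stop (amber). The scheme is a
parameter because published campaigns do not always state theirs.

## The selection simulator

Real screening data for such campaigns are rarely deposited, so the
simulator is a first-class module: it generates multi-round campaigns with
known ground truth, which is what the analytics are validated against.

**Latent structure.** Each variant carries a dissociation constant $K_D$
drawn log-uniformly over a configurable range (default $10^{-9}$ to
$10^{-5}$ mol/L, bracketing typical Fc/FcγR affinities) and a log-normal
relative display level (sdlog 0.3). The wild type is always included at its
own $K_D$ (default 1 µM, a typical low-affinity receptor interaction).

**Staining.** A cell's signal is single-site equilibrium occupancy times
display level times multiplicative log-normal noise:
$$S = d \cdot \frac{C}{C + K_D} \cdot \varepsilon, \qquad
  \varepsilon \sim \mathrm{LogNormal}(0, \sigma),$$
with $\sigma = \sqrt{\ln(1 + \mathrm{CV}^2)}$ and CV defaulting to 0.3.
This is the simplest model consistent with equilibrium staining at
concentration $C$; the default campaign stains at 250 nM in round 1 and
125 nM in later rounds.

**Sorting.** Per round, cells are sampled multinomially from the population
to the assayed count (default $10^7$, the scale of cells passed through a
sorter in such campaigns), each cell draws one signal, the top
`gate_fraction` (default 1%) by signal is retained, and the retained cells
are resampled with replacement to the expansion size (default $10^7$,
emulating post-sort culture). The gate acts on the binding-channel signal
only; display is modelled as noise rather than as a second gate axis. One
variant per cell is assumed (low-MOI infection).

**Sequencing.** Each read is forward barcode + upstream constant flank +
variant DNA + downstream constant flank. Templates are drawn multinomially
in proportion to abundance; every base is substituted independently with
probability ε (default 0.001) to a uniformly chosen other base; qualities
are a constant Phred string. Substitution-only errors are a stated
simplification — no indels, chimeras or PCR bias — which keeps trimming and
translation exactly testable.

**Reproducibility.** Every stage (library draw, each round, each sequencing
run) uses its own seed derived deterministically from the master seed, so a
campaign is byte-identical across runs and stages can be re-run
independently.

## Read processing

The processing chain mirrors standard amplicon practice: a quality filter
(mean Phred ≥ 15 and ≤ 5 N bases, the spirit of fastp defaults; exact fastp
parity is a non-goal), barcode demultiplexing, constant-region trimming,
frame +1 translation, and exact-sequence counting.

Numerical conventions worth stating:

* **Demultiplexing** matches the read prefix against each barcode with at
  most `max_mismatch` substitutions (default 0). Reads matching no barcode
  or more than one go to an unassigned bin; barcodes within the radius *of
  each other* are a configuration error.
* **Trimming** locates each flank as the substring window minimising
  Hamming mismatches, subject to a budget of ⌊rate · flank length⌋
  mismatches (rate 0.1 by default, i.e. 1 mismatch per 10-base flank).
  The upstream flank takes the leftmost minimal window, the downstream
  flank the rightmost minimal window after the upstream hit; the enclosed
  region is returned, and an empty region is a rejection. The search is
  substitution-only, consistent with the simulator's error model.
* **Translation** uses the standard genetic code from base 1; a length not
  divisible by 3 or an internal stop is a counted rejection. Codons with
  ambiguous bases translate to `X`.
* **Counting** groups exact sequences; frequencies are proportions over
  the sample's *accepted* reads. Tables sort by copies descending with
  lexicographic tie-breaks, so all outputs are deterministic.

Every rejection is counted by reason, and the accounting identity
(input = quality + flank + length + stop + accepted) holds on every run.

## Selection analytics

The enrichment score between a before and an after table is a pseudocounted
frequency ratio,
$$\mathrm{score} = \frac{(c_a + \pi)/N_a}{(c_b + \pi)/N_b},$$
with π = 0.5 reads per table by default, so sequences absent on one side
remain finite and positive. With π = 0 and no zero counts this reduces to
the plain frequency ratio. Campaign reports in this field typically rank by
copy number and call "enriched" by eye; an explicit score is needed for
recovery analysis against ground truth.

Cumulative curves rank variants by copy number and accumulate frequency;
beneficial-variant calls take variants with more than `min_copies` copies
(default 1000) and report their pooled frequency. Position probability
matrices are copy-weighted amino-acid frequencies per variable position,
with the standard logo color classes (hydrophobic G,A,V,L,I,M,P,F,Y,W;
positive R,K,H; negative D,E; polar uncharged C,S,T,N,Q). Sequences
containing non-standard letters (e.g. `X` from ambiguous codons) are
excluded and counted so columns always sum to 1.

## Assay arithmetic

Percent cytotoxicity from LDH release is
$$\%\,\mathrm{Cytotoxicity} = \frac{\mathrm{exp} - \mathrm{spont}_E -
  \mathrm{spont}_T}{\mathrm{max}_T - \mathrm{spont}_T} \times 100,$$
reported as-is (with a warning) when outside [0, 100], and invariant under
uniform rescaling of the four signals.

Selectivity ratios divide two affinity values for the same variant and
round **half-up** at the table's printed precision (2 or 4 decimals in the
bundled panels); base R's round-half-to-even would disagree with printed
tables on boundary cells. The sentinels NB (no measurable binding) and WB
(weak binding) make a ratio undefined, rendered `/`. The bundled KD panels
under `inst/extdata/` reproduce their printed ratio columns cellwise at
printed precision; one printed cell (a fucosylated wild-type ratio of
0.1403) implies more precision in the underlying KDs than their printed
3 significant figures, and reproduces exactly from the printed values here,
but such cells are verified only to the precision the printed KDs support.

## What the simulator does and does not establish

Passing recovery tests on simulated data shows the analytics correctly
invert the simulator's generative model — occupancy-driven selection with
multiplicative noise and substitution sequencing errors. Real campaigns add
PCR amplification bias, indels and chimeras, double-positive gating on a
display channel, growth-rate differences during expansion, and
non-equilibrium staining, none of which are modelled; conclusions about
robustness to those effects cannot be drawn from these tests.

One structural limitation deserves emphasis. Repeated stringent sorting is
an information bottleneck: with a hard top-1% gate, variants whose signal
distribution lies well below the gate threshold go extinct in a round, and
an extinct variant's later counts carry no information about its affinity
rank. After two such rounds over a four-decade $K_D$ range, the large
extinct fraction means rank correlations between latent affinity and
end-to-end enrichment are capped well below what the surviving variants
alone would support — a property of the campaign design, not of the
analytics, and visible directly in the ground-truth abundances before any
sequencing noise enters. Single-round enrichment, gentler gates, or deeper
per-round sequencing of intermediate pools all relax the cap. The
acceptance script reports the measured two-round rank recovery honestly
rather than restating this analysis.

## Problem sizes and runtime choices

The bundled tests validate on deliberately modest sizes chosen to exercise
every code path: 30-residue synthetic complexes against an all-pairs
oracle; libraries of 2–8 positions (variant spaces up to ~11,000);
campaigns of 40–1,000 variants with $10^5$–$10^7$ cells and $10^3$–$10^5$
reads per sample; $10^4$ reads against the exhaustive demultiplexing
oracle. Monte-Carlo checks (coverage, staining noise, open-gate proportion
preservation) use 3σ acceptance bands around their closed forms.

## Known limitations

* mmCIF structures, structure superposition and ΔΔG scanning are out of
  scope; the interface module reads PDB-format coordinates only.
* The exact loop memberships of any particular published library cannot be
  verified from coordinates alone; the module reports candidates.
* Indel-tolerant trimming, UMI handling, paired-end merging and clustering
  or denoising of counts are not implemented.
* Dose–response (4PL) and SPR kinetic fitting are out of scope; only ratio
  arithmetic on given KD/EC50 values is provided.
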