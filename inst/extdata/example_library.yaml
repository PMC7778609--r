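# Example two-position degenerate library over a CH2 interface loop
# (EU 265-270 of the IgG1 Fc; variable region covers EU 264-273).
name: loop2
positions:
  - {eu: 265, wt: D, codon: 2}
  - {eu: 266, wt: V, codon: 3}
  - {eu: 267, wt: S, codon: 4}
  - {eu: 268, wt: H, codon: 5}
  - {eu: 269, wt: E, codon: 6}
  - {eu: 270, wt: D, codon: 7}
ref_dna: GTGGACGTGAGCCACGAGGACCCCGAGGTG
up_flank: ACCTGCGTGGTG
down_flank: AAGTTCAACTGG
barcode_fwd: AAGACG
barcode_rev: CGTCTT
codon_scheme: NNK
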