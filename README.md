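# crisprEscape

Quantifying bacteriophage escape from CRISPR-Cas targeting.

When bacteria expressing Cas12a or Cas9 are challenged with phage, mutants
whose target region no longer matches the crRNA can sweep the population
within hours — especially when the crRNA already carries a mismatch.
`crisprEscape` implements the computational side of that experiment as a
tested R pipeline, for anyone profiling escape mutants from amplicon deep
sequencing, long-read sequencing of phage genomic regions, and in vitro
cleavage assays:

- **Amplicon variant classification** — extract the PAM + protospacer
  window (24 nt by default: 4 nt PAM + 20 nt protospacer) from paired
  reads via flanking anchors, enforce R1/R2 concordance (pairs whose
  window sequences disagree are removed from analysis; R1 is used when
  the mates do not overlap the window), and classify each read as
  wildtype, single/multiple substitution, single deletion or complex,
  with PAM-relative position labels (`T-2C` = PAM position −2, T→C;
  single-nucleotide deletions reported at the position adjacent to the
  3′ side, with the first-mismatch label kept alongside).
- **Enrichment statistics** — per-position mutation Z-scores against a
  non-targeted control,

  Z(p) = (x̄(p) − μ̄(p)) / σ,

  with σ one pooled standard deviation of the proportions at all
  positions in all samples; haplotype nucleotide diversity,

  D = (1/L) Σᵢ₌₂ⁿ Σⱼ₌₁^{i−1} 2 xᵢ xⱼ πᵢⱼ,   L = 24;

  and seed:PAM-distal mutant competition read ratios.
- **Long-read deletion calling** — piecewise (prefix/suffix) matching of
  each read to the wild-type region, leftmost-normalised breakpoints,
  junction microhomology length/sequence with the equivalent-placement
  ambiguity window, aggregation and genome-coordinate translation
  (TSV + BED out).
- **Cleavage kinetics** — fraction cleaved = (nicked + linear) / total,
  first-order fits f(t) = A·(1 − e^(−k·t)) for k_obs with a
  deterministic multi-start, replicate summaries and unpaired two-tailed
  t tests.
- **Synthetic data generators** — seeded Wright–Fisher-style phage
  populations under selection, paired-end amplicon reads with planted
  discordant pairs, long reads with planted microhomology-flanked
  deletions, and kinetics time courses, so the whole pipeline is
  testable end to end with known ground truth.

## Worked example

The numbered scripts under `analysis/` run a complete simulated escape
experiment. `analysis/01_simulate_escape.R` builds a population that is
99.8% wild type plus two escape genotypes (a PAM mutation at position −2
and a seed substitution at position 3) at 0.1% each, propagating with a
20× survival advantage, and emits paired FASTQs for generations 0/3/6
plus non-targeted controls. `analysis/02_classify_amplicons.R` then
classifies and summarises:

```
Fraction mutated over time (mean of 2 replicates +/- SD):
  time mean_fraction sd_fraction n_replicates
1    0       0.00316    0.000754            2
2    3       0.93885    0.012625            2
3    6       1.00000    0.000000            2

Top positional enrichment Z-scores (PAM-relative positions):
  index    z
3    -2 3.43
7     3 3.23
1    -4 0.00
2    -3 0.00
```

The escape fraction rises from ~0.3% at generation 0 to 100% by
generation 6, and only the two planted positions are enriched over the
control (all other |Z| < 1). `analysis/03_longread_deletions.R` recovers
planted 80–1200 nt deletions with their junction microhomology:

```
  del_start del_end genome_start genome_end length homology_length homology_seq support
2      1501    1800        20501      20800    300               0                   104
3      4001    5200        23001      24200   1200               6       TCTGGA      94
4      7001    7080        26001      26080     80               3          CGG      89
```

`analysis/04_cleavage_kinetics.R` fits k_obs for a fast (matched crRNA)
and a slow (mismatched target) condition — recovering 0.0496 and
0.00283 s⁻¹ for true rates 0.05 and 0.003 (a 17.5× reduction,
t = 142, p = 1.5e-08) — and `analysis/05_competition_and_report.R`
computes competition ratios (1.98 and 0.49 for 2:1 and 1:2 mixes) and
renders the Z-score heat map and time-course figures.

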