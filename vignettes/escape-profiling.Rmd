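---
title: "Profiling phage escape from CRISPR-Cas targeting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling phage escape from CRISPR-Cas targeting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprEscape)
```

## The problem

When a lytic phage infects bacteria expressing a Cas effector (Cas12a or
Cas9) guided against an essential region of the phage genome, the phage
population that emerges from the culture is enriched for *escape
mutants*: genomes whose protospacer or PAM has changed enough to impair
cleavage. Deep sequencing of a PCR amplicon spanning the target, sampled
over the course of infection, reads out that selection directly; a
crRNA that already carries a mismatch (emulating a preexisting target
mutation) lowers the barrier to escape and concentrates new mutations in
characteristic regions (the PAM and seed for a seed-mismatched crRNA;
PAM-distal positions behave differently between effectors). This
package implements the quantitative layer of that experiment: read
classification, enrichment statistics, long-read deletion calling and
cleavage kinetics.

## Coordinate and labelling conventions

The unit of analysis is the PAM + protospacer window (default 4 + 20 =
24 nt). Internally everything is 1-based and closed on the amplicon
plus strand; PAM-relative labels appear only at the reporting layer.
PAM positions are negative (−1 adjacent to the protospacer);
protospacer positions count 1..20 from the PAM-proximal end, so for a
5′ PAM (Cas12a-style) the window string reads −4..−1, 1..20 left to
right, while for a 3′ PAM (Cas9-style) it reads 20..1, −1..−3. A
variant label such as `T-2C` means PAM position −2, reference T,
observed C.

Region boundaries are configuration, not biology fixed in code: the
defaults are seed = positions 1–6, mid = 7–12, PAM-distal = 13 onward,
consistent with how single-mismatch positions are usually grouped; they
can be overridden per `target_spec()`.

Two conventions for placing single-nucleotide deletions coexist in
published displays: the position *adjacent to the 3′ side* of the
(leftmost-resolved) excision, and the *first position where a
positionwise mismatch occurs*. The two differ by one base, and within a
homopolymer run the excised base is intrinsically ambiguous. We resolve
the ambiguity to the leftmost equivalent placement, compute the first
positionwise mismatch (which is the rightmost equivalent placement) and
store *both* labels on every deletion call, tabulating by the
3′-adjacent label by default with a switch
(`tabulate_variants(..., deletion_convention = "first_mismatch")`).
Either label is invariant to which base of a homopolymer run was
actually lost.

## Read-pair concordance

The amplicon design guarantees that both mates overlap the entire
window, and that redundancy is used as an error filter: a pair whose R1
and R2 window sequences disagree at any base is removed from analysis
(`rejected_discordant`), which suppresses sequencing errors to the rate
at which *both* mates err identically. When only one mate reaches the
window (plus its flanking anchors) that mate's window is used — R1 by
design; we treat an R2-only pair symmetrically rather than discarding
it, since silently dropping reads would break the partition audit
(every pair lands in exactly one of accepted / rejected_discordant /
rejected_unalignable). Whether the concordance filter was enforced for
all samples or only for negative controls in the original design is
ambiguous; it is on for all samples by default and exposed as
`require_concordance = FALSE` for the relaxed behaviour (R1 wins).

Windows are located by two flanking anchor sequences (12 nt by
default) matched exactly, with a fallback of at most one mismatch per
anchor and no indels: window location stays deterministic and cheap,
reads with more damaged anchors are `rejected_unalignable`, and an
anchor occurring twice makes the read ambiguous rather than guessed.

## Enrichment Z-scores

For each position $p$,
$$Z(p) = \frac{\bar{x}(p) - \bar{\mu}(p)}{\sigma}$$
where $\bar{x}$ and $\bar{\mu}$ are cross-replicate means of the
mutated-read proportion at $p$ in experimental and control samples and
$\sigma$ is a *single pooled* standard deviation of the proportions at
all positions in all supplied samples — experimental and control
together, read literally from the definition. The denominator (n vs
n−1) is not specified by the definition; sample SD is the default with
`sd_denominator = "population"` as the alternative. Because $\sigma$
pools over positions, a strong enrichment at a few positions inflates
$\sigma$ and deflates all Z values — this is a property of the
statistic itself, not of this implementation, and is why the simulated
escape experiment yields planted-position Z around 3 rather than the
double digits seen when only a minority of the population is mutated.
All-identical proportions make $\sigma = 0$; that raises a classed
degenerate-input error rather than returning NaN.

## Nucleotide diversity

$$D = \frac{1}{L} \sum_{i=2}^{n} \sum_{j=1}^{i-1} 2\, x_i x_j\, \pi_{ij}$$

with $x_i$ the frequency of haplotype $i$ over the window, $\pi_{ij}$
the pairwise Hamming distance, and $L = 24$. The index form is
implemented exactly as printed — no $n/(n-1)$ sample-size correction is
applied because none is applied in the source definition. The treatment
of single-deletion haplotypes under a Hamming distance is undefined;
default behaviour aligns them by inserting a gap at the deletion slot
(the first-mismatch position), counting the gap as one difference
against any base and zero against a gap at the same slot, with
`deletions = "exclude"` to drop them and renormalise instead.

## Long-read deletion calling

Each long read is interpreted as reference prefix + reference suffix
with one contiguous interval excised. With $d = |\mathrm{ref}| -
|\mathrm{read}|$ fixed by the lengths, the caller scores every junction
placement $l$ by the number of mismatches of `read[1..l]` against the
reference prefix plus mismatches of the remainder against the
reference suffix — computable for all $l$ in one pass with cumulative
sums. The minimum-cost placement set is exact at zero error (its width
equals the junction microhomology); isolated substitution errors leave
the argmin inside the true window except when an error lands directly
on a junction-adjacent base (~1–2% of reads at 0.5% error, the observed
failure mode in the recovery study). A read is:

- `none` if it has the reference length;
- `deletion` if the best placement leaves at most 1 mismatch per 100
  read bases (`max_mismatch_rate = 0.01`) and at least `min_anchor`
  (default 20) matched bases flank the junction on both sides;
- `unresolved` otherwise — reads with two separated deletions or heavy
  corruption are counted and reported, never silently dropped.

Breakpoints are normalised to the leftmost equivalent placement
(standard variant-normalisation practice; deterministic), then
`microhomology()` reports the homologous junction sequence and the
ambiguity interval of equivalent placements, whose width equals the
homology length. Aggregation keys events by canonical breakpoints (so
placements within one homology window merge), sums support, and
translates coordinates by the amplicon's genomic offset. The original
long-read processing script's anchor lengths and error handling are not
documented; `min_anchor = 20` and the 1-per-100 budget are this
package's declared defaults, not inferred values.

## Cleavage kinetics

Fraction cleaved pools the nicked and linearised bands over total DNA;
it is homogeneous in the band intensities, so raw densitometry units
work directly. Time courses (default quench times 7, 15, 30, 60, 300,
900, 1800 s) are fitted to $f(t) = A(1 - e^{-kt})$ by bounded
Levenberg–Marquardt least squares started from a fixed grid of rates
$\{10^{-4}, 10^{-3}, 10^{-2}, 10^{-1}, 1\}$ s⁻¹ — a deterministic
multi-start with no RNG dependence; best RSS wins. Whether the plateau
$A$ was fitted or fixed at 1 in the original fits is unstated; several
gels plateau well below complete cleavage, so $A \in [0,1]$ is fitted
by default with a `fix_plateau` override. A rate fast enough that
$f(7\,\mathrm{s}) \ge 0.99A$ is reported with a `lower_bound` flag: the
first quench time cannot resolve it. All-zero courses return the
degenerate $k = 0$ fit, flagged. Replicates are summarised as mean ±
sample SD of converged $k_{obs}$, and conditions compared with the
classical unpaired two-tailed $t$ test (equal-variance form by default,
matching the conventional reading of an unqualified "unpaired t test";
Welch via `var_equal = FALSE`).

## What the synthetic data emulate — and what they do not

The generators exist so that every stage is testable against planted
ground truth:

- `simulate_population()` is discrete-generation Wright–Fisher-style
  multinomial resampling with multiplicative survival weights. No
  population model is prescribed by the underlying experiment; weight
  ratios are an explicit stand-in for relative cleavage rates (a
  genotype cleaved ~20× slower gets ~20× the weight). De novo
  mutants arising from the per-base error process inherit their
  parent's weight; genuinely escaping genotypes must be declared with
  their own weights. No recombination-mediated propagation is
  modelled.
- `emit_amplicon_reads()` collapses PCR and sequencing error into one
  per-base substitution rate (the two are not distinguishable in real
  amplicon data either) and plants R1/R2-discordant pairs at a known
  rate, flagged in read identifiers, so the concordance filter can be
  audited read by read. Qualities are fixed; no realistic Illumina
  error profile is attempted.
- `build_deletion_reference()` + `emit_long_reads()` engineer exact
  junction microhomologies by copying the homology k-mer across the
  junction and then blocking accidental extension on both sides, so
  the planted homology length is exact by construction.
- `emit_timecourse()` inverts the kinetic model with Gaussian noise
  clipped to [0, 1].

Every generator takes an explicit seed, uses one RNG stream, and
restores the caller's RNG state: identical inputs and seed give
byte-identical outputs. Passing tests on these data demonstrates the
correctness of the statistical machinery, not the realism of Illumina
or PacBio error processes: structured errors (homopolymer indels,
quality decay, chimeric PCR products) are out of scope and real data
will exercise the `rejected_unalignable`/`unresolved` paths more.

## Study conditions used in the bundled analyses

The `analysis/` scripts and the acceptance script run: a 50,000-genome
population for 6 generations with wild type at weight 0.05 vs two
escape genotypes (PAM −2 and seed 3 substitutions) at weight 1.0 and
initial frequency 0.1% each, sampled at generations 0/3/6 with 2
replicates of 2,000 read pairs and a 0.1% per-base error floor;
100 planted deletions of 50–2,000 nt with 0–10 nt microhomology on a
10 kb reference, recovered at 0% and 0.5% read error; and k ∈ {0.001,
0.01, 0.1} s⁻¹ recovered from 100 noisy (1% SD) time courses each.
These sizes keep the full suite within a few minutes on one CPU while
leaving sampling error far smaller than the effects measured.

## Known limitations

- The amplicon classifier handles substitutions and single-nucleotide
  deletions; multi-nucleotide deletions within the window are counted
  `complex` and excluded from per-position substitution tabulation
  (the amplicon analysis this mirrors reports only single-nucleotide
  variants), while large deletions are the long-read caller's job.
- The long-read caller models exactly one contiguous deletion per
  read; insertions, inversions and multi-deletion reads land in
  `unresolved`.
- The pooled-σ Z-score is scale-coupled across positions (see above);
  comparisons of Z magnitudes between samples with very different
  overall mutation loads should be made with care.
- No multiple-testing correction is applied to positional Z-scores,
  by design parity with the statistic's usual reporting.
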