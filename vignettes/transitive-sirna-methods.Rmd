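---
title: "Methods: detecting and explaining transitive siRNA production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and explaining transitive siRNA production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The biological question

When an ARGONAUTE-containing RISC slices a miRNA target, the transcript is
cut between the target nucleotides paired to miRNA positions 10 and 11,
leaving a capped but unpolyadenylated 5' fragment and an uncapped 3'
fragment. Cytoplasmic decay pathways normally remove these fragments
quickly. When 3'-5' decay through the SKI2-3-8/exosome route is
compromised, many miRNA targets start producing RDR6-dependent secondary
("transitive") siRNAs — low-abundance, predominantly 21 nt, and confined
to a narrow region immediately adjacent to the cleavage site, on the 5'
side for most targets but exclusively on the 3' side for a few. transitr
implements the computational side of this analysis as a reusable,
fully-tested pipeline driven by a synthetic data generator.

# The statistical model

## Scanning-window differential accumulation

Reads are counted per genomic window (300 nt, advancing 150 nt, so every
interior position is covered by exactly two windows), separately for each
read size 19-26 nt and each sample. A read belongs to every window
containing its 5'-end coordinate (start on the plus strand, `end - 1` on
the minus strand). This assignment rule is a package decision: the
original analysis does not state one, and 5'-end assignment gives each
read a well-defined multiplicity (at most two with the default geometry),
which makes count conservation exactly testable. Strands are pooled by
default because transitive siRNAs derive from both strands of the
RDR6-made dsRNA; a `stranded` flag provides per-strand matrices for
diagnostics.

## The exact negative-binomial test

Counts are modeled as negative binomial with common dispersion
$\phi$ (variance $\mu + \phi\mu^2$; $\phi = 0$ recovers Poisson).
For a two-genotype comparison with replicates, libraries are first
equalized by total-count rescaling to their geometric mean (a documented
simplification of quantile adjustment; median-of-ratios is available as a
config switch). Replicate counts are summed within groups and the group-A
sum $S$ is tested conditional on the grand total $t$. With equalized
libraries the group sums are NB with sizes $n_A/\phi$ and $n_B/\phi$ and
a shared success probability, so the conditional law of $S$ given $t$ is
negative hypergeometric — the probability parameter cancels — and is
computed exactly:

$$P(S = s \mid t) \propto \binom{s + n_A/\phi - 1}{s}\binom{t - s + n_B/\phi - 1}{t - s}.$$

The two-sided p-value sums $P(S = s)$ over all splits with probability at
most that of the observed split; $t = 0$ yields $p = 1$ by convention.
The test equals an exact binomial test in the Poisson limit and is
verified against exhaustive enumeration by explicit convolution of
per-replicate pmfs for small totals.

The common dispersion is estimated by maximizing the summed conditional
log-likelihood of within-group splits given group totals (a qCML
analogue), with a method-of-moments estimator
$\hat\phi = \max(0, \sum(v_i - m_i)/\sum m_i^2)$ as an independent
cross-check; both are clamped to $[0, 10]$. On data simulated at
$\phi = 0.2$ both recover the truth within $[0.15, 0.25]$, and on Poisson
data both fall below 0.02.

Significance defaults to the raw $p < 0.05$ rule, matching the original
analysis; Benjamini-Hochberg adjustment is available and recommended for
new analyses (`adjust = "BH"`). Windows whose summed counts fall below
`min_total_count = 5` are reported with `p = NA` and are never
significant.

## Loci and enrichment

Significant windows of the same direction that overlap (or fall within a
configurable gap, default 0 — sufficient given the 2x window overlap) are
merged into loci across size classes. A locus is a miRNA-target locus iff
it overlaps at least 1 nt of a gene carrying a target-site record.
Enrichment of targets among locus genes is a Fisher test computed over
genes: the one-sided p is the hypergeometric upper tail, the two-sided p
sums all tables with probability at most the observed, and both are
verified against exhaustive table enumeration for margins up to 30.

## Cleavage-site profiles and spreading direction

The cleavage coordinate $c$ is the transcript index of the first
nucleotide of the 3' fragment: with a 1-based closed site $[s, e]$ whose
3'-most nucleotide pairs miRNA position 1, the cut falls between $e - 10$
and $e - 9$, so $c = e - 10$ in 0-based coordinates. Profiles count read
5' ends within $\pm 500$ nt of $c$; a 5' end exactly at $c$ belongs to
the 3' side (half-open convention, fixed and tested). With side totals
$n_5$ and $n_3$: below `min_reads = 10` total the call is `none`
(strictly fewer — a profile with exactly `min_reads` reads is
classified); a side holding at least `exclusivity = 0.9` of the reads
gives an exclusive call; otherwise `bidirectional`. The 0.9 default is a
package choice — the original work says "exclusively" without a number —
and both knobs are exposed. Per-10-million normalization is display-only
and can never change a call.

## Duplex energies and the spreading-side prediction

Hybridization free energy between two RNA strands is computed by a
dynamic program over intermolecular pairings only (no hairpins), scoring
adjacent pairs with nearest-neighbor stack terms
$\Delta G(T) = \Delta H - T\Delta S/1000$, interior loops/bulges with a
length-penalty table (Jacobson-Stockmayer extrapolation beyond 6 nt,
treated as purely entropic and scaled by $T/310.15$), terminal AU/GU
penalties at the two outermost pairs, and one duplex-initiation term.
Watson-Crick parameters follow the standard 1 M NaCl nearest-neighbor
set; G·U wobble entries are bundled working values in the same style and
are labeled as such in the parameter file. The model was chosen to be the
smallest one whose optimum is verifiable by brute force: the DP equals
exhaustive enumeration over all non-crossing pairings for strands up to
8 nt. Loop-closing AU penalties and dangling ends are omitted;
swapping the parameter TSV requires no code change.

Salt correction (the 150 mM NaCl / 5 mM MgCl$_2$ conditions of the
original calculations) is deliberately not modeled: the downstream
prediction compares two energies for the same miRNA under identical
conditions, and `predict_side` is provably invariant under adding any
constant to both — a property the test suite asserts.

For a target site split at $c$, `fragment_energies` computes `dG5`
(miRNA positions 11..L against the site region on the 5' fragment) and
`dG3` (miRNA positions 1..10 against the region on the 3' fragment) at
21 °C. The prediction rule: transitive siRNAs arise on the side of the
fragment *least* stably paired (less negative $\Delta G$); when
$|\Delta G_5 - \Delta G_3| \le \tau$ (default $\tau = 2$ kcal/mol) the
call defaults to `five_prime`, because free-strand energies
systematically understate pairing of the 3' fragment to the miRNA 5'
half (AGO pre-organizes miRNA nucleotides 2-5 helically). $\tau$ is a
mandatory, visible parameter and the pipeline reports k/n over a
$\tau$-grid (0, 1, 2, 3) so the sensitivity is explicit. Prediction
accuracy k of n over eligible targets (single small RNA, exclusive
direction call) is scored with the exact binomial upper tail
$P(X \ge k)$ at $p_0 = 0.5$, computed in integer arithmetic for
$n \le 64$ (Pascal's triangle with big-integer addition; $\binom{64}{32}$
overflows doubles).

## 3'-RACE tails

Clone inserts are matched exactly against the expected 5'-fragment
sequence, anchored at the 5' end and extended maximally (a clone
nucleotide equal to the next reference nucleotide is always templated),
so ambiguous tails are shortened, never lengthened. The unmatched suffix
is the non-templated tail; clones matching fewer than `min_match = 20` nt
are non-fragment cDNAs, and clones running past the reference 3' end
whose continuation matches the downstream mRNA context are classified as
uncleaved-mRNA clones. Tails classify by strictly most frequent
nucleotide with ties going to the first tail nucleotide (so "UUA" is a U
tail and "AAC" an A tail, as in the published table). Exact matching is
justified by Sanger-sequenced clones; no indel alignment is attempted.

# The synthetic world

The generator states one fixed world (all values overridable in
`sim_config()`):

* four genotypes (SKI2_RDR6, ski2_RDR6, SKI2_rdr6, ski2_rdr6) × two
  replicates;
* a 2 × 150 kb genome with 120 non-overlapping genes (1.4-2.4 kb) on both
  strands, 30 of them miRNA-targeted with perfect reverse-complement
  21-nt sites (mismatch injection per miRNA half available for duplex
  tests);
* planted transitive signal: mean 100 reads per locus per sample in
  ski2_RDR6, 8-fold over wild type, 5' ends within 150 nt of the
  cleavage site on the planted side(s) (70% 5', 20% 3', 10%
  bidirectional), 80% 21-mers, fully RDR6-dependent (removed from rdr6
  genotypes);
* NB replicate noise with $\phi = 0.2$ throughout — the same
  parameterization the test assumes, so recovery tests are
  self-consistent;
* background degradation reads: mean 5 per gene per sample, uniform
  position/size/strand. This value is not stated anywhere; it was set so
  that background inside a ±500 nt profile window stays an order of
  magnitude below planted peaks, which is what published
  cleavage-adjacent siRNA profiles look like (peaks on near-zero
  background). A substantially higher background (e.g. 20) pushes
  exclusive loci under the 0.9 exclusivity threshold and contradicts the
  stated recovery behaviour;
* library ballast: 20 intergenic high-abundance, non-differential
  small-RNA source loci (mean 1000 reads per sample). Real small-RNA
  libraries are dominated by miRNA/heterochromatic-siRNA reads, making
  transitive siRNAs a negligible library fraction. Without ballast the
  planted signal was most of the case library and total-count
  normalization crushed an 8-fold effect to below 2-fold (composition
  bias); with it, the stated total-count default behaves as it does on
  real data;
* RACE clones: (possibly 3'-trimmed) fragment prefixes plus tails drawn
  from a configurable spectrum, with exact truth records.

What a green test does establish: the windowing, counting, testing,
merging, profiling, energy and tail machinery is internally correct and
recovers planted truth under realistic noise. What it does not: spliced
transcripts (genes are unspliced; real use needs exonic projection),
multi-mapping ambiguity (counts are per alignment record), sequencing
error (none simulated), and any numeric claim about the original
sequencing data (locus counts like 189/173 are data-dependent and out of
scope).

# Numerical choices and edge cases

* Coordinates are 0-based half-open everywhere internally; GFF3 and the
  site TSV (1-based closed) convert exactly once at the boundary.
* Equalized counts are rounded to integers before the conditional test;
  pmf comparisons use a `1 + 1e-9` relative guard so ties in probability
  mass are included deterministically.
* The qCML dispersion optimizer works on $\log\phi$ over
  $[10^{-6}, 10]$ and snaps to 0 when the boundary fits at least as well
  (Poisson data leave the conditional likelihood flat near zero).
* `merge_windows` with gap 0 merges overlapping-or-abutting windows via
  IRanges; direction never mixes.
* Ties in `classify_tail` go to the first tail nucleotide; the
  maximal-templated rule makes extraction deterministic for any clone.
* Stage seeds derive from the global seed by hashing stage names
  (`stage_seed`), all below $2^{31}$, so every stage has an independent,
  reproducible stream and a rerun is byte-identical.

# Known limitations

Tag-wise/trended dispersion, GLM designs with more than two groups,
partition-function duplex energies, intramolecular structure, salt
corrections, and reproduction of the original study's genome-scale locus
counts are all out of scope. The exact test's concordance with any
particular edgeR version is not claimed: the original settings are
unreported, so this package documents and tests its own exact
formulation instead.
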