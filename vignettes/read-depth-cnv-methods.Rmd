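---
title: "Methods: read-depth copy-number calling in rdcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-depth copy-number calling in rdcnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcnv)
```

## The model

Read-depth (RD) copy-number inference rests on one assumption: after
correcting systematic coverage biases, the expected sequencing depth of a
genomic segment is proportional to the number of copies of that segment in
the sampled genome. `rdcnv` works on a fixed lattice of non-overlapping
1 kb bins. For a diploid individual sequenced to mean pair coverage
$c$ (in $\times$), the expected raw depth of bin $b$ is modelled as

$$\mathbb{E}[d_b] = \frac{c}{2}\, \mathrm{CN}_b \, g(\mathrm{gc}_b)\,
  (1 - m_b),$$

where $\mathrm{CN}_b$ is the (unknown) copy number, $g(\cdot)$ a
multiplicative GC-composition bias, and $m_b$ the repeat-masked fraction of
the bin. Estimation inverts this model in two stages:

1. a *diploid baseline* $D$ — the depth a CN 2 bin should have — seeded
   from 1:1 orthologous genic regions (near-universally single-copy across
   mammals, hence a safe diploid anchor when nothing else is known about
   the genome), then re-estimated genome-wide;
2. *GC-interval correction factors* estimated on predicted diploid bins
   and applied everywhere, after which $\widehat{\mathrm{CN}}_b = 2 d^*_b / D$.

The two stages matter because coding regions are GC-rich: factors fit only
on ortholog bins would extrapolate badly into AT-rich sequence. The
genome-wide diploid set (provisional CN in $[1.5, 2.5]$) breaks that
composition bias. Males get their X bins outside the pseudo-autosomal
region doubled, so X copy numbers are comparable across sexes; the seeded
baseline uses autosomal anchors only, since X orthologs are haploid in
males.

Mappability is handled by normalising each included bin to *effective depth
per unmapped-masked base*, $d_b/(1 - m_b)$, before any estimation. Bins
with $m_b > 0.8$ are excluded outright and flagged (`NA`), never reported
as CN 0. The 0.8 rule is this package's choice: a bin with fewer than 200
usable bases contributes more noise than signal at ~10x coverage.

## From CN tracks to MCRs and CNVRs

Per individual, bins whose copy number rounds (half-up) to at least 4 —
equivalently CN > 3 — are chained into **multi-copy regions (MCRs)**; runs
must span at least 6 kb. Rounding rather than thresholding the continuous
estimate avoids noise-driven run breaking exactly at the threshold; a
`continuous = TRUE` mode applies the literal CN > 3 comparison instead.
Bins with estimated CN below 1 are dropped before chaining — they cannot
be gains, and removing them keeps a gap-tolerant chaining mode from
bridging across confidently non-amplified sequence.

Two gap-semantics decisions are deliberate:

* **Observed below-threshold bins break chains** (`max_gap_bins = 0` by
  default). "Chaining" with no printed gap rule is read conservatively;
  the parameter makes the alternative testable.
* **Excluded bins never break chains** (`bridge_excluded = TRUE` by
  default). A fully masked bin carries no depth evidence for or against a
  gain. Pipelines that define bins over unmasked sequence never encounter
  such bins; on a fixed lattice, letting them split runs would discard
  true events that merely span a masked repeat. Regions still must start
  and end on qualifying bins, and the 6 kb minimum applies to the full
  span. Setting `bridge_excluded = FALSE` restores strict behaviour.

**CNVRs** are population objects: all individuals' MCRs are merged by
single-linkage union (book-ended, i.e. boundary-sharing, intervals count
as contact, keeping bin-aligned fragments of one event together), each
merged region gets a CN value for *every* individual — including those
with no MCR there, whose near-2 values supply the contrast — and regions
whose sample standard deviation (with the $n-1$ denominator; the $n$
choice is not printed anywhere authoritative, so the conventional unbiased
variant is used and its threshold behaviour is pinned by a test) reaches
0.7 are called. The matrix uses continuous CN so the dispersion statistic
is not inflated by integer quantisation. Merged regions keep their union
coordinates; no re-trimming is attempted.

## Gene, context and group reports

*Genes.* A gene is a candidate when ≥ 70% of its length (inclusive) is
covered by the CNVR union; coverage fraction is invariant to how CNVRs are
fragmented. Exon-level CN per individual is the overlap-weighted mean of
per-bin CN over the gene's exons — depth exists at bin resolution here, so
base-resolution exon depth is approximated by bin-overlap weighting; a
gene tiling whole bins reproduces the plain bin mean exactly. Genes pass
when some individual's exonic CN exceeds 2 (strict) and the
across-individual s.d. reaches 0.5 (inclusive), matching the printed
operators; this screens out CNVR calls driven by high-copy segments
outside exons. Enrichment is a generic upper-tail hypergeometric test per
annotation term with Benjamini–Hochberg correction; no ontology-graph
propagation is performed (term mappings are taken as flat input).

*Context.* Fixed-width 10 kb flank intervals are laid on both sides of
CNVRs and of segmental duplications (clipped at chromosome ends and
flagged); the background ("other") set tiles the remaining genome at the
same width, dropping sub-width remainders so every background interval has
identical size and no base belongs to two sets. Repeat-family densities
are bases per interval; enrichment uses a two-sided Fisher exact test on
base counts (the table's construction from base counts rather than
interval counts is a documented choice), computed by summing
hypergeometric point probabilities via `dhyper`'s log-gamma machinery so
margins in the millions are exact; a chi-square fallback exists for speed.
SD proximity counts an SD when it intersects a CNVR expanded by 10 kb on
both sides, with the percentage reported truncated to one decimal as
proximity tables conventionally print it, alongside full precision.

*Groups.* Comparisons use a balanced, seed-deterministic subset (3 per
group by default) so group CNVR counts are not driven by unequal sample
sizes. Each group's CNVR set is a full re-run of merge → matrix → s.d.
call on that group's members only; a union-of-groups set is likewise
computed from the union's members, which can legitimately differ from the
union of per-group call sets (a region fixed within each group but
divergent between groups appears only in the combined computation — a
test documents such a case). A CNVR is *group-specific* when it overlaps
(≥ 1 base) no CNVR of any other group, and the specificity ratio is
specific/total rounded to two decimals — the definition uniquely
consistent with both published example ratios (277/2289 → 0.12, 151/2084
→ 0.07). Per-group gene statistics are reported as the mean and s.d.
across member individuals of the count of candidate genes whose exonic CN
exceeds 2 in that individual; the source material does not define its
"cumulative count" precisely, so this interpretation is fixed here.

## The simulator: what it emulates, what it does not

`simulate_genome()` + `simulate_cohort()` generate the full study design:
a ~20 Mb genome (three autosomes and an X with a 300 kb PAR) at 1 kb bins,
the 16-individual cohort (4 groups, published coverages 7.1–11x), and 56
gain events by default — 20 shared, 16 group-scoped, 20 private — with
integer CN uniform on [4, 10] (the supported range extends to 32,
matching the highest gene copy numbers RD studies report).

* **GC landscape**: a bounded AR(1) per chromosome (mean 0.42, marginal
  s.d. 0.05, lag-1 correlation 0.95, clipped to [0.2, 0.7]) gives
  realistically autocorrelated composition without modelling sequence.
  Bins around event sites can carry a small GC dip (0.03), mirroring the
  lower GC observed at CNV loci.
* **Event sizes**: 6 kb plus a geometric excess (discretised exponential)
  truncated at 60 kb, mean ≈ 13 kb — the right-skewed spectrum RD gain
  catalogues show, with the analytic mean available in closed form for
  tests.
* **Noise**: negative binomial on per-bin base counts with a single
  dispersion parameter (`variance = mean + 0.005·mean²`; Poisson at 0).
  No noise model is printed for the original data; NB is the standard
  over-dispersion choice for sequencing depth.
* **Repeats and masking**: ~1200 elements of four families; the masked
  fraction of a bin is its repeat-union coverage, and depth is attenuated
  by (1 − masked) generatively. L1 elements are preferentially placed in
  the 10 kb flank *upstream of event anchors* — never inside events —
  because flank enrichment is the signal the context module measures,
  while interior masking would erase the depth evidence the event exists
  to provide. Background elements can still land inside events, which is
  the realistic residual case discussed under recovery below.
* **Diploid anchors**: ortholog genes are never overlapped by events, by
  construction — they are the pipeline's ground truth for CN 2.
* **SDs**: half are placed with midpoints within 8 kb of event anchors so
  SD/CNVR proximity has a known positive rate.

Not emulated: real sequence, alignment artefacts and multi-mapping,
dispersed duplications (an event's copies have a single locus here),
CN losses (a loss mode exists behind `allow_losses`, off by default,
mirroring the gain-only scope of the calling side), inter-individual
coverage correlation, and batch effects. Passing recovery tests on this
generator therefore demonstrates correctness of the estimation and calling
machinery under the stated model — not robustness to alignment pathology.

## Numerical and degenerate-input choices

* Rounding for chaining is half-up (`floor(cn + 0.5)`), not banker's
  rounding, so behaviour is monotone in CN and CN 3.5 chains.
* All interval arithmetic is 0-based half-open; writers state the
  convention in file headers, and 1-based inclusive input is converted
  only behind an explicit flag.
* GC intervals with fewer than 50 diploid bins merge into their nearest
  well-supported neighbour before factors are computed; a single populated
  interval degenerates, with a warning, to unit factors. Interval width
  0.01 and the support floor are configurable; they fix the
  bias-variance trade of the factor fit at ~10x coverage.
* The diploid refinement window [1.5, 2.5] is symmetric about CN 2 and
  excludes single-copy male X bins automatically.
* Degenerate inputs fail loudly with named errors: too few ortholog bins
  ("baseline unstable"), an empty diploid window ("refinement failed"),
  non-positive baseline, CN matrices with one individual (undefined
  s.d.), Fisher tables with an empty margin, event placement that cannot
  satisfy the no-overlap constraints.
* Oracle-style equalities (means, factors, overlap fractions) are tested
  to 1e-9 relative tolerance against brute-force recomputation.

## Recovery benchmarking

`evaluate_recovery()` scores called CNVRs against truth events that are
*polymorphic*: truth-side CN s.d. at or above the calling threshold with
at least 3 individuals off the modal value — the events a dispersion-based
caller can detect in principle. One further restriction defines the
headline rate: an event is *callable* only if its non-excluded bins span
at least the 6 kb minimum. An event whose unmasked extent is shorter can
never satisfy the span rule, whatever the caller does; such events are a
property of the simulated repeat landscape, not of the method, so they are
excluded from the headline denominator (the unrestricted rate is reported
alongside). On the default conditions the pipeline recovers all callable
polymorphic events with zero median boundary error, and event-free
simulations produce no CNVRs across 20 seeds.

Problem sizes throughout the tests and the acceptance script — a 20 Mb
genome, 16 individuals, 56 events, 20 null seeds — were chosen as the
smallest design that exercises every scope class and keeps the s.d.
statistics well away from small-sample artefacts.

## Known limitations

* Boundaries are bin-resolution; no split-read or pair-end refinement.
* CN losses are out of scope on the calling side (the catalogue is
  gains-only; the simulator's loss mode exists for future work).
* The exon CN is a bin-overlap approximation of base-level exon depth.
* Fisher enrichment on base counts treats bases as independent draws;
  spatially autocorrelated repeat placement makes its p-values
  optimistic, which is why the density ordering itself is also reported.
* The group-specificity partition uses ≥ 1-base overlap; reciprocal
  overlap fractions are a possible refinement but are not implemented.
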