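---
title: "Methods: genetic dissection of the egusi seed-coat trait"
author: "egusimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic dissection of the egusi seed-coat trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egusimap)
```

## The genetic model

Egusi watermelon seeds have a thin, membranous seed coat. The trait behaves
as a two-locus system with inhibitory epistasis: a main recessive locus
(*eg*, chromosome 6) and a recessive suppressor locus (chromosome 1). The
default penetrance table encodes

> egusi ⟺ genotype *aa* at the main locus **and** at least one dominant
> (non-suppressing) allele at the suppressor locus (*BB* or *Bb*).

With both loci segregating in an F2, the egusi class collects
`aa,BB` (1/16) + `aa,Bb` (2/16) = 3/16, hence the 13:3 non-egusi : egusi
ratio. In a backcross of the F1 to the egusi parent, the suppressor's
homozygous-recessive class cannot occur at all — the suppressor is invisible
in that population and the main locus segregates 1:1. `enumerate_ratio()`
derives these ratios exactly by enumerating unlinked genotype-class
frequencies; `make_cross()` reproduces them stochastically; the agreement of
the two routes is a standing property test.

The default parent fixtures are `B3 = aa BB` (egusi donor), `X1625 = AA bb`
and `B4 = AA BB`. The `B4` assignment deserves a note: its narrative origin
(selected from a backcross-derived line with thick seed coats) would suggest
it could carry *eg*, but `AA BB` is the only homozygous assignment that is
simultaneously consistent with a non-egusi F1, a 1:1 backcross, a 3:1 selfed
backcross, and chromosome-6 mapping in crosses to B3. We adopt it as the
package default and treat the narrative tension as outside the model's
scope.

## The cross simulator

Individuals are represented as two "origin tracks" per chromosome —
run-length encodings of which founder line each homolog segment descends
from. Meiosis uses the Haldane model: crossover counts are Poisson with mean
equal to the chromosome's genetic length in Morgans, with no interference,
and positions are uniform along the chromosome. The cM–bp map is linear per
chromosome; nothing in the pipeline depends on map non-linearity, and no
interference model is asserted by the data the package emulates. The default
genome is 11 chromosomes × 36.5 Mb × 82.2 cM (total ≈ 904 cM, matching the
published total map length); every piece of it is configurable through
`genome_spec()`.

Pooled sequencing is modeled in two stages: the pool's true donor-allele
frequency at a SNP is the mean allelic dosage over the pooled plants divided
by two; read depth is Poisson(`mean_depth`) and donor-allele reads are
Binomial(depth, f(1−e) + (1−f)e). The default error rate is 0 — depth noise
and composition noise dominate pooled designs, and a symmetric error rate
simply shrinks Δ(SNP-index) toward 0 without changing the structure of any
test. What the generator deliberately does *not* emulate: read mapping
artifacts, allele-specific bias, variable per-site depth profiles,
segregation-distorting loci, and phenotyping error. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean
generative model, not robustness to real-data pathologies.

## BSA-seq scanning

Per SNP, the pool's SNP index is `alt/(ref+alt)` with the donor (B3) allele
as alt; Δ(SNP-index) is the egusi-pool index minus the other pool's index.
Windows of 250 kb advance in 5-kb steps, anchored at multiples of the step
from position 0 and half-open, which is what makes region boundaries land on
the 5-kb grid. A window needs `min_snps = 3` SNPs to be defined (the
published analysis is silent here; three is the smallest count for which a
mean is more than an anecdote). Significance is two-sided on |Δ|, with the
sign reported.

**The permutation null.** The per-window threshold is the empirical 99%
quantile of |window-mean Δ| over 1,000 Monte-Carlo replicates, conditioned
on the observed per-SNP depths. Each replicate draws each pool's
*composition* once — under a BC1 design each of the m plants carries 1 or 2
donor alleles with probability ½; under an F2, 0/1/2 at ¼/½/¼ — and then
draws per-SNP read counts binomially at that frequency. Composition is drawn
once per window rather than independently per SNP for a structural reason:
a pooled library is a single draw of m plants shared by every SNP it covers,
and SNPs 250 kb apart are, for mapping purposes, completely linked
(≈ 0.3 cM under the default map). Composition noise therefore does not
average out across the SNPs of a window, while read noise does. A per-SNP
null would understate the window-mean variance roughly s-fold (s = SNPs per
window) and flag a large fraction of truly null windows. With the shared
draw, the null matches the data-generating process: across replicate null
genomes the observed exceedance rate at 99% confidence sits at ≈ 1%
(recomputed by both the test suite and `scripts/acceptance.R`).

One consequence worth knowing: exceedance clusters. Pool composition is
shared chromosome-wide, and its autocorrelation decays only over tens of
centimorgans, so when a null chromosome exceeds its thresholds it tends to
do so in runs. Calibration experiments therefore count chromosomes ×
replicates — not raw windows — as the effective Monte-Carlo unit when
setting tolerances.

Regions are maximal runs of grid-consecutive significant windows, reported
with the signed peak Δ and its threshold. The thresholds printed for the
original pooled data (0.40–0.42) are functions of that experiment's depth
profile and are not recomputable from published information; the package's
claims about thresholding are calibration and planted-QTL recovery
properties instead.

## Fine-mapping

Genotype calls over an ordered marker panel (`a` = homozygous recurrent
parent, `h` = heterozygous, `b` = homozygous donor) plus phenotypes form a
graphical genotype. Under the single-locus recessive model, an egusi plant
must be `a` at the causal position; a non-egusi plant must be `h` (BC1) or
`h`/`b` (selfed generations, heterozygote fully dominant). Each maximal run
of consistent informative markers is extended outward to the *positions of
the nearest flanking inconsistent markers* — closed at those markers,
clamped to the panel — and the causal interval is the intersection of all
plants' allowed sets, reported as a marker-flanked interval. Placing
boundaries at flanking marker positions (rather than, say, midpoints)
reproduces marker-bounded interval reporting as practiced: the chromosome-6
chain of 452.7 kb → 209.3 kb → 15.7 kb falls out of exactly this rule
applied to the panel positions and breakpoint structure.

Missing calls are transparent: a breakpoint next to a missing call is
localized between the nearest informative markers. Plants whose informative
calls are all inconsistent with their phenotype (an empty allowed set) are
excluded from the intersection and reported by id rather than failing the
run — the same handling the original mapping applied to its one
genotype-phenotype-inconsistent plant. A panel-wide conflict (empty global
intersection among individually-consistent plants) is an error that names a
conflicting pair. `narrow_interval()` is checked against a brute-force
oracle that tests every candidate position against every plant directly
from the quantifier definition of "allowed".

Marker QC mirrors standard pre-mapping hygiene: drop markers with > 50%
missing calls or with segregation distortion at χ² P < 0.05 against the
design ratio (1:1 for BC1, 1:2:1 for selfed).

## Segregation testing

`chi_square_gof()` is the plain Pearson statistic with expected counts from
the hypothesis weights, df = k−1, upper-tail P, and **no continuity
correction** — the form that reproduces all five published χ²/P pairs to
four decimals (a Yates-corrected 52:47 vs 1:1 would give 0.1616, not the
published 0.2525). Values are reported to four decimals, matching the
published precision. `rank_models()` orders hypotheses by χ² (ties by
label) and calls a hypothesis compatible at P ≥ α, α = 0.05 by convention.

## CAPS/dCAPS screening

Restriction-site feasibility is evaluated on the forward strand with IUPAC
expansion, with non-palindromic patterns additionally tested as their
reverse complement (all seven built-in enzymes happen to be palindromic,
so the extra test is defensive). A CAPS exists when site presence — over
all pattern placements overlapping the SNP — differs between the alleles.
When it does not, `design_dcaps()` searches placements overlapping the SNP
for at most `max_mismatches` (default 1) base changes strictly 5′ of the
SNP (the primer region) such that, after modification, a site overlapping
the SNP exists in exactly one allele. Presence is assessed amplicon-wide
across overlapping placements, so a design can work either by creating a
site in one allele or by destroying one of two shifted sites; sites that do
not overlap the SNP are ignored since they appear in both alleles and cut
both amplicons identically. Minimal-mismatch solutions win; ties prefer the
placement starting nearest the SNP, then the leftmost. Primer
thermodynamics (Tm, GC content, secondary structure) are deliberately out
of scope.

## Numerical and reproducibility choices

* Coordinates are 1-based inclusive everywhere internally; conversion to
  0-based half-open happens only at BED export.
* kb widths are rounded to one decimal; χ² and P to four, matching the
  precision of the quantities they reproduce.
* All stochastic entry points take a `seed`; window thresholds derive a
  per-window sub-seed so results are independent of evaluation order.
  Fixed seed ⇒ bit-identical populations, count tables and thresholds.
* Zero-depth records are undefined for SNP-index purposes and are dropped
  before scanning; windows below `min_snps` are reported but never
  significant.

## Problem sizes used by the checks

The test suite and acceptance script verify the stochastic properties at
deliberately chosen sizes: F2 phenotype ratios at n = 16,000 (3·SE band
around 3/16); backcross ratios at n = 2,000–10,000; null calibration over
20 replicate 11-chromosome genomes of 2.5 Mb per chromosome with
non-overlapping 250-kb windows (≥ 2,000 defined windows, 1,000 permutations
each); planted-QTL recovery over 20 replicates of a genome with an 8-Mb
chromosome 6 (locus at 7.0 Mb) and 2-Mb background chromosomes, pools of
20 vs 20 at 30× depth; oracle equivalence over 200 random panels and
hundreds of random SNP contexts. Simulation sizes are scaled so the whole
battery runs in minutes on a single core while keeping every Monte-Carlo
tolerance at 3·SE of the quantity under test.

## Known limitations

* The epistasis model is fully penetrant; incomplete penetrance and
  phenotyping error are not modeled (and the fine-mapper's
  inconsistent-plant reporting is the only concession to them).
* Exact ratio enumeration requires unlinked model loci; linked-locus
  segregation is refused rather than approximated.
* The permutation null conditions on observed depths and assumes the
  design's genotype frequencies; strong segregation distortion in a real
  population would shift both Δ and its null.
* dCAPS proposals are combinatorial, not thermodynamic: a proposed primer
  is a site-logic solution, not a validated oligo.
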