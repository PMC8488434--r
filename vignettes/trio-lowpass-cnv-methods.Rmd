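---
title: "Methods: trio-based rare CNV analysis from low-pass genome sequencing"
author: "triocnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio-based rare CNV analysis from low-pass genome sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`triocnv` implements read-depth copy number variant (CNV) analysis for
trio-based low-pass genome sequencing: a fetus (proband) and both
parents sequenced to roughly 0.25-0.3-fold depth (about 15-18 million
single-end 50-bp reads on a 3-Gb genome), binned into windows, and
screened for rare deletions and duplications whose mode of inheritance
(de novo vs maternal/paternal/biparental) drives clinical weight.

The observation model is simple and deliberate. Uniquely aligned reads
are deposited into non-overlapping 5-kb *fine* windows; at 0.25-fold a
fine window holds on the order of 25 reads, so counts are close to
Poisson. The expected count of window $w$ is

$$\mu_w \propto m_w \, b(\mathrm{gc}_w) \, \frac{c_w}{2},$$

with mappability $m_w$, a smooth GC bias $b(\cdot)$, and $c_w$ the
expected copy number: inside an event present in a fraction $f$ of
cells with variant copy number $v$, $c_w = f v + (1-f)\cdot 2$;
elsewhere the diploid (or sex-chromosome) baseline. After GC correction
and panel normalization the *copy ratio* of a window has expectation
$c_w/2$: 1 for diploid, 0.5 for a constitutional heterozygous
deletion, 1.5 for a three-copy duplication, 0.75 for a 50% mosaic
deletion. Inverting this gives the mosaic level estimate used
throughout:

$$\hat f = \frac{2\,\lvert \bar r - 1\rvert}{\text{copies changed}},
\qquad \hat f \in (0, 1].$$

Reporting happens on a 50-kb *sliding* grid advanced in 5-kb steps;
every sliding window is exactly the mean of its 10 fine windows, so
the two grids never disagree about counts.

# The synthetic data generator

No patient data ship with the package; every stage is exercised
against a generator whose defaults encode the targeted study design:

* depth 0.25-fold (reads per sample = `depth * genome / read_length`),
  read length 50 bp;
* Poisson counts (a negative-binomial overdispersion hook exists but
  defaults off, so tests have an exact variance oracle);
* a smooth quadratic GC bias `1 + b1(gc-0.5) + b2(gc-0.5)^2` with
  gentle defaults `(0.3, -1.5)` -- strong enough that an uncorrected
  pipeline fails, weak enough to be invertible by median scaling;
* a GC field simulated as an AR(1)-smoothed Gaussian clamped to
  [0.3, 0.7] -- autocorrelated like real genomes, featureless
  otherwise;
* a reference panel of 2,000 samples, the scale of the population
  datasets the rarity and U-test screens assume;
* Mendelian transmission: each parental heterozygous event passes to
  the proband independently with probability 1/2; two transmitting
  carriers at one deletion locus produce a homozygously deleted
  proband.

One global seed drives everything through named sub-streams (one per
sample), so any individual sample is reproducible regardless of how
many others are simulated. Truth intervals snap outward to fine-window
boundaries, the physical resolution limit of read-depth calling.

What the generator does *not* emulate -- and therefore what green
tests do not certify on real data: wave artefacts and mappability
holes, segmental duplications and reference gaps, batch- and
library-specific GC curves, maternal cell contamination, and alignment
errors. The simulator validates the pipeline's statistics, not its
robustness to every artefact of real sequencing.

Internally all coordinates are 1-based inclusive (the R/IRanges
convention; BED-style 0-based starts appear only as a companion column
in written tables).

# Windowing, GC correction, normalization, QC

GC correction groups fine windows into 1%-GC bins and rescales each
bin by `global median / bin median`; bins with median zero are masked.
The method is crude by design: it is monotone, robust, and exactly
inverts the simulated bias family, which is what the tests verify
(post-correction stratum medians within 5% under a known 2x bias).

Panel normalization divides a sample's corrected counts by the
per-window panel median (medians resist CNVs in panel members), then
rescales so the *median of per-autosome median ratios* is 1. The
two-stage rescale matters on small genomes: with a whole trisomic
chromosome occupying a third of a desk-scale genome, a plain global
median lands in the background's upper tail; the per-chromosome form
is exact whenever fewer than half the autosomes are aneuploid, and is
indistinguishable from the plain median on genome-scale data.

Quality control is the genome-wide standard deviation of sliding-window
copy ratios, excluding masked windows and aneuploid chromosomes, with
pass defined as SD <= 0.1. Clean 0.25-fold simulations sit near 0.065.
One desk-scale caveat recurs in the tests and analysis scripts: on a
50-Mb simulated genome a realistic multi-event load is a *visible
fraction of all windows*, so true events themselves push the SD past
0.1 -- on 3 Gb the same events would move it by nothing. Multi-event
simulations therefore call with `override_qc = TRUE`; this is a
property of the miniature genome, not of the method.

For XY samples, X and Y are excluded from aneuploidy detection,
segmentation and QC rather than rescaled against the female-dominated
panel; hemizygous-deletion labelling on male X/Y happens in the
fine-grid scan, which needs no baseline. A production deployment would
keep a sex-matched panel subset instead.

# Calling

**Aneuploidy.** A chromosome is flagged when its mean fine-window
ratio deviates from 1 by more than `detection_z` (default 3) standard
errors *and* by at least 0.10 -- half the 20% minimal mosaic level for
large events. The absolute floor prevents a focal CNV from tipping a
whole chromosome on small genomes, and encodes the detection limit the
method claims for chromosome-scale mosaicism. Calls at estimated
fraction >= 0.9 are reported constitutional.

**Coarse segmentation** marks sliding windows where
`|ratio - 1| > detection_z * MAD_w`, with the per-window MAD taken
from the panel's own sliding ratios; marked windows of one direction
that overlap or abut merge into clusters. A cluster becomes a segment
only if it contains a run of at least `min_marked_run = 10`
*consecutive* marked windows -- one full sliding span. The rationale:
any real event at the 50-kb reporting resolution contains at least one
sliding window composed entirely of deviant fine windows and in
practice marks ~13 consecutive windows (partial-overlap neighbours
join), whereas noise excursions of the 10-window moving average --
which are strongly autocorrelated -- rarely persist a full span. On
white-noise profiles at z = 3 this yields zero segments in >= 95% of
runs; a plain mark-and-merge rule would not (about 27 expected marks
per 10,000 windows).

**Breakpoint refinement** fits a two-segment step to the *fine* ratios
around each coarse boundary and moves the boundary to the fine-window
edge maximizing the CUSUM-weighted mean contrast
$\sqrt{n_1 n_2 / n}\,\lvert \bar r_1 - \bar r_2 \rvert$ (the plain
contrast is maximized by tiny noisy edge groups). The search reaches
`refinement_span` (100 kb) outward and *to the segment midpoint*
inward, because merged clusters overshoot true boundaries by however
far marked windows extend past the event. Ties resolve to the edge
closest to the coarse boundary, so a flat profile leaves the segment
unchanged and a noiseless step is recovered exactly. On constitutional
events at 0.25-fold the median boundary error in the test suite is
0-5 kb (tolerance asserted: <= 10 kb). On mosaic events the step is
shallower and individual boundaries are noisier, but the region mean
-- and hence the mosaic level -- remains accurate.

**Typing.** Losses with mean ratio < 0.25 are homozygous deletions
(two copies changed), gains above 1.75 triplications; the cut points
are midpoints between the adjacent constitutional expectations.

**Homozygous/hemizygous deletions** are additionally scanned on the
fine grid as maximal runs of >= 2 consecutive windows with ratio in
[0, 0.1] (>= 10 kb at the defaults), labelled hemizygous on male X/Y.
This run-length rule is exact and closed-form, so the test suite
checks it against a brute-force scan over all window runs.

**Mosaic gate.** Calls are kept only at estimated fractions >= 30%
(events < 2.5 Mb) or >= 20% (>= 2.5 Mb) -- the claimed detection
minima; anything below is indistinguishable from noise at this depth.

**Statistical screens.** Each surviving call carries three p-values:

1. *population U-test*: the proband's region-mean ratio ranked among
   the panel samples' region means, as an exact two-sided one-vs-N
   rank (permutation) p-value, `2 * min(rank, N+2-rank) / (N+1)`. The
   floor is `2/(N+1)`, so the default `filter_alpha = 1e-3` is
   attainable exactly when the panel reaches ~2,000 samples -- the
   population scale this screen presupposes. A normal-approximation
   rank test is *wrong* for n1 = 1, hence the explicit form.
2. *whole-sample t*: Welch t of the region's fine ratios against all
   other autosomal fine ratios;
3. *whole-chromosome t*: the same against the remainder of the call's
   chromosome.

A call is kept iff all three p <= 1e-3 (per call, no multiplicity
correction: these are screens, not inference). The U-test is what
removes common copy number polymorphisms: a locus deleted in half the
panel leaves the proband's region mean in the middle of the panel
distribution. Screens run *after* refinement (better region means on
refined boundaries); the fine-grid homozygous-deletion calls are
merged in afterwards with their p-values reported but not gated -- a
two-window region gives a Welch t with ~1 degree of freedom that can
never reach 1e-3, and the run-length rule is itself the screen at that
scale. Regions the panel does not cover are flagged not-evaluable and
retained.

# Trio inheritance

Proband calls are matched to parental calls by same direction class
(loss vs gain) and reciprocal overlap >= 0.5 -- the field's standard
concordance criterion -- with ties broken by size similarity. Matched
in one parent: maternal/paternal; in both: biparental.

An unmatched call is labelled de novo only after interrogating the
parents' *raw coverage*: a transmitting parent carries one changed
allele, so its expected region deviation is the proband's deviation
divided by the copies changed (half for het events, exactly half again
for a homozygous deletion, whose carrier parents sit at ratio 0.5).
The no-evidence band is half that expected single-allele deviation; a
parent deviating beyond it in the event direction *rescues* the call
as inherited (flagged `rescued`). This guards against the costliest
error -- a parental call missed by thresholding would otherwise
promote an inherited variant to de novo, and de novo status is what
escalates clinical action. Both-parent rescue yields biparental, which
is how a homozygous proband deletion with two uncalled het carrier
parents (the thalassaemia-style case in the analysis scripts) resolves.

Rarity: a call is rare iff no frequency-table locus of the same class
matches it (same 0.5 reciprocal-overlap semantics) with carrier
frequency >= 1%. "Allele frequency" is operationalized as *carrier*
frequency among panel samples -- read-depth calls are unphased, so
true allele counts are unavailable; this is documented divergence, not
oversight.

# Clinical classification

Full point-based ACMG CNV scoring requires curated external evidence
(dosage maps, literature, case databases) that this package
deliberately takes as *input flags*, never fetches. Classification is
a five-outcome deterministic cascade: loss over a haploinsufficient
disease gene (or gain over a triplosensitive one) is pathogenic when
de novo or inside a configured syndrome region, else likely
pathogenic; any other disease-gene overlap is VUS; with no disease
gene, a configured benign-region match is benign, inherited calls are
likely benign, and de novo remainders are VUS. Missing inheritance is
an error -- the premise of trio analysis is that interpretation
without it is unsafe. The cascade is total (exhaustively enumerated in
the tests) and every decision records its rule codes.

Nomenclature follows the ISCN/HGVS-flavoured reporting style
`seq[GRCh37/hg19] del(9)(q34.3)dn chr9:g.140608441_140673160del`,
with multi-band spans joined first-band-last-band with no separator,
`dn` appended for de novo calls, and sub-constitutional mosaic levels
bracketed at two decimals (`del[0.5]`). The grammar is lossless: a
parser ships with the package and the tests round-trip random calls.

# Cohort statistics

Incidences are reported with Wilson score intervals without continuity
correction (closed form, hand-implemented; base R has none). The 2x2
comparisons use Pearson chi-square without continuity correction
(routed to Fisher's exact test on zero margins), Fisher's two-sided
p-value being the sum of table probabilities no larger than the
observed one -- conventions differ, so this one is stated.
Kruskal-Wallis uses the tie-corrected H with a chi-square reference;
all-identical input returns H = 0, p = 1 with a warning rather than
NaN. Dual-route checks in the tests pin these to independent oracles:
chi-square against the squared two-proportion z statistic, Fisher
against full hypergeometric enumeration for n <= 30.

The cohort summary mirrors the referral-indication table shape of
prenatal studies: per indication and overall, cases with >= 1 rare
CNV, total rare CNVs and per-case rate, de novo cases/counts,
small (< 100 kb) or mosaic (< 0.9) calls, calls requiring parental
analysis, and diagnostic (P/LP) yield with its Wilson interval.
Report rendering rounds percentages to two decimals and per-case rates
to two in tables and one in prose.

# Problem sizes, determinism, degenerate inputs

The test and analysis configurations use a 50-Mb single-chromosome
genome (10,000 fine windows) at 0.25-fold with a 2,000-sample panel --
large enough that every statistic operates in its intended regime,
small enough that the full suite simulates hundreds of samples in
minutes. Performance suites: 100 single-event replicates (100 kb-2 Mb,
recall and boundary error), 20 replicates of the 1-Mb 50% mosaic
deletion (fraction recovery +/- 0.05), 20 simulated trios (de novo
precision/recall >= 0.9). Panel dispersion is estimated from a
200-sample subset (the MAD stabilizes long before that; the full
matrix is kept only for the U-test).

Degenerate inputs are errors, not guesses: mosaic level at ratio 1 is
undefined; GC correction refuses all-zero counts or < 100 usable
windows; QC refuses < 100 windows; classification refuses missing
inheritance; zero-margin tables are routed to Fisher. Masked windows
propagate as `NA` and a sliding window needs >= 8 of its 10 fine
windows unmasked. All randomness flows from explicit integer seeds
through named sub-streams.

# Known limitations

* Sensitivity claims stop at the stated mosaic minima; nothing below
  20-30% mosaicism is recoverable at this depth, by design.
* Y-chromosome analysis needs a male panel subset that the bundled
  desk-scale panels do not provide.
* Balanced rearrangements, insertional translocations and the
  orientation of gains are invisible to read depth and out of scope.
* The GC correction and normalization are validated by simulation
  against their own bias family, not by equality with any external
  implementation.
* Categories other than the cascade's worked paths rest on the input
  dosage flags; the package never audits those flags against external
  databases.
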