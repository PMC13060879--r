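---
title: "Models and methods in mpramap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mpramap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A massively parallel reporter assay (MPRA) measures the regulatory
activity of thousands of candidate sequences in parallel. Each candidate
oligo is linked to many random 15 bp barcodes; after delivery (here, the
lentiviral flavor usable in neurons), barcodes are counted in the DNA
fraction (what went in) and the RNA fraction (what was transcribed). A
sequence's activity is the RNA/DNA barcode ratio, and questions about
cis-regulatory elements (CREs) and variant effects become comparisons of
these ratios. `mpramap` covers the computational side of such a locus
study end to end: library design, barcode association, activity
quantification against a scrambled-control null, CRE calling, and
allele-effect classification, with a synthetic-data generator that makes
every stage testable against known truth.

# Coordinates and sequence handling

All in-memory coordinates are 1-based inclusive, the convention every
printed genomic span uses; lengths are `end - start + 1`. Conversion to
BED's 0-based half-open convention happens only in `read_bed()` /
`write_bed()` (delegated to rtracklayer), so no arithmetic elsewhere needs
to know about it. A span such as chr17:45,894,271–45,894,297 can be
described as 27 bp (inclusive) or 26 bp (exclusive); both conventions
appear in practice for the same span, so `interval_length()` exposes both
and the package asserts neither as canonical.

N bases are accepted in input genomes, but any designer whose window
contains an N skips that window with a logged report: enumerating
"alternate bases" of N is undefined, and a scramble or deletion of an N
window would silently test a different composition than intended.

# Library design rules

**Tiling** (`design_tiles`): fixed-length oligos (default 270 bp) start at
the region start and every `step` (default 90 bp) thereafter while the
window fits, emitted once per strand; the minus-strand oligo is the
reverse complement of the same genomic window. Interior bases are
therefore covered by `2 * tile_len / step` = 6 oligos at the defaults.
Windows are never shifted to fit; a region shorter than one tile is an
error.

**Saturation mutagenesis** (`design_saturation`): for every base of the
target region, five oligos — the centered reference window (odd length,
default 219 bp, so the center is position `(len + 1) / 2` with equal
flanks), the three alternate bases at the center, and the reference window
with a centered 5 bp deletion (center ± 2 removed; 214 bp). "Centered"
is taken as symmetric removal — the only centering that leaves equal
flanks. Positions whose window would leave the contig are skipped rather
than shifted, because shifting would silently break the centering
invariant; edge behavior is reported in the `"skipped"` attribute.

**Known variants** (`design_variant_oligos`): SNVs get a 219 bp pair with
the variant base centered. A deletion of k bases gets a reference oligo of
219 bp (k odd) or 218 bp (k even), chosen so the deleted span sits with
exactly equal flanks `(ref_len - k) / 2`; the alternate is the reference
minus the span. Insertions mirror this rule on the alternate side: the
allele carrying the insertion is 219 bp for odd k and 218 bp for even k
with the inserted bases centered, and the reference is that length minus
k. The even/odd-to-length mapping for insertions is not forced by the
deletion rule; the mirror assignment was adopted because it keeps "the
odd-parity allele is full length" uniform across variant types, and it is
recorded in the design manifest. Under this scheme flanks are always
exactly equal, so no 3'/5' asymmetry ever arises. Indels over 10 bp and
variants with allele count 0 are rejected with machine-readable reasons
(`indel_gt_10`, `ac_zero`); VCF-anchored alleles are normalized internally
while `variant_key` keeps the caller's spelling for joins. Variants at or
above an allele-frequency threshold are represented twice
(`apply_replicate_rule`). The threshold is configurable (default 1.0 on
the table's frequency scale) because "frequency of 1 or more" is
ambiguous between a proportion and a percentage; with the default, only
fixed variants qualify, and users with percent-scaled tables should pass
`af_threshold = 1` on that scale.

**Scrambled controls** (`make_scrambles`): each control is a seeded
permutation of a source oligo's bases, so GC (indeed full composition) is
matched exactly rather than approximately; at least one scramble exists
for every distinct oligo length in the pool, so length never separates
controls from tested sequences; optionally the first few scrambles get
three center-base-substituted siblings, mirroring how tested variants
differ from their references. All designers are pure functions of
(genome, parameters, seed).

# Barcode association

Fragment-mode libraries (sheared-BAC style) are assigned to 100 bp
non-overlapping bins by the fragment midpoint. For even-length fragments
the midpoint is taken as the lower of the two central coordinates
(`floor((start + end) / 2)`): a deterministic, strand-free tie-break.
Oligo-mode libraries keep only alignments whose CIGAR is a single match
run exactly equal to the designed length (`219M`, `218M`, ...), which
discards clipped, gapped, and wrong-length matches in one rule. Barcodes
observed for more than one element are removed absolutely — no plurality
rescue — because a barcode whose majority element is wrong poisons that
element's ratio silently. The builder returns a filter-accounting report
whose categories partition the input records exactly; a conservation test
enforces this. Minimum read support per barcode defaults to 1
(no support filter) and is configurable.

# Activity model

Counts are normalized to counts-per-million per (fraction, replicate)
column; a zero column is an error naming the column. Element activity per
replicate is the ratio of sums over the element's barcodes with a
pseudocount (default 1.0) on both numerator and denominator; ratio-of-sums
rather than mean-of-ratios, so a barcode with near-zero DNA cannot
contribute an unbounded ratio. Replicates are combined by geometric mean
(equal weights), i.e. `log_alpha` is the mean of per-replicate log ratios.

Significance uses a robust empirical null built from the scrambled
controls: `mad.score` is the element's log activity standardized by the
null median and 1.4826·MAD (the consistency-scaled median absolute
deviation), and `pval.mad` is the upper-tail standard-normal probability
of that score, floored at 2.2e-16. The parametric normal tail (rather than
an empirical percentile) is what makes p-values far below `1/n_null`
meaningful, which is precisely what a floor of 2.2e-16 presupposes. The
test is one-sided for activation by default, since the screening question
is positive regulatory activity; `two_sided = TRUE` is available.
Benjamini–Hochberg adjustment is computed over the tested (non-control)
elements; controls receive scores but are not part of the family, since
they are the null sample itself. At least 20 nulls are required, and a
zero null MAD (e.g. all controls identical) is an error rather than an
infinite score. For strand-tiled designs, forward and reverse oligos of a
window are combined before calling: mean of strand log activities, pooled
barcode counts, significance recomputed on the combined value; windows
with one strand missing pass through flagged.

# CRE calling and annotation

Significant elements are joined left-to-right, merging on overlap or a gap
of at most `adjacency_gap` bp. The default gap 0 makes abutting 100 bp
bins ("consecutive") merge while a single intervening non-significant bin
breaks the run; tiles at a 90 bp step overlap by 180 bp, so overlap
merging suffices there. Whether one intervening non-significant bin should
be tolerated is a judgment call; the gap parameter exposes it rather than
hard-coding it. Merging is idempotent and equals an interval-union oracle
by construction (and is cross-checked against `GenomicRanges::reduce` in
the tests). cCRE annotation is any-overlap; when several classes overlap
one CRE, the promoter-most class wins by the fixed precedence PLS > pELS >
dELS > CA-H3K4me3 > CA-TF > CA-CTCF > CA > TF. The precedence is a package
choice (annotation sources report tallies without a tie rule); all
overlapping classes are retained alongside the winner so no information is
lost.

# Variant effects

The per-variant effect is the mean over replicates of the difference of
log activities, alt minus ref — natural log by default with a `log_base =
2` switch, recorded in output, since fold-change bases differ across
tools. The default test is a two-sided one-sample t-test on the replicate
differences; a seeded barcode-permutation test is available for designs
with few replicates but many barcodes. SNVs and InDels form separate BH
families so the longer indel oligos cannot distort the SNV family. Calls
are effect-size gated: gain iff `adj_p <= 0.05` and `logFC > 0.1`, loss
iff `adj_p <= 0.05` and `logFC < -0.1`, otherwise not significant; the
0.1 cutoff is strict (`>`, not `>=`). Sharing between two
cell types: shared requires a call in both with the same direction;
discordant is a call in both with opposite directions; otherwise
cell-type-specific or none. Window summaries count calls whose focal
position lies inside a window (inclusive coordinates) — the shape of
"how many effects fall in the high-occupancy-target region" questions.

The motif-disruption score is a deliberately simple single-PWM analogue of
motif-disruption screens: best log2-odds hit (uniform background,
probabilities clipped at 1e-6 before logging) over all offsets and both
strands, alt minus ref; negative means disruption. Because every window
score shifts equally under a background change, the delta is invariant to
it. External per-variant score tables (e.g. sequence-model predictions)
are joined on `variant_key`; agreement is Spearman's rho with average
ranks and the t-approximation p (via `cor.test(exact = FALSE)`), plus the
sign-concordance fraction among called effects. Unmatched keys are
returned, never silently dropped.

# The synthetic-data generator

The generator emulates the statistical structure of MPRA count data, not
its molecular detail. Per element, a truncated-Poisson number of barcodes
(mean `lambda_bc = 10`, min 1 — a typical post-filter association yield);
per barcode, a log-normal abundance (`sigma_d = 0.5`, the spread cloning
and amplification impose on DNA representation); per replicate, Poisson
DNA counts around the replicate's share of a 1e6 expected total depth, and
negative-binomial RNA counts with mean equal to the DNA scale times
`exp(true activity)` and dispersion `phi = 0.1` (size 10), the standard
overdispersed-count model for expression readouts. Three replicates by
default. The activity landscape — baseline, planted enhancer intervals
with log-unit effects, planted per-variant logFC — is declared up front
and emitted as a first-class truth table, so recovery tests never reach
into simulator internals. Planted effect sizes of ±0.5 log units sit
safely above the 0.1 decision threshold while remaining realistic for
regulatory variants.

What the generator does not emulate: sequencing error and barcode
misassignment, position-dependent GC or mappability bias, replicate batch
effects, integration-site effects of lentiviral delivery, and any
correlation between neighboring elements beyond what the landscape
plants. Tests passing on this model therefore demonstrate that the
estimators and calling rules are correct and calibrated under clean
overdispersed counts — not that they are robust to artifacts real
libraries can carry.

# Numerical choices and problem sizes

Degenerate inputs fail loudly: zero-count library columns, zero null MAD,
fewer than 20 nulls, regions shorter than a tile, zero-depth replicates.
Ties and parities are fixed deterministically (lower-central midpoints,
equal-flank centering, promoter-most annotation precedence). All
randomness flows through explicit seeds, restored after use, so package
calls never disturb the caller's RNG stream.

The test suite exercises the statistical properties at sizes chosen to
make binomial bounds tight while keeping the default run fast: 2,000
true-null elements for calibration (99% binomial bounds at nominal 0.01 /
0.05 / 0.1), 200 planted variants for logFC recovery (sign accuracy and
RMSE), 1,000 random instances for the interval-union oracle, and a full
default-configuration pipeline run (two cell types, ~600 oligos, depth
1e6) as the end-to-end check. The pipeline default configuration is the
package's standard study condition set and is written out as
`resolved_config.yaml` with every run; its summary numbers are recomputed
from the stage files each time, never cached.

# Known limitations

The activity estimator is a fully specified ratio-of-sums/geometric-mean
pipeline, not a generative count model: it does not borrow strength
across elements, model barcode-level dispersion, or shrink estimates, so
confidence at very low barcode counts is optimistic compared to
model-based MPRA tools. The replicate t-test has few degrees of freedom
at 3 replicates; the permutation alternative trades that for barcode-level
exchangeability assumptions. The motif score handles one PWM at a time
and uniform backgrounds only. cCRE annotation is binary any-overlap,
ignoring overlap fraction. None of the wet-lab-dependent headline tallies
of any particular study can be reproduced from synthetic data; what the
package guarantees is that, given counts with the declared structure, its
design rules, filters, and statistics behave exactly as specified here.
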