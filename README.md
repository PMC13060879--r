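# mpramap

Design and inference for massively parallel reporter assays (MPRAs).

MPRAs test thousands of candidate regulatory sequences at once: each
candidate is cloned upstream of a reporter and tagged with random 15 bp
barcodes, and its activity is read out as the abundance of its barcodes in
the RNA fraction relative to the DNA (delivered plasmid) fraction.
`mpramap` implements the full desk side of such a study of cis-regulatory
elements (CREs) and variant effects at a locus:

- **Library design** — strand-tiled oligos (270 bp every 90 bp on both
  strands, giving 6x interior coverage), per-base saturation mutagenesis
  (for every position: a centered 219 bp reference oligo, the 3 alternate
  bases, and a centered 5 bp deletion), known SNV/InDel variant pairs with
  the parity-aware centering rule (reference oligos of 219 bp for
  odd-length deletions, 218 bp for even, so the deleted span has equal
  flanks), and GC-matched scrambled negative controls.
- **Barcode association** — barcode-to-element dictionaries from
  association sequencing: 100 bp locus bins with midpoint assignment for
  sheared-fragment libraries, exact CIGAR-length matching (`219M`, `218M`,
  ...) for designed-oligo libraries, and absolute removal of barcodes seen
  for more than one element.
- **Activity quantification** — counts-per-million normalization,
  ratio-of-sums activity per element and replicate
  `alpha_r = (sum RNA + c) / (sum DNA + c)`, and a robust empirical-null
  test against the scrambled controls:

  ```
  mad.score = (log alpha - median(log alpha_null)) / (1.4826 * MAD(log alpha_null))
  pval.mad  = upper-tail normal probability, floored at 2.2e-16
  ```

  with Benjamini–Hochberg adjustment; elements with `pval.mad <= 0.05` are
  called active.
- **CRE calling** — overlapping and consecutive significant bins/oligos
  are joined into CREs, compared across cell types, and classified against
  ENCODE cCRE annotations (PLS > pELS > dELS > CA-H3K4me3 > CA-TF >
  CA-CTCF > CA > TF precedence).
- **Variant effects** — per-variant `logFC = mean_r(log alpha_alt,r -
  log alpha_ref,r)` with a replicate t-test (or barcode permutation),
  separate BH families for SNVs and InDels, gain/loss calls at
  `adj. p <= 0.05` and `|logFC| > 0.1`, cross-cell-type sharing with
  shared directionality, genomic window summaries, a PWM log-odds
  motif-disruption score, and Spearman agreement with external
  per-variant scores.
- **Synthetic data** — toy genomes, variant tables, and DNA/RNA barcode
  counts from a declared noise model (log-normal DNA abundance, Poisson
  DNA counts, negative-binomial RNA counts, truncated-Poisson barcodes per
  element) over a known activity landscape, with first-class truth tables.

## Worked example

```r
library(mpramap)

genome <- make_toy_genome(10000, seed = 1)
region <- genomic_interval("chrS", 1, 10000)

# strand tiling: 109 windows per strand, 6x interior coverage
tiles <- design_tiles(region, genome, tile_len = 270, step = 90)
nrow(tiles)
#> [1] 218

# saturation mutagenesis over a 300 bp window: 5 oligos per position
sat <- design_saturation(genomic_interval("chrS", 3001, 3300), genome)
table(sat$allele_class)
#>
#>    del5     ref snv_alt
#>     300     300     900

# a 2 bp deletion gets a 218 bp reference oligo; 3 bp gets 219 bp
cs <- as.character(genome[[1]])
del2 <- data.frame(chrom = "chrS", pos = 5000L,
                   ref = substr(cs, 5000, 5002), alt = substr(cs, 5000, 5000),
                   AC = 3L, AF = 0.01)
design_variant_oligos(del2, genome)$oligos$length
#> [1] 218 216

# simulate counts over a planted landscape and test activity
scr <- make_scrambles(tiles, n = 150, rng_seed = 2)
design <- rbind(tiles, scr[names(tiles)])
land <- activity_landscape(enhancers = data.frame(
  chrom = "chrS", start = 2000, end = 2400, effect = 2))
sim <- simulate_counts(design, land, default_noise_model(), seed = 3)
act <- element_activity(normalize_counts(sim$counts))
is_null <- act$element_id %in% sim$truth$element_id[sim$truth$is_null]
res <- mad_test(act[!is_null, ], act[is_null, ])
truth <- sim$truth[match(res$element_id, sim$truth$element_id), ]
c(active = sum(res$active),
  planted_recovered = sum(res$active & truth$true_log_activity > 0))
#>            active planted_recovered
#>                23                10
```

All 10 oligos whose windows have their midpoint inside the planted
enhancer at chrS:2000–2400 (5 tile positions x 2 strands) are called
active; the remaining calls are the nominal false positives expected from
thresholding `pval.mad` at 0.05 over 218 tiles. Filtering on `adj_p`
instead narrows the list to 14 elements, and joining those with
`call_cres()` yields a CRE spanning the planted interval.

The one-call version of the whole chain is
`run_pipeline(default_run_config(seed = 1), out_dir = "run1")`, which
writes the design manifest, per-cell-type activity and effect tables, CRE
BED files, a sharing table, and a JSON summary recomputed from those
files.

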