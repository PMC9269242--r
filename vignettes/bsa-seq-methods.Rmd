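---
title: "Mapping trait loci from extreme-pool resequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping trait loci from extreme-pool resequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsascan)
```

## The method

Bulked-segregant analysis by sequencing (BSA-seq) localises quantitative
trait loci by sequencing two pooled DNA samples drawn from the phenotypic
extremes of a population — here emulating a design in which 49 accessions
with extremely high and 49 with extremely low seed tocopherol content were
bulked out of a 1525-accession soybean panel and resequenced at roughly 40×
per pool.

At every biallelic site the **SNP/InDel index** of a pool is the
alternate-allele read count divided by the total read count — an estimate of
the pooled allele frequency. The **Δ index** is the difference between the
high and the low pool:

$$\mathrm{index}_p = \frac{\mathrm{ALT}_p}{\mathrm{REF}_p + \mathrm{ALT}_p},
\qquad
\Delta = \mathrm{index}_{\mathrm{high}} - \mathrm{index}_{\mathrm{low}}.$$

Away from any trait locus the two pools are random draws from the same
population and $\Delta$ fluctuates around zero; near a causal locus the
extreme-phenotype selection drives the pools toward opposite alleles and
$|\Delta|$ approaches one. The scan aggregates $\Delta$ in sliding windows
(2 Mb advanced by 10 kb, by default), computes simulated confidence
intervals per window, and calls candidate regions where the window mean
exceeds an association threshold (default 0.90) *and* leaves its null CI,
consistently in both the SNP and the InDel track.

## Variant filters

Four rules, applied in a fixed and reported order (first match claims the
site):

1. multi-allelic sites;
2. total depth below 4× in either pool;
3. index below 0.3 — interpreted as *both pools below 0.3* (a shared
   sequencing artefact or rare allele; a site with one pool near 0 and the
   other high is exactly the signal the scan looks for, so an either-pool
   reading would discard true positives; `filter_config(low_index_mode =
   "either")` switches the semantics);
4. same inferred genotype class in both pools, operationalised as both
   indices inside the same homozygous band (`< 0.1` or `> 0.9`; the band
   half-width is a package choice, configurable via `hom_band`).

A fifth rule used for cross-derived pools (recessive alleles not inherited
from the recessive parent) has no meaning in a natural population, where no
parents exist; it is available behind
`filter_config(parental_recessive_filter = TRUE)` and off by default.

## The simulated null and its calibration

BSA-seq scans customarily plot depth-aware simulated confidence intervals
around the Δ track, but the construction is rarely spelled out. The package
adopts the natural-population analogue of the QTL-seq simulated null, with
two refinements that measurement on the package's own null world forced:

* **Two-stage resampling.** Under the no-locus null the two bulks are
  still *different* 49-accession subsets, so their true allele frequencies
  differ by bulk-composition sampling (variance $p(1-p)/2n$ per bulk of $n$
  diploid accessions) before a single read is drawn. Each null replicate
  therefore first draws a bulk frequency
  $q^\ast \sim \mathrm{Binomial}(2n,\hat p)/2n$ per pool — $\hat p$ being
  the pooled alternate fraction over both bulks — and then alternate read
  counts $\mathrm{Binomial}(d, q^\ast)$ at the observed pool depth $d$.
  Read-only resampling (available as `scan_config(null_model = "reads")`)
  is measurably anti-conservative: ~13% of null windows fell outside a
  nominal 95% CI in our calibration experiments. With the two-stage null,
  CI width no longer vanishes at infinite depth; it converges to the
  bulk-composition floor, which is the correct behaviour for a pooled
  design.

* **Ascertainment conditioning.** A retained site's observed indices
  passed the filters, so its null replicates are conditioned on passing
  them too (failing replicates are resampled from the passing ones).
  Without this, sites near the filter boundaries contribute only their
  divergent draws to the observed data but their full distribution to the
  null, inflating the outside-CI fraction to ~7–8%. With both refinements
  the measured null coverage is 5–6% outside a 95% CI.

Calibration is asserted on *non-overlapping* windows: with the default
2 Mb / 10 kb grid adjacent windows share 99.5% of their member variants, so
the genome contributes only about (genome length / window size) independent
draws and an empirical fraction over them is statistically meaningless.
The calibration experiment therefore tiles the null genome with 500 kb
non-overlapping windows (1000 of them), which is a choice about how many
independent draws back the estimate, not about the statistic itself.

## Consequence classification

Variants are classified against gene models into the mutually exclusive
categories *exonic, splicing, intronic, upstream/downstream (joint),
upstream, downstream, intergenic*, with precedence in that order when a
variant touches several regions. Definitions: upstream/downstream are the
1 kb flanks of the transcription start/end (strand-aware); splicing is
within 2 bp of an exon/intron junction on the intron side of multi-exon
transcripts; the joint category applies when one gene's upstream flank
overlaps another's downstream flank. The taxonomy carries no UTR class, so
genic positions outside the CDS intervals and their introns are reported
as intronic (genic non-coding) — a documented convention, mirrored by the
brute-force oracle in the test suite so that oracle equivalence tests the
scan logic rather than the convention.

Exonic SNVs are classified by rebuilding the affected codon from the genome
with the variant substituted and translating both codons with the standard
nuclear code (synonymous / non-synonymous / stop-gain / stop-loss). Coding
indels are frameshift when the net inserted/deleted length is not a
multiple of three; in-frame indels fully inside the coding sequence are
additionally checked for immediate stop-codon creation or elimination by
retranslating the edited codon window. Indels spanning a CDS boundary are
assigned exonic by the length rule alone and flagged
(`cds_boundary = TRUE`), since no boundary rule is stated anywhere — the
simplest consistent choice.

## Candidate genes, haplotypes, enrichment

Genes inside a candidate region are ranked by the severity of their worst
variant: frameshift/stop > non-synonymous > other genic > regulatory
(up/downstream), ties by position. The haplotype comparison splits
accessions by their allele at a candidate site and compares the phenotype
between REF and ALT carriers in every environment with Welch's
unequal-variance *t* test — the test behind the original figure is unnamed,
and Welch is the robust default for unequal group sizes; a permutation test
is provided as an independent cross-check and agrees within Monte-Carlo
error in the test suite. Heterozygous accessions are excluded by default
(`include_het = TRUE` pools them with ALT carriers), since their grouping
in the original analysis is unstated.

GO over-representation is the one-sided hypergeometric (Fisher upper tail)
$P(X \ge k)$ with the annotated study-set size $n$ and per-ontology
annotated background $N$. The choice is not arbitrary: enrichment services
print an *Expected* column ($Kn/N$) without publishing $N$; back-solving
$N$ from it (`backsolve_background()`, study set $n = 83$) reproduces such
a report's p-values 0.004, 0.008 and 0.019 exactly at three decimals,
which identifies the statistic behind the service. No multiple-testing correction is applied by default,
matching raw $p < 0.05$ reporting; Benjamini–Hochberg is available behind
`fdr = TRUE`.

## The synthetic world

The generator emulates the stated experiment rather than an arbitrary
benchmark:

* 1525 accessions (mixed cultivar/landrace labels), five location-year
  environments (`A17, B17, B18, H17, H18`), phenotype baseline 230 µg·g⁻¹
  with residual sd 35 µg·g⁻¹ per environment and environment offsets of
  sd 10 µg·g⁻¹ — placing the simulated pool means near the reported
  high/low pool contrast;
* one causal biallelic locus, additive effect 40 µg·g⁻¹ at frequency 0.4,
  i.e. single-environment narrow-sense $h^2 = 2p(1-p)a^2 /
  (2p(1-p)a^2 + \sigma_e^2) \approx 0.39$; selecting extremes on the
  five-environment mean sharpens the effective heritability to ~0.76,
  which is what drives the pools toward near-fixation
  ($\Delta \approx 0.99$ at the locus);
* neutral allele frequencies uniform on [0.05, 0.5], Hardy–Weinberg
  genotypes, site-independent by default;
* pooled reads: depth Poisson(40) per pool per site, alternate reads
  binomial at the error-adjusted pool frequency (symmetric read error
  0.001), equal DNA contribution per accession;
* a desk-scale genome of 20 × 5 Mb with ~120 variants/Mb (15% 1-bp
  indels). The real experiment's ~1 Gb genome and 3.5M SNPs are far beyond
  desk scale; density and genome size only need to give every 2 Mb window
  enough members of both variant classes.

**Block LD mode** (`ld = TRUE`) copies the causal genotype onto flanking
sites within 1.5 Mb with per-accession probability 0.95. Without linkage a
single causal site cannot lift a 2 Mb window mean above the 0.90 threshold
no matter how complete the fixation, because its neutral window-mates
average ~0; the long haplotype blocks of a selfing crop like soybean are
exactly what gives real scans their wide peaks. The block parameters are
chosen so that windows centred on the locus average
$\approx 0.95 \times \Delta_{\mathrm{causal}}$, mirroring scans in which
the peak clears a 0.90 threshold. What the generator does *not* emulate:
genome-wide background LD, population structure and kinship,
multi-locus genetic architecture, reference bias in read mapping, and
caller artefacts — so a green recovery test establishes that the scan
arithmetic and calling logic work under the stated sampling model, not
that the method is robust to those real-data complications.

## Numerical choices and degenerate inputs

* Windows are anchored at base 1 and advanced by the step; tail windows
  truncated at the chromosome end are kept but flagged and excluded from
  region calling, as are windows with fewer than 10 member variants of the
  scanned class (suppresses single-variant spikes; not part of the original
  description).
* The index is undefined at zero depth; `compute_index()` refuses it and
  the depth filter guarantees it never reaches the scan.
* Pool selection breaks phenotype ties by accession id through one total
  ordering, so tied cohorts still yield deterministic, disjoint pools.
* Empirical CI quantiles use the default type-7 estimator; 10,000
  replicates by default, reducible for speed at the cost of CI accuracy
  (tests that do not measure CI accuracy use a few hundred).
* All stochastic stages run under a single seed; re-running a pipeline
  configuration byte-reproduces every output file.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(rng_seed = 1, ld = TRUE)
res <- run_bsa_pipeline(cfg, scan_cfg = scan_config(null_reps = 500))
glance(res)
autoplot(res$scan, chrom = "Chr05")
res$gene_priority
tidy(res$haplotype)
```

## Known limitations

* Per-window CIs are pointwise; no genome-wide multiplicity control is
  applied to the CI criterion (the 0.90 threshold, which the default mode
  also requires, is far stricter than any pointwise band under the null).
* Isoform handling reports per-mRNA and summarises the worst effect;
  canonical-transcript selection is out of scope.
* The enrichment test ignores the GO graph (no term propagation), matching
  the flat gene→term table it consumes.
* The parental-recessive filter and either-pool low-index semantics exist
  but are untested against any cross-derived dataset.
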