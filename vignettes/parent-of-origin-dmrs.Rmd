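---
title: "Calling parent-of-origin DMRs from uniparental disomy and hemizygous deletion designs"
author: "podmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling parent-of-origin DMRs from uniparental disomy and hemizygous deletion designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podmr)
```

## The design

Genomic imprinting leaves parent-of-origin-specific DNA methylation at CpG
dinucleotides. Ordinary case-control bisulfite sequencing cannot attribute
methylation to a parental allele, but two natural experiments can:

* **Uniparental disomy (UPD).** A upd(16)mat individual carries two
  maternal copies of chromosome 16 and therefore exposes the pure maternal
  epigenotype; upd(16)pat exposes the paternal one; a biparental control
  averages the two. At an imprinted locus the three group means are
  expected to be ordered, with the control intermediate.
* **Hemizygous deletion.** A carrier of a heterozygous deletion of the
  maternal allele is hemizygous across the deleted interval: the measured
  methylation there comes entirely from the remaining paternal allele, and
  can be contrasted with dizygous controls that average both alleles.

`podmr` implements region callers for both designs, a targeted re-scan for
small candidate regions that fall below the main size threshold, a simple
run-of-homozygosity screen to corroborate isodisomy from SNV genotypes, and
a synthetic data generator that emulates the allelic structure the callers
assume.

## Site model

The input is a per-sample table of strand-resolved CpG cytosine counts
(methylated `m`, unmethylated `u`) in Bismark cytosine-report or coverage
format. Forward- and reverse-strand cytosines of one dinucleotide are
distinct loci throughout, keyed `(chrom, pos, strand)`; they are measured
independently by the sequencer and are never destranded. Percent
methylation is the raw proportion

$$\beta = 100 \cdot \frac{m}{m + u},$$

undefined (never zero) at zero coverage. No smoothing, normalisation or
beta-binomial shrinkage is applied anywhere: the callers work on raw pooled
proportions and hard thresholds, so every call is directly traceable to the
counts.

## Trio (UPD) mode

`call_blood_dmrs()` proceeds in five steps:

1. **Pool.** Counts are summed at each locus within the `upd16mat`,
   `upd16pat` and `biparental` categories; pooling trades per-sample
   resolution for coverage. Per-sample counts are retained for the
   concordance filter.
2. **Intersect.** Only loci with pooled coverage of at least one read in
   *every* category are analysed. Representation is judged on the pooled
   category, not per sample, because pooling precedes the intersection.
3. **Classify.** A locus qualifies when
   $|\beta_{mat} - \beta_{pat}| \ge \delta$ (default $\delta = 40$
   percentage points) *and* the control is strictly intermediate
   ($\beta_{mat} > \beta_{ctrl} > \beta_{pat}$ or the mirror image). Ties
   fail: an equality is no evidence of an ordered allelic pattern.
4. **Collapse.** Maximal runs of adjacent qualifying sites with the same
   direction become regions. Adjacency is over the ordered set of
   analysed loci, not base pairs — the capture design leaves gaps, and a
   neighbouring analysed CpG is the natural unit. Two same-direction
   regions separated by exactly one discordant site are merged, and the
   merge is applied iteratively left to right until a fixed point, so the
   pattern `M M x M x M` forms a single region. A *discordant site* is any
   classifiable site that fails to qualify in the region's direction,
   including a lone opposite-direction qualifying site, which is absorbed
   as a separator and does not surface as a region of its own. Absorbed
   separators never count toward a region's site total.
5. **Filter.** A region survives when (a) it has at least `min_sites = 5`
   qualifying sites; (b) the median pooled coverage over its member sites
   is at least `min_median_cov = 10` in every category; and (c) no
   category contains two samples whose region-level percents differ by
   more than `intra_discord = 50` while both have median per-site coverage
   above `intra_cov = 3`. The concordance rule is evaluated at region
   level on per-sample counts summed over member sites — per-site
   evaluation at 3x coverage would be dominated by sampling noise. With a
   single sample in a category it passes vacuously.

All thresholds are arguments with the defaults above; the defaults are the
operating point the callers are tested at.

## Hemizygous (lung) mode

`call_lung_dmrs()` restricts every sample to the deleted interval (1-based
inclusive on both ends), keeps loci captured at least once in every sample,
and compares the carrier with each dizygous control separately: a site
qualifies when $|\beta_{hemi} - \beta_{ctrl_i}| \ge 20$ for **every**
control with all differences of one sign. Controls that straddle the
carrier are no evidence. Parental attribution follows from the design: if
the carrier (which lost, say, the maternal allele) is *more* methylated
than every control, the exposed paternal allele carries the methylation;
if *less*, the missing methylation must have sat on the deleted maternal
allele. The deleted parent is an input — the caller never infers deletion
parental origin from methylation.

Collapsing reuses the trio-mode machinery but with the single-discordant
merge **off** by default (switchable): the hemizygous rule is stated for
adjacent matching sites only. Region filters: at least `min_dmc = 5`
qualifying cytosines and a median per-site coverage of at least
`min_median_cov = 7` in every individual sample. The looser coverage bar
reflects that nothing is pooled in this mode; requiring it of every sample
(rather than of some pooled aggregate) is the reading consistent with the
trio rule's "in any sample category".

## Targeted small-region re-scan

Regions of two to four qualifying sites are individually too small for the
main trio filter but become credible when independent evidence lines up.
`call_targeted_candidates()` re-collapses the trio site calls, keeps 2-4
site regions inside a user-supplied target interval (the trio coverage and
concordance filters still apply), and then:

* **masks** any candidate with an SNV (union over all supplied samples)
  on either base of a member CpG dinucleotide — a C-to-anything or
  G-to-anything variant destroys the CpG on one allele and mimics allelic
  methylation. The footprint of a forward-strand cytosine at `pos` is
  `pos, pos+1`; of a reverse-strand cytosine, `pos-1, pos`. Masking drops
  the whole candidate, not just the affected site;
* **promotes** the survivors that (1) lie within a maternal-deletion
  interval, so the relevant allele is exposed in the carrier tissue,
  (2) show the same inferred methylated parent at one or more member sites
  in the hemizygous contrast at its own threshold
  (`min_concordant_sites = 1`; the cross-tissue "resemblance" has no
  quantitative definition, so the weakest useful one is the default and it
  is configurable), and (3) span more than one CpG dinucleotide — a
  forward/reverse pair at one dinucleotide counts once, since both strands
  report the same methylation mark.

## Run-of-homozygosity screen

Isodisomy produces megabase-scale runs of homozygous genotypes.
`detect_roh()` is a transparent run-length detector over position-sorted
SNV genotypes: maximal runs of homozygous calls, optionally tolerating a
configured number of embedded heterozygous calls, with a minimum SNV
support (default 25). `flag_isodisomy()` raises the flag when any run
exceeds 10 Mb. This is deliberately not an HMM: no genotype likelihoods or
population allele frequencies enter, because the artifact's purpose is the
long-run flag, not fine-grained ROH boundary inference. Runs are reported
disjoint; after a run is broken by an excess heterozygous call, scanning
resumes past that call.

## The synthetic data generator

`sim_config()` / `simulate_truth()` / `sample_counts()` generate studies
with known ground truth:

* **Site grid.** Dinucleotides are laid down with geometric gaps (mean
  `spacing_mean = 100` bp); each emits a forward and a reverse cytosine
  at adjacent positions that share their methylation probabilities but
  receive independent read draws.
* **Background.** Each dinucleotide draws one methylation probability,
  identical on both alleles, from a low/high/intermediate beta mixture
  (proportions 0.45/0.45/0.10; shapes Beta(2,18), Beta(18,2), Beta(5,5)),
  mimicking the bimodal somatic methylome with a minor intermediate
  fraction.
* **Planted DMRs.** Non-overlapping regions of `region_width` consecutive
  sites overwrite one parental probability to `effect_high = 0.95` /
  `effect_low = 0.05`, alternating maternal/paternal direction.
  `invert_truth()` flips planted directions to emulate tissue-specific
  inversion of a parental bias.
* **Reads.** Coverage is negative-binomial (`mean_coverage = 30`,
  dispersion `size = 8`), emulating uneven capture; methylated counts are
  binomial at the site's expected methylation: maternal allele probability
  for `upd16mat`, paternal for `upd16pat`, their mean for `biparental`,
  and for a hemizygous carrier the remaining allele inside the deletion at
  thinned (halved) coverage and the biparental mean outside. A per-sample,
  per-site gaussian jitter on the logit scale (`jitter_sd = 0.25`) stands
  in for technical and biological between-sample variability.

The generator emulates the *allelic* structure the callers assume and
nothing else: no read-level artefacts, no bisulfite conversion failure, no
mapping bias, no cell-type heterogeneity, and background allele
probabilities that are exactly equal rather than merely close. Passing
recovery and calibration tests therefore demonstrates that the callers
implement their rules correctly and are well calibrated under binomial
noise — not that the thresholds are optimal for real tissue.

## Numerical and degenerate-input choices

* Percent methylation is kept as an exact double of the counts; nothing is
  rounded before reporting. Threshold comparisons are `>=` / strict `>`
  exactly as stated above, so a delta of exactly 40 (or 20) qualifies and
  an intermediate-control tie fails.
* Zero-coverage loci are retained by the readers and excluded by the
  stage that owns the relevant policy (intersection, the
  covered-everywhere prefilter, or classification), so inclusion decisions
  are visible in the attrition log rather than hidden in parsing.
* Empty inputs propagate to empty (not failed) outputs with warnings;
  unsorted site calls are sorted internally with a warning; a BED write of
  unsorted regions sorts with a note.
* Coordinates are 1-based inclusive everywhere inside the package
  (matching the count-file dialects); BED conversion to 0-based half-open
  happens only at the I/O boundary, in one place.

## Test problem sizes

The recovery and calibration tests run at 5,000 sites per replicate with
10 planted 8-site regions (trio mode, 20 replicates), 100 null genomes of
5,000 sites, and exhaustive oracle comparison over all 3^12 length-12
site patterns. These sizes give the sensitivity and false-positive
estimates two-digit stability while keeping the whole suite fast enough to
run routinely. The hemizygous-mode fixtures plant 16-site (8-dinucleotide)
regions — the size of a typical germline DMR — because that mode contrasts
single samples at halved carrier coverage with no discordant-site merge,
so individual sites fail to qualify a few percent of the time even at a
90-point allelic separation; narrow planted regions would probe marginal
power rather than the mode's mechanics.

## Known limitations

* The callers apply no statistical significance testing or multiple-testing
  control, by design: they reproduce a thresholded descriptive screen, and
  their output is a candidate list, not an inference.
* Pooling assumes samples within a category are exchangeable; the
  intra-category concordance filter catches gross violations only at
  region level.
* The hemizygous mode requires the deletion interval and its parental
  origin as trusted inputs.
* The ROH detector ignores allele frequencies and genotyping error, so its
  runs are only a coarse isodisomy screen.
* With the discordant-site merge off (lung default), a single noisy site
  can split an otherwise clean region; the trio mode's merge absorbs one
  such site but not two.
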