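---
title: "Calling homopolymer heteroplasmy and linking it to copy number and lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling homopolymer heteroplasmy and linking it to copy number and lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohet)
```

## The measurement problem

Mouse mtDNA carries a poly-adenine loop in the origin of light-strand
replication (OriL): a G anchor at nt 5171 followed by a reference run of 11
adenines from nt 5172. Individual mtDNA molecules within one animal differ
in the length of this run (9A-13A), and the fraction of molecules carrying
12 adenines -- the "12A heteroplasmy" -- is the phenotype of interest: it
varies between strains, correlates negatively with the mtDNA/nDNA
copy-number ratio, and correlates negatively with lifespan. A second,
biologically inert poly-A at nt 9821 in mt-Tr (T anchor, 8A reference run)
serves as a location control.

Measuring a homopolymer run length from short-read data is harder than
calling a SNV. Aligners place run-length differences as indels that they
are free to left- or right-shift within the run; polymerase slippage during
the long-range PCR creates ±1-unit artefacts that mimic real alleles; and a
read that ends inside the run is uninformative about its total length.
`mitohet` implements the calling chain around these three problems, plus
the downstream quantification (ddPCR Poisson inversion) and cohort
statistics, and a seeded generator that produces all inputs with ground
truth.

## The caller

Reads arrive as a minimal SAM text dialect (`parse_sam()` /
`write_sam()`), Phred+33 only, 1-based positions, half-open spans.
Secondary and supplementary alignments are excluded at parse time: whether
they were counted originally is unknowable, and excluding them is the
conservative choice for a single-locus counter.

**Filtering.** A read is retained iff its mate is present, its mean base
quality is at least 30, and it is at least 30 bp long
(`filter_reads()`). The published thresholds are strict-less-than
discards, so equality is retained. Duplicate marking
(`mark_duplicates()`) keys on the *fragment*: reference, leftmost
position, CIGAR, strand, and mate position. An earlier key without the
mate coordinate proved biased at amplicon depth: thousands of
motif-spanning reads share only ~130 valid start positions, the key space
saturates, and because the expected number of distinct keys is concave in
class size, the majority allele loses disproportionately more reads --
inflating the minor-allele fraction by several points. Keying on the
fragment (as Picard-style markers do) removes the bias while still
collapsing true PCR copies.

**Extraction.** `extract_motif()` reconstructs the read's sequence over
the window from one base before the anchor to six reference bases past the
run (`reconstruct_window()` walks the CIGAR: M/=/X emit query bases, D
emits nothing, I emits its bases when the insertion point is inside the
window, left edge inclusive). The run length is then read off the
reconstructed text -- first maximal anchor-base run, then the maximal
repeat-base run after it. Because the text is assembled before counting,
the call is invariant to where the aligner placed the indel inside the
run; the generator emits both left- and right-aligned CIGARs to prove it.
The slack of six bases accommodates observed runs up to 13A plus error.

Two censoring rules matter for unbiasedness. A read must show a
non-adenine *terminator* after the run: a read ending on the 7th A cannot
distinguish 11A from 12A, and truncating it to "7" would bias the spectrum
downward, so it is censored (`reason = "not_spanning"`). And a motif whose
mean base quality (anchor run plus adenine run) is below 20 is discarded
-- again strict-less-than.

**Spectrum and classification.** Accepted observations are tallied into a
`length_spectrum`; fractions sum to 1 by construction. The per-sample
statistics are the fraction at reference length + 1 (`plus_one_fraction`,
the 12A statistic used downstream) and the aggregate fraction above the
reference (`gt_ref_fraction`). Point alleles are handled separately by a
quality-floored pileup (`pileup_frequencies()`, bases ≥ Q30) and the fixed
bands of `classify_site()`: alternate frequency strictly above 90% is
homoplasmic, 40-90% inclusive heteroplasmic, below 40% low-level. The
bands are exposed for both point and length alleles but reported
separately, since the original rule's scope over repeat alleles is not
documented.

## ddPCR copy number

With droplets Poisson-occupied, the negative fraction estimates
`exp(-lambda)`, so `lambda = -log(n_neg/n_total)` copies per droplet
(`droplet_concentration()`), with the delta-method standard error
`sqrt((n_total - n_neg)/(n_total * n_neg))`. A fully positive well is
saturated and errors out; a fully negative well is a valid zero. The
mtDNA/nDNA ratio (mt-Co1/Vdac1, mt-Nd5/Vdac1) is the ratio of lambdas with
a log-normal interval from summed squared relative errors
(`copy_ratio()`); the copies-per-microlitre conversion cancels in the
ratio and is omitted. The log-normal delta method was chosen over profile
likelihood because it is the standard ddPCR practice, closed-form, and
directly testable against simulated droplets.

## Cohort statistics

All tests are two-sided, unadjusted, with mid-ranks for ties.

* `km_estimate()` wraps the product-limit machinery of the survival
  package with log(-log) intervals, but reports the median as the *first*
  time S(t) falls to 0.5 or below. (The survival package averages times
  when S(t) sits exactly at 0.5; with four subjects dying at 1, 2, 3, 4 it
  reports 2.5 where the first-crossing convention reports 2.)
* `logrank_test()` and `gehan_test()` share one weighted risk-set walk:
  observed minus hypergeometric-expected events per distinct event time,
  with weight 1 (log-rank) or the pooled number at risk (Gehan-Breslow,
  emphasising early separation -- the relevant sensitivity when one strain
  dies earlier). The Gehan weighting is hand-authored because the survival
  package's `rho = 1` variant weights by S(t), which is Peto-Prentice, not
  Gehan.
* `spearman_test()` is the Pearson correlation of mid-ranks; for n ≤ 9 the
  p-value is an exact full-permutation enumeration, above that the t
  approximation on n - 2 df.
* `mann_whitney_u()` enumerates all assignments of pooled ranks when the
  smaller group has ≤ 8 observations (exact under ties, which the base
  `wilcox.test` does not provide); larger samples use the tie-corrected
  normal approximation with continuity correction. Enumeration is
  additionally capped at 2e6 assignments to bound memory when the other
  group is large.
* `power_sample_size()` iterates the noncentral-t power function for the
  smallest group size reaching the target power. The canonical lifespan
  design -- detecting a 10% difference at two-sided 0.05 with power 0.8 --
  is encoded as d = 0.5, i.e. a 10% mean difference against an assumed 20%
  SD of lifespan; that assumption is a documented default (it is the
  standardisation that reproduces the canonical 64 per group), not a
  hidden constant.

```{r sample-size}
power_sample_size(0.5, alpha = 0.05, power = 0.8)
```

## What the generator emulates, and what it does not

`simulate_polyA_reads()` draws each read's true allele from a stated
mixture, applies slippage with per-read probability (default 0.005) and a
symmetric ±1 geometric-tailed magnitude (tail parameter 0.2) -- the
simplest model producing the observed 9A-13A spread around 11A -- plus
per-base substitutions (default 0.002, short-read-realistic) and normal
Phred qualities (mean 35, sd 3). Read lengths are 150 minus a uniform
0-30 bp trimming jitter, and fragment lengths are uniform 250-450 bp,
giving each fragment a distinct coordinate identity; both kinds of
variability are what real trimmed paired-end libraries look like, and the
duplicate-marking proxy depends on them. Indels are left-aligned by
default with a right-aligned option for placement-invariance tests. Only
the motif-spanning mate of each fragment is emitted, with paired-complete
flags: the other mate carries no motif information, and mate-overlap
double counting is therefore absent from simulated spectra (in real data
both mates may span the site; the caller counts both and flags this in
its report contract).

`simulate_droplets()` is the exact zero-class model. `simulate_cohort()`
draws heteroplasmy per animal from a truncated normal on [0, 1] (strain
means 0.10 and 0.22, sd 0.06 -- the ~10% versus >20% strain contrast),
lifespan from a left-skewed skew-normal (location 820, scale 160, shape
-4 days; the Azzalini representation, sampled directly) shifted by -400
days per unit heteroplasmy -- so the 0.12 strain gap translates into
roughly the 50-day female lifespan difference -- with Bernoulli censoring
at 8%, and 85 females per strain. A copy ratio declining with
heteroplasmy (base 150, slope -120, 15% log-normal noise) is attached.

Not emulated: base-caller-realistic quality strings or error-by-quality
correlation, PCR chimeras, full tiling of the 16.3 kb mtDNA, reads
crossing the circular junction, and real inter-animal pedigree structure.
Passing recovery tests therefore demonstrate that the *calling chain* is
unbiased under a realistic error model, not that real libraries are free
of systematic artefacts the model lacks.

## Validation sizes and numerical choices

The test suite checks the extractor against an independent brute-force
oracle (per-position window assembly plus linear scan) on 10,000 mixed
M/I/D/S reads including both indel placements; recovers f12 = 0.25 within
±0.02 in ≥ 95 of 100 seeds at 5,000 spanning motifs and slippage 0.005
(the binomial SE at that depth is 0.006, so the band is ≈ 3.3 SE);
verifies 3-SE coverage of the Poisson inversion at lambda 0.1/0.7/2.0 over
1,000 trials each; and calibrates the type-I error of log-rank, Gehan,
Mann-Whitney and Spearman to [0.03, 0.07] at nominal 5% over 2,000 null
replicates. These sizes were chosen so each property is tested at
meaningful resolution while the whole suite stays fast enough to run
routinely.

Degenerate inputs have explicit contracts rather than incidental
behaviour: an empty read set filters to an empty set with a zero report; a
spectrum with no accepted observations has total 0 and refuses metrics; a
saturated ddPCR well errors; an all-censored cohort yields S ≡ 1 with an
undefined median; constant input to Spearman errors.

## Limitations

The duplicate marker is a fragment-coordinate proxy, not a mate-pair graph:
optical duplicates and duplicates of reads with identical fragments are
indistinguishable from biology. The repeat caller reports spectra per
sample and does not phase the two heteroplasmic sites. The classifier
bands are fixed constants by design; they are exposed as flags in the
pipeline layer but their values are the published ones. The skew-normal
lifespan generator is a sampling device, not a fitted model of any real
cohort.
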