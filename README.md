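# mitohet

Quantifying mitochondrial homopolymer heteroplasmy from deep-sequencing
reads, mtDNA copy number from droplet digital PCR, and their association
with lifespan in ageing cohorts.

## The problem

Mouse mtDNA carries a poly-adenine loop in the origin of light-strand
replication (OriL): a G anchor at nt 5171 followed by a reference run of
11 adenines from nt 5172. The fraction of mtDNA molecules whose run is 12
adenines — the *12A heteroplasmy* — varies between individuals and
strains, depresses the mtDNA/nDNA copy-number ratio, and correlates
negatively with lifespan. Calling a homopolymer run length from short
reads is not a SNV call: aligners shift run indels freely within the run,
PCR slippage fabricates ±1-unit alleles, and reads ending inside the run
are uninformative. `mitohet` is for researchers who need this measurement
chain — repeat-length caller, ddPCR quantification, cohort statistics —
as tested, seeded, reusable R functions.

At its core, for a read *r* spanning the anchored window, the caller
reconstructs the aligned query text by a CIGAR walk and reads off the
maximal run length *L(r)*; the per-sample spectrum is
*f(L) = #{r : L(r) = L} / N* over accepted reads, with the 12A statistic
*f(12)* and the aggregate *Σ<sub>L>11</sub> f(L)*. Reads are accepted iff
mate present, mean quality ≥ 30, length ≥ 30 bp, not a PCR duplicate
(fragment-key collapse), motif mean quality ≥ 20, and terminator visible.
ddPCR concentrations invert the Poisson zero class, λ = −ln(n₋/n), and
the copy ratio is λ_mt/λ_nuc with a log-normal delta-method interval.
The statistics layer provides Kaplan–Meier with first-crossing median and
log(−log) CI, log-rank and Gehan–Breslow tests, Spearman correlation
(exact permutation p for n ≤ 9), Mann–Whitney U (exact under ties for
small groups), and noncentral-t sample-size search.

## Worked example

Simulate a 4,000-read sample at a known allele mixture, round-trip it
through SAM, and call the spectrum:

```r
library(mitohet)
site <- oril_site()                       # G anchor @5171, 11A run @5172
sim  <- simulate_polyA_reads(site,
          c("10" = 0.05, "11" = 0.68, "12" = 0.22, "13" = 0.05),
          n_reads = 4000, seed = 11)
reads <- mark_duplicates(filter_reads(parse_sam(write_sam(sim$reads)))$reads)
spec  <- count_spectrum(extract_motifs(reads, site), site)
spec
#> <length_spectrum> OriL-5172: 3981 observations
#>      0      1      2      3      4      5      6      7      8      9     10
#> 0.0010 0.0023 0.0008 0.0018 0.0015 0.0010 0.0015 0.0013 0.0025 0.0025 0.0515
#>     11     12     13     14
#> 0.6684 0.2190 0.0445 0.0005
met <- heteroplasmy_metrics(spec)
sprintf("f12 = %.4f, >11A = %.4f", met$plus_one_fraction, met$gt_ref_fraction)
#> "f12 = 0.2190, >11A = 0.2640"
```

The called `f12 = 0.2190` recovers the simulated 0.22 within binomial
error; the stray short lengths are substitution errors truncating the
run, exactly as in real data. Copy number and cohort inference:

```r
copy_ratio(simulate_droplets(1.5, 20000, "mt-Co1", seed = 12),
           simulate_droplets(0.3, 20000, "Vdac1",  seed = 13))
#> <copy_ratio> mt-Co1/Vdac1 = 4.9656 [4.8087, 5.1276]   (truth 5.0)

res <- run_analyze(simulate_cohort(seed = 14))
res$report[1, ]
#>                analysis  group statistic   value        p
#> 1 spearman_het_lifespan pooled       rho -0.2339 0.002145
```

Higher heteroplasmy, shorter life: the simulated cohort (85 females per
strain, strain means 10% and 22% heteroplasmy, −400 days per unit
heteroplasmy) reproduces the negative Spearman correlation and a
between-strain log-rank difference (`res$report` also carries per-strain
KM medians with 95% CIs, log-rank/Gehan chi-squares, and the
Mann–Whitney comparison of heteroplasmy).

A thin CLI over the same functions ships in `inst/cli/mitohet.R`
(`simulate`, `call-heteroplasmy`, `copy-number`, `analyze` subcommands).

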