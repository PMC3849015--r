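# poolBSA

Bulk segregant mapping from low-coverage pooled sequencing, by regional
averaging of SNP frequencies.

## The problem

To locate the loci behind a selectable trait (the motivating case is
phosphine resistance in the red flour beetle, *Tribolium castaneum*), two
pools of progeny from a defined cross are sequenced: survivors of a
discriminating selection, and unselected siblings from the same cohort.  At
low coverage (~5x) individual pooled SNP frequencies are too noisy to call
linkage site by site, and parentage assignment of SNPs is unreliable.

The scan implemented here needs neither.  For every called SNP it takes the
**primary variant frequency** — the percentage of reads supporting the most
common allele at the site, *regardless of reference identity*.  In a
segregating pool this statistic hovers in the 60–80% band (read sampling at
low coverage inflates it above the true 50%); in a region driven to
homozygosity by selection it approaches 100%.  Both pools' SNP tables are
merged, aligned by position, and averaged over a **dynamic window**: a fixed
count of consecutive SNPs (300 for chromosomes, 50 for short sequences)
advancing one SNP per step, so the window's physical span adapts to SNP
density and assembly gaps.  A **candidate region** is a run of windows where
the selected pool's mean reaches near homozygosity (>= 90%) while the
unselected pool stays heterozygous (<= 85%) — differential homozygosity,
displayed graphically, with no association statistics required.

Around the scan the package provides:

* readers/writers for per-pool SNP tables (counts and frequency dialects),
  pooled VCF with allele depths, merged tables, window profiles and BED
  region output;
* a forward simulator of the experiment: two fully homozygous parental
  strains fixed for alternative alleles at every site, F1 -> F2 from a
  single sibling pair, free mating to the target cohort, all-or-nothing
  selection of resistance homozygotes, Poisson-coverage pooled sequencing
  with miscall errors, and a truth table of the simulated loci;
* the downstream marker-genetics toolkit: 1:2:1 segregation chi-square and
  G tests, allele frequencies, Hardy-Weinberg tests, the Kosambi map
  function `d = 25 ln((1+2r)/(1-2r))`, two-point recombination/LOD
  estimation from F2 genotypes, recombinant-count map distances
  `r = k/(2Ng)` in selected advanced-intercross survivors, and
  genotype-by-dose epistasis summaries.

## Worked example

Simulate the default experiment (two 400 kb chromosomes with 1,000 SNP
sites and 100 cM each, a resistance locus at the 40% position of each,
selection of double homozygotes at F4, pools of up to 100 beetles at 5x)
and scan it:

```r
library(poolBSA)
cfg  <- simConfig(seed = 42)
res  <- simulateExperiment(cfg)
scan <- scanPools(res$selected, res$unselected)
candidateRegions(scan)
#> GRanges object with 2 ranges and 5 metadata columns:
#>       seqnames        ranges strand |    regionId meanSelPct meanUnselPct
#>   [1]     chr1 113000-193800      * |    region_1    93.8327      62.6228
#>   [2]     chr2 112200-197000      * |    region_2    94.5440      64.0419
#>        nWindows     nSnps
#>   [1]        62       111
#>   [2]        64       113
res$truth
#>   chrom site  posBp expSelFreq
#> 1  chr1  400 159800          1
#> 2  chr2  400 159800          1
```

Both called regions contain their true locus (159,800 bp).  The selected
pool's window means plateau above 90% over the linked region while the
unselected means stay near 63% — the low-coverage heterozygous band.
`plotScan(scanProfile(scan), candidateRegions(scan), file = "scan.png")`
draws the two traces with the regions shaded.

The marker statistics reproduce their printed reference values:

```r
h <- mendelianChisq(34, 43, 17, nTested = 94)   # observed vs n/4 : n/2 : n/4
sprintf("chi2 = %.2f, df = %d, P = %.3f", h$statistic, h$parameter, h$p.value)
#> "chi2 = 6.83, df = 1, P = 0.009"
round(alleleFrequencies(20, 52, 22), 2)         # resistant-allele frequency
#>    p    q
#> 0.49 0.51
advancedIntercrossDistance(9, 48, 3)            # 9 recombinants / 48 / F4
#> [1] 3.125
```

The first call says a marker with 34/43/17 rr/rs/ss genotypes among 94
tested deviates from 1:2:1 (P = 0.009, resistant homozygotes in excess);
the last converts 9 recombinant individuals among 48 selected F4 survivors
(3 meioses from the F1 gametes) into a 3.1 cM marker–locus distance.

A command-line wrapper with `scan` / `simulate` / `genetics` / `map2pt` /
`epistasis` subcommands ships in `inst/scripts/poolbsa`.

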