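---
title: "Mapping trait loci by regional averaging of pooled SNP frequencies"
author: "poolBSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping trait loci by regional averaging of pooled SNP frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolBSA)
```

## The method

Bulk segregant analysis compares two pools of progeny from a defined cross:
one selected for the trait, one left unselected.  With both parents fully
homozygous and fixed for alternative alleles, every informative SNP
segregates in the cross; selection drives the chromosomal neighbourhood of
a trait locus toward homozygosity in the selected pool while the unselected
pool keeps segregating.

At low sequencing coverage (~5 reads per site per pool) the per-site allele
frequency estimate is hopeless — at coverage 6 a truly 50/50 site shows a
*primary variant frequency* (the share of reads carrying the site's most
common allele, whichever that is) of 65.6% on average, and any value from
50 to 100 in a single observation.  The method therefore averages the
statistic regionally instead of modelling sites individually:

1. **Call filters.** A site enters a pool's table only with coverage >= 6
   and a variant-allele frequency >= 35% relative to the declared
   reference.  These two filters emulate the tail end of a quality-aware
   caller's pipeline; base-quality handling itself is upstream of this
   package.
2. **Merge.** The two pools' tables are merged into one row per site in
   the union, sorted by position, one frequency column per pool.  Where
   only one pool called a site, the other pool's cell is blank.
3. **Dynamic window.** The primary variant frequency is averaged over a
   window of a fixed *count* of SNPs (not fixed bp), advancing one SNP per
   step.  Each pool's mean skips blank cells, exactly as a spreadsheet
   AVERAGE over a column with gaps.  A window therefore spans more
   physical distance where SNPs are sparse (assembly gaps, low coverage)
   and less where they cluster, which is what makes the method robust to
   fragmented references.
4. **Region call.** A candidate region is a maximal run of at least
   `minWindows` consecutive windows with the selected mean at or above
   `selMinPct` and the unselected mean at or below `unselMaxPct`,
   spanning the first qualifying window's first SNP to the last one's
   last SNP.

There is deliberately no association statistic or significance model: the
signal is differential regional homozygosity, read from the averaged
traces.  The original analysis called regions from plots; the thresholds
here are an explicit, configurable operationalisation of its stated
selection rule (selected near homozygosity at 90–100%, unselected still
heterozygous at ~50–80%), and they are echoed into every output header.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `windowChrom` | 300 | SNPs | resolution/noise compromise for chromosome-scale sequences at ~5x |
| `windowScaffold` | 50 | SNPs | short sequences carry few SNPs; 40 is the other historically used value |
| `scaffoldLenCutoff` | 1e6 | bp | chromosomes in beetle-sized assemblies are >4 Mb, unplaced scaffolds sub-Mb |
| `minCov` | 6 | reads | call filter |
| `minVarFreqPct` | 35 | % | call filter |
| `selMinPct` | 90 | % | "near homozygosity" in the selected pool |
| `unselMaxPct` | 85 | % | upper edge of the heterozygous band plus margin |
| `minWindows` | 3 | windows | a single qualifying window is noise; three consecutive is a region |

Two values deserve comment.  The scaffold window has been used at both 40
and 50 SNPs; 50 is the default here and 40 is one `scanConfig()` argument
away.  And `unselMaxPct` sits above the observed 60–80% band so that the
unselected ceiling rarely decides a call on its own; its real job is to
reject *shared* fixed differences (both pools near 100%), which are
strain-level, not selection-driven.

**The window must stay genetically narrow.**  The window's SNP count only
has meaning relative to the sequence's SNP total: a 300-SNP window on a
sequence with 500 merged rows spans most of the sequence, and if that
sequence represents tens of centimorgans the average inevitably mixes the
homozygous core with flanking segregating material and the selected trace
never reaches 90%.  In the motivating datasets a 300-SNP window covered
roughly 0.5–1 Mb of a real chromosome — about 2 cM — which is narrow
relative to the several-cM linkage decay around a locus selected at F4.
This is why short sequences get the small window, and why the simulated
sequences below (1,000 sites each) route to it.

## The simulator

`simConfig()` / `simulateExperiment()` emulate the full experiment:

* two fully homozygous parental strains differing at every SNP site;
* F1 from the parental pair, an F2 cohort of 194 from a single F1 sibling
  pair, then discrete free-mating cohorts of 750 (within the 500–1000
  census range such crosses are actually kept at), monoecious, mates drawn
  with replacement, no selfing avoidance;
* meiosis with Poisson crossover counts (mean = map length in Morgans) and
  uniform breakpoint placement — Haldane's no-interference model.  The
  Kosambi function is used only for reporting map distances, not for
  simulation;
* all-or-nothing selection at the discriminating dose: only individuals
  homozygous resistant at *every* resistance locus survive.  Graded rules
  can be supplied as functions of genotype and dose;
* pooled sequencing: per site, coverage ~ Poisson(5); each read samples one
  of the pool's 2N chromosomes with replacement (equimolar individuals)
  and miscalls to one of the three other bases with probability 0.001;
  the call filters are then applied with the susceptible strain as
  reference.

Defaults (chosen once, as the package's standing study conditions): two
chromosomes, 1,000 SNP sites each, 400 kb physical length — matching the
~2.5 called-SNPs/kb density of real pooled data, so the scan's window
routing behaves as it would on equivalently SNP-dense real sequences —
100 cM genetic length, one resistance locus at the 40% position of each
chromosome, pools of up to 100 individuals.  At the 750 census, a
discriminating dose on double homozygotes leaves ~50–90 survivors, so the
selected pool is often the whole survivor set; the real experiments exposed
>10,000 beetles to pool exactly 100 survivors, which is out of scale for
routine simulation and changes nothing structurally.

A master seed drives separate streams for parents, pedigree,
selection/pooling and sequencing, so runs are byte-reproducible and
subsystems can be varied independently.

What the simulator does *not* emulate: read mapping and base-quality
artefacts (errors are uniform miscalls), reference mis-assembly (each
simulated sequence is internally correctly ordered), varying SNP density,
sex, overlapping generations, and fitness costs (allele-frequency drift is
analysed by the marker statistics, not generated by the simulator).
Passing the scan-recovery tests therefore shows the statistic and window
logic work under idealised sequencing noise — not that any particular real
assembly's artefacts are handled.

### Calibration of the heterozygous band

With a balanced pool (allele frequency exactly 1/2) and no sequencing
error, conditioning on coverage *c*, the expected primary variant
frequency is E[max(X, c−X)]/c with X ~ Binomial(c, 1/2): 68.75% at c = 5
and 65.625% at c = 6.  This is why the unselected trace of a 5x experiment
sits in the 60–80% band rather than at 50%, and the test suite checks the
simulator against these enumerated values.  Note the 35% variant filter is
*not* part of this expectation; conditioning on it would shift the
coverage-6 value to 61.9%.

## Marker statistics: conventions that matter

* **Segregation chi-square.** Expectations are (n/4, n/2, n/4) from the
  *tested* count, which in historical data sheets can differ from the
  genotyped total in either direction; both conventions are live, and the
  tested-count one reproduces the published statistics exactly.  The
  p-value uses df = 1 by default, matching how these tables are printed,
  although a three-class goodness-of-fit test canonically has df = 2; the
  df is an argument and the type-I calibration test uses df = 2.
* **Allele frequencies** divide by the genotyped total (not the tested
  count) — again the convention that reproduces the published values.
* **The literal Hardy-Weinberg test** (`hweChisq()`) is provided
  separately because "tested for HWE" in this literature usually turns out
  to mean the 1:2:1 test: on a heterozygote-rich sample such as 38/48/8
  the two statistics are 1.77 versus 18.8.
* **Two-point mapping** maximises the phase-known F2 9-class likelihood by
  bounded 1-D optimisation (tolerance 1e-8, boundary at r = 0 checked
  explicitly); LOD compares against r = 0.5; Kosambi distances are
  attached.  Phase is assumed known from the genotyped parents; there is
  no phase estimation and no multipoint ordering.
* **Recombinant-based distance** in selected survivors is k/(2Ng) with two
  scored chromosomes per individual and g meiotic generations between the
  F1 gametes and the scored cohort (F4 means g = 3), reported as 100r cM;
  the Kosambi correction is negligible at these distances and exposed as
  an option.  Under the reproduced convention, 7 recombinants among 48 F4
  survivors give 2.43 cM where 2.5 has been printed; the difference is a
  rounding convention on the published side that cannot be recovered from
  the formula.

### A caveat the simulator exposes

The k/(2Ng) formula treats every one of the g meioses as an independent
chance to observe recombination.  In a closed random-mating cohort it is
not: once an ancestor is homozygous across the marker–locus interval, its
meioses cannot produce observable recombinants.  The gametic frequency of
the recombinant haplotype follows h_{t+1} = (1−r) h_t + r/4 from
h_1 = r/2, which grows more slowly than g·r.  Simulating two markers
3.125 cM apart, selecting locus homozygotes at F4 and scoring the flanking
marker recovers ~1.9 cM — matching that recurrence to within sampling
error, and about 40% below the nominal formula value.  The package
implements the field's formula as specified (and the test suite pins the
recurrence oracle), but distances estimated this way should be read as
lower bounds at small g.

## Numerical and degenerate-input choices

* Primary-allele ties (exactly 50% at even coverage) break to the
  alphabetically first base; the statistic is symmetric there, so only
  determinism is at stake.
* `N` allele counts are dropped before the primary variant is computed;
  frequency-dialect counts are reconstructed by rounding coverage x
  frequency.
* Coordinates are 1-based closed everywhere internally; only BED export is
  0-based half-open.  Strand is ignored (pooled counts are strandless).
* Sequences with fewer rows than the window produce a single
  whole-sequence window, with a warning; windows never cross sequence
  boundaries; a pool's window mean is missing only when the window holds
  no cell for that pool, and such windows never qualify for a region.
* Sequence lengths, used only to route chromosome versus scaffold windows,
  are taken from `scanConfig(seqLengths=)` when provided and otherwise
  estimated as the maximal SNP position.
* Empty survivor sets raise an explicit error suggesting a larger cohort
  or lower dose, rather than returning an empty pool.

## Problem sizes in the test suite

The suite simulates 30 selection runs plus 30 no-selection controls at the
default configuration (two chromosomes x 1,000 sites, F4, ~1 s per run)
for locus-recovery and false-positive rates; 600,000 sites for the
pool-seq calibration; 100 seeds x 4 recombination fractions (F2, n = 200)
for estimator recovery; and 100 random merged tables against a brute-force
per-window oracle.  These sizes give sub-percentage-point Monte Carlo
error on every checked quantity while keeping a full run around a minute.

## Known limitations

* No significance model for regions: the scan ranks and displays; it does
  not test.  Thresholds are conventions, exposed in the configuration and
  echoed in outputs.
* The frequency-dialect reader assumes one variant per row, as
  spreadsheet-style caller exports provide; multiallelic sites split
  across rows will be rejected as duplicates of one position.
* The simulator's equimolar-pool assumption ignores DNA-quantity variation
  between individuals, and its uniform miscall model is far simpler than
  real base-calling error; both choices are conservative for the scan,
  which only consumes frequencies of the two real alleles.
* `readVcfPool()` requires per-allele depths (`AD`); VCFs carrying only
  genotypes or total depth cannot be converted to pool frequencies.
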