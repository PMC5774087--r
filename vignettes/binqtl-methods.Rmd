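---
title: "Bin maps and minor-effect QTLs from low-coverage RIL genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin maps and minor-effect QTLs from low-coverage RIL genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binqtl)
```

## The problem

Genotyping-by-sequencing (GBS) delivers very cheap but very sparse genotype
calls: at ~0.08x depth each recombinant inbred line (RIL) is observed at
roughly 8% of the segregating SNPs, each observation is effectively a single
read, and per-site allele miscall rates sit near 0.6–0.9%. Individually
these calls are far too noisy for mapping. Because a RIL's chromosome is a
coarse mosaic of parental segments, however, consecutive observations are
highly redundant, and a sliding-window consensus recovers the mosaic almost
perfectly. `binqtl` implements that recovery and everything downstream of
it: population-wide recombination bins, a Kosambi genetic map, segregation
-distortion screening, genotype imputation, a composite-interval-mapping
style genome scan with permutation thresholds and 1.5-LOD support
intervals, multi-environment BLUPs and heritability, and the
recombinant-derived progeny-test logic used to verify a mapped QTL in
introgression lines.

## Genotype calling from sparse observations

Each line x chromosome is processed independently.

1. **Windows.** A 15-SNP window slides by one SNP over the line's observed
   alleles. The window is called homozygous for a parent when more than
   11 of 15 sites carry that parent's allele, heterozygous otherwise. All
   thresholds in the caller are strict inequalities; ties keep the item.
   With 0.9% per-site error the probability that a window inside a true
   homozygous tract is called the *opposite* homozygote is the binomial
   tail P(X >= 12 | n = 15, p = 0.009) < 1e-18 — effectively impossible,
   which is the robustness the window consensus buys.
2. **Breakpoints.** A crossover appears as a short run of heterozygous
   windows. Runs shorter than 7 windows flanked by different homozygous
   genotypes are split at the run midpoint (odd runs give the extra window
   to the left — an arbitrary but fixed choice); runs flanked by the same
   genotype adopt it; short runs at chromosome ends adopt their single
   flank. Runs of 7 or more windows are kept as heterozygous. On clean
   dense data a crossover actually produces an 8-window heterozygous run
   (minority counts 4–11 under the >11/15 rule), which therefore survives
   to step 4 and is removed there; both routes resolve the crossover, and
   the breakpoint is still counted across the resulting gap.
3. **Blocks.** Each observed SNP takes the genotype of the window centered
   on it (terminal windows cover the chromosome ends); runs of identical
   per-SNP genotype become blocks, and the physical boundary between two
   blocks is placed at the midpoint between their flanking observed SNPs.
   Blocks are 1-based inclusive and tile the chromosome.
4. **Block filters.** Blocks with fewer than 5 sequenced SNPs or shorter
   than 300 kb become missing (false double-crossover guard). Stretches of
   *small* blocks (below the heterozygous-block minima) that switch
   genotype at least 3 times within any 10 consecutive non-missing blocks
   are consolidated into one heterozygous block — the "frequently
   transient genotypes" rule; restricting it to small blocks matters,
   because consecutive blocks always alternate and an unrestricted rule
   would consolidate ordinary crossover patterns. Heterozygous blocks with
   fewer than 15 SNPs or shorter than 1 Mb then become missing, and
   same-genotype blocks separated only by missing runs are merged across
   the gap (the parsimonious call for an unobserved interior).
5. **Line filters.** Lines with more than 15% residual heterozygous length
   (measured over the called, non-missing physical length) or more than
   360 breakpoints are excluded, with reasons reported.

## Bins, distortion, imputation, and the genetic map

Bin boundaries on a chromosome are the union of all retained lines' block
boundaries; a bin is therefore an interval with no breakpoint in any line,
and within a line its genotype is constant. Bins shorter than 5 kb merge
into their right neighbour (left at the chromosome end), the merged bin
taking per line the genotype of the larger constituent.

Segregation distortion is screened per bin with a df = 1 chi-square
goodness-of-fit of the homozygote counts against 1:1 (heterozygous and
missing lines ignored), Bonferroni-corrected over the tested bins, flagged
at adjusted p < 0.01. Separately, bins whose parental frequency ratio
exceeds 2:1 or whose heterozygous frequency exceeds 15% are discarded
before mapping — these are two distinct screens (diagnostic flagging vs
map hygiene) and are kept as distinct operations. The ratio/heterozygosity
discard is applied before the chi-square screen's denominator is formed for
mapping purposes; the order is configurable because the source protocol
leaves it ambiguous.

Downstream QTL models are two-state, so residual heterozygous calls are set
missing and every missing cell is filled by a two-state Viterbi decoding
over {P1, P2}: transition probabilities between adjacent bins come from the
current map interval through the selfed-RIL relation R = 2r/(1+2r),
emissions allow a genotyping error of 1e-4 (a knob; results are insensitive
over 1e-6..1e-2 because the chain is anchored by long runs of observed
homozygous bins). One map–impute pass is used.

Adjacent-bin recombinant fractions R (discordant / doubly informative
lines) are converted to per-meiosis fractions r = R/(2(1−R)), clamped to
[0, 0.5), and to map distances through the Kosambi function
d = 25 ln((1+2r)/(1−2r)) cM. With thousands of bins in physical order the
chain of adjacent intervals is the dense-map analogue of multipoint
estimation; full multipoint EM would change essentially nothing here and is
deliberately not implemented. Two caveats are worth stating plainly:

* **Finite-generation bias.** The correction r = R/(2(1−R)) assumes
  fixation. At F7 (six selfing generations) the expected recombinant
  fraction is ~91% of its fixation value for small r (exact two-locus
  Markov computation), so total map length is systematically
  underestimated by roughly 10–15% relative to the simulated truth. We
  keep the fixation correction because it is the standard RIL estimator
  this pipeline mirrors; the recovery test asserts a 20% band and pins the
  oracle ratio instead of pretending the bias away.
* **Averaging conventions.** The per-chromosome summary reports the mean
  adjacent interval both as mean(interval cM) and as total/(bins−1)-style
  quantities; published tables are not always explicit about which
  convention they print.

The recombination landscape is summarized as cM/Mb in 1-Mb windows, each
adjacent-bin interval's cM apportioned to windows by physical overlap
between the two bin midpoints, with Pearson correlations against any
supplied per-window annotation track.

## QTL scanning

The scan is marker regression at bins with background cofactors — the
dense-map realization of composite interval mapping. With bins every
fraction of a cM, testing between markers adds nothing, so the one
intentional methodological simplification in this package is to scan *at*
bins:

* **Cofactors** are chosen by forward stepwise regression: at each step the
  bin with the largest residual-sum-of-squares reduction enters if its
  partial F exceeds the threshold implied by an entry p of 0.001, up to 5
  cofactors, with candidates within 10 cM of an already-chosen cofactor
  ineligible (prevents stacking several cofactors on one QTL). The source
  protocol names CIM without parameters; these defaults are declared, not
  inferred.
* **LOD** at a bin is (n/2) log10(RSS_reduced/RSS_full), the reduced model
  holding the cofactors that survive a 10 cM exclusion window around the
  tested bin. With no cofactors this reduces to the identity
  LOD = −(n/2) log10(1−R²), which the tests verify against direct least
  squares at machine precision.
* **Thresholds** come from permutations of the phenotype across lines, the
  genome-wide maximum LOD recorded per permutation and the empirical 95th
  percentile taken. Cofactors are reselected inside every permutation —
  costlier, but the null distribution is dishonest otherwise. Permutation
  i uses seed `seed + i`, making the threshold invariant to evaluation
  order (and to any parallel schedule).
* **Peaks and intervals.** Local maxima at or above the threshold are
  peaks; two maxima on a chromosome are distinct QTLs only if the profile
  between them drops at least 1.5 LOD below the lesser peak. The support
  interval is the contiguous run of bins within 1.5 LOD of the peak,
  extended one bin outward per side.
* **Effects.** At a peak, y = μ + a·x with x ∈ {−1, +1} for the two
  homozygotes (heterozygotes, if any survive imputation, are coded 0);
  a is the additive effect, signed so that the second parent's allele
  increasing the trait is positive, and PVE = 100 R² of this single-locus
  fit.

## Phenotypes across environments

Line values are BLUPs from y_ij = μ + env_j + g_i + e_ij with environments
fixed and lines random (REML via lme4); an optional replicate term nests
replication within environment, exposed but not asserted because field
block layouts are rarely published. Heritability is reported on the
entry-mean basis, h² = σ²_g/(σ²_g + σ²_e/n_env), the convention stated
explicitly in the output since the underlying formula reference is often
not printed in source protocols. Trait correlations are pairwise-complete
Pearson with two-sided p-values.

## Progeny testing

A verification family segregates a recombinant parent's heterozygous
segment; carriers and homozygous recurrent-parent progeny are compared with
the classic equal-variance two-sample t-test ("simple t-test"). A
significant family places the QTL inside its heterozygous segment, a
non-significant one outside. The refined interval is the intersection of
significant families' segments minus the union of non-significant
families' segments, clipped to the prior QTL interval; an empty result is
flagged as a contradiction rather than silently returned. Exclusions from
families whose smaller genotype class has fewer than 20 progeny are
reported as weak evidence and not subtracted, since a non-significant
result in an underpowered family excludes nothing.

## The simulator: what it emulates and what it does not

`simulate_population()` builds each line from an F1 by six generations
(default) of self-pollination with single-seed descent, two independent
meioses per generation, crossovers Poisson with mean (genetic length in
cM)/100 per meiosis and positions drawn from an optional 1-Mb intensity
track (uniform by default). Observations are independent Bernoulli
site-samples at rate 0.08 per SNP; at a heterozygous site a single
observation emits one parental allele at random (at 0.08x a site is
effectively seen once), and the emitted allele flips with the
parent-appropriate error rate (0.6% / 0.9% defaults). These defaults are
the study conditions of the reference population and are not tuned.

Deliberately not modelled: read-level sequencing (the pipeline consumes SNP
calls, not reads), restriction-fragment structure, barcode demultiplexing,
crossover interference (no interference parameters are available; the
Kosambi function is used downstream as a mapping convention, not as a
claim about the simulated process), and sibling structure within families
(single-seed descent keeps one lineage per line). Passing tests on this
generator therefore demonstrate correctness of the *pipeline logic* under
the stated statistical structure, not robustness to artefacts real GBS data
can contain (index hopping, reference bias, paralogy), which the
window-consensus design addresses only in aggregate.

Default problem sizes in the test and acceptance suites — 100–500 lines,
1–10 chromosomes, 200-permutation thresholds, 20-replicate recovery runs —
were chosen as the smallest sizes at which the calibration and recovery
properties are statistically meaningful; the statistical conclusions do not
change at larger sizes.

## Numerical and degenerate-input choices

* All caller thresholds are strict, as phrased; equality keeps the item.
* Chromosomes with fewer observed SNPs than one window are wholly missing
  for that line; lines missing a whole chromosome are left missing by the
  imputer with a warning rather than guessed.
* r estimates are clamped to [0, 0.5); the Kosambi inverse round-trips to
  < 1e-12 over a dense grid.
* Bins with fewer than 2 informative lines are excluded from the
  distortion screen and its Bonferroni denominator; pairs with fewer than
  10 doubly informative lines carry a low-confidence flag; bins with fewer
  than 20 informative lines get LOD NA.
* Viterbi ties resolve to the first state by `which.max`; the emission
  error breaks exact ties in practice.
* A constant phenotype yields LOD 0 everywhere, an empty cofactor set and
  a zero permutation threshold, rather than an error.

## Known limitations

Adjacent-interval map estimation trusts the physical bin order (no
LOD-based reordering); the F7 map-length bias described above; no epistasis
or multiple-QTL model fitting; the VCF reader handles only the minimal
biallelic GT-field form this pipeline writes; marker genotypes in progeny
testing are taken as error-free, as appropriate for PCR markers.
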