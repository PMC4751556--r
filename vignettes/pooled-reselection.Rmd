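---
title: "Models and methods behind poolscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

# The experiment this package models

`poolscan` analyses genome-reselection experiments: a mixed population is
founded from F1 hybrids of two inbred strains (here called the *dark
founder* and the *reference founder*), split into replicate populations
reared under contrasting environments — a 12-hour light–dark cycle (LD)
versus constant darkness (DD) — and pool-sequenced at a few time points.
Because every founder-diagnostic SNP starts at frequency 0.5, any
systematic, replicated divergence in allele frequency between the two
environments measures environment-dependent selection on the surrounding
genomic region.

The package covers the full chain: a forward simulator that generates
ground-truth-labelled inputs; sync/TSV count-table I/O; founder-SNP
filtering and frequency estimation; a Fisher exact contrast scan with
trajectory typing; candidate-region clustering and a LOD localisation
scan with credible intervals; competition-assay fitness statistics; and
allele-specific qPCR frequency estimation.

# The forward simulator

`simulate_generations()` implements a diploid Wright–Fisher model:

* **State.** Each individual carries two haplotypes recorded as
  founder-origin bit vectors over the SNP map (1 = dark founder).
  Generation 0 is entirely F1: one complete dark haplotype plus one
  complete reference haplotype per individual.
* **Selection.** Viability selection with multiplicative fitness across
  loci and per-locus genotype fitness $1$, $1+hs$, $1+s$ for 0/1/2 dark
  alleles; $s$ is `s_LD` or `s_DD` from the founder map depending on the
  rearing condition, and $h$ defaults to 0.5 (genic selection).  Parents
  are drawn with probability proportional to fitness, which is equivalent
  to viability selection followed by random mating.
* **Recombination.** Gametes receive Poisson-distributed crossovers at
  `recomb_cM_per_Mb` (default 2 cM/Mb, a realistic female rate for
  *Drosophila melanogaster*); chromosomes assort independently.  Male
  meiosis is achiasmatic in *Drosophila*, so by default only one of the
  two transmissions per offspring recombines.  Sexes are not tracked:
  each offspring draws two distinct parents and the "maternal"
  transmission recombines, preserving the 50% recombining-meiosis
  fraction without a sex model.
* **Census regulation.** Population size is constant (default
  N = 1000, the scale of the emulated design).  The real experiment's
  populations fluctuated roughly 300–2000 and were remixed across 16
  vials every generation, which keeps them effectively panmictic; vial
  substructure is therefore not modelled.

Pool sequencing (`sample_pooled_reads()`) draws a depth per SNP (Poisson
with mean 179 by default, or fixed) and dark-supporting reads as
Binomial(depth, $f(1-\varepsilon) + (1-f)\varepsilon$) with a symmetric
per-read error $\varepsilon$ (default $10^{-3}$, an Illumina-scale
post-filtering rate).  No mapping bias, indel error, or FASTQ-level
detail is modelled.

`simulate_reselection()` wires the whole design together: one base
population sequenced at generation 0, then 3 replicates per condition
sequenced at generations 22 and 49.  The default SNP map holds 5000
founder SNPs across the five major chromosome arms — a down-scaled
stand-in for the ~1.4×10⁵ SNPs of the full design, chosen so that a
complete simulated experiment runs in about a minute while preserving a
realistic SNP spacing relative to linkage-block size.

## Planted selection regimes

`reselection_regimes()` plants loci matching the three trajectory types
the scan distinguishes, with selection coefficients (LD, DD) of
(0.010, 0.160) for type 1, (−0.140, 0.012) for type 2 and
(−0.260, −0.038) for type 3.  Each satisfies a between-condition
contrast $|s_{DD} - s_{LD}| \ge 0.15$.  Under the deterministic
single-locus recursion these yield expected generation-49 DD frequencies
of about 0.98, 0.57 and 0.28 — near the middles of the three
classification bins — while making the LD–DD contrast (and hence the
exact-test signal) as large as each bin allows.

The default is **one locus per type**, which follows from a capacity
argument rather than convenience.  The top-5% significance tier used for
typing holds 5% of all tested SNPs, i.e. about 6 Mb worth of genome at
any SNP density.  A strongly contrasted locus swept over 49 generations
drags a hitchhiking footprint of roughly $s/(r\,\ln 2Ns)$ — several
megabases at these parameters — whose SNPs nearly match the focal locus
in significance.  Three such footprints already fill the tier; planting
more loci per type makes it arithmetically impossible for weaker-signal
types to rank, regardless of the method.  Simulations with three loci
per type confirmed exactly that failure mode.

## What the simulator does not capture

Real pool-seq data add mapping bias near structural variants (the
emulated study had to discard a centromeric stretch of chromosome 2 for
this reason), uneven DNA contributions of individuals to the pool,
batch-varying error rates, and many loci under weak, polygenic
selection.  Passing the synthetic recovery tests therefore demonstrates
that the statistics behave correctly under the stated model, not that
every real-data artefact is handled.

# Frequency estimation and the founder filter

Frequencies are dark-allele read fractions; SNPs below a minimum depth
of 5 (the variant-caller setting of the emulated workflow) are flagged
missing per population, and a SNP missing in any population used by a
given test is dropped from that test only.  `select_founder_snps()`
keeps SNPs whose generation-0 frequency lies in the closed interval
[0.4, 0.6]; the bounds are inclusive so the filter is a closed,
idempotent set operation.  At 179× depth this filter retains about 99%
of true frequency-0.5 SNPs (the binomial prediction checked by the test
suite).

# The contrast scan

Replicate counts are merged by summation (the pooled analogue of merging
alignments), and each SNP is tested with a **two-sided Fisher exact
test** on the 2×2 dark/other × LD/DD table.  The two-sided p-value sums
all hypergeometric outcomes with probability not exceeding the observed
one (the probability-mass convention of `stats::fisher.test`, with a
$1+10^{-7}$ relative tolerance in the comparison); this differs from
doubling the smaller tail and is the convention asserted against an
independent enumeration oracle in the tests.  Depths above a 9000-read
cap are down-sampled hypergeometrically (seeded, reproducible).

Classification then applies, in order:

* **Bonferroni**: $p_{\text{bonf}} = \min(1, p\,m)$ with $m$ = number of
  tested SNPs, significant at $p_{\text{bonf}} < 0.01$;
* **top-5% ranking** over all tested SNPs (not only significant ones),
  ties broken by genomic order for determinism;
* **direction**: sign of AFC = mean DD frequency − mean LD frequency,
  with per-condition means computed as unweighted means over replicate
  frequencies;
* **typing** of top-ranked, higher-in-DD SNPs by mean DD frequency:
  type 1 in [0.8, 1], type 2 in [0.35, 0.8), type 3 in [0, 0.35).
  The inner boundaries are left-closed so that every frequency maps to
  exactly one type.

The direction-bias test is a 1-df chi-square goodness of fit against a
50:50 split without continuity correction (counts are large).  QQ data
pair the sorted observed $-\log_{10}p$ with $-\log_{10}(i/(m+1))$.
Population structure is summarised by non-metric MDS
(`MASS::isoMDS`, Kruskal stress-1 in percent) on Euclidean distances
between complete-case frequency profiles; populations with exactly
identical profiles are collapsed onto one point first, because zero
dissimilarities are inadmissible in the stress minimisation.

# Region calling and localisation

Significant SNPs within 100 kb of each other are linked into candidate
regions (single-linkage, order-independent, 1-based inclusive
coordinates).  Region/ROH overlap counts any shared base, and gene
reporting requires both region overlap and at least one founder variant
inside the gene span.

The localisation scan bins merged counts into 1-kb windows and scores
each bin with a generalized likelihood-ratio LOD,
$$\mathrm{LOD} = \log_{10}
\frac{\max_{p_1,p_2} L_{LD}(p_1)\,L_{DD}(p_2)}{\max_{p} L_{LD}(p)\,L_{DD}(p)},$$
with closed-form binomial MLEs.  Two adjustments reflect pool-seq
reality:

* **Chromosome-count cap.** Reads beyond $2 \times$`pool_n` (default
  2 × 3000 chromosomes) are proportionally rescaled: read depth beyond
  the number of pooled chromosomes re-measures the same pool and must
  not inflate confidence.
* **Fixed-SNP filter.** SNPs at frequency < 0.01 or > 0.99 in either
  condition are excluded before scanning, since near-fixed sites carry
  no usable contrast and destabilise the likelihood ratio.

Two Gaussian smoothing modes serve two different questions:

* **Detection (`"sum"`, bandwidth 30 bins).** An unnormalised kernel sum
  accumulates the LOD of linked neighbouring bins — a composite
  likelihood.  Reads in different bins are independent samples, and
  linked bins share the underlying contrast, so summing their scores is
  the natural aggregate; it is also what makes a fixed LOD threshold
  (default 75, with ≥1 Mb peak separation) meaningful when a single
  1-kb bin contains only one or a few SNPs.
* **Localisation (`"mean"`, bandwidth 100 bins).** For *position*,
  linked bins are redundant rather than independent: a composite-sum
  posterior $\propto 10^{\mathrm{LOD}}$ grossly overstates positional
  precision (in calibration runs it covered planted loci far below its
  nominal level).  Credible intervals therefore recompute the track over
  a window centred at the peak with a normalised Gaussian filter, whose
  local-average scale reflects how slowly positional information decays
  along a linkage block, and take the smallest contiguous bin run
  containing the peak bin that reaches 90% of the normalised
  $10^{\mathrm{LOD}}$ mass, grown greedily toward the heavier neighbour.

The credible window defaults to 1 Mb; `lod_peaks_with_ci()` widens it
per peak to the extent of elevated composite LOD (above half the
detection threshold within ±1.5 Mb), clamped to [1, 3] Mb — the same
rule, made systematic, as recalculating the widest peak over 3 Mb.
Each peak can finally be labelled with the majority trajectory type of
the typed SNPs inside its interval (`peak_selection_type()`).

At full SNP density (~1 SNP/kb) the local averages are supported by many
SNPs and intervals tighten to tens of kilobases; at the down-scaled
density used in the tests (one SNP per ~24 kb) they span hundreds of
kilobases to a few megabases, which is the honest localisation limit of
that density.

# Fitness assay statistics

Progeny of the four-way competition assay are classified by their
fluorescent markers (neither = White, GFP only = Green, DsRed only =
Red, both = Yellow), and the tester's comparative fitness is
$$\mathrm{CF} = \frac{2W + (G + R)}{2\,(W+G+R+Y)} \times 100,$$
the tester's share of parental genomes in the offspring pool; CF of
tester and competitor always sum to 100 and CF = 50 means equal fitness.
Condition contrasts of per-vial proportions use an exact conditional
Mann–Whitney test (full enumeration of group assignments with mid-ranks
— appropriate for 5–10 vials per group, where normal approximations are
poor) and a Welch t-test on arcsin-square-root transformed proportions.
Proportions are computed per vial and tested across vials, the vial
being the replicate unit.

# qPCR frequency estimation

Allele-specific primers differing at the 3′ terminal base amplify their
matched template earlier.  A primer pair qualifies only if on both pure
founder templates the matched primer leads by strictly more than 4.25
cycles.  With per-cycle efficiency $E$ (default 2, exposed as a
parameter since real efficiencies run slightly lower), a sample with
dark-allele frequency $f$ gives
$\Delta Ct = \log_E\!\frac{1-f}{f} + \text{offset}$; normalising against
a 50:50 calibrator removes the offset and inverts to
$f = 1/(1 + E^{\Delta\Delta Ct})$.  The simulator adds Normal cycle
noise (default SD 0.3 cycles, calibrated so that a 116-sample batch
reproduces the strong qPCR/sequencing concordance, R² ≈ 0.9, expected of
the assay); the estimator is the exact inverse of the simulator at zero
noise.  Concordance is reported as the OLS coefficient of
determination, which for a simple regression equals the squared
correlation — invariant to affine rescaling of the predictor, but not of
the response.

# Numerical and testing choices

* All stochastic functions take a `seed` and restore the caller's RNG
  state; identical seed and configuration give byte-identical output.
* Likelihoods are computed in log space with the $0\log 0 = 0$
  convention; binomial coefficients cancel in every ratio used.
* Test problem sizes are deliberately modest: unit tests run
  populations of tens to hundreds of individuals over 10–20 generations,
  and the end-to-end recovery checks run four complete experiments at
  the default scale (5000 SNPs, N = 1000, 49 generations, 3+3
  replicates, 179×); the full suite completes in a few minutes on one
  core.
* Degenerate inputs fail loudly and early: extinct populations report
  the generation, ragged or ambiguous sync input reports the line,
  zero-variance concordance and empty progeny tables are errors rather
  than NaNs.

# Worked example

```{r example, eval = FALSE}
sim <- simulate_reselection(seed = 1)
res <- reselection_scan(sim$counts)
table(res$scan$type_label)
peaks <- lod_peaks_with_ci(res$merged_LD, res$merged_DD)
peak_selection_type(peaks, res$scan)
```

# Known limitations

* The localisation scan is a composite-likelihood surrogate, not a full
  Bayesian linkage model; its detection threshold inherits meaning from
  the smoothing bandwidth, and its credible intervals are calibrated
  empirically (planted-locus coverage ≥ 80% at the default design), not
  derived.
* Typing is rank-based, so its sensitivity depends on how much of the
  genome competes for the tier (see the capacity argument above);
  dense multi-locus architectures will crowd out weak signals.
* The simulator's constant-N, panmictic, two-allele model omits
  demographic structure, *de novo* mutation and structural variation.
* Multi-allelic sites are dropped, not modelled.
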