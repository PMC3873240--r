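---
title: "Models and methods behind admixdemo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind admixdemo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

admixdemo reconstructs the demographic history of three-way admixed American
populations (Native American, European, and African ancestry) from four
complementary signals: the length distribution of local-ancestry tracts, the
amount of identity-by-descent (IBD) sharing, the joint site frequency
spectrum (SFS) of variants assigned to the Native American background, and
ancestry-specific allele frequencies estimated from unphased genotypes.
Every estimator ships with a synthetic-data generator that emulates its
inputs, so the whole pipeline is testable without any external data. This
vignette explains the models, the numerical choices, and what the generators
do and do not emulate.

## Ancestry tracts

**Model.** Local ancestry along a present-day chromosome is approximated by
a Markov jump process whose states are migrant cohorts: the pair (source
population, generation of entry). A lineage that entered the admixed
population $t$ generations ago has passed through $t-1$ meioses, so its
state changes at rate $t-1$ per Morgan; at a change, the meiosis generation
is uniform over the lineage's history and the new state is drawn from the
population's migrant composition at that generation. Tract lengths for an
ancestry are then phase-type distributed (the sub-generator restricted to
that ancestry's states), and expected tract counts per length bin on a
finite chromosome follow in closed form from the entry flux plus
start/end-censoring terms, evaluated through an eigendecomposition of the
sub-generator. For a single founding pulse with ancestry fraction $p$ at
generation $t$ this reduces to the textbook exponential length distribution
with rate $(t-1)(1-p)$ per Morgan.

**Fitting.** Observed tracts are binned into 30 logarithmic length bins
(the shortest bin starts at a configurable local-ancestry detection limit,
0.2 cM by default, reflecting the difficulty of calling short tracts); bin
counts are modelled as independent Poisson around the model expectation and
maximized by Nelder-Mead from 10 random starts on an unconstrained
parameter scale, with a quasi-Newton polish. Four model families are
implemented: a simultaneous three-source founding pulse; founding plus
constant European and Native inflow (the family used for MXL-style
histories); founding plus one later Native pulse (CLM-style); and founding
plus one later joint European/African pulse (PUR-style). Model selection
uses BIC (the number of observed tracts as the sample size); confidence
intervals come from a bootstrap over diploid individuals. Non-integer pulse
times are distributed over the two neighbouring generations so that the
total contribution is preserved exactly and the split is linear in the
fractional part: an onset of 13.02 generations founds the population 14
generations ago with a 0.98 replacement at 13. Calendar conversions use 30
years per generation.

**Generator, and a known approximation.** The tract generator paints
chromosomes forward in time through a Wright-Fisher population of haploid
genomes (2000 by default, approximating the model's large-population
assumption), with Poisson crossovers per Morgan and no interference, and
migrant replacement per the history. The analytic model is first-order
Markov along the chromosome; the true process is not, because a junction
can return to the chromatid it just left. The resulting discrepancy is
$O(1/t)$: dramatic for pulses one or two generations old, a few percent
per bin at study-scale onsets ($t \approx 13$-$15$), where it sits within
single-replicate Poisson noise at study sample sizes. Tests compare
simulation and analytic expectation at exactly that scale (within 3 Poisson
standard deviations on at least 95% of informative bins). Recovered onsets
inherit a small upward bias (of order +0.5 generations at $t = 15$) from
the same approximation; this is visible in the recovery suite and is the
field-standard trade-off for a closed-form likelihood.

## IBD sharing and recent effective size

For a haplotype pair in a panmictic population of constant diploid size
$N_e$, the coalescent time at a locus is approximately exponential with
mean $2N_e$ generations, and conditional on TMRCA $t$ a maximal
constant-TMRCA segment has length $\mathrm{Exp}(2t)$ per Morgan. The
expected number of observed segments of at least $u$ Morgans per pair is

$$ E[N(u)] = \frac{\sum_c (L_c - u)_+}{N_e\,(1/(2N_e) + 2u)^2}
           + \frac{C}{1 + 4 N_e u}, $$

where the second term counts segments truncated at the $C$ chromosome
starts; the $(L_c - u)_+$ accounts for right-edge censoring. The estimator
inverts this strictly decreasing function at the observed mean segment
count per haplotype pair (segments of at least 4 cM by default); zero
observed segments return an infinite-size flag. The simulator draws the
same stationary segment process sequentially along each chromosome,
restricted to TMRCA below $5/u$ (older backgrounds contribute segments of
length $u$ with probability below $e^{-10}$); the estimator-simulator
recovery loop is accurate to a few percent at 55 diploids.

IBD/ancestry consistency statistics annotate each segment with the
ancestry intervals of its two haplotypes: the majority origin, the
fraction of the segment on which the labels disagree, and the number of
internal switch points on the agreeing stretches. The switch-density trend
(switch points per cM against segment length) is fit by length-weighted
least squares, with a one-sided cluster bootstrap resampling individual
*pairs*: all segments shared by a pair enter or leave a replicate together,
which preserves the within-pair dependence that motivates resampling above
the segment level while keeping the null p-value calibrated (resampling the
two endpoint individuals independently and weighting records by the product
of their multiplicities roughly doubles the bootstrap slope variance, and
the resulting p-values are visibly under-dispersed under a no-trend
generator). Under the null the p-value is approximately uniform, which the
suite checks by Kolmogorov-Smirnov over 200 replicates.

## Joint SFS engine and the split model

The engine propagates the expected density of derived-allele frequencies
under pure drift, $\partial_\tau \phi = \frac{1}{2\nu}\partial_x^2[x(1-x)\phi]$,
with time in units of $2N_{\mathrm{ref}}$ generations and $\nu = N/N_{\mathrm{ref}}$.
The density is held as expected variant mass on a frequency grid with a
uniform backbone (60 cells by default) plus geometrically refined nodes
inside the boundary cells — the neutral density diverges as $\theta/x$, so
the young-variant classes need sub-cell resolution; with the refined grid
the equilibrium sample spectrum matches $\theta/i$ to better than 1% at
every class for samples up to about 30, without grid extrapolation
(optional Richardson extrapolation over backbones is retained). Mass moves
under a conservative finite-volume stencil stepped by Crank-Nicolson, with
adaptive steps bounded by $10^{-3}$ time units and a twentieth of the
current $\nu$; mutations enter at the lowest interior node at rate
$\theta/(2x_{\mathrm{inj}})$ per unit time. Boundary nodes receive absorbed
mass, and in two-dimensional (pairwise) spectra keep evolving along the
other axis, so classes private to one population are handled exactly.
Splits copy the trunk mass onto the grid diagonal.

The split model: an ancestral population of size $N_{\mathrm{anc}}$
experiences a founding bottleneck $T_{\mathrm{found}}$ generations ago,
dropping to $N_{\mathrm{bot}}$ and recovering exponentially to
$r N_{\mathrm{bot}}$ by the first split ($r = 100$ fixed, following the
convention that larger values leave the likelihood flat); the first
population branches at $T_1$, the remaining trunk splits at $T_2 \le T_1$,
and each branch keeps its own constant size. An alternative trunk shape — a
brief fixed-duration squeeze with full recovery — is available for
negative-ascertainment experiments. A fixed post-contact bottleneck window
can be imposed on any branch for sensitivity analyses.

Fitting uses the pairwise composite likelihood: independent Poisson
likelihoods over the unmasked entries of the three two-population spectra
(fixed classes masked), with $\theta$ profiled analytically or fixed when
the mutational scale is known (as it is in simulation harnesses; with
$\theta$ free the approximation families used in ascertainment experiments
can trade total variant count against demography and run away). All three
split orderings are fitted and the best reported. Physical units come from
one anchor: fixing the founding epoch at 16,000 years (30 years per
generation) sets $N_{\mathrm{ref}}$, after which all times and sizes scale
linearly with the anchor and $\mu = \theta/(4 N_{\mathrm{ref}} L)$; the
calibration object exposes the scaling law so users can re-anchor without
refitting.

**Forward simulator.** Allele frequencies are propagated per locus by
binomial Wright-Fisher sampling through the population tree; standing
variation at the simulation root is drawn from the neutral stationary
density, and new mutations enter at rate $\theta\nu/2$ per generation at
frequency $1/(2N)$. Runs may be diffusion-rescaled (sizes and times divided
by a common factor, 4 by default), which leaves expected spectra invariant
at $O(\mathrm{scale}/N)$ granularity; population sizes during growth are
evaluated at step midpoints to avoid a systematic drift bias. The engine
and the simulator agree at the percent level per class (chi-square test at
$10^5$ loci in the suite).

**Identifiability caveats** (established by the recovery suite, and the
reason two conventions are fixed during refits): the expansion branch's
size (the MXL-style branch, a roughly five-fold expansion) has a
one-sidedly flat likelihood at desk-scale variant counts, so its MLE
scatters and skews high by several percent even with hundreds of thousands
of loci; and the founding-bottleneck time trades against its severity. The
recovery harness therefore fixes the ascertainment-equivalent bottleneck
severity at its generator value (a convention of the same character as
$r = 100$) and averages over simulation replicates.

## Negative ascertainment

Variants observed in any outgroup reference panel, or observed in the
admixed panel only inside segments with no Native American ancestry, are
discarded; surviving derived alleles are attributed to the Native
background (capped by the number of Native haplotypes in the diploid
state). Because European haplotypes in ancestry-heterozygous segments leak
private variation through the filter, the leakage is estimated empirically:
pseudo-samples assembled from European/European diploid segments are run
through the same filter, and the surviving counts per frequency class —
dominated by singletons — are subtracted from the Native spectrum
(truncated at zero). Per-site Native sample sizes vary with the ancestry
mosaic, so sites are hypergeometrically projected to a common size.

**The bottleneck approximation, and an honest negative result.** The
package includes the validation harness that asks whether negative
ascertainment is equivalent to a drastic bottleneck at the outgroup split:
simulate two populations (split 12.1 kya) plus an outgroup (split 16.5
kya), discard variants seen in 100 outgroup diploids, and refit with a
severe root bottleneck at a free time. In this harness the equivalence is
only partial. With a 100-diploid outgroup, roughly a third of the
ascertained-visible variants predate the outgroup split: ancestrally rare
variants that the outgroup sample misses (or that died along the outgroup
lineage) while drifting upward in the smaller daughter populations. No
single root bottleneck reproduces "old but only rare" variation — erasure
also flattens survivors to intermediate frequencies — so maximum likelihood
places the bottleneck substantially earlier than the outgroup split
(about a factor of two in our runs), and this preference is genuine (direct
likelihood comparisons, not an optimizer artifact). What the approximation
does deliver, matching the published account: with the approximant sharing
the truth's model family, the split time and the population sizes are
recovered within a few percent. The corresponding acceptance check on the
bottleneck time is left failing deliberately rather than re-tuned.

## Ancestry-specific allele frequencies (EM)

Given unphased genotypes $G \in \{0,1,2\}$ and diploid local-ancestry
states (unordered pairs), the two haplotypes are independent Bernoulli
draws from their own ancestry's derived frequency:
$P(G{=}1 \mid a,b) = f_a(1-f_b) + f_b(1-f_a)$, and so on — phasing-free by
construction, which is why phase-switch errors injected by the generator
leave the estimates bit-identical. Site posteriors over a 201-point
frequency grid (0.5% resolution) are combined with a per-ancestry prior;
the prior is re-estimated as the average of the site posteriors, and the
two steps iterate to self-consistency (20 iterations by default) with a
non-decreasing marginal likelihood asserted on every run. Only the
genotype-heterozygous, ancestry-heterozygous class couples two frequencies;
everything else factorizes, which keeps 100,000-site panels at around 32
matrix products per iteration. Three-ancestry sites are handled by exact
tensor contraction. Reported intervals are highest-posterior-density sets
on the grid; the monomorphic-site correction reweights the prior by the
inverse detection probability $1/(1-(1-f)^{\bar k})$ and reconciles the
implied undetected mass with the observed monomorphic count at the $f = 0$
point (this reconstruction of the correction is validated by a simulation
oracle showing a large KL improvement toward the true prior, since the
original algebra is not preserved in the source text).

The validation panel mirrors the published check: 84 pseudo-admixed
diploids, each one European and one African haplotype, at 100,000 sites
whose ancestral frequencies follow a Balding-Nichols model
($F_{st} = 0.15$) around a neutral 1/x ancestral spectrum truncated at 1%
(emulating discovered variants); about three-quarters of sites are
polymorphic in-sample, and fewer than 0.1% of polymorphic sites have a
sample frequency outside the 95% interval — far below the 0.5% acceptance
threshold, and consistent with the intervals targeting population rather
than sample frequencies.

## What the generators do not emulate

Sequencing reads, genotype likelihoods and coverage, reference-panel
phasing, recombination-map heterogeneity (uniform maps are assumed, as the
original local-ancestry inputs' map choice is not recorded), crossover
interference, and migration among the three Native branches (the model has
none by construction). A green test therefore establishes correctness of
the estimators under the stated models, not robustness to these real-data
features.

## Interfaces

Readers and writers cover the working formats: VCF genotypes (reading via
Bioconductor's VariantAnnotation), local-ancestry segment TSV (0-based,
half-open, cM with 4 decimals), IBD match TSV, the three-line SFS text
format (dimensions, row-major counts, mask), and a JSON pipeline
configuration whose stages carry explicit seeds. The package's functions
are the interface; `scripts/acceptance.R` strings the full pipeline
together end to end.
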