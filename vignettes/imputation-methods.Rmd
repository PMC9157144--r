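---
title: "Evaluating genotype imputation for damaged, low-coverage genomes: models and methods"
author: "paleoimpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating genotype imputation for damaged, low-coverage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ancient genomes are usually sequenced to well below 1x coverage, and the
molecules carry post-mortem cytosine deamination, read as C→T (and, on the
complementary strand, G→A) substitutions. Genotype imputation against a
phased reference panel of modern haplotypes can recover much of the missing
information, but its behaviour on this kind of input — probabilistic
genotype likelihoods rather than called genotypes, heavy missingness,
damage-driven site exclusion, and a reference panel that may not represent
the sample's ancestry — needs systematic measurement before imputed
genotypes are trusted downstream.

`paleoimpute` is a self-contained framework for exactly that measurement.
It simulates a phased reference panel and damaged low-coverage study
individuals whose true genotypes are known, pushes them through a genotype
likelihood → damage filter → imputation pipeline, and scores the result with
the metric suite used in empirical imputation studies: overlap-stratified
genotype concordance, heterozygote discordance binned by minor allele
frequency (MAF), reference-affinity differences, posterior-probability
filtering with retained fractions, and principal-component projection of
samples with missing data.

# The synthetic data generator

## Haplotype panel

The panel is generated by a sequential product-of-approximate-conditionals
(PAC) scheme. Haplotype 1 is drawn per site from a Beta(0.2, 2)
site-frequency prior, skewed toward rare alleles. Every later haplotype is a
recombining mosaic of the haplotypes generated before it: the template
switches between adjacent markers $m$ and $m+1$ with probability
$1 - e^{-\rho_m}$, and each copied allele is flipped with miscopy
probability $\theta_\text{sim}$. The same mosaic process, applied to the
finished panel, generates the study individuals' haplotypes.

The defaults were fixed once, on realism grounds:

* `theta_sim = 0.02` (panel generation). This sets panel diversity; it
  yields a per-site heterozygosity of roughly 0.15 at segregating sites,
  typical of human SNP-array-density marker sets, and a strongly
  rare-skewed frequency spectrum.
* `rho_scale = 5e-7` per bp, so an average 1 kb inter-marker interval has
  switch intensity $\rho \approx 5\times 10^{-4}$ and copying segments span
  about 2 Mb (roughly 2 cM) — the scale of haplotype sharing a
  population-matched panel offers. Note that pairwise LD between two panel
  haplotypes decays faster than the per-copy switch rate, because the
  sequential construction compounds switches along the copying genealogy
  (mean path length $\approx 2\ln K$); the chosen scale keeps that
  compounded decay at a realistic hundreds-of-kb scale. An early candidate
  value ten times larger produced panels whose haplotype sharing decayed
  within ~20 markers — much too fast for meaningful imputation and
  unrepresentative of dense human data.
* `transition_fraction = 2/3`: human SNP sets are transition-enriched;
  each marker gets a C/T or G/A pair (strand randomised) with this
  probability and a transversion pair otherwise.
* 10% of the haplotypes form a mildly diverged subpopulation (extra
  independent allele flips at rate 0.02). Restricting imputation to the
  remaining 90% ("SUBSET") emulates a smaller population-specific panel,
  while "FULL" adds the diverged diversity — the contrast behind the
  configuration comparison.
* `divergence_rate` on study individuals (default 0) adds private variation
  not represented in the panel, emulating ancestries (e.g. hunter-gatherer
  genomes) that modern panels do not cover.

Study individuals are sampled with `theta_sim = 0.001`, so their haplotypes
are near-exact panel mosaics with a ~0.1% private-allele rate; those private
alleles are the irreducible error floor of any panel-based imputation.

## Reads, error and damage

Per site and individual, read depth is Poisson with mean equal to the
target coverage $C$; each read carries one of the two true alleles with
probability 1/2, a base error flips ref↔alt with probability
$\varepsilon$ (default 0.01), and deamination then acts at the nucleotide
level: a carried C is observed as T with probability $\delta$ (default
0.02), and independently G as A. The observed base is counted toward
whichever allele it matches; at transversion sites a deamination product
matches neither allele and the read is discarded. Because both strand
orientations of a transition pair funnel damage the same way (C→T on one
strand is G→A on the other), the model is strand-symmetric by construction.
Counts are drawn directly from the per-read multinomial these rules imply,
which is distributionally identical to simulating individual reads.

Downsampling to a lower coverage keeps each read independently with
probability target/realised — binomial thinning of the counts, equivalent
to read-level downsampling of alignments, and composable (thinning to 1x
then 0.5x equals thinning to 0.5x directly).

The generator deliberately does **not** emulate mappability structure,
contamination, indels, multi-allelic sites, base-quality variation, or the
block-like LD of real recombination maps. Passing benchmarks here therefore
show that the pipeline behaves correctly *under the model's own
assumptions* — matched panel, honest likelihoods, Poisson depth — and gives
an upper bound on, not a guarantee of, real-data performance.

# Genotype likelihoods and filters

For alt-allele dosage $g \in \{0,1,2\}$ with $r$ ref and $a$ alt reads,

$$L(g) \propto p_g^{\,a} (1-p_g)^{\,r}, \qquad
  p_g = \tfrac{g}{2}(1-\varepsilon) + \bigl(1-\tfrac{g}{2}\bigr)\varepsilon,$$

normalised to sum to one; zero-depth sites are flagged missing and carry the
flat triple. A single scalar $\varepsilon$ is used rather than per-base
qualities because the simulated pileups carry none. Deliberately, the
likelihood model knows nothing about deamination — exactly like a standard
caller run on ancient data — so damage shows up as reference bias unless
filtered.

Gold-standard ("HQ") genotypes are called from 30x source reads as the
flat-prior posterior mode, with Phred-scaled confidence
$-10\log_{10}(1-\text{posterior})$ capped at 99 to avoid infinities, and
pass filters DP ≥ 15, QUAL ≥ 50, and (heterozygotes only) both allele
depths ≥ 25% of the total.

The deamination site filter drops, per individual, every site where the SNP
is a C↔T pair and the most likely genotype contains a T allele, and
correspondingly A at G↔A pairs. Argmax ties are resolved conservatively: if
any tied genotype contains the damage-product allele, the site is dropped.
Missing sites are kept. Dropped sites re-enter imputation as missing data
(flat likelihood), so they are imputed purely from flanking haplotype
context — at 1x this filter, not depth, is the dominant source of
missingness at transition sites, which is the realistic and intended
behaviour of this pipeline family.

# The imputation engine

## Model

The engine is a diploid Li–Stephens haplotype-copying hidden Markov model:
the hidden state at marker $m$ is an ordered pair $(j,k)$ of panel
haplotypes ($K^2$ states), with uniform initial distribution. Transitions
factorise per haplotype,

$$P(j' \mid j) = (1-\tau_m)\,\delta_{jj'} + \tau_m / K,
  \qquad \tau_m = 1 - e^{-\rho_m},$$

with $\rho_m$ taken from the panel's inter-marker intensities (a genetic
map, when one is supplied for real data). Emission in state $(j,k)$ is

$$e_{jk}(m) = \sum_g A\bigl(g \mid h_j[m], h_k[m]\bigr)\, L_g(m),$$

where $A$ is the dosage distribution after independent per-allele miscopy
with probability $\theta$ (default $10^{-3}$, matching the study-mosaic
rate) and $L$ is the genotype likelihood triple; missing sites contribute a
constant emission. Posterior genotype probabilities come from
forward–backward with an emission re-decomposition that yields the full
posterior over the ordered true-allele pair, from which GP, dosage
($DS = GP_1 + 2\,GP_2$), the best-guess genotype and the phased best-guess
haplotypes all derive.

## Numerics and complexity

The factorised transition makes one forward or backward update $O(K^2)$
via row sums, column sums and the grand total. Underflow is controlled by
rescaling; the rescaling is folded into the transition constants (each step
divides by the previous vector's total), so no separate normalisation pass
is needed. Forward vectors for the backward sweep are stored blockwise with
checkpoints and recomputed inside blocks, keeping memory at
$O(K^2(B + M/B))$. Arithmetic is double precision throughout; the *stored*
forward copies switch to single precision above $2\times10^7$ state-markers,
where the ~$10^{-7}$ relative storage error is far below the statistical
resolution of the posteriors. On small instances storage stays double, and
the engine agrees with exact path enumeration to $10^{-10}$ — the test
suite enforces this on random tiny instances, and additionally checks the
fused implementation against an independent dense-matrix forward–backward
at larger K and across block layouts.

Long marker sets are processed in overlapping windows (defaults: 50,000
markers per segment, 25,000 overlap) and stitched by assigning each marker
to the window whose midpoint is nearest, ties to the earlier window. At the
default benchmark size a single window covers everything; a property test
verifies that windowed and unwindowed posteriors agree to well under
$10^{-3}$ mean absolute difference when the overlap spans the HMM's
correlation length.

## Joint study samples

Imputation methods that model the study sample jointly let low-coverage
individuals inform one another. This engine uses an iterative
panel-augmentation surrogate: iteration 1 imputes every individual against
the panel alone; each later iteration re-imputes each individual against
the panel augmented with the phased best-guess haplotypes of all *other*
study individuals from the previous pass (two iterations by default).
Phasing takes the maximum-posterior ordered allele pair per site, with
exact ties between the two heterozygote orderings resolved by keeping the
previous orientation (switch-minimising). No claim of equivalence to any
specific joint-modelling implementation is made; only the directional
benefit — joint mode helps, most visibly for rare heterozygotes — is
asserted and tested.

# Evaluation metrics

Evaluation is restricted to sites with a passing gold-standard call, split
into *overlapping* (≥ 1 read in the downsampled input) and *nonoverlapping*
(zero reads; imputed purely from context) sets. Concordance is the fraction
of sites whose imputed best-guess equals the gold standard, overall and per
gold-standard genotype class. Heterozygote discordance is binned into 50
equal-width MAF bins over (0, 0.5], left-open edges, MAF estimated from the
full panel; monomorphic sites are excluded and empty bins are reported as
missing rather than zero. An optional 3-point moving average can smooth
binned curves (off by default, for raw reporting).

Reference affinity is the fraction of a sample's sites whose genotype
equals the most frequent genotype among panel individuals (ties toward the
lower alt dosage, a deterministic, reference-majority-conservative choice);
the per-bin difference affinity(HQ) − affinity(imputed), averaged over
individuals, is negative where imputation has made the sample more
reference-like than its own gold standard — the quantitative signature of
reference bias.

The posterior filter removes sites with max GP below 0.99 and reports
retained fractions overall and per MAF bin (mean, min, max over
individuals).

# PCA projection with missing data

A reference PCA is fitted to a synthetic "modern panel" of diploid
genotypes drawn from the simulated reference population (60 individuals by
default), after removing markers with MAF < 1% or missingness > 10%.
Entries are normalised with the EIGENSTRAT convention,
$(g - 2p)/\sqrt{p(1-p)}$, missing entries set to 0 after centring, and the
top 2 components retained; component signs are canonicalised (the
largest-magnitude loading positive) for reproducibility.

A sample observed at only a subset of sites is projected by known data
regression (KDR): a minimum-norm least-squares map is fitted from the
reference samples' normalised genotypes at the observed sites to their
stored scores, and applied to the sample. The pseudoinverse handles
observed-site counts both above and below the reference sample count
without an explicit ridge penalty; with all sites observed in the exact-fit
regime, a reference sample recovers its stored score. For each evaluation
individual three projections are compared in PC1–2: the gold-standard
calls, the GP-filtered imputed genotypes, and the "low-coverage" genotypes
(best guess from the filtered likelihoods at sites with data, missing
elsewhere). Their distances to the gold-standard projection quantify how
much of the information lost by downsampling imputation recovers.

# Benchmark scale and reproducibility

The default benchmark is desk-scale by design: K = 200 panel haplotypes,
M = 20,000 markers on one 20 Mb synthetic chromosome (~1 kb spacing), 5
evaluation individuals simulated at 30x for gold-standard calling and
downsampled to 0.1–2.0x for imputation; joint runs can add background
"ancient" individuals at mixed coverages. These sizes keep a full
configuration comparison, coverage sweep, in-depth filtered analysis and
PCA comparison reproducible in minutes on a single core while preserving
every contrast of interest. Every stochastic stage draws from its own
stream derived deterministically from one root seed, so a configuration
reproduces its outputs exactly.

# Known limitations

* The PAC generator's copying genealogy compounds recombination along the
  panel, so panel-internal LD is shorter-ranged than the study-to-panel
  match length; both scales are realistic only to first order.
* The folded site-frequency spectrum carries a small pile-up near MAF 0.5
  from high-prior sites drifting toward fixation; MAF-binned curves near
  0.5 are accordingly noisier.
* The joint mode is a surrogate; its augmented haplotypes are best guesses
  and can recalibrate (slightly lower) posterior confidence even as
  accuracy improves.
* Real-data adapters (external panel and GL VCFs, genetic maps) exercise
  the same engine but none of the claims tested here transfer to real data
  automatically — mapping bias, contamination and panel mis-specification
  are all outside the generator.
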