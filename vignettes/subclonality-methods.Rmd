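---
title: "Models and methods behind subclonality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind subclonality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subclonality)
```

# The problem

A bulk tumor sample is a mixture of cell populations: euploid (normal)
cells and one or more aneuploid tumor clones, each defined by the somatic
events it carries. Two local quantities summarize this mixture. For a
somatic copy-number alteration (sCNA), the **segmental aneuploid genome
proportion (sAGP)** is the fraction of sampled cells that carry that
particular alteration — a per-segment generalization of a single global
tumor purity. For a somatic point mutation, the **cancer cell fraction
(CCF)** is the fraction of cells carrying the mutant allele. This package
estimates both from standard inputs — allele-specific SNP intensities or
read counts for the copy-number side, and somatic variant read counts for
the mutation side — and then summarizes the macroscopic clonal structure of
the sample from the resulting sAGP or CCF spectrum.

# Regional two-way mixing and canonical lines

Each genomic segment is summarized by its median log R ratio (LRR, the
log2 tumor/normal total-signal ratio) and its median folded B-allele
fraction (fBAF = |BAF − 0.5|, over germline-heterozygous markers). Under
the model, each segment mixes exactly two local populations: the euploid
state (1, 2) and one aneuploid state with minor/total copies
$(n_b, n_t)$ present in a fraction $p$ (the sAGP) of cells. The expected
signals are

$$\mathrm{fBAF}(p) = \left|\frac{p\,n_b + 1 - p}{p\,n_t + 2(1-p)} -
\tfrac12\right| + x_0, \qquad
\mathrm{LRR}(p) = \log_2\!\big(p\,n_t + 2(1-p)\big) - 1 + y_0,$$

where $(x_0, y_0)$ is the observed position of the balanced state. As $p$
runs from 0 to 1 each state traces a *canonical line* starting at the
origin; mixing with euploid cells contracts aneuploid segments toward the
origin along their line. Fitting a segment means finding the closest point
over all candidate lines ($0 \le n_b \le n_t/2$, $n_t \le 6$ by default):

* **Criterion (a)** — only lines whose minimized Euclidean distance is at
  most $2\sqrt{sd_{BAF}^2 + sd_{LRR}^2}$ are admissible, where the two
  noise scales come from the scatter of the baseline cluster (MAD ×
  1.4826, floored at $10^{-3}$ so that noiseless input remains fittable).
* **Criterion (b)** — among admissible lines, minimize
  $F = |\bar n_t(p) - \mathrm{ploidy}| + |p_s - p|$ with
  $\bar n_t(p) = 2(1-p) + n_t p$. We read the selection rule as an absolute
  deviation on both terms — the intent is "total copy number close to the
  genome-wide ploidy and sAGP close to the sample-wide AGP", which a signed
  difference would not express. Exact ties resolve by smaller residual,
  then lower $n_t$.

Segments within the criterion-(a) threshold of the origin are called
euploid ($p = 0$); segments with no admissible line fail the regional
two-way mixing hypothesis and are reported missing (`NA`), a state that
propagates into CCF estimation.

Because criterion (b) needs the sample-wide AGP $p_s$ and the average
ploidy, which themselves depend on the per-segment fits, estimation is
two-pass: the first pass resolves ambiguity by residual alone, after which
$p_s$ is taken as the largest kernel-density mode of the fitted sAGP values
and ploidy as the length-weighted mean of $\bar n_t$; the second pass
applies criterion (b) with those values. The 1-D minimization over $p$ on
each line uses a 101-point grid scan followed by local refinement — the
fold in the BAF coordinate creates a non-smooth point that defeats naive
local optimizers.

The near-origin genotype ambiguity after whole-genome doubling (an AABB
balanced state sits at the same fBAF as AB) is handled by an optional,
conservative heuristic: refit with the origin reinterpreted as (2, 4) and
keep it only if the aggregate residual halves. It is off by default; the
full ascertainment procedure for doubled genomes is out of scope.

# Mutation scenarios and CCF

For a mutation inside an sCNA with known $(n_b, n_t, p)$, the relation
between the somatic allele frequency $f$ (mutant reads / depth) and CCF
depends on the order and phase of the two events. Four scenarios cover the
possibilities under the maximal-parsimony assumption (no recurrent events):
the mutation preceded the sCNA and sits on the amplified/retained parental
chromosome (**A1**) or on the other one (**A2**); the sCNA preceded the
mutation (**B**); the two arose on independent lineages (**C**). Each
scenario implies three coexisting subpopulations with fractions
$r_0 + r_1 + r_2 = 1$, and linear algebra on the expected read fractions
gives, with $\bar n_t = 2(1-p) + n_t p$:

$$\mathrm{CCF}^{A_1} = \bar n_t f - p(n_a - 1), \quad
\mathrm{CCF}^{A_2} = \bar n_t f - p(n_b - 1)\ (n_b \ge 1), \quad
\mathrm{CCF}^{B/C} = \bar n_t f.$$

For $n_b = 0$ states (deletion, LOH) the A2 branch — the mutation was on
the chromosome that was later lost — shares the B/C expression. Here CCF
is defined as the fraction of cells *physically carrying* at least one
mutant copy: cells that lost the mutant allele do not count. This choice
follows the per-type results (CN-LOH: $2f$; deletion: $f(2-p)$ in every
scenario) rather than the general $n_b \ge 1$ formula, whose naive
extension to $n_b = 0$ would count carriers of zero copies. For the same
reason A2 is dropped from the admissible set of CN-LOH and balanced-gain
states, where it is fully degenerate with C (same populations, same
expression); hemizygous deletion retains all four labels, with A2
numerically identical to C. In diploid territory the relation collapses to
$\mathrm{CCF} = 2f$.

Each scenario also constrains the attainable $f$ to an interval (its
*zone*): e.g. A1 of an amplification allows
$f \in [2p/(2+p),\,(1+p)/(2+p)]$ while B allows $[0,\,p/(2+p)]$. The
scenario posterior integrates the binomial read-count likelihood over each
zone (flat prior on the true $f$), in closed form via the regularized
incomplete beta function, and normalizes. The smallest combination of
scenarios reaching posterior probability 0.95 — searched singles, then
pairs, triples, full set, by decreasing mass — is assigned; probabilities
are re-normalized over the admissible set before thresholding. CCF is
reported when all assigned scenarios share one expression (so CCF is often
identifiable even when the scenario is not); conflicting sets (A1 joined
with another label, for amplification or CN-LOH) yield a missing CCF with
both candidate values kept for QC. Observations outside every zone —
possible under read noise — fall back to the B/C expression and are
flagged. Posterior moments of CCF come from the binomial likelihood
composed with the inverse CCF expression under a flat prior on CCF,
integrated by Simpson's rule on 2001 fixed points; point estimates are
clipped to [0, 1] with the pre-clip value retained.

# Clonal structure

The genome-wide spectrum of sAGP values (or a CCF spectrum) is summarized
by two competing models. Model-1 is a single Gaussian peak over a uniform
background,
$\ell = \sum_i \ln\!\big(A/\mathrm{range}(Y) + (1-A)\,N(y_i;\mu,\sigma)\big)$
with $A, \mu \in (0,1)$, fitted by multi-start bounded optimization.
Model-2 is a Dirichlet-process mixture of normals with a
normal/inverse-gamma base measure (the 1-D form of the
normal/inverse-Wishart), fitted by Gibbs sampling: collapsed
Chinese-restaurant updates for assignments, conjugate draws for cluster
parameters, a Gamma update for the base-precision scale $k_0$, and an
Escobar–West update for the concentration, with Gamma(1, 1) priors on both
— the concentration's Gamma hyperparameters are the natural reading of the
two otherwise-unused prior constants in the model's parameter count.
Defaults are 10,000 iterations, 2,000 burn-in, thinning 5.

The DP fit is reported as a point estimate: the posterior-mode number of
occupied clusters, represented by the retained sample of that size with
the highest joint density (classification likelihood × parameter priors ×
partition prior). Using the joint density, not the raw likelihood, matters:
maximizing the likelihood over thousands of retained states selects
degenerate tiny-variance clusters and overstates the fit. The
log-likelihood entered into BIC is the mixture log-density of the data at
this point estimate, with $k = 3$ (Model-1) against $k = 7$ (Model-2, its
hyperparameter count); the smaller BIC wins. Peaks with less than 5% of
the mass are not counted (a reporting threshold only, configurable). The
chain is run on sorted input with a fixed seed, which makes the fit
exchangeable in the order of the data. A stability heuristic warns when
the modal cluster count does not dominate the last quarter of the chain —
expected, and harmless, on near-uniform spectra.

Before fitting, per-bin spectra are filtered: bins with median folded BAF
≤ 0.04 and |median LRR| ≤ 0.16 are declared euploid (sAGP 0), values
≤ 0.05 are removed so the near-zero pile does not masquerade as a peak,
and samples with fewer than 50 surviving values are flagged rather than
fitted.

# Segmentation

Two spatial units are supported. Fixed bins of 500 germline-heterozygous
markers give identically-sized, spatially correlated units suited to
spectrum exploration; trailing part-bins keep their own bin if they hold at
least half a bin's het markers, otherwise they merge into the previous bin.
Alternatively, change-point detection on LRR (all markers) and on folded
BAF (het markers) yields natural sCNA units: recursive binary splitting
accepts the split maximizing the standardized mean-difference statistic
when its permutation p-value is below 0.01 (1,000 permutations, first
maximum on ties), stopping below 5 markers per segment. The change-point
engine is deliberately simple and pluggable — externally produced segment
tables can be supplied instead — since change-point detection is
established prior art; what is specific here is the merge rule (a BAF
change point within 5 markers of an LRR change point is discarded as a
blurred duplicate of the same event, BAF marker positions being sparser)
and the summaries (medians, chosen over means for robustness where the
two conventions conflict; BAF is folded before the median is taken).
When counts rather than array intensities are supplied, per-site LRR is
median-centered genome-wide so the euploid mode sits near zero before
baseline anchoring; the baseline offset $y_0$ absorbs the remainder.

# The simulator and what it does (and does not) show

`simulateSegments()` reproduces the validation conditions used throughout:
200 euploid + 200 sCNA segments, the sCNAs split 2:1 between a dominant
clone and a minor clone, states drawn 2/7 deletion (0,1), 2/7 CN-LOH
(0,2), 2/7 amplification (1,3), 1/7 balanced doubling (2,4), and observed
summaries drawn from the canonical position plus Gaussian noise with
$\sigma_{BAF} = 0.01$ and $\sigma_{LRR} = 0.04$ — segment-level scales
equivalent to an sCNA of roughly 36 array markers. `simulateVariants()`
places mutations uniformly by genome length (the default layout makes
euploid territory half the genome), draws each in-sCNA mutation's scenario
uniformly from the admissible set and its SAF uniformly within the
scenario's zone, and samples reads as $N \sim$ Poisson(coverage) (zero
depths redrawn) and $S \sim$ Binomial$(N, f)$. Deliberately, the *estimated*
$(n_b, n_t, p)$ of the host segment — not the simulation truth — drives the
variant simulation and the CCF benchmark, so upstream estimation error
propagates realistically.

What the simulator does not emulate: GC waves and other spatial intensity
artifacts, marker-level overdispersion, sequencing error in $S$,
multi-population mixtures within one segment, and genome doubling. Passing
the validation therefore demonstrates correctness of the estimators under
the stated noise model, not robustness to platform artifacts.

Benchmark results in this package are computed, not quoted:
`runCcfValidation()` runs the four dominant/minor settings
(0.9, 0.8), (0.9, 0.4), (0.5, 0.3), (0.3, 0.1) at coverages 50 and 100
with 4,000 variants each, and `runComparisonProtocol()` runs the
200-CNA / 1,000-mutation protocol with sAGP ~ U(0,1) at coverage 50.
At these sizes the whole benchmark completes in a few minutes on one
core. One observation from running it: at coverage 50 the rank correlation
between true and estimated CCF is limited by binomial read noise itself —
for the euploid half of the variants no estimator can beat the noise floor
of the $2S/N$ relation — so the low-coverage cases sit at that floor, and
no amount of modeling recovers rank information the reads do not carry.
The comparison protocol also scores two deliberately mis-specified
estimators (one ignores the mutation-only population, i.e. applies the
B/C expression everywhere; one forces A1 everywhere); both trail the full
model, reproducing the characteristic biases of methods that skip the
scenario taxonomy.

# Numerical and design choices

* Heterozygous-site calling from the matched normal uses a fixed band
  (normal BAF within 0.5 ± 0.2); germline genotypes are assumed known to
  that precision, genotype calling itself being upstream.
* Coordinates are 1-based inclusive (VCF convention); interval arithmetic
  is half-open internally. Multi-allelic VCF records are skipped (the
  model is biallelic); tabular somatic input (chrom, pos, S, N) is
  accepted as a fallback.
* The criterion-(a) threshold multiplier (2), the candidate-state bound
  ($n_t \le 6$), the scenario threshold (0.95, applied to re-normalized
  probabilities), QC filters (depth ≥ 20, SAF ≥ 0.05; mirror the
  recommended variant QC and are disabled inside the simulation
  benchmarks, which score every simulated read), and all DP priors are
  exposed in configuration.
* An optional standardized metric (per-axis residuals divided by the
  baseline noise scales) is available behind a flag for samples with very
  unequal BAF/LRR noise; the default keeps the single combined threshold.
* One sample-wide noise scale is used for all segments rather than
  per-segment rescaling by marker count; long segments are therefore
  fitted conservatively.
* Degenerate inputs: constant series produce no change points; samples
  without a balanced segment cluster are unanalyzable (error, not a
  guess); chromosomes with fewer than half a bin of het markers become a
  single bin with a warning; zero-depth variants are rejected and counted.

# Known limitations

Three-way local mixtures, fractional (non-integer) subclonal copy numbers,
phasing from read-backed haplotypes, and full subclone tree reconstruction
are out of scope. The two-way mixing assumption degrades in genomes with
dense, overlapping aberrations or after whole-genome doubling, where the
baseline heuristic above is only a guard rail. sAGP values from bins are
identically distributed but spatially correlated; values from sCNAs are
independent but not identically distributed — the clonal-structure fits
treat both as i.i.d. and should be read accordingly.
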