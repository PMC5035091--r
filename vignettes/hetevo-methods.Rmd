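---
title: "Models and methods behind hetevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hetevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetevo)
```

# The experimental system

`hetevo` analyses transcriptomes from an experimental-evolution design in
which replicate *Drosophila* populations evolved for many generations under
one of four selective regimes — constant cadmium-enriched diet (`Cad`),
constant salt-enriched diet (`Salt`), temporally alternating diets (`Temp`),
or a spatially mixed regime with soft selection (`Spatial`) — and were then
assayed by RNA-seq in both diets.  Three ancestors anchor the analyses: the
naive grand ancestor `GA`, and the two diet-adapted ancestors `AC` (cadmium)
and `AS` (salt), whose cross founded the twenty evolved populations.

The canonical layout (`canonical_design()`) has 46 samples: five
experimental blocks each holding one replicate population of every regime in
both diets (8 samples per block), plus the three ancestors in both diets as
block 6.  `validate_design()` enforces this balance and reports every
violation rather than failing at the first.

# Normalization and the surrogate expression model

Expression of gene $i$ in sample $s$ is the proportion
$E_{i,s} = c_{i,s} / \sum_g c_{g,s}$, proportional to the concentration of
the gene's cDNA in the sample, analysed on the $\log_2(E + \varepsilon)$
scale.  The pseudo-proportion $\varepsilon$ defaults to half the smallest
representable proportion, $1/(2\max_s\sum_g c_{g,s})$, which keeps
zero-count genes finite without letting them dominate ranks; the value used
is recorded in the run manifest.

Unequal sequencing depth is removed before analysis by down-sampling every
sample, without replacement, to its block's minimum column total
(`downsample_counts()`).  This is a multivariate hypergeometric draw over
the sample's gene counts — the count-space equivalent of sampling raw
mapped reads without replacement.

Differential expression uses a deliberately simple surrogate engine:
per-gene ordinary least squares on $\log_2(E+\varepsilon)$ with the fixed
effects of the study design,

* `~ diet + history + diet:history + block` for two-regime contrasts across
  both diets,
* `~ history + block` within one diet, and
* `~ diet + block` within one regime,

with sum-to-zero factor contrasts and partial $F$-tests per effect
(`fit_gene_models()`).  The design is perfectly balanced, so the partial
tests coincide with sequential ones.  This choice trades the
negative-binomial empirical-Bayes machinery of the standard engines for a
fully specified, dependency-free model whose inputs to the downstream
bespoke statistics — $\log_2$ fold changes and per-effect significance —
are the same quantities.  The substitution is recorded in the run manifest.
Genes with fewer than 10 reads summed over the contrast's samples are
reported untested, because least squares on logs of near-zero proportions
is unstable.  Benjamini–Hochberg q-values are computed per effect across
tested genes (`bh_adjust()`, a thin veneer over `stats::p.adjust` kept as a
named operation so the step-up definition is pinned by tests).

Under null simulations the per-effect type-I rate of this surrogate is
nominal to within Monte-Carlo error (the acceptance suite checks
$0.05 \pm 3\,\mathrm{SE}$ over 2000 genes), which is what the downstream
screens need from it.

# Countergradient analysis

Two screens are intersected: genes ancestrally plastic in `GA`
($|\log_2\mathrm{FC}|$ between diets $> 0.4$, strict), and genes with an
evolved history effect between `Cad` and `Salt` ($q < 0.1$, strict).  The
ancestral direction is captured by $Z = \pm 1$ (positive = up-regulated in
cadmium).  For each block $j$ and gene $i$ the polarized pair divergence is

$$\tfrac{1}{2} Z_i \left(\log_2 E_{cad,i,Cad_j} + \log_2 E_{salt,i,Cad_j}
 - \log_2 E_{cad,i,Salt_j} - \log_2 E_{salt,i,Salt_j}\right),$$

the evolved difference averaged over assay diets, oriented by ancestral
plasticity.  Negative values mean the evolved divergence opposes the
ancestral plastic response — countergradient variation.  Two tests
summarize the pattern: a one-df goodness-of-fit chi-square of the opposing
gene count against one half (no continuity correction), and a one-sample
t-test of the five per-block means against zero, using population pairs,
not genes, as the unit of replication.  A gene with an exactly zero
ancestral fold change (possible only on degenerate input) is excluded
rather than assigned an arbitrary polarity.

# Plasticity screens, scores, and the adaptive distance

The diet-adapted ancestors assayed in their own diets provide the
"Optimal" states ($O_{cad}$ = AC in cadmium, $O_{salt}$ = AS in salt); each
assayed in the other diet provides the "Non-adapted" states ($N$).

*Predicted increased plasticity*: optima differ
($|\log_2(O_{cad}/O_{salt})| > 0.4$) while both ancestors are only weakly
plastic (each ancestor's $|\log_2\mathrm{FC}|$ below half a reference
divergence $D$).  The source material describes $D$ in two non-equivalent
ways — the optimal-pair difference, and the AC-vs-AS difference within each
diet.  The default uses the optimal-pair difference (the same quantity as
criterion i); `reference = "within_diet"` implements the other reading,
requiring both ancestor plasticities to stay below
$\tfrac12\min_d|\log_2(AC_d/AS_d)|$.  Both readings recover the planted
gene class in simulation.  The polarity $Y = \mathrm{sign}\,
\log_2(O_{cad}/O_{salt})$ makes plasticity toward each diet's optimum
positive, and the per-population score is the mean of
$Y \cdot \log_2\mathrm{FC}$ over the set.

*Predicted decreased plasticity*: optima similar but both ancestors
consistently perturbed in the foreign diet
($|\log_2(O_d/N_d)| > 0.3$ in both diets, same sign;
$|\log_2(O_{cad}/O_{salt})|$ under half the smaller perturbation).  The
score is the mean absolute $\log_2\mathrm{FC}$, so no polarity is needed.

*Adaptive distance.*  For diet $d$, gene $i$, population $j$:
$$\Phi_{d,i,j} = \frac{E_{d,i,j} - O_{d,i}}{N_{d,i} - O_{d,i}},$$
0 at the adapted ancestor's expression, 1 at the non-adapted ancestor's.
$\Phi$ is invariant to any affine transformation applied jointly to $E$,
$O$ and $N$, so the choice of expression scale is immaterial.  Values
outside $[0,1]$ (overshooting the optimum, or worse than the non-adapted
state) are reported raw with a flag rather than clamped, since the metric
is only calibrated between its two anchors; genes with $N = O$ have
undefined $\Phi$ and are dropped with a warning.

Regime-level inference uses one-way ANOVA with the between-regime variance
fraction $SS_{regime}/SS_{total}$ and Tukey HSD adjusted pairwise
p-values.  The heterogeneity test compares nested linear models: an
explicit heterogeneous-vs-constant class column, a within-class history
column, and block, against the same model without the class column — a
likelihood-ratio chi-square whose df equals the number of dropped
parameters (one).  Block is a fixed effect here: with twenty population
scores and five blocks, a random-intercept fit is not reliably estimable
across the simulation settings the package must handle, and the fixed
treatment is recorded in the manifest.

# Allelic plasticity

Pooled RNA-seq allele counts at polymorphic sites let the package test
whether the *relative* expression of a gene's two alleles shifts between
diets ("allelic plasticity"), distinct from abundance plasticity.  The two
diet assays of a population are assumed to share allele frequencies, so a
between-diet shift in the expressed allele ratio reflects expression, not
genotype.

The stages, per regime: (1) per-site down-sampling to the block's minimum
site coverage (hypergeometric over the two alleles; a zero-coverage sample
zeroes the site for its whole block, flagged); (2) site screening on the
regime's ten samples — average diversity $2p_iq_i > 0.2$, total count
$n_i > 100$ (both strict), and $n_i$ at least half the gene's total count
in the allele table; (3) the most informative site per gene (highest
$n_i p_i q_i$, ties to the smallest position); (4) a
Cochran–Mantel–Haenszel test of diet × allele association stratified by
replicate population,
$$\chi^2_{CMH} = \frac{\left(\max\left(\left|\sum_k (a_k - E_k)\right| -
\tfrac12,\, 0\right)\right)^2}{\sum_k V_k},$$
with strata of total $\le 1$ skipped; genes at $p < 0.01$ are flagged
allelically plastic.  The continuity correction is clamped at zero;
`stats::mantelhaen.test`, which squares the corrected deviation without
clamping, serves as an independent cross-check in the tests wherever the
two conventions coincide.

*Enrichment.*  Over the genes present in both the allelic and the
abundance analyses, $f_1$ is the allelic-plastic fraction among genes with
significant abundance plasticity (diet effect $p < 0.05$), $f_2$ among
those without, and $\mathit{diff\_f} = f_1 - f_2$.  Its null distribution
comes from permutations that relabel reads across diets within each
population: the cadmium count of allele a is redrawn from the central
hypergeometric distribution conditioned on the site's per-diet and
per-allele totals — the exact distribution of a uniformly random
relabelling, without materializing read-level labels.  Chance significants
are fewer than observed ones, so randomly chosen genes are promoted until
the observed significant count is matched (demoted in the rare opposite
case, which is counted and reported); abundance flags stay fixed at their
observed values.  The p-value is
$\min\!\left(1,\, 2\,\frac{\#\{\mathit{diff\_f}_{perm} \ge
\mathit{diff\_f}_{obs}\} + 1}{n_{perm} + 1}\right)$ — the add-one guard
prevents zero p-values at finite $n_{perm}$, and ties count as extreme.
Doubling a one-sided tail makes the test conservative by construction
(null rejection at 0.05 runs near 0.025), which the calibration test
accounts for.

*Direction alignment.*  For genes that are both allelically plastic and
strongly differentiated genomically ($q < 0.001$ at the gene's most
differentiated SNP), each gene contributes $+1$ if the allele
over-expressed in cadmium is the allele at higher genomic frequency in
cadmium-selected populations, $-1$ otherwise; the mean sign is
bootstrapped over genes (percentile interval) and the verdict is whether
the interval excludes zero.

*SNP-region enrichment.*  Per region category (exon, intron, 1 kb flank), a
2×2 chi-square without continuity correction tests whether genes carrying
differentiated SNPs in that region are enriched for differential
expression, over the genes present in both the SNP and expression
analyses; genes with SNPs in several regions enter each relevant test.

# The synthetic-data generator

`simulate_experiment()` draws a full data set under the canonical design
with planted ground truth, so that every downstream stage can be tested
against known answers.  Counts are negative binomial with mean
$\mu_{g,s} = L_s \, 2^{\eta_{g,s}} / \sum_g 2^{\eta_{g,s}}$, where
$\eta_{g,s}$ adds a log-normal baseline, the gene class's regime × diet
offsets, and a per-gene block effect; dispersion 0 is a noise-free mode in
which counts equal their rounded expectations, used for exact identity
tests.  Three planted classes besides neutral genes encode the study's
focal patterns:

* *countergradient*: `GA` plastic with sign $Z$, evolved Cad-vs-Salt
  difference of sign $-Z$; the Salt lineage retains the ancestral plastic
  response while the Cad lineage has lost it (adaptation rendering the
  perturbation benign);
* *increased-plasticity targets*: optima separated by $\delta$ with sign
  $Y$, each ancestor sitting at its own optimum in both diets, the
  heterogeneous regimes plastic toward each optimum, each constant regime
  tracking only its own;
* *decreased-plasticity targets*: coincident optima, both ancestors (and
  both constant regimes) perturbed by the same signed shift in their
  foreign diet, heterogeneous regimes unperturbed.

Allele-count sites get binomial draws around population allele frequencies
shared between the two diet assays; a planted log-odds bias of the cadmium
assay is assigned with probability `r_plastic` to genes that are
diet-plastic in the Salt regime and `r_nonplastic` to the rest (defaults
0.2 and 0.1, the roughly two-fold enrichment the design emulates).  The
SNP table marks genes' SNPs as strongly differentiated more often when the
gene carries a history effect, and aligns SNP direction with the planted
expression bias for 90% of biased genes.  Three independent RNG streams
(counts, alleles, SNPs) derive from the single seed, so enabling or
resizing one table never perturbs another; a fixed seed makes all output
byte-identical.

## Chosen scales and effect sizes

Effect sizes are not reported by the study for its real data, so the
defaults are set for test power at desk scale: all planted effects are 1
on the $\log_2$ scale, block effects have SD 0.1, and 5% of genes belong
to each planted class.  Two choices deserve explanation:

* *Dispersion 0.002.*  Samples are pools of 80 larvae, and pooling
  averages away most biological variability; gene-wise dispersions in the
  0.001–0.01 range are typical for such data.
* *Library size $10^6$.*  Tests run at 2000 genes, so $10^6$ reads give a
  median per-gene coverage of a few hundred — the same "fold-change noise
  well below the screen thresholds" regime as the study's 20–30 million
  reads over a full transcriptome.  At substantially shallower depth,
  single-sample-pair $\log_2$ fold changes in the low-expression tail are
  shot-noise dominated (SD approaching the 0.4 screen threshold), and the
  ancestral-plasticity screen degenerates into a coin flip for weakly
  expressed genes — a property of the depth, not of the method.

What the generator does *not* emulate: mapping error, linkage between
sites, selection during the assay window, GC or length biases, and any
correlation structure among genes beyond the shared library-size
normalization.  Passing recovery tests therefore shows that the statistics
identify the patterns they were designed for under the design's sampling
noise — not that they are robust to every artefact of real sequencing
data.

# Numerical and degenerate-input policies

* All screen thresholds are strict inequalities.
* Down-sampling targets are conserved exactly; a sample already at its
  block minimum is returned unchanged, and zero counts stay zero.
* A gene with identical expression everywhere yields zero estimates and a
  reported $p = 1$ rather than an undefined statistic.
* The one-sample block test refuses a zero-SD input (undefined t); the
  regime ANOVA reports $p = 1$ and variance fraction 0 when all scores are
  equal.
* CMH informative-site ties break to the smallest genomic position;
  all-degenerate strata are an error.
* $\Phi$ outside $[0,1]$ is flagged, never clamped; $N = O$ drops the gene
  with a warning.
* Every stochastic stage takes an explicit seed, and the pipeline derives
  all of them from one configured seed; two runs with the same data and
  config produce byte-identical TSV/JSON outputs.

# Problem sizes used by the test suite

Recovery tests run at 2000 genes (the default configuration); unit tests
use 250–800 genes.  The permutation-null calibration uses 200 simulated
data sets at 250 genes and 200 permutations each; the enrichment-power
check uses 15 data sets at 800 genes and 300 permutations; down-sampling
moments use 10 000 seeds.  These sizes complete in minutes on one CPU
while leaving Monte-Carlo error well inside the asserted tolerances.

# Known limitations

* The surrogate OLS engine does not shrink dispersions; at very low
  counts it loses power relative to negative-binomial engines, and the
  10-read filter is a blunt instrument compared to independent filtering.
* The heterogeneity test treats block as fixed; with many more blocks a
  random-intercept model would be preferable.
* The permutation p-value is conservative (doubled one-sided tail with
  ties counted as extreme), so its nominal-level rejection rate sits near
  half the level.
* Allelic analyses assume the two diet assays of a population share allele
  frequencies; growth-rate differences between genotypes during the assay
  would violate this and are not detectable from these data alone.
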