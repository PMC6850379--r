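---
title: "Methods: models, estimators and design choices in fastz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in fastz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The question the package addresses

In female-heterogametic (ZW) systems the Z chromosome is hemizygous in
females, so recessive mutations on the Z are exposed to selection in one sex.
This predicts "fast-Z" evolution: elevated rates of adaptive substitution on
the Z relative to the autosomes, strongest for genes expressed mainly in
females. Testing the prediction requires, for strata of genes defined by
chromosome class and sex-biased expression: per-site diversity
($\pi_n$, $\pi_s$), per-site divergence to an outgroup species (dN, dS), the
proportion of adaptive nonsynonymous substitutions ($\alpha$), and the
per-mutation adaptive and nonadaptive substitution rates
($\omega_a = \alpha\,\mathrm{dN/dS}$,
$\omega_{na} = (1-\alpha)\,\mathrm{dN/dS}$), each with gene-bootstrap
confidence intervals. `fastz` implements this chain end to end, together
with a synthetic-data generator that draws from exactly the model family the
estimators assume, so every estimator can be validated by parameter recovery.

## Codon statistics

`count_alignment()` consumes codon alignments of $n$ ingroup haplotypes plus
one outgroup sequence. Site counting is Nei–Gojobori equal-weight counting on
the ingroup consensus codon: a position contributes $f$ synonymous sites,
where $f$ is the fraction of its three possible single-nucleotide changes
that preserve the amino acid (changes into stop codons count as
nonsynonymous). Codons containing `N`, a gap, or a stop in any sequence are
excluded as a unit — the complete-case analogue of upstream missing-genotype
masking — so $L_n + L_s = 3 \times \text{codons used}$ holds exactly.

A site with two or more segregating ingroup alleles is polymorphism; a
monomorphic site differing from the outgroup is a fixed difference; a site
that is both counts as polymorphism only (the conventional
McDonald–Kreitman bookkeeping, avoiding double counting). Variants are
classified synonymous/nonsynonymous by their amino-acid effect with the
other two codon positions held at the ingroup majority. Codons carrying
several fixed differences are resolved by averaging over minimal mutational
pathways, skipping pathways through stops, which can yield fractional
divergence counts; polymorphism and SFS entries stay integer. Tri-allelic
sites contribute one variant per non-ancestral allele, and the per-site
heterozygosity $(n^2 - \sum_a k_a^2)/(n(n-1))$ is allocated to classes in
proportion to each allele's $k(n-k)$ weight, which keeps per-gene $\pi$
identical to the brute-force average over all $\binom{n}{2}$ sequence pairs.

SFS entries are polarised by the outgroup where its allele segregates in the
ingroup (derived-allele count); otherwise the variant falls in the
minor-allele (folded) bin and the count of such sites is recorded. Divergence
is reported uncorrected by default; a Jukes–Cantor flag exists but the
analyses here run at dS around 0.15–0.2 where the correction is modest, and
whichever choice is made applies to both classes alike.

## Classic McDonald–Kreitman $\alpha$

$\alpha = 1 - \frac{dS \times P_n}{dN \times P_s}$, with the polymorphism
and divergence compartments in *consistent units*: when site totals are
available the polymorphism counts are normalised per site, which is
algebraically identical to the all-raw-count form
$1 - (D_s P_n)/(D_n P_s)$ because the site totals cancel. Mixing per-site
divergence with raw polymorphism counts would move the neutral null away
from $\alpha = 0$ whenever $L_n \neq L_s$; the consistent-units form keeps
the null at zero, which the package verifies on neutral simulations.
$\alpha$ is reported per pooled stratum (ratio-of-sums pooling); per-gene
values are available but are noisy and frequently undefined.

## The DFE ("modelling") approach

Classic $\alpha$ is biased downward by segregating slightly deleterious
mutations. The modelling estimator fits a gamma distribution of deleterious
fitness effects (DFE) to the synonymous and nonsynonymous site frequency
spectra under the Poisson random field (PRF) model and infers the expected
dN/dS under near-neutrality.

Writing $S = 4N_e s \le 0$ for the population-scaled selection coefficient,
the stationary density of mutant frequency $x$ is
$$f(x; S) \propto \frac{1}{x(1-x)} \cdot \frac{1 - e^{-S(1-x)}}{1 - e^{-S}},$$
and binomial sampling of $n$ haplotypes gives the expected density of sites
at derived count $i$ per unit mutational input,
$$H(S, i, n) = \int_0^1 f(x;S)\, \binom{n}{i} x^i (1-x)^{n-i}\, dx,$$
with neutral limit $1/i$. The expected count in bin $i$ is
$\theta L\, r_i \bar H_i$, where $\bar H_i$ averages $H$ over the gamma DFE
(for synonymous sites $\bar H_i = 1/i$), and $r_i$ ($r_1 \equiv 1$) are
nuisance factors shared between the two classes that absorb demography and
ascertainment. Every bin of both spectra is an independent Poisson
observation. The expected near-neutral divergence ratio is the mean relative
fixation probability $E[S/(1 - e^{-S})]$ over the DFE, and
$$\alpha = 1 - \frac{E[\mathrm{dN/dS}]_{\text{neutral}}}{\mathrm{dN/dS}_{\text{obs}}},
\qquad \omega_a = \alpha\,\mathrm{dN/dS}, \qquad
\omega_{na} = (1 - \alpha)\,\mathrm{dN/dS},$$
so $\omega_a + \omega_{na} = \mathrm{dN/dS}$ holds by construction for every
fit.

**Numerics.** The frequency integral uses 96-node Gauss–Legendre quadrature
on $(0,1)$; the integrand is a degree-$\le n$ polynomial times a smooth
selection kernel, so the rule is near-exact, and the kernel is evaluated in
the form $e^{-Tx}(1 - e^{-T(1-x)})/(1 - e^{-T})$, $T = -S$, which is stable
for arbitrarily large $|S|$. The gamma mixing integral is Gauss–Legendre in
$\log T$ between extreme gamma quantiles (160 nodes, weights renormalised),
which remains accurate for shape $< 1$ with very large mean $|S|$; both
integrals are validated in the test suite against adaptive quadrature and
dense Riemann sums.

**Optimisation.** Given (shape, mean $S$), the Poisson MLEs of $\theta$ and
of every $r_i$, $i \ge 2$, are closed-form and are profiled out, leaving a
2-D search over $(\log \text{shape}, \log |{\bar S}|)$ run by L-BFGS-B from
six dispersed starts (a warm start can be supplied, which the bootstrap
uses). The DFE is identified by the per-bin nonsynonymous:synonymous count
ratios, from which the shared $r_i$ cancel. Spectra are fitted folded by
default — robust to polarisation error, at no cost on exact-model data
(folded and unfolded fits agree in the tests); unfolded fitting is available
when the outgroup polarises cleanly. When the nonsynonymous spectrum is
empty but $D_n > 0$ the fit runs to the strong-selection boundary and
$\alpha \to 1$, flagged via `at_boundary`.

## Expression classification

RPKM is $N_c \times 10^9 / (N_{tot} \times L_c)$; per-gene expression is the
unweighted mean across samples within each sex. A gene is female biased when
$\mathrm{RPKM}_f/\mathrm{RPKM}_m > 1.5$, male biased when $< 0.66$, and
unbiased otherwise — both inequalities strict, so ratios exactly at a
threshold are unbiased. A gene expressed only in females has infinite ratio
and is classified female (flagged); a gene with zero expression in both
sexes is unbiased and flagged unexpressed. Ovary/gut tissue bias is a pure
thresholding of an externally fitted differential-expression table
(adjusted $p < 0.05$ and $|\log_2 FC| > 1.5$); dispersion estimation and
Wald testing are deliberately not reimplemented — the upstream DE tool owns
them, including any batch term in its design. The 2×2 ovary/gut ×
Z/autosome enrichment test is a Pearson chi-square without continuity
correction, with a warning when any expected count drops below 5.

## Bootstrap

All intervals are gene bootstraps: genes are resampled with replacement to
the original number, the pooled statistic is recomputed (1000 replicates by
default), and 95% percentile bounds are reported. Percentile rather than
BCa intervals are the minimal-assumption choice. Replicates where a
statistic is undefined (e.g. a resample with $D_n = 0$) are dropped and
counted. DFE refits inside replicates start from the point estimate's
(shape, mean $S$) to keep 1000 refits tractable; omitting the warm start
forces cold multi-start refits for validation. Significance between strata
is judged by interval overlap, matching how such tables are annotated.

## The synthetic-data generator

`simulate_counts()` draws per-gene counts directly from the PRF
expectations — synonymous bin $i$ is Poisson with mean $\theta_s L_s / i$,
nonsynonymous bins use $\bar H_i$ under the gamma DFE, $D_s$ is Poisson
$(L_s \cdot d_s)$ and $D_n$ Poisson
$(L_n d_s (\omega_{na} + \omega_a))$ with
$\omega_a = \frac{p_a}{1-p_a}\omega_{na}$ — rather than running forward
Wright–Fisher simulation. Recovery tests are therefore exact-model tests and
run in seconds; what passing them shows is that the estimators are correct
under their own assumptions, not that real data meet those assumptions.
Features of real data deliberately absent: linked selection and sweep
signatures in polymorphism (adaptive substitutions contribute to divergence
only — the standard MK assumption), recombination-rate variation,
demographic change (demography enters the fitter only through the $r_i$
nuisance terms), and read-level noise. Z-linked genes have polymorphism
scaled by `ne_ratio_Z` applied to $\theta$ only; divergence is left equal
across classes because the neutral substitution rate is independent of
$N_e$, with an optional Z divergence multiplier (`div_mult_z`) to emulate
male-biased mutation. Spectra are simulated unfolded; folding is a
deterministic downstream transform.

Defaults describe a large-$N_e$ butterfly-like population: $\theta_s =
0.027$/site and $d_s = 0.162$/site (typical autosomal synonymous diversity
and divergence for such taxa), a leptokurtic gamma DFE (shape 0.4, mean
$S = -2000$), adaptive fraction 0.6, `ne_ratio_Z` at its neutral 1:1
sex-ratio expectation of 0.75, an even Z/autosome gene split so both strata
are estimated with equal precision, gene lengths lognormal around 450
codons, and $n = 20$ ingroup haplotypes (ten diploids). 15% of genes are
latently female biased and 15% male biased. Expression counts are negative
binomial with lognormal baseline expression, ±40% library-size variation
and dispersion 0.05; biased genes have the female-sample mean scaled by
`bias_fold` (male-biased genes mirrored).

`emit_alignments()` realises simulated counts as FASTA codon alignments:
each gene gets a random stop-free coding sequence, and every variant is
placed on a uniformly chosen eligible codon as a single-nucleotide change of
the required class, at most one variant per codon (sequences are regrown if
too short, a bounded number of times). Counting emitted alignments with
`count_alignment()` reproduces the simulator's bookkeeping exactly, which is
the package's strongest correctness oracle for the codon machinery.

## Diversity ratio and regression

The Z:autosome ratio of pooled per-site synonymous diversity has neutral
equilibrium expectation 0.75 under a 1:1 sex ratio; background selection on
the Z, sex-biased demography or bottlenecks push it lower. The expression
regression is OLS of $\log \pi_n$ on $\log \pi_s$, a chromosome-class
indicator and $\log$ mean RPKM (natural logs, the model string read in its
only internally consistent form); genes with zero $\pi_n$, $\pi_s$ or RPKM
are excluded and counted, and single-class designs are rejected as rank
deficient. The overall mean RPKM is the default covariate, with sex-specific
means available via `rpkm_col`.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit integer seed, and identical
seeds reproduce outputs exactly (the pipeline reruns byte-identically).
The validation suite uses simulation sizes chosen to bound Monte-Carlo
error well below the tolerances being checked while keeping a laptop-scale
run: 2000 genes for the diversity-ratio and DFE-recovery checks, 600 for
the neutral MK null, 200 datasets × 200 genes × 1000 replicates for
bootstrap coverage, 2000 genes for classifier recovery.

```{r, eval = FALSE}
library(fastz)
truth <- sim_truth(n_genes = 1000, seed = 1)
sim <- simulate_counts(truth)
fit <- fit_dfe(sim)
coef(fit)
```

## Known limitations

* The DFE family is a gamma on deleterious effects only; no beneficial mass
  in polymorphism, no lognormal or displaced-gamma alternatives, and no
  asymptotic-MK estimator.
* Pathway averaging for multi-hit codons and the tri-allelic allocation rule
  are conventions; other reasonable conventions would differ at third-decimal
  level on realistic data.
* $\theta$ and the DFE are fitted per pooled stratum, not per gene; strata
  mixing very different mutation rates dilute the fit.
* Percentile bootstrap intervals undercover slightly for strongly skewed
  statistics at small gene counts (the coverage test runs at 200 genes where
  coverage is within a few points of nominal).
* The generator's PRF independence assumptions (free recombination between
  sites, equilibrium demography) are exactly the fitter's assumptions —
  convenient for validation, silent about robustness to their violation.
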