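---
title: "Quasi-likelihood score tests for multivariate family-based association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-likelihood score tests for multivariate family-based association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The testing problem

Family samples are a mainstay of genetic association studies, but they
break the independence assumptions behind ordinary regression tests:
relatives share polygenic background, so both genotypes and phenotypes
are correlated within families. `mfqls` implements a *retrospective*
quasi-likelihood score test of the joint null hypothesis that none of
$M$ variants affects any of $Q$ phenotypes,

$$H_0:\; \beta_{11} = \beta_{12} = \cdots = \beta_{MQ} = 0,$$

treating the genotypes as the random quantity given the phenotypes.
Retrospective conditioning makes the test robust to phenotype
non-normality and lets dichotomous and quantitative traits be mixed
freely; the price is that genotype moments must be modelled through the
relatedness structure.

## Ingredients

Let $\Phi$ be the $N \times N$ relationship matrix (twice the kinship
coefficients off the diagonal, $1 + $ inbreeding on it, block-diagonal
across families), or the empirical genomic relationship matrix (GRM)
when population substructure makes pedigree kinship insufficient.  Let
$X$ be the $N \times M$ matrix of minor-allele counts and $T = Y - \mu$
the matrix of offset-adjusted phenotypes.

Three quantities assemble the test:

* the **$\Phi$-weighted centering projector**
  $A = \Phi^{-1} - \Phi^{-1}\mathbf{1}
  (\mathbf{1}^t\Phi^{-1}\mathbf{1})^{-1}\mathbf{1}^t\Phi^{-1}$, which
  annihilates constants ($A\mathbf{1}=0$) and embeds the best linear
  unbiased (generalized-least-squares) allele-frequency estimator
  $\hat g_m = (\mathbf{1}^t\Phi^{-1}\mathbf{1})^{-1}
  \mathbf{1}^t\Phi^{-1}X^m$;
* the **score** $S = \mathrm{vec}(T^t \Phi A X)$, a length-$MQ$ vector
  (marker-major ordering: entry $(m-1)Q + q$ pairs marker $m$ with
  phenotype $q$);
* its **variance** $\mathrm{var}(S) = \Psi \otimes (T^t \Phi A \Phi T)$,
  where $\Psi$ is the $M \times M$ sample covariance of the
  per-individual genotype vectors, under the working assumption
  $\mathrm{var}(\mathrm{vec}(X)) = \Psi \otimes \Phi$.

Then $S^t\,\mathrm{var}(S)^{-1} S \sim \chi^2(MQ)$ under the null.
Because $A$ kills constants, the statistic is invariant to the centering
constant used for the genotypes — the minor/major coding ambiguity has
no operational consequence, and monomorphic markers are annihilated
(they are removed from the tested set with a warning; a set losing all
markers returns a no-test sentinel rather than an error).

## Phenotype offsets and the three variants

The offset $\mu$ determines efficiency.  For randomly sampled families
the best choice is the **BLUP offset**: fit, per phenotype, the null
linear mixed model $y = Z\alpha + B + E$ with
$\mathrm{var}(B) = \sigma^2_B \Phi$ and
$\mathrm{var}(E) = \sigma^2_E I$, and subtract both the fixed-effect fit
and the predicted polygenic effect.  Writing
$H = \hat\sigma^2_B\Phi + \hat\sigma^2_E I$ and $r$ for the GLS
residual, the adjusted phenotype has the compact closed form

$$T^q = \hat\sigma^2_{E,q}\, (H^q)^{-1} r^q,$$

equal to the usual projector expression
$(I - Z(Z^tH^{-1}Z)^{-1}Z^tH^{-1} - \hat\sigma^2_B\Phi P)Y$.  A useful
consequence — and the invariant the tests verify — is plain
orthogonality $Z^t T^q = 0$.  (The superficially attractive identity
$Z^t H^{-1} T^q = 0$ is false; it is the GLS residual $r$, not $T$,
that is $H$-orthogonal to $Z$.)  Dichotomous phenotypes are run through
the same linear-model machinery; the quasi-likelihood argument needs
only first and second moments, and generalized linear mixed models
would reintroduce the integration problems the approach avoids.

The three published configurations differ in the working covariance
$V$ and the offset:

| method | $V$ | $\mu$ | intended use |
|---|---|---|---|
| `MFQLS` | $I$ | BLUP | default, quantitative or dichotomous |
| `MMQLS` | $I$ | prevalence $K_q$ | dichotomous, ascertained families |
| `MMASTOR` | $\mathrm{diag}(H^1,\dots,H^Q)$ | BLUP | mixed-model score benchmark |

`MMASTOR` needs a multivariate covariance formula that the original
derivation only states for $V = I$; applying the same covariance
algebra gives blocks
$\Psi_{mm'}\,(T^q)^t (H^q)^{-1}\Phi A \Phi (H^{q'})^{-1} T^{q'}$,
which is what the package computes (the result is tagged
`"extension"`).  Internally all three share one code path: `MMASTOR`
is the $V= I$ core applied to the reweighted matrix with columns
$(H^q)^{-1}T^q$.

## Missing data

*Missing phenotypes*: the corresponding entries of $T$ are set to
exactly zero; those individuals still sharpen $\Psi$ and the allele
frequencies.

*Missing genotypes*: individuals $U$ without genotypes contribute
through the conditional expectation
$E(X^U \mid X^O) = \hat g_m\mathbf{1} +
\Phi^{UO}(\Phi^{OO})^{-1}(X^O - \hat g_m\mathbf{1})$ (values clipped to
$[0,2]$, never rounded — the score is linear in $X$).  The resulting
score is $S^* = \mathrm{vec}\!\left(T^t\,\Phi_{\cdot O}\,A^O X^O\right)$
with $A^O$ the centering projector built on $\Phi^{OO}$.  The original
display defines its projector on the full partitioned matrix with
$\mathbf{1}_N$, which does not conform dimensionally with the
surrounding products; the $\Phi^{OO}$ reading is the unique one under
which (a) everything conforms, (b) $S^*$ coincides with "complete $X$
by its conditional expectation, then apply the ordinary score", and
(c) $S^*$ reduces *exactly* to $S$ when no genotypes are missing.  The
weight matrix $W$ in that display is likewise taken as the identity,
the only choice consistent with the reduction property.  Both facts
are verified numerically in the test suite.

## Null-model fitting

Each phenotype's variance components are estimated by restricted
maximum likelihood, profiled to one dimension: on the eigenbasis of
$\Phi$ the covariance is diagonal in
$h = \sigma^2_B/(\sigma^2_B+\sigma^2_E)$, and the restricted
log-likelihood is maximized over $h \in [0, 1-10^{-6}]$ by Brent search
(tolerance $10^{-8}$), with an explicit check of the $h = 0$ boundary
(Brent never evaluates endpoints).  This has the same stationary points
as the average-information iteration usually recommended, but is exact
and cannot diverge.  Cross-phenotype polygenic covariances are never
needed for the offset — $H^q$ involves only phenotype $q$'s components
— so $Q$ univariate fits suffice.  The eigendecomposition of $\Phi$ is
computed once and shared across phenotypes, and in replicate studies
across replicates; for the canonical simulation pedigree only the
$10\times10$ family block is decomposed.

Degenerate cases: a constant phenotype is an error (variance
unidentifiable); $\Phi = I$ makes the likelihood flat in $h$ and the
boundary $h = 0$ with the OLS residual variance is returned.

## Numerical choices

* **Singular $\Phi$**: duplicate rows (e.g. both members of an MZ twin
  pair) make $\Phi$ singular; matrices with smallest eigenvalue below
  $10^{-8}$ are rejected unless a ridge (default $10^{-6}$) is
  requested.  GRMs built with allele frequencies estimated from the
  sample are *always* singular in the $\mathbf{1}$ direction (each
  standardized column sums to zero), so the structured-calibration path
  applies the ridge routinely; the statistic is continuous in this
  limit because the near-null direction only sharpens the centering.
* **Rank-deficient $\mathrm{var}(S)$** (collinear markers): eigenvalues
  below $10^{-8}\times$ the largest are discarded, the statistic uses
  the pseudo-inverse, and the degrees of freedom drop to the retained
  rank — a full-$MQ$ reference would be anti-conservative.
* **vec ordering** is marker-major throughout, matching
  $\Psi \otimes (\cdot)$ with markers on the left Kronecker factor, and
  is covered by an oracle test against the literal summed Kronecker
  forms.
* **Monomorphic markers** are detected as constant columns among the
  analyzed individuals (equivalent to $\hat p \in \{0,1\}$ for genuine
  count data, but also invariant to the constant shifts the statistic
  itself ignores).

## The simulator

The generator reproduces the stated calibration world: extended
families of 10 over three generations — two grandparents, two of their
children married to unrelated spouses, four grandchildren (the figure
describing the original topology is not machine-readable; this
documented stand-in has the right size and depth, and type-I error
calibration is insensitive to topology).  Defaults are the published
conditions: 100 families, two test loci with minor-allele frequencies
from $U(0.1, 0.4)$ (the substructure tables use $U(0.1, 0.5)$, matching
their notes), LD parameterized by Lewontin's $D'$ via
$d = D'\min(p_A(1-p_B), (1-p_A)p_B)$, founder haplotypes multinomial at
haplotype-level Hardy–Weinberg, children inheriting one haplotype per
parent without recombination.  Polygenic effects follow the additive
model (founders $MVN(0,\Sigma_B)$, children = mid-parent $+\,
MVN(0, 0.5\Sigma_B)$); phenotypes add independent Gaussian errors with
the published $\Sigma_B$, $\sigma^2_{E,q}$ and cross-phenotype
correlation $\rho = 0.2$.

Dichotomous traits threshold the liability at the upper-$K_q$ quantile
of the *theoretical* null marginal law, so case counts are binomial
rather than fixed per replicate; prevalences are $(0.1, 0.2)$ for
$Q = 2$ and $(0.1, 0.1, 0.2, 0.2, 0.3)$ for $Q = 5$.

Substructure uses two Balding–Nichols subpopulations
($\mathrm{Beta}(p(1-F_{ST})/F_{ST}, (1-p)(1-F_{ST})/F_{ST})$), founders
labelled independently with probability $1/2$, and a phenotype mean
difference of $0.2$ between populations.  Because founder labels can
mix within a family and the original description is silent about
non-founders, each individual carries a continuous ancestry proportion
(mean of its parents'), and the $0.2$ shift scales with it; a
family-level assignment is available by flag.  The null panel behind
the GRM draws ancestral frequencies from the same uniform law and keeps
only markers whose subpopulation minor-allele frequencies both exceed
$0.1$ (common variants, as in the original panel).

**What the simulator does not emulate** — recombination within the
tested locus pair, more than two causal loci, genotyping error,
ascertained (proband-sampled) families, non-Gaussian residuals,
locus-specific substructure.  A green calibration therefore establishes
correct null behavior under the stated generative world, not robustness
to those phenomena; in particular the GRM fix assumes substructure is
uniform across the genome.

## Replicate studies and their scaling

`calibrate_type1()` re-runs the homogeneous-population null study at
full scale (minutes per configuration, thanks to the cached block
eigendecomposition).  `calibrate_structured()` regenerates the world of
the substructure study, with one deliberate scale-down: a fresh
100{,}000-marker panel and $N\times N$ GRM per replicate is far outside
any desktop budget (the GRM product alone is $\sim 10^{10}$ flops), so
the ancestry labels, panel and GRM are drawn once per configuration and
replicates redraw phenotypes, polygenic effects and test markers
conditional on them.  The calibration being demonstrated — the GRM
absorbing the substructure-induced phenotype–genotype confounding — is
conditional on the realized GRM either way.  A
`use_grm = FALSE` negative control keeps the pedigree kinship matrix
despite substructure and shows the inflation the GRM removes.

Power comparisons need effect sizes the reference tables do not print.
They were fixed a priori from a noncentrality argument (per-cell
noncentrality $\approx N_{\mathrm{eff}}\beta^2\,2p(1-p)/\sigma^2_Y$
targeting mid-range power at $\alpha = 0.005$, $N = 1000$):
$\beta = 0.12$ on quantitative phenotypes and $\beta = 0.25$ on the
liability scale (thresholding attenuates the observable effect).  Power
runs are compared only as orderings — method dominance and growth in
$Q$ — never against printed power numbers.

When empirical type-I error cells are compared against the published
cells, both sides are 10{,}000-replicate Monte-Carlo estimates, so the
comparison uses the two-sample binomial tolerance
$3\sqrt{\alpha(1-\alpha)(1/R_{\mathrm{emp}} + 1/10{,}000)}$.

## Known limitations

* Offsets for proband-ascertained families (beyond the prevalence
  offset) are out of scope, as is LD-reference imputation of missing
  genotypes — the conditional-expectation scheme uses kinship only.
* The GRM route inherits the usual caveat: it is only as good as the
  panel, and substructure that varies along the genome defeats it.
* The exact-rank pseudo-inverse makes perfectly collinear marker sets
  testable but cannot rescue sets whose information is genuinely zero
  (all-monomorphic sets return a no-test sentinel).
* X-chromosome kinship and IBD-segment relatedness are not implemented.
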