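---
title: "Mapping ongoing selection with birth date as the dependent variable"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping ongoing selection with birth date as the dependent variable}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdsmap)
```

## The inverted regression

A locus under sustained directional selection changes frequency in a
consistent direction, generation after generation. In a population sampled
across decades, genotype at such a locus therefore carries information about
*when* an individual was born: carriers of the rising allele are
concentrated among recent birth cohorts. `bdsmap` exploits this by fitting
birth date (a decimal-year continuous variable) as the **dependent**
variable of a genome-wide mixed model.

Why not the obvious direction — allele count regressed on birth date? That
scan (implemented here as `poisson_birthdate_scan()`, deliberately, as the
contrast) is confounded by any non-random sampling of families over time.
Families differ in allele frequency by ordinary drift; if some families are
genotyped mostly in recent years (a new popular sire line; a herd whose
archive was sampled late), family differences masquerade as temporal trends
at every locus, and the false-positive rate explodes. Putting birth date on
the left side lets the fitted covariance structure do the correction: the
animal term with a genomic relationship matrix (GBLUP) or the kinship in the
two-stage association scan (EMMAX) absorbs the family component of birth
date, leaving per-SNP effects calibrated. Moving the time trend into a
random animal effect on the *allele-count* side cannot achieve this, because
that term would swallow exactly the frequency trend being sought.

The test suite's `confounded_sampling` fixture encodes the failure mode
explicitly: a neutral two-herd population in which a small closed herd is
sampled only late and the main herd only early. On those data the Poisson
scan's genomic inflation factor (median χ²/0.4549) runs several-fold above
1 while the EMMAX scan stays within a few percent of 1 — the package's core
claim, recomputed by `scripts/acceptance.R` on every run.

## Models

### GBLUP of birth date and ASE backsolving

With dosage matrix $M$ ($n$ animals × $m$ SNPs), base-generation
frequencies $p$, and $Z = M - 2p$:

$$y = X\beta + g + e,\qquad g \sim N(0,\, G\sigma^2_g),\qquad
  G = \frac{ZZ'}{2\sum_i p_i(1-p_i)}.$$

Variance components come from exact single-kernel REML
(`reml_single_kernel()`): the kernel is eigendecomposed once, the restricted
likelihood is profiled to a one-dimensional function of
$h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$, and Brent search (tolerance
1e-8) finds the maximizer with an explicit check of both boundaries. The
fit is deterministic; `reml_profile()` exposes the same objective on a grid
for diagnostics, and the suite asserts the optimizer is never beaten on a
100-point grid.

Allele substitution effects are recovered from the animal solutions as
$\alpha = Z'G^{-1}\hat g / (2\sum_i p_i(1-p_i))$, which is algebraically the
ridge SNP-BLUP solution at $\lambda = 2\sum p_i(1-p_i)\,\sigma^2_e /
\sigma^2_g$ (asserted to 1e-6 against a dense joint solve). Each SNP is
summarized by its additive variance $2p_i(1-p_i)\alpha_i^2$; GBLUP attaches
no p-values, so ranking and top-$k$ selection run on this variance, with
ties broken by map order (chromosome, then position) for reproducibility.

Weighted records (deregressed EBVs) enter through a residual covariance
$\sigma^2_e\,\mathrm{diag}(1/w)$ in Henderson's equations; equal weights
reduce exactly to the unweighted model.

### EMMAX two-stage scan

Variance components are estimated once under the null (no SNP) on a
Balding–Nichols kinship — per-SNP centering by $2p$ and scaling by
$2p(1-p)$, averaged over SNPs — then held fixed. Each SNP is tested as a
fixed effect by OLS in the whitened basis
$\mathrm{diag}(1/\sqrt{rd_i + 1 - r})\,U'$ from $K = UDU'$, with the
residual variance re-estimated per SNP and a t-test on $n - p - 1$ degrees
of freedom. With $K = I$ this is *exactly* per-SNP OLS (asserted to 1e-10),
and p-values are invariant to affine rescaling of $y$. Benjamini–Hochberg
q-values come from a validated wrapper over `stats::p.adjust`.

### BayesCπ

`bayescpi_fit()` implements the spike-and-slab mixture in compiled code:
each locus has an inclusion indicator (prior probability $1-\pi$) and,
when included, an effect from a common-variance slab; $\pi$ carries a
uniform prior and is drawn from its Beta conditional given the count of
included loci. Hyper-priors are scaled inverse chi-square with 4 degrees of
freedom; scales derive from the starting variance components so the prior
means equal the starting values, with the slab start
$\sigma^2_\beta = \sigma^2_g / ((1-\pi_0)\sum 2p_iq_i)$. Defaults follow
the published run protocol: 160,000 sweeps, 1,000 burn-in, $\pi_0 = 0.9$.
The locus update order is fixed (map order) so runs are bit-reproducible
under a seed; a `shuffle` flag exists. The sampler's inclusion
probabilities were validated against exact enumeration of all $2^m$ models
on a small fixture (agreement at Monte-Carlo precision), and the running
residual is asserted to match a from-scratch recomputation to 1e-8.

**Weak identifiability of π at desk scale.** On data with *no* signal, the
posterior of $\pi$ under a uniform prior is well-behaved only while the
slab prior stays anchored by the sample. When markers outnumber records,
the chain can drift into a regime of many near-zero included effects: the
slab variance ratchets down, the Occam cost of inclusion vanishes, and
$\pi$ random-walks far below its starting value — with the conspicuous
signature that *no individual locus* ever attains a high inclusion
probability. This is a property of the model, not of the sampler (the
enumeration check rules that out). Consequently the package's pure-noise
calibration checks run at $n \ge m$, where the posterior mean of $\pi$
concentrates above 0.9 reproducibly; with real sparse signal the slab is
anchored by the causal effects and the behaviour is unproblematic at any of
the sizes exercised here. Reported alongside $\pi$ is
$k = \mathrm{round}((1-\pi)m)$, the implied count of selected loci; because
of this rounding convention a reported percentage of selected SNPs need not
reproduce $k$ exactly.

### Drift test and effective population size

For two cohorts $t$ generations apart with earlier-cohort frequency $p_1$:

$$z = \frac{p_2 - p_1}{\sqrt{t \cdot p_1(1-p_1)/(2N_e)}}$$

(autosomes; the X chromosome uses $1.5N_e$ in place of $2N_e$, i.e. a
*larger* drift variance and less ready flagging). A SNP is attributed to
selection when the two-sided $-\log_{10}(p)$ exceeds 8. Choices worth
making explicit:

* the *earlier* cohort supplies the variance (loci fixed there are skipped
  with a warning rather than flagged);
* the test is two-sided;
* finite-cohort binomial sampling noise is **not** added to the drift
  variance — a fidelity choice that matches the published construction;
  with cohorts much smaller than the census this makes the test
  anticonservative, which is why the calibration fixture genotypes whole
  cohorts;
* the `generations` multiplier (default 1, the adjacent-cohort case) is
  this package's own generalization, needed to span multi-generation gaps
  in simulations; it uses the linear small-drift approximation
  $\mathrm{Var}(\Delta p) \approx t\,pq/2N_e$, slightly conservative for
  large $t$ because terminal heterozygosity decays.

$N_e$ itself comes from `ne_from_inbreeding_regression()`: OLS of
individual inbreeding on generation number, $N_e = 1/(2\Delta F)$,
$SE(N_e) \approx 2N_e\,SE(\Delta F)$. Generation number defaults to
$(\text{birth year} - 1950)/5$ — the 5-year generation interval of the
cattle population this emulates — and both pedigree inbreeding
(Meuwissen–Luo recursion; founders $F=0$) and genomic inbreeding (GRM
diagonal − 1, signed relative to the base frequencies) are accepted. Note
the direction of the $N_e$ sensitivity: at fixed data, assuming a larger
$N_e$ shrinks the neutral envelope and flags *more* loci, so an honest
$N_e$ matters.

### Selection intensities

From the expected response $\Delta q = -i\,p\,q\,a/\sigma$, with dominance
assumed zero so the trait ASE proxies $a$, the regressor for each trait is
$x_j = p_jq_j\,\mathrm{ASE}_j/\sigma_{\mathrm{ASE}}$, standardized by that
trait's ASE standard deviation over the SNP set entering the regression
(computed on the pruned top-SNP set). Birth-date ASEs are regressed on each
trait's regressor by GLS with error covariance proportional to the signed
LD matrix $V$; runs of map-consecutive SNPs at $r = \pm 1$ are pruned to
their first member beforehand (perfect correlation is transitive, so
adjacent-pair checks find the runs). $V = I$ reduces the fit exactly to
OLS. Estimates are invariant to positive rescaling of a trait's ASEs; SEs
use the REML-style residual estimate, the slope being invariant to how the
scalar error variance is handled. A joint multi-trait fit is computed, but
only its adjusted $R^2$ is reported as trustworthy — trait ASEs are heavily
collinear, and the condition number of the whitened design is attached to
the result as a warning signal. Single-trait significance is reported
against a Bonferroni threshold of $0.05/T$.

## Data handling

QC applies, in this order: SNP call rate ≥ 0.90 → animal call rate ≥ 0.95
→ MAF ≥ 0.01 → HWE $\chi^2 \le 300$ (1 df, autosomal and pseudoautosomal
loci only; the extreme cutoff targets assay artefacts such as variants
inside CNVs, not selected loci). The order is a package decision — the
thresholds themselves do not determine one — fixed so that reports are
reproducible; MAF and HWE use non-missing calls after the call-rate steps.
QC is idempotent: a second pass removes nothing.

Missing genotypes are imputed by mean dosage (default, deterministic;
fractional dosages result) or by sampling from Hardy–Weinberg at the
observed frequency (seeded). At the sub-percent missingness typical of
filtered array data, downstream matrices are insensitive to the choice; no
haplotype-phasing imputation is attempted.

Base-generation allele frequencies come from a declared early cohort
(explicit id list or the `earliest_cohort()` rule) and are clamped to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 1/(4n_\text{base})$, so loci
monomorphic in the base cannot produce degenerate scalings. A ridge of
1e-8 stabilizes $G$ before inversion (small fixtures routinely have
$n > \mathrm{rank}$). X-linked loci enter the GRM like autosomes by
default, with an `exclude_x` flag.

EBV deregression defaults to `mode = "simple"` ($\mathrm{dEBV} =
\mathrm{EBV}/r^2$, weight $w = (1-h^2)/((c + (1-r^2)/r^2)h^2)$, where $c$
is the fraction of genetic variance not captured by markers); the
parent-average-removing variant is provided for fidelity to the cited
deregression procedure but the exact variant used upstream of a given EBV
set is rarely recoverable, so the simple form is the default. Weights
diverge as $r^2 \to 1$ with $c = 0$ and are capped (default 1e6) with a
warning.

## The simulator, and what passing tests do not show

`simulate_selected_population()` advances a population in yearly steps:
truncation selection within herd on an index of EBV proxies (era-dependent
weights, allowing mid-span sign reversals of the kind selection-goal changes
produce), geometric sire-usage skew emulating artificial insemination,
Mendelian segregation with Haldane recombination on a uniform
1 Morgan/chromosome map, and closed sub-herds. Setting the breeding-year
step and parent ages to the generation interval collapses it to discrete
generations. EBV proxies are true breeding values plus noise calibrated to
a target accuracy — the package tests *mapping* methods, not genetic
evaluation systems, so no inner evaluation is simulated. Sampling schedules
(`sample_genotyped()`) make the genotyped subset explicit, because biased
temporal family sampling is precisely the confounder the method exists to
defeat.

Scale choices are desk-scale by design: fixtures use 1,000 SNPs on 5
chromosomes, populations of a few thousand animals, and effective sizes of
tens to hundreds; the `selected_sweep` fixture sizes its single QTL by the
breeder's equation so the sweep spans all 10 generations without fixing.
What the simulator does **not** emulate: sequence-level mutation, dominance
and epistasis (the ASE framework itself assumes additivity), genotyping
error, pedigree errors, and real LD structure beyond what uniform
recombination on short chromosomes produces. Passing tests therefore show
the machinery is correct and calibrated under the stated population models
— not that any particular real dataset satisfies those models.

One desk-scale effect deserves emphasis: at small simulated $N_e$, kinship
and birth date are *genuinely* correlated even under neutrality (relatives
are born near each other in time, and drift is fast), so the REML
"heritability of birth date" on raw neutral simulations is substantially
positive. The package's null calibration of REML therefore uses a response
drawn independently of the genotypes — the limit the inverted regression's
null statement refers to, where drift is negligible and genotype frequency
is independent of time. The same logic at real scale (effective sizes in
the hundreds) makes the neutral expectation near zero.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive (PLINK MAP convention); BED input is
  converted on import. Pseudoautosomal loci are treated as autosomal.
* PED reading counts the lexicographically smaller allele, making
  write→read round trips the identity; missing is `0 0`.
* Gene–SNP distance is point-to-nearest-edge, 0 inside the gene; a window
  of 100 kb is the default reporting radius, and annotation/map chromosome
  name mismatches are an error rather than a silent empty join.
* Top-$k$ selection accepts either an explicit $k$ or a fraction (rounded),
  since a reported fraction and a reported count need not agree after
  rounding.
* Collinear SNPs in EMMAX get effect 0 and p = 1 with a warning; zero
  total genotype counts, all-missing loci, empty QC output, cyclic
  pedigrees, non-PSD kernels, and non-positive $\Delta F$ all raise
  immediate, specific errors.
* All stochastic entry points take explicit seeds and restore the caller's
  RNG state.

## Known limitations

* Single-kernel REML only; no multi-kernel or dominance models.
* The EMMAX scan defaults to an intercept-only fixed design; covariates can
  be passed but the birth-date analyses here do not use them.
* The drift test's multi-generation variance is linear in $t$; for gaps
  long enough that heterozygosity decays appreciably it overstates the
  envelope slightly.
* BayesCπ's $\pi$ is weakly identified on signal-free data when markers
  outnumber records (see above); interpret $\pi$ jointly with the
  per-locus inclusion probabilities.
* The Meuwissen–Luo recursion in R is comfortable to a few thousand
  animals; far larger pedigrees would want a compiled path.
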