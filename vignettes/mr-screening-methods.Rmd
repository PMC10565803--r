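---
title: "Methods: two-sample MR screening with mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

# Scope and model

`mrscreen` implements a complete two-sample Mendelian randomization (MR)
screen: many exposures (designed around gut-microbiota taxa from a
consortium GWAS) are tested one at a time against a single binary
outcome using only GWAS summary statistics. The causal target is the
log-odds effect $\theta$ of a unit change in the exposure on the
outcome.

Three assumptions underpin every estimate: instruments are (1)
associated with the exposure, (2) independent of confounders of the
exposure–outcome relationship, and (3) affect the outcome only through
the exposure (exclusion restriction). The package tests what is testable
— instrument strength for (1), heterogeneity and directional pleiotropy
for (3) — and the synthetic-data generator violates (3) on demand so the
diagnostics can be validated against known ground truth.

# Instrument selection

Candidate instruments must pass $p < 10^{-5}$ (strict inequality) in the
exposure GWAS — the conventional suggestive threshold for
small-GWAS exposures such as microbiota taxa, where genome-wide
significance would leave most taxa without instruments. Independence is
enforced by greedy LD clumping against an explicit $r^2$ matrix: sort by
ascending p-value, take the best remaining SNP as an index, and discard
every SNP on the same chromosome within 10,000 kb whose $r^2$ with the
index exceeds 0.001. Taking the LD matrix as an input (square or
long-format text) rather than computing it from a reference panel keeps
the algorithm deterministic and testable offline; the matrix used in
practice would come from a European reference panel.

Ties on p-value are broken by chromosome, then position, then SNP
identifier, which makes the output invariant to input row order.
Candidates absent from the LD matrix are dropped with a warning rather
than assumed independent — a conservative choice where no guidance
exists. Stage counts (input, removed by p, removed by LD, missing from
LD, retained) are conserved and recorded on the result.

# Harmonization

Outcome effects are aligned to the exposure's effect allele. Identical
allele pairs are kept; swapped pairs have the outcome beta negated;
palindromic SNPs (A/T, C/G) are removed *unconditionally* — no
allele-frequency rescue is attempted, because frequency-based strand
inference is unreliable near MAF 0.5 and the screening design can afford
the loss of instruments. Strand-complement pairs (e.g. exposure A/G vs
outcome T/C) are treated as allele mismatches and dropped rather than
silently complemented: complementing is ambiguous precisely for the
palindromic SNPs already excluded, and dropping is logged and auditable.
Instruments missing from the outcome GWAS are dropped (no proxy lookup);
every removal carries a reason code and the kept + dropped counts equal
the input count.

# Estimators

All estimator formulas are implemented in closed form; weighted
least-squares routines from base R appear only as independent oracles in
the test suite.

**Wald ratio** (one instrument): $\hat\theta_j = \hat\beta_{Yj} /
\hat\beta_{Xj}$ with first-order SE $se_{Yj}/|\hat\beta_{Xj}|$. The
first-order approximation ignores exposure-side noise; see Limitations.

**IVW** (primary, $k \ge 2$): the $w_j$-weighted mean of Wald ratios
with $w_j = \hat\beta_{Xj}^2 / se_{Yj}^2$. The reported SE is
multiplicative random-effects, $se_{\mathrm{fixed}} \cdot \max(1,
\sqrt{Q/(k-1)})$: overdispersion inflates the SE, but the variance is
floored at the fixed-effect value so homogeneous sets are not
anti-conservative. The floor makes the reported test slightly
conservative under exact homogeneity (its null rejection rate at
$\alpha = 0.05$ is about 0.04 for $k = 10$, by integration over the
$\chi^2$ law of $Q$); the fixed-effect p-value, which is exactly
calibrated under homogeneity, is always reported alongside
(`pvalue_fixed`), and the package's calibration studies are run on it.

**MR-Egger** ($k \ge 3$): weighted regression of outcome on exposure
betas with a free intercept. Because the fit is not invariant to allele
orientation, instruments are first oriented so $\hat\beta_{Xj} \ge 0$
(the exposure-increasing-allele convention), making the result
deterministic. The residual variance is floored at 1 (the same
multiplicative random-effects convention), and p-values use the $t$
distribution with $k - 2$ degrees of freedom. Internally studentized
residuals from this fit drive the per-SNP pleiotropy flags below.

**Weighted median** ($k \ge 2$): ratios are sorted, cumulative-weight
midpoints $s_j = \sum_{i \le j} w_i - w_j/2$ formed (weights normalized
to one), and the estimate linearly interpolated at $s = 0.5$, clamping
to the extreme ratios outside $[s_1, s_k]$ so small $k$ is well defined.
The SE is the standard deviation over parametric-bootstrap replicates
(default 1,000) that redraw both exposure and outcome betas from their
sampling distributions; the seed is a mandatory argument, and the
caller's RNG state is restored. Instruments with $\hat\beta_{Xj} = 0$
are dropped with a warning before ratios are formed.

Every estimate carries OR $= e^{\hat\theta}$ and the 95% CI
$e^{\hat\theta \pm 1.96\,se}$.

# Sensitivity suite

*Cochran's Q* uses the same weights as IVW and the upper $\chi^2_{k-1}$
tail. *Instrument strength* follows $R^2 = 2\,\mathrm{MAF}(1 -
\mathrm{MAF})\hat\beta_X^2$ and $F = \frac{R^2}{1-R^2}\cdot\frac{n - k -
1}{k}$. The $k$ in the F formula is 1 by default: per-SNP F values (the
quantity the $F > 10$ filter screens on, and the one reported per
instrument) correspond to the single-instrument reading, which for
standardized traits reduces to approximately the squared z-score; the
caller may pass the taxon's full instrument count for the joint reading.
Missing allele frequency leaves $R^2$/F undefined; the default
weak-instrument policy keeps such instruments with a warning
(configurable to strict removal), since dropping on missing metadata
would silently bias screens of sparsely annotated GWAS. *Leave-one-out*
recomputes IVW without each instrument and flags a row influential when
the sign of the estimate or the side of $p = 0.05$ changes.

# Verdict logic and decision rules

Per taxon: `no_instruments` if nothing survives selection, filtering and
harmonization; `unreliable` if Q or the Egger intercept rejects at
$\alpha$ ($p \le 0.05$); `associated` if the primary estimate has $p <
\alpha$ and neither diagnostic rejects; otherwise `not_associated`.
Direction (risk/protective) is the side of OR = 1. Diagnostics that
cannot be computed (too few instruments) cannot reject. Verdicts are a
pure function of the p-values and $\alpha$, so re-annotation is
idempotent.

The majority-invalid rules — "use the weighted median when most
instruments are heterogeneous; Egger remains valid when most are
pleiotropic" — require a per-SNP classification that screening practice
leaves unspecified. We operationalize: an instrument is *heterogeneous*
when its Q contribution $w_j(\hat\theta_j - \hat\theta)^2$ exceeds the
upper $\chi^2_1$ $\alpha$ quantile, and *pleiotropic* when its absolute
studentized Egger residual exceeds the two-sided normal $\alpha$
quantile. A >50% majority marks the weighted median (heterogeneity) or
MR-Egger (pleiotropy; taking precedence when both majorities occur) as
the *headline* estimate. This is annotation only: IVW is always
reported, and verdicts do not change.

No multiple-testing correction enters the verdicts — screening at
nominal $p < 0.05$ across ~200 taxa is the field's practice and its
weakness; reports include a Benjamini–Hochberg column (per method,
across exposures) for information only.

Batches sort exposures by trait identifier, exclude unnamed taxa
(identifiers containing `"unknown"`, configurable), derive per-taxon
seeds as `seed + index` so results are reproducible and order-stable,
and capture per-taxon failures without aborting the screen.

# Synthetic data: what it emulates and what it does not

`simulate_taxon()` generates the summary-statistic *façade* of a
microbiota-style exposure and a case-control outcome. Defaults are the
study conditions the package is designed around: exposure sample size
18,340 and outcome size 77,257 (8,288 cases + 68,969 controls) on the
log-odds scale; 10 true instruments per taxon; MAF uniform on
(0.05, 0.5); instrument effects from Normal(0, 0.08) on the
standardized-trait scale, resampled until they clear the suggestive
threshold at the exposure sample size with probability near 1 (so
"number of planted instruments" is meaningful ground truth); standard
errors from the standardized-trait approximation $1/\sqrt{2\,
\mathrm{MAF}(1-\mathrm{MAF})\,n}$, which makes the F/R² statistics
internally consistent with the generated sample sizes; and 50 decoy null
SNPs per true instrument so the p-value filter does nontrivial work.
P-values equal the normal tails of the observed z-scores to machine
precision.

Direct (pleiotropic) effects are added in the exposure-increasing-allele
frame: the generated outcome effect is $\theta\beta_{Xj} +
\mathrm{sign}(\beta_{Xj})\,\alpha_j$. Allele coding is arbitrary, so a
*directional* mean pleiotropy is only definable relative to the allele
that raises the exposure; defining it in that frame is also what makes
the MR-Egger intercept (computed after the same orientation) estimate
$E[\alpha_j]$, which the recovery studies verify. `pleio_frac` controls
the fraction of invalid instruments, `het_sd` adds ratio-level noise
that Cochran's Q should detect, and `palindrome_frac` plants
strand-ambiguous alleles for harmonization tests.

Not emulated: real LD structure (the generator emits independent SNPs
spaced beyond the clump window, plus a separate block-diagonal LD
builder for clumping tests), case-control asymmetry beyond the normal
approximation of log-OR estimates, winner's-curse selection of
instruments, sample overlap between the two GWAS, and any actual
microbial-abundance biology. Passing calibration on these synthetics
therefore validates the *statistical machinery*, not robustness to
realistic LD misspecification or overlap bias.

# Validation study sizes and numerical choices

The packaged validation studies (test suite and `scripts/acceptance.R`)
use: 1,000 null taxa through the full pipeline for Type-I-error and Q
calibration, judged against the 95% binomial band around 0.05; 500
replicates at $\theta = 0.2$, $k = 20$ and sample sizes of 200,000 for
mean-recovery checks (large samples keep regression-dilution bias well
inside the Monte-Carlo band — see Limitations); 200 replicates for the
weighted-median scenario with 40% invalid instruments, evaluated on the
replicates where invalid instruments hold under half the weight (the
estimator's consistency premise); and a 20-taxon batch with 8 planted
causal taxa for verdict logic, with chance rejections of the
nominal-level diagnostics bounded by 99% binomial bands rather than
asserted away. Bootstrap replicates are reduced to 100 inside the large
calibration loops (the weighted-median SE does not enter those
assertions). Estimator equivalence to weighted-least-squares oracles is
asserted to $10^{-10}$; the weighted median is checked against a
weighted-absolute-deviation grid minimizer, which provably lies at an
endpoint of the interpolation interval bracketing the estimate.

Degenerate inputs are errors, not guesses: identical alleles, $se \le
0$, $R^2 \ge 1$, zero exposure-beta variance in Egger, degenerate MAF
ranges. Rows violating record invariants are dropped and counted at
read time, never silently repaired; duplicate rsIDs keep the first
occurrence, logged.

# Known limitations

- The first-order Wald-ratio variance ignores exposure-side sampling
  error. At large causal effects this inflates Cochran's Q beyond its
  nominal law (the extra ratio variance $\theta^2 se_X^2$ is absent from
  the weights), so strongly causal taxa are flagged heterogeneous more
  often than $\alpha$; under the null ($\theta = 0$) calibration is
  exact. Modified-weight Q statistics would address this but are outside
  the implemented scope.
- Regression dilution: noisy exposure betas attenuate IVW slightly
  (relative bias of order $se_X^2 / \beta_X^2$); negligible at the
  instrument strengths the generator enforces, but visible for weak
  instruments.
- Unconditional palindrome removal and mismatch dropping lose
  instruments that frequency-aware tools would rescue; instrument counts
  will run lower than pipelines that infer strand.
- Verdicts use nominal significance across many exposures by design;
  the BH column quantifies, but does not act on, the resulting
  multiplicity.
- No reverse-direction MR, proxy-SNP lookup, MR-PRESSO/mode-based
  estimators, or LD estimation from genotypes.
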