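---
title: "Methods: genomic breed composition from SNP-BLUP and supervised admixture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic breed composition from SNP-BLUP and supervised admixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(breedcomp)
```

breedcomp estimates the breed composition of purebred and crossbred
cattle from SNP genotypes by two routes — a SNP-BLUP ridge regression and
a supervised admixture likelihood — and studies how far genotyping density
can be reduced before those estimates degrade. Because the motivating
application concerns proprietary national-herd genotypes, the package
carries its own simulator whose defaults encode the study conditions; all
package results are statements about that simulated system, and this
vignette is explicit about what the simulator does and does not emulate.

## The simulated system

Thirteen breeds (labelled after the Irish beef/dairy breeds the pipeline
targets: Angus, Aubrac, Blonde d'Aquitaine, Belgian Blue, Charolais,
Friesian, Hereford, Holstein, Limousin, Parthenaise, Saler, Shorthorn,
Simmental) diverge from a common ancestral population under the
Balding–Nichols model: each SNP has an ancestral frequency $p \sim
U(0.05, 0.95)$ and the breed-$k$ frequency is drawn

$$ f_{kj} \sim \mathrm{Beta}\!\left(p_j \tfrac{1-F_k}{F_k},\;
   (1-p_j)\tfrac{1-F_k}{F_k}\right), $$

so $E[f_{kj}] = p_j$ and $\mathrm{Var}(f_{kj}) = F_k\,p_j(1-p_j)$.
Purebred genotypes are Binomial$(2, f_{kj})$, independent across loci
(Hardy–Weinberg, **no within-breed LD** — see Limitations). Crossbreds
are built from explicit gametes: a purebred parent transmits a
whole-breed gamete; an F1 parent transmits a recombination mosaic of its
two breeds under the Haldane model (Poisson crossovers, 1 cM/Mb linear
map on 29 cattle autosomes totalling ~2.5 Gbp, scalable). Each
transmitted locus carries a breed-of-origin label, and the *realized*
genome fraction per breed — not just the pedigree expectation — is stored
and used as evaluation truth. An `independent_loci` mode draws gamete
origins independently per locus for cheap unit tests.

**Drift calibration.** The package measures divergence with Wright's
index computed from breed allele frequencies,
$F_{st,j} = s^2_j / (\bar p_j (1-\bar p_j))$, where $s^2$ is the
*population* (divide-by-$B$) variance across breeds — the convention
under which a fixed difference between two breeds gives exactly
$F_{st}=1$. Under this estimator two Balding–Nichols breeds with drift
$F$ each have expected pairwise $F_{st} \approx S/(1-S)$ with
$S = F/2$, i.e. roughly **half** the drift coefficient (the familiar
$E[F_{st}] = F$ holds only for the sample-variance convention). The
default drift is therefore uniform $F = 0.15$, which realizes pairwise
$F_{st} \approx 0.065$–$0.072$, in the middle of the 0.039–0.146
envelope reported between European cattle breeds. A graded per-breed
drift that spans the whole envelope was evaluated and deliberately
rejected: under Balding–Nichols a drift gradient concentrates the
highest *global* per-SNP $F_{st}$ values on contrasts involving the
most-drifted breeds, which makes "highest-Fst" panels *worse* than
random ones — the opposite of the system being emulated, where
Fst-ranked panels are the best selection strategy. Divergence magnitude
and informativeness structure take precedence over reproducing the
envelope's extremes.

## SNP-BLUP breed composition

For each target breed a balanced 1/0 response is built: all $n_t$
training animals of the breed are coded 1 and $n_t$ animals drawn from
the other $B-1$ breeds (per-breed counts differing by at most one,
remainders seeded) are coded 0; everything else is excluded. All SNPs
enter as i.i.d. random effects. With $p$ the coded-1 fraction, the
phenotypic variance of the indicator is the Bernoulli variance $pq$; with
heritability $h^2 = 0.999$ the genetic variance $h^2pq$ is split equally
over the $m$ SNPs, giving the ridge parameter

$$ \lambda \;=\; \frac{\sigma^2_e}{\sigma^2_g/m} \;=\;
   m\,\frac{1-h^2}{h^2} \;\approx\; 0.001\,m .$$

(The alternative convention $\lambda = (1-h^2)/h^2$, i.e. the full
genetic variance per SNP, is available as `lambda_mode = "total"`; the
per-SNP split is the default because it preserves the SNP-BLUP/GBLUP
equivalence.) The mixed-model equations are solved in the centered form,
through the primal $m \times m$ system when $m \le n$ and the dual
$n \times n$ kernel form otherwise; the two agree to $10^{-8}$ and are
cross-checked against a dense normal-equation inversion in the tests.
Note that $\lambda \approx 0.001m$ is *very* light regularisation: the
fit nearly interpolates its training data, which matters for the
contamination experiment below.

Predictions multiply the fitted allele-substitution effects by each
animal's allele counts. The fitted intercept is **not** added by default:
the method description multiplies effects by allele counts only, and
adding the intercept (~0.05 for balanced codings) shifts every
competitor breed's score upward, inflating exactly the leakage the 0.05
zeroing must remove. `include_intercept = TRUE` restores the recentred
scores (training target animals average exactly 1), which is the right
choice when the raw scores themselves are of interest.

Post-processing, in order: negatives clamped to zero; values below 0.05
set to zero; the remainder rescaled to sum to one (an animal losing all
breeds is flagged unassignable rather than erroring). A purebred is
*assigned* when its largest proportion is $\ge 0.90$, boundary
inclusive.

## Supervised admixture EM

Breed allele frequencies are frozen at their observed values in the
labelled training purebreds (clamped to $[\varepsilon, 1-\varepsilon]$,
$\varepsilon = 10^{-6}$), and each animal's ancestry vector $q$ on the
$K$-simplex maximises the binomial likelihood

$$ \ell(q) = \sum_j \big[ g_j \log \textstyle\sum_k q_k f_{kj}
   + (2-g_j) \log \sum_k q_k (1-f_{kj}) \big] $$

by EM from the uniform start ($\ell$ is concave in $q$ for fixed $F$, so
the optimum is global and no restarts are needed). Iteration stops when
the log-likelihood improves by less than `tol` ($10^{-6}$) or at
`max_iter` (2000). The production path runs all animals together through
BLAS matrix products, checking the (asserted non-decreasing)
log-likelihood every 8 updates; a compiled per-animal loop and a plain-R
reference that asserts monotonicity every iteration implement the same
update and agree to machine precision. This is a frozen-frequency
"projection" analysis: validation animals never influence $\hat F$. The
joint-update behaviour of the ADMIXTURE program is out of scope; the
difference vanishes as the labelled training grows.

Two numerical facts worth knowing. First, at a simplex corner the EM
approaches the optimum sublinearly, so purebred animals typically exhaust
`max_iter` with `converged = FALSE` while $q$ has long stopped moving at
any meaningful scale; quasi-Newton acceleration is deliberately not
implemented. Second, with frozen frequencies estimated from finite
training the per-animal optimum genuinely sits slightly inside the
corner (worst-case $\hat q_{true} \approx 0.96$–$0.98$ even with 500
training animals per breed); the mean across animals stays above 0.99
and the 0.05-zero/rescale step absorbs the leakage, so assignment is
unaffected.

The same post-processing and assignment rules as SNP-BLUP are applied
downstream.

## Low-density panels

SNPs are scored on a *separate* SNP-selection population (never the
training or validation animals, to avoid selection bias) by five
measures: per-SNP Wright $F_{st}$ across all breeds; a PCA weighting
(eigenvalue-weighted sum of squared SNP loadings over the leading $B-1$
axes of the standardized-genotype covariance — the number of axes that
separate $B$ clusters; exact weighting is a config parameter since the
reference algorithm's is unstated); the SD across breeds of the per-breed
SNP-BLUP effect fitted on this population; seeded random-forest
impurity importance (500 trees, $\sqrt m$ candidate features); and a
one-vs-rest PLS regression on a $\pm 1$ breed code (10 latent
components; per-SNP weight = max $|$coefficient$|$ over the $B$ models).
Panels of 100–7,500 SNPs allocate their density to chromosomes
proportionally to physical length by largest-remainder rounding — the
same allocation for every strategy at a given density — and pick within
chromosome by strategy: random; PAM position-medoids (`cluster::pam`,
build + swap, i.e. a deterministic local search); highest score per
contiguous equal-count block (remainder SNPs appended to the last
blocks); highest score per PAM cluster; or highest score outright, ties
broken by lower basepair. No LD threshold or minimum spacing is applied,
mirroring the study design.

## Evaluation

Agreement between two composition tables is summarised by the mean
signed difference, mean absolute difference, SD of differences, RMSE and
Bland–Altman limits (mean $\pm$ 2 SD), overall or per breed (per-breed
scope restricted to animals carrying the breed at $\ge 0.05$). The
full-panel SNP-BLUP compositions are the gold standard for panel
evaluation; crossbred deviation is measured on the main breed (the
largest gold-standard proportion per animal). A paired two-sided t-test
p-value of the mean difference is reported but never gates anything.
The mislabeling experiment replaces a fraction (default half) of one
breed's training animals with freshly simulated F1 crossbreds labelled
as purebred, refits both predictors and reports the breed's
purebred-validation assignment at the 0.90 and 0.60 thresholds.

## Problem sizes

The shipped analysis scripts and tests run a desk-scale study: 13
breeds, 5,000 SNPs on the 5 largest autosomes (10,000 for the panel
study), 100 training / 50 purebred-validation / 200 SNP-selection
animals per breed, ~389 crossbreds in the Table-proportioned designs,
and panel densities 100–2,000. These sizes were chosen so a complete run
stays in the minutes range on one core while keeping every per-breed
subpopulation large enough for stable frequency estimates. The original
system is an order of magnitude larger in every dimension (49,213 SNPs,
500/250/up-to-1,000 animals per breed); where a conclusion depends on
that scale it is called out below.

## What passing tests do and do not show

The simulator reproduces the divergence magnitude, the population
layout, the crossbred ancestry mosaics and the two estimation methods,
and on it both predictors assign essentially all purebreds from the full
panel and recover F1 ancestry at 0.5 per parental breed. Two study
findings are *not* reproduced, for reasons that are themselves
informative:

* **Position-based and random panels at 2,000 SNPs.** Real genomes carry
  extensive LD, so a position-spread subset tags most of the genome; the
  simulator's purebred genotypes are independent across loci, so a PAM
  or random panel is just a smaller experiment. Combined with the
  near-interpolating ridge ($\lambda \approx 0.001m$) and 100 training
  animals per breed, 2,000-SNP position-based panels leave enough noise
  in the eleven competitor scores that the 0.05 zeroing cannot clean
  them, and assignment lands near 25–50% where the study reports >85%.
  Score-ranked panels (Fst, PCA, SNP-BLUP-SD) do reach ~100%,
  reproducing the study's ordering of informative over positional and
  random selection.
* **SNP-BLUP's sensitivity to mislabeled training animals.** On real
  data the regression collapsed under 50% mislabeled crossbreds while
  admixture was unaffected. In this simulator admixture is indeed
  unaffected (its corrupted reference frequency for the breed is still
  closest to a purebred's genotype, so $\hat q$ stays at the corner),
  but the near-interpolating ridge also keeps fitting the uncontaminated
  half of its training class and loses only a few percent. The
  differential sensitivity appears to require real-data LD and
  relatedness structure; treat the simulated experiment as a bound, not
  a reproduction.

Other known limitations: no genotyping error, no missingness in
simulated data (QC and mean-imputation are exercised on constructed
fixtures), unrelated individuals apart from the explicit cross
pedigrees, and a mean-imputation stand-in where the original pipeline
used family-informed imputation — equivalent on complete synthetic data,
not on real data.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <s> --out <path>` regenerates the two
summary quantities from scratch: the full-panel purebred assignment rate
(minimum of the two predictors; 13 breeds, 5,000 SNPs, 100/50 animals
per breed) and the minimum SNP-BLUP assignment rate over 2,000-SNP
panels built by the Fst-highest, PCA-highest, PAM-medoid and
SNP-BLUP-SD strategies from a separate 200-per-breed selection
population at 10,000 SNPs. The numbered scripts under `analysis/` run
the full desk-scale study and write their tables under `results/`.
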