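---
title: "Dietary networks from Gaussian graphical models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary networks from Gaussian graphical models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietggm)
```

## The problem

Dietary pattern analysis asks how foods are eaten *together*. Classical
data-reduction tools (PCA, factor analysis, cluster analysis) summarize the
marginal correlation structure of food-group intakes, but marginal
correlations confound direct and indirect relations: fruit and fish may
correlate only because both track a generally health-conscious diet. A
Gaussian graphical model (GGM) instead works with the *conditional*
dependence structure. If intakes $x \sim N(\mu, \Sigma)$ and
$\Omega = \Sigma^{-1}$ is the precision matrix, then

$$\rho_{ij} = -\frac{\omega_{ij}}{\sqrt{\omega_{ii}\,\omega_{jj}}}$$

is the partial correlation between food groups $i$ and $j$ given all other
groups, and $\omega_{ij} = 0$ means conditional independence. The graph with
an edge wherever $\omega_{ij} \neq 0$ is the dietary network: its connected
assemblies are interpretable dietary patterns, and foods that sit in several
link communities at once are the "central" foods holding a pattern together.

`dietggm` implements that whole chain for subjects-by-food-groups intake
tables (g/d, typically from a food frequency questionnaire mapped to a
35-group registry): standardization, sparse precision estimation by
graphical lasso, partial-correlation edge lists, overlapping link-community
detection, dietary-network assembly with central foods, per-subject network
scores with tertiles, and tertile logistic regression against general and
abdominal obesity outcomes. A synthetic cohort generator with planted
structure provides ground truth for every stage.

## Sparse precision estimation

The graphical lasso maximizes the penalized log-likelihood

$$\log\det\Omega - \mathrm{tr}(S\Omega) - \lambda \sum_{i \neq j} |\omega_{ij}|,$$

with $S$ the sample correlation matrix of standardized intakes. We estimate
on the correlation scale because network scores standardize intakes anyway
and partial correlations are the reported edge weights. The penalty applies
to off-diagonal elements only (a `penalize_diagonal` flag restores the
alternative), which keeps the two limiting regimes exact and testable: at
$\lambda = 0$ the solution is $S^{-1}$, and for
$\lambda \ge \max_{i \neq j} |S_{ij}|$ the solution is exactly diagonal with
$\omega_{ii} = 1/s_{ii}$.

The solver is block coordinate descent over rows (each row update is a lasso
subproblem solved by coordinate descent), implemented in C++. Convergence is
declared when the maximum elementwise change of the working covariance in a
sweep falls below `tol` ($10^{-6}$ by default); non-convergence after
`maxit` (500) sweeps is an error, never a silent result. Edge existence uses
a numerical zero of $10^{-10}$ on $|\omega_{ij}|$, and $|\rho| \ge 0.20$
flags an edge as strong — the conventional cut for a sizeable conditional
association in dietary networks. Positive partial correlations are drawn
solid, negative dashed, line width proportional to $|\rho|$ in the GraphML
export.

### Choosing the penalty

The penalty is selected by the extended BIC,

$$\mathrm{EBIC}_\gamma(\lambda) = -2\,\ell(\hat\Omega_\lambda) + k \log n + 4 k \gamma \log p,$$

with $k$ the number of selected edges and $\gamma = 0.5$, over a 30-point
log-spaced grid from $\lambda_{\max} = \max|S_{ij}|$ down two decades. One
design decision matters here: $\ell$ is evaluated at the
**maximum-likelihood estimate restricted to the selected support** (the
penalized estimate's zero pattern, refitted with $\lambda = 0$ under
equality constraints), not at the lasso-shrunk estimate itself. Evaluated at
the shrunk estimate, the likelihood keeps improving as $\lambda$ falls and
the criterion drifts toward dense graphs; the support-refit formulation
removes that shrinkage bias and is what the EBIC consistency theory is
stated for. The same refit supplies the reported partial correlations, so
edge weights are not attenuated by the penalty. Ties in EBIC go to the
larger (sparser) penalty.

## Link communities and dietary networks

Communities are detected over *edges*, not nodes, so a food group can belong
to several communities — nested and overlapping patterns are exactly what
distinguishes, say, butter's role in a saturated-fats cluster from its role
in a baked-goods cluster. Two edges sharing a node $k$, $(i,k)$ and $(j,k)$,
are compared through the inclusive neighborhoods of their outer endpoints:

$$s\big((i,k),(j,k)\big) = \frac{|n^+(i) \cap n^+(j)|}{|n^+(i) \cup n^+(j)|},
\qquad n^+(x) = \{x\} \cup \mathrm{neighbors}(x),$$

and edges with no shared node have similarity 0. Edges are agglomerated by
single linkage — the canonical choice for link communities, with the useful
property that the partition at any similarity threshold equals the connected
components of the threshold graph, making the cut reproducible regardless of
merge-order tie-breaking. The dendrogram is cut where the partition density

$$D = \frac{2}{M} \sum_c m_c\, \frac{m_c - n_c + 1}{(n_c - 2)(n_c - 1)}$$

is maximal ($m_c$ edges and $n_c$ nodes in community $c$; two-node
communities contribute 0). Ties go to the higher similarity threshold, i.e.
more and smaller communities. The suite verifies the cut against exhaustive
enumeration on all fixtures up to 12 edges. A weighted (Tanimoto,
$|\rho|$-weighted) similarity and a strong-edges-only mode are available
behind flags; the defaults are the unweighted similarity on all nonzero
edges.

Dietary networks are the connected components of the union of community
edge sets; components with fewer than 3 food groups are dropped. Within a
network, the central food maximizes community membership count, with ties
broken by the largest sum of $|\rho|$ over incident edges. Networks are
named by size rank and can be renamed (e.g. "healthy", "unhealthy",
"saturated fats").

## Scoring and association

Per network, loadings are the first principal component of the correlation
matrix of that network's standardized columns, scaled by
$\sqrt{\lambda_1}$ (factor-loading convention). PCA runs per network rather
than on all 35 groups — the reading most consistent with scoring "within
each network" — and a global-PCA flag exists for sensitivity analysis. The
eigenvector sign is anchored so the central food's loading is non-negative;
without an anchor the sign of scores would flip between runs. A
(near-)tied leading eigenvalue within $10^{-8}$ raises a degenerate-loading
error rather than returning an arbitrary axis. Scores are
$\mathrm{score}_s = \sum_j \mathrm{loading}_j\, z_{sj}$ and are tertiled by
rank with stable tie-breaking (earlier subject to the lower tertile,
remainder subjects to the lower tertiles), so group sizes differ by at most
one even with ties. Any positive rescaling of loadings is inert under
tertiling, which is why the loading-scale convention is a presentation
choice, not a modeling one.

Obesity outcomes: general adiposity is BMI $\ge$ 30 kg/m² (inclusive);
abdominal adiposity is waist circumference $>$ 102 cm (men) / $>$ 88 cm
(women), or waist-to-hip ratio $>$ 0.90 (men) / $>$ 0.85 (women), both
strict. Odds ratios across score tertiles come from maximum-likelihood
logistic regression with T1 as reference and Wald CIs
$\exp(\hat\beta \pm z_{1-\alpha/2}\,\mathrm{SE})$. The trend test enters
the tertile index 1–3 as a single continuous term (ordinal coding, the
standard nutrition-epidemiology choice; tertile-median coding is available).
The default adjustment set is age, sex, occupation, smoking, education,
marital status, menopausal status, physical activity and energy intake;
the set is config-driven because published adjustment lists in this
literature often differ between abstract, methods and table footnotes.
Menopausal status for men is the explicit level `not_applicable`, never
missing; since that level duplicates `sex == "man"`, the aliased coefficient
is dropped from the fit with a message (the model is identical under either
parameterization). Collinearity affecting the tertile terms themselves, or
separation, is an error.

Descriptive tables across tertiles use one-way ANOVA for continuous and
Pearson $\chi^2$ for categorical covariates. The design-stage sample-size
helper implements $n = p(1-p)z^2/E^2$ (times an optional design effect);
with prevalence 0.65, margin 0.04 and $\alpha = 0.05$ it returns 546,
and with a design effect of 1.5 the usual rounding-up to a recruitment
target of ~850 follows.

## The synthetic cohort generator

The generator is the test bed: no subject-level cohort of this kind is
publicly deposited, so every downstream claim is validated against planted
ground truth.

* **Planted structure.** Disjoint blocks of food groups share a common
  within-block partial correlation; optional *bridge* pairs connect blocks.
  Blocks are kept disjoint so each planted community is unambiguous; bridges
  exist because purely disjoint blocks could never assemble into fewer
  networks than blocks, whereas real dietary networks are built from several
  linked communities. The default structure has 35 groups, six blocks of
  sizes 5, 8, 5, 6, 3, 3 laid onto registry groups (a cooked-vegetable and a
  fruit/raw-vegetable community bridged into a healthy network; processed
  meat, snack and fruit-juice communities bridged into an unhealthy network;
  butter–margarine–animal fat as a saturated-fats network), 30 foods in
  networks and five background groups. Within-block partials default to
  0.20/0.12/0.20/0.16/0.25/0.30 and bridges to 0.20 — values inside each
  block's positive-definiteness bound and detectable at $n = 850$, which is
  the default cohort size.
* **Feasibility and honesty.** An equi-partial block of $n$ nodes is
  positive definite only for $\rho < 1/(n-1)$. Requested structures outside
  that bound are made feasible by diagonal loading in steps of 0.05 until
  the smallest eigenvalue reaches 0.05 (loading beyond 10 is an
  "infeasible" error). Loading shrinks the achieved partials below the
  request, so the generator *re-reports* the achieved partial-correlation
  matrix and all recovery checks measure against it — the planted numbers
  are never assumed.
* **Marginals.** Rows are multivariate normal with
  $\Sigma = \Omega^{-1}$ — the latent scale on which the GGM's
  distributional assumption holds exactly. An `expshift` transform,
  $\mathrm{intake} = m\,e^{0.4 z}$, maps latent z-scores monotonically to
  positive, right-skewed g/d values resembling FFQ intakes; identity
  marginals are available for estimator-focused checks. The transform
  distorts correlations somewhat (a monotone transform of a Gaussian is not
  Gaussian), which is deliberate: it lets the suite confirm the pipeline is
  robust to realistic skew, and it is why both marginal modes exist.
* **Covariates and outcomes.** Covariates mirror a community-based urban
  cohort: mean age 44.7 (SD 10.8, truncated 20–59), 69% women, 63% low
  physical activity (< 3000 MET-min/week), 5.2% current smokers, 80.9%
  married, energy 2586 ± 1140 kcal/d, BMI 27.8 ± 5.6 kg/m², and
  menopause rates applying to women only. Outcomes are Bernoulli draws from
  the same tertile logistic model the association stage fits
  ($\mathrm{logit}\,p = \alpha + \sum \log\mathrm{OR} \times
  \mathbb{1}[\text{tertile}]$), so planted odds ratios are recoverable and
  the generative and analysis models are exact inverses. When real data are
  loaded instead, outcomes come from measured anthropometry via the
  threshold definitions above.

Everything is a pure function of its inputs and a seed; identical seeds give
byte-identical tables.

### What passing tests do and do not show

The generator draws from the estimator's own model family (on the latent
scale) with homogeneous within-block effects and independent subjects.
Passing recovery tests therefore demonstrates correctness of the
implementation and adequate power at the stated sizes — not that FFQ
measurement error, energy misreporting, item-level aggregation noise, or
population stratification in real cohorts are harmless. Near-collinear food
groups (e.g. partial correlations approaching 1, as can happen when two
groups are essentially the same foods) are not planted by default; the
estimator tolerates them only through the penalty.

## Validation sizes and numerical choices

The test suite and the acceptance script use: 20 replicate cohorts of
$n = 850$ and 35 groups for structure recovery (median edge F1 and planted
block/network Jaccard, both expected at 1.0 under the defaults); $n =
100{,}000$ for point recovery of a planted adjusted OR of 1.5; 200
replicates at $n = 850$ for Wald CI coverage (expected ≈ 95%) and trend-test
type-I error (expected ≈ 5%); Monte-Carlo checks at $n = 100{,}000$ for the
generator's moments; and exhaustive enumeration for community cuts up to 12
edges. These sizes make the whole suite run in well under a minute on one
CPU while keeping every stochastic band at least several Monte-Carlo
standard errors wide.

Other numerical choices: sample SD with $n-1$ throughout; standardization
rejects constant columns (zero-variance food groups cannot enter a
correlation model) and errors on missing intakes unless complete-case
dropping is requested; an optional $\log(x+1)$ pre-transform for skewed
intakes is off by default because the estimation target is the correlation
structure of reported intakes unless the analyst decides otherwise.

## Known limitations

* The mapping from communities to networks is the connected-component rule;
  narrative groupings in published figures can differ from it, and with
  undeposited source cohorts the rule cannot be checked against them —
  numeric reproduction of published partial correlations, community counts
  or odds ratios is explicitly out of scope.
* No nonparanormal/copula extension: heavily non-Gaussian marginals are
  handled only by the optional log transform.
* No bootstrapped edge-stability assessment; a single EBIC-selected graph is
  reported.
* Single-factor PCA scoring only; no varimax rotation or reduced-rank
  regression alternatives.
* No multiple-testing correction across network-outcome pairs, matching
  standard practice in this literature.
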