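---
title: "Assessing sediment heavy-metal contamination with mHQ and ECI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing sediment heavy-metal contamination with mHQ and ECI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedqual)
```

## The assessment problem

Benthic sediments integrate heavy-metal inputs to an aquatic ecosystem and
are the compartment where contamination first becomes toxicologically
relevant to bottom-dwelling organisms. Monitoring campaigns therefore
produce tables of metal concentrations (mg/kg dry weight) per site, metal
and sampling period — either totals or the five operationally defined pools
of a Tessier sequential extraction (exchangeable F1, carbonate-bound F2,
Fe–Mn-oxide-bound F3, organic-bound F4, residual F5). The recurring question
is how to collapse such a table into defensible per-metal severities and a
single per-site risk figure. `sedqual` implements a pair of composite
indices designed for exactly that, alongside the classical suite used to
validate them.

## The modified hazard quotient

A single-guideline hazard quotient (HQ = C/TEL) asks only whether a
concentration exceeds one effect threshold. The modified hazard quotient
folds all three commonly tabulated effect levels into one number:

$$mHQ_i = \sqrt{C_i \left(\frac{1}{TEL_i} + \frac{1}{PEL_i} +
\frac{1}{SEL_i}\right)}$$

where TEL, PEL and SEL are the threshold, probable and severe effect levels
for metal *i*: concentrations below TEL rarely harm benthic biota, above PEL
frequently do, and above SEL affect most benthic species. Because the three
reciprocals weight the stricter guideline most heavily, mHQ responds early
to concentrations that approach the cautionary threshold. The square root is
a deliberate drawdown: it compresses the scale so that the eight severity
classes (`classify_mhq()`, 0.5-unit steps from 0.5 to 3.5) are evenly spaced,
and it gives the index a testable scaling law — quadrupling a concentration
doubles the index.

Interval boundaries are left-closed (`a <= x < b`) and a value exactly on a
cut belongs to the upper class; this makes the classification a total
partition of the non-negative reals (the top class is reached at exactly
3.5). If a guideline table lacks an effect level for some metal the
available reciprocal terms are used and the result is flagged
(`partial_guidelines`), since dropping a term changes the index scale.

## The ecological contamination index

Site-level aggregation is done by

$$ECI = B_n \sum_{i=1}^{n} mHQ_i, \qquad B_n = 1/\lambda_1,$$

where $\lambda_1$ is the leading eigenvalue of a correlation-matrix PCA of
the site's metal concentrations (periods × metals). The sum collects the
per-metal severities; the PCA-derived weight ties the aggregate to the
site's source structure, since the first component of these datasets is
interpreted as the common anthropogenic contamination factor. `n` is the
number of metals with a computed mHQ at the site; metals with missing data
are excluded and reported rather than silently rescaling the sum. The
seven ECI classes (`classify_eci()`) run from uncontaminated (< 2) to
extremely contaminated (≥ 7), again as left-closed intervals.

Two genuinely open choices are exposed as options with these defaults:

* **Which eigenvalue.** `bn_weight()` defaults to the first *unrotated*
  eigenvalue of the site's metals-only correlation PCA (`component`
  selectable, varimax optional). PC1 is the component identified with
  anthropogenic loading, and on the bundled case study the reciprocal of
  the published PC1 eigenvalues reproduces the published ECIs.
* **Aggregation of periods.** The default computes one index from the
  arithmetic mean concentration over periods (`aggregation = "mean"`);
  `"period_mean"` instead computes an mHQ per period and averages the
  indices. By concavity of the square root the second route is never
  larger; on the bundled data the two differ by well under 1%.

## Classical comparison indices

A new index is only credible if it ranks contamination the way the
established ones do. The package therefore provides, behind one surface
(`classical_indices()`): contamination factors CF = C/B against
average-shale backgrounds, their percentage shares (%DC), the modified
degree of contamination (mean CF) and pollution load index (geometric mean
CF), Håkanson's potential ecological risk (Er = Tr × CF, site sum RI,
shares %Ri), effect-level quotients, and — from fraction records — the risk
assessment code RAC = (F1+F2)/ΣF × 100 and individual contamination factor
ICF = (F1+F2+F3+F4)/F5. `concordance()` quantifies agreement between the
metal orderings of any two indices as exact-match flags plus Spearman rank
correlations (computed by the exact rank-difference formula, since strict
orderings are permutations). The indices with formulas defined only in
secondary literature (CSI, mRAC, PCI) are deliberately not implemented;
externally computed columns can be compared through `concordance()`
directly.

## Constants and their provenance

The defaults are pinned in two documented, user-overridable text files:

* `default-guidelines.csv` — freshwater TEL/PEL (Smith et al. 1996) and
  Ontario SEL (Persaud et al. 1993) for Cd, Cr, Cu, Ni, Pb.
* `default-constants.csv` — average-shale backgrounds (Turekian & Wedepohl
  1961) and Håkanson (1980) toxic-response factors, with the conventional
  value 5 for Ni.

All concentrations are mg/kg dry weight throughout; there is no unit
conversion layer. Any guideline table with the same columns can be
substituted, including marine/estuarine TEL-PEL compilations; the worked
results below use the bundled freshwater set.

## The bundled case study

`case_study_concentrations()` returns the 150 monthly mean records (5 sites
× 5 metals × 6 months) of a survey of five Equatorial Atlantic coastal
ecosystems — Qua Iboe Estuary (QUE), Douglas Creek (DOU), Stubbs Creek
(STB), Okorotip Creek (OKT) and Qua Iboe River (QUR) — and
`case_study_pca()` the matching published two-component PCA summaries.
Both live as checksummed plain CSV files under `inst/extdata`, never inlined
in code, so the reference numbers can be audited directly.

```{r}
run <- run_pipeline(case_study_concentrations(),
                    bn = sapply(case_study_pca(), function(m) m$eigenvalues[1]))
run$eci[c("site", "eci", "class")]
unique(run$metal_rankings$sequence)
```

Every index in the run ranks the metals Cd > Pb > Cu > Cr > Ni at every
site, and cadmium dominates the ECI contributions — the concordance that
motivates trusting the composite indices. Douglas Creek is the most
contaminated site.

## The synthetic generator

`generate_dataset()` emulates a multi-site fraction survey: per (site,
metal, period) the total is lognormal with the scenario's target mean
(times a per-site contamination multiplier) and coefficient of variation,
then split across F1–F5 by a Dirichlet draw centred on the scenario's
fraction proportions. Lognormal + Dirichlet guarantees non-negativity and
maps directly onto the mean ± s.d. summaries real campaigns publish; the
default scenario mirrors the case-study magnitudes (Cd ≈ 4.8, Cr ≈ 19.5,
Cu ≈ 37.8, Ni ≈ 2.2, Pb ≈ 180 mg/kg, CV 0.27, six periods). `cv = 0` with
`dirichlet_conc = Inf` gives exact noise-free values, and a fixed seed
reproduces a dataset bit for bit.

What the generator does *not* emulate — seasonality beyond i.i.d. periods,
spatial autocorrelation between sites, correlated metal co-occurrence, and
measurement censoring at detection limits — bounds what passing tests show:
they demonstrate correct index arithmetic and parameter recovery under the
stated noise model, not robustness to structured real-world noise.

## Numerical choices

* PCA is computed by SVD of the standardized data matrix (numerically
  stabler than forming the correlation matrix); tests cross-check against a
  dense eigendecomposition to 1e-10. Eigenvalues of a p-metal correlation
  PCA sum to p; with fewer observations than metals the trailing
  eigenvalues are exactly zero, reported but never retained.
* Loadings are eigenvectors scaled by the square root of their eigenvalue,
  with each component's largest-magnitude loading made positive (published
  loading signs are convention-dependent).
* Varimax rotation uses Kaiser row-normalization by default (toggleable)
  and preserves communalities to 1e-8; a single retained component is
  returned unchanged with a warning.
* Ranking ties are broken alphabetically and flagged; site-ranking ties
  keep input order and are flagged.
* Test problem sizes are kept small by design — 6×5 matrices for PCA
  oracles, 400–1000 periods for generator recovery — because the
  convergence bounds tested (3·CV/√N) already bind at those sizes.

## Limitations

The ECI weight inherits the instability of small-sample eigenvalues: with
six periods, λ₁ carries substantial sampling error, and the package
deliberately lets the user supply published or pooled eigenvalues instead
(`bn =` a named vector). Point estimates only: the ± s.d. columns of the
survey are carried through readers but no uncertainty propagation is
attempted. Guideline choice matters more than any other option — switching
between freshwater and marine TEL/PEL sets shifts mHQ(Cd) by roughly 6% —
which is why every run's manifest records the constants used.
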