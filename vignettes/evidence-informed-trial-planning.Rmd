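---
title: "Evidence-informed trial planning with a negative binomial NMA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-informed trial planning with a negative binomial NMA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmaplan)
```

## The problem

A clinical development programme rarely designs its next trial from the
totality of available evidence. Phase III trials are typically sized from the
preceding phase II trial alone, even when randomised trials of comparator
treatments and real-world-evidence (RWE) studies — observational and routine
clinical practice studies — already constrain the plausible effect. `nmaplan`
implements a sequential planning loop for count outcomes (here, relapses in
relapsing-remitting multiple sclerosis, but any event-rate endpoint fits):

1. pool all arm-level evidence available at a milestone — RCT and RWE at face
   value — in a Bayesian network meta-analysis (NMA) with a negative binomial
   likelihood;
2. take the *predictive* distribution of the comparison of interest, i.e.
   what a new study would estimate;
3. simulate the next two-arm trial under that predictive effect, analyse each
   replicate with negative binomial regression, and search for the smallest
   per-arm sample size reaching the target power while the false-positive
   rate stays at the nominal level;
4. substitute the simulated, re-sized trial back into the network and compare
   the totality of evidence before and after;
5. project recruitment time for the re-sized programme.

## The model

For arm $k$ of study $i$, let $Y_{ik}$ be the relapse count and $E_{ik}$ the
person-years of exposure. The likelihood is negative binomial on the
mean/overdispersion scale:

$$Y_{ik} \sim \mathrm{NB}(\mu_{ik}, \kappa), \qquad
  \mu_{ik} = E_{ik}\,\lambda_{ik}, \qquad
  \mathrm{Var}(Y_{ik}) = \mu_{ik} + \mu_{ik}^2/\kappa,$$

$$\log \lambda_{ik} = \mu_i + \delta_{ik},$$

where $\mu_i$ is the log annualised relapse rate (ARR) of study $i$'s
baseline arm ($\delta_{i1}=0$), and $\delta_{ik}$ is the study-specific
contrast. Under random effects,
$\delta_{ik} \sim N(d_{t_{ik}} - d_{t_{i1}}, \sigma^2)$ with between-arm
correlation $1/2$ in multi-arm studies (constructed conditionally arm by
arm); under fixed effects $\delta_{ik}$ equals the basic-parameter contrast
and $\sigma \equiv 0$. The basic parameters $d_t$ are log rate ratios versus
the reference treatment ($d_{\mathrm{ref}} = 0$); every relative effect is a
difference $d_a - d_b$, so within each posterior draw the rate-ratio matrix
is exactly consistent and reciprocal.

The classical $(\gamma, p)$ negative binomial parameterisation relates to the
mean scale by $\gamma = \kappa$, $p = \kappa/(\kappa + \mu)$;
`nb_mean_to_gp()` / `nb_gp_to_mean()` convert and round-trip exactly. We work
on the mean scale because the exposure offset $E_{ik}$ enters naturally
there.

RWE arms enter the likelihood identically to RCT arms — pooling at face
value, no weighting or bias adjustment. The evidence-source tag demonstrably
never reaches the likelihood: relabelling every RWE study as RCT reproduces
the posterior draws bit-identically (this is a test).

### Priors and their defaults

| parameter | prior | default | why |
|---|---|---|---|
| $d_t$, $\mu_i$ | $N(0, 10^2)$ | sd 10 | vague on the log-rate scale; rates of $e^{\pm 20}$ are beyond any relapse endpoint |
| $\sigma$ | $U(0, u)$ | $u = 2$ | conventional uniform prior for between-study SD of log rate ratios; 2 allows 7-fold study-to-study swings |
| $\kappa$ | Gamma(0.1, 0.1) | shared across studies | weakly informative, mildly centred at 1; per-study $\kappa$ available as `kappa_mode = "per_study"`, and `kappa_fixed` pins it (e.g. very large for a Poisson-limit fit) |

Study baselines $\mu_i$ are independent (no baseline exchangeability), the
standard arm-based choice that keeps RWE baseline rates from influencing
relative effects. A single shared $\kappa$ is the default because individual
studies contribute few arms. All of these are switches in `nma_config()`.

### Sampling and convergence

No general-purpose MCMC engine is assumed: the sampler is a compiled adaptive
random-walk Metropolis-within-Gibbs with two non-standard moves that matter
in practice:

* a **joint translation** of $d_t$ together with the coupled study contrasts
  (leaving the random-effects residuals invariant), which breaks the strong
  prior coupling that otherwise makes $d$ mix an order of magnitude slower;
* a **joint rescaling** of $(\sigma, \delta)$ in which the prior change
  cancels the transform Jacobian exactly, so the likelihood drives the move —
  this avoids the usual funnel between $\sigma$ and its residuals.

Proposal scales adapt toward 44% acceptance during burn-in only. Chains are
seeded deterministically from `nma_config(seed = )` through R's RNG: the same
data, configuration and seed reproduce draws bit-identically. Convergence is
policed per reported parameter with split-$\hat R$ (threshold 1.05) and an
effective-sample-size floor (400); violations attach warnings to the
posterior and are never silent. Defaults (3 chains, 2000 burn-in, 5000 kept
draws) fit the 12-study test network in under two seconds with all
diagnostics clean.

## Trial simulation and sample-size search

`simulate_counts()` draws one count per patient from
$\mathrm{NB}(\text{ARR} \times \text{follow-up}, \kappa)$. Follow-up is an
explicit design parameter (default 1 year) — simulation-based sizing needs
it, and person-years per arm are subjects × follow-up throughout (no
dropout, staggered entry or interim looks are modelled).

`analyze_trial()` fits the negative binomial regression
$\log y = \beta_0 + \beta_1 x + \log(\text{follow-up})$ by maximum
likelihood. Because the two-group model is saturated, $\hat\beta_1$ is the
log ratio of observed ARRs for *any* dispersion; the common $\kappa$ is
profiled out by 1-D optimisation and the Wald standard error uses the
expected information at $\hat\kappa$. This specialised fit matches
`MASS::glm.nb` to five decimals (a test, against that and a brute-force
likelihood-grid oracle) while being ~50× faster, which is what makes
$10^4$-replicate power estimates take seconds. A likelihood-ratio test is
available via `test = "lrt"`.

Degenerate replicates are handled loudly: all-zero counts in both arms
refuse analysis ("inestimable effect"); a single all-zero arm flags the
result non-converged. `estimate_power()` excludes such replicates with a
count and aborts if exclusions exceed 1%.

`find_sample_size()` searches a coarse grid (step 25), smooths with isotonic
regression — raw Monte-Carlo power is not monotone — then refines at step 1
inside the bracketing interval, pooling all evaluated points before
thresholding; ties break toward the smaller n. An unreachable target returns
the boundary with `attained = FALSE` rather than a number.

The predictive effect can enter as a plug-in (predictive median, default) or
by full predictive integration (`effect_mode = "assurance"`, redrawing the
effect each replicate). Both are legitimate readings of designing "from the
predictive distribution"; they are reported side by side by the planner and
coincide as $\sigma \to 0$. For a symmetric effect distribution assurance
power is at most the plug-in power when the power function is concave over
the draw range; the test suite checks this empirically on a stock scenario
but does not assert it as a theorem.

## The synthetic world

`generator_truth()` fixes the test-suite's stated world: 4 treatments, 12
two-arm studies of 200 patients per arm followed 2 years, baseline ARR drawn
uniformly from 0.4–0.7 relapses per person-year, true log rate ratios
$(-0.77, -0.35, -0.10)$ versus reference (rate ratios ≈ 0.46, 0.70, 0.90,
echoing the spread of effects seen across disease-modifying treatments in
this indication), between-study SD 0.1, per-patient dispersion 1. These are
documented package defaults for testing, not estimates from any trial. Arm
totals are drawn in one negative binomial call using the closure of the NB
family under convolution (n patients at dispersion $\kappa$ give an arm
total at dispersion $n\kappa$).

What the generator does *not* emulate: unequal follow-up within a study,
dropout, baseline covariates and effect modification, reporting biases, and
the efficacy–effectiveness gap between RCT and RWE estimates. A green
parameter-recovery test therefore establishes that the sampler recovers the
stated hierarchical model's truth, not that pooling heterogeneous designs at
face value is unbiased in the field.

The packaged 9-study RWE fixture (`fixture_rwe()`) carries arm-level
subjects, relapses, person-years and descriptive EDSS for seven
disease-modifying treatments. The typeset source table runs digits together
in places; every ambiguous cell was resolved once — keyed on each study's
constant person-years/subject ratio — and the cell-by-cell reading is
documented in `inst/extdata/rwe_studies_provenance.md`, including the merge
of the two glatiramer acetate cohorts of one study into a single arm.

## Numerical choices and degenerate inputs

* Rate-ratio matrices summarise per draw with the posterior **median** by
  default (medians of jointly near-normal log contrasts are near-additive,
  so summarised matrices stay near-consistent); the mean is available but can
  explode for weakly identified networks, since $E[e^X]$ is tail-sensitive.
* `consistency_check()` evaluates every treatment triangle of a summarised
  matrix; it is a diagnostic for matrices assembled from published point
  summaries — per-draw matrices are consistent by construction.
* Empty networks are valid containers (summaries report zero counts,
  connectivity "not applicable"); disconnected networks are accepted at read
  time so partial evidence can be inspected, and refused at fit time naming
  the components.
* Treatment labels are canonicalised by trimming, whitespace-collapsing and
  case-folding; dose variants ("Rebif 22" / "Rebif 44") stay distinct — no
  dose merging.
* The dispersion search in `analyze_trial()` runs on $\log\kappa \in
  [-8, 16]$; under-dispersed samples hit the Poisson-limit boundary
  harmlessly, since $\hat\beta_1$ does not depend on $\kappa$.
* `swap_trial()` inserts the replacement at the replaced study's position, so
  a no-op substitution reproduces the original network — and hence, with the
  same seed, the original posterior — exactly.

## Open design choices made here

* Negative binomial conventions vary across the literature (size/probability
  $(\gamma, p)$ forms, and failure-before-success counts whose roles are
  sometimes stated inverted); this package commits to the mean/overdispersion
  scale everywhere and documents the exact conversion.
* Whether "above/below diagonal" in published rate-ratio matrices means
  row-versus-column or the reverse is fixed here as row-relative-to-column;
  the loop-product check validates this reading's internal consistency.
* Whether published simulations redrew the effect per replicate or plugged
  in a point estimate is not stated; both modes are implemented
  (`effect_mode`).
* The planner derives the control-arm ARR from the network's pooled observed
  rate of the control treatment and the dispersion from the posterior median
  of $\kappa$, both overridable — headline sample sizes always hinge on these
  interim inputs, which published programmes rarely print, so they are user
  inputs here, not constants.

## Known limitations

Rankings and SUCRA-style summaries inherit the face-value pooling assumption;
no risk-of-bias weighting of RWE is provided by design. Multi-arm simulated
trials are out of scope (pairwise designs only). The sampler is tuned for
networks of tens of studies; very large networks would warrant gradient-based
samplers. Recovery of between-study SD $\sigma$ in networks with few studies
is prior-dominated — as it is in any Bayesian NMA.
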