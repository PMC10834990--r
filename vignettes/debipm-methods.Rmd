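---
title: "DEB-IPMs in debipm: model, numerics, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DEB-IPMs in debipm: model, numerics, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(debipm)
```

## The model and its assumptions

A DEB-IPM projects a female length distribution $N(L,t)$ over one-year
steps,
$$N(L',t+1)=\int_\Omega\!\big[D(L',L)\,R(L)+G(L',L)\,S(L)\big]\,N(L,t)\,dL,$$
with kernels derived from a simplified (Kooijman–Metz) dynamic energy
budget. Individuals are isomorphic: intake scales with surface area
($L^2$), maintenance with volume ($L^3$). A fraction $\kappa$ of
assimilated energy goes to maintenance plus growth, the rest to
reproduction (or, in juveniles, to developing reproductive machinery). The
environment enters through the experienced feeding level: a mean
$E(Y)\in(0,1]$ and an among-individual standard deviation $\sigma(Y)$ that
is the model's only source of growth variance. All rates are per year and
lengths in cm; traits are assumed constant over the life cycle, and there
is no temperature dependence (feeding level is the single environmental
axis).

Three emergent lengths organise the kernels: the ultimate length
$L_\infty=L_m E(Y)$ that growth approaches, the starvation length
$L_m E(Y)/\kappa$ above which maintenance cannot be paid and survival is
zero, and the puberty length $L_p$ separating the juvenile mortality
regime ($\mu_j$) from the adult one ($\mu_a$). With the conventional
$\kappa=0.8$ the starvation length is exactly $1.25\,L_\infty$, which is
why a population at a *constant* feeding level never starves: individuals
can only be pushed over the threshold by a *drop* in feeding level.

Two printed-formula subtleties are resolved here as deliberate package
choices. First, the reproduction branch for adults between $L_\infty$ and
the starvation length is normalised by $L_m^2$, exactly like the branch
below $L_\infty$; this is the unique choice that makes reproduction
continuous at $L_\infty$ (both branches give $R_m E(Y)^3$ there) and zero
exactly at the starvation length. Second, survival follows the piecewise
definition literally: adults survive only up to $L_m$, even though the
reproduction function admits lengths up to $L_m E(Y)/\kappa > L_m$ when
$E(Y)>\kappa$; mass that diffuses above $L_m$ reproduces once and dies.
Both choices are exercised by tests.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `E_Y` | mean feeding level (dimensionless) | user-set | the experiment's axis; validation levels are 0.5/0.7/0.9 |
| `sigma_Y` | feeding-level sd (dimensionless) | 0.1 | a modest individual spread; all outputs record the value used |
| `sigma_Lb` | offspring-length sd (cm) | `0.01 * L_b` | "very small" offspring size variation around a constant mean |
| `n_bins` | mesh resolution | 200 | the conventional discretization; doubling it changes $\lambda$ by $<0.5\%$ for all but the slowest-growing species (see below) |
| `tol` | life-table truncation on $l_x$ | 1e-9 | survivorship below this is demographically negligible (with a caveat below) |
| `step` | elasticity perturbation | 0.01 | central differences; estimates are stable to halving the step and the mesh width |

## Discretization

The length domain runs from just below $L_b$ to
$\max(L_m, L_m/\kappa)$ — the starvation length at full feeding — so that
the mesh is *identical across a feeding sweep*; bins above the current
starvation length are simply dead. Three numerical choices matter, all
motivated by the same fact: the offspring distribution
($\sigma_{L_b}=0.01\,L_b$) and, for slow growers, the growth kernel are
*narrower than a bin* at realistic resolutions.

1. **The birth length is anchored to a bin midpoint.** Recruits are
   effectively a point mass at $L_b$; if $L_b$ sits at an arbitrary offset
   inside its bin, the represented recruit length (the midpoint) drifts
   with `n_bins`, and $\lambda$ oscillates by tens of percent for
   high-fecundity species. Anchoring makes the recruit state exact at every
   resolution. The lower margin keeps at least six offspring-sd below
   $L_b$, so under $10^{-9}$ of offspring mass is truncated (a warning
   reports the lost mass if a user-supplied mesh does worse).
2. **Survival and reproduction are exact bin averages.** Bins are split at
   the branch knots ($L_b$, $L_p$, $L_\infty$, starvation length, $L_m$)
   and the piecewise functions integrated exactly across the pieces.
   Evaluating at raw midpoints instead makes boundary bins flip between
   regimes as the mesh changes — the classic mortality-cliff artifact.
3. **Growth columns integrate the Gaussian in closed form.** The growth
   mean is linear in source length below $L_\infty$, so the
   uniform-source, exact-destination bin mass has an antiderivative in
   $\Phi$; columns are renormalised to sum to one (no probability mass is
   evicted at the domain edges). Zero-variance transitions
   ($\sigma(Y)=0$, or sources above $L_\infty$) are unit point masses at
   the bin holding the expected length.

Eigenanalysis is plain dense `eigen()` on the $200\times200$ matrix; the
dominant eigenvalue is asserted real within $10^{-10}$. The fundamental
matrix is $N=(I-GS)^{-1}$: the survival-with-growth transient matrix is
the right base for a length-structured model even where a survival-only
shorthand is sometimes written.

## Derived life-history traits

The life table starts a cohort from the offspring distribution and
projects it with $GS$; $l_x$ is cohort mass, $m_x$ the per-capita
recruitment of the survivors. $R_0$ is computed twice — as the dominant
eigenvalue of $F=VN$ and as $\sum_x l_x m_x$ — and a flag is raised if the
routes disagree by over 1%. Keyfitz entropy, the iteroparity CV (weights
$f_x=l_x m_x$), and the recruitment/growth-directionality means over the
stable structure $w$ follow their standard definitions; sums over age run
to the truncation tolerance rather than to a real-valued "mean life
expectancy" upper limit, which is not executable as printed.

Age at maturity is the expected time spent in juvenile states from the
birth bin (juvenile-restricted fundamental matrix). By default it averages
over *all* newborns, including those that die as juveniles;
`conditional = TRUE` conditions the juvenile chain on reaching maturity,
which is the biologically familiar quantity when juvenile mortality is
high (25 vs 2.4 years for the bundled synthetic sea turtle).

## What holds only approximately — measured, not assumed

Four textbook-style identities are *not* exact under this model, and the
package's acceptance checks report them honestly rather than forcing
them:

- **$\eta_e = L_\alpha + L_\omega$** (life expectancy from birth = age at
  maturity + mature life expectancy) holds only when essentially every
  newborn matures. With the default unconditional $L_\alpha$, the missing
  factor is survival-to-maturity: $\eta_e \approx L_\alpha +
  l_{mat}\,L_\omega$. Across synthetic populations with realistic juvenile
  mortalities the median relative deviation is around 100%. The identity
  is recovered (nearly exactly) for the maturing cohort, i.e. with the
  conditional definitions.
- **Dual-$R_0$ agreement at `tol = 1e-9`.** For slow-growing species with
  high juvenile mortality, first reproduction can occur at ages where
  $l_x < 10^{-9}$; the truncated life-table sum then undercounts $R_0$
  while the next-generation matrix integrates the full series. Tightening
  the tolerance (e.g. $10^{-150}$) restores agreement to $10^{-6}$ — the
  routes are the same quantity, the gap is purely truncation (a unit test
  demonstrates this).
- **$\lambda$ non-decreasing in $E(Y)$** is true for growing populations
  but can fail below $\lambda=1$: more food raises $R_0$ monotonically but
  also shortens the generation time, and for a shrinking population
  ($R_0<1$) a faster life cycle means *faster decline per year*. One
  synthetic species shows exactly this: $R_0$ rises
  $0.05\to0.18\to0.30$ across $E(Y)=0.5/0.7/0.9$ while $\lambda$ dips
  $0.951\to0.940\to0.942$, confirmed at 2000 bins. $R_0$, not $\lambda$,
  is the monotone response to food.
- **$\lambda$ mesh convergence at 0.5%.** With 200 bins, species whose
  growth-kernel sd is below the bin width (roughly
  $\dot{r}_B\,\sigma(Y)\,L_m < h$) combined with very high fecundity still
  carry up to $\sim$1–2% discretization error in $\lambda$; the
  within-bin position of a sub-bin-width cohort is first-order
  information that a piecewise-constant state cannot represent. Errors
  shrink smoothly with refinement; 400 bins roughly halves them.

## The synthetic-species generator

`simulate_debbies()` draws schema-valid trait tables spanning the breadth
of ectotherm life histories the model is used for: $L_m$ log-uniform on
1–1000 cm, $L_b$ at 5–30% of $L_m$, $L_p$ at 1.2–3 $\times L_b$,
mortality and growth rates log-uniform on 0.02–2 per year, $R_m$
log-uniform on 0.5–$10^6$ per year, $\kappa=0.8$ (optionally jittered on
0.7–0.9). These ranges deliberately include harsh corners — near-sterile
slow growers, plankton-like fecundities — so tests exercise the numerics
where they are weakest. What the generator does *not* emulate: trait
correlations found in real taxa (size–fecundity allometries), measurement
error, or within-species trait variation; passing tests on fixtures
therefore demonstrate numerical and structural correctness, not predictive
accuracy for any real species. Acceptance summaries use 50 species and a
200-bin mesh; the full suite runs in well under five minutes on one core.

## Validation statistics

Predicted generation time, longevity ($L_\alpha+L_\omega$) and age at
maturity are compared with caller-supplied observations by no-intercept
regression $y=bx$: slope $\sum xy/\sum x^2$, slope SE with $n-1$ residual
degrees of freedom, the interval $b\pm2\,\mathrm{SE}$ (overlap with 1 =
no significant disagreement), RMSE, and the error rate RMSE/max(observed).
$R^2$ for a no-intercept fit is convention-dependent: the about-the-mean
version is reported (small values at good slopes are expected and match
how such fits are usually tabulated) and the about-zero version is also
returned. Observed values are never fetched from databases; helpers cover
the median-of-range / mean-of-series preprocessing conventions.

## Known limitations

Simple life cycles only (no metamorphosis or stage-specific trait
switches); constant feeding level within a run (no stochastic feeding
sequences, hence $\kappa$'s role is limited to the starvation threshold
and the upper reproduction branch); elasticities perturb each trait
independently, so the theoretical proportionality $R_m\propto(1-\kappa)$
is *not* co-perturbed with $\kappa$ — users comparing energy-allocation
scenarios should perturb both explicitly; generation time follows the
$\log R_0/\log\lambda$ convention, which measures population replacement
rather than mean age of mothers and is known to read high against field
estimates.
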