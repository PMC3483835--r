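---
title: "Modelling protein turnover experiments and their biases"
author: "proteoturn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling protein turnover experiments and their biases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoturn)
```

## The model

The steady-state abundance of a cellular protein is set by the balance of
synthesis and removal. `proteoturn` implements the minimal deterministic
model of that balance:

$$\frac{dP}{dt} = M(t)\,R - P(t)\,(D + V), \qquad
  \frac{dM}{dt} = T(t) - k_M\,M(t),$$

where $M$ is the mRNA copy number per cell, $R$ the translation rate
(proteins per mRNA per hour), $D$ the first-order protein degradation rate
constant, $V = \ln 2 / t_{\mathrm{double}}$ the dilution rate due to cell
growth, and $k_M = \ln 2 / t_{1/2,\mathrm{mRNA}}$ the mRNA decay rate. At
steady state $P_0 = M_0 R / (D + V)$.

Assumptions worth stating explicitly:

* **First-order kinetics everywhere.** Both mRNA and protein decay are
  exponential; there is no saturable (Michaelis–Menten) degradation and no
  stochastic birth–death noise. These are deliberate non-goals: the package
  models population-average immunoblot/MS readouts, not single cells.
* **Dilution acts on protein only.** The user-supplied mRNA half-life is
  interpreted as the *effective* (chemical plus dilution) decay actually
  measured in mRNA decay experiments, so no separate dilution term is added
  to mRNA. Whether an alternative convention (chemical-only mRNA decay plus
  explicit dilution) is preferable is genuinely open; we chose the effective
  convention because it is what a decay time course measures, and document
  it rather than exposing a switch.
* **Accounting is per average cell.** $V$ enters as a first-order loss on
  $P$; setting the cells non-dividing ($V = 0$) recovers a per-culture view.
* **Two distinct half-lives.** `proteinHalfLife` is always the
  degradation-only value $\ln 2 / D$; every summary also reports the
  effective removal half-life $\ln 2 / (D + V)$, because in dividing cells
  the two differ and chase experiments measure the latter.

## Parameters

| Parameter | Units | Default/Typical | Meaning |
|---|---|---|---|
| `mrnaCopies` | copies/cell | 1–100 | steady mRNA level $M_0$ |
| `translationRate` | /mRNA/h | 0.1–10 | proteins made per mRNA per hour |
| `mrnaHalfLife` | h | 0.1–100 | effective mRNA decay half-life |
| `proteinHalfLife` | h | 0.1–100 | degradation-only half-life $\ln2/D$ |
| `doublingTime` | h or non-dividing | 12–72 | sets $V$; `Inf` for quiescent cells |

All conversions between half-lives and rate constants use $\ln 2$; hours
and per-hour units are used throughout because that is how the input
quantities (half-lives, doubling times) are reported in practice.

```{r}
tp <- TurnoverParams(mrnaCopies = 10, translationRate = 2,
                     mrnaHalfLife = 0.5, proteinHalfLife = 2,
                     doublingTime = "non-dividing")
tp
```

## Simulating the standard designs

Perturbations are instantaneous multiplier steps (synthesis, transcription,
degradation, label switch). Drug uptake and washout kinetics are not
modelled; a lagged onset can emulate them. Because the system is linear with
piecewise-constant coefficients, trajectories are propagated
*piecewise-analytically*: within each segment the exact solution

$$P(\tau) = P_s e^{-k\tau} + R'\left[M_\infty\,\varphi_1(k,\tau)
  + (M_s - M_\infty)\,\varphi_2(k_M,k,\tau)\right]$$

is evaluated with the stable kernels $\varphi_1(k,\tau)=(1-e^{-k\tau})/k$
and $\varphi_2(k_M,k,\tau)=(e^{-k_M\tau}-e^{-k\tau})/(k-k_M)$, and states
are chained across breakpoints with exact continuity. There is no step-size
error; the `integrateReference()` numeric integrator (lsoda, relative
tolerance $10^{-10}$, restarted at every breakpoint) exists purely as an
independent oracle, and the test suite holds the two routes together to
within $10^{-6}$ relative on randomized parameter ensembles.

```{r}
sc <- scenarioPreset("chx_chase", samplingTimes = c(0, 1, 2, 4, 8))
simulateScenario(sc, tp)
```

The presets encode the canonical designs: `chx_chase` (total synthesis
block), `tet_off` (transcriptional shutoff), `sirna_knockdown`
(transcription reduced to a residual fraction, with an optional independent
translation multiplier because RNA interference acts through mRNA decay
and/or translational inhibition), `degradation_inhibitor` (degradation
multiplier, with an optional transcriptional side-effect multiplier because
proteasome inhibitors can upregulate transcription) and
`chx_plus_inhibitor`. `pulseChase()` and `silacSwitch()` add the labelled
pool bookkeeping; newly synthesised protein is assumed kinetically
identical to pre-existing protein unless an explicit labelled-pool
degradation multiplier is supplied.

## Numerical choices

* **Degeneracy.** The transcription-shutoff solution
  $[k_P e^{-k_M t} - k_M e^{-k_P t}]/(k_P - k_M)$ cancels catastrophically
  when $k_M \to k_P$. We evaluate it through
  $e^{-k_P t} + k_P \varphi_2(k_M, k_P, t)$ with $\varphi_2$ written via
  `expm1`, which is uniformly stable; only the exactly-equal case switches
  to the limit $(1 + kt)e^{-kt}$. Continuity across the switch is tested at
  $k_M = k_P(1 \pm 10^{-7})$ to within $10^{-6}$.
* **Overflow.** For widely separated rates ($d\,\tau > 500$) the `expm1`
  form would overflow and the plain two-term difference is used instead (no
  cancellation risk there).
* **t50 tie-breaks.** The model-free apparent half-life interpolates the
  replicate means piecewise-linearly after forcing monotonicity with a
  running minimum; a mean exactly at 0.5 resolves to the earliest crossing.
  Non-crossing data raise an explicit error rather than extrapolating.
* **Dense grids.** Bias grids sample each noiseless decline at 2049 points
  over six (mRNA + effective protein) half-lives, which keeps the
  interpolation error of the 50% crossing orders of magnitude below the 2%
  band used in the tests.

## Half-life estimation and its concepts

`fitHalfLife()` offers a log-linear fit, a nonlinear one-exponential fit
(Levenberg–Marquardt, initialised from the log-linear fit; the default,
being robust to mild multiplicative noise) and the model-free
`t50_interpolated`. Every estimate carries a `concept` label —
`degradation_only`, `effective_removal` or `apparent` — because the same
number means different things under different designs: an ideal chase in
dividing cells estimates $\ln 2/(D+V)$, not $\ln 2/D$, and any shutoff
design estimates only an *apparent* half-life. No estimator attempts
two-exponential blind deconvolution of a single protein trace: with
realistic noise the pair $(k_M, k_P)$ is poorly identifiable from protein
data alone, so the package flags the confound instead of fitting it.

The central bias result is quantified by `apparentVsTrueGrid()`: for a
transcriptional shutoff the apparent-over-true ratio tends to 1 only as
$t_{1/2,\mathrm{mRNA}}/t_{1/2,\mathrm{protein}} \to 0$, passes the
bisection-oracle value $\approx 2.42$ at equal half-lives (the root of
$(1+\ln 2\,\tau)e^{-\ln 2\,\tau} = 1/2$), and grows without bound when mRNA
outlives the protein — the decline then measures mRNA decay. For siRNA
knockdown there is an additional, often overlooked bias: the decline
plateaus at the residual fraction $f$, so even with instantaneous mRNA
relaxation the 50%-of-initial reading sits at
$\log_2[(1-f)/(\tfrac12-f)]$ effective half-lives ($\approx 1.41$ at
$f = 0.2$). The grid reports this honestly rather than subtracting the
plateau, because that is what reading a blot does.

## The measurement model

Replicate observations are the true channel value times an independent
lognormal factor with mean exactly 1 and coefficient of variation `cv`
(default 0.10, a typical densitometry spread); signals are normalised to
the mean $t=0$ signal, mirroring percent-of-initial plotting. The detection
floor (default 0, i.e. off) censors on the normalised scale, since it is
specified as a relative signal. What this generator emulates is
multiplicative, unbiased, independent noise; what it does not emulate is
blot saturation, antibody cross-reactivity, correlated replicate effects or
MS missingness. Passing the recovery tests (with cv = 0.10, 3 replicates
and 8 time points over 4 half-lives, the median of 200 seeded fits lands
within 5% of truth and ≥ 90% within 15%) therefore demonstrates estimator
correctness under the stated noise model, not robustness to every real
artefact.

## The appraisal engine

The evidence-grading rules are shipped verbatim in a versioned JSON file
(`inst/extdata/appraisal_rules.json`): ten single-item checklist
conclusions plus twelve tick-combination rules, each with its conclusion
and compulsory controls. Matching is deterministic; a rule matches when
every group of its pattern (with "untagged or tagged" as an alternation)
intersects the declared ticks. Two aspects were genuinely open and are
package decisions:

* **Precedence.** When several combination rules match, the most specific
  (largest pattern) supplies the overall grade and headline conclusion; the
  compulsory controls of *all* matched rules are aggregated, since a
  superset design inherits every caution of its parts. A worst-case-only
  aggregation was rejected because it would let the generic
  single-item grades override the specific rule written for exactly that
  design (e.g. steady-state SILAC under basal conditions grades as good
  evidence even though its components alone are only "partial").
* **Grades for combination rules.** The checklist prints grades only for
  single items; combination rules are graded from their conclusion wording:
  "cannot be attributed (exclusively) to protein degradation" →
  `insufficient`, "may/can be attributed" → `partial`, steady-state
  SILAC → `good_evidence`.

Declaring both "untagged" and "tagged" proceeds with a warning (the rules
are written for "1 or 2"), and tick sets matching no combination rule fall
back to the single-item conclusions, graded worst-case.

## Problem sizes and limitations

The test and acceptance workloads use 100-parameter-set oracle ensembles,
2049-point noiseless grids and 200-seed recovery sweeps; these sizes were
chosen so every property is exercised across the full half-life range
(0.1–100 h, doubling times 12–72 h or non-dividing) while the whole suite
runs in seconds. Known limitations: no mechanistic model of tag effects,
subcellular transport, PTM/PPI-dependent degradation or the
amino-acid-starvation response (the latter is representable only as an
explicit degradation multiplier during a pulse); no stochastic single-cell
simulation; and no attempt to fit $k_M$ and $k_P$ jointly from protein data.
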