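---
title: "Modelling HIF-1 driven glycolysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HIF-1 driven glycolysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model behind **glycohif**, the assumptions it
makes, the parameters that matter, how the synthetic parameter generator
and the calibration work, and the numerical and design choices a
maintainer would want to know about.

## The model

Hypoxia is sensed by cells through the accumulation of the transcription
factor HIF-1, which upregulates glucose transporters and most glycolytic
enzymes. The package represents this axis with a deliberately compact
26-state ODE system:

* **Metabolites (13, mM).** Intracellular glucose, G6P, F6P, F1,6BP,
  DHAP, GA3P, 1,3-BPG, 3PG, 2PG, PEP, pyruvate, acetyl-CoA, lactate. Each
  follows a mass balance: the stoichiometry-weighted sum of producing
  minus consuming reaction rates. Rates are Michaelis–Menten: the
  irreversible form for the canonically irreversible steps (HK, PFK-1,
  PK, PDH, the pentose-phosphate entry, PGCM) and a reversible
  one-substrate/one-product form
  $v = E\,(V_f S/K_s - V_r P/K_p)/(1 + S/K_s + P/K_p)$
  for transport and the bidirectional steps (GLUT, PGI, ALDO, TPI, GAPDH,
  PGK, PGM, ENO, LDH). Aldolase has two products; its rate law uses GA3P
  as the product-side ligand and carries DHAP by stoichiometry only — a
  harmless simplification because the law is operated near equilibrium.
* **Enzyme states (13, relative level, baseline 1).** Twelve levels are
  forced by HIF-1 through mass action, $dE/dt = K_{Eh}\,[\mathrm{HIF}]$,
  so each ramps linearly under step hypoxia — the closed form
  $E(t) = 1 + K_{Eh}\,h\,t$ is used throughout the tests as an oracle.
  The thirteenth state is *active* pyruvate dehydrogenase, interconverted
  by the PDK/PDP phosphorylation cycle; the phosphorylated fraction is
  the derived complement of a conserved total, not a separate state.
  Enzyme levels rescale their reaction's capacity linearly (effective
  $V_{max}$ = reference $V_{max}$ × level). Working in relative levels
  keeps $K_{Eh}$ interpretable without absolute enzyme concentrations.
* **Boundary species (fixed).** Extracellular glucose (5 mM), a glucose
  1-phosphate pool (0.1 mM) feeding glycogenolysis through PGCM, and four
  sinks: the pentose-phosphate drain on G6P, a glycerol-phosphate shunt on
  DHAP, acetyl-CoA consumption (TCA), and first-order lactate export.

Oxygen enters only through a monotone inverse-Hill map
$\mathrm{HIF}(O_2) = H_b + (H_{max}-H_b)\,
 o_{1/2}^{\,n}/(o_{1/2}^{\,n} + O_2^{\,n})$. No mechanistic HIF-1
stabilization/degradation model is included; HIF-1 is an input held
constant during a scenario (step hypoxia).

### Assumptions worth stating

* **Cofactors are folded into $V_{max}$.** ATP/ADP and NAD⁺/NADH are not
  states; redox and energy feedbacks are absent. The practical consequence
  is discussed under *limitations*.
* **All twelve couplings are inductions** (sign +1); the sign field exists
  so a parameter table can encode repression.
* **The glycerol-phosphate shunt.** A drain on DHAP (glycerol-3-phosphate
  / lipid synthesis, active in proliferating cells) is included as a sixth
  boundary. Structurally, an enzyme can only control the lactate output if
  it sits at an entry with a fixed substrate or competes at a branch
  point; without a triose-level branch, GAPDH — mid-chain and
  supply-limited — could exert no flux control at all, contrary to its
  observed role as a strong regulator. The shunt provides that branch:
  induced GAPDH pulls GA3P down, the near-equilibrium TPI transmits the
  pull to DHAP, and flux is diverted from the shunt into the lower
  pathway.

## Parameters

The canonical container is a CSV table with columns
`scope, id, parameter, value, unit, provenance` (units from a fixed
vocabulary; provenance one of `literature`, `database`, `calibrated`).
The tunable quantities that matter most:

| parameter | unit | default | role |
|---|---|---|---|
| `K_Eh` (12×) | level/(µM·min) | calibrated, ~2e-5–6e-3 | HIF-1 induction strength per enzyme; sets both the hypoxic response and the sensitivity-scan classes |
| `H_max` | µM | 1.0 | HIF-1 at 0% O₂; only the products $K_{Eh} H$ are identified, so the µM scale is a convention |
| `o2_half`, `hill_n` | %, – | 1.2, 2.8 | position/steepness of the O₂→HIF-1 curve; chosen so lactate is flat above 6% O₂, rises gently to 1.5% and steeply below |
| `lactate_turnover` | 1/min | 0.6 (calibrated 0.96) | first-order export; sets the lactate residence time and thereby the ~5 min onset delay |
| `pdh_flux` | mM/min | 3.4 | normoxic flux through PDH; the oxidative branch competing with LDH at pyruvate |
| `ppp_flux`, `glycogenolysis_flux`, `shunt_flux` | mM/min | 2.6, 1.2, 1.6 | branch fluxes at G6P and DHAP; the reservoirs from which induced PGI/PFK-1/GAPDH/PGCM divert carbon |
| `k_pdk`, `k_pdp` | 1/min | 1.0, 0.5 | PDK/PDP cycle; fast relative to the 30-min horizon, so active PDH tracks the rising PDK level |
| group thresholds | % | 0.5 / 5 | unchanged vs B vs A classification cutoffs |
| scan thresholds | % | 1 / 5 | insensitive vs slight vs strong classification cutoffs |

Fluxes are large (glucose uptake ≈ 5 mM/min) — a deliberately aggressive
Warburg-type phenotype in which intracellular lactate turns over in about
a minute. This is what lets a 30-minute enzymatic drift of a few percent
move the lactate level visibly within the scenario.

## The synthetic generator

`generate_parameters()` stands in for a published parameter table. It
fixes a physiologically plausible normoxic operating point (metabolite
concentrations in the 0.05–5 mM range), lays out a *consistent flux
distribution* over the network (export and branch fluxes chosen first,
interior fluxes by conservation), and then **solves** each reaction's
limiting rates so the operating point is an exact root of the right-hand
side: for an irreversible step $V_{max} = J\,(K_m+S)/S$; for a reversible
step the forward/reverse pair is solved from the flux and a prescribed
disequilibrium ratio $r = (V_r P/K_p)/(V_f S/K_s)$. The ratio is the key
structural dial: $r \to 1$ puts a step near equilibrium (no flux control
by its own enzyme, strong transmission of downstream pulls), $r \to 0$
makes it effectively irreversible. Half-saturation constants,
concentrations and the $K_{Eh}$ can be jittered or drawn log-uniformly
under a seed to produce random but steady families; the construction is
exact for every draw (residual ~1e-15, checked against a 1e-8 bound).

What the generator does *not* emulate: measurement noise, cofactor pools,
isoenzymes, allosteric regulation (notably F2,6BP activation of PFK-1),
and any cell-line-specific absolute scale. Passing tests therefore show
that the *mechanism* reproduces the targeted behaviours under a plausible
parameterization — not that these are the kinetics of any particular
cell.

## Calibration of the shipped fixture

`calibrate_reference_fixture()` runs a damped Newton iteration (numerical
Jacobian, box constraints, step halving) over eight knobs — the
HK/PGK/GAPDH/PGM/ENO/LDH induction constants, a joint gain on the
PGI/PFK-1/PGCM couplings, and the lactate-export constant — against eight
observables of the severe-hypoxia run: four metabolite drifts forced to
zero (GA3P, 3PG, 2PG, pyruvate), the glucose and 1,3-BPG drops (−6%), the
30-min lactate (6.05 mM) and the onset delay (5 min). The export constant
is included because the delay is governed almost entirely by the lactate
residence time. Four iterations (~35 integrations) converge; a final
verification re-runs the classification and the 36-run sensitivity scan
and stamps the result `conforming`. Calibration is a build-time tool: its
output is versioned and shipped as `inst/extdata/reference_parameters.csv`
(entries it touched carry provenance `calibrated`), and a user-supplied
table is interchangeable with the fixture everywhere.

Infeasible targets are refused rather than chased: a hypoxic lactate below
baseline is impossible with induction-only couplings, and the routine
returns the uncalibrated set flagged non-conforming with the reason.

## Numerical choices

* **Solver contract, not solver name.** Scenarios integrate with a
  stiff-capable adaptive method (`deSolve::lsoda`) at rtol 1e-8 /
  atol 1e-10. The contract is enforced by two oracles in the test suite:
  a fixed-step classical RK4 integration at dt = 0.001 min must agree to
  1e-5 relative on all 26 states at t = 30, and halving the tolerances
  must move lactate by less than 1e-6 mM.
* **Negative-state guard.** States are clipped at zero before rate
  evaluation; solutions are required to stay above −1e-9.
* **Determinism.** Identical inputs give bit-identical trajectories;
  factor-1 rows of the sensitivity scan reuse the reference run, so the
  identity holds exactly. CSV writers use 17-significant-digit round-trip
  formatting, making repeated saves byte-identical.
* **Delay measurement.** The onset delay is the first crossing of a 1%
  relative lactate excess over the baseline trajectory, linearly
  interpolated between grid points (0.1-min default grid).
* **Problem sizes.** The default suite integrates the 26-state system a
  few dozen times over 30 model-minutes (plus one 30 000-step RK4 run);
  the full sensitivity scan is 36 integrations. Everything is sized to
  run comfortably on a single CPU.

## Design decisions on open ground

* **The 26-state partition.** The state list (13 metabolites + 12 coupled
  enzymes + active PDH) was chosen so that the metabolite classification
  (2 group A, 5 group B, 5 unchanged, lactate separate) and the twelve
  named induction constants plus the PDH cycle account exactly for the
  model dimension.
* **Oxygen map form.** Only the *shape* of the O₂→HIF-1 relationship is
  constrained (flat-gentle-steep lactate response); a 4-parameter inverse
  Hill curve is the simplest monotone family with that shape, and the
  type is replaceable by a tabulated curve.
* **GAPDH's sign.** With cofactors excluded, induced GAPDH *increases*
  lactate here (it diverts carbon from the glycerol-phosphate shunt). In
  a fuller model, GAPDH competes with LDH for NAD⁺/NADH, and its
  induction can lower lactate. The package asserts GAPDH's membership in
  the strong class — the magnitude of control — but not the sign of its
  effect.
* **GLUT's small coupling.** GLUT sits at an entry with a fixed substrate
  pool, so any appreciable induction would feed straight into lactate.
  Its insensitivity therefore requires a small `K_Eh` on this timescale —
  consistent with transport not being the controlling step, and with
  control residing downstream (PFK-1) and in glycogenolysis (PGCM).
* **Classification thresholds** (0.5%/5% groups; 1%/5% scan) are exposed
  in the configuration rather than hard-wired, since only the "<5%"
  boundary of group B is externally fixed.

## Known limitations

* No ATP/ADP/NAD⁺/NADH states, no allosteric feedback, no Haldane
  consistency between the forward/reverse limits and thermodynamic
  equilibrium constants.
* HIF-1 forcing is constant per scenario; time-varying oxygen and the
  upstream HIF-1 stabilization network are out of scope.
* Enzyme levels ramp linearly without saturation, so scenarios much
  longer than ~1 h would need induction saturation to stay meaningful.
* The sensitivity scan is local and one-at-a-time; no global (Sobol or
  Morris) analysis is attempted.
* SBML export is validated structurally (well-formed document, consistent
  references, deterministic output); round-tripping through an external
  SBML simulator is not part of the test suite.
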