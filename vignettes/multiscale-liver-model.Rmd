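---
title: "Coupling a genome-scale liver metabolic network to whole-body pharmacokinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling a genome-scale liver metabolic network to whole-body pharmacokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbpkfba)
```

## The modelling problem

Whole-body PBPK models describe drug absorption, distribution, metabolism
and excretion with physiological volumes and flows, but treat the
intracellular space as a well-stirred bag. Genome-scale metabolic networks
(GSMNs) describe that intracellular space mechanistically — every
enzyme-catalysed reaction attributable to the genome, each linked to genes
through Boolean gene–protein–reaction (GPR) rules — but only at steady
state, because kinetic parameterisation of thousands of reactions is not
feasible. This package joins the two: the GSMN serves as the mechanistic
model of liver metabolism inside the PBPK liver compartment, and a small
ODE model of cortisol–GR–PXR signalling sets the CYP3A4 level that drives
phase-I metabolism. The motivating use case is toxic-metabolite kinetics:
a parent drug is converted by CYP3A4 to a reactive metabolite whose
elimination depends on hepatic glutathione (GSH) availability, which the
network computes as a maximal production flux.

## Flux balance analysis

With stoichiometric matrix $S$ ($M$ internal metabolites × $N$ reactions),
steady state means $Sv = 0$; thermodynamic direction and measured uptake
rates enter as bounds $l \le v \le u$; a capability is scored by the LP
$\max z = a^\top v$. Decisions worth recording:

* **Bounds are closed intervals.** Strict inequalities are not
  representable in LP; the conventional closed form is used.
* **External metabolites** (suffix `xt` in the tabular dialect, or SBML
  `boundaryCondition` species) are unbalanced sources/sinks and are
  excluded from the rows of $S$. Exchange reactions are identified
  structurally: their internal-metabolite stoichiometry is all of one sign
  (or empty).
* **Reversibility is encoded purely by bounds** — no reaction splitting.
* **Degenerate optima.** `fba()` returns one optimal vertex. The value
  $z$ is unique; the vertex is not. Callers coupling *fluxes* (rather
  than $z$) into ODEs must check `flux_variability()` /
  `uniqueness_guard()`; the package deliberately couples only the
  objective value into the PBPK layer.
* **Tolerances.** Balance residual and bound feasibility are checked at
  $10^{-6}$ (model flux units); the essentiality influence threshold
  defaults to $10^{-6}$ relative, which separates genuine influence from
  LP round-off while resolving the three decimal places at which knockout
  ratios are conventionally reported.

### The LP engine

No linear-programming package is available in the supported dependency
set, and the two general-purpose simplex routines shipped with other
packages proved unreliable on degenerate knockout systems (crashes and
singular-basis failures). The package therefore carries its own dense
two-phase bounded-variable primal simplex with Bland's smallest-index
rule, which guarantees termination under degeneracy. Fixed variables
(knockouts, `l = u`) are eliminated before pivoting. Networks in scope
are tens of reactions, where dense refactorisation per iteration is cheap;
the design trades speed for exactness and robustness, and genuinely
genome-scale models (thousands of reactions) would need an industrial LP
backend. Correctness is established in the test suite by three
independent routes: brute-force vertex enumeration on every ≤8-reaction
fixture, a second R simplex implementation, and scipy's HiGHS interface.
Unboundedness is detected by re-solving with an enlarged bounding box
(infinite bounds are capped at $10^6$) and comparing optima.

### Sampling

The paper-level method family is Markov-chain Monte Carlo over the flux
polytope. The specific algorithm is unspecified there, so the package
implements hit-and-run: directions are drawn in the null space of $S$
restricted to non-fixed reactions (every sample satisfies the balance
equations to numerical precision), and the feasible chord is sampled
uniformly. Defaults (100 burn-in steps, thinning 10) are modest; the
sampler is exercised on toy networks where symmetry gives an analytic
check (a symmetric two-branch network must split flux evenly on average).

## The PBPK layer

A standard perfusion-limited 14-compartment human: lung in series, the
splanchnic organs (gut, spleen) draining through the liver, arterial and
venous blood pools. Default physiology is a 70-kg adult (cardiac output
390 L/h; organ volumes and flow fractions from standard tables), shipped
as code and fully overridable — the drug parameters are deliberately
generic example values (`fup = 0.3`, `CL_phaseI = 30` L/h, `CLmet = 12`
L/h, MW 151.2 g/mol), not a model of any particular compound. Amounts
are in mg with 1:1 parent→metabolite mass stoichiometry.

Two formula readings were genuinely open:

* **GSH conjugation**: the rate is implemented as
  $SF \cdot CL_{met} \cdot (A_{tox}/V_{li}) \cdot f_{up}$ — intrinsic
  clearance times an unbound liver concentration, the standard well-stirred
  form. The alternative reading $A_{tox}/(V_{li} f_{up})$ is dimensionally
  admissible but pharmacologically non-standard and was rejected.
* **Competitive inhibition**: at substrate concentration equal to
  $K_m$, the inhibited relative rate is $1/(1 + I/(2K_i))$, which
  reproduces the canonical worked example (activity 50% at $I = 2K_i$
  with $K_i = 50$ mM). The inhibitor concentration is taken as *total*
  liver metabolite concentration (flagged: unbound would also be
  defensible), converted to mM via the molar mass.

A deliberately reduced one-compartment parameterisation
(`pbpk_parameters_onecomp()`) shares the dosing, liver biochemistry and
integration machinery but collapses distribution to a single volume; it
exists so the integrator and clearance arithmetic can be verified against
$C_0 e^{-(f_{up} CL/V)t}$ to $10^{-6}$ relative. Mass is reconciled at
every output time (administered = in body + eliminated) to well under
0.5%; output rows coinciding exactly with a bolus time accept either the
pre- or post-event convention.

## The gene-regulation layer

The source model for CYP3A4 regulation is published only in outline, so
this module implements the minimal motif set that the evidence fixes, with
every rate exposed in configuration and an explicit warning that it is a
stand-in, not a reproduction:

* rapid-equilibrium binding with the affinity ladder
  $K_d^{MR} = 1$ nM, $K_d^{GR} = 10$ nM, $K_d^{PXR} = 10$ μM — the same
  cortisol level engages the receptors over four orders of magnitude, so
  stress-level cortisol moves PXR occupancy proportionally far more than
  the nearly saturated GR;
* activated GR represses GR synthesis (negative feedback) and induces PXR
  synthesis (positive feedforward);
* CYP3A4 synthesis is a saturating function of the weighted activated
  PXR + GR drive, with first-order degradation.

Degradation rates (0.1–0.2 h⁻¹) give the hours-scale responses gene
regulation exhibits. Synthesis rates are *back-calculated* so the
unperturbed system rests exactly at the homeostatic reference — 705 nM
total liver CYP3A4, baseline cortisol 100 nM — making homeostatic
neutrality (the regulatory layer does not perturb metabolism at baseline)
a structural property rather than a tuning outcome. The chronic-stress
schedule sustains cortisol at 5× baseline (optionally with decaying
boluses); MR is carried in the ladder for occupancy reporting but has no
downstream edge. Metabolism couples linearly:
`cyp3a4_scale(cyp, 705) = cyp/705`.

## The quasi-steady-state loop

Within each coupling step (default $\Delta t$ = 5 min, short against both
PK and gene-regulation timescales): feedforward (concentrations → bounds),
FBA, feedback ($z$ → scaling factor), ODE advance. Fixed choices:

* **Bounds scale statelessly from the stored wild-type bounds** each step
  — two consecutive 50% activities give 0.5, never 0.25.
* **Only the objective value is fed back.** Feeding example-solution
  fluxes into the ODEs is out of scope: under-constrained networks let the
  LP flip between alternative optima and would make the ODE trajectory
  discontinuous. `uniqueness_guard()` (warning, or error in strict mode)
  covers users who couple additional reactions.
* **Scaling table**: proportional mode $SF = z/z_{ref}$ by default, with
  $z_{ref}$ the wild-type optimum; breakpoint lookup (step or linear) is
  available where a calibrated table exists. When a *perturbed* network
  is simulated, $z_{ref}$ must be supplied from the unperturbed model —
  the default (the supplied network's own optimum) would silently
  re-normalise a knockout to $SF = 1$.
* **GRN and PBPK advance in the same integrator call** in step 4, with
  CYP3A4 read continuously from the GRN state inside the right-hand side;
  the GSH scaling factor is piecewise-constant per step.
* Under feedback-only coupling the bounds never change, so the LP is
  evaluated once and cached — matching the observation that a single
  evaluation suffices when there is no feedforward.
* An infeasible FBA mid-run aborts with the step index and a bounds
  snapshot, rather than continuing from an undefined state.

## Fixtures and what the tests do (and do not) show

All test inputs are generated in code:

* `make_fig1_like()` reproduces the canonical illustration of FBA
  degeneracy *by its stated properties* (its literal stoichiometry is not
  published): three alternative optimal vertices at $z_{max} = 1$, exactly
  one essential reaction, one reversible transport, all bound magnitudes 1.
  The optimal face is a 2-simplex over three alternative routes.
* `make_mini_liver()` is a ~16-reaction hepatic GSH toy: glutamine/
  glutamate supply, cystine reduction consuming NADPH, serine → glycine
  through the folate cycle, GSH synthesis and export (the objective).
  Its ground truth is derived analytically from the flux balance and
  frozen in the tests: the methylene-THF dehydrogenase step is essential
  (it is both the sole THF-recycling entry and the NADPH source), the
  formyl-THF dehydrogenase step is partially limiting
  ($z_{rel} = 0.3$, set by the capacity of the alternative formyl-THF
  drain), and the GSH export cap fixes $z_{max} = 1$.
* `make_parallel_paths()` realises branch redundancy: the two equivalent
  branches are individually non-essential and fully degenerate at the
  optimum. A network in which *no* reaction knockout changes the optimum
  is not constructible in bounded LP — some binding bound always pins
  $z_{max}$ — so redundancy is asserted over the branch reactions.

Problem sizes were chosen so the whole suite (including several
multiscale runs at 6–8 simulated hours and the 3^N vertex enumerations)
completes in a couple of minutes. What passing tests show: correctness of
the LP kernel against independent oracles, analytic limits of the ODE
layers, and the directional responses of the coupled system (knockout and
chronic stress raise the toxic-metabolite peak; neutral links recover the
uncoupled model; halving $\Delta t$ moves the peak by <1%). What they do
not show: quantitative fidelity to any real drug (the example-drug and
regulatory parameters are unpublished placeholders) or performance on
genuinely genome-scale networks.

## A worked run

```{r example, eval = FALSE}
ml <- make_mini_liver()
pb <- pbpk_parameters(dosing = list(route = "iv_bolus", dose = 500, times = 0))
grn <- grn_parameters()
fb <- feedback_link(scaling_table("proportional",
                                  z_ref = fba(ml$network, ml$objective)$z))
m <- multiscale_model(knockout_reactions(ml$network, "FTHLDH"),
                      ml$objective, pb, grn = grn, feedback = fb,
                      config = coupling_config(dt = 5 / 60, mode = "full"))
tr <- simulate_multiscale(m, 24)
max(tr$c_liver_met)   # liver metabolite peak, mg/L
```

## Known limitations

* The simplex is dense and unsuited to networks beyond a few hundred
  reactions; the optional published-model check will be slow there.
* Perfusion-limited tissues only; no gut absorption model beyond a
  first-order depot; no population variability.
* The GRN is a motif-level stand-in; absolute induction magnitudes are
  not calibrated.
* Drug-as-PXR-ligand interactions (induction DDIs) are a documented
  extension point, not implemented.
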