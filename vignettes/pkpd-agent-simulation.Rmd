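---
title: "Coupled pharmacokinetics and pharmacodynamics in an agent-based 2D cell population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled pharmacokinetics and pharmacodynamics in an agent-based 2D cell population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkpdabm)
```

`pkpdabm` simulates how a systemically administered drug reaches and
acts on a 2D population of off-lattice cell agents. The pipeline has
five coupled layers, each updated on its own cadence:

1. **Systemic pharmacokinetics (PK)** — the drug's circulation
   concentration under dosing and elimination,
2. **Extravasation** — vessel-adjacent boundary voxels of the
   microenvironment pinned to the circulation concentration scaled by a
   Biot number,
3. **Microenvironment transport** — diffusion, decay, and cellular
   uptake of the drug on a voxel grid,
4. **Pharmacodynamics (PD)** — per-cell accumulation of an abstract
   damage quantity from internalized drug, with repair,
5. **Phenotype effects** — Hill-type modulation of proliferation,
   apoptosis, necrosis, and motility rates by the damage level.

This vignette documents the model equations, the numerical scheme, the
tunable parameters with their defaults and rationale, what the packaged
sample experiments do and do not emulate, and the design decisions made
where the design was genuinely open.

## Systemic pharmacokinetics

All drugs are given as intravenous boluses: a dose instantaneously
raises the circulation concentration $C$ (arbitrary units) by the
configured amount. Between doses the circulation evolves under one of
three models, selected per substrate:

* **One-compartment** (`"1C"`): linear elimination,
  $\mathrm{d}C/\mathrm{d}t = -\lambda C$.
* **Two-compartment** (`"2C"`): exchange with a peripheral compartment
  $P$ at clearance rates $k_{12}$, $k_{21}$ with central-to-peripheral
  volume ratio $R$,
  $$\mathrm{d}C/\mathrm{d}t = \tfrac{k_{21}}{R}P - k_{12}C - \lambda C,
    \qquad
    \mathrm{d}P/\mathrm{d}t = k_{12}R\,C - k_{21}P.$$
  The volume ratio makes the exchange mass-conserving in concentration
  units: with $\lambda = 0$ the invariant $C + P/R$ is constant, and
  the peripheral compartment produces the characteristic biphasic
  (two-slope) decline of $\log C$ after a bolus.
* **SBML-defined** (`"SBML"`): an arbitrary ODE model supplied as an
  SBML file. The circulation readout is the species named
  `circulation_concentration` when present, otherwise the first listed
  species; a named species is the less ambiguous rule, so it takes
  precedence, with position as the fallback. Dosing must be encoded in
  the file itself as time-triggered events.

Both compartmental models are advanced by their **exact closed forms**:
the one-compartment update is $C \mapsto C e^{-\lambda\,\Delta t}$ and
the two-compartment update applies $\exp(M\Delta t)$ computed by the
$2\times2$ eigendecomposition. The discriminant
$((k_{12}{+}\lambda)-k_{21})^2 + 4k_{12}k_{21}$ is nonnegative for
admissible (nonnegative) rates, so the eigenvalues are always real;
when the discriminant falls below $10^{-12}\,\mathrm{tr}^2$ the
repeated-root limit $e^{\mu t}(I + t(M-\mu I))$ is used instead, which
avoids the catastrophic cancellation of the two-exponential formula.
Zero-rate edge cases are continuous limits of the same formulas. For a
fixed step the propagator matrix is computed once and reused; reuse is
bit-for-bit identical to fresh computation.

The SBML subset supported covers compartments, parameters, species,
rate rules, reactions with arithmetic kinetic laws, and events whose
triggers compare time with a constant. Integration uses `deSolve`'s
adaptive `lsoda` (relative tolerance $10^{-10}$), split exactly at
event trigger times; each event fires at most once. Unsupported
constructs (algebraic or assignment rules, delays, function
definitions) are rejected with an error naming the construct. Model
time is taken to be minutes unless the file declares seconds, which
are converted, because the whole simulator runs in minutes.

## Dosing schedules

Doses are given at a fixed interval until the simulation ends or the
maximum count is reached. The first `number_loading_doses` doses carry
the (typically larger) loading amount. The first dose time is either
fixed or triggered by **confluence**: the summed cell cross-section
area divided by the domain area, monitored on the phenotype time step.
The realized first dose therefore quantizes to the phenotype grid —
the trigger condition is only observable at monitoring times. If
confluence never reaches the threshold, no doses are given and a
warning is logged; this is a legitimate outcome of the experiment, not
an error.

Within one diffusion interval the event order is fixed and pinned by
test: doses due at the interval start are applied to the circulation
first, then the PK model advances, then the Dirichlet boundary is
refreshed, then the field diffuses. "Dose before advance" was chosen
so a dose given at $t$ is already visible in the concentration
reported at $t$.

Missing configuration values follow a warn-and-default policy where a
sensible default exists (PK model two-compartment, Biot number 1,
damage model concentration-based, Hill power 1, first dose at time 0)
and a hard error where none does (dose amount; dose interval with more
than one dose; the three damage-accumulation rates; saturation rate
and EC50 of any active mechanism). All errors are reported together.

## Microenvironment transport

The domain is a 2D rectangle of square voxels (default
$[-400, 400]\,\mu m$ square at $20\,\mu m$, with a nominal $20\,\mu m$
slab thickness so voxel and cell volumes are commensurable). Per
substrate the field obeys
$\partial_t u = D\nabla^2 u - \lambda_d u$ with zero-flux outer edges
except the configured Dirichlet edges, whose voxels are held at (Biot
number $\times$ circulation). The sample experiments activate only the
bottom edge, emulating drug entering from vasculature below the
tissue.

The solver uses dimension splitting — an implicit tridiagonal solve
along x, then along y, then exact exponential decay — which is
unconditionally stable, so the diffusion step can be chosen for
accuracy rather than stability. Dirichlet voxels are written as
identity rows into the tridiagonal systems, so the scheme's fixed
point is the exact discrete steady state of the pinned problem; the
test suite verifies the 1D pinned-boundary steady state against the
analytic $\cosh$ profile to 1% at $10\,\mu m$ resolution, and mass
conservation (no pinning, no decay) to rounding error. The x-then-y
sweep order is fixed; symmetric inputs are regression-tested to stay
symmetric to $10^{-10}$.

**Cellular uptake** treats each cell as a sink in the voxel containing
its center (nearest-voxel semantics: one cell, one voxel). All cells
in a voxel are relaxed implicitly and simultaneously,
$$u' = \frac{u}{1 + \Delta t \sum_i \rho_i V_{c,i}/V_{vox}},$$
and cell $i$ internalizes mass $u' \Delta t\, \rho_i V_{c,i}$. The
simultaneous form is order-independent and conserves mass exactly by
construction: what leaves the voxel is exactly what the cells gain.
Internalized mass is credited as a concentration (mass over cell
volume) under the concentration-based damage model (`AUC`) and as a
raw amount under the amount-based model (`AUC_amount`); with a fixed
cell volume the two differ by that constant factor.

## Pharmacodynamics

Per (substrate, cell type), the internalized drug $A$ and damage $D$
evolve as
$$\mathrm{d}A/\mathrm{d}t = -mA, \qquad
  \mathrm{d}D/\mathrm{d}t = A - r_1 D - r_0,$$
with metabolism rate $m$, linear repair rate $r_1$, constant repair
rate $r_0$, and a unit proportionality of internalized drug into
damage (damage is an abstract quantity, so its scale is set by this
convention). The update over a PD step $t$ is the exact solution
$$A' = A e^{-mt}, \qquad
  D' = D e^{-r_1 t} + A\,t\,e^{-r_1 t}\,\varphi((r_1{-}m)t)
       - r_0\,t\,\varphi(-r_1 t),$$
written through $\varphi(x) = (e^x - 1)/x$ with $\varphi(0) = 1$
(cubic series below $|x| < 10^{-5}$). This makes the limit branches
$r_1 = 0$, $m = 0$, and $m = r_1$ the continuous limits of one
arithmetic path instead of special cases, and the suite verifies
continuity of the repeated-rate branch and equality with an adaptive
ODE oracle to $10^{-8}$.

$D$ is clamped at zero after each update: the constant repair term
would otherwise drive damage negative at low exposure, and damage is
by definition nonnegative. The clamp is applied to the end-of-step
value, which differs from a reflecting boundary by $O(\Delta t^2)$
within a step.

PD is solved on the mechanics time step by default and per-pair
overridable; each pair's step must be a positive multiple of the
mechanics step, and elapsed time is accumulated so pairs fire exactly
when due. Because the update is closed-form, its four constants are
**precomputed** per pair and reused; the cached path routes through
exactly the same arithmetic as the direct path, so the two are
bit-for-bit identical, and caches are invalidated whenever parameters
or the step change. Precomputation can be disabled globally or
per pair for populations with per-cell parameter heterogeneity.

## Effects on phenotype

The damage value (not the instantaneous internalized amount) drives a
Hill-type factor
$$f = 1 + \frac{(f_{sat}-1)(D/EC50)^n}{1 + (D/EC50)^n}, \qquad
  f_{sat} = \frac{\text{saturation rate}}{\text{base rate}},$$
which moves a targeted rate from its base value ($D = 0$, $f = 1$)
toward the saturation rate ($D \to \infty$), passing halfway at
$D = EC50$. Each mechanism of action is off by default; a
configuration flag above 0.5 activates it (flags are stored as
doubles, matching the convention that "true" means a value > 0.5).
Both inhibitory ($f_{sat} < 1$) and stimulatory ($f_{sat} > 1$)
effects are allowed for every mechanism, including motility — the
functional form supports both and neither is privileged.

When several substrates target the same mechanism, their factors
**multiply** for proliferation, apoptosis, and motility speed.
Necrosis is **additive** —
$\text{base} + \sum_s \text{sat}_s (D_s/EC50_s)^n/(1+(D_s/EC50_s)^n)$
— because the base necrosis rate is commonly zero, which makes
$f_{sat}$ undefined; a multiplicative mechanism on a zero base rate is
rejected at configuration load with a pointer to the additive pattern.
Rates are **reset to base before every application**, so applying the
effects twice in a step equals applying them once and drug effects
never stack across steps; this also means a cell whose damage has
fully repaired returns exactly to its base rates.

## Cell agents

Cells are off-lattice discs with a type-defined radius. Division,
apoptosis, and necrosis compete within each phenotype step by sampling
an exponential waiting time per risk from the current rates and taking
the earliest event inside the step — unbiased for small steps, and
exact as a competing-risk resolution. Daughters are placed one radius
from the parent at a uniform angle. Under the concentration-based
damage model, internalized concentration and damage are intensive and
both daughters inherit them; under the amount-based model the pool and
its damage are split equally (conservation of the extensive quantity).
How damage partitions at division is not observable from the model
definition itself; these two rules are the package's own convention
and are pinned by test. Dead cells are removed immediately — death
staging (swelling, lysis) is deliberately out of scope.

Motility is a persistent random walk (heading redrawn with probability
$\Delta t/\tau$ per mechanics step, default persistence $\tau = 5$
min), giving ballistic short-time and diffusive long-time behavior.
Volume exclusion pushes overlapping pairs apart along their axis with
a relaxation displacement capped at half the overlap; neighbor search
uses cell-list binning so mechanics stays near-linear in cell count.

Randomness comes from a single seeded RNG with a fixed draw order
(three uniforms per cell per phenotype step, then division angles),
which makes whole runs bit-reproducible: the determinism contract
(same seed and configuration, byte-identical output files) is part of
the acceptance suite. Per-cell random streams were considered and
rejected: they only buy invariance under population edits, which the
package does not promise, at real bookkeeping cost.

## Sample experiments and the dose sweep

The packaged samples (see `list_samples()`) emulate a reduced-scale
version of a treated 2D tumor: ~200 cells seeded in a 200 um disc
inside an 800 um domain, simulated for 48 h. One sample per mechanism
of action, one two-drug combination (anti-proliferative plus
pro-apoptotic, multiplicative and additive effects exercised
together), one confluence-triggered start, and one SBML-defined PK
run. Two minimal templates (`template_1C`, `template_2C`) are starting
points for new models.

Since the model is specified in arbitrary concentration units, the
sample parameters were chosen once, from timescale reasoning, to put
the experiment in a pharmacologically sensible regime — not fitted to
any dataset:

| Parameter | Value | Rationale |
|---|---|---|
| prolif_rate | 5e-4 /min | ~23 h doubling, a fast-growing cell line |
| apop_rate | 5e-5 /min | long natural lifetime relative to 48 h |
| elimination $\lambda$ | 0.01 /min | ~70 min central half-life |
| $k_{12}, k_{21}$ | 0.005 /min | distribution comparable to elimination |
| dose | 10 a.u. q12h ×3 | repeated bolus course |
| diffusion $D$ | 6e4 um²/min | penetration length $\sqrt{D/\lambda_d}$ ≫ domain |
| decay $\lambda_d$ | 0.01 /min | slow extracellular degradation |
| uptake $\rho$ | 0.02 /min | cells sample their voxel on minutes scale |
| metabolism $m$ | 0.05 /min | ~14 min intracellular half-life |
| repair $r_1$, $r_0$ | 0.005 /min, 1e-4 /min | damage persists ~3 h after exposure |
| EC50 | 100 damage | the damage scale reached under a 10 a.u. dose ($D_{ss} \approx \rho u / (m r_1)$) |
| Hill power | 2 | moderately switch-like response |

The time steps at this scale are diffusion 0.1 min, mechanics 1 min,
phenotype 6 min (the implicit transport solver is unconditionally
stable, so the diffusion step is an accuracy choice); snapshots every
6 h. The dose sweep runs 8 single-bolus doses (a control plus 7
log-spaced over 3.5 orders of magnitude) with 5 replicate seeds each —
a scaled-down version of the 16-dose, 5-replicate design the full
experiment would use — and reports final cell counts relative to the
control mean.

What passing these experiments shows — and does not show. The samples
demonstrate that exposure, damage, and effect propagate through the
stack with the right signs, orderings, and conservation laws
(drug-on < drug-off for anti-proliferation, monotone dose-response,
combination at least as effective as either single agent). They do not
calibrate against any real tumor: there are no cell-cycle phases, no
oxygen or nutrient coupling, no pressure-dependent growth arrest, no
death staging, a 2D slab geometry, and arbitrary concentration units.
Quantitative agreement with any specific biological system is out of
scope by design.

## Known limitations

* 2D domains only; no anisotropic diffusion or explicit vasculature
  beyond Dirichlet edges.
* Compartmental PK is linear; saturable (Michaelis–Menten) elimination
  and oral absorption are not modeled. Nonlinear kinetics can be
  brought in through an SBML-defined model.
* The SBML subset is deliberately narrow (see above); full SBML
  compliance is a non-goal.
* One voxel per cell for exchange; cells near voxel boundaries do not
  spread their uptake over neighboring voxels.
* Effects are deterministic functions of damage; stochastic
  effect-delay models and intracellular signal transduction are not
  implemented.
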