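---
title: "Validating retrosynthesis predictions with constrained reaction-network exploration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating retrosynthesis predictions with constrained reaction-network exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcfill)
```

## The problem

AI retrosynthesis models propose single-step disconnections with a
confidence score derived from a forward-prediction model. For reaction
classes that are rare in the training data the confidence is low even when
the chemistry is sound, and no experimental data exists to settle the
question. First-principles reaction-network exploration can fill that gap:
starting from the suggested precursors, an automated search for elementary
steps either finds the suggested transformation (and its competitors) on the
potential-energy surface or fails to, and the result is folded back into the
confidence score.

qcfill implements that loop as a reusable pipeline with a pluggable energy
backend:

1. **molecule preparation** — SMILES to molecular graphs, total charge from
   the string, spin multiplicity guessed, stereoisomers enumerated,
   sanitized 3D starting structures;
2. **trial generation** — constrained bimolecular elementary-step trials,
   optionally pruned by an atom-to-atom mapping;
3. **step search** — one calculation per trial through the backend contract;
4. **network aggregation** — structures aggregate into compounds by
   connectivity, elementary steps aggregate into reactions by their
   compound-level endpoints;
5. **feasibility** — endothermic rule-out plus a Maxwell–Boltzmann
   kinetic-dominance test, producing a verdict
   (validated / invalidated / inconclusive);
6. **confidence update and budgeting** — a pluggable combiner and a
   core-hour scaling model.

## Models and assumptions

### Energy-only feasibility

All comparisons use total electronic energies: barriers are
$E_\mathrm{TS} - E_\mathrm{react}$ and reaction energies
$E_\mathrm{prod} - E_\mathrm{react}$, with no zero-point, thermal or
entropic corrections. Pre-exponential factors are likewise ignored; the
kinetic argument is purely about the population able to cross a barrier.

### Thermodynamic rule-out

Assuming thermodynamic control, endothermic reactions
($\Delta E > \texttt{endo\_tol}$, default 0 kJ/mol) are removed before any
kinetic comparison. `endo_tol` exists because semiempirical energies carry
tens of kJ/mol of uncertainty; the default keeps the strict sign rule.

### Maxwell–Boltzmann kinetic dominance

The kinetic-energy distribution of the reactants is modeled with the
three-translational-degree-of-freedom Maxwell–Boltzmann form. Its survival
function is the regularized upper incomplete gamma function

$$P(KE > E) \;=\; Q\!\left(\tfrac{3}{2}, \tfrac{E}{RT}\right)
 \;=\; \operatorname{erfc}\sqrt{x} + \tfrac{2}{\sqrt{\pi}}\sqrt{x}\,e^{-x},
 \qquad x = E/RT .$$

The 3-DOF form is a deliberate choice: with it, the window between a
218 kJ/mol target barrier and a 250 kJ/mol competitor barrier at 373.15 K
holds four orders of magnitude more population than the region above
250 kJ/mol, which is the regime in which an energy-only dominance argument
is meaningful:

```{r}
dominance_ratio(218, 250, feasibility_config(temperature = 373.15))
```

A reaction is *validated* when it survives the thermodynamic filter and its
dominance ratio against every surviving, more exothermic competitor is at
least `dominance_threshold` (default 100 — deliberately conservative, three
orders of magnitude below the case above, and configurable). Competitors
*less* exothermic than the target are ignored: under thermodynamic control
they do not threaten the target's product. "100 °C" is interpreted as
exactly 373.15 K.

### Verdict boundaries

A target absent from the network is *invalidated* only when the exploration
executed every generated trial and backend errors stayed within
`error_budget`. If the trial budget ran out, or errors exceeded the budget,
the verdict is *inconclusive*: a failed search does not prove
non-existence, and step searches can fail for technical reasons (an
approximate method struggling with a particular electronic structure) as
easily as for chemical ones. The Friedel–Crafts fixture is built to land on
exactly this boundary.

## Trial generation and mapping-based pruning

Default constraints mirror a narrow production setup: bimolecular
association trials only (no unimolecular rearrangements, no dissociations),
exactly one forming intermolecular bond, every non-hydrogen atom reactive,
2 rotamers and 2 attack points per reactive pair. "Two attack points" is
the minimal reading of "multiple"; both counts are configurable. The trial
count is therefore $|A|\,|B| \times 2 \times 2$ — quadratic in system size,
which is what drives the resource model below.

When an atom-mapped reaction SMILES is available, the mapping is reduced to
three derived sets: *changed atoms* (incident bond multiset differs between
the two sides, hydrogen counts included), *formed bonds* and *broken
bonds*. Pruned enumeration keeps only atoms participating in a **formed**
bond, and only atom pairs that are formed cross-bonds. Changed-atom status
alone is deliberately not sufficient: a leaving group (the iodine of
iodoethane) changes its bonding but is not an attack site for a
bond-*formation* trial, and including it would double the trial count
without adding a coordinate the search could use. On the ether-synthesis
example this prunes 84 trials to 4.

The orchestrator's default, however, is the *full* heavy-atom exploration
(`prune_with_mapping = FALSE`): competing reactions — here, the ring-attack
substitutions — live outside the mapped coordinate, and a dominance verdict
needs them in the network. The pruned mode is the minimal-cost
target-confirmation mode.

## The surrogate backend

The surrogate is a graph-level bond-increment energy model (a fixed table
of bond energies by element pair and bond order) plus an explicit rule
table mapping trials to step outcomes. It is a pure function of the
molecular graph: byte-identical results across runs and platforms. Its job
is to make the *pipeline logic* — enumeration, aggregation, filtering,
verdicts, budgets — fully testable; it is not a model of any real
potential-energy surface, and its increments are a self-consistent toy
parameterization.

Real energies enter through the external adapter contract: XYZ plus charge
and spin multiplicity in, total energy (Hartree, converted at
2625.499639 kJ/mol) out, with the program's own convergence verdict treated
as authoritative and a missing executable reported as an *error* outcome,
never as a silent `no_step`. Transition-state searching is delegated
entirely to the external program. Restricted open-shell treatment and C1
symmetry are launch options of that program, not emulated here.

## The Williamson fixture

The end-to-end fixture encodes the ether-synthesis case study: iodoethane +
phenol → ethoxybenzene + HI, an SN2 displacement in a single elementary
step. Its rule table reproduces the published semiempirical exploration
energetics — target barrier 218 kJ/mol at ΔE −34 kJ/mol, with ortho and
para ring-attack competitors at 250/−48 and 253/−52 — and pads the network
with synthetic decoy reactions so the compound-level statistics match the
published outcome: 38 reactions, 34 of them endothermic, 4 survivors of the
thermodynamic filter. The published tally has four exothermic reactions but
prints energetics for only three, so the fixture's fourth exothermic
reaction (ΔE −10 kJ/mol, barrier 260) is an invention; it is less
exothermic than the target and therefore never enters the dominance
comparison. The decoy products and their positive energies are likewise
placeholders: only the counts and the four exothermic reactions carry
meaning. What passing this fixture shows is that the pipeline's filtering
and dominance logic reproduce the published *argument*; it says nothing
about any real potential-energy surface, which would require the external
backend.

The fixture confidence 0.42 is synthetic (the platform's scores are not
published); with the default combiner weight it updates to 0.71 on
validation.

## Numerical choices

* **3D embedding** is a deterministic seeded layout: atoms start at
  positions drawn from a package-local linear congruential generator (so
  R's global RNG stream is never touched), are refined by BFGS on a spring
  objective (bonded pairs pulled to the sum of covalent radii, nonbonded
  pairs repelled), and finish with a hard clash-repair sweep guaranteeing a
  minimum interatomic distance `d_min` = 0.5 Å — overlapping atoms are the
  classic cause of failing first-principles calculations. Up to 5 re-seeded
  restarts precede a sanitization error. Geometries are *starting guesses*
  for a backend, not equilibrium structures.
* **Compound identity** is an exact canonical graph key: the
  hydrogen-suppressed graph with formal charges and hydrogen counts is
  canonicalized (BLISS, via igraph) with bond orders encoded as colored
  auxiliary vertices. Stereo descriptors and 3D information are ignored —
  compound identity is connectivity-only.
* **Spin multiplicity** uses the electron-parity rule (even count →
  singlet, odd → doublet): the crude-but-fast limit of automatic spin
  guessing, overridable per structure and replaceable by a backend-provided
  guess.
* **Stereoisomer enumeration** assigns both settings of every unspecified
  tetrahedral center and double-bond geometry ($2^k$ graphs), capped at
  $2^6$ per molecule to bound downstream exploration; substituent
  distinguishability is decided by Weisfeiler–Lehman refinement.
  Stereochemistry that SMILES cannot encode at all (axial chirality) is
  out of scope; such inputs should be treated as stereo-incomplete rather
  than guessed.
* **Elementary-step invariants** tolerate 1 kJ/mol of saddle-point
  violation (`E_TS ≥ max(E_react, E_prod) − tol`), absorbing numerical
  noise in backend energies.
* **Trial ordering** is lexicographic on (atom A, atom B, rotamer, attack)
  so logs and serialized trial lists are diffable.
* **Confidence combiner** (pluggable): validated
  $c' = 1-(1-c)(1-w)$, invalidated $c' = c(1-w)$, inconclusive $c' = c$,
  with $w = 0.5$ by default. The platform's own combination rule is not
  published; this default is an artifact decision with the required
  monotonicity properties (validation never lowers, invalidation never
  raises, bounds preserved), and any replacement is held to the same
  contract.

## Resource model

The budget arithmetic rounds the average cost of an elementary-step trial
to 20 CPU seconds (averaged over successful and unsuccessful trials), so a
single core probes $604800/20 = 30240$ trials in one week and 100 cores
about 3 million. Per-trial cost scales quadratically with system size for
semiempirical methods, and the bimolecular trial count is itself quadratic,
so doubling the reactant sizes cuts one week's coverage by
$2^{2+2} = 16$. A DFT backend typically costs another factor of 100–1000
per trial; that range is surfaced as advisory text only, since it is
hardware- and system-dependent.

```{r}
trials_in_budget(budget_model())
coverage_factor(2)
feasibility_report(budget_model(), planned_trials = 84)$advisory
```

## Problem sizes used in the test suite

The suite validates the trial-combinatorics closed form against brute-force
enumeration on 50 random molecule pairs of up to 12 heavy atoms each, runs
the 84-trial Williamson exploration end to end, the 184-trial
Friedel–Crafts decomposition under a 150-trial budget, and three-step
random routes. These sizes exercise every code path at interactive
turnaround; nothing in the logic is size-limited except by the budget
model itself.

## Known limitations

* The surrogate backend cannot discover chemistry that is not in its rule
  table; real validation requires an external electronic-structure program
  (the published reference point is a tight-binding method), and the
  published per-calculation counts and wall times are properties of that
  stack, not reproducible here.
* Byproduct and work-up fields of the route schema are recorded but not
  acted upon; solvation is out of scope.
* Multi-step transformations need a user-supplied decomposition into
  elementary sub-reactions; automated intermediate discovery is not
  attempted.
* Homo-coupling (a molecule reacting with a second copy of itself) is
  generated only when the stoichiometry input requests it.
* Catalyst dimerization is supported only by explicitly adding the dimer as
  an input species (`add_species`); no automatic dimer generation.
* Re-ranking of a multi-step search with the updated confidences is left to
  the consumer; the package emits updated routes and reports.
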