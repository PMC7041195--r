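---
title: "Exact bi-objective knockout design: model, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact bi-objective knockout design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretoKnock)
```

## The modelling frame

A constraint-based metabolic model consists of a stoichiometric matrix
$S \in \mathbb{R}^{m \times n}$ (rows metabolites, columns reactions),
flux bounds $LB_j \le v_j \le UB_j$ in mmol·gDW⁻¹·h⁻¹, and named
objective reactions. Under the steady-state approximation the metabolite
concentrations are constant, so every admissible flux vector satisfies
$Sv = 0$; flux balance analysis (FBA) picks from this cone the vector
maximising one flux, conventionally the biomass pseudo-reaction.
Reversibility is encoded purely by the sign of the lower bound — there is
no separate flag, which keeps every downstream program a statement about
bounds only.

Strain design by reaction deletion attaches a binary $y_j$ to each
*inessential* reaction ($j \in J_I$; the essential set $J_E$ is never
knockable) and couples it to the flux through

$$LB_j\,(1-y_j) \;\le\; v_j \;\le\; UB_j\,(1-y_j),$$

which is exact for any sign pattern of the bounds and needs no big-M
constant. With a cardinality constraint $\sum_j y_j = K$ and the two
maximised objectives (product flux first, biomass second) this is the
bi-objective mixed-binary program solved by `solveBOP()`.

**Assumptions worth keeping in mind.** Steady state; deletion removes a
*reaction*, not a gene (no gene–protein–reaction mapping); objective
reactions must be declared explicitly (`biomassId`, `targetIds`) — we do
not trust a file's default objective silently; and all bounds must be
finite before the mixed-integer programs run (`capInfiniteBounds()`, cap
1000 by convention for genome-scale models).

## Computing the frontier

`solveBOP()` returns the **extreme supported nondominated points**: the
vertices of the concave envelope of the attainable objective region. The
search is the classical dichotomic scheme — solve the two lexicographic
anchor problems, then recursively probe the weight vector normal to each
adjacent pair of points; a new point is accepted when it improves the
chord's weighted score by more than $10^{-6}$, and recursion stops
otherwise. Every scalarised program is re-optimised lexicographically
(first listed objective first) among weighted-score ties, so the reported
point is unique and reproducible regardless of which optimal vertex the
simplex happens to visit.

Two caveats are inherent to the weighted-sum approach rather than to this
implementation. First, mixed-integer bi-objective programs can possess
*unsupported* nondominated points (strictly inside the hull); these are
not on the default path, and `epsilonConstraintFront()` is provided as a
sweep that can reveal them at a chosen grid resolution. Second, the
frontier is a set of points, not the full attainable boundary: a segment
of the boundary attainable by one deletion set is represented by its
endpoints.

The cardinality constraint is an equality by default (`kEquality = TRUE`:
exactly $K$ deletions, matching the program as stated above); a config
flag relaxes it to $\le K$, which avoids padding deletions of zero-flux
reactions when that is preferable.

## Enumerating equivalent deletion sets

Many deletion sets can realise the same frontier point. Fixing the
objectives at their point values and repeatedly solving the feasibility
program, each found support $\bar y$ is excluded with the no-good cut

$$\sum_{j \in \rho(\bar y)} y_j \le K - 1,$$

which also excludes every superset. Termination is by infeasibility —
a certificate that the list is complete (`isExhausted()`); a `maxSets`
budget (default 1000) guards against the $\binom{|J_I|}{K}$ growth, and a
truncated run is reported as such. For $K = 0$ the unique empty set
admits no cut, which is signalled explicitly. Discovery order is
solver-dependent, so results are reported sorted lexicographically on
member ids — outputs are stable even if the search path is not.

In MOMA mode the first solve minimises the Manhattan adjustment
$f(v) = \sum_i |v_i - \bar v_i|$ to a reference flux (default: the
biomass-optimal FBA solution, i.e. the wild type), linearised with
internal variables $z_i \ge \pm (v_i - \bar v_i)$ that never appear in
outputs. The L1 norm (rather than the Euclidean one) keeps the whole
model linear and favours sparse adjustments. Enumeration then adds
$f(v) \le f^* + \text{cap}$ and proceeds with no-good cuts as before, so
only minimally-adjusted equivalent sets are listed.

## Numerical choices

* **Tolerances** (`solverConfig()`): feasibility, integrality, zero-flux
  and objective-match tolerances all default to $10^{-6}$, the usual
  LP-solver feasibility scale. The zero-flux tolerance decides which
  reactions count as active when candidates are derived from a reference
  flux.
* **Fixing objectives** uses two-sided inequalities with
  `objectiveMatchTol` slack; exact equalities on floating MILP objectives
  are brittle, and the window also lets externally supplied points (e.g.
  values read off a published frontier) be used directly.
* **Crisp lexicographic pins.** Inside a single scalarised solve, the
  pins that hold earlier objectives during re-optimisation use a much
  tighter internal tolerance ($10^{-9}$). With a $10^{-6}$ pin the
  optimiser would trade one objective's slack for the other and every
  reported corner would be off by the tolerance.
* **MOMA cap** (`momaCapTol()`, $10\times$ the match tolerance): the
  $\pm 10^{-6}$ objective window perturbs every subset's minimal distance
  by the same order, so accepting sets within exactly $10^{-6}$ of $f^*$
  would sit on the noise boundary. The cap dominates that jitter while
  staying far below genuine distance gaps, which are set by capacity and
  uptake differences (order $10^{-2}$ and larger in realistic data).
* **Incumbent polishing.** When a branch-and-bound relaxation is integral
  within tolerance, the binaries are fixed at their rounded values and
  the LP re-solved before the solution is accepted; otherwise the
  continuous part can retain slack "leaked" through the integrality
  tolerance (a reaction carrying $10^{-6} \cdot UB$ flux while nominally
  deleted). If polishing cannot realise the relaxation bound, the node
  is branched rather than closed — another integer assignment may hide in
  the gap.
* **Degenerate inputs.** An infeasible model and an unbounded objective
  (possible before bound capping) are reported as distinct statuses, not
  errors, by `solveFBA()`; `simpleOptKnock()` flags infeasible sub-LPs
  and continues; an enumeration started at an unattainable point returns
  an empty result with an `inconsistent-point` warning.
* **The LP/MILP core** is a dense bounded-variable two-phase primal
  simplex (Dantzig pricing with a switch to Bland's rule against
  cycling), refactorising the basis at every iteration, plus a
  deterministic depth-first branch-and-bound. It is deliberately simple
  and transparent, and is cross-checked in the test suite against
  `boot::simplex` and `pracma::linprog` on random programs. Dense
  refactorisation scales to the tens-to-hundreds of reactions this
  package targets; genome-scale models parse and run FBA, but the
  mixed-integer layers are not tuned for them.

## Design decisions on open points

* **Candidate rule.** The workflow description ("reactions with nonzero
  reference flux") and the program definition (all of $J_I$) pull in
  different directions. Default: *all inessential reactions* are
  candidates, so the frontier and enumeration defaults agree with the
  program as stated; `restrictToActive = TRUE` switches to the
  active-in-reference rule, and `knockoutCandidates()` implements exactly
  that computation. The pipeline logs which rule was used.
* **Essentiality.** How $J_E$ was constructed is usually a modelling
  choice, so a user-supplied essential set always wins;
  `classifyEssential()` is a convenience that calls a reaction essential
  when its single knockout drops the biomass optimum below a floor
  (default $10^{-3} \times$ wild-type optimum; the comparison is strict,
  so a floor of 0 declares nothing essential).
* **Witness identity.** Among equally optimal deletion sets the witness
  reported with a frontier point is solver-determined; anything
  downstream that needs *all* of them should use the enumeration, which
  is the point of having it.

## What the synthetic fixtures emulate — and what they do not

`makeBranchedNetwork()` builds uptake → hub → parallel-branch networks:
branch 1 feeds biomass, branch 2 the product, extra branches by-products,
optionally with a duplicated product branch (the source of equivalent
deletion sets). `randomToySpec(seed)` draws 2–6 branches, capacities
between 30 % and 120 % of the uptake bound (5–15), and a duplicate
product branch with probability 0.3 — enough to exercise binding
capacities, redundancy and by-product drains, with closed-form expectations
(growth equals uptake when branches are unconstrained; the $K=1$ frontier
contains both single-branch corners). Generation is deterministic per
seed down to the serialised JSON bytes.

These toys are trees with a single substrate and no cofactor coupling, no
reversible internal cycles, and no alternate-optimum degeneracy beyond
the deliberate duplicate branch. Passing the oracle-equivalence suite on
them demonstrates the *exactness machinery* — frontier, cuts, distances —
not predictive fidelity on real metabolism, where model curation,
reversible loops and many-optima degeneracy dominate. The brute-force
oracles (`bruteForceFront()`, `bruteForceEnumerate()`) use only
single-objective LPs over explicit subsets, a code path disjoint from the
branch-and-bound, and include a final concave-envelope reduction so that
both routes compute the same mathematical object (extreme supported
points); the test suite runs them on TOY-B plus twenty seeded networks
with $|J_I| \le 10$ and $K \in \{1, 2\}$, sizes chosen so the whole suite
completes in about a minute on one core.

## Known limitations

* Dense simplex: fine to a few hundred reactions, not genome scale.
* Supported points only on the default frontier path (see above).
* Reaction-level deletions; no gene rules, no thermodynamic constraints.
* FBA references with many alternate optima can shift MOMA distances;
  fixing a reference flux file is the reproducible choice there.
* SBML support is a Level-3 FBC-v2 *reader*; the JSON dialect is the
  canonical write format (schema: `metabolites[{id,name,compartment}]`,
  `reactions[{id,stoich{met:coef},lb,ub}]`, `biomass`, `targets`,
  `essential`; infinite bounds serialise as the strings `"inf"`/`"-inf"`).
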