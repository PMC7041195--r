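# paretoKnock

Exact bi-objective knockout design for constraint-based metabolic models.

## The problem

Metabolic engineers routinely want a microbe to do two competing things at
once — most classically, to grow (so the strain is viable and easy to
ferment) *and* to overproduce a target compound that competes with growth
for the carbon source. Single-objective strain-design tools answer this
with a bi-level program and a fixed biomass floor; `paretoKnock` instead
treats it as a genuine multi-objective problem: it computes the whole
Pareto frontier of (product flux, biomass flux) attainable under a fixed
number *K* of reaction deletions, so the engineer can inspect the entire
trade-off *a posteriori* and pick the operating point to take to the
bench. Because a single frontier point is usually reachable through many
different deletion sets, the package then enumerates **all** equivalent
knockout sets per point — optionally only those whose mutant flux state
stays closest (in Manhattan distance) to the wild-type flux distribution,
the linear-programming flavour of MOMA.

The package is aimed at systems/synthetic biologists working with
small-to-medium constraint-based models, and at methodologists who want an
exact, fully testable reference implementation: every mixed-integer result
is cross-checked in the test suite against independent brute-force LP
oracles.

## The model

With stoichiometric matrix `S` (metabolites × reactions), fluxes `v`
(mmol·gDW⁻¹·h⁻¹), bounds `LB ≤ v ≤ UB`, and deletion binaries
`y_j ∈ {0,1}` over the inessential reaction set `J_I`, the core program is
the bi-objective mixed-binary LP

```
max  (v_prod , v_biomass)
s.t. S v = 0
     LB_j ≤ v_j ≤ UB_j                      j ∈ J_E   (essential)
     LB_j (1-y_j) ≤ v_j ≤ UB_j (1-y_j)      j ∈ J_I   (knockable)
     Σ_j y_j = K ,  y binary
```

Its extreme supported nondominated points are found exactly by dichotomic
(Aneja–Nair–style) weighted-sum search with lexicographic tie-breaking; an
ε-constraint sweep is available as a complement. For each frontier point
`(v*_prod, v*_biomass)` the enumeration fixes both objective values and
repeatedly solves the feasibility program, excluding each solution ȳ with
the no-good cut `Σ_{j∈supp(ȳ)} y_j ≤ K−1` until infeasibility certifies
completeness. In MOMA mode the program first minimises
`f(v) = Σ_i |v_i − v̄_i|` against a reference flux `v̄` (linearised with
`z_i ≥ ±(v_i − v̄_i)`), then only deletion sets attaining the minimal
adjustment `f*` are enumerated.

All programs are solved with a built-in bounded-variable two-phase simplex
(C++) plus branch-and-bound — the package has no external solver
dependency.

## Worked example

The bundled TOY-B network is a 3-metabolite, 6-reaction branched toy:
glucose uptake (≤ 10) feeds a hub that drains into a biomass branch `R1`
and two redundant product branches `R2`/`R2b`.

```r
library(paretoKnock)
toy <- makeBranchedNetwork(toySpecB())

solveFBA(toy)
#> FluxVector [optimal]: objective EX_bio = 10 over 6 reactions

front <- solveBOP(toy, K = 1)
front
#> ParetoFront with 2 nondominated point(s) (K = 1)
#>     EX_prod EX_bio
#> R2b      10      0
#> R2b       0     10

ref <- solveFBA(toy)
enumerateMoma(toy, paretoPoints(front)[[2]], reference = ref)
#> EnumerationResult [moma] at (0, 10): 2 set(s), complete, f* = 0
enumerateMoma(toy, paretoPoints(front)[[1]], reference = ref)
#> EnumerationResult [moma] at (10, 0): 3 set(s), complete, f* = 40
```

Reading: with one deletion the trade-off has two corners. At the growth
corner (product 0, biomass 10) either redundant product branch (`R2` or
`R2b`) may be deleted and the mutant can keep the wild-type flux state
exactly (`f* = 0`). At the no-growth corner (product 10, biomass 0) every
one of the three singleton deletions is equivalent, and any of them forces
the mutant to reroute 40 flux units relative to the wild type.

The same workflow runs from the shell:

```sh
paretoknock pipeline --model toyb.json --k 1 --mode moma --out-dir run/
```

writing `reference_flux.tsv`, `candidates.txt`, `pareto_front.tsv` (+ JSON
twin with witness fluxes), `enumeration.tsv`, a run log and a digest
manifest; reruns are byte-identical.

Genome-scale SBML (Level 3, FBC v2) models load with
`loadModel(path, "sbml", targetIds = ...)`, with bound-override TSVs and
`capInfiniteBounds()` to normalise ±INF bounds; note the built-in dense
simplex targets small and medium networks, not genome scale (see the
vignette).

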