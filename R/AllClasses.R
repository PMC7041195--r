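#' @import methods
#' @importFrom Matrix Matrix sparseMatrix
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' MetabolicModel: a constraint-based metabolic model
#'
#' Container for a stoichiometric model: an m x n sparse stoichiometric
#' matrix S (rows = metabolites, columns = reactions), per-reaction flux
#' bounds in mmol/gDW/h, and named objective reactions.  Reaction
#' reversibility is encoded purely by the bounds (a negative lower bound
#' means the reaction can run backwards); there is no separate flag.
#'
#' @slot metabolites data.frame with columns `id`, `name`, `compartment`.
#' @slot reactions data.frame with columns `id`, `lb`, `ub`, `is_exchange`.
#'   `is_exchange` marks single-metabolite (boundary) reactions and is used
#'   for reporting only, never by the optimisation programs.
#' @slot stoichiometry sparse `dgCMatrix`, metabolites x reactions, with
#'   dimnames set to the respective ids.  Negative coefficients consume.
#' @slot biomassId id of the biomass (growth) pseudo-reaction.
#' @slot targetIds ids of the production objective reaction(s).
#' @slot essentialIds ids of reactions that must never be knocked out
#'   (the essential set J_E); candidates for deletion are drawn from the
#'   complement (the inessential set J_I).
#'
#' @seealso [loadModel()], [makeBranchedNetwork()], [solveFBA()]
#' @export
setClass("MetabolicModel",
  representation(
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "Matrix",
    biomassId = "character",
    targetIds = "character",
    essentialIds = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  if (!all(c("id", "name", "compartment") %in% names(met)))
    msg <- c(msg, "metabolites must have columns id, name, compartment")
  if (!all(c("id", "lb", "ub", "is_exchange") %in% names(rxn)))
    msg <- c(msg, "reactions must have columns id, lb, ub, is_exchange")
  if (length(msg)) return(msg)
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicate reaction ids")
  if (any(!nzchar(met$id))) msg <- c(msg, "empty metabolite id")
  if (any(!nzchar(rxn$id))) msg <- c(msg, "empty reaction id")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    msg <- c(msg, "stoichiometry dimensions do not match metabolites/reactions")
  else {
    if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
      msg <- c(msg, "stoichiometry dimnames must equal metabolite/reaction ids")
    if (any(Matrix::colSums(S != 0) == 0))
      msg <- c(msg, "every reaction needs a nonempty stoichiometry")
  }
  if (any(is.na(rxn$lb)) || any(is.na(rxn$ub)))
    msg <- c(msg, "reaction bounds must not be NA")
  else if (any(rxn$lb > rxn$ub))
    msg <- c(msg, "reaction lower bound exceeds upper bound")
  if (length(object@biomassId) != 1L || !(object@biomassId %in% rxn$id))
    msg <- c(msg, "biomassId must name exactly one existing reaction")
  if (!all(object@targetIds %in% rxn$id))
    msg <- c(msg, "every targetId must name an existing reaction")
  if (length(object@targetIds) < 1L)
    msg <- c(msg, "at least one target reaction is required")
  if (!all(object@essentialIds %in% rxn$id))
    msg <- c(msg, "essentialIds must be a subset of reaction ids")
  if (length(msg)) msg else TRUE
})

#' FluxVector: a steady-state flux assignment
#'
#' One solution of a flux program: a named flux value per reaction plus the
#' objective value reached.  `status` distinguishes an optimal solution from
#' an infeasibility or unboundedness certificate, in which case `values` is
#' empty and `objectiveValue` is `NA`.
#'
#' @slot values named numeric, flux per reaction id (mmol/gDW/h).
#' @slot objectiveValue objective optimum, `NA` unless status is "optimal".
#' @slot objectiveId id of the optimised reaction.
#' @slot status one of "optimal", "infeasible", "unbounded".
#' @export
setClass("FluxVector",
  representation(
    values = "numeric",
    objectiveValue = "numeric",
    objectiveId = "character",
    status = "character"
  ),
  prototype(values = numeric(), objectiveValue = NA_real_,
            objectiveId = NA_character_, status = "optimal")
)

setValidity("FluxVector", function(object) {
  msg <- character()
  if (length(object@status) != 1L ||
      !object@status %in% c("optimal", "infeasible", "unbounded"))
    msg <- c(msg, "status must be optimal, infeasible or unbounded")
  if (object@status == "optimal" && is.null(names(object@values)))
    msg <- c(msg, "optimal flux values must be named by reaction id")
  if (length(object@objectiveValue) != 1L)
    msg <- c(msg, "objectiveValue must have length 1")
  if (length(msg)) msg else TRUE
})

#' SolverConfig: numerical tolerances and reproducibility settings
#'
#' @slot feasibilityTol constraint violation tolerance (default 1e-6).
#' @slot integralityTol tolerance for rounding binary variables (1e-6).
#' @slot zeroFluxTol threshold below which a reference flux counts as zero
#'   when picking knockout candidates (1e-6, the solver feasibility scale).
#' @slot objectiveMatchTol two-sided slack used when fixing an objective to
#'   a previously computed optimum (1e-6).
#' @slot randomSeed integer seed recorded with every run.
#' @slot timeLimit wall-clock limit per program in seconds (advisory).
#' @slot restrictToActive if TRUE, knockout candidates are the inessential
#'   reactions carrying nonzero flux in the reference FBA solution; if
#'   FALSE (default), all inessential reactions are eligible.
#' @slot kEquality if TRUE (default) exactly K reactions are deleted
#'   (sum of binaries equal to K); if FALSE at most K.
#' @export
setClass("SolverConfig",
  representation(
    feasibilityTol = "numeric",
    integralityTol = "numeric",
    zeroFluxTol = "numeric",
    objectiveMatchTol = "numeric",
    randomSeed = "integer",
    timeLimit = "numeric",
    restrictToActive = "logical",
    kEquality = "logical"
  )
)

setValidity("SolverConfig", function(object) {
  tols <- c(object@feasibilityTol, object@integralityTol,
            object@zeroFluxTol, object@objectiveMatchTol)
  if (any(!is.finite(tols)) || any(tols <= 0))
    return("all tolerances must be positive")
  TRUE
})

#' KnockoutSet: a set of K deleted reactions
#'
#' Binary decision y over the inessential reactions with exactly K ones;
#' stored as the sorted ids of the deleted reactions.
#'
#' @slot members sorted character vector of deleted reaction ids.
#' @slot k integer, the knockout budget K.
#' @export
setClass("KnockoutSet",
  representation(members = "character", k = "integer"))

setValidity("KnockoutSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@members)) msg <- c(msg, "duplicate members")
  if (is.unsorted(object@members)) msg <- c(msg, "members must be sorted")
  if (length(msg)) msg else TRUE
})

#' ParetoPoint: one nondominated objective tuple with witnesses
#'
#' @slot objectives named numeric tuple, ordered (target first, biomass
#'   second for the bi-objective program).
#' @slot witnessFlux a [FluxVector-class] attaining the objectives.
#' @slot witnessKnockouts the [KnockoutSet-class] under which it is attained.
#' @export
setClass("ParetoPoint",
  representation(
    objectives = "numeric",
    witnessFlux = "FluxVector",
    witnessKnockouts = "KnockoutSet"
  )
)

#' ParetoFront: the nondominated frontier of a bi-objective knockout program
#'
#' @slot points list of [ParetoPoint-class], sorted by the first objective
#'   in decreasing order (so the second objective is nondecreasing).
#' @slot problemSpec list recording the model digest, K, objective ids and
#'   range restrictions that produced the front.
#' @export
setClass("ParetoFront",
  representation(points = "list", problemSpec = "list"))

setValidity("ParetoFront", function(object) {
  if (!all(vapply(object@points, is, logical(1), class2 = "ParetoPoint")))
    return("points must all be ParetoPoint objects")
  TRUE
})

#' EnumerationResult: all equivalent knockout sets at one frontier point
#'
#' @slot point the [ParetoPoint-class] whose objective values were fixed.
#' @slot knockoutSets list of distinct [KnockoutSet-class] objects, sorted
#'   canonically (lexicographically on member ids).
#' @slot mode "all" (plain enumeration) or "moma" (restricted to sets
#'   admitting a flux state at minimal Manhattan distance to the reference).
#' @slot fStar minimal L1 distance to the reference flux ("moma" mode; `NA`
#'   otherwise).
#' @slot exhausted TRUE iff the final program was proved infeasible, i.e.
#'   the list is complete rather than truncated at `maxSets`.
#' @export
setClass("EnumerationResult",
  representation(
    point = "ParetoPoint",
    knockoutSets = "list",
    mode = "character",
    fStar = "numeric",
    exhausted = "logical"
  )
)

#' ToySpec: recipe for a deterministic branched toy network
#'
#' Describes an uptake -> hub -> n parallel branch network in which the
#' first branch feeds biomass, the second feeds the product and any further
#' branches feed by-products.  Used to build fixtures with closed-form
#' Pareto fronts.
#'
#' @slot nBranches integer >= 2.
#' @slot branchCapacities upper flux bound per branch reaction.
#' @slot uptakeBound upper bound of the uptake exchange.
#' @slot duplicateProduct if TRUE the product branch is duplicated
#'   (a second, redundant reaction into the same product metabolite).
#' @slot seed integer recorded for provenance.
#' @export
setClass("ToySpec",
  representation(
    nBranches = "integer",
    branchCapacities = "numeric",
    uptakeBound = "numeric",
    duplicateProduct = "logical",
    seed = "integer"
  )
)

setValidity("ToySpec", function(object) {
  msg <- character()
  if (object@nBranches < 2L) msg <- c(msg, "nBranches must be >= 2")
  if (length(object@branchCapacities) != object@nBranches)
    msg <- c(msg, "need one capacity per branch")
  if (any(object@branchCapacities <= 0)) msg <- c(msg, "capacities must be > 0")
  if (object@uptakeBound <= 0) msg <- c(msg, "uptakeBound must be > 0")
  if (length(msg)) msg else TRUE
})
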