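#' @include AllClasses.R
NULL

#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))
#' @export
setGeneric("stoichMatrix", function(x) standardGeneric("stoichMatrix"))
#' @export
setGeneric("reactionBounds", function(x) standardGeneric("reactionBounds"))
#' @export
setGeneric("biomassId", function(x) standardGeneric("biomassId"))
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))
#' @export
setGeneric("essentialIds", function(x) standardGeneric("essentialIds"))
#' @export
setGeneric("essentialIds<-", function(x, value) standardGeneric("essentialIds<-"))

#' @export
setGeneric("fluxValues", function(x) standardGeneric("fluxValues"))
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))
#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))

#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @export
setGeneric("knockoutSize", function(x) standardGeneric("knockoutSize"))

#' @export
setGeneric("objectives", function(x) standardGeneric("objectives"))
#' @export
setGeneric("witnessFlux", function(x) standardGeneric("witnessFlux"))
#' @export
setGeneric("witnessKnockouts", function(x) standardGeneric("witnessKnockouts"))

#' @export
setGeneric("paretoPoints", function(x) standardGeneric("paretoPoints"))
#' @export
setGeneric("objectiveMatrix", function(x) standardGeneric("objectiveMatrix"))

#' @export
setGeneric("knockoutSets", function(x) standardGeneric("knockoutSets"))
#' @export
setGeneric("isExhausted", function(x) standardGeneric("isExhausted"))
#' @export
setGeneric("fStar", function(x) standardGeneric("fStar"))

#' @export
setGeneric("solveFBA", function(model, objectiveId = biomassId(model),
                                sense = c("max", "min"),
                                config = solverConfig())
  standardGeneric("solveFBA"))

#' @export
setGeneric("simulateKnockout",
  function(model, knockouts, objectiveId = biomassId(model),
           sense = c("max", "min"), config = solverConfig())
  standardGeneric("simulateKnockout"))

#' @export
setGeneric("knockoutCandidates",
  function(model, reference, config = solverConfig())
  standardGeneric("knockoutCandidates"))

#' @export
setGeneric("classifyEssential",
  function(model, biomassFloor = NULL, config = solverConfig())
  standardGeneric("classifyEssential"))

#' @export
setGeneric("simpleOptKnock",
  function(model, targetId = targetIds(model)[1], config = solverConfig())
  standardGeneric("simpleOptKnock"))

#' @export
setGeneric("weightedSumSolve",
  function(model, K, weights, objectiveIds = NULL, candidates = NULL,
           rangeLimits = NULL, config = solverConfig())
  standardGeneric("weightedSumSolve"))

#' @export
setGeneric("solveBOP",
  function(model, K, targetId = NULL, candidates = NULL, rangeLimits = NULL,
           config = solverConfig())
  standardGeneric("solveBOP"))

#' @export
setGeneric("epsilonConstraintFront",
  function(model, K, gridStep, targetId = NULL, candidates = NULL,
           rangeLimits = NULL, config = solverConfig())
  standardGeneric("epsilonConstraintFront"))

#' @export
setGeneric("enumerateEquivalent",
  function(model, point, K = knockoutSize(witnessKnockouts(point)),
           candidates = NULL, config = solverConfig(), maxSets = 1000L)
  standardGeneric("enumerateEquivalent"))

#' @export
setGeneric("momaDistanceLP",
  function(model, point, K = knockoutSize(witnessKnockouts(point)),
           reference = NULL, candidates = NULL, config = solverConfig())
  standardGeneric("momaDistanceLP"))

#' @export
setGeneric("enumerateMoma",
  function(model, point, K = knockoutSize(witnessKnockouts(point)),
           reference = NULL, candidates = NULL, config = solverConfig(),
           maxSets = 1000L)
  standardGeneric("enumerateMoma"))

#' @export
setGeneric("capInfiniteBounds", function(model, cap = 1000)
  standardGeneric("capInfiniteBounds"))

#' @export
setGeneric("applyBoundOverrides", function(model, overrides)
  standardGeneric("applyBoundOverrides"))

#' @export
setGeneric("makeBranchedNetwork", function(spec)
  standardGeneric("makeBranchedNetwork"))
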