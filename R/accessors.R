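#' @include AllGenerics.R
NULL

#' Accessors for MetabolicModel
#'
#' @param x a [MetabolicModel-class].
#' @return `reactionIds`/`metaboliteIds` return character vectors in model
#'   (file) order; `stoichMatrix` the sparse m x n stoichiometric matrix;
#'   `reactionBounds` a data.frame with columns `id`, `lb`, `ub`;
#'   `biomassId`, `targetIds`, `essentialIds` the respective reaction ids.
#' @aliases reactionIds metaboliteIds stoichMatrix reactionBounds biomassId
#'   targetIds essentialIds essentialIds<-
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setMethod("reactionIds", "MetabolicModel", function(x) x@reactions$id)

#' @rdname model-accessors
#' @export
setMethod("metaboliteIds", "MetabolicModel", function(x) x@metabolites$id)

#' @rdname model-accessors
#' @export
setMethod("stoichMatrix", "MetabolicModel", function(x) x@stoichiometry)

#' @rdname model-accessors
#' @export
setMethod("reactionBounds", "MetabolicModel",
          function(x) x@reactions[, c("id", "lb", "ub")])

#' @rdname model-accessors
#' @export
setMethod("biomassId", "MetabolicModel", function(x) x@biomassId)

#' @rdname model-accessors
#' @export
setMethod("targetIds", "MetabolicModel", function(x) x@targetIds)

#' @rdname model-accessors
#' @export
setMethod("essentialIds", "MetabolicModel", function(x) x@essentialIds)

#' @rdname model-accessors
#' @param value replacement character vector of reaction ids.
#' @export
setReplaceMethod("essentialIds", "MetabolicModel", function(x, value) {
  x@essentialIds <- as.character(value)
  validObject(x)
  x
})

#' Accessors for FluxVector
#'
#' @param x a [FluxVector-class].
#' @aliases fluxValues objectiveValue solverStatus
#' @name flux-accessors
NULL

#' @rdname flux-accessors
#' @export
setMethod("fluxValues", "FluxVector", function(x) x@values)

#' @rdname flux-accessors
#' @export
setMethod("objectiveValue", "FluxVector", function(x) x@objectiveValue)

#' @rdname flux-accessors
#' @export
setMethod("solverStatus", "FluxVector", function(x) x@status)

#' Accessors for KnockoutSet, ParetoPoint, ParetoFront, EnumerationResult
#'
#' @param x the object.
#' @aliases members knockoutSize objectives witnessFlux witnessKnockouts
#'   paretoPoints objectiveMatrix knockoutSets isExhausted fStar
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
setMethod("members", "KnockoutSet", function(x) x@members)

#' @rdname result-accessors
#' @export
setMethod("knockoutSize", "KnockoutSet", function(x) x@k)

#' @rdname result-accessors
#' @export
setMethod("objectives", "ParetoPoint", function(x) x@objectives)

#' @rdname result-accessors
#' @export
setMethod("witnessFlux", "ParetoPoint", function(x) x@witnessFlux)

#' @rdname result-accessors
#' @export
setMethod("witnessKnockouts", "ParetoPoint", function(x) x@witnessKnockouts)

#' @rdname result-accessors
#' @export
setMethod("paretoPoints", "ParetoFront", function(x) x@points)

#' @rdname result-accessors
#' @export
setMethod("objectiveMatrix", "ParetoFront", function(x) {
  if (!length(x@points)) return(matrix(numeric(), 0, 0))
  do.call(rbind, lapply(x@points, objectives))
})

#' @rdname result-accessors
#' @export
setMethod("knockoutSets", "EnumerationResult", function(x) x@knockoutSets)

#' @rdname result-accessors
#' @export
setMethod("isExhausted", "EnumerationResult", function(x) x@exhausted)

#' @rdname result-accessors
#' @export
setMethod("fStar", "EnumerationResult", function(x) x@fStar)

#' @rdname result-accessors
#' @export
setMethod("objectives", "ParetoFront", function(x) objectiveMatrix(x))

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", nrow(object@metabolites), "metabolites x",
      nrow(object@reactions), "reactions\n")
  cat("  biomass:", object@biomassId,
      "| targets:", paste(object@targetIds, collapse = ", "), "\n")
  cat("  essential (never knockable):", length(object@essentialIds),
      "| exchanges:", sum(object@reactions$is_exchange), "\n")
})

setMethod("show", "FluxVector", function(object) {
  cat("FluxVector [", object@status, "]", sep = "")
  if (object@status == "optimal") {
    cat(": objective", object@objectiveId, "=",
        format(object@objectiveValue), "over", length(object@values),
        "reactions")
  }
  cat("\n")
})

setMethod("show", "KnockoutSet", function(object) {
  cat("KnockoutSet (K=", object@k, "): {",
      paste(object@members, collapse = ", "), "}\n", sep = "")
})

setMethod("show", "ParetoPoint", function(object) {
  cat("ParetoPoint (", paste(format(object@objectives), collapse = ", "),
      ") via {", paste(object@witnessKnockouts@members, collapse = ", "),
      "}\n", sep = "")
})

setMethod("show", "ParetoFront", function(object) {
  cat("ParetoFront with ", length(object@points),
      " nondominated point(s) (K = ", object@problemSpec$K, ")\n",
      sep = "")
  if (length(object@points)) {
    m <- objectiveMatrix(object)
    rownames(m) <- vapply(object@points, function(p)
      paste(p@witnessKnockouts@members, collapse = ";"), character(1))
    print(round(m, 6))
  }
})

setMethod("show", "EnumerationResult", function(object) {
  cat("EnumerationResult [", object@mode, "] at (",
      paste(format(round(object@point@objectives, 6), trim = TRUE),
            collapse = ", "),
      "): ", length(object@knockoutSets), " set(s), ",
      if (object@exhausted) "complete" else "truncated", sep = "")
  if (object@mode == "moma") cat(", f* =", format(object@fStar))
  cat("\n")
})

setMethod("show", "SolverConfig", function(object) {
  cat("SolverConfig: feasibilityTol", object@feasibilityTol,
      "| zeroFluxTol", object@zeroFluxTol,
      "| objectiveMatchTol", object@objectiveMatchTol, "\n")
  cat("  K-constraint:", if (object@kEquality) "equality (= K)" else
    "relaxed (<= K)",
      "| candidates:", if (object@restrictToActive)
        "active-in-reference" else "all inessential", "\n")
})

setMethod("show", "ToySpec", function(object) {
  cat("ToySpec:", object@nBranches, "branches, uptake",
      object@uptakeBound,
      if (object@duplicateProduct) "(duplicated product branch)" else "",
      "\n")
})
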