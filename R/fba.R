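#' @include model-core.R
NULL

## Base flux LP of a model: steady state S v = 0, LB <= v <= UB.
#' @noRd
.fluxLP <- function(model) {
  S <- as.matrix(model@stoichiometry)
  n <- ncol(S)
  list(A = S,
       b = numeric(nrow(S)),
       sense = rep("=", nrow(S)),
       obj = numeric(n),
       lb = model@reactions$lb,
       ub = model@reactions$ub,
       vars = model@reactions$id)
}

.asFlux <- function(res, objectiveId, rxnIds) {
  if (res$status != "optimal") {
    return(methods::new("FluxVector", values = numeric(),
                        objectiveValue = NA_real_,
                        objectiveId = objectiveId, status = res$status))
  }
  v <- res$x[rxnIds]
  methods::new("FluxVector", values = v, objectiveValue = res$objval,
               objectiveId = objectiveId, status = "optimal")
}

#' Flux balance analysis
#'
#' Solves the FBA linear program: optimise the flux of one reaction subject
#' to steady-state mass balance `S v = 0` and the flux bounds.  Returns the
#' optimal basic solution found by the simplex; models with alternate
#' optima may admit other flux vectors with the same objective value.
#'
#' @param model a [MetabolicModel-class].
#' @param objectiveId reaction to optimise (default: the biomass reaction).
#' @param sense `"max"` (default) or `"min"`.
#' @param config a [SolverConfig-class].
#' @return a [FluxVector-class]; its `status` slot is `"infeasible"` or
#'   `"unbounded"` (possible before infinite bounds are capped) when no
#'   optimum exists.
#' @examples
#' toy <- makeBranchedNetwork(toySpecB())
#' solveFBA(toy)
#' @export
setMethod("solveFBA", "MetabolicModel",
  function(model, objectiveId = biomassId(model), sense = c("max", "min"),
           config = solverConfig()) {
    sense <- match.arg(sense)
    if (!objectiveId %in% model@reactions$id)
      stop("objective reaction '", objectiveId, "' is not in the model")
    lp <- .fluxLP(model)
    lp$obj[match(objectiveId, lp$vars)] <- 1
    res <- .solveLP(lp, maximize = sense == "max")
    .asFlux(res, objectiveId, lp$vars)
  })

#' Simulate reaction knockouts
#'
#' Fixes the upper and lower flux bounds of each knocked-out reaction to
#' zero and solves the resulting FBA program.
#'
#' @inheritParams solveFBA
#' @param knockouts character vector of reaction ids (may be empty, in
#'   which case this is exactly [solveFBA()]).
#' @return a [FluxVector-class].
#' @export
setMethod("simulateKnockout", "MetabolicModel",
  function(model, knockouts, objectiveId = biomassId(model),
           sense = c("max", "min"), config = solverConfig()) {
    sense <- match.arg(sense)
    solveFBA(knockoutModel(model, knockouts), objectiveId, sense, config)
  })

#' Knockout candidates from a reference flux
#'
#' The inessential reactions that carry nonzero flux in the reference
#' solution: `{j : |v_j| > zeroFluxTol}` minus the essential set.  This
#' defines the candidate set J_I handed to the mixed-integer programs.
#'
#' @param model a [MetabolicModel-class].
#' @param reference a feasible [FluxVector-class] for `model`, typically
#'   the wild-type FBA optimum.
#' @param config a [SolverConfig-class]; `zeroFluxTol` sets the activity
#'   threshold.
#' @return character vector of reaction ids, in model order.
#' @export
setMethod("knockoutCandidates", "MetabolicModel",
  function(model, reference, config = solverConfig()) {
    v <- fluxValues(reference)
    active <- names(v)[abs(v) > config@zeroFluxTol]
    ids <- model@reactions$id
    ids[ids %in% setdiff(active, model@essentialIds)]
  })

#' Classify essential reactions by single-knockout growth
#'
#' Convenience helper: a reaction is called essential when deleting it
#' drops the biomass optimum below `biomassFloor`.  The comparison is
#' strict, so a floor of 0 declares nothing essential (a knockout that
#' merely zeroes growth does not make the program infeasible).  A
#' user-supplied essential set on the model always takes precedence in the
#' workflow; this helper just proposes one.
#'
#' @param model a [MetabolicModel-class].
#' @param biomassFloor growth threshold; default `1e-3` times the wild-type
#'   biomass optimum.
#' @param config a [SolverConfig-class].
#' @return character vector of reaction ids classified essential.
#' @export
setMethod("classifyEssential", "MetabolicModel",
  function(model, biomassFloor = NULL, config = solverConfig()) {
    if (is.null(biomassFloor)) {
      wt <- solveFBA(model, config = config)
      if (solverStatus(wt) != "optimal")
        stop("wild-type FBA has no optimum; cannot derive a biomass floor")
      biomassFloor <- 1e-3 * objectiveValue(wt)
    }
    stopifnot(biomassFloor >= 0)
    ess <- vapply(model@reactions$id, function(j) {
      f <- simulateKnockout(model, j, config = config)
      if (solverStatus(f) != "optimal") return(TRUE)
      objectiveValue(f) < biomassFloor
    }, logical(1))
    model@reactions$id[ess]
  })

#' SimpleOptKnock single-deletion screen
#'
#' For every reaction j: knock j out, maximise biomass, fix biomass at that
#' optimum (within `objectiveMatchTol` to avoid an empty interior), then
#' maximise and minimise the target flux.  Reports one record per reaction.
#' Sub-programs that are infeasible are flagged and the scan continues.
#'
#' @param model a [MetabolicModel-class].
#' @param targetId the product reaction (default: first target of the
#'   model).
#' @param config a [SolverConfig-class].
#' @return data.frame with columns `reaction_id`, `biomass_max`,
#'   `target_max`, `target_min`, `feasible`.
#' @export
setMethod("simpleOptKnock", "MetabolicModel",
  function(model, targetId = targetIds(model)[1], config = solverConfig()) {
    tol <- config@objectiveMatchTol
    rows <- lapply(model@reactions$id, function(j) {
      ko <- knockoutModel(model, j)
      bio <- solveFBA(ko, biomassId(model), "max", config)
      if (solverStatus(bio) != "optimal")
        return(data.frame(reaction_id = j, biomass_max = NA_real_,
                          target_max = NA_real_, target_min = NA_real_,
                          feasible = FALSE))
      b <- objectiveValue(bio)
      fixed <- applyBoundOverrides(ko, list(
        boundOverride(biomassId(model), "lower", b - tol),
        boundOverride(biomassId(model), "upper", b + tol)))
      tmax <- solveFBA(fixed, targetId, "max", config)
      tmin <- solveFBA(fixed, targetId, "min", config)
      data.frame(reaction_id = j, biomass_max = b,
                 target_max = objectiveValue(tmax),
                 target_min = objectiveValue(tmin),
                 feasible = TRUE)
    })
    do.call(rbind, rows)
  })

#' Check a flux vector against a model
#'
#' Asserts steady state (`|S v| <= tol` per metabolite) and bound
#' satisfaction (`LB - tol <= v <= UB + tol`).
#'
#' @param model a [MetabolicModel-class].
#' @param flux a [FluxVector-class] (or named numeric).
#' @param tol tolerance, default the feasibility tolerance 1e-6.
#' @return TRUE invisibly, or an error describing the first violation.
#' @export
validateFlux <- function(model, flux, tol = 1e-6) {
  v <- if (methods::is(flux, "FluxVector")) fluxValues(flux) else flux
  v <- v[model@reactions$id]
  if (anyNA(v)) stop("flux vector does not cover all reactions")
  resid <- as.numeric(model@stoichiometry %*% v)
  if (any(abs(resid) > tol))
    stop("mass balance violated at metabolite ",
         model@metabolites$id[which.max(abs(resid))],
         " (residual ", max(abs(resid)), ")")
  if (any(v < model@reactions$lb - tol) || any(v > model@reactions$ub + tol))
    stop("flux bound violated at reaction ",
         model@reactions$id[which.max(pmax(model@reactions$lb - v,
                                           v - model@reactions$ub))])
  invisible(TRUE)
}

#' Write a flux vector as a 2-column TSV
#'
#' @param flux a [FluxVector-class].
#' @param path output file; columns `reaction_id`, `flux`.
#' @return `path`, invisibly.
#' @export
writeFluxTSV <- function(flux, path) {
  v <- fluxValues(flux)
  utils::write.table(
    data.frame(reaction_id = names(v), flux = as.numeric(v)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flux vector from a 2-column TSV
#'
#' @param path file with columns `reaction_id`, `flux`.
#' @return a [FluxVector-class] (status `"optimal"`, objective `NA`).
#' @export
readFluxTSV <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  methods::new("FluxVector",
               values = stats::setNames(as.numeric(tab$flux),
                                        tab$reaction_id),
               objectiveValue = NA_real_, objectiveId = NA_character_,
               status = "optimal")
}

#' Write a SimpleOptKnock table as TSV
#'
#' @param tab the data.frame from [simpleOptKnock()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSimpleOptKnockTSV <- function(tab, path) {
  utils::write.table(tab[, c("reaction_id", "biomass_max", "target_max",
                             "target_min")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
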