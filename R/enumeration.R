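#' @include pareto.R
NULL

#' No-good cut excluding a found knockout set
#'
#' Builds the linear constraint `sum_{j in found} y_j <= K - 1`, which
#' excludes the found set and every superset of it from further search.
#' With K = 0 the unique empty set admits no such cut (it would read
#' `0 <= -1`), which is signalled explicitly: enumeration of the empty
#' deletion set ends after its first solution.
#'
#' @param found a [KnockoutSet-class] (or character vector of reaction
#'   ids) with exactly K members.
#' @return an object of class `"noGoodCut"`: list with elements `ids`
#'   (the members), `rhs` (`K - 1`) and `sense` (`"<="`).
#' @examples
#' noGoodCut(knockoutSet("R2"))       # y_R2 <= 0
#' noGoodCut(knockoutSet(c("R1", "R2")))  # y_R1 + y_R2 <= 1
#' @export
noGoodCut <- function(found) {
  ids <- if (methods::is(found, "KnockoutSet")) members(found)
         else sort(as.character(found))
  K <- length(ids)
  if (K == 0L)
    stop("no-good cut undefined for the empty set (K = 0): the unique ",
         "empty deletion set cannot be excluded")
  structure(list(ids = ids, rhs = K - 1L, sense = "<="),
            class = "noGoodCut")
}

#' @noRd
.applyCut <- function(lp, cut) {
  coef <- stats::setNames(rep(1, length(cut$ids)), paste0("y:", cut$ids))
  .lpAddRow(lp, coef, cut$sense, cut$rhs)
}

## Rows fixing the frontier objective values: two-sided inequalities with
## objectiveMatchTol slack (exact equality on floating MILP objectives is
## brittle).
#' @noRd
.fixObjectiveRows <- function(lp, objectives, tol) {
  for (id in names(objectives)) {
    var <- stats::setNames(1, paste0("v:", id))
    lp <- .lpAddRow(lp, var, ">=", objectives[[id]] - tol)
    lp <- .lpAddRow(lp, var, "<=", objectives[[id]] + tol)
  }
  lp
}

#' @noRd
.enumLoop <- function(lp, built, K, maxSets, firstCut = NULL) {
  sets <- list()
  exhausted <- FALSE
  if (!is.null(firstCut)) {
    sets <- list(firstCut)
    if (K == 0L) {
      ## the empty set is the unique set; no cut can exclude it
      return(list(sets = sets, exhausted = TRUE))
    }
    lp <- .applyCut(lp, noGoodCut(firstCut))
  }
  repeat {
    if (length(sets) >= maxSets) break
    res <- .solveMILP(lp, built$intIdx, maximize = FALSE,
                      firstFeasible = TRUE)
    if (res$status != "optimal") {
      exhausted <- TRUE
      break
    }
    found <- knockoutSet(built$candidates[res$x[built$yvars] > 0.5], K)
    sets[[length(sets) + 1L]] <- found
    if (K == 0L) {
      exhausted <- TRUE
      break
    }
    lp <- .applyCut(lp, noGoodCut(found))
  }
  list(sets = sets, exhausted = exhausted)
}

#' @noRd
.sortSets <- function(sets) {
  if (!length(sets)) return(sets)
  keys <- vapply(sets, function(s) paste(members(s), collapse = ";"),
                 character(1))
  sets[order(keys)]
}

#' Enumerate all equivalent knockout sets at a frontier point
#'
#' Iteratively solves the feasibility program that fixes the point's
#' objective values (within `objectiveMatchTol`) over the knockout
#' constraints, adding a [noGoodCut()] after every solution, until the
#' program is proved infeasible (a certificate that no further equivalent
#' set exists) or `maxSets` solutions have been collected.
#'
#' @param model a [MetabolicModel-class] with finite bounds.
#' @param point a [ParetoPoint-class] whose objectives are attainable
#'   (from [solveBOP()] or user-fixed).
#' @param K number of deletions (default: the witness knockout size).
#' @param candidates candidate reaction ids J_I; must match the set used
#'   to compute the point.  Default derived per `config`.
#' @param config a [SolverConfig-class].
#' @param maxSets iteration budget; a warning is logged when it truncates
#'   the enumeration (the number of equivalent sets can grow
#'   combinatorially with K).
#' @return an [EnumerationResult-class] with mode `"all"`; knockout sets
#'   are reported sorted canonically (lexicographically on member ids)
#'   regardless of discovery order.  A point that is infeasible at the
#'   first iteration yields an empty, non-exhausted result with a
#'   `"paretoKnock_inconsistentPoint"` warning.
#' @export
setMethod("enumerateEquivalent", "MetabolicModel",
  function(model, point, K = knockoutSize(witnessKnockouts(point)),
           candidates = NULL, config = solverConfig(), maxSets = 1000L) {
    if (is.null(candidates)) candidates <- .defaultCandidates(model, config)
    built <- .knockoutMILP(model, candidates, K, config)
    lp <- .fixObjectiveRows(built$lp, objectives(point),
                            config@objectiveMatchTol)
    out <- .enumLoop(lp, built, K, maxSets)
    if (!length(out$sets) && out$exhausted)
      warning(structure(
        class = c("paretoKnock_inconsistentPoint", "warning", "condition"),
        list(message = "point infeasible at iteration 0", call = NULL)))
    if (maxSets > 0L && !out$exhausted && length(out$sets) >= maxSets)
      warning("enumeration truncated at maxSets = ", maxSets,
              " without an infeasibility certificate")
    methods::new("EnumerationResult", point = point,
                 knockoutSets = .sortSets(out$sets), mode = "all",
                 fStar = NA_real_, exhausted = out$exhausted)
  })

#' Minimal Manhattan adjustment at a frontier point
#'
#' Solves the MOMA-style mixed-integer program: among all flux states and
#' K-deletion sets attaining the point's objective values, minimise the
#' Manhattan (L1) distance `f(v) = sum_i |v_i - ref_i|` to the reference
#' flux.  The absolute values are linearised through auxiliary variables
#' `z_i >= v_i - ref_i`, `z_i >= -(v_i - ref_i)`; the `z_i` are internal
#' and never reported.
#'
#' @inheritParams enumerateEquivalent
#' @param reference a [FluxVector-class] covering all model reactions;
#'   default the biomass-optimal FBA solution (the wild-type state).
#' @return list with `fStar` (the minimal L1 distance) and `firstSet`
#'   (the optimising [KnockoutSet-class]).
#' @export
setMethod("momaDistanceLP", "MetabolicModel",
  function(model, point, K = knockoutSize(witnessKnockouts(point)),
           reference = NULL, candidates = NULL, config = solverConfig()) {
    if (is.null(reference)) reference <- solveFBA(model, config = config)
    if (is.null(candidates)) candidates <- .defaultCandidates(model, config)
    built <- .knockoutMILP(model, candidates, K, config,
                           reference = reference)
    lp <- .fixObjectiveRows(built$lp, objectives(point),
                            config@objectiveMatchTol)
    lp$obj[] <- 0
    lp$obj[match(built$zvars, lp$vars)] <- 1
    res <- .solveMILP(lp, built$intIdx, maximize = FALSE)
    if (res$status != "optimal")
      .stopInfeasible(paste0("distance program at the point is ",
                             res$status))
    list(fStar = res$objval,
         firstSet = knockoutSet(built$candidates[res$x[built$yvars] > 0.5],
                                K))
  })

#' Distance cap for MOMA-restricted enumeration
#'
#' A knockout set counts as distance-minimal when it admits a flux state
#' with `f(v) <= f* + momaCapTol(config)`.  The cap is ten times the
#' objective-matching tolerance because fixing the objectives within a
#' `+-objectiveMatchTol` window perturbs every subset's minimal distance
#' by the same order; the cap must dominate that numerical jitter while
#' staying far below any genuine distance gap between inequivalent sets.
#'
#' @param config a [SolverConfig-class].
#' @return the cap added to f*.
#' @export
momaCapTol <- function(config = solverConfig()) 10 * config@objectiveMatchTol

#' Enumerate the MOMA-closest equivalent knockout sets
#'
#' First solves the minimal-adjustment program ([momaDistanceLP()]) to
#' obtain the optimal L1 distance f*; then restricts the enumeration to
#' flux states with `f(v) <= f* + momaCapTol(config)` (the opposite
#' direction is implied by optimality of f*) and iterates no-good cuts as
#' in [enumerateEquivalent()].  The result is always a subset of the
#' plain enumeration at the same tolerances.
#'
#' @inheritParams momaDistanceLP
#' @param maxSets iteration budget, as in [enumerateEquivalent()].
#' @return an [EnumerationResult-class] with mode `"moma"` and `fStar`
#'   filled in.
#' @export
setMethod("enumerateMoma", "MetabolicModel",
  function(model, point, K = knockoutSize(witnessKnockouts(point)),
           reference = NULL, candidates = NULL, config = solverConfig(),
           maxSets = 1000L) {
    if (is.null(reference)) reference <- solveFBA(model, config = config)
    if (is.null(candidates)) candidates <- .defaultCandidates(model, config)
    first <- tryCatch(
      momaDistanceLP(model, point, K, reference, candidates, config),
      infeasibleProgram = function(e) NULL)
    if (is.null(first)) {
      warning(structure(
        class = c("paretoKnock_inconsistentPoint", "warning", "condition"),
        list(message = "point infeasible at iteration 0", call = NULL)))
      return(methods::new("EnumerationResult", point = point,
                          knockoutSets = list(), mode = "moma",
                          fStar = NA_real_, exhausted = FALSE))
    }
    built <- .knockoutMILP(model, candidates, K, config,
                           reference = reference)
    lp <- .fixObjectiveRows(built$lp, objectives(point),
                            config@objectiveMatchTol)
    ## the +-objectiveMatchTol window on the objectives perturbs each
    ## subset's minimal distance by O(tol), so the acceptance cap must
    ## dominate that noise: sets within momaCapTol() of f* count as
    ## distance-minimal
    lp <- .lpAddRow(lp, stats::setNames(rep(1, length(built$zvars)),
                                        built$zvars),
                    "<=", first$fStar + momaCapTol(config))
    if (maxSets < 1L) {
      out <- list(sets = list(), exhausted = FALSE)
    } else {
      out <- .enumLoop(lp, built, K, maxSets, firstCut = first$firstSet)
    }
    if (maxSets > 0L && !out$exhausted && length(out$sets) >= maxSets)
      warning("enumeration truncated at maxSets = ", maxSets,
              " without an infeasibility certificate")
    methods::new("EnumerationResult", point = point,
                 knockoutSets = .sortSets(out$sets), mode = "moma",
                 fStar = first$fStar, exhausted = out$exhausted)
  })

#' Write enumeration results as TSV
#'
#' One row per (point label, set index): semicolon-joined reaction ids,
#' the minimal L1 distance (or NA outside "moma" mode) and the exhaustion
#' flag.
#'
#' @param results list of [EnumerationResult-class] (or a single one).
#' @param path output file.
#' @param labels optional point labels; default `point1`, `point2`, ...
#' @return `path`, invisibly.
#' @export
writeEnumerationTSV <- function(results, path, labels = NULL) {
  if (methods::is(results, "EnumerationResult")) results <- list(results)
  if (is.null(labels)) labels <- paste0("point", seq_along(results))
  rows <- list()
  for (i in seq_along(results)) {
    res <- results[[i]]
    o <- objectives(res@point)
    if (!length(res@knockoutSets)) {
      rows[[length(rows) + 1L]] <- data.frame(
        point = labels[i], set_index = NA_integer_, knockouts = "",
        f_star = res@fStar, exhausted = res@exhausted)
    }
    for (s in seq_along(res@knockoutSets)) {
      rows[[length(rows) + 1L]] <- data.frame(
        point = labels[i], set_index = s,
        knockouts = paste(members(res@knockoutSets[[s]]), collapse = ";"),
        f_star = res@fStar, exhausted = res@exhausted)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
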