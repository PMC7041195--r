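#' @include fba.R
NULL

## ------------------------------------------------------------------------
## Knockout MILP construction
##
## Variables (prefixed to keep namespaces apart):
##   v:<rxn>  flux of every reaction
##   y:<rxn>  deletion binary, one per candidate (inessential) reaction
##   z:<rxn>  L1 deviation helper, only when a reference flux is given
##
## Constraints:
##   S v = 0                                  (steady state)
##   v_j + LB_j y_j >= LB_j                   (deleted reactions carry no
##   v_j + UB_j y_j <= UB_j                    flux; exact for any bound
##                                             signs, no big-M)
##   sum y = K   (or <= K when relaxed)
##   z_i >= +-(v_i - ref_i)                   (reference mode only)
##
## Variable bounds: candidates get [min(LB,0), max(UB,0)] so that y=1 and
## v=0 is always box-feasible; the coupling rows restore the original
## bounds when y=0.
## ------------------------------------------------------------------------

#' @noRd
.stopInfeasible <- function(msg) {
  stop(structure(class = c("infeasibleProgram", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @noRd
.knockoutMILP <- function(model, candidates, K, config, reference = NULL) {
  rxn <- model@reactions
  if (!all(candidates %in% rxn$id))
    stop("unknown candidate reaction(s): ",
         paste(setdiff(candidates, rxn$id), collapse = ", "))
  if (any(candidates %in% model@essentialIds))
    stop("candidates must not contain essential reactions")
  if (any(!is.finite(rxn$lb)) || any(!is.finite(rxn$ub)))
    stop("model has infinite bounds; call capInfiniteBounds() first")
  n <- nrow(rxn)
  vvars <- paste0("v:", rxn$id)
  yvars <- paste0("y:", candidates)
  zvars <- if (is.null(reference)) character() else paste0("z:", rxn$id)
  vars <- c(vvars, yvars, zvars)

  lb <- c(rxn$lb, rep(0, length(yvars)), rep(0, length(zvars)))
  ub <- c(rxn$ub, rep(1, length(yvars)), rep(Inf, length(zvars)))
  ci <- match(candidates, rxn$id)
  lb[ci] <- pmin(rxn$lb[ci], 0)
  ub[ci] <- pmax(rxn$ub[ci], 0)

  S <- as.matrix(model@stoichiometry)
  A <- cbind(S, matrix(0, nrow(S), length(yvars) + length(zvars)))
  colnames(A) <- vars
  b <- numeric(nrow(S))
  sense <- rep("=", nrow(S))

  addRow <- function(A, coef) rbind(A, coef, deparse.level = 0)
  rows <- list()
  for (k in seq_along(candidates)) {
    j <- ci[k]
    lo <- numeric(length(vars)); hi <- numeric(length(vars))
    lo[j] <- 1; lo[n + k] <- rxn$lb[j]
    hi[j] <- 1; hi[n + k] <- rxn$ub[j]
    A <- rbind(A, lo, hi, deparse.level = 0)
    b <- c(b, rxn$lb[j], rxn$ub[j])
    sense <- c(sense, ">=", "<=")
  }
  if (length(yvars)) {
    card <- numeric(length(vars))
    card[n + seq_along(yvars)] <- 1
    A <- rbind(A, card, deparse.level = 0)
    b <- c(b, K)
    sense <- c(sense, if (config@kEquality) "=" else "<=")
  } else if (K > 0 && config@kEquality) {
    stop("K = ", K, " deletions requested but there are no candidates")
  }
  if (!is.null(reference)) {
    ref <- if (methods::is(reference, "FluxVector")) fluxValues(reference)
           else reference
    ref <- ref[rxn$id]
    if (anyNA(ref)) stop("reference flux must cover all model reactions")
    for (j in seq_len(n)) {
      up <- numeric(length(vars)); dn <- numeric(length(vars))
      zc <- n + length(yvars) + j
      up[j] <- 1;  up[zc] <- -1   # v - z <= ref
      dn[j] <- 1;  dn[zc] <- +1   # v + z >= ref
      A <- rbind(A, up, dn, deparse.level = 0)
      b <- c(b, ref[[j]], ref[[j]])
      sense <- c(sense, "<=", ">=")
    }
  }
  lp <- list(A = A, b = b, sense = sense, obj = numeric(length(vars)),
             lb = lb, ub = ub, vars = vars)
  list(lp = lp, intIdx = n + seq_along(yvars), vvars = vvars,
       yvars = yvars, zvars = zvars, candidates = candidates, n = n)
}

#' @noRd
.defaultCandidates <- function(model, config) {
  if (config@restrictToActive) {
    ref <- solveFBA(model, config = config)
    if (solverStatus(ref) != "optimal")
      stop("cannot derive knockout candidates: wild-type FBA is ",
           solverStatus(ref))
    knockoutCandidates(model, ref, config)
  } else {
    setdiff(model@reactions$id, model@essentialIds)
  }
}

#' @noRd
.milpExtract <- function(res, built, K) {
  v <- res$x[built$vvars]
  names(v) <- sub("^v:", "", names(v))
  ysel <- built$candidates[res$x[built$yvars] > 0.5]
  list(flux = v, knockouts = knockoutSet(ysel, K))
}

## add rows restricting listed objective reactions to [lo, hi]
#' @noRd
.addRangeRows <- function(lp, rangeLimits) {
  for (id in names(rangeLimits)) {
    lim <- rangeLimits[[id]]
    var <- paste0("v:", id)
    if (!var %in% lp$vars)
      stop("range limit names unknown reaction '", id, "'")
    if (is.finite(lim[1]))
      lp <- .lpAddRow(lp, stats::setNames(1, var), ">=", lim[1])
    if (length(lim) > 1 && is.finite(lim[2]))
      lp <- .lpAddRow(lp, stats::setNames(1, var), "<=", lim[2])
  }
  lp
}

#' Weighted-sum scalarisation of the bi-objective knockout program
#'
#' Maximises `sum(weights * objectives)` subject to steady state, the
#' knockout coupling constraints, the cardinality constraint on deletions
#' and any range limits.  Among optima of the weighted score, ties are
#' broken by lexicographic re-optimisation: the first listed objective is
#' maximised first, then the second, so the reported point is reproducible.
#'
#' @param model a [MetabolicModel-class] with finite bounds.
#' @param K number of deletions.
#' @param weights nonnegative weights, one per objective, not all zero.
#' @param objectiveIds objective reactions in order; default
#'   `c(targetIds(model)[1], biomassId(model))` (product first).
#' @param candidates candidate (inessential) reaction ids J_I; default
#'   derived per `config` (active-in-reference or all inessential).
#' @param rangeLimits optional named list `list(rxn = c(lo, hi))`
#'   restricting objective values, e.g. to exclude zero-biomass points.
#' @param config a [SolverConfig-class].
#' @return a [ParetoPoint-class] (one supported point; not necessarily
#'   nondominated when a weight is zero).
#' @export
setMethod("weightedSumSolve", "MetabolicModel",
  function(model, K, weights, objectiveIds = NULL, candidates = NULL,
           rangeLimits = NULL, config = solverConfig()) {
    if (is.null(objectiveIds))
      objectiveIds <- c(targetIds(model)[1], biomassId(model))
    stopifnot(length(weights) == length(objectiveIds))
    if (all(weights == 0) || any(weights < 0))
      stop("weights must be nonnegative and not all zero")
    if (is.null(candidates)) candidates <- .defaultCandidates(model, config)
    if (K > length(candidates) && config@kEquality)
      .stopInfeasible(paste0("infeasible: K = ", K, " exceeds the ",
                             length(candidates), " candidate reactions"))
    built <- .knockoutMILP(model, candidates, K, config)
    lp <- built$lp
    if (!is.null(rangeLimits)) lp <- .addRangeRows(lp, rangeLimits)
    ovars <- paste0("v:", objectiveIds)
    stopifnot(all(ovars %in% lp$vars))
    ## the lexicographic pins use a tolerance well below objectiveMatchTol
    ## so reported points stay crisp (no tol-for-tol trading between
    ## objectives)
    lexTol <- 1e-9

    lp$obj[] <- 0
    lp$obj[match(ovars, lp$vars)] <- weights
    res <- .solveMILP(lp, built$intIdx, maximize = TRUE)
    if (res$status != "optimal")
      .stopInfeasible(paste0("weighted-sum program is ", res$status))
    wstar <- res$objval
    ## lexicographic re-optimisation among weighted-score ties
    lp <- .lpAddRow(lp, stats::setNames(weights, ovars), ">=",
                    wstar - lexTol)
    for (i in seq_along(ovars)) {
      lp$obj[] <- 0
      lp$obj[match(ovars[i], lp$vars)] <- 1
      res <- .solveMILP(lp, built$intIdx, maximize = TRUE)
      if (res$status != "optimal")
        stop("lexicographic re-optimisation unexpectedly ", res$status)
      if (i < length(ovars))
        lp <- .lpAddRow(lp, stats::setNames(1, ovars[i]), ">=",
                        res$objval - lexTol)
    }
    ext <- .milpExtract(res, built, K)
    objv <- stats::setNames(ext$flux[objectiveIds], objectiveIds)
    methods::new("ParetoPoint", objectives = objv,
                 witnessFlux = methods::new(
                   "FluxVector", values = ext$flux,
                   objectiveValue = unname(objv[1]),
                   objectiveId = objectiveIds[1], status = "optimal"),
                 witnessKnockouts = ext$knockouts)
  })

#' Nondominance filter
#'
#' Keeps the maximal (nondominated) subset of objective tuples under
#' componentwise maximisation: a point is dropped when another point is at
#' least as good in every objective (within `tol`) and strictly better
#' (beyond `tol`) in at least one.  Duplicate tuples (equal within `tol`
#' in every component) are collapsed to their first occurrence.  The result
#' is ordered by the first objective, descending, ties keeping input order.
#'
#' @param points numeric matrix (rows = points) or list of equal-length
#'   numeric tuples.
#' @param tol comparison tolerance (default 1e-6).
#' @return matrix of the retained rows.
#' @examples
#' dominanceFilter(rbind(c(10, 0), c(0, 10), c(9, 0)))
#' @export
dominanceFilter <- function(points, tol = 1e-6) {
  m <- if (is.matrix(points)) points else do.call(rbind, points)
  if (!nrow(m)) return(m)
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(m))) {
      if (i == j || !keep[i]) next
      dominates <- all(m[j, ] >= m[i, ] - tol) && any(m[j, ] > m[i, ] + tol)
      duplicate <- all(abs(m[j, ] - m[i, ]) <= tol) && j < i
      if ((keep[j] && dominates) || duplicate) keep[i] <- FALSE
    }
  }
  m <- m[keep, , drop = FALSE]
  m[order(-m[, 1]), , drop = FALSE]
}

#' Solve the bi-objective knockout program
#'
#' Computes all extreme supported nondominated points of the bi-objective
#' mixed-binary program (product flux and biomass flux both maximised,
#' exactly K deletions among the candidate reactions) by dichotomic
#' weighted-sum search: the two lexicographic anchor problems are solved
#' first, then the weight normal to each adjacent pair of points is probed
#' recursively until no point improves the chord by more than 1e-6.
#' Unsupported nondominated points (possible in mixed-integer programs) are
#' not on this path; see [epsilonConstraintFront()] for a grid sweep.
#'
#' @inheritParams weightedSumSolve
#' @param targetId the product objective; default the model's first target.
#' @return a [ParetoFront-class], sorted by product flux descending.  When
#'   an anchor program is infeasible an empty front is returned with a
#'   `"paretoKnock_infeasible"` warning.
#' @examples
#' toy <- makeBranchedNetwork(toySpecB())
#' solveBOP(toy, K = 1)
#' @export
setMethod("solveBOP", "MetabolicModel",
  function(model, K, targetId = NULL, candidates = NULL, rangeLimits = NULL,
           config = solverConfig()) {
    if (is.null(targetId)) targetId <- targetIds(model)[1]
    objectiveIds <- c(targetId, biomassId(model))
    if (is.null(candidates)) candidates <- .defaultCandidates(model, config)
    spec <- list(modelDigest = modelDigest(model), K = K,
                 objectiveIds = objectiveIds, rangeLimits = rangeLimits,
                 kEquality = config@kEquality, candidates = candidates)
    solveAt <- function(w) weightedSumSolve(model, K, w, objectiveIds,
                                            candidates, rangeLimits, config)
    anchors <- tryCatch(
      list(solveAt(c(1, 0)), solveAt(c(0, 1))),
      infeasibleProgram = function(e) NULL)
    if (is.null(anchors)) {
      warning(structure(
        class = c("paretoKnock_infeasible", "warning", "condition"),
        list(message = "anchor program infeasible; empty Pareto front",
             call = sys.call(-1))))
      return(methods::new("ParetoFront", points = list(), problemSpec = spec))
    }
    pts <- anchors
    recurse <- function(p, q, depth) {
      if (depth > 50) return(invisible(NULL))
      op <- objectives(p); oq <- objectives(q)
      w <- c(oq[2] - op[2], op[1] - oq[1])
      if (any(w <= 1e-9)) return(invisible(NULL))
      r <- solveAt(w / sum(w))
      wn <- w / sum(w)
      if (sum(wn * objectives(r)) > sum(wn * op) + 1e-6) {
        pts[[length(pts) + 1L]] <<- r
        recurse(p, r, depth + 1)
        recurse(r, q, depth + 1)
      }
      invisible(NULL)
    }
    recurse(anchors[[1]], anchors[[2]], 1)
    .assembleFront(pts, spec, tol = config@objectiveMatchTol)
  })

#' @noRd
.assembleFront <- function(pts, spec, tol = 1e-6) {
  om <- do.call(rbind, lapply(pts, objectives))
  nd <- dominanceFilter(om, tol)
  sel <- integer(nrow(nd))
  for (r in seq_len(nrow(nd)))
    sel[r] <- which(apply(abs(om - matrix(nd[r, ], nrow(om), ncol(om),
                                          byrow = TRUE)), 1,
                          max) <= tol)[1]
  methods::new("ParetoFront", points = pts[sel], problemSpec = spec)
}

#' Epsilon-constraint sweep over the product flux
#'
#' Complementary frontier scan: for a grid of lower bounds on the product
#' flux, maximise biomass lexicographically (biomass first, then product).
#' Unlike the dichotomic weighted-sum search this can reveal unsupported
#' nondominated points of the mixed-integer program; it is a sweep, so the
#' resolution is set by `gridStep`.
#'
#' @inheritParams solveBOP
#' @param gridStep spacing of the product-flux grid; default 1/20 of the
#'   anchor product range.
#' @return a [ParetoFront-class].
#' @export
setMethod("epsilonConstraintFront", "MetabolicModel",
  function(model, K, gridStep, targetId = NULL, candidates = NULL,
           rangeLimits = NULL, config = solverConfig()) {
    if (is.null(targetId)) targetId <- targetIds(model)[1]
    objectiveIds <- c(targetId, biomassId(model))
    if (is.null(candidates)) candidates <- .defaultCandidates(model, config)
    anchor <- weightedSumSolve(model, K, c(1, 0), objectiveIds, candidates,
                               rangeLimits, config)
    pmax_ <- objectives(anchor)[1]
    if (missing(gridStep) || is.null(gridStep)) gridStep <- pmax_ / 20
    eps <- seq(0, pmax_, by = gridStep)
    pts <- list(anchor)
    for (e in eps) {
      lim <- rangeLimits
      lim[[targetId]] <- c(max(e, if (!is.null(lim[[targetId]]))
        lim[[targetId]][1] else -Inf),
        if (!is.null(lim[[targetId]])) lim[[targetId]][2] else Inf)
      p <- tryCatch(
        weightedSumSolve(model, K, c(0, 1), objectiveIds, candidates,
                         lim, config),
        infeasibleProgram = function(err) NULL)
      if (!is.null(p)) pts[[length(pts) + 1L]] <- p
    }
    spec <- list(modelDigest = modelDigest(model), K = K,
                 objectiveIds = objectiveIds, rangeLimits = rangeLimits,
                 kEquality = config@kEquality, candidates = candidates,
                 method = "epsilon-constraint", gridStep = gridStep)
    .assembleFront(pts, spec, tol = config@objectiveMatchTol)
  })

#' Write a Pareto front as TSV (and JSON twin)
#'
#' The TSV has one row per point: the objective columns, K, and the
#' witness knockout ids semicolon-joined.  The JSON twin additionally
#' carries the witness flux vectors.
#'
#' @param front a [ParetoFront-class].
#' @param path TSV output file; the JSON twin replaces the extension with
#'   `.json` unless `jsonPath` is given.
#' @param jsonPath optional explicit JSON path.
#' @return `path`, invisibly.
#' @export
writeFrontTSV <- function(front, path, jsonPath = NULL) {
  pts <- paretoPoints(front)
  onames <- front@problemSpec$objectiveIds
  tab <- do.call(rbind, lapply(pts, function(p) {
    o <- objectives(p)
    data.frame(t(stats::setNames(as.numeric(o), onames)),
               K = knockoutSize(witnessKnockouts(p)),
               knockouts = paste(members(witnessKnockouts(p)),
                                 collapse = ";"))
  }))
  if (is.null(tab)) {
    tab <- data.frame(matrix(numeric(), 0, length(onames) + 2,
                             dimnames = list(NULL, c(onames, "K",
                                                     "knockouts"))))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (is.null(jsonPath)) jsonPath <- sub("\\.tsv$", ".json", path)
  doc <- list(problem = front@problemSpec,
              points = lapply(pts, function(p) list(
                objectives = as.list(stats::setNames(
                  as.numeric(objectives(p)), onames)),
                knockouts = members(witnessKnockouts(p)),
                witness_flux = as.list(fluxValues(witnessFlux(p))))))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), jsonPath)
  invisible(path)
}
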