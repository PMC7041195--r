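#' @include enumeration.R
NULL

#' Specify a branched toy network
#'
#' @param nBranches number of parallel branches leaving the hub metabolite
#'   (branch 1 feeds biomass, branch 2 the product, further branches
#'   by-products).
#' @param branchCapacities upper flux bound per branch reaction; default
#'   1000 (effectively unconstrained at toy scale).
#' @param uptakeBound upper bound of the substrate uptake exchange.
#' @param duplicateProduct add a second, redundant reaction into the
#'   product metabolite (creates equivalent knockout sets).
#' @param seed integer recorded for provenance.
#' @return a [ToySpec-class].
#' @export
toySpec <- function(nBranches = 2L, branchCapacities = rep(1000, nBranches),
                    uptakeBound = 10, duplicateProduct = FALSE, seed = 0L) {
  methods::new("ToySpec", nBranches = as.integer(nBranches),
               branchCapacities = as.numeric(branchCapacities),
               uptakeBound = as.numeric(uptakeBound),
               duplicateProduct = isTRUE(duplicateProduct),
               seed = as.integer(seed))
}

#' The TOY-B reference fixture
#'
#' Two branches with a duplicated product branch and uptake 10:
#' metabolites \{A, B, C\}, reactions \{EX_glc: ->A [0,10]; R1: A->B
#' [0,1000]; R2: A->C [0,1000]; R2b: A->C [0,1000]; EX_bio: B-> [0,1000];
#' EX_prod: C-> [0,1000]\}.  Biomass is EX_bio, the product target
#' EX_prod, and the exchanges are essential, leaving J_I = \{R1, R2, R2b\}.
#'
#' @return a [ToySpec-class].
#' @export
toySpecB <- function() toySpec(2L, c(1000, 1000), 10, TRUE, 0L)

#' Build a branched uptake -> hub -> sinks toy model
#'
#' Deterministic: the same spec always yields the same model (and the same
#' bytes through [writeModelJSON()]).  All reactions are irreversible.
#' The uptake and all sink exchanges are marked essential, so the branch
#' reactions form the inessential candidate set.
#'
#' @param spec a [ToySpec-class].
#' @return a [MetabolicModel-class].
#' @examples
#' makeBranchedNetwork(toySpecB())
#' @export
setMethod("makeBranchedNetwork", "ToySpec", function(spec) {
  n <- spec@nBranches
  hub <- "A"
  bmets <- LETTERS[seq_len(n) + 1L]
  mets <- data.frame(id = c(hub, bmets), name = c(hub, bmets),
                     compartment = "c")
  sinkIds <- c("EX_bio", "EX_prod",
               if (n > 2) paste0("EX_by", seq(3, n)))
  branchIds <- paste0("R", seq_len(n))
  ids <- c("EX_glc", branchIds[1:min(2, n)],
           if (spec@duplicateProduct) "R2b",
           if (n > 2) branchIds[3:n],
           sinkIds)
  stoich <- list()
  lbv <- ubv <- numeric(0)
  add <- function(coef, lb, ub) {
    stoich[[length(stoich) + 1L]] <<- coef
    lbv <<- c(lbv, lb); ubv <<- c(ubv, ub)
  }
  add(stats::setNames(1, hub), 0, spec@uptakeBound)            # EX_glc
  add(stats::setNames(c(-1, 1), c(hub, bmets[1])), 0,
      spec@branchCapacities[1])                                # R1
  if (n >= 2)
    add(stats::setNames(c(-1, 1), c(hub, bmets[2])), 0,
        spec@branchCapacities[2])                              # R2
  if (spec@duplicateProduct)
    add(stats::setNames(c(-1, 1), c(hub, bmets[2])), 0,
        spec@branchCapacities[2])                              # R2b
  if (n > 2) for (i in 3:n)
    add(stats::setNames(c(-1, 1), c(hub, bmets[i])), 0,
        spec@branchCapacities[i])                              # R3..
  for (i in seq_len(n))
    add(stats::setNames(-1, bmets[i]), 0, 1000)                # sinks
  metabolicModel(mets, data.frame(id = ids, lb = lbv, ub = ubv), stoich,
                 biomassId = "EX_bio", targetIds = "EX_prod",
                 essentialIds = c("EX_glc", sinkIds))
})

#' Draw a seeded random branched toy spec
#'
#' Deterministic given `seed`; used to generate families of small
#' networks with known oracle fronts for property testing.  Branch counts
#' 2-6, capacities between 30% and 120% of the uptake bound, uptake 5-15,
#' product branch duplicated with probability 0.3 - enough variety to
#' exercise binding capacities, redundant branches and by-product drains.
#'
#' @param seed integer.
#' @return a [ToySpec-class].
#' @export
randomToySpec <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  n <- sample(2:6, 1)
  U <- sample(5:15, 1)
  caps <- round(stats::runif(n, 0.3 * U, 1.2 * U), 2)
  dup <- stats::runif(1) < 0.3
  toySpec(n, caps, U, dup, seed)
}

## objective tuple achieved by a flux solution
#' @noRd
.lpObjPair <- function(x, objectiveIds) {
  stats::setNames(as.numeric(x[paste0("v:", objectiveIds)]), objectiveIds)
}

## LP over a fixed knockout: lexicographic maximisation in the id order
#' @noRd
.lexLP <- function(lp, objectiveIds, tol = 1e-9) {
  for (id in objectiveIds) {
    lp$obj[] <- 0
    lp$obj[match(paste0("v:", id), lp$vars)] <- 1
    res <- .solveLP(lp, maximize = TRUE)
    if (res$status != "optimal") return(NULL)
    lp <- .lpAddRow(lp, stats::setNames(1, paste0("v:", id)), ">=",
                    res$objval - tol)
  }
  res
}

## Reduce a nondominated 2-objective set (first objective descending) to
## its extreme supported points: vertices of the upper-right concave
## envelope.  Chord-interior images of decision-space vertices (and
## below-chord unsupported points) are dropped, since the weighted-sum
## programs characterise extreme supported points only.
#' @noRd
.extremeSupported <- function(m, tol = 1e-6) {
  if (nrow(m) <= 2) return(m)
  cross2 <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  stack <- list(m[1, ])
  for (i in 2:nrow(m)) {
    cc <- m[i, ]
    while (length(stack) >= 2) {
      a <- stack[[length(stack) - 1]]
      b <- stack[[length(stack)]]
      scale <- 1 + abs(cc[1] - a[1]) + abs(cc[2] - a[2])
      if (cross2(a, b, cc) <= tol * scale)
        stack[[length(stack)]] <- NULL
      else break
    }
    stack[[length(stack) + 1L]] <- cc
  }
  do.call(rbind, stack)
}

#' @noRd
.subsetsOf <- function(candidates, K, kEquality) {
  sizes <- if (kEquality) K else 0:K
  out <- list()
  for (s in sizes) {
    if (s == 0) { out[[length(out) + 1L]] <- character(0); next }
    if (s > length(candidates)) next
    cmb <- utils::combn(candidates, s, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' @noRd
.fluxOnlyLP <- function(model, rangeLimits = NULL) {
  lp <- .fluxLP(model)
  lp$vars <- paste0("v:", lp$vars)
  colnames(lp$A) <- lp$vars
  if (!is.null(rangeLimits)) lp <- .addRangeRows(lp, rangeLimits)
  lp
}

#' Brute-force oracle for the bi-objective front
#'
#' Independent reference implementation used to validate [solveBOP()]:
#' for every K-subset of the candidates, fixes those reactions to zero and
#' solves single-objective LPs only (a dense weight grid over the two
#' objectives plus both lexicographic anchors), then unions all achieved
#' objective tuples, applies [dominanceFilter()] and finally keeps the
#' vertices of the concave envelope.  The last step matters on networks
#' with binding branch capacities: a decision-space vertex of one subset
#' can land in the interior of (or below) a chord spanned by other
#' subsets' points, and such images are not extreme supported points of
#' the mixed-integer program, which is the set the weighted-sum search
#' characterises.  No mixed-integer machinery is involved, so the code
#' path is disjoint from the program under test.
#'
#' @param model a [MetabolicModel-class] with finite bounds.
#' @param K knockout budget.
#' @param candidates candidate reaction ids (J_I).
#' @param weightGridSize number of grid weights on `[0, 1]` (default 101;
#'   the anchors are always added so extreme points cannot be missed).
#' @param rangeLimits as in [solveBOP()].
#' @param objectiveIds objective pair, default `(target, biomass)`.
#' @param config a [SolverConfig-class]; `kEquality` selects exactly-K
#'   versus at-most-K subsets.
#' @return matrix of nondominated objective tuples, first objective
#'   descending.
#' @export
bruteForceFront <- function(model, K, candidates,
                            weightGridSize = 101L, rangeLimits = NULL,
                            objectiveIds = NULL, config = solverConfig()) {
  if (is.null(objectiveIds))
    objectiveIds <- c(targetIds(model)[1], biomassId(model))
  if (choose(length(candidates), K) > 1e4)
    stop("combinatorial budget exceeded: C(", length(candidates), ",", K,
         ") subsets")
  subsets <- .subsetsOf(candidates, K, config@kEquality)
  ws <- seq(0, 1, length.out = weightGridSize)
  pts <- list()
  for (sub in subsets) {
    lp <- .fluxOnlyLP(knockoutModel(model, sub), rangeLimits)
    ovars <- paste0("v:", objectiveIds)
    oidx <- match(ovars, lp$vars)
    for (perm in list(objectiveIds, rev(objectiveIds))) {
      res <- .lexLP(lp, perm)
      if (!is.null(res))
        pts[[length(pts) + 1L]] <- .lpObjPair(res$x, objectiveIds)
    }
    for (w in ws) {
      lp$obj[] <- 0
      lp$obj[oidx] <- c(w, 1 - w)
      res <- .solveLP(lp, maximize = TRUE)
      if (res$status == "optimal")
        pts[[length(pts) + 1L]] <- .lpObjPair(res$x, objectiveIds)
    }
  }
  if (!length(pts))
    return(matrix(numeric(), 0, 2,
                  dimnames = list(NULL, objectiveIds)))
  m <- dominanceFilter(do.call(rbind, pts), tol = config@objectiveMatchTol)
  m <- .extremeSupported(m, tol = config@objectiveMatchTol)
  colnames(m) <- objectiveIds
  m
}

#' Brute-force oracle for equivalent-knockout enumeration
#'
#' For every K-subset of the candidates, tests by LP whether the subset
#' admits a flux state attaining the point's objective values (within
#' `objectiveMatchTol`); when a reference flux is given, also records the
#' minimal L1 distance to it per feasible subset.  Reference list for
#' validating [enumerateEquivalent()] and [enumerateMoma()].
#'
#' @inheritParams bruteForceFront
#' @param point a [ParetoPoint-class] (or named numeric objective tuple).
#' @param reference optional [FluxVector-class] for the distance record.
#' @return list with `sets` (list of [KnockoutSet-class], canonical
#'   order), `distances` (numeric per set, `NULL` without reference) and
#'   `minDistance`.
#' @export
bruteForceEnumerate <- function(model, point, K, candidates,
                                reference = NULL, objectiveIds = NULL,
                                config = solverConfig()) {
  if (is.null(objectiveIds))
    objectiveIds <- c(targetIds(model)[1], biomassId(model))
  if (choose(length(candidates), K) > 1e4)
    stop("combinatorial budget exceeded: C(", length(candidates), ",", K,
         ") subsets")
  objv <- if (methods::is(point, "ParetoPoint")) objectives(point)
          else point
  names(objv) <- objectiveIds
  tol <- config@objectiveMatchTol
  subsets <- .subsetsOf(candidates, K, config@kEquality)
  sets <- list()
  dists <- numeric(0)
  for (sub in subsets) {
    kom <- knockoutModel(model, sub)
    lp <- .fluxOnlyLP(kom)
    lp <- .fixObjectiveRows(lp, objv, tol)
    lp$obj[] <- 0
    res <- .solveLP(lp)
    if (res$status != "optimal") next
    sets[[length(sets) + 1L]] <- knockoutSet(sub, K)
    if (!is.null(reference)) {
      built <- .knockoutMILP(kom, character(0), 0L, config,
                             reference = reference)
      dlp <- .fixObjectiveRows(built$lp, objv, tol)
      dlp$obj[] <- 0
      dlp$obj[match(built$zvars, dlp$vars)] <- 1
      dres <- .solveLP(dlp)
      dists <- c(dists, if (dres$status == "optimal") dres$objval
                 else NA_real_)
    }
  }
  ord <- order(vapply(sets, function(s) paste(members(s), collapse = ";"),
                      character(1)))
  list(sets = sets[ord],
       distances = if (is.null(reference)) NULL else dists[ord],
       minDistance = if (is.null(reference) || !length(dists)) NA_real_
       else min(dists, na.rm = TRUE))
}
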