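## Internal LP / MILP interface over the compiled bounded-variable simplex.
##
## An LP is a plain list:
##   A     : dense numeric matrix (rows = constraints, cols = variables)
##   b     : right-hand side
##   sense : character vector per row, one of "<=", "=", ">="
##   obj   : objective coefficients
##   lb,ub : variable bounds (may be +-Inf)
##   vars  : variable names (column names of A)

.lpStatus <- c("optimal", "infeasible", "unbounded", "numeric_failure")

#' @noRd
.solveLP <- function(lp, maximize = FALSE) {
  stopifnot(nrow(lp$A) == length(lp$b), ncol(lp$A) == length(lp$obj))
  A <- lp$A
  b <- lp$b
  lb <- lp$lb
  ub <- lp$ub
  obj <- if (maximize) -lp$obj else lp$obj
  ineq <- which(lp$sense != "=")
  if (length(ineq)) {
    S <- matrix(0, nrow(A), length(ineq))
    slb <- sub <- numeric(length(ineq))
    for (k in seq_along(ineq)) {
      i <- ineq[k]
      S[i, k] <- 1
      if (lp$sense[i] == "<=") { slb[k] <- 0; sub[k] <- Inf }
      else { slb[k] <- -Inf; sub[k] <- 0 }
    }
    A <- cbind(A, S)
    obj <- c(obj, numeric(length(ineq)))
    lb <- c(lb, slb)
    ub <- c(ub, sub)
  }
  res <- .cppSolveLP(A, b, obj, lb, ub)
  status <- .lpStatus[res$status + 1L]
  if (status != "optimal") {
    return(list(status = status, x = NULL, objval = NA_real_))
  }
  x <- res$x[seq_along(lp$obj)]
  names(x) <- lp$vars
  list(status = "optimal", x = x,
       objval = if (maximize) -res$objval else res$objval)
}

#' @noRd
.lpAddRow <- function(lp, coef, sense, rhs) {
  ## coef: named numeric over a subset of lp$vars
  row <- numeric(length(lp$vars))
  names(row) <- lp$vars
  stopifnot(all(names(coef) %in% lp$vars))
  row[names(coef)] <- coef
  lp$A <- rbind(lp$A, row, deparse.level = 0)
  lp$b <- c(lp$b, rhs)
  lp$sense <- c(lp$sense, sense)
  lp
}

#' @noRd
.lpSetBounds <- function(lp, ids, lb = NULL, ub = NULL) {
  idx <- match(ids, lp$vars)
  stopifnot(!anyNA(idx))
  if (!is.null(lb)) lp$lb[idx] <- lb
  if (!is.null(ub)) lp$ub[idx] <- ub
  lp
}

## Depth-first branch and bound on binary variables.
## intIdx: indices of 0/1 variables. firstFeasible: stop at the first
## integral solution (used for pure feasibility programs with obj == 0).
#' @noRd
.solveMILP <- function(lp, intIdx, maximize = FALSE, firstFeasible = FALSE,
                       intTol = 1e-6) {
  if (length(intIdx) == 0L) {
    return(.solveLP(lp, maximize))
  }
  origObj <- lp$obj
  sgn <- if (maximize) -1 else 1
  lp$obj <- sgn * origObj  # minimise internally
  best <- NULL
  bestObj <- Inf
  root_lb <- lp$lb
  root_ub <- lp$ub
  stack <- list(list(lb = root_lb, ub = root_ub))
  unboundedRoot <- FALSE
  nodes <- 0L
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    lp$lb <- node$lb
    lp$ub <- node$ub
    rel <- .solveLP(lp, maximize = FALSE)
    if (rel$status == "unbounded" && nodes == 1L) unboundedRoot <- TRUE
    if (rel$status != "optimal") next
    relVal <- rel$objval
    if (relVal >= bestObj - 1e-9) next
    frac <- abs(rel$x[intIdx] - round(rel$x[intIdx]))
    nodeClosed <- FALSE
    if (all(frac <= intTol)) {
      ## polish: re-solve with the binaries fixed at their rounded values,
      ## so the continuous part cannot keep slack exploited through the
      ## integrality tolerance
      plp <- lp
      plp$lb[intIdx] <- plp$ub[intIdx] <- round(rel$x[intIdx])
      pol <- .solveLP(plp, maximize = FALSE)
      if (pol$status == "optimal" && pol$objval < bestObj - 1e-9) {
        best <- pol$x
        best[intIdx] <- round(best[intIdx])
        bestObj <- pol$objval
        if (firstFeasible) break
      }
      ## the node is settled only if polishing realises the relaxation
      ## bound; otherwise a different integer assignment may hide in the
      ## tolerance gap and the node must still be branched
      nodeClosed <- pol$status == "optimal" && pol$objval <= relVal + 1e-9
    }
    if (nodeClosed) next
    freeInt <- intIdx[node$lb[intIdx] < node$ub[intIdx]]
    if (!length(freeInt)) next
    j <- freeInt[which.max(frac[match(freeInt, intIdx)])]
    up <- node; up$lb[j] <- 1; up$ub[j] <- 1
    dn <- node; dn$lb[j] <- 0; dn$ub[j] <- 0
    ## push down-branch first so the up-branch (knockout active) is explored
    ## first; deterministic order
    stack[[length(stack) + 1L]] <- dn
    stack[[length(stack) + 1L]] <- up
  }
  if (is.null(best)) {
    status <- if (unboundedRoot) "unbounded" else "infeasible"
    return(list(status = status, x = NULL, objval = NA_real_))
  }
  list(status = "optimal", x = best, objval = sum(origObj * best))
}
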