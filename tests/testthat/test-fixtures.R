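# Toy network generator and brute-force oracles.

test_that("TOY-B is built exactly as documented", {
  m <- toyB()
  expect_equal(length(reactionIds(m)), 6L)
  expect_equal(length(metaboliteIds(m)), 3L)
  expect_equal(reactionIds(m),
               c("EX_glc", "R1", "R2", "R2b", "EX_bio", "EX_prod"))
  b <- reactionBounds(m)
  expect_equal(b$ub, c(10, 1000, 1000, 1000, 1000, 1000))
  expect_equal(b$lb, rep(0, 6))
  expect_equal(essentialIds(m), c("EX_glc", "EX_bio", "EX_prod"))
})

test_that("closed forms: uptake bound caps growth, branch capacity binds", {
  m7 <- makeBranchedNetwork(toySpec(2, c(1000, 1000), uptakeBound = 7))
  expect_equal(objectiveValue(solveFBA(m7)), 7, tolerance = 1e-9)
  m3 <- makeBranchedNetwork(toySpec(3, c(4, 4, 4), uptakeBound = 10))
  expect_equal(objectiveValue(solveFBA(m3)), 4, tolerance = 1e-9)
})

test_that("the generator is deterministic down to the serialised bytes", {
  s1 <- randomToySpec(99)
  s2 <- randomToySpec(99)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  writeModelJSON(makeBranchedNetwork(s1), f1)
  writeModelJSON(makeBranchedNetwork(s2), f2)
  expect_identical(readLines(f1), readLines(f2))
  # drawing a spec does not disturb the session RNG stream
  set.seed(1); a <- runif(3)
  set.seed(1); invisible(randomToySpec(5)); b <- runif(3)
  expect_identical(a, b)
})

test_that("the oracle refuses combinatorially explosive inputs", {
  m <- toyB()
  expect_error(bruteForceFront(m, 10, paste0("x", 1:40)),
               "combinatorial budget")
  expect_error(bruteForceEnumerate(m, c(EX_prod = 0, EX_bio = 10), 10,
                                   paste0("x", 1:40)),
               "combinatorial budget")
})

test_that("brute-force front honours K=0 and range restrictions", {
  m <- toyB()
  lpOnly <- bruteForceFront(m, 0, character(0))
  expect_equal(unname(lpOnly), rbind(c(10, 0), c(0, 10)), tolerance = 1e-6)
  ranged <- bruteForceFront(m, 1, toyCandidates,
                            rangeLimits = list(EX_bio = c(5, Inf)))
  expect_equal(unname(ranged), rbind(c(5, 5), c(0, 10)), tolerance = 1e-6)
})

test_that("feasible oracle subsets re-verify through knockout simulation", {
  for (s in c(2, 11)) {
    m <- makeBranchedNetwork(randomToySpec(s))
    cand <- setdiff(reactionIds(m), essentialIds(m))
    fr <- solveBOP(m, 1, candidates = cand)
    for (pt in paretoPoints(fr)) {
      o <- objectives(pt)
      bf <- bruteForceEnumerate(m, pt, 1, cand)
      for (s2 in bf$sets) {
        km <- knockoutModel(m, members(s2))
        km <- applyBoundOverrides(km, list(
          boundOverride(biomassId(m), "lower", o[[2]] - 1e-6),
          boundOverride(biomassId(m), "upper", o[[2]] + 1e-6)))
        best <- solveFBA(km, targetIds(m)[1], "max")
        expect_equal(solverStatus(best), "optimal")
        expect_gte(objectiveValue(best), o[[1]] - 1e-5)
      }
    }
  }
})

test_that("an infeasible objective pair yields no oracle subsets", {
  bf <- bruteForceEnumerate(toyB(), c(EX_prod = 10, EX_bio = 10), 1,
                            toyCandidates)
  expect_length(bf$sets, 0L)
})
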