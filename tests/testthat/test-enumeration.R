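# No-good cuts, equivalent-set enumeration, MOMA restriction.
#
# Expected set lists below were computed with the brute-force LP oracle
# (bruteForceEnumerate) and verified by hand on the 6-reaction toy; note
# that at the zero-biomass corner every singleton deletion is equivalent,
# because nothing forces the biomass branch to carry flux.

frontPoints <- function(m, K, cand) {
  paretoPoints(solveBOP(m, K, candidates = cand))
}

test_that("no-good cuts exclude a found set and all its supersets", {
  cut1 <- noGoodCut(knockoutSet("R2"))
  expect_equal(cut1$ids, "R2")
  expect_equal(cut1$rhs, 0L)           # y_R2 <= 0
  cut2 <- noGoodCut(knockoutSet(c("R1", "R2")))
  expect_equal(cut2$rhs, 1L)           # y_R1 + y_R2 <= 1
  expect_equal(cut2$sense, "<=")
  # any superset of {R1, R2} violates the cut
  y <- c(R1 = 1, R2 = 1, R3 = 1)
  expect_gt(sum(y[cut2$ids]), cut2$rhs)
  expect_error(noGoodCut(knockoutSet(character(0))), "empty set")
})

test_that("enumeration at the growth corner finds both redundant product branches", {
  m <- toyB()
  pts <- frontPoints(m, 1, toyCandidates)
  growth <- pts[[2]]                   # (0, 10)
  expect_equal(unname(objectives(growth)), c(0, 10), tolerance = 1e-6)
  res <- enumerateEquivalent(m, growth, 1, candidates = toyCandidates)
  expectSameSets(knockoutSets(res), list("R2", "R2b"))
  expect_true(isExhausted(res))
})

test_that("enumeration at the zero-biomass corner finds every singleton", {
  m <- toyB()
  prodPt <- frontPoints(m, 1, toyCandidates)[[1]]   # (10, 0)
  res <- enumerateEquivalent(m, prodPt, 1, candidates = toyCandidates)
  oracle <- bruteForceEnumerate(m, prodPt, 1, toyCandidates)
  expectSameSets(knockoutSets(res), list("R1", "R2", "R2b"))
  expect_identical(setKeys(knockoutSets(res)), setKeys(oracle$sets))
  expect_true(isExhausted(res))
})

test_that("a zero budget returns an empty, non-exhausted result", {
  m <- toyB()
  pt <- frontPoints(m, 1, toyCandidates)[[1]]
  suppressWarnings(
    res <- enumerateEquivalent(m, pt, 1, candidates = toyCandidates,
                               maxSets = 0L))
  expect_length(knockoutSets(res), 0L)
  expect_false(isExhausted(res))
})

test_that("an unattainable point is flagged inconsistent", {
  m <- toyB()
  fake <- methods::new("ParetoPoint",
                       objectives = c(EX_prod = 10, EX_bio = 10),
                       witnessFlux = solveFBA(m),
                       witnessKnockouts = knockoutSet("R1"))
  expect_warning(
    res <- enumerateEquivalent(m, fake, 1, candidates = toyCandidates),
    class = "paretoKnock_inconsistentPoint")
  expect_length(knockoutSets(res), 0L)
})

test_that("minimal Manhattan adjustment matches the hand-computed toy values", {
  m <- toyB()
  ref <- solveFBA(m)
  pts <- frontPoints(m, 1, toyCandidates)
  # at (0, 10) the mutant can reuse the wild-type flux exactly
  d0 <- momaDistanceLP(m, pts[[2]], 1, reference = ref,
                       candidates = toyCandidates)
  expect_equal(d0$fStar, 0, tolerance = 1e-6)
  # at (10, 0) carbon reroutes: |dR1|=10, reroute 10, bio 10, prod 10
  d1 <- momaDistanceLP(m, pts[[1]], 1, reference = ref,
                       candidates = toyCandidates)
  expect_equal(d1$fStar, 40, tolerance = 1e-5)
  # self-distance of a mutant's own optimum is zero
  selfFlux <- witnessFlux(pts[[1]])
  dSelf <- momaDistanceLP(m, pts[[1]], 1, reference = selfFlux,
                          candidates = toyCandidates)
  expect_equal(dSelf$fStar, 0, tolerance = 1e-5)
})

test_that("MOMA-restricted enumeration keeps only distance-minimal sets", {
  m <- toyB()
  ref <- solveFBA(m)
  pts <- frontPoints(m, 1, toyCandidates)
  g <- enumerateMoma(m, pts[[2]], 1, reference = ref,
                     candidates = toyCandidates)
  expect_equal(fStar(g), 0, tolerance = 1e-6)
  expectSameSets(knockoutSets(g), list("R2", "R2b"))
  expect_true(isExhausted(g))
  p <- enumerateMoma(m, pts[[1]], 1, reference = ref,
                     candidates = toyCandidates)
  expect_equal(fStar(p), 40, tolerance = 1e-5)
  # all three singletons reroute the same 40 units at the no-growth corner
  expectSameSets(knockoutSets(p), list("R1", "R2", "R2b"))
})

test_that("a capacity-limited duplicate branch leaves the growth corner intact", {
  m <- toyBNarrowR2b()                  # R2b upper bound 5
  ref <- solveFBA(m)
  pts <- frontPoints(m, 1, toyCandidates)
  growth <- pts[[length(pts)]]
  expect_equal(unname(objectives(growth)), c(0, 10), tolerance = 1e-6)
  g <- enumerateMoma(m, growth, 1, reference = ref,
                     candidates = toyCandidates)
  expect_equal(fStar(g), 0, tolerance = 1e-6)
  expectSameSets(knockoutSets(g), list("R2", "R2b"))
})

test_that("MOMA sets are a subset of the plain enumeration with optimal distance", {
  for (s in c(3, 12, 17)) {
    m <- makeBranchedNetwork(randomToySpec(s))
    cand <- setdiff(reactionIds(m), essentialIds(m))
    ref <- solveFBA(m)
    K <- min(2, length(cand))
    for (pt in frontPoints(m, K, cand)) {
      all_ <- enumerateEquivalent(m, pt, K, candidates = cand)
      mom <- enumerateMoma(m, pt, K, reference = ref, candidates = cand)
      expect_true(all(setKeys(knockoutSets(mom)) %in%
                      setKeys(knockoutSets(all_))))
      # distance optimality split at the momaCapTol threshold
      oracle <- bruteForceEnumerate(m, pt, K, cand, reference = ref)
      inMoma <- setKeys(oracle$sets) %in% setKeys(knockoutSets(mom))
      expect_true(all(oracle$distances[inMoma] <=
                      fStar(mom) + momaCapTol() + 1e-9))
      expect_true(all(oracle$distances[!inMoma] >
                      fStar(mom) + momaCapTol() - 2e-6))
    }
  }
})

test_that("enumeration terminates within the subset-count bound", {
  m <- makeBranchedNetwork(randomToySpec(16))
  cand <- setdiff(reactionIds(m), essentialIds(m))
  K <- min(2, length(cand))
  for (pt in frontPoints(m, K, cand)) {
    res <- enumerateEquivalent(m, pt, K, candidates = cand)
    expect_lte(length(knockoutSets(res)), choose(length(cand), K))
    expect_true(isExhausted(res))
    # all sets have size K and are pairwise distinct
    expect_true(all(vapply(knockoutSets(res), function(s)
      length(members(s)), integer(1)) == K))
    expect_equal(anyDuplicated(setKeys(knockoutSets(res))), 0L)
  }
})

test_that("the enumeration TSV writer emits one row per point and set", {
  m <- toyB()
  ref <- solveFBA(m)
  pts <- frontPoints(m, 1, toyCandidates)
  enums <- lapply(pts, function(p)
    enumerateMoma(m, p, 1, reference = ref, candidates = toyCandidates))
  tf <- tempfile(fileext = ".tsv")
  writeEnumerationTSV(enums, tf)
  tab <- read.delim(tf)
  expect_equal(names(tab),
               c("point", "set_index", "knockouts", "f_star", "exhausted"))
  expect_equal(nrow(tab), 5L)           # 3 sets at (10,0), 2 at (0,10)
  expect_setequal(round(tab$f_star, 4), c(40, 0))
})
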