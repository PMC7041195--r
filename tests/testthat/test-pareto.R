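# Bi-objective knockout program: scalarisation, dominance, frontier.

test_that("weighted-sum scalarisation reproduces the TOY-B corner points", {
  m <- toyB()
  p1 <- weightedSumSolve(m, 1, c(1, 0), candidates = toyCandidates)
  expect_equal(unname(objectives(p1)), c(10, 0), tolerance = 1e-6)
  # witness choice among equally optimal deletions is solver-determined;
  # it must be a candidate singleton and re-verify against the objectives
  expect_true(members(witnessKnockouts(p1)) %in% toyCandidates)
  expect_equal(
    objectiveValue(simulateKnockout(m, members(witnessKnockouts(p1)),
                                    "EX_prod")),
    10, tolerance = 1e-6)
  p2 <- weightedSumSolve(m, 1, c(0, 1), candidates = toyCandidates)
  expect_equal(unname(objectives(p2)), c(0, 10), tolerance = 1e-6)
  expect_true(members(witnessKnockouts(p2)) %in% c("R2", "R2b"))
})

test_that("equal weights break ties lexicographically on the first objective", {
  # any flux split with prod + bio = 10 scores 5; the reported point must
  # be the product-first lexicographic optimum (10, 0)
  p <- weightedSumSolve(toyB(), 1, c(0.5, 0.5), candidates = toyCandidates)
  expect_equal(unname(objectives(p)), c(10, 0), tolerance = 1e-6)
})

test_that("dominance filter keeps exactly the nondominated tuples", {
  out <- dominanceFilter(rbind(c(10, 0), c(0, 10), c(9, 0)))
  expect_equal(out, rbind(c(10, 0), c(0, 10)))
  expect_equal(dominanceFilter(rbind(c(10, 0))), rbind(c(10, 0)))
  # duplicates collapse; incomparable points both survive (ethanol/biomass
  # pairs of realistic magnitude)
  out2 <- dominanceFilter(rbind(c(8.8, 0.43), c(11.8, 0.41), c(8.8, 0.43)))
  expect_equal(nrow(out2), 2L)
  expect_equal(out2[, 1], c(11.8, 8.8))
  # antichain property: no row weakly dominates another
  for (i in seq_len(nrow(out2)))
    for (j in seq_len(nrow(out2)))
      if (i != j)
        expect_false(all(out2[i, ] >= out2[j, ] - 1e-9) &&
                     any(out2[i, ] > out2[j, ] + 1e-9))
})

test_that("the TOY-B frontier at K=1 is the two-corner front", {
  fr <- solveBOP(toyB(), 1, candidates = toyCandidates)
  om <- objectiveMatrix(fr)
  expect_equal(unname(om), rbind(c(10, 0), c(0, 10)), tolerance = 1e-6)
  expect_equal(fr@problemSpec$K, 1)
})

test_that("K=0 with no candidates degenerates to the pure flux trade-off", {
  fr <- solveBOP(toyB(), 0, candidates = character(0))
  expect_equal(unname(objectiveMatrix(fr)), rbind(c(10, 0), c(0, 10)),
               tolerance = 1e-6)
})

test_that("range limits restrict the frontier as constraints, not filters", {
  fr <- solveBOP(toyB(), 1, candidates = toyCandidates,
                 rangeLimits = list(EX_bio = c(5, Inf)))
  expect_equal(unname(objectiveMatrix(fr)), rbind(c(5, 5), c(0, 10)),
               tolerance = 1e-6)
})

test_that("an infeasible anchor yields an empty front with a signal", {
  expect_warning(
    fr <- solveBOP(toyB(), 5, candidates = toyCandidates),
    class = "paretoKnock_infeasible")
  expect_length(paretoPoints(fr), 0L)
})

test_that("witnesses re-verify: knockouts plus objective fixing reproduce the point", {
  for (s in c(6, 10)) {
    m <- makeBranchedNetwork(randomToySpec(s))
    cand <- setdiff(reactionIds(m), essentialIds(m))
    fr <- solveBOP(m, 1, candidates = cand)
    for (p in paretoPoints(fr)) {
      o <- objectives(p)
      ko <- members(witnessKnockouts(p))
      km <- knockoutModel(m, ko)
      km <- applyBoundOverrides(km, list(
        boundOverride(biomassId(m), "lower", o[[2]] - 1e-6),
        boundOverride(biomassId(m), "upper", o[[2]] + 1e-6)))
      best <- solveFBA(km, targetIds(m)[1], "max")
      expect_equal(objectiveValue(best), o[[1]], tolerance = 1e-5)
      expect_true(validateFlux(knockoutModel(m, ko), witnessFlux(p),
                               tol = 1e-6))
    }
  }
})

test_that("frontiers are monotone: product up, biomass down", {
  for (s in c(8, 15, 19)) {
    m <- makeBranchedNetwork(randomToySpec(s))
    cand <- setdiff(reactionIds(m), essentialIds(m))
    om <- objectiveMatrix(solveBOP(m, min(2, length(cand)),
                                   candidates = cand))
    ord <- order(om[, 1])                    # product ascending
    expect_true(all(diff(om[ord, 2]) <= 1e-6))  # biomass nonincreasing
  }
})

test_that("the epsilon-constraint sweep agrees with the dichotomic front on TOY-B", {
  m <- toyB()
  fr <- epsilonConstraintFront(m, 1, gridStep = 2.5,
                               candidates = toyCandidates)
  om <- objectiveMatrix(fr)
  expect_true(nrow(om) >= 2)
  expect_equal(om[1, ], c(EX_prod = 10, EX_bio = 0), tolerance = 1e-6)
  expect_equal(om[nrow(om), ], c(EX_prod = 0, EX_bio = 10),
               tolerance = 1e-6)
})

test_that("front TSV and JSON writers emit the frontier with witnesses", {
  fr <- solveBOP(toyB(), 1, candidates = toyCandidates)
  tf <- tempfile(fileext = ".tsv")
  writeFrontTSV(fr, tf)
  tab <- read.delim(tf)
  expect_equal(nrow(tab), 2L)
  expect_equal(names(tab), c("EX_prod", "EX_bio", "K", "knockouts"))
  js <- jsonlite::fromJSON(sub("\\.tsv$", ".json", tf),
                           simplifyVector = FALSE)
  expect_length(js$points, 2L)
  expect_equal(js$points[[1]]$objectives$EX_prod, 10, tolerance = 1e-6)
  expect_length(js$points[[1]]$witness_flux, 6L)
})
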