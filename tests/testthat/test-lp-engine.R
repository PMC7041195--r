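# FBA, knockout simulation, essentiality, SimpleOptKnock.

test_that("FBA on TOY-B returns the unique biomass-optimal vertex", {
  f <- solveFBA(toyB())
  expect_equal(solverStatus(f), "optimal")
  expect_equal(objectiveValue(f), 10, tolerance = 1e-8)
  expect_equal(fluxValues(f),
               c(EX_glc = 10, R1 = 10, R2 = 0, R2b = 0, EX_bio = 10,
                 EX_prod = 0),
               tolerance = 1e-8)
  expect_true(validateFlux(toyB(), f))
})

test_that("cutting carbon uptake drives the biomass optimum to zero", {
  starved <- applyBoundOverrides(toyB(), boundOverride("EX_glc", "upper", 0))
  expect_equal(objectiveValue(solveFBA(starved)), 0, tolerance = 1e-9)
})

test_that("knockout simulation equals FBA with zeroed bounds", {
  m <- toyB()
  expect_equal(objectiveValue(simulateKnockout(m, "R1")), 0,
               tolerance = 1e-9)
  expect_equal(objectiveValue(simulateKnockout(m, "R2")), 10,
               tolerance = 1e-9)
  expect_equal(objectiveValue(simulateKnockout(m, "R1", "EX_prod")), 10,
               tolerance = 1e-9)
  # empty knockout set is exactly plain FBA
  expect_equal(objectiveValue(simulateKnockout(m, character(0))),
               objectiveValue(solveFBA(m)), tolerance = 1e-9)
})

test_that("every returned flux vector satisfies mass balance and bounds", {
  set.seed(5)
  for (s in c(2, 9, 13)) {
    m <- makeBranchedNetwork(randomToySpec(s))
    cand <- setdiff(reactionIds(m), essentialIds(m))
    for (i in 1:4) {
      ko <- sample(cand, min(2, length(cand)))
      f <- simulateKnockout(m, ko)
      expect_true(validateFlux(m |> knockoutModel(ko), f, tol = 1e-6))
    }
  }
})

test_that("adding knockouts never increases the biomass optimum", {
  m <- makeBranchedNetwork(randomToySpec(4))
  cand <- setdiff(reactionIds(m), essentialIds(m))
  for (j in cand) {
    single <- objectiveValue(simulateKnockout(m, j))
    for (j2 in setdiff(cand, j)) {
      double <- objectiveValue(simulateKnockout(m, c(j, j2)))
      expect_lte(double, single + 1e-9)
    }
  }
})

test_that("knockout candidates are the active inessential reactions", {
  m <- toyB()
  ref <- solveFBA(m)
  expect_equal(knockoutCandidates(m, ref), "R1")
  m0 <- m
  essentialIds(m0) <- character(0)
  expect_equal(knockoutCandidates(m0, ref), c("EX_glc", "R1", "EX_bio"))
  zero <- methods::new("FluxVector",
                       values = setNames(numeric(6), reactionIds(m)),
                       objectiveValue = 0, objectiveId = "EX_bio",
                       status = "optimal")
  expect_equal(knockoutCandidates(m, zero), character(0))
})

test_that("essentiality helper honours its biomass floor semantics", {
  m <- toyB()
  expect_equal(classifyEssential(m, biomassFloor = 1e-3),
               c("EX_glc", "R1", "EX_bio"))
  # strict comparison: floor 0 declares nothing essential
  expect_equal(classifyEssential(m, biomassFloor = 0), character(0))
  # a parallel duplicate of the biomass branch makes R1 redundant
  expect_equal(classifyEssential(toyBDupBiomass(), biomassFloor = 1e-3),
               c("EX_glc", "EX_bio"))
})

test_that("SimpleOptKnock reports biomass and target extremes per deletion", {
  tab <- simpleOptKnock(toyB())
  row <- function(id) tab[tab$reaction_id == id, ]
  r1 <- row("R1")
  expect_equal(r1$biomass_max, 0, tolerance = 1e-8)
  expect_equal(r1$target_max, 10, tolerance = 1e-5)
  expect_equal(r1$target_min, 0, tolerance = 1e-5)
  r2 <- row("R2")
  expect_equal(unlist(r2[, 2:4], use.names = FALSE), c(10, 0, 0),
               tolerance = 1e-5)
  glc <- row("EX_glc")
  expect_equal(unlist(glc[, 2:4], use.names = FALSE), c(0, 0, 0),
               tolerance = 1e-5)
  # its biomass column is the single-knockout objective
  for (j in tab$reaction_id)
    expect_equal(row(j)$biomass_max,
                 objectiveValue(simulateKnockout(toyB(), j)),
                 tolerance = 1e-8)
})

test_that("flux vectors survive the TSV writer round trip", {
  f <- solveFBA(toyB())
  tf <- tempfile(fileext = ".tsv")
  writeFluxTSV(f, tf)
  f2 <- readFluxTSV(tf)
  expect_equal(fluxValues(f2), fluxValues(f))
})
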