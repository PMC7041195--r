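# Model containers, readers, bound normalisation.

toybJSON <- system.file("extdata", "toyb.json", package = "paretoKnock")
toybSBML <- system.file("extdata", "toyb.sbml.xml", package = "paretoKnock")

test_that("the TOY-B JSON fixture loads with the expected dimensions", {
  m <- loadModel(toybJSON, "json")
  expect_s4_class(m, "MetabolicModel")
  expect_equal(length(reactionIds(m)), 6L)
  expect_equal(length(metaboliteIds(m)), 3L)
  expect_equal(biomassId(m), "EX_bio")
  expect_equal(targetIds(m), "EX_prod")
  expect_equal(dim(stoichMatrix(m)), c(3L, 6L))
  # reaction order is the file order
  expect_equal(reactionIds(m),
               c("EX_glc", "R1", "R2", "R2b", "EX_bio", "EX_prod"))
  # exchanges are the single-metabolite reactions
  expect_equal(reactionIds(m)[m@reactions$is_exchange],
               c("EX_glc", "EX_bio", "EX_prod"))
})

test_that("JSON write-read round trip reproduces S, bounds and objectives", {
  m <- makeBranchedNetwork(randomToySpec(3))
  tf <- tempfile(fileext = ".json")
  writeModelJSON(m, tf)
  m2 <- loadModel(tf, "json")
  expect_true(all(stoichMatrix(m) == stoichMatrix(m2)))
  expect_identical(reactionBounds(m), reactionBounds(m2))
  expect_identical(biomassId(m), biomassId(m2))
  expect_identical(targetIds(m), targetIds(m2))
  expect_identical(essentialIds(m), essentialIds(m2))
})

test_that("malformed models are rejected with informative errors", {
  doc <- jsonlite::fromJSON(toybJSON, simplifyVector = FALSE)
  # reaction citing an unknown metabolite
  bad <- doc
  bad$reactions[[2]]$stoich <- list(X = -1)
  tf <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(bad, auto_unbox = TRUE), tf)
  expect_error(loadModel(tf, "json"), "unknown metabolite.*X")
  # missing bound is an error, never a silent default
  bad2 <- doc
  bad2$reactions[[3]]$lb <- NULL
  writeLines(jsonlite::toJSON(bad2, auto_unbox = TRUE), tf)
  expect_error(loadModel(tf, "json"), "lower bound")
  # biomass id must resolve
  bad3 <- doc
  bad3$biomass <- "EX_nope"
  writeLines(jsonlite::toJSON(bad3, auto_unbox = TRUE), tf)
  expect_error(loadModel(tf, "json"), "biomassId")
})

test_that("the SBML FBC reader recovers species, bounds and the objective", {
  m <- loadModel(toybSBML, "sbml", targetIds = "EX_prod")
  # boundary species A_ext is excluded from S
  expect_equal(metaboliteIds(m), c("A", "B", "C"))
  expect_equal(reactionIds(m),
               c("EX_glc", "R1", "R2", "R2b", "EX_bio", "EX_prod"))
  expect_equal(biomassId(m), "EX_bio")     # from the active FBC objective
  b <- reactionBounds(m)
  expect_equal(b$ub[b$id == "EX_glc"], 10)
  expect_equal(b$lb[b$id == "R2b"], -Inf)  # INF parameters survive as Inf
  expect_equal(b$ub[b$id == "R2b"], Inf)
  # bound parameters must exist
  txt <- readLines(toybSBML)
  tf <- tempfile(fileext = ".xml")
  writeLines(sub('fbc:upperFluxBound="ten"', 'fbc:upperFluxBound="nope"',
                 txt), tf)
  expect_error(loadModel(tf, "sbml", targetIds = "EX_prod"), "nope")
})

test_that("capInfiniteBounds caps only infinite bounds and is idempotent", {
  m <- loadModel(toybSBML, "sbml", targetIds = "EX_prod")
  c1 <- capInfiniteBounds(m, 1000)
  b <- reactionBounds(c1)
  expect_equal(b$lb[b$id == "R2b"], -1000)
  expect_equal(b$ub[b$id == "R2b"], 1000)
  expect_equal(b$ub[b$id == "EX_glc"], 10)    # finite bounds untouched
  expect_identical(reactionBounds(capInfiniteBounds(c1, 1000)), b)
  # one-sided capping with a different cap
  m2 <- applyBoundOverrides(c1, boundOverride("R2b", "upper", 10))
  m2@reactions$lb[m2@reactions$id == "R2b"] <- -Inf
  b2 <- reactionBounds(capInfiniteBounds(m2, 50))
  expect_equal(b2$lb[b2$id == "R2b"], -50)
  expect_equal(b2$ub[b2$id == "R2b"], 10)
})

test_that("bound overrides replace bounds in order and validate", {
  m <- toyB()
  m2 <- applyBoundOverrides(m, list(boundOverride("EX_glc", "lower", -10),
                                    boundOverride("R2", "upper", 6)))
  b <- reactionBounds(m2)
  expect_equal(b$lb[b$id == "EX_glc"], -10)
  expect_equal(b$ub[b$id == "R2"], 6)
  # raising a lower bound above zero is fine while below the upper bound
  m3 <- applyBoundOverrides(m, boundOverride("R1", "lower", 5))
  expect_equal(reactionBounds(m3)$lb[2], 5)
  expect_error(applyBoundOverrides(m, boundOverride("R9", "lower", 1)),
               "unknown reaction")
  expect_error(applyBoundOverrides(m, boundOverride("R1", "lower", 2000)),
               "above upper bound")
})

test_that("override TSVs round-trip through readBoundOverrides", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\twhich\tvalue",
               "EX_glc\tlower\t-10", "R2\tupper\t6"), tf)
  ov <- readBoundOverrides(tf)
  expect_length(ov, 2L)
  expect_equal(ov[[1]]$reactionId, "EX_glc")
  expect_equal(ov[[2]]$value, 6)
  m <- applyBoundOverrides(toyB(), ov)
  expect_equal(reactionBounds(m)$lb[1], -10)
})
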