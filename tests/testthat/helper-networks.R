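# Shared fixtures and comparison helpers.

toyB <- function() makeBranchedNetwork(toySpecB())

toyCandidates <- c("R1", "R2", "R2b")

# canonical string key per knockout set, for order-insensitive comparison
setKeys <- function(sets) {
  sort(vapply(sets, function(s) paste(members(s), collapse = ";"),
              character(1)))
}

expectSameSets <- function(sets, expected) {
  expect_identical(setKeys(sets),
                   sort(vapply(expected, function(x)
                     paste(sort(x), collapse = ";"), character(1))))
}

# TOY-B with the biomass branch duplicated (R1b parallel to R1)
toyBDupBiomass <- function() {
  mets <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                     compartment = "c")
  rxns <- data.frame(
    id = c("EX_glc", "R1", "R1b", "R2", "R2b", "EX_bio", "EX_prod"),
    lb = 0, ub = c(10, 1000, 1000, 1000, 1000, 1000, 1000))
  stoich <- list(c(A = 1), c(A = -1, B = 1), c(A = -1, B = 1),
                 c(A = -1, C = 1), c(A = -1, C = 1), c(B = -1), c(C = -1))
  metabolicModel(mets, rxns, stoich, biomassId = "EX_bio",
                 targetIds = "EX_prod",
                 essentialIds = c("EX_glc", "EX_bio", "EX_prod"))
}

# variant of TOY-B with the duplicate product branch capacity-limited
toyBNarrowR2b <- function() {
  m <- toyB()
  applyBoundOverrides(m, boundOverride("R2b", "upper", 5))
}
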