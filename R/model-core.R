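#' @include accessors.R
NULL

#' Construct a MetabolicModel from parts
#'
#' Low-level constructor used by the readers and the fixture generator.
#' Reactions and metabolites keep their given (file) order; that order is
#' stable through every downstream computation.
#'
#' @param metabolites data.frame with columns `id` and optionally `name`,
#'   `compartment`.
#' @param reactions data.frame with columns `id`, `lb`, `ub`.
#' @param stoich list of named numeric vectors, one per reaction in the same
#'   order, mapping metabolite id to stoichiometric coefficient (negative =
#'   consumed).
#' @param biomassId,targetIds,essentialIds objective and essential reaction
#'   ids (see [MetabolicModel-class]).
#' @return a validated [MetabolicModel-class].
#' @export
metabolicModel <- function(metabolites, reactions, stoich, biomassId,
                           targetIds, essentialIds = character()) {
  metabolites <- as.data.frame(metabolites)
  reactions <- as.data.frame(reactions)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment))
    metabolites$compartment <- NA_character_
  metabolites <- metabolites[, c("id", "name", "compartment")]
  if (length(stoich) != nrow(reactions))
    stop("need one stoichiometry per reaction")
  mids <- as.character(metabolites$id)
  triplets <- do.call(rbind, lapply(seq_along(stoich), function(j) {
    sj <- stoich[[j]]
    if (!length(sj)) stop("reaction '", reactions$id[j],
                          "' has empty stoichiometry")
    if (any(!is.finite(sj))) stop("reaction '", reactions$id[j],
                                  "' has non-finite coefficients")
    bad <- setdiff(names(sj), mids)
    if (length(bad))
      stop("reaction '", reactions$id[j], "' cites unknown metabolite(s): ",
           paste(bad, collapse = ", "))
    data.frame(i = match(names(sj), mids), j = j, x = as.numeric(sj))
  }))
  S <- Matrix::sparseMatrix(i = triplets$i, j = triplets$j, x = triplets$x,
                            dims = c(nrow(metabolites), nrow(reactions)),
                            dimnames = list(mids, as.character(reactions$id)))
  nmet <- Matrix::colSums(S != 0)
  reactions$is_exchange <- nmet == 1L
  reactions <- reactions[, c("id", "lb", "ub", "is_exchange")]
  reactions$lb <- as.numeric(reactions$lb)
  reactions$ub <- as.numeric(reactions$ub)
  methods::new("MetabolicModel",
               metabolites = metabolites, reactions = reactions,
               stoichiometry = S, biomassId = as.character(biomassId),
               targetIds = as.character(targetIds),
               essentialIds = as.character(essentialIds))
}

#' Solver configuration
#'
#' @param feasibilityTol,integralityTol,zeroFluxTol,objectiveMatchTol
#'   positive tolerances, see [SolverConfig-class].
#' @param randomSeed integer recorded with runs for provenance.
#' @param timeLimit advisory per-program limit in seconds.
#' @param restrictToActive if TRUE, knockout candidates default to the
#'   inessential reactions active in the reference FBA flux; if FALSE
#'   (default) every inessential reaction is eligible, so the candidate set
#'   is exactly the complement of the essential set.
#' @param kEquality delete exactly K reactions (TRUE, default) or at most K.
#' @return a [SolverConfig-class].
#' @export
solverConfig <- function(feasibilityTol = 1e-6, integralityTol = 1e-6,
                         zeroFluxTol = 1e-6, objectiveMatchTol = 1e-6,
                         randomSeed = 1L, timeLimit = Inf,
                         restrictToActive = FALSE, kEquality = TRUE) {
  methods::new("SolverConfig",
               feasibilityTol = feasibilityTol,
               integralityTol = integralityTol,
               zeroFluxTol = zeroFluxTol,
               objectiveMatchTol = objectiveMatchTol,
               randomSeed = as.integer(randomSeed),
               timeLimit = timeLimit,
               restrictToActive = restrictToActive,
               kEquality = kEquality)
}

#' Construct a KnockoutSet
#'
#' @param members reaction ids with y = 1; stored sorted.
#' @param k the knockout budget K; defaults to `length(members)` (they can
#'   differ under the relaxed at-most-K constraint).
#' @return a [KnockoutSet-class].
#' @export
knockoutSet <- function(members, k = length(members)) {
  methods::new("KnockoutSet", members = sort(as.character(members)),
               k = as.integer(k))
}

#' Construct a bound override
#'
#' @param reactionId reaction to modify.
#' @param which `"lower"` or `"upper"`.
#' @param value new bound (mmol/gDW/h).
#' @return a `boundOverride` record (plain list).
#' @seealso [applyBoundOverrides()], [readBoundOverrides()]
#' @export
boundOverride <- function(reactionId, which = c("lower", "upper"), value) {
  which <- match.arg(which)
  structure(list(reactionId = as.character(reactionId), which = which,
                 value = as.numeric(value)), class = "boundOverride")
}

#' Read bound overrides from a 3-column TSV
#'
#' Columns: `reaction_id`, `which` (`lower`/`upper`), `value`.  A header
#' line is optional.
#'
#' @param path TSV file.
#' @return list of override records, in file order.
#' @export
readBoundOverrides <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("reaction_id", "which", "value"))
  if (identical(tolower(tab[1, 1]), "reaction_id")) tab <- tab[-1, ]
  lapply(seq_len(nrow(tab)), function(i)
    boundOverride(tab$reaction_id[i], tab$which[i], as.numeric(tab$value[i])))
}

# ---------------------------------------------------------------------------
# JSON dialect
#
# {"metabolites":[{"id","name","compartment"}],
#  "reactions":[{"id","stoich":{met: coef},"lb","ub"}],
#  "biomass": id, "targets": [ids], "essential": [ids]}
# Infinite bounds are serialised as the strings "inf" / "-inf".
# ---------------------------------------------------------------------------

.jsonBound <- function(x) {
  if (is.character(x)) {
    x <- tolower(x)
    if (x %in% c("inf", "+inf", "infinity")) return(Inf)
    if (x %in% c("-inf", "-infinity")) return(-Inf)
    stop("unparseable bound value: ", x)
  }
  as.numeric(x)
}

#' Load a metabolic model
#'
#' Reads either the package JSON dialect (the canonical interchange format,
#' see the vignette for the schema) or an SBML Level 3 file with the FBC v2
#' extension.  Reaction order is the file order.  Missing bounds are an
#' error, never silently defaulted.
#'
#' @param path model file.
#' @param dialect `"json"` or `"sbml"`.
#' @param biomassId,targetIds required for SBML when the file's active FBC
#'   objective does not identify them; for JSON they override the stored
#'   ids when given.
#' @param essentialIds optional essential set override.
#' @return a validated [MetabolicModel-class].
#' @export
loadModel <- function(path, dialect = c("json", "sbml"), biomassId = NULL,
                      targetIds = NULL, essentialIds = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path)
  m <- switch(dialect,
              json = .loadModelJSON(path, biomassId, targetIds, essentialIds),
              sbml = .loadModelSBML(path, biomassId, targetIds, essentialIds))
  validObject(m)
  m
}

.loadModelJSON <- function(path, biomassId, targetIds, essentialIds) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("metabolites", "reactions", "biomass", "targets"))
    if (is.null(doc[[field]]))
      stop("JSON model misses required field '", field, "'")
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) {
      if (is.null(m$id)) stop("metabolite without id")
      m$id
    }, character(1)),
    name = vapply(doc$metabolites, function(m)
      if (is.null(m$name)) NA_character_ else m$name, character(1)),
    compartment = vapply(doc$metabolites, function(m)
      if (is.null(m$compartment)) NA_character_ else m$compartment,
      character(1)))
  mets$name <- ifelse(is.na(mets$name), mets$id, mets$name)
  rxns <- data.frame(
    id = vapply(doc$reactions, function(r) {
      if (is.null(r$id)) stop("reaction without id")
      r$id
    }, character(1)))
  rxns$lb <- vapply(doc$reactions, function(r) {
    if (is.null(r$lb)) stop("reaction '", r$id, "' misses lower bound")
    .jsonBound(r$lb)
  }, numeric(1))
  rxns$ub <- vapply(doc$reactions, function(r) {
    if (is.null(r$ub)) stop("reaction '", r$id, "' misses upper bound")
    .jsonBound(r$ub)
  }, numeric(1))
  stoich <- lapply(doc$reactions, function(r) {
    if (is.null(r$stoich) || !length(r$stoich))
      stop("reaction '", r$id, "' has empty stoichiometry")
    unlist(r$stoich)
  })
  metabolicModel(
    mets, rxns, stoich,
    biomassId = if (is.null(biomassId)) doc$biomass else biomassId,
    targetIds = if (is.null(targetIds)) unlist(doc$targets) else targetIds,
    essentialIds = if (is.null(essentialIds))
      as.character(unlist(doc$essential)) else essentialIds)
}

#' Write a model in the JSON dialect
#'
#' Inverse of `loadModel(..., dialect = "json")`: a write-then-read round
#' trip reproduces stoichiometry, bounds and objective ids exactly.
#'
#' @param model a [MetabolicModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeModelJSON <- function(model, path) {
  S <- model@stoichiometry
  fmtB <- function(x) {
    if (x == Inf) "inf" else if (x == -Inf) "-inf" else x
  }
  rx <- lapply(seq_len(nrow(model@reactions)), function(j) {
    col <- S[, j]
    nz <- which(col != 0)
    list(id = model@reactions$id[j],
         stoich = as.list(stats::setNames(as.numeric(col[nz]),
                                          rownames(S)[nz])),
         lb = fmtB(model@reactions$lb[j]),
         ub = fmtB(model@reactions$ub[j]))
  })
  mets <- lapply(seq_len(nrow(model@metabolites)), function(i) {
    m <- model@metabolites[i, ]
    out <- list(id = m$id, name = m$name)
    if (!is.na(m$compartment)) out$compartment <- m$compartment
    out
  })
  doc <- list(metabolites = mets, reactions = rx,
              biomass = model@biomassId,
              targets = as.list(model@targetIds),
              essential = as.list(model@essentialIds))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SBML Level 3 + FBC v2 (reader only)
# ---------------------------------------------------------------------------

.loadModelSBML <- function(path, biomassId, targetIds, essentialIds) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure: ",
                                           conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  getAttr <- function(node, at) xml2::xml_attr(node, at)
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(
    vapply(params, function(p) {
      v <- getAttr(p, "value")
      if (is.na(v)) return(NA_real_)
      if (toupper(v) == "INF") Inf
      else if (toupper(v) == "-INF") -Inf
      else as.numeric(v)
    }, numeric(1)),
    vapply(params, function(p) getAttr(p, "id"), character(1)))

  spn <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(spn)) stop("SBML format error: no species found")
  spec <- data.frame(
    id = vapply(spn, function(x) getAttr(x, "id"), character(1)),
    name = vapply(spn, function(x) getAttr(x, "name"), character(1)),
    compartment = vapply(spn, function(x) getAttr(x, "compartment"),
                         character(1)),
    boundary = vapply(spn, function(x) {
      identical(getAttr(x, "boundaryCondition"), "true")
    }, logical(1)))
  spec$name <- ifelse(is.na(spec$name), spec$id, spec$name)
  keep <- spec[!spec$boundary, c("id", "name", "compartment")]

  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rxn_nodes)) stop("SBML format error: no reactions found")
  ids <- vapply(rxn_nodes, function(x) getAttr(x, "id"), character(1))
  boundFor <- function(node, at, rid) {
    ref <- xml2::xml_attr(node, at, ns = ns)
    if (is.na(ref))
      stop("SBML format error: reaction '", rid, "' misses fbc:", at)
    v <- if (ref %in% names(pval)) pval[[ref]] else NA_real_
    if (is.na(v))
      stop("SBML format error: bound parameter '", ref, "' of reaction '",
           rid, "' is undefined")
    v
  }
  lb <- numeric(length(ids))
  ub <- numeric(length(ids))
  stoich <- vector("list", length(ids))
  for (k in seq_along(rxn_nodes)) {
    node <- rxn_nodes[[k]]
    lb[k] <- boundFor(node, "fbc:lowerFluxBound", ids[k])
    ub[k] <- boundFor(node, "fbc:upperFluxBound", ids[k])
    coef <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(node,
                                 paste0("./s:", side, "/s:speciesReference"),
                                 ns)
      for (r in refs) {
        sid <- getAttr(r, "species")
        st <- getAttr(r, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (sid %in% keep$id) {
          cur <- if (sid %in% names(coef)) coef[[sid]] else 0
          coef[sid] <- cur + sgn * st
        }
      }
    }
    coef <- coef[coef != 0]
    if (!length(coef))
      stop("SBML format error: reaction '", ids[k],
           "' touches only boundary species; no interior stoichiometry")
    stoich[[k]] <- coef
  }

  if (is.null(biomassId)) {
    obj <- xml2::xml_find_first(
      doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
      ns)
    if (!inherits(obj, "xml_missing"))
      biomassId <- xml2::xml_attr(obj, "fbc:reaction", ns = ns)
    if (is.null(biomassId) || is.na(biomassId))
      stop("SBML file declares no usable FBC objective; supply biomassId")
  }
  if (is.null(targetIds))
    stop("targetIds must be given for SBML models")
  metabolicModel(keep, data.frame(id = ids, lb = lb, ub = ub), stoich,
                 biomassId = biomassId, targetIds = targetIds,
                 essentialIds = if (is.null(essentialIds)) character()
                 else essentialIds)
}

# ---------------------------------------------------------------------------
# bound normalisation
# ---------------------------------------------------------------------------

#' Replace infinite flux bounds by a finite cap
#'
#' Every lower bound of `-Inf` becomes `-cap` and every upper bound of
#' `Inf` becomes `cap`; finite bounds are untouched.  Idempotent.
#'
#' @param model a [MetabolicModel-class].
#' @param cap positive cap (default 1000 mmol/gDW/h, the conventional value
#'   for genome-scale models).
#' @return a new model with capped bounds.
#' @export
setMethod("capInfiniteBounds", "MetabolicModel", function(model, cap = 1000) {
  stopifnot(is.numeric(cap), length(cap) == 1L, cap > 0)
  model@reactions$lb[model@reactions$lb == -Inf] <- -cap
  model@reactions$ub[model@reactions$ub == Inf] <- cap
  validObject(model)
  model
})

#' Apply bound overrides to a model
#'
#' Replaces the stated bounds in order.  Unknown reaction ids and overrides
#' that leave a reaction with lower > upper are errors.
#'
#' @param model a [MetabolicModel-class].
#' @param overrides list of [boundOverride()] records (or a single one).
#' @return a new model with the overridden bounds.
#' @export
setMethod("applyBoundOverrides", "MetabolicModel", function(model, overrides) {
  if (inherits(overrides, "boundOverride")) overrides <- list(overrides)
  for (ov in overrides) {
    j <- match(ov$reactionId, model@reactions$id)
    if (is.na(j))
      stop("bound override names unknown reaction '", ov$reactionId, "'")
    if (ov$which == "lower") model@reactions$lb[j] <- ov$value
    else model@reactions$ub[j] <- ov$value
    if (model@reactions$lb[j] > model@reactions$ub[j])
      stop("override leaves reaction '", ov$reactionId,
           "' with lower bound ", model@reactions$lb[j],
           " above upper bound ", model@reactions$ub[j])
  }
  validObject(model)
  model
})

#' Zero the bounds of knocked-out reactions
#'
#' @param model a [MetabolicModel-class].
#' @param knockouts reaction ids whose upper and lower flux bounds are fixed
#'   to zero.
#' @return a new model simulating the deletion.
#' @export
knockoutModel <- function(model, knockouts) {
  knockouts <- as.character(knockouts)
  idx <- match(knockouts, model@reactions$id)
  if (anyNA(idx))
    stop("unknown knockout reaction(s): ",
         paste(knockouts[is.na(idx)], collapse = ", "))
  model@reactions$lb[idx] <- 0
  model@reactions$ub[idx] <- 0
  model
}

#' Stable digest of a model
#'
#' MD5 of the canonical JSON serialisation; used to stamp results with the
#' model they came from.
#'
#' @param model a [MetabolicModel-class].
#' @return hex digest string.
#' @export
modelDigest <- function(model) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeModelJSON(model, tf)
  unname(tools::md5sum(tf))
}
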