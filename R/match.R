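#' @include fingerprint.R
NULL

.asMolecule <- function(x) {
  if (is(x, "Molecule")) x else parseStructure(as.character(x))
}

#' @rdname matchSubstructure
setMethod("matchSubstructure", signature(target = "Molecule"),
  function(target, query) {
    query <- .asMolecule(query)
    if (nrow(query@atoms) == 0L) {
      return(new("MatchResult", matched = TRUE, atomMap = integer()))
    }
    map <- cr_subgraph_match(
      .atomCodes(query), .edgeMatrix(query), as.integer(query@bonds$order),
      .atomCodes(target), .edgeMatrix(target), as.integer(target@bonds$order)
    )
    new("MatchResult", matched = length(map) > 0L, atomMap = as.integer(map))
  })

#' Fingerprint screen for substructure search
#'
#' The necessary-condition test run before verification: passes iff every
#' query bit is set in the target. Sound (never rejects a true match) for
#' fingerprints generated with the same parameters.
#'
#' @param queryFp,targetFp [Fingerprint-class] objects.
#' @return logical scalar.
#' @export
screenPass <- function(queryFp, targetFp) {
  if (queryFp@paramsId != targetFp@paramsId) {
    .crStop("chemreg_params_mismatch_error", "fingerprint parameters differ")
  }
  identical(queryFp@bits & targetFp@bits, queryFp@bits)
}

#' @rdname matchExact
setMethod("matchExact", signature(target = "Molecule", query = "Molecule"),
  function(target, query) {
    structureKey(target) == structureKey(query)
  })

#' @rdname matchSmarts
setMethod("matchSmarts", signature(target = "Molecule"),
  function(target, smarts) {
    pattern <- if (is(smarts, "SmartsPattern")) smarts@pattern else as.character(smarts)
    obmol <- ChemmineOB::forEachMol("SMILES", canonicalForm(target), identity)
    n <- tryCatch(
      ChemmineOB::smartsSearch_OB(obmol, pattern),
      error = function(e) {
        .crStop("chemreg_parse_error",
                sprintf("invalid SMARTS pattern: %s", pattern))
      }
    )
    sum(unlist(n)) > 0
  })
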