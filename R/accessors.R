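#' @include AllGenerics.R
NULL

#' @rdname molecule-accessors
setMethod("molAtoms", "Molecule", function(x) x@atoms)

#' @rdname molecule-accessors
setMethod("molBonds", "Molecule", function(x) x@bonds)

#' @rdname molecule-accessors
setMethod("sourceText", "Molecule", function(x) x@sourceText)

#' @rdname fingerprint-accessors
setMethod("fpBits", "Fingerprint", function(x) x@bits)

#' @rdname fingerprint-accessors
setMethod("fpPopcount", "Fingerprint", function(x) x@popcount)

#' @rdname fingerprint-accessors
setMethod("fpParamsId", "Fingerprint", function(x) x@paramsId)

#' @rdname page-accessors
setMethod("pageItems", "Page", function(x) x@items)

#' @rdname page-accessors
setMethod("totalCount", "Page", function(x) x@totalCount)

#' @rdname page-accessors
setMethod("countFromCache", "Page", function(x) x@countFromCache)

setMethod("show", "Molecule", function(object) {
  nc <- max(.componentsMembership(object), 0L)
  cat(sprintf("Molecule: %d heavy atom(s), %d bond(s), %d component(s)\n",
              nrow(object@atoms), nrow(object@bonds), nc))
  if (!is.na(object@canonicalSmiles)) {
    cat("  canonical SMILES:", object@canonicalSmiles, "\n")
  }
})

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint [%s]: %d of %d bits set\n",
              object@paramsId, object@popcount, 8L * length(object@bits)))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: %s", if (object@matched) "matched" else "not matched"))
  if (object@matched && length(object@atomMap)) {
    cat(" (atoms", paste(object@atomMap, collapse = ","), ")")
  }
  cat("\n")
})

setMethod("show", "PlanDecision", function(object) {
  cat(sprintf("PlanDecision: %s (estimated candidates: %s)\n",
              object@strategy, format(object@estimatedCandidates)))
})

setMethod("show", "Page", function(object) {
  cat(sprintf("Page %d (size %d): %d item(s) of %d total%s\n",
              object@pageIndex, object@pageSize, nrow(object@items),
              object@totalCount,
              if (object@countFromCache) " [count cached]" else ""))
})

setMethod("show", "SaveOutcome", function(object) {
  cat(sprintf("SaveOutcome: id %s, %d structure(s) created, %d reused\n",
              format(object@record$id), object@structuresCreated,
              object@structuresReused))
})

setMethod("show", "ImportReport", function(object) {
  cat(sprintf(paste0("ImportReport: %d record(s) read, %d compound(s) created, ",
                     "%d structure(s) created, %d reused, %d failure(s)\n"),
              object@recordsRead, object@compoundsCreated,
              object@structuresCreated, object@structuresReused,
              length(object@failures)))
})

setMethod("show", "SecurityContext", function(object) {
  cat(sprintf("SecurityContext: %s, user '%s', roles: %s\n",
              if (object@enabled) "enabled" else "disabled", object@user,
              if (length(object@roles)) paste(object@roles, collapse = ", ") else "(none)"))
})
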