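#' @title Condition classes
#' @description All errors signalled by ChemRegistry carry the class
#' `chemreg_error` plus one specific subclass, so callers can use
#' `tryCatch(..., chemreg_parse_error = ...)` style handlers.
#' @name chemreg-conditions
#' @details Specific classes:
#' \itemize{
#'   \item `chemreg_parse_error` — syntactically invalid structure or formula text
#'   \item `chemreg_valence_error` — chemically impossible atom under the reject policy
#'   \item `chemreg_keygen_error` — both the InChIKey and the fallback key failed
#'   \item `chemreg_unknown_element_error` — element symbol outside the mass table
#'   \item `chemreg_params_mismatch_error` — fingerprints from different parameter sets
#'   \item `chemreg_store_error` — unusable store target
#'   \item `chemreg_constraint_error` — store-level constraint violation
#'   \item `chemreg_uniqueness_error` — duplicate compound/container under the active policy
#'   \item `chemreg_concurrent_modification_error` — optimistic-lock version mismatch
#'   \item `chemreg_not_found_error` — referenced entity does not exist
#'   \item `chemreg_unknown_field_error` — filter/sort field not on the target type
#'   \item `chemreg_authorization_error` — write denied by the security guard
#'   \item `chemreg_format_error` — malformed SD-file record
#'   \item `chemreg_abort_error` — import aborted under the abort policy
#' }
NULL

.crStop <- function(class, message, ...) {
  message <- if (length(message)) paste(message, collapse = "") else class
  cond <- structure(
    class = c(class, "chemreg_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}
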