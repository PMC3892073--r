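#' @include parse.R
NULL

.md5hex <- function(s) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  con <- file(tf, open = "wb")
  writeBin(charToRaw(s), con)
  close(con)
  unname(tools::md5sum(tf))
}

.isStandardKey <- function(key) {
  is.character(key) && length(key) == 1L && !is.na(key) && nchar(key) == 27L &&
    substr(key, 15, 15) == "-" && substr(key, 26, 26) == "-" &&
    grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", key)
}

#' @rdname structureKey
setMethod("structureKey", "Molecule", function(mol) {
  comp <- .componentsMembership(mol)
  if (length(comp) && max(comp) > 1L) {
    .crStop("chemreg_constraint_error",
            "structureKey requires a single connected component; split first")
  }
  can <- canonicalForm(mol)
  key <- trimws(.obConvert("SMI", "INCHIKEY", can))
  key <- sub("[[:space:]].*$", "", key)
  if (.isStandardKey(key)) return(key)
  # fallback for species the InChI algorithm cannot represent
  digest <- tryCatch(.md5hex(can), error = function(e) NA_character_)
  if (is.na(digest)) {
    .crStop("chemreg_keygen_error",
            sprintf("both InChIKey and fallback key generation failed for %s", can))
  }
  paste0("XK-", digest)
})

#' @rdname molecularWeight
setMethod("molecularWeight", "Molecule", function(mol) {
  atoms <- mol@atoms
  if (!nrow(atoms)) return(0)
  sum(.elementMass(atoms$element, atoms$isotope)) +
    sum(atoms$hcount) * .atomicWeights[["H"]]
})

.elementCounts <- function(mol) {
  atoms <- mol@atoms
  counts <- tapply(rep(1L, nrow(atoms)), atoms$element, sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  h <- sum(atoms$hcount)
  if (h > 0) {
    counts["H"] <- h + if ("H" %in% names(counts)) counts[["H"]] else 0L
  }
  counts[counts > 0L]
}

.hillOrder <- function(counts) {
  els <- names(counts)
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    ord <- c("C", if ("H" %in% els) "H", rest)
  } else {
    ord <- sort(els)
  }
  counts[ord]
}

.formatFormula <- function(counts) {
  counts <- .hillOrder(counts)
  paste0(vapply(seq_along(counts), function(i) {
    paste0(names(counts)[i], if (counts[i] > 1L) counts[i] else "")
  }, character(1)), collapse = "")
}

#' @rdname grossFormula
setMethod("grossFormula", "Molecule", function(mol) {
  .formatFormula(.elementCounts(mol))
})

#' Parse a gross formula string into element counts
#'
#' Accepts any element order (Hill normalisation is applied by the callers
#' that compare formulas); repeated element tokens accumulate.
#'
#' @param formula formula text such as `"C2H6O"` or `"H6C6"`.
#' @return named integer vector of element counts.
#' @export
parseFormula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(trimws(formula))) {
    .crStop("chemreg_parse_error", "formula must be a non-empty string")
  }
  f <- gsub("[[:space:]]+", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  if (sum(attr(m, "match.length")) != nchar(f) || !length(toks)) {
    .crStop("chemreg_parse_error", sprintf("invalid formula text: %s", formula))
  }
  els <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(sub("^[A-Z][a-z]?", "", paste0(toks, "")))
  cnt[is.na(cnt)] <- 1L
  out <- tapply(cnt, els, sum)
  stats::setNames(as.integer(out), names(out))
}

#' @rdname matchFormula
setMethod("matchFormula", "Molecule", function(mol, formula) {
  want <- .hillOrder(parseFormula(formula))
  have <- .hillOrder(.elementCounts(mol))
  identical(names(want), names(have)) && all(want == have)
})
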