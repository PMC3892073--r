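#' @include AllClasses.R AllGenerics.R
#' @useDynLib ChemRegistry, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# byte popcount table, filled in .onLoad
.POPTAB <- vapply(0:255, function(b) sum(bitwAnd(b, 2^(0:7)) > 0), numeric(1))

.rawPopcount <- function(r) as.integer(sum(.POPTAB[as.integer(r) + 1L]))

#' Fingerprint parameters
#'
#' Parameters of the hashed linear-path screening fingerprint. Fingerprints
#' are only comparable (and only valid for screening against each other)
#' when generated with identical parameters; the `id` field is stored with
#' every fingerprint and checked by [similarity()].
#'
#' @param nbits bit vector length; must be a multiple of 8 (default 2048).
#' @param maxlen maximum number of atoms per linear path (default 7).
#' @return list with `nbits`, `maxlen` and the derived `id`.
#' @export
fpParams <- function(nbits = 2048L, maxlen = 7L) {
  nbits <- as.integer(nbits)
  maxlen <- as.integer(maxlen)
  if (nbits < 8L || nbits %% 8L != 0L) {
    .crStop("chemreg_constraint_error", "nbits must be a positive multiple of 8")
  }
  if (maxlen < 1L) .crStop("chemreg_constraint_error", "maxlen must be >= 1")
  list(nbits = nbits, maxlen = maxlen, id = sprintf("lp%d-%d-v1", nbits, maxlen))
}

# integer atom invariant: element, formal charge and aromaticity — exactly
# the attributes the substructure matcher compares, which is what makes the
# fingerprint screen sound (no false negatives)
.atomCodes <- function(mol) {
  atoms <- mol@atoms
  z <- .atomicNumbers[atoms$element]
  z[is.na(z)] <- 119L + match(atoms$element[is.na(z)], unique(atoms$element[is.na(z)]))
  as.integer((z * 64L + (pmax(pmin(atoms$charge, 15L), -15L) + 16L)) * 2L +
               as.integer(atoms$aromatic))
}

.edgeMatrix <- function(mol) {
  b <- mol@bonds
  cbind(as.integer(b$from), as.integer(b$to))
}

#' @rdname fingerprint
setMethod("fingerprint", "Molecule", function(mol, params = fpParams()) {
  bits <- cr_path_bits(.atomCodes(mol), .edgeMatrix(mol),
                       as.integer(mol@bonds$order), params$maxlen, params$nbits)
  logi <- logical(params$nbits)
  logi[bits + 1L] <- TRUE
  new("Fingerprint", bits = packBits(logi, type = "raw"),
      popcount = sum(logi), paramsId = params$id)
})

#' @rdname similarity
setMethod("similarity", signature(a = "Fingerprint", b = "Fingerprint"),
  function(a, b, metric = c("tanimoto", "tversky", "euclid_sub"),
           alpha = 1, beta = 1) {
    metric <- match.arg(metric)
    if (a@paramsId != b@paramsId) {
      .crStop("chemreg_params_mismatch_error",
              sprintf("fingerprint parameters differ: %s vs %s",
                      a@paramsId, b@paramsId))
    }
    if (alpha < 0 || beta < 0) {
      .crStop("chemreg_constraint_error", "alpha and beta must be >= 0")
    }
    na <- a@popcount
    nb <- b@popcount
    nc <- .rawPopcount(a@bits & b@bits)
    den <- switch(metric,
      tanimoto = na + nb - nc,
      tversky = alpha * (na - nc) + beta * (nb - nc) + nc,
      euclid_sub = na
    )
    if (den == 0) return(1) # two empty fingerprints are identical
    nc / den
  })
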