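#' @include AllClasses.R
NULL

#' Molecule accessors
#'
#' `molAtoms` returns the atom table, `molBonds` the bond table and
#' `sourceText` the original input text of a [Molecule-class].
#'
#' @param x a `Molecule`.
#' @return data.frame (atoms/bonds) or character scalar (source text).
#' @rdname molecule-accessors
#' @export
setGeneric("molAtoms", function(x) standardGeneric("molAtoms"))

#' @rdname molecule-accessors
#' @export
setGeneric("molBonds", function(x) standardGeneric("molBonds"))

#' @rdname molecule-accessors
#' @export
setGeneric("sourceText", function(x) standardGeneric("sourceText"))

#' Split a molecule into its connected components
#'
#' One [Molecule-class] per connected component, input order preserved.
#' A connected molecule returns itself as the single element.
#'
#' @param mol a [Molecule-class].
#' @return list of `Molecule`.
#' @examples
#' length(splitComponents(parseStructure("[NH+]1=CC=CC=C1.[Br-]"))) # 2
#' @export
setGeneric("splitComponents", function(mol) standardGeneric("splitComponents"))

#' Structure key (standard InChIKey)
#'
#' The 27-character standard InChIKey of a single-component molecule, used as
#' the unique, immutable identity of stored structures. When the InChI
#' algorithm cannot represent the species, a deterministic fallback key
#' `"XK-" + 32-hex MD5 of the canonical SMILES` preserves the unique-key
#' mechanism.
#'
#' @param mol a single-component [Molecule-class].
#' @return character scalar key.
#' @export
setGeneric("structureKey", function(mol) standardGeneric("structureKey"))

#' Molecular weight
#'
#' Sum of standard atomic weights (embedded IUPAC 2021 abridged table) over
#' all atoms including implicit hydrogens, in g/mol. Isotope-labelled atoms
#' contribute their mass number.
#'
#' @param mol a [Molecule-class].
#' @return numeric scalar, g/mol.
#' @export
setGeneric("molecularWeight", function(mol) standardGeneric("molecularWeight"))

#' Gross formula in Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetical (all
#' alphabetical when no carbon). The formal charge is excluded.
#'
#' @param mol a single-component [Molecule-class].
#' @return character scalar, e.g. `"C2H6O"`.
#' @export
setGeneric("grossFormula", function(mol) standardGeneric("grossFormula"))

#' Canonical SMILES
#'
#' Invariant under input atom ordering and a fixed point under re-parsing.
#'
#' @param mol a [Molecule-class].
#' @return character scalar canonical SMILES.
#' @export
setGeneric("canonicalForm", function(mol) standardGeneric("canonicalForm"))

#' Screening fingerprint of a molecule
#'
#' Hashed linear atom/bond paths of 1..`maxlen` atoms folded into a
#' fixed-length bit vector. The screen is sound for substructure search: if
#' a query embeds into a target (same atom invariants and bond orders) then
#' every query bit is set in the target, so `fp(Q) & fp(T) == fp(Q)`.
#' A multi-component molecule's fingerprint equals the bitwise OR of its
#' components' fingerprints (paths never cross components).
#'
#' @param mol a [Molecule-class].
#' @param params fingerprint parameters from [fpParams()].
#' @return a [Fingerprint-class].
#' @export
setGeneric("fingerprint", function(mol, params = fpParams()) {
  standardGeneric("fingerprint")
})

#' Fingerprint accessors
#'
#' `fpBits` returns the packed bit vector, `fpPopcount` the cached number of
#' set bits and `fpParamsId` the generation parameter identifier of a
#' [Fingerprint-class].
#'
#' @param x a `Fingerprint`.
#' @return raw vector, integer, or character scalar respectively.
#' @rdname fingerprint-accessors
#' @export
setGeneric("fpBits", function(x) standardGeneric("fpBits"))

#' @rdname fingerprint-accessors
#' @export
setGeneric("fpPopcount", function(x) standardGeneric("fpPopcount"))

#' @rdname fingerprint-accessors
#' @export
setGeneric("fpParamsId", function(x) standardGeneric("fpParamsId"))

#' Fingerprint similarity
#'
#' With `a = |A|`, `b = |B|`, `c = |A intersect B|` set-bit counts:
#' `tanimoto = c / (a + b - c)` (the Jaccard index),
#' `tversky = c / (alpha (a - c) + beta (b - c) + c)`, and
#' `euclid_sub = c / a` — the fraction of query bits present in the target,
#' with the query as the first argument. `0/0` is defined as 1 (two empty
#' fingerprints are identical). `tversky(alpha = 1, beta = 1)` equals
#' `tanimoto`; `tversky(alpha = 1, beta = 0)` equals `euclid_sub`.
#'
#' @param a,b [Fingerprint-class] objects with matching `paramsId`.
#' @param metric one of `"tanimoto"`, `"tversky"`, `"euclid_sub"`.
#' @param alpha,beta non-negative Tversky weights.
#' @return score in `[0, 1]`.
#' @export
setGeneric("similarity", function(a, b, metric = c("tanimoto", "tversky", "euclid_sub"),
                                  alpha = 1, beta = 1) {
  standardGeneric("similarity")
})

#' Substructure match (verification)
#'
#' Subgraph-monomorphism semantics respecting element, aromaticity, formal
#' charge and bond order; implicit hydrogens on the query do not constrain
#' the target. Extra target bonds between mapped atoms are allowed, so a
#' propane chain matches cyclopropane.
#'
#' @param target a [Molecule-class].
#' @param query a [Molecule-class] (or SMILES text) parsed as a relaxed
#'   pattern.
#' @return a [MatchResult-class] holding one embedding's atom set.
#' @export
setGeneric("matchSubstructure", function(target, query) {
  standardGeneric("matchSubstructure")
})

#' Exact structure match
#'
#' True iff both single-component molecules have the same structure key.
#'
#' @param target,query single-component [Molecule-class] objects.
#' @return logical scalar.
#' @export
setGeneric("matchExact", function(target, query) standardGeneric("matchExact"))

#' SMARTS match
#'
#' SMARTS semantics of the OpenBabel dialect (atom/bond primitives and
#' logical operators).
#'
#' @param target a [Molecule-class].
#' @param smarts SMARTS text or a [SmartsPattern-class].
#' @return logical scalar.
#' @export
setGeneric("matchSmarts", function(target, smarts) standardGeneric("matchSmarts"))

#' Gross formula match
#'
#' True iff the element-count multiset of the molecule (including implicit
#' hydrogens) equals that of the formula text; both sides are Hill
#' normalised first, so `"H6C6"` matches benzene.
#'
#' @param mol a [Molecule-class].
#' @param formula formula text such as `"C2H6O"`.
#' @return logical scalar.
#' @export
setGeneric("matchFormula", function(mol, formula) standardGeneric("matchFormula"))

#' Page accessors
#'
#' `pageItems` returns the result rows of the page, `totalCount` the total
#' number of rows of the whole query and `countFromCache` whether that total
#' was served from the count cache.
#'
#' @param x a `Page`.
#' @return data.frame, integer, or logical respectively.
#' @rdname page-accessors
#' @export
setGeneric("pageItems", function(x) standardGeneric("pageItems"))

#' @rdname page-accessors
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' @rdname page-accessors
#' @export
setGeneric("countFromCache", function(x) standardGeneric("countFromCache"))
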