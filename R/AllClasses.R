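#' Molecule: a parsed chemical graph
#'
#' Heavy atoms carry element symbol, formal charge, isotope mass number
#' (0 = natural abundance), implicit hydrogen count and an aromaticity flag;
#' bonds carry 1-based atom indices and an order in 1, 2, 3 or 4 (aromatic).
#' Hydrogens written explicitly in the input are folded into the implicit
#' count of their heavy neighbour (an all-hydrogen species such as `[H][H]`
#' keeps its H atoms as graph atoms).
#'
#' @slot atoms data.frame with columns `element`, `charge`, `isotope`,
#'   `hcount`, `aromatic`.
#' @slot bonds data.frame with columns `from`, `to`, `order`.
#' @slot sourceText the original input text.
#' @slot canonicalSmiles canonical SMILES, `NA` until computed.
#' @aliases Molecule
#' @exportClass Molecule
setClass("Molecule",
  representation(
    atoms = "data.frame",
    bonds = "data.frame",
    sourceText = "character",
    canonicalSmiles = "character"
  ),
  prototype(
    atoms = data.frame(
      element = character(), charge = integer(), isotope = integer(),
      hcount = integer(), aromatic = logical(), stringsAsFactors = FALSE
    ),
    bonds = data.frame(from = integer(), to = integer(), order = integer()),
    sourceText = NA_character_,
    canonicalSmiles = NA_character_
  ),
  validity = function(object) {
    n <- nrow(object@atoms)
    b <- object@bonds
    msgs <- character()
    need <- c("element", "charge", "isotope", "hcount", "aromatic")
    if (!all(need %in% names(object@atoms))) {
      msgs <- c(msgs, "atoms must have element/charge/isotope/hcount/aromatic")
    }
    if (nrow(b)) {
      if (any(b$from < 1L | b$from > n | b$to < 1L | b$to > n)) {
        msgs <- c(msgs, "bond atom indices out of range")
      }
      if (any(b$from == b$to)) msgs <- c(msgs, "bonds must connect distinct atoms")
      if (any(!b$order %in% 1:4)) msgs <- c(msgs, "bond order must be in 1..4")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' SMARTS query pattern
#'
#' A validated SMARTS pattern usable with [matchSmarts()] and the `smarts`
#' search mode. SMARTS patterns are query-only objects: they are not
#' molecules and have no structure key or weight.
#'
#' @slot pattern the SMARTS text.
#' @exportClass SmartsPattern
setClass("SmartsPattern", representation(pattern = "character"))

#' Screening fingerprint
#'
#' Fixed-length bit vector derived from hashed linear atom/bond paths, used
#' as a necessary-condition screen before substructure verification and as
#' the basis of similarity scores.
#'
#' @slot bits raw vector packing the bit vector (8 bits per byte).
#' @slot popcount cached number of set bits.
#' @slot paramsId identifier of the generation parameters; fingerprints are
#'   only comparable when it matches.
#' @exportClass Fingerprint
setClass("Fingerprint",
  representation(bits = "raw", popcount = "integer", paramsId = "character"),
  validity = function(object) {
    pc <- sum(.POPTAB[as.integer(object@bits) + 1L])
    if (pc != object@popcount) "popcount does not match bits" else TRUE
  }
)

#' Substructure match result
#'
#' @slot matched logical.
#' @slot atomMap 1-based target atom indices covered by one embedding of the
#'   query (empty when unmatched).
#' @exportClass MatchResult
setClass("MatchResult",
  representation(matched = "logical", atomMap = "integer"))

#' Compound store
#'
#' The in-process registration database: structure, compound, composition,
#' containable, container, role and user tables plus the count cache,
#' instrumentation counters and configuration. Create with [chemStore()] or
#' [openStore()]; all registry and search operations take a ChemStore as
#' their first argument. The object has reference semantics (its tables live
#' in an environment), like a database connection.
#'
#' @slot .env environment holding the tables and bookkeeping.
#' @exportClass ChemStore
setClass("ChemStore", representation(.env = "environment"))

#' Structure query
#'
#' The chemical part of a search: a mode (`exact`, `sub`, `smarts`,
#' `similarity`, `formula`), the query text, similarity metric settings and
#' optional molecular weight bounds applied to the matching component.
#'
#' @slot mode search mode.
#' @slot queryText SMILES, SMARTS or formula text.
#' @slot metric one of `tanimoto`, `tversky`, `euclid_sub`.
#' @slot alpha,beta Tversky weights.
#' @slot minScore,maxScore inclusive similarity bounds in `[0, 1]`.
#' @slot mwMin,mwMax optional molecular weight bounds in g/mol.
#' @exportClass StructureQuery
setClass("StructureQuery",
  representation(
    mode = "character", queryText = "character", metric = "character",
    alpha = "numeric", beta = "numeric",
    minScore = "numeric", maxScore = "numeric",
    mwMin = "numeric", mwMax = "numeric"
  ),
  validity = function(object) {
    msgs <- character()
    if (!object@mode %in% c("exact", "sub", "smarts", "similarity", "formula")) {
      msgs <- c(msgs, "mode must be exact/sub/smarts/similarity/formula")
    }
    if (!object@metric %in% c("tanimoto", "tversky", "euclid_sub")) {
      msgs <- c(msgs, "metric must be tanimoto/tversky/euclid_sub")
    }
    if (object@minScore > object@maxScore) msgs <- c(msgs, "minScore > maxScore")
    if (!is.na(object@mwMin) && !is.na(object@mwMax) && object@mwMin > object@mwMax) {
      msgs <- c(msgs, "mwMin > mwMax")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' Search request
#'
#' A combined structure + property query against one target type, with
#' sorting, 0-based paging and the mixture-aware distinct flag. When
#' `distinct` is `NA` the store-wide default applies (see
#' [setDistinctDefault()]).
#'
#' @slot target a registered compound type, `containable:<type>`, or
#'   `container`.
#' @slot structure a [StructureQuery-class] or `NULL`.
#' @slot filters list of `list(field=, op=, value=)` with op one of `eq`,
#'   `like-prefix`, `range`.
#' @slot sort list of `c(field, "asc"|"desc")`; id ascending is always
#'   appended as the deterministic tie-break.
#' @slot pageIndex 0-based page index.
#' @slot pageSize records per page (default 4).
#' @slot distinct logical or `NA` (use store default).
#' @exportClass SearchRequest
setClass("SearchRequest",
  representation(
    target = "character", structure = "ANY", filters = "list",
    sort = "list", pageIndex = "integer", pageSize = "integer",
    distinct = "logical"
  ),
  validity = function(object) {
    msgs <- character()
    if (object@pageIndex < 0L) msgs <- c(msgs, "pageIndex must be >= 0")
    if (object@pageSize < 1L) msgs <- c(msgs, "pageSize must be >= 1")
    if (!is.null(object@structure) && !is(object@structure, "StructureQuery")) {
      msgs <- c(msgs, "structure must be a StructureQuery or NULL")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' One page of search results
#'
#' @slot items data.frame of result rows (at most `pageSize`).
#' @slot pageIndex,pageSize paging position.
#' @slot totalCount total number of rows of the whole query.
#' @slot countFromCache whether `totalCount` was served from the count cache.
#' @slot plan the [PlanDecision-class] used, or `NULL` when no planning
#'   applied.
#' @exportClass Page
setClass("Page",
  representation(
    items = "data.frame", pageIndex = "integer", pageSize = "integer",
    totalCount = "integer", countFromCache = "logical", plan = "ANY"
  ))

#' Query plan decision
#'
#' Whether a structure search screens the whole structure index
#' (`INDEX_SCREEN`) or fetches candidates by property filter first and
#' verifies each with the substructure matcher (`PROPERTY_FIRST`).
#'
#' @slot strategy `"INDEX_SCREEN"` or `"PROPERTY_FIRST"`.
#' @slot estimatedCandidates estimated number of property-filter candidates.
#' @exportClass PlanDecision
setClass("PlanDecision",
  representation(strategy = "character", estimatedCandidates = "numeric"))

#' Security context
#'
#' Read filtering and write guards are permissive when `enabled` is `FALSE`
#' (every user sees everything); when enabled, rows are readable iff their
#' `read_role` is null or among the user's roles.
#'
#' @slot enabled logical.
#' @slot user user name.
#' @slot roles the user's role names.
#' @exportClass SecurityContext
setClass("SecurityContext",
  representation(enabled = "logical", user = "character", roles = "character"))

#' Outcome of a registry save
#'
#' @slot record the persisted record (named list; compounds include their
#'   compositions).
#' @slot structuresCreated number of new structure rows the save inserted.
#' @slot structuresReused number of existing structure rows reused by
#'   InChIKey lookup.
#' @exportClass SaveOutcome
setClass("SaveOutcome",
  representation(record = "list", structuresCreated = "integer",
                 structuresReused = "integer"))

#' SD-file import report
#'
#' @slot recordsRead,compoundsCreated,structuresCreated,structuresReused counts.
#' @slot failures list of `list(index=, reason=)` for records that failed
#'   under the `skip` policy.
#' @exportClass ImportReport
setClass("ImportReport",
  representation(
    recordsRead = "integer", compoundsCreated = "integer",
    structuresCreated = "integer", structuresReused = "integer",
    failures = "list"
  ))

#' Fixture generator specification
#'
#' @slot nCompounds number of SD records to generate.
#' @slot mixtureFraction fraction of records that are mixtures (exact by
#'   construction).
#' @slot maxHeavyAtoms upper bound on heavy atoms per main component.
#' @slot seed RNG seed; the same spec yields byte-identical SD output.
#' @slot namePrefix prefix of generated compound names.
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(
    nCompounds = "integer", mixtureFraction = "numeric",
    maxHeavyAtoms = "integer", seed = "integer", namePrefix = "character"
  ),
  validity = function(object) {
    if (object@mixtureFraction < 0 || object@mixtureFraction > 1) {
      "mixtureFraction must be in [0, 1]"
    } else if (object@nCompounds < 1L) {
      "nCompounds must be >= 1"
    } else TRUE
  }
)
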