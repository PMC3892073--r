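#' @include registry.R
NULL

#' Build a structure query
#'
#' @param mode `"exact"`, `"sub"`, `"smarts"`, `"similarity"` or `"formula"`.
#' @param query SMILES (exact/sub/similarity), SMARTS or formula text.
#' @param metric similarity metric (`similarity` mode).
#' @param alpha,beta Tversky weights.
#' @param minScore,maxScore inclusive similarity bounds.
#' @param mwMin,mwMax optional molecular weight bounds (g/mol) on the
#'   matching component.
#' @return a [StructureQuery-class].
#' @export
structureQuery <- function(mode, query, metric = "tanimoto", alpha = 1, beta = 1,
                           minScore = 0, maxScore = 1,
                           mwMin = NA_real_, mwMax = NA_real_) {
  new("StructureQuery", mode = mode, queryText = query, metric = metric,
      alpha = alpha, beta = beta, minScore = minScore, maxScore = maxScore,
      mwMin = as.numeric(mwMin), mwMax = as.numeric(mwMax))
}

#' Build a search request
#'
#' @param target a registered compound type (e.g. `"Compound"`),
#'   `"containable:<type>"`, or `"container"`.
#' @param structure a [StructureQuery-class] or `NULL`.
#' @param filters list of `list(field=, op=, value=)`; `op` is `"eq"`,
#'   `"like-prefix"` or `"range"` (value = `c(lo, hi)`).
#' @param sort list of `c(field, "asc"|"desc")`; id ascending is always
#'   appended as tie-break, and is the default sort when empty.
#' @param pageIndex 0-based page index.
#' @param pageSize page size (default 4 records per page).
#' @param distinct `TRUE` (each compound at most once), `FALSE` (one row per
#'   matching component) or `NA` (store default).
#' @return a [SearchRequest-class].
#' @export
searchRequest <- function(target = "Compound", structure = NULL, filters = list(),
                          sort = list(), pageIndex = 0L, pageSize = 4L,
                          distinct = NA) {
  new("SearchRequest", target = target, structure = structure, filters = filters,
      sort = sort, pageIndex = as.integer(pageIndex),
      pageSize = as.integer(pageSize), distinct = as.logical(distinct))
}

# ---- filters -----------------------------------------------------------------

.checkFields <- function(tbl, request) {
  fields <- c(
    vapply(request@filters, function(f) f$field, character(1)),
    vapply(request@sort, function(s) s[[1]], character(1))
  )
  miss <- setdiff(fields, names(tbl))
  if (length(miss)) {
    .crStop("chemreg_unknown_field_error",
            sprintf("unknown field(s) on target '%s': %s",
                    request@target, paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

.applyFilters <- function(tbl, filters) {
  keep <- rep(TRUE, nrow(tbl))
  for (f in filters) {
    v <- tbl[[f$field]]
    keep <- keep & switch(f$op,
      "eq" = !is.na(v) & v == f$value,
      "like-prefix" = !is.na(v) & startsWith(as.character(v), as.character(f$value)),
      "range" = !is.na(v) & v >= f$value[1] & v <= f$value[2],
      .crStop("chemreg_constraint_error", sprintf("unknown filter op: %s", f$op))
    )
  }
  keep
}

.orderRows <- function(rows, sort) {
  keys <- list()
  for (s in sort) {
    v <- xtfrm(rows[[s[[1]]]])
    if (length(s) > 1L && identical(s[[2]], "desc")) v <- -v
    keys[[length(keys) + 1L]] <- v
  }
  keys[[length(keys) + 1L]] <- rows$id
  if (!is.null(rows$structure_id)) keys[[length(keys) + 1L]] <- rows$structure_id
  rows[do.call(order, keys), , drop = FALSE]
}

# ---- structure predicate over the structure table ------------------------------

.hexToRaw <- function(s) {
  n <- nchar(s)
  as.raw(strtoi(substring(s, seq(1L, n, 2L), seq(2L, n, 2L)), 16L))
}

.structureFp <- function(store, sid, hex) {
  env <- store@.env
  k <- as.character(sid)
  fp <- env$fps[[k]]
  if (is.null(fp)) {
    fp <- .hexToRaw(hex)
    env$fps[[k]] <- fp
  }
  fp
}

# ids of structures satisfying the structure query (optionally restricted to
# a candidate set); also reports how many molecules were run through the
# verifier
.structureMatchIds <- function(store, sq, sids = NULL) {
  st <- .tbl(store, "structures")
  if (!is.null(sids)) st <- st[st$id %in% sids, , drop = FALSE]
  if (!is.na(sq@mwMin)) st <- st[st$mol_weight >= sq@mwMin - 1e-9, , drop = FALSE]
  if (!is.na(sq@mwMax)) st <- st[st$mol_weight <= sq@mwMax + 1e-9, , drop = FALSE]
  verified <- 0L
  if (!nrow(st)) return(list(ids = integer(), verified = verified))
  fpp <- do.call(fpParams, store@.env$config$fingerprint[c("nbits", "maxlen")])

  ids <- switch(sq@mode,
    "exact" = {
      qmol <- parseStructure(sq@queryText)
      qkeys <- vapply(splitComponents(qmol), structureKey, character(1))
      st$id[st$structure_key %in% qkeys]
    },
    "formula" = {
      want <- .formatFormula(parseFormula(sq@queryText))
      st$id[st$formula == want]
    },
    "similarity" = {
      qfp <- fingerprint(parseStructure(sq@queryText), fpp)
      qb <- qfp@bits
      qn <- qfp@popcount
      score <- vapply(seq_len(nrow(st)), function(i) {
        tb <- .structureFp(store, st$id[i], st$fp_hex[i])
        tn <- .rawPopcount(tb)
        cn <- .rawPopcount(qb & tb)
        den <- switch(sq@metric,
          tanimoto = qn + tn - cn,
          tversky = sq@alpha * (qn - cn) + sq@beta * (tn - cn) + cn,
          euclid_sub = qn
        )
        if (den == 0) 1 else cn / den
      }, numeric(1))
      st$id[score >= sq@minScore - 1e-12 & score <= sq@maxScore + 1e-12]
    },
    "sub" = {
      qmol <- parseStructure(sq@queryText)
      qfp <- fingerprint(qmol, fpp)
      qb <- qfp@bits
      pass <- vapply(seq_len(nrow(st)), function(i) {
        tb <- .structureFp(store, st$id[i], st$fp_hex[i])
        identical(qb & tb, qb)
      }, logical(1))
      cand <- which(pass)
      verified <- length(cand)
      hits <- vapply(cand, function(i) {
        matchSubstructure(.structureGraph(store, st$id[i]), qmol)@matched
      }, logical(1))
      st$id[cand[hits]]
    },
    "smarts" = {
      pat <- parseStructure(sq@queryText, format = "smarts")
      verified <- nrow(st)
      hits <- vapply(seq_len(nrow(st)), function(i) {
        matchSmarts(.structureGraph(store, st$id[i]), pat)
      }, logical(1))
      st$id[hits]
    },
    .crStop("chemreg_constraint_error", sprintf("unknown search mode: %s", sq@mode))
  )
  list(ids = ids, verified = verified)
}

# ---- planner -------------------------------------------------------------------

#' Plan a structure search
#'
#' Decides between screening the whole structure index (`INDEX_SCREEN`) and
#' fetching candidates by property index first, verifying each candidate
#' with the substructure matcher (`PROPERTY_FIRST`). `PROPERTY_FIRST` is
#' chosen only when a property filter exists and its estimated candidate
#' count is at most `tau` times the table plus at most `nMax` rows —
#' the regime where per-candidate verification beats a full index scan.
#'
#' @param request a [SearchRequest-class] with a structure query.
#' @param stats [tableStats()] output.
#' @param tau maximum candidate fraction for `PROPERTY_FIRST` (default 0.05).
#' @param nMax maximum absolute candidate count (default 5000).
#' @return a [PlanDecision-class].
#' @export
planSearch <- function(request, stats, tau = 0.05, nMax = 5000L) {
  tn <- if (request@target == "container") {
    "containers"
  } else if (startsWith(request@target, "containable:")) {
    paste0("containables_", sub("^containable:", "", request@target))
  } else {
    paste0("compounds_", request@target)
  }
  rows <- stats$tables$rows[stats$tables$table == tn]
  if (!length(rows)) rows <- 0L
  if (!length(request@filters) || rows == 0L) {
    return(new("PlanDecision", strategy = "INDEX_SCREEN",
               estimatedCandidates = as.numeric(rows)))
  }
  frac <- 1
  for (f in request@filters) {
    key <- paste(tn, f$field, sep = ".")
    fr <- if (f$op == "eq") {
      d <- stats$columns$distinct[stats$columns$table == tn &
                                    stats$columns$column == f$field]
      if (length(d) && d > 0) 1 / d else 1
    } else if (f$op == "like-prefix") {
      pb <- stats$prefixBuckets[[key]]
      if (is.null(pb)) {
        1
      } else {
        val <- as.character(f$value)
        bl <- stats$bucketLen
        cnt <- if (nchar(val) >= bl) {
          b <- pb[substr(val, 1L, bl)]
          if (is.na(b)) 0 else as.numeric(b)
        } else {
          sum(pb[startsWith(names(pb), val)])
        }
        # prefixes longer than the bucket resolution thin out further
        (cnt / rows) * 10^(-max(0L, nchar(val) - bl))
      }
    } else if (f$op == "range") {
      rng <- stats$prefixBuckets[[key]]
      if (is.numeric(rng) && all(c("min", "max") %in% names(rng)) &&
          rng[["max"]] > rng[["min"]]) {
        w <- (min(f$value[2], rng[["max"]]) - max(f$value[1], rng[["min"]])) /
          (rng[["max"]] - rng[["min"]])
        max(0, min(1, w))
      } else 0.3
    } else 1
    frac <- frac * max(0, min(1, fr))
  }
  est <- ceiling(frac * rows)
  strategy <- if (est <= tau * rows && est <= nMax) "PROPERTY_FIRST" else "INDEX_SCREEN"
  new("PlanDecision", strategy = strategy, estimatedCandidates = as.numeric(est))
}

# ---- count cache ---------------------------------------------------------------

.countCacheKey <- function(store, request, distinct, ctx) {
  sq <- request@structure
  sqKey <- if (is.null(sq)) {
    "-"
  } else {
    qt <- sq@queryText
    if (sq@mode %in% c("exact", "sub", "similarity")) {
      can <- .obCanonical("SMI", .stripSmilesWhitespace(qt))
      if (!is.na(can)) qt <- can
    } else if (sq@mode == "formula") {
      qt <- tryCatch(.formatFormula(parseFormula(qt)), error = function(e) qt)
    }
    paste(sq@mode, qt, sq@metric, sq@alpha, sq@beta, sq@minScore, sq@maxScore,
          sq@mwMin, sq@mwMax, sep = "|")
  }
  fKey <- paste(vapply(request@filters, function(f) {
    paste(f$field, f$op, paste(f$value, collapse = ".."), sep = ":")
  }, character(1)), collapse = ";")
  roleKey <- if (ctx@enabled) {
    paste(sort(ctx@roles), collapse = ",")
  } else "*"
  paste(request@target, sqKey, fKey, distinct, roleKey, sep = "||")
}

.cachedCount <- function(store, key, nrows) {
  env <- store@.env
  hit <- env$cache[[key]]
  if (!is.null(hit)) {
    return(list(count = hit, fromCache = TRUE))
  }
  env$counters$count_computations <- env$counters$count_computations + 1L
  .crLog(store, "debug", sprintf("count computed for %s: %d", key, nrows))
  env$cache[[key]] <- as.integer(nrows)
  list(count = as.integer(nrows), fromCache = FALSE)
}

# ---- search --------------------------------------------------------------------

#' Search compounds, containables or containers
#'
#' A compound matches when at least one of its component structures
#' satisfies the structure query (including the molecular weight bounds) and
#' the compound satisfies every property filter. With `distinct = TRUE`
#' every compound appears at most once; with `distinct = FALSE` the result
#' has one row for every matching component of a compound, so mixtures with
#' several matching components contribute several rows. Results are sorted
#' (id ascending is always the final tie-break), the requested page is
#' sliced, and the total count is served from the count cache when the same
#' logical query was already counted; any write clears the cache. When
#' security is enabled, the read-role predicate is composed into the query —
#' hidden rows are absent from the items and from `totalCount`.
#'
#' @param store a [ChemStore-class].
#' @param request a [SearchRequest-class].
#' @param user user name for read filtering, or `NULL`.
#' @return a [Page-class].
#' @export
searchCompounds <- function(store, request, user = NULL) {
  validObject(request)
  if (request@target == "container" || startsWith(request@target, "containable:")) {
    return(.searchViaContainers(store, request, user))
  }
  type <- .checkType(store, request@target)
  ctab <- .tbl(store, paste0("compounds_", type))
  .checkFields(ctab, request)
  ctx <- securityContext(store, user)
  pred <- readablePredicate(ctx, "compound")
  keep <- pred(ctab$read_role) & .applyFilters(ctab, request@filters)
  distinct <- if (is.na(request@distinct)) {
    isTRUE(store@.env$config$distinct_default)
  } else request@distinct
  sq <- request@structure
  plan <- NULL

  if (is.null(sq)) {
    rows <- ctab[keep, , drop = FALSE]
  } else {
    if (sq@mode %in% c("sub", "smarts")) {
      cfgP <- store@.env$config$planner
      plan <- planSearch(request, tableStats(store),
                         tau = cfgP$tau, nMax = cfgP$n_max)
      .crLog(store, "debug",
             sprintf("plan: %s (estimated candidates %s) for %s '%s'",
                     plan@strategy, format(plan@estimatedCandidates),
                     sq@mode, sq@queryText))
    }
    comp <- .tbl(store, "compositions")
    comp <- comp[comp$compound_type == type & comp$compound_id %in% ctab$id[keep], ,
                 drop = FALSE]
    if (!is.null(plan) && plan@strategy == "PROPERTY_FIRST") {
      sm <- .structureMatchIds(store, sq, sids = unique(comp$structure_id))
    } else {
      sm <- .structureMatchIds(store, sq)
    }
    store@.env$counters$last_verified <- sm$verified
    comp <- comp[comp$structure_id %in% sm$ids, , drop = FALSE]
    rows <- ctab[match(comp$compound_id, ctab$id), , drop = FALSE]
    st <- .tbl(store, "structures")
    rows$structure_id <- comp$structure_id
    rows$structure_key <- st$structure_key[match(comp$structure_id, st$id)]
    rows$percentage <- comp$percentage
    if (distinct) {
      rows <- rows[!duplicated(rows$id), , drop = FALSE]
      rows$structure_id <- NULL
      rows$structure_key <- NULL
      rows$percentage <- NULL
    }
  }
  rows <- .orderRows(rows, request@sort)
  rownames(rows) <- NULL
  cc <- .cachedCount(store, .countCacheKey(store, request, distinct, ctx), nrow(rows))
  lo <- request@pageIndex * request@pageSize + 1L
  hi <- min(nrow(rows), lo + request@pageSize - 1L)
  items <- if (lo <= nrow(rows)) rows[lo:hi, , drop = FALSE] else rows[0, , drop = FALSE]
  rownames(items) <- NULL
  new("Page", items = items, pageIndex = request@pageIndex,
      pageSize = request@pageSize, totalCount = cc$count,
      countFromCache = cc$fromCache, plan = plan)
}

#' Total count of a search, using the count cache
#'
#' The count is computed the first time a logical query (paging aside) runs
#' and cached; subsequent requests reuse the cached value until a write
#' clears the cache.
#'
#' @inheritParams searchCompounds
#' @return integer total count.
#' @export
countResults <- function(store, request, user = NULL) {
  totalCount(searchCompounds(store, request, user = user))
}

#' Search bar-coded containers
#'
#' Convenience wrapper for [searchCompounds()] with target `"container"`:
#' the structure query applies to the compound reachable through the
#' container's containable, and when security is enabled both the
#' containable's and the compound's read role must be readable.
#'
#' @inheritParams searchCompounds
#' @return a [Page-class] of container rows.
#' @export
searchContainers <- function(store, request, user = NULL) {
  request@target <- "container"
  searchCompounds(store, request, user = user)
}

# containers / containables share the join logic: container -> containable ->
# compound; both read roles must pass (conjunction)
.searchViaContainers <- function(store, request, user) {
  isContainer <- request@target == "container"
  ctx <- securityContext(store, user)
  pred <- readablePredicate(ctx, "container")

  if (isContainer) {
    base <- .tbl(store, "containers")
    ctypes <- base$containable_type
    cids <- base$containable_id
  } else {
    ctype <- sub("^containable:", "", request@target)
    .checkType(store, ctype)
    base <- .tbl(store, paste0("containables_", ctype))
    ctypes <- rep(ctype, nrow(base))
    cids <- base$id
  }
  .checkFields(base, request)

  compoundType <- character(nrow(base))
  compoundId <- rep(NA_integer_, nrow(base))
  readOk <- rep(FALSE, nrow(base))
  for (ty in .compoundTypes(store)) {
    sel <- which(ctypes == ty)
    if (!length(sel)) next
    cont <- .tbl(store, paste0("containables_", ty))
    m <- match(cids[sel], cont$id)
    compoundType[sel] <- ty
    compoundId[sel] <- cont$compound_id[m]
    contRole <- cont$read_role[m]
    ctab <- .tbl(store, paste0("compounds_", ty))
    cmpRole <- ctab$read_role[match(cont$compound_id[m], ctab$id)]
    ok <- pred(contRole) & pred(cmpRole)
    if (isContainer) {
      readOk[sel] <- !is.na(m) & ok
    } else {
      readOk[sel] <- pred(base$read_role[sel]) & pred(cmpRole)
    }
  }
  keep <- readOk & .applyFilters(base, request@filters)

  distinct <- if (is.na(request@distinct)) {
    isTRUE(store@.env$config$distinct_default)
  } else request@distinct
  sq <- request@structure

  rows <- base[keep, , drop = FALSE]
  rows$compound_type <- compoundType[keep]
  rows$compound_id <- compoundId[keep]
  if (!is.null(sq)) {
    sm <- .structureMatchIds(store, sq)
    store@.env$counters$last_verified <- sm$verified
    comp <- .tbl(store, "compositions")
    comp <- comp[comp$structure_id %in% sm$ids, , drop = FALSE]
    compKey <- paste(comp$compound_type, comp$compound_id)
    rowKey <- paste(rows$compound_type, rows$compound_id)
    hits <- lapply(seq_len(nrow(rows)), function(i) {
      which(compKey == rowKey[i])
    })
    idx <- rep(seq_len(nrow(rows)), lengths(hits))
    rows <- rows[idx, , drop = FALSE]
    rows$structure_id <- comp$structure_id[unlist(hits)]
    if (distinct) {
      rows <- rows[!duplicated(rows$id), , drop = FALSE]
      rows$structure_id <- NULL
    }
  }
  rows <- .orderRows(rows, request@sort)
  rownames(rows) <- NULL
  cc <- .cachedCount(store, .countCacheKey(store, request, distinct, ctx), nrow(rows))
  lo <- request@pageIndex * request@pageSize + 1L
  hi <- min(nrow(rows), lo + request@pageSize - 1L)
  items <- if (lo <= nrow(rows)) rows[lo:hi, , drop = FALSE] else rows[0, , drop = FALSE]
  rownames(items) <- NULL
  new("Page", items = items, pageIndex = request@pageIndex,
      pageSize = request@pageSize, totalCount = cc$count,
      countFromCache = cc$fromCache, plan = NULL)
}

#' Find compounds by CAS number
#'
#' CAS numbers are nullable and not unique, so several compounds may share
#' one; a null CAS never matches.
#'
#' @param store a [ChemStore-class].
#' @param cas CAS number text.
#' @param type compound type.
#' @return data.frame of matching compound rows.
#' @export
findByCas <- function(store, cas, type = "Compound") {
  .checkType(store, type)
  tbl <- .tbl(store, paste0("compounds_", type))
  if (is.null(cas) || is.na(cas)) return(tbl[0, , drop = FALSE])
  out <- tbl[!is.na(tbl$cas) & tbl$cas == cas, , drop = FALSE]
  rownames(out) <- NULL
  out
}
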