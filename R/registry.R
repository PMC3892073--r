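#' @include store.R match.R security.R
NULL

#' Create a compound draft
#'
#' The input to [saveCompound()] and [updateCompound()]. Compositions are
#' given as structure text: a plain character vector (no percentages), or a
#' list of `list(text=, percentage=)`. A single text with several
#' disconnected components (a salt or other mixture) is expanded into one
#' composition per distinct component with the percentage unset.
#'
#' @param compoundName compound name.
#' @param compositions character vector of structure texts, or list of
#'   `list(text=, percentage=)`.
#' @param cas CAS number; nullable, duplicates allowed.
#' @param readRole read role name or `NA` (world-readable).
#' @param extra named list of extra registered field values.
#' @param type registered compound type.
#' @param id,expectedVersion target id and expected version, for updates.
#' @return a `compoundDraft` list.
#' @export
compoundDraft <- function(compoundName, compositions, cas = NA_character_,
                          readRole = NA_character_, extra = list(),
                          type = "Compound", id = NA_integer_,
                          expectedVersion = NA_integer_) {
  if (is.character(compositions)) {
    compositions <- lapply(compositions, function(t) list(text = t, percentage = NA_real_))
  }
  if (!length(compositions)) {
    .crStop("chemreg_constraint_error", "a compound draft needs at least one composition")
  }
  structure(
    list(
      compoundName = compoundName, compositions = compositions, cas = cas,
      readRole = readRole, extra = extra, type = type, id = id,
      expectedVersion = expectedVersion
    ),
    class = "compoundDraft"
  )
}

# ---- hooks -------------------------------------------------------------------

#' Register a pre-save hook
#'
#' The hook runs inside the save transaction before any compound (or
#' containable/container) of that kind is created or updated, and may freely
#' rewrite the draft — the extension point for structure normalisation, salt
#' stripping or default-filling, none of which the registry does by itself
#' (structures are stored exactly as submitted). One hook per kind; a later
#' registration replaces the earlier one, `NULL` removes it. A hook error
#' aborts the save and leaves the store unchanged.
#'
#' @param store a [ChemStore-class].
#' @param kind `"compound"`, `"containable"` or `"container"`.
#' @param hook `function(draft) draft`, or `NULL`.
#' @return the store, invisibly.
#' @export
registerPreSaveHook <- function(store, kind = c("compound", "containable", "container"),
                                hook) {
  kind <- match.arg(kind)
  if (is.null(hook)) {
    if (!is.null(store@.env$hooks[[kind]])) rm(list = kind, envir = store@.env$hooks)
  } else {
    store@.env$hooks[[kind]] <- hook
  }
  invisible(store)
}

.runHook <- function(store, kind, draft) {
  hook <- store@.env$hooks[[kind]]
  if (is.null(hook)) draft else hook(draft)
}

# ---- structure resolution (dedup + immutability) ------------------------------

.structureFromMolecule <- function(store, mol, actor) {
  key <- structureKey(mol)
  tbl <- .tbl(store, "structures")
  hit <- which(tbl$structure_key == key)
  if (length(hit)) {
    return(list(id = tbl$id[hit[1]], created = FALSE, key = key))
  }
  fpp <- do.call(fpParams, store@.env$config$fingerprint[c("nbits", "maxlen")])
  fp <- fingerprint(mol, fpp)
  row <- storeInsert(store, "structures", list(
    structure_text = canonicalForm(mol),
    structure_key = key,
    mol_weight = molecularWeight(mol),
    formula = grossFormula(mol),
    fp_hex = paste(as.character(fp@bits), collapse = ""),
    fp_params = fp@paramsId
  ), actor = actor)
  sid <- row$id[1]
  env <- store@.env
  .txnUndo(store, local({
    s <- as.character(sid)
    function() if (!is.null(env$graphs[[s]])) rm(list = s, envir = env$graphs)
  }))
  env$graphs[[as.character(sid)]] <- mol
  list(id = sid, created = TRUE, key = key)
}

# expand draft compositions into distinct structure rows; a multi-component
# text becomes one composition per distinct component without percentages
.resolveCompositions <- function(store, compositions, actor) {
  out <- list()
  created <- 0L
  reused <- 0L
  seen <- character()
  for (entry in compositions) {
    mol <- .asMolecule(entry$text)
    comps <- splitComponents(mol)
    pct <- if (length(comps) > 1L) NA_real_ else entry$percentage
    for (cm in comps) {
      res <- .structureFromMolecule(store, cm, actor)
      if (res$key %in% seen) next # duplicate component collapses
      seen <- c(seen, res$key)
      if (res$created) created <- created + 1L else reused <- reused + 1L
      out[[length(out) + 1L]] <- list(structure_id = res$id, percentage = pct)
    }
  }
  pcts <- vapply(out, function(x) x$percentage %||% NA_real_, numeric(1))
  bad <- !is.na(pcts) & (pcts <= 0 | pcts > 100)
  if (any(bad)) {
    .crStop("chemreg_constraint_error", "percentages must lie in (0, 100]")
  }
  if (sum(pcts, na.rm = TRUE) > 100 + 1e-9) {
    .crStop("chemreg_constraint_error", "composition percentages sum to more than 100")
  }
  list(compositions = out, created = created, reused = reused)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- uniqueness policies -------------------------------------------------------

.findExistingCompound <- function(store, type, draft, excludeId = NA_integer_) {
  policy <- store@.env$config$uniqueness[[type]] %||% "none"
  tbl <- .tbl(store, paste0("compounds_", type))
  if (is.function(policy)) return(policy(store, type, draft, excludeId))
  if (identical(policy, "none")) return(NULL)
  if (identical(policy, "by-cas")) {
    if (is.na(draft$cas)) return(NULL)
    hit <- which(!is.na(tbl$cas) & tbl$cas == draft$cas)
    if (!is.na(excludeId)) hit <- hit[tbl$id[hit] != excludeId]
    return(if (length(hit)) tbl$id[hit[1]] else NULL)
  }
  if (identical(policy, "by-composition")) {
    keys <- sort(unique(vapply(draft$compositions, function(e) {
      comps <- splitComponents(.asMolecule(e$text))
      paste(vapply(comps, structureKey, character(1)), collapse = "\r")
    }, character(1))))
    keySet <- sort(unique(unlist(strsplit(keys, "\r", fixed = TRUE))))
    comp <- .tbl(store, "compositions")
    st <- .tbl(store, "structures")
    for (cid in tbl$id) {
      if (!is.na(excludeId) && cid == excludeId) next
      sids <- comp$structure_id[comp$compound_type == type & comp$compound_id == cid]
      have <- sort(st$structure_key[match(sids, st$id)])
      if (identical(have, keySet)) return(cid)
    }
    return(NULL)
  }
  NULL
}

# ---- compound save / update ----------------------------------------------------

.guard <- function(store, operation, kind, actor) {
  ctx <- securityContext(store, actor)
  guardWrite(ctx, operation, kind,
             store@.env$config$security$write_permissions)
}

#' Save a new compound
#'
#' Runs the pre-save hook, applies the uniqueness policy, resolves every
#' component structure by InChIKey — reusing existing structure rows and
#' creating the missing ones with their molecular weight, formula and
#' screening fingerprint — and persists the compound atomically with
#' `version = 0`. Structure rows are never modified: the structure table
#' grows monotonically.
#'
#' @param store a [ChemStore-class].
#' @param draft a [compoundDraft()].
#' @param actor user name recorded in the audit metadata.
#' @return a [SaveOutcome-class].
#' @export
saveCompound <- function(store, draft, actor = "anonymous") {
  .guard(store, "save", "compound", actor)
  .checkType(store, draft$type)
  outcome <- .withTxn(store, {
    draft <- .runHook(store, "compound", draft)
    dup <- .findExistingCompound(store, draft$type, draft)
    if (!is.null(dup)) {
      .crStop("chemreg_uniqueness_error",
              sprintf("duplicate compound under the active policy (existing id %d)", dup),
              existingId = dup)
    }
    res <- .resolveCompositions(store, draft$compositions, actor)
    row <- as.list(c(
      list(compound_name = draft$compoundName, cas = draft$cas,
           read_role = draft$readRole),
      draft$extra
    ))
    rec <- storeInsert(store, paste0("compounds_", draft$type), row, actor = actor)
    for (cp in res$compositions) {
      storeInsert(store, "compositions", list(
        compound_type = draft$type, compound_id = rec$id[1],
        structure_id = cp$structure_id, percentage = cp$percentage
      ), actor = actor)
    }
    new("SaveOutcome",
        record = c(as.list(rec), list(compositions = res$compositions, type = draft$type)),
        structuresCreated = res$created, structuresReused = res$reused)
  })
  .invalidateCache(store)
  outcome
}

#' Update a compound with optimistic locking
#'
#' The draft must carry the target `id` and the `expectedVersion` the caller
#' last read. On a version mismatch a `chemreg_concurrent_modification_error`
#' is raised and nothing changes; on success the version increments by
#' exactly 1. Compositions are replaced wholesale; structures referenced by
#' the new compositions are resolved to existing-or-new rows, and previously
#' referenced structure rows remain untouched (immutability).
#'
#' @inheritParams saveCompound
#' @return a [SaveOutcome-class].
#' @export
updateCompound <- function(store, draft, actor = "anonymous") {
  .guard(store, "update", "compound", actor)
  .checkType(store, draft$type)
  tname <- paste0("compounds_", draft$type)
  outcome <- .withTxn(store, {
    draft <- .runHook(store, "compound", draft)
    tbl <- .tbl(store, tname)
    i <- which(tbl$id == draft$id)
    if (!length(i)) {
      .crStop("chemreg_not_found_error",
              sprintf("no %s with id %s", draft$type, format(draft$id)))
    }
    if (is.na(draft$expectedVersion) || tbl$version[i] != draft$expectedVersion) {
      .crStop("chemreg_concurrent_modification_error",
              sprintf("version mismatch: expected %s, stored %d",
                      format(draft$expectedVersion), tbl$version[i]))
    }
    dup <- .findExistingCompound(store, draft$type, draft, excludeId = draft$id)
    if (!is.null(dup)) {
      .crStop("chemreg_uniqueness_error",
              sprintf("duplicate compound under the active policy (existing id %d)", dup),
              existingId = dup)
    }
    res <- .resolveCompositions(store, draft$compositions, actor)
    tbl <- .tbl(store, tname) # structures inserts do not touch this table
    tbl$compound_name[i] <- draft$compoundName
    tbl$cas[i] <- draft$cas
    tbl$read_role[i] <- draft$readRole
    for (f in names(draft$extra)) tbl[[f]][i] <- draft$extra[[f]]
    tbl$modified_by[i] <- actor
    tbl$modified_at[i] <- as.numeric(Sys.time())
    tbl$version[i] <- tbl$version[i] + 1L
    .tblReplace(store, tname, tbl)
    comp <- .tbl(store, "compositions")
    keep <- !(comp$compound_type == draft$type & comp$compound_id == draft$id)
    .tblReplace(store, "compositions", comp[keep, , drop = FALSE])
    for (cp in res$compositions) {
      storeInsert(store, "compositions", list(
        compound_type = draft$type, compound_id = draft$id,
        structure_id = cp$structure_id, percentage = cp$percentage
      ), actor = actor)
    }
    rec <- .tbl(store, tname)[which(.tbl(store, tname)$id == draft$id), , drop = FALSE]
    new("SaveOutcome",
        record = c(as.list(rec), list(compositions = res$compositions, type = draft$type)),
        structuresCreated = res$created, structuresReused = res$reused)
  })
  .invalidateCache(store)
  outcome
}

#' Delete a compound
#'
#' Removes the compound and its compositions. Orphaned structure rows are
#' retained (immutability favours retention); containables referencing the
#' compound block the delete.
#'
#' @param store a [ChemStore-class].
#' @param type compound type.
#' @param id compound id.
#' @param actor user name.
#' @return invisibly, the number of compositions removed.
#' @export
deleteCompound <- function(store, type, id, actor = "anonymous") {
  .guard(store, "delete", "compound", actor)
  .checkType(store, type)
  n <- .withTxn(store, {
    tname <- paste0("compounds_", type)
    tbl <- .tbl(store, tname)
    i <- which(tbl$id == id)
    if (!length(i)) {
      .crStop("chemreg_not_found_error", sprintf("no %s with id %s", type, format(id)))
    }
    cont <- .tbl(store, paste0("containables_", type))
    if (any(cont$compound_id == id)) {
      .crStop("chemreg_constraint_error",
              "compound is referenced by containables and cannot be deleted")
    }
    comp <- .tbl(store, "compositions")
    drop <- comp$compound_type == type & comp$compound_id == id
    .tblReplace(store, "compositions", comp[!drop, , drop = FALSE])
    .tblReplace(store, tname, tbl[-i, , drop = FALSE])
    sum(drop)
  })
  .invalidateCache(store)
  invisible(n)
}

#' Replace a structure everywhere it occurs
#'
#' Structures are immutable, so "changing" one means repointing every
#' composition that references it to the (existing or newly created)
#' structure of the new text. The old structure row remains unchanged.
#'
#' @param store a [ChemStore-class].
#' @param key structure key of the structure to replace.
#' @param newText structure text of the replacement (single component).
#' @param actor user name.
#' @return number of compositions repointed.
#' @export
replaceStructure <- function(store, key, newText, actor = "anonymous") {
  .guard(store, "update", "compound", actor)
  n <- .withTxn(store, {
    st <- .tbl(store, "structures")
    i <- which(st$structure_key == key)
    if (!length(i)) {
      .crStop("chemreg_not_found_error", sprintf("no structure with key %s", key))
    }
    oldId <- st$id[i[1]]
    mol <- .asMolecule(newText)
    comps <- splitComponents(mol)
    if (length(comps) > 1L) {
      .crStop("chemreg_constraint_error",
              "replacement structure must be a single component")
    }
    res <- .structureFromMolecule(store, comps[[1]], actor)
    comp <- .tbl(store, "compositions")
    hit <- which(comp$structure_id == oldId)
    if (length(hit) && res$id != oldId) {
      comp$structure_id[hit] <- res$id
      # collapse any duplicate (compound, structure) memberships
      dupKey <- paste(comp$compound_type, comp$compound_id, comp$structure_id)
      comp <- comp[!duplicated(dupKey), , drop = FALSE]
      .tblReplace(store, "compositions", comp)
    }
    length(hit)
  })
  .invalidateCache(store)
  n
}

# ---- containables / containers -------------------------------------------------

#' Save a containable (batch / lot)
#'
#' A containable groups samples of one compound with a common source — a
#' batch in a registration system, a lot in an inventory system.
#'
#' @param store a [ChemStore-class].
#' @param type compound type the containable belongs to.
#' @param compoundId the compound.
#' @param readRole read role or `NA`.
#' @param extra named list of registered extra field values.
#' @param actor user name.
#' @return a [SaveOutcome-class] (no structures involved).
#' @export
saveContainable <- function(store, type, compoundId, readRole = NA_character_,
                            extra = list(), actor = "anonymous") {
  .guard(store, "save", "containable", actor)
  .checkType(store, type)
  outcome <- .withTxn(store, {
    draft <- .runHook(store, "containable", list(
      type = type, compoundId = compoundId, readRole = readRole, extra = extra
    ))
    ctbl <- .tbl(store, paste0("compounds_", draft$type))
    if (!draft$compoundId %in% ctbl$id) {
      .crStop("chemreg_constraint_error",
              sprintf("containable references missing compound %s (%s)",
                      format(draft$compoundId), draft$type))
    }
    rec <- storeInsert(store, paste0("containables_", draft$type),
                       as.list(c(list(compound_id = draft$compoundId,
                                      read_role = draft$readRole), draft$extra)),
                       actor = actor)
    new("SaveOutcome", record = c(as.list(rec), list(type = draft$type)),
        structuresCreated = 0L, structuresReused = 0L)
  })
  .invalidateCache(store)
  outcome
}

#' Save a bar-coded container
#'
#' A container is a physically available vessel holding exactly one
#' containable; its barcode is unique and non-null.
#'
#' @param store a [ChemStore-class].
#' @param barcode unique barcode text.
#' @param containableType,containableId the containable held.
#' @param actor user name.
#' @return the persisted container row (one-row data.frame).
#' @export
saveContainer <- function(store, barcode, containableType, containableId,
                          actor = "anonymous") {
  .guard(store, "save", "container", actor)
  .checkType(store, containableType)
  rec <- .withTxn(store, {
    draft <- .runHook(store, "container", list(
      barcode = barcode, containableType = containableType,
      containableId = containableId
    ))
    if (is.null(draft$barcode) || is.na(draft$barcode) || !nzchar(draft$barcode)) {
      .crStop("chemreg_constraint_error", "barcode must be non-null")
    }
    tbl <- .tbl(store, "containers")
    if (draft$barcode %in% tbl$barcode) {
      .crStop("chemreg_uniqueness_error",
              sprintf("a container with barcode '%s' already exists", draft$barcode))
    }
    cont <- .tbl(store, paste0("containables_", draft$containableType))
    if (!draft$containableId %in% cont$id) {
      .crStop("chemreg_constraint_error",
              sprintf("container references missing containable %s (%s)",
                      format(draft$containableId), draft$containableType))
    }
    storeInsert(store, "containers", list(
      barcode = draft$barcode, containable_type = draft$containableType,
      containable_id = draft$containableId
    ), actor = actor)
  })
  .invalidateCache(store)
  rec
}

# ---- reads ---------------------------------------------------------------------

#' Fetch a compound with its compositions
#'
#' @param store a [ChemStore-class].
#' @param type compound type.
#' @param id compound id.
#' @return named list: the compound row plus a `compositions` data.frame
#'   (structure id, key, text, percentage).
#' @export
getCompound <- function(store, type, id) {
  .checkType(store, type)
  tbl <- .tbl(store, paste0("compounds_", type))
  i <- which(tbl$id == id)
  if (!length(i)) {
    .crStop("chemreg_not_found_error", sprintf("no %s with id %s", type, format(id)))
  }
  comp <- .tbl(store, "compositions")
  comp <- comp[comp$compound_type == type & comp$compound_id == id, , drop = FALSE]
  st <- .tbl(store, "structures")
  m <- match(comp$structure_id, st$id)
  compositions <- data.frame(
    structure_id = comp$structure_id,
    structure_key = st$structure_key[m],
    structure_text = st$structure_text[m],
    mol_weight = st$mol_weight[m],
    percentage = comp$percentage,
    stringsAsFactors = FALSE
  )
  rownames(compositions) <- NULL
  c(as.list(tbl[i, , drop = FALSE]), list(compositions = compositions, type = type))
}

# parsed-graph cache for stored structures
.structureGraph <- function(store, sid) {
  env <- store@.env
  k <- as.character(sid)
  g <- env$graphs[[k]]
  if (is.null(g)) {
    st <- .tbl(store, "structures")
    i <- which(st$id == sid)
    if (!length(i)) {
      .crStop("chemreg_not_found_error", sprintf("no structure with id %s", format(sid)))
    }
    g <- parseStructure(st$structure_text[i])
    env$graphs[[k]] <- g
  }
  g
}
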