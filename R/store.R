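#' @include conditions.R AllClasses.R
#' @importFrom utils modifyList read.delim write.table head tail
NULL

# ---- configuration ----------------------------------------------------------

#' Default store configuration
#'
#' @return nested list: `fingerprint` (nbits, maxlen), `planner` (tau, n_max,
#'   prefix_bucket), `distinct_default`, `security` (enabled,
#'   write_permissions), `uniqueness` (per-type policy), `logging` (level).
#' @export
defaultConfig <- function() {
  list(
    fingerprint = list(nbits = 2048L, maxlen = 7L),
    planner = list(tau = 0.05, n_max = 5000L, prefix_bucket = 6L),
    distinct_default = TRUE,
    security = list(enabled = FALSE, write_permissions = list()),
    uniqueness = list(),
    logging = list(level = "info")
  )
}

#' Read a YAML configuration file
#'
#' Missing keys fall back to [defaultConfig()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list merged on top (CLI flags override config).
#' @return configuration list.
#' @export
readConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      .crStop("chemreg_store_error", sprintf("config file not found: %s", path))
    }
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  modifyList(cfg, overrides)
}

.LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L)

.crLog <- function(store, level, msg) {
  cfg <- store@.env$config$logging$level
  if (is.null(cfg)) cfg <- "info"
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[cfg]]) {
    message(sprintf("[chemreg %s] %s", level, msg))
  }
  invisible(NULL)
}

# ---- schema ------------------------------------------------------------------

.META_COLS <- c("created_by", "created_at", "modified_by", "modified_at", "version")

.emptyMeta <- function() {
  data.frame(
    created_by = character(), created_at = numeric(),
    modified_by = character(), modified_at = numeric(),
    version = integer(), stringsAsFactors = FALSE
  )
}

.newMeta <- function(actor) {
  now <- as.numeric(Sys.time()) # stored as UTC epoch seconds
  list(created_by = actor, created_at = now,
       modified_by = actor, modified_at = now, version = 0L)
}

.emptyStructures <- function() {
  cbind(
    data.frame(
      id = integer(), structure_text = character(), structure_key = character(),
      mol_weight = numeric(), formula = character(), fp_hex = character(),
      fp_params = character(), stringsAsFactors = FALSE
    ),
    .emptyMeta()
  )
}

.emptyCompounds <- function(extraFields = character()) {
  base <- data.frame(
    id = integer(), compound_name = character(), cas = character(),
    read_role = character(), stringsAsFactors = FALSE
  )
  for (f in extraFields) base[[f]] <- character()
  cbind(base, .emptyMeta())
}

.emptyCompositions <- function() {
  data.frame(
    compound_type = character(), compound_id = integer(),
    structure_id = integer(), percentage = numeric(), stringsAsFactors = FALSE
  )
}

.emptyContainables <- function(extraFields = character()) {
  base <- data.frame(
    id = integer(), compound_id = integer(), read_role = character(),
    stringsAsFactors = FALSE
  )
  for (f in extraFields) base[[f]] <- character()
  cbind(base, .emptyMeta())
}

.emptyContainers <- function() {
  cbind(
    data.frame(
      id = integer(), barcode = character(), containable_type = character(),
      containable_id = integer(), stringsAsFactors = FALSE
    ),
    .emptyMeta()
  )
}

#' Create an in-process compound store
#'
#' Initialises the schema (structure, composition, container, role and user
#' tables) and registers the default compound type `"Compound"`. The store
#' lives in memory; use [saveStore()] / [openStore()] to persist it as a
#' directory of TSV tables.
#'
#' @param config configuration list, see [readConfig()].
#' @return a [ChemStore-class].
#' @examples
#' store <- chemStore()
#' saveCompound(store, compoundDraft("ethanol", "CCO"), actor = "ada")
#' @export
chemStore <- function(config = list()) {
  env <- new.env(parent = emptyenv())
  env$tables <- list()
  env$types <- list()
  env$seq <- new.env(parent = emptyenv())
  env$counters <- new.env(parent = emptyenv())
  env$counters$count_computations <- 0L
  env$counters$last_verified <- 0L
  env$cache <- new.env(parent = emptyenv())
  env$hooks <- new.env(parent = emptyenv())
  env$graphs <- new.env(parent = emptyenv())
  env$fps <- new.env(parent = emptyenv())
  env$txn <- NULL
  env$config <- modifyList(defaultConfig(), config)
  store <- new("ChemStore", .env = env)
  initSchema(store)
  registerCompoundType(store, "Compound")
  store
}

#' Initialise (or re-check) the store schema
#'
#' Creates every missing base table; idempotent — existing tables and their
#' rows are never touched.
#'
#' @param store a [ChemStore-class].
#' @return the store, invisibly.
#' @export
initSchema <- function(store) {
  env <- store@.env
  add <- function(name, proto) {
    if (is.null(env$tables[[name]])) env$tables[[name]] <- proto
  }
  add("structures", .emptyStructures())
  add("compositions", .emptyCompositions())
  add("containers", .emptyContainers())
  add("roles", data.frame(role = character(), stringsAsFactors = FALSE))
  add("users", data.frame(user = character(), roles = character(),
                          stringsAsFactors = FALSE))
  invisible(store)
}

#' Register a compound type
#'
#' Compound types follow table-per-concrete-class semantics: each type gets
#' its own compound and containable tables and is stored and searched
#' independently of every other type.
#'
#' @param store a [ChemStore-class].
#' @param type type name, e.g. `"Compound"`, `"SecretCompound"`.
#' @param compoundFields,containableFields extra (text) column names.
#' @return the store, invisibly.
#' @export
registerCompoundType <- function(store, type,
                                 compoundFields = character(),
                                 containableFields = character()) {
  env <- store@.env
  if (!is.null(env$types[[type]])) {
    old <- env$types[[type]]
    if (!identical(old$compoundFields, compoundFields) ||
        !identical(old$containableFields, containableFields)) {
      .crStop("chemreg_constraint_error",
              sprintf("type '%s' already registered with different fields", type))
    }
    return(invisible(store))
  }
  env$types[[type]] <- list(compoundFields = compoundFields,
                            containableFields = containableFields)
  env$tables[[paste0("compounds_", type)]] <- .emptyCompounds(compoundFields)
  env$tables[[paste0("containables_", type)]] <- .emptyContainables(containableFields)
  invisible(store)
}

.tbl <- function(store, name) {
  t <- store@.env$tables[[name]]
  if (is.null(t)) {
    .crStop("chemreg_store_error", sprintf("no such table: %s", name))
  }
  t
}

.compoundTypes <- function(store) names(store@.env$types)

.checkType <- function(store, type) {
  if (!type %in% .compoundTypes(store)) {
    .crStop("chemreg_not_found_error", sprintf("unknown compound type: %s", type))
  }
  invisible(type)
}

.nextId <- function(store, name) {
  env <- store@.env
  cur <- if (is.null(env$seq[[name]])) 0L else env$seq[[name]]
  nxt <- cur + 1L
  .txnUndo(store, local({
    prev <- cur
    nm <- name
    function() env$seq[[nm]] <- prev
  }))
  env$seq[[name]] <- nxt
  nxt
}

# ---- transactions ------------------------------------------------------------

.txnUndo <- function(store, fn) {
  txn <- store@.env$txn
  if (!is.null(txn)) txn$undo[[length(txn$undo) + 1L]] <- fn
  invisible(NULL)
}

# run expr atomically: on error every journaled mutation is rolled back in
# reverse order; nested calls join the outer transaction
.withTxn <- function(store, expr) {
  env <- store@.env
  if (!is.null(env$txn)) return(force(expr))
  txn <- new.env(parent = emptyenv())
  txn$undo <- list()
  env$txn <- txn
  ok <- FALSE
  on.exit({
    if (!ok) {
      for (fn in rev(txn$undo)) fn()
    }
    env$txn <- NULL
  })
  res <- force(expr)
  ok <- TRUE
  res
}

.tblAppend <- function(store, name, rows) {
  env <- store@.env
  old <- env$tables[[name]]
  nBefore <- nrow(old)
  .txnUndo(store, local({
    nm <- name
    n0 <- nBefore
    function() env$tables[[nm]] <- head(env$tables[[nm]], n0)
  }))
  rows <- rows[names(old)]
  env$tables[[name]] <- rbind(old, rows)
  invisible(NULL)
}

# full pre-image undo; updates and deletes are rare and tables are modest
.tblReplace <- function(store, name, newTable) {
  env <- store@.env
  old <- env$tables[[name]]
  .txnUndo(store, local({
    nm <- name
    prev <- old
    function() env$tables[[nm]] <- prev
  }))
  env$tables[[name]] <- newTable
  invisible(NULL)
}

# ---- raw, constraint-enforcing inserts ---------------------------------------

#' Store-level row insert with constraint enforcement
#'
#' The raw insert path beneath the registry: enforces the unique constraints
#' (structure key, container barcode, role name) and non-null requirements at
#' the store level, independent of any application logic. Registry operations
#' funnel through this; tests may call it directly to verify the constraints.
#'
#' @param store a [ChemStore-class].
#' @param table table name (`"structures"`, `"containers"`, `"roles"`,
#'   `"users"`, `"compositions"`, `"compounds_<type>"`,
#'   `"containables_<type>"`).
#' @param row named list of column values; missing meta columns are filled,
#'   a missing `id` is drawn from the table sequence.
#' @param actor user name recorded in the audit metadata.
#' @return the inserted row as a one-row data.frame.
#' @export
storeInsert <- function(store, table, row, actor = "system") {
  tbl <- .tbl(store, table)
  row <- as.list(row)
  if ("id" %in% names(tbl) && is.null(row$id)) row$id <- .nextId(store, table)
  if (all(.META_COLS %in% names(tbl))) {
    meta <- .newMeta(actor)
    for (m in .META_COLS) if (is.null(row[[m]])) row[[m]] <- meta[[m]]
  }
  if (table == "structures") {
    key <- row$structure_key
    if (is.null(key) || is.na(key) || !nzchar(key)) {
      .crStop("chemreg_constraint_error", "structure_key must be non-null")
    }
    if (key %in% tbl$structure_key) {
      .crStop("chemreg_constraint_error",
              sprintf("unique constraint violated: structure_key '%s' exists", key))
    }
  }
  if (table == "containers") {
    bc <- row$barcode
    if (is.null(bc) || is.na(bc) || !nzchar(bc)) {
      .crStop("chemreg_constraint_error", "barcode must be non-null")
    }
    if (bc %in% tbl$barcode) {
      .crStop("chemreg_constraint_error",
              sprintf("unique constraint violated: barcode '%s' exists", bc))
    }
  }
  if (table == "roles") {
    if (row$role %in% tbl$role) {
      .crStop("chemreg_constraint_error",
              sprintf("unique constraint violated: role '%s' exists", row$role))
    }
  }
  if (table == "compositions") {
    dup <- tbl$compound_type == row$compound_type &
      tbl$compound_id == row$compound_id &
      tbl$structure_id == row$structure_id
    if (any(dup)) {
      .crStop("chemreg_constraint_error",
              "unique constraint violated: (compound, structure) composition exists")
    }
  }
  df <- tbl[0, , drop = FALSE]
  for (col in names(df)) {
    val <- row[[col]]
    if (is.null(val)) val <- NA
    df[1L, col] <- val
  }
  .withTxn(store, .tblAppend(store, table, df))
  df
}

# ---- stats -------------------------------------------------------------------

#' Table statistics for the query planner
#'
#' Row counts per table and, for the indexed columns (compound name, CAS,
#' structure key, molecular weight, barcode), distinct-value counts plus
#' prefix-bucket counts for text columns and value ranges for numeric ones.
#' All numbers are computed exactly and flagged as such.
#'
#' @param store a [ChemStore-class].
#' @return list with elements `tables` (data.frame of table, rows),
#'   `columns` (data.frame of table, column, distinct, exact) and
#'   `prefixBuckets` (named list of prefix-count tables).
#' @export
tableStats <- function(store) {
  env <- store@.env
  nms <- names(env$tables)
  tables <- data.frame(
    table = nms,
    rows = vapply(nms, function(n) nrow(env$tables[[n]]), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(tables) <- NULL
  cols <- list()
  buckets <- list()
  bucketLen <- env$config$planner$prefix_bucket
  idxCols <- list(structures = c("structure_key", "mol_weight"),
                  containers = "barcode")
  for (ty in .compoundTypes(store)) {
    idxCols[[paste0("compounds_", ty)]] <- c("compound_name", "cas")
  }
  for (tn in names(idxCols)) {
    tbl <- env$tables[[tn]]
    for (cn in idxCols[[tn]]) {
      v <- tbl[[cn]]
      cols[[length(cols) + 1L]] <- data.frame(
        table = tn, column = cn,
        distinct = length(unique(v[!is.na(v)])),
        exact = TRUE, stringsAsFactors = FALSE
      )
      if (is.character(v)) {
        pb <- table(substr(v[!is.na(v)], 1L, bucketLen))
        buckets[[paste(tn, cn, sep = ".")]] <- pb
      } else if (is.numeric(v) && length(v)) {
        buckets[[paste(tn, cn, sep = ".")]] <-
          c(min = suppressWarnings(min(v, na.rm = TRUE)),
            max = suppressWarnings(max(v, na.rm = TRUE)))
      }
    }
  }
  list(
    tables = tables,
    columns = do.call(rbind, cols),
    prefixBuckets = buckets,
    bucketLen = bucketLen
  )
}

# ---- count cache + counters --------------------------------------------------

.invalidateCache <- function(store) {
  env <- store@.env
  rm(list = ls(env$cache), envir = env$cache)
  invisible(NULL)
}

#' Instrumentation counters
#'
#' @param store a [ChemStore-class].
#' @return list with `count_computations` (number of times a total count was
#'   actually computed rather than served from the cache) and `last_verified`
#'   (molecules verified by the substructure matcher in the most recent
#'   search).
#' @export
storeCounters <- function(store) {
  as.list(store@.env$counters)
}

#' Set the store-wide default for distinct queries
#'
#' Requests whose `distinct` flag is `NA` use this default. Disabling
#' distinct queries application-wide is the appropriate setting for
#' single-component compound databases, where the result sets are identical
#' anyway and the distinct pass costs time.
#'
#' @param store a [ChemStore-class].
#' @param enabled logical.
#' @return the store, invisibly.
#' @export
setDistinctDefault <- function(store, enabled) {
  store@.env$config$distinct_default <- isTRUE(enabled)
  invisible(store)
}

#' Set the duplicate-compound policy for a type
#'
#' @param store a [ChemStore-class].
#' @param type compound type.
#' @param policy `"none"` (default — duplicates allowed), `"by-cas"`,
#'   `"by-composition"` (set of structure keys), or a function
#'   `(store, type, draft, excludeId) -> existing id or NULL`.
#' @return the store, invisibly.
#' @export
setUniquenessPolicy <- function(store, type, policy) {
  .checkType(store, type)
  if (is.character(policy)) {
    policy <- match.arg(policy, c("none", "by-cas", "by-composition"))
  } else if (!is.function(policy)) {
    .crStop("chemreg_constraint_error", "policy must be a name or a function")
  }
  store@.env$config$uniqueness[[type]] <- policy
  invisible(store)
}

# ---- persistence -------------------------------------------------------------

#' Persist a store as a directory of TSV tables
#'
#' Everything needed to reopen the store is written as plain text: one TSV
#' per table, a YAML file with types, sequences, counters and configuration,
#' and the count cache (so paging across CLI invocations still reuses cached
#' counts).
#'
#' @param store a [ChemStore-class].
#' @param dir target directory (created if missing).
#' @return the directory, invisibly.
#' @export
saveStore <- function(store, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    .crStop("chemreg_store_error", sprintf("cannot create store directory: %s", dir))
  }
  env <- store@.env
  for (nm in names(env$tables)) {
    utils::write.table(env$tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = TRUE, na = "NA")
  }
  cfg <- env$config
  # function-valued uniqueness policies are in-process only
  cfg$uniqueness <- Filter(is.character, cfg$uniqueness)
  meta <- list(
    types = env$types,
    seq = as.list(env$seq),
    counters = as.list(env$counters),
    config = cfg,
    cache = as.list(env$cache)
  )
  yaml::write_yaml(meta, file.path(dir, "store.yaml"))
  invisible(dir)
}

#' Reopen a persisted store
#'
#' @param dir directory written by [saveStore()].
#' @return a [ChemStore-class].
#' @export
openStore <- function(dir) {
  metaPath <- file.path(dir, "store.yaml")
  if (!file.exists(metaPath)) {
    .crStop("chemreg_store_error", sprintf("not a store directory: %s", dir))
  }
  meta <- yaml::read_yaml(metaPath)
  store <- chemStore(config = meta$config)
  env <- store@.env
  env$types <- lapply(meta$types, function(t) {
    list(compoundFields = as.character(unlist(t$compoundFields)),
         containableFields = as.character(unlist(t$containableFields)))
  })
  for (ty in names(env$types)) {
    env$tables[[paste0("compounds_", ty)]] <-
      .emptyCompounds(env$types[[ty]]$compoundFields)
    env$tables[[paste0("containables_", ty)]] <-
      .emptyContainables(env$types[[ty]]$containableFields)
  }
  for (f in list.files(dir, pattern = "\\.tsv$")) {
    nm <- sub("\\.tsv$", "", f)
    proto <- env$tables[[nm]]
    got <- utils::read.delim(file.path(dir, f), sep = "\t",
                             stringsAsFactors = FALSE, na.strings = "NA",
                             colClasses = if (!is.null(proto)) {
                               vapply(proto, function(c) class(c)[1], character(1))
                             } else NA)
    env$tables[[nm]] <- got
  }
  for (k in names(meta$seq)) env$seq[[k]] <- as.integer(meta$seq[[k]])
  for (k in names(meta$counters)) env$counters[[k]] <- as.integer(meta$counters[[k]])
  for (k in names(meta$cache)) env$cache[[k]] <- as.integer(meta$cache[[k]])
  store
}

setMethod("show", "ChemStore", function(object) {
  env <- object@.env
  cat("ChemStore\n")
  for (nm in sort(names(env$tables))) {
    cat(sprintf("  %-28s %6d row(s)\n", nm, nrow(env$tables[[nm]])))
  }
  cat(sprintf("  compound types: %s\n", paste(.compoundTypes(object), collapse = ", ")))
  cat(sprintf("  security: %s\n",
              if (isTRUE(env$config$security$enabled)) "enabled" else "disabled"))
})
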