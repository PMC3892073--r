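#' @include registry.R
NULL

# ---- reading -------------------------------------------------------------------

#' Read an SD-file into records
#'
#' Splits an MDL SD-file (V2000 connection tables plus tagged data fields,
#' records terminated by `$$$$`) into records. Property order is preserved
#' and multi-line values are kept; CRLF and LF line endings are both
#' accepted, and a missing trailing newline is tolerated. A malformed record
#' — including a truncated final record with no `$$$$` — becomes an error
#' entry (`list(index=, error=<condition>)`) without affecting its
#' neighbours.
#'
#' @param input path to an SD-file, or the file content as a single string.
#' @return list of records `list(index=, molBlock=, properties=)`; failed
#'   records carry `error` instead of `molBlock`.
#' @export
readSdf <- function(input) {
  text <- if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
              file.exists(input)) {
    readChar(input, file.info(input)$size, useBytes = TRUE)
  } else {
    paste(input, collapse = "\n")
  }
  lines <- strsplit(gsub("\r\n", "\n", text, fixed = TRUE), "\n", fixed = TRUE)[[1]]
  delim <- which(trimws(lines) == "$$$$")
  starts <- c(1L, delim + 1L)
  ends <- c(delim - 1L, length(lines))
  terminated <- c(rep(TRUE, length(delim)), FALSE)

  out <- list()
  idx <- 0L
  for (r in seq_along(starts)) {
    if (starts[r] > ends[r] ||
        !any(nzchar(trimws(lines[starts[r]:ends[r]])))) {
      next # empty trailing chunk
    }
    idx <- idx + 1L
    chunk <- lines[starts[r]:ends[r]]
    rec <- tryCatch({
      if (!terminated[r]) {
        .crStop("chemreg_format_error",
                sprintf("record %d is truncated (no $$$$ terminator)", idx))
      }
      endMol <- grep("^M  END", chunk)[1]
      if (is.na(endMol)) {
        .crStop("chemreg_format_error",
                sprintf("record %d has no M  END line", idx))
      }
      molBlock <- paste(chunk[1:endMol], collapse = "\n")
      props <- character()
      tags <- character()
      i <- endMol + 1L
      n <- length(chunk)
      while (i <= n) {
        ln <- chunk[i]
        if (startsWith(ln, ">")) {
          tag <- sub("^>.*?<([^>]*)>.*$", "\\1", ln)
          if (identical(tag, ln)) {
            .crStop("chemreg_format_error",
                    sprintf("record %d has a malformed data header: %s", idx, ln))
          }
          vals <- character()
          i <- i + 1L
          while (i <= n && nzchar(chunk[i])) {
            vals <- c(vals, chunk[i])
            i <- i + 1L
          }
          tags <- c(tags, tag)
          props <- c(props, paste(vals, collapse = "\n"))
        }
        i <- i + 1L
      }
      names(props) <- tags
      list(index = idx, molBlock = molBlock, properties = props)
    }, chemreg_format_error = function(e) list(index = idx, error = e))
    out[[idx]] <- rec
  }
  out
}

# ---- import --------------------------------------------------------------------

#' Import compounds from an SD-file
#'
#' Each record becomes one compound draft: the mol block is its (single)
#' composition text, so a record with several disconnected fragments is
#' assumed to be a mixture and stored as one composition per distinct
#' component with percentages unset. Drafts are saved through the registry,
#' so structure dedup by InChIKey applies across the whole import. Import is
#' atomic per record: a failed record never leaves a partially saved
#' compound.
#'
#' @param store a [ChemStore-class].
#' @param input SD-file path or content (see [readSdf()]).
#' @param mapping named character vector `tag -> compound field`; must map
#'   some tag to `compound_name` unless `nameGenerator` is given. Mapped
#'   fields beyond the base ones must be registered extra fields of the
#'   type; unmapped tags are ignored.
#' @param policy `"skip"` (record failures, continue) or `"abort"` (raise a
#'   `chemreg_abort_error` on the first failure).
#' @param actor user name.
#' @param type compound type to import into.
#' @param nameGenerator optional `function(index, record) name`.
#' @return an [ImportReport-class].
#' @export
importCompounds <- function(store, input, mapping = c(compound_name = "compound_name"),
                            policy = c("skip", "abort"), actor = "anonymous",
                            type = "Compound", nameGenerator = NULL) {
  policy <- match.arg(policy)
  .checkType(store, type)
  if (!"compound_name" %in% mapping && is.null(nameGenerator)) {
    .crStop("chemreg_constraint_error",
            "mapping must provide compound_name, or supply a nameGenerator")
  }
  baseFields <- c("compound_name", "cas", "read_role")
  extraFields <- store@.env$types[[type]]$compoundFields
  records <- readSdf(input)
  created <- 0L
  sCreated <- 0L
  sReused <- 0L
  failures <- list()
  for (rec in records) {
    res <- tryCatch({
      if (!is.null(rec$error)) stop(rec$error)
      vals <- list()
      for (tag in names(mapping)) {
        if (tag %in% names(rec$properties)) {
          vals[[mapping[[tag]]]] <- rec$properties[[tag]]
        }
      }
      unknown <- setdiff(names(vals), c(baseFields, extraFields))
      if (length(unknown)) {
        .crStop("chemreg_unknown_field_error",
                sprintf("mapping targets unregistered field(s): %s",
                        paste(unknown, collapse = ", ")))
      }
      nm <- vals$compound_name
      if (is.null(nm) && !is.null(nameGenerator)) nm <- nameGenerator(rec$index, rec)
      if (is.null(nm)) {
        .crStop("chemreg_format_error",
                sprintf("record %d has no compound name", rec$index))
      }
      draft <- compoundDraft(
        compoundName = nm,
        compositions = list(list(text = rec$molBlock, percentage = NA_real_)),
        cas = vals$cas %||% NA_character_,
        readRole = vals$read_role %||% NA_character_,
        extra = vals[setdiff(names(vals), baseFields)],
        type = type
      )
      saveCompound(store, draft, actor = actor)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (policy == "abort") {
        .crStop("chemreg_abort_error",
                sprintf("import aborted at record %d: %s", rec$index,
                        conditionMessage(res)),
                cause = res, index = rec$index)
      }
      failures[[length(failures) + 1L]] <-
        list(index = rec$index, reason = conditionMessage(res))
    } else {
      created <- created + 1L
      sCreated <- sCreated + res@structuresCreated
      sReused <- sReused + res@structuresReused
    }
  }
  new("ImportReport",
      recordsRead = length(records), compoundsCreated = created,
      structuresCreated = sCreated, structuresReused = sReused,
      failures = failures)
}

# ---- export --------------------------------------------------------------------

# molfile header line 2 normally carries program/timestamp; fix it so the
# same store exports byte-identical files
.scrubMolBlock <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  if (length(lines) >= 2L) lines[2] <- "  ChemRegistry"
  paste(lines, collapse = "\n")
}

#' Export compounds as an SD-file
#'
#' One record per compound; a mixture is written as a single multi-fragment
#' mol block (components in composition order). The selected compound fields
#' are written as property tags (null values are omitted), and when any
#' composition carries a percentage a `percentages` tag lists one value per
#' component in order (`NA` for unset).
#'
#' @param store a [ChemStore-class].
#' @param ids compound ids to export (e.g. from a search page's items).
#' @param file output path or connection.
#' @param fields compound fields to write as tags.
#' @param type compound type.
#' @return number of records written, invisibly.
#' @export
exportCompounds <- function(store, ids, file, fields = c("compound_name", "cas"),
                            type = "Compound") {
  .checkType(store, type)
  ctab <- .tbl(store, paste0("compounds_", type))
  miss <- setdiff(fields, names(ctab))
  if (length(miss)) {
    .crStop("chemreg_unknown_field_error",
            sprintf("unknown field(s): %s", paste(miss, collapse = ", ")))
  }
  comp <- .tbl(store, "compositions")
  st <- .tbl(store, "structures")
  smiles <- character(length(ids))
  pcts <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    rows <- comp[comp$compound_type == type & comp$compound_id == ids[k], ,
                 drop = FALSE]
    if (!nrow(rows)) {
      .crStop("chemreg_not_found_error",
              sprintf("no compositions for compound %s", format(ids[k])))
    }
    texts <- st$structure_text[match(rows$structure_id, st$id)]
    smiles[k] <- paste(texts, collapse = ".")
    pcts[[k]] <- rows$percentage
  }
  # one batch conversion for all records
  sdf <- .obConvert("SMI", "SDF", paste0(paste(smiles, collapse = "\n"), "\n"))
  if (!nzchar(sdf)) {
    .crStop("chemreg_store_error", "SD conversion of stored structures failed")
  }
  blocks <- strsplit(sdf, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  if (length(blocks) != length(ids)) {
    .crStop("chemreg_store_error", "SD conversion returned unexpected record count")
  }
  out <- character(length(ids))
  for (k in seq_along(ids)) {
    i <- which(ctab$id == ids[k])
    # line 1 is the (possibly empty) title line of the mol block
    lines <- strsplit(blocks[k], "\n", fixed = TRUE)[[1]]
    lines[1] <- as.character(ctab$compound_name[i]) # title line
    if (length(lines) >= 2L) lines[2] <- "  ChemRegistry"
    tagLines <- character()
    for (f in fields) {
      v <- ctab[[f]][i]
      if (!is.na(v)) {
        tagLines <- c(tagLines, sprintf(">  <%s>", f), as.character(v), "")
      }
    }
    if (any(!is.na(pcts[[k]]))) {
      tagLines <- c(tagLines, ">  <percentages>",
                    paste(ifelse(is.na(pcts[[k]]), "NA", format(pcts[[k]])),
                          collapse = ";"), "")
    }
    out[k] <- paste(c(lines, tagLines, "$$$$"), collapse = "\n")
  }
  writeLines(out, file, sep = "\n")
  invisible(length(ids))
}
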