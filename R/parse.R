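#' @import methods
#' @importFrom ChemmineOB convertFormat forEachMol smartsSearch_OB
NULL

# ---- OpenBabel plumbing ----------------------------------------------------

.obConvert <- function(from, to, text, opts = NULL) {
  if (is.null(opts)) opts <- data.frame(names = character(), args = character())
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, text, options = opts),
    error = function(e) ""
  )
  if (!is.character(out) || length(out) != 1L) out <- ""
  out
}

.obCanonical <- function(from, text) {
  out <- .obConvert(from, "CAN", text)
  if (!nzchar(out)) return(NA_character_)
  first <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
  sub("[[:space:]].*$", "", trimws(first))
}

# ---- input validation ------------------------------------------------------

.stripSmilesWhitespace <- function(text) gsub("[[:space:]]+", "", text)

# light structural pre-validation so common SMILES mistakes get a position
.preValidateSmiles <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  inBracket <- FALSE
  ring <- integer()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (inBracket) {
      if (ch == "]") inBracket <- FALSE
      i <- i + 1L
      next
    }
    if (ch == "[") {
      inBracket <- TRUE
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        return(list(ok = FALSE, pos = i, reason = "unmatched closing parenthesis"))
      }
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        return(list(ok = FALSE, pos = i, reason = "'%' must be followed by two digits"))
      }
      num <- as.integer(paste0(chars[i + 1L], chars[i + 2L]))
      ring <- c(ring, num)
      i <- i + 2L
    } else if (grepl("^[0-9]$", ch)) {
      ring <- c(ring, as.integer(ch))
    }
    i <- i + 1L
  }
  if (inBracket) return(list(ok = FALSE, pos = n, reason = "unterminated bracket atom"))
  if (depth > 0L) return(list(ok = FALSE, pos = n, reason = "unmatched opening parenthesis"))
  odd <- as.integer(names(which(table(ring) %% 2L == 1L)))
  if (length(odd)) {
    pos <- utils::tail(which(chars %in% as.character(odd %% 10L)), 1)
    return(list(
      ok = FALSE, pos = if (length(pos)) pos else n,
      reason = sprintf("unclosed ring bond(s): %s", paste(odd, collapse = ", "))
    ))
  }
  list(ok = TRUE, pos = NA_integer_, reason = NA_character_)
}

# ---- V2000 / MOL2 block readers (for blocks OpenBabel itself emitted) ------

.parseMolfileBlock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- grep("V2000", lines, fixed = TRUE)[1]
  if (is.na(counts)) {
    .crStop("chemreg_parse_error", "no V2000 counts line found in molfile")
  }
  natoms <- suppressWarnings(as.integer(substr(lines[counts], 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(lines[counts], 4, 6)))
  if (is.na(natoms) || is.na(nbonds)) {
    .crStop("chemreg_parse_error", "malformed V2000 counts line")
  }
  atomLines <- lines[seq(counts + 1L, length.out = natoms)]
  bondLines <- if (nbonds > 0) lines[seq(counts + natoms + 1L, length.out = nbonds)] else character()
  element <- trimws(substr(atomLines, 32, 34))
  charge <- integer(natoms)
  isotope <- integer(natoms)
  for (ml in grep("^M  (CHG|ISO)", lines, value = TRUE)) {
    kind <- substr(ml, 4, 6)
    nent <- as.integer(substr(ml, 7, 9))
    for (k in seq_len(nent)) {
      off <- 10L + (k - 1L) * 8L
      idx <- as.integer(substr(ml, off, off + 3L))
      val <- as.integer(substr(ml, off + 4L, off + 7L))
      if (kind == "CHG") charge[idx] <- val else isotope[idx] <- val
    }
  }
  bonds <- data.frame(
    from = as.integer(substr(bondLines, 1, 3)),
    to = as.integer(substr(bondLines, 4, 6)),
    order = as.integer(substr(bondLines, 7, 9))
  )
  list(element = element, charge = charge, isotope = isotope, bonds = bonds)
}

.parseMol2Block <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  aStart <- grep("^@<TRIPOS>ATOM", lines)[1]
  bStart <- grep("^@<TRIPOS>BOND", lines)[1]
  sect <- grep("^@<TRIPOS>", lines)
  aEnd <- min(c(sect[sect > aStart], length(lines) + 1L)) - 1L
  bEnd <- min(c(sect[sect > bStart], length(lines) + 1L)) - 1L
  atomLines <- lines[seq(aStart + 1L, aEnd)]
  atomLines <- atomLines[nzchar(trimws(atomLines))]
  types <- vapply(strsplit(trimws(atomLines), "[[:space:]]+"), `[`, character(1), 6)
  bonds <- NULL
  if (!is.na(bStart) && bEnd > bStart) {
    bondLines <- lines[seq(bStart + 1L, bEnd)]
    bondLines <- bondLines[nzchar(trimws(bondLines))]
    if (length(bondLines)) {
      parts <- strsplit(trimws(bondLines), "[[:space:]]+")
      bonds <- data.frame(
        from = vapply(parts, function(p) as.integer(p[2]), integer(1)),
        to = vapply(parts, function(p) as.integer(p[3]), integer(1)),
        type = vapply(parts, `[`, character(1), 4),
        stringsAsFactors = FALSE
      )
    }
  }
  list(types = types, bonds = bonds)
}

# ---- graph construction ----------------------------------------------------

.buildMolecule <- function(molBlock, mol2Block, sourceText, canonical) {
  mb <- .parseMolfileBlock(molBlock)
  m2 <- .parseMol2Block(mol2Block)

  isH <- mb$element == "H"
  # keep H atoms only when the molecule has no heavy atom neighbourhood to
  # fold them into (e.g. molecular hydrogen)
  foldable <- isH
  if (all(isH)) foldable[] <- FALSE

  keep <- which(!foldable)
  rank <- integer(length(mb$element))
  rank[keep] <- seq_along(keep)

  hcount <- integer(length(keep))
  bonds <- mb$bonds
  if (nrow(bonds)) {
    hb <- foldable[bonds$from] | foldable[bonds$to]
    for (r in which(hb)) {
      heavy <- if (foldable[bonds$from[r]]) bonds$to[r] else bonds$from[r]
      if (!foldable[heavy]) hcount[rank[heavy]] <- hcount[rank[heavy]] + 1L
    }
    bonds <- bonds[!hb, , drop = FALSE]
    bonds$from <- rank[bonds$from]
    bonds$to <- rank[bonds$to]
  }

  # overlay OpenBabel's aromaticity perception from the mol2 form; the mol2
  # output was produced without added hydrogens, so align by heavy-atom rank
  m2H <- grepl("^H($|\\.)", m2$types)
  m2rank <- integer(length(m2$types))
  m2rank[!m2H] <- seq_len(sum(!m2H))
  aromaticBond <- matrix(FALSE, nrow = length(keep), ncol = length(keep))
  aromAtom <- logical(length(keep))
  if (!is.null(m2$bonds) && nrow(m2$bonds)) {
    ar <- m2$bonds$type == "ar"
    for (r in which(ar)) {
      f <- m2$bonds$from[r]; t <- m2$bonds$to[r]
      if (!m2H[f] && !m2H[t]) {
        aromaticBond[m2rank[f], m2rank[t]] <- TRUE
        aromaticBond[m2rank[t], m2rank[f]] <- TRUE
        aromAtom[m2rank[f]] <- TRUE
        aromAtom[m2rank[t]] <- TRUE
      }
    }
  }
  if (nrow(bonds)) {
    # keep the kekulized order for lossless molfile round-trips; `order`
    # carries the aromatic overlay used by matching and fingerprints
    bonds$kek <- bonds$order
    isAr <- aromaticBond[cbind(bonds$from, bonds$to)]
    bonds$order[isAr] <- 4L
  } else {
    bonds$kek <- integer()
  }

  atoms <- data.frame(
    element = mb$element[keep],
    charge = mb$charge[keep],
    isotope = mb$isotope[keep],
    hcount = hcount,
    aromatic = aromAtom,
    stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  new("Molecule", atoms = atoms, bonds = bonds,
      sourceText = sourceText, canonicalSmiles = canonical)
}

# ---- valence policy --------------------------------------------------------

.maxValence <- c(
  H = 1, B = 3, C = 4, N = 4, O = 3, F = 1, Si = 4, P = 5, S = 6,
  Cl = 4, Br = 4, I = 4
)

.checkValence <- function(mol) {
  atoms <- mol@atoms
  bonds <- mol@bonds
  deg <- numeric(nrow(atoms))
  if (nrow(bonds)) {
    ord <- ifelse(bonds$order == 4L, 1.5, bonds$order)
    for (r in seq_len(nrow(bonds))) {
      deg[bonds$from[r]] <- deg[bonds$from[r]] + ord[r]
      deg[bonds$to[r]] <- deg[bonds$to[r]] + ord[r]
    }
  }
  tot <- floor(deg) + atoms$hcount
  lim <- .maxValence[atoms$element]
  bad <- which(!is.na(lim) & tot > lim + abs(atoms$charge))
  if (length(bad)) {
    .crStop("chemreg_valence_error",
            sprintf("atom %d (%s) exceeds allowed valence (%g bonds+H)",
                    bad[1], atoms$element[bad[1]], tot[bad[1]]))
  }
  invisible(TRUE)
}

# ---- public parse ----------------------------------------------------------

#' Parse a chemical structure
#'
#' Accepts SMILES or a V2000 molfile block (auto-detected: molfile iff the
#' text contains a V2000 counts line) and returns a [Molecule-class] graph.
#' Whitespace inside SMILES is stripped before parsing, so text printed with
#' spaces around bonds (e.g. `"[NH+]1 = CC = CC = C1.[Br-]"`) parses.
#' `format = "smarts"` validates a query pattern and returns a
#' [SmartsPattern-class].
#'
#' @param text structure text.
#' @param format `"auto"`, `"smiles"`, `"molfile"` or `"smarts"`.
#' @param valence `"accept"` (store as submitted, the default — no
#'   standardisation is applied) or `"reject"` to signal a
#'   `chemreg_valence_error` for chemically impossible atoms.
#' @return a [Molecule-class] (or [SmartsPattern-class] for SMARTS).
#' @examples
#' mol <- parseStructure("CCO")
#' grossFormula(mol)
#' @export
parseStructure <- function(text, format = c("auto", "smiles", "molfile", "smarts"),
                           valence = c("accept", "reject")) {
  format <- match.arg(format)
  valence <- match.arg(valence)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    .crStop("chemreg_parse_error", "structure text must be a non-empty string")
  }
  if (format == "auto") {
    format <- if (grepl("V2000", text, fixed = TRUE)) "molfile" else "smiles"
  }
  if (format == "smarts") {
    probe <- .obProbeMol()
    ok <- tryCatch({
      ChemmineOB::smartsSearch_OB(probe, text)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) .crStop("chemreg_parse_error", sprintf("invalid SMARTS pattern: %s", text))
    return(new("SmartsPattern", pattern = text))
  }

  original <- text
  if (format == "smiles") {
    text <- .stripSmilesWhitespace(text)
    pv <- .preValidateSmiles(text)
    if (!pv$ok) {
      .crStop("chemreg_parse_error",
              sprintf("invalid SMILES at position %d: %s", pv$pos, pv$reason),
              position = pv$pos, reason = pv$reason)
    }
    from <- "SMI"
  } else {
    from <- "MOL"
  }

  molH <- .obConvert(from, "MOL", text, opts = data.frame(names = "h", args = ""))
  if (!nzchar(molH)) {
    .crStop("chemreg_parse_error",
            sprintf("structure text could not be parsed as %s", format))
  }
  mol2 <- .obConvert(from, "MOL2", text)
  canonical <- .obCanonical(from, text)
  mol <- .buildMolecule(molH, mol2, original, canonical)
  if (valence == "reject") .checkValence(mol)
  mol
}

# a tiny cached molecule for SMARTS validation probes
.obCache <- new.env(parent = emptyenv())
.obProbeMol <- function() {
  if (is.null(.obCache$probe)) {
    .obCache$probe <- ChemmineOB::forEachMol("SMILES", "C", identity)
  }
  .obCache$probe
}

# ---- molfile writer (explicit hydrogens, aromatic bonds as order 4) --------

.writeMolfile <- function(mol, title = "") {
  atoms <- mol@atoms
  bonds <- mol@bonds
  nH <- sum(atoms$hcount)
  natoms <- nrow(atoms) + nH
  extra <- data.frame(from = integer(), to = integer(), order = integer())
  if (nH > 0) {
    hIdx <- nrow(atoms)
    hFrom <- integer(nH)
    hTo <- integer(nH)
    k <- 1L
    for (i in seq_len(nrow(atoms))) {
      hc <- atoms$hcount[i]
      if (hc > 0) {
        for (j in seq_len(hc)) {
          hIdx <- hIdx + 1L
          hFrom[k] <- i
          hTo[k] <- hIdx
          k <- k + 1L
        }
      }
    }
    extra <- data.frame(from = hFrom, to = hTo, order = rep(1L, nH))
  }
  # prefer the stored kekulized orders: molfile bond order 4 is query-only
  # and kekulization of charged aromatics on re-read is not reliable
  writeOrd <- if ("kek" %in% names(bonds)) bonds$kek else bonds$order
  bonds <- data.frame(from = bonds$from, to = bonds$to, order = writeOrd)
  allBonds <- rbind(bonds, extra)
  lines <- c(
    title,
    "  ChemRegistry",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", natoms, nrow(allBonds))
  )
  atomLine <- function(el) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0", 0, 0, 0, el)
  }
  lines <- c(lines, vapply(atoms$element, atomLine, character(1)))
  if (nH > 0) lines <- c(lines, rep(atomLine("H"), nH))
  if (nrow(allBonds)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              allBonds$from, allBonds$to, allBonds$order))
  }
  propLine <- function(tag, idx, val) {
    out <- character()
    for (s in split(seq_along(idx), ceiling(seq_along(idx) / 8))) {
      out <- c(out, paste0(
        sprintf("M  %s%3d", tag, length(s)),
        paste0(sprintf("%4d%4d", idx[s], val[s]), collapse = "")
      ))
    }
    out
  }
  chg <- which(mol@atoms$charge != 0L)
  if (length(chg)) lines <- c(lines, propLine("CHG", chg, mol@atoms$charge[chg]))
  iso <- which(mol@atoms$isotope != 0L)
  if (length(iso)) lines <- c(lines, propLine("ISO", iso, mol@atoms$isotope[iso]))
  lines <- c(lines, "M  END")
  paste0(paste(lines, collapse = "\n"), "\n")
}

# ---- components ------------------------------------------------------------

.componentsMembership <- function(mol) {
  n <- nrow(mol@atoms)
  comp <- integer(n)
  bonds <- mol@bonds
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$from[r]]] <- c(adj[[bonds$from[r]]], bonds$to[r])
    adj[[bonds$to[r]]] <- c(adj[[bonds$to[r]]], bonds$from[r])
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      for (v in adj[[u]]) {
        if (comp[v] == 0L) {
          comp[v] <- cur
          queue <- c(queue, v)
        }
      }
    }
  }
  comp
}

#' @rdname splitComponents
setMethod("splitComponents", "Molecule", function(mol) {
  comp <- .componentsMembership(mol)
  k <- max(comp, 0L)
  if (k <= 1L) return(list(mol))
  out <- vector("list", k)
  for (ci in seq_len(k)) {
    idx <- which(comp == ci)
    rank <- integer(nrow(mol@atoms))
    rank[idx] <- seq_along(idx)
    keepB <- mol@bonds$from %in% idx
    b <- mol@bonds[keepB, , drop = FALSE]
    b$from <- rank[b$from]
    b$to <- rank[b$to]
    rownames(b) <- NULL
    a <- mol@atoms[idx, , drop = FALSE]
    rownames(a) <- NULL
    sub <- new("Molecule", atoms = a, bonds = b,
               sourceText = NA_character_, canonicalSmiles = NA_character_)
    can <- .obCanonical("MOL", .writeMolfile(sub))
    sub@canonicalSmiles <- can
    sub@sourceText <- if (is.na(can)) NA_character_ else can
    out[[ci]] <- sub
  }
  out
})

#' @rdname canonicalForm
setMethod("canonicalForm", "Molecule", function(mol) {
  if (!is.na(mol@canonicalSmiles)) return(mol@canonicalSmiles)
  can <- .obCanonical("MOL", .writeMolfile(mol))
  if (is.na(can)) {
    .crStop("chemreg_parse_error", "could not canonicalise molecule")
  }
  can
})
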