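#' @include sdf.R
NULL

#' Fixture generator specification
#'
#' @param nCompounds number of SD records.
#' @param mixtureFraction fraction of records that are mixtures; the number
#'   of multi-fragment records is `round(nCompounds * mixtureFraction)`,
#'   exact by construction.
#' @param maxHeavyAtoms cap on heavy atoms of a record's main component.
#' @param seed RNG seed; identical specs produce byte-identical SD-files.
#' @param namePrefix compound name prefix; names are
#'   `sprintf("%s%05d", namePrefix, i)`, so prefix filters of graded length
#'   select graded fractions of the set.
#' @return a [FixtureSpec-class].
#' @export
fixtureSpec <- function(nCompounds, mixtureFraction = 0.2, maxHeavyAtoms = 18L,
                        seed = 1L, namePrefix = "CR") {
  new("FixtureSpec", nCompounds = as.integer(nCompounds),
      mixtureFraction = mixtureFraction,
      maxHeavyAtoms = as.integer(maxHeavyAtoms), seed = as.integer(seed),
      namePrefix = namePrefix)
}

# fragment grammar: every entry is a valid, valence-legal SMILES fragment;
# scaffolds carry one substitution slot
.FIX_SCAFFOLDS <- c(
  "c1ccc(%s)cc1", "c1ccnc(%s)c1", "c1ccc2ccccc2c1", "c1csc(%s)c1",
  "c1ccc(%s)o1", "C1CCC(%s)CC1", "C1CCN(%s)CC1", "C1CCOC1", "C1CCNC1"
)
.FIX_SUBSTITUENTS <- c(
  "C", "CC", "CCC", "O", "OC", "N", "NC", "F", "Cl", "Br", "C(=O)O",
  "C(=O)OC", "C#N", "C(F)(F)F", "OCC", "CO", "CN", "C(C)C", "S", "SC",
  "N(C)C", "CCO", "C=C"
)
.FIX_PARTNERS <- c(
  "[Na+]", "[K+]", "[Cl-]", "[Br-]", "O", "CCO", "CS(=O)(=O)O", "Cl",
  "OC(=O)C(=O)O", "CC(=O)O"
)

.countHeavy <- function(smiles) {
  m <- gregexpr("Cl|Br|Si|Se|[BCNOPSFI]|[cnops]", smiles)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

.fixtureSmiles <- function(spec) {
  n <- spec@nCompounds
  maxH <- spec@maxHeavyAtoms
  scaffolds <- .FIX_SCAFFOLDS
  subs <- .FIX_SUBSTITUENTS
  main <- character(n)
  for (i in seq_len(n)) {
    if (stats::runif(1) < 0.6) {
      repeat {
        sc <- sample(scaffolds, 1L)
        sm <- if (grepl("%s", sc, fixed = TRUE)) {
          sprintf(sc, sample(subs, 1L))
        } else sc
        if (.countHeavy(sm) <= maxH) break
      }
      main[i] <- sm
    } else {
      k <- sample(3:min(maxH, 12L), 1L)
      letters <- sample(c("C", "N", "O"), k, replace = TRUE,
                        prob = c(0.72, 0.14, 0.14))
      # branches only on carbon keep every chain valence-legal
      toks <- vapply(seq_len(k), function(j) {
        if (j > 1L && j < k && letters[j] == "C" && stats::runif(1) < 0.2) {
          paste0(letters[j], "(C)")
        } else letters[j]
      }, character(1))
      main[i] <- paste(toks, collapse = "")
    }
  }
  nMix <- round(n * spec@mixtureFraction)
  mixIdx <- if (nMix > 0) sort(sample(seq_len(n), nMix)) else integer()
  full <- main
  for (i in mixIdx) {
    extra <- sample(.FIX_PARTNERS, sample(1:2, 1L))
    full[i] <- paste(c(main[i], extra), collapse = ".")
  }
  cas <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    u <- stats::runif(1)
    if (u < 0.65 || i == 1L) {
      cas[i] <- sprintf("%d-%02d-%d", sample(10000:99999, 1L),
                        sample(0:99, 1L), sample(0:9, 1L))
    } else if (u < 0.72) {
      prev <- cas[seq_len(i - 1L)]
      prev <- prev[!is.na(prev)]
      if (length(prev)) cas[i] <- sample(prev, 1L)
    }
  }
  data.frame(
    record = seq_len(n),
    name = sprintf("%s%05d", spec@namePrefix, seq_len(n)),
    cas = cas,
    smiles = full,
    n_components = lengths(strsplit(full, ".", fixed = TRUE)),
    stringsAsFactors = FALSE
  )
}

#' Generate a deterministic synthetic SD-file
#'
#' Molecules are assembled from a fragment grammar (aromatic and saturated
#' ring scaffolds with substituents, heteroatom chains, and salt/solvate
#' partners for mixture records), so every record is parseable and
#' valence-legal by construction. The same [fixtureSpec()] yields
#' byte-identical output. The manifest lists, per record, the name, CAS,
#' component count and the sorted set of structure keys — the expected
#' values that import tests check against.
#'
#' @param spec a [fixtureSpec()].
#' @param out path of the SD-file to write.
#' @param manifest compute structure keys for the manifest (set `FALSE` to
#'   skip the key computation for large fixture sets).
#' @param manifestPath optional TSV path for the manifest.
#' @return the manifest data.frame (without `keys` when `manifest = FALSE`),
#'   invisibly.
#' @export
genFixtures <- function(spec, out, manifest = TRUE, manifestPath = NULL) {
  validObject(spec)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec@seed)
  tab <- .fixtureSmiles(spec)

  sdf <- .obConvert("SMI", "SDF", paste0(paste(tab$smiles, collapse = "\n"), "\n"))
  if (!nzchar(sdf)) {
    .crStop("chemreg_store_error", "fixture SMILES failed SD conversion")
  }
  blocks <- strsplit(sdf, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  if (length(blocks) != nrow(tab)) {
    .crStop("chemreg_store_error", "fixture SD conversion returned unexpected record count")
  }
  recs <- character(nrow(tab))
  for (k in seq_len(nrow(tab))) {
    # line 1 is the (possibly empty) title line of the mol block
    lines <- strsplit(blocks[k], "\n", fixed = TRUE)[[1]]
    lines[1] <- tab$name[k]
    if (length(lines) >= 2L) lines[2] <- "  ChemRegistry"
    tagLines <- c(">  <compound_name>", tab$name[k], "")
    if (!is.na(tab$cas[k])) {
      tagLines <- c(tagLines, ">  <cas>", tab$cas[k], "")
    }
    recs[k] <- paste(c(lines, tagLines, "$$$$"), collapse = "\n")
  }
  writeLines(recs, out, sep = "\n")

  if (manifest) {
    keyCache <- new.env(parent = emptyenv())
    keyOf <- function(frag) {
      k <- keyCache[[frag]]
      if (is.null(k)) {
        k <- structureKey(parseStructure(frag))
        keyCache[[frag]] <- k
      }
      k
    }
    tab$keys <- vapply(strsplit(tab$smiles, ".", fixed = TRUE), function(frags) {
      paste(sort(unique(vapply(frags, keyOf, character(1)))), collapse = ";")
    }, character(1))
  }
  if (!is.null(manifestPath)) {
    utils::write.table(tab, manifestPath, sep = "\t", row.names = FALSE,
                       quote = TRUE, na = "NA")
  }
  invisible(tab)
}
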