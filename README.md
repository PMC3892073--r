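# ChemRegistry

An embeddable chemical compound registration database for R, with chemical
structure search. It is a library (plus a thin CLI) for building the systems
organic-chemistry research runs on — chemical registration systems,
inventory systems, in-house compound databases — where every piece of data
must be retrievable *by chemical structure*.

## What it does

* **Unique, immutable structures.** Every stored structure is keyed by its
  standard InChIKey (with a deterministic `XK-…` fallback when the InChI
  algorithm cannot represent a species). Saving a compound reuses existing
  structure rows and inserts only novel ones; editing a compound repoints
  its compositions and never mutates a structure row. Molecular weight and
  Hill-order gross formula are computed and stored per structure.
* **Mixtures.** A compound is a set of compositions; structure text with
  disconnected components (salts, solvates) is stored as a mixture of its
  distinct components, percentages unset. A search matches a compound when
  at least one component matches.
* **Five search modes** — exact (key equality), substructure, SMARTS,
  similarity and gross formula — combinable with property filters
  (`eq` / `like-prefix` / `range`), molecular-weight ranges and multi-field
  sorting. Similarity offers Tanimoto, Tversky (query-first asymmetry) and
  substructure-Euclidean (`c/a`) scores over hashed linear-path screening
  fingerprints; the fingerprint screen is sound for substructure search (no
  false negatives).
* **Paging with cached counts.** Results are paged (4 records per page by
  default, deterministic id tie-break); the total count is computed once
  per logical query and served from a cache that every write clears.
  Mixture-aware `distinct` semantics collapse per-component rows, with a
  store-wide default for single-component databases.
* **A query planner** that chooses between screening the structure index
  (`INDEX_SCREEN`) and fetching candidates by a selective property filter
  first, verifying each with the substructure matcher (`PROPERTY_FIRST`) —
  both provably returning the same hit set.
* **Registry semantics:** transactional saves with per-record rollback,
  audit metadata, optimistic locking (version column, incremented by 1 per
  update, stale updates rejected), pluggable duplicate-compound policies,
  and a pre-save hook per entity kind for normalisation or defaulting.
* **Batches and bar-coded containers** (containables/containers) that are
  structure-searchable through their compound, with optional role-based
  read filtering composed into the query and method-level write guards.
* **SD-file import and export** (V2000), mixture-aware, atomic per record,
  with exact roundtrips; and a deterministic synthetic fixture generator.

## Worked example

```r
library(ChemRegistry)

store <- chemStore()

# a salt: two ions in one structure text, stored as a mixture
out <- saveCompound(store,
  compoundDraft("pyridinium bromide", "[NH+]1 = CC = CC = C1.[Br-]",
                cas = "39416-48-3"),
  actor = "jdoe")
out
#> SaveOutcome: id 1, 2 structure(s) created, 0 reused

getCompound(store, "Compound", 1)$compositions
#>   structure_id               structure_key structure_text mol_weight percentage
#> 1            1 JUJWROOIHBZHMG-UHFFFAOYSA-O   c1ccc[nH+]c1     80.110         NA
#> 2            2 CPELXLSAUQHCOX-UHFFFAOYSA-M          [Br-]     79.904         NA

# a second compound sharing the bromide: the structure row is reused
saveCompound(store, compoundDraft("ethyl bromide soln", c("CCBr", "[Br-]")))
#> SaveOutcome: id 2, 1 structure(s) created, 1 reused

# an exact search for the bromide ion returns both compounds
page <- searchCompounds(store, searchRequest(
  structure = structureQuery("exact", "[Br-]"), distinct = TRUE))
page
#> Page 0 (size 4): 2 item(s) of 2 total
pageItems(page)[, c("id", "compound_name", "cas", "version")]
#>   id      compound_name        cas version
#> 1  1 pyridinium bromide 39416-48-3       0
#> 2  2 ethyl bromide soln       <NA>       0
```

The two `structures created` lines show InChIKey dedup at work: the salt
created rows for the pyridinium cation and bromide; the second save created
only the novel `CCBr` row and reused the bromide. The `version` column is
the optimistic-locking counter checked by `updateCompound()`.

## Command line

```sh
Rscript inst/scripts/chemreg.R init --store db
Rscript inst/scripts/chemreg.R gen-fixtures --file fx.sdf --n 1000 --seed 7
Rscript inst/scripts/chemreg.R import --store db --file fx.sdf
Rscript inst/scripts/chemreg.R search --store db --mode sub --query c1ccccc1 \
    --filter 'compound_name^=CR000' --page 0 --page-size 4
```

The store persists as a directory of TSV tables plus the count cache, so
paging across invocations reuses the cached total.

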