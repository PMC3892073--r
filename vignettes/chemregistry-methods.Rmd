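---
title: "ChemRegistry: design and methods of a structure-searchable compound registry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ChemRegistry: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Organic chemistry research produces compounds together with analytical,
physicochemical and administrative data, and the scientists involved must be
able to store this material and retrieve it *by chemical structure*.
ChemRegistry is an embeddable registration-database library for building such
systems in R: a chemical registration system, an inventory system, or a plain
compound database. The domain model has four layers:

* **structures** — unique, immutable chemical graphs keyed by standard
  InChIKey, with stored molecular weight and gross formula;
* **compounds** — descriptive entities made of one or more *compositions*
  (structure memberships with an optional relative-occurrence percentage); a
  compound with several compositions is a mixture;
* **containables** — batches (registration) or lots (inventory) of one
  compound;
* **containers** — physically existing, bar-coded vessels holding exactly
  one containable.

Users operate on compounds; the registry manages structures. When a compound
is saved, each component structure is resolved by its InChIKey: an existing
row is reused, a novel one is inserted. Editing a compound never mutates a
structure row — the edit repoints the composition to the
(existing-or-created) row of the new structure and the old row remains. This
unique-and-immutable discipline is what makes dedup, audit and
cross-referencing reliable, and the tests pin it down to byte-identical old
rows after edits.

# Structure identity

The identity of a stored structure is its **standard InChIKey** (27
characters, `14-10-1` layout), computed by the InChI algorithm via
OpenBabel. Keys canonicalise over atom order and input notation, so `OCC`
and `CCO` resolve to one row. For the rare species the InChI algorithm
cannot represent, a fallback key `"XK-" + MD5(canonical SMILES)` (32 hex
digits) preserves the unique-constraint mechanism; fallback keys are
deterministic and collide only on digest collision.

Two caveats are deliberate design choices. First, **no
standardisation/normalisation is applied**: structures are stored exactly as
submitted. Tautomer drawing variants therefore register as distinct
structures unless the application installs a pre-save hook that normalises
drafts (that hook — one per entity kind, run inside the save transaction on
both create and update — is the designated extension point). Second, the
standard InChIKey folds protonation state into its final character, so
pyridine and pyridinium get distinct keys, which is the behaviour a registry
wants.

# Mixtures and salts

A draft composition whose text contains several disconnected components is
treated as a mixture: one composition per **distinct** component, with no
percentages set. A salt written as `[NH+]1=CC=CC=C1.[Br-]` becomes a
two-composition compound; a doubly charged salt with two identical anions,
`[NH+]1=CC=[NH+]C=C1.[Br-].[Br-]`, stores as a mixture of the dication and
the bromide — the duplicate anion collapses because a composition is a
(compound, structure) membership and the structure table is deduplicated.
The graph-level `splitComponents()` still reports all three fragments;
collapsing is registry semantics, not chemistry. Stoichiometric multiplicity
is representable through the percentage field when an application needs it.

Searching is component-based: a compound matches when **at least one** of
its components satisfies the structure query, and molecular-weight bounds
apply to that same matching component. An exact search for either ion of a
salt therefore returns the salt.

# Matching and the screening fingerprint

Substructure verification uses subgraph *monomorphism* (extra bonds among
mapped target atoms are allowed, so a propane chain matches cyclopropane)
respecting element, formal charge, aromaticity and bond order. Implicit
hydrogens on the query do not constrain the target; SMARTS mode (OpenBabel
dialect) is the escape hatch for precise constraints such as `[CH3]`.
Aromaticity is OpenBabel's perception, applied uniformly to stored and query
molecules — consistency within the system is what the invariants require,
since every substructure semantics is only meaningful relative to one
aromaticity model.

Candidate pruning uses a **hashed linear-path fingerprint**: all simple
paths of 1–7 atoms are encoded over (element, charge, aromaticity) atom
invariants and bond orders, hashed direction-invariantly (FNV-1a of the
lexicographically smaller direction) into 2048 bits. Because the matcher
compares exactly the invariants the paths encode, every path of a true
subgraph is a path of its target, so the screen `fp(Q) & fp(T) == fp(Q)` is
*sound* — it never rejects a true match. The tests drive this with 500+
random edge-deleted subgraph pairs against an independent igraph VF2 oracle.
Path length 7 and 2048 bits are the defaults because typical registry
molecules (10–40 heavy atoms) then set a few hundred bits, sparse enough to
discriminate; both are configurable, and fingerprints are only comparable
when their parameter identifier matches.

Similarity search scores fingerprints with `a = |A|`, `b = |B|`,
`c = |A ∩ B|`:

* Tanimoto (Jaccard): `c / (a + b − c)`;
* Tversky: `c / (α(a−c) + β(b−c) + c)` — the first argument is the query
  (asymmetry convention, test-pinned);
* substructure-Euclidean: `c / a`, the fraction of query bits present in the
  target. The exact substructure-Euclidean formula of database cartridges is
  not published; `c/a` is adopted here because it is the natural
  "containment fraction" and reduces to Tversky(1, 0).

`0/0` is defined as 1: two empty fingerprints are identical, and identity
consistency outranks the convention's other degenerate readings. Bounds are
inclusive on both ends; `maxScore` defaults to 1.

# Search execution, paging and the count cache

A search request combines an optional structure query with property filters
(`eq`, `like-prefix`, `range`), multi-field sorting (id ascending is always
appended — paging without a total order is not reproducible), 0-based paging
(default 4 records per page) and the `distinct` flag. With
`distinct = FALSE` a mixture contributes one row per matching component;
with `distinct = TRUE` each compound appears once. Distinct is implemented
by dedup-on-compound-id during candidate assembly, so both planner
strategies share one code path, and a store-wide default
(`setDistinctDefault`) lets single-component databases skip the distinct
pass — their result sets are provably identical either way. Paging requires
the total count; recounting on every page is wasteful, so the total is
**cached** keyed by the normalised logical query (target, canonicalised
structure query, filters, distinct flag, and the user's role set when
security is enabled — counts are never shared across privilege levels). Any
write clears the whole cache. That is coarser than per-entity-kind
invalidation, but container and containable results reach through compound
rows, so the coarse clear is the simplest provably coherent rule; the
coherence tests recheck 100 random query/write interleavings.

# The query planner

A structure index scan is a poor plan when a property filter is highly
selective — verifying a handful of candidates beats screening the whole
structure table. The planner estimates the property-filter candidate count
from exact table statistics (distinct counts for `eq`, 6-character prefix
buckets for `like-prefix` with a 10× thinning per extra prefix character,
value-range interpolation for `range`) and chooses `PROPERTY_FIRST` when the
estimate is at most `τ = 0.05` of the table and at most `N_max = 5000` rows;
otherwise `INDEX_SCREEN`. Both strategies return identical hit sets by
construction — the planner only chooses evaluation order — and the
equivalence is tested over a selectivity sweep. `PROPERTY_FIRST` requires a
property filter; planning applies to the verification-bound modes (`sub`,
`smarts`). τ and `N_max` are configurable; the defaults mark the regime
where per-candidate verification (∼0.1 ms each) clearly undercuts a full
screen.

# The store, transactions and audit metadata

The store is an in-process set of tables inside an environment, with the
relational constraints enforced at the store layer (unique structure key,
unique non-null barcode, unique role names, unique compound–structure
membership), raw-insert accessible for testing, and TSV-directory
persistence for the CLI. Every entity carries audit metadata (creator,
modifier, UTC timestamps) and an optimistic-locking **version** column:
created at 0, incremented by exactly 1 per successful update, and checked
against the caller's `expectedVersion` so concurrent modifications surface
as `chemreg_concurrent_modification_error` instead of lost updates.
Registry operations are transactional via an undo journal (append
watermarks, pre-image snapshots): a failure anywhere — including inside a
user hook — rolls every table back, which the tests check with row-count
snapshots around injected failures. Compound types follow
table-per-concrete-class semantics: each registered type owns its compound
and containable tables and is stored and searched independently. CAS numbers
are nullable and deliberately not unique; duplicate-compound policy is
pluggable (`none` by default, `by-cas`, `by-composition`, or a custom
function), because which duplicates to reject is an application decision.
Deleting a compound retains orphaned structure rows — immutability favours
retention.

# Security model

Authorization is optional and entirely off by default: a disabled context
makes every read predicate constant-true and every write allowed.
When enabled, compounds and containables carry a nullable `read_role`; a row
is readable iff its role is null or among the caller's roles, and the
predicate is composed **into** the query — never applied after paging — so
page contents and totals are consistent and hidden rows never leak through
counts. Container searches require both the containable's and the compound's
read role (conjunction: a container is as secret as anything it reaches).
Writes pass a method-level guard with deny-by-default when a kind is missing
from the permission map. Authentication is out of scope; the caller supplies
the user name.

# SD-file exchange

Import reads MDL SD-files (V2000; CRLF or LF; multi-line and ordered
property values; a truncated or malformed record fails alone and is reported
with its index). Each record becomes one draft; disconnected fragments are
assumed to be a mixture. Import is atomic per record, not per file. Export
writes one record per compound — mixtures as a single multi-fragment mol
block in composition order — with selected fields as property tags and a
`percentages` tag when set; the mol-block header's timestamp line is fixed
to a constant so identical stores export byte-identical files. Structures
are stored as canonical SMILES; V3000 and reaction files are out of scope.

# The synthetic fixture generator

`genFixtures()` assembles molecules from a fragment grammar — aromatic and
saturated ring scaffolds with one substitution slot, a substituent
vocabulary, heteroatom chains with carbon-only branching, and salt/solvate
partners for mixtures — so every record is parseable and valence-legal by
construction, with common fragments recurring to exercise dedup. Mixture
counts are exact (`round(n × fraction)` records get 1–2 extra fragments),
names are zero-padded (`CR00001`, …) so prefix filters of graded length
select graded fractions, and ∼65% of records get a CAS-shaped number with
occasional deliberate duplicates. Output is byte-identical per seed and the
session RNG state is restored. What the generator does **not** emulate:
stereochemistry, isotopic labelling, macrocycles, tautomer-prone motifs and
the size distribution of real vendor catalogues — so passing tests show the
machinery is correct on representative drug-like graphs, not that every
exotic chemotype round-trips.

# Numerical and degenerate-input choices

* Molecular weights come from an embedded IUPAC 2021 abridged standard
  atomic weight table (reproducible to 0.01 g/mol); isotope-labelled atoms
  contribute their mass number — an approximation of order 0.1 g/mol,
  acceptable because weight is a search range, not an analytical quantity.
* Gross formulas are Hill-ordered with charge excluded, so formula search is
  plain text equality on normalised counts (`H6C6` finds benzene).
* Explicit hydrogens fold into the heavy-atom graph's implicit counts; an
  all-hydrogen species keeps its atoms.
* Whitespace inside SMILES is stripped before parsing (structure text is
  often printed with spaces around bonds).
* The valence policy defaults to accept-as-is (no normalisation); `reject`
  enables a light typical-valence check.
* Empty query graphs match trivially; zero-hit pages are empty data frames
  with a zero total.
* Percentages live in (0, 100], sum at most 100 (+1e−9 tolerance); unset
  means unknown.

# Problem sizes used by the test suite

The acceptance-style tests run against synthetic stores of 300 (cache
coherence), 1,000 (planner sweep), 2,000 (distinct/paging invariants, 20%
mixtures) and 10,000 compounds (the five-query paging protocol with 4
records per page), 500 screening pairs and 1,000 matcher/oracle pairs —
sizes chosen so the whole suite exercises every code path at
registry-realistic scale while staying a desk-side run.

# Known limitations

* No tautomer or resonance-aware search modes; no 3D or stereo-aware
  matching (stereo descriptors survive in stored SMILES but do not
  constrain substructure matches).
* The embedded store targets embedded/single-process use; there is no
  server backend, schema migration or soft delete.
* SMARTS mode scans candidates without a fingerprint screen (a sound screen
  for arbitrary SMARTS would require pattern-bit analysis), so it pairs
  best with property filters.
* Isotope masses are mass numbers, not exact isotopic masses.
* The count cache clears wholesale on any write; a high-write workload
  recounts more than a finer-grained invalidation would.
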