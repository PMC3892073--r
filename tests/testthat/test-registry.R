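# Registry service: dedup, immutability, optimistic locking, hooks,
# uniqueness policies, atomicity.

test_that("saving reuses existing structures by key", {
  store <- chemStore()
  o1 <- saveCompound(store, compoundDraft("ethanol", "CCO"))
  expect_identical(o1@structuresCreated, 1L)
  expect_identical(o1@structuresReused, 0L)
  nStruct <- nrow(ChemRegistry:::.tbl(store, "structures"))
  o2 <- saveCompound(store, compoundDraft("ethanol again", "OCC"))
  expect_identical(o2@structuresCreated, 0L)
  expect_identical(o2@structuresReused, 1L)
  expect_identical(nrow(ChemRegistry:::.tbl(store, "structures")), nStruct)
})

test_that("salts split into per-component compositions without percentages", {
  store <- chemStore()
  o <- quietly(saveCompound(store, compoundDraft("pyridinium bromide",
                                                 "[NH+]1 = CC = CC = C1.[Br-]")))
  expect_identical(length(o@record$compositions), 2L)
  expect_true(all(is.na(vapply(o@record$compositions,
                               function(x) x$percentage, numeric(1)))))

  # multiply-charged salt: stored as a mixture of the two distinct ions
  o2 <- quietly(saveCompound(store, compoundDraft("dication dibromide",
                                                  "[NH+]1=CC=[NH+]C=C1.[Br-].[Br-]")))
  expect_identical(length(o2@record$compositions), 2L)
  expect_identical(o2@structuresCreated, 1L) # bromide reused from the first salt
  expect_identical(o2@structuresReused, 1L)

  # exact search for either ion returns the salt
  hits <- searchCompounds(store, searchRequest(
    structure = quietly(structureQuery("exact", "[Br-]")), distinct = TRUE))
  expect_identical(totalCount(hits), 2L)
})

test_that("updates use optimistic locking and leave old structures untouched", {
  store <- chemStore()
  o <- saveCompound(store, compoundDraft("x", "CCO"))
  id <- o@record$id
  stBefore <- ChemRegistry:::.tbl(store, "structures")

  u <- updateCompound(store, compoundDraft("x2", "CCN", id = id, expectedVersion = 0L))
  expect_identical(u@record$version, 1L)

  # old structure row byte-identical after the edit
  stAfter <- ChemRegistry:::.tbl(store, "structures")
  expect_identical(stAfter[1, ], stBefore[1, ])
  expect_identical(nrow(stAfter), 2L)
  cmp <- getCompound(store, "Compound", id)
  expect_identical(cmp$compositions$structure_text, "CCN")

  # stale version detected
  expect_error(
    updateCompound(store, compoundDraft("x3", "CCC", id = id, expectedVersion = 0L)),
    class = "chemreg_concurrent_modification_error"
  )
  # version increments by exactly one per successful update
  u2 <- updateCompound(store, compoundDraft("x3", "CCC", id = id, expectedVersion = 1L))
  expect_identical(u2@record$version, 2L)

  expect_error(
    updateCompound(store, compoundDraft("y", "C", id = 999L, expectedVersion = 0L)),
    class = "chemreg_not_found_error"
  )
})

test_that("replaceStructure repoints all referencing compositions", {
  store <- chemStore()
  saveCompound(store, compoundDraft("a", "CCO"))
  saveCompound(store, compoundDraft("b", c("CCO", "c1ccccc1")))
  key <- structureKey(parseStructure("CCO"))
  n <- replaceStructure(store, key, "CCCO")
  expect_identical(n, 2L)
  for (id in 1:2) {
    texts <- getCompound(store, "Compound", id)$compositions$structure_text
    expect_true("CCCO" %in% texts)
    expect_false("CCO" %in% texts)
  }
  # the old row remains
  st <- ChemRegistry:::.tbl(store, "structures")
  expect_true(key %in% st$structure_key)

  # replacing toward an existing structure repoints without creating a row
  key2 <- structureKey(parseStructure("c1ccccc1"))
  nr <- nrow(st)
  n2 <- replaceStructure(store, structureKey(parseStructure("CCCO")), "c1ccccc1")
  expect_identical(n2, 2L)
  expect_identical(nrow(ChemRegistry:::.tbl(store, "structures")), nr)
  # compound b now references benzene only once (duplicates collapse)
  expect_identical(nrow(getCompound(store, "Compound", 2L)$compositions), 1L)

  expect_error(replaceStructure(store, "NOSUCHKEY", "CCO"),
               class = "chemreg_not_found_error")
})

test_that("containers enforce barcode uniqueness through the registry", {
  store <- chemStore()
  o <- saveCompound(store, compoundDraft("a", "CCO"))
  ct <- saveContainable(store, "Compound", o@record$id)
  expect_identical(ct@record$version, 0L)
  rec <- saveContainer(store, "BC-1", "Compound", ct@record$id)
  expect_identical(rec$version, 0L)
  expect_error(saveContainer(store, "BC-1", "Compound", ct@record$id),
               class = "chemreg_uniqueness_error")
  expect_error(saveContainer(store, NA, "Compound", ct@record$id),
               class = "chemreg_constraint_error")
  expect_error(saveContainable(store, "Compound", 999L),
               class = "chemreg_constraint_error")
  expect_error(saveContainer(store, "BC-2", "Compound", 999L),
               class = "chemreg_constraint_error")
})

test_that("pre-save hooks run on create and update, and abort atomically", {
  store <- chemStore()
  registerPreSaveHook(store, "compound", function(draft) {
    draft$compoundName <- toupper(draft$compoundName)
    draft
  })
  o <- saveCompound(store, compoundDraft("quiet", "CCO"))
  expect_identical(o@record$compound_name, "QUIET")
  u <- updateCompound(store, compoundDraft("louder", "CCO", id = o@record$id,
                                           expectedVersion = 0L))
  expect_identical(u@record$compound_name, "LOUDER")

  # a raising hook leaves every table unchanged
  snapshot <- vapply(names(store@.env$tables),
                     function(n) nrow(ChemRegistry:::.tbl(store, n)), integer(1))
  registerPreSaveHook(store, "compound", function(draft) stop("hook failed"))
  expect_error(saveCompound(store, compoundDraft("nope", "CCN")))
  after <- vapply(names(store@.env$tables),
                  function(n) nrow(ChemRegistry:::.tbl(store, n)), integer(1))
  expect_identical(after, snapshot)

  # removing the hook restores default behaviour
  registerPreSaveHook(store, "compound", NULL)
  o2 <- saveCompound(store, compoundDraft("plain", "CCN"))
  expect_identical(o2@record$compound_name, "plain")
})

test_that("mid-save failures roll back partial structure inserts", {
  store <- chemStore()
  saveCompound(store, compoundDraft("seed", "CCO"))
  snapshot <- nrow(ChemRegistry:::.tbl(store, "structures"))
  # second composition is unparseable: the valid first one must roll back too
  expect_error(
    quietly(saveCompound(store, compoundDraft("broken", c("c1ccccc1", "C1CC")))),
    class = "chemreg_parse_error"
  )
  expect_identical(nrow(ChemRegistry:::.tbl(store, "structures")), snapshot)
  expect_identical(nrow(ChemRegistry:::.tbl(store, "compounds_Compound")), 1L)
  expect_identical(nrow(ChemRegistry:::.tbl(store, "compositions")), 1L)
})

test_that("the structure table grows monotonically, by novel keys only", {
  store <- chemStore()
  texts <- c("CCO", "CCN", "CCO", "c1ccccc1", "OCC", "CCN.CCO", "c1ccccc1")
  novel <- character()
  for (i in seq_along(texts)) {
    before <- ChemRegistry:::.tbl(store, "structures")
    o <- quietly(saveCompound(store, compoundDraft(sprintf("c%d", i), texts[i])))
    after <- ChemRegistry:::.tbl(store, "structures")
    # old rows never mutated
    expect_identical(after[seq_len(nrow(before)), ], before)
    keys <- quietly(vapply(splitComponents(parseStructure(texts[i])),
                           structureKey, character(1)))
    newKeys <- setdiff(unique(keys), novel)
    expect_identical(nrow(after) - nrow(before), length(newKeys))
    novel <- c(novel, newKeys)
  }
})

test_that("uniqueness policies reject duplicates as configured", {
  store <- chemStore()
  # default policy is permissive
  saveCompound(store, compoundDraft("a", "CCO", cas = "64-17-5"))
  saveCompound(store, compoundDraft("b", "CCO", cas = "64-17-5"))

  setUniquenessPolicy(store, "Compound", "by-cas")
  expect_error(saveCompound(store, compoundDraft("c", "CCN", cas = "64-17-5")),
               class = "chemreg_uniqueness_error")
  saveCompound(store, compoundDraft("c", "CCN", cas = "107-15-3"))

  setUniquenessPolicy(store, "Compound", "by-composition")
  expect_error(saveCompound(store, compoundDraft("d", "OCC")),
               class = "chemreg_uniqueness_error")
  saveCompound(store, compoundDraft("d", c("CCO", "CCN")))

  # an update may keep its own composition under the policy (self excluded)
  cmp <- getCompound(store, "Compound", 4L)
  u <- updateCompound(store, compoundDraft("d2", c("CCO", "CCN"),
                                           id = 4L, expectedVersion = cmp$version))
  expect_identical(u@record$compound_name, "d2")
})

test_that("deleting a compound retains orphan structures", {
  store <- chemStore()
  o <- saveCompound(store, compoundDraft("gone", "CCO"))
  deleteCompound(store, "Compound", o@record$id)
  expect_identical(nrow(ChemRegistry:::.tbl(store, "compounds_Compound")), 0L)
  expect_identical(nrow(ChemRegistry:::.tbl(store, "compositions")), 0L)
  expect_identical(nrow(ChemRegistry:::.tbl(store, "structures")), 1L)
  o2 <- saveCompound(store, compoundDraft("back", "CCO"))
  expect_identical(o2@structuresReused, 1L)
})
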