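# Search engine: mixture-aware distinct semantics, paging, count cache,
# planner, molecular weight ranges, CAS lookup.

mixture_store <- function() {
  store <- chemStore()
  saveCompound(store, compoundDraft("hexane", "CCCCCC", cas = "110-54-3"))
  saveCompound(store, compoundDraft("ethanol", "CCO", cas = "64-17-5"))
  saveCompound(store, compoundDraft("M", c("c1ccccc1", "Cc1ccccc1")))
  store
}

test_that("a compound matches when at least one component matches", {
  store <- mixture_store()
  p <- searchCompounds(store, searchRequest(
    structure = structureQuery("sub", "c1ccccc1"), distinct = TRUE))
  expect_identical(totalCount(p), 1L)
  expect_identical(pageItems(p)$compound_name, "M")

  # non-distinct: one row per matching component
  pn <- searchCompounds(store, searchRequest(
    structure = structureQuery("sub", "c1ccccc1"), distinct = FALSE))
  expect_identical(totalCount(pn), 2L)
  expect_identical(unique(pageItems(pn)$compound_name), "M")
  expect_identical(length(unique(pageItems(pn)$structure_id)), 2L)
})

test_that("distinct results are the compound projection of non-distinct results", {
  store <- chemStore()
  f <- tempfile(fileext = ".sdf")
  quietly(genFixtures(fixtureSpec(80, mixtureFraction = 0.25, seed = 3), f,
                      manifest = FALSE))
  quietly(importCompounds(store, f, mapping = c(compound_name = "compound_name")))
  for (q in c("C", "c1ccccc1", "CCO", "O")) {
    sq <- structureQuery("sub", q)
    d <- pageItems(searchCompounds(store, searchRequest(
      structure = sq, distinct = TRUE, pageSize = 10000L)))
    n <- pageItems(searchCompounds(store, searchRequest(
      structure = sq, distinct = FALSE, pageSize = 10000L)))
    expect_identical(sort(unique(n$id)), sort(d$id), info = q)
    expect_lte(nrow(d), nrow(n))
  }
})

test_that("similarity search at score 1 returns exactly the query compound", {
  store <- mixture_store()
  p <- searchCompounds(store, searchRequest(
    structure = structureQuery("similarity", "CCO", minScore = 1.0),
    distinct = TRUE))
  expect_identical(pageItems(p)$compound_name, "ethanol")
})

test_that("molecular weight bounds restrict the matching component", {
  store <- mixture_store()
  # benzene is ~78, toluene ~92: bounds select within the mixture M
  p <- searchCompounds(store, searchRequest(
    structure = structureQuery("sub", "c1ccccc1", mwMin = 85, mwMax = 100),
    distinct = FALSE))
  expect_identical(totalCount(p), 1L)
  key <- pageItems(p)$structure_key
  expect_identical(key, structureKey(parseStructure("Cc1ccccc1")))
})

test_that("paging concatenates exactly and totals stay constant", {
  store <- mixture_store()
  saveCompound(store, compoundDraft("propane", "CCC"))
  saveCompound(store, compoundDraft("butane", "CCCC"))
  # 5 hits, page size 4: page 0 has 4 items, page 1 has 1, both count 5
  sq <- structureQuery("sub", "C")
  p0 <- searchCompounds(store, searchRequest(structure = sq, pageIndex = 0L,
                                             pageSize = 4L, distinct = TRUE))
  p1 <- searchCompounds(store, searchRequest(structure = sq, pageIndex = 1L,
                                             pageSize = 4L, distinct = TRUE))
  expect_identical(nrow(pageItems(p0)), 4L)
  expect_identical(nrow(pageItems(p1)), 1L)
  expect_identical(totalCount(p0), 5L)
  expect_identical(totalCount(p1), 5L)
  # concatenated pages equal the unpaged sorted result, no duplicates
  unpaged <- pageItems(searchCompounds(store, searchRequest(
    structure = sq, pageSize = 1000L, distinct = TRUE)))
  got <- rbind(pageItems(p0), pageItems(p1))
  expect_identical(got$id, unpaged$id)
  expect_false(any(duplicated(got$id)))
})

test_that("sorting is deterministic with id as final tie-break", {
  store <- mixture_store()
  p <- searchCompounds(store, searchRequest(
    sort = list(c("compound_name", "desc")), pageSize = 10L))
  nm <- pageItems(p)$compound_name
  expect_identical(nm, sort(nm, decreasing = TRUE))
  expect_error(
    searchCompounds(store, searchRequest(sort = list(c("no_such_field", "asc")))),
    class = "chemreg_unknown_field_error"
  )
})

test_that("counts are cached per query and invalidated by writes", {
  store <- mixture_store()
  sq <- structureQuery("sub", "c1ccccc1")
  base <- storeCounters(store)$count_computations
  p0 <- searchCompounds(store, searchRequest(structure = sq, pageIndex = 0L))
  p1 <- searchCompounds(store, searchRequest(structure = sq, pageIndex = 1L))
  expect_false(countFromCache(p0))
  expect_true(countFromCache(p1))
  expect_identical(storeCounters(store)$count_computations, base + 1L)

  # an equivalent query text hits the same cache entry
  p2 <- searchCompounds(store, searchRequest(structure = structureQuery("sub", "C1=CC=CC=C1")))
  expect_true(countFromCache(p2))

  # any write clears the cache
  saveCompound(store, compoundDraft("new", "CCCO"))
  expect_identical(length(ls(store@.env$cache)), 0L)
  p3 <- searchCompounds(store, searchRequest(structure = sq))
  expect_false(countFromCache(p3))

  # distinct and non-distinct counts are cached separately
  nd <- searchCompounds(store, searchRequest(structure = sq, distinct = FALSE))
  expect_false(countFromCache(nd))
  expect_lte(totalCount(p3), totalCount(nd))
})

test_that("the planner picks PROPERTY_FIRST only for selective filters", {
  store <- chemStore()
  f <- tempfile(fileext = ".sdf")
  quietly(genFixtures(fixtureSpec(300, mixtureFraction = 0.1, seed = 17), f,
                      manifest = FALSE))
  quietly(importCompounds(store, f,
                          mapping = c(compound_name = "compound_name", cas = "cas")))
  st <- tableStats(store)

  narrow <- searchRequest(structure = structureQuery("sub", "C"),
                          filters = list(list(field = "compound_name",
                                              op = "like-prefix", value = "CR00001")))
  expect_identical(planSearch(narrow, st)@strategy, "PROPERTY_FIRST")

  broad <- searchRequest(structure = structureQuery("sub", "C"),
                         filters = list(list(field = "compound_name",
                                             op = "like-prefix", value = "CR")))
  expect_identical(planSearch(broad, st)@strategy, "INDEX_SCREEN")

  nofilter <- searchRequest(structure = structureQuery("sub", "C"))
  expect_identical(planSearch(nofilter, st)@strategy, "INDEX_SCREEN")

  # both strategies return identical hit sets, and the property-first path
  # verifies no more structures than the filtered candidates reference
  for (val in c("CR0001", "CR001", "CR00022")) {
    req <- searchRequest(structure = structureQuery("sub", "c1ccccc1"),
                         filters = list(list(field = "compound_name",
                                             op = "like-prefix", value = val)),
                         distinct = TRUE, pageSize = 10000L)
    store@.env$config$planner$tau <- 0.05
    a <- searchCompounds(store, req)
    va <- storeCounters(store)$last_verified
    store@.env$config$planner$tau <- 0 # force INDEX_SCREEN
    b <- searchCompounds(store, req)
    store@.env$config$planner$tau <- 0.05
    expect_identical(sort(pageItems(a)$id), sort(pageItems(b)$id), info = val)
    if (a@plan@strategy == "PROPERTY_FIRST") {
      nCand <- length(unique(ChemRegistry:::.tbl(store, "compositions")$structure_id[
        ChemRegistry:::.tbl(store, "compositions")$compound_id %in%
          pageItems(searchCompounds(store, searchRequest(
            filters = req@filters, pageSize = 10000L)))$id]))
      expect_lte(va, nCand)
    }
  }
})

test_that("the distinct default applies when requests leave it unset", {
  store <- mixture_store()
  setDistinctDefault(store, FALSE)
  p <- searchCompounds(store, searchRequest(structure = structureQuery("sub", "c1ccccc1")))
  expect_identical(totalCount(p), 2L) # duplicate rows from the mixture
  # per-request distinct overrides the default
  p2 <- searchCompounds(store, searchRequest(structure = structureQuery("sub", "c1ccccc1"),
                                             distinct = TRUE))
  expect_identical(totalCount(p2), 1L)
  # with only single-component compounds the default does not change results
  single <- chemStore()
  setDistinctDefault(single, FALSE)
  saveCompound(single, compoundDraft("a", "CCO"))
  saveCompound(single, compoundDraft("b", "CCC"))
  pd <- searchCompounds(single, searchRequest(structure = structureQuery("sub", "C")))
  pt <- searchCompounds(single, searchRequest(structure = structureQuery("sub", "C"),
                                              distinct = TRUE))
  expect_identical(sort(pageItems(pd)$id), sort(pageItems(pt)$id))
  expect_identical(totalCount(pd), totalCount(pt))
})

test_that("formula and smarts search modes work through the engine", {
  store <- mixture_store()
  pf <- searchCompounds(store, searchRequest(
    structure = structureQuery("formula", "H6C6"), distinct = TRUE))
  expect_identical(pageItems(pf)$compound_name, "M")
  ps <- searchCompounds(store, searchRequest(
    structure = structureQuery("smarts", "[cH3]"), distinct = TRUE))
  expect_identical(totalCount(ps), 0L)
  ps2 <- searchCompounds(store, searchRequest(
    structure = structureQuery("smarts", "c[CH3]"), distinct = TRUE))
  expect_identical(pageItems(ps2)$compound_name, "M")
})

test_that("findByCas returns all matches and never matches null", {
  store <- chemStore()
  saveCompound(store, compoundDraft("a", "CCO", cas = "64-17-5"))
  saveCompound(store, compoundDraft("b", "CCN", cas = "64-17-5"))
  saveCompound(store, compoundDraft("c", "CCC"))
  expect_identical(nrow(findByCas(store, "64-17-5")), 2L)
  expect_identical(nrow(findByCas(store, "0-00-0")), 0L)
  expect_identical(nrow(findByCas(store, NA)), 0L)
})
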