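# Fingerprints, screening, substructure/SMARTS/exact/formula matching and
# similarity metrics.

test_that("fingerprints are deterministic and non-empty", {
  p <- fpParams()
  a <- fingerprint(parseStructure("c1ccc(Cl)cc1CCN"), p)
  b <- fingerprint(parseStructure("c1ccc(Cl)cc1CCN"), p)
  expect_identical(fpBits(a), fpBits(b))
  expect_identical(fpParamsId(a), p$id)
  expect_gte(fpPopcount(fingerprint(parseStructure("C"), p)), 1L)
})

test_that("multi-component fingerprint equals the OR of component fingerprints", {
  p <- fpParams()
  mix <- quietly(parseStructure("CCO.c1ccccc1"))
  comps <- quietly(splitComponents(mix))
  orBits <- Reduce(`|`, lapply(comps, function(m) fpBits(fingerprint(m, p))))
  expect_identical(fpBits(fingerprint(mix, p)), orBits)
})

test_that("fingerprint screen is sound: no false negatives on true subgraphs", {
  set.seed(202)
  smiles <- fixture_smiles(120, seed = 31)
  p <- fpParams()
  pairs <- 0L
  while (pairs < 500L) {
    sm <- sample(smiles, 1L)
    target <- quietly(parseStructure(sm))
    query <- delete_edges_subgraph(target, sample(0:3, 1L))
    expect_true(or_subgraph_match(target, query)) # true subgraph by construction
    expect_true(screenPass(fingerprint(query, p), fingerprint(target, p)))
    pairs <- pairs + 1L
  }
})

test_that("substructure matcher agrees with the brute-force oracle", {
  set.seed(303)
  pool <- unique(fixture_smiles(150, seed = 77))
  mols <- quietly(lapply(pool, parseStructure))
  mols <- Filter(function(m) nrow(molAtoms(m)) <= 12L, mols)
  expect_gte(length(mols), 20L)
  checked <- 0L
  agree <- TRUE
  while (checked < 400L) {
    t <- mols[[sample(length(mols), 1L)]]
    q <- if (runif(1) < 0.5) {
      delete_edges_subgraph(mols[[sample(length(mols), 1L)]], sample(0:2, 1L))
    } else {
      mols[[sample(length(mols), 1L)]]
    }
    got <- matchSubstructure(t, q)@matched
    want <- or_subgraph_match(t, q)
    if (got != want) agree <- FALSE
    checked <- checked + 1L
  }
  expect_true(agree)
})

test_that("substructure matching respects semantics and returns an embedding", {
  r <- matchSubstructure(parseStructure("CCOC"), parseStructure("CCO"))
  expect_true(r@matched)
  expect_identical(length(r@atomMap), 3L)
  expect_true(all(r@atomMap %in% 1:4))

  expect_true(matchSubstructure(parseStructure("c1ccccc1"),
                                parseStructure("c1ccccc1"))@matched)
  expect_false(matchSubstructure(parseStructure("CCO"), parseStructure("N"))@matched)
  # chain matches a ring (monomorphism, not induced)
  expect_true(matchSubstructure(parseStructure("C1CC1"), parseStructure("CCC"))@matched)
  # bond order is respected: aliphatic C-C query does not match aromatic ring
  expect_false(matchSubstructure(parseStructure("c1ccccc1"),
                                 parseStructure("C=C"))@matched)
  # charge is respected
  expect_false(quietly(matchSubstructure(parseStructure("CCO"),
                                         parseStructure("[O-]")))@matched)
  # implicit hydrogens on the query do not constrain the target
  expect_true(matchSubstructure(parseStructure("CC(C)(C)C"), parseStructure("C"))@matched)
})

test_that("exact match equals structure-key equality", {
  expect_true(matchExact(parseStructure("OCC"), parseStructure("CCO")))
  expect_true(quietly(matchExact(parseStructure("[Br-]"), parseStructure("[Br-]"))))
  expect_false(matchExact(parseStructure("CCO"), parseStructure("CCN")))
})

test_that("SMARTS matching follows the toolkit dialect", {
  expect_true(matchSmarts(parseStructure("CCO"), "[#6]"))
  expect_false(matchSmarts(parseStructure("CCO"), "[F]"))
  expect_true(matchSmarts(parseStructure("c1ccccc1"), "c1ccccc1"))
  expect_true(matchSmarts(parseStructure("CC(=O)O"), "[CX3](=O)[OX2H1]"))
  expect_error(matchSmarts(parseStructure("CCO"), "[[["),
               class = "chemreg_parse_error")
  expect_s4_class(parseStructure("[#7,#8]", format = "smarts"), "SmartsPattern")
})

test_that("similarity metrics implement the documented formulas", {
  p <- fpParams()
  a <- fingerprint(parseStructure("CCO"), p)
  expect_identical(similarity(a, a, "tanimoto"), 1)
  expect_identical(similarity(a, a, "tversky"), 1)
  expect_identical(similarity(a, a, "euclid_sub"), 1)

  b <- fingerprint(parseStructure("c1ccncc1"), p)
  # symmetry of tanimoto
  expect_equal(similarity(a, b, "tanimoto"), similarity(b, a, "tanimoto"))
  # tversky(1,1) == tanimoto on any pair
  expect_equal(similarity(a, b, "tversky", alpha = 1, beta = 1),
               similarity(a, b, "tanimoto"))
  # tversky(1,0) == euclid_sub with the same argument order
  expect_equal(similarity(a, b, "tversky", alpha = 1, beta = 0),
               similarity(a, b, "euclid_sub"))
  expect_gte(similarity(a, b, "tanimoto"), 0)
  expect_lte(similarity(a, b, "tanimoto"), 1)

  # direct formula check: construct fingerprints with known bit counts
  mk <- function(idx) {
    logi <- logical(p$nbits)
    logi[idx] <- TRUE
    new("Fingerprint", bits = packBits(logi, type = "raw"),
        popcount = length(idx), paramsId = p$id)
  }
  fa <- mk(1:4)
  fb <- mk(3:4)
  expect_equal(similarity(fa, fb, "tanimoto"), 0.5) # a=4, b=2, c=2
  expect_equal(similarity(mk(1:2), mk(3:4), "tanimoto"), 0)
  expect_equal(similarity(mk(integer()), mk(integer()), "tanimoto"), 1)

  expect_error(similarity(a, fingerprint(parseStructure("CCO"), fpParams(maxlen = 5L))),
               class = "chemreg_params_mismatch_error")
})

test_that("similarity scores lie in [0,1] across fixture pairs", {
  p <- fpParams()
  fps <- lapply(fixture_smiles(30, seed = 5), function(s) {
    fingerprint(quietly(parseStructure(s)), p)
  })
  for (i in seq_along(fps)) {
    j <- sample(length(fps), 1L)
    for (m in c("tanimoto", "tversky", "euclid_sub")) {
      s <- similarity(fps[[i]], fps[[j]], m, alpha = 0.3, beta = 0.7)
      expect_gte(s, 0)
      expect_lte(s, 1)
    }
  }
})

test_that("formula matching Hill-normalises both sides", {
  expect_true(matchFormula(parseStructure("CCO"), "C2H6O"))
  expect_false(matchFormula(parseStructure("CCO"), "C2H6O2"))
  expect_true(matchFormula(parseStructure("c1ccccc1"), "H6C6"))
  expect_error(matchFormula(parseStructure("CCO"), "xyz"),
               class = "chemreg_parse_error")
})
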