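# Parsing, component splitting, structure keys, weights and formulas.

test_that("SMILES parsing builds the expected graphs", {
  m <- parseStructure("CCO")
  expect_s4_class(m, "Molecule")
  expect_identical(nrow(molAtoms(m)), 3L)
  expect_identical(grossFormula(m), "C2H6O")

  # whitespace inside SMILES is stripped before parsing
  salt <- quietly(parseStructure("[NH+]1 = CC = CC = C1.[Br-]"))
  expect_identical(length(splitComponents(salt)), 2L)

  # aromatic perception is deterministic across parses
  b1 <- parseStructure("c1ccccc1")
  b2 <- parseStructure("c1ccccc1")
  expect_identical(molAtoms(b1), molAtoms(b2))
  expect_identical(molBonds(b1), molBonds(b2))
  expect_true(all(molAtoms(b1)$aromatic))
  expect_true(all(molBonds(b1)$order == 4L))
})

test_that("invalid structure text raises a parse error with position info", {
  err <- tryCatch(parseStructure("C1CC"), chemreg_parse_error = function(e) e)
  expect_s3_class(err, "chemreg_parse_error")
  expect_match(conditionMessage(err), "ring")

  expect_error(parseStructure(""), class = "chemreg_parse_error")
  expect_error(parseStructure("C(C"), class = "chemreg_parse_error")
  expect_error(parseStructure("not-a-molecule"), class = "chemreg_parse_error")
})

test_that("molfile input is auto-detected and parsed", {
  mol <- parseStructure("CCO")
  block <- ChemRegistry:::.writeMolfile(mol)
  expect_true(grepl("V2000", block))
  again <- parseStructure(block) # format = auto
  expect_identical(grossFormula(again), "C2H6O")
  expect_identical(structureKey(again), structureKey(mol))
})

test_that("valence policy can reject impossible atoms", {
  expect_error(parseStructure("C(C)(C)(C)(C)C", valence = "reject"),
               class = "chemreg_valence_error")
  # accept-as-is is the default: stored exactly as submitted
  expect_s4_class(parseStructure("C(C)(C)(C)(C)C"), "Molecule")
})

test_that("component splitting preserves order and conserves atoms", {
  s <- quietly(parseStructure("[NH+]1=CC=[NH+]C=C1.[Br-].[Br-]"))
  comps <- quietly(splitComponents(s))
  expect_identical(length(comps), 3L)
  keys <- quietly(vapply(comps, structureKey, character(1)))
  expect_identical(length(unique(keys)), 2L)
  expect_identical(sum(vapply(comps, function(m) nrow(molAtoms(m)), integer(1))),
                   nrow(molAtoms(s)))
  # first component is the dication, in input order
  expect_identical(nrow(molAtoms(comps[[1]])), 6L)

  one <- splitComponents(parseStructure("CCO"))
  expect_identical(length(one), 1L)
})

test_that("structure keys are standard InChIKeys, canonical over atom order", {
  # frozen from the official InChI algorithm (via the toolkit) on "CCO"
  expect_identical(structureKey(parseStructure("CCO")),
                   "LFQSCWFLJHTTHZ-UHFFFAOYSA-N")
  expect_identical(structureKey(parseStructure("OCC")),
                   structureKey(parseStructure("CCO")))
  key <- structureKey(parseStructure("c1ccncc1"))
  expect_identical(nchar(key), 27L)
  expect_identical(substr(key, 15, 15), "-")
  expect_identical(substr(key, 26, 26), "-")

  expect_error(structureKey(parseStructure("CCO.CCN")),
               class = "chemreg_constraint_error")
})

test_that("key and canonical form are invariant under atom-order shuffles", {
  set.seed(101)
  smiles <- fixture_smiles(40, seed = 9)
  for (sm in smiles[1:40]) {
    mol <- quietly(parseStructure(sm))
    for (r in 1:5) {
      shuffled <- permute_atoms(mol)
      reparsed <- quietly(parseStructure(ChemRegistry:::.writeMolfile(shuffled)))
      expect_identical(quietly(structureKey(reparsed)),
                       quietly(structureKey(mol)))
      expect_identical(quietly(canonicalForm(reparsed)),
                       quietly(canonicalForm(mol)))
    }
  }
})

test_that("canonical form is a fixed point under re-parsing", {
  smiles <- fixture_smiles(100, seed = 23)
  for (sm in smiles) {
    can <- quietly(canonicalForm(parseStructure(sm)))
    expect_identical(quietly(canonicalForm(parseStructure(can))), can)
  }
  expect_identical(nrow(molAtoms(parseStructure(canonicalForm(parseStructure("C"))))), 1L)
})

test_that("molecular weights match hand-computed sums of atomic weights", {
  expect_equal(molecularWeight(parseStructure("c1ccccc1")), 78.11, tolerance = 0.01)
  expect_equal(molecularWeight(parseStructure("O")), 18.02, tolerance = 0.01)
  expect_equal(molecularWeight(parseStructure("C")), 16.04, tolerance = 0.01)

  # additivity across components
  mix <- quietly(parseStructure("CCO.c1ccccc1.[Br-]"))
  comps <- quietly(splitComponents(mix))
  expect_equal(molecularWeight(mix),
               sum(vapply(comps, molecularWeight, numeric(1))),
               tolerance = 1e-6)
})

test_that("gross formulas are in Hill order with charge excluded", {
  expect_identical(grossFormula(parseStructure("c1ccccc1")), "C6H6")
  expect_identical(grossFormula(parseStructure("[Br-]")), "Br")
  expect_identical(grossFormula(parseStructure("OS(=O)(=O)O")), "H2O4S")
  # no carbon: everything alphabetical
  expect_identical(grossFormula(parseStructure("N")), "H3N")
})

test_that("fallback keys are deterministic and distinct per canonical form", {
  with_mocked_bindings(
    .obConvert = mock_no_inchikey,
    {
      k1 <- fallbackKeyFor("CCO")
      k2 <- fallbackKeyFor("CCN")
      expect_match(k1, "^XK-[0-9a-f]{32}$")
      expect_match(k2, "^XK-[0-9a-f]{32}$")
      expect_false(k1 == k2)
      expect_identical(k1, fallbackKeyFor("OCC"))
    }
  )
})
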