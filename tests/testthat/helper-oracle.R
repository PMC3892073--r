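# Independent brute-force subgraph-isomorphism oracle (igraph VF2, verified
# monomorphism semantics) and graph-level fixture helpers. The oracle derives
# its colours from the public atom/bond tables, not from the package's
# internal invariant encoding.

or_subgraph_match <- function(target, query) {
  ta <- molAtoms(target)
  qa <- molAtoms(query)
  if (nrow(qa) == 0L) return(TRUE)
  if (nrow(qa) > nrow(ta)) return(FALSE)
  lab <- function(a) paste(a$element, a$charge, a$aromatic)
  levs <- unique(c(lab(ta), lab(qa)))
  tcol <- match(lab(ta), levs)
  qcol <- match(lab(qa), levs)
  tb <- molBonds(target)
  qb <- molBonds(query)
  mkgraph <- function(n, b) {
    igraph::make_empty_graph(n = n, directed = FALSE) +
      igraph::edges(as.vector(t(cbind(b$from, b$to))))
  }
  tg <- mkgraph(nrow(ta), tb)
  qg <- mkgraph(nrow(qa), qb)
  igraph::subgraph_isomorphic(
    qg, tg, method = "vf2",
    vertex.color1 = tcol, vertex.color2 = qcol,
    edge.color1 = as.integer(tb$order), edge.color2 = as.integer(qb$order)
  )
}

# deterministic pool of fixture SMILES drawn from the package's fragment
# grammar (single components only)
fixture_smiles <- function(n, seed = 42L, maxHeavy = 14L) {
  tab <- ChemRegistry:::.fixtureSmiles(
    fixtureSpec(n, mixtureFraction = 0, maxHeavyAtoms = maxHeavy, seed = seed)
  )
  tab$smiles
}

# build a Molecule directly from atom/bond tables (no parsing involved)
graph_molecule <- function(atoms, bonds) {
  new("Molecule", atoms = atoms, bonds = bonds,
      sourceText = NA_character_, canonicalSmiles = NA_character_)
}

# random edge-deleted subgraph of a molecule: a true substructure by
# construction (implicit hydrogens are cleared — queries do not constrain H)
delete_edges_subgraph <- function(mol, ndrop) {
  b <- molBonds(mol)
  a <- molAtoms(mol)
  a$hcount <- 0L
  if (nrow(b) == 0L || ndrop == 0L) return(graph_molecule(a, b))
  drop <- sample(seq_len(nrow(b)), min(ndrop, nrow(b)))
  graph_molecule(a, b[-drop, , drop = FALSE])
}

# permute atom order of a molecule and return the permuted graph
permute_atoms <- function(mol, perm = sample(nrow(molAtoms(mol)))) {
  a <- molAtoms(mol)[order(perm), , drop = FALSE]
  rownames(a) <- NULL
  b <- molBonds(mol)
  b$from <- perm[b$from]
  b$to <- perm[b$to]
  graph_molecule(a, b)
}

# quiet wrapper: OpenBabel prints perception warnings on stderr
quietly <- function(expr) suppressWarnings(suppressMessages(expr))

# the real converter, captured before any mocking
real_obConvert <- ChemRegistry:::.obConvert

# conversion stub that pretends the InChI algorithm cannot represent the
# species, to exercise the fallback key path
mock_no_inchikey <- function(from, to, text, opts = NULL) {
  if (to == "INCHIKEY") "" else real_obConvert(from, to, text, opts)
}

fallbackKeyFor <- function(smiles) {
  quietly(structureKey(parseStructure(smiles)))
}
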