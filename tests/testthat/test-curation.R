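# Retro template application, hydrogen completion, subset logic,
# stereochemistry reattachment, per-record curation, by-product balancing.

test_that("retro application rewrites each embedding into reactant candidates", {
  r <- parse_reaction(grignard_record(), "g1")
  t <- extract_generic_template(r)
  cands <- apply_retro_template(t, r$products)
  expect_gt(length(cands), 0)
  keysets <- lapply(cands, function(cand)
    sort(vapply(cand, canonical_key, character(1))))
  want <- sort(c(canonical_key(parse_smiles("Brc1ccccc1")),
                 canonical_key(parse_smiles("O=Cc1ccccc1"))))
  expect_true(any(vapply(keysets, identical, logical(1), y = want)))

  # pattern absent from the product -> empty candidate list
  amide_t <- parse_template("[#6:1]-[#7:2]>>Cl-[#6:1].[#7:2]")
  expect_length(apply_retro_template(amide_t, r$products), 0)
})

test_that("candidate count equals the embedding count on a symmetric substrate", {
  # pattern C-O in dimethyl ether: two symmetric embeddings, one distinct
  # candidate after deduplication of identical rewrites
  t <- parse_template("[#6:1]-[#8:2]>>Br-[#6:1].[#8:2]")
  prod <- parse_smiles("[CH3:1][O:2][CH3:3]")
  cands <- apply_retro_template(t, list(prod))
  # oracle: brute-force enumeration of injective label-preserving assignments
  embeds <- 0L
  atoms <- prod$atoms
  for (i in seq_len(nrow(atoms))) for (j in seq_len(nrow(atoms))) {
    if (i == j) next
    if (atoms$element[i] == "C" && atoms$element[j] == "O" &&
        !is.na(rxncurate:::bond_between(prod, i, j))) embeds <- embeds + 1L
  }
  expect_equal(embeds, 2L)
  # the two embeddings rewrite to map-distinct candidates
  expect_equal(length(cands), 2L)
  # on a map-free symmetric substrate both rewrites coincide
  keys <- unique(vapply(cands, function(cand)
    paste(sort(vapply(cand, canonical_key, character(1))), collapse = "|"),
    character(1)))
  expect_length(keys, 1)
})

test_that("hydrogen completion enumerates valence-consistent assignments", {
  vt <- default_valence_table()
  # neutral one-bond sulfur: exactly the 1-H and 5-H variants
  frag <- parse_smiles("CS")
  frag$atoms$hcount[frag$atoms$element == "S"] <- NA_integer_
  out <- complete_hydrogens(frag, vt)
  hs <- sort(vapply(out, function(m) m$atoms$hcount[m$atoms$element == "S"],
                    integer(1)))
  expect_identical(hs, c(1L, 5L))
  # saturated neutral carbon: single 0-H variant
  frag2 <- parse_smiles("CC(C)(C)C")
  frag2$atoms$hcount[2] <- NA_integer_
  out2 <- complete_hydrogens(frag2, vt)
  expect_length(out2, 1)
  expect_equal(out2[[1]]$atoms$hcount[2], 0L)
  # arithmetic oracle over the valence entries
  for (el in c("S", "P", "N", "O")) {
    for (nb in 0:2) {
      atoms <- rxncurate:::new_atom(el)
      mol <- molgraph(atoms)
      if (nb > 0) {
        for (q in seq_len(nb)) mol$atoms <- rbind(mol$atoms, rxncurate:::new_atom("C", hcount = 3L))
        mol$bonds <- data.frame(a1 = 1L, a2 = 1L + seq_len(nb), order = 1,
                                stereo = NA_character_, ref1 = NA_integer_,
                                ref2 = NA_integer_)
      }
      got <- sort(vapply(complete_hydrogens(mol, vt), function(m)
        m$atoms$hcount[1], integer(1)))
      want <- sort(unique(as.integer(vt[[el]] - nb)))
      want <- want[want >= 0]
      expect_identical(got, want, label = paste(el, nb))
    }
  }
  # unknown element fails loudly
  mo <- molgraph(rxncurate:::new_atom("Pt"))
  expect_error(complete_hydrogens(mo, vt), "valence entry")
})

test_that("reactant-subset comparison is a mapping-agnostic multiset test", {
  ald <- parse_smiles("CC=O"); amine <- parse_smiles("CN")
  expect_true(is_reactant_subset(list(ald), list(ald, amine)))
  expect_true(is_reactant_subset(list(ald, amine), list(ald, amine)))
  expect_false(is_reactant_subset(list(ald, amine), list(ald)))
  # multiplicity counts
  expect_false(is_reactant_subset(list(ald, ald), list(ald, amine)))
  # maps do not matter
  expect_true(is_reactant_subset(list(parse_smiles("[CH3:9][CH:8]=[O:7]")),
                                 list(ald)))
  # monotonicity: c subset of c' preserves the relation
  set.seed(4)
  pool <- lapply(c("CCO", "CC=O", "CN", "c1ccccc1", "CC(C)O"), parse_smiles)
  for (k in 1:20) {
    o <- pool[sample(5, sample(2, 1))]
    c1 <- c(o, pool[sample(5, 1)])
    c2 <- c(c1, pool[sample(5, 1)])
    expect_true(is_reactant_subset(o, c1) <= is_reactant_subset(o, c2))
    expect_true(is_reactant_subset(o, c1))
  }
})

test_that("stereochemistry transfers by exact correspondence and is idempotent", {
  orig <- list(parse_smiles("N[C@@H](C)C(=O)O"), parse_smiles("F/C=C/F"))
  bare <- lapply(orig, function(m) {
    m$atoms$chiral <- 0L
    if (nrow(m$bonds)) { m$bonds$stereo <- NA_character_
                         m$bonds$ref1 <- NA_integer_; m$bonds$ref2 <- NA_integer_ }
    m
  })
  cur <- reattach_stereochemistry(orig, bare)
  expect_identical(write_smiles(cur[[1]]), write_smiles(orig[[1]]))
  expect_identical(write_smiles(cur[[2]]), write_smiles(orig[[2]]))
  # idempotent
  cur2 <- reattach_stereochemistry(orig, cur)
  expect_identical(lapply(cur2, write_smiles), lapply(cur, write_smiles))
  # fragments with no counterpart stay stereo-free
  extra <- parse_smiles("OP(O)OC")   # phosphite-like, P untagged
  cur3 <- reattach_stereochemistry(orig, list(extra))
  expect_true(all(cur3[[1]]$atoms$chiral == 0L))
})

test_that("curation validates, repairs and removes as the template dictates", {
  r <- parse_reaction(grignard_record(), "g1")
  t <- extract_generic_template(r); t$frequency <- 10L
  lib <- template_library(list(t), 5L)

  # correct, correctly mapped record: validated, nothing changes
  o <- curate_reaction(r, lib)
  expect_identical(o$status, "validated")
  expect_false(o$mapping_changed)
  expect_identical(write_reaction(o$curated_reaction), write_reaction(r))

  # missing reactant restored
  miss <- r; miss$reactants <- miss$reactants[2]
  om <- curate_reaction(miss, lib)
  expect_identical(om$status, "repaired")
  expect_length(om$added_fragments, 1)
  expect_identical(reactant_keyset(om$curated_reaction), reactant_keyset(r))

  # map swap corrected: curated transformation equals the pristine one
  sw <- parse_reaction(sub("[OH:4][CH:5]", "[OH:5][CH:4]", grignard_record(),
                           fixed = TRUE), "g-swap")
  os <- curate_reaction(sw, lib)
  expect_identical(os$status, "repaired")
  expect_true(os$mapping_changed)
  expect_true(cgr_isomorphic(build_cgr(remove_spectators(os$curated_reaction)),
                             build_cgr(remove_spectators(r))))

  # element mismatch at the mapped position (O replaced by C in the product):
  # no template applies, the record is removed
  bad <- parse_reaction(sub("[OH:4]", "[CH3:4]", grignard_record(),
                            fixed = TRUE), "g-el")
  ob <- curate_reaction(bad, lib)
  expect_identical(ob$status, "removed")
  expect_null(ob$curated_reaction)
})

test_that("curation is idempotent and sound on family fixtures", {
  data <- generate_fixture_dataset(builtin_families(), 8L, seed = 13)
  lib <- extract_template_library(data, min_frequency = 2L)
  for (rxn in data[seq(1, 24, by = 5)]) {
    o1 <- curate_reaction(rxn, lib)
    expect_false(o1$status == "removed", label = rxn$id)  # soundness
    o2 <- curate_reaction(o1$curated_reaction, lib)
    expect_identical(o2$status, "validated", label = rxn$id)
    expect_identical(write_reaction(o2$curated_reaction),
                     write_reaction(o1$curated_reaction), label = rxn$id)
    # atom accounting: every mapped heavy product atom has a same-element
    # preimage among the curated reactants
    cur <- remove_spectators(o1$curated_reaction)
    rmap <- do.call(rbind, lapply(cur$reactants, function(m)
      data.frame(map = m$atoms$map, el = m$atoms$element)))
    for (pm in cur$products) {
      ok <- !is.na(pm$atoms$map)
      hit <- match(pm$atoms$map[ok], rmap$map)
      expect_false(anyNA(hit), label = rxn$id)
      expect_identical(rmap$el[hit], pm$atoms$element[ok], label = rxn$id)
    }
  }
})

test_that("by-product balancing conserves heavy atoms", {
  r <- remove_spectators(parse_reaction(grignard_record(), "g"))
  bal <- add_byproducts(r)
  expect_identical(heavy_atom_counts(bal$reactants),
                   heavy_atom_counts(bal$products))
  # the appended by-product is HBr
  extra <- setdiff(vapply(bal$products, canonical_key, character(1)),
                   vapply(r$products, canonical_key, character(1)))
  expect_identical(extra, canonical_key(parse_smiles("Br")))
  # already balanced reactions stay unchanged
  h <- parse_reaction("[CH2:1]=[CH2:2]>>[CH2:1]1[CH2:2]O1", "ep")
  expect_identical(write_reaction(add_byproducts(h)), write_reaction(h))
  # element-count audit over a fixture batch
  data <- generate_fixture_dataset(builtin_families(c("Br", "F")), 4L, seed = 8)
  for (rxn in data) {
    bal <- add_byproducts(remove_spectators(rxn))
    expect_identical(heavy_atom_counts(bal$reactants),
                     heavy_atom_counts(bal$products), label = rxn$id)
  }
})
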