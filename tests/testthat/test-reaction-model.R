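# Reaction parsing, normalization, serialization and the CGR.

test_that("reaction SMILES parse into normalized mapped reactions", {
  r <- parse_reaction("[CH3:1][C:2](=[O:3])[H]>>[CH3:1][CH:2]([OH:3])C", "ex1")
  expect_length(r$reactants, 1)
  expect_length(r$products, 1)
  # the unmapped product carbon is retained and flagged map-absent
  expect_true(any(is.na(r$products[[1]]$atoms$map)))
  # explicit hydrogens fold into implicit counts: reactant is an aldehyde CH
  ra <- r$reactants[[1]]$atoms
  expect_equal(ra$hcount[ra$map == 2 & !is.na(ra$map)], 1L)

  # isotope labels are stripped on ingest
  iso <- parse_reaction("[13CH4:1]>>[CH4:1]", "iso")
  expect_identical(canonical_key(iso$reactants[[1]]),
                   canonical_key(iso$products[[1]]))
  expect_true(all(is.na(iso$reactants[[1]]$atoms$isotope)))

  # malformed molecule text raises a parse error carrying the record id
  err <- tryCatch(parse_reaction("xyzzy>>C", "rec42"), error = identity)
  expect_s3_class(err, "rxn_parse_error")
  expect_match(conditionMessage(err), "rec42")

  # agent-field molecules land in spectators, no maps required
  r3 <- parse_reaction("[CH3:1][OH:2]>CCO>[CH3:1][OH:2]", "ag")
  expect_length(r3$spectators, 1)

  # duplicate map numbers within one side are rejected
  expect_error(parse_reaction("[CH3:1][CH3:1]>>[CH3:1]", "dup"),
               class = "rxn_parse_error")
})

test_that("parse -> serialize -> parse round-trips every fixture record", {
  set.seed(42)
  data <- generate_fixture_dataset(builtin_families(c("Br", "F")),
                                   n_per_family = 5L, seed = 42)
  records <- c(vapply(data, write_reaction, character(1)),
               grignard_record(), diels_alder_record(),
               "F/C=C/F.[OH:1]C>>[OH:1]/C=C/F",
               "N[C@@H](C)C(=O)[OH:1]>>N[C@@H](C)C(=O)[O:1]C")
  for (rec in records) {
    r1 <- parse_reaction(rec, "a")
    s1 <- write_reaction(r1)
    r2 <- parse_reaction(s1, "b")
    expect_identical(write_reaction(r2), s1, label = rec)
    # graph-identical up to serialization: keys with maps retained agree
    k1 <- sort(vapply(c(r1$reactants, r1$products), canonical_key,
                      character(1), ignore_maps = FALSE))
    k2 <- sort(vapply(c(r2$reactants, r2$products), canonical_key,
                      character(1), ignore_maps = FALSE))
    expect_identical(k1, k2, label = rec)
  }
})

test_that("canonical keys identify molecules and respect flags", {
  expect_identical(canonical_key(parse_smiles("OCC")),
                   canonical_key(parse_smiles("CCO")))
  expect_identical(canonical_key(parse_smiles("[CH3:7]O")),
                   canonical_key(parse_smiles("[CH3:9]O")))
  # charge states distinguish: neutral vs protonated amine (oracle: the two
  # 2-atom label sets differ in exactly the charge/H labels)
  a <- parse_smiles("CN"); b <- parse_smiles("C[NH3+]")
  expect_false(identical(canonical_key(a), canonical_key(b)))
  expect_false(identical(sort(paste(a$atoms$element, a$atoms$charge, a$atoms$hcount)),
                         sort(paste(b$atoms$element, b$atoms$charge, b$atoms$hcount))))
  # maps retained on request
  expect_false(identical(canonical_key(parse_smiles("[CH3:7]O"), ignore_maps = FALSE),
                         canonical_key(parse_smiles("[CH3:9]O"), ignore_maps = FALSE)))
})

test_that("spectator removal is conservative and reversible", {
  r <- parse_reaction("[CH3:1][OH:2].CCOCC>>[CH3:1][OH:2]", "s")
  core <- remove_spectators(r)
  expect_length(core$reactants, 1)
  expect_length(core$spectators, 1)
  # round trip reproduces the molecule multiset
  expect_identical(sort(vapply(reinstate_spectators(core)$reactants,
                               canonical_key, character(1))),
                   sort(vapply(r$reactants, canonical_key, character(1))))
  # atom multiset conservation over the fixture set
  data <- generate_fixture_dataset(builtin_families(), 4L, seed = 3)
  for (rxn in data) {
    core <- remove_spectators(rxn)
    el <- function(mols) sort(unlist(lapply(mols, function(m) m$atoms$element)))
    expect_identical(el(c(core$reactants, core$spectators)), el(rxn$reactants))
  }
  # fully participating reactants stay put
  r2 <- parse_reaction("[CH3:1][OH:2]>>[CH3:1][OH:2]", "t")
  expect_length(remove_spectators(r2)$reactants, 1)
  # all-spectator reactions are unusable
  r3 <- parse_reaction("CC.CO>>[CH4:1]", "u")
  expect_error(remove_spectators(r3), class = "rxn_empty_core")
})

test_that("the CGR superposes both sides with before/after bond orders", {
  # identity reaction: zero changed edges
  idr <- parse_reaction("[CH3:1][OH:2]>>[CH3:1][OH:2]", "id")
  expect_equal(nrow(cgr_changed_edges(build_cgr(idr))), 0)

  # hydrogenation: oracle = hand diff of the bond dictionaries
  # before: {1-2: 2}; after: {1-2: 1} -> one changed edge, h +1 on both C
  h <- parse_reaction("[CH2:1]=[CH2:2].[H][H]>>[CH3:1][CH3:2]", "h2")
  g <- build_cgr(h)
  ch <- cgr_changed_edges(g)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$before, 2)
  expect_equal(ch$after, 1)
  expect_equal(g$nodes$h_after - g$nodes$h_before, c(1L, 1L))

  # molecule order within a side does not matter
  g2 <- build_cgr(parse_reaction("[H][H].[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]", "p"))
  expect_true(cgr_equal(g, g2))

  # duplicate map within one side is an integrity error (bypassing the
  # parse-time check by editing the graph)
  bad <- h
  bad$reactants[[1]]$atoms$map <- c(1L, 1L)
  expect_error(build_cgr(bad), class = "cgr_integrity_error")
})

test_that("any CGR-distinct map transposition is detected (exhaustive)", {
  # a small unsymmetric product: every product-map transposition either
  # changes the CGR or swaps truly equivalent atoms
  rec <- "Br[CH2:1][CH2:2][CH3:3].[OH:4][CH3:5]>>[CH2:1]([O:4][CH3:5])[CH2:2][CH3:3]"
  r <- parse_reaction(rec, "x")
  base <- build_cgr(r)
  mol <- r$products[[1]]
  mapped <- which(!is.na(mol$atoms$map))
  n_distinct <- 0L
  for (i in seq_along(mapped)) for (j in seq_along(mapped)) {
    if (i >= j) next
    sw <- r
    mm <- mol$atoms$map
    mm[c(mapped[i], mapped[j])] <- mm[c(mapped[j], mapped[i])]
    sw$products[[1]]$atoms$map <- mm
    g <- build_cgr(sw)
    # oracle for equivalence: identical element + identical sorted incident
    # (neighbor element, order) stubs in the product AND both atoms play the
    # same role on the reactant side
    if (!cgr_equal(base, g)) n_distinct <- n_distinct + 1L
    expect_identical(cgr_equal(base, g), cgr_equal(g, base))
  }
  # in this molecule all 5 mapped atoms are pairwise non-equivalent:
  # all 10 transpositions must change the CGR
  expect_equal(n_distinct, 10L)
})
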