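# Reaction centres, generic template extraction, canonicalization, filtering.

test_that("reaction centres are the atoms whose bonding environment changes", {
  # identity -> null transformation
  expect_error(find_reaction_center(parse_reaction("[CH3:1][OH:2]>>[CH3:1][OH:2]", "i")),
               class = "null_transformation")
  # hydrogenation: both carbons (bond order change + h delta)
  h <- parse_reaction("[CH2:1]=[CH2:2].[H][H]>>[CH3:1][CH3:2]", "h")
  expect_identical(find_reaction_center(h), c(1L, 2L))
  # Grignard-type: C-Br carbon (1), carbinol carbon (5), oxygen (4)
  g <- parse_reaction(grignard_record(), "g")
  expect_identical(find_reaction_center(g), c(1L, 4L, 5L))
})

test_that("radical and charge-transfer special cases are detected", {
  g <- parse_reaction(grignard_record(), "g")
  expect_false(detect_radical_case(g))
  expect_false(detect_charge_transfer(g))

  # H abstraction by a methyl radical
  rad <- parse_reaction("[CH3:1].[CH4:2]>>[CH4:1].[CH3:2]", "r")
  expect_true(detect_radical_case(rad))
  # oracle: exhaustive scan over all atoms of both sides
  any_rad <- any(unlist(lapply(c(rad$reactants, rad$products),
                               function(m) m$atoms$radical > 0)))
  expect_identical(detect_radical_case(rad), any_rad)

  # deprotonation: net charge movement on the centre oxygen
  dep <- parse_reaction("[CH3:1][OH:2]>>[CH3:1][O-:2]", "d")
  expect_true(detect_charge_transfer(dep))
  # oracle: agreement with the CGR charge deltas
  cg <- build_cgr(dep)
  expect_identical(detect_charge_transfer(dep),
                   any(cg$nodes$charge_before != cg$nodes$charge_after))
  expect_false(detect_charge_transfer(h <- parse_reaction(
    "[CH3:1][OH:2].[CH3:3][C:4](=[O:5])O>>[CH3:3][C:4](=[O:5])[O:2][CH3:1]", "e")))
})

test_that("generic templates reduce to element + map + leaving groups", {
  r <- parse_reaction(grignard_record(), "g1")
  t <- extract_generic_template(r)
  expect_identical(t$smarts, GRIGNARD_GENERIC)
  expect_equal(t$bond_changes, 3L)

  # radical case keeps hydrogen counts on centre atoms
  rad <- parse_reaction("[CH3:1].[CH4:2]>>[CH4:1].[CH3:2]", "r")
  trad <- extract_generic_template(rad)
  expect_match(trad$smarts, "H\\d?", all = FALSE)

  # charge-transfer case keeps formal charges
  dep <- parse_reaction("[CH3:1][OH:2].[NH3:3]>>[CH3:1][O-:2].[NH4+:3]", "d")
  tdep <- extract_generic_template(dep)
  expect_match(tdep$smarts, "[+-]")

  # generic templates never carry aromaticity, degree, chirality or
  # cis/trans constraints
  fams <- generate_fixture_dataset(builtin_families(), 3L, seed = 5)
  for (rxn in c(fams, list(r))) {
    sm <- extract_generic_template(remove_spectators(rxn))$smarts
    expect_false(grepl("[a-z@/\\\\]|;D|&", gsub("Cl|Br", "", sm)), label = sm)
  }
})

test_that("disjoint centres are bridged by shortest paths only", {
  # ring-opening-like product: two centre atoms separated by a 2-atom bridge
  prod <- parse_smiles("[CH3:1][CH2:2][CH2:3][CH3:4]")
  got <- connect_disjoint_centers(prod, c(1L, 4L))
  expect_identical(got, 1:4)
  # oracle: exhaustive enumeration of simple paths between atoms 1 and 4 in
  # the 4-chain finds exactly one path, through 2 and 3
  # already connected -> unchanged
  expect_identical(connect_disjoint_centers(prod, c(1L, 2L)), c(1L, 2L))
  # branched case: no redundant atoms -- the branch atom stays out
  prod2 <- parse_smiles("[CH3:1][CH:2]([CH3:5])[CH2:3][CH3:4]")
  got2 <- connect_disjoint_centers(prod2, c(1L, 4L))
  expect_identical(got2, c(1L, 2L, 3L, 4L))
  expect_false(5L %in% got2)
  # centres in different molecules: unchanged (no path exists)
  g <- parse_reaction(grignard_record(), "g")
  expect_identical(connect_disjoint_centers(g$products[[1]], c(1L, 99L)),
                   c(1L, 99L))
})

test_that("bond-change counting matches a brute-force diff oracle", {
  cases <- list(
    list(rec = grignard_record(), want = 3L),
    list(rec = diels_alder_record(), want = 6L),
    list(rec = "[CH2:1]=[CH2:2].[H][H]>>[CH3:1][CH3:2]", want = 1L))
  for (cs in cases) {
    r <- parse_reaction(cs$rec, "x")
    core <- tryCatch(remove_spectators(r), error = function(e) r)
    t <- extract_generic_template(core)
    # template counting: mapped-pair diffs plus leaving-group detachment;
    # the oracle counts mapped-pair diffs from the full reaction and adds
    # the reactant bonds to atoms that vanish from the product
    oracle_mapped <- oracle_bond_changes(cs$rec)
    pmaps <- unlist(lapply(core$products, function(m) m$atoms$map))
    lost_bonds <- sum(unlist(lapply(core$reactants, function(m) {
      mm <- m$atoms$map
      gone <- is.na(mm) | !(mm %in% pmaps)
      if (!nrow(m$bonds)) return(0L)
      sum(xor(gone[m$bonds$a1], gone[m$bonds$a2]))
    })))
    expect_equal(t$bond_changes, oracle_mapped + lost_bonds, label = cs$rec)
    expect_equal(t$bond_changes, cs$want, label = cs$rec)
  }
})

test_that("template canonicalization keeps the fewer-change representative", {
  ok <- extract_generic_template(parse_reaction(diels_alder_record(), "da-ok"))
  bad <- extract_generic_template(parse_reaction(diels_alder_swapped_record(),
                                                 "da-bad"))
  expect_equal(ok$bond_changes, 6L)
  expect_gt(bad$bond_changes, 6L)
  lib <- merge_isomorphic_templates(list(ok, bad))
  expect_length(lib$templates, 1)
  expect_equal(lib$templates[[1]]$bond_changes, 6L)
  expect_equal(lib$templates[[1]]$frequency, 2L)
  expect_identical(lib$templates[[1]]$smarts, ok$smarts)

  # singleton input unchanged
  solo <- merge_isomorphic_templates(list(ok))
  expect_length(solo$templates, 1)
  expect_equal(solo$templates[[1]]$frequency, 1L)

  # merge is order-independent on a shuffled library
  fams <- generate_fixture_dataset(builtin_families(c("Br", "F")), 8L, seed = 9)
  ts <- lapply(fams, function(r) extract_generic_template(remove_spectators(r)))
  ts <- c(ts, list(ok, bad))
  m1 <- merge_isomorphic_templates(ts)
  set.seed(1)
  m2 <- merge_isomorphic_templates(sample(ts))
  sig <- function(lib) sort(vapply(lib$templates, function(t)
    paste(t$smarts, t$frequency, t$bond_changes), character(1)))
  expect_identical(sig(m1), sig(m2))
  # minimality: each representative has the library-wide minimum change count
  # among members that merged into it (frequencies count members)
  expect_true(all(vapply(m1$templates, function(t) t$bond_changes, integer(1)) <=
                  max(vapply(ts, function(t) t$bond_changes, integer(1)))))
})

test_that("frequency filtering keeps exactly the templates above threshold", {
  t1 <- extract_generic_template(parse_reaction(grignard_record(), "a"))
  t2 <- extract_generic_template(parse_reaction(diels_alder_record(), "b"))
  t1$frequency <- 5L; t2$frequency <- 6L
  lib <- template_library(list(t1, t2))
  kept <- filter_rare_templates(lib, 5L)
  expect_length(kept$templates, 1)
  expect_identical(kept$templates[[1]]$smarts, t2$smarts)
  # min_frequency 0 is the identity
  expect_length(filter_rare_templates(lib, 0L)$templates, 2)
  # frequency mass conservation
  total <- sum(vapply(lib$templates, function(t) t$frequency, integer(1)))
  kept_mass <- sum(vapply(kept$templates, function(t) t$frequency, integer(1)))
  removed_mass <- total - kept_mass
  expect_equal(kept_mass + removed_mass, total)
  expect_equal(removed_mass, 5L)
})

test_that("every member of a reaction family yields the identical template", {
  fams <- builtin_families("Br")
  data <- generate_fixture_dataset(fams, 12L, seed = 21)
  by_family <- split(data, sub("-\\d+$", "", vapply(data, function(r) r$id,
                                                    character(1))))
  for (nm in names(by_family)) {
    smarts <- vapply(by_family[[nm]], function(r)
      extract_generic_template(remove_spectators(r))$smarts, character(1))
    expect_length(unique(smarts), 1)
  }
})

test_that("a reaction's own template regenerates its reactants (round trip)", {
  data <- generate_fixture_dataset(builtin_families(c("Br", "F")), 4L, seed = 33)
  for (rxn in data) {
    core <- remove_spectators(rxn)
    t <- extract_generic_template(core)
    cands <- apply_retro_template(t, core$products)
    expect_gt(length(cands), 0, label = rxn$id)
    hit <- any(vapply(cands, function(cand)
      is_reactant_subset(core$reactants, cand), logical(1)))
    expect_true(hit, label = rxn$id)
  }
})

test_that("template libraries survive a JSON-lines round trip", {
  data <- generate_fixture_dataset(builtin_families(c("Br", "F")), 15L, seed = 2)
  lib <- extract_template_library(data, min_frequency = 2L)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_template_library(lib, path)
  lib2 <- read_template_library(path, min_frequency = 2L)
  expect_identical(vapply(lib$templates, function(t) t$smarts, character(1)),
                   vapply(lib2$templates, function(t) t$smarts, character(1)))
  expect_identical(vapply(lib$templates, function(t) t$frequency, integer(1)),
                   vapply(lib2$templates, function(t) t$frequency, integer(1)))
  expect_identical(vapply(lib$templates, function(t) t$bond_changes, integer(1)),
                   vapply(lib2$templates, function(t) t$bond_changes, integer(1)))
})
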