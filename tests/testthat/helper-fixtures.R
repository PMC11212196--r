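# Shared fixtures, built in code.

# Grignard-type record whose detailed (radius-1) retro template is the
# documented worked example: PhBr + PhCHO -> benzhydrol, maps chosen to
# mirror that template's numbering (4 = O, 5 = carbinol C, 1 = ipso C).
grignard_record <- function() {
  paste0("Br[c:1]1[cH:2][cH:9][cH:10][cH:11][cH:3]1.",
         "[CH:5](=[O:4])[c:6]1[cH:12][cH:13][cH:14][cH:15][cH:16]1",
         ">>",
         "[OH:4][CH:5]([c:6]1[cH:12][cH:13][cH:14][cH:15][cH:16]1)",
         "[c:1]1[cH:2][cH:9][cH:10][cH:11][cH:3]1")
}

GRIGNARD_GENERIC <- "[#6:1]-[#6:2]-[#8:3]>>Br-[#6:1].[#6:2]=[#8:3]"

# correctly mapped butadiene + ethene -> cyclohexene
diels_alder_record <- function() {
  paste0("[CH2:1]=[CH:2][CH:3]=[CH2:4].[CH2:5]=[CH2:6]>>",
         "[CH2:1]1[CH:2]=[CH:3][CH2:4][CH2:5][CH2:6]1")
}

# same reaction with product maps 2 and 5 transposed: a mapping error that
# inflates the apparent number of bond changes but leaves both pattern
# graphs isomorphic
diels_alder_swapped_record <- function() {
  paste0("[CH2:1]=[CH:2][CH:3]=[CH2:4].[CH2:5]=[CH2:6]>>",
         "[CH2:1]1[CH:5]=[CH:3][CH2:4][CH2:2][CH2:6]1")
}

# small single-template library from one template string, with a frequency
lib_from_smarts <- function(smarts, frequency = 10L) {
  t <- parse_template(smarts)
  t$frequency <- as.integer(frequency)
  template_library(list(t), min_frequency = 5L)
}

# mapping-agnostic reactant key multiset
reactant_keyset <- function(rxn) {
  sort(vapply(reinstate_spectators(rxn)$reactants, canonical_key, character(1)))
}

# independent brute-force count of bond changes between the two sides of a
# fully specified atom-mapped reaction (oracle: compares bond dictionaries
# keyed by map pairs, counting formation / breakage / order change once each;
# bonds to unmapped atoms count on their own side)
oracle_bond_changes <- function(rxn_smiles) {
  r <- parse_reaction(rxn_smiles, "oracle")
  dict <- function(mols) {
    d <- list()
    for (m in mols) {
      mm <- m$atoms$map
      b <- m$bonds
      if (nrow(b)) for (k in seq_len(nrow(b))) {
        m1 <- mm[b$a1[k]]; m2 <- mm[b$a2[k]]
        if (is.na(m1) || is.na(m2)) next
        d[[paste(min(m1, m2), max(m1, m2))]] <- b$order[k]
      }
    }
    d
  }
  before <- dict(r$reactants); after <- dict(r$products)
  keys <- union(names(before), names(after))
  sum(vapply(keys, function(k) {
    b <- if (is.null(before[[k]])) 0 else before[[k]]
    a <- if (is.null(after[[k]])) 0 else after[[k]]
    b != a
  }, logical(1)))
}
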