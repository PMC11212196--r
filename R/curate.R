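# Template-guided curation: retro application of generic templates to a
# reaction's products, reactant-subset validation, repair of missing
# reactants and atom maps, stereochemistry reattachment, optional
# by-product balancing.

#' Default valence table
#'
#' Allowed bond-order sums per element and charge state, used when
#' completing hydrogens on template-written atoms.  Neutral sulfur is
#' allowed two or six bonds, phosphorus three or five; lookups for elements
#' without an entry fail loudly.
#'
#' @return a named list; names are `"El"` or `"El<+/-charge>"`.
#' @export
default_valence_table <- function() {
  list(H = 1, B = 3, C = 4, N = 3, `N+1` = 4, `N-1` = 2,
       O = 2, `O+1` = 3, `O-1` = 1, F = 1, Cl = 1, Br = 1, I = 1,
       P = c(3, 5), S = c(2, 6), `S-1` = 1, Si = 4, Se = c(2, 6),
       Li = 1, Na = 1, K = 1, Mg = 2, Zn = 2, Sn = 4, B3 = 3)
}

allowed_valences <- function(element, charge, vt) {
  key <- if (is.na(charge) || charge == 0L) element
         else sprintf("%s%+d", element, charge)
  v <- vt[[key]]
  if (is.null(v))
    stop("no valence entry for ", key,
         "; extend the valence table to cover this element/charge state")
  v
}

#' Enumerate hydrogen completions of a fragment
#'
#' Every atom with an undetermined hydrogen count (`NA`) receives each
#' hydrogen count compatible with an allowed valence of its element and
#' charge state; one fragment variant is produced per combination.  Atoms
#' whose count the template specified verbatim are untouched.
#'
#' @param fragment a [molgraph()] possibly containing `NA` hydrogen counts.
#' @param vt valence table from [default_valence_table()].
#' @param max_variants cap on the enumeration (guards combinatorial blowup).
#' @return list of fully specified molgraphs; empty if no valence fits.
#' @export
complete_hydrogens <- function(fragment, vt = default_valence_table(),
                               max_variants = 64L) {
  na_atoms <- which(is.na(fragment$atoms$hcount))
  if (!length(na_atoms)) return(list(fragment))
  sums <- bond_order_sums(fragment)
  choices <- lapply(na_atoms, function(i) {
    v <- allowed_valences(fragment$atoms$element[i], fragment$atoms$charge[i], vt)
    h <- as.integer(v - ceiling(sums[i] - 1e-9))
    sort(unique(h[h >= 0L]))
  })
  if (any(lengths(choices) == 0L)) return(list())
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) > max_variants) grid <- grid[seq_len(max_variants), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(r) {
    f <- fragment
    f$atoms$hcount[na_atoms] <- as.integer(unlist(grid[r, ]))
    f
  })
}

#' Multiset reactant-subset test
#'
#' `TRUE` when the multiset of mapping-agnostic canonical keys of `original`
#' is contained in that of `candidate`.  Atom maps, stereochemistry and
#' spectators never influence the comparison.
#'
#' @param original,candidate lists of [molgraph()].
#' @return logical.
#' @export
is_reactant_subset <- function(original, candidate) {
  ok <- table(vapply(original, canonical_key, character(1)))
  ck <- table(vapply(candidate, canonical_key, character(1)))
  all(names(ok) %in% names(ck)) &&
    all(ok <= ck[names(ok)])
}

# ---- retro template application --------------------------------------------

#' Apply a retro template to a product set
#'
#' Every embedding of the template's product pattern into the combined
#' product graph yields candidate reactant multisets: pattern bonds are
#' deleted, reactant-pattern bonds and leaving-group atoms attached,
#' unmatched product atoms copied through with their maps, and hydrogen
#' counts on rewritten atoms re-derived from the valence table (enumerating
#' all valence-consistent assignments).  Chemically impossible rewrites
#' (no valence fits) are discarded.
#'
#' @param t a `generic_template`.
#' @param products list of product [molgraph()]s.
#' @param vt valence table.
#' @return list of candidate reactant multisets (each a list of molgraphs),
#'   deterministically ordered; empty when the pattern does not embed.
#' @export
apply_retro_template <- function(t, products, vt = default_valence_table()) {
  target <- mol_union(products)$mol
  pp <- t$product_pattern
  np <- n_atoms(pp)
  if (np == 0 || n_atoms(target) < np) return(list())

  zs <- sort(unique(c(atomic_number(pp$atoms$element),
                      atomic_number(target$atoms$element))))
  ords <- sort(unique(c(pp$bonds$order, target$bonds$order)))
  gp <- igraph::make_graph(rbind(pp$bonds$a1, pp$bonds$a2), n = np,
                           directed = FALSE)
  gt <- igraph::make_graph(rbind(target$bonds$a1, target$bonds$a2),
                           n = n_atoms(target), directed = FALSE)
  embeddings <- tryCatch(
    igraph::subgraph_isomorphisms(
      gp, gt, method = "vf2",
      # colors follow the underlying (target, pattern) argument order
      vertex.color1 = match(atomic_number(target$atoms$element), zs),
      vertex.color2 = match(atomic_number(pp$atoms$element), zs),
      edge.color1 = match(target$bonds$order, ords),
      edge.color2 = match(pp$bonds$order, ords)),
    error = function(e) list())
  if (!length(embeddings)) return(list())

  # reactant-side pattern lookups by (renumbered) map
  rp_union <- mol_union(t$reactant_patterns)$mol
  rmaps <- rp_union$atoms$map

  candidates <- list(); seen <- character()
  for (emb in embeddings) {
    m <- as.integer(emb)   # pattern atom i -> target atom m[i]
    # H / charge specification filters (radical / charge-transfer templates)
    ok <- TRUE
    for (i in seq_len(np)) {
      if (!is.na(pp$atoms$hcount[i]) &&
          pp$atoms$hcount[i] != target$atoms$hcount[m[i]]) { ok <- FALSE; break }
      if (!is.na(pp$atoms$charge[i]) &&
          pp$atoms$charge[i] != target$atoms$charge[m[i]]) { ok <- FALSE; break }
    }
    if (!ok) next

    g <- target
    # delete product-pattern bonds
    drop_bonds <- integer()
    if (nrow(pp$bonds)) for (k in seq_len(nrow(pp$bonds))) {
      bk <- bond_between(g, m[pp$bonds$a1[k]], m[pp$bonds$a2[k]])
      drop_bonds <- c(drop_bonds, bk)
    }
    if (length(drop_bonds)) g$bonds <- g$bonds[-drop_bonds, , drop = FALSE]
    target_of_map <- m[order(pp$atoms$map)]       # map mm -> target index

    # rewrite matched atoms: H re-derived (or per spec), charge per spec
    for (i in seq_len(np)) {
      ti <- m[i]
      g$atoms$hcount[ti] <- NA_integer_
      g$atoms$chiral[ti] <- 0L
      g$atoms$radical[ti] <- 0L
    }
    # reactant pattern content
    new_idx <- integer(n_atoms(rp_union))   # rp atom -> index in g
    for (j in seq_len(n_atoms(rp_union))) {
      if (!is.na(rmaps[j])) {
        ti <- target_of_map[rmaps[j]]
        new_idx[j] <- ti
        if (!is.na(rp_union$atoms$hcount[j]))
          g$atoms$hcount[ti] <- rp_union$atoms$hcount[j]
        if (!is.na(rp_union$atoms$charge[j]))
          g$atoms$charge[ti] <- rp_union$atoms$charge[j]
      } else {
        at <- rp_union$atoms[j, , drop = FALSE]
        at$charge <- ifelse(is.na(at$charge), 0L, at$charge)
        at$map <- NA_integer_
        g$atoms <- rbind(g$atoms, at)
        new_idx[j] <- nrow(g$atoms)
      }
    }
    if (nrow(rp_union$bonds)) for (k in seq_len(nrow(rp_union$bonds))) {
      b <- rp_union$bonds[k, ]
      i1 <- new_idx[b$a1]; i2 <- new_idx[b$a2]
      if (!is.na(rmaps[b$a1]) && !is.na(rmaps[b$a2])) {
        g$bonds <- rbind(g$bonds,
                         data.frame(a1 = i1, a2 = i2, order = b$order,
                                    stereo = NA_character_, ref1 = NA_integer_,
                                    ref2 = NA_integer_))
      } else {
        g$bonds <- rbind(g$bonds,
                         data.frame(a1 = i1, a2 = i2, order = b$order,
                                    stereo = NA_character_, ref1 = NA_integer_,
                                    ref2 = NA_integer_))
      }
    }
    rownames(g$bonds) <- NULL; rownames(g$atoms) <- NULL
    # drop dangling stereo annotations on touched double bonds
    if (nrow(g$bonds)) {
      touched <- c(m, new_idx)
      bad <- !is.na(g$bonds$stereo) &
        (g$bonds$ref1 %in% touched | g$bonds$ref2 %in% touched |
         g$bonds$a1 %in% touched | g$bonds$a2 %in% touched)
      g$bonds$stereo[bad] <- NA_character_
    }

    mols <- mol_split(g)
    variant_sets <- lapply(mols, complete_hydrogens, vt = vt)
    if (any(lengths(variant_sets) == 0L)) next   # valence-impossible rewrite
    n_var <- prod(lengths(variant_sets))
    if (n_var > 64) n_var <- 64
    idx_grid <- expand.grid(lapply(variant_sets, seq_along),
                            KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(min(nrow(idx_grid), n_var))) {
      cand <- lapply(seq_along(mols), function(q)
        variant_sets[[q]][[idx_grid[r, q]]])
      sig <- paste(sort(vapply(cand, canonical_key, character(1),
                               ignore_maps = FALSE)), collapse = "|")
      if (!(sig %in% seen)) {
        seen <- c(seen, sig)
        candidates[[length(candidates) + 1L]] <- cand
      }
    }
  }
  # deterministic ordering: fewest total heavy atoms, then canonical keys
  if (length(candidates) > 1) {
    sz <- vapply(candidates, function(cs)
      sum(vapply(cs, function(mq) sum(mq$atoms$element != "H"), integer(1))),
      integer(1))
    kk <- vapply(candidates, function(cs)
      paste(sort(vapply(cs, canonical_key, character(1))), collapse = "|"),
      character(1))
    candidates <- candidates[order(sz, kk)]
  }
  candidates
}

# ---- stereochemistry reattachment ------------------------------------------

mol_igraph_exact <- function(mol) {
  a <- mol$atoms
  vsig <- paste0(atomic_number(a$element), "|", a$charge, "|", a$hcount, "|",
                 as.integer(a$aromatic))
  esig <- sprintf("%.1f", mol$bonds$order)
  g <- igraph::make_graph(rbind(mol$bonds$a1, mol$bonds$a2),
                          n = n_atoms(mol), directed = FALSE)
  list(g = g, vsig = vsig, esig = esig)
}

# one exact isomorphism original -> curated, or NULL
exact_correspondence <- function(orig, cur) {
  if (n_atoms(orig) != n_atoms(cur) || nrow(orig$bonds) != nrow(cur$bonds))
    return(NULL)
  a <- mol_igraph_exact(orig); b <- mol_igraph_exact(cur)
  vlev <- sort(unique(c(a$vsig, b$vsig)))
  elev <- sort(unique(c(a$esig, b$esig)))
  maps <- tryCatch(igraph::subgraph_isomorphisms(
    a$g, b$g, method = "vf2",
    vertex.color1 = match(b$vsig, vlev), vertex.color2 = match(a$vsig, vlev),
    edge.color1 = match(b$esig, elev), edge.color2 = match(a$esig, elev)),
    error = function(e) list())
  if (!length(maps)) return(NULL)
  as.integer(maps[[1]])
}

#' Reattach stereochemistry from original to curated reactants
#'
#' For each curated molecule whose constitution matches an original reactant,
#' an exact one-to-one atom correspondence (colored graph isomorphism)
#' transfers tetrahedral parities and double-bond cis/trans labels from the
#' original.  Newly added fragments stay stereo-free: the generic template
#' does not encode chirality, so, e.g., phosphorus stereocentres of a
#' restored phosphite cannot be inferred.  The transfer is idempotent.
#'
#' @param original,curated lists of [molgraph()].
#' @return `curated` with stereochemistry transferred where possible.
#' @export
reattach_stereochemistry <- function(original, curated) {
  okeys <- vapply(original, canonical_key, character(1))
  used <- logical(length(original))
  for (ci in seq_along(curated)) {
    key <- canonical_key(curated[[ci]])
    oi <- which(okeys == key & !used)
    if (!length(oi)) next
    oi <- oi[1]
    sigma <- exact_correspondence(original[[oi]], curated[[ci]])
    if (is.null(sigma)) {
      warning("no exact atom correspondence for ", key,
              "; stereochemistry left off")
      next
    }
    used[oi] <- TRUE
    om <- original[[oi]]; cm <- curated[[ci]]
    adj_o <- mol_adjacency(om)
    for (i in seq_len(n_atoms(om))) {
      if (om$atoms$chiral[i] == 0L) next
      j <- sigma[i]
      nb_o <- sort(adj_o$nbr[[i]])
      nb_c_img <- sigma[nb_o]
      par <- om$atoms$chiral[i]
      if (perm_parity(rank(nb_c_img)) == 1L) par <- 3L - par
      cm$atoms$chiral[j] <- par
    }
    if (nrow(om$bonds)) for (k in seq_len(nrow(om$bonds))) {
      st <- om$bonds$stereo[k]
      if (is.na(st)) next
      bk <- bond_between(cm, sigma[om$bonds$a1[k]], sigma[om$bonds$a2[k]])
      if (is.na(bk)) next
      flip <- cm$bonds$a1[bk] != sigma[om$bonds$a1[k]]
      cm$bonds$stereo[bk] <- st
      cm$bonds$ref1[bk] <- sigma[if (flip) om$bonds$ref2[k] else om$bonds$ref1[k]]
      cm$bonds$ref2[bk] <- sigma[if (flip) om$bonds$ref1[k] else om$bonds$ref2[k]]
    }
    curated[[ci]] <- cm
  }
  curated
}

# ---- per-reaction curation --------------------------------------------------

#' Curate one reaction against a template library
#'
#' Templates are tried in descending frequency (the most common
#' transformation wins when several match, which is why a frequent
#' bromide-template can replace a rarer fluoride); within a template,
#' candidate reactant sets are tried in deterministic order (fewest added
#' heavy atoms first).  The first candidate whose reactants form a superset
#' of the original reactants is accepted: the original reactants are
#' replaced by the candidate (with stereochemistry reattached), restoring
#' missing reactants and correcting the mapping.  If nothing matches, the
#' record is removed.
#'
#' @param rxn a `mapped_reaction`.
#' @param lib a filtered `template_library`.
#' @param vt valence table.
#' @return a `curation_outcome`: status (`validated`/`repaired`/`removed`),
#'   matched template, curated reaction, added fragments, mapping-change
#'   flag and notes.
#' @export
curate_reaction <- function(rxn, lib, vt = default_valence_table()) {
  outcome <- function(status, matched = NA_character_, curated = NULL,
                      added = list(), mapping_changed = FALSE, notes = "") {
    structure(list(id = rxn$id, status = status, matched_template = matched,
                   curated_reaction = curated, added_fragments = added,
                   mapping_changed = mapping_changed, notes = notes),
              class = "curation_outcome")
  }
  core <- tryCatch(remove_spectators(rxn), error = function(e) e)
  if (inherits(core, "error"))
    return(outcome("removed", notes = conditionMessage(core)))
  before <- tryCatch(build_cgr(core), error = function(e) e)
  if (inherits(before, "error"))
    return(outcome("removed", notes = conditionMessage(before)))

  orig_keys <- sort(vapply(core$reactants, canonical_key, character(1)))
  for (t in lib$templates) {
    cands <- apply_retro_template(t, core$products, vt)
    repair <- NULL
    for (cand in cands) {
      if (!is_reactant_subset(core$reactants, cand)) next
      # fresh maps for atoms the template introduced (leaving groups)
      used_maps <- c(side_maps(cand), side_maps(core$products))
      next_map <- if (length(used_maps)) max(used_maps) + 1L else 1L
      for (q in seq_along(cand)) {
        mm <- cand[[q]]$atoms$map
        nn <- sum(is.na(mm))
        if (nn) {
          cand[[q]]$atoms$map[is.na(mm)] <- seq.int(next_map, length.out = nn)
          next_map <- next_map + nn
        }
      }
      cand <- reattach_stereochemistry(core$reactants, cand)
      curated <- core
      curated$reactants <- cand
      after <- build_cgr(curated)
      mapping_changed <- !cgr_equal(before, after)
      cand_keys <- vapply(cand, canonical_key, character(1))
      added <- key_multiset_diff(cand, cand_keys, orig_keys)
      if (!mapping_changed && !length(added))
        return(outcome("validated", matched = t$smarts, curated = rxn))
      # remember the first (minimal) repair; keep scanning this template's
      # candidates in case a later embedding reproduces the original exactly
      # (symmetric substrates give map-permuted candidates)
      if (is.null(repair))
        repair <- outcome("repaired", matched = t$smarts, curated = curated,
                          added = added, mapping_changed = mapping_changed)
    }
    if (!is.null(repair)) return(repair)
  }
  outcome("removed", notes = "no template candidate matched the reactants")
}

# molecules of cand whose canonical key exceeds the original multiset
key_multiset_diff <- function(cand, cand_keys, orig_keys) {
  remaining <- orig_keys
  added <- list()
  for (q in seq_along(cand)) {
    hit <- match(cand_keys[q], remaining)
    if (!is.na(hit)) remaining <- remaining[-hit]
    else added[[length(added) + 1L]] <- cand[[q]]
  }
  added
}

#' @export
print.curation_outcome <- function(x, ...) {
  cat("<curation_outcome ", x$id, "> ", x$status,
      if (!is.na(x$matched_template)) paste0(" via ", x$matched_template),
      if (x$mapping_changed) " [mapping changed]",
      if (length(x$added_fragments)) paste0(" +", length(x$added_fragments),
                                            " fragment(s)"),
      "\n", sep = "")
  invisible(x)
}

# ---- by-product balancing ---------------------------------------------------

#' Balance a reaction by appending electroneutral by-products
#'
#' Reactant atoms that do not reappear in any product are grouped into
#' connected leaving-group fragments, capped with hydrogens (one per lost
#' bond order unit, plus neutralization of formal charge), and appended to
#' the product side, after which heavy-atom counts balance exactly.
#' Fragments that cannot be neutralized by hydrogen addition alone are left
#' out with a warning.
#'
#' @param rxn a curated `mapped_reaction`.
#' @return the reaction with by-products appended to `products`.
#' @export
add_byproducts <- function(rxn) {
  pmaps <- side_maps(rxn$products)
  for (rm in rxn$reactants) {
    a <- rm$atoms
    gone <- is.na(a$map) | !(a$map %in% pmaps)
    if (!any(gone)) next
    adj <- mol_adjacency(rm)
    sub_idx <- which(gone)
    frag_all <- mol_subgraph(rm, sub_idx)
    comp <- mol_components(frag_all)
    for (ci in seq_len(max(comp, 0L))) {
      orig_idx <- sub_idx[comp == ci]
      frag <- mol_subgraph(rm, orig_idx)
      ok <- TRUE
      for (fi in seq_along(orig_idx)) {
        i <- orig_idx[fi]
        lost <- 0
        for (tt in seq_along(adj$nbr[[i]])) {
          if (!gone[adj$nbr[[i]][tt]]) lost <- lost + rm$bonds$order[adj$bond[[i]][tt]]
        }
        h_new <- frag$atoms$hcount[fi] + as.integer(round(lost)) - frag$atoms$charge[fi]
        if (h_new < 0L) { ok <- FALSE; break }
        frag$atoms$hcount[fi] <- h_new
        frag$atoms$charge[fi] <- 0L
      }
      if (!ok) {
        warning("record ", rxn$id,
                ": leaving fragment cannot be neutralized by H addition; skipped")
        next
      }
      frag$atoms$map <- NA_integer_
      rxn$products <- c(rxn$products, list(frag))
    }
  }
  rxn
}
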