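# Generic retrosynthetic template extraction.
#
# A generic template is a radius-0 retro transformation: the product-side
# pattern covers exactly the reaction-centre atoms (plus shortest-path
# connectors when the centre is disjoint within one product molecule), the
# reactant side additionally carries leaving-group atoms.  Pattern atoms
# retain only element and map number; hydrogen counts are added for radical
# reactions and formal charges for charge-transfer reactions.

#' Find the reaction centre
#'
#' Mapped atoms incident to any CGR edge whose order changed, plus atoms
#' whose hydrogen count or formal charge changes, plus atoms bonded to
#' side-only (leaving/incoming) atoms.
#'
#' @param rxn a `mapped_reaction` (spectators already removed or ignored).
#' @return integer vector of atom-map numbers.
#' @export
find_reaction_center <- function(rxn) {
  cgr <- build_cgr(rxn)
  changed <- cgr_changed_edges(cgr)
  maps <- integer()
  if (nrow(changed)) {
    km <- strsplit(changed$key, " ")
    maps <- c(maps, as.integer(unlist(km)))
  }
  nd <- cgr$nodes
  maps <- c(maps,
            nd$map[nd$h_before != nd$h_after |
                   nd$charge_before != nd$charge_after],
            cgr$loose_attach$map)
  maps <- sort(unique(maps))
  if (!length(maps))
    stop(structure(class = c("null_transformation", "error", "condition"),
                   list(message = paste0("record ", rxn$id,
                                         ": no change between reactants and products"),
                        call = NULL, id = rxn$id)))
  maps
}

#' Radical special case
#'
#' `TRUE` when any reaction-centre atom carries unpaired electrons on either
#' side; generic templates then record hydrogen counts on centre atoms so
#' that open-shell species are represented faithfully.
#'
#' @param rxn a `mapped_reaction`.
#' @param centers optional precomputed centre map set.
#' @return logical.
#' @export
detect_radical_case <- function(rxn, centers = NULL) {
  if (is.null(centers)) centers <- find_reaction_center(rxn)
  for (m in c(rxn$reactants, rxn$products)) {
    hit <- !is.na(m$atoms$map) & m$atoms$map %in% centers & m$atoms$radical > 0L
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Charge-transfer special case
#'
#' `TRUE` when any mapped centre atom changes formal charge between the two
#' sides; generic templates then record formal charges on centre atoms.
#'
#' @inheritParams detect_radical_case
#' @return logical.
#' @export
detect_charge_transfer <- function(rxn, centers = NULL) {
  cgr <- build_cgr(rxn)
  if (is.null(centers)) centers <- find_reaction_center(rxn)
  nd <- cgr$nodes
  any(nd$map %in% centers & nd$charge_before != nd$charge_after)
}

#' Connect disjoint reaction centres within one product molecule
#'
#' When centre atoms fall into several connected fragments of the
#' centre-induced subgraph of a single product molecule, the atoms on
#' (unweighted) shortest paths between the fragments are added, so that no
#' redundant atom enters the template.  Centres lying in different product
#' molecules are returned unchanged.
#'
#' @param product a [molgraph()] (one product molecule).
#' @param centers atom-map numbers of centre atoms present in `product`.
#' @return possibly enlarged set of atom-map numbers.
#' @export
connect_disjoint_centers <- function(product, centers) {
  idx <- which(!is.na(product$atoms$map) & product$atoms$map %in% centers)
  if (length(idx) < 2) return(centers)
  sub_comp <- function(indices) {
    sub <- mol_subgraph(product, indices)
    comp <- mol_components(sub)
    split(indices, comp[match(indices, sort(unique(indices)))])
  }
  adj <- mol_adjacency(product)
  # BFS shortest path between two index sets, deterministic by atom index
  bfs_path <- function(from, to) {
    prev <- rep(NA_integer_, n_atoms(product))
    seen <- logical(n_atoms(product))
    queue <- sort(from); seen[queue] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% to) {
        path <- v
        while (!is.na(prev[v])) { v <- prev[v]; path <- c(path, v) }
        return(rev(path))
      }
      for (w in sort(adj$nbr[[v]])) {
        if (!seen[w]) { seen[w] <- TRUE; prev[w] <- v; queue <- c(queue, w) }
      }
    }
    NULL
  }
  current <- idx
  repeat {
    comps <- sub_comp(current)
    if (length(comps) <= 1) break
    # connect the component containing the smallest atom index to the
    # nearest other component
    comps <- comps[order(vapply(comps, min, integer(1)))]
    from <- comps[[1]]
    to <- unlist(comps[-1])
    path <- bfs_path(from, to)
    if (is.null(path)) break   # different molecules cannot happen here
    current <- sort(unique(c(current, path)))
  }
  sort(unique(c(centers, product$atoms$map[current])))
}

# ---- template construction --------------------------------------------------

#' Extract the generic template of a reaction
#'
#' @param rxn a `mapped_reaction` with spectators removed.
#' @param centers optional precomputed centre set.
#' @return an object of class `generic_template` with fields
#'   `product_pattern`, `reactant_patterns`, `bond_changes`, `frequency`,
#'   `example_ids` and the serialized `smarts` string.
#' @export
extract_generic_template <- function(rxn, centers = NULL) {
  if (is.null(centers)) centers <- find_reaction_center(rxn)
  radical <- detect_radical_case(rxn, centers)
  charge_tr <- detect_charge_transfer(rxn, centers)

  # special case: bridge disjoint centres within each product molecule
  for (pm in rxn$products) {
    pmaps <- pm$atoms$map
    if (sum(!is.na(pmaps) & pmaps %in% centers) >= 2)
      centers <- connect_disjoint_centers(pm, centers)
  }

  pattern_atoms <- function(mol, keep, side) {
    sub <- mol_subgraph(mol, keep)
    a <- sub$atoms
    mapped <- !is.na(a$map) & a$map %in% centers
    a$hcount <- ifelse(radical & mapped, a$hcount, NA_integer_)
    a$charge <- ifelse(charge_tr & mapped, a$charge, NA_integer_)
    a$aromatic <- FALSE; a$chiral <- 0L; a$radical <- 0L; a$isotope <- NA_integer_
    a$map[!mapped] <- NA_integer_
    sub$atoms <- a
    if (nrow(sub$bonds)) {
      sub$bonds$stereo <- NA_character_
      sub$bonds$ref1 <- NA_integer_; sub$bonds$ref2 <- NA_integer_
    }
    sub
  }

  # product side: centre atoms of every product molecule
  prod_parts <- list()
  for (pm in rxn$products) {
    keep <- which(!is.na(pm$atoms$map) & pm$atoms$map %in% centers)
    if (length(keep)) prod_parts[[length(prod_parts) + 1L]] <- pattern_atoms(pm, keep, "P")
  }
  product_pattern <- mol_union(prod_parts)$mol

  # reactant side: centre atoms plus attached leaving-group atoms (atoms that
  # do not reappear in any product), reached through such atoms only
  pmaps_all <- side_maps(rxn$products)
  react_parts <- list()
  for (rm in rxn$reactants) {
    a <- rm$atoms
    is_center <- !is.na(a$map) & a$map %in% centers
    not_in_prod <- is.na(a$map) | !(a$map %in% pmaps_all)
    if (!any(is_center)) next
    adj <- mol_adjacency(rm)
    keep <- which(is_center)
    queue <- keep
    seen <- logical(n_atoms(rm)); seen[keep] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj$nbr[[v]]) {
        if (!seen[w] && not_in_prod[w]) {
          seen[w] <- TRUE; keep <- c(keep, w); queue <- c(queue, w)
        }
      }
    }
    react_parts[[length(react_parts) + 1L]] <- pattern_atoms(rm, sort(keep), "R")
  }

  t <- structure(list(product_pattern = product_pattern,
                      reactant_patterns = react_parts,
                      bond_changes = 0L, frequency = 1L,
                      example_ids = rxn$id, smarts = ""),
                 class = "generic_template")
  t <- renumber_template(t)
  t$bond_changes <- count_bond_changes(t)
  t$smarts <- template_smarts(t)
  t
}

# renumber pattern maps 1..k by a deterministic canonical traversal of the
# product pattern (root: lowest atomic number, then canonical rank)
renumber_template <- function(t) {
  pp <- t$product_pattern
  n <- n_atoms(pp)
  rank <- canonical_ranks(pp, ignore_maps = TRUE)
  z <- atomic_number(pp$atoms$element)
  adj <- mol_adjacency(pp)
  visited <- logical(n)
  order_out <- integer(0)
  comp <- mol_components(pp)
  repeat {
    cand <- which(!visited)
    if (!length(cand)) break
    root <- cand[order(z[cand], rank[cand], cand)][1]
    stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (visited[v]) next
      visited[v] <- TRUE
      order_out <- c(order_out, v)
      nb <- adj$nbr[[v]]
      nb <- nb[!visited[nb]]
      nb <- nb[order(z[nb], rank[nb], nb)]
      if (length(nb)) stack <- c(stack, rev(nb))
    }
  }
  new_map <- integer(n)
  new_map[order_out] <- seq_len(n)
  old_map <- pp$atoms$map
  pp$atoms$map <- new_map
  t$product_pattern <- pp
  lookup <- stats::setNames(new_map, as.character(old_map))
  t$reactant_patterns <- lapply(t$reactant_patterns, function(rp) {
    mm <- rp$atoms$map
    ok <- !is.na(mm)
    rp$atoms$map[ok] <- unname(lookup[as.character(mm[ok])])
    rp
  })
  # order reactant fragments by their smallest map number
  minmap <- vapply(t$reactant_patterns, function(rp)
    min(c(rp$atoms$map[!is.na(rp$atoms$map)], Inf)), numeric(1))
  t$reactant_patterns <- t$reactant_patterns[order(minmap)]
  t
}

#' Count bond changes of a generic template
#'
#' Number of atom pairs whose bond order differs between the product pattern
#' and the reactant patterns; formation, breakage and order change each count
#' one.  Bonds involving leaving-group atoms are breakages.  Hydrogen-count
#' and charge specifications do not count.
#'
#' @param t a `generic_template`.
#' @return nonnegative integer.
#' @export
count_bond_changes <- function(t) {
  pair_orders <- function(mol) {
    out <- list()
    b <- mol$bonds; mm <- mol$atoms$map
    if (nrow(b)) for (k in seq_len(nrow(b))) {
      m1 <- mm[b$a1[k]]; m2 <- mm[b$a2[k]]
      if (!is.na(m1) && !is.na(m2))
        out[[paste(min(m1, m2), max(m1, m2))]] <- b$order[k]
    }
    out
  }
  po <- pair_orders(t$product_pattern)
  ro <- list()
  n_leaving_bonds <- 0L
  for (rp in t$reactant_patterns) {
    ro <- c(ro, pair_orders(rp))
    mm <- rp$atoms$map
    b <- rp$bonds
    # mapped-to-leaving bonds break; bonds internal to a leaving group persist
    if (nrow(b)) n_leaving_bonds <- n_leaving_bonds +
        sum(xor(is.na(mm[b$a1]), is.na(mm[b$a2])))
  }
  keys <- union(names(po), names(ro))
  changed <- sum(vapply(keys, function(k) {
    pb <- if (is.null(po[[k]])) 0 else po[[k]]
    rb <- if (is.null(ro[[k]])) 0 else ro[[k]]
    pb != rb
  }, logical(1)))
  as.integer(changed + n_leaving_bonds)
}

#' @export
print.generic_template <- function(x, ...) {
  cat("<generic_template> ", x$smarts, "  (", x$bond_changes,
      " bond changes, frequency ", x$frequency, ")\n", sep = "")
  invisible(x)
}

# ---- SMARTS-dialect serialization ------------------------------------------

pattern_atom_token <- function(a) {
  spec_h <- !is.na(a$hcount)
  spec_c <- !is.na(a$charge)
  if (is.na(a$map) && !spec_h && !spec_c) return(a$element)
  z <- atomic_number(a$element)
  h_txt <- if (!spec_h) "" else if (a$hcount == 1L) "H" else paste0("H", a$hcount)
  c_txt <- if (!spec_c) "" else if (a$charge == 1L) "+" else
    if (a$charge == -1L) "-" else sprintf("%+d", a$charge)
  map_txt <- if (is.na(a$map)) "" else paste0(":", a$map)
  paste0("[#", z, h_txt, c_txt, map_txt, "]")
}

# DFS writer for pattern graphs: explicit bond symbols, no stereo
write_pattern_fragment <- function(mol, start) {
  adj <- mol_adjacency(mol)
  n <- n_atoms(mol)
  mm <- mol$atoms$map
  prio <- ifelse(is.na(mm), 1e6 + seq_len(n), mm)  # mapped atoms by map number
  visited <- logical(n)
  bond_used <- logical(nrow(mol$bonds))
  ring_bonds <- integer(0)
  children <- vector("list", n)
  order_visited <- integer(0)
  dfs <- function(u) {
    visited[u] <<- TRUE
    order_visited <<- c(order_visited, u)
    nbrs <- adj$nbr[[u]]
    for (t in order(prio[nbrs], nbrs)) {
      v <- nbrs[t]; bk <- adj$bond[[u]][t]
      if (bond_used[bk]) next
      bond_used[bk] <<- TRUE
      if (visited[v]) ring_bonds <<- c(ring_bonds, bk)
      else { children[[u]] <<- c(children[[u]], v); dfs(v) }
    }
  }
  dfs(start)
  ring_digit <- seq_along(ring_bonds)
  bond_sym <- function(bk) switch(sprintf("%.1f", mol$bonds$order[bk]),
                                  "1.0" = "-", "2.0" = "=", "3.0" = "#", "1.5" = ":")
  emitted <- logical(length(ring_bonds))
  emit <- function(u) {
    res <- pattern_atom_token(mol$atoms[u, ])
    for (r in seq_along(ring_bonds)) {
      bk <- ring_bonds[r]
      if (u %in% c(mol$bonds$a1[bk], mol$bonds$a2[bk])) {
        res <- paste0(res, if (!emitted[r]) bond_sym(bk) else "", ring_digit[r])
        emitted[r] <<- TRUE
      }
    }
    kids <- children[[u]]
    if (length(kids)) {
      for (ci in seq_along(kids)) {
        v <- kids[ci]
        bk <- adj$bond[[u]][match(v, adj$nbr[[u]])]
        inner <- paste0(bond_sym(bk), emit(v))
        if (ci < length(kids)) inner <- paste0("(", inner, ")")
        res <- paste0(res, inner)
      }
    }
    res
  }
  emit(start)
}

write_pattern_side <- function(mols, reactant_side = FALSE) {
  frags <- character(); keys <- numeric()
  for (mol in mols) {
    for (m in mol_split(mol)) {
      mm <- m$atoms$map
      unmapped <- which(is.na(mm))
      start <- if (reactant_side && length(unmapped)) {
        z <- atomic_number(m$atoms$element[unmapped])
        unmapped[order(-z, unmapped)][1]
      } else {
        mapped <- which(!is.na(mm))
        if (length(mapped)) mapped[order(mm[mapped])][1] else 1L
      }
      frags <- c(frags, write_pattern_fragment(m, start))
      keys <- c(keys, min(c(mm[!is.na(mm)], Inf)))
    }
  }
  frags[order(keys)]
}

#' Serialize a generic template in the SMARTS dialect
#'
#' Retro direction: `product_pattern>>reactant_patterns`, atoms printed as
#' atomic-number primitives (`[#6:1]`), leaving-group atoms as bare element
#' symbols, all bonds explicit.
#'
#' @param t a `generic_template`.
#' @return character scalar.
#' @export
template_smarts <- function(t) {
  prod <- write_pattern_side(list(t$product_pattern), reactant_side = FALSE)
  # product fragments keep map order; reactant fragments were ordered already
  react <- unlist(lapply(t$reactant_patterns, function(rp)
    write_pattern_side(list(rp), reactant_side = TRUE)))
  paste0(paste(prod, collapse = "."), ">>", paste(react, collapse = "."))
}

#' Parse a template from its SMARTS-dialect serialization
#'
#' @param s template string as produced by [template_smarts()].
#' @return a `generic_template` (frequency 1, no provenance).
#' @export
parse_template <- function(s) {
  halves <- strsplit(s, ">>", fixed = TRUE)[[1]]
  if (length(halves) != 2) stop("template must contain '>>'")
  parse_side <- function(txt) lapply(strsplit(txt, ".", fixed = TRUE)[[1]],
                                     parse_smiles, pattern = TRUE)
  prods <- parse_side(halves[1])
  t <- structure(list(product_pattern = mol_union(prods)$mol,
                      reactant_patterns = parse_side(halves[2]),
                      bond_changes = 0L, frequency = 1L,
                      example_ids = character(), smarts = s),
                 class = "generic_template")
  t$bond_changes <- count_bond_changes(t)
  t
}
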