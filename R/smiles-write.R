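# Canonical SMILES output.
#
# Canonical ranks come from iterative neighbourhood refinement of an initial
# atom invariant (element, charge, H count, aromaticity, degree, optionally
# atom map), with remaining ties broken by promoting the lowest-index member
# of the lowest tied class and re-refining.  Atoms left tied by refinement
# are treated as symmetry-equivalent, so the choice does not affect the
# emitted string for ordinary organic molecules.

canonical_ranks <- function(mol, ignore_maps = TRUE) {
  n <- n_atoms(mol)
  if (n == 0) return(integer())
  a <- mol$atoms
  adj <- mol_adjacency(mol)
  deg <- lengths(adj$nbr)
  inv <- sprintf("%03d|%+03d|%02d|%d|%d|%s",
                 atomic_number(a$element), ifelse(is.na(a$charge), 99L, a$charge),
                 ifelse(is.na(a$hcount), 99L, a$hcount),
                 as.integer(a$aromatic), deg,
                 if (ignore_maps) "" else sprintf("%05d", ifelse(is.na(a$map), 0L, a$map)))
  # include incident bond-order multiset so edge labels shape the invariant
  bond_sig <- vapply(seq_len(n), function(i) {
    ords <- sort(mol$bonds$order[adj$bond[[i]]])
    paste(sprintf("%.1f", ords), collapse = ",")
  }, character(1))
  rank <- match(paste(inv, bond_sig), sort(unique(paste(inv, bond_sig))))

  refine <- function(rank) {
    repeat {
      key <- vapply(seq_len(n), function(i) {
        paste0(sprintf("%04d", rank[i]), "|",
               paste(sort(sprintf("%.1f:%04d", mol$bonds$order[adj$bond[[i]]],
                                  rank[adj$nbr[[i]]])), collapse = ";"))
      }, character(1))
      new_rank <- match(key, sort(unique(key)))
      if (identical(new_rank, rank)) return(rank)
      rank <- new_rank
    }
  }
  rank <- refine(rank)
  while (length(unique(rank)) < n) {
    tied <- which(tabulate(rank, nbins = n) > 1)
    cls <- min(tied)
    members <- which(rank == cls)
    rank <- rank * 2L
    rank[members[1]] <- rank[members[1]] - 1L
    rank <- match(rank, sort(unique(rank)))
    rank <- refine(rank)
  }
  rank
}

#' Write a molecular graph as canonical SMILES
#'
#' @param mol a [molgraph()].
#' @param with_maps include atom-map numbers.
#' @param with_stereo include tetrahedral parity and double-bond cis/trans.
#' @param ignore_maps_in_ranking if `TRUE` (default) atom maps do not
#'   influence the canonical atom ordering, only the printed annotations.
#' @return SMILES string; disconnected components are joined with `.`.
#' @export
write_smiles <- function(mol, with_maps = TRUE, with_stereo = TRUE,
                         ignore_maps_in_ranking = TRUE) {
  comps <- mol_split(mol)
  parts <- vapply(comps, function(m)
    write_smiles_component(m, with_maps, with_stereo, ignore_maps_in_ranking),
    character(1))
  paste(sort(parts), collapse = ".")
}

write_smiles_component <- function(mol, with_maps, with_stereo, ignore_maps) {
  n <- n_atoms(mol)
  rank <- canonical_ranks(mol, ignore_maps = ignore_maps)
  adj <- mol_adjacency(mol)
  start <- which.min(rank)

  # DFS; collect spanning-tree children and ring-closure bonds
  parent <- rep(NA_integer_, n)
  children <- vector("list", n)
  order_visited <- integer(0)
  visited <- logical(n)
  ring_bonds <- integer(0)   # bond row indices closing rings
  bond_used <- logical(nrow(mol$bonds))
  dfs <- function(u) {
    visited[u] <<- TRUE
    order_visited <<- c(order_visited, u)
    nbrs <- adj$nbr[[u]]
    ord <- order(rank[nbrs], nbrs)
    for (t in ord) {
      v <- nbrs[t]; bk <- adj$bond[[u]][t]
      if (bond_used[bk]) next
      bond_used[bk] <<- TRUE
      if (visited[v]) {
        ring_bonds <<- c(ring_bonds, bk)
      } else {
        parent[v] <<- u
        children[[u]] <<- c(children[[u]], v)
        dfs(v)
      }
    }
  }
  dfs(start)

  # ring-closure digit assignment, reusing digits after both ends are emitted
  ring_digit <- integer(0)
  if (length(ring_bonds)) {
    pos <- match(order_visited, order_visited)  # identity; used below via match
    ends <- lapply(ring_bonds, function(bk) c(mol$bonds$a1[bk], mol$bonds$a2[bk]))
    opens <- vapply(ends, function(e) min(match(e, order_visited)), numeric(1))
    closes <- vapply(ends, function(e) max(match(e, order_visited)), numeric(1))
    o <- order(opens, closes)
    ring_bonds <- ring_bonds[o]; opens <- opens[o]; closes <- closes[o]
    in_use <- list()
    ring_digit <- integer(length(ring_bonds))
    for (r in seq_along(ring_bonds)) {
      d <- 1L
      while (!is.null(in_use[[as.character(d)]]) && in_use[[as.character(d)]] > opens[r])
        d <- d + 1L
      ring_digit[r] <- d
      in_use[[as.character(d)]] <- closes[r]
    }
  }

  # directional characters for stereo double bonds
  dir_char <- rep(NA_character_, nrow(mol$bonds))
  if (with_stereo && nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      st <- mol$bonds$stereo[k]
      if (is.na(st) || mol$bonds$order[k] != 2) next
      r1 <- mol$bonds$ref1[k]; r2 <- mol$bonds$ref2[k]
      if (is.na(r1) || is.na(r2)) next
      b1 <- bond_between(mol, r1, mol$bonds$a1[k])
      b2 <- bond_between(mol, r2, mol$bonds$a2[k])
      if (is.na(b1) || is.na(b2) || mol$bonds$order[b1] != 1 ||
          mol$bonds$order[b2] != 1) next
      if (!is.na(dir_char[b1]) || !is.na(dir_char[b2])) next  # conflict: skip
      # desired side signs: cis -> equal, trans -> opposite
      s1 <- 1L
      s2 <- if (st == "cis") 1L else -1L
      set_dir <- function(bk, refatom, dblatom, s) {
        # '/' means dir +1 written ref->dbl; written orientation here is
        # tree orientation parent->child
        wr_from <- if (!is.na(parent[mol$bonds$a2[bk]]) &&
                       parent[mol$bonds$a2[bk]] == mol$bonds$a1[bk])
          mol$bonds$a1[bk] else mol$bonds$a2[bk]
        towards_dbl <- (wr_from == refatom)
        d <- if (towards_dbl) s else -s
        dir_char[bk] <<- if (d == 1L) "/" else "\\"
      }
      set_dir(b1, r1, mol$bonds$a1[k], s1)
      set_dir(b2, r2, mol$bonds$a2[k], s2)
    }
  }

  default_bond <- function(bk) {
    o <- mol$bonds$order[bk]
    i <- mol$bonds$a1[bk]; j <- mol$bonds$a2[bk]
    both_arom <- mol$atoms$aromatic[i] && mol$atoms$aromatic[j]
    (o == 1 && !both_arom) || (o == AROMATIC_ORDER && both_arom)
  }
  bond_token <- function(bk) {
    if (!is.na(dir_char[bk])) return(dir_char[bk])
    if (default_bond(bk)) return("")
    switch(sprintf("%.1f", mol$bonds$order[bk]),
           "1.0" = "-", "2.0" = "=", "3.0" = "#", "1.5" = ":")
  }

  atom_ring <- function(u) which(vapply(ring_bonds, function(bk)
    u %in% c(mol$bonds$a1[bk], mol$bonds$a2[bk]), logical(1)))

  emitted_ring <- logical(length(ring_bonds))

  atom_token <- function(u, out_seq) {
    a <- mol$atoms[u, ]
    el <- a$element
    sym <- if (a$aromatic) tolower(el) else el
    chiral_tag <- ""
    if (with_stereo && a$chiral != 0L) {
      conv <- c(if (a$hcount == 1L) 0L, sort(adj$nbr[[u]]))
      if (length(conv) == 4L && length(out_seq) == 4L &&
          setequal(conv, out_seq)) {
        par <- a$chiral
        if (perm_parity(match(out_seq, conv)) == 1L) par <- 3L - par
        chiral_tag <- if (par == 1L) "@" else "@@"
      }
    }
    map_txt <- if (with_maps && !is.na(a$map)) paste0(":", a$map) else ""
    default_h <- if (el %in% ORGANIC_SUBSET && !is.na(a$hcount)) {
      sums <- sum(mol$bonds$order[adj$bond[[u]]])
      default_implicit_h(el, sums)
    } else -1L
    plain <- isTRUE(el %in% ORGANIC_SUBSET && !is.na(a$charge) &&
      a$charge == 0L && is.na(a$isotope) && chiral_tag == "" &&
      map_txt == "" && a$radical == 0L && !is.na(a$hcount) &&
      a$hcount == default_h)
    if (plain) return(sym)
    h_txt <- if (is.na(a$hcount) || a$hcount == 0L) "" else
      if (a$hcount == 1L) "H" else paste0("H", a$hcount)
    chg_txt <- if (is.na(a$charge) || a$charge == 0L) "" else
      if (a$charge == 1L) "+" else if (a$charge == -1L) "-" else
        sprintf("%+d", a$charge)
    iso_txt <- if (is.na(a$isotope)) "" else as.character(a$isotope)
    paste0("[", iso_txt, sym, chiral_tag, h_txt, chg_txt, map_txt, "]")
  }

  emit <- function(u) {
    # output-order neighbour sequence for chirality bookkeeping
    out_seq <- integer()
    if (!is.na(parent[u])) out_seq <- parent[u]
    if (mol$atoms$hcount[u] == 1L && mol$atoms$chiral[u] != 0L)
      out_seq <- c(out_seq, 0L)
    srings <- atom_ring(u)
    ring_txt <- ""
    for (r in srings) {
      bk <- ring_bonds[r]
      other <- setdiff(c(mol$bonds$a1[bk], mol$bonds$a2[bk]), u)
      tokd <- if (ring_digit[r] > 9) paste0("%", ring_digit[r]) else ring_digit[r]
      btxt <- if (!emitted_ring[r]) bond_token(ring_bonds[r]) else ""
      emitted_ring[r] <<- TRUE
      ring_txt <- paste0(ring_txt, btxt, tokd)
      out_seq <- c(out_seq, other)
    }
    kids <- children[[u]]
    out_seq <- c(out_seq, kids)
    res <- paste0(atom_token(u, out_seq), ring_txt)
    if (length(kids)) {
      for (ci in seq_along(kids)) {
        v <- kids[ci]
        bk <- adj$bond[[u]][match(v, adj$nbr[[u]])]
        inner <- paste0(bond_token(bk), emit(v))
        if (ci < length(kids)) inner <- paste0("(", inner, ")")
        res <- paste0(res, inner)
      }
    }
    res
  }
  emit(start)
}

#' Canonical structural key of a molecule
#'
#' A deterministic canonical serialization over elements, charges, hydrogen
#' counts and bond orders.  Stereochemistry and isotopes never enter the key;
#' atom maps enter only when `ignore_maps = FALSE`.  Two molecular graphs that
#' are isomorphic under these labels yield identical keys.
#'
#' @param mol a [molgraph()].
#' @param ignore_maps drop atom-map numbers from the key (default).
#' @return character scalar.
#' @export
canonical_key <- function(mol, ignore_maps = TRUE) {
  m <- mol
  m$atoms$isotope <- NA_integer_
  write_smiles(m, with_maps = !ignore_maps, with_stereo = FALSE,
               ignore_maps_in_ranking = ignore_maps)
}
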