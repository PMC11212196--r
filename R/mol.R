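# Molecular graph data model.
#
# A molgraph stores heavy atoms (hydrogens are implicit, folded into per-atom
# counts) as a data frame plus an edge list.  Bond orders are numeric:
# 1, 2, 3 and 1.5 for aromatic.  Chirality is a tetrahedral parity stored
# relative to a fixed neighbour convention (implicit H first, then heavy
# neighbours by ascending atom index): 1 = anticlockwise (@), 2 = clockwise
# (@@), 0 = none.  Double-bond stereo is stored on the bond as cis/trans
# relative to one reference neighbour on each end.

AROMATIC_ORDER <- 1.5

#' Construct a molecular graph
#'
#' Low-level constructor used by the SMILES parser and the rewrite machinery.
#' Most users obtain molgraphs via [parse_smiles()] or [parse_reaction()].
#'
#' @param atoms data frame with columns `element` (symbol), `charge`,
#'   `hcount` (implicit hydrogen count, `NA` = to be derived), `aromatic`,
#'   `map` (atom-map number, `NA` = unmapped), `radical` (unpaired electron
#'   count), `chiral` (0/1/2 parity code), `isotope` (`NA` = unspecified).
#' @param bonds data frame with columns `a1`, `a2` (atom indices), `order`
#'   (1, 2, 3 or 1.5), `stereo` (`NA`, `"cis"` or `"trans"`), `ref1`, `ref2`
#'   (reference neighbour atom indices for stereo bonds).
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds = empty_bonds()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  for (col in c("charge", "hcount", "map", "radical", "chiral", "isotope")) {
    if (is.null(atoms[[col]])) {
      atoms[[col]] <- rep(if (col %in% c("map", "isotope")) NA_integer_ else 0L,
                          nrow(atoms))
    }
    atoms[[col]] <- as.integer(atoms[[col]])
  }
  if (is.null(atoms$aromatic)) atoms$aromatic <- rep(FALSE, nrow(atoms))
  if (is.null(bonds$stereo)) bonds$stereo <- rep(NA_character_, nrow(bonds))
  if (is.null(bonds$ref1)) bonds$ref1 <- rep(NA_integer_, nrow(bonds))
  if (is.null(bonds$ref2)) bonds$ref2 <- rep(NA_integer_, nrow(bonds))
  structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
}

empty_bonds <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = numeric(),
             stereo = character(), ref1 = integer(), ref2 = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds: ",
      write_smiles(x), "\n", sep = "")
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

# neighbour list: for each atom, integer vector of adjacent atom indices
# (in bond-table order) and parallel bond-row indices.
mol_adjacency <- function(mol) {
  n <- n_atoms(mol)
  nbr <- rep(list(integer(0)), n)
  bidx <- rep(list(integer(0)), n)
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b$a1[k]; j <- b$a2[k]
      nbr[[i]] <- c(nbr[[i]], j); bidx[[i]] <- c(bidx[[i]], k)
      nbr[[j]] <- c(nbr[[j]], i); bidx[[j]] <- c(bidx[[j]], k)
    }
  }
  list(nbr = nbr, bond = bidx)
}

# sum of bond orders incident to each atom (aromatic counts 1.5)
bond_order_sums <- function(mol) {
  s <- numeric(n_atoms(mol))
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      s[b$a1[k]] <- s[b$a1[k]] + b$order[k]
      s[b$a2[k]] <- s[b$a2[k]] + b$order[k]
    }
  }
  s
}

bond_between <- function(mol, i, j) {
  b <- mol$bonds
  k <- which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))
  if (length(k)) k[1] else NA_integer_
}

# connected components; returns integer membership vector
mol_components <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n)
  adj <- mol_adjacency(mol)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj$nbr[[v]]) {
        if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# extract induced subgraph on a set of atom indices (keeps bonds between them)
mol_subgraph <- function(mol, keep) {
  keep <- sort(unique(keep))
  remap <- integer(n_atoms(mol))
  remap[keep] <- seq_along(keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- mol$bonds
  sel <- b$a1 %in% keep & b$a2 %in% keep
  b <- b[sel, , drop = FALSE]
  if (nrow(b)) {
    b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
    b$ref1 <- ifelse(!is.na(b$ref1) & b$ref1 %in% keep, remap[pmax(b$ref1, 1L)], NA_integer_)
    b$ref2 <- ifelse(!is.na(b$ref2) & b$ref2 %in% keep, remap[pmax(b$ref2, 1L)], NA_integer_)
  }
  rownames(b) <- NULL
  # chirality parities were stored relative to ascending neighbour index;
  # index-order is preserved under subsetting, so parities survive unless a
  # neighbour was dropped (then the parity is meaningless and is cleared).
  if (nrow(atoms)) {
    adj_old <- mol_adjacency(mol)
    for (ii in seq_along(keep)) {
      if (atoms$chiral[ii] != 0L) {
        if (!all(adj_old$nbr[[keep[ii]]] %in% keep)) atoms$chiral[ii] <- 0L
      }
    }
  }
  molgraph(atoms, b)
}

# split a molgraph into a list of connected-component molgraphs
mol_split <- function(mol) {
  comp <- mol_components(mol)
  lapply(seq_len(max(comp, 0L)), function(k) mol_subgraph(mol, which(comp == k)))
}

# disjoint union of a list of molgraphs; returns combined molgraph plus the
# offset of each input's atoms in the result
mol_union <- function(mols) {
  if (!length(mols)) return(list(mol = molgraph(empty_atoms()), offsets = integer()))
  offs <- integer(length(mols))
  atoms <- list(); bonds <- list()
  off <- 0L
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    offs[i] <- off
    atoms[[i]] <- m$atoms
    b <- m$bonds
    if (nrow(b)) {
      b$a1 <- b$a1 + off; b$a2 <- b$a2 + off
      b$ref1 <- b$ref1 + off; b$ref2 <- b$ref2 + off
    }
    bonds[[i]] <- b
    off <- off + n_atoms(m)
  }
  a <- do.call(rbind, atoms); rownames(a) <- NULL
  b <- do.call(rbind, bonds); rownames(b) <- NULL
  list(mol = molgraph(a, b), offsets = offs)
}

empty_atoms <- function() {
  data.frame(element = character(), charge = integer(), hcount = integer(),
             aromatic = logical(), map = integer(), radical = integer(),
             chiral = integer(), isotope = integer(), stringsAsFactors = FALSE)
}

new_atom <- function(element, charge = 0L, hcount = NA_integer_,
                     aromatic = FALSE, map = NA_integer_, radical = 0L,
                     chiral = 0L, isotope = NA_integer_) {
  data.frame(element = element, charge = as.integer(charge),
             hcount = as.integer(hcount), aromatic = aromatic,
             map = as.integer(map), radical = as.integer(radical),
             chiral = as.integer(chiral), isotope = as.integer(isotope),
             stringsAsFactors = FALSE)
}

# ---- element tables ---------------------------------------------------------

ATOMIC_NUMBERS <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L,
  Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L, S = 16L,
  Cl = 17L, Ar = 18L, K = 19L, Ca = 20L, Ti = 22L, Cr = 24L, Mn = 25L,
  Fe = 26L, Co = 27L, Ni = 28L, Cu = 29L, Zn = 30L, Ga = 31L, Ge = 32L,
  As = 33L, Se = 34L, Br = 35L, Rb = 37L, Sr = 38L, Zr = 40L, Mo = 42L,
  Ru = 44L, Rh = 45L, Pd = 46L, Ag = 47L, Cd = 48L, In = 49L, Sn = 50L,
  Sb = 51L, Te = 52L, I = 53L, Cs = 55L, Ba = 56L, W = 74L, Pt = 78L,
  Au = 79L, Hg = 80L, Tl = 81L, Pb = 82L, Bi = 83L)

atomic_number <- function(element) {
  z <- ATOMIC_NUMBERS[element]
  if (any(is.na(z))) stop("unknown element symbol: ",
                          paste(element[is.na(z)], collapse = ", "))
  unname(z)
}

element_from_z <- function(z) {
  sym <- names(ATOMIC_NUMBERS)[match(z, ATOMIC_NUMBERS)]
  if (any(is.na(sym))) stop("unknown atomic number: ",
                            paste(z[is.na(sym)], collapse = ", "))
  sym
}

# SMILES organic-subset default valences (used for implicit-H perception)
SMILES_VALENCES <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                        S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# implicit H for an organic-subset atom given its incident bond-order sum:
# smallest default valence that accommodates the bonds, minus the bonds.
default_implicit_h <- function(element, order_sum) {
  v <- SMILES_VALENCES[[element]]
  if (is.null(v)) return(0L)
  need <- ceiling(order_sum - 1e-9)
  fit <- v[v >= need]
  if (!length(fit)) return(0L)
  as.integer(fit[1] - need)
}

# fill NA hcounts of organic-subset-style atoms from default valences;
# used after parsing bare (non-bracket) atoms.
perceive_implicit_h <- function(mol) {
  na_h <- which(is.na(mol$atoms$hcount))
  if (!length(na_h)) return(mol)
  sums <- bond_order_sums(mol)
  for (i in na_h) {
    mol$atoms$hcount[i] <- default_implicit_h(mol$atoms$element[i], sums[i])
  }
  mol
}

# heavy-atom element count table (named integer vector), used for balance audits
heavy_atom_counts <- function(mols) {
  els <- unlist(lapply(mols, function(m) m$atoms$element[m$atoms$element != "H"]))
  if (!length(els)) return(integer())
  tab <- table(els)
  stats::setNames(as.integer(tab), names(tab))
}
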