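# SMILES / SMARTS-dialect parser.
#
# Supports the subset of daylight SMILES needed for single-step organic
# reactions: bracket atoms with isotope / chirality / H count / charge /
# atom-map, the organic subset (B C N O P S F Cl Br I) plus aromatic
# b c n o p s, bond symbols - = # : / \, branches, and ring closures
# (including %nn).  In pattern mode, atomic-number primitives ([#6:1]) are
# accepted and unannotated atoms are hydrogen-unconstrained.

BRACKET_RE <- paste0(
  "^\\[(\\d+)?",                        # isotope
  "(#\\d+|[A-Z][a-z]?|as|se|[bcnops])", # element
  "(@@|@)?",                            # tetrahedral parity
  "(H\\d*)?",                           # hydrogen count
  "(\\+\\d+|-\\d+|\\+{1,3}|-{1,3})?",   # formal charge
  "(?::(\\d+))?",                       # atom map
  "\\]")

parse_charge_token <- function(tok) {
  if (is.na(tok) || tok == "") return(0L)
  sign <- if (substr(tok, 1, 1) == "+") 1L else -1L
  digits <- gsub("[+-]", "", tok)
  if (digits == "") sign * nchar(tok) else sign * as.integer(digits)
}

#' Parse a single-molecule SMILES string
#'
#' @param s SMILES text without `.` separators.
#' @param pattern logical; parse in SMARTS-dialect pattern mode, where
#'   `[#6:1]`-style atomic-number atoms are accepted and atoms without an
#'   explicit H specification are hydrogen-unconstrained (`hcount = NA`).
#' @return a [molgraph()].
#' @export
parse_smiles <- function(s, pattern = FALSE) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s))
    stop("empty or invalid SMILES string")
  if (grepl("\\.", s)) stop("parse_smiles() takes a single component; split on '.' first")

  atoms <- list(); bonds <- list()
  bracketed <- logical()
  enc <- list()                 # chirality encounter sequences (0 = implicit H)
  prev <- NA_integer_
  pending <- NULL               # pending bond symbol
  pend_dir <- 0L                # +1 '/', -1 '\'
  stack <- list()
  rings <- list()               # open ring closures keyed by token
  dir_info <- list()            # directional single bonds: (bond k, from, to, dir)

  add_bond <- function(i, j, sym, dir) {
    k <- length(bonds) + 1L
    bonds[[k]] <<- list(a1 = i, a2 = j, sym = sym)
    if (!is.null(sym) && dir != 0L)
      dir_info[[length(dir_info) + 1L]] <<- list(k = k, from = i, to = j, dir = dir)
    k
  }

  add_atom <- function(at, is_bracket) {
    idx <- length(atoms) + 1L
    atoms[[idx]] <<- at
    bracketed[idx] <<- is_bracket
    seq0 <- integer()
    if (!is.na(prev)) {
      add_bond(prev, idx, pending, pend_dir)
      enc[[prev]] <<- c(enc[[prev]], idx)
      seq0 <- prev
    }
    if (is_bracket && at$chiral != 0L && !is.na(at$hcount) && at$hcount == 1L)
      seq0 <- c(seq0, 0L)
    enc[[idx]] <<- seq0
    pending <<- NULL; pend_dir <<- 0L
    prev <<- idx
  }

  handle_ring <- function(tok) {
    key <- as.character(tok)
    cur <- prev
    if (is.na(cur)) stop("ring closure before any atom")
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = cur, sym = pending)
      enc[[cur]] <<- c(enc[[cur]], -tok)
    } else {
      open <- rings[[key]]
      sym <- if (!is.null(pending)) pending else open$sym
      if (!is.null(pending) && !is.null(open$sym) && pending != open$sym)
        stop("conflicting ring-closure bond symbols")
      add_bond(open$atom, cur, sym, 0L)
      enc[[open$atom]][enc[[open$atom]] == -tok] <<- cur
      enc[[cur]] <<- c(enc[[cur]], open$atom)
      rings[[key]] <<- NULL
    }
    pending <<- NULL; pend_dir <<- 0L
  }

  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      if (is.na(prev)) stop("branch open without preceding atom")
      stack[[length(stack) + 1L]] <- prev
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES")
      prev <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- if (ch %in% c("/", "\\")) "-" else ch
      pend_dir <- if (ch == "/") 1L else if (ch == "\\") -1L else 0L
      i <- i + 1L
    } else if (ch == "%") {
      tok <- as.integer(substr(s, i + 1L, i + 2L))
      if (is.na(tok)) stop("malformed %nn ring closure")
      handle_ring(tok)
      i <- i + 3L
    } else if (grepl("^[0-9]$", ch)) {
      handle_ring(as.integer(ch))
      i <- i + 1L
    } else if (ch == "[") {
      m <- regexec(BRACKET_RE, substr(s, i, n), perl = TRUE)[[1]]
      if (m[1] == -1) stop("malformed bracket atom at position ", i, " in '", s, "'")
      g <- regmatches(substr(s, i, n), list(m))[[1]]
      iso <- if (g[2] == "") NA_integer_ else as.integer(g[2])
      sym <- g[3]
      aromatic <- FALSE
      if (grepl("^#", sym)) {
        if (!pattern) stop("atomic-number atom outside pattern mode: ", sym)
        element <- element_from_z(as.integer(substr(sym, 2, nchar(sym))))
      } else if (sym %in% c("b", "c", "n", "o", "p", "s", "as", "se")) {
        aromatic <- TRUE
        element <- if (nchar(sym) == 2) {
          paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 2))
        } else toupper(sym)
      } else {
        element <- sym
        atomic_number(element)  # validate
      }
      chiral <- if (g[4] == "@") 1L else if (g[4] == "@@") 2L else 0L
      hcount <- if (g[5] == "") {
        if (pattern) NA_integer_ else 0L
      } else if (g[5] == "H") 1L else as.integer(substr(g[5], 2, nchar(g[5])))
      charge <- if (g[6] == "" && pattern) NA_integer_ else parse_charge_token(g[6])
      map <- if (g[7] == "") NA_integer_ else as.integer(g[7])
      add_atom(new_atom(element, charge = charge, hcount = hcount,
                        aromatic = aromatic, map = map, chiral = chiral,
                        isotope = iso), TRUE)
      i <- i + attr(m, "match.length")[1]
    } else {
      two <- substr(s, i, i + 1L)
      pat_charge <- if (pattern) NA_integer_ else 0L
      if (two %in% c("Cl", "Br")) {
        add_atom(new_atom(two, charge = pat_charge), FALSE)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(new_atom(ch, charge = pat_charge), FALSE)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(new_atom(toupper(ch), aromatic = TRUE, charge = pat_charge), FALSE)
        i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' at position ", i, " in '", s, "'")
      }
    }
  }
  if (length(stack)) stop("unbalanced '(' in SMILES")
  if (length(rings)) stop("unclosed ring bond in SMILES")
  if (!length(atoms)) stop("SMILES contains no atoms")

  adf <- do.call(rbind, atoms)
  # resolve bond orders; default depends on aromaticity of both endpoints
  bdf <- empty_bonds()
  if (length(bonds)) {
    bdf <- data.frame(
      a1 = vapply(bonds, function(b) b$a1, integer(1)),
      a2 = vapply(bonds, function(b) b$a2, integer(1)),
      order = vapply(bonds, function(b) {
        if (is.null(b$sym)) {
          if (adf$aromatic[b$a1] && adf$aromatic[b$a2]) AROMATIC_ORDER else 1
        } else switch(b$sym, "-" = 1, "=" = 2, "#" = 3, ":" = AROMATIC_ORDER)
      }, numeric(1)),
      stereo = NA_character_, ref1 = NA_integer_, ref2 = NA_integer_,
      stringsAsFactors = FALSE)
  }
  mol <- molgraph(adf, bdf)

  if (!pattern) mol <- perceive_implicit_h(mol)

  # tetrahedral parity: re-express each @/@@ relative to the convention
  # (implicit H first, then neighbours by ascending atom index)
  for (a in seq_len(n_atoms(mol))) {
    if (mol$atoms$chiral[a] == 0L) next
    seq_enc <- enc[[a]]
    if (any(seq_enc < 0L) || length(seq_enc) != 4L) {
      mol$atoms$chiral[a] <- 0L  # unsupported chiral environment
      next
    }
    conv <- c(if (0L %in% seq_enc) 0L, sort(seq_enc[seq_enc > 0L]))
    if (perm_parity(match(conv, seq_enc)) == 1L)
      mol$atoms$chiral[a] <- 3L - mol$atoms$chiral[a]
  }

  mol <- resolve_bond_stereo(mol, dir_info)
  if (!pattern) {
    mol <- perceive_radicals(mol, bracketed)
    mol <- fold_explicit_h(mol)
  }
  mol
}

# parity (0/1) of a permutation given as an index vector
perm_parity <- function(p) {
  inv <- 0L
  n <- length(p)
  if (n > 1) {
    for (i in seq_len(n - 1)) inv <- inv + sum(p[(i + 1):n] < p[i])
  }
  as.integer(inv %% 2L)
}

# convert parsed directional single bonds into cis/trans labels on double bonds
resolve_bond_stereo <- function(mol, dir_info) {
  if (!length(dir_info)) return(mol)
  # side sign of directional neighbour x relative to double-bond atom a:
  # dir if written x -> a, else -dir
  side_sign <- function(d, dbl_atom) {
    if (d$to == dbl_atom) d$dir else -d$dir
  }
  b <- mol$bonds
  for (k in which(b$order == 2)) {
    a1 <- b$a1[k]; a2 <- b$a2[k]
    d1 <- Filter(function(d) a1 %in% c(d$from, d$to), dir_info)
    d2 <- Filter(function(d) a2 %in% c(d$from, d$to), dir_info)
    d1 <- Filter(function(d) !(a2 %in% c(d$from, d$to)), d1)
    d2 <- Filter(function(d) !(a1 %in% c(d$from, d$to)), d2)
    if (!length(d1) || !length(d2)) next
    ref_atom <- function(d, dbl) if (d$from == dbl) d$to else d$from
    o1 <- order(vapply(d1, ref_atom, integer(1), dbl = a1))
    o2 <- order(vapply(d2, ref_atom, integer(1), dbl = a2))
    d1 <- d1[[o1[1]]]; d2 <- d2[[o2[1]]]
    s1 <- side_sign(d1, a1); s2 <- side_sign(d2, a2)
    b$stereo[k] <- if (s1 == s2) "cis" else "trans"
    b$ref1[k] <- ref_atom(d1, a1)
    b$ref2[k] <- ref_atom(d2, a2)
  }
  mol$bonds <- b
  mol
}

# unpaired electrons for neutral subvalent bracket atoms ([CH3] etc.)
perceive_radicals <- function(mol, bracketed) {
  sums <- bond_order_sums(mol)
  for (i in seq_len(n_atoms(mol))) {
    if (!bracketed[i]) next
    el <- mol$atoms$element[i]
    if (mol$atoms$charge[i] != 0L || !el %in% names(SMILES_VALENCES)) next
    v0 <- SMILES_VALENCES[[el]][1]
    deficit <- v0 - ceiling(sums[i] - 1e-9) - mol$atoms$hcount[i]
    if (deficit > 0) mol$atoms$radical[i] <- as.integer(deficit)
  }
  mol
}

# fold explicit neutral hydrogen atoms bonded to one heavy atom into that
# atom's implicit H count; frees template logic to reason over heavy atoms
fold_explicit_h <- function(mol) {
  adj <- mol_adjacency(mol)
  drop <- integer()
  for (i in seq_len(n_atoms(mol))) {
    at <- mol$atoms[i, ]
    if (at$element != "H" || at$charge != 0L) next
    nb <- adj$nbr[[i]]
    if (length(nb) != 1L || mol$atoms$element[nb] == "H") next
    if (mol$bonds$order[adj$bond[[i]]] != 1) next
    j <- nb
    mol$atoms$hcount[j] <- mol$atoms$hcount[j] + 1L
    # parity fix-up: the folded H moves from its ascending-index slot to the
    # implicit-H-first slot of the neighbour's convention ordering
    if (mol$atoms$chiral[j] != 0L) {
      nbrs_sorted <- sort(adj$nbr[[j]])
      p <- match(i, nbrs_sorted)
      had_h <- mol$atoms$hcount[j] - 1L > 0L  # H already in convention? (rare)
      shift <- p - 1L + as.integer(had_h)
      if (shift %% 2L == 1L)
        mol$atoms$chiral[j] <- 3L - mol$atoms$chiral[j]
    }
    drop <- c(drop, i)
  }
  if (length(drop)) mol <- mol_subgraph(mol, setdiff(seq_len(n_atoms(mol)), drop))
  mol
}

# strip isotope labels (they do not affect the chemical transformation)
strip_isotopes <- function(mol) {
  mol$atoms$isotope <- NA_integer_
  mol
}
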