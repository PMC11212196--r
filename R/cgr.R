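# Condensed graph of reaction (CGR): the superposition of reactant and
# product graphs under the atom mapping, with (order_before, order_after)
# edge labels.  Absent bonds are encoded as order 0, so the changed-edge set
# is exactly the reaction-centre bond set.

#' Build the condensed graph of reaction
#'
#' Nodes are keyed by atom-map number for atoms mapped on both sides;
#' reactant-only and product-only atoms (unmapped, or carrying an orphan map)
#' become side-specific nodes whose bonds have order 0 on the missing side.
#'
#' @param rxn a `mapped_reaction` (spectators are ignored).
#' @return an object of class `cgr` with fields `nodes` (map, element,
#'   h_before/h_after, charge_before/charge_after) and `edges`
#'   (`before`/`after` bond orders); unpaired atoms are summarized in
#'   `loose` signatures used for equality checks.
#' @export
build_cgr <- function(rxn) {
  ru <- mol_union(rxn$reactants)$mol
  pu <- mol_union(rxn$products)$mol
  for (side in list(ru, pu)) {
    mm <- side$atoms$map
    if (anyDuplicated(mm[!is.na(mm)]))
      stop(structure(class = c("cgr_integrity_error", "error", "condition"),
                     list(message = paste0("record ", rxn$id,
                                           ": duplicate atom-map number within one side"),
                          call = NULL)))
  }
  rmaps <- ru$atoms$map; pmaps <- pu$atoms$map
  shared <- intersect(rmaps[!is.na(rmaps)], pmaps[!is.na(pmaps)])
  r_of <- match(shared, rmaps)   # reactant atom index per shared map
  p_of <- match(shared, pmaps)

  nodes <- data.frame(
    map = shared,
    element = pu$atoms$element[p_of],
    element_r = ru$atoms$element[r_of],
    h_before = ru$atoms$hcount[r_of],
    h_after = pu$atoms$hcount[p_of],
    charge_before = ru$atoms$charge[r_of],
    charge_after = pu$atoms$charge[p_of],
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$map), , drop = FALSE]
  rownames(nodes) <- NULL

  # edges among shared-mapped atoms
  edge_key <- function(m1, m2) paste(pmin(m1, m2), pmax(m1, m2))
  before <- list(); after <- list()
  collect <- function(mol, maps_ok, store) {
    b <- mol$bonds
    out <- list()
    if (nrow(b)) for (k in seq_len(nrow(b))) {
      m1 <- mol$atoms$map[b$a1[k]]; m2 <- mol$atoms$map[b$a2[k]]
      if (!is.na(m1) && !is.na(m2) && m1 %in% shared && m2 %in% shared)
        out[[edge_key(m1, m2)]] <- b$order[k]
    }
    out
  }
  before <- collect(ru)
  after <- collect(pu)
  keys <- union(names(before), names(after))
  edges <- data.frame(key = as.character(keys),
                      before = vapply(keys, function(k)
                        if (is.null(before[[k]])) 0 else before[[k]],
                        numeric(1), USE.NAMES = FALSE),
                      after = vapply(keys, function(k)
                        if (is.null(after[[k]])) 0 else after[[k]],
                        numeric(1), USE.NAMES = FALSE),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$key), , drop = FALSE]
  rownames(edges) <- NULL

  # side-only atoms: signature = element, charge, H, sorted incident stubs
  # (neighbour element-or-map with before/after orders)
  loose_side <- function(mol, side) {
    adj <- mol_adjacency(mol)
    mm <- mol$atoms$map
    solo <- which(is.na(mm) | !(mm %in% shared))
    vapply(solo, function(i) {
      stubs <- sort(vapply(seq_along(adj$nbr[[i]]), function(t) {
        j <- adj$nbr[[i]][t]
        lab <- if (!is.na(mm[j]) && mm[j] %in% shared) paste0("m", mm[j])
               else mol$atoms$element[j]
        paste0(lab, ":", mol$bonds$order[adj$bond[[i]][t]])
      }, character(1)))
      paste0(side, "|", mol$atoms$element[i], "|", mol$atoms$charge[i], "|",
             mol$atoms$hcount[i], "|", paste(stubs, collapse = ","))
    }, character(1))
  }
  loose <- sort(c(loose_side(ru, "R"), loose_side(pu, "P")))

  # attachment points of side-only atoms onto shared-mapped atoms
  attach_side <- function(mol, side) {
    adj <- mol_adjacency(mol)
    mm <- mol$atoms$map
    solo <- which(is.na(mm) | !(mm %in% shared))
    out <- integer()
    for (i in solo) {
      for (j in adj$nbr[[i]]) {
        if (!is.na(mm[j]) && mm[j] %in% shared) out <- c(out, mm[j])
      }
    }
    if (length(out)) data.frame(map = out, side = side, stringsAsFactors = FALSE)
    else data.frame(map = integer(), side = character(), stringsAsFactors = FALSE)
  }
  loose_attach <- rbind(attach_side(ru, "R"), attach_side(pu, "P"))

  structure(list(nodes = nodes, edges = edges, loose = loose,
                 loose_attach = loose_attach, ru = ru, pu = pu,
                 shared = shared, id = rxn$id),
            class = "cgr")
}

#' @export
print.cgr <- function(x, ...) {
  ch <- cgr_changed_edges(x)
  cat("<cgr> ", nrow(x$nodes), " mapped nodes, ", nrow(x$edges), " edges (",
      nrow(ch), " changed), ", length(x$loose), " side-only atoms\n", sep = "")
  invisible(x)
}

#' Changed edges of a CGR (the reaction-centre bond set)
#' @param cgr a `cgr` object.
#' @return subset of `cgr$edges` where the bond order differs between sides.
#' @export
cgr_changed_edges <- function(cgr) {
  cgr$edges[cgr$edges$before != cgr$edges$after, , drop = FALSE]
}

#' Strict CGR equality
#'
#' Equality up to map-number-preserving identity: the mapped node tables,
#' the mapped edge tables, and the side-only atom signature multisets must
#' all agree.  Use [cgr_isomorphic()] for a mapping-renaming-tolerant
#' comparison of the underlying transformation.
#'
#' @param a,b `cgr` objects.
#' @return logical.
#' @export
cgr_equal <- function(a, b) {
  isTRUE(all.equal(a$nodes, b$nodes, check.attributes = FALSE)) &&
    isTRUE(all.equal(a$edges, b$edges, check.attributes = FALSE)) &&
    identical(a$loose, b$loose)
}

#' CGR identity up to renaming of atom-map numbers
#'
#' Tests whether two CGRs describe the same transformation irrespective of
#' which atoms carry which map numbers, via colored graph isomorphism
#' (node color: element + hydrogen and charge deltas; edge color:
#' before/after order pair).
#'
#' @param a,b `cgr` objects.
#' @return logical.
#' @export
cgr_isomorphic <- function(a, b) {
  if (nrow(a$nodes) != nrow(b$nodes) || nrow(a$edges) != nrow(b$edges))
    return(FALSE)
  # full superposition graph: shared-mapped nodes plus side-only atoms
  build <- function(x) {
    nshared <- nrow(x$nodes)
    r_solo <- which(is.na(x$ru$atoms$map) | !(x$ru$atoms$map %in% x$shared))
    p_solo <- which(is.na(x$pu$atoms$map) | !(x$pu$atoms$map %in% x$shared))
    # vertex ids: 1..nshared shared (by nodes-table order), then r_solo, p_solo
    rid <- stats::setNames(seq_along(r_solo) + nshared, r_solo)
    pid <- stats::setNames(seq_along(p_solo) + nshared + length(r_solo), p_solo)
    vsig <- c(if (nshared) paste0("S|", x$nodes$element, "|",
                     x$nodes$h_after - x$nodes$h_before, "|",
                     x$nodes$charge_after - x$nodes$charge_before),
              if (length(r_solo)) paste0("R|", x$ru$atoms$element[r_solo], "|",
                     x$ru$atoms$charge[r_solo], "|", x$ru$atoms$hcount[r_solo]),
              if (length(p_solo)) paste0("P|", x$pu$atoms$element[p_solo], "|",
                     x$pu$atoms$charge[p_solo], "|", x$pu$atoms$hcount[p_solo]))
    km <- strsplit(x$edges$key, " ")
    e1 <- match(as.integer(vapply(km, `[`, character(1), 1)), x$nodes$map)
    e2 <- match(as.integer(vapply(km, `[`, character(1), 2)), x$nodes$map)
    esig <- paste0(x$edges$before, ">", x$edges$after)
    solo_edges <- function(mol, solo, id_of, before_side) {
      bb <- mol$bonds; mm <- mol$atoms$map
      out_e1 <- integer(); out_e2 <- integer(); out_sig <- character()
      if (nrow(bb)) for (k in seq_len(nrow(bb))) {
        i <- bb$a1[k]; j <- bb$a2[k]
        si <- i %in% solo; sj <- j %in% solo
        if (!si && !sj) next
        vi <- if (si) id_of[[as.character(i)]] else match(mm[i], x$nodes$map)
        vj <- if (sj) id_of[[as.character(j)]] else match(mm[j], x$nodes$map)
        out_e1 <- c(out_e1, vi); out_e2 <- c(out_e2, vj)
        out_sig <- c(out_sig, if (before_side) paste0(bb$order[k], ">0")
                              else paste0("0>", bb$order[k]))
      }
      list(e1 = out_e1, e2 = out_e2, sig = out_sig)
    }
    re <- solo_edges(x$ru, r_solo, as.list(rid), TRUE)
    pe <- solo_edges(x$pu, p_solo, as.list(pid), FALSE)
    e1 <- c(e1, re$e1, pe$e1); e2 <- c(e2, re$e2, pe$e2)
    esig <- c(esig, re$sig, pe$sig)
    nv <- nshared + length(r_solo) + length(p_solo)
    g <- igraph::make_graph(rbind(e1, e2), n = nv, directed = FALSE)
    list(g = g, vsig = vsig, esig = esig)
  }
  ga <- build(a); gb <- build(b)
  vlev <- sort(unique(c(ga$vsig, gb$vsig)))
  elev <- sort(unique(c(ga$esig, gb$esig)))
  vca <- match(ga$vsig, vlev); vcb <- match(gb$vsig, vlev)
  if (!identical(sort(tabulate(vca, length(vlev))),
                 sort(tabulate(vcb, length(vlev))))) return(FALSE)
  igraph::isomorphic(ga$g, gb$g, method = "vf2",
                     vertex.color1 = vca, vertex.color2 = vcb,
                     edge.color1 = match(ga$esig, elev),
                     edge.color2 = match(gb$esig, elev))
}
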