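# Template canonicalization and the template library.
#
# Templates whose reactant-side and product-side pattern graphs are both
# isomorphic (ignoring map numbering) describe the same chemical
# transformation; among them the member with the fewest bond changes is kept
# (principle of minimum chemical distance), frequencies are summed.

pattern_igraph <- function(mols) {
  u <- mol_union(mols)$mol
  a <- u$atoms
  vsig <- paste0(atomic_number(a$element), "|",
                 ifelse(is.na(a$hcount), -1L, a$hcount), "|",
                 ifelse(is.na(a$charge), 99L, a$charge))
  esig <- sprintf("%.1f", u$bonds$order)
  g <- igraph::make_graph(rbind(u$bonds$a1, u$bonds$a2),
                          n = n_atoms(u), directed = FALSE)
  list(g = g, vsig = vsig, esig = esig)
}

patterns_isomorphic <- function(pa, pb) {
  if (igraph::vcount(pa$g) != igraph::vcount(pb$g) ||
      igraph::ecount(pa$g) != igraph::ecount(pb$g)) return(FALSE)
  vlev <- sort(unique(c(pa$vsig, pb$vsig)))
  elev <- sort(unique(c(pa$esig, pb$esig)))
  va <- match(pa$vsig, vlev); vb <- match(pb$vsig, vlev)
  if (!identical(sort(tabulate(va, length(vlev))),
                 sort(tabulate(vb, length(vlev))))) return(FALSE)
  igraph::isomorphic(pa$g, pb$g, method = "vf2",
                     vertex.color1 = va, vertex.color2 = vb,
                     edge.color1 = match(pa$esig, elev),
                     edge.color2 = match(pb$esig, elev))
}

strip_pattern_maps <- function(mol) { mol$atoms$map <- NA_integer_; mol }

template_hash <- function(t) {
  pk <- canonical_key(strip_pattern_maps(t$product_pattern))
  rk <- sort(vapply(t$reactant_patterns, function(rp)
    canonical_key(strip_pattern_maps(rp)), character(1)))
  paste(pk, paste(rk, collapse = "."), sep = ">>")
}

#' Merge isomorphic generic templates
#'
#' Templates whose product patterns and reactant patterns are pairwise graph
#' isomorphic (node labels: element plus any H/charge specification; edge
#' labels: bond order; map numbers ignored) are combined.  The representative
#' is the member with the fewest bond changes, ties broken by the
#' lexicographically smallest serialization, and frequencies are summed, so
#' the merge is order-independent.
#'
#' @param ts list of `generic_template` objects.
#' @return an unfiltered `template_library`.
#' @export
merge_isomorphic_templates <- function(ts) {
  stopifnot(length(ts) > 0)
  hashes <- vapply(ts, template_hash, character(1))
  groups <- list()          # each: indices into ts
  for (bucket in split(seq_along(ts), hashes)) {
    sub_groups <- list()    # within-bucket: verified isomorphism classes
    pg <- lapply(bucket, function(i) pattern_igraph(list(ts[[i]]$product_pattern)))
    rg <- lapply(bucket, function(i) pattern_igraph(ts[[i]]$reactant_patterns))
    for (bi in seq_along(bucket)) {
      placed <- FALSE
      for (gi in seq_along(sub_groups)) {
        ref <- sub_groups[[gi]][1]
        if (patterns_isomorphic(pg[[bi]], pg[[ref]]) &&
            patterns_isomorphic(rg[[bi]], rg[[ref]])) {
          sub_groups[[gi]] <- c(sub_groups[[gi]], bi)
          placed <- TRUE
          break
        }
      }
      if (!placed) sub_groups[[length(sub_groups) + 1L]] <- bi
    }
    for (sg in sub_groups)
      groups[[length(groups) + 1L]] <- bucket[sg]
  }
  merged <- lapply(groups, function(idx) {
    members <- ts[idx]
    bc <- vapply(members, function(t) t$bond_changes, integer(1))
    sm <- vapply(members, function(t) t$smarts, character(1))
    rep_i <- order(bc, sm)[1]
    rep <- members[[rep_i]]
    rep$frequency <- sum(vapply(members, function(t) t$frequency, integer(1)))
    ids <- unlist(lapply(members, function(t) t$example_ids))
    rep$example_ids <- utils::head(unique(ids), 10L)
    rep
  })
  template_library(merged, min_frequency = 0L)
}

#' Construct a template library
#'
#' @param templates list of `generic_template` objects (assumed merged).
#' @param min_frequency the threshold the library was filtered at.
#' @return a `template_library`, sorted by descending frequency (ties by
#'   serialization).
#' @export
template_library <- function(templates, min_frequency = 0L) {
  freq <- vapply(templates, function(t) t$frequency, integer(1))
  sm <- vapply(templates, function(t) t$smarts, character(1))
  templates <- templates[order(-freq, sm)]
  structure(list(templates = templates,
                 min_frequency = as.integer(min_frequency)),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat("<template_library> ", length(x$templates), " templates (min frequency ",
      x$min_frequency, ")\n", sep = "")
  for (t in utils::head(x$templates, 10L))
    cat(sprintf("  %6d  %s\n", t$frequency, t$smarts))
  if (length(x$templates) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
length.template_library <- function(x) length(x$templates)

#' Remove rare templates
#'
#' Retains exactly the templates whose occurrence frequency exceeds
#' `min_frequency` (default 5: templates seen five times or fewer are
#' removed, as rare transformations are likely extraction artefacts from
#' erroneous records).
#'
#' @param lib a `template_library` (merged).
#' @param min_frequency integer threshold.
#' @return filtered `template_library`; empty is legal (callers warn).
#' @export
filter_rare_templates <- function(lib, min_frequency = 5L) {
  keep <- Filter(function(t) t$frequency > min_frequency, lib$templates)
  template_library(keep, min_frequency = min_frequency)
}

#' Extract, merge and filter templates from a reaction set
#'
#' Spectators are removed per reaction; duplicate reactions (identical
#' canonical reaction serializations) count once toward template frequency;
#' reactions with no detectable transformation or other extraction failures
#' are skipped and reported.
#'
#' @param reactions list of `mapped_reaction` objects.
#' @param min_frequency frequency threshold for [filter_rare_templates()].
#' @param dedupe count duplicate reactions once.
#' @return a `template_library`; skipped records are available via
#'   `attr(, "skipped")`.
#' @export
extract_template_library <- function(reactions, min_frequency = 5L,
                                     dedupe = TRUE) {
  ts <- list()
  skipped_id <- character(); skipped_why <- character()
  seen <- character()
  for (rxn in reactions) {
    res <- tryCatch({
      core <- remove_spectators(rxn)
      if (dedupe) {
        key <- write_reaction(core, with_spectators = FALSE)
        if (key %in% seen) NULL else {
          seen <- c(seen, key)
          extract_generic_template(core)
        }
      } else extract_generic_template(core)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped_id <- c(skipped_id, rxn$id)
      skipped_why <- c(skipped_why, conditionMessage(res))
    } else if (!is.null(res)) {
      ts[[length(ts) + 1L]] <- res
    }
  }
  if (!length(ts)) stop("no templates could be extracted from the input reactions")
  lib <- merge_isomorphic_templates(ts)
  lib <- filter_rare_templates(lib, min_frequency)
  attr(lib, "skipped") <- data.frame(id = skipped_id, reason = skipped_why,
                                     stringsAsFactors = FALSE)
  lib
}

# ---- JSON-lines persistence -------------------------------------------------

#' Write a template library as JSON lines
#'
#' One object per line: `{"template": ..., "frequency": ...,
#' "bond_changes": ..., "example_ids": [...]}`.
#'
#' @param lib a `template_library`.
#' @param path output file.
#' @export
write_template_library <- function(lib, path) {
  lines <- vapply(lib$templates, function(t) {
    jsonlite::toJSON(list(template = t$smarts, frequency = t$frequency,
                          bond_changes = t$bond_changes,
                          example_ids = as.character(t$example_ids)),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a template library from JSON lines
#'
#' @param path file written by [write_template_library()].
#' @param min_frequency recorded threshold (metadata only; no re-filtering).
#' @return a `template_library`.
#' @export
read_template_library <- function(path, min_frequency = 5L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ts <- lapply(lines, function(ln) {
    o <- jsonlite::fromJSON(ln)
    t <- parse_template(o$template)
    t$frequency <- as.integer(o$frequency)
    t$example_ids <- as.character(o$example_ids)
    if (!is.null(o$bond_changes) &&
        as.integer(o$bond_changes) != t$bond_changes)
      warning("stored bond_changes disagrees with recomputation for ",
              o$template)
    t
  })
  template_library(ts, min_frequency = min_frequency)
}
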