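# Synthetic reaction families, noise injection and curation scoring.
#
# The fixture generator emulates families of correctly mapped single-step
# reactions sharing one transformation with varied substituents, optionally
# with several alternative leaving groups (which creates competing templates
# of different frequencies, the effect that depresses exact missing-reactant
# recovery on real data).  Noise injection reproduces three error types:
# removal of a reactant, a structural modification of the product (addition
# of C or O, substitution of C by O or N), and swapping of two atom-map
# numbers in the product.

chain_smiles <- function(len, m0) {
  if (len < 1) stop("chain length must be >= 1")
  if (len == 1) return(sprintf("[CH3:%d]", m0))
  paste0(paste0(sprintf("[CH2:%d]", m0 + seq_len(len - 1) - 1), collapse = ""),
         sprintf("[CH3:%d]", m0 + len - 1))
}

PARA_SUBS <- list(
  H = "[cH:4]",
  Me = "[c:4]([CH3:17])",
  Et = "[c:4]([CH2:17][CH3:18])",
  OMe = "[c:4]([O:17][CH3:18])",
  nPr = "[c:4]([CH2:17][CH2:18][CH3:19])")

#' Built-in reaction family specifications
#'
#' Three single-step families with distinct generic templates: aryl-halide
#' carbonyl addition (Grignard-like, template
#' `[#6:1]-[#6:2]-[#8:3]>>X-[#6:1].[#6:2]=[#8:3]`), Williamson-type ether
#' formation (`[#6:1]-[#8:2]>>X-[#6:1].[#8:2]`) and amide formation from an
#' acyl halide (`[#6:1]-[#7:2]>>X-[#6:1].[#7:2]`).  Substituent pools give
#' each (family, leaving group) pair at least 25 distinct members.
#'
#' @param leaving_groups halide leaving groups per family, e.g. `"Br"` or
#'   `c("Br", "F")`; more than one creates competing templates.
#' @param lg_probs sampling weights over `leaving_groups`.
#' @return list of family specs usable by [generate_fixture_dataset()].
#' @export
builtin_families <- function(leaving_groups = "Br",
                             lg_probs = rep(1 / length(leaving_groups),
                                            length(leaving_groups))) {
  stopifnot(length(leaving_groups) == length(lg_probs))
  draw_lg <- function() sample(leaving_groups, 1L, prob = lg_probs)
  list(
    list(name = "grignard", sample = function() {
      lg <- draw_lg()
      para <- PARA_SUBS[[sample(length(PARA_SUBS), 1L)]]
      ch <- chain_smiles(sample(5L, 1L), 20L)
      paste0(
        sprintf("%s[c:1]1[cH:2][cH:3]%s[cH:5][cH:6]1", lg, para), ".",
        sprintf("[CH:7](=[O:8])%s", ch), ">>",
        sprintf("[OH:8][CH:7](%s)[c:1]1[cH:2][cH:3]%s[cH:5][cH:6]1", ch, para))
    }),
    list(name = "ether", sample = function() {
      lg <- draw_lg()
      la <- sample(5L, 1L); lb <- sample(5L, 1L)
      cha <- chain_smiles(la, 20L)
      chb <- chain_smiles(lb, 40L)
      paste0(sprintf("%s[CH2:1]%s", lg, cha), ".",
             sprintf("[OH:10]%s", chb), ">>",
             sprintf("[CH2:1]([O:10]%s)%s", chb, cha))
    }),
    list(name = "amide", sample = function() {
      lg <- draw_lg()
      chr <- chain_smiles(sample(5L, 1L), 40L)
      chp <- chain_smiles(sample(5L, 1L), 50L)
      paste0(sprintf("%s[C:20](=[O:21])%s", lg, chr), ".",
             sprintf("[NH2:30]%s", chp), ">>",
             sprintf("[C:20](=[O:21])([NH:30]%s)%s", chp, chr))
    }))
}

#' Generate a synthetic fixture dataset
#'
#' Every record is a correctly mapped single-step reaction; each family
#' yields one generic template per leaving group when extracted.
#'
#' @param families list of family specs (see [builtin_families()]); each has
#'   a `name` and a `sample` closure returning one reaction SMILES.
#' @param n_per_family records per family.
#' @param seed RNG seed.
#' @return list of `mapped_reaction` objects with ids `<family>-<i>`.
#' @export
generate_fixture_dataset <- function(families = builtin_families(),
                                     n_per_family = 100L, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (fam in families) {
    for (i in seq_len(n_per_family)) {
      smi <- fam$sample()
      rxn <- tryCatch(parse_reaction(smi, sprintf("%s-%d", fam$name, i)),
                      error = function(e)
                        stop("family '", fam$name, "' generated an invalid ",
                             "reaction: ", conditionMessage(e)))
      out[[length(out) + 1L]] <- rxn
    }
  }
  out
}

#' Noise configuration
#'
#' @param noise_ratio fraction of records corrupted (benchmark levels:
#'   0.09, 0.15, 0.30, 0.45, 0.60).
#' @param type_probs probabilities over the three error types
#'   `missing_reactant`, `structural_mod`, `map_swap` (equal by default).
#' @param seed RNG seed.
#' @return a `noise_config` list.
#' @export
noise_config <- function(noise_ratio = 0.15,
                         type_probs = c(missing_reactant = 1 / 3,
                                        structural_mod = 1 / 3,
                                        map_swap = 1 / 3),
                         seed = 1L) {
  stopifnot(noise_ratio >= 0, noise_ratio <= 1,
            length(type_probs) == 3, abs(sum(type_probs) - 1) < 1e-8)
  names(type_probs) <- c("missing_reactant", "structural_mod", "map_swap")
  structure(list(noise_ratio = noise_ratio, type_probs = type_probs,
                 seed = as.integer(seed)), class = "noise_config")
}

# ---- individual corruptions -------------------------------------------------

corrupt_missing_reactant <- function(rxn) {
  if (length(rxn$reactants) < 2) return(NULL)
  drop <- sample(length(rxn$reactants), 1L)
  rxn$reactants <- rxn$reactants[-drop]
  rxn
}

corrupt_structural <- function(rxn) {
  edits <- sample(c("add_C", "add_O", "sub_O", "sub_N"))  # random order
  for (edit in edits) {
    pi <- sample(length(rxn$products), 1L)
    mol <- rxn$products[[pi]]
    sums <- bond_order_sums(mol)
    if (edit %in% c("add_C", "add_O")) {
      sites <- which(mol$atoms$hcount >= 1L)
      if (!length(sites)) next
      s <- if (length(sites) == 1) sites else sample(sites, 1L)
      el <- if (edit == "add_C") "C" else "O"
      mol$atoms$hcount[s] <- mol$atoms$hcount[s] - 1L
      mol$atoms <- rbind(mol$atoms,
                         new_atom(el, hcount = if (el == "C") 3L else 1L))
      mol$bonds <- rbind(mol$bonds,
                         data.frame(a1 = s, a2 = nrow(mol$atoms), order = 1,
                                    stereo = NA_character_, ref1 = NA_integer_,
                                    ref2 = NA_integer_))
    } else {
      tgt_el <- if (edit == "sub_O") "O" else "N"
      val <- if (tgt_el == "O") 2 else 3
      need <- ceiling(sums - 1e-9)
      sites <- which(mol$atoms$element == "C" & mol$atoms$charge == 0L &
                     mol$atoms$radical == 0L & need <= val &
                     (!mol$atoms$aromatic | tgt_el == "N"))
      if (!length(sites)) next
      s <- if (length(sites) == 1) sites else sample(sites, 1L)
      mol$atoms$element[s] <- tgt_el
      mol$atoms$hcount[s] <- as.integer(val - need[s])
      mol$atoms$chiral[s] <- 0L
    }
    rownames(mol$atoms) <- NULL; rownames(mol$bonds) <- NULL
    rxn$products[[pi]] <- mol
    return(rxn)
  }
  NULL
}

corrupt_map_swap <- function(rxn, pristine_cgr) {
  pi_pool <- which(vapply(rxn$products, function(m) sum(!is.na(m$atoms$map)),
                          integer(1)) >= 2)
  if (!length(pi_pool)) return(NULL)
  for (attempt in seq_len(25L)) {
    pi <- if (length(pi_pool) == 1) pi_pool else sample(pi_pool, 1L)
    mol <- rxn$products[[pi]]
    mapped <- which(!is.na(mol$atoms$map))
    pair <- sample(mapped, 2L)
    cand <- rxn
    mm <- mol$atoms$map
    mm[pair] <- mm[rev(pair)]
    cand$products[[pi]]$atoms$map <- mm
    swapped_cgr <- tryCatch(build_cgr(cand), error = function(e) NULL)
    if (is.null(swapped_cgr)) next
    # the swap must change the transformation itself, not merely permute
    # labels between symmetry-equivalent atoms
    if (!cgr_isomorphic(swapped_cgr, pristine_cgr)) return(cand)
  }
  NULL
}

#' Inject synthetic errors into a reaction set
#'
#' `floor(noise_ratio * n)` records, selected without replacement, each
#' receive exactly one error drawn from `type_probs`.  A record that cannot
#' take the drawn error (single reactant and `missing_reactant`, no valid
#' edit site, no CGR-changing swap) gets another type; if no type applies it
#' stays clean.
#'
#' @param data list of `mapped_reaction` (parse-clean).
#' @param cfg a [noise_config()].
#' @return list with `reactions` (corrupted list) and `labels` (data frame
#'   `id`, `error_type`) plus the pristine originals in
#'   `attr(labels, "pristine")` keyed by id.
#' @export
inject_noise <- function(data, cfg = noise_config()) {
  set.seed(cfg$seed)
  n <- length(data)
  ids <- vapply(data, function(r) r$id, character(1))
  n_bad <- floor(cfg$noise_ratio * n)
  victims <- if (n_bad > 0) sort(sample(n, n_bad)) else integer()
  out <- data
  types <- rep("clean", n)
  for (v in victims) {
    rxn <- data[[v]]
    remaining <- cfg$type_probs
    repeat {
      ty <- sample(names(remaining), 1L, prob = remaining)
      res <- switch(ty,
        missing_reactant = corrupt_missing_reactant(rxn),
        structural_mod = corrupt_structural(rxn),
        map_swap = corrupt_map_swap(rxn, build_cgr(rxn)))
      if (!is.null(res)) {
        out[[v]] <- res
        types[v] <- ty
        break
      }
      remaining <- remaining[names(remaining) != ty]
      if (!length(remaining)) break   # record stays clean
    }
  }
  labels <- data.frame(id = ids, error_type = types, stringsAsFactors = FALSE)
  attr(labels, "pristine") <- stats::setNames(data, ids)
  list(reactions = out, labels = labels)
}

# ---- scoring ----------------------------------------------------------------

#' Score curation outcomes against ground-truth labels
#'
#' Success criteria follow the benchmark design: a `missing_reactant` record
#' succeeds when the curated reactant multiset equals the pristine one
#' (mapping-agnostic); a `structural_mod` record succeeds when it was
#' removed; a `map_swap` record succeeds when the curated CGR describes the
#' same transformation as the pristine CGR.
#'
#' @param outcomes list of `curation_outcome`.
#' @param labels labels from [inject_noise()] (with pristine attribute).
#' @return an `evaluation_report` with percentage success rates, the
#'   residual proportion, and per-type counts.
#' @export
evaluate_curation <- function(outcomes, labels) {
  oid <- vapply(outcomes, function(o) o$id, character(1))
  if (!setequal(oid, labels$id) || length(oid) != nrow(labels))
    stop("outcome ids and label ids do not match")
  pristine <- attr(labels, "pristine")
  o_of <- stats::setNames(outcomes, oid)

  reactant_keys <- function(rxn) {
    sort(vapply(reinstate_spectators(rxn)$reactants, canonical_key,
                character(1)))
  }
  per_type <- list(missing_reactant = logical(), structural_mod = logical(),
                   map_swap = logical())
  removed <- 0L
  for (k in seq_len(nrow(labels))) {
    id <- labels$id[k]; ty <- labels$error_type[k]
    o <- o_of[[id]]
    if (o$status == "removed") removed <- removed + 1L
    if (ty == "clean") next
    hit <- switch(ty,
      missing_reactant = o$status != "removed" &&
        identical(reactant_keys(o$curated_reaction),
                  reactant_keys(pristine[[id]])),
      structural_mod = o$status == "removed",
      map_swap = o$status != "removed" &&
        cgr_isomorphic(build_cgr(tryCatch(remove_spectators(o$curated_reaction),
                                          error = function(e) o$curated_reaction)),
                       build_cgr(tryCatch(remove_spectators(pristine[[id]]),
                                          error = function(e) pristine[[id]]))))
    per_type[[ty]] <- c(per_type[[ty]], isTRUE(hit))
  }
  pct <- function(x) if (!length(x)) NA_real_ else 100 * mean(x)
  structure(list(
    success_missing_reactants = pct(per_type$missing_reactant),
    success_structural_detection = pct(per_type$structural_mod),
    success_map_curation = pct(per_type$map_swap),
    residual_proportion = 100 * (1 - removed / nrow(labels)),
    counts = c(n = nrow(labels),
               vapply(per_type, length, integer(1)),
               removed = removed)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  missing-reactant recovery : %6.2f%% (n=%d)\n",
              x$success_missing_reactants, x$counts[["missing_reactant"]]))
  cat(sprintf("  structural detection      : %6.2f%% (n=%d)\n",
              x$success_structural_detection, x$counts[["structural_mod"]]))
  cat(sprintf("  map curation              : %6.2f%% (n=%d)\n",
              x$success_map_curation, x$counts[["map_swap"]]))
  cat(sprintf("  residual proportion       : %6.2f%%\n", x$residual_proportion))
  invisible(x)
}

#' Run the full noise benchmark
#'
#' Generates fixtures, injects noise, extracts a template library from the
#' corrupted data, curates every record, and scores the outcome.
#'
#' @param families family specs.
#' @param n_per_family records per family.
#' @param cfg a [noise_config()].
#' @param min_frequency template frequency threshold.
#' @return list with `report`, `outcomes`, `labels`, `library`.
#' @export
run_noise_benchmark <- function(families = builtin_families(),
                                n_per_family = 200L,
                                cfg = noise_config(),
                                min_frequency = 5L) {
  data <- generate_fixture_dataset(families, n_per_family, seed = cfg$seed)
  noisy <- inject_noise(data, cfg)
  lib <- extract_template_library(noisy$reactions, min_frequency = min_frequency)
  if (!length(lib$templates)) stop("template library is empty after filtering")
  outcomes <- lapply(noisy$reactions, curate_reaction, lib = lib)
  report <- evaluate_curation(outcomes, noisy$labels)
  list(report = report, outcomes = outcomes, labels = noisy$labels,
       library = lib)
}
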