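# End-to-end pipeline: extract -> canonicalize -> filter -> curate -> report.

#' Pipeline configuration
#'
#' @param input path to a reactions file (text/CSV/TSV), or `NULL` when
#'   `reactions` are passed to [run_pipeline()] directly.
#' @param reaction_col,id_col column names for delimited input.
#' @param min_frequency template frequency threshold (templates at or below
#'   it are discarded).
#' @param enable_byproducts append electroneutral leaving-group by-products
#'   to curated reactions.
#' @param reinstate_spectators put removed spectator molecules back into the
#'   curated output.
#' @param valence_overrides named list merged over [default_valence_table()].
#' @param seed RNG seed (recorded for provenance; the pipeline itself is
#'   deterministic).
#' @return a `pipeline_config` list, serialized alongside every output.
#' @export
pipeline_config <- function(input = NULL, reaction_col = "reaction",
                            id_col = "id", min_frequency = 5L,
                            enable_byproducts = FALSE,
                            reinstate_spectators = TRUE,
                            valence_overrides = NULL, seed = 1L) {
  structure(list(input = input, reaction_col = reaction_col, id_col = id_col,
                 min_frequency = as.integer(min_frequency),
                 enable_byproducts = isTRUE(enable_byproducts),
                 reinstate_spectators = isTRUE(reinstate_spectators),
                 valence_overrides = valence_overrides,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the two-stage cleaning pipeline
#'
#' Stage one extracts generic templates from every parse-clean record,
#' merges isomorphic templates under minimum bond change, and removes rare
#' ones.  Stage two applies the library back to every record's products and
#' validates, repairs or removes the record.  Outputs (when `out_dir` is
#' given): `templates.jsonl`, `curated.csv`
#' (`id, original_reaction, curated_reaction, status, notes`),
#' `summary.json` and `config.json`.
#'
#' @param cfg a [pipeline_config()].
#' @param reactions optional list of pre-parsed `mapped_reaction` (bypasses
#'   `cfg$input`).
#' @param out_dir output directory, or `NULL` for in-memory results only.
#' @return (invisibly) a list with `summary`, `library`, `outcomes`,
#'   `curated` data frame.
#' @export
run_pipeline <- function(cfg = pipeline_config(), reactions = NULL,
                         out_dir = NULL) {
  if (is.null(reactions)) {
    if (is.null(cfg$input)) stop("either cfg$input or reactions must be given")
    tab <- read_reaction_file(cfg$input, reaction_col = cfg$reaction_col,
                              id_col = cfg$id_col)
    parsed <- parse_reaction_table(tab)
    reactions <- parsed$reactions
    dropped <- parsed$dropped
  } else {
    dropped <- data.frame(id = character(), reason = character())
  }
  if (!length(reactions)) stop("no parse-clean reactions in the input")
  originals <- stats::setNames(
    vapply(reactions, write_reaction, character(1)),
    vapply(reactions, function(r) r$id, character(1)))

  vt <- default_valence_table()
  if (!is.null(cfg$valence_overrides))
    vt[names(cfg$valence_overrides)] <- cfg$valence_overrides

  lib <- extract_template_library(reactions, min_frequency = cfg$min_frequency)
  if (!length(lib$templates))
    stop("template library is empty after frequency filtering; ",
         "every record would be removed (lower min_frequency?)")

  outcomes <- lapply(reactions, curate_reaction, lib = lib, vt = vt)

  rows <- lapply(outcomes, function(o) {
    cur_txt <- NA_character_
    if (o$status != "removed") {
      cur <- o$curated_reaction
      if (cfg$enable_byproducts) cur <- add_byproducts(cur)
      if (cfg$reinstate_spectators) cur <- reinstate_spectators(cur)
      cur_txt <- write_reaction(cur, with_spectators = !cfg$reinstate_spectators)
    }
    data.frame(id = o$id, original_reaction = unname(originals[o$id]),
               curated_reaction = cur_txt, status = o$status,
               notes = o$notes, stringsAsFactors = FALSE)
  })
  curated <- do.call(rbind, rows)

  status <- vapply(outcomes, function(o) o$status, character(1))
  summary <- list(
    n_reactions = length(reactions),
    n_dropped_unparsable = nrow(dropped),
    n_templates = length(lib$templates),
    validated = sum(status == "validated"),
    repaired = sum(status == "repaired"),
    removed = sum(status == "removed"),
    residual_proportion = 100 * mean(status != "removed"),
    repaired_missing_reactants = sum(vapply(outcomes, function(o)
      length(o$added_fragments) > 0, logical(1))),
    repaired_mappings = sum(vapply(outcomes, function(o)
      isTRUE(o$mapping_changed), logical(1))),
    removed_records = lapply(outcomes[status == "removed"], function(o)
      list(id = o$id, reason = o$notes)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_template_library(lib, file.path(out_dir, "templates.jsonl"))
    utils::write.csv(curated, file.path(out_dir, "curated.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  invisible(list(summary = summary, library = lib, outcomes = outcomes,
                 curated = curated))
}
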