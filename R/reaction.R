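# Atom-mapped reactions: parsing, normalization, spectator handling.

#' Parse an atom-mapped reaction SMILES record
#'
#' Accepts both the `reactants>agents>products` and `reactants>>products`
#' dialects.  Agent-field molecules are placed in the spectator list without
#' requiring atom maps.  Isotope labels are stripped on ingest (they do not
#' affect the chemical transformation) and explicit hydrogens are folded into
#' implicit counts.  Unmapped product atoms are permitted: they signal
#' missing reactant information that is handled downstream.
#'
#' @param record reaction SMILES text.
#' @param id opaque record identifier carried through curation.
#' @return an object of class `mapped_reaction` with fields `reactants`,
#'   `products`, `spectators` (lists of [molgraph()]) and `id`.
#' @export
parse_reaction <- function(record, id = NA_character_) {
  fields <- strsplit(record, ">", fixed = TRUE)[[1]]
  if (length(fields) == 2) fields <- c(fields, "")
  if (length(fields) != 3)
    stop_rxn_parse(id, "expected 2 or 3 '>'-delimited fields")
  parse_side <- function(txt) {
    if (!nzchar(txt)) return(list())
    parts <- strsplit(txt, ".", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    lapply(parts, function(p) {
      m <- tryCatch(parse_smiles(p), error = function(e)
        stop_rxn_parse(id, conditionMessage(e)))
      strip_isotopes(m)
    })
  }
  reactants <- parse_side(fields[1])
  spectators <- parse_side(fields[2])
  products <- parse_side(fields[3])
  if (!length(reactants) || !length(products))
    stop_rxn_parse(id, "reaction must have at least one reactant and one product")
  rxn <- structure(list(reactants = reactants, products = products,
                        spectators = spectators, id = id),
                   class = "mapped_reaction")
  for (side in c("reactants", "products")) {
    maps <- side_maps(rxn[[side]])
    if (anyDuplicated(maps))
      stop_rxn_parse(id, paste0("duplicate atom-map number on ", side, " side"))
  }
  rxn
}

stop_rxn_parse <- function(id, msg) {
  stop(structure(class = c("rxn_parse_error", "error", "condition"),
                 list(message = paste0("record ", id, ": ", msg),
                      call = NULL, id = id)))
}

side_maps <- function(mols) {
  m <- unlist(lapply(mols, function(x) x$atoms$map))
  m[!is.na(m)]
}

#' @export
print.mapped_reaction <- function(x, ...) {
  cat("<mapped_reaction ", x$id, "> ", write_reaction(x), "\n", sep = "")
  invisible(x)
}

#' Serialize a mapped reaction back to reaction SMILES
#'
#' @param rxn a `mapped_reaction`.
#' @param with_spectators place spectator molecules in the agent field.
#' @return reaction SMILES string.
#' @export
write_reaction <- function(rxn, with_spectators = TRUE) {
  side_txt <- function(mols) paste(sort(vapply(mols, write_smiles, character(1))),
                                   collapse = ".")
  paste0(side_txt(rxn$reactants), ">",
         if (with_spectators && length(rxn$spectators)) side_txt(rxn$spectators) else "",
         ">", side_txt(rxn$products))
}

#' Move spectator reactants aside
#'
#' A reactant molecule is a spectator when it contributes no mapped
#' non-hydrogen atom to any product.  Spectators are retained on the reaction
#' object so they can be reinstated after curation.
#'
#' @param rxn a `mapped_reaction` whose product atoms carry maps.
#' @return the reaction with spectators moved out of `reactants`.
#' @export
remove_spectators <- function(rxn) {
  pmaps <- side_maps(rxn$products)
  is_spec <- vapply(rxn$reactants, function(m) {
    heavy <- m$atoms$element != "H"
    maps <- m$atoms$map[heavy]
    !any(!is.na(maps) & maps %in% pmaps)
  }, logical(1))
  if (all(is_spec))
    stop(structure(class = c("rxn_empty_core", "error", "condition"),
                   list(message = paste0("record ", rxn$id,
                                         ": every reactant is a spectator"),
                        call = NULL, id = rxn$id)))
  rxn$spectators <- c(rxn$spectators, rxn$reactants[is_spec])
  rxn$reactants <- rxn$reactants[!is_spec]
  rxn
}

#' Reinstate previously removed spectators
#'
#' @param rxn a `mapped_reaction`.
#' @return the reaction with all spectator molecules back among the reactants.
#' @export
reinstate_spectators <- function(rxn) {
  rxn$reactants <- c(rxn$reactants, rxn$spectators)
  rxn$spectators <- list()
  rxn
}

# detectable data error: a product map referring to a different element than
# the same map on the reactant side
map_element_mismatch <- function(rxn) {
  rmap <- list()
  for (m in rxn$reactants) {
    ok <- !is.na(m$atoms$map)
    rmap[as.character(m$atoms$map[ok])] <- m$atoms$element[ok]
  }
  for (m in rxn$products) {
    ok <- !is.na(m$atoms$map)
    for (i in which(ok)) {
      key <- as.character(m$atoms$map[i])
      if (!is.null(rmap[[key]]) && rmap[[key]] != m$atoms$element[i])
        return(TRUE)
    }
  }
  FALSE
}

# ---- file I/O ---------------------------------------------------------------

#' Read reactions from a text/CSV/TSV file
#'
#' Plain-text files carry one reaction SMILES per line (ids are line numbers).
#' Delimited files must have a reaction column and, optionally, an id column.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"text"`, `"csv"` or `"tsv"`.
#' @param reaction_col,id_col column names for delimited input.
#' @return data frame with columns `id` and `reaction`.
#' @export
read_reaction_file <- function(path, format = c("auto", "text", "csv", "tsv"),
                               reaction_col = "reaction", id_col = "id") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "csv") "csv" else if (ext %in% c("tsv", "tab")) "tsv" else "text"
  }
  if (format == "text") {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    return(data.frame(id = as.character(seq_along(lines)), reaction = lines,
                      stringsAsFactors = FALSE))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (!reaction_col %in% names(df))
    stop("reaction column '", reaction_col, "' not found in ", path)
  id <- if (id_col %in% names(df)) as.character(df[[id_col]])
        else as.character(seq_len(nrow(df)))
  data.frame(id = id, reaction = df[[reaction_col]], stringsAsFactors = FALSE)
}

#' Parse a table of reaction records, dropping unparsable rows
#'
#' @param records data frame with `id` and `reaction` columns.
#' @param quiet suppress per-record messages for dropped rows.
#' @return list with `reactions` (list of `mapped_reaction`) and `dropped`
#'   (data frame of ids and reasons).
#' @export
parse_reaction_table <- function(records, quiet = TRUE) {
  out <- list(); drop_id <- character(); drop_why <- character()
  for (k in seq_len(nrow(records))) {
    r <- tryCatch(parse_reaction(records$reaction[k], records$id[k]),
                  error = function(e) e)
    if (inherits(r, "error")) {
      drop_id <- c(drop_id, records$id[k])
      drop_why <- c(drop_why, conditionMessage(r))
      if (!quiet) message("dropped ", records$id[k], ": ", conditionMessage(r))
    } else {
      out[[length(out) + 1L]] <- r
    }
  }
  list(reactions = out,
       dropped = data.frame(id = drop_id, reason = drop_why,
                            stringsAsFactors = FALSE))
}
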