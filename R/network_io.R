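#' Read a metabolic network from TSV tables
#'
#' The reaction table has columns `reaction_id`, `equation` (grammar
#' `"2 A + B -> C + 3 D"`, see [parse_equation()]), `reversible`,
#' `atp_category`, `scenario_tag`; the metabolite table has `id`, `name`,
#' `compartment`, `formula` (e.g. `"C6H12O6"`, empty allowed for exchange
#' pseudo-species) and `balanced`.
#'
#' @param reactions_path Path to the reaction TSV.
#' @param metabolites_path Path to the metabolite TSV.
#' @param po P/O ratio of the network.
#' @param substrate_uptake Id of the substrate-uptake reaction.
#' @return A [cs_network].
#' @seealso [write_network_tsv()], [read_network_json()]
#' @export
read_network_tsv <- function(reactions_path, metabolites_path, po = 1.0,
                             substrate_uptake = "GLT") {
  rx <- readr::read_tsv(reactions_path, show_col_types = FALSE,
                        progress = FALSE)
  mets <- readr::read_tsv(metabolites_path, show_col_types = FALSE,
                          progress = FALSE)
  need_rx <- c("reaction_id", "equation", "reversible", "atp_category",
               "scenario_tag")
  need_m <- c("id", "name", "compartment", "formula", "balanced")
  miss <- setdiff(need_rx, names(rx))
  if (length(miss) > 0) {
    abort(paste0("Reaction table is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "cs_schema_error")
  }
  miss <- setdiff(need_m, names(mets))
  if (length(miss) > 0) {
    abort(paste0("Metabolite table is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "cs_schema_error")
  }
  reactions <- bind_rows(lapply(seq_len(nrow(rx)), function(i) {
    reaction_row(rx$reaction_id[[i]], rx$equation[[i]],
                 reversible = isTRUE(as.logical(rx$reversible[[i]])),
                 atp_category = rx$atp_category[[i]] %|NA|% "none",
                 scenario_tag = rx$scenario_tag[[i]])
  }))
  mets$formula[is.na(mets$formula)] <- ""
  cs_network(mets[need_m], reactions, po = po,
             substrate_uptake = substrate_uptake)
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

#' Write a metabolic network to TSV tables
#'
#' @param network A [cs_network].
#' @param reactions_path,metabolites_path Output paths.
#' @return Invisibly, the network.
#' @export
write_network_tsv <- function(network, reactions_path, metabolites_path) {
  rx <- tibble::tibble(
    reaction_id = network$reactions$id,
    equation = vapply(network$reactions$stoich, format_equation,
                      character(1)),
    reversible = network$reactions$reversible,
    atp_category = network$reactions$atp_category,
    scenario_tag = network$reactions$scenario_tag)
  readr::write_tsv(rx, reactions_path, progress = FALSE)
  readr::write_tsv(network$metabolites[, c("id", "name", "compartment",
                                           "formula", "balanced")],
                   metabolites_path, progress = FALSE)
  invisible(network)
}

#' Read a metabolic network from a single JSON document
#'
#' JSON layout: an object with fields `po`, `substrate_uptake`,
#' `metabolites` (array of objects with the metabolite-table fields) and
#' `reactions` (array with the reaction-table fields).
#'
#' @param path Path to the JSON file.
#' @return A [cs_network].
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("metabolites", "reactions")
  miss <- setdiff(need, names(doc))
  if (length(miss) > 0) {
    abort(paste0("Network JSON is missing field(s): ",
                 paste(miss, collapse = ", ")), class = "cs_schema_error")
  }
  rx <- as_tibble(doc$reactions)
  reactions <- bind_rows(lapply(seq_len(nrow(rx)), function(i) {
    reaction_row(rx$reaction_id[[i]], rx$equation[[i]],
                 reversible = isTRUE(as.logical(rx$reversible[[i]])),
                 atp_category = rx$atp_category[[i]] %|NA|% "none",
                 scenario_tag = rx$scenario_tag[[i]])
  }))
  mets <- as_tibble(doc$metabolites)
  mets$formula[is.na(mets$formula)] <- ""
  cs_network(mets, reactions, po = doc$po %||% 1.0,
             substrate_uptake = doc$substrate_uptake %||% "GLT")
}

#' Write a metabolic network to a single JSON document
#'
#' @param network A [cs_network].
#' @param path Output path.
#' @return Invisibly, the network.
#' @export
write_network_json <- function(network, path) {
  doc <- list(
    po = network$po,
    substrate_uptake = network$substrate_uptake,
    metabolites = network$metabolites[, c("id", "name", "compartment",
                                          "formula", "balanced")],
    reactions = tibble::tibble(
      reaction_id = network$reactions$id,
      equation = vapply(network$reactions$stoich, format_equation,
                        character(1)),
      reversible = network$reactions$reversible,
      atp_category = network$reactions$atp_category,
      scenario_tag = network$reactions$scenario_tag))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(network)
}
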