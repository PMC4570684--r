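chemostat_columns <- function() {
  c(strain = "c", dilution_rate_1_per_h = "d", feed_glucose_g_per_l = "d",
    residual_glucose_mM = "d", biomass_gdw_per_l = "d",
    viability_fraction = "d", resveratrol_uM = "d", coumaric_uM = "d",
    phloretic_uM = "d", cinnamic_uM = "d", q_o2_mmol_gx_h = "d",
    q_co2_mmol_gx_h = "d")
}

#' Path to a bundled example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @examples
#' chemostoich_example()
#' @export
chemostoich_example <- function(file = NULL) {
  base <- system.file("extdata", package = "chemostoich")
  if (is.null(file)) return(dir(base))
  path <- file.path(base, file)
  if (!file.exists(path)) {
    abort(glue::glue("No bundled file '{file}'"), class = "cs_io_error")
  }
  path
}

#' Read steady-state chemostat records from CSV
#'
#' Expects a UTF-8, comma-separated file with decimal points and a header
#' carrying the mandatory columns `strain`, `dilution_rate_1_per_h`,
#' `feed_glucose_g_per_l`, `residual_glucose_mM`, `biomass_gdw_per_l`
#' plus the optional `viability_fraction`, the four product
#' concentrations (`resveratrol_uM`, `coumaric_uM`, `phloretic_uM`,
#' `cinnamic_uM`) and measured gas-exchange rates (`q_o2_mmol_gx_h`,
#' `q_co2_mmol_gx_h`); empty cells are missing values. Record invariants
#' (positive dilution rate and feed, viability in \[0, 1\], residual below
#' feed) are enforced on read.
#'
#' @param path CSV path.
#' @return A tibble of chemostat records.
#' @examples
#' read_chemostat_csv(chemostoich_example("table2_chemostats.csv"))
#' @export
read_chemostat_csv <- function(path) {
  cols <- chemostat_columns()
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  mandatory <- c("strain", "dilution_rate_1_per_h", "feed_glucose_g_per_l",
                 "residual_glucose_mM", "biomass_gdw_per_l")
  miss <- setdiff(mandatory, hdr)
  if (length(miss) > 0) {
    abort(paste0("Chemostat CSV is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")), class = "cs_schema_error")
  }
  spec <- do.call(readr::cols,
                  c(as.list(cols[intersect(names(cols), hdr)]),
                    list(.default = readr::col_guess())))
  recs <- readr::read_csv(path, col_types = spec, progress = FALSE)
  probs <- readr::problems(recs)
  if (nrow(probs) > 0) {
    abort(paste0("Non-numeric or malformed cell(s): ",
                 paste(sprintf("row %d, column %d (%s)", probs$row,
                               probs$col, probs$expected),
                       collapse = "; ")), class = "cs_parse_error")
  }
  if (nrow(recs) > 0) validate_records(recs)
  if (nrow(recs) > 0 && "residual_glucose_mM" %in% names(recs)) {
    mw <- cs_constants()$glucose_molar_mass
    over <- recs$residual_glucose_mM / 1000 * mw >= recs$feed_glucose_g_per_l
    if (any(over, na.rm = TRUE)) {
      abort("Residual glucose at or above the feed concentration",
            class = "cs_record_error")
    }
  }
  recs
}

#' Write chemostat records to CSV
#'
#' Inverse of [read_chemostat_csv()]; a well-formed file survives a
#' read-write round trip unchanged.
#'
#' @param records Records tibble.
#' @param path Output path.
#' @return Invisibly, the records.
#' @export
write_chemostat_csv <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(records)
}

#' Read and validate an analysis configuration
#'
#' YAML with the optional top-level keys `network` (a file path or
#' `"default"`), `network_metabolites`, `scenario` (e.g. `"nadp,nadp"`),
#' `po`, `products`, `product_max_yields`, `constants`, `simulate`
#' (`preset`, `seed` and parameter overrides) and `output_dir`. Unknown
#' keys are rejected by name.
#'
#' @param path YAML path.
#' @return A named list of class `cs_config`.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("network", "network_metabolites", "scenario", "po", "products",
             "product_max_yields", "constants", "simulate", "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration key(s): ",
                 paste(unknown, collapse = ", "),
                 "; known keys are: ", paste(known, collapse = ", ")),
          class = "cs_config_error")
  }
  if (!is.null(cfg$constants)) {
    cfg$constants <- do.call(cs_constants, cfg$constants)
  }
  structure(cfg, class = "cs_config")
}

report_payload <- function(x, ...) UseMethod("report_payload")

#' @export
report_payload.cs_yield <- function(x, ...) {
  list(
    type = "yield_result",
    product = x$product,
    scenario = list(ald_cofactor = toupper(x$scenario$ald),
                    gdh_cofactor = toupper(x$scenario$gdh)),
    po = x$po,
    yield = x$yield, yield_unit = "mol product (mol glucose)-1",
    glucose_per_product = x$glucose_per_product,
    glucose_per_product_unit = "mol glucose (mol product)-1",
    atp = list(glycolysis_slp = x$atp$glycolysis_slp,
               tca_slp = x$atp$tca_slp, oxphos = x$atp$oxphos,
               total = x$atp$total,
               unit = "mol ATP (mol product)-1"),
    overall_reaction = attr(x$overall, "equation"))
}

#' @export
report_payload.maintenance_fit <- function(x, ...) {
  list(
    type = "maintenance_fit",
    m_s = x$m_s, m_s_se = x$m_s_se, m_s_unit = "mmol glucose gX-1 h-1",
    y_xs_max = x$y_xs_max_g_g, y_xs_max_se = x$y_xs_max_se_g_g,
    y_xs_max_unit = "g biomass (g glucose)-1",
    n = nrow(x$data))
}

#' @export
report_payload.data.frame <- function(x, ...) {
  list(type = "table", n = nrow(x), records = x)
}

#' @export
report_payload.default <- function(x, ...) x

#' Write an analysis report as JSON
#'
#' Serialises any stage result (a yield result, a maintenance fit, a
#' rates table, or a plain list) to a JSON document with a stable key
#' order, explicit units in sibling keys, the package version and a hash
#' of the payload for provenance.
#'
#' @param results Result object or named list of result objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @seealso [read_report()]
#' @export
write_report <- function(results, path) {
  payload <- if (is.list(results) && is.null(attr(results, "class")) &&
                 !is.data.frame(results)) {
    lapply(results, report_payload)
  } else {
    report_payload(results)
  }
  doc <- list(
    package = "chemostoich",
    version = as.character(packageVersion("chemostoich")),
    content_hash = rlang::hash(payload),
    results = payload)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(glue::glue("Directory '{dir}' does not exist"),
          class = "cs_io_error")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Report path written by [write_report()].
#' @return The parsed document (a named list).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
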