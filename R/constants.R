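#' Physical and biological constants used throughout the package
#'
#' Central place for the unit-conversion constants of the physiology
#' pipeline. Each can be overridden per call where a function accepts a
#' `constants` argument.
#'
#' @details
#' * `glucose_molar_mass`: 180.16 g/mol.
#' * `gas_molar_volume`: 24.06 l/mol (20 degrees C, 1 atm), used by
#'   [gas_rates()].
#' * `biomass_formula`: the one-carbon ("Cmol") biomass unit CH1.8O0.5N0.2,
#'   a standard composition for glucose-grown yeast.
#' * `biomass_cmol_mass`: 26.4 g dry weight per Cmol (includes ash).
#' * `gamma_biomass`: degree of reduction of the Cmol unit
#'   (4 + 1.8 - 2*0.5 - 3*0.2 = 4.2 electrons).
#'
#' @param ... named overrides for individual constants.
#' @return A named list of constants.
#' @examples
#' cs_constants()
#' cs_constants(gas_molar_volume = 22.414)
#' @export
cs_constants <- function(...) {
  base <- list(
    glucose_molar_mass = 180.16,   # g/mol
    gas_molar_volume   = 24.06,    # l/mol at 20 C, 1 atm
    biomass_formula    = "CH1.8O0.5N0.2",
    biomass_cmol_mass  = 26.4,     # g dry weight per Cmol
    gamma_biomass      = 4.2,      # electrons per Cmol
    gamma_glucose      = 24        # electrons per mol glucose
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown) > 0) {
    abort(paste0("Unknown constant(s): ", paste(unknown, collapse = ", ")),
          class = "cs_config_error")
  }
  modifyList(base, dots)
}

# The four phenylpropanoid products tracked by the physiology pipeline.
# Degrees of reduction follow the C=4, H=1, O=-2, N=-3 convention.
#' Product catalogue of the extended pathway
#'
#' The four excreted phenylpropanoid products, their elemental formulas,
#' carbon counts, degrees of reduction and the ids they carry in the
#' built-in metabolic network.
#'
#' @return A tibble with one row per product.
#' @examples
#' cs_products()
#' @export
cs_products <- function() {
  tibble::tibble(
    product         = c("resveratrol", "coumaric", "phloretic", "cinnamic"),
    formula         = c("C14H12O3", "C9H8O3", "C9H10O3", "C9H8O2"),
    n_carbon        = c(14, 9, 9, 9),
    gamma           = c(62, 38, 40, 40),
    metabolite_ext  = c("resv.e", "cou.e", "phloret.e", "cinn.e"),
    export_reaction = c("SNQ2", "EX_COU", "EX_PHLOR", "EX_CINN"),
    conc_column     = c("resveratrol_uM", "coumaric_uM", "phloretic_uM",
                        "cinnamic_uM")
  )
}
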