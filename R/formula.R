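ELEMENTS <- c("C", "H", "O", "N")

#' Parse an elemental formula into C/H/O/N counts
#'
#' Formulas are restricted to the four elements balanced by the network
#' (carbon, hydrogen, oxygen, nitrogen); counts may be fractional, as in
#' the Cmol biomass unit `"CH1.8O0.5N0.2"`. An empty string parses to the
#' all-zero count vector (used for exchange pseudo-species).
#'
#' @param formula Character vector of formulas such as `"C6H12O6"`.
#' @return A numeric matrix with one row per formula and columns C, H, O, N.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula(c("CO2", "CH1.8O0.5N0.2"))
#' @export
parse_formula <- function(formula) {
  out <- matrix(0, nrow = length(formula), ncol = length(ELEMENTS),
                dimnames = list(formula, ELEMENTS))
  for (i in seq_along(formula)) {
    f <- formula[[i]]
    if (is.na(f) || !nzchar(f)) next
    m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f)[[1]]
    toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f))[[1]]
    if (sum(nchar(toks)) != nchar(f)) {
      abort(glue::glue("Cannot parse formula '{f}'"), class = "cs_formula_error")
    }
    for (tok in toks) {
      el <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
      n  <- sub("^[A-Z][a-z]?", "", tok)
      n  <- if (nzchar(n)) as.numeric(n) else 1
      if (!el %in% ELEMENTS) {
        abort(glue::glue("Element '{el}' in '{f}' is not tracked (only C, H, O, N)"),
              class = "cs_formula_error")
      }
      out[i, el] <- out[i, el] + n
    }
  }
  out
}

#' Degree of reduction of a compound
#'
#' Available electrons per mole under the convention C = 4, H = 1, O = -2,
#' N = -3 (nitrogen counted at the ammonia reference level). Glucose gives
#' 24, resveratrol 62, the Cmol biomass unit 4.2.
#'
#' @param formula Character vector of elemental formulas.
#' @return Numeric vector of electrons per mole.
#' @examples
#' degree_of_reduction("C6H12O6")   # 24
#' degree_of_reduction("C14H12O3")  # 62
#' @export
degree_of_reduction <- function(formula) {
  counts <- parse_formula(formula)
  unname(drop(counts %*% c(C = 4, H = 1, O = -2, N = -3)))
}
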