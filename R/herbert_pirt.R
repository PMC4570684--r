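#' Decompose substrate uptake over growth, maintenance and products
#'
#' Splits the biomass-specific substrate uptake rate according to the
#' Herbert-Pirt relation
#' `q_s = mu / Y_X/S^max + m_s + sum_i(q_p_i / Y_Pi/S^max)`:
#' the maintenance fraction is `m_s / |q_s|`, the product fraction is
#' `sum_i(q_p_i / Y_Pi/S^max) / |q_s|` with the maximum theoretical
#' product yields taken from the stoichiometric model, and growth is
#' assigned the remaining fraction, so the three fractions sum to one by
#' construction. When maintenance and product formation alone exceed the
#' measured uptake the row is flagged (`inconsistent = TRUE`, with a
#' warning) — a signal that rates and parameters do not belong together —
#' but fractions are still returned.
#'
#' @param rates Data frame of rate rows as returned by [specific_rates()]
#'   (needs `q_s_mmol_gx_h` and the per-product `q_*_mmol_gx_h` columns;
#'   missing product columns count as zero).
#' @param m_s Maintenance coefficient (mmol glucose/gX/h).
#' @param product_max_yields Named vector of maximum theoretical product
#'   yields (mol product / mol glucose) for `resveratrol`, `coumaric`,
#'   `phloretic`, `cinnamic`. Defaults to the yields of the built-in
#'   network under the NADP/NADP scenario.
#' @return The input tibble with `f_maintenance`, `f_product`, `f_growth`
#'   and `inconsistent` appended.
#' @examples
#' recs <- read_chemostat_csv(chemostoich_example("table2_chemostats.csv"))
#' herbert_pirt_split(specific_rates(recs), m_s = 0.12)[,
#'   c("strain", "f_maintenance", "f_product", "f_growth")]
#' @export
herbert_pirt_split <- function(rates, m_s,
                               product_max_yields = default_max_yields()) {
  rates <- as_tibble(rates)
  if (!"q_s_mmol_gx_h" %in% names(rates)) {
    abort("Rates table needs column q_s_mmol_gx_h (see specific_rates())",
          class = "cs_schema_error")
  }
  qs <- abs(rates$q_s_mmol_gx_h)
  if (any(qs <= 0, na.rm = TRUE)) {
    abort("Herbert-Pirt split needs |q_s| > 0", class = "cs_record_error")
  }
  prods <- cs_products()
  miss <- setdiff(prods$product, names(product_max_yields))
  if (length(miss) > 0) {
    abort(paste0("product_max_yields is missing: ",
                 paste(miss, collapse = ", ")), class = "cs_config_error")
  }
  product_term <- rep(0, nrow(rates))
  for (p in prods$product) {
    col <- paste0("q_", p, "_mmol_gx_h")
    if (col %in% names(rates)) {
      qp <- rates[[col]]
      qp[is.na(qp)] <- 0
      product_term <- product_term + qp / product_max_yields[[p]]
    }
  }
  f_maint <- m_s / qs
  f_prod <- product_term / qs
  inconsistent <- f_maint + f_prod > 1
  if (any(inconsistent, na.rm = TRUE)) {
    warn(paste0(sum(inconsistent, na.rm = TRUE),
                " record(s) have maintenance + product fractions above 1; ",
                "rates and parameters are mutually inconsistent"))
  }
  rates$f_maintenance <- f_maint
  rates$f_product <- f_prod
  rates$f_growth <- 1 - f_maint - f_prod
  rates$inconsistent <- inconsistent
  rates
}

#' Maximum theoretical product yields of the built-in network
#'
#' Computes (and caches for the session) the zero-growth maximum yields
#' of the four phenylpropanoid products on glucose from the built-in
#' stoichiometric model under a cofactor scenario.
#'
#' @param scenario Cofactor scenario, default `"nadp,nadp"` (the major
#'   isoenzymes of glucose-grown *S. cerevisiae* are NADP-dependent).
#' @param po P/O ratio.
#' @return Named numeric vector over the products of [cs_products()].
#' @examples
#' round(default_max_yields(), 3)  # 0.282, 0.522, 0.500, 0.545
#' @export
default_max_yields <- local({
  cache <- list()
  function(scenario = "nadp,nadp", po = 1.0) {
    key <- paste(format(po), paste(unlist(as_scenario(scenario)),
                                   collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    net <- build_default_network(po = po)
    prods <- cs_products()$product
    out <- vapply(prods, function(p) max_yield(net, scenario, p)$yield,
                  numeric(1))
    cache[[key]] <<- out
    out
  }
})

#' Stacked-fraction plot of the substrate distribution
#'
#' @param split Output of [herbert_pirt_split()] for records at several
#'   dilution rates.
#' @return A ggplot: stacked substrate fractions versus dilution rate.
#' @export
plot_herbert_pirt <- function(split) {
  long <- tidyr::pivot_longer(
    split[, c("dilution_rate_1_per_h", "f_maintenance", "f_product",
              "f_growth")],
    cols = c("f_maintenance", "f_product", "f_growth"),
    names_to = "term", values_to = "fraction")
  long$term <- factor(long$term,
                      levels = c("f_growth", "f_product", "f_maintenance"),
                      labels = c("growth", "product", "maintenance"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$dilution_rate_1_per_h),
                                     y = .data$fraction, fill = .data$term)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = expression(D ~ (h^-1)), y = "fraction of q_s",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
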