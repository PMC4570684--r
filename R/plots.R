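#' Plot the ATP breakdown of a yield result
#'
#' Bar chart of the ATP produced per mol product by source (glycolytic
#' SLP, TCA SLP, oxidative phosphorylation), which at zero growth must
#' total the pathway ATP demand.
#'
#' @param object A `cs_yield` from [max_yield()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cs_yield <- function(object, ...) {
  dat <- tibble::tibble(
    source = factor(c("glycolysis (SLP)", "TCA (SLP)", "oxphos"),
                    levels = c("glycolysis (SLP)", "TCA (SLP)", "oxphos")),
    atp = c(object$atp$glycolysis_slp, object$atp$tca_slp,
            object$atp$oxphos))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$source, y = .data$atp)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "mol ATP per mol product",
      title = sprintf("%s, ALD %s / GDH %s: Y = %.3f mol/mol, ATP total %g",
                      object$product, toupper(object$scenario$ald),
                      toupper(object$scenario$gdh), object$yield,
                      object$atp$total)) +
    ggplot2::theme_minimal()
}

#' Plot scenario yields side by side
#'
#' @param yields Output of [scenario_yields()].
#' @return A ggplot object.
#' @export
plot_scenario_yields <- function(yields) {
  yields$scenario <- paste0("ALD ", yields$ald_cofactor, "\nGDH ",
                            yields$gdh_cofactor)
  ggplot2::ggplot(yields,
                  ggplot2::aes(x = .data$scenario,
                               y = .data$yield_mol_mol)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL,
                  y = expression(Y[P/S]^max ~ (mol ~ mol^-1))) +
    ggplot2::theme_minimal()
}
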