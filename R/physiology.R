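validate_records <- function(records) {
  need <- c("strain", "dilution_rate_1_per_h", "feed_glucose_g_per_l",
            "residual_glucose_mM", "biomass_gdw_per_l")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("Chemostat records are missing column(s): ",
                 paste(miss, collapse = ", ")), class = "cs_schema_error")
  }
  with(records, {
    if (any(dilution_rate_1_per_h <= 0, na.rm = TRUE))
      abort("Dilution rate must be > 0", class = "cs_record_error")
    if (any(feed_glucose_g_per_l <= 0, na.rm = TRUE))
      abort("Feed glucose must be > 0", class = "cs_record_error")
    if ("viability_fraction" %in% names(records) &&
        any(viability_fraction < 0 | viability_fraction > 1, na.rm = TRUE))
      abort("Viability must lie in [0, 1]", class = "cs_record_error")
  })
  invisible(records)
}

#' Biomass-specific rates, yields and carbon recovery of chemostat records
#'
#' For each steady-state record, applies the standard chemostat balances:
#' glucose uptake `q_s = -D (S_in - C_s) / X` (stored negative, in
#' mmol glucose per g dry weight per h), product formation
#' `q_p = C_p D / X` for each of the four phenylpropanoid products and
#' their pool, yields `Y_X/S` (g/g) and `Y_P/S = q_p / |q_s|` (mol/mol),
#' the respiratory quotient `RQ = q_CO2 / |q_O2|` where off-gas rates are
#' present, and the carbon recovery
#' `(q_CO2 + biomass carbon + product carbon) / (6 |q_s|)` using the Cmol
#' biomass composition from [cs_constants()].
#'
#' @param records Data frame of chemostat records in the column layout of
#'   [read_chemostat_csv()].
#' @param constants Constants list from [cs_constants()].
#' @return The input tibble with rate, yield and recovery columns
#'   appended (`q_s_mmol_gx_h`, `q_<product>_mmol_gx_h`,
#'   `q_pooled_mmol_gx_h`, `y_xs_g_g`, `y_ps_<product>`, `y_ps_pooled`,
#'   `rq`, `carbon_recovery`).
#' @examples
#' recs <- read_chemostat_csv(chemostoich_example("table2_chemostats.csv"))
#' specific_rates(recs)[, c("strain", "q_s_mmol_gx_h", "y_ps_pooled")]
#' @export
specific_rates <- function(records, constants = cs_constants()) {
  records <- as_tibble(records)
  validate_records(records)
  if (any(records$biomass_gdw_per_l <= 0, na.rm = TRUE)) {
    abort("Biomass concentration must be > 0 to define specific rates",
          class = "cs_record_error")
  }
  prods <- cs_products()
  for (cc in prods$conc_column) {
    if (!cc %in% names(records)) records[[cc]] <- 0
  }
  mw <- constants$glucose_molar_mass

  D <- records$dilution_rate_1_per_h
  X <- records$biomass_gdw_per_l
  s_res_gl <- records$residual_glucose_mM / 1000 * mw
  if (any(s_res_gl >= records$feed_glucose_g_per_l, na.rm = TRUE)) {
    abort("Residual glucose exceeds feed concentration",
          class = "cs_record_error")
  }
  qs_g <- D * (records$feed_glucose_g_per_l - s_res_gl) / X   # g/gX/h
  qs <- -qs_g / mw * 1000                                     # mmol/gX/h

  out <- records
  out$q_s_mmol_gx_h <- qs
  q_p <- matrix(0, nrow = nrow(records), ncol = nrow(prods),
                dimnames = list(NULL, prods$product))
  for (i in seq_len(nrow(prods))) {
    conc_mM <- records[[prods$conc_column[i]]] / 1000
    conc_mM[is.na(conc_mM)] <- 0
    q_p[, i] <- conc_mM * D / X
    out[[paste0("q_", prods$product[i], "_mmol_gx_h")]] <- q_p[, i]
  }
  out$q_pooled_mmol_gx_h <- rowSums(q_p)

  out$y_xs_g_g <- X / (records$feed_glucose_g_per_l - s_res_gl)
  for (i in seq_len(nrow(prods))) {
    out[[paste0("y_ps_", prods$product[i])]] <- q_p[, i] / abs(qs)
  }
  out$y_ps_pooled <- out$q_pooled_mmol_gx_h / abs(qs)

  q_o2 <- if ("q_o2_mmol_gx_h" %in% names(records)) {
    records$q_o2_mmol_gx_h
  } else rep(NA_real_, nrow(records))
  q_co2 <- if ("q_co2_mmol_gx_h" %in% names(records)) {
    records$q_co2_mmol_gx_h
  } else rep(NA_real_, nrow(records))
  out$rq <- ifelse(!is.na(q_o2) & !is.na(q_co2) & abs(q_o2) > 0,
                   q_co2 / abs(q_o2), NA_real_)

  # carbon recovery: all terms in mmol carbon per gX per h
  c_biomass <- 1000 * D / constants$biomass_cmol_mass
  c_products <- drop(q_p %*% prods$n_carbon)
  out$carbon_recovery <- ifelse(
    is.na(q_co2), NA_real_,
    (q_co2 + c_biomass + c_products) / (6 * abs(qs)))
  out
}

#' Biomass-specific gas exchange rates from off-gas data
#'
#' Molar balances over the reactor head space: the outlet gas flow is
#' obtained from the inlet flow by an inert-gas correction
#' (`F_out = F_in (1 - x_CO2_in - x_O2_in) / (1 - x_CO2_out - x_O2_out)`),
#' and the transfer rates are normalised per gram of biomass.
#'
#' @param flow_l_min Inlet gas flow (l/min).
#' @param x_co2_in,x_o2_in Inlet mole fractions of CO2 and O2.
#' @param x_co2_out,x_o2_out Outlet mole fractions of CO2 and O2.
#' @param biomass_gdw_per_l Biomass concentration (g dry weight / l).
#' @param volume_l Broth volume (l).
#' @param constants Constants list (`gas_molar_volume` is used).
#' @return A one-row tibble `(q_o2_mmol_gx_h, q_co2_mmol_gx_h)`; oxygen
#'   uptake is negative by the sign convention of the rate tables.
#' @examples
#' gas_rates(0.5, 0.0004, 0.2095, 0.0004, 0.2095, 3.7, 1)  # zero exchange
#' @export
gas_rates <- function(flow_l_min, x_co2_in, x_o2_in, x_co2_out, x_o2_out,
                      biomass_gdw_per_l, volume_l,
                      constants = cs_constants()) {
  if (any(flow_l_min <= 0)) {
    abort("Gas flow must be > 0", class = "cs_record_error")
  }
  fracs <- c(x_co2_in, x_o2_in, x_co2_out, x_o2_out)
  if (any(fracs < 0 | fracs > 1)) {
    abort("Mole fractions must lie in [0, 1]", class = "cs_record_error")
  }
  if (any(x_co2_out + x_o2_out > 1) || any(x_co2_in + x_o2_in > 1)) {
    abort("CO2 and O2 mole fractions sum above 1", class = "cs_record_error")
  }
  f_in <- flow_l_min * 60 / constants$gas_molar_volume        # mol/h
  f_out <- f_in * (1 - x_co2_in - x_o2_in) / (1 - x_co2_out - x_o2_out)
  total_x <- biomass_gdw_per_l * volume_l                     # g biomass
  q_co2 <- (f_out * x_co2_out - f_in * x_co2_in) * 1000 / total_x
  q_o2 <- (f_out * x_o2_out - f_in * x_o2_in) * 1000 / total_x
  tibble::tibble(q_o2_mmol_gx_h = q_o2, q_co2_mmol_gx_h = q_co2)
}

#' Specific growth rate of the viable biomass fraction
#'
#' In a chemostat at steady state the viable cells must grow fast enough
#' to replace the washout of total biomass, so `mu = D / viability`. At a
#' dilution rate of 0.025 1/h and 76 % viability this gives ca. 0.03 1/h.
#'
#' @param D Dilution rate (1/h).
#' @param viability Viable fraction, in (0, 1].
#' @return Specific growth rate (1/h).
#' @examples
#' viable_growth_rate(0.025, 0.76)  # ~0.033
#' @export
viable_growth_rate <- function(D, viability) {
  if (any(viability <= 0) || any(viability > 1)) {
    abort("Viability must lie in (0, 1]", class = "cs_record_error")
  }
  D / viability
}

#' Assess the chemostat steady-state criterion
#'
#' A culture is considered at steady state when, after at least 6 volume
#' changes, both the dry weight and the specific CO2 production rate have
#' changed by less than 3 % over the last 2 consecutive volume changes.
#'
#' @param series Data frame with columns `volume_changes` (time expressed
#'   in reactor volume changes), `dry_weight_g_l` and `q_co2_mmol_gx_h`.
#' @param threshold Relative-change threshold, default 0.03.
#' @param min_volume_changes Volume changes required before the window,
#'   default 6.
#' @return A one-row tibble `(steady, drift_dry_weight, drift_q_co2)`.
#' @export
check_steady_state <- function(series, threshold = 0.03,
                               min_volume_changes = 6) {
  need <- c("volume_changes", "dry_weight_g_l", "q_co2_mmol_gx_h")
  miss <- setdiff(need, names(series))
  if (length(miss) > 0) {
    abort(paste0("Series is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "cs_schema_error")
  }
  t_end <- max(series$volume_changes)
  if (t_end < min_volume_changes + 2 ||
      min(series$volume_changes) > t_end - 2) {
    abort(paste0("Series must cover at least 2 volume changes beyond the ",
                 min_volume_changes, "th to assess steady state"),
          class = "cs_not_assessable_error")
  }
  drift <- function(y) {
    at <- function(t) approx(series$volume_changes, y, xout = t)$y
    y0 <- at(t_end - 2)
    abs(at(t_end) - y0) / abs(y0)
  }
  d_dw <- drift(series$dry_weight_g_l)
  d_co2 <- drift(series$q_co2_mmol_gx_h)
  tibble::tibble(steady = d_dw < threshold && d_co2 < threshold,
                 drift_dry_weight = d_dw, drift_q_co2 = d_co2)
}

#' Monod residual substrate concentration
#'
#' Solves the Monod relation `mu = mu_max C_s / (K_s + C_s)` for the
#' residual substrate concentration at a given specific growth rate:
#' `C_s = K_s mu / (mu_max - mu)`.
#'
#' @param mu Specific growth rate (1/h), must satisfy `0 <= mu < mu_max`.
#' @param mu_max Maximum specific growth rate (1/h).
#' @param ks Substrate saturation constant (mM).
#' @return Residual substrate concentration (mM).
#' @examples
#' monod_residual(0.15, 0.25, 0.247)  # ~0.37 mM
#' @export
monod_residual <- function(mu, mu_max, ks) {
  stopifnot(mu_max > 0, ks > 0)
  if (any(mu < 0) || any(mu >= mu_max)) {
    abort("Monod kinetics require 0 <= mu < mu_max",
          class = "cs_saturation_error")
  }
  ks * mu / (mu_max - mu)
}

#' Substrate saturation constant from one residual measurement
#'
#' Inverts the Monod relation: `K_s = C_s (mu_max - mu) / mu`.
#'
#' @param mu Specific growth rate (1/h), `0 < mu < mu_max`.
#' @param mu_max Maximum specific growth rate (1/h).
#' @param cs Residual substrate concentration (mM).
#' @return Saturation constant K_s (mM).
#' @examples
#' fit_ks(0.15, 0.25, 0.37)  # ~0.247 mM
#' @export
fit_ks <- function(mu, mu_max, cs) {
  stopifnot(mu_max > 0, all(cs >= 0))
  if (any(mu <= 0) || any(mu >= mu_max)) {
    abort("K_s is identified only for 0 < mu < mu_max",
          class = "cs_saturation_error")
  }
  cs * (mu_max - mu) / mu
}
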