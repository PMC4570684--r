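#' True parameters for the synthetic chemostat generator
#'
#' Bundles and validates the ground-truth parameters a synthetic
#' steady-state dataset is generated from: the maximum biomass yield and
#' maintenance coefficient of the linear rate relation, a linear
#' growth-rate dependence of pooled product formation
#' `q_pooled(mu) = qp_intercept + qp_slope * mu` split over the four
#' phenylpropanoid products by fixed composition fractions, Monod
#' residual-glucose kinetics, a piecewise-linear viability-versus-D
#' profile, feed concentration, the dilution-rate design, replicate
#' count and a multiplicative noise level per observable.
#'
#' @param y_xs_max_g_g Maximum biomass yield on glucose (g/g).
#' @param m_s Maintenance coefficient (mmol glucose/gX/h).
#' @param qp_intercept,qp_slope Linear pooled-product model
#'   (mmol/gX/h and mmol/gX, so `qp_slope * mu` is a rate).
#' @param product_fractions Named fractions over
#'   resveratrol/coumaric/phloretic/cinnamic; must sum to 1.
#' @param product_max_yields Named maximum theoretical product yields
#'   (mol/mol) used in the generating Herbert-Pirt relation; defaults to
#'   the built-in network's NADP/NADP yields.
#' @param s_in Feed glucose (g/l).
#' @param mu_max,ks Monod parameters (1/h, mM).
#' @param viability_breaks,viability_values Breakpoints of the
#'   piecewise-linear viability profile v(D); the default declines from
#'   0.76 at D = 0.025 to 1.0 at and above D = 0.075.
#' @param dilution_rates Dilution rates of the design (1/h).
#' @param replicates Independent cultures per dilution rate.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise; either a scalar for all observables or
#'   a named vector over `residual_glucose`, `biomass`, `resveratrol`,
#'   `coumaric`, `phloretic`, `cinnamic`, `q_o2`, `q_co2`.
#' @param viable_mu Use the viability-corrected growth rate `D / v(D)`
#'   instead of `mu = D` in the generating relations (off by default; the
#'   rate tables index everything by D).
#' @param strain Strain label written into the records.
#' @return A validated list of class `cs_parameters`.
#' @seealso [preset_reference()], [preset_producer()], [generate_dataset()]
#' @export
chemostat_parameters <- function(y_xs_max_g_g = 0.52,
                                 m_s = 0.10,
                                 qp_intercept = 0,
                                 qp_slope = 0,
                                 product_fractions = c(
                                   resveratrol = 0.659, coumaric = 0.130,
                                   phloretic = 0.181, cinnamic = 0.030),
                                 product_max_yields = default_max_yields(),
                                 s_in = 7.5,
                                 mu_max = 0.40,
                                 ks = 0.30,
                                 viability_breaks = c(0.025, 0.075),
                                 viability_values = c(0.76, 1.0),
                                 dilution_rates = c(0.025, 0.05, 0.10, 0.15),
                                 replicates = 2,
                                 noise_cv = 0.02,
                                 viable_mu = FALSE,
                                 strain = "synthetic") {
  stopifnot(y_xs_max_g_g > 0, m_s >= 0, s_in > 0, mu_max > 0, ks > 0,
            replicates >= 1, all(dilution_rates > 0), all(noise_cv >= 0))
  if (abs(sum(product_fractions) - 1) > 1e-9) {
    abort("product_fractions must sum to 1", class = "cs_config_error")
  }
  prods <- cs_products()$product
  if (!all(prods %in% names(product_fractions)) ||
      !all(prods %in% names(product_max_yields))) {
    abort("product_fractions and product_max_yields must cover all products",
          class = "cs_config_error")
  }
  if (any(dilution_rates >= mu_max)) {
    abort("All dilution rates must be below mu_max (washout otherwise)",
          class = "cs_infeasible_design_error")
  }
  structure(list(
    y_xs_max_g_g = y_xs_max_g_g, m_s = m_s,
    qp_intercept = qp_intercept, qp_slope = qp_slope,
    product_fractions = product_fractions[prods],
    product_max_yields = product_max_yields[prods],
    s_in = s_in, mu_max = mu_max, ks = ks,
    viability_breaks = viability_breaks,
    viability_values = viability_values,
    dilution_rates = dilution_rates, replicates = replicates,
    noise_cv = noise_cv, viable_mu = viable_mu, strain = strain),
    class = "cs_parameters")
}

#' Reference-strain generator preset
#'
#' Non-producing strain: maximum biomass yield 0.52 g/g, maintenance
#' coefficient 0.10 mmol/gX/h, no product formation, duplicate cultures
#' at D = 0.025, 0.05, 0.10 and 0.15 1/h, 2 % measurement noise.
#'
#' @param ... Overrides passed to [chemostat_parameters()].
#' @return A `cs_parameters` object.
#' @export
preset_reference <- function(...) {
  defaults <- list(
    y_xs_max_g_g = 0.52, m_s = 0.10, qp_intercept = 0, qp_slope = 0,
    mu_max = 0.40, ks = 0.30,
    dilution_rates = c(0.025, 0.05, 0.10, 0.15), replicates = 2,
    noise_cv = 0.02, strain = "reference")
  do.call(chemostat_parameters, modifyList(defaults, list(...)))
}

#' Producer-strain generator preset
#'
#' Resveratrol-producing strain: maintenance coefficient 0.12 mmol/gX/h,
#' pooled product formation proportional to growth rate and reaching
#' 0.024 mmol/gX/h at D = 0.15 1/h, product composition from the
#' steady-state effluent ratios, Monod parameters mu_max = 0.25 1/h and
#' K_s = 0.247 mM (residual glucose 0.37 mM at D = 0.15), viability
#' declining to 0.76 at D = 0.025.
#'
#' @param ... Overrides passed to [chemostat_parameters()].
#' @return A `cs_parameters` object.
#' @export
preset_producer <- function(...) {
  defaults <- list(
    y_xs_max_g_g = 0.52, m_s = 0.12,
    qp_intercept = 0, qp_slope = 0.16,
    mu_max = 0.25, ks = 0.247,
    dilution_rates = c(0.025, 0.05, 0.075, 0.10, 0.15), replicates = 2,
    noise_cv = 0.02, strain = "producer")
  do.call(chemostat_parameters, modifyList(defaults, list(...)))
}

viability_at <- function(params, D) {
  v <- approx(params$viability_breaks, params$viability_values, xout = D,
              rule = 2)$y
  pmin(pmax(v, 0), 1)
}

noise_cv_for <- function(params, observable) {
  cv <- params$noise_cv
  if (length(cv) == 1 && is.null(names(cv))) return(unname(cv))
  if (observable %in% names(cv)) return(unname(cv[[observable]]))
  0
}

# Mean-one multiplicative log-normal factors under a dedicated RNG
# substream, so adding an observable leaves the others untouched.
noise_factors <- function(n, cv, seed) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  withr_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(withr_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", withr_seed, envir = globalenv())
  })
  set.seed(seed)
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate a synthetic steady-state chemostat dataset
#'
#' For every dilution rate and replicate the generator evaluates the
#' ground truth exactly — `mu = D` (or the viability-corrected variant),
#' the linear pooled-product model, the Herbert-Pirt relation for
#' `q_s`, Monod kinetics for the residual glucose, the reactor glucose
#' balance for the biomass concentration, and carbon plus
#' degree-of-reduction closure for the gas exchange rates — and then
#' applies mean-one multiplicative log-normal noise per observable.
#' Noiseless datasets are exact fixed points of the physiology pipeline
#' (100 % carbon recovery, estimators return the true parameters).
#'
#' @param params A [chemostat_parameters()] object.
#' @param seed Integer seed; the same seed reproduces the dataset
#'   bit-identically. Each observable draws from its own substream.
#' @param constants Constants list from [cs_constants()].
#' @return A tibble of chemostat records in the column layout of
#'   [read_chemostat_csv()].
#' @examples
#' recs <- generate_dataset(preset_reference(), seed = 42)
#' fit_maintenance(specific_rates(recs))$m_s  # ~0.10
#' @export
generate_dataset <- function(params, seed = 1,
                             constants = cs_constants()) {
  stopifnot(inherits(params, "cs_parameters"))
  prods <- cs_products()
  mw <- constants$glucose_molar_mass

  design <- tidyr::expand_grid(D = params$dilution_rates,
                               replicate = seq_len(params$replicates))
  D <- design$D
  v <- viability_at(params, D)
  mu <- if (params$viable_mu) D / v else D

  q_pooled <- params$qp_intercept + params$qp_slope * mu
  if (any(q_pooled < 0)) {
    abort("Pooled product model yields negative rates",
          class = "cs_infeasible_design_error")
  }
  q_p <- outer(q_pooled, params$product_fractions)  # n x 4, mmol/gX/h
  colnames(q_p) <- prods$product

  growth_term <- 1000 * mu / (mw * params$y_xs_max_g_g)
  product_term <- drop(q_p %*% (1 / params$product_max_yields))
  q_s <- growth_term + params$m_s + product_term     # mmol/gX/h, magnitude
  if (any(q_s <= params$m_s & mu > 0)) {
    abort("Design gives q_s <= m_s: no substrate left for growth",
          class = "cs_infeasible_design_error")
  }

  c_s <- monod_residual(mu, params$mu_max, params$ks)  # mM
  c_s_gl <- c_s / 1000 * mw
  if (any(c_s_gl >= params$s_in)) {
    abort("Residual glucose reaches the feed concentration",
          class = "cs_infeasible_design_error")
  }
  X <- D * (params$s_in - c_s_gl) / (q_s * mw / 1000)  # gX/l

  # close carbon and degree-of-reduction balances exactly (before noise)
  c_biomass <- 1000 * mu / constants$biomass_cmol_mass       # mmol C/gX/h
  q_co2 <- 6 * q_s - c_biomass - drop(q_p %*% prods$n_carbon)
  electrons <- constants$gamma_glucose * q_s -
    constants$gamma_biomass * 1000 * mu / constants$biomass_cmol_mass -
    drop(q_p %*% prods$gamma)
  q_o2 <- -electrons / 4

  conc_uM <- sweep(q_p, 1, X / D, `*`) * 1000  # mmol/gX/h -> uM in effluent

  seed_base <- as.integer(seed)
  sub <- function(k) (seed_base * 131L + k * 7919L) %% .Machine$integer.max
  n <- nrow(design)
  noisy <- function(x, observable, k) {
    x * noise_factors(n, noise_cv_for(params, observable), sub(k))
  }

  tibble::tibble(
    strain = params$strain,
    dilution_rate_1_per_h = D,
    replicate = design$replicate,
    feed_glucose_g_per_l = params$s_in,
    residual_glucose_mM = noisy(c_s, "residual_glucose", 1L),
    biomass_gdw_per_l = noisy(X, "biomass", 2L),
    viability_fraction = v,
    resveratrol_uM = noisy(conc_uM[, "resveratrol"], "resveratrol", 3L),
    coumaric_uM = noisy(conc_uM[, "coumaric"], "coumaric", 4L),
    phloretic_uM = noisy(conc_uM[, "phloretic"], "phloretic", 5L),
    cinnamic_uM = noisy(conc_uM[, "cinnamic"], "cinnamic", 6L),
    q_o2_mmol_gx_h = noisy(q_o2, "q_o2", 7L),
    q_co2_mmol_gx_h = noisy(q_co2, "q_co2", 8L))
}
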