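#' Estimate the maintenance coefficient by ordinary least squares
#'
#' Fits the linear rate relation `q_s = mu / Y_X/S^max + m_s` to a table
#' of steady-state points: the intercept is the maintenance coefficient
#' `m_s` (mmol glucose per g dry weight per h) and the slope is the
#' inverse maximum biomass yield `1 / Y_X/S^max` (here in
#' mmol glucose per g biomass, converted to the g/g yield via the glucose
#' molar mass). Standard errors come from the usual OLS formulas. The
#' regression is unweighted by default; `weights` passes through to
#' [stats::lm()] for a weighted variant.
#'
#' @param points Data frame with columns `mu` (specific growth rate, 1/h)
#'   and `q_s` (glucose uptake, mmol/gX/h; magnitudes are used, so the
#'   negative stored convention is accepted). The output of
#'   [specific_rates()] is accepted directly (`dilution_rate_1_per_h` and
#'   `q_s_mmol_gx_h` are picked up).
#' @param weights Optional regression weights.
#' @param constants Constants list from [cs_constants()].
#' @return An object of class `maintenance_fit` with elements `m_s`,
#'   `m_s_se`, `y_xs_max_g_g`, `y_xs_max_se_g_g`, `slope`, `slope_se`,
#'   the underlying `lm` fit and the data used.
#' @examples
#' pts <- tibble::tibble(mu = c(0.025, 0.05, 0.10, 0.15),
#'                       q_s = 0.10 + mu * 1000 / (180.16 * 0.52))
#' fit <- fit_maintenance(pts)
#' fit$m_s            # 0.10, exact at zero noise
#' fit$y_xs_max_g_g   # 0.52
#' @export
fit_maintenance <- function(points, weights = NULL,
                            constants = cs_constants()) {
  points <- as_tibble(points)
  if (!"mu" %in% names(points) && "dilution_rate_1_per_h" %in% names(points)) {
    points$mu <- points$dilution_rate_1_per_h
  }
  if (!"q_s" %in% names(points) && "q_s_mmol_gx_h" %in% names(points)) {
    points$q_s <- points$q_s_mmol_gx_h
  }
  miss <- setdiff(c("mu", "q_s"), names(points))
  if (length(miss) > 0) {
    abort(paste0("Maintenance fit needs column(s): ",
                 paste(miss, collapse = ", ")), class = "cs_schema_error")
  }
  dat <- tibble::tibble(mu = points$mu, q_s = abs(points$q_s))
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < 3 || length(unique(dat$mu)) < 2) {
    abort("Maintenance regression needs >= 3 points with >= 2 distinct mu",
          class = "cs_degenerate_design_error")
  }
  fit <- if (is.null(weights)) {
    lm(q_s ~ mu, data = dat)
  } else {
    lm(q_s ~ mu, data = dat, weights = weights)
  }
  co <- summary(fit)$coefficients
  m_s <- co["(Intercept)", "Estimate"]
  m_s_se <- co["(Intercept)", "Std. Error"]
  slope <- co["mu", "Estimate"]
  slope_se <- co["mu", "Std. Error"]
  mw <- constants$glucose_molar_mass
  # slope [mmol glucose / g biomass] -> Y_X/S^max [g biomass / g glucose]
  y_max <- 1000 / (slope * mw)
  y_max_se <- y_max * slope_se / slope  # first-order (delta method)
  structure(list(
    m_s = m_s, m_s_se = m_s_se,
    slope = slope, slope_se = slope_se,
    y_xs_max_g_g = y_max, y_xs_max_se_g_g = y_max_se,
    fit = fit, data = dat, constants = constants),
    class = "maintenance_fit")
}

#' @export
print.maintenance_fit <- function(x, ...) {
  cat("<maintenance_fit>\n")
  cat(sprintf("  m_s        = %.4f +/- %.4f mmol gX^-1 h^-1\n",
              x$m_s, x$m_s_se))
  cat(sprintf("  Y_X/S^max  = %.4f +/- %.4f g g^-1\n",
              x$y_xs_max_g_g, x$y_xs_max_se_g_g))
  cat(sprintf("  n = %d points, residual sd = %.4g\n",
              nrow(x$data), summary(x$fit)$sigma))
  invisible(x)
}

#' @describeIn fit_maintenance Parameter table (term, estimate, std.error).
#' @param x A `maintenance_fit`.
#' @param ... Unused.
#' @export
tidy.maintenance_fit <- function(x, ...) {
  tibble::tibble(
    term = c("m_s", "inv_y_xs_max", "y_xs_max_g_g"),
    estimate = c(x$m_s, x$slope, x$y_xs_max_g_g),
    std.error = c(x$m_s_se, x$slope_se, x$y_xs_max_se_g_g),
    unit = c("mmol gX-1 h-1", "mmol glucose (g biomass)-1", "g g-1"))
}

#' @describeIn fit_maintenance One-row model summary (r.squared, sigma, n).
#' @export
glance.maintenance_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 nobs = nrow(x$data))
}

#' @describeIn fit_maintenance Data with fitted values and residuals.
#' @export
augment.maintenance_fit <- function(x, ...) {
  dat <- x$data
  dat$.fitted <- stats::fitted(x$fit)
  dat$.resid <- stats::residuals(x$fit)
  dat
}

#' @describeIn fit_maintenance Plot the rate relation and fitted line.
#' @param object A `maintenance_fit`.
#' @export
autoplot.maintenance_fit <- function(object, ...) {
  dat <- augment(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mu, y = .data$q_s)) +
    ggplot2::geom_abline(intercept = object$m_s, slope = object$slope,
                         colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(mu ~ (h^-1)),
      y = expression(q[s] ~ (mmol ~ gX^-1 ~ h^-1)),
      title = sprintf("m_s = %.3f ± %.3f mmol gX^-1 h^-1",
                      object$m_s, object$m_s_se)) +
    ggplot2::theme_minimal()
}

#' Convert a glucose maintenance coefficient to ATP equivalents
#'
#' `m_ATP = m_s x (ATP yield of fully respiratory glucose dissimilation)`.
#' The ATP yield should come from the stoichiometric network via
#' [atp_per_glucose()] (16 mol ATP per mol glucose at P/O 1.0), so that
#' e.g. `m_s = 0.12` translates to 1.92 mmol ATP per g dry weight per h.
#'
#' @param m_s Maintenance coefficient (mmol glucose/gX/h).
#' @param atp_per_glc mol ATP per mol glucose fully respired.
#' @return m_ATP (mmol ATP/gX/h).
#' @examples
#' maintenance_atp(0.12, atp_per_glucose(1.0))  # 1.92
#' @export
maintenance_atp <- function(m_s, atp_per_glc) {
  stopifnot(all(m_s >= 0), all(atp_per_glc >= 0))
  m_s * atp_per_glc
}
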