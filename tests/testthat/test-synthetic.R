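test_that("noiseless datasets are exact fixed points of the pipeline", {
  recs <- generate_dataset(preset_reference(noise_cv = 0), seed = 1)
  rt <- specific_rates(recs)
  expect_equal(rt$carbon_recovery, rep(1, nrow(rt)), tolerance = 1e-12)
  expect_true(all(rt$rq > 0.95 & rt$rq < 1.1))
  fit <- suppressWarnings(fit_maintenance(rt))
  expect_equal(fit$m_s, 0.10, tolerance = 1e-10)
  expect_equal(fit$y_xs_max_g_g, 0.52, tolerance = 1e-10)
  # the generating Herbert-Pirt relation is recovered term by term
  hp <- herbert_pirt_split(rt, m_s = 0.10)
  expect_equal(hp$f_maintenance + hp$f_product + hp$f_growth,
               rep(1, nrow(hp)))
})

test_that("noiseless producer records satisfy their generating relations", {
  params <- preset_producer(noise_cv = 0)
  recs <- generate_dataset(params, seed = 1)
  rt <- specific_rates(recs)
  expect_equal(rt$carbon_recovery, rep(1, nrow(rt)), tolerance = 1e-12)
  # pooled productivity follows the linear model exactly
  expect_equal(rt$q_pooled_mmol_gx_h,
               params$qp_slope * rt$dilution_rate_1_per_h,
               tolerance = 1e-9)
  # residual glucose follows Monod exactly
  expect_equal(rt$residual_glucose_mM,
               monod_residual(rt$dilution_rate_1_per_h, params$mu_max,
                              params$ks),
               tolerance = 1e-12)
})

test_that("generation is deterministic per seed and seed-sensitive", {
  a <- generate_dataset(preset_reference(), seed = 42)
  b <- generate_dataset(preset_reference(), seed = 42)
  expect_identical(a, b)
  c <- generate_dataset(preset_reference(), seed = 43)
  expect_false(identical(a, c))
})

test_that("observable noise streams are independent", {
  # silencing one observable's noise must not perturb the others
  noisy <- generate_dataset(preset_reference(), seed = 9)
  partial <- generate_dataset(
    preset_reference(noise_cv = c(residual_glucose = 0, biomass = 0.02,
                                  resveratrol = 0, coumaric = 0,
                                  phloretic = 0, cinnamic = 0,
                                  q_o2 = 0.02, q_co2 = 0.02)),
    seed = 9)
  expect_identical(noisy$biomass_gdw_per_l, partial$biomass_gdw_per_l)
  expect_identical(noisy$q_co2_mmol_gx_h, partial$q_co2_mmol_gx_h)
  expect_false(identical(noisy$residual_glucose_mM,
                         partial$residual_glucose_mM))
})

test_that("infeasible designs are refused", {
  # washout: dilution rate at mu_max
  expect_error(preset_producer(dilution_rates = c(0.1, 0.25)),
               class = "cs_infeasible_design_error")
  # negative product rates
  expect_error(
    generate_dataset(preset_producer(qp_intercept = -1), seed = 1),
    class = "cs_infeasible_design_error")
  # malformed composition
  expect_error(
    chemostat_parameters(product_fractions = c(
      resveratrol = 0.9, coumaric = 0.3, phloretic = 0, cinnamic = 0)),
    class = "cs_config_error")
})

test_that("the producer preset reproduces the observed productivity pattern", {
  rp <- specific_rates(generate_dataset(preset_producer(), seed = 11))
  top <- rp$q_pooled_mmol_gx_h[rp$dilution_rate_1_per_h == 0.15]
  expect_equal(mean(top), 0.024, tolerance = 0.15)
  r2 <- summary(lm(q_pooled_mmol_gx_h ~ dilution_rate_1_per_h,
                   data = rp))$r.squared
  expect_gt(r2, 0.9)
})

test_that("viability declines at low dilution rates per the default profile", {
  recs <- generate_dataset(preset_producer(noise_cv = 0), seed = 1)
  v <- setNames(recs$viability_fraction, recs$dilution_rate_1_per_h)
  expect_equal(unname(v[names(v) == "0.025"]), rep(0.76, 2))
  expect_equal(unname(v[as.numeric(names(v)) >= 0.075]),
               rep(1, sum(as.numeric(names(v)) >= 0.075)))
})

test_that("maintenance estimates are unbiased at the design noise level", {
  ms <- vapply(1:60, function(s) {
    fit_maintenance(specific_rates(
      generate_dataset(preset_reference(), seed = s)))$m_s
  }, numeric(1))
  expect_lt(abs(mean(ms) - 0.10), 0.005)
})
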