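test_that("specific rates recompute the steady-state producer record", {
  recs <- read_chemostat_csv(table2_path)
  rt <- specific_rates(recs)
  fs <- rt[rt$strain == "FS09322", ]
  expect_equal(round(fs$y_ps_pooled, 3), 0.016)
  expect_equal(round(fs$q_pooled_mmol_gx_h, 2), 0.02)
  expect_lt(fs$q_s_mmol_gx_h, 0)  # uptake stored negative
  expect_equal(round(fs$y_xs_g_g, 2), 0.44)
  # respiratory quotient near one for fully respiratory metabolism
  expect_true(all(rt$rq > 0.95 & rt$rq < 1.1))
  # both strains recover >95 % of substrate carbon
  expect_true(all(rt$carbon_recovery > 0.95))
})

test_that("zero product concentrations give zero pooled rate and yield", {
  recs <- read_chemostat_csv(table2_path)
  ref <- specific_rates(recs[recs$strain == "CEN.PK113-7D", ])
  expect_equal(ref$q_pooled_mmol_gx_h, 0)
  expect_equal(ref$y_ps_pooled, 0)
})

test_that("zero biomass is an undefined-rate error", {
  recs <- read_chemostat_csv(table2_path)
  recs$biomass_gdw_per_l[1] <- 0
  expect_error(specific_rates(recs), class = "cs_record_error")
})

test_that("gas rates invert the reactor molar balance (round trip)", {
  co <- cs_constants()
  X <- 3.738; V <- 1; flow <- 0.5
  x_co2_in <- 0.0004; x_o2_in <- 0.2095
  q_co2_true <- 2.65; q_o2_true <- -2.61
  f_in <- flow * 60 / co$gas_molar_volume
  f_out <- f_in + (q_co2_true + q_o2_true) * X * V / 1000
  x_co2_out <- (f_in * x_co2_in + q_co2_true * X * V / 1000) / f_out
  x_o2_out <- (f_in * x_o2_in + q_o2_true * X * V / 1000) / f_out
  got <- gas_rates(flow, x_co2_in, x_o2_in, x_co2_out, x_o2_out, X, V)
  expect_equal(got$q_co2_mmol_gx_h, q_co2_true, tolerance = 1e-9)
  expect_equal(got$q_o2_mmol_gx_h, q_o2_true, tolerance = 1e-9)
  # identical inlet and outlet composition: no exchange
  zero <- gas_rates(flow, x_co2_in, x_o2_in, x_co2_in, x_o2_in, X, V)
  expect_equal(unlist(zero), c(q_o2_mmol_gx_h = 0, q_co2_mmol_gx_h = 0))
  # doubling the biomass halves the specific rates
  half <- gas_rates(flow, x_co2_in, x_o2_in, x_co2_out, x_o2_out, 2 * X, V)
  expect_equal(half$q_co2_mmol_gx_h, q_co2_true / 2, tolerance = 1e-9)
  expect_error(gas_rates(flow, 0.6, 0.5, 0.2, 0.2, X, V),
               class = "cs_record_error")
})

test_that("the viability correction rescales the growth rate", {
  expect_equal(round(viable_growth_rate(0.025, 0.76), 2), 0.03)
  expect_equal(viable_growth_rate(0.10, 1.0), 0.10)
  v <- seq(0.5, 1, by = 0.1)
  expect_true(all(diff(viable_growth_rate(0.05, v)) < 0))
  expect_error(viable_growth_rate(0.1, 0), class = "cs_record_error")
})

test_that("steady-state criterion follows the two-volume-change window", {
  flat <- tibble::tibble(volume_changes = 0:10, dry_weight_g_l = 3.7,
                         q_co2_mmol_gx_h = 2.65)
  expect_true(check_steady_state(flat)$steady)
  # 5 % drift per volume change: 10 % over the window
  drifting <- tibble::tibble(volume_changes = 0:10,
                             dry_weight_g_l = 3.7 * (1.05^(0:10)),
                             q_co2_mmol_gx_h = 2.65)
  expect_false(check_steady_state(drifting)$steady)
  # 2.9 % total change over the last two volume changes is still steady
  near <- tibble::tibble(volume_changes = c(0, 8, 10),
                         dry_weight_g_l = c(3.7, 3.7, 3.7 * 1.029),
                         q_co2_mmol_gx_h = 2.65)
  res <- check_steady_state(near)
  expect_true(res$steady)
  expect_equal(res$drift_dry_weight, 0.029, tolerance = 1e-9)
  # too short a span cannot be assessed
  short <- tibble::tibble(volume_changes = 0:5, dry_weight_g_l = 3.7,
                          q_co2_mmol_gx_h = 2.65)
  expect_error(check_steady_state(short),
               class = "cs_not_assessable_error")
})

test_that("Monod kinetics invert cleanly and behave monotonically", {
  expect_equal(fit_ks(0.15, 0.25, 0.37), 0.2467, tolerance = 1e-3)
  expect_equal(monod_residual(0, 0.25, 0.5), 0)
  # round trip
  ks <- fit_ks(0.15, 0.25, 0.37)
  expect_equal(monod_residual(0.15, 0.25, ks), 0.37, tolerance = 1e-12)
  # residual strictly increasing in mu
  mus <- seq(0, 0.24, by = 0.02)
  expect_true(all(diff(monod_residual(mus, 0.25, 0.2)) > 0))
  # lower mu_max at equal D and K_s -> strictly higher residual glucose
  expect_gt(monod_residual(0.10, 0.25, 0.2),
            monod_residual(0.10, 0.40, 0.2))
  expect_error(monod_residual(0.3, 0.25, 0.2),
               class = "cs_saturation_error")
  expect_error(fit_ks(0.25, 0.25, 0.37), class = "cs_saturation_error")
})
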