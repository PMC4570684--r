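test_that("fractions sum to one by construction", {
  rp <- specific_rates(generate_dataset(preset_producer(), seed = 3))
  hp <- herbert_pirt_split(rp, m_s = 0.12)
  expect_equal(hp$f_maintenance + hp$f_product + hp$f_growth,
               rep(1, nrow(hp)), tolerance = 1e-12)
  expect_true(all(hp$f_maintenance >= 0 & hp$f_product >= 0 &
                    hp$f_growth >= 0))
})

test_that("a non-producing strain puts everything into growth + maintenance", {
  rt <- specific_rates(generate_dataset(preset_reference(noise_cv = 0),
                                        seed = 1))
  hp <- herbert_pirt_split(rt, m_s = 0.10)
  expect_equal(hp$f_product, rep(0, nrow(hp)))
  expect_equal(hp$f_growth, 1 - 0.10 / abs(rt$q_s_mmol_gx_h),
               tolerance = 1e-12)
})

test_that("maintenance equal to uptake is the (1, 0, 0) boundary", {
  rates <- tibble::tibble(q_s_mmol_gx_h = -0.4)
  hp <- herbert_pirt_split(rates, m_s = 0.4)
  expect_equal(c(hp$f_maintenance, hp$f_product, hp$f_growth), c(1, 0, 0))
  expect_false(hp$inconsistent)
})

test_that("over-committed records are flagged, not dropped", {
  rates <- tibble::tibble(q_s_mmol_gx_h = -0.3)
  expect_warning(hp <- herbert_pirt_split(rates, m_s = 0.4),
                 regexp = "inconsistent")
  expect_true(hp$inconsistent)
  expect_lt(hp$f_growth, 0)
})

test_that("the producer record's product fraction sits at ~5 %", {
  # printed producer rates with the model's own maximum yields
  recs <- read_chemostat_csv(table2_path)
  rt <- specific_rates(recs[recs$strain == "FS09322", ])
  # use the printed q_s magnitude (1.22) for the denominator convention
  rt$q_s_mmol_gx_h <- -1.22
  hp <- herbert_pirt_split(rt, m_s = 0.12)
  expect_gt(hp$f_product, 0.04)
  expect_lt(hp$f_product, 0.055)
})

test_that("maintenance fraction rises monotonically as D falls", {
  rp <- specific_rates(generate_dataset(preset_producer(noise_cv = 0),
                                        seed = 1))
  hp <- herbert_pirt_split(rp, m_s = 0.12)
  means <- tapply(hp$f_maintenance, hp$dilution_rate_1_per_h, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) < 0))
})

test_that("the built-in maximum yields match the stoichiometric model", {
  ys <- default_max_yields()
  expect_equal(round(unname(ys), 3),
               c(0.282, 0.522, 0.500, 0.545))
})

test_that("the stacked fraction plot builds", {
  rp <- specific_rates(generate_dataset(preset_producer(), seed = 5))
  hp <- herbert_pirt_split(rp, m_s = 0.12)
  expect_s3_class(plot_herbert_pirt(hp), "ggplot")
})
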