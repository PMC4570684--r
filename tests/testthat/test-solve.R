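test_that("the NADP/NADP zero-growth solution matches the hand-derived optimum", {
  sol <- solve_min_substrate(net_nadp_nadp, "resveratrol")
  expect_equal(sol$glucose_per_product, 85 / 24, tolerance = 1e-9)
  # the NADPH books close without the oxidative PPP or the oxidase
  expect_equal(unname(sol$fluxes["ZWF"]), 0, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["NPOX"]), 0, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["ATPM"]), 0, tolerance = 1e-9)
  # steady state on every balanced metabolite
  S <- stoich_matrix(net_nadp_nadp)
  bal <- net_nadp_nadp$metabolites$balanced
  expect_true(all(abs(S[bal, ] %*% sol$fluxes[colnames(S)]) < 1e-9))
})

test_that("NADPH demand falls on the oxidative PPP when ALD supplies NADH", {
  sol <- solve_min_substrate(net_nad_nadp, "resveratrol")
  # 3 NADPH demanded, none from ALD: 1.5 G6P through the oxidative branch
  expect_equal(unname(sol$fluxes["ZWF"]), 1.5, tolerance = 1e-9)
})

test_that("surplus NADPH in the NADP-ALD/NAD-GDH scenario exits via the oxidase", {
  sol <- solve_min_substrate(net_nadp_nad, "resveratrol")
  expect_equal(unname(sol$fluxes["NPOX"]), 1, tolerance = 1e-9)
})

test_that("a zero basis flux yields the all-zero distribution", {
  sol <- solve_min_substrate(net_nadp_nadp, "resveratrol", basis_flux = 0)
  expect_true(all(abs(sol$fluxes) < 1e-9))
  expect_equal(sol$objective, 0, tolerance = 1e-12)
})

test_that("fluxes scale linearly with the basis and the yield is invariant", {
  one <- solve_min_substrate(net_nadp_nadp, "resveratrol", basis_flux = 1)
  two <- solve_min_substrate(net_nadp_nadp, "resveratrol", basis_flux = 2)
  expect_equal(two$fluxes, 2 * one$fluxes, tolerance = 1e-8)
  expect_equal(two$glucose_per_product, one$glucose_per_product,
               tolerance = 1e-9)
})

test_that("deleting the stilbene synthase makes resveratrol export infeasible", {
  net <- net_nadp_nadp
  net$reactions <- net$reactions[net$reactions$id != "STS", ]
  expect_error(solve_min_substrate(net, "resveratrol"),
               class = "cs_infeasible_error")
})

test_that("solving an unscenarioed network is refused", {
  expect_error(solve_min_substrate(default_net, "resveratrol"),
               class = "cs_config_error")
})

test_that("the reported vector carries no futile two-way flux", {
  for (net in list(net_nadp_nadp, net_nad_nad)) {
    sol <- solve_min_substrate(net, "resveratrol")
    # L1 minimization: a reversible reaction never runs in both
    # directions, so |flux| is the whole story per reaction
    expect_true(all(abs(sol$fluxes) < 20))  # bounded, no runaway cycle
    expect_equal(unname(sol$fluxes[sol$export_reaction]), 1,
                 tolerance = 1e-9)
  }
})

test_that("ATP breakdowns reproduce the four cofactor scenarios", {
  expected <- list(
    list(net = net_nadp_nad, atp = c(2.875, 0.875, 9.25)),
    list(net = net_nadp_nadp, atp = c(2.750, 0.750, 9.50)),
    list(net = net_nad_nad, atp = c(2.500, 0.500, 10.00)),
    list(net = net_nad_nadp, atp = c(2.375, 0.375, 10.25)))
  for (case in expected) {
    sol <- solve_min_substrate(case$net, "resveratrol")
    bd <- atp_breakdown(case$net, sol)
    expect_equal(c(bd$glycolysis_slp, bd$tca_slp, bd$oxphos), case$atp,
                 tolerance = 1e-9)
    expect_equal(bd$total, 13, tolerance = 1e-9)
    expect_equal(bd$total, bd$glycolysis_slp + bd$tca_slp + bd$oxphos)
  }
})

test_that("a zero flux vector has an all-zero ATP breakdown", {
  zero <- setNames(rep(0, nrow(net_nadp_nadp$reactions)),
                   net_nadp_nadp$reactions$id)
  bd <- atp_breakdown(net_nadp_nadp, zero)
  expect_equal(as.numeric(bd[1, ]), c(0, 0, 0, 0))
})

test_that("foreign reaction names in a flux vector raise an accounting error", {
  expect_error(atp_breakdown(net_nadp_nadp, c(NOT_A_REACTION = 1)),
               class = "cs_accounting_error")
})

test_that("overall reactions close element and electron balances", {
  for (net in list(net_nadp_nadp, net_nad_nadp, net_nad_nad, net_nadp_nad)) {
    sol <- solve_min_substrate(net, "resveratrol")
    ov <- overall_reaction(net, sol)
    expect_true(all(abs(attr(ov, "element_residual")) < 1e-9))
    expect_lt(abs(attr(ov, "electron_residual")), 1e-7)
    # nitrogen cycles internally: PAL ammonia is re-assimilated by GDH
    expect_equal(ov$coefficient[ov$species == "nh3"], 0, tolerance = 1e-9)
    # degree-of-reduction identity: 24 glc = 62 + 4 O2
    glc <- ov$coefficient[ov$species == "glucose"]
    o2 <- ov$coefficient[ov$species == "o2"]
    expect_equal(24 * glc, 62 + 4 * o2, tolerance = 1e-7)
  }
})

test_that("the NADP/NADP overall reaction matches the printed equation", {
  ov <- overall_reaction(net_nadp_nadp,
                         solve_min_substrate(net_nadp_nadp, "resveratrol"))
  co <- setNames(ov$coefficient, ov$species)
  expect_equal(unname(round(co[c("glucose", "o2", "product", "co2", "h2o")],
                            2)),
               c(3.54, 5.75, 1, 7.25, 15.25))
})

test_that("the NAD-ALD/NADP-GDH overall reaction matches the hand balance", {
  ov <- overall_reaction(net_nad_nadp,
                         solve_min_substrate(net_nad_nadp, "resveratrol"))
  co <- setNames(ov$coefficient, ov$species)
  expect_equal(unname(co[c("glucose", "o2", "co2", "h2o")]),
               c(3.604167, 6.125, 7.625, 15.625), tolerance = 1e-6)
})

test_that("scenario yields are ordered and confined to the narrow band", {
  ys <- scenario_yields(default_net, "resveratrol")
  y <- function(a, g) ys$yield_mol_mol[ys$ald_cofactor == a &
                                         ys$gdh_cofactor == g]
  expect_gte(y("NADP", "NADP"), y("NAD", "NAD"))
  expect_gte(y("NAD", "NAD"), y("NAD", "NADP"))
  expect_true(all(ys$yield_mol_mol > 0.27 & ys$yield_mol_mol < 0.29))
  expect_equal(round(y("NADP", "NADP"), 3), 0.282)
  expect_equal(round(y("NAD", "NAD"), 3), 0.279)
  expect_equal(round(y("NAD", "NADP"), 3), 0.277)
})

test_that("pathway intermediates reach their hand-derived maximum yields", {
  # cinnamate: 11 carbons per product at zero combustion -> 6/11
  expect_equal(max_yield(default_net, "nadp,nadp", "cinnamic")$yield,
               6 / 11, tolerance = 1e-9)
  # phloretate: one extra NADPH -> 2 glucose per product
  expect_equal(max_yield(default_net, "nadp,nadp", "phloretic")$yield,
               0.5, tolerance = 1e-9)
  # coumarate: 23/2 carbons -> 12/23
  expect_equal(max_yield(default_net, "nadp,nadp", "coumaric")$yield,
               12 / 23, tolerance = 1e-9)
})

test_that("ATP demand is 13 with export, 12 without, and scenario-independent", {
  for (net in list(net_nadp_nadp, net_nad_nad, net_nadp_nad)) {
    expect_equal(atp_demand(net, "resveratrol"), 13, tolerance = 1e-9)
  }
  expect_equal(atp_demand(net_nadp_nadp, "resveratrol",
                          include_export = FALSE), 12, tolerance = 1e-9)
  # cinnamate costs only the shikimate kinase ATP
  expect_equal(atp_demand(net_nadp_nadp, "cinnamic"), 1, tolerance = 1e-9)
})

test_that("complete combustion yields 4 + 12 P/O ATP per glucose", {
  expect_equal(atp_per_glucose(1.0), 16, tolerance = 1e-8)
  expect_equal(atp_per_glucose(0), 4, tolerance = 1e-8)
  expect_equal(atp_per_glucose(1.5), 22, tolerance = 1e-8)
})

test_that("yield results tidy into the scenario table layout", {
  td <- tidy(max_yield(default_net, "nadp,nadp", "resveratrol"))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_equal(td$atp_total, 13, tolerance = 1e-9)
  expect_equal(round(td$yield_mol_mol, 3), 0.282)
})
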