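test_that("equation grammar parses coefficients, sides and arrows", {
  s <- parse_equation("2 A + B -> C + 3 D")
  expect_equal(s[c("A", "B", "C", "D")], c(A = -2, B = -1, C = 1, D = 3))
  expect_equal(parse_equation("fbp <-> dhap + g3p"),
               c(fbp = -1, dhap = 1, g3p = 1))
  # netting of species on both sides
  expect_equal(parse_equation("a + b -> a + c"), c(b = -1, c = 1))
  expect_error(parse_equation("a + b"), class = "cs_parse_error")
  # round trip through the formatter
  for (eq in c("glc.c + atp -> g6p + adp",
               "accoa.m + 3 nad.m + fad + gdp + 3 h2o.c -> coa.m + 3 nadh.m + fadh2 + gtp + 2 co2.c",
               "nadh + 0.5 o2.c + adp -> nad + h2o.c + atp")) {
    expect_equal(parse_equation(format_equation(parse_equation(eq))),
                 parse_equation(eq))
  }
})

test_that("the default network is element-balanced", {
  report <- validate_element_balance(default_net)
  expect_true(attr(report, "valid"))
  expect_true(all(report$checked))
  expect_true(all(abs(as.matrix(report[, c("C", "H", "O", "N")])) < 1e-12))
})

test_that("a corrupted stoichiometry is flagged with the element residual", {
  net <- default_net
  i <- which(net$reactions$id == "STS")
  # STS releasing 3 CO2 instead of 4 leaves one carbon unaccounted
  net$reactions$stoich[[i]]["co2.c"] <- 3
  report <- validate_element_balance(net)
  expect_false(attr(report, "valid"))
  expect_equal(report$C[report$reaction_id == "STS"], -1)
  expect_true(all(abs(report$C[report$reaction_id != "STS"]) < 1e-12))
})

test_that("an empty network validates trivially", {
  empty <- cs_network(
    tibble::tibble(id = character(), name = character(),
                   compartment = character(), formula = character(),
                   balanced = logical()),
    tibble::tibble(id = character(), stoich = list(), reversible = logical(),
                   atp_category = character(), scenario_tag = character(),
                   active = logical()))
  report <- validate_element_balance(empty)
  expect_equal(nrow(report), 0)
  expect_true(attr(report, "valid"))
})

test_that("unknown metabolite references name the offending reaction", {
  mets <- default_net$metabolites
  rxns <- dplyr::bind_rows(default_net$reactions,
                           chemostoich:::reaction_row("BAD", "glc.c -> nope"))
  expect_error(cs_network(mets, rxns, po = 1),
               regexp = "nope.*BAD", class = "cs_validation_error")
})

test_that("scenario application keeps exactly one variant of each enzyme", {
  act <- function(net) net$reactions$id[net$reactions$active]
  expect_true(all(c("ALD6", "GDH13") %in% act(net_nadp_nadp)))
  expect_false(any(c("ALD23", "GDH2") %in% act(net_nadp_nadp)))
  expect_true(all(c("ALD23", "GDH2") %in% act(net_nad_nad)))
  expect_false(any(c("ALD6", "GDH13") %in% act(net_nad_nad)))
  # idempotence
  twice <- apply_scenario(net_nadp_nadp, cofactor_scenario("nadp", "nadp"))
  expect_identical(twice$reactions$active, net_nadp_nadp$reactions$active)
  # all non-tagged reactions untouched
  tags <- default_net$reactions$scenario_tag
  expect_true(all(net_nad_nadp$reactions$active[is.na(tags)]))
})

test_that("a network missing a tagged variant is a configuration error", {
  net <- default_net
  net$reactions <- net$reactions[net$reactions$id != "GDH2", ]
  expect_error(apply_scenario(net, cofactor_scenario("nadp", "nadp")),
               class = "cs_config_error")
})

test_that("string scenarios are accepted", {
  a <- apply_scenario(default_net, "nad,nadp")
  expect_identical(a$reactions$active, net_nad_nadp$reactions$active)
})
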