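# Shared fixtures: networks are cheap to build but the LP solves dominate,
# so scenario-applied networks are constructed once per test run.
default_net <- build_default_network()

net_nadp_nadp <- apply_scenario(default_net, cofactor_scenario("nadp", "nadp"))
net_nad_nadp <- apply_scenario(default_net, cofactor_scenario("nad", "nadp"))
net_nad_nad <- apply_scenario(default_net, cofactor_scenario("nad", "nad"))
net_nadp_nad <- apply_scenario(default_net, cofactor_scenario("nadp", "nad"))

table2_path <- chemostoich_example("table2_chemostats.csv")

# tiny valid network: one substrate, one product, one conversion
toy_network <- function() {
  mets <- tibble::tibble(
    id = c("a.e", "a.c", "b.e"),
    name = c("A (ext)", "A", "B (ext)"),
    compartment = c("extracellular", "cytosol", "extracellular"),
    formula = c("C2H4O2", "C2H4O2", "C2H4O2"),
    balanced = c(FALSE, TRUE, FALSE))
  rxns <- dplyr::bind_rows(
    chemostoich:::reaction_row("GLT", "a.e -> a.c"),
    chemostoich:::reaction_row("CONV", "a.c -> b.e"))
  cs_network(mets, rxns)
}
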