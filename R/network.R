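#' Construct a metabolic network
#'
#' A network couples a metabolite table to a reaction table. Metabolites
#' carry elemental formulas (C/H/O/N, phosphate groups and protons are not
#' tracked; see the package vignette for the bookkeeping conventions) and a
#' `balanced` flag: balanced species must be at steady state when fluxes
#' are solved, unbalanced species are freely exchanged sinks/sources
#' (extracellular glucose, O2, CO2, H2O, NH3 and the excreted products).
#'
#' @param metabolites Tibble with columns `id`, `name`, `compartment`
#'   (`"cytosol"`, `"mitochondrion"` or `"extracellular"`), `formula`,
#'   `balanced` (logical).
#' @param reactions Tibble with columns `id`, `stoich` (list column of
#'   named numeric vectors, negative = consumed), `reversible` (logical),
#'   `atp_category` (one of `"glycolysis_slp"`, `"tca_slp"`, `"oxphos"`,
#'   `"atp_demand"`, `"none"`), `scenario_tag` (`NA` or one of
#'   `"ald_nadp"`, `"ald_nad"`, `"gdh_nadp"`, `"gdh_nad"`), `active`
#'   (logical).
#' @param po P/O ratio: mol ATP formed per electron pair transferred to
#'   oxygen by the respiratory chain. Default 1.0, the in vivo value for
#'   glucose-grown *S. cerevisiae*.
#' @param substrate_uptake Id of the substrate-uptake reaction minimized
#'   by [solve_min_substrate()].
#' @return An object of class `cs_network`.
#' @seealso [build_default_network()], [validate_element_balance()]
#' @export
cs_network <- function(metabolites, reactions, po = 1.0,
                       substrate_uptake = "GLT") {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  if (anyDuplicated(metabolites$id)) {
    abort("Duplicate metabolite ids", class = "cs_network_error")
  }
  if (anyDuplicated(reactions$id)) {
    abort("Duplicate reaction ids", class = "cs_network_error")
  }
  bad <- setdiff(metabolites$compartment,
                 c("cytosol", "mitochondrion", "extracellular"))
  if (length(bad) > 0) {
    abort(paste0("Unknown compartment(s): ", paste(bad, collapse = ", ")),
          class = "cs_network_error")
  }
  cats <- c("glycolysis_slp", "tca_slp", "oxphos", "atp_demand", "none")
  bad <- setdiff(reactions$atp_category, cats)
  if (length(bad) > 0) {
    abort(paste0("Unknown atp_category: ", paste(bad, collapse = ", ")),
          class = "cs_network_error")
  }
  if (!"active" %in% names(reactions)) reactions$active <- TRUE
  # every referenced metabolite must exist
  refs <- unique(unlist(lapply(reactions$stoich, names)))
  missing <- setdiff(refs, metabolites$id)
  if (length(missing) > 0) {
    offenders <- reactions$id[vapply(reactions$stoich, function(s) {
      any(names(s) %in% missing)
    }, logical(1))]
    abort(glue::glue(
      "Unknown metabolite id(s) {paste(missing, collapse = ', ')} ",
      "in reaction(s) {paste(offenders, collapse = ', ')}"),
      class = "cs_validation_error")
  }
  structure(
    list(metabolites = metabolites, reactions = reactions, po = po,
         substrate_uptake = substrate_uptake),
    class = "cs_network")
}

#' @export
print.cs_network <- function(x, ...) {
  act <- sum(x$reactions$active)
  cat(glue::glue(
    "<cs_network> {nrow(x$metabolites)} metabolites, ",
    "{nrow(x$reactions)} reactions ({act} active), P/O = {x$po}"), "\n")
  invisible(x)
}

#' Parse a reaction equation string
#'
#' Grammar: `"2 A + B -> C + 3 D"`. Metabolite ids are whitespace-free
#' tokens, optionally preceded by a numeric coefficient; `"<->"` is
#' accepted as an alternative arrow (reversibility itself is a separate
#' field). Species appearing on both sides are netted.
#'
#' @param equation Character scalar.
#' @return Named numeric vector of signed coefficients (negative =
#'   consumed).
#' @examples
#' parse_equation("glc.c + atp -> g6p + adp")
#' parse_equation("fbp <-> dhap + g3p")
#' @export
parse_equation <- function(equation) {
  sides <- strsplit(equation, "<->|->", fixed = FALSE)[[1]]
  if (length(sides) != 2) {
    abort(glue::glue("Equation '{equation}' must contain exactly one arrow"),
          class = "cs_parse_error")
  }
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (term in terms) {
      toks <- strsplit(term, "\\s+")[[1]]
      if (length(toks) == 1) {
        coef <- 1; id <- toks[[1]]
      } else if (length(toks) == 2 &&
                 grepl("^[0-9.]+(/[0-9.]+)?$", toks[[1]])) {
        coef <- if (grepl("/", toks[[1]])) {
          parts <- as.numeric(strsplit(toks[[1]], "/")[[1]])
          parts[[1]] / parts[[2]]
        } else as.numeric(toks[[1]])
        id <- toks[[2]]
      } else {
        abort(glue::glue("Cannot parse term '{term}' in '{equation}'"),
              class = "cs_parse_error")
      }
      prev <- if (id %in% names(out)) out[[id]] else 0
      out[id] <- prev + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[[1]], -1)
  rhs <- parse_side(sides[[2]], +1)
  all_ids <- union(names(lhs), names(rhs))
  v <- setNames(numeric(length(all_ids)), all_ids)
  v[names(lhs)] <- v[names(lhs)] + lhs
  v[names(rhs)] <- v[names(rhs)] + rhs
  v[abs(v) > 0]
}

#' Render a stoichiometry vector back into an equation string
#'
#' Inverse of [parse_equation()] up to term order and coefficient
#' formatting.
#'
#' @param stoich Named numeric vector of signed coefficients.
#' @param arrow Arrow token to use.
#' @return Character scalar.
#' @export
format_equation <- function(stoich, arrow = "->") {
  fmt <- function(ids, coefs) {
    if (length(ids) == 0) return("")
    paste(ifelse(abs(coefs - 1) < 1e-12, ids,
                 paste(format(coefs, trim = TRUE, digits = 10), ids)),
          collapse = " + ")
  }
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(fmt(names(lhs), -unname(lhs)), arrow, fmt(names(rhs), unname(rhs)))
}

reaction_row <- function(id, equation, reversible = FALSE,
                         atp_category = "none", scenario_tag = NA_character_) {
  tibble::tibble(
    id = id,
    stoich = list(parse_equation(equation)),
    reversible = reversible,
    atp_category = atp_category,
    scenario_tag = scenario_tag,
    active = TRUE)
}

#' Build the curated default metabolic network
#'
#' Constructs the compartmented stoichiometric model of *S. cerevisiae*
#' central carbon metabolism extended with the heterologous resveratrol
#' pathway: glycolysis (with a lumped GAPDH-PGK-PGM-ENO step), oxidative
#' and non-oxidative pentose phosphate pathway, the pyruvate
#' decarboxylase / acetaldehyde dehydrogenase / acetyl-CoA synthetase
#' route to cytosolic acetyl-CoA, acetyl-CoA carboxylase, mitochondrial
#' pyruvate dehydrogenase and a lumped TCA cycle, respiration of NADH and
#' FADH2 at the configured P/O ratio, a non-phosphorylating NADPH oxidase,
#' a lumped shikimate pathway to chorismate, chorismate mutase / prephenate
#' dehydratase, aromatic aminotransferase with glutamate-dehydrogenase
#' ammonium assimilation (NADPH- and NADH-dependent variants), PAL2, C4H
#' (an O2- and NADPH-dependent monooxygenase), 4CL (AMP-forming, counted
#' as 2 ATP), STS (releasing 4 CO2 per stilbene), ATP-dependent
#' resveratrol export (Snq2) and passive export of coumaric, cinnamic and
#' phloretic acid.
#'
#' Both acetaldehyde-dehydrogenase cofactor variants (Ald6-type NADP,
#' Ald2/3-type NAD) and both glutamate-dehydrogenase variants (Gdh1/3-type
#' NADP, Gdh2-type NAD) are present and scenario-tagged; use
#' [apply_scenario()] to activate exactly one of each before solving.
#'
#' Bookkeeping conventions (see the methods vignette): phosphate groups
#' and protons are untracked, NAD(P)H carries two more hydrogens than
#' NAD(P), AMP-forming activations transfer 2 ATP equivalents, and water
#' is explicit so every reaction over balanced metabolites conserves
#' C, H, O and N exactly.
#'
#' @param po P/O ratio (mol ATP per electron pair), default 1.0.
#' @param phloretic_cofactor Cofactor of the (enzymatically uncharacterised)
#'   coumarate reduction to phloretic acid: `"nadph"` (default) or
#'   `"nadh"`.
#' @return A [cs_network] passing [validate_element_balance()].
#' @examples
#' net <- build_default_network()
#' net
#' @export
build_default_network <- function(po = 1.0,
                                  phloretic_cofactor = c("nadph", "nadh")) {
  phloretic_cofactor <- match.arg(phloretic_cofactor)
  m <- function(id, name, compartment, formula, balanced = TRUE) {
    tibble::tibble(id = id, name = name, compartment = compartment,
                   formula = formula, balanced = balanced)
  }
  metabolites <- bind_rows(
    # extracellular exchange species (freely exchanged, unbalanced)
    m("glc.e", "glucose (extracellular)", "extracellular", "C6H12O6", FALSE),
    m("o2.e", "oxygen (extracellular)", "extracellular", "O2", FALSE),
    m("co2.e", "carbon dioxide (extracellular)", "extracellular", "CO2", FALSE),
    m("h2o.e", "water (extracellular)", "extracellular", "H2O", FALSE),
    m("nh3.e", "ammonia (extracellular)", "extracellular", "NH3", FALSE),
    m("resv.e", "resveratrol (extracellular)", "extracellular", "C14H12O3", FALSE),
    m("cou.e", "coumaric acid (extracellular)", "extracellular", "C9H8O3", FALSE),
    m("cinn.e", "cinnamic acid (extracellular)", "extracellular", "C9H8O2", FALSE),
    m("phloret.e", "phloretic acid (extracellular)", "extracellular", "C9H10O3", FALSE),
    # cytosol: sugars and glycolysis (phosphate groups untracked)
    m("glc.c", "glucose", "cytosol", "C6H12O6"),
    m("g6p", "glucose 6-phosphate", "cytosol", "C6H12O6"),
    m("f6p", "fructose 6-phosphate", "cytosol", "C6H12O6"),
    m("fbp", "fructose 1,6-bisphosphate", "cytosol", "C6H12O6"),
    m("dhap", "dihydroxyacetone phosphate", "cytosol", "C3H6O3"),
    m("g3p", "glyceraldehyde 3-phosphate", "cytosol", "C3H6O3"),
    m("pep", "phosphoenolpyruvate", "cytosol", "C3H4O3"),
    m("pyr.c", "pyruvate", "cytosol", "C3H4O3"),
    # pentose phosphate pathway
    m("ru5p", "ribulose 5-phosphate", "cytosol", "C5H10O5"),
    m("x5p", "xylulose 5-phosphate", "cytosol", "C5H10O5"),
    m("r5p", "ribose 5-phosphate", "cytosol", "C5H10O5"),
    m("s7p", "sedoheptulose 7-phosphate", "cytosol", "C7H14O7"),
    m("e4p", "erythrose 4-phosphate", "cytosol", "C4H8O4"),
    # acetyl-CoA route (CoA sulfur untracked)
    m("acald", "acetaldehyde", "cytosol", "C2H4O"),
    m("ace", "acetate", "cytosol", "C2H4O2"),
    m("coa.c", "coenzyme A", "cytosol", "C21H36N7O16"),
    m("accoa.c", "acetyl-CoA", "cytosol", "C23H38N7O17"),
    m("malcoa", "malonyl-CoA", "cytosol", "C24H38N7O19"),
    # aromatic amino acid route
    m("chor", "chorismate", "cytosol", "C10H10O6"),
    m("phepyr", "phenylpyruvate", "cytosol", "C9H8O3"),
    m("glu", "glutamate", "cytosol", "C5H9NO4"),
    m("akg", "2-oxoglutarate", "cytosol", "C5H6O5"),
    m("phe", "phenylalanine", "cytosol", "C9H11NO2"),
    # phenylpropanoid pathway
    m("cinn.c", "cinnamic acid", "cytosol", "C9H8O2"),
    m("cou.c", "coumaric acid", "cytosol", "C9H8O3"),
    m("coucoa", "coumaroyl-CoA", "cytosol", "C30H42N7O18"),
    m("resv.c", "resveratrol", "cytosol", "C14H12O3"),
    m("phloret.c", "phloretic acid", "cytosol", "C9H10O3"),
    # small molecules shared across compartments (free diffusion assumed)
    m("co2.c", "carbon dioxide", "cytosol", "CO2"),
    m("o2.c", "oxygen", "cytosol", "O2"),
    m("h2o.c", "water", "cytosol", "H2O"),
    m("nh3.c", "ammonia", "cytosol", "NH3"),
    # cofactors: ATP/ADP share a formula (phosphoryl transfer untracked),
    # reduced nicotinamide/flavin carriers carry +H2
    m("atp", "ATP", "cytosol", "C10H15N5O10"),
    m("adp", "ADP", "cytosol", "C10H15N5O10"),
    m("nad", "NAD+", "cytosol", "C21H27N7O14"),
    m("nadh", "NADH", "cytosol", "C21H29N7O14"),
    m("nadp", "NADP+", "cytosol", "C21H27N7O14"),
    m("nadph", "NADPH", "cytosol", "C21H29N7O14"),
    # mitochondrion
    m("pyr.m", "pyruvate (mitochondrial)", "mitochondrion", "C3H4O3"),
    m("coa.m", "coenzyme A (mitochondrial)", "mitochondrion", "C21H36N7O16"),
    m("accoa.m", "acetyl-CoA (mitochondrial)", "mitochondrion", "C23H38N7O17"),
    m("nad.m", "NAD+ (mitochondrial)", "mitochondrion", "C21H27N7O14"),
    m("nadh.m", "NADH (mitochondrial)", "mitochondrion", "C21H29N7O14"),
    m("fad", "FAD", "mitochondrion", "C27H33N9O15"),
    m("fadh2", "FADH2", "mitochondrion", "C27H35N9O15"),
    m("gdp", "GDP", "mitochondrion", "C10H15N5O11"),
    m("gtp", "GTP", "mitochondrion", "C10H15N5O11")
  )

  r <- reaction_row
  reactions <- bind_rows(
    # transport / exchange
    r("GLT", "glc.e -> glc.c"),
    r("O2T", "o2.e -> o2.c"),
    r("CO2T", "co2.c -> co2.e"),
    r("H2OT", "h2o.c -> h2o.e", reversible = TRUE),
    r("NH3T", "nh3.e -> nh3.c", reversible = TRUE),
    # glycolysis; net substrate-level ATP of the pathway is the sum over
    # this category (kinase investments count negatively)
    r("HK", "glc.c + atp -> g6p + adp", atp_category = "glycolysis_slp"),
    r("PGI", "g6p -> f6p", reversible = TRUE),
    r("PFK", "f6p + atp -> fbp + adp", atp_category = "glycolysis_slp"),
    r("FBA", "fbp -> dhap + g3p", reversible = TRUE),
    r("TPI", "dhap -> g3p", reversible = TRUE),
    r("GAPDH_ENO", "g3p + nad + adp -> pep + nadh + atp",
      atp_category = "glycolysis_slp"),
    r("PYK", "pep + adp -> pyr.c + atp", atp_category = "glycolysis_slp"),
    # pentose phosphate pathway
    r("ZWF", "g6p + 2 nadp + h2o.c -> ru5p + co2.c + 2 nadph"),
    r("RPE", "ru5p -> x5p", reversible = TRUE),
    r("RKI", "ru5p -> r5p", reversible = TRUE),
    r("TKL1", "x5p + r5p -> s7p + g3p", reversible = TRUE),
    r("TAL", "s7p + g3p -> f6p + e4p", reversible = TRUE),
    r("TKL2", "x5p + e4p -> f6p + g3p", reversible = TRUE),
    # cytosolic acetyl-CoA and malonyl-CoA supply
    r("PDC", "pyr.c -> acald + co2.c"),
    r("ALD6", "acald + nadp + h2o.c -> ace + nadph",
      scenario_tag = "ald_nadp"),
    r("ALD23", "acald + nad + h2o.c -> ace + nadh",
      scenario_tag = "ald_nad"),
    r("ACS", "ace + coa.c + 2 atp -> accoa.c + 2 adp + h2o.c",
      atp_category = "atp_demand"),
    r("ACC", "accoa.c + co2.c + atp -> malcoa + adp",
      atp_category = "atp_demand"),
    # mitochondrial dissimilation
    r("PYT", "pyr.c -> pyr.m"),
    r("PDH", "pyr.m + coa.m + nad.m -> accoa.m + co2.c + nadh.m"),
    r("TCA", paste("accoa.m + 3 nad.m + fad + gdp + 3 h2o.c ->",
                   "coa.m + 3 nadh.m + fadh2 + gtp + 2 co2.c"),
      atp_category = "tca_slp"),
    r("NDK", "gtp + adp -> gdp + atp"),
    # respiration (both cytosolic and mitochondrial NADH respire at the
    # same P/O: external dehydrogenase assumption)
    r("RESP_NADH_C", glue::glue(
      "nadh + 0.5 o2.c + {po} adp -> nad + h2o.c + {po} atp"),
      atp_category = "oxphos"),
    r("RESP_NADH_M", glue::glue(
      "nadh.m + 0.5 o2.c + {po} adp -> nad.m + h2o.c + {po} atp"),
      atp_category = "oxphos"),
    r("RESP_FADH2", glue::glue(
      "fadh2 + 0.5 o2.c + {po} adp -> fad + h2o.c + {po} atp"),
      atp_category = "oxphos"),
    # non-phosphorylating reoxidation of surplus cytosolic NADPH
    r("NPOX", "nadph + 0.5 o2.c -> nadp + h2o.c"),
    # ATP dissipation (zero in minimum-substrate optima; carries the
    # maintenance demand in the combustion problem)
    r("ATPM", "atp -> adp", atp_category = "atp_demand"),
    # lumped shikimate pathway and phenylalanine synthesis
    r("SHIK", "e4p + 2 pep + atp + nadph -> chor + adp + nadp + 4 h2o.c",
      atp_category = "atp_demand"),
    r("CMPDT", "chor -> phepyr + co2.c + h2o.c"),
    r("AAT", "phepyr + glu -> phe + akg"),
    r("GDH13", "akg + nh3.c + nadph -> glu + nadp + h2o.c",
      scenario_tag = "gdh_nadp"),
    r("GDH2", "akg + nh3.c + nadh -> glu + nad + h2o.c",
      scenario_tag = "gdh_nad"),
    # heterologous phenylpropanoid pathway
    r("PAL2", "phe -> cinn.c + nh3.c"),
    r("C4H", "cinn.c + o2.c + nadph -> cou.c + nadp + h2o.c"),
    r("FCL", "cou.c + coa.c + 2 atp -> coucoa + 2 adp + h2o.c",
      atp_category = "atp_demand"),
    r("STS", "coucoa + 3 malcoa -> resv.c + 4 co2.c + 4 coa.c"),
    r("PHLRED", glue::glue(
      "cou.c + {if (phloretic_cofactor == 'nadph') 'nadph' else 'nadh'} ",
      "-> phloret.c + ",
      "{if (phloretic_cofactor == 'nadph') 'nadp' else 'nad'}")),
    # product export: resveratrol export is ATP-dependent (Snq2), the
    # acids leave passively
    r("SNQ2", "resv.c + atp -> resv.e + adp", atp_category = "atp_demand"),
    r("EX_COU", "cou.c -> cou.e"),
    r("EX_CINN", "cinn.c -> cinn.e"),
    r("EX_PHLOR", "phloret.c -> phloret.e")
  )

  net <- cs_network(metabolites, reactions, po = po)
  report <- validate_element_balance(net)
  if (!attr(report, "valid")) {
    abort("Default network failed element balance validation",
          class = "cs_validation_error")
  }
  net
}

#' Check element conservation of every reaction
#'
#' Computes, for each reaction, the net production of C, H, O and N implied
#' by its stoichiometry and the metabolite formulas. Reactions whose every
#' metabolite carries a formula are checked; a reaction touching a species
#' without a formula is reported with `checked = FALSE`. The network is
#' valid when all checked residuals are zero (|residual| < `tol`).
#'
#' @param network A [cs_network].
#' @param tol Residual tolerance, default `1e-9`.
#' @return A tibble `(reaction_id, C, H, O, N, checked)` with attribute
#'   `valid`.
#' @examples
#' rep <- validate_element_balance(build_default_network())
#' attr(rep, "valid")
#' @export
validate_element_balance <- function(network, tol = 1e-9) {
  stopifnot(inherits(network, "cs_network"))
  counts <- parse_formula(network$metabolites$formula)
  rownames(counts) <- network$metabolites$id
  has_formula <- nzchar(network$metabolites$formula) &
    !is.na(network$metabolites$formula)
  names(has_formula) <- network$metabolites$id
  rows <- purrr::map2(network$reactions$id, network$reactions$stoich,
    function(id, s) {
      unknown <- setdiff(names(s), network$metabolites$id)
      if (length(unknown) > 0) {
        abort(glue::glue(
          "Reaction {id} references unknown metabolite(s): ",
          paste(unknown, collapse = ", ")), class = "cs_validation_error")
      }
      checked <- all(has_formula[names(s)])
      res <- if (checked) {
        drop(s %*% counts[names(s), , drop = FALSE])
      } else setNames(rep(NA_real_, 4), ELEMENTS)
      tibble::tibble(reaction_id = id, C = res[["C"]], H = res[["H"]],
                     O = res[["O"]], N = res[["N"]], checked = checked)
    })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(reaction_id = character(), C = double(),
                          H = double(), O = double(), N = double(),
                          checked = logical())
  }
  resid <- as.matrix(out[out$checked %in% TRUE, c("C", "H", "O", "N")])
  attr(out, "valid") <- nrow(resid) == 0 || all(abs(resid) < tol)
  out
}

#' Define a cofactor scenario
#'
#' The extended network carries NADP- and NAD-dependent variants of both
#' acetaldehyde dehydrogenase (Ald6-type vs Ald2/3-type) and glutamate
#' dehydrogenase (Gdh1/3-type vs Gdh2-type). A scenario picks one of each.
#'
#' @param ald Cofactor of the acetaldehyde dehydrogenase, `"nadp"` or
#'   `"nad"`.
#' @param gdh Cofactor of the glutamate dehydrogenase, `"nadp"` or
#'   `"nad"`.
#' @return An object of class `cs_scenario`.
#' @examples
#' cofactor_scenario("nadp", "nadp")
#' @export
cofactor_scenario <- function(ald = c("nadp", "nad"), gdh = c("nadp", "nad")) {
  ald <- match.arg(tolower(ald), c("nadp", "nad"))
  gdh <- match.arg(tolower(gdh), c("nadp", "nad"))
  structure(list(ald = ald, gdh = gdh), class = "cs_scenario")
}

#' @export
print.cs_scenario <- function(x, ...) {
  cat(glue::glue("<cs_scenario> ALD: {toupper(x$ald)}, GDH: {toupper(x$gdh)}"),
      "\n")
  invisible(x)
}

as_scenario <- function(scenario) {
  if (inherits(scenario, "cs_scenario")) return(scenario)
  if (is.character(scenario) && length(scenario) == 1 && grepl(",", scenario)) {
    parts <- trimws(strsplit(scenario, ",")[[1]])
    return(cofactor_scenario(parts[[1]], parts[[2]]))
  }
  if (is.character(scenario) && length(scenario) == 2) {
    return(cofactor_scenario(scenario[[1]], scenario[[2]]))
  }
  abort("Cannot interpret scenario; use cofactor_scenario() or 'nadp,nad'",
        class = "cs_config_error")
}

#' Activate one cofactor scenario on a network
#'
#' Deactivates the acetaldehyde-dehydrogenase and glutamate-dehydrogenase
#' variants not selected by `scenario`; all other reactions are untouched.
#' Applying the same scenario twice is a no-op.
#'
#' @param network A [cs_network] containing both scenario-tagged variants
#'   of each enzyme.
#' @param scenario A [cofactor_scenario()], or a string like `"nadp,nad"`
#'   (ALD cofactor first).
#' @return The network with exactly one ALD and one GDH reaction active.
#' @examples
#' net <- apply_scenario(build_default_network(), cofactor_scenario("nadp", "nadp"))
#' @export
apply_scenario <- function(network, scenario) {
  stopifnot(inherits(network, "cs_network"))
  scenario <- as_scenario(scenario)
  tags <- network$reactions$scenario_tag
  for (enz in c("ald", "gdh")) {
    have <- tags[grepl(paste0("^", enz, "_"), tags %||% "")]
    need <- paste0(enz, c("_nadp", "_nad"))
    if (!all(need %in% tags)) {
      abort(glue::glue(
        "Network is missing scenario-tagged variant(s): ",
        paste(setdiff(need, tags), collapse = ", ")),
        class = "cs_config_error")
    }
  }
  keep <- c(paste0("ald_", scenario$ald), paste0("gdh_", scenario$gdh))
  network$reactions$active <- is.na(tags) | tags %in% keep
  network$scenario <- scenario
  network
}

#' Stoichiometric matrix of the active reactions
#'
#' @param network A [cs_network].
#' @param active_only Drop inactive (scenario-excluded) reactions.
#' @return A dense numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(network, active_only = TRUE) {
  rxns <- network$reactions
  if (active_only) rxns <- rxns[rxns$active, ]
  S <- matrix(0, nrow = nrow(network$metabolites), ncol = nrow(rxns),
              dimnames = list(network$metabolites$id, rxns$id))
  for (j in seq_len(nrow(rxns))) {
    s <- rxns$stoich[[j]]
    S[names(s), j] <- s
  }
  S
}
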