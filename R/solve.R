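# Dense two-phase simplex with Bland's anti-cycling rule for
# equality-constrained LPs in non-negative variables:
#   min/max c'x  s.t.  A x = b, x >= 0.
# The flux problems are small (tens of variables) but heavily degenerate
# (conserved cofactor moieties, futile reversible pairs), which calls for
# Bland's rule; the objective optimum is detected to `eps`.
simplex_core <- function(tab, basis, n_real, eps, max_iter) {
  m <- nrow(tab) - 1
  it <- 0
  repeat {
    it <- it + 1
    if (it > max_iter) {
      abort("Simplex iteration limit reached", class = "cs_solver_error")
    }
    red <- tab[m + 1, seq_len(ncol(tab) - 1)]
    enter <- which(red < -eps)[1]  # Bland: lowest index
    if (is.na(enter)) return(list(tab = tab, basis = basis))
    col <- tab[seq_len(m), enter]
    rows <- which(col > eps)
    if (length(rows) == 0) {
      abort("Linear program is unbounded", class = "cs_unbounded_error")
    }
    ratios <- tab[rows, ncol(tab)] / col[rows]
    cand <- rows[ratios <= min(ratios) + eps]
    leave <- cand[which.min(basis[cand])]  # Bland: lowest basis index
    piv <- tab[leave, enter]
    tab[leave, ] <- tab[leave, ] / piv
    for (r in setdiff(seq_len(m + 1), leave)) {
      if (abs(tab[r, enter]) > 0) {
        tab[r, ] <- tab[r, ] - tab[r, enter] * tab[leave, ]
      }
    }
    basis[leave] <- enter
  }
}

cs_lp <- function(obj, A_eq, b_eq, maximize = FALSE, n_iter = 20000,
                  eps = 1e-9) {
  # conserved moieties (ATP/ADP, NAD/NADH, ...) make balance rows linearly
  # dependent: keep an independent subset and verify the full system on
  # the returned solution.
  qrt <- qr(t(A_eq))
  keep <- sort(qrt$pivot[seq_len(qrt$rank)])
  A <- A_eq[keep, , drop = FALSE]
  b <- b_eq[keep]
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  m <- nrow(A)
  n <- ncol(A)
  cvec <- if (maximize) -obj else obj

  # phase 1: minimize the sum of artificial variables
  tab <- rbind(cbind(A, diag(m), b),
               c(-colSums(A), rep(0, m), -sum(b)))
  basis <- n + seq_len(m)
  res <- simplex_core(tab, basis, n, eps, n_iter)
  if (res$tab[m + 1, ncol(res$tab)] < -sqrt(eps)) {
    abort("Linear program is infeasible", class = "cs_infeasible_error")
  }
  tab <- res$tab
  basis <- res$basis
  # drive any residual (zero-valued) artificials out of the basis
  for (r in which(basis > n)) {
    enter <- which(abs(tab[r, seq_len(n)]) > eps)[1]
    if (!is.na(enter)) {
      piv <- tab[r, enter]
      tab[r, ] <- tab[r, ] / piv
      for (rr in setdiff(seq_len(m + 1), r)) {
        if (abs(tab[rr, enter]) > 0) {
          tab[rr, ] <- tab[rr, ] - tab[rr, enter] * tab[r, ]
        }
      }
      basis[r] <- enter
    }
  }
  ok <- basis <= n
  tab2 <- cbind(tab[seq_len(m), seq_len(n), drop = FALSE][ok, , drop = FALSE],
                tab[seq_len(m), ncol(tab)][ok])
  basis <- basis[ok]
  m2 <- nrow(tab2)
  # phase 2: rebuild reduced costs for the true objective
  z <- cvec
  rhs <- 0
  for (r in seq_len(m2)) {
    cb <- cvec[basis[r]]
    if (cb != 0) {
      z <- z - cb * tab2[r, seq_len(n)]
      rhs <- rhs + cb * tab2[r, n + 1]
    }
  }
  tab2 <- rbind(tab2, c(z, -rhs))
  res <- simplex_core(tab2, basis, n, eps, n_iter)
  x <- numeric(n)
  x[res$basis] <- res$tab[seq_len(m2), n + 1]
  x[x < 0 & x > -eps] <- 0
  if (any(abs(A_eq %*% x - b_eq) > 1e-7)) {
    abort("Linear program solution violates the full constraint system",
          class = "cs_infeasible_error")
  }
  value <- sum(obj * x)
  list(solution = x, value = value)
}

check_scenario_applied <- function(network) {
  tags <- network$reactions$scenario_tag
  act <- network$reactions$active
  for (enz in c("ald", "gdh")) {
    n_active <- sum(act & !is.na(tags) & grepl(paste0("^", enz, "_"), tags))
    if (n_active != 1) {
      abort(glue::glue(
        "Network has {n_active} active {toupper(enz)} variants; ",
        "call apply_scenario() first"), class = "cs_config_error")
    }
  }
  invisible(network)
}

resolve_export <- function(network, product) {
  prods <- cs_products()
  if (product %in% prods$product) {
    rid <- prods$export_reaction[prods$product == product]
  } else if (product %in% network$reactions$id) {
    rid <- product
  } else {
    abort(glue::glue(
      "Unknown product '{product}': expected one of ",
      "{paste(prods$product, collapse = ', ')} or a reaction id"),
      class = "cs_config_error")
  }
  if (!rid %in% network$reactions$id[network$reactions$active]) {
    abort(glue::glue("Export reaction '{rid}' is absent or inactive"),
          class = "cs_infeasible_error")
  }
  rid
}

#' Solve the zero-growth minimum-substrate flux distribution
#'
#' Fixes the export flux of one product at `basis_flux`, imposes
#' steady-state balances on every balanced metabolite and irreversibility
#' constraints, and minimizes the glucose-uptake flux by linear
#' programming. Because the non-phosphorylating NADPH oxidase and the
#' oxidative pentose phosphate pathway admit a carbon-wasting cycle, the
#' optimal objective is unique but the flux vector can be degenerate; a
#' second stage minimizes the L1 norm of the flux vector at the fixed
#' optimal glucose requirement so the reported vector is reproducible.
#'
#' @param network A [cs_network] with a scenario applied
#'   (see [apply_scenario()]).
#' @param product Product name (see [cs_products()]) or export reaction id.
#' @param basis_flux Export flux the solution is scaled to (default 1, so
#'   all fluxes are mol per mol product).
#' @return An object of class `cs_flux`: named flux vector (`fluxes`),
#'   optimal glucose uptake (`objective`), glucose requirement per mol
#'   product (`glucose_per_product`), plus the product and basis used.
#' @examples
#' net <- apply_scenario(build_default_network(), cofactor_scenario("nadp", "nadp"))
#' sol <- solve_min_substrate(net, "resveratrol")
#' sol$glucose_per_product  # ~3.54 mol glucose per mol resveratrol
#' @export
solve_min_substrate <- function(network, product = "resveratrol",
                                basis_flux = 1) {
  stopifnot(inherits(network, "cs_network"), basis_flux >= 0)
  check_scenario_applied(network)
  export_id <- resolve_export(network, product)

  rxns <- network$reactions[network$reactions$active, ]
  S <- stoich_matrix(network, active_only = TRUE)
  balanced <- network$metabolites$id[network$metabolites$balanced]
  S_bal <- S[balanced, , drop = FALSE]

  # split reversible reactions into forward/backward non-negative parts
  rev <- rxns$reversible
  A <- cbind(S_bal, -S_bal[, rev, drop = FALSE])
  var_rxn <- c(rxns$id, rxns$id[rev])
  var_dir <- c(rep(1, nrow(rxns)), rep(-1, sum(rev)))

  # steady state on balanced species + fixed product export
  export_row <- as.numeric(var_rxn == export_id) * var_dir
  A_eq <- rbind(A, export_row)
  b_eq <- c(rep(0, nrow(S_bal)), basis_flux)

  obj <- as.numeric(var_rxn == network$substrate_uptake & var_dir == 1)
  st1 <- cs_lp(obj, A_eq, b_eq, maximize = FALSE)
  opt <- st1$value

  # stage 2: minimal L1 norm at the optimal substrate requirement
  A_eq2 <- rbind(A_eq, obj)
  b_eq2 <- c(b_eq, opt)
  # numerically tight system: fall back to the stage-1 vertex, which is
  # already an optimal basic solution, if the L1 refinement cannot pivot
  st2 <- tryCatch(
    cs_lp(rep(1, ncol(A_eq2)), A_eq2, b_eq2, maximize = FALSE),
    cs_infeasible_error = function(e) st1,
    cs_solver_error = function(e) st1)
  x <- st2$solution

  fluxes <- setNames(rep(0, nrow(rxns)), rxns$id)
  for (k in seq_along(x)) {
    fluxes[var_rxn[[k]]] <- fluxes[var_rxn[[k]]] + var_dir[[k]] * x[[k]]
  }
  fluxes[abs(fluxes) < 1e-12] <- 0

  # sanity: steady state and irreversibility
  resid <- S_bal %*% fluxes
  if (any(abs(resid) > 1e-8)) {
    abort("Flux solution violates steady-state balances",
          class = "cs_solver_error")
  }
  if (any(fluxes[!rxns$reversible] < -1e-9)) {
    abort("Irreversible reaction carries negative flux",
          class = "cs_solver_error")
  }

  structure(list(
    fluxes = fluxes,
    objective = opt,
    glucose_per_product = if (basis_flux > 0) opt / basis_flux else NA_real_,
    basis_flux = basis_flux,
    product = product,
    export_reaction = export_id,
    scenario = network$scenario,
    po = network$po), class = "cs_flux")
}

#' @export
print.cs_flux <- function(x, ...) {
  cat(glue::glue(
    "<cs_flux> product: {x$product}, basis {x$basis_flux}, ",
    "glucose uptake {format(x$objective, digits = 6)}"), "\n")
  invisible(x)
}

#' Tidy a flux distribution into a tibble
#'
#' @param x A `cs_flux` from [solve_min_substrate()].
#' @param drop_zero Drop reactions carrying (numerically) zero flux.
#' @param ... Unused.
#' @return Tibble `(reaction_id, flux)` in mol per mol product.
#' @export
tidy.cs_flux <- function(x, drop_zero = FALSE, ...) {
  out <- tibble::tibble(reaction_id = names(x$fluxes),
                        flux = unname(x$fluxes))
  if (drop_zero) out <- out[abs(out$flux) > 1e-12, ]
  out
}

category_atp_flux <- function(network, flux, category) {
  rxns <- network$reactions[network$reactions$active, ]
  unknown <- setdiff(names(flux), network$reactions$id)
  if (length(unknown) > 0) {
    abort(paste0("Flux vector names unknown reaction(s): ",
                 paste(unknown, collapse = ", ")),
          class = "cs_accounting_error")
  }
  sel <- rxns$id[rxns$atp_category == category]
  coef_of <- function(s, n) if (n %in% names(s)) s[[n]] else 0
  total <- 0
  for (rid in sel) {
    s <- rxns$stoich[[which(rxns$id == rid)]]
    coef <- coef_of(s, "atp") + coef_of(s, "gtp")
    v <- if (rid %in% names(flux)) flux[[rid]] else 0
    total <- total + coef * v
  }
  unname(total)
}

#' ATP production breakdown of a zero-growth flux solution
#'
#' Sums net ATP formation by source along a flux distribution:
#' glycolytic substrate-level phosphorylation (phosphoglycerate-kinase
#' lump and pyruvate kinase net of the hexokinase and phosphofructokinase
#' investments), TCA-cycle substrate-level phosphorylation (succinyl-CoA
#' level GTP), and oxidative phosphorylation (P/O times the reduced
#' cofactors oxidized by phosphorylating respiration). At zero growth the
#' total equals the pathway ATP demand of the product.
#'
#' @param network The [cs_network] the flux was solved on.
#' @param flux A `cs_flux` or named flux vector.
#' @return One-row tibble `(glycolysis_slp, tca_slp, oxphos, total)` in
#'   mol ATP per mol product, of class `cs_atp_breakdown`.
#' @examples
#' net <- apply_scenario(build_default_network(), "nadp,nadp")
#' atp_breakdown(net, solve_min_substrate(net, "resveratrol"))
#' @export
atp_breakdown <- function(network, flux) {
  stopifnot(inherits(network, "cs_network"))
  if (inherits(flux, "cs_flux")) flux <- flux$fluxes
  glyc <- category_atp_flux(network, flux, "glycolysis_slp")
  tca <- category_atp_flux(network, flux, "tca_slp")
  oxph <- category_atp_flux(network, flux, "oxphos")
  out <- tibble::tibble(glycolysis_slp = glyc, tca_slp = tca, oxphos = oxph,
                        total = glyc + tca + oxph)
  class(out) <- c("cs_atp_breakdown", class(out))
  out
}

#' Net overall conversion reaction of a flux solution
#'
#' Nets all exchange fluxes (glucose, O2 in; product, CO2, H2O, NH3 out)
#' into one input-output equation per mol product, and verifies that the
#' equation closes the C, H, O, N balances and the degree-of-reduction
#' (electron) balance.
#'
#' @param network The [cs_network] the flux was solved on.
#' @param flux A `cs_flux` from [solve_min_substrate()].
#' @param tol Closure tolerance, default `1e-9`.
#' @return A tibble `(species, coefficient, role)` per mol product, class
#'   `cs_overall_reaction`, with attributes `equation` (formatted string),
#'   `element_residual` and `electron_residual`.
#' @examples
#' net <- apply_scenario(build_default_network(), "nadp,nadp")
#' overall_reaction(net, solve_min_substrate(net, "resveratrol"))
#' @export
overall_reaction <- function(network, flux, tol = 1e-9) {
  stopifnot(inherits(network, "cs_network"), inherits(flux, "cs_flux"))
  S <- stoich_matrix(network, active_only = TRUE)
  v <- flux$fluxes[colnames(S)]
  net_prod <- drop(S %*% v)  # net production per metabolite
  ext <- network$metabolites[!network$metabolites$balanced, ]
  net_ext <- net_prod[ext$id]
  basis <- if (flux$basis_flux > 0) flux$basis_flux else 1
  net_ext <- net_ext / basis

  prods <- cs_products()
  prod_met <- if (flux$product %in% prods$product) {
    prods$metabolite_ext[prods$product == flux$product]
  } else {
    # export reaction id given: its extracellular species
    s <- network$reactions$stoich[[which(network$reactions$id ==
                                           flux$export_reaction)]]
    intersect(names(s)[s > 0], ext$id)[1]
  }

  species_map <- c(glucose = "glc.e", o2 = "o2.e", co2 = "co2.e",
                   h2o = "h2o.e", nh3 = "nh3.e")
  out <- tibble::tibble(
    species = c("glucose", "o2", "product", "co2", "h2o", "nh3"),
    coefficient = unname(c(-net_ext[species_map[["glucose"]]],
                    -net_ext[species_map[["o2"]]],
                    net_ext[[prod_met]],
                    net_ext[species_map[["co2"]]],
                    net_ext[species_map[["h2o"]]],
                    net_ext[species_map[["nh3"]]])),
    role = c("input", "input", "output", "output", "output", "output"))
  out$coefficient[abs(out$coefficient) < 1e-12] <- 0

  # element closure over all exchange species
  counts <- parse_formula(ext$formula)
  elem_res <- drop(net_ext[ext$id] %*% counts)
  if (any(abs(elem_res) > tol)) {
    abort(paste0("Overall reaction does not close element balance: ",
                 paste(sprintf("%s=%.3g", names(elem_res), elem_res),
                       collapse = ", ")), class = "cs_balance_error")
  }
  # degree-of-reduction closure: electrons in glucose = electrons in
  # product + 4 per O2 (other outputs have gamma 0)
  gam <- degree_of_reduction(ext$formula)
  names(gam) <- ext$id
  electron_res <- sum(net_ext[ext$id] * gam)
  if (abs(electron_res) > tol * 100) {
    abort("Overall reaction does not close the electron balance",
          class = "cs_balance_error")
  }

  fmt <- function(x) format(round(x, 10), trim = TRUE, digits = 6)
  inputs <- out[out$role == "input" & out$coefficient != 0, ]
  outputs <- out[out$role == "output" & out$coefficient != 0, ]
  eq <- paste(
    paste(fmt(inputs$coefficient), inputs$species, collapse = " + "),
    "->",
    paste(fmt(outputs$coefficient), outputs$species, collapse = " + "))

  attr(out, "equation") <- eq
  attr(out, "element_residual") <- elem_res
  attr(out, "electron_residual") <- electron_res
  class(out) <- c("cs_overall_reaction", class(out))
  out
}

#' Maximum theoretical product yield under a cofactor scenario
#'
#' Applies the scenario, solves the zero-growth minimum-glucose problem
#' for unit product export, and reports the maximum theoretical yield
#' Y_P/S^max = 1 / (glucose requirement), together with the ATP breakdown
#' and the net overall reaction of the optimal flux distribution.
#'
#' @param network A [cs_network] (scenario need not be applied yet).
#' @param scenario A [cofactor_scenario()] or string like `"nadp,nadp"`.
#' @param product Product name, default `"resveratrol"`.
#' @return An object of class `cs_yield` with elements `yield`
#'   (mol product / mol glucose), `scenario`, `product`, `atp`
#'   (the breakdown tibble), `overall` (the overall-reaction tibble) and
#'   `flux`.
#' @examples
#' y <- max_yield(build_default_network(), "nadp,nadp", "resveratrol")
#' round(y$yield, 3)  # 0.282
#' @export
max_yield <- function(network, scenario, product = "resveratrol") {
  net <- apply_scenario(network, scenario)
  flux <- solve_min_substrate(net, product, basis_flux = 1)
  structure(list(
    yield = 1 / flux$glucose_per_product,
    glucose_per_product = flux$glucose_per_product,
    scenario = net$scenario,
    product = product,
    po = net$po,
    atp = atp_breakdown(net, flux),
    overall = overall_reaction(net, flux),
    flux = flux), class = "cs_yield")
}

#' @export
print.cs_yield <- function(x, ...) {
  cat(glue::glue(
    "<cs_yield> {x$product}, ALD {toupper(x$scenario$ald)} / ",
    "GDH {toupper(x$scenario$gdh)}: ",
    "Y_P/S^max = {format(round(x$yield, 3), nsmall = 3)} mol/mol"), "\n")
  cat("  ATP: ", paste(sprintf("%s %.3f", names(x$atp), as.numeric(x$atp[1, ])),
                       collapse = ", "), "\n", sep = "")
  cat("  ", attr(x$overall, "equation"), "\n", sep = "")
  invisible(x)
}

#' @describeIn max_yield One-row tibble view of a yield result.
#' @param x A `cs_yield`.
#' @param ... Unused.
#' @export
tidy.cs_yield <- function(x, ...) {
  ov <- x$overall
  co <- function(sp) ov$coefficient[ov$species == sp]
  tibble::tibble(
    product = x$product,
    ald_cofactor = toupper(x$scenario$ald),
    gdh_cofactor = toupper(x$scenario$gdh),
    yield_mol_mol = x$yield,
    glucose_per_product = x$glucose_per_product,
    atp_glycolysis = x$atp$glycolysis_slp,
    atp_tca = x$atp$tca_slp,
    atp_oxphos = x$atp$oxphos,
    atp_total = x$atp$total,
    o2_per_product = co("o2"),
    co2_per_product = co("co2"),
    h2o_per_product = co("h2o"))
}

#' Maximum yields across all four cofactor scenarios
#'
#' Convenience wrapper running [max_yield()] for every combination of
#' acetaldehyde-dehydrogenase and glutamate-dehydrogenase cofactor.
#'
#' @param network A [cs_network].
#' @param product Product name.
#' @return Tibble with one row per scenario (see [tidy.cs_yield]).
#' @export
scenario_yields <- function(network, product = "resveratrol") {
  grid <- expand.grid(ald = c("nadp", "nad"), gdh = c("nadp", "nad"),
                      stringsAsFactors = FALSE)
  bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    tidy(max_yield(network, cofactor_scenario(grid$ald[i], grid$gdh[i]),
                   product))
  }))
}

#' Pathway ATP demand per mol of product
#'
#' Sums the ATP consumed by the ATP-demand reactions (shikimate kinase
#' lump, the AMP-forming CoA ligations counted as 2 ATP equivalents,
#' acetyl-CoA carboxylase, and the ATP-dependent exporter) along the
#' unit-product minimum-glucose solution. For resveratrol this is 13 mol
#' ATP per mol exported product (12 without the export step), independent
#' of the cofactor scenario.
#'
#' @param network A [cs_network] with a scenario applied.
#' @param product Product name.
#' @param include_export Count the ATP cost of the export step (default
#'   `TRUE`).
#' @return Scalar, mol ATP per mol product.
#' @examples
#' net <- apply_scenario(build_default_network(), "nadp,nadp")
#' atp_demand(net, "resveratrol")        # 13
#' atp_demand(net, "resveratrol", include_export = FALSE)  # 12
#' @export
atp_demand <- function(network, product = "resveratrol",
                       include_export = TRUE) {
  check_scenario_applied(network)
  flux <- solve_min_substrate(network, product, basis_flux = 1)
  rxns <- network$reactions[network$reactions$active, ]
  sel <- rxns$id[rxns$atp_category == "atp_demand"]
  if (!include_export) sel <- setdiff(sel, flux$export_reaction)
  total <- 0
  for (rid in sel) {
    s <- rxns$stoich[[which(rxns$id == rid)]]
    coef <- if ("atp" %in% names(s)) s[["atp"]] else 0
    v <- if (rid %in% names(flux$fluxes)) flux$fluxes[[rid]] else 0
    total <- total - coef * v  # consumed -> positive
  }
  unname(total)
}

#' ATP yield of fully respiratory glucose dissimilation
#'
#' Computes, from the network itself, the mol ATP formed per mol glucose
#' completely combusted to CO2 and H2O: the linear program fixes glucose
#' uptake at 1 and maximizes flux through the ATP-dissipation reaction.
#' At P/O 1.0 the curated network gives 16 (4 by substrate-level
#' phosphorylation plus 10 NADH and 2 FADH2 respired).
#'
#' @param po P/O ratio. Ignored when `network` is supplied (the network's
#'   own P/O applies).
#' @param network Optionally, a prebuilt [cs_network]; defaults to
#'   [build_default_network()] at `po`.
#' @return Scalar, mol ATP per mol glucose.
#' @examples
#' atp_per_glucose(1.0)  # 16
#' atp_per_glucose(0)    # 4
#' @export
atp_per_glucose <- function(po = 1.0, network = NULL) {
  stopifnot(po >= 0)
  if (is.null(network)) network <- build_default_network(po = po)
  net <- apply_scenario(network, cofactor_scenario("nadp", "nadp"))
  rxns <- net$reactions[net$reactions$active, ]
  S <- stoich_matrix(net, active_only = TRUE)
  balanced <- net$metabolites$id[net$metabolites$balanced]
  S_bal <- S[balanced, , drop = FALSE]
  rev <- rxns$reversible
  A <- cbind(S_bal, -S_bal[, rev, drop = FALSE])
  var_rxn <- c(rxns$id, rxns$id[rev])
  var_dir <- c(rep(1, nrow(rxns)), rep(-1, sum(rev)))
  uptake_row <- as.numeric(var_rxn == net$substrate_uptake & var_dir == 1)
  A_eq <- rbind(A, uptake_row)
  b_eq <- c(rep(0, nrow(S_bal)), 1)
  obj <- as.numeric(var_rxn == "ATPM" & var_dir == 1)
  st <- cs_lp(obj, A_eq, b_eq, maximize = TRUE)
  st$value
}
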