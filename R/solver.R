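#' @title Determined-system flux solver and energy ledger
#' @name mfa_solver
#' @description
#' The flux model is solved snapshot by snapshot. The fixed fluxes (glucose
#' inflow, seven measured outflows, eighteen biomass drains) plus the
#' acetate-branch switch and the glyoxylate regime rule leave a square
#' 22-unknown/22-balance linear system in which the CO2 transport flux, the
#' oxidative-phosphorylation flux and the ATP-dissipation (spilling) flux
#' close the carbon, NADH and ATP nodes. In `"constraint"` mode (default)
#' the measured CO2 evolution rate additionally fixes the CO2 transport
#' flux, the system becomes overdetermined by one and is solved by least
#' squares with reported residuals; in `"redundancy"` mode the square system
#' is solved exactly and the predicted CO2 rate is compared with the
#' measurement.
NULL

#' Acetate branch regime: excretion (Pta/Ack) vs re-assimilation (Acs)
#'
#' The acetate synthesis and re-assimilation branches form a futile cycle
#' whose net direction cannot be resolved from extracellular data, so one
#' branch is constrained to zero per regime: net excretion activates
#' Pta/Ack, net consumption (or zero) activates Acs.
#'
#' @param snapshot A `SteadyStateSnapshot`.
#' @return `"net_excretion"` if the acetate rate is positive, else
#'   `"net_assimilation"`.
#' @export
acs_pta_switch <- function(snapshot) {
  if (snapshot$q_products[["acetate"]] > 0) "net_excretion" else "net_assimilation"
}

# glyoxylate-shunt regime rule: repressed on glucose, carries a fixed
# fraction of acetate assimilation during co-utilisation
.glx_flux <- function(snapshot, glx_fraction) {
  q_ace <- snapshot$q_products[["acetate"]]
  if (q_ace < 0) glx_fraction * (-q_ace) else 0
}

#' Solve the determined flux system for one snapshot
#'
#' @param network A `MetabolicNetwork` (default network assumed for ids).
#' @param snapshot A `SteadyStateSnapshot`.
#' @param drains Named flux vector over the 18 biomass-drain reactions, from
#'   [drain_fluxes()].
#' @param mode `"constraint"` (measured CO2 fixes the CO2 transport flux;
#'   least squares, residuals reported) or `"redundancy"` (square solve; CO2
#'   prediction checked against the measurement).
#' @param glx_fraction Fraction of net acetate assimilation routed through
#'   the glyoxylate shunt (default 0.3); the shunt is 0 when acetate is not
#'   consumed.
#' @param tol Numeric tolerance for rank checks and the gross-infeasibility
#'   guard.
#' @return Object of class `"FluxSolution"`: `fluxes` (named, all 50
#'   reactions), `fixed_mask` (`"fixed"`/`"solved"`), `residuals` (per
#'   balanced metabolite), `co2_residual` (redundancy mode), `regime`,
#'   `condition_diagnostic`, `sign_violations` (irreversible reactions with
#'   negative flux), `mu`.
#' @export
solve_fluxes <- function(network, snapshot, drains,
                         mode = c("constraint", "redundancy"),
                         glx_fraction = 0.3, tol = 1e-9) {
  mode <- match.arg(mode)
  S <- stoichiometric_matrix(network)
  roles <- reaction_roles(network)
  ids <- colnames(S)

  fixed <- c(PTS = unname(snapshot$q_glc))
  for (sp in names(.species_outflow)) {
    rid <- .species_outflow[[sp]]
    if (rid %in% ids) fixed[rid] <- snapshot$q_products[[sp]]
  }
  miss <- setdiff(names(roles)[roles == "biomass_drain"], names(drains))
  if (length(miss))
    stop("drain flux missing for: ", paste(miss, collapse = ", "))
  fixed <- c(fixed, drains[names(drains) %in% ids])

  regime <- acs_pta_switch(snapshot)
  fixed[if (regime == "net_excretion") "ACS" else "PTA"] <- 0
  fixed["GLX"] <- .glx_flux(snapshot, glx_fraction)

  # the square system (CO2 transport free) predicts the CO2 evolution rate
  # from the carbon bookkeeping; its mismatch with the measurement is the
  # natural consistency diagnostic (a least-squares residual alone can hide
  # a gross mismatch by redistributing carbon fluxes)
  sq <- .solve_balances(S, fixed)
  co2_mismatch <- unname(sq$fluxes["OUT_CO2"] - snapshot$r_co2)
  scale <- max(1, abs(snapshot$q_glc))
  if (mode == "constraint") {
    # "gross" means beyond anything measurement noise produces: flag only a
    # mismatch of order the CO2 rate itself (factor ~1.5 and worse)
    if (abs(co2_mismatch) > 0.5 * max(1, abs(sq$fluxes[["OUT_CO2"]])))
      stop("gross infeasibility: measured CO2 rate deviates from the ",
           "carbon-balance prediction by ", format(co2_mismatch),
           " mmol/gDCW/h")
    fixed["OUT_CO2"] <- snapshot$r_co2
    sv <- .solve_balances(S, fixed)
  } else {
    sv <- sq
  }
  v <- sv$fluxes
  residuals <- sv$residuals

  rev_ok <- vapply(network$reactions, `[[`, TRUE, "reversible")
  names(rev_ok) <- ids
  sign_viol <- names(v)[!rev_ok & v < -1e-6 * scale]

  structure(list(
    fluxes = v,
    fixed_mask = stats::setNames(
      ifelse(ids %in% names(fixed), "fixed", "solved"), ids),
    residuals = residuals,
    co2_residual = co2_mismatch,
    regime = regime, mode = mode,
    condition_diagnostic = sv$condition,
    sign_violations = sign_viol,
    mu = snapshot$mu
  ), class = "FluxSolution")
}

# Core linear solve of the metabolite balances given the fixed fluxes.
#
# The energy closure is block-triangular: the oxidative-phosphorylation flux
# appears only in the NADH and ATP rows and the dissipation (spilling) flux
# only in the ATP row, so the carbon + NADPH core is solved first and the
# two energy fluxes follow by exact back-substitution. This keeps every
# carbon flux numerically independent of the P/O ratio (which only enters
# the ATP row) and mirrors how the balances determine each other.
.solve_balances <- function(S, fixed) {
  ids <- colnames(S)
  unknown <- setdiff(ids, names(fixed))
  staged <- all(c("OXPHOS", "ATPSPILL") %in% unknown) &&
    all(c("ATP", "NADH") %in% rownames(S)) &&
    all(S[setdiff(rownames(S), c("ATP", "NADH")), c("OXPHOS", "ATPSPILL")] == 0) &&
    S["NADH", "ATPSPILL"] == 0

  v <- stats::setNames(numeric(length(ids)), ids)
  v[names(fixed)] <- fixed

  core_rows <- if (staged) setdiff(rownames(S), c("ATP", "NADH")) else rownames(S)
  core_cols <- if (staged) setdiff(unknown, c("OXPHOS", "ATPSPILL")) else unknown
  A <- S[core_rows, core_cols, drop = FALSE]
  b <- -as.vector(S[core_rows, names(fixed), drop = FALSE] %*% fixed)
  qrA <- qr(A)
  if (qrA$rank < length(core_cols)) {
    ns <- svd(A, nv = length(core_cols))$v[
      , (qrA$rank + 1L):length(core_cols), drop = FALSE]
    stop("underdetermined flux system; free direction(s) involve: ",
         paste(core_cols[apply(abs(ns) > 1e-8, 1, any)], collapse = ", "))
  }
  v[core_cols] <- qr.coef(qrA, b)
  if (staged) {
    v["OXPHOS"] <- -sum(S["NADH", ids != "OXPHOS"] * v[ids != "OXPHOS"]) /
      S["NADH", "OXPHOS"]
    v["ATPSPILL"] <- -sum(S["ATP", ids != "ATPSPILL"] * v[ids != "ATPSPILL"]) /
      S["ATP", "ATPSPILL"]
  }
  list(fluxes = v,
       residuals = stats::setNames(as.vector(S %*% v), rownames(S)),
       condition = kappa(A, exact = FALSE))
}

#' @export
print.FluxSolution <- function(x, ...) {
  cat(sprintf(
    "FluxSolution (%s, %s): %d fluxes, max |residual| %.2e, condition %.1f\n",
    x$mode, x$regime, length(x$fluxes), max(abs(x$residuals)),
    x$condition_diagnostic))
  if (length(x$sign_violations))
    cat("  sign violations:", paste(x$sign_violations, collapse = ", "), "\n")
  invisible(x)
}

# signed contribution of each reaction to a cofactor node
.node_contrib <- function(network, fluxes, metab) {
  vapply(network$reactions, function(r) {
    co <- r$stoich[metab]
    if (is.na(co)) 0 else co * fluxes[[r$id]]
  }, numeric(1)) |> stats::setNames(reaction_ids(network))
}

#' ATP/NADH/CO2 bookkeeping of a flux solution
#'
#' Sums substrate-level phosphorylation and oxidative phosphorylation (at
#' the network's P/O ratio) into total ATP production, attributes
#' growth-associated consumption to the biomass drains, reads the spilling
#' (dissipation) flux, and computes the TCA-cycle share of CO2 and NADH
#' production and the glycolytic share of ATP production.
#'
#' @param network A `MetabolicNetwork`.
#' @param solution A `FluxSolution` from [solve_fluxes()].
#' @param drains Named drain flux vector used in the solve.
#' @return Object of class `"EnergyLedger"`: `atp_total`, `atp_growth`,
#'   `atp_spilling`, `atp_other` (remaining stoichiometric consumption, e.g.
#'   kinase steps and Acs re-assimilation), `atp_spilling_specific`
#'   (mmol per g DCW, the per-biomass view `atp_spilling / mu`),
#'   `frac_atp_glycolysis`, `frac_co2_tca`, `frac_nadh_tca`.
#' @export
energy_ledger <- function(network, solution, drains) {
  v <- solution$fluxes
  roles <- reaction_roles(network)
  atp <- .node_contrib(network, v, "ATP")
  nadh <- .node_contrib(network, v, "NADH")
  co2 <- .node_contrib(network, v, "CO2")

  prod_atp <- sum(pmax(atp, 0))
  spill <- unname(v["ATPSPILL"])
  growth <- -sum(pmin(atp[roles == "biomass_drain"], 0))
  other <- sum(-pmin(atp[roles != "biomass_drain"], 0)) - spill
  if (spill < -1e-6 * max(1, prod_atp))
    warning("negative ATP spilling (", format(spill),
            "): over-constrained energetics")
  tca <- c("ICD", "AKGDH", "MDH", "GLX")
  prod_co2 <- sum(pmax(co2, 0))
  prod_nadh <- sum(pmax(nadh, 0))
  structure(list(
    atp_total = prod_atp, atp_growth = growth, atp_spilling = spill,
    atp_other = other,
    atp_spilling_specific = if (solution$mu > 0) spill / solution$mu else 0,
    frac_atp_glycolysis = if (prod_atp > 0)
      sum(pmax(atp[c("GAPD", "PYK")], 0)) / prod_atp else 0,
    frac_co2_tca = if (prod_co2 > 0)
      sum(pmax(co2[c("ICD", "AKGDH")], 0)) / prod_co2 else 0,
    frac_nadh_tca = if (prod_nadh > 0)
      sum(pmax(nadh[tca], 0)) / prod_nadh else 0,
    mu = solution$mu
  ), class = "EnergyLedger")
}

#' @export
print.EnergyLedger <- function(x, ...) {
  cat(sprintf(
    paste0("EnergyLedger (mu=%.3f): ATP total %.2f, growth %.2f, spilling",
           " %.2f mmol/gDCW/h (%.1f mmol/gDCW)\n"),
    x$mu, x$atp_total, x$atp_growth, x$atp_spilling,
    x$atp_spilling_specific))
  cat(sprintf("  fractions: glycolytic ATP %.2f, TCA CO2 %.2f, TCA NADH %.2f\n",
              x$frac_atp_glycolysis, x$frac_co2_tca, x$frac_nadh_tca))
  invisible(x)
}

#' Counterfactual re-routing of measured by-product outflows to pyruvate
#'
#' Re-solves the snapshot with the lactate, pyrimidine-intermediate and
#' N-acetyl-aspartate outflows removed and an equal-carbon generic outflow
#' placed at pyruvate — the situation of a study that had not measured those
#' by-products and attributed the unclosed carbon to a pyruvate sink.
#'
#' @param network A `MetabolicNetwork`.
#' @param snapshot A `SteadyStateSnapshot` with nonzero rerouted products.
#' @param drains Named drain flux vector.
#' @param ... Passed to [solve_fluxes()].
#' @return List with `base` and `rerouted` `FluxSolution`s, the per-reaction
#'   relative `deviations` (on fluxes of meaningful size), and a `summary`
#'   vector of percent deviations for PDH, the TCA cycle (mean of CS, ICD,
#'   AKGDH, MDH) and Ppc.
#' @export
reroute_counterfactual <- function(network, snapshot, drains, ...) {
  rerouted_species <- c("lactate", "CBASP", "DHO", "orotate", "NAA")
  base <- solve_fluxes(network, snapshot, drains, ...)

  carbon <- sum(vapply(rerouted_species, function(sp)
    carbon_count(sp) * snapshot$q_products[[sp]], numeric(1)))
  q_pyr <- carbon / 3  # equal carbon as a 3-C pyruvate outflow

  net_cf <- network
  net_cf$metabolites <- rbind(
    net_cf$metabolites,
    data.frame(id = "PYRUVATE.e", name = "pyruvate (hypothetical outflow)",
               carbon = 3, cofactor = FALSE, external = TRUE))
  net_cf$reactions <- c(net_cf$reactions, list(
    reaction("OUT_PYR_CF", c(PYR = -1, PYRUVATE.e = 1), "outflow")))
  snap_cf <- snapshot
  snap_cf$q_products[rerouted_species] <- 0
  # the added outflow is not a measured species; impose the equal-carbon rate
  cf <- solve_fluxes_fixed_extra(net_cf, snap_cf, drains,
                                 extra_fixed = c(OUT_PYR_CF = q_pyr), ...)

  common <- intersect(names(base$fluxes), names(cf$fluxes))
  scale <- max(abs(base$fluxes))
  big <- common[abs(base$fluxes[common]) > 1e-6 * scale]
  deviations <- abs(cf$fluxes[big] - base$fluxes[big]) / abs(base$fluxes[big])
  tca <- mean(deviations[c("CS", "ICD", "AKGDH", "MDH")], na.rm = TRUE)
  list(base = base, rerouted = cf, deviations = deviations,
       summary = c(PDH = unname(deviations["PDH"]) * 100,
                   TCA = tca * 100,
                   PPC = unname(deviations["PPC"]) * 100))
}

# solve with additional fixed fluxes beyond the standard roles (used by the
# counterfactual, where the hypothetical pyruvate outflow is imposed)
solve_fluxes_fixed_extra <- function(network, snapshot, drains, extra_fixed,
                                     mode = c("constraint", "redundancy"),
                                     glx_fraction = 0.3, tol = 1e-9) {
  mode <- match.arg(mode)
  S <- stoichiometric_matrix(network)
  ids <- colnames(S)
  fixed <- c(PTS = unname(snapshot$q_glc))
  for (sp in names(.species_outflow)) {
    rid <- .species_outflow[[sp]]
    if (rid %in% ids) fixed[rid] <- snapshot$q_products[[sp]]
  }
  fixed <- c(fixed, drains[names(drains) %in% ids])
  regime <- acs_pta_switch(snapshot)
  fixed[if (regime == "net_excretion") "ACS" else "PTA"] <- 0
  fixed["GLX"] <- .glx_flux(snapshot, glx_fraction)
  if (mode == "constraint") fixed["OUT_CO2"] <- snapshot$r_co2
  fixed[names(extra_fixed)] <- extra_fixed
  sv <- .solve_balances(S, fixed)
  structure(list(fluxes = sv$fluxes,
                 fixed_mask = stats::setNames(
                   ifelse(ids %in% names(fixed), "fixed", "solved"), ids),
                 residuals = sv$residuals, co2_residual = NA_real_,
                 regime = regime, mode = mode,
                 condition_diagnostic = sv$condition,
                 sign_violations = character(), mu = snapshot$mu),
            class = "FluxSolution")
}
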