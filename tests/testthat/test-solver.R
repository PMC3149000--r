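test_that("an all-zero snapshot yields the all-zero flux vector", {
  snap <- steady_state_snapshot(0, 0)
  drains <- drain_fluxes(composition_at_mu(ref_comp_table(), 0.3), 0)
  sol <- solve_fluxes(ref_network(), snap, drains)
  expect_length(sol$fluxes, 50L)
  expect_true(all(abs(sol$fluxes) < 1e-12))
})

test_that("acetate regime switch follows the sign of the acetate rate", {
  mk <- function(q) steady_state_snapshot(0.3, 3, c(acetate = q))
  expect_identical(acs_pta_switch(mk(1)), "net_excretion")
  expect_identical(acs_pta_switch(mk(-1)), "net_assimilation")
  expect_identical(acs_pta_switch(mk(0)), "net_assimilation")
  # at zero acetate both branches end up at zero flux
  st <- true_state_at(0.15)  # below overflow onset
  sol <- solve_fluxes(ref_network(), st$snapshot, st$drains)
  expect_identical(unname(sol$fluxes["PTA"]), 0)
  expect_lt(abs(sol$fluxes["ACS"]), 1e-10)
})

test_that("solver reproduces ground truth exactly on noise-free snapshots", {
  for (mu in c(0.12, 0.30, 0.47)) {
    st <- true_state_at(mu)
    sol <- solve_fluxes(ref_network(), st$snapshot, st$drains)
    expect_lt(rel_l2(sol$fluxes, st$fluxes), 1e-10)
    expect_lt(max(abs(sol$residuals)), 1e-9)
    expect_length(sol$sign_violations, 0)
  }
})

test_that("solver agrees with the brute-force dense least-squares oracle", {
  withr::local_seed(11)
  net <- ref_network()
  for (k in 1:20) {
    mu <- stats::runif(1, 0.12, 0.47)
    rs <- random_feasible_snapshot(mu)
    sol <- solve_fluxes(net, rs$snapshot, rs$drains)
    vo <- oracle_solve(net, rs$snapshot, rs$drains)
    expect_lt(rel_l2(sol$fluxes, vo), 1e-8)
  }
})

test_that("redundancy mode predicts the measured CO2 rate on clean data", {
  st <- true_state_at(0.35)
  sol <- solve_fluxes(ref_network(), st$snapshot, st$drains,
                      mode = "redundancy")
  expect_lt(abs(sol$co2_residual), 1e-9)
  expect_lt(max(abs(sol$residuals)), 1e-9)
})

test_that("gross infeasibility is reported, not absorbed", {
  st <- true_state_at(0.35)
  snap <- st$snapshot
  snap$r_co2 <- snap$r_co2 * 3  # wildly inconsistent CO2 measurement
  expect_error(solve_fluxes(ref_network(), snap, st$drains),
               "infeasibility")
})

test_that("energy ledger closes and scales with the solution", {
  st <- true_state_at(0.40)
  net <- ref_network()
  sol <- solve_fluxes(net, st$snapshot, st$drains)
  led <- energy_ledger(net, sol, st$drains)
  # production = growth + spilling + other consumption
  expect_equal(led$atp_total, led$atp_growth + led$atp_spilling + led$atp_other,
               tolerance = 1e-6)
  for (fr in c("frac_atp_glycolysis", "frac_co2_tca", "frac_nadh_tca")) {
    expect_gte(led[[fr]], 0)
    expect_lte(led[[fr]], 1)
  }
  # zero solution -> zero ledger
  sol0 <- solve_fluxes(net, steady_state_snapshot(0, 0),
                       drain_fluxes(composition_at_mu(ref_comp_table(), 0.3), 0))
  led0 <- energy_ledger(net, sol0, numeric())
  expect_equal(led0$atp_total, 0)
  expect_equal(led0$atp_spilling, 0)
})

test_that("scaling all inputs by k scales every flux and ledger entry by k", {
  st <- true_state_at(0.30)
  net <- ref_network()
  k <- 1.7
  snap2 <- st$snapshot
  snap2$q_glc <- k * snap2$q_glc
  snap2$q_products <- k * snap2$q_products
  snap2$r_co2 <- k * snap2$r_co2
  sol1 <- solve_fluxes(net, st$snapshot, st$drains)
  sol2 <- solve_fluxes(net, snap2, k * st$drains)
  expect_equal(sol2$fluxes, k * sol1$fluxes, tolerance = 1e-10)
  led1 <- energy_ledger(net, sol1, st$drains)
  led2 <- energy_ledger(net, sol2, k * st$drains)
  expect_equal(led2$atp_total, k * led1$atp_total, tolerance = 1e-10)
  expect_equal(led2$atp_spilling, k * led1$atp_spilling, tolerance = 1e-10)
  expect_equal(led2$frac_co2_tca, led1$frac_co2_tca, tolerance = 1e-10)
})

test_that("changing the P/O ratio rescales only the oxidative ATP term", {
  st <- true_state_at(0.30)
  net2 <- build_default_network(po_ratio = 2)
  net4 <- build_default_network(po_ratio = 4)
  sol2 <- solve_fluxes(net2, st$snapshot, st$drains)
  sol4 <- solve_fluxes(net4, st$snapshot, st$drains)
  carbon <- setdiff(names(sol2$fluxes), c("ATPSPILL", "OXPHOS"))
  expect_identical(sol2$fluxes[carbon], sol4$fluxes[carbon])  # bit-identical
  expect_identical(sol2$fluxes["OXPHOS"], sol4$fluxes["OXPHOS"])
  led2 <- energy_ledger(net2, sol2, st$drains)
  led4 <- energy_ledger(net4, sol4, st$drains)
  ox2 <- 2 * sol2$fluxes[["OXPHOS"]]
  ox4 <- 4 * sol4$fluxes[["OXPHOS"]]
  expect_equal(ox4, 2 * ox2, tolerance = 1e-12)
  expect_equal(led4$atp_total - led2$atp_total, ox2, tolerance = 1e-9)
})

# deliberately drop the glyoxylate rule to exercise the rank diagnostics
solve_fluxes_missing_glx <- function(network, snapshot, drains) {
  S <- stoichiometric_matrix(network)
  ids <- colnames(S)
  fixed <- c(PTS = unname(snapshot$q_glc), drains)
  for (sp in names(coliflux:::.species_outflow))
    fixed[coliflux:::.species_outflow[[sp]]] <- snapshot$q_products[[sp]]
  fixed["ACS"] <- 0
  unknown <- setdiff(ids, names(fixed))
  A <- S[, unknown]
  qrA <- qr(A)
  if (qrA$rank < length(unknown)) {
    ns <- svd(A, nv = length(unknown))$v[
      , (qrA$rank + 1L):length(unknown), drop = FALSE]
    stop("underdetermined flux system; free direction(s) involve: ",
         paste(unknown[apply(abs(ns) > 1e-8, 1, any)], collapse = ", "))
  }
  invisible(NULL)
}

test_that("underdetermined systems are diagnosed with their free directions", {
  net <- ref_network()
  st <- true_state_at(0.30)
  # withholding the glyoxylate rule re-opens the shunt/TCA nullspace
  expect_error(
    solve_fluxes_missing_glx(net, st$snapshot, st$drains),
    "underdetermined.*GLX")
})

test_that("counterfactual rerouting preserves exported carbon and is null without wasting", {
  net <- ref_network()
  st <- true_state_at(0.47)
  rc <- reroute_counterfactual(net, st$snapshot, st$drains)
  # identical exported carbon between the paired solutions
  boundary_carbon <- function(sol, network) {
    cc <- stats::setNames(network$metabolites$carbon, network$metabolites$id)
    tot <- 0
    ext <- setdiff(network$metabolites$id[network$metabolites$external],
                   c("GLC.e", "BIO.C"))
    for (r in network$reactions)
      for (nm in intersect(names(r$stoich), ext))
        tot <- tot + r$stoich[[nm]] * cc[[nm]] * sol$fluxes[[r$id]]
    tot
  }
  net_cf <- net
  net_cf$metabolites <- rbind(net_cf$metabolites,
    data.frame(id = "PYRUVATE.e", name = "x", carbon = 3, cofactor = FALSE,
               external = TRUE))
  net_cf$reactions <- c(net_cf$reactions,
    list(reaction("OUT_PYR_CF", c(PYR = -1, PYRUVATE.e = 1), "outflow")))
  expect_equal(boundary_carbon(rc$base, net),
               boundary_carbon(rc$rerouted, net_cf), tolerance = 1e-9)
  expect_true(all(rc$summary > 0))
  # a snapshot without the rerouted products gives identical solutions
  snap0 <- st$snapshot
  snap0$q_products[c("lactate", "CBASP", "DHO", "orotate", "NAA")] <- 0
  sol0 <- solve_fluxes(net, snap0, st$drains, mode = "redundancy")
  rc0 <- reroute_counterfactual(net, snap0, st$drains, mode = "redundancy")
  common <- names(sol0$fluxes)
  expect_equal(rc0$rerouted$fluxes[common], rc0$base$fluxes[common],
               tolerance = 1e-9)
})
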