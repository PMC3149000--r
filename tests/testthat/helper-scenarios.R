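# Shared fixtures, computed once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

ref_network <- function() cached("network", build_default_network())

ref_comp_table <- function() cached("comp_table", default_composition_table())

# noise-free reference A-stat scenario (exact ground truth)
ref_astat_clean <- function() cached("astat_clean",
  generate_scenario(scenario_config("astat", noise_cv = 0),
                    network = ref_network(), comp_table = ref_comp_table()))

# reference A-stat scenario at the default 2 % measurement noise
ref_astat_noisy <- function() cached("astat_noisy",
  generate_scenario(scenario_config("astat", seed = 7L),
                    network = ref_network(), comp_table = ref_comp_table()))

# drains at a given growth rate, default composition
drains_at <- function(mu) drain_fluxes(composition_at_mu(ref_comp_table(), mu), mu)

# exact true state at one growth rate of the default A-stat conditions
true_state_at <- function(mu) {
  sc <- ref_astat_clean()
  i <- which.min(abs(sc$truth$mu - mu))
  list(snapshot = sc$truth$snapshots[[i]], fluxes = sc$truth$fluxes[i, ],
       drains = sc$truth$drains[[i]], mu = sc$truth$mu[i])
}

# independent brute-force oracle: dense least-squares solve of the full
# 50-flux system (balance rows + one unit row per fixed flux) via the
# SVD pseudo-inverse; shares no code path with solve_fluxes()
oracle_solve <- function(network, snapshot, drains, glx_fraction = 0.3,
                         co2_fixed = TRUE) {
  S <- stoichiometric_matrix(network)
  ids <- colnames(S)
  fixed <- c(PTS = unname(snapshot$q_glc),
             OUT_ACE = snapshot$q_products[["acetate"]],
             OUT_LAC = snapshot$q_products[["lactate"]],
             OUT_CBASP = snapshot$q_products[["CBASP"]],
             OUT_DHO = snapshot$q_products[["DHO"]],
             OUT_ORO = snapshot$q_products[["orotate"]],
             OUT_NAA = snapshot$q_products[["NAA"]],
             OUT_VPROD = snapshot$q_products[["Vprod"]],
             drains)
  fixed[if (snapshot$q_products[["acetate"]] > 0) "ACS" else "PTA"] <- 0
  q_ace <- snapshot$q_products[["acetate"]]
  fixed["GLX"] <- if (q_ace < 0) glx_fraction * (-q_ace) else 0
  if (co2_fixed) fixed["OUT_CO2"] <- snapshot$r_co2
  unit_rows <- t(vapply(names(fixed), function(id) {
    e <- numeric(length(ids)); names(e) <- ids; e[id] <- 1; e
  }, numeric(length(ids))))
  A <- rbind(S, unit_rows)
  b <- c(numeric(nrow(S)), unname(fixed))
  sv <- svd(A)
  keep <- sv$d > 1e-10 * max(sv$d)
  v <- sv$v[, keep] %*% ((t(sv$u[, keep]) %*% b) / sv$d[keep])
  stats::setNames(as.vector(v), ids)
}

# random feasible snapshot: multiplicative perturbation of a true state,
# with the CO2 rate taken from the carbon bookkeeping (square solve with the
# CO2 transport free) so that an exactly balanced flux vector exists
random_feasible_snapshot <- function(mu, spread = 0.2) {
  st <- true_state_at(mu)
  s <- st$snapshot
  s$q_glc <- s$q_glc * stats::runif(1, 1 - spread, 1 + spread)
  s$q_products <- s$q_products * stats::runif(7, 1 - spread, 1 + spread)
  sq <- solve_fluxes(ref_network(), s, st$drains, mode = "redundancy")
  s$r_co2 <- unname(sq$fluxes["OUT_CO2"])
  list(snapshot = s, drains = st$drains)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
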