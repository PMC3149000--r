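#' @title Synthetic continuous-cultivation scenarios with known ground truth
#' @name synthetic_data
#' @description
#' Generates chemostat, A-stat (accelerostat) and D-stat time series whose
#' physiology follows the qualitative profiles of glucose-limited E. coli
#' K-12 MG1655 cultures: two-phase acetate overflow starting near mu = 0.27
#' 1/h with faster accumulation after mu = 0.46 1/h, three-phase excretion
#' of the pyrimidine-pathway intermediates (carbamoyl-aspartate and
#' dihydroorotate rise until overflow onset; dihydroorotate then declines
#' while orotate and carbamoyl-aspartate level off and rise again in the
#' fast-accumulation phase), N-acetyl-aspartate rising with growth rate,
#' total by-product carbon wasting growing from about 3 to 11 percent of
#' consumed carbon over the ramp at constant biomass yield, and
#' dilution-rate-repressed glucose/acetate co-utilisation in D-stat. Every
#' generated state carries an exactly balanced ground-truth flux vector, so
#' the rate calculations, the flux solver and the carbon/energy summaries
#' can all be validated without any measured data.
NULL

#' Scenario configuration
#'
#' Profile breakpoints are the growth rates at which the emulated physiology
#' changes phase; fractions are shares of consumed carbon.
#'
#' @param regime `"astat"`, `"dstat"` or `"chemostat"`.
#' @param acceleration A-stat dilution-rate acceleration (1/h^2).
#' @param mu_range Growth-rate span of the ramp (1/h).
#' @param overflow_onset_mu Growth rate where acetate excretion starts (1/h).
#' @param fast_accumulation_mu Growth rate where the second, faster acetate
#'   phase and the renewed orotate/carbamoyl-aspartate rise begin (1/h).
#' @param pdh_saturation_mu Growth rate of maximum pyruvate-dehydrogenase
#'   throughput in the emulated profiles (1/h); shapes the Vprod curve.
#' @param wasting_start_frac,wasting_end_frac Total by-product carbon
#'   wasting at the start and end of the A-stat ramp.
#' @param dstat_wasting_plateau Summed non-acetate wasting fraction in
#'   D-stat, independent of co-utilisation capability.
#' @param coutilisation_capability Glucose-acetate co-utilisation capability
#'   in `[0, 1]` (D-stat).
#' @param dilution_rate Dilution rate (1/h) for chemostat/D-stat regimes.
#' @param yxs Biomass yield on glucose, g DCW per g (constant over mu).
#' @param feed_glc Feed glucose (mM); 25 mM = 4.5 g/L.
#' @param noise_cv Multiplicative log-normal measurement noise CV.
#' @param dt Sampling interval (h).
#' @param duration D-stat/chemostat duration (h); A-stat duration follows
#'   from `mu_range` and `acceleration`.
#' @param seed Integer RNG seed for the noise realisation.
#' @return A list of class `"ScenarioConfig"`.
#' @export
scenario_config <- function(regime = c("astat", "dstat", "chemostat"),
                            acceleration = 0.01,
                            mu_range = c(0.10, 0.48),
                            overflow_onset_mu = 0.27,
                            fast_accumulation_mu = 0.46,
                            pdh_saturation_mu = 0.42,
                            wasting_start_frac = 0.03,
                            wasting_end_frac = 0.11,
                            dstat_wasting_plateau = 0.055,
                            coutilisation_capability = 0.5,
                            dilution_rate = 0.30,
                            yxs = 0.45, feed_glc = 25,
                            noise_cv = 0.02, dt = 0.25, duration = 24,
                            seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(acceleration > 0, mu_range[1] > 0, mu_range[2] > mu_range[1],
            overflow_onset_mu < fast_accumulation_mu,
            wasting_start_frac >= 0, wasting_start_frac <= 1,
            wasting_end_frac >= 0, wasting_end_frac <= 1,
            coutilisation_capability >= 0, coutilisation_capability <= 1,
            noise_cv >= 0, yxs > 0)
  structure(as.list(environment()), class = "ScenarioConfig")
}

# smooth hinge: 0 below x0, ~linear above, quadratically smoothed over w
# residual broth glucose under strong limitation (mM)
.resid_glc <- 0.05

.hinge <- function(x, x0, w = 0.01) {
  d <- x - x0
  ifelse(d <= 0, 0, ifelse(d < w, d^2 / (2 * w), d - w / 2))
}

# logistic transition centred at x0 with width k
.lgs <- function(x, x0, k = 0.012) 1 / (1 + exp(-(x - x0) / k))

# per-species carbon-wasting fraction profiles for the growth-rate ramp.
# Returns fractions of consumed carbon for each by-product at mu.
.wasting_fractions <- function(mu, cfg) {
  on <- cfg$overflow_onset_mu
  fast <- cfg$fast_accumulation_mu
  lo <- cfg$mu_range[1]; hi <- cfg$mu_range[2]
  rise <- function(mu) pmin(1, pmax(0, (mu - lo) / (on - lo)))  # 0->1 up to onset
  # pyrimidine intermediates: three-phase pattern
  cbasp <- 0.010 + 0.006 * rise(mu) + 0.006 * .hinge(mu, fast) / max(hi - fast, 1e-6)
  dho <- (0.008 + 0.006 * rise(mu)) * (1 - 0.7 * .lgs(mu, on + 0.02))
  oro <- 0.007 + 0.004 * rise(mu) + 0.005 * .hinge(mu, fast) / max(hi - fast, 1e-6)
  lac <- 0.004 + 0.003 * (mu - lo) / (hi - lo)
  naa <- 0.008 * .hinge(mu, 0.22) / max(hi - 0.22, 1e-6)
  # normalise the non-acetate group so its sum at the ramp start equals the
  # configured starting wasting fraction
  base_lo <- 0.010 + 0.008 + 0.007 + 0.004  # cbasp+dho+oro+lac at mu = lo
  sc <- cfg$wasting_start_frac / base_lo
  w <- cbind(CBASP = cbasp, DHO = dho, orotate = oro, lactate = lac,
             NAA = naa) * sc
  # two-phase acetate closes the total to wasting_end_frac at the ramp top
  nonace_hi <- sum(.nonace_at(hi, cfg, sc))
  a_hi <- max(cfg$wasting_end_frac - nonace_hi, 0)
  s1 <- 0.7 * a_hi / max(hi - on, 1e-6)
  s2 <- 0.3 * a_hi / max(hi - fast, 1e-6)^2
  ace <- s1 * .hinge(mu, on, w = 0.005) + s2 * pmax(mu - fast, 0)^2
  cbind(w, acetate = ace,
        Vprod = 0.006 * rise(mu) * (1 - 0.6 * .lgs(mu, cfg$pdh_saturation_mu)))
}

.nonace_at <- function(mu, cfg, sc) {
  on <- cfg$overflow_onset_mu; fast <- cfg$fast_accumulation_mu
  lo <- cfg$mu_range[1]; hi <- cfg$mu_range[2]
  rise <- min(1, max(0, (mu - lo) / (on - lo)))
  c(0.010 + 0.006 * rise + 0.006 * .hinge(mu, fast) / max(hi - fast, 1e-6),
    (0.008 + 0.006 * rise) * (1 - 0.7 * .lgs(mu, on + 0.02)),
    0.007 + 0.004 * rise + 0.005 * .hinge(mu, fast) / max(hi - fast, 1e-6),
    0.004 + 0.003 * (mu - lo) / (hi - lo),
    0.008 * .hinge(mu, 0.22) / max(hi - 0.22, 1e-6)) * sc
}

# maximum specific acetate uptake capacity (mmol/gDCW/h): scales with the
# co-utilisation capability and is repressed with rising dilution rate
.acetate_capacity <- function(cap, D) {
  cap * 2.5 * max(0, 1 - D / 0.55)
}

# build the exactly balanced true state at one growth rate
.true_state <- function(mu, cfg, network, comp_table, q_ace_uptake = 0,
                        dstat = FALSE) {
  comp <- composition_at_mu(comp_table, mu)
  drains <- drain_fluxes(comp, mu)
  q_glc <- mu / (cfg$yxs * 0.18016) - q_ace_uptake / 3
  if (q_glc <= 0) stop("config infeasible: non-positive glucose uptake")
  denom <- 6 * q_glc + 2 * q_ace_uptake
  w <- .wasting_fractions(mu, cfg)[1, ]
  if (dstat) {
    # in D-stat the summed non-acetate wasting sits at the configured
    # plateau regardless of dilution rate or co-utilisation capability
    nonace <- c("CBASP", "DHO", "orotate", "lactate", "NAA")
    w[nonace] <- w[nonace] * cfg$dstat_wasting_plateau / sum(w[nonace])
    w["acetate"] <- 0
  }
  cc <- c(CBASP = 5, DHO = 5, orotate = 5, lactate = 3, NAA = 6,
          acetate = 2, Vprod = 4)
  qp <- denom * w / cc[names(w)]
  if (q_ace_uptake > 0) qp["acetate"] <- -q_ace_uptake
  snap <- steady_state_snapshot(mu, q_glc, qp)
  sol <- .generator_solve(network, snap, drains)
  snap$r_co2 <- unname(sol$fluxes["OUT_CO2"])
  snap$biomass_yield <- mu / (q_glc * 0.18016)
  list(snapshot = snap, fluxes = sol$fluxes, drains = drains)
}

# square generator solve: CO2 transport left free (redundancy wiring)
.generator_solve <- function(network, snap, drains) {
  sol <- solve_fluxes(network, snap, drains, mode = "redundancy")
  bad <- sol$sign_violations
  if (length(bad))
    stop("config infeasible: no sign-feasible flux vector (",
         paste(bad, collapse = ", "), ")")
  sol
}

#' Generate a synthetic cultivation scenario
#'
#' Builds the growth-rate schedule of the chosen regime, constructs exactly
#' balanced ground-truth flux vectors at each sampling time by solving the
#' network forward from the configured physiology profiles, converts them to
#' concentration time series through the inverse of the dilution balances
#' (integrating the broth mass balances for the A-stat ramp), and applies
#' seeded multiplicative log-normal noise to the observed columns.
#'
#' @param config A [scenario_config()].
#' @param network Flux model (default [build_default_network()]).
#' @param comp_table Composition table (default
#'   [default_composition_table()]).
#' @return List of class `"CultureScenario"`: `series` (the observed
#'   time-series data.frame in the format of [read_timeseries()]), `truth`
#'   (noise-free snapshots, drain vectors and the 50-flux ground-truth
#'   matrix per time point) and `config`.
#' @export
generate_scenario <- function(config, network = build_default_network(),
                              comp_table = default_composition_table()) {
  stopifnot(inherits(config, "ScenarioConfig"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  if (config$regime == "astat") {
    duration <- (config$mu_range[2] - config$mu_range[1]) / config$acceleration
    time <- seq(0, duration, by = config$dt)
    D <- config$mu_range[1] + config$acceleration * time
    ace_feed <- rep(0, length(time))
    uptake <- rep(0, length(time))
  } else if (config$regime == "chemostat") {
    time <- seq(0, config$duration, by = config$dt)
    D <- rep(config$dilution_rate, length(time))
    ace_feed <- rep(0, length(time))
    uptake <- rep(0, length(time))
  } else {  # dstat: acetate feed ramps at constant dilution rate
    time <- seq(0, config$duration, by = config$dt)
    D <- rep(config$dilution_rate, length(time))
    ace_feed <- 30 * time / max(time)
    uptake <- numeric(length(time))  # filled below (needs biomass)
  }

  n <- length(time)
  states <- vector("list", n)
  for (i in seq_len(n)) {
    up <- 0
    if (config$regime == "dstat" && ace_feed[i] > 0) {
      # supply-limited uptake consistent with the biomass that uptake itself
      # produces (X = D feed_glc / q_glc, q_glc = mu/(Yxs Mglc) - up/3):
      # complete consumption of the fed acetate gives
      # up = a feed_ace / (feed_glc + feed_ace/3), a = mu/(Yxs Mglc);
      # the repressible capacity caps it, leaving residual broth acetate
      a <- D[i] / (config$yxs * 0.18016)
      supply <- a * ace_feed[i] / ((config$feed_glc - .resid_glc) + ace_feed[i] / 3)
      up <- min(supply,
                .acetate_capacity(config$coutilisation_capability, D[i]))
    }
    states[[i]] <- .true_state(D[i], config, network, comp_table,
                               q_ace_uptake = up,
                               dstat = config$regime == "dstat")
    uptake[i] <- up
  }

  fluxes <- do.call(rbind, lapply(states, `[[`, "fluxes"))
  rownames(fluxes) <- NULL
  snaps <- lapply(states, `[[`, "snapshot")
  mus <- vapply(snaps, `[[`, 0, "mu")

  # biomass follows from the stationary glucose balance
  resid_glc <- .resid_glc
  X <- vapply(seq_len(n), function(i)
    D[i] * (config$feed_glc - resid_glc) / snaps[[i]]$q_glc, numeric(1))

  species <- c("acetate", "lactate", "CBASP", "DHO", "orotate", "NAA")
  qmat <- vapply(species, function(sp)
    vapply(snaps, function(s) s$q_products[[sp]], numeric(1)),
    numeric(n))
  conc <- matrix(0, n, length(species), dimnames = list(NULL, species))
  if (config$regime == "astat" && n > 1) {
    # integrate broth balances dP/dt = qP X - D P along the ramp
    for (k in seq_along(species)) {
      qf <- stats::approxfun(time, qmat[, k] * X, rule = 2)
      Df <- stats::approxfun(time, D, rule = 2)
      feedf <- stats::approxfun(time,
        if (species[k] == "acetate") ace_feed else rep(0, n), rule = 2)
      out <- deSolve::ode(
        y = c(P = 0), times = time,
        func = function(t, y, p) list(qf(t) + Df(t) * (feedf(t) - y[1])),
        method = "lsoda")
      conc[, k] <- pmax(out[, "P"], 0)
    }
  } else {
    # stationary balances at each sampling time (slow feed ramp)
    for (k in seq_along(species)) {
      feed <- if (species[k] == "acetate") ace_feed else rep(0, n)
      conc[, k] <- pmax(feed + qmat[, k] * X / D, 0)
    }
  }

  r_co2 <- vapply(snaps, `[[`, 0, "r_co2")
  noise <- function(v) v * exp(stats::rnorm(length(v), 0, config$noise_cv))
  series <- data.frame(
    time = time, dilution_rate = D,
    biomass = noise(X),
    feed_glc = config$feed_glc, feed_ace = ace_feed,
    glc = noise(rep(resid_glc, n)),
    ace = noise(conc[, "acetate"]), lac = noise(conc[, "lactate"]),
    cbasp = noise(conc[, "CBASP"]), dho = noise(conc[, "DHO"]),
    oro = noise(conc[, "orotate"]), naa = noise(conc[, "NAA"]),
    co2_rate = noise(r_co2 * X)
  )
  structure(list(series = series,
                 truth = list(time = time, mu = mus, snapshots = snaps,
                              fluxes = fluxes,
                              drains = lapply(states, `[[`, "drains"),
                              biomass = X),
                 config = config),
            class = "CultureScenario")
}

#' Measured rates implied by a balanced flux vector
#'
#' The inverse of the solver's input mapping: reads the boundary fluxes of a
#' full 50-flux vector back into a measurement snapshot. Errors if the
#' vector does not satisfy the metabolite balances.
#'
#' @param flux A `FluxSolution` or named 50-flux vector.
#' @param mu Growth rate to stamp on the snapshot (1/h).
#' @param X Biomass concentration (g DCW/L), optional bookkeeping.
#' @param network The network the fluxes refer to.
#' @param tol Balance tolerance.
#' @return A `SteadyStateSnapshot`.
#' @export
forward_simulate <- function(flux, mu, X = NA_real_,
                             network = build_default_network(), tol = 1e-6) {
  v <- if (inherits(flux, "FluxSolution")) flux$fluxes else flux
  S <- stoichiometric_matrix(network)
  v <- v[colnames(S)]
  if (anyNA(v)) stop("flux vector does not cover the network's reactions")
  resid <- max(abs(S %*% v))
  if (resid > tol)
    stop("imbalanced flux input (max residual ", format(resid), ")")
  qp <- vapply(names(.species_outflow), function(sp)
    unname(v[.species_outflow[[sp]]]), numeric(1))
  steady_state_snapshot(mu, q_glc = unname(v["PTS"]), q_products = qp,
                        r_co2 = unname(v["OUT_CO2"]), biomass = X)
}
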