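#' @title End-to-end analysis pipeline
#' @name pipeline
#' @description
#' `run_pipeline()` chains the stages: time series -> quasi-steady
#' snapshots on a growth-rate grid -> flux solutions -> energy ledgers ->
#' carbon balances and wasting profile, optionally writing every result as
#' a delimited table with units in the headers plus a run log of thresholds
#' and residual diagnostics.
NULL

#' Run the full analysis over a growth-rate grid
#'
#' @param series Cultivation time series ([read_timeseries()] format) or a
#'   `CultureScenario` (its observed `series` is used).
#' @param mu_grid Growth rates (1/h) at which to take snapshots; for
#'   chemostat/D-stat regimes each grid value selects the time window where
#'   the (slowly ramping) state passes that growth rate — for a plain
#'   chemostat give one value.
#' @param regime `"astat"`, `"chemostat"` or `"dstat"` (D-stat snapshots use
#'   the chemostat balances over short windows of the feed ramp).
#' @param network Flux model (default [build_default_network()]).
#' @param comp_table Composition table (default
#'   [default_composition_table()]).
#' @param mode Solver mode, `"constraint"` or `"redundancy"`.
#' @param glx_fraction Glyoxylate-shunt share of acetate assimilation.
#' @param out_dir Optional directory for the result tables
#'   (`fluxes.tsv`, `ledger.tsv`, `balance.tsv`, `wasting.tsv`,
#'   `run_log.txt`).
#' @param window_h Window half-width (h) for chemostat/D-stat windows.
#' @return List of class `"PipelineBundle"`: `snapshots`, `solutions`,
#'   `ledgers`, `balances`, `wasting` (data.frame), `flux_table`
#'   (long-format data.frame), `log` (character).
#' @export
run_pipeline <- function(series, mu_grid,
                         regime = c("astat", "chemostat", "dstat"),
                         network = build_default_network(),
                         comp_table = default_composition_table(),
                         mode = c("constraint", "redundancy"),
                         glx_fraction = 0.3,
                         out_dir = NULL, window_h = 1) {
  regime <- match.arg(regime)
  mode <- match.arg(mode)
  if (inherits(series, "CultureScenario")) series <- series$series
  log <- c(sprintf("coliflux pipeline | regime=%s mode=%s glx_fraction=%.2f",
                   regime, mode, glx_fraction),
           sprintf("snapshots at mu = %s", paste(mu_grid, collapse = ", ")))

  snapshots <- if (regime == "astat") {
    astat_snapshots(series, mu_grid)
  } else {
    lapply(mu_grid, function(mu) {
      if (regime == "chemostat") {
        specific_rates_chemostat(series)
      } else {
        # D-stat: the dilution rate is fixed; mu indexes the feed ramp only
        # through time windows, so interpret the grid as window centres
        t0 <- mu  # for dstat the grid is in hours along the ramp
        win <- c(max(min(series$time), t0 - window_h),
                 min(max(series$time), t0 + window_h))
        specific_rates_chemostat(series, window = win, drift_tol = 0.25)
      }
    })
  }

  solutions <- list(); ledgers <- list(); balances <- list()
  flux_rows <- list()
  for (i in seq_along(snapshots)) {
    snap <- snapshots[[i]]
    comp <- composition_at_mu(comp_table, snap$mu)
    drains <- drain_fluxes(comp, snap$mu)
    sol <- solve_fluxes(network, snap, drains, mode = mode,
                        glx_fraction = glx_fraction)
    led <- energy_ledger(network, sol, drains)
    bal <- carbon_balance(snap, biomass_carbon(comp, network))
    solutions[[i]] <- sol; ledgers[[i]] <- led; balances[[i]] <- bal
    flux_rows[[i]] <- data.frame(
      mu = snap$mu, reaction = names(sol$fluxes),
      flux_mmol_gDCW_h = unname(sol$fluxes),
      status = unname(sol$fixed_mask))
    log <- c(log, sprintf(
      "mu=%.3f regime=%s max|residual|=%.3e condition=%.1f%s",
      snap$mu, sol$regime, max(abs(sol$residuals)),
      sol$condition_diagnostic,
      if (length(sol$sign_violations))
        paste0(" sign_violations=", paste(sol$sign_violations, collapse = "/"))
      else ""))
  }

  wasting <- wasting_profile(balances,
    species = if (regime == "dstat")
      c("lactate", "NAA", "orotate", "DHO", "CBASP")
    else c("acetate", "lactate", "NAA", "orotate", "DHO", "CBASP"))

  bundle <- structure(list(
    snapshots = snapshots, solutions = solutions, ledgers = ledgers,
    balances = balances, wasting = wasting,
    flux_table = do.call(rbind, flux_rows), log = log
  ), class = "PipelineBundle")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) utils::write.table(
      d, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
    wt(bundle$flux_table, "fluxes.tsv")
    wt(ledger_table(bundle), "ledger.tsv")
    wt(balance_table(bundle), "balance.tsv")
    wt(bundle$wasting, "wasting.tsv")
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  bundle
}

#' Energy-ledger table of a pipeline bundle
#' @param bundle A `PipelineBundle`.
#' @return data.frame, one row per snapshot (rates mmol/gDCW/h; the
#'   `_specific` column mmol/gDCW).
#' @export
ledger_table <- function(bundle) {
  do.call(rbind, lapply(bundle$ledgers, function(l)
    data.frame(mu = l$mu, atp_total = l$atp_total, atp_growth = l$atp_growth,
               atp_spilling = l$atp_spilling,
               atp_spilling_specific = l$atp_spilling_specific,
               frac_atp_glycolysis = l$frac_atp_glycolysis,
               frac_co2_tca = l$frac_co2_tca,
               frac_nadh_tca = l$frac_nadh_tca)))
}

#' Carbon-balance table of a pipeline bundle
#' @param bundle A `PipelineBundle`.
#' @return data.frame, one row per snapshot (fractions of consumed carbon).
#' @export
balance_table <- function(bundle) {
  do.call(rbind, lapply(bundle$balances, function(b)
    cbind(data.frame(mu = b$mu, frac_biomass = b$frac_biomass,
                     frac_co2 = b$frac_co2, gap = b$gap),
          as.data.frame(t(b$frac_products)))))
}

#' Compare per-biomass by-product production against a reference table
#'
#' Reproduces the layout of an A-stat vs chemostat by-product comparison:
#' per-biomass production O_x = q_x / mu (mmol per g DCW) for each species
#' at matched growth rates, with absolute and relative differences.
#'
#' @param bundle A `PipelineBundle` (or a list of `SteadyStateSnapshot`s).
#' @param reference data.frame with columns `species`, `mu`, `value`
#'   (mmol per g DCW), e.g. from [read_byproduct_reference()].
#' @return data.frame: `species`, `mu`, `reference`, `computed`,
#'   `abs_diff`, `rel_diff`.
#' @export
compare_snapshots <- function(bundle, reference) {
  snaps <- if (inherits(bundle, "PipelineBundle")) bundle$snapshots else bundle
  mus <- vapply(snaps, `[[`, 0, "mu")
  rows <- lapply(seq_len(nrow(reference)), function(i) {
    r <- reference[i, ]
    j <- which(abs(mus - r$mu) < 1e-6)
    if (!length(j))
      stop("no snapshot at mu = ", r$mu, " to match the reference")
    s <- snaps[[j[1]]]
    computed <- s$q_products[[as.character(r$species)]] / s$mu
    data.frame(species = r$species, mu = r$mu, reference = r$value,
               computed = computed, abs_diff = computed - r$value,
               rel_diff = if (!is.na(r$value) && r$value != 0)
                 (computed - r$value) / r$value else NA_real_)
  })
  do.call(rbind, rows)
}

#' Read the bundled by-product reference table
#'
#' Loads the measured A-stat/chemostat per-biomass by-product production
#' reference shipped with the package (printed literature values; mmol per
#' g DCW) into the long format [compare_snapshots()] expects.
#'
#' @param path Reference file; default the bundled
#'   `table1_byproducts.tsv`.
#' @param source `"chemostat"` or `"astat"` column set to read.
#' @return data.frame with `species`, `mu`, `value` (and `sd` for A-stat).
#' @export
read_byproduct_reference <- function(
    path = system.file("extdata", "table1_byproducts.tsv",
                       package = "coliflux"),
    source = c("chemostat", "astat")) {
  source <- match.arg(source)
  d <- utils::read.delim(path, comment.char = "#")
  out <- data.frame(species = d$species, mu = d$mu,
                    value = if (source == "chemostat") d$chemostat
                            else d$astat_mean)
  if (source == "astat") out$sd <- d$astat_sd
  out
}
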