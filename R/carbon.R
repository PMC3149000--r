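#' Fractional carbon recovery for one snapshot
#'
#' Carbon in = 6 x glucose uptake + 2 x acetate uptake (when acetate is
#' co-consumed, D-stat); recoveries are the biomass, CO2 and per-product
#' carbon flows as fractions of carbon in; consumed species never appear as
#' negative recoveries (they enter the denominator instead). The identity
#' sum(recoveries) + gap = 1 holds exactly by construction.
#'
#' @param snapshot A `SteadyStateSnapshot` with `q_glc > 0`.
#' @param biomass_carbon Biomass carbon content, mmol C per g DCW (from
#'   [biomass_carbon()]).
#' @return Object of class `"CarbonBalance"`: `mu`, `frac_biomass`,
#'   `frac_co2`, `frac_products` (named), `gap`.
#' @export
carbon_balance <- function(snapshot, biomass_carbon) {
  if (snapshot$q_glc <= 0) stop("carbon balance requires glucose uptake > 0")
  q_ace <- snapshot$q_products[["acetate"]]
  denom <- 6 * snapshot$q_glc + 2 * max(-q_ace, 0)
  fp <- vapply(names(snapshot$q_products), function(sp) {
    q <- snapshot$q_products[[sp]]
    if (q > 0) carbon_count(sp) * q / denom else 0
  }, numeric(1))
  fb <- unname(snapshot$mu * biomass_carbon / denom)
  fc <- unname(snapshot$r_co2 / denom)
  recovered <- fb + fc + sum(fp)  # gap defined off this sum => identity exact
  structure(list(mu = snapshot$mu, frac_biomass = fb,
                 frac_co2 = fc, frac_products = fp,
                 gap = 1 - recovered),
            class = "CarbonBalance")
}

#' @export
print.CarbonBalance <- function(x, ...) {
  cat(sprintf(
    "CarbonBalance (mu=%.3f): biomass %.1f%%, CO2 %.1f%%, products %.1f%%, gap %.1f%%\n",
    x$mu, 100 * x$frac_biomass, 100 * x$frac_co2,
    100 * sum(x$frac_products), 100 * x$gap))
  invisible(x)
}

#' Carbon wasting profile across a growth-rate ramp
#'
#' Long-format table of per-species wasting fractions (share of carbon in)
#' against growth rate, plus the summed wasting over a chosen species set.
#'
#' @param balances List of `CarbonBalance` objects (>= 2), e.g. one per
#'   snapshot of a ramp.
#' @param species Species counted into `total_wasting`; default the six
#'   by-products of the growth-rate ramp (acetate, lactate, NAA, orotate,
#'   DHO, CBASP). Use the five non-acetate species for co-utilisation
#'   experiments where acetate is a substrate.
#' @return data.frame with `mu`, one column per product species, and
#'   `total_wasting`.
#' @export
wasting_profile <- function(balances,
                            species = c("acetate", "lactate", "NAA",
                                        "orotate", "DHO", "CBASP")) {
  if (length(balances) < 2L) stop("need at least 2 balances")
  rows <- lapply(balances, function(b) {
    out <- as.data.frame(t(b$frac_products))
    out$mu <- b$mu
    out$total_wasting <- sum(b$frac_products[species])
    out
  })
  d <- do.call(rbind, rows)
  d[, c("mu", setdiff(names(d), c("mu", "total_wasting")), "total_wasting")]
}
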