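#' One physiological steady (or quasi-steady) state
#'
#' Collects the measured specific rates that feed one flux solve: growth
#' rate, glucose uptake, by-product excretion/consumption and CO2 evolution.
#' Sign convention: `q_glc` is uptake, positive; product rates are excretion
#' positive, consumption negative (acetate is consumed in D-stat
#' co-utilisation).
#'
#' @param mu Specific growth rate (1/h).
#' @param q_glc Specific glucose uptake rate (mmol per g DCW per h, >= 0).
#' @param q_products Named numeric vector over (a subset of) `acetate,
#'   lactate, CBASP, DHO, orotate, NAA, Vprod`; missing species count as 0.
#' @param r_co2 Specific CO2 evolution rate (mmol per g DCW per h).
#' @param biomass Optional biomass concentration (g DCW/L) the snapshot was
#'   derived at.
#' @return Object of class `"SteadyStateSnapshot"` with `biomass_yield`
#'   (g DCW per g glucose) computed from `mu` and `q_glc`.
#' @export
steady_state_snapshot <- function(mu, q_glc, q_products = numeric(), r_co2 = 0,
                                  biomass = NA_real_) {
  stopifnot(mu >= 0, q_glc >= 0)
  species <- c("acetate", "lactate", "CBASP", "DHO", "orotate", "NAA", "Vprod")
  qp <- stats::setNames(numeric(length(species)), species)
  if (length(q_products)) {
    unknown <- setdiff(names(q_products), species)
    if (length(unknown))
      stop("unknown product species: ", paste(unknown, collapse = ", "))
    qp[names(q_products)] <- q_products
  }
  structure(
    list(mu = mu, q_glc = q_glc, q_products = qp, r_co2 = r_co2,
         biomass = biomass,
         biomass_yield = if (q_glc > 0) mu / (q_glc * 0.18016) else NA_real_),
    class = "SteadyStateSnapshot"
  )
}

#' @export
print.SteadyStateSnapshot <- function(x, ...) {
  cat(sprintf(
    "SteadyStateSnapshot: mu=%.3f 1/h, q_glc=%.3f, r_CO2=%.3f mmol/gDCW/h, Yxs=%.3f g/g\n",
    x$mu, x$q_glc, x$r_co2, x$biomass_yield))
  nz <- x$q_products[x$q_products != 0]
  if (length(nz))
    cat("  products:", paste(names(nz), signif(nz, 4), sep = "=",
                             collapse = ", "), "\n")
  invisible(x)
}

# outflow reaction id for each measured species
.species_outflow <- c(acetate = "OUT_ACE", lactate = "OUT_LAC",
                      CBASP = "OUT_CBASP", DHO = "OUT_DHO",
                      orotate = "OUT_ORO", NAA = "OUT_NAA",
                      Vprod = "OUT_VPROD")
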