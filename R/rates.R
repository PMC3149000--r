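#' @title Specific rates from cultivation time series
#' @name rates
#' @description
#' Converts broth concentration time series of continuous cultivations into
#' biomass-specific rates. For a chemostat at steady state the balances
#' reduce to algebra in the dilution rate; for an A-stat ramp the
#' quasi-steady balances keep the accumulation terms, with derivatives
#' estimated by centred local linear regression. Units throughout:
#' concentrations mM, biomass g DCW/L, dilution rate 1/h, specific rates
#' mmol per g DCW per h.
NULL

# observed column -> snapshot species
.ts_species <- c(ace = "acetate", lac = "lactate", cbasp = "CBASP",
                 dho = "DHO", oro = "orotate", naa = "NAA")

#' Read / write the cultivation time-series text format
#'
#' Tab-delimited with header: `time` (h), `dilution_rate` (1/h), `biomass`
#' (g DCW/L), `feed_glc`, `feed_ace` (mM in feed), `glc`, `ace`, `lac`,
#' `cbasp`, `dho`, `oro`, `naa` (mM in broth), `co2_rate` (volumetric CO2
#' evolution, mmol/L/h). Missing values are linearly interpolated with a
#' message reporting the count.
#'
#' @param path File path.
#' @param series Time-series data.frame (for the writer).
#' @return `read_timeseries()`: a validated data.frame;
#'   `write_timeseries()`: invisibly `path`.
#' @export
read_timeseries <- function(path) {
  d <- utils::read.delim(path, comment.char = "#")
  need <- c("time", "dilution_rate", "biomass", "feed_glc", "feed_ace",
            "glc", "ace", "lac", "cbasp", "dho", "oro", "naa", "co2_rate")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("time series lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.unsorted(d$time, strictly = TRUE))
    stop("time must be strictly increasing")
  n_na <- sum(is.na(d[need]))
  if (n_na > 0) {
    message("interpolating ", n_na, " missing value(s)")
    for (cn in need) if (anyNA(d[[cn]]))
      d[[cn]] <- stats::approx(d$time[!is.na(d[[cn]])],
                               d[[cn]][!is.na(d[[cn]])],
                               xout = d$time, rule = 2)$y
  }
  d
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# coliflux time series: time h | dilution_rate 1/h | biomass gDCW/L |",
    "# feed/broth concentrations mM | co2_rate mmol/L/h"), con)
  utils::write.table(series, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# centred local linear regression derivative and fitted value; near the
# series edges the window is one-sided, where a plain linear fit is biased
# for curved signals, so a quadratic term is added there (standard local
# polynomial boundary correction)
.local_fit <- function(time, y, t0, window = 11L) {
  i0 <- which.min(abs(time - t0))
  half <- (window - 1L) %/% 2L
  truncated <- (i0 - half < 1L) || (i0 + half > length(time))
  if (truncated) half <- 2L * half  # widen the one-sided window
  idx <- max(1L, i0 - half):min(length(time), i0 + half)
  dt <- time[idx] - t0
  X <- if (truncated && length(idx) >= 4L) cbind(1, dt, dt^2) else cbind(1, dt)
  fit <- stats::lm.fit(X, y[idx])
  c(value = unname(fit$coefficients[1]), slope = unname(fit$coefficients[2]))
}

#' Specific rates of a chemostat window
#'
#' Steady-state balances: mu = D, q_S = D (S_feed - S) / X, q_P = D P / X,
#' r_CO2 = CER / X, averaged over the window. Stationarity of every species
#' is asserted: relative drift across the window above `drift_tol` raises an
#' error naming the species.
#'
#' @param series Time-series data.frame ([read_timeseries()] format).
#' @param window Numeric length-2 time interval (h); default the whole series.
#' @param drift_tol Maximum tolerated relative concentration drift (default
#'   0.05).
#' @return A `SteadyStateSnapshot`.
#' @export
specific_rates_chemostat <- function(series, window = range(series$time),
                                     drift_tol = 0.05) {
  idx <- series$time >= window[1] & series$time <= window[2]
  if (sum(idx) < 2L) stop("window contains fewer than 2 samples")
  d <- series[idx, ]
  if (max(d$dilution_rate) - min(d$dilution_rate) > 1e-9 * max(1, mean(d$dilution_rate)))
    stop("dilution rate not constant over window")
  for (cn in c("biomass", "glc", names(.ts_species))) {
    m <- mean(d[[cn]])
    scale_ref <- max(m, 0.02 * mean(d$feed_glc))  # ignore near-zero traces
    if ((max(d[[cn]]) - min(d[[cn]])) > drift_tol * 2 * scale_ref)
      stop("non-stationary concentration over window: ", cn)
  }
  D <- mean(d$dilution_rate); X <- mean(d$biomass)
  qp <- vapply(names(.ts_species), function(cn)
    D * mean(d[[cn]] - (if (cn == "ace") d$feed_ace else 0)) / X, numeric(1))
  names(qp) <- .ts_species
  steady_state_snapshot(
    mu = D,
    q_glc = max(0, D * mean(d$feed_glc - d$glc) / X),
    q_products = qp,
    r_co2 = mean(d$co2_rate) / X,
    biomass = X)
}

#' Specific rates of an A-stat at one time point
#'
#' Quasi-steady balances with accumulation terms:
#' mu = D + (dX/dt)/X, q_P = (dP/dt + D (P - P_feed)) / X,
#' q_S = (D (S_feed - S) - dS/dt) / X, r_CO2 = CER / X.
#' Derivatives come from a centred local linear regression over `window`
#' samples; on stationary data the formulas reduce exactly to the chemostat
#' ones.
#'
#' @param series Time-series data.frame.
#' @param t Time point (h) inside the series.
#' @param window Regression window in samples (default 11).
#' @param max_acceleration Precondition on the dilution-rate acceleration
#'   (1/h^2); the quasi-steady treatment assumes a slow ramp.
#' @return A `SteadyStateSnapshot`.
#' @export
specific_rates_astat <- function(series, t, window = 11L,
                                 max_acceleration = 0.0105) {
  if (t < min(series$time) || t > max(series$time))
    stop("t outside the time series")
  dDdt <- .local_fit(series$time, series$dilution_rate, t, window)[["slope"]]
  if (abs(dDdt) > max_acceleration)
    stop("dilution-rate acceleration ", format(dDdt),
         " exceeds the quasi-steady bound ", max_acceleration)
  fX <- .local_fit(series$time, series$biomass, t, window)
  if (fX[["value"]] <= 0) stop("non-positive biomass at t = ", t)
  D <- .local_fit(series$time, series$dilution_rate, t, window)[["value"]]
  X <- fX[["value"]]
  mu <- D + fX[["slope"]] / X

  qp <- vapply(names(.ts_species), function(cn) {
    f <- .local_fit(series$time, series[[cn]], t, window)
    feed <- if (cn == "ace")
      .local_fit(series$time, series$feed_ace, t, window)[["value"]] else 0
    (f[["slope"]] + D * (f[["value"]] - feed)) / X
  }, numeric(1))
  names(qp) <- .ts_species

  fS <- .local_fit(series$time, series$glc, t, window)
  fFeed <- .local_fit(series$time, series$feed_glc, t, window)
  q_glc <- (D * (fFeed[["value"]] - fS[["value"]]) - fS[["slope"]]) / X
  r_co2 <- .local_fit(series$time, series$co2_rate, t, window)[["value"]] / X
  steady_state_snapshot(mu = max(mu, 0), q_glc = max(q_glc, 0),
                        q_products = qp, r_co2 = r_co2, biomass = X)
}

#' Snapshots over a growth-rate grid of an A-stat ramp
#'
#' Convenience wrapper: maps each requested growth rate to the ramp time
#' where the dilution rate crosses it and evaluates
#' [specific_rates_astat()] there.
#'
#' @param series Time-series data.frame.
#' @param mu_grid Growth rates (1/h) within the ramp's dilution-rate range.
#' @param ... Passed to [specific_rates_astat()].
#' @return List of `SteadyStateSnapshot`s.
#' @export
astat_snapshots <- function(series, mu_grid, ...) {
  lapply(mu_grid, function(mu) {
    if (mu < min(series$dilution_rate) || mu > max(series$dilution_rate))
      stop("mu = ", mu, " outside the ramp's dilution-rate range")
    t <- stats::approx(series$dilution_rate, series$time, xout = mu,
                       ties = "ordered")$y
    specific_rates_astat(series, t, ...)
  })
}

#' Growth rate at which acetate overflow starts
#'
#' The smallest growth rate at which the specific acetate excretion rate
#' exceeds `threshold` and stays above it for all later snapshots.
#'
#' The crossing growth rate overestimates a gradual onset by roughly
#' `threshold / slope`, so when the post-crossing excretion rises with a
#' clearly positive slope the estimate is refined by back-extrapolating a
#' linear fit over the first `refine_points` post-crossing snapshots to its
#' zero crossing; for step-like profiles (near-zero slope, or a zero
#' crossing implausibly far below the threshold crossing) the crossing
#' growth rate itself is returned.
#'
#' @param snapshots List of `SteadyStateSnapshot`s ordered by mu (>= 5,
#'   spanning the onset).
#' @param threshold Excretion threshold (mmol per g DCW per h, default 0.05).
#' @param refine_points Snapshots used in the back-extrapolation (default 5).
#' @return Onset growth rate (1/h), or `NA` with a `"no overflow in range"`
#'   message attribute if acetate never stays above the threshold.
#' @export
detect_overflow_onset <- function(snapshots, threshold = 0.05,
                                  refine_points = 5L) {
  if (length(snapshots) < 5L) stop("need at least 5 snapshots")
  mus <- vapply(snapshots, `[[`, 0, "mu")
  q_ace <- vapply(snapshots, function(s) s$q_products[["acetate"]], numeric(1))
  above <- q_ace > threshold
  sustained <- rev(cumprod(rev(above))) > 0  # above from here to the end
  if (!any(sustained))
    return(structure(NA_real_, message = "no overflow in range"))
  k <- which(sustained)[1]
  idx <- k:min(k + refine_points - 1L, length(mus))
  if (length(idx) >= 3L) {
    fit <- stats::coef(stats::lm(q_ace[idx] ~ mus[idx]))
    slope <- fit[[2]]
    if (is.finite(slope) && slope > 0) {
      mu0 <- -fit[[1]] / slope
      spacing <- stats::median(diff(mus))
      if (mu0 < mus[k] && mu0 > mus[k] - (refine_points + 1L) * spacing)
        return(unname(mu0))
    }
  }
  mus[k]
}
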