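# stationary chemostat series implied by a snapshot (inverse balances)
stationary_series <- function(snap, D = snap$mu, X = 2, feed_glc = 25,
                              n = 12, feed_ace = 0) {
  data.frame(
    time = seq(0, by = 0.5, length.out = n),
    dilution_rate = D, biomass = X,
    feed_glc = feed_glc, feed_ace = feed_ace,
    glc = feed_glc - snap$q_glc * X / D,
    ace = feed_ace + snap$q_products[["acetate"]] * X / D,
    lac = snap$q_products[["lactate"]] * X / D,
    cbasp = snap$q_products[["CBASP"]] * X / D,
    dho = snap$q_products[["DHO"]] * X / D,
    oro = snap$q_products[["orotate"]] * X / D,
    naa = snap$q_products[["NAA"]] * X / D,
    co2_rate = snap$r_co2 * X)
}

test_that("chemostat balances reduce to the textbook arithmetic", {
  # D = 0.1 1/h, X = 1 g/L, product at 1 mM, feed 0 -> q_P = 0.1
  snap0 <- steady_state_snapshot(0.1, q_glc = 2.5,
                                 q_products = c(lactate = 0.1), r_co2 = 0)
  s <- stationary_series(snap0, X = 1, feed_glc = 25)
  expect_equal(s$lac[1], 1)  # the 1 mM broth concentration
  rec <- specific_rates_chemostat(s)
  expect_equal(rec$q_products[["lactate"]], 0.1, tolerance = 1e-12)
  # D = 0.1, feed glucose 25 mM, residual 0, X = 1 -> q_glc = 2.5
  expect_equal(s$glc[1], 0)
  expect_equal(rec$q_glc, 2.5, tolerance = 1e-12)
  expect_equal(rec$mu, 0.1)
})

test_that("noise-free chemostat round-trip recovers the snapshot to 1e-10", {
  st <- true_state_at(0.30)
  snap <- forward_simulate(st$fluxes, mu = 0.30, network = ref_network())
  rec <- specific_rates_chemostat(stationary_series(snap))
  measurable <- c("acetate", "lactate", "CBASP", "DHO", "orotate", "NAA")
  expect_equal(rec$q_glc, snap$q_glc, tolerance = 1e-10)
  expect_equal(rec$q_products[measurable], snap$q_products[measurable],
               tolerance = 1e-10)
  expect_equal(rec$r_co2, snap$r_co2, tolerance = 1e-10)
  expect_equal(rec$biomass_yield, snap$biomass_yield, tolerance = 1e-10)
})

test_that("chemostat estimator rejects drifting concentrations by species", {
  snap <- true_state_at(0.30)$snapshot
  s <- stationary_series(snap)
  s$dho <- s$dho * seq(1, 2, length.out = nrow(s))
  expect_error(specific_rates_chemostat(s), "dho")
})

test_that("A-stat rates reduce exactly to chemostat rates on stationary data", {
  snap <- true_state_at(0.30)$snapshot
  s <- stationary_series(snap, n = 24)
  rec_c <- specific_rates_chemostat(s)
  rec_a <- specific_rates_astat(s, t = s$time[12])
  expect_equal(rec_a$mu, rec_c$mu, tolerance = 1e-9)
  expect_equal(rec_a$q_glc, rec_c$q_glc, tolerance = 1e-9)
  expect_equal(rec_a$q_products, rec_c$q_products, tolerance = 1e-9)
  # (both estimators see the same six measurable species)
})

test_that("a linear product ramp with no dilution term gives q = slope/X", {
  n <- 21; X <- 2; c_slope <- 0.3
  s <- data.frame(time = seq(0, 5, length.out = n), dilution_rate = 0,
                  biomass = X, feed_glc = 25, feed_ace = 0, glc = 25,
                  ace = c_slope * seq(0, 5, length.out = n), lac = 0,
                  cbasp = 0, dho = 0, oro = 0, naa = 0, co2_rate = 0)
  rec <- specific_rates_astat(s, t = 2.5)
  expect_equal(rec$q_products[["acetate"]], c_slope / X, tolerance = 1e-9)
})

test_that("A-stat estimator enforces the slow-acceleration precondition", {
  sc <- ref_astat_clean()
  s <- sc$series
  s$dilution_rate <- 0.1 + 0.05 * s$time  # five times the quasi-steady bound
  expect_error(specific_rates_astat(s, t = 10), "acceleration")
  expect_error(specific_rates_astat(sc$series, t = 1e4), "outside")
})

test_that("synthetic A-stat rates are recovered within 2 % at interior points", {
  sc <- ref_astat_clean()
  for (mu in c(0.15, 0.25, 0.33, 0.42)) {
    i <- which.min(abs(sc$truth$mu - mu))
    tr <- sc$truth$snapshots[[i]]
    rec <- specific_rates_astat(sc$series, t = sc$truth$time[i])
    expect_equal(rec$mu, tr$mu, tolerance = 0.02)
    expect_equal(rec$q_glc, tr$q_glc, tolerance = 0.02)
    expect_equal(rec$r_co2, tr$r_co2, tolerance = 0.02)
    for (sp in c("acetate", "lactate", "CBASP", "DHO", "orotate", "NAA"))
      if (tr$q_products[[sp]] > 0.01)
        expect_equal(rec$q_products[[sp]], tr$q_products[[sp]],
                     tolerance = 0.02)
  }
})

test_that("overflow onset detection handles step, absent and ramp profiles", {
  mk <- function(mu, q) steady_state_snapshot(mu, 1, c(acetate = q))
  mus <- seq(0.1, 0.5, by = 0.025)
  # step at 0.3
  step <- lapply(mus, function(m) mk(m, if (m >= 0.3) 1 else 0))
  expect_equal(detect_overflow_onset(step), 0.3)
  # no overflow anywhere
  none <- lapply(mus, function(m) mk(m, 0))
  expect_true(is.na(detect_overflow_onset(none)))
  expect_identical(attr(detect_overflow_onset(none), "message"),
                   "no overflow in range")
  # gradual ramp starting at 0.3: back-extrapolation undoes the threshold lag
  ramp <- lapply(mus, function(m) mk(m, max(0, 2 * (m - 0.3))))
  expect_equal(detect_overflow_onset(ramp), 0.3, tolerance = 1e-6)
  expect_error(detect_overflow_onset(ramp[1:3]), "at least 5")
})

test_that("generated onset parameter is read back within one grid spacing", {
  sc <- ref_astat_noisy()
  snaps <- astat_snapshots(sc$series, seq(0.12, 0.47, by = 0.01))
  on <- detect_overflow_onset(snaps)
  expect_lt(abs(on - sc$config$overflow_onset_mu), 0.015)
})

test_that("D-stat co-utilisation yields negative acetate rates", {
  sc <- generate_scenario(scenario_config(
    "dstat", dilution_rate = 0.10, coutilisation_capability = 0.9,
    seed = 3L), network = ref_network(), comp_table = ref_comp_table())
  win <- c(16, 20)
  rec <- specific_rates_chemostat(sc$series, window = win, drift_tol = 0.3)
  expect_lt(rec$q_products[["acetate"]], 0)
  expect_gt(rec$q_glc, 0)
})

test_that("missing time-series values are interpolated on read", {
  sc <- ref_astat_clean()
  path <- withr::local_tempfile(fileext = ".tsv")
  s <- sc$series
  s$ace[c(40, 40:40, 80)] <- NA
  write_timeseries(s, path)
  expect_message(d <- read_timeseries(path), "interpolating")
  expect_false(anyNA(d$ace))
})
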