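# CV, log-linear calibration, R^2 trajectory, read-time rule, LOD, and the
# metric-selection screen.

std5 <- data.frame(
  chamber_id = paste0("chamber_", 1:5),
  concentration_ng_per_ml = c(0, 1, 10, 100, 1000),
  stringsAsFactors = FALSE
)

test_that("coefficient_of_variation matches direct computation", {
  expect_equal(coefficient_of_variation(c(5.071, 4.984, 5.056, 5.011)),
               0.0079787823, tolerance = 1e-8)
  expect_equal(coefficient_of_variation(c(3, 3, 3)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero")
})

test_that("noiseless log-linear signals are recovered exactly", {
  sig <- setNames(2 - 0.3 * log10(c(1, 10, 100, 1000)), std5$chamber_id[2:5])
  m <- fit_calibration(std5, sig, t_read = 100)
  expect_equal(m$slope, -0.3, tolerance = 1e-12)
  expect_equal(m$intercept, 2, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(m$n, 4)
  expect_equal(m$t_read, 100)
})

test_that("degenerate and underdetermined designs are flagged", {
  flat <- setNames(rep(1.5, 4), std5$chamber_id[2:5])
  m <- fit_calibration(std5, flat)
  expect_true(m$degenerate)
  expect_true(is.na(m$r_squared))
  short <- std5[1:3, ]  # only 2 nonzero standards
  expect_error(fit_calibration(short, flat), "3 distinct")
  expect_error(fit_calibration(std5, flat[1:3]), "no signal")
})

test_that("OLS matches the closed-form normal-equations oracle", {
  set.seed(55)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    conc <- sort(10^runif(n, 0, 3))
    std <- data.frame(chamber_id = paste0("c", seq_len(n)),
                      concentration_ng_per_ml = conc)
    y <- setNames(1 - 0.1 * log10(conc) + rnorm(n, 0, 0.05), std$chamber_id)
    m <- fit_calibration(std, y)
    o <- oracle_ols(log10(conc), unname(y))
    expect_equal(m$slope, o$slope, tolerance = 1e-10)
    expect_equal(m$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(m$r_squared, o$r_squared, tolerance = 1e-10)
  }
})

test_that("R^2 is affine-invariant while the slope rescales", {
  set.seed(77)
  conc <- c(1, 10, 100, 1000)
  std <- std5[2:5, ]
  y <- setNames(1 - 0.1 * log10(conc) + rnorm(4, 0, 0.02), std$chamber_id)
  m1 <- fit_calibration(std, y)
  m2 <- fit_calibration(std, 3.5 * y + 2)
  expect_equal(m2$r_squared, m1$r_squared, tolerance = 1e-10)
  expect_equal(m2$slope, 3.5 * m1$slope, tolerance = 1e-10)
})

test_that("r2_trajectory agrees with pointwise fits and handles failures", {
  tgrid <- c(30, 60, 90)
  mk_trace <- function(id, asym) {
    t <- 0:100
    kinetic_trace(id, t, 1 - asym * (1 - exp(-t / 40)))
  }
  traces <- list(chamber_2 = mk_trace("chamber_2", 0.05),
                 chamber_3 = mk_trace("chamber_3", 0.10),
                 chamber_4 = mk_trace("chamber_4", 0.15),
                 chamber_5 = mk_trace("chamber_5", 0.20))
  r2 <- r2_trajectory(traces, std5, tgrid)
  for (i in seq_along(tgrid)) {
    sig <- vapply(traces, value_at, numeric(1), t_query = tgrid[i])
    m <- fit_calibration(std5, sig)
    expect_equal(r2$r_squared[i], m$r_squared, tolerance = 1e-12)
    expect_equal(r2$slope[i], m$slope, tolerance = 1e-12)
  }
  # single-point grid consistency
  one <- r2_trajectory(traces, std5, 45)
  expect_equal(nrow(one), 1)
  expect_equal(one$r_squared, fit_calibration(
    std5, vapply(traces, value_at, numeric(1), t_query = 45))$r_squared)
  # identical traces: degenerate at every grid time -> NA
  same <- lapply(traces, function(tr) kinetic_trace(tr$chamber_id, tr$times,
                                                    rep(1, length(tr$times))))
  r2_na <- r2_trajectory(same, std5, tgrid)
  expect_true(all(is.na(r2_na$r_squared)))
})

test_that("r2 grows over time when concentration separation grows", {
  # construct traces whose separation widens with t, so R^2 of the fit
  # against log-concentration increases monotonically
  t <- seq(0, 100, 5)
  conc <- c(1, 10, 100, 1000)
  traces <- setNames(lapply(seq_along(conc), function(i) {
    sep <- log10(conc[i]) * (t / 100) * 0.1
    bend <- 0.02 * sin(i + 1)          # time-constant lack of fit
    kinetic_trace(std5$chamber_id[i + 1], t, 1 - sep + bend)
  }), std5$chamber_id[2:5])
  r2 <- r2_trajectory(traces, std5, seq(10, 100, 10))
  expect_true(all(diff(r2$r_squared) > 0))
})

test_that("earliest_reliable_time requires a sustained crossing", {
  expect_equal(earliest_reliable_time(c(0.4, 0.8, 0.96, 0.97),
                                      times = c(25, 50, 75, 100)), 75)
  expect_equal(earliest_reliable_time(c(0.96, 0.90, 0.97, 0.98),
                                      times = c(25, 50, 75, 100)), 75)
  expect_true(is.na(earliest_reliable_time(c(0.5, 0.7, 0.9),
                                           times = c(1, 2, 3))))
  df <- data.frame(time_s = c(10, 20, 30), r_squared = c(0.99, 0.99, 0.99))
  expect_equal(earliest_reliable_time(df), 10)
  # monotone non-decreasing in the threshold
  set.seed(3)
  r2 <- pmin(1, cumsum(runif(20, 0, 0.12)))
  times <- seq_along(r2)
  prev <- -Inf
  for (thr in c(0.5, 0.7, 0.9, 0.95)) {
    cur <- earliest_reliable_time(r2, threshold = thr, times = times)
    if (!is.na(cur)) {
      expect_gte(cur, prev)
      prev <- cur
    }
  }
})

test_that("LOD inverts the curve per the blank +/- k sd rule", {
  m <- structure(list(slope = -0.1, intercept = 1.0, r_squared = 0.99,
                      degenerate = FALSE), class = "calibration_model")
  # sd = 0: LOD sits where the fitted signal equals the blank mean
  zero_sd <- estimate_lod(m, c(0.95, 0.95))
  expect_equal(zero_sd$lod, 10^((0.95 - 1.0) / -0.1), tolerance = 1e-12)
  # larger blank sd -> larger LOD for a decreasing-signal curve
  small <- estimate_lod(m, c(0.95, 0.951))
  large <- estimate_lod(m, c(0.94, 0.96))
  expect_gt(large$lod, small$lod)
  # closed-form oracle, both slope signs
  set.seed(13)
  for (rep in 1:20) {
    slope <- sample(c(-1, 1), 1) * runif(1, 0.05, 0.3)
    inter <- runif(1, 0.5, 1.5)
    blanks <- inter + rnorm(4, 0, 0.01)
    mm <- structure(list(slope = slope, intercept = inter,
                         degenerate = FALSE), class = "calibration_model")
    got <- estimate_lod(mm, blanks)
    expect_equal(got$lod, oracle_lod(slope, inter, blanks),
                 tolerance = 1e-9)
  }
  flat <- structure(list(slope = 0, intercept = 1, degenerate = TRUE),
                    class = "calibration_model")
  expect_error(estimate_lod(flat, c(1, 1)), "LOD undefined")
  expect_error(estimate_lod(m, 1.0), "2 blank")
})

test_that("compare_metrics screens by CV and discordant-chip agreement", {
  ods <- c(A = 5.071, B = 4.984, C = 4.528, D = 5.056, E = 5.011)
  ref <- data.frame(chip_id = names(ods), od = unname(ods))
  scaled <- ods * 0.37                       # positive scaling of the ODs
  # invert the ordering of C and A: C becomes concordant, A the outlier
  inverted <- ods; inverted[["C"]] <- 5.02; inverted[["A"]] <- 4.40
  res <- compare_metrics(list(scaled = scaled, inverted = inverted), ref)
  expect_equal(attr(res, "discordant_chip"), "C")
  srow <- res[res$metric == "scaled", ]
  expect_true(srow$pass)
  expect_equal(srow$cv, coefficient_of_variation(scaled[c("A", "B", "D", "E")]))
  expect_false(res[res$metric == "inverted", ]$trend_pass)
  # missing chip -> not evaluable
  res2 <- compare_metrics(list(partial = scaled[1:4]), ref)
  expect_false(res2$evaluable)
  expect_false(res2$pass)
})

test_that("random metrics fail the trend flag at the permutation rate", {
  ods <- c(A = 5.071, B = 4.984, C = 4.528, D = 5.056, E = 5.011)
  ref <- data.frame(chip_id = names(ods), od = unname(ods))
  set.seed(99)
  hits <- 0L
  n <- 400L
  for (i in seq_len(n)) {
    rnd <- setNames(runif(5), names(ods))
    res <- compare_metrics(list(rnd = rnd), ref)
    hits <- hits + res$trend_pass
  }
  # exchangeable random values single out each chip with probability 1/5
  expect_equal(hits / n, 0.2, tolerance = 0.3)
})
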