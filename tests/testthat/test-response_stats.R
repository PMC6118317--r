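# Small results table built in code: 2 control wells + 2 doses, 3 timepoints.
make_results <- function(ctrl_fms = c(0.6, 0.6, 0.6),
                         drug_fms = list(d1 = c(0.3, 0.3, 0.3),
                                         d2 = c(0.15, 0.15, 0.15))) {
  times <- c(0, 5, 10)
  rows <- list()
  add <- function(well, dose, is_control, fms) {
    data.frame(well = well, time_min = times, compound = "cmpd",
               dose = dose, unit = "mM", strain = "N2", stage = "L1",
               is_control = is_control, fms = fms,
               moving_px = round(fms * 200), total_px = 200, valid = TRUE)
  }
  rbind(add("A01", 0, TRUE, ctrl_fms), add("A02", 0, TRUE, ctrl_fms),
        add("B01", 1, FALSE, drug_fms$d1), add("B02", 2, FALSE, drug_fms$d2))
}

test_that("control traces normalize to exactly 1 and drug wells to the ratio", {
  res <- make_results()
  tr <- normalize_to_controls(res)
  ctrl <- tr[tr$dose == 0, ]
  expect_true(all(ctrl$fms_norm == 1))
  expect_true(all(tr$fms_norm[tr$dose == 1] == 0.5))
  expect_true(all(tr$fms_norm[tr$dose == 2] == 0.25))
  expect_true(all(tr$n_wells[tr$dose == 0] == 2))
})

test_that("control floor marks timepoints missing and no controls is fatal", {
  res <- make_results(ctrl_fms = c(0.6, 0.01, 0.6))
  expect_warning(tr <- normalize_to_controls(res), "floor")
  expect_true(all(is.na(tr$fms_norm[tr$time_min == 5])))
  expect_false(anyNA(tr$fms_norm[tr$time_min != 5]))

  res2 <- make_results()
  res2$is_control <- FALSE
  expect_error(normalize_to_controls(res2), "control")
})

test_that("dose-time matrix slicing is consistent in both directions", {
  doses <- c(0.5, 1, 2, 4, 6, 8, 10, 12)
  times <- seq(0, 180, 5)
  s <- simulate_response_surface(kinetics_config(noise_sigma = 0),
                                 doses, times)
  traces <- expand.grid(time_min = times, dose = doses)
  traces$compound <- "cmpd"; traces$unit <- "mM"
  traces$strain <- "N2"; traces$stage <- "L1"; traces$n_wells <- 1
  traces$fms_norm <- s$matrix[cbind(match(traces$dose, doses),
                                    match(traces$time_min, times))]
  dtm <- build_dose_time_matrix(traces)
  expect_equal(dim(dtm$values), c(8, 37))
  # column at t = 60 equals each trace's value at 60 min
  expect_equal(unname(dtm$values[, dtm$times == 60]),
               unname(s$matrix[, times == 60]))
  # transpose round-trip
  tv <- t(dtm$values)
  expect_equal(unname(tv[dtm$times == 60, ]),
               unname(dtm$values[, dtm$times == 60]))
  # duplicate dose/time is an error
  dup <- rbind(traces, traces[1, ])
  expect_error(build_dose_time_matrix(dup), "duplicate")
})

test_that("logistic fit recovers parameters exactly from noiseless data", {
  doses <- c(0.125, 0.25, 0.5, 1, 2, 4, 6, 8)
  y <- logistic3_curve(doses, A = 0.1, B = 5, M = 1)
  f <- fit_logistic3(doses, y)
  expect_true(f$converged)
  expect_lt(abs(f$A - 0.1) / 0.1, 1e-4)
  expect_lt(abs(f$B - 5) / 5, 1e-4)
  expect_lt(abs(f$M - 1) / 1, 1e-4)
  expect_lt(f$rss, 1e-12)
  # fitted curve at x = M equals (1 + A) / 2 (closed form)
  expect_equal(logistic3_curve(f$M, f$A, f$B, f$M), (1 + f$A) / 2)
  expect_error(fit_logistic3(c(1, 2, 3), c(1, 0.5, 0.1)), "4 distinct")
})

test_that("logistic fit recovers parameters from noisy replicates", {
  doses <- c(0.125, 0.25, 0.5, 1, 2, 4, 6, 8)
  y <- logistic3_curve(doses, A = 0.1, B = 5, M = 1)
  set.seed(11)
  errM <- errA <- numeric(60)
  for (r in seq_along(errM)) {
    f <- fit_logistic3(doses, y + rnorm(8, 0, 0.03))
    errM[r] <- abs(f$M - 1)
    errA[r] <- abs(f$A - 0.1)
  }
  expect_lt(median(errM), 0.10)
  expect_lt(median(errA), 0.05)
})

test_that("flat responses yield a convergent, non-informative logistic fit", {
  doses <- c(0.5, 1, 2, 4, 8)
  set.seed(3)
  y <- 1 + rnorm(5, 0, 0.01)
  f <- fit_logistic3(doses, y)
  expect_true(f$converged)
  # plateau data: fitted curve stays near 1 across the dose range
  pred <- logistic3_curve(doses, f$A, f$B, f$M)
  expect_true(all(abs(pred - 1) < 0.1))
})

test_that("exponential fit is exact (linear least squares)", {
  doses <- c(0.25, 0.5, 1, 2, 4)
  y <- 0.8 * exp(-doses) + 0.2
  f <- fit_exponential(doses, y)
  expect_lt(abs(f$M - 0.8), 1e-6)
  expect_lt(abs(f$A - 0.2), 1e-6)
  expect_lt(f$rss, 1e-12)

  # constant responses admit the degenerate M = 0 solution
  fc <- fit_exponential(doses, rep(0.7, 5))
  expect_lt(abs(fc$M), 1e-9)
  expect_lt(abs(fc$A - 0.7), 1e-9)

  set.seed(5)
  errA <- replicate(60, {
    fn <- fit_exponential(doses, y + rnorm(5, 0, 0.03))
    abs(fn$A - 0.2)
  })
  expect_lt(median(errA), 0.05)

  expect_error(fit_exponential(c(1, 2), c(1, 0.5)), "3 distinct")
})

test_that("model selection follows the response range, override wins", {
  doses <- 1:8
  full <- seq(1.0, 0.05, length.out = 8)
  shallow <- seq(1.0, 0.7, length.out = 8)
  expect_identical(select_model(doses, full), "logistic3")
  expect_identical(select_model(doses, shallow), "exponential")
  expect_identical(select_model(doses, shallow, override = "logistic3"),
                   "logistic3")
})

test_that("EC50 is the logistic midpoint; non-converged fits refuse", {
  doses <- c(0.25, 0.5, 1, 2, 4, 8)
  f <- fit_logistic3(doses, logistic3_curve(doses, 0.05, 4, 2))
  expect_lt(abs(ec50(f) - 2), 1e-4 * 2)
  bad <- structure(list(converged = FALSE), class = "logistic_fit")
  expect_error(ec50(bad), "non-converged")
})

test_that("a simulated antagonist shift is recovered in the EC50 ratio", {
  times <- seq(0, 180, 5)
  doses1 <- c(0.125, 0.25, 0.5, 1, 2, 4, 6, 8)
  s1 <- simulate_response_surface(
    kinetics_config(M_true = 0.76, noise_sigma = 0.02, seed = 1),
    doses1, times)
  s2 <- simulate_response_surface(
    kinetics_config(M_true = 0.76 * 2.1, noise_sigma = 0.02, seed = 2),
    doses1, times)
  f1 <- fit_logistic3(s1$doses, s1$matrix[, ncol(s1$matrix)])
  f2 <- fit_logistic3(s2$doses, s2$matrix[, ncol(s2$matrix)])
  ratio <- ec50(f2) / ec50(f1)
  expect_lt(abs(ratio - 2.1) / 2.1, 0.10)
})

test_that("proportional recovery reproduces the defining formula", {
  tr <- recovery_trace(min_fms = 0.2, window_level = 0.6)
  rec <- proportional_recovery(tr$times, tr$fms)
  expect_true(rec$defined)
  expect_equal(rec$score, (0.6 - 0.2) / (1 - 0.2))

  # no paralysis: undefined
  flat <- proportional_recovery(tr$times, rep(1, length(tr$times)))
  expect_false(flat$defined)
  expect_true(is.na(flat$score))

  # full recovery to 1.0 scores exactly 1
  full <- recovery_trace(min_fms = 0, window_level = 1)
  expect_equal(proportional_recovery(full$times, full$fms)$score, 1.0)

  # monotone non-recovering trace whose window mean equals the minimum
  mono <- c(seq(1, 0.3, length.out = 31), rep(0.3, 6))
  expect_equal(proportional_recovery(tr$times, mono)$score, 0)

  # window defaults adapt to shorter assays
  short_t <- seq(0, 120, 5)
  short <- proportional_recovery(short_t, c(seq(1, 0.2, length.out = 10),
                                            rep(0.5, 15)))
  expect_equal(short$fms_after_recovery, 0.5)

  expect_error(proportional_recovery(seq(0, 100, 5), rep(0.5, 21),
                                     window = c(150, 180)), "window")
})

test_that("response classification distinguishes the kinetic archetypes", {
  t <- seq(0, 180, 5)
  expect_identical(classify_response(t, rep(1, 37)), "no_effect")
  drop <- c(seq(1, 0.05, length.out = 10), rep(0.05, 27))
  expect_identical(classify_response(t, drop), "sustained_paralysis")

  doses <- c(0.5, 1, 2, 4, 8)
  s <- simulate_response_surface(
    kinetics_config(recovery_rate = 0.08, recovery_onset_min = 40,
                    noise_sigma = 0), doses, t)
  expect_identical(classify_response(t, s$matrix[5, ]), "sustained_recovery")

  # transient: rises then falls back before the window
  transient <- c(seq(1, 0.1, length.out = 8), seq(0.1, 0.9, length.out = 10),
                 seq(0.9, 0.3, length.out = 19))
  expect_identical(classify_response(t, transient), "transient_recovery")
})
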