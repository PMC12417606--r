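clinical_school <- function() {
  prevalence_estimate(0.37, 0.34, 0.41, "direct", service = "Clinical")
}
clinical_updated <- function() {
  prevalence_estimate(1.22, 1.16, 1.28, "direct", service = "Clinical")
}

test_that("delta is the point difference with the wider interval's width", {
  d <- compute_delta(clinical_school(), clinical_updated())
  expect_equal(d$delta, 0.85)
  expect_equal(d$ci_width, max(0.41 - 0.34, 1.28 - 1.16))

  same <- compute_delta(clinical_school(), clinical_school())
  expect_equal(same$delta, 0)

  # projection is additive on the percentage-point scale
  expect_equal(apply_delta(1.29, d), 1.29 + 0.85)
  expect_equal(apply_delta(0.43, d), 1.28)

  other <- prevalence_estimate(1.2, 1.1, 1.3, "direct", service = "Elsewhere")
  expect_error(compute_delta(clinical_school(), other), "same service")
  crude <- prevalence_estimate(1.22, 1.16, 1.28, "crude", service = "Clinical")
  expect_error(compute_delta(clinical_school(), crude), "standardization")
})

test_that("bounded priors carry school lower bounds and delta-shifted uppers", {
  d <- compute_delta(clinical_school(), clinical_updated())
  est <- data.frame(
    service = c("Aconcagua", "Clinical", "Big"),
    point = c(0.43, 0.37, 0.40),
    population = c(46840, 132242, 100000)
  )
  pr <- build_priors(est, d, clinical_service = "Clinical")
  expect_equal(nrow(pr), 3L)
  expect_equal(pr$lower[1], 0.0043)
  expect_equal(pr$upper[1], 0.0128)
  expect_equal(pr$upper[pr$service == "Clinical"], 0.0122)
  expect_equal(pr$y, round(pr$lower * pr$n))

  # zero delta gives degenerate priors
  d0 <- compute_delta(clinical_school(), clinical_school())
  pr0 <- build_priors(est[est$service != "Clinical", ], d0)
  expect_equal(pr0$lower, pr0$upper)

  # upper bounds cap at 1
  big <- data.frame(service = "X", point = 99.8, population = 1000)
  dbig <- compute_delta(
    prevalence_estimate(1, 0.9, 1.1, "direct"),
    prevalence_estimate(2, 1.9, 2.1, "direct")
  )
  expect_warning(prc <- build_priors(big, dbig), "capped")
  expect_equal(prc$upper, 1)
})

make_priors <- function(df) {
  class(df) <- c("service_priors", "data.frame")
  df
}

test_that("sampler respects prior support and is seed-reproducible", {
  d <- compute_delta(clinical_school(), clinical_updated())
  est <- data.frame(
    service = sprintf("S%d", 1:5), point = c(0.43, 0.75, 0.83, 0.30, 0.37),
    population = c(46840, 19890, 119378, 36651, 132242)
  )
  pr <- build_priors(est, d)
  cfg <- mcmc_config(burn_in = 300, kept = 600, chains = 2, seed = 8)
  fit <- run_mcmc(pr, cfg)
  for (s in seq_len(nrow(pr))) {
    expect_true(all(fit$samples[, s, ] >= pr$lower[s]))
    expect_true(all(fit$samples[, s, ] <= pr$upper[s]))
  }
  expect_true(all(is.finite(fit$summary$rhat)))
  expect_true(all(fit$summary$cri_low <= fit$summary$cri_high))

  fit2 <- run_mcmc(pr, cfg)
  expect_identical(fit$samples, fit2$samples)
  expect_identical(fit$summary, fit2$summary)
})

test_that("degenerate and prior-only limits behave as expected", {
  # lower = upper: point mass
  pr <- make_priors(data.frame(
    service = "Fixed", lower = 0.005, upper = 0.005, n = 10000, y = 50
  ))
  fit <- run_mcmc(pr, mcmc_config(burn_in = 100, kept = 200, chains = 2, seed = 3))
  expect_true(all(fit$samples == 0.005))
  expect_equal(fit$summary$mean, 0.005)

  # likelihood withheld: posterior mean near the prior midpoint
  pr2 <- make_priors(data.frame(
    service = "Flat", lower = 0.004, upper = 0.012, n = 50000, y = 200
  ))
  fit2 <- run_mcmc(pr2, mcmc_config(
    burn_in = 500, kept = 3000, chains = 2, seed = 4, use_likelihood = FALSE
  ))
  expect_equal(fit2$summary$mean, 0.008, tolerance = 0.03)
})

test_that("sampler agrees with a grid-integration posterior within 0.02 points", {
  pr <- make_priors(data.frame(
    service = c("A", "B", "C"),
    lower = c(0.0043, 0.0075, 0.0083),
    upper = c(0.0128, 0.0160, 0.0167),
    n = c(46840, 19890, 119378),
    y = c(201, 149, 991)
  ))
  fit <- run_mcmc(pr, mcmc_config(
    burn_in = 1000, kept = 2000, chains = 2, seed = 12, sigma_fixed = 0
  ))
  for (s in 1:3) {
    g <- oracle_grid_posterior(pr$lower[s], pr$upper[s], pr$n[s], pr$y[s])
    expect_lt(abs(100 * fit$summary$mean[s] - 100 * g$mean), 0.02)
  }
})

test_that("posterior concentrates at the lower bound as n grows", {
  n <- 1000000L
  lower <- 0.004
  pr <- make_priors(data.frame(
    service = "Dense", lower = lower, upper = 0.013, n = n, y = round(lower * n)
  ))
  fit <- run_mcmc(pr, mcmc_config(burn_in = 800, kept = 1500, chains = 2,
                                  seed = 7, sigma_fixed = 0))
  expect_lt(fit$summary$mean - lower, 0.1 * (0.013 - 0.004))
})

test_that("credible bands have the prescribed width and truncate at zero", {
  band <- credible_band(1.28, 0.50 - 0.37, 0.12)
  expect_equal(band[2] - band[1], 0.13)
  expect_equal(band, c(1.215, 1.345))
  # within printed precision of the published [1.21, 1.34]
  expect_lt(max(abs(band - c(1.21, 1.34))), 0.011)

  degenerate <- credible_band(2, 0, 0)
  expect_equal(degenerate, c(2, 2))

  clipped <- credible_band(0.05, 0.5, 0.2)
  expect_equal(clipped[1], 0)
  wide <- credible_band(99.9, 0, 90)
  expect_lte(wide[2], 100)
})

test_that("national projection adds the delta and quantifies unmet need", {
  d <- compute_delta(clinical_school(), clinical_updated())
  nat <- prevalence_estimate(0.46, 0.45, 0.47, "direct")
  proj <- national_projection(nat, d, 3056306, 14210, posited_cases = 40113)
  expect_equal(proj$prevalence_pct, 1.31)
  expect_equal(proj$unmet_cases, 25903)
  expect_equal(round(proj$unmet_pct, 1), 64.6)

  # zero delta: posited count from school prevalence alone
  d0 <- compute_delta(clinical_school(), clinical_school())
  proj0 <- national_projection(nat, d0, 1000000, 2000)
  expect_equal(proj0$posited_cases, round(0.46 / 100 * 1000000))
  expect_equal(proj0$unmet_cases, proj0$posited_cases - 2000)
})
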