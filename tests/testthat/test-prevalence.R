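test_that("crude prevalence reproduces printed registry rates", {
  est <- crude_prevalence(14549, 3056306)
  expect_equal(round(est$point, 2), 0.48)
  est2 <- crude_prevalence(1620, 132242)
  expect_equal(round(est2$point, 2), 1.23)
  expect_lt(est2$ci_low, est2$point)
  expect_gt(est2$ci_high, est2$point)

  zero <- crude_prevalence(0, 1000)
  expect_equal(zero$point, 0)
  expect_equal(zero$ci_low, 0)
  expect_gt(zero$ci_high, 0)

  expect_error(crude_prevalence(1, 0), "positive")
  expect_error(crude_prevalence(11, 10), "cases")
})

test_that("direct standardization obeys closed-form identities", {
  std <- toy_std()
  # constant rate: point equals the common rate whatever the weights
  strata <- expand.grid(age_band = AGE_BANDS_TEST, sex = c("F", "M"),
                        stringsAsFactors = FALSE)
  strata$population <- c(100, 200, 300, 400, 500, 600, 700, 800) * 10
  strata$cases <- strata$population * 0.02
  std_uneven <- std
  std_uneven$weight <- seq(100, 800, by = 100)
  est <- direct_standardize(strata, std_uneven)
  expect_equal(est$point, 2)

  # two strata with rates 1% and 3%, standard weights 3:1 -> 1.5%
  s2 <- data.frame(age_band = c("6-8", "9-11"), sex = "F",
                   cases = c(10, 30), population = c(1000, 1000))
  w2 <- data.frame(age_band = c("6-8", "9-11"), sex = "F", weight = c(3, 1))
  expect_equal(direct_standardize(s2, w2)$point, 1.5)

  # crude equals direct when weights are proportional to own populations
  strata$cases <- rpois(8, strata$population * 0.015)
  own <- strata[c("age_band", "sex")]
  own$weight <- strata$population * 7 # arbitrary rescaling
  crude <- crude_prevalence(sum(strata$cases), sum(strata$population))
  expect_equal(direct_standardize(strata, own)$point, crude$point,
               tolerance = 1e-12)
})

test_that("random stratified tables match the weighted-sum oracle", {
  set.seed(301)
  std <- toy_std()
  for (i in 1:25) {
    strata <- expand.grid(age_band = AGE_BANDS_TEST, sex = c("F", "M"),
                          stringsAsFactors = FALSE)
    strata$population <- sample(500:5000, 8)
    strata$cases <- rbinom(8, strata$population, runif(1, 0.001, 0.05))
    std$weight <- sample(100:10000, 8)
    est <- direct_standardize(strata, std)
    expect_equal(est$point, oracle_direct(strata, std), tolerance = 1e-12)
    # invariance to rescaling all weights
    std_scaled <- std
    std_scaled$weight <- std$weight * 137.5
    expect_equal(direct_standardize(strata, std_scaled)$point, est$point,
                 tolerance = 1e-12)
  }
})

test_that("gamma limits collapse to exact Poisson limits for one stratum", {
  for (cases in c(1, 5, 50, 488)) {
    n <- 120000
    strata <- data.frame(age_band = "6-8", sex = "M", cases = cases, population = n)
    std <- data.frame(age_band = "6-8", sex = "M", weight = n)
    ci <- gamma_ci(strata, std)
    exact <- 100 * c(qchisq(0.025, 2 * cases) / 2, qchisq(0.975, 2 * (cases + 1)) / 2) / n
    expect_equal(ci, exact, tolerance = 1e-10)
  }
})

test_that("gamma limits approach normal limits for large counts", {
  n <- 2e6
  cases <- 20000
  strata <- data.frame(age_band = "6-8", sex = "M", cases = cases, population = n)
  std <- data.frame(age_band = "6-8", sex = "M", weight = n)
  ci <- gamma_ci(strata, std)
  r <- cases / n
  normal <- 100 * (r + c(-1, 1) * qnorm(0.975) * sqrt(cases) / n)
  expect_equal(ci[1], normal[1], tolerance = 0.01)
  expect_equal(ci[2], normal[2], tolerance = 0.01)
})

test_that("gamma limits handle zero cases and shrink with more cases", {
  strata <- data.frame(age_band = "6-8", sex = "M", cases = 0, population = 1000)
  std <- data.frame(age_band = "6-8", sex = "M", weight = 1000)
  ci <- gamma_ci(strata, std)
  expect_equal(ci[1], 0)
  expect_gt(ci[2], 0)

  # width non-increasing in total cases at fixed rates
  widths <- vapply(c(10, 40, 160, 640, 2560), function(k) {
    s <- data.frame(age_band = c("6-8", "9-11"), sex = "M",
                    cases = c(k, 2 * k), population = c(100 * k, 100 * k))
    w <- data.frame(age_band = c("6-8", "9-11"), sex = "M", weight = c(3, 1))
    ci <- gamma_ci(s, w)
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("missing standard strata and impossible strata are rejected", {
  strata <- data.frame(age_band = c("6-8", "9-11"), sex = "M",
                       cases = c(5, 2), population = c(100, 100))
  std <- data.frame(age_band = "6-8", sex = "M", weight = 100)
  expect_error(direct_standardize(strata, std), "no standard weight")
  strata2 <- data.frame(age_band = "6-8", sex = "M", cases = 5, population = 0)
  std2 <- data.frame(age_band = "6-8", sex = "M", weight = 100)
  expect_error(direct_standardize(strata2, std2), "zero population")
})

test_that("prevalence table recovers the built-in sex ratio and closes shares", {
  sim <- simulate_registry(small_sim_config(
    seed = 31, clinical_pop = 150000, prevalence = 0.02, detection = 1
  ))
  st <- sim$students[sim$students$health_service == "Clinical", ]
  std <- std_population()
  tab <- prevalence_table(st, list(character(0), "sex"), std)

  overall <- tab[tab$variable == "(overall)", ]
  expect_equal(nrow(overall), 1L)
  bysex <- tab[tab$variable == "sex", ]
  mfr <- bysex$direct_pct[bysex$level == "M"] / bysex$direct_pct[bysex$level == "F"]
  expect_gt(mfr, 4.5)
  expect_lt(mfr, 8)
  expect_equal(sum(bysex$share_pct), 100, tolerance = 0.02)
})
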