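# Independent oracles and shared fixtures for the test suite.
# Every oracle is coded from the defining formula, independent of the
# package's implementation path.

# brute-force weighted-sum oracle for direct standardization (percent)
oracle_direct <- function(strata, std) {
  key <- function(tab) paste(tab$age_band, tab$sex)
  w <- std$weight[match(key(strata), key(std))]
  100 * sum(w * strata$cases / strata$population) / sum(w)
}

# sum-of-logs oracle for the composite Fellegi-Sunter weight
oracle_weight <- function(sims, ms, us) {
  tot <- 0
  for (j in seq_along(sims)) {
    tot <- tot + sims[j] * log2(ms[j] / us[j]) +
      (1 - sims[j]) * log2((1 - ms[j]) / (1 - us[j]))
  }
  tot
}

# Riemann-integration posterior for one service at sigma = 0
# (y ~ Binomial(n, p), p ~ Uniform(lower, upper))
oracle_grid_posterior <- function(lower, upper, n, y, len = 4001) {
  g <- seq(lower, upper, length.out = len)
  w <- dbinom(y, n, g)
  w <- w / sum(w)
  list(mean = sum(g * w),
       cri = c(g[min(which(cumsum(w) >= 0.025))],
               g[min(which(cumsum(w) >= 0.975))]))
}

# transposition detector over explicit date components
oracle_date_sim <- function(a, b) {
  if (a == b) return(1)
  pa <- as.integer(strsplit(format(a, "%Y-%m-%d"), "-")[[1]])
  pb <- as.integer(strsplit(format(b, "%Y-%m-%d"), "-")[[1]])
  if (pa[1] == pb[1] && pa[2] == pb[3] && pa[3] == pb[2]) return(0.8)
  0
}

# small two-service configuration; clinical service carries the linkage load
small_sim_config <- function(seed, clinical_pop = 30000,
                             prevalence = 0.02, detection = 0.5,
                             capture = 0.9, errors = list(dob = 0.03, commune = 0.03, ses = 0.03),
                             ...) {
  sim_config(
    seed = seed,
    services = data.frame(
      service = c("Other", "Clinical"),
      population = c(2000L, as.integer(clinical_pop))
    ),
    clinical_service = "Clinical",
    true_prevalence = prevalence,
    school_detection_prob = detection,
    clinical_capture_prob = capture,
    field_error_rates = errors,
    ...
  )
}

# run linkage on a simulation and score it against the truth table
run_linkage_experiment <- function(seed, threshold = 9, ...) {
  sim <- simulate_registry(small_sim_config(seed, ...))
  flagged <- sim$students[sim$students$asd_flag &
    sim$students$health_service == "Clinical", ]
  ms <- suppressMessages(link_records(
    flagged, sim$patients,
    default_field_specs(n_communes = 21),
    threshold = threshold
  ))
  c(evaluate_linkage(ms, sim$truth)[c("precision", "recall")],
    list(matchset = ms, sim = sim))
}

toy_std <- function() {
  expand.grid(age_band = AGE_BANDS_TEST, sex = c("F", "M"),
              weight = 1000, stringsAsFactors = FALSE)
}
AGE_BANDS_TEST <- c("6-8", "9-11", "12-14", "15-18")
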