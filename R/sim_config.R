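FEE_BANDS <- c(
  "Free", "US$1.15-US$11.50", "US$11.51-US$28.75", "US$28.76-US$57.51",
  "US$57.52-US$115.01", ">US$115.02", "Missing"
)

ETHNICITIES <- c("Mapuche", "Aymara", "Other", "None")

#' Simulation configuration for the synthetic registry generator
#'
#' Builds and validates the configuration driving [simulate_registry()].
#' The generator creates a national school registry covering every health
#' service plus a clinical EHR extract covering exactly one designated
#' service (the clinical validation catchment), with shared latent
#' individuals so that linkage and prevalence estimates can be scored
#' against ground truth.
#'
#' @param seed integer RNG seed; identical configuration and seed give
#'   byte-identical output tables.
#' @param services data frame with columns `service` (name), `population`
#'   (children aged 6-18) and optionally `n_communes` (default 8; the
#'   clinical service defaults to 21).
#' @param true_prevalence named numeric vector (or scalar, recycled) of the
#'   true condition prevalence per service.
#' @param clinical_service name of the service covered by the EHR extract.
#' @param school_detection_prob probability that a truly affected child
#'   carries the registry ASD flag (scalar, or named per-service vector).
#' @param clinical_capture_prob probability that a truly affected child in
#'   the clinical service appears in the EHR extract.
#' @param field_error_rates named list with elements `dob` (day/month
#'   transposition, else +/- 1 day), `commune` (mis-recorded commune) and
#'   `ses` (insurance band off by one); each the per-record probability that
#'   the clinical copy of the field is corrupted relative to the registry.
#' @param commune_missing_prob probability a registry row lacks an address
#'   commune (to be imputed from the school's commune).
#' @param sex_ratio_mfr male-to-female prevalence risk ratio.
#' @param age_band_gradient multiplicative prevalence trend across the four
#'   age bands (band k carries relative rate `gradient^(k-1)`; values < 1
#'   make prevalence peak in the 6-8 band).
#' @param multi_commune_prob probability that an EHR patient appears under a
#'   second commune (duplicate patient row).
#' @param prob_male proportion of boys in the registry.
#' @param band_shares length-4 proportions of children per age band.
#' @param fee_band_probs length-7 proportions over school fee bands
#'   (including `Missing`).
#' @param ethnicity_probs length-4 proportions over
#'   Mapuche/Aymara/Other/None.
#' @param immigrant_prob,rural_prob marginal probabilities of immigration
#'   status and rural residence.
#' @param sen_other_prob probability that an unaffected child accesses a
#'   special-education programme under some non-ASD category.
#' @param insurance_probs proportions over the ordinal insurance bands
#'   (the SES proxy carried by both sources).
#' @param school_size mean number of pupils per school.
#' @param reference_date date at which ages and age bands are evaluated.
#' @return object of class `sim_config` (a validated list).
#' @seealso [chile_sim_config()] for defaults that mirror the published
#'   2021 Chilean registry margins.
#' @export
sim_config <- function(seed = 1L,
                       services = data.frame(
                         service = c("North", "Clinical", "South"),
                         population = c(20000L, 30000L, 20000L)
                       ),
                       true_prevalence = 0.012,
                       clinical_service = "Clinical",
                       school_detection_prob = 0.30,
                       clinical_capture_prob = 0.84,
                       field_error_rates = list(dob = 0.02, commune = 0.03, ses = 0.05),
                       commune_missing_prob = 0.02,
                       sex_ratio_mfr = 6,
                       age_band_gradient = 0.86,
                       multi_commune_prob = 0.01,
                       prob_male = 0.5134,
                       band_shares = c(0.2449, 0.2511, 0.2453, 0.2587),
                       fee_band_probs = c(0.7167, 0.0004, 0.0119, 0.0677, 0.0886, 0.0983, 0.0164),
                       ethnicity_probs = c(0.0577, 0.0069, 0.0071, 0.9283),
                       immigrant_prob = 0.04,
                       rural_prob = 0.0782,
                       sen_other_prob = 0.108,
                       insurance_probs = c(0.30, 0.30, 0.20, 0.12, 0.08),
                       school_size = 450,
                       reference_date = as.Date("2021-06-30")) {
  stopifnot(is.data.frame(services), all(c("service", "population") %in% names(services)))
  if (anyDuplicated(services$service) > 0) {
    stop("duplicated service names in configuration", call. = FALSE)
  }
  if (any(services$population <= 0)) {
    stop("configuration error: service populations must be > 0", call. = FALSE)
  }
  if (!clinical_service %in% services$service) {
    stop("configuration error: clinical_service not among services", call. = FALSE)
  }
  if (is.null(services$n_communes)) {
    services$n_communes <- ifelse(services$service == clinical_service, 21L, 8L)
  }

  tp <- true_prevalence
  if (is.null(names(tp))) tp <- stats::setNames(rep_len(tp, nrow(services)), services$service)
  dp <- school_detection_prob
  if (is.null(names(dp))) dp <- stats::setNames(rep_len(dp, nrow(services)), services$service)
  if (!all(services$service %in% names(tp)) || !all(services$service %in% names(dp))) {
    stop("configuration error: per-service parameters must name every service", call. = FALSE)
  }

  probs <- c(
    tp, dp, clinical_capture_prob, unlist(field_error_rates),
    commune_missing_prob, multi_commune_prob, prob_male, band_shares,
    fee_band_probs, ethnicity_probs, immigrant_prob, rural_prob,
    sen_other_prob, insurance_probs
  )
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("configuration error: all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!all(c("dob", "commune", "ses") %in% names(field_error_rates))) {
    stop("configuration error: field_error_rates needs dob, commune and ses", call. = FALSE)
  }
  if (sex_ratio_mfr <= 0 || age_band_gradient <= 0) {
    stop("configuration error: sex_ratio_mfr and age_band_gradient must be > 0", call. = FALSE)
  }

  cfg <- list(
    seed = as.integer(seed), services = services,
    true_prevalence = tp[services$service],
    clinical_service = clinical_service,
    school_detection_prob = dp[services$service],
    clinical_capture_prob = clinical_capture_prob,
    field_error_rates = field_error_rates,
    commune_missing_prob = commune_missing_prob,
    sex_ratio_mfr = sex_ratio_mfr,
    age_band_gradient = age_band_gradient,
    multi_commune_prob = multi_commune_prob,
    prob_male = prob_male,
    band_shares = band_shares / sum(band_shares),
    fee_band_probs = fee_band_probs / sum(fee_band_probs),
    ethnicity_probs = ethnicity_probs / sum(ethnicity_probs),
    immigrant_prob = immigrant_prob, rural_prob = rural_prob,
    sen_other_prob = sen_other_prob,
    insurance_probs = insurance_probs / sum(insurance_probs),
    school_size = school_size,
    reference_date = as.Date(reference_date)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Configuration mirroring the 2021 Chilean registry margins
#'
#' Returns a [sim_config()] whose services, child populations, per-service
#' school-flag prevalence and clinically corrected true prevalence follow
#' the published national registry and health-service tables (29 health
#' services, 3.06 million children, clinical catchment Araucania Sur).
#' Per-service detection probability is the ratio of school-flag to true
#' prevalence, so the generated registry reproduces the published
#' school-prevalence geography in expectation.
#'
#' @param scale factor applied to every service population (use `scale < 1`
#'   for fast test-sized registries; prevalences are unaffected).
#' @param seed RNG seed.
#' @param ... further arguments passed to [sim_config()].
#' @return a `sim_config`.
#' @export
chile_sim_config <- function(scale = 1, seed = 1L, ...) {
  tab <- chile_service_table()
  services <- data.frame(
    service = tab$service,
    population = pmax(1L, as.integer(round(tab$population * scale)))
  )
  true_prev <- stats::setNames(tab$updated_prev / 100, tab$service)
  detect <- stats::setNames(tab$school_prev / tab$updated_prev, tab$service)
  sim_config(
    seed = seed, services = services, true_prevalence = true_prev,
    clinical_service = "Araucania Sur", school_detection_prob = detect, ...
  )
}

#' Published per-service prevalence table
#'
#' Health-service child populations with adjusted school prevalence and
#' adjusted clinically updated prevalence (percent, with 95% limits), as
#' shipped in `extdata/chile_services_2021.csv`. Service names are
#' ASCII-normalised.
#'
#' @return data frame with one row per health service.
#' @export
chile_service_table <- function() {
  path <- system.file("extdata", "chile_services_2021.csv", package = "prevalink")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published national registry summary counts
#'
#' Named vector of headline counts from the 2021 registry and the clinical
#' linkage study (total pupils, ASD flags by sex, SEN programme totals,
#' clinical-service matches and residuals, national projections), as
#' shipped in `extdata/chile_registry_counts_2021.csv`.
#'
#' @return named numeric vector.
#' @export
chile_registry_counts <- function() {
  path <- system.file("extdata", "chile_registry_counts_2021.csv", package = "prevalink")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$value, tab$key)
}
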