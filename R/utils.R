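#' @keywords internal
"_PACKAGE"

AGE_BANDS <- c("6-8", "9-11", "12-14", "15-18")

# lower/upper age in whole years covered by each band
AGE_BAND_LIMITS <- list(
  "6-8"   = c(6L, 8L),
  "9-11"  = c(9L, 11L),
  "12-14" = c(12L, 14L),
  "15-18" = c(15L, 18L)
)

logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))

#' Age band for a date of birth at a reference date
#'
#' Assigns each date of birth to one of the four school age bands
#' (6-8, 9-11, 12-14, 15-18 completed years) at the reference date.
#'
#' @param dob vector of dates (`Date` or ISO-8601 strings).
#' @param reference_date date at which age is evaluated.
#' @return factor with levels `"6-8"`, `"9-11"`, `"12-14"`, `"15-18"`;
#'   `NA` for ages outside 6-18.
#' @export
age_band <- function(dob, reference_date) {
  dob <- as.Date(dob)
  reference_date <- as.Date(reference_date)
  age <- floor(as.numeric(reference_date - dob) / 365.25)
  band <- rep(NA_character_, length(age))
  band[age >= 6 & age <= 8] <- "6-8"
  band[age >= 9 & age <= 11] <- "9-11"
  band[age >= 12 & age <= 14] <- "12-14"
  band[age >= 15 & age <= 18] <- "15-18"
  factor(band, levels = AGE_BANDS)
}

# Deterministic per-stage seed derived from one pipeline seed; kept < 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 1L, prevalence = 2L, link = 3L, delta = 4L,
    bayes = 5L, report = 6L, determinants = 7L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 131L + off * 104729) %% 2147483647)
}

# report-boundary percent formatting: 2 d.p., round half to even (base round)
fmt_pct <- function(x, digits = 2) round(x, digits)

`%||%` <- function(a, b) if (is.null(a)) b else a
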