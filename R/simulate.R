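#' Simulate a school registry and clinical EHR extract with ground truth
#'
#' Draws one latent child population per health service, records every
#' child in the school registry, and records truly affected children of
#' the designated clinical service in an EHR extract with probability
#' `clinical_capture_prob`. Truly affected children carry the registry ASD
#' flag with probability `school_detection_prob` (and then always carry
#' the SEN flag: the registry records ASD only through the SEN programme).
#' Individual risk is modulated multiplicatively by sex (male-to-female
#' ratio `sex_ratio_mfr`) and age band (`age_band_gradient`), normalised
#' so that each service's marginal prevalence equals its configured true
#' prevalence.
#'
#' Clinical fields are copied from the registry truth and then corrupted
#' independently per field at the configured error rates (date of birth:
#' day/month transposition when valid, else a one-day shift; commune:
#' replaced by another commune of the service; insurance band: off by
#' one). With probability `multi_commune_prob` a patient appears under a
#' second commune as a duplicate row sharing the `patient_id`.
#'
#' @param config a [sim_config()].
#' @return object of class `registry_sim`: list with elements
#'   `students` (one row per child), `patients` (EHR rows for the clinical
#'   service), `truth` (one row per truly affected child, mapping
#'   `latent_person_id` to registry/EHR membership), `school_communes`
#'   (school to commune map) and `config`.
#' @examples
#' sim <- simulate_registry(sim_config(seed = 7, services = data.frame(
#'   service = c("A", "B"), population = c(2000, 3000)
#' ), clinical_service = "B"))
#' table(sim$students$asd_flag)
#' @export
simulate_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  svc <- config$services
  n_total <- sum(svc$population)
  service <- rep(svc$service, svc$population)

  sex <- ifelse(stats::runif(n_total) < config$prob_male, "M", "F")
  band <- sample(AGE_BANDS, n_total, replace = TRUE, prob = config$band_shares)
  lim <- do.call(rbind, AGE_BAND_LIMITS)[band, , drop = FALSE]
  # integer ages-in-days drawn so that floor(days / 365.25) stays inside
  # the band's completed-year limits
  lo_d <- ceiling(lim[, 1] * 365.25)
  hi_d <- ceiling((lim[, 2] + 1) * 365.25) - 1
  dob <- config$reference_date -
    (lo_d + floor(stats::runif(n_total) * (hi_d - lo_d + 1)))

  # commune and school assignment, per service (commune sizes follow a
  # mildly skewed rank-size law; each school belongs to one commune)
  commune <- character(n_total)
  school_id <- character(n_total)
  map_list <- vector("list", nrow(svc))
  pos <- 0L
  for (i in seq_len(nrow(svc))) {
    n_s <- svc$population[i]
    k <- svc$n_communes[i]
    idx <- pos + seq_len(n_s)
    pos <- pos + n_s
    cprob <- (seq_len(k))^-0.8
    cprob <- cprob / sum(cprob)
    cnames <- sprintf("%s C%02d", svc$service[i], seq_len(k))
    ci <- sample.int(k, n_s, replace = TRUE, prob = cprob)
    commune[idx] <- cnames[ci]
    n_sch <- pmax(1L, as.integer(round(n_s * cprob / config$school_size)))
    sch_commune <- rep(cnames, n_sch)
    sch_names <- sprintf("%s-SCH%04d", svc$service[i], seq_along(sch_commune))
    offset <- c(0L, cumsum(n_sch))
    school_id[idx] <- sch_names[offset[ci] + sample_int_vec(n_sch[ci])]
    map_list[[i]] <- data.frame(
      school_id = sch_names, commune = sch_commune,
      stringsAsFactors = FALSE
    )
  }
  school_communes <- do.call(rbind, map_list)

  fee_band <- sample(FEE_BANDS, n_total, replace = TRUE, prob = config$fee_band_probs)
  ethnicity <- sample(ETHNICITIES, n_total, replace = TRUE, prob = config$ethnicity_probs)
  immigrant <- stats::runif(n_total) < config$immigrant_prob
  rural <- stats::runif(n_total) < config$rural_prob
  insurance <- sample.int(length(config$insurance_probs), n_total,
    replace = TRUE, prob = config$insurance_probs
  )

  # individual risk: service base rate x sex ratio x age-band gradient,
  # normalised so the service marginal equals the configured prevalence
  e_sex <- config$prob_male * config$sex_ratio_mfr + (1 - config$prob_male)
  g <- config$age_band_gradient^(seq_along(AGE_BANDS) - 1)
  e_band <- sum(config$band_shares * g)
  base <- config$true_prevalence[service]
  p_asd <- base * ifelse(sex == "M", config$sex_ratio_mfr, 1) / e_sex *
    g[match(band, AGE_BANDS)] / e_band
  is_asd <- stats::runif(n_total) < pmin(p_asd, 1)

  detect <- config$school_detection_prob[service]
  asd_flag <- is_asd & (stats::runif(n_total) < detect)
  sen_flag <- asd_flag | (!asd_flag & stats::runif(n_total) < config$sen_other_prob)

  commune_obs <- commune
  commune_obs[stats::runif(n_total) < config$commune_missing_prob] <- NA_character_

  latent_person_id <- sprintf("L%08d", seq_len(n_total))
  students <- data.frame(
    student_id = sprintf("S%08d", seq_len(n_total)),
    sex = sex, dob = dob, age_band = band, health_service = service,
    commune = commune_obs, school_id = school_id, school_fee_band = fee_band,
    ses_proxy = insurance, ethnicity = ethnicity, immigrant = immigrant, rural = rural,
    sen_flag = sen_flag, asd_flag = asd_flag,
    stringsAsFactors = FALSE
  )

  patients <- simulate_patients(
    config, latent_person_id, service, sex, dob, commune, insurance,
    fee_band, is_asd
  )

  truth_idx <- which(is_asd)
  truth <- data.frame(
    latent_person_id = latent_person_id[truth_idx],
    student_id = students$student_id[truth_idx],
    health_service = service[truth_idx],
    is_asd = TRUE,
    in_school_registry_as_asd = asd_flag[truth_idx],
    in_ehr = latent_person_id[truth_idx] %in% patients$latent_person_id,
    stringsAsFactors = FALSE
  )

  structure(
    list(
      students = students, patients = patients, truth = truth,
      school_communes = school_communes, config = config
    ),
    class = "registry_sim"
  )
}

# sample one integer uniformly in 1..m for each element of m (vectorised)
sample_int_vec <- function(m) {
  1L + as.integer(floor(stats::runif(length(m)) * m))
}

simulate_patients <- function(config, latent_person_id, service, sex, dob,
                              commune, insurance, fee_band, is_asd) {
  err <- config$field_error_rates
  cand <- which(is_asd & service == config$clinical_service)
  cap <- cand[stats::runif(length(cand)) < config$clinical_capture_prob]
  n <- length(cap)
  empty <- data.frame(
    patient_id = character(), dob = as.Date(character()), sex = character(),
    commune = character(), insurance_status = integer(),
    fee_band_proxy = character(), icd10 = character(),
    latent_person_id = character(), stringsAsFactors = FALSE
  )
  if (n == 0) return(empty)

  dob_p <- dob[cap]
  corrupt <- stats::runif(n) < err$dob
  if (any(corrupt)) dob_p[corrupt] <- corrupt_dob(dob_p[corrupt])

  svc_communes <- sort(unique(commune[service == config$clinical_service]))
  com_p <- commune[cap]
  corrupt <- stats::runif(n) < err$commune
  if (any(corrupt)) {
    com_p[corrupt] <- other_commune(com_p[corrupt], svc_communes)
  }

  ins_p <- insurance[cap]
  corrupt <- stats::runif(n) < err$ses
  if (any(corrupt)) {
    shift <- ifelse(stats::runif(sum(corrupt)) < 0.5, -1L, 1L)
    ins_p[corrupt] <- pmin(
      pmax(ins_p[corrupt] + shift, 1L),
      length(config$insurance_probs)
    )
  }

  icd <- sample(c("F84.0", "F84.1", "F84.5", "F84.8", "F84.9"), n,
    replace = TRUE, prob = c(0.55, 0.10, 0.20, 0.05, 0.10)
  )

  patients <- data.frame(
    patient_id = sprintf("E%07d", seq_len(n)),
    dob = dob_p, sex = sex[cap], commune = com_p,
    insurance_status = ins_p, fee_band_proxy = fee_band[cap],
    icd10 = icd, latent_person_id = latent_person_id[cap],
    stringsAsFactors = FALSE
  )

  # residential moves: a second row under another commune, same patient_id
  dup <- which(stats::runif(n) < config$multi_commune_prob)
  if (length(dup) > 0 && length(svc_communes) > 1) {
    extra <- patients[dup, , drop = FALSE]
    extra$commune <- other_commune(extra$commune, svc_communes)
    patients <- rbind(patients, extra)
  }
  patients[order(patients$patient_id, patients$commune), , drop = FALSE]
}

# day/month transposition when it yields a different valid date, else +/- 1 day
corrupt_dob <- function(d) {
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m"))
  day <- as.integer(format(d, "%d"))
  swappable <- day <= 12 & day != m
  out <- d
  out[swappable] <- as.Date(sprintf("%04d-%02d-%02d", y[swappable], day[swappable], m[swappable]))
  n_rest <- sum(!swappable)
  if (n_rest > 0) {
    out[!swappable] <- d[!swappable] +
      ifelse(stats::runif(n_rest) < 0.5, -1L, 1L)
  }
  out
}

# replace each commune by a different one drawn from the service's list
other_commune <- function(x, pool) {
  if (length(pool) < 2) return(x)
  vapply(x, function(ci) sample(setdiff(pool, ci), 1L), character(1), USE.NAMES = FALSE)
}

#' Write simulated tables to CSV
#'
#' Writes `students.csv`, `patients.csv`, `truth.csv` and
#' `school_communes.csv` (UTF-8, ISO-8601 dates, fixed column order) to a
#' directory.
#'
#' @param sim a `registry_sim` from [simulate_registry()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "registry_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("students.csv", "patients.csv", "truth.csv", "school_communes.csv"))
  tabs <- sim[c("students", "patients", "truth", "school_communes")]
  for (i in seq_along(paths)) {
    utils::write.csv(tabs[[i]], paths[i], row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(paths)
}

#' Impute missing address communes from the school's commune
#'
#' Rows with a missing commune receive their school's commune. Rows whose
#' school is absent from the map are retained with the explicit marker
#' `"(unknown)"` and listed in a rejects report attached as attribute
#' `"rejects"`.
#'
#' @param students student table with `commune` and `school_id` columns.
#' @param school_map data frame with columns `school_id` and `commune`
#'   (e.g. the `school_communes` element of a simulation).
#' @return the student table with no missing communes; attribute
#'   `"rejects"` holds the rows (if any) whose school was unmapped.
#' @export
impute_commune <- function(students, school_map) {
  stopifnot(all(c("school_id", "commune") %in% names(school_map)))
  miss <- which(is.na(students$commune) | students$commune == "")
  rejects <- students[0, , drop = FALSE]
  if (length(miss) > 0) {
    lookup <- stats::setNames(school_map$commune, school_map$school_id)
    imputed <- lookup[students$school_id[miss]]
    unmapped <- is.na(imputed)
    if (any(unmapped)) {
      rejects <- students[miss[unmapped], , drop = FALSE]
      imputed[unmapped] <- "(unknown)"
    }
    students$commune[miss] <- imputed
  }
  attr(students, "rejects") <- rejects
  students
}
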