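#' Pipeline configuration
#'
#' Bundles the stage configurations for [run_pipeline()]. One global seed
#' cascades deterministically to per-stage seeds, so a rerun with the same
#' configuration reproduces every artifact byte for byte.
#'
#' @param sim a [sim_config()] (its seed is overridden by the cascade).
#' @param specs linkage field specifications.
#' @param threshold linkage acceptance threshold (bits).
#' @param mcmc an [mcmc_config()] (seed overridden by the cascade).
#' @param std standard population table.
#' @param out_dir artifact directory.
#' @param seed global pipeline seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            specs = NULL,
                            threshold = 9,
                            mcmc = mcmc_config(),
                            std = std_population(),
                            out_dir = tempfile("prevalink"),
                            seed = 1L) {
  structure(
    list(sim = sim, specs = specs, threshold = threshold, mcmc = mcmc,
         std = std, out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full estimation pipeline
#'
#' Stage order: simulate the registry and EHR extract; impute missing
#' communes from the school map; compute per-service standardized
#' prevalence; link clinical patients to flagged students; compute the
#' adjusted prevalence delta; build bounded priors and run the MCMC
#' projection; emit the per-service report, the national unmet-need
#' report, and a JSON manifest of artifact hashes. Stages read their
#' inputs from `out_dir`, so a subset can be rerun provided the upstream
#' artifacts exist.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stages to run (default all, in
#'   order): `"simulate"`, `"prevalence"`, `"link"`, `"delta"`, `"bayes"`,
#'   `"report"`.
#' @return invisibly, a list with the manifest, per-stage results and
#'   counts log.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "prevalence", "link",
                                    "delta", "bayes", "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  counts <- list()

  need <- function(path, stage) {
    if (!file.exists(path)) {
      stop("stage '", stage, "': missing input ", basename(path), call. = FALSE)
    }
    path
  }
  read_dated <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if ("dob" %in% names(tab)) tab$dob <- as.Date(tab$dob)
    tab
  }

  if ("simulate" %in% stages) {
    cfg <- config$sim
    cfg$seed <- stage_seed(config$seed, "simulate")
    sim <- simulate_registry(cfg)
    students <- impute_commune(sim$students, sim$school_communes)
    attr(students, "rejects") <- NULL
    sim$students <- students
    write_sim(sim, out)
    counts$students <- nrow(sim$students)
    counts$patients <- nrow(sim$patients)
    message("simulate: ", counts$students, " students, ",
            counts$patients, " patient rows")
    res$sim <- sim
  }

  students <- read_dated(need(file.path(out, "students.csv"), "prevalence"))
  clinical <- config$sim$clinical_service

  if ("prevalence" %in% stages) {
    by_service <- prevalence_table(students, list("health_service"), config$std)
    overall <- prevalence_table(
      students, list(character(0), "sex", "age_band", "ethnicity"), config$std
    )
    utils::write.csv(by_service, file.path(out, "prevalence_by_service.csv"),
                     row.names = FALSE)
    utils::write.csv(overall, file.path(out, "prevalence_overall.csv"),
                     row.names = FALSE)
    message("prevalence: ", nrow(by_service), " service estimates")
    res$prevalence <- list(by_service = by_service, overall = overall)
  }

  if ("link" %in% stages) {
    patients <- read_dated(need(file.path(out, "patients.csv"), "link"))
    flagged <- students[students$asd_flag & students$health_service == clinical, ]
    specs <- config$specs %||% default_field_specs(
      n_communes = length(unique(patients$commune))
    )
    ms <- link_records(flagged, patients, specs, threshold = config$threshold)
    utils::write.csv(ms$pairs, file.path(out, "matches.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(patient_id = ms$unmatched_patients),
      file.path(out, "unmatched_patients.csv"), row.names = FALSE
    )
    utils::write.csv(ms$greyzone, file.path(out, "greyzone.csv"), row.names = FALSE)
    counts$blocked <- nrow(ms$scored)
    counts$matches <- nrow(ms$pairs)
    counts$unmatched_patients <- length(ms$unmatched_patients)
    message("link: ", counts$matches, " matches, ",
            counts$unmatched_patients, " unmatched patients")
    res$matchset <- ms
  }

  if ("delta" %in% stages) {
    patients <- read_dated(need(file.path(out, "patients.csv"), "delta"))
    unmatched <- utils::read.csv(need(file.path(out, "unmatched_patients.csv"), "delta"),
                                 stringsAsFactors = FALSE)
    svc_students <- students[students$health_service == clinical, ]
    school_est <- direct_standardize(
      stratum_counts(svc_students), config$std, service = clinical
    )

    # updated cases: flagged pupils plus unmatched unique clinical patients
    uniq <- dedupe_patients(patients)
    extra <- uniq[uniq$patient_id %in% unmatched$patient_id, , drop = FALSE]
    extra_strata <- data.frame(
      age_band = age_band(extra$dob, config$sim$reference_date),
      sex = extra$sex
    )
    extra_counts <- stats::aggregate(
      list(extra = rep(1L, nrow(extra_strata))),
      extra_strata, FUN = sum
    )
    strata <- stratum_counts(svc_students)
    strata <- merge(strata, extra_counts, by = c("age_band", "sex"), all.x = TRUE)
    strata$extra[is.na(strata$extra)] <- 0L
    strata$cases <- pmin(strata$cases + strata$extra, strata$population)
    strata$extra <- NULL
    updated_est <- direct_standardize(strata, config$std, service = clinical)

    delta <- compute_delta(school_est, updated_est)
    delta_tab <- data.frame(
      delta = delta$delta, ci_width = delta$ci_width,
      school_pct = school_est$point, updated_pct = updated_est$point
    )
    utils::write.csv(delta_tab, file.path(out, "delta.csv"), row.names = FALSE)
    message(sprintf("delta: %.3f points (school %.3f -> updated %.3f)",
                    delta$delta, school_est$point, updated_est$point))
    res$delta <- delta
  }

  if ("bayes" %in% stages) {
    need(file.path(out, "delta.csv"), "bayes")
    if (is.null(res$delta)) {
      d <- utils::read.csv(file.path(out, "delta.csv"))
      school_est <- prevalence_estimate(d$school_pct, d$school_pct, d$school_pct,
                                        "direct", service = clinical)
      updated_est <- prevalence_estimate(d$updated_pct,
                                         d$updated_pct - d$ci_width / 2,
                                         d$updated_pct + d$ci_width / 2,
                                         "direct", service = clinical)
      res$delta <- compute_delta(school_est, updated_est)
    }
    by_service <- utils::read.csv(need(file.path(out, "prevalence_by_service.csv"),
                                       "bayes"), stringsAsFactors = FALSE)
    pops <- table(students$health_service)
    service_est <- data.frame(
      service = by_service$level,
      point = by_service$direct_pct,
      population = as.integer(pops[by_service$level])
    )
    priors <- build_priors(service_est, res$delta, clinical_service = clinical)
    mc <- config$mcmc
    mc$seed <- stage_seed(config$seed, "bayes")
    fit <- run_mcmc(priors, mc)
    summ <- fit$summary
    school_w <- (by_service$direct_hi - by_service$direct_lo)[
      match(summ$service, by_service$level)
    ]
    summ$projection_pct <- apply_delta(
      by_service$direct_pct[match(summ$service, by_service$level)], res$delta
    )
    bands <- t(mapply(credible_band, summ$projection_pct, school_w,
                      res$delta$ci_width))
    summ$projection_pct <- fmt_pct(summ$projection_pct)
    summ$band_lo <- fmt_pct(bands[, 1])
    summ$band_hi <- fmt_pct(bands[, 2])
    utils::write.csv(summ, file.path(out, "posterior_summaries.csv"),
                     row.names = FALSE)
    flat <- as.data.frame(matrix(aperm(fit$samples, c(1, 3, 2)),
                                 ncol = dim(fit$samples)[2]))
    names(flat) <- dimnames(fit$samples)[[2]]
    utils::write.csv(flat, file.path(out, "posterior_samples.csv"),
                     row.names = FALSE)
    counts$posterior_summaries <- nrow(summ)
    message("bayes: ", nrow(summ), " posterior summaries; converged = ",
            fit$converged)
    res$mcmc <- fit
  }

  if ("report" %in% stages) {
    need(file.path(out, "posterior_summaries.csv"), "report")
    unmatched <- utils::read.csv(need(file.path(out, "unmatched_patients.csv"),
                                      "report"), stringsAsFactors = FALSE)
    accessors <- sum(students$asd_flag & students$health_service == clinical)
    unmet <- unmet_need_report(nrow(unmatched), accessors)
    utils::write.csv(as.data.frame(unmet), file.path(out, "unmet_need.csv"),
                     row.names = FALSE)

    national <- direct_standardize(stratum_counts(students), config$std)
    proj <- national_projection(national, res$delta, nrow(students),
                                sum(students$asd_flag))
    utils::write.csv(
      data.frame(
        national_school_pct = fmt_pct(national$point),
        national_updated_pct = fmt_pct(proj$prevalence_pct),
        band_lo = fmt_pct(proj$band[1]), band_hi = fmt_pct(proj$band[2]),
        posited_cases = proj$posited_cases, unmet_cases = proj$unmet_cases,
        unmet_pct = fmt_pct(proj$unmet_pct)
      ),
      file.path(out, "national_projection.csv"), row.names = FALSE
    )
    res$national <- proj
    res$unmet <- unmet
    message(sprintf("report: national updated prevalence %.2f%%",
                    proj$prevalence_pct))
  }

  artifacts <- list.files(out, pattern = "\\.csv$", full.names = TRUE)
  manifest <- data.frame(
    file = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  res$counts <- counts
  invisible(res)
}

#' Unmet-need report for the clinical service
#'
#' Total cases are the unmatched clinical patients plus the pupils who do
#' access school-based support; the access and unmet percentages are
#' reported at 2 d.p.
#'
#' @param unmatched_patients unique clinical patients without a registry
#'   match.
#' @param accessors pupils accessing support for the condition.
#' @return list with `total_cases`, `accessors`, `unmatched_patients`,
#'   `access_pct`, `unmet_pct`.
#' @export
unmet_need_report <- function(unmatched_patients, accessors) {
  if (unmatched_patients < 0 || accessors < 0) {
    stop("inconsistent counts", call. = FALSE)
  }
  total <- unmatched_patients + accessors
  if (total == 0) stop("no cases: empty report", call. = FALSE)
  list(
    total_cases = total,
    accessors = accessors,
    unmatched_patients = unmatched_patients,
    access_pct = fmt_pct(100 * accessors / total),
    unmet_pct = fmt_pct(100 * unmatched_patients / total)
  )
}
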