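mk_students <- function(ids, sex, dob, commune = "C1", ses = 3L) {
  data.frame(
    student_id = ids, sex = sex, dob = as.Date(dob), commune = commune,
    insurance_status = ses, stringsAsFactors = FALSE
  )
}
mk_patients <- function(ids, sex, dob, commune = "C1", ses = 3L) {
  data.frame(
    patient_id = ids, sex = sex, dob = as.Date(dob), commune = commune,
    insurance_status = ses, stringsAsFactors = FALSE
  )
}

test_that("blocking keeps exactly the sex+dob agreeing pairs", {
  s <- mk_students(c("A", "B"), c("M", "F"), c("2010-01-01", "2012-05-05"))
  p <- mk_patients(c("X", "Y"), c("M", "F"), c("2013-01-01", "2014-05-05"))
  expect_equal(nrow(block_pairs(s, p)), 0L)

  p2 <- mk_patients("X", "M", "2010-01-01")
  cand <- block_pairs(s, p2)
  expect_equal(cand, data.frame(student_id = "A", patient_id = "X",
                                stringsAsFactors = FALSE))

  # no-noise synthetic run: candidates cover every true link, and equal the
  # exhaustive enumeration of sex+dob agreements
  sim <- simulate_registry(small_sim_config(
    seed = 17, clinical_pop = 10000, detection = 1, capture = 1,
    errors = list(dob = 0, commune = 0, ses = 0), multi_commune_prob = 0
  ))
  flagged <- sim$students[sim$students$asd_flag &
    sim$students$health_service == "Clinical", ]
  cand <- block_pairs(flagged, sim$patients)
  truth_pairs <- merge(sim$truth, sim$patients[c("patient_id", "latent_person_id")])
  expect_true(all(paste(truth_pairs$student_id, truth_pairs$patient_id) %in%
    paste(cand$student_id, cand$patient_id)))
  exhaustive <- merge(
    flagged[c("student_id", "sex", "dob")],
    sim$patients[c("patient_id", "sex", "dob")], by = c("sex", "dob")
  )
  expect_equal(nrow(cand), nrow(exhaustive))
})

test_that("field similarities follow the comparator definitions", {
  com <- field_spec("commune", "exact", m = 0.9, u = 0.05)
  expect_equal(as.numeric(field_similarity("Temuco", "Temuco", com)), 1)
  expect_equal(as.numeric(field_similarity("Temuco", "Villarrica", com)), 0)

  ses6 <- field_spec("ses", "ordinal", m = 0.8, u = 0.2, max_rank = 6)
  expect_equal(as.numeric(field_similarity(2, 3, ses6)), 1 - 1 / 5)
  expect_equal(as.numeric(field_similarity(1, 6, ses6)), 0)

  dspec <- field_spec("dob", "date_tolerant", m = 0.95, u = 0.001)
  expect_equal(as.numeric(field_similarity(
    as.Date("1990-03-07"), as.Date("1990-07-03"), dspec
  )), 0.8)

  # all date pairs on a small grid against the transposition oracle
  grid <- seq(as.Date("2011-02-09"), as.Date("2011-02-09") + 120, by = 7)
  grid <- c(grid, as.Date(c("2011-09-02", "2011-02-09", "2012-02-09")))
  for (a in seq_along(grid)) {
    for (b in seq_along(grid)) {
      expect_equal(
        as.numeric(field_similarity(grid[a], grid[b], dspec)),
        oracle_date_sim(grid[a], grid[b])
      )
    }
  }

  # missing values score zero and are counted
  s <- field_similarity(c(NA, "A"), c("A", "A"), com)
  expect_equal(as.numeric(s), c(0, 1))
  expect_equal(attr(s, "n_missing"), 1L)
})

test_that("composite pair weight matches the log-ratio formula", {
  one <- list(field_spec("f", "exact", m = 0.9, u = 0.1))
  expect_equal(pair_weight(1, one), log2(9))
  expect_equal(pair_weight(0, one), log2(0.1 / 0.9))

  # uninformative fields contribute nothing
  flat <- list(list(name = "f1", m = 0.4, u = 0.4), list(name = "f2", m = 0.7, u = 0.7))
  expect_equal(pair_weight(c(0.3, 0.9), flat), 0)
  expect_error(pair_weight(1, list(list(name = "f", m = 0.1, u = 0.4))),
               "configuration error")

  set.seed(77)
  specs <- list(
    field_spec("a", "exact", m = 0.95, u = 0.01),
    field_spec("b", "exact", m = 0.8, u = 0.3),
    field_spec("c", "ordinal", m = 0.7, u = 0.2, max_rank = 5)
  )
  for (i in 1:20) {
    sims <- runif(3)
    expect_equal(
      pair_weight(sims, specs),
      oracle_weight(sims, c(0.95, 0.8, 0.7), c(0.01, 0.3, 0.2)),
      tolerance = 1e-12
    )
  }
})

test_that("bijective assignment is greedy, thresholded and order-invariant", {
  scored <- data.frame(
    student_id = c("A", "A", "B"), patient_id = c("X", "Y", "Y"),
    weight = c(5, 4, 3), stringsAsFactors = FALSE
  )
  students <- data.frame(student_id = c("A", "B"))
  patients <- data.frame(patient_id = c("X", "Y"))
  ms <- assign_bijective(scored, students, patients, threshold = 0)
  expect_equal(ms$pairs$student_id, c("A", "B"))
  expect_equal(ms$pairs$patient_id, c("X", "Y"))

  # all below threshold -> empty
  empty <- assign_bijective(scored, students, patients, threshold = 10)
  expect_equal(nrow(empty$pairs), 0L)
  expect_setequal(empty$unmatched_patients, c("X", "Y"))

  # permuting input rows never changes the result (ties included)
  tied <- data.frame(
    student_id = c("A", "A", "B", "B"), patient_id = c("X", "Y", "X", "Y"),
    weight = c(2, 2, 2, 2), stringsAsFactors = FALSE
  )
  base <- assign_bijective(tied, students, patients, threshold = 0)$pairs
  set.seed(5)
  for (i in 1:10) {
    perm <- tied[sample(nrow(tied)), ]
    expect_equal(assign_bijective(perm, students, patients, threshold = 0)$pairs, base)
  }

  # raising the threshold never increases accepted pairs
  set.seed(6)
  big <- data.frame(
    student_id = sample(sprintf("S%02d", 1:20), 60, TRUE),
    patient_id = sample(sprintf("P%02d", 1:20), 60, TRUE),
    weight = runif(60, -5, 15), stringsAsFactors = FALSE
  )
  big <- big[!duplicated(big[1:2]), ]
  counts <- vapply(seq(-5, 15, by = 1), function(th) {
    nrow(assign_bijective(big, data.frame(student_id = unique(big$student_id)),
                          data.frame(patient_id = unique(big$patient_id)), th)$pairs)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("patient deduplication keeps one row per patient with all communes", {
  p <- data.frame(
    patient_id = c("P1", "P1", "P2"), sex = c("M", "M", "F"),
    dob = as.Date(c("2010-01-01", "2010-01-01", "2011-02-02")),
    commune = c("A", "B", "C"), insurance_status = c(2L, 2L, 3L),
    stringsAsFactors = FALSE
  )
  u <- dedupe_patients(p)
  expect_equal(nrow(u), 2L)
  expect_equal(u$communes[u$patient_id == "P1"], "A;B")
  expect_equal(nrow(attr(u, "conflicts")), 0L)

  # already-unique table is the identity up to the communes column
  u2 <- dedupe_patients(p[c(1, 3), ])
  expect_equal(u2$patient_id, c("P1", "P2"))

  # conflicting dob within one patient is reported
  pc <- p
  pc$dob[2] <- as.Date("2010-01-02")
  expect_equal(unique(attr(dedupe_patients(pc), "conflicts")$patient_id), "P1")

  # synthetic multi-commune extract dedupes to the latent person count
  sim <- simulate_registry(small_sim_config(seed = 23, clinical_pop = 10000,
                                            multi_commune_prob = 0.3))
  u3 <- dedupe_patients(sim$patients)
  expect_equal(nrow(u3), length(unique(sim$patients$latent_person_id)))
})

test_that("match rates reproduce the printed unique-patient rate", {
  rates <- match_rates(233, 488, 1376, 233 + 1132)
  expect_equal(rates$pct[rates$denominator == "unique patients"], 17.07)
  expect_equal(match_rates(0, 10, 10, 10)$pct, c(0, 0, 0))
  expect_equal(match_rates(10, 20, 15, 10)$pct[3], 100)
  expect_error(match_rates(1, 0, 1, 1), "positive")
})

test_that("Cohen's kappa follows the agreement formula", {
  expect_equal(cohens_kappa(matrix(c(30, 0, 0, 20), 2)), 1)
  # independent raters: observed equals chance agreement
  expect_equal(cohens_kappa(matrix(c(16, 24, 4, 6), 2)), 0, tolerance = 1e-12)
  tab <- matrix(c(45, 1, 1, 3), 2)
  po <- 48 / 50
  pe <- (46 * 46 + 4 * 4) / 50^2
  expect_equal(cohens_kappa(tab), (po - pe) / (1 - pe))
  expect_error(cohens_kappa(matrix(c(10, 0, 0, 0), 2)), "undefined")
})

test_that("noise-free linkage recovers every true link exactly", {
  res <- run_linkage_experiment(
    seed = 41, clinical_pop = 15000, detection = 1, capture = 1,
    errors = list(dob = 0, commune = 0, ses = 0),
    commune_missing_prob = 0, multi_commune_prob = 0
  )
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
})
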