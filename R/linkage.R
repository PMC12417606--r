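#' Field specification for Fellegi-Sunter linkage
#'
#' Declares one comparison field with its comparator and the conditional
#' agreement probabilities `m` (given a true match) and `u` (given a
#' non-match). Full agreement contributes `log2(m/u)` bits to the
#' composite pair weight, full disagreement `log2((1-m)/(1-u))`;
#' fractional similarities interpolate linearly between the two.
#'
#' @param name field name (must exist in both tables; `"dob"`, `"sex"`,
#'   `"commune"`, `"ses"`).
#' @param comparator one of `"exact"`, `"date_tolerant"` (1 for equal
#'   dates, 0.8 for a day/month transposition, 0 otherwise) or
#'   `"ordinal"` (`1 - |rank difference| / (max_rank - 1)`).
#' @param m,u agreement probabilities, `0 < u < m < 1`.
#' @param max_rank number of ordinal ranks (required for `"ordinal"`).
#' @return object of class `field_spec`.
#' @export
field_spec <- function(name, comparator = c("exact", "date_tolerant", "ordinal"),
                       m, u, max_rank = NULL) {
  comparator <- match.arg(comparator)
  if (!(u > 0 && m > u && m < 1)) {
    stop("configuration error: need 0 < u < m < 1 for field '", name, "'", call. = FALSE)
  }
  if (comparator == "ordinal" && (is.null(max_rank) || max_rank < 2)) {
    stop("ordinal comparator needs max_rank >= 2", call. = FALSE)
  }
  structure(
    list(name = name, comparator = comparator, m = m, u = u, max_rank = max_rank),
    class = "field_spec"
  )
}

#' Default linkage field specifications
#'
#' Date of birth (date-tolerant), sex (exact), commune of residence
#' (exact, `u = 1 / n_communes`) and the ordinal insurance-based SES
#' proxy. The m/u values are conventional starting points and should be
#' reviewed against the data at hand; all are surfaced here rather than
#' hard-coded downstream.
#'
#' @param n_communes number of communes in the catchment (drives the
#'   chance-agreement probability of the commune field).
#' @param ses_ranks number of ordinal SES ranks.
#' @return named list of [field_spec()]s.
#' @export
default_field_specs <- function(n_communes = 21, ses_ranks = 5) {
  list(
    dob = field_spec("dob", "date_tolerant", m = 0.95, u = 0.001),
    sex = field_spec("sex", "exact", m = 0.98, u = 0.5),
    commune = field_spec("commune", "exact", m = 0.90, u = 1 / n_communes),
    ses = field_spec("ses", "ordinal", m = 0.80, u = 0.20, max_rank = ses_ranks)
  )
}

#' Deduplicate patient rows to unique patients
#'
#' Patients who lived in more than one commune appear as multiple rows
#' sharing a `patient_id`. Collapses to one row per patient, retaining
#' every recorded commune (semicolon-joined in `communes`; comparison uses
#' the best similarity over the set). Rows disagreeing on sex or date of
#' birth within a patient are flagged in the `"conflicts"` attribute and
#' resolved by the first row in (dob, sex) sort order.
#'
#' @param patients patient table.
#' @return unique-patient table with attribute `"conflicts"`.
#' @export
dedupe_patients <- function(patients) {
  ord <- order(patients$patient_id, as.Date(patients$dob), patients$sex, patients$commune)
  p <- patients[ord, , drop = FALSE]
  first <- !duplicated(p$patient_id)
  uniq <- p[first, , drop = FALSE]
  communes <- tapply(p$commune, p$patient_id, function(x) {
    paste(sort(unique(x)), collapse = ";")
  })
  uniq$communes <- as.character(communes[uniq$patient_id])
  key <- paste(p$patient_id, p$dob, p$sex)
  n_keys <- tapply(key, p$patient_id, function(x) length(unique(x)))
  conflict_ids <- names(n_keys)[n_keys > 1]
  attr(uniq, "conflicts") <- patients[patients$patient_id %in% conflict_ids, , drop = FALSE]
  rownames(uniq) <- NULL
  uniq
}

#' Block candidate pairs on sex and date of birth
#'
#' Returns every (student, patient) pair agreeing exactly on sex and date
#' of birth. With `loose = TRUE` blocking relaxes to sex plus birth year
#' and month, recovering day-level near-misses for the date-tolerant
#' comparator (off by default).
#'
#' @param students student table (typically the condition-flagged subset).
#' @param patients unique-patient table (see [dedupe_patients()]).
#' @param loose block on year+month instead of the full date.
#' @return data frame of candidate `student_id` / `patient_id` pairs.
#' @export
block_pairs <- function(students, patients, loose = FALSE) {
  key <- function(tab) {
    d <- as.Date(tab$dob)
    if (loose) paste(tab$sex, format(d, "%Y-%m")) else paste(tab$sex, format(d, "%Y-%m-%d"))
  }
  s <- data.frame(
    student_id = students$student_id, blk = key(students),
    stringsAsFactors = FALSE
  )
  p <- data.frame(
    patient_id = patients$patient_id, blk = key(patients),
    stringsAsFactors = FALSE
  )
  out <- merge(s, p, by = "blk")[, c("student_id", "patient_id")]
  out <- out[order(out$student_id, out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Field similarity under a comparator
#'
#' Vectorised similarity in `[0, 1]`. Missing values score 0 (neutral
#' disagreement); the number of missing comparisons is attached as
#' attribute `"n_missing"`.
#'
#' @param a,b field values from the two records.
#' @param spec a [field_spec()].
#' @return numeric vector of similarities.
#' @export
field_similarity <- function(a, b, spec) {
  miss <- is.na(a) | is.na(b)
  s <- switch(spec$comparator,
    exact = as.numeric(as.character(a) == as.character(b)),
    date_tolerant = date_similarity(a, b),
    ordinal = 1 - abs(as.numeric(a) - as.numeric(b)) / (spec$max_rank - 1)
  )
  s[miss] <- 0
  s <- pmin(pmax(s, 0), 1)
  attr(s, "n_missing") <- sum(miss)
  s
}

date_similarity <- function(a, b) {
  a <- as.Date(a)
  b <- as.Date(b)
  s <- as.numeric(a == b)
  swapped <- !is.na(a) & !is.na(b) & a != b &
    format(a, "%Y") == format(b, "%Y") &
    format(a, "%d") == format(b, "%m") &
    format(a, "%m") == format(b, "%d")
  s[swapped] <- 0.8
  s
}

#' Composite Fellegi-Sunter pair weight
#'
#' `sum_f [ s_f log2(m_f/u_f) + (1 - s_f) log2((1-m_f)/(1-u_f)) ]` in bits,
#' with fractional similarities entering linearly.
#'
#' @param similarities numeric matrix (pairs x fields) or vector, columns
#'   named/ordered as `specs`.
#' @param specs list of [field_spec()]s.
#' @return numeric vector of weights (bits).
#' @export
pair_weight <- function(similarities, specs) {
  if (is.null(dim(similarities))) similarities <- matrix(similarities, nrow = 1)
  stopifnot(ncol(similarities) == length(specs))
  w <- 0
  for (j in seq_along(specs)) {
    f <- specs[[j]]
    if (f$m < f$u) stop("configuration error: m < u for field '", f$name, "'", call. = FALSE)
    agree <- log2(f$m / f$u)
    disagree <- log2((1 - f$m) / (1 - f$u))
    w <- w + similarities[, j] * agree + (1 - similarities[, j]) * disagree
  }
  as.numeric(w)
}

#' Score blocked candidate pairs
#'
#' Computes per-field similarities and the composite weight for each
#' candidate pair. The commune field is compared against every commune the
#' patient was recorded under (best similarity wins); the SES proxy is the
#' ordinal insurance band.
#'
#' @param pairs candidate pairs from [block_pairs()].
#' @param students student table with `dob`, `sex`, `commune` and an SES
#'   proxy column (`insurance_status`, `ses_proxy` or `ses`, first found).
#' @param patients unique-patient table.
#' @param specs list of [field_spec()]s (default [default_field_specs()]).
#' @return `pairs` with one similarity column per field plus `weight`.
#' @export
score_pairs <- function(pairs, students, patients, specs = default_field_specs()) {
  si <- match(pairs$student_id, students$student_id)
  pi <- match(pairs$patient_id, patients$patient_id)
  stopifnot(!anyNA(si), !anyNA(pi))
  ses_col <- intersect(c("insurance_status", "ses_proxy", "ses"), names(students))[1]
  if (is.na(ses_col)) stop("students table lacks an SES proxy column", call. = FALSE)
  communes <- if ("communes" %in% names(patients)) {
    strsplit(patients$communes[pi], ";", fixed = TRUE)
  } else {
    as.list(patients$commune[pi])
  }
  s_commune <- mapply(function(sc, pc) {
    if (is.na(sc) || length(pc) == 0) 0 else as.numeric(sc %in% pc)
  }, students$commune[si], communes, USE.NAMES = FALSE)

  sims <- cbind(
    dob = field_similarity(students$dob[si], patients$dob[pi], specs$dob),
    sex = field_similarity(students$sex[si], patients$sex[pi], specs$sex),
    commune = s_commune,
    ses = field_similarity(students[[ses_col]][si], patients$insurance_status[pi], specs$ses)
  )
  out <- pairs
  out[colnames(sims)] <- as.data.frame(sims)
  out$weight <- pair_weight(sims, specs[colnames(sims)])
  out
}

#' Bijective assignment of scored pairs
#'
#' Greedy descent by weight: a pair is accepted iff its weight is at least
#' the threshold and neither the student nor the patient is already taken.
#' Ties are broken by (student_id, patient_id) lexicographic order, which
#' makes the result invariant to input row order.
#'
#' @param scored scored pairs from [score_pairs()].
#' @param students,patients the tables that were linked (to enumerate the
#'   unmatched residuals).
#' @param threshold acceptance threshold in bits.
#' @return object of class `match_set`: list with `pairs` (accepted,
#'   one-to-one), `unmatched_students`, `unmatched_patients` and
#'   `threshold`.
#' @export
assign_bijective <- function(scored, students, patients, threshold = 9) {
  keep <- scored[scored$weight >= threshold, , drop = FALSE]
  keep <- keep[order(-keep$weight, keep$student_id, keep$patient_id), , drop = FALSE]
  taken_s <- character(0)
  taken_p <- character(0)
  acc <- logical(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    sid <- keep$student_id[i]
    pid <- keep$patient_id[i]
    if (!(sid %in% taken_s) && !(pid %in% taken_p)) {
      acc[i] <- TRUE
      taken_s <- c(taken_s, sid)
      taken_p <- c(taken_p, pid)
    }
  }
  pairs <- keep[acc, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(
      pairs = pairs,
      unmatched_students = sort(setdiff(students$student_id, pairs$student_id)),
      unmatched_patients = sort(setdiff(patients$patient_id, pairs$patient_id)),
      threshold = threshold
    ),
    class = "match_set"
  )
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf(
    "match_set: %d accepted pairs (threshold %.2f bits), %d unmatched students, %d unmatched patients\n",
    nrow(x$pairs), x$threshold, length(x$unmatched_students), length(x$unmatched_patients)
  ))
  invisible(x)
}

#' End-to-end probabilistic linkage
#'
#' Deduplicates patients, blocks on sex and date of birth, scores the
#' candidate pairs and assigns a bijective match set.
#'
#' @inheritParams score_pairs
#' @inheritParams assign_bijective
#' @param patients raw patient table (rows may repeat per commune).
#' @param loose passed to [block_pairs()].
#' @param greyzone_margin pairs scoring within this many bits below the
#'   threshold are returned in `greyzone` for clerical inspection.
#' @return a `match_set` with extra elements `scored` (all scored
#'   candidates), `greyzone` and `unique_patients`.
#' @export
link_records <- function(students, patients, specs = default_field_specs(),
                         threshold = 9, loose = FALSE, greyzone_margin = 3) {
  uniq <- dedupe_patients(patients)
  cand <- block_pairs(students, uniq, loose = loose)
  message("linkage: ", nrow(cand), " blocked candidate pairs")
  scored <- score_pairs(cand, students, uniq, specs)
  ms <- assign_bijective(scored, students, uniq, threshold)
  ms$scored <- scored
  ms$greyzone <- scored[scored$weight < threshold &
    scored$weight >= threshold - greyzone_margin, , drop = FALSE]
  ms$unique_patients <- uniq
  ms
}

#' Match-rate report
#'
#' Percentages of condition-flagged school records, patient rows and
#' unique patients having an accepted match, at 2 d.p.
#'
#' @param n_matches number of accepted pairs.
#' @param students_with_flag number of condition-flagged school records.
#' @param patient_rows number of raw patient rows.
#' @param unique_patients number of unique patients.
#' @return data frame with `denominator`, `n`, `matched`, `pct`.
#' @export
match_rates <- function(n_matches, students_with_flag, patient_rows, unique_patients) {
  if (min(students_with_flag, patient_rows, unique_patients) <= 0) {
    stop("denominators must be positive", call. = FALSE)
  }
  data.frame(
    denominator = c("school records", "patient rows", "unique patients"),
    n = c(students_with_flag, patient_rows, unique_patients),
    matched = n_matches,
    pct = fmt_pct(100 * n_matches / c(students_with_flag, patient_rows, unique_patients))
  )
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginals.
#'
#' @param tab 2x2 matrix (or coercible) of rater agreement counts.
#' @return kappa (scalar).
#' @export
cohens_kappa <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2, ncol(tab) == 2, all(tab >= 0))
  n <- sum(tab)
  if (n == 0) stop("empty agreement table", call. = FALSE)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    stop("chance agreement is 1; kappa undefined", call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Score a match set against simulation ground truth
#'
#' Precision and recall of the accepted pairs relative to the generator's
#' truth table. A pair is correct when the matched student is the latent
#' person behind the patient; the recall denominator is the number of
#' unique patients whose latent person is condition-flagged in the school
#' registry.
#'
#' @param matchset a `match_set` from [link_records()].
#' @param truth truth table from [simulate_registry()].
#' @param patients unique-patient table carrying `latent_person_id` (the
#'   `unique_patients` element of the match set by default).
#' @return list with `precision`, `recall`, `n_true_links`.
#' @export
evaluate_linkage <- function(matchset, truth, patients = matchset$unique_patients) {
  expected <- stats::setNames(truth$student_id, truth$latent_person_id)
  latent <- stats::setNames(patients$latent_person_id, patients$patient_id)
  linkable <- truth$in_school_registry_as_asd &
    truth$latent_person_id %in% patients$latent_person_id
  n_true <- sum(linkable)
  prs <- matchset$pairs
  if (nrow(prs) == 0) {
    return(list(precision = NA_real_, recall = 0, n_true_links = n_true))
  }
  correct <- prs$student_id == expected[latent[prs$patient_id]]
  correct[is.na(correct)] <- FALSE
  list(
    precision = mean(correct),
    recall = if (n_true == 0) NA_real_ else sum(correct) / n_true,
    n_true_links = n_true
  )
}
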