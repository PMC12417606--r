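#' Prevalence estimate container
#'
#' @param point,ci_low,ci_high percent-scale estimate and 95% limits.
#' @param method `"crude"` or `"direct"`.
#' @param n_cases,n_pop numerator and denominator counts.
#' @param level confidence level.
#' @param service optional service label (checked by [compute_delta()]).
#' @return object of class `prevalence_estimate`.
#' @export
prevalence_estimate <- function(point, ci_low, ci_high, method,
                                n_cases = NA_real_, n_pop = NA_real_,
                                level = 0.95, service = NULL) {
  stopifnot(ci_low <= point + 1e-9, point <= ci_high + 1e-9)
  structure(
    list(
      point = point, ci_low = ci_low, ci_high = ci_high, method = method,
      n_cases = n_cases, n_pop = n_pop, level = level, service = service
    ),
    class = "prevalence_estimate"
  )
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf(
    "%s prevalence%s: %.2f%% (%d%% CI %.2f-%.2f), %s/%s\n",
    x$method, if (is.null(x$service)) "" else paste0(" [", x$service, "]"),
    x$point, round(100 * x$level), x$ci_low, x$ci_high,
    format(x$n_cases, big.mark = ","), format(x$n_pop, big.mark = ",")
  ))
  invisible(x)
}

#' CI width in percentage points
#' @param x a `prevalence_estimate`.
#' @export
ci_width <- function(x) x$ci_high - x$ci_low

#' Crude prevalence with exact Poisson confidence limits
#'
#' Point estimate `100 * cases / population` with exact Poisson
#' (chi-square) limits on the case count, scaled to percent.
#'
#' @param cases,population case and denominator counts.
#' @param level confidence level (default 0.95).
#' @param service optional service label.
#' @return a [prevalence_estimate()].
#' @examples
#' crude_prevalence(1620, 132242) # 1.23% as in a clinical catchment of 132k
#' @export
crude_prevalence <- function(cases, population, level = 0.95, service = NULL) {
  if (length(population) != 1 || population <= 0) {
    stop("population must be a single positive count", call. = FALSE)
  }
  if (cases < 0 || cases > population) stop("cases must lie in [0, population]", call. = FALSE)
  a <- 1 - level
  low <- if (cases == 0) 0 else stats::qchisq(a / 2, 2 * cases) / 2
  high <- stats::qchisq(1 - a / 2, 2 * (cases + 1)) / 2
  prevalence_estimate(
    point = 100 * cases / population,
    ci_low = 100 * low / population, ci_high = 100 * high / population,
    method = "crude", n_cases = cases, n_pop = population,
    level = level, service = service
  )
}

#' Stratum case/population counts
#'
#' Aggregates a student table into per-stratum case and population counts
#' for standardization.
#'
#' @param students student table.
#' @param case_col logical column marking cases (default `"asd_flag"`).
#' @param by stratification columns (default age band and sex).
#' @return data frame with the `by` columns plus `cases` and `population`.
#' @export
stratum_counts <- function(students, case_col = "asd_flag",
                           by = c("age_band", "sex")) {
  stopifnot(all(c(case_col, by) %in% names(students)))
  key <- interaction(students[by], drop = FALSE, sep = "\r")
  cases <- tapply(as.logical(students[[case_col]]), key, sum)
  pop <- tapply(rep(1L, nrow(students)), key, sum)
  keys <- do.call(rbind, strsplit(names(cases), "\r", fixed = TRUE))
  out <- data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- by
  out$cases <- as.integer(ifelse(is.na(cases), 0L, cases))
  out$population <- as.integer(ifelse(is.na(pop), 0L, pop))
  out[out$population > 0 | out$cases > 0, , drop = FALSE]
}

check_std <- function(strata, std) {
  stopifnot(
    all(c("cases", "population") %in% names(strata)),
    all(c("weight") %in% names(std))
  )
  if (any(std$weight <= 0)) stop("standard weights must be > 0", call. = FALSE)
  by <- setdiff(names(std), "weight")
  if (anyDuplicated(std[by]) > 0) stop("duplicated standard strata", call. = FALSE)
  m <- merge(strata, std, by = by, all.x = TRUE, sort = TRUE)
  if (any(is.na(m$weight))) {
    miss <- m[is.na(m$weight), by, drop = FALSE]
    stop(
      "no standard weight for stratum: ",
      paste(apply(miss, 1, paste, collapse = "/"), collapse = ", "),
      call. = FALSE
    )
  }
  bad <- m$population == 0 & m$cases > 0
  if (any(bad)) stop("stratum with cases but zero population", call. = FALSE)
  drop <- m$population == 0 & m$cases == 0
  if (any(drop)) {
    warning(sum(drop), " empty stratum/strata dropped from standardization")
    m <- m[!drop, , drop = FALSE]
  }
  m
}

#' Directly standardized prevalence with gamma confidence limits
#'
#' Weighted average of stratum-specific rates using an external standard
#' population, `100 * sum(w_i r_i) / sum(w_i)`, with gamma (Fay-Feuer)
#' limits from [gamma_ci()]. The estimate is invariant to rescaling all
#' standard weights by a constant, and equals the crude estimate when the
#' weights are proportional to the data's own stratum populations.
#'
#' @param strata data frame of stratum counts (from [stratum_counts()] or
#'   built directly) with `cases`, `population` and the stratum columns.
#' @param std standard population: the same stratum columns plus `weight`.
#' @param level confidence level.
#' @param service optional service label.
#' @return a [prevalence_estimate()] with `method = "direct"`.
#' @export
direct_standardize <- function(strata, std, level = 0.95, service = NULL) {
  m <- check_std(strata, std)
  w <- m$weight / sum(m$weight)
  rate <- ifelse(m$population > 0, m$cases / m$population, 0)
  point <- sum(w * rate)
  ci <- gamma_ci(strata, std, level = level)
  prevalence_estimate(
    point = 100 * point, ci_low = ci[1], ci_high = ci[2],
    method = "direct", n_cases = sum(m$cases), n_pop = sum(m$population),
    level = level, service = service
  )
}

#' Gamma (Fay-Feuer) confidence limits for a standardized rate
#'
#' Treats the weighted case sum as gamma distributed and inverts
#' chi-square quantiles. With a single stratum whose weight equals its own
#' population the limits reduce to the exact Poisson chi-square limits for
#' the count. With zero cases the lower limit is 0 and the upper limit
#' uses the maximal stratum weight.
#'
#' @inheritParams direct_standardize
#' @return length-2 numeric vector `(low, high)` on the percent scale.
#' @references Fay MP, Feuer EJ (1997) Confidence intervals for directly
#'   standardized rates: a method based on the gamma distribution.
#'   Statistics in Medicine 16:791-801.
#' @export
gamma_ci <- function(strata, std, level = 0.95) {
  stopifnot(level > 0, level < 1)
  m <- check_std(strata, std)
  a <- 1 - level
  w <- (m$weight / sum(m$weight)) / m$population
  y <- sum(w * m$cases)
  v <- sum(w^2 * m$cases)
  wmax <- max(w)
  low <- if (y <= 0) 0 else (v / (2 * y)) * stats::qchisq(a / 2, 2 * y^2 / v)
  vup <- v + wmax^2
  yup <- y + wmax
  high <- (vup / (2 * yup)) * stats::qchisq(1 - a / 2, 2 * yup^2 / vup)
  100 * c(low, high)
}

#' Crude and standardized prevalence by grouping
#'
#' For each requested grouping (a character vector of student-table
#' columns; `character(0)` gives a single overall row) computes counts,
#' the within-variable percentage share, and crude and directly
#' standardized prevalence of the case flag.
#'
#' @param students student table.
#' @param groupings list of character vectors of grouping columns.
#' @param std standard population table (`age_band`, `sex`, `weight`).
#' @param case_col logical case column (default `"asd_flag"`).
#' @param level confidence level.
#' @return data frame with one row per group: grouping variable and level,
#'   `n`, `share_pct`, `cases`, crude and direct estimates with limits.
#' @export
prevalence_table <- function(students, groupings = list(character(0)),
                             std, case_col = "asd_flag", level = 0.95) {
  rows <- list()
  for (g in groupings) {
    stopifnot(all(g %in% names(students)))
    if (length(g) == 0) {
      grp <- factor(rep("(all)", nrow(students)))
      label <- "(overall)"
    } else {
      grp <- interaction(students[g], drop = TRUE, sep = " / ")
      label <- paste(g, collapse = " / ")
    }
    for (lev in levels(grp)) {
      sub <- students[grp == lev, , drop = FALSE]
      cases <- sum(as.logical(sub[[case_col]]))
      cr <- if (nrow(sub) > 0) crude_prevalence(cases, nrow(sub), level) else NULL
      di <- if (nrow(sub) > 0) {
        direct_standardize(stratum_counts(sub, case_col), std, level)
      } else {
        NULL
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = label, level = lev, n = nrow(sub),
        share_pct = fmt_pct(100 * nrow(sub) / nrow(students)),
        cases = cases,
        crude_pct = if (is.null(cr)) NA_real_ else fmt_pct(cr$point),
        crude_lo = if (is.null(cr)) NA_real_ else fmt_pct(cr$ci_low),
        crude_hi = if (is.null(cr)) NA_real_ else fmt_pct(cr$ci_high),
        direct_pct = if (is.null(di)) NA_real_ else fmt_pct(di$point),
        direct_lo = if (is.null(di)) NA_real_ else fmt_pct(di$ci_low),
        direct_hi = if (is.null(di)) NA_real_ else fmt_pct(di$ci_high),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Packaged synthetic standard population
#'
#' Age-band by sex weights built from the published registry's marginal
#' age-band and sex distributions under independence. This is a synthetic
#' stand-in for census projections (which cannot be redistributed), shipped
#' as `extdata/std_population_synthetic.csv`.
#'
#' @return data frame with columns `age_band`, `sex`, `weight`.
#' @export
std_population <- function() {
  path <- system.file("extdata", "std_population_synthetic.csv", package = "prevalink")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
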