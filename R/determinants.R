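#' Adjusted prevalence ratios by Poisson regression with robust variance
#'
#' Fits a log-link Poisson regression to a binary outcome (the standard
#' modified-Poisson device for prevalence ratios) and replaces the
#' model-based variance with the sandwich (HC0) estimator. Exponentiated
#' coefficients are adjusted prevalence ratios (aPR) with Wald intervals.
#'
#' @param data covariate table.
#' @param outcome name of the logical/0-1 outcome column.
#' @param covariates character vector of covariate columns; character and
#'   logical columns are treated as factors.
#' @param ref_levels named list giving the reference level per covariate
#'   (defaults to the first level alphabetically).
#' @param level confidence level for the Wald intervals.
#' @param alpha significance flag threshold (two-sided; default 0.001).
#' @param max_iter IRLS iteration cap.
#' @return object of class `pr_model`: list with `fit` (the `glm`),
#'   `vcov` (sandwich), `table` (variable, level, aPR, limits, p,
#'   significance flag) and `ref_levels`.
#' @export
fit_poisson_robust <- function(data, outcome, covariates,
                               ref_levels = list(), level = 0.95,
                               alpha = 0.001, max_iter = 50) {
  stopifnot(outcome %in% names(data), all(covariates %in% names(data)))
  y <- as.numeric(data[[outcome]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)

  df <- data.frame(.y = y)
  for (v in covariates) {
    x <- data[[v]]
    if (is.character(x) || is.logical(x) || is.factor(x)) {
      x <- factor(x)
      if (nlevels(x) < 2) {
        stop("zero-variance covariate: '", v, "'", call. = FALSE)
      }
      if (!is.null(ref_levels[[v]])) x <- stats::relevel(x, ref = ref_levels[[v]])
    } else if (stats::var(x) == 0) {
      stop("zero-variance covariate: '", v, "'", call. = FALSE)
    }
    df[[v]] <- x
  }

  form <- stats::as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  fit <- stats::glm(form, data = df, family = stats::poisson(link = "log"),
                    control = stats::glm.control(maxit = max_iter, epsilon = 1e-12))
  if (!fit$converged) stop("Poisson fit did not converge", call. = FALSE)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop(
      "singular design; aliased column(s): ",
      paste(names(beta)[is.na(beta)], collapse = ", "),
      call. = FALSE
    )
  }

  V <- sandwich::vcovHC(fit, type = "HC0")
  se <- sqrt(diag(V))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- 2 * stats::pnorm(-abs(beta / se))

  rows <- list()
  for (v in covariates) {
    x <- df[[v]]
    if (is.factor(x)) {
      levs <- levels(x)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = levs, term = c("(reference)", paste0(v, levs[-1])),
        stringsAsFactors = FALSE
      )
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "(per unit)", term = v, stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  idx <- match(tab$term, names(beta))
  tab$aPR <- ifelse(is.na(idx), 1, exp(beta[idx]))
  tab$ci_low <- ifelse(is.na(idx), 1, exp(beta[idx] - z * se[idx]))
  tab$ci_high <- ifelse(is.na(idx), 1, exp(beta[idx] + z * se[idx]))
  tab$p <- ifelse(is.na(idx), NA_real_, p[idx])
  tab$significant <- !is.na(tab$p) & tab$p < alpha
  tab$term <- NULL
  rownames(tab) <- NULL

  structure(
    list(fit = fit, vcov = V, table = tab, level = level,
         ref_levels = lapply(df[covariates], function(x) {
           if (is.factor(x)) levels(x)[1] else NA_character_
         })),
    class = "pr_model"
  )
}

#' @export
print.pr_model <- function(x, digits = 2, ...) {
  tab <- x$table
  tab$aPR <- round(tab$aPR, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Wald intervals for a fitted prevalence-ratio model
#'
#' Recomputes `exp(beta +/- z * robust_se)` at an arbitrary level from the
#' stored sandwich variance.
#'
#' @param model a `pr_model`.
#' @param level confidence level.
#' @return data frame with `term`, `aPR`, `ci_low`, `ci_high`.
#' @export
wald_intervals <- function(model, level = 0.95) {
  beta <- stats::coef(model$fit)
  se <- sqrt(diag(model$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    term = names(beta), aPR = exp(beta),
    ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    row.names = NULL
  )
}
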