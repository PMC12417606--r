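#' Adjusted prevalence delta between linked and registry estimates
#'
#' The correction carried from the clinical-validation service to every
#' other service: the difference, in percentage points, between the
#' standardized prevalence after linkage (school flags plus unmatched
#' clinical cases) and the standardized school-registry prevalence in the
#' same service. Its interval width is the maximum of the two source
#' interval widths.
#'
#' @param school_est [prevalence_estimate()] from school data in the
#'   clinical service.
#' @param updated_est [prevalence_estimate()] after linkage, same service
#'   and standardization.
#' @return object of class `delta_estimate`: list with `delta` (points),
#'   `ci_width` (points), and the two sources.
#' @export
compute_delta <- function(school_est, updated_est) {
  stopifnot(inherits(school_est, "prevalence_estimate"),
            inherits(updated_est, "prevalence_estimate"))
  if (!is.null(school_est$service) && !is.null(updated_est$service) &&
      school_est$service != updated_est$service) {
    stop("delta requires estimates from the same service", call. = FALSE)
  }
  if (school_est$method != updated_est$method) {
    stop("delta requires the same standardization method", call. = FALSE)
  }
  delta <- updated_est$point - school_est$point
  if (delta < 0) warning("negative adjusted prevalence delta")
  structure(
    list(
      delta = delta,
      ci_width = max(ci_width(school_est), ci_width(updated_est)),
      source_school = school_est, source_updated = updated_est
    ),
    class = "delta_estimate"
  )
}

#' @export
print.delta_estimate <- function(x, ...) {
  cat(sprintf(
    "adjusted prevalence delta: %.2f points (school %.2f%% -> updated %.2f%%), ci width %.2f\n",
    x$delta, x$source_school$point, x$source_updated$point, x$ci_width
  ))
  invisible(x)
}

#' Bounded uniform priors per health service
#'
#' Each service's prior on true prevalence is Uniform(lower, upper) with
#' `lower` its standardized school prevalence and `upper = lower + delta`
#' (proportion scale; capped at 1 with a warning). The clinical service's
#' upper bound is its directly observed updated prevalence. The binomial
#' observation attached to each service is the adjusted expected case
#' count `y = round(lower * n)`.
#'
#' @param service_est data frame with columns `service`, `point` (percent),
#'   `population` and optionally `y` (case count override).
#' @param delta a `delta_estimate`.
#' @param clinical_service name of the clinical service (its upper bound
#'   comes from the delta's updated source estimate), or `NULL`.
#' @return data frame of class `service_priors` with columns `service`,
#'   `lower`, `upper` (proportions), `n`, `y`.
#' @export
build_priors <- function(service_est, delta, clinical_service = NULL) {
  stopifnot(inherits(delta, "delta_estimate"),
            all(c("service", "point", "population") %in% names(service_est)))
  lower <- service_est$point / 100
  upper <- lower + delta$delta / 100
  if (!is.null(clinical_service)) {
    i <- service_est$service == clinical_service
    lower[i] <- delta$source_school$point / 100
    upper[i] <- delta$source_updated$point / 100
  }
  if (any(upper > 1)) {
    warning("prior upper bound capped at 1 for ",
            sum(upper > 1), " service(s)")
    upper <- pmin(upper, 1)
  }
  if (any(lower < 0 | lower > upper)) stop("invalid prior bounds", call. = FALSE)
  n <- service_est$population
  y <- if ("y" %in% names(service_est)) service_est$y else round(lower * n)
  if (any(y > n)) stop("case count exceeds population", call. = FALSE)
  out <- data.frame(
    service = service_est$service, lower = lower, upper = upper, n = n, y = y,
    stringsAsFactors = FALSE
  )
  class(out) <- c("service_priors", "data.frame")
  out
}

#' MCMC configuration
#'
#' @param burn_in adaptation/burn-in iterations discarded.
#' @param kept retained iterations per chain (no thinning by default).
#' @param thinning keep every `thinning`-th draw.
#' @param chains number of independent chains (for split R-hat).
#' @param seed RNG seed; chain c uses `seed + c - 1`.
#' @param proposal_sd initial random-walk step for prevalence, as a
#'   fraction of each prior's width (auto-tuned during burn-in to a
#'   20-50% acceptance rate).
#' @param sigma_fixed if non-`NULL`, the random-effect scale is fixed at
#'   this value instead of being sampled (0 removes the random effect).
#' @param use_likelihood `FALSE` samples from the priors alone.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(burn_in = 2000, kept = 2000, thinning = 1,
                        chains = 4, seed = 1L, proposal_sd = 0.25,
                        sigma_fixed = NULL, use_likelihood = TRUE) {
  stopifnot(burn_in > 0, kept > 0, thinning >= 1, chains >= 1)
  structure(
    list(burn_in = as.integer(burn_in), kept = as.integer(kept),
         thinning = as.integer(thinning), chains = as.integer(chains),
         seed = as.integer(seed), proposal_sd = proposal_sd,
         sigma_fixed = sigma_fixed, use_likelihood = isTRUE(use_likelihood)),
    class = "mcmc_config"
  )
}

#' Metropolis-within-Gibbs sampler for bounded-prior prevalence projection
#'
#' For each service s: prior `p_s ~ Uniform(lower_s, upper_s)`; likelihood
#' `y_s ~ Binomial(n_s, pi_s)` with `logit(pi_s) = logit(p_s) + b_s`;
#' service random effect `b_s ~ Normal(0, sigma^2)` and
#' `sigma ~ Half-Normal(1)`. Each sweep updates all `p_s` by a random walk
#' on the prevalence scale (proposals outside the prior support are
#' rejected, so every kept draw respects its bounds), all `b_s` by a
#' Gaussian random walk, and `log(sigma)` by a random walk with the
#' half-normal prior and Jacobian. Step sizes are tuned during burn-in
#' only, so the kept stream is a fixed-kernel Markov chain.
#'
#' @param priors a `service_priors` table from [build_priors()].
#' @param cfg an [mcmc_config()].
#' @return object of class `mcmc_fit`: list with `summary` (one row per
#'   service: posterior mean, mode, 95% credible limits on the proportion
#'   scale, split R-hat, kept draws), `samples` (kept x service x chain
#'   array of prevalence draws), `sigma` (kept sigma draws per chain),
#'   `converged` (all R-hat <= 1.1) and `config`.
#' @export
run_mcmc <- function(priors, cfg = mcmc_config()) {
  stopifnot(inherits(priors, "service_priors"), inherits(cfg, "mcmc_config"))
  S <- nrow(priors)
  lower <- priors$lower
  upper <- priors$upper
  width <- upper - lower
  n <- priors$n
  y <- priors$y
  n_keep <- cfg$kept %/% cfg$thinning

  loglik <- function(p, b) {
    if (!cfg$use_likelihood) return(rep(0, S))
    eta <- logit(pmin(pmax(p, 1e-12), 1 - 1e-12)) + b
    stats::dbinom(y, n, invlogit(eta), log = TRUE)
  }

  samples <- array(NA_real_, c(n_keep, S, cfg$chains),
                   dimnames = list(NULL, priors$service, NULL))
  sigma_draws <- matrix(NA_real_, n_keep, cfg$chains)

  for (ch in seq_len(cfg$chains)) {
    set.seed(cfg$seed + ch - 1L)
    p <- lower + stats::runif(S) * width
    p[width == 0] <- lower[width == 0]
    b <- rep(0, S)
    sigma <- cfg$sigma_fixed %||% 0.5
    step_p <- pmax(cfg$proposal_sd * width, 1e-12)
    step_r <- pmax(cfg$proposal_sd * width, 1e-12)
    step_b <- rep(0.3, S)
    step_s <- 0.3
    acc_p <- acc_b <- acc_r <- rep(0, S)
    acc_s <- 0
    ll <- loglik(p, b)
    kept_i <- 0L
    total <- cfg$burn_in + cfg$kept

    for (it in seq_len(total)) {
      # prevalence update (uniform prior cancels; reject outside support)
      prop <- p + stats::rnorm(S, 0, step_p)
      ok <- prop >= lower & prop <= upper & width > 0
      if (any(ok)) {
        ll_prop <- ll
        ll_prop[ok] <- loglik(prop, b)[ok]
        acc <- ok & log(stats::runif(S)) < (ll_prop - ll)
        p[acc] <- prop[acc]
        ll[acc] <- ll_prop[acc]
        acc_p <- acc_p + acc
      }

      # interweaving move: shift p along the likelihood ridge, absorbing
      # the shift into b so the linear predictor (and likelihood) is
      # unchanged; only the random-effect prior enters the ratio
      if (cfg$use_likelihood && (is.null(cfg$sigma_fixed) || cfg$sigma_fixed > 0)) {
        prop <- p + stats::rnorm(S, 0, step_r)
        ok <- prop > pmax(lower, 1e-12) & prop < pmin(upper, 1 - 1e-12) & width > 0
        if (any(ok)) {
          b_prop <- b + logit(pmin(pmax(p, 1e-12), 1 - 1e-12)) -
            logit(pmin(pmax(prop, 1e-12), 1 - 1e-12))
          lr <- stats::dnorm(b_prop, 0, sigma, log = TRUE) -
            stats::dnorm(b, 0, sigma, log = TRUE)
          acc <- ok & log(stats::runif(S)) < lr
          p[acc] <- prop[acc]
          b[acc] <- b_prop[acc]
          acc_r <- acc_r + acc
        }
      }

      # random effect update
      if (is.null(cfg$sigma_fixed) || cfg$sigma_fixed > 0) {
        prop_b <- b + stats::rnorm(S, 0, step_b)
        ll_prop <- loglik(p, prop_b)
        lr <- ll_prop - ll +
          stats::dnorm(prop_b, 0, sigma, log = TRUE) -
          stats::dnorm(b, 0, sigma, log = TRUE)
        acc <- log(stats::runif(S)) < lr
        b[acc] <- prop_b[acc]
        ll[acc] <- ll_prop[acc]
        acc_b <- acc_b + acc
      }

      # random-effect scale: RW on log sigma, Half-Normal(1) prior
      if (is.null(cfg$sigma_fixed)) {
        prop_s <- sigma * exp(stats::rnorm(1, 0, step_s))
        lr <- sum(stats::dnorm(b, 0, prop_s, log = TRUE)) -
          sum(stats::dnorm(b, 0, sigma, log = TRUE)) +
          (-prop_s^2 / 2) - (-sigma^2 / 2) +
          log(prop_s) - log(sigma)
        if (log(stats::runif(1)) < lr) {
          sigma <- prop_s
          acc_s <- acc_s + 1
        }
      }

      # step-size adaptation, burn-in only, every 100 sweeps
      if (it <= cfg$burn_in && it %% 100 == 0) {
        rate_p <- acc_p / 100
        step_p <- step_p * ifelse(rate_p > 0.5, 1.3, ifelse(rate_p < 0.2, 0.7, 1))
        step_p <- pmin(pmax(step_p, 1e-12), pmax(width, 1e-12))
        rate_r <- acc_r / 100
        step_r <- step_r * ifelse(rate_r > 0.5, 1.3, ifelse(rate_r < 0.2, 0.7, 1))
        step_r <- pmin(pmax(step_r, 1e-12), pmax(width, 1e-12))
        rate_b <- acc_b / 100
        step_b <- step_b * ifelse(rate_b > 0.5, 1.3, ifelse(rate_b < 0.2, 0.7, 1))
        if (acc_s / 100 > 0.5) step_s <- step_s * 1.3
        if (acc_s / 100 < 0.2) step_s <- step_s * 0.7
        acc_p <- acc_b <- acc_r <- rep(0, S)
        acc_s <- 0
      }

      if (it > cfg$burn_in) {
        k <- it - cfg$burn_in
        if (k %% cfg$thinning == 0) {
          kept_i <- kept_i + 1L
          samples[kept_i, , ch] <- p
          sigma_draws[kept_i, ch] <- sigma
        }
      }
    }
  }

  rhat <- vapply(seq_len(S), function(s) {
    if (width[s] == 0) return(1)
    split_rhat(samples[, s, , drop = FALSE])
  }, numeric(1))

  summ <- data.frame(
    service = priors$service,
    mean = apply(samples, 2, mean),
    mode = vapply(seq_len(S), function(s) {
      x <- as.vector(samples[, s, ])
      if (width[s] == 0 || length(unique(x)) < 10) return(stats::median(x))
      d <- stats::density(x, from = lower[s], to = upper[s])
      d$x[which.max(d$y)]
    }, numeric(1)),
    cri_low = apply(samples, 2, stats::quantile, probs = 0.025),
    cri_high = apply(samples, 2, stats::quantile, probs = 0.975),
    rhat = rhat,
    n_kept = n_keep * cfg$chains,
    stringsAsFactors = FALSE
  )
  rownames(summ) <- NULL
  converged <- all(is.finite(summ$rhat)) && all(summ$rhat <= 1.1)
  if (!converged) warning("chains flagged non-converged (split R-hat > 1.1)")

  structure(
    list(summary = summ, samples = samples, sigma = sigma_draws,
         converged = converged, priors = priors, config = cfg),
    class = "mcmc_fit"
  )
}

#' Split R-hat (Gelman-Rubin) over chains
#'
#' Each chain is split in half; the potential scale reduction factor is
#' computed over the resulting 2C half-chains.
#'
#' @param x draws: iterations x 1 x chains array, or iterations x chains
#'   matrix.
#' @return scalar R-hat (1 for zero-variance draws).
#' @export
split_rhat <- function(x) {
  if (length(dim(x)) == 3) x <- x[, 1, ]
  x <- as.matrix(x)
  n <- nrow(x) %/% 2
  if (n < 2) return(NA_real_)
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  mns <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(mns)
  if (W < 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Credible band of prescribed width around a projection
#'
#' Band centred on the projected prevalence whose width is the maximum of
#' the school-estimate interval width and the delta interval width,
#' truncated to `[0, 100]` percent.
#'
#' @param point projected prevalence (percent).
#' @param school_ci_width,delta_ci_width interval widths in points.
#' @return length-2 vector `(low, high)` in percent.
#' @export
credible_band <- function(point, school_ci_width, delta_ci_width) {
  stopifnot(school_ci_width >= 0, delta_ci_width >= 0)
  w <- max(school_ci_width, delta_ci_width)
  c(max(0, point - w / 2), min(100, point + w / 2))
}

#' Apply the adjusted prevalence delta to school estimates
#'
#' Additive projection on the percentage-point scale:
#' `projection = school point + delta`.
#'
#' @param points school-standardized prevalences (percent).
#' @param delta a `delta_estimate` or a numeric delta in points.
#' @return numeric vector of projected prevalences.
#' @export
apply_delta <- function(points, delta) {
  d <- if (inherits(delta, "delta_estimate")) delta$delta else delta
  points + d
}

#' National projection and unmet need
#'
#' Adds the adjusted prevalence delta to the national school-standardized
#' prevalence, converts to a posited national case count, and subtracts
#' the number of children accessing special-education support to give the
#' unmet need. When the posited count has been computed externally on
#' age-sex-adjusted weights it can be supplied via `posited_cases`.
#'
#' @param school_national national school [prevalence_estimate()].
#' @param delta a `delta_estimate` (or numeric points).
#' @param population national child population.
#' @param sen_accessors children accessing support for the condition.
#' @param posited_cases optional externally adjusted posited case count
#'   overriding `prevalence x population`.
#' @return list with `prevalence_pct`, `band` (credible band),
#'   `posited_cases`, `unmet_cases`, `unmet_pct`, `access_pct`.
#' @export
national_projection <- function(school_national, delta, population,
                                sen_accessors, posited_cases = NULL) {
  stopifnot(population > 0, sen_accessors >= 0)
  d <- if (inherits(delta, "delta_estimate")) delta$delta else delta
  dw <- if (inherits(delta, "delta_estimate")) delta$ci_width else 0
  prev <- school_national$point + d
  posited <- posited_cases %||% round(prev / 100 * population)
  unmet <- posited - sen_accessors
  if (unmet < 0) warning("negative unmet need: accessors exceed posited cases")
  list(
    prevalence_pct = prev,
    band = credible_band(prev, ci_width(school_national), dw),
    posited_cases = posited,
    unmet_cases = unmet,
    unmet_pct = 100 * unmet / posited,
    access_pct = 100 * sen_accessors / posited
  )
}
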