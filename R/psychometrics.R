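# Internal logistic fit on aggregated cells: angle grid with green counts k
# out of n. Returns coefficients (intercept, slope per degree) plus a
# separation flag. Complete separation (or non-convergence) falls back to a
# ridge-penalised maximum likelihood fit so the PSE is always finite.
fit_logistic_cells <- function(angle, k, n, ridge = 1e-4) {
  keep <- n > 0
  angle <- angle[keep]; k <- k[keep]; n <- n[keep]
  if (length(unique(angle)) < 2L) {
    stop("unidentifiable: need responses at >= 2 distinct angles", call. = FALSE)
  }
  if (sum(k) == 0 || sum(k) == sum(n)) {
    stop("degenerate data: all responses identical (proportion green = ",
         round(sum(k) / sum(n)), "); cannot fit a psychometric function",
         call. = FALSE)
  }
  x <- cbind(1, angle)
  fit <- suppressWarnings(
    stats::glm.fit(x, k / n, weights = n, family = stats::binomial())
  )
  p_hat <- fit$fitted.values
  separated <- !fit$converged || all(pmin(p_hat, 1 - p_hat) < 1e-6)
  if (!separated) {
    return(list(coef = unname(fit$coefficients), penalized = FALSE))
  }
  # ridge-penalised logistic log-likelihood; small fixed penalty keeps the
  # slope finite while leaving well-identified fits essentially untouched
  negll <- function(b) {
    eta <- b[1] + b[2] * angle
    -sum(k * eta - n * log1p(exp(eta))) + ridge * sum(b^2)
  }
  grad <- function(b) {
    eta <- b[1] + b[2] * angle
    p <- stats::plogis(eta)
    d <- n * p - k
    c(sum(d), sum(d * angle)) + 2 * ridge * b
  }
  start <- c(-mean(angle) * 0.5, 0.5)
  opt <- stats::optim(start, negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(coef = opt$par, penalized = TRUE)
}

aggregate_cells <- function(trials) {
  stopifnot(all(c("angle_deg", "response") %in% names(trials)))
  tr <- trials[!is.na(trials$response), ]
  if (!all(tr$response %in% c(0L, 1L))) {
    stop("responses must be coded 0/1", call. = FALSE)
  }
  k <- rowsum(tr$response, tr$angle_deg)
  n <- rowsum(rep(1L, nrow(tr)), tr$angle_deg)
  tibble::tibble(angle_deg = as.numeric(rownames(k)),
                 n_green = as.numeric(k), n_total = as.numeric(n))
}

#' Fit a psychometric function to one object's responses
#'
#' Maximum-likelihood logistic regression of the green-response probability
#' on tilt angle, pooled over sides and repetitions. On complete separation
#' the fit falls back to a fixed small ridge penalty (1e-4 on the
#' coefficients) and is flagged `converged = "penalized"`, guaranteeing a
#' finite PSE; callers may exclude flagged fits. The link family is isolated
#' here, so swapping the logistic for a cumulative normal is a local change.
#'
#' @param trials trial tibble with `angle_deg` and binary `response`
#'   (0 = red, 1 = green), or an aggregated table with `angle_deg`,
#'   `n_green`, `n_total`.
#' @return A `psychometric_fit`: list with `intercept`, `slope` (per
#'   degree), `pse` (`-intercept/slope`, degrees), `converged`
#'   (`"yes"`/`"penalized"`), `n_trials` and the aggregated `cells`.
#' @export
fit_psychometric <- function(trials) {
  cells <- if (all(c("n_green", "n_total") %in% names(trials))) {
    tibble::as_tibble(trials[, c("angle_deg", "n_green", "n_total")])
  } else {
    aggregate_cells(trials)
  }
  res <- fit_logistic_cells(cells$angle_deg, cells$n_green, cells$n_total)
  b <- res$coef
  structure(
    list(intercept = b[1], slope = b[2], pse = -b[1] / b[2],
         converged = if (res$penalized) "penalized" else "yes",
         n_trials = sum(cells$n_total), cells = cells),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> PSE %.2f deg (slope %.3f/deg, %d trials, converged: %s)\n",
    x$pse, x$slope, x$n_trials, x$converged))
  invisible(x)
}

#' Point of subjective equality of a fitted psychometric function
#'
#' The tilt at which the fitted probability of a green response is exactly
#' 0.5: `-intercept / slope`.
#'
#' @param fit a `psychometric_fit`.
#' @return PSE in degrees.
#' @export
pse <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (fit$slope <= 0) {
    stop("non-monotone fit: slope must be positive to report a PSE", call. = FALSE)
  }
  -fit$intercept / fit$slope
}

#' Bootstrap distribution of the PSE
#'
#' Parametric bootstrap (the default): each resample redraws every angle
#' cell's green count from a binomial at the fitted probability, refits, and
#' records the PSE; the 95% interval is the 2.5/97.5 percentile of the
#' replicates. `nonparametric = TRUE` resamples trial rows instead.
#'
#' @param trials as in [fit_psychometric()].
#' @param n_resamples number of bootstrap resamples.
#' @param seed integer seed.
#' @param nonparametric resample trials rather than redrawing binomial
#'   counts.
#' @return A `bootstrap_pse`: list with `mean_pse`, `ci_low`, `ci_high`,
#'   `replicates`, `n_resamples`, `n_failed`, `seed`.
#' @export
bootstrap_pse <- function(trials, n_resamples = 1000L, seed = 1L,
                          nonparametric = FALSE) {
  fit <- fit_psychometric(trials)
  cells <- fit$cells
  p_hat <- stats::plogis(fit$intercept + fit$slope * cells$angle_deg)
  nc <- nrow(cells)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      if (nonparametric) {
        k <- vapply(seq_len(nc), function(j) {
          sum(sample(c(rep(1L, cells$n_green[j]),
                       rep(0L, cells$n_total[j] - cells$n_green[j])),
                     cells$n_total[j], replace = TRUE))
        }, numeric(1))
      } else {
        k <- stats::rbinom(nc, cells$n_total, p_hat)
      }
      out <- tryCatch(
        fit_logistic_cells(cells$angle_deg, k, cells$n_total),
        error = function(e) NULL
      )
      if (is.null(out)) NA_real_ else -out$coef[1] / out$coef[2]
    }, numeric(1))
  })
  n_failed <- sum(is.na(reps))
  if (n_failed > n_resamples / 2) {
    stop("unstable bootstrap: more than 50% of replicates failed to converge",
         call. = FALSE)
  }
  reps_ok <- reps[!is.na(reps)]
  ci <- unname(stats::quantile(reps_ok, c(0.025, 0.975), type = 7))
  structure(
    list(mean_pse = mean(reps_ok), ci_low = ci[1], ci_high = ci[2],
         replicates = reps_ok, n_resamples = n_resamples,
         n_failed = n_failed, seed = seed, original_fit = fit),
    class = "bootstrap_pse"
  )
}

#' @export
print.bootstrap_pse <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_pse> mean %.2f deg, 95%% CI [%.2f, %.2f] (%d resamples, %d failed)\n",
    x$mean_pse, x$ci_low, x$ci_high, x$n_resamples, x$n_failed))
  invisible(x)
}

#' Per-responder, per-object PSE table
#'
#' Applies [fit_psychometric()] to every (responder, object) slice of a
#' trial table, optionally with bootstrap confidence intervals. The same
#' routine serves simulated observers, ingested behavioural data, and
#' model-generated response tables.
#'
#' @param trials trial tibble with `responder_id`, `object_id`,
#'   `angle_deg`, `response`.
#' @param n_boot bootstrap resamples for CIs; 0 skips the bootstrap.
#' @param seed bootstrap seed.
#' @return Tidy tibble: `responder_id`, `object_id`, `pse`, `ci_low`,
#'   `ci_high`, `converged`.
#' @export
pse_table <- function(trials, n_boot = 0L, seed = 1L) {
  stopifnot(all(c("responder_id", "object_id") %in% names(trials)))
  groups <- unique(trials[, c("responder_id", "object_id")])
  dplyr::bind_rows(lapply(seq_len(nrow(groups)), function(i) {
    sl <- trials[trials$responder_id == groups$responder_id[i] &
                   trials$object_id == groups$object_id[i], ]
    row <- tibble::tibble(
      responder_id = groups$responder_id[i],
      object_id = groups$object_id[i],
      pse = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      converged = NA_character_
    )
    fit <- tryCatch(fit_psychometric(sl), error = function(e) NULL)
    if (is.null(fit)) {
      row$converged <- "failed"
      return(row)
    }
    row$pse <- fit$pse
    row$converged <- fit$converged
    if (n_boot > 0L) {
      bs <- tryCatch(
        bootstrap_pse(sl, n_resamples = n_boot,
                      seed = seed + i),
        error = function(e) NULL
      )
      if (!is.null(bs)) {
        row$ci_low <- bs$ci_low
        row$ci_high <- bs$ci_high
      }
    }
    row
  }))
}
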