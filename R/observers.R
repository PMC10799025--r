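#' Parameters for a simulated observer
#'
#' A simulated observer judges "falls to the green mat" with probability
#' \deqn{p(\theta) = \gamma + (1 - \gamma - \lambda)\,
#'   F\!\big((\theta - (\theta_c + b)) / s\big)}
#' where \eqn{F} is the standard logistic function, \eqn{\theta_c} the
#' object's critical angle, \eqn{b} the PSE bias (negative values move the
#' perceived tipping point below ground truth: a safe-side bias), and
#' \eqn{s} the psychometric spread. Guess (\eqn{\gamma}) and lapse
#' (\eqn{\lambda}) rates default to zero and exist only to stress-test
#' fitting.
#'
#' @param pse_bias signed offset in degrees added to each object's critical
#'   angle.
#' @param slope_scale psychometric spread in degrees (> 0).
#' @param guess_rate,lapse_rate asymptote parameters in \[0, 0.5) with
#'   `guess_rate + lapse_rate < 1`.
#' @return An `observer_params` list.
#' @export
observer_params <- function(pse_bias = 0, slope_scale = 4,
                            guess_rate = 0, lapse_rate = 0) {
  if (slope_scale <= 0) stop("invalid params: slope_scale must be > 0", call. = FALSE)
  if (guess_rate < 0 || guess_rate >= 0.5 || lapse_rate < 0 || lapse_rate >= 0.5 ||
      guess_rate + lapse_rate >= 1) {
    stop("invalid params: guess/lapse rates out of range", call. = FALSE)
  }
  structure(list(pse_bias = pse_bias, slope_scale = slope_scale,
                 guess_rate = guess_rate, lapse_rate = lapse_rate),
            class = "observer_params")
}

#' Default observer cohorts
#'
#' Two tunable cohorts bracketing the qualitative adult-over-child
#' precision ordering seen in developmental work: "adult_like" (PSE bias
#' -4 degrees, spread 4 degrees) and "child_like" (bias -8, spread 8). Both
#' carry the safe-side bias (negative PSE bias). These are configuration
#' defaults, not estimates of any participant group.
#'
#' @return Named list of [observer_params()].
#' @export
observer_cohorts <- function() {
  list(
    adult_like = observer_params(pse_bias = -4, slope_scale = 4),
    child_like = observer_params(pse_bias = -8, slope_scale = 8)
  )
}

#' Probability of a "green" response for a simulated observer
#'
#' @param catalog catalog rows (recycled against `tilt_deg`).
#' @param tilt_deg tilt angle(s) in degrees.
#' @param params an [observer_params()].
#' @inheritParams centroid_height
#' @return Probability of responding green; strictly increasing in tilt.
#' @export
response_probability <- function(catalog, tilt_deg, params,
                                 include_base_cap = FALSE) {
  stopifnot(inherits(params, "observer_params"))
  theta_c <- critical_angle(catalog, include_base_cap = include_base_cap)
  mid <- theta_c + params$pse_bias
  core <- stats::plogis((tilt_deg - mid) / params$slope_scale)
  params$guess_rate + (1 - params$guess_rate - params$lapse_rate) * core
}

#' Simulate binary fall judgments for one observer
#'
#' Fills a [trial_grid()] with independent Bernoulli responses at the
#' observer's [response_probability()], plus the ground-truth label
#' (1 = green). Identical seeds give identical tables.
#'
#' @param design an [experiment_design()].
#' @param catalog catalog containing every design object.
#' @param params an [observer_params()].
#' @param seed integer seed.
#' @inheritParams centroid_height
#' @return Trial tibble with `response` and `label` filled (1 = green,
#'   0 = red).
#' @export
simulate_responses <- function(design, catalog, params, seed,
                               include_base_cap = FALSE) {
  catalog <- validate_catalog(catalog, require_unique = TRUE)
  if (!all(design$objects %in% catalog$object_id)) {
    stop("design references objects missing from the catalog", call. = FALSE)
  }
  grid <- trial_grid(design)
  cat_idx <- match(grid$object_id, catalog$object_id)
  p <- response_probability(catalog[cat_idx, ], grid$angle_deg, params,
                            include_base_cap = include_base_cap)
  grid$response <- withr::with_seed(seed, stats::rbinom(nrow(grid), 1L, p))
  grid$label <- as.integer(
    fall_label(catalog[cat_idx, ], grid$angle_deg,
               include_base_cap = include_base_cap) == "green")
  grid
}

#' Simulate a cohort of observers
#'
#' Each observer draws an individual PSE bias from a normal distribution
#' centred on the cohort bias (`bias_sd` between-observer spread), then
#' responds via [simulate_responses()]. Between-observer variability is what
#' gives the downstream group-level t-tests something to test.
#'
#' @inheritParams simulate_responses
#' @param n_observers number of observers.
#' @param bias_sd between-observer standard deviation of the PSE bias, in
#'   degrees.
#' @param cohort_name prefix for responder ids.
#' @return Trial tibble with a `responder_id` column.
#' @export
simulate_cohort <- function(design, catalog, params, n_observers, seed,
                            bias_sd = 2, cohort_name = "obs",
                            include_base_cap = FALSE) {
  stopifnot(inherits(params, "observer_params"), n_observers >= 1L)
  biases <- withr::with_seed(seed, stats::rnorm(n_observers, params$pse_bias, bias_sd))
  seeds <- withr::with_seed(seed + 1L, sample.int(.Machine$integer.max %/% 2L, n_observers))
  dplyr::bind_rows(lapply(seq_len(n_observers), function(i) {
    pi_params <- observer_params(biases[i], params$slope_scale,
                                 params$guess_rate, params$lapse_rate)
    tab <- simulate_responses(design, catalog, pi_params, seeds[i],
                              include_base_cap = include_base_cap)
    tab$responder_id <- sprintf("%s_%02d", cohort_name, i)
    tab[, c("responder_id", setdiff(names(tab), "responder_id"))]
  }))
}
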