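# Fast R^2 of y on a predictor matrix (with intercept), via .lm.fit.
r_squared <- function(y, x) {
  x <- cbind(1, x)
  res <- stats::.lm.fit(x, y)$residuals
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) stop("response has zero variance", call. = FALSE)
  1 - sum(res^2) / ss_tot
}

#' Test PSEs against ground-truth critical angles
#'
#' Computes each responder's mean (PSE - ground truth) over objects and
#' tests the responder means against zero with a two-sided one-sample
#' t-test. Negative mean differences mean PSEs below ground truth: the
#' safe-side bias.
#'
#' @param pse_tab tibble with `responder_id`, `object_id`, `pse` (e.g. from
#'   [pse_table()]).
#' @param truth tibble with `object_id`, `critical_angle` (from
#'   [ground_truth()]).
#' @return One-row tibble: `n`, `mean_difference`, `t`, `df`, `p`,
#'   `cohens_d`, `ci_low`, `ci_high`, `exact_shift` (flag set when the
#'   responder means have zero variance, in which case `t`/`p` are `NA`
#'   rather than infinite).
#' @export
pse_truth_difference <- function(pse_tab, truth) {
  stopifnot(all(c("responder_id", "object_id", "pse") %in% names(pse_tab)))
  m <- dplyr::left_join(pse_tab, truth[, c("object_id", "critical_angle")],
                        by = "object_id")
  if (anyNA(m$critical_angle)) {
    stop("ground truth missing for some objects", call. = FALSE)
  }
  m$diff <- m$pse - m$critical_angle
  per <- tapply(m$diff, m$responder_id, mean, na.rm = TRUE)
  per <- per[!is.na(per)]
  if (length(per) < 2L) stop("need >= 2 responders", call. = FALSE)
  mu <- mean(per); s <- stats::sd(per); n <- length(per)
  if (s < 1e-12) {
    # degenerate: every responder shifted identically; an exact null gives
    # the null identity (t = 0, p = 1) rather than 0/0, a nonzero shift is
    # flagged instead of reporting an infinite t
    if (abs(mu) < 1e-12) {
      return(tibble::tibble(n = n, mean_difference = 0, t = 0, df = n - 1,
                            p = 1, cohens_d = 0, ci_low = 0, ci_high = 0,
                            exact_shift = FALSE))
    }
    return(tibble::tibble(n = n, mean_difference = mu, t = NA_real_,
                          df = n - 1, p = NA_real_, cohens_d = NA_real_,
                          ci_low = mu, ci_high = mu, exact_shift = TRUE))
  }
  tt <- stats::t.test(per, mu = 0)
  tibble::tibble(
    n = n, mean_difference = mu, t = unname(tt$statistic),
    df = unname(tt$parameter), p = tt$p.value, cohens_d = mu / s,
    ci_low = tt$conf.int[1], ci_high = tt$conf.int[2], exact_shift = FALSE
  )
}

#' Linear trend of PSEs over stability-ordered objects
#'
#' Regresses PSE on the orthonormal linear polynomial contrast of object
#' rank, with objects ordered by decreasing ground-truth critical angle
#' (most stable first) unless an explicit `object_order` is given. A
#' negative slope means PSEs fall off with decreasing stability, tracking
#' the physics. Because the slope's magnitude depends on the contrast
#' coding, slopes are comparable by sign and ordering, not absolute size.
#'
#' @param pse_tab tibble with `responder_id`, `object_id`, `pse`.
#' @param truth ground-truth table used to order objects (ignored when
#'   `object_order` is supplied).
#' @param object_order optional explicit object ordering (character).
#' @return One-row tibble: `b` (contrast slope), `p`, `effect_size`
#'   (partial eta squared of the contrast), `n_objects`, `n_rows`.
#' @export
linear_trend <- function(pse_tab, truth = NULL, object_order = NULL) {
  if (is.null(object_order)) {
    if (is.null(truth)) stop("supply truth or object_order", call. = FALSE)
    ord <- truth[order(-truth$critical_angle), ]
    object_order <- ord$object_id[ord$object_id %in% pse_tab$object_id]
  }
  k <- length(object_order)
  if (k < 3L) stop("trend undefined: need >= 3 ordered objects", call. = FALSE)
  tab <- pse_tab[pse_tab$object_id %in% object_order & !is.na(pse_tab$pse), ]
  contrast <- stats::contr.poly(k)[, 1]
  z <- contrast[match(tab$object_id, object_order)]
  fit <- stats::lm(tab$pse ~ z)
  sm <- summary(fit)
  ss_fit <- sum((stats::fitted(fit) - mean(tab$pse))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  tibble::tibble(
    b = unname(stats::coef(fit)[2]),
    p = sm$coefficients[2, 4],
    effect_size = ss_fit / (ss_fit + ss_res),
    n_objects = k, n_rows = nrow(tab)
  )
}

#' Regress human response proportions on model response proportions
#'
#' Multiple regression of human per-(object, angle) green proportions on
#' one or more models' proportions, with a BIC-approximate Bayes factor per
#' predictor comparing the full model against the model with that predictor
#' dropped: `BF10 = exp((BIC_reduced - BIC_full) / 2)`.
#'
#' @param human tibble with `object_id`, `angle_deg`, `prop_green`.
#' @param models named list of model per-angle tibbles (same columns, e.g.
#'   `per_angle` from a `model_run`).
#' @return List with `coefficients` (tibble: term, b, p, bf10, bf01),
#'   `r_squared`, `n`, `rank_deficient`.
#' @export
human_model_regression <- function(human, models) {
  stopifnot(is.list(models), length(models) >= 1L, !is.null(names(models)))
  dat <- human[, c("object_id", "angle_deg", "prop_green")]
  names(dat)[3] <- "human"
  for (nm in names(models)) {
    m <- models[[nm]][, c("object_id", "angle_deg", "prop_green")]
    names(m)[3] <- nm
    dat <- dplyr::inner_join(dat, m, by = c("object_id", "angle_deg"))
  }
  preds <- names(models)
  if (nrow(dat) < length(preds) + 2L) {
    stop("need at least p + 2 aligned observations", call. = FALSE)
  }
  x <- as.matrix(dat[, preds, drop = FALSE])
  y <- dat$human
  xd <- cbind(`(Intercept)` = 1, x)
  rank_deficient <- qr(xd)$rank < ncol(xd)
  if (rank_deficient) {
    warning("rank-deficient predictors; using pseudoinverse coefficients",
            call. = FALSE)
    beta <- drop(MASS::ginv(xd) %*% y)
    names(beta) <- colnames(xd)
    fitted <- drop(xd %*% beta)
    r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
    coefs <- tibble::tibble(term = preds, b = beta[preds], p = NA_real_,
                            bf10 = NA_real_, bf01 = NA_real_)
    return(list(coefficients = coefs, r_squared = r2, n = nrow(dat),
                rank_deficient = TRUE))
  }
  full <- stats::lm(y ~ x)
  sm <- summary(full)
  bic_full <- stats::BIC(full)
  rows <- lapply(seq_along(preds), function(j) {
    red <- if (length(preds) == 1L) {
      stats::lm(y ~ 1)
    } else {
      stats::lm(y ~ x[, -j, drop = FALSE])
    }
    bf10 <- exp((stats::BIC(red) - bic_full) / 2)
    tibble::tibble(term = preds[j], b = unname(stats::coef(full)[j + 1L]),
                   p = sm$coefficients[j + 1L, 4], bf10 = bf10,
                   bf01 = 1 / bf10)
  })
  list(coefficients = dplyr::bind_rows(rows), r_squared = sm$r.squared,
       n = nrow(dat), rank_deficient = FALSE)
}

# Commonality components from all-subset R^2 values, via the Moebius-style
# alternating sum over subsets: with f(T) = R2(full) - R2(full \ T),
# component(S) = sum_{T subseteq S} (-1)^{|S| - |T|} f(T).
commonality_components <- function(y, xs) {
  p <- length(xs)
  subsets <- lapply(seq_len(2^p - 1), function(m) which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0))
  r2_of <- function(idx) {
    if (length(idx) == 0) return(0)
    r_squared(y, do.call(cbind, xs[idx]))
  }
  r2_full <- r2_of(seq_len(p))
  f <- function(T) r2_full - r2_of(setdiff(seq_len(p), T))
  comp <- vapply(subsets, function(S) {
    subT <- c(list(integer(0)), lapply(subsets, function(T) T)[
      vapply(subsets, function(T) all(T %in% S), logical(1))])
    sum(vapply(subT, function(T) (-1)^(length(S) - length(T)) * f(T), numeric(1)))
  }, numeric(1))
  names(comp) <- vapply(subsets, function(S) paste(names(xs)[S], collapse = ":"),
                        character(1))
  list(components = comp, r2_full = r2_full)
}

#' Variance partitioning (commonality analysis) for 2-3 predictors
#'
#' Decomposes the full-model R-squared into the variance unique to each
#' predictor and shared among every predictor subset, from the R-squared
#' values of all subset regressions. The components always sum exactly to
#' the full R-squared; negative shared components (suppression) are
#' reported, flagged, not clipped.
#'
#' @param y response vector.
#' @param predictors named list of 2 or 3 numeric predictor vectors.
#' @return A `partition_result`: list with `components` (tibble:
#'   `component` name such as `"centroid"` or `"centroid:height"`, `value`,
#'   `pct_of_explainable`), `r2_full`, `suppression` flag.
#' @export
variance_partitioning <- function(y, predictors) {
  stopifnot(is.list(predictors), !is.null(names(predictors)))
  p <- length(predictors)
  if (p < 2L || p > 3L) stop("supply 2 or 3 predictors", call. = FALSE)
  lens <- lengths(predictors)
  if (any(lens != length(y))) stop("predictors must align with y", call. = FALSE)
  if (any(vapply(predictors, stats::sd, numeric(1)) < 1e-12)) {
    stop("constant predictor", call. = FALSE)
  }
  cc <- commonality_components(y, predictors)
  structure(
    list(
      components = tibble::tibble(
        component = names(cc$components),
        value = unname(cc$components),
        pct_of_explainable = 100 * unname(cc$components) / cc$r2_full
      ),
      r2_full = cc$r2_full,
      suppression = any(cc$components < 0)
    ),
    class = "partition_result"
  )
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> R2_full = %.4f%s\n", x$r2_full,
              if (x$suppression) " (suppression present)" else ""))
  print(x$components)
  invisible(x)
}

#' Permutation test for a difference in unique variance
#'
#' Tests whether predictor `x1` explains a different amount of unique
#' variance in `y` than `x2`. The observed statistic is
#' `unique(x1) - unique(x2)`; the null distribution swaps the pair
#' `(x1_i, x2_i)` independently within each observation with probability
#' one half per permutation, which enforces exchangeability of the two
#' predictors while preserving each observation's values. Two-sided p-value
#' with the add-one correction.
#'
#' @param y response vector.
#' @param x1,x2 predictor vectors.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return Tibble: `observed` (unique-variance difference), `p`, `n_perm`,
#'   plus a `scheme` column recording the permutation scheme.
#' @export
unique_variance_permutation <- function(y, x1, x2, n_perm = 1000L, seed = 1L) {
  stopifnot(length(x1) == length(y), length(x2) == length(y))
  n <- length(y)
  stat <- function(a, b) {
    r2_full <- r_squared(y, cbind(a, b))
    (r2_full - r_squared(y, b)) - (r2_full - r_squared(y, a))
  }
  obs <- stat(x1, x2)
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sw <- stats::runif(n) < 0.5
      a <- ifelse(sw, x2, x1)
      b <- ifelse(sw, x1, x2)
      stat(a, b)
    }, numeric(1))
  })
  p <- (1 + sum(abs(perms) >= abs(obs))) / (n_perm + 1)
  tibble::tibble(observed = obs, p = p, n_perm = n_perm,
                 scheme = "rowwise pair swap, prob 1/2")
}

#' Weighted correlations between embedding principal components and
#' geometric features
#'
#' Reduces a scene-by-dimension embedding matrix by PCA, retaining the
#' leading components up to `variance_threshold` of the variance. For each
#' bootstrap resample of scenes, each retained component's scores are
#' correlated with each geometric feature across scenes; absolute
#' correlations are used (component signs are arbitrary) and averaged with
#' weights equal to each component's explained-variance share. Reports the
#' mean weighted coefficient, percentile CI, and a one-sample t-test of the
#' bootstrap replicates against zero.
#'
#' @param embedding numeric matrix, scenes x dimensions.
#' @param features data frame of per-scene feature values (same row order).
#' @param variance_threshold cumulative variance the retained components
#'   must reach.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return List with `coefficients` (tibble: `feature`, `estimate`,
#'   `ci_low`, `ci_high`, `t`, `p`), `n_components`, `weights`.
#' @export
weighted_pca_correlation <- function(embedding, features,
                                     variance_threshold = 0.90,
                                     n_boot = 1000L, seed = 1L) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) < 2L) stop("need >= 2 scenes", call. = FALSE)
  keep <- apply(embedding, 2, stats::sd) > 1e-12
  if (!any(keep)) stop("embedding is constant", call. = FALSE)
  pc <- stats::prcomp(embedding[, keep, drop = FALSE], center = TRUE)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  m <- which(cumsum(share) >= variance_threshold)[1]
  if (is.na(m) || m < 1L) stop("threshold error: no components retained", call. = FALSE)
  scores <- pc$x[, seq_len(m), drop = FALSE]
  w <- share[seq_len(m)] / sum(share[seq_len(m)])
  fm <- as.matrix(features)
  n <- nrow(scores)
  boot <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      r <- suppressWarnings(abs(stats::cor(scores[idx, , drop = FALSE],
                                           fm[idx, , drop = FALSE])))
      drop(crossprod(r, w))  # weighted mean |r| per feature
    })
  })
  boot <- do.call(rbind, boot)
  colnames(boot) <- colnames(fm)
  rows <- lapply(colnames(fm), function(f) {
    v <- boot[, f]; v <- v[!is.na(v)]
    ci <- unname(stats::quantile(v, c(0.025, 0.975)))
    if (stats::sd(v) < 1e-12) {
      # degenerate bootstrap distribution (e.g. |r| identically 1)
      tstat <- if (abs(mean(v)) < 1e-12) 0 else Inf
      pval <- if (abs(mean(v)) < 1e-12) 1 else 0
    } else {
      tt <- stats::t.test(v, mu = 0)
      tstat <- unname(tt$statistic)
      pval <- tt$p.value
    }
    tibble::tibble(feature = f, estimate = mean(v), ci_low = ci[1],
                   ci_high = ci[2], t = tstat, p = pval)
  })
  list(coefficients = dplyr::bind_rows(rows), n_components = m,
       weights = w)
}
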