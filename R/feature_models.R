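# Linear max-margin classifier (L2-regularised squared-hinge loss):
#   min_{w,b}  0.5 ||w||^2 + C * sum_i max(0, 1 - y_i (x_i w + b))^2
# Squared hinge keeps the objective differentiable so BFGS converges fast on
# the small (tens to low hundreds of rows, few features) problems here.
# Feature scaling is the caller's job.
fit_linear_svm <- function(x, y01, C = 1) {
  x <- as.matrix(x)
  y <- ifelse(y01 > 0, 1, -1)
  if (length(unique(y)) < 2L) {
    stop("untrainable: training data contain a single class", call. = FALSE)
  }
  d <- ncol(x)
  obj <- function(par) {
    w <- par[1:d]; b <- par[d + 1L]
    m <- 1 - y * (drop(x %*% w) + b)
    0.5 * sum(w^2) + C * sum(pmax(m, 0)^2)
  }
  grad <- function(par) {
    w <- par[1:d]; b <- par[d + 1L]
    m <- 1 - y * (drop(x %*% w) + b)
    act <- pmax(m, 0)
    gy <- -2 * C * act * y
    c(w + drop(crossprod(x, gy)), sum(gy))
  }
  opt <- stats::optim(numeric(d + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  list(w = opt$par[1:d], b = opt$par[d + 1L])
}

predict_linear_svm <- function(model, x) {
  as.integer(drop(as.matrix(x) %*% model$w) + model$b > 0)
}

feature_names <- c("base", "centroid", "height", "tb_ratio")

#' Build the classifier training table
#'
#' One row per (catalog object, angle) over the union of the designs' angle
#' grids. Predictors are the requested geometric features plus the tilt
#' angle; the outcome is the ground-truth fall label (1 = green, off the
#' table).
#'
#' @param catalog catalog tibble.
#' @param designs list of [experiment_design()]s whose angle grids are
#'   pooled.
#' @param feature_set non-empty subset of
#'   `c("base", "centroid", "height", "tb_ratio")`.
#' @inheritParams centroid_height
#' @return Tibble with `object_id`, the feature columns, `angle_deg`,
#'   `label`.
#' @export
build_training_table <- function(catalog, designs, feature_set,
                                 include_base_cap = FALSE) {
  if (length(feature_set) == 0) {
    stop("configuration error: feature_set must be non-empty", call. = FALSE)
  }
  if (!all(feature_set %in% feature_names)) {
    stop("unknown features: ",
         paste(setdiff(feature_set, feature_names), collapse = ", "),
         call. = FALSE)
  }
  if (inherits(designs, "experiment_design")) designs <- list(designs)
  catalog <- validate_catalog(catalog, require_unique = TRUE)
  angles <- sort(unique(unlist(lapply(designs, `[[`, "angles"))))
  feats <- object_features(catalog, include_base_cap = include_base_cap)
  tab <- tidyr::expand_grid(object_id = catalog$object_id, angle_deg = angles)
  tab <- dplyr::left_join(tab, feats[, c("object_id", feature_set)],
                          by = "object_id")
  idx <- match(tab$object_id, catalog$object_id)
  tab$label <- as.integer(
    fall_label(catalog[idx, ], tab$angle_deg,
               include_base_cap = include_base_cap) == "green")
  tab[, c("object_id", feature_set, "angle_deg", "label")]
}

# Columns used as predictors: everything except object_id and label.
predictor_cols <- function(table) setdiff(names(table), c("object_id", "label"))

#' Leave-one-object-out resampled predictions
#'
#' Withholds one object, then for each of `n_resamples` iterations draws a
#' class-stratified bootstrap of the remaining training rows (preserving the
#' fall-label proportions), z-scores predictors by the resampled training
#' statistics, fits the linear max-margin classifier with regularisation
#' `C`, and predicts the held-out object's rows at every angle.
#'
#' @param table output of [build_training_table()] (or the embedding
#'   analogue).
#' @param left_out_object object id to withhold.
#' @param C regularisation strength (> 0).
#' @param n_resamples number of stratified bootstrap resamples.
#' @param seed integer seed.
#' @return Binary matrix `n_resamples x n_angles` (1 = green), with angle
#'   column names.
#' @export
loo_predict <- function(table, left_out_object, C = 1, n_resamples = 1000L,
                        seed = 1L) {
  if (!left_out_object %in% table$object_id) {
    stop("left-out object not present in the training table", call. = FALSE)
  }
  train <- table[table$object_id != left_out_object, ]
  # canonical row order: resampling draws must not depend on catalog order
  train <- train[order(train$object_id), ]
  test <- table[table$object_id == left_out_object, ]
  has_angle <- "angle_deg" %in% names(table)
  if (has_angle) {
    train <- train[order(train$object_id, train$angle_deg), ]
    test <- test[order(test$angle_deg), ]
  }
  if (length(unique(train$object_id)) < 2L) {
    stop("need >= 2 training objects", call. = FALSE)
  }
  if (length(unique(train$label)) < 2L) {
    stop("untrainable: training data contain a single class", call. = FALSE)
  }
  cols <- predictor_cols(table)
  xtr_all <- as.matrix(train[, cols])
  xte <- as.matrix(test[, cols])
  idx_pos <- which(train$label == 1L)
  idx_neg <- which(train$label == 0L)
  y <- train$label
  preds <- withr::with_seed(seed, {
    t(vapply(seq_len(n_resamples), function(i) {
      take <- c(sample(idx_pos, length(idx_pos), replace = TRUE),
                sample(idx_neg, length(idx_neg), replace = TRUE))
      xtr <- xtr_all[take, , drop = FALSE]
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, stats::sd)
      sdv[sdv < 1e-12] <- 1
      xs <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      model <- fit_linear_svm(xs, y[take], C = C)
      xts <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
      predict_linear_svm(model, xts)
    }, integer(nrow(test))))
  })
  colnames(preds) <- if (has_angle) {
    format(test$angle_deg, trim = TRUE)
  } else {
    as.character(seq_len(nrow(test)))
  }
  preds
}

#' Aggregate resampled predictions into a response curve
#'
#' @param prediction_matrix output of [loo_predict()].
#' @return Tibble with `angle_deg` and `prop_green` (per-angle mean over
#'   resamples).
#' @export
model_response_curve <- function(prediction_matrix) {
  if (length(prediction_matrix) == 0) stop("empty prediction matrix", call. = FALSE)
  tibble::tibble(
    angle_deg = as.numeric(colnames(prediction_matrix)),
    prop_green = unname(colMeans(prediction_matrix))
  )
}

#' Run a geometric-feature classifier model end to end
#'
#' Iterates every catalog object as the held-out test object, aggregates the
#' resampled binary predictions into per-angle green proportions, and fits a
#' psychometric function to each object's curve exactly as for behavioural
#' data, yielding one PSE per object.
#'
#' @inheritParams build_training_table
#' @inheritParams loo_predict
#' @param n_boot bootstrap draws for model PSE CIs (re-aggregating resampled
#'   prediction rows); 0 skips.
#' @return A `model_run`: list with `feature_set`, `C`, `n_resamples`,
#'   `seed`, `per_angle` (object x angle proportions), `per_object_pse`,
#'   and `predictions` (per-object resample matrices).
#' @export
model_pse_pipeline <- function(catalog, designs, feature_set, C = 1,
                               n_resamples = 1000L, seed = 1L, n_boot = 0L,
                               include_base_cap = FALSE) {
  table <- build_training_table(catalog, designs, feature_set,
                                include_base_cap = include_base_cap)
  run_loo_pipeline(table, feature_label = paste(feature_set, collapse = "+"),
                   C = C, n_resamples = n_resamples, seed = seed,
                   n_boot = n_boot)
}

# Per-object resampling seeds keyed by sorted object id, so results do not
# depend on catalog row order.
object_seeds <- function(seed, objects) {
  srt <- sort(unique(objects))
  drawn <- withr::with_seed(seed, sample.int(.Machine$integer.max %/% 2L,
                                             length(srt)))
  stats::setNames(drawn, srt)[objects]
}

# Shared LOO -> aggregate -> psychometric-fit chain for feature and
# embedding models.
run_loo_pipeline <- function(table, feature_label, C, n_resamples, seed,
                             n_boot = 0L) {
  objects <- unique(table$object_id)
  seeds <- object_seeds(seed, objects)
  predictions <- list()
  per_angle <- list()
  pse_rows <- list()
  for (i in seq_along(objects)) {
    obj <- objects[i]
    preds <- loo_predict(table, obj, C = C, n_resamples = n_resamples,
                         seed = seeds[i])
    curve <- model_response_curve(preds)
    cells <- tibble::tibble(angle_deg = curve$angle_deg,
                            n_green = round(curve$prop_green * n_resamples),
                            n_total = n_resamples)
    fit <- tryCatch(fit_psychometric(cells), error = function(e) NULL)
    row <- tibble::tibble(object_id = obj, pse = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          converged = "failed")
    if (!is.null(fit)) {
      row$pse <- fit$pse
      row$converged <- fit$converged
      if (n_boot > 0L) {
        bpse <- withr::with_seed(seeds[i] + 1L, {
          vapply(seq_len(n_boot), function(b) {
            take <- sample.int(nrow(preds), nrow(preds), replace = TRUE)
            k <- colSums(preds[take, , drop = FALSE])
            out <- tryCatch(
              fit_logistic_cells(curve$angle_deg, k, rep(nrow(preds), ncol(preds))),
              error = function(e) NULL)
            if (is.null(out)) NA_real_ else -out$coef[1] / out$coef[2]
          }, numeric(1))
        })
        bpse <- bpse[!is.na(bpse)]
        if (length(bpse) >= n_boot / 2) {
          ci <- unname(stats::quantile(bpse, c(0.025, 0.975)))
          row$ci_low <- ci[1]; row$ci_high <- ci[2]
        }
      }
    }
    predictions[[obj]] <- preds
    per_angle[[obj]] <- dplyr::mutate(curve, object_id = obj, .before = 1)
    pse_rows[[obj]] <- row
  }
  structure(
    list(feature_set = feature_label, C = C, n_resamples = n_resamples,
         seed = seed,
         per_angle = dplyr::bind_rows(per_angle),
         per_object_pse = dplyr::bind_rows(pse_rows),
         predictions = predictions),
    class = "model_run"
  )
}

#' @export
print.model_run <- function(x, ...) {
  cat(sprintf("<model_run> features: %s (C = %g, %d resamples)\n",
              x$feature_set, x$C, x$n_resamples))
  print(x$per_object_pse)
  invisible(x)
}

#' Run an image-embedding classifier model end to end
#'
#' Replaces the geometric features with an arbitrary scene-image embedding:
#' each (object, angle) scene over the pooled design grids (one side only)
#' is rendered with [scene_raster()], embedded with `extractor`, reduced by
#' PCA to the components explaining `variance_threshold` of the variance,
#' and the reduced features enter the same leave-one-object-out classifier
#' chain as the geometric models. The tilt angle is *not* appended: the
#' image itself carries it.
#'
#' @inheritParams model_pse_pipeline
#' @param extractor function mapping a `scene_image` to a fixed-length
#'   numeric vector.
#' @param variance_threshold proportion of embedding variance the retained
#'   principal components must explain; `NULL` skips the PCA and feeds the
#'   raw embedding to the classifier.
#' @param size canvas size in pixels for the rasteriser.
#' @param pca_scope `"global"` fits the PCA once on all scenes (the
#'   default); `"train"` refits it inside each leave-one-object-out fold on
#'   training scenes only.
#' @param side presentation side used for the scene set.
#' @return A `model_run`, as for [model_pse_pipeline()].
#' @export
embedding_pipeline <- function(catalog, designs, extractor, C = 1,
                               n_resamples = 1000L, seed = 1L,
                               variance_threshold = 0.9, size = 64L,
                               pca_scope = c("global", "train"),
                               side = "right", n_boot = 0L) {
  pca_scope <- match.arg(pca_scope)
  if (inherits(designs, "experiment_design")) designs <- list(designs)
  catalog <- validate_catalog(catalog, require_unique = TRUE)
  angles <- sort(unique(unlist(lapply(designs, `[[`, "angles"))))
  grid <- tidyr::expand_grid(object_id = catalog$object_id, angle_deg = angles)
  emb <- lapply(seq_len(nrow(grid)), function(i) {
    img <- scene_raster(catalog[catalog$object_id == grid$object_id[i], ],
                        grid$angle_deg[i], side = side, size = size)
    v <- extractor(img)
    if (!is.numeric(v)) stop("extractor must return a numeric vector", call. = FALSE)
    v
  })
  lens <- lengths(emb)
  if (length(unique(lens)) != 1L) {
    stop("interface error: extractor output length varies across images",
         call. = FALSE)
  }
  emb <- do.call(rbind, emb)
  feat <- if (is.null(variance_threshold)) {
    emb
  } else {
    reduce_by_pca(emb, variance_threshold)
  }
  if (all(apply(feat, 2, stats::sd) < 1e-12)) {
    stop("untrainable: embedding features are constant across scenes",
         call. = FALSE)
  }
  colnames(feat) <- paste0("e", seq_len(ncol(feat)))
  idx <- match(grid$object_id, catalog$object_id)
  table <- dplyr::bind_cols(
    tibble::tibble(object_id = grid$object_id),
    tibble::as_tibble(feat),
    tibble::tibble(
      angle_deg = grid$angle_deg,
      label = as.integer(fall_label(catalog[idx, ], grid$angle_deg) == "green")
    )
  )
  # the angle column is metadata here, not a predictor: drop it from the
  # table fed to the classifier but keep it for aggregation
  table_pred <- table
  if (pca_scope == "train" && !is.null(variance_threshold)) {
    return(run_loo_pipeline_foldpca(table, emb, variance_threshold, C,
                                    n_resamples, seed, n_boot))
  }
  run_loo_pipeline_embed(table_pred, C, n_resamples, seed, n_boot)
}

reduce_by_pca <- function(emb, variance_threshold) {
  keep <- apply(emb, 2, stats::sd) > 1e-12
  if (!any(keep)) {
    stop("untrainable: embedding features are constant across scenes",
         call. = FALSE)
  }
  pc <- stats::prcomp(emb[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  m <- which(cumsum(share) >= variance_threshold)[1]
  if (is.na(m) || m < 1L) stop("threshold error: no components retained", call. = FALSE)
  pc$x[, seq_len(m), drop = FALSE]
}

# Embedding tables carry angle_deg only for aggregation; exclude it from the
# predictors by reusing the generic chain on a table whose predictors are
# the embedding columns.
run_loo_pipeline_embed <- function(table, C, n_resamples, seed, n_boot) {
  ecols <- setdiff(names(table), c("object_id", "label", "angle_deg"))
  objects <- unique(table$object_id)
  seeds <- object_seeds(seed, objects)
  predictions <- list(); per_angle <- list(); pse_rows <- list()
  for (i in seq_along(objects)) {
    obj <- objects[i]
    sub <- table[, c("object_id", ecols, "label")]
    # stash angles so prediction columns are labelled by angle
    ang <- table$angle_deg[table$object_id == obj]
    preds <- loo_predict_embed(sub, ang, obj, C, n_resamples, seeds[i])
    curve <- model_response_curve(preds)
    cells <- tibble::tibble(angle_deg = curve$angle_deg,
                            n_green = round(curve$prop_green * n_resamples),
                            n_total = n_resamples)
    fit <- tryCatch(fit_psychometric(cells), error = function(e) NULL)
    row <- tibble::tibble(object_id = obj, pse = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          converged = "failed")
    if (!is.null(fit)) { row$pse <- fit$pse; row$converged <- fit$converged }
    predictions[[obj]] <- preds
    per_angle[[obj]] <- dplyr::mutate(curve, object_id = obj, .before = 1)
    pse_rows[[obj]] <- row
  }
  structure(
    list(feature_set = "embedding", C = C, n_resamples = n_resamples,
         seed = seed, per_angle = dplyr::bind_rows(per_angle),
         per_object_pse = dplyr::bind_rows(pse_rows),
         predictions = predictions),
    class = "model_run"
  )
}

loo_predict_embed <- function(table, test_angles, left_out_object, C,
                              n_resamples, seed) {
  preds <- loo_predict(table, left_out_object, C = C,
                       n_resamples = n_resamples, seed = seed)
  # loo_predict ordered test rows by angle_deg; embedding tables have no
  # angle predictor, so row order is the original (already angle-sorted)
  colnames(preds) <- format(sort(test_angles), trim = TRUE)
  preds
}

run_loo_pipeline_foldpca <- function(table, emb, variance_threshold, C,
                                     n_resamples, seed, n_boot) {
  objects <- unique(table$object_id)
  seeds <- object_seeds(seed, objects)
  predictions <- list(); per_angle <- list(); pse_rows <- list()
  for (i in seq_along(objects)) {
    obj <- objects[i]
    tr_idx <- table$object_id != obj
    keep <- apply(emb[tr_idx, , drop = FALSE], 2, stats::sd) > 1e-12
    pc <- stats::prcomp(emb[tr_idx, keep, drop = FALSE], center = TRUE)
    share <- pc$sdev^2 / sum(pc$sdev^2)
    m <- which(cumsum(share) >= variance_threshold)[1]
    scores_tr <- pc$x[, seq_len(m), drop = FALSE]
    scores_te <- scale(emb[!tr_idx, keep, drop = FALSE], pc$center,
                       FALSE) %*% pc$rotation[, seq_len(m), drop = FALSE]
    sub <- tibble::tibble(object_id = c(table$object_id[tr_idx],
                                        table$object_id[!tr_idx]))
    feat <- rbind(scores_tr, scores_te)
    colnames(feat) <- paste0("e", seq_len(m))
    sub <- dplyr::bind_cols(sub, tibble::as_tibble(feat))
    sub$label <- c(table$label[tr_idx], table$label[!tr_idx])
    ang <- table$angle_deg[!tr_idx]
    preds <- loo_predict_embed(sub, ang, obj, C, n_resamples, seeds[i])
    curve <- model_response_curve(preds)
    cells <- tibble::tibble(angle_deg = curve$angle_deg,
                            n_green = round(curve$prop_green * n_resamples),
                            n_total = n_resamples)
    fit <- tryCatch(fit_psychometric(cells), error = function(e) NULL)
    row <- tibble::tibble(object_id = obj, pse = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          converged = "failed")
    if (!is.null(fit)) { row$pse <- fit$pse; row$converged <- fit$converged }
    predictions[[obj]] <- preds
    per_angle[[obj]] <- dplyr::mutate(curve, object_id = obj, .before = 1)
    pse_rows[[obj]] <- row
  }
  structure(
    list(feature_set = "embedding(train-pca)", C = C,
         n_resamples = n_resamples, seed = seed,
         per_angle = dplyr::bind_rows(per_angle),
         per_object_pse = dplyr::bind_rows(pse_rows),
         predictions = predictions),
    class = "model_run"
  )
}
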