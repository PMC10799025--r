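#' Read and validate a trial table CSV
#'
#' Schema: `responder_id` (optional), `object_id`, `angle_deg`, `side`,
#' `rep`, `response` (0/1/NA), `label` (0/1/NA). Recorded behavioural data
#' exported in this schema drop into the fitting and statistics layers
#' unchanged.
#'
#' @param path CSV path.
#' @return Validated trial tibble.
#' @export
read_trials <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("object_id", "angle_deg", "side", "rep", "response", "label")
  problems <- character(0)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    problems <- c(problems, paste0("missing columns: ",
                                   paste(missing, collapse = ", ")))
  } else {
    if (!is.numeric(tab$angle_deg)) problems <- c(problems, "angle_deg: not numeric")
    if (!all(tab$side %in% c("left", "right"))) {
      problems <- c(problems, "side: values outside {left, right}")
    }
    if (!all(is.na(tab$response) | tab$response %in% c(0, 1))) {
      problems <- c(problems, "response: values outside {0, 1, NA}")
    }
    if (!all(is.na(tab$label) | tab$label %in% c(0, 1))) {
      problems <- c(problems, "label: values outside {0, 1, NA}")
    }
  }
  if (length(problems)) {
    stop("trial table validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  tab
}

#' @rdname read_trials
#' @param trials trial tibble to write.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' @param catalog catalog tibble, or path to a catalog CSV/YAML; `NULL`
#'   uses [stimulus_catalog()].
#' @param designs named list of designs, or path to a designs YAML; `NULL`
#'   uses [experiment_designs()].
#' @param cohorts named list of [observer_params()]; `NULL` uses
#'   [observer_cohorts()].
#' @param n_observers simulated observers per cohort and design.
#' @param feature_sets list of feature sets (character vectors) for the
#'   classifier models.
#' @param C regularisation strength.
#' @param n_resamples stratified bootstrap resamples per left-out object.
#' @param n_boot bootstrap resamples for PSE confidence intervals.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory.
#' @param run_embedding also run the toy pixel-embedding model.
#' @return A `run_config` list, validated (referenced files must exist).
#' @export
run_config <- function(catalog = NULL, designs = NULL, cohorts = NULL,
                       n_observers = 12L,
                       feature_sets = list("base", "centroid", "height",
                                           "tb_ratio"),
                       C = 1, n_resamples = 1000L, n_boot = 0L, seed = 1L,
                       out_dir = tempfile("tiltfall_run_"),
                       run_embedding = FALSE) {
  if (is.character(catalog)) {
    if (!file.exists(catalog)) {
      stop("pre-flight validation: catalog file does not exist: ", catalog,
           call. = FALSE)
    }
    catalog <- read_catalog(catalog)
  }
  if (is.character(designs)) {
    if (!file.exists(designs)) {
      stop("pre-flight validation: designs file does not exist: ", designs,
           call. = FALSE)
    }
    designs <- read_designs(designs)
  }
  if (is.null(catalog)) catalog <- stimulus_catalog()
  if (is.null(designs)) designs <- experiment_designs(catalog)
  if (is.null(cohorts)) cohorts <- observer_cohorts()
  catalog <- validate_catalog(catalog, require_unique = TRUE)
  for (d in designs) {
    if (!all(d$objects %in% catalog$object_id)) {
      stop("pre-flight validation: design '", d$name,
           "' references objects missing from the catalog", call. = FALSE)
    }
  }
  structure(
    list(catalog = catalog, designs = designs, cohorts = cohorts,
         n_observers = as.integer(n_observers), feature_sets = feature_sets,
         C = C, n_resamples = as.integer(n_resamples),
         n_boot = as.integer(n_boot), seed = as.integer(seed),
         out_dir = out_dir, run_embedding = isTRUE(run_embedding)),
    class = "run_config"
  )
}

stage_log <- function(stage, t0) {
  message(sprintf("[tiltfall] %-10s %6.1fs", stage,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (observer cohorts per design) -> fit (per-responder
#' psychometric PSEs) -> models (leave-one-object-out classifier runs per
#' feature set, optionally a pixel-embedding run) -> stats (PSE-vs-truth
#' tests, linear trends, human-model regression, variance partitioning,
#' permutation test). Every intermediate table is written as CSV under
#' `config$out_dir`, and a JSON manifest records the configuration, derived
#' stage seeds and MD5 hashes of every output. Re-running the same
#' configuration reproduces every CSV bit-identically.
#'
#' @param config a [run_config()].
#' @return The manifest (invisibly), with the output directory in
#'   `$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[3]
  catalog <- config$catalog
  designs <- config$designs
  truth <- ground_truth(catalog)
  write_catalog(catalog, file.path(config$out_dir, "catalog.csv"))
  readr::write_csv(truth, file.path(config$out_dir, "ground_truth.csv"))

  # stage: simulate ---------------------------------------------------------
  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max %/% 2L, 64L))
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }
  trials <- list()
  for (cohort in names(config$cohorts)) {
    for (dn in names(designs)) {
      trials[[paste(cohort, dn, sep = ".")]] <- simulate_cohort(
        designs[[dn]], catalog, config$cohorts[[cohort]],
        n_observers = config$n_observers, seed = next_seed(),
        cohort_name = paste(cohort, dn, sep = "_")
      )
    }
  }
  all_trials <- dplyr::bind_rows(trials, .id = "cohort_design")
  all_trials <- tidyr::separate(all_trials, "cohort_design",
                                c("cohort", "design"), sep = "\\.")
  write_trials(all_trials, file.path(config$out_dir, "trials.csv"))
  stage_log("simulate", t0)

  # stage: fit ---------------------------------------------------------------
  pse_tab <- pse_table(all_trials, n_boot = config$n_boot, seed = next_seed())
  cohort_of <- all_trials[!duplicated(all_trials$responder_id),
                          c("responder_id", "cohort")]
  pse_tab <- dplyr::left_join(pse_tab, cohort_of, by = "responder_id")
  readr::write_csv(pse_tab, file.path(config$out_dir, "pse_humanlike.csv"))
  stage_log("fit", t0)

  # stage: models ------------------------------------------------------------
  runs <- list()
  for (fs in config$feature_sets) {
    nm <- paste(fs, collapse = "+")
    runs[[nm]] <- model_pse_pipeline(catalog, designs, fs, C = config$C,
                                     n_resamples = config$n_resamples,
                                     seed = next_seed(),
                                     n_boot = config$n_boot)
    readr::write_csv(runs[[nm]]$per_angle,
                     file.path(config$out_dir, paste0("model_", nm, "_curve.csv")))
    readr::write_csv(runs[[nm]]$per_object_pse,
                     file.path(config$out_dir, paste0("model_", nm, "_pse.csv")))
  }
  if (config$run_embedding) {
    runs$embedding <- embedding_pipeline(catalog, designs, pixel_embedding,
                                         C = config$C,
                                         n_resamples = config$n_resamples,
                                         seed = next_seed())
    readr::write_csv(runs$embedding$per_angle,
                     file.path(config$out_dir, "model_embedding_curve.csv"))
    readr::write_csv(runs$embedding$per_object_pse,
                     file.path(config$out_dir, "model_embedding_pse.csv"))
  } else {
    next_seed()  # keep downstream seeds stable either way
  }
  stage_log("models", t0)

  # stage: stats -------------------------------------------------------------
  stats_rows <- list()
  for (cohort in names(config$cohorts)) {
    sub <- pse_tab[pse_tab$cohort == cohort & !is.na(pse_tab$pse), ]
    stats_rows[[paste0("truth_", cohort)]] <- dplyr::mutate(
      pse_truth_difference(sub, truth), analysis = "pse_vs_truth",
      who = cohort, .before = 1)
  }
  model_pse <- lapply(runs, function(r) {
    dplyr::mutate(r$per_object_pse, responder_id = "model")
  })
  for (nm in names(model_pse)) {
    readr::write_csv(
      dplyr::mutate(model_pse[[nm]], model = nm),
      file.path(config$out_dir, paste0("model_", nm, "_pse_tidy.csv")))
  }
  truth_diffs <- dplyr::bind_rows(stats_rows)
  readr::write_csv(truth_diffs, file.path(config$out_dir, "stats_truth.csv"))

  # trends over the condition-1A objects (the stability-ordered set)
  ids_1a <- designs[[1]]$objects
  trend_rows <- list()
  for (cohort in names(config$cohorts)) {
    sub <- pse_tab[pse_tab$cohort == cohort &
                     pse_tab$object_id %in% ids_1a & !is.na(pse_tab$pse), ]
    if (length(unique(sub$object_id)) >= 3L) {
      trend_rows[[cohort]] <- dplyr::mutate(
        linear_trend(sub, truth), who = cohort, .before = 1)
    }
  }
  for (nm in names(runs)) {
    sub <- runs[[nm]]$per_object_pse
    sub <- sub[sub$object_id %in% ids_1a & !is.na(sub$pse), ]
    sub$responder_id <- nm
    if (length(unique(sub$object_id)) >= 3L) {
      trend_rows[[nm]] <- dplyr::mutate(
        linear_trend(sub, truth), who = nm, .before = 1)
    }
  }
  trends <- dplyr::bind_rows(trend_rows)
  readr::write_csv(trends, file.path(config$out_dir, "stats_trends.csv"))

  # human-model regression + variance partitioning on centroid & height
  human_curves <- human_response_curves(all_trials)
  reg <- vpa <- perm <- NULL
  single_models <- runs[vapply(runs, function(r)
    r$feature_set %in% feature_names, logical(1))]
  if (all(c("centroid", "height") %in% names(single_models))) {
    curves <- lapply(single_models, `[[`, "per_angle")
    reg <- human_model_regression(human_curves, curves)
    readr::write_csv(reg$coefficients,
                     file.path(config$out_dir, "stats_regression.csv"))
    joined <- human_curves
    names(joined)[names(joined) == "prop_green"] <- "human"
    for (nm in c("centroid", "height")) {
      m <- curves[[nm]][, c("object_id", "angle_deg", "prop_green")]
      names(m)[3] <- nm
      joined <- dplyr::inner_join(joined, m, by = c("object_id", "angle_deg"))
    }
    vpa <- variance_partitioning(joined$human,
                                 list(centroid = joined$centroid,
                                      height = joined$height))
    readr::write_csv(vpa$components,
                     file.path(config$out_dir, "stats_vpa.csv"))
    perm <- unique_variance_permutation(joined$human, joined$centroid,
                                        joined$height, n_perm = 1000L,
                                        seed = next_seed())
    readr::write_csv(perm, file.path(config$out_dir, "stats_permutation.csv"))
  }
  stage_log("stats", t0)

  outputs <- list.files(config$out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tiltfall")),
    seed = config$seed,
    stage_seeds = seeds[seq_len(si)],
    n_observers = config$n_observers,
    feature_sets = config$feature_sets,
    C = config$C, n_resamples = config$n_resamples, n_boot = config$n_boot,
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs)),
    out_dir = config$out_dir
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Per-(object, angle) human response proportions
#'
#' Proportion of green responses per object and angle, pooled over
#' responders, sides and repetitions: the response-curve format shared by
#' humans and models.
#'
#' @param trials trial tibble with responses.
#' @return Tibble with `object_id`, `angle_deg`, `prop_green`, `n`.
#' @export
human_response_curves <- function(trials) {
  tr <- trials[!is.na(trials$response), ]
  out <- dplyr::summarise(
    dplyr::group_by(tr, .data$object_id, .data$angle_deg),
    prop_green = mean(.data$response), n = dplyr::n(), .groups = "drop")
  out
}
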