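# Study-level orchestration: one seeded configuration drives the synthetic
# study end to end (simulate -> match -> ROC per quality group -> null ->
# observer models) and produces a single report.

#' Study configuration
#'
#' All parameters of a full synthetic study. The configuration holds plain
#' values only, so it serializes losslessly to YAML
#' ([write_study_config()] / [read_study_config()]); a serialized copy is
#' written alongside every study output.
#'
#' @param seed Single study seed; every random stage derives child seeds
#'   from it.
#' @param n_individuals Number of bears.
#' @param occasions Occasions per individual (recycled); `NULL` = three
#'   each, one for the last individual (43 sets at the default 15 bears;
#'   set it to `rep(3, 14)` for a 42-set pool).
#' @param n_trials,n_sets_per_trial,distinct_range Trial design: trials,
#'   sets per trial, and the admissible range of distinct individuals per
#'   trial.
#' @param quality_probs Set-quality proportions (`high`, `low`,
#'   `unsuitable`).
#' @param spot,render Parameter lists for [spot_config()] /
#'   [render_config()] (plain lists; constructed at run time).
#' @param grid_width,grid_height,crop_window,target_landmarks Standard-grid
#'   parameters (`target_landmarks` a list of three `(x, y)` pairs).
#' @param binarize_method,binarize_window,binarize_offset,min_component_size
#'   Pipeline parameters.
#' @param n_null Permutation-null replicates per trial.
#' @param n_bootstrap_roc ROC band replicates.
#' @param n_bootstrap_model Parametric-bootstrap replicates for the
#'   repeatability SE and group-rate uncertainty.
#' @param out_dir Optional output directory (photos, tables, JSON report).
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1, n_individuals = 15, occasions = NULL,
                         n_trials = 5, n_sets_per_trial = 15,
                         distinct_range = c(10, 11),
                         quality_probs = c(high = 0.253, low = 0.414,
                                           unsuitable = 0.333),
                         spot = list(), render = list(),
                         grid_width = 256, grid_height = 256,
                         crop_window = c(48, 112, 207, 211),
                         target_landmarks = list(
                           eye = c(176, 64), nose_notch = c(80, 120),
                           mouth_trailing_edge = c(144, 208)),
                         binarize_method = "adaptive", binarize_window = 15,
                         binarize_offset = 25, min_component_size = 2,
                         n_null = 1000, n_bootstrap_roc = 1000,
                         n_bootstrap_model = 1000, out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_individuals >= 2, cfg$n_trials >= 1, cfg$n_null >= 1,
            cfg$n_bootstrap_roc >= 1, cfg$n_bootstrap_model >= 0)
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "<study_config> seed %d: %d bears, %d trials x %d sets, grid %dx%d\n",
    x$seed, x$n_individuals, x$n_trials, x$n_sets_per_trial,
    x$grid_width, x$grid_height))
  invisible(x)
}

#' Write / read a study configuration as YAML
#'
#' @param config A [study_config()].
#' @param path `.yaml` path.
#' @return `read_study_config()` returns the reconstructed
#'   `study_config`; the writer returns `path` invisibly.
#' @export
write_study_config <- function(config, path) {
  raw <- unclass(config)
  # yaml drops names on atomic vectors; store named vectors as maps
  raw$quality_probs <- as.list(config$quality_probs)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  raw$quality_probs <- unlist(raw$quality_probs)
  raw$crop_window <- unlist(raw$crop_window)
  raw$distinct_range <- unlist(raw$distinct_range)
  raw$target_landmarks <- lapply(raw$target_landmarks, unlist)
  do.call(study_config, raw)
}

config_grid <- function(config) {
  standard_grid(config$grid_width, config$grid_height,
                do.call(landmarks, lapply(config$target_landmarks,
                                          as.numeric)),
                config$crop_window)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("study stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run a full synthetic identification study
#'
#' Executes, from one seed: individual and photo-set simulation, trial
#' composition, photo rendering and processing, pairwise Chamfer
#' dissimilarities with per-quality-group ROC threshold optimization and
#' bootstrap bands, the permutation null, simulated observer ratings with
#' confusion statistics, rating repeatability and the experience GLMM.
#' Deterministic: the same configuration yields an identical report. Each
#' stage logs its input/output sizes so exclusions are auditable.
#'
#' @param config A [study_config()].
#' @return A list of class `study_report` holding every computed
#'   statistic. When `config$out_dir` is set, photos, tables, the YAML
#'   config copy and a JSON report are written there.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  grid <- config_grid(config)
  spot_cfg <- do.call(spot_config, config$spot)
  render_cfg <- do.call(render_config, config$render)

  individuals <- stage("simulate", {
    sim_individuals(config$n_individuals, seed, spot_cfg, grid)
  })
  occasions <- config$occasions
  if (is.null(occasions)) {
    occasions <- c(rep(3, config$n_individuals - 1), 1)
  }
  sets <- stage("simulate", sim_photo_sets(individuals, seed, occasions))
  trials <- stage("simulate", {
    sim_trials(sets, config$n_trials, seed, config$n_sets_per_trial,
               config$distinct_range)
  })
  message(sprintf("simulate: %d bears, %d sets, %d trials",
                  nrow(individuals), nrow(sets), config$n_trials))

  photos <- stage("render", {
    render_study_photos(sets, individuals, seed, config$quality_probs,
                        render_cfg, grid)
  })
  bins <- stage("match", {
    process_photos(photos, grid, method = config$binarize_method,
                   window = config$binarize_window,
                   offset = config$binarize_offset,
                   min_component_size = config$min_component_size)
  })
  diss <- stage("match", pairwise_dissimilarity(bins))
  message(sprintf(
    "match: %d photos -> %d set pairs (%d incomparable, %d sets excluded)",
    nrow(photos), nrow(diss), sum(diss$status == "incomparable"),
    length(attr(diss, "excluded_sets"))))

  trial_slots <- left_join(trials,
                           distinct(photos, .data$set_id, .data$quality),
                           by = "set_id")
  quality_summary <- summarise_quality(trial_slots)

  roc <- stage("roc", {
    lapply(setNames(c("high", "low"), c("high", "low")), function(g) {
      sub <- filter(diss, .data$quality_group == g, .data$status == "ok")
      if (sum(sub$truth == "same") < 2 ||
          sum(sub$truth == "different") < 2) return(NULL)
      curve <- roc_curve(sub, quality_group = g)
      band <- roc_band(sub, n_replicates = config$n_bootstrap_roc,
                       seed = child_seed(seed, "roc", g))
      n_ind <- length(unique(c(sub$individual_a, sub$individual_b)))
      list(curve = curve, band = band, n_individuals = n_ind)
    })
  })

  null <- stage("null", simulate_null(trials, config$n_null, seed))

  observers <- sim_observers()
  comparisons <- stage("observers", build_comparison_table(trials))
  ratings <- stage("observers", sim_ratings(comparisons, observers, seed))
  outcomes <- stage("observers", classify_outcomes(comparisons, ratings))
  message(sprintf("observers: %d comparisons x %d observers = %d cells",
                  nrow(comparisons), nrow(observers), nrow(outcomes)))
  overall_rates <- confusion_rates(outcomes)
  by_observer <- outcomes |>
    group_by(.data$observer_id) |>
    dplyr::group_modify(~ confusion_rates(.x)) |>
    ungroup()
  unanimity <- unanimity_proportion(ratings)
  null_positions <- compare_to_null(
    by_observer[, c("observer_id", "fpr", "fnr")], null)

  records <- build_rating_records(outcomes, observers)
  repeatability <- stage("observers", {
    fit_rating_repeatability(records, config$n_bootstrap_model,
                             child_seed(seed, "rpt"))
  })
  experience <- stage("observers", fit_experience_model(records))
  group_rates <- group_rate_table(experience)

  report <- structure(list(
    config = unclass(config),
    design = list(
      n_individuals = nrow(individuals), n_sets = nrow(sets),
      n_trials = config$n_trials,
      distinct_individuals_per_trial = trials |>
        group_by(.data$trial_id) |>
        summarise(k = length(unique(.data$individual_id)),
                  .groups = "drop"),
      n_comparisons = nrow(comparisons)),
    quality_summary = quality_summary,
    dissimilarity = list(
      n_pairs = nrow(diss),
      n_incomparable = sum(diss$status == "incomparable"),
      excluded_sets = attr(diss, "excluded_sets"),
      by_group = diss |>
        filter(.data$status == "ok") |>
        group_by(.data$quality_group, .data$truth) |>
        summarise(n = n(), median = median(.data$dissimilarity),
                  .groups = "drop")),
    roc = lapply(roc, function(r) {
      if (is.null(r)) return(NULL)
      list(summary = glance(r$curve), n_individuals = r$n_individuals,
           band = as_tibble(r$band))
    }),
    null = glance(null),
    observer_stats = list(
      unanimity_proportion = unanimity,
      overall = overall_rates, by_observer = by_observer,
      null_positions = null_positions),
    repeatability = glance(repeatability),
    experience = list(coefficients = tidy(experience),
                      variance_components = glance(experience),
                      group_rates = group_rates)
  ), class = "study_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_study_config(config, file.path(config$out_dir, "config.yaml"))
    write_photos(photos, file.path(config$out_dir, "photos"))
    readr::write_csv(diss, file.path(config$out_dir, "dissimilarity.csv"))
    export_ratings(comparisons, ratings,
                   file.path(config$out_dir, "ratings.csv"))
    write_study_report(report, file.path(config$out_dir, "report.json"))
  }
  report
}

#' Serialize a study report to JSON
#'
#' @param report A [run_study()] result.
#' @param path `.json` path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null",
                       force = TRUE)
  invisible(path)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  design: %d bears, %d sets, %d trials, %d comparisons\n",
              x$design$n_individuals, x$design$n_sets, x$design$n_trials,
              x$design$n_comparisons))
  cat(sprintf("  unanimity %.3f, repeatability R %.3f (SE %.3f)\n",
              x$observer_stats$unanimity_proportion,
              x$repeatability$R, x$repeatability$se))
  for (g in names(x$roc)) {
    if (is.null(x$roc[[g]])) next
    s <- x$roc[[g]]$summary
    cat(sprintf(
      "  ROC (%s): optimal threshold %.2f, FPR %.3f, FNR %.3f, ER %.3f\n",
      g, s$optimal_threshold, s$fpr, s$fnr, s$error_rate))
  }
  cat(sprintf("  null: FPR %.3f (%.3f-%.3f), FNR %.3f (%.3f-%.3f)\n",
              x$null$mean_fpr, x$null$fpr_lower, x$null$fpr_upper,
              x$null$mean_fnr, x$null$fnr_lower, x$null$fnr_upper))
  invisible(x)
}
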