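#' Pipeline configuration
#'
#' All tunable settings of the end-to-end pipeline in one validated list.
#' Defaults follow the analysis conventions used throughout the package:
#' k scanned over 2..24 with 100 maximum iterations and the final fit
#' re-run at 1000 iterations, 20 restarts, a 0.10 representative-track
#' margin, and the classifier hyperparameters of [classifier_spec()].
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param n_tracks,n_events,n_people,n_participants Synthetic input sizes.
#' @param invalid_frac Planted fraction of filter-failing events.
#' @param effects Planted preference effects for the ratings generator.
#' @param noise_sd Rating noise s.d. (slider units).
#' @param k_range Candidate k for the elbow scan.
#' @param restarts k-means restarts.
#' @param scan_max_iter,fit_max_iter k-means iteration caps for the scan and
#'   the final fit.
#' @param margin Representative-track threshold margin.
#' @param diversity_window Moving-average window for the smoothed diversity
#'   profile.
#' @param classifier A [classifier_spec()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_tracks = 10000,
                            n_events = 2e6,
                            n_people = 2000,
                            n_participants = 176,
                            invalid_frac = 0.1,
                            effects = stats::setNames(
                              c(4.34, -4.38, 0.34, -4.64, 10.92),
                              subdivision_levels()),
                            noise_sd = 20,
                            k_range = 2:24,
                            restarts = 20,
                            scan_max_iter = 100,
                            fit_max_iter = 1000,
                            margin = 0.10,
                            diversity_window = 3,
                            classifier = classifier_spec()) {
  stopifnot(invalid_frac >= 0, invalid_frac < 1, margin >= 0,
            diversity_window %% 2 == 1,
            inherits(classifier, "classifier_spec"))
  structure(as.list(environment()), class = "pipeline_config")
}

derive_seed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Run the full analysis pipeline
#'
#' Executes the stages end to end on synthetic inputs: generate (catalog,
#' events, diaries, ratings), filter and aggregate, cluster (scan, elbow,
#' fit), variability/diversity/correlation, training set and classifier,
#' representative tracks and preference statistics. All artifacts are
#' written to `dir` as CSV/JSON together with a `manifest.json` recording
#' seeds, sizes and file hashes; a rerun with the same config reproduces the
#' hashes.
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory (created if needed).
#' @param stages Subset of
#'   `c("simulate", "aggregate", "cluster", "diversity", "classify",
#'   "preference")` to run; later stages require earlier ones in the same
#'   call.
#' @return Invisibly, a list of in-memory results per stage plus
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), dir = tempdir(),
                         stages = c("simulate", "aggregate", "cluster",
                                    "diversity", "classify", "preference")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  path <- function(f) file.path(dir, f)

  profiles <- regime_profiles("diurnal5")
  schedule <- weekly_schedule("diurnal5")

  if ("simulate" %in% stages) {
    res$catalog <- generate_track_catalog(config$n_tracks, profiles,
                                          seed = derive_seed(config$seed, 1))
    res$events <- generate_streaming_events(
      res$catalog, schedule, config$n_events, config$invalid_frac,
      seed = derive_seed(config$seed, 2))
    res$diaries <- generate_activity_diaries(
      config$n_people, seed = derive_seed(config$seed, 3))
    res$ratings <- generate_ratings(
      config$n_participants, effects = config$effects,
      noise_sd = config$noise_sd, seed = derive_seed(config$seed, 4))
    write_track_catalog(res$catalog, path("catalog.csv"))
    write_event_log(res$events, path("events.csv"))
    readr::write_csv(res$diaries, path("diaries.csv"), progress = FALSE)
    readr::write_csv(res$ratings, path("ratings.csv"), progress = FALSE)
  }
  if ("aggregate" %in% stages) {
    kept <- filter_events(res$events)
    res$hourly <- aggregate_hourly(kept, res$catalog)
    write_hourly_table(res$hourly, path("hourly.csv"))
  }
  if ("cluster" %in% stages) {
    z <- zscore_hourly(res$hourly)
    res$curve <- kmeans_scan(z$scaled, config$k_range, config$restarts,
                             config$scan_max_iter,
                             seed = derive_seed(config$seed, 5))
    res$k <- select_k_elbow(res$curve)
    res$model <- fit_subdivisions(z$scaled, z$scaler, res$k,
                                  config$restarts, config$fit_max_iter,
                                  seed = derive_seed(config$seed, 6))
    readr::write_csv(res$curve, path("inertia_curve.csv"), progress = FALSE)
    write_subdivision_model(res$model, path("subdivision_model.json"))
    readr::write_csv(relative_profiles(res$model),
                     path("relative_profiles.csv"), progress = FALSE)
  }
  if ("diversity" %in% stages) {
    res$variability <- feature_variability(res$hourly)
    hourly_act <- preprocess_diaries(res$diaries)
    res$diversity <- activity_diversity(hourly_act)
    res$diversity$smoothed <- moving_average(res$diversity$diversity,
                                             config$diversity_window)
    res$correlation <- correlate_diversity_variability(
      res$diversity$diversity, res$variability$variability)
    readr::write_csv(res$variability, path("variability.csv"),
                     progress = FALSE)
    readr::write_csv(res$diversity, path("diversity.csv"), progress = FALSE)
    jsonlite::write_json(as.list(res$correlation), path("correlation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if ("classify" %in% stages) {
    res$trainset <- build_training_set(res$catalog, res$model)
    res$classifier <- train_classifier(res$trainset, config$classifier,
                                       seed = derive_seed(config$seed, 7))
    jsonlite::write_json(
      list(holdout_accuracy = res$classifier$metrics$holdout_accuracy,
           holdout_loss = res$classifier$metrics$holdout_loss,
           epochs_run = res$classifier$metrics$epochs_run,
           per_class = res$classifier$metrics$per_class_accuracy),
      path("classifier_metrics.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "columns")
  }
  if ("preference" %in% stages) {
    res$candidates <- select_representative_candidates(
      res$catalog, res$model, config$margin)
    res$shortlist <- pca_select(res$candidates)
    kept_ratings <- exclude_participants(res$ratings)
    res$scores <- preference_differences(kept_ratings)
    res$pref_stats <- ttest_vs_zero(res$scores)
    readr::write_csv(res$shortlist, path("shortlist.csv"), progress = FALSE)
    readr::write_csv(tibble::as_tibble(res$pref_stats),
                     path("preference_stats.csv"), progress = FALSE)
  }

  files <- setdiff(list.files(dir, full.names = TRUE), path("manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("diurnalmusic")),
    seed = config$seed,
    sizes = list(n_tracks = config$n_tracks, n_events = config$n_events,
                 n_people = config$n_people,
                 n_participants = config$n_participants),
    stages = stages,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  res$manifest <- manifest
  invisible(res)
}
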