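# Config-driven, end-to-end reproduction of the attack experiment families
# on synthetic cohorts: per split, fit the PLDA on the known (enrollment)
# data, calibrate the acceptance threshold by bootstrap, run the attack and
# tabulate outcomes; then aggregate and compute trend statistics.

#' Experiment configuration
#'
#' @param generator a [generator_config()] for the cohort universe.
#' @param series list of `c(n_known, n_unknown, n_overlap)` triples.
#' @param splits_per_size independent splits per triple.
#' @param threshold_spec `"default"`, `"strict"` or a [threshold_spec()].
#' @param bootstrap list with `subset_size` and `runs` for
#'   [bootstrap_threshold()].
#' @param variant,N acceptance rule, see [accept_matches()].
#' @param probe_task,enroll_task task filters for the splits (cross-task,
#'   within-task and single-task scenarios are all expressed through these).
#' @param exclude_recordings recording ids withheld from enrollment.
#' @param pool_probes replace each probe by the speaker's mean embedding
#'   across all recordings.
#' @param master_seed integer; every random stage derives its seed from it.
#' @param label free-text scenario label carried into the outputs.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(generator, series, splits_per_size = 20L,
                              threshold_spec = "strict",
                              bootstrap = list(subset_size = 100L, runs = 100L),
                              variant = "all", N = NULL,
                              probe_task = NULL, enroll_task = NULL,
                              exclude_recordings = NULL, pool_probes = FALSE,
                              master_seed = 1L, label = "experiment") {
  if (!inherits(generator, "generator_config")) rr_config_error("generator must be a generator_config")
  if (is.character(threshold_spec)) threshold_spec <- threshold_preset(threshold_spec)
  if (!inherits(threshold_spec, "threshold_spec")) rr_config_error("invalid threshold_spec")
  if (!is.list(series) || length(series) == 0L) rr_config_error("series must be a non-empty list of triples")
  structure(list(generator = generator, series = series,
                 splits_per_size = as.integer(splits_per_size),
                 threshold_spec = threshold_spec,
                 bootstrap = modifyList(list(subset_size = 100L, runs = 100L), bootstrap),
                 variant = variant, N = N,
                 probe_task = probe_task, enroll_task = enroll_task,
                 exclude_recordings = exclude_recordings,
                 pool_probes = isTRUE(pool_probes),
                 master_seed = as.integer(master_seed), label = label),
            class = "experiment_config")
}

#' Preset experiment configurations
#'
#' Desk-scale analogues of the study's experiment families, shrunk roughly
#' tenfold in set sizes while preserving overlap and split counts:
#'
#' * `"realistic"`: known set growing through 200, 500, 1000 speakers,
#'   unknown set of 50 with 5 overlap speakers, 20 splits per size, strict
#'   detection-cost preset, all matches above threshold accepted.
#' * `"full_overlap"`: the same sizes with every unknown speaker present in
#'   the known set (overlap = 50).
#' * `"task_cross"`: a six-task clinical-style cohort; enrollment always on
#'   sentence repetition, probes drawn from `probe_task`; default
#'   detection-cost preset; 500 known / 55 unknown / 5 overlap.
#' * `"task_within"`: enrollment and probes both on `probe_task`.
#'
#' @param name preset name.
#' @param master_seed integer master seed.
#' @param probe_task probe task for the task presets (e.g. `"vowel"`,
#'   `"sentence"`, `"amr"`).
#' @param n_speakers cohort universe size (defaults fit the largest split).
#' @return an [experiment_config()].
#' @export
experiment_preset <- function(name = c("realistic", "full_overlap",
                                       "task_cross", "task_within"),
                              master_seed = 1L, probe_task = "vowel",
                              n_speakers = NULL) {
  name <- match.arg(name)
  if (name %in% c("realistic", "full_overlap")) {
    gen <- cohort_preset("voxceleb_like", n_speakers = n_speakers %||% 1100L,
                         seed = derive_seed(master_seed, 0L, "cohort"))
    overlap <- if (name == "realistic") 5L else 50L
    experiment_config(
      generator = gen,
      series = lapply(c(200L, 500L, 1000L), function(k) c(k, 50L, overlap)),
      splits_per_size = 20L, threshold_spec = "strict",
      bootstrap = list(subset_size = 100L, runs = 100L),
      master_seed = master_seed, label = name)
  } else {
    gen <- cohort_preset("mayo_like", n_speakers = n_speakers %||% 600L,
                         seed = derive_seed(master_seed, 0L, "cohort"))
    experiment_config(
      generator = gen,
      series = list(c(500L, 55L, 5L)),
      splits_per_size = 20L, threshold_spec = "default",
      bootstrap = list(subset_size = 100L, runs = 100L),
      probe_task = probe_task,
      enroll_task = if (name == "task_cross") "sentence" else probe_task,
      master_seed = master_seed,
      label = sprintf("%s_%s", name, probe_task))
  }
}

#' Run an experiment end to end
#'
#' Generates the cohort, samples the split series, and for every split:
#' fits a PLDA model on the split's enrollment recordings, calibrates the
#' acceptance threshold by [bootstrap_threshold()] on the known speakers'
#' enrollment data, runs the attack and tabulates outcomes. A failing split
#' is recorded in the manifest and does not abort the experiment. Fully
#' deterministic given `master_seed`.
#'
#' @param config an [experiment_config()].
#' @param output_dir optional directory; when given, writes
#'   `summaries.csv` (one risk-summary row per split), `aggregate.csv`
#'   and `manifest.json`.
#' @return an `experiment_result`: list with `summaries` (data frame),
#'   `aggregate`, `trend` (FA vs comparisons, `NULL` when undefined),
#'   `manifest` (per-split status) and the `config`.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- generate_cohort(config$generator)
  series_master <- derive_seed(config$master_seed, 1L, "series")
  grid <- expand.grid(j = seq_len(config$splits_per_size),
                      i = seq_along(config$series))[, c("i", "j")]
  grid <- grid[order(grid$i, grid$j), ]
  summaries <- NULL
  manifest <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    size <- config$series[[grid$i[i]]]
    split_seed <- series_seed(series_master, grid$i[i], grid$j[i])
    split <- NULL
    res <- tryCatch({
      split <- make_split(cohort, size[1L], size[2L], size[3L],
                          probe_task = config$probe_task,
                          enroll_task = config$enroll_task,
                          exclude_recordings = config$exclude_recordings,
                          seed = split_seed)
      known_cohort <- cohort_subset(cohort, split$enrollment$recording_id)
      model <- fit_plda(known_cohort$embeddings, known_cohort$records$speaker_id)
      subset_size <- min(config$bootstrap$subset_size, length(split$known_speakers))
      cal <- bootstrap_threshold(known_cohort, model, config$threshold_spec,
                                 subset_size = subset_size,
                                 runs = config$bootstrap$runs,
                                 seed = derive_seed(config$master_seed, i, "calibration"))
      tab <- run_attack(model, split, cohort, cal$value,
                        variant = config$variant, N = config$N,
                        pool_probes = config$pool_probes)
      s <- count_outcomes(tab, split)
      s$split <- i
      s$threshold <- cal$value
      s$label <- config$label
      list(summary = s, status = "ok", error = NA_character_)
    }, error = function(e) {
      list(summary = NULL, status = "failed", error = conditionMessage(e))
    })
    manifest[[i]] <- list(
      split = i, seed = split_seed,
      n_known = if (!is.null(split)) length(split$known_speakers) else size[1L],
      n_unknown = if (!is.null(split)) nrow(split$unknown_probes) else size[2L],
      n_overlap = if (!is.null(split)) length(split$overlap_speakers) else size[3L],
      status = res$status, error = res$error)
    if (!is.null(res$summary)) summaries <- rbind(summaries, res$summary)
  }
  agg <- if (!is.null(summaries)) aggregate_risk(summaries) else NULL
  trend <- if (!is.null(summaries) &&
               nrow(summaries) >= 3L &&
               length(unique(summaries$comparisons)) >= 2L &&
               length(unique(summaries$FA)) >= 2L) {
    fa_trend(summaries, "comparisons")
  } else NULL
  result <- structure(list(summaries = summaries, aggregate = agg, trend = trend,
                           manifest = manifest, config = config),
                      class = "experiment_result")
  if (!is.null(output_dir)) write_experiment_result(result, output_dir)
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  ok <- sum(vapply(x$manifest, function(m) m$status == "ok", logical(1)))
  cat(sprintf("<experiment_result> '%s': %d/%d splits succeeded\n",
              x$config$label, ok, length(x$manifest)))
  if (!is.null(x$aggregate)) print(x$aggregate)
  if (!is.null(x$trend)) print(x$trend)
  invisible(x)
}

#' Persist an experiment result
#'
#' Writes `summaries.csv`, `aggregate.csv` and `manifest.json` into
#' `output_dir` (created if needed). CSV numbers are written with enough
#' digits to round-trip, so identical configurations and seeds produce
#' byte-identical files.
#'
#' @param result an `experiment_result`.
#' @param output_dir target directory.
#' @return `output_dir`, invisibly.
#' @export
write_experiment_result <- function(result, output_dir) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    for (cn in names(df)) {
      if (is.numeric(df[[cn]])) df[[cn]] <- sprintf("%.17g", df[[cn]])
    }
    df
  }
  if (!is.null(result$summaries)) {
    write.table(fmt(as.data.frame(result$summaries)),
                file.path(output_dir, "summaries.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$aggregate)) {
    write.table(fmt(result$aggregate), file.path(output_dir, "aggregate.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
  }
  trend <- if (!is.null(result$trend)) {
    list(r = result$trend$r, t = result$trend$t, df = result$trend$df,
         p = result$trend$p, n = result$trend$n, x_axis = result$trend$x_axis)
  } else NULL
  jsonlite::write_json(list(label = result$config$label,
                            master_seed = result$config$master_seed,
                            splits = result$manifest,
                            trend = trend),
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(output_dir)
}
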