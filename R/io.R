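# Configuration, serialization and command entry points for reproducible
# runs. A single YAML document describes the model, engine, lesion schedule,
# paradigm and seeds; outputs are plain delimited tables plus a manifest that
# regenerates the run.

#' Default run configuration
#'
#' The committed calibrated defaults: likelihood reliabilities, feedback
#' preferences, policy precision, the nine-day precision staircase with
#' daily alternation of the affected language, and the feedback-control
#' lesion target.
#'
#' @return nested list of class `aphasim_config`.
#' @export
default_config <- function() {
  structure(list(
    model = list(
      cue_noise = 0.3,
      word_confusability = 0.25,
      feedback_noise = 0.25,
      preferences = list(neutral = 0, positive = 3, negative = -6),
      floor = 1e-8),
    engine = list(
      gamma = 16,
      max_iter = 16L,
      conv_tol = 1e-4,
      risk_over = "outcomes",
      action_mode = "deterministic"),
    lesion = list(
      omega = c(0.1, 0.1, 0.1, 0.1, 0.25, 0.25, 0.5, 0.5, 1),
      affected = list(),  # empty: alternate daily starting with L1
      preset = "feedback-control",
      timescale = "daily",
      stretch = 7L),
    paradigm = list(
      days = 9L,
      items_per_block = 5L),
    seeds = list(base = 1L),
    output = list(dir = "aphasim-results")),
    class = "aphasim_config")
}

#' @keywords internal
.merge_config <- function(defaults, given, path = "") {
  extra <- setdiff(names(given), names(defaults))
  if (length(extra))
    .stopf("unknown configuration field%s: %s",
           if (length(extra) > 1) "s" else "",
           paste0(sub("^\\.", "", paste0(path, ".", extra)),
                  collapse = ", "))
  for (k in names(given)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .merge_config(defaults[[k]],
                                     as.list(given[[k]]),
                                     paste0(path, ".", k))
    } else {
      defaults[[k]] <- given[[k]]
    }
  }
  defaults
}

#' @keywords internal
.validate_config <- function(cfg) {
  om <- unlist(cfg$lesion$omega)
  if (length(om) == 0L || any(!is.finite(om) | om <= 0))
    .stopf("configuration field lesion.omega must contain positive values")
  for (fld in c("cue_noise", "word_confusability", "feedback_noise")) {
    v <- cfg$model[[fld]]
    if (!is.numeric(v) || v < 0 || v >= 0.5)
      .stopf("configuration field model.%s must lie in [0, 0.5)", fld)
  }
  if (cfg$engine$gamma <= 0)
    .stopf("configuration field engine.gamma must be positive")
  if (cfg$paradigm$items_per_block > 12L)
    .stopf("configuration field paradigm.items_per_block cannot exceed 12")
  if (!is.numeric(cfg$seeds$base))
    .stopf("configuration field seeds.base must be an integer seed")
  cfg$seeds$base <- as.integer(cfg$seeds$base)
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills every omitted field with the committed
#' default, rejects unknown keys, and validates field values (naming the
#' offending field).
#'
#' @param path YAML file path, or `NULL` for the pure defaults.
#' @return validated `aphasim_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) .stopf("configuration file '%s' not found", path)
    given <- yaml::read_yaml(path)
    if (!is.null(given)) cfg <- .merge_config(cfg, given)
  }
  .validate_config(structure(cfg, class = "aphasim_config"))
}

#' Write a configuration to YAML
#'
#' Round-trips with [load_config()].
#'
#' @param config an `aphasim_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @keywords internal
.schedule_from_config <- function(cfg) {
  make_schedule(omega = unlist(cfg$lesion$omega),
                days = cfg$paradigm$days,
                affected = if (length(cfg$lesion$affected))
                  unlist(cfg$lesion$affected) else NULL,
                preset = cfg$lesion$preset,
                timescale = cfg$lesion$timescale,
                stretch = cfg$lesion$stretch)
}

#' @keywords internal
.model_from_config <- function(cfg) {
  pr <- cfg$model$preferences
  build_task_model(cue_noise = cfg$model$cue_noise,
                   word_confusability = cfg$model$word_confusability,
                   feedback_noise = cfg$model$feedback_noise,
                   preferences = c(pr$neutral, pr$positive, pr$negative),
                   floor = cfg$model$floor)
}

#' Execute a configured study and write its outputs
#'
#' Runs the two-subject study described by the configuration and writes, to
#' the output directory: `scores.tsv` (one row per subject x day x block
#' cell), `pattern.yaml` (classifier flags for both subjects),
#' `traces.tsv` (belief trajectories for the lesioned subject) and
#' `manifest.yaml` (the full configuration, the seeds used and package and R
#' versions — sufficient to regenerate every table bit-identically).
#'
#' @param config an `aphasim_config` (or path to one).
#' @param subjects which subjects' outputs to write.
#' @param quiet suppress progress messages.
#' @return named character vector of written file paths, invisibly.
#' @export
run_command <- function(config = default_config(),
                        subjects = c("both", "control", "lesioned"),
                        quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  config <- .validate_config(config)
  subjects <- match.arg(subjects)
  dir <- config$output$dir
  parent <- dirname(dir)
  if (!dir.exists(parent))
    .stopf("output location '%s' does not exist", parent)
  dir.create(dir, showWarnings = FALSE)

  if (!quiet) message("building task model and running study ...")
  model <- .model_from_config(config)
  schedule <- .schedule_from_config(config)
  study <- run_study(model, schedule,
                     days = config$paradigm$days,
                     base_seed = config$seeds$base,
                     items_per_block = config$paradigm$items_per_block,
                     action_mode = config$engine$action_mode,
                     gamma = config$engine$gamma,
                     risk_over = config$engine$risk_over,
                     max_iter = config$engine$max_iter,
                     conv_tol = config$engine$conv_tol)

  keep <- if (subjects == "both") c("control", "lesioned") else subjects
  scores <- score_study(study)
  scores <- scores[scores$subject %in% keep, ]

  paths <- c(scores = file.path(dir, "scores.tsv"),
             pattern = file.path(dir, "pattern.yaml"),
             traces = file.path(dir, "traces.tsv"),
             manifest = file.path(dir, "manifest.yaml"))

  utils::write.table(scores, paths[["scores"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  pattern <- lapply(study[keep], function(s) {
    rep <- classify_pattern(s)
    list(subject = s$subject,
         alternate_antagonism = rep$alternate_antagonism,
         antagonism_switch_days = as.list(rep$antagonism_switch_days),
         paradoxical_translation = rep$paradoxical_translation,
         paradox_days = as.list(rep$paradox_days),
         accessible_by_day = as.list(rep$per_day$accessible))
  })
  yaml::write_yaml(pattern, paths[["pattern"]])

  trace_subject <- if (subjects == "control") "control" else "lesioned"
  traces <- export_belief_traces(study[[trace_subject]]$records)
  utils::write.table(traces, paths[["traces"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(config = unclass(config),
                   day_seeds = as.list(study$control$seeds),
                   package_version =
                     as.character(utils::packageVersion("aphasim")),
                   r_version = R.version.string)
  yaml::write_yaml(manifest, paths[["manifest"]])

  if (!quiet) message("wrote ", paste(basename(paths), collapse = ", "),
                      " to ", dir)
  invisible(paths)
}

#' Summarise a written study
#'
#' Reads `scores.tsv` (and `pattern.yaml` if present) from a results
#' directory and renders a per-day bar-chart-style text summary with overall
#' percentages and classifier flags.
#'
#' @param dir results directory written by [run_command()].
#' @return the scores data.frame, invisibly.
#' @export
report_command <- function(dir) {
  score_file <- file.path(dir, "scores.tsv")
  if (!file.exists(score_file))
    .stopf("no scores.tsv under '%s'", dir)
  scores <- utils::read.delim(score_file, stringsAsFactors = FALSE)
  for (subj in unique(scores$subject)) {
    d <- scores[scores$subject == subj, ]
    pct <- 100 * sum(d$correct) / sum(d$n)
    cat(sprintf("%s: %s%% correct overall\n", subj,
                format(pct, digits = 4)))
    tab <- stats::xtabs(correct ~ day + paste(context, stimulus_language),
                        data = d)
    print(tab)
  }
  pat_file <- file.path(dir, "pattern.yaml")
  if (file.exists(pat_file)) {
    pattern <- yaml::read_yaml(pat_file)
    cat("\nrecovery-pattern flags:\n")
    for (p in pattern)
      cat(sprintf("  %s: alternate antagonism = %s, paradoxical translation = %s\n",
                  p$subject, p$alternate_antagonism,
                  p$paradoxical_translation))
  }
  invisible(scores)
}
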