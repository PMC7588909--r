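# Paradigm runner: daily blocks of naming, repetition and translation in both
# languages, for a control and a lesioned subject driven by matched random
# streams, plus scoring and recovery-pattern classification.

# the fixed daily block order
#' @keywords internal
.block_plan <- function() {
  data.frame(
    block = 1:6,
    context = c("naming", "repetition", "translation",
                "naming", "repetition", "translation"),
    stimulus_language = c("L1", "L1", "L1", "L2", "L2", "L2"),
    stringsAsFactors = FALSE)
}

#' Run a single trial
#'
#' Epoch 1: the environment presents the stimulus; the agent infers hidden
#' states under each policy, evaluates expected free energy one epoch ahead,
#' and forms a policy posterior. The agent then acts (chooses a language to
#' speak). Epoch 2: the environment returns the spoken-language outcomes and
#' feedback, and the agent updates its beliefs over both epochs. The full
#' belief and policy trace is recorded.
#'
#' @param model the (possibly lesioned) agent model; the environment always
#'   uses the intact mapping.
#' @param setup an `aphasim_trial_setup`.
#' @param seed optional integer seed for the trial's random stream (only
#'   consumed in `"sample"` mode).
#' @param action_mode action selection mode, `"deterministic"` or
#'   `"sample"`.
#' @param gamma policy precision.
#' @param risk_over risk variant for [expected_free_energy()].
#' @param max_iter,conv_tol engine iteration controls.
#' @return list of class `aphasim_trial_record`.
#' @export
run_trial <- function(model, setup, seed = NULL,
                      action_mode = c("deterministic", "sample"),
                      gamma = 16, risk_over = "outcomes", max_iter = 16L,
                      conv_tol = 1e-4) {
  action_mode <- match.arg(action_mode)
  if (!is.null(seed)) set.seed(seed)
  npol <- nrow(model$policies)
  obs <- observation_set(model)
  obs[, 1] <- environment_step(model, setup, 1L)

  bel1 <- lapply(seq_len(npol), function(p)
    infer_states(model, obs, p, max_iter, conv_tol))
  efe <- lapply(seq_len(npol), function(p)
    expected_free_energy(model, bel1[[p]], p, risk_over = risk_over))
  Fv <- vapply(bel1, `[[`, numeric(1), "F")
  Gv <- vapply(efe, `[[`, numeric(1), "G")
  post <- policy_posterior(Fv, Gv, gamma)
  act <- select_action(post, model$policies, action_mode)
  spoken <- .LANGS[act$actions[["target"]]]

  obs[, 2] <- environment_step(model, setup, 2L, action = spoken)
  bel2 <- lapply(seq_len(npol), function(p)
    infer_states(model, obs, p, max_iter, conv_tol))
  F2 <- vapply(bel2, `[[`, numeric(1), "F")
  post2 <- softmax(-F2, scale = gamma)

  marginal <- function(bels, weights) {
    out <- lapply(names(model$factors), function(f) {
      q <- 0
      for (p in seq_along(bels)) q <- q + weights[p] * bels[[p]]$Q[[f]]
      q
    })
    names(out) <- names(model$factors)
    out
  }

  structure(list(
    day = setup$day, block = setup$block, setup = setup,
    observations = obs,
    beliefs_epoch1 = marginal(bel1, post),
    beliefs_final = marginal(bel2, post2),
    per_policy = list(epoch1 = bel1, final = bel2),
    policy_eval = list(F = Fv, G = Gv,
                       risk = vapply(efe, `[[`, numeric(1), "risk"),
                       ambiguity = vapply(efe, `[[`, numeric(1), "ambiguity"),
                       posterior = post),
    converged = all(vapply(c(bel1, bel2), `[[`, logical(1), "converged")),
    action = spoken,
    feedback = .FEEDBACK[obs["feedback", 2]],
    correct = unname(obs["feedback", 2] == 2L)),
    class = "aphasim_trial_record")
}

#' Run one simulated testing day
#'
#' Six consecutive blocks in fixed order — picture naming in L1, word
#' repetition in L1, word translation from L1 to L2, picture naming in L2,
#' word repetition in L2 and word translation from L2 to L1 — with
#' `items_per_block` concepts drawn uniformly without replacement from the
#' twelve-concept corpus using the day's seeded stream.
#'
#' @param model the intact agent model; the day's lesion (if any) is applied
#'   internally from `schedule`.
#' @param schedule an `aphasim_schedule` (use [intact_schedule()] for a
#'   control subject).
#' @param day day index.
#' @param seed integer seed driving item sampling (and trial streams in
#'   sampling mode).
#' @param items_per_block items per block (at most 12).
#' @param keep_records return full trial records alongside the counts.
#' @param ... further arguments to [run_trial()].
#' @return list with `scores` (one row per task x stimulus-language cell) and
#'   `records`.
#' @export
run_day <- function(model, schedule, day, seed, items_per_block = 5L,
                    keep_records = TRUE, ...) {
  if (items_per_block > 12L)
    .stopf("items_per_block cannot exceed the 12-concept corpus")
  plan <- .block_plan()
  day_model <- lesion_model(model, schedule, day)
  voc <- attr(model, "task")$vocabulary
  records <- list()
  scores <- plan
  scores$day <- day
  scores$correct <- 0L
  scores$n <- items_per_block

  for (b in seq_len(nrow(plan))) {
    set.seed(.child_seed(seed, b))
    items <- sample(voc$concept, items_per_block, replace = FALSE)
    for (i in seq_along(items)) {
      setup <- trial_setup(plan$context[b], plan$stimulus_language[b],
                           items[i], block = b, day = day)
      rec <- run_trial(day_model, setup,
                       seed = .child_seed(seed, b * 100L + i), ...)
      scores$correct[b] <- scores$correct[b] + as.integer(rec$correct)
      if (keep_records) records[[length(records) + 1L]] <- rec
    }
  }
  list(scores = scores[, c("day", "block", "context", "stimulus_language",
                           "correct", "n")],
       records = records)
}

#' Run the full study for control and lesioned subjects
#'
#' Both subjects are exposed to the same daily paradigm with identical
#' per-day and per-trial random streams derived from `base_seed`, so any
#' behavioural difference is attributable to the lesion alone. The control
#' subject runs with precision 1 (no lesion) every day.
#'
#' @param model the intact task model.
#' @param schedule_lesioned an `aphasim_schedule` for the lesioned subject.
#' @param days number of days (default: length of the schedule).
#' @param base_seed integer base seed.
#' @param schedule_control control schedule (default: intact every day).
#' @param keep_records keep full trial records (set `FALSE` to save memory).
#' @param ... further arguments to [run_trial()].
#' @return list of class `aphasim_study` with elements `control` and
#'   `lesioned`, each carrying `subject`, `scores`, `records` and `seeds`.
#' @export
run_study <- function(model, schedule_lesioned = make_schedule(),
                      days = nrow(schedule_lesioned), base_seed = 1L,
                      schedule_control = intact_schedule(days),
                      keep_records = TRUE, ...) {
  day_seeds <- vapply(seq_len(days), function(d) .child_seed(base_seed, d),
                      integer(1))
  one_subject <- function(label, schedule) {
    scores <- list()
    records <- list()
    for (d in seq_len(days)) {
      res <- run_day(model, schedule, d, day_seeds[d],
                     keep_records = keep_records, ...)
      scores[[d]] <- res$scores
      records <- c(records, res$records)
    }
    list(subject = label,
         scores = do.call(rbind, scores),
         records = records,
         seeds = day_seeds)
  }
  structure(list(control = one_subject("control", schedule_control),
                 lesioned = one_subject("lesioned", schedule_lesioned)),
            class = "aphasim_study")
}

#' Tabulate study scores
#'
#' @param study an `aphasim_study`, or a single subject element of one.
#' @return data.frame with one row per subject x day x task x
#'   stimulus-language cell plus a `percent` summary attribute
#'   (`attr(x, "percent")`, named by subject).
#' @export
score_study <- function(study) {
  subjects <- if (inherits(study, "aphasim_study")) study else list(study)
  rows <- lapply(subjects, function(s) {
    if (is.null(s$scores) || nrow(s$scores) == 0L)
      return(NULL)
    cbind(subject = s$subject, s$scores)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject = character(), day = integer(),
                      block = integer(), context = character(),
                      stimulus_language = character(), correct = integer(),
                      n = integer())
  }
  pct <- vapply(split(out, out$subject),
                function(d) 100 * sum(d$correct) / sum(d$n), numeric(1))
  attr(out, "percent") <- pct
  out
}

#' Classify the recovery pattern of a subject
#'
#' Operationalises the clinical pattern descriptions. For each day the
#' naming-accessible language is the language in which naming is "able"
#' (at least `able` of `n` correct) while the other is "unable" (at most
#' `unable` correct). Alternate antagonism holds when the accessible language
#' switches between at least one pair of consecutive days. Paradoxical
#' translation holds on a day when translation into the accessible language
#' is unable, translation into the inaccessible language is able, and
#' repetition is able in both languages.
#'
#' @param scores a subject's `scores` data.frame (from [run_day()] /
#'   [run_study()]), or a subject element of an `aphasim_study`.
#' @param able,unable thresholds on correct counts (must satisfy
#'   `able > unable`).
#' @return list of class `aphasim_pattern_report`: per-day table, both flags
#'   and their supporting days.
#' @export
classify_pattern <- function(scores, able = 4L, unable = 1L) {
  if (able <= unable)
    .stopf("inconsistent thresholds: able (%s) must exceed unable (%s)",
           able, unable)
  if (is.list(scores) && !is.data.frame(scores) && !is.null(scores$scores))
    scores <- scores$scores
  cell <- function(d, ctx, lang) {
    r <- scores$correct[scores$day == d & scores$context == ctx &
                          scores$stimulus_language == lang]
    if (length(r) != 1L) NA_integer_ else r
  }
  days <- sort(unique(scores$day))
  per_day <- lapply(days, function(d) {
    nam <- c(L1 = cell(d, "naming", "L1"), L2 = cell(d, "naming", "L2"))
    rep_ <- c(L1 = cell(d, "repetition", "L1"),
              L2 = cell(d, "repetition", "L2"))
    trans_from <- c(L1 = cell(d, "translation", "L1"),
                    L2 = cell(d, "translation", "L2"))
    is_able <- function(x) !is.na(x) & x >= able
    is_unable <- function(x) !is.na(x) & x <= unable
    accessible <-
      if (is_able(nam["L1"]) && is_unable(nam["L2"])) "L1"
      else if (is_able(nam["L2"]) && is_unable(nam["L1"])) "L2"
      else if (is_able(nam["L1"]) && is_able(nam["L2"])) "both"
      else "neither"
    paradox <- FALSE
    if (accessible %in% .LANGS) {
      inacc <- setdiff(.LANGS, accessible)
      into_acc <- trans_from[inacc]      # translating from the other language
      into_inacc <- trans_from[accessible]
      paradox <- is_unable(into_acc) && is_able(into_inacc) &&
        is_able(rep_["L1"]) && is_able(rep_["L2"])
    }
    data.frame(day = d, accessible = accessible, paradox = paradox,
               stringsAsFactors = FALSE)
  })
  per_day <- do.call(rbind, per_day)

  switches <- integer(0)
  if (nrow(per_day) > 1L) for (i in seq_len(nrow(per_day) - 1L)) {
    a <- per_day$accessible[i]
    b <- per_day$accessible[i + 1L]
    if (a %in% .LANGS && b %in% .LANGS && a != b)
      switches <- c(switches, per_day$day[i + 1L])
  }

  structure(list(
    per_day = per_day,
    alternate_antagonism = length(switches) > 0L,
    antagonism_switch_days = switches,
    paradoxical_translation = any(per_day$paradox),
    paradox_days = per_day$day[per_day$paradox],
    thresholds = c(able = able, unable = unable)),
    class = "aphasim_pattern_report")
}

#' @export
print.aphasim_pattern_report <- function(x, ...) {
  cat("<recovery pattern report>\n")
  cat("  alternate antagonism:    ", x$alternate_antagonism,
      if (length(x$antagonism_switch_days))
        sprintf(" (switches entering days %s)",
                paste(x$antagonism_switch_days, collapse = ", ")) else "",
      "\n", sep = "")
  cat("  paradoxical translation: ", x$paradoxical_translation,
      if (length(x$paradox_days))
        sprintf(" (days %s)", paste(x$paradox_days, collapse = ", "))
      else "", "\n", sep = "")
  cat("  accessible language by day: ",
      paste(x$per_day$accessible, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Export belief trajectories for chosen trials
#'
#' Tabulates the policy-averaged posterior expectations for the
#' heard-language and target-language factors, at both update times (end of
#' epoch 1, end of epoch 2) and about both epochs — the states-by-epochs
#' layout of a belief-updating raster.
#'
#' @param records list of `aphasim_trial_record`s.
#' @param selection integer indices of the trials to export (default all).
#' @param factors factors to export.
#' @return data.frame with one row per trial x factor x state x update time
#'   x epoch believed about.
#' @export
export_belief_traces <- function(records, selection = seq_along(records),
                                 factors = c("heard", "target")) {
  rows <- list()
  for (i in selection) {
    rec <- records[[i]]
    for (f in factors) {
      for (when in c(1L, 2L)) {
        q <- if (when == 1L) rec$beliefs_epoch1[[f]] else
          rec$beliefs_final[[f]]
        for (about in seq_len(ncol(q))) {
          rows[[length(rows) + 1L]] <- data.frame(
            trial = i, day = rec$day, block = rec$block,
            context = rec$setup$context,
            stimulus_language = rec$setup$heard,
            concept = rec$setup$concept,
            factor = f, state = rownames(q),
            updated_at_epoch = when, about_epoch = about,
            probability = q[, about],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(trial = integer(), day = integer(), block = integer(),
                      context = character(), stimulus_language = character(),
                      concept = character(), factor = character(),
                      state = character(), updated_at_epoch = integer(),
                      about_epoch = integer(), probability = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
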