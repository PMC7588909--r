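# The in-silico precision lesion: a temperature-like operator omega on
# targeted likelihood columns of the agent's model, plus day-indexed
# schedules. omega = 1 leaves the stored representation bitwise unchanged;
# omega -> 0 drives targeted columns to the uniform distribution.

#' Describe a lesion target
#'
#' Selects the likelihood columns whose precision is reduced. Columns are
#' selected by the affected language: a column is targeted when its
#' heard-language index (the epoch-1, stimulus role) or its target-language
#' index (the epoch-2, response role) equals the affected language, within
#' the targeted modalities, epochs and contexts of the chosen preset.
#'
#' Presets:
#' * `"feedback-control"` (calibrated default): the feedback modality's
#'   epoch-2 columns with heard language = affected, in the two
#'   control-demanding contexts (naming and translation). Word repetition's
#'   evaluative mapping is spared, mirroring control-resource accounts in
#'   which repetition demands no language selection.
#' * `"audition-language"`: all auditory-stream evidence about the affected
#'   language — audition and language columns with heard = affected at
#'   epoch 1 or target = affected at epoch 2, in every context.
#' * `"audition"`, `"language"`: single-modality variants of the above.
#' * `"epoch2"`: audition and language epoch-2 columns only
#'   (target = affected).
#'
#' @param affected `"L1"` or `"L2"`.
#' @param preset one of the preset names above.
#' @return list of class `aphasim_lesion_target`.
#' @export
lesion_target <- function(affected,
                          preset = c("feedback-control", "audition-language",
                                     "audition", "language", "epoch2")) {
  if (!affected %in% .LANGS) .stopf("affected language must be L1 or L2")
  preset <- match.arg(preset)
  spec <- switch(preset,
    "feedback-control" = list(modalities = "feedback",
                              contexts = c("naming", "translation"),
                              epochs = 2L, role = "heard"),
    "audition-language" = list(modalities = c("audition", "language"),
                               contexts = .CONTEXTS, epochs = 1:2,
                               role = "by-epoch"),
    "audition" = list(modalities = "audition", contexts = .CONTEXTS,
                      epochs = 1:2, role = "by-epoch"),
    "language" = list(modalities = "language", contexts = .CONTEXTS,
                      epochs = 1:2, role = "by-epoch"),
    "epoch2" = list(modalities = c("audition", "language"),
                    contexts = .CONTEXTS, epochs = 2L, role = "target"))
  structure(c(list(affected = affected, preset = preset), spec),
            class = "aphasim_lesion_target")
}

# Logical mask over joint-state columns (factor-1-fastest order) for one
# lesion target. `role` decides which language index must equal the affected
# language: the heard index (epoch-1 stimulus role), the target index
# (epoch-2 response role), or the role matching each column's epoch.
#' @keywords internal
.lesion_mask <- function(model, target) {
  nf <- lengths(model$factors)
  grid <- expand.grid(lapply(nf, seq_len))
  aff <- match(target$affected, .LANGS)
  cxs <- match(target$contexts, .CONTEXTS)
  in_epoch <- grid$epoch %in% target$epochs
  in_ctx <- grid$context %in% cxs
  lang_hit <- switch(target$role,
    "heard" = grid$heard == aff,
    "target" = grid$target == aff,
    "by-epoch" = (grid$epoch == 1L & grid$heard == aff) |
                 (grid$epoch == 2L & grid$target == aff))
  in_epoch & in_ctx & lang_hit
}

#' Apply a precision reduction to targeted likelihood columns
#'
#' For every targeted column `c`, replaces it with
#' `normalise(exp(omega * log(c)))`. `omega = 1` returns the input unchanged;
#' `omega -> 0` flattens the column towards uniform. Untargeted columns are
#' untouched. The transform is monotone, so the ordering of entries within a
#' column is preserved.
#'
#' @param likelihoods named list of (floored, normalised) likelihood arrays.
#' @param omega positive precision; values outside `(0, 1]` trigger a
#'   warning.
#' @param target an `aphasim_lesion_target`.
#' @param model the model the likelihoods belong to (for factor layout).
#' @return the likelihood list with targeted columns flattened.
#' @export
apply_precision <- function(likelihoods, omega, target, model) {
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0)
    .stopf("omega must be a positive scalar")
  if (omega > 1)
    warning("omega > 1 sharpens rather than flattens the targeted columns",
            call. = FALSE)
  if (omega == 1) return(likelihoods)
  mask <- .lesion_mask(model, target)
  for (m in target$modalities) {
    A <- likelihoods[[m]]
    flat <- matrix(A, nrow = dim(A)[1])
    cols <- which(mask)
    lesioned <- exp(omega * log(flat[, cols, drop = FALSE]))
    flat[, cols] <- sweep(lesioned, 2, colSums(lesioned), "/")
    likelihoods[[m]] <- array(flat, dim = dim(A))
  }
  likelihoods
}

#' Build a day-indexed precision schedule
#'
#' The default nine-day schedule follows the staircase
#' `0.1, 0.1, 0.1, 0.1, 0.25, 0.25, 0.5, 0.5, 1` with the affected language
#' alternating daily (odd days L1, even days L2). A `"slow"` timescale
#' stretches each day of the trajectory over `stretch` days and alternates
#' the affected language at the same stretched rhythm, reproducing the same
#' recovery pattern over weeks rather than days.
#'
#' @param omega numeric vector of per-day precisions (recycled against
#'   `days`); the default staircase if `NULL`.
#' @param days number of days (default length of the trajectory).
#' @param affected per-day affected languages; default daily alternation
#'   starting with `"L1"`.
#' @param preset lesion-target preset passed to [lesion_target()].
#' @param timescale `"daily"` or `"slow"`.
#' @param stretch days per step for the slow timescale.
#' @return data.frame of class `aphasim_schedule` with columns `day`,
#'   `omega`, `affected`, `preset`.
#' @export
make_schedule <- function(omega = NULL, days = NULL, affected = NULL,
                          preset = "feedback-control",
                          timescale = c("daily", "slow"), stretch = 7L) {
  timescale <- match.arg(timescale)
  if (is.null(omega)) omega <- c(0.1, 0.1, 0.1, 0.1, 0.25, 0.25, 0.5, 0.5, 1)
  if (length(omega) == 0L) .stopf("schedule requires at least one day")
  if (any(!is.finite(omega) | omega <= 0))
    .stopf("schedule field 'omega' must be positive")
  if (any(omega > 1))
    warning("schedule contains omega > 1 (outside (0, 1])", call. = FALSE)
  if (timescale == "slow") omega <- rep(omega, each = stretch)
  if (is.null(days)) days <- length(omega)
  omega <- rep_len(omega, days)
  if (is.null(affected)) {
    step <- if (timescale == "slow") stretch else 1L
    affected <- .LANGS[((ceiling(seq_len(days) / step) - 1L) %% 2L) + 1L]
  }
  affected <- rep_len(affected, days)
  if (!all(affected %in% .LANGS))
    .stopf("schedule field 'affected' must be L1 or L2")
  structure(data.frame(day = seq_len(days), omega = omega,
                       affected = affected, preset = preset,
                       stringsAsFactors = FALSE),
            class = c("aphasim_schedule", "data.frame"))
}

#' Schedule with no lesion on any day
#'
#' @param days number of days.
#' @return an `aphasim_schedule` with `omega = 1` throughout.
#' @export
intact_schedule <- function(days = 9L) {
  make_schedule(omega = rep(1, days), days = days,
                affected = rep("L1", days))
}

#' Lesion a model according to a schedule day
#'
#' Pure function: returns a copy of the model with the day's precision
#' reduction applied to its likelihoods; the input model is unchanged and an
#' `omega = 1` day returns a model equal to the input.
#'
#' @param model an `aphasim_model` built by [build_task_model()].
#' @param schedule an `aphasim_schedule`.
#' @param day day index.
#' @return the (possibly) lesioned model.
#' @export
lesion_model <- function(model, schedule, day) {
  row <- schedule[schedule$day == day, ]
  if (nrow(row) != 1L) .stopf("schedule has no entry for day %s", day)
  target <- lesion_target(row$affected, row$preset)
  model$A <- apply_precision(model$A, row$omega, target, model)
  model
}
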