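# The generative process (environment side): holds the true trial states and
# emits outcomes deterministically from the intact task mapping. The lesion
# never touches this side, so lesioned and control subjects receive identical
# stimuli under matched seeds; only belief formation differs.

#' Define the true states of one trial
#'
#' @param context `"naming"`, `"repetition"` or `"translation"`.
#' @param heard stimulus language, `"L1"` or `"L2"`. For naming this is the
#'   language the picture must be named in (the cue language); for
#'   translation it is the source language of the heard word.
#' @param concept concept name.
#' @param block,day bookkeeping indices.
#' @return list of class `aphasim_trial_setup`.
#' @export
trial_setup <- function(context, heard, concept, block = NA_integer_,
                        day = NA_integer_) {
  if (!context %in% .CONTEXTS) .stopf("unknown context '%s'", context)
  if (!heard %in% .LANGS) .stopf("unknown language '%s'", heard)
  if (!concept %in% .CONCEPTS) .stopf("unknown concept '%s'", concept)
  structure(list(context = context, heard = heard, concept = concept,
                 block = block, day = day),
            class = "aphasim_trial_setup")
}

#' Emit the environment's outcomes for one epoch
#'
#' Epoch 1 presents the stimulus: the task cue, the stimulus-language cue,
#' the heard word (repetition/translation) or the picture (naming), and
#' neutral feedback. Epoch 2 reflects the agent's response: the spoken
#' language (the agent's chosen target language), the spoken word, and
#' positive or negative feedback computed from the true context, the true
#' heard language and the chosen language.
#'
#' @param model the task model (only its level names are used; emission is
#'   from the intact deterministic mapping).
#' @param setup an `aphasim_trial_setup`.
#' @param epoch 1 or 2.
#' @param action for epoch 2, the agent's chosen target language
#'   (`"L1"`/`"L2"` or action index).
#' @return named integer vector of outcome levels, one per modality.
#' @export
environment_step <- function(model, setup, epoch, action = NULL) {
  task <- attr(model, "task")
  if (is.null(task)) .stopf("model does not carry task metadata")
  voc <- task$vocabulary
  lv <- model$modalities
  cx <- match(setup$context, .CONTEXTS)
  h <- match(setup$heard, .LANGS)
  k <- match(setup$concept, voc$concept)
  na_aud <- length(lv$audition)
  na_vis <- length(lv$visual)
  word_idx <- function(lang, k) match(word_for(voc$concept[k], .LANGS[lang],
                                               voc), lv$audition)

  if (epoch == 1L) {
    c(task = cx,
      language = h,
      audition = if (cx == 1L) na_aud else word_idx(h, k),
      visual = if (cx == 1L) k else na_vis,
      feedback = 1L)
  } else {
    if (is.character(action)) action <- match(action, .LANGS)
    if (is.null(action) || is.na(action))
      .stopf("epoch 2 requires the agent's chosen language")
    positive <- .feedback_positive(cx, h, action)
    c(task = cx,
      language = as.integer(action),
      audition = word_idx(action, k),
      visual = na_vis,
      feedback = if (positive) 2L else 3L)
  }
}
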