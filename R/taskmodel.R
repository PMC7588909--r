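# The bilingual three-task generative model: picture naming, word repetition
# and word translation over a twelve-concept vocabulary in two languages.
# Five hidden-state factors (context, heard language, target language,
# concept, epoch) and five outcome modalities (task, language, audition,
# visual, feedback).

.CONCEPTS <- c("man", "girl", "baby", "ring", "scarf", "hat",
               "cat", "dog", "parrot", "leaflet", "book", "newspaper")
.L1_WORDS <- c("homme", "fille", "l'enfant", "bague", "echarpe", "chapeau",
               "chatte", "chienne", "perroquet", "brochure", "livre",
               "la feuille")
.LANGS <- c("L1", "L2")
.CONTEXTS <- c("naming", "repetition", "translation")
.FEEDBACK <- c("neutral", "positive", "negative")

#' Default bilingual vocabulary
#'
#' Twelve concepts, each with one word per language: L1 carries the French
#' forms and L2 the English forms (which coincide with the concept names).
#' Fully replaceable; any 12 x 2 table of distinct words works.
#'
#' @return data.frame with columns `concept`, `L1`, `L2`.
#' @export
default_vocabulary <- function() {
  data.frame(concept = .CONCEPTS, L1 = .L1_WORDS, L2 = .CONCEPTS,
             stringsAsFactors = FALSE)
}

#' @keywords internal
.check_vocabulary <- function(vocabulary) {
  need <- c("concept", "L1", "L2")
  if (!is.data.frame(vocabulary) || !all(need %in% names(vocabulary)))
    .stopf("vocabulary must be a data.frame with columns concept, L1, L2")
  if (nrow(vocabulary) != 12L)
    .stopf("vocabulary must have exactly 12 concepts")
  words <- c(vocabulary$L1, vocabulary$L2)
  if (anyDuplicated(words) || anyDuplicated(vocabulary$concept))
    .stopf("vocabulary words and concepts must be distinct")
  vocabulary
}

#' Look up the word for a concept in a language
#'
#' @param concept concept name (e.g. `"man"`).
#' @param language `"L1"` or `"L2"`.
#' @param vocabulary vocabulary table (see [default_vocabulary()]).
#' @return the word as a character scalar.
#' @export
word_for <- function(concept, language, vocabulary = default_vocabulary()) {
  vocabulary <- .check_vocabulary(vocabulary)
  i <- match(concept, vocabulary$concept)
  if (is.na(i)) .stopf("unknown concept '%s'", concept)
  if (!language %in% .LANGS) .stopf("unknown language '%s'", language)
  vocabulary[[language]][i]
}

#' Factor and modality specifications of the task model
#'
#' @param vocabulary vocabulary table.
#' @return list with `factors` and `modalities`, each a named list of level
#'   names. The audition modality interleaves the two languages' words per
#'   concept plus an `"N/A"` level (25 levels); visual has the 12 pictures
#'   plus `"N/A"` (13 levels).
#' @export
task_specs <- function(vocabulary = default_vocabulary()) {
  vocabulary <- .check_vocabulary(vocabulary)
  words <- as.vector(rbind(vocabulary$L2, vocabulary$L1))
  list(
    factors = list(
      context = .CONTEXTS,
      heard = .LANGS,
      target = .LANGS,
      concept = vocabulary$concept,
      epoch = c("e1", "e2")),
    modalities = list(
      task = .CONTEXTS,
      language = .LANGS,
      audition = c(words, "N/A"),
      visual = c(vocabulary$concept, "N/A"),
      feedback = .FEEDBACK))
}

#' @keywords internal
.other_lang <- function(i) 3L - i

# positive-feedback rule: naming/repetition reward matching heard and target
# languages at epoch 2; translation rewards a language switch.
#' @keywords internal
.feedback_positive <- function(context, heard, target) {
  if (context == 3L) heard != target else heard == target
}

#' Build the per-modality likelihood tensors
#'
#' Implements, column by column over the joint hidden state
#' (context, heard, target, concept, epoch):
#' * `task` reports the context (identity) at both epochs.
#' * `language` reports the heard language at epoch 1 (the stimulus or cue
#'   language, emitted with reliability `1 - cue_noise`) and the target
#'   (spoken) language at epoch 2.
#' * `audition` is `"N/A"` during picture naming at epoch 1; otherwise the
#'   word of the heard language and concept at epoch 1 and of the target
#'   language and concept at epoch 2. A fraction `word_confusability` of the
#'   probability mass sits on the translation-equivalent word (the confusable
#'   alternative in a bilingual lexicon).
#' * `visual` shows the picture of the concept during naming at epoch 1 and
#'   `"N/A"` otherwise.
#' * `feedback` is neutral at epoch 1 regardless of languages; at epoch 2 it
#'   is positive when heard and target language match for naming or
#'   repetition, positive when they differ for translation, and negative
#'   otherwise, emitted with reliability `1 - feedback_noise` (the remaining
#'   mass split over the two other levels).
#'
#' @param specs output of [task_specs()].
#' @param vocabulary vocabulary table.
#' @param cue_noise,word_confusability,feedback_noise likelihood reliability
#'   parameters in `[0, 0.5)`.
#' @return named list of likelihood arrays (not yet floored; flooring happens
#'   in [generative_model()]).
#' @export
build_likelihood <- function(specs, vocabulary = default_vocabulary(),
                             cue_noise = 0.3, word_confusability = 0.25,
                             feedback_noise = 0.25) {
  vocabulary <- .check_vocabulary(vocabulary)
  for (p in c(cue_noise, word_confusability, feedback_noise))
    if (!is.numeric(p) || p < 0 || p >= 0.5)
      .stopf("likelihood noise parameters must lie in [0, 0.5)")
  nf <- lengths(specs$factors)
  nm <- lengths(specs$modalities)
  na_aud <- nm[["audition"]]
  na_vis <- nm[["visual"]]
  # word level index for (language, concept): levels interleave L2/L1 per
  # concept, so concept k occupies levels 2k-1 (L2) and 2k (L1)
  word_level <- function(lang, k) if (lang == 2L) 2L * k - 1L else 2L * k

  A <- list(
    task = array(0, dim = c(nm[["task"]], nf)),
    language = array(0, dim = c(nm[["language"]], nf)),
    audition = array(0, dim = c(na_aud, nf)),
    visual = array(0, dim = c(na_vis, nf)),
    feedback = array(0, dim = c(nm[["feedback"]], nf)))

  for (cx in 1:3) for (h in 1:2) for (t in 1:2) for (k in 1:12)
    for (e in 1:2) {
      A$task[cx, cx, h, t, k, e] <- 1

      if (e == 1L) {
        A$language[h, cx, h, t, k, e] <- 1 - cue_noise
        A$language[.other_lang(h), cx, h, t, k, e] <- cue_noise
      } else {
        A$language[t, cx, h, t, k, e] <- 1
      }

      if (e == 1L && cx == 1L) {
        A$audition[na_aud, cx, h, t, k, e] <- 1
      } else {
        lang <- if (e == 1L) h else t
        A$audition[word_level(lang, k), cx, h, t, k, e] <-
          1 - word_confusability
        A$audition[word_level(.other_lang(lang), k), cx, h, t, k, e] <-
          word_confusability
      }

      if (e == 1L && cx == 1L) {
        A$visual[k, cx, h, t, k, e] <- 1
      } else {
        A$visual[na_vis, cx, h, t, k, e] <- 1
      }

      if (e == 1L) {
        A$feedback[1L, cx, h, t, k, e] <- 1
      } else {
        lev <- if (.feedback_positive(cx, h, t)) 2L else 3L
        A$feedback[lev, cx, h, t, k, e] <- 1 - feedback_noise
        A$feedback[setdiff(1:3, lev), cx, h, t, k, e] <- feedback_noise / 2
      }
    }
  A
}

#' Build the per-factor transition tensors
#'
#' Context, heard language and concept are identity (they persist through the
#' trial). The target-language factor has two actions, "speak L1" and
#' "speak L2", each mapping every previous state to the chosen language. The
#' epoch factor moves from 1 to 2, with 2 absorbing.
#'
#' @param specs output of [task_specs()].
#' @return named list of transition arrays `[next, previous, action]`.
#' @export
build_transitions <- function(specs) {
  nf <- lengths(specs$factors)
  idmat <- function(n) array(diag(n), dim = c(n, n, 1L))
  target <- array(0, dim = c(2L, 2L, 2L))
  target[1L, , 1L] <- 1  # speak L1, regardless of previous target
  target[2L, , 2L] <- 1  # speak L2
  epoch <- array(0, dim = c(2L, 2L, 1L))
  epoch[2L, 1L, 1L] <- 1  # 1 -> 2
  epoch[2L, 2L, 1L] <- 1  # 2 absorbing
  list(context = idmat(nf[["context"]]),
       heard = idmat(nf[["heard"]]),
       target = target,
       concept = idmat(nf[["concept"]]),
       epoch = epoch)
}

#' Build initial priors and outcome preferences
#'
#' The agent starts each trial knowing only that it is at epoch 1; beliefs
#' about context, languages and concept are uniform (the environment, not the
#' prior, fixes the true trial states). Preferences are non-zero only for the
#' feedback modality.
#'
#' @param specs output of [task_specs()].
#' @param preferences numeric length-3 vector of log-preferences over
#'   (neutral, positive, negative) feedback, in nats.
#' @return list with `D` (priors) and `C` (log-preferences).
#' @export
build_priors_and_preferences <- function(specs,
                                         preferences = c(0, 3, -6)) {
  if (length(preferences) != 3L)
    .stopf("feedback preferences must have length 3")
  D <- lapply(specs$factors, function(lv) rep(1 / length(lv), length(lv)))
  D$epoch <- c(1, 0)
  C <- lapply(specs$modalities, function(lv) rep(0, length(lv)))
  C$feedback <- as.numeric(preferences)
  list(D = D, C = C)
}

#' Build the policy set
#'
#' Exactly two one-step policies, "speak L1" and "speak L2", each selecting
#' one action on the target-language factor and the single implicit action on
#' every other factor.
#'
#' @param specs output of [task_specs()].
#' @return integer policy matrix (policies x factors).
#' @export
build_policies <- function(specs) {
  p <- matrix(1L, nrow = 2L, ncol = length(specs$factors),
              dimnames = list(c("speak_L1", "speak_L2"),
                              names(specs$factors)))
  p["speak_L2", "target"] <- 2L
  p
}

#' Assemble the full bilingual task model
#'
#' Convenience constructor gluing together [task_specs()],
#' [build_likelihood()], [build_transitions()],
#' [build_priors_and_preferences()] and [build_policies()] into a validated
#' [generative_model()]. The vocabulary and noise parameters are attached as
#' attributes for use by the environment and the lesion machinery.
#'
#' @param vocabulary vocabulary table.
#' @param cue_noise,word_confusability,feedback_noise likelihood reliability
#'   parameters (see [build_likelihood()]).
#' @param preferences feedback log-preferences
#'   (see [build_priors_and_preferences()]).
#' @param floor probability floor.
#' @return an `aphasim_model` with attribute `task` carrying the task
#'   metadata.
#' @export
build_task_model <- function(vocabulary = default_vocabulary(),
                             cue_noise = 0.3, word_confusability = 0.25,
                             feedback_noise = 0.25,
                             preferences = c(0, 3, -6), floor = 1e-8) {
  vocabulary <- .check_vocabulary(vocabulary)
  specs <- task_specs(vocabulary)
  A <- build_likelihood(specs, vocabulary, cue_noise, word_confusability,
                        feedback_noise)
  B <- build_transitions(specs)
  pc <- build_priors_and_preferences(specs, preferences)
  pol <- build_policies(specs)
  m <- generative_model(specs$factors, specs$modalities, A, B,
                        pc$D, pc$C, pol, horizon = 2L, floor = floor)
  attr(m, "task") <- list(vocabulary = vocabulary, cue_noise = cue_noise,
                          word_confusability = word_confusability,
                          feedback_noise = feedback_noise,
                          preferences = preferences)
  m
}
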