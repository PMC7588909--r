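# a small, fast study shared by several tests: 2 days, 2 items per block
small_study <- run_study(TASK_MODEL, make_schedule(), days = 2,
                         base_seed = 7L, items_per_block = 2L)

test_that("a trial spans exactly two epochs and records a consistent outcome", {
  rec <- run_trial(TASK_MODEL, trial_setup("repetition", "L1", "man"))
  expect_identical(ncol(rec$observations), 2L)
  expect_false(anyNA(rec$observations))
  expect_identical(rec$correct, rec$feedback == "positive")
  expect_true(rec$converged)
  for (f in names(TASK_MODEL$factors)) for (tau in 1:2) {
    expect_equal(sum(rec$beliefs_epoch1[[f]][, tau]), 1, tolerance = 1e-8)
    expect_equal(sum(rec$beliefs_final[[f]][, tau]), 1, tolerance = 1e-8)
  }
})

test_that("an omega = 1 lesion leaves the trial record identical", {
  m1 <- lesion_model(TASK_MODEL, intact_schedule(1), 1)
  s <- trial_setup("translation", "L2", "parrot")
  expect_identical(run_trial(TASK_MODEL, s), run_trial(m1, s))
})

test_that("a day runs 6 blocks x items trials with reproducible item draws", {
  d1 <- run_day(TASK_MODEL, intact_schedule(1), 1, seed = 99L,
                keep_records = TRUE)
  expect_identical(length(d1$records), 30L)
  expect_identical(sum(d1$scores$n), 30L)
  expect_identical(nrow(d1$scores), 6L)
  d2 <- run_day(TASK_MODEL, intact_schedule(1), 1, seed = 99L,
                keep_records = TRUE)
  items1 <- vapply(d1$records, function(r) r$setup$concept, character(1))
  items2 <- vapply(d2$records, function(r) r$setup$concept, character(1))
  expect_identical(items1, items2)
  d3 <- run_day(TASK_MODEL, intact_schedule(1), 1, seed = 100L,
                keep_records = TRUE)
  items3 <- vapply(d3$records, function(r) r$setup$concept, character(1))
  expect_false(identical(items1, items3))
  # within a block, items are drawn without replacement
  for (b in 1:6)
    expect_false(anyDuplicated(items1[(b - 1) * 5 + 1:5]) > 0)
  expect_error(run_day(TASK_MODEL, intact_schedule(1), 1, 1L,
                       items_per_block = 13L), "12")
})

test_that("the intact subject stays at ceiling across many seeds", {
  for (seed in 1:20) {
    d <- run_day(TASK_MODEL, intact_schedule(1), 1, seed = seed,
                 items_per_block = 1L, keep_records = FALSE)
    expect_identical(sum(d$scores$correct), sum(d$scores$n))
  }
})

test_that("studies use matched seeds and score into per-cell counts", {
  sc <- score_study(small_study)
  expect_identical(nrow(sc), 2L * 2L * 6L)  # subjects x days x blocks
  expect_true(all(sc$correct >= 0 & sc$correct <= sc$n))
  expect_equal(unname(attr(sc, "percent")[["control"]]), 100)
  # item sequences identical across subjects trial-for-trial
  ic <- vapply(small_study$control$records, function(r) r$setup$concept,
               character(1))
  il <- vapply(small_study$lesioned$records, function(r) r$setup$concept,
               character(1))
  expect_identical(ic, il)
  # zero days gives empty results
  empty <- run_study(TASK_MODEL, make_schedule(), days = 0, base_seed = 1L)
  expect_identical(nrow(score_study(empty)), 0L)
})

test_that("an all-intact 'lesioned' subject reproduces control trial-for-trial", {
  st <- run_study(TASK_MODEL, intact_schedule(2), days = 2, base_seed = 11L,
                  items_per_block = 2L)
  expect_identical(st$control$scores, st$lesioned$scores)
  for (i in seq_along(st$control$records))
    expect_identical(st$control$records[[i]]$observations,
                     st$lesioned$records[[i]]$observations)
})

test_that("score_study counts hand-built records correctly", {
  fake <- list(subject = "control",
               scores = data.frame(day = 1L, block = 1L, context = "naming",
                                   stimulus_language = "L1", correct = 3L,
                                   n = 5L),
               records = list(), seeds = 1L)
  sc <- score_study(fake)
  expect_identical(sc$correct, 3L)
  expect_equal(unname(attr(sc, "percent")), 60)
  empty <- score_study(list(subject = "x", scores = NULL))
  expect_identical(nrow(empty), 0L)
})

# helper: build a full-study score table from a per-day cell matrix
profile_scores <- function(days) {
  rows <- list()
  for (d in seq_along(days)) {
    cells <- days[[d]]
    rows[[d]] <- data.frame(
      day = d, block = 1:6,
      context = c("naming", "repetition", "translation",
                  "naming", "repetition", "translation"),
      stimulus_language = c("L1", "L1", "L1", "L2", "L2", "L2"),
      correct = as.integer(cells), n = 5L)
  }
  do.call(rbind, rows)
}

test_that("the classifier recognises the alternate-antagonism pattern", {
  # cells per day: naming L1, rep L1, trans from L1, naming L2, rep L2,
  # trans from L2. Day 1 mirrors the lesioned day-3 profile, day 2 its
  # alternate; day 3 fully recovered.
  prof <- profile_scores(list(c(0, 5, 0, 5, 5, 5),
                              c(5, 5, 5, 0, 5, 0),
                              c(5, 5, 5, 5, 5, 5)))
  rep <- classify_pattern(prof)
  expect_true(rep$alternate_antagonism)
  expect_true(rep$paradoxical_translation)
  expect_identical(rep$per_day$accessible, c("L2", "L1", "both"))
  expect_identical(rep$paradox_days, c(1L, 2L))

  # control profile: everything at ceiling, both flags false
  ctrl <- profile_scores(replicate(3, rep(5, 6), simplify = FALSE))
  crep <- classify_pattern(ctrl)
  expect_false(crep$alternate_antagonism)
  expect_false(crep$paradoxical_translation)

  # a single deficient language on all days: no switch, no antagonism
  stuck <- profile_scores(replicate(3, c(0, 5, 5, 5, 5, 5),
                                    simplify = FALSE))
  srep <- classify_pattern(stuck)
  expect_false(srep$alternate_antagonism)

  expect_error(classify_pattern(prof, able = 1, unable = 4), "inconsistent")
})

test_that("belief traces reflect the stimulus and the planned response", {
  rec <- run_trial(TASK_MODEL, trial_setup("repetition", "L1", "man"))
  tr <- export_belief_traces(list(rec))
  expect_true(all(c("factor", "state", "updated_at_epoch", "about_epoch",
                    "probability") %in% names(tr)))
  # heard language reveals itself during epoch 1
  h <- tr[tr$factor == "heard" & tr$updated_at_epoch == 1 &
            tr$about_epoch == 1, ]
  expect_gt(h$probability[h$state == "L1"], 0.85)
  # empty selection gives an empty table
  expect_identical(nrow(export_belief_traces(list(rec), integer(0))), 0L)
})

test_that("a lesioned naming trial plans the wrong language at epoch 1", {
  m3 <- lesion_model(TASK_MODEL, DEFAULT_SCHEDULE, 3)  # affected L1
  rec <- run_trial(m3, trial_setup("naming", "L1", "man"))
  expect_identical(rec$action, "L2")
  tr <- export_belief_traces(list(rec))
  tgt <- tr[tr$factor == "target" & tr$updated_at_epoch == 1 &
              tr$about_epoch == 2, ]
  expect_gt(tgt$probability[tgt$state == "L2"],
            tgt$probability[tgt$state == "L1"])
})
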