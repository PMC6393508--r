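test_that("MFT simulator emits the factorial session layout", {
  set.seed(50)
  tr <- simulate_mft_subject("s1", 3.82, 0.99)
  expect_equal(nrow(tr), 432L)
  expect_equal(length(unique(tr$block)), 12L)
  # one exposure time per block, three blocks per exposure time
  per_block <- unique(tr[, c("block", "exposure_time_ms")])
  expect_equal(nrow(per_block), 12L)
  expect_equal(as.integer(table(per_block$exposure_time_ms)), rep(3L, 4))
  # 36 trials per congruency-by-exposure cell
  cells <- aggregate_mft_cells(tr)
  expect_equal(nrow(cells), 12L)
  expect_true(all(cells$n_trials == 36L))
})

test_that("MFT simulator approaches its limiting accuracies", {
  set.seed(51)
  high <- simulate_mft_subject("s", 12, 0.99, trials_per_cell = 600L)
  cells <- aggregate_mft_cells(high)
  inc <- cells[cells$minority_count > 0, ]
  expect_true(all(inc$n_correct / inc$n_trials > 0.95))
  low <- simulate_mft_subject("s", 0.01, 0.99, trials_per_cell = 600L)
  lc <- aggregate_mft_cells(low)
  hard <- lc[lc$minority_count == 2 & lc$exposure_time == 0.25, ]
  expect_lt(abs(hard$n_correct / hard$n_trials - 0.5), 0.07)
})

test_that("flanker simulator produces 288 trials with the conflict cost", {
  set.seed(52)
  tr <- simulate_ant_subject("s1", conflict_shift_ms = 144)
  expect_equal(nrow(tr), 288L)
  expect_setequal(unique(tr$cue), c("none", "double", "valid", "invalid"))
  big <- do.call(rbind, lapply(1:30, function(i)
    simulate_ant_subject("s", 144)))
  expect_equal(conflict_effect(big), -144, tolerance = 0.05)
  zero <- do.call(rbind, lapply(1:30, function(i)
    simulate_ant_subject("s", 0)))
  expect_lt(abs(conflict_effect(zero)), 5)
})

test_that("N-back simulator uses the battery trial counts", {
  set.seed(53)
  nb <- simulate_nback_subject("s1")
  expect_equal(sum(nb$n_trials[nb$task == "spatial"]), 240L)
  expect_equal(unique(nb$n_trials[nb$task == "verbal"]), 18L)
  # degenerate truth: index collapses to ceiling difference
  perfect <- simulate_nback_subject(
    "s", spatial_acc = c(`0` = 1, `1` = 1, `2` = 1))
  acc <- setNames(perfect$accuracy[perfect$task == "spatial"],
                  perfect$level[perfect$task == "spatial"])
  expect_equal(nback_index(acc, "spatial"), 0)
  # accuracies recovered within binomial error
  reps <- do.call(rbind, lapply(1:200, function(i) simulate_nback_subject("s")))
  sp2 <- reps[reps$task == "spatial" & reps$level == 2, "accuracy"]
  expect_lt(abs(mean(sp2) - 0.51), 3 * sqrt(0.51 * 0.49 / (200 * 80)))
})

test_that("span simulator matches its closed-form ANL expectation", {
  set.seed(54)
  reps <- do.call(rbind, lapply(1:300, function(i)
    simulate_span_subject("s")))
  for (task in c("ospan", "rotspan", "symspan")) {
    strength <- c(ospan = 2.9, rotspan = 2.6, symspan = 1.9)[[task]]
    observed <- mean(vapply(split(reps[reps$task == task, ],
                                  rep(1:300, each = length(
                                    cogcap:::span_designs[[task]]))),
                            anl_score, numeric(1)))
    expect_lt(abs(observed - expected_anl(strength, task)), 0.04)
  }
  # degenerate strengths
  perfect <- simulate_span_subject("s", strength = c(ospan = 50, rotspan = 50,
                                                     symspan = 50))
  expect_equal(anl_score(perfect[perfect$task == "ospan", ]), 1)
  hopeless <- simulate_span_subject("s", strength = c(ospan = -50,
                                                      rotspan = -50,
                                                      symspan = -50))
  expect_equal(anl_score(hopeless[hopeless$task == "symspan", ]), 0)
})

test_that("cohort simulation is reproducible and carries the design counts", {
  cfg <- default_population(n_subjects = 6L, seed = 99L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$mft_trials), 6L * 432L)
  expect_equal(nrow(a$ant_trials), 6L * 288L)
  expect_equal(nrow(a$truth), 6L)
  bad <- cfg
  bad$latent_cor <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(simulate_cohort(bad), "positive semidefinite")
})

test_that("true capacities correlate with the working-memory factor", {
  co <- simulate_cohort(default_population(n_subjects = 200L, seed = 7L))
  # attenuated target: loading(ccc) * cor(CC, WM)
  target <- 0.80 * 0.96
  observed <- cor(co$truth$ccc_true, co$truth$wm)
  expect_lt(abs(observed - target), 0.12)
})

test_that("cohort tables round-trip through the CSV writers and readers", {
  co <- simulate_cohort(default_population(n_subjects = 3L, seed = 15L))
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("mft_trials.csv", "ant_trials.csv", "nback_summary.csv",
           "span_trials.csv", "composites.csv", "truth.csv",
           "config.json")))))
  back <- read_cohort(dir)
  for (tb in c("mft_trials", "ant_trials", "nback_summary", "span_trials",
               "composites", "truth")) {
    expect_equal(back[[tb]], co[[tb]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # and the read-back tables score identically
  m1 <- score_battery(co$mft_trials, co$ant_trials, co$nback_summary,
                      co$span_trials, co$composites)
  m2 <- score_battery(back$mft_trials, back$ant_trials, back$nback_summary,
                      back$span_trials, back$composites)
  expect_equal(m1, m2, tolerance = 1e-10)
})

test_that("injected exclusion violators are flagged by the filter", {
  viol <- data.frame(
    subject_index = 1:5,
    rule = c("mft_valid_responses", "ant_accuracy", "nback0_accuracy",
             "span_distractor_accuracy", "us_education"))
  cfg <- default_population(n_subjects = 12L, seed = 21L)
  # margins wide enough that no clean subject trips a rule by chance
  cfg$nback0_verbal <- 0.999
  cfg$span_distractor_acc <- 0.999
  co <- simulate_cohort(cfg, exclusion_violators = viol)
  fields <- exclusion_fields(co$mft_trials, co$ant_trials, co$nback_summary,
                             co$span_trials, co$composites)
  res <- apply_exclusion_criteria(fields)
  expect_setequal(setdiff(fields$subject_id, res$kept$subject_id),
                  sprintf("S%03d", 1:5))
  expect_equal(nrow(res$kept), 7L)
})
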