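#' Simulate one subject's masked majority-function task session
#'
#' Generates trial-level data under the grouping-search capacity model.
#' On each trial the search terminates voluntarily with probability
#' \eqn{1 - (1 - P_{group})^{2^C ET / N_{maj}}} (the same real-valued
#' attempt exponent as the closed-form accuracy equation); a voluntarily
#' terminated trial is correct with probability \code{p0}, a forced
#' termination is a guess correct with probability \code{p_guess}. An
#' integer-attempt mode (\code{floor} of the exponent, attempts drawn as
#' independent group samples) is available for brute-force cross-checks.
#' The default session is 12 blocks of 36 trials (one exposure time per
#' block, three blocks per exposure time, 12 trials per congruency per
#' block): 432 trials.
#'
#' @param subject_id Subject identifier.
#' @param capacity True capacity C in bits per second.
#' @param p0 True baseline accuracy.
#' @param design Design grid from \code{\link{mft_design}}.
#' @param trials_per_cell Trials per congruency-by-exposure cell
#'   (default 36).
#' @param p_guess Guessing accuracy.
#' @param valid_prop Probability that a trial receives a response
#'   (default 1; lower it to exercise the exclusion filter).
#' @param integer_attempts Use floor(2^C ET / N_maj) independent group
#'   draws instead of the real-valued exponent.
#' @return Data.frame of trials: \code{subject_id}, \code{block},
#'   \code{majority_count}, \code{minority_count}, \code{exposure_time_ms},
#'   \code{responded}, \code{correct}, \code{rt_ms} (NA; response times
#'   are not modelled).
#' @export
simulate_mft_subject <- function(subject_id, capacity, p0,
                                 design = mft_design(),
                                 trials_per_cell = 36L, p_guess = 0.5,
                                 valid_prop = 1, integer_attempts = FALSE) {
  ets <- sort(unique(design$exposure_time))
  blocks_per_et <- 3L
  per_block <- trials_per_cell / blocks_per_et
  rows <- list()
  block <- 0L
  for (et in ets) {
    cells <- design[design$exposure_time == et, , drop = FALSE]
    for (b in seq_len(blocks_per_et)) {
      block <- block + 1L
      for (i in seq_len(nrow(cells))) {
        cell <- cells[i, ]
        k <- 2^capacity * et / cell$group_size
        p_vt <- if (integer_attempts) {
          1 - (1 - cell$p_group)^floor(k)
        } else {
          1 - (1 - cell$p_group)^k
        }
        nt <- as.integer(per_block)
        vt <- stats::rbinom(nt, 1L, p_vt) == 1L
        correct <- ifelse(vt, stats::rbinom(nt, 1L, p0),
                          stats::rbinom(nt, 1L, p_guess)) == 1L
        responded <- stats::rbinom(nt, 1L, valid_prop) == 1L
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subject_id, block = block,
          majority_count = cell$majority_count,
          minority_count = cell$minority_count,
          exposure_time_ms = et * 1000,
          responded = responded,
          correct = correct & responded,
          rt_ms = NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate one subject's flanker (attention network) session
#'
#' Plumbing generator (no cognitive-process realism): response times are
#' drawn from a normal distribution truncated below at 100 ms, incongruent
#' trials shifted by the subject's conflict amount; accuracy is near
#' ceiling with a configurable lapse rate. Four cue conditions crossed
#' with two congruencies over 4 blocks of 72 trials: 288 trials.
#'
#' @param subject_id Subject identifier.
#' @param conflict_shift_ms True RT cost of incongruent flankers (ms).
#' @param base_rt_ms,rt_sd_ms Mean and SD of the congruent RT
#'   distribution (ms).
#' @param lapse Error probability per trial.
#' @param n_blocks,trials_per_block Session layout (defaults 4 x 72).
#' @return Data.frame: \code{subject_id}, \code{block}, \code{cue},
#'   \code{congruency}, \code{correct}, \code{rt_ms}.
#' @export
simulate_ant_subject <- function(subject_id, conflict_shift_ms,
                                 base_rt_ms = 520, rt_sd_ms = 60,
                                 lapse = 0.02, n_blocks = 4L,
                                 trials_per_block = 72L) {
  n <- n_blocks * trials_per_block
  cue <- rep(c("none", "double", "valid", "invalid"), length.out = n)
  congruency <- rep(rep(c("congruent", "incongruent"), each = 4L),
                    length.out = n)
  shift <- ifelse(congruency == "incongruent", conflict_shift_ms, 0)
  rt <- pmax(100, stats::rnorm(n, base_rt_ms + shift, rt_sd_ms))
  data.frame(subject_id = subject_id,
             block = rep(seq_len(n_blocks), each = trials_per_block),
             cue = cue, congruency = congruency,
             correct = stats::rbinom(n, 1L, 1 - lapse) == 1L,
             rt_ms = rt)
}

#' Simulate one subject's N-back accuracies
#'
#' Binomial draws per load level with the battery's trial counts: 80
#' trials per level for the spatial task (12 blocks of 20, four per
#' level over levels 0-2, 240 trials in total) and 18 per level for the
#' verbal task (one 18-letter block per level over levels 0-3).
#'
#' @param subject_id Subject identifier.
#' @param spatial_acc Named true accuracies for levels "0", "1", "2".
#' @param verbal_acc Named true accuracies for levels "0" to "3".
#' @return Long data.frame: \code{subject_id}, \code{task}, \code{level},
#'   \code{accuracy}, \code{n_trials}.
#' @export
simulate_nback_subject <- function(subject_id,
                                   spatial_acc = c(`0` = 0.99, `1` = 0.76,
                                                   `2` = 0.51),
                                   verbal_acc = c(`0` = 0.95, `1` = 0.91,
                                                  `2` = 0.90, `3` = 0.87)) {
  one <- function(task, acc, n_per_level) {
    lv <- as.integer(names(acc))
    obs <- stats::rbinom(length(acc), n_per_level, acc) / n_per_level
    data.frame(subject_id = subject_id, task = task, level = lv,
               accuracy = obs, n_trials = n_per_level)
  }
  rbind(one("spatial", spatial_acc, 80L), one("verbal", verbal_acc, 18L))
}

span_designs <- list(
  ospan = c(2, 3, 4, 5, 6, 7, 3, 4, 5, 6),
  rotspan = c(3, 4, 5, 6, 7, 4, 5, 6),
  symspan = rep(2:5, 2)
)

#' Simulate one subject's complex-span sessions
#'
#' Per-element recall probability follows a logistic in set size,
#' \eqn{q(s) = logit^{-1}(strength - slope (s - 2))}; a trial is fully
#' recalled in order with probability \eqn{q(s)^s}. Distractor accuracy is
#' near ceiling and configurable so the 85% exclusion rule can be
#' exercised. Set-size lists: OSpan 10 trials over sizes 2-7, RotSpan 8
#' trials over 3-7, SymSpan 8 trials over 2-5.
#'
#' @param subject_id Subject identifier.
#' @param strength Named recall-strength intercepts for \code{ospan},
#'   \code{rotspan}, \code{symspan} (logit units).
#' @param slope Set-size slope in logit units.
#' @param distractor_acc True distractor-task accuracy.
#' @return Data.frame: \code{subject_id}, \code{task}, \code{set_size},
#'   \code{fully_correct}, \code{distractor_correct},
#'   \code{distractor_total}.
#' @export
simulate_span_subject <- function(subject_id,
                                  strength = c(ospan = 2.9, rotspan = 2.6,
                                               symspan = 1.9),
                                  slope = 0.25, distractor_acc = 0.95) {
  rows <- lapply(names(span_designs), function(task) {
    sizes <- span_designs[[task]]
    q <- stats::plogis(strength[[task]] - slope * (sizes - 2))
    data.frame(subject_id = subject_id, task = task, set_size = sizes,
               fully_correct = stats::rbinom(length(sizes), 1L, q^sizes) == 1L,
               distractor_correct = stats::rbinom(length(sizes), sizes,
                                                  distractor_acc),
               distractor_total = sizes)
  })
  do.call(rbind, rows)
}

#' Expected ANL score of the span generator
#'
#' Closed-form expectation \eqn{\sum_i s_i q(s_i)^{s_i} / \sum_i s_i}
#' for a given strength, used as the oracle for the span generator.
#'
#' @inheritParams simulate_span_subject
#' @param task One of \code{"ospan"}, \code{"rotspan"}, \code{"symspan"}.
#' @param strength Scalar strength intercept.
#' @return Expected ANL score.
#' @export
expected_anl <- function(strength, task, slope = 0.25) {
  sizes <- span_designs[[task]]
  q <- stats::plogis(strength - slope * (sizes - 2))
  sum(sizes * q^sizes) / sum(sizes)
}

#' Default population configuration for the cohort simulator
#'
#' The population model mirrors the study's conditions: latent factors
#' (IQ, CC, WM) with correlations 0.84 (IQ-CC), 0.87 (IQ-WM) and 0.96
#' (CC-WM); each measure loads on one factor and its true task parameter
#' is mapped from the measure-level latent score onto the scale of the
#' observed summary statistics (capacity around 3.82 +/- 0.62 bps,
#' conflict cost around 144 +/- 42 ms, and so on). Composite scores are
#' emitted on the IQ metric (mean 100, SD 15).
#'
#' @param n_subjects Cohort size (default 88, the analyzed sample size).
#' @param seed Global seed; per-task substreams are derived from it.
#' @param latent_cor 3x3 latent correlation matrix for (IQ, CC, WM).
#' @param loading_map Data.frame \code{measure}, \code{factor},
#'   \code{loading}; unique variance is \code{1 - loading^2}.
#' @return Configuration list for \code{\link{simulate_cohort}}.
#' @export
default_population <- function(n_subjects = 88L, seed = 1L,
                               latent_cor = NULL, loading_map = NULL) {
  if (is.null(latent_cor)) {
    latent_cor <- matrix(c(1, 0.84, 0.87,
                           0.84, 1, 0.96,
                           0.87, 0.96, 1), 3, 3,
                         dimnames = list(c("IQ", "CC", "WM"),
                                         c("IQ", "CC", "WM")))
  }
  if (is.null(loading_map)) {
    loading_map <- data.frame(
      measure = c("fsiq", "vci", "pri", "wmi", "psi",
                  "ccc", "ec",
                  "spatial_nback", "verbal_nback", "ospan", "rotspan",
                  "symspan"),
      factor = c(rep("IQ", 5), rep("CC", 2), rep("WM", 5)),
      loading = c(0.95, 0.55, 0.75, 0.60, 0.55,
                  0.80, 0.45,
                  0.50, 0.25, 0.65, 0.60, 0.70))
  }
  list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
       latent_cor = latent_cor, loading_map = loading_map,
       p0 = 0.99, ccc_mean = 3.82, ccc_sd = 0.62, ccc_range = c(0.5, 8),
       conflict_mean = 144.06, conflict_sd = 41.65,
       conflict_range = c(20, 400),
       education_years = 16,
       nback0_spatial = 0.99, nback0_verbal = 0.95,
       span_distractor_acc = 0.95,
       mft_trials_per_cell = 36L,
       span_slope = 0.25,
       span_strength_mean = c(ospan = 2.9, rotspan = 2.6, symspan = 1.9),
       span_strength_sd = 1.0)
}

#' Simulate a full cohort across the battery
#'
#' Draws per-subject latent scores from the configured factor correlation
#' matrix, maps them to true task parameters, and generates trial-level
#' data for every task plus the composite-score table. Fully reproducible
#' from the configuration seed; each task stage uses its own derived
#' substream so adding a stage does not perturb the others.
#'
#' @param config Configuration from \code{\link{default_population}}.
#' @param exclusion_violators Optional data.frame \code{subject_index},
#'   \code{rule} injecting known violations of the exclusion criteria
#'   (rules: \code{mft_valid_responses}, \code{ant_accuracy},
#'   \code{nback0_accuracy}, \code{span_distractor_accuracy},
#'   \code{us_education}).
#' @return List with \code{mft_trials}, \code{ant_trials},
#'   \code{nback_summary}, \code{span_trials}, \code{composites},
#'   \code{truth} (per-subject latent scores and true parameters) and
#'   \code{config}.
#' @export
simulate_cohort <- function(config = default_population(),
                            exclusion_violators = NULL) {
  ev <- eigen(config$latent_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("latent_cor must be positive semidefinite", call. = FALSE)
  }
  n <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  lm <- config$loading_map

  set.seed(substream_seed(config$seed, 1L))
  Z <- matrix(stats::rnorm(n * 3), n, 3) %*%
    chol((config$latent_cor + t(config$latent_cor)) / 2)
  colnames(Z) <- colnames(config$latent_cor)
  meas_latent <- sapply(seq_len(nrow(lm)), function(i) {
    lam <- lm$loading[i]
    lam * Z[, lm$factor[i]] + sqrt(1 - lam^2) * stats::rnorm(n)
  })
  colnames(meas_latent) <- lm$measure

  violated <- function(rule) {
    idx <- integer(0)
    if (!is.null(exclusion_violators)) {
      idx <- exclusion_violators$subject_index[exclusion_violators$rule == rule]
    }
    seq_len(n) %in% idx
  }

  truth <- data.frame(
    subject_id = ids,
    iq = Z[, "IQ"], cc = Z[, "CC"], wm = Z[, "WM"],
    ccc_true = clamp(config$ccc_mean + config$ccc_sd * meas_latent[, "ccc"],
                     config$ccc_range[1], config$ccc_range[2]),
    p0_true = config$p0,
    conflict_shift_true = clamp(
      config$conflict_mean - config$conflict_sd * meas_latent[, "ec"],
      config$conflict_range[1], config$conflict_range[2]),
    spatial2_true = clamp(0.51 + 0.22 * meas_latent[, "spatial_nback"],
                          0.05, 0.995),
    verbal3_true = clamp(0.87 + 0.12 * meas_latent[, "verbal_nback"],
                         0.05, 0.995),
    ospan_strength = config$span_strength_mean[["ospan"]] +
      config$span_strength_sd * meas_latent[, "ospan"],
    rotspan_strength = config$span_strength_mean[["rotspan"]] +
      config$span_strength_sd * meas_latent[, "rotspan"],
    symspan_strength = config$span_strength_mean[["symspan"]] +
      config$span_strength_sd * meas_latent[, "symspan"],
    education_years = ifelse(violated("us_education"), 12,
                             config$education_years)
  )

  set.seed(substream_seed(config$seed, 2L))
  mft <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_mft_subject(
      ids[i], truth$ccc_true[i], truth$p0_true[i],
      trials_per_cell = config$mft_trials_per_cell,
      valid_prop = if (violated("mft_valid_responses")[i]) 0.80 else 1)
  }))

  set.seed(substream_seed(config$seed, 3L))
  ant <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_ant_subject(
      ids[i], truth$conflict_shift_true[i],
      lapse = if (violated("ant_accuracy")[i]) 0.25 else 0.02)
  }))

  set.seed(substream_seed(config$seed, 4L))
  nb <- do.call(rbind, lapply(seq_len(n), function(i) {
    sp0 <- if (violated("nback0_accuracy")[i]) 0.70 else config$nback0_spatial
    vb0 <- config$nback0_verbal
    simulate_nback_subject(
      ids[i],
      spatial_acc = c(`0` = sp0,
                      `1` = clamp((sp0 + truth$spatial2_true[i]) / 2 - 0.1,
                                  0.05, 0.995),
                      `2` = truth$spatial2_true[i]),
      verbal_acc = c(`0` = vb0, `1` = 0.91, `2` = 0.90,
                     `3` = truth$verbal3_true[i]))
  }))

  set.seed(substream_seed(config$seed, 5L))
  span <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_span_subject(
      ids[i],
      strength = c(ospan = truth$ospan_strength[i],
                   rotspan = truth$rotspan_strength[i],
                   symspan = truth$symspan_strength[i]),
      slope = config$span_slope,
      distractor_acc = if (violated("span_distractor_accuracy")[i]) 0.70
                       else config$span_distractor_acc)
  }))

  set.seed(substream_seed(config$seed, 6L))
  composites <- data.frame(
    subject_id = ids,
    fsiq = round(100 + 15 * meas_latent[, "fsiq"], 1),
    vci = round(100 + 15 * meas_latent[, "vci"], 1),
    pri = round(100 + 15 * meas_latent[, "pri"], 1),
    wmi = round(100 + 15 * meas_latent[, "wmi"], 1),
    psi = round(100 + 15 * meas_latent[, "psi"], 1),
    education_years = truth$education_years
  )

  list(mft_trials = mft, ant_trials = ant, nback_summary = nb,
       span_trials = span, composites = composites, truth = truth,
       config = config)
}

#' Write / read a simulated cohort as CSV files
#'
#' \code{write_cohort} writes \code{mft_trials.csv}, \code{ant_trials.csv},
#' \code{nback_summary.csv}, \code{span_trials.csv}, \code{composites.csv},
#' \code{truth.csv} and \code{config.json} into a directory;
#' \code{read_cohort} reads them back (the configuration echo is returned
#' as parsed JSON, not rebuilt into matrices).
#'
#' @param cohort A cohort list from \code{\link{simulate_cohort}}.
#' @param dir Target directory (created if missing).
#' @return \code{write_cohort}: the directory, invisibly.
#'   \code{read_cohort}: a cohort-shaped list of data.frames.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("mft_trials", "ant_trials", "nback_summary", "span_trials",
              "composites", "truth")
  for (tb in tables) {
    utils::write.csv(cohort[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  cfg <- cohort$config
  cfg$latent_cor <- as.data.frame(cfg$latent_cor)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  schemas <- list(mft_trials = c(rt_ms = "numeric"))
  rd <- function(tb) {
    utils::read.csv(file.path(dir, paste0(tb, ".csv")),
                    colClasses = schemas[[tb]] %||% NA)
  }
  out <- list(mft_trials = rd("mft_trials"), ant_trials = rd("ant_trials"),
              nback_summary = rd("nback_summary"),
              span_trials = rd("span_trials"),
              composites = rd("composites"), truth = rd("truth"))
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) out$config <- jsonlite::fromJSON(cfg_path)
  out
}
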