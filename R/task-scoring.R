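#' Remove error and outlying-RT flanker trials
#'
#' Error trials are dropped first; then, separately within each congruency
#' condition, trials whose response time lies more than 3 SD from that
#' condition's mean RT (mean and SD computed over the condition's correct
#' trials, single pass, no re-trimming) are removed. A condition with fewer
#' than two correct trials passes through untrimmed with a warning.
#'
#' @param trials Data.frame of flanker trials with columns
#'   \code{congruency} ("congruent"/"incongruent"), \code{correct}
#'   (logical or 0/1) and \code{rt_ms}.
#' @param sd_limit Trimming threshold in SD units (default 3).
#' @return List with \code{trials} (surviving trials),
#'   \code{prop_excluded} (proportion of input trials removed, errors and
#'   RT outliers combined), \code{n_error_removed}, \code{n_rt_removed}.
#' @export
trim_rt_trials <- function(trials, sd_limit = 3) {
  stopifnot_cols(trials, c("congruency", "correct", "rt_ms"), "trials")
  if (nrow(trials) == 0L) stop("no trials supplied", call. = FALSE)
  n_in <- nrow(trials)
  ok <- trials[as.logical(trials$correct), , drop = FALSE]
  n_err <- n_in - nrow(ok)
  if (nrow(ok) == 0L) {
    warning("all trials are errors; no trials survive trimming")
    return(list(trials = ok, prop_excluded = 1,
                n_error_removed = n_err, n_rt_removed = 0L))
  }
  keep <- rep(TRUE, nrow(ok))
  for (cond in unique(ok$congruency)) {
    sel <- ok$congruency == cond
    if (sum(sel) < 2L) {
      warning(sprintf("condition '%s' has < 2 correct trials; left untrimmed",
                      cond))
      next
    }
    m <- mean(ok$rt_ms[sel])
    s <- stats::sd(ok$rt_ms[sel])
    if (s > 0) keep[sel] <- abs(ok$rt_ms[sel] - m) <= sd_limit * s
  }
  out <- ok[keep, , drop = FALSE]
  list(trials = out,
       prop_excluded = (n_in - nrow(out)) / n_in,
       n_error_removed = n_err,
       n_rt_removed = sum(!keep))
}

#' Reverse-coded flanker conflict effect
#'
#' Mean RT of congruent trials minus mean RT of incongruent trials, in
#' milliseconds. Because incongruent trials are typically slower the value
#' is typically negative; a less negative conflict effect indicates more
#' efficient executive control. Trials are trimmed with
#' \code{\link{trim_rt_trials}} first unless \code{trim = FALSE}.
#'
#' @param trials Flanker trial data.frame (see \code{\link{trim_rt_trials}}).
#' @param trim Apply error/RT trimming before averaging (default TRUE).
#' @return Conflict effect in milliseconds.
#' @export
conflict_effect <- function(trials, trim = TRUE) {
  if (trim) trials <- trim_rt_trials(trials)$trials
  cong <- trials$rt_ms[trials$congruency == "congruent"]
  inc <- trials$rt_ms[trials$congruency == "incongruent"]
  if (length(cong) == 0L || length(inc) == 0L) {
    stop("both congruent and incongruent trials are required", call. = FALSE)
  }
  mean(cong) - mean(inc)
}

#' N-back performance index
#'
#' Accuracy of the hardest load condition minus accuracy of the 0-back
#' condition: 2-back minus 0-back for the spatial task, 3-back minus
#' 0-back for the verbal task. Since 0-back accuracy is near ceiling the
#' index is expected to be negative; values closer to zero indicate better
#' working-memory updating.
#'
#' @param accuracy_by_level Named numeric vector of per-level accuracies;
#'   names are the load levels ("0", "1", "2", and "3" for verbal).
#' @param task \code{"spatial"} or \code{"verbal"}.
#' @return Accuracy difference in \[-1, 1\].
#' @examples
#' nback_index(c(`0` = 0.99, `1` = 0.76, `2` = 0.51), "spatial")  # -0.48
#' @export
nback_index <- function(accuracy_by_level, task = c("spatial", "verbal")) {
  task <- match.arg(task)
  required <- if (task == "spatial") c("0", "1", "2") else c("0", "1", "2", "3")
  hardest <- if (task == "spatial") "2" else "3"
  lv <- names(accuracy_by_level)
  if (!all(required %in% lv)) {
    stop(sprintf("%s N-back requires accuracy at levels %s", task,
                 paste(required, collapse = ", ")), call. = FALSE)
  }
  if (any(accuracy_by_level < 0 | accuracy_by_level > 1)) {
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  }
  unname(accuracy_by_level[hardest] - accuracy_by_level["0"])
}

#' All-or-nothing-load (ANL) span score
#'
#' A complex-span trial contributes its full set size when every memory
#' element was recalled in the correct serial order, and nothing otherwise;
#' the score is the contributed sum divided by the total number of elements
#' to be recalled, a proportion in \[0, 1\].
#'
#' @param trials Data.frame of span trials with columns \code{set_size}
#'   and \code{fully_correct} (logical or 0/1); if a \code{task} column is
#'   present it must hold a single task.
#' @return ANL score in \[0, 1\].
#' @examples
#' anl_score(data.frame(set_size = c(2, 3, 4),
#'                      fully_correct = c(TRUE, FALSE, TRUE)))  # 6/9
#' @export
anl_score <- function(trials) {
  stopifnot_cols(trials, c("set_size", "fully_correct"), "trials")
  if (nrow(trials) == 0L) stop("no trials supplied", call. = FALSE)
  if ("task" %in% names(trials) && length(unique(trials$task)) > 1L) {
    stop("anl_score expects trials from a single task; got: ",
         paste(unique(trials$task), collapse = ", "), call. = FALSE)
  }
  if (any(trials$set_size < 1)) stop("set_size must be >= 1", call. = FALSE)
  sum(trials$set_size * as.logical(trials$fully_correct)) / sum(trials$set_size)
}

# thresholds are strict: a subject is removed only when strictly BELOW
exclusion_rules <- data.frame(
  rule = c("mft_valid_responses", "ant_accuracy", "nback0_accuracy",
           "span_distractor_accuracy", "us_education"),
  field = c("mft_valid_prop", "ant_accuracy", "nback0_min",
            "distractor_min", "education_years"),
  threshold = c(0.95, 0.90, 0.90, 0.85, 15),
  stringsAsFactors = FALSE
)

#' Apply the participant exclusion criteria
#'
#' Removes subjects who fail any of the battery's performance and
#' background criteria: proportion of valid MFT-M responses below 95%,
#' overall flanker accuracy below 90%, 0-back accuracy in either N-back
#' task below 90%, distractor-task accuracy in any complex-span task below
#' 85%, or fewer than 15 years of US education. All thresholds are strict
#' ("less than"): a subject exactly at a threshold is kept. Removal is the
#' union over rules, so the operation is order-independent and idempotent.
#'
#' @param cohort Data.frame with one row per subject and columns
#'   \code{subject_id}, \code{mft_valid_prop}, \code{ant_accuracy},
#'   \code{nback0_min} (minimum 0-back accuracy over the two N-back tasks),
#'   \code{distractor_min} (minimum distractor accuracy over the three span
#'   tasks) and \code{education_years}.
#' @return List with \code{kept} (the surviving rows) and \code{report}
#'   (one row per violated rule per removed subject: \code{subject_id},
#'   \code{rule}, \code{value}, \code{threshold}).
#' @export
apply_exclusion_criteria <- function(cohort) {
  stopifnot_cols(cohort, c("subject_id", exclusion_rules$field), "cohort")
  for (f in exclusion_rules$field) {
    if (any(is.na(cohort[[f]]))) {
      bad <- cohort$subject_id[is.na(cohort[[f]])]
      stop(sprintf("missing value in criterion field '%s' for subject(s): %s",
                   f, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  reports <- lapply(seq_len(nrow(exclusion_rules)), function(i) {
    r <- exclusion_rules[i, ]
    viol <- cohort[[r$field]] < r$threshold
    data.frame(subject_id = cohort$subject_id[viol],
               rule = rep(r$rule, sum(viol)),
               value = cohort[[r$field]][viol],
               threshold = rep(r$threshold, sum(viol)))
  })
  report <- do.call(rbind, reports)
  kept <- cohort[!cohort$subject_id %in% report$subject_id, , drop = FALSE]
  list(kept = kept, report = report)
}

#' Build per-subject exclusion-criterion fields from raw task data
#'
#' Computes, for each subject, the quantities the exclusion filter tests:
#' proportion of MFT-M trials with a response, overall (pre-trimming)
#' flanker accuracy, minimum 0-back accuracy across N-back tasks, minimum
#' distractor accuracy across span tasks, and years of US education taken
#' from the composite-score table.
#'
#' @param mft_trials,ant_trials,nback_summary,span_trials,composites The
#'   five raw tables (see the package's CSV schemas).
#' @return Data.frame suitable for \code{\link{apply_exclusion_criteria}}.
#' @export
exclusion_fields <- function(mft_trials, ant_trials, nback_summary,
                             span_trials, composites) {
  agg1 <- function(df, value, by = "subject_id", fun = mean) {
    out <- stats::aggregate(df[[value]], list(subject_id = df[[by]]), fun)
    names(out)[2] <- value
    out
  }
  mft <- agg1(transform(mft_trials, responded = as.numeric(responded)),
              "responded")
  names(mft)[2] <- "mft_valid_prop"
  ant <- agg1(transform(ant_trials, correct = as.numeric(correct)), "correct")
  names(ant)[2] <- "ant_accuracy"
  nb0 <- nback_summary[nback_summary$level == 0, , drop = FALSE]
  nb <- stats::aggregate(nb0$accuracy, list(subject_id = nb0$subject_id), min)
  names(nb)[2] <- "nback0_min"
  span_trials$dacc <- span_trials$distractor_correct /
    pmax(span_trials$distractor_total, 1L)
  sp <- stats::aggregate(
    span_trials$dacc,
    list(subject_id = span_trials$subject_id, task = span_trials$task), mean)
  sp <- stats::aggregate(sp$x, list(subject_id = sp$subject_id), min)
  names(sp)[2] <- "distractor_min"
  edu <- composites[, c("subject_id", "education_years")]
  out <- Reduce(function(a, b) merge(a, b, by = "subject_id", all = TRUE),
                list(mft, ant, nb, sp, edu))
  out
}

#' Score the full battery into the per-subject measures table
#'
#' Runs every scorer over the raw task tables and joins the results with
#' the WAIS composite scores into the 12-measure manifest-variable table
#' that feeds the correlation and covariance-structure stages.
#'
#' @inheritParams exclusion_fields
#' @param ccc_options List of options passed to \code{\link{fit_ccc}}.
#' @return Data.frame with columns \code{subject_id}, \code{fsiq},
#'   \code{vci}, \code{pri}, \code{wmi}, \code{psi}, \code{ccc}, \code{ec},
#'   \code{spatial_nback}, \code{verbal_nback}, \code{ospan},
#'   \code{rotspan}, \code{symspan}, \code{education_years}.
#' @export
score_battery <- function(mft_trials, ant_trials, nback_summary, span_trials,
                          composites, ccc_options = list()) {
  ccc <- do.call(fit_ccc_cohort, c(list(trials = mft_trials), ccc_options))
  ccc <- ccc[, c("subject_id", "ccc_bps")]
  names(ccc)[2] <- "ccc"

  ids <- unique(ant_trials$subject_id)
  ec <- data.frame(subject_id = ids, ec = vapply(ids, function(id) {
    conflict_effect(ant_trials[ant_trials$subject_id == id, , drop = FALSE])
  }, numeric(1)))

  nb_rows <- lapply(unique(nback_summary$subject_id), function(id) {
    sub <- nback_summary[nback_summary$subject_id == id, , drop = FALSE]
    idx <- function(task) {
      s <- sub[sub$task == task, , drop = FALSE]
      acc <- stats::setNames(s$accuracy, as.character(s$level))
      nback_index(acc, task)
    }
    data.frame(subject_id = id, spatial_nback = idx("spatial"),
               verbal_nback = idx("verbal"))
  })
  nb <- do.call(rbind, nb_rows)

  sp_rows <- lapply(unique(span_trials$subject_id), function(id) {
    sub <- span_trials[span_trials$subject_id == id, , drop = FALSE]
    data.frame(
      subject_id = id,
      ospan = anl_score(sub[sub$task == "ospan", , drop = FALSE]),
      rotspan = anl_score(sub[sub$task == "rotspan", , drop = FALSE]),
      symspan = anl_score(sub[sub$task == "symspan", , drop = FALSE]))
  })
  sp <- do.call(rbind, sp_rows)

  comp <- composites[, c("subject_id", "fsiq", "vci", "pri", "wmi", "psi",
                         "education_years")]
  out <- Reduce(function(a, b) merge(a, b, by = "subject_id"),
                list(comp, ccc, ec, nb, sp))
  out[, c("subject_id", "fsiq", "vci", "pri", "wmi", "psi", "ccc", "ec",
          "spatial_nback", "verbal_nback", "ospan", "rotspan", "symspan",
          "education_years")]
}
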