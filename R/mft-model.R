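#' Probability of sampling a congruent group of arrows
#'
#' In the masked majority-function task (MFT-M) the observer is assumed to
#' use a grouping search: repeatedly sample \code{group_size} arrows out of
#' the displayed set until all arrows in the sampled group point the same
#' way (a congruent group). This function returns the per-attempt success
#' probability \eqn{P_{group}}, the hypergeometric probability that a random
#' subset of size \code{group_size} is drawn entirely from the majority or
#' entirely from the minority:
#' \deqn{P_{group} = \frac{\binom{maj}{k} + \binom{min}{k}}{\binom{maj+min}{k}}.}
#'
#' @param majority_count Number of arrows pointing in the majority direction.
#' @param minority_count Number of arrows pointing in the minority direction.
#' @param group_size Number of arrows sampled per attempt (default 3, the
#'   majority size of a five-arrow display).
#' @return Probability in \[0, 1\]. Vectorized over its arguments.
#' @examples
#' group_success_probability(5, 0)  # 1.0
#' group_success_probability(4, 1)  # 0.4
#' group_success_probability(3, 2)  # 0.1
#' @export
group_success_probability <- function(majority_count, minority_count,
                                      group_size = 3L) {
  if (any(majority_count < 0) || any(minority_count < 0)) {
    stop("arrow counts must be non-negative", call. = FALSE)
  }
  if (any(majority_count < minority_count)) {
    stop("majority_count must be >= minority_count", call. = FALSE)
  }
  total <- majority_count + minority_count
  if (any(group_size < 1) || any(group_size > total)) {
    stop("group_size must be between 1 and the total arrow count",
         call. = FALSE)
  }
  (choose(majority_count, group_size) + choose(minority_count, group_size)) /
    choose(total, group_size)
}

#' Expected number of to-be-scanned arrows
#'
#' The mean number of arrows processed before a congruent group is found:
#' the group size divided by the per-attempt success probability,
#' \eqn{N = N_{maj} / P_{group}}.
#'
#' @inheritParams group_success_probability
#' @return Expected scan count \eqn{N} (a real number, at least
#'   \code{group_size}).
#' @examples
#' expected_scanned_arrows(4, 1)  # 7.5
#' @export
expected_scanned_arrows <- function(majority_count, minority_count,
                                    group_size = 3L) {
  p <- group_success_probability(majority_count, minority_count, group_size)
  if (any(p == 0)) {
    stop("degenerate condition: congruent group has probability 0",
         call. = FALSE)
  }
  group_size / p
}

#' Information entropy of a congruency condition
#'
#' The information content, in bits, of one condition of the masked
#' majority-function task: \eqn{\log_2 N}, where \eqn{N} is the expected
#' number of to-be-scanned arrows. For the five-arrow, group-of-three
#' design this gives 1.58 bits (5:0), 2.91 bits (4:1) and 4.91 bits (3:2).
#'
#' @inheritParams group_success_probability
#' @return Entropy in bits.
#' @export
information_entropy_bits <- function(majority_count, minority_count,
                                     group_size = 3L) {
  log2(expected_scanned_arrows(majority_count, minority_count, group_size))
}

#' Information rate of a design cell
#'
#' Bits of information per second demanded by one congruency-by-exposure
#' cell: \eqn{\log_2(N / ET)} with the exposure time \eqn{ET} in seconds.
#' Over the standard design (three ratios crossed with exposure times of
#' 0.25 to 2 s) the rate spans roughly 0.58 to 6.91 bps.
#'
#' @inheritParams group_success_probability
#' @param exposure_time Exposure time in seconds (> 0).
#' @return Information rate in bits per second.
#' @export
information_rate_bps <- function(majority_count, minority_count,
                                 exposure_time, group_size = 3L) {
  if (any(exposure_time <= 0)) {
    stop("exposure_time must be positive", call. = FALSE)
  }
  n <- expected_scanned_arrows(majority_count, minority_count, group_size)
  log2(n / exposure_time)
}

#' The factorial design of the masked majority-function task
#'
#' Builds the congruency-by-exposure design grid with all derived
#' information-theoretic quantities attached. The default is the
#' five-arrow design: ratios 5:0, 4:1, 3:2 crossed with exposure times of
#' 0.25, 0.5, 1 and 2 seconds (12 cells).
#'
#' @param exposure_times Exposure times in seconds.
#' @param ratios List of \code{c(majority, minority)} pairs.
#' @param group_size Arrows sampled per attempt.
#' @return A data.frame with one row per design cell: \code{majority_count},
#'   \code{minority_count}, \code{group_size}, \code{exposure_time},
#'   \code{p_group}, \code{n_scanned}, \code{entropy_bits}, \code{rate_bps}.
#' @examples
#' d <- mft_design()
#' range(d$rate_bps)
#' @export
mft_design <- function(exposure_times = c(0.25, 0.5, 1, 2),
                       ratios = list(c(5, 0), c(4, 1), c(3, 2)),
                       group_size = 3L) {
  maj <- vapply(ratios, `[`, numeric(1), 1L)
  mino <- vapply(ratios, `[`, numeric(1), 2L)
  grid <- expand.grid(ratio = seq_along(ratios),
                      exposure_time = exposure_times,
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    majority_count = maj[grid$ratio],
    minority_count = mino[grid$ratio],
    group_size = group_size,
    exposure_time = grid$exposure_time
  )
  out$p_group <- group_success_probability(out$majority_count,
                                           out$minority_count, group_size)
  out$n_scanned <- expected_scanned_arrows(out$majority_count,
                                           out$minority_count, group_size)
  out$entropy_bits <- log2(out$n_scanned)
  out$rate_bps <- log2(out$n_scanned / out$exposure_time)
  out
}

#' Expected response accuracy under the capacity model
#'
#' Closed-form expected accuracy for one design cell given a capacity of
#' cognitive control \eqn{C} (bits per second). A trial terminates
#' voluntarily (a congruent group found within the exposure time), in which
#' case the response is correct with the baseline probability \eqn{p_0},
#' or is forced to terminate, in which case the observer guesses at
#' \eqn{p_{guess}}:
#' \deqn{E[acc] = p_0 - (1 - P_{group})^{2^C \cdot ET / N_{maj}}
#'       (p_0 - p_{guess}).}
#' The exponent \eqn{2^C ET / N_{maj}} is the (real-valued) number of
#' sampling attempts afforded by the exposure time at capacity \eqn{C}.
#'
#' @param capacity Capacity of cognitive control, bits per second.
#' @param majority_count,minority_count Arrow counts of the condition.
#' @param exposure_time Exposure time in seconds.
#' @param p0 Baseline accuracy on informed (voluntarily terminated) trials.
#' @param p_guess Guessing accuracy on forced-termination trials
#'   (default 0.5).
#' @param group_size Arrows sampled per attempt.
#' @return Expected accuracy, bounded between \code{p_guess} and \code{p0}
#'   (when \code{p0 >= p_guess}); nondecreasing in \code{capacity} and in
#'   \code{exposure_time}.
#' @examples
#' expected_accuracy(4, 3, 2, exposure_time = 0.25, p0 = 0.99)  # 0.5642
#' @export
expected_accuracy <- function(capacity, majority_count, minority_count,
                              exposure_time, p0, p_guess = 0.5,
                              group_size = 3L) {
  if (any(p0 < 0 | p0 > 1) || any(p_guess < 0 | p_guess > 1)) {
    stop("p0 and p_guess must lie in [0, 1]", call. = FALSE)
  }
  if (any(exposure_time <= 0)) {
    stop("exposure_time must be positive", call. = FALSE)
  }
  p_group <- group_success_probability(majority_count, minority_count,
                                       group_size)
  k <- 2^capacity * exposure_time / group_size
  # (1 - p_group)^k with 0^0 := 1 so the fully congruent cell returns p0
  p0 - (1 - p_group)^k * (p0 - p_guess)
}

#' Aggregate MFT-M trials into per-cell accuracy counts
#'
#' Collapses trial-level data to one row per congruency-by-exposure cell
#' with trial and correct counts. Only trials with a response are counted
#' (unanswered trials carry no accuracy information).
#'
#' @param trials Data.frame of MFT-M trials with columns
#'   \code{majority_count}, \code{minority_count}, \code{exposure_time}
#'   (seconds) or \code{exposure_time_ms}, \code{responded}, \code{correct}.
#' @return Data.frame with columns \code{majority_count},
#'   \code{minority_count}, \code{exposure_time}, \code{n_trials},
#'   \code{n_correct}.
#' @export
aggregate_mft_cells <- function(trials) {
  stopifnot_cols(trials, c("majority_count", "minority_count",
                           "responded", "correct"), "trials")
  if (!"exposure_time" %in% names(trials)) {
    stopifnot_cols(trials, "exposure_time_ms", "trials")
    trials$exposure_time <- trials$exposure_time_ms / 1000
  }
  trials <- trials[as.logical(trials$responded), , drop = FALSE]
  agg <- stats::aggregate(
    cbind(n_trials = rep(1L, nrow(trials)),
          n_correct = as.integer(trials$correct)) ~
      majority_count + minority_count + exposure_time,
    data = trials, FUN = sum)
  agg[order(agg$exposure_time, -agg$majority_count), , drop = FALSE]
}

#' Baseline accuracy from congruent cells
#'
#' The baseline accuracy \eqn{p_0} is the trial-weighted mean accuracy over
#' all fully congruent (5:0) cells, pooled across exposure times. Congruent
#' cells are those with \code{minority_count == 0}.
#'
#' @param cells Per-cell accuracy data.frame as produced by
#'   \code{\link{aggregate_mft_cells}}.
#' @return Probability \eqn{p_0}.
#' @export
baseline_accuracy <- function(cells) {
  stopifnot_cols(cells, c("minority_count", "n_trials", "n_correct"), "cells")
  cong <- cells[cells$minority_count == 0 & cells$n_trials > 0, , drop = FALSE]
  if (nrow(cong) == 0L) {
    stop("no congruent (minority_count == 0) cells with trials: p0 not estimable",
         call. = FALSE)
  }
  sum(cong$n_correct) / sum(cong$n_trials)
}

#' Estimate the capacity of cognitive control (CCC)
#'
#' Two-stage maximum-likelihood estimation of the capacity parameter
#' \eqn{C}: the baseline accuracy \eqn{p_0} is first estimated from the
#' congruent (5:0) cells, then \eqn{C} is chosen to maximize the binomial
#' log-likelihood of the incongruent cell counts under
#' \code{\link{expected_accuracy}},
#' \deqn{\ell(C) = \sum_j n^{corr}_j \log \hat p_j +
#'       (n_j - n^{corr}_j) \log(1 - \hat p_j),}
#' with predicted accuracies clamped to \eqn{[\epsilon, 1-\epsilon]}.
#' A least-squares objective (minimizing the sum of squared differences
#' between observed and predicted cell accuracies) is available for
#' sensitivity checks. The search uses a coarse grid pre-scan followed by
#' golden-section/parabolic refinement, so flat likelihood regions do not
#' stall the optimizer. Congruent cells are constant in \eqn{C} and enter
#' only through \eqn{p_0}.
#'
#' @param cells Per-cell accuracies (see \code{\link{aggregate_mft_cells}}),
#'   with \code{majority_count}, \code{minority_count}, \code{exposure_time},
#'   \code{n_trials}, \code{n_correct}.
#' @param p_guess Guessing accuracy (default 0.5).
#' @param bounds Search interval for \eqn{C} in bits per second.
#' @param objective \code{"binomial"} (default) or \code{"least_squares"}.
#' @param p0 Optional fixed baseline accuracy; estimated from congruent
#'   cells when \code{NULL}.
#' @param epsilon Probability clamp for the likelihood.
#' @return An object of class \code{ccc_fit}: \code{capacity} (bps),
#'   \code{baseline_accuracy}, \code{p_guess}, \code{log_likelihood},
#'   \code{per_cell} (observed vs predicted accuracy per incongruent cell),
#'   \code{converged}, \code{at_bound}, \code{objective}, \code{bounds}.
#' @examples
#' d <- mft_design()
#' cells <- d[, c("majority_count", "minority_count", "exposure_time")]
#' cells$n_trials <- 36L
#' cells$n_correct <- round(36 * expected_accuracy(
#'   3.82, cells$majority_count, cells$minority_count,
#'   cells$exposure_time, p0 = 0.99))
#' fit_ccc(cells)
#' @export
fit_ccc <- function(cells, p_guess = 0.5, bounds = c(0.1, 10),
                    objective = c("binomial", "least_squares"),
                    p0 = NULL, epsilon = 1e-6) {
  objective <- match.arg(objective)
  stopifnot_cols(cells, c("majority_count", "minority_count", "exposure_time",
                          "n_trials", "n_correct"), "cells")
  if (is.null(p0)) p0 <- baseline_accuracy(cells)
  inc <- cells[cells$minority_count > 0 & cells$n_trials > 0, , drop = FALSE]
  if (nrow(inc) == 0L) {
    stop("no incongruent cells with trials: capacity not estimable",
         call. = FALSE)
  }
  obs <- inc$n_correct / inc$n_trials

  pred_at <- function(C) {
    expected_accuracy(C, inc$majority_count, inc$minority_count,
                      inc$exposure_time, p0 = p0, p_guess = p_guess,
                      group_size = inc$group_size %||% 3L)
  }
  neg_obj <- function(C) {
    p <- clamp(pred_at(C), epsilon, 1 - epsilon)
    if (objective == "binomial") {
      -sum(inc$n_correct * log(p) + (inc$n_trials - inc$n_correct) * log(1 - p))
    } else {
      sum((obs - p)^2)
    }
  }

  grid <- seq(bounds[1], bounds[2], length.out = 101L)
  vals <- vapply(grid, neg_obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(neg_obj, interval = c(lo, hi), tol = 1e-6)
  capacity <- opt$minimum
  # keep whichever of grid point / refined point is better
  if (neg_obj(grid[i]) < opt$objective) capacity <- grid[i]

  tol <- 1e-3 * diff(bounds)
  at_bound <- (capacity - bounds[1]) < tol || (bounds[2] - capacity) < tol
  if (at_bound) capacity <- clamp(capacity, bounds[1], bounds[2])

  # non-identifiability: the data carry no evidence about C when every
  # incongruent accuracy sits at or beyond the guessing/ceiling levels
  identifiable <- any(obs > p_guess) && any(obs < p0)

  pred <- pred_at(capacity)
  pc <- clamp(pred, epsilon, 1 - epsilon)
  ll <- sum(inc$n_correct * log(pc) + (inc$n_trials - inc$n_correct) * log(1 - pc))

  structure(list(
    capacity = capacity,
    baseline_accuracy = p0,
    p_guess = p_guess,
    log_likelihood = ll,
    per_cell = data.frame(
      majority_count = inc$majority_count,
      minority_count = inc$minority_count,
      exposure_time = inc$exposure_time,
      n_trials = inc$n_trials,
      observed = obs,
      predicted = pred
    ),
    converged = identifiable && !at_bound,
    at_bound = at_bound,
    objective = objective,
    bounds = bounds
  ), class = "ccc_fit")
}

#' @export
print.ccc_fit <- function(x, ...) {
  cat("Capacity of cognitive control fit\n")
  cat(sprintf("  C        = %.3f bps%s\n", x$capacity,
              if (x$at_bound) " (at search bound)" else ""))
  cat(sprintf("  p0       = %.4f   p_guess = %.2f\n",
              x$baseline_accuracy, x$p_guess))
  cat(sprintf("  logLik   = %.3f   objective = %s   converged = %s\n",
              x$log_likelihood, x$objective, x$converged))
  cat(sprintf("  %d incongruent cells; mean |obs - pred| = %.4f\n",
              nrow(x$per_cell),
              mean(abs(x$per_cell$observed - x$per_cell$predicted))))
  invisible(x)
}

#' Fit the capacity model for every subject in a trial table
#'
#' @param trials MFT-M trial data.frame (multiple subjects) with a
#'   \code{subject_id} column and the columns accepted by
#'   \code{\link{aggregate_mft_cells}}.
#' @param ... Passed on to \code{\link{fit_ccc}}.
#' @return Data.frame with one row per subject: \code{subject_id},
#'   \code{ccc_bps}, \code{p0}, \code{loglik}, \code{converged},
#'   \code{at_bound}.
#' @export
fit_ccc_cohort <- function(trials, ...) {
  stopifnot_cols(trials, "subject_id", "trials")
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(id) {
    fit <- fit_ccc(aggregate_mft_cells(
      trials[trials$subject_id == id, , drop = FALSE]), ...)
    data.frame(subject_id = id, ccc_bps = fit$capacity,
               p0 = fit$baseline_accuracy, loglik = fit$log_likelihood,
               converged = fit$converged, at_bound = fit$at_bound)
  })
  do.call(rbind, rows)
}
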