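#' Run the full analysis sequence
#'
#' Executes the study's analysis pipeline on raw task tables: participant
#' exclusion, battery scoring (capacity fit, conflict effect, N-back
#' indices, span scores), the correlation/Bayes-factor table, and the
#' four latent-variable model fits with their comparisons.
#'
#' @param cohort List of raw tables (\code{mft_trials}, \code{ant_trials},
#'   \code{nback_summary}, \code{span_trials}, \code{composites}), e.g.
#'   from \code{\link{simulate_cohort}} or \code{\link{read_cohort}}.
#' @param out_dir Optional directory; when given, every stage's artifact
#'   is written as CSV/JSON together with a run manifest.
#' @param apply_exclusions Run the exclusion filter first (default TRUE).
#' @param ccc_options Options passed to \code{\link{fit_ccc}}.
#' @param bf_sided Sidedness of the correlation Bayes factors.
#' @param models Named list of \code{\link{sem_model}}s to fit (default
#'   \code{\link{battery_sem_models}()}).
#' @param seed Seed for the model-fit start jitter.
#' @return List with \code{exclusion} (kept ids and report),
#'   \code{measures}, \code{summary} (per-index mean/SD/range),
#'   \code{correlations} (\code{cor_bf_table}), \code{sem_fits},
#'   \code{sem_comparisons} and \code{sem_index_table}.
#' @export
run_full_analysis <- function(cohort, out_dir = NULL,
                              apply_exclusions = TRUE,
                              ccc_options = list(), bf_sided = 2,
                              models = battery_sem_models(), seed = 1L) {
  needed <- c("mft_trials", "ant_trials", "nback_summary", "span_trials",
              "composites")
  missing <- setdiff(needed, names(cohort))
  if (length(missing)) {
    stop("cohort is missing table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  excl <- NULL
  if (apply_exclusions) {
    fields <- exclusion_fields(cohort$mft_trials, cohort$ant_trials,
                               cohort$nback_summary, cohort$span_trials,
                               cohort$composites)
    excl <- apply_exclusion_criteria(fields)
    keep <- excl$kept$subject_id
    if (length(keep) == 0L) {
      stop("no subjects remain after exclusion; nothing to analyze",
           call. = FALSE)
    }
    for (tb in needed) {
      cohort[[tb]] <- cohort[[tb]][cohort[[tb]]$subject_id %in% keep, ,
                                   drop = FALSE]
    }
  }

  measures <- score_battery(cohort$mft_trials, cohort$ant_trials,
                            cohort$nback_summary, cohort$span_trials,
                            cohort$composites, ccc_options = ccc_options)
  summary_tbl <- summarize_measures(measures)
  cors <- correlation_table(measures, bf_sided = bf_sided)

  mvars <- setdiff(names(measures), c("subject_id", "education_years"))
  complete <- measures[stats::complete.cases(measures[, mvars]), mvars]
  S <- stats::cov(complete)
  n <- nrow(complete)
  fits <- lapply(models, fit_ml, S = S, n = n, seed = seed)

  comparisons <- list()
  if (all(c("gc_gf_cc", "gc_gf_wm") %in% names(fits))) {
    comparisons$gc_gf_cc_vs_gc_gf_wm <-
      compare_sem_models(fits$gc_gf_cc, fits$gc_gf_wm)
  }
  index_tbl <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, chi_square = f$chi_square, df = f$df,
               rmsea = f$rmsea, tli = f$tli, cfi = f$cfi, bic = f$bic,
               converged = f$converged)
  }))

  result <- list(exclusion = excl, measures = measures,
                 summary = summary_tbl, correlations = cors,
                 sem_fits = fits, sem_comparisons = comparisons,
                 sem_index_table = index_tbl, n = n)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(measures, file.path(out_dir, "measures.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tbl, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(cors$long, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(index_tbl, file.path(out_dir, "sem_fit_indices.csv"),
                     row.names = FALSE)
    if (!is.null(excl)) {
      utils::write.csv(excl$report, file.path(out_dir, "exclusion_report.csv"),
                       row.names = FALSE)
    }
    manifest <- list(seed = seed, n_analyzed = n, bf_sided = bf_sided,
                     models = names(models),
                     package_version = as.character(
                       utils::packageVersion("cogcap")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  result
}

#' Per-index summary of the measures table
#'
#' Mean, SD, minimum and maximum for every battery index and composite
#' score, one row per index (SD is NA with a single subject).
#'
#' @param measures Per-subject measures data.frame.
#' @return Data.frame with columns \code{index}, \code{mean}, \code{sd},
#'   \code{min}, \code{max}.
#' @export
summarize_measures <- function(measures) {
  vars <- setdiff(names(measures), c("subject_id", "education_years"))
  do.call(rbind, lapply(vars, function(v) {
    x <- measures[[v]]
    data.frame(index = v, mean = mean(x, na.rm = TRUE),
               sd = if (sum(!is.na(x)) > 1L) stats::sd(x, na.rm = TRUE)
                    else NA_real_,
               min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE))
  }))
}
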