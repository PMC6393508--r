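`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Derive a per-stage random seed from one global seed, so adding a stage
# does not perturb the streams of existing stages. Kept below 2^31.
substream_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 2011L + stage * 7919L
}
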