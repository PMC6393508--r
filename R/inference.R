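#' One-tailed Pearson correlation
#'
#' Product-moment correlation with a one-tailed p value from the t
#' transform \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}}. The battery's measures
#' are coded so that every directional hypothesis is positive (e.g., the
#' conflict effect is reverse-coded), hence the default upper tail.
#'
#' @param x,y Numeric vectors of equal length (>= 4); pairs with missing
#'   values are dropped.
#' @param alternative \code{"greater"} (default) or \code{"less"}.
#' @return List with \code{r}, \code{n}, \code{t}, \code{p_one_tailed}.
#' @export
pearson_one_tailed <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L || length(y) != n) {
    stop("need >= 4 complete pairs of equal length", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- if (alternative == "greater") {
    stats::pt(t, df = n - 2, lower.tail = FALSE)
  } else {
    stats::pt(t, df = n - 2)
  }
  list(r = r, n = n, t = t, p_one_tailed = p)
}

#' Default Bayes factor for a Pearson correlation
#'
#' Jeffreys-Zellner-Siow (JZS) default Bayes factor BF10 for a correlation,
#' computed by one-dimensional numerical quadrature over the g prior:
#' \deqn{BF_{10} = \sqrt{n/2}\,\Gamma(1/2)^{-1} \int_0^\infty
#'   (1+g)^{(n-2)/2}\,[1+(1-r^2)g]^{-(n-1)/2}\, g^{-3/2} e^{-n/(2g)}\,dg.}
#' The default two-sided test depends on the data only through
#' \eqn{(|r|, n)}, so equal rounded correlations yield equal Bayes
#' factors. A one-sided variant for a positive correlation is available
#' for sensitivity analysis; it rescales BF10 by twice the posterior
#' probability of a positive correlation (Fisher-z normal approximation).
#'
#' @param r Sample correlation, |r| < 1.
#' @param n Sample size, > 3.
#' @param sided 2 (default) or 1 (positive-correlation alternative).
#' @return BF10 (> 0). Values above 1 favor a nonzero correlation.
#' @examples
#' jzs_correlation_bf(0.31, 88)  # 6.20
#' @export
jzs_correlation_bf <- function(r, n, sided = 2) {
  if (length(r) > 1L || length(n) > 1L) {
    return(mapply(jzs_correlation_bf, r, n, MoreArgs = list(sided = sided)))
  }
  if (n <= 3) stop("n must exceed 3", call. = FALSE)
  if (abs(r) >= 1) stop("|r| must be below 1", call. = FALSE)
  integrand <- function(g) {
    exp((n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p((1 - r^2) * g) -
          1.5 * log(g) - n / (2 * g))
  }
  quad <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
                     subdivisions = 500L),
    error = function(e) stop("quadrature failed for r = ", r, ", n = ", n,
                             ": ", conditionMessage(e), call. = FALSE))
  bf <- sqrt(n / 2) / gamma(0.5) * quad$value
  if (sided == 1) {
    post_pos <- stats::pnorm(atanh(r) * sqrt(n - 3))
    bf <- 2 * bf * post_pos
  }
  bf
}

#' Evidence category of a Bayes factor
#'
#' Maps BF10 to the conventional evidence bands: above 100 decisive
#' evidence for a correlation, above 3 substantial, below 1/3 substantial
#' evidence for the null, and between 1/3 and 3 insensitive (the data do
#' not distinguish the hypotheses). Boundary values fall in the weaker
#' category (e.g., BF = 3 is "insensitive").
#'
#' @param bf10 Positive Bayes factor(s).
#' @return Character vector: \code{"decisive"}, \code{"substantial"},
#'   \code{"insensitive"} or \code{"substantial_null"}.
#' @export
interpret_bf <- function(bf10) {
  if (any(bf10 <= 0)) stop("Bayes factors must be positive", call. = FALSE)
  ifelse(bf10 > 100, "decisive",
         ifelse(bf10 > 3, "substantial",
                ifelse(bf10 < 1 / 3, "substantial_null", "insensitive")))
}

#' Compare two dependent correlations sharing a variable
#'
#' Tests whether the correlation of an outcome with predictor 1 differs
#' from its correlation with predictor 2, given the intercorrelation of the
#' two predictors, using Fisher r-to-z transformed coefficients. Two
#' variants of the correlated-correlations z test are implemented:
#' Steiger's Z1* (default) and the Meng-Rosenthal-Rubin z. Both are
#' antisymmetric in (r1, r2) and reduce to z = 0 when r1 = r2.
#'
#' @param r1,r2 Correlations of the shared outcome with each predictor.
#' @param r_predictors Correlation between the two predictors.
#' @param n Sample size (> 3).
#' @param method \code{"steiger"} (default) or \code{"meng"}.
#' @return List with \code{z}, \code{p_one_tailed} (upper tail for
#'   r1 > r2), \code{method}, and the inputs.
#' @examples
#' compare_dependent_correlations(0.87, 0.84, 0.96, 88)$z
#' @export
compare_dependent_correlations <- function(r1, r2, r_predictors, n,
                                           method = c("steiger", "meng")) {
  method <- match.arg(method)
  if (any(abs(c(r1, r2, r_predictors)) >= 1)) {
    stop("all correlations must have absolute value below 1", call. = FALSE)
  }
  if (n <= 3) stop("n must exceed 3", call. = FALSE)
  R <- matrix(c(1, r1, r2, r1, 1, r_predictors, r2, r_predictors, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("the correlation triple is inadmissible (non positive semidefinite)",
         call. = FALSE)
  }
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  rbar2 <- (r1^2 + r2^2) / 2
  if (method == "meng") {
    f <- min((1 - r_predictors) / (2 * (1 - rbar2)), 1)
    h <- (1 - f * rbar2) / (1 - rbar2)
    z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r_predictors) * h))
  } else {
    rb <- (r1 + r2) / 2
    psi <- r_predictors * (1 - 2 * rb^2) -
      0.5 * rb^2 * (1 - 2 * rb^2 - r_predictors^2)
    s <- psi / (1 - rb^2)^2
    z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  }
  list(z = z, p_one_tailed = stats::pnorm(z, lower.tail = FALSE),
       r1 = r1, r2 = r2, r_predictors = r_predictors, n = n, method = method)
}

format_bf <- function(bf) {
  ifelse(bf > 100, ">100", sprintf("%.2f", bf))
}

stars_one_tailed <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Correlation/Bayes-factor table over the measures
#'
#' Lower-triangle report of one-tailed Pearson correlations with
#' significance stars (one-tailed 0.05 / 0.01 / 0.001) and the default JZS
#' Bayes factor per cell. Pairs are used pairwise-complete with the
#' per-cell n recorded. Bayes factors are computed on the correlation
#' rounded to two decimals, so equal printed correlations carry equal
#' Bayes factors; BF above 100 renders as ">100".
#'
#' @param measures Per-subject measures data.frame.
#' @param vars Columns to correlate (default: the 12 battery measures
#'   present in \code{measures}).
#' @param bf_sided Sidedness of the Bayes factor (default 2).
#' @return Object of class \code{cor_bf_table}: \code{long} (data.frame
#'   \code{var1, var2, n, r, p_one_tailed, stars, bf10, bf_category}) and
#'   \code{vars}. \code{print()} renders the triangular text matrix.
#' @export
correlation_table <- function(measures, vars = NULL, bf_sided = 2) {
  default_vars <- c("fsiq", "vci", "pri", "wmi", "psi", "ccc", "ec",
                    "spatial_nback", "verbal_nback", "ospan", "rotspan",
                    "symspan")
  vars <- vars %||% intersect(default_vars, names(measures))
  if (length(vars) < 2L) stop("need at least two variables", call. = FALSE)
  pairs <- utils::combn(vars, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    v1 <- pairs[1L, j]; v2 <- pairs[2L, j]
    ct <- pearson_one_tailed(measures[[v1]], measures[[v2]])
    r2d <- round(ct$r, 2)
    bf <- jzs_correlation_bf(r2d, ct$n, sided = bf_sided)
    data.frame(var1 = v1, var2 = v2, n = ct$n, r = ct$r,
               p_one_tailed = ct$p_one_tailed,
               stars = stars_one_tailed(ct$p_one_tailed),
               bf10 = bf, bf_category = interpret_bf(bf))
  })
  structure(list(long = do.call(rbind, rows), vars = vars,
                 bf_sided = bf_sided),
            class = "cor_bf_table")
}

#' @export
print.cor_bf_table <- function(x, digits = 2, ...) {
  vars <- x$vars
  p <- length(vars)
  rcell <- matrix("", p, p, dimnames = list(vars, vars))
  bcell <- matrix("", p, p, dimnames = list(vars, vars))
  for (i in seq_len(nrow(x$long))) {
    row <- x$long[i, ]
    rcell[row$var2, row$var1] <-
      paste0(sprintf(paste0("%.", digits, "f"), row$r), row$stars)
    bcell[row$var2, row$var1] <- paste0("(", format_bf(row$bf10), ")")
  }
  cat("One-tailed Pearson correlations (Bayes factors in parentheses)\n")
  for (i in seq(2L, p)) {
    cat(format(vars[i], width = 14),
        paste(format(rcell[i, seq_len(i - 1L)], width = 8), collapse = " "),
        "\n")
    cat(format("", width = 14),
        paste(format(bcell[i, seq_len(i - 1L)], width = 8), collapse = " "),
        "\n")
  }
  cat("  columns:", paste(vars[-p], collapse = ", "), "\n")
  cat("  *p<0.05 **p<0.01 ***p<0.001 (one-tailed); BF > 100 shown as >100\n")
  invisible(x)
}

#' @export
as.data.frame.cor_bf_table <- function(x, ...) x$long
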