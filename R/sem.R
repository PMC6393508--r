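#' Specify a correlated-factor covariance-structure model
#'
#' Defines a confirmatory factor model: each latent variable loads on a
#' set of manifest variables, latent variances are fixed to 1 (so latent
#' covariances are correlations and all loadings are free), manifest error
#' variances are free and bounded below by 0 unless explicitly fixed to 0,
#' and selected pairs of manifests may share a free error covariance.
#' A latent with a single indicator is identified by fixing that
#' indicator's error variance to 0 (list it in \code{fixed_error}).
#'
#' @param name Model label.
#' @param loadings Named list: latent name -> character vector of manifest
#'   variable names it loads on.
#' @param fixed_error Manifest names whose error variance is fixed to 0.
#' @param error_cov_links List of 2-element character vectors: pairs of
#'   manifests whose error covariance is free.
#' @return Object of class \code{sem_model} with elements \code{name},
#'   \code{latents}, \code{manifests}, \code{loadings}, \code{fixed_error},
#'   \code{links}.
#' @examples
#' m <- sem_model("toy", list(f = c("a", "b", "c")))
#' sem_free_params(m)
#' @export
sem_model <- function(name, loadings, fixed_error = character(),
                      error_cov_links = list()) {
  latents <- names(loadings)
  if (is.null(latents) || any(latents == "")) {
    stop("loadings must be a named list (latent -> manifests)", call. = FALSE)
  }
  if (any(lengths(loadings) == 0L)) {
    stop("every latent must load on at least one manifest", call. = FALSE)
  }
  manifests <- unique(unlist(loadings, use.names = FALSE))
  if (!all(fixed_error %in% manifests)) {
    stop("fixed_error names a variable that is not a manifest", call. = FALSE)
  }
  for (lk in error_cov_links) {
    if (length(lk) != 2L || !all(lk %in% manifests) || lk[1] == lk[2]) {
      stop("error_cov_links must be pairs of distinct declared manifests",
           call. = FALSE)
    }
  }
  structure(list(name = name, latents = latents, manifests = manifests,
                 loadings = loadings, fixed_error = fixed_error,
                 links = error_cov_links),
            class = "sem_model")
}

#' @export
print.sem_model <- function(x, ...) {
  fp <- sem_free_params(x)
  p <- length(x$manifests)
  cat(sprintf("sem_model '%s': %d latents, %d manifests, %d free parameters, df = %d\n",
              x$name, length(x$latents), p, nrow(fp),
              p * (p + 1) / 2 - nrow(fp)))
  for (l in x$latents) {
    cat(sprintf("  %s -> %s\n", l, paste(x$loadings[[l]], collapse = ", ")))
  }
  if (length(x$fixed_error)) {
    cat("  error variance fixed to 0:", paste(x$fixed_error, collapse = ", "), "\n")
  }
  for (lk in x$links) cat(sprintf("  error covariance: %s <-> %s\n", lk[1], lk[2]))
  invisible(x)
}

#' Free-parameter table of a model
#'
#' @param model A \code{\link{sem_model}}.
#' @return Data.frame with columns \code{name} (e.g.
#'   \code{"lambda:f:a"}, \code{"phi:f1:f2"}, \code{"theta:a"},
#'   \code{"link:a:b"}), \code{type}, \code{lower}, \code{upper}.
#' @export
sem_free_params <- function(model) {
  rows <- list()
  for (l in model$latents) {
    for (m in model$loadings[[l]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste("lambda", l, m, sep = ":"), type = "loading",
        lower = -Inf, upper = Inf)
    }
  }
  nl <- length(model$latents)
  if (nl > 1L) {
    for (i in seq_len(nl - 1L)) for (j in seq(i + 1L, nl)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste("phi", model$latents[i], model$latents[j], sep = ":"),
        type = "latent_correlation", lower = -0.999, upper = 0.999)
    }
  }
  for (m in setdiff(model$manifests, model$fixed_error)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste("theta", m, sep = ":"), type = "error_variance",
      lower = 0, upper = Inf)
  }
  for (lk in model$links) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste("link", lk[1], lk[2], sep = ":"), type = "error_covariance",
      lower = -Inf, upper = Inf)
  }
  do.call(rbind, rows)
}

#' Model degrees of freedom
#'
#' \eqn{df = p(p+1)/2 - q} for p manifests and q free parameters.
#' @param model A \code{\link{sem_model}}.
#' @return Integer degrees of freedom.
#' @export
sem_df <- function(model) {
  p <- length(model$manifests)
  as.integer(p * (p + 1) / 2 - nrow(sem_free_params(model)))
}

# unpack a named theta vector into Lambda (p x m), Phi (m x m), Theta (p x p)
sem_matrices <- function(model, theta) {
  p <- length(model$manifests)
  nl <- length(model$latents)
  L <- matrix(0, p, nl, dimnames = list(model$manifests, model$latents))
  Phi <- diag(nl)
  dimnames(Phi) <- list(model$latents, model$latents)
  Th <- matrix(0, p, p, dimnames = list(model$manifests, model$manifests))
  for (nm in names(theta)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    switch(parts[1],
           lambda = { L[parts[3], parts[2]] <- theta[[nm]] },
           phi = { Phi[parts[2], parts[3]] <- Phi[parts[3], parts[2]] <- theta[[nm]] },
           theta = { Th[parts[2], parts[2]] <- theta[[nm]] },
           link = { Th[parts[2], parts[3]] <- Th[parts[3], parts[2]] <- theta[[nm]] },
           stop("unknown parameter name: ", nm, call. = FALSE))
  }
  list(Lambda = L, Phi = Phi, Theta = Th)
}

#' Model-implied covariance matrix
#'
#' \eqn{\Sigma(\theta) = \Lambda \Phi \Lambda^\top + \Theta}, with
#' \eqn{\Lambda} the loading matrix, \eqn{\Phi} the latent correlation
#' matrix (unit diagonal) and \eqn{\Theta} the error (co)variance matrix
#' (diagonal plus any linked error covariances).
#'
#' @param model A \code{\link{sem_model}}.
#' @param theta Named parameter vector; names as in
#'   \code{\link{sem_free_params}}. Parameters not named keep their fixed
#'   values (latent variances 1, fixed error variances 0).
#' @return Symmetric p x p matrix with manifest names.
#' @export
implied_covariance <- function(model, theta) {
  fp <- sem_free_params(model)
  if (is.null(names(theta)) || !all(names(theta) %in% fp$name)) {
    stop("theta must be named with free-parameter names; see sem_free_params()",
         call. = FALSE)
  }
  mats <- sem_matrices(model, theta)
  with(mats, Lambda %*% Phi %*% t(Lambda) + Theta)
}

# F_ML and its analytic gradient (dF = tr[A dSigma] with
# A = Sigma^-1 - Sigma^-1 S Sigma^-1), as fn/gr closures for optim.
# Parameter names are parsed into integer indices once, and fn caches the
# gradient so the paired gr call at the same point is free.
sem_objective_factory <- function(model, S, logdetS) {
  p <- length(model$manifests)
  nl <- length(model$latents)
  fp <- sem_free_params(model)
  m_id <- stats::setNames(seq_len(p), model$manifests)
  l_id <- stats::setNames(seq_len(nl), model$latents)
  parts <- strsplit(fp$name, ":", fixed = TRUE)
  kind <- vapply(parts, `[`, character(1), 1L)
  i1 <- integer(nrow(fp)); i2 <- integer(nrow(fp))
  for (k in seq_len(nrow(fp))) {
    pr <- parts[[k]]
    if (kind[k] == "lambda") { i1[k] <- m_id[[pr[3]]]; i2[k] <- l_id[[pr[2]]] }
    else if (kind[k] == "phi") { i1[k] <- l_id[[pr[2]]]; i2[k] <- l_id[[pr[3]]] }
    else if (kind[k] == "theta") { i1[k] <- i2[k] <- m_id[[pr[2]]] }
    else { i1[k] <- m_id[[pr[2]]]; i2[k] <- m_id[[pr[3]]] }
  }
  is_lam <- kind == "lambda"; is_phi <- kind == "phi"
  is_th <- kind == "theta"; is_lnk <- kind == "link"

  cache <- new.env(parent = emptyenv())
  cache$par <- NULL

  evaluate <- function(theta) {
    L <- matrix(0, p, nl)
    L[cbind(i1[is_lam], i2[is_lam])] <- theta[is_lam]
    Phi <- diag(nl)
    Phi[cbind(i1[is_phi], i2[is_phi])] <- theta[is_phi]
    Phi[cbind(i2[is_phi], i1[is_phi])] <- theta[is_phi]
    Th <- matrix(0, p, p)
    Th[cbind(i1[is_th], i1[is_th])] <- theta[is_th]
    Th[cbind(i1[is_lnk], i2[is_lnk])] <- theta[is_lnk]
    Th[cbind(i2[is_lnk], i1[is_lnk])] <- theta[is_lnk]
    LP <- L %*% Phi
    Sigma <- LP %*% t(L) + Th
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) {
      ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
      return(list(value = 1e8 * (1 + abs(ev)),
                  gradient = rep(0, length(theta))))
    }
    Sinv <- chol2inv(ch)
    value <- 2 * sum(log(diag(ch))) + sum(S * Sinv) - logdetS - p
    A <- Sinv - Sinv %*% S %*% Sinv
    ALP <- A %*% LP
    LAL <- crossprod(L, A %*% L)
    grad <- numeric(length(theta))
    grad[is_lam] <- 2 * ALP[cbind(i1[is_lam], i2[is_lam])]
    grad[is_phi] <- 2 * LAL[cbind(i1[is_phi], i2[is_phi])]
    grad[is_th] <- diag(A)[i1[is_th]]
    grad[is_lnk] <- 2 * A[cbind(i1[is_lnk], i2[is_lnk])]
    list(value = value, gradient = grad)
  }

  list(
    fn = function(theta) {
      res <- evaluate(theta)
      cache$par <- theta
      cache$gradient <- res$gradient
      res$value
    },
    gr = function(theta) {
      if (!is.null(cache$par) && identical(cache$par, theta)) {
        return(cache$gradient)
      }
      evaluate(theta)$gradient
    }
  )
}

# start values on the standardized (correlation) scale
sem_start_values <- function(model, jitter = NULL) {
  fp <- sem_free_params(model)
  start <- c(lambda = 0.7, phi = 0.3, theta = 0.5,
             link = 0)[vapply(strsplit(fp$name, ":", fixed = TRUE),
                              `[`, character(1), 1L)]
  if (!is.null(jitter)) {
    start <- start + stats::runif(length(start), -jitter, jitter)
    start <- pmin(pmax(start, pmax(fp$lower, -3) + 1e-3),
                  pmin(fp$upper, 3) - 1e-3)
  }
  stats::setNames(start, fp$name)
}

# rescale standardized estimates back to the raw covariance metric
sem_unstandardize <- function(theta, fp, sds) {
  out <- theta
  for (i in seq_along(theta)) {
    parts <- strsplit(fp$name[i], ":", fixed = TRUE)[[1]]
    out[i] <- switch(parts[1],
                     lambda = theta[i] * sds[[parts[3]]],
                     phi = theta[i],
                     theta = theta[i] * sds[[parts[2]]]^2,
                     link = theta[i] * sds[[parts[2]]] * sds[[parts[3]]])
  }
  out
}

#' Fit a covariance-structure model by maximum likelihood
#'
#' Minimizes the Wishart ML discrepancy
#' \eqn{F_{ML} = \log|\Sigma(\theta)| + tr(S \Sigma(\theta)^{-1})
#'   - \log|S| - p}
#' over the model's free parameters, with error variances bounded below by
#' 0, using L-BFGS-B with analytic gradients and multiple jittered starts
#' around scaled principal-axis initial values. The test statistic is
#' \eqn{\chi^2 = (n-1) F_{ML}}. Fit indices (RMSEA, TLI, CFI against the
#' independence baseline, BIC \eqn{= \chi^2 + q \ln n}) are attached via
#' \code{\link{fit_indices}}.
#'
#' @param model A \code{\link{sem_model}}.
#' @param S Sample covariance matrix with manifest names on both
#'   dimensions (may contain more variables than the model uses).
#' @param n Number of observations behind \code{S} (> p).
#' @param starts Number of optimization starts (default 5).
#' @param seed Seed for the start jitter.
#' @return Object of class \code{sem_fit}: \code{theta} (named estimates),
#'   \code{f_min}, \code{chi_square}, \code{df}, \code{q},
#'   \code{implied_cov}, \code{standardized} (standardized loadings and
#'   latent correlations), \code{converged}, plus the index fields added
#'   by \code{\link{fit_indices}} (\code{chi_sq_over_df}, \code{rmsea},
#'   \code{tli}, \code{cfi}, \code{bic}, \code{cutoffs}).
#' @export
fit_ml <- function(model, S, n, starts = 5L, seed = 1L) {
  S <- as.matrix(S)
  if (is.null(rownames(S))) stop("S needs dimnames", call. = FALSE)
  missing <- setdiff(model$manifests, rownames(S))
  if (length(missing)) {
    stop("S lacks model manifests: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  S <- S[model$manifests, model$manifests]
  S <- (S + t(S)) / 2
  p <- nrow(S)
  if (n <= p) stop("n must exceed the number of manifest variables",
                   call. = FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("S must be positive definite", call. = FALSE)

  # the model is scale-free (every manifest has a free loading and error),
  # so fit on the correlation metric for conditioning and rescale after
  sds <- sqrt(diag(S))
  R <- stats::cov2cor(S)
  logdetR <- sum(log(eigen(R, symmetric = TRUE, only.values = TRUE)$values))

  fp <- sem_free_params(model)
  best <- NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  obj <- sem_objective_factory(model, R, logdetR)
  for (s in seq_len(starts)) {
    start <- sem_start_values(model, jitter = if (s == 1L) NULL else 0.4)
    opt <- stats::optim(
      par = unname(start), fn = obj$fn, gr = obj$gr,
      method = "L-BFGS-B", lower = fp$lower, upper = fp$upper,
      control = list(maxit = 5000L, factr = 1e4, pgtol = 1e-8))
    if (is.null(best) ||
        opt$value < best$value - 1e-9 ||
        (opt$value < best$value + 1e-9 && opt$convergence == 0)) best <- opt
    if (best$value < 1e-10 && best$convergence == 0) break
  }

  theta <- sem_unstandardize(stats::setNames(best$par, fp$name), fp, sds)
  Sigma <- implied_covariance(model, theta)
  f_min <- max(best$value, 0)
  q <- nrow(fp)
  df <- as.integer(p * (p + 1) / 2 - q)
  if (df < 0) stop("model has more free parameters than moments", call. = FALSE)

  # completely standardized solution: loadings scaled by implied manifest SDs
  mats <- sem_matrices(model, theta)
  sds <- sqrt(diag(Sigma))
  std_load <- mats$Lambda / sds
  latent_cor <- mats$Phi

  fit <- structure(list(
    model = model, theta = theta, S = S, n = n,
    f_min = f_min, chi_square = (n - 1) * f_min, df = df, q = q,
    implied_cov = Sigma,
    standardized = list(loadings = std_load, latent_correlations = latent_cor,
                        error_variances = diag(mats$Theta) / sds^2),
    converged = best$convergence == 0 && best$value < 1e7
  ), class = "sem_fit")
  fit_indices(fit, n = n)
}

# analytic independence-baseline fit: Sigma = diag(S)
sem_baseline <- function(S, n) {
  p <- nrow(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  f_b <- sum(log(diag(S))) - sum(log(ev))
  list(chi_square = (n - 1) * f_b, df = p * (p - 1) / 2)
}

#' Complete a fit with indices and cut-off verdicts
#'
#' Adds \eqn{\chi^2/df}, RMSEA, TLI, CFI, and BIC to a fitted model.
#' \deqn{RMSEA = \sqrt{\max(\chi^2 - df, 0) / (df (n-1))}}
#' \deqn{TLI = \frac{\chi^2_b/df_b - \chi^2_m/df_m}{\chi^2_b/df_b - 1}}
#' \deqn{CFI = 1 - \frac{\max(\chi^2_m - df_m, 0)}
#'   {\max(\chi^2_b - df_b,\; \chi^2_m - df_m,\; 0)}}
#' \deqn{BIC = \chi^2 + q \ln n}
#' Cut-offs for acceptable fit: \eqn{\chi^2/df < 2}, RMSEA < 0.06, TLI and
#' CFI above 0.95. With df = 0 (saturated model) RMSEA is reported as 0.
#'
#' @param fit A \code{sem_fit}.
#' @param baseline Optional baseline fit (list with \code{chi_square} and
#'   \code{df}); defaults to the analytic independence model on the same
#'   manifest panel.
#' @param n Sample size (defaults to \code{fit$n}).
#' @return The completed \code{sem_fit}.
#' @export
fit_indices <- function(fit, baseline = NULL, n = fit$n) {
  if (is.null(baseline)) baseline <- sem_baseline(fit$S, n)
  chi_m <- fit$chi_square; df_m <- fit$df
  chi_b <- baseline$chi_square; df_b <- baseline$df
  fit$chi_sq_over_df <- if (df_m > 0) chi_m / df_m else NA_real_
  fit$rmsea <- if (df_m > 0) {
    sqrt(max(chi_m - df_m, 0) / (df_m * (n - 1)))
  } else 0
  fit$saturated <- df_m == 0
  ratio_b <- chi_b / df_b
  ratio_m <- if (df_m > 0) chi_m / df_m else 1
  fit$tli <- (ratio_b - ratio_m) / (ratio_b - 1)
  denom <- max(chi_b - df_b, chi_m - df_m, 0)
  fit$cfi <- if (denom == 0) 1 else 1 - max(chi_m - df_m, 0) / denom
  fit$cfi <- clamp(fit$cfi, 0, 1)
  fit$bic <- chi_m + fit$q * log(n)
  fit$baseline <- baseline
  fit$cutoffs <- c(chi_sq_over_df = isTRUE(fit$chi_sq_over_df < 2) || df_m == 0,
                   rmsea = fit$rmsea < 0.06,
                   tli = fit$tli > 0.95,
                   cfi = fit$cfi > 0.95)
  fit
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("ML covariance-structure fit: '%s' (n = %d)\n",
              x$model$name, x$n))
  cat(sprintf("  chi^2 = %.2f on df = %d (chi^2/df = %s), converged = %s\n",
              x$chi_square, x$df,
              if (is.na(x$chi_sq_over_df)) "saturated"
              else sprintf("%.2f", x$chi_sq_over_df),
              x$converged))
  cat(sprintf("  RMSEA = %.3f  TLI = %.3f  CFI = %.3f  BIC = %.2f\n",
              x$rmsea, x$tli, x$cfi, x$bic))
  cat("  latent correlations:\n")
  lc <- x$standardized$latent_correlations
  print(round(lc, 3))
  invisible(x)
}

#' Compare two fitted models
#'
#' Reports the chi-square difference (descriptive for non-nested pairs)
#' and the BIC difference with its evidence band: a BIC difference above 2
#' is positive evidence against the higher-BIC model, above 6 strong,
#' above 10 very strong.
#'
#' @param fit_a,fit_b Fitted models (\code{sem_fit}).
#' @return List with \code{chi_sq_diff}, \code{df_diff}, \code{p_value}
#'   (when \code{df_diff > 0}), \code{bic_diff} (absolute),
#'   \code{preferred} (name of the lower-BIC model) and \code{bic_band}.
#' @export
compare_sem_models <- function(fit_a, fit_b) {
  dchi <- abs(fit_a$chi_square - fit_b$chi_square)
  ddf <- abs(fit_a$df - fit_b$df)
  dbic <- abs(fit_a$bic - fit_b$bic)
  band <- if (dbic > 10) "very_strong" else if (dbic > 6) "strong"
          else if (dbic > 2) "positive" else "none"
  list(chi_sq_diff = dchi, df_diff = ddf,
       p_value = if (ddf > 0) stats::pchisq(dchi, ddf, lower.tail = FALSE)
                 else NA_real_,
       bic_diff = dbic,
       preferred = if (fit_a$bic <= fit_b$bic) fit_a$model$name
                   else fit_b$model$name,
       bic_band = band)
}

#' The four latent-variable models of the battery
#'
#' Returns the correlated-factor model specifications relating
#' intelligence (IQ), cognitive control (CC) and working memory (WM):
#' \enumerate{
#'   \item \code{iq_cc_wm}: IQ (VCI, PRI, WMI, PSI), CC (CCC, EC) and WM
#'     (spatial/verbal N-back, OSpan, RotSpan, SymSpan), with free error
#'     covariances WMI-CCC and WMI-OSpan; df = 39.
#'   \item \code{gc_gf_cc}: Gc (VCI, error variance fixed to 0 as its
#'     single indicator), Gf (PRI, WMI, PSI) and CC; df = 7.
#'   \item \code{gc_gf_wm}: Gc, Gf and WM; df = 25.
#'   \item \code{cc_wm}: CC and WM; df = 13.
#' }
#'
#' @return Named list of \code{\link{sem_model}} objects.
#' @export
battery_sem_models <- function() {
  wm_ind <- c("spatial_nback", "verbal_nback", "ospan", "rotspan", "symspan")
  list(
    iq_cc_wm = sem_model(
      "iq_cc_wm",
      loadings = list(IQ = c("vci", "pri", "wmi", "psi"),
                      CC = c("ccc", "ec"),
                      WM = wm_ind),
      error_cov_links = list(c("wmi", "ccc"), c("wmi", "ospan"))),
    gc_gf_cc = sem_model(
      "gc_gf_cc",
      loadings = list(Gc = "vci",
                      Gf = c("pri", "wmi", "psi"),
                      CC = c("ccc", "ec")),
      fixed_error = "vci"),
    gc_gf_wm = sem_model(
      "gc_gf_wm",
      loadings = list(Gc = "vci",
                      Gf = c("pri", "wmi", "psi"),
                      WM = wm_ind),
      fixed_error = "vci"),
    cc_wm = sem_model(
      "cc_wm",
      loadings = list(CC = c("ccc", "ec"), WM = wm_ind))
  )
}

#' Serialize / deserialize a model specification as JSON
#'
#' @param model A \code{\link{sem_model}}.
#' @param path Optional file path; when NULL the JSON string is returned.
#' @return \code{sem_model_to_json}: the JSON string (invisibly when
#'   written to file). \code{sem_model_from_json}: a \code{sem_model}.
#' @export
sem_model_to_json <- function(model, path = NULL) {
  obj <- list(name = model$name, loadings = model$loadings,
              fixed_error = model$fixed_error,
              error_cov_links = model$links)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname sem_model_to_json
#' @param json JSON string or file path to read.
#' @export
sem_model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  links <- obj$error_cov_links
  if (is.data.frame(links)) links <- as.list(as.data.frame(t(links)))
  if (is.matrix(links)) links <- split(links, row(links))
  sem_model(obj$name, lapply(obj$loadings, as.character),
            fixed_error = as.character(obj$fixed_error),
            error_cov_links = lapply(links, as.character))
}

#' Simulate multivariate data from a specified model
#'
#' Draws n observations from the multivariate normal distribution with
#' covariance \eqn{\Sigma(\theta)}; used for parameter-recovery studies.
#'
#' @param model A \code{\link{sem_model}}.
#' @param theta Named parameter vector.
#' @param n Number of observations.
#' @return n x p data matrix with manifest column names.
#' @export
simulate_sem_data <- function(model, theta, n) {
  Sigma <- implied_covariance(model, theta)
  ch <- chol(Sigma)
  z <- matrix(stats::rnorm(n * nrow(Sigma)), n, nrow(Sigma))
  x <- z %*% ch
  colnames(x) <- model$manifests
  x
}
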