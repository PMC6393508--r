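# Exhaustive subset-enumeration oracle for the congruent-group probability:
# label the arrows, enumerate every size-k subset, count unanimous ones.
enumerate_group_probability <- function(majority, minority, k) {
  arrows <- c(rep(1L, majority), rep(0L, minority))
  total <- majority + minority
  if (k > total) return(0)
  subsets <- utils::combn(total, k)
  unanimous <- apply(subsets, 2L, function(idx) {
    s <- arrows[idx]
    all(s == 1L) || all(s == 0L)
  })
  mean(unanimous)
}

# Brute-force process simulation of one MFT-M cell with an integer number
# of sampling attempts: each attempt succeeds with p_group; success within
# the budget means an informed response (p0), otherwise a guess (p_guess).
simulate_cell_brute_force <- function(n_reps, attempts, p_group, p0,
                                      p_guess = 0.5) {
  vt <- stats::rbinom(n_reps, attempts, p_group) > 0L
  correct <- ifelse(vt, stats::rbinom(n_reps, 1L, p0),
                    stats::rbinom(n_reps, 1L, p_guess))
  mean(correct)
}

# Per-cell accuracy table whose counts are the rounded model predictions.
make_model_cells <- function(capacity, p0, n_per_cell = 36L) {
  d <- mft_design()
  cells <- d[, c("majority_count", "minority_count", "exposure_time")]
  cells$n_trials <- n_per_cell
  cells$n_correct <- round(n_per_cell * expected_accuracy(
    capacity, cells$majority_count, cells$minority_count,
    cells$exposure_time, p0 = p0))
  cells
}

# Named parameter vector for the three-factor battery model with the
# study-scale latent correlations; used by the recovery checks.
battery_model_theta <- function(model,
                                phi = c(`phi:IQ:CC` = 0.84,
                                        `phi:IQ:WM` = 0.87,
                                        `phi:CC:WM` = 0.96),
                                link_value = 0.05) {
  fp <- sem_free_params(model)
  theta <- stats::setNames(numeric(nrow(fp)), fp$name)
  loadings <- c(vci = 0.55, pri = 0.75, wmi = 0.60, psi = 0.55,
                ccc = 0.80, ec = 0.45,
                spatial_nback = 0.50, verbal_nback = 0.25,
                ospan = 0.65, rotspan = 0.60, symspan = 0.70)
  for (l in model$latents) {
    for (m in model$loadings[[l]]) {
      theta[paste("lambda", l, m, sep = ":")] <- loadings[[m]]
      nm <- paste("theta", m, sep = ":")
      if (nm %in% names(theta)) theta[nm] <- 1 - loadings[[m]]^2
    }
  }
  for (nm in intersect(names(phi), names(theta))) theta[nm] <- phi[[nm]]
  theta[grep("^link:", names(theta))] <- link_value
  theta
}

# Path-tracing evaluation of a two-factor toy model's implied covariance:
# cov(x, y) = lambda_x phi(fx, fy) lambda_y (+ error terms on the diagonal
# and on linked pairs). Independent of the matrix-algebra implementation.
toy_path_tracing <- function(lam, phi, err, link = NULL) {
  vars <- names(lam)
  fac <- c(a = "f1", b = "f1", c = "f2", d = "f2")
  Sigma <- matrix(0, 4, 4, dimnames = list(vars, vars))
  for (x in vars) for (y in vars) {
    f_cor <- if (fac[[x]] == fac[[y]]) 1 else phi
    Sigma[x, y] <- lam[[x]] * f_cor * lam[[y]]
  }
  diag(Sigma) <- diag(Sigma) + err
  if (!is.null(link)) {
    Sigma[link$pair[1], link$pair[2]] <-
      Sigma[link$pair[1], link$pair[2]] + link$value
    Sigma[link$pair[2], link$pair[1]] <-
      Sigma[link$pair[2], link$pair[1]] + link$value
  }
  Sigma
}
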