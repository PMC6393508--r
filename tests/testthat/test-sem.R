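toy_model <- function(link = FALSE) {
  sem_model("toy", list(f1 = c("a", "b"), f2 = c("c", "d")),
            error_cov_links = if (link) list(c("a", "c")) else list())
}

test_that("model specification validates its structure", {
  m <- toy_model()
  expect_s3_class(m, "sem_model")
  expect_equal(m$manifests, c("a", "b", "c", "d"))
  expect_error(sem_model("bad", list(f = character())), "at least one")
  expect_error(sem_model("bad", list(c("a", "b"))), "named list")
  expect_error(sem_model("bad", list(f = c("a", "b")), fixed_error = "z"),
               "not a manifest")
  expect_error(sem_model("bad", list(f = c("a", "b")),
                         error_cov_links = list(c("a", "z"))), "pairs")
  expect_output(print(m), "2 latents, 4 manifests")
})

test_that("implied covariance matches path tracing on a toy model", {
  set.seed(30)
  for (rep in 1:5) {
    lam <- setNames(runif(4, 0.3, 0.9), c("a", "b", "c", "d"))
    phi <- runif(1, -0.5, 0.9)
    err <- setNames(runif(4, 0.2, 1), c("a", "b", "c", "d"))
    link_val <- runif(1, -0.1, 0.1)
    m <- toy_model(link = TRUE)
    theta <- c(`lambda:f1:a` = lam[["a"]], `lambda:f1:b` = lam[["b"]],
               `lambda:f2:c` = lam[["c"]], `lambda:f2:d` = lam[["d"]],
               `phi:f1:f2` = phi,
               `theta:a` = err[["a"]], `theta:b` = err[["b"]],
               `theta:c` = err[["c"]], `theta:d` = err[["d"]],
               `link:a:c` = link_val)
    oracle <- toy_path_tracing(lam, phi, err,
                               link = list(pair = c("a", "c"),
                                           value = link_val))
    expect_equal(implied_covariance(m, theta), oracle, tolerance = 1e-12)
  }
})

test_that("implied covariance handles the degenerate corners", {
  m <- sem_model("one", list(f = c("a", "b", "c")))
  zero <- c(`lambda:f:a` = 0, `lambda:f:b` = 0, `lambda:f:c` = 0,
            `theta:a` = 1, `theta:b` = 2, `theta:c` = 3)
  expect_equal(implied_covariance(m, zero), diag(c(1, 2, 3)),
               ignore_attr = TRUE)
  ones <- c(`lambda:f:a` = 1, `lambda:f:b` = 1, `lambda:f:c` = 1,
            `theta:a` = 0, `theta:b` = 0, `theta:c` = 0)
  expect_equal(implied_covariance(m, ones), matrix(1, 3, 3),
               ignore_attr = TRUE)
  expect_error(implied_covariance(m, c(bogus = 1)), "free-parameter")
})

test_that("a saturated model fits perfectly", {
  m <- sem_model("sat", list(f = c("a", "b", "c")))
  expect_equal(sem_df(m), 0L)
  S <- matrix(c(1, .5, .4, .5, 1, .3, .4, .3, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  fit <- fit_ml(m, S, n = 100)
  expect_lt(fit$chi_square, 1e-6)
  expect_equal(fit$df, 0L)
  expect_equal(fit$rmsea, 0)
  expect_true(fit$saturated)
})

test_that("ML fitting round-trips parameters generated from the model", {
  m <- battery_sem_models()$iq_cc_wm
  theta_true <- battery_model_theta(m)
  Sigma <- implied_covariance(m, theta_true)
  fit <- fit_ml(m, Sigma, n = 500)
  expect_lt(fit$f_min, 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$theta[names(theta_true)], theta_true, tolerance = 1e-3)
  # latent correlations recovered essentially exactly
  lc <- fit$standardized$latent_correlations
  expect_equal(lc["IQ", "CC"], 0.84, tolerance = 1e-4)
  expect_equal(lc["CC", "WM"], 0.96, tolerance = 1e-4)
})

test_that("chi-square grows with n for a misspecified independence-style fit", {
  m <- toy_model()
  set.seed(31)
  x <- simulate_sem_data(battery_sem_models()$cc_wm,
                         battery_model_theta(battery_sem_models()$cc_wm,
                                             phi = c(`phi:CC:WM` = 0.9)),
                         400)
  S4 <- cov(x[, c("ccc", "ec", "ospan", "rotspan")])
  dimnames(S4) <- list(c("a", "b", "c", "d"), c("a", "b", "c", "d"))
  # a no-correlation model on correlated data misfits, increasingly with n
  m0 <- sem_model("null", list(f1 = c("a", "b"), f2 = c("c", "d")))
  fp <- sem_free_params(m0)
  th <- setNames(rep(0, nrow(fp)), fp$name)
  f200 <- fit_ml(m0, S4, 200)
  f400 <- fit_ml(m0, S4, 400)
  expect_gt(f200$chi_square, 0)
  expect_gt(f400$chi_square, f200$chi_square)
})

test_that("chi-square is invariant to manifest relabeling", {
  m <- battery_sem_models()$gc_gf_cc
  set.seed(32)
  x <- simulate_sem_data(battery_sem_models()$iq_cc_wm,
                         battery_model_theta(battery_sem_models()$iq_cc_wm),
                         300)
  S <- cov(x)
  fit1 <- fit_ml(m, S, 300)
  perm <- sample(colnames(S))
  fit2 <- fit_ml(m, S[perm, perm], 300)
  expect_equal(fit1$chi_square, fit2$chi_square, tolerance = 1e-5)
  # and to the order in which the model lists the loadings
  m_rev <- sem_model("rev", rev(lapply(m$loadings, rev)),
                     fixed_error = m$fixed_error)
  fit3 <- fit_ml(m_rev, S, 300)
  expect_equal(fit1$chi_square, fit3$chi_square, tolerance = 1e-5)
})

test_that("freeing a parameter never worsens the discrepancy", {
  set.seed(33)
  x <- simulate_sem_data(battery_sem_models()$iq_cc_wm,
                         battery_model_theta(battery_sem_models()$iq_cc_wm),
                         250)
  S <- cov(x[, c("vci", "pri", "wmi", "psi")])
  dimnames(S) <- list(c("a", "b", "c", "d"), c("a", "b", "c", "d"))
  nested <- fit_ml(toy_model(), S, 250)
  fuller <- fit_ml(toy_model(link = TRUE), S, 250)
  expect_lte(fuller$f_min, nested$f_min + 1e-8)
})

test_that("the four battery models carry the published degrees of freedom", {
  models <- battery_sem_models()
  expect_equal(vapply(models, sem_df, integer(1)),
               c(iq_cc_wm = 39L, gc_gf_cc = 7L, gc_gf_wm = 25L,
                 cc_wm = 13L))
  # free-parameter counts behind them
  expect_equal(vapply(models, function(m) nrow(sem_free_params(m)),
                      integer(1)),
               c(iq_cc_wm = 27L, gc_gf_cc = 14L, gc_gf_wm = 20L,
                 cc_wm = 15L))
  # the single-indicator Gc latent is identified by its fixed error
  expect_equal(models$gc_gf_cc$fixed_error, "vci")
})

test_that("fit indices follow their formulas and cut-offs", {
  m <- battery_sem_models()$iq_cc_wm
  set.seed(34)
  x <- simulate_sem_data(m, battery_model_theta(m), 300)
  fit <- fit_ml(m, cov(x), 300)
  expect_equal(fit$bic, fit$chi_square + fit$q * log(300))
  expect_equal(fit$chi_sq_over_df, fit$chi_square / fit$df)
  rmsea_manual <- sqrt(max(fit$chi_square - fit$df, 0) / (fit$df * 299))
  expect_equal(fit$rmsea, rmsea_manual)
  expect_true(fit$cfi >= 0 && fit$cfi <= 1)
  # chi^2 below df pins RMSEA at zero (the well-fitting pattern)
  if (fit$chi_square < fit$df) expect_equal(fit$rmsea, 0)
  expect_named(fit$cutoffs, c("chi_sq_over_df", "rmsea", "tli", "cfi"))
})

test_that("model comparison applies the BIC evidence bands", {
  m <- battery_sem_models()$cc_wm
  set.seed(35)
  x <- simulate_sem_data(m, battery_model_theta(
    m, phi = c(`phi:CC:WM` = 0.9)), 300)
  fit <- fit_ml(m, cov(x), 300)
  same <- compare_sem_models(fit, fit)
  expect_equal(same$chi_sq_diff, 0)
  expect_equal(same$bic_diff, 0)
  expect_equal(same$bic_band, "none")
  fake <- fit
  fake$bic <- fit$bic + 42.86
  fake$model$name <- "other"
  cmp <- compare_sem_models(fit, fake)
  expect_equal(cmp$bic_band, "very_strong")
  expect_equal(cmp$preferred, "cc_wm")
  fake$bic <- fit$bic + 4
  expect_equal(compare_sem_models(fit, fake)$bic_band, "positive")
})

test_that("model specs round-trip through JSON", {
  for (m in battery_sem_models()) {
    js <- sem_model_to_json(m)
    m2 <- sem_model_from_json(js)
    expect_equal(m2$loadings, m$loadings)
    expect_equal(m2$fixed_error, m$fixed_error)
    expect_equal(sem_df(m2), sem_df(m))
  }
})

test_that("degenerate inputs are rejected", {
  m <- toy_model()
  S <- diag(4)
  expect_error(fit_ml(m, S, 100), "dimnames")
  dimnames(S) <- list(c("a", "b", "c", "z"), c("a", "b", "c", "z"))
  expect_error(fit_ml(m, S, 100), "lacks model manifests")
  S2 <- matrix(1, 4, 4, dimnames = list(c("a", "b", "c", "d"),
                                        c("a", "b", "c", "d")))
  expect_error(fit_ml(m, S2, 100), "positive definite")
  # more free parameters than moments
  m_over <- sem_model("over", list(f = c("a", "b")))
  S3 <- matrix(c(1, .3, .3, 1), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(fit_ml(m_over, S3, 100), "more free parameters")
})
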