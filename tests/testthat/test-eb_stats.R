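make_roles <- function(X, roles) structure(X, roles = roles)

test_that("least-squares fits recover exact linear relationships", {
  X <- make_roles(cbind(intercept = rep(1, 4), x = 0:3),
                  c("intercept", "cofactor_effect"))
  rownames(X) <- paste0("o", 1:4)
  Y <- matrix(1:4, nrow = 1, dimnames = list("P1", rownames(X)))
  fit <- fit_linear_models(Y, X)
  expect_equal(unname(fit$coefficients[1, ]), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(fit$sigma2), 0, tolerance = 1e-20)
  expect_equal(fit$df_residual, 2L)
  expect_equal(unname(fit$amean), 2.5)
  # noiseless Y = X beta recovers any beta exactly
  beta <- c(-2.5, 0.75)
  Y2 <- matrix(drop(X %*% beta), nrow = 1, dimnames = list("P2", rownames(X)))
  fit2 <- fit_linear_models(Y2, X)
  expect_equal(unname(fit2$coefficients[1, ]), beta, tolerance = 1e-12)
  expect_equal(unname(fit2$sigma2), 0, tolerance = 1e-20)
})

test_that("fits match the SVD pseudo-inverse oracle on random designs", {
  set.seed(101)
  layout <- cofactor_layout()
  X <- cofactor_design(layout)
  Y <- matrix(rnorm(20 * 12, mean = 8), 20, 12,
              dimnames = list(sprintf("P%02d", 1:20), rownames(X)))
  fit <- fit_linear_models(Y, X)
  expect_equal(unname(fit$unscaled_variances),
               diag(solve(crossprod(X))), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (g in 1:20) {
    oracle <- pinv_fit_oracle(Y[g, ], X)
    expect_equal(unname(fit$coefficients[g, ]), oracle$beta, tolerance = 1e-10)
    expect_equal(unname(fit$sigma2[g]), oracle$s2, tolerance = 1e-10)
  }
  expect_equal(fit$df_residual, 8L)
  expect_error(fit_linear_models(Y[, 1:10], X), "dimension mismatch")
})

test_that("scaling the data scales estimates but not moderated t", {
  set.seed(7)
  X <- cofactor_design(cofactor_layout())
  Y <- matrix(rnorm(200 * 12, 8), 200, 12,
              dimnames = list(sprintf("P%03d", 1:200), rownames(X)))
  fit <- fit_linear_models(Y, X)
  prior <- estimate_variance_prior(fit, trend = FALSE)
  st <- moderated_t_test(fit, prior, "cofactor_effect")
  fit3 <- fit_linear_models(3 * Y, X)
  prior3 <- estimate_variance_prior(fit3, trend = FALSE)
  st3 <- moderated_t_test(fit3, prior3, "cofactor_effect")
  expect_equal(st3$estimate, 3 * st$estimate, tolerance = 1e-9)
  expect_equal(st3$t, st$t, tolerance = 1e-9)
})

test_that("trigamma inversion solves trigamma(x) = y to high precision", {
  x <- c(0.01, 0.1, 0.5, 1, 2, 5, 20, 1e3)
  y <- trigamma(x)
  expect_equal(trigamma_inverse(y), x, tolerance = 1e-7)
  expect_equal(trigamma_inverse(Inf), 0)
  expect_equal(trigamma_inverse(0), Inf)
})

test_that("variance prior is recovered from scaled inverse-chi-square draws", {
  set.seed(202)
  n <- 5000L
  d0 <- 4; s02 <- 0.05; dg <- 8L
  sigma2 <- d0 * s02 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, dg) / dg
  fit <- structure(list(sigma2 = s2, df_residual = dg,
                        amean = rnorm(n, 8)), class = "protein_fit")
  prior <- estimate_variance_prior(fit, trend = FALSE)
  expect_lt(abs(prior$df_prior - d0) / d0, 0.15)
  expect_lt(abs(prior$var_prior[1] - s02) / s02, 0.15)
  # matches the established empirical-Bayes implementation without trend
  sq <- limma::squeezeVar(s2, df = dg)
  expect_equal(prior$df_prior, sq$df.prior, tolerance = 1e-6)
  expect_equal(prior$var_prior[1], sq$var.prior, tolerance = 1e-6)
})

test_that("intensity-dependent variance trend is recovered", {
  set.seed(303)
  n <- 5000L
  d0 <- 6; dg <- 8L
  A <- rnorm(n, 0, 2)
  s02_A <- 0.02 + 0.03 / (1 + exp(A))         # sigmoid(-A)
  sigma2 <- d0 * s02_A / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, dg) / dg
  fit <- structure(list(sigma2 = s2, df_residual = dg, amean = A),
                   class = "protein_fit")
  prior <- estimate_variance_prior(fit, trend = TRUE, span = 0.5)
  central <- A > quantile(A, 0.05) & A < quantile(A, 0.95)
  rel_err <- abs(prior$var_prior - s02_A) / s02_A
  expect_lt(max(rel_err[central]), 0.20)
  expect_lt(abs(prior$df_prior - d0) / d0, 0.25)
})

test_that("identical residual variances collapse to an infinite prior", {
  fit <- structure(list(sigma2 = rep(0.04, 200), df_residual = 8L,
                        amean = rnorm(200, 8)), class = "protein_fit")
  expect_warning(prior <- estimate_variance_prior(fit, trend = FALSE),
                 "Inf")
  expect_equal(prior$df_prior, Inf)
})

test_that("posterior variance is the stated convex combination", {
  # worked case: d0 = 1, s0^2 = 1, d_g = 2, s_g^2 = 4 -> (1 + 8)/3 = 3
  expect_equal(squeeze_variances(4, 2, list(df_prior = 1, var_prior = 1)), 3)
  set.seed(5)
  s2 <- rexp(100); s0 <- rexp(100)
  sq <- squeeze_variances(s2, 6, list(df_prior = 3, var_prior = s0))
  expect_true(all(sq >= pmin(s2, s0) - 1e-12 & sq <= pmax(s2, s0) + 1e-12))
  expect_equal(squeeze_variances(s2, 6, list(df_prior = Inf, var_prior = s0)), s0)
  expect_equal(squeeze_variances(s2, 6, list(df_prior = 0, var_prior = s0)), s2)
})

test_that("moderation with d0 = 0 reproduces the classical t-test exactly", {
  set.seed(11)
  X <- cofactor_design(cofactor_layout())
  Y <- matrix(rnorm(60 * 12, 8), 60, 12,
              dimnames = list(sprintf("P%02d", 1:60), rownames(X)))
  fit <- fit_linear_models(Y, X)
  prior0 <- list(df_prior = 0, var_prior = rep(1, 60))
  st <- moderated_t_test(fit, prior0, "cofactor_effect")
  j <- which(colnames(X) == "cofactor")
  t_classic <- fit$coefficients[, j] /
    sqrt(fit$sigma2 * fit$unscaled_variances[j])
  expect_equal(st$t, unname(t_classic), tolerance = 1e-12)
  expect_equal(st$p_value,
               unname(2 * pt(-abs(t_classic), df = fit$df_residual)),
               tolerance = 1e-12)
  # per-protein classical t via lm() on one protein agrees
  sm <- summary(lm(Y[5, ] ~ 0 + X))
  expect_equal(unname(st$t[5]), unname(sm$coefficients[j, "t value"]),
               tolerance = 1e-9)
})

test_that("huge prior df converges to the normal-reference closed form", {
  set.seed(13)
  X <- cofactor_design(cofactor_layout())
  Y <- matrix(rnorm(50 * 12, 8), 50, 12,
              dimnames = list(sprintf("P%02d", 1:50), rownames(X)))
  fit <- fit_linear_models(Y, X)
  j <- which(colnames(X) == "cofactor")
  s0 <- rep(0.8, 50)
  st_big <- moderated_t_test(fit, list(df_prior = 1e8, var_prior = s0),
                             "cofactor_effect")
  t_limit <- fit$coefficients[, j] / sqrt(s0 * fit$unscaled_variances[j])
  expect_equal(st_big$t, unname(t_limit), tolerance = 1e-6)
  st_inf <- moderated_t_test(fit, list(df_prior = Inf, var_prior = s0),
                             "cofactor_effect")
  expect_equal(st_inf$p_value, unname(2 * pnorm(-abs(t_limit))),
               tolerance = 1e-10)
})

test_that("moderated pipeline agrees with the established implementation", {
  cfg <- simulation_config("cofactor", n_proteins = 1500, seed = 17)
  sim <- generate_experiment(cfg)
  res <- run_cofactor_analysis(sim)
  efit <- limma::eBayes(limma::lmFit(res$norm$log2pm, res$design), trend = TRUE)
  j <- which(colnames(res$design) == "cofactor")
  expect_equal(res$stats$estimate, unname(efit$coefficients[, j]),
               tolerance = 1e-9)
  # trend smoothers differ (lowess here, regression splines there), so
  # moderated statistics agree closely but not to machine precision
  expect_gt(cor(res$stats$t, efit$t[, j]), 0.999)
  expect_lt(median(abs(res$stats$p_value - efit$p.value[, j])), 1e-3)
})

test_that("BH adjustment matches the literal step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(adjust_bh(1), 1)
  set.seed(19)
  for (i in 1:5) {
    p <- runif(200)^(i / 2)
    expect_equal(adjust_bh(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
  p_tied <- c(0.02, 0.02, 0.5, 0.5, 1)
  expect_equal(adjust_bh(p_tied), bh_stepup_oracle(p_tied))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_bh(c(0.5, NA)), "finite")
  # adjusted never below raw
  p <- runif(100)
  expect_true(all(adjust_bh(p) >= p))
})

test_that("significance calls use a strict threshold on adjusted p", {
  expect_true(call_significance(0.0099, alpha = 0.01))
  expect_false(call_significance(0.01, alpha = 0.01))
  expect_true(all(call_significance(runif(20), alpha = 1)))
})
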