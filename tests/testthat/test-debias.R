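debias_fixture <- function(n = 50, seed = 23) {
  set.seed(seed)
  X <- cofactor_design(cofactor_layout())
  truth_rep <- 0.7
  obs <- layout_observations(cofactor_layout())
  mu <- outer(rnorm(n, 8), rep(1, 12)) +
    outer(rnorm(n, 0, 0.5), X[, "cofactor"]) +
    truth_rep * matrix(as.numeric(obs$replicate == "R2"), n, 12, byrow = TRUE)
  Y <- mu + matrix(rnorm(n * 12, sd = 0.2), n, 12)
  dimnames(Y) <- list(sprintf("P%03d", seq_len(n)), rownames(X))
  list(Y = Y, X = X, fit = fit_linear_models(Y, X))
}

test_that("bias removal is exact: nuisance refits vanish, effects unchanged", {
  fx <- debias_fixture()
  deb <- remove_bias(fx$Y, fx$fit)
  expect_equal(deb$removed_roles, c("replicate_bias", "intercept"))
  refit <- fit_linear_models(deb$values, fx$X)
  expect_lt(max(abs(refit$coefficients[, c("intercept", "rep_R2")])), 1e-10)
  # tested effects and residual variances untouched
  expect_equal(refit$coefficients[, "cofactor"],
               fx$fit$coefficients[, "cofactor"], tolerance = 1e-10)
  expect_equal(refit$sigma2, fx$fit$sigma2, tolerance = 1e-10)
  # invariant: values = Y - X_bias %*% beta_bias exactly
  bias_cols <- c("intercept", "rep_R2")
  expect_equal(deb$values,
               fx$Y - fx$fit$coefficients[, bias_cols] %*%
                 t(fx$X[, bias_cols]), tolerance = 1e-14)
})

test_that("debiasing with no roles is the identity and twice is idempotent", {
  fx <- debias_fixture(n = 20, seed = 29)
  expect_equal(remove_bias(fx$Y, fx$fit, roles = character(0))$values, fx$Y)
  deb1 <- remove_bias(fx$Y, fx$fit)
  fit2 <- fit_linear_models(deb1$values, fx$X)
  deb2 <- remove_bias(deb1$values, fit2)
  expect_equal(deb2$values, deb1$values, tolerance = 1e-10)
  expect_error(remove_bias(fx$Y, fx$fit, roles = "inhibition_effect"),
               "absent")
})

test_that("dose-response profiles average replicates per condition", {
  layout <- inhibitor_layout()
  obs <- layout_observations(layout)
  V <- matrix(5, 2, nrow(obs),
              dimnames = list(c("Pa", "Pb"), obs$key))
  prof <- dose_response_profile("Pa", V, layout)
  expect_equal(prof$mean_log2, rep(5, 10))
  expect_equal(sort(unique(prof$conc_uM)), c(0, 0.2, 1, 5, 25))
  expect_equal(sort(unique(prof$inhibitor)), c("Olaparib", "Rucaparib"))
  expect_error(dose_response_profile("nope", V, layout), "unknown protein")

  # constructed monotone response: -0.3 log2 per log10 step above 0.1 uM
  slope <- -0.3
  y <- ifelse(obs$conc_uM > 0, slope * log10(obs$conc_uM / 0.1), 0)
  V2 <- matrix(y, 1, nrow(obs), byrow = TRUE,
               dimnames = list("Pm", obs$key))
  prof2 <- dose_response_profile("Pm", V2, layout)
  ola <- prof2[prof2$inhibitor == "Olaparib", ]
  expect_equal(ola$mean_log2[order(ola$conc_uM)],
               c(0, slope * log10(c(0.2, 1, 5, 25) / 0.1)), tolerance = 1e-12)
  # single replicate: means equal raw values
  lay1 <- inhibitor_layout(replicates = "R1")
  obs1 <- layout_observations(lay1)
  V3 <- matrix(rnorm(10), 1, 10, dimnames = list("Ps", obs1$key))
  prof3 <- dose_response_profile("Ps", V3, lay1)
  expect_equal(sort(prof3$mean_log2), sort(unname(V3[1, ])))
})

test_that("inhibitor responses contrast high dose against vehicle baseline", {
  layout <- inhibitor_layout(replicates = "R1")
  obs <- layout_observations(layout)
  y <- numeric(10)
  y[obs$conc_uM == 0] <- 1                           # baseline 1
  y[obs$inhibitor == "Olaparib" & obs$conc_uM == 25] <- -0.5
  y[obs$inhibitor == "Rucaparib" & obs$conc_uM == 25] <- 2
  V <- matrix(y, 1, 10, byrow = TRUE, dimnames = list("Pr", obs$key))
  resp <- inhibitor_responses(V, layout)
  expect_equal(resp$olaparib_response, -1.5)
  expect_equal(resp$rucaparib_response, 1)
})

test_that("volcano records carry -log10 adjusted p with a cap", {
  fx <- debias_fixture(n = 30, seed = 31)
  prior <- suppressWarnings(estimate_variance_prior(fx$fit, trend = FALSE))
  st <- moderated_t_test(fx$fit, prior, "cofactor_effect")
  st$p_adjusted[1] <- 0.01
  st$p_adjusted[2] <- 0
  v <- export_volcano(st, known_targets = rep(c(TRUE, FALSE), c(10, 20)))
  expect_equal(v$neg_log10_padj[1], 2)
  expect_equal(v$neg_log10_padj[2], 16)
  expect_true(v$capped[2])
  expect_false(v$capped[1])
  expect_equal(v$effect, st$estimate)
  expect_equal(sum(v$known_target), 10)
})
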