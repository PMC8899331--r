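twelve_row_fixture <- function() {
  data.frame(group = rep(c("healthy", "aMCI", "AD"), each = 4),
             x = c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0, 0, 1))
}

test_that("intercept-only model: Nagelkerke 0, modal-group predictions", {
  df <- data.frame(group = rep(c("healthy", "aMCI", "AD"), c(5, 4, 3)))
  f <- fit_multinomial(df)
  expect_equal(f$nagelkerke_r2, 0, tolerance = 1e-9)
  expect_equal(f$model_chisq, 0, tolerance = 1e-9)
  expect_true(all(f$confusion$counts[, "healthy"] ==
                    rowSums(f$confusion$counts)))
  # fitted probabilities equal observed shares
  expect_equal(unname(f$fitted[1, ]), c(5, 4, 3) / 12, tolerance = 1e-6)
})

test_that("fitted log-likelihood matches the grid-search oracle", {
  df <- twelve_row_fixture()
  f <- fit_multinomial(df, "x")
  y <- factor(df$group, levels = c("healthy", "aMCI", "AD"))
  X <- cbind(1, df$x)
  o <- grid_oracle_multinom(X, y)
  expect_lt(abs(f$log_lik - o$log_lik), 1e-3)
  expect_gte(f$log_lik, o$log_lik - 1e-3)
  # coefficients agree with the oracle's argmax
  expect_equal(f$coefficients$b, o$beta, tolerance = 1e-2)
})

test_that("Exp(B) is exactly exp(B) with matching Wald CIs", {
  f <- fit_multinomial(twelve_row_fixture(), "x")
  expect_equal(f$coefficients$exp_b, exp(f$coefficients$b), tolerance = 1e-9)
  expect_equal(f$coefficients$ci_lower,
               exp(f$coefficients$b - 1.96 * f$coefficients$se),
               tolerance = 1e-9)
  expect_equal(f$coefficients$wald,
               (f$coefficients$b / f$coefficients$se)^2, tolerance = 1e-9)
})

test_that("confusion matrices conserve group sizes and rates", {
  scen <- default_paper_like_scenario(5)
  m <- cohort_metrics_table(scen$records, scen$labeling)
  f <- fit_multinomial(m, c("n_words", "age"))
  cm <- f$confusion
  expect_equal(unname(rowSums(cm$counts)), unname(table(m$group)[rownames(cm$counts)]),
               ignore_attr = TRUE)
  expect_equal(cm$overall_percent,
               100 * sum(diag(cm$counts)) / sum(cm$counts))
  # overall rate is the group-size-weighted mean of per-group rates
  w <- rowSums(cm$counts) / sum(cm$counts)
  expect_equal(cm$overall_percent, sum(w * cm$percent_correct))
})

test_that("per-predictor LR tests have 2 df and are order-invariant", {
  scen <- default_paper_like_scenario(6)
  m <- cohort_metrics_table(scen$records, scen$labeling)
  f <- fit_multinomial(m, c("n_words", "age", "adj_returns"))
  expect_equal(f$predictor_lr$df, rep(2L, 3))
  expect_true(all(f$predictor_lr$lr_chisq >= 0))
  expect_equal(f$model_df, 6L)
  # model chi-square equals the LR against the intercept-only fit
  f0 <- fit_multinomial(m)
  expect_equal(f$model_chisq, 2 * (f$log_lik - f0$log_lik), tolerance = 1e-6)
  expect_equal(f$aic, 2 * f$n_parameters - 2 * f$log_lik)
  expect_equal(f$bic, f$n_parameters * log(f$n) - 2 * f$log_lik)
})

test_that("near-separable data with ridge fallback reach R2 > 0.95", {
  set.seed(60)
  n <- 20
  df <- data.frame(
    group = rep(c("healthy", "aMCI", "AD"), each = n),
    z = c(rnorm(n, 0, 0.1), rnorm(n, 6, 0.1), rnorm(n, 12, 0.1)))
  f <- suppressWarnings(fit_multinomial(df, "z", penalty = 1e-4))
  expect_gt(f$nagelkerke_r2, 0.95)
  expect_true(f$nagelkerke_r2 <= 1)
  # unpenalized fit on the same data flags separation
  expect_warning(fit_multinomial(df, "z"), "separation")
})

test_that("collinear predictors trigger a condition-number warning", {
  scen <- default_paper_like_scenario(7)
  m <- cohort_metrics_table(scen$records, scen$labeling)
  m$n_words_copy <- m$n_words * 2 + 1e-8 * rnorm(nrow(m))
  w <- capture_warnings(fit_multinomial(m, c("n_words", "n_words_copy")))
  expect_true(any(grepl("collinear", w)))
})

test_that("model suite fits Models 1-4 independently with shared reference", {
  scen <- default_paper_like_scenario(8)
  m <- cohort_metrics_table(scen$records, scen$labeling)
  suite <- model_suite(m)
  expect_named(suite$models, paste0("model", 1:4))
  expect_equal(nrow(suite$comparison), 4L)
  expect_named(suite$confusions, c("model1", "model4"))
  expect_true(all(grepl("vs AD", suite$models$model4$coefficients$contrast)))
  # Model 1 parameters are unchanged by Model 4's existence
  alone <- fit_multinomial(m, c("n_words", "age"), model_id = "model1")
  expect_equal(suite$models$model1$coefficients$b, alone$coefficients$b,
               tolerance = 1e-9)
  # Model 4 nests Model 1: its likelihood cannot be worse
  expect_gte(suite$models$model4$log_lik, suite$models$model1$log_lik - 1e-6)
})

test_that("planted returns effect raises Model 4 over Model 1", {
  scen <- default_paper_like_scenario(9)
  m <- cohort_metrics_table(scen$records, scen$labeling)
  suite <- model_suite(m)
  expect_gt(suite$models$model4$nagelkerke_r2,
            suite$models$model1$nagelkerke_r2)
  # recovered contrast signs: healthy and aMCI show more returning than AD
  co <- suite$models$model4$coefficients
  b_ret <- co$b[co$term == "adj_returns"]
  expect_true(all(b_ret > 0))
})
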