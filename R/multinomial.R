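#' Multinomial logistic regression for diagnostic-group prediction
#'
#' Maximum-likelihood multinomial logit with one linear predictor set per
#' non-reference group (contrast against the reference, default `"AD"` so
#' contrasts read "healthy vs AD" and "aMCI vs AD"). Fitted by BFGS on the
#' analytic log-likelihood and gradient; Wald standard errors come from the
#' numerically differentiated Hessian at the optimum; per-predictor
#' significance from likelihood-ratio refits.
#'
#' @param metrics cohort metrics table (or any data frame with a `group`
#'   column over [fluency_groups] plus the predictor columns).
#' @param predictors character vector of predictor column names (may be
#'   empty for the intercept-only model).
#' @param reference reference group label. Default `"AD"`.
#' @param penalty optional ridge penalty `lambda/2 * sum(beta^2)` on the
#'   non-intercept coefficients (0 = plain ML). Used as a fallback for
#'   (near-)separable data.
#' @param model_id label carried into reports.
#' @param lr_tests compute per-predictor likelihood-ratio refits (default
#'   `TRUE`).
#' @return object of class `multinom_result`; see Details.
#' @details Fields: `coefficients` (per contrast: B, SE, Wald, p, Exp(B)
#'   with 95 percent CI), `log_lik`, `null_log_lik`, `model_chisq` (+ df, p),
#'   `predictor_lr` (per-predictor chi-square, df, p), `nagelkerke_r2`,
#'   `aic`, `bic` (`AIC = 2p - 2LL`, `BIC = p log n - 2LL`), `fitted`
#'   (probability matrix), `confusion` ([confusion_matrix]), `converged`,
#'   `separation` flag, `n`, `n_parameters`.
#' @export
fit_multinomial <- function(metrics, predictors = character(0),
                            reference = "AD", penalty = 0,
                            model_id = NULL, lr_tests = TRUE) {
  df <- as.data.frame(metrics)
  if (!"group" %in% names(df)) stop("metrics must contain a 'group' column")
  y <- as.character(df$group)
  levs <- unique(c(setdiff(fluency_groups(), reference)))
  levs <- c(levs[levs %in% y], reference)
  if (!reference %in% y) stop("reference group ", reference, " absent from data")
  bad <- setdiff(unique(y), fluency_groups())
  if (length(bad) > 0L) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  y <- factor(y, levels = levs)  # reference last
  miss <- setdiff(predictors, names(df))
  if (length(miss) > 0L) stop("predictor column(s) missing: ",
                              paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(df[, predictors, drop = FALSE]))
  storage.mode(X) <- "double"
  if (length(predictors) > 1L) {
    kappa_x <- kappa(scale(X[, -1L, drop = FALSE]), exact = TRUE)
    if (is.finite(kappa_x) && kappa_x > 30)
      warning(sprintf(
        "predictors are (near-)collinear (condition number %.1f); ",
        kappa_x), "coefficients may be unstable")
  }
  fit <- multinom_ml(X, y, penalty = penalty)
  n <- length(y); K1 <- nlevels(y) - 1L; P <- ncol(X)
  npar <- K1 * P
  # null (intercept-only) log-likelihood for chi-square / pseudo-R2
  ll0 <- if (P == 1L) fit$log_lik else
    multinom_ml(X[, 1L, drop = FALSE], y, penalty = 0)$log_lik
  chisq <- max(0, 2 * (fit$log_lik - ll0))
  chisq_df <- K1 * (P - 1L)
  r2_cs <- 1 - exp(2 * (ll0 - fit$log_lik) / n)
  r2_max <- 1 - exp(2 * ll0 / n)
  nagelkerke <- if (r2_max > 0) r2_cs / r2_max else 0
  # Wald machinery
  se <- wald <- pw <- fit$beta * NA_real_
  if (all(is.finite(fit$hessian))) {
    vc <- try(solve(fit$hessian), silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc) > 0)) {
      se[] <- sqrt(diag(vc))
      wald <- (fit$beta / se)^2
      pw <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
    }
  }
  coefs <- lapply(seq_len(K1), function(k) {
    idx <- (k - 1L) * P + seq_len(P)
    data.frame(contrast = paste(levels(y)[k], "vs", reference),
               term = colnames(X), b = fit$beta[idx], se = se[idx],
               wald = wald[idx], p_wald = pw[idx],
               exp_b = exp(fit$beta[idx]),
               ci_lower = exp(fit$beta[idx] - 1.96 * se[idx]),
               ci_upper = exp(fit$beta[idx] + 1.96 * se[idx]),
               row.names = NULL)
  })
  coefs <- do.call(rbind, coefs)
  # per-predictor LR tests (refit without each predictor, both contrasts)
  pred_lr <- NULL
  if (lr_tests && length(predictors) > 0L) {
    pred_lr <- do.call(rbind, lapply(predictors, function(p) {
      Xr <- X[, setdiff(colnames(X), p), drop = FALSE]
      llr <- multinom_ml(Xr, y, penalty = penalty)$log_lik
      lr <- max(0, 2 * (fit$log_lik - llr))
      data.frame(predictor = p, lr_chisq = lr, df = K1,
                 p_value = stats::pchisq(lr, df = K1, lower.tail = FALSE))
    }))
  }
  probs <- multinom_probs(X, matrix(fit$beta, nrow = K1, byrow = TRUE))
  colnames(probs) <- levels(y)
  pred <- factor(levels(y)[max.col(probs, ties.method = "first")],
                 levels = levels(y))
  structure(list(
    model_id = model_id %||% paste(predictors, collapse = "+"),
    predictors = predictors, reference = reference,
    coefficients = coefs, log_lik = fit$log_lik, null_log_lik = ll0,
    model_chisq = chisq, model_df = chisq_df,
    model_p = stats::pchisq(chisq, df = max(1L, chisq_df), lower.tail = FALSE),
    predictor_lr = pred_lr, nagelkerke_r2 = nagelkerke,
    aic = 2 * npar - 2 * fit$log_lik,
    bic = npar * log(n) - 2 * fit$log_lik,
    fitted = probs, confusion = confusion_matrix(y, pred),
    converged = fit$converged, separation = fit$separation,
    n = n, n_parameters = npar), class = "multinom_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Core ML fit: y a factor with the REFERENCE level LAST; X the design
# matrix including intercept. Coefficients are stored contrast-major
# (contrast 1 terms, contrast 2 terms, ...).
multinom_ml <- function(X, y, penalty = 0) {
  K <- nlevels(y); K1 <- K - 1L; P <- ncol(X); n <- nrow(X)
  Yind <- outer(as.integer(y), seq_len(K1), `==`) * 1  # n x K1 indicators
  pen_mask <- rep(rep(c(0, 1), c(1L, P - 1L)), K1)     # no penalty on intercepts
  negll <- function(beta) {
    B <- matrix(beta, nrow = K1, byrow = TRUE)
    eta <- X %*% t(B)
    # numerically stable log-sum-exp over (0, eta_1..eta_K1)
    mx <- pmax(0, apply(eta, 1L, max))
    lse <- mx + log(exp(-mx) + rowSums(exp(eta - mx)))
    ll <- sum(Yind * eta) - sum(lse)
    -(ll) + penalty / 2 * sum((beta * pen_mask)^2)
  }
  grad <- function(beta) {
    B <- matrix(beta, nrow = K1, byrow = TRUE)
    Pr <- multinom_probs(X, B)[, seq_len(K1), drop = FALSE]
    G <- crossprod(X, Pr - Yind)          # P x K1, d(-ll)/dB[k, p] = G[p, k]
    g <- as.numeric(G)                    # contrast-major ordering
    g + penalty * beta * pen_mask
  }
  beta0 <- numeric(K1 * P)
  opt <- stats::optim(beta0, negll, grad, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-12))
  hess <- stats::optimHess(opt$par, negll, grad)
  # separation heuristic: runaway standardized coefficients
  sds <- apply(X, 2L, stats::sd); sds[sds == 0] <- 1
  bstd <- matrix(opt$par, nrow = K1, byrow = TRUE) %*% diag(sds, P, P)
  separation <- any(abs(bstd[, -1L, drop = FALSE]) > 25) ||
    (P > 1L && penalty == 0 && any(!is.finite(hess)))
  if (separation && penalty == 0)
    warning("possible (quasi-)separation: coefficient estimates are not ",
            "trustworthy; consider a ridge penalty")
  list(beta = opt$par, log_lik = -(negll(opt$par)) +
         penalty / 2 * sum((opt$par * pen_mask)^2),
       converged = opt$convergence == 0L, hessian = hess,
       separation = separation)
}

multinom_probs <- function(X, B) {
  eta <- X %*% t(B)                        # n x K1
  mx <- pmax(0, apply(eta, 1L, max))
  denom <- exp(-mx) + rowSums(exp(eta - mx))
  cbind(exp(eta - mx), exp(-mx)) / denom   # cols: contrasts..., reference
}

#' @export
print.multinom_result <- function(x, ...) {
  cat(sprintf(
    "<multinom_result '%s': chi^2(%d) = %.2f, p = %.4g, Nagelkerke R^2 = %.3f, AIC = %.2f, BIC = %.2f>\n",
    x$model_id, x$model_df, x$model_chisq, x$model_p, x$nagelkerke_r2,
    x$aic, x$bic))
  if (!x$converged) cat("  [optimizer did not converge]\n")
  if (x$separation) cat("  [separation suspected]\n")
  invisible(x)
}

#' Confusion matrix with classification rates
#'
#' @param observed,predicted factors over the same levels.
#' @return object of class `confusion_matrix`: `counts` (observed rows x
#'   predicted columns), `percent_correct` per group, `overall_percent`,
#'   `predicted_share` (column percentages of total).
#' @export
confusion_matrix <- function(observed, predicted) {
  lv <- levels(observed)
  counts <- table(observed = observed,
                  predicted = factor(predicted, levels = lv))
  counts <- unclass(counts)
  per_group <- ifelse(rowSums(counts) > 0,
                      100 * diag(counts) / rowSums(counts), NA_real_)
  structure(list(counts = counts,
                 percent_correct = per_group,
                 overall_percent = 100 * sum(diag(counts)) / sum(counts),
                 predicted_share = 100 * colSums(counts) / sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- cbind(x$counts, `correct (%)` = round(x$percent_correct, 1))
  print(m)
  cat(sprintf("overall correct: %.1f%%\n", x$overall_percent))
  invisible(x)
}

#' Fit the standard four-model comparison suite
#'
#' Model 1: number of words + age. Models 2-4 add, respectively, adjusted
#' switches, number of sub-categories, and adjusted returns (one addition
#' each; predictors are never combined across models because of their
#' collinearity). All models share the reference group. Classification
#' tables are reported for Models 1 and 4.
#'
#' @param metrics cohort metrics table.
#' @param reference reference group. Default `"AD"`.
#' @param penalty forwarded to [fit_multinomial].
#' @return object of class `model_suite`: `models` (named list of
#'   `multinom_result`), `comparison` data frame (chi-square, pseudo-R2,
#'   BIC, AIC, p), `confusions` (Models 1 and 4).
#' @export
model_suite <- function(metrics, reference = "AD", penalty = 0) {
  spec <- list(
    model1 = c("n_words", "age"),
    model2 = c("n_words", "age", "adj_switches"),
    model3 = c("n_words", "age", "n_subcategories"),
    model4 = c("n_words", "age", "adj_returns"))
  models <- lapply(names(spec), function(id)
    fit_multinomial(metrics, spec[[id]], reference = reference,
                    penalty = penalty, model_id = id))
  names(models) <- names(spec)
  comparison <- do.call(rbind, lapply(models, function(m)
    data.frame(model = m$model_id, chisq = m$model_chisq, df = m$model_df,
               nagelkerke_r2 = m$nagelkerke_r2, bic = m$bic, aic = m$aic,
               p = m$model_p)))
  rownames(comparison) <- NULL
  structure(list(models = models, comparison = comparison,
                 confusions = list(model1 = models$model1$confusion,
                                   model4 = models$model4$confusion)),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("<model_suite>\n")
  print(x$comparison, digits = 4)
  invisible(x)
}
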