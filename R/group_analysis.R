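#' Spearman correlation table of the fluency variables
#'
#' Rank correlations between the six movement variables (words,
#' sub-categories, switches, adjusted switches, returns, adjusted returns)
#' with per-pair p-values and significance stars
#' (`* p < .05, ** p < .01, *** p < .001`).
#'
#' @param metrics cohort metrics table from [cohort_metrics_table].
#' @param variables columns to correlate; defaults to the six fluency
#'   variables.
#' @return object of class `correlation_table`: `rho` (symmetric, unit
#'   diagonal), `p_value`, `stars` (character matrix), `n`.
#' @export
spearman_table <- function(metrics,
                           variables = c("n_words", "n_subcategories",
                                         "n_switches", "adj_switches",
                                         "n_returns", "adj_returns")) {
  if (nrow(metrics) < 3L) stop("need at least 3 participants")
  X <- as.matrix(metrics[, variables, drop = FALSE])
  const <- apply(X, 2L, function(v) length(unique(v)) < 2L)
  if (any(const))
    warning("constant column(s), correlations undefined: ",
            paste(variables[const], collapse = ", "))
  p <- length(variables)
  rho <- diag(1, p); pv <- matrix(NA_real_, p, p)
  dimnames(rho) <- dimnames(pv) <- list(variables, variables)
  for (i in seq_len(p - 1L)) for (j in seq(i + 1L, p)) {
    if (const[i] || const[j]) { rho[i, j] <- rho[j, i] <- NA_real_; next }
    ct <- suppressWarnings(
      stats::cor.test(X[, i], X[, j], method = "spearman", exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  stars <- matrix("", p, p, dimnames = dimnames(rho))
  stars[!is.na(pv) & pv < 0.05] <- "*"
  stars[!is.na(pv) & pv < 0.01] <- "**"
  stars[!is.na(pv) & pv < 0.001] <- "***"
  structure(list(rho = rho, p_value = pv, stars = stars, n = nrow(X)),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  cat(sprintf("<correlation_table: Spearman rho over n = %d participants>\n",
              x$n))
  m <- matrix(paste0(formatC(x$rho, format = "f", digits = 2), x$stars),
              nrow(x$rho), dimnames = dimnames(x$rho))
  diag(m) <- "1"
  print(m, quote = FALSE)
  invisible(x)
}

#' One-way ANOVA with partial eta-squared and Bonferroni pairwise tests
#'
#' `F = MSB / MSW`; `partial eta^2 = SSB / (SSB + SSW)` (equal to plain
#' eta-squared in the one-way design). Pairwise comparisons are pooled-SD t
#' tests with Bonferroni-adjusted p-values.
#'
#' @param values numeric response, one per participant.
#' @param groups group labels (factor or character).
#' @return object of class `group_test`: `statistic` (F), `df` (between,
#'   within), `p_value`, `partial_eta_sq`, `pairwise` data frame
#'   (group_a, group_b, p_adjusted), `means`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  g <- nlevels(groups)
  if (g < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 members")
  n <- length(values)
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- g - 1L; df2 <- n - g
  if (ssw <= 0 && ssb <= 0) stop("zero variance everywhere; F undefined")
  if (ssw <= 0) stop("zero within-group variance; F undefined")
  f <- (ssb / df1) / (ssw / df2)
  pw <- NULL
  lev <- levels(groups)
  mse <- ssw / df2
  for (i in seq_len(g - 1L)) for (j in seq(i + 1L, g)) {
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    tval <- (means[i] - means[j]) / se
    praw <- 2 * stats::pt(-abs(tval), df2)
    pw <- rbind(pw, data.frame(group_a = lev[i], group_b = lev[j],
                               diff = unname(means[i] - means[j]),
                               p_raw = unname(praw),
                               p_adjusted = unname(min(1, praw * choose(g, 2)))))
  }
  structure(list(statistic = f, df = c(between = df1, within = df2),
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 partial_eta_sq = ssb / (ssb + ssw),
                 pairwise = pw, means = means),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  if (!is.null(x$wilks_lambda))
    cat(sprintf(
      "<group_test (MANOVA): F(%g, %g) = %.2f, p = %.4g, Wilks' lambda = %.3f, partial eta^2 = %.3f>\n",
      x$df[1], x$df[2], x$statistic, x$p_value, x$wilks_lambda,
      x$partial_eta_sq))
  else
    cat(sprintf(
      "<group_test (ANOVA): F(%d, %d) = %.2f, p = %.4g, partial eta^2 = %.3f>\n",
      x$df[1], x$df[2], x$statistic, x$p_value, x$partial_eta_sq))
  invisible(x)
}

#' One-way MANOVA via Wilks' lambda
#'
#' Computes the hypothesis (H) and error (E) SSCP matrices,
#' `lambda = det(E) / det(H + E)`, Rao's F approximation, and the
#' multivariate `partial eta^2 = 1 - lambda^(1/s)` with
#' `s = min(#DVs, #groups - 1)`. Implemented directly so the one-DV case
#' degenerates exactly to the univariate F.
#'
#' @param dependents numeric matrix or data frame of dependent variables
#'   (one row per participant).
#' @param groups group labels.
#' @return object of class `group_test` with fields `statistic` (approx. F),
#'   `df` (df1, df2), `p_value`, `wilks_lambda`, `partial_eta_sq`.
#' @export
manova_wilks <- function(dependents, groups) {
  Y <- as.matrix(dependents)
  groups <- droplevels(as.factor(groups))
  g <- nlevels(groups)
  if (g < 2L) stop("need at least 2 groups")
  p <- ncol(Y); n <- nrow(Y)
  if (min(table(groups)) <= p)
    stop("each group needs more members than there are dependent variables")
  grand <- colMeans(Y)
  E <- matrix(0, p, p); H <- matrix(0, p, p)
  for (lv in levels(groups)) {
    Yg <- Y[groups == lv, , drop = FALSE]
    mg <- colMeans(Yg)
    C <- sweep(Yg, 2L, mg)
    E <- E + crossprod(C)
    H <- H + nrow(Yg) * tcrossprod(mg - grand)
  }
  detE <- det(E)
  if (!is.finite(detE) || detE <= .Machine$double.eps * max(abs(E))^p)
    stop("error SSCP matrix is (near-)singular: dependent variables are ",
         "collinear; drop or combine DVs")
  lambda <- detE / det(H + E)
  q <- g - 1L; v <- n - g
  t_exp <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- v + q - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * t_exp - (p * q - 2) / 2
  lam_t <- lambda^(1 / t_exp)
  f <- ((1 - lam_t) / lam_t) * (df2 / df1)
  s <- min(p, q)
  structure(list(statistic = f, df = c(df1 = df1, df2 = df2),
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 wilks_lambda = lambda,
                 partial_eta_sq = 1 - lambda^(1 / s)),
            class = "group_test")
}

#' ANOVA report over all fluency variables
#'
#' Convenience wrapper: one-way ANOVA per movement variable plus the MANOVA
#' over the four DVs used for multivariate control of type-1 error
#' (sub-categories, switches, adjusted switches, adjusted returns).
#'
#' @param metrics cohort metrics table.
#' @return list with `anova` (named list of `group_test`) and `manova`.
#' @export
group_difference_report <- function(metrics) {
  vars <- c("n_words", "n_subcategories", "n_switches", "adj_switches",
            "n_returns", "adj_returns")
  an <- lapply(vars, function(v) oneway_anova(metrics[[v]], metrics$group))
  names(an) <- vars
  mdv <- c("n_subcategories", "n_switches", "adj_switches", "adj_returns")
  list(anova = an,
       manova = manova_wilks(metrics[, mdv], metrics$group),
       manova_dependents = mdv)
}
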