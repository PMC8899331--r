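# Independent oracles, written deliberately differently from the package
# implementations they check.

# Run-length scorer: explicit loop, no rle(). Returns the same fields as
# compute_metrics plus the ordered run table.
rle_oracle <- function(labels) {
  n <- length(labels)
  if (n == 0L) {
    return(list(n_words = 0L, n_subcategories = 0L, n_switches = 0L,
                n_returns = 0L, adj_switches = 0, adj_returns = 0,
                runs = data.frame(label = character(0), length = integer(0),
                                  visit = integer(0))))
  }
  run_label <- character(0); run_len <- integer(0)
  for (i in seq_len(n)) {
    if (i == 1L || labels[i] != labels[i - 1L]) {
      run_label <- c(run_label, labels[i]); run_len <- c(run_len, 1L)
    } else {
      run_len[length(run_len)] <- run_len[length(run_len)] + 1L
    }
  }
  switches <- 0L
  for (i in seq_len(n - 1L)) if (labels[i] != labels[i + 1L])
    switches <- switches + 1L
  returns <- 0L; seen <- character(0); visit <- integer(length(run_label))
  for (j in seq_along(run_label)) {
    visit[j] <- sum(run_label[seq_len(j)] == run_label[j])
    if (run_label[j] %in% seen) returns <- returns + 1L
    seen <- c(seen, run_label[j])
  }
  list(n_words = n, n_subcategories = length(unique(labels)),
       n_switches = switches, n_returns = returns,
       adj_switches = 100 * switches / n, adj_returns = 100 * returns / n,
       runs = data.frame(label = run_label, length = run_len, visit = visit))
}

random_label_sequence <- function(alphabet_max = 8L, len_max = 60L) {
  len <- sample.int(len_max + 1L, 1L) - 1L
  k <- sample.int(alphabet_max, 1L)
  if (len == 0L) character(0) else sample(LETTERS[seq_len(k)], len, replace = TRUE)
}

# Multinomial log-likelihood computed directly from softmax probabilities
# (reference level LAST in levels(y)).
oracle_loglik <- function(beta, X, y) {
  K1 <- nlevels(y) - 1L
  B <- matrix(beta, nrow = K1, byrow = TRUE)
  eta <- cbind(X %*% t(B), 0)
  pr <- exp(eta) / rowSums(exp(eta))
  sum(log(pr[cbind(seq_along(y), as.integer(y))]))
}

# Brute-force maximization: cyclic per-coordinate grid refinement of the
# log-likelihood (no gradients, independent of the BFGS path).
grid_oracle_multinom <- function(X, y, sweeps = 80L, span = 8) {
  npar <- (nlevels(y) - 1L) * ncol(X)
  beta <- numeric(npar)
  best <- oracle_loglik(beta, X, y)
  for (s in seq_len(sweeps)) {
    for (j in seq_len(npar)) {
      cand <- beta[j] + seq(-span, span, length.out = 21L)
      lls <- vapply(cand, function(v) {
        b <- beta; b[j] <- v; oracle_loglik(b, X, y)
      }, 0)
      pick <- which.max(lls)
      beta[j] <- cand[pick]; best <- lls[pick]
    }
    span <- span * 0.7
  }
  list(beta = beta, log_lik = best)
}

make_blobs <- function(centers, n_per = 20L, sd = 1, seed = 1L) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2L,
          centers[i, ], `+`)))
  rownames(X) <- sprintf("b%d_%02d", rep(seq_len(nrow(centers)), each = n_per),
                         rep(seq_len(n_per), nrow(centers)))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

tiny_w2v_text <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}
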