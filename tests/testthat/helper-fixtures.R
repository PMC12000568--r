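# shared fixtures and independent oracles

# tiny metabolite table with controllable detection pattern
tiny_table <- function(values, months = c(5, 6, 11)[seq_len(nrow(values))],
                       detected = NULL) {
  metabolite_table(values, months = months, detected = detected)
}

# 9-sample study-design months: 6 rainy (May-Oct), 3 dry (Nov-Jan)
study_months <- c(5:12, 1)

# permutation oracle for the one-tailed Mann-Whitney test: Monte-Carlo
# estimate of P(U* >= U_obs) under random group assignment
mw_permutation_p <- function(x, y, n_draws = 10000) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[(m + 1):(m + n)]) - n * (n + 1) / 2
  hits <- 0
  for (b in seq_len(n_draws)) {
    idx <- sample.int(m + n, n)
    u <- sum(r[idx]) - n * (n + 1) / 2
    if (u >= u_obs - 1e-9) hits <- hits + 1
  }
  hits / n_draws
}

# full-enumeration oracle (exact), independent of the package implementation:
# enumerates group assignments over the raw values, recomputing U from scratch
mw_enumeration_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); n <- length(y)
  count_u <- function(xx, yy)
    sum(outer(yy, xx, ">")) + 0.5 * sum(outer(yy, xx, "=="))
  u_obs <- count_u(x, y)
  sets <- combn(m + n, n)
  stats <- apply(sets, 2, function(idx) count_u(pooled[-idx], pooled[idx]))
  mean(stats >= u_obs - 1e-9)
}

# rank-then-Pearson Spearman oracle
spearman_oracle <- function(x, y) stats::cor(rank(x), rank(y))

# linear-interpolation IQR oracle from first principles on the sorted vector
iqr_oracle <- function(v) {
  s <- sort(v); n <- length(s)
  qq <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  qq(0.75) - qq(0.25)
}

# planted regression problem on standardized iid-normal features
planted_problem <- function(n, p, k, noise_sd, seed) {
  set.seed(seed)
  X <- standardize(matrix(rnorm(n * p), n))
  colnames(X) <- sprintf("m%03d", seq_len(p))
  sup <- sample(p, k)
  beta <- runif(k, 1, 2) * sample(c(-1, 1), k, replace = TRUE)
  y <- drop(X[, sup, drop = FALSE] %*% beta) + rnorm(n, 0, noise_sd)
  list(X = X, y = y, support = colnames(X)[sup], beta = beta)
}
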