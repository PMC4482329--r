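# Small deterministic fixtures built in code.

# tiny longitudinal dataset: g genes x p patients x t times, linear trends
make_tiny_data <- function(g = 3, p = 4, tt = 0:3, seed = 1,
                           slope_sd = 0, slope_mean = 0, sigma = 0.6,
                           sigma_c = 0.3) {
  set.seed(seed)
  grid <- expand.grid(gene = sprintf("g%02d", seq_len(g)),
                      patient = sprintf("P%02d", seq_len(p)),
                      time = tt, stringsAsFactors = FALSE)
  u <- grid$time - mean(tt)
  slopes <- rnorm(g, slope_mean, slope_sd)
  names(slopes) <- sprintf("g%02d", seq_len(g))
  cgp <- rnorm(g * p, 0, sigma_c)
  names(cgp) <- as.vector(outer(sprintf("g%02d", seq_len(g)),
                                sprintf("P%02d", seq_len(p)), paste))
  grid$value <- slopes[grid$gene] * u +
    cgp[paste(grid$gene, grid$patient)] +
    rnorm(nrow(grid), 0, sigma)
  tibble::as_tibble(grid)
}

# exact marginal normal log-likelihood from first principles: covariance
# built record-by-record from the model definition (independent of the
# package's design machinery)
dense_loglik_oracle <- function(df, mean_vec, sigma2, sigma2_c, sigma_h2,
                                basis_fun) {
  n <- nrow(df)
  B <- basis_fun(df$time)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      v <- 0
      if (df$gene[i] == df$gene[j]) {
        if (df$patient[i] == df$patient[j]) v <- v + sigma2_c
        v <- v + sum(sigma_h2 * B[i, ] * B[j, ])
      }
      if (i == j) v <- v + sigma2
      V[i, j] <- v
    }
  }
  r <- df$value - mean_vec
  R <- chol(V)
  w <- backsolve(R, r, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(w^2))
}
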