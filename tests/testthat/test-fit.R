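# Likelihood correctness of the profiled ML fitter.

test_that("model collapses to the iid closed form when no grouping variance exists", {
  # data constructed so every gene-x-patient mean is exactly zero: the
  # variance-ratio estimates must then sit on the boundary and the loglik
  # equal the iid Gaussian ML loglik with per-gene means + pooled variance
  set.seed(3)
  g <- 3; p <- 4; tt <- 0:3
  df <- expand.grid(gene = paste0("g", 1:g), patient = paste0("p", 1:p),
                    time = tt, stringsAsFactors = FALSE)
  df <- df[order(df$gene, df$patient, df$time), ]
  e <- rnorm(nrow(df))
  gp <- paste(df$gene, df$patient)
  df$value <- e - ave(e, gp)          # centre within gene x patient
  d0 <- build_design(tibble::as_tibble(df), tcgsa_spec("linear"), "H0")
  f0 <- fit_ml(d0)
  n <- nrow(df)
  res <- df$value - ave(df$value, df$gene)
  s2 <- sum(res^2) / n
  ll_iid <- -n / 2 * (log(2 * pi * s2) + 1)
  expect_equal(f0$loglik, ll_iid, tolerance = 1e-6)
  expect_lt(f0$varcomp[["sigma2_c"]], 1e-6)
})

test_that("fit_ml beats a brute-force grid over the exact dense likelihood", {
  for (seed in c(2, 5, 9)) {
    df <- make_tiny_data(g = 2, p = 2, tt = 0:2, seed = seed,
                         slope_sd = 0.3, slope_mean = 0.4)
    des <- build_design(df, tcgsa_spec("linear"), "H1")
    fit <- fit_ml(des)
    dfs <- des$data
    t_bar <- mean(unique(dfs$time))
    bfun <- function(t) cbind(t - t_bar)
    gene_means <- ave(dfs$value, dfs$gene)
    best_grid <- -Inf
    for (eta in seq(-1, 1, by = 0.25)) {
      for (s2c in c(0, 0.05, 0.2, 0.5)) {
        for (s2h in c(0, 0.05, 0.2, 0.5)) {
          for (s2 in c(0.2, 0.4, 0.8, 1.5)) {
            mu <- gene_means + eta * (dfs$time - t_bar)
            ll <- dense_loglik_oracle(dfs, mu, s2, s2c, s2h, bfun)
            best_grid <- max(best_grid, ll)
          }
        }
      }
    }
    expect_gte(fit$loglik, best_grid - 1e-6)
  }
})

test_that("profiled fit agrees with lme4 maximum likelihood", {
  skip_if_not_installed("lme4")
  df <- make_tiny_data(g = 4, p = 5, tt = 0:4, seed = 11, slope_sd = 0.2,
                       slope_mean = 0.3)
  des <- build_design(df, tcgsa_spec("linear"), "H1")
  fit <- fit_ml(des)
  dd <- as.data.frame(df)
  dd$u <- dd$time - mean(unique(dd$time))
  dd$gp <- paste(dd$gene, dd$patient)
  m <- lme4::lmer(value ~ gene + u + (1 | gp) + (0 + u | gene), data = dd,
                  REML = FALSE,
                  control = lme4::lmerControl(check.conv.singular = "ignore"))
  expect_equal(fit$loglik, as.numeric(logLik(m)), tolerance = 1e-5)
  # our optimum is never worse
  expect_gte(fit$loglik, as.numeric(logLik(m)) - 1e-6)
})

test_that("loglik_at is self-consistent and matches a first-principles dense oracle", {
  df <- make_tiny_data(g = 3, p = 3, tt = 0:3, seed = 21, slope_sd = 0.25)
  des <- build_design(df, tcgsa_spec("linear"), "H1")
  fit <- fit_ml(des)
  expect_equal(loglik_at(des, fit), fit$loglik, tolerance = 1e-8)

  # arbitrary (non-fitted) parameter values against the oracle
  alpha <- setNames(c(0.1, -0.2, 0.05), des$genes)
  eta <- setNames(0.3, "t1")
  ll_pkg <- loglik_at(des, list(
    fixef = list(alpha = alpha, shared = eta),
    sigma2 = 0.5, varcomp = c(0.12, 0.07)
  ))
  dfs <- des$data
  t_bar <- mean(unique(dfs$time))
  mu <- alpha[dfs$gene] + 0.3 * (dfs$time - t_bar)
  ll_oracle <- dense_loglik_oracle(dfs, mu, 0.5, 0.12, 0.07,
                                   function(t) cbind(t - t_bar))
  expect_equal(ll_pkg, ll_oracle, tolerance = 1e-8)

  # all variances zero except sigma: sum of iid normal log-densities
  ll0 <- loglik_at(des, list(fixef = list(alpha = alpha, shared = eta),
                             sigma2 = 0.5, varcomp = c(0, 0)))
  expect_equal(ll0, sum(dnorm(dfs$value, mu, sqrt(0.5), log = TRUE)),
               tolerance = 1e-10)
  expect_error(loglik_at(des, list(fixef = list(alpha = alpha, shared = eta),
                                   sigma2 = 0.5, varcomp = c(-0.1, 0))),
               ">= 0")
})

test_that("nested fits are monotone and invariant to relabeling and row order", {
  for (seed in c(4, 14)) {
    df <- make_tiny_data(g = 3, p = 4, tt = 0:3, seed = seed,
                         slope_sd = 0.15, slope_mean = 0.1)
    f0 <- fit_ml(build_design(df, tcgsa_spec("linear"), "H0"))
    f1 <- fit_ml(build_design(df, tcgsa_spec("linear"), "H1"))
    expect_gte(f1$loglik, f0$loglik - 1e-6)

    # permute rows and relabel genes/patients: same maximised likelihood
    perm <- df[sample(nrow(df)), ]
    perm$gene <- paste0("z_", perm$gene)
    perm$patient <- paste0("w_", perm$patient)
    f1p <- fit_ml(build_design(perm, tcgsa_spec("linear"), "H1"))
    expect_equal(f1p$loglik, f1$loglik, tolerance = 1e-6)
    expect_equal(unname(f1p$varcomp), unname(f1$varcomp), tolerance = 1e-4)
  }
})

test_that("adding a constant shifts only the set-level mean", {
  df <- make_tiny_data(g = 3, p = 4, tt = 0:3, seed = 8, slope_sd = 0.15)
  f <- fit_ml(build_design(df, tcgsa_spec("linear"), "H1"))
  df2 <- dplyr::mutate(df, value = value + 5)
  f2 <- fit_ml(build_design(df2, tcgsa_spec("linear"), "H1"))
  expect_equal(f2$coefficients$mu, f$coefficients$mu + 5, tolerance = 1e-5)
  expect_equal(unname(f2$varcomp), unname(f$varcomp), tolerance = 1e-5)
  expect_equal(f2$sigma2, f$sigma2, tolerance = 1e-7)
  # H1 - H0 loglik difference unchanged
  f0 <- fit_ml(build_design(df, tcgsa_spec("linear"), "H0"))
  f02 <- fit_ml(build_design(df2, tcgsa_spec("linear"), "H0"))
  expect_equal(f2$loglik - f02$loglik, f$loglik - f0$loglik,
               tolerance = 1e-6)
})

test_that("deleting a patient equals fitting the reduced dataset directly", {
  df <- make_tiny_data(g = 3, p = 4, tt = 0:3, seed = 13, slope_sd = 0.2)
  reduced <- df[df$patient != "P03", ]
  f_del <- fit_ml(build_design(reduced, tcgsa_spec("linear"), "H1"))
  rebuilt <- tibble::as_tibble(as.data.frame(reduced))
  f_dir <- fit_ml(build_design(rebuilt, tcgsa_spec("linear"), "H1"))
  expect_equal(f_del$loglik, f_dir$loglik, tolerance = 1e-10)
})

test_that("parameters are recovered on average across simulated sets", {
  set.seed(99)
  eta_hat <- numeric(30)
  pars <- sim_params(hom = list(eta = c(0.5, 0, 0), sigma_h = c(0.3, 0, 0)),
                     sigma_c = 0.5)
  for (i in seq_along(eta_hat)) {
    d <- simulate_gene_set("homogeneous", n_genes = 8, n_patients = 6,
                           times = 0:4, params = pars)
    f <- fit_ml(build_design(d, tcgsa_spec("linear"), "H1"))
    eta_hat[i] <- f$coefficients$shared[["t1"]]
  }
  # eta1 = 0.5; MC error ~ sd/sqrt(30)
  expect_lt(abs(mean(eta_hat) - 0.5), 3 * sd(eta_hat) / sqrt(30) + 0.02)
})

test_that("the balanced fast path equals the general blockwise path", {
  df <- make_tiny_data(g = 4, p = 4, tt = 0:3, seed = 31, slope_sd = 0.2)
  des_b <- build_design(df, tcgsa_spec("cubic"), "H1")
  expect_true(des_b$pre$balanced)
  # drop one record: forces the general path on almost identical data
  des_g <- build_design(df[-1, ], tcgsa_spec("cubic"), "H1")
  expect_false(des_g$pre$balanced)
  theta <- c(0.4, 0.1, 0.02, 0.005)
  b <- tcgsa:::.pll_core(des_b, theta, grad = TRUE)
  # same theta, same data minus a row: logliks differ, but both paths must
  # agree with the dense oracle; cross-check the balanced path directly
  dfs <- des_b$data
  t_bar <- mean(unique(dfs$time))
  co <- tcgsa:::.pll_core(des_b, theta, coef = TRUE)
  mu <- co$alpha[dfs$gene] +
    drop(cbind(dfs$time - t_bar, (dfs$time - t_bar)^2,
               (dfs$time - t_bar)^3) %*% co$shared)
  ll_o <- dense_loglik_oracle(dfs, mu, co$sigma2, theta[1] * co$sigma2,
                              theta[2:4] * co$sigma2,
                              function(t) cbind(t - t_bar, (t - t_bar)^2,
                                                (t - t_bar)^3))
  expect_equal(b$ll, ll_o, tolerance = 1e-8)
  # numeric gradient check of the analytic gradient
  eps <- 1e-5
  for (k in seq_along(theta)) {
    th2 <- theta; th2[k] <- th2[k] + eps
    num <- (tcgsa:::.pll_core(des_b, th2)$ll - b$ll) / eps
    expect_equal(b$grad[k], num, tolerance = 1e-2)
  }
})

test_that("unstructured random-trend covariance matches lme4's correlated fit", {
  skip_if_not_installed("lme4")
  set.seed(42)
  p <- sim_params(hom = list(eta = c(0.1, 0.02, 0),
                             sigma_h = c(0.1, 0.02, 0.005)))
  d <- simulate_gene_set("homogeneous", n_genes = 6, n_patients = 6,
                         times = 0:5, params = p)
  dd <- as.data.frame(d)
  dd$u <- dd$time - mean(unique(dd$time))
  dd$gp <- paste(dd$gene, dd$patient)
  m <- lme4::lmer(value ~ gene + u + I(u^2) + (1 | gp) +
                    (0 + u + I(u^2) | gene),
                  data = dd, REML = FALSE,
                  control = lme4::lmerControl(check.conv.singular = "ignore",
                                              calc.derivs = FALSE))
  bas <- time_basis("custom", times = 0:5,
                    fun = function(t) { u <- t - 2.5; cbind(t1 = u, t2 = u^2) })
  f <- fit_ml(build_design(d, tcgsa_spec(bas, random_cov = "unstructured"),
                           "H1"))
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-4)
  Sh <- attr(f$varcomp, "Sigma_h")
  expect_equal(dim(Sh), c(2L, 2L))
  vc <- lme4::VarCorr(m)$gene
  expect_equal(unname(diag(Sh)), unname(diag(vc[1:2, 1:2])), tolerance = 1e-2)
})
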