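# BLUP prediction, shrinkage, gap-statistic trend splitting.

strong_fit <- function(seed = 7, sigma = 0.6, sigma_h1 = 0.25,
                       g = 5, p = 5, tt = 0:4) {
  set.seed(seed)
  pars <- sim_params(sigma = sigma,
                     hom = list(eta = c(0.4, 0, 0),
                                sigma_h = c(sigma_h1, 0, 0)))
  d <- simulate_gene_set("homogeneous", n_genes = g, n_patients = p,
                         times = tt, params = pars)
  fit_ml(build_design(d, tcgsa_spec("linear"), "H1"))
}

test_that("BLUPs equal the closed-form G Z' V^-1 (y - X b) of a dense oracle", {
  fit <- strong_fit()
  des <- fit$design
  re <- random_effects(fit)
  # dense oracle per gene block from first principles
  pre <- des$pre
  t_bar <- mean(unique(des$data$time))
  for (g in c(1L, 3L)) {
    rows <- des$block_rows[[g]]
    Z <- pre$Z
    y <- pre$Y[, g]
    r <- y - fit$coefficients$alpha[g] - drop(pre$C %*% fit$coefficients$shared)
    Gmat <- diag(fit$varcomp[des$col_var])
    V <- fit$sigma2 * diag(nrow(Z)) + Z %*% Gmat %*% t(Z)
    u_oracle <- drop(Gmat %*% t(Z) %*% solve(V, r))
    u_pkg <- re$value[re$block == des$genes[g]]
    expect_equal(u_pkg, u_oracle, tolerance = 1e-6)
  }
  # count: (levels x dimension) realisations per block
  expect_equal(nrow(re), length(des$genes) * ncol(des$pre$Z))
})

test_that("predictions shrink per-gene slopes towards the set average", {
  # large residual noise relative to the slope variance
  fit <- strong_fit(seed = 9, sigma = 1.5, sigma_h1 = 0.1)
  pred <- blup_predict(fit)
  t_bar <- mean(unique(pred$time))
  slope_of <- function(v, tt) coef(lm(v ~ I(tt - t_bar)))[2]
  genes <- unique(pred$gene)
  sl_fit <- sl_ols <- numeric(length(genes))
  for (i in seq_along(genes)) {
    sub <- pred[pred$gene == genes[i], ]
    sl_fit[i] <- slope_of(sub$fitted, sub$time)
    sl_ols[i] <- slope_of(sub$observed, sub$time)
  }
  # BLUP slopes lie strictly inside the spread of the per-gene OLS slopes
  expect_lt(sd(sl_fit), sd(sl_ols))
  expect_lt(mean(abs(sl_fit - mean(sl_ols))),
            mean(abs(sl_ols - mean(sl_ols))))
  # and overall predicted variance never exceeds observed variance
  expect_lte(var(pred$fitted), var(pred$observed))
})

test_that("predictions approach the data when the residual noise vanishes", {
  fit <- strong_fit(seed = 12, sigma = 1e-3, sigma_h1 = 0.3)
  pred <- blup_predict(fit)
  expect_lt(max(abs(pred$fitted - pred$observed)), 0.05)
})

test_that("gap statistic finds one trend in a tight bundle, two when split", {
  set.seed(21)
  tt <- 0:7
  one <- matrix(rep(sin(tt / 2), each = 12), 12) +
    matrix(rnorm(12 * 8, 0, 0.01), 12)
  expect_equal(as.integer(gap_statistic_k(one)), 1L)

  two <- rbind(
    matrix(rep(tt, each = 10), 10) + rnorm(80, 0, 0.05),
    matrix(rep(-tt, each = 10), 10) + rnorm(80, 0, 0.05)
  )
  expect_equal(as.integer(gap_statistic_k(two)), 2L)
  # deterministic given seed, invariant to row order
  k1 <- gap_statistic_k(two, seed = 99)
  k2 <- gap_statistic_k(two[sample(nrow(two)), ], seed = 99)
  expect_equal(as.integer(k1), as.integer(k2))
})

test_that("gap statistic recovers the three noiseless sub-trend means", {
  pars <- sim_params()
  tt <- 0:7
  u <- tt - mean(tt)
  B <- cbind(u, u^2, u^3)
  sub_means <- do.call(rbind, pars$het$etas) %*% t(B)
  traj <- sub_means[rep(1:3, length.out = 24), ] +
    matrix(rnorm(24 * 8, 0, 0.01), 24)
  expect_equal(as.integer(gap_statistic_k(traj, seed = 4)), 3L)
})

test_that("degenerate matrices yield a single trend", {
  expect_equal(as.integer(gap_statistic_k(matrix(1, 5, 4))), 1L)
  expect_equal(as.integer(gap_statistic_k(matrix(rnorm(4), 1, 4))), 1L)
})

test_that("trend summaries are medians with unit-variance display copies", {
  traj <- rbind(g1 = c(0, 1, 2, 3), g2 = c(0, -1, -2, -3),
                g3 = c(1, 1.2, 1.4, 1.6))
  # one gene per cluster: the trend is that gene's trajectory
  p1 <- summarize_trends(traj, labels = c(1, 2, 3))
  expect_equal(unname(p1$trend_median[1, ]), unname(traj[1, ]))
  expect_equal(p1$n_trends, 3L)
  # symmetric pair in one cluster: median is zero everywhere
  p2 <- summarize_trends(traj[1:2, ], labels = c(1, 1))
  expect_equal(unname(p2$trend_median[1, ]), rep(0, 4))
  # display copies have variance one (unless degenerate)
  p3 <- summarize_trends(traj, labels = c(1, 2, 2))
  expect_equal(apply(p3$trend_display, 1, var), c(`1` = 1, `2` = 1))
  expect_error(summarize_trends(traj, labels = c(1, 2)), "one entry")
})

test_that("summarising an already-summarised single trend is idempotent", {
  traj <- rbind(g1 = c(0.4, 0.9, 1.7, 2.2))
  p <- summarize_trends(traj, labels = 1)
  p2 <- summarize_trends(p$trend_median, labels = 1)
  expect_equal(unname(p2$trend_median), unname(p$trend_median))
})

test_that("trend decomposition and heatmap assembly work end to end", {
  set.seed(31)
  pars <- sim_params(hom = list(eta = c(0.6, 0, 0), sigma_h = c(0.05, 0, 0)))
  frags <- list(
    simulate_gene_set("homogeneous", n_genes = 12, n_patients = 6,
                      times = 0:4, params = pars,
                      gene_ids = sprintf("a_g%02d", 1:12)),
    simulate_gene_set("null", n_genes = 12, n_patients = 6, times = 0:4,
                      gene_ids = sprintf("b_g%02d", 1:12))
  )
  data <- dplyr::bind_rows(frags)
  sets <- gene_sets(c("up", "flat"),
                    list(sprintf("a_g%02d", 1:12), sprintf("b_g%02d", 1:12)))
  res <- run_tcgsa(data, sets, tcgsa_spec("linear"), keep_fits = TRUE)
  expect_true(res$table$significant[res$table$set_name == "up"])

  tr <- tcgsa_trends(res, data, sets, B = 20, seed = 5)
  expect_equal(names(tr$partitions), "up")
  expect_equal(sort(unique(tr$assignments$gene)), sprintf("a_g%02d", 1:12))

  hm <- heatmap_table(res, tr, ordering = "LR_percentile")
  expect_equal(nrow(hm$matrix), tr$partitions[["up"]]$n_trends)
  expect_true(all(diff(hm$row_info$LR_percentile) <= 0))

  # no significant sets: empty result with a warning
  res0 <- res
  res0$table$significant <- FALSE
  expect_warning(tr0 <- tcgsa_trends(res0, data, sets), "no significant")
  expect_warning(hm0 <- heatmap_table(res0, tr0), "no significant")
  expect_equal(nrow(hm0$matrix), 0L)
})
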