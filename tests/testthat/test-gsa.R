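test_that("BY adjustment matches the hand formula and the BH relation", {
  p <- c(0.01, 0.02, 0.04)
  m <- 3
  cm <- sum(1 / (1:m))
  # direct step-up formula
  ps <- sort(p)
  hand <- pmin(1, rev(cummin(rev(m * cm / (1:m) * ps))))
  expect_equal(adjust_pvalues(p, "BY"), hand)
  # BY = BH * c(m) before monotonicity/cap (here no capping occurs)
  expect_equal(adjust_pvalues(p, "BY"), adjust_pvalues(p, "BH") * cm)
})

test_that("BY caps at one and is the identity for a single test", {
  expect_equal(adjust_pvalues(c(1, 1, 1), "BY"), c(1, 1, 1))
  expect_equal(adjust_pvalues(0.04, "BY"), 0.04)
})

test_that("adjustment methods are ordered BY >= BH >= raw", {
  set.seed(2)
  p <- runif(25)^2
  expect_true(all(adjust_pvalues(p, "BY") >= adjust_pvalues(p, "BH") - 1e-12))
  expect_true(all(adjust_pvalues(p, "BH") >= p - 1e-12))
})

test_that("invalid p-values are rejected", {
  expect_error(adjust_pvalues(c(0.1, NaN)), "NaN")
  expect_error(adjust_pvalues(c(0.1, NA)), "missing")
  expect_error(adjust_pvalues(c(0.1, 1.2)), "\\[0, 1\\]")
})

make_collection_data <- function(seed = 5) {
  set.seed(seed)
  frags <- list(
    simulate_gene_set("homogeneous", n_genes = 12, n_patients = 6,
                      times = 0:4,
                      params = sim_params(hom = list(
                        eta = c(0.5, 0, 0), sigma_h = c(0.05, 0, 0))),
                      gene_ids = sprintf("s1_g%02d", 1:12)),
    simulate_gene_set("null", n_genes = 12, n_patients = 6, times = 0:4,
                      gene_ids = sprintf("s2_g%02d", 1:12)),
    simulate_gene_set("null", n_genes = 5, n_patients = 6, times = 0:4,
                      gene_ids = sprintf("s3_g%02d", 1:5))
  )
  list(
    data = dplyr::bind_rows(frags),
    sets = gene_sets(c("strong", "flat", "tiny"),
                     list(sprintf("s1_g%02d", 1:12),
                          sprintf("s2_g%02d", 1:12),
                          sprintf("s3_g%02d", 1:5)))
  )
}

test_that("run_tcgsa filters small sets, tests the rest, and reports counts", {
  cd <- make_collection_data()
  res <- run_tcgsa(cd$data, cd$sets, tcgsa_spec("linear"), alpha = 0.05)
  expect_equal(nrow(res$table), 2L)                    # tiny set discarded
  expect_equal(res$report$n_discarded, 1L)
  expect_equal(res$report$discarded$set_name, "tiny")
  expect_match(res$report$discarded$reason, "size<10")
  expect_equal(res$report$n_retained + res$report$n_discarded,
               res$report$n_total)
  tab <- res$table
  expect_true(all(tab$LR >= 0))
  expect_equal(tab$q, c(1L, 1L))
  expect_equal(tab$r, c(1L, 1L))
  expect_true(all(tab$p_adj >= tab$p_raw - 1e-12))
  # the strong set dominates
  expect_lt(tab$p_raw[tab$set_name == "strong"], 1e-4)
  expect_gt(tab$p_raw[tab$set_name == "flat"], 0.05)
  # LR percentile defined only for significant sets
  expect_true(all(is.na(tab$LR_percentile[!tab$significant])))
})

test_that("q and r track the basis dimension", {
  cd <- make_collection_data()
  res_c <- run_tcgsa(cd$data, cd$sets, tcgsa_spec("cubic"))
  expect_equal(unique(res_c$table$q), 3L)
  expect_equal(unique(res_c$table$r), 3L)
  res_s <- run_tcgsa(cd$data, cd$sets, tcgsa_spec("natural_spline",
                                                  knots = 2))
  expect_equal(unique(res_s$table$q), 3L)   # K + 1
  expect_equal(unique(res_s$table$r), 3L)
})

test_that("results are invariant to the order of the collection", {
  cd <- make_collection_data()
  res1 <- run_tcgsa(cd$data, cd$sets, tcgsa_spec("linear"))
  res2 <- run_tcgsa(cd$data, cd$sets[c(2, 1, 3), ], tcgsa_spec("linear"))
  expect_equal(sort(res1$table$p_raw), sort(res2$table$p_raw),
               tolerance = 1e-10)
})

test_that("run_tcgsa validates its inputs", {
  cd <- make_collection_data()
  expect_error(run_tcgsa(cd$data, cd$sets, alpha = 0), "alpha")
  foreign <- gene_sets("other", list(c("X1", "X2")))
  expect_error(run_tcgsa(cd$data, foreign), "no gene")
})

test_that("one-group wrapper refuses group specs and vice versa", {
  cd <- make_collection_data()
  d <- cd$data[cd$data$gene %in% sprintf("s1_g%02d", 1:12), ]
  expect_error(lrt_one_group(d, tcgsa_spec(group_effects = TRUE)),
               "group_comparison")
  expect_error(lrt_group_comparison(d, tcgsa_spec("linear")), "group_effects")
  spec <- tcgsa_spec("linear", group_effects = TRUE)
  expect_error(lrt_group_comparison(d, spec), "2 groups")
})
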