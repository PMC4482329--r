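# Structural counts follow directly from the model definitions.

two_by_two <- function() {
  tibble::tibble(
    gene = rep(c("g1", "g2"), each = 6),
    patient = rep(rep(c("p1", "p2"), each = 3), 2),
    time = rep(0:2, 4),
    value = c(1.2, 0.8, 1.1, 0.4, 0.6, 0.2,
              -0.3, 0.1, -0.2, 0.5, 0.9, 0.7)
  )
}

test_that("gene-fixed design has the structural counts of the one-group model", {
  des <- build_design(two_by_two(), tcgsa_spec("linear"), "H1")
  expect_equal(des$kind, "gene_blocks")
  # fixed: per-gene intercepts (mu + gene contrast) + 1 trend column
  expect_equal(des$rank_fixed, 3L)
  expect_equal(des$fixed_names, "t1")
  # random: 2 patient-intercept levels per gene block + 1 slope level per gene
  Z <- des$pre$Z
  expect_equal(ncol(Z), 3L)                       # per block
  expect_equal(des$pre$G * ncol(Z), 6L)           # 4 gene-x-patient + 2 slopes
  expect_equal(des$theta_names, c("sigma2_c", "sigma2_h1"))
  expect_equal(des$n_random_dims, 2L)

  des0 <- build_design(two_by_two(), tcgsa_spec("linear"), "H0")
  expect_equal(des0$rank_fixed, 2L)
  expect_equal(des0$theta_names, "sigma2_c")
})

test_that("random-intercept (parsimonious) design pools patients and genes", {
  des <- build_design(two_by_two(),
                      tcgsa_spec("linear", intercept_structure = "random"),
                      "H1")
  expect_equal(des$kind, "single")
  # random: 2 patient intercepts + 2 gene intercepts + 2 gene slopes
  expect_equal(ncol(des$pre$Z), 6L)
  expect_equal(des$theta_names, c("sigma2_c", "sigma2_beta", "sigma2_h1"))
})

test_that("group-comparison design duplicates trend columns per group at full rank", {
  d <- two_by_two()
  d <- dplyr::bind_rows(
    dplyr::mutate(d, group = "A"),
    dplyr::mutate(d, patient = sub("p", "q", patient), group = "B",
                  value = value + 0.3)
  )
  spec <- tcgsa_spec("linear", group_effects = TRUE)
  h1 <- build_design(d, spec, "H1")
  h0 <- build_design(d, spec, "H0")
  # numeric rank oracle: assemble the full fixed matrix by hand and qr() it
  assemble <- function(des) {
    X <- matrix(0, des$n_obs, length(des$genes))
    X[cbind(seq_len(des$n_obs), match(des$data$gene, des$genes))] <- 1
    for (g in seq_len(des$pre$G)) {
      rows <- des$block_rows[[g]]
      Cg <- if (des$pre$balanced) des$pre$C else des$pre$per[[g]]$C
      if (g == 1) X <- cbind(X, matrix(0, des$n_obs, ncol(Cg)))
      X[rows, length(des$genes) + seq_len(ncol(Cg))] <- Cg
    }
    X
  }
  expect_equal(qr(assemble(h1))$rank, h1$rank_fixed)
  expect_equal(qr(assemble(h0))$rank, h0$rank_fixed)
  # H1 adds (M-1)*d = 1 group-specific trend contrast
  expect_equal(h1$rank_fixed - h0$rank_fixed, 1L)
  # default: shared random part, r = 0
  expect_equal(h1$n_random_dims - h0$n_random_dims, 0L)

  spec_r <- tcgsa_spec("linear", group_effects = TRUE, group_random = TRUE)
  h1r <- build_design(d, spec_r, "H1")
  expect_equal(h1r$n_random_dims - h0$n_random_dims, 1L)
})

test_that("indicator-basis aliasing with the intercepts is resolved by rank", {
  d <- two_by_two()
  spec1 <- tcgsa_spec("indicator_day1", t_ref = 1)
  h1 <- build_design(d, spec1, "H1")
  h0 <- build_design(d, spec1, "H0")
  # one-group: the pair (1{t=ref}, 1{t!=ref}) sums to the intercept, so the
  # trend contributes one identifiable contrast
  expect_equal(h1$rank_fixed - h0$rank_fixed, 1L)
  # but both indicator columns keep their random (heterogeneity) dimension
  expect_equal(h1$n_random_dims - h0$n_random_dims, 2L)

  dg <- dplyr::bind_rows(
    dplyr::mutate(d, group = "A"),
    dplyr::mutate(d, patient = sub("p", "q", patient), group = "B")
  )
  spec <- tcgsa_spec("indicator_day1", t_ref = 1, group_effects = TRUE)
  g1 <- build_design(dg, spec, "H1")
  g0 <- build_design(dg, spec, "H0")
  # with the group intercept delta_m retained under both hypotheses (it is
  # baseline, not tested signal), the group-specific indicator pair loses
  # its level dof to delta_m: one identifiable group-trend contrast remains
  expect_equal(g1$rank_fixed - g0$rank_fixed, 1L)
})

test_that("degenerate subsets are rejected", {
  d <- two_by_two()
  expect_error(build_design(d[d$gene == "g1", ], tcgsa_spec()), "degenerate")
  expect_error(build_design(d[d$patient == "p1", ], tcgsa_spec()),
               "degenerate")
  expect_error(build_design(d[d$time == 0, ], tcgsa_spec()), "degenerate")
  expect_error(build_design(d, tcgsa_spec("linear", group_effects = TRUE)),
               "group")
})
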