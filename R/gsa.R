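# Per-set likelihood-ratio tests -----------------------------------------

# Map a nested model's fitted variance ratios onto the larger model's
# parameter vector (shared names carried over, tested components started
# just off the boundary).
.theta_embed <- function(theta_from, names_to) {
  out <- setNames(rep(1e-3, length(names_to)), names_to)
  common <- intersect(names(theta_from), names_to)
  out[common] <- theta_from[common]
  out
}

.lrt_set <- function(data_sub, spec, set_name = NA_character_,
                     control = fit_control()) {
  if (!inherits(data_sub, "tcgsa_expression")) {
    data_sub <- as_expression_dataset(data_sub)
  }
  if (!isTRUE(attr(data_sub, "tcgsa_sorted"))) {
    data_sub <- data_sub[order(data_sub$gene, data_sub$patient,
                               data_sub$time), ]
    attr(data_sub, "tcgsa_sorted") <- TRUE
  }
  d0 <- build_design(data_sub, spec, "H0")
  d1 <- build_design(data_sub, spec, "H1")
  f0 <- fit_ml(d0, control)
  f1 <- fit_ml(d1, control)

  q <- d1$rank_fixed - d0$rank_fixed
  r <- d1$n_random_dims - d0$n_random_dims

  status <- "ok"
  LR <- NA_real_
  p_raw <- NA_real_
  if (!f0$converged || !f1$converged) {
    status <- "not_assessed"
  } else {
    LR <- 2 * (f1$loglik - f0$loglik)
    if (LR < -1e-6) {
      # independent optimisations can land on different local optima; retry
      # each model from the other's solution before giving up
      ctl0 <- modifyList(control, list(
        start_theta = list(.theta_embed(f1$theta, d0$theta_names))
      ))
      ctl1 <- modifyList(control, list(
        start_theta = list(.theta_embed(f0$theta, d1$theta_names))
      ))
      f0b <- fit_ml(d0, ctl0)
      f1b <- fit_ml(d1, ctl1)
      if (f0b$converged && f0b$loglik > f0$loglik) f0 <- f0b
      if (f1b$converged && f1b$loglik > f1$loglik) f1 <- f1b
      LR <- 2 * (f1$loglik - f0$loglik)
    }
    if (LR < -1e-6) {
      status <- "not_assessed"
      LR <- NA_real_
    } else {
      LR <- max(LR, 0)
      p_raw <- mixture_chisq_survival(LR, q, r)
    }
  }

  structure(
    list(set_name = set_name, fit_H0 = f0, fit_H1 = f1,
         LR = LR, q = q, r = r, p_raw = p_raw, status = status),
    class = "tcgsa_set_fit"
  )
}

#' @export
print.tcgsa_set_fit <- function(x, ...) {
  cat(sprintf("<tcgsa_set_fit> %s: LR=%.4g (q=%d, r=%d) p=%.4g [%s]\n",
              x$set_name, x$LR, x$q, x$r, x$p_raw, x$status))
  invisible(x)
}

#' Likelihood-ratio test of one gene set over time (one-group design)
#'
#' Tests whether the genes of a set are stable over time: the null removes
#' all trend terms, fixed and random, so that a rejection can be driven by a
#' shared set-level trend, by between-gene heterogeneity of trends, or both.
#' With a basis of dimension `d`, `q = r = d` and the p-value comes from
#' [mixture_chisq_survival()].
#'
#' @param data expression measurements of one gene set.
#' @param spec a [tcgsa_spec()] without group effects.
#' @param set_name label carried into the result.
#' @param control see [fit_control()].
#' @return A `tcgsa_set_fit` with the H0/H1 fits, `LR`, `q`, `r`, `p_raw`
#'   and a convergence `status` (fits that cannot be assessed are flagged,
#'   never given a fabricated p-value).
#' @export
lrt_one_group <- function(data, spec = tcgsa_spec(), set_name = NA_character_,
                          control = fit_control()) {
  if (spec$group_effects) {
    stop_tcgsa("spec has group_effects; use lrt_group_comparison()")
  }
  .lrt_set(data, spec, set_name, control)
}

#' Likelihood-ratio test of group differences in a gene set's time profile
#'
#' The null fits one shared time trend (fixed and random parts) for all
#' groups; the alternative gives each group its own fixed trend coefficients
#' (and, with `spec$group_random`, its own random-trend variances). With `M`
#' groups and basis dimension `d`, the default comparison has
#' `q = (M-1) * d`, `r = 0` (a plain chi-square); with group-specific random
#' variances `r = (M-1) * d`.
#'
#' @inheritParams lrt_one_group
#' @param spec a [tcgsa_spec()] with `group_effects = TRUE`.
#' @export
lrt_group_comparison <- function(data, spec, set_name = NA_character_,
                                 control = fit_control()) {
  if (!spec$group_effects) {
    stop_tcgsa("spec must have group_effects = TRUE")
  }
  if (is.null(data$group) || length(unique(data$group)) < 2L) {
    stop_tcgsa("group comparison requires >= 2 groups",
               class = "tcgsa_validation_error")
  }
  tab <- table(unique(data.frame(p = data$patient, g = data$group))$g)
  if (any(tab < 2)) {
    stop_tcgsa("every group needs >= 2 patients",
               class = "tcgsa_validation_error")
  }
  .lrt_set(data, spec, set_name, control)
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper over [stats::p.adjust()] with Benjamini-Yekutieli as the
#' default: gene sets overlap functionally and are correlated, and BY
#' controls the FDR under arbitrary dependence (inflating Benjamini-Hochberg
#' by the harmonic factor `c(m) = sum(1/u)`).
#'
#' @param p numeric vector of raw p-values in `[0, 1]` (no NaN).
#' @param method `"BY"` (default), `"BH"`, `"bonferroni"` or `"holm"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(p, method = c("BY", "BH", "bonferroni", "holm")) {
  method <- match.arg(method)
  if (any(is.nan(p))) stop_tcgsa("NaN p-values are not allowed")
  if (any(is.na(p))) stop_tcgsa("missing p-values are not allowed")
  if (any(p < 0 | p > 1)) stop_tcgsa("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Run the full time-course gene set analysis
#'
#' Filters the collection by observed set size, runs the appropriate
#' likelihood-ratio test per retained set, adjusts p-values across retained
#' sets, and ranks significant sets by likelihood-ratio percentile (the LR
#' magnitude indicates how acute the expression variation is).
#'
#' @param data an expression dataset (see [as_expression_dataset()]).
#' @param sets a gene set collection (see [gene_sets()], [read_gmt()]).
#' @param spec a [tcgsa_spec()].
#' @param alpha significance threshold on adjusted p-values, in `(0, 1)`.
#' @param adjust multiple-testing method, see [adjust_pvalues()].
#' @param min_size,max_size observed-size band for retaining a set.
#' @param keep_fits retain the per-set model fits (needed afterwards only if
#'   you want to avoid refitting in [tcgsa_trends()]).
#' @param control see [fit_control()].
#' @param verbose print per-set progress.
#' @return A `tcgsa_result`: list with `table` (one row per retained set:
#'   `set_name`, `n_genes_observed`, `LR`, `q`, `r`, `p_raw`, `p_adj`,
#'   `significant`, `LR_percentile`, `convergence_status`), `report`
#'   (retained/discarded/failed accounting and the configuration used), and
#'   optionally `fits`.
#' @export
run_tcgsa <- function(data, sets, spec = tcgsa_spec(), alpha = 0.05,
                      adjust = "BY", min_size = 10, max_size = 500,
                      keep_fits = FALSE, control = fit_control(),
                      verbose = FALSE) {
  data <- as_expression_dataset(data)
  if (!(alpha > 0 && alpha < 1)) stop_tcgsa("`alpha` must be in (0, 1)")
  universe <- unique(data$gene)
  if (!any(unlist(sets$genes) %in% universe)) {
    stop_tcgsa("no gene of any set is observed in the dataset",
               class = "tcgsa_validation_error")
  }
  sets <- filter_gene_sets(sets, data, min_size, max_size)
  discarded <- dplyr::filter(sets, !.data$retained)
  retained <- dplyr::filter(sets, .data$retained)

  # freeze the basis on the full dataset's observed times so every set is
  # modelled on the same time function
  spec_rs <- spec
  spec_rs$basis <- resolve_basis(spec, sort(unique(data$time)))

  fits <- vector("list", nrow(retained))
  rows <- vector("list", nrow(retained))
  for (i in seq_len(nrow(retained))) {
    nm <- retained$set_name[i]
    sub <- data[data$gene %in% retained$genes[[i]], , drop = FALSE]
    sf <- tryCatch(
      .lrt_set(sub, spec_rs, set_name = nm, control = control),
      error = function(e) {
        structure(list(set_name = nm, LR = NA_real_, q = NA_integer_,
                       r = NA_integer_, p_raw = NA_real_,
                       status = paste0("error: ", conditionMessage(e))),
                  class = "tcgsa_set_fit")
      }
    )
    if (verbose) {
      message(sprintf("[%d/%d] %s: LR=%.3g p=%.3g (%s)",
                      i, nrow(retained), nm, sf$LR, sf$p_raw, sf$status))
    }
    rows[[i]] <- tibble::tibble(
      set_name = nm,
      n_genes_observed = retained$n_genes_observed[i],
      LR = sf$LR, q = sf$q, r = sf$r, p_raw = sf$p_raw,
      convergence_status = sf$status
    )
    if (keep_fits) fits[[i]] <- sf
  }
  tab <- dplyr::bind_rows(rows)

  tab$p_adj <- NA_real_
  assessed <- !is.na(tab$p_raw)
  if (any(assessed)) {
    tab$p_adj[assessed] <- adjust_pvalues(tab$p_raw[assessed], adjust)
  }
  tab$significant <- !is.na(tab$p_adj) & tab$p_adj <= alpha
  tab$LR_percentile <- NA_real_
  n_sig <- sum(tab$significant)
  if (n_sig > 0) {
    tab$LR_percentile[tab$significant] <-
      100 * rank(tab$LR[tab$significant], ties.method = "average") / n_sig
  }
  tab <- tab[, c("set_name", "n_genes_observed", "LR", "q", "r", "p_raw",
                 "p_adj", "significant", "LR_percentile",
                 "convergence_status")]

  basis <- spec_rs$basis
  report <- list(
    n_total = nrow(sets),
    n_retained = nrow(retained),
    n_discarded = nrow(discarded),
    n_failed = sum(!assessed),
    n_significant = n_sig,
    discarded = tibble::tibble(
      set_name = discarded$set_name,
      n_genes_observed = discarded$n_genes_observed,
      reason = ifelse(discarded$n_genes_observed < min_size,
                      sprintf("size<%d", min_size),
                      sprintf("size>%d", max_size))
    ),
    config = list(
      basis = basis$kind, d = basis$d, center_time = spec$center_time,
      intercept_structure = spec$intercept_structure,
      trend_grouping = spec$trend_grouping,
      group_effects = spec$group_effects,
      group_random = spec$group_random,
      random_cov = spec$random_cov,
      alpha = alpha, adjust = adjust,
      min_size = min_size, max_size = max_size
    )
  )

  structure(
    list(table = tab, report = report, spec = spec_rs,
         fits = if (keep_fits) setNames(fits, retained$set_name) else NULL),
    class = "tcgsa_result"
  )
}

#' @export
print.tcgsa_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<tcgsa_result> %s basis: %d/%d sets retained (%d discarded), %d significant at %s=%g%s\n",
    r$config$basis, r$n_retained, r$n_total, r$n_discarded, r$n_significant,
    r$config$adjust, r$config$alpha,
    if (r$n_failed > 0) sprintf(", %d not assessed", r$n_failed) else ""
  ))
  print(x$table, n = 10)
  invisible(x)
}
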