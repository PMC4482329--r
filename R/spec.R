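#' Specify the gene-set mixed model
#'
#' Collects every modelling switch for the per-set linear mixed model:
#'
#' * `basis`: the time-function kind (see [time_basis()]) or an already-built
#'   `tcgsa_basis` object. Each basis column receives a fixed set-level trend
#'   coefficient and a random per-gene (or per-patient) deviation.
#' * `intercept_structure`: `"gene_fixed"` keeps a fixed effect per gene plus
#'   a gene-by-patient random intercept; `"random"` is the more parsimonious
#'   variant with a random gene intercept and a random patient intercept
#'   shared across genes.
#' * `trend_grouping`: random trend coefficients grouped by `"gene"`
#'   (heterogeneity between genes, the default) or by `"patient"`
#'   (heterogeneity between patients).
#' * `group_effects`: `TRUE` turns on the multi-group comparison: fixed group
#'   intercepts and group-specific trend coefficients; the test then asks
#'   whether the time profiles differ between groups.
#' * `group_random`: with `group_effects`, also make the random-trend
#'   variances group-specific under the alternative (then the tested random
#'   dimension `r` is `(M-1) * d`; with the default shared random part
#'   `r = 0` and the null is a plain chi-square).
#' * `random_cov`: `"diagonal"` assumes the random trend coefficients are
#'   mutually independent (required by the default chi-square-mixture null);
#'   `"unstructured"` fits a full covariance, in which case the default null
#'   approximation is no longer valid and p-values should be interpreted
#'   with care.
#'
#' @param basis character kind or `tcgsa_basis` object.
#' @param knots,t_ref forwarded to [time_basis()] when `basis` is a kind.
#' @param intercept_structure,trend_grouping,group_effects,group_random,random_cov
#'   see above.
#' @param center_time centre time at the mean observed time before basis
#'   expansion (numerical conditioning; does not change the tests).
#' @return An object of class `tcgsa_spec`.
#' @export
tcgsa_spec <- function(basis = "linear", knots = NULL, t_ref = NULL,
                       intercept_structure = c("gene_fixed", "random"),
                       trend_grouping = c("gene", "patient"),
                       group_effects = FALSE,
                       group_random = FALSE,
                       random_cov = c("diagonal", "unstructured"),
                       center_time = TRUE) {
  intercept_structure <- match.arg(intercept_structure)
  trend_grouping <- match.arg(trend_grouping)
  random_cov <- match.arg(random_cov)
  if (!inherits(basis, "tcgsa_basis") && !is.character(basis)) {
    stop_tcgsa("`basis` must be a basis kind or a tcgsa_basis object")
  }
  structure(
    list(
      basis = basis, knots = knots, t_ref = t_ref,
      intercept_structure = intercept_structure,
      trend_grouping = trend_grouping,
      group_effects = isTRUE(group_effects),
      group_random = isTRUE(group_random),
      random_cov = random_cov,
      center_time = isTRUE(center_time)
    ),
    class = "tcgsa_spec"
  )
}

#' @export
print.tcgsa_spec <- function(x, ...) {
  bk <- if (inherits(x$basis, "tcgsa_basis")) x$basis$kind else x$basis
  cat(sprintf(
    "<tcgsa_spec> basis=%s, intercepts=%s, trend random on %s%s, Sigma_h %s\n",
    bk, x$intercept_structure, x$trend_grouping,
    if (x$group_effects) {
      sprintf(", group comparison (%s random part)",
              if (x$group_random) "group-specific" else "shared")
    } else "",
    x$random_cov
  ))
  invisible(x)
}

# Resolve the basis of a spec against the observed times of a dataset.
resolve_basis <- function(spec, times) {
  if (inherits(spec$basis, "tcgsa_basis")) {
    return(spec$basis)
  }
  time_basis(spec$basis, times = times, knots = spec$knots,
             t_ref = spec$t_ref, center = spec$center_time)
}
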