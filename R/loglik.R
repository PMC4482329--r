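#' Exact marginal log-likelihood at given parameter values
#'
#' Evaluates the marginal Gaussian log-likelihood
#' `y ~ N(X b, Z G Z' + sigma2 I)` of a design bundle at arbitrary fixed
#' effects and variance components, by dense linear algebra on each
#' independent covariance block. At the fitted parameters it reproduces
#' `fit_ml()`'s reported log-likelihood; it also serves as the evaluation
#' hook for likelihood-ratio bookkeeping and external checks.
#'
#' @param design a `tcgsa_design`.
#' @param params either a `tcgsa_fit` (its estimates are used) or a list
#'   with elements `fixef` (for gene-block designs: `list(alpha=, shared=)`;
#'   for single-block designs: `list(beta=)`), `sigma2`, and `varcomp`
#'   (named variances on the natural scale, ordered as
#'   `design$theta_names`).
#' @return The log-likelihood (a single number).
#' @export
loglik_at <- function(design, params) {
  stopifnot(inherits(design, "tcgsa_design"))
  if (inherits(params, "tcgsa_fit")) {
    fx <- params$coefficients
    params <- list(
      fixef = if (design$kind == "single") list(beta = fx$beta)
              else list(alpha = fx$alpha, shared = fx$shared),
      sigma2 = params$sigma2,
      varcomp = as.numeric(params$varcomp)
    )
  }
  sigma2 <- params$sigma2
  varcomp <- as.numeric(params$varcomp)
  .assert_number(sigma2, "sigma2", lower = 0)
  if (length(varcomp) != length(design$theta_names)) {
    stop_tcgsa(sprintf("`varcomp` must have %d value(s): %s",
                       length(design$theta_names),
                       paste(design$theta_names, collapse = ", ")))
  }
  if (!is.null(design$unstr)) {
    stop_tcgsa("loglik_at supports diagonal random covariance only")
  }
  if (any(varcomp < 0)) stop_tcgsa("variance components must be >= 0")

  dvec <- varcomp[design$col_var]
  ll <- 0
  dense_block <- function(yres, Z) {
    V <- sigma2 * diag(nrow(Z)) + Z %*% (dvec * t(Z))
    R <- chol(V)
    w <- backsolve(R, yres, transpose = TRUE)
    -0.5 * (nrow(Z) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(w^2))
  }

  if (design$kind == "single") {
    b <- params$fixef$beta
    r <- design$y - drop(design$pre$X %*% b)
    return(dense_block(r, design$pre$Z))
  }

  alpha <- params$fixef$alpha
  eta <- params$fixef$shared
  pre <- design$pre
  if (pre$balanced) {
    fixed_part <- if (design$p_c > 0) drop(pre$C %*% eta) else 0
    for (g in seq_len(pre$G)) {
      r <- pre$Y[, g] - alpha[g] - fixed_part
      ll <- ll + dense_block(r, pre$Z)
    }
  } else {
    for (g in seq_len(pre$G)) {
      b <- pre$per[[g]]
      r <- b$y - alpha[g]
      if (design$p_c > 0) r <- r - drop(b$C %*% eta)
      ll <- ll + dense_block(r, b$Z)
    }
  }
  ll
}
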