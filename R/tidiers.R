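# broom-style tidiers ------------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a gene set analysis result
#'
#' @param x a `tcgsa_result`.
#' @param ... unused.
#' @return The per-set results tibble.
#' @method tidy tcgsa_result
#' @export
tidy.tcgsa_result <- function(x, ...) x$table

#' One-row summary of a gene set analysis
#'
#' @param x a `tcgsa_result`.
#' @param ... unused.
#' @method glance tcgsa_result
#' @export
glance.tcgsa_result <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_total = r$n_total, n_retained = r$n_retained,
    n_discarded = r$n_discarded, n_failed = r$n_failed,
    n_significant = r$n_significant,
    basis = r$config$basis, adjust = r$config$adjust,
    alpha = r$config$alpha
  )
}

#' Tidy a per-set mixed-model fit
#'
#' @param x a `tcgsa_fit`.
#' @param ... unused.
#' @return A tibble of parameter estimates: fixed effects then variance
#'   components (natural scale) and the residual variance.
#' @method tidy tcgsa_fit
#' @export
tidy.tcgsa_fit <- function(x, ...) {
  cf <- x$coefficients
  fixed <- if (x$design$kind == "single") {
    tibble::tibble(term = names(cf$beta), estimate = unname(cf$beta),
                   type = "fixed")
  } else {
    dplyr::bind_rows(
      tibble::tibble(term = "mu", estimate = cf$mu, type = "fixed"),
      tibble::tibble(term = paste0("beta_", names(cf$beta_gene)),
                     estimate = unname(cf$beta_gene), type = "fixed"),
      tibble::tibble(term = names(cf$shared), estimate = unname(cf$shared),
                     type = "fixed")
    )
  }
  dplyr::bind_rows(
    fixed,
    tibble::tibble(term = names(x$varcomp),
                   estimate = as.numeric(x$varcomp), type = "varcomp"),
    tibble::tibble(term = "sigma2", estimate = x$sigma2, type = "varcomp")
  )
}

#' @method glance tcgsa_fit
#' @export
glance.tcgsa_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, sigma2 = x$sigma2,
                 n_obs = x$n_obs, n_params = x$n_params,
                 converged = x$converged)
}

#' Tidy a set-level likelihood ratio test
#'
#' @param x a `tcgsa_set_fit`.
#' @param ... unused.
#' @method tidy tcgsa_set_fit
#' @export
tidy.tcgsa_set_fit <- function(x, ...) {
  tibble::tibble(set_name = x$set_name, LR = x$LR, q = x$q, r = x$r,
                 p_raw = x$p_raw, convergence_status = x$status)
}

#' Tidy a simulation study
#'
#' @param x a `tcgsa_sim_study`.
#' @param ... unused.
#' @return The per-run rates tibble.
#' @method tidy tcgsa_sim_study
#' @export
tidy.tcgsa_sim_study <- function(x, ...) x$per_run

#' @method glance tcgsa_sim_study
#' @export
glance.tcgsa_sim_study <- function(x, ...) x$summary
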