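#' Survival function of the boundary chi-square mixture
#'
#' When a likelihood ratio simultaneously tests `q` fixed effects and `r`
#' variance components against the boundary of the parameter space, its null
#' distribution is not a single chi-square but the binomially weighted
#' mixture
#' \deqn{LR \sim \sum_{k=q}^{q+r} \binom{r}{k-q} 2^{-r} \chi^2_{(k)},}
#' valid when the tested random effects are mutually independent (the
#' diagonal covariance default). `r = 0` reduces to the ordinary
#' `chi^2_q` test; a `chi^2_0` term (possible when `q = 0`) is a point mass
#' at zero.
#'
#' @param x quantile(s), `>= 0` (vectorised).
#' @param q number of tested fixed effects (integer `>= 0`).
#' @param r number of tested random effects (integer `>= 0`).
#' @return `P(LR > x)` under the mixture null, in `[0, 1]`.
#' @examples
#' mixture_chisq_survival(0, 1, 1)     # 1
#' mixture_chisq_survival(3.84, 1, 0)  # standard chi-square_1 tail
#' @export
mixture_chisq_survival <- function(x, q, r) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_tcgsa("`x` must be finite and >= 0")
  }
  if (length(q) != 1L || length(r) != 1L ||
      q != as.integer(q) || r != as.integer(r) || q < 0 || r < 0) {
    stop_tcgsa("`q` and `r` must be single non-negative integers")
  }
  q <- as.integer(q)
  r <- as.integer(r)
  if (r == 0L) {
    if (q == 0L) return(ifelse(x <= 0, 1, 0))
    return(pchisq(x, df = q, lower.tail = FALSE))
  }
  ks <- q:(q + r)
  w <- choose(r, ks - q) / 2^r
  out <- numeric(length(x))
  for (i in seq_along(ks)) {
    k <- ks[i]
    surv_k <- if (k == 0L) ifelse(x <= 0, 1, 0) else {
      pchisq(x, df = k, lower.tail = FALSE)
    }
    out <- out + w[i] * surv_k
  }
  pmin(pmax(out, 0), 1)
}

#' Mixture weights of the boundary chi-square null
#'
#' @param q,r as in [mixture_chisq_survival()].
#' @return A tibble with columns `df` and `weight` (`C(r, df-q) / 2^r`).
#' @export
mixture_chisq_weights <- function(q, r) {
  ks <- q:(q + r)
  tibble::tibble(df = ks, weight = choose(r, ks - q) / 2^r)
}
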