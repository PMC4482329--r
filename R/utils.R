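#' @importFrom rlang .data abort warn inform
#' @importFrom stats pchisq qchisq p.adjust median sd var quantile rnorm runif
#'   setNames optim dist hclust cutree dnorm coef
#' @importFrom utils head modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_tcgsa <- function(msg, class = "tcgsa_error") {
  rlang::abort(msg, class = class)
}

# scale rows and columns of a symmetric matrix by s (S %*% A %*% S for diag S)
.sym_scale <- function(A, s) {
  A * tcrossprod(s)
}

.assert_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower) {
    stop_tcgsa(sprintf("`%s` must be a single finite number >= %s", name, lower))
  }
  invisible(x)
}
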