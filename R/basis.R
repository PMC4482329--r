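#' Construct a time-function basis
#'
#' Builds the basis used to model the set-level trend \eqn{f_g(t)}: each of its
#' `d` columns gets a fixed set-level coefficient and a gene-level (or
#' patient-level) random deviation in the mixed model. Available kinds:
#'
#' * `"linear"`: one column, `t` itself (`d = 1`).
#' * `"cubic"`: columns `t`, `t^2`, `t^3` (`d = 3`).
#' * `"natural_spline"`: a natural cubic spline basis with `knots` internal
#'   knots placed at equally spaced quantiles of the distinct observed times,
#'   boundary knots at the observed extremes (`d = knots + 1`).
#' * `"indicator_day1"`: two indicator columns `1{t == t_ref}` and
#'   `1{t != t_ref}` (`d = 2`), for designs where the response at a single
#'   visit (e.g. day 1 after vaccination) must not be smoothed into a
#'   polynomial trend.
#' * `"custom"`: any `fun(t)` returning a numeric matrix with one row per
#'   time value.
#'
#' When `center = TRUE` polynomial columns are built from `t - mean(times)`;
#' this improves the conditioning of the cubic terms, changes none of the
#' likelihood-ratio tests (the fixed-part span is identical), and is the
#' default inside [tcgsa_spec()]. The default here is `center = FALSE` so that
#' `evaluate(t)` returns the plain powers of `t`.
#'
#' @param kind basis kind, see above.
#' @param times numeric vector of observed measurement times.
#' @param knots number of internal knots (natural spline only), `>= 1`.
#' @param t_ref reference time for the indicator basis; must be one of
#'   `times`.
#' @param fun for `kind = "custom"`, a function mapping a time vector to a
#'   numeric matrix.
#' @param center logical; centre `t` on `mean(times)` before basis expansion.
#' @return An object of class `tcgsa_basis`: a list with elements `kind`,
#'   `d` (number of columns), `evaluate` (a deterministic function
#'   `time vector -> matrix`), `colnames`, and kind-specific details.
#' @examples
#' b <- time_basis("cubic", times = 0:7)
#' b$evaluate(2) # 2, 4, 8
#' @export
time_basis <- function(kind = c("linear", "cubic", "natural_spline",
                                "indicator_day1", "custom"),
                       times, knots = NULL, t_ref = NULL, fun = NULL,
                       center = FALSE) {
  kind <- match.arg(kind)
  if (missing(times) || length(times) == 0L || !is.numeric(times)) {
    stop_tcgsa("`times` must be a non-empty numeric vector of observed times")
  }
  times <- sort(unique(as.numeric(times)))
  t_bar <- if (center) mean(times) else 0

  out <- switch(kind,
    linear = {
      list(
        d = 1L,
        evaluate = function(t) {
          matrix(t - t_bar, ncol = 1L, dimnames = list(NULL, "t1"))
        },
        colnames = "t1"
      )
    },
    cubic = {
      list(
        d = 3L,
        evaluate = function(t) {
          u <- t - t_bar
          cbind(t1 = u, t2 = u^2, t3 = u^3)
        },
        colnames = c("t1", "t2", "t3")
      )
    },
    natural_spline = {
      if (is.null(knots) || knots < 1L) {
        stop_tcgsa("natural_spline basis requires `knots` >= 1")
      }
      n_interior <- length(times) - 2L
      if (knots >= length(times) - 1L || knots > n_interior) {
        stop_tcgsa(sprintf(
          "too many internal knots (%d) for %d distinct observed times",
          knots, length(times)
        ))
      }
      u_obs <- times - t_bar
      bknots <- range(u_obs)
      probs <- seq_len(knots) / (knots + 1)
      kn <- unname(quantile(u_obs, probs = probs, type = 7))
      d <- knots + 1L
      cn <- paste0("ns", seq_len(d))
      list(
        d = d,
        evaluate = function(t) {
          m <- unclass(splines::ns(t - t_bar, knots = kn,
                                   Boundary.knots = bknots))
          m <- matrix(as.numeric(m), nrow = length(t))
          colnames(m) <- cn
          m
        },
        colnames = cn,
        knots = kn + t_bar, boundary = bknots + t_bar
      )
    },
    indicator_day1 = {
      if (is.null(t_ref)) stop_tcgsa("indicator basis requires `t_ref`")
      if (!any(times == t_ref)) {
        stop_tcgsa(sprintf("`t_ref` = %s is not an observed time", t_ref))
      }
      list(
        d = 2L,
        evaluate = function(t) {
          cbind(ind_ref = as.numeric(t == t_ref),
                ind_other = as.numeric(t != t_ref))
        },
        colnames = c("ind_ref", "ind_other"),
        t_ref = t_ref
      )
    },
    custom = {
      if (!is.function(fun)) stop_tcgsa("custom basis requires `fun`")
      probe <- fun(times)
      if (!is.matrix(probe) || nrow(probe) != length(times)) {
        stop_tcgsa("custom basis `fun` must return a matrix with one row per time")
      }
      cn <- colnames(probe) %||% paste0("f", seq_len(ncol(probe)))
      list(
        d = ncol(probe),
        evaluate = function(t) {
          m <- fun(t)
          colnames(m) <- cn
          m
        },
        colnames = cn
      )
    }
  )

  structure(
    c(out, list(kind = kind, times = times, center = center, t_bar = t_bar)),
    class = "tcgsa_basis"
  )
}

#' @export
print.tcgsa_basis <- function(x, ...) {
  cat(sprintf("<tcgsa_basis> kind=%s d=%d over times [%s, %s]%s\n",
              x$kind, x$d, min(x$times), max(x$times),
              if (x$center) sprintf(" (centred at %.3g)", x$t_bar) else ""))
  invisible(x)
}
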