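# Profiled marginal likelihood -------------------------------------------
#
# The marginal model is y ~ N(X b, sigma2 * (I + Z D Z')), with D the
# diagonal (or blockwise Cholesky-factored) matrix of variance RATIOS
# theta = sigma_v^2 / sigma^2. Fixed effects and sigma^2 are profiled out in
# closed form, leaving an optimisation over theta >= 0 only. All algebra
# runs through the k x k capacitance matrix M = I + L'Z'Z L (L = sqrt(D)),
# so the boundary theta = 0 is exactly representable -- which the
# chi-square-mixture null of the LRT requires.
#
# Identities used (per independent covariance block, W = (I + Z D Z')^-1):
#   u' W v        = u'v - (L'Z'u)' M^-1 (L'Z'v)
#   log det(I+ZDZ') = log det(M)
#   d pll / d theta_v = ||Z_v' W r||^2 / (2 sigmahat2) - tr(Z_v' W Z_v) / 2
#   BLUP: u_hat = D Z' W r = L M^-1 L' Z' r
# The last two follow from the envelope theorem at the profiled optimum.

# apply L' (rows transform) to a matrix with k rows
.lt_apply <- function(Lspec, A) {
  if (Lspec$type == "diag") {
    Lspec$s * A
  } else {
    out <- Lspec$s * A
    out[Lspec$cols, ] <- crossprod(Lspec$Lam, A[Lspec$cols, , drop = FALSE])
    out
  }
}

.make_L <- function(design, theta) {
  if (is.null(design$unstr)) {
    s <- sqrt(pmax(theta[design$col_var], 0))
    list(type = "diag", s = s)
  } else {
    un <- design$unstr
    s <- numeric(length(design$col_var))
    dcols <- which(!is.na(design$col_var))
    s[dcols] <- sqrt(pmax(theta[design$col_var[dcols]], 0))
    Lam <- matrix(0, un$dim, un$dim)
    Lam[un$ij] <- theta[un$param_idx]
    diag(Lam) <- pmax(diag(Lam), 0)
    list(type = "unstr", s = s, cols = un$cols, Lam = Lam)
  }
}

# One evaluation of the profiled log-likelihood. Returns ll, and optionally
# the analytic gradient (diagonal structures only) and profiled coefficients.
.pll_core <- function(design, theta, grad = FALSE, coef = FALSE) {
  pre <- design$pre
  n <- design$n_obs
  L <- .make_L(design, theta)
  diag_struct <- L$type == "diag"
  if (grad && !diag_struct) grad <- FALSE

  if (design$kind == "single") {
    return(.pll_single(design, L, grad, coef))
  }
  if (pre$balanced) {
    .pll_balanced(design, L, grad, coef)
  } else {
    .pll_blocks(design, L, grad, coef)
  }
}

.pll_balanced <- function(design, L, grad, coef) {
  pre <- design$pre
  n <- design$n_obs
  G <- pre$G
  p_c <- ncol(pre$C)

  A <- .lt_apply(L, t(.lt_apply(L, pre$ZtZ)))
  M <- A
  diag(M) <- diag(M) + 1
  R <- chol(M)
  logdet <- G * 2 * sum(log(diag(R)))

  TZ1 <- backsolve(R, .lt_apply(L, cbind(pre$Zt1)), transpose = TRUE)
  TZY <- backsolve(R, .lt_apply(L, pre$ZtY), transpose = TRUE)
  a <- pre$n_b - sum(TZ1^2)
  v <- pre$oneY - drop(crossprod(TZY, TZ1))
  yyw <- pre$yy - colSums(TZY^2)

  if (p_c > 0) {
    TZC <- backsolve(R, .lt_apply(L, pre$ZtC), transpose = TRUE)
    u <- pre$Ct1 - drop(crossprod(TZC, TZ1))
    Fm <- pre$CtC - crossprod(TZC)
    Wm <- pre$CtY - crossprod(TZC, TZY)
    Ftot <- G * (Fm - tcrossprod(u) / a)
    rhs <- rowSums(Wm) - u * sum(v) / a
    eta <- drop(solve(Ftot, rhs))
    alpha <- (v - sum(u * eta)) / a
    RSS <- sum(yyw) - sum(v^2) / a - sum(eta * rhs)
  } else {
    eta <- numeric(0)
    alpha <- v / a
    RSS <- sum(yyw) - sum(v^2) / a
  }
  sigma2 <- RSS / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1) - logdet / 2

  out <- list(ll = ll, sigma2 = sigma2, RSS = RSS)
  if (coef || grad) {
    k <- nrow(pre$ZtZ)
    ZtR <- pre$ZtY - outer(pre$Zt1, alpha)
    if (p_c > 0) ZtR <- ZtR - drop(pre$ZtC %*% eta)
    out$ZtR <- ZtR
  }
  if (grad) {
    TZZ <- backsolve(R, .lt_apply(L, pre$ZtZ), transpose = TRUE)
    TZR <- backsolve(R, .lt_apply(L, out$ZtR), transpose = TRUE)
    ZWR <- out$ZtR - crossprod(TZZ, TZR)
    diagZWZ <- diag(pre$ZtZ) - colSums(TZZ^2)
    gr <- vapply(seq_along(design$theta_names), function(vv) {
      J <- which(design$col_var == vv)
      sum(ZWR[J, , drop = FALSE]^2) / (2 * sigma2) -
        G * sum(diagZWZ[J]) / 2
    }, 0)
    out$grad <- gr
    out$ZWR <- ZWR
    out$diagZWZ_tot <- G * diagZWZ
  }
  if (coef) {
    out$alpha <- setNames(alpha, design$genes)
    out$shared <- setNames(eta, design$fixed_names)
    out$cache <- list(R = R, L = L)
  }
  out
}

.pll_blocks <- function(design, L, grad, coef) {
  pre <- design$pre
  n <- design$n_obs
  G <- pre$G
  p_c <- design$p_c

  logdet <- 0
  a <- v <- yyacc <- numeric(G)
  Facc <- matrix(0, p_c, p_c)
  racc <- numeric(p_c)
  Wl <- vector("list", G)
  ul <- vector("list", G)
  Rl <- vector("list", G)
  for (g in seq_len(G)) {
    b <- pre$per[[g]]
    A <- .lt_apply(L, t(.lt_apply(L, b$ZtZ)))
    M <- A
    diag(M) <- diag(M) + 1
    R <- chol(M)
    logdet <- logdet + 2 * sum(log(diag(R)))
    TZ1 <- backsolve(R, .lt_apply(L, cbind(b$Zt1)), transpose = TRUE)
    TZy <- backsolve(R, .lt_apply(L, cbind(b$Zty)), transpose = TRUE)
    a[g] <- b$n_b - sum(TZ1^2)
    v[g] <- b$oney - sum(TZy * TZ1)
    yyacc[g] <- b$yy - sum(TZy^2)
    if (p_c > 0) {
      TZC <- backsolve(R, .lt_apply(L, b$ZtC), transpose = TRUE)
      u_g <- b$Ct1 - drop(crossprod(TZC, TZ1))
      F_g <- b$CtC - crossprod(TZC)
      w_g <- b$Cty - drop(crossprod(TZC, TZy))
      Facc <- Facc + F_g - tcrossprod(u_g) / a[g]
      racc <- racc + w_g - u_g * v[g] / a[g]
      ul[[g]] <- u_g
    }
    Rl[[g]] <- R
  }
  if (p_c > 0) {
    eta <- drop(solve(Facc, racc))
    alpha <- (v - vapply(ul, function(u) sum(u * eta), 0)) / a
    RSS <- sum(yyacc) - sum(v^2 / a) - sum(eta * racc)
  } else {
    eta <- numeric(0)
    alpha <- v / a
    RSS <- sum(yyacc) - sum(v^2 / a)
  }
  sigma2 <- RSS / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1) - logdet / 2

  out <- list(ll = ll, sigma2 = sigma2, RSS = RSS)
  if (grad || coef) {
    k <- length(design$col_var)
    ZtR <- matrix(0, k, G)
    for (g in seq_len(G)) {
      b <- pre$per[[g]]
      zr <- b$Zty - alpha[g] * b$Zt1
      if (p_c > 0) zr <- zr - drop(b$ZtC %*% eta)
      ZtR[, g] <- zr
    }
    out$ZtR <- ZtR
  }
  if (grad) {
    k <- length(design$col_var)
    ZWR <- matrix(0, k, G)
    diagZWZ_tot <- numeric(k)
    for (g in seq_len(G)) {
      b <- pre$per[[g]]
      R <- Rl[[g]]
      TZZ <- backsolve(R, .lt_apply(L, b$ZtZ), transpose = TRUE)
      TZR <- backsolve(R, .lt_apply(L, cbind(out$ZtR[, g])), transpose = TRUE)
      ZWR[, g] <- out$ZtR[, g] - drop(crossprod(TZZ, TZR))
      diagZWZ_tot <- diagZWZ_tot + diag(b$ZtZ) - colSums(TZZ^2)
    }
    gr <- vapply(seq_along(design$theta_names), function(vv) {
      J <- which(design$col_var == vv)
      sum(ZWR[J, , drop = FALSE]^2) / (2 * sigma2) -
        sum(diagZWZ_tot[J]) / 2
    }, 0)
    out$grad <- gr
    out$ZWR <- ZWR
    out$diagZWZ_tot <- diagZWZ_tot
  }
  if (coef) {
    out$alpha <- setNames(alpha, design$genes)
    out$shared <- setNames(eta, design$fixed_names)
    out$cache <- list(Rl = Rl, L = L)
  }
  out
}

.pll_single <- function(design, L, grad, coef) {
  pre <- design$pre
  n <- design$n_obs
  A <- .lt_apply(L, t(.lt_apply(L, pre$ZtZ)))
  M <- A
  diag(M) <- diag(M) + 1
  R <- chol(M)
  logdet <- 2 * sum(log(diag(R)))
  TZX <- backsolve(R, .lt_apply(L, pre$ZtX), transpose = TRUE)
  TZy <- backsolve(R, .lt_apply(L, cbind(pre$Zty)), transpose = TRUE)
  XtWX <- pre$XtX - crossprod(TZX)
  XtWy <- pre$Xty - drop(crossprod(TZX, TZy))
  ytWy <- pre$yty - sum(TZy^2)
  b <- drop(solve(XtWX, XtWy))
  RSS <- ytWy - sum(b * XtWy)
  sigma2 <- RSS / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1) - logdet / 2

  out <- list(ll = ll, sigma2 = sigma2, RSS = RSS)
  if (grad || coef) {
    out$ZtR <- cbind(pre$Zty - drop(pre$ZtX %*% b))
  }
  if (grad) {
    TZZ <- backsolve(R, .lt_apply(L, pre$ZtZ), transpose = TRUE)
    TZR <- backsolve(R, .lt_apply(L, out$ZtR), transpose = TRUE)
    ZWR <- out$ZtR - crossprod(TZZ, TZR)
    diagZWZ <- diag(pre$ZtZ) - colSums(TZZ^2)
    gr <- vapply(seq_along(design$theta_names), function(vv) {
      J <- which(design$col_var == vv)
      sum(ZWR[J, , drop = FALSE]^2) / (2 * sigma2) - sum(diagZWZ[J]) / 2
    }, 0)
    out$grad <- gr
    out$ZWR <- ZWR
    out$diagZWZ_tot <- diagZWZ
  }
  if (coef) {
    out$beta <- setNames(b, design$fixed_names)
    out$cache <- list(R = R, L = L)
  }
  out
}

# Method-of-moments starting values for the variance ratios: regress OLS
# residuals on each random column (per covariance block); the excess of the
# squared coefficient over its sampling noise estimates lambda.
.moment_start <- function(design) {
  at0 <- .pll_core(design, rep(0, length(design$theta_names)),
                   grad = FALSE, coef = TRUE)
  sigma2 <- at0$sigma2
  ZWR <- at0$ZtR   # at theta = 0, W = I: Z'r per block (k x n_blocks)
  k <- nrow(ZWR)

  # per-block diag(Z'Z), matching the columns of ZWR
  dzz <- if (design$kind == "single") {
    cbind(diag(design$pre$ZtZ))
  } else if (design$pre$balanced) {
    matrix(diag(design$pre$ZtZ), k, design$pre$G)
  } else {
    vapply(design$pre$per, function(b) diag(b$ZtZ), numeric(k))
  }

  # one random level per (column, block): coefficient of residuals on it
  mom_col <- function(J) {
    zzm <- dzz[J, , drop = FALSE]
    use <- zzm > 1e-10
    if (!any(use)) return(0.3)
    cc2 <- (ZWR[J, , drop = FALSE][use] / zzm[use])^2
    est <- mean(cc2) - mean(sigma2 / zzm[use])
    max(est / sigma2, 0.05)
  }

  n_theta <- length(design$theta_names)
  mom <- numeric(n_theta)
  for (vv in seq_len(n_theta)) {
    J <- which(!is.na(design$col_var) & design$col_var == vv)
    mom[vv] <- if (length(J) == 0) 0.3 else mom_col(J)
  }
  if (!is.null(design$unstr)) {
    un <- design$unstr
    mom[un$param_idx] <- 0
    diag_idx <- un$param_idx[un$ij[, "row"] == un$ij[, "col"]]
    mom[diag_idx] <- vapply(un$cols, function(j) sqrt(mom_col(j)), 0)
  }
  mom
}

#' Control parameters for the profiled ML fit
#'
#' @param start_scales multiplicative factors applied to the moment starting
#'   values; one quasi-Newton run per factor.
#' @param extra_scales additional factors tried only if no initial run
#'   converges.
#' @param maxit,factr passed to [stats::optim()] (`L-BFGS-B`).
#' @param start_theta optional list of explicit starting vectors (used, e.g.,
#'   to restart a fit from a nested model's solution).
#' @export
fit_control <- function(start_scales = c(1, 0.1, 10),
                        extra_scales = c(0.01, 100),
                        maxit = 300, factr = 1e7,
                        start_theta = NULL) {
  list(start_scales = start_scales, extra_scales = extra_scales,
       maxit = maxit, factr = factr, start_theta = start_theta)
}

#' Fit the gene-set mixed model by maximum likelihood
#'
#' Maximises the marginal Gaussian likelihood of a design built by
#' [build_design()]. Fixed effects and the residual variance are profiled
#' out analytically; the remaining variance ratios are maximised by
#' `L-BFGS-B` with a box constraint at zero (so variance components can sit
#' exactly on the boundary), restarting from scaled method-of-moments
#' values. REML is deliberately not offered: the likelihood-ratio test
#' compares models with different fixed parts, which REML likelihoods cannot
#' do.
#'
#' @param design a `tcgsa_design`.
#' @param control see [fit_control()].
#' @return An object of class `tcgsa_fit` with elements `loglik`, `sigma2`,
#'   `theta` (variance ratios), `varcomp` (variances, natural scale),
#'   `coefficients`, `converged`, `n_obs`, `n_params`, and the design.
#' @export
fit_ml <- function(design, control = fit_control()) {
  stopifnot(inherits(design, "tcgsa_design"))
  n_theta <- length(design$theta_names)
  use_grad <- is.null(design$unstr)

  neg_big <- 1e30
  cache <- new.env(parent = emptyenv())
  fn <- function(par) {
    res <- tryCatch(.pll_core(design, par, grad = use_grad),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$ll)) return(neg_big)
    if (use_grad) {
      cache$par <- par
      cache$grad <- res$grad
    }
    -res$ll
  }
  gr <- function(par) {
    if (!is.null(cache$par) && isTRUE(all.equal(par, cache$par))) {
      return(-cache$grad)
    }
    res <- tryCatch(.pll_core(design, par, grad = TRUE),
                    error = function(e) NULL)
    if (is.null(res)) return(rep(0, length(par)))
    -res$grad
  }

  run_start <- function(par0) {
    tryCatch(
      optim(par0, fn, gr = if (use_grad) gr else NULL,
            method = "L-BFGS-B",
            lower = design$theta_lower, upper = rep(1e8, n_theta),
            control = list(maxit = control$maxit, factr = control$factr)),
      error = function(e) list(value = neg_big, par = par0,
                               convergence = 99L, message = conditionMessage(e))
    )
  }
  scale_start <- function(mom, sc) {
    if (is.null(design$unstr)) return(pmax(mom * sc, 1e-4))
    out <- mom
    out[1] <- max(out[1] * sc, 1e-4)
    dix <- design$unstr$param_idx[design$unstr$ij[, "row"] ==
                                    design$unstr$ij[, "col"]]
    out[dix] <- pmax(out[dix] * sqrt(sc), 1e-3)
    out
  }

  if (n_theta == 0L) {
    res <- .pll_core(design, numeric(0), coef = TRUE)
    best <- list(par = numeric(0), value = -res$ll, convergence = 0L)
  } else {
    mom <- .moment_start(design)
    starts <- lapply(control$start_scales, function(sc) scale_start(mom, sc))
    for (st in control$start_theta) {
      if (length(st) == n_theta) starts <- c(starts, list(pmax(st, 0)))
    }
    runs <- lapply(starts, run_start)
    ok <- vapply(runs, function(r) r$convergence == 0L && r$value < neg_big, NA)
    if (!any(ok)) {
      runs <- c(runs, lapply(control$extra_scales,
                             function(sc) run_start(scale_start(mom, sc))))
      ok <- vapply(runs, function(r) r$convergence == 0L && r$value < neg_big, NA)
    }
    vals <- vapply(runs, `[[`, 0, "value")
    best <- runs[[which.min(vals)]]
  }

  theta <- setNames(as.numeric(best$par), design$theta_names)
  final <- tryCatch(.pll_core(design, theta, coef = TRUE),
                    error = function(e) NULL)
  converged <- !is.null(final) && is.finite(final$ll) &&
    (n_theta == 0L || any(ok))
  if (is.null(final)) {
    final <- list(ll = NA_real_, sigma2 = NA_real_)
  }

  varcomp <- if (is.null(design$unstr)) {
    setNames(theta * final$sigma2, design$theta_names)
  } else {
    vc <- setNames(theta * final$sigma2, design$theta_names)
    L <- .make_L(design, theta)
    attr(vc, "Sigma_h") <- final$sigma2 * tcrossprod(L$Lam)
    vc[1] <- theta[1] * final$sigma2
    vc
  }

  coefficients <- if (design$kind == "single") {
    list(beta = final$beta)
  } else {
    mu <- mean(final$alpha)
    list(mu = mu, beta_gene = final$alpha - mu, alpha = final$alpha,
         shared = final$shared)
  }

  structure(
    list(
      loglik = final$ll,
      sigma2 = final$sigma2,
      theta = theta,
      varcomp = varcomp,
      coefficients = coefficients,
      converged = converged,
      n_obs = design$n_obs,
      n_params = design$rank_fixed + length(theta) + 1L,
      design = design,
      cache = final$cache,
      ZtR = final$ZtR
    ),
    class = "tcgsa_fit"
  )
}

#' @export
logLik.tcgsa_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' @export
print.tcgsa_fit <- function(x, ...) {
  cat(sprintf(
    "<tcgsa_fit> %s (%s) logLik=%.4f sigma=%.4f %s n=%d%s\n",
    x$design$hypothesis, x$design$kind, x$loglik, sqrt(x$sigma2),
    paste(sprintf("%s=%.4g", names(x$varcomp), as.numeric(x$varcomp)),
          collapse = " "),
    x$n_obs,
    if (x$converged) "" else " [NOT CONVERGED]"
  ))
  invisible(x)
}
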