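# Design bundles ---------------------------------------------------------
#
# A design bundle holds everything the profiled ML fitter needs for one gene
# set under one hypothesis. Two layouts are used:
#
# * "gene_blocks": fixed gene effects with gene-grouped random trends. The
#   marginal covariance is then block-diagonal across genes, each block
#   containing that gene's patient-intercept indicators and trend columns.
#   The per-gene fixed intercepts (mu + beta_g) are absorbed as local
#   intercepts and solved by Schur complement, so the shared fixed columns C
#   (group contrasts, trend coefficients) stay small.
# * "single": one covariance block for the whole subset; used when random
#   effects cross genes (random gene/patient intercepts, or patient-grouped
#   trends).
#
# Cross-products are precomputed once per design; every likelihood
# evaluation afterwards works on k x k matrices, where k is the number of
# random-effect columns per block.

#' Build the mixed-model design for one gene set
#'
#' @param data expression measurements restricted to one gene set (a data
#'   frame with columns `gene`, `patient`, `time`, `value`[, `group`]).
#' @param spec a [tcgsa_spec()].
#' @param hypothesis `"H1"` (full trend model) or `"H0"` (the corresponding
#'   null: no trend terms for one-group designs; a shared trend across
#'   groups when `spec$group_effects`).
#' @return An opaque design bundle (class `tcgsa_design`) consumed by
#'   [fit_ml()] and [loglik_at()].
#' @export
build_design <- function(data, spec, hypothesis = c("H1", "H0")) {
  hypothesis <- match.arg(hypothesis)
  if (!inherits(data, "tcgsa_expression")) {
    data <- as_expression_dataset(data)
  }
  genes <- sort(unique(data$gene))
  patients <- sort(unique(data$patient))
  times <- sort(unique(data$time))
  if (length(genes) < 2L || length(patients) < 2L || length(times) < 2L) {
    stop_tcgsa(
      "degenerate subset: need >= 2 genes, >= 2 patients, >= 2 distinct times",
      class = "tcgsa_validation_error"
    )
  }
  if (spec$group_effects) {
    if (is.null(data[["group"]])) {
      stop_tcgsa("spec has group_effects but data has no `group` column",
                 class = "tcgsa_validation_error")
    }
    groups <- sort(unique(data[["group"]]))
    if (length(groups) < 2L) {
      stop_tcgsa("group comparison requires >= 2 groups",
                 class = "tcgsa_validation_error")
    }
  } else {
    groups <- NULL
  }

  basis <- resolve_basis(spec, times)
  d <- basis$d

  if (!isTRUE(attr(data, "tcgsa_sorted"))) {
    ord <- order(data$gene, data$patient, data$time)
    data <- data[ord, ]
    attr(data, "tcgsa_sorted") <- TRUE
  }

  gene_grouped <- spec$intercept_structure == "gene_fixed" &&
    spec$trend_grouping == "gene"

  if (gene_grouped) {
    des <- .design_gene_blocks(data, spec, hypothesis, basis, genes,
                               patients, groups)
  } else {
    des <- .design_single_block(data, spec, hypothesis, basis, genes,
                                patients, groups)
  }
  des$data <- data
  des$spec <- spec
  des$basis <- basis
  des$hypothesis <- hypothesis
  des$genes <- genes
  des$patients <- patients
  des$groups <- groups
  des$n_obs <- nrow(data)
  class(des) <- "tcgsa_design"
  des
}

# Shared fixed columns (beyond per-gene intercepts) evaluated on a set of
# rows: group contrasts, trend columns, group x trend interactions.
.shared_fixed_cols <- function(time, group, basis, spec, hypothesis, groups) {
  cols <- NULL
  if (spec$group_effects) {
    for (m in groups[-1]) {
      cols <- cbind(cols, as.numeric(group == m))
      colnames(cols)[ncol(cols)] <- paste0("group_", m)
    }
  }
  with_trend <- hypothesis == "H1" || spec$group_effects
  if (with_trend) {
    B <- basis$evaluate(time)
    colnames(B) <- basis$colnames
    cols <- cbind(cols, B)
    if (spec$group_effects && hypothesis == "H1") {
      for (m in groups[-1]) {
        Bm <- B * as.numeric(group == m)
        colnames(Bm) <- paste0(basis$colnames, ":group_", m)
        cols <- cbind(cols, Bm)
      }
    }
  }
  if (is.null(cols)) cols <- matrix(0, nrow = length(time), ncol = 0L)
  cols
}

# Random-effect columns of one gene block: patient-intercept indicators plus
# per-gene trend columns (possibly masked per group).
.random_cols_block <- function(time, patient, group, basis, spec, hypothesis,
                               patients, groups) {
  np <- length(patients)
  Zp <- matrix(0, nrow = length(time), ncol = np)
  Zp[cbind(seq_along(patient), match(patient, patients))] <- 1
  colnames(Zp) <- paste0("pat_", patients)
  col_var <- rep(1L, np)          # theta[1] = patient-in-gene intercept ratio
  term_dims <- c(intercept_gene_patient = 1L)
  theta_names <- "sigma2_c"
  Z <- Zp

  with_random_trend <- hypothesis == "H1" || spec$group_effects
  if (with_random_trend) {
    B <- basis$evaluate(time)
    d <- ncol(B)
    if (spec$group_effects && spec$group_random && hypothesis == "H1") {
      for (m in groups) {
        Bm <- B * as.numeric(group == m)
        colnames(Bm) <- paste0("h_", basis$colnames, "_", m)
        Z <- cbind(Z, Bm)
        col_var <- c(col_var, length(theta_names) + seq_len(d))
        theta_names <- c(theta_names,
                         paste0("sigma2_h", seq_len(d), "_", m))
      }
      term_dims <- c(term_dims,
                     setNames(rep(ncol(B), length(groups)),
                              paste0("trend_", groups)))
    } else {
      colnames(B) <- paste0("h_", basis$colnames)
      Z <- cbind(Z, B)
      col_var <- c(col_var, length(theta_names) + seq_len(d))
      theta_names <- c(theta_names, paste0("sigma2_h", seq_len(d)))
      term_dims <- c(term_dims, trend = d)
    }
  }
  list(Z = Z, col_var = col_var, theta_names = theta_names,
       term_dims = term_dims)
}

.design_gene_blocks <- function(data, spec, hypothesis, basis, genes,
                                patients, groups) {
  G <- length(genes)
  idx <- split(seq_len(nrow(data)), factor(data$gene, levels = genes))

  # balanced iff every gene shares the same (patient, time[, group]) pattern
  grp <- data[["group"]]
  pat_key <- vapply(idx, function(i) {
    paste(data$patient[i], data$time[i],
          if (!is.null(grp)) grp[i] else "", collapse = "|")
  }, "")
  balanced <- length(unique(pat_key)) == 1L

  build_block <- function(rows) {
    rc <- .random_cols_block(data$time[rows], data$patient[rows],
                             grp[rows], basis, spec, hypothesis,
                             patients, groups)
    C <- .shared_fixed_cols(data$time[rows], grp[rows], basis, spec,
                            hypothesis, groups)
    c(rc, list(C = C, rows = rows))
  }

  blocks <- if (balanced) {
    b1 <- build_block(idx[[1]])
    lapply(idx, function(rows) list(rows = rows))
  } else {
    lapply(idx, build_block)
  }
  proto <- if (balanced) b1 else blocks[[1]]

  # drop fixed columns aliased with the per-gene intercepts: centre C within
  # each block, then rank-reveal by pivoted QR
  p_c_full <- ncol(proto$C)
  keep <- seq_len(p_c_full)
  rank_C <- 0L
  if (p_c_full > 0) {
    Cc <- if (balanced) {
      sweep(b1$C, 2, colMeans(b1$C))
    } else {
      do.call(rbind, lapply(blocks, function(b) {
        sweep(b$C, 2, colMeans(b$C))
      }))
    }
    qc <- qr(Cc)
    rank_C <- qc$rank
    keep <- sort(qc$pivot[seq_len(rank_C)])
  }
  fixed_names <- colnames(proto$C)[keep]

  pre <- if (balanced) {
    Z <- b1$Z
    C <- b1$C[, keep, drop = FALSE]
    n_b <- nrow(Z)
    Y <- matrix(data$value, nrow = n_b, ncol = G)
    list(
      balanced = TRUE, n_b = n_b, G = G,
      Z = Z, C = C,
      ZtZ = crossprod(Z), Zt1 = colSums(Z), ZtC = crossprod(Z, C),
      CtC = crossprod(C), Ct1 = colSums(C),
      Y = Y, ZtY = crossprod(Z, Y), CtY = crossprod(C, Y),
      oneY = colSums(Y), yy = colSums(Y^2)
    )
  } else {
    per <- lapply(blocks, function(b) {
      Z <- b$Z
      C <- b$C[, keep, drop = FALSE]
      yv <- data$value[b$rows]
      list(
        n_b = nrow(Z), Z = Z, C = C, rows = b$rows,
        ZtZ = crossprod(Z), Zt1 = colSums(Z), ZtC = crossprod(Z, C),
        CtC = crossprod(C), Ct1 = colSums(C),
        Zty = drop(crossprod(Z, yv)), Cty = drop(crossprod(C, yv)),
        oney = sum(yv), yy = sum(yv^2), y = yv
      )
    })
    list(balanced = FALSE, G = G, per = per)
  }

  # parameter bookkeeping; with unstructured Sigma_h the per-column trend
  # variance ratios are replaced by the entries of one lower-triangular
  # relative Cholesky factor Lambda_h (d x d) shared across genes
  col_var <- proto$col_var
  theta_names <- proto$theta_names
  theta_lower <- rep(0, length(theta_names))
  unstr <- NULL
  trend_cols <- which(col_var > 1L)
  if (spec$random_cov == "unstructured" && length(trend_cols) > 0) {
    if (spec$group_effects && spec$group_random) {
      stop_tcgsa("unstructured Sigma_h is not available with group-specific random trends")
    }
    d <- length(trend_cols)
    ij <- which(lower.tri(diag(d), diag = TRUE), arr.ind = TRUE)
    ij <- ij[order(ij[, "col"], ij[, "row"]), , drop = FALSE]
    vech_names <- paste0("Lh_", ij[, "row"], ij[, "col"])
    theta_names <- c("sigma2_c", vech_names)
    theta_lower <- c(0, ifelse(ij[, "row"] == ij[, "col"], 0, -Inf))
    unstr <- list(dim = d, cols = trend_cols, ij = ij,
                  param_idx = 1L + seq_len(nrow(ij)))
    col_var[trend_cols] <- NA_integer_
  }

  list(
    kind = "gene_blocks",
    y = data$value,
    block_rows = lapply(idx, identity),
    pre = pre,
    col_var = col_var,
    theta_names = theta_names,
    theta_lower = theta_lower,
    term_dims = proto$term_dims,
    n_random_dims = sum(proto$term_dims),
    fixed_names = fixed_names,
    p_c = length(keep),
    rank_fixed = G + rank_C,
    unstr = unstr
  )
}

.design_single_block <- function(data, spec, hypothesis, basis, genes,
                                 patients, groups) {
  if (spec$random_cov == "unstructured") {
    stop_tcgsa(paste0("unstructured Sigma_h requires the default ",
                      "gene-fixed intercepts with gene-grouped trends"))
  }
  n <- nrow(data)
  G <- length(genes)
  P <- length(patients)

  # fixed part
  X <- matrix(1, nrow = n, ncol = 1L, dimnames = list(NULL, "(Intercept)"))
  if (spec$intercept_structure == "gene_fixed") {
    gf <- factor(data$gene, levels = genes)
    cm <- stats::contr.sum(G)
    Xg <- cm[as.integer(gf), , drop = FALSE]
    colnames(Xg) <- paste0("gene_", genes[-G])
    X <- cbind(X, Xg)
  }
  Cs <- .shared_fixed_cols(data$time, data[["group"]], basis, spec,
                           hypothesis, groups)
  X <- cbind(X, Cs)
  qx <- qr(X)
  rank_X <- qx$rank
  keep <- sort(qx$pivot[seq_len(rank_X)])
  X <- X[, keep, drop = FALSE]

  # random part
  Z <- NULL
  col_var <- integer(0)
  theta_names <- character(0)
  term_dims <- integer(0)
  add_term <- function(Zt, vars, nms, dims) {
    Z <<- cbind(Z, Zt)
    col_var <<- c(col_var, length(theta_names) + vars)
    theta_names <<- c(theta_names, nms)
    term_dims <<- c(term_dims, dims)
  }

  if (spec$intercept_structure == "gene_fixed") {
    gp <- factor(paste(data$gene, data$patient, sep = ":"))
    Zgp <- matrix(0, n, nlevels(gp))
    Zgp[cbind(seq_len(n), as.integer(gp))] <- 1
    add_term(Zgp, rep(1L, nlevels(gp)), "sigma2_c",
             c(intercept_gene_patient = 1L))
  } else {
    pf <- factor(data$patient, levels = patients)
    Zp <- matrix(0, n, P)
    Zp[cbind(seq_len(n), as.integer(pf))] <- 1
    add_term(Zp, rep(1L, P), "sigma2_c", c(intercept_patient = 1L))
    gf <- factor(data$gene, levels = genes)
    Zg <- matrix(0, n, G)
    Zg[cbind(seq_len(n), as.integer(gf))] <- 1
    add_term(Zg, rep(1L, G), "sigma2_beta", c(intercept_gene = 1L))
  }

  with_random_trend <- hypothesis == "H1" || spec$group_effects
  if (with_random_trend) {
    B <- basis$evaluate(data$time)
    d <- ncol(B)
    lev <- if (spec$trend_grouping == "gene") genes else patients
    lab <- if (spec$trend_grouping == "gene") data$gene else data$patient
    lf <- factor(lab, levels = lev)
    Zt <- matrix(0, n, length(lev) * d)
    for (k in seq_len(d)) {
      cols <- (seq_along(lev) - 1L) * d + k
      Zt[cbind(seq_len(n), cols[as.integer(lf)])] <- B[, k]
    }
    add_term(Zt, rep(seq_len(d), times = length(lev)),
             paste0("sigma2_h", seq_len(d)), c(trend = d))
  }

  list(
    kind = "single",
    y = data$value,
    pre = list(
      balanced = FALSE, single = TRUE,
      X = X, Z = Z,
      XtX = crossprod(X), Xty = drop(crossprod(X, data$value)),
      yty = sum(data$value^2),
      ZtZ = crossprod(Z), ZtX = crossprod(Z, X),
      Zty = drop(crossprod(Z, data$value))
    ),
    col_var = col_var,
    theta_names = theta_names,
    theta_lower = rep(0, length(theta_names)),
    term_dims = term_dims,
    n_random_dims = sum(term_dims),
    fixed_names = colnames(X),
    p_c = ncol(X),
    rank_fixed = rank_X,
    unstr = NULL
  )
}

#' @export
print.tcgsa_design <- function(x, ...) {
  cat(sprintf(
    "<tcgsa_design> %s, %s: %d obs, %d genes, %d patients; fixed rank %d; %d variance ratio(s): %s\n",
    x$kind, x$hypothesis, x$n_obs, length(x$genes), length(x$patients),
    x$rank_fixed, length(x$theta_names),
    paste(x$theta_names, collapse = ", ")
  ))
  invisible(x)
}
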