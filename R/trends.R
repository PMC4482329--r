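# BLUP trajectory prediction and trend decomposition ---------------------

# apply L (not L') to a matrix with k rows
.l_apply <- function(Lspec, A) {
  if (Lspec$type == "diag") {
    Lspec$s * A
  } else {
    out <- Lspec$s * A
    out[Lspec$cols, ] <- Lspec$Lam %*% A[Lspec$cols, , drop = FALSE]
    out
  }
}

#' Best linear unbiased predictions of the random effects
#'
#' Conditional means of the random effects given the data at the ML variance
#' estimates, `u_hat = G Z' V^{-1} (y - X b_hat)`, computed blockwise as
#' `L M^{-1} L' Z' r`.
#'
#' @param fit a converged `tcgsa_fit`.
#' @return A tibble with one row per random-effect realisation: `block`
#'   (the gene for gene-blocked designs, `"all"` otherwise), `effect` (the
#'   random column label) and `value`.
#' @export
random_effects <- function(fit) {
  stopifnot(inherits(fit, "tcgsa_fit"))
  if (!fit$converged) stop_tcgsa("fit did not converge; BLUPs unavailable")
  design <- fit$design
  L <- .make_L(design, fit$theta)
  blup_block <- function(R, ztr) {
    t1 <- .lt_apply(L, cbind(ztr))
    drop(.l_apply(L, backsolve(R, backsolve(R, t1, transpose = TRUE))))
  }
  if (design$kind == "single") {
    u <- blup_block(fit$cache$R, fit$ZtR[, 1])
    return(tibble::tibble(block = "all", effect = colnames(design$pre$Z),
                          value = u))
  }
  pre <- design$pre
  G <- pre$G
  out <- vector("list", G)
  for (g in seq_len(G)) {
    R <- if (pre$balanced) fit$cache$R else fit$cache$Rl[[g]]
    Zcols <- if (pre$balanced) colnames(pre$Z) else colnames(pre$per[[g]]$Z)
    u <- blup_block(R, fit$ZtR[, g])
    out[[g]] <- tibble::tibble(block = design$genes[g], effect = Zcols,
                               value = u)
  }
  dplyr::bind_rows(out)
}

#' Predict gene trajectories from the fitted mixed model
#'
#' Fitted value = fixed part + BLUP random part for every observed
#' measurement. Because the random effects are shrunken towards the
#' set-level average when the residual noise is large relative to the
#' random-effect variances, the predicted trajectories are smoother than the
#' raw data, which is what makes the trend decomposition workable.
#'
#' @param fit a converged `tcgsa_fit`.
#' @return A tibble `(gene, patient, time[, group], observed, fitted)`.
#' @export
blup_predict <- function(fit) {
  stopifnot(inherits(fit, "tcgsa_fit"))
  if (!fit$converged) stop_tcgsa("fit did not converge; predictions unavailable")
  design <- fit$design
  L <- .make_L(design, fit$theta)
  fitted <- numeric(design$n_obs)
  blup_block <- function(R, ztr) {
    t1 <- .lt_apply(L, cbind(ztr))
    drop(.l_apply(L, backsolve(R, backsolve(R, t1, transpose = TRUE))))
  }
  if (design$kind == "single") {
    u <- blup_block(fit$cache$R, fit$ZtR[, 1])
    fitted <- drop(design$pre$X %*% fit$coefficients$beta) +
      drop(design$pre$Z %*% u)
  } else {
    pre <- design$pre
    alpha <- fit$coefficients$alpha
    eta <- fit$coefficients$shared
    for (g in seq_len(pre$G)) {
      rows <- design$block_rows[[g]]
      Z <- if (pre$balanced) pre$Z else pre$per[[g]]$Z
      C <- if (pre$balanced) pre$C else pre$per[[g]]$C
      R <- if (pre$balanced) fit$cache$R else fit$cache$Rl[[g]]
      u <- blup_block(R, fit$ZtR[, g])
      fx <- alpha[g] + if (ncol(C) > 0) drop(C %*% eta) else 0
      fitted[rows] <- fx + drop(Z %*% u)
    }
  }
  out <- design$data
  out$observed <- out$value
  out$fitted <- fitted
  out$value <- NULL
  class(out) <- setdiff(class(out), "tcgsa_expression")
  out
}

#' Per-gene median trajectories
#'
#' Summarises predictions (or raw values) as the median over patients per
#' (gene, time): the clustering substrate for trend splitting.
#'
#' @param pred a tibble with `gene`, `time` and the column `col`.
#' @param col which column to summarise (`"fitted"` or `"observed"`).
#' @return A genes-by-times numeric matrix (dimnames set).
#' @export
gene_trajectories <- function(pred, col = "fitted") {
  wide <- pred |>
    dplyr::group_by(.data$gene, .data$time) |>
    dplyr::summarise(v = median(.data[[col]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "time", values_from = "v")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

#' Choose the number of trends with the gap statistic
#'
#' Compares the log within-cluster dispersion of Ward hierarchical
#' clusterings cut at `k = 1..k_max` against `B` reference datasets drawn
#' from a single multivariate normal component with the data's mean and
#' covariance -- the literal "one trend plus jointly Gaussian variation"
#' null that trend splitting is meant to reject. The dispersion is
#' Tibshirani's `W_k = sum_c sum_{i,j in c} d^2_ij / (2 n_c)` (within-cluster
#' sum of squares). The reported `k` is the smallest one whose gap lies
#' within `se_factor` standard errors of the largest gap.
#'
#' A box-shaped (uniform-over-ranges) reference was rejected during
#' development: smooth predicted trajectories live on a low-dimensional,
#' highly correlated manifold, and against a box reference the gap curve
#' rises with `k` indefinitely, splitting even perfectly homogeneous sets.
#'
#' @param traj genes-by-features numeric matrix (e.g. from
#'   [gene_trajectories()]).
#' @param k_max largest number of clusters to consider; default
#'   `min(10, nrow - 1)`.
#' @param B number of reference draws.
#' @param seed RNG seed used locally (the caller's RNG state is restored).
#' @param se_factor multiple of the reference standard error used by the
#'   selection rule.
#' @return The selected number of clusters (integer >= 1), with the gap
#'   table (`logW`, `E.logW`, `gap`, `SE.sim`) attached as attribute
#'   `"gap"`.
#' @export
gap_statistic_k <- function(traj, k_max = NULL, B = 50, seed = 1234,
                            se_factor = 2) {
  traj <- as.matrix(traj)
  n <- nrow(traj)
  if (n < 2L) return(1L)
  k_max <- k_max %||% min(10L, n - 1L)
  if (k_max < 1L) stop_tcgsa("`k_max` must be >= 1")
  k_max <- min(k_max, n - 1L)
  if (k_max < 2L) return(1L)
  rng <- apply(traj, 2, function(x) diff(range(x)))
  if (all(rng < 1e-12)) return(1L)  # degenerate: all genes identical

  w_k <- function(x, labels) {
    s <- 0
    for (l in unique(labels)) {
      xs <- x[labels == l, , drop = FALSE]
      if (nrow(xs) > 1) s <- s + sum(dist(xs)^2) / nrow(xs)
    }
    s
  }
  log_w_curve <- function(x) {
    hc <- hclust(dist(x), method = "ward.D2")
    vapply(seq_len(k_max), function(k) {
      log(max(w_k(x, cutree(hc, k)), 1e-300))
    }, 0)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  logW <- log_w_curve(traj)
  ee <- eigen(cov(traj), symmetric = TRUE)
  A <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), ncol(traj))
  mu <- colMeans(traj)
  ref <- vapply(seq_len(B), function(b) {
    xr <- sweep(matrix(rnorm(n * ncol(traj)), n) %*% t(A), 2, mu, "+")
    log_w_curve(xr)
  }, numeric(k_max))
  gap <- rowMeans(ref) - logW
  se <- apply(ref, 1, sd) * sqrt(1 + 1 / B)
  k <- cluster::maxSE(gap, se, method = "globalSEmax",
                      SE.factor = se_factor)
  structure(as.integer(k),
            gap = cbind(logW = logW, E.logW = rowMeans(ref),
                        gap = gap, SE.sim = se))
}

#' Summarise the trends of a partitioned gene set
#'
#' The median over genes (of per-gene medians over patients) at each time
#' summarises each trend; a display copy is rescaled to unit variance over
#' time so that trends of different amplitude are comparable on one heatmap.
#'
#' @param traj genes-by-times matrix of per-gene median trajectories
#'   (raw scale).
#' @param labels integer/character cluster label per gene (named or in row
#'   order of `traj`).
#' @param set_name label carried along.
#' @return A `tcgsa_trend_partition`: list with `set_name`, `trajectories`,
#'   `labels`, `n_trends`, `trend_median` (trends x times, raw) and
#'   `trend_display` (unit-variance copy).
#' @export
summarize_trends <- function(traj, labels, set_name = NA_character_) {
  traj <- as.matrix(traj)
  if (length(labels) != nrow(traj)) {
    stop_tcgsa("`labels` must have one entry per gene")
  }
  labs <- as.character(labels)
  lev <- unique(labs)
  if (any(table(factor(labs, levels = lev)) == 0)) {
    stop_tcgsa("empty cluster")
  }
  med <- t(vapply(lev, function(l) {
    apply(traj[labs == l, , drop = FALSE], 2, median)
  }, numeric(ncol(traj))))
  rownames(med) <- lev
  disp <- t(apply(med, 1, function(x) {
    s <- sd(x)
    if (is.finite(s) && s > 1e-12) x / s else x
  }))
  dimnames(disp) <- dimnames(med)
  structure(
    list(set_name = set_name,
         trajectories = traj,
         labels = setNames(labs, rownames(traj)),
         n_trends = length(lev),
         trend_median = med,
         trend_display = disp),
    class = "tcgsa_trend_partition"
  )
}

#' @export
print.tcgsa_trend_partition <- function(x, ...) {
  cat(sprintf("<tcgsa_trend_partition> %s: %d gene(s) in %d trend(s)\n",
              x$set_name, nrow(x$trajectories), x$n_trends))
  invisible(x)
}

#' Decompose significant gene sets into trends
#'
#' For every significant set of a [run_tcgsa()] result: predict per-gene
#' trajectories by BLUP from the H1 fit, take per-gene medians over
#' patients, standardise each gene's trajectory, split with Ward clustering
#' + the gap statistic, and summarise each trend by its median. Only
#' significant sets are partitioned (test first, characterise after).
#'
#' @param result a `tcgsa_result`.
#' @param data the expression dataset the result was computed from (used to
#'   refit sets whose fits were not kept).
#' @param sets the gene set collection (same requirement).
#' @param k_max,B,seed forwarded to [gap_statistic_k()].
#' @return A `tcgsa_trends`: list with `partitions` (named list of
#'   `tcgsa_trend_partition`), `assignments` (tibble `set_name`, `gene`,
#'   `trend`), and `predictions` (per-set BLUP prediction tibbles).
#' @export
tcgsa_trends <- function(result, data = NULL, sets = NULL, k_max = NULL,
                         B = 50, seed = 1234) {
  stopifnot(inherits(result, "tcgsa_result"))
  sig <- result$table$set_name[result$table$significant]
  if (length(sig) == 0) {
    warning("no significant gene sets; nothing to partition")
    return(structure(list(partitions = list(),
                          assignments = tibble::tibble(
                            set_name = character(), gene = character(),
                            trend = character()),
                          predictions = list()),
                     class = "tcgsa_trends"))
  }
  partitions <- list()
  predictions <- list()
  for (nm in sig) {
    fit <- NULL
    if (!is.null(result$fits)) fit <- result$fits[[nm]]$fit_H1
    if (is.null(fit)) {
      if (is.null(data) || is.null(sets)) {
        stop_tcgsa("fits were not kept; supply `data` and `sets` to refit")
      }
      genes <- sets$genes[[match(nm, sets$set_name)]]
      sub <- as_expression_dataset(data)
      sub <- sub[sub$gene %in% genes, , drop = FALSE]
      fit <- fit_ml(build_design(sub, result$spec, "H1"))
    }
    pred <- blup_predict(fit)
    traj <- gene_trajectories(pred, "fitted")
    # gene-centred (baseline removed), amplitude retained: per-gene
    # variance scaling would blow homogeneous sets' estimation noise up to
    # unit size and fabricate spurious trends
    ctraj <- sweep(traj, 1, rowMeans(traj))
    k <- gap_statistic_k(ctraj, k_max = k_max, B = B, seed = seed)
    labels <- if (k == 1L) rep(1L, nrow(traj)) else {
      cutree(hclust(dist(ctraj), method = "ward.D2"), k = k)
    }
    partitions[[nm]] <- summarize_trends(traj, labels, set_name = nm)
    predictions[[nm]] <- pred
  }
  assignments <- dplyr::bind_rows(lapply(partitions, function(p) {
    tibble::tibble(set_name = p$set_name,
                   gene = names(p$labels), trend = unname(p$labels))
  }))
  structure(list(partitions = partitions, assignments = assignments,
                 predictions = predictions),
            class = "tcgsa_trends")
}

#' Assemble the trends-by-times heatmap table
#'
#' One row per trend of each significant set, values being the
#' unit-variance trend medians; rows ordered either by hierarchical
#' clustering of the trends or by decreasing likelihood-ratio percentile of
#' the parent set.
#'
#' @param result a `tcgsa_result`.
#' @param trends a `tcgsa_trends` for the same result.
#' @param ordering `"hierarchical"` or `"LR_percentile"`.
#' @return A `tcgsa_heatmap`: list with `matrix` (trends x times) and
#'   `row_info` (tibble `set_name`, `trend`, `LR_percentile`). Empty, with
#'   a warning, when nothing is significant.
#' @export
heatmap_table <- function(result, trends,
                          ordering = c("hierarchical", "LR_percentile")) {
  ordering <- match.arg(ordering)
  if (length(trends$partitions) == 0) {
    warning("no significant gene sets; empty heatmap")
    return(structure(list(matrix = matrix(0, 0, 0),
                          row_info = tibble::tibble(
                            set_name = character(), trend = character(),
                            LR_percentile = numeric())),
                     class = "tcgsa_heatmap"))
  }
  pct <- setNames(result$table$LR_percentile, result$table$set_name)
  rows <- list()
  info <- list()
  for (p in trends$partitions) {
    for (l in rownames(p$trend_display)) {
      rows[[length(rows) + 1L]] <- p$trend_display[l, ]
      info[[length(info) + 1L]] <- tibble::tibble(
        set_name = p$set_name, trend = l,
        LR_percentile = unname(pct[p$set_name])
      )
    }
  }
  m <- do.call(rbind, rows)
  row_info <- dplyr::bind_rows(info)
  rownames(m) <- paste0(row_info$set_name, ":", row_info$trend)
  ord <- if (ordering == "LR_percentile") {
    order(-row_info$LR_percentile, row_info$set_name, row_info$trend)
  } else if (nrow(m) > 2) {
    hclust(dist(m), method = "ward.D2")$order
  } else {
    seq_len(nrow(m))
  }
  structure(list(matrix = m[ord, , drop = FALSE],
                 row_info = row_info[ord, ],
                 ordering = ordering),
            class = "tcgsa_heatmap")
}
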