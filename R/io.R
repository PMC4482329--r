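# Results and configuration I/O ------------------------------------------

#' Assemble a run configuration
#'
#' A plain serialisable list of every analysis switch; written into each
#' run report so an output directory is self-describing, and
#' round-trippable through JSON.
#'
#' @param expr,gmt input paths (optional).
#' @param basis,knots,t_ref time-function choice.
#' @param intercept_structure,trend_grouping,group_effects,group_random,random_cov
#'   model switches, see [tcgsa_spec()].
#' @param alpha,adjust,min_size,max_size testing switches.
#' @param seed RNG seed.
#' @param out output directory.
#' @return A named list of class `tcgsa_config`.
#' @export
tcgsa_config <- function(expr = NULL, gmt = NULL, basis = "linear",
                         knots = NULL, t_ref = NULL,
                         intercept_structure = "gene_fixed",
                         trend_grouping = "gene",
                         group_effects = FALSE, group_random = FALSE,
                         random_cov = "diagonal",
                         alpha = 0.05, adjust = "BY",
                         min_size = 10, max_size = 500,
                         seed = NULL, out = NULL) {
  structure(
    list(expr = expr, gmt = gmt, basis = basis, knots = knots, t_ref = t_ref,
         intercept_structure = intercept_structure,
         trend_grouping = trend_grouping,
         group_effects = group_effects, group_random = group_random,
         random_cov = random_cov, alpha = alpha, adjust = adjust,
         min_size = min_size, max_size = max_size, seed = seed, out = out),
    class = "tcgsa_config"
  )
}

#' @rdname tcgsa_config
#' @param config a `tcgsa_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname tcgsa_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- tcgsa_config()
  for (nm in intersect(names(raw), names(cfg))) {
    if (!is.null(raw[[nm]])) cfg[[nm]] <- raw[[nm]]
  }
  cfg
}

#' Spec from a configuration
#' @param config a `tcgsa_config`.
#' @export
spec_from_config <- function(config) {
  tcgsa_spec(
    basis = config$basis, knots = config$knots, t_ref = config$t_ref,
    intercept_structure = config$intercept_structure,
    trend_grouping = config$trend_grouping,
    group_effects = config$group_effects,
    group_random = config$group_random,
    random_cov = config$random_cov
  )
}

#' Write analysis outputs to a directory
#'
#' Produces a deterministic file set: `results.tsv` (one row per retained
#' set with raw and adjusted p-values), `trends.tsv` (gene-to-trend
#' assignments) and `heatmap.tsv` when trend partitions are supplied, and
#' `run_report.json` (configuration, set accounting, convergence failures).
#' Numeric columns are written with full precision.
#'
#' @param result a `tcgsa_result`.
#' @param outdir output directory (created if missing).
#' @param trends optional `tcgsa_trends`.
#' @param heatmap optional `tcgsa_heatmap`.
#' @param config optional `tcgsa_config` recorded in the report.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, outdir, trends = NULL, heatmap = NULL,
                          config = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  fmt <- function(df) {
    df2 <- df
    num <- vapply(df2, is.numeric, NA)
    df2[num] <- lapply(df2[num], function(x) {
      ifelse(is.na(x), NA_character_, sprintf("%.12g", x))
    })
    df2
  }
  p_res <- file.path(outdir, "results.tsv")
  readr::write_tsv(fmt(result$table), p_res, progress = FALSE)
  paths <- c(paths, p_res)

  if (!is.null(trends) && nrow(trends$assignments) > 0) {
    p_tr <- file.path(outdir, "trends.tsv")
    readr::write_tsv(trends$assignments, p_tr, progress = FALSE)
    paths <- c(paths, p_tr)
  }
  if (!is.null(heatmap) && nrow(heatmap$matrix) > 0) {
    p_hm <- file.path(outdir, "heatmap.tsv")
    hm <- tibble::as_tibble(cbind(heatmap$row_info,
                                  as.data.frame(heatmap$matrix)))
    readr::write_tsv(fmt(hm), p_hm, progress = FALSE)
    paths <- c(paths, p_hm)
  }

  report <- list(
    config = if (!is.null(config)) unclass(config) else result$report$config,
    n_total = result$report$n_total,
    n_retained = result$report$n_retained,
    n_discarded = result$report$n_discarded,
    n_failed = result$report$n_failed,
    n_significant = result$report$n_significant,
    discarded = result$report$discarded,
    not_assessed = result$table$set_name[
      result$table$convergence_status != "ok"]
  )
  p_rep <- file.path(outdir, "run_report.json")
  jsonlite::write_json(report, p_rep, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE, dataframe = "rows")
  paths <- c(paths, p_rep)
  invisible(paths)
}

#' Read back a results table written by [write_results()]
#' @param path path to `results.tsv`.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    set_name = "c", n_genes_observed = "i", LR = "d",
                    q = "i", r = "i", p_raw = "d", p_adj = "d",
                    significant = "l", LR_percentile = "d",
                    convergence_status = "c"
                  ))
}
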