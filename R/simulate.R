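# Synthetic longitudinal expression data ---------------------------------

#' Default generator parameters
#'
#' The generative model is the one the analysis fits: per gene `g`, patient
#' `p`, time `t`,
#' `y = mu + beta_g + c_gp + (eta + h_g)' B(u) + eps`, with
#' `B(u) = (u, u^2, u^3)` on centred time `u = t - mean(times)`,
#' `c_gp ~ N(0, sigma_c^2)`, `h_gk ~ N(0, sigma_h_k^2)` independent and
#' `eps ~ N(0, sigma^2)`.
#'
#' * `null` sets: `eta = 0`, `sigma_h = 0` (flat, gene + gene-by-patient
#'   intercepts + noise).
#' * `homogeneous` sets: one weak, mostly monotone cubic set-level trend
#'   shared by all genes plus small per-gene coefficient deviations --
#'   a single coherent dynamic of subtle amplitude.
#' * `heterogeneous` sets: genes split round-robin across `n_subtrends`
#'   sub-trends of comparable amplitude and opposing signs (mean trend near
#'   zero; the signal lives in the between-gene heterogeneity) plus the same
#'   small per-gene deviations.
#'
#' Amplitudes are in residual-SD units (`sigma = 1`): the homogeneous trend
#' is calibrated so that a 50-gene, 20-patient, 8-time set is rejected with
#' probability around 0.85, and the heterogeneous sub-trends are strong
#' enough to be both rejected and split into their three dynamics.
#'
#' @param ... named overrides of the defaults.
#' @return A list of generator parameters.
#' @export
sim_params <- function(...) {
  defaults <- list(
    mu = 0, sigma = 1, sigma_c = 0.5, sigma_beta = 0.5,
    hom = list(
      eta = c(0.014, 0.005, 0),
      sigma_h = c(0.02, 0.004, 0.001)
    ),
    het = list(
      etas = list(
        c(0, 0.12, 0),
        c(-0.21, -0.06, 0),
        c(0.21, -0.06, 0)
      ),
      sigma_h = c(0.02, 0.004, 0.001)
    )
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    stop_tcgsa(paste0("unknown generator parameter(s): ",
                      paste(bad, collapse = ", ")))
  }
  # top-level components are replaced wholesale (no recursive merging)
  defaults[names(over)] <- over
  defaults
}

#' Simulate one gene set's longitudinal expression
#'
#' Draws one gene-set fragment from the generative model of [sim_params()],
#' using the caller's RNG state.
#'
#' @param kind `"null"`, `"homogeneous"` or `"heterogeneous"`.
#' @param n_genes,n_patients number of genes / patients.
#' @param times numeric vector of measurement times.
#' @param params see [sim_params()].
#' @param gene_ids,patient_ids optional explicit IDs.
#' @return An expression tibble of `n_genes * n_patients * length(times)`
#'   records, with the per-gene sub-trend assignment in attribute
#'   `"subtrend"`.
#' @export
simulate_gene_set <- function(kind = c("null", "homogeneous", "heterogeneous"),
                              n_genes = 50, n_patients = 20, times = 0:7,
                              params = sim_params(),
                              gene_ids = NULL, patient_ids = NULL) {
  kind <- match.arg(kind)
  if (params$sigma < 0 || params$sigma_c < 0 || params$sigma_beta < 0) {
    stop_tcgsa("standard deviations must be >= 0")
  }
  gene_ids <- gene_ids %||% sprintf("g%03d", seq_len(n_genes))
  patient_ids <- patient_ids %||% sprintf("P%02d", seq_len(n_patients))
  u <- times - mean(times)
  B <- cbind(u, u^2, u^3)
  n_t <- length(times)

  beta_g <- rnorm(n_genes, 0, params$sigma_beta)
  sub <- rep(NA_integer_, n_genes)
  eta_mat <- matrix(0, n_genes, 3)   # per-gene mean-trend coefficients
  sigma_h <- c(0, 0, 0)
  if (kind == "homogeneous") {
    eta_mat <- matrix(params$hom$eta, n_genes, 3, byrow = TRUE)
    sigma_h <- params$hom$sigma_h
  } else if (kind == "heterogeneous") {
    n_sub <- length(params$het$etas)
    sub <- rep(seq_len(n_sub), length.out = n_genes)
    eta_mat <- do.call(rbind, params$het$etas)[sub, , drop = FALSE]
    sigma_h <- params$het$sigma_h
  }
  if (any(sigma_h < 0)) stop_tcgsa("sigma_h must be >= 0")
  h <- matrix(rnorm(n_genes * 3, 0, rep(sigma_h, each = n_genes)),
              n_genes, 3)
  coef_g <- eta_mat + if (kind == "null") 0 else h
  trend_g <- coef_g %*% t(B)       # n_genes x n_t

  c_gp <- matrix(rnorm(n_genes * n_patients, 0, params$sigma_c),
                 n_genes, n_patients)
  # rows laid out gene-major, then patient, then time
  gi <- rep(seq_len(n_genes), each = n_patients * n_t)
  pi <- rep(rep(seq_len(n_patients), each = n_t), times = n_genes)
  ti <- rep(seq_len(n_t), times = n_genes * n_patients)
  value <- params$mu +
    beta_g[gi] +
    c_gp[cbind(gi, pi)] +
    trend_g[cbind(gi, ti)] +
    rnorm(n_genes * n_patients * n_t, 0, params$sigma)

  out <- tibble::tibble(
    gene = gene_ids[gi],
    patient = patient_ids[pi],
    time = times[ti],
    value = value
  )
  attr(out, "subtrend") <- setNames(sub, gene_ids)
  attr(out, "kind") <- kind
  out
}

#' Define a simulation scenario
#'
#' A scenario mirrors one row-group of a type-I error / power study: `n_sets`
#' non-overlapping gene sets of `genes_per_set` genes measured on
#' `n_patients` patients at `times`, a proportion `prop_H1` of sets carrying
#' a real temporal signal, and of those a proportion `prop_het`
#' heterogeneous (several opposing sub-trends) with the rest homogeneous.
#'
#' @param prop_H1 proportion of sets under the alternative (e.g. 0, 0.27,
#'   0.85).
#' @param n_sets,genes_per_set,n_patients,times design dimensions; defaults
#'   are 100 sets x 50 genes, 20 patients, 8 equally spaced times.
#' @param prop_het proportion of H1 sets that are heterogeneous.
#' @param params generator parameters, see [sim_params()].
#' @param seed master RNG seed; every run and set derives a child seed from
#'   it, so identical seeds give bit-identical data.
#' @return A `tcgsa_scenario` list, including the per-set ground-truth
#'   `kinds` vector.
#' @export
simulation_scenario <- function(prop_H1 = 0, n_sets = 100, genes_per_set = 50,
                                n_patients = 20, times = 0:7,
                                prop_het = 0.25, params = sim_params(),
                                seed = 1234) {
  if (prop_H1 < 0 || prop_H1 > 1) stop_tcgsa("`prop_H1` must be in [0, 1]")
  n_H1 <- round(prop_H1 * n_sets)
  n_het <- round(prop_het * n_H1)
  n_hom <- n_H1 - n_het
  kinds <- c(rep("homogeneous", n_hom), rep("heterogeneous", n_het),
             rep("null", n_sets - n_H1))
  structure(
    list(prop_H1 = prop_H1, n_sets = n_sets, genes_per_set = genes_per_set,
         n_patients = n_patients, times = times, prop_het = prop_het,
         params = params, seed = seed, kinds = kinds,
         n_H1 = n_H1, n_het = n_het),
    class = "tcgsa_scenario"
  )
}

#' Generate one full simulation run
#'
#' @param scenario a [simulation_scenario()].
#' @param run_seed seed for this run (a child of the scenario seed inside
#'   [run_simulation_study()]).
#' @return A list with `data` (expression tibble of all sets), `sets` (the
#'   matching gene set collection) and `truth` (tibble `set_name`, `kind`).
#' @export
simulate_run <- function(scenario, run_seed) {
  set.seed(run_seed)
  set_seeds <- sample.int(2^31 - 2, scenario$n_sets)
  set_names <- sprintf("set%03d", seq_len(scenario$n_sets))
  frags <- vector("list", scenario$n_sets)
  genes <- vector("list", scenario$n_sets)
  for (s in seq_len(scenario$n_sets)) {
    set.seed(set_seeds[s])
    ids <- sprintf("%s_g%03d", set_names[s], seq_len(scenario$genes_per_set))
    frags[[s]] <- simulate_gene_set(
      scenario$kinds[s], n_genes = scenario$genes_per_set,
      n_patients = scenario$n_patients, times = scenario$times,
      params = scenario$params, gene_ids = ids
    )
    genes[[s]] <- ids
  }
  list(
    data = dplyr::bind_rows(frags),
    sets = gene_sets(set_name = set_names, genes = genes,
                     description = scenario$kinds),
    truth = tibble::tibble(set_name = set_names, kind = scenario$kinds)
  )
}

#' Run a type-I error / power study
#'
#' For each run: generate every set from a child seed, analyse the full
#' dataset with [run_tcgsa()] once per time-function basis, and tally
#' rejections against the generating truth. Rates are averaged over runs
#' with Monte-Carlo standard errors.
#'
#' @param scenario a [simulation_scenario()].
#' @param n_runs number of independent runs (>= 1).
#' @param bases character vector of basis kinds to fit (e.g.
#'   `c("linear", "cubic")`).
#' @param alpha significance level.
#' @param adjust multiple-testing method for the corrected rates.
#' @param control see [fit_control()].
#' @param verbose print per-run progress.
#' @return A `tcgsa_sim_study`: list with `per_run` (one row per run x
#'   basis: `typeI_raw`, `typeI_adj`, `power_raw`, `power_adj`, counts) and
#'   `summary` (means and standard errors per basis).
#' @export
run_simulation_study <- function(scenario, n_runs = 20,
                                 bases = c("linear", "cubic"),
                                 alpha = 0.05, adjust = "BY",
                                 control = fit_control(), verbose = FALSE) {
  stopifnot(inherits(scenario, "tcgsa_scenario"), n_runs >= 1)
  set.seed(scenario$seed)
  run_seeds <- sample.int(2^31 - 2, n_runs)
  rows <- list()
  for (run in seq_len(n_runs)) {
    sim <- simulate_run(scenario, run_seeds[run])
    is_null <- sim$truth$kind == "null"
    for (b in bases) {
      spec <- tcgsa_spec(basis = b)
      res <- run_tcgsa(sim$data, sim$sets, spec, alpha = alpha,
                       adjust = adjust, control = control)
      tab <- dplyr::left_join(sim$truth, res$table, by = "set_name")
      rej_raw <- !is.na(tab$p_raw) & tab$p_raw < alpha
      rej_adj <- !is.na(tab$p_adj) & tab$significant
      rows[[length(rows) + 1L]] <- tibble::tibble(
        run = run, basis = b,
        n_null = sum(is_null), n_H1 = sum(!is_null),
        n_failed = sum(is.na(tab$p_raw)),
        typeI_raw = if (any(is_null)) mean(rej_raw[is_null]) else NA_real_,
        typeI_adj = if (any(is_null)) mean(rej_adj[is_null]) else NA_real_,
        power_raw = if (any(!is_null)) mean(rej_raw[!is_null]) else NA_real_,
        power_adj = if (any(!is_null)) mean(rej_adj[!is_null]) else NA_real_
      )
      if (verbose) {
        r <- rows[[length(rows)]]
        message(sprintf(
          "run %d/%d [%s]: typeI=%.3f/%.3f power=%.3f/%.3f",
          run, n_runs, b, r$typeI_raw, r$typeI_adj, r$power_raw, r$power_adj
        ))
      }
    }
  }
  per_run <- dplyr::bind_rows(rows)
  summarise_rates <- function(df) {
    df |>
      dplyr::group_by(.data$basis) |>
      dplyr::summarise(dplyr::across(
        dplyr::all_of(c("typeI_raw", "typeI_adj", "power_raw", "power_adj")),
        list(mean = ~ mean(.x), se = ~ sd(.x) / sqrt(dplyr::n()))
      ), n_runs = dplyr::n(), .groups = "drop")
  }
  structure(
    list(per_run = per_run, summary = summarise_rates(per_run),
         scenario = scenario, n_runs = n_runs, bases = bases,
         alpha = alpha, adjust = adjust),
    class = "tcgsa_sim_study"
  )
}

#' @export
print.tcgsa_sim_study <- function(x, ...) {
  cat(sprintf("<tcgsa_sim_study> prop_H1=%g, %d sets x %d runs, alpha=%g (%s)\n",
              x$scenario$prop_H1, x$scenario$n_sets, x$n_runs, x$alpha,
              x$adjust))
  print(x$summary)
  invisible(x)
}
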