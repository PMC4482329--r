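#' Validate a long-form expression dataset
#'
#' Checks and normalises a data frame of longitudinal expression
#' measurements. One row is one measurement of one gene (or probe; IDs are
#' treated opaquely) in one patient at one time point, on a normalised log
#' scale. Grouped designs carry an extra `group` column.
#'
#' @param df a data frame with columns `gene`, `patient`, `time`, `value` and
#'   optionally `group`.
#' @return A tibble with class `tcgsa_expression`, columns coerced to
#'   (character, character, double, double[, character]).
#' @details Duplicated `(gene, patient, time)` measurements and non-finite
#'   values are rejected with the offending keys/rows named. Visits need not
#'   be balanced across patients: missing-at-random gaps are handled by the
#'   likelihood, not imputation.
#' @export
as_expression_dataset <- function(df) {
  required <- c("gene", "patient", "time", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_tcgsa(paste0("missing required column(s): ",
                      paste(missing_cols, collapse = ", ")),
               class = "tcgsa_validation_error")
  }
  out <- tibble::tibble(
    gene = as.character(df$gene),
    patient = as.character(df$patient),
    time = as.numeric(df$time),
    value = as.numeric(df$value)
  )
  if ("group" %in% names(df)) out$group <- as.character(df$group)

  if (any(is.na(out$gene) | out$gene == "")) {
    stop_tcgsa(sprintf("empty gene id at row(s): %s",
                       paste(head(which(is.na(out$gene) | out$gene == ""), 5),
                             collapse = ", ")),
               class = "tcgsa_validation_error")
  }
  bad <- which(!is.finite(out$value) | !is.finite(out$time))
  if (length(bad) > 0) {
    stop_tcgsa(sprintf("non-finite time/value at row(s): %s",
                       paste(head(bad, 5), collapse = ", ")),
               class = "tcgsa_validation_error")
  }
  key <- paste(out$gene, out$patient, out$time, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    offending <- unique(paste0("(", out$gene[dup], ", ", out$patient[dup],
                               ", ", out$time[dup], ")"))
    stop_tcgsa(paste0("duplicated (gene, patient, time) measurement(s): ",
                      paste(head(offending, 5), collapse = "; ")),
               class = "tcgsa_validation_error")
  }
  class(out) <- c("tcgsa_expression", class(out))
  out
}

#' Read longitudinal expression data from delimited text
#'
#' Long layout expects header columns `gene`, `patient`, `time`, `value` and
#' optionally `group`. Wide layout expects a genes-by-samples matrix whose
#' first column holds gene IDs, plus a sample annotation (data frame or file)
#' with columns `sample`, `patient`, `time` and optionally `group` mapping
#' each sample column to its design coordinates.
#'
#' @param path path to a TSV (default) or CSV file; `.csv` extensions are
#'   read comma-separated.
#' @param layout `"long"` or `"wide"`.
#' @param annotation for `layout = "wide"`, the sample annotation data frame
#'   or the path to one.
#' @return A validated [as_expression_dataset()] tibble.
#' @export
read_expression <- function(path, layout = c("long", "wide"),
                            annotation = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    stop_tcgsa(sprintf("file not found: %s", path),
               class = "tcgsa_validation_error")
  }
  df <- .read_delim_auto(path)
  if (layout == "long") {
    return(as_expression_dataset(df))
  }
  if (is.null(annotation)) {
    stop_tcgsa("wide layout requires a sample `annotation`",
               class = "tcgsa_validation_error")
  }
  annot <- if (is.character(annotation)) {
    .read_delim_auto(annotation)
  } else {
    tibble::as_tibble(annotation)
  }
  need <- c("sample", "patient", "time")
  if (!all(need %in% names(annot))) {
    stop_tcgsa("annotation must have columns sample, patient, time",
               class = "tcgsa_validation_error")
  }
  gene_col <- names(df)[1]
  sample_cols <- setdiff(names(df), gene_col)
  unknown <- setdiff(sample_cols, as.character(annot$sample))
  if (length(unknown) > 0) {
    stop_tcgsa(paste0("sample column(s) missing from annotation: ",
                      paste(head(unknown, 5), collapse = ", ")),
               class = "tcgsa_validation_error")
  }
  long <- tidyr::pivot_longer(df, cols = dplyr::all_of(sample_cols),
                              names_to = "sample", values_to = "value")
  long <- dplyr::left_join(long, annot, by = "sample")
  long$gene <- long[[gene_col]]
  as_expression_dataset(long)
}

.read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Read gene set definitions in GMT format
#'
#' One set per line: name, description, then member gene IDs, tab-separated.
#' CRLF line endings and trailing tabs are tolerated.
#'
#' @param path path to a `.gmt` file.
#' @return A tibble with class `tcgsa_genesets`: columns `set_name`,
#'   `description` and the list-column `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop_tcgsa(sprintf("file not found: %s", path),
               class = "tcgsa_validation_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- strsplit(lines, "\t", fixed = TRUE)
  parsed <- lapply(parsed, function(f) f[nzchar(f)])
  short <- vapply(parsed, length, 1L) < 3L
  if (any(short)) {
    stop_tcgsa(sprintf("GMT line(s) with fewer than 3 fields: %s",
                       paste(head(which(short), 5), collapse = ", ")),
               class = "tcgsa_validation_error")
  }
  nm <- vapply(parsed, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop_tcgsa(paste0("duplicated gene set name(s): ",
                      paste(unique(nm[duplicated(nm)]), collapse = ", ")),
               class = "tcgsa_validation_error")
  }
  gene_sets(
    set_name = nm,
    description = vapply(parsed, `[[`, "", 2L),
    genes = lapply(parsed, function(f) unique(f[-(1:2)]))
  )
}

#' Build a gene set collection
#'
#' @param set_name character vector of unique set names.
#' @param description character vector (recycled if length 1).
#' @param genes list of character vectors of member gene IDs.
#' @return A `tcgsa_genesets` tibble.
#' @export
gene_sets <- function(set_name, genes, description = "") {
  if (anyDuplicated(set_name)) {
    stop_tcgsa("gene set names must be unique",
               class = "tcgsa_validation_error")
  }
  if (any(vapply(genes, length, 1L) == 0L)) {
    stop_tcgsa("gene lists must be non-empty",
               class = "tcgsa_validation_error")
  }
  out <- tibble::tibble(
    set_name = as.character(set_name),
    description = rep_len(as.character(description), length(set_name)),
    genes = as.list(genes)
  )
  class(out) <- c("tcgsa_genesets", class(out))
  out
}

#' Flag gene sets retained after size filtering
#'
#' A set is retained when the number of its member genes *observed in the
#' dataset* lies within `[min_size, max_size]`; sets outside the band are
#' discarded from testing (and from the multiple-testing universe).
#'
#' @param sets a `tcgsa_genesets` tibble.
#' @param data an expression dataset (only its gene universe is used).
#' @param min_size,max_size inclusive bounds on observed set size.
#' @return `sets` with integer column `n_genes_observed` and logical column
#'   `retained` added.
#' @export
filter_gene_sets <- function(sets, data, min_size = 10, max_size = 500) {
  universe <- unique(data$gene)
  n_obs <- vapply(sets$genes, function(g) sum(g %in% universe), 1L)
  sets$n_genes_observed <- n_obs
  sets$retained <- n_obs >= min_size & n_obs <= max_size
  sets
}
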