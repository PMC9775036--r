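#' Construct a survival dataset
#'
#' Bundles an expression matrix with right-censored outcomes. Rows are
#' samples, columns are genes. Samples whose outcome is unknown (the
#' unlabeled pool used by [fit_dfsc()]) carry `NA` time/event and
#' `labeled_mask = FALSE`.
#'
#' @param X Numeric matrix, `n` samples x `p` genes. Row/column names are
#'   used as sample and gene identifiers when `sample_ids`/`gene_ids` are
#'   not given.
#' @param time Non-negative follow-up times (time to event or censoring);
#'   `NA` for unlabeled samples.
#' @param event Event indicator in `{0, 1}` (1 = event observed,
#'   0 = right-censored); `NA` for unlabeled samples.
#' @param sample_ids,gene_ids Unique character identifiers.
#'
#' @return An object of class `survival_dataset`: a list with elements
#'   `X`, `time`, `event`, `sample_ids`, `gene_ids`, `labeled_mask`.
#' @examples
#' X <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("s", 1:4), paste0("g", 1:5)))
#' ds <- survival_dataset(X, time = c(5, 2, NA, 7), event = c(1, 0, NA, 1))
#' ds$labeled_mask
#' @export
survival_dataset <- function(X, time, event, sample_ids = NULL, gene_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  sample_ids <- as.character(sample_ids %||% rownames(X) %||% paste0("sample_", seq_len(n)))
  gene_ids <- as.character(gene_ids %||% colnames(X) %||% paste0("gene_", seq_len(p)))
  if (length(sample_ids) != n) stop_dfsc("length(sample_ids) must equal nrow(X)")
  if (length(gene_ids) != p) stop_dfsc("length(gene_ids) must equal ncol(X)")
  if (anyDuplicated(sample_ids)) stop_dfsc("sample_ids must be unique")
  if (anyDuplicated(gene_ids)) stop_dfsc("gene_ids must be unique")
  if (anyNA(X)) stop_dfsc("X contains missing values; impute or filter before constructing the dataset")
  time <- as.double(time); event <- as.double(event)
  if (length(time) != n || length(event) != n)
    stop_dfsc("time and event must have one entry per sample")
  labeled <- !is.na(time) & !is.na(event)
  if (any(time[labeled] < 0)) stop_dfsc("time must be non-negative for labeled samples")
  if (!all(event[labeled] %in% c(0, 1))) stop_dfsc("event must be 0 or 1 for labeled samples")
  rownames(X) <- sample_ids; colnames(X) <- gene_ids
  structure(
    list(X = X, time = time, event = event, sample_ids = sample_ids,
         gene_ids = gene_ids, labeled_mask = labeled),
    class = "survival_dataset"
  )
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf(
    "survival_dataset: %d samples x %d genes (%d labeled, %d events, %d unlabeled)\n",
    length(x$sample_ids), length(x$gene_ids), sum(x$labeled_mask),
    sum(x$event[x$labeled_mask] == 1), sum(!x$labeled_mask)))
  invisible(x)
}

#' Number of samples / genes in a survival dataset
#' @param dataset A `survival_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(dataset) length(dataset$sample_ids)

#' @rdname n_samples
#' @export
n_genes <- function(dataset) length(dataset$gene_ids)

#' Subset a survival dataset by sample
#'
#' @param dataset A `survival_dataset`.
#' @param idx Integer or logical sample index, or character sample ids.
#' @return A `survival_dataset` with the selected rows.
#' @export
subset_samples <- function(dataset, idx) {
  if (is.character(idx)) idx <- match(idx, dataset$sample_ids)
  if (anyNA(idx)) stop_dfsc("unknown sample ids in subset")
  survival_dataset(dataset$X[idx, , drop = FALSE],
                   time = dataset$time[idx], event = dataset$event[idx],
                   sample_ids = dataset$sample_ids[idx], gene_ids = dataset$gene_ids)
}

#' Keep only labeled samples
#' @param dataset A `survival_dataset`.
#' @return A `survival_dataset` containing the labeled rows.
#' @export
labeled_subset <- function(dataset) subset_samples(dataset, which(dataset$labeled_mask))

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Load expression and clinical tables into a survival dataset
#'
#' The expression file is TSV/CSV with a `sample_id` first column and one
#' column per gene (samples as rows); set `transpose = TRUE` for the
#' genes-as-rows dialect common in TCGA exports. The clinical file needs
#' columns `sample_id`, `time`, `event`; rows with empty time/event are
#' kept as unlabeled samples.
#'
#' @param expr_file,clinical_file Paths to the two tables.
#' @param transpose Expression file has genes as rows.
#' @param impute Impute missing expression values with the per-gene median
#'   (default `FALSE`: missing values are an error).
#' @return A [survival_dataset()].
#' @export
read_survival_data <- function(expr_file, clinical_file, transpose = FALSE,
                               impute = FALSE) {
  expr <- read_table_auto(expr_file)
  if (transpose) {
    gene_ids <- as.character(expr[[1]])
    X <- t(as.matrix(expr[, -1, drop = FALSE]))
    colnames(X) <- gene_ids
  } else {
    X <- as.matrix(expr[, -1, drop = FALSE])
    rownames(X) <- as.character(expr[[1]])
  }
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    if (!impute)
      stop_dfsc("expression matrix has missing values; pass impute = TRUE for per-gene median imputation")
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- stats::median(X[!nas, j])
    }
  }
  clin <- read_table_auto(clinical_file)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(clin)))
    stop_dfsc("clinical file must have columns sample_id, time, event")
  m <- match(rownames(X), as.character(clin$sample_id))
  if (anyNA(m)) stop_dfsc("samples missing from clinical file: ",
                          paste(utils::head(rownames(X)[is.na(m)]), collapse = ", "))
  survival_dataset(X, time = as.numeric(clin$time)[m],
                   event = as.numeric(clin$event)[m])
}
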