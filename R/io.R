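#' Read a gene-level count matrix
#'
#' Reads a delimited text file whose first column holds gene identifiers and
#' whose header row holds sample identifiers, as distributed in GEO
#' supplementary count tables.
#'
#' @param path Path to a TSV or CSV file.
#' @param delim Field delimiter. `NULL` (default) guesses from the file
#'   extension: `.csv` is comma-separated, anything else tab-separated.
#' @return A tibble with a character `gene_id` column followed by one numeric
#'   column per sample, in file order.
#' @export
read_counts <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "scatterde_error_io")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(raw) == 0L) {
    abort("no data rows in count file", class = "scatterde_error_io")
  }
  names(raw)[1] <- "gene_id"
  counts <- validate_counts(raw, source = path)
  counts
}

# Shared validation for count tables, whether read from disk or passed in
# memory. Enforces unique ids, numeric non-negative counts, >= 2 samples.
validate_counts <- function(tbl, source = "counts") {
  gene_id <- as.character(tbl[[1]])
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    abort(
      paste0("duplicate gene id in ", source, ": ",
             paste(head(dup, 5), collapse = ", ")),
      class = "scatterde_error_invalid"
    )
  }
  sample_ids <- names(tbl)[-1]
  if (length(sample_ids) < 2L) {
    abort("count matrix needs at least 2 samples",
          class = "scatterde_error_invalid")
  }
  if (anyDuplicated(sample_ids)) {
    abort("duplicate sample id in header", class = "scatterde_error_invalid")
  }
  out <- tibble(gene_id = gene_id)
  for (s in sample_ids) {
    col <- tbl[[s]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad) > 0L) {
      abort(
        paste0("non-numeric count at row ", bad[1], " (gene ",
               gene_id[bad[1]], "), column ", s),
        class = "scatterde_error_invalid"
      )
    }
    if (anyNA(num)) {
      abort(paste0("missing count value in column ", s),
            class = "scatterde_error_invalid")
    }
    if (any(num < 0)) {
      abort(paste0("negative count in column ", s),
            class = "scatterde_error_invalid")
    }
    out[[s]] <- num
  }
  out
}

#' Read a gene-length table
#'
#' @param path Two-column delimited file: gene id, length in base pairs.
#' @param delim Field delimiter, guessed from the extension when `NULL`.
#' @return A tibble with columns `gene_id`, `length_bp`.
#' @export
read_gene_lengths <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  tbl <- readr::read_delim(path, delim = delim, col_types = "cd",
                           progress = FALSE)
  names(tbl)[1:2] <- c("gene_id", "length_bp")
  if (any(!is.finite(tbl$length_bp)) || any(tbl$length_bp <= 0)) {
    abort("gene lengths must be positive", class = "scatterde_error_invalid")
  }
  if (anyDuplicated(tbl$gene_id)) {
    abort("duplicate gene id in length table",
          class = "scatterde_error_invalid")
  }
  tbl
}

#' Read a sample-design table
#'
#' @param path Delimited file with columns `sample_id`, `condition`,
#'   `replicate`.
#' @param delim Field delimiter, guessed from the extension when `NULL`.
#' @return A tibble with character columns `sample_id`, `condition`,
#'   `replicate`.
#' @export
read_design <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  tbl <- readr::read_delim(path, delim = delim, col_types = "ccc",
                           progress = FALSE)
  names(tbl)[1:3] <- c("sample_id", "condition", "replicate")
  validate_design(tbl)
}

validate_design <- function(design) {
  design <- as_tibble(design)
  design$sample_id <- as.character(design$sample_id)
  design$condition <- as.character(design$condition)
  design$replicate <- as.character(design$replicate)
  if (anyDuplicated(design$sample_id)) {
    abort("duplicate sample id in design", class = "scatterde_error_invalid")
  }
  key <- paste(design$condition, design$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate (condition, replicate) pair in design",
          class = "scatterde_error_invalid")
  }
  design
}

# ---- expression-table helpers -----------------------------------------------

sample_cols <- function(x) setdiff(names(x), "gene_id")

expr_scale <- function(x) {
  sc <- attr(x, "expr_scale")
  if (is.null(sc)) "linear" else sc
}

set_expr_scale <- function(x, scale) {
  attr(x, "expr_scale") <- scale
  x
}

expr_matrix <- function(x) {
  m <- as.matrix(x[sample_cols(x)])
  rownames(m) <- x$gene_id
  m
}

samples_of <- function(design, condition) {
  design$sample_id[design$condition == condition]
}

#' TPM-normalize a count matrix
#'
#' Converts raw read counts to Transcripts Per Million: per sample, each
#' gene's count is divided by its length in kilobases to give a read rate,
#' and rates are rescaled to sum to one million.
#'
#' @param counts Tibble from [read_counts()]: `gene_id` plus sample columns.
#' @param gene_lengths Tibble with columns `gene_id`, `length_bp` covering
#'   every gene in `counts`.
#' @return A tibble of the same shape holding TPM values (linear scale);
#'   every sample column sums to 1e6.
#' @export
tpm_normalize <- function(counts, gene_lengths) {
  counts <- validate_counts(counts)
  len <- gene_lengths$length_bp[match(counts$gene_id, gene_lengths$gene_id)]
  if (anyNA(len)) {
    missing <- counts$gene_id[is.na(len)]
    abort(
      paste0("no gene length for: ", paste(head(missing, 5), collapse = ", "),
             if (length(missing) > 5) sprintf(" (and %d more)",
                                              length(missing) - 5) else ""),
      class = "scatterde_error_invalid"
    )
  }
  m <- expr_matrix(counts)
  rate <- m / (len / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) {
    abort(paste0("all-zero sample column (TPM undefined): ",
                 paste(colnames(m)[tot == 0], collapse = ", ")),
          class = "scatterde_error_invalid")
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  out <- tibble(gene_id = counts$gene_id)
  for (s in colnames(tpm)) out[[s]] <- unname(tpm[, s])
  set_expr_scale(out, "linear")
}

#' Log10-transform a TPM table
#'
#' @param tpm Linear-scale expression tibble from [tpm_normalize()].
#' @param floor Positive TPM value clamped from below before taking logs, so
#'   zeros stay finite. Default `1e-3`.
#' @return Expression tibble on the log10 scale.
#' @export
log10_transform <- function(tpm, floor = 1e-3) {
  if (expr_scale(tpm) != "linear") {
    abort("input is already on the log10 scale",
          class = "scatterde_error_invalid")
  }
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0) {
    abort("floor must be a positive number", class = "scatterde_error_invalid")
  }
  out <- tpm
  for (s in sample_cols(tpm)) out[[s]] <- log10(pmax(tpm[[s]], floor))
  set_expr_scale(out, "log10")
}

#' Select the best-correlated replicate pair of a condition
#'
#' Among all replicate samples of one condition, returns the pair whose
#' log10 expression profiles have the highest Pearson correlation across all
#' genes. With exactly two replicates that pair is returned unconditionally.
#' Correlation ties are broken toward the lexicographically smallest sorted
#' pair of sample ids.
#'
#' @param tpm Linear-scale expression tibble.
#' @param design Design tibble (`sample_id`, `condition`, `replicate`).
#' @param condition Condition label to look up.
#' @param floor Pseudo-TPM added before the log10 used for correlation.
#' @return Character vector of two sample ids, sorted.
#' @export
select_replicate_pair <- function(tpm, design, condition, floor = 1e-3) {
  ids <- sort(samples_of(design, condition))
  if (length(ids) < 2L) {
    abort(paste0("condition '", condition, "' has fewer than 2 replicates"),
          class = "scatterde_error_invalid")
  }
  if (length(ids) == 2L) return(ids)
  lg <- log10(as.matrix(tpm[ids]) + floor)
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  r <- vapply(pairs, function(p) cor(lg[, p[1]], lg[, p[2]]), numeric(1))
  # ids are pre-sorted, so combn order is already the lexicographic tie order
  # and which.max's first-winner rule implements the tie-break
  pairs[[which.max(r)]]
}
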