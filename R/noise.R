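#' Per-gene expression noise between two samples
#'
#' Expression noise of gene i between samples j and k is the squared
#' coefficient of variation of the two values,
#' `eta2_i = 2 * (x_ij - x_ik)^2 / (x_ij + x_ik)^2`, i.e. the two-sample
#' variance `(x_ij - x_ik)^2 / 2` divided by the squared mean
#' `(x_ij + x_ik)^2 / 4`. It is symmetric in the two samples and bounded in
#' `[0, 2]`, with 2 attained when one value is zero.
#'
#' @param x_j,x_k Equal-length non-negative expression vectors (linear TPM).
#' @return Numeric vector of per-gene noise values.
#' @export
gene_pair_noise <- function(x_j, x_k) {
  if (length(x_j) != length(x_k)) {
    abort("expression vectors differ in length",
          class = "scatterde_error_invalid")
  }
  tot <- x_j + x_k
  if (any(tot == 0)) {
    abort("noise undefined for genes with zero expression in both samples",
          class = "scatterde_error_invalid")
  }
  2 * (x_j - x_k)^2 / tot^2
}

#' Aggregate transcriptome-wide noise
#'
#' @param per_gene Numeric vector of per-gene noise values.
#' @param mode `"mean"` (default) averages over genes; `"sum"` totals them.
#' @return A single non-negative number.
#' @export
transcriptome_noise <- function(per_gene, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (length(per_gene) == 0L) {
    abort("empty noise vector", class = "scatterde_error_invalid")
  }
  if (mode == "mean") mean(per_gene) else sum(per_gene)
}

#' Pairwise noise table for two samples of an expression tibble
#'
#' @param tpm Linear-scale expression tibble.
#' @param sample_j,sample_k Sample column names.
#' @return Tibble with columns `gene_id`, `pair`, `eta2`.
#' @export
pair_noise <- function(tpm, sample_j, sample_k) {
  tibble(
    gene_id = tpm$gene_id,
    pair = paste(sample_j, sample_k, sep = "/"),
    eta2 = gene_pair_noise(tpm[[sample_j]], tpm[[sample_k]])
  )
}

#' Replicate-noise baseline for a two-condition comparison
#'
#' The baseline is the average, over the two compared conditions, of the
#' mean transcriptome noise between each condition's selected replicate
#' pair. It estimates the scatter one expects between any two samples from
#' technical and culture variability alone, and is the reference level
#' against which the overlay dot size is calibrated.
#'
#' @param tpm Linear-scale expression tibble (filtered).
#' @param design Design tibble.
#' @param conditions Character vector of the two compared condition labels.
#' @param pairs Optional named list `condition -> c(sample, sample)` of
#'   replicate pairs; selected by [select_replicate_pair()] when `NULL`.
#' @param mode Aggregation mode per condition, see [transcriptome_noise()].
#' @return A single non-negative number.
#' @export
replicate_noise_baseline <- function(tpm, design, conditions, pairs = NULL,
                                     mode = "mean") {
  if (length(conditions) != 2L) {
    abort("exactly two conditions required", class = "scatterde_error_invalid")
  }
  per_cond <- vapply(conditions, function(cond) {
    p <- if (!is.null(pairs) && !is.null(pairs[[cond]])) pairs[[cond]]
         else select_replicate_pair(tpm, design, cond)
    x <- tpm[[p[1]]]
    y <- tpm[[p[2]]]
    # genes unobserved in both replicates carry no noise information
    keep <- x + y > 0
    transcriptome_noise(gene_pair_noise(x[keep], y[keep]), mode)
  }, numeric(1))
  mean(per_cond)
}
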