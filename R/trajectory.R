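#' Pearson-correlation response trajectory
#'
#' For each condition (time point), the Pearson correlation of log10
#' expression between the anchor condition and that condition over a gene
#' subset, averaged over all replicate pairings of the two conditions.
#' A transcriptome that responds to the perturbation decorrelates from the
#' anchor over time; a subset untouched by the response stays near 1.
#'
#' @param lg Log10-scale expression tibble.
#' @param design Design tibble; conditions are time labels.
#' @param anchor Anchor condition label (reference time).
#' @param subset Optional character vector of gene ids (default all).
#' @param times Optional condition ordering (default: order of first
#'   appearance in the design).
#' @return Tibble with columns `time`, `r`.
#' @export
correlation_trajectory <- function(lg, design, anchor, subset = NULL,
                                   times = NULL) {
  if (is.null(times)) times <- unique(design$condition)
  if (!anchor %in% times) {
    abort("anchor condition not present in the design",
          class = "scatterde_error_invalid")
  }
  x <- expr_matrix(lg)
  if (!is.null(subset)) {
    if (length(subset) == 0L) {
      abort("empty gene subset", class = "scatterde_error_invalid")
    }
    x <- x[rownames(x) %in% subset, , drop = FALSE]
  }
  anchor_s <- samples_of(design, anchor)
  rows <- purrr::map(times, function(t) {
    target_s <- samples_of(design, t)
    rs <- c(outer(anchor_s, target_s, Vectorize(function(a, b) {
      if (sd(x[, a]) == 0 || sd(x[, b]) == 0) {
        abort("constant expression vector; correlation undefined",
              class = "scatterde_error_invalid")
      }
      cor(x[, a], x[, b])
    })))
    tibble(time = t, r = mean(rs))
  })
  bind_rows(rows)
}

#' Principal-component response trajectory
#'
#' Principal components are computed on the samples-by-genes matrix of
#' log10 expression (samples as observations, genes mean-centered, no
#' unit-variance scaling). The trajectory is the per-time average of the
#' replicate scores on PC1 and PC2; the PC1 sign is fixed so the anchor
#' (first time) sits at a non-positive score.
#'
#' @inheritParams correlation_trajectory
#' @return A `scatterde_traj` object: `$trajectory` (tibble `time`, `PC1`,
#'   `PC2`), `$scores` (per-sample scores), `$explained` (variance
#'   fractions of all components, summing to 1).
#' @export
pc_trajectory <- function(lg, design, subset = NULL, times = NULL) {
  if (is.null(times)) times <- unique(design$condition)
  if (length(times) < 2L) {
    abort("need at least 2 time points", class = "scatterde_error_invalid")
  }
  x <- expr_matrix(lg)
  if (!is.null(subset)) {
    x <- x[rownames(x) %in% subset, , drop = FALSE]
  }
  if (nrow(x) < 2L) {
    abort("need at least 2 genes in the subset",
          class = "scatterde_error_invalid")
  }
  keep <- design$sample_id[design$condition %in% times]
  obs <- t(x[, keep, drop = FALSE])  # samples x genes
  pc <- prcomp(obs, center = TRUE, scale. = FALSE)
  scores <- pc$x
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  anchor_samples <- samples_of(design, times[1])
  if (mean(scores[anchor_samples, 1]) > 0) scores[, 1] <- -scores[, 1]
  score_tbl <- tibble(
    sample_id = rownames(scores),
    condition = design$condition[match(rownames(scores), design$sample_id)],
    PC1 = unname(scores[, 1]),
    PC2 = if (ncol(scores) >= 2) unname(scores[, 2]) else 0
  )
  traj <- score_tbl |>
    group_by(.data$condition) |>
    summarise(PC1 = mean(.data$PC1), PC2 = mean(.data$PC2)) |>
    ungroup()
  traj <- traj[match(times, traj$condition), ]
  names(traj)[1] <- "time"
  structure(
    list(trajectory = traj, scores = score_tbl, explained = explained),
    class = "scatterde_traj"
  )
}

#' @export
print.scatterde_traj <- function(x, ...) {
  cat("<scatterde_traj> ", nrow(x$trajectory), " time points; PC1 ",
      sprintf("%.1f%%", 100 * x$explained[1]), ", PC2 ",
      sprintf("%.1f%%", 100 * ifelse(length(x$explained) > 1,
                                     x$explained[2], 0)), " variance\n",
      sep = "")
  invisible(x)
}

#' @exportS3Method
tidy.scatterde_traj <- function(x, ...) x$trajectory

#' @exportS3Method
glance.scatterde_traj <- function(x, ...) {
  tibble(pc1_var = x$explained[1],
         pc2_var = if (length(x$explained) > 1) x$explained[2] else 0,
         n_times = nrow(x$trajectory))
}
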