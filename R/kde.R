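#' Bandwidths for a 2D diagonal-kernel density estimate
#'
#' @param points 2D points (tibble with `u`, `v` or a 2-column matrix),
#'   at least 10 of them.
#' @param method `"silverman"` (default): per dimension
#'   `h_d = sd_d * n^(-1/6)`, the normal-reference rate for a bivariate
#'   kernel; `"plugin"`: univariate Sheather-Jones per dimension.
#' @return Named numeric vector `c(h1, h2)` in log10-TPM units.
#' @export
estimate_bandwidth <- function(points, method = c("silverman", "plugin")) {
  method <- match.arg(method)
  p <- as_xy(points)
  n <- nrow(p)
  if (n < 10L) {
    abort("need at least 10 points to estimate a bandwidth",
          class = "scatterde_error_invalid")
  }
  s <- c(sd(p[, 1]), sd(p[, 2]))
  if (any(s == 0)) {
    abort("zero variance in one dimension; bandwidth undefined",
          class = "scatterde_error_invalid")
  }
  h <- switch(method,
    silverman = s * n^(-1 / 6),
    plugin = c(bw.SJ(p[, 1]), bw.SJ(p[, 2]))
  )
  setNames(h, c("h1", "h2"))
}

#' Build the between-replicate kernel density model
#'
#' The replicate cloud pools both conditions: with `X_k` the concatenation
#' of condition-1 and condition-2 log10-TPM values at replicate k, the
#' cloud is the 2m points `(X_1[j], X_2[j])` — equivalently the union of
#' the two within-condition replicate clouds. The density is a mixture of
#' 2D Gaussian kernels with diagonal bandwidth matrix `diag(h1^2, h2^2)`
#' centered at those points.
#'
#' @param lg Log10-scale expression tibble.
#' @param design Design tibble.
#' @param cond1,cond2 Condition labels.
#' @param pairs Optional named list of replicate pairs per condition.
#' @param bandwidth Bandwidth method, see [estimate_bandwidth()].
#' @return A `scatterde_kde` object: `$points` (2m x 2 matrix), `$h`
#'   (bandwidths), `$bandwidth` (method name).
#' @export
build_kde_model <- function(lg, design, cond1, cond2, pairs = NULL,
                            bandwidth = c("silverman", "plugin")) {
  bandwidth <- match.arg(bandwidth)
  rc1 <- build_replicate_cloud(lg, design, cond1,
                               if (!is.null(pairs)) pairs[[cond1]])
  rc2 <- build_replicate_cloud(lg, design, cond2,
                               if (!is.null(pairs)) pairs[[cond2]])
  pts <- as_xy(bind_rows(rc1, rc2))
  h <- estimate_bandwidth(pts, bandwidth)
  structure(list(points = pts, h = h, bandwidth = bandwidth),
            class = "scatterde_kde")
}

#' @export
print.scatterde_kde <- function(x, ...) {
  cat("<scatterde_kde> ", nrow(x$points), " kernels, ", x$bandwidth,
      " bandwidth h = (", signif(x$h[1], 4), ", ", signif(x$h[2], 4), ")\n",
      sep = "")
  invisible(x)
}

#' Lower-orthant CDF of the kernel density model
#'
#' `F(p) = (1/2m) * sum_j Phi((p1 - X1[j])/h1) * Phi((p2 - X2[j])/h2)`:
#' the mixture probability mass below-left of the query point.
#'
#' @param p Query points: numeric length-2 vector, 2-column matrix, or
#'   tibble with `u`, `v`.
#' @param model A `scatterde_kde` object.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
kde_cdf <- function(p, model) {
  q <- if (is.numeric(p) && is.null(dim(p)) && length(p) == 2L) {
    matrix(p, ncol = 2)
  } else {
    as_xy(p)
  }
  h <- model$h
  X <- model$points
  vapply(seq_len(nrow(q)), function(i) {
    mean(pnorm((q[i, 1] - X[, 1]) / h[1]) * pnorm((q[i, 2] - X[, 2]) / h[2]))
  }, numeric(1))
}

# mixture density of the model at query points (rows of matrix q)
kde_density <- function(q, model) {
  h <- model$h
  X <- model$points
  vapply(seq_len(nrow(q)), function(i) {
    mean(dnorm(q[i, 1], X[, 1], h[1]) * dnorm(q[i, 2], X[, 2], h[2]))
  }, numeric(1))
}

#' Initialize a DE report from an overlay result
#'
#' @param overlay A `scatterde_overlay` object.
#' @param tpm Linear-scale expression tibble (for fold changes).
#' @param design Design tibble.
#' @param cond1,cond2 Condition labels; the log2 fold change is
#'   `log2(mean TPM in cond2 / mean TPM in cond1)`, means taken across the
#'   condition's replicates.
#' @return A `scatterde_report` tibble: `gene_id`, `de_overlay`,
#'   `log2_fc`, `p` (`NA` until [de_pvalues()]), `de_final` (overlay call
#'   until [apply_cutoffs()]).
#' @export
de_report <- function(overlay, tpm, design, cond1, cond2) {
  m <- expr_matrix(tpm)
  mean1 <- rowMeans(m[, samples_of(design, cond1), drop = FALSE])
  mean2 <- rowMeans(m[, samples_of(design, cond2), drop = FALSE])
  fc <- log2(mean2 / mean1)
  out <- tibble(
    gene_id = overlay$per_gene$gene_id,
    de_overlay = overlay$per_gene$de,
    log2_fc = fc[match(overlay$per_gene$gene_id, tpm$gene_id)],
    p = NA_real_,
    de_final = overlay$per_gene$de
  )
  attr(out, "dot_size") <- overlay$dot_size
  attr(out, "conditions") <- c(cond1, cond2)
  if (!is.null(overlay$scan)) attr(out, "pairs") <- overlay$scan$pairs
  class(out) <- c("scatterde_report", class(out))
  out
}

#' Kernel-density p-values for a DE report
#'
#' Evaluates, per gene, the probability that its between-condition point
#' belongs to the between-replicate scatter cloud. The default `"cdf"` mode
#' is the literal lower-orthant integral `F(x_i1, x_i2)` of the replicate
#' KDE; `"two_sided"` is `2 * min(F, 1 - F)`; `"hdr"` is the
#' highest-density-region probability `P(f(X) <= f(x_i))` for `X` drawn
#' from the KDE (near 1 deep inside the cloud, near 0 far outside),
#' estimated by Monte Carlo.
#'
#' @param report A `scatterde_report` tibble.
#' @param model A `scatterde_kde` object.
#' @param lg Log10-scale expression tibble.
#' @param mode `"cdf"` (default), `"two_sided"`, or `"hdr"`.
#' @param combos `"r1"` (default) evaluates the replicate-1 combination
#'   (cond1-rep1, cond2-rep1); `"max"` evaluates all four combinations and
#'   keeps the largest (most conservative) probability.
#' @param pairs Named list `condition -> c(sample, sample)`; taken from the
#'   report (as built by [de_report()] on an [overlay_de()] result) when
#'   `NULL`.
#' @param n_mc Monte-Carlo sample size for `"hdr"`.
#' @param seed Optional integer making the `"hdr"` Monte Carlo
#'   reproducible without touching the caller's RNG stream.
#' @return The report with its `p` column filled; mode recorded in
#'   attribute `"p_mode"`.
#' @export
de_pvalues <- function(report, model, lg, mode = c("cdf", "two_sided", "hdr"),
                       combos = c("r1", "max"), pairs = NULL,
                       n_mc = 20000L, seed = NULL) {
  mode <- match.arg(mode)
  combos <- match.arg(combos)
  if (is.null(pairs)) pairs <- attr(report, "pairs")
  conds <- attr(report, "conditions")
  if (is.null(pairs) || is.null(conds)) {
    abort("replicate pairs unknown; pass `pairs` or build the report from an overlay_de() result",
          class = "scatterde_error_invalid")
  }
  idx <- match(report$gene_id, lg$gene_id)
  point_sets <- if (combos == "r1") {
    list(cbind(lg[[pairs[[conds[1]]][1]]][idx], lg[[pairs[[conds[2]]][1]]][idx]))
  } else {
    unlist(lapply(1:2, function(a) lapply(1:2, function(b) {
      cbind(lg[[pairs[[conds[1]]][a]]][idx], lg[[pairs[[conds[2]]][b]]][idx])
    })), recursive = FALSE)
  }
  eval_p <- switch(mode,
    cdf = function(q) kde_cdf(q, model),
    two_sided = function(q) {
      f <- kde_cdf(q, model)
      2 * pmin(f, 1 - f)
    },
    hdr = function(q) hdr_pvalue(q, model, n_mc, seed)
  )
  pv <- do.call(pmax, lapply(point_sets, eval_p))
  report$p <- pv
  attr(report, "p_mode") <- mode
  attr(report, "bandwidth") <- model$h
  report
}

# HDR probability by Monte Carlo: p(q) = P(f(X) <= f(q)) for X drawn from
# the kernel mixture — one minus the coverage of the smallest
# highest-density region containing q. Near 1 deep inside the cloud, near
# 0 far outside. One shared sample is used for all query points.
hdr_pvalue <- function(q, model, n_mc, seed = NULL) {
  run <- function() {
    j <- sample.int(nrow(model$points), n_mc, replace = TRUE)
    xs <- cbind(rnorm(n_mc, model$points[j, 1], model$h[1]),
                rnorm(n_mc, model$points[j, 2], model$h[2]))
    f_mc <- kde_density(xs, model)
    f_q <- kde_density(q, model)
    vapply(f_q, function(fq) mean(f_mc <= fq), numeric(1))
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# generator state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Apply p-value and fold-change cutoffs to a DE report
#'
#' `de_final` keeps a gene when it is an overlay DE call, its p-value is
#' below `p_cutoff` (if set), and its absolute log2 fold change is at
#' least `log2(fold_cutoff)` (if set). Cutoffs only ever remove genes.
#'
#' @param report A `scatterde_report` with p-values when `p_cutoff` is set.
#' @param p_cutoff Probability cutoff in `[0, 1]`, or `NULL` to skip.
#' @param fold_cutoff Fold-change cutoff (ratio scale, >= 1), or `NULL`.
#' @return The report with `de_final` updated; cutoffs recorded in
#'   attributes.
#' @export
apply_cutoffs <- function(report, p_cutoff = NULL, fold_cutoff = NULL) {
  keep <- report$de_overlay
  if (!is.null(p_cutoff)) {
    if (!is.numeric(p_cutoff) || p_cutoff < 0 || p_cutoff > 1) {
      abort("p_cutoff must lie in [0, 1]", class = "scatterde_error_invalid")
    }
    if (anyNA(report$p)) {
      abort("p-values missing; run de_pvalues() first",
            class = "scatterde_error_invalid")
    }
    keep <- keep & report$p < p_cutoff
  }
  if (!is.null(fold_cutoff)) {
    if (!is.numeric(fold_cutoff) || fold_cutoff < 1) {
      abort("fold_cutoff must be a ratio >= 1",
            class = "scatterde_error_invalid")
    }
    keep <- keep & abs(report$log2_fc) >= log2(fold_cutoff)
  }
  report$de_final <- keep
  attr(report, "p_cutoff") <- p_cutoff
  attr(report, "fold_cutoff") <- fold_cutoff
  report
}
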