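# shared fixture builders; everything is generated in code

toy_path <- function(file) {
  system.file("extdata", file, package = "scatterde", mustWork = TRUE)
}

# small expression tibble straight from a matrix (linear TPM scale)
expr_tbl <- function(m, gene_id = sprintf("g%03d", seq_len(nrow(m))),
                     scale = "linear") {
  out <- tibble::tibble(gene_id = gene_id)
  for (j in seq_len(ncol(m))) {
    out[[colnames(m)[j] %||% paste0("s", j)]] <- m[, j]
  }
  attr(out, "expr_scale") <- scale
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

two_cond_design <- function() {
  tibble::tibble(
    sample_id = c("c1_r1", "c1_r2", "c2_r1", "c2_r2"),
    condition = rep(c("c1", "c2"), each = 2),
    replicate = rep(c("r1", "r2"), 2)
  )
}

# random overlay instance: a diagonal-ish cloud plus query points
random_instance <- function(n_genes, seed) {
  set.seed(seed)
  base <- runif(n_genes, 0, 3)
  cloud <- cbind(base + rnorm(n_genes, 0, 0.03),
                 base + rnorm(n_genes, 0, 0.03))
  queries <- cbind(base + rnorm(n_genes, 0, 0.05),
                   base + rnorm(n_genes, 0, 0.05))
  list(cloud = cloud, queries = queries)
}

# plain-loop nearest-distance oracle, deliberately independent of the
# package's vectorized/bucketed implementations
oracle_min_dist <- function(p, q, metric = "euclidean") {
  vapply(seq_len(nrow(p)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(q))) {
      dx <- abs(p[i, 1] - q[j, 1])
      dy <- abs(p[i, 2] - q[j, 2])
      d <- if (metric == "euclidean") sqrt(dx^2 + dy^2) else max(dx, dy)
      if (d < best) best <- d
    }
    best
  }, numeric(1))
}
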