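#' Configuration for the synthetic count generator
#'
#' Describes a two-condition (or time-series) RNA-seq experiment with a
#' lognormal expression baseline, multiplicative lognormal replicate noise,
#' and a subset of genes carrying injected fold changes. Defaults emulate a
#' small bacterial-scale dataset: 2000 genes, 15% replicate CV (within the
#' 5-20% band typical of bulk RNA-seq replicates), 200 DE genes at 4- to
#' 8-fold change.
#'
#' @param m Number of genes.
#' @param baseline_meanlog,baseline_sdlog Natural-log mean and sd of the
#'   lognormal baseline of relative expression (TPM-like units).
#' @param replicate_cv Fractional coefficient of variation of the
#'   multiplicative replicate noise; `0` gives deterministic expected
#'   counts (identical replicates).
#' @param n_de Number of genes with an injected fold change.
#' @param fold_range Length-2 vector, minimum and maximum fold change
#'   (ratio scale, >= 1).
#' @param direction_prob Probability that an injected change is up (vs
#'   down) in condition 2. Only honored when `balance_mass = FALSE`.
#' @param balance_mass When `TRUE` (default), fold-change directions are
#'   assigned so the DE genes' total expression mass is (nearly) conserved
#'   between conditions. TPM is compositional — each sample sums to one
#'   million — so an unbalanced injection would shift every non-DE gene's
#'   TPM by the mass ratio, a library-composition artifact unrelated to
#'   the genes' own regulation. Balancing emulates experiments whose
#'   global expression budget is preserved, the situation in which
#'   cross-sample TPM comparison is meaningful; with minimum folds well
#'   above 1, conservation forces more down- than up-regulated genes.
#' @param spike_frac Fraction of genes replaced by a low-expression noise
#'   spike (drawn well below the baseline bulk); spike genes never carry
#'   fold changes.
#' @param lengths_range Gene-length bounds in base pairs.
#' @param library_size Total counts per sample.
#' @param time_points Optional vector of time labels; when set, conditions
#'   become one per time point and injected fold changes ramp
#'   geometrically from none at the first time to the full fold at the
#'   last.
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @return A `scatterde_synth_config` list.
#' @export
synth_config <- function(m = 2000, baseline_meanlog = 2.5,
                         baseline_sdlog = 1.2, replicate_cv = 0.15,
                         n_de = 200, fold_range = c(4, 8),
                         direction_prob = 0.5, balance_mass = TRUE,
                         spike_frac = 0, lengths_range = c(500, 3000),
                         library_size = 5e6, time_points = NULL, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    abort("seed is mandatory (field: seed)", class = "scatterde_error_invalid")
  }
  check <- function(ok, field) {
    if (!ok) abort(paste0("invalid synthetic config (field: ", field, ")"),
                   class = "scatterde_error_invalid")
  }
  check(is.numeric(m) && m >= 1, "m")
  check(n_de >= 0 && n_de <= m, "n_de")
  check(length(fold_range) == 2L && fold_range[1] >= 1 &&
          fold_range[2] >= fold_range[1], "fold_range")
  check(replicate_cv >= 0, "replicate_cv")
  check(direction_prob >= 0 && direction_prob <= 1, "direction_prob")
  check(spike_frac >= 0 && spike_frac < 1, "spike_frac")
  check(length(lengths_range) == 2L && lengths_range[1] > 0 &&
          lengths_range[2] >= lengths_range[1], "lengths_range")
  check(library_size > 0, "library_size")
  structure(
    list(m = as.integer(m), baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog, replicate_cv = replicate_cv,
         n_de = as.integer(n_de), fold_range = fold_range,
         direction_prob = direction_prob, balance_mass = isTRUE(balance_mass),
         spike_frac = spike_frac,
         lengths_range = lengths_range, library_size = library_size,
         time_points = time_points, seed = as.integer(seed)),
    class = "scatterde_synth_config"
  )
}

#' Generate a synthetic count matrix with known DE structure
#'
#' Per gene, a baseline expression is drawn from the configured lognormal;
#' DE genes have their condition-2 mean multiplied by the true fold (up or
#' down). Each sample's expression is the condition mean times
#' multiplicative lognormal noise with the configured CV (mean 1), and
#' counts are drawn multinomially to the library size with gene-length
#' weighting, so TPM normalization recovers the intended relative
#' expression without bias. With `replicate_cv = 0` the expected counts
#' are returned directly (no sampling), so replicates are identical.
#'
#' @param cfg A [synth_config()].
#' @return A list: `counts` (tibble as from [read_counts()]),
#'   `gene_lengths`, `design`, and `truth` (tibble `gene_id`, `is_de`,
#'   `true_fold` — the applied condition-2/condition-1 ratio, below 1 for
#'   down-regulation).
#' @export
generate_counts <- function(cfg) {
  if (!inherits(cfg, "scatterde_synth_config")) {
    abort("cfg must come from synth_config()",
          class = "scatterde_error_invalid")
  }
  with_local_seed(cfg$seed, {
    m <- cfg$m
    gene_id <- sprintf("gene_%05d", seq_len(m))
    lengths <- round(runif(m, cfg$lengths_range[1], cfg$lengths_range[2]))
    base <- rlnorm(m, cfg$baseline_meanlog, cfg$baseline_sdlog)
    n_spike <- floor(cfg$spike_frac * m)
    spike_idx <- if (n_spike > 0) sample.int(m, n_spike) else integer()
    if (n_spike > 0) {
      # a dim population well below the bulk (around and below ~1 TPM at
      # the default baseline), emulating low-expression technical noise
      base[spike_idx] <- rlnorm(n_spike, cfg$baseline_meanlog - 6.5, 0.5)
    }
    eligible <- setdiff(seq_len(m), spike_idx)
    if (cfg$n_de > length(eligible)) {
      abort("n_de exceeds the number of non-spike genes (field: n_de)",
            class = "scatterde_error_invalid")
    }
    de_idx <- if (cfg$n_de > 0) sort(sample(eligible, cfg$n_de)) else integer()
    fold <- rep(1, m)
    if (cfg$n_de > 0) {
      f <- runif(cfg$n_de, cfg$fold_range[1], cfg$fold_range[2])
      up <- if (cfg$balance_mass) {
        # choose directions so the DE genes' total mass change is near
        # zero: visit genes in decreasing potential effect and push the
        # running imbalance toward zero (number-partitioning greedy)
        # balance expression mass: every gene's TPM scales with
        # 1 / sum(mu), so conserving sum(mu) over the DE set keeps
        # non-DE TPM comparable across conditions
        b_de <- base[de_idx]
        gain <- b_de * (f - 1)        # mass added if up-regulated
        loss <- b_de * (1 - 1 / f)    # mass removed if down-regulated
        ord <- order(pmax(gain, loss), decreasing = TRUE)
        up_i <- logical(cfg$n_de)
        imbalance <- 0
        for (i in ord) {
          up_i[i] <- abs(imbalance + gain[i]) < abs(imbalance - loss[i])
          imbalance <- imbalance + if (up_i[i]) gain[i] else -loss[i]
        }
        up_i
      } else {
        runif(cfg$n_de) < cfg$direction_prob
      }
      fold[de_idx] <- ifelse(up, f, 1 / f)
    }

    conditions <- if (is.null(cfg$time_points)) c("c1", "c2")
                  else paste0("t", cfg$time_points)
    n_t <- length(conditions)
    # per-condition mean: two-condition designs apply the full fold to
    # condition 2; time series ramp it geometrically across time points
    cond_mean <- function(ci) {
      if (is.null(cfg$time_points)) {
        if (ci == 1L) base else base * fold
      } else {
        base * fold^((ci - 1) / max(1L, n_t - 1L))
      }
    }
    s2 <- log(1 + cfg$replicate_cv^2)
    draw_sample <- function(mu) {
      noise <- if (cfg$replicate_cv == 0) 1
               else rlnorm(length(mu), -s2 / 2, sqrt(s2))
      w <- mu * noise * lengths / 1000  # read-rate weights
      p <- w / sum(w)
      if (cfg$replicate_cv == 0) round(cfg$library_size * p)
      else as.numeric(rmultinom(1, cfg$library_size, p))
    }
    counts <- tibble(gene_id = gene_id)
    design <- tibble(sample_id = character(), condition = character(),
                     replicate = character())
    for (ci in seq_len(n_t)) {
      for (rep_i in 1:2) {
        sid <- paste0(conditions[ci], "_r", rep_i)
        counts[[sid]] <- draw_sample(cond_mean(ci))
        design <- bind_rows(design, tibble(sample_id = sid,
                                           condition = conditions[ci],
                                           replicate = paste0("r", rep_i)))
      }
    }
    list(
      counts = counts,
      gene_lengths = tibble(gene_id = gene_id, length_bp = lengths),
      design = design,
      truth = tibble(gene_id = gene_id,
                     is_de = seq_len(m) %in% de_idx,
                     true_fold = fold)
    )
  })
}

#' Write a synthetic dataset as the TSV formats the readers accept
#'
#' @param sim Output of [generate_counts()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (`counts`, `gene_lengths`,
#'   `design`, `truth`).
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    gene_lengths = file.path(dir, "gene_lengths.tsv"),
    design = file.path(dir, "design.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(sim$counts, paths$counts)
  readr::write_tsv(sim$gene_lengths, paths$gene_lengths)
  readr::write_tsv(sim$design, paths$design)
  readr::write_tsv(sim$truth, paths$truth)
  invisible(paths)
}

#' Score a DE report against simulation ground truth
#'
#' @param report A `scatterde_report` (uses `de_final`) or any tibble with
#'   `gene_id` and a logical `de` column.
#' @param truth Truth tibble from [generate_counts()]. Genes absent from
#'   the report (e.g. filtered out) count as not called.
#' @return One-row tibble: `sensitivity`, `fdr`, `precision`, plus the
#'   confusion-matrix counts `tp`, `fp`, `fn`, `tn`. An empty call set has
#'   `fdr = 0` and `precision = 1` by convention.
#' @export
truth_evaluation <- function(report, truth) {
  call_col <- if ("de_final" %in% names(report)) "de_final"
              else if ("de" %in% names(report)) "de"
              else abort("report carries no DE call column",
                         class = "scatterde_error_invalid")
  if (!all(report$gene_id %in% truth$gene_id)) {
    abort("report contains genes absent from the truth table",
          class = "scatterde_error_invalid")
  }
  called_genes <- report$gene_id[report[[call_col]]]
  called <- truth$gene_id %in% called_genes
  tp <- sum(called & truth$is_de)
  fp <- sum(called & !truth$is_de)
  fn <- sum(!called & truth$is_de)
  tn <- sum(!called & !truth$is_de)
  tibble(
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    fdr = if (tp + fp == 0) 0 else fp / (tp + fp),
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}
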