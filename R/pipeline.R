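#' Run the full overlay DE pipeline
#'
#' Executes: read inputs, TPM-normalize, fit expression distributions and
#' filter low expression, compute the replicate-noise baseline, sweep dot
#' sizes, select the working dot size, call DE genes, compute KDE
#' p-values, apply cutoffs, and write all tables, a JSON manifest, and an
#' overlay SVG to the output directory. Identical configuration and inputs
#' give byte-identical tabular outputs.
#'
#' @param config A named list, or path to a YAML file holding one.
#'   Recognized fields: `counts`, `gene_lengths`, `design` (paths or
#'   tibbles); `cond1`, `cond2`; `floor` (default 1e-3);
#'   `filter_threshold` (TPM; fitted via [lower_tail_threshold()] when
#'   `NULL`), `filter_rule` (default `"mean"`), `families`; `grid`
#'   (default [default_dot_grid()]); `dot_size` (fixed size, skipping
#'   sweep selection); `metric`; `noise_mode`; `p_mode`, `p_combos`,
#'   `p_cutoff`, `fold_cutoff`; `render` (default TRUE); `out_dir`
#'   (required); `seed` (default 1).
#' @return Invisibly, a list with the report, sweep table, overlay result,
#'   baseline, selected dot size, distribution fit, filtered TPM table and
#'   output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(floor = 1e-3, filter_threshold = NULL, filter_rule = "mean",
         families = c("lognormal", "pareto", "burr", "loglogistic",
                      "weibull"),
         grid = default_dot_grid(), dot_size = NULL, metric = "euclidean",
         noise_mode = "mean", p_mode = "cdf", p_combos = "r1",
         p_cutoff = NULL, fold_cutoff = NULL, render = TRUE, seed = 1L),
    config[!vapply(config, is.null, logical(1))]
  )
  for (field in c("counts", "gene_lengths", "design", "cond1", "cond2",
                  "out_dir")) {
    if (is.null(cfg[[field]])) {
      abort(paste0("config field missing: ", field),
            class = "scatterde_error_config")
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "scatterde_error_pipeline", parent = e)
    })
    message(sprintf("[scatterde] %-12s %6.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  counts <- stage("read", {
    if (is.character(cfg$counts)) read_counts(cfg$counts)
    else validate_counts(cfg$counts)
  })
  gl <- if (is.character(cfg$gene_lengths)) read_gene_lengths(cfg$gene_lengths)
        else as_tibble(cfg$gene_lengths)
  design <- if (is.character(cfg$design)) read_design(cfg$design)
            else validate_design(cfg$design)

  tpm <- stage("normalize", tpm_normalize(counts, gl))

  filt <- stage("filter", {
    if (!is.null(cfg$filter_threshold)) {
      list(fit = NULL,
           spec = filter_spec(cfg$filter_threshold, cfg$filter_rule))
    } else {
      vals <- as.vector(expr_matrix(tpm))
      vals <- vals[vals > 0]
      fit <- select_best_family(vals, cfg$families)
      list(fit = fit,
           spec = lower_tail_threshold(vals, fit, cfg$filter_rule))
    }
  })
  fit <- filt$fit
  fspec <- filt$spec
  tpm_f <- filter_low_expression(tpm, fspec)

  pairs <- setNames(
    list(select_replicate_pair(tpm_f, design, cfg$cond1, cfg$floor),
         select_replicate_pair(tpm_f, design, cfg$cond2, cfg$floor)),
    c(cfg$cond1, cfg$cond2)
  )
  baseline <- stage("noise", {
    replicate_noise_baseline(tpm_f, design, c(cfg$cond1, cfg$cond2), pairs,
                             mode = cfg$noise_mode)
  })

  sweep <- stage("sweep", {
    sweep_dot_sizes(tpm_f, design, cfg$cond1, cfg$cond2, grid = cfg$grid,
                    floor = cfg$floor, metric = cfg$metric,
                    noise_mode = cfg$noise_mode, pairs = pairs)
  })
  dot_size <- if (!is.null(cfg$dot_size)) {
    structure(cfg$dot_size, reached_baseline = NA)
  } else {
    select_dot_size(sweep, baseline)
  }

  overlay <- stage("call", {
    overlay_de(tpm_f, design, cfg$cond1, cfg$cond2, as.numeric(dot_size),
               floor = cfg$floor, metric = cfg$metric, pairs = pairs)
  })

  lg <- log10_transform(tpm_f, cfg$floor)
  model <- build_kde_model(lg, design, cfg$cond1, cfg$cond2, pairs)
  report <- stage("pvalue", {
    de_report(overlay, tpm_f, design, cfg$cond1, cfg$cond2) |>
      de_pvalues(model, lg, mode = cfg$p_mode, combos = cfg$p_combos,
                 pairs = pairs, seed = cfg$seed) |>
      apply_cutoffs(cfg$p_cutoff, cfg$fold_cutoff)
  })

  paths <- stage("write", {
    write_outputs(cfg, counts, tpm_f, design, pairs, baseline, fit, fspec,
                  sweep, dot_size, overlay, model, report)
  })

  invisible(list(report = report, sweep = sweep, overlay = overlay,
                 baseline = baseline, dot_size = as.numeric(dot_size),
                 reached_baseline = attr(dot_size, "reached_baseline"),
                 fit = fit, filter = fspec, tpm = tpm_f, pairs = pairs,
                 model = model, paths = paths))
}

write_outputs <- function(cfg, counts, tpm_f, design, pairs, baseline, fit,
                          fspec, sweep, dot_size, overlay, model, report) {
  out <- cfg$out_dir
  paths <- list(
    de_genes = file.path(out, "de_genes.tsv"),
    sweep = file.path(out, "sweep.tsv"),
    noise = file.path(out, "noise.tsv"),
    fit = file.path(out, "fit.json"),
    manifest = file.path(out, "manifest.json"),
    overlay = file.path(out, "overlay.svg")
  )

  de_tbl <- overlay$per_gene
  de_tbl$de_overlay <- de_tbl$de
  de_tbl$de <- NULL
  de_tbl <- left_join(de_tbl,
                      report[c("gene_id", "p", "log2_fc", "de_final")],
                      by = "gene_id")
  de_tbl$dot_size <- as.numeric(dot_size)
  readr::write_tsv(de_tbl, paths$de_genes)

  readr::write_tsv(as_tibble(sweep), paths$sweep)

  scan <- overlay$scan
  noise_long <- scan$eta2 |>
    tidyr::pivot_longer(-"gene_id", names_to = "combo", values_to = "eta2")
  readr::write_tsv(noise_long, paths$noise)

  fit_json <- list(
    chosen_family = if (is.null(fit)) NULL else fit$family,
    threshold_tpm = fspec$threshold,
    rule = fspec$rule,
    fits = if (is.null(fit)) NULL else {
      lapply(attr(fit, "all_fits"), function(f) {
        list(family = f$family, params = as.list(f$params),
             loglik = f$loglik, aic = f$aic)
      })
    }
  )
  jsonlite::write_json(fit_json, paths$fit, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  manifest <- list(
    conditions = c(cfg$cond1, cfg$cond2),
    replicate_pairs = pairs,
    floor = cfg$floor,
    filter = list(threshold_tpm = fspec$threshold, rule = fspec$rule,
                  fitted = is.null(cfg$filter_threshold),
                  family = if (is.null(fit)) NULL else fit$family),
    grid = cfg$grid,
    dot_size = as.numeric(dot_size),
    dot_size_fixed = !is.null(cfg$dot_size),
    reached_baseline = attr(dot_size, "reached_baseline"),
    metric = cfg$metric,
    noise_mode = cfg$noise_mode,
    replicate_noise_baseline = baseline,
    bandwidth_method = model$bandwidth,
    bandwidth = as.list(model$h),
    p_mode = cfg$p_mode,
    p_combos = cfg$p_combos,
    p_cutoff = cfg$p_cutoff,
    fold_cutoff = cfg$fold_cutoff,
    n_genes_after_filter = nrow(tpm_f),
    de_count_overlay = overlay$de_count,
    de_count_final = sum(report$de_final),
    seed = cfg$seed
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  if (isTRUE(cfg$render)) {
    render_overlay(overlay, paths$overlay)
  } else {
    paths$overlay <- NULL
  }
  paths
}

#' Render an overlay scatter as an SVG file
#'
#' Draws the combined replicate clouds (grey) and one between-condition
#' point set, with DE genes green and non-DE genes orange. Dot radii are
#' the working dot size in log10-TPM data units, so the picture shows the
#' geometry the caller actually used. Written as plain SVG markup; glyphs
#' carry class attributes (`rep`, `de`, `nonde`) for downstream styling or
#' inspection.
#'
#' @param overlay A `scatterde_overlay` from [overlay_de()] (it carries
#'   its scan geometry).
#' @param path Output file path.
#' @param combo Which between-condition combination to draw (default
#'   `"r1_r1"`).
#' @return Invisibly, `path`.
#' @export
render_overlay <- function(overlay, path, combo = "r1_r1") {
  if (is.null(overlay$scan)) {
    abort("overlay carries no scan geometry; build it with overlay_de()",
          class = "scatterde_error_invalid")
  }
  scan <- overlay$scan
  rep_pts <- bind_rows(scan$rep_clouds)
  cmb <- scan$combos[scan$combos$combo == combo, ]
  de <- overlay$per_gene$de[match(cmb$gene_id, overlay$per_gene$gene_id)]

  all_u <- c(rep_pts$u, cmb$u)
  all_v <- c(rep_pts$v, cmb$v)
  pad <- 0.05 * max(diff(range(all_u)), diff(range(all_v)), 1e-6)
  x0 <- min(all_u) - pad
  x1 <- max(all_u) + pad
  y0 <- min(all_v) - pad
  y1 <- max(all_v) + pad
  size <- 600
  sc <- size / max(x1 - x0, y1 - y0)
  tx <- function(u) (u - x0) * sc
  ty <- function(v) size - (v - y0) * sc  # svg y grows downward
  r_px <- max(overlay$dot_size * sc, 0.5)

  circ <- function(u, v, cls, fill) {
    sprintf('<circle class="%s" cx="%.2f" cy="%.2f" r="%.2f" fill="%s"/>',
            cls, tx(u), ty(v), r_px, fill)
  }
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            size + 60, size + 60, size + 60, size + 60),
    '<g transform="translate(40,10)">',
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="white" stroke="black"/>',
            size, size),
    circ(rep_pts$u, rep_pts$v, "rep", "#bbbbbb"),
    circ(cmb$u[!de], cmb$v[!de], "nonde", "#e08214"),
    if (any(de)) circ(cmb$u[de], cmb$v[de], "de", "#1a9850") else character(),
    '</g>',
    sprintf('<text x="%d" y="%d" text-anchor="middle">log10(TPM), %s</text>',
            40 + size %/% 2, size + 45, scan$conditions[1]),
    sprintf('<text x="12" y="%d" transform="rotate(-90 12 %d)" text-anchor="middle">log10(TPM), %s</text>',
            10 + size %/% 2, 10 + size %/% 2, scan$conditions[2]),
    '</svg>'
  )
  writeLines(lines, path)
  invisible(path)
}
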