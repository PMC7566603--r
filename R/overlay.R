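#' Default dot-size grid
#'
#' Dot sizes from 0.001 to 0.009 log10-TPM in steps of 0.001, plus 0.015.
#'
#' @return Numeric vector of dot sizes (log10-TPM units).
#' @export
default_dot_grid <- function() c(seq(0.001, 0.009, by = 0.001), 0.015)

#' Build the replicate scatter cloud of one condition
#'
#' Each gene contributes one point whose coordinates are its log10-TPM in
#' the condition's two selected replicates. This cloud is the empirical null
#' of no differential expression: it shows how far apart two measurements of
#' the same transcriptome fall.
#'
#' @param lg Log10-scale expression tibble.
#' @param design Design tibble.
#' @param condition Condition label.
#' @param pair Optional character vector of two sample ids; chosen by
#'   [select_replicate_pair()] order when `NULL` (with exactly two
#'   replicates, those two).
#' @return Tibble with columns `gene_id`, `u`, `v`; the samples used are in
#'   attribute `"samples"` and the label in `"label"`.
#' @export
build_replicate_cloud <- function(lg, design, condition, pair = NULL) {
  if (expr_scale(lg) != "log10") {
    abort("clouds are built from log10-scale expression",
          class = "scatterde_error_invalid")
  }
  if (is.null(pair)) {
    ids <- sort(samples_of(design, condition))
    if (length(ids) < 2L) {
      abort(paste0("no replicate pair available for condition '", condition,
                   "'"), class = "scatterde_error_invalid")
    }
    pair <- ids[1:2]
  }
  out <- tibble(gene_id = lg$gene_id, u = lg[[pair[1]]], v = lg[[pair[2]]])
  attr(out, "samples") <- pair
  attr(out, "label") <- paste0("replicate_cloud_", condition)
  out
}

#' Build the four between-condition point sets
#'
#' With two replicates per condition there are four replicate-by-condition
#' combinations; each gives every gene a 2D point (log10-TPM in condition 1
#' replicate a, log10-TPM in condition 2 replicate b).
#'
#' @inheritParams build_replicate_cloud
#' @param cond1,cond2 Condition labels.
#' @param pairs Optional named list `condition -> c(sample, sample)`.
#' @return Tibble with columns `gene_id`, `combo` (`"r1_r1"`, `"r1_r2"`,
#'   `"r2_r1"`, `"r2_r2"`; condition-1 replicate first), `u`, `v`. The
#'   sample map is in attribute `"pairs"`.
#' @export
build_condition_points <- function(lg, design, cond1, cond2, pairs = NULL) {
  if (expr_scale(lg) != "log10") {
    abort("clouds are built from log10-scale expression",
          class = "scatterde_error_invalid")
  }
  get_pair <- function(cond) {
    if (!is.null(pairs) && !is.null(pairs[[cond]])) return(pairs[[cond]])
    ids <- sort(samples_of(design, cond))
    if (length(ids) < 2L) {
      abort(paste0("condition '", cond, "' needs 2 replicates"),
            class = "scatterde_error_invalid")
    }
    ids[1:2]
  }
  p1 <- get_pair(cond1)
  p2 <- get_pair(cond2)
  combos <- tidyr::expand_grid(a = 1:2, b = 1:2)
  out <- purrr::pmap(combos, function(a, b) {
    tibble(gene_id = lg$gene_id, combo = paste0("r", a, "_r", b),
           u = lg[[p1[a]]], v = lg[[p2[b]]])
  })
  out <- bind_rows(out)
  attr(out, "pairs") <- setNames(list(p1, p2), c(cond1, cond2))
  out
}

as_xy <- function(x) {
  if (is.matrix(x)) return(x)
  cbind(x$u, x$v)
}

# Minimum distance from each query point to any cloud point, computed in
# chunks so the distance matrix never exceeds a few MB. Empty cloud -> Inf.
min_cloud_distance <- function(points, cloud,
                               metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  p <- as_xy(points)
  q <- as_xy(cloud)
  n <- nrow(p)
  if (nrow(q) == 0L) return(rep(Inf, n))
  out <- numeric(n)
  chunk <- max(1L, floor(2e6 / nrow(q)))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    dx <- abs(outer(p[idx, 1], q[, 1], "-"))
    dy <- abs(outer(p[idx, 2], q[, 2], "-"))
    d <- if (metric == "euclidean") sqrt(dx^2 + dy^2) else pmax(dx, dy)
    out[idx] <- apply(d, 1, min)
  }
  out
}

#' Test dot overlap against a scatter cloud
#'
#' Dots are disks of radius `dot_size` in log10-TPM data units; a query dot
#' overlaps the cloud when its center lies within `2 * dot_size` of any
#' cloud point (touching counts). The `"grid"` method buckets cloud points
#' into cells of side `2 * dot_size` and only inspects the 3x3 neighborhood
#' of each query; it returns exactly the same answer as the `"brute"`
#' all-pairs scan.
#'
#' @param points Query points: a tibble with `u`, `v` columns or a 2-column
#'   matrix.
#' @param cloud Cloud points, same formats. An empty cloud overlaps nothing.
#' @param dot_size Dot radius in log10-TPM units, positive.
#' @param metric `"euclidean"` disks (default) or `"chebyshev"` squares.
#' @param method `"grid"` (indexed, default) or `"brute"`.
#' @return Logical vector, one entry per query point.
#' @export
is_overlapped <- function(points, cloud, dot_size,
                          metric = c("euclidean", "chebyshev"),
                          method = c("grid", "brute")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  if (!is.numeric(dot_size) || length(dot_size) != 1L || dot_size <= 0) {
    abort("dot_size must be a positive number",
          class = "scatterde_error_invalid")
  }
  p <- as_xy(points)
  q <- as_xy(cloud)
  if (nrow(q) == 0L) return(rep(FALSE, nrow(p)))
  r <- 2 * dot_size
  if (method == "brute") {
    return(min_cloud_distance(p, q, metric) <= r)
  }
  # grid index: any point within r of a query sits in one of the 9 cells
  # around the query's cell, because the cell side equals r
  cell_key <- function(m) paste(floor(m[, 1] / r), floor(m[, 2] / r))
  buckets <- split(seq_len(nrow(q)), cell_key(q))
  cx <- floor(p[, 1] / r)
  cy <- floor(p[, 2] / r)
  vapply(seq_len(nrow(p)), function(i) {
    keys <- paste(rep(cx[i] + (-1:1), each = 3), cy[i] + (-1:1))
    cand <- unlist(buckets[keys], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0L) return(FALSE)
    dx <- abs(q[cand, 1] - p[i, 1])
    dy <- abs(q[cand, 2] - p[i, 2])
    d <- if (metric == "euclidean") sqrt(dx^2 + dy^2) else pmax(dx, dy)
    any(d <= r)
  }, logical(1))
}

#' Call DE genes from overlaid scatter clouds
#'
#' A gene is differentially expressed at the given dot size when, in every
#' one of the four replicate-by-condition combinations, its
#' between-condition point is not overlapped by any point of the combined
#' replicate clouds (each gene's own replicate points are part of the
#' clouds). Because replicate labels are arbitrary, the clouds are used in
#' both axis orientations (mirrored across the diagonal), which makes the
#' DE set invariant to replicate relabeling and to condition order.
#'
#' @param combo_points Tibble from [build_condition_points()].
#' @param rep_clouds A list of the two replicate-cloud tibbles, or one
#'   tibble of their union.
#' @param dot_size Dot radius in log10-TPM units.
#' @inheritParams is_overlapped
#' @return A `scatterde_overlay` object with `$per_gene` (tibble: `gene_id`,
#'   one logical `overlap_*` column per combination, `de`), `$dot_size` and
#'   `$de_count`. Has [tidy()] and [glance()] methods.
#' @export
call_de <- function(combo_points, rep_clouds, dot_size,
                    metric = c("euclidean", "chebyshev"),
                    method = c("grid", "brute")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  cloud <- if (is.data.frame(rep_clouds)) rep_clouds else bind_rows(rep_clouds)
  genes <- unique(combo_points$gene_id)
  by_combo <- split(combo_points, combo_points$combo)
  for (cc in by_combo) {
    if (!identical(sort(cc$gene_id), sort(unique(cloud$gene_id))) ||
        !identical(sort(cc$gene_id), sort(genes))) {
      abort("combination points and replicate clouds cover different genes",
            class = "scatterde_error_invalid")
    }
  }
  cloud_xy <- symmetrize_cloud(cloud)
  per_gene <- tibble(gene_id = by_combo[[1]]$gene_id)
  for (nm in names(by_combo)) {
    cc <- by_combo[[nm]]
    ov <- is_overlapped(cc, cloud_xy, dot_size, metric, method)
    per_gene[[paste0("overlap_", nm)]] <- ov[match(per_gene$gene_id,
                                                   cc$gene_id)]
  }
  flag_cols <- grep("^overlap_", names(per_gene), value = TRUE)
  per_gene$de <- !Reduce(`|`, per_gene[flag_cols])
  structure(
    list(per_gene = per_gene, dot_size = dot_size, metric = metric,
         de_count = sum(per_gene$de)),
    class = "scatterde_overlay"
  )
}

#' @exportS3Method
tidy.scatterde_overlay <- function(x, ...) x$per_gene

#' @exportS3Method
glance.scatterde_overlay <- function(x, ...) {
  tibble(dot_size = x$dot_size, de_count = x$de_count,
         n_genes = nrow(x$per_gene), metric = x$metric)
}

#' @export
print.scatterde_overlay <- function(x, ...) {
  cat("<scatterde_overlay> dot_size = ", x$dot_size, ": ", x$de_count,
      " of ", nrow(x$per_gene), " genes DE\n", sep = "")
  invisible(x)
}

# The null cloud used for overlap tests: both orientations of every
# replicate pair. Replicate labels are arbitrary, so the cloud of "how far
# apart can two measurements of the same transcriptome fall" is unordered;
# mirroring it across the diagonal makes DE calls invariant to replicate
# relabeling and to condition order.
symmetrize_cloud <- function(cloud) {
  xy <- as_xy(cloud)
  rbind(xy, xy[, 2:1, drop = FALSE])
}

# Precompute, per gene and combination, the distance from the
# between-condition point to the nearest replicate-cloud point, plus the
# per-combination linear-TPM noise. Everything downstream of the geometry
# (DE at any dot size, sweep rows) is thresholding of these distances.
overlay_scan <- function(tpm, design, cond1, cond2, floor = 1e-3,
                         metric = "euclidean", pairs = NULL) {
  if (expr_scale(tpm) != "linear") {
    abort("overlay_scan expects linear TPM input",
          class = "scatterde_error_invalid")
  }
  if (is.null(pairs)) {
    pairs <- setNames(
      list(select_replicate_pair(tpm, design, cond1, floor),
           select_replicate_pair(tpm, design, cond2, floor)),
      c(cond1, cond2)
    )
  }
  lg <- log10_transform(tpm, floor)
  rc1 <- build_replicate_cloud(lg, design, cond1, pairs[[cond1]])
  rc2 <- build_replicate_cloud(lg, design, cond2, pairs[[cond2]])
  cloud <- symmetrize_cloud(bind_rows(rc1, rc2))
  combos <- build_condition_points(lg, design, cond1, cond2, pairs)
  by_combo <- split(combos, combos$combo)
  dist <- tibble(gene_id = tpm$gene_id)
  eta2 <- tibble(gene_id = tpm$gene_id)
  for (nm in names(by_combo)) {
    cc <- by_combo[[nm]]
    d <- min_cloud_distance(cc, cloud, metric)
    dist[[nm]] <- d[match(dist$gene_id, cc$gene_id)]
    a <- as.integer(substr(nm, 2, 2))
    b <- as.integer(substr(nm, 5, 5))
    x <- tpm[[pairs[[cond1]][a]]]
    y <- tpm[[pairs[[cond2]][b]]]
    # genes unobserved in both samples of a combo carry no noise
    # information; they sit at the log floor and are overlap-covered
    eta2[[nm]] <- ifelse(x + y == 0, NA_real_, 2 * (x - y)^2 / (x + y)^2)
  }
  structure(
    list(dist = dist, eta2 = eta2, pairs = pairs,
         conditions = c(cond1, cond2), metric = metric, floor = floor,
         rep_clouds = list(rc1, rc2), combos = combos),
    class = "scatterde_scan"
  )
}

# DE flags at one dot size from a precomputed scan: a gene is DE when every
# combination's point is farther than 2 * dot_size from the cloud.
scan_de <- function(scan, dot_size) {
  combo_cols <- setdiff(names(scan$dist), "gene_id")
  crit <- do.call(pmin, scan$dist[combo_cols])
  crit > 2 * dot_size
}

#' Sweep the overlay over a grid of dot sizes
#'
#' For each dot size, counts DE genes and records the between-condition
#' noise (averaged over the four combinations) of the DE and non-DE gene
#' sets. Larger dots cover more of the plane, so the DE set shrinks as the
#' dot size grows.
#'
#' @param tpm Linear-scale, filtered expression tibble.
#' @param design Design tibble.
#' @param cond1,cond2 Condition labels.
#' @param grid Ascending positive dot sizes; defaults to
#'   [default_dot_grid()].
#' @param floor Log-transform floor, TPM units.
#' @param metric Overlap metric, see [is_overlapped()].
#' @param noise_mode `"mean"` or `"sum"`, see [transcriptome_noise()].
#' @param pairs Optional named list of replicate pairs.
#' @return A `scatterde_sweep` tibble with columns `dot_size`, `de_count`,
#'   `de_noise`, `nonde_noise` (noise entries are `NA` when a set is
#'   empty); the underlying scan is kept in attribute `"scan"`.
#' @export
sweep_dot_sizes <- function(tpm, design, cond1, cond2,
                            grid = default_dot_grid(), floor = 1e-3,
                            metric = "euclidean", noise_mode = "mean",
                            pairs = NULL) {
  if (length(grid) == 0L) {
    abort("empty dot-size grid", class = "scatterde_error_invalid")
  }
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE)) {
    abort("grid must be strictly ascending positive dot sizes",
          class = "scatterde_error_invalid")
  }
  scan <- overlay_scan(tpm, design, cond1, cond2, floor, metric, pairs)
  combo_cols <- setdiff(names(scan$eta2), "gene_id")
  set_noise <- function(keep) {
    if (!any(keep)) return(NA_real_)
    mean(vapply(combo_cols, function(cc) {
      vals <- na.omit(scan$eta2[[cc]][keep])
      if (length(vals) == 0L) return(NA_real_)
      transcriptome_noise(vals, noise_mode)
    }, numeric(1)))
  }
  rows <- purrr::map(grid, function(s) {
    de <- scan_de(scan, s)
    tibble(dot_size = s, de_count = sum(de),
           de_noise = set_noise(de), nonde_noise = set_noise(!de))
  })
  out <- bind_rows(rows)
  attr(out, "scan") <- scan
  attr(out, "noise_mode") <- noise_mode
  class(out) <- c("scatterde_sweep", class(out))
  out
}

#' Select the working dot size from a sweep
#'
#' The dot size is calibrated against the replicate-noise baseline: tiny
#' dots call almost every gene DE, leaving a non-DE set whose
#' between-condition noise is far below what replicates alone produce; as
#' the dot size grows the non-DE set absorbs ordinarily noisy genes and its
#' noise rises toward the baseline. The selected size is the smallest grid
#' size at which the non-DE between-condition noise has reached (>=) the
#' replicate baseline — the first size past the crossing. If the non-DE
#' noise never reaches the baseline the largest grid size is returned with
#' a warning, flagged in the `"reached_baseline"` attribute.
#'
#' @param sweep A `scatterde_sweep` tibble.
#' @param baseline Replicate-noise baseline from
#'   [replicate_noise_baseline()], same noise mode as the sweep.
#' @return The selected dot size (scalar), with attribute
#'   `"reached_baseline"`.
#' @export
select_dot_size <- function(sweep, baseline) {
  if (nrow(sweep) == 0L) {
    abort("empty sweep table", class = "scatterde_error_invalid")
  }
  if (!is.numeric(baseline) || baseline < 0) {
    abort("baseline must be a non-negative number",
          class = "scatterde_error_invalid")
  }
  ok <- !is.na(sweep$nonde_noise) & sweep$nonde_noise >= baseline
  if (any(ok)) {
    out <- sweep$dot_size[which(ok)[1]]
    attr(out, "reached_baseline") <- TRUE
  } else {
    warn("non-DE noise never reaches the replicate baseline; falling back to the largest dot size")
    out <- sweep$dot_size[nrow(sweep)]
    attr(out, "reached_baseline") <- FALSE
  }
  out
}

#' Overlay DE calls at one dot size, end to end
#'
#' Convenience wrapper: builds clouds from filtered linear TPM, computes
#' per-combination overlap flags at `dot_size`, and returns the
#' `scatterde_overlay` result.
#'
#' @inheritParams sweep_dot_sizes
#' @param dot_size Dot radius in log10-TPM units.
#' @return A `scatterde_overlay` object (see [call_de()]).
#' @export
overlay_de <- function(tpm, design, cond1, cond2, dot_size, floor = 1e-3,
                       metric = "euclidean", pairs = NULL) {
  scan <- overlay_scan(tpm, design, cond1, cond2, floor, metric, pairs)
  combo_cols <- setdiff(names(scan$dist), "gene_id")
  per_gene <- tibble(gene_id = scan$dist$gene_id)
  for (nm in combo_cols) {
    per_gene[[paste0("overlap_", nm)]] <- scan$dist[[nm]] <= 2 * dot_size
  }
  per_gene$de <- scan_de(scan, dot_size)
  structure(
    list(per_gene = per_gene, dot_size = dot_size, metric = scan$metric,
         de_count = sum(per_gene$de), scan = scan),
    class = "scatterde_overlay"
  )
}
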