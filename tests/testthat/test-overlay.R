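lg_from <- function(m, gene_id = sprintf("g%03d", seq_len(nrow(m)))) {
  expr_tbl(m, gene_id = gene_id, scale = "log10")
}

test_that("clouds are identity mappings of the expression table", {
  set.seed(301)
  m <- matrix(rnorm(20), 5, 4,
              dimnames = list(NULL, c("c1_r1", "c1_r2", "c2_r1", "c2_r2")))
  lg <- lg_from(m)
  des <- two_cond_design()
  rc <- build_replicate_cloud(lg, des, "c1")
  expect_equal(rc$u, m[, "c1_r1"])
  expect_equal(rc$v, m[, "c1_r2"])
  expect_equal(nrow(rc), 5)

  combos <- build_condition_points(lg, des, "c1", "c2")
  expect_equal(sort(unique(combos$combo)),
               c("r1_r1", "r1_r2", "r2_r1", "r2_r2"))
  expect_equal(nrow(combos), 20)
  r2r1 <- combos[combos$combo == "r2_r1", ]
  expect_equal(r2r1$u, m[, "c1_r2"])
  expect_equal(r2r1$v, m[, "c2_r1"])

  # identical replicates put every replicate-cloud point on the diagonal
  m2 <- m
  m2[, "c1_r2"] <- m2[, "c1_r1"]
  rc2 <- build_replicate_cloud(lg_from(m2), des, "c1")
  expect_equal(rc2$u, rc2$v)

  expect_error(build_replicate_cloud(expr_tbl(m), des, "c1"), "log10")
})

test_that("overlap predicate matches hand-computed distances", {
  p <- matrix(c(1, 1), ncol = 2)
  near <- matrix(c(1.005, 1.005), ncol = 2)   # distance ~0.00707
  far <- matrix(c(1.010, 1.010), ncol = 2)    # distance ~0.01414
  for (method in c("grid", "brute")) {
    expect_true(is_overlapped(p, near, 0.004, "euclidean", method))
    expect_false(is_overlapped(p, far, 0.004, "euclidean", method))
    # chebyshev: |dx| = |dy| = 0.005 <= 0.008; 0.010 > 0.008
    expect_true(is_overlapped(p, near, 0.004, "chebyshev", method))
    expect_false(is_overlapped(p, far, 0.004, "chebyshev", method))
  }
  # touching counts as overlap (0.008 = 2 * 0.004 exactly in binary)
  expect_true(is_overlapped(matrix(c(0, 0), ncol = 2),
                            matrix(c(0.008, 0), ncol = 2), 0.004))
  expect_false(is_overlapped(p, matrix(numeric(0), ncol = 2), 0.004))
  expect_error(is_overlapped(p, near, 0), "positive")
})

test_that("indexed overlap equals brute force on random instances", {
  for (seed in 1:15) {
    inst <- random_instance(150, seed)
    s <- c(0.001, 0.004, 0.02)[seed %% 3 + 1]
    for (metric in c("euclidean", "chebyshev")) {
      expect_identical(
        is_overlapped(inst$queries, inst$cloud, s, metric, "grid"),
        is_overlapped(inst$queries, inst$cloud, s, metric, "brute"))
    }
  }
})

test_that("DE calls require non-overlap in all four combinations", {
  des <- two_cond_design()
  # 5 genes identical everywhere; gene 6 strongly induced in c2
  base <- c(0.5, 1, 1.5, 2, 2.5, 1)
  m <- cbind(c1_r1 = base, c1_r2 = base,
             c2_r1 = base + c(rep(0, 5), 1), c2_r2 = base + c(rep(0, 5), 1))
  lg <- lg_from(m)
  combos <- build_condition_points(lg, des, "c1", "c2")
  reps <- list(build_replicate_cloud(lg, des, "c1"),
               build_replicate_cloud(lg, des, "c2"))
  ov <- call_de(combos, reps, dot_size = 0.004)
  expect_equal(ov$per_gene$de, c(rep(FALSE, 5), TRUE))
  expect_equal(ov$de_count, 1)
  # a gene identical in all samples coincides with its own cloud points
  expect_false(ov$per_gene$de[1])
  expect_true(all(ov$per_gene$overlap_r1_r1[1:5]))

  bad <- combos[combos$gene_id != "g001", ]
  expect_error(call_de(bad, reps, 0.004), "different genes")
})

test_that("call_de equals an exhaustive distance-scan oracle", {
  set.seed(302)
  n <- 120
  base <- runif(n, 0, 3)
  m <- cbind(c1_r1 = base + rnorm(n, 0, 0.05),
             c1_r2 = base + rnorm(n, 0, 0.05),
             c2_r1 = base + rnorm(n, 0, 0.08),
             c2_r2 = base + rnorm(n, 0, 0.08))
  des <- two_cond_design()
  lg <- lg_from(m)
  combos <- build_condition_points(lg, des, "c1", "c2")
  reps <- list(build_replicate_cloud(lg, des, "c1"),
               build_replicate_cloud(lg, des, "c2"))
  # the null cloud is unordered in its replicate axes: both orientations
  one_way <- rbind(cbind(m[, "c1_r1"], m[, "c1_r2"]),
                   cbind(m[, "c2_r1"], m[, "c2_r2"]))
  cloud_xy <- rbind(one_way, one_way[, 2:1])
  for (s in c(0.002, 0.01)) {
    ov <- call_de(combos, reps, s)
    de_oracle <- rep(TRUE, n)
    for (a in 1:2) for (b in 1:2) {
      pts <- cbind(m[, paste0("c1_r", a)], m[, paste0("c2_r", b)])
      de_oracle <- de_oracle & (oracle_min_dist(pts, cloud_xy) > 2 * s)
    }
    expect_equal(ov$per_gene$de, de_oracle)
  }
})

test_that("overlay_de agrees with call_de on the same geometry", {
  sim <- generate_counts(synth_config(m = 150, n_de = 15, seed = 303))
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)
  lg <- log10_transform(tpm)
  des <- sim$design
  ov1 <- overlay_de(tpm, des, "c1", "c2", 0.004)
  combos <- build_condition_points(lg, des, "c1", "c2")
  reps <- list(build_replicate_cloud(lg, des, "c1"),
               build_replicate_cloud(lg, des, "c2"))
  ov2 <- call_de(combos, reps, 0.004)
  expect_equal(ov1$per_gene$de, ov2$per_gene$de)
  expect_equal(ov1$per_gene$overlap_r1_r2, ov2$per_gene$overlap_r1_r2)
})

test_that("DE sets shrink monotonically with dot size", {
  sim <- generate_counts(synth_config(m = 300, n_de = 30, seed = 304))
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)
  sets <- lapply(default_dot_grid(), function(s) {
    ov <- overlay_de(tpm, sim$design, "c1", "c2", s)
    ov$per_gene$gene_id[ov$per_gene$de]
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("condition order does not change the DE set", {
  sim <- generate_counts(synth_config(m = 200, n_de = 20, seed = 305))
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)
  ov12 <- overlay_de(tpm, sim$design, "c1", "c2", 0.003)
  ov21 <- overlay_de(tpm, sim$design, "c2", "c1", 0.003)
  expect_equal(ov12$per_gene$gene_id[ov12$per_gene$de],
               ov21$per_gene$gene_id[ov21$per_gene$de])
})

test_that("self-comparison yields no DE genes", {
  sim <- generate_counts(synth_config(m = 200, n_de = 20, seed = 306))
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)
  # pretend condition 2 is a copy of condition 1's samples
  tpm_self <- tpm
  tpm_self$c2_r1 <- tpm$c1_r1
  tpm_self$c2_r2 <- tpm$c1_r2
  for (s in c(0.001, 0.004, 0.015)) {
    ov <- overlay_de(tpm_self, sim$design, "c1", "c2", s)
    expect_equal(ov$de_count, 0)
  }
})

test_that("the sweep table matches per-size recomputation", {
  sim <- generate_counts(synth_config(m = 200, n_de = 20, seed = 307))
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)
  grid <- c(0.002, 0.006, 0.012)
  sw <- sweep_dot_sizes(tpm, sim$design, "c1", "c2", grid = grid)
  expect_equal(sw$dot_size, grid)
  expect_true(all(diff(sw$de_count) <= 0))
  pair_names <- list(c("c1_r1", "c2_r1"), c("c1_r1", "c2_r2"),
                     c("c1_r2", "c2_r1"), c("c1_r2", "c2_r2"))
  for (i in seq_along(grid)) {
    ov <- overlay_de(tpm, sim$design, "c1", "c2", grid[i])
    expect_equal(sw$de_count[i], ov$de_count)
    de <- ov$per_gene$de
    noise_of <- function(keep) {
      mean(vapply(pair_names, function(p) {
        mean(gene_pair_noise(tpm[[p[1]]][keep], tpm[[p[2]]][keep]))
      }, numeric(1)))
    }
    expect_equal(sw$de_noise[i], noise_of(de))
    expect_equal(sw$nonde_noise[i], noise_of(!de))
  }
  expect_error(sweep_dot_sizes(tpm, sim$design, "c1", "c2",
                               grid = numeric(0)), "empty")
  expect_error(sweep_dot_sizes(tpm, sim$design, "c1", "c2",
                               grid = c(0.004, 0.002)), "ascending")
})

test_that("dot-size selection finds the first size past the baseline crossing", {
  sweep_tbl <- tibble::tibble(
    dot_size = c(0.001, 0.002, 0.003, 0.004),
    de_count = c(40, 30, 20, 10),
    de_noise = c(0.5, 0.6, 0.7, 0.8),
    nonde_noise = c(0.010, 0.018, 0.026, 0.031)
  )
  class(sweep_tbl) <- c("scatterde_sweep", class(sweep_tbl))
  picked <- select_dot_size(sweep_tbl, baseline = 0.022)
  expect_equal(as.numeric(picked), 0.003)
  expect_true(attr(picked, "reached_baseline"))
  # independent scan of the same contract
  expect_equal(as.numeric(picked),
               sweep_tbl$dot_size[min(which(sweep_tbl$nonde_noise >= 0.022))])

  # baseline above every non-DE noise: fall back to the largest, flagged
  expect_warning(fallback <- select_dot_size(sweep_tbl, baseline = 0.05),
                 "largest")
  expect_equal(as.numeric(fallback), 0.004)
  expect_false(attr(fallback, "reached_baseline"))

  # zero baseline: any nonzero non-DE noise already exceeds it
  picked0 <- select_dot_size(sweep_tbl, baseline = 0)
  expect_equal(as.numeric(picked0), 0.001)
})

test_that("selection on generated data matches a direct scan of the sweep", {
  sim <- generate_counts(synth_config(m = 400, n_de = 60,
                                      fold_range = c(2, 4), seed = 308))
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)
  baseline <- replicate_noise_baseline(tpm, sim$design, c("c1", "c2"))
  sw <- sweep_dot_sizes(tpm, sim$design, "c1", "c2")
  qualifying <- which(!is.na(sw$nonde_noise) & sw$nonde_noise >= baseline)
  picked <- if (length(qualifying) == 0) {
    expect_warning(p <- select_dot_size(sw, baseline), "largest")
    expect_equal(as.numeric(p), max(sw$dot_size))
    p
  } else {
    p <- select_dot_size(sw, baseline)
    expect_equal(as.numeric(p), sw$dot_size[qualifying[1]])
    p
  }
  expect_true(as.numeric(picked) %in% sw$dot_size)
})

test_that("overlay results tidy and glance cleanly", {
  sim <- generate_counts(synth_config(m = 100, n_de = 10, seed = 309))
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)
  ov <- overlay_de(tpm, sim$design, "c1", "c2", 0.004)
  td <- tidy(ov)
  expect_true(all(c("gene_id", "de") %in% names(td)))
  gl <- glance(ov)
  expect_equal(gl$de_count, sum(td$de))
  expect_equal(gl$dot_size, 0.004)
})
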