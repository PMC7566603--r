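test_that("lognormal MLE has its closed form", {
  v <- exp(0:2)  # log-values 0, 1, 2
  fit <- fit_family(v, "lognormal")
  expect_equal(fit$params[["meanlog"]], 1, tolerance = 1e-12)
  expect_equal(fit$params[["sdlog"]]^2, 2 / 3, tolerance = 1e-12)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
  expect_equal(fit$loglik, sum(dlnorm(v, 1, sqrt(2 / 3), log = TRUE)))
})

test_that("degenerate and invalid inputs are refused", {
  expect_error(fit_family(rep(3, 50), "weibull"), "zero-variance")
  expect_error(fit_family(c(-1, rlnorm(20)), "lognormal"), "positive")
  expect_error(fit_family(rlnorm(2), "lognormal"), "at least 3")
})

test_that("lognormal parameters are recovered from seeded draws", {
  set.seed(101)
  v <- rlnorm(5000, 2, 0.8)
  fit <- fit_family(v, "lognormal")
  expect_lt(abs(fit$params[["meanlog"]] - 2) / 2, 0.05)
  expect_lt(abs(fit$params[["sdlog"]] - 0.8) / 0.8, 0.05)
})

test_that("optimized fits agree with fitdistrplus", {
  set.seed(102)
  v <- rweibull(2000, shape = 1.4, scale = 30)
  fit <- fit_family(v, "weibull")
  ref <- fitdistrplus::fitdist(v, "weibull")
  expect_equal(unname(fit$params["shape"]), unname(ref$estimate["shape"]),
               tolerance = 1e-3)
  expect_equal(unname(fit$params["scale"]), unname(ref$estimate["scale"]),
               tolerance = 1e-3)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)

  set.seed(103)
  v2 <- rlnorm(2000, 1.5, 0.9)
  fit2 <- fit_family(v2, "lognormal")
  ref2 <- fitdistrplus::fitdist(v2, "lnorm")
  expect_equal(unname(fit2$params["meanlog"]),
               unname(ref2$estimate["meanlog"]), tolerance = 1e-3)
  expect_equal(fit2$aic, ref2$aic, tolerance = 1e-4)
})

test_that("AIC selection identifies the generating family", {
  set.seed(104)
  v <- rlnorm(2000, 0, 1)
  best <- select_best_family(v, c("lognormal", "weibull"))
  expect_equal(best$family, "lognormal")
  # verify the AIC ordering by recomputing both likelihoods directly
  fits <- attr(best, "all_fits")
  ll <- vapply(fits, function(f) {
    p <- f$params
    switch(f$family,
      lognormal = sum(dlnorm(v, p["meanlog"], p["sdlog"], log = TRUE)),
      weibull = sum(dweibull(v, p["shape"], p["scale"], log = TRUE)))
  }, numeric(1))
  aic <- 2 * vapply(fits, function(f) f$n_params, integer(1)) - 2 * ll
  expect_equal(vapply(fits, function(f) f$aic, numeric(1)), aic,
               tolerance = 1e-8)
  expect_equal(best$family,
               fits[[which.min(aic)]]$family)
})

test_that("family selection handles single candidates and failures", {
  set.seed(105)
  v <- rlnorm(200, 1, 0.5)
  expect_equal(select_best_family(v, "weibull")$family, "weibull")
  expect_error(select_best_family(rep(2, 100), c("lognormal", "weibull")),
               "all family fits failed")
})

test_that("Burr and log-logistic fits improve on their starting values", {
  set.seed(106)
  # log-logistic sample via inverse CDF: x = s * (u/(1-u))^(1/a)
  u <- runif(3000)
  v <- 20 * (u / (1 - u))^(1 / 2.5)
  fit <- fit_family(v, "loglogistic")
  expect_lt(abs(fit$params[["shape"]] - 2.5) / 2.5, 0.1)
  expect_lt(abs(fit$params[["scale"]] - 20) / 20, 0.1)
  # Burr nests the log-logistic (shape2 = 1): its ML fit cannot be worse
  burr <- fit_family(v, "burr")
  expect_gte(burr$loglik, fit$loglik - 1e-3)
})

test_that("lower-tail threshold is benign when the fit matches the data", {
  set.seed(107)
  v <- rlnorm(5000, 2, 0.8)
  fs <- lower_tail_threshold(v, fit_family(v, "lognormal"))
  expect_s3_class(fs, "scatterde_filter_spec")
  expect_gte(mean(v > fs$threshold), 0.99)
})

test_that("lower-tail threshold separates a low-expression spike", {
  set.seed(108)
  bulk_meanlog <- 2
  v <- c(rlnorm(4000, bulk_meanlog, 0.7), runif(800, 0.05, 0.8))
  fit <- fit_family(v, "lognormal")
  fs <- lower_tail_threshold(v, fit)
  # between the spike's central mass (< 0.8 TPM) and the bulk mode
  expect_gt(fs$threshold, 0.3)
  expect_lt(fs$threshold, exp(bulk_meanlog))

  # dense-grid scan oracle for the first sub-mode sign change
  y <- log10(v)
  emp <- density(y, bw = "nrd0")
  dfun <- fitted_density(fit)
  grid <- seq(min(y), max(y), length.out = 4096)
  gv <- dfun(10^grid) * 10^grid * log(10)
  ev <- approx(emp$x, emp$y, xout = grid, rule = 2)$y
  below_mode <- grid[seq_len(which.max(gv))]
  sgn <- sign(ev - gv)[seq_len(which.max(gv))]
  first_flip <- which(sgn[-1] != sgn[-length(sgn)])[1]
  oracle_t <- 10^below_mode[first_flip]
  expect_equal(log10(fs$threshold), log10(oracle_t), tolerance = 0.02)
})

test_that("threshold is density-based, not count-based", {
  set.seed(109)
  v <- c(rlnorm(3000, 2, 0.7), runif(600, 0.05, 0.8))
  t1 <- lower_tail_threshold(v, fit_family(v, "lognormal"))$threshold
  vv <- rep(v, 2)
  t2 <- lower_tail_threshold(vv, fit_family(vv, "lognormal"))$threshold
  expect_lt(abs(t2 - t1) / t1, 0.1)
})

test_that("threshold falls back to the minimum without a crossing", {
  set.seed(110)
  v <- rlnorm(100, 0, 0.3)
  # a fit centered far above the data: fitted density is ~0 on the data's
  # range, so the empirical density never crosses it from above
  far_fit <- fit_family(rlnorm(100, 10, 0.3), "lognormal")
  fs <- lower_tail_threshold(v, far_fit)
  expect_equal(fs$threshold, min(v))
  expect_error(lower_tail_threshold(rlnorm(20), far_fit), "at least 50")
})

test_that("filter rules behave as documented", {
  # g1 = (6, 6): above threshold everywhere; g2 = (0, 8): mean 4
  tpm <- expr_tbl(rbind(c(6, 6), c(0, 8)) |>
                    (\(m) {colnames(m) <- c("a", "b"); m})(),
                  gene_id = c("g1", "g2"))
  expect_equal(filter_low_expression(tpm, 5, "mean")$gene_id, "g1")
  expect_equal(filter_low_expression(tpm, 5, "any")$gene_id, c("g1", "g2"))
  expect_equal(filter_low_expression(tpm, 5, "all")$gene_id, "g1")
  expect_equal(filter_low_expression(tpm, 3, "mean")$gene_id, c("g1", "g2"))
  expect_error(filter_low_expression(tpm, 100, "mean"), "no genes pass")
})

test_that("filtering equals a brute-force scan and tiny thresholds are identity", {
  set.seed(111)
  m <- matrix(rlnorm(400, 1, 1.5), 100, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  tpm <- expr_tbl(m)
  for (rule in c("mean", "all", "any")) {
    kept <- filter_low_expression(tpm, 3, rule)$gene_id
    oracle <- tpm$gene_id[vapply(seq_len(nrow(m)), function(i) {
      switch(rule,
        mean = mean(m[i, ]) > 3,
        all = all(m[i, ] > 3),
        any = any(m[i, ] > 3))
    }, logical(1))]
    expect_equal(kept, oracle)
  }
  expect_equal(filter_low_expression(tpm, 1e-12, "mean")$gene_id,
               tpm$gene_id)
})

test_that("fit objects tidy and glance like models", {
  set.seed(112)
  fit <- fit_family(rlnorm(500, 1, 0.6), "lognormal")
  td <- tidy(fit)
  expect_equal(td$term, c("meanlog", "sdlog"))
  gl <- glance(fit)
  expect_equal(gl$family, "lognormal")
  expect_equal(gl$AIC, fit$aic)
})
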