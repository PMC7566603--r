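#' Maximum-likelihood fit of an expression-distribution family
#'
#' Fits one candidate family to transcriptome-wide (positive, linear-scale)
#' expression values by maximum likelihood. Lognormal and Pareto have
#' closed-form estimates; Weibull, log-logistic and Burr (type XII) are
#' optimized from method-of-moments starting values, so fits are
#' deterministic. The Pareto location is fixed at `min(values)` and only the
#' shape is free.
#'
#' @param values Positive numeric vector, length at least 10.
#' @param family One of `"lognormal"`, `"pareto"`, `"burr"`,
#'   `"loglogistic"`, `"weibull"`.
#' @return A `scatterde_fit` object: family, named parameter vector,
#'   log-likelihood, AIC (`2k - 2*loglik`), and the sample size. Has
#'   [tidy()] and [glance()] methods.
#' @export
fit_family <- function(values, family = c("lognormal", "pareto", "burr",
                                          "loglogistic", "weibull")) {
  family <- match.arg(family)
  values <- as.numeric(values)
  if (anyNA(values) || any(values <= 0)) {
    abort("values must all be positive", class = "scatterde_error_invalid")
  }
  n <- length(values)
  if (n < 3L) {
    abort("need at least 3 values to fit", class = "scatterde_error_invalid")
  }
  if (max(values) == min(values)) {
    abort("zero-variance sample", class = "scatterde_error_invalid")
  }
  est <- switch(family,
    lognormal = fit_lognormal(values),
    pareto = fit_pareto(values),
    weibull = fit_optim(values, family),
    loglogistic = fit_optim(values, family),
    burr = fit_optim(values, family)
  )
  k <- n_free_params(family)
  structure(
    list(family = family, params = est$params, loglik = est$loglik,
         aic = 2 * k - 2 * est$loglik, n_params = k, n = n),
    class = "scatterde_fit"
  )
}

n_free_params <- function(family) {
  switch(family, lognormal = 2L, weibull = 2L, loglogistic = 2L,
         burr = 3L, pareto = 1L)
}

fit_lognormal <- function(x) {
  lx <- log(x)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))  # ML variance, not the n-1 version
  list(params = c(meanlog = mu, sdlog = sigma),
       loglik = sum(dlnorm(x, mu, sigma, log = TRUE)))
}

fit_pareto <- function(x) {
  xm <- min(x)
  shape <- length(x) / sum(log(x / xm))
  ll <- length(x) * log(shape) + length(x) * shape * log(xm) -
    (shape + 1) * sum(log(x))
  list(params = c(shape = shape, min = xm), loglik = ll)
}

# log-densities on positive support, parameterized on the log scale so the
# optimizer is unconstrained
log_density <- function(family, x, par) {
  switch(family,
    weibull = dweibull(x, shape = par[1], scale = par[2], log = TRUE),
    loglogistic = {
      a <- par[1]; s <- par[2]
      log(a) - log(s) + (a - 1) * (log(x) - log(s)) -
        2 * log1p((x / s)^a)
    },
    burr = {
      cc <- par[1]; k <- par[2]; s <- par[3]
      log(cc) + log(k) - log(s) + (cc - 1) * (log(x) - log(s)) -
        (k + 1) * log1p((x / s)^cc)
    }
  )
}

mom_start <- function(family, x) {
  switch(family,
    weibull = {
      cv <- sd(x) / mean(x)
      shape <- cv^(-1.086)  # Justus approximation
      c(shape, mean(x) / gamma(1 + 1 / shape))
    },
    loglogistic = {
      a <- pi / (sqrt(3) * sd(log(x)))  # logistic sd of log x = pi/(a*sqrt(3))
      c(a, stats::median(x))
    },
    burr = {
      st <- mom_start("loglogistic", x)  # Burr with shape2 = 1
      c(st[1], 1, st[2])
    }
  )
}

fit_optim <- function(x, family) {
  start <- mom_start(family, x)
  nll <- function(lpar) {
    val <- suppressWarnings(-sum(log_density(family, x, exp(lpar))))
    if (!is.finite(val)) 1e10 else val
  }
  opt <- optim(log(start), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  par <- exp(opt$par)
  names(par) <- switch(family,
    weibull = c("shape", "scale"),
    loglogistic = c("shape", "scale"),
    burr = c("shape1", "shape2", "scale")
  )
  list(params = par, loglik = -opt$value)
}

#' Density function of a fitted family
#'
#' @param fit A `scatterde_fit` object.
#' @return A function of `x` evaluating the fitted density on linear scale.
#' @export
fitted_density <- function(fit) {
  p <- fit$params
  switch(fit$family,
    lognormal = function(x) dlnorm(x, p[["meanlog"]], p[["sdlog"]]),
    weibull = function(x) dweibull(x, p[["shape"]], p[["scale"]]),
    loglogistic = function(x) {
      out <- exp(log_density("loglogistic", x, c(p[["shape"]], p[["scale"]])))
      ifelse(x > 0, out, 0)
    },
    burr = function(x) {
      out <- exp(log_density("burr", x,
                             c(p[["shape1"]], p[["shape2"]], p[["scale"]])))
      ifelse(x > 0, out, 0)
    },
    pareto = function(x) {
      ifelse(x >= p[["min"]],
             p[["shape"]] * p[["min"]]^p[["shape"]] / x^(p[["shape"]] + 1), 0)
    }
  )
}

#' @exportS3Method
tidy.scatterde_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @exportS3Method
glance.scatterde_fit <- function(x, ...) {
  tibble(family = x$family, logLik = x$loglik, AIC = x$aic,
         n_params = x$n_params, nobs = x$n)
}

#' @export
print.scatterde_fit <- function(x, ...) {
  cat("<scatterde_fit> ", x$family, " (n = ", x$n, ")\n", sep = "")
  cat("  ", paste(names(x$params), signif(x$params, 5), sep = " = ",
                  collapse = ", "), "\n", sep = "")
  cat("  logLik = ", signif(x$loglik, 7), ", AIC = ", signif(x$aic, 7),
      "\n", sep = "")
  invisible(x)
}

#' Select the best-fitting family by AIC
#'
#' Fits every candidate family and returns the one with the smallest AIC.
#' AIC ties are broken toward fewer free parameters, then alphabetically by
#' family name.
#'
#' @param values Positive numeric vector.
#' @param families Character vector of candidate family names.
#' @return The winning `scatterde_fit`, carrying all per-family fits in
#'   attribute `"all_fits"`.
#' @export
select_best_family <- function(values,
                               families = c("lognormal", "pareto", "burr",
                                            "loglogistic", "weibull")) {
  if (length(families) < 1L) {
    abort("need at least one candidate family",
          class = "scatterde_error_invalid")
  }
  fits <- list()
  errors <- character()
  for (f in families) {
    res <- tryCatch(fit_family(values, f), error = function(e) e)
    if (inherits(res, "error")) {
      errors[f] <- conditionMessage(res)
    } else {
      fits[[length(fits) + 1L]] <- res
    }
  }
  if (length(fits) == 0L) {
    abort(paste0("all family fits failed: ",
                 paste(names(errors), errors, sep = ": ", collapse = "; ")),
          class = "scatterde_error_fit")
  }
  aic <- map_dbl(fits, "aic")
  k <- map_dbl(fits, "n_params")
  fam <- vapply(fits, function(f) f$family, character(1))
  ord <- order(aic, k, fam)
  best <- fits[[ord[1]]]
  attr(best, "all_fits") <- fits
  best
}

#' Low-expression filter specification
#'
#' @param threshold Positive TPM cutoff.
#' @param rule Membership rule: `"mean"` keeps genes whose mean TPM across
#'   samples exceeds the threshold; `"all"`/`"any"` require all/any samples
#'   to exceed it.
#' @return A `scatterde_filter_spec` object.
#' @export
filter_spec <- function(threshold, rule = c("mean", "all", "any")) {
  rule <- match.arg(rule)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("threshold must be a positive number",
          class = "scatterde_error_invalid")
  }
  structure(list(threshold = threshold, rule = rule),
            class = "scatterde_filter_spec")
}

#' Lower-tail intersection threshold
#'
#' Derives a low-expression cutoff as the point, below the fitted
#' distribution's mode, where the empirical density of log10 expression
#' (Gaussian kernel, Silverman's rule-of-thumb bandwidth) first crosses the
#' fitted density. Low-expression technical noise shows up as an excess of
#' empirical density over the fitted bulk in the lower tail; the crossing
#' marks where that excess ends. When no crossing exists below the mode the
#' threshold falls back to `min(values)` (nothing is filtered).
#'
#' @param values Positive linear-scale expression values, length >= 50.
#' @param fit `scatterde_fit` obtained on these values.
#' @param rule Membership rule passed through to the returned spec.
#' @return A [filter_spec()] with the threshold in TPM units.
#' @export
lower_tail_threshold <- function(values, fit, rule = "mean") {
  values <- as.numeric(values)
  if (length(values) < 50L) {
    abort("need at least 50 values for a reliable density estimate",
          class = "scatterde_error_invalid")
  }
  if (any(values <= 0)) {
    abort("values must all be positive", class = "scatterde_error_invalid")
  }
  y <- log10(values)
  emp <- density(y, bw = "nrd0")  # Gaussian kernel, Silverman bandwidth
  dfun <- fitted_density(fit)
  # fitted density mapped to log10 space: g(y) = f(10^y) * 10^y * ln(10)
  g <- function(yy) dfun(10^yy) * 10^yy * log(10)
  grid <- seq(min(y), max(y), length.out = 1024L)
  gv <- g(grid)
  mode_idx <- which.max(gv)
  if (mode_idx > 1L) {
    sub <- seq_len(mode_idx)
    diff_v <- stats::approx(emp$x, emp$y, xout = grid[sub], rule = 2)$y -
      gv[sub]
    s <- sign(diff_v)
    crossing <- which(s[-length(s)] * s[-1] < 0 | s[-length(s)] == 0)
    if (length(crossing) > 0L) {
      i <- crossing[1]
      return(filter_spec(10^mean(grid[c(i, i + 1L)]), rule))
    }
  }
  filter_spec(min(values), rule)
}

#' Filter lowly expressed genes
#'
#' @param tpm Linear-scale expression tibble.
#' @param spec A [filter_spec()], or a bare positive number used as the
#'   threshold.
#' @param rule Membership rule when `spec` is a bare number.
#' @return The expression tibble restricted to genes passing the rule; the
#'   sample set is unchanged.
#' @export
filter_low_expression <- function(tpm, spec, rule = "mean") {
  if (expr_scale(tpm) != "linear") {
    abort("filtering operates on linear TPM values",
          class = "scatterde_error_invalid")
  }
  if (!inherits(spec, "scatterde_filter_spec")) spec <- filter_spec(spec, rule)
  m <- expr_matrix(tpm)
  keep <- switch(spec$rule,
    mean = rowMeans(m) > spec$threshold,
    all = apply(m, 1, function(r) all(r > spec$threshold)),
    any = apply(m, 1, function(r) any(r > spec$threshold))
  )
  if (!any(keep)) {
    abort("no genes pass the low-expression filter",
          class = "scatterde_error_filter")
  }
  set_expr_scale(tpm[keep, , drop = FALSE], "linear")
}
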