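#' @exportS3Method
autoplot.scatterde_sweep <- function(object, baseline = NULL, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("de_noise", "nonde_noise"), names_to = "set",
                        values_to = "noise") |>
    mutate(set = ifelse(.data$set == "de_noise", "DE genes", "non-DE genes"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$dot_size,
                                          y = .data$noise,
                                          colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dot size (log10 TPM)",
                  y = "between-condition expression noise",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_hline(yintercept = baseline,
                                 linetype = "dashed", colour = "blue")
  }
  p
}

#' @exportS3Method
autoplot.scatterde_overlay <- function(object, combo = "r1_r1", ...) {
  if (is.null(object$scan)) {
    abort("overlay carries no scan geometry; build it with overlay_de()",
          class = "scatterde_error_invalid")
  }
  rep_pts <- bind_rows(object$scan$rep_clouds)
  cmb <- object$scan$combos[object$scan$combos$combo == combo, ]
  cmb$status <- ifelse(
    object$per_gene$de[match(cmb$gene_id, object$per_gene$gene_id)],
    "DE", "non-DE")
  ggplot2::ggplot() +
    ggplot2::geom_point(data = rep_pts,
                        ggplot2::aes(x = .data$u, y = .data$v),
                        colour = "grey70", size = 0.4) +
    ggplot2::geom_point(data = cmb,
                        ggplot2::aes(x = .data$u, y = .data$v,
                                     colour = .data$status), size = 0.4) +
    ggplot2::scale_colour_manual(values = c("DE" = "#1a9850",
                                            "non-DE" = "#e08214")) +
    ggplot2::labs(x = paste0("log10(TPM), ", object$scan$conditions[1]),
                  y = paste0("log10(TPM), ", object$scan$conditions[2]),
                  colour = NULL,
                  title = sprintf("dot size %.3f: %d DE genes",
                                  object$dot_size, object$de_count)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.scatterde_fit <- function(object, values = NULL, ...) {
  dfun <- fitted_density(object)
  p <- ggplot2::ggplot()
  if (!is.null(values)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble(x = log10(values)),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = 60, fill = "grey80")
    rng <- range(log10(values))
  } else {
    rng <- log10(c(1e-2, 1e4))
  }
  grid <- tibble(x = seq(rng[1], rng[2], length.out = 400))
  grid$y <- dfun(10^grid$x) * 10^grid$x * log(10)
  p + ggplot2::geom_line(data = grid,
                         ggplot2::aes(x = .data$x, y = .data$y),
                         colour = "firebrick") +
    ggplot2::labs(x = "log10(TPM)", y = "density",
                  title = paste0("fitted ", object$family)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.scatterde_traj <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               label = .data$time)) +
    ggplot2::geom_path(arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt"))) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)",
                  100 * ifelse(length(object$explained) > 1,
                               object$explained[2], 0))) +
    ggplot2::theme_minimal()
}
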