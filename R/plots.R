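# ggplot2 views of the main result types: the SE rank ("hockey stick")
# curve, Kaplan-Meier curves, the dose-response boxes, the saturation curve
# and PCA scores.

#' Plot the super-enhancer rank curve
#'
#' The classic hockey-stick view: regions ordered by ascending total signal,
#' super-enhancers above the tangency cutoff highlighted.
#'
#' @param object An `se_rank` from [rank_superenhancers()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.se_rank <- function(object, ...) {
  cutoff <- attr(object, "cutoff_signal")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$signal,
                                       color = .data$is_se)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                                name = "super-enhancer") +
    {if (is.finite(cutoff)) ggplot2::geom_hline(yintercept = cutoff,
                                                linetype = "dashed")} +
    ggplot2::labs(x = "rank (ascending signal)", y = "total signal",
                  title = "Super-enhancer rank curve") +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot (right-continuous step curve starting at S(0) = 1).
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble(time = c(0, object$time), survival = c(1, object$survival))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Compare Kaplan-Meier curves across groups
#'
#' @param records Survival records tibble (`time`, `event`, `group`).
#' @return A ggplot with one step curve per group.
#' @export
plot_km_groups <- function(records) {
  curves <- purrr::imap_dfr(split(records, records$group), function(rec, g) {
    km <- km_estimate(rec)
    tibble(group = g, time = c(0, km$time), survival = c(1, km$survival))
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Plot the enhancer dose-response
#'
#' Expression fold-change distributions of genes bucketed by their number of
#' altered linked enhancers.
#'
#' @param object A `dose_response` from [enhancer_dose_response()].
#' @param ... Unused.
#' @return A ggplot of per-bucket log2 fold-change boxes.
#' @export
autoplot.dose_response <- function(object, ...) {
  gd <- attr(object, "gene_doses")
  ggplot2::ggplot(gd, ggplot2::aes(x = .data$dose_bucket, y = log2(.data$fc))) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "altered linked enhancers", y = "log2 expression FC") +
    ggplot2::theme_minimal()
}

#' Plot an element-discovery saturation curve
#'
#' @param curve Output of [saturation_curve()].
#' @return A ggplot of mean cumulative distinct elements (+/- sd) vs samples.
#' @export
plot_saturation <- function(curve) {
  sat <- attr(curve, "saturation_k")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$mean_count)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_count - .data$sd_count,
                                      ymax = .data$mean_count + .data$sd_count),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    {if (!is.na(sat)) ggplot2::geom_vline(xintercept = sat, linetype = "dashed")} +
    ggplot2::labs(x = "samples", y = "distinct elements") +
    ggplot2::theme_minimal()
}

#' Plot PCA sample scores
#'
#' @param object An `epr_pca` from [pca_samples()].
#' @param sheet Optional sample sheet supplying tissue colors.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2 scores.
#' @export
autoplot.epr_pca <- function(object, sheet = NULL, ...) {
  df <- object$scores
  if (!is.null(sheet)) {
    df <- left_join(df, sheet %>% select("sample_id", "tissue"), by = "sample_id")
  }
  ve <- round(100 * object$var_explained[1:2], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.null(sheet)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$tissue))
  } else p + ggplot2::geom_point()
  p +
    ggplot2::labs(x = paste0("PC1 (", ve[1], "%)"),
                  y = paste0("PC2 (", ve[2], "%)")) +
    ggplot2::theme_minimal()
}
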