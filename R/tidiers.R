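# broom-style tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Kaplan-Meier curve
#'
#' @param x A `km_curve`.
#' @param ... Unused.
#' @return The step table: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `estimate`.
#' @export
tidy.km_curve <- function(x, ...) {
  tibble(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
         n_censor = x$n_censor, estimate = x$survival)
}

#' One-row summary of a Kaplan-Meier curve
#'
#' @param x A `km_curve`.
#' @param timepoint Survival readout timepoint in months (default 24).
#' @param ... Unused.
#' @return Tibble `n`, `events`, `median_survival`, `rate_at_timepoint`.
#' @export
glance.km_curve <- function(x, timepoint = 24, ...) {
  med <- x$time[which(x$survival <= 0.5)[1]]
  tibble(n = attr(x, "n"), events = sum(x$n_event),
         median_survival = ifelse(length(med) == 0, NA_real_, med),
         rate_at_timepoint = survival_at(x, timepoint))
}

#' Tidy a super-enhancer ranking
#'
#' @param x An `se_rank`.
#' @param ... Unused.
#' @return Tibble `se_id`, `rank`, `signal`, `is_se`.
#' @export
tidy.se_rank <- function(x, ...) {
  tibble(se_id = x$se_id, rank = x$rank, signal = x$signal, is_se = x$is_se)
}

#' One-row summary of a super-enhancer ranking
#'
#' @param x An `se_rank`.
#' @param ... Unused.
#' @return Tibble `n_regions`, `n_se`, `cutoff_signal`, `cutoff_rank`.
#' @export
glance.se_rank <- function(x, ...) {
  tibble(n_regions = nrow(x), n_se = sum(x$is_se),
         cutoff_signal = attr(x, "cutoff_signal"),
         cutoff_rank = attr(x, "cutoff_rank"))
}

#' Tidy PCA sample scores
#'
#' @param x An `epr_pca`.
#' @param ... Unused.
#' @return The sample-score tibble.
#' @export
tidy.epr_pca <- function(x, ...) x$scores

#' Variance summary of a PCA
#'
#' @param x An `epr_pca`.
#' @param ... Unused.
#' @return Tibble `component`, `var_explained`.
#' @export
glance.epr_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$var_explained)),
         var_explained = x$var_explained)
}

#' Tidy a dose-response summary
#'
#' @param x A `dose_response`.
#' @param ... Unused.
#' @return The pairwise Wilcoxon test table (`bucket_a`, `bucket_b`,
#'   `p_value`).
#' @export
tidy.dose_response <- function(x, ...) attr(x, "tests")

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
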