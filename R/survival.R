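# Kaplan-Meier estimation, fixed-timepoint survival rates, the two-group
# log-rank test, and median-split stratification of patients by gene
# expression. Estimation goes through the survival package; the wrappers add
# the package's degenerate-case rules and tidy output.

#' Kaplan-Meier curve for one group
#'
#' Product-limit estimator: censored subjects leave the risk set after their
#' time; the curve is a right-continuous step function starting at 1.
#'
#' @param records Tibble with `time` (months, >= 0) and `event` (logical or
#'   0/1; TRUE = death/progression).
#' @return An object of class `km_curve`: tibble `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (one row per distinct observed time),
#'   with attribute `n` (subjects).
#' @export
km_estimate <- function(records) {
  check_columns(records, c("time", "event"), "survival records")
  if (nrow(records) < 1) abort("need >= 1 record", class = "epr_data_error")
  if (any(records$time < 0)) abort("negative survival time", class = "epr_data_error")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = data.frame(time = records$time,
                                             event = as.integer(records$event)))
  out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                n_censor = fit$n.censor, survival = fit$surv)
  attr(out, "n") <- nrow(records)
  class(out) <- c("km_curve", class(out))
  out
}

#' Survival probability at a fixed timepoint
#'
#' Right-continuous step-function evaluation of a Kaplan-Meier curve: the
#' value after the last event time at or before `t` (1 before the first
#' event).
#'
#' @param curve A `km_curve`.
#' @param t Timepoint in months (default 24, a 2-year rate).
#' @return Survival probability in \[0, 1\].
#' @export
survival_at <- function(curve, t = 24) {
  if (t < 0) abort("t must be >= 0", class = "epr_config_error")
  idx <- which(curve$time <= t)
  if (length(idx) == 0) return(1)
  curve$survival[max(idx)]
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic (observed vs expected events summed over
#' distinct event times), chi-square with 1 df, two-sided p. With no events
#' at all, the statistic is 0 and p = 1 with a warning.
#'
#' @param records Tibble with `time`, `event`, `group` (exactly two levels).
#' @return One-row tibble `statistic`, `df`, `p_value`, `n_a`, `n_b`.
#' @export
logrank_test <- function(records) {
  check_columns(records, c("time", "event", "group"), "survival records")
  groups <- unique(records$group)
  if (length(groups) != 2) abort("need exactly two groups", class = "epr_data_error")
  n_a <- sum(records$group == groups[1])
  n_b <- sum(records$group == groups[2])
  if (n_a == 0 || n_b == 0) abort("both groups must be non-empty", class = "epr_data_error")
  if (sum(records$event) == 0) {
    warn("no events in either group; log-rank p set to 1")
    return(tibble(statistic = 0, df = 1L, p_value = 1, n_a = n_a, n_b = n_b))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = data.frame(time = records$time,
                                              event = as.integer(records$event),
                                              group = records$group))
  tibble(statistic = fit$chisq, df = 1L,
         p_value = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE),
         n_a = n_a, n_b = n_b)
}

#' Median split of samples by a gene's expression
#'
#' Samples strictly above the median are `high`, strictly below are `low`;
#' samples exactly at the median are assigned alternately (in sorted
#' sample_id order, starting with the currently smaller group) to balance
#' group sizes.
#'
#' @param tpm Expression tibble (`gene_id` + sample columns).
#' @param gene_id Gene to split on.
#' @param samples Optional subset of samples (e.g. those with survival
#'   records).
#' @return Tibble `sample_id`, `value`, `group`.
#' @export
median_split <- function(tpm, gene_id, samples = NULL) {
  m <- signal_to_matrix(tpm)
  if (!gene_id %in% rownames(m)) {
    abort(paste0("gene not found: ", gene_id), class = "epr_data_error")
  }
  v <- m[gene_id, ]
  if (!is.null(samples)) v <- v[intersect(samples, names(v))]
  if (length(v) < 2) abort("need >= 2 samples", class = "epr_data_error")
  med <- stats::median(v)
  if (all(v == v[1])) abort("no split possible: all-equal expression",
                            class = "epr_data_error")
  group <- ifelse(v > med, "high", ifelse(v < med, "low", NA))
  ties <- sort(names(v)[is.na(group)])
  for (s in ties) {
    n_low <- sum(group == "low", na.rm = TRUE)
    n_high <- sum(group == "high", na.rm = TRUE)
    group[s] <- if (n_low <= n_high) "low" else "high"
  }
  tibble(sample_id = names(v), value = unname(v), group = unname(group)) %>%
    arrange(.data$sample_id)
}
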