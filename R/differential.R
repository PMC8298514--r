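# Paired differential calling: per-patient fold-change/difference evidence,
# recurrence-thresholded gain/loss calls, paired-t validation with BH
# correction, and the six-group tissue-specificity classification.

#' Per-pair fold change and difference table
#'
#' For every element and complete patient pair of a comparison, computes the
#' pseudocounted fold change `(case + eps) / (ref + eps)` and the signed
#' difference `case - ref` of normalized signal.
#'
#' @param signal Quantile-normalized signal tibble.
#' @param pairs Pair table from [patient_pairs()].
#' @param comparison One of `"EC_vs_Nor"`, `"LNC_vs_Nor"`, `"LNC_vs_EC"`.
#' @param pseudocount Pseudocount eps added to both sides of the ratio
#'   (default 0.1 RPKM, small relative to the 0.5 absolute-difference guard).
#' @return Tibble `element_id`, `patient_id`, `fc`, `diff` (one row per
#'   element x pair).
#' @export
pairwise_change <- function(signal, pairs, comparison = "EC_vs_Nor",
                            pseudocount = 0.1) {
  comparison <- match.arg(comparison, COMPARISONS)
  if (!is_normalized(signal)) {
    warn("signal matrix is not flagged as quantile-normalized")
  }
  pairs <- pairs %>% filter(.data$comparison == !!comparison)
  if (nrow(pairs) == 0) abort("no complete pairs for this comparison",
                              class = "epr_data_error")
  m <- signal_to_matrix(signal)
  missing <- setdiff(c(pairs$case_sample, pairs$ref_sample), colnames(m))
  if (length(missing) > 0) {
    abort(paste0("pair references sample absent from matrix: ", missing[1]),
          class = "epr_data_error")
  }
  purrr::pmap_dfr(pairs[c("patient_id", "case_sample", "ref_sample")],
    function(patient_id, case_sample, ref_sample) {
      x <- m[, case_sample]; y <- m[, ref_sample]
      tibble(element_id = rownames(m), patient_id = patient_id,
             fc = (x + pseudocount) / (y + pseudocount), diff = x - y)
    })
}

#' Call recurrently gained and lost elements
#'
#' A patient pair casts a gain vote for an element when `fc >= fc_min` and
#' `diff >= diff_min`, and a loss vote when `fc <= 1/fc_min` and
#' `diff <= -diff_min`. An element is gained (lost) when its gain (loss)
#' votes reach `recurrence_min`; the pathological case of both is reported as
#' unaltered with `conflict = TRUE`.
#'
#' @param table Per-pair table from [pairwise_change()].
#' @param fc_min Fold-change threshold (default 2).
#' @param diff_min Absolute-difference threshold in RPKM (default 0.5).
#' @param recurrence_min Minimum number of supporting pairs (default 6, as in
#'   a 6-of-10 design).
#' @return Tibble `element_id`, `status` (gained/lost/unaltered),
#'   `gain_votes`, `loss_votes`, `recurrence_count`, `mean_fc`, `mean_diff`,
#'   `conflict`.
#' @export
call_differential <- function(table, fc_min = 2, diff_min = 0.5,
                              recurrence_min = 6) {
  if (fc_min <= 0 || diff_min <= 0) {
    abort("thresholds must be positive", class = "epr_config_error")
  }
  n_pairs <- length(unique(table$patient_id))
  if (recurrence_min > n_pairs) {
    abort("recurrence_min exceeds the number of pairs", class = "epr_config_error")
  }
  table %>%
    group_by(.data$element_id) %>%
    summarise(
      gain_votes = sum(.data$fc >= fc_min & .data$diff >= diff_min),
      loss_votes = sum(.data$fc <= 1 / fc_min & .data$diff <= -diff_min),
      mean_fc = mean(.data$fc),
      mean_diff = mean(.data$diff),
      .groups = "drop"
    ) %>%
    mutate(
      conflict = .data$gain_votes >= recurrence_min & .data$loss_votes >= recurrence_min,
      status = case_when(
        .data$conflict ~ "unaltered",
        .data$gain_votes >= recurrence_min ~ "gained",
        .data$loss_votes >= recurrence_min ~ "lost",
        TRUE ~ "unaltered"
      ),
      recurrence_count = case_when(
        .data$status == "gained" ~ .data$gain_votes,
        .data$status == "lost" ~ .data$loss_votes,
        TRUE ~ pmax(.data$gain_votes, .data$loss_votes)
      )
    ) %>%
    select("element_id", "status", "gain_votes", "loss_votes",
           "recurrence_count", "mean_fc", "mean_diff", "conflict")
}

#' Paired-t validation of differential calls
#'
#' For every called (non-unaltered) element, a two-sided paired t-test on the
#' per-pair signal differences, Benjamini-Hochberg-adjusted across all called
#' elements of the comparison. Zero-variance differences are degenerate: p is
#' 0 when the mean difference is nonzero and 1 otherwise.
#'
#' @param signal Normalized signal tibble.
#' @param pairs Pair table filtered or filterable to one comparison.
#' @param calls Output of [call_differential()].
#' @param comparison Comparison to test.
#' @param q_max Significance cut used for the reported passing fraction
#'   (default 0.1).
#' @return Tibble `element_id`, `status`, `p_value`, `q_value` with attribute
#'   `fraction_significant` (share of called elements with q < `q_max`).
#' @export
paired_significance <- function(signal, pairs, calls, comparison = "EC_vs_Nor",
                                q_max = 0.1) {
  comparison <- match.arg(comparison, COMPARISONS)
  pairs <- pairs %>% filter(.data$comparison == !!comparison)
  if (nrow(pairs) < 2) abort("need >= 2 pairs", class = "epr_data_error")
  m <- signal_to_matrix(signal)
  called <- calls %>% filter(.data$status != "unaltered")
  if (nrow(called) == 0) {
    out <- tibble(element_id = character(), status = character(),
                  p_value = numeric(), q_value = numeric())
    attr(out, "fraction_significant") <- NA_real_
    return(out)
  }
  diffs <- m[called$element_id, pairs$case_sample, drop = FALSE] -
    m[called$element_id, pairs$ref_sample, drop = FALSE]
  p <- vapply(seq_len(nrow(diffs)), function(i) {
    d <- diffs[i, ]
    if (stats::sd(d) == 0) {
      if (mean(d) != 0) 0 else 1
    } else {
      stats::t.test(d)$p.value
    }
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  out <- tibble(element_id = called$element_id, status = called$status,
                p_value = p, q_value = q)
  attr(out, "fraction_significant") <- mean(q < q_max)
  out
}

#' Six-group tissue-specificity classification of enhancers
#'
#' Combines the EC-vs-Nor and LNC-vs-Nor calls: G1 EC-specific gain, G2
#' LNC-specific gain, G3 common gain, G4 EC-specific loss, G5 LNC-specific
#' loss, G6 common loss. An element gained in one comparison and lost in the
#' other is `discordant`; elements altered in neither are `none`.
#'
#' @param calls_ec Calls for EC_vs_Nor ([call_differential()] output).
#' @param calls_lnc Calls for LNC_vs_Nor over the same catalog.
#' @return Tibble `element_id`, `status_ec`, `status_lnc`, `group`.
#' @export
assign_groups <- function(calls_ec, calls_lnc) {
  if (!setequal(calls_ec$element_id, calls_lnc$element_id)) {
    abort("call sets cover different element catalogs", class = "epr_data_error")
  }
  inner_join(calls_ec %>% select("element_id", status_ec = "status"),
             calls_lnc %>% select("element_id", status_lnc = "status"),
             by = "element_id") %>%
    mutate(group = case_when(
      .data$status_ec == "gained" & .data$status_lnc == "unaltered" ~ "G1",
      .data$status_ec == "unaltered" & .data$status_lnc == "gained" ~ "G2",
      .data$status_ec == "gained" & .data$status_lnc == "gained" ~ "G3",
      .data$status_ec == "lost" & .data$status_lnc == "unaltered" ~ "G4",
      .data$status_ec == "unaltered" & .data$status_lnc == "lost" ~ "G5",
      .data$status_ec == "lost" & .data$status_lnc == "lost" ~ "G6",
      .data$status_ec != "unaltered" & .data$status_lnc != "unaltered" ~ "discordant",
      TRUE ~ "none"
    )) %>%
    arrange(.data$element_id)
}
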