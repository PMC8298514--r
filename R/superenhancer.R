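# Super-enhancer identification and differential calling: stitching nearby
# enhancers, ranking stitched regions by total signal with the slope-1
# tangency cutoff of the scaled rank curve, and the two differential-SE
# strategies (group-mean difference; paired recurrence) plus their
# combination.

#' Stitch enhancers into super-enhancer candidate regions
#'
#' Consecutive enhancers on a chromosome whose gap (`next start - previous
#' end`) is at most `stitch_distance` are merged transitively; the stitched
#' span runs from the smallest start to the largest end.
#'
#' @param enhancers Element tibble (`chrom`, `start`, `end`, `element_id`).
#' @param stitch_distance Maximum gap in bp (default 12500, the conventional
#'   stitching window).
#' @return Tibble `se_id`, `chrom`, `start`, `end`, `n_constituents`,
#'   `constituents` (list-column of element ids), sorted by (chrom, start).
#' @export
stitch_enhancers <- function(enhancers, stitch_distance = 12500) {
  if (stitch_distance < 0) abort("stitch_distance must be >= 0", class = "epr_config_error")
  if (nrow(enhancers) == 0) {
    return(tibble(se_id = character(), chrom = character(), start = integer(),
                  end = integer(), n_constituents = integer(),
                  constituents = list()))
  }
  check_columns(enhancers, c("chrom", "start", "end", "element_id"), "enhancer table")
  gr <- GenomicRanges::GRanges(enhancers$chrom,
                               IRanges::IRanges(enhancers$start + 1L, enhancers$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = stitch_distance + 1L,
                                  with.revmap = TRUE)
  revmap <- S4Vectors::mcols(merged)$revmap
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    constituents = lapply(revmap, function(i) sort(enhancers$element_id[i]))
  ) %>%
    mutate(n_constituents = lengths(.data$constituents)) %>%
    arrange(.data$chrom, .data$start, .data$end) %>%
    mutate(se_id = sprintf("se_%05d", dplyr::row_number())) %>%
    select("se_id", "chrom", "start", "end", "n_constituents", "constituents")
  out
}

#' Total signal of stitched regions per sample
#'
#' Total region signal approximated as the length-weighted sum over
#' constituent elements of input-subtracted RPKM x element length / 1000.
#'
#' @param stitched Output of [stitch_enhancers()].
#' @param elements Element tibble supplying constituent coordinates.
#' @param signal Signal tibble over the constituent elements.
#' @return Tibble `se_id` + one numeric column per sample.
#' @export
se_signal <- function(stitched, elements, signal) {
  m <- signal_to_matrix(signal)
  len_kb <- stats::setNames((elements$end - elements$start) / 1000,
                            elements$element_id)
  vals <- t(vapply(stitched$constituents, function(ids) {
    colSums(m[ids, , drop = FALSE] * len_kb[ids])
  }, numeric(ncol(m))))
  if (ncol(m) == 1) vals <- matrix(vals, ncol = 1, dimnames = list(NULL, colnames(m)))
  rownames(vals) <- stitched$se_id
  matrix_to_signal(vals, id_col = "se_id", normalized = is_normalized(signal))
}

#' Rank stitched regions and call super-enhancers by the tangency cutoff
#'
#' Regions are sorted by ascending signal and both axes scaled to \[0, 1\];
#' the cutoff is the tangency point of the slope-1 support line (the rank
#' minimizing scaled signal minus scaled rank, ties resolved toward the
#' higher rank). Regions with signal strictly above the cutoff signal are
#' flagged as super-enhancers.
#'
#' @param regions Tibble with `se_id` (or first column as id) and a `signal`
#'   column, or a named numeric vector.
#' @return An object of class `se_rank`: tibble `se_id`, `signal`, `rank`
#'   (ascending), `is_se`, with attributes `cutoff_signal` and `cutoff_rank`.
#'   Fewer than 3 regions, or all-equal signal, yield zero super-enhancers
#'   (with a warning in the former case).
#' @export
rank_superenhancers <- function(regions) {
  if (is.numeric(regions)) {
    regions <- tibble(se_id = names(regions) %||% as.character(seq_along(regions)),
                      signal = unname(regions))
  }
  if (!"signal" %in% names(regions)) {
    abort("regions need a 'signal' column", class = "epr_config_error")
  }
  sig <- regions$signal
  if (any(!is.finite(sig)) || any(sig < 0)) {
    abort("signals must be finite and >= 0", class = "epr_data_error")
  }
  ord <- order(sig)
  out <- tibble(se_id = regions$se_id[ord], signal = sig[ord],
                rank = seq_along(sig))
  n <- nrow(out)
  cutoff_rank <- NA_integer_; cutoff_signal <- Inf
  if (n < 3) {
    if (n > 0) warn("fewer than 3 regions; all flagged non-SE")
    out$is_se <- FALSE
  } else if (max(out$signal) == min(out$signal)) {
    out$is_se <- FALSE
  } else {
    x <- (out$rank - 1) / (n - 1)
    y <- (out$signal - out$signal[1]) / (out$signal[n] - out$signal[1])
    d <- y - x
    cutoff_rank <- max(which(d == min(d)))
    cutoff_signal <- out$signal[cutoff_rank]
    out$is_se <- out$signal > cutoff_signal
  }
  attr(out, "cutoff_rank") <- cutoff_rank
  attr(out, "cutoff_signal") <- cutoff_signal
  class(out) <- c("se_rank", class(out))
  out
}

#' Differential super-enhancers by group-mean difference
#'
#' Per SE, the difference of group means (case minus reference); gained when
#' the difference exceeds `gain_diff`, lost when below `loss_diff`. Output is
#' ranked by difference, descending.
#'
#' @param se_sig SE signal tibble from [se_signal()].
#' @param sheet Sample sheet.
#' @param comparison Comparison to evaluate.
#' @param gain_diff,loss_diff Mean-difference thresholds (defaults +2 / -2).
#' @return Tibble `se_id`, `mean_case`, `mean_ref`, `diff`, `status`.
#' @export
differential_se_mean <- function(se_sig, sheet, comparison = "EC_vs_Nor",
                                 gain_diff = 2, loss_diff = -2) {
  comparison <- match.arg(comparison, COMPARISONS)
  tis <- comparison_tissues(comparison)
  m <- signal_to_matrix(se_sig)
  case_samples <- sheet$sample_id[sheet$tissue == tis[["case"]]]
  ref_samples <- sheet$sample_id[sheet$tissue == tis[["ref"]]]
  case_samples <- intersect(case_samples, colnames(m))
  ref_samples <- intersect(ref_samples, colnames(m))
  if (length(case_samples) == 0 || length(ref_samples) == 0) {
    abort("empty group for comparison", class = "epr_data_error")
  }
  tibble(
    se_id = rownames(m),
    mean_case = rowMeans(m[, case_samples, drop = FALSE]),
    mean_ref = rowMeans(m[, ref_samples, drop = FALSE])
  ) %>%
    mutate(diff = .data$mean_case - .data$mean_ref,
           status = case_when(.data$diff > gain_diff ~ "gained",
                              .data$diff < loss_diff ~ "lost",
                              TRUE ~ "unaltered")) %>%
    arrange(desc(.data$diff))
}

#' Differential super-enhancers by paired recurrence
#'
#' Per patient pair, the pseudocounted fold change of SE signal; a gain vote
#' when `fc >= fc_gain`, a loss vote when `fc <= fc_loss`; status by
#' `recurrence_min` votes. Output is ranked by group-level fold change
#' (pseudocounted ratio of group means), descending.
#'
#' @param se_sig SE signal tibble.
#' @param pairs Pair table from [patient_pairs()].
#' @param comparison Comparison to evaluate.
#' @param recurrence_min Minimum supporting pairs (default 5, as in 5-of-10
#'   or 5-of-8 designs).
#' @param fc_gain,fc_loss Fold-change thresholds (defaults 2 and 0.7; the
#'   loss cut is looser because losses are rarer).
#' @param pseudocount Shared pseudocount (default 0.1).
#' @return Tibble `se_id`, `fc`, `gain_votes`, `loss_votes`, `status`.
#' @export
differential_se_paired <- function(se_sig, pairs, comparison = "EC_vs_Nor",
                                   recurrence_min = 5, fc_gain = 2,
                                   fc_loss = 0.7, pseudocount = 0.1) {
  comparison <- match.arg(comparison, COMPARISONS)
  pairs <- pairs %>% filter(.data$comparison == !!comparison)
  if (nrow(pairs) == 0) abort("no complete pairs for this comparison",
                              class = "epr_data_error")
  if (recurrence_min > nrow(pairs)) {
    abort("recurrence_min exceeds the number of pairs", class = "epr_config_error")
  }
  m <- signal_to_matrix(se_sig)
  fc_pair <- sapply(seq_len(nrow(pairs)), function(i) {
    (m[, pairs$case_sample[i]] + pseudocount) /
      (m[, pairs$ref_sample[i]] + pseudocount)
  })
  fc_pair <- matrix(fc_pair, nrow = nrow(m))
  gain_votes <- rowSums(fc_pair >= fc_gain)
  loss_votes <- rowSums(fc_pair <= fc_loss)
  group_fc <- (rowMeans(m[, pairs$case_sample, drop = FALSE]) + pseudocount) /
    (rowMeans(m[, pairs$ref_sample, drop = FALSE]) + pseudocount)
  tibble(se_id = rownames(m), fc = group_fc,
         gain_votes = gain_votes, loss_votes = loss_votes) %>%
    mutate(status = case_when(
      .data$gain_votes >= recurrence_min & .data$loss_votes >= recurrence_min ~ "unaltered",
      .data$gain_votes >= recurrence_min ~ "gained",
      .data$loss_votes >= recurrence_min ~ "lost",
      TRUE ~ "unaltered")) %>%
    arrange(desc(.data$fc))
}

#' Combine the two differential-SE strategies
#'
#' Combined status is gained (lost) when either strategy says so; conflicting
#' strategies yield unaltered with a conflict flag. High confidence requires
#' both strategies to agree on a non-unaltered status and the SE to pass both
#' the fold-change and the absolute-difference thresholds in that direction.
#'
#' @param mean_calls Output of [differential_se_mean()].
#' @param paired_calls Output of [differential_se_paired()] over the same SE
#'   catalog.
#' @param fc_gain,fc_loss,gain_diff,loss_diff High-confidence thresholds
#'   (defaults 2, 0.7, +2, -2).
#' @return Tibble `se_id`, `mean_status`, `paired_status`, `combined_status`,
#'   `fc`, `abs_diff`, `conflict`, `high_confidence`, ranked by fold change.
#' @export
combine_se_calls <- function(mean_calls, paired_calls, fc_gain = 2,
                             fc_loss = 0.7, gain_diff = 2, loss_diff = -2) {
  if (!setequal(mean_calls$se_id, paired_calls$se_id)) {
    abort("strategy call sets cover different SE catalogs", class = "epr_data_error")
  }
  inner_join(mean_calls %>% select("se_id", mean_status = "status", abs_diff = "diff"),
             paired_calls %>% select("se_id", paired_status = "status", "fc"),
             by = "se_id") %>%
    mutate(
      conflict = (.data$mean_status == "gained" & .data$paired_status == "lost") |
        (.data$mean_status == "lost" & .data$paired_status == "gained"),
      combined_status = case_when(
        .data$conflict ~ "unaltered",
        .data$mean_status == "gained" | .data$paired_status == "gained" ~ "gained",
        .data$mean_status == "lost" | .data$paired_status == "lost" ~ "lost",
        TRUE ~ "unaltered"),
      high_confidence = !.data$conflict &
        .data$mean_status == .data$paired_status &
        ((.data$combined_status == "gained" & .data$fc > fc_gain &
            .data$abs_diff > gain_diff) |
           (.data$combined_status == "lost" & .data$fc < fc_loss &
              .data$abs_diff < loss_diff))
    ) %>%
    arrange(desc(.data$fc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
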