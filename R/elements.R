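# Consensus element catalog: merging per-sample peak calls, promoter/enhancer
# classification by TSS proximity, input-subtracted RPKM scoring, quantile
# normalization, saturation curves and row z-scoring.

#' Merge per-sample peaks into a consensus catalog
#'
#' Intervals sharing at least one base are merged transitively into maximal
#' nonoverlapping intervals per chromosome (book-ended half-open intervals do
#' not merge). Each consensus interval records how many samples contributed at
#' least one overlapping peak.
#'
#' @param peak_sets Named list of peak tibbles (`chrom`, `start`, `end`), one
#'   per sample, or a single tibble for one sample.
#' @return Tibble `chrom`, `start`, `end`, `element_id`, `n_samples`, sorted
#'   by (chrom, start, end).
#' @export
merge_peaks <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(sample1 = peak_sets)
  peak_sets <- purrr::keep(peak_sets, ~ nrow(.x) > 0)
  if (length(peak_sets) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  element_id = character(), n_samples = integer()))
  }
  if (is.null(names(peak_sets))) names(peak_sets) <- paste0("sample", seq_along(peak_sets))
  all_peaks <- purrr::imap_dfr(peak_sets, ~ mutate(.x[c("chrom", "start", "end")],
                                                   .sample = .y))
  gr <- GenomicRanges::GRanges(all_peaks$chrom,
                               IRanges::IRanges(all_peaks$start + 1L, all_peaks$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  n_samples <- tapply(all_peaks$.sample[S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits),
                      function(s) length(unique(s)))
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    n_samples = as.integer(n_samples[as.character(seq_along(merged))])
  ) %>%
    arrange(.data$chrom, .data$start, .data$end) %>%
    mutate(element_id = sprintf("el_%06d", dplyr::row_number()), .before = "n_samples")
  out
}

# Distance from a half-open interval [start, end) to a single-bp TSS:
# 0 when the TSS falls on a covered base, otherwise the distance from the
# closest covered base.
interval_tss_distance <- function(start, end, tss) {
  ifelse(tss >= start & tss <= end - 1L, 0L,
         pmin(abs(start - tss), abs(end - 1L - tss)))
}

#' Classify consensus elements as promoter elements or enhancers
#'
#' A promoter element lies completely within `window` bp of some TSS; an
#' enhancer has every base more than `window` bp from every TSS; anything
#' straddling the window edge is `ambiguous` (excluded from both downstream
#' sets by default; set `ambiguous_as_promoter = TRUE` to fold them into
#' promoter elements).
#'
#' @param elements Consensus tibble (`chrom`, `start`, `end`, `element_id`).
#' @param tss TSS tibble from [read_tss()].
#' @param window Half-width of the promoter window in bp (default 2000).
#' @param ambiguous_as_promoter Reassign window-straddling elements to
#'   `promoter_element`.
#' @return `elements` with `element_class` and `nearest_tss_distance` added.
#' @export
classify_elements <- function(elements, tss, window = 2000,
                              ambiguous_as_promoter = FALSE) {
  if (window <= 0) abort("window must be positive", class = "epr_config_error")
  if (nrow(tss) == 0) abort("TSS set is empty", class = "epr_config_error")
  check_columns(elements, c("chrom", "start", "end", "element_id"), "element table")
  res <- elements
  res$nearest_tss_distance <- NA_integer_
  res$element_class <- NA_character_
  for (ch in unique(res$chrom)) {
    idx <- which(res$chrom == ch)
    pos <- sort(tss$tss[tss$chrom == ch])
    if (length(pos) == 0) {
      # no TSS on this chromosome: everything is distal
      res$nearest_tss_distance[idx] <- NA_integer_
      res$element_class[idx] <- "enhancer"
      next
    }
    s <- res$start[idx]; e <- res$end[idx]
    # nearest distance via the sorted-position neighbors of both boundaries
    nearest <- vapply(seq_along(idx), function(k) {
      i <- findInterval(c(s[k], e[k] - 1L), pos)
      cand <- unique(pmax(1L, pmin(length(pos), c(i, i + 1L))))
      covered <- any(pos >= s[k] & pos <= e[k] - 1L)
      if (covered) return(0L)
      as.integer(min(interval_tss_distance(s[k], e[k], pos[cand])))
    }, integer(1))
    # promoter: some TSS in [e - 1 - window, s + window]
    is_prom <- vapply(seq_along(idx), function(k) {
      lo <- e[k] - 1L - window; hi <- s[k] + window
      if (lo > hi) return(FALSE)
      i <- findInterval(hi, pos)
      i >= 1 && pos[i] >= lo
    }, logical(1))
    cls <- ifelse(is_prom, "promoter_element",
                  ifelse(nearest > window, "enhancer", "ambiguous"))
    res$nearest_tss_distance[idx] <- nearest
    res$element_class[idx] <- cls
  }
  if (ambiguous_as_promoter) {
    res$element_class[res$element_class == "ambiguous"] <- "promoter_element"
  }
  res
}

#' Input-subtracted RPKM signal matrix
#'
#' RPKM = reads x 1e9 / (region length in bp x mapped library size). The
#' returned value per region and sample is `max(0, RPKM_chip - RPKM_input)`:
#' regions where the matched input exceeds the ChIP signal floor at zero.
#'
#' @param region_counts Tibble or matrix of ChIP read counts (regions x
#'   samples); first column may be `element_id`.
#' @param region_lengths Region lengths in bp (recycled along rows).
#' @param library_sizes Named (or positionally matched) mapped-read totals per
#'   sample.
#' @param input_counts,input_library_sizes Matched input library, same shapes;
#'   `NULL` for no input subtraction.
#' @return Signal tibble (`element_id` + one column per sample) with
#'   attribute `normalized = FALSE`.
#' @export
rpkm_signal <- function(region_counts, region_lengths, library_sizes,
                        input_counts = NULL, input_library_sizes = NULL) {
  m <- if (is.data.frame(region_counts)) signal_to_matrix(region_counts) else {
    storage.mode(region_counts) <- "double"; region_counts
  }
  if (any(m < 0)) abort("negative read counts", class = "epr_data_error")
  if (any(region_lengths <= 0)) abort("region lengths must be positive", class = "epr_data_error")
  if (any(library_sizes <= 0)) abort("library sizes must be positive", class = "epr_data_error")
  rpkm <- function(counts, lens, libs) {
    sweep(counts * 1e9 / lens, 2, libs, `/`)
  }
  chip <- rpkm(m, region_lengths, library_sizes)
  if (!is.null(input_counts)) {
    mi <- if (is.data.frame(input_counts)) signal_to_matrix(input_counts) else {
      storage.mode(input_counts) <- "double"; input_counts
    }
    if (any(mi < 0)) abort("negative input counts", class = "epr_data_error")
    if (!all(dim(mi) == dim(m))) abort("input counts shape mismatch", class = "epr_data_error")
    chip <- chip - rpkm(mi, region_lengths, input_library_sizes)
  }
  matrix_to_signal(pmax(chip, 0), normalized = FALSE)
}

#' Quantile-normalize a signal matrix
#'
#' Classic quantile normalization: the reference distribution is the row-wise
#' mean of each column's sorted values; each column's values are replaced by
#' the reference values at their within-column ranks, averaging reference
#' values across tied ranks. After normalization every column carries the same
#' multiset of values.
#'
#' @param signal Signal tibble (id column + sample columns).
#' @return Normalized signal tibble (attribute `normalized = TRUE`). A
#'   single-column matrix is returned unchanged with a warning.
#' @export
quantile_normalize <- function(signal) {
  id_col <- names(signal)[1]
  m <- signal_to_matrix(signal, id_col)
  if (ncol(m) < 2) {
    warn("quantile normalization needs >= 2 columns; returning input unchanged")
    return(signal)
  }
  if (anyNA(m)) abort("missing values in signal matrix", class = "epr_data_error")
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    v <- numeric(length(col))
    v[order(col)] <- ref
    # average the reference over tied value spans
    stats::ave(v, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(m)
  matrix_to_signal(out, id_col = id_col, normalized = TRUE)
}

#' Element-discovery saturation curve
#'
#' For random orderings of the samples, counts the cumulative number of
#' distinct elements after the first k samples; reports the mean and sd over
#' permutations. The saturation point is the smallest k whose mean increment
#' to k+1 falls below `stability_threshold` of the running total.
#'
#' @param sample_sets Named list of character vectors of element ids, one per
#'   sample.
#' @param n_permutations Number of random orderings (default 100).
#' @param seed RNG seed.
#' @param stability_threshold Marginal-gain fraction defining stability
#'   (default 0.01).
#' @return Tibble `k`, `mean_count`, `sd_count` with attribute
#'   `saturation_k` (`NA` if never saturating within n - 1).
#' @export
saturation_curve <- function(sample_sets, n_permutations = 100, seed = 1,
                             stability_threshold = 0.01) {
  if (length(sample_sets) == 0) abort("need >= 1 sample set", class = "epr_config_error")
  if (n_permutations < 1) abort("n_permutations must be >= 1", class = "epr_config_error")
  n <- length(sample_sets)
  counts <- with_stream(seed, "misc", {
    vapply(seq_len(n_permutations), function(p) {
      ord <- sample.int(n)
      seen <- character(0)
      vapply(ord, function(i) {
        seen <<- union(seen, sample_sets[[i]])
        length(seen)
      }, numeric(1))
    }, numeric(n))
  })
  counts <- matrix(counts, nrow = n)
  out <- tibble(k = seq_len(n),
                mean_count = rowMeans(counts),
                sd_count = apply(counts, 1, stats::sd))
  sat <- NA_integer_
  if (n >= 2) {
    inc <- diff(out$mean_count)
    ok <- which(inc < stability_threshold * out$mean_count[-n])
    if (length(ok) > 0) sat <- ok[1]
  } else {
    sat <- 1L
  }
  attr(out, "saturation_k") <- sat
  out
}

#' Row-wise z-score transformation
#'
#' Each row is centered to mean 0 and scaled to sd 1 (sample sd, n - 1);
#' constant rows map to all zeros.
#'
#' @param tbl Signal or expression tibble (id column + sample columns).
#' @return Tibble of the same shape.
#' @export
zscore_rows <- function(tbl) {
  id_col <- names(tbl)[1]
  m <- signal_to_matrix(tbl, id_col)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  sdv[sdv == 0] <- Inf  # constant rows -> 0 after division
  out <- (m - mu) / sdv
  matrix_to_signal(out, id_col = id_col, normalized = is_normalized(tbl))
}
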