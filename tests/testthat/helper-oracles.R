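# Independent brute-force oracles. Each recomputes a quantity by a different
# route than the implementation (per-bp enumeration, step-up recursion,
# closed-form combinatorics, hand product-limit) so that agreement is
# evidence, not tautology.

# Per-basepair union of half-open intervals on one chromosome, on a doubled
# grid (odd cells are base centers, even cells boundaries) so that book-ended
# intervals, which share no base, stay separate.
oracle_merge_1chrom <- function(start, end, max_coord = 10000) {
  covered <- logical(2 * max_coord)
  for (i in seq_along(start)) covered[(2 * start[i] + 1):(2 * end[i] - 1)] <- TRUE
  r <- rle(covered)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = (lo[keep] - 1L) %/% 2L, end = (hi[keep] + 1L) %/% 2L)
}

# Benjamini-Hochberg step-up by direct recursion over the sorted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exhaustive tangency scan: for each candidate rank, test whether the slope-1
# line through it supports the whole scaled curve from below; among support
# points take the highest rank.
oracle_tangency <- function(signal) {
  n <- length(signal)
  s <- sort(signal)
  if (n < 3 || max(s) == min(s)) return(list(cutoff_rank = NA, is_se = rep(FALSE, n)))
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  support <- vapply(seq_len(n), function(i) {
    all(y - x >= (y[i] - x[i]) - 1e-12)
  }, logical(1))
  cr <- max(which(support))
  list(cutoff_rank = cr, cutoff_signal = s[cr], is_se_sorted = s > s[cr])
}

# Tie-corrected Spearman: Pearson product-moment formula applied to midranks,
# written out by hand.
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  da <- ra - mean(ra); db <- rb - mean(rb)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# All-pairs nearest-TSS scan with the lexicographic tie rule.
oracle_nearest <- function(elements, tss) {
  vapply(seq_len(nrow(elements)), function(i) {
    mid <- (elements$start[i] + elements$end[i]) / 2
    cand <- tss[tss$chrom == elements$chrom[i], ]
    if (nrow(cand) == 0) return(NA_character_)
    d <- abs(mid - cand$tss)
    hits <- cand$gene_id[d == min(d)]
    min(hits)
  }, character(1))
}

# Upper-tail hypergeometric by explicit pmf enumeration with choose().
oracle_hyper <- function(overlap, set_size, query_size, universe_size) {
  hi <- min(set_size, query_size)
  if (overlap > hi) return(0)
  sum(vapply(overlap:hi, function(i) {
    choose(set_size, i) * choose(universe_size - set_size, query_size - i) /
      choose(universe_size, query_size)
  }, numeric(1)))
}

# Hand product-limit estimator over distinct times.
oracle_km <- function(time, event) {
  ut <- sort(unique(time))
  s <- 1
  out <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  tibble::tibble(time = ut, survival = out)
}

# Hand log-rank statistic: sum of observed-minus-expected over event times.
oracle_logrank <- function(time, event, group) {
  g <- group == unique(group)[1]
  ut <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ut) {
    n <- sum(time >= t); n1 <- sum(time >= t & g)
    d <- sum(time == t & event); d1 <- sum(time == t & event & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}
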