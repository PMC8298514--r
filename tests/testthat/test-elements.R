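# Consensus catalog construction, classification, signal scoring,
# normalization, saturation, z-scores.

test_that("merge_peaks merges overlaps but not book-ended half-open intervals", {
  merged <- merge_peaks(list(
    a = tibble::tibble(chrom = "chr1", start = 100L, end = 200L),
    b = tibble::tibble(chrom = "chr1", start = 150L, end = 300L)
  ))
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(100L, 300L))
  expect_equal(merged$n_samples, 2L)

  booked <- merge_peaks(list(
    a = tibble::tibble(chrom = "chr1", start = 100L, end = 200L),
    b = tibble::tibble(chrom = "chr1", start = 200L, end = 300L)
  ))
  expect_equal(nrow(booked), 2)

  two_chrom <- merge_peaks(tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"), start = c(0L, 50L, 0L),
    end = c(100L, 150L, 100L)))
  expect_equal(nrow(two_chrom), 2)

  expect_equal(nrow(merge_peaks(list())), 0)
})

test_that("merge_peaks equals the per-basepair union oracle on random instances", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample.int(50, 1)
    peaks <- random_peaks(n)
    got <- merge_peaks(peaks)
    want <- oracle_merge_1chrom(peaks$start, peaks$end)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("classification separates promoter, enhancer and ambiguous elements", {
  tss <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 10000L, strand = "+")
  el <- tibble::tibble(chrom = "chr1",
                       start = c(8500L, 13000L, 11500L),
                       end = c(9500L, 14000L, 12500L),
                       element_id = c("a", "b", "c"))
  cl <- classify_elements(el, tss, window = 2000)
  expect_equal(cl$element_class, c("promoter_element", "enhancer", "ambiguous"))
  expect_equal(cl$nearest_tss_distance[2], 3000L)
  expect_error(classify_elements(el, tss, window = 0), "window")
})

test_that("classification agrees with an exhaustive per-base distance check", {
  set.seed(11)
  tss <- tibble::tibble(gene_id = paste0("g", 1:8), chrom = "chr1",
                        tss = sort(sample.int(50000, 8)), strand = "+")
  window <- 2000
  el <- random_peaks(150, max_coord = 50000) %>%
    dplyr::mutate(element_id = paste0("e", dplyr::row_number()))
  got <- classify_elements(el, tss, window = window)
  for (i in seq_len(nrow(el))) {
    bases <- el$start[i]:(el$end[i] - 1L)
    dmat <- outer(bases, tss$tss, function(b, t) abs(b - t))
    per_base_min <- apply(dmat, 1, min)
    cls <- if (any(apply(dmat, 2, max) <= window)) "promoter_element"
           else if (min(per_base_min) > window) "enhancer" else "ambiguous"
    expect_equal(got$element_class[i], cls)
    expect_equal(got$nearest_tss_distance[i], as.integer(min(per_base_min)))
  }
})

test_that("every element falls in exactly one class and counts sum to catalog size", {
  co <- small_cohort()
  cl <- classify_elements(co$elements, co$tss)
  expect_true(all(cl$element_class %in% c("promoter_element", "enhancer",
                                          "ambiguous")))
  expect_equal(sum(table(cl$element_class)), nrow(co$elements))
})

test_that("rpkm_signal computes input-subtracted RPKM with flooring at zero", {
  counts <- tibble::tibble(element_id = "r1", s1 = 100)
  sig <- rpkm_signal(counts, region_lengths = 500, library_sizes = 1e7)
  expect_equal(sig$s1, 20)

  # input exceeding ChIP floors at 0
  chip <- tibble::tibble(element_id = "r1", s1 = 25)   # RPKM 5
  input <- tibble::tibble(element_id = "r1", s1 = 35)  # RPKM 7
  out <- rpkm_signal(chip, 500, 1e7, input, 1e7)
  expect_equal(out$s1, 0)

  # chip equal to input gives zero everywhere
  same <- rpkm_signal(chip, 500, 1e7, chip, 1e7)
  expect_true(all(same$s1 == 0))
  expect_error(rpkm_signal(tibble::tibble(element_id = "r1", s1 = -1), 500, 1e7),
               "negative")
})

test_that("quantile normalization matches the sorted-mean reference and contract", {
  m <- tibble::tibble(element_id = c("a", "b"), s1 = c(1, 3), s2 = c(2, 4))
  qn <- quantile_normalize(m)
  expect_equal(qn$s1, c(1.5, 3.5))
  expect_equal(qn$s2, c(1.5, 3.5))
  expect_true(attr(qn, "normalized"))

  # identical columns are a fixed point
  ident <- tibble::tibble(element_id = letters[1:4], s1 = c(4, 1, 3, 2),
                          s2 = c(4, 1, 3, 2))
  expect_equal(quantile_normalize(ident)$s1, ident$s1)

  # all output columns carry identical sorted values, means equal
  set.seed(3)
  big <- matrix_stub <- tibble::as_tibble(
    cbind(data.frame(element_id = paste0("e", 1:500)),
          matrix(rlnorm(500 * 6), 500, 6, dimnames = list(NULL, paste0("s", 1:6)))))
  qb <- quantile_normalize(big)
  vals <- as.matrix(qb[, -1])
  ref <- sort(vals[, 1])
  for (j in 2:6) expect_lt(max(abs(sort(vals[, j]) - ref)), 1e-9)
  expect_lt(diff(range(colMeans(vals))), 1e-9)

  one <- tibble::tibble(element_id = "a", s1 = 5)
  expect_warning(same <- quantile_normalize(one), ">= 2 columns")
  expect_equal(same$s1, 5)
})

test_that("quantile normalization agrees with limma on tie-free matrices", {
  set.seed(9)
  m <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(paste0("e", 1:200),
                                                      paste0("s", 1:5)))
  tbl <- tibble::as_tibble(cbind(data.frame(element_id = rownames(m)), m))
  got <- as.matrix(quantile_normalize(tbl)[, -1])
  want <- limma::normalizeQuantiles(m, ties = TRUE)
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
})

test_that("saturation curves behave for identical, disjoint and seeded inputs", {
  ident <- replicate(5, paste0("e", 1:40), simplify = FALSE)
  names(ident) <- paste0("s", 1:5)
  flat <- saturation_curve(ident, n_permutations = 10, seed = 1)
  expect_true(all(flat$mean_count == 40))
  expect_equal(attr(flat, "saturation_k"), 1L)

  disjoint <- lapply(1:5, function(i) paste0("s", i, "_", 1:10))
  names(disjoint) <- paste0("s", 1:5)
  lin <- saturation_curve(disjoint, n_permutations = 5, seed = 1)
  expect_equal(lin$mean_count, seq(10, 50, by = 10))
  expect_true(is.na(attr(lin, "saturation_k")))

  mixed <- lapply(1:6, function(i) paste0("e", sample.int(100, 60)))
  names(mixed) <- paste0("s", 1:6)
  a <- saturation_curve(mixed, n_permutations = 20, seed = 5)
  b <- saturation_curve(mixed, n_permutations = 20, seed = 5)
  expect_identical(a, b)
  expect_error(saturation_curve(mixed, n_permutations = 0), "n_permutations")
})

test_that("row z-scores use sample sd, zero constant rows, and are idempotent", {
  m <- tibble::tibble(id = c("a", "b"), s1 = c(1, 5), s2 = c(2, 5), s3 = c(3, 5))
  z <- zscore_rows(m)
  expect_equal(unlist(z[1, -1], use.names = FALSE), c(-1, 0, 1))
  expect_equal(unlist(z[2, -1], use.names = FALSE), c(0, 0, 0))
  z2 <- zscore_rows(z)
  expect_equal(as.matrix(z2[, -1]), as.matrix(z[, -1]), tolerance = 1e-12)
})
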