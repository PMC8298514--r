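# Gene linking, expression utilities, dose-response, biomarkers, signatures,
# priming, enrichment, PCA and clustering.

test_that("nearest-gene assignment uses midpoints with lexicographic ties", {
  tss <- tibble::tibble(gene_id = c("geneA", "geneB"), chrom = "chr1",
                        tss = c(4000L, 7000L), strand = "+")
  el <- tibble::tibble(chrom = "chr1", start = 4800L, end = 5200L,
                       element_id = "e1")  # midpoint 5000
  link <- assign_nearest_gene(el, tss)
  expect_equal(link$gene_id, "geneA")
  expect_equal(link$distance, 1000)

  tie <- assign_nearest_gene(el, tibble::tibble(
    gene_id = c("geneZ", "geneB"), chrom = "chr1",
    tss = c(4000L, 6000L), strand = "+"))
  expect_equal(tie$gene_id, "geneB")  # equidistant, lexicographically smaller
})

test_that("nearest-gene assignment equals the all-pairs brute-force scan", {
  set.seed(14)
  tss <- tibble::tibble(gene_id = sprintf("g%03d", 1:40),
                        chrom = sample(c("chr1", "chr2"), 40, TRUE),
                        tss = sample.int(100000, 40), strand = "+")
  el <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 400, TRUE),
                       start = sample.int(100000, 400)) %>%
    mutate(end = start + sample.int(500, 400),
           element_id = sprintf("e%04d", dplyr::row_number()))
  got <- assign_nearest_gene(el, tss)
  expect_equal(got$gene_id, oracle_nearest(el, tss))
})

test_that("the CPM filter retains genes by library-normalized expression", {
  # library sums are exactly 10^6, so counts are CPM directly
  counts <- tibble::tibble(gene_id = c("hi", "lo", "bulk"),
                           s1 = c(15, 0, 999985), s2 = c(15, 0, 999985))
  kept <- cpm_filter(counts, cpm_min = 1, min_samples = 2)
  expect_true("hi" %in% kept$gene_id)      # cpm 15 > 1 in both samples
  expect_false("lo" %in% kept$gene_id)
  expect_equal(nrow(cpm_filter(counts, min_samples = 0)), 3)
  expect_error(cpm_filter(counts, min_samples = 5), "min_samples")
})

test_that("the Welch stand-in DE test detects planted shifts and not null genes", {
  set.seed(17)
  n_genes <- 400
  base <- matrix(2^rnorm(n_genes * 20, 5, 0.3), n_genes, 20)
  base[1:200, 11:20] <- base[1:200, 11:20] * 4  # planted 4-fold shift
  tpm <- tibble::as_tibble(cbind(
    data.frame(gene_id = sprintf("g%03d", 1:n_genes)),
    `colnames<-`(base, c(paste0("P", 1:10, "_Nor"), paste0("P", 1:10, "_EC")))))
  sheet <- tibble::tibble(sample_id = colnames(tpm)[-1],
                          patient_id = rep(paste0("P", 1:10), 2),
                          tissue = rep(c("Nor", "EC"), each = 10))
  de <- de_test(tpm, sheet, "EC_vs_Nor")
  expect_gte(mean(de$de[1:200]), 0.99)          # planted genes recovered
  expect_lte(mean(de$de[201:400]), 0.01)        # null genes stay quiet
  expect_equal(unique(de$direction[1:200][de$de[1:200]]), "up")
  expect_identical(attr(de, "method"), "welch_bh")

  flat <- tpm; flat[, -1] <- 1
  de0 <- de_test(flat, sheet, "EC_vs_Nor")
  expect_true(all(de0$pvalue == 1))
  expect_false(any(de0$de))
})

test_that("dose-response is strictly monotone on additively coupled cohorts", {
  co <- small_cohort()
  res <- cohort_calls(co)
  links <- assign_nearest_gene(res$elements, co$tss)
  fc <- expression_fc(co$tpm, co$sheet, "EC_vs_Nor")
  gained <- co$truth$elements$element_id[co$truth$elements$class %in% c("G1", "G3")]
  dr <- suppressWarnings(enhancer_dose_response(links, gained, fc))
  med <- dr$median_fc[as.character(dr$dose) != "0"]
  expect_true(all(diff(med) > 0))
  tests <- tidy(dr)
  adjacent <- tests[tests$bucket_a != "0", ]
  expect_true(all(adjacent$p_value < 0.01))
})

test_that("Wilcoxon on identical distributions is non-significant", {
  dr_null <- suppressWarnings(enhancer_dose_response(
    tibble::tibble(element_id = character(), gene_id = character(),
                   distance = numeric()),
    character(0),
    tibble::tibble(gene_id = paste0("g", 1:30), fc = rlnorm(30))))
  expect_equal(nrow(tidy(dr_null)), 0)  # single bucket, no tests
})

test_that("Spearman correlation matches the tie-corrected rank formula", {
  up <- correlate_signal_expression(
    tibble::tibble(element_id = "e", gene_id = "g", distance = 0),
    tibble::tibble(element_id = "e", s1 = 1, s2 = 2, s3 = 3, s4 = 4),
    tibble::tibble(gene_id = "g", s1 = 10, s2 = 20, s3 = 25, s4 = 90))
  expect_equal(up$r, 1)
  down <- correlate_signal_expression(
    tibble::tibble(element_id = "e", gene_id = "g", distance = 0),
    tibble::tibble(element_id = "e", s1 = 1, s2 = 2, s3 = 3, s4 = 4),
    tibble::tibble(gene_id = "g", s1 = 90, s2 = 25, s3 = 20, s4 = 10))
  expect_equal(down$r, -1)

  set.seed(19)
  for (i in 1:300) {
    a <- sample(rnorm(20), 20, replace = TRUE)  # replacement induces ties
    b <- sample(rnorm(20), 20, replace = TRUE)
    expect_equal(stats::cor(a, b, method = "spearman"), oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
})

test_that("biomarker panels keep positive correlations and rank by fold change", {
  corr <- tibble::tibble(element_id = paste0("e", 1:6),
                         gene_id = paste0("g", 1:6),
                         r = c(0.9, 0.8, 0.7, -0.5, 0.6, 0.5), n_shared = 10)
  attr(corr, "by_gene") <- corr
  fc <- tibble::tibble(gene_id = paste0("g", 1:6), fc = c(2, 8, 4, 9, 1.5, 3))
  grp <- tibble::tibble(element_id = paste0("e", 1:6), group = "G1")
  links <- tibble::tibble(element_id = paste0("e", 1:6),
                          gene_id = paste0("g", 1:6), distance = 0)
  panel <- select_biomarkers(corr, fc, grp, links, groups = "G1",
                             top_corr = 4, top_n = 3)
  # r > 0 keeps g1,g2,g3,g5,g6; top 4 by r: g1,g2,g3,g5; top 3 by fc: g2,g3,g1
  expect_equal(panel$gene_id, c("g2", "g3", "g1"))

  corr_neg <- corr %>% mutate(r = -abs(r))
  attr(corr_neg, "by_gene") <- corr_neg
  none <- suppressWarnings(select_biomarkers(corr_neg, fc, grp, links,
                                             groups = "G1"))
  expect_equal(nrow(none), 0)
})

test_that("panels are stable under permutation of input gene order", {
  co <- small_cohort()
  res <- cohort_calls(co)
  links <- assign_nearest_gene(res$elements, co$tss)
  corr <- correlate_signal_expression(links, res$signal, co$tpm)
  fc <- expression_fc(co$tpm, co$sheet, "EC_vs_Nor")
  p1 <- suppressWarnings(select_biomarkers(corr, fc, res$groups, links, top_n = 5))
  set.seed(4)
  corr2 <- corr[sample.int(nrow(corr)), ]
  attr(corr2, "by_gene") <- attr(corr, "by_gene")[sample.int(nrow(attr(corr, "by_gene"))), ]
  p2 <- suppressWarnings(select_biomarkers(corr2, fc[sample.int(nrow(fc)), ],
                                           res$groups, links, top_n = 5))
  expect_equal(p1, p2)
})

test_that("signature classification assigns obvious patterns and breaks ties", {
  panels <- tibble::tibble(subgroup = c("g1", "g2", "g3", "g6"),
                           gene_id = c("a", "b", "c", "d"),
                           r = 1, fc = 2, panel_rank = 1)
  # one sample per tissue pattern: scores driven by the panel genes
  tpm <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                        nor = c(1, 1, 1, 100), ec = c(100, 1, 100, 1),
                        lnc = c(1, 100, 100, 1), odd = c(100, 100, 1, 1))
  sig <- classify_sample_signature(panels, tpm)
  expect_equal(sig$assigned[sig$sample_id == "nor"], "Nor")
  expect_equal(sig$assigned[sig$sample_id == "ec"], "EC")
  expect_equal(sig$assigned[sig$sample_id == "lnc"], "LNC")
  expect_equal(sig$assigned[sig$sample_id == "odd"], "unclassified")
})

test_that("priming requires group-linked enhancers with metastasis-only regulation", {
  grp <- tibble::tibble(element_id = c("e3", "e6"), group = c("G3", "G6"))
  links <- tibble::tibble(element_id = c("e3", "e3", "e6"),
                          gene_id = c("late_up", "both_up", "late_down"),
                          distance = 0)
  de_tbl <- function(genes, dirs) {
    tibble::tibble(gene_id = genes, log2FC = 0, pvalue = 0.001, padj = 0.001,
                   de = dirs != "none", direction = dirs)
  }
  de_ec <- de_tbl(c("late_up", "both_up", "late_down"), c("none", "up", "none"))
  de_lnc <- de_tbl(c("late_up", "both_up", "late_down"), c("up", "up", "down"))
  pr <- classify_priming(grp, de_ec, de_lnc, links)
  expect_equal(pr$gene_id[pr$priming == "pre_activated"], "late_up")
  expect_equal(pr$gene_id[pr$priming == "pre_silenced"], "late_down")
  expect_false("both_up" %in% pr$gene_id)
})

test_that("hypergeometric enrichment matches closed-form and enumeration", {
  u <- paste0("g", 1:10)
  out <- hypergeometric_enrichment(u[1:5], list(s = u[1:5]), u)
  expect_equal(out$p_value, 1 / choose(10, 5), tolerance = 1e-12)

  none <- hypergeometric_enrichment(u[1:2], list(s = u[9:10]), u)
  expect_equal(none$p_value, 1)

  set.seed(23)
  for (i in 1:300) {
    N <- sample(5:20, 1)
    uni <- paste0("g", 1:N)
    s <- sample(uni, sample.int(N, 1))
    q <- sample(uni, sample.int(N, 1))
    got <- hypergeometric_enrichment(q, list(s = s), uni)
    want <- oracle_hyper(length(intersect(q, s)), length(s), length(q), N)
    expect_equal(got$p_value, want, tolerance = 1e-9)
  }
  expect_error(hypergeometric_enrichment("g1", list(), character(0)), "empty universe")
})

test_that("PCA separates constructed clouds with fixed sign convention", {
  set.seed(25)
  m <- cbind(matrix(rnorm(50 * 5, 0, 0.1), 50, 5),
             matrix(rnorm(50 * 5, 3, 0.1), 50, 5))
  colnames(m) <- paste0("s", 1:10)
  tbl <- tibble::as_tibble(cbind(data.frame(element_id = paste0("e", 1:50)), m))
  fit <- pca_samples(tbl)
  pc1 <- fit$scores$PC1
  expect_true(all(pc1[1:5] < 0) != all(pc1[1:5] > 0))  # group-coherent
  expect_true(max(pc1[1:5]) < min(pc1[6:10]) || min(pc1[1:5]) > max(pc1[6:10]))
  expect_gt(fit$var_explained[1], fit$var_explained[2])
  fit2 <- pca_samples(tbl)
  expect_identical(fit$scores, fit2$scores)

  # 2-feature toy: variance shares equal hand-computed eigenvalue ratios
  toy <- tibble::tibble(element_id = c("a", "b"),
                        s1 = c(0, 0), s2 = c(2, 0), s3 = c(4, 6))
  cf <- pca_samples(toy, n_components = 2)
  ev <- eigen(stats::cov(cbind(c(0, 2, 4), c(0, 0, 6))))$values
  expect_equal(cf$var_explained, ev / sum(ev), tolerance = 1e-12)
})

test_that("clustering recovers tissues and keeps monotone merge heights", {
  co <- small_cohort()
  res <- cohort_calls(co)
  called <- res$groups$element_id[res$groups$group != "none"]
  sub <- res$signal[res$signal$element_id %in% called, ]
  cl <- cluster_samples(sub, k = 3)
  lab <- dplyr::inner_join(cl$labels, co$sheet, by = "sample_id")
  agreement <- lab %>%
    dplyr::count(cluster, tissue) %>%
    dplyr::group_by(cluster) %>%
    dplyr::slice_max(n, n = 1, with_ties = FALSE) %>%
    dplyr::pull(n) %>% sum()
  expect_gte(agreement / nrow(lab), 0.9)
  expect_true(all(diff(cl$tree$height) >= -1e-12))

  dup <- tibble::tibble(element_id = paste0("e", 1:5),
                        s1 = rnorm(5), s2 = 1:5 + 0.5)
  dup$s3 <- dup$s2
  tree <- cluster_samples(dup, k = 2)
  expect_lt(tree$tree$height[1], 1e-12)

  const <- tibble::tibble(element_id = paste0("e", 1:5), s1 = rnorm(5), s2 = 1)
  expect_error(cluster_samples(const, k = 2), "constant sample column.*s2")
})
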