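# Enhancer-expression integration: nearest-TSS gene links, CPM filtering, a
# Welch-t stand-in differential-expression test (external tables importable),
# enhancer dose-response, signal-expression correlation, biomarker panels and
# tissue signatures, priming classification, hypergeometric enrichment, PCA
# and hierarchical clustering of samples.

#' Assign each element to its nearest-TSS gene
#'
#' Distance is measured from the element midpoint to the TSS; equidistant
#' TSSs are resolved to the lexicographically smallest gene id.
#'
#' @param elements Element tibble (`chrom`, `start`, `end`, `element_id`).
#' @param tss TSS tibble.
#' @return Tibble `element_id`, `gene_id`, `distance` (bp; `NA` gene for
#'   elements on chromosomes without any TSS).
#' @export
assign_nearest_gene <- function(elements, tss) {
  if (nrow(tss) == 0) abort("TSS set is empty", class = "epr_config_error")
  out <- elements %>%
    transmute(.data$element_id, .data$chrom,
              mid = (.data$start + .data$end) / 2,
              gene_id = NA_character_, distance = NA_real_)
  for (ch in unique(out$chrom)) {
    idx <- which(out$chrom == ch)
    ts <- tss %>% filter(.data$chrom == ch) %>% arrange(.data$tss, .data$gene_id)
    if (nrow(ts) == 0) next
    # smallest gene_id at each distinct position, positions sorted ascending
    by_pos <- ts %>% group_by(.data$tss) %>% slice(1) %>% ungroup()
    pos <- by_pos$tss; gene <- by_pos$gene_id
    mid <- out$mid[idx]
    i <- findInterval(mid, pos)
    lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(pos))
    d_lo <- ifelse(i >= 1, abs(mid - pos[lo]), Inf)
    d_hi <- ifelse(i < length(pos), abs(mid - pos[hi]), Inf)
    dmin <- pmin(d_lo, d_hi)
    g <- ifelse(d_lo < d_hi, gene[lo],
                ifelse(d_hi < d_lo, gene[hi], pmin(gene[lo], gene[hi])))
    out$gene_id[idx] <- g
    out$distance[idx] <- dmin
  }
  out %>% select("element_id", "gene_id", "distance")
}

#' Filter genes by counts-per-million expression
#'
#' Keeps genes with CPM above `cpm_min` in at least `min_samples` samples
#' (CPM = count x 1e6 / library column sum).
#'
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @param cpm_min CPM threshold (default 1).
#' @param min_samples Minimum number of samples exceeding the threshold
#'   (default 18, matching an 18-sample retention design).
#' @return The filtered counts tibble.
#' @export
cpm_filter <- function(counts, cpm_min = 1, min_samples = 18) {
  m <- signal_to_matrix(counts)
  if (min_samples > ncol(m)) {
    abort("min_samples exceeds the number of samples", class = "epr_config_error")
  }
  libs <- colSums(m)
  if (any(libs <= 0)) abort("zero library size", class = "epr_data_error")
  cpm <- sweep(m, 2, libs, `/`) * 1e6
  keep <- rowSums(cpm > cpm_min) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Welch-t stand-in differential expression test
#'
#' A documented stand-in for a count-model DE analysis: per-gene two-sided
#' Welch t-test on `log2(TPM + 1)`, BH-adjusted; a gene is differentially
#' expressed when its linear fold change exceeds `fc_min` (in either
#' direction) and q < `fdr_max`. Outputs are labeled with method
#' `"welch_bh"`; externally produced tables import via [import_de_table()].
#'
#' @param tpm TPM tibble (`gene_id` + sample columns), linear scale.
#' @param sheet Sample sheet.
#' @param comparison Comparison to test.
#' @param fc_min Linear fold-change threshold (default 1.5).
#' @param fdr_max FDR threshold (default 0.05).
#' @return Tibble `gene_id`, `log2FC`, `pvalue`, `padj`, `de`, `direction`
#'   with attribute `method = "welch_bh"`.
#' @export
de_test <- function(tpm, sheet, comparison = "EC_vs_Nor", fc_min = 1.5,
                    fdr_max = 0.05) {
  comparison <- match.arg(comparison, COMPARISONS)
  tis <- comparison_tissues(comparison)
  m <- log2(signal_to_matrix(tpm) + 1)
  case <- intersect(sheet$sample_id[sheet$tissue == tis[["case"]]], colnames(m))
  ref <- intersect(sheet$sample_id[sheet$tissue == tis[["ref"]]], colnames(m))
  if (length(case) < 2 || length(ref) < 2) {
    abort("need >= 2 samples per group", class = "epr_data_error")
  }
  xc <- m[, case, drop = FALSE]; xr <- m[, ref, drop = FALSE]
  log2fc <- rowMeans(xc) - rowMeans(xr)
  p <- vapply(seq_len(nrow(m)), function(i) {
    a <- xc[i, ]; b <- xr[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      stats::t.test(a, b)$p.value
    }
  }, numeric(1))
  out <- tibble(gene_id = rownames(m), log2FC = log2fc, pvalue = p,
                padj = stats::p.adjust(p, method = "BH")) %>%
    mutate(de = abs(.data$log2FC) > log2(fc_min) & .data$padj < fdr_max,
           direction = case_when(!.data$de ~ "none",
                                 .data$log2FC > 0 ~ "up",
                                 TRUE ~ "down"))
  attr(out, "method") <- "welch_bh"
  out
}

#' Import an externally produced differential-expression table
#'
#' @param path TSV with columns `gene_id`, `log2FC`, `pvalue`, `padj`.
#' @param fc_min,fdr_max Thresholds used to derive `de` and `direction`.
#' @return Tibble with the same schema as [de_test()].
#' @export
import_de_table <- function(path, fc_min = 1.5, fdr_max = 0.05) {
  tbl <- as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  check_columns(tbl, c("gene_id", "log2FC", "pvalue", "padj"), "DE table")
  out <- tbl %>%
    mutate(de = abs(.data$log2FC) > log2(fc_min) & .data$padj < fdr_max,
           direction = case_when(!.data$de ~ "none",
                                 .data$log2FC > 0 ~ "up",
                                 TRUE ~ "down"))
  attr(out, "method") <- "imported"
  out
}

#' Group-mean expression fold change per gene
#'
#' Pseudocounted ratio of group-mean TPM (case over reference), the scale on
#' which biomarker and dose-response analyses rank genes.
#'
#' @param tpm TPM tibble.
#' @param sheet Sample sheet.
#' @param comparison Comparison.
#' @param pseudocount Added to both group means (default 1 TPM).
#' @return Tibble `gene_id`, `fc`, `log2FC`.
#' @export
expression_fc <- function(tpm, sheet, comparison = "EC_vs_Nor", pseudocount = 1) {
  comparison <- match.arg(comparison, COMPARISONS)
  tis <- comparison_tissues(comparison)
  m <- signal_to_matrix(tpm)
  case <- intersect(sheet$sample_id[sheet$tissue == tis[["case"]]], colnames(m))
  ref <- intersect(sheet$sample_id[sheet$tissue == tis[["ref"]]], colnames(m))
  fc <- (rowMeans(m[, case, drop = FALSE]) + pseudocount) /
    (rowMeans(m[, ref, drop = FALSE]) + pseudocount)
  tibble(gene_id = rownames(m), fc = fc, log2FC = log2(fc))
}

#' Enhancer dose-response on gene expression
#'
#' Genes are bucketed by their number of altered (gained or lost) linked
#' enhancers (default buckets 1, 2, >= 3; genes with none form the reference
#' bucket 0) and each bucket's expression fold-change distribution is
#' summarized. Two-sided Wilcoxon rank-sum tests compare adjacent buckets and
#' every bucket against the reference.
#'
#' @param links Gene links from [assign_nearest_gene()].
#' @param altered_elements Character vector of element ids carrying the
#'   alteration of interest (e.g. all gained enhancers of a comparison).
#' @param gene_fc Tibble `gene_id`, `fc` from [expression_fc()].
#' @param max_dose Doses >= `max_dose` are pooled (default 3).
#' @return An object of class `dose_response`: tibble `dose`, `n_genes`,
#'   `median_fc` with attributes `tests` (pairwise Wilcoxon p-values) and
#'   `gene_doses`.
#' @export
enhancer_dose_response <- function(links, altered_elements, gene_fc,
                                   max_dose = 3) {
  doses <- links %>%
    filter(!is.na(.data$gene_id)) %>%
    group_by(.data$gene_id) %>%
    summarise(dose = sum(.data$element_id %in% altered_elements), .groups = "drop")
  gene_doses <- gene_fc %>%
    left_join(doses, by = "gene_id") %>%
    mutate(dose = tidyr::replace_na(.data$dose, 0L),
           dose_bucket = ifelse(.data$dose >= max_dose,
                                paste0(max_dose, "+"), as.character(.data$dose)))
  levels <- c(as.character(0:(max_dose - 1)), paste0(max_dose, "+"))
  gene_doses$dose_bucket <- factor(gene_doses$dose_bucket, levels = levels)
  summary <- gene_doses %>%
    group_by(dose = .data$dose_bucket) %>%
    summarise(n_genes = n(), median_fc = stats::median(.data$fc), .groups = "drop")
  present <- as.character(summary$dose[summary$n_genes > 0])
  empty <- setdiff(levels, present)
  if (length(empty) > 0) warn(paste0("empty dose bucket(s): ", paste(empty, collapse = ", ")))
  pairs_to_test <- list()
  nonzero <- setdiff(present, "0")
  if (length(nonzero) >= 2) {
    for (i in seq_len(length(nonzero) - 1)) {
      pairs_to_test <- c(pairs_to_test, list(c(nonzero[i], nonzero[i + 1])))
    }
  }
  if ("0" %in% present) {
    for (b in nonzero) pairs_to_test <- c(pairs_to_test, list(c("0", b)))
  }
  tests <- purrr::map_dfr(pairs_to_test, function(pr) {
    fa <- gene_doses$fc[gene_doses$dose_bucket == pr[1]]
    fb <- gene_doses$fc[gene_doses$dose_bucket == pr[2]]
    p <- suppressWarnings(stats::wilcox.test(fa, fb)$p.value)
    tibble(bucket_a = pr[1], bucket_b = pr[2], p_value = p)
  })
  attr(summary, "tests") <- tests
  attr(summary, "gene_doses") <- gene_doses
  class(summary) <- c("dose_response", class(summary))
  summary
}

#' Spearman correlation between element signal and linked-gene expression
#'
#' Per link, the Spearman rank correlation between the element's H3K27ac
#' signal and the linked gene's expression across the shared samples. A
#' per-gene summary keeps each gene's best (largest-r) link.
#'
#' @param links Gene links.
#' @param signal Signal tibble over elements.
#' @param tpm Expression tibble over genes.
#' @param min_shared Minimum shared samples (default 3).
#' @return Tibble `element_id`, `gene_id`, `r`, `n_shared` (r is `NA` when
#'   either vector is constant) with attribute `by_gene` (best link per
#'   gene).
#' @export
correlate_signal_expression <- function(links, signal, tpm, min_shared = 3) {
  ms <- signal_to_matrix(signal)
  me <- signal_to_matrix(tpm)
  shared <- intersect(colnames(ms), colnames(me))
  if (length(shared) < min_shared) {
    abort(paste0("need >= ", min_shared, " shared samples"), class = "epr_data_error")
  }
  links2 <- links %>%
    filter(!is.na(.data$gene_id), .data$element_id %in% rownames(ms),
           .data$gene_id %in% rownames(me))
  sx <- ms[links2$element_id, shared, drop = FALSE]
  ex <- me[links2$gene_id, shared, drop = FALSE]
  r <- vapply(seq_len(nrow(links2)), function(i) {
    a <- sx[i, ]; b <- ex[i, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = "spearman")
  }, numeric(1))
  out <- tibble(element_id = links2$element_id, gene_id = links2$gene_id,
                r = r, n_shared = length(shared))
  by_gene <- out %>%
    filter(!is.na(.data$r)) %>%
    group_by(.data$gene_id) %>%
    arrange(desc(.data$r), .data$element_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  attr(out, "by_gene") <- by_gene
  out
}

#' Select biomarker panels from correlated, fold-changed genes
#'
#' For each enhancer group, genes linked to that group's enhancers are
#' filtered to positive signal-expression correlation, the `top_corr` most
#' correlated are kept, re-ranked by expression fold change in the group's
#' direction (descending for gain groups, ascending for loss groups), and the
#' top `top_n` form the panel. Ties break deterministically by gene id.
#'
#' @param correlations Output of [correlate_signal_expression()] (its
#'   per-gene best links are used).
#' @param gene_fc Tibble `gene_id`, `fc`, or a named list of such tibbles
#'   keyed by enhancer group so each subgroup is ranked by the fold change of
#'   its own comparison (e.g. LNC_vs_Nor for the LNC-specific group G2).
#' @param group_assignment Output of [assign_groups()].
#' @param links Gene links.
#' @param groups Enhancer groups to build panels for (default G1, G2, G3,
#'   G6).
#' @param top_corr Correlation pre-selection size (default 100).
#' @param top_n Panel size (default 10).
#' @return Tibble `subgroup` (`g1`, `g2`, ...), `gene_id`, `r`, `fc`,
#'   `panel_rank`.
#' @export
select_biomarkers <- function(correlations, gene_fc, group_assignment, links,
                              groups = c("G1", "G2", "G3", "G6"),
                              top_corr = 100, top_n = 10) {
  by_gene <- attr(correlations, "by_gene") %||% correlations
  purrr::map_dfr(groups, function(g) {
    fc_tbl <- if (is.data.frame(gene_fc)) gene_fc else {
      if (is.null(gene_fc[[g]])) abort(paste0("no fold-change table for group ", g),
                                       class = "epr_config_error")
      gene_fc[[g]]
    }
    gl <- links %>%
      semi_join(group_assignment %>% filter(.data$group == g), by = "element_id") %>%
      distinct(.data$gene_id) %>%
      filter(!is.na(.data$gene_id))
    cand <- by_gene %>%
      semi_join(gl, by = "gene_id") %>%
      filter(.data$r > 0) %>%
      inner_join(fc_tbl %>% select("gene_id", "fc"), by = "gene_id") %>%
      arrange(desc(.data$r), .data$gene_id) %>%
      slice_head(n = top_corr)
    loss_group <- g %in% c("G4", "G5", "G6")
    cand <- if (loss_group) {
      cand %>% arrange(.data$fc, .data$gene_id)
    } else {
      cand %>% arrange(desc(.data$fc), .data$gene_id)
    }
    panel <- cand %>% slice_head(n = top_n)
    if (nrow(panel) < top_n) {
      warn(paste0("group ", g, ": only ", nrow(panel), " qualifying genes"))
    }
    panel %>%
      transmute(subgroup = tolower(g), .data$gene_id, .data$r, .data$fc,
                panel_rank = dplyr::row_number())
  })
}

# The three tissue signatures over the (g1, g2, g3, g6) subgroup scores.
TISSUE_SIGNATURES <- list(
  Nor = c(g1 = "-", g2 = "-", g3 = "-", g6 = "+"),
  EC  = c(g1 = "+", g2 = "-", g3 = "+", g6 = "-"),
  LNC = c(g1 = "-", g2 = "+", g3 = "+", g6 = "-")
)

#' Classify samples by the biomarker tissue signatures
#'
#' Each sample receives a mean z-scored expression score per subgroup; signs
#' are matched against the tissue signature patterns Nor (g1- g2- g3- g6+),
#' EC (g1+ g2- g3+ g6-) and LNC (g1- g2+ g3+ g6-) by minimum Hamming
#' distance. Distance ties yield `unclassified`.
#'
#' The default sign threshold is 0: z-scored expression is centered per gene,
#' so a positive subgroup score means above-cohort-average expression,
#' matching the +/- semantics of the signatures regardless of how many
#' samples carry each pattern. A cohort-median threshold
#' (`sign_threshold = "median"`) is also provided, but it pins the +/- split
#' to half the cohort and therefore misassigns samples whenever a pattern is
#' carried by more (or fewer) than half the samples.
#'
#' @param panels Biomarker panels from [select_biomarkers()].
#' @param tpm Expression tibble.
#' @param sign_threshold `"zero"` (default) or `"median"`.
#' @return Tibble `sample_id`, one score column per subgroup, `assigned`.
#' @export
classify_sample_signature <- function(panels, tpm,
                                      sign_threshold = c("zero", "median")) {
  sign_threshold <- match.arg(sign_threshold)
  subgroups <- names(TISSUE_SIGNATURES[[1]])
  used <- intersect(subgroups, unique(panels$subgroup))
  if (length(used) == 0) abort("no usable panels", class = "epr_config_error")
  z <- signal_to_matrix(zscore_rows(tpm))
  scores <- vapply(used, function(sg) {
    genes <- intersect(panels$gene_id[panels$subgroup == sg], rownames(z))
    if (length(genes) == 0) return(rep(NA_real_, ncol(z)))
    colMeans(z[genes, , drop = FALSE])
  }, numeric(ncol(z)))
  scores <- matrix(scores, ncol = length(used),
                   dimnames = list(colnames(z), used))
  signs <- apply(scores, 2, function(s) {
    thr <- if (sign_threshold == "median") stats::median(s) else 0
    ifelse(s > thr, "+", "-")
  })
  signs <- matrix(signs, ncol = length(used), dimnames = dimnames(scores))
  assigned <- vapply(seq_len(nrow(signs)), function(i) {
    d <- vapply(TISSUE_SIGNATURES, function(sig) {
      sum(signs[i, used] != sig[used])
    }, numeric(1))
    best <- which(d == min(d))
    if (length(best) > 1) "unclassified" else names(d)[best]
  }, character(1))
  bind_cols(tibble(sample_id = rownames(scores)),
            as_tibble(scores, .name_repair = "minimal"),
            tibble(assigned = assigned))
}

#' Classify priming of enhancer-linked genes
#'
#' Pre-activated genes are linked to a commonly gained (G3) enhancer, are not
#' upregulated in the primary tumor but are upregulated in the metastasis;
#' pre-silenced genes mirror this with common loss (G6) and downregulation.
#'
#' @param group_assignment Output of [assign_groups()].
#' @param de_ec,de_lnc DE tables for EC_vs_Nor and LNC_vs_Nor.
#' @param links Gene links.
#' @return Tibble `gene_id`, `priming` (`pre_activated` / `pre_silenced`).
#' @export
classify_priming <- function(group_assignment, de_ec, de_lnc, links) {
  linked_genes <- function(g) {
    links %>%
      semi_join(group_assignment %>% filter(.data$group == g), by = "element_id") %>%
      filter(!is.na(.data$gene_id)) %>%
      distinct(.data$gene_id) %>%
      pull(.data$gene_id)
  }
  dir_of <- function(de, gene) {
    d <- de$direction[match(gene, de$gene_id)]
    tidyr::replace_na(d, "none")
  }
  g3 <- linked_genes("G3")
  pre_act <- g3[dir_of(de_ec, g3) != "up" & dir_of(de_lnc, g3) == "up"]
  g6 <- linked_genes("G6")
  pre_sil <- g6[dir_of(de_ec, g6) != "down" & dir_of(de_lnc, g6) == "down"]
  bind_rows(tibble(gene_id = pre_act, priming = "pre_activated"),
            tibble(gene_id = pre_sil, priming = "pre_silenced")) %>%
    arrange(.data$priming, .data$gene_id)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric p-value for observing at least the observed
#' overlap between the query and each annotation set within the universe;
#' BH-adjusted across sets.
#'
#' @param query Character vector of gene ids (must lie in `universe`).
#' @param sets Named list of character vectors.
#' @param universe Character vector defining the background.
#' @return Tibble `set`, `overlap`, `set_size`, `query_size`, `p_value`,
#'   `q_value`.
#' @export
hypergeometric_enrichment <- function(query, sets, universe) {
  if (length(universe) == 0) abort("empty universe", class = "epr_config_error")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  out <- purrr::imap_dfr(sets, function(s, nm) {
    s <- intersect(unique(s), universe)
    ov <- length(intersect(query, s))
    p <- stats::phyper(ov - 1, length(s), length(universe) - length(s),
                       length(query), lower.tail = FALSE)
    tibble(set = nm, overlap = ov, set_size = length(s),
           query_size = length(query), p_value = p)
  })
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Principal component analysis of samples
#'
#' Rows (features) are centered and the samples projected onto the leading
#' principal components. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making repeated runs identical.
#'
#' @param tbl Feature-by-sample tibble.
#' @param n_components Number of components to keep (default 2; truncated
#'   with a warning beyond the matrix rank).
#' @return An object of class `epr_pca`: list with `scores` (tibble
#'   `sample_id`, `PC1`, ...), `loadings`, and `var_explained`.
#' @export
pca_samples <- function(tbl, n_components = 2) {
  m <- signal_to_matrix(tbl)
  if (ncol(m) < 2) abort("need >= 2 samples", class = "epr_data_error")
  fit <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k_max <- sum(fit$sdev > 1e-12)
  if (n_components > k_max) {
    warn(paste0("requested ", n_components, " components; rank supports ", k_max))
    n_components <- k_max
  }
  k <- seq_len(n_components)
  rot <- fit$rotation[, k, drop = FALSE]
  flip <- vapply(k, function(j) {
    v <- rot[, j]; sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x[, k, drop = FALSE], 2, flip, `*`)
  rot <- sweep(rot, 2, flip, `*`)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  out <- list(
    scores = bind_cols(tibble(sample_id = rownames(scores)),
                       as_tibble(scores, .name_repair = "minimal")),
    loadings = rot,
    var_explained = ve[k]
  )
  class(out) <- "epr_pca"
  out
}

#' Hierarchical clustering of samples
#'
#' Distance is 1 - Pearson correlation between sample columns (or Euclidean),
#' with average linkage; flat labels are cut at `k`.
#'
#' @param tbl Feature-by-sample tibble.
#' @param k Number of flat clusters (default 3).
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage Agglomeration method (default `"average"`).
#' @return An object of class `epr_hclust`: list with the `hclust` tree and
#'   `labels` (tibble `sample_id`, `cluster`).
#' @export
cluster_samples <- function(tbl, k = 3, distance = c("correlation", "euclidean"),
                            linkage = "average") {
  distance <- match.arg(distance)
  m <- signal_to_matrix(tbl)
  if (ncol(m) < 2) abort("need >= 2 samples", class = "epr_data_error")
  if (distance == "correlation") {
    const <- colnames(m)[apply(m, 2, stats::sd) == 0]
    if (length(const) > 0) {
      abort(paste0("constant sample column under correlation distance: ",
                   const[1]), class = "epr_data_error")
    }
    d <- stats::as.dist(1 - stats::cor(m))
  } else {
    d <- stats::dist(t(m))
  }
  tree <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(tree, k = k)
  out <- list(tree = tree,
              labels = tibble(sample_id = names(labels),
                              cluster = as.integer(labels)))
  class(out) <- "epr_hclust"
  out
}
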