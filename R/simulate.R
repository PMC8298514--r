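# Paired-cohort simulator: plants recurrent enhancer gains/losses of the six
# tissue-specificity classes into a lognormal H3K27ac signal baseline, with
# sign-matched expression shifts at linked genes, and emits everything the
# pipeline consumes (elements, TSS annotation, raw RPKM, expression, sample
# sheet) together with the planted truth.

#' Cohort simulation configuration
#'
#' Defaults describe a ten-patient paired design (Nor/EC for all, LNC for
#' eight) over 5000 consensus elements with planted class counts
#' 50/50/100/50/50/100 (G1..G6), a 4-fold planted effect carried by 80% of
#' pairs, and lognormal noise of scale 0.3.
#'
#' @param n_patients Number of patients (each with Nor and EC samples).
#' @param n_lnc_patients Patients that additionally have an LNC sample
#'   (<= `n_patients`).
#' @param n_elements Total consensus elements.
#' @param promoter_fraction Fraction of elements placed within the promoter
#'   window of their gene's TSS.
#' @param n_gained_ec,n_gained_lnc,n_common_gained Planted gain counts
#'   (classes G1, G2, G3).
#' @param n_lost_ec,n_lost_lnc,n_common_lost Planted loss counts (G4, G5,
#'   G6).
#' @param effect_fc Multiplicative planted effect on RPKM (> 1; losses use
#'   its reciprocal).
#' @param recurrence_fraction Fraction of pairs carrying each planted effect;
#'   the carrier count is `ceiling(fraction x pairs)` so planted recurrence
#'   is at least the configured fraction.
#' @param noise_sd Lognormal noise scale: total sd of log signal per cell,
#'   split into equal-variance patient-level (shared across a patient's
#'   tissues, cancelled by pairing) and residual per-sample components. Also
#'   used as the expression noise scale.
#' @param expr_coupling Additive log2 expression shift per planted linked
#'   enhancer (sign-matched to gain/loss).
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline of element RPKM.
#' @param expr_meanlog,expr_sdlog Lognormal baseline of gene TPM.
#' @param seed RNG seed (split into named substreams internally, so adding
#'   one simulated component never perturbs another).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 10, n_lnc_patients = 8,
                          n_elements = 5000, promoter_fraction = 0.3,
                          n_gained_ec = 50, n_gained_lnc = 50,
                          n_common_gained = 100, n_lost_ec = 50,
                          n_lost_lnc = 50, n_common_lost = 100,
                          effect_fc = 4, recurrence_fraction = 0.8,
                          noise_sd = 0.3, expr_coupling = 1,
                          baseline_meanlog = 1, baseline_sdlog = 0.8,
                          expr_meanlog = 3, expr_sdlog = 1, seed = 1) {
  cfg <- as.list(environment())
  planted <- n_gained_ec + n_gained_lnc + n_common_gained + n_lost_ec +
    n_lost_lnc + n_common_lost
  n_prom <- round(promoter_fraction * n_elements)
  if (planted + n_prom > n_elements) {
    abort("planted counts plus promoter elements exceed n_elements",
          class = "epr_config_error")
  }
  if (n_lnc_patients > n_patients) {
    abort("n_lnc_patients must be <= n_patients", class = "epr_config_error")
  }
  if (recurrence_fraction <= 0 || recurrence_fraction > 1) {
    abort("recurrence_fraction must be in (0, 1]", class = "epr_config_error")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0", class = "epr_config_error")
  if (effect_fc <= 1) abort("effect_fc must exceed 1", class = "epr_config_error")
  class(cfg) <- "cohort_config"
  cfg
}

CLASS_TISSUES <- list(G1 = "EC", G2 = "LNC", G3 = c("EC", "LNC"),
                      G4 = "EC", G5 = "LNC", G6 = c("EC", "LNC"))
GAIN_CLASSES <- c("G1", "G2", "G3")
LOSS_CLASSES <- c("G4", "G5", "G6")

# Allocate planted elements of one class to genes with doses cycling
# 1, 2, 3, ... so the dose-response buckets are all populated.
allocate_doses <- function(n) {
  doses <- integer(0)
  pattern <- c(1L, 2L, 3L)
  i <- 1L
  while (sum(doses) < n) {
    d <- min(pattern[(i - 1L) %% 3L + 1L], n - sum(doses))
    doses <- c(doses, d)
    i <- i + 1L
  }
  doses
}

#' Simulate a paired Nor/EC/LNC cohort with planted effects
#'
#' Lays out one genomic locus per gene (TSS plus up to three enhancers within
#' stitching range, all > 2 kb from the TSS), draws lognormal baseline RPKM
#' per element, multiplies planted elements by `effect_fc` (gains) or its
#' reciprocal (losses) in the affected tissue for a carrier subset of
#' patients, and shifts linked-gene expression by `expr_coupling` log2 units
#' per planted enhancer, sign-matched. Planted element baselines are drawn
#' from the upper half of the baseline activity distribution (a recurrently
#' lost enhancer presupposes robust activity in the reference tissue); this
#' also guarantees that at zero noise every planted effect clears the
#' default calling thresholds deterministically.
#'
#' @param config A [cohort_config()].
#' @return A list of class `enhancer_cohort` with components `elements`,
#'   `tss`, `signal` (raw input-subtracted RPKM tibble), `counts`, `tpm`,
#'   `sheet`, and `truth` (list with `elements` and `genes` truth tibbles).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n_prom <- round(cfg$promoter_fraction * cfg$n_elements)
  planted_counts <- c(G1 = cfg$n_gained_ec, G2 = cfg$n_gained_lnc,
                      G3 = cfg$n_common_gained, G4 = cfg$n_lost_ec,
                      G5 = cfg$n_lost_lnc, G6 = cfg$n_common_lost)
  n_background <- cfg$n_elements - n_prom - sum(planted_counts)

  # ---- gene/element layout (deterministic) ----
  genes <- list()
  for (cl in names(planted_counts)) {
    if (planted_counts[[cl]] == 0) next
    for (d in allocate_doses(planted_counts[[cl]])) {
      genes[[length(genes) + 1L]] <- list(class = cl, n_enh = d, promoter = FALSE)
    }
  }
  for (i in seq_len(n_prom)) {
    genes[[length(genes) + 1L]] <- list(class = "unaltered", n_enh = 0L, promoter = TRUE)
  }
  for (i in seq_len(n_background)) {
    genes[[length(genes) + 1L]] <- list(class = "unaltered", n_enh = 1L, promoter = FALSE)
  }
  n_genes <- length(genes)
  genes_per_chrom <- 1000L
  gene_tbl <- tibble(
    gene_id = sprintf("gene_%05d", seq_len(n_genes)),
    class = vapply(genes, `[[`, character(1), "class"),
    n_enh = vapply(genes, function(g) as.integer(g$n_enh), integer(1)),
    promoter = vapply(genes, `[[`, logical(1), "promoter"),
    chrom = paste0("chr", (seq_len(n_genes) - 1L) %/% genes_per_chrom + 1L),
    tss = ((seq_len(n_genes) - 1L) %% genes_per_chrom) * 50000L + 10000L
  )
  enh_offsets <- c(5000L, 8000L, 11000L)
  el_list <- purrr::pmap_dfr(gene_tbl, function(gene_id, class, n_enh, promoter,
                                                chrom, tss) {
    rows <- list()
    if (promoter) {
      rows[[1]] <- tibble(chrom = chrom, start = tss - 500L, end = tss + 100L,
                          gene_id = gene_id, class = "unaltered")
    }
    if (n_enh > 0) {
      for (k in seq_len(n_enh)) {
        rows[[length(rows) + 1L]] <- tibble(
          chrom = chrom, start = tss + enh_offsets[k],
          end = tss + enh_offsets[k] + 600L, gene_id = gene_id, class = class)
      }
    }
    bind_rows(rows)
  })
  el_list <- el_list %>%
    arrange(.data$chrom, .data$start, .data$end) %>%
    mutate(element_id = sprintf("el_%06d", dplyr::row_number()))
  tss_tbl <- gene_tbl %>%
    transmute(.data$gene_id, .data$chrom, tss = .data$tss, strand = "+")

  # ---- sample sheet ----
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  lnc_patients <- patients[seq_len(cfg$n_lnc_patients)]
  sheet <- bind_rows(
    tibble(patient_id = patients, tissue = "Nor"),
    tibble(patient_id = patients, tissue = "EC"),
    tibble(patient_id = lnc_patients, tissue = "LNC")
  ) %>%
    mutate(sample_id = paste(.data$patient_id, .data$tissue, sep = "_")) %>%
    select("sample_id", "patient_id", "tissue") %>%
    arrange(.data$patient_id, match(.data$tissue, TISSUES))

  # ---- carriers ----
  planted_idx <- which(el_list$class != "unaltered")
  n_carr <- c(EC = ceiling(cfg$recurrence_fraction * cfg$n_patients),
              LNC = ceiling(cfg$recurrence_fraction * cfg$n_lnc_patients))
  carriers <- with_stream(cfg$seed, "carriers", {
    lapply(planted_idx, function(i) {
      tis <- CLASS_TISSUES[[el_list$class[i]]]
      out <- list(EC = character(0), LNC = character(0))
      if ("EC" %in% tis) out$EC <- sort(sample(patients, n_carr[["EC"]]))
      if ("LNC" %in% tis) out$LNC <- sort(sample(lnc_patients, n_carr[["LNC"]]))
      out
    })
  })

  # ---- signal ----
  n_el <- nrow(el_list)
  samples <- sheet$sample_id
  mult <- matrix(1, n_el, length(samples), dimnames = list(el_list$element_id, samples))
  for (j in seq_along(planted_idx)) {
    i <- planted_idx[j]
    f <- if (el_list$class[i] %in% GAIN_CLASSES) cfg$effect_fc else 1 / cfg$effect_fc
    for (t in CLASS_TISSUES[[el_list$class[i]]]) {
      cols <- paste(carriers[[j]][[t]], t, sep = "_")
      mult[i, cols] <- f
    }
  }
  # Noise decomposes into a patient-level component (shared by all tissues
  # of a patient, cancelled by the paired design) and a residual per-sample
  # component, equal variance shares; total marginal log-sd is noise_sd.
  signal_m <- with_stream(cfg$seed, "signal", {
    base <- stats::rlnorm(n_el, cfg$baseline_meanlog, cfg$baseline_sdlog)
    # planted (recurrently altered) elements are drawn from the upper half of
    # the activity distribution: a recurrent loss presupposes robust baseline
    # activity, and a recurrent gain produces it
    base[planted_idx] <- stats::qlnorm(stats::runif(length(planted_idx), 0.5, 1),
                                       cfg$baseline_meanlog, cfg$baseline_sdlog)
    comp_sd <- cfg$noise_sd / sqrt(2)
    patient_noise <- matrix(stats::rnorm(n_el * cfg$n_patients, 0, comp_sd),
                            n_el, cfg$n_patients, dimnames = list(NULL, patients))
    residual <- matrix(stats::rnorm(n_el * length(samples), 0, comp_sd),
                       n_el, length(samples))
    noise <- exp(patient_noise[, sheet$patient_id, drop = FALSE] + residual)
    base * mult * noise
  })
  dimnames(signal_m) <- list(el_list$element_id, samples)

  # ---- expression ----
  shift_of <- function(class, n_enh, tissue) {
    if (!class %in% names(CLASS_TISSUES)) return(0)
    if (!tissue %in% CLASS_TISSUES[[class]]) return(0)
    sgn <- if (class %in% GAIN_CLASSES) 1 else -1
    sgn * cfg$expr_coupling * n_enh
  }
  gene_truth <- gene_tbl %>%
    mutate(shift_ec = purrr::map2_dbl(.data$class, .data$n_enh, shift_of, tissue = "EC"),
           shift_lnc = purrr::map2_dbl(.data$class, .data$n_enh, shift_of, tissue = "LNC")) %>%
    select("gene_id", "class", "n_enh", "shift_ec", "shift_lnc")
  expr <- with_stream(cfg$seed, "expression", {
    base <- stats::rlnorm(n_genes, cfg$expr_meanlog, cfg$expr_sdlog)
    shift <- cbind(Nor = 0, EC = gene_truth$shift_ec, LNC = gene_truth$shift_lnc)
    tpm <- vapply(seq_along(samples), function(s) {
      tis <- sheet$tissue[s]
      base * 2^shift[, tis] * exp(stats::rnorm(n_genes, 0, cfg$noise_sd))
    }, numeric(n_genes))
    counts <- matrix(stats::rpois(n_genes * length(samples), tpm * 10),
                     n_genes, length(samples))
    list(tpm = tpm, counts = counts)
  })
  dimnames(expr$tpm) <- dimnames(expr$counts) <- list(gene_tbl$gene_id, samples)

  # carriers as list-columns aligned to planted rows
  carrier_ec <- carrier_lnc <- vector("list", n_el)
  for (j in seq_along(planted_idx)) {
    carrier_ec[[planted_idx[j]]] <- carriers[[j]]$EC
    carrier_lnc[[planted_idx[j]]] <- carriers[[j]]$LNC
  }
  truth_el <- el_list %>%
    select("element_id", class = "class", gene_id = "gene_id") %>%
    mutate(carrier_ec = carrier_ec, carrier_lnc = carrier_lnc)

  out <- list(
    elements = el_list %>% select("chrom", "start", "end", "element_id"),
    tss = tss_tbl,
    signal = matrix_to_signal(signal_m, normalized = FALSE),
    counts = matrix_to_signal(expr$counts, id_col = "gene_id"),
    tpm = matrix_to_signal(expr$tpm, id_col = "gene_id"),
    sheet = sheet,
    truth = list(elements = truth_el, genes = gene_truth),
    config = cfg
  )
  class(out) <- "enhancer_cohort"
  out
}

#' Simulate two-group survival records
#'
#' Exponential event times per group (the second group's hazard multiplied by
#' `hazard_ratio`), administratively censored at `follow_up` months.
#'
#' @param n_per_group Subjects per group (>= 1).
#' @param hazard_ratio Hazard of group B relative to group A (> 0).
#' @param follow_up Administrative censoring time in months.
#' @param seed RNG seed.
#' @param base_hazard Monthly baseline hazard of group A (default 0.02).
#' @return Tibble `subject_id`, `time`, `event`, `group`.
#' @export
simulate_survival <- function(n_per_group, hazard_ratio, follow_up = 60,
                              seed = 1, base_hazard = 0.02) {
  if (n_per_group < 1) abort("n_per_group must be >= 1", class = "epr_config_error")
  if (hazard_ratio <= 0) abort("hazard_ratio must be positive", class = "epr_config_error")
  if (follow_up < 0) abort("follow_up must be >= 0", class = "epr_config_error")
  with_stream(seed, "survival", {
    t_a <- stats::rexp(n_per_group, rate = base_hazard)
    t_b <- stats::rexp(n_per_group, rate = base_hazard * hazard_ratio)
    raw <- c(t_a, t_b)
    tibble(
      subject_id = sprintf("S%03d", seq_len(2 * n_per_group)),
      time = pmin(raw, follow_up),
      event = raw <= follow_up,
      group = rep(c("A", "B"), each = n_per_group)
    )
  })
}
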