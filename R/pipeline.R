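# One-config orchestration of the full analysis: simulate (or load) ->
# element classification and normalization -> differential calling and
# six-group classification -> super-enhancers -> expression integration ->
# survival. Emits files plus a digest manifest; identical config and seed
# reproduce identical digests.

#' Pipeline configuration with study-default thresholds
#'
#' Every threshold defaults to the analysis design's stated value: fold
#' change >= 2 with absolute difference >= 0.5 recurrent in >= 6 pairs for
#' element calls; 12,500 bp stitching; SE calls at FC > 2 / < 0.7 and mean
#' difference > 2 / < -2 with >= 5 supporting pairs; CPM > 1 in >= 18
#' samples; DE at FC > 1.5 and FDR < 0.05; survival read out at 24 months.
#'
#' @param simulate A [cohort_config()] describing the synthetic cohort, or
#'   `NULL` when `paths` provide real inputs.
#' @param paths Named list of input paths (`elements`, `tss`, `signal`,
#'   `counts`, `tpm`, `sheet`) used when `simulate` is `NULL`.
#' @param window Promoter window (bp).
#' @param pseudocount Pseudocount for fold changes (RPKM).
#' @param fc_min,diff_min,recurrence Element-call thresholds; `recurrence`
#'   is a named vector per comparison.
#' @param stitch_distance SE stitching gap (bp).
#' @param se_recurrence,se_fc_gain,se_fc_loss,se_gain_diff,se_loss_diff
#'   SE-call thresholds.
#' @param cpm_min,cpm_min_samples Expression retention filter.
#' @param de_fc_min,de_fdr_max Differential-expression thresholds.
#' @param panel_top_corr,panel_top_n Biomarker panel sizes.
#' @param survival_timepoint Survival readout (months).
#' @param seed Seed forwarded to every random component.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list (YAML round-trippable via
#'   [write_pipeline_config()] / [read_pipeline_config()]).
#' @export
pipeline_config <- function(simulate = cohort_config(), paths = NULL,
                            window = 2000, pseudocount = 0.1, fc_min = 2,
                            diff_min = 0.5,
                            recurrence = c(EC_vs_Nor = 6, LNC_vs_Nor = 6,
                                           LNC_vs_EC = 6),
                            stitch_distance = 12500, se_recurrence = 5,
                            se_fc_gain = 2, se_fc_loss = 0.7,
                            se_gain_diff = 2, se_loss_diff = -2,
                            cpm_min = 1, cpm_min_samples = 18,
                            de_fc_min = 1.5, de_fdr_max = 0.05,
                            panel_top_corr = 100, panel_top_n = 10,
                            survival_timepoint = 24, seed = 1,
                            out_dir = tempfile("enhancerpair_run_")) {
  cfg <- as.list(environment())
  if (is.null(simulate) && is.null(paths)) {
    abort("either a simulate block or input paths are required",
          class = "epr_config_error")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @return `path` invisibly; `read_pipeline_config()` returns the config.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$simulate <- if (!is.null(x$simulate)) unclass(x$simulate)
  x$recurrence <- as.list(x$recurrence)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- if (!is.null(x$simulate)) do.call(cohort_config, x$simulate)
  x$simulate <- NULL
  x$recurrence <- unlist(x$recurrence)
  cfg <- do.call(pipeline_config, c(list(simulate = sim), x))
  cfg
}

stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    abort(paste0("stage '", name, "': ", conditionMessage(e)),
          class = "epr_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, element classification and quantile normalization,
#' per-comparison differential calling with six-group classification,
#' super-enhancer identification and differential calling, expression
#' integration (links, DE, dose-response, correlations, biomarker panels,
#' signatures, priming), and survival stratification; writes all result
#' tables under `config$out_dir` and a `manifest.tsv` of md5 digests.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results plus the `manifest`
#'   tibble (`file`, `md5`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(config$out_dir, paste0(...))

  cohort <- stage("inputs", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$seed <- config$seed
      simulate_cohort(sim)
    } else {
      p <- config$paths
      for (need in c("elements", "tss", "signal", "sheet")) {
        if (is.null(p[[need]]) || !file.exists(p[[need]])) {
          abort(paste0("missing input '", need, "'"))
        }
      }
      list(elements = read_peaks(p$elements, "bed6") %>%
             rename(element_id = "name") %>%
             select("chrom", "start", "end", "element_id"),
           tss = read_tss(p$tss),
           signal = read_matrix(p$signal, id_col = "element_id"),
           counts = if (!is.null(p$counts)) read_matrix(p$counts, id_col = "gene_id"),
           tpm = if (!is.null(p$tpm)) read_matrix(p$tpm, id_col = "gene_id"),
           sheet = read_sample_sheet(p$sheet))
    }
  })

  res <- list(config = config)
  res$elements <- stage("elements", {
    el <- classify_elements(cohort$elements, cohort$tss, window = config$window)
    norm <- quantile_normalize(cohort$signal)
    list(catalog = el, signal = norm)
  })
  el <- res$elements$catalog
  norm <- res$elements$signal
  enhancers <- el %>% filter(.data$element_class == "enhancer")
  pairs <- patient_pairs(cohort$sheet)

  res$differential <- stage("differential", {
    enh_signal <- norm %>% filter(.data$element_id %in% enhancers$element_id)
    calls <- lapply(c("EC_vs_Nor", "LNC_vs_Nor"), function(cmp) {
      tab <- pairwise_change(enh_signal, pairs, cmp,
                             pseudocount = config$pseudocount)
      call_differential(tab, fc_min = config$fc_min,
                        diff_min = config$diff_min,
                        recurrence_min = config$recurrence[[cmp]])
    })
    names(calls) <- c("EC_vs_Nor", "LNC_vs_Nor")
    groups <- assign_groups(calls$EC_vs_Nor, calls$LNC_vs_Nor)
    list(calls = calls, groups = groups)
  })

  res$superenhancer <- stage("superenhancer", {
    stitched <- stitch_enhancers(enhancers, config$stitch_distance)
    sig <- se_signal(stitched, el, norm)
    m <- signal_to_matrix(sig)
    group_mean <- rowMeans(m)
    ranked <- rank_superenhancers(tibble(se_id = rownames(m), signal = group_mean))
    mean_calls <- differential_se_mean(sig, cohort$sheet, "EC_vs_Nor",
                                       gain_diff = config$se_gain_diff,
                                       loss_diff = config$se_loss_diff)
    paired_calls <- differential_se_paired(sig, pairs, "EC_vs_Nor",
                                           recurrence_min = config$se_recurrence,
                                           fc_gain = config$se_fc_gain,
                                           fc_loss = config$se_fc_loss,
                                           pseudocount = config$pseudocount)
    combined <- combine_se_calls(mean_calls, paired_calls,
                                 fc_gain = config$se_fc_gain,
                                 fc_loss = config$se_fc_loss,
                                 gain_diff = config$se_gain_diff,
                                 loss_diff = config$se_loss_diff)
    list(stitched = stitched, signal = sig, ranked = ranked,
         combined = combined)
  })

  res$integration <- stage("integration", {
    if (is.null(cohort$tpm)) return(NULL)
    links <- assign_nearest_gene(el, cohort$tss)
    kept <- cpm_filter(cohort$counts, cpm_min = config$cpm_min,
                       min_samples = min(config$cpm_min_samples,
                                         ncol(cohort$counts) - 1L))
    tpm_kept <- cohort$tpm %>% filter(.data$gene_id %in% kept$gene_id)
    de_ec <- de_test(tpm_kept, cohort$sheet, "EC_vs_Nor",
                     fc_min = config$de_fc_min, fdr_max = config$de_fdr_max)
    de_lnc <- de_test(tpm_kept, cohort$sheet, "LNC_vs_Nor",
                      fc_min = config$de_fc_min, fdr_max = config$de_fdr_max)
    fc_ec <- expression_fc(tpm_kept, cohort$sheet, "EC_vs_Nor")
    fc_lnc <- expression_fc(tpm_kept, cohort$sheet, "LNC_vs_Nor")
    groups <- res$differential$groups
    gained_ec <- groups$element_id[groups$group %in% c("G1", "G3")]
    dose <- suppressWarnings(
      enhancer_dose_response(links, gained_ec, fc_ec))
    correlations <- correlate_signal_expression(links, norm, tpm_kept)
    panels <- suppressWarnings(
      select_biomarkers(correlations,
                        list(G1 = fc_ec, G2 = fc_lnc, G3 = fc_ec, G6 = fc_ec),
                        groups, links,
                        top_corr = config$panel_top_corr,
                        top_n = config$panel_top_n))
    signatures <- classify_sample_signature(panels, tpm_kept)
    priming <- classify_priming(groups, de_ec, de_lnc, links)
    list(links = links, de_ec = de_ec, de_lnc = de_lnc, dose = dose,
         correlations = correlations, panels = panels,
         signatures = signatures, priming = priming)
  })

  res$survival <- stage("survival", {
    records <- simulate_survival(n_per_group = 9, hazard_ratio = 2,
                                 follow_up = 60, seed = config$seed)
    km <- lapply(split(records, records$group), km_estimate)
    rates <- vapply(km, survival_at, numeric(1), t = config$survival_timepoint)
    lr <- logrank_test(records)
    list(records = records, km = km, rates = rates, logrank = lr)
  })

  stage("outputs", {
    write_bed(el, outfile("elements.bed"))
    write_matrix(norm, outfile("signal_normalized.tsv"))
    readr::write_tsv(res$differential$groups, outfile("groups.tsv"))
    for (cmp in names(res$differential$calls)) {
      readr::write_tsv(res$differential$calls[[cmp]],
                       outfile("differential_", cmp, ".tsv"))
    }
    write_bed(res$superenhancer$stitched %>%
                mutate(element_id = .data$se_id),
              outfile("superenhancers.bed"))
    readr::write_tsv(res$superenhancer$stitched %>%
                       mutate(constituents = vapply(.data$constituents,
                                                    paste, character(1),
                                                    collapse = ",")),
                     outfile("superenhancers.tsv"))
    readr::write_tsv(as_tibble(res$superenhancer$combined),
                     outfile("differential_se_EC_vs_Nor.tsv"))
    if (!is.null(res$integration)) {
      readr::write_tsv(res$integration$panels, outfile("biomarker_panels.tsv"))
      readr::write_tsv(res$integration$signatures, outfile("signatures.tsv"))
      readr::write_tsv(res$integration$priming, outfile("priming.tsv"))
      readr::write_tsv(res$integration$de_ec, outfile("de_EC_vs_Nor.tsv"))
    }
    readr::write_tsv(as_tibble(res$survival$km[[1]]), outfile("km_groupA.tsv"))
    readr::write_tsv(res$survival$logrank, outfile("logrank.tsv"))
  })

  files <- sort(list.files(config$out_dir, full.names = TRUE,
                           pattern = "\\.(bed|tsv)$"))
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  readr::write_tsv(manifest, outfile("manifest.tsv"))
  res$manifest <- manifest
  invisible(res)
}
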