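suppressPackageStartupMessages(library(dplyr))

# Shared fixtures, built once per test run. The small cohort keeps the
# property tests fast; the full-size acceptance cohort is simulated inside
# test-acceptance.R at its stated scale.

.fixtures <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- cohort_config(n_patients = 10, n_lnc_patients = 8,
                         n_elements = 1200, promoter_fraction = 0.3,
                         n_gained_ec = 20, n_gained_lnc = 20,
                         n_common_gained = 40, n_lost_ec = 20,
                         n_lost_lnc = 20, n_common_lost = 40, seed = 7)
    .fixtures$small <- simulate_cohort(cfg)
  }
  .fixtures$small
}

# Runs the element + differential stages once over a cohort.
cohort_calls <- function(co, recurrence_min = 6, use_raw = FALSE) {
  el <- classify_elements(co$elements, co$tss)
  sig <- if (use_raw) {
    s <- co$signal; attr(s, "normalized") <- TRUE; s
  } else {
    quantile_normalize(co$signal)
  }
  pairs <- patient_pairs(co$sheet)
  enh <- el[el$element_class == "enhancer", ]
  enh_sig <- sig[sig$element_id %in% enh$element_id, ]
  attr(enh_sig, "normalized") <- attr(sig, "normalized")
  calls_ec <- call_differential(pairwise_change(enh_sig, pairs, "EC_vs_Nor"),
                                recurrence_min = recurrence_min)
  calls_lnc <- call_differential(pairwise_change(enh_sig, pairs, "LNC_vs_Nor"),
                                 recurrence_min = recurrence_min)
  list(elements = el, signal = sig, pairs = pairs, enhancers = enh,
       calls_ec = calls_ec, calls_lnc = calls_lnc,
       groups = assign_groups(calls_ec, calls_lnc))
}

random_peaks <- function(n, max_coord = 10000) {
  start <- sample.int(max_coord - 50, n)
  width <- sample.int(200, n)
  tibble::tibble(chrom = "chr1", start = start,
                 end = pmin(start + width, max_coord))
}
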