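# Paired differential calling, significance, and the six-group rule table.

make_pair_signal <- function(values_case, values_ref, n_pairs = 10) {
  # one element, constant across pairs unless vectors given per pair
  ids <- sprintf("P%02d", seq_len(n_pairs))
  sheet <- tibble::tibble(
    sample_id = c(paste0(ids, "_Nor"), paste0(ids, "_EC")),
    patient_id = rep(ids, 2),
    tissue = rep(c("Nor", "EC"), each = n_pairs))
  vals <- c(rep_len(values_ref, n_pairs), rep_len(values_case, n_pairs))
  sig <- tibble::as_tibble(cbind(data.frame(element_id = "e1"),
                                 as.data.frame(t(vals))))
  names(sig) <- c("element_id", sheet$sample_id)
  attr(sig, "normalized") <- TRUE
  list(signal = sig, pairs = patient_pairs(sheet))
}

test_that("pairwise fold changes use the pseudocounted ratio and raw difference", {
  x <- make_pair_signal(3.0, 1.0, n_pairs = 3)
  tab <- pairwise_change(x$signal, x$pairs, "EC_vs_Nor", pseudocount = 0.1)
  expect_equal(tab$fc, rep(3.1 / 1.1, 3), tolerance = 1e-12)
  expect_equal(tab$diff, rep(2, 3))

  zero_ref <- make_pair_signal(1.0, 0.0, n_pairs = 2)
  tab2 <- pairwise_change(zero_ref$signal, zero_ref$pairs, "EC_vs_Nor")
  expect_equal(tab2$fc, rep(11, 2), tolerance = 1e-12)
  expect_equal(tab2$diff, rep(1, 2))

  same <- make_pair_signal(2.0, 2.0, n_pairs = 2)
  tab3 <- pairwise_change(same$signal, same$pairs, "EC_vs_Nor")
  expect_equal(tab3$fc, rep(1, 2))
  expect_equal(tab3$diff, rep(0, 2))
})

test_that("differential calls require fold change, difference, and recurrence", {
  tab <- tibble::tibble(
    element_id = rep(c("gain7", "fc_only", "gain5"), each = 10),
    patient_id = rep(sprintf("P%02d", 1:10), 3),
    fc = c(rep(3, 7), rep(1, 3),      # 7 passing pairs
           rep(3, 10),                # fc passes, diff fails
           rep(3, 5), rep(1, 5)),     # only 5 passing pairs
    diff = c(rep(1, 7), rep(0, 3),
             rep(0.3, 10),
             rep(1, 5), rep(0, 5)))
  calls <- call_differential(tab, fc_min = 2, diff_min = 0.5, recurrence_min = 6)
  calls <- calls[match(c("gain7", "fc_only", "gain5"), calls$element_id), ]
  expect_equal(calls$status, c("gained", "unaltered", "unaltered"))
  expect_equal(calls$recurrence_count[1], 7L)
})

test_that("loss calls are symmetric and raising recurrence is monotone", {
  co <- small_cohort()
  res <- cohort_calls(co)
  enh_sig <- res$signal[res$signal$element_id %in% res$enhancers$element_id, ]
  attr(enh_sig, "normalized") <- TRUE
  tab <- pairwise_change(enh_sig, res$pairs, "EC_vs_Nor")
  n_called <- vapply(4:9, function(r) {
    calls <- call_differential(tab, recurrence_min = r)
    sum(calls$status != "unaltered")
  }, numeric(1))
  expect_true(all(diff(n_called) <= 0))
})

test_that("calls are invariant to element and pair row order", {
  co <- small_cohort()
  res <- cohort_calls(co)
  enh_sig <- res$signal[res$signal$element_id %in% res$enhancers$element_id, ]
  attr(enh_sig, "normalized") <- TRUE
  tab <- pairwise_change(enh_sig, res$pairs, "EC_vs_Nor")
  set.seed(2)
  shuffled <- tab[sample.int(nrow(tab)), ]
  a <- call_differential(tab) %>% dplyr::arrange(element_id)
  b <- call_differential(shuffled) %>% dplyr::arrange(element_id)
  expect_equal(a, b)
})

test_that("paired significance handles degenerate difference vectors", {
  x <- make_pair_signal(2.0, 1.0, n_pairs = 3)  # differences all exactly 1
  calls <- tibble::tibble(element_id = "e1", status = "gained")
  out <- paired_significance(x$signal, x$pairs, calls, "EC_vs_Nor")
  expect_equal(out$p_value, 0)
  expect_equal(out$q_value, 0)

  flat <- make_pair_signal(1.0, 1.0, n_pairs = 3)  # all differences zero
  out2 <- paired_significance(flat$signal, flat$pairs, calls, "EC_vs_Nor")
  expect_equal(out2$p_value, 1)
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  set.seed(8)
  for (i in 1:300) {
    p <- runif(sample.int(50, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("the six-group rule table covers all status combinations", {
  combos <- expand.grid(ec = c("gained", "lost", "unaltered"),
                        lnc = c("gained", "lost", "unaltered"),
                        stringsAsFactors = FALSE)
  calls_ec <- tibble::tibble(element_id = paste0("e", 1:9), status = combos$ec)
  calls_lnc <- tibble::tibble(element_id = paste0("e", 1:9), status = combos$lnc)
  grp <- assign_groups(calls_ec, calls_lnc)
  grp <- grp[match(paste0("e", 1:9), grp$element_id), ]
  lookup <- function(ec, lnc) {
    if (ec == "gained" && lnc == "unaltered") "G1"
    else if (ec == "unaltered" && lnc == "gained") "G2"
    else if (ec == "gained" && lnc == "gained") "G3"
    else if (ec == "lost" && lnc == "unaltered") "G4"
    else if (ec == "unaltered" && lnc == "lost") "G5"
    else if (ec == "lost" && lnc == "lost") "G6"
    else if (ec != "unaltered" && lnc != "unaltered") "discordant"
    else "none"
  }
  expect_equal(grp$group, mapply(lookup, combos$ec, combos$lnc, USE.NAMES = FALSE))
  expect_error(assign_groups(calls_ec[1:3, ], calls_lnc), "different element catalogs")
})

test_that("noise-free cohorts are recovered exactly by the caller", {
  cfg <- cohort_config(n_patients = 10, n_lnc_patients = 8, n_elements = 1200,
                       n_gained_ec = 20, n_gained_lnc = 20, n_common_gained = 40,
                       n_lost_ec = 20, n_lost_lnc = 20, n_common_lost = 40,
                       noise_sd = 0, recurrence_fraction = 1, seed = 3)
  co <- simulate_cohort(cfg)
  res <- cohort_calls(co, use_raw = TRUE)
  truth <- co$truth$elements[co$truth$elements$element_id %in%
                               res$enhancers$element_id, ]
  cmp <- dplyr::inner_join(res$groups, truth, by = "element_id")
  expected <- ifelse(cmp$class == "unaltered", "none", cmp$class)
  expect_identical(cmp$group, expected)
})

test_that("planted per-pair fold change is exact at zero noise and full recurrence", {
  cfg <- cohort_config(n_patients = 4, n_lnc_patients = 4, n_elements = 120,
                       n_gained_ec = 10, n_gained_lnc = 0, n_common_gained = 0,
                       n_lost_ec = 0, n_lost_lnc = 0, n_common_lost = 0,
                       promoter_fraction = 0.2, effect_fc = 4,
                       recurrence_fraction = 1, noise_sd = 0, seed = 5)
  co <- simulate_cohort(cfg)
  m <- as.matrix(co$signal[, -1]); rownames(m) <- co$signal$element_id
  planted <- co$truth$elements$element_id[co$truth$elements$class == "G1"]
  for (p in sprintf("P%02d", 1:4)) {
    ratio <- m[planted, paste0(p, "_EC")] / m[planted, paste0(p, "_Nor")]
    expect_equal(unname(ratio), rep(4, length(planted)), tolerance = 1e-12)
  }
})
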