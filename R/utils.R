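# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom generics tidy glance
NULL

# Comparisons are always case-vs-reference in this fixed orientation.
COMPARISONS <- c("EC_vs_Nor", "LNC_vs_Nor", "LNC_vs_EC")
TISSUES <- c("Nor", "EC", "LNC")

comparison_tissues <- function(comparison) {
  switch(comparison,
    EC_vs_Nor  = c(case = "EC",  ref = "Nor"),
    LNC_vs_Nor = c(case = "LNC", ref = "Nor"),
    LNC_vs_EC  = c(case = "LNC", ref = "EC"),
    abort(paste0("unknown comparison '", comparison, "'"), class = "epr_config_error")
  )
}

# Signal tibbles carry samples as columns and a single `element_id` (or
# `gene_id`) key column; these helpers convert to/from a base matrix.
signal_to_matrix <- function(tbl, id_col = NULL) {
  if (is.null(id_col)) id_col <- names(tbl)[1]
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  rownames(m) <- tbl[[id_col]]
  storage.mode(m) <- "double"
  m
}

matrix_to_signal <- function(m, id_col = "element_id", normalized = FALSE) {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- bind_cols(tibble(!!id_col := rownames(m)), out)
  attr(out, "normalized") <- normalized
  out
}

is_normalized <- function(tbl) isTRUE(attr(tbl, "normalized"))

check_columns <- function(tbl, cols, what) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing column(s): ", paste(missing, collapse = ", ")),
          class = "epr_format_error")
  }
  invisible(tbl)
}

# Deterministic sub-seed per named stream so adding one simulated component
# never perturbs the draws of another. Kept below 2^31.
stream_seed <- function(seed, stream) {
  streams <- c(layout = 1L, signal = 2L, expression = 3L, survival = 4L,
               carriers = 5L, misc = 6L)
  if (!stream %in% names(streams)) abort(paste0("unknown RNG stream '", stream, "'"))
  (as.integer(seed) %% 20000000L) * 100L + streams[[stream]]
}

with_stream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  force(code)
}
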