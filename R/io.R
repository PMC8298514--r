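# Readers and writers for the plain-text formats the pipeline touches:
# BED3/BED6/narrowPeak peak calls, sample sheets, signal/expression matrices,
# and TSS annotation. Coordinates are 0-based half-open (BED convention)
# everywhere inside the package; the only 1-based dialect accepted is a
# GTF-derived TSS table, converted on read.

#' Read peak calls from BED3, BED6 or ENCODE narrowPeak
#'
#' @param path Path to a tab-separated peak file without header.
#' @param format One of `"bed3"`, `"bed6"`, `"narrowPeak"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand` and,
#'   depending on the format, `name`, `score` and `summit` (absolute summit
#'   coordinate, `NA` when the narrowPeak summit offset is -1). Input order is
#'   preserved.
#' @details Coordinates are 0-based half-open. Rows with `start >= end` are
#'   rejected with an error naming the offending line.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t600", tf)
#' read_peaks(tf, "bed3")
#' @export
read_peaks <- function(path, format = c("bed3", "bed6", "narrowPeak")) {
  format <- tryCatch(match.arg(format), error = function(e)
    abort(paste0("unknown peak format '", format[1], "'"), class = "epr_config_error"))
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "epr_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ncols <- switch(format, bed3 = 3L, bed6 = 6L, narrowPeak = 10L)
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < ncols)
  if (length(bad) > 0) {
    abort(paste0("expected >=", ncols, " columns at line ", bad[1]),
          class = "epr_format_error")
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  nn <- which(is.na(start) | is.na(end))
  if (length(nn) > 0) {
    abort(paste0("non-numeric coordinate at line ", nn[1]), class = "epr_format_error")
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(paste0("start >= end at line ", bad[1]), class = "epr_format_error")
  }
  if (any(start < 0)) {
    abort(paste0("negative start at line ", which(start < 0)[1]),
          class = "epr_format_error")
  }
  out <- tibble(chrom = col(1), start = start, end = end)
  if (format == "bed3") {
    out$strand <- "."
  } else {
    out$name <- col(4)
    out$score <- suppressWarnings(as.numeric(col(5)))
    strand <- col(6)
    strand[!strand %in% c("+", "-", ".")] <- "."
    out$strand <- strand
  }
  if (format == "narrowPeak") {
    offset <- suppressWarnings(as.integer(col(10)))
    out$summit <- ifelse(is.na(offset) | offset < 0, NA_integer_, start + offset)
  }
  out
}

#' Read and validate a cohort sample sheet
#'
#' @param path TSV with header columns `sample_id`, `patient_id`, `tissue`
#'   (`Nor`, `EC` or `LNC`).
#' @return A validated tibble. Patients contributing to no complete pair
#'   trigger a warning.
#' @seealso [patient_pairs()] for the derived per-comparison pair table.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "epr_io_error")
  sheet <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             check.names = FALSE)
  validate_sample_sheet(as_tibble(sheet))
}

validate_sample_sheet <- function(sheet) {
  check_columns(sheet, c("sample_id", "patient_id", "tissue"), "sample sheet")
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sample_id: ", dup[1]), class = "epr_format_error")
  }
  bad <- setdiff(unique(sheet$tissue), TISSUES)
  if (length(bad) > 0) {
    abort(paste0("unknown tissue '", bad[1], "' (expected Nor, EC or LNC)"),
          class = "epr_format_error")
  }
  key <- paste(sheet$patient_id, sheet$tissue)
  if (anyDuplicated(key)) {
    abort(paste0("duplicated (patient_id, tissue): ", key[duplicated(key)][1]),
          class = "epr_format_error")
  }
  unpaired <- sheet %>%
    group_by(.data$patient_id) %>%
    filter(n() == 1) %>%
    pull(.data$patient_id)
  if (length(unpaired) > 0) {
    warn(paste0("patient(s) with a single tissue contribute to no pair: ",
                paste(unpaired, collapse = ", ")))
  }
  sheet
}

#' Derive complete patient pairs for each comparison
#'
#' A patient contributes a pair to a comparison when both tissues of that
#' comparison are present. The result is independent of sheet row order.
#'
#' @param sheet A sample sheet (see [read_sample_sheet()]).
#' @param comparison Optional subset of `"EC_vs_Nor"`, `"LNC_vs_Nor"`,
#'   `"LNC_vs_EC"`.
#' @return Tibble with columns `comparison`, `patient_id`, `case_sample`,
#'   `ref_sample`, sorted by comparison then patient.
#' @export
patient_pairs <- function(sheet, comparison = COMPARISONS) {
  sheet <- validate_sample_sheet(sheet)
  comparison <- match.arg(comparison, COMPARISONS, several.ok = TRUE)
  purrr::map_dfr(comparison, function(cmp) {
    tis <- comparison_tissues(cmp)
    case <- sheet %>% filter(.data$tissue == tis[["case"]])
    ref <- sheet %>% filter(.data$tissue == tis[["ref"]])
    inner_join(
      case %>% select(patient_id = "patient_id", case_sample = "sample_id"),
      ref %>% select(patient_id = "patient_id", ref_sample = "sample_id"),
      by = "patient_id"
    ) %>%
      mutate(comparison = cmp, .before = 1) %>%
      arrange(.data$patient_id)
  })
}

#' Read a labeled numeric matrix from TSV
#'
#' First column holds row identifiers, remaining columns are numeric. Missing
#' or non-numeric cells are errors (never imputed); duplicate row ids are
#' errors.
#'
#' @param path TSV path.
#' @param id_col Name to give the identifier column (default taken from the
#'   file header).
#' @return Tibble: id column plus one numeric column per sample.
#' @export
read_matrix <- function(path, id_col = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "epr_io_error")
  lines <- readLines(path)
  if (length(lines) < 1) abort("empty matrix file", class = "epr_format_error")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nc <- length(header)
  badlen <- which(vapply(body, length, 1L) != nc)
  if (length(badlen) > 0) {
    abort(paste0("column count mismatch at line ", badlen[1] + 1L),
          class = "epr_format_error")
  }
  ids <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate row id: ", ids[duplicated(ids)][1]),
          class = "epr_format_error")
  }
  samples <- header[-1]
  vals <- matrix(NA_real_, nrow = length(body), ncol = nc - 1L,
                 dimnames = list(ids, samples))
  for (j in seq_len(nc - 1L)) {
    colchr <- vapply(body, `[[`, character(1), j + 1L)
    v <- suppressWarnings(as.numeric(colchr))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      abort(paste0("non-numeric cell '", colchr[bad[1]], "' at row '",
                   ids[bad[1]], "', column '", samples[j], "'"),
            class = "epr_format_error")
    }
    vals[, j] <- v
  }
  if (is.null(id_col)) id_col <- if (nzchar(header[1])) header[1] else "id"
  matrix_to_signal(vals, id_col = id_col)
}

#' Write a labeled matrix as TSV with a fixed float format
#'
#' Floats are printed as `%.6g` so that write/read round-trips are
#' byte-identical.
#'
#' @param tbl Tibble whose first column is the row identifier.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(tbl, path) {
  id_col <- names(tbl)[1]
  m <- signal_to_matrix(tbl, id_col)
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.6g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write elements as a sorted BED6 file
#'
#' @param elements Tibble with `chrom`, `start`, `end`, an identifier column
#'   (`element_id` or `name`) and optionally `mean_signal`.
#' @param path Output path.
#' @param score_scale Multiplier from mean signal to BED score; scores are
#'   clipped to \[0, 1000\].
#' @return `path`, invisibly. Rows are sorted by (chrom, start, end).
#' @export
write_bed <- function(elements, path, score_scale = 100) {
  if (nrow(elements) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  check_columns(elements, c("chrom", "start", "end"), "element table")
  name <- if ("element_id" %in% names(elements)) elements$element_id
          else if ("name" %in% names(elements)) elements$name
          else paste0("el_", seq_len(nrow(elements)))
  sig <- if ("mean_signal" %in% names(elements)) elements$mean_signal else 0
  score <- pmin(1000, pmax(0, round(sig * score_scale)))
  out <- tibble(chrom = elements$chrom, start = elements$start,
                end = elements$end, name = name, score = score, strand = ".") %>%
    arrange(.data$chrom, .data$start, .data$end)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", out$chrom, out$start, out$end,
                     out$name, as.integer(out$score), out$strand), path)
  invisible(path)
}

#' Read TSS annotation
#'
#' Accepts the package's minimal TSS TSV (`gene_id`, `chrom`, `tss`,
#' `strand`; 0-based) or BED6 gene spans from which the strand-aware TSS is
#' derived (start for `+`, `end - 1` for `-`).
#'
#' @param path Input path.
#' @param format `"tsv"` or `"bed6"`.
#' @param one_based Set `TRUE` for a 1-based (GTF-derived) TSS TSV; positions
#'   are shifted to the package's 0-based convention.
#' @return Tibble `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss <- function(path, format = c("tsv", "bed6"), one_based = FALSE) {
  format <- match.arg(format)
  if (format == "bed6") {
    spans <- read_peaks(path, "bed6")
    out <- tibble(gene_id = spans$name, chrom = spans$chrom,
                  tss = ifelse(spans$strand == "-", spans$end - 1L, spans$start),
                  strand = spans$strand)
  } else {
    tbl <- as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
    check_columns(tbl, c("gene_id", "chrom", "tss", "strand"), "TSS table")
    out <- tbl %>% select("gene_id", "chrom", "tss", "strand")
    if (one_based) out$tss <- out$tss - 1L
  }
  if (any(out$tss < 0)) abort("negative TSS coordinate", class = "epr_format_error")
  if (anyDuplicated(out$gene_id)) {
    abort(paste0("duplicate gene_id: ", out$gene_id[duplicated(out$gene_id)][1]),
          class = "epr_format_error")
  }
  out
}
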