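#' Read a Ct table from CSV/TSV
#'
#' Two dialects: `wide` (first column = gene ID, remaining columns = one
#' sample each) and `long` (columns `sample`, `gene`, `replicate`, `ct`;
#' `replicate` optional). The delimiter is auto-detected from the file
#' extension (`.csv` = comma, otherwise tab). Some qPCR exports use a
#' decimal comma; `decimal_comma = TRUE` converts on read.
#'
#' @param path File path.
#' @param dialect `"wide"` or `"long"`.
#' @param decimal_comma Read numbers with "," as the decimal separator.
#' @param sample_info Optional tibble `sample`, `tissue` joined onto the
#'   result.
#' @return A tidy Ct tibble (`gene`, `sample`, `ct`, plus `replicate` /
#'   `tissue` where available). Duplicate (gene, sample, replicate) keys
#'   and non-numeric Ct values are errors naming the offending rows.
#' @export
read_ct_table <- function(path, dialect = c("wide", "long"),
                          decimal_comma = FALSE, sample_info = NULL) {
  dialect <- match.arg(dialect)
  raw <- read_delim_auto(path, decimal_comma = decimal_comma)
  if (dialect == "wide") {
    if (ncol(raw) < 2) {
      abort_refstab("Wide Ct table needs a gene column plus >= 1 sample.",
                    "parse_error")
    }
    names(raw)[1] <- "gene"
    out <- raw %>%
      tidyr::pivot_longer(-"gene", names_to = "sample",
                          values_to = "ct_raw") %>%
      mutate(row = rep(seq_len(nrow(raw)), each = ncol(raw) - 1))
  } else {
    names(raw) <- tolower(names(raw))
    needed <- c("sample", "gene", "ct")
    missing_cols <- setdiff(needed, names(raw))
    if (length(missing_cols) > 0) {
      abort_refstab(
        paste0("Long Ct table is missing column(s): ",
               toString(missing_cols)),
        "parse_error"
      )
    }
    out <- raw %>%
      rename(ct_raw = "ct") %>%
      mutate(row = seq_len(nrow(raw)))
  }
  ct_num <- parse_numeric_strict(out$ct_raw, out$row, what = "Ct")
  out <- out %>%
    mutate(ct = ct_num) %>%
    select(-"ct_raw", -"row")
  key_cols <- intersect(c("gene", "sample", "replicate"), names(out))
  dup <- out %>% count(across(all_of(key_cols))) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_refstab(
      paste0("Duplicate (", toString(key_cols), ") keys, e.g.: ",
             paste(unlist(dup[1, key_cols]), collapse = " / ")),
      "duplicate_keys"
    )
  }
  if (!is.null(sample_info)) {
    out <- out %>% left_join(sample_info, by = "sample")
  }
  out %>% select(any_of(c("gene", "sample", "tissue", "animal",
                          "replicate", "ct")))
}

read_delim_auto <- function(path, decimal_comma = FALSE) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  locale <- readr::locale(decimal_mark = if (decimal_comma) "," else ".",
                          grouping_mark = "")
  readr::read_delim(path, delim = delim, col_types = readr::cols(),
                    locale = locale, progress = FALSE,
                    show_col_types = FALSE)
}

parse_numeric_strict <- function(x, row, what = "value") {
  if (is.numeric(x)) return(as.numeric(x))
  parsed <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(parsed) & !is.na(x))
  if (length(bad) > 0) {
    abort_refstab(
      paste0("Non-numeric ", what, " '", x[bad[1]], "' at data row ",
             row[bad[1]], "."),
      "parse_error"
    )
  }
  parsed
}

#' Write a Ct table to CSV/TSV
#'
#' @param ct_data Tidy Ct tibble.
#' @param path Output path (`.csv` = comma, otherwise tab).
#' @param dialect `"long"` (default; keeps replicate structure) or
#'   `"wide"` (replicates averaged, genes x samples).
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct_data, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    reduced <- reduce_replicates(ct_data)
    out <- reduced %>%
      select("gene", "sample", "ct") %>%
      tidyr::pivot_wider(names_from = "sample", values_from = "ct")
  } else {
    out <- ct_data
  }
  write_table_auto(out, path)
  invisible(path)
}

write_table_auto <- function(x, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(x, path)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}

#' Read a wide TPM abundance table
#'
#' First column = transcript ID, remaining columns = samples.
#'
#' @inheritParams read_ct_table
#' @return A tidy tibble `transcript_id`, `sample`, `tpm` (plus `tissue`
#'   when `sample_info` is given).
#' @export
read_tpm_table <- function(path, decimal_comma = FALSE, sample_info = NULL) {
  raw <- read_delim_auto(path, decimal_comma = decimal_comma)
  names(raw)[1] <- "transcript_id"
  out <- raw %>%
    tidyr::pivot_longer(-"transcript_id", names_to = "sample",
                        values_to = "tpm_raw") %>%
    mutate(row = rep(seq_len(nrow(raw)), each = ncol(raw) - 1))
  out$tpm <- parse_numeric_strict(out$tpm_raw, out$row, what = "TPM")
  out <- out %>% select(-"tpm_raw", -"row")
  if (!is.null(sample_info)) {
    out <- out %>% left_join(sample_info, by = "sample")
  }
  validate_tpm_data(out)
  out
}

#' Load the packaged multi-tissue CV table
#'
#' A packaged fixture mirroring the published screening summary of an
#' octopus (*Octopus vulgaris*) multi-tissue study: 77 transcript rows
#' selected in silico across four tissue groups (Nervous, Adult, Arm,
#' Brain) plus 8 reference genes from previous cephalopod studies, with
#' the printed CV percentages.
#'
#' @return A candidate tibble `transcript_id`, `group`, `gene_name`,
#'   `accession`, `cv_percent`, `source`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_cv.tsv", package = "refstab",
                      mustWork = TRUE)
  fx <- readr::read_tsv(path, col_types = "ccccdc", progress = FALSE)
  expected_cols <- c("transcript_id", "group", "gene_name", "accession",
                     "cv_percent", "source")
  counts <- table(fx$group)
  ok <- identical(names(fx), expected_cols) &&
    nrow(fx) == 85 &&
    sum(fx$source == "in_silico") == 77 &&
    sum(fx$source == "previously_published") == 8 &&
    identical(as.integer(counts[c("Adult", "Arm", "Brain", "Nervous")]),
              c(19L, 19L, 20L, 19L)) &&
    all(is.finite(fx$cv_percent)) && all(fx$cv_percent > 0)
  if (!ok) {
    abort_refstab("Packaged CV table is corrupted.", "corrupted_fixture")
  }
  fx
}
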