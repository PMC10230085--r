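#' Define tissue groups and CV cutoffs
#'
#' A tissue grouping maps named groups to their member tissue labels and,
#' for screening, to a CV cutoff in percent. Groups may overlap.
#'
#' @param groups Named list: group name -> character vector of tissue
#'   labels.
#' @param cutoffs Named numeric vector of CV cutoffs in percent (one per
#'   group, all > 0), or a single value recycled; may be omitted for
#'   stability groupings.
#' @return A tibble `group`, `tissue`, `cutoff`.
#' @examples
#' tissue_grouping(list(Brain = c("SEM", "SUB", "OL")), c(Brain = 15))
#' @export
tissue_grouping <- function(groups, cutoffs = NULL) {
  if (!is.list(groups) || is.null(names(groups)) ||
      any(names(groups) == "")) {
    abort_refstab("`groups` must be a named list of tissue vectors.",
                  "invalid_grouping")
  }
  if (any(lengths(groups) == 0)) {
    abort_refstab("Every group must have at least one member tissue.",
                  "invalid_grouping")
  }
  if (is.null(cutoffs)) {
    cutoffs <- setNames(rep(NA_real_, length(groups)), names(groups))
  } else if (length(cutoffs) == 1 && is.null(names(cutoffs))) {
    cutoffs <- setNames(rep(cutoffs, length(groups)), names(groups))
  }
  missing_cut <- setdiff(names(groups), names(cutoffs))
  if (length(missing_cut) > 0) {
    abort_refstab(paste0("No cutoff for group(s): ", toString(missing_cut)),
                  "invalid_grouping")
  }
  if (any(!is.na(cutoffs) & cutoffs <= 0)) {
    abort_refstab("Cutoffs must be > 0.", "invalid_grouping")
  }
  purrr::imap(groups, function(tis, g) {
    tibble(group = g, tissue = as.character(tis), cutoff = cutoffs[[g]])
  }) %>%
    bind_rows()
}

#' Default tissue groupings
#'
#' `screen_grouping_default()` returns the transcriptome-screen groups:
#' Brain (SEM, SUB, OL; cutoff 15%), Nervous (Brain + StG, GG; 15%),
#' Arm (Tip_R1, ARM_R1, MUSC_R1, ARM_R4; 15%) and Adult (all nine
#' RNA-seq tissues; 20%, relaxed for the higher whole-body variability).
#'
#' `stability_grouping_default()` returns the qPCR stability groups:
#' Nervous (SEM, SUB, OL, GG, StG), Allex (Nervous plus GILL, MANT,
#' ARM_R1, ARM_R4, MUSC_R1 — everything except the arm tips) and Adult
#' (Allex plus Tip_R1 and Tip_R4).
#'
#' @return A tibble as from [tissue_grouping()].
#' @export
screen_grouping_default <- function() {
  brain <- c("SEM", "SUB", "OL")
  nervous <- c(brain, "StG", "GG")
  arm <- c("Tip_R1", "ARM_R1", "MUSC_R1", "ARM_R4")
  tissue_grouping(
    list(Adult = c(nervous, arm), Brain = brain, Nervous = nervous,
         Arm = arm),
    cutoffs = c(Adult = 20, Brain = 15, Nervous = 15, Arm = 15)
  )
}

#' @rdname screen_grouping_default
#' @export
stability_grouping_default <- function() {
  nervous <- c("SEM", "SUB", "OL", "GG", "StG")
  allex <- c(nervous, "GILL", "MANT", "ARM_R1", "ARM_R4", "MUSC_R1")
  tissue_grouping(list(
    Nervous = nervous,
    Allex = allex,
    Adult = c(allex, "Tip_R1", "Tip_R4")
  ))
}

validate_tpm_data <- function(tpm_data) {
  needed <- c("transcript_id", "sample", "tpm")
  missing_cols <- setdiff(needed, names(tpm_data))
  if (length(missing_cols) > 0) {
    abort_refstab(
      paste0("`tpm_data` is missing column(s): ", toString(missing_cols)),
      "missing_columns"
    )
  }
  if (any(tpm_data$tpm < 0, na.rm = TRUE)) {
    abort_refstab("Abundances must be >= 0.", "negative_abundance")
  }
  invisible(tpm_data)
}

#' Keep transcripts expressed above a floor in every sample
#'
#' Retains transcripts whose abundance is strictly greater than `floor`
#' in all samples — the conventional screen that candidate reference
#' genes must be detectably expressed everywhere. Transcript order is
#' preserved.
#'
#' @param tpm_data Tidy abundance tibble: `transcript_id`, `sample`,
#'   `tpm` (plus any metadata columns, carried through).
#' @param floor Abundance floor (>= 0); default 1.5.
#' @return The filtered tibble. Warns (does not error) if nothing
#'   survives.
#' @export
apply_expression_floor <- function(tpm_data, floor = 1.5) {
  validate_tpm_data(tpm_data)
  if (floor < 0) abort_refstab("`floor` must be >= 0.", "invalid_floor")
  keep <- tpm_data %>%
    group_by(.data$transcript_id) %>%
    summarise(keep = all(.data$tpm > floor), .groups = "drop") %>%
    filter(.data$keep)
  out <- tpm_data %>% semi_join(keep, by = "transcript_id")
  if (nrow(out) == 0) {
    warn("No transcript exceeds the expression floor in every sample.")
  }
  out
}

#' Coefficient of variation of abundance within tissue groups
#'
#' For each group, pools all samples whose tissue belongs to the group
#' and computes, per transcript, `cv_percent = 100 * sd / mean` with the
#' sample (n - 1) standard deviation. Transcripts with zero group mean
#' have no defined CV; they are dropped with a warning.
#'
#' @inheritParams apply_expression_floor
#' @param grouping A [tissue_grouping()] tibble (needs `group`, `tissue`;
#'   `cutoff` carried through if present).
#' @param sample_info Optional tibble `sample`, `tissue`; not needed if
#'   `tpm_data` already has a `tissue` column.
#' @return A tibble `transcript_id`, `group`, `cv_percent` (one row per
#'   transcript x group with >= 2 member samples).
#' @export
compute_group_cv <- function(tpm_data, grouping, sample_info = NULL) {
  validate_tpm_data(tpm_data)
  if (!is.null(sample_info)) {
    tpm_data <- tpm_data %>%
      select(-any_of("tissue")) %>%
      left_join(sample_info, by = "sample")
  }
  if (!"tissue" %in% names(tpm_data)) {
    abort_refstab("Provide tissue labels via `sample_info` or a `tissue` column.",
                  "missing_columns")
  }
  groups <- unique(grouping$group)
  purrr::map(groups, function(g) {
    member <- grouping$tissue[grouping$group == g]
    sub <- tpm_data %>% filter(.data$tissue %in% member)
    if (n_distinct(sub$sample) < 2) {
      abort_refstab(
        paste0("Group '", g, "' has fewer than 2 member samples."),
        "invalid_grouping"
      )
    }
    cv <- sub %>%
      group_by(.data$transcript_id) %>%
      summarise(mean_tpm = mean(.data$tpm), sd_tpm = sd(.data$tpm),
                .groups = "drop")
    undefined <- cv$transcript_id[cv$mean_tpm == 0]
    if (length(undefined) > 0) {
      warn(paste0("Group '", g, "': CV undefined (zero mean) for ",
                  length(undefined), " transcript(s); excluded."))
    }
    cv %>%
      filter(.data$mean_tpm > 0) %>%
      mutate(group = g, cv_percent = 100 * .data$sd_tpm / .data$mean_tpm) %>%
      select("transcript_id", "group", "cv_percent")
  }) %>%
    bind_rows()
}

#' Flag candidate reference genes against per-group CV cutoffs
#'
#' Joins CV records to the grouping's cutoffs and flags
#' `passes_cutoff = cv_percent < cutoff` (strict). Non-annotated
#' transcripts (no gene name) are dropped before flagging, since only
#' annotated candidates proceed to validation.
#'
#' @param cv_records Tibble from [compute_group_cv()] (columns
#'   `transcript_id`, `group`, `cv_percent`), or any candidate table with
#'   those columns.
#' @param grouping A [tissue_grouping()] tibble with non-missing cutoffs.
#' @param annotation Optional tibble `transcript_id`, `gene_name`;
#'   transcripts absent from it (or with `NA` gene name) are treated as
#'   non-annotated and dropped. If `cv_records` already has a
#'   `gene_name` column it is used directly.
#' @return A candidate tibble `transcript_id`, `gene_name`, `group`,
#'   `cv_percent`, `cutoff`, `passes_cutoff`.
#' @export
screen_candidates <- function(cv_records, grouping, annotation = NULL) {
  if (!is.null(annotation)) {
    cv_records <- cv_records %>%
      select(-any_of("gene_name")) %>%
      left_join(annotation, by = "transcript_id")
  }
  if (!"gene_name" %in% names(cv_records)) {
    abort_refstab("Provide `annotation` or a `gene_name` column.",
                  "missing_columns")
  }
  cutoffs <- grouping %>% distinct(.data$group, .data$cutoff)
  unknown <- setdiff(unique(cv_records$group), cutoffs$group)
  if (length(unknown) > 0) {
    abort_refstab(paste0("Unknown group(s): ", toString(unknown)),
                  "unknown_group")
  }
  if (any(is.na(cutoffs$cutoff))) {
    abort_refstab("Grouping has no cutoffs; supply them via tissue_grouping().",
                  "invalid_grouping")
  }
  cv_records %>%
    filter(!is.na(.data$gene_name)) %>%
    select(-any_of("cutoff")) %>%
    left_join(cutoffs, by = "group") %>%
    mutate(passes_cutoff = .data$cv_percent < .data$cutoff) %>%
    select("transcript_id", "gene_name", "group", "cv_percent", "cutoff",
           "passes_cutoff")
}

#' Genes whose transcript appears in more than one group
#'
#' @param candidates A candidate tibble with `transcript_id`, `gene_name`
#'   and `group` columns.
#' @return Sorted character vector of unique gene names whose transcript
#'   ID occurs under two or more distinct groups.
#' @export
shared_across_groups <- function(candidates) {
  shared <- candidates %>%
    distinct(.data$transcript_id, .data$group, .data$gene_name) %>%
    group_by(.data$transcript_id) %>%
    filter(n_distinct(.data$group) >= 2) %>%
    ungroup()
  sort(unique(shared$gene_name))
}

#' Summarise CV statistics for one group of candidates
#'
#' @param candidates A candidate tibble with `transcript_id`, `gene_name`,
#'   `group` and `cv_percent`.
#' @param group Group name to summarise.
#' @param thresholds Optional numeric CV thresholds (percent); for each,
#'   the count of transcripts and of unique gene names with CV strictly
#'   below it is reported.
#' @return A one-row tibble: `group`, `n_transcripts`, `n_genes`,
#'   `cv_mean`, `cv_min`, `cv_max`, plus a nested `below` tibble
#'   (`threshold`, `n_transcripts`, `n_genes`) when thresholds are given.
#' @export
summarize_group <- function(candidates, group, thresholds = NULL) {
  rows <- candidates[candidates$group == group, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort_refstab(paste0("Group '", group, "' is empty."), "empty_group")
  }
  out <- tibble(
    group = group,
    n_transcripts = n_distinct(rows$transcript_id),
    n_genes = n_distinct(rows$gene_name),
    cv_mean = mean(rows$cv_percent),
    cv_min = min(rows$cv_percent),
    cv_max = max(rows$cv_percent)
  )
  if (!is.null(thresholds)) {
    below <- purrr::map(thresholds, function(th) {
      sub <- rows[rows$cv_percent < th, , drop = FALSE]
      tibble(threshold = th,
             n_transcripts = n_distinct(sub$transcript_id),
             n_genes = n_distinct(sub$gene_name))
    }) %>% bind_rows()
    out$below <- list(below)
  }
  out
}
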