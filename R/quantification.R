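#' Per-sample normalization factor from reference genes
#'
#' The normalization factor of a sample is the geometric mean of the
#' relative quantities (see [ct_to_quantity()]) of the chosen reference
#' genes in that sample. With a single reference the factor is that
#' gene's quantity.
#'
#' @inheritParams ct_to_quantity
#' @param ref_genes Character vector of reference gene IDs present in
#'   `ct_data`.
#' @return A tibble `sample`, `nf`.
#' @export
normalization_factor <- function(ct_data, ref_genes, efficiency = 2) {
  validate_ct_data(ct_data)
  missing_genes <- setdiff(ref_genes, unique(ct_data$gene))
  if (length(ref_genes) < 1 || length(missing_genes) > 0) {
    abort_refstab(
      paste0("Reference gene(s) not in data: ", toString(missing_genes)),
      "missing_gene"
    )
  }
  ct_to_quantity(ct_data %>% filter(.data$gene %in% ref_genes),
                 efficiency = efficiency) %>%
    group_by(.data$sample) %>%
    summarise(nf = geomean(.data$quantity), .groups = "drop")
}

#' Efficiency-corrected relative expression against a calibrator tissue
#'
#' Pfaffl-style ratios: for each target gene and sample,
#' `ratio = E_t^(Ct_cal - Ct_sample) / prod_r E_r^(Ct_cal,r - Ct_sample,r)^(1/n_ref)`,
#' i.e. the target's efficiency-corrected fold change over the
#' calibrator, divided by the geometric mean of the reference genes' fold
#' changes. The calibrator Ct of each gene is the mean Ct across the
#' calibrator tissue's samples, so the calibrator tissue's ratios average
#' about 1 by construction. With all efficiencies at 2 this reduces
#' exactly to the classical `2^-ddCt`.
#'
#' @inheritParams normalization_factor
#' @param targets Character vector of target gene IDs.
#' @param calibrator Calibrator tissue label (must appear in the data's
#'   `tissue` column).
#' @param efficiency Amplification factors per cycle (scalar, named
#'   vector or data frame) covering targets and references; default 2
#'   (100% efficiency).
#' @return A tibble `target`, `sample`, `tissue` (and `animal` when
#'   present), `ratio`, `normalizer`.
#' @export
pfaffl_ratio <- function(ct_data, targets, ref_genes, calibrator,
                         efficiency = 2) {
  validate_ct_data(ct_data, require_tissue = TRUE)
  reduced <- reduce_replicates(ct_data)
  genes <- unique(c(targets, ref_genes))
  missing_genes <- setdiff(genes, unique(reduced$gene))
  if (length(missing_genes) > 0) {
    abort_refstab(paste0("Gene(s) not in data: ", toString(missing_genes)),
                  "missing_gene")
  }
  if (!calibrator %in% reduced$tissue) {
    abort_refstab(paste0("Calibrator tissue '", calibrator,
                         "' not present in the data."),
                  "missing_calibrator")
  }
  eff <- resolve_efficiency(genes, efficiency)

  cal <- reduced %>%
    filter(.data$tissue == calibrator, .data$gene %in% genes) %>%
    group_by(.data$gene) %>%
    summarise(ct_cal = mean(.data$ct), .groups = "drop")
  no_cal <- setdiff(genes, cal$gene)
  if (length(no_cal) > 0) {
    abort_refstab(
      paste0("No calibrator measurement for gene(s): ", toString(no_cal)),
      "missing_calibrator"
    )
  }

  # efficiency-corrected fold change over the calibrator, per gene/sample
  fold <- reduced %>%
    filter(.data$gene %in% genes) %>%
    left_join(cal, by = "gene") %>%
    mutate(fold = unname(eff[.data$gene]) ^ (.data$ct_cal - .data$ct))

  nf <- fold %>%
    filter(.data$gene %in% ref_genes) %>%
    group_by(.data$sample) %>%
    summarise(nf = geomean(.data$fold), .groups = "drop")

  meta <- intersect(c("tissue", "animal"), names(fold))
  fold %>%
    filter(.data$gene %in% targets) %>%
    left_join(nf, by = "sample") %>%
    mutate(ratio = .data$fold / .data$nf,
           normalizer = paste(ref_genes, collapse = "+")) %>%
    rename(target = "gene") %>%
    select("target", "sample", all_of(meta), "ratio", "normalizer")
}

#' Compare relative expression across tissues
#'
#' Per target gene: one-way ANOVA of log2 ratios across tissues, followed
#' by all pairwise two-sample pooled-variance t tests with Bonferroni
#' adjustment (`p_adj = min(1, p_raw * n_pairs)`; the family is the set
#' of pairwise tissue comparisons for that gene). Tests are two-tailed.
#'
#' @param ratios Tibble from [pfaffl_ratio()] (columns `target`,
#'   `tissue`, `ratio` > 0).
#' @param alpha Significance level (0 < alpha < 1), default 0.05.
#' @return A `ratio_comparison` object: list with `anova` (per-target
#'   `f_statistic`, `df_between`, `df_within`, `p_value`), `pairwise`
#'   (per tissue pair `estimate` = log2 mean difference, `p_raw`,
#'   `p_adj`, `significant`) and `alpha`. Supports [tidy()] (pairwise)
#'   and [glance()] (ANOVA).
#' @export
compare_groups <- function(ratios, alpha = 0.05) {
  needed <- c("target", "tissue", "ratio")
  if (!all(needed %in% names(ratios))) {
    abort_refstab(paste0("`ratios` needs columns: ", toString(needed)),
                  "missing_columns")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort_refstab("`alpha` must lie in (0, 1).", "invalid_alpha")
  }
  if (any(ratios$ratio <= 0)) {
    abort_refstab("Ratios must be positive.", "invalid_ratio")
  }
  res <- ratios %>%
    mutate(y = log2(.data$ratio)) %>%
    group_by(.data$target) %>%
    group_split() %>%
    purrr::map(function(d) {
      tis <- split(d$y, d$tissue)
      if (length(tis) < 2 || any(lengths(tis) < 2)) {
        abort_refstab("Need >= 2 tissues with >= 2 observations each.",
                      "degenerate_design")
      }
      if (all(vapply(tis, var, numeric(1)) == 0)) {
        abort_refstab("Zero within-group variance in every group.",
                      "degenerate_design")
      }
      fit <- anova(lm(y ~ tissue, data = d))
      anova_row <- tibble(
        target = d$target[1],
        df_between = fit$Df[1], df_within = fit$Df[2],
        f_statistic = fit$`F value`[1], p_value = fit$`Pr(>F)`[1]
      )
      pairs <- combn(sort(names(tis)), 2)
      n_pairs <- ncol(pairs)
      pairwise <- purrr::map(seq_len(n_pairs), function(i) {
        a <- tis[[pairs[1, i]]]; b <- tis[[pairs[2, i]]]
        t_res <- pooled_t_test(a, b)
        tibble(target = d$target[1],
               tissue_a = pairs[1, i], tissue_b = pairs[2, i],
               estimate = mean(a) - mean(b),
               statistic = t_res$statistic, p_raw = t_res$p_value)
      }) %>%
        bind_rows() %>%
        mutate(p_adj = pmin(1, .data$p_raw * n_pairs),
               significant = .data$p_adj < alpha)
      list(anova = anova_row, pairwise = pairwise)
    })
  structure(
    list(anova = bind_rows(purrr::map(res, "anova")),
         pairwise = bind_rows(purrr::map(res, "pairwise")),
         alpha = alpha),
    class = "ratio_comparison"
  )
}

# classical two-sample pooled-variance t test (two-tailed)
pooled_t_test <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t_stat,
       p_value = 2 * pt(-abs(t_stat), df = n1 + n2 - 2))
}

#' @export
print.ratio_comparison <- function(x, ...) {
  cat("Tissue comparison of relative expression (alpha =", x$alpha, ")\n\n")
  cat("ANOVA per target:\n")
  print(x$anova)
  cat("\nPairwise (Bonferroni-adjusted):\n")
  print(x$pairwise, n = 10)
  invisible(x)
}
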