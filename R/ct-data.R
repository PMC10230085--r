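#' Ct data utilities
#'
#' Throughout the package Ct data travel as a tidy tibble with one row per
#' measurement and columns `gene`, `sample`, `ct`, plus optional `tissue`,
#' `animal` and `replicate`. These helpers validate that layout, average
#' technical replicates and pivot to a gene-by-sample matrix for the
#' stability algorithms.
#'
#' @name ct-data
NULL

validate_ct_data <- function(ct_data, require_tissue = FALSE) {
  if (!is.data.frame(ct_data)) {
    abort_refstab("`ct_data` must be a data frame.", "type_error")
  }
  needed <- c("gene", "sample", "ct")
  missing_cols <- setdiff(needed, names(ct_data))
  if (length(missing_cols) > 0) {
    abort_refstab(
      paste0("`ct_data` is missing column(s): ", toString(missing_cols)),
      "missing_columns"
    )
  }
  if (require_tissue && !"tissue" %in% names(ct_data)) {
    abort_refstab("`ct_data` must have a `tissue` column for this analysis.",
                  "missing_columns")
  }
  if (!is.numeric(ct_data$ct)) {
    abort_refstab("`ct` must be numeric.", "type_error")
  }
  if (any(!is.finite(ct_data$ct))) {
    abort_refstab("`ct` contains non-finite values.", "nonfinite_ct")
  }
  invisible(ct_data)
}

#' Average technical replicates to one mean Ct per gene and sample
#'
#' qPCR reactions are typically run in technical triplicates on the same
#' cDNA; downstream stability analysis operates on the arithmetic mean Ct
#' per (gene, sample) cell.
#'
#' @param ct_data Tidy Ct tibble with columns `gene`, `sample`, `ct` and
#'   optionally `replicate`, `tissue`, `animal`.
#' @return A tibble with one row per (gene, sample) and the replicate-mean
#'   `ct`; grouping metadata columns (`tissue`, `animal`) are carried along.
#' @examples
#' reps <- tibble::tibble(
#'   gene = "g1", sample = "s1", replicate = 1:3, ct = c(20.0, 20.2, 20.4)
#' )
#' reduce_replicates(reps)
#' @export
reduce_replicates <- function(ct_data) {
  validate_ct_data(ct_data)
  meta <- intersect(c("tissue", "animal"), names(ct_data))
  ct_data %>%
    group_by(across(all_of(c("gene", "sample", meta)))) %>%
    summarise(ct = mean(.data$ct), .groups = "drop")
}

# gene x sample numeric matrix from tidy Ct data (replicates averaged).
# Stability algorithms require a complete matrix.
ct_wide <- function(ct_data, require_complete = TRUE) {
  reduced <- reduce_replicates(ct_data)
  wide <- reduced %>%
    select("gene", "sample", "ct") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "ct")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  if (require_complete && anyNA(m)) {
    bad <- rownames(m)[apply(m, 1, anyNA)]
    abort_refstab(
      paste0(
        "Ct matrix has missing cells (genes: ", toString(head(bad, 5)),
        "). Stability algorithms require complete matrices; drop the ",
        "affected genes or samples upstream."
      ),
      "missing_cells"
    )
  }
  m
}

# per-gene amplification factor (fold change per cycle, e.g. 2 at 100%
# efficiency). `efficiency` may be a scalar, a named vector, or a data
# frame with columns gene / efficiency. Values must exceed 1.
resolve_efficiency <- function(genes, efficiency = 2) {
  if (is.data.frame(efficiency)) {
    if (!all(c("gene", "efficiency") %in% names(efficiency))) {
      abort_refstab(
        "Efficiency data frame needs columns `gene` and `efficiency`.",
        "missing_columns"
      )
    }
    efficiency <- setNames(efficiency$efficiency, efficiency$gene)
  }
  if (length(efficiency) == 1 && is.null(names(efficiency))) {
    eff <- setNames(rep(as.numeric(efficiency), length(genes)), genes)
  } else {
    missing_genes <- setdiff(genes, names(efficiency))
    if (length(missing_genes) > 0) {
      abort_refstab(
        paste0("No efficiency given for gene(s): ",
               toString(head(missing_genes, 5))),
        "missing_efficiency"
      )
    }
    eff <- efficiency[genes]
  }
  if (any(!is.finite(eff)) || any(eff <= 1)) {
    abort_refstab("Amplification factors must be finite and > 1.",
                  "invalid_efficiency")
  }
  eff
}

#' Convert mean Ct values to relative quantities
#'
#' Expresses each gene's signal on a linear scale relative to its most
#' abundant sample: `Q = E^(min(Ct) - Ct)` per gene, so the per-gene
#' maximum quantity is 1. `E` is the amplification factor per cycle
#' (2 at 100% efficiency). This is the standard preprocessing step of
#' geNorm-style analyses.
#'
#' @inheritParams reduce_replicates
#' @param efficiency Amplification factor per cycle: a scalar (default 2),
#'   a named vector keyed by gene, or a data frame with columns `gene`,
#'   `efficiency`.
#' @return A tibble `gene`, `sample`, `quantity`.
#' @examples
#' cts <- tibble::tibble(gene = "g1", sample = paste0("s", 1:3),
#'                       ct = c(20, 21, 22))
#' ct_to_quantity(cts)  # quantities 1, 0.5, 0.25
#' @export
ct_to_quantity <- function(ct_data, efficiency = 2) {
  m <- ct_wide(ct_data)
  q <- quantity_matrix(m, resolve_efficiency(rownames(m), efficiency))
  as_tibble(q, rownames = "gene") %>%
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "quantity")
}

quantity_matrix <- function(ct_matrix, eff) {
  ref <- apply(ct_matrix, 1, min)
  eff ^ (ref - ct_matrix)
}
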