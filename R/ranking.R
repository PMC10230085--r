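#' Rank genes within one stability method
#'
#' Ascending rank by stability value (1 = most stable). Ties receive the
#' average rank, except for a geNorm fit, whose elimination-order ranks
#' are kept: the final pair shares rank 1 and the next gene takes rank 2.
#'
#' @param stability A stability tibble (`gene`, `value`) from one method,
#'   or a `genorm_fit`.
#' @return A tibble `gene`, `rank`.
#' @export
rank_method <- function(stability) {
  if (inherits(stability, "genorm_fit")) {
    return(stability$stability %>% select("gene", "rank"))
  }
  if (!all(c("gene", "value") %in% names(stability))) {
    abort_refstab("`stability` needs `gene` and `value` columns.",
                  "missing_columns")
  }
  stability %>%
    mutate(rank = rank_avg(.data$value)) %>%
    select("gene", "rank") %>%
    arrange(.data$rank, .data$gene)
}

#' Comprehensive ranking by geometric mean of per-method ranks
#'
#' Aggregates two or more per-method rankings RefFinder-style: each
#' gene's comprehensive score is the geometric mean of its ranks across
#' methods, and the final ranking is ascending in that score (smaller =
#' more stable), with deterministic ties broken by gene ID.
#'
#' @param stability Either a combined stability tibble with columns
#'   `method`, `gene`, `rank` (e.g. from [stability_all()]) or a named
#'   list of per-method tables / `genorm_fit`s.
#' @return A tibble with one row per gene: `gene`, one `rank_<method>`
#'   column per method, `geomean_rank`, `final_rank`.
#' @examples
#' s <- tibble::tibble(
#'   method = rep(c("a", "b"), each = 2),
#'   gene = rep(c("g1", "g2"), 2),
#'   rank = c(1, 2, 2, 1)
#' )
#' reffinder_aggregate(s)
#' @export
reffinder_aggregate <- function(stability) {
  if (is.list(stability) && !is.data.frame(stability)) {
    stability <- purrr::imap(stability, function(x, nm) {
      if (inherits(x, "genorm_fit")) x <- x$stability
      if (!"method" %in% names(x)) x$method <- nm
      x %>% select("method", "gene", "rank")
    }) %>% bind_rows()
  }
  needed <- c("method", "gene", "rank")
  if (!all(needed %in% names(stability))) {
    abort_refstab("Need columns `method`, `gene`, `rank`.",
                  "missing_columns")
  }
  methods <- unique(stability$method)
  if (length(methods) < 2) {
    abort_refstab("Comprehensive ranking needs >= 2 methods.",
                  "too_few_methods")
  }
  gene_sets <- split(stability$gene, stability$method)
  all_genes <- sort(unique(stability$gene))
  bad <- purrr::imap(gene_sets, function(g, m) {
    diff <- c(setdiff(all_genes, g), setdiff(g, all_genes))
    if (length(diff) == 0) NULL else paste0(m, ": ", toString(diff))
  }) %>% purrr::compact()
  if (length(bad) > 0) {
    abort_refstab(
      paste0("Gene sets differ across methods — ",
             paste(unlist(bad), collapse = "; ")),
      "mismatched_genes"
    )
  }
  wide <- stability %>%
    select("method", "gene", "rank") %>%
    tidyr::pivot_wider(names_from = "method", values_from = "rank",
                       names_prefix = "rank_")
  rank_cols <- paste0("rank_", methods)
  wide %>%
    mutate(geomean_rank = exp(rowMeans(log(as.matrix(
      wide[, rank_cols, drop = FALSE]
    ))))) %>%
    arrange(.data$geomean_rank, .data$gene) %>%
    mutate(final_rank = row_number())
}
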