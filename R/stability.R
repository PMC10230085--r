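#' Expression stability algorithms
#'
#' Four classical Ct-based screens for reference-gene stability, all
#' operating on a complete mean-Ct table (technical replicates are
#' averaged automatically):
#'
#' * [stability_genorm()] — mean pairwise variation `M` with stepwise
#'   exclusion of the least stable gene and the `V(n/n+1)` pairwise
#'   variation of cumulative normalization factors.
#' * [stability_normfinder()] — model-based variance decomposition; the
#'   stability value is the estimated per-gene SD.
#' * [stability_bestkeeper()] — descriptive Ct statistics; genes are
#'   ranked by the mean absolute deviation of raw Ct, and correlated
#'   against the BestKeeper index (per-sample geometric mean Ct).
#' * [stability_deltact()] — mean SD of pairwise Ct differences.
#'
#' Lower values mean more stable expression for every method.
#'
#' @name stability
NULL

check_dims <- function(m, min_genes, min_samples, method) {
  if (nrow(m) < min_genes) {
    abort_refstab(paste0(method, " needs at least ", min_genes, " genes."),
                  "too_few_genes")
  }
  if (ncol(m) < min_samples) {
    abort_refstab(paste0(method, " needs at least ", min_samples, " samples."),
                  "too_few_samples")
  }
  invisible(m)
}

# pairwise SD matrix: element (j, k) = SD over samples of (row_j - row_k),
# computed from the row covariance matrix.
pairwise_sd_matrix <- function(Y) {
  S <- cov(t(Y))
  d <- outer(diag(S), diag(S), "+") - 2 * S
  d[d < 0] <- 0  # numerical guard
  sqrt(d)
}

genorm_m_values <- function(Y) {
  sdm <- pairwise_sd_matrix(Y)
  rowSums(sdm) / (nrow(Y) - 1)
}

#' geNorm stability analysis
#'
#' Converts Ct to relative quantities (`E^(min Ct - Ct)` per gene), then
#' for each gene computes `M`, the mean over all partner genes of the
#' sample SD of pairwise log2 expression ratios. The gene with the
#' largest `M` is removed and `M` recomputed, iterating until two genes
#' remain; those two share rank 1. The pairwise variation `V(n/n+1)` is
#' the SD of `log2(NF_n / NF_(n+1))`, where `NF_n` is the per-sample
#' geometric mean quantity of the `n` most stable genes.
#'
#' @inheritParams ct_to_quantity
#' @return A `genorm_fit` object: list with `stability` (tibble `method`,
#'   `gene`, `value`, `rank`; a gene's value is its `M` in the round of
#'   its elimination, the final pair shares the last round's `M`),
#'   `rounds` (per-round `M` values), `elimination` (genes in order of
#'   removal), `final_pair`, `pairwise_variation` (tibble `n`, `v`),
#'   `n_genes`, `n_samples`. Supports [tidy()] and [glance()].
#' @export
stability_genorm <- function(ct_data, efficiency = 2) {
  m <- ct_wide(ct_data)
  check_dims(m, 3, 2, "geNorm")
  eff <- resolve_efficiency(rownames(m), efficiency)
  Y <- log2(quantity_matrix(m, eff))  # log2 relative quantities

  remaining <- rownames(Y)
  elimination <- character(0)
  rounds <- list()
  value <- setNames(numeric(length(remaining)), remaining)
  round_i <- 1L
  while (length(remaining) >= 2) {
    M <- genorm_m_values(Y[remaining, , drop = FALSE])
    rounds[[round_i]] <- tibble(round = round_i, gene = remaining,
                                m_value = unname(M))
    if (length(remaining) == 2) {
      value[remaining] <- M
      break
    }
    # largest M leaves; ties broken by gene ID for reproducibility
    worst <- remaining[order(-M, remaining)][1]
    value[worst] <- M[[worst]]
    elimination <- c(elimination, worst)
    remaining <- setdiff(remaining, worst)
    round_i <- round_i + 1L
  }
  final_pair <- sort(remaining)

  # stability order: final pair first (joint rank 1), then reverse
  # elimination order
  ordering <- c(final_pair, rev(elimination))
  rank <- setNames(c(1, 1, seq_len(length(elimination)) + 1), ordering)

  # V(n/n+1) on cumulative normalization factors, most stable genes first
  k <- nrow(Y)
  pv <- NULL
  if (k >= 3) {
    log_nf <- vapply(2:k, function(n) {
      colMeans(Y[ordering[1:n], , drop = FALSE])
    }, numeric(ncol(Y)))
    v <- vapply(seq_len(k - 2), function(i) {
      sd(log_nf[, i] - log_nf[, i + 1])
    }, numeric(1))
    pv <- tibble(n = 2:(k - 1), v = v)
  }

  structure(
    list(
      stability = tibble(method = "genorm", gene = names(rank),
                         value = unname(value[names(rank)]),
                         rank = unname(rank)) %>% arrange(.data$rank, .data$gene),
      rounds = bind_rows(rounds),
      elimination = elimination,
      final_pair = final_pair,
      pairwise_variation = pv,
      n_genes = k,
      n_samples = ncol(Y)
    ),
    class = "genorm_fit"
  )
}

#' @export
print.genorm_fit <- function(x, ...) {
  cat("geNorm stability analysis:", x$n_genes, "genes,",
      x$n_samples, "samples\n")
  cat("Most stable pair (joint rank 1):",
      paste(x$final_pair, collapse = " / "), "\n\n")
  print(x$stability, n = 10)
  invisible(x)
}

#' NormFinder stability analysis
#'
#' Model-based estimation of per-gene expression variance on log2
#' relative quantities. In the ungrouped default, each sample's gene
#' average is subtracted (removing sample-wide scale differences) and the
#' per-gene variance of the residuals, `z_i`, is corrected for the
#' contribution of the other genes:
#' `sigma2_i = max(0, (z_i - sum(z) / (k (k - 1))) * k / (k - 2))`.
#' The stability value is `sqrt(sigma2_i)`. With `grouped = TRUE`, the
#' same variance estimate is formed within each tissue group and combined
#' with the gene's mean absolute inter-group deviation (intra- plus
#' inter-group variation).
#'
#' @inheritParams ct_to_quantity
#' @param grouped Use the tissue column of `ct_data` as groups
#'   (opt-in; default ungrouped).
#' @return A stability tibble `method`, `gene`, `value`, `rank` (average
#'   ranks on ties).
#' @export
stability_normfinder <- function(ct_data, grouped = FALSE, efficiency = 2) {
  m <- ct_wide(ct_data)
  check_dims(m, 3, 3, "NormFinder")
  eff <- resolve_efficiency(rownames(m), efficiency)
  Y <- log2(quantity_matrix(m, eff))
  k <- nrow(Y)

  if (!grouped) {
    value <- normfinder_sd(Y)
  } else {
    validate_ct_data(ct_data, require_tissue = TRUE)
    map <- reduce_replicates(ct_data) %>% distinct(.data$sample, .data$tissue)
    tissue_of <- setNames(map$tissue, map$sample)[colnames(Y)]
    groups <- split(colnames(Y), tissue_of)
    if (any(lengths(groups) < 3)) {
      abort_refstab("Grouped NormFinder needs >= 3 samples per group.",
                    "too_few_samples")
    }
    intra <- vapply(groups, function(cols) {
      normfinder_sd(Y[, cols, drop = FALSE])
    }, numeric(k))
    dbar <- vapply(groups, function(cols) {
      Yg <- Y[, cols, drop = FALSE]
      rowMeans(sweep(Yg, 2, colMeans(Yg)))
    }, numeric(k))
    inter <- abs(dbar - rowMeans(dbar))
    value <- rowMeans(inter) + rowMeans(intra)
  }
  tibble(method = "normfinder", gene = rownames(Y), value = unname(value),
         rank = rank_avg(value)) %>%
    arrange(.data$rank, .data$gene)
}

normfinder_sd <- function(Y) {
  k <- nrow(Y)
  d <- sweep(Y, 2, colMeans(Y))
  z <- apply(d, 1, var)
  sig2 <- pmax(0, (z - sum(z) / (k * (k - 1))) * k / (k - 2))
  sqrt(sig2)
}

#' BestKeeper stability analysis
#'
#' Descriptive statistics on raw Ct per gene: arithmetic mean, min, max,
#' "SD" (the method's convention: mean absolute deviation from the
#' arithmetic mean) and CV% (100 * SD / mean). The BestKeeper index is
#' the per-sample geometric mean of Ct across genes; each gene is
#' Pearson-correlated against it. Genes are ranked by SD ascending;
#' SD > 1 Ct flags a gene as inconsistent.
#'
#' @inheritParams reduce_replicates
#' @return A `bestkeeper_fit` object: list with `stability` (tibble
#'   `method`, `gene`, `value` = SD, `rank`), `descriptives` (per-gene
#'   `ct_mean`, `ct_min`, `ct_max`, `sd_ct`, `cv_percent`, `r` vs the
#'   index, `inconsistent`), and `index` (tibble `sample`,
#'   `bestkeeper_index`). Supports [tidy()] and [glance()].
#' @export
stability_bestkeeper <- function(ct_data) {
  m <- ct_wide(ct_data)
  check_dims(m, 2, 3, "BestKeeper")
  mu <- rowMeans(m)
  mad_ct <- rowMeans(abs(m - mu))
  index <- apply(m, 2, geomean)
  r <- apply(m, 1, function(x) {
    if (sd(x) == 0 || sd(index) == 0) NA_real_ else stats::cor(x, index)
  })
  descriptives <- tibble(
    gene = rownames(m), n_samples = ncol(m),
    ct_mean = unname(mu), ct_min = apply(m, 1, min),
    ct_max = apply(m, 1, max), sd_ct = unname(mad_ct),
    cv_percent = unname(100 * mad_ct / mu), r = unname(r),
    inconsistent = unname(mad_ct > 1)
  )
  structure(
    list(
      stability = tibble(method = "bestkeeper", gene = rownames(m),
                         value = unname(mad_ct),
                         rank = unname(rank_avg(mad_ct))) %>%
        arrange(.data$rank, .data$gene),
      descriptives = descriptives,
      index = tibble(sample = colnames(m), bestkeeper_index = unname(index))
    ),
    class = "bestkeeper_fit"
  )
}

#' @export
print.bestkeeper_fit <- function(x, ...) {
  cat("BestKeeper analysis:", nrow(x$descriptives), "genes,",
      x$descriptives$n_samples[1], "samples\n\n")
  print(x$stability, n = 10)
  invisible(x)
}

#' Comparative delta-Ct stability analysis
#'
#' For every ordered gene pair, the SD over samples of the Ct difference
#' is computed; a gene's stability value is the mean of these SDs across
#' all partners. The gene with the lowest mean SD varies least relative
#' to the rest of the panel and is the most suitable reference.
#'
#' @inheritParams reduce_replicates
#' @return A stability tibble `method`, `gene`, `value`, `rank`.
#' @export
stability_deltact <- function(ct_data) {
  m <- ct_wide(ct_data)
  check_dims(m, 2, 2, "delta-Ct")
  sdm <- pairwise_sd_matrix(m)
  value <- rowSums(sdm) / (nrow(m) - 1)
  tibble(method = "deltact", gene = rownames(m), value = unname(value),
         rank = rank_avg(value)) %>%
    arrange(.data$rank, .data$gene)
}

#' Run several stability methods and combine their tables
#'
#' @inheritParams stability_normfinder
#' @param methods Subset of `"genorm"`, `"normfinder"`, `"bestkeeper"`,
#'   `"deltact"`.
#' @return A combined stability tibble (`method`, `gene`, `value`,
#'   `rank`); the full geNorm and BestKeeper fits are attached as
#'   attributes `"genorm_fit"` and `"bestkeeper_fit"`.
#' @export
stability_all <- function(ct_data,
                          methods = c("genorm", "normfinder", "bestkeeper",
                                      "deltact"),
                          efficiency = 2, grouped = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  attrs <- list()
  if ("genorm" %in% methods) {
    fit <- stability_genorm(ct_data, efficiency = efficiency)
    out$genorm <- fit$stability
    attrs$genorm_fit <- fit
  }
  if ("normfinder" %in% methods) {
    out$normfinder <- stability_normfinder(ct_data, grouped = grouped,
                                           efficiency = efficiency)
  }
  if ("bestkeeper" %in% methods) {
    fit <- stability_bestkeeper(ct_data)
    out$bestkeeper <- fit$stability
    attrs$bestkeeper_fit <- fit
  }
  if ("deltact" %in% methods) {
    out$deltact <- stability_deltact(ct_data)
  }
  combined <- bind_rows(out)
  attributes(combined) <- c(attributes(combined), attrs)
  combined
}
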