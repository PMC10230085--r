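# Independent brute-force oracles and small fixture builders. These
# deliberately use explicit loops and textbook formulas, not the
# package's vectorised implementations.

# tidy Ct tibble from a genes x samples matrix
ct_tibble <- function(m, tissues = NULL) {
  d <- tibble::tibble(
    gene = rep(rownames(m), times = ncol(m)),
    sample = rep(colnames(m), each = nrow(m))
  )
  d$ct <- unname(mapply(function(g, s) m[g, s], d$gene, d$sample))
  if (!is.null(tissues)) {
    d$tissue <- tissues[match(d$sample, colnames(m))]
  }
  d
}

random_ct_matrix <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    m <- matrix(runif(n_genes * n_samples, 18, 32),
                nrow = n_genes,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("s", seq_len(n_samples))))
    m
  })
}

# geNorm M by the definition: mean over partners of the SD of pairwise
# log2 quantity ratios
oracle_genorm_m <- function(m, eff = 2) {
  q <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (g in seq_len(nrow(m))) {
    q[g, ] <- eff ^ (min(m[g, ]) - m[g, ])
  }
  M <- numeric(nrow(m))
  for (j in seq_len(nrow(m))) {
    sds <- c()
    for (k in seq_len(nrow(m))) {
      if (k == j) next
      sds <- c(sds, stats::sd(log2(q[j, ] / q[k, ])))
    }
    M[j] <- mean(sds)
  }
  names(M) <- rownames(m)
  M
}

# full geNorm elimination by repeated oracle_genorm_m
oracle_genorm_elimination <- function(m, eff = 2) {
  remaining <- rownames(m)
  elim <- character(0)
  while (length(remaining) > 2) {
    M <- oracle_genorm_m(m[remaining, , drop = FALSE], eff)
    worst <- remaining[order(-M, remaining)][1]
    elim <- c(elim, worst)
    remaining <- setdiff(remaining, worst)
  }
  list(elimination = elim, final_pair = sort(remaining))
}

# comparative delta-Ct stability: mean over partners of SD of Ct diffs
oracle_deltact <- function(m) {
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    sds <- c()
    for (j in seq_len(nrow(m))) {
      if (i == j) next
      sds <- c(sds, stats::sd(m[i, ] - m[j, ]))
    }
    out[i] <- mean(sds)
  }
  names(out) <- rownames(m)
  out
}

# BestKeeper descriptives by hand
oracle_bestkeeper <- function(m) {
  n <- ncol(m)
  mean_ct <- apply(m, 1, mean)
  mad_ct <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    mad_ct[i] <- sum(abs(m[i, ] - mean_ct[i])) / n
  }
  index <- numeric(n)
  for (j in seq_len(n)) {
    index[j] <- prod(m[, j]) ^ (1 / nrow(m))
  }
  r <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    # constant rows have no defined correlation, like the implementation
    r[i] <- if (stats::sd(m[i, ]) == 0) NA_real_ else stats::cor(m[i, ], index)
  }
  list(mean = mean_ct, mad = setNames(mad_ct, rownames(m)),
       cv = 100 * mad_ct / mean_ct, index = index,
       r = setNames(r, rownames(m)))
}

# OLS by explicit normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}
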