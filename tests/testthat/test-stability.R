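test_that("technical replicates reduce to their arithmetic mean", {
  reps <- tibble::tibble(gene = "g1", sample = "s1", replicate = 1:3,
                         ct = c(20.0, 20.2, 20.4))
  expect_equal(reduce_replicates(reps)$ct, 20.2)

  single <- tibble::tibble(gene = "g1", sample = "s1", ct = 21.3)
  expect_equal(reduce_replicates(single)$ct, 21.3)

  long <- tidyr::expand_grid(gene = c("a", "b"), sample = c("s1", "s2"),
                             replicate = 1:3) |>
    dplyr::mutate(ct = 20 + seq_len(12) / 10)
  wide <- reduce_replicates(long)
  hand <- tapply(long$ct, list(long$gene, long$sample), mean)
  for (i in seq_len(nrow(wide))) {
    expect_equal(wide$ct[i], hand[wide$gene[i], wide$sample[i]])
  }
})

test_that("Ct converts to relative quantities with per-gene max 1", {
  cts <- tibble::tibble(gene = "g1", sample = paste0("s", 1:3),
                        ct = c(20, 21, 22))
  expect_equal(ct_to_quantity(cts)$quantity, c(1, 0.5, 0.25))

  const <- tibble::tibble(gene = "g1", sample = paste0("s", 1:3), ct = 25)
  expect_equal(ct_to_quantity(const)$quantity, rep(1, 3))

  two <- tibble::tibble(gene = "g1", sample = c("s1", "s2"), ct = c(20, 21))
  expect_equal(ct_to_quantity(two, efficiency = 1.9)$quantity, c(1, 1 / 1.9))
})

test_that("perfectly correlated genes have zero pairwise variation", {
  withr::with_seed(5, {
    a <- runif(4, 20, 25)
  })
  m <- rbind(A = a, B = a + 3, C = a + c(0.5, -0.2, 0.1, 0.4))
  colnames(m) <- paste0("s", 1:4)
  fit <- stability_genorm(ct_tibble(m))
  stab <- fit$stability
  # A and B share every log-ratio SD except the one with C, so M_A = M_B
  expect_equal(stab$value[stab$gene == "A"], stab$value[stab$gene == "B"],
               tolerance = 1e-12)
  expect_equal(fit$final_pair, c("A", "B"))
})

test_that("stability measures are invariant to per-gene Ct shifts", {
  m <- random_ct_matrix(5, 8, seed = 21)
  shifted <- m
  shifted["g2", ] <- shifted["g2", ] + 5
  d0 <- ct_tibble(m)
  d1 <- ct_tibble(shifted)

  g0 <- stability_genorm(d0)$stability |> dplyr::arrange(gene)
  g1 <- stability_genorm(d1)$stability |> dplyr::arrange(gene)
  expect_equal(g0$value, g1$value, tolerance = 1e-10)

  n0 <- stability_normfinder(d0) |> dplyr::arrange(gene)
  n1 <- stability_normfinder(d1) |> dplyr::arrange(gene)
  expect_equal(n0$value, n1$value, tolerance = 1e-10)

  dc0 <- stability_deltact(d0) |> dplyr::arrange(gene)
  dc1 <- stability_deltact(d1) |> dplyr::arrange(gene)
  expect_equal(dc0$value, dc1$value, tolerance = 1e-10)

  # BestKeeper: the documented asymmetry — SD unchanged, CV% changed
  b0 <- stability_bestkeeper(d0)
  b1 <- stability_bestkeeper(d1)
  expect_equal(b0$descriptives$sd_ct[order(b0$descriptives$gene)],
               b1$descriptives$sd_ct[order(b1$descriptives$gene)],
               tolerance = 1e-10)
  cv0 <- b0$descriptives$cv_percent[b0$descriptives$gene == "g2"]
  cv1 <- b1$descriptives$cv_percent[b1$descriptives$gene == "g2"]
  expect_false(isTRUE(all.equal(cv0, cv1)))
})

test_that("geNorm matches a brute-force oracle on random matrices", {
  for (seed in 1:4) {
    n_genes <- 3 + seed %% 3  # 4, 5, 6, 4
    m <- random_ct_matrix(n_genes + 1, 6, seed = seed)
    fit <- stability_genorm(ct_tibble(m))
    first_round <- fit$rounds[fit$rounds$round == 1, ]
    M_oracle <- oracle_genorm_m(m)
    expect_equal(setNames(first_round$m_value, first_round$gene),
                 M_oracle[first_round$gene], tolerance = 1e-10)
    ora <- oracle_genorm_elimination(m)
    expect_equal(fit$elimination, ora$elimination)
    expect_equal(fit$final_pair, ora$final_pair)
  }
})

test_that("geNorm elimination never increases the remaining maximum M", {
  m <- random_ct_matrix(7, 10, seed = 77)
  fit <- stability_genorm(ct_tibble(m))
  max_by_round <- tapply(fit$rounds$m_value, fit$rounds$round, max)
  expect_true(all(diff(max_by_round) <= 1e-12))
})

test_that("geNorm pairwise variation is defined for n = 2..k-1", {
  m <- random_ct_matrix(6, 8, seed = 13)
  fit <- stability_genorm(ct_tibble(m))
  expect_equal(fit$pairwise_variation$n, 2:5)
  expect_true(all(fit$pairwise_variation$v >= 0))
})

test_that("NormFinder gives zero stability to additively identical genes", {
  base <- seq(20, 23, length.out = 6)
  m <- rbind(a = base, b = base + 1, c = base - 2)
  colnames(m) <- paste0("s", 1:6)
  out <- stability_normfinder(ct_tibble(m))
  expect_equal(out$value, rep(0, 3), tolerance = 1e-12)
})

test_that("NormFinder recovers known per-gene variances", {
  # replicate-averaged estimates isolate estimator accuracy from the
  # sampling noise of any single draw
  k <- 10; n <- 200; n_rep <- 10
  sigma <- seq(0.2, 1.1, length.out = k)
  est2 <- vapply(seq_len(n_rep), function(rep_seed) {
    m <- withr::with_seed(rep_seed, {
      mu <- runif(k, 20, 28)
      delta <- rnorm(n, 0, 1)  # sample-wide shifts, removed by centering
      t(vapply(seq_len(k), function(i) {
        mu[i] + delta + rnorm(n, 0, sigma[i])
      }, numeric(n)))
    })
    rownames(m) <- sprintf("g%02d", seq_len(k))
    colnames(m) <- paste0("s", seq_len(n))
    out <- stability_normfinder(ct_tibble(m)) |> dplyr::arrange(gene)
    out$value^2
  }, numeric(k))
  rel_err <- abs(rowMeans(est2) - sigma^2) / sigma^2
  expect_true(all(rel_err < 0.25))
})

test_that("BestKeeper descriptives match a hand-computed oracle", {
  m <- rbind(g1 = c(20.1, 20.3, 19.9, 20.2),
             g2 = c(25.0, 26.1, 24.7, 25.8),
             g3 = c(30.2, 30.2, 30.2, 30.2))
  colnames(m) <- paste0("s", 1:4)
  fit <- stability_bestkeeper(ct_tibble(m))
  ora <- oracle_bestkeeper(m)
  desc <- fit$descriptives |> dplyr::arrange(gene)
  expect_equal(desc$sd_ct, unname(ora$mad[desc$gene]), tolerance = 1e-10)
  expect_equal(desc$cv_percent, unname(ora$cv), tolerance = 1e-10)
  expect_equal(fit$index$bestkeeper_index, ora$index, tolerance = 1e-10)
  expect_equal(desc$r[1:2], unname(ora$r[1:2]), tolerance = 1e-10)
  # constant gene: zero SD, rank 1, undefined correlation
  expect_equal(desc$sd_ct[desc$gene == "g3"], 0)
  expect_equal(fit$stability$rank[fit$stability$gene == "g3"], 1)
  expect_true(is.na(desc$r[desc$gene == "g3"]))
})

test_that("identical profiles make the BestKeeper index degenerate", {
  prof <- c(22.5, 23.1, 21.9, 22.8)
  m <- rbind(a = prof, b = prof, c = prof)
  colnames(m) <- paste0("s", 1:4)
  fit <- stability_bestkeeper(ct_tibble(m))
  expect_equal(fit$index$bestkeeper_index, prof, tolerance = 1e-12)
  expect_equal(fit$descriptives$r, rep(1, 3), tolerance = 1e-12)
})

test_that("delta-Ct stability matches a brute-force all-pairs oracle", {
  # constant-offset pair: both stabilities zero
  base <- c(20, 21.5, 19.8, 22)
  m2 <- rbind(A = base, B = base + 2)
  colnames(m2) <- paste0("s", 1:4)
  out2 <- stability_deltact(ct_tibble(m2))
  expect_equal(out2$value, c(0, 0), tolerance = 1e-12)

  m <- random_ct_matrix(4, 6, seed = 3)
  out <- stability_deltact(ct_tibble(m)) |> dplyr::arrange(gene)
  ora <- oracle_deltact(m)
  expect_equal(out$value, unname(ora[out$gene]), tolerance = 1e-12)

  # permutation equivariance: relabeling genes permutes the values
  perm <- m[c(3, 1, 4, 2), ]
  out_perm <- stability_deltact(ct_tibble(perm)) |> dplyr::arrange(gene)
  expect_equal(out_perm$value, out$value, tolerance = 1e-12)
})

test_that("stability values are non-negative and rankings complete", {
  m <- random_ct_matrix(6, 9, seed = 55)
  d <- ct_tibble(m)
  all_tables <- stability_all(d)
  expect_true(all(all_tables$value >= 0))
  for (meth in unique(all_tables$method)) {
    genes <- all_tables$gene[all_tables$method == meth]
    expect_setequal(genes, rownames(m))
  }
})

test_that("missing cells are rejected with guidance", {
  d <- ct_tibble(random_ct_matrix(4, 4, seed = 9))[-1, ]
  expect_error(stability_genorm(d), class = "refstab_missing_cells")
})

test_that("minimum panel sizes are enforced", {
  m <- random_ct_matrix(2, 5, seed = 1)
  expect_error(stability_genorm(ct_tibble(m)),
               class = "refstab_too_few_genes")
  expect_error(stability_normfinder(ct_tibble(m)),
               class = "refstab_too_few_genes")
})
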