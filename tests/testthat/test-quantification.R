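test_that("normalization factor is the geometric mean of ref quantities", {
  m <- rbind(r1 = c(20, 20, 20), r2 = c(20, 18, 22))
  colnames(m) <- paste0("s", 1:3)
  d <- ct_tibble(m)

  # single reference: NF equals its own quantity
  nf1 <- normalization_factor(d, "r2")
  q2 <- ct_to_quantity(d |> dplyr::filter(gene == "r2"))
  expect_equal(nf1$nf, q2$quantity[match(nf1$sample, q2$sample)])

  # two references with quantities 1 and 4 -> NF 2
  m2 <- rbind(a = c(20, 20), b = c(22, 20))
  colnames(m2) <- c("s1", "s2")
  nf2 <- normalization_factor(ct_tibble(m2), c("a", "b"))
  expect_equal(nf2$nf[nf2$sample == "s2"], 1)
  expect_equal(nf2$nf[nf2$sample == "s1"], sqrt(1 * 0.25))

  # three references: log-domain oracle
  m3 <- random_ct_matrix(3, 5, seed = 41)
  d3 <- ct_tibble(m3)
  nf3 <- normalization_factor(d3, rownames(m3))
  q <- ct_to_quantity(d3)
  ora <- tapply(log(q$quantity), q$sample, mean)
  expect_equal(nf3$nf, as.numeric(exp(ora[nf3$sample])), tolerance = 1e-12)
})

make_quant_data <- function() {
  # 2 tissues x 2 animals, calibrator CAL; hand-set Ct values
  tibble::tribble(
    ~gene, ~sample, ~tissue, ~ct,
    "tgt", "c1", "CAL", 25, "tgt", "c2", "CAL", 25,
    "tgt", "x1", "EXP", 22, "tgt", "x2", "EXP", 22,
    "ref", "c1", "CAL", 20, "ref", "c2", "CAL", 20,
    "ref", "x1", "EXP", 19, "ref", "x2", "EXP", 19
  )
}

test_that("Pfaffl ratios follow the efficiency-corrected closed form", {
  d <- make_quant_data()
  # E = 2: dCt_t = 3, dCt_r = 1 -> ratio 2^3 / 2^1 = 4
  r <- pfaffl_ratio(d, targets = "tgt", ref_genes = "ref",
                    calibrator = "CAL")
  expect_equal(r$ratio[r$tissue == "EXP"], c(4, 4))
  # calibrator samples: ratio 1 by construction
  expect_equal(r$ratio[r$tissue == "CAL"], c(1, 1))

  # mixed efficiencies: 1.95^2.5 / 2.0^1
  d2 <- d
  d2$ct[d2$gene == "tgt" & d2$tissue == "EXP"] <- 22.5
  r2 <- pfaffl_ratio(d2, targets = "tgt", ref_genes = "ref",
                     calibrator = "CAL",
                     efficiency = c(tgt = 1.95, ref = 2.0))
  expect_equal(unique(r2$ratio[r2$tissue == "EXP"]), 1.95^2.5 / 2.0,
               tolerance = 1e-12)
})

test_that("with E = 2 everywhere the ratio equals 2^-ddCt", {
  tl <- c("CAL", "E1", "E2")
  m <- random_ct_matrix(4, 9, seed = 61)
  d <- ct_tibble(m, tissues = rep(tl, each = 3))
  r <- pfaffl_ratio(d, targets = "g1", ref_genes = c("g2", "g3"),
                    calibrator = "CAL")
  cal_ct <- rowMeans(m[, 1:3])
  for (i in seq_len(nrow(r))) {
    s <- r$sample[i]
    dct_t <- unname(m["g1", s] - cal_ct["g1"])
    dct_r <- mean(c(m["g2", s] - cal_ct["g2"], m["g3", s] - cal_ct["g3"]))
    expect_equal(r$ratio[i], 2^-(dct_t - dct_r), tolerance = 1e-12)
  }
})

test_that("a reference normalized by itself gives ratio 1 everywhere", {
  m <- random_ct_matrix(3, 6, seed = 71)
  d <- ct_tibble(m, tissues = rep(c("CAL", "X"), each = 3))
  r <- pfaffl_ratio(d, targets = "g1", ref_genes = "g1", calibrator = "CAL")
  expect_equal(r$ratio, rep(1, 6), tolerance = 1e-12)
})

test_that("missing calibrator measurements abort", {
  d <- make_quant_data() |> dplyr::filter(!(gene == "ref" &
                                              tissue == "CAL"))
  expect_error(
    pfaffl_ratio(d, targets = "tgt", ref_genes = "ref", calibrator = "CAL"),
    class = "refstab_missing_calibrator"
  )
  expect_error(
    pfaffl_ratio(make_quant_data(), targets = "tgt", ref_genes = "ref",
                 calibrator = "NOPE"),
    class = "refstab_missing_calibrator"
  )
})

test_that("planted fold changes are recovered; unstable refs inflate variance", {
  tl <- unique(stability_grouping_default()$tissue)
  sim <- simulate_ct_matrix(sim_design(
    n_genes = 8, frac_stable = 0.5, sigma_stable = 0.05,
    sigma_unstable = 1.5, seed = 19, tissue_labels = tl
  ))
  truth <- sim$truth
  stable <- truth$gene[truth$is_stable]
  unstable <- truth$gene[!truth$is_stable]

  # plant a 2^3 = 8-fold up-regulation of one gene in tissue SEM
  target <- stable[1]
  ct <- sim$ct |>
    dplyr::mutate(ct = ifelse(gene == target & tissue == "SEM", ct - 3, ct))
  refs <- stable[2:3]
  r <- pfaffl_ratio(ct, targets = target, ref_genes = refs,
                    calibrator = "GG")
  mean_sem <- mean(r$ratio[r$tissue == "SEM"])
  expect_lt(abs(log2(mean_sem) - 3), 0.5)

  # normalizing by unstable genes inflates the spread of log-ratios
  r_bad <- pfaffl_ratio(ct, targets = target, ref_genes = unstable[1:2],
                        calibrator = "GG")
  expect_gt(var(log2(r_bad$ratio[r_bad$tissue != "SEM"])),
            var(log2(r$ratio[r$tissue != "SEM"])))
})

test_that("tissue comparison applies ANOVA plus Bonferroni correctly", {
  # 5 tissues -> 10 pairwise comparisons; adjusted p = min(1, 10 * raw)
  tl <- paste0("T", 1:5)
  d <- withr::with_seed(23, tibble::tibble(
    target = "g",
    tissue = rep(tl, each = 4),
    ratio = 2^rnorm(20, rep(c(0, 0, 0, 1, 3), each = 4), 0.3)
  ))
  cmp <- compare_groups(d)
  expect_equal(nrow(cmp$pairwise), 10)
  expect_equal(cmp$pairwise$p_adj,
               pmin(1, cmp$pairwise$p_raw * 10), tolerance = 1e-12)
  expect_equal(cmp$pairwise$significant, cmp$pairwise$p_adj < 0.05)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  d <- withr::with_seed(37, tibble::tibble(
    target = "g",
    tissue = rep(c("A", "B"), each = 5),
    ratio = 2^rnorm(10, rep(c(0, 1), each = 5), 0.4)
  ))
  cmp <- compare_groups(d)
  expect_equal(cmp$anova$f_statistic, cmp$pairwise$statistic^2,
               tolerance = 1e-10)
  expect_equal(cmp$anova$p_value, cmp$pairwise$p_raw, tolerance = 1e-10)
})

test_that("three-group ANOVA matches a sums-of-squares oracle", {
  # means 1, 1, 5 on the log2 scale; equal n, equal variance
  y <- c(0.8, 1.2, 1.0, 0.9, 1.1, 1.0, 4.8, 5.2, 5.0)
  d <- tibble::tibble(target = "g", tissue = rep(c("A", "B", "C"), each = 3),
                      ratio = 2^y)
  cmp <- compare_groups(d)
  groups <- split(y, d$tissue)
  grand <- mean(y)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - grand)^2
  }, numeric(1)))
  ss_within <- sum(vapply(groups, function(g) {
    sum((g - mean(g))^2)
  }, numeric(1)))
  f_oracle <- (ss_between / 2) / (ss_within / 6)
  expect_equal(cmp$anova$f_statistic, f_oracle, tolerance = 1e-10)
})

test_that("degenerate designs abort", {
  flat <- tibble::tibble(target = "g", tissue = rep(c("A", "B"), each = 3),
                         ratio = rep(c(2, 4), each = 3))
  expect_error(compare_groups(flat), class = "refstab_degenerate_design")

  tiny <- tibble::tibble(target = "g", tissue = c("A", "B"), ratio = c(1, 2))
  expect_error(compare_groups(tiny), class = "refstab_degenerate_design")
})
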