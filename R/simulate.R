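#' Simulation design for synthetic Ct matrices
#'
#' Describes a multi-tissue qPCR panel with planted ground truth. Each
#' gene gets a baseline Ct drawn uniformly from `baseline_ct_range`; a
#' fraction `frac_stable` of genes is "stable" (tissue effects drawn with
#' SD `sigma_stable` in Ct units), the rest "unstable" (`sigma_unstable`).
#' Tissue effects are drawn once per (gene, tissue) and shared across
#' animals, so instability is structured tissue-specific expression rather
#' than i.i.d. noise. Animals contribute a shared random shift
#' (`sigma_animal`), technical replicates add measurement noise
#' (`sigma_tech`).
#'
#' The default design mirrors a typical multi-tissue reference-gene study:
#' 12 tissues, 5 animals, technical triplicates.
#'
#' @param n_genes,n_tissues,n_animals,n_tech_reps Panel dimensions
#'   (counts, all >= 1).
#' @param baseline_ct_range Length-2 interval of per-gene baseline Ct.
#' @param sigma_stable,sigma_unstable Ct SD of tissue effects for stable
#'   and unstable genes (>= 0).
#' @param frac_stable Proportion of genes planted stable, in \[0, 1\].
#' @param sigma_animal,sigma_tech Ct SD of animal effects and technical
#'   replicate noise (>= 0).
#' @param seed Integer seed; the same design and seed give bit-identical
#'   output.
#' @param tissue_labels Optional character vector of tissue names (length
#'   `n_tissues`); defaults to `T01`, `T02`, ...
#' @return A `sim_design` list, for [simulate_ct_matrix()].
#' @export
sim_design <- function(n_genes = 20, n_tissues = 12, n_animals = 5,
                       n_tech_reps = 3, baseline_ct_range = c(18, 32),
                       sigma_stable = 0.1, sigma_unstable = 1.5,
                       frac_stable = 0.25, sigma_animal = 0.15,
                       sigma_tech = 0.1, seed = 1L, tissue_labels = NULL) {
  counts <- c(n_genes = n_genes, n_tissues = n_tissues,
              n_animals = n_animals, n_tech_reps = n_tech_reps)
  sds <- c(sigma_stable = sigma_stable, sigma_unstable = sigma_unstable,
           sigma_animal = sigma_animal, sigma_tech = sigma_tech)
  if (any(!is.finite(c(counts, sds, baseline_ct_range, frac_stable, seed)))) {
    abort_refstab("Design parameters must be finite.", "invalid_design")
  }
  if (any(counts < 1)) {
    abort_refstab("Counts must all be >= 1.", "invalid_design")
  }
  if (any(sds < 0)) {
    abort_refstab("All SDs must be >= 0.", "invalid_design")
  }
  if (frac_stable < 0 || frac_stable > 1) {
    abort_refstab("`frac_stable` must lie in [0, 1].", "invalid_design")
  }
  if (length(baseline_ct_range) != 2 ||
      baseline_ct_range[1] > baseline_ct_range[2]) {
    abort_refstab("`baseline_ct_range` must be an increasing interval.",
                  "invalid_design")
  }
  if (!is.null(tissue_labels) && length(tissue_labels) != n_tissues) {
    abort_refstab("`tissue_labels` must have length `n_tissues`.",
                  "invalid_design")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
         n_animals = as.integer(n_animals),
         n_tech_reps = as.integer(n_tech_reps),
         baseline_ct_range = as.numeric(baseline_ct_range),
         sigma_stable = sigma_stable, sigma_unstable = sigma_unstable,
         frac_stable = frac_stable, sigma_animal = sigma_animal,
         sigma_tech = sigma_tech, seed = as.integer(seed),
         tissue_labels = tissue_labels),
    class = "sim_design"
  )
}

#' Simulate a replicate-level Ct table with planted ground truth
#'
#' Generates `Ct(g, t, a, r) = B_g + D_gt + A_a + e_gtar` where `B_g` is
#' the gene baseline, `D_gt` a zero-mean normal tissue effect with SD
#' `sigma_stable` or `sigma_unstable` by gene class, `A_a` a normal animal
#' effect and `e` technical noise. Samples are tissue-by-animal
#' combinations; the tissue effect is shared across animals.
#'
#' @param design A [sim_design()].
#' @return A list with `ct` (tidy replicate-level tibble: `gene`, `sample`,
#'   `tissue`, `animal`, `replicate`, `ct`) and `truth` (per-gene tibble:
#'   `gene`, `is_stable`, `tissue_effect_sd` (generative SD),
#'   `realized_sd` (SD of the drawn tissue effects), `baseline`).
#' @examples
#' sim <- simulate_ct_matrix(sim_design(n_genes = 4, seed = 7))
#' head(sim$ct)
#' sim$truth
#' @export
simulate_ct_matrix <- function(design) {
  if (!inherits(design, "sim_design")) {
    abort_refstab("`design` must come from sim_design().", "invalid_design")
  }
  d <- design
  withr::with_seed(d$seed, {
    genes <- sprintf("gene%02d", seq_len(d$n_genes))
    tissues <- d$tissue_labels %||% sprintf("T%02d", seq_len(d$n_tissues))
    animals <- sprintf("A%d", seq_len(d$n_animals))
    n_stable <- round(d$frac_stable * d$n_genes)
    is_stable <- c(rep(TRUE, n_stable), rep(FALSE, d$n_genes - n_stable))
    sigma_gene <- ifelse(is_stable, d$sigma_stable, d$sigma_unstable)
    baseline <- runif(d$n_genes, d$baseline_ct_range[1], d$baseline_ct_range[2])
    tissue_eff <- matrix(
      rnorm(d$n_genes * d$n_tissues, 0, rep(sigma_gene, times = d$n_tissues)),
      nrow = d$n_genes, dimnames = list(genes, tissues)
    )
    animal_eff <- rnorm(d$n_animals, 0, d$sigma_animal)

    grid <- tidyr::expand_grid(
      gene = genes, tissue = tissues, animal = animals,
      replicate = seq_len(d$n_tech_reps)
    )
    noise <- rnorm(nrow(grid), 0, d$sigma_tech)
    ct <- grid %>%
      mutate(
        sample = paste(.data$tissue, .data$animal, sep = "_"),
        ct = baseline[match(.data$gene, genes)] +
          tissue_eff[cbind(match(.data$gene, genes),
                           match(.data$tissue, tissues))] +
          animal_eff[match(.data$animal, animals)] +
          noise
      ) %>%
      select("gene", "sample", "tissue", "animal", "replicate", "ct")

    truth <- tibble(
      gene = genes,
      is_stable = is_stable,
      tissue_effect_sd = sigma_gene,
      realized_sd = apply(tissue_eff, 1, sd),
      baseline = baseline
    )
    list(ct = ct, truth = truth)
  })
}

#' Simulate a lognormal TPM abundance matrix with controlled CV
#'
#' Each transcript's abundance across samples is lognormal with log-scale
#' SD solving `CV = sqrt(exp(sigma^2) - 1)`, so the realized
#' coefficient of variation converges to the target as the number of
#' samples grows. Sample columns are one per (tissue, replicate).
#'
#' @param n_transcripts Number of transcripts.
#' @param tissues Character vector of tissue labels.
#' @param n_reps Biological replicates per tissue.
#' @param target_cv Per-transcript target CV as a fraction (scalar or
#'   length `n_transcripts`); must be >= 0.
#' @param mean_tpm Median abundance per transcript (scalar or vector),
#'   in TPM.
#' @param seed Integer seed.
#' @return A list with `tpm` (tidy tibble `transcript_id`, `sample`,
#'   `tissue`, `tpm`) and `truth` (`transcript_id`, `target_cv`).
#' @export
simulate_tpm_matrix <- function(n_transcripts, tissues, n_reps = 1,
                                target_cv = 0.2, mean_tpm = 50, seed = 1L) {
  if (any(target_cv < 0) || any(!is.finite(target_cv))) {
    abort_refstab("`target_cv` must be finite and >= 0.", "invalid_design")
  }
  if (any(mean_tpm <= 0)) {
    abort_refstab("`mean_tpm` must be positive.", "invalid_design")
  }
  target_cv <- rep_len(target_cv, n_transcripts)
  mean_tpm <- rep_len(mean_tpm, n_transcripts)
  withr::with_seed(seed, {
    transcripts <- sprintf("tr%05d", seq_len(n_transcripts))
    samples <- tidyr::expand_grid(tissue = tissues, rep = seq_len(n_reps)) %>%
      mutate(sample = paste(.data$tissue, .data$rep, sep = "_"))
    sdlog <- sqrt(log(1 + target_cv^2))
    n_s <- nrow(samples)
    vals <- exp(rep(log(mean_tpm), each = n_s) +
                  rnorm(n_transcripts * n_s, 0, rep(sdlog, each = n_s)))
    tpm <- tibble(
      transcript_id = rep(transcripts, each = n_s),
      sample = rep(samples$sample, times = n_transcripts),
      tissue = rep(samples$tissue, times = n_transcripts),
      tpm = vals
    )
    list(tpm = tpm,
         truth = tibble(transcript_id = transcripts, target_cv = target_cv))
  })
}

#' Simulate a qPCR dilution series with known true efficiency
#'
#' Generates `Ct = intercept + m * log10(conc) + noise` with slope
#' `m = -1 / log10(1 + E / 100)`, the standard-curve relationship between
#' amplification efficiency and dilution slope. The default
#' concentrations are four-fold dilutions from 10 down to 0.15625
#' ng/uL.
#'
#' @param true_eff_percent True amplification efficiency in percent
#'   (0 < E <= 150).
#' @param intercept_ct Ct at 1 unit concentration.
#' @param concentrations Template concentrations (> 0), e.g. ng/uL.
#' @param noise_sd Ct SD of measurement noise (>= 0).
#' @param seed Integer seed.
#' @param primer_id Label carried into the output.
#' @return A tibble `primer_id`, `concentration`, `ct`.
#' @export
simulate_dilution_series <- function(true_eff_percent, intercept_ct = 30,
                                     concentrations = 10 / 4^(0:5),
                                     noise_sd = 0, seed = 1L,
                                     primer_id = "primer1") {
  if (!is.finite(true_eff_percent) || true_eff_percent <= 0 ||
      true_eff_percent > 150) {
    abort_refstab("`true_eff_percent` must lie in (0, 150].", "invalid_design")
  }
  if (any(concentrations <= 0)) {
    abort_refstab("Concentrations must be positive.", "invalid_design")
  }
  if (noise_sd < 0) {
    abort_refstab("`noise_sd` must be >= 0.", "invalid_design")
  }
  m <- -1 / log10(1 + true_eff_percent / 100)
  withr::with_seed(seed, {
    tibble(
      primer_id = primer_id,
      concentration = as.numeric(concentrations),
      ct = intercept_ct + m * log10(concentrations) +
        rnorm(length(concentrations), 0, noise_sd)
    )
  })
}
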