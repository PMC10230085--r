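#' Assemble and validate a pipeline configuration
#'
#' Configuration for [run_pipeline()]. Defaults run the whole workflow on
#' synthetic data: a TPM screen over the default screen groups, a
#' dilution-series efficiency check, the four stability methods on each
#' default stability group, the comprehensive ranking, and (optionally)
#' efficiency-corrected quantification against a calibrator tissue.
#' Configurations can also be read from YAML with [read_pipeline_config()];
#' direct arguments override file values.
#'
#' @param seed Integer seed driving every simulated input.
#' @param out_dir Output directory for tables and the run log.
#' @param n_genes,frac_stable,sigma_stable,sigma_unstable Ct-panel design
#'   forwarded to [sim_design()] (12 tissues x 5 animals x triplicates).
#' @param n_transcripts,screen_floor TPM screen: number of simulated
#'   transcripts and expression floor.
#' @param efficiency_band Length-2 QC band in percent.
#' @param methods Stability methods to run.
#' @param quantify Run the quantification stage.
#' @param targets,ref_genes Genes for quantification; `NULL` picks the
#'   least-stable genes as targets and the comprehensive top 2 of
#'   `quantify_group` as references.
#' @param calibrator Calibrator tissue (required when `quantify = TRUE`).
#' @param quantify_group Stability group whose samples feed
#'   quantification.
#' @param alpha Significance level for tissue comparisons.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("refstab_run"),
                            n_genes = 20, frac_stable = 0.25,
                            sigma_stable = 0.1, sigma_unstable = 1.5,
                            n_transcripts = 200, screen_floor = 1.5,
                            efficiency_band = c(98, 102),
                            methods = c("genorm", "normfinder",
                                        "bestkeeper", "deltact"),
                            quantify = TRUE, targets = NULL,
                            ref_genes = NULL, calibrator = "GG",
                            quantify_group = "Nervous", alpha = 0.05) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir, n_genes = n_genes,
    frac_stable = frac_stable, sigma_stable = sigma_stable,
    sigma_unstable = sigma_unstable, n_transcripts = n_transcripts,
    screen_floor = screen_floor, efficiency_band = efficiency_band,
    methods = methods, quantify = quantify, targets = targets,
    ref_genes = ref_genes, calibrator = calibrator,
    quantify_group = quantify_group, alpha = alpha
  )
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (length(cfg$efficiency_band) != 2 ||
      cfg$efficiency_band[1] >= cfg$efficiency_band[2]) {
    abort_refstab("`efficiency_band` must be an increasing interval.",
                  "invalid_config")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    abort_refstab("`alpha` must lie in (0, 1).", "invalid_config")
  }
  bad <- setdiff(cfg$methods,
                 c("genorm", "normfinder", "bestkeeper", "deltact"))
  if (length(bad) > 0) {
    abort_refstab(paste0("Unknown method(s): ", toString(bad)),
                  "invalid_config")
  }
  if (isTRUE(cfg$quantify) &&
      (is.null(cfg$calibrator) || !nzchar(cfg$calibrator))) {
    abort_refstab("Quantification requested but no calibrator tissue set.",
                  "invalid_config")
  }
  stab_groups <- stability_grouping_default()
  if (isTRUE(cfg$quantify) &&
      !cfg$quantify_group %in% unique(stab_groups$group)) {
    abort_refstab(paste0("Unknown `quantify_group`: ", cfg$quantify_group),
                  "invalid_config")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()].
#' @param ... Overrides applied on top of the file values.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full reference-gene workflow on synthetic data
#'
#' Executes screen, efficiency QC, per-group stability, comprehensive
#' ranking, and (optionally) quantification, writing each result table
#' to `out_dir` together with a `run_log.yaml` recording the seed,
#' package version and all parameters. Rerunning with the same
#' configuration reproduces byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all result tables
#'   (`screen_candidates`, `screen_summary`, `efficiency`, `stability`,
#'   `comprehensive`, `ratios`, `comparison`, `truth`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_refstab(paste0("Pipeline stage '", name, "' failed: ",
                           conditionMessage(e)),
                    "stage_error")
    })
  }

  # --- screen: simulated TPM over the screen tissue groups -------------
  screen_res <- stage("screen", {
    grouping <- screen_grouping_default()
    tissues <- unique(grouping$tissue)
    cv_targets <- rep(c(0.08, 0.25, 0.60),
                      length.out = cfg$n_transcripts)  # mixed stability
    sim <- simulate_tpm_matrix(cfg$n_transcripts, tissues, n_reps = 3,
                               target_cv = cv_targets,
                               seed = cfg$seed)
    floored <- apply_expression_floor(sim$tpm, floor = cfg$screen_floor)
    annotation <- tibble(
      transcript_id = sim$truth$transcript_id,
      gene_name = paste0("gene_", sim$truth$transcript_id)
    )
    cands <- compute_group_cv(floored, grouping) %>%
      screen_candidates(grouping, annotation = annotation)
    summary <- purrr::map(unique(grouping$group),
                          ~ summarize_group(cands, .x)) %>% bind_rows()
    list(candidates = cands, summary = summary)
  })
  write_table_auto(screen_res$candidates,
                   file.path(cfg$out_dir, "screen_candidates.tsv"))
  write_table_auto(screen_res$summary,
                   file.path(cfg$out_dir, "screen_summary.tsv"))

  # --- efficiency: simulated dilution series ---------------------------
  eff_res <- stage("efficiency", {
    true_eff <- c(p1 = 100, p2 = 99, p3 = 101.5, p4 = 95, p5 = 104)
    purrr::imap(true_eff, function(e, id) {
      simulate_dilution_series(e, noise_sd = 0.05,
                               seed = cfg$seed + match(id, names(true_eff)),
                               primer_id = id)
    }) %>%
      bind_rows() %>%
      estimate_efficiency(low = cfg$efficiency_band[1],
                          high = cfg$efficiency_band[2])
  })
  write_table_auto(eff_res, file.path(cfg$out_dir, "efficiency.tsv"))

  # --- stability + comprehensive ranking per group ---------------------
  stab_grouping <- stability_grouping_default()
  design <- sim_design(
    n_genes = cfg$n_genes, n_tissues = 12, n_animals = 5,
    sigma_stable = cfg$sigma_stable, sigma_unstable = cfg$sigma_unstable,
    frac_stable = cfg$frac_stable, seed = cfg$seed,
    tissue_labels = unique(stab_grouping$tissue)
  )
  sim <- stage("simulate", simulate_ct_matrix(design))
  write_table_auto(sim$truth, file.path(cfg$out_dir, "truth.tsv"))

  groups <- unique(stab_grouping$group)
  stab_res <- stage("stability", {
    purrr::map(groups, function(g) {
      member <- stab_grouping$tissue[stab_grouping$group == g]
      ct_g <- sim$ct %>% filter(.data$tissue %in% member)
      stability_all(ct_g, methods = cfg$methods) %>%
        mutate(group = g)
    }) %>% setNames(groups)
  })
  comp_res <- stage("rank", {
    purrr::map(stab_res, function(s) {
      reffinder_aggregate(s) %>% mutate(group = s$group[1])
    }) %>% setNames(groups)
  })
  for (g in groups) {
    write_table_auto(stab_res[[g]],
                     file.path(cfg$out_dir, paste0("stability_", g, ".tsv")))
    write_table_auto(comp_res[[g]],
                     file.path(cfg$out_dir,
                               paste0("comprehensive_", g, ".tsv")))
  }

  # --- quantification --------------------------------------------------
  ratios <- comparison <- NULL
  if (isTRUE(cfg$quantify)) {
    quant <- stage("quantify", {
      comp <- comp_res[[cfg$quantify_group]]
      refs <- cfg$ref_genes %||% head(comp$gene[order(comp$final_rank)], 2)
      targets <- cfg$targets %||%
        utils::tail(comp$gene[order(comp$final_rank)], 2)
      member <- stab_grouping$tissue[stab_grouping$group ==
                                       cfg$quantify_group]
      ct_g <- sim$ct %>% filter(.data$tissue %in% member)
      r <- pfaffl_ratio(ct_g, targets = targets, ref_genes = refs,
                        calibrator = cfg$calibrator)
      list(ratios = r, comparison = compare_groups(r, alpha = cfg$alpha))
    })
    ratios <- quant$ratios
    comparison <- quant$comparison
    write_table_auto(ratios, file.path(cfg$out_dir, "ratios.tsv"))
    write_table_auto(comparison$pairwise,
                     file.path(cfg$out_dir, "comparisons.tsv"))
    write_table_auto(comparison$anova,
                     file.path(cfg$out_dir, "anova.tsv"))
  }

  log_cfg <- unclass(cfg)
  log_cfg$package_version <- as.character(utils::packageVersion("refstab"))
  yaml::write_yaml(log_cfg, file.path(cfg$out_dir, "run_log.yaml"))

  invisible(list(
    screen_candidates = screen_res$candidates,
    screen_summary = screen_res$summary,
    efficiency = eff_res,
    stability = stab_res,
    comprehensive = comp_res,
    ratios = ratios,
    comparison = comparison,
    truth = sim$truth
  ))
}
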