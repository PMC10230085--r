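#' Tidy and glance methods
#'
#' Broom-style accessors for the package's fitted objects.
#'
#' @param x A `genorm_fit`, `bestkeeper_fit` or `ratio_comparison`.
#' @param ... Unused.
#' @return `tidy()` returns the per-gene (or per-comparison) tibble;
#'   `glance()` a one-row (or per-target) summary tibble.
#' @name refstab-tidiers
NULL

#' @rdname refstab-tidiers
#' @method tidy genorm_fit
#' @export
tidy.genorm_fit <- function(x, ...) {
  x$stability
}

#' @rdname refstab-tidiers
#' @method glance genorm_fit
#' @export
glance.genorm_fit <- function(x, ...) {
  tibble(
    n_genes = x$n_genes,
    n_samples = x$n_samples,
    final_pair = paste(x$final_pair, collapse = "/"),
    v_2_3 = if (!is.null(x$pairwise_variation)) {
      x$pairwise_variation$v[x$pairwise_variation$n == 2]
    } else {
      NA_real_
    }
  )
}

#' @rdname refstab-tidiers
#' @method tidy bestkeeper_fit
#' @export
tidy.bestkeeper_fit <- function(x, ...) {
  x$descriptives %>%
    left_join(x$stability %>% select("gene", "rank"), by = "gene")
}

#' @rdname refstab-tidiers
#' @method glance bestkeeper_fit
#' @export
glance.bestkeeper_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$descriptives),
    n_samples = x$descriptives$n_samples[1],
    n_inconsistent = sum(x$descriptives$inconsistent)
  )
}

#' @rdname refstab-tidiers
#' @method tidy ratio_comparison
#' @export
tidy.ratio_comparison <- function(x, ...) {
  x$pairwise
}

#' @rdname refstab-tidiers
#' @method glance ratio_comparison
#' @export
glance.ratio_comparison <- function(x, ...) {
  x$anova
}
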