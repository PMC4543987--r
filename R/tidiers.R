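#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a CNV association fit into its region table
#'
#' One row per CNVR with span, type, anchor p-value, carrier counts and
#' (if annotated) genes/exonic/cytoband, sorted by ascending p.
#'
#' @param x A `cnv_assoc` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cnv_assoc
#' @export
tidy.cnv_assoc <- function(x, ...) {
  out <- x$regions
  out$region <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  select(out, "region", dplyr::everything(), -"member_probes")
}

#' One-row summary of a CNV association fit
#'
#' @param x A `cnv_assoc` object.
#' @param ... Unused.
#' @return A tibble with `n_cases`, `n_controls`, `n_tests`, `threshold`,
#'   `fwer`, `n_regions`, `n_significant`, `min_p`.
#' @method glance cnv_assoc
#' @export
glance.cnv_assoc <- function(x, ...) {
  tibble(
    n_cases = x$n_cases, n_controls = x$n_controls,
    n_tests = x$n_tests, threshold = x$threshold, fwer = x$fwer,
    n_regions = nrow(x$regions),
    n_significant = sum(x$regions$significant),
    min_p = if (nrow(x$regions) > 0) min(x$regions$p) else NA_real_
  )
}

#' @method tidy cnv_pca
#' @export
tidy.cnv_pca <- function(x, ...) x$coordinates

#' @method glance cnv_pca
#' @export
glance.cnv_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$coordinates), n_probes = x$n_probes,
         eigenvalue_1 = x$eigenvalues[1],
         prop_var_1 = x$eigenvalues[1] / sum(x$eigenvalues))
}

#' @method tidy cohort_profile
#' @export
tidy.cohort_profile <- function(x, ...) x$table

#' @method glance cohort_profile
#' @export
glance.cohort_profile <- function(x, ...) {
  t <- x$table
  get <- function(m, col) t[[col]][t$metric == m]
  tibble(n_cases = get("n_samples", "cases"),
         n_controls = get("n_samples", "controls"),
         mean_cnvs_cases = get("mean_cnvs_per_subject", "cases"),
         mean_cnvs_controls = get("mean_cnvs_per_subject", "controls"),
         p_total = get("mean_cnvs_per_subject", "p"))
}

#' Plot the per-probe association scan of a CNV association fit
#'
#' -log10 Fisher p per probe along the genome, faceted by chromosome,
#' coloured by CNV type, with the experiment-wide threshold drawn as a
#' dashed line.
#'
#' @param object A `cnv_assoc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cnv_assoc
#' @export
autoplot.cnv_assoc <- function(object, ...) {
  df <- filter(object$probe_tests, .data$a + .data$c > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6,
                                   y = -log10(.data$p),
                                   colour = .data$cnv_type)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$threshold),
                        linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)),
                  colour = "CNV type") +
    ggplot2::theme_minimal()
}

#' Plot genotype PCA coordinates
#'
#' @param object A `cnv_pca` object.
#' @param labels Optional named vector (sample_id -> label) used to colour
#'   points, e.g. ethnicity or phenotype.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2.
#' @method autoplot cnv_pca
#' @export
autoplot.cnv_pca <- function(object, labels = NULL, ...) {
  df <- object$coordinates
  df$label <- if (is.null(labels)) "sample" else labels[df$sample_id]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-subject CNV burden by group
#'
#' @param object A `cohort_profile` object.
#' @param ... Unused.
#' @return A ggplot of per-subject total/deletion/duplication counts.
#' @method autoplot cohort_profile
#' @export
autoplot.cohort_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_subject,
                            c("total", "deletions", "duplications"),
                            names_to = "class", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype, y = .data$count,
                                   fill = .data$phenotype)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$class), scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "CNV calls per subject") +
    ggplot2::theme_minimal()
}
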