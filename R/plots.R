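#' Fold-change / significance overview of a differential-expression report
#'
#' @param object A `de_report` from [subtype_report()].
#' @param ... Unused.
#' @return A ggplot: per comparison, log2 fold change against -log10 p with
#'   the 1.8-fold arrow thresholds marked.
#' @export
autoplot.de_report <- function(object, ...) {
  ggplot(object, aes(x = log2(.data$fold_change), y = -log10(.data$p_value),
                     colour = .data$arrow)) +
    geom_point(alpha = 0.8) +
    geom_vline(xintercept = c(-log2(1.8), log2(1.8)), linetype = "dotted") +
    geom_hline(yintercept = -log10(0.05), linetype = "dotted") +
    facet_wrap(~comparison) +
    scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                   none = "grey60")) +
    labs(x = expression(log[2] ~ "fold change"), y = expression(-log[10] ~ p),
         title = "Differential miRNA expression between subtypes") +
    theme_minimal()
}

#' Heatmap of a miRNA abundance matrix
#'
#' log2-transformed, floor-imputed abundances, samples in columns; a quick
#' visual analogue of the cohort heatmap.
#'
#' @param abundance Long abundance tibble.
#' @param samples Optional metadata with `sample_id`, `subtype` to order and
#'   annotate columns.
#' @return A ggplot tile plot.
#' @export
plot_abundance_heatmap <- function(abundance, samples = NULL) {
  dat <- impute_floor(abundance) %>% mutate(log2_value = log2(.data$value))
  if (!is.null(samples)) {
    dat <- left_join(dat, select(samples, "sample_id", "subtype"),
                     by = "sample_id") %>%
      arrange(.data$subtype, .data$sample_id)
    dat$sample_id <- factor(dat$sample_id, levels = unique(dat$sample_id))
  }
  ggplot(dat, aes(x = .data$sample_id, y = .data$mirna,
                  fill = .data$log2_value)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = expression(log[2] ~ "abundance"),
         title = "miRNA abundance") +
    theme_minimal() +
    theme(axis.text.x = element_blank(), axis.ticks.x = element_blank())
}

#' Replicate fold-change overview of Argonaute association calls
#'
#' @param object An `ago_calls` tibble.
#' @param ... Unused.
#' @return A ggplot: minimum replicate fold change against -log10 p per
#'   antibody, with the 1.8-fold / 0.05 decision boundaries.
#' @export
autoplot.ago_calls <- function(object, ...) {
  ggplot(object, aes(x = log2(.data$min_fc), y = -log10(.data$p_value),
                     colour = .data$passed)) +
    geom_point(alpha = 0.8) +
    geom_vline(xintercept = log2(1.8), linetype = "dotted") +
    geom_hline(yintercept = -log10(0.05), linetype = "dotted") +
    facet_wrap(~antibody) +
    scale_colour_manual(values = c(`TRUE` = "#27ae60", `FALSE` = "grey60")) +
    labs(x = expression(log[2] ~ "min replicate FC vs isotype"),
         y = expression(-log[10] ~ p), colour = "associated",
         title = "Argonaute association calls") +
    theme_minimal()
}
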