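#' Cohort composition summary
#'
#' Counts and percentages (two decimals) per categorical characteristic
#' (cytogenetic subtype, FAB class, sex) and medians with min-max ranges for
#' numeric characteristics (age, white blood cell count, blast content, the
#' latter stratified by tissue source), in the layout of a clinical
#' characteristics table.
#'
#' @param samples Sample tibble with at least `sample_id` and `subtype`;
#'   `fab`, `sex`, `age`, `wbc`, `blast_percent`, `tissue` are summarized
#'   when present.
#' @return A list of tibbles: `categorical` (`characteristic`, `level`,
#'   `n`, `percent`) and `numeric` (`characteristic`, `stratum`, `n`,
#'   `median`, `min`, `max`).
#' @export
cohort_summary <- function(samples) {
  samples <- as_tibble(samples)
  if (nrow(samples) == 0) abort("empty cohort")
  n_total <- nrow(samples)
  cat_one <- function(col) {
    if (!col %in% names(samples)) return(NULL)
    samples %>%
      count(level = as.character(.data[[col]])) %>%
      mutate(characteristic = col, percent = round(100 * .data$n / n_total, 2)) %>%
      select("characteristic", "level", "n", "percent")
  }
  num_one <- function(col, by_tissue = FALSE) {
    if (!col %in% names(samples)) return(NULL)
    grp <- if (by_tissue && "tissue" %in% names(samples)) {
      group_by(samples, stratum = .data$tissue)
    } else mutate(samples, stratum = "all") %>% group_by(.data$stratum)
    grp %>%
      summarise(n = sum(!is.na(.data[[col]])),
                median = median(.data[[col]], na.rm = TRUE),
                min = min(.data[[col]], na.rm = TRUE),
                max = max(.data[[col]], na.rm = TRUE), .groups = "drop") %>%
      mutate(characteristic = col) %>%
      select("characteristic", "stratum", "n", "median", "min", "max")
  }
  list(
    categorical = bind_rows(map(c("subtype", "fab", "sex"), cat_one)),
    numeric = bind_rows(num_one("age"), num_one("wbc"),
                        num_one("blast_percent", by_tissue = TRUE))
  )
}

#' Detection filter for the cohort heatmap
#'
#' Retains miRNAs detected in at least `min_samples` samples; all remaining
#' miRNAs are summarized into a single reserved `all_others` row (per-sample
#' sum of their values, detected wherever any member was detected).
#'
#' @param abundance Long abundance tibble.
#' @param min_samples Minimum number of samples with detection (inclusive,
#'   default 3).
#' @return List with `retained` (character vector) and `abundance` (long
#'   tibble over retained miRNAs plus the `all_others` aggregate).
#' @export
detection_filter <- function(abundance, min_samples = 3) {
  det <- abundance %>%
    group_by(.data$mirna) %>%
    summarise(n_det = sum(.data$detected), .groups = "drop")
  retained <- det$mirna[det$n_det >= min_samples]
  rest <- abundance %>%
    filter(!.data$mirna %in% retained) %>%
    group_by(.data$sample_id) %>%
    summarise(mirna = "all_others",
              value = sum(.data$value[.data$detected], na.rm = TRUE),
              detected = any(.data$detected), .groups = "drop") %>%
    mutate(value = if_else(.data$detected, .data$value, NA_real_))
  list(
    retained = retained,
    abundance = bind_rows(filter(abundance, .data$mirna %in% retained), rest)
  )
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p by enumeration of rank assignments when the pooled sample is
#' small (`n_x + n_y <= exact_limit`) and tie-free; otherwise the normal
#' approximation with tie and continuity correction. The p-value depends
#' only on ranks, so it is invariant under strictly monotone transforms.
#'
#' @param x,y Numeric value vectors for the two groups.
#' @param exact_limit Largest pooled size for the exact computation
#'   (default 12).
#' @return A single two-sided p-value in (0, 1].
#' @export
mwu_test <- function(x, y, exact_limit = 12) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= exact_limit
  p <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
  min(p, 1)
}

#' Fold change between two groups as a ratio of medians
#'
#' Medians are robust on ratio-scale abundances and match the rank-based
#' testing; set `estimator = "mean"` for a mean-ratio variant. Not-detected
#' values should be floor-imputed upstream ([impute_floor()]) so they
#' participate. A zero denominator median is replaced by `floor` and the
#' result flagged.
#'
#' @param a,b Numeric value vectors (group A / group B).
#' @param estimator `"median"` (default) or `"mean"`.
#' @param floor Value standing in for a zero denominator.
#' @return A list with `fc` and `flagged`.
#' @export
group_fold_change <- function(a, b, estimator = c("median", "mean"),
                              floor = 1e-3) {
  estimator <- match.arg(estimator)
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  est <- if (estimator == "median") median else mean
  num <- est(a)
  den <- est(b)
  flagged <- den <= 0
  if (flagged) den <- floor
  list(fc = num / den, flagged = flagged)
}

#' Differential miRNA expression between cytogenetic subtypes
#'
#' For every miRNA and comparison: fold change (ratio of group medians after
#' floor imputation), Mann-Whitney U p-value, significance stars
#' (`p < 0.05` / `0.01` / `0.001`) and an up/down arrow when the fold change
#' is at least 1.8 (or at most 1/1.8). The report is restricted to miRNAs
#' carrying an arrow in at least one comparison; stars reflect raw p-values,
#' with an optional Benjamini-Hochberg column available but off by default.
#'
#' @param abundance Long abundance tibble.
#' @param samples Metadata tibble with `sample_id`, `subtype`.
#' @param comparisons Named list; each element is `list(a = <subtypes>,
#'   b = <subtypes> or "rest")`.
#' @param fc_arrow Arrow threshold (default 1.8).
#' @param adjust Add a `p_adj` (Benjamini-Hochberg, per comparison) column.
#' @param restrict If `TRUE` (default) keep only arrowed miRNAs.
#' @return A `de_report` tibble: `mirna`, `comparison`, `fold_change`,
#'   `p_value`, `stars`, `arrow` (and `p_adj` when requested).
#' @export
subtype_report <- function(abundance, samples, comparisons, fc_arrow = 1.8,
                           adjust = FALSE, restrict = TRUE) {
  stopifnot(is.list(comparisons), !is.null(names(comparisons)))
  known <- unique(samples$subtype)
  imp <- impute_floor(abundance) %>%
    left_join(select(samples, "sample_id", "subtype"), by = "sample_id")
  one_comparison <- function(spec, label) {
    a_lab <- spec$a
    b_lab <- if (identical(spec$b, "rest")) setdiff(known, a_lab) else spec$b
    unknown <- setdiff(c(a_lab, b_lab), known)
    if (length(unknown)) {
      abort(paste0("comparison '", label, "' names unknown subtype(s): ",
                   paste(unknown, collapse = ", ")))
    }
    imp %>%
      filter(.data$subtype %in% c(a_lab, b_lab)) %>%
      group_by(.data$mirna) %>%
      summarise(
        fold_change = group_fold_change(.data$value[.data$subtype %in% a_lab],
                                        .data$value[.data$subtype %in% b_lab])$fc,
        p_value = mwu_test(.data$value[.data$subtype %in% a_lab],
                           .data$value[.data$subtype %in% b_lab]),
        .groups = "drop"
      ) %>%
      mutate(comparison = label)
  }
  out <- imap(comparisons, one_comparison) %>%
    bind_rows() %>%
    mutate(
      stars = p_stars(.data$p_value),
      arrow = case_when(.data$fold_change >= fc_arrow ~ "up",
                        .data$fold_change <= 1 / fc_arrow ~ "down",
                        TRUE ~ "none")
    ) %>%
    select("mirna", "comparison", "fold_change", "p_value", "stars", "arrow")
  if (adjust) {
    out <- out %>%
      group_by(.data$comparison) %>%
      mutate(p_adj = p.adjust(.data$p_value, method = "BH")) %>%
      ungroup()
  }
  if (restrict) {
    arrowed <- unique(out$mirna[out$arrow != "none"])
    out <- filter(out, .data$mirna %in% arrowed)
  }
  class(out) <- c("de_report", class(out))
  out
}

#' qPCR delta-CT helper
#'
#' `delta_ct = ct_target - ct_reference` relative to a loading control (e.g.
#' U6 snoRNA) and the linear level transform `2^(-ct_target)`; a delta-CT
#' difference of -1 between conditions is a 2-fold higher expression.
#'
#' @param ct_target,ct_reference Cycle-threshold vectors (recycled).
#' @return Tibble `ct_target`, `ct_reference`, `delta_ct`, `level`.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  tibble(ct_target = ct_target, ct_reference = ct_reference,
         delta_ct = ct_target - ct_reference, level = 2^(-ct_target))
}
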