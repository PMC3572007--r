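#' Significance stars from a p-value
#'
#' Standard star annotation used throughout the reports: `p < 0.05` one star,
#' `p < 0.01` two, `p < 0.001` three, otherwise the empty string.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of `""`, `"*"`, `"**"`, `"***"`.
#' @export
p_stars <- function(p) {
  stopifnot(is.numeric(p))
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Floor-impute not-detected abundances
#'
#' Replaces not-detected values with half the smallest detected value of the
#' same sample, so rank tests, fold changes and log transforms are defined
#' everywhere. Samples with no detected feature at all receive `fallback`.
#'
#' @param abundance Long abundance tibble with columns `sample_id`, `mirna`,
#'   `value`, `detected`.
#' @param fallback Floor used when a sample has no detected feature.
#' @return The tibble with `value` imputed and unchanged `detected` mask.
#' @export
impute_floor <- function(abundance, fallback = 1e-3) {
  stopifnot(all(c("sample_id", "mirna", "value", "detected") %in% names(abundance)))
  abundance %>%
    group_by(.data$sample_id) %>%
    mutate(
      .floor = {
        det <- .data$value[.data$detected & is.finite(.data$value) & .data$value > 0]
        if (length(det)) min(det) / 2 else fallback
      },
      value = if_else(.data$detected & is.finite(.data$value), .data$value, .data$.floor)
    ) %>%
    ungroup() %>%
    select(-".floor")
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which two labelings agree (same/same or
#' different/different). Used to score recovery of planted subtype structure
#' by unsupervised clustering.
#'
#' @param a,b Label vectors of equal length.
#' @return The Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  pairs <- combn(length(a), 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}

#' Samples x miRNAs matrix from a long abundance tibble
#'
#' Pivots the long abundance form into the samples-by-features matrix used
#' by the classifier and the clustering stage. Floor-impute first
#' ([impute_floor()]) when not-detected entries are present.
#'
#' @param abundance Long abundance tibble (`sample_id`, `mirna`, `value`).
#' @param log2 Return log2-transformed values (default `FALSE`).
#' @return Numeric matrix, rows named by sample, columns by miRNA.
#' @export
abundance_matrix <- function(abundance, log2 = FALSE) {
  wide <- abundance %>%
    select("sample_id", "mirna", "value") %>%
    pivot_wider(names_from = "mirna", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  if (log2) base::log2(m) else m
}

# internal alias kept for terseness
abundance_wide <- function(abundance) abundance_matrix(abundance)

check_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
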