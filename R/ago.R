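#' Replicate-matched IP/control fold changes
#'
#' Fold changes between the Argonaute immunoprecipitate and the isotype
#' control are computed per biological replicate (`ip_r / control_r`),
#' since the replicates were processed as parallel batches; set
#' `mode = "mean_control"` to divide every IP replicate by the mean control
#' level instead. Zero control levels are floor-imputed (half the smallest
#' positive control level) and flagged.
#'
#' @param ip,control IP tibbles (`antibody`, `replicate`, `feature`, `level`)
#'   restricted to one antibody and the control, same features and replicate
#'   indices.
#' @param mode `"replicate"` (default) or `"mean_control"`.
#' @return Tibble `feature`, `replicate`, `fc`, `flagged`.
#' @export
replicate_fold_changes <- function(ip, control,
                                   mode = c("replicate", "mean_control")) {
  mode <- match.arg(mode)
  ip <- as_tibble(ip)
  control <- as_tibble(control)
  if (mode == "mean_control") {
    control <- control %>%
      group_by(.data$feature) %>%
      summarise(level = mean(.data$level), .groups = "drop") %>%
      expand_grid(replicate = unique(ip$replicate)) %>%
      select("feature", "replicate", "level")
  }
  joined <- inner_join(select(ip, "feature", "replicate", ip_level = "level"),
                       select(control, "feature", "replicate",
                              control_level = "level"),
                       by = c("feature", "replicate"))
  if (nrow(joined) < nrow(ip)) {
    abort("missing replicate pairing between IP and control")
  }
  floor_val <- {
    pos <- joined$control_level[joined$control_level > 0]
    if (length(pos)) min(pos) / 2 else 1e-3
  }
  joined %>%
    mutate(flagged = .data$control_level <= 0,
           fc = .data$ip_level / if_else(.data$flagged, floor_val,
                                         .data$control_level)) %>%
    select("feature", "replicate", "fc", "flagged")
}

#' Two-sided Welch t-test on log2 levels
#'
#' Two-sample t-test for unequal variances (Welch-Satterthwaite degrees of
#' freedom), applied to log2-transformed levels so ratio-scale variance is
#' stabilized. Degenerate inputs follow explicit conventions: zero variance
#' in both groups with equal means gives p = 1; with unequal means, p = 0
#' (flagged in the attribute `degenerate`).
#'
#' @param a,b Numeric level vectors (length >= 2 each), positive.
#' @param log2_transform Transform to log2 before testing (default `TRUE`).
#' @return A single two-sided p-value.
#' @export
welch_t_test <- function(a, b, log2_transform = TRUE) {
  if (length(a) < 2 || length(b) < 2) abort("need >= 2 values per group")
  if (log2_transform) {
    stopifnot(all(a > 0), all(b > 0))
    a <- log2(a)
    b <- log2(b)
  }
  if (sd(a) == 0 && sd(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  t.test(a, b, var.equal = FALSE)$p.value
}

#' Decide whether a feature is Argonaute-associated
#'
#' A feature passes iff every replicate fold change is at least `fc_min`
#' (inclusive, "at least 1.8") and the p-value is strictly below `alpha`.
#'
#' @param fc Numeric vector of per-replicate fold changes, finite, positive.
#' @param p Welch p-value.
#' @param fc_min Fold-change threshold (default 1.8).
#' @param alpha Significance threshold (default 0.05).
#' @return Tibble row: `min_fc`, `p_value`, `passed`.
#' @export
call_associated <- function(fc, p, fc_min = 1.8, alpha = 0.05) {
  stopifnot(all(is.finite(fc)), all(fc > 0), length(p) == 1)
  tibble(min_fc = min(fc), p_value = as.numeric(p),
         passed = min(fc) >= fc_min && p < alpha)
}

#' Call Ago-associated features for every antibody against the isotype
#'
#' Applies [replicate_fold_changes()], [welch_t_test()] and
#' [call_associated()] to every tested antibody (all but the isotype and
#' beads-only controls) and feature of an IP dataset. The beads-only control
#' is carried through reporting but takes no part in the filter.
#'
#' @param ip_data IP tibble (`cell_line`, `antibody`, `replicate`, `feature`,
#'   `level`), including an `isotype` antibody.
#' @param fc_min,alpha Thresholds of [call_associated()].
#' @param mode Fold-change mode, see [replicate_fold_changes()].
#' @return An `ago_calls` tibble: `cell_line`, `antibody`, `feature`,
#'   `fc` (list-column of replicate fold changes), `min_fc`, `p_value`,
#'   `passed`.
#' @export
call_ago_associations <- function(ip_data, fc_min = 1.8, alpha = 0.05,
                                  mode = c("replicate", "mean_control")) {
  mode <- match.arg(mode)
  ip_data <- as_tibble(ip_data)
  if (!"isotype" %in% ip_data$antibody) abort("no isotype control in ip_data")
  control <- filter(ip_data, .data$antibody == "isotype")
  tested <- setdiff(unique(ip_data$antibody), c("isotype", "beads"))
  out <- map_dfr(tested, function(ab) {
    ip <- filter(ip_data, .data$antibody == ab)
    fcs <- replicate_fold_changes(ip, control, mode = mode)
    levels_by_feature <- split(ip$level, ip$feature)
    ctrl_by_feature <- split(control$level, control$feature)
    fcs %>%
      group_by(.data$feature) %>%
      summarise(fc = list(.data$fc), .groups = "drop") %>%
      mutate(
        antibody = ab,
        cell_line = ip$cell_line[1],
        p_value = map_dbl(.data$feature, function(f) {
          welch_t_test(levels_by_feature[[f]], ctrl_by_feature[[f]])
        })
      )
  })
  calls <- out %>%
    mutate(min_fc = map_dbl(.data$fc, min),
           passed = .data$min_fc >= fc_min & .data$p_value < alpha) %>%
    select("cell_line", "antibody", "feature", "fc", "min_fc",
           "p_value", "passed")
  class(calls) <- c("ago_calls", class(calls))
  calls
}

#' Cross-Argonaute exclusivity partition and overlap statistics
#'
#' For every feature associated with at least one Argonaute protein, records
#' the exact subset of antibodies it passed, yielding the full 15-cell
#' partition of the association union (plus the empty cell for completeness
#' of bookkeeping). Summary percentages — e.g. the fraction bound
#' exclusively to Ago2, or shared by all four Argonautes — are taken
#' relative to the union of associated features.
#'
#' @param calls An `ago_calls` tibble (or any tibble with `feature`,
#'   `antibody`, `passed`).
#' @return List with `features` (tibble `feature`, `agos`, `combination`,
#'   `n_agos`), `cells` (per-combination counts and percentages), and
#'   `summary` (union size, exclusive-per-Ago and all-four percentages).
#' @export
association_sets <- function(calls) {
  antibodies <- sort(unique(calls$antibody))
  assoc <- calls %>%
    filter(.data$passed) %>%
    group_by(.data$feature) %>%
    summarise(agos = list(sort(unique(.data$antibody))), .groups = "drop") %>%
    mutate(combination = map_chr(.data$agos, paste, collapse = "+"),
           n_agos = map_int(.data$agos, length))
  union_n <- nrow(assoc)
  cells <- assoc %>%
    count(.data$combination, name = "n") %>%
    mutate(percent = if (union_n > 0) round(100 * .data$n / union_n, 2) else 0) %>%
    arrange(dplyr::desc(.data$n))
  exclusive <- map_dbl(antibodies, function(ab) {
    sum(assoc$combination == ab)
  })
  summary <- tibble(
    statistic = c(paste0("exclusive_", antibodies), "all_antibodies", "union"),
    n = c(exclusive, sum(assoc$n_agos == length(antibodies)), union_n)
  ) %>%
    mutate(percent = if (union_n > 0) round(100 * .data$n / union_n, 2)
           else 0)
  summary$percent[summary$statistic == "union"] <- 100
  list(features = assoc, cells = cells, summary = summary)
}
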