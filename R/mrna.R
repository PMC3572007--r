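#' Quantile-normalize a probe intensity matrix across arrays
#'
#' Forces every array's value distribution onto the across-array mean
#' quantile distribution while preserving within-array ranks; ties receive
#' the mean of their quantile values. A single array is returned unchanged
#' with a warning.
#'
#' @param M Probes x arrays numeric matrix.
#' @return Matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(M) {
  M <- as.matrix(M)
  if (ncol(M) < 2) {
    warn("single array: quantile normalization is the identity")
    return(M)
  }
  out <- limma::normalizeQuantiles(M, ties = TRUE)
  dimnames(out) <- dimnames(M)
  out
}

#' Summarize probes to probesets by median polish
#'
#' Fits the additive two-way model `log2 intensity = probe effect + array
#' effect + overall` per probeset by iterated row/column median sweeps,
#' run to convergence (largest absolute change below `eps`), and reports
#' `overall + array effect` as the probeset expression — the standard
#' robust summarization of probe-level arrays. Summaries are invariant to
#' probe order within a probeset.
#'
#' @param M Probes x arrays numeric matrix on the log2 scale, all finite.
#' @param probe_map Tibble with columns `probe_id`, `probeset_id`, mapping
#'   every row of `M` (by rowname) to exactly one probeset.
#' @param eps Relative convergence tolerance on the residual fit (default
#'   1e-10, tight enough that reported effects are stable to ~1e-6).
#' @param maxiter Iteration cap (default 1000, ample for convergence at
#'   `eps` on typical probeset sizes).
#' @return Tibble `probeset_id`, `array_id`, `expression` (log2).
#' @export
median_polish_summarize <- function(M, probe_map, eps = 1e-10,
                                    maxiter = 1000) {
  M <- as.matrix(M)
  if (any(!is.finite(M))) abort("M must be finite on the log2 scale")
  stopifnot(all(c("probe_id", "probeset_id") %in% names(probe_map)),
            !is.null(rownames(M)))
  probe_map <- as_tibble(probe_map)
  if (anyDuplicated(probe_map$probe_id)) {
    abort("every probe must map to exactly one probeset")
  }
  missing <- setdiff(rownames(M), probe_map$probe_id)
  if (length(missing)) {
    abort(paste0("unmapped probe(s): ", paste(head(missing, 3), collapse = ", ")))
  }
  arrays <- colnames(M) %||% paste0("A", seq_len(ncol(M)))
  sets <- split(probe_map$probe_id, probe_map$probeset_id)
  map_dfr(names(sets), function(ps) {
    sub <- M[sets[[ps]], , drop = FALSE]
    expr <- if (nrow(sub) == 1) {
      as.numeric(sub)
    } else {
      fit <- medpolish(sub, eps = eps, maxiter = maxiter, trace.iter = FALSE)
      unname(fit$overall + fit$col)
    }
    tibble(probeset_id = ps, array_id = arrays, expression = expr)
  })
}
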