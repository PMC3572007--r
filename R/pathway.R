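#' Hypergeometric over-representation p-value
#'
#' One-sided tail probability of drawing at least `k` pathway members when
#' `n` genes are drawn without replacement from a universe of `N` genes of
#' which `K` belong to the pathway:
#' `p = sum_{j = k}^{min(K, n)} C(K, j) C(N-K, n-j) / C(N, n)`, evaluated
#' through the log-space-stable hypergeometric tail so universes of tens of
#' thousands of genes pose no numerical problem. Monotone decreasing in `k`
#' at fixed `(K, n, N)`.
#'
#' @param k Observed overlap (associated genes in the pathway).
#' @param K Pathway size within the universe.
#' @param n Number of associated genes.
#' @param N Universe size.
#' @return The one-sided p-value; `k = 0` gives exactly 1.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  k <- check_scalar_count(k, "k", min = 0)
  K <- check_scalar_count(K, "K", min = 0)
  n <- check_scalar_count(n, "n", min = 0)
  N <- check_scalar_count(N, "N", min = 1)
  if (K > N || n > N || k > min(K, n)) {
    abort("bounds violated: need k <= min(K, n) and K, n <= N")
  }
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway over-representation among Ago-associated genes
#'
#' One record per pathway with overlap `k`, pathway size `K`, query size
#' `n`, universe size `N`, the hypergeometric p-value and significance
#' stars; sorted by p. Stars reflect raw p-values (the convention of the
#' enrichment tables this reproduces); a Benjamini-Hochberg column is
#' available but off by default. Query genes outside the universe are
#' dropped with a warning, as are out-of-universe pathway members.
#'
#' @param assoc_genes Character vector of associated genes (the query).
#' @param pathways Named list of character vectors.
#' @param N Universe size (default 42500, the probed human gene universe);
#'   configurable to the actual probed universe.
#' @param universe Optional explicit universe vector; defaults to an
#'   anonymous universe of size `N` containing all pathway and query genes.
#' @param adjust Add a BH-adjusted column `p_adj`.
#' @param context Optional label (cell line / antibody) stamped on records.
#' @return An `enrichment_result` tibble: `pathway`, `context`, `k`, `K`,
#'   `n`, `N`, `p_value`, `stars`.
#' @export
enrich_pathways <- function(assoc_genes, pathways, N = 42500, universe = NULL,
                            adjust = FALSE, context = NA_character_) {
  if (length(pathways) == 0) {
    return(structure(tibble(pathway = character(0), context = character(0),
                            k = integer(0), K = integer(0), n = integer(0),
                            N = integer(0), p_value = numeric(0),
                            stars = character(0)),
                     class = c("enrichment_result", class(tibble()))))
  }
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  assoc_genes <- unique(assoc_genes)
  if (!is.null(universe)) {
    N <- length(unique(universe))
    out_q <- setdiff(assoc_genes, universe)
    if (length(out_q)) {
      warn(sprintf("dropping %d query gene(s) outside the universe",
                   length(out_q)))
      assoc_genes <- intersect(assoc_genes, universe)
    }
    pathways <- map(pathways, intersect, universe)
  }
  n_query <- length(assoc_genes)
  out <- imap(pathways, function(genes, nm) {
    genes <- unique(genes)
    tibble(pathway = nm, k = length(intersect(assoc_genes, genes)),
           K = length(genes))
  }) %>%
    bind_rows()
  out$context <- context
  out$n <- n_query
  out$N <- N
  out$p_value <- map2(out$k, out$K,
                      function(k, K) hypergeom_pvalue(k, K, n_query, N)) %>%
    unlist()
  out$stars <- p_stars(out$p_value)
  out <- out %>%
    arrange(.data$p_value, .data$pathway) %>%
    select("pathway", "context", "k", "K", "n", "N", "p_value", "stars")
  if (adjust) out$p_adj <- p.adjust(out$p_value, method = "BH")
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Cross-Argonaute pathway overlap
#'
#' How concerted is pathway-level regulation across the four Argonaute
#' proteins: a pathway counts as detected for an Argonaute context either
#' when at least one associated gene maps to it (`mode = "mapped"`, the
#' default — a pathway "could be identified") or when its enrichment is
#' significant at `alpha` (`mode = "significant"`). Reports the total
#' number of distinct detected pathways and the fraction detected in every
#' context.
#'
#' @param results Named list (one element per Argonaute context) of
#'   `enrichment_result` tibbles.
#' @param mode `"mapped"` or `"significant"`.
#' @param alpha Threshold for `mode = "significant"`.
#' @return List with `per_context` (named list of pathway id vectors),
#'   `n_total`, `n_shared`, `shared_fraction`.
#' @export
cross_ago_pathway_overlap <- function(results, mode = c("mapped", "significant"),
                                      alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is.list(results), length(results) >= 2, !is.null(names(results)))
  detected <- map(results, function(res) {
    if (mode == "mapped") res$pathway[res$k >= 1]
    else res$pathway[res$p_value < alpha]
  })
  total <- unique(unlist(detected))
  shared <- Reduce(intersect, detected)
  list(per_context = detected, n_total = length(total),
       n_shared = length(shared),
       shared_fraction = if (length(total)) length(shared) / length(total) else 0)
}

#' Dot plot of pathway enrichment results
#'
#' @param object An `enrichment_result`.
#' @param top Number of top pathways to show.
#' @param ... Unused.
#' @return A ggplot: pathways against -log10 p, dot size the overlap `k`.
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  dat <- head(arrange(object, .data$p_value), top)
  ggplot(dat, aes(x = -log10(.data$p_value),
                  y = stats::reorder(.data$pathway, -.data$p_value))) +
    geom_point(aes(size = .data$k)) +
    labs(x = expression(-log[10] ~ p), y = NULL, size = "overlap k",
         title = "Pathway over-representation") +
    theme_minimal()
}
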