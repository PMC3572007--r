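#' Intersect target-prediction sources
#'
#' Keeps a (miRNA, gene) edge iff it is reported by at least `min_sources`
#' of the prediction tables (default 2 of 3), recording the supporting
#' sources on the edge. Malformed rows (missing miRNA or gene) are skipped
#' and counted in the `n_skipped` attribute. Removing a source can only
#' shrink the retained edge set.
#'
#' @param tables List of prediction tibbles (`mirna`, `gene`, optionally
#'   `source`), or one long tibble with a `source` column.
#' @param min_sources Minimum number of supporting sources (default 2).
#' @return Tibble `mirna`, `gene`, `sources` (list-column), `n_sources`.
#' @export
intersect_predictions <- function(tables, min_sources = 2) {
  if (is.data.frame(tables)) {
    stopifnot("source" %in% names(tables))
    long <- as_tibble(tables)
  } else {
    long <- imap(tables, function(tab, nm) {
      tab <- as_tibble(tab)
      if (!"source" %in% names(tab)) tab$source <- nm
      tab
    }) %>% bind_rows()
  }
  bad <- is.na(long$mirna) | is.na(long$gene) | long$mirna == "" | long$gene == ""
  if (any(bad)) {
    warn(sprintf("skipping %d malformed prediction row(s)", sum(bad)))
    long <- long[!bad, ]
  }
  out <- long %>%
    distinct(.data$mirna, .data$gene, .data$source) %>%
    group_by(.data$mirna, .data$gene) %>%
    summarise(sources = list(sort(unique(.data$source))), .groups = "drop") %>%
    mutate(n_sources = map_int(.data$sources, length)) %>%
    filter(.data$n_sources >= min_sources) %>%
    arrange(.data$mirna, .data$gene)
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Group miRNAs into seed-sequence families
#'
#' Default rule: miRNAs sharing identical nucleotides 2-8 (the seed, the
#' primary determinant of target recognition) form one sequence group named
#' `seqgrp-<representative>` after the lexicographically smallest member.
#' Sequences shorter than 8 nt become singleton groups with a warning. An
#' alternative full-length rule groups miRNAs whose edit distance is at most
#' `max_dist` (single linkage over the similarity graph).
#'
#' @param mirnas Tibble with columns `mirna`, `sequence` (A/C/G/U).
#' @param rule `"seed"` (default) or `"edit"`.
#' @param max_dist Edit-distance threshold for `rule = "edit"`.
#' @return Tibble `group`, `mirna`, `sequence`, `representative`; groups
#'   partition the input and are invariant to input order.
#' @export
build_seq_groups <- function(mirnas, rule = c("seed", "edit"), max_dist = 3) {
  rule <- match.arg(rule)
  mirnas <- as_tibble(mirnas) %>% arrange(.data$mirna)
  stopifnot(all(c("mirna", "sequence") %in% names(mirnas)),
            !anyDuplicated(mirnas$mirna))
  bad <- grepl("[^ACGU]", toupper(mirnas$sequence))
  if (any(bad)) abort("sequences must be over the alphabet {A, C, G, U}")
  if (rule == "seed") {
    short <- nchar(mirnas$sequence) < 8
    if (any(short)) {
      warn(sprintf("%d sequence(s) shorter than 8 nt kept as singletons",
                   sum(short)))
    }
    key <- if_else(short, paste0("short:", mirnas$mirna),
                   substr(toupper(mirnas$sequence), 2, 8))
  } else {
    d <- utils::adist(toupper(mirnas$sequence))
    g <- igraph::graph_from_adjacency_matrix(d <= max_dist, mode = "undirected",
                                             diag = FALSE)
    key <- as.character(igraph::components(g)$membership)
  }
  mirnas %>%
    mutate(.key = key) %>%
    group_by(.data$.key) %>%
    mutate(representative = min(.data$mirna),
           group = paste0("seqgrp-", .data$representative)) %>%
    ungroup() %>%
    select("group", "mirna", "sequence", "representative") %>%
    arrange(.data$group, .data$mirna)
}

#' Assemble the miRNA-mRNA regulatory network
#'
#' Bipartite graph between sequence-group nodes and mRNA nodes: an edge
#' exists iff some member miRNA of the group and the mRNA are both
#' Ago-associated (with any Argonaute) and a retained, source-filtered
#' prediction edge links them. Node attributes carry per-Ago association
#' flags and signal levels; edge attributes carry the supporting sources
#' and member miRNAs. Node and edge order is deterministic.
#'
#' @param assoc_mirnas Tibble `feature`, `antibody`, `passed` for miRNAs
#'   (e.g. an `ago_calls` result).
#' @param assoc_mrnas Same, for mRNAs (features are gene ids).
#' @param edges Retained prediction edges ([intersect_predictions()]).
#' @param seqgroups Sequence groups ([build_seq_groups()]).
#' @param signal Optional tibble `feature`, `signal` of expression levels to
#'   stamp onto nodes.
#' @return An igraph graph (possibly empty) with `type` = `"seqgroup"` /
#'   `"mrna"` node attribute.
#' @export
assemble_network <- function(assoc_mirnas, assoc_mrnas, edges, seqgroups,
                             signal = NULL) {
  agos_of <- function(calls) {
    calls %>%
      filter(.data$passed) %>%
      group_by(.data$feature) %>%
      summarise(agos = paste(sort(unique(.data$antibody)), collapse = "+"),
                .groups = "drop")
  }
  mir_assoc <- agos_of(assoc_mirnas)
  mrna_assoc <- agos_of(assoc_mrnas)
  kept <- edges %>%
    filter(.data$mirna %in% mir_assoc$feature,
           .data$gene %in% mrna_assoc$feature) %>%
    inner_join(select(seqgroups, "mirna", "group"), by = "mirna")
  grp_edges <- kept %>%
    group_by(.data$group, .data$gene) %>%
    summarise(
      sources = paste(sort(unique(unlist(.data$sources))), collapse = "+"),
      member_mirnas = paste(sort(unique(.data$mirna)), collapse = "+"),
      .groups = "drop"
    ) %>%
    arrange(.data$group, .data$gene)
  if (nrow(grp_edges) == 0) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  grp_attr <- seqgroups %>%
    semi_join(kept, by = "mirna") %>%
    inner_join(mir_assoc, by = c(mirna = "feature")) %>%
    group_by(name = .data$group) %>%
    summarise(agos = paste(sort(unique(unlist(strsplit(.data$agos, "[+]")))),
                           collapse = "+"),
              members = paste(sort(.data$mirna), collapse = "+"),
              .groups = "drop") %>%
    mutate(type = "seqgroup")
  mrna_attr <- mrna_assoc %>%
    filter(.data$feature %in% grp_edges$gene) %>%
    rename(name = "feature") %>%
    mutate(type = "mrna", members = NA_character_) %>%
    arrange(.data$name)
  nodes <- bind_rows(grp_attr, mrna_attr)
  if (!is.null(signal)) {
    nodes <- left_join(nodes, rename(as_tibble(signal), name = "feature"),
                       by = "name")
  }
  igraph::graph_from_data_frame(grp_edges, directed = FALSE, vertices = nodes)
}

#' Export a network as GraphML / SIF / TSV edge list
#'
#' GraphML keeps all node and edge attributes; SIF writes
#' `seqgroup targets mrna` triples; the TSV edge list carries the edge
#' attributes as columns.
#'
#' @param graph An igraph graph from [assemble_network()].
#' @param path Output path without extension.
#' @param formats Subset of `c("graphml", "sif", "tsv")`.
#' @return Invisibly, the written paths.
#' @export
write_network <- function(graph, path, formats = c("graphml", "sif", "tsv")) {
  formats <- match.arg(formats, several.ok = TRUE)
  written <- character(0)
  el <- if (igraph::ecount(graph) > 0) {
    as_tibble(igraph::as_data_frame(graph, what = "edges"))
  } else tibble(from = character(0), to = character(0))
  if ("graphml" %in% formats) {
    f <- paste0(path, ".graphml")
    igraph::write_graph(graph, f, format = "graphml")
    written <- c(written, f)
  }
  if ("sif" %in% formats) {
    f <- paste0(path, ".sif")
    writeLines(if (nrow(el)) paste(el$from, "targets", el$to) else character(0), f)
    written <- c(written, f)
  }
  if ("tsv" %in% formats) {
    f <- paste0(path, ".edges.tsv")
    readr::write_tsv(el, f, progress = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}
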