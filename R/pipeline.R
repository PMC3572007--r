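# Cytogenetic categories pooled into the MLL-rearranged class.
MLL_SUBTYPES <- c("t(4;11)", "t(6;11)", "t(9;11)", "t(10;11)", "t(11;19)",
                  "other t(11q23)")

#' Default pipeline configuration
#'
#' Every fixed constant of the analysis in one place: the 100-LU / 50%-pixel
#' spot filter, the 1.8-fold and p < 0.05 association thresholds, 10-fold
#' cross-validation, the 42,500-gene universe, the 2-of-3 prediction-source
#' rule and the minimum-3-samples detection filter. The default
#' cross-validation uses 50 repeats, a desk-scale reduction of the
#' full-scale 1000; raise `classifier$iterations` to match.
#'
#' @param seed Global seed, mandatory before running.
#' @return Nested configuration list (YAML-serializable).
#' @export
pipeline_defaults <- function(seed = NULL) {
  list(
    seed = seed,
    sim = list(noise_cv = 0.2),
    quant = list(min_intensity = 100, min_frac_px = 0.5, ref_amount_fmol = 1,
                 input_mass_ug = 3),
    de = list(
      min_samples = 3, fc_arrow = 1.8,
      comparisons = list(
        "t(8;21) vs t(15;17)" = list(a = "t(8;21)", b = "t(15;17)"),
        "t(8;21) vs all other" = list(a = "t(8;21)", b = "rest"),
        "t(15;17) vs all other" = list(a = "t(15;17)", b = "rest"),
        "MLL rearranged vs all other" = list(a = MLL_SUBTYPES, b = "rest")
      )
    ),
    classifier = list(folds = 10, iterations = 50, n_delta = 30,
                      classes = c("t(8;21)", "t(15;17)", "MLL rearranged")),
    enrichment = list(fc_min = 1.8, alpha = 0.05),
    network = list(min_sources = 2, grouping_rule = "seed"),
    pathway = list(N = 42500, alpha = 0.05)
  )
}

#' Print the default configuration as YAML
#'
#' @return Invisibly, the defaults list.
#' @export
show_defaults <- function() {
  cat(yaml::as.yaml(pipeline_defaults()))
  invisible(pipeline_defaults())
}

pool_mll <- function(subtype) {
  if_else(subtype %in% MLL_SUBTYPES, "MLL rearranged", subtype)
}

#' Run the full analysis pipeline on synthetic or provided inputs
#'
#' Executes the stages in dependency order — simulate, quantify,
#' de / cluster / classify, call-ago, network, pathways — writing each
#' stage's outputs into `out_dir` together with a provenance manifest
#' (configuration, seed, package version, md5 checksum and record count per
#' file). A stage failure aborts with the failing stage named; outputs of
#' completed stages are retained.
#'
#' @param config Configuration list as from [pipeline_defaults()], or a path
#'   to a YAML file of the same shape. `config$seed` is mandatory.
#' @param out_dir Run directory, created if needed.
#' @param stages Character vector of stages to run, or `"all"`.
#' @param sim_override Optional [sim_config()] replacing the internally
#'   constructed one (e.g. to scale the synthetic cohort).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config, out_dir, stages = "all", sim_override = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) {
    abort("config$seed is mandatory; refusing to run an unseeded pipeline")
  }
  all_stages <- c("simulate", "quantify", "de", "cluster", "classify",
                  "call-ago", "network", "pathways")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  outputs <- character(0)
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }
  seed <- as.integer(config$seed)

  run_stage("simulate", function() {
    scfg <- sim_override %||% do.call(sim_config, c(config$sim, list(seed = seed)))
    res$sim_cfg <<- scfg
    res$cohort <<- simulate_cohort(scfg)
    res$ip <<- simulate_ip_experiment(scfg)
    write_spot_tables(res$cohort$spots, file.path(out_dir, "spots"))
    readr::write_tsv(res$cohort$samples, file.path(out_dir, "metadata.tsv"),
                     progress = FALSE)
    readr::write_tsv(res$ip, file.path(out_dir, "ip_levels.tsv"),
                     progress = FALSE)
    outputs <<- c(outputs, file.path(out_dir, c("metadata.tsv", "ip_levels.tsv")))
    log_stage("simulate", sprintf("%d samples, %d spot records, %d IP records",
                                  nrow(res$cohort$samples),
                                  nrow(res$cohort$spots), nrow(res$ip)))
  })

  run_stage("quantify", function() {
    qcfg <- do.call(quant_config, config$quant)
    res$abundance <<- quantify_cohort(res$cohort$spots, qcfg,
                                      calibration_expected(res$sim_cfg))
    f <- file.path(out_dir, "abundance.tsv")
    write_abundance(res$abundance, f)
    outputs <<- c(outputs, f, paste0(f, ".mask.tsv"))
    log_stage("quantify", sprintf("%d of %d feature measurements detected",
                                  sum(res$abundance$detected),
                                  nrow(res$abundance)))
  })

  run_stage("de", function() {
    present <- unique(res$cohort$samples$subtype)
    # restrict pooled comparison groups to the subtypes the cohort holds;
    # comparisons with no remaining group-A member are skipped with a note
    comparisons <- map(config$de$comparisons, function(cm) {
      a <- unlist(cm$a)
      b <- unlist(cm$b)
      list(a = intersect(a, present),
           b = if (identical(b, "rest")) "rest" else intersect(b, present))
    })
    empty <- vapply(comparisons, function(cm) {
      length(cm$a) == 0 || length(cm$b) == 0
    }, logical(1))
    if (any(empty)) {
      message(sprintf("[de] skipping comparison(s) without cohort members: %s",
                      paste(names(comparisons)[empty], collapse = ", ")))
      comparisons <- comparisons[!empty]
    }
    det <- detection_filter(res$abundance, min_samples = config$de$min_samples)
    res$de <<- subtype_report(
      filter(res$abundance, .data$mirna %in% det$retained),
      res$cohort$samples, comparisons, fc_arrow = config$de$fc_arrow)
    f <- file.path(out_dir, "de_report.tsv")
    readr::write_tsv(res$de, f, progress = FALSE)
    outputs <<- c(outputs, f)
    log_stage("de", sprintf("%d retained miRNAs, %d report rows",
                            length(det$retained), nrow(res$de)))
  })

  run_stage("cluster", function() {
    imp <- impute_floor(res$abundance)
    X <- log2(abundance_wide(imp))
    res$dendro <<- complete_linkage(euclidean_distances(X))
    f <- file.path(out_dir, "dendrogram.newick")
    write_newick(res$dendro, f)
    outputs <<- c(outputs, f)
    log_stage("cluster", sprintf("%d leaves", res$dendro$n_leaves))
  })

  run_stage("classify", function() {
    samples <- mutate(res$cohort$samples, class = pool_mll(.data$subtype))
    keep <- samples$class %in% config$classifier$classes
    imp <- impute_floor(res$abundance)
    X <- log2(abundance_wide(imp))[samples$sample_id[keep], , drop = FALSE]
    res$cv <<- cross_validate_nsc(
      X, samples$class[keep], folds = config$classifier$folds,
      iterations = config$classifier$iterations, seed = seed)
    f <- file.path(out_dir, "cv_report.tsv")
    readr::write_tsv(tidy(res$cv), f, progress = FALSE)
    outputs <<- c(outputs, f)
    log_stage("classify", sprintf(
      "accuracy %.3f at delta %.3g, %d surviving features",
      res$cv$accuracy, res$cv$chosen_delta, length(res$cv$surviving_features)))
  })

  run_stage("call-ago", function() {
    res$calls <<- call_ago_associations(res$ip,
                                        fc_min = config$enrichment$fc_min,
                                        alpha = config$enrichment$alpha)
    f <- file.path(out_dir, "ago_calls.tsv")
    readr::write_tsv(select(res$calls, -"fc"), f, progress = FALSE)
    outputs <<- c(outputs, f)
    log_stage("call-ago", sprintf("%d of %d feature-antibody tests associated",
                                  sum(res$calls$passed), nrow(res$calls)))
  })

  run_stage("network", function() {
    set.seed(seed + 10L)
    mir_ids <- sort(unique(res$calls$feature))
    genes <- sprintf("GENE%05d", seq_len(2000))
    seqs <- map_chr(mir_ids, function(...) {
      paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = "")
    })
    res$seqgroups <<- build_seq_groups(tibble(mirna = mir_ids, sequence = seqs),
                                       rule = config$network$grouping_rule)
    assoc_mirs <- unique(res$calls$feature[res$calls$passed])
    assoc_genes <- sample(genes, 150)
    res$assoc_mrnas <<- tibble(feature = genes, antibody = "Ago2",
                               passed = genes %in% assoc_genes)
    true_edges <- expand_grid(mirna = assoc_mirs, gene = assoc_genes) %>%
      dplyr::slice_sample(n = min(400, length(assoc_mirs) * length(assoc_genes)))
    preds <- simulate_target_predictions(mir_ids, genes, true_edges, res$sim_cfg)
    res$edges <<- intersect_predictions(preds,
                                        min_sources = config$network$min_sources)
    res$graph <<- assemble_network(res$calls, res$assoc_mrnas, res$edges,
                                   res$seqgroups)
    outputs <<- c(outputs, write_network(res$graph, file.path(out_dir, "network")))
    log_stage("network", sprintf("%d edges retained, graph with %d nodes / %d edges",
                                 nrow(res$edges), igraph::vcount(res$graph),
                                 igraph::ecount(res$graph)))
  })

  run_stage("pathways", function() {
    genes <- sort(unique(res$assoc_mrnas$feature))
    pw <- simulate_pathways(genes, res$sim_cfg)
    f_gmt <- file.path(out_dir, "pathways.gmt")
    write_gmt(pw, f_gmt)
    assoc <- res$assoc_mrnas$feature[res$assoc_mrnas$passed]
    res$enrichment <<- enrich_pathways(assoc, pw, N = length(genes))
    f <- file.path(out_dir, "enrichment.tsv")
    readr::write_tsv(res$enrichment, f, progress = FALSE)
    outputs <<- c(outputs, f_gmt, f)
    log_stage("pathways", sprintf("%d pathways tested, %d starred",
                                  nrow(res$enrichment),
                                  sum(res$enrichment$stars != "")))
  })

  manifest <- list(
    package = "agomir",
    version = as.character(utils::packageVersion("agomir")),
    seed = seed,
    stages = stages,
    config = config,
    files = map(sort(unique(outputs)), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)),
           bytes = file.size(f))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(c(res, list(manifest = manifest_path)))
}
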