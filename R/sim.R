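#' Simulation configuration for the synthetic study emulator
#'
#' Bundles every knob of the synthetic-data generators that emulate the data
#' structure of a quantitative two-color miRNA microarray study of an AML
#' cohort: a universal reference of 493 synthetic miRNA oligonucleotides at
#' 1 fmol each in the second channel, calibration and control spots,
#' cytogenetic-subtype groups with planted fold changes, triplicate Argonaute
#' immunoprecipitation (IP) experiments against an isotype control, partially
#' overlapping target-prediction sources, and pathway collections over a
#' large gene universe.
#'
#' @param n_mirnas Number of miRNA probes / reference oligos (default 493).
#' @param n_samples_per_group Named integer vector, samples per cytogenetic
#'   subtype. Defaults to the enriched pediatric-AML composition used
#'   throughout (102 samples over eleven cytogenetic categories).
#' @param planted_fc Tibble with columns `mirna`, `subtype`, `fc`: true
#'   fold change of a miRNA in one subtype relative to its cohort baseline.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   spot noise (0 = noise-free, exactly invertible generation).
#' @param background_mean,background_sd Additive per-spot background, light
#'   units (LU).
#' @param n_calibration_spots Number of spiked-in calibration spots per array.
#' @param calibration_lu Expected calibrated intensity of each calibration
#'   spot, LU.
#' @param signal_per_fmol Scanner gain: LU of background-corrected signal per
#'   fmol of hybridized oligo.
#' @param frac_absent Fraction of miRNAs whose true signal sits below the
#'   100-LU detection filter (exercises the not-detected mask).
#' @param ip_replicates Biological replicates per IP antibody (default 3;
#'   at least 2 so the Welch test is defined).
#' @param planted_enrichment Tibble with columns `feature`, `ago`, `ratio`:
#'   true IP/isotype enrichment of a feature in one Argonaute pull-down.
#' @param n_ip_features Number of features measured in the IP experiment.
#' @param n_genes Size of the gene universe (default 42500).
#' @param n_pathways Number of synthetic pathway gene sets.
#' @param pathway_size_range Length-2 integer vector, inclusive range of
#'   pathway sizes.
#' @param prediction_overlap Probability that a true miRNA-target edge is
#'   reported by each of the three prediction sources, independently.
#' @param n_decoys_per_source Decoy (false) edges added to each source.
#' @param seed Integer seed; mandatory, every generator is a pure function
#'   of the configuration.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_mirnas = 493,
                       n_samples_per_group = c(
                         "t(4;11)" = 1, "t(6;11)" = 2, "t(9;11)" = 16,
                         "t(10;11)" = 6, "t(11;19)" = 5, "other t(11q23)" = 3,
                         "t(15;17)" = 14, "inv(16)" = 13, "t(8;21)" = 24,
                         "normal karyotype" = 4, "other" = 14
                       ),
                       planted_fc = NULL,
                       noise_cv = 0.2,
                       background_mean = 40,
                       background_sd = 8,
                       n_calibration_spots = 10,
                       calibration_lu = 2000,
                       signal_per_fmol = 1000,
                       frac_absent = 0.15,
                       ip_replicates = 3,
                       planted_enrichment = NULL,
                       n_ip_features = 100,
                       n_genes = 42500,
                       n_pathways = 50,
                       pathway_size_range = c(10, 200),
                       prediction_overlap = 0.8,
                       n_decoys_per_source = 200,
                       seed = NULL) {
  if (is.null(seed)) {
    abort("`seed` is mandatory: synthetic data must be reproducible.")
  }
  n_mirnas <- check_scalar_count(n_mirnas, "n_mirnas")
  n_genes <- check_scalar_count(n_genes, "n_genes")
  n_pathways <- check_scalar_count(n_pathways, "n_pathways")
  ip_replicates <- check_scalar_count(ip_replicates, "ip_replicates")
  if (ip_replicates < 2) {
    abort("`ip_replicates` must be >= 2 (replicate t-test undefined otherwise).")
  }
  if (is.null(names(n_samples_per_group)) || any(n_samples_per_group < 1)) {
    abort("`n_samples_per_group` must be a named vector of positive counts.")
  }
  stopifnot(
    noise_cv >= 0, background_mean >= 0, background_sd >= 0,
    signal_per_fmol > 0, calibration_lu > 0,
    frac_absent >= 0, frac_absent < 1,
    prediction_overlap >= 0, prediction_overlap <= 1,
    length(pathway_size_range) == 2,
    pathway_size_range[1] >= 1, pathway_size_range[2] <= n_genes,
    pathway_size_range[1] <= pathway_size_range[2]
  )
  if (!is.null(planted_fc)) {
    planted_fc <- as_tibble(planted_fc)
    stopifnot(all(c("mirna", "subtype", "fc") %in% names(planted_fc)),
              all(planted_fc$fc > 0))
    unknown <- setdiff(planted_fc$subtype, names(n_samples_per_group))
    if (length(unknown)) {
      abort(paste0("planted_fc names unknown subtype(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(planted_enrichment)) {
    planted_enrichment <- as_tibble(planted_enrichment)
    stopifnot(all(c("feature", "ago", "ratio") %in% names(planted_enrichment)),
              all(planted_enrichment$ratio > 0))
    unknown <- setdiff(planted_enrichment$ago, paste0("Ago", 1:4))
    if (length(unknown)) {
      abort(paste0("planted_enrichment names unknown antibody(ies): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  structure(
    list(
      n_mirnas = n_mirnas, n_samples_per_group = n_samples_per_group,
      planted_fc = planted_fc, noise_cv = noise_cv,
      background_mean = background_mean, background_sd = background_sd,
      n_calibration_spots = check_scalar_count(n_calibration_spots,
                                               "n_calibration_spots"),
      calibration_lu = calibration_lu, signal_per_fmol = signal_per_fmol,
      frac_absent = frac_absent, ip_replicates = ip_replicates,
      planted_enrichment = planted_enrichment,
      n_ip_features = check_scalar_count(n_ip_features, "n_ip_features"),
      n_genes = n_genes, n_pathways = n_pathways,
      pathway_size_range = as.integer(pathway_size_range),
      prediction_overlap = prediction_overlap,
      n_decoys_per_source = check_scalar_count(n_decoys_per_source,
                                               "n_decoys_per_source", min = 0),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Expected calibration-spot intensities for a configuration
#'
#' @param config A [sim_config()].
#' @return Named numeric vector, expected LU per calibration probe id.
#' @export
calibration_expected <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  setNames(rep(config$calibration_lu, config$n_calibration_spots),
           sprintf("CAL-%02d", seq_len(config$n_calibration_spots)))
}

# Multiplicative log-normal noise with mean 1 and coefficient of variation cv.
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a two-color miRNA microarray cohort
#'
#' Generates one spot table per sample plus sample metadata. The reference
#' channel carries the universal reference (1 fmol per miRNA); the sample
#' channel carries a per-miRNA baseline abundance multiplied by the planted
#' subtype fold change, perturbed by multiplicative log-normal noise and a
#' per-array per-channel gain that the spiked-in calibration spots remove
#' again downstream. Backgrounds are additive; negative-control spots carry
#' no signal; a configurable fraction of miRNAs sits below the detection
#' filter.
#'
#' With `noise_cv = 0` generation is exactly invertible: the quantification
#' pipeline returns the planted abundances bit-exactly.
#'
#' @param config A [sim_config()].
#' @return A list with elements `spots` (tibble of all spot records, one
#'   array per sample, in the spot-table column dialect of
#'   [write_spot_tables()]), `samples` (metadata tibble) and `truth`
#'   (tibble `mirna`, `subtype`, `amount_fmol` of true hybridized amounts).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mirnas <- sprintf("miR-%03d", seq_len(config$n_mirnas))
  subtypes <- names(config$n_samples_per_group)

  # Per-miRNA baseline hybridized amount (fmol); heavy-tailed across miRNAs,
  # shared by all samples so planted fold changes are the only group signal.
  baseline <- rlnorm(config$n_mirnas, meanlog = log(1), sdlog = 1)
  absent <- runif(config$n_mirnas) < config$frac_absent
  # below the 100-LU filter at the default gain of 1000 LU/fmol
  baseline[absent] <- runif(sum(absent), 0.005, 0.08)

  fc_lookup <- matrix(1, nrow = config$n_mirnas, ncol = length(subtypes),
                      dimnames = list(mirnas, subtypes))
  if (!is.null(config$planted_fc)) {
    pf <- config$planted_fc
    stopifnot(all(pf$mirna %in% mirnas))
    fc_lookup[cbind(match(pf$mirna, mirnas), match(pf$subtype, subtypes))] <- pf$fc
  }

  samples <- tibble(
    sample_id = sprintf("S%03d", seq_len(sum(config$n_samples_per_group))),
    subtype = rep(subtypes, times = config$n_samples_per_group)
  ) %>%
    mutate(
      tissue = sample(c("bone_marrow", "peripheral_blood"), n(),
                      replace = TRUE, prob = c(71, 31) / 102),
      blast_percent = round(pmin(100, pmax(
        if_else(.data$tissue == "bone_marrow", 20, 50),
        rnorm(n(), mean = if_else(.data$tissue == "bone_marrow", 74, 87), sd = 12)
      ))),
      age = round(runif(n(), 0.5, 17.9), 1),
      sex = sample(c("female", "male"), n(), replace = TRUE),
      wbc = round(rlnorm(n(), meanlog = log(42.5), sdlog = 0.9), 1),
      fab = sample(c("M0", "M1", "M2", "M3", "M4", "M4eo", "M5", "M6",
                     "not determined"), n(), replace = TRUE)
    )

  cal_exp <- calibration_expected(config)
  n_pos <- 4L
  n_neg <- 8L

  one_array <- function(sample_id, subtype) {
    amounts <- baseline * fc_lookup[, subtype]
    true_sig <- c(
      amounts * config$signal_per_fmol,       # sample channel, miRNA spots
      cal_exp, rep(5000, n_pos), rep(0, n_neg)
    )
    true_ref <- c(
      rep(1 * config$signal_per_fmol, config$n_mirnas),  # 1 fmol reference
      cal_exp, rep(5000, n_pos), rep(0, n_neg)
    )
    probe_id <- c(mirnas, names(cal_exp), sprintf("POS-%02d", seq_len(n_pos)),
                  sprintf("NEG-%02d", seq_len(n_neg)))
    probe_class <- rep(c("mirna", "calibration", "position_control",
                         "negative_control"),
                       c(config$n_mirnas, length(cal_exp), n_pos, n_neg))
    nspot <- length(probe_id)
    gain <- if (config$noise_cv > 0) {
      rlnorm(2, sdlog = config$noise_cv / 2)
    } else c(1, 1)
    bg_s <- pmax(0, rnorm(nspot, config$background_mean, config$background_sd))
    bg_r <- pmax(0, rnorm(nspot, config$background_mean, config$background_sd))
    sig_s <- true_sig * gain[1] * lnoise(nspot, config$noise_cv)
    sig_r <- true_ref * gain[2] * lnoise(nspot, config$noise_cv)
    frac <- function(sig) if_else(sig > 100, runif(nspot, 0.85, 1), runif(nspot, 0, 0.4))
    tibble(
      array_id = sample_id, probe_id = probe_id, probe_class = probe_class,
      ch_sample_fg = bg_s + sig_s, ch_sample_bg = bg_s,
      ch_sample_bg_sd = config$background_sd,
      ch_sample_frac_px2sd = frac(sig_s),
      ch_ref_fg = bg_r + sig_r, ch_ref_bg = bg_r,
      ch_ref_bg_sd = config$background_sd,
      ch_ref_frac_px2sd = frac(sig_r)
    )
  }

  spots <- map2(samples$sample_id, samples$subtype, one_array) %>% bind_rows()
  truth <- expand_grid(mirna = mirnas, subtype = subtypes) %>%
    mutate(amount_fmol = baseline[match(.data$mirna, mirnas)] *
             fc_lookup[cbind(match(.data$mirna, mirnas),
                             match(.data$subtype, subtypes))])
  list(spots = spots, samples = samples, truth = truth)
}

#' Simulate an Argonaute immunoprecipitation experiment
#'
#' Feature levels for each antibody (Ago1-4, isotype control, empty beads)
#' across biological replicates. Planted-enriched features have expected
#' IP/isotype ratio equal to the planted value; all other ratios have
#' expectation 1. With `noise_cv = 0` the replicate fold changes equal the
#' planted ratios exactly.
#'
#' @param config A [sim_config()]; `planted_enrichment` supplies the truth.
#' @param features Optional character vector of feature ids; defaults to
#'   `config$n_ip_features` synthetic miRNA ids.
#' @param cell_line Label stored on every measurement.
#' @return Tibble `cell_line`, `antibody`, `replicate`, `feature`, `level`.
#' @export
simulate_ip_experiment <- function(config, features = NULL,
                                   cell_line = "KASUMI-1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  if (is.null(features)) {
    features <- sprintf("miR-%03d", seq_len(config$n_ip_features))
  }
  antibodies <- c(paste0("Ago", 1:4), "isotype", "beads")
  baseline <- rlnorm(length(features), meanlog = log(100), sdlog = 1)
  enr <- matrix(1, nrow = length(features), ncol = length(antibodies),
                dimnames = list(features, antibodies))
  if (!is.null(config$planted_enrichment)) {
    pe <- config$planted_enrichment
    stopifnot(all(pe$feature %in% features))
    enr[cbind(match(pe$feature, features), match(pe$ago, antibodies))] <- pe$ratio
  }
  expand_grid(antibody = antibodies,
              replicate = seq_len(config$ip_replicates),
              feature = features) %>%
    mutate(
      cell_line = cell_line,
      level = baseline[match(.data$feature, features)] *
        enr[cbind(match(.data$feature, features),
                  match(.data$antibody, antibodies))] *
        lnoise(n(), config$noise_cv)
    ) %>%
    select("cell_line", "antibody", "replicate", "feature", "level")
}

#' Simulate three target-prediction tables
#'
#' Each true miRNA-target edge appears independently in each of the three
#' sources with probability `prediction_overlap`; each source additionally
#' reports decoy edges drawn from non-true pairs.
#'
#' @param mirnas,genes Identifier vectors.
#' @param true_edges Tibble with columns `mirna`, `gene` (subset of
#'   `mirnas` x `genes`).
#' @param config A [sim_config()].
#' @return Named list of three tibbles (`src1`, `src2`, `src3`), each with
#'   columns `mirna`, `gene`, `source`.
#' @export
simulate_target_predictions <- function(mirnas, genes, true_edges, config) {
  stopifnot(inherits(config, "sim_config"))
  true_edges <- as_tibble(true_edges)
  stopifnot(all(true_edges$mirna %in% mirnas), all(true_edges$gene %in% genes))
  set.seed(config$seed + 2L)
  true_key <- paste(true_edges$mirna, true_edges$gene)
  make_source <- function(src) {
    keep <- runif(nrow(true_edges)) < config$prediction_overlap
    hits <- true_edges[keep, , drop = FALSE]
    nd <- config$n_decoys_per_source
    decoys <- tibble(mirna = sample(mirnas, nd * 2, replace = TRUE),
                     gene = sample(genes, nd * 2, replace = TRUE)) %>%
      filter(!paste(.data$mirna, .data$gene) %in% true_key) %>%
      distinct() %>%
      head(nd)
    bind_rows(hits, decoys) %>% mutate(source = src)
  }
  sources <- paste0("src", 1:3)
  setNames(map(sources, make_source), sources)
}

#' Simulate a pathway gene-set collection
#'
#' Named gene sets with sizes uniform in `pathway_size_range`, drawn from the
#' gene universe. An optional planted pathway (e.g., fully contained in a
#' designated query set) is prepended unchanged, so over-representation of a
#' constructed query is known by design.
#'
#' @param genes Character vector, the gene universe.
#' @param config A [sim_config()].
#' @param planted Optional named list of character vectors prepended as-is.
#' @return Named list of character vectors (GMT-writable, see [write_gmt()]).
#' @export
simulate_pathways <- function(genes, config, planted = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  rng <- config$pathway_size_range
  if (rng[2] > length(genes)) {
    abort("pathway_size_range exceeds the gene universe")
  }
  size_pool <- seq(rng[1], rng[2])
  sizes <- size_pool[sample.int(length(size_pool), config$n_pathways,
                                replace = TRUE)]
  pw <- map(sizes, function(s) sample(genes, s))
  names(pw) <- sprintf("PW%04d", seq_along(pw))
  if (!is.null(planted)) {
    stopifnot(is.list(planted), !is.null(names(planted)),
              all(unlist(planted) %in% genes))
    pw <- c(planted, pw)
  }
  pw
}
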