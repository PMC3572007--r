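#' Quantification configuration
#'
#' Fixed constants of the quantitative two-color miRNA array protocol: a spot
#' is analyzable only if its background-corrected intensity exceeds
#' `min_intensity` light units (strictly) and strictly more than
#' `min_frac_px` of its pixels lie two background standard deviations above
#' background, in both channels; the reference channel carries
#' `ref_amount_fmol` of every reference miRNA; `input_mass_ug` of total RNA
#' was labeled for the sample channel.
#'
#' @param min_intensity Detection threshold, light units (default 100).
#' @param min_frac_px Pixel-fraction threshold (default 0.5).
#' @param sd_mult Background SD multiplier folded into the pixel fraction
#'   statistic upstream (default 2; recorded for provenance).
#' @param ref_amount_fmol Amount of each reference oligo (default 1 fmol).
#' @param input_mass_ug Labeled input RNA mass (default 3 ug).
#' @return A `quant_config` list.
#' @export
quant_config <- function(min_intensity = 100, min_frac_px = 0.5, sd_mult = 2,
                         ref_amount_fmol = 1, input_mass_ug = 3) {
  stopifnot(min_intensity >= 0, min_frac_px >= 0, min_frac_px <= 1,
            ref_amount_fmol > 0, input_mass_ug > 0)
  structure(list(min_intensity = min_intensity, min_frac_px = min_frac_px,
                 sd_mult = sd_mult, ref_amount_fmol = ref_amount_fmol,
                 input_mass_ug = input_mass_ug),
            class = "quant_config")
}

#' Background-correct spots and apply the detection filter
#'
#' Per channel: corrected intensity is foreground minus background, floored
#' at zero; the channel passes iff corrected intensity strictly exceeds
#' `min_intensity` and the fraction of pixels two SDs above background
#' strictly exceeds `min_frac_px`. A spot is analyzable iff both channels
#' pass. Raising `min_intensity` can only shrink the passing set.
#'
#' @param spots Spot tibble of a cohort or single array (spot-record columns).
#' @param cfg A [quant_config()].
#' @return The input with added columns `corrected_sample`, `corrected_ref`,
#'   `pass_sample`, `pass_ref`, `analyzable`.
#' @export
filter_spots <- function(spots, cfg = quant_config()) {
  stopifnot(inherits(cfg, "quant_config"))
  if (nrow(spots) == 0) {
    return(mutate(spots, corrected_sample = numeric(0), corrected_ref = numeric(0),
                  pass_sample = logical(0), pass_ref = logical(0),
                  analyzable = logical(0)))
  }
  spots %>%
    mutate(
      corrected_sample = pmax(.data$ch_sample_fg - .data$ch_sample_bg, 0),
      corrected_ref = pmax(.data$ch_ref_fg - .data$ch_ref_bg, 0),
      pass_sample = .data$corrected_sample > cfg$min_intensity &
        .data$ch_sample_frac_px2sd > cfg$min_frac_px,
      pass_ref = .data$corrected_ref > cfg$min_intensity &
        .data$ch_ref_frac_px2sd > cfg$min_frac_px,
      analyzable = .data$pass_sample & .data$pass_ref
    )
}

#' Calibrate channel intensities with the spiked-in calibration spots
#'
#' Per array and channel, the scale factor is the median over passing
#' calibration spots of expected/observed corrected intensity; all corrected
#' intensities of that channel are multiplied by the factor, so calibration
#' spots afterwards match their expectation in median. The median makes the
#' factor robust to single aberrant calibration spots.
#'
#' @param spots Output of [filter_spots()].
#' @param cfg A [quant_config()].
#' @param expected_calibration Named numeric vector mapping calibration probe
#'   ids to their expected intensity (light units).
#' @return The input with `corrected_sample`/`corrected_ref` rescaled and
#'   per-array columns `cal_factor_sample`, `cal_factor_ref`.
#' @export
calibrate_channels <- function(spots, cfg = quant_config(),
                               expected_calibration) {
  stopifnot(inherits(cfg, "quant_config"), is.numeric(expected_calibration),
            !is.null(names(expected_calibration)))
  factor_for <- function(obs, pass, ids, array_id, channel) {
    use <- pass & ids %in% names(expected_calibration)
    if (!any(use)) {
      abort(sprintf("array %s: no passing calibration spot in the %s channel",
                    array_id, channel))
    }
    median(expected_calibration[ids[use]] / obs[use])
  }
  spots %>%
    group_by(.data$array_id) %>%
    mutate(
      cal_factor_sample = factor_for(
        .data$corrected_sample, .data$pass_sample & .data$probe_class == "calibration",
        .data$probe_id, .data$array_id[1], "sample"),
      cal_factor_ref = factor_for(
        .data$corrected_ref, .data$pass_ref & .data$probe_class == "calibration",
        .data$probe_id, .data$array_id[1], "reference"),
      corrected_sample = .data$corrected_sample * .data$cal_factor_sample,
      corrected_ref = .data$corrected_ref * .data$cal_factor_ref
    ) %>%
    ungroup()
}

#' Normalize the sample channel to the universal-reference channel
#'
#' For every analyzable miRNA spot the ratio is calibrated sample intensity
#' over calibrated reference intensity; non-analyzable spots (or zero
#' reference) are marked not-detected. No global normalization is applied:
#' the universal reference in the second channel is the sole normalizer, so
#' samples with very different dynamic ranges stay comparable. Multiple
#' spots of the same probe are summarized by their median ratio.
#'
#' @param spots Output of [calibrate_channels()].
#' @param cfg A [quant_config()].
#' @return Long abundance tibble `sample_id`, `mirna`, `value` (ratio,
#'   dimensionless), `detected`; attribute `unit = "ratio"`.
#' @export
normalize_to_reference <- function(spots, cfg = quant_config()) {
  out <- spots %>%
    filter(.data$probe_class == "mirna") %>%
    mutate(
      detected = .data$analyzable & .data$corrected_ref > 0,
      ratio = if_else(.data$detected,
                      .data$corrected_sample / .data$corrected_ref, NA_real_)
    ) %>%
    group_by(sample_id = .data$array_id, mirna = .data$probe_id) %>%
    summarise(value = unname(median(.data$ratio[.data$detected])),
              detected = any(.data$detected), .groups = "drop") %>%
    mutate(value = unname(if_else(.data$detected, .data$value, NA_real_)))
  attr(out, "unit") <- "ratio"
  out
}

#' Convert reference ratios to absolute amounts (fmol per microgram)
#'
#' `amount = ratio * ref_amount_fmol / input_mass_ug`. With the defaults
#' (1 fmol reference, 3 ug labeled input) a ratio of 3 is 1 fmol/ug. The
#' detection mask propagates unchanged.
#'
#' @param ratios Output of [normalize_to_reference()].
#' @param cfg A [quant_config()].
#' @return Abundance tibble with `value` in fmol/ug; attribute
#'   `unit = "fmol_per_ug"`.
#' @export
to_absolute <- function(ratios, cfg = quant_config()) {
  stopifnot(inherits(cfg, "quant_config"))
  out <- mutate(ratios,
                value = .data$value * cfg$ref_amount_fmol / cfg$input_mass_ug)
  attr(out, "unit") <- "fmol_per_ug"
  out
}

#' Full spot-to-abundance quantification
#'
#' Convenience pipeline filter -> calibrate -> normalize (-> absolute).
#'
#' @param spots Raw spot tibble (one or many arrays).
#' @param cfg A [quant_config()].
#' @param expected_calibration Named expected calibration intensities.
#' @param absolute If `TRUE` (default) convert ratios to fmol/ug.
#' @return Long abundance tibble.
#' @export
quantify_cohort <- function(spots, cfg = quant_config(), expected_calibration,
                            absolute = TRUE) {
  out <- spots %>%
    filter_spots(cfg) %>%
    calibrate_channels(cfg, expected_calibration) %>%
    normalize_to_reference(cfg)
  if (absolute) out <- to_absolute(out, cfg)
  out
}
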