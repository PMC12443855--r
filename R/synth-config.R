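#' Configuration for the synthetic methylome generator
#'
#' Bundles every knob of the synthetic data generator into a validated list.
#' The defaults describe the desk-scale study the package is tested against:
#' 8 chromosomes, ~5000 cytosines laid out in dense clumps (so that region
#' clustering has something to find), 71 samples split 9/36/26 across
#' paradormancy/endodormancy/ecodormancy, four cultivars, ~1% of cytosines
#' carrying a planted stage effect and ~6% carrying a cultivar-specific
#' confounding effect on a disjoint locus set.
#'
#' Effects act on the logit scale, so methylation levels stay inside (0,1)
#' without clipping.  Coverage is negative-binomial (the usual overdispersed
#' model for WGBS depth); `coverage_dispersion` is the NB `size` parameter,
#' smaller meaning more overdispersed.
#'
#' @param seed Integer seed; every stochastic step of the generator derives
#'   from it, and equal seeds give byte-identical output.
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param n_cytosines Total number of cytosines to place across the genome.
#' @param class_counts Named integer vector of samples per stage, names from
#'   [dormancy_stages].
#' @param n_cultivars Number of cultivars; samples are assigned cultivars
#'   balanced within each stage so that cultivar and stage stay uncorrelated.
#' @param frac_informative Fraction of cytosines given a stage-dependent
#'   methylation offset.
#' @param stage_effect Logit-scale magnitude of the planted stage effect.
#' @param frac_confounder Fraction of cytosines given a cultivar-specific
#'   offset (disjoint from the informative set).
#' @param cultivar_effect Logit-scale magnitude of the cultivar effect.
#' @param coverage_mean,coverage_dispersion Negative-binomial read-depth
#'   parameters (mean and size).
#' @param base_level_by_context Named numeric baseline methylation per
#'   context (CG/CHG/CHH), each in (0,1).
#' @param context_mix Named numeric proportions of CG/CHG/CHH cytosines;
#'   must sum to 1.
#' @param locus_noise_sd,sample_noise_sd Logit-scale standard deviations of
#'   per-locus baseline jitter and per-(sample, locus) biological noise.
#' @param te_fraction Target fraction of the genome covered by simulated
#'   transposable elements.
#' @param informative_te_enrichment Sampling weight multiplier for placing
#'   informative loci inside TE or chromosome-4 QTL intervals (>= 1).
#'
#' @return A list of class `"synth_config"`.
#' @seealso [simulate_genome_annotation()], [simulate_methylomes()]
#' @export
#' @examples
#' cfg <- synth_config(seed = 7, n_cytosines = 500)
#' cfg$class_counts
synth_config <- function(seed = 1L,
                         chrom_lengths = setNames(rep(2e6L, 8),
                                                  paste0("chr_", 1:8)),
                         n_cytosines = 5000L,
                         class_counts = c(paradormancy = 9L,
                                          endodormancy = 36L,
                                          ecodormancy = 26L),
                         n_cultivars = 4L,
                         frac_informative = 0.01,
                         stage_effect = 2.0,
                         frac_confounder = 0.06,
                         cultivar_effect = 3.0,
                         coverage_mean = 20,
                         coverage_dispersion = 10,
                         base_level_by_context = c(CG = 0.5, CHG = 0.3,
                                                   CHH = 0.1),
                         context_mix = c(CG = 0.30, CHG = 0.25, CHH = 0.45),
                         locus_noise_sd = 0.5,
                         sample_noise_sd = 0.5,
                         te_fraction = 0.5,
                         informative_te_enrichment = 3) {
  cfg <- list(seed = as.integer(seed),
              chrom_lengths = chrom_lengths,
              n_cytosines = as.integer(n_cytosines),
              class_counts = class_counts,
              n_cultivars = as.integer(n_cultivars),
              frac_informative = frac_informative,
              stage_effect = stage_effect,
              frac_confounder = frac_confounder,
              cultivar_effect = cultivar_effect,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              base_level_by_context = base_level_by_context,
              context_mix = context_mix,
              locus_noise_sd = locus_noise_sd,
              sample_noise_sd = sample_noise_sd,
              te_fraction = te_fraction,
              informative_te_enrichment = informative_te_enrichment)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (is.null(names(cfg$chrom_lengths)) || any(!nzchar(names(cfg$chrom_lengths))))
    abort("`chrom_lengths` must be a named vector of chromosome lengths.")
  if (length(cfg$chrom_lengths) < 1 || any(cfg$chrom_lengths <= 0))
    abort("`chrom_lengths` must be non-empty and positive.")
  if (!all(names(cfg$class_counts) %in% dormancy_stages))
    abort("`class_counts` names must be dormancy stages.")
  if (any(cfg$class_counts < 1))
    abort("every entry of `class_counts` must be >= 1.")
  if (cfg$frac_informative <= 0 || cfg$frac_confounder < 0 ||
      cfg$frac_informative + cfg$frac_confounder >= 1)
    abort("`frac_informative` + `frac_confounder` must lie in (0, 1).")
  if (abs(sum(cfg$context_mix) - 1) > 1e-8)
    abort("`context_mix` must sum to 1.")
  if (!setequal(names(cfg$context_mix), methylation_contexts) ||
      !setequal(names(cfg$base_level_by_context), methylation_contexts))
    abort("context parameters must be named CG, CHG, CHH.")
  if (any(cfg$base_level_by_context <= 0 | cfg$base_level_by_context >= 1))
    abort("`base_level_by_context` entries must lie in (0, 1).")
  if (cfg$coverage_mean <= 0)
    abort("`coverage_mean` must be positive.")
  if (cfg$coverage_dispersion <= 0)
    abort("`coverage_dispersion` must be positive.")
  if (!all(is.finite(c(cfg$stage_effect, cfg$cultivar_effect,
                       cfg$locus_noise_sd, cfg$sample_noise_sd))))
    abort("all effect and noise parameters must be finite.")
  if (cfg$te_fraction < 0 || cfg$te_fraction >= 1)
    abort("`te_fraction` must lie in [0, 1).")
  if (cfg$informative_te_enrichment < 1)
    abort("`informative_te_enrichment` must be >= 1.")
  invisible(cfg)
}
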