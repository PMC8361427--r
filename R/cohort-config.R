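#' Configuration for the synthetic twin-cohort generator
#'
#' Bundles and validates every tunable of [generate_cohort()]. Defaults encode
#' the study conditions the generator emulates: male-male twin pairs entering
#' at ages 51-60, up to three assessment waves about 5.7 years apart, roughly
#' 12% of baseline-normal participants converting to MCI by the final wave, an
#' AD polygenic risk score distributed N(58.4, 7.5^2), and group effects scaled
#' so the downstream *signature-score* standardized mean difference equals the
#' configured value (0.36 for the MD signature, 0.16 for thickness/volume).
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_pairs Number of twin pairs entering at baseline (>= 2).
#' @param p_mz Proportion of monozygotic pairs.
#' @param waves Number of assessment waves (>= 1).
#' @param wave_gap_mean,wave_gap_sd Mean and SD (years) of inter-wave interval.
#' @param baseline_age_range Two-element numeric, baseline age bounds (years).
#' @param conversion_rate Probability that a baseline-normal subject is a
#'   latent converter (expressed in cognition by the final wave).
#' @param effect_sizes Named numeric, signature-level group SMDs injected for
#'   latent converters: `md` (positive = higher/worse MD) and
#'   `thickness_volume` (applied as a *decrease* in thickness/volume).
#' @param twin_icc Within-pair intraclass correlation of traits for MZ pairs.
#' @param dz_share DZ-pair ICC as a share of the MZ ICC (default 0.5).
#' @param prs_mean,prs_sd AD polygenic risk score distribution.
#' @param practice_effect Mean score inflation (SD units) for returnees at
#'   waves >= 2.
#' @param attrition_effect Mean score deficit (SD units) of future dropouts at
#'   their pre-dropout waves.
#' @param dropout_rate Marginal per-transition probability a subject misses
#'   all later waves. Dropout is confined to a latent dropout-prone (frail)
#'   subgroup so that future dropouts carry exactly the configured attrition
#'   deficit while fresh replacement subjects remain representative of the
#'   source population.
#' @param frailty_rate Share of dropout-prone subjects (must be >=
#'   `dropout_rate`); their per-transition dropout probability is
#'   `dropout_rate / frailty_rate`.
#' @param replacement_rate Number of replacement pairs recruited at each wave
#'   after baseline, as a fraction of `n_pairs`; replacements take tests for
#'   the first time and anchor the practice-effect estimate.
#' @param scanner_labels List (length `waves`) of character vectors of scanner
#'   labels in use at each wave.
#' @param tests_per_domain Cognitive tests per domain (6 domains; default 3,
#'   giving the 18-test battery).
#' @param md_missing_rate Probability a subject-wave has no usable diffusion
#'   data (all MD columns missing).
#' @param coupling Numeric (length `waves`), per-wave share of signature-level
#'   variance carried by a common "brain health" factor that links the two
#'   modalities with opposite sign; drives the negative, magnitude-increasing
#'   thickness/volume vs MD score correlation across waves.
#' @param age_logodds,prs_logodds Log-odds per SD of baseline age and PRS in
#'   the latent conversion model (intercept solved so the marginal rate equals
#'   `conversion_rate`).
#' @param converter_domain_drop,converter_global_drop Final-wave cognitive
#'   decline for converters, in SD units: drop applied to every test of the
#'   primarily affected domain (memory) and to all other tests.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_pairs = 200L,
                          p_mz = 0.5,
                          waves = 3L,
                          wave_gap_mean = 5.7,
                          wave_gap_sd = 0.5,
                          baseline_age_range = c(51, 60),
                          conversion_rate = 0.118,
                          effect_sizes = c(md = 0.36, thickness_volume = 0.16),
                          twin_icc = 0.5,
                          dz_share = 0.5,
                          prs_mean = 58.4,
                          prs_sd = 7.5,
                          practice_effect = 0.15,
                          attrition_effect = 0.2,
                          dropout_rate = 0.12,
                          frailty_rate = 0.35,
                          replacement_rate = 0.16,
                          scanner_labels = NULL,
                          tests_per_domain = 3L,
                          md_missing_rate = 0.08,
                          coupling = NULL,
                          age_logodds = 0.35,
                          prs_logodds = 0.25,
                          converter_domain_drop = 3.0,
                          converter_global_drop = 0.6) {
  if (is.null(scanner_labels))
    scanner_labels <- lapply(seq_len(waves), function(w)
      paste0("scanner_w", w, c("A", "B")))
  if (is.null(coupling))
    coupling <- seq(0.30, 0.65, length.out = max(waves, 2L))[seq_len(waves)]
  cfg <- list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
              p_mz = p_mz, waves = as.integer(waves),
              wave_gap_mean = wave_gap_mean, wave_gap_sd = wave_gap_sd,
              baseline_age_range = baseline_age_range,
              conversion_rate = conversion_rate, effect_sizes = effect_sizes,
              twin_icc = twin_icc, dz_share = dz_share,
              prs_mean = prs_mean, prs_sd = prs_sd,
              practice_effect = practice_effect,
              attrition_effect = attrition_effect,
              dropout_rate = dropout_rate, frailty_rate = frailty_rate,
              replacement_rate = replacement_rate,
              scanner_labels = scanner_labels,
              tests_per_domain = as.integer(tests_per_domain),
              md_missing_rate = md_missing_rate, coupling = coupling,
              age_logodds = age_logodds, prs_logodds = prs_logodds,
              converter_domain_drop = converter_domain_drop,
              converter_global_drop = converter_global_drop)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  probs <- c(p_mz = cfg$p_mz, conversion_rate = cfg$conversion_rate,
             twin_icc = cfg$twin_icc, dz_share = cfg$dz_share,
             dropout_rate = cfg$dropout_rate, frailty_rate = cfg$frailty_rate,
             md_missing_rate = cfg$md_missing_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities outside [0, 1]: ", paste(names(probs)[bad], collapse = ", "))
  if (cfg$n_pairs < 2L) stop("n_pairs must be at least 2")
  if (cfg$waves < 1L) stop("waves must be at least 1")
  if (length(cfg$scanner_labels) != cfg$waves)
    stop("scanner_labels must have one entry per wave")
  if (length(cfg$coupling) != cfg$waves || any(cfg$coupling < 0 | cfg$coupling > 1))
    stop("coupling must be per-wave values in [0, 1]")
  if (cfg$dropout_rate > 0 && cfg$frailty_rate < cfg$dropout_rate)
    stop("frailty_rate must be at least dropout_rate")
  stopifnot(all(c("md", "thickness_volume") %in% names(cfg$effect_sizes)),
            cfg$tests_per_domain >= 1L,
            cfg$prs_sd > 0, cfg$wave_gap_sd >= 0,
            diff(cfg$baseline_age_range) >= 0)
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d twin pairs (p_MZ = %.2f), %d waves ~%.1f y apart\n",
              x$n_pairs, x$p_mz, x$waves, x$wave_gap_mean))
  cat(sprintf("  baseline age %g-%g, conversion rate %.3f\n",
              x$baseline_age_range[1], x$baseline_age_range[2],
              x$conversion_rate))
  cat(sprintf("  injected signature SMDs: MD %.2f, thickness/volume %.2f\n",
              x$effect_sizes[["md"]], x$effect_sizes[["thickness_volume"]]))
  cat(sprintf("  practice %.2f SD, attrition %.2f SD, dropout %.2f/wave, seed %d\n",
              x$practice_effect, x$attrition_effect, x$dropout_rate, x$seed))
  invisible(x)
}
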