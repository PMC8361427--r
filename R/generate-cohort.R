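#' @importFrom stats rnorm runif rbinom plogis qlogis uniroot median sd
NULL

# Cognitive domains of the 18-test battery (6 domains x tests_per_domain).
cognitive_domains <- function() {
  c("memory", "executive", "attention", "language", "visuospatial", "speed")
}

# Cortical regions measured by thickness; hippocampus is measured by volume.
cortical_regions <- function() {
  c("entorhinal", "middletemporal", "bankssts", "superiortemporal",
    "isthmuscingulate", "lateralorbitofrontal", "medialorbitofrontal")
}

signature_regions <- function() c(cortical_regions(), "hippocampus")

# Variance shares of the ROI-level latent model: a common per-modality factor
# (f), a persistent ROI-specific component (u) and transient wave noise (e).
roi_variance_shares <- function() c(f = 0.4, u = 0.3, e = 0.3)

# z-score that maps constant vectors to zero instead of NaN
zscore_safe <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Pair-correlated standard normals: an n_subjects x k matrix (a plain vector
# when k = 1) in which the two members of a pair correlate rho (per-pair
# vector), marginally N(0, 1).
rpairnorm <- function(pair_index, rho, k = 1L) {
  n_pairs <- max(pair_index)
  P <- matrix(rnorm(n_pairs * k), n_pairs, k)
  Z <- matrix(rnorm(length(pair_index) * k), length(pair_index), k)
  out <- sqrt(rho) * P[pair_index, , drop = FALSE] + sqrt(1 - rho) * Z
  if (k == 1L) drop(out) else out
}

# Closed-form per-ROI shift (in residual-SD units) that yields a target
# signature-level SMD, given the generator's factor shares and the weights.
roi_shift_for_smd <- function(target_smd, weights = signature_weights()$weight) {
  sh <- roi_variance_shares()
  var_sig <- sh[["f"]] * sum(weights)^2 + (1 - sh[["f"]]) * sum(weights^2)
  target_smd * sqrt(var_sig) / sum(weights)
}

#' Generate a synthetic longitudinal twin cohort
#'
#' Produces a long-format table (one row per subject and attended wave) with
#' the statistical structure the downstream analyses assume: twin pairs with a
#' configurable within-pair trait correlation, up to three waves, ROI
#' morphometry (cortical thickness, hippocampal volume, grey-matter MD) driven
#' by a latent factor model whose cross-modality coupling grows across waves,
#' an 18-test cognitive battery in six domains with practice inflation for
#' returnees and a persistent deficit for future dropouts, attrition
#' replacement pairs recruited at later waves, and latent converters whose
#' ROI measures carry shifts calibrated (in closed form) so the downstream
#' *signature-score* SMD equals the configured effect size and whose cognition
#' declines by the final wave.
#'
#' @param config A [cohort_config()] object.
#' @return A tibble with one row per subject x attended wave. Generator-only
#'   columns (`true_group`, `future_dropout`) are marked in the column
#'   dictionary; see the package vignette.
#' @export
generate_cohort <- function(config = cohort_config()) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed)

  waves <- cfg$waves
  regions <- signature_regions()
  n_reg <- length(regions)
  hemis <- c("lh", "rh")
  n_roi <- n_reg * 2L                     # 16 ROI x hemisphere entries
  domains <- cognitive_domains()
  n_tests <- length(domains) * cfg$tests_per_domain

  ## -- pairs ----------------------------------------------------------------
  n_rep <- if (waves > 1L) round(cfg$replacement_rate * cfg$n_pairs) else 0L
  entry_wave_pair <- c(rep(1L, cfg$n_pairs),
                       rep(seq_len(waves)[-1], each = n_rep))
  n_pairs_total <- length(entry_wave_pair)
  zygosity_pair <- ifelse(runif(n_pairs_total) < cfg$p_mz, "MZ", "DZ")
  rho_pair <- ifelse(zygosity_pair == "MZ", cfg$twin_icc,
                     cfg$twin_icc * cfg$dz_share)

  n_subj <- n_pairs_total * 2L
  pair_index <- rep(seq_len(n_pairs_total), each = 2L)
  rho <- rho_pair[pair_index]
  subj <- tibble::tibble(
    subject_id = sprintf("S%05d", seq_len(n_subj)),
    pair_id = sprintf("P%04d", pair_index),
    zygosity = zygosity_pair[pair_index],
    entry_wave = entry_wave_pair[pair_index],
    replacement = entry_wave_pair[pair_index] > 1L
  )

  ## -- subject-level traits -------------------------------------------------
  # baseline-equivalent age per pair; replacements come from the same birth
  # cohort and enter later, so their age at entry accrues through the wave gaps
  entry_age_pair <- runif(n_pairs_total, cfg$baseline_age_range[1],
                          cfg$baseline_age_range[2])
  subj$entry_age <- entry_age_pair[pair_index]
  subj$education <- pmin(20, pmax(8, round(13.9 + 2.2 * rpairnorm(pair_index, rho))))
  subj$icv <- as.vector(1.5e6 + 1.5e5 * rpairnorm(pair_index, rho))
  subj$prs <- as.vector(cfg$prs_mean + cfg$prs_sd * rpairnorm(pair_index, rho))

  # cognition latents: general ability g, age-20 GCA, persistent domain effects.
  # With transient per-test noise SD 0.45 (below), persistent variance is
  # (0.7^2 + 0.25^2) / (0.7^2 + 0.25^2 + 0.45^2) ~ 0.73 of the total, i.e. a
  # test-retest reliability in the 0.7-0.8 range typical of neuropsychological
  # batteries; keeping the transient share this small also keeps the actuarial
  # classifier's chance-impairment floor low enough that the realized converter
  # fraction tracks the configured latent conversion rate.
  g <- 0.7 * rpairnorm(pair_index, rho)
  subj$gca_age20 <- as.vector(g + 0.25 * rpairnorm(pair_index, rho))
  dom_eff <- 0.25 * rpairnorm(pair_index, rho, k = length(domains))

  # brain latents: persistent modality factors and ROI-specific components
  A_tv <- rpairnorm(pair_index, rho)             # thickness/volume factor
  B_md <- rpairnorm(pair_index, rho)             # MD factor
  U <- rpairnorm(pair_index, rho, k = n_roi * 2L)  # persistent, per ROI x modality
  H <- rpairnorm(pair_index, rho, k = waves)       # wave-specific health factor
  pbad_noise <- rpairnorm(pair_index, rho, k = waves)
  if (waves == 1L) {  # keep wave-indexed latents as one-column matrices
    H <- cbind(H)
    pbad_noise <- cbind(pbad_noise)
  }

  ## -- attendance -----------------------------------------------------------
  # dropout is confined to a latent dropout-prone (frail) subgroup: frail
  # subjects carry the configured pre-dropout deficit on cognition, so future
  # dropouts have exactly that mean deficit while fresh replacements remain
  # representative of the source population
  subj$frail <- runif(n_subj) < cfg$frailty_rate
  q_drop <- if (cfg$dropout_rate > 0) cfg$dropout_rate / cfg$frailty_rate else 0
  last_wave <- subj$entry_wave
  for (w in seq_len(waves - 1L)) {
    at_risk <- last_wave == w & subj$entry_wave <= w
    drop <- subj$frail & (runif(n_subj) < q_drop)
    last_wave <- ifelse(at_risk & !drop, w + 1L, last_wave)
  }
  subj$last_wave <- last_wave
  subj$future_dropout <- last_wave < waves

  ## -- latent conversion ----------------------------------------------------
  # every subject (including replacements, who come from the same birth
  # cohort) is eligible; conversion odds rise with baseline age and PRS
  subj$true_group <- "CN-stable"
  if (waves > 1L && cfg$conversion_rate > 0) {
    lp0 <- cfg$age_logodds * zscore_safe(subj$entry_age) +
      cfg$prs_logodds * zscore_safe(subj$prs)
    if (cfg$conversion_rate >= 1) {
      p <- rep(1, n_subj)
    } else {
      alpha <- uniroot(function(a) mean(plogis(a + lp0)) - cfg$conversion_rate,
                       c(-20, 20))$root
      p <- plogis(alpha + lp0)
    }
    subj$true_group[rbinom(n_subj, 1L, p) == 1L] <- "converter"
  }
  converter <- subj$true_group == "converter"

  ## -- subject x wave grid --------------------------------------------------
  gaps <- matrix(rnorm(n_subj * max(waves - 1L, 1L), cfg$wave_gap_mean,
                       cfg$wave_gap_sd), n_subj)
  age_mat <- matrix(subj$entry_age, n_subj, waves)
  if (waves > 1L)
    for (w in 2:waves)
      age_mat[, w] <- age_mat[, w - 1L] + pmax(gaps[, w - 1L], 0.5)

  # scanner per subject-wave, from that wave's label set
  scanner_mat <- vapply(seq_len(waves), function(w) {
    labs <- cfg$scanner_labels[[w]]
    labs[sample.int(length(labs), n_subj, replace = TRUE)]
  }, character(n_subj))
  scanner_mat <- matrix(scanner_mat, n_subj, waves)
  scan_z <- matrix(0, n_subj, waves)        # scanner offset in residual-SD units
  for (w in seq_len(waves)) {
    labs <- cfg$scanner_labels[[w]]
    off <- seq(-0.15, 0.15, length.out = max(length(labs), 2L))[seq_along(labs)]
    scan_z[, w] <- off[match(scanner_mat[, w], labs)]
  }

  ## -- ROI measures ---------------------------------------------------------
  sh <- roi_variance_shares()
  d_md <- roi_shift_for_smd(cfg$effect_sizes[["md"]])
  d_tv <- roi_shift_for_smd(cfg$effect_sizes[["thickness_volume"]])
  mu_thk <- c(entorhinal = 3.30, middletemporal = 2.95, bankssts = 2.55,
              superiortemporal = 2.80, isthmuscingulate = 2.45,
              lateralorbitofrontal = 2.70, medialorbitofrontal = 2.55)
  mu_md <- c(entorhinal = 1.05, middletemporal = 0.92, bankssts = 0.88,
             superiortemporal = 0.90, isthmuscingulate = 0.98,
             lateralorbitofrontal = 0.94, medialorbitofrontal = 0.96,
             hippocampus = 1.00)

  rows <- vector("list", waves)
  E <- rpairnorm(pair_index, rho, k = n_roi * 2L * waves)   # transient ROI noise
  md_missing <- matrix(runif(n_subj * waves) < cfg$md_missing_rate, n_subj)
  cog_noise <- rpairnorm(pair_index, rho, k = n_tests * waves)

  roi_cols <- as.vector(t(outer(regions, hemis, paste, sep = "_")))

  for (w in seq_len(waves)) {
    c_w <- cfg$coupling[w]
    F_tv <- sqrt(c_w) * H[, w] + sqrt(1 - c_w) * A_tv
    F_md <- -sqrt(c_w) * H[, w] + sqrt(1 - c_w) * B_md
    age_c <- age_mat[, w] - 60

    dat <- tibble::tibble(
      subject_id = subj$subject_id, pair_id = subj$pair_id,
      zygosity = subj$zygosity, wave = w,
      age = age_mat[, w], education = subj$education,
      scanner = scanner_mat[, w], icv = subj$icv, prs = subj$prs,
      replacement = subj$replacement, entry_wave = subj$entry_wave,
      true_group = subj$true_group, future_dropout = subj$future_dropout
    )

    # predicted brain age: gap (PBAD) loads on the shared health factor, so
    # more negative PBAD (older-looking brain) tracks worse signatures
    pbad <- 3 * (sqrt(0.6) * H[, w] + sqrt(0.4) * pbad_noise[, w])
    dat$predicted_brain_age <- age_mat[, w] - pbad
    dat$gca_age20 <- subj$gca_age20

    for (j in seq_len(n_roi)) {
      reg <- regions[(j + 1L) %/% 2L]
      e_tv <- E[, (w - 1L) * n_roi * 2L + j]
      e_md <- E[, (w - 1L) * n_roi * 2L + n_roi + j]
      u_tv <- U[, j]
      u_md <- U[, n_roi + j]
      z_tv <- sqrt(sh[["f"]]) * F_tv + sqrt(sh[["u"]]) * u_tv +
        sqrt(sh[["e"]]) * e_tv - d_tv * converter
      z_md <- sqrt(sh[["f"]]) * F_md + sqrt(sh[["u"]]) * u_md +
        sqrt(sh[["e"]]) * e_md + d_md * converter
      if (reg == "hippocampus") {
        dat[[paste0("vol_", roi_cols[j])]] <-
          4200 - 15 * age_c + 0.002 * (subj$icv - 1.5e6) +
          350 * (z_tv + scan_z[, w])
      } else {
        dat[[paste0("thk_", roi_cols[j])]] <-
          mu_thk[[reg]] - 0.012 * age_c + 0.12 * (z_tv + scan_z[, w])
      }
      dat[[paste0("md_", roi_cols[j])]] <-
        mu_md[[reg]] + 0.004 * age_c + 0.045 * (z_md + scan_z[, w])
    }
    md_na <- md_missing[, w]
    if (any(md_na))
      dat[md_na, paste0("md_", roi_cols)] <- NA_real_

    # cognition: normative-z scores (age/education-adjusted norms assumed)
    returnee <- w > subj$entry_wave
    decline_wave <- w == waves & converter
    for (tt in seq_len(n_tests)) {
      dom_i <- (tt - 1L) %/% cfg$tests_per_domain + 1L
      dom <- domains[min(dom_i, length(domains))]
      sc <- g + dom_eff[, min(dom_i, ncol(dom_eff))] +
        0.45 * cog_noise[, (w - 1L) * n_tests + tt] +
        cfg$practice_effect * returnee -
        cfg$attrition_effect * subj$frail
      drop_sz <- ifelse(dom == "memory", cfg$converter_domain_drop,
                        cfg$converter_global_drop)
      sc <- sc - drop_sz * decline_wave
      k <- (tt - 1L) %% cfg$tests_per_domain + 1L
      dat[[sprintf("cog_%s_%d", dom, k)]] <- as.vector(sc)
    }
    rows[[w]] <- dat
  }

  out <- do.call(rbind, rows)
  attended <- out$wave >= out$entry_wave &
    out$wave <= subj$last_wave[match(out$subject_id, subj$subject_id)]
  out <- out[attended, , drop = FALSE]
  out <- out[order(out$subject_id, out$wave), , drop = FALSE]
  attr(out, "config") <- cfg
  out
}

#' Long-format cognitive test scores from a cohort table
#'
#' Reshapes the `cog_*` columns of a [generate_cohort()] table into the long
#' per-test format consumed by the diagnosis functions.
#'
#' @param cohort A cohort tibble.
#' @return Tibble with columns `subject_id`, `pair_id`, `wave`, `entry_wave`,
#'   `replacement`, `gca_age20`, `test_id`, `domain`, `normative_z` and a
#'   `returnee` flag (took the battery at an earlier wave).
#' @export
cohort_test_scores <- function(cohort) {
  cog_cols <- grep("^cog_", names(cohort), value = TRUE)
  if (length(cog_cols) == 0L) stop("no cognitive score columns in cohort")
  base <- cohort[c("subject_id", "pair_id", "wave", "entry_wave",
                   "replacement", "gca_age20")]
  long <- do.call(rbind, lapply(cog_cols, function(cl) {
    x <- base
    x$test_id <- cl
    x$domain <- sub("^cog_([a-z]+)_\\d+$", "\\1", cl)
    x$normative_z <- cohort[[cl]]
    x
  }))
  long$returnee <- long$wave > long$entry_wave
  tibble::as_tibble(long)
}
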