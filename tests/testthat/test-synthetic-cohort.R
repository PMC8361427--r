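test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(seed = 11L, n_pairs = 60L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(seed = 12L, n_pairs = 60L))
  expect_false(identical(a$thk_entorhinal_lh, c2$thk_entorhinal_lh))
})

test_that("cohort table satisfies its structural invariants", {
  co <- small_cohort()
  # one row per subject x attended wave
  expect_equal(anyDuplicated(paste(co$subject_id, co$wave)), 0L)
  # pairs group at most two subjects
  per_pair <- tapply(co$subject_id, co$pair_id,
                     function(s) length(unique(s)))
  expect_true(all(per_pair <= 2))
  # age strictly increasing within subject
  ok <- tapply(seq_len(nrow(co)), co$subject_id, function(ix) {
    ix <- ix[order(co$wave[ix])]
    all(diff(co$age[ix]) > 0)
  })
  expect_true(all(ok))
  # all 16 ROI columns present per modality, MD missing only as whole rows
  w <- signature_weights()
  key <- paste(w$region, w$hemi, sep = "_")
  tv_cols <- ifelse(w$region == "hippocampus", paste0("vol_", key),
                    paste0("thk_", key))
  expect_true(all(c(tv_cols, paste0("md_", key)) %in% names(co)))
  md <- as.matrix(co[paste0("md_", key)])
  n_na <- rowSums(is.na(md))
  expect_true(all(n_na %in% c(0L, 16L)))
  # replacements enter after wave 1 and never appear before their entry wave
  expect_true(all(co$wave >= co$entry_wave))
  expect_true(all(co$entry_wave[co$replacement] > 1L))
})

test_that("latent converter fraction is a binomial draw around the configured rate", {
  cfg <- cohort_config(seed = 21L, n_pairs = 2000L)
  co <- generate_cohort(cfg)
  subj <- co[!duplicated(co$subject_id), ]
  frac <- mean(subj$true_group == "converter")
  n <- nrow(subj)
  band <- 3 * sqrt(0.118 * 0.882 / n)
  expect_lt(abs(frac - 0.118), band)
})

test_that("null effect sizes leave the latent groups' ROI means indistinguishable", {
  cfg <- cohort_config(seed = 31L, n_pairs = 600L,
                       effect_sizes = c(md = 0, thickness_volume = 0))
  co <- generate_cohort(cfg)
  conv <- co$true_group == "converter"
  cols <- grep("^(thk|vol|md)_", names(co), value = TRUE)
  expect_length(cols, 32L)
  # checking every ROI measure at a per-column 3-SE bound has ~8% family
  # false-failure by design; bound the max |z| with a multiplicity-adjusted
  # cutoff instead (per-column alpha 6e-5, family ~0.2%)
  for (col in cols) {
    x <- co[[col]][conv]; y <- co[[col]][!conv]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    se <- sqrt(var(x) / length(x) + var(y) / length(y))
    expect_lt(abs(mean(x) - mean(y)), 4 * se, label = col)
  }
})

test_that("within-pair correlation recovers the configured MZ ICC", {
  cfg <- cohort_config(seed = 41L, n_pairs = 5000L, waves = 1L,
                       coupling = 0.3)
  co <- generate_cohort(cfg)
  mz <- co[co$zygosity == "MZ", ]
  pairs <- split(seq_len(nrow(mz)), mz$pair_id)
  pairs <- pairs[vapply(pairs, length, integer(1)) == 2L]
  for (trait in c("prs", "gca_age20", "thk_middletemporal_rh")) {
    m <- t(vapply(pairs, function(ix) mz[[trait]][ix], numeric(2)))
    # double-entered intraclass correlation
    icc <- cor(c(m[, 1], m[, 2]), c(m[, 2], m[, 1]))
    expect_lt(abs(icc - cfg$twin_icc), 0.05)
  }
})

test_that("DZ pairs correlate at the configured share of the MZ ICC", {
  cfg <- cohort_config(seed = 43L, n_pairs = 5000L, waves = 1L,
                       coupling = 0.3)
  co <- generate_cohort(cfg)
  dz <- co[co$zygosity == "DZ", ]
  pairs <- split(seq_len(nrow(dz)), dz$pair_id)
  pairs <- pairs[vapply(pairs, length, integer(1)) == 2L]
  m <- t(vapply(pairs, function(ix) dz[["prs"]][ix], numeric(2)))
  icc <- cor(c(m[, 1], m[, 2]), c(m[, 2], m[, 1]))
  expect_lt(abs(icc - cfg$twin_icc * cfg$dz_share), 0.05)
})

test_that("configuration validation rejects out-of-range settings", {
  expect_error(cohort_config(n_pairs = 1), "n_pairs")
  expect_error(cohort_config(conversion_rate = 1.2), "probabilities")
  expect_error(cohort_config(waves = 0), "waves")
  expect_error(cohort_config(dropout_rate = 0.5, frailty_rate = 0.3),
               "frailty_rate")
  expect_error(cohort_config(coupling = c(0.2, 0.4)), "coupling")
  expect_s3_class(cohort_config(), "cohort_config")
  expect_output(print(cohort_config()), "twin pairs")
})

test_that("test-score reshaping preserves values and flags returnees", {
  co <- small_cohort()
  ts <- cohort_test_scores(co)
  expect_equal(nrow(ts), nrow(co) * 18L)
  expect_setequal(unique(ts$domain),
                  c("memory", "executive", "attention", "language",
                    "visuospatial", "speed"))
  # spot-check one cell against the wide table
  row <- co[17, ]
  got <- ts$normative_z[ts$subject_id == row$subject_id &
                          ts$wave == row$wave &
                          ts$test_id == "cog_memory_2"]
  expect_equal(got, row$cog_memory_2)
  expect_equal(ts$returnee, ts$wave > ts$entry_wave)
})
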