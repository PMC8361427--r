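#' Concurrent group comparison by linear mixed model
#'
#' Fits `score ~ group * wave` (or main effects only) with random intercepts
#' for twin pair and for subject nested within pair, mirroring repeated
#' measures within subjects and correlation within twin dyads. Tests use
#' Satterthwaite-approximate denominator degrees of freedom. The group effect
#' size is a standardized mean difference: the model-adjusted group difference
#' divided by the pooled within-group SD of the raw outcome (positive = second
#' group level, typically MCI, higher).
#'
#' @param data Long tibble with the outcome plus `group` (2-level factor or
#'   character; first level is the reference, e.g. robust-CN), `wave`,
#'   `subject_id`, `pair_id`.
#' @param outcome Name of the outcome column.
#' @param include_interaction Include the group-by-wave interaction (default
#'   TRUE). When the interaction is non-significant the caller is expected to
#'   refit with main effects only, as [concurrent_analysis()] does.
#' @return Object of class `lmm_result`: list with `fixed_effects` (tibble of
#'   estimates, SE, Satterthwaite df, t, p), `smd`, `interaction_p` (NA for
#'   main-effects fits), `group_levels`, `converged`, `degraded` (TRUE when
#'   the mixed fit failed and an independence model was used), `n`, `model`.
#' @export
fit_concurrent_lmm <- function(data, outcome = "score",
                               include_interaction = TRUE) {
  stopifnot(all(c(outcome, "group", "wave", "subject_id", "pair_id")
                %in% names(data)))
  d <- data.frame(y = data[[outcome]],
                  group = factor(data$group),
                  wave = factor(data$wave),
                  subject_id = data$subject_id, pair_id = data$pair_id)
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$group)) != 2L)
    stop("group must have exactly two observed levels")
  if (length(unique(d$subject_id)) < 4L) stop("too few subjects")

  fixed <- if (include_interaction && nlevels(droplevels(d$wave)) > 1L)
    y ~ group * wave else if (nlevels(droplevels(d$wave)) > 1L)
    y ~ group + wave else y ~ group
  form <- stats::update(fixed, . ~ . + (1 | pair_id) + (1 | subject_id))

  degraded <- FALSE
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(form, data = d, REML = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    degraded <- TRUE
    fit <- stats::lm(fixed, data = d)
  }

  if (inherits(fit, "lmerModLmerTest")) {
    ct <- stats::coef(summary(fit))
    fe <- tibble::tibble(term = rownames(ct), estimate = ct[, "Estimate"],
                         se = ct[, "Std. Error"], df = ct[, "df"],
                         t = ct[, "t value"], p = ct[, "Pr(>|t|)"])
    interaction_p <- NA_real_
    if (include_interaction && any(grepl(":", rownames(ct)))) {
      an <- stats::anova(fit, type = 3)  # Satterthwaite type III
      ir <- grep(":", rownames(an))
      interaction_p <- an[ir, "Pr(>F)"][1]
    }
    converged <- length(fit@optinfo$conv$lme4$messages) == 0L
  } else {
    ct <- stats::coef(summary(fit))
    fe <- tibble::tibble(term = rownames(ct), estimate = ct[, "Estimate"],
                         se = ct[, "Std. Error"],
                         df = stats::df.residual(fit), t = ct[, "t value"],
                         p = ct[, "Pr(>|t|)"])
    interaction_p <- if (include_interaction && any(grepl(":", rownames(ct)))) {
      an <- stats::anova(fit)
      ir <- grep(":", rownames(an))
      an[ir, "Pr(>F)"][1]
    } else NA_real_
    converged <- TRUE
  }

  glev <- levels(droplevels(d$group))
  smd <- smd_from_model(fit, outcome_values = d$y, group = d$group)
  structure(list(fixed_effects = fe, smd = smd, interaction_p = interaction_p,
                 group_levels = glev, converged = converged,
                 degraded = degraded, n = length(unique(d$subject_id)),
                 n_obs = nrow(d), model = fit),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> %d subjects, %d observations%s\n", x$n, x$n_obs,
              if (x$degraded) " [degraded: independence fallback]" else ""))
  gi <- grep("^group", x$fixed_effects$term)[1]
  if (!is.na(gi))
    cat(sprintf("  group (%s vs %s): est %.3f, t(%.1f) = %.2f, p = %.3g, SMD = %.3f\n",
                x$group_levels[2], x$group_levels[1],
                x$fixed_effects$estimate[gi], x$fixed_effects$df[gi],
                x$fixed_effects$t[gi], x$fixed_effects$p[gi], x$smd))
  if (!is.na(x$interaction_p))
    cat(sprintf("  group x wave interaction p = %.3g\n", x$interaction_p))
  invisible(x)
}

#' Standardized mean difference for a fitted group effect
#'
#' The adjusted group-coefficient estimate divided by the pooled within-group
#' SD of the raw outcome (a Cohen's-d-analogue for the clustered design).
#'
#' @param model A fitted model containing a `group` fixed effect.
#' @param outcome_values Raw outcome values used for the pooled SD.
#' @param group Group factor aligned with `outcome_values`.
#' @return The SMD (positive = second group level higher, adjusted).
#' @export
smd_from_model <- function(model, outcome_values, group) {
  fe <- if (inherits(model, "merMod")) lme4::fixef(model)
        else stats::coef(model)
  gi <- grep("^group", names(fe))
  gi <- gi[!grepl(":", names(fe)[gi])][1]
  if (is.na(gi)) stop("model has no group main effect")
  ps <- pooled_sd(outcome_values, group)
  if (ps == 0) stop("zero pooled outcome SD")
  unname(fe[gi]) / ps
}

pooled_sd <- function(x, g) {
  g <- droplevels(factor(g))
  v <- tapply(x, g, stats::var)
  n <- tapply(x, g, length)
  sqrt(sum((n - 1) * v) / (sum(n) - length(v)))
}

#' Paper-style concurrent analysis for one outcome
#'
#' Fits the interaction model first; when the group-by-wave interaction is not
#' significant at `alpha`, refits with main effects only and reports that
#' model (the usual workflow for these comparisons).
#'
#' @inheritParams fit_concurrent_lmm
#' @param alpha Significance level for the interaction test (default 0.05).
#' @return An `lmm_result`; its `interaction_p` records the interaction test
#'   from the first fit, and `refit_main_effects` marks whether the reported
#'   fit is the main-effects model.
#' @export
concurrent_analysis <- function(data, outcome = "score", alpha = 0.05) {
  full <- fit_concurrent_lmm(data, outcome, include_interaction = TRUE)
  if (!is.na(full$interaction_p) && full$interaction_p >= alpha) {
    main <- fit_concurrent_lmm(data, outcome, include_interaction = FALSE)
    main$interaction_p <- full$interaction_p
    main$refit_main_effects <- TRUE
    return(main)
  }
  full$refit_main_effects <- FALSE
  full
}

#' Per-wave correlation between the two signature scores
#'
#' Pearson correlation (with p-value) between thickness/volume and MD
#' signature scores within each wave, over paired complete observations.
#'
#' @param scores_tv,scores_md Tibbles from [score_signatures()] for the two
#'   modalities (columns `subject_id`, `wave`, `score`).
#' @return Tibble `wave`, `r`, `p`, `n`.
#' @export
wave_correlations <- function(scores_tv, scores_md) {
  m <- merge(scores_tv[c("subject_id", "wave", "score")],
             scores_md[c("subject_id", "wave", "score")],
             by = c("subject_id", "wave"), suffixes = c("_tv", "_md"))
  out <- lapply(sort(unique(m$wave)), function(w) {
    d <- m[m$wave == w & stats::complete.cases(m[c("score_tv", "score_md")]), ]
    if (nrow(d) < 3L) stop("need at least 3 paired observations per wave")
    if (sd(d$score_tv) == 0 || sd(d$score_md) == 0)
      stop("constant scores at wave ", w)
    ct <- stats::cor.test(d$score_tv, d$score_md)
    tibble::tibble(wave = w, r = unname(ct$estimate), p = ct$p.value,
                   n = nrow(d))
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up FDR control at level `q`; rejection flags are monotone in the
#' p-values. Wraps the standard BH adjustment.
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return Logical rejection flags.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH") <= q
}
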