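#' Predictor sets of the five risk models
#'
#' Model 1: age + PRS; Model 2: + thickness/volume signature; Model 3: + MD
#' signature; Model 4: both signatures; Model 5: age + PRS + PBAD-adjusted
#' thickness/volume and MD signatures.
#'
#' @return Named list of character vectors of predictor column names.
#' @export
model_specs <- function() {
  list(
    `1` = c("age", "prs"),
    `2` = c("age", "prs", "tv_signature"),
    `3` = c("age", "prs", "md_signature"),
    `4` = c("age", "prs", "tv_signature", "md_signature"),
    `5` = c("age", "prs", "tv_pbad_adj", "md_pbad_adj")
  )
}

#' Fit a clustered logistic risk model
#'
#' Mixed-effects logistic regression of the conversion outcome on z-scored
#' predictors with a random intercept per twin pair (Laplace marginal
#' likelihood). Fitted probabilities are computed from the *fixed effects
#' only*; the pair intercepts affect estimation, not scoring. If the mixed fit
#' fails (e.g. separation or zero cluster variance pathologies) an ordinary
#' logistic fit is used and flagged as degraded.
#'
#' @param data Tibble with the outcome, predictors and `pair_id`.
#' @param outcome Name of the binary (0/1 or logical) outcome column.
#' @param predictors Character vector of predictor columns; z-scored within
#'   the analysis sample before fitting.
#' @return Object of class `risk_model`: list with `coefficients` tibble
#'   (estimate, se, z, p, odds ratio with Wald CI), `fitted` (fixed-effects
#'   probabilities), `labels`, `converged`, `degraded`, `notes` (captured
#'   summary warnings, e.g. Hessian fallbacks), `n`, `model`.
#' @export
fit_risk_model <- function(data, outcome = "converted",
                           predictors = model_specs()[["1"]]) {
  stopifnot(all(c(outcome, predictors, "pair_id") %in% names(data)))
  d <- data[stats::complete.cases(data[c(outcome, predictors, "pair_id")]), ]
  y <- as.integer(d[[outcome]])
  if (!all(y %in% 0:1)) stop("outcome must be binary")
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  X <- sapply(predictors, function(p) {
    x <- d[[p]]
    if (sd(x) == 0) stop("zero-variance predictor: ", p)
    (x - mean(x)) / sd(x)
  })
  dd <- data.frame(y = y, X, pair_id = d$pair_id)
  form <- stats::as.formula(paste("y ~", paste(predictors, collapse = " + "),
                                  "+ (1 | pair_id)"))
  degraded <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      lme4::glmer(form, data = dd, family = stats::binomial, nAGQ = 1L),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage")),
    error = function(e) NULL)
  if (is.null(fit)) {
    degraded <- TRUE
    fit <- stats::glm(stats::as.formula(
      paste("y ~", paste(predictors, collapse = " + "))),
      data = dd, family = stats::binomial)
  }
  # summarizing near-degenerate mixed fits can warn about a non-PD Hessian;
  # record such notes on the result instead of emitting them
  notes <- character()
  quiet_summary <- function(f) withCallingHandlers(
    stats::coef(summary(f)),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "merMod")) {
    ct <- quiet_summary(fit)
    converged <- length(fit@optinfo$conv$lme4$messages) == 0L
    beta <- lme4::fixef(fit)
  } else {
    ct <- quiet_summary(fit)
    converged <- fit$converged
    beta <- stats::coef(fit)
  }
  if (any(abs(beta[-1]) > 10))
    warning("very large coefficients; possible complete separation")
  est <- ct[, 1]; se <- ct[, 2]
  coefs <- tibble::tibble(
    term = rownames(ct), estimate = est, se = se, z = ct[, 3],
    p = ct[, 4], or = exp(est),
    or_lo = exp(est - stats::qnorm(0.975) * se),
    or_hi = exp(est + stats::qnorm(0.975) * se))
  eta <- as.vector(cbind(1, as.matrix(dd[predictors])) %*% beta)
  structure(list(coefficients = coefs, fitted = stats::plogis(eta),
                 labels = y, predictors = predictors, converged = converged,
                 degraded = degraded, notes = notes, n = nrow(dd),
                 model = fit),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> n = %d (%d events)%s\n", x$n, sum(x$labels),
              if (x$degraded) " [degraded: plain logistic fallback]" else ""))
  cf <- x$coefficients[x$coefficients$term != "(Intercept)", ]
  for (i in seq_len(nrow(cf)))
    cat(sprintf("  %-14s OR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
                cf$term[i], cf$or[i], cf$or_lo[i], cf$or_hi[i], cf$p[i]))
  invisible(x)
}

#' Area under the ROC curve
#'
#' AUC as the Mann-Whitney concordance probability with midrank tie handling
#' (equivalent to trapezoidal integration of the empirical ROC curve).
#'
#' @param probabilities Numeric scores or probabilities.
#' @param labels Binary labels (0/1 or logical), 1 = positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(probabilities, labels) {
  labels <- as.integer(labels)
  ok <- !is.na(probabilities) & !is.na(labels)
  probabilities <- probabilities[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-optimal ROC operating point
#'
#' Scans all candidate cutoffs (midpoints between sorted unique scores, plus
#' minus/plus infinity) and returns the threshold maximizing Youden's J
#' (sensitivity + specificity - 1). A score counts as positive when it is at
#' or above the threshold. Ties in J are broken toward the higher threshold,
#' i.e. toward higher specificity.
#'
#' @inheritParams roc_auc
#' @return List with `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
youden_threshold <- function(probabilities, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  u <- sort(unique(probabilities))
  cand <- c(-Inf, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- list(j = -Inf, threshold = -Inf, sensitivity = NA, specificity = NA)
  for (thr in cand) {
    pred <- probabilities >= thr
    sens <- sum(pred & labels == 1L) / n_pos
    spec <- sum(!pred & labels == 0L) / n_neg
    j <- sens + spec - 1
    if (j > best$j || (j == best$j && thr > best$threshold))
      best <- list(j = j, threshold = thr, sensitivity = sens,
                   specificity = spec)
  }
  best[c("threshold", "sensitivity", "specificity", "j")]
}

#' Confusion counts and summary metrics from rates and group sizes
#'
#' Reconstructs the confusion matrix implied by a reported sensitivity and
#' specificity with known case/control counts (nearest-integer rounding), and
#' derives accuracy, positive and negative predictive values. Useful for
#' checking published operating points.
#'
#' @param sens,spec Sensitivity and specificity in \[0, 1\].
#' @param n_pos,n_neg Positive (case) and negative (control) counts.
#' @return List with `tp`, `fp`, `tn`, `fn`, `accuracy`, `ppv`, `npv`
#'   (`ppv`/`npv` are `NA` when undefined).
#' @export
confusion_metrics <- function(sens, spec, n_pos, n_neg) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1, n_pos > 0, n_neg > 0)
  tp <- round(sens * n_pos); tn <- round(spec * n_neg)
  fn <- n_pos - tp; fp <- n_neg - tn
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / (n_pos + n_neg),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Full ROC report for a fitted model
#'
#' AUC with a stratified-bootstrap percentile CI, the Youden-optimal threshold
#' with the sensitivity/specificity realized at that threshold on the fitted
#' probabilities, and the resulting confusion counts and metrics.
#'
#' @param probabilities Fitted probabilities.
#' @param labels Binary labels.
#' @param n_boot Bootstrap replicates for the AUC CI (default 2000).
#' @param seed Seed for the bootstrap streams.
#' @param conf_level CI level (default 0.95).
#' @return List of class `roc_report` with `auc`, `auc_ci`, `threshold`,
#'   `sensitivity`, `specificity`, `j`, `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `ppv`, `npv`, `n_pos`, `n_neg`.
#' @export
roc_report <- function(probabilities, labels, n_boot = 2000L, seed = 1L,
                       conf_level = 0.95) {
  labels <- as.integer(labels)
  yj <- youden_threshold(probabilities, labels)
  auc <- roc_auc(probabilities, labels)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    ix <- c(sample(pos, length(pos), replace = TRUE),
            sample(neg, length(neg), replace = TRUE))
    roc_auc(probabilities[ix], labels[ix])
  }, numeric(1))
  a <- (1 - conf_level) / 2
  pred <- probabilities >= yj$threshold
  tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
  tn <- sum(!pred & labels == 0L); fn <- sum(!pred & labels == 1L)
  structure(list(auc = auc,
                 auc_ci = unname(stats::quantile(boot, c(a, 1 - a))),
                 threshold = yj$threshold, sensitivity = yj$sensitivity,
                 specificity = yj$specificity, j = yj$j,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / length(labels),
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("<roc_report> AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  Youden threshold %.4f: sens %.3f, spec %.3f, acc %.3f, ppv %.3f, npv %.3f\n",
              x$threshold, x$sensitivity, x$specificity, x$accuracy,
              x$ppv, x$npv))
  invisible(x)
}

#' Stratified-bootstrap comparison of two AUCs
#'
#' Resamples cases and controls separately with replacement, recomputes the
#' AUC difference of two models' scores per replicate, and reports a two-sided
#' p-value from the normal approximation: `D = observed difference / bootstrap
#' SD of the difference`, referred to a standard normal. A percentile-based
#' p-value (fraction of replicate differences crossing zero, doubled) is also
#' returned. Deterministic given `seed`; symmetric in the two models.
#'
#' @param probs_a,probs_b Scores of the two models, on the same subjects.
#' @param labels Shared binary labels.
#' @param n_boot Bootstrap replicates (default 2000; < 100 warns).
#' @param seed Root seed for the replicate streams.
#' @return List with `auc_a`, `auc_b`, `diff`, `sd_boot`, `statistic`, `p`
#'   (normal approximation), `p_percentile`, `n_boot_used` (degenerate
#'   single-class resamples are skipped and counted out).
#' @export
bootstrap_auc_compare <- function(probs_a, probs_b, labels, n_boot = 2000L,
                                  seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(length(probs_a) == length(labels),
            length(probs_b) == length(labels))
  if (n_boot < 100L) warning("fewer than 100 bootstrap replicates")
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present")
  auc_a <- roc_auc(probs_a, labels); auc_b <- roc_auc(probs_b, labels)
  obs <- auc_a - auc_b
  if (isTRUE(all.equal(probs_a, probs_b)))
    return(list(auc_a = auc_a, auc_b = auc_b, diff = 0, sd_boot = 0,
                statistic = 0, p = 1, p_percentile = 1,
                n_boot_used = 0L))
  set.seed(seed)
  diffs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    ix <- c(sample(pos, length(pos), replace = TRUE),
            sample(neg, length(neg), replace = TRUE))
    lb <- labels[ix]
    diffs[b] <- roc_auc(probs_a[ix], lb) - roc_auc(probs_b[ix], lb)
  }
  diffs <- diffs[!is.na(diffs)]
  sd_boot <- sd(diffs)
  if (sd_boot == 0)
    return(list(auc_a = auc_a, auc_b = auc_b, diff = obs, sd_boot = 0,
                statistic = 0, p = 1, p_percentile = 1,
                n_boot_used = length(diffs)))
  stat <- obs / sd_boot
  p_perc <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  list(auc_a = auc_a, auc_b = auc_b, diff = obs, sd_boot = sd_boot,
       statistic = stat, p = 2 * stats::pnorm(-abs(stat)),
       p_percentile = min(p_perc, 1), n_boot_used = length(diffs))
}
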