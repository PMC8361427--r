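#' Residualize an ROI measure on nuisance covariates
#'
#' Regresses an ROI measure on age and scanner (as unordered categorical
#' indicators; reference level is the first label alphabetically), optionally
#' plus estimated intracranial volume (used for hippocampal volume), and
#' returns the OLS residuals standardized to mean 0 and SD 1. Missing values
#' propagate (their residuals are `NA`); the fit uses complete cases only.
#'
#' @param values Numeric ROI measure.
#' @param age Numeric, years.
#' @param scanner Optional character/factor scanner label.
#' @param icv Optional numeric intracranial volume.
#' @return Standardized residuals, same length as `values`.
#' @export
residualize_roi <- function(values, age, scanner = NULL, icv = NULL) {
  n <- length(values)
  stopifnot(length(age) == n)
  df <- data.frame(.y = values, .age = age)
  form <- .y ~ .age
  if (!is.null(scanner)) {
    stopifnot(length(scanner) == n)
    df$.scanner <- factor(scanner)
    if (nlevels(droplevels(df$.scanner[!is.na(values)])) > 1L)
      form <- stats::update(form, . ~ . + .scanner)
  }
  if (!is.null(icv)) {
    stopifnot(length(icv) == n)
    df$.icv <- icv
    form <- stats::update(form, . ~ . + .icv)
  }
  ok <- stats::complete.cases(df)
  if (sum(ok) < 3L) stop("need at least 3 complete observations")
  if (sd(values[ok]) == 0) stop("constant ROI values")
  fit <- stats::lm(form, data = df[ok, , drop = FALSE])
  res <- rep(NA_real_, n)
  res[ok] <- stats::residuals(fit)
  s <- sd(res[ok])
  if (!is.finite(s) || s < 1e-12)
    stop("residuals are constant; covariates explain the ROI exactly")
  res / s
}

#' Weighted composite of standardized ROI residuals
#'
#' The raw signature score: the weighted sum over the 16 region x hemisphere
#' standardized residuals using the published weights. No normalization by the
#' weight sum is applied; the final per-wave z-scoring makes the scale
#' irrelevant. Any missing residual makes the composite missing (the 16 fixed
#' components define the signature; no partial reweighting).
#'
#' @param std_residuals Numeric matrix (subjects x 16) or vector (length 16) of
#'   standardized residuals; columns named `<region>_<hemi>` matching the
#'   weight table.
#' @param weights Weight table from [signature_weights()].
#' @return Numeric vector of raw composite scores (`NA` where any component is
#'   missing).
#' @export
composite_score <- function(std_residuals, weights = signature_weights()) {
  check_weight_table(weights)
  if (is.null(dim(std_residuals)))
    std_residuals <- matrix(std_residuals, nrow = 1,
                            dimnames = list(NULL, names(std_residuals)))
  key <- paste(weights$region, weights$hemi, sep = "_")
  if (!is.null(colnames(std_residuals))) {
    if (!all(key %in% colnames(std_residuals)))
      stop("residual columns do not cover the 16 weighted ROIs")
    std_residuals <- std_residuals[, key, drop = FALSE]
  } else if (ncol(std_residuals) != 16L) {
    stop("unnamed residual input must have exactly 16 columns")
  }
  as.vector(std_residuals %*% weights$weight)
}

#' Compute signature scores for a cohort
#'
#' For each wave, residualizes every ROI measure of the requested modality on
#' age and scanner (plus ICV for hippocampal volume), forms the weighted
#' composite, and z-scores it within wave over the analysis sample. The
#' thickness/volume modality uses cortical thickness plus hippocampal volume;
#' the MD modality uses grey-matter MD for the same 16 ROIs with the same
#' weights. Residualization is fit on the full sample at each wave (not
#' CN-only) so the covariate model does not depend on diagnosis; see the
#' vignette.
#'
#' @param cohort Cohort tibble from [generate_cohort()] (or any table with the
#'   same column dictionary).
#' @param weights Weight table; defaults to the published weights.
#' @param modality `"thickness_volume"`, `"md"`, or `"both"`.
#' @param icv_adjust_hippocampus Regress ICV out of hippocampal volume
#'   (default TRUE; never applied to MD).
#' @return Tibble `subject_id`, `wave`, `modality`, `score` (per-wave z units).
#' @export
score_signatures <- function(cohort, weights = signature_weights(),
                             modality = c("both", "thickness_volume", "md"),
                             icv_adjust_hippocampus = TRUE) {
  modality <- match.arg(modality)
  mods <- if (modality == "both") c("thickness_volume", "md") else modality
  check_weight_table(weights)
  key <- paste(weights$region, weights$hemi, sep = "_")

  out <- list()
  for (m in mods) {
    cols <- vapply(seq_len(nrow(weights)), function(i) {
      prefix <- if (m == "md") "md"
                else if (weights$region[i] == "hippocampus") "vol" else "thk"
      paste0(prefix, "_", key[i])
    }, character(1))
    missing_cols <- setdiff(cols, names(cohort))
    if (length(missing_cols) > 0L)
      stop("cohort lacks ROI columns for modality ", m, ": ",
           paste(missing_cols, collapse = ", "))
    for (w in sort(unique(cohort$wave))) {
      rows <- which(cohort$wave == w)
      Z <- matrix(NA_real_, length(rows), 16L, dimnames = list(NULL, key))
      for (i in seq_len(16L)) {
        use_icv <- m == "thickness_volume" &&
          weights$region[i] == "hippocampus" && icv_adjust_hippocampus
        Z[, i] <- residualize_roi(cohort[[cols[i]]][rows],
                                  age = cohort$age[rows],
                                  scanner = cohort$scanner[rows],
                                  icv = if (use_icv) cohort$icv[rows])
      }
      raw <- composite_score(Z, weights)
      sc <- zscore_na(raw)
      out[[length(out) + 1L]] <- tibble::tibble(
        subject_id = cohort$subject_id[rows], wave = w, modality = m,
        score = sc)
    }
  }
  do.call(rbind, out)
}

# z-score ignoring NAs; errors if fewer than 2 usable values
zscore_na <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("too few non-missing scores to standardize")
  s <- sd(x[ok])
  if (s == 0) stop("constant scores cannot be standardized")
  (x - mean(x[ok])) / s
}

#' Predicted brain age difference (PBAD)
#'
#' PBAD is chronological age minus model-predicted brain age; lower (more
#' negative) values indicate a brain that looks older than its chronological
#' age.
#'
#' @param cohort Table with `subject_id`, `wave`, `age`,
#'   `predicted_brain_age`.
#' @return Tibble `subject_id`, `wave`, `chronological_age`,
#'   `predicted_brain_age`, `pbad`.
#' @export
compute_pbad <- function(cohort) {
  stopifnot(all(c("age", "predicted_brain_age") %in% names(cohort)))
  if (anyNA(cohort$age) || anyNA(cohort$predicted_brain_age))
    stop("both ages must be present for every row")
  tibble::tibble(subject_id = cohort$subject_id, wave = cohort$wave,
                 chronological_age = cohort$age,
                 predicted_brain_age = cohort$predicted_brain_age,
                 pbad = cohort$age - cohort$predicted_brain_age)
}

#' Adjust signature scores for predicted brain age difference
#'
#' Residualizes each per-wave, per-modality score on PBAD and re-standardizes,
#' yielding scores orthogonal to the brain-age gap (used to check whether the
#' signatures index Alzheimer-related change rather than general ageing).
#'
#' @param scores Tibble from [score_signatures()].
#' @param pbad Tibble from [compute_pbad()].
#' @return `scores` with `score` replaced by the PBAD-adjusted, re-standardized
#'   value and a `pbad_adjusted = TRUE` marker column.
#' @export
pbad_adjust <- function(scores, pbad) {
  keys <- paste(scores$subject_id, scores$wave)
  pb <- pbad$pbad[match(keys, paste(pbad$subject_id, pbad$wave))]
  if (anyNA(pb)) stop("PBAD missing for some subject-wave rows")
  out <- scores
  for (m in unique(scores$modality)) {
    for (w in unique(scores$wave)) {
      rows <- which(scores$modality == m & scores$wave == w)
      ok <- rows[!is.na(scores$score[rows])]
      if (length(ok) < 3L) next
      if (sd(pb[ok]) == 0) stop("PBAD constant across the sample")
      fit <- stats::lm(scores$score[ok] ~ pb[ok])
      res <- rep(NA_real_, length(rows))
      res[match(ok, rows)] <- stats::residuals(fit)
      if (sd(res, na.rm = TRUE) < 1e-12)
        stop("scores are a linear function of PBAD; adjusted score undefined")
      out$score[rows] <- zscore_na(res)
    }
  }
  out$pbad_adjusted <- TRUE
  out
}
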