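#' Adjust cognitive scores for young-adult general cognitive ability
#'
#' Removes long-standing ability differences before diagnosis: each test's
#' normative-z scores are regressed on a measure of general cognitive ability
#' administered in young adulthood (around age 20), and the GCA slope is
#' removed while keeping the normative-z scale and level (scores of a person
#' at the sample-mean GCA are unchanged; residual spread is *not* re-inflated,
#' so lifelong-low-ability individuals are no longer over-flagged).
#'
#' @param scores Long tibble with `test_id`, `normative_z` and `gca_age20`
#'   (as from [cohort_test_scores()]).
#' @return `scores` with `normative_z` replaced by the GCA-adjusted value.
#' @export
gca_adjust <- function(scores) {
  stopifnot(all(c("test_id", "normative_z", "gca_age20") %in% names(scores)))
  out <- scores
  for (tid in unique(scores$test_id)) {
    rows <- which(scores$test_id == tid)
    ok <- rows[!is.na(scores$normative_z[rows]) & !is.na(scores$gca_age20[rows])]
    if (length(ok) < 3L) next
    g <- scores$gca_age20[ok]
    if (sd(g) == 0) stop("GCA constant across the sample")
    y <- scores$normative_z[ok]
    b <- stats::cov(y, g) / stats::var(g)
    adj <- y - b * (g - mean(g))
    if (sd(adj) < 1e-12)
      stop("scores are a linear function of GCA; adjusted score undefined")
    out$normative_z[ok] <- adj
  }
  out
}

#' Attrition effect of a test at a wave
#'
#' The difference between the mean prior-wave score of returnees and the mean
#' prior-wave score of all individuals tested at that prior wave. Positive
#' values mean returnees were higher-functioning than the full prior-wave
#' sample (selective dropout of lower scorers).
#'
#' @param returnee_prior Numeric prior-wave scores of subjects who returned.
#' @param all_prior Numeric prior-wave scores of all subjects at that wave.
#' @return `mean(returnee_prior) - mean(all_prior)`.
#' @export
attrition_effect <- function(returnee_prior, all_prior) {
  returnee_prior <- returnee_prior[!is.na(returnee_prior)]
  all_prior <- all_prior[!is.na(all_prior)]
  if (length(returnee_prior) == 0L) stop("empty returnee set")
  if (length(all_prior) == 0L) stop("empty prior-wave sample")
  mean(returnee_prior) - mean(all_prior)
}

#' Practice effect of a test at a wave (replacement-subjects method)
#'
#' Returnees differ from demographically matched first-time replacement
#' subjects both through practice and through selective attrition; the
#' practice effect is the returnee-minus-replacement difference score with the
#' attrition effect removed.
#'
#' @param returnee_current Current-wave scores of returnees.
#' @param replacement_current Current-wave scores of first-exposure
#'   replacement subjects.
#' @param attrition Attrition effect for the same test/wave (from
#'   [attrition_effect()]).
#' @return `(mean(returnee_current) - mean(replacement_current)) - attrition`.
#' @export
practice_effect <- function(returnee_current, replacement_current, attrition) {
  returnee_current <- returnee_current[!is.na(returnee_current)]
  replacement_current <- replacement_current[!is.na(replacement_current)]
  if (length(replacement_current) == 0L)
    stop("no replacement subjects at this wave")
  if (length(returnee_current) == 0L) stop("empty returnee set")
  (mean(returnee_current) - mean(replacement_current)) - attrition
}

#' Estimate the practice/attrition adjustment ledger
#'
#' For every test and every wave after the first, computes the attrition
#' effect (returnees vs all subjects at the previous wave) and the practice
#' effect (returnees vs replacement subjects at the current wave, minus
#' attrition).
#'
#' @param scores Long test-score tibble from [cohort_test_scores()] (needs
#'   `subject_id`, `wave`, `test_id`, `normative_z`, `returnee`,
#'   `replacement`).
#' @return Tibble `test_id`, `wave`, `attrition_effect`, `practice_effect`,
#'   `returnee_n`, `replacement_n`.
#' @export
estimate_adjustments <- function(scores) {
  waves <- sort(unique(scores$wave))
  out <- list()
  for (w in waves[-1]) {
    cur <- scores[scores$wave == w, ]
    prev <- scores[scores$wave == w - 1L, ]
    returnee_ids <- unique(cur$subject_id[cur$returnee])
    for (tid in unique(scores$test_id)) {
      cur_t <- cur[cur$test_id == tid, ]
      prev_t <- prev[prev$test_id == tid, ]
      ret_cur <- cur_t$normative_z[cur_t$returnee]
      rep_cur <- cur_t$normative_z[!cur_t$returnee & cur_t$replacement]
      ret_prev <- prev_t$normative_z[prev_t$subject_id %in% returnee_ids]
      att <- attrition_effect(ret_prev, prev_t$normative_z)
      pe <- if (length(rep_cur[!is.na(rep_cur)]) > 0L)
        practice_effect(ret_cur, rep_cur, att) else NA_real_
      out[[length(out) + 1L]] <- tibble::tibble(
        test_id = tid, wave = w, attrition_effect = att, practice_effect = pe,
        returnee_n = sum(!is.na(ret_cur)),
        replacement_n = sum(!is.na(rep_cur)))
    }
  }
  if (length(out) == 0L)
    return(tibble::tibble(test_id = character(), wave = integer(),
                          attrition_effect = numeric(),
                          practice_effect = numeric(),
                          returnee_n = integer(), replacement_n = integer()))
  do.call(rbind, out)
}

#' Apply practice-effect adjustments to returnee scores
#'
#' Subtracts each test/wave practice effect from the scores of returning
#' participants; first-exposure scores (wave 1 and replacement entries) are
#' unchanged.
#'
#' @param scores Long test-score tibble (needs `test_id`, `wave`,
#'   `normative_z`, `returnee`).
#' @param ledger Adjustment ledger from [estimate_adjustments()].
#' @return `scores` with adjusted `normative_z`.
#' @export
apply_adjustments <- function(scores, ledger) {
  out <- scores
  idx <- which(scores$returnee)
  if (length(idx) == 0L) return(out)
  key <- paste(scores$test_id[idx], scores$wave[idx])
  m <- match(key, paste(ledger$test_id, ledger$wave))
  if (anyNA(m))
    stop("ledger lacks entries for some returnee test-wave cells")
  pe <- ledger$practice_effect[m]
  if (anyNA(pe))
    stop("practice effect undefined (no replacements) for some returnee cells")
  out$normative_z[idx] <- out$normative_z[idx] - pe
  out
}

#' Actuarial (Jak-Bondi) classification of one subject-wave
#'
#' A cognitive domain is impaired when at least `min_tests` of its tests fall
#' strictly more than `threshold` SDs below the normative mean
#' (`normative_z < -threshold`); the label is MCI when at least one domain is
#' impaired, CN otherwise. A domain with fewer than `min_tests` scoreable
#' tests is indeterminate; the label is missing (`NA`) when any domain is
#' indeterminate and no other domain is already impaired.
#'
#' @param normative_z Numeric scores for one subject-wave.
#' @param domain Character domain of each score.
#' @param threshold Impairment cutoff in SD units (default 1.5).
#' @param min_tests Tests below cutoff required per domain (default 2).
#' @return List with `label` (`"CN"`, `"MCI"` or `NA`) and `impaired_domains`
#'   (character vector).
#' @export
classify_wave <- function(normative_z, domain, threshold = 1.5,
                          min_tests = 2L) {
  stopifnot(length(normative_z) == length(domain))
  doms <- unique(domain)
  impaired <- character()
  indeterminate <- FALSE
  for (d in doms) {
    z <- normative_z[domain == d]
    z <- z[!is.na(z)]
    if (length(z) < min_tests) { indeterminate <- TRUE; next }
    if (sum(z < -threshold) >= min_tests) impaired <- c(impaired, d)
  }
  label <- if (length(impaired) > 0L) "MCI"
           else if (indeterminate) NA_character_ else "CN"
  list(label = label, impaired_domains = impaired)
}

#' Classify every subject-wave of a long test-score table
#'
#' @param scores Long test-score tibble (needs `subject_id`, `wave`, `domain`,
#'   `normative_z`).
#' @inheritParams classify_wave
#' @return Tibble `subject_id`, `wave`, `label`, `n_impaired_domains`,
#'   `impaired_domains` (comma-separated).
#' @export
diagnose_cohort <- function(scores, threshold = 1.5, min_tests = 2L) {
  key <- paste(scores$subject_id, scores$wave)
  groups <- split(seq_len(nrow(scores)), key)
  res <- lapply(groups, function(ix) {
    cl <- classify_wave(scores$normative_z[ix], scores$domain[ix],
                        threshold, min_tests)
    tibble::tibble(subject_id = scores$subject_id[ix[1]],
                   wave = scores$wave[ix[1]], label = cl$label,
                   n_impaired_domains = length(cl$impaired_domains),
                   impaired_domains = paste(cl$impaired_domains,
                                            collapse = ","))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$subject_id, out$wave), ]
  rownames(out) <- NULL
  out
}

#' Longitudinal diagnostic status from per-wave labels
#'
#' Assigns each subject one status over their attended waves: subjects with
#' any MCI-to-CN reversion are excluded reverters; subjects CN at wave 1 who
#' are MCI at the final study wave are converters (the predictive-analysis
#' outcome); other subjects with any MCI label are MCI; subjects CN at every
#' attended wave are robust-CN.
#'
#' @param labels Tibble `subject_id`, `wave`, `label` from
#'   [diagnose_cohort()].
#' @param final_wave Index of the study's final wave (default: max observed).
#' @return Tibble `subject_id`, `status` in `robust_CN`, `MCI`, `converter`,
#'   `excluded_reverter`.
#' @export
longitudinal_status <- function(labels, final_wave = max(labels$wave)) {
  groups <- split(seq_len(nrow(labels)), labels$subject_id)
  res <- lapply(groups, function(ix) {
    ix <- ix[order(labels$wave[ix])]
    lab <- labels$label[ix]
    wv <- labels$wave[ix]
    known <- !is.na(lab)
    lab_k <- lab[known]; wv_k <- wv[known]
    if (length(lab_k) == 0L) return(NULL)
    reverted <- any(diff(match(lab_k, c("CN", "MCI"))) < 0)
    status <- if (reverted) "excluded_reverter"
      else if (any(wv_k == 1L & lab_k == "CN") &&
               any(wv_k == final_wave & lab_k == "MCI")) "converter"
      else if (any(lab_k == "MCI")) "MCI"
      else "robust_CN"
    tibble::tibble(subject_id = labels$subject_id[ix[1]], status = status)
  })
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}
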