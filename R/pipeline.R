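#' Run the full signature analysis pipeline
#'
#' Orchestrates the stages end to end: simulate (or load) the cohort, score
#' both signatures with PBAD adjustment, run the actuarial diagnosis with
#' practice/attrition correction, fit the concurrent mixed models, and fit the
#' five predictive models with ROC reports and stratified-bootstrap
#' comparisons against the age + PRS baseline. FDR control is applied
#' separately to the concurrent and the predictive families.
#'
#' When `out_dir` is given, each stage's artifact is written there (CSV/JSON)
#' together with a manifest recording the configuration hash and per-stage
#' input/output digests; re-running with the same configuration skips stages
#' whose recorded inputs and outputs are intact, and a corrupted or removed
#' intermediate file triggers re-execution of exactly that stage and its
#' downstream dependents.
#'
#' @param config A [cohort_config()]; its seed drives every stochastic stage.
#' @param out_dir Optional output directory for artifacts and the manifest.
#' @param n_boot Bootstrap replicates for AUC CIs and model comparisons.
#' @param threshold,min_tests Diagnosis parameters (see [classify_wave()]).
#' @param fdr_q FDR level for both analysis families.
#' @param force Recompute all stages even when cached artifacts match.
#' @return List of class `pipeline_result` with elements `cohort`, `scores`
#'   (wide per subject-wave), `diagnosis`, `status`, `concurrent` (per-outcome
#'   `lmm_result`s, SMD/p table with FDR flags, wave correlations),
#'   `prediction` (per-model `risk_model`/`roc_report`, comparison table,
#'   Table-3-shaped `report`), and `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         n_boot = 2000L, threshold = 1.5, min_tests = 2L,
                         fdr_q = 0.05, force = FALSE) {
  cfg_hash <- hash_object(config)
  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   package_version = as.character(utils::packageVersion("adsignatures")),
                   parameters = list(n_boot = n_boot, threshold = threshold,
                                     min_tests = min_tests, fdr_q = fdr_q),
                   stages = list(), stages_run = character(),
                   warnings = character())
  old <- if (!is.null(out_dir)) read_manifest(out_dir) else NULL

  ## stage: cohort ------------------------------------------------------------
  st <- stage_io(out_dir, old, "cohort", inputs = cfg_hash, force = force,
                 compute = function() generate_cohort(config),
                 reader = read_cohort_csv, writer = write_full_csv)
  cohort <- st$value; manifest <- record_stage(manifest, st)

  ## stage: signatures ---------------------------------------------------------
  st <- stage_io(out_dir, old, "signatures",
                 inputs = c(cfg_hash, st$digest), force = force || st$ran,
                 compute = function() build_score_table(cohort),
                 reader = function(p) tibble::as_tibble(
                   utils::read.csv(p, stringsAsFactors = FALSE)),
                 writer = write_full_csv)
  scores <- st$value; manifest <- record_stage(manifest, st)
  sig_ran <- st$ran

  ## stage: diagnosis ----------------------------------------------------------
  st <- stage_io(out_dir, old, "diagnosis",
                 inputs = c(cfg_hash, manifest$stages$cohort$output_digest),
                 force = force || manifest$stages$cohort$ran,
                 compute = function() run_diagnosis(cohort, threshold, min_tests),
                 reader = function(p) tibble::as_tibble(
                   utils::read.csv(p, stringsAsFactors = FALSE)),
                 writer = write_full_csv)
  diagnosis <- st$value; manifest <- record_stage(manifest, st)
  diag_ran <- st$ran

  status <- longitudinal_status(diagnosis, final_wave = config$waves)

  ## stage: concurrent ---------------------------------------------------------
  concurrent <- run_concurrent(cohort, scores, status, fdr_q)
  manifest$stages_run <- c(manifest$stages_run, "concurrent")

  ## stage: prediction ---------------------------------------------------------
  prediction <- run_prediction(cohort, scores, diagnosis, status, config,
                               n_boot = n_boot, seed = config$seed,
                               fdr_q = fdr_q)
  manifest$stages_run <- c(manifest$stages_run, "prediction")

  for (m in names(concurrent$models))
    if (concurrent$models[[m]]$degraded)
      manifest$warnings <- c(manifest$warnings,
                             paste("concurrent", m, "used independence fallback"))
  for (m in names(prediction$models))
    if (prediction$models[[m]]$degraded)
      manifest$warnings <- c(manifest$warnings,
                             paste("prediction model", m, "used plain logistic fallback"))

  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(concurrent = concurrent$table, wave_correlations = concurrent$correlations,
           prediction = prediction$report),
      file.path(out_dir, "reports.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    write_manifest(manifest, out_dir)
  }

  structure(list(cohort = cohort, scores = scores, diagnosis = diagnosis,
                 status = status, concurrent = concurrent,
                 prediction = prediction, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  cohort: %d subjects, %d rows; converters (latent): %d\n",
              length(unique(x$cohort$subject_id)), nrow(x$cohort),
              sum(x$cohort$true_group[!duplicated(x$cohort$subject_id)] == "converter")))
  cat("  concurrent group effects (FDR-flagged):\n")
  ct <- x$concurrent$table
  for (i in seq_len(nrow(ct)))
    cat(sprintf("    %-12s SMD %+0.3f, p = %.3g%s\n", ct$outcome[i],
                ct$smd[i], ct$p[i], if (ct$fdr_significant[i]) " *" else ""))
  cat("  predictive models:\n")
  print(as.data.frame(x$prediction$report), digits = 3, row.names = FALSE)
  invisible(x)
}

# Wide per subject-wave score table: both signatures plus PBAD-adjusted forms.
build_score_table <- function(cohort) {
  sc <- score_signatures(cohort, modality = "both")
  pb <- compute_pbad(cohort)
  adj <- pbad_adjust(sc, pb)
  key <- function(d) paste(d$subject_id, d$wave)
  tv <- sc[sc$modality == "thickness_volume", ]
  md <- sc[sc$modality == "md", ]
  tva <- adj[adj$modality == "thickness_volume", ]
  mda <- adj[adj$modality == "md", ]
  out <- tibble::tibble(subject_id = tv$subject_id, wave = tv$wave,
                        tv_signature = tv$score)
  out$md_signature <- md$score[match(key(out), key(md))]
  out$tv_pbad_adj <- tva$score[match(key(out), key(tva))]
  out$md_pbad_adj <- mda$score[match(key(out), key(mda))]
  out$pbad <- pb$pbad[match(key(out), key(pb))]
  out
}

run_diagnosis <- function(cohort, threshold, min_tests) {
  ts <- cohort_test_scores(cohort)
  ts <- gca_adjust(ts)
  ledger <- estimate_adjustments(ts)
  ts <- apply_adjustments(ts, ledger)
  diagnose_cohort(ts, threshold = threshold, min_tests = min_tests)
}

run_concurrent <- function(cohort, scores, status, fdr_q) {
  grp <- status$status[match(scores$subject_id, status$subject_id)]
  d <- scores
  d$group <- ifelse(grp == "robust_CN", "robust_CN",
                    ifelse(grp %in% c("MCI", "converter"), "MCI", NA))
  d$group <- factor(d$group, levels = c("robust_CN", "MCI"))
  d$pair_id <- cohort$pair_id[match(d$subject_id, cohort$subject_id)]
  d <- d[!is.na(d$group), ]
  outcomes <- c(tv = "tv_signature", md = "md_signature",
                tv_pbad = "tv_pbad_adj", md_pbad = "md_pbad_adj")
  models <- lapply(outcomes, function(oc) concurrent_analysis(d, outcome = oc))
  names(models) <- names(outcomes)
  tab <- do.call(rbind, lapply(names(models), function(nm) {
    fx <- models[[nm]]$fixed_effects
    gi <- grep("^group", fx$term)
    gi <- gi[!grepl(":", fx$term[gi])][1]
    tibble::tibble(outcome = nm, smd = models[[nm]]$smd,
                   t = fx$t[gi], df = fx$df[gi], p = fx$p[gi],
                   interaction_p = models[[nm]]$interaction_p)
  }))
  tab$fdr_significant <- fdr_bh(tab$p, q = fdr_q)
  corr <- wave_correlations(
    tibble::tibble(subject_id = scores$subject_id, wave = scores$wave,
                   score = scores$tv_signature),
    tibble::tibble(subject_id = scores$subject_id, wave = scores$wave,
                   score = scores$md_signature))
  list(models = models, table = tab, correlations = corr, data = d)
}

run_prediction <- function(cohort, scores, diagnosis, status, config,
                           n_boot, seed, fdr_q) {
  final_wave <- config$waves
  base <- cohort[cohort$wave == 1L, ]
  lab1 <- diagnosis$label[match(paste(base$subject_id, 1L),
                                paste(diagnosis$subject_id, diagnosis$wave))]
  st <- status$status[match(base$subject_id, status$subject_id)]
  sc1 <- scores[scores$wave == 1L, ]
  m <- match(base$subject_id, sc1$subject_id)
  d <- tibble::tibble(subject_id = base$subject_id, pair_id = base$pair_id,
                      age = base$age, prs = base$prs,
                      tv_signature = sc1$tv_signature[m],
                      md_signature = sc1$md_signature[m],
                      tv_pbad_adj = sc1$tv_pbad_adj[m],
                      md_pbad_adj = sc1$md_pbad_adj[m],
                      status = st, label_w1 = lab1)
  has_final <- base$subject_id %in%
    diagnosis$subject_id[diagnosis$wave == final_wave & !is.na(diagnosis$label)]
  d <- d[!is.na(d$label_w1) & d$label_w1 == "CN" & has_final &
           !is.na(d$status) & d$status != "excluded_reverter", ]
  d$converted <- as.integer(d$status == "converter")
  d <- d[stats::complete.cases(d[c("age", "prs", "tv_signature",
                                   "md_signature", "tv_pbad_adj",
                                   "md_pbad_adj")]), ]

  specs <- model_specs()
  models <- lapply(specs, function(pr)
    fit_risk_model(d, outcome = "converted", predictors = pr))
  rocs <- lapply(seq_along(models), function(i)
    roc_report(models[[i]]$fitted, models[[i]]$labels, n_boot = n_boot,
               seed = seed + i))
  names(rocs) <- names(specs)
  comparisons <- lapply(2:5, function(i)
    bootstrap_auc_compare(models[[i]]$fitted, models[[1]]$fitted,
                          d$converted, n_boot = n_boot, seed = seed + 100 + i))
  names(comparisons) <- paste0("model", 2:5, "_vs_model1")
  comp_p <- vapply(comparisons, function(x) x$p, numeric(1))
  comp_fdr <- fdr_bh(comp_p, q = fdr_q)

  report <- do.call(rbind, lapply(seq_along(specs), function(i) {
    r <- rocs[[i]]
    tibble::tibble(model = as.integer(names(specs)[i]),
                   predictors = paste(specs[[i]], collapse = "+"),
                   auc = r$auc, auc_lo = r$auc_ci[1], auc_hi = r$auc_ci[2],
                   sensitivity = r$sensitivity, specificity = r$specificity,
                   accuracy = r$accuracy, ppv = r$ppv, npv = r$npv,
                   p_vs_model1 = if (i == 1) NA_real_ else comp_p[i - 1],
                   fdr_significant = if (i == 1) NA else comp_fdr[i - 1])
  }))
  list(models = models, rocs = rocs, comparisons = comparisons,
       report = report, data = d)
}

## -- artifact/caching helpers ------------------------------------------------

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

write_full_csv <- function(x, path) {
  df <- as.data.frame(x)
  for (cl in names(df))
    if (is.double(df[[cl]])) df[[cl]] <- format(df[[cl]], digits = 17L,
                                                trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
}

read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(d)
}

read_manifest <- function(out_dir) {
  p <- file.path(out_dir, "manifest.json")
  if (!file.exists(p)) return(NULL)
  tryCatch(jsonlite::read_json(p, simplifyVector = TRUE),
           error = function(e) NULL)
}

write_manifest <- function(manifest, out_dir) {
  manifest$stages <- lapply(manifest$stages, function(s)
    s[c("inputs_digest", "file", "output_digest", "ran")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

# Execute one cacheable stage: reuse the on-disk artifact when the recorded
# input digest and the file's digest both match, otherwise compute and write.
stage_io <- function(out_dir, old_manifest, name, inputs, force, compute,
                     reader, writer) {
  inputs_digest <- hash_object(paste(inputs, collapse = "|"))
  if (is.null(out_dir)) {
    return(list(name = name, value = compute(), ran = TRUE,
                inputs_digest = inputs_digest, digest = NA_character_,
                file = NA_character_))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, paste0(name, ".csv"))
  rec <- old_manifest$stages[[name]]
  if (!force && !is.null(rec) && file.exists(path) &&
      identical(rec$inputs_digest, inputs_digest) &&
      identical(unname(tools::md5sum(path)), rec$output_digest)) {
    return(list(name = name, value = reader(path), ran = FALSE,
                inputs_digest = inputs_digest, digest = rec$output_digest,
                file = path))
  }
  value <- compute()
  writer(value, path)
  dg <- unname(tools::md5sum(path))
  list(name = name, value = value, ran = TRUE,
       inputs_digest = inputs_digest, digest = dg, file = path)
}

record_stage <- function(manifest, st) {
  manifest$stages[[st$name]] <- list(inputs_digest = st$inputs_digest,
                                     file = st$file, output_digest = st$digest,
                                     ran = st$ran)
  if (st$ran) manifest$stages_run <- c(manifest$stages_run, st$name)
  manifest
}
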