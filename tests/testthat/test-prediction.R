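test_that("roc_auc equals brute-force pairwise concordance, including ties", {
  # worked example: scores (0.1, 0.4, 0.35, 0.8), labels (0, 0, 1, 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(30)
  for (i in 1:40) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- if (i %% 2 == 0) round(runif(n), 1) else rnorm(n)  # force ties
    expect_equal(roc_auc(scores, labels), auc_brute(scores, labels),
                 info = paste("draw", i))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(31)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, 0.3)
  base <- roc_auc(scores, labels)
  expect_equal(roc_auc(plogis(scores), labels), base)
  expect_equal(roc_auc(exp(2 * scores) + 5, labels), base)
  expect_equal(roc_auc(rank(scores), labels), base)
})

test_that("youden_threshold equals the exhaustive scan with its tie-break", {
  set.seed(32)
  for (i in 1:40) {
    n <- sample(8:150, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- if (i %% 2 == 0) sample(seq(0, 1, 0.1), n, TRUE) else runif(n)
    got <- youden_threshold(scores, labels)
    want <- youden_brute(scores, labels)
    expect_equal(got$threshold, unname(want["thr"]), info = paste("draw", i))
    expect_equal(got$sensitivity, unname(want["sens"]))
    expect_equal(got$specificity, unname(want["spec"]))
    expect_equal(got$j, unname(want["j"]))
  }
  # a perfect separator picks the midpoint with sens = spec = 1
  yj <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(yj$j, 1)
  expect_equal(yj$threshold, 0.5)
})

test_that("confusion_metrics reconstructs counts from rates", {
  cm <- confusion_metrics(sens = 0.8, spec = 0.9, n_pos = 20, n_neg = 149)
  expect_equal(cm$tp, 16)
  expect_equal(cm$fn, 4)
  expect_equal(cm$tn, 134)
  expect_equal(cm$fp, 15)
  expect_equal(cm$accuracy, 150 / 169)
  expect_equal(cm$ppv, 16 / 31)
  expect_equal(cm$npv, 134 / 138)
  expect_error(confusion_metrics(1.2, 0.5, 10, 10), "sens")
})

test_that("risk models recover predictor effects with clustered data", {
  set.seed(33)
  n_pairs <- 400
  pair <- rep(seq_len(n_pairs), each = 2)
  pair_eff <- rnorm(n_pairs, 0, 0.7)[pair]
  x1 <- rnorm(2 * n_pairs)
  x2 <- rnorm(2 * n_pairs)
  eta <- -1.5 + 1.0 * x1 + 0 * x2 + pair_eff
  d <- tibble::tibble(converted = rbinom(2 * n_pairs, 1, plogis(eta)),
                      age = x1, prs = x2, pair_id = pair)
  m <- fit_risk_model(d, predictors = c("age", "prs"))
  expect_s3_class(m, "risk_model")
  cf <- m$coefficients
  expect_gt(cf$estimate[cf$term == "age"], 0.5)
  expect_lt(cf$p[cf$term == "age"], 1e-4)
  expect_gt(cf$p[cf$term == "prs"], 0.01)
  expect_equal(cf$or, exp(cf$estimate))
  expect_equal(cf$or_lo, exp(cf$estimate - qnorm(0.975) * cf$se))
  # fitted values are fixed-effects-only probabilities in (0, 1)
  expect_true(all(m$fitted > 0 & m$fitted < 1))
  expect_equal(length(m$fitted), nrow(d))
  expect_output(print(m), "OR")
})

test_that("model specs match the five predictor sets", {
  sp <- model_specs()
  expect_equal(names(sp), as.character(1:5))
  expect_equal(sp[["1"]], c("age", "prs"))
  expect_equal(sp[["4"]], c("age", "prs", "tv_signature", "md_signature"))
  expect_equal(sp[["5"]], c("age", "prs", "tv_pbad_adj", "md_pbad_adj"))
})

test_that("adding a predictor never lowers in-sample AUC of nested fits", {
  set.seed(34)
  n <- 300
  d <- tibble::tibble(converted = rbinom(n, 1, 0.3),
                      age = rnorm(n), prs = rnorm(n), noise = rnorm(n),
                      pair_id = seq_len(n))
  f1 <- glm(converted ~ age + prs, binomial, data = d)
  f2 <- glm(converted ~ age + prs + noise, binomial, data = d)
  expect_gte(roc_auc(fitted(f2), d$converted) + 1e-12,
             roc_auc(fitted(f1), d$converted))
})

test_that("roc_report's operating point is consistent with its own threshold", {
  set.seed(35)
  scores <- runif(120)
  labels <- rbinom(120, 1, plogis(3 * (scores - 0.5)))
  rep_ <- roc_report(scores, labels, n_boot = 200, seed = 4)
  pred <- scores >= rep_$threshold
  expect_equal(rep_$sensitivity, mean(pred[labels == 1]))
  expect_equal(rep_$specificity, mean(!pred[labels == 0]))
  expect_equal(rep_$tp + rep_$fn, sum(labels == 1))
  expect_equal(rep_$tn + rep_$fp, sum(labels == 0))
  expect_equal(rep_$accuracy, (rep_$tp + rep_$tn) / 120)
  expect_true(rep_$auc_ci[1] <= rep_$auc && rep_$auc <= rep_$auc_ci[2])
  expect_output(print(rep_), "AUC")
})

test_that("roc_auc agrees with pROC on shared inputs", {
  skip_if_not_installed("pROC")
  set.seed(36)
  scores <- c(rnorm(60), round(rnorm(40), 1))
  labels <- rbinom(100, 1, 0.45)
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(roc_auc(scores, labels), want, tolerance = 1e-12)
})

test_that("bootstrap AUC comparison is symmetric and deterministic", {
  set.seed(37)
  labels <- rbinom(150, 1, 0.35)
  a <- rnorm(150) + labels
  b <- rnorm(150) + 0.5 * labels
  r1 <- bootstrap_auc_compare(a, b, labels, n_boot = 400, seed = 8)
  r2 <- bootstrap_auc_compare(b, a, labels, n_boot = 400, seed = 8)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$diff, -r2$diff)
  r3 <- bootstrap_auc_compare(a, b, labels, n_boot = 400, seed = 8)
  expect_identical(r1, r3)
  # identical models compare as equal with p = 1
  same <- bootstrap_auc_compare(a, a, labels, n_boot = 400, seed = 8)
  expect_equal(same$p, 1)
  expect_equal(same$diff, 0)
  expect_warning(bootstrap_auc_compare(a, b, labels, n_boot = 50, seed = 8),
                 "100")
})

test_that("a separating model beats a random one decisively", {
  set.seed(38)
  hits <- vapply(1:20, function(s) {
    set.seed(300 + s)
    labels <- rbinom(200, 1, 0.3)
    good <- labels + rnorm(200, 0, 0.25)    # nearly separating
    rand <- rnorm(200)
    bootstrap_auc_compare(good, rand, labels, n_boot = 200,
                          seed = 500 + s)$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
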