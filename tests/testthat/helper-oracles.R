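# Brute-force reference implementations used as independent oracles.
# These are deliberately naive (loops, exhaustive scans) and share no code
# with the package internals they check.

# AUC as explicit pairwise concordance with 1/2 credit for ties.
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Youden scan over the same candidate set the package documents (midpoints
# plus infinities), re-derived with explicit counting and the documented
# tie-break toward the higher threshold.
youden_brute <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
  rows <- t(vapply(cand, function(thr) {
    sens <- mean(scores[labels == 1] >= thr)
    spec <- mean(scores[labels == 0] < thr)
    c(thr = thr, sens = sens, spec = spec, j = sens + spec - 1)
  }, numeric(4)))
  jmax <- max(rows[, "j"])
  hit <- rows[rows[, "j"] == jmax, , drop = FALSE]
  hit[which.max(hit[, "thr"]), ]
}

# Benjamini-Hochberg step-up by hand: largest i with p_(i) <= i*q/m rejects
# all hypotheses with p <= p_(i).
bh_brute <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  if (length(k) == 0) return(rep(FALSE, m))
  p <= ps[max(k)]
}

# Jak-Bondi re-count with explicit loops over domains and tests.
classify_brute <- function(z, domain, threshold = 1.5, min_tests = 2) {
  impaired <- character()
  indeterminate <- FALSE
  for (d in unique(domain)) {
    zz <- z[domain == d]
    zz <- zz[!is.na(zz)]
    if (length(zz) < min_tests) {
      indeterminate <- TRUE
    } else {
      hits <- 0
      for (v in zz) if (v < -threshold) hits <- hits + 1
      if (hits >= min_tests) impaired <- c(impaired, d)
    }
  }
  if (length(impaired) > 0) "MCI" else if (indeterminate) NA_character_ else "CN"
}

# Shared small cohort so structural tests don't regenerate repeatedly.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_config(seed = 42L, n_pairs = 120L))
    cache
  }
})
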