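#' Generate a voxel phantom with known grey-matter MD
#'
#' Builds a small 3-D MD array plus a grey-matter volume-fraction array with a
#' known ground truth, for validating the partial-volume and robust weighting
#' estimators. Contamination is confined to voxels whose grey-matter fraction
#' is at most 0.5: interior voxels are pure grey matter (fraction 1, MD equal
#' to `true_gm_md`), rim voxels mix grey matter with CSF (upper half of the
#' volume) or white matter (lower half) at fractions drawn in \[0, 0.5\]. Under
#' the default Tukey weighting (`t = 0.5`) every contaminated voxel receives
#' weight 0, so on a noise-free phantom the fraction-weighted estimator
#' recovers `true_gm_md` exactly while the unweighted mean is biased.
#'
#' @param seed Integer seed (rim fractions and noise are random).
#' @param shape Integer length-3 array dimensions; at most 64^3 voxels.
#' @param true_gm_md,true_wm_md,true_csf_md Tissue MD values (10^-3 mm^2/s).
#' @param fraction_field `"rim"` (default), `"uniform"` (fraction 1
#'   everywhere), `"zero"` (fraction 0 everywhere; every downstream weight is
#'   0), or a numeric array of fractions in \[0, 1\] with `shape` dimensions
#'   (voxel MD is then the fraction-weighted mix of grey matter and CSF).
#' @param rim_width Rim thickness in voxels for `"rim"`.
#' @param noise_sd SD of additive Gaussian noise on the MD array (default 0).
#' @return List with arrays `md` and `gm_fraction`, logical array `interior`
#'   (fraction == 1), and `truth` (list of the three tissue MD values).
#' @export
generate_md_phantom <- function(seed = 1L, shape = c(12L, 12L, 12L),
                                true_gm_md = 0.85, true_wm_md = 0.70,
                                true_csf_md = 3.0,
                                fraction_field = "rim",
                                rim_width = 2L, noise_sd = 0) {
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (prod(shape) > 64^3) stop("phantom too large; keep within 64^3 voxels")
  set.seed(seed)

  if (is.character(fraction_field)) {
    fraction_field <- match.arg(fraction_field, c("rim", "uniform", "zero"))
    frac <- array(1, dim = shape)
    if (fraction_field == "zero") frac[] <- 0
    if (fraction_field == "rim") {
      idx <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                         k = seq_len(shape[3]))
      edge_dist <- pmin(idx$i - 1L, shape[1] - idx$i,
                        idx$j - 1L, shape[2] - idx$j,
                        idx$k - 1L, shape[3] - idx$k)
      rim <- edge_dist < rim_width
      frac[array(rim, dim = shape)] <- runif(sum(rim), 0, 0.5)
    }
  } else {
    if (!identical(dim(fraction_field), as.integer(shape)) &&
        !identical(dim(fraction_field), shape))
      stop("fraction_field dimensions must match shape")
    if (any(fraction_field < 0 | fraction_field > 1))
      stop("fractions must lie in [0, 1]")
    frac <- fraction_field
  }

  # non-grey share mixes with CSF in the upper half of the volume and with
  # white matter in the lower half
  contaminant <- array(true_csf_md, dim = shape)
  k_half <- seq_len(shape[3]) <= shape[3] / 2
  contaminant[, , k_half] <- true_wm_md
  md <- frac * true_gm_md + (1 - frac) * contaminant
  if (noise_sd > 0) md <- md + rnorm(length(md), 0, noise_sd)
  md <- array(md, dim = shape)

  list(md = md, gm_fraction = frac, interior = frac == 1,
       truth = list(gm = true_gm_md, wm = true_wm_md, csf = true_csf_md))
}
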