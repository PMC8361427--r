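#' Mean diffusivity from diffusion tensor eigenvalues
#'
#' MD is the average diffusion over all directions, i.e. the mean of the three
#' tensor eigenvalues. Vectorized over voxels.
#'
#' @param l1,l2,l3 Numeric vectors of tensor eigenvalues (same units, e.g.
#'   10^-3 mm^2/s).
#' @return Numeric vector `(l1 + l2 + l3) / 3`.
#' @examples
#' md_from_eigenvalues(1.5, 1.0, 0.5)  # 1.0
#' @export
md_from_eigenvalues <- function(l1, l2, l3) {
  if (any(!is.finite(c(l1, l2, l3))))
    stop("eigenvalues must be finite")
  (l1 + l2 + l3) / 3
}

#' Tukey-bisquare partial-volume weight
#'
#' Weight given to a diffusion sample according to the grey-matter volume
#' fraction `v` of the voxel it falls in:
#' \deqn{w(v) = (1 - ((1 - v)/t)^2)^2 \quad \text{if } 1 - v < t, \text{ else } 0.}
#' With the default scaling factor `t = 0.5` any voxel with volume fraction
#' at or below 0.5 receives weight 0, and fractions above 0.5 map to weights
#' rising smoothly from 0 to `w(1) = 1`. This excludes or downweights samples
#' contaminated by CSF or white matter.
#'
#' @param v Numeric vector of grey-matter volume fractions in \[0, 1\].
#' @param t Tunable scaling factor in (0, 1\]; default 0.5.
#' @return Numeric vector of weights in \[0, 1\].
#' @examples
#' fraction_weight(c(0.5, 0.75, 1))  # 0, 0.5625, 1
#' @export
fraction_weight <- function(v, t = 0.5) {
  stopifnot(length(t) == 1L, is.finite(t), t > 0, t <= 1)
  if (any(!is.na(v) & (v < 0 | v > 1)))
    stop("volume fractions must lie in [0, 1]")
  u <- (1 - v) / t
  ifelse(u < 1, (1 - u^2)^2, 0)
}

#' Partial-volume-weighted cortical MD at one vertex
#'
#' Combines the 7 MD samples taken along the surface normal (0.8 to 2.0 mm in
#' 0.2 mm steps) into a single vertex estimate, weighting each sample by the
#' Tukey-bisquare weight of the grey-matter fraction of its voxel.
#'
#' @param md_samples Numeric vector of MD samples (>= 0).
#' @param gm_fractions Grey-matter volume fractions in \[0, 1\], same length.
#' @param t Scaling factor passed to [fraction_weight()].
#' @param n_samples Expected profile length (default 7); set to `NA` to accept
#'   any length.
#' @return The weighted MD estimate, or `NA_real_` if every sample has weight 0
#'   (flagged missing, not zero).
#' @examples
#' cortical_vertex_md(c(1, 1, 1, 1, 1, 1, 2), c(1, 1, 1, 1, 1, 1, 0.75))
#' @export
cortical_vertex_md <- function(md_samples, gm_fractions, t = 0.5,
                               n_samples = 7L) {
  if (length(md_samples) != length(gm_fractions))
    stop("md_samples and gm_fractions must have equal length")
  if (!is.na(n_samples) && length(md_samples) != n_samples)
    stop("expected ", n_samples, " profile samples")
  if (any(md_samples < 0, na.rm = TRUE))
    stop("MD samples must be non-negative")
  w <- fraction_weight(gm_fractions, t)
  w[is.na(md_samples)] <- 0
  sw <- sum(w)
  if (sw == 0) return(NA_real_)
  sum(w * md_samples, na.rm = TRUE) / sw
}

#' Robust subcortical ROI MD
#'
#' Suppresses CSF partial-volume contamination in a subcortical ROI by
#' downweighting voxels whose MD lies far from the ROI median, relative to a
#' typical dispersion (the median absolute deviation from the median, averaged
#' across subjects) multiplied by a fixed factor (default 4.7). Weights follow
#' Tukey's bisquare: `(1 - u^2)^2` for `|u| < 1`, else 0, with
#' `u = (md - median) / (mad_multiplier * roi_mad)`.
#'
#' @param md_values Numeric vector of voxel MD values within the ROI.
#' @param roi_mad Typical dispersion of the ROI (across-subject-averaged MAD);
#'   must be > 0.
#' @param mad_multiplier Dispersion scale factor; default 4.7.
#' @return Weight-normalized mean MD, or `NA_real_` if all weights vanish.
#' @examples
#' subcortical_roi_md(c(1, 1, 1, 5), roi_mad = 0.1)  # 1
#' @export
subcortical_roi_md <- function(md_values, roi_mad, mad_multiplier = 4.7) {
  stopifnot(length(roi_mad) == 1L, is.finite(roi_mad), roi_mad > 0,
            mad_multiplier > 0)
  md_values <- md_values[!is.na(md_values)]
  if (length(md_values) == 0L) stop("empty voxel set")
  u <- (md_values - stats::median(md_values)) / (mad_multiplier * roi_mad)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sw <- sum(w)
  if (sw == 0) return(NA_real_)
  sum(w * md_values) / sw
}

#' ROI MD estimate over a voxel phantom
#'
#' Applies either the partial-volume fraction weighting (cortical style) or the
#' median/MAD robust weighting (subcortical style) to the voxels of a phantom
#' selected by a logical mask. See [generate_md_phantom()] for phantoms with
#' known ground truth.
#'
#' @param phantom A list with arrays `md` and `gm_fraction` (as returned by
#'   [generate_md_phantom()]).
#' @param mask Logical array of the same dimension selecting ROI voxels.
#' @param method `"fraction"` (grey-matter fraction weighting) or `"robust"`
#'   (median/MAD bisquare weighting).
#' @param t Scaling factor for the fraction method.
#' @param roi_mad,mad_multiplier Dispersion parameters for the robust method.
#' @return The weighted ROI MD estimate (`NA_real_` when all weights are 0).
#' @export
phantom_roi_md <- function(phantom, mask, method = c("fraction", "robust"),
                           t = 0.5, roi_mad = NULL, mad_multiplier = 4.7) {
  method <- match.arg(method)
  stopifnot(is.list(phantom), !is.null(phantom$md))
  if (!identical(dim(mask), dim(phantom$md)))
    stop("mask dimensions must match the phantom")
  if (!any(mask)) stop("empty mask")
  md <- phantom$md[mask]
  if (method == "fraction") {
    v <- phantom$gm_fraction[mask]
    w <- fraction_weight(v, t)
    sw <- sum(w)
    if (sw == 0) return(NA_real_)
    sum(w * md) / sw
  } else {
    if (is.null(roi_mad)) stop("roi_mad is required for the robust method")
    subcortical_roi_md(md, roi_mad = roi_mad, mad_multiplier = mad_multiplier)
  }
}
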