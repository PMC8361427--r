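#' Published Alzheimer's disease signature ROI weights
#'
#' The signature is a weighted combination of eight bilateral regions of
#' interest: seven cortical regions measured by mean thickness (entorhinal,
#' middle temporal, banks of the superior temporal sulcus, superior temporal,
#' isthmus cingulate, lateral orbitofrontal, medial orbitofrontal) plus the
#' hippocampus measured by volume, with separate weights per hemisphere. The
#' same regions and weights are reused for the grey-matter mean-diffusivity
#' (MD) signature. Weights were derived in an independent case-control sample
#' and are treated here as fixed constants.
#'
#' @return A tibble with 16 rows and columns `region`, `hemi` (`"lh"`/`"rh"`)
#'   and `weight`.
#' @examples
#' w <- signature_weights()
#' sum(w$weight)  # 7.044
#' @export
signature_weights <- function() {
  tibble::tibble(
    region = rep(c("entorhinal", "middletemporal", "bankssts",
                   "superiortemporal", "isthmuscingulate",
                   "lateralorbitofrontal", "medialorbitofrontal",
                   "hippocampus"), each = 2L),
    hemi = rep(c("lh", "rh"), times = 8L),
    weight = c(0.626, 0.586,
               0.554, 0.496,
               0.444, 0.435,
               0.410, 0.322,
               0.377, 0.387,
               0.303, 0.245,
               0.263, 0.279,
               0.696, 0.621)
  )
}

# validate a user-supplied weight table against the expected shape
check_weight_table <- function(weights) {
  stopifnot(is.data.frame(weights),
            all(c("region", "hemi", "weight") %in% names(weights)))
  if (nrow(weights) != 16L)
    stop("weight table must have exactly 16 region x hemisphere rows")
  if (any(!is.finite(weights$weight)) || any(weights$weight <= 0))
    stop("weights must be positive and finite")
  if (anyDuplicated(paste(weights$region, weights$hemi)))
    stop("duplicated region/hemisphere entries in weight table")
  invisible(weights)
}
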