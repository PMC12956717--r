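#' Lung densitometry: LAV%, Perc15, MLD
#'
#' Computes the three parenchymal indices over the lung mask, on raw HU:
#' \itemize{
#'   \item LAV% = 100 x |lung voxels with HU < threshold| / |lung voxels|
#'   \item Perc15 = 15th percentile of the lung HU distribution
#'   \item MLD = mean HU over lung voxels
#' }
#' The percentile uses the lower order statistic at `ceiling(0.15 n)` (no
#' interpolation), fixed so results are exact and testable. The default LAA
#' threshold of -950 HU is the field standard for inspiratory HRCT; it is a
#' documented assumption, exposed as an argument.
#'
#' @param v `ct_volume`, raw HU.
#' @param lung `label_mask` aligned to `v` (any non-zero label counts).
#' @param laa_threshold HU cutoff defining low-attenuation voxels.
#' @return `lung_metrics` list: `lav_percent`, `perc15`, `mld`,
#'   `laa_threshold`, `n_lung_voxels`. An empty mask yields `NA` metrics with
#'   `flag = "empty_mask"` (never zeros).
#' @export
lung_metrics <- function(v, lung, laa_threshold = -950) {
  stopifnot(inherits(v, "ct_volume"), inherits(lung, "label_mask"))
  check_aligned(v, lung)
  sel <- mask_logical(lung)
  n <- sum(sel)
  if (n == 0L) {
    return(structure(list(lav_percent = NA_real_, perc15 = NA_real_,
                          mld = NA_real_, laa_threshold = laa_threshold,
                          n_lung_voxels = 0L, flag = "empty_mask"),
                     class = "lung_metrics"))
  }
  hu <- v$data[sel]
  structure(list(
    lav_percent = 100 * sum(hu < laa_threshold) / n,
    perc15 = percentile_lower(hu, 0.15),
    mld = mean(hu),
    laa_threshold = laa_threshold,
    n_lung_voxels = n,
    flag = NULL), class = "lung_metrics")
}

#' Lower-order-statistic percentile
#'
#' Order statistic at `ceiling(p * n)` of the sorted sample - the exact,
#' interpolation-free convention used for Perc15.
#'
#' @param x numeric sample.
#' @param p probability in (0, 1].
#' @return the order statistic.
#' @export
percentile_lower <- function(x, p) {
  n <- length(x)
  if (n == 0L) stop("empty sample")
  sort(x, method = "quick")[max(1L, ceiling(p * n))]
}

#' @export
print.lung_metrics <- function(x, ...) {
  if (!is.null(x$flag)) {
    cat("<lung_metrics> flagged:", x$flag, "\n")
  } else {
    cat(sprintf("<lung_metrics> LAV%% %.2f | Perc15 %.1f HU | MLD %.1f HU (n=%d, LAA<%g HU)\n",
                x$lav_percent, x$perc15, x$mld, x$n_lung_voxels, x$laa_threshold))
  }
  invisible(x)
}
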