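#' Agatston coronary calcium score
#'
#' Classic Agatston protocol: per axial slice, 8-connected components of
#' `{HU >= hu_threshold}` within the search region; lesions below
#' `min_area_mm2` are dropped; each lesion scores
#' `area(mm^2) x weight(peak HU) x (slice spacing / 3 mm)` with the density
#' weights 130-199 -> 1, 200-299 -> 2, 300-399 -> 3, >= 400 -> 4.
#' The slice-spacing factor adapts the 3 mm-slice protocol to thin-slice
#' acquisitions; disable with `normalize_slice = FALSE`.
#'
#' Must be run on the raw HU volume: a volume clamped at 400 HU makes the
#' top density class unreachable (a warning is raised when the data look
#' clamped).
#'
#' @param v `ct_volume`, raw HU.
#' @param roi `label_mask` marking the coronary search region.
#' @param hu_threshold calcium threshold, default 130 HU.
#' @param min_area_mm2 minimum lesion area, default 1.
#' @param normalize_slice apply the `spacing/3` factor (default `TRUE`).
#' @return `agatston_result` list: `cacs` and `lesion_table` (data.frame
#'   `slice`, `area_mm2`, `peak_hu`, `weight`, `score`).
#' @export
agatston_score <- function(v, roi, hu_threshold = 130, min_area_mm2 = 1,
                           normalize_slice = TRUE) {
  stopifnot(inherits(v, "ct_volume"), inherits(roi, "label_mask"))
  check_aligned(v, roi)
  sel <- mask_logical(roi)
  if (max(v$data[sel]) >= 395 && max(v$data[sel]) <= 400 && all(v$data <= 400))
    warning("volume appears truncated at 400 HU; Agatston density class 4 unreachable")
  pix_area <- v$spacing[1] * v$spacing[2]
  slice_factor <- if (normalize_slice) v$spacing[3] / 3 else 1
  rows <- list()
  for (z in seq_len(dim(v$data)[3])) {
    cand <- (v$data[, , z] >= hu_threshold) & sel[, , z]
    if (!any(cand)) next
    lab <- label2d_cpp(cand, TRUE)
    for (id in seq_len(max(lab))) {
      inles <- lab == id
      area <- sum(inles) * pix_area
      if (area < min_area_mm2) next
      peak <- max(v$data[, , z][inles])
      w <- agatston_weight(peak)
      rows[[length(rows) + 1L]] <- data.frame(
        slice = z, area_mm2 = area, peak_hu = peak, weight = w,
        score = area * w * slice_factor)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice = integer(), area_mm2 = numeric(), peak_hu = numeric(),
               weight = integer(), score = numeric())
  structure(list(cacs = sum(tab$score), lesion_table = tab),
            class = "agatston_result")
}

#' Agatston density weight for a peak HU
#' @param peak_hu lesion peak attenuation (HU), `>= 130`.
#' @return integer weight 1-4.
#' @export
agatston_weight <- function(peak_hu) {
  stopifnot(all(peak_hu >= 130))
  1L + findInterval(peak_hu, c(200, 300, 400))
}

#' Left-ventricular mass from a myocardium mask
#'
#' `mass = voxel count x voxel volume (mL) x density`, with the standard
#' myocardial density 1.05 g/mL.
#'
#' @param myocardium binary `label_mask`.
#' @param density_g_ml g/mL, default 1.05.
#' @return mass in grams; an empty mask returns 0 with attribute
#'   `flag = "empty_mask"` and a warning.
#' @export
lv_mass <- function(myocardium, density_g_ml = 1.05) {
  stopifnot(inherits(myocardium, "label_mask"))
  n <- sum(mask_logical(myocardium))
  if (n == 0L) {
    warning("empty myocardium mask; mass reported as 0")
    return(structure(0, flag = "empty_mask"))
  }
  n * voxel_volume(myocardium) / 1000 * density_g_ml
}

#' Left-ventricular volumes and ejection fraction
#'
#' Two-phase voxel summation: `edv`/`esv` from the end-diastolic and
#' end-systolic blood-pool masks, `sv = edv - esv`, `ef = 100 sv / edv`.
#'
#' @param blood_ed,blood_es binary `label_mask`s of the LV blood pool at ED
#'   and ES; both non-empty, with `|ED| > |ES|`.
#' @return `lv_function` list: `edv_ml`, `esv_ml`, `sv_ml`, `ef_percent`.
#' @export
lv_function <- function(blood_ed, blood_es) {
  stopifnot(inherits(blood_ed, "label_mask"), inherits(blood_es, "label_mask"))
  if (max(abs(blood_ed$spacing - blood_es$spacing)) > 1e-9)
    stop("ED and ES masks have different spacing")
  ned <- sum(mask_logical(blood_ed))
  nes <- sum(mask_logical(blood_es))
  if (ned == 0L || nes == 0L) stop("empty blood-pool mask")
  edv <- ned * voxel_volume(blood_ed) / 1000
  esv <- nes * voxel_volume(blood_es) / 1000
  if (esv >= edv)
    stop("inconsistent phases: ESV (", esv, " mL) >= EDV (", edv, " mL)")
  structure(list(edv_ml = edv, esv_ml = esv, sv_ml = edv - esv,
                 ef_percent = 100 * (edv - esv) / edv),
            class = "lv_function")
}

#' Full cardiac metric set
#'
#' @param v raw-HU `ct_volume` (for Agatston).
#' @param roi coronary search `label_mask`.
#' @param myocardium,blood_ed,blood_es see [lv_mass()] and [lv_function()].
#' @param ... passed to [agatston_score()].
#' @return `cardiac_metrics` list: `cacs`, `lesion_table`, `lvm_g`,
#'   `edv_ml`, `esv_ml`, `sv_ml`, `ef_percent`.
#' @export
cardiac_metrics <- function(v, roi, myocardium, blood_ed, blood_es, ...) {
  ag <- agatston_score(v, roi, ...)
  lf <- lv_function(blood_ed, blood_es)
  structure(c(list(cacs = ag$cacs, lesion_table = ag$lesion_table,
                   lvm_g = as.numeric(lv_mass(myocardium))), unclass(lf)),
            class = "cardiac_metrics")
}
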