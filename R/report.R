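#' Biomarker report
#'
#' The 11 quantified indices with units. Metrics not computed are `NA`
#' ("explicitly marked absent"), never silently zero.
#'
#' @param lav_percent,perc15_hu,mld_hu lung densitometry: low-attenuation
#'   volume %, 15th percentile HU, mean lung density HU.
#' @param wa_percent,pi10_mm airway wall area % and Pi10 (mm).
#' @param bv5_percent,fractal_dimension vessel small-vessel volume share %
#'   and box-counting dimension.
#' @param cacs,lvm_g,ef_percent,sv_ml cardiac: Agatston units, LV mass (g),
#'   ejection fraction %, stroke volume (mL).
#' @param provenance optional list (seed, config, versions) stored verbatim.
#' @return a `biomarker_report`.
#' @export
biomarker_report <- function(lav_percent = NA_real_, perc15_hu = NA_real_,
                             mld_hu = NA_real_, wa_percent = NA_real_,
                             pi10_mm = NA_real_, bv5_percent = NA_real_,
                             fractal_dimension = NA_real_, cacs = NA_real_,
                             lvm_g = NA_real_, ef_percent = NA_real_,
                             sv_ml = NA_real_, provenance = NULL) {
  structure(list(
    lav_percent = lav_percent, perc15_hu = perc15_hu, mld_hu = mld_hu,
    wa_percent = wa_percent, pi10_mm = pi10_mm,
    bv5_percent = bv5_percent, fractal_dimension = fractal_dimension,
    cacs = cacs, lvm_g = lvm_g, ef_percent = ef_percent, sv_ml = sv_ml,
    provenance = provenance), class = "biomarker_report")
}

report_units <- c(
  lav_percent = "%", perc15_hu = "HU", mld_hu = "HU", wa_percent = "%",
  pi10_mm = "mm", bv5_percent = "%", fractal_dimension = "",
  cacs = "AU", lvm_g = "g", ef_percent = "%", sv_ml = "mL")

#' Write a biomarker report to JSON and CSV
#'
#' JSON keys are the metric names of [biomarker_report()]; absent metrics
#' serialize as `null`. A CSV with columns `metric,value,unit` is written
#' next to the JSON when `csv = TRUE`.
#'
#' @param report a `biomarker_report`.
#' @param path output JSON path.
#' @param csv also write `<path without .json>.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv = TRUE) {
  stopifnot(inherits(report, "biomarker_report"))
  out <- report[names(report_units)]
  out$provenance <- report$provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  if (csv) {
    tab <- data.frame(metric = names(report_units),
                      value = unlist(report[names(report_units)], use.names = FALSE),
                      unit = unname(report_units))
    utils::write.csv(tab, sub("\\.json$", ".csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Read a biomarker report written by [write_report()]
#' @param path JSON path.
#' @return a `biomarker_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  do.call(biomarker_report, c(lapply(x[names(report_units)], num),
                              list(provenance = x$provenance)))
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat("<biomarker_report>\n")
  for (k in names(report_units)) {
    v <- x[[k]]
    cat(sprintf("  %-18s %s %s\n", k,
                if (is.na(v)) "absent" else format(v, digits = 6),
                report_units[[k]]))
  }
  invisible(x)
}
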