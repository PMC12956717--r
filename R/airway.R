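#' Airway measurement configuration
#'
#' @param n_rays rays cast in the measurement plane (default 64).
#' @param step_mm sampling step along each ray (default 0.1 mm, sub-voxel
#'   linear interpolation).
#' @param max_radius_mm search range per ray (default 15 mm).
#' @param min_wall_contrast_hu minimum rise from lumen to wall peak for a ray
#'   to count (default 100 HU).
#' @param lumen_max_hu precondition: the centre sample must be below this HU
#'   to be considered inside an air-filled lumen (default -900).
#' @param max_failed_fraction measurement rejected when more than this
#'   fraction of rays finds no wall (default 0.25).
#' @return an `airway_config`.
#' @export
airway_config <- function(n_rays = 64, step_mm = 0.1, max_radius_mm = 15,
                          min_wall_contrast_hu = 100, lumen_max_hu = -900,
                          max_failed_fraction = 0.25) {
  structure(as.list(environment()), class = "airway_config")
}

#' Measure one airway cross-section by FWHM ray casting
#'
#' Casts `n_rays` equally spaced rays in the plane normal to `axis` through
#' `center`. Along each ray the inner wall edge is localized at the
#' half-rise between the lumen HU and the peak wall HU, and the outer edge at
#' the half-fall from the peak toward the parenchymal level beyond the wall
#' (full-width-half-maximum rule, sub-voxel by linear interpolation). Radii
#' are averaged over rays and areas follow the circular model
#' `LA = pi r_l^2`, `WA = pi (r_o^2 - r_l^2)`, `Pi = 2 pi r_l`.
#'
#' @param v raw-HU `ct_volume`.
#' @param center length-3 physical point (mm; voxel `(1,1,1)` centre is
#'   `(0,0,0)`), inside the lumen.
#' @param axis length-3 local centreline direction (mm space).
#' @param cfg an [airway_config()].
#' @return `airway_measurement` list: `lumen_radius`, `lumen_diameter`,
#'   `wall_thickness` (mm), `lumen_area`, `wall_area` (mm^2),
#'   `internal_perimeter` (mm), `wa_percent`, `wa_la_ratio`, `n_rays_used`.
#' @export
measure_cross_section <- function(v, center, axis, cfg = airway_config()) {
  stopifnot(inherits(v, "ct_volume"), inherits(cfg, "airway_config"))
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal in-plane basis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  w <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])

  to_vox <- function(p) 1 + p / v$spacing           # physical mm -> voxel coords
  hu0 <- interp3(v$data, matrix(to_vox(center), 1))
  if (is.na(hu0) || hu0 > cfg$lumen_max_hu)
    stop("center is not inside an air-filled lumen (HU ",
         round(hu0), " > ", cfg$lumen_max_hu, ")")

  t <- seq(0, cfg$max_radius_mm, by = cfg$step_mm)
  angles <- 2 * pi * (seq_len(cfg$n_rays) - 1) / cfg$n_rays
  r_in <- r_out <- rep(NA_real_, cfg$n_rays)
  for (i in seq_along(angles)) {
    dirv <- cos(angles[i]) * u + sin(angles[i]) * w
    pts <- t(center + outer(dirv, t))
    pts <- sweep(pts, 2, v$spacing, "/") + 1
    hu <- interp3(v$data, pts)
    hu <- hu[!is.na(hu)]
    if (length(hu) < 5) next
    ipk <- which.max(hu)
    peak <- hu[ipk]
    if (ipk == 1 || peak - hu0 < cfg$min_wall_contrast_hu) next
    # inner edge: first crossing of the lumen/peak half level before the peak
    half_in <- (hu0 + peak) / 2
    pre <- hu[1:ipk]
    k <- which(pre[-1] >= half_in & pre[-length(pre)] < half_in)
    if (!length(k)) next
    k <- k[length(k)]                               # crossing adjacent to the wall
    frac <- (half_in - pre[k]) / (pre[k + 1] - pre[k])
    r_in[i] <- (k - 1 + frac) * cfg$step_mm
    # outer edge: half-fall from peak toward the parenchymal level beyond
    post <- hu[ipk:length(hu)]
    parench <- stats::median(post[max(1, length(post) - 9):length(post)])
    half_out <- (peak + parench) / 2
    k2 <- which(post[-length(post)] > half_out & post[-1] <= half_out)
    if (!length(k2)) next
    k2 <- k2[1]
    frac2 <- (post[k2] - half_out) / (post[k2] - post[k2 + 1])
    r_out[i] <- (ipk - 1 + k2 - 1 + frac2) * cfg$step_mm
  }
  ok <- !is.na(r_in) & !is.na(r_out) & r_out > r_in
  if (mean(!ok) > cfg$max_failed_fraction)
    stop("measurement rejected: no wall found on ",
         round(100 * mean(!ok)), "% of rays")
  airway_measurement(mean(r_in[ok]), mean(r_out[ok]) - mean(r_in[ok]),
                     n_rays_used = sum(ok))
}

#' Assemble an airway measurement from lumen radius and wall thickness
#'
#' Circular-model bookkeeping shared by the HU-based and mask-based paths.
#'
#' @param lumen_radius mm, `> 0`.
#' @param wall_thickness mm, `> 0`.
#' @param n_rays_used rays contributing (HU path) or `NA`.
#' @return an `airway_measurement`.
#' @export
airway_measurement <- function(lumen_radius, wall_thickness, n_rays_used = NA_integer_) {
  stopifnot(lumen_radius > 0, wall_thickness > 0)
  r_o <- lumen_radius + wall_thickness
  la <- pi * lumen_radius^2
  wa <- pi * (r_o^2 - lumen_radius^2)
  structure(list(
    lumen_radius = lumen_radius, lumen_diameter = 2 * lumen_radius,
    wall_thickness = wall_thickness, lumen_area = la, wall_area = wa,
    internal_perimeter = 2 * pi * lumen_radius,
    wa_percent = 100 * wa / (wa + la), wa_la_ratio = wa / la,
    n_rays_used = n_rays_used), class = "airway_measurement")
}

#' Measure an axis-aligned airway cross-section from truth masks
#'
#' Voxel-counting path: lumen/wall areas are exact voxel counts times the
#' in-plane pixel area on one axial slice of a z-aligned airway; radii are
#' back-derived from the circular model. Used to cross-check the FWHM path.
#'
#' @param lumen,wall binary `label_mask`s.
#' @param slice axial slice index.
#' @return an `airway_measurement` whose `lumen_area`/`wall_area` are the
#'   exact voxel-count areas (the derived radii are circular-model
#'   equivalents).
#' @export
measure_cross_section_mask <- function(lumen, wall, slice) {
  stopifnot(inherits(lumen, "label_mask"), inherits(wall, "label_mask"))
  pix <- lumen$spacing[1] * lumen$spacing[2]
  la <- sum(mask_logical(lumen)[, , slice]) * pix
  wa <- sum(mask_logical(wall)[, , slice]) * pix
  if (la <= 0 || wa <= 0) stop("slice does not intersect the airway")
  r_l <- sqrt(la / pi)
  r_o <- sqrt((la + wa) / pi)
  m <- airway_measurement(r_l, r_o - r_l)
  m$lumen_area <- la          # keep the exact counts, not the circular fit
  m$wall_area <- wa
  m$wa_percent <- 100 * wa / (wa + la)
  m$wa_la_ratio <- wa / la
  m
}

#' Pi10: airway-wall summary regression
#'
#' Ordinary least squares of `sqrt(WA)` on the internal perimeter Pi across
#' airways; Pi10 is the fitted `sqrt(WA)` at Pi = 10 mm - the standard
#' airway-remodelling summary.
#'
#' @param measurements list of `airway_measurement` objects (>= 2 with
#'   distinct internal perimeters).
#' @return `pi10_result` list: `pi10` (mm), `slope`, `intercept`,
#'   `n_airways`, `r_squared`.
#' @export
pi10_regression <- function(measurements) {
  if (length(measurements) < 2L) stop("insufficient airways: need >= 2")
  stopifnot(all(vapply(measurements, inherits, logical(1), "airway_measurement")))
  pi_mm <- vapply(measurements, `[[`, numeric(1), "internal_perimeter")
  sqrt_wa <- sqrt(vapply(measurements, `[[`, numeric(1), "wall_area"))
  if (length(unique(pi_mm)) < 2L)
    stop("degenerate fit: all internal perimeters identical")
  fit <- stats::lm(sqrt_wa ~ pi_mm)
  co <- stats::coef(fit)
  sst <- sum((sqrt_wa - mean(sqrt_wa))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(pi10 = unname(co[1] + co[2] * 10),
                 slope = unname(co[2]), intercept = unname(co[1]),
                 n_airways = length(measurements), r_squared = r2),
            class = "pi10_result")
}
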