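#' Synthetic thorax phantom specification
#'
#' Declares the geometry and attenuation of a seeded synthetic thorax CT:
#' soft-tissue body, two aerated lungs with low-attenuation emphysema
#' pockets, z-aligned airway tubes with distinct lumen/wall densities,
#' vessel cylinders (or a branching tree via [vessel_tree()]), a two-phase
#' left-ventricular blood pool with a myocardial shell, and calcified
#' plaques. Identical spec + seed gives a voxel-identical phantom.
#'
#' All centres are fractional 1-based voxel coordinates; radii, thicknesses
#' and lengths are mm. Components set to `NULL` are omitted, so targeted
#' single-structure phantoms (one airway tube, a cylinder pair) are specs
#' too.
#'
#' @param shape grid size `(nx, ny, nz)` in voxels.
#' @param spacing voxel spacing `(dx, dy, dz)` mm.
#' @param lung_hu,emphysema_hu,soft_tissue_hu,air_hu region attenuations
#'   (defaults -850, -980, 40, -1000 HU).
#' @param emphysema_fraction target fraction of lung voxels converted to
#'   emphysema pockets, in `[0, 1]`; hit exactly in voxel counts.
#' @param lungs list of ellipsoids `list(center, semi_mm)`; `"auto"` places
#'   two lungs scaled to the grid.
#' @param airways list of `list(center_xy, z_range, lumen_radius,
#'   wall_thickness, wall_hu)`; `"auto"` puts one tube per lung.
#' @param vessels list of cylinders `list(p0, p1, radius)` (voxel-coordinate
#'   endpoints, mm radius); `"auto"` places three z-cylinders per lung
#'   (radii 2.5, 1, 1 mm).
#' @param vessel_hu vessel attenuation, default 30 HU.
#' @param lv `list(edv_ml, esv_ml, myo_thickness_mm, blood_hu, myo_hu,
#'   center, axis_ratio_z)` or `"auto"` (EDV 120 mL, ESV 48 mL, 8 mm wall,
#'   contrast blood 300 HU, myocardium 80 HU, prolate 1:1:2).
#' @param plaques list of `list(slice, center_xy, area_mm2, peak_hu)`;
#'   `"auto"` paints three plaques of 4/9/1 mm^2 at 250/450/150 HU.
#' @param emphysema_pockets number of seeded pocket centres, default 12.
#' @param noise_sd additive Gaussian noise SD in HU (0 = noiseless).
#' @param seed integer seed driving pocket placement and noise.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 128), spacing = c(1, 1, 1),
                         lung_hu = -850, emphysema_hu = -980,
                         emphysema_fraction = 0.30, soft_tissue_hu = 40,
                         air_hu = -1000, lungs = "auto", airways = "auto",
                         vessels = "auto", vessel_hu = 30, lv = "auto",
                         plaques = "auto", emphysema_pockets = 12,
                         noise_sd = 0, seed = 1) {
  if (emphysema_fraction < 0 || emphysema_fraction > 1)
    stop("emphysema_fraction must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  d <- shape
  ctr <- (d + 1) / 2
  if (identical(lungs, "auto"))
    lungs <- list(
      list(center = c(0.27 * d[1], ctr[2], ctr[3]),
           semi_mm = c(0.17 * d[1], 0.31 * d[2], 0.36 * d[3]) * spacing),
      list(center = c(0.73 * d[1], ctr[2], ctr[3]),
           semi_mm = c(0.17 * d[1], 0.31 * d[2], 0.36 * d[3]) * spacing))
  if (identical(airways, "auto"))
    airways <- lapply(lungs, function(L)
      list(center_xy = round(c(L$center[1], 0.38 * d[2])),
           z_range = round(c(0.25, 0.75) * d[3]),
           lumen_radius = 2, wall_thickness = 1, wall_hu = -100))
  if (identical(vessels, "auto"))
    vessels <- do.call(c, lapply(lungs, function(L) {
      xc <- L$center[1]; yc <- L$center[2]
      sx <- if (xc < ctr[1]) -1 else 1        # lateral offset away from the heart
      zr <- round(c(0.25, 0.78) * d[3])
      list(list(p0 = c(xc, yc - 0.19 * d[2], zr[1]),
                p1 = c(xc, yc - 0.19 * d[2], zr[2]), radius = 2.5),
           list(p0 = c(xc, yc + 0.19 * d[2], zr[1]),
                p1 = c(xc, yc + 0.19 * d[2], zr[2]), radius = 1),
           list(p0 = c(xc + sx * 0.078 * d[1], yc, zr[1]),
                p1 = c(xc + sx * 0.078 * d[1], yc, zr[2]), radius = 1))
    }))
  if (identical(lv, "auto"))
    lv <- list(edv_ml = 120, esv_ml = 48, myo_thickness_mm = 8,
               blood_hu = 300, myo_hu = 80,
               center = c(ctr[1], 0.55 * d[2], ctr[3]),
               axis_ratio_z = 2)
  if (identical(plaques, "auto"))
    plaques <- list(
      list(slice = round(0.23 * d[3]), center_xy = c(ctr[1] - 6, 0.16 * d[2]),
           area_mm2 = 4, peak_hu = 250),
      list(slice = round(0.27 * d[3]), center_xy = c(ctr[1], 0.16 * d[2]),
           area_mm2 = 9, peak_hu = 450),
      list(slice = round(0.31 * d[3]), center_xy = c(ctr[1] + 6, 0.16 * d[2]),
           area_mm2 = 1, peak_hu = 150))
  if (!is.null(lv)) {
    if (lv$esv_ml >= lv$edv_ml) stop("esv_target must be < edv_target")
    if (lv$myo_thickness_mm <= 0) stop("myocardial thickness must be > 0")
  }
  for (a in airways %||% list())
    if (a$lumen_radius <= 0 || a$wall_thickness <= 0)
      stop("airway radii/thicknesses must be > 0")
  for (vs in vessels %||% list())
    if (vs$radius <= 0) stop("vessel radii must be > 0")
  structure(list(shape = shape, spacing = spacing, lung_hu = lung_hu,
                 emphysema_hu = emphysema_hu,
                 emphysema_fraction = emphysema_fraction,
                 soft_tissue_hu = soft_tissue_hu, air_hu = air_hu,
                 lungs = lungs, airways = airways, vessels = vessels,
                 vessel_hu = vessel_hu, lv = lv, plaques = plaques,
                 emphysema_pockets = emphysema_pockets,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recursive branching vessel tree
#'
#' Deterministic binary tree of tapering cylinders: each branch splits into
#' two children rotated by `+/-branch_angle_deg` (alternating the rotation
#' plane per generation), with radius scaled by `taper` and length by
#' `length_taper`.
#'
#' @param root length-3 voxel-coordinate start point.
#' @param direction initial axis (any norm).
#' @param length_mm root branch length.
#' @param radius_mm root radius.
#' @param depth generations (1 = root only).
#' @param taper radius ratio per generation, default 0.7.
#' @param length_taper length ratio per generation, default 0.8.
#' @param branch_angle_deg half-angle between children, default 35.
#' @return list of cylinders `list(p0, p1, radius)` usable as the `vessels`
#'   field of [phantom_spec()].
#' @export
vessel_tree <- function(root, direction = c(0, 0, 1), length_mm = 40,
                        radius_mm = 3, depth = 4, taper = 0.7,
                        length_taper = 0.8, branch_angle_deg = 35) {
  stopifnot(depth >= 1, radius_mm > 0)
  dirn <- direction / sqrt(sum(direction^2))
  segs <- list()
  grow <- function(p0, dirn, len, rad, lvl) {
    p1 <- p0 + dirn * len
    segs[[length(segs) + 1L]] <<- list(p0 = p0, p1 = p1, radius = rad)
    if (lvl >= depth) return(invisible())
    # rotation plane alternates with generation for a 3D spread
    ref <- if (lvl %% 2 == 0) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * dirn) * dirn
    if (sqrt(sum(u^2)) < 1e-6) u <- c(0, 1, 0) - sum(c(0, 1, 0) * dirn) * dirn
    u <- u / sqrt(sum(u^2))
    th <- branch_angle_deg * pi / 180
    for (s in c(-1, 1)) {
      child <- cos(th) * dirn + s * sin(th) * u
      grow(p1, child / sqrt(sum(child^2)), len * length_taper,
           rad * taper, lvl + 1)
    }
  }
  grow(root, dirn, length_mm, radius_mm, 1)
  segs
}

# coordinate arrays (1-based voxel indices) for a grid
grid_coords <- function(d) {
  list(x = slice.index(array(0L, d), 1),
       y = slice.index(array(0L, d), 2),
       z = slice.index(array(0L, d), 3))
}

check_fits <- function(what, lo, hi, d) {
  if (any(lo < 1) || any(hi > d))
    stop("structure does not fit the grid: ", what,
         " (extent ", paste(round(lo, 1), collapse = ","), " .. ",
         paste(round(hi, 1), collapse = ","), ")")
}

# fractional in-plane disc coverage of each pixel footprint (supersampled)
disc_coverage <- function(xs, ys, cx, cy, spacing, r_in, r_out, nsub = 5) {
  off <- (seq_len(nsub) - (nsub + 1) / 2) / nsub
  rin2 <- if (r_in <= 0) -Inf else r_in^2
  cov <- matrix(0, length(xs), length(ys))
  for (ox in off) for (oy in off) {
    rho2 <- outer(((xs + ox - cx) * spacing[1])^2,
                  ((ys + oy - cy) * spacing[2])^2, "+")
    cov <- cov + (rho2 > rin2 & rho2 <= r_out^2)
  }
  cov / nsub^2
}

# paint one z-aligned airway (anti-aliased HU, binary centre-inclusion masks)
paint_airway <- function(vol, aw, spacing, air_hu) {
  d <- dim(vol)
  rl <- aw$lumen_radius; ro <- rl + aw$wall_thickness
  cx <- aw$center_xy[1]; cy <- aw$center_xy[2]
  margin <- ro / spacing[1:2] + 1
  check_fits("airway", c(cx - margin[1], cy - margin[2], aw$z_range[1]),
             c(cx + margin[1], cy + margin[2], aw$z_range[2]), d)
  xs <- floor(cx - margin[1]):ceiling(cx + margin[1])
  ys <- floor(cy - margin[2]):ceiling(cy + margin[2])
  cov_l <- disc_coverage(xs, ys, cx, cy, spacing, -1, rl)
  cov_w <- disc_coverage(xs, ys, cx, cy, spacing, rl, ro)
  zs <- aw$z_range[1]:aw$z_range[2]
  sub <- vol[xs, ys, zs, drop = FALSE]
  blend <- function(old, l, w) l * air_hu + w * aw$wall_hu + (1 - l - w) * old
  for (k in seq_along(zs))
    sub[, , k] <- blend(sub[, , k], cov_l, cov_w)
  vol[xs, ys, zs] <- sub
  rho2 <- outer(((xs - cx) * spacing[1])^2, ((ys - cy) * spacing[2])^2, "+")
  lum2d <- rho2 <= rl^2
  wal2d <- rho2 > rl^2 & rho2 <= ro^2
  lumen <- wall <- array(FALSE, d)
  lumen[xs, ys, zs] <- array(lum2d, c(length(xs), length(ys), length(zs)))
  wall[xs, ys, zs] <- array(wal2d, c(length(xs), length(ys), length(zs)))
  list(vol = vol, lumen = lumen, wall = wall)
}

# voxels within radius of segment p0-p1 (voxel coords; radius mm)
paint_cylinder <- function(d, spacing, p0, p1, radius, what = "vessel") {
  lo <- pmin(p0, p1) - radius / spacing
  hi <- pmax(p0, p1) + radius / spacing
  check_fits(what, lo, hi, d)
  xs <- max(1, floor(lo[1])):min(d[1], ceiling(hi[1]))
  ys <- max(1, floor(lo[2])):min(d[2], ceiling(hi[2]))
  zs <- max(1, floor(lo[3])):min(d[3], ceiling(hi[3]))
  g <- expand.grid(x = xs, y = ys, z = zs)
  p <- sweep(as.matrix(g), 2, spacing, "*")
  a <- p0 * spacing; b <- p1 * spacing
  ab <- b - a
  tt <- pmin(pmax(as.numeric((sweep(p, 2, a) %*% ab) / sum(ab^2)), 0), 1)
  nearest <- sweep(outer(tt, ab), 2, a, "+")
  inside <- rowSums((p - nearest)^2) <= radius^2
  m <- array(FALSE, d)
  m[as.matrix(g[inside, ])] <- TRUE
  m
}

#' Generate a synthetic thorax phantom with ground truth
#'
#' Paints the structures declared in the spec into an HU volume, derives the
#' truth masks, and computes the analytically expected value of every
#' biomarker from the voxelized geometry (voxel counts, recorded plaque
#' parameters), so recovery by the quantification branches can be asserted
#' exactly. Deterministic: identical spec (including its seed) gives a
#' voxel-identical phantom.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (`ct_volume`; noisy when `spec$noise_sd > 0`)
#'   and `truth` (class `phantom_truth`): `masks` (named `label_mask` list),
#'   `expected` (per-branch metric values), `spec`, and `volume_noiseless`
#'   when noise was added.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape; sp <- spec$spacing
  co <- grid_coords(d)
  vol <- array(spec$air_hu, d)

  inside_ellipsoid <- function(center, semi_mm) {
    ((co$x - center[1]) * sp[1] / semi_mm[1])^2 +
      ((co$y - center[2]) * sp[2] / semi_mm[2])^2 +
      ((co$z - center[3]) * sp[3] / semi_mm[3])^2 <= 1
  }

  # body: soft-tissue ellipsoid filling most of the grid
  body <- inside_ellipsoid((d + 1) / 2, 0.47 * d * sp)
  vol[body] <- spec$soft_tissue_hu

  lung_region <- array(FALSE, d)
  for (i in seq_along(spec$lungs %||% list())) {
    L <- spec$lungs[[i]]
    check_fits(paste0("lung ", i), L$center - L$semi_mm / sp,
               L$center + L$semi_mm / sp, d)
    lung_region <- lung_region | inside_ellipsoid(L$center, L$semi_mm)
  }
  vol[lung_region] <- spec$lung_hu

  # vessels (painted before airways/heart; ownership by largest radius)
  vessel_mask <- array(FALSE, d)
  vessel_radius_of <- array(NA_real_, d)
  cyls <- spec$vessels %||% list()
  if (length(cyls)) {
    ord <- order(vapply(cyls, `[[`, numeric(1), "radius"))
    for (ci in ord) {
      cy <- cyls[[ci]]
      m <- paint_cylinder(d, sp, cy$p0, cy$p1, cy$radius)
      vessel_mask <- vessel_mask | m
      vessel_radius_of[m] <- cy$radius
    }
    vol[vessel_mask] <- spec$vessel_hu
  }

  # airways (anti-aliased walls over whatever is underneath)
  air_lumen <- air_wall <- array(FALSE, d)
  for (aw in spec$airways %||% list()) {
    pa <- paint_airway(vol, aw, sp, spec$air_hu)
    vol <- pa$vol
    air_lumen <- air_lumen | pa$lumen
    air_wall <- air_wall | pa$wall
  }

  # left ventricle: exact-count ED/ES pools under a prolate ellipsoidal norm
  blood_ed <- blood_es <- myo <- array(FALSE, d)
  if (!is.null(spec$lv)) {
    lv <- spec$lv
    vox_ml <- prod(sp) / 1000
    n_ed <- round(lv$edv_ml / vox_ml)
    n_es <- round(lv$esv_ml / vox_ml)
    # semi-axis scale implied by the target volume: (4/3) pi a^2 (ratio a)
    a_mm <- (3 * lv$edv_ml * 1000 / (4 * pi * lv$axis_ratio_z))^(1 / 3)
    ext <- c(a_mm, a_mm, a_mm * lv$axis_ratio_z) + lv$myo_thickness_mm + 4 * sp
    check_fits("left ventricle", lv$center - ext / sp, lv$center + ext / sp, d)
    bb <- co$x >= lv$center[1] - ext[1] / sp[1] & co$x <= lv$center[1] + ext[1] / sp[1] &
          co$y >= lv$center[2] - ext[2] / sp[2] & co$y <= lv$center[2] + ext[2] / sp[2] &
          co$z >= lv$center[3] - ext[3] / sp[3] & co$z <= lv$center[3] + ext[3] / sp[3]
    idx <- which(bb)
    rho <- sqrt(((co$x[idx] - lv$center[1]) * sp[1])^2 +
                ((co$y[idx] - lv$center[2]) * sp[2])^2 +
                (((co$z[idx] - lv$center[3]) * sp[3]) / lv$axis_ratio_z)^2)
    if (length(idx) < n_ed)
      stop("structure does not fit the grid: left ventricle (EDV target)")
    ord <- idx[order(rho, idx)]
    blood_ed[ord[seq_len(n_ed)]] <- TRUE
    blood_es[ord[seq_len(n_es)]] <- TRUE
    shell <- edt_feature_cpp(blood_ed, d, sp)$dist
    myo <- !blood_ed & shell <= lv$myo_thickness_mm & shell > 0
    vol[myo] <- lv$myo_hu
    vol[blood_ed] <- lv$blood_hu
  }
  heart <- blood_ed | myo
  lung_mask <- lung_region & !air_lumen & !air_wall & !heart
  vessel_mask <- vessel_mask & !heart

  # emphysema: exact count of lung voxels nearest the seeded pocket centres
  emph <- array(FALSE, d)
  if (!is.null(spec$lungs) && spec$emphysema_fraction > 0) {
    eligible <- which(lung_mask & !vessel_mask)
    target <- round(spec$emphysema_fraction * sum(lung_mask))
    if (target > length(eligible))
      stop("emphysema target exceeds available lung parenchyma")
    centers <- with_seed(spec$seed, sample(eligible, spec$emphysema_pockets))
    ex <- co$x[eligible]; ey <- co$y[eligible]; ez <- co$z[eligible]
    dmin <- rep(Inf, length(eligible))
    for (cc in centers) {
      dd <- ((ex - co$x[cc]) * sp[1])^2 + ((ey - co$y[cc]) * sp[2])^2 +
            ((ez - co$z[cc]) * sp[3])^2
      dmin <- pmin(dmin, dd)
    }
    pick <- eligible[order(dmin, eligible)[seq_len(target)]]
    emph[pick] <- TRUE
    vol[emph] <- spec$emphysema_hu
  }

  # calcified plaques: axis-aligned squares on single slices
  calcium <- array(FALSE, d)
  plaque_rows <- list()
  for (i in seq_along(spec$plaques %||% list())) {
    pl <- spec$plaques[[i]]
    side <- round(sqrt(pl$area_mm2 / (sp[1] * sp[2])))
    side <- max(1L, side)
    xs <- round(pl$center_xy[1] - (side - 1) / 2) + 0:(side - 1)
    ys <- round(pl$center_xy[2] - (side - 1) / 2) + 0:(side - 1)
    check_fits(paste0("plaque ", i), c(min(xs), min(ys), pl$slice),
               c(max(xs), max(ys), pl$slice), d)
    if (any(vol[xs, ys, pl$slice] < -500))
      stop("plaque ", i, " placed outside soft tissue")
    vol[xs, ys, pl$slice] <- pl$peak_hu
    calcium[xs, ys, pl$slice] <- TRUE
    area <- side^2 * sp[1] * sp[2]
    w <- agatston_weight(pl$peak_hu)
    plaque_rows[[i]] <- data.frame(slice = pl$slice, area_mm2 = area,
                                   peak_hu = pl$peak_hu, weight = w,
                                   score = area * w * sp[3] / 3)
  }
  lesion_table <- if (length(plaque_rows)) do.call(rbind, plaque_rows) else
    data.frame(slice = integer(), area_mm2 = numeric(), peak_hu = numeric(),
               weight = integer(), score = numeric())

  # coronary search region: plaque slices dilated by a margin box
  roi <- array(FALSE, d)
  if (length(spec$plaques %||% list())) {
    for (pl in spec$plaques) {
      mar <- 6
      xs <- max(1, round(pl$center_xy[1]) - mar):min(d[1], round(pl$center_xy[1]) + mar)
      ys <- max(1, round(pl$center_xy[2]) - mar):min(d[2], round(pl$center_xy[2]) + mar)
      zs <- max(1, pl$slice - 2):min(d[3], pl$slice + 2)
      roi[xs, ys, zs] <- TRUE
    }
  }

  # ---- expected metric values from the voxelized geometry ----
  vox_ml <- prod(sp) / 1000
  expected <- list()
  if (any(lung_mask)) {
    hu <- vol[lung_mask]
    expected$lung <- list(
      lav_percent = 100 * sum(emph) / sum(lung_mask),
      mld = mean(hu),
      perc15 = percentile_lower(hu, 0.15),
      n_lung_voxels = sum(lung_mask))
  }
  if (length(spec$airways %||% list())) {
    expected$airway <- lapply(spec$airways, function(aw) {
      rl <- aw$lumen_radius; ro <- rl + aw$wall_thickness
      mid <- round(mean(aw$z_range))
      list(lumen_radius = rl, wall_thickness = aw$wall_thickness,
           mid_slice = mid,
           la_circle = pi * rl^2, wa_circle = pi * (ro^2 - rl^2),
           wa_percent_circle = 100 * (ro^2 - rl^2) / ro^2,
           wa_la_ratio_circle = (ro^2 - rl^2) / rl^2)
    })
  }
  if (any(vessel_mask)) {
    r_own <- vessel_radius_of[vessel_mask]
    expected$vessel <- list(
      bv5_percent = 100 * sum(pi * r_own^2 < 5) / sum(vessel_mask),
      total_vessel_volume_ml = sum(vessel_mask) * vox_ml)
  }
  expected$cardiac <- list(cacs = sum(lesion_table$score),
                           lesion_table = lesion_table)
  if (!is.null(spec$lv)) {
    expected$cardiac <- c(expected$cardiac, list(
      edv_ml = sum(blood_ed) * vox_ml, esv_ml = sum(blood_es) * vox_ml,
      sv_ml = (sum(blood_ed) - sum(blood_es)) * vox_ml,
      ef_percent = 100 * (sum(blood_ed) - sum(blood_es)) / sum(blood_ed),
      lvm_g = sum(myo) * vox_ml * 1.05))
  }

  mk <- function(m) label_mask(m, spacing = sp)
  masks <- list(lung = mk(lung_mask), emphysema = mk(emph),
                airway_lumen = mk(air_lumen), airway_wall = mk(air_wall),
                vessels = mk(vessel_mask), blood_ed = mk(blood_ed),
                blood_es = mk(blood_es), myocardium = mk(myo),
                calcium = mk(calcium), roi = mk(roi))

  clean <- ct_volume(vol, spacing = sp)
  out_vol <- if (spec$noise_sd > 0)
    degrade(clean, spec$noise_sd, seed = spec$seed) else clean
  truth <- structure(list(masks = masks, expected = expected, spec = spec,
                          volume_noiseless = if (spec$noise_sd > 0) clean),
                     class = "phantom_truth")
  list(volume = out_vol, truth = truth)
}

#' Add seeded Gaussian noise to a volume
#'
#' @param v `ct_volume`.
#' @param noise_sd noise SD in HU; 0 returns the input unchanged.
#' @param seed RNG seed; the same seed reproduces the output exactly.
#' @return a `ct_volume`.
#' @export
degrade <- function(v, noise_sd, seed = 1) {
  stopifnot(inherits(v, "ct_volume"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd == 0) return(v)
  noisy <- with_seed(seed, v$data + array(stats::rnorm(length(v$data),
                                                       sd = noise_sd),
                                          dim(v$data)))
  ct_volume(noisy, spacing = v$spacing, origin = v$origin)
}

#' Ideal airway tube phantom
#'
#' A single z-aligned airway tube embedded in uniform parenchyma, with
#' anti-aliased lumen/wall edges in the HU volume and exact centre-inclusion
#' truth masks - the standard fixture for wall-measurement checks.
#'
#' The default grid uses 0.5 mm in-plane voxels: with a 1 mm wall on a 1 mm
#' grid the FWHM operator hits the classic partial-volume wall-thickening
#' bias (the sampled wall peak never reaches the true wall attenuation), so
#' wall checks are run at the sub-millimetre in-plane resolution airway
#' reconstructions use.
#'
#' @param lumen_radius,wall_thickness mm.
#' @param shape,spacing grid geometry.
#' @param wall_hu,parenchyma_hu,air_hu attenuations.
#' @return list `volume` (`ct_volume`), `lumen`, `wall` (`label_mask`s),
#'   `center` (tube centre, voxel coords).
#' @export
airway_tube_phantom <- function(lumen_radius = 2, wall_thickness = 1,
                                shape = c(64, 64, 24), spacing = c(0.5, 0.5, 1),
                                wall_hu = -100, parenchyma_hu = -850,
                                air_hu = -1000) {
  d <- shape
  ctr <- floor((d[1:2] + 1) / 2)      # integer centre: symmetric digital disc
  vol <- array(parenchyma_hu, d)
  pa <- paint_airway(vol, list(center_xy = ctr, z_range = c(1, d[3]),
                               lumen_radius = lumen_radius,
                               wall_thickness = wall_thickness,
                               wall_hu = wall_hu),
                     spacing, air_hu)
  list(volume = ct_volume(pa$vol, spacing = spacing),
       lumen = label_mask(pa$lumen, spacing = spacing),
       wall = label_mask(pa$wall, spacing = spacing),
       center = c(ctr, (d[3] + 1) / 2))
}

#' Digital cylinder mask
#'
#' Binary z-aligned cylinder by voxel-centre inclusion - the exact digital
#' solid used for vessel-profiling checks.
#'
#' @param shape,spacing grid geometry.
#' @param center_xy in-plane centre (voxel coords).
#' @param radius mm.
#' @param z_range inclusive slice range.
#' @return a `label_mask`.
#' @export
digital_cylinder <- function(shape, spacing = c(1, 1, 1), center_xy, radius,
                             z_range) {
  m <- paint_cylinder(shape, spacing,
                      c(center_xy, z_range[1]), c(center_xy, z_range[2]),
                      radius, what = "cylinder")
  label_mask(m, spacing = spacing)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> masks:", paste(names(x$masks), collapse = ", "), "\n")
  if (!is.null(x$expected$lung))
    cat(sprintf("  lung: LAV%% %.2f, MLD %.1f, Perc15 %.1f\n",
                x$expected$lung$lav_percent, x$expected$lung$mld,
                x$expected$lung$perc15))
  if (!is.null(x$expected$vessel))
    cat(sprintf("  vessel: BV5%% %.2f\n", x$expected$vessel$bv5_percent))
  if (!is.null(x$expected$cardiac$ef_percent))
    cat(sprintf("  cardiac: CACS %.2f, EF %.1f%%, SV %.1f mL\n",
                x$expected$cardiac$cacs, x$expected$cardiac$ef_percent,
                x$expected$cardiac$sv_ml))
  invisible(x)
}
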