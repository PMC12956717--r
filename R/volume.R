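#' CT volume container
#'
#' A thin container for a 3D scalar grid in Hounsfield units plus its
#' anisotropic voxel spacing. Arrays follow R's column-major native layout:
#' `data[x, y, z]` with `spacing = c(dx, dy, dz)` in mm, matching how RNifti
#' exposes NIfTI images. All voxel coordinates are 1-based.
#'
#' Quantification always operates on the raw HU grid. [preprocess()] returns
#' a separate object (the model-input copy) and never mutates its input, so
#' the raw HU volume is preserved by construction.
#'
#' @param data numeric 3D array of HU values, all finite.
#' @param spacing numeric length-3, voxel edge lengths in mm, strictly
#'   positive, ordered `(dx, dy, dz)`.
#' @param origin numeric length-3 mm offset of voxel `(1,1,1)`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  if (any(!is.finite(data)))
    stop("HU values must be finite")
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin), axis_order = "xyz"),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm, HU range [", round(min(x$data)), ", ", round(max(x$data)), "]\n",
      sep = "")
  invisible(x)
}

#' Label mask aligned to a CT volume
#'
#' Integer (or logical) grid with the same shape and spacing as its paired
#' volume. `labels` maps structure names to the integer codes present.
#'
#' @param data integer/logical 3D array.
#' @param spacing voxel spacing in mm, `(dx, dy, dz)`.
#' @param labels named integer vector, e.g. `c(lung = 1L)`. Binary logical
#'   masks default to `c(foreground = 1L)`.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), labels = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D mask")
  if (is.logical(data)) {
    if (is.null(labels)) labels <- c(foreground = 1L)
  } else {
    data <- array(as.integer(data), dim = dim(data))
    if (is.null(labels)) {
      vals <- sort(setdiff(unique(as.integer(data)), 0L))
      labels <- stats::setNames(vals, paste0("label", vals))
    }
    present <- setdiff(unique(as.integer(data)), 0L)
    if (length(setdiff(present, as.integer(labels))))
      stop("mask contains values outside the declared label map")
  }
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  structure(list(data = data, spacing = as.numeric(spacing),
                 labels = labels),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, labels: ", paste(names(x$labels), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# logical foreground view of a mask (any non-zero label)
mask_logical <- function(m) {
  if (is.logical(m$data)) m$data else m$data != 0L
}

check_aligned <- function(v, m) {
  if (!identical(dim(v$data), dim(m$data)))
    stop("mask shape does not match volume")
  if (max(abs(v$spacing - m$spacing)) > 1e-9)
    stop("mask spacing does not match volume")
  invisible(TRUE)
}

#' Voxel volume in mm^3
#' @param x a `ct_volume` or `label_mask`.
#' @return scalar, mm^3 per voxel.
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' Read a 3D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [ct_volume()], taking voxel spacing
#' from the header. Integer-typed data round-trip bit-exactly with
#' [write_volume()].
#'
#' @param path path to an existing 3D NIfTI file.
#' @return a `ct_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) stop("expected 3D volume, got ", length(d), "D")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(sp <= 0)) stop("non-positive voxel spacing in header")
  ct_volume(array(as.numeric(img), dim = d), spacing = sp)
}

#' Write a CT volume to NIfTI
#'
#' @param v a `ct_volume`.
#' @param path output `.nii` or `.nii.gz` path.
#' @param datatype NIfTI storage type; whole-valued grids are stored as
#'   `int16` (lossless for HU) and everything else as `float` by default.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = NULL) {
  stopifnot(inherits(v, "ct_volume"))
  if (is.null(datatype)) {
    whole <- all(v$data == round(v$data)) &&
      min(v$data) >= -32768 && max(v$data) <= 32767
    datatype <- if (whole) "int16" else "float"
  }
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a label mask from NIfTI
#' @param path NIfTI file with integer labels.
#' @param labels optional named integer label map.
#' @return a `label_mask`.
#' @export
read_mask <- function(path, labels = NULL) {
  v <- read_volume(path)
  if (max(abs(v$data - round(v$data))) > 1e-6)
    stop("mask file contains non-integer values")
  label_mask(array(as.integer(round(v$data)), dim(v$data)),
             spacing = v$spacing, labels = labels)
}

#' Write a label mask to NIfTI
#' @param m a `label_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(m, path) {
  stopifnot(inherits(m, "label_mask"))
  dat <- if (is.logical(m$data)) array(as.integer(m$data), dim(m$data)) else m$data
  write_volume(ct_volume(dat, spacing = m$spacing), path, datatype = "int16")
}

#' Preprocessing configuration
#'
#' Gaussian denoising followed by HU windowing and optional linear
#' normalization of the window to `[0, 1]` - the standard model-input chain.
#' Sigma defaults to 1 (low end of the common 1-1.5 range, to minimally blur
#' thin airway walls) and is interpreted in voxel units unless
#' `sigma_units = "mm"`.
#'
#' @param gaussian_sigma non-negative smoothing width; 0 disables smoothing.
#' @param sigma_units `"voxels"` (default) or `"mm"`.
#' @param hu_window length-2 `(low, high)` HU clamp, default `c(-1000, 400)`.
#' @param normalize if `TRUE`, map `low -> 0`, `high -> 1` affinely.
#' @return a `preprocess_config`.
#' @export
preprocess_config <- function(gaussian_sigma = 1, sigma_units = c("voxels", "mm"),
                              hu_window = c(-1000, 400), normalize = TRUE) {
  sigma_units <- match.arg(sigma_units)
  if (gaussian_sigma < 0) stop("sigma must be >= 0")
  if (length(hu_window) != 2L || hu_window[1] >= hu_window[2])
    stop("hu_window must satisfy low < high")
  structure(list(gaussian_sigma = gaussian_sigma, sigma_units = sigma_units,
                 hu_window = as.numeric(hu_window), normalize = normalize),
            class = "preprocess_config")
}

# separable Gaussian convolution along one array axis; kernel truncated at
# 3 sigma and renormalized at the edges (no value bleed-in from padding)
gauss_axis <- function(arr, sigma, axis) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  n <- dim(arr)[axis]
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  a <- K %*% matrix(a, nrow = d[1])
  dim(a) <- d
  aperm(a, order(perm))
}

#' Preprocess a CT volume for model input
#'
#' Applies `clamp(gaussian(v), low, high)` and, when `cfg$normalize`, the
#' affine map sending the window to `[0, 1]`. Returns a new volume; the raw
#' HU input is untouched (quantification must always read raw HU - the 400 HU
#' clamp would destroy the top Agatston density class).
#'
#' @param v a `ct_volume` with raw HU.
#' @param cfg a [preprocess_config()].
#' @return a `ct_volume`; normalized outputs carry `units = "normalized"` as
#'   an attribute.
#' @export
preprocess <- function(v, cfg = preprocess_config()) {
  stopifnot(inherits(v, "ct_volume"), inherits(cfg, "preprocess_config"))
  dat <- v$data
  if (cfg$gaussian_sigma > 0) {
    sig <- if (cfg$sigma_units == "mm") cfg$gaussian_sigma / v$spacing
           else rep(cfg$gaussian_sigma, 3)
    for (ax in 1:3) dat <- gauss_axis(dat, sig[ax], ax)
  }
  lo <- cfg$hu_window[1]; hi <- cfg$hu_window[2]
  dat <- pmin(pmax(dat, lo), hi)
  if (cfg$normalize) dat <- (dat - lo) / (hi - lo)
  out <- ct_volume(dat, spacing = v$spacing, origin = v$origin)
  attr(out, "units") <- if (cfg$normalize) "normalized" else "HU"
  out
}

#' Trilinear interpolation into a 3D grid
#'
#' @param arr 3D numeric array.
#' @param pts n x 3 matrix of 1-based fractional voxel coordinates.
#' @param fill value returned outside the grid.
#' @return numeric vector of length `nrow(pts)`.
#' @keywords internal
interp3 <- function(arr, pts, fill = NA_real_) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  out <- rep(fill, nrow(pts))
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) arr[cbind(i, j, k)]
  v <- idx(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    idx(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    idx(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    idx(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    idx(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    idx(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    idx(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    idx(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[ok] <- v
  out
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
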