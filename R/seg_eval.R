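#' Dice coefficient and IoU for a mask pair
#'
#' `dice = 2|A&B| / (|A|+|B|)`, `iou = |A&B| / |A|B|`. The two are linked by
#' `dice = 2 iou / (1 + iou)` for every pair. When both masks are empty the
#' convention here is `dice = iou = 1` with `flag = "both_empty"` (agreement
#' on absence); alternative conventions return 0 or NaN - see the vignette.
#'
#' @param pred,ref aligned binary `label_mask`s (or logical arrays).
#' @return list `dice`, `iou`, and optionally `flag`.
#' @export
dice_iou <- function(pred, ref) {
  a <- if (inherits(pred, "label_mask")) mask_logical(pred) else pred
  b <- if (inherits(ref, "label_mask")) mask_logical(ref) else ref
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0)
    return(list(dice = 1, iou = 1, flag = "both_empty"))
  inter <- sum(a & b)
  list(dice = 2 * inter / (na + nb), iou = inter / (na + nb - inter))
}

#' Agreement metrics for paired continuous measurements
#'
#' Pearson r, Spearman rho and RMSE between predicted and reference series.
#' Zero variance in either series leaves the correlations `NA` with
#' `flag = "zero_variance"` (undefined, not 0).
#'
#' @param pred,ref numeric vectors of equal length `>= 3`, finite.
#' @return list `pearson_r`, `spearman_rho`, `rmse`, `n`, optional `flag`.
#' @export
regression_agreement <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("series lengths differ")
  if (length(pred) < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(pred)) || any(!is.finite(ref))) stop("non-finite values")
  rmse <- sqrt(mean((pred - ref)^2))
  if (stats::var(pred) == 0 || stats::var(ref) == 0)
    return(list(pearson_r = NA_real_, spearman_rho = NA_real_, rmse = rmse,
                n = length(pred), flag = "zero_variance"))
  list(pearson_r = stats::cor(pred, ref),
       spearman_rho = stats::cor(pred, ref, method = "spearman"),
       rmse = rmse, n = length(pred))
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p g) + eps) / (sum(p) + sum(g) + eps)` for a probability map
#' against a binary reference; the differentiable segmentation loss. The
#' smoothing constant `eps` (default 1e-7) only guards the empty-empty case.
#'
#' @param prob numeric array in `[0, 1]`.
#' @param ref binary mask (`label_mask` or logical/0-1 array), same shape.
#' @param eps smoothing constant.
#' @return loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(prob, ref, eps = 1e-7) {
  g <- if (inherits(ref, "label_mask")) mask_logical(ref) else ref
  if (!identical(dim(prob), dim(g))) stop("shapes differ")
  if (min(prob) < 0 || max(prob) > 1) stop("probabilities must lie in [0, 1]")
  g <- as.numeric(g)
  1 - (2 * sum(prob * g) + eps) / (sum(prob) + sum(g) + eps)
}

#' Combined segmentation + regression loss
#'
#' Weighted sum of soft-Dice terms (mean over segmentation heads) and the
#' MSE of the regression head; reduces to either component when the other
#' weight is 0.
#'
#' @param dice_losses numeric vector of per-head soft-Dice losses (may be
#'   empty).
#' @param pred,target numeric regression predictions and targets (may be
#'   empty).
#' @param w_seg,w_reg non-negative weights (defaults 1, 1: no branch weights
#'   are prescribed, so heads count equally).
#' @return scalar loss.
#' @export
combined_loss <- function(dice_losses = numeric(), pred = numeric(),
                          target = numeric(), w_seg = 1, w_reg = 1) {
  if (w_seg < 0 || w_reg < 0) stop("weights must be >= 0")
  if (length(pred) != length(target)) stop("regression lengths differ")
  seg <- if (length(dice_losses)) mean(dice_losses) else 0
  reg <- if (length(pred)) mean((pred - target)^2) else 0
  w_seg * seg + w_reg * reg
}

#' Stratified train/validation/test split plus k-fold assignment
#'
#' Deterministic under `seed`. Within every stratum, items are shuffled and
#' allocated to test/val/train with counts rounded from the fractions
#' (70/15/15 by default); k-fold ids are dealt cyclically over the shuffled
#' order so folds partition each stratum as evenly as possible.
#'
#' @param items vector of item identifiers.
#' @param strata stratification key, same length (default: one stratum).
#' @param fractions `(train, val, test)` summing to 1.
#' @param k folds for cross-validation, default 5.
#' @param seed RNG seed.
#' @return data.frame `item`, `stratum`, `split` (train/val/test), `fold`.
#' @export
make_splits <- function(items, strata = NULL, fractions = c(0.70, 0.15, 0.15),
                        k = 5, seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (is.null(strata)) strata <- rep("all", length(items))
  if (length(strata) != length(items)) stop("strata length mismatch")
  tab <- table(strata)
  if (any(tab < k))
    stop("stratum smaller than k: ", paste(names(tab)[tab < k], collapse = ", "))
  out <- with_seed(seed, {
    parts <- lapply(split(seq_along(items), strata), function(idx) {
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_val <- round(fractions[2] * n)
      n_test <- round(fractions[3] * n)
      n_train <- n - n_val - n_test
      data.frame(
        item = items[idx],
        stratum = strata[idx],
        split = rep(c("train", "val", "test"), c(n_train, n_val, n_test)),
        fold = rep_len(seq_len(k), n))
    })
    do.call(rbind, parts)
  })
  rownames(out) <- NULL
  out
}

#' Augmentation configuration
#'
#' Sampled-parameter ranges for the standard augmentation set: in-plane
#' rotation (degrees), horizontal/vertical (in-plane) flips, random crop
#' scale, and a global additive intensity perturbation (HU). Collapsing all
#' ranges (rotation `c(0,0)`, crop `c(1,1)`, amplitude 0, flips off) makes
#' [augment()] the identity.
#'
#' @param rotation_deg length-2 range, default `c(-10, 10)`.
#' @param flip_horizontal,flip_vertical allow the in-plane flips.
#' @param crop_scale length-2 range within `[0, 1]`, default `c(0.8, 1)`.
#' @param intensity_amplitude_hu max |additive shift|, default 10 HU.
#' @return an `augment_config`.
#' @export
augment_config <- function(rotation_deg = c(-10, 10), flip_horizontal = TRUE,
                           flip_vertical = TRUE, crop_scale = c(0.8, 1),
                           intensity_amplitude_hu = 10) {
  if (any(crop_scale <= 0) || any(crop_scale > 1)) stop("crop_scale in (0, 1]")
  structure(as.list(environment()), class = "augment_config")
}

#' Apply one sampled augmentation to a paired volume and mask
#'
#' Samples one transform (angle, flips, crop window, intensity shift) inside
#' the configured ranges and applies the *same* geometric transform to both
#' inputs: bilinear in-plane resampling for the volume, nearest-neighbour
#' for the mask. The intensity shift touches the volume only. Deterministic
#' under `seed`.
#'
#' @param v `ct_volume`.
#' @param mask `label_mask` aligned to `v`.
#' @param cfg an [augment_config()].
#' @param seed RNG seed.
#' @param fill_hu out-of-field fill for the rotated volume, default -1000.
#' @return list `volume`, `mask`, `params` (the sampled transform).
#' @export
augment <- function(v, mask, cfg = augment_config(), seed = 1, fill_hu = -1000) {
  stopifnot(inherits(v, "ct_volume"), inherits(mask, "label_mask"))
  check_aligned(v, mask)
  d <- dim(v$data)
  params <- with_seed(seed, {
    crop_lim <- pmax(1L, floor(stats::runif(1, cfg$crop_scale[1], cfg$crop_scale[2]) * d))
    list(angle_deg = stats::runif(1, cfg$rotation_deg[1], cfg$rotation_deg[2]),
         flip_h = cfg$flip_horizontal && stats::runif(1) < 0.5,
         flip_v = cfg$flip_vertical && stats::runif(1) < 0.5,
         crop_dim = crop_lim,
         crop_off = vapply(d - crop_lim, function(m) if (m > 0)
           sample.int(m + 1L, 1L) - 1L else 0L, integer(1)),
         shift_hu = stats::runif(1, -cfg$intensity_amplitude_hu,
                                 cfg$intensity_amplitude_hu))
  })
  vol <- v$data
  msk <- mask$data
  if (params$angle_deg != 0) {
    vol <- rotate_z(vol, params$angle_deg, bilinear = TRUE, fill = fill_hu)
    msk <- rotate_z(msk, params$angle_deg, bilinear = FALSE, fill = 0L)
  }
  if (params$flip_h) { vol <- vol[rev(seq_len(d[1])), , , drop = FALSE]
                       msk <- msk[rev(seq_len(d[1])), , , drop = FALSE] }
  if (params$flip_v) { vol <- vol[, rev(seq_len(d[2])), , drop = FALSE]
                       msk <- msk[, rev(seq_len(d[2])), , drop = FALSE] }
  if (any(params$crop_dim < d)) {
    ix <- params$crop_off[1] + seq_len(params$crop_dim[1])
    iy <- params$crop_off[2] + seq_len(params$crop_dim[2])
    iz <- params$crop_off[3] + seq_len(params$crop_dim[3])
    vol <- vol[ix, iy, iz, drop = FALSE]
    msk <- msk[ix, iy, iz, drop = FALSE]
  }
  if (params$shift_hu != 0) vol <- vol + params$shift_hu
  list(volume = ct_volume(vol, spacing = v$spacing),
       mask = label_mask(msk, spacing = mask$spacing, labels = mask$labels),
       params = params)
}

# in-plane rotation about each slice centre; bilinear or nearest-neighbour
rotate_z <- function(arr, angle_deg, bilinear = TRUE, fill = 0) {
  d <- dim(arr)
  th <- angle_deg * pi / 180
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  # inverse map: source coords for each target pixel
  xs <- cx + cos(th) * (g$x - cx) + sin(th) * (g$y - cy)
  ys <- cy - sin(th) * (g$x - cx) + cos(th) * (g$y - cy)
  out <- array(fill, d)
  if (bilinear) {
    inb <- xs >= 1 & xs <= d[1] & ys >= 1 & ys <= d[2]
    x0 <- pmin(floor(xs[inb]), d[1] - 1L); y0 <- pmin(floor(ys[inb]), d[2] - 1L)
    fx <- xs[inb] - x0; fy <- ys[inb] - y0
    for (z in seq_len(d[3])) {
      sl <- arr[, , z]
      val <- sl[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
        sl[cbind(x0 + 1, y0)] * fx * (1 - fy) +
        sl[cbind(x0, y0 + 1)] * (1 - fx) * fy +
        sl[cbind(x0 + 1, y0 + 1)] * fx * fy
      dst <- matrix(fill, d[1], d[2])
      dst[cbind(g$x[inb], g$y[inb])] <- val
      out[, , z] <- dst
    }
  } else {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2]
    for (z in seq_len(d[3])) {
      sl <- matrix(fill, d[1], d[2])
      sl[cbind(g$x[ok], g$y[ok])] <- arr[, , z][cbind(xi[ok], yi[ok])]
      out[, , z] <- sl
    }
  }
  if (is.integer(arr)) array(as.integer(out), d) else out
}
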