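# Two-shell log-slope diffusivity estimation, masking, windowing and
# partial-volume bias reporting.
#
# The core estimate is MDT = [ln s(b1) - ln s(b2)] / (b2 - b1), with
# b1 = 1500 and b2 = 2500 s/mm^2 by default.  Because both shells sit in
# the high-b regime where free water (3.0 um^2/ms) retains < 0.1 percent
# of its signal, the slope reflects tissue alone.  Natural logarithms are
# used throughout (the base cancels only if used consistently).

#' Two-shell tissue diffusivity (scalar form)
#'
#' `[ln(s1) - ln(s2)] / (b2 - b1)`, converted from mm^2/s to um^2/ms
#' (factor 1e3).  For mono-exponential signals this inverts the decay
#' exactly.  Vectorised; signals at or below the floor raise an error in
#' scalar use — use [mdt_map_from_shells()] for maps, where such voxels
#' are flagged invalid instead.
#'
#' @param s1,s2 Signals at `b1` and `b2` (unitless, positive).
#' @param b1,b2 b-values, s/mm^2, with `b2 > b1 >= 0`.
#' @param floor Positive signal floor below which the estimate is
#'   undefined (guards against the rectified noise floor masquerading as
#'   low diffusivity).
#' @return Diffusivity, um^2/ms.
#' @examples
#' compute_mdt(exp(-1.05), exp(-1.75), 1500, 2500)  # 0.7
#' @export
compute_mdt <- function(s1, s2, b1 = 1500, b2 = 2500, floor = 1e-6) {
  if (b2 <= b1 || b1 < 0) stop("need b2 > b1 >= 0")
  if (any(s1 <= floor) || any(s2 <= floor))
    stop("signal at or below the floor (", floor, ")")
  (log(s1) - log(s2)) / (b2 - b1) * 1e3
}

#' Conventional ADC from a b = 0 and one diffusion-weighted signal
#'
#' `[ln(s0) - ln(sb)] / b` in um^2/ms — the estimate MDT is compared
#' against.  Because it anchors at b = 0, where CSF contributes fully, it
#' is confounded by CSF partial volume.
#'
#' @param s0 Signal at b = 0.
#' @param sb Signal at b-value `b`.
#' @param b b-value, s/mm^2, positive.
#' @inheritParams compute_mdt
#' @return Diffusivity, um^2/ms.
#' @export
compute_adc <- function(s0, sb, b, floor = 1e-6) {
  if (b <= 0) stop("need b > 0")
  if (any(s0 <= floor) || any(sb <= floor))
    stop("signal at or below the floor (", floor, ")")
  (log(s0) - log(sb)) / b * 1e3
}

#' Construct an MDT map from two shell volumes
#'
#' Voxelwise two-shell estimate with a validity mask: voxels where either
#' input signal is at or below the floor are invalid (NA), never clamped
#' to a fake value.
#'
#' @param s1,s2 3D arrays of signals at `b1` and `b2` on a common grid.
#' @param affine 4x4 voxel-to-world affine of the grid.
#' @inheritParams compute_mdt
#' @param window Display window `c(lo, hi)`, um^2/ms; default
#'   `c(0.5, 0.9)`.
#' @return An `mdt_map`: `values` (um^2/ms, NA where invalid), `valid`,
#'   `affine`, `b = c(b1, b2)`, `window`.
#' @export
mdt_map_from_shells <- function(s1, s2, b1 = 1500, b2 = 2500, affine = diag(4),
                                floor = 1e-6, window = c(0.5, 0.9)) {
  if (b2 <= b1 || b1 < 0) stop("need b2 > b1 >= 0")
  stopifnot(all(dim(s1) == dim(s2)))
  valid <- s1 > floor & s2 > floor
  values <- array(NA_real_, dim(s1))
  values[valid] <- (log(s1[valid]) - log(s2[valid])) / (b2 - b1) * 1e3
  new_mdt_map(values, valid, affine, c(b1, b2), window)
}

#' Construct an ADC map from a b = 0 volume and one shell volume
#'
#' @param s0,sb 3D arrays on a common grid.
#' @inheritParams compute_adc
#' @inheritParams mdt_map_from_shells
#' @return An `mdt_map` (provenance `b = c(0, b)`).
#' @export
adc_map_from_shells <- function(s0, sb, b, affine = diag(4), floor = 1e-6,
                                window = c(0.5, 0.9)) {
  if (b <= 0) stop("need b > 0")
  stopifnot(all(dim(s0) == dim(sb)))
  valid <- s0 > floor & sb > floor
  values <- array(NA_real_, dim(s0))
  values[valid] <- (log(s0[valid]) - log(sb[valid])) / b * 1e3
  new_mdt_map(values, valid, affine, c(0, b), window)
}

new_mdt_map <- function(values, valid, affine, b, window = c(0.5, 0.9)) {
  if (window[1] >= window[2]) stop("window must satisfy lo < hi")
  structure(list(values = values, valid = valid, affine = affine,
                 b = b, window = window),
            class = "mdt_map")
}

#' @export
print.mdt_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf(
    "<mdt_map> %s grid, b = (%g, %g) s/mm^2, window (%.2g, %.2g) um^2/ms\n",
    paste(dim(x$values), collapse = "x"), x$b[1], x$b[2],
    x$window[1], x$window[2]))
  if (length(v))
    cat(sprintf("  %d valid voxel(s); median %.3f um^2/ms (IQR %.3f-%.3f)\n",
                length(v), stats::median(v),
                stats::quantile(v, 0.25), stats::quantile(v, 0.75)))
  else cat("  no valid voxels\n")
  invisible(x)
}

# nearest-neighbour resampling of an array onto a target grid
resample_nearest <- function(data, affine, target_dim, target_affine,
                             fill = 0) {
  n <- prod(target_dim)
  ijk <- cbind(
    rep(seq_len(target_dim[1]) - 1, times = target_dim[2] * target_dim[3]),
    rep(rep(seq_len(target_dim[2]) - 1, each = target_dim[1]),
        times = target_dim[3]),
    rep(seq_len(target_dim[3]) - 1, each = target_dim[1] * target_dim[2]),
    rep(1, n))
  world <- ijk %*% t(target_affine)
  src <- world %*% t(solve(affine))
  idx <- round(src[, 1:3]) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= dim(data)[1] &
        idx[, 2] >= 1 & idx[, 2] <= dim(data)[2] &
        idx[, 3] >= 1 & idx[, 3] <= dim(data)[3]
  out <- rep(fill, n)
  out[ok] <- data[idx[ok, , drop = FALSE]]
  array(out, target_dim)
}

#' Restrict an MDT map to a cortical mask
#'
#' The binary mask is resampled onto the map grid with nearest-neighbour
#' interpolation (binary semantics) if its grid differs, then voxels
#' outside the mask are invalidated; values inside are unchanged.  An
#' empty mask is valid but triggers a warning.
#'
#' @param map An `mdt_map`.
#' @param mask 3D array (logical or 0/1).
#' @param mask_affine Affine of the mask grid; defaults to the map's
#'   affine (grid-matched mask).
#' @return The masked `mdt_map`.
#' @export
apply_cortical_mask <- function(map, mask, mask_affine = NULL) {
  stopifnot(inherits(map, "mdt_map"))
  if (is.null(mask_affine)) mask_affine <- map$affine
  mask <- (mask > 0.5) * 1
  if (!all(dim(mask) == dim(map$values)) ||
      max(abs(mask_affine - map$affine)) > 1e-6) {
    mask <- resample_nearest(mask, mask_affine, dim(map$values), map$affine)
  }
  if (!any(mask > 0)) warning("cortical mask is empty")
  keep <- mask > 0
  map$valid <- map$valid & keep
  map$values[!map$valid] <- NA_real_
  map
}

#' Window an MDT map for display
#'
#' Linear windowing to `[0, 1]`: `(clamp(v, lo, hi) - lo) / (hi - lo)`.
#' Invalid voxels render as 0 — which is why CSF, whose high-b signal
#' falls below the floor, appears dark.  The default window (0.5, 0.9)
#' um^2/ms is the tight display range the suppressed-CSF map supports.
#'
#' @param map An `mdt_map`.
#' @param lo,hi Window bounds, um^2/ms, `lo < hi`; default the map's
#'   stored window.
#' @return 3D array in `[0, 1]`.
#' @export
render_window <- function(map, lo = NULL, hi = NULL) {
  stopifnot(inherits(map, "mdt_map"))
  if (is.null(lo)) lo <- map$window[1]
  if (is.null(hi)) hi <- map$window[2]
  if (lo >= hi) stop("window must satisfy lo < hi")
  out <- (pmin(pmax(map$values, lo), hi) - lo) / (hi - lo)
  out[!map$valid] <- 0
  out
}

#' Partial-volume bias report
#'
#' Stratifies voxels by CSF fraction and reports, per bin, the mean
#' signed bias and RMSE of the MDT and ADC estimates against the
#' CSF-excluded ground-truth tissue diffusivity.  All inputs must be on
#' the same grid.  Empty bins are reported with `n = 0` and NA
#' statistics.
#'
#' @param csf_fraction 3D array of per-voxel CSF fractions.
#' @param ground_truth List with `values` and `valid` as returned by
#'   [ground_truth_tissue_md()] (grid-matched to the maps).
#' @param mdt,adc `mdt_map` objects on the same grid.
#' @param breaks CSF-fraction bin edges; default `seq(0, 0.5, 0.1)`.
#' @param keep_empty Keep rows for bins with no valid voxels (default
#'   FALSE: empty bins are reported by their absence).
#' @return A data frame with one row per nonempty bin: `bin_lo`,
#'   `bin_hi`, `n`, `mdt_bias`, `mdt_rmse`, `adc_bias`, `adc_rmse`.
#' @export
pv_bias_report <- function(csf_fraction, ground_truth, mdt, adc,
                           breaks = seq(0, 0.5, by = 0.1),
                           keep_empty = FALSE) {
  stopifnot(inherits(mdt, "mdt_map"), inherits(adc, "mdt_map"),
            all(dim(csf_fraction) == dim(mdt$values)),
            all(dim(ground_truth$values) == dim(mdt$values)))
  ok <- ground_truth$valid & mdt$valid & adc$valid
  rows <- lapply(seq_len(length(breaks) - 1L), function(i) {
    lo <- breaks[i]; hi <- breaks[i + 1L]
    sel <- ok & csf_fraction >= lo &
      (if (i == length(breaks) - 1L) csf_fraction <= hi else csf_fraction < hi)
    if (!any(sel))
      return(data.frame(bin_lo = lo, bin_hi = hi, n = 0L,
                        mdt_bias = NA_real_, mdt_rmse = NA_real_,
                        adc_bias = NA_real_, adc_rmse = NA_real_))
    dm <- mdt$values[sel] - ground_truth$values[sel]
    da <- adc$values[sel] - ground_truth$values[sel]
    data.frame(bin_lo = lo, bin_hi = hi, n = sum(sel),
               mdt_bias = mean(dm), mdt_rmse = sqrt(mean(dm^2)),
               adc_bias = mean(da), adc_rmse = sqrt(mean(da^2)))
  })
  out <- do.call(rbind, rows)
  if (!keep_empty) out <- out[out$n > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
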