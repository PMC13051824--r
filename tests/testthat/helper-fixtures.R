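# Shared fixtures: small phantoms and geometries sized for fast tests,
# plus an independent brute-force implementation of the stack-sampling
# forward model used as an oracle.

tiny_phantom <- function(shape = c(16L, 16L, 16L)) {
  build_phantom(shape, spacing = 1, ribbon_mm = 2, csf_rim_mm = 1,
                ventricle_radius = 0.9, sulcal_width_mm = 1)
}

demo_phantom <- function(shape = c(32L, 32L, 32L)) {
  build_phantom(shape, spacing = 1)
}

paper_geometry <- function() stack_geometry()  # 1.53 x 1.53 x 5.2, 6 rotations

fast_geometry <- function(angles = c(0, 60, 120)) {
  stack_geometry(in_plane = c(1, 1), slice_thickness = 3,
                 rotation_angles = angles)
}

# two-compartment tissue + CSF voxel used across estimator tests
tissue_csf_mixture <- function(md_tissue = 0.7, f_tissue = 0.7,
                               f_csf = 0.3) {
  compartment_mixture(
    diffusion_compartment(md_tissue, fraction = f_tissue),
    diffusion_compartment(FREE_WATER_MD, fraction = f_csf))
}

# Independent, loop-based evaluation of one stack voxel:
# profile-weighted trilinear interpolation along the slice axis.
# Deliberately naive; used only on tiny instances.
naive_sample_stack <- function(volume, spacing, frame, profile) {
  dm <- dim(volume)
  interp <- function(q) {
    ci <- q / spacing + (dm - 1) / 2
    f0 <- floor(ci); d <- ci - f0
    acc <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      idx <- f0 + c(cx, cy, cz)
      if (any(idx < 0) || any(idx > dm - 1)) next
      w <- prod(ifelse(c(cx, cy, cz) == 1, d, 1 - d))
      acc <- acc + w * volume[idx[1] + 1, idx[2] + 1, idx[3] + 1]
    }
    acc
  }
  sigma <- frame$spacing[3] / (2 * sqrt(2 * log(2)))
  step <- min(spacing, frame$spacing[3])
  halfwidth <- if (profile == "boxcar") frame$spacing[3] / 2 else 2.5 * sigma
  m <- floor(halfwidth / step + 1e-9)
  taps <- (-m:m) * step
  w <- if (profile == "boxcar") rep(1, length(taps)) else
    exp(-taps^2 / (2 * sigma^2))
  w <- w / sum(w)
  out <- array(0, frame$dim)
  for (k in seq_len(frame$dim[3])) for (j in seq_len(frame$dim[2]))
    for (i in seq_len(frame$dim[1])) {
      g <- c((i - 1 - (frame$dim[1] - 1) / 2) * frame$spacing[1],
             (j - 1 - (frame$dim[2] - 1) / 2) * frame$spacing[2],
             (k - 1 - (frame$dim[3] - 1) / 2) * frame$spacing[3])
      p <- as.numeric(frame$u %*% g)
      acc <- 0
      for (t in seq_along(taps))
        acc <- acc + w[t] * interp(p + taps[t] * frame$u[, 3])
      out[i, j, k] <- acc
    }
  out
}
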