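# End-to-end pipeline: phantom -> simulated session -> repetition
# averaging -> per-shell super-resolution -> MDT/ADC maps, masking,
# windowing, and the partial-volume bias report.

#' Assemble a pipeline configuration
#'
#' @param phantom_shape,phantom_spacing Phantom grid and spacing (mm).
#' @param lesions List of [lesion_spec()] objects to insert.
#' @param protocol A `btensor_protocol`; default [mdt_protocol()].
#' @param geometry A `stack_geometry`; default the six-rotation
#'   1.53 x 1.53 x 5.2 mm scheme.
#' @param sigma Rician noise level.
#' @param seed Integer seed controlling all randomness.
#' @param srr An [srr_config()].
#' @param b1,b2 Estimator shells, s/mm^2; must be present in the
#'   protocol.
#' @param floor Signal floor for the estimator.
#' @param window Display window, um^2/ms.
#' @param mask_threshold Cortex-fraction threshold used to derive the
#'   cortical mask from the phantom's ground truth.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(phantom_shape = c(48L, 48L, 48L),
                            phantom_spacing = 1,
                            lesions = list(),
                            protocol = mdt_protocol(),
                            geometry = stack_geometry(),
                            sigma = 0.02, seed = 1L,
                            srr = srr_config(),
                            b1 = 1500, b2 = 2500,
                            floor = 1e-6, window = c(0.5, 0.9),
                            mask_threshold = 0.5) {
  if (!all(c(b1, b2) %in% protocol$b))
    stop("b1/b2 must be shells of the protocol")
  if (b2 <= b1) stop("need b2 > b1")
  structure(list(phantom_shape = phantom_shape,
                 phantom_spacing = phantom_spacing, lesions = lesions,
                 protocol = protocol, geometry = geometry, sigma = sigma,
                 seed = as.integer(seed), srr = srr, b1 = b1, b2 = b2,
                 floor = floor, window = window,
                 mask_threshold = mask_threshold),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognised keys (all optional, defaults as in [pipeline_config()]):
#' `phantom: {shape, spacing}`, `lesions: [{kind, center, radius,
#' delta_md}]`, `protocol: {b, repetitions, te_ms, tr_ms}`, `geometry:
#' {in_plane, slice_thickness, rotation_angles, slice_profile}`,
#' `sigma`, `seed`, `srr: {target_spacing, regularizer, lambda, tol,
#' max_iter}`, `estimator: {b1, b2, floor, window}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  args <- list()
  ph <- cfg$phantom
  if (!is.null(ph$shape)) args$phantom_shape <- as.integer(unlist(ph$shape))
  if (!is.null(ph$spacing)) args$phantom_spacing <- ph$spacing
  if (!is.null(cfg$lesions))
    args$lesions <- lapply(cfg$lesions, function(l)
      lesion_spec(l$kind, unlist(l$center), l$radius, l$delta_md,
                  if (is.null(l$target_classes)) NULL else
                    unlist(l$target_classes)))
  if (!is.null(cfg$protocol))
    args$protocol <- btensor_protocol(
      unlist(cfg$protocol$b),
      repetitions = unlist(cfg$protocol$repetitions),
      echo_time = cfg$protocol$te_ms %||% NA_real_,
      repetition_time = cfg$protocol$tr_ms %||% NA_real_)
  if (!is.null(cfg$geometry)) {
    g <- cfg$geometry
    args$geometry <- stack_geometry(
      in_plane = unlist(g$in_plane) %||% c(1.53, 1.53),
      slice_thickness = g$slice_thickness %||% 5.2,
      rotation_axis = g$rotation_axis %||% "AP",
      rotation_angles = unlist(g$rotation_angles) %||% seq(0, 150, 30),
      slice_profile = g$slice_profile %||% "gaussian")
  }
  if (!is.null(cfg$sigma)) args$sigma <- cfg$sigma
  if (!is.null(cfg$seed)) args$seed <- cfg$seed
  if (!is.null(cfg$srr)) {
    s <- cfg$srr
    args$srr <- srr_config(
      target_spacing = s$target_spacing,
      regularizer = s$regularizer %||% "first_difference",
      lambda = s$lambda %||% 1e-2, tol = s$tol %||% 1e-6,
      max_iter = s$max_iter %||% 500L)
  }
  if (!is.null(cfg$estimator)) {
    e <- cfg$estimator
    if (!is.null(e$b1)) args$b1 <- e$b1
    if (!is.null(e$b2)) args$b2 <- e$b2
    if (!is.null(e$floor)) args$floor <- e$floor
    if (!is.null(e$window)) args$window <- unlist(e$window)
  }
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(serialize_config(cfg), tmp, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  unname(tools::md5sum(tmp))
}

serialize_config <- function(cfg) {
  list(phantom = list(shape = cfg$phantom_shape,
                      spacing = cfg$phantom_spacing),
       lesions = lapply(cfg$lesions, unclass),
       protocol = list(b = cfg$protocol$b,
                       repetitions = cfg$protocol$repetitions,
                       te_ms = attr(cfg$protocol, "echo_time"),
                       tr_ms = attr(cfg$protocol, "repetition_time")),
       geometry = unclass(cfg$geometry),
       sigma = cfg$sigma, seed = cfg$seed,
       srr = unclass(cfg$srr),
       estimator = list(b1 = cfg$b1, b2 = cfg$b2, floor = cfg$floor,
                        window = cfg$window))
}

# tri-linear resampling of a 3D array onto a target grid (zero fill)
resample_trilinear <- function(data, affine, target_dim, target_affine) {
  n <- prod(target_dim)
  ijk <- cbind(
    rep(seq_len(target_dim[1]) - 1, times = target_dim[2] * target_dim[3]),
    rep(rep(seq_len(target_dim[2]) - 1, each = target_dim[1]),
        times = target_dim[3]),
    rep(seq_len(target_dim[3]) - 1, each = target_dim[1] * target_dim[2]),
    rep(1, n))
  src <- ijk %*% t(target_affine) %*% t(solve(affine))
  ci <- src[, 1:3]
  f0 <- floor(ci)
  d <- ci - f0
  dm <- dim(data)
  out <- numeric(n)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- f0[, 1] + cx; iy <- f0[, 2] + cy; iz <- f0[, 3] + cz
    w <- (if (cx) d[, 1] else 1 - d[, 1]) *
         (if (cy) d[, 2] else 1 - d[, 2]) *
         (if (cz) d[, 3] else 1 - d[, 3])
    ok <- ix >= 0 & ix < dm[1] & iy >= 0 & iy < dm[2] & iz >= 0 & iz < dm[3]
    if (!any(ok)) next
    out[ok] <- out[ok] +
      w[ok] * data[cbind(ix[ok] + 1, iy[ok] + 1, iz[ok] + 1)]
  }
  array(out, target_dim)
}

#' Run the full pipeline in memory
#'
#' Builds the phantom (inserting any configured lesions), simulates the
#' rotated-stack session, averages repetitions, reconstructs every shell
#' to the isotropic target grid, computes the MDT and comparison ADC
#' maps, derives a cortical mask from the phantom's cortex fractions,
#' applies windowing, and compiles the CSF-fraction-stratified bias
#' report.  Identical config + seed gives identical output.
#'
#' @param cfg A `pipeline_config`.
#' @return A `pipeline_result` with the phantom, session metadata, SRR
#'   result, maps, bias report and lesion ROI statistics.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  phantom <- build_phantom(cfg$phantom_shape, cfg$phantom_spacing)
  for (l in cfg$lesions) phantom <- insert_lesion(phantom, l)

  session <- simulate_session(phantom, cfg$protocol, cfg$geometry,
                              sigma = cfg$sigma, seed = cfg$seed)
  avg <- average_repetitions(session)
  recon <- reconstruct_all_shells(avg, cfg$srr)

  i1 <- match(cfg$b1, recon$b)
  i2 <- match(cfg$b2, recon$b)
  s1 <- pmax(recon$volumes[[i1]], 0)
  s2 <- pmax(recon$volumes[[i2]], 0)
  mdt <- mdt_map_from_shells(s1, s2, cfg$b1, cfg$b2, recon$affine,
                             floor = cfg$floor, window = cfg$window)
  i0 <- match(0, recon$b)
  adc <- if (!is.na(i0)) {
    s0 <- pmax(recon$volumes[[i0]], 0)
    adc_map_from_shells(s0, s1, cfg$b1, recon$affine, floor = cfg$floor,
                        window = cfg$window)
  } else NULL

  # ground truth, CSF fraction and cortical mask on the map grid
  gt_hr <- ground_truth_tissue_md(phantom)
  gtv <- gt_hr$values; gtv[!gt_hr$valid] <- 0
  gt_map <- resample_trilinear(gtv, phantom$affine, recon$dim, recon$affine)
  gt_valid <- resample_trilinear(gt_hr$valid * 1, phantom$affine,
                                 recon$dim, recon$affine) > 0.99
  csf_map <- resample_trilinear(phantom$frac$csf, phantom$affine,
                                recon$dim, recon$affine)
  cortex_map <- resample_trilinear(phantom$frac$cortex, phantom$affine,
                                   recon$dim, recon$affine)
  cortical_mask <- cortex_map >= cfg$mask_threshold
  mdt_masked <- apply_cortical_mask(mdt, cortical_mask * 1)
  display <- render_window(mdt)

  bias <- if (!is.null(adc))
    pv_bias_report(csf_map, list(values = gt_map, valid = gt_valid),
                   mdt, adc)
  else NULL

  lesion_stats <- lapply(cfg$lesions, function(l)
    lesion_roi_stats(phantom, mdt, l))

  structure(list(config = cfg, config_hash = config_hash(cfg),
                 phantom = phantom, session = avg,
                 recon = recon, mdt = mdt, adc = adc,
                 mdt_masked = mdt_masked, display = display,
                 cortical_mask = cortical_mask,
                 ground_truth = list(values = gt_map, valid = gt_valid),
                 csf_fraction = csf_map,
                 bias_report = bias, lesion_stats = lesion_stats),
            class = "pipeline_result")
}

#' Lesion versus contralateral ROI statistics on a map
#'
#' The lesion ROI is the set of valid map voxels inside `radius_scale`
#' times the lesion radius whose (tri-linearly resampled) target-class
#' fraction is at least `frac_threshold`; the control ROI is its mirror
#' image through the mid-sagittal plane (x -> -x).  Shrinking the radius
#' keeps the ROI in the lesion core, away from the reconstruction's
#' partial-volume shell.
#'
#' @param phantom The `phantom_volume` the lesion was inserted into.
#' @param map An `mdt_map`.
#' @param lesion The `lesion_spec`.
#' @param frac_threshold Minimum target-class fraction.
#' @param radius_scale ROI radius as a fraction of the lesion radius.
#' @return List with `lesion_mean`, `contralateral_mean`, `difference`
#'   (um^2/ms) and the ROI voxel counts.
#' @export
lesion_roi_stats <- function(phantom, map, lesion, frac_threshold = 0.5,
                             radius_scale = 0.8) {
  stopifnot(inherits(map, "mdt_map"), inherits(lesion, "lesion_spec"))
  frac_hr <- Reduce(`+`, phantom$frac[lesion$target_classes])
  dm <- dim(map$values)
  frac <- resample_trilinear(frac_hr, phantom$affine, dm, map$affine)
  roi_mean <- function(center) {
    n <- prod(dm)
    ijk <- cbind(
      rep(seq_len(dm[1]) - 1, times = dm[2] * dm[3]),
      rep(rep(seq_len(dm[2]) - 1, each = dm[1]), times = dm[3]),
      rep(seq_len(dm[3]) - 1, each = dm[1] * dm[2]),
      rep(1, n))
    world <- ijk %*% t(map$affine)
    d2 <- (world[, 1] - center[1])^2 + (world[, 2] - center[2])^2 +
      (world[, 3] - center[3])^2
    sel <- array(d2 <= (radius_scale * lesion$radius)^2, dm) &
      frac >= frac_threshold & map$valid
    list(mean = if (any(sel)) mean(map$values[sel]) else NA_real_,
         n = sum(sel))
  }
  les <- roi_mean(lesion$center)
  ctr <- roi_mean(lesion$center * c(-1, 1, 1))
  list(lesion_mean = les$mean, contralateral_mean = ctr$mean,
       difference = les$mean - ctr$mean,
       n_lesion = les$n, n_contralateral = ctr$n)
}

#' Run the pipeline and write every stage to disk
#'
#' Writes the phantom, the simulated stacks, the per-shell
#' reconstructions, all maps (MDT, validity, masked, display, ADC), the
#' bias report (TSV + JSON) and a manifest recording the package
#' version, seed and config hash.  Existing outputs are not overwritten
#' unless `force = TRUE`.
#'
#' @param cfg A `pipeline_config`.
#' @param out_dir Output directory.
#' @param force Overwrite an existing manifest.
#' @return The `pipeline_result`, invisibly.
#' @export
run_pipeline_to_dir <- function(cfg, out_dir, force = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force)
    stop("output manifest already exists (use force = TRUE): ", manifest_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_pipeline(cfg)

  write_phantom(res$phantom, file.path(out_dir, "phantom"))
  write_stacks(res$session, file.path(out_dir, "stacks"))
  write_srr_result(res$recon, file.path(out_dir, "srr"))

  maps_dir <- file.path(out_dir, "maps")
  dir.create(maps_dir, showWarnings = FALSE)
  mv <- res$mdt$values; mv[!res$mdt$valid] <- 0
  write_nifti(mv, res$mdt$affine, file.path(maps_dir, "mdt.nii.gz"),
              datatype = "float")
  write_nifti(res$mdt$valid * 1, res$mdt$affine,
              file.path(maps_dir, "mdt_valid.nii.gz"), datatype = "float")
  mm <- res$mdt_masked$values; mm[!res$mdt_masked$valid] <- 0
  write_nifti(mm, res$mdt$affine, file.path(maps_dir, "mdt_cortical.nii.gz"),
              datatype = "float")
  write_nifti(res$display, res$mdt$affine,
              file.path(maps_dir, "mdt_display.nii.gz"), datatype = "float")
  if (!is.null(res$adc)) {
    av <- res$adc$values; av[!res$adc$valid] <- 0
    write_nifti(av, res$adc$affine, file.path(maps_dir, "adc.nii.gz"),
                datatype = "float")
  }
  if (!is.null(res$bias_report)) {
    utils::write.table(res$bias_report,
                       file.path(out_dir, "bias_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(res$bias_report, file.path(out_dir, "bias_report.json"),
                         dataframe = "rows", digits = NA)
  }
  jsonlite::write_json(
    list(package = "mdtmap",
         version = as.character(utils::packageVersion("mdtmap")),
         seed = cfg$seed, config_hash = res$config_hash,
         config = serialize_config(cfg),
         lesion_stats = res$lesion_stats),
    manifest_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(res)
}
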