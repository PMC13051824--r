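# Digital brain phantoms: concentric cortex/WM/CSF anatomy with
# anti-aliased partial-volume boundaries and insertable lesions.

PHANTOM_CLASSES <- c("csf", "cortex", "white_matter", "deep_nuclei")

default_diffusivities <- function() {
  c(cortex = 0.8, white_matter = 0.7, csf = FREE_WATER_MD, deep_nuclei = 0.7)
}

# voxel-center world coordinates along one axis (volume centred at 0)
axis_coords <- function(n, spacing) (seq_len(n) - 1 - (n - 1) / 2) * spacing

phantom_affine <- function(dim, spacing) {
  aff <- diag(c(rep(spacing, 3), 1))
  aff[1:3, 4] <- -(dim - 1) / 2 * spacing
  aff
}

# Label one set of sample points (world mm, vectors of equal length).
# Codes: 0 background, 1 csf, 2 cortex, 3 white_matter, 4 deep_nuclei.
# Geometry: spherical head; subarachnoid CSF rim; cortical ribbon; WM core;
# central spherical ventricle; two sulcal CSF clefts along the diagonal
# planes x = z and x = -z (mirror-symmetric in x); optional paired deep
# nuclei.  All radii in mm.
label_points <- function(x, y, z, g) {
  r <- sqrt(x^2 + y^2 + z^2)
  lab <- integer(length(r))                       # background
  inside <- r <= g$head_radius
  lab[inside] <- 1L                               # provisional CSF
  cortex <- inside & r <= g$cortex_outer & r > g$cortex_inner
  lab[cortex] <- 2L
  wm <- inside & r <= g$cortex_inner
  lab[wm] <- 3L
  # sulcal clefts cut CSF through the ribbon (not into WM)
  if (g$sulcal_width > 0) {
    hw <- g$sulcal_width / 2
    in_sulcus <- r > g$cortex_inner & r <= g$cortex_outer &
      (abs(x - z) / sqrt(2) < hw | abs(x + z) / sqrt(2) < hw)
    lab[in_sulcus & inside] <- 1L
  }
  # periventricular CSF
  lab[r <= g$ventricle_radius] <- 1L
  if (isTRUE(g$deep_nuclei)) {
    for (s in c(-1, 1)) {
      d2 <- (x - s * g$nucleus_offset[1])^2 + (y - g$nucleus_offset[2])^2 +
        (z - g$nucleus_offset[3])^2
      lab[d2 <= g$nucleus_radius^2 & lab == 3L] <- 4L
    }
  }
  lab
}

#' Build a digital brain phantom
#'
#' Constructs a spherical-head phantom with, from outside in: background,
#' a subarachnoid CSF rim with sulcal invaginations, a cortical ribbon, a
#' white-matter core with optional paired deep nuclei, and a central
#' CSF-filled ventricle.  Voxels on tissue boundaries carry fractional
#' compartment mixtures computed by supersampled occupancy, so partial
#' volume — the phenomenon the MDT estimator is designed to defeat — is
#' represented explicitly rather than as hard labels.
#'
#' @param shape Grid dimensions, e.g. `c(48, 48, 48)`; minimum 16 per axis.
#' @param spacing Isotropic voxel spacing, mm.
#' @param head_radius Outer head radius, mm; default 44 percent of the
#'   smallest field of view extent.
#' @param csf_rim_mm Thickness of the subarachnoid CSF rim, mm.
#' @param ribbon_mm Cortical ribbon thickness, mm (must be at least one
#'   voxel).
#' @param sulcal_width_mm Width of the sulcal CSF clefts, mm (0 disables).
#' @param ventricle_radius Radius of the central ventricle, mm; default
#'   11 percent of the smallest field of view extent.
#' @param deep_nuclei Logical: include paired deep gray nuclei.
#' @param diffusivities Named vector of per-class mean diffusivities,
#'   um^2/ms; defaults cortex 0.8, white_matter 0.7, csf 3.0,
#'   deep_nuclei 0.7.
#' @param supersample Occupancy supersampling factor per axis (>= 1;
#'   default 3, i.e. 27 subsamples per voxel).
#' @return A `phantom_volume`: list with `dim`, `spacing`, `affine`,
#'   per-class fraction arrays `frac`, per-class diffusivity arrays `md`,
#'   the geometry parameters and the lesion log.
#' @export
build_phantom <- function(shape = c(48L, 48L, 48L), spacing = 1,
                          head_radius = NULL, csf_rim_mm = 2,
                          ribbon_mm = 3.5, sulcal_width_mm = 1.5,
                          ventricle_radius = NULL, deep_nuclei = TRUE,
                          diffusivities = default_diffusivities(),
                          supersample = 3L) {
  shape <- as.integer(rep_len(shape, 3L))
  if (any(shape < 16L)) stop("phantom grid must be at least 16 voxels per axis")
  if (spacing <= 0) stop("spacing must be positive")
  if (ribbon_mm < spacing) stop("cortical ribbon must be at least one voxel thick")
  supersample <- max(1L, as.integer(supersample))
  fov <- shape * spacing
  if (is.null(head_radius)) head_radius <- 0.44 * min(fov)
  if (is.null(ventricle_radius)) ventricle_radius <- 0.11 * min(fov)
  stopifnot(all(PHANTOM_CLASSES %in% names(diffusivities)))

  g <- list(head_radius = head_radius,
            cortex_outer = head_radius - csf_rim_mm,
            cortex_inner = head_radius - csf_rim_mm - ribbon_mm,
            sulcal_width = sulcal_width_mm,
            ventricle_radius = ventricle_radius,
            deep_nuclei = deep_nuclei,
            nucleus_radius = 0.07 * min(fov),
            nucleus_offset = c(0.14, -0.08, 0) * min(fov))
  if (g$cortex_inner <= ventricle_radius + 2 * spacing)
    stop("geometry leaves no white-matter core")

  xs <- axis_coords(shape[1], spacing)
  ys <- axis_coords(shape[2], spacing)
  zs <- axis_coords(shape[3], spacing)
  X <- array(rep(xs, times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(ys, each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(zs, each = shape[1] * shape[2]), shape)

  counts <- lapply(PHANTOM_CLASSES, function(k) array(0, shape))
  names(counts) <- PHANTOM_CLASSES
  offs <- (seq_len(supersample) - (supersample + 1) / 2) / supersample * spacing
  codes <- c(csf = 1L, cortex = 2L, white_matter = 3L, deep_nuclei = 4L)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    lab <- label_points(X + ox, Y + oy, Z + oz, g)
    for (k in PHANTOM_CLASSES)
      counts[[k]] <- counts[[k]] + (lab == codes[[k]])
  }
  frac <- lapply(counts, function(a) a / supersample^3)
  md <- lapply(PHANTOM_CLASSES, function(k) array(diffusivities[[k]], shape))
  names(md) <- PHANTOM_CLASSES

  structure(list(dim = shape, spacing = spacing,
                 affine = phantom_affine(shape, spacing),
                 frac = frac, md = md,
                 diffusivities = diffusivities,
                 geometry = g, lesions = list()),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("<phantom_volume> %s voxels @ %.3g mm, %d lesion(s)\n",
              paste(x$dim, collapse = "x"), x$spacing, length(x$lesions)))
  tf <- tissue_fraction(x)
  cat(sprintf("  head volume: %.0f voxels; mean CSF fraction in head: %.3f\n",
              sum(tf + x$frac$csf > 0.5),
              mean(x$frac$csf[tf + x$frac$csf > 0.5])))
  invisible(x)
}

# total (non-CSF, non-background) tissue fraction per voxel
tissue_fraction <- function(phantom) {
  Reduce(`+`, phantom$frac[setdiff(PHANTOM_CLASSES, "csf")])
}

#' Specify a lesion to insert into a phantom
#'
#' Three scenario kinds mirror the clinical patterns MDT is used on:
#' `focal_hyperintense` raises cortical diffusivity (focal cortical
#' dysplasia-like), `tumor` raises diffusivity in cortex and white matter
#' (glioma-like), `ischemia` lowers diffusivity (cytotoxic edema-like).
#'
#' @param kind One of `"focal_hyperintense"`, `"tumor"`, `"ischemia"`.
#' @param center Lesion centre in world coordinates, mm (length 3).
#' @param radius Lesion radius, mm, positive.
#' @param delta_md Magnitude of the diffusivity change, um^2/ms.  Applied
#'   with positive sign for `focal_hyperintense` and `tumor` and negative
#'   sign for `ischemia`.
#' @param target_classes Tissue classes affected; defaults by kind
#'   (cortex; cortex + white matter; cortex + white matter).
#' @return A `lesion_spec`.
#' @export
lesion_spec <- function(kind = c("focal_hyperintense", "tumor", "ischemia"),
                        center, radius, delta_md, target_classes = NULL) {
  kind <- match.arg(kind)
  if (radius <= 0) stop("lesion radius must be positive")
  stopifnot(length(center) == 3L)
  if (is.null(target_classes))
    target_classes <- switch(kind,
      focal_hyperintense = "cortex",
      tumor = c("cortex", "white_matter"),
      ischemia = c("cortex", "white_matter"))
  stopifnot(all(target_classes %in% setdiff(PHANTOM_CLASSES, "csf")))
  structure(list(kind = kind, center = as.numeric(center),
                 radius = radius, delta_md = delta_md,
                 target_classes = target_classes),
            class = "lesion_spec")
}

#' Insert a lesion into a phantom
#'
#' Shifts the per-voxel diffusivity of the lesion's target classes inside
#' its sphere; compartment fractions are untouched, so the ground-truth
#' tissue diffusivity changes but the anatomy does not.
#'
#' @param phantom A `phantom_volume`.
#' @param lesion A `lesion_spec`.
#' @return The modified `phantom_volume`.
#' @export
insert_lesion <- function(phantom, lesion) {
  stopifnot(inherits(phantom, "phantom_volume"), inherits(lesion, "lesion_spec"))
  xs <- axis_coords(phantom$dim[1], phantom$spacing)
  ys <- axis_coords(phantom$dim[2], phantom$spacing)
  zs <- axis_coords(phantom$dim[3], phantom$spacing)
  d2 <- outer(outer((xs - lesion$center[1])^2, (ys - lesion$center[2])^2, `+`),
              (zs - lesion$center[3])^2, `+`)
  inside <- d2 <= lesion$radius^2
  if (!any(inside)) stop("lesion lies wholly outside the volume")
  shift <- if (lesion$kind == "ischemia") -abs(lesion$delta_md) else lesion$delta_md
  for (k in lesion$target_classes) {
    new_md <- phantom$md[[k]]
    new_md[inside] <- new_md[inside] + shift
    if (any(new_md[inside] <= 0.05))
      stop("lesion would drive ", k, " diffusivity to <= 0.05 um^2/ms")
    phantom$md[[k]] <- new_md
  }
  phantom$lesions <- c(phantom$lesions, list(lesion))
  phantom
}

#' Ground-truth tissue diffusivity map
#'
#' The quantity the MDT estimator targets: the fraction-weighted mean
#' diffusivity over the non-CSF, non-background compartments of each
#' voxel.  CSF is excluded *by definition* — a voxel that is 60 percent
#' cortex at 0.8 and 40 percent CSF has ground truth 0.8.  Voxels with
#' total tissue fraction below `min_tissue` are marked invalid.
#'
#' @param phantom A `phantom_volume`.
#' @param min_tissue Minimum tissue fraction for a voxel to be valid.
#' @return List with `values` (um^2/ms; NA where invalid), `valid`
#'   (logical array) and `affine`.
#' @export
ground_truth_tissue_md <- function(phantom, min_tissue = 0.05) {
  stopifnot(inherits(phantom, "phantom_volume"))
  tissue <- setdiff(PHANTOM_CLASSES, "csf")
  tf <- tissue_fraction(phantom)
  num <- Reduce(`+`, lapply(tissue, function(k) phantom$frac[[k]] * phantom$md[[k]]))
  valid <- tf >= min_tissue
  values <- array(NA_real_, phantom$dim)
  values[valid] <- num[valid] / tf[valid]
  list(values = values, valid = valid, affine = phantom$affine)
}

#' Noiseless shell signal of a phantom
#'
#' Evaluates the mixture forward model per voxel for one spherical-encoding
#' shell: `sum_k frac_k * exp(-b * md_k * 1e-3)`.
#'
#' @param phantom A `phantom_volume`.
#' @param b b-value, s/mm^2.
#' @return 3D array of signals in `[0, 1]`.
#' @export
phantom_shell_signal <- function(phantom, b) {
  stopifnot(inherits(phantom, "phantom_volume"), length(b) == 1L, b >= 0)
  sig <- array(0, phantom$dim)
  for (k in PHANTOM_CLASSES)
    sig <- sig + phantom$frac[[k]] * exp(-b * phantom$md[[k]] * 1e-3)
  sig
}

#' Write a phantom to disk (NIfTI fraction maps + JSON manifest)
#'
#' One 4D NIfTI holds the four class fraction maps (in `PHANTOM_CLASSES`
#' order), a second holds the per-class diffusivity maps; the manifest
#' records spacing, geometry, class diffusivities and lesions.
#'
#' @param phantom A `phantom_volume`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frac4 <- array(unlist(phantom$frac, use.names = FALSE),
                 c(phantom$dim, length(PHANTOM_CLASSES)))
  md4 <- array(unlist(phantom$md, use.names = FALSE),
               c(phantom$dim, length(PHANTOM_CLASSES)))
  write_nifti(frac4, phantom$affine, file.path(dir, "fractions.nii.gz"))
  write_nifti(md4, phantom$affine, file.path(dir, "diffusivity.nii.gz"))
  gt <- ground_truth_tissue_md(phantom)
  gtv <- gt$values; gtv[!gt$valid] <- 0
  write_nifti(gtv, phantom$affine, file.path(dir, "ground_truth_mdt.nii.gz"))
  write_nifti(array(as.numeric(gt$valid), phantom$dim), phantom$affine,
              file.path(dir, "ground_truth_valid.nii.gz"))
  jsonlite::write_json(
    list(classes = as.list(PHANTOM_CLASSES),
         spacing = phantom$spacing, dim = phantom$dim,
         diffusivities = as.list(phantom$diffusivities),
         geometry = phantom$geometry[c("head_radius", "cortex_outer",
                                       "cortex_inner", "sulcal_width",
                                       "ventricle_radius", "nucleus_radius")],
         lesions = lapply(phantom$lesions, unclass)),
    file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom written by [write_phantom()]
#'
#' @param dir Directory containing `fractions.nii.gz`, `diffusivity.nii.gz`
#'   and `phantom.json`.
#' @return A `phantom_volume`.
#' @export
read_phantom <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "phantom.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fr <- read_nifti(file.path(dir, "fractions.nii.gz"))
  md <- read_nifti(file.path(dir, "diffusivity.nii.gz"))
  dm <- dim(fr$data)[1:3]
  frac <- lapply(seq_along(PHANTOM_CLASSES), function(i) fr$data[, , , i])
  mdl <- lapply(seq_along(PHANTOM_CLASSES), function(i) md$data[, , , i])
  names(frac) <- names(mdl) <- PHANTOM_CLASSES
  lesions <- lapply(man$lesions, function(l)
    lesion_spec(l$kind, unlist(l$center), l$radius, l$delta_md,
                unlist(l$target_classes)))
  structure(list(dim = as.integer(dm), spacing = as.numeric(man$spacing),
                 affine = fr$affine, frac = frac, md = mdl,
                 diffusivities = unlist(man$diffusivities),
                 geometry = as.list(man$geometry), lesions = lesions),
            class = "phantom_volume")
}
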