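# Thin NIfTI layer over RNifti: lossless (data, affine) round trips with
# RAS+ enforced on read.

#' Read a 3D/4D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file and returns the data array and its
#' voxel-to-world affine.  Images not stored in RAS+ orientation are
#' reoriented (data permuted/flipped consistently) with a warning.
#'
#' @param path Path to a NIfTI file.
#' @return List with `data` (3D or 4D array) and `affine` (4x4 matrix).
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd < 3L || nd > 4L)
    stop("expected a 3D or 4D NIfTI, got ", nd, "D: ", path)
  orient <- RNifti::orientation(img)
  if (orient != "RAS") {
    warning("reorienting ", path, " from ", orient, " to RAS+")
    RNifti::orientation(img) <- "RAS"
  }
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  data <- array(as.numeric(img), dim(img))
  list(data = data, affine = aff)
}

#' Write a 3D/4D array as NIfTI
#'
#' Stores the affine in both the sform and qform (code 2, "aligned") so
#' the geometry round-trips losslessly.
#'
#' @param data 3D or 4D numeric array.
#' @param affine 4x4 voxel-to-world affine (RAS+).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; `"double"` (default) round-trips
#'   bitwise, `"float"` is the conventional choice for maps.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, affine, path, datatype = "double") {
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L) stop("only 3D or 4D volumes are supported")
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  img <- RNifti::asNifti(data, datatype = datatype)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
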