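# Multi-compartment Gaussian diffusion signal under b-tensor encoding.
#
# Unit conventions used throughout the package: b-values in s/mm^2,
# diffusivities in um^2/ms.  The product b * D is made dimensionless by an
# explicit factor of 1e-3 (1 um^2/ms = 1e-3 mm^2/s), so that attenuation is
# exp(-b * D * 1e-3).

#' Free-water (CSF) diffusivity at body temperature
#'
#' The mean diffusivity assigned to cerebrospinal fluid, modeled as a free
#' water compartment: 3.0 um^2/ms.  At b = 2500 s/mm^2 a compartment with
#' this diffusivity retains `exp(-7.5)`, about 0.055 percent, of its b = 0
#' signal, which is what makes the high-b two-shell estimate insensitive to
#' CSF partial volume.
#'
#' @format A length-one numeric, um^2/ms.
#' @export
FREE_WATER_MD <- 3.0

#' Create a Gaussian diffusion compartment
#'
#' A compartment is characterised by its mean diffusivity, an optional full
#' diffusion tensor (needed only for linear, i.e. directional, encoding of
#' anisotropic media), and the signal fraction it contributes to a voxel.
#' Fractions are signal fractions at the protocol's echo time; relaxation
#' weighting is folded into them rather than modeled explicitly.
#'
#' @param md Mean diffusivity, um^2/ms.  May be omitted when `tensor` is
#'   given, in which case `md = tr(tensor)/3`.
#' @param tensor Optional symmetric positive semi-definite 3x3 diffusion
#'   tensor, um^2/ms.  If both `md` and `tensor` are supplied they must
#'   agree (`tr(tensor)/3 == md` within 1e-9).
#' @param fraction Signal fraction in `[0, 1]`.
#' @return An object of class `diffusion_compartment`.
#' @examples
#' csf <- diffusion_compartment(md = FREE_WATER_MD, fraction = 0.3)
#' wm  <- diffusion_compartment(tensor = diag(c(1.7, 0.2, 0.2)), fraction = 0.7)
#' wm$md  # 0.7
#' @export
diffusion_compartment <- function(md = NULL, tensor = NULL, fraction = 1) {
  if (is.null(md) && is.null(tensor))
    stop("supply `md`, `tensor`, or both")
  if (!is.null(tensor)) {
    tensor <- as.matrix(tensor)
    if (!all(dim(tensor) == c(3L, 3L)))
      stop("`tensor` must be a 3x3 matrix")
    if (max(abs(tensor - t(tensor))) > 1e-9)
      stop("`tensor` must be symmetric")
    ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-9)
      stop("`tensor` must be positive semi-definite")
    md_t <- sum(diag(tensor)) / 3
    if (!is.null(md) && abs(md - md_t) > 1e-9)
      stop("`md` and tr(tensor)/3 disagree: ", md, " vs ", md_t)
    md <- md_t
  }
  stopifnot(length(md) == 1L, is.finite(md), length(fraction) == 1L)
  if (md <= 0) stop("`md` must be positive")
  if (fraction < 0 || fraction > 1) stop("`fraction` must be in [0, 1]")
  structure(list(md = md, tensor = tensor, fraction = fraction),
            class = "diffusion_compartment")
}

#' Create a compartment mixture (voxel content model)
#'
#' An ordered list of compartments whose fractions sum to at most 1; any
#' remainder is zero-signal background (e.g. air).  An empty mixture is a
#' pure background voxel.
#'
#' @param ... `diffusion_compartment` objects, or a single list of them.
#' @return An object of class `compartment_mixture`.
#' @export
compartment_mixture <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && !inherits(comps[[1L]], "diffusion_compartment"))
    comps <- comps[[1L]]
  for (c in comps)
    if (!inherits(c, "diffusion_compartment"))
      stop("all elements must be diffusion_compartment objects")
  total <- sum(vapply(comps, `[[`, numeric(1), "fraction"))
  if (length(comps) && total > 1 + 1e-9)
    stop("compartment fractions sum to ", total, " > 1")
  structure(list(compartments = comps), class = "compartment_mixture")
}

#' Signal attenuation of one compartment under b-tensor encoding
#'
#' For spherical (isotropic) tensor encoding a Gaussian compartment
#' attenuates as `exp(-b * md * 1e-3)` regardless of tensor orientation;
#' for linear encoding along unit vector g it attenuates as
#' `exp(-b * (g' D g) * 1e-3)`.
#'
#' @param comp A `diffusion_compartment`.
#' @param b b-value(s), s/mm^2, nonnegative.
#' @param shape `"spherical"` or `"linear"`.
#' @param direction Unit 3-vector; required iff `shape == "linear"`.
#' @return Attenuation in `(0, 1]`, same length as `b`.
#' @examples
#' csf <- diffusion_compartment(md = FREE_WATER_MD)
#' compartment_attenuation(csf, 2500)  # exp(-7.5) ~ 5.53e-4
#' @export
compartment_attenuation <- function(comp, b, shape = c("spherical", "linear"),
                                    direction = NULL) {
  stopifnot(inherits(comp, "diffusion_compartment"))
  shape <- match.arg(shape)
  if (any(b < 0)) stop("negative b-value")
  if (shape == "spherical") {
    d_eff <- comp$md
  } else {
    if (is.null(direction)) stop("linear encoding requires a direction")
    direction <- as.numeric(direction)
    nrm <- sqrt(sum(direction^2))
    if (!isTRUE(abs(nrm - 1) <= 1e-9))
      stop("direction must have unit norm (got ", nrm, ")")
    d_eff <- if (is.null(comp$tensor)) comp$md else
      as.numeric(direction %*% comp$tensor %*% direction)
  }
  exp(-b * d_eff * 1e-3)
}

#' Signal of a compartment mixture
#'
#' Fraction-weighted sum of the compartment attenuations; this is the
#' forward model of a partial-volume voxel.  At b = 0 it returns the total
#' signal fraction; an empty mixture returns 0.
#'
#' @inheritParams compartment_attenuation
#' @param mixture A `compartment_mixture`.
#' @return Signal in `[0, 1]`, same length as `b`.
#' @export
mixture_signal <- function(mixture, b, shape = c("spherical", "linear"),
                           direction = NULL) {
  stopifnot(inherits(mixture, "compartment_mixture"))
  shape <- match.arg(shape)
  if (any(b < 0)) stop("negative b-value")
  s <- rep(0, length(b))
  for (comp in mixture$compartments)
    s <- s + comp$fraction * compartment_attenuation(comp, b, shape, direction)
  s
}

#' Add Rician noise to a magnitude signal
#'
#' Magnitude MRI noise: the noiseless signal is perturbed by independent
#' zero-mean Gaussian noise in the real and imaginary channels and the
#' modulus is taken, `|s + n1 + i n2|`.  At low SNR this rectifies toward a
#' positive noise floor (Rayleigh mean `sigma * sqrt(pi/2)` at s = 0).
#'
#' @param signal Nonnegative signal value(s); any numeric array.
#' @param sigma Noise standard deviation per channel, `>= 0`; `sigma = 0`
#'   returns the input unchanged.
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG stream is used.
#' @return Noisy magnitude, same shape as `signal`.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (length(sigma) != 1L || sigma < 0) stop("`sigma` must be a scalar >= 0")
  if (sigma == 0) return(signal)
  if (!is.null(seed)) set.seed(seed)
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, sd = sigma))^2 +
              stats::rnorm(n, sd = sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

#' @export
print.diffusion_compartment <- function(x, ...) {
  cat(sprintf("<diffusion_compartment> md = %.4g um^2/ms, fraction = %.3g%s\n",
              x$md, x$fraction,
              if (is.null(x$tensor)) "" else ", full tensor"))
  invisible(x)
}

#' @export
print.compartment_mixture <- function(x, ...) {
  cat(sprintf("<compartment_mixture> %d compartment(s), total fraction %.3g\n",
              length(x$compartments),
              sum(vapply(x$compartments, `[[`, numeric(1), "fraction"))))
  invisible(x)
}
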