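# Model-based super-resolution reconstruction.
#
# Each shell's isotropic volume x is recovered from its rotated
# thick-slice stacks y_r by regularized least squares,
#
#     argmin_x  sum_r || A_r x - y_r ||^2  +  lambda || L x ||^2,
#
# where A_r is the sparse forward operator of rotation r (resample, slice
# blur, decimate) and L is the identity or the 3D first-difference
# operator.  The normal equations are solved with conjugate gradients;
# matrix-vector products use the stored sparse A_r and their transposes,
# so the adjoint is exact.

#' Configure the super-resolution reconstruction
#'
#' @param target_spacing Isotropic output spacing, mm.  `NULL` (default)
#'   uses the stack geometry's first in-plane spacing, i.e. the
#'   super-resolved grid matches the in-plane resolution.
#' @param regularizer `"first_difference"` (default) or `"identity"`.
#' @param lambda Nonnegative regularization weight.  With
#'   `lambda_scale = "relative"` (default) the effective weight is
#'   `lambda` times the mean diagonal of the data term `sum_r A_r' A_r`,
#'   so the default 1e-2 means "1 percent of the data-term scale"
#'   independent of geometry; `"absolute"` uses `lambda` as-is.
#' @param tol Relative-residual stopping tolerance of the solver.
#' @param max_iter Iteration cap; non-convergence is reported via the
#'   diagnostics and a warning, and the partial result is returned.
#' @param init `"zeros"` (default) or `"stack_average"` (adjoint-based
#'   back-projection normalised by sensitivity).
#' @param lambda_scale `"relative"` or `"absolute"`; see `lambda`.
#' @return An `srr_config`.
#' @export
srr_config <- function(target_spacing = NULL,
                       regularizer = c("first_difference", "identity"),
                       lambda = 1e-2, tol = 1e-6, max_iter = 500L,
                       init = c("zeros", "stack_average"),
                       lambda_scale = c("relative", "absolute")) {
  regularizer <- match.arg(regularizer)
  init <- match.arg(init)
  lambda_scale <- match.arg(lambda_scale)
  if (!is.null(target_spacing) && target_spacing <= 0)
    stop("target spacing must be positive")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (tol <= 0) stop("tolerance must be positive")
  structure(list(target_spacing = target_spacing, regularizer = regularizer,
                 lambda = lambda, tol = tol, max_iter = as.integer(max_iter),
                 init = init, lambda_scale = lambda_scale),
            class = "srr_config")
}

# 3D forward-difference operator (3 * n rows, zero rows at the far edges)
first_difference_operator <- function(dm) {
  n <- prod(dm)
  diff_axis <- function(axis) {
    idx <- array(seq_len(n), dm)
    lo <- switch(axis,
                 idx[-dm[1], , , drop = FALSE],
                 idx[, -dm[2], , drop = FALSE],
                 idx[, , -dm[3], drop = FALSE])
    hi <- switch(axis,
                 idx[-1, , , drop = FALSE],
                 idx[, -1, , drop = FALSE],
                 idx[, , -1, drop = FALSE])
    m <- length(lo)
    Matrix::sparseMatrix(i = c(seq_len(m), seq_len(m)),
                         j = c(as.integer(hi), as.integer(lo)),
                         x = c(rep(1, m), rep(-1, m)),
                         dims = c(m, n))
  }
  rbind(diff_axis(1L), diff_axis(2L), diff_axis(3L))
}

# Conjugate-residual iteration on the (SPD) normal equations: the
# conjugate-direction Krylov method that minimises the residual 2-norm
# at every step, so the residual history is monotone non-increasing
# (plain CG minimises the error in the M-norm and its residual can
# oscillate).  apply_M must implement
# x -> (sum_r A_r' A_r + lambda L'L) x; one application per iteration.
cg_solve <- function(apply_M, rhs, x0, tol, max_iter) {
  x <- x0
  r <- rhs - apply_M(x)
  p <- r
  Mr <- apply_M(r)
  Mp <- Mr
  rMr <- sum(r * Mr)
  b_norm <- sqrt(sum(rhs * rhs))
  if (b_norm == 0) b_norm <- 1
  resid <- sqrt(sum(r * r)) / b_norm
  history <- resid
  it <- 0L
  while (resid > tol && it < max_iter) {
    denom <- sum(Mp * Mp)
    if (denom <= 0 || rMr <= 0) break   # numerically converged/singular
    alpha <- rMr / denom
    x <- x + alpha * p
    r <- r - alpha * Mp
    Mr <- apply_M(r)
    rMr_new <- sum(r * Mr)
    beta <- rMr_new / rMr
    p <- r + beta * p
    Mp <- Mr + beta * Mp
    rMr <- rMr_new
    resid <- sqrt(sum(r * r)) / b_norm
    history <- c(history, resid)
    it <- it + 1L
  }
  list(x = x, iterations = it, residual = resid,
       residual_history = history, converged = resid <= tol)
}

# Shared machinery: operators from the target grid to each stored stack
# frame, data-term diagonal, regularizer, effective lambda.
srr_system <- function(session, cfg) {
  fov <- session$hr_fov
  ts <- cfg$target_spacing
  if (is.null(ts)) ts <- session$geometry$in_plane[1]
  if (ts > session$geometry$slice_thickness + 1e-9)
    stop("target spacing must not exceed the slice thickness")
  dm <- pmax(2L, as.integer(round(fov / ts)))
  ops <- lapply(session$stacks, function(st)
    build_stack_operator(dm, ts, st$frame, session$geometry$slice_profile))
  opsT <- lapply(ops, Matrix::t)
  diag_data <- Reduce(`+`, lapply(ops, function(A) Matrix::colSums(A^2)))
  lambda_eff <- if (cfg$lambda_scale == "relative")
    cfg$lambda * mean(diag_data) else cfg$lambda
  L <- switch(cfg$regularizer,
              identity = Matrix::Diagonal(prod(dm)),
              first_difference = first_difference_operator(dm))
  LT <- Matrix::t(L)
  apply_M <- function(v) {
    out <- numeric(length(v))
    for (r in seq_along(ops))
      out <- out + as.numeric(opsT[[r]] %*% (ops[[r]] %*% v))
    out + lambda_eff * as.numeric(LT %*% (L %*% v))
  }
  affine <- phantom_affine(dm, ts)
  list(dim = dm, spacing = ts, affine = affine, ops = ops, opsT = opsT,
       apply_M = apply_M, lambda_eff = lambda_eff, diag_data = diag_data)
}

#' Reconstruct one shell's isotropic volume from its rotated stacks
#'
#' Solves the regularized least-squares problem for a single shell given
#' a repetition-averaged `lowres_stacks` session.  With fewer than two
#' rotations the problem is under-determined beyond the regularization
#' and an error is raised.
#'
#' @param session A repetition-averaged `lowres_stacks`
#'   (see [average_repetitions()]).
#' @param shell Shell index into the session's protocol.
#' @param cfg An [srr_config()].
#' @param system Internal: a precomputed operator system (used by
#'   [reconstruct_all_shells()] to share operators across shells).
#' @return List with `data` (3D array on the isotropic target grid),
#'   `affine`, `spacing`, and `diagnostics` (iterations, relative
#'   residual, convergence flag, effective lambda).
#' @export
reconstruct_shell <- function(session, shell = 1L, cfg = srr_config(),
                              system = NULL) {
  stopifnot(inherits(session, "lowres_stacks"), inherits(cfg, "srr_config"))
  if (!session$averaged)
    session <- average_repetitions(session)
  if (length(session$stacks) < 2L)
    stop("at least two rotations are required for super-resolution")
  if (is.null(system)) system <- srr_system(session, cfg)
  ys <- lapply(session$stacks, function(st)
    as.numeric(st$shells[[shell]][, , , 1]))
  rhs <- numeric(prod(system$dim))
  for (r in seq_along(ys))
    rhs <- rhs + as.numeric(system$opsT[[r]] %*% ys[[r]])
  x0 <- if (cfg$init == "zeros") numeric(length(rhs)) else
    rhs / pmax(system$diag_data, 1e-12)
  sol <- cg_solve(system$apply_M, rhs, x0, cfg$tol, cfg$max_iter)
  if (!sol$converged)
    warning(sprintf(
      "SRR did not converge in %d iterations (relative residual %.3g); partial result returned",
      sol$iterations, sol$residual))
  list(data = array(sol$x, system$dim), affine = system$affine,
       spacing = system$spacing,
       diagnostics = list(iterations = sol$iterations,
                          residual = sol$residual,
                          residual_history = sol$residual_history,
                          converged = sol$converged,
                          lambda_eff = system$lambda_eff))
}

#' Reconstruct every shell onto one common isotropic grid
#'
#' All shells share the stack geometry, so the forward operators are built
#' once and reused; shell order is preserved and the b = 0 shell (if
#' present) is included.
#'
#' @inheritParams reconstruct_shell
#' @return An `srr_result`: list with `volumes` (one 3D array per shell,
#'   named `b<value>`), `b` (shell b-values), common `affine` and
#'   `spacing`, per-shell `diagnostics`, and the `config`.
#' @export
reconstruct_all_shells <- function(session, cfg = srr_config()) {
  stopifnot(inherits(session, "lowres_stacks"))
  if (!session$averaged) session <- average_repetitions(session)
  system <- srr_system(session, cfg)
  ns <- nrow(session$protocol)
  volumes <- vector("list", ns)
  diagnostics <- vector("list", ns)
  for (s in seq_len(ns)) {
    rec <- reconstruct_shell(session, s, cfg, system = system)
    volumes[[s]] <- rec$data
    diagnostics[[s]] <- rec$diagnostics
  }
  names(volumes) <- names(diagnostics) <-
    paste0("b", format(session$protocol$b, trim = TRUE, scientific = FALSE))
  structure(list(volumes = volumes, b = session$protocol$b,
                 affine = system$affine, spacing = system$spacing,
                 dim = system$dim, diagnostics = diagnostics, config = cfg),
            class = "srr_result")
}

#' @export
print.srr_result <- function(x, ...) {
  cat(sprintf("<srr_result> %d shell(s) on a %s grid @ %.4g mm isotropic\n",
              length(x$volumes), paste(x$dim, collapse = "x"), x$spacing))
  for (s in seq_along(x$volumes))
    cat(sprintf("  %s: %d solver iteration(s), relative residual %.3g%s\n",
                names(x$volumes)[s], x$diagnostics[[s]]$iterations,
                x$diagnostics[[s]]$residual,
                if (x$diagnostics[[s]]$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Write per-shell reconstructions + diagnostics to disk
#'
#' @param result An `srr_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_srr_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(result$volumes))
    write_nifti(result$volumes[[s]], result$affine,
                file.path(dir, paste0("shell_", names(result$volumes)[s],
                                      ".nii.gz")))
  jsonlite::write_json(
    list(b = result$b, spacing = result$spacing, dim = result$dim,
         config = unclass(result$config),
         diagnostics = lapply(result$diagnostics, function(d)
           d[c("iterations", "residual", "converged", "lambda_eff")])),
    file.path(dir, "srr.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
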