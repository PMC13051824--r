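# Build a minimal averaged session from explicit stack data (used to feed
# the solver exactly the y vectors an oracle also sees).
session_from_stacks <- function(frames, ys, geometry, hr_dim, spacing) {
  structure(list(
    stacks = lapply(seq_along(frames), function(r)
      list(frame = frames[[r]],
           shells = list(array(ys[[r]], c(frames[[r]]$dim, 1))))),
    protocol = btensor_protocol(0, repetitions = 1L),
    geometry = geometry, sigma = 0, seed = NULL,
    hr_fov = hr_dim * spacing, frame_fov = (hr_dim - 1) * spacing,
    averaged = TRUE), class = "lowres_stacks")
}

test_that("solver matches the dense normal-equation oracle on tiny instances", {
  set.seed(42)
  for (hd in list(c(6L, 6L, 6L), c(10L, 9L, 8L), c(12L, 12L, 12L))) {
    geo <- stack_geometry(in_plane = c(1, 1), slice_thickness = 2,
                          rotation_angles = c(0, 60, 120))
    x0 <- array(stats::runif(prod(hd)), hd)
    frames <- lapply(geo$rotation_angles, mdtmap:::stack_frame,
                     geometry = geo, fov = (hd - 1) * 1)
    As <- lapply(frames, function(fr)
      mdtmap:::build_stack_operator(hd, 1, fr, "gaussian"))
    ys <- lapply(As, function(A) as.numeric(A %*% as.numeric(x0)))
    # independent dense solve of (sum A'A + lambda I) x = sum A'y
    M <- Reduce(`+`, lapply(As, function(A) as.matrix(Matrix::crossprod(A)))) +
      0.1 * diag(prod(hd))
    rhs <- Reduce(`+`, mapply(function(A, y)
      as.numeric(Matrix::t(A) %*% y), As, ys, SIMPLIFY = FALSE))
    xd <- solve(M, rhs)
    ses <- session_from_stacks(frames, ys, geo, hd, 1)
    rec <- reconstruct_shell(ses, 1,
      srr_config(target_spacing = 1, regularizer = "identity", lambda = 0.1,
                 lambda_scale = "absolute", tol = 1e-12, max_iter = 3000))
    expect_lt(max(abs(as.numeric(rec$data) - xd)), 1e-6)
  }
})

test_that("solver residual is monotone non-increasing", {
  set.seed(5)
  hd <- c(8L, 8L, 8L)
  geo <- stack_geometry(in_plane = c(1, 1), slice_thickness = 2.5,
                        rotation_angles = c(0, 45, 90, 135))
  x0 <- array(stats::runif(prod(hd)), hd)
  frames <- lapply(geo$rotation_angles, mdtmap:::stack_frame,
                   geometry = geo, fov = (hd - 1) * 1)
  As <- lapply(frames, function(fr)
    mdtmap:::build_stack_operator(hd, 1, fr, "gaussian"))
  ys <- lapply(As, function(A)
    as.numeric(A %*% as.numeric(x0)) + 0.01 * stats::rnorm(nrow(A)))
  ses <- session_from_stacks(frames, ys, geo, hd, 1)
  rec <- reconstruct_shell(ses, 1, srr_config(target_spacing = 1,
                                              tol = 1e-10, max_iter = 500))
  h <- rec$diagnostics$residual_history
  expect_true(all(diff(h) <= 1e-12))
})

test_that("very large identity regularization drives the solution to zero", {
  p <- tiny_phantom()
  geo <- fast_geometry()
  ses <- average_repetitions(
    simulate_session(p, btensor_protocol(0, repetitions = 1L), geo, sigma = 0))
  base <- reconstruct_shell(ses, 1,
    srr_config(target_spacing = 1, regularizer = "identity", lambda = 0.1,
               lambda_scale = "absolute", tol = 1e-10, max_iter = 1000))
  huge <- reconstruct_shell(ses, 1,
    srr_config(target_spacing = 1, regularizer = "identity", lambda = 1e9,
               lambda_scale = "absolute", tol = 1e-10, max_iter = 1000))
  expect_lt(sqrt(sum(huge$data^2)), 1e-6 * sqrt(sum(base$data^2)))
})

test_that("rotation order does not affect the reconstruction", {
  p <- tiny_phantom()
  geo <- stack_geometry(in_plane = c(1, 1), slice_thickness = 3,
                        rotation_angles = c(0, 60, 120))
  ses <- average_repetitions(
    simulate_session(p, btensor_protocol(0, repetitions = 1L), geo, sigma = 0))
  perm <- ses
  ord <- c(3, 1, 2)
  perm$stacks <- ses$stacks[ord]
  perm$geometry$rotation_angles <- geo$rotation_angles[ord]
  cfg <- srr_config(target_spacing = 1, tol = 1e-10, max_iter = 500)
  r1 <- reconstruct_shell(ses, 1, cfg)
  r2 <- reconstruct_shell(perm, 1, cfg)
  expect_lt(max(abs(r1$data - r2$data)), 1e-8)
})

test_that("noiseless six-rotation reconstruction is self-consistent with the phantom", {
  p <- tiny_phantom()
  geo <- stack_geometry(in_plane = c(1, 1), slice_thickness = 4,
                        rotation_angles = seq(0, 150, 30))
  ses <- average_repetitions(
    simulate_session(p, btensor_protocol(c(0, 1500), repetitions = c(1, 1)),
                     geo, sigma = 0))
  rec <- reconstruct_all_shells(ses, srr_config(target_spacing = 1,
                                                lambda = 1e-3, tol = 1e-8,
                                                max_iter = 1000))
  for (s in 1:2) {
    x <- phantom_shell_signal(p, c(0, 1500)[s])
    err <- sqrt(sum((rec$volumes[[s]] - x)^2) / sum(x^2))
    expect_lt(err, 0.05)
  }
  expect_equal(names(rec$volumes), c("b0", "b1500"))
})

test_that("reconstruction error grows smoothly with noise, no blow-up", {
  p <- tiny_phantom()
  geo <- stack_geometry(in_plane = c(1, 1), slice_thickness = 4,
                        rotation_angles = seq(0, 150, 30))
  x <- phantom_shell_signal(p, 0)
  rec_err <- function(sg, lam) {
    ses <- average_repetitions(
      simulate_session(p, btensor_protocol(0, repetitions = 1L), geo,
                       sigma = sg, seed = 77),
      rician_correction = "none")
    rec <- reconstruct_shell(ses, 1,
      srr_config(target_spacing = 1, lambda = lam, max_iter = 600))
    sqrt(sum((rec$data - x)^2) / sum(x^2))
  }
  errs <- vapply(c(0, 0.02, 0.05), rec_err, numeric(1), lam = 1e-2)
  expect_true(all(diff(errs) > 0))       # more noise, more error
  expect_lt(errs[3], 2.5 * 0.05 / 0.02 * errs[2])  # smooth: < linear x 2.5
  expect_lt(errs[3], 0.35)               # no blow-up at sigma 0.05
  expect_lt(rec_err(0.05, 1e-3), 1)      # weak regularization: degraded, finite
})

test_that("under-determined and misconfigured reconstructions are rejected", {
  p <- tiny_phantom()
  geo <- stack_geometry(in_plane = c(1, 1), slice_thickness = 3,
                        rotation_angles = 0)
  ses <- average_repetitions(
    simulate_session(p, btensor_protocol(0, repetitions = 1L), geo, sigma = 0))
  expect_error(reconstruct_shell(ses, 1, srr_config(target_spacing = 1)),
               "two rotations")
  expect_error(srr_config(lambda = -1), "lambda")
  expect_error(srr_config(tol = 0), "tolerance")
  geo2 <- fast_geometry()
  ses2 <- average_repetitions(
    simulate_session(p, btensor_protocol(0, repetitions = 1L), geo2, sigma = 0))
  expect_error(reconstruct_shell(ses2, 1, srr_config(target_spacing = 10)),
               "slice thickness")
  # non-convergence is reported, not hidden
  expect_warning(
    reconstruct_shell(ses2, 1, srr_config(target_spacing = 1, tol = 1e-14,
                                          max_iter = 2L)),
    "did not converge")
})
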