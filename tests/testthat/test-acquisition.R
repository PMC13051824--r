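test_that("identity geometry reproduces the source volume", {
  p <- tiny_phantom()
  g <- stack_geometry(in_plane = c(1, 1), slice_thickness = 1,
                      rotation_angles = c(0, 90), slice_profile = "boxcar")
  sig <- phantom_shell_signal(p, 1500)
  st <- sample_stack(sig, 1, g, 0)
  expect_equal(dim(st$data), dim(sig))
  expect_lt(max(abs(st$data - sig)), 1e-6)
})

test_that("slice profiles have unit DC gain", {
  u <- array(1, c(20, 20, 20))
  for (prof in c("gaussian", "boxcar")) {
    g <- stack_geometry(in_plane = c(1, 1), slice_thickness = 4,
                        slice_profile = prof)
    st <- sample_stack(u, 1, g, 0)
    # interior voxels (away from the zero-padded boundary)
    n <- dim(st$data)
    core <- st$data[8:13, 8:13, ceiling(n[3] / 2)]
    expect_equal(max(abs(core - 1)), 0, tolerance = 1e-9)
  }
})

test_that("stack sampling matches an independent loop-based oracle", {
  set.seed(21)
  vol <- array(stats::runif(8^3), c(8, 8, 8))
  for (prof in c("gaussian", "boxcar")) {
    g <- stack_geometry(in_plane = c(1, 1), slice_thickness = 2.5,
                        slice_profile = prof)
    for (ang in c(0, 35, 120)) {
      st <- sample_stack(vol, 1, g, ang)
      ref <- naive_sample_stack(vol, 1, st$frame, prof)
      expect_lt(max(abs(st$data - ref)), 1e-10)
    }
  }
})

test_that("stack geometry validation", {
  expect_error(stack_geometry(slice_thickness = 1), "in-plane")
  expect_error(stack_geometry(rotation_angles = c(0, 190)), "180")
  expect_error(stack_geometry(rotation_angles = numeric(0)), "at least one")
  p <- tiny_phantom()
  g <- fast_geometry()
  expect_error(sample_stack(phantom_shell_signal(p, 0), 1, g, -5), "180")
})

test_that("the six-rotation three-shell session produces 246 volumes", {
  p <- tiny_phantom()
  ses <- simulate_session(p, mdt_protocol(), paper_geometry(),
                          sigma = 0.02, seed = 3)
  nvol <- sum(vapply(ses$stacks, function(st)
    sum(vapply(st$shells, function(v) dim(v)[4], numeric(1))), numeric(1)))
  expect_equal(nvol, (1 + 16 + 24) * 6)
})

test_that("simulation is deterministic under a fixed seed and exact when noiseless", {
  p <- tiny_phantom()
  g <- fast_geometry()
  proto <- btensor_protocol(c(0, 1500), repetitions = c(1, 2))
  s1 <- simulate_session(p, proto, g, sigma = 0.03, seed = 42)
  s2 <- simulate_session(p, proto, g, sigma = 0.03, seed = 42)
  expect_identical(s1$stacks, s2$stacks)
  # noiseless b=0 stack equals the sampled total signal fraction
  s0 <- simulate_session(p, proto, g, sigma = 0)
  total <- Reduce(`+`, p$frac)
  st <- sample_stack(total, p$spacing, g, g$rotation_angles[1])
  expect_equal(s0$stacks[[1]]$shells[[1]][, , , 1], st$data)
})

test_that("repetition averaging: mean, noise scaling, and Rician floor correction", {
  p <- tiny_phantom()
  g <- fast_geometry(angles = c(0, 90))
  proto <- btensor_protocol(c(0, 1500), repetitions = c(1, 2))
  ses <- simulate_session(p, proto, g, sigma = 0)
  # identical (noiseless) repetitions: mean equals any member; [0.2, 0.4] -> 0.3
  avg <- average_repetitions(ses)
  expect_equal(avg$stacks[[1]]$shells[[2]][, , , 1],
               ses$stacks[[1]]$shells[[2]][, , , 1])
  fake <- ses
  fake$stacks[[1]]$shells[[2]][] <- rep(c(0.2, 0.4),
    each = prod(dim(fake$stacks[[1]]$shells[[2]])[1:3]))
  expect_equal(unique(as.numeric(
    average_repetitions(fake)$stacks[[1]]$shells[[2]])), 0.3)

  # 16 noisy repetitions at sigma 0.02: voxelwise error std ~ sigma/4
  proto16 <- btensor_protocol(0, repetitions = 16L)
  clean <- average_repetitions(simulate_session(p, proto16, g, sigma = 0))
  noisy <- simulate_session(p, proto16, g, sigma = 0.02, seed = 9)
  avgn <- average_repetitions(noisy, rician_correction = "none")
  resid <- avgn$stacks[[1]]$shells[[1]] - clean$stacks[[1]]$shells[[1]]
  inside <- clean$stacks[[1]]$shells[[1]] > 0.9  # high SNR: no rectification
  expect_equal(stats::sd(resid[inside]), 0.02 / 4, tolerance = 0.2)

  # moment correction removes the noise floor in signal-free voxels
  avgc <- average_repetitions(noisy, rician_correction = "moment")
  outside <- clean$stacks[[1]]$shells[[1]] < 1e-9
  floor_none <- mean(avgn$stacks[[1]]$shells[[1]][outside])
  floor_corr <- mean(avgc$stacks[[1]]$shells[[1]][outside])
  expect_gt(floor_none, 0.02)        # rectified floor ~ sigma*sqrt(pi/2)
  expect_lt(floor_corr, floor_none / 3)

  # missing repetitions are detected
  broken <- noisy
  broken$stacks[[1]]$shells[[1]] <-
    broken$stacks[[1]]$shells[[1]][, , , 1:8, drop = FALSE]
  expect_error(average_repetitions(broken), "missing repetitions")
})

test_that("forward operator passes the adjoint test on random instances", {
  set.seed(33)
  g <- paper_geometry()
  for (ang in c(0, 30, 75)) {
    fr <- mdtmap:::stack_frame(g, ang, c(11, 11, 11))
    A <- mdtmap:::build_stack_operator(c(12, 12, 12), 1, fr, "gaussian")
    for (i in 1:5) {
      x <- stats::rnorm(ncol(A)); y <- stats::rnorm(nrow(A))
      gap <- abs(sum((A %*% x) * y) - sum(x * (Matrix::t(A) %*% y)))
      expect_lte(gap, 1e-8 * sqrt(sum(x^2)) * sqrt(sum(y^2)))
    }
  }
})

test_that("rotation by 0 degrees commutes with averaging", {
  p <- tiny_phantom()
  g <- stack_geometry(in_plane = c(1, 1), slice_thickness = 3,
                      rotation_angles = 0)
  proto <- btensor_protocol(1500, repetitions = 4L)
  ses <- simulate_session(p, proto, g, sigma = 0.02, seed = 13)
  # average in stack space, vs sample the averaged repetitions directly:
  # with one rotation at 0 deg both orders apply the same linear operator
  avg <- average_repetitions(ses, rician_correction = "none")
  man <- apply(ses$stacks[[1]]$shells[[1]], 1:3, mean)
  expect_equal(avg$stacks[[1]]$shells[[1]][, , , 1], man)
})

test_that("stack session disk round trip validates its manifest", {
  p <- tiny_phantom()
  g <- fast_geometry(angles = c(0, 45))
  proto <- btensor_protocol(c(0, 2500), repetitions = c(1, 2))
  ses <- simulate_session(p, proto, g, sigma = 0.01, seed = 8)
  d <- tempfile()
  write_stacks(ses, d)
  back <- read_stacks(d)
  expect_equal(back$stacks[[2]]$shells[[2]], ses$stacks[[2]]$shells[[2]],
               tolerance = 1e-12)
  expect_equal(back$geometry$rotation_angles, g$rotation_angles)
  expect_false(back$averaged)
  # corrupt the manifest volume count
  man <- jsonlite::read_json(file.path(d, "stacks.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  man$shells[[2]]$reps <- 5
  jsonlite::write_json(man, file.path(d, "stacks.json"), auto_unbox = TRUE,
                       null = "null")
  expect_error(read_stacks(d), "manifest declares")
  unlink(d, recursive = TRUE)
})
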