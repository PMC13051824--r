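test_that("phantom fractions conserve mass and label pure regions correctly", {
  p <- demo_phantom()
  total <- Reduce(`+`, p$frac)
  expect_true(all(total <= 1 + 1e-12))
  expect_true(all(vapply(p$frac, function(a) all(a >= 0), logical(1))))
  # fractions sum to exactly 1 inside the head (strict interior)
  xs <- mdtmap:::axis_coords(p$dim[1], p$spacing)
  r <- sqrt(outer(outer(xs^2, xs^2, `+`), xs^2, `+`))
  interior <- r < p$geometry$head_radius - 2 * p$spacing
  expect_true(all(abs(total[interior] - 1) < 1e-12))
  # deep interior WM voxels (outside ventricle and nuclei) are pure WM
  wm_band <- r > p$geometry$ventricle_radius + 2 & r < p$geometry$cortex_inner - 2
  pure_wm <- wm_band & p$frac$deep_nuclei == 0
  expect_true(any(pure_wm))
  expect_true(all(p$frac$white_matter[pure_wm] == 1))
  # ventricle centre is pure CSF
  ctr <- (p$dim + 1) / 2
  expect_equal(p$frac$csf[ctr[1], ctr[2], ctr[3]], 1)
})

test_that("supersampled occupancy approximates analytic volumes", {
  p <- demo_phantom()
  # ventricle: a sphere fully interior to WM, so CSF fraction integrates
  # to its analytic volume
  xs <- mdtmap:::axis_coords(p$dim[1], p$spacing)
  r <- sqrt(outer(outer(xs^2, xs^2, `+`), xs^2, `+`))
  near <- r < p$geometry$ventricle_radius + 2
  vol_est <- sum(p$frac$csf[near])
  vol_true <- 4 / 3 * pi * p$geometry$ventricle_radius^3
  expect_equal(vol_est, vol_true, tolerance = 0.02)
  # occupancy converges: doubling the supersampling moves boundary
  # fractions by at most O(1/supersample)
  p6 <- build_phantom(p$dim, supersample = 6L)
  dmax <- max(abs(p6$frac$cortex - p$frac$cortex))
  expect_lt(dmax, 0.2)
  expect_lt(mean(abs(p6$frac$cortex - p$frac$cortex)), 0.005)
})

test_that("phantom geometry validation", {
  expect_error(build_phantom(c(8, 8, 8)), "16")
  expect_error(build_phantom(c(32, 32, 32), spacing = -1), "spacing")
  expect_error(build_phantom(c(32, 32, 32), ribbon_mm = 0.5), "ribbon")
  expect_error(build_phantom(c(16, 16, 16), ventricle_radius = 5),
               "white-matter core")
})

test_that("lesion insertion shifts diffusivity as specified", {
  p <- demo_phantom()
  ctr <- c(11, 0, 0)  # mid-ribbon for the 32^3 default geometry
  # identity at delta 0
  p0 <- insert_lesion(p, lesion_spec("focal_hyperintense", ctr, 4, 0))
  expect_equal(p0$md, p$md)
  expect_equal(p0$frac, p$frac)
  # focal +0.15 on cortex md 0.8 -> 0.95
  p1 <- insert_lesion(p, lesion_spec("focal_hyperintense", ctr, 4, 0.15))
  expect_equal(max(p1$md$cortex), 0.95)
  expect_equal(p1$md$white_matter, p$md$white_matter)
  expect_equal(p1$frac, p$frac)  # fractions untouched
  # ischemia -0.35 on WM md 0.7 -> 0.35
  p2 <- insert_lesion(p, lesion_spec("ischemia", c(0, 0, 6), 4, 0.35))
  expect_equal(min(p2$md$white_matter), 0.35)
  # voxel count inside the sphere matches the analytic volume within 10%
  n_in <- sum(p2$md$white_matter < p$md$white_matter[1, 1, 1])
  expect_equal(n_in, 4 / 3 * pi * 4^3, tolerance = 0.1)
  # errors
  expect_error(insert_lesion(p, lesion_spec("tumor", c(500, 0, 0), 3, 0.2)),
               "outside")
  expect_error(insert_lesion(p, lesion_spec("ischemia", c(0, 0, 6), 3, 0.7)),
               "0.05")
})

test_that("disjoint lesions commute and repeated zero-delta insertion is idempotent", {
  p <- demo_phantom()
  l1 <- lesion_spec("focal_hyperintense", c(11, 0, 0), 3, 0.1)
  l2 <- lesion_spec("ischemia", c(-6, 0, 0), 2.5, 0.2)
  a <- insert_lesion(insert_lesion(p, l1), l2)
  b <- insert_lesion(insert_lesion(p, l2), l1)
  expect_equal(a$md, b$md)
  l0 <- lesion_spec("tumor", c(0, 0, 6), 3, 0)
  expect_equal(insert_lesion(insert_lesion(p, l0), l0)$md, p$md)
})

test_that("ground truth is the CSF-excluded tissue-weighted mean", {
  p <- demo_phantom()
  gt <- ground_truth_tissue_md(p)
  # pure WM voxel
  xs <- mdtmap:::axis_coords(p$dim[1], p$spacing)
  r <- sqrt(outer(outer(xs^2, xs^2, `+`), xs^2, `+`))
  wm_pure <- p$frac$white_matter == 1
  expect_true(all(gt$values[wm_pure] == 0.7))
  # mixed-voxel arithmetic: synthetic fractions
  q <- p
  q$frac$cortex[1, 1, 1] <- 0.6; q$frac$csf[1, 1, 1] <- 0.4
  q$frac$white_matter[1, 1, 1] <- 0; q$frac$deep_nuclei[1, 1, 1] <- 0
  expect_equal(ground_truth_tissue_md(q)$values[1, 1, 1], 0.8)
  q$frac$cortex[1, 1, 1] <- 0.3; q$frac$white_matter[1, 1, 1] <- 0.3
  q$frac$csf[1, 1, 1] <- 0.4
  expect_equal(ground_truth_tissue_md(q)$values[1, 1, 1], 0.75)
  # voxels that are nearly pure CSF are invalid
  expect_false(any(gt$valid[p$frac$csf > 0.96]))
  # invariance to the CSF fraction at fixed tissue composition
  q2 <- p
  q2$frac$csf <- q2$frac$csf * 0.5
  gt2 <- ground_truth_tissue_md(q2)
  expect_equal(gt2$values[gt$valid], gt$values[gt$valid])
})

test_that("phantom disk round trip preserves fractions, diffusivity and lesions", {
  p <- insert_lesion(tiny_phantom(),
                     lesion_spec("focal_hyperintense", c(5, 0, 0), 2, 0.15))
  d <- tempfile()
  write_phantom(p, d)
  q <- read_phantom(d)
  expect_equal(q$frac, p$frac, tolerance = 1e-12)
  expect_equal(q$md, p$md, tolerance = 1e-12)
  expect_equal(q$dim, p$dim)
  expect_equal(length(q$lesions), 1L)
  expect_equal(q$lesions[[1]]$delta_md, 0.15)
  unlink(d, recursive = TRUE)
})
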