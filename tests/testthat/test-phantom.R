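test_that("single-sphere phantom matches a brute-force voxel-centre scan", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), spacing_mm = c(1, 1, 1),
                       tissue_defs = list(list(
                         label = 1L, name = "ball",
                         shape = list(type = "ellipsoid",
                                      center = c(15.5, 15.5, 15.5),
                                      semiaxes = c(5, 5, 5)))))
  vol <- generate_label_phantom(spec)
  # oracle: scan every voxel centre directly
  gc <- expand.grid(x = 0:31, y = 0:31, z = 0:31)
  inside <- sqrt((gc$x - 15.5)^2 + (gc$y - 15.5)^2 + (gc$z - 15.5)^2) <= 5
  expect_identical(sum(vol$labels == 1L), sum(inside))
  expect_identical(as.vector(vol$labels == 1L), inside)
})

test_that("empty tissue list gives all-background; geometry overflow errors", {
  spec <- phantom_spec(c(8, 8, 8), c(1, 1, 1), list())
  expect_true(all(generate_label_phantom(spec)$labels == 0L))
  bad <- phantom_spec(c(8, 8, 8), c(1, 1, 1), list(list(
    label = 1L, name = "toobig",
    shape = list(type = "ellipsoid", center = c(3.5, 3.5, 3.5),
                 semiaxes = c(20, 2, 2)))))
  expect_error(generate_label_phantom(bad), "toobig")
})

test_that("default head phantom has all contracted tissues and is deterministic", {
  vol1 <- generate_label_phantom(default_head_spec(32))
  vol2 <- generate_label_phantom(default_head_spec(32))
  expect_identical(vol1$labels, vol2$labels)
  present <- unique(as.vector(vol1$labels))
  for (lb in 1:8) expect_true(lb %in% present)  # skin..ventricles
})

test_that("render_contrast follows the intensity model", {
  vol <- generate_label_phantom(default_head_spec(24))
  means <- default_head_spec(24)$contrast_means$t1
  clean <- render_contrast(vol, means, noise_sigma = 0, bias_amplitude = 0)
  expect_equal(as.vector(clean$values),
               unname(means[as.character(as.vector(vol$labels))]))
  # noise SD in a large uniform region within 5% of sigma
  big <- array(0L, c(25, 25, 25))
  lv <- label_volume(big)
  noisy <- render_contrast(lv, c("0" = 10), noise_sigma = 2, seed = 7)
  expect_lt(abs(sd(noisy$values) - 2) / 2, 0.05)
  expect_gt(prod(dim(noisy$values)), 1e4)
  # two contrasts on the same labels are voxelwise label-consistent
  t2 <- render_contrast(vol, default_head_spec(24)$contrast_means$t2,
                        noise_sigma = 0)
  lb <- as.vector(vol$labels)
  for (id in unique(lb)) {
    expect_equal(length(unique(clean$values[vol$labels == id])), 1L)
    expect_equal(length(unique(t2$values[vol$labels == id])), 1L)
  }
  expect_error(render_contrast(vol, c("0" = 1)), "label")
  # determinism
  n1 <- render_contrast(lv, c("0" = 10), noise_sigma = 2, seed = 9)
  n2 <- render_contrast(lv, c("0" = 10), noise_sigma = 2, seed = 9)
  expect_identical(n1$values, n2$values)
})

test_that("bias field is smooth, bounded and multiplicative", {
  big <- label_volume(array(0L, c(20, 20, 20)))
  img <- render_contrast(big, c("0" = 100), noise_sigma = 0,
                         bias_amplitude = 0.2, seed = 3)
  expect_true(all(img$values >= 100 * 0.8 - 1e-9))
  expect_true(all(img$values <= 100 * 1.2 + 1e-9))
  expect_gt(diff(range(img$values)), 1)  # the field actually varies
})

test_that("mode-A rater matches the STAPLE generative model", {
  truth <- array(FALSE, c(25, 25, 16))
  truth[3:12, 3:12, 3:12] <- TRUE   # 1000 fg
  stopifnot(sum(truth) == 1000)
  model <- rater_model(0.9, 0.95, seed = 11)
  out <- simulate_rater(truth, model)
  # |out n truth| ~ Binomial(1000, 0.9): within 3 SD
  hits <- sum(out & truth)
  expect_lt(abs(hits - 900), 3 * sqrt(1000 * 0.9 * 0.1) + 1e-9)
  # false positives ~ Binomial(B, 0.05)
  B <- sum(!truth)
  fp <- sum(out & !truth)
  expect_lt(abs(fp - 0.05 * B), 3 * sqrt(B * 0.05 * 0.95))
  # plug-in expected Dice
  FG <- sum(truth)
  Ed <- 2 * 0.9 * FG / (0.9 * FG + FG + 0.05 * B)
  expect_lt(abs(dice(out, truth) - Ed), 0.05)
  # perfect rater reproduces truth
  expect_identical(simulate_rater(truth, rater_model(1, 1, seed = 1)), truth)
})

test_that("mode-B jitter displaces the boundary but stays deterministic", {
  truth <- ball_mask(24, 7)
  model <- rater_model(1, 1, boundary_jitter_mm = 1.5, seed = 5)
  out1 <- simulate_rater(truth, model, spacing = c(1, 1, 1))
  out2 <- simulate_rater(truth, model, spacing = c(1, 1, 1))
  expect_identical(out1, out2)
  expect_false(identical(out1, truth))   # boundary moved somewhere
  expect_gt(dice(out1, truth), 0.7)      # but it is still the same structure
})

test_that("analytic tensor field has the prescribed anisotropy", {
  vol <- generate_label_phantom(default_head_spec(32))
  tf <- make_tensor_field(vol)
  fa_map <- fa(tf)
  expect_equal(max(abs(fa_map[vol$labels == 6L])), 0)      # GM isotropic
  lam <- c(1.4e-3, 0.35e-3, 0.35e-3)
  fa_wm <- sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  expect_equal(unique(round(fa_map[vol$labels == 7L], 10)), round(fa_wm, 10))
  # principal eigenvector parallel to the arc tangents by construction
  pd <- principal_direction(tf)
  wm <- which(as.vector(vol$labels == 7L))
  ctr <- vol$origin + (dim(vol$labels) - 1) / 2 * vol$spacing
  gc <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
  dx <- (gc$x[wm] - 1) - ctr[1]; dz <- (gc$z[wm] - 1) - ctr[3]
  r <- sqrt(dx^2 + dz^2)
  ok <- r > 1e-6
  vx <- -dz[ok] / r[ok]; vz <- dx[ok] / r[ok]
  dots <- abs(pd[wm[ok], 1] * vx + pd[wm[ok], 3] * vz)
  expect_true(all(dots > 0.999))
  expect_error(make_tensor_field(vol, diffusivities = list(
    wm = c(1e-3, -1e-4, 1e-4), gm = 1e-3, csf = 1e-3)), "positive")
})

test_that("synthetic DWI follows the signal equation", {
  vol <- generate_label_phantom(default_head_spec(16))
  tf <- make_tensor_field(vol)
  proto <- default_protocol(8, 800)
  dwi <- synth_dwi(tf, proto, s0 = 50, noise_sigma = 0)
  expect_equal(unique(as.vector(dwi[, , , 1])), 50)   # b = 0 volume
  # isotropic voxel: S = s0 exp(-b d) for every direction
  csf <- which(vol$labels == 5L)[1]
  ijk <- arrayInd(csf, dim(vol$labels))
  for (m in 2:9)
    expect_equal(dwi[ijk[1], ijk[2], ijk[3], m], 50 * exp(-800 * 3.0e-3),
                 tolerance = 1e-12)
  # determinism with noise
  a <- synth_dwi(tf, proto, noise_sigma = 1, seed = 4)
  b <- synth_dwi(tf, proto, noise_sigma = 1, seed = 4)
  expect_identical(a, b)
})

test_that("phantom bundle writes NIfTI + JSON + FSL text files", {
  dir <- file.path(tempdir(), "bundle_test")
  spec <- default_head_spec(12)
  paths <- write_phantom_bundle(spec, dir, dwi = TRUE)
  expect_true(all(file.exists(unlist(paths))))
  lab <- read_nifti(paths$labels)
  expect_s3_class(lab, "label_volume")
  expect_identical(dim(lab$labels), c(12L, 12L, 12L))
  bv <- scan(paths$bvals, quiet = TRUE)
  expect_equal(sum(bv == 0), 1)
  expect_equal(sum(bv == 800), 32)
  unlink(dir, recursive = TRUE)
})
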