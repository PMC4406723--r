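test_that("diffusion protocols are validated", {
  expect_error(diffusion_protocol(rep(800, 7), matrix(rnorm(21), 7)), "b = 0")
  expect_error(diffusion_protocol(c(0, rep(800, 3)),
                                  rbind(c(0, 0, 0), diag(3))), ">= 6")
  # collinear directions are rank-deficient
  g <- matrix(rep(c(1, 0, 0), 7), ncol = 3, byrow = TRUE)
  expect_error(diffusion_protocol(c(0, rep(800, 6)), rbind(c(0, 0, 0), g[1:6, ])),
               "under-determined|independent")
  proto <- default_protocol()
  expect_length(proto$bvals, 33L)
  nrm <- sqrt(rowSums(proto$bvecs[-1, ]^2))
  expect_equal(nrm, rep(1, 32), tolerance = 1e-12)
})

test_that("noiseless fit recovers the generating tensors to 1e-10", {
  vol <- generate_label_phantom(default_head_spec(20))
  tf <- make_tensor_field(vol)
  proto <- default_protocol(12, 800)
  dwi <- synth_dwi(tf, proto, s0 = 100, noise_sigma = 0)
  fit <- fit_tensor(dwi, proto, mask = tf$mask)
  sel <- rep(as.vector(tf$mask), 6)
  expect_lt(max(abs(fit$D[, , , 1:6][sel] - tf$D[, , , 1:6][sel])) / max(tf$D),
            1e-10)
  expect_equal(unique(round(fit$s0[tf$mask], 8)), 100)
  # isotropic decay recovers D = d I exactly
  iso <- which(vol$labels == 5L)[1]
  ijk <- arrayInd(iso, dim(vol$labels))
  expect_equal(fit$D[ijk[1], ijk[2], ijk[3], 1:3], rep(3.0e-3, 3),
               tolerance = 1e-12)
  expect_equal(fit$D[ijk[1], ijk[2], ijk[3], 4:6], rep(0, 3),
               tolerance = 1e-12)
})

test_that("fa matches the eigenvalue formula and is rotation invariant", {
  expect_equal(fa(diag(c(1, 1, 1) * 1e-3)), 0)
  expect_equal(fa(diag(c(1, 0, 0))), 1)
  lam <- c(1.4e-3, 0.35e-3, 0.35e-3)
  expect_equal(fa(diag(lam)),
               sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2)),
               tolerance = 1e-12)
  expect_equal(fa(c(0, 0, 0, 0, 0, 0)), 0)
  set.seed(10)
  for (rep in 1:5) {
    D <- crossprod(matrix(rnorm(9), 3))
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    expect_equal(fa(D), fa(Q %*% D %*% t(Q)), tolerance = 1e-9)
  }
})

test_that("noisy WM fit keeps the principal direction within 5 degrees", {
  vol <- generate_label_phantom(default_head_spec(32))
  tf <- make_tensor_field(vol)
  proto <- default_protocol()
  dwi <- synth_dwi(tf, proto, s0 = 100, noise_sigma = 5, seed = 4)  # SNR 20
  fit <- fit_tensor(dwi, proto, mask = vol$labels == 7L)
  pd_true <- principal_direction(tf)
  pd_fit <- principal_direction(fit)
  wm <- which(as.vector(vol$labels == 7L) & as.vector(fit$mask))
  ang <- acos(pmin(1, abs(rowSums(pd_true[wm, ] * pd_fit[wm, ])))) * 180 / pi
  expect_lt(median(ang), 5)
})

test_that("mask_tensors intersects the validity mask", {
  vol <- generate_label_phantom(default_head_spec(20))
  tf <- make_tensor_field(vol)
  proto <- default_protocol(8)
  fit <- fit_tensor(synth_dwi(tf, proto), proto)
  all_labels <- unique(as.vector(vol$labels))
  same <- mask_tensors(fit, vol, all_labels)
  expect_identical(same$mask, fit$mask)
  wm_only <- mask_tensors(fit, vol, 7L)
  expect_identical(sum(wm_only$mask), sum(vol$labels == 7L))
  expect_warning(mask_tensors(fit, vol, 999L), "empty")
})

test_that("conductivity mapping scales eigenvalues, preserves eigenvectors, caps at 1.8", {
  vol <- generate_label_phantom(default_head_spec(20))
  tf <- make_tensor_field(vol)
  cm <- map_conductivity(tf, vol, fallback = default_conductivities())
  sg <- matrix(cm$sigma, ncol = 6)
  Dm <- matrix(tf$D, ncol = 6)
  idx <- which(as.vector(vol$labels == 7L))[1:20]
  for (i in idx) {
    S <- matrix(c(sg[i, 1], sg[i, 4], sg[i, 5], sg[i, 4], sg[i, 2], sg[i, 6],
                  sg[i, 5], sg[i, 6], sg[i, 3]), 3, 3)
    D <- matrix(c(Dm[i, 1], Dm[i, 4], Dm[i, 5], Dm[i, 4], Dm[i, 2], Dm[i, 6],
                  Dm[i, 5], Dm[i, 6], Dm[i, 3]), 3, 3)
    es <- eigen(S, symmetric = TRUE)
    ed <- eigen(D, symmetric = TRUE)
    expect_true(all(es$values <= 1.8 + 1e-12))
    expect_true(all(es$values > 0))
    expect_gt(abs(sum(es$vectors[, 1] * ed$vectors[, 1])), 1 - 1e-9)
    # below the cap the scaling is exactly linear (0.844 S.s/mm^3 x 1000)
    expect_equal(es$values, pmin(844 * ed$values, 1.8), tolerance = 1e-9)
  }
  # CSF diffusivity maps above the cap and is clipped to CSF conductivity
  csf <- which(as.vector(vol$labels == 5L))[1]
  expect_equal(sg[csf, 1], 1.8, tolerance = 1e-9)
  expect_error(map_conductivity(tf, vol, fallback = c("0" = 0)), "fallback")
})

test_that("sample_to_grid interpolates components tri-linearly", {
  d <- c(6, 6, 6)
  lab <- label_volume(array(1L, d))
  cm <- scalar_conductivity_map(lab, c("1" = 1))
  # constant field: constant everywhere
  pts <- matrix(runif(30, 0.5, 4.5), ncol = 3)
  out <- sample_to_grid(cm, pts)
  expect_true(all(abs(out[, 1] - 1) < 1e-12))
  # linear Dxx along x reproduces exact linear values
  lin <- cm
  gx <- array(rep(0:5, times = 36), d)
  lin$sigma[, , , 1] <- 0.1 + 0.05 * gx
  ptsx <- cbind(seq(0.25, 4.75, by = 0.5), 2, 2)
  got <- sample_to_grid(lin, ptsx)
  expect_equal(got[, 1], 0.1 + 0.05 * ptsx[, 1], tolerance = 1e-9)
  # out-of-grid points fall back
  far <- sample_to_grid(cm, matrix(c(100, 100, 100), 1), fallback = 0.25)
  expect_equal(far[1, 1:3], rep(0.25, 3))
})
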