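test_that("voxel solver reproduces the parallel-plate closed form", {
  d <- c(8, 8, 16)
  sig <- array(2, d); attr(sig, "spacing") <- c(1, 1, 1)
  sol <- solve_voxel(sig, bar_montage(d))
  L <- 15e-3; A <- 64e-6
  inner <- field_magnitude(sol, "E")[, , 2:15]
  expect_lt(max(abs(inner - 1 / L)) * L, 1e-6)
  expect_equal(unname(sol$electrode_currents["A"]), 2 * A / L,
               tolerance = 1e-10)
  expect_lt(abs(sum(sol$electrode_currents)) / sum(abs(sol$electrode_currents)),
            1e-6)
  # discrete maximum principle
  expect_gte(min(sol$potential, na.rm = TRUE), 0)
  expect_lte(max(sol$potential, na.rm = TRUE), 1)
})

test_that("two-layer series bar matches the 1-D circuit solution", {
  d <- c(8, 8, 16)
  sig <- array(1, d); sig[, , 9:16] <- 4
  attr(sig, "spacing") <- c(1, 1, 1)
  sol <- solve_voxel(sig, bar_montage(d))
  E <- field_magnitude(sol, "E")
  expect_equal(E[4, 4, 4] / E[4, 4, 12], 4, tolerance = 1e-6)
  A <- 64e-6
  Rtot <- (7.5e-3 / 1 + 7.5e-3 / 4) / A
  expect_lt(abs(sol$electrode_currents["A"] - 1 / Rtot) * Rtot, 1e-4)
})

test_that("potential is invariant under uniform conductivity scaling", {
  d <- c(6, 6, 10)
  set.seed(3)
  sig <- array(runif(prod(d), 0.5, 2), d); attr(sig, "spacing") <- c(1, 1, 1)
  s1 <- solve_voxel(sig, bar_montage(d))
  sig3 <- sig * 3; attr(sig3, "spacing") <- c(1, 1, 1)
  s2 <- solve_voxel(sig3, bar_montage(d))
  expect_lt(max(abs(s1$potential - s2$potential), na.rm = TRUE), 1e-7)
  expect_equal(s2$J, 3 * s1$J, tolerance = 1e-6)
})

test_that("disconnected electrodes and full tensors are rejected", {
  d <- c(4, 4, 8)
  sig <- array(1, d); sig[, , 4] <- 0   # insulating wall
  attr(sig, "spacing") <- c(1, 1, 1)
  expect_error(solve_voxel(sig, bar_montage(d)), "disconnected")
  lab <- label_volume(array(1L, d))
  cm <- scalar_conductivity_map(lab, c("1" = 1))
  cm$sigma[, , , 4] <- 0.3   # off-diagonal term
  expect_error(solve_voxel(cm, bar_montage(d)), "solve_fem")
})

test_that("FEM agrees with the voxel solver at matched effective gap", {
  # FEM fixes all corner nodes of electrode voxel layers, so its effective
  # plate gap with nz voxels equals the voxel solver's with nz - 1
  d_f <- c(6, 6, 12); d_v <- c(6, 6, 11)
  sig_f <- array(0.5, d_f); attr(sig_f, "spacing") <- c(1, 1, 1)
  sig_v <- array(0.5, d_v); attr(sig_v, "spacing") <- c(1, 1, 1)
  sf <- solve_fem(sig_f, bar_montage(d_f))
  sv <- solve_voxel(sig_v, bar_montage(d_v))
  Ef <- field_magnitude(sf, "E")[3, 3, 6]
  Ev <- field_magnitude(sv, "E")[3, 3, 6]
  expect_lt(abs(Ef - Ev) / Ev, 1e-6)
  expect_lt(abs(sum(sf$electrode_currents)) / sum(abs(sf$electrode_currents)),
            1e-6)
})

test_that("FEM matches the anisotropic homogeneous closed form", {
  d <- c(6, 6, 12)
  lab <- label_volume(array(1L, d))
  cm <- scalar_conductivity_map(lab, c("1" = 1))
  cm$sigma[, , , 1] <- 0.3; cm$sigma[, , , 2] <- 0.7; cm$sigma[, , , 3] <- 1.2
  sol <- solve_fem(cm, bar_montage(d), sample_centroids = FALSE)
  L <- 10e-3   # corner-plane gap
  inner <- 3:10
  expect_lt(max(abs(sol$E[, , inner, 3] - 1 / L)) * L, 1e-6)
  expect_lt(max(abs(sol$J[, , inner, 3] - 1.2 / L)) * L / 1.2, 1e-6)
  # transverse currents vanish up to the 1e-8 solver residual
  expect_lt(max(abs(sol$J[, , inner, 1])), 1e-4 * 1.2 / L)
  expect_lt(max(abs(sol$J[, , inner, 2])), 1e-4 * 1.2 / L)
})

test_that("grid refinement converges monotonically on a misaligned interface", {
  run <- function(nz, zi = 6.3) {
    d <- c(4, 4, nz)
    h <- 16 / (nz - 1)
    z <- ((1:nz) - 1) * h
    sig <- array(rep(ifelse(z <= zi, 1, 4), each = 16), d)
    attr(sig, "spacing") <- c(h, h, h)
    sol <- solve_voxel(sig, bar_montage(d))
    Rtot <- zi / 1 + (16 - zi) / 4
    phi_exact <- ifelse(z <= zi, 1 - z / Rtot, 1 - (zi + (z - zi) / 4) / Rtot)
    max(abs(sol$potential[2, 2, ] - phi_exact))
  }
  errs <- vapply(c(11, 21, 41), run, 1)
  expect_true(all(diff(errs) < 0))
})

test_that("montage presets and comparisons behave", {
  vol <- generate_label_phantom(default_head_spec(32))
  m <- montage_preset("fpz_cz", vol)
  expect_length(m$electrodes, 2L)
  ring <- montage_preset("cz_ring", vol)
  expect_length(ring$electrodes, 5L)
  # overlap is rejected
  big <- montage_preset("fpz_cz", vol, radius_deg = 25)
  e_dup <- big$electrodes[[1]]
  e_dup$potential <- 0
  expect_error(electrode_montage(list(big$electrodes[[1]], e_dup)), "overlap")
  # identical solutions compare to unit ratios; doubling V doubles E
  d <- c(6, 6, 10)
  sig <- array(1, d); attr(sig, "spacing") <- c(1, 1, 1)
  s1 <- solve_voxel(sig, bar_montage(d))
  region <- array(TRUE, d)
  cmp <- compare_montages(s1, s1, region)
  expect_equal(cmp$ratio_E_median, 1)
  expect_equal(cmp$ratio_J_median, 1)
  s2 <- solve_voxel(sig, bar_montage(d, v = c(2, 0)))
  expect_equal(median(field_magnitude(s2, "E")[region]) /
                 median(field_magnitude(s1, "E")[region]), 2,
               tolerance = 1e-9)
  expect_error(compare_montages(s1, s1, array(FALSE, d)), "region|TRUE")
})

test_that("scalar vs tensor study is consistent for isotropic tensors", {
  vol <- generate_label_phantom(default_head_spec(24))
  scal <- default_conductivities()
  smap <- scalar_conductivity_map(vol, scal)
  mont <- montage_preset("fpz_cz", vol)
  brain <- vol$labels %in% c(6L, 7L)
  st <- scalar_vs_tensor_study(vol, scal, smap, mont, brain)
  expect_lt(abs(st$ratio_E_median - 1), 1e-3)
})
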