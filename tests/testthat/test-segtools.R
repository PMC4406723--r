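test_that("gaussian_smooth matches the sampled analytic kernel", {
  n <- 33
  arr <- array(0, c(n, n, n)); arr[17, 17, 17] <- 1
  sm <- gaussian_smooth(scalar_image(arr), fwhm_mm = 4)
  sig <- 4 / (2 * sqrt(2 * log(2)))
  r <- max(1, ceiling(4 * sig)); off <- (-r):r
  k1 <- exp(-off^2 / (2 * sig^2)); k1 <- k1 / sum(k1)
  expected <- outer(outer(k1, k1), k1)
  idx <- 17 + off
  expect_lt(max(abs(sm$values[idx, idx, idx] - expected)) / max(expected), 1e-6)
  expect_equal(sum(sm$values), 1)          # mass preserved
  # identity and constant cases
  expect_equal(gaussian_smooth(scalar_image(arr), 0)$values, arr)
  cst <- scalar_image(array(3.7, c(5, 6, 7)))
  expect_equal(gaussian_smooth(cst, 5)$values, cst$values)
  # sd convention is narrower than fwhm at the same width
  a <- gaussian_smooth(scalar_image(arr), 2, kind = "fwhm")$values[17, 17, 17]
  b <- gaussian_smooth(scalar_image(arr), 2, kind = "sd")$values[17, 17, 17]
  expect_gt(a, b)
})

test_that("otsu threshold maximizes between-class variance and is scale-invariant", {
  v <- array(c(rep(10, 400), rep(100, 600)), c(10, 10, 10))
  th <- threshold_histogram(scalar_image(v))
  expect_identical(sum(th$mask), 600L)
  expect_true(all(v[th$mask] == 100))
  # manual threshold
  man <- threshold_histogram(scalar_image(v), method = 55)
  expect_identical(man$mask, th$mask)
  # invariance under increasing affine rescaling
  set.seed(2)
  img <- array(c(rnorm(500, 10, 2), rnorm(500, 60, 5)), c(10, 10, 10))
  m1 <- threshold_histogram(scalar_image(img))$mask
  m2 <- threshold_histogram(scalar_image(img * 3.2 + 17))$mask
  expect_identical(m1, m2)
  expect_error(threshold_histogram(scalar_image(array(1, c(3, 3, 3)))),
               "non-constant")
})

test_that("region_grow equals a brute-force component oracle", {
  # two same-intensity blobs separated by an out-of-band wall
  img <- array(0, c(12, 12, 12))
  img[2:4, 2:4, 2:4] <- 5
  img[8:10, 8:10, 8:10] <- 5
  out <- region_grow(scalar_image(img), matrix(c(3, 3, 3), 1), 4, 6)
  expect_identical(sum(out), 27L)
  expect_true(all(which(out, arr.ind = TRUE) <= 4))
  # uniform image floods completely
  u <- region_grow(scalar_image(array(1, c(5, 5, 5))), matrix(c(1, 1, 1), 1), 0, 2)
  expect_true(all(u))
  # out-of-band seed yields empty mask
  e <- region_grow(scalar_image(img), matrix(c(6, 6, 6), 1), 4, 6)
  expect_false(any(e))
  # randomized oracle: output is the union of in-band 6-components hit by seeds
  set.seed(31)
  for (rep in 1:5) {
    im <- array(sample(0:3, 8^3, replace = TRUE), c(8, 8, 8))
    seed_vox <- matrix(sample(1:8, 3), 1)
    got <- region_grow(scalar_image(im * 1.0), seed_vox, 2, 3)
    # oracle: BFS flood fill written independently
    band <- im >= 2 & im <= 3
    visited <- array(FALSE, dim(im))
    if (band[seed_vox]) {
      queue <- list(as.vector(seed_vox))
      visited[seed_vox] <- TRUE
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        for (ax in 1:3) for (dl in c(-1, 1)) {
          q <- v; q[ax] <- q[ax] + dl
          if (all(q >= 1) && all(q <= 8) && band[q[1], q[2], q[3]] &&
              !visited[q[1], q[2], q[3]]) {
            visited[q[1], q[2], q[3]] <- TRUE
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
    expect_identical(got, visited)
  }
})

test_that("kmeans_labels clusters intensities deterministically", {
  v <- array(rep(c(1, 9), each = 500), c(10, 10, 10))
  km <- kmeans_labels(scalar_image(v), 2, seed = 3)
  expect_identical(km$labels[v == 1][1], 1L)
  expect_identical(km$labels[v == 9][1], 2L)
  expect_true(all(km$labels[v == 1] == 1L))
  set.seed(1)
  v3 <- array(c(rnorm(3000, 0, 0.5), rnorm(3000, 10, 0.5),
                rnorm(3000, 20, 0.5)), c(30, 30, 10))
  truth <- array(rep(1:3, each = 3000), c(30, 30, 10))
  km3 <- kmeans_labels(scalar_image(v3), 3, seed = 7)
  expect_lt(mean(km3$labels != truth), 0.01)
  km3b <- kmeans_labels(scalar_image(v3), 3, seed = 7)
  expect_identical(km3$labels, km3b$labels)
  expect_error(kmeans_labels(scalar_image(array(rep(1:2, 4), c(2, 2, 2))), 5),
               "distinct")
})

test_that("morphology follows set-theoretic contracts", {
  cube <- array(FALSE, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- TRUE
  expect_identical(morph_cleanup(cube, "close", radius_vox = 1), cube)
  # opening is idempotent
  set.seed(8)
  m <- random_small_mask(c(10, 10, 10), 0.4)
  o1 <- morph_cleanup(m, "open", radius_vox = 1)
  o2 <- morph_cleanup(o1, "open", radius_vox = 1)
  expect_identical(o1, o2)
  # island removal
  iso <- array(FALSE, c(7, 7, 7)); iso[2, 2, 2] <- TRUE; iso[5:6, 5:6, 5:6] <- TRUE
  out <- morph_cleanup(iso, "remove_islands", min_island_size = 2)
  expect_false(out[2, 2, 2])
  expect_identical(sum(out), 8L)
  # hole filling restores a solid cube, and is idempotent
  holed <- cube; holed[5, 5, 5] <- FALSE
  filled <- morph_cleanup(holed, "fill_holes")
  expect_identical(filled, cube)
  expect_identical(morph_cleanup(filled, "fill_holes"), filled)
})

test_that("interslice interpolation blends signed distance fields", {
  cc <- expand.grid(1:21, 1:21)
  r <- sqrt((cc$Var1 - 11)^2 + (cc$Var2 - 11)^2)
  d1 <- matrix(r <= 4, 21, 21)
  d2 <- matrix(r <= 8, 21, 21)
  out <- interslice_interpolate(d1, d2, 1)
  expect_identical(out[[1]], d1)
  expect_identical(out[[3]], d2)
  mid <- out[[2]]
  # mid slice should be within one pixel-ring of the radius-6 disk
  expect_lte(sum(mid & !(r <= 7)), 0)
  expect_lte(sum(!mid & (r <= 5)), 0)
  # identical endpoints reproduce themselves in between
  same <- interslice_interpolate(d1, d1, 3)
  for (s in same) expect_identical(s, d1)
  expect_length(interslice_interpolate(d1, d2, 0), 2L)
  expect_error(interslice_interpolate(matrix(FALSE, 3, 3), d1[1:3, 1:3], 1),
               "nonempty")
})

test_that("marker watershed partitions a two-basin gradient image", {
  x <- array(rep(seq(-1, 1, length.out = 20)^2, each = 1), c(20, 5, 5))
  img <- scalar_image(x)
  markers <- array(0L, c(20, 5, 5))
  markers[3, 3, 3] <- 1L; markers[18, 3, 3] <- 2L
  ws <- watershed_markers(img, markers)
  expect_identical(ws$labels[2, 3, 3], 1L)
  expect_identical(ws$labels[19, 3, 3], 2L)
  expect_true(all(ws$labels %in% c(0L, 1L, 2L)))
})
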