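test_that("dice matches its definition and error contract", {
  d <- c(5, 1, 1)
  s1 <- array(c(TRUE, TRUE, TRUE, FALSE, FALSE), d)
  s2 <- array(TRUE, d)
  expect_equal(dice(s1, s2), 2 * 3 / (3 + 5))
  expect_equal(dice(s2, s2), 1)
  s3 <- array(c(FALSE, FALSE, FALSE, TRUE, TRUE), d)
  expect_equal(dice(s1, s3), 0)
  expect_error(dice(array(FALSE, d), array(FALSE, d)), "empty")
  # symmetry and monotonicity in the intersection
  expect_equal(dice(s1, s2), dice(s2, s1))
})

test_that("boundary_points finds exposed voxel faces", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  bp <- boundary_points(one, c(1, 1, 1))
  expect_equal(nrow(bp), 1L)
  expect_equal(as.vector(bp), c(1, 1, 1))
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  expect_equal(nrow(boundary_points(cube, c(1, 1, 1))), 26L)  # all but centre
  full <- array(TRUE, c(4, 4, 4))
  expect_equal(nrow(boundary_points(full, c(1, 1, 1))), 64 - 8)  # outer shell
})

test_that("mhd reproduces the hand example and the brute-force oracle", {
  x <- array(FALSE, c(4, 4, 4)); y <- x
  x[1, 1, 1] <- TRUE
  y[1, 1, 1] <- TRUE; y[1, 1, 3] <- TRUE
  # d(X,Y) = 0, d(Y,X) = mean(0, 2)/... boundary pts: X={0}, Y={0, 2mm}
  expect_equal(mhd(x, y, spacing = c(1, 1, 1)), 1)
  expect_equal(mhd(x, x, spacing = c(1, 1, 1)), 0)
  expect_equal(mhd(x, y), mhd(y, x))
  set.seed(3)
  for (rep in 1:20) {
    a <- random_small_mask(c(6, 6, 6), 0.25)
    b <- random_small_mask(c(6, 6, 6), 0.25)
    sp <- c(0.7, 1, 1.3)
    expect_equal(mhd(a, b, spacing = sp), brute_mhd(a, b, sp),
                 tolerance = 1e-9)
  }
  expect_error(mhd(x, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("dice = 1 iff mhd = 0 for nonempty masks", {
  set.seed(4)
  for (rep in 1:10) {
    a <- random_small_mask(c(6, 6, 6))
    b <- random_small_mask(c(6, 6, 6))
    d_eq <- isTRUE(all.equal(dice(a, b), 1))
    m_zero <- mhd(a, b) < 1e-12
    expect_identical(d_eq, m_zero)
  }
})

test_that("kruskal_wallis agrees with the reference implementation", {
  set.seed(6)
  for (rep in 1:10) {
    g <- list(rnorm(7), rnorm(5, 0.5), sample(1:4, 6, replace = TRUE))
    ours <- kruskal_wallis(g)
    ref <- stats::kruskal.test(unlist(g),
                               rep(seq_along(g), lengths(g)))
    expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$H, 0)
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$p, 1)
})

test_that("exact permutation p matches full enumeration", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  ex <- kruskal_wallis(g, exact = TRUE)
  # oracle: enumerate all 20 assignments of ranks 1..6 into two triples
  combs <- utils::combn(6, 3)
  stat <- function(sel) {
    r1 <- sum(sel); r2 <- sum(setdiff(1:6, sel))
    12 / (6 * 7) * (r1^2 / 3 + r2^2 / 3) - 3 * 7
  }
  hs <- apply(combs, 2, stat)
  h_obs <- stat(1:3)
  expect_equal(ex$H, h_obs, tolerance = 1e-10)
  expect_equal(ex$p, mean(hs >= h_obs - 1e-12), tolerance = 1e-12)
  expect_error(kruskal_wallis(list(rnorm(6), rnorm(6)), exact = TRUE),
               "n <= 10")
})

test_that("lilliefors is deterministic, calibrated-ish, and powerful", {
  set.seed(8)
  x <- rnorm(30)
  a <- lilliefors(x, n_mc = 500, seed = 4)
  b <- lilliefors(x, n_mc = 500, seed = 4)
  expect_identical(a, b)
  # exponential data are rejected with high probability
  nulltab <- lilliefors_null(100, n_mc = 1000, seed = 2)
  rej <- mean(vapply(1:40, function(i) {
    lilliefors(rexp(100), null_stats = nulltab)$p < 0.01
  }, TRUE))
  expect_gt(rej, 0.95)
  expect_error(lilliefors(rep(1, 10)), "variance")
})

test_that("variability study scores raters against a STAPLE consensus", {
  truth1 <- ball_mask(14, 4)
  truth2 <- ball_mask(14, 3, center = c(5, 5, 5))
  raters <- list(
    s1 = replicate(3, truth1, simplify = FALSE),
    s2 = replicate(3, truth2, simplify = FALSE))
  st <- variability_study(raters)
  expect_true(all(st$table$dice == 1))
  expect_true(all(st$table$mhd_mm == 0))
  expect_equal(st$tests$dice$H, 0)
  # a degraded rater must rank strictly lowest on mean Dice
  set.seed(77)
  structures <- list(ball_mask(20, 6), ball_mask(20, 4, center = c(6, 6, 6)),
                     ball_mask(20, 5, center = c(14, 14, 8)))
  raters2 <- lapply(seq_along(structures), function(si) {
    truth <- structures[[si]]
    lapply(1:3, function(j) {
      pj <- if (j == 2) 0.7 else 0.97
      simulate_rater(truth, rater_model(pj, 0.999, seed = 100 * si + j))
    })
  })
  names(raters2) <- paste0("structure", 1:3)
  st2 <- variability_study(raters2)
  means <- st2$summary$dice_mean
  expect_lt(means[2], min(means[c(1, 3)]))
})
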