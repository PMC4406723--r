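# Shared fixture builders. All fixtures are generated in code; nothing is
# stored on disk.

# logical ball mask on an n^3 grid
ball_mask <- function(n, radius, center = rep((n + 1) / 2, 3)) {
  gc <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  d <- sqrt((gc$x - center[1])^2 + (gc$y - center[2])^2 + (gc$z - center[3])^2)
  array(d <= radius, c(n, n, n))
}

# random small mask with a guaranteed nonempty blob
random_small_mask <- function(dim, p = 0.3) {
  m <- array(runif(prod(dim)) < p, dim)
  if (!any(m)) m[ceiling(dim[1] / 2), ceiling(dim[2] / 2), ceiling(dim[3] / 2)] <- TRUE
  m
}

# brute-force directed mean boundary distance (independent of the package's
# chunked implementation path)
brute_mhd <- function(s1, s2, spacing) {
  bp <- function(m) {
    w <- which(m, arr.ind = TRUE)
    d <- dim(m)
    keep <- logical(nrow(w))
    for (i in seq_len(nrow(w))) {
      v <- w[i, ]
      nb_out <- FALSE
      for (ax in 1:3) for (dl in c(-1, 1)) {
        q <- v; q[ax] <- q[ax] + dl
        if (q[ax] < 1 || q[ax] > d[ax] || !m[q[1], q[2], q[3]]) nb_out <- TRUE
      }
      keep[i] <- nb_out
    }
    sweep(w[keep, , drop = FALSE] - 1, 2, spacing, `*`)
  }
  X <- bp(s1); Y <- bp(s2)
  dd <- function(A, B) {
    mean(apply(A, 1, function(a) min(sqrt(colSums((t(B) - a)^2)))))
  }
  max(dd(X, Y), dd(Y, X))
}

# tiny two-electrode bar montage on a d-grid along z
bar_montage <- function(d, v = c(1, 0)) {
  m1 <- array(FALSE, d); m1[, , 1] <- TRUE
  m2 <- array(FALSE, d); m2[, , d[3]] <- TRUE
  electrode_montage(list(list(name = "A", potential = v[1], mask = m1),
                         list(name = "B", potential = v[2], mask = m2)))
}

# one seeded registration recovery trial; returns corner error in voxels
registration_trial <- function(trial_seed, n = 64, config = list()) {
  set.seed(trial_seed)
  spec <- registration_phantom_spec(n)
  vol <- generate_label_phantom(spec)
  fix_img <- render_contrast(vol, spec$contrast_means$t1, noise_sigma = 3.5,
                             seed = trial_seed * 7 + 1)
  ctr <- fix_img$origin + (dim(fix_img$values) - 1) / 2 * fix_img$spacing
  tt <- runif(3, -1, 1)
  tt <- tt / sqrt(sum(tt^2)) * runif(1, 0, 5)          # ||t|| <= 5 mm
  T_true <- affine_transform(tt, runif(3, -0.17, 0.17), # rot <= ~10 deg
                             runif(3, 0.95, 1.05),      # scale 0.95-1.05
                             runif(3, -0.02, 0.02), center = ctr)
  mv <- render_moving_acquisition(vol, T_true, spec$contrast_means$t2,
                                  fix_img, noise_sigma = 3.5,
                                  seed = trial_seed * 7 + 2)
  Tr <- register_affine(mv, fix_img,
                        config = modifyList(list(seed = trial_seed), config))
  T_expect <- affine_from_matrix(solve(T_true$matrix), center = ctr)
  corner_error(Tr, T_expect, dim(fix_img$values), fix_img$spacing)
}
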