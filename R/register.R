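# 12-DOF intensity-based affine registration maximizing normalized mutual
# information, with a coarse-to-fine pyramid and a derivative-free local
# optimizer. Also the declared stand-in for non-rigid DWI registration.

#' 12-parameter affine transform
#'
#' Parameters are translation (mm), rotation (radians, applied as
#' `Rz %*% Ry %*% Rx`), scale, and shear (`hxy, hxz, hyz`, upper
#' triangular). The homogeneous matrix acts about `center` (mm) as
#' `M(x) = t + c + R Sh Sc (x - c)` — composition order `T . R . Sh . Sc`,
#' fixed and documented. Parameter and matrix forms round-trip to 1e-9.
#'
#' @param translation,rotation,scale,shear numeric length-3 each.
#' @param center rotation/scaling centre in mm.
#' @return object of class `affine_transform` with `$params` (length 12)
#'   and `$matrix` (4 x 4).
#' @export
affine_transform <- function(translation = c(0, 0, 0),
                             rotation = c(0, 0, 0),
                             scale = c(1, 1, 1),
                             shear = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  params <- c(as.numeric(translation), as.numeric(rotation),
              as.numeric(scale), as.numeric(shear))
  stopifnot(length(params) == 12L, all(is.finite(params)), all(scale != 0))
  structure(list(params = params, center = as.numeric(center),
                 matrix = affine_params_to_matrix(params, center)),
            class = "affine_transform")
}

rot_mat <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

affine_params_to_matrix <- function(params, center = c(0, 0, 0)) {
  t <- params[1:3]; r <- params[4:6]; s <- params[7:9]; h <- params[10:12]
  Sh <- diag(3); Sh[1, 2] <- h[1]; Sh[1, 3] <- h[2]; Sh[2, 3] <- h[3]
  A <- rot_mat(r) %*% Sh %*% diag(s)
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- t + center - A %*% center
  M
}

#' Decompose a homogeneous affine matrix into the 12 canonical parameters
#'
#' Inverts the `T . R . Sh . Sc` composition (QR-based); assumes a proper
#' (positive-determinant) transform.
#'
#' @param M 4 x 4 homogeneous matrix.
#' @param center the centre the matrix acts about.
#' @return an `affine_transform`.
#' @export
affine_from_matrix <- function(M, center = c(0, 0, 0)) {
  A <- M[1:3, 1:3]
  qr_ <- qr(A)
  Q <- qr.Q(qr_); U <- qr.R(qr_)
  sgn <- sign(diag(U)); sgn[sgn == 0] <- 1
  Q <- Q %*% diag(sgn); U <- diag(sgn) %*% U
  if (det(Q) < 0) stop("improper (reflecting) transform")
  beta <- asin(max(-1, min(1, -Q[3, 1])))
  alpha <- atan2(Q[3, 2], Q[3, 3])
  gamma <- atan2(Q[2, 1], Q[1, 1])
  s <- diag(U)
  h <- c(U[1, 2] / s[2], U[1, 3] / s[3], U[2, 3] / s[3])
  t <- M[1:3, 4] - center + A %*% center
  affine_transform(translation = as.numeric(t),
                   rotation = c(alpha, beta, gamma),
                   scale = s, shear = h, center = center)
}

#' Map points (mm) through an affine transform
#' @param transform an `affine_transform`.
#' @param pts n x 3 matrix of points in mm.
#' @return n x 3 matrix.
#' @export
transform_points <- function(transform, pts) {
  pts <- matrix(pts, ncol = 3L)
  t(transform$matrix[1:3, 1:3] %*% t(pts) + transform$matrix[1:3, 4])
}

#' Resample an image onto a new grid through an affine transform
#'
#' Output voxel centres are mapped through the inverse transform into the
#' source image and interpolated there; samples falling outside the source
#' field of view are `NA` (invalid — excluded from similarity measures).
#'
#' @param img a `scalar_image` (source).
#' @param spacing_mm output grid spacing (ignored when `reference` given).
#' @param transform an `affine_transform` mapping source world coordinates
#'   to output world coordinates (identity by default).
#' @param interp `"linear"` or `"nearest"`.
#' @param reference optional `scalar_image` whose grid defines the output.
#' @return a `scalar_image` (values `NA` where invalid).
#' @export
resample <- function(img, spacing_mm = img$spacing,
                     transform = affine_transform(),
                     interp = c("linear", "nearest"), reference = NULL) {
  stopifnot(inherits(img, "scalar_image"))
  interp <- match.arg(interp)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  stopifnot(all(spacing_mm > 0))
  if (!is.null(reference)) {
    odim <- dim(reference$values)
    ospacing <- reference$spacing
    oorigin <- reference$origin
  } else {
    ext <- (dim(img$values) - 1) * img$spacing
    odim <- pmax(1L, as.integer(floor(ext / spacing_mm)) + 1L)
    ospacing <- spacing_mm
    oorigin <- img$origin
  }
  Minv <- solve(transform$matrix)
  vals <- .resample_affine_cpp(as.numeric(img$values), dim(img$values),
                               img$spacing, img$origin,
                               odim, ospacing, oorigin,
                               as.numeric(t(Minv[1:3, ])),
                               interp == "nearest")
  scalar_image(array(vals, odim), spacing = ospacing, origin = oorigin)
}

entropy_from_counts <- function(cnt) {
  p <- cnt[cnt > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

joint_histogram <- function(av, bv, bins, range_a = NULL, range_b = NULL) {
  if (is.null(range_a)) range_a <- quantile(av, c(0.01, 0.99), names = FALSE)
  if (is.null(range_b)) range_b <- quantile(bv, c(0.01, 0.99), names = FALSE)
  if (range_a[2] <= range_a[1]) range_a <- range(av) + c(-0.5, 0.5)
  if (range_b[2] <= range_b[1]) range_b <- range(bv) + c(-0.5, 0.5)
  ea <- seq(range_a[1], range_a[2], length.out = bins + 1L)
  eb <- seq(range_b[1], range_b[2], length.out = bins + 1L)
  ia <- pmin(pmax(findInterval(av, ea, rightmost.closed = TRUE), 1L), bins)
  ib <- pmin(pmax(findInterval(bv, eb, rightmost.closed = TRUE), 1L), bins)
  counts <- tabulate(ia + bins * (ib - 1L), bins * bins)
  matrix(counts, bins, bins)
}

#' Normalized mutual information between two images
#'
#' Studholme's dialect `(H(A) + H(B)) / H(A, B)`, computed from a joint
#' histogram over the valid (non-`NA`) overlap, with per-image bin edges
#' spanning the 1st-99th intensity percentiles. Always in `[1, 2]`;
#' exactly 2 for identical non-constant images under this construction.
#'
#' @param a,b congruent `scalar_image`s.
#' @param bins histogram bins per image (default 64).
#' @return scalar NMI value.
#' @export
nmi <- function(a, b, bins = 64L) {
  stopifnot(inherits(a, "scalar_image"), inherits(b, "scalar_image"))
  check_congruent(a, b)
  ok <- is.finite(a$values) & is.finite(b$values)
  if (!any(ok)) stop("empty valid overlap")
  J <- joint_histogram(a$values[ok], b$values[ok], bins)
  ha <- entropy_from_counts(rowSums(J))
  hb <- entropy_from_counts(colSums(J))
  hab <- entropy_from_counts(J)
  if (hab == 0) return(2)  # both effectively constant: perfectly redundant
  (ha + hb) / hab
}

downsample_level <- function(img, factor) {
  if (factor <= 1) return(img)
  sm <- gaussian_smooth(img, fwhm_mm = 1.2 * factor * img$spacing)
  resample(sm, spacing_mm = img$spacing * factor)
}

# fast NMI objective at one pyramid level: fixed-image bins precomputed,
# moving image warped and binned inside one fused C++ pass; `stride`
# evaluates the similarity on a regular subgrid of the fixed image
nmi_objective_level <- function(moving, fixed, bins, center, stride = 1L,
                                foreground_mask = TRUE) {
  fv <- as.vector(fixed$values)
  okf <- is.finite(fv)
  if (foreground_mask) {
    # restrict the similarity to the head: background air carries no
    # alignment information and doubles the evaluation cost. The Otsu mask
    # is closed and dilated so dark tissues (CSF, skull) and the scalp
    # boundary band stay inside the similarity region.
    fg <- tryCatch({
      m <- threshold_histogram(fixed)$mask
      m <- morph_cleanup(m, "fill_holes")
      morph_cleanup(m, "dilate", radius_vox = 2)
    }, error = function(e) NULL)
    if (!is.null(fg) && mean(fg) > 0.05) okf <- okf & as.vector(fg)
  }
  rf <- quantile(fv[okf], c(0.01, 0.99), names = FALSE)
  if (rf[2] <= rf[1]) rf <- range(fv[okf]) + c(-0.5, 0.5)
  fb <- integer(length(fv))
  stepf <- (rf[2] - rf[1]) / bins
  fb[okf] <- pmin(pmax(floor((fv[okf] - rf[1]) / stepf), 0), bins - 1) + 1L
  mvv <- as.vector(moving$values)
  okm <- is.finite(mvv)
  rm_ <- quantile(mvv[okm], c(0.01, 0.99), names = FALSE)
  if (rm_[2] <= rm_[1]) rm_ <- range(mvv[okm]) + c(-0.5, 0.5)
  stepm <- (rm_[2] - rm_[1]) / bins
  mov_vals <- moving$values
  mov_vals[!is.finite(mov_vals)] <- rm_[1] - stepm  # falls in the first bin
  mov_vals <- as.numeric(mov_vals)
  d_out <- dim(fixed$values)
  function(p) {
    tr <- affine_transform(p[1:3], p[4:6], 1 + p[7:9], p[10:12],
                           center = center)
    Minv <- solve(tr$matrix)
    val <- .nmi_warped(mov_vals, dim(moving$values),
                       moving$spacing, moving$origin,
                       d_out, fixed$spacing, fixed$origin,
                       as.numeric(t(Minv[1:3, ])), fb, as.integer(bins),
                       rm_[1], stepm, 100L, as.integer(stride))
    if (val < 0) return(10)       # overlap collapsed
    if (!is.finite(val)) stop("non-finite NMI during search")
    -val
  }
}

# robust 1D line minimization: coarse scan (handles local dips) + Brent refine
line_min_scan <- function(f, p, k, w, n_scan = 13L) {
  xs <- seq(p[k] - w, p[k] + w, length.out = n_scan)
  vals <- vapply(xs, function(x) { q <- p; q[k] <- x; f(q) }, 1)
  i <- which.min(vals)
  lo <- xs[max(1L, i - 1L)]
  hi <- xs[min(n_scan, i + 1L)]
  g <- function(x) { q <- p; q[k] <- x; f(q) }
  o <- optimize(g, lower = lo, upper = hi, tol = max((hi - lo) * 1e-3, 1e-6))
  if (o$objective < vals[i]) list(x = o$minimum, v = o$objective)
  else list(x = xs[i], v = vals[i])
}

cd_minimize <- function(f, p, dof, widths, sweeps, shrink = 0.5) {
  w <- widths
  fp <- f(p)
  for (sw in seq_len(sweeps)) {
    for (k in dof) {
      r <- line_min_scan(f, p, k, w[k])
      if (r$v <= fp) { p[k] <- r$x; fp <- r$v }
    }
    w <- w * shrink
  }
  list(par = p, value = fp)
}

# Nelder-Mead polish with transform-appropriate parameter scaling
nm_polish <- function(ob, p, maxit, scale = 1) {
  o <- optim(p, ob, method = "Nelder-Mead",
             control = list(maxit = maxit, reltol = 1e-10,
                            parscale = scale * c(rep(1, 3), rep(0.03, 3),
                                                 rep(0.012, 6))))
  list(par = o$par, value = o$value)
}

#' Intensity-based 12-DOF affine registration
#'
#' Maximizes normalized mutual information between the transformed moving
#' image and the fixed image with a staged, derivative-free search:
#'
#' 1. at half resolution, a deterministic grid over coarse rotations
#'    (coupled rotations create optimizer-stable local minima on smooth
#'    head shapes) scored by translation-only coordinate descent; the best
#'    starts are refined rigidly, then with scales added;
#' 2. at full resolution on a stride-2 voxel subgrid, full 12-DOF cyclic
#'    coordinate descent whose line searches combine a bracketing scan
#'    (stepping over local dips of the piecewise-smooth NMI surface) with
#'    Brent refinement;
#' 3. a final full-resolution polish (BOBYQA when `minqa` is available,
#'    Nelder-Mead otherwise).
#'
#' The returned transform maps moving-image world coordinates into
#' fixed-image world coordinates, acting about the fixed-image centre;
#' apply it with `resample(moving, transform = T, reference = fixed)`.
#'
#' @param moving,fixed `scalar_image`s.
#' @param config list; recognized entries: `bins` (64, full resolution;
#'   half at the coarse level), `bounds` (search half-widths for the 12
#'   parameters; default 6 mm, 0.2 rad, 0.08, 0.08), `rot_grid` (coarse
#'   rotation grid offsets as a fraction of the rotation bound, default
#'   `c(-0.65, 0, 0.65)`), `n_keep` (grid starts refined, 3),
#'   `multistart` (extra random rotation starts, 0), `fine_sweeps` (3),
#'   `polish_evals` (300), `seed` (1).
#' @return an `affine_transform` with attribute `nmi` (final value).
#' @export
register_affine <- function(moving, fixed, config = list()) {
  stopifnot(inherits(moving, "scalar_image"), inherits(fixed, "scalar_image"))
  cfg <- modifyList(list(bins = 64L,
                         bounds = c(rep(6, 3), rep(0.2, 3), rep(0.08, 6)),
                         rot_grid = c(-0.65, 0, 0.65), n_keep = 5L,
                         multistart = 0L, fine_sweeps = 4L,
                         polish_evals = 600L, seed = 1L), config)
  center <- fixed$origin + (dim(fixed$values) - 1) / 2 * fixed$spacing
  widths0 <- cfg$bounds
  set.seed(cfg$seed)
  # --- stage 1: half resolution, global-ish rigid search then affine ---
  fix2 <- downsample_level(fixed, 2)
  mov2 <- gaussian_smooth(moving, 2.4 * moving$spacing)
  bins2 <- max(16L, cfg$bins %/% 2L)
  ob2s <- nmi_objective_level(mov2, fix2, bins2, center, stride = 2L)
  ob2 <- nmi_objective_level(mov2, fix2, bins2, center)
  rgrid <- cfg$rot_grid * widths0[4]
  combos <- as.matrix(expand.grid(rgrid, rgrid, rgrid))
  if (cfg$multistart > 0)
    combos <- rbind(combos,
                    matrix(runif(3 * cfg$multistart, -widths0[4], widths0[4]),
                           ncol = 3))
  scored <- apply(combos, 1, function(r) {
    s <- rep(0, 12); s[4:6] <- r
    cd_minimize(ob2s, s, 1:3, widths0, sweeps = 1L)$value
  })
  # refine the best grid starts: cheap stride-2 coordinate descent first,
  # then a rigid polish on the full half-res objective (the stride-2
  # surface occasionally prefers a spurious rotation basin)
  best <- NULL
  for (i in order(scored)[seq_len(min(cfg$n_keep, nrow(combos)))]) {
    s <- rep(0, 12); s[4:6] <- combos[i, ]
    r <- cd_minimize(ob2s, s, 1:6, widths0, sweeps = 2L)
    r <- cd_minimize(ob2, r$par, 1:6, widths0 * 0.5, sweeps = 1L)
    r <- nm_polish(ob2, r$par, 300)
    if (is.null(best) || r$value < best$value) best <- r
  }
  p <- best$par
  p <- cd_minimize(ob2, p, 1:9, widths0 * 0.35, sweeps = 2L)$par
  p <- nm_polish(ob2, p, 400)$par
  # --- stage 2: full resolution, full 12 DOF, wide catch basin ---
  # the first (wide) sweeps run on a stride-2 subgrid; the final sweeps and
  # the polish use every voxel
  obfs <- nmi_objective_level(moving, fixed, cfg$bins, center, stride = 2L)
  obf <- nmi_objective_level(moving, fixed, cfg$bins, center)
  n_wide <- max(1L, cfg$fine_sweeps - 2L)
  p <- cd_minimize(obfs, p, 1:12, widths0 * 0.3, n_wide, shrink = 0.55)$par
  p <- cd_minimize(obf, p, 1:12, widths0 * 0.3 * 0.55^n_wide,
                   cfg$fine_sweeps - n_wide, shrink = 0.55)$par
  # --- stage 3: full-resolution polish ---
  best <- nm_polish(obf, p, cfg$polish_evals, scale = 0.3)
  p <- best$par
  out <- affine_transform(p[1:3], p[4:6], 1 + p[7:9], p[10:12],
                          center = center)
  attr(out, "nmi") <- -best$value
  attr(out, "note") <- "affine substitution for non-rigid registration stages"
  out
}

#' Simulate a second acquisition of a phantom in a different pose
#'
#' Warps the ground-truth labels through `transform` (nearest-neighbour,
#' onto the reference grid) and renders a fresh contrast with independent
#' noise — the synthetic analogue of re-scanning the subject after motion,
#' rather than interpolating an existing rendering (which would imprint
#' interpolation smoothness correlated with the pose).
#'
#' @param labels ground-truth `label_volume`.
#' @param transform `affine_transform` (the simulated subject motion).
#' @param means contrast means for the new acquisition.
#' @param reference `scalar_image` defining the output grid.
#' @param noise_sigma,seed noise model of the new acquisition.
#' @return a `scalar_image`.
#' @export
render_moving_acquisition <- function(labels, transform, means, reference,
                                      noise_sigma = 0, seed = 1L) {
  lab_img <- scalar_image(labels$labels + 0, labels$spacing, labels$origin)
  warped <- resample(lab_img, transform = transform, reference = reference,
                     interp = "nearest")
  lw <- warped$values
  lw[!is.finite(lw)] <- 0
  vol2 <- label_volume(array(as.integer(lw), dim(lw)),
                       reference$spacing, reference$origin)
  render_contrast(vol2, means, noise_sigma = noise_sigma, seed = seed)
}

#' Mean corner-point error between two transforms
#'
#' Maps the eight corners of a grid through both transforms and returns
#' the mean Euclidean discrepancy, expressed in voxels of the given
#' spacing — the standard summary of affine registration error.
#'
#' @param estimated,reference `affine_transform`s.
#' @param dim grid dimensions (voxels).
#' @param spacing voxel spacing (mm).
#' @return mean corner discrepancy in voxel units.
#' @export
corner_error <- function(estimated, reference, dim, spacing = c(1, 1, 1)) {
  corners <- as.matrix(expand.grid(c(0, dim[1] - 1) * spacing[1],
                                   c(0, dim[2] - 1) * spacing[2],
                                   c(0, dim[3] - 1) * spacing[3]))
  a <- transform_points(estimated, corners)
  b <- transform_points(reference, corners)
  mean(sqrt(rowSums((a - b)^2))) / mean(spacing)
}

#' Serialize / deserialize an affine transform as JSON
#' @param transform an `affine_transform`.
#' @param path file path.
#' @return `path` (write) or an `affine_transform` (read).
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(params = transform$params,
                            center = transform$center,
                            matrix = transform$matrix,
                            units = "mm", convention = "voxel-centre"),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- as.numeric(x$params)
  affine_transform(p[1:3], p[4:6], p[7:9], p[10:12],
                   center = as.numeric(x$center))
}
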