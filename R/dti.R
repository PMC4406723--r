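# Diffusion tensor reconstruction (log-linear least squares), fractional
# anisotropy, tissue masking, and the linear mapping from diffusion tensors
# to anisotropic electrical conductivity with an eigenvalue cap.

#' Diffusion acquisition protocol
#'
#' @param bvals numeric vector of b-values, s/mm^2 (at least one 0).
#' @param bvecs n x 3 matrix of gradient directions; unit vectors for
#'   b > 0 (normalized here with a check), the zero vector allowed for
#'   b = 0.
#' @return object of class `diffusion_protocol`.
#' @export
diffusion_protocol <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- matrix(as.numeric(bvecs), ncol = 3L)
  stopifnot(length(bvals) == nrow(bvecs), all(bvals >= 0))
  if (!any(bvals == 0)) stop("protocol needs at least one b = 0 measurement")
  hi <- bvals > 0
  if (sum(hi) < 6) stop("protocol needs >= 6 diffusion-weighted directions")
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(nrm[hi] == 0)) stop("zero gradient vector with b > 0")
  bvecs[hi, ] <- bvecs[hi, ] / nrm[hi]
  proto <- structure(list(bvals = bvals, bvecs = bvecs),
                     class = "diffusion_protocol")
  X <- dti_design_matrix(proto)
  if (qr(X)$rank < 7L)
    stop("under-determined protocol: directions are not independent enough")
  proto
}

#' Default protocol: 32 directions at b = 800 s/mm^2 plus one b = 0
#'
#' Directions are a deterministic spherical Fibonacci point set.
#'
#' @param n_dirs number of diffusion-weighted directions (default 32).
#' @param bval diffusion weighting, s/mm^2 (default 800).
#' @return a `diffusion_protocol`.
#' @export
default_protocol <- function(n_dirs = 32L, bval = 800) {
  i <- seq_len(n_dirs) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_dirs
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  diffusion_protocol(c(0, rep(bval, n_dirs)), rbind(c(0, 0, 0), dirs))
}

# design matrix of ln S = X beta, beta = (ln s0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
dti_design_matrix <- function(protocol) {
  b <- protocol$bvals
  g <- protocol$bvecs
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Per voxel, ordinary least squares of `ln S = ln S0 - b g' D g` over all
#' measurements (7 unknowns). Voxels with any non-positive signal are
#' dropped from the mask. Negative eigenvalues are clamped to
#' `eps = 1e-6 mm^2/s` and flagged.
#'
#' @param dwi 4D array (grid x measurements) as from [synth_dwi()].
#' @param protocol a [diffusion_protocol()].
#' @param mask optional logical array restricting the fit.
#' @return a `tensor_field` with `s0`, `mask`, and `conditioned` (logical
#'   array: eigenvalues were clamped).
#' @export
fit_tensor <- function(dwi, protocol, mask = NULL) {
  stopifnot(inherits(protocol, "diffusion_protocol"), length(dim(dwi)) == 4L)
  d <- dim(dwi)[1:3]
  nvol <- dim(dwi)[4]
  stopifnot(nvol == length(protocol$bvals))
  S <- matrix(dwi, ncol = nvol)
  if (is.null(mask)) mask <- array(TRUE, d)
  fit_sel <- as.vector(mask) & rowSums(S <= 0) == 0
  X <- dti_design_matrix(protocol)
  XtXinvXt <- solve(crossprod(X), t(X))
  beta <- matrix(0, length(fit_sel), 7L)
  if (any(fit_sel))
    beta[fit_sel, ] <- t(XtXinvXt %*% t(log(S[fit_sel, , drop = FALSE])))
  Dm <- beta[, 2:7, drop = FALSE]
  conditioned <- rep(FALSE, nrow(Dm))
  eps <- 1e-6
  idx_fit <- which(fit_sel)
  for (i in idx_fit) {
    Dv <- Dm[i, ]
    M <- matrix(c(Dv[1], Dv[4], Dv[5],
                  Dv[4], Dv[2], Dv[6],
                  Dv[5], Dv[6], Dv[3]), 3, 3)
    ev <- eigen(M, symmetric = TRUE)
    if (any(ev$values < eps)) {
      lam <- pmax(ev$values, eps)
      M2 <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
      Dm[i, ] <- c(M2[1, 1], M2[2, 2], M2[3, 3], M2[1, 2], M2[1, 3], M2[2, 3])
      conditioned[i] <- TRUE
    }
  }
  spacing <- attr(dwi, "spacing"); origin <- attr(dwi, "origin")
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (is.null(origin)) origin <- c(0, 0, 0)
  structure(list(D = array(Dm, c(d, 6L)),
                 s0 = array(exp(beta[, 1]) * fit_sel, d),
                 mask = array(fit_sel, d),
                 conditioned = array(conditioned, d),
                 spacing = spacing, origin = origin),
            class = "tensor_field")
}

tensor_to_matrix <- function(Dv) {
  matrix(c(Dv[1], Dv[4], Dv[5],
           Dv[4], Dv[2], Dv[6],
           Dv[5], Dv[6], Dv[3]), 3, 3)
}

#' Fractional anisotropy of a symmetric tensor
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||` over the
#' eigenvalues; the zero tensor maps to 0 by convention.
#'
#' @param tensor length-6 component vector (xx, yy, zz, xy, xz, yz), a
#'   3 x 3 symmetric matrix, or a `tensor_field` (then an FA array comes
#'   back).
#' @return scalar in `[0, 1]`, or an array for a field.
#' @export
fa <- function(tensor) {
  if (inherits(tensor, "tensor_field")) {
    Dm <- matrix(tensor$D, ncol = 6L)
    out <- vapply(seq_len(nrow(Dm)), function(i) fa(Dm[i, ]), 1)
    return(array(out, dim(tensor$mask)))
  }
  M <- if (is.matrix(tensor)) tensor else tensor_to_matrix(tensor)
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  nl <- sqrt(sum(lam^2))
  if (nl == 0) return(0)
  sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / nl
}

#' Principal eigenvector field of a tensor field
#' @param field a `tensor_field`.
#' @return matrix (n_voxels x 3), rows are unit principal directions
#'   (zero rows outside the mask).
#' @export
principal_direction <- function(field) {
  Dm <- matrix(field$D, ncol = 6L)
  out <- matrix(0, nrow(Dm), 3)
  for (i in which(as.vector(field$mask))) {
    ev <- eigen(tensor_to_matrix(Dm[i, ]), symmetric = TRUE)
    out[i, ] <- ev$vectors[, 1]
  }
  out
}

#' Restrict a tensor field to selected tissue labels
#'
#' @param field a `tensor_field`.
#' @param labels a congruent `label_volume`.
#' @param keep_labels integer label ids to keep.
#' @return the field with its validity mask intersected.
#' @export
mask_tensors <- function(field, labels, keep_labels) {
  stopifnot(inherits(field, "tensor_field"), inherits(labels, "label_volume"))
  if (!identical(dim(field$mask), dim(labels$labels)))
    stop("grids are not congruent")
  m <- field$mask & (labels$labels %in% as.integer(keep_labels))
  if (!any(m)) warning("mask_tensors: resulting mask is empty")
  field$mask <- m
  field
}

#' Map diffusion tensors to anisotropic electrical conductivity
#'
#' `sigma = k * D` applied eigenvalue-wise (eigenvectors preserved), with
#' the resulting eigenvalues clipped to `(eps, cap]`; the default cap of
#' 1.8 S/m is the CSF conductivity. Voxels outside the DTI mask receive
#' the isotropic fallback scalar of their tissue label.
#'
#' @param field a `tensor_field` (diffusivities in mm^2/s).
#' @param labels a congruent `label_volume` (for fallbacks).
#' @param scale_k linear scale, S s/mm^3 (default 0.844, the standard
#'   literature coefficient; configurable).
#' @param cap maximum conductivity eigenvalue, S/m (default 1.8).
#' @param fallback named numeric vector: label id (as name) -> scalar
#'   conductivity S/m; must cover every label present.
#' @param unit_gain conversion of `scale_k * D` (S/mm given the default
#'   units) to S/m; default 1000. Set to 1 if `scale_k` is already in
#'   S s/(m mm^2).
#' @return a `conductivity_map`: list with `sigma` (grid x 6 array, S/m),
#'   `tensor_mask` (where DTI-derived), `cap`, `spacing`, `origin`.
#' @export
map_conductivity <- function(field, labels, scale_k = 0.844, cap = 1.8,
                             fallback, unit_gain = 1000) {
  stopifnot(inherits(field, "tensor_field"), scale_k > 0, cap > 0)
  scale_k <- scale_k * unit_gain
  d <- dim(field$mask)
  present <- sort(unique(as.vector(labels$labels)))
  missing <- setdiff(as.character(present), names(fallback))
  if (length(missing))
    stop("missing fallback conductivity for label(s): ",
         paste(missing, collapse = ", "))
  eps <- 1e-6
  sig <- array(0, c(d, 6L))
  sigm <- matrix(sig, ncol = 6L)
  # fallback scalars everywhere first
  fb <- unname(fallback[as.character(as.vector(labels$labels))])
  fb <- pmin(pmax(fb, 0), cap)
  sigm[, 1] <- fb; sigm[, 2] <- fb; sigm[, 3] <- fb
  # tensor voxels: eigenvalue-wise scale + clip
  Dm <- matrix(field$D, ncol = 6L)
  for (i in which(as.vector(field$mask))) {
    ev <- eigen(tensor_to_matrix(Dm[i, ]), symmetric = TRUE)
    lam <- pmin(pmax(scale_k * ev$values, eps), cap)
    M2 <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    sigm[i, ] <- c(M2[1, 1], M2[2, 2], M2[3, 3], M2[1, 2], M2[1, 3], M2[2, 3])
  }
  structure(list(sigma = array(sigm, c(d, 6L)), tensor_mask = field$mask,
                 cap = cap, spacing = field$spacing, origin = field$origin),
            class = "conductivity_map")
}

#' Sample a conductivity (or diffusion) tensor field at target points
#'
#' Component-wise trilinear interpolation at the target centroids,
#' followed by re-symmetrization (structural) and eigenvalue re-clipping.
#' Points outside the source grid get the fallback scalar.
#'
#' @param map a `conductivity_map`.
#' @param points n x 3 matrix of target positions in mm.
#' @param fallback scalar conductivity for out-of-grid points (default 0).
#' @param cap eigenvalue cap (default from the map).
#' @return n x 6 matrix of tensor components.
#' @export
sample_to_grid <- function(map, points, fallback = 0, cap = map$cap) {
  stopifnot(inherits(map, "conductivity_map"))
  d <- dim(map$tensor_mask)
  pts <- matrix(points, ncol = 3L)
  n <- nrow(pts)
  out <- matrix(0, n, 6L)
  for (k in 1:6) {
    comp <- array(map$sigma[, , , k], d)
    img <- scalar_image(comp, map$spacing, map$origin)
    out[, k] <- trilinear_at(img, pts)
  }
  oob <- !is.finite(out[, 1])
  out[oob, ] <- 0
  out[oob, 1:3] <- fallback
  # eigenvalue re-clip
  eps <- 1e-9
  for (i in which(!oob)) {
    M <- tensor_to_matrix(out[i, ])
    ev <- eigen(M, symmetric = TRUE)
    lam <- pmin(pmax(ev$values, eps), cap)
    if (any(lam != ev$values)) {
      M2 <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
      out[i, ] <- c(M2[1, 1], M2[2, 2], M2[3, 3], M2[1, 2], M2[1, 3], M2[2, 3])
    }
  }
  out
}

# trilinear interpolation of a scalar_image at arbitrary mm points
trilinear_at <- function(img, pts) {
  d <- dim(img$values)
  cx <- (pts[, 1] - img$origin[1]) / img$spacing[1]
  cy <- (pts[, 2] - img$origin[2]) / img$spacing[2]
  cz <- (pts[, 3] - img$origin[3]) / img$spacing[3]
  ok <- cx >= 0 & cy >= 0 & cz >= 0 &
    cx <= d[1] - 1 & cy <= d[2] - 1 & cz <= d[3] - 1
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  x0 <- pmin(floor(cx[ok]), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(cy[ok]), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(cz[ok]), d[3] - 2); z0 <- pmax(z0, 0)
  if (d[1] == 1) x0 <- rep(0, sum(ok))
  if (d[2] == 1) y0 <- rep(0, sum(ok))
  if (d[3] == 1) z0 <- rep(0, sum(ok))
  fx <- cx[ok] - x0; fy <- cy[ok] - y0; fz <- cz[ok] - z0
  at <- function(i, j, k) {
    img$values[cbind(pmin(i + 1, d[1]), pmin(j + 1, d[2]), pmin(k + 1, d[3]))]
  }
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    at(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    at(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    at(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    at(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[ok] <- v
  out
}
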