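# Semi-automatic segmentation primitives: the classic toolbox used to build
# masks from image contrasts (smoothing, thresholding, region growing,
# k-means, morphology, inter-slice interpolation). Foreground connectivity
# is 6-connected everywhere.

#' Separable Gaussian smoothing with a kernel width given in mm
#'
#' The kernel width is interpreted as full width at half maximum by
#' default (`kind = "fwhm"`); set `kind = "sd"` to interpret it as the
#' Gaussian standard deviation instead (the convention the source tools
#' leave ambiguous). Boundaries are handled by replicate-clamping, which
#' preserves constant images exactly.
#'
#' @param img a `scalar_image`.
#' @param fwhm_mm numeric length-1 or length-3 kernel width in mm; 0 means
#'   identity along that axis.
#' @param kind `"fwhm"` (default) or `"sd"`.
#' @return a `scalar_image`.
#' @export
gaussian_smooth <- function(img, fwhm_mm, kind = c("fwhm", "sd")) {
  stopifnot(inherits(img, "scalar_image"))
  kind <- match.arg(kind)
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3L)
  stopifnot(all(fwhm_mm >= 0))
  sigma_mm <- if (kind == "fwhm") fwhm_mm / (2 * sqrt(2 * log(2))) else fwhm_mm
  arr <- img$values
  d <- dim(arr)
  for (ax in 1:3) {
    sig <- sigma_mm[ax] / img$spacing[ax]
    if (sig <= 0) next
    r <- max(1L, ceiling(4 * sig))
    off <- (-r):r
    w <- exp(-off^2 / (2 * sig^2))
    w <- w / sum(w)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (j in seq_along(off)) {
      src <- pmin(pmax(seq_len(n) + off[j], 1L), n)
      K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + w[j]
    }
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), nrow = n)
    m <- K %*% m
    arr <- aperm(array(m, d[perm]), order(perm))
  }
  scalar_image(arr, spacing = img$spacing, origin = img$origin)
}

#' Histogram-based thresholding
#'
#' Automatic mode maximizes the between-class variance over all candidate
#' splits of the observed intensity values (Otsu's criterion, evaluated
#' exhaustively on the value histogram); the returned mask is
#' `{v >= threshold}` with the threshold placed at the smallest value of
#' the upper class, which makes the mask invariant under increasing affine
#' rescaling of the intensities.
#'
#' @param img a `scalar_image`.
#' @param method `"otsu"` or a numeric manual threshold.
#' @param max_levels automatic mode quantizes to at most this many distinct
#'   values (default 4096) before the exhaustive split search.
#' @return list with `mask` (logical array) and `threshold`.
#' @export
threshold_histogram <- function(img, method = "otsu", max_levels = 4096L) {
  stopifnot(inherits(img, "scalar_image"))
  v <- as.vector(img$values)
  if (is.numeric(method)) {
    return(list(mask = array(img$values >= method, dim(img$values)),
                threshold = method))
  }
  stopifnot(identical(method, "otsu"))
  u <- sort(unique(v))
  if (length(u) < 2L) stop("automatic thresholding needs a non-constant image")
  if (length(u) > max_levels) {
    br <- seq(min(v), max(v), length.out = max_levels + 1L)
    idx <- pmin(findInterval(v, br, rightmost.closed = TRUE), max_levels)
    cnt <- tabulate(idx, max_levels)
    mids <- (br[-1] + br[-length(br)]) / 2
    keep <- cnt > 0
    u <- mids[keep]; cnt <- cnt[keep]
  } else {
    cnt <- tabulate(match(v, u), length(u))
  }
  n <- sum(cnt)
  cw <- cumsum(cnt)
  cm <- cumsum(cnt * u)
  tot <- cm[length(cm)]
  w0 <- cw[-length(cw)] / n
  mu0 <- cm[-length(cm)] / cw[-length(cw)]
  mu1 <- (tot - cm[-length(cm)]) / (n - cw[-length(cw)])
  between <- w0 * (1 - w0) * (mu0 - mu1)^2
  i <- which.max(between)
  thr <- u[i + 1L]
  list(mask = array(img$values >= thr, dim(img$values)), threshold = thr)
}

#' Seeded region growing within an intensity band
#'
#' 6-connected flood fill of voxels with intensity in `[low, high]`
#' reachable from the seeds. A seed whose own intensity is out of band
#' contributes nothing (not an error).
#'
#' @param img a `scalar_image`.
#' @param seeds integer matrix (n x 3) of 1-based voxel indices.
#' @param low,high intensity band, `low <= high`.
#' @return logical array.
#' @export
region_grow <- function(img, seeds, low, high) {
  stopifnot(inherits(img, "scalar_image"), low <= high)
  seeds <- matrix(as.integer(seeds), ncol = 3L)
  d <- dim(img$values)
  if (any(seeds < 1L) || any(t(seeds) > d)) stop("seed outside the grid")
  band <- img$values >= low & img$values <= high
  lab <- array(.cc_label6(band, d), d)
  keep <- unique(lab[seeds])
  keep <- keep[keep > 0L]
  array(lab %in% keep, d)
}

#' K-means clustering of voxel intensities (Lloyd's algorithm)
#'
#' Clusters the scalar intensities into `k` groups; output labels are
#' relabelled in ascending order of cluster mean, so the result is a
#' deterministic function of (image, k, seed). Convergence is declared
#' when the assignments stop changing.
#'
#' @param img a `scalar_image`.
#' @param k number of clusters (>= 2).
#' @param seed integer seed for centre initialization.
#' @param max_iter iteration cap.
#' @return a `label_volume` with labels 1..k.
#' @export
kmeans_labels <- function(img, k, seed = 1L, max_iter = 200L) {
  stopifnot(inherits(img, "scalar_image"), k >= 2L)
  v <- as.vector(img$values)
  u <- unique(v)
  if (k > length(u)) stop("k exceeds the number of distinct intensity values")
  set.seed(seed)
  centers <- sort(sample(u, k))
  assign_old <- integer(length(v))
  for (it in seq_len(max_iter)) {
    o <- order(centers)
    cs <- centers[o]
    cuts <- (cs[-1] + cs[-k]) / 2
    a_sorted <- findInterval(v, cuts) + 1L
    assign <- o[a_sorted]  # sorted position -> original centre id
    for (j in seq_len(k)) {
      sel <- assign == j
      if (any(sel)) {
        centers[j] <- mean(v[sel])
      } else {
        # deterministic re-seed: value farthest from its nearest centre
        dmin <- vapply(u, function(x) min(abs(x - centers)), 1)
        centers[j] <- u[which.max(dmin)]
      }
    }
    if (identical(assign, assign_old)) break
    assign_old <- assign
  }
  relab <- order(order(centers))
  label_volume(array(relab[assign], dim(img$values)),
               spacing = img$spacing, origin = img$origin)
}

# Euclidean-ball dilation/erosion in voxel units via the distance transform
dilate_ball <- function(mask, radius) {
  if (radius <= 0 || !any(mask)) return(mask)
  d2 <- .edt_sq(mask, dim(mask), c(1, 1, 1))
  array(d2 <= radius^2 + 1e-9, dim(mask))
}
erode_ball <- function(mask, radius) !dilate_ball(!mask, radius)

#' Morphological mask cleanup
#'
#' Opening/closing use a Euclidean ball structuring element of
#' `radius_vox` voxels (implemented exactly via the distance transform).
#' Island removal deletes 6-connected foreground components smaller than
#' `min_island_size`; hole filling fills background components that do not
#' touch the volume border.
#'
#' @param mask logical 3D array.
#' @param operation one of `"open"`, `"close"`, `"erode"`, `"dilate"`,
#'   `"remove_islands"`, `"fill_holes"`.
#' @param radius_vox ball radius in voxels (open/close/erode/dilate).
#' @param min_island_size minimum component size kept (remove_islands).
#' @return logical array.
#' @export
morph_cleanup <- function(mask, operation, radius_vox = 1,
                          min_island_size = 2L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, radius_vox >= 0)
  d <- dim(mask)
  switch(operation,
    dilate = dilate_ball(mask, radius_vox),
    erode = erode_ball(mask, radius_vox),
    open = dilate_ball(erode_ball(mask, radius_vox), radius_vox),
    close = erode_ball(dilate_ball(mask, radius_vox), radius_vox),
    remove_islands = {
      lab <- .cc_label6(mask, d)
      if (max(lab) == 0L) return(mask)
      sizes <- tabulate(lab[lab > 0L])
      keep <- which(sizes >= min_island_size)
      array(lab %in% keep & lab > 0L, d)
    },
    fill_holes = {
      lab <- array(.cc_label6(!mask, d), d)
      if (max(lab) == 0L) return(mask)
      border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                         lab[, , 1], lab[, , d[3]]))
      border <- border[border > 0L]
      mask | (lab > 0L & !(lab %in% border))
    },
    stop("unknown operation: ", operation))
}

#' Topologically flexible interpolation between two slices
#'
#' Realized with signed Euclidean distance transforms: each endpoint mask
#' is converted to a signed distance field (negative inside), the fields
#' are blended linearly for each intermediate slice, and the intermediate
#' mask is the region where the blended distance is `<= 0`. Endpoints are
#' reproduced exactly, and topology is free to change between slices.
#'
#' @param mask_first,mask_last logical matrices of the same shape, both
#'   nonempty.
#' @param n_between number of intermediate slices (>= 0).
#' @param spacing in-plane spacing in mm (length 2).
#' @return list of `n_between + 2` logical matrices, endpoints included.
#' @export
interslice_interpolate <- function(mask_first, mask_last, n_between,
                                   spacing = c(1, 1)) {
  stopifnot(is.logical(mask_first), is.logical(mask_last),
            identical(dim(mask_first), dim(mask_last)), n_between >= 0)
  if (!any(mask_first) || !any(mask_last))
    stop("endpoint masks must be nonempty")
  d2 <- dim(mask_first)
  sdf <- function(m) {
    # negative inside the mask, positive outside
    m3 <- array(m, c(d2, 1L))
    sp <- c(spacing, 1)
    sqrt(.edt_sq(m3, dim(m3), sp)) - sqrt(.edt_sq(!m3, dim(m3), sp))
  }
  s0 <- sdf(mask_first)
  s1 <- sdf(mask_last)
  out <- vector("list", n_between + 2L)
  out[[1]] <- mask_first
  if (n_between > 0) {
    for (i in seq_len(n_between)) {
      t <- i / (n_between + 1)
      out[[i + 1L]] <- matrix(((1 - t) * s0 + t * s1) <= 0, d2[1], d2[2])
    }
  }
  out[[n_between + 2L]] <- mask_last
  out
}

#' Marker-based watershed on the gradient magnitude (experimental)
#'
#' A simple priority-flood: voxels are visited in increasing order of
#' gradient magnitude and take the label of an already-labelled
#' 6-neighbour. Provided as an experimental stand-in for interactive
#' watershed tools; no parameters beyond the markers.
#'
#' @param img a `scalar_image`.
#' @param markers integer array, 0 = unlabelled, >0 = marker labels.
#' @return a `label_volume` (0 where unreachable).
#' @export
watershed_markers <- function(img, markers) {
  stopifnot(inherits(img, "scalar_image"),
            identical(dim(img$values), dim(markers)))
  d <- dim(img$values)
  g <- gradient_magnitude(img)
  lab <- as.integer(markers)
  ord <- order(as.vector(g))
  nb_off <- c(-1L, 1L, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  # repeat sweeps until stable (few passes suffice on smooth gradients)
  repeat {
    changed <- FALSE
    for (v in ord) {
      if (lab[v] != 0L) next
      x <- (v - 1L) %% nx
      y <- ((v - 1L) %/% nx) %% ny
      z <- (v - 1L) %/% (nx * ny)
      ok <- c(x > 0, x < nx - 1, y > 0, y < ny - 1, z > 0, z < nz - 1)
      for (k in which(ok)) {
        l <- lab[v + nb_off[k]]
        if (l != 0L) { lab[v] <- l; changed <- TRUE; break }
      }
    }
    if (!changed) break
  }
  label_volume(array(lab, d), spacing = img$spacing, origin = img$origin)
}

gradient_magnitude <- function(img) {
  a <- img$values
  d <- dim(a)
  g2 <- array(0, d)
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    idx_p <- idx_m <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_p[[ax]] <- ip; idx_m[[ax]] <- im
    diff <- (do.call(`[`, c(list(a), idx_p)) -
               do.call(`[`, c(list(a), idx_m))) / (2 * img$spacing[ax])
    g2 <- g2 + diff^2
  }
  array(sqrt(g2), d)
}
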