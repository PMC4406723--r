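# Synthetic head phantom: analytic nested-tissue geometry with exactly known
# ground truth, rendered image contrasts, simulated raters, and synthetic
# diffusion data. Stands in for subject MRI/DTI throughout the pipeline.

#' Phantom specification
#'
#' Describes an analytic multi-tissue phantom: grid geometry, an ordered
#' list of tissue solids (outermost first; voxel assignment is
#' last-writer-wins so inner tissues carve into outer ones), per-contrast
#' mean intensities, and noise/bias parameters.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm positive numeric length-3, mm.
#' @param tissue_defs ordered list; each element a list with `label`
#'   (unique positive integer), `name`, and `shape`: either
#'   `list(type = "ellipsoid", center, semiaxes)` or
#'   `list(type = "cylinder", center, radius, axis, half_length)`, all mm.
#' @param contrast_means named list of contrasts; each a named numeric
#'   vector mapping label id (as name, `"0"` = background) to mean
#'   intensity.
#' @param noise_sigma,bias_amplitude nonnegative reals; see
#'   [render_contrast()].
#' @param seed integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, spacing_mm, tissue_defs,
                         contrast_means = list(), noise_sigma = 0,
                         bias_amplitude = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            noise_sigma >= 0, bias_amplitude >= 0)
  labs <- vapply(tissue_defs, function(t) as.integer(t$label), 1L)
  if (anyDuplicated(labs)) stop("tissue label ids must be unique")
  if (length(labs) && any(labs <= 0L)) stop("tissue label ids must be > 0")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 tissue_defs = tissue_defs, contrast_means = contrast_means,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default desk-scale head phantom specification
#'
#' A 64 mm toy head: skin, three skull layers (outer table, diploe, inner
#' table), CSF, grey matter, white matter, ventricles, and two eye globes
#' placed anteriorly (carved into the front of the toy skull so they sit
#' under a frontal electrode). T1-like and T2-like contrast means swap the
#' relative brightness of CSF and white matter, as the real sequences do.
#'
#' @param n grid size per axis (default 64).
#' @param spacing isotropic spacing in mm (default 1).
#' @param seed integer seed.
#' @return a `phantom_spec`.
#' @export
default_head_spec <- function(n = 64L, spacing = 1, seed = 1L) {
  n <- as.integer(n)
  ctr <- rep((n - 1) / 2 * spacing, 3)
  s <- n * spacing / 64  # scale the 64 mm reference head to the grid
  ell <- function(label, name, semi, off = c(0, 0, 0)) {
    list(label = label, name = name,
         shape = list(type = "ellipsoid", center = ctr + off * s,
                      semiaxes = semi * s))
  }
  defs <- list(
    ell(1L, "skin",             c(25.0, 30.0, 27.0)),
    ell(2L, "skull_outer",      c(22.5, 27.5, 24.5)),
    ell(3L, "skull_diploe",     c(21.5, 26.5, 23.5)),
    ell(4L, "skull_inner",      c(20.5, 25.5, 22.5)),
    ell(5L, "csf",              c(19.5, 24.5, 21.5)),
    ell(6L, "gm",               c(18.0, 23.0, 20.0)),
    ell(7L, "wm",               c(13.5, 18.0, 15.0)),
    ell(8L, "ventricles",       c(3.5, 7.0, 4.5), off = c(0, 0, -1)),
    ell(9L, "eye_left",         c(3, 3, 3), off = c(-8, 25, -2)),
    ell(10L, "eye_right",       c(3, 3, 3), off = c(8, 25, -2)))
  t1 <- c("0" = 0, "1" = 60, "2" = 30, "3" = 50, "4" = 30, "5" = 15,
          "6" = 70, "7" = 95, "8" = 15, "9" = 25, "10" = 25)
  t2 <- c("0" = 0, "1" = 60, "2" = 20, "3" = 40, "4" = 20, "5" = 100,
          "6" = 75, "7" = 55, "8" = 100, "9" = 90, "10" = 90)
  phantom_spec(grid_shape = rep(n, 3), spacing_mm = rep(spacing, 3),
               tissue_defs = defs,
               contrast_means = list(t1 = t1, t2 = t2),
               noise_sigma = 3, bias_amplitude = 0, seed = seed)
}

#' Head phantom specification with fiducial-like internal markers
#'
#' The nested-ellipsoid head is nearly axis-symmetric, which leaves scale
#' and shear weakly constrained in registration studies. This variant adds
#' four small asymmetric intra-cranial marker ellipsoids with distinct
#' contrast in both renderings, the synthetic analogue of the internal
#' landmarks real anatomy provides.
#'
#' @param n,spacing,seed as [default_head_spec()].
#' @return a `phantom_spec`.
#' @export
registration_phantom_spec <- function(n = 64L, spacing = 1, seed = 1L) {
  spec <- default_head_spec(n, spacing, seed)
  ctr <- rep((n - 1) / 2 * spacing, 3)
  s <- n * spacing / 64
  ell <- function(label, name, semi, off) {
    list(label = label, name = name,
         shape = list(type = "ellipsoid", center = ctr + off * s,
                      semiaxes = semi * s))
  }
  spec$tissue_defs <- c(spec$tissue_defs, list(
    ell(11L, "marker1", c(2.5, 2.5, 2.5), c(7, 5, 6)),
    ell(12L, "marker2", c(3.0, 2.0, 2.5), c(-8, -6, 4)),
    ell(13L, "marker3", c(2.0, 3.0, 2.0), c(5, -9, -5)),
    ell(14L, "marker4", c(2.5, 2.0, 3.0), c(-4, 8, -7))))
  spec$contrast_means$t1 <- c(spec$contrast_means$t1,
                              "11" = 110, "12" = 40, "13" = 85, "14" = 20)
  spec$contrast_means$t2 <- c(spec$contrast_means$t2,
                              "11" = 30, "12" = 95, "13" = 15, "14" = 70)
  spec
}

inside_shape <- function(shape, gc) {
  if (shape$type == "ellipsoid") {
    c0 <- shape$center; a <- shape$semiaxes
    ((gc$x - c0[1]) / a[1])^2 + ((gc$y - c0[2]) / a[2])^2 +
      ((gc$z - c0[3]) / a[3])^2 <= 1
  } else if (shape$type == "cylinder") {
    c0 <- shape$center
    ax <- shape$axis / sqrt(sum(shape$axis^2))
    dx <- gc$x - c0[1]; dy <- gc$y - c0[2]; dz <- gc$z - c0[3]
    t <- dx * ax[1] + dy * ax[2] + dz * ax[3]
    r2 <- (dx - t * ax[1])^2 + (dy - t * ax[2])^2 + (dz - t * ax[3])^2
    abs(t) <= shape$half_length & r2 <= shape$radius^2
  } else stop("unknown shape type: ", shape$type)
}

shape_bbox <- function(shape) {
  if (shape$type == "ellipsoid") {
    rbind(shape$center - shape$semiaxes, shape$center + shape$semiaxes)
  } else {
    ax <- shape$axis / sqrt(sum(shape$axis^2))
    ext <- abs(ax) * shape$half_length +
      shape$radius * sqrt(pmax(0, 1 - ax^2))
    rbind(shape$center - ext, shape$center + ext)
  }
}

#' Generate the ground-truth label volume of a phantom
#'
#' Voxels are assigned by testing their centres against each tissue solid
#' in order (outermost first, last writer wins); unassigned voxels are
#' background air (label 0).
#'
#' @param spec a [phantom_spec()].
#' @return a `label_volume` with the phantom's tissue table attached.
#' @export
generate_label_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  origin <- c(0, 0, 0)
  lo <- origin - sp / 2
  hi <- origin + (d - 1) * sp + sp / 2
  gc <- grid_coords(d, sp, origin)
  labels <- array(0L, d)
  for (t in spec$tissue_defs) {
    bb <- shape_bbox(t$shape)
    if (any(bb[1, ] < lo) || any(bb[2, ] > hi))
      stop(sprintf("tissue '%s' exceeds the grid", t$name))
    labels[inside_shape(t$shape, gc)] <- as.integer(t$label)
  }
  tt <- data.frame(
    label = vapply(spec$tissue_defs, function(t) as.integer(t$label), 1L),
    name = vapply(spec$tissue_defs, function(t) as.character(t$name), ""))
  label_volume(labels, spacing = sp, origin = origin, tissue_table = tt)
}

# smooth low-order multiplicative bias field in [1-amp, 1+amp]:
# sum of 3 low-frequency cosine components with seeded random orientation
bias_field <- function(dim, spacing, amplitude, seed) {
  if (amplitude == 0) return(array(1, dim))
  set.seed(seed)
  gc <- grid_coords(dim, spacing, c(0, 0, 0))
  ext <- dim * spacing
  b <- array(0, dim)
  for (k in 1:3) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    freq <- runif(1, 0.5, 1.5) * pi / max(ext)
    phase <- runif(1, 0, 2 * pi)
    b <- b + cos(freq * (gc$x * dir[1] + gc$y * dir[2] + gc$z * dir[3]) + phase)
  }
  b <- b / max(abs(b))
  1 + amplitude * b
}

#' Render a scalar image contrast from a label volume
#'
#' Intensity model: `mean(label) * bias(x) + noise`, with a smooth
#' multiplicative low-order bias field of relative amplitude
#' `bias_amplitude` and additive zero-mean Gaussian noise of SD
#' `noise_sigma`. Deterministic given `seed`.
#'
#' @param labels a `label_volume`.
#' @param means named numeric vector, label id (as name) to mean intensity;
#'   every label present in the volume (including `"0"`) must be covered.
#' @param noise_sigma,bias_amplitude nonnegative reals.
#' @param seed integer seed.
#' @return a `scalar_image`.
#' @export
render_contrast <- function(labels, means, noise_sigma = 0,
                            bias_amplitude = 0, seed = 1L) {
  stopifnot(inherits(labels, "label_volume"))
  present <- sort(unique(as.vector(labels$labels)))
  missing <- setdiff(as.character(present), names(means))
  if (length(missing))
    stop("no contrast mean for label(s): ", paste(missing, collapse = ", "))
  d <- dim(labels$labels)
  base <- array(unname(means[as.character(as.vector(labels$labels))]), d)
  img <- base * bias_field(d, labels$spacing, bias_amplitude, seed)
  if (noise_sigma > 0) {
    set.seed(seed + 1L)
    img <- img + array(rnorm(prod(d), 0, noise_sigma), d)
  }
  scalar_image(img, spacing = labels$spacing, origin = labels$origin)
}

#' Rater performance model
#'
#' Parameters of a simulated human rater: per-voxel sensitivity `p`
#' (probability a true foreground voxel is marked), specificity `q`
#' (probability a true background voxel is left unmarked), and an optional
#' spatially correlated boundary jitter amplitude in mm.
#'
#' @param sensitivity,specificity reals in (0, 1].
#' @param boundary_jitter_mm nonnegative real.
#' @param seed integer seed.
#' @return object of class `rater_model`.
#' @export
rater_model <- function(sensitivity, specificity, boundary_jitter_mm = 0,
                        seed = 1L) {
  stopifnot(sensitivity > 0, sensitivity <= 1,
            specificity > 0, specificity <= 1, boundary_jitter_mm >= 0)
  structure(list(p = sensitivity, q = specificity,
                 jitter = boundary_jitter_mm, seed = as.integer(seed)),
            class = "rater_model")
}

#' Simulate a rater's binary segmentation of a known truth mask
#'
#' With `boundary_jitter_mm = 0` (mode A) each true voxel is kept with
#' probability `p` and each background voxel marked with probability
#' `1 - q`, independently — exactly the STAPLE generative model. With
#' jitter > 0 (mode B) the truth boundary is first displaced by a smooth
#' random field of the requested mm amplitude (spatially correlated error,
#' which STAPLE's independence assumption does not cover), then mode A is
#' applied.
#'
#' @param truth logical 3D array (or `label_volume`, foreground = nonzero).
#' @param model a [rater_model()].
#' @param spacing voxel spacing in mm (needed for jitter).
#' @return logical 3D array.
#' @export
simulate_rater <- function(truth, model, spacing = c(1, 1, 1)) {
  stopifnot(inherits(model, "rater_model"))
  if (inherits(truth, "label_volume")) {
    spacing <- truth$spacing
    truth <- truth$labels > 0L
  }
  stopifnot(is.logical(truth), any(truth))
  d <- dim(truth)
  set.seed(model$seed)
  base <- truth
  if (model$jitter > 0) {
    sdf <- sqrt(.edt_sq(truth, dim(truth), spacing)) -
      sqrt(.edt_sq(!truth, dim(truth), spacing))  # negative inside
    field <- array(rnorm(prod(d)), d)
    field <- gaussian_smooth(scalar_image(field, spacing), fwhm_mm = 4 * spacing)$values
    field <- field / stats::sd(field) * model$jitter
    base <- (sdf - field) <= 0
    if (!any(base)) base <- truth  # degenerate jitter wiped the structure
  }
  u <- array(runif(prod(d)), d)
  out <- array(FALSE, d)
  out[base] <- u[base] < model$p
  out[!base] <- u[!base] >= model$q
  out
}

#' Analytic diffusion tensor field for a phantom
#'
#' CSF and grey matter are isotropic with the given diffusivities; white
#' matter carries cigar-shaped tensors (`lambda1 > lambda2 = lambda3`)
#' whose principal axis follows an analytic fiber family: tangents of arcs
#' around the anterior-posterior axis through the brain centre, a toy
#' corpus-callosum-like arching geometry.
#'
#' @param labels a `label_volume`.
#' @param diffusivities list with `wm` (length-3 eigenvalues, mm^2/s,
#'   descending), `gm` and `csf` (scalars).
#' @param wm_label,gm_labels,csf_labels label ids (defaults match
#'   [default_head_spec()]).
#' @return a `tensor_field`: list with `D` (array dim x 6, component order
#'   xx, yy, zz, xy, xz, yz), `mask`, `spacing`, `origin`.
#' @export
make_tensor_field <- function(labels,
                              diffusivities = list(
                                wm = c(1.4e-3, 0.35e-3, 0.35e-3),
                                gm = 0.8e-3, csf = 3.0e-3),
                              wm_label = 7L, gm_labels = 6L,
                              csf_labels = c(5L, 8L)) {
  stopifnot(inherits(labels, "label_volume"))
  lam <- sort(as.numeric(diffusivities$wm), decreasing = TRUE)
  if (any(lam <= 0) || diffusivities$gm <= 0 || diffusivities$csf <= 0)
    stop("diffusivities must be positive (tensor must be positive-definite)")
  d <- dim(labels$labels)
  D <- array(0, c(d, 6L))
  mask <- array(FALSE, d)
  iso_set <- function(ids, val) {
    m <- labels$labels %in% ids
    for (k in 1:3) {
      Dk <- D[, , , k]; Dk[m] <- val; D[, , , k] <<- Dk
    }
    mask[m] <<- TRUE
  }
  iso_set(gm_labels, diffusivities$gm)
  iso_set(csf_labels, diffusivities$csf)
  wm <- labels$labels == wm_label
  if (any(wm)) {
    gc <- grid_coords(d, labels$spacing, labels$origin)
    ctr <- labels$origin + (d - 1) / 2 * labels$spacing
    dx <- gc$x[wm] - ctr[1]
    dz <- gc$z[wm] - ctr[3]
    r <- sqrt(dx^2 + dz^2)
    vx <- ifelse(r > 1e-9, -dz / pmax(r, 1e-9), 1)
    vz <- ifelse(r > 1e-9, dx / pmax(r, 1e-9), 0)
    l1 <- lam[1]; l2 <- lam[2]
    comps <- list(
      xx = l2 + (l1 - l2) * vx * vx,
      yy = rep(l2, sum(wm)),
      zz = l2 + (l1 - l2) * vz * vz,
      xy = rep(0, sum(wm)),
      xz = (l1 - l2) * vx * vz,
      yz = rep(0, sum(wm)))
    for (k in seq_along(comps)) {
      Dk <- D[, , , k]; Dk[wm] <- comps[[k]]; D[, , , k] <- Dk
    }
    mask[wm] <- TRUE
  }
  structure(list(D = D, mask = mask, spacing = labels$spacing,
                 origin = labels$origin),
            class = "tensor_field")
}

#' Synthesize a diffusion-weighted image stack from a tensor field
#'
#' Per voxel and measurement, `S = s0 * exp(-b * g' D g)` plus additive
#' Gaussian noise. Voxels outside the tensor mask carry zero diffusivity
#' (signal `s0`). Deterministic given `seed`.
#'
#' @param tensors a `tensor_field`.
#' @param protocol a [diffusion_protocol()].
#' @param s0 baseline signal.
#' @param noise_sigma Gaussian noise SD.
#' @param seed integer seed.
#' @return 4D array (grid x n_measurements) with attributes `spacing`,
#'   `origin`.
#' @export
synth_dwi <- function(tensors, protocol, s0 = 100, noise_sigma = 0,
                      seed = 1L) {
  stopifnot(inherits(tensors, "tensor_field"),
            inherits(protocol, "diffusion_protocol"))
  d <- dim(tensors$mask)
  nvol <- length(protocol$bvals)
  Dm <- matrix(tensors$D, ncol = 6L)  # xx yy zz xy xz yz
  out <- array(0, c(d, nvol))
  for (m in seq_len(nvol)) {
    b <- protocol$bvals[m]
    g <- protocol$bvecs[m, ]
    if (b == 0) {
      s <- rep(s0, nrow(Dm))
    } else {
      quad <- Dm[, 1] * g[1]^2 + Dm[, 2] * g[2]^2 + Dm[, 3] * g[3]^2 +
        2 * (Dm[, 4] * g[1] * g[2] + Dm[, 5] * g[1] * g[3] +
               Dm[, 6] * g[2] * g[3])
      s <- s0 * exp(-b * quad)
    }
    out[, , , m] <- array(s, d)
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    out <- out + array(rnorm(length(out), 0, noise_sigma), dim(out))
  }
  attr(out, "spacing") <- tensors$spacing
  attr(out, "origin") <- tensors$origin
  out
}

#' Write the full phantom bundle to disk
#'
#' Emits ground-truth labels and every configured contrast as NIfTI, the
#' spec as JSON, and (optionally) DWI + FSL-style bvals/bvecs.
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if absent).
#' @param dwi logical; also synthesize and write diffusion data.
#' @return invisible list of written paths.
#' @export
write_phantom_bundle <- function(spec, dir, dwi = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  vol <- generate_label_phantom(spec)
  paths$labels <- file.path(dir, "labels.nii")
  write_nifti(vol, paths$labels)
  for (nm in names(spec$contrast_means)) {
    img <- render_contrast(vol, spec$contrast_means[[nm]],
                           noise_sigma = spec$noise_sigma,
                           bias_amplitude = spec$bias_amplitude,
                           seed = spec$seed)
    paths[[nm]] <- file.path(dir, paste0(nm, ".nii"))
    write_nifti(img, paths[[nm]])
  }
  spec_out <- spec
  class(spec_out) <- NULL
  paths$spec <- file.path(dir, "phantom_spec.json")
  jsonlite::write_json(spec_out, paths$spec, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (dwi) {
    proto <- default_protocol()
    tf <- make_tensor_field(vol)
    stack <- synth_dwi(tf, proto, s0 = 100, noise_sigma = spec$noise_sigma,
                       seed = spec$seed + 2L)
    paths$dwi <- file.path(dir, "dwi.nii")
    write_nifti(stack, paths$dwi, spacing = vol$spacing, origin = vol$origin)
    paths$bvals <- file.path(dir, "bvals")
    paths$bvecs <- file.path(dir, "bvecs")
    writeLines(paste(protocol_format(proto$bvals), collapse = " "),
               paths$bvals)
    writeLines(apply(t(proto$bvecs), 1, function(r)
      paste(protocol_format(r), collapse = " ")), paths$bvecs)
  }
  invisible(paths)
}

protocol_format <- function(x) formatC(x, format = "g", digits = 10)
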