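#' Scalar image on a regular 3D grid
#'
#' Container for a real-valued volume with voxel spacing and origin in mm.
#' World coordinates follow the voxel-centre convention:
#' `x_mm = origin + (index - 1) * spacing`.
#'
#' @param values numeric 3D array (finite or NA for invalid samples).
#' @param spacing positive numeric length-3, mm per voxel.
#' @param origin numeric length-3, world position (mm) of voxel (1,1,1).
#' @return object of class `scalar_image`.
#' @export
scalar_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3L, all(spacing > 0), length(origin) == 3L,
            all(is.finite(spacing)), all(is.finite(origin)))
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "scalar_image")
}

#' Integer tissue-label volume
#'
#' @param labels integer 3D array; 0 is background air, positive ids are
#'   tissues.
#' @param spacing,origin grid geometry in mm (voxel-centre convention).
#' @param tissue_table optional data.frame with columns `label`, `name`.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         tissue_table = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be >= 0")
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(labels = labels, spacing = spacing,
                 origin = as.numeric(origin), tissue_table = tissue_table),
            class = "label_volume")
}

#' @export
print.scalar_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("scalar_image %d x %d x %d, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  ids <- sort(unique(as.vector(x$labels)))
  cat(sprintf("label_volume %d x %d x %d, spacing %s mm, labels: %s\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              paste(ids, collapse = ", ")))
  invisible(x)
}

# world coordinates (mm) of every voxel centre along one axis
axis_coords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

# voxel-centre coordinate arrays for a grid; returns list(x, y, z) arrays
grid_coords <- function(dim, spacing, origin) {
  cx <- axis_coords(dim[1], spacing[1], origin[1])
  cy <- axis_coords(dim[2], spacing[2], origin[2])
  cz <- axis_coords(dim[3], spacing[3], origin[3])
  list(x = array(rep(cx, times = dim[2] * dim[3]), dim),
       y = array(rep(rep(cy, each = dim[1]), times = dim[3]), dim),
       z = array(rep(cz, each = dim[1] * dim[2]), dim))
}

check_congruent <- function(a, b) {
  da <- if (inherits(a, "label_volume")) dim(a$labels) else dim(a$values)
  db <- if (inherits(b, "label_volume")) dim(b$labels) else dim(b$values)
  if (!identical(da, db)) stop("grids are not congruent")
  invisible(TRUE)
}

# binary mask helper: accepts logical array or label_volume + label id
as_mask_array <- function(mask) {
  if (inherits(mask, "label_volume")) return(mask$labels > 0L)
  if (is.logical(mask)) return(mask)
  if (is.numeric(mask)) return(mask != 0)
  stop("cannot interpret mask")
}
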