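# Validation metrics and rater-variability statistics: Dice overlap,
# modified Hausdorff distance on boundary voxels, Kruskal-Wallis and
# Lilliefors tests, and the per-structure/per-rater study table.

#' Dice similarity index
#'
#' `D = 2 |S1 n S2| / (|S1| + |S2|)`; 1 means perfect agreement. Undefined
#' (error) when both masks are empty.
#'
#' @param s1,s2 congruent binary masks (logical arrays or matrices).
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(s1, s2) {
  s1 <- as_mask_array(s1); s2 <- as_mask_array(s2)
  if (!identical(dim(s1), dim(s2))) stop("grids are not congruent")
  n1 <- sum(s1); n2 <- sum(s2)
  if (n1 + n2 == 0) stop("undefined Dice: both masks empty")
  2 * sum(s1 & s2) / (n1 + n2)
}

#' Boundary voxel centres of a mask, in mm
#'
#' A voxel is a boundary voxel when at least one face-neighbour
#' (6-neighbourhood in 3D, 4-neighbourhood for 2D slices) is outside the
#' mask or outside the grid.
#'
#' @param mask logical matrix (2D slice) or 3D array, nonempty.
#' @param spacing mm per voxel (length 2 or 3 to match).
#' @return n x d matrix of boundary point coordinates in mm.
#' @export
boundary_points <- function(mask, spacing = NULL) {
  stopifnot(is.logical(mask), any(mask))
  d <- dim(mask)
  nd <- length(d)
  if (is.null(spacing)) spacing <- rep(1, nd)
  stopifnot(length(spacing) == nd)
  interior <- array(TRUE, d)
  for (ax in seq_len(nd)) {
    n <- d[ax]
    for (dir in c(-1L, 1L)) {
      idx <- pmin(pmax(seq_len(n) + dir, 1L), n)
      sub <- rep(list(quote(expr = )), nd)
      sub[[ax]] <- idx
      shifted <- do.call(`[`, c(list(mask), sub, list(drop = FALSE)))
      # voxels at the grid edge see "outside" in that direction
      edge <- rep(list(quote(expr = )), nd)
      edge[[ax]] <- if (dir < 0) 1L else n
      shifted <- array(shifted, d)
      tmp <- array(TRUE, d)
      tmp[] <- shifted
      eidx <- as.list(edge)
      tmp <- do.call(`[<-`, c(list(tmp), eidx, list(value = FALSE)))
      interior <- interior & tmp
    }
  }
  bnd <- mask & !interior
  w <- which(bnd, arr.ind = TRUE)
  sweep(w - 1, 2, spacing, `*`)
}

directed_mean_dist <- function(X, Y) {
  # mean over X of the nearest distance to Y; chunked O(|X||Y|) brute
  # force on explicit coordinate differences (the expanded-square form
  # loses ~1e-8 absolute accuracy to cancellation near zero)
  nX <- nrow(X)
  chunk <- max(1L, floor(2e6 / max(1L, nrow(Y))))
  total <- 0
  i <- 1L
  while (i <= nX) {
    j <- min(nX, i + chunk - 1L)
    Xi <- X[i:j, , drop = FALSE]
    d2 <- outer(Xi[, 1], Y[, 1], `-`)^2
    for (k in 2:ncol(X)) d2 <- d2 + outer(Xi[, k], Y[, k], `-`)^2
    total <- total + sum(sqrt(apply(d2, 1, min)))
    i <- j + 1L
  }
  total / nX
}

#' Modified Hausdorff distance between two masks, in mm
#'
#' `MHD = max(d(S1, S2), d(S2, S1))` with
#' `d(X, Y) = mean_x min_y ||x - y||` over the two boundary point sets
#' (L2 norm in mm). Set `boundary = FALSE` for the full-mask variant
#' (all voxel centres instead of boundary voxels).
#'
#' @param s1,s2 congruent nonempty binary masks.
#' @param spacing mm per voxel.
#' @param boundary compute on boundary voxels (default, the documented
#'   interpretation) or on full masks.
#' @return nonnegative scalar, mm.
#' @export
mhd <- function(s1, s2, spacing = NULL, boundary = TRUE) {
  s1 <- as_mask_array(s1); s2 <- as_mask_array(s2)
  if (!identical(dim(s1), dim(s2))) stop("grids are not congruent")
  if (!any(s1) || !any(s2)) stop("undefined MHD: empty mask")
  nd <- length(dim(s1))
  if (is.null(spacing)) spacing <- rep(1, nd)
  pts <- function(m) {
    if (boundary) boundary_points(m, spacing)
    else sweep(which(m, arr.ind = TRUE) - 1, 2, spacing, `*`)
  }
  X <- pts(s1); Y <- pts(s2)
  max(directed_mean_dist(X, Y), directed_mean_dist(Y, X))
}

kw_statistic <- function(values, grp, k) {
  n <- length(values)
  r <- rank(values)
  sums <- vapply(split(r, grp), sum, 1)
  ns <- vapply(split(r, grp), length, 1L)
  H <- 12 / (n * (n + 1)) * sum(sums^2 / ns) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) H <- H / corr else H <- 0
  H
}

#' Kruskal-Wallis rank test
#'
#' Midrank-based H with tie correction; p-value from the chi-square
#' approximation with `k - 1` degrees of freedom, or from the exact
#' permutation distribution (`exact = TRUE`, total n <= 10).
#'
#' @param groups list of >= 2 numeric vectors.
#' @param exact use the exact permutation null (enumerates all group
#'   assignments; limited to total n <= 10).
#' @return list with `H`, `p`, `df`, `method`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, 1L) >= 1L))
  values <- unlist(groups, use.names = FALSE)
  grp <- rep(seq_along(groups), vapply(groups, length, 1L))
  k <- length(groups)
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, df = k - 1L, method = "degenerate"))
  H <- kw_statistic(values, grp, k)
  if (exact) {
    n <- length(values)
    if (n > 10) stop("exact permutation limited to total n <= 10")
    perms <- permn_groups(n, vapply(groups, length, 1L))
    Hs <- vapply(perms, function(g) kw_statistic(values, g, k), 1)
    p <- mean(Hs >= H - 1e-12)
    return(list(H = H, p = p, df = k - 1L, method = "exact permutation"))
  }
  list(H = H, p = pchisq(H, df = k - 1, lower.tail = FALSE), df = k - 1L,
       method = "chi-square approximation")
}

# all distinct assignments of n items into groups of the given sizes
permn_groups <- function(n, sizes) {
  out <- list()
  rec <- function(items, grp, gi) {
    if (gi > length(sizes)) { out[[length(out) + 1L]] <<- grp; return() }
    if (gi == length(sizes)) {
      grp[items] <- gi
      out[[length(out) + 1L]] <<- grp
      return()
    }
    cmb <- utils::combn(items, sizes[gi], simplify = FALSE)
    for (sel in cmb) {
      g2 <- grp; g2[sel] <- gi
      rec(setdiff(items, sel), g2, gi + 1L)
    }
  }
  rec(seq_len(n), integer(n), 1L)
  out
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  F <- pnorm(z)
  max(pmax(seq_len(n) / n - F, F - (seq_len(n) - 1) / n))
}

#' Simulate the Lilliefors null distribution of the KS statistic
#'
#' @param n sample size.
#' @param n_mc Monte-Carlo replicates.
#' @param seed integer seed.
#' @return numeric vector of null statistics.
#' @export
lilliefors_null <- function(n, n_mc = 1e4, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n_mc), function(i) lilliefors_stat(rnorm(n)), 1)
}

#' Lilliefors normality test with a Monte-Carlo p-value
#'
#' KS statistic of the sample against a normal with estimated mean and SD;
#' the p-value comes from a seeded Monte-Carlo simulation of the null
#' (standard normal samples of the same size, same statistic).
#'
#' @param sample numeric vector, n >= 4, nonzero variance.
#' @param n_mc Monte-Carlo replicates (default 1e4).
#' @param seed integer seed.
#' @param null_stats optional precomputed null statistics from
#'   [lilliefors_null()] (shared across many tests for speed).
#' @return list with `statistic`, `p`, `n`.
#' @export
lilliefors <- function(sample, n_mc = 1e4, seed = 1L, null_stats = NULL) {
  n <- length(sample)
  stopifnot(n >= 4L)
  if (sd(sample) == 0) stop("zero-variance sample")
  D <- lilliefors_stat(sample)
  if (is.null(null_stats)) null_stats <- lilliefors_null(n, n_mc, seed)
  p <- (1 + sum(null_stats >= D)) / (length(null_stats) + 1)
  list(statistic = D, p = p, n = n)
}

#' Inter-rater variability study against a STAPLE consensus
#'
#' For each structure the raters' masks are fused with STAPLE into a
#' consensus ground truth; each rater is then scored against it with Dice
#' and MHD. The output mirrors a structures-by-raters report: one row per
#' (structure, rater) with `dice` and `mhd_mm`, plus per-rater summaries
#' (mean +/- SD across structures) and Kruskal-Wallis tests across raters
#' on both metrics. Raw p-values; no multiplicity correction.
#'
#' @param raters named list: structure -> list of the raters' binary masks
#'   (same rater count and order per structure).
#' @param spacing voxel spacing in mm.
#' @param context slice/volume label stored in the table (default
#'   `"volume"`).
#' @param staple_args extra arguments passed to [staple()].
#' @return list with `table` (data.frame), `summary` (per-rater), `tests`
#'   (Kruskal-Wallis on dice and mhd), `consensus` (list of GT masks).
#' @export
variability_study <- function(raters, spacing = c(1, 1, 1),
                              context = "volume", staple_args = list()) {
  stopifnot(is.list(raters), length(raters) >= 1L)
  structures <- names(raters)
  if (is.null(structures)) structures <- paste0("structure", seq_along(raters))
  nr <- length(raters[[1]])
  stopifnot(nr >= 2L)
  rows <- list()
  consensus <- list()
  for (si in seq_along(raters)) {
    masks <- lapply(raters[[si]], as_mask_array)
    st <- do.call(staple, c(list(masks = masks), staple_args))
    gt <- st$consensus
    consensus[[structures[si]]] <- gt
    for (j in seq_len(nr)) {
      rows[[length(rows) + 1L]] <- data.frame(
        structure = structures[si], rater = j,
        dice = dice(masks[[j]], gt),
        mhd_mm = mhd(masks[[j]], gt, spacing = spacing),
        context = context)
    }
  }
  tab <- do.call(rbind, rows)
  by_rater <- split(tab, tab$rater)
  summ <- do.call(rbind, lapply(by_rater, function(x) data.frame(
    rater = x$rater[1],
    dice_mean = mean(x$dice), dice_sd = sd(x$dice),
    mhd_mean = mean(x$mhd_mm), mhd_sd = sd(x$mhd_mm))))
  tests <- list(
    dice = kruskal_wallis(lapply(by_rater, `[[`, "dice")),
    mhd = kruskal_wallis(lapply(by_rater, `[[`, "mhd_mm")))
  list(table = tab, summary = summ, tests = tests, consensus = consensus)
}

#' Write a variability report bundle (CSV table + JSON summary)
#' @param study result of [variability_study()].
#' @param dir output directory.
#' @return invisible vector of paths.
#' @export
write_variability_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pc <- file.path(dir, "variability_table.csv")
  pj <- file.path(dir, "variability_summary.json")
  write.csv(study$table, pc, row.names = FALSE)
  jsonlite::write_json(list(summary = study$summary, tests = study$tests),
                       pj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(pc, pj))
}
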