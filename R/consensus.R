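# STAPLE: expectation-maximization estimation of a hidden binary consensus
# segmentation and per-rater sensitivity/specificity from R raters' masks.
# Binary, applied structure by structure; voxels are conditionally
# independent given the prevalence prior (an optional mean-field smoothing
# replaces the global prior by a locally averaged posterior).

STAPLE_EPS <- 1e-5

clip_pq <- function(x) pmin(pmax(x, STAPLE_EPS), 1 - STAPLE_EPS)

masks_to_matrix <- function(masks) {
  masks <- lapply(masks, as_mask_array)
  d <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), d)) stop("masks are not congruent")
  list(D = vapply(masks, as.vector, logical(prod(d))), dim = d)
}

#' STAPLE E-step: posterior foreground probability per voxel
#'
#' `W_i = a_i / (a_i + b_i)` with
#' `a_i = pi * prod_j p_j^d_ij (1 - p_j)^(1 - d_ij)` and
#' `b_i = (1 - pi) * prod_j (1 - q_j)^d_ij q_j^(1 - d_ij)`; evaluated in
#' log-space.
#'
#' @param masks list of congruent binary masks (logical arrays).
#' @param p,q per-rater sensitivity/specificity vectors.
#' @param prior scalar prevalence, or an array of per-voxel priors.
#' @return numeric array `W` in `[0, 1]`.
#' @export
staple_estep <- function(masks, p, q, prior) {
  mm <- masks_to_matrix(masks)
  D <- mm$D
  p <- clip_pq(p); q <- clip_pq(q)
  la <- D %*% log(p) + (1 - D) %*% log1p(-p)
  lb <- D %*% log1p(-q) + (1 - D) %*% log(q)
  pr <- if (length(prior) == 1L) rep(prior, nrow(D)) else as.vector(prior)
  pr <- pmin(pmax(pr, STAPLE_EPS), 1 - STAPLE_EPS)
  la <- la + log(pr)
  lb <- lb + log1p(-pr)
  W <- 1 / (1 + exp(lb - la))
  if (length(prior) == 1L && (prior >= 1 || prior <= 0))
    W[] <- as.numeric(prior >= 1)  # degenerate prior short-circuits
  array(W, mm$dim)
}

#' STAPLE M-step: performance parameters from the posterior
#'
#' `p_j = sum_i W_i d_ij / sum_i W_i`,
#' `q_j = sum_i (1 - W_i)(1 - d_ij) / sum_i (1 - W_i)`; estimates are
#' clipped to `[1e-5, 1 - 1e-5]`.
#'
#' @param masks list of congruent binary masks.
#' @param W posterior array from [staple_estep()].
#' @return list with `p`, `q`, and `prevalence = mean(W)`.
#' @export
staple_mstep <- function(masks, W) {
  mm <- masks_to_matrix(masks)
  D <- mm$D
  w <- as.vector(W)
  sw <- sum(w); swc <- sum(1 - w)
  if (sw <= 0 || swc <= 0) stop("degenerate posterior: all-foreground or all-background")
  p <- clip_pq(as.vector(crossprod(D, w)) / sw)
  q <- clip_pq(as.vector(crossprod(1 - D, 1 - w)) / swc)
  list(p = p, q = q, prevalence = sw / length(w))
}

staple_loglik <- function(D, p, q, pr) {
  la <- D %*% log(p) + (1 - D) %*% log1p(-p) + log(pr)
  lb <- D %*% log1p(-q) + (1 - D) %*% log(q) + log1p(-pr)
  m <- pmax(la, lb)
  sum(m + log(exp(la - m) + exp(lb - m)))
}

#' Simultaneous truth and performance level estimation (STAPLE)
#'
#' Alternates E- and M-steps until the maximum change in `W` drops below
#' `tol` or `max_iter` is reached. The consensus mask is `{W > 0.5}` with
#' ties at exactly 0.5 assigned to foreground. The default prior is a
#' fixed global prevalence equal to the mean foreground fraction across
#' raters; `prior_mode = "estimated"` re-estimates it each M-step, and
#' `spatial_smoothing = "meanfield"` replaces the global prior by a local
#' average of `W` (weight `beta`) to encode spatial homogeneity.
#'
#' @param masks list of >= 2 congruent binary masks (R = 1 is allowed but
#'   degenerate).
#' @param prior_mode `"fixed"` or `"estimated"`.
#' @param pi0 initial/fixed prevalence; default mean foreground fraction.
#' @param init_p,init_q initial performance (classic 0.9999).
#' @param tol convergence tolerance on `max |dW|` (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @param spatial_smoothing `"off"` or `"meanfield"`.
#' @param beta mean-field mixing weight in (0, 1].
#' @return object of class `consensus_result`: `W`, `consensus` (logical),
#'   `p`, `q`, `prevalence`, `trace` (per-iteration log-likelihood,
#'   non-decreasing), `iterations`.
#' @export
staple <- function(masks, prior_mode = c("fixed", "estimated"), pi0 = NULL,
                   init_p = 0.9999, init_q = 0.9999, tol = 1e-6,
                   max_iter = 100L, spatial_smoothing = c("off", "meanfield"),
                   beta = 0.5) {
  prior_mode <- match.arg(prior_mode)
  spatial_smoothing <- match.arg(spatial_smoothing)
  mm <- masks_to_matrix(masks)
  D <- mm$D
  R <- ncol(D)
  fg <- colMeans(D)
  if (all(fg == 0) || all(fg == 1)) stop("degenerate consensus: all masks empty or full")
  if (is.null(pi0)) pi0 <- mean(fg)
  p <- clip_pq(rep(init_p, R))
  q <- clip_pq(rep(init_q, R))
  pr <- min(max(pi0, STAPLE_EPS), 1 - STAPLE_EPS)
  W_old <- NULL
  trace <- numeric(0)
  prior_arr <- pr
  it <- 0L
  repeat {
    it <- it + 1L
    W <- staple_estep(asplit_masks(D, mm$dim), p, q, prior_arr)
    trace <- c(trace, staple_loglik(D, p, q,
                                    prior_to_vec(prior_arr, nrow(D))))
    m <- staple_mstep(asplit_masks(D, mm$dim), W)
    p <- m$p; q <- m$q
    if (prior_mode == "estimated") pr <- m$prevalence
    prior_arr <- if (spatial_smoothing == "meanfield") {
      sm <- gaussian_smooth(scalar_image(W, rep(1, 3)), fwhm_mm = 2)$values
      (1 - beta) * pr + beta * sm
    } else pr
    if (!is.null(W_old) && max(abs(W - W_old)) < tol) break
    if (it >= max_iter) break
    W_old <- W
  }
  structure(list(W = W, consensus = W >= 0.5, p = p, q = q,
                 prevalence = if (length(pr) == 1) pr else mean(pr),
                 trace = trace, iterations = it),
            class = "consensus_result")
}

prior_to_vec <- function(prior, n) {
  v <- if (length(prior) == 1L) rep(prior, n) else as.vector(prior)
  pmin(pmax(v, STAPLE_EPS), 1 - STAPLE_EPS)
}

# rebuild the list-of-arrays view the step functions take (cheap views)
asplit_masks <- function(D, d) {
  lapply(seq_len(ncol(D)), function(j) array(D[, j], d))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("STAPLE consensus: %d voxels foreground, %d raters, %d iterations\n",
              sum(x$consensus), length(x$p), x$iterations))
  cat("  p:", paste(sprintf("%.4f", x$p), collapse = " "), "\n")
  cat("  q:", paste(sprintf("%.4f", x$q), collapse = " "), "\n")
  invisible(x)
}

#' Write a consensus result to disk (W map, mask, performance table)
#' @param result a `consensus_result`.
#' @param dir output directory.
#' @param spacing,origin grid geometry for the NIfTI outputs.
#' @return invisible vector of paths.
#' @export
write_consensus <- function(result, dir, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pw <- file.path(dir, "staple_W.nii")
  pm <- file.path(dir, "staple_consensus.nii")
  pj <- file.path(dir, "staple_performance.json")
  write_nifti(scalar_image(result$W, spacing, origin), pw)
  write_nifti(label_volume(array(as.integer(result$consensus),
                                 dim(result$W)), spacing, origin), pm)
  jsonlite::write_json(list(p = result$p, q = result$q,
                            prevalence = result$prevalence,
                            iterations = result$iterations,
                            loglik_trace = result$trace),
                       pj, auto_unbox = TRUE, digits = NA)
  invisible(c(pw, pm, pj))
}
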