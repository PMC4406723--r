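# Orchestration of the two end-to-end studies: the segmentation validation
# study (phantom -> raters -> STAPLE ground truth -> Dice/MHD tables ->
# normality + rank tests) and the tACS study (phantom -> tensors -> DWI ->
# tensor fit -> conductivity -> montage comparison + scalar-vs-tensor
# comparison). Every stochastic stage takes an explicit seed derived from
# the study seed, and every output bundle carries provenance metadata.

# rolling polynomial hash (mod 2^31-1) for provenance config fingerprints
fnv1a_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

provenance <- function(config, seeds) {
  list(config_hash = fnv1a_hash(config),
       seeds = seeds,
       package_version = as.character(utils::packageVersion("headforge")),
       substitutions = c(
         "affine NMI registration substitutes non-rigid B-spline DWI registration",
         "direct voxel-interface extraction substitutes Delaunay-refinement meshing",
         "first-order tetrahedra substitute second-order cells"),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

#' Default validation-study configuration
#'
#' Three equal simulated raters (mode A, sensitivity 0.95, specificity
#' 0.999) outline six phantom structures on a 48-voxel head; STAPLE builds
#' the consensus ground truth and the raters are scored against it.
#'
#' @param seed study seed.
#' @param out_dir output directory (NULL = no files written).
#' @return config list.
#' @export
validation_config <- function(seed = 1L, out_dir = NULL) {
  list(
    phantom = list(n = 48L, spacing = 1, seed = seed),
    structures = c(5L, 6L, 7L, 8L, 9L, 10L),
    raters = list(
      list(sensitivity = 0.95, specificity = 0.999, boundary_jitter_mm = 0),
      list(sensitivity = 0.95, specificity = 0.999, boundary_jitter_mm = 0),
      list(sensitivity = 0.95, specificity = 0.999, boundary_jitter_mm = 0)),
    staple = list(prior_mode = "fixed"),
    context = "volume",
    seed = as.integer(seed),
    out_dir = out_dir)
}

#' Run the segmentation validation study
#'
#' Phantom generation, simulated raters per structure, STAPLE consensus,
#' Dice/MHD tables in the structures-by-raters report format, Lilliefors
#' normality checks of the per-rater Dice values, and Kruskal-Wallis tests
#' across raters. Fully reproducible from (config, seed).
#'
#' @param config list as from [validation_config()].
#' @return report bundle: `study` (see [variability_study()]),
#'   `lilliefors` per rater, `provenance`, `config`.
#' @export
run_validation_study <- function(config = validation_config()) {
  spec <- default_head_spec(n = config$phantom$n,
                            spacing = config$phantom$spacing,
                            seed = config$phantom$seed)
  vol <- generate_label_phantom(spec)
  tissue <- vol$tissue_table
  raters <- list()
  for (si in seq_along(config$structures)) {
    lb <- config$structures[si]
    truth <- vol$labels == lb
    if (!any(truth)) stop("structure label absent from phantom: ", lb)
    masks <- lapply(seq_along(config$raters), function(j) {
      rm <- config$raters[[j]]
      model <- rater_model(rm$sensitivity, rm$specificity,
                           rm$boundary_jitter_mm %||% 0,
                           seed = config$seed + 1000L * si + j)
      simulate_rater(truth, model, spacing = vol$spacing)
    })
    nm <- tissue$name[match(lb, tissue$label)]
    raters[[nm %||% as.character(lb)]] <- masks
  }
  study <- variability_study(raters, spacing = vol$spacing,
                             context = config$context,
                             staple_args = config$staple)
  lf <- lapply(split(study$table, study$table$rater), function(x) {
    if (length(unique(x$dice)) < 2 || length(x$dice) < 4)
      return(list(statistic = NA, p = NA, n = nrow(x)))
    lilliefors(x$dice, n_mc = 2000, seed = config$seed)
  })
  bundle <- list(study = study, lilliefors = lf,
                 provenance = provenance(config, config$seed),
                 config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_variability_report(study, config$out_dir)
    jsonlite::write_json(list(lilliefors = lf,
                              provenance = bundle$provenance,
                              config = config),
                         file.path(config$out_dir, "validation_meta.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  bundle
}

#' Default tACS-study configuration
#' @param seed study seed.
#' @param out_dir output directory (NULL = no files written).
#' @return config list.
#' @export
tacs_config <- function(seed = 1L, out_dir = NULL) {
  list(
    phantom = list(n = 48L, spacing = 1, seed = seed),
    protocol = list(n_dirs = 32L, bval = 800),
    dwi = list(s0 = 100, noise_sigma = 2),
    conductivity = list(scale_k = 0.844, cap = 1.8),
    montage_potentials = c(1, 0),
    seed = as.integer(seed),
    out_dir = out_dir)
}

#' Run the tACS simulation study
#'
#' Builds the phantom and its analytic white-matter tensor field,
#' synthesizes and refits diffusion data, maps the fitted tensors to
#' conductivity (capped at 1.8 S/m), solves the frontalis-vertex and
#' Cz-ring montages with scalar conductivities on the voxel solver
#' (comparing eye-region current density), and compares scalar vs
#' DTI-tensor property assignment on the FEM solver for the frontal
#' montage.
#'
#' @param config list as from [tacs_config()].
#' @return report bundle with `montage_comparison`, `anisotropy_study`,
#'   `fit_quality`, `provenance`, `config`.
#' @export
run_tacs_study <- function(config = tacs_config()) {
  spec <- default_head_spec(n = config$phantom$n,
                            spacing = config$phantom$spacing,
                            seed = config$phantom$seed)
  vol <- generate_label_phantom(spec)
  tensors_true <- make_tensor_field(vol)
  proto <- default_protocol(config$protocol$n_dirs, config$protocol$bval)
  dwi <- synth_dwi(tensors_true, proto, s0 = config$dwi$s0,
                   noise_sigma = config$dwi$noise_sigma,
                   seed = config$seed + 11L)
  fitted <- fit_tensor(dwi, proto, mask = tensors_true$mask)
  fitted_masked <- mask_tensors(fitted, vol, keep_labels = c(5L, 6L, 7L, 8L))
  cmap <- map_conductivity(fitted_masked, vol,
                           scale_k = config$conductivity$scale_k,
                           cap = config$conductivity$cap,
                           fallback = default_conductivities())
  scal <- default_conductivities()
  sc_map <- scalar_conductivity_map(vol, scal, cap = config$conductivity$cap)
  sc_arr <- array(sc_map$sigma[, , , 1], dim(vol$labels))
  attr(sc_arr, "spacing") <- vol$spacing
  m_front <- montage_preset("fpz_cz", vol,
                            potentials = config$montage_potentials)
  m_ring <- montage_preset("cz_ring", vol,
                           potentials = config$montage_potentials)
  sol_front <- solve_voxel(sc_arr, m_front)
  sol_ring <- solve_voxel(sc_arr, m_ring)
  eye_mask <- vol$labels %in% c(9L, 10L)
  mc <- compare_montages(sol_front, sol_ring, eye_mask)
  brain_mask <- vol$labels %in% c(6L, 7L)
  aniso <- scalar_vs_tensor_study(vol, scal, cmap, m_front, brain_mask)
  fa_true <- fa(tensors_true)
  fa_fit <- fa(fitted_masked)
  wm <- vol$labels == 7L
  fit_quality <- list(
    median_fa_error_wm = median(abs(fa_fit[wm] - fa_true[wm])),
    conditioned_fraction = mean(fitted$conditioned[tensors_true$mask]))
  bundle <- list(montage_comparison = mc, anisotropy_study = aniso,
                 fit_quality = fit_quality,
                 provenance = provenance(config, config$seed),
                 config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(bundle[c("montage_comparison", "anisotropy_study",
                                  "fit_quality", "provenance", "config")],
                         file.path(config$out_dir, "tacs_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write_nifti(scalar_image(field_magnitude(sol_front, "E"), vol$spacing),
                file.path(config$out_dir, "E_front.nii"))
    write_nifti(scalar_image(field_magnitude(sol_ring, "E"), vol$spacing),
                file.path(config$out_dir, "E_ring.nii"))
  }
  bundle
}
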