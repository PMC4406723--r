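# Quasi-electrostatic forward solvers for transcranial stimulation:
# div(sigma grad phi) = 0 with Dirichlet electrode patches and zero-flux
# outer boundaries. Two discretizations mirror the two solver families:
# a 7-point finite-volume scheme on voxels (scalar or diagonal tensors,
# harmonic-mean face conductances) and P1 finite elements on a structured
# 6-tetrahedra-per-voxel mesh (full anisotropic tensors). At 10 Hz the
# quasi-static approximation holds and conductivities are purely real.
# Systems are SPD and solved directly (sparse Cholesky); the relative
# residual is recomputed and checked against `tol`.

# Incomplete-Cholesky preconditioned conjugate gradients for the SPD
# reduced systems (C++ core). The sparse direct factorizations available
# here are far slower than PCG on these 3D grids, and CG's
# relative-residual stop maps directly onto the solver tolerance contract.
pcg_solve <- function(K, b, tol = 1e-8, max_iter = 20000L) {
  b <- as.numeric(b)
  K <- methods::as(methods::as(K, "generalMatrix"), "CsparseMatrix")
  res <- .pcg_ic0(K@p, K@i, K@x, b, tol, as.integer(max_iter))
  if (res$residual > tol)
    stop(sprintf("CG did not converge in %d iterations (residual %.3e)",
                 res$iterations, res$residual))
  res
}

#' Electrode montage
#'
#' @param electrodes list of electrodes, each
#'   `list(name, potential, mask)` with `mask` a logical array of
#'   electrode voxels; or use [montage_preset()].
#' @return object of class `electrode_montage`.
#' @export
electrode_montage <- function(electrodes) {
  stopifnot(length(electrodes) >= 2L)
  pots <- vapply(electrodes, function(e) e$potential, 1)
  if (length(unique(pots)) < 2L) stop("montage needs >= 2 distinct potentials")
  cover <- NULL
  for (e in electrodes) {
    m <- e$mask
    if (!is.null(cover) && any(cover & m)) stop("electrode patches overlap")
    cover <- if (is.null(cover)) m else cover | m
  }
  structure(list(electrodes = electrodes), class = "electrode_montage")
}

# 10-20-like scalp directions on the phantom (y = anterior, z = superior)
ten_twenty_dirs <- function() {
  deg <- pi / 180
  list(
    Cz  = c(0, 0, 1),
    Fpz = c(0, cos(20 * deg), sin(20 * deg)),
    Fz  = c(0, cos(55 * deg), sin(55 * deg)),
    Pz  = c(0, -cos(55 * deg), sin(55 * deg)),
    C3  = c(-cos(45 * deg), 0, sin(45 * deg)),
    C4  = c(cos(45 * deg), 0, sin(45 * deg)))
}

#' Build a preset tACS montage on a phantom scalp
#'
#' Electrode patches are angular cones about 10-20-like directions from
#' the head centre, intersected with the skin label. Presets: `"fpz_cz"`
#' (two large patches, the frontalis-vertex configuration) and `"cz_ring"`
#' (Cz at one potential vs Fz, C3, C4, Pz at the other).
#'
#' @param name `"fpz_cz"` or `"cz_ring"`.
#' @param labels a `label_volume`.
#' @param skin_label skin label id (default 1).
#' @param potentials length-2: potentials (V) of the two electrode groups
#'   (default `c(1, 0)` -> first-named electrode(s) at 1 V).
#' @param radius_deg angular patch radii; defaults 25 (large) / 12 (small).
#' @return an `electrode_montage`.
#' @export
montage_preset <- function(name = c("fpz_cz", "cz_ring"), labels,
                           skin_label = 1L, potentials = c(1, 0),
                           radius_deg = NULL) {
  name <- match.arg(name)
  stopifnot(inherits(labels, "label_volume"))
  d <- dim(labels$labels)
  ctr <- labels$origin + (d - 1) / 2 * labels$spacing
  gc <- grid_coords(d, labels$spacing, labels$origin)
  dx <- gc$x - ctr[1]; dy <- gc$y - ctr[2]; dz <- gc$z - ctr[3]
  nrm <- sqrt(dx^2 + dy^2 + dz^2); nrm[nrm == 0] <- 1
  skin <- labels$labels == skin_label
  dirs <- ten_twenty_dirs()
  cone <- function(dname, rdeg) {
    v <- dirs[[dname]]
    cosang <- (dx * v[1] + dy * v[2] + dz * v[3]) / nrm
    skin & (cosang >= cos(rdeg * pi / 180))
  }
  if (name == "fpz_cz") {
    r <- if (is.null(radius_deg)) 25 else radius_deg
    els <- list(
      list(name = "Fpz", potential = potentials[1], mask = cone("Fpz", r)),
      list(name = "Cz", potential = potentials[2], mask = cone("Cz", r)))
  } else {
    r <- if (is.null(radius_deg)) 12 else radius_deg
    els <- list(list(name = "Cz", potential = potentials[1], mask = cone("Cz", r)))
    for (nm in c("Fz", "C3", "C4", "Pz"))
      els[[length(els) + 1L]] <- list(name = nm, potential = potentials[2],
                                      mask = cone(nm, r))
  }
  for (e in els) if (!any(e$mask)) stop("empty electrode patch: check geometry")
  electrode_montage(els)
}

# normalize conductivity input to per-voxel diagonal (voxel solver) or
# full 6-component (FEM) representation
cond_to_components <- function(cond, d) {
  if (inherits(cond, "conductivity_map")) {
    sig <- matrix(cond$sigma, ncol = 6L)
    list(sig = sig, spacing = cond$spacing, origin = cond$origin)
  } else if (is.array(cond) && length(dim(cond)) == 3L) {
    v <- as.vector(cond)
    list(sig = cbind(v, v, v, 0, 0, 0),
         spacing = attr(cond, "spacing") %||% c(1, 1, 1),
         origin = attr(cond, "origin") %||% c(0, 0, 0))
  } else stop("cond must be a conductivity_map or a 3D array")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxel finite-volume solve of the quasi-static potential
#'
#' 7-point finite-volume discretization with face conductance
#' `harmonic_mean(sigma_i, sigma_j) * area / distance`; Dirichlet
#' potentials on electrode voxels, zero flux on the remaining outer
#' boundary. Scalar and diagonal tensors only (full tensors route to
#' [solve_fem()]). E is recovered by central differences of the potential
#' and `J = sigma E`.
#'
#' @param cond conductivity: 3D array (scalar per voxel, S/m) or a
#'   `conductivity_map` with (near-)diagonal tensors.
#' @param montage an `electrode_montage` on the same grid.
#' @param tol relative residual bound (default 1e-8).
#' @param spacing grid spacing (when `cond` is a bare array without
#'   attributes).
#' @return object of class `field_solution` with `potential` (array, NA
#'   outside the conductive domain), `E`, `J` (grid x 3 arrays, V/m and
#'   A/m^2 with mm converted to m), `residual`, `electrode_currents` (A),
#'   `domain`, `method`.
#' @export
solve_voxel <- function(cond, montage, tol = 1e-8, spacing = NULL) {
  cc <- cond_to_components(cond, NULL)
  if (!is.null(spacing)) cc$spacing <- spacing
  d <- if (inherits(cond, "conductivity_map")) dim(cond$tensor_mask)
       else dim(cond)
  sig <- cc$sig
  if (max(abs(sig[, 4:6])) > 1e-9 * max(sig[, 1:3]))
    stop("voxel solver handles scalar/diagonal tensors only; use solve_fem")
  sp_m <- cc$spacing * 1e-3  # mm -> m
  n <- prod(d)
  domain <- matrix(sig[, 1:3] > 0, ncol = 3L)
  domain <- array(domain[, 1] | domain[, 2] | domain[, 3], d)
  # electrode voxels and their potentials
  epot <- rep(NA_real_, n)
  for (e in montage$electrodes) {
    if (!identical(dim(e$mask), d)) stop("electrode mask grid mismatch")
    epot[as.vector(e$mask)] <- e$potential
  }
  if (any(!is.na(epot) & !as.vector(domain)))
    stop("electrode voxels must be conductive")
  # connectivity between electrodes over the conductive domain
  lab <- array(.cc_label6(as.vector(domain), d), d)
  comp <- unique(lab[!is.na(array(epot, d)) & domain])
  if (length(comp) > 1) stop("disconnected electrodes: no conductive path")
  active <- as.vector(lab == comp)
  idx <- which(active)
  map <- integer(n); map[idx] <- seq_along(idx)
  # face conductances per axis
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  diag_acc <- numeric(length(idx))
  stride <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    keep <- rep(TRUE, n)
    pos <- arrayInd(seq_len(n), d)[, ax]
    keep <- pos < d[ax]
    i1 <- which(keep & active)
    i2 <- i1 + stride[ax]
    ok <- active[i2]
    i1 <- i1[ok]; i2 <- i2[ok]
    s1 <- sig[i1, ax]; s2 <- sig[i2, ax]
    g <- 2 * s1 * s2 / (s1 + s2) *
      prod(sp_m[-ax]) / sp_m[ax]
    gi <- map[i1]; gj <- map[i2]
    trip_i <- c(trip_i, gi, gj)
    trip_j <- c(trip_j, gj, gi)
    trip_x <- c(trip_x, -g, -g)
    diag_acc[gi] <- diag_acc[gi] + g
    diag_acc[gj] <- diag_acc[gj] + g
  }
  K <- Matrix::sparseMatrix(i = c(trip_i, seq_along(idx)),
                            j = c(trip_j, seq_along(idx)),
                            x = c(trip_x, diag_acc),
                            dims = c(length(idx), length(idx)))
  eact <- epot[idx]
  fixed <- which(!is.na(eact))
  free <- which(is.na(eact))
  if (length(fixed) == 0) stop("no electrode voxels in the conductive domain")
  phi <- numeric(length(idx))
  phi[fixed] <- eact[fixed]
  rhs <- as.numeric(-K[free, fixed, drop = FALSE] %*% phi[fixed])
  Kff <- K[free, free, drop = FALSE]
  cg <- pcg_solve(Kff, rhs, tol = tol)
  phi[free] <- cg$x
  resid <- cg$residual
  if (resid > tol) stop(sprintf("solver did not reach tol: residual %.3e", resid))
  pot <- rep(NA_real_, n)
  pot[idx] <- phi
  pot <- array(pot, d)
  # E by central differences inside the domain (one-sided at domain edges)
  E <- array(0, c(d, 3L))
  for (ax in 1:3) {
    h <- sp_m[ax]
    shift <- function(off) {
      id <- seq_len(d[ax]) + off
      id[id < 1L] <- 1L; id[id > d[ax]] <- d[ax]
      sub <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      sub[[ax]] <- id
      array(pot[sub[[1]], sub[[2]], sub[[3]]], d)
    }
    pp <- shift(1L); pm <- shift(-1L)
    ok_p <- !is.na(pp); ok_m <- !is.na(pm)
    num <- ifelse(ok_p, pp, pot) - ifelse(ok_m, pm, pot)
    den <- (ifelse(ok_p, 1, 0) + ifelse(ok_m, 1, 0)) * h
    g <- ifelse(den > 0 & !is.na(pot), num / den, 0)
    g[is.na(g)] <- 0
    E[, , , ax] <- -g
  }
  J <- E
  for (ax in 1:3) J[, , , ax] <- E[, , , ax] * array(sig[, ax], d)
  # electrode currents: flux from electrode voxels into non-electrode ones
  currents <- vapply(montage$electrodes, function(e) {
    ev <- which(as.vector(e$mask) & active)
    tot <- 0
    for (ax in 1:3) {
      for (sgn in c(1L, -1L)) {
        pos <- arrayInd(ev, d)[, ax]
        okv <- if (sgn > 0) pos < d[ax] else pos > 1L
        v1 <- ev[okv]
        v2 <- v1 + sgn * stride[ax]
        okn <- active[v2] & is.na(epot[v2])
        v1 <- v1[okn]; v2 <- v2[okn]
        if (!length(v1)) next
        s1 <- sig[v1, ax]; s2 <- sig[v2, ax]
        g <- 2 * s1 * s2 / (s1 + s2) * prod(sp_m[-ax]) / sp_m[ax]
        tot <- tot + sum(g * (pot[v1] - pot[v2]))
      }
    }
    tot
  }, 1)
  names(currents) <- vapply(montage$electrodes, `[[`, "", "name")
  structure(list(potential = pot, E = E, J = J, residual = resid,
                 electrode_currents = currents, domain = array(active, d),
                 spacing = cc$spacing, origin = cc$origin,
                 method = "voxel_fv"),
            class = "field_solution")
}

#' Magnitude of a per-voxel vector field
#' @param sol a `field_solution`.
#' @param which `"E"` or `"J"`.
#' @return 3D array of magnitudes.
#' @export
field_magnitude <- function(sol, which = c("E", "J")) {
  which <- match.arg(which)
  F <- sol[[which]]
  sqrt(F[, , , 1]^2 + F[, , , 2]^2 + F[, , , 3]^2)
}

# Kuhn 6-tetrahedra subdivision of the unit cube: local corner ids 0..7
# (binary xyz), each tet (c000, ..., c111) along an axis permutation path.
kuhn_tets <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    v <- c(0, 0, 0)
    ids <- integer(4)
    ids[1] <- 1L
    for (k in 1:3) {
      v[p[k]] <- 1
      ids[k + 1] <- 1L + v[1] + 2L * v[2] + 4L * v[3]
    }
    ids
  })
}

#' Tetrahedral P1 finite-element solve supporting anisotropic tensors
#'
#' Each conductive voxel is split into 6 tetrahedra (structured Kuhn
#' subdivision, conformal across faces); linear elements; the element
#' stiffness is `V * G' sigma G` with the tensor sampled at the element
#' centroid via [sample_to_grid()]. Dirichlet electrode voxels fix all
#' their corner nodes.
#'
#' @param cond a `conductivity_map` (full tensors allowed) or 3D scalar
#'   array.
#' @param montage an `electrode_montage`.
#' @param tol relative residual bound (default 1e-8).
#' @param sample_centroids sample tensors at tet centroids through
#'   trilinear interpolation (default TRUE); FALSE uses the host voxel's
#'   tensor directly.
#' @return a `field_solution` with per-node `potential_nodes`, per-element
#'   `E_elem`, `J_elem`, `elem_voxel`, plus voxel-averaged `E`, `J` arrays
#'   for region statistics.
#' @export
solve_fem <- function(cond, montage, tol = 1e-8, sample_centroids = TRUE) {
  cc <- cond_to_components(cond, NULL)
  d <- if (inherits(cond, "conductivity_map")) dim(cond$tensor_mask)
       else dim(cond)
  sig <- cc$sig
  sp_m <- cc$spacing * 1e-3
  n <- prod(d)
  act <- sig[, 1] > 0 | sig[, 2] > 0 | sig[, 3] > 0
  # SPD check on tensors (cheap necessary conditions + eigen where needed)
  if (any(sig[act, 1] < 0) || any(sig[act, 2] < 0) || any(sig[act, 3] < 0))
    stop("non-SPD conductivity tensor")
  epot <- rep(NA_real_, n)
  for (e in montage$electrodes) epot[as.vector(e$mask)] <- e$potential
  lab <- .cc_label6(act, d)
  comp <- unique(lab[!is.na(epot) & act])
  comp <- comp[comp > 0]
  if (length(comp) == 0) stop("no electrode voxels in the conductive domain")
  if (length(comp) > 1) stop("disconnected electrodes: no conductive path")
  vox <- which(lab == comp)
  nvox <- length(vox)
  vi <- arrayInd(vox, d)  # voxel lattice indices
  nc <- d + 1L
  corner_lin <- function(ix, iy, iz) ix + (iy - 1L) * nc[1] +
    (iz - 1L) * nc[1] * nc[2]
  corner_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  corners <- matrix(0L, nvox, 8)
  for (k in 1:8)
    corners[, k] <- corner_lin(vi[, 1] + corner_off[k, 1],
                               vi[, 2] + corner_off[k, 2],
                               vi[, 3] + corner_off[k, 3])
  used_nodes <- sort(unique(as.vector(corners)))
  nmap <- integer(prod(nc)); nmap[used_nodes] <- seq_along(used_nodes)
  corners_m <- matrix(nmap[corners], nvox, 8)
  nnode <- length(used_nodes)
  # node coordinates in m (voxel corner lattice; voxel centre convention)
  ni <- arrayInd(used_nodes, nc)
  node_xyz <- sweep(sweep(ni - 1.5, 2, sp_m, `*`), 2, cc$origin * 1e-3, `+`)
  tets <- kuhn_tets()
  # per-shape gradients of P1 basis (constant per element)
  unit_corners <- corner_off
  shape_G <- lapply(tets, function(ids) {
    X <- sweep(unit_corners[ids, ], 2, sp_m, `*`)  # 4 x 3 vertex coords
    Mmat <- cbind(1, X)
    C <- solve(Mmat)           # rows: coefficients; gradient of basis i = C[2:4, i]
    list(G = C[2:4, , drop = FALSE], V = abs(det(Mmat)) / 6)
  })
  # element tensors
  elem_sig <- function(ids, shape) {
    if (inherits(cond, "conductivity_map") && sample_centroids) {
      cen_unit <- colMeans(unit_corners[ids, ])
      cen <- sweep(sweep(vi - 1.5 + matrix(cen_unit, nvox, 3, byrow = TRUE),
                         2, cc$spacing, `*`), 2, cc$origin, `+`)
      sample_to_grid(cond, cen, fallback = 0)
    } else {
      sig[vox, , drop = FALSE]
    }
  }
  NI <- list(); NJ <- list(); NX <- list()
  elemE_G <- vector("list", 6)
  for (s in 1:6) {
    ids <- tets[[s]]
    G <- shape_G[[s]]$G; V <- shape_G[[s]]$V
    es <- elem_sig(ids, s)
    # sigma * G per basis function, contracted: K_ij = V * gi' sigma gj
    for (i in 1:4) for (j in i:4) {
      gi <- G[, i]; gj <- G[, j]
      cij <- V * (gi[1] * gj[1] * es[, 1] + gi[2] * gj[2] * es[, 2] +
                    gi[3] * gj[3] * es[, 3] +
                    (gi[1] * gj[2] + gi[2] * gj[1]) * es[, 4] +
                    (gi[1] * gj[3] + gi[3] * gj[1]) * es[, 5] +
                    (gi[2] * gj[3] + gi[3] * gj[2]) * es[, 6])
      NI[[length(NI) + 1L]] <- corners_m[, ids[i]]
      NJ[[length(NJ) + 1L]] <- corners_m[, ids[j]]
      NX[[length(NX) + 1L]] <- cij
      if (i != j) {
        NI[[length(NI) + 1L]] <- corners_m[, ids[j]]
        NJ[[length(NJ) + 1L]] <- corners_m[, ids[i]]
        NX[[length(NX) + 1L]] <- cij
      }
    }
    elemE_G[[s]] <- list(G = G, ids = ids, sig = es, V = V)
  }
  K <- Matrix::sparseMatrix(i = unlist(NI), j = unlist(NJ), x = unlist(NX),
                            dims = c(nnode, nnode))
  # Dirichlet: all corner nodes of electrode voxels
  node_pot <- rep(NA_real_, nnode)
  for (e in montage$electrodes) {
    ev <- which(as.vector(e$mask)[vox])
    if (!length(ev)) next
    node_pot[unique(as.vector(corners_m[ev, ]))] <- e$potential
  }
  fixed <- which(!is.na(node_pot))
  free <- which(is.na(node_pot))
  phi <- numeric(nnode)
  phi[fixed] <- node_pot[fixed]
  rhs <- as.numeric(-K[free, fixed, drop = FALSE] %*% phi[fixed])
  Kff <- K[free, free, drop = FALSE]
  cg <- pcg_solve(Kff, rhs, tol = tol)
  phi[free] <- cg$x
  resid <- cg$residual
  if (resid > tol) stop(sprintf("solver did not reach tol: residual %.3e", resid))
  # reactions at electrode nodes -> electrode currents
  r_all <- as.numeric(K %*% phi)
  currents <- vapply(montage$electrodes, function(e) {
    ev <- which(as.vector(e$mask)[vox])
    if (!length(ev)) return(0)
    sum(r_all[unique(as.vector(corners_m[ev, ]))])
  }, 1)
  names(currents) <- vapply(montage$electrodes, `[[`, "", "name")
  # constant per-element E and J; voxel-averaged fields for statistics
  Evox <- array(0, c(d, 3L)); Jvox <- array(0, c(d, 3L))
  Eacc <- matrix(0, nvox, 3); Jacc <- matrix(0, nvox, 3)
  for (s in 1:6) {
    G <- elemE_G[[s]]$G; ids <- elemE_G[[s]]$ids; es <- elemE_G[[s]]$sig
    pe <- matrix(phi[corners_m[, ids]], nvox, 4)
    Ee <- -pe %*% t(G)
    Je <- cbind(es[, 1] * Ee[, 1] + es[, 4] * Ee[, 2] + es[, 5] * Ee[, 3],
                es[, 4] * Ee[, 1] + es[, 2] * Ee[, 2] + es[, 6] * Ee[, 3],
                es[, 5] * Ee[, 1] + es[, 6] * Ee[, 2] + es[, 3] * Ee[, 3])
    Eacc <- Eacc + Ee / 6
    Jacc <- Jacc + Je / 6
  }
  for (ax in 1:3) {
    tmp <- array(0, d); tmp[vox] <- Eacc[, ax]; Evox[, , , ax] <- tmp
    tmp <- array(0, d); tmp[vox] <- Jacc[, ax]; Jvox[, , , ax] <- tmp
  }
  pot <- rep(NA_real_, n)
  # voxel potential = mean of its corners (for maps/exports)
  pot[vox] <- rowMeans(matrix(phi[corners_m], nvox, 8))
  structure(list(potential = array(pot, d), E = Evox, J = Jvox,
                 potential_nodes = phi, residual = resid,
                 electrode_currents = currents,
                 domain = array(seq_len(n) %in% vox, d),
                 spacing = cc$spacing, origin = cc$origin,
                 method = "fem_p1"),
            class = "field_solution")
}

#' Compare two field solutions within a region
#'
#' @param solution_a,solution_b `field_solution`s on the same grid.
#' @param region_mask logical array, nonempty.
#' @return list with per-solution median/quantile `|E|` and `|J|` plus
#'   the (a / b) ratios of the medians.
#' @export
compare_montages <- function(solution_a, solution_b, region_mask) {
  stopifnot(any(region_mask))
  stats_of <- function(sol) {
    e <- field_magnitude(sol, "E")[region_mask]
    j <- field_magnitude(sol, "J")[region_mask]
    list(E_median = median(e), E_p95 = quantile(e, 0.95, names = FALSE),
         J_median = median(j), J_p95 = quantile(j, 0.95, names = FALSE))
  }
  a <- stats_of(solution_a); b <- stats_of(solution_b)
  list(a = a, b = b,
       ratio_E_median = a$E_median / b$E_median,
       ratio_J_median = a$J_median / b$J_median)
}

#' Isotropic conductivity map from a per-tissue scalar table
#' @param labels a `label_volume`.
#' @param table named numeric vector: label id (as name) -> S/m.
#' @param cap eigenvalue cap (default 1.8 S/m).
#' @return a `conductivity_map`.
#' @export
scalar_conductivity_map <- function(labels, table, cap = 1.8) {
  stopifnot(inherits(labels, "label_volume"))
  present <- sort(unique(as.vector(labels$labels)))
  missing <- setdiff(as.character(present), names(table))
  if (length(missing))
    stop("missing conductivity for label(s): ", paste(missing, collapse = ", "))
  d <- dim(labels$labels)
  v <- pmin(unname(table[as.character(as.vector(labels$labels))]), cap)
  sig <- cbind(v, v, v, 0, 0, 0)
  structure(list(sigma = array(sig, c(d, 6L)),
                 tensor_mask = array(FALSE, d), cap = cap,
                 spacing = labels$spacing, origin = labels$origin),
            class = "conductivity_map")
}

#' Default per-tissue scalar conductivities (S/m, 10 Hz literature values)
#'
#' Covers the default phantom labels: skin 0.1, cortical skull tables
#' 0.008, diploe 0.025, CSF 1.8, GM 0.2, WM 0.15, ventricles 1.8 (CSF),
#' eyes 0.5 (vitreous), background 0.
#'
#' @return named numeric vector.
#' @export
default_conductivities <- function() {
  c("0" = 0, "1" = 0.1, "2" = 0.008, "3" = 0.025, "4" = 0.008,
    "5" = 1.8, "6" = 0.2, "7" = 0.15, "8" = 1.8, "9" = 0.5, "10" = 0.5)
}

#' Scalar vs DTI-tensor conductivity comparison study
#'
#' Solves the same montage twice — per-tissue scalar conductivities vs a
#' DTI-derived tensor map — and reports the tensor/scalar ratio of the
#' median `|E|` within the brain mask, with distribution summaries. The
#' form mirrors the anisotropy comparison performed on full head models;
#' the magnitude of the change is geometry-dependent at desk scale.
#'
#' @param labels a `label_volume`.
#' @param scalar_table named scalar conductivities (label id -> S/m).
#' @param tensor_map a `conductivity_map` with DTI-derived tensors.
#' @param montage an `electrode_montage`.
#' @param brain_mask logical array over which fields are compared.
#' @param tol solver tolerance.
#' @return list with both solutions' brain-field summaries and
#'   `ratio_E_median` (tensor / scalar).
#' @export
scalar_vs_tensor_study <- function(labels, scalar_table, tensor_map, montage,
                                   brain_mask, tol = 1e-8) {
  smap <- scalar_conductivity_map(labels, scalar_table, cap = tensor_map$cap)
  sol_s <- solve_fem(smap, montage, tol = tol, sample_centroids = FALSE)
  sol_t <- solve_fem(tensor_map, montage, tol = tol, sample_centroids = FALSE)
  es <- field_magnitude(sol_s, "E")[brain_mask]
  et <- field_magnitude(sol_t, "E")[brain_mask]
  list(scalar = list(E_median = median(es), E_p95 = quantile(es, 0.95, names = FALSE)),
       tensor = list(E_median = median(et), E_p95 = quantile(et, 0.95, names = FALSE)),
       ratio_E_median = median(et) / median(es),
       direction = if (median(et) < median(es)) "tensor model weakens the brain field"
                   else "tensor model strengthens the brain field")
}
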