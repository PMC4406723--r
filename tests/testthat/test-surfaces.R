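test_that("single voxel extracts to an exact cube", {
  lab <- array(0L, c(4, 4, 4)); lab[2, 2, 2] <- 1L
  mesh <- extract_interfaces(label_volume(lab, spacing = rep(0.5, 3)))
  expect_equal(nrow(mesh$vertices), 8L)
  expect_equal(nrow(mesh$triangles), 12L)
  expect_equal(mesh_area(mesh), 6 * 0.25)
  a <- audit_mesh(mesh)
  expect_equal(a$regions$region_1$volume_mm3, 0.125)
  expect_equal(a$regions$region_1$euler, 2)
  expect_true(a$regions$region_1$watertight)
  expect_true(a$regions$region_1$oriented)
  expect_identical(a$self_intersections, 0L)
})

test_that("interfaces between regions are stored once and shared", {
  lab <- array(0L, c(4, 4, 4)); lab[2, 2, 2] <- 1L; lab[3, 2, 2] <- 2L
  mesh <- extract_interfaces(label_volume(lab))
  iface <- (mesh$tags[, 1] == 1 & mesh$tags[, 2] == 2) |
    (mesh$tags[, 1] == 2 & mesh$tags[, 2] == 1)
  expect_identical(sum(iface), 2L)   # one face = two triangles, once
  # both regions closed, conformal by shared storage
  a <- audit_mesh(mesh)
  expect_true(a$regions$region_1$watertight)
  expect_true(a$regions$region_2$watertight)
  # region volumes sum to the two voxels
  expect_equal(a$regions$region_1$volume_mm3 + a$regions$region_2$volume_mm3, 2)
})

test_that("a voxelized ball is a topological sphere", {
  ball <- ball_mask(20, 7)
  mesh <- extract_interfaces(label_volume(array(as.integer(ball), dim(ball))))
  a <- audit_mesh(mesh)
  expect_equal(a$regions$region_1$euler, 2)
  expect_equal(a$regions$region_1$volume_mm3, sum(ball))
})

test_that("Taubin smoothing reduces distance to the ideal sphere", {
  ball <- ball_mask(24, 8, center = c(12.5, 12.5, 12.5))
  lv <- label_volume(array(as.integer(ball), dim(ball)))
  mesh <- extract_interfaces(lv)
  expect_identical(smooth_mesh(mesh, 0), mesh)
  sm <- smooth_mesh(mesh)
  rms_to_sphere <- function(m) {
    ctr <- c(11.5, 11.5, 11.5)  # world coords of voxel (12.5,...) centre
    r <- sqrt(rowSums(sweep(m$vertices, 2, ctr)^2))
    sqrt(mean((r - 8)^2))
  }
  expect_lt(rms_to_sphere(sm), rms_to_sphere(mesh))
  # volume within 2% at defaults
  a <- audit_mesh(sm)
  expect_lt(abs(a$regions$region_1$volume_mm3 - sum(ball)) / sum(ball), 0.02)
  expect_identical(a$self_intersections, 0L)
})

test_that("simplification shrinks triangle count under guard invariants", {
  ball <- ball_mask(20, 7)
  lv <- label_volume(array(as.integer(ball), dim(ball)))
  mesh <- smooth_mesh(extract_interfaces(lv))
  # target below current minimum edge = identity
  same <- simplify_mesh(mesh, target_edge_mm = 1e-4)
  expect_identical(same$triangles, mesh$triangles)
  simp <- simplify_mesh(mesh, target_edge_mm = 1.5)
  expect_lt(nrow(simp$triangles), nrow(mesh$triangles))
  a <- audit_mesh(simp)
  expect_true(a$regions$region_1$watertight)
  expect_true(a$regions$region_1$oriented)
  expect_equal(a$regions$region_1$euler, 2)
  expect_identical(a$self_intersections, 0L)
  expect_lt(abs(a$regions$region_1$volume_mm3 - sum(ball)) / sum(ball), 0.02)
})

test_that("adaptive sizing keeps shorter edges in thin structures", {
  # thin slab + thick blob in one volume
  lab <- array(0L, c(28, 28, 28))
  lab[4:24, 4:24, 4:5] <- 1L              # slab, 2 voxels thick
  ball <- ball_mask(28, 6, center = c(14, 14, 18))
  lab[ball] <- 2L
  lv <- label_volume(lab)
  mesh <- smooth_mesh(extract_interfaces(lv))
  simp <- simplify_mesh(mesh, target_edge_mm = 3, sizing = "adaptive")
  edge_mean <- function(m, label) {
    sel <- m$tags[, 1] == label | m$tags[, 2] == label
    tris <- m$triangles[sel, , drop = FALSE]
    e <- unique(rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)]))
    mean(sqrt(rowSums((m$vertices[e[, 1], , drop = FALSE] -
                         m$vertices[e[, 2], , drop = FALSE])^2)))
  }
  expect_lt(edge_mean(simp, 1L), edge_mean(simp, 2L))
})

test_that("audit flags an inverted triangle", {
  lab <- array(0L, c(4, 4, 4)); lab[2:3, 2:3, 2:3] <- 1L
  mesh <- extract_interfaces(label_volume(lab))
  bad <- mesh
  bad$triangles[1, ] <- bad$triangles[1, c(1, 3, 2)]
  a <- audit_mesh(bad)
  expect_false(a$regions$region_1$oriented)
})

test_that("multi-region nested phantom stays conformal through the pipeline", {
  # Thin 1-voxel shells (skull tables at this resolution) contain
  # diagonal-touch pinched edges straight out of voxel-face extraction, so
  # strict 2-manifoldness cannot hold there; the closed (boundaryless,
  # orientation-balanced) contract must survive every stage, and thick
  # regions must stay strictly watertight.
  spec <- default_head_spec(24)
  vol <- generate_label_phantom(spec)
  mesh <- extract_interfaces(vol)
  sm <- smooth_mesh(mesh)
  simp <- simplify_mesh(sm, target_edge_mm = 1.5)
  thick <- paste0("region_", c(7, 8, 9, 10))   # WM, ventricles, eyes
  for (m in list(mesh, sm, simp)) {
    a <- audit_mesh(m)
    for (nm in names(a$regions)) expect_true(a$regions[[nm]]$closed)
    for (nm in thick) expect_true(a$regions[[nm]]$watertight)
    expect_identical(a$self_intersections, 0L)
  }
})

test_that("mesh export writes readable PLY and STL", {
  lab <- array(0L, c(4, 4, 4)); lab[2, 2, 2] <- 1L
  mesh <- extract_interfaces(label_volume(lab))
  dir <- file.path(tempdir(), "mesh_test")
  p1 <- write_mesh(mesh, dir, "ply")
  p2 <- write_mesh(mesh, dir, "stl")
  expect_true(all(file.exists(c(p1, p2))))
  ply <- readLines(p1[1])
  expect_identical(ply[1], "ply")
  expect_true(any(grepl("element vertex 8", ply)))
  unlink(dir, recursive = TRUE)
})
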