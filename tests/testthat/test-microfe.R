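test_that("voxel meshes count elements, nodes and interface faces correctly", {
  m <- build_mesh(block_label(2, 2, 4, 50))
  expect_identical(m$n_elements, 16L)
  expect_identical(m$n_nodes, 45L)
  expect_identical(nrow(m$interface$corners), 0L)

  # half-bone/half-cement split at mid-height: one interface face per
  # cross-section voxel
  arr <- array(1L, dim = c(3, 3, 4)); arr[, , 3:4] <- 2L
  ms <- build_mesh(label_volume(arr, 50))
  expect_identical(nrow(ms$interface$corners), 9L)
  expect_true(all(ms$interface$axis == 3L))

  # random label fixture vs a brute-force voxel-walk oracle
  set.seed(31)
  arr2 <- array(sample(0:2, 6 * 5 * 7, TRUE, prob = c(0.35, 0.35, 0.3)),
                dim = c(6, 5, 7))
  arr2[, , 1][arr2[, , 1] == 0L] <- 1L
  arr2[, , 7][arr2[, , 7] == 0L] <- 2L
  arr2[3, 3, ] <- 1L  # guarantee a spanning column
  m2 <- build_mesh(label_volume(arr2, 50))
  # oracle: count solid voxels and distinct corner nodes by direct enumeration
  solid_idx <- which(arr2 > 0L, arr.ind = TRUE)
  corners <- unique(do.call(rbind, lapply(seq_len(nrow(solid_idx)), function(r) {
    v <- solid_idx[r, ]
    expand.grid(v[1] + 0:1, v[2] + 0:1, v[3] + 0:1)
  })))
  expect_lte(m2$n_elements, nrow(solid_idx))  # floating components may drop
  kept <- m2$n_elements
  # rebuild oracle on the kept voxels only
  kept_idx <- m2$vox + 1L
  corners_kept <- unique(do.call(rbind, lapply(seq_len(nrow(kept_idx)), function(r) {
    v <- kept_idx[r, ]
    expand.grid(v[1] + 0:1, v[2] + 0:1, v[3] + 0:1)
  })))
  expect_identical(m2$n_nodes, nrow(corners_kept))
  # interface oracle: count adjacent bone/cement voxel pairs among kept voxels
  lab_kept <- array(0L, dim = dim(arr2)); lab_kept[kept_idx] <- m2$mat
  nf <- 0L
  for (ax in 1:3) {
    dd <- dim(arr2); dd[ax] <- dd[ax] - 1L
    for (i in seq_len(dd[1])) for (j in seq_len(dd[2])) for (k in seq_len(dd[3])) {
      a <- lab_kept[i, j, k]
      b <- lab_kept[i + (ax == 1), j + (ax == 2), k + (ax == 3)]
      if ((a == 1L && b == 2L) || (a == 2L && b == 1L)) nf <- nf + 1L
    }
  }
  expect_identical(nrow(m2$interface$corners), nf)

  # unloadable specimens are refused
  arr3 <- array(0L, dim = c(4, 4, 6)); arr3[2, 2, 1:3] <- 1L
  expect_error(build_mesh(label_volume(arr3, 50)), "span")
})

test_that("element stiffness has rigid-body null space, scales with E, matches quadrature oracle", {
  mat <- material("bone", 280, 0.3)
  K <- element_stiffness(mat, 50)
  expect_equal(K, t(K), tolerance = 1e-15)
  # six rigid modes: three translations, three infinitesimal rotations
  corners <- trabevalid:::hex_corners() * 0.05
  modes <- cbind(rep(c(1, 0, 0), 8), rep(c(0, 1, 0), 8), rep(c(0, 0, 1), 8),
                 as.vector(t(cbind(-corners[, 2], corners[, 1], 0))),
                 as.vector(t(cbind(0, -corners[, 3], corners[, 2]))),
                 as.vector(t(cbind(corners[, 3], 0, -corners[, 1]))))
  expect_lt(max(abs(K %*% modes)), 1e-12 * max(abs(K)) * max(abs(modes)))
  expect_equal(qr(K)$rank, 18L)

  # K(E = 2280) = (2280/280) K(E = 280) elementwise at fixed nu
  K2 <- element_stiffness(material("cement", 2280, 0.3), 50)
  expect_equal(K2, (2280 / 280) * K, tolerance = 1e-12)

  # fine-quadrature numerical-integration oracle
  Ko <- element_stiffness_oracle(mat, 50)
  expect_lt(max(abs(K - Ko)) / max(abs(K)), 1e-8)
})

test_that("patch test: affine Dirichlet data is reproduced at interior nodes", {
  mesh <- build_mesh(block_label(3, 3, 5, 100))
  set.seed(5)
  A <- matrix(runif(9, -0.01, 0.01), 3)
  b0 <- runif(3, -0.005, 0.005)
  coords <- trabevalid:::mesh_node_coords(mesh)
  gnx <- mesh$dims[1] + 1L; gny <- mesh$dims[2] + 1L; gnz <- mesh$dims[3] + 1L
  ijk <- trabevalid:::key_to_ijk(mesh$node_key, gnx, gny)
  bnd <- which(ijk[, 1] %in% c(0, gnx - 1L) | ijk[, 2] %in% c(0, gny - 1L) |
               ijk[, 3] %in% c(0, gnz - 1L))
  uaff <- coords %*% t(A) + matrix(b0, nrow(coords), 3, byrow = TRUE)
  cons <- data.frame(node = rep(bnd, 3), comp = rep(1:3, each = length(bnd)),
                     value = c(uaff[bnd, 1], uaff[bnd, 2], uaff[bnd, 3]))
  sol <- solve_microfe(mesh, constraints = cons, opts = solver_options(1e-13, 5000))
  expect_lt(max(abs(sol$displacements - uaff)), 1e-10)
})

test_that("homogeneous bar reproduces EA/L stiffness and the constant-strain state", {
  # E = 280 MPa, A = 1 mm^2, L = 2 mm -> 140 N/mm
  bar <- block_label(4, 4, 8, 250)
  mesh <- build_mesh(bar)
  bc <- build_boundary_conditions(c(0, 0, -0.01), c(0, 0, 0), 1L, 2)
  sol <- solve_microfe(mesh, bc, opts = solver_options(1e-12, 5000), bc_mode = "axial")
  expect_equal(apparent_stiffness(sol), 140, tolerance = 1e-8)
  expect_equal(sol$stiffness_energy, 140, tolerance = 1e-8)
  # uniform compressive stress E u / L
  expect_equal(as.vector(sol$stress[, 3]), rep(-1.4, mesh$n_elements),
               tolerance = 1e-8)
  expect_lt(max(abs(sol$stress[, c(1, 2, 4, 5, 6)])), 1e-8)
  # force balance
  expect_lt(abs(sol$reactions$top[3] + sol$reactions$bottom[3]),
            1e-6 * abs(sol$reactions$top[3]))

  # doubling the applied displacement doubles reactions, stiffness unchanged
  bc2 <- build_boundary_conditions(c(0, 0, -0.02), c(0, 0, 0), 1L, 2)
  sol2 <- solve_microfe(mesh, bc2, opts = solver_options(1e-12, 5000), bc_mode = "axial")
  expect_equal(sol2$reactions$top[3], 2 * sol$reactions$top[3], tolerance = 1e-8)
  expect_equal(apparent_stiffness(sol2), 140, tolerance = 1e-8)
})

test_that("series composite matches the springs-in-series closed form", {
  # L1 = L2 = 1 mm, E1 = 280, E2 = 2280, A = 1 mm^2, nu = 0 (the closed form
  # is exact only without lateral coupling)
  arr <- array(1L, dim = c(4, 4, 8)); arr[, , 5:8] <- 2L
  mats <- list(bone = material("bone", 280, 0), cement = material("cement", 2280, 0))
  mesh <- build_mesh(label_volume(arr, 250), mats)
  bc <- build_boundary_conditions(c(0, 0, -0.01), c(0, 0, 0), 1L, 2)
  sol <- solve_microfe(mesh, bc, opts = solver_options(1e-12, 20000), bc_mode = "axial")
  expect_equal(apparent_stiffness(sol), 1 / (1 / 280 + 1 / 2280), tolerance = 1e-8)

  # with nu = 0.3 the formula is a close approximation (interface constraint)
  mesh3 <- build_mesh(label_volume(arr, 250), default_materials())
  sol3 <- solve_microfe(mesh3, bc, opts = solver_options(1e-12, 20000), bc_mode = "axial")
  expect_equal(apparent_stiffness(sol3), 1 / (1 / 280 + 1 / 2280), tolerance = 0.03)
})

test_that("identical end displacements give a stress-free rigid motion", {
  mesh <- build_mesh(block_label(3, 3, 6, 200))
  bc <- suppressWarnings(build_boundary_conditions(c(0.003, 0.001, -0.002),
                                                   c(0.003, 0.001, -0.002), 1L, 1.2))
  sol <- solve_microfe(mesh, bc, opts = solver_options(1e-12, 5000))
  expect_lt(max(abs(sol$stress)), 1e-9)
  expect_lt(max(abs(c(sol$reactions$top, sol$reactions$bottom))), 1e-9)
})

test_that("PCG matches a dense direct-solve oracle on a small two-material mesh", {
  set.seed(11)
  arr <- array(sample(0:2, 27, TRUE, prob = c(0.3, 0.4, 0.3)), dim = c(3, 3, 3))
  arr[, , 1][arr[, , 1] == 0L] <- 1L
  arr[, , 3][arr[, , 3] == 0L] <- 2L
  arr[2, 2, ] <- 1L
  mesh <- build_mesh(label_volume(arr, 100))
  expect_lte(3L * mesh$n_nodes, 500L)  # within the dense-oracle regime
  bc <- build_boundary_conditions(c(0.001, 0, -0.003), c(0, 0, 0.003), 1L, 0.3)
  sol <- solve_microfe(mesh, bc, opts = solver_options(1e-12, 5000))
  lay <- trabevalid:::build_layout(mesh, interface_model("tied"), 0.1)
  ends <- trabevalid:::end_constraints(mesh, lay, bc, "clamped")
  u_oracle <- dense_solve_oracle(mesh, ends$dofs, ends$values)
  expect_lt(max(abs(sol$u - u_oracle)), 1e-8)
})

test_that("linearity: solutions at 3% and 5% strain are scalar multiples", {
  set.seed(23)
  arr <- array(sample(0:2, 4 * 4 * 6, TRUE), dim = c(4, 4, 6))
  arr[2:3, 2:3, ] <- 1L
  mesh <- build_mesh(label_volume(arr, 100))
  h <- 0.6
  bc3 <- build_boundary_conditions(c(0, 0, -0.03 * h / 2), c(0, 0, 0.03 * h / 2), 1L, h)
  bc5 <- build_boundary_conditions(c(0, 0, -0.05 * h / 2), c(0, 0, 0.05 * h / 2), 2L, h)
  s3 <- solve_microfe(mesh, bc3, opts = solver_options(1e-13, 10000))
  s5 <- solve_microfe(mesh, bc5, opts = solver_options(1e-13, 10000))
  expect_lt(max(abs(s5$u - (5 / 3) * s3$u)) / max(abs(s5$u)), 1e-8)
  expect_equal(apparent_stiffness(s3), apparent_stiffness(s5), tolerance = 1e-8)
})

test_that("von Mises closed forms hold", {
  expect_equal(von_mises(c(5, 0, 0, 0, 0, 0)), 5)
  expect_equal(von_mises(c(3, 3, 3, 0, 0, 0)), 0)
  expect_equal(von_mises(c(0, 0, 0, 2, 0, 0)), sqrt(3) * 2)
  m <- rbind(c(1, 2, 3, 0.5, -0.5, 0.25), c(0, 0, 0, 0, 0, 1))
  expect_equal(von_mises(m)[2], sqrt(3))
  expect_error(von_mises(c(1, 2, 3)), "6 components")
  expect_error(apparent_stiffness(structure(list(bcs = NULL), class = "fe_solution")),
               "no boundary conditions")
})

test_that("frictionless penalty solutions approach the tied solution monotonically", {
  arr <- array(1L, dim = c(3, 3, 6)); arr[, , 4:6] <- 2L
  arr[2, 2, 3] <- 2L  # a cement finger for interdigitation
  mesh <- build_mesh(label_volume(arr, 200))
  bc <- build_boundary_conditions(c(0.0005, 0, -0.01), c(0, 0, 0.01), 1L, 1.2)
  tied <- solve_microfe(mesh, bc, opts = solver_options(1e-12, 20000))
  field_of <- function(sol) do.call(cbind, solution_field(sol))
  ref <- field_of(tied)
  dev <- vapply(c(1e2, 1e3, 1e4, 1e5, 1e6), function(pen) {
    s <- solve_microfe(mesh, bc, interface_model("frictionless_penalty", pen),
                       opts = solver_options(1e-12, 40000))
    sqrt(sum((field_of(s) - ref)^2))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  # the limit closes the normal gap only (tangential sliding stays free), so
  # the deviation floors out rather than vanishing
  expect_lt(dev[5], 0.5 * dev[1])
})

test_that("INP and VTK exports round-trip counts and field lengths", {
  arr <- array(1L, dim = c(2, 2, 3)); arr[, , 3] <- 2L
  mesh <- build_mesh(label_volume(arr, 100))
  inp <- tempfile(fileext = ".inp")
  export_mesh(mesh, path = inp)
  back <- import_inp(inp)
  expect_identical(nrow(back$nodes), mesh$n_nodes)
  expect_identical(nrow(back$elements), mesh$n_elements)
  expect_identical(sum(back$elset == "BONE"), sum(mesh$mat == 1L))
  expect_identical(sum(back$elset == "CEMENT"), sum(mesh$mat == 2L))

  # a one-element mesh has 8 nodes and 1 element
  one <- build_mesh(block_label(1, 1, 1, 100))
  inp1 <- tempfile(fileext = ".inp")
  export_mesh(one, path = inp1)
  b1 <- import_inp(inp1)
  expect_identical(dim(b1$nodes), c(8L, 3L))
  expect_identical(nrow(b1$elements), 1L)

  bc <- build_boundary_conditions(c(0, 0, -0.001), c(0, 0, 0.001), 1L, 0.3)
  sol <- solve_microfe(mesh, bc, opts = solver_options(1e-10, 2000))
  vtk <- tempfile(fileext = ".vtk")
  export_mesh(mesh, sol, vtk)
  lines <- readLines(vtk)
  expect_identical(sum(grepl("^POINTS", lines)), 1L)
  npts <- as.integer(strsplit(grep("^POINTS", lines, value = TRUE), " ")[[1]][2])
  ncel <- as.integer(strsplit(grep("^CELLS", lines, value = TRUE), " ")[[1]][2])
  expect_identical(npts, mesh$n_nodes)
  expect_identical(ncel, mesh$n_elements)
  vm_at <- grep("SCALARS von_mises", lines) + 2L
  expect_equal(length(scan(text = lines[vm_at:(vm_at + ncel - 1L)], quiet = TRUE)),
               mesh$n_elements)
})
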