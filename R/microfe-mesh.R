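#' Linear elastic material
#'
#' @param name Material name.
#' @param E Elastic modulus, MPa (> 0).
#' @param nu Poisson's ratio, `0 <= nu < 0.5`.
#' @return A `material` object.
#' @export
material <- function(name, E, nu) {
  if (!is.finite(E) || E <= 0) stopf("E must be positive (MPa)")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5) stopf("nu must satisfy 0 <= nu < 0.5")
  structure(list(name = name, E = E, nu = nu), class = "material")
}

#' Default specimen materials
#'
#' Homogeneous linear elastic polyurethane foam (bone surrogate, E = 280 MPa)
#' and PMMA cement (E = 2280 MPa), both with Poisson's ratio 0.3.
#' @return Named list with elements `bone` and `cement`.
#' @export
default_materials <- function() {
  list(bone = material("bone", 280, 0.3), cement = material("cement", 2280, 0.3))
}

# local corner order of the trilinear hexahedron (x fastest, bottom then top
# face); matches the C3D8 convention and the C++ kernels.
hex_corners <- function() {
  cbind(c(0, 1, 1, 0, 0, 1, 1, 0),
        c(0, 0, 1, 1, 0, 0, 1, 1),
        c(0, 0, 0, 0, 1, 1, 1, 1))
}

# isotropic elasticity matrix (engineering shear strains), MPa
elasticity_matrix <- function(material) {
  lam <- material$E * material$nu / ((1 + material$nu) * (1 - 2 * material$nu))
  mu <- material$E / (2 * (1 + material$nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  D[4, 4] <- D[5, 5] <- D[6, 6] <- mu
  D
}

# strain-displacement matrix (6 x 24) of the cube element with edge h_mm at
# local coordinates (xi, eta, zeta) in [-1, 1]^3
hex_B <- function(xi, eta, zeta, h_mm) {
  s <- 2 * hex_corners() - 1
  dN <- cbind(s[, 1] * (1 + eta * s[, 2]) * (1 + zeta * s[, 3]),
              s[, 2] * (1 + xi * s[, 1]) * (1 + zeta * s[, 3]),
              s[, 3] * (1 + xi * s[, 1]) * (1 + eta * s[, 2])) / 8
  dN <- dN * (2 / h_mm)
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    ix <- 3 * (a - 1) + 1
    B[1, ix] <- dN[a, 1]
    B[2, ix + 1] <- dN[a, 2]
    B[3, ix + 2] <- dN[a, 3]
    B[4, ix] <- dN[a, 2]; B[4, ix + 1] <- dN[a, 1]
    B[5, ix + 1] <- dN[a, 3]; B[5, ix + 2] <- dN[a, 2]
    B[6, ix] <- dN[a, 3]; B[6, ix + 2] <- dN[a, 1]
  }
  B
}

#' Stiffness matrix of a cubic trilinear hexahedral element
#'
#' Standard 8-node trilinear hexahedron with 2x2x2 Gauss quadrature, for a
#' cube of edge `h` micrometres. DOF order is (node 1 x, y, z, node 2 x, ...)
#' with the corner numbering of the C3D8 convention. Units: MPa and mm, so
#' the matrix maps mm displacements to N forces.
#'
#' @param material A [material()].
#' @param h Element edge length, micrometres.
#' @return Symmetric 24 x 24 matrix with a 6-dimensional rigid-body null
#'   space, scaling linearly with `E` at fixed `nu`.
#' @export
element_stiffness <- function(material, h) {
  stopifnot(inherits(material, "material"), h > 0)
  h_mm <- vox_mm(h)
  D <- elasticity_matrix(material)
  g <- 1 / sqrt(3)
  K <- matrix(0, 24, 24)
  detJ <- (h_mm / 2)^3
  for (xi in c(-g, g)) for (eta in c(-g, g)) for (zeta in c(-g, g)) {
    B <- hex_B(xi, eta, zeta, h_mm)
    K <- K + crossprod(B, D %*% B) * detJ
  }
  (K + t(K)) / 2
}

#' Build a voxel hexahedral mesh from a label volume
#'
#' One 8-node hexahedral element per solid voxel, bone and cement elements
#' sharing nodes (the tied-interface layout), with the cement-bone interface
#' faces enumerated for the frictionless contact linearization. Marker voxels
#' take the majority material of their non-marker solid 6-neighbours; marker
#' voxels isolated in background are excluded. Solid components not connected
#' to either end plane are dropped (they would float freely under the end
#' displacements); the remaining solid must span both end planes.
#'
#' @param label A [label_volume()] at model resolution (50 um by default
#'   pipelines).
#' @param materials Named list with `bone` and `cement` [material()]s.
#' @return A `voxel_mesh` object.
#' @export
build_mesh <- function(label, materials = default_materials()) {
  stopifnot(inherits(label, "label_volume"))
  d <- dim(label$data)
  arr <- label$data
  # resolve markers to their underlying material
  mk <- which(arr == LBL[["marker"]])
  if (length(mk)) {
    ijk <- arrayInd(mk, d)
    resolved <- integer(length(mk))
    for (t in seq_along(mk)) {
      i <- ijk[t, 1]; j <- ijk[t, 2]; k <- ijk[t, 3]
      nb <- c(if (i > 1) arr[i - 1, j, k], if (i < d[1]) arr[i + 1, j, k],
              if (j > 1) arr[i, j - 1, k], if (j < d[2]) arr[i, j + 1, k],
              if (k > 1) arr[i, j, k - 1], if (k < d[3]) arr[i, j, k + 1])
      nb <- nb[nb == LBL[["bone"]] | nb == LBL[["cement"]]]
      resolved[t] <- if (length(nb) == 0L) LBL[["background"]]
        else if (sum(nb == LBL[["cement"]]) > sum(nb == LBL[["bone"]])) LBL[["cement"]]
        else LBL[["bone"]]
    }
    arr[mk] <- resolved
  }
  solid <- arr == LBL[["bone"]] | arr == LBL[["cement"]]
  if (!any(solid)) stopf("empty solid phase: nothing to mesh")
  cc <- .cc_label26(as.vector(solid), as.integer(d))
  ncomp <- attr(cc, "n_components")
  cc <- array(cc, dim = d)
  bottom_ids <- unique(cc[, , 1][cc[, , 1] > 0L])
  top_ids <- unique(cc[, , d[3]][cc[, , d[3]] > 0L])
  anchored <- union(bottom_ids, top_ids)
  if (length(intersect(bottom_ids, top_ids)) == 0L)
    stopf("solid phase does not span both end planes: unloadable specimen")
  if (length(anchored) < ncomp) {
    drop <- sum(solid) - sum(cc %in% anchored)
    message(sprintf("build_mesh: dropping %d free-floating solid voxels", drop))
    solid <- solid & array(cc %in% anchored, dim = d)
    arr[!solid] <- LBL[["background"]]
  }
  idx <- which(solid)
  ijk <- arrayInd(idx, d) - 1L  # 0-based voxel indices
  mat <- as.integer(arr[idx])
  gnx <- d[1] + 1L; gny <- d[2] + 1L; gnz <- d[3] + 1L
  corners <- hex_corners()
  keys <- matrix(0L, nrow(ijk), 8L)
  for (a in 1:8) {
    keys[, a] <- (ijk[, 1] + corners[a, 1]) +
      gnx * ((ijk[, 2] + corners[a, 2]) + gny * (ijk[, 3] + corners[a, 3]))
  }
  ukeys <- sort(unique(as.vector(keys)))
  elem_nodes <- matrix(match(keys, ukeys) - 1L, nrow(ijk), 8L)
  iface <- interface_faces(arr, d, gnx, gny)
  mesh <- structure(list(
    dims = d, voxel_size = label$voxel_size, origin = label$origin,
    vox = ijk, mat = mat, elem_nodes = elem_nodes,
    node_key = ukeys, n_nodes = length(ukeys), n_elements = nrow(ijk),
    interface = iface, materials = materials,
    specimen = specimen_geometry(label)), class = "voxel_mesh")
  mesh
}

# enumerate voxel faces where bone and cement elements meet; returns corner
# grid keys (nface x 4) and the face normal axis (1 = x, 2 = y, 3 = z)
interface_faces <- function(arr, d, gnx, gny) {
  corners_list <- list()
  axes <- integer()
  cpat <- list(
    # corners of the shared face between voxel v and v + e_axis, as offsets
    # from the 0-based index of v
    x = cbind(c(1, 1, 1, 1), c(0, 1, 0, 1), c(0, 0, 1, 1)),
    y = cbind(c(0, 1, 0, 1), c(1, 1, 1, 1), c(0, 0, 1, 1)),
    z = cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), c(1, 1, 1, 1)))
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 2L) next
    sel_lo <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    sel_hi <- sel_lo
    sel_lo[[axis]] <- seq_len(n - 1L)
    sel_hi[[axis]] <- 2:n
    a_lo <- arr[sel_lo[[1]], sel_lo[[2]], sel_lo[[3]], drop = FALSE]
    a_hi <- arr[sel_hi[[1]], sel_hi[[2]], sel_hi[[3]], drop = FALSE]
    hit <- which((a_lo == LBL[["bone"]] & a_hi == LBL[["cement"]]) |
                 (a_lo == LBL[["cement"]] & a_hi == LBL[["bone"]]))
    if (!length(hit)) next
    dd <- d; dd[axis] <- n - 1L
    ijk <- arrayInd(hit, dd) - 1L
    pat <- cpat[[axis]]
    corn <- matrix(0L, length(hit), 4L)
    for (a in 1:4) {
      corn[, a] <- (ijk[, 1] + pat[a, 1]) +
        gnx * ((ijk[, 2] + pat[a, 2]) + gny * (ijk[, 3] + pat[a, 3]))
    }
    corners_list[[length(corners_list) + 1L]] <- corn
    axes <- c(axes, rep(axis, length(hit)))
  }
  list(corners = if (length(corners_list)) do.call(rbind, corners_list)
       else matrix(0L, 0L, 4L),
       axis = axes)
}

#' @export
print.voxel_mesh <- function(x, ...) {
  cat(sprintf("<voxel_mesh> %d hexahedral elements (%d bone, %d cement), %d nodes, h = %g um\n",
              x$n_elements, sum(x$mat == 1L), sum(x$mat == 2L), x$n_nodes,
              x$voxel_size))
  cat(sprintf("  %d cement-bone interface faces\n", nrow(x$interface$corners)))
  invisible(x)
}

# corner grid key -> 0-based (i, j, k) corner indices
key_to_ijk <- function(key, gnx, gny) {
  i <- key %% gnx
  j <- (key %/% gnx) %% gny
  k <- key %/% (gnx * gny)
  cbind(i, j, k)
}

# node coordinates (mm) of a mesh
mesh_node_coords <- function(mesh) {
  gnx <- mesh$dims[1] + 1L; gny <- mesh$dims[2] + 1L
  ijk <- key_to_ijk(mesh$node_key, gnx, gny)
  sweep(ijk * vox_mm(mesh$voxel_size), 2, mesh$origin, `+`)
}
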