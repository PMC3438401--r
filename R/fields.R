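# Nodal displacement fields on voxel node grids: constructors for scripted
# fields, nearest-node extension of a mesh field to the full grid, and
# trilinear resampling between resolutions. Fields are lists of arrays
# ux/uy/uz (mm) over the (nx+1) x (ny+1) x (nz+1) node grid of a volume.

node_grid_dims <- function(vol_or_dims) {
  d <- if (is.list(vol_or_dims) && !is.null(vol_or_dims$data)) dim(vol_or_dims$data)
       else vol_or_dims
  d + 1L
}

#' Zero displacement field on a volume's node grid
#' @param volume A volume object (or integer dims vector).
#' @return List of zero arrays `ux`, `uy`, `uz`.
#' @export
zero_field <- function(volume) {
  gd <- node_grid_dims(volume)
  list(ux = array(0, gd), uy = array(0, gd), uz = array(0, gd))
}

#' Uniform rigid translation field
#' @param volume A volume object.
#' @param shift Length-3 translation, mm.
#' @return Displacement field list.
#' @export
translation_field <- function(volume, shift) {
  f <- zero_field(volume)
  f$ux[] <- shift[1]; f$uy[] <- shift[2]; f$uz[] <- shift[3]
  f
}

#' Uniform axial compression field
#'
#' `uz = -strain * (z - z_center)`, lateral components zero: nominal axial
#' strain about the specimen mid-height.
#'
#' @param volume A volume object.
#' @param strain Nominal compressive strain (e.g. 0.03).
#' @return Displacement field list.
#' @export
axial_strain_field <- function(volume, strain) {
  gd <- node_grid_dims(volume)
  vx <- vox_mm(volume$voxel_size)
  z <- volume$origin[3] + (seq_len(gd[3]) - 1) * vx
  zc <- mean(range(z))
  f <- zero_field(volume)
  f$uz <- array(rep(-strain * (z - zc), each = gd[1] * gd[2]), gd)
  f
}

#' Localized plastic-collapse perturbation field
#'
#' A crush band: material above `z_center` moves down by up to `amplitude`
#' through a smooth sigmoidal transition of width `width`. Used to emulate
#' trabecular collapse beyond the elastic limit that a linear elastic model
#' cannot follow.
#'
#' @param volume A volume object.
#' @param amplitude Collapse displacement magnitude, mm.
#' @param z_center Band centre, mm (defaults to specimen mid-height).
#' @param width Band width, mm.
#' @return Displacement field list.
#' @export
collapse_field <- function(volume, amplitude, z_center = NULL, width = 0.5) {
  gd <- node_grid_dims(volume)
  vx <- vox_mm(volume$voxel_size)
  z <- volume$origin[3] + (seq_len(gd[3]) - 1) * vx
  zc <- z_center %||% mean(range(z))
  prof <- -amplitude * stats::pnorm((z - zc) / width)
  f <- zero_field(volume)
  f$uz <- array(rep(prof, each = gd[1] * gd[2]), gd)
  f
}

#' Add two displacement fields
#' @param f,g Displacement field lists on the same node grid.
#' @return Their sum.
#' @export
add_fields <- function(f, g) {
  list(ux = f$ux + g$ux, uy = f$uy + g$uy, uz = f$uz + g$uz)
}

# Extend a field defined only at `defined` node-grid positions (logical array)
# to the full grid by nearest defined node.
extend_field_nearest <- function(field, defined) {
  gd <- dim(field$ux)
  ft <- .edt3d(as.vector(defined), as.integer(gd), TRUE)$feature
  list(ux = array(field$ux[ft], gd),
       uy = array(field$uy[ft], gd),
       uz = array(field$uz[ft], gd))
}

# Resample a node-grid field at spacing h_um onto the node grid of a target
# volume with spacing t_um (trilinear).
resample_field <- function(field, h_um, target_dims, t_um) {
  gd <- dim(field$ux)
  td <- as.integer(target_dims + 1L)
  out <- .resample_field_trilinear(as.vector(field$ux), as.vector(field$uy),
                                   as.vector(field$uz), as.integer(gd),
                                   vox_mm(h_um), td, vox_mm(t_um))
  list(ux = array(out$ux, td), uy = array(out$uy, td), uz = array(out$uz, td))
}
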