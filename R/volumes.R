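#' Grayscale image volume
#'
#' A 3D scalar image with isotropic voxels, the in-memory form of a micro-CT
#' scan. Arrays are indexed `[x, y, z]`; the z axis is the loading axis.
#'
#' @param data 3D numeric array of intensities (finite).
#' @param voxel_size Isotropic voxel edge length in micrometres (> 0).
#' @param origin World position (mm) of the corner of voxel `(1, 1, 1)`;
#'   length-3 numeric.
#' @return An object of class `grayscale_volume`.
#' @export
grayscale_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("data must be a 3D array")
  if (!all(is.finite(data))) stopf("intensities must be finite")
  check_voxgeom(voxel_size, origin)
  structure(list(data = data, voxel_size = voxel_size, origin = as.numeric(origin)),
            class = c("grayscale_volume", "volume"))
}

#' Label volume
#'
#' A per-voxel class map with codes 0 background, 1 bone, 2 cement,
#' 3 marker. Shares the geometry conventions of [grayscale_volume()].
#'
#' @param data 3D integer array with codes in `0:3`.
#' @param voxel_size Voxel edge length, micrometres.
#' @param origin World position (mm) of the corner of voxel `(1, 1, 1)`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("data must be a 3D array")
  if (length(data) == 0L) stopf("label grid must be non-empty")
  storage.mode(data) <- "integer"
  rng <- range(data)
  if (rng[1] < 0L || rng[2] > 3L)
    stopf("label codes must lie in {0 background, 1 bone, 2 cement, 3 marker}")
  check_voxgeom(voxel_size, origin)
  structure(list(data = data, voxel_size = voxel_size, origin = as.numeric(origin)),
            class = c("label_volume", "volume"))
}

check_voxgeom <- function(voxel_size, origin) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stopf("voxel_size must be a single positive number (micrometres)")
  if (!is.numeric(origin) || length(origin) != 3L || !all(is.finite(origin)))
    stopf("origin must be a finite length-3 numeric (mm)")
  invisible(TRUE)
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels @ %g um, origin (%g, %g, %g) mm\n",
              class(x)[1], d[1], d[2], d[3], x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  if (inherits(x, "label_volume")) {
    tb <- tabulate(x$data + 1L, nbins = 4L)
    cat(sprintf("  background %d | bone %d | cement %d | marker %d\n",
                tb[1], tb[2], tb[3], tb[4]))
  } else {
    cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

# World coordinates (mm) of voxel centres along one axis.
axis_coords <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vox_mm(vol$voxel_size)
}

# Specimen geometry attribute (cylinder centre/radius/height), set by the
# generator and used for slice-plan region masks.
specimen_geometry <- function(vol) attr(vol, "specimen")

`specimen_geometry<-` <- function(vol, value) {
  attr(vol, "specimen") <- value
  vol
}

# Solid-phase logical mask (bone or cement).
solid_mask <- function(label) label$data == LBL[["bone"]] | label$data == LBL[["cement"]]
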