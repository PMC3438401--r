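#' Rasterize a label volume through a nodal displacement field
#'
#' Every solid voxel's hexahedron is carried through its 8 nodal
#' displacements, decomposed into 6 tetrahedra, and rasterized into the target
#' grid by point-in-tetrahedron tests at 2x supersampled pixel centres; a
#' target pixel is solid when at least half of its sample points fall inside
#' the deformed solid, with cement taking priority over bone on overlap.
#' Marker blobs are warped alongside and re-painted on top. Inverted
#' (negative-volume) tetrahedra -- a sign of excessive element distortion --
#' trigger a warning naming the first affected elements.
#'
#' @param label A [label_volume()].
#' @param displacements Displacement field list (`ux`, `uy`, `uz`, mm) on the
#'   label grid's nodes (dimension `dim(label) + 1`).
#' @param target_voxel_size Target resolution, micrometres (must not be
#'   coarser than the source).
#' @param target_dim,target_origin Target grid (defaults to a grid of the
#'   requested resolution covering the deformed bounding box).
#' @return A [label_volume()] on the target grid.
#' @export
warp_labels <- function(label, displacements, target_voxel_size,
                        target_dim = NULL, target_origin = NULL) {
  stopifnot(inherits(label, "label_volume"))
  d <- dim(label$data)
  gd <- d + 1L
  for (comp in c("ux", "uy", "uz")) {
    if (!identical(dim(displacements[[comp]]), as.integer(gd)) &&
        !identical(dim(displacements[[comp]]), gd))
      stopf("displacement field %s must be defined on the %d x %d x %d node grid",
            comp, gd[1], gd[2], gd[3])
  }
  if (target_voxel_size > label$voxel_size + 1e-9)
    stopf("target resolution must be at least as fine as the source")
  h <- vox_mm(label$voxel_size)
  t <- vox_mm(target_voxel_size)
  if (is.null(target_dim) || is.null(target_origin)) {
    vx <- vox_mm(label$voxel_size)
    xr <- range(label$origin[1] + (seq_len(gd[1]) - 1) * vx + range(displacements$ux))
    yr <- range(label$origin[2] + (seq_len(gd[2]) - 1) * vx + range(displacements$uy))
    zr <- range(label$origin[3] + (seq_len(gd[3]) - 1) * vx + range(displacements$uz))
    target_origin <- c(xr[1], yr[1], zr[1])
    target_dim <- pmax(1L, as.integer(ceiling(c(diff(xr), diff(yr), diff(zr)) / t)))
  }
  run_raster <- function(sel_codes, as_code) {
    idx <- which(array(label$data %in% sel_codes, dim = d))
    if (!length(idx)) return(NULL)
    ijk <- arrayInd(idx, d) - 1L
    mat <- as.integer(label$data[idx])
    if (!is.null(as_code)) mat <- rep(1L, length(idx))
    .rasterize_warped(ijk, mat,
                      as.vector(displacements$ux), as.vector(displacements$uy),
                      as.vector(displacements$uz), as.integer(gd), h, label$origin,
                      as.integer(target_dim), t, as.numeric(target_origin))
  }
  solid <- run_raster(c(LBL[["bone"]], LBL[["cement"]]), NULL)
  out <- if (is.null(solid)) array(0L, dim = target_dim)
         else array(solid$labels, dim = target_dim)
  inverted <- if (is.null(solid)) integer(0) else solid$inverted_elements
  if (any(label$data == LBL[["marker"]])) {
    mk <- run_raster(LBL[["marker"]], 1L)
    out[array(mk$labels > 0L, dim = target_dim)] <- LBL[["marker"]]
    inverted <- c(inverted, mk$inverted_elements)
  }
  if (length(inverted))
    warning(sprintf("%d element(s) produced inverted tetrahedra under the field (first: %s); the deformation may be too severe for linear kinematics",
                    length(inverted), paste(utils::head(inverted, 3), collapse = ", ")),
            call. = FALSE)
  res <- label_volume(out, target_voxel_size, target_origin)
  attributes(res)["specimen"] <- attributes(label)["specimen"]
  res
}

#' Sagittal slice plan for morphology comparison
#'
#' Vertical (sagittal) comparison slices at three x-stations distributed
#' through the specimen: station positions are the x-coordinates of the three
#' fiducial marker centroids when markers are present, or 25/50/75% of the
#' specimen width otherwise. Each station carries a registered region mask
#' (the cylinder cross-section chord, when the specimen geometry is known).
#'
#' @param x A [label_volume()] (markers coded 3) or `NULL` when `stations` is
#'   given.
#' @param stations Optional explicit x-stations, mm (length 3).
#' @param min_marker_voxels Marker components smaller than this are treated
#'   as segmentation noise, not markers.
#' @return A `slice_plan` object.
#' @export
slice_plan <- function(x = NULL, stations = NULL, min_marker_voxels = 5L) {
  if (is.null(stations)) {
    if (is.null(x)) stopf("either a marker label volume or explicit stations are required")
    stopifnot(inherits(x, "label_volume"))
    mk <- x$data == LBL[["marker"]]
    if (any(mk)) {
      cc <- .cc_label26(as.vector(mk), as.integer(dim(x$data)))
      ncomp <- attr(cc, "n_components")
      sizes <- tabulate(cc[cc > 0L], nbins = ncomp)
      real <- which(sizes >= min_marker_voxels)
      if (length(real) != 3L)
        stopf("expected exactly 3 markers for the slice plan, found %d", length(real))
      xs <- axis_coords(x, 1)
      idx <- which(mk)
      keep <- cc[idx] %in% real
      stations <- sort(tapply(xs[arrayInd(idx[keep], dim(x$data))[, 1]],
                              cc[idx][keep], mean))
    } else {
      xr <- x$origin[1] + c(0, dim(x$data)[1]) * vox_mm(x$voxel_size)
      stations <- xr[1] + diff(xr) * c(0.25, 0.5, 0.75)
    }
  }
  stations <- as.numeric(stations)
  if (length(stations) != 3L || !all(is.finite(stations)))
    stopf("a slice plan has exactly 3 finite x-stations")
  geo <- if (!is.null(x)) specimen_geometry(x) else NULL
  if (!is.null(x)) {
    xr <- x$origin[1] + c(0, dim(x$data)[1]) * vox_mm(x$voxel_size)
    if (any(stations < xr[1]) || any(stations > xr[2]))
      stopf("slice stations fall outside the volume bounds")
  }
  structure(list(axis = "sagittal", stations = sort(stations), geometry = geo),
            class = "slice_plan")
}

#' @export
print.slice_plan <- function(x, ...) {
  cat(sprintf("<slice_plan> sagittal stations at x = %s mm\n",
              paste(sprintf("%.3f", x$stations), collapse = ", ")))
  invisible(x)
}

#' Extract a sagittal slice
#'
#' Single-pixel-thick slice at the voxel plane nearest to the station.
#'
#' @param label A [label_volume()].
#' @param station x-position, mm.
#' @return Integer matrix (y by z) of label codes.
#' @export
extract_sagittal_slice <- function(label, station) {
  stopifnot(inherits(label, "label_volume"))
  vx <- vox_mm(label$voxel_size)
  i <- round((station - label$origin[1]) / vx + 0.5)
  i <- min(max(i, 1L), dim(label$data)[1])
  label$data[i, , ]
}

# Region mask (y by z logical) of the registered comparison area at a station:
# the chord of the specimen cylinder, full height.
station_region <- function(plan, label, station) {
  d <- dim(label$data)[2:3]
  geo <- plan$geometry %||% specimen_geometry(label)
  if (is.null(geo)) return(matrix(TRUE, d[1], d[2]))
  half <- geo$radius^2 - (station - geo$center[1])^2
  if (half <= 0) return(matrix(FALSE, d[1], d[2]))
  half <- sqrt(half)
  y <- label$origin[2] + (seq_len(d[1]) - 0.5) * vox_mm(label$voxel_size)
  z <- label$origin[3] + (seq_len(d[2]) - 0.5) * vox_mm(label$voxel_size)
  iny <- abs(y - geo$center[2]) <= half
  inz <- z >= geo$z0 & z <= geo$z0 + geo$height
  outer(iny, inz)
}

#' Pixel-wise morphological comparison of two slices
#'
#' Within the registered region, a pixel that is solid (bone or cement) in the
#' model slice but background in the scan slice is a false positive; solid in
#' the scan but background in the model is a false negative. The denominator
#' is the count of solid scan pixels in the region, so errors are fractions of
#' the observed trabecular-and-cement structure. Marker pixels are excluded
#' from all counts. The total error is the sum of the false-positive and
#' false-negative fractions.
#'
#' @param fe_slice Model-predicted label slice (matrix).
#' @param uct_slice Scan-derived label slice (matrix, same grid).
#' @param region Logical region mask (same dimensions).
#' @param station,increment Optional identifiers copied into the record.
#' @return One-row data frame with counts and percentages.
#' @export
compare_slices <- function(fe_slice, uct_slice, region = NULL,
                           station = NA_real_, increment = NA) {
  if (!identical(dim(fe_slice), dim(uct_slice)))
    stopf("slice grids differ: %s vs %s", paste(dim(fe_slice), collapse = "x"),
          paste(dim(uct_slice), collapse = "x"))
  if (is.null(region)) region <- matrix(TRUE, nrow(fe_slice), ncol(fe_slice))
  if (!identical(dim(region), dim(fe_slice)))
    stopf("region mask grid differs from the slice grid")
  use <- region & fe_slice != LBL[["marker"]] & uct_slice != LBL[["marker"]]
  fe_solid <- (fe_slice == LBL[["bone"]] | fe_slice == LBL[["cement"]]) & use
  uct_solid <- (uct_slice == LBL[["bone"]] | uct_slice == LBL[["cement"]]) & use
  fp <- sum(fe_solid & !uct_solid)
  fn <- sum(!fe_solid & uct_solid)
  match_solid <- sum(fe_solid & uct_solid)
  denom <- sum(uct_solid)
  if (denom == 0L)
    stopf("no solid scan pixels in the registered region: denominator undefined")
  data.frame(increment = increment, station = station,
             match_solid = match_solid, false_positive = fp,
             false_negative = fn, denominator = denom,
             fp_pct = 100 * fp / denom, fn_pct = 100 * fn / denom,
             total_pct = 100 * fp / denom + 100 * fn / denom)
}

#' Compare two label volumes over a slice plan
#'
#' Runs [compare_slices()] at each station of the plan.
#'
#' @param fe_labels Model-predicted [label_volume()] at scan resolution.
#' @param uct_labels Scan-derived [label_volume()] on the same grid.
#' @param plan A [slice_plan()].
#' @param increment Identifier copied into the records.
#' @return Data frame with one row per station.
#' @export
morphology_comparison <- function(fe_labels, uct_labels, plan, increment = NA) {
  stopifnot(inherits(plan, "slice_plan"))
  if (!identical(dim(fe_labels$data), dim(uct_labels$data)))
    stopf("label volumes must share a grid for comparison")
  recs <- lapply(plan$stations, function(s) {
    compare_slices(extract_sagittal_slice(fe_labels, s),
                   extract_sagittal_slice(uct_labels, s),
                   station_region(plan, uct_labels, s),
                   station = s, increment = increment)
  })
  do.call(rbind, recs)
}

#' Aggregate morphology comparison records
#'
#' Mean and standard deviation of the false-positive, false-negative and
#' total error percentages per load increment.
#'
#' @param records Data frame of [compare_slices()] rows.
#' @param by Grouping column (default `"increment"`).
#' @return Summary data frame, one row per group.
#' @export
aggregate_morphology <- function(records, by = "increment") {
  if (is.null(records) || nrow(records) == 0L) stopf("no comparison records to aggregate")
  groups <- split(records, records[[by]], drop = TRUE)
  out <- lapply(groups, function(g) {
    data.frame(increment = g[[by]][1], n_slices = nrow(g),
               fp_mean = mean(g$fp_pct), fp_sd = if (nrow(g) > 1) sd(g$fp_pct) else 0,
               fn_mean = mean(g$fn_pct), fn_sd = if (nrow(g) > 1) sd(g$fn_pct) else 0,
               total_mean = mean(g$total_pct),
               total_sd = if (nrow(g) > 1) sd(g$total_pct) else 0)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # the unloaded calibration row leads, load increments follow in order
  key <- suppressWarnings(as.numeric(res$increment))
  res[order(!is.na(key), key), , drop = FALSE]
}

#' Unloaded-state calibration
#'
#' Applies the morphology metric to the unloaded model (rasterized with zero
#' deformation at scan resolution) against the unloaded scan labels,
#' measuring the baseline error attributable to model generation --
#' segmentation, downsampling and voxel remeshing -- before any load.
#'
#' @param fe_labels Undeformed model labels rasterized at scan resolution.
#' @param uct_labels Unloaded scan labels on the same grid.
#' @param plan A [slice_plan()].
#' @return Data frame of per-station records with `increment = "initial"`.
#' @export
calibrate_unloaded <- function(fe_labels, uct_labels, plan) {
  morphology_comparison(fe_labels, uct_labels, plan, increment = "initial")
}

#' Write a red/green/blue comparison overlay PNG
#'
#' Green: model and scan agree on solid; red: false positive; blue: false
#' negative; white: background agreement. Marker pixels and pixels outside
#' the region are dimmed.
#'
#' @param fe_slice,uct_slice,region As in [compare_slices()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(fe_slice, uct_slice, region = NULL, path) {
  if (is.null(region)) region <- matrix(TRUE, nrow(fe_slice), ncol(fe_slice))
  fe_solid <- fe_slice == LBL[["bone"]] | fe_slice == LBL[["cement"]]
  uct_solid <- uct_slice == LBL[["bone"]] | uct_slice == LBL[["cement"]]
  dimg <- dim(fe_slice)
  img <- array(1, dim = c(dimg[2], dimg[1], 3))  # PNG rows = z, cols = y
  set_px <- function(mask, rgb) {
    m <- t(mask)
    for (c_i in 1:3) {
      ch <- img[, , c_i]
      ch[m] <- rgb[c_i]
      img[, , c_i] <<- ch
    }
  }
  set_px(fe_solid & uct_solid, c(0, 0.8, 0))
  set_px(fe_solid & !uct_solid, c(0.9, 0, 0))
  set_px(!fe_solid & uct_solid, c(0, 0, 0.9))
  set_px(!region, c(0.85, 0.85, 0.85))
  set_px(fe_slice == LBL[["marker"]] | uct_slice == LBL[["marker"]], c(0.6, 0.6, 0.6))
  png::writePNG(img[rev(seq_len(dimg[2])), , , drop = FALSE], path)
  invisible(path)
}
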