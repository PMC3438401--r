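#' Parameters of the synthetic open-cell foam specimen
#'
#' Defaults reproduce the physical specimens the method was developed on:
#' cylindrical open-cell rigid polyurethane foam cores of ~6 mm diameter and
#' ~12 mm height with porosity over 95%, cell size 1.5-2.5 mm and strut
#' thickness 0.15-0.3 mm, cement end-caps 2-4 mm deep, imaged at 25 um
#' isotropic voxels.
#'
#' @param cylinder_diameter Specimen diameter, mm.
#' @param cylinder_height Specimen height, mm (z is the loading axis).
#' @param cell_size_range Low/high of the foam cell size, mm.
#' @param strut_thickness_range Low/high of the strut thickness (diameter), mm.
#' @param cement_cap_depth_range Low/high of the admissible cement cap depth, mm.
#' @param voxel_size Isotropic voxel size of the emulated scan, micrometres.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return A validated `foam_params` list.
#' @export
foam_params <- function(cylinder_diameter = 6,
                        cylinder_height = 12,
                        cell_size_range = c(1.5, 2.5),
                        strut_thickness_range = c(0.15, 0.3),
                        cement_cap_depth_range = c(2, 4),
                        voxel_size = 25,
                        seed = 42L) {
  p <- list(cylinder_diameter = cylinder_diameter,
            cylinder_height = cylinder_height,
            cell_size_range = as.numeric(cell_size_range),
            strut_thickness_range = as.numeric(strut_thickness_range),
            cement_cap_depth_range = as.numeric(cement_cap_depth_range),
            voxel_size = voxel_size,
            seed = as.integer(seed))
  lens <- c(p$cylinder_diameter, p$cylinder_height, p$voxel_size,
            p$cell_size_range, p$strut_thickness_range)
  if (!all(is.finite(lens)) || any(lens <= 0))
    stopf("all lengths must be positive and finite")
  for (nm in c("cell_size_range", "strut_thickness_range", "cement_cap_depth_range")) {
    r <- p[[nm]]
    if (length(r) != 2L || r[1] > r[2] || any(r < 0))
      stopf("%s must be an ordered non-negative (low, high) pair", nm)
  }
  if (p$cylinder_diameter / vox_mm(p$voxel_size) < 16)
    stopf("voxel_size too coarse: fewer than 16 voxels across the cylinder diameter")
  class(p) <- "foam_params"
  p
}

#' Micro-CT imaging emulator parameters
#'
#' Class mean intensities, per-class Gaussian noise, and the scanner
#' point-spread function. Defaults give deliberately overlapping bone and
#' cement grayscale distributions, as observed for polyurethane foam and PMMA
#' cement scanned together.
#'
#' @param class_mean_gray Named mean intensity per label
#'   (background/bone/cement/marker); must satisfy
#'   background < bone < cement.
#' @param class_sd_gray Named per-class noise standard deviation (>= 0).
#' @param psf_sigma Gaussian point-spread sigma, micrometres (>= 0).
#' @param seed Integer seed for the noise field.
#' @return A validated `imaging_params` list.
#' @export
imaging_params <- function(class_mean_gray = c(background = 25, bone = 105,
                                               cement = 155, marker = 230),
                           class_sd_gray = c(background = 6, bone = 8,
                                             cement = 8, marker = 5),
                           psf_sigma = 15,
                           seed = 1L) {
  need <- c("background", "bone", "cement", "marker")
  if (!all(need %in% names(class_mean_gray)) || !all(need %in% names(class_sd_gray)))
    stopf("class maps must name background, bone, cement and marker")
  m <- class_mean_gray[need]
  if (!(m[["background"]] < m[["bone"]] && m[["bone"]] < m[["cement"]]))
    stopf("class means must satisfy background < bone < cement")
  if (any(class_sd_gray < 0)) stopf("class sds must be >= 0")
  if (psf_sigma < 0) stopf("psf_sigma must be >= 0")
  structure(list(class_mean_gray = m, class_sd_gray = class_sd_gray[need],
                 psf_sigma = psf_sigma, seed = as.integer(seed)),
            class = "imaging_params")
}

#' Generate a synthetic open-cell foam specimen
#'
#' Builds a cylindrical open-cell strut network as the edge skeleton of a
#' Poisson-Voronoi tessellation: seed points with mean spacing drawn from
#' `cell_size_range` are scattered in and around the cylinder, the loci where
#' three or more Voronoi cells meet form the strut centrelines, and each strut
#' is dilated to its own thickness drawn from `strut_thickness_range`. Strut
#' thickness sampling is pre-narrowed from a trial stamping so the expected
#' solid fraction is below 5%, then a global bisection shrink enforces the
#' porosity bound exactly; the shrink is refused if it would push struts below
#' one voxel.
#'
#' @param params A [foam_params()] object.
#' @return A [label_volume()] with codes 0/1 whose solid phase is a single
#'   26-connected component touching both end planes and occupying < 5% of
#'   the cylinder interior. Specimen geometry and the strut centreline are
#'   attached as attributes.
#' @export
generate_foam_lattice <- function(params) {
  stopifnot(inherits(params, "foam_params"))
  d <- params$cylinder_diameter
  H <- params$cylinder_height
  vx <- vox_mm(params$voxel_size)
  nx <- max(2L, round(d / vx))
  nz <- max(2L, round(H / vx))
  dims <- c(nx, nx, nz)
  origin <- c(0, 0, 0)
  cx <- d / 2
  R <- d / 2
  target_solid <- 0.046  # aim below the 5% bound with margin for stamping noise

  with_seed(params$seed, {
    spacing <- runif(1, params$cell_size_range[1], params$cell_size_range[2])
    margin <- spacing
    box_lo <- c(-margin, -margin, -margin)
    box_hi <- c(d + margin, d + margin, H + margin)
    vol_box <- prod(box_hi - box_lo)
    lambda <- 1 / spacing^3
    nseed <- max(12L, rpois(1, lambda * vol_box))
    seeds <- cbind(runif(nseed, box_lo[1], box_hi[1]),
                   runif(nseed, box_lo[2], box_hi[2]),
                   runif(nseed, box_lo[3], box_hi[3]))

    # Voronoi labelling at scan resolution, padded so edges cross the
    # cylinder boundary and both end planes
    cvox <- vx
    pad <- 6 * cvox
    corigin <- c(-pad, -pad, -pad)
    cdims <- as.integer(ceiling((c(d, d, H) + 2 * pad) / cvox))
    clab <- voronoi_labels(seeds, cdims, cvox, corigin)
    ep <- .voronoi_edge_points(clab, cdims, cvox, corigin)
    if (nrow(ep$points) < 10L)
      stopf("degenerate foam lattice: too few strut centreline points")

    # keep centreline points near the cylinder
    r_hi_max <- params$strut_thickness_range[2] / 2 + cvox
    pr <- sqrt((ep$points[, 1] - cx)^2 + (ep$points[, 2] - cx)^2)
    keep <- pr <= R + r_hi_max & ep$points[, 3] >= -r_hi_max &
      ep$points[, 3] <= H + r_hi_max
    pts <- ep$points[keep, , drop = FALSE]
    sid <- ep$strut_id[keep]
    vert <- ep$vertex[keep]

    t_lo <- params$strut_thickness_range[1]
    t_hi <- params$strut_thickness_range[2]

    # the discrete centreline is a ~1-voxel tube, so stamped struts come out
    # about half a voxel thicker than the nominal radius; compensate
    stamp_radius <- function(r) pmax(r - vx / 2, vx / 2)

    # trial stamping at the thinnest struts to calibrate the sampling range
    cylmask <- cylinder_mask(dims, vx, origin, cx, cx, R)
    ncyl <- sum(cylmask)
    q_trial <- .stamp_struts(pts, stamp_radius(rep(t_lo / 2, nrow(pts))),
                             dims, vx, origin)
    f_lo <- sum(q_trial <= 1 & cylmask) / ncyl
    if (f_lo <= 0) stopf("degenerate foam lattice: no struts inside the cylinder")
    Et2 <- target_solid / f_lo * t_lo^2     # admissible mean squared thickness
    disc <- 12 * Et2 - 3 * t_lo^2
    b <- if (disc <= 0) t_lo else (-t_lo + sqrt(disc)) / 2
    b <- min(max(b, t_lo), t_hi)

    # one thickness per strut (keyed by the Voronoi cell triple)
    uid <- sort(unique(sid))
    t_of_uid <- runif(length(uid), t_lo, b)
    radii <- t_of_uid[match(sid, uid)] / 2

    q <- .stamp_struts(pts, stamp_radius(radii), dims, vx, origin)
    # global shrink factor: porosity(s) = 1 - #{q <= s}/ncyl is monotone in s,
    # so the minimal shrink achieving the target is an order statistic of the
    # stamped ratios inside the cylinder
    qf <- q[cylmask]
    qf <- qf[is.finite(qf)]
    s <- 1
    if (length(qf) / ncyl > 0.05) {
      k <- floor(0.048 * ncyl)
      if (k < 1) stopf("porosity >= 95%% unreachable: cylinder too small")
      s <- sort(qf, partial = k)[k]
      # lattice quantization ties many ratios; step below the tie block if it
      # overshoots the bound
      while (sum(qf <= s) > 0.05 * ncyl) {
        below <- qf[qf < s]
        if (!length(below))
          stopf("porosity >= 95%% unreachable after strut-thickness adjustment")
        s <- max(below)
      }
      if (s * t_lo / 2 < vx)
        stopf(paste0("porosity >= 95%% unreachable: shrinking strut radii to ",
                     sprintf("%.4f", s * t_lo / 2),
                     " mm would fall below one voxel (", vx, " mm)"))
      if (1 - sum(qf <= s) / ncyl < 0.95)
        stopf("porosity >= 95%% unreachable after strut-thickness adjustment")
    }

    solid <- array(q <= s, dim = dims) & cylmask
    lab <- .cc_label26(as.vector(solid), as.integer(dims))
    ncomp <- attr(lab, "n_components")
    if (ncomp == 0L) stopf("degenerate foam lattice: empty solid phase")
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    main <- which.max(sizes)
    arr <- array(as.integer(lab == main), dim = dims)
    if (!any(arr[, , 1] > 0L) || !any(arr[, , nz] > 0L))
      stopf("strut network does not span both end planes; retry with another seed")

    out <- label_volume(arr, params$voxel_size, origin)
    specimen_geometry(out) <- list(center = c(cx, cx), radius = R, height = H,
                                   z0 = 0)
    attr(out, "foam_params") <- params
    attr(out, "struts") <- list(points = pts, radii = radii * s, vertex = vert,
                                shrink = s, spacing = spacing)
    out
  })
}

# Nearest-seed (Voronoi) labelling of a voxel grid via the feature transform
# of the seed set (exact to the voxel-centre snapping of the seeds).
voronoi_labels <- function(seeds, dims, vox, origin) {
  idx <- sweep(seeds, 2, origin, `-`) / vox + 0.5
  idx <- pmin(pmax(round(idx), 1), matrix(rep(dims, each = nrow(seeds)), ncol = 3))
  lin <- idx[, 1] + dims[1] * ((idx[, 2] - 1) + dims[2] * (idx[, 3] - 1))
  seed_at <- integer(prod(dims))
  seed_at[lin] <- seq_len(nrow(seeds))   # later seed wins a shared voxel
  mask <- seed_at > 0L
  ft <- .edt3d(mask, as.integer(dims), TRUE)$feature
  array(seed_at[ft], dim = dims)
}

cylinder_mask <- function(dims, vx, origin, cx, cy, R) {
  x <- origin[1] + (seq_len(dims[1]) - 0.5) * vx
  y <- origin[2] + (seq_len(dims[2]) - 0.5) * vx
  inxy <- outer((x - cx)^2, (y - cy)^2, `+`) <= R^2
  array(rep(inxy, dims[3]), dim = dims)
}

#' Fill the specimen ends with cement
#'
#' Emulates embedding both specimen ends in PMMA cement: every non-bone voxel
#' of the cylinder cross-section within the cap depth of an end plane becomes
#' cement, while foam struts inside the cap are retained as bone, producing
#' the interdigitated composite region.
#'
#' @param label A foam [label_volume()].
#' @param depth_top,depth_bottom Cap depths, mm. Zero disables a cap;
#'   non-zero depths must lie in the specimen's admissible cap depth range.
#' @param seed Unused placeholder kept for interface stability (cap filling
#'   is deterministic).
#' @return The augmented [label_volume()].
#' @export
add_cement_caps <- function(label, depth_top, depth_bottom, seed = 0L) {
  stopifnot(inherits(label, "label_volume"))
  fp <- attr(label, "foam_params")
  if (!is.null(fp)) {
    rng <- fp$cement_cap_depth_range
    for (dpt in c(depth_top, depth_bottom))
      if (dpt != 0 && (dpt < rng[1] || dpt > rng[2]))
        stopf("cap depth %g mm outside the admissible range [%g, %g] mm",
              dpt, rng[1], rng[2])
  }
  dims <- dim(label$data)
  vx <- vox_mm(label$voxel_size)
  height <- dims[3] * vx
  if (depth_top + depth_bottom >= height)
    stopf("cement caps overlap: depth_top + depth_bottom >= specimen height")
  geo <- specimen_geometry(label)
  mask <- if (!is.null(geo))
    cylinder_mask(dims, vx, label$origin, geo$center[1], geo$center[2], geo$radius)
  else array(TRUE, dim = dims)
  z <- label$origin[3] + (seq_len(dims[3]) - 0.5) * vx
  z0 <- label$origin[3]
  capz <- (z - z0) < depth_bottom | (z0 + height - z) < depth_top
  cap <- mask & array(rep(capz, each = dims[1] * dims[2]), dim = dims)
  arr <- label$data
  fill <- cap & arr == LBL[["background"]]
  arr[fill] <- LBL[["cement"]]
  out <- label_volume(arr, label$voxel_size, label$origin)
  attributes(out)[c("specimen", "foam_params", "struts")] <-
    attributes(label)[c("specimen", "foam_params", "struts")]
  attr(out, "cap_depths") <- c(bottom = depth_bottom, top = depth_top)
  out
}

#' Embed fiducial markers
#'
#' Writes small spherical marker blobs (code 3) at the given world positions,
#' emulating the manual paint markers added to scans to define registration
#' areas. Markers overwrite whatever label is present (they are painted on the
#' image) but may not overlap one another.
#'
#' @param label A [label_volume()].
#' @param positions Matrix (n x 3) of marker centres, mm; may have zero rows.
#' @param radius_voxels Marker sphere radius in voxels (default 3).
#' @return The [label_volume()] with markers embedded.
#' @export
embed_markers <- function(label, positions, radius_voxels = 3L) {
  stopifnot(inherits(label, "label_volume"))
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (nrow(positions) == 0L) return(label)
  dims <- dim(label$data)
  vx <- vox_mm(label$voxel_size)
  lo <- label$origin
  hi <- label$origin + dims * vx
  arr <- label$data
  r <- radius_voxels
  offs <- expand.grid(di = -r:r, dj = -r:r, dk = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 + offs$dk^2 <= r^2, ]
  for (m in seq_len(nrow(positions))) {
    p <- positions[m, ]
    if (any(p < lo) || any(p > hi))
      stopf("marker %d at (%g, %g, %g) mm lies outside the volume", m, p[1], p[2], p[3])
    ci <- pmin(pmax(floor((p - lo) / vx) + 1, 1), dims)
    ii <- pmin(pmax(ci[1] + offs$di, 1), dims[1])
    jj <- pmin(pmax(ci[2] + offs$dj, 1), dims[2])
    kk <- pmin(pmax(ci[3] + offs$dk, 1), dims[3])
    idx <- unique(cbind(ii, jj, kk))
    if (any(arr[idx] == LBL[["marker"]]))
      stopf("marker %d overlaps a previously placed marker", m)
    arr[idx] <- LBL[["marker"]]
  }
  out <- label_volume(arr, label$voxel_size, label$origin)
  attributes(out)[c("specimen", "foam_params", "struts", "cap_depths")] <-
    attributes(label)[c("specimen", "foam_params", "struts", "cap_depths")]
  attr(out, "marker_positions") <- positions
  out
}

#' Emulate a micro-CT scan of a labelled specimen
#'
#' Maps each voxel to its class mean intensity, convolves with an isotropic
#' Gaussian point-spread function, and adds independent Gaussian noise with
#' the class standard deviation of the underlying (pre-blur) label.
#' Deterministic under a fixed seed.
#'
#' @param label A [label_volume()].
#' @param imaging An [imaging_params()] object.
#' @return A [grayscale_volume()] on the same grid.
#' @export
emulate_uct <- function(label, imaging) {
  stopifnot(inherits(label, "label_volume"), inherits(imaging, "imaging_params"))
  dims <- dim(label$data)
  means <- imaging$class_mean_gray
  sds <- imaging$class_sd_gray
  img <- array(means[label$data + 1L], dim = dims)
  sig_vox <- imaging$psf_sigma / label$voxel_size
  if (sig_vox > 0) {
    kr <- max(1L, ceiling(3 * sig_vox))
    kern <- exp(-((-kr:kr)^2) / (2 * sig_vox^2))
    kern <- kern / sum(kern)
    img <- array(.blur_separable(as.vector(img), as.integer(dims), kern), dim = dims)
  }
  if (any(sds > 0)) {
    sdmap <- sds[label$data + 1L]
    noise <- with_seed(imaging$seed, rnorm(length(img)))
    img <- img + array(noise * sdmap, dim = dims)
  }
  out <- grayscale_volume(img, label$voxel_size, label$origin)
  attributes(out)[c("specimen", "marker_positions")] <-
    attributes(label)[c("specimen", "marker_positions")]
  out
}

#' Synthesize a loaded-state scan from a displacement field
#'
#' Carries the label volume through a nodal displacement field (delegating to
#' [warp_labels()]) and images the result with [emulate_uct()], producing the
#' closed-loop "experimental" scan of the specimen in a loaded state. The
#' field must be defined on the label grid's nodes.
#'
#' @param label A [label_volume()].
#' @param displacement_field List with arrays `ux`, `uy`, `uz` (mm) of
#'   dimension `dim(label) + 1` (the node grid).
#' @param imaging An [imaging_params()] object.
#' @return A [grayscale_volume()] of the deformed specimen on the same grid.
#' @export
synthesize_loaded_scan <- function(label, displacement_field, imaging) {
  warped <- warp_labels(label, displacement_field,
                        target_voxel_size = label$voxel_size,
                        target_dim = dim(label$data),
                        target_origin = label$origin)
  emulate_uct(warped, imaging)
}
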