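two_material_label <- function() {
  arr <- array(0L, dim = c(20, 20, 40))
  arr[5:15, 5:15, 3:20] <- 1L
  arr[8:12, 8:12, 21:38] <- 2L
  label_volume(arr, 50)
}

test_that("warping with trivial fields is exact", {
  lab <- two_material_label()
  # zero displacement at equal resolution: identity
  w0 <- warp_labels(lab, zero_field(lab), 50, dim(lab$data), lab$origin)
  expect_identical(w0$data, lab$data)

  # uniform translation by two target voxels: exact shifted copy
  wt <- warp_labels(lab, translation_field(lab, c(0.1, 0, 0)), 50,
                    dim(lab$data), lab$origin)
  ref <- array(0L, dim(lab$data)); ref[3:20, , ] <- lab$data[1:18, , ]
  expect_identical(wt$data, ref)

  # rasterizing to the finer scan grid doubles every solid voxel in each axis
  wf <- warp_labels(lab, zero_field(lab), 25, dim(lab$data) * 2L, lab$origin)
  expect_identical(wf$data[seq(1, 39, 2), seq(1, 39, 2), seq(1, 79, 2)], lab$data)
  expect_identical(sum(wf$data > 0L), 8L * sum(lab$data > 0L))

  # markers ride along
  labm <- embed_markers(lab, matrix(c(0.2, 0.2, 1.8), 1), radius_voxels = 2L)
  wm <- warp_labels(labm, zero_field(labm), 50, dim(labm$data), labm$origin)
  expect_identical(wm$data, labm$data)
})

test_that("uniform axial strain shrinks the solid extent accordingly", {
  lab <- two_material_label()
  ws <- warp_labels(lab, axial_strain_field(lab, 0.10), 50, dim(lab$data), lab$origin)
  zext <- function(a) diff(range(which(apply(a > 0L, 3, any)))) + 1L
  e0 <- zext(lab$data)
  expect_lte(abs(zext(ws$data) - 0.9 * e0), 1 + 1e-9)  # within one voxel
  # solid volume approximately conserved laterally (no lateral strain)
  expect_lt(abs(sum(ws$data > 0L) / sum(lab$data > 0L) - 0.9), 0.03)
})

test_that("excessively distorted elements are flagged as inverted", {
  lab <- label_volume(array(1L, dim = c(2, 2, 2)), 100)
  f <- zero_field(lab)
  f$uz[, , 2] <- -0.35  # middle node layer pushed through the bottom
  expect_warning(warp_labels(lab, f, 100, dim(lab$data), lab$origin), "inverted")
})

test_that("slice plans come from markers, defaults, and explicit stations", {
  lab <- two_material_label()
  pos <- cbind(c(0.3, 0.5, 0.7), c(0.2, 0.8, 0.5), c(1, 1, 1))
  labm <- embed_markers(lab, pos, radius_voxels = 2L)
  plan <- slice_plan(labm)
  expect_equal(plan$stations, sort(pos[, 1]), tolerance = 0.051)

  # whole-voxel translation of the volume shifts the stations by the same amount
  sh <- 3 * 50 / 1000
  wt <- warp_labels(labm, translation_field(labm, c(sh, 0, 0)), 50,
                    dim(labm$data), labm$origin)
  plan_t <- slice_plan(wt)
  expect_equal(plan_t$stations, plan$stations + sh, tolerance = 1e-9)

  # no markers: fractional 25/50/75% defaults across the width
  plan0 <- slice_plan(lab)
  expect_equal(plan0$stations, c(0.25, 0.5, 0.75) * 1)
  # explicit stations win; wrong marker counts fail
  expect_equal(slice_plan(stations = c(0.2, 0.5, 0.8))$stations, c(0.2, 0.5, 0.8))
  bad <- embed_markers(lab, pos[1:2, ], radius_voxels = 2L)
  expect_error(slice_plan(bad), "exactly 3 markers")
  expect_error(slice_plan(stations = c(0.2, 0.5)), "exactly 3")
})

test_that("slice comparison identities and the brute-force pixel oracle agree", {
  # identical slices: zero error
  set.seed(41)
  s <- matrix(sample(0:2, 400, TRUE), 20, 20)
  r0 <- compare_slices(s, s)
  expect_identical(r0$false_positive + r0$false_negative, 0L)
  expect_identical(r0$total_pct, 0)

  # swapping the inputs swaps FP and FN exactly
  s2 <- matrix(sample(0:2, 400, TRUE), 20, 20)
  a <- compare_slices(s, s2)
  b <- compare_slices(s2, s)
  expect_identical(a$false_positive, b$false_negative)
  expect_identical(a$false_negative, b$false_positive)

  # total = FP + FN, and percentages are 100 * count / denominator
  expect_equal(a$total_pct, a$fp_pct + a$fn_pct)
  expect_equal(a$fp_pct, 100 * a$false_positive / a$denominator)

  # random 100x100 slices with markers and a region mask vs the naive oracle
  for (trial in 1:5) {
    set.seed(trial + 100)
    fe <- matrix(sample(0:3, 1e4, TRUE, prob = c(0.55, 0.2, 0.2, 0.05)), 100, 100)
    uct <- matrix(sample(0:3, 1e4, TRUE, prob = c(0.5, 0.25, 0.2, 0.05)), 100, 100)
    region <- matrix(runif(1e4) < 0.8, 100, 100)
    got <- compare_slices(fe, uct, region)
    want <- compare_slices_oracle(fe, uct, region)
    expect_identical(got$false_positive, want$fp)
    expect_identical(got$false_negative, want$fn)
    expect_identical(got$match_solid, want$match_solid)
    expect_identical(got$denominator, want$denom)
    expect_equal(got$total_pct, want$total_pct)
  }

  # the crafted counting example: region 100 px, scan solid 60, model solid 70,
  # overlap 55 -> FP 15, FN 5, denominator 60, total 33.33%
  fe <- matrix(0L, 10, 10); uct <- matrix(0L, 10, 10)
  set.seed(7)
  fe[sample(100, 70)] <- 1L
  uct[sample(which(fe == 1L), 55)] <- 1L
  uct[sample(which(fe == 0L), 5)] <- 1L
  r <- compare_slices(fe, uct)
  expect_identical(r$false_positive, 15L)
  expect_identical(r$false_negative, 5L)
  expect_identical(r$denominator, 60L)
  expect_equal(r$total_pct, 100 * 20 / 60, tolerance = 1e-12)

  expect_error(compare_slices(matrix(0L, 3, 3), matrix(0L, 4, 4)), "grids differ")
})

test_that("aggregation reproduces the mean/SD bookkeeping", {
  recs <- rbind(
    data.frame(increment = "initial", station = 1, match_solid = 1,
               false_positive = 1, false_negative = 1, denominator = 100,
               fp_pct = 2.25, fn_pct = 1.57, total_pct = 3.82),
    data.frame(increment = "initial", station = 2, match_solid = 1,
               false_positive = 1, false_negative = 1, denominator = 100,
               fp_pct = 2.25, fn_pct = 1.57, total_pct = 3.82))
  agg <- aggregate_morphology(recs)
  # mean FP 2.25% and mean FN 1.57% give mean total error 3.82%
  expect_equal(agg$fp_mean, 2.25)
  expect_equal(agg$fn_mean, 1.57)
  expect_equal(agg$total_mean, 3.82)
  expect_equal(agg$total_sd, 0)

  rec3 <- data.frame(increment = 3, station = 1, match_solid = 1,
                     false_positive = 1, false_negative = 1, denominator = 100,
                     fp_pct = 9.92, fn_pct = 7.95, total_pct = 17.87)
  agg3 <- aggregate_morphology(rec3)
  expect_equal(agg3$total_mean, agg3$fp_mean + agg3$fn_mean)
  expect_equal(agg3$total_mean, 17.87)

  # single record: mean equals the record, SD zero
  expect_equal(aggregate_morphology(rec3)$fp_sd, 0)
  expect_error(aggregate_morphology(rec3[0, ]), "no comparison records")
})

test_that("closed-loop calibration on noiseless fixtures is nearly exact", {
  # model slices rasterized from the segmentation of the same (noise-free)
  # scan of a geometric phantom: the residual is pure resampling error.
  # (Foam-like fixtures carry an intrinsic ~2.5-3% strut-boundary staircase
  # at 25 -> 50 um; the phantom isolates the resampling path itself.)
  vx <- 0.025
  d <- as.integer(c(120, 120, 240))
  x <- (seq_len(d[1]) - 0.5) * vx
  z <- (seq_len(d[3]) - 0.5) * vx
  arr <- array(0L, d)
  rxy <- sqrt(outer((x - 1.5)^2, (x - 1.5)^2, `+`))
  core <- array(rep(rxy <= 1.05, d[3]), d) &
    array(rep(z > 0.4 & z < 5.6, each = d[1] * d[2]), d)
  arr[core] <- 1L
  tt <- seq(0, 1, length.out = 300)            # oblique rod
  pts <- cbind(0.7 + 1.6 * tt, 0.7 + 1.6 * tt, 1.2 + 3.6 * tt)
  q <- trabevalid:::.stamp_struts(pts, rep(0.2, nrow(pts)), d, vx, c(0, 0, 0))
  arr[array(q <= 1, d)] <- 1L
  spec_cyl <- array(rep(rxy <= 1.4, d[3]), d)  # cement caps
  capz <- array(rep(z < 1 | z > 5, each = d[1] * d[2]), d)
  arr[spec_cyl & capz & arr == 0L] <- 2L
  lab <- label_volume(arr, 25)

  im0 <- imaging_params(class_sd_gray = c(background = 0, bone = 0, cement = 0,
                                          marker = 0), psf_sigma = 0)
  scan <- emulate_uct(lab, im0)
  m <- im0$class_mean_gray
  thr <- segmentation_thresholds((m[["background"]] + m[["bone"]]) / 2,
                                 (m[["bone"]] + m[["cement"]]) / 2)
  seg25 <- segment(scan, thr)
  seg50 <- segment(downsample_mean(scan, 2), thr)
  mesh <- build_mesh(seg50)
  ml <- trabevalid:::mesh_label_volume(mesh)
  fe0 <- warp_labels(ml, zero_field(ml), 25, dim(scan$data), scan$origin)
  plan <- slice_plan(stations = c(0.9, 1.5, 2.1))
  plan$geometry <- list(center = c(1.5, 1.5), radius = 1.4, height = 6, z0 = 0)
  cal <- calibrate_unloaded(fe0, seg25, plan)
  expect_true(all(cal$increment == "initial"))
  expect_lt(mean(cal$total_pct), 2)

  # identical inputs give exactly zero
  cal0 <- calibrate_unloaded(seg25, seg25, plan)
  expect_true(all(cal0$total_pct == 0))
})

test_that("overlay PNGs are written with the slice geometry", {
  fe <- matrix(sample(0:2, 100, TRUE), 10, 10)
  uct <- matrix(sample(0:2, 100, TRUE), 10, 10)
  path <- tempfile(fileext = ".png")
  write_overlay_png(fe, uct, path = path)
  img <- png::readPNG(path)
  expect_identical(dim(img), c(10L, 10L, 3L))
})
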