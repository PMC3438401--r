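#' Pipeline configuration
#'
#' All parameters of an end-to-end closed-loop run: specimen generation,
#' imaging, segmentation, boundary conditions, solver, validation. Defaults
#' follow the study conditions -- materials E = 280/2280 MPa with nu = 0.3,
#' scans at 25 um downsampled by 2 to 50 um model resolution, and three
#' compression increments at ~3, ~5 and ~15% nominal strain -- on a
#' desk-scale specimen (4 mm diameter x 8 mm height with 1.33 mm cement
#' caps).
#'
#' @param specimen [foam_params()] of the specimen to generate.
#' @param cap_depth Cement cap depth at each end, mm.
#' @param imaging [imaging_params()] for the scan emulator.
#' @param thresholds `"auto"` or a [segmentation_thresholds()] object.
#' @param marker_threshold Intensity above which scan voxels are treated as
#'   fiducial markers.
#' @param increments Nominal compressive strains of the load increments.
#' @param materials Named list of [material()]s (`bone`, `cement`).
#' @param interface [interface_model()] for the cement-bone interface.
#' @param solver [solver_options()].
#' @param downsample_factor Scan-to-model downsampling factor.
#' @param min_component_voxels Connectivity-filter threshold at model
#'   resolution (scaled by `factor^3` at scan resolution).
#' @param landmarks_per_end Landmark points generated per specimen end.
#' @param landmark_noise Landmark picking noise (standard deviation), mm.
#' @param seed Master seed; all stage seeds derive from it.
#' @param output_dir Optional directory for artifacts (scans, labels,
#'   boundary conditions, results, overlays, manifest).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(specimen = foam_params(cylinder_diameter = 4,
                                                   cylinder_height = 8,
                                                   cement_cap_depth_range = c(1, 2),
                                                   seed = 42L),
                            cap_depth = 4 / 3,
                            imaging = imaging_params(),
                            thresholds = "auto",
                            marker_threshold = 190,
                            increments = c(0.03, 0.05, 0.15),
                            materials = default_materials(),
                            interface = interface_model("tied"),
                            solver = solver_options(tolerance = 1e-6),
                            downsample_factor = 2L,
                            min_component_voxels = 8L,
                            landmarks_per_end = 8L,
                            landmark_noise = 0.0125,
                            seed = 1L,
                            output_dir = NULL) {
  stopifnot(inherits(specimen, "foam_params"), inherits(imaging, "imaging_params"),
            inherits(interface, "interface_model"), inherits(solver, "solver_options"))
  if (!identical(thresholds, "auto") && !inherits(thresholds, "segmentation_thresholds"))
    stopf("thresholds must be \"auto\" or a segmentation_thresholds object")
  if (any(increments < 0) || any(!is.finite(increments)))
    stopf("increments must be finite non-negative nominal strains")
  structure(list(specimen = specimen, cap_depth = cap_depth, imaging = imaging,
                 thresholds = thresholds, marker_threshold = marker_threshold,
                 increments = increments, materials = materials,
                 interface = interface, solver = solver,
                 downsample_factor = as.integer(downsample_factor),
                 min_component_voxels = as.integer(min_component_voxels),
                 landmarks_per_end = as.integer(landmarks_per_end),
                 landmark_noise = landmark_noise,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

# Default marker positions: three markers spread across the width (x), off
# the specimen axis (y), at mid-height -- recoverable sagittal stations.
default_marker_positions <- function(params) {
  d <- params$cylinder_diameter
  H <- params$cylinder_height
  cbind(x = d * c(0.3, 0.5, 0.7),
        y = d / 2 + d * 0.38 * c(1, -1, 1),
        z = H * c(0.5, 0.5, 0.5))
}

# Stage 1 of the pipeline: generate the specimen and its unloaded scan,
# segment at both resolutions, build the mesh and the slice plan, and measure
# the unloaded calibration error. Shared by run_pipeline(),
# compare_interfaces() and the acceptance checks.
prepare_specimen <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sp <- config$specimen
  sp$seed <- derive_seed(config$seed, "foam")
  foam <- generate_foam_lattice(sp)
  capped <- add_cement_caps(foam, config$cap_depth, config$cap_depth)
  labels_gt <- embed_markers(capped, default_marker_positions(sp))
  img <- config$imaging
  img$seed <- derive_seed(config$seed, "scan0")
  scan0 <- emulate_uct(labels_gt, img)
  ds <- downsample_mean(scan0, config$downsample_factor)
  thr <- if (identical(config$thresholds, "auto")) auto_thresholds(ds) else config$thresholds
  seg50 <- segment(ds, thr, marker_mask = ds$data >= config$marker_threshold)
  f50 <- connectivity_filter(seg50, config$min_component_voxels)
  seg25 <- segment(scan0, thr, marker_mask = scan0$data >= config$marker_threshold)
  f25 <- connectivity_filter(seg25,
                             config$min_component_voxels * config$downsample_factor^3)
  plan <- slice_plan(f25$label)
  mesh <- build_mesh(f50$label, config$materials)
  # undeformed model rasterized back at scan resolution: calibration baseline
  mesh_labels <- mesh_label_volume(mesh)
  fe0 <- warp_labels(mesh_labels, zero_field(mesh_labels),
                     target_voxel_size = scan0$voxel_size,
                     target_dim = dim(scan0$data), target_origin = scan0$origin)
  calibration <- calibrate_unloaded(fe0, f25$label, plan)
  list(config = config, foam = foam, labels_gt = labels_gt, scan0 = scan0,
       thresholds = thr, seg50 = f50$label, seg50_report = f50$report,
       seg25 = f25$label, seg25_report = f25$report, plan = plan, mesh = mesh,
       mesh_labels = mesh_labels, fe0 = fe0, calibration = calibration)
}

# label volume of the meshed voxels (bone/cement on the model grid)
mesh_label_volume <- function(mesh) {
  arr <- array(0L, dim = mesh$dims)
  arr[mesh$vox + 1L] <- mesh$mat
  out <- label_volume(arr, mesh$voxel_size, mesh$origin)
  specimen_geometry(out) <- mesh$specimen
  out
}

# Emulated landmark measurement: points picked on both end faces in the
# unloaded scan, re-picked after loading; picking noise emulates the manual
# point selection on 25-um images.
measure_boundary_conditions <- function(config, height, increment, strain) {
  sp <- config$specimen
  n <- config$landmarks_per_end
  with_seed(derive_seed(config$seed, paste0("landmarks", increment)), {
    mk_points <- function(zval) {
      r <- sqrt(runif(n)) * sp$cylinder_diameter * 0.45
      th <- runif(n, 0, 2 * pi)
      cbind(sp$cylinder_diameter / 2 + r * cos(th),
            sp$cylinder_diameter / 2 + r * sin(th),
            rep(zval, n))
    }
    ref_top <- mk_points(height)
    ref_bot <- mk_points(0)
    u_top_true <- c(0, 0, -strain * height / 2)
    u_bot_true <- c(0, 0, +strain * height / 2)
    noise <- function() matrix(rnorm(3 * n, 0, config$landmark_noise), n, 3)
    top_ref <- landmark_set("top", ref_top, "unloaded")
    bot_ref <- landmark_set("bottom", ref_bot, "unloaded")
    top_load <- landmark_set("top", sweep(ref_top, 2, u_top_true, `+`) + noise(), increment)
    bot_load <- landmark_set("bottom", sweep(ref_bot, 2, u_bot_true, `+`) + noise(), increment)
    u_top <- compute_end_displacements(top_ref, top_load)
    u_bot <- compute_end_displacements(bot_ref, bot_load)
    # the estimator averages picking noise; the axial components still carry
    # it, so enforce the compressive sign convention seen in the images
    build_boundary_conditions(u_top, u_bot, increment, height)
  })
}

#' Run the closed-loop validation pipeline
#'
#' Generates a cement-augmented specimen and its unloaded scan, segments it,
#' builds and solves the micro-FE model, synthesizes loaded-state
#' "experimental" scans from the solved displacement field (optionally plus a
#' perturbation emulating inelastic collapse), and measures the deformed
#' morphology error at each increment. The FE system is solved once at the
#' first non-zero increment; the linear solutions at the other increments are
#' scalar multiples in the same boundary-condition direction.
#'
#' @param config A [pipeline_config()].
#' @param perturbation Optional `function(strain, volume)` returning a
#'   displacement field added to the experimental-side deformation (the
#'   model side never sees it).
#' @return A `trabevalid_run` with the comparison records, summary table,
#'   stiffness and peak stress per increment, calibration baseline and a
#'   reproducibility manifest.
#' @export
run_pipeline <- function(config, perturbation = NULL) {
  prep <- prepare_specimen(config)
  run_increments(prep, config$interface, perturbation = perturbation,
                 write_outputs = TRUE)
}

# Stage 2: solve and validate each increment on a prepared specimen. A
# pre-computed solution for the first increment (same prep, same interface)
# can be supplied to avoid re-solving.
run_increments <- function(prep, interface, perturbation = NULL,
                           write_outputs = FALSE, x0 = NULL, solution = NULL) {
  config <- prep$config
  height <- config$specimen$cylinder_height
  increments <- config$increments[config$increments > 0]
  records <- prep$calibration
  stiffness <- data.frame()
  bcs1 <- NULL
  fe_warped <- list()
  if (!length(increments)) solution <- NULL
  if (length(increments)) {
    bcs_list <- lapply(seq_along(increments), function(i)
      measure_boundary_conditions(config, height, i, increments[i]))
    bcs1 <- bcs_list[[1]]
    if (is.null(solution))
      solution <- solve_microfe(prep$mesh, bcs1, interface, config$solver, x0 = x0)
    else if (solution$interface$kind != interface$kind)
      stopf("supplied solution was computed with a different interface model")
    base_field <- solution_field(solution)
    gt <- strip_markers(prep$labels_gt)
    for (i in seq_along(increments)) {
      scale <- bcs_list[[i]]$nominal_strain / bcs1$nominal_strain
      field_i <- lapply(base_field, function(a) a * scale)
      fe_i <- warp_labels(prep$mesh_labels, field_i,
                          target_voxel_size = prep$scan0$voxel_size,
                          target_dim = dim(prep$scan0$data),
                          target_origin = prep$scan0$origin)
      fe_warped[[i]] <- fe_i
      # experimental side: same physical deformation applied to the ground
      # truth, imaged and segmented like a real loaded scan
      exp_field <- resample_mesh_field(prep, field_i)
      if (!is.null(perturbation))
        exp_field <- add_fields(exp_field, perturbation(increments[i], gt))
      img <- config$imaging
      img$seed <- derive_seed(config$seed, paste0("scan", i))
      scan_i <- synthesize_loaded_scan(gt, exp_field, img)
      seg_i <- segment(scan_i, prep$thresholds)
      f_i <- connectivity_filter(seg_i, config$min_component_voxels *
                                          config$downsample_factor^3)
      rec <- morphology_comparison(fe_i, f_i$label, prep$plan, increment = i)
      records <- rbind(records, rec)
      stiffness <- rbind(stiffness, data.frame(
        increment = i, nominal_strain = increments[i],
        apparent_stiffness = solution$stiffness_energy,
        max_von_mises = solution$max_von_mises * scale,
        reaction_top_z = solution$reactions$top[3] * scale))
    }
  }
  summary <- aggregate_morphology(records)
  run <- structure(list(
    config = config, prep = prep, interface = interface,
    solution = solution, bcs = bcs1, records = records, summary = summary,
    stiffness = stiffness, fe_warped = fe_warped,
    manifest = build_manifest(config, prep, solution, records)),
    class = "trabevalid_run")
  if (write_outputs && !is.null(config$output_dir)) write_run_outputs(run)
  run
}

strip_markers <- function(label) {
  arr <- label$data
  arr[arr == LBL[["marker"]]] <- LBL[["background"]]
  out <- label_volume(arr, label$voxel_size, label$origin)
  attributes(out)["specimen"] <- attributes(label)["specimen"]
  out
}

# extend the solved 50-um mesh field to the full node grid (nearest mesh
# node) and resample it onto the 25-um ground-truth grid
resample_mesh_field <- function(prep, field) {
  mesh <- prep$mesh
  gd <- mesh$dims + 1L
  defined <- array(FALSE, gd)
  defined[mesh$node_key + 1] <- TRUE
  full <- extend_field_nearest(field, defined)
  resample_field(full, mesh$voxel_size, dim(prep$labels_gt$data),
                 prep$labels_gt$voxel_size)
}

build_manifest <- function(config, prep, solution, records) {
  list(package_version = as.character(packageVersion("trabevalid")),
       seed = config$seed,
       specimen = unclass(config$specimen),
       imaging = unclass(config$imaging),
       thresholds = unclass(prep$thresholds),
       increments = config$increments,
       interface = unclass(config$interface),
       n_elements = prep$mesh$n_elements,
       n_nodes = prep$mesh$n_nodes,
       solver = if (!is.null(solution)) solution$diagnostics else NULL,
       calibration_total_mean = mean(prep$calibration$total_pct),
       records_digest = paste(format(round(records$total_pct, 6)), collapse = ","))
}

write_run_outputs <- function(run) {
  dir.create(run$config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outd <- run$config$output_dir
  write_stack(run$prep$scan0, file.path(outd, "scan_unloaded.nrrd"))
  write_stack(run$prep$seg50, file.path(outd, "labels_model.nrrd"))
  write.csv(run$records, file.path(outd, "morphology_records.csv"), row.names = FALSE)
  write.csv(run$summary, file.path(outd, "morphology_summary.csv"), row.names = FALSE)
  if (nrow(run$stiffness)) {
    write.csv(run$stiffness, file.path(outd, "stiffness.csv"), row.names = FALSE)
    write_boundary_conditions(run$bcs, file.path(outd, "boundary_conditions.json"))
  }
  for (i in seq_along(run$fe_warped)) {
    s <- run$prep$plan$stations[2]
    write_overlay_png(extract_sagittal_slice(run$fe_warped[[i]], s),
                      extract_sagittal_slice(run$prep$seg25, s),
                      station_region(run$prep$plan, run$prep$seg25, s),
                      file.path(outd, sprintf("overlay_increment%d.png", i)))
  }
  files <- list.files(outd, full.names = TRUE)
  manifest <- run$manifest
  manifest$output_hashes <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, file.path(outd, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outd)
}

#' @export
print.trabevalid_run <- function(x, ...) {
  cat("<trabevalid_run>\n")
  cat(sprintf("  specimen: %g x %g mm, %d elements, %d nodes\n",
              x$config$specimen$cylinder_diameter, x$config$specimen$cylinder_height,
              x$prep$mesh$n_elements, x$prep$mesh$n_nodes))
  cat(sprintf("  interface: %s\n", x$interface$kind))
  cat("  deformed-morphology error (mean over slices):\n")
  s <- x$summary
  for (r in seq_len(nrow(s)))
    cat(sprintf("    %-8s FP %5.2f%%  FN %5.2f%%  total %5.2f%% (sd %.2f)\n",
                format(s$increment[r]), s$fp_mean[r], s$fn_mean[r],
                s$total_mean[r], s$total_sd[r]))
  invisible(x)
}

#' Tied vs frictionless interface sensitivity comparison
#'
#' Runs the same prepared specimen with the tied and the linearized
#' frictionless interface models and reports the paired differences in
#' apparent stiffness, peak von Mises stress and predicted deformed
#' morphology per increment.
#'
#' @param config A [pipeline_config()].
#' @param prep Optional pre-computed [prepare_specimen()] result (advanced
#'   use; must match `config`).
#' @param tied_run Optional pre-computed tied-interface run on `prep`.
#' @return List with both runs and a `comparison` data frame.
#' @export
compare_interfaces <- function(config, prep = NULL, tied_run = NULL) {
  if (is.null(prep)) prep <- prepare_specimen(config)
  run_tied <- tied_run %||% run_increments(prep, interface_model("tied"))
  # warm-start the penalty solve from the tied solution mapped to the split
  # DOF layout
  x0 <- NULL
  if (!is.null(run_tied$solution)) {
    lay_fl <- build_layout(prep$mesh, interface_model("frictionless_penalty"),
                           vox_mm(prep$mesh$voxel_size))
    u_t <- run_tied$solution$displacements
    full <- rbind(u_t, u_t[lay_fl$dup_of, , drop = FALSE])
    x0 <- as.vector(t(full))
  }
  run_fl <- run_increments(prep, interface_model("frictionless_penalty"), x0 = x0)
  comparison <- data.frame()
  for (i in seq_len(nrow(run_tied$stiffness))) {
    kt <- run_tied$stiffness$apparent_stiffness[i]
    kf <- run_fl$stiffness$apparent_stiffness[i]
    vt <- run_tied$stiffness$max_von_mises[i]
    vf <- run_fl$stiffness$max_von_mises[i]
    morph <- morphology_comparison(run_fl$fe_warped[[i]], run_tied$fe_warped[[i]],
                                   prep$plan, increment = i)
    comparison <- rbind(comparison, data.frame(
      increment = i,
      stiffness_tied = kt, stiffness_frictionless = kf,
      stiffness_diff_pct = 100 * abs(kt - kf) / kt,
      max_vm_tied = vt, max_vm_frictionless = vf,
      max_vm_diff_pct = 100 * abs(vt - vf) / vt,
      morphology_diff_pct = mean(morph$total_pct)))
  }
  list(tied = run_tied, frictionless = run_fl, comparison = comparison)
}
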