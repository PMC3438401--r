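#' Landmark set on one specimen end
#'
#' Coordinates of matched landmark points recorded on the top or bottom
#' specimen end in one load state. Correspondence between states is by point
#' index.
#'
#' @param end `"top"` or `"bottom"`.
#' @param points Matrix (n x 3) of point coordinates, mm; n >= 5.
#' @param state Load increment identifier (e.g. `"unloaded"`, `1L`).
#' @return A `landmark_set` object.
#' @export
landmark_set <- function(end = c("top", "bottom"), points, state = "unloaded") {
  end <- match.arg(end)
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 5L)
    stopf("at least 5 landmark points are required per end (got %d)", nrow(points))
  if (!all(is.finite(points))) stopf("landmark coordinates must be finite")
  structure(list(end = end, points = points, state = state), class = "landmark_set")
}

#' Mean end displacement from matched landmarks
#'
#' The componentwise mean of `loaded - ref` over all matched points: the
#' average difference between the coordinates of the same points in the two
#' states. Permutation-consistent (points correspond by index) and linear in
#' the inputs.
#'
#' @param ref Landmarks in the reference (unloaded) state.
#' @param loaded Landmarks in the loaded state, same end and point count.
#' @return Length-3 displacement vector, mm.
#' @export
compute_end_displacements <- function(ref, loaded) {
  stopifnot(inherits(ref, "landmark_set"), inherits(loaded, "landmark_set"))
  if (ref$end != loaded$end)
    stopf("landmark sets are from different ends (%s vs %s)", ref$end, loaded$end)
  if (nrow(ref$points) != nrow(loaded$points))
    stopf("point correspondence broken: %d reference vs %d loaded points",
          nrow(ref$points), nrow(loaded$points))
  colMeans(loaded$points - ref$points)
}

#' Package end displacements as boundary conditions
#'
#' Records the per-increment displacement vectors of the two specimen ends and
#' the nominal compressive strain
#' `(|u_top_z| + |u_bottom_z|) / specimen height`.
#'
#' @param u_top,u_bottom Length-3 displacement vectors, mm.
#' @param increment Load increment identifier.
#' @param height Specimen height, mm.
#' @return A `boundary_conditions` object.
#' @export
build_boundary_conditions <- function(u_top, u_bottom, increment, height) {
  u_top <- as.numeric(u_top); u_bottom <- as.numeric(u_bottom)
  if (length(u_top) != 3L || length(u_bottom) != 3L ||
      !all(is.finite(c(u_top, u_bottom))))
    stopf("end displacements must be finite length-3 vectors (mm)")
  if (!is.finite(height) || height <= 0) stopf("height must be positive (mm)")
  tz <- u_top[3]; bz <- u_bottom[3]
  if (tz != 0 && bz != 0 && sign(tz) == sign(bz))
    warning("axial end displacements share a sign (rigid transport, not compression toward the centre)",
            call. = FALSE)
  if (all(c(u_top, u_bottom) == 0) && !identical(increment, 0L) && !identical(increment, "initial"))
    warning("zero end displacements at a non-zero load increment", call. = FALSE)
  structure(list(increment = increment, u_top = u_top, u_bottom = u_bottom,
                 nominal_strain = abs(tz - bz) / height, height = height),
            class = "boundary_conditions")
}

#' @export
print.boundary_conditions <- function(x, ...) {
  cat(sprintf("<boundary_conditions> increment %s: u_top (%g, %g, %g) mm, u_bottom (%g, %g, %g) mm, nominal strain %.3g%%\n",
              format(x$increment), x$u_top[1], x$u_top[2], x$u_top[3],
              x$u_bottom[1], x$u_bottom[2], x$u_bottom[3], 100 * x$nominal_strain))
  invisible(x)
}

#' Read / write landmark CSV files
#'
#' Landmark tables have columns `end`, `state`, `x_mm`, `y_mm`, `z_mm`.
#'
#' @param path CSV file path.
#' @return `read_landmarks()` returns a list of [landmark_set()] objects,
#'   one per (end, state) pair.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("end", "state", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stopf("landmark CSV must have columns %s", paste(need, collapse = ", "))
  groups <- split(df, list(df$end, df$state), drop = TRUE)
  lapply(groups, function(g)
    landmark_set(g$end[1], as.matrix(g[, c("x_mm", "y_mm", "z_mm")]), g$state[1]))
}

#' @param sets List of [landmark_set()] objects.
#' @rdname read_landmarks
#' @export
write_landmarks <- function(sets, path) {
  rows <- lapply(sets, function(s)
    data.frame(end = s$end, state = s$state, x_mm = s$points[, 1],
               y_mm = s$points[, 2], z_mm = s$points[, 3]))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write boundary conditions as JSON
#' @param bcs A [build_boundary_conditions()] object or list of them.
#' @param path Output path.
#' @export
write_boundary_conditions <- function(bcs, path) {
  if (inherits(bcs, "boundary_conditions")) bcs <- list(bcs)
  jsonlite::write_json(lapply(bcs, unclass), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
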