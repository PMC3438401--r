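#' Export a voxel mesh (and optional solution) to Abaqus INP or legacy VTK
#'
#' The INP file carries nodes, C3D8 elements split into BONE/CEMENT element
#' sets with solid sections and elastic materials, plus TOP/BOTTOM boundary
#' node sets. The VTK file is a legacy ASCII unstructured grid with nodal
#' displacement vectors and element von Mises stress when a solution is given.
#'
#' @param mesh A [build_mesh()] result.
#' @param solution Optional [solve_microfe()] result.
#' @param path Output file path.
#' @param format `"inp"` or `"vtk"` (inferred from the extension when `NULL`).
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, solution = NULL, path, format = NULL) {
  stopifnot(inherits(mesh, "voxel_mesh"))
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               inp = "inp", vtk = "vtk",
                               stopf("cannot infer export format from '%s'", path))
  if (format == "inp") export_inp(mesh, path) else export_vtk(mesh, solution, path)
  invisible(path)
}

export_inp <- function(mesh, path) {
  coords <- mesh_node_coords(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*HEADING", con)
  writeLines("voxel micro-FE mesh (trabevalid)", con)
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(mesh$n_nodes),
                     coords[, 1], coords[, 2], coords[, 3]), con)
  en1 <- mesh$elem_nodes + 1L
  for (m in 1:2) {
    rows <- which(mesh$mat == m)
    if (!length(rows)) next
    setname <- if (m == 1L) "BONE" else "CEMENT"
    writeLines(sprintf("*ELEMENT, TYPE=C3D8, ELSET=%s", setname), con)
    writeLines(sprintf("%d, %s", rows,
                       apply(en1[rows, , drop = FALSE], 1, paste, collapse = ", ")), con)
  }
  for (m in 1:2) {
    mt <- if (m == 1L) mesh$materials$bone else mesh$materials$cement
    setname <- if (m == 1L) "BONE" else "CEMENT"
    if (!any(mesh$mat == m)) next
    writeLines(sprintf("*SOLID SECTION, ELSET=%s, MATERIAL=%s", setname,
                       toupper(mt$name)), con)
    writeLines(sprintf("*MATERIAL, NAME=%s", toupper(mt$name)), con)
    writeLines("*ELASTIC", con)
    writeLines(sprintf("%.9g, %.9g", mt$E, mt$nu), con)
  }
  gnx <- mesh$dims[1] + 1L; gny <- mesh$dims[2] + 1L; gnz <- mesh$dims[3] + 1L
  kidx <- mesh$node_key %/% (gnx * gny)
  for (set in list(c("BOTTOM", 0L), c("TOP", gnz - 1L))) {
    nodes <- which(kidx == as.integer(set[2]))
    if (!length(nodes)) next
    writeLines(sprintf("*NSET, NSET=%s", set[1]), con)
    writeLines(vapply(split(nodes, ceiling(seq_along(nodes) / 8)),
                      paste, character(1), collapse = ", "), con)
  }
}

#' Minimal Abaqus INP import
#'
#' Reads nodes, C3D8 elements and their element sets from files written by
#' [export_mesh()] (round-trip checks and interoperability).
#'
#' @param path INP file path.
#' @return List with `nodes` (n x 3 coordinates), `elements` (nel x 8 node
#'   ids) and `elset` (character per element).
#' @export
import_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nodes <- list(); elems <- list(); elset <- character()
  mode <- ""
  current_set <- ""
  for (line in lines) {
    if (startsWith(line, "*")) {
      up <- toupper(line)
      if (startsWith(up, "*NODE")) mode <- "node"
      else if (startsWith(up, "*ELEMENT")) {
        mode <- "elem"
        current_set <- sub(".*ELSET=([^,]*).*", "\\1", up)
      } else mode <- ""
      next
    }
    if (mode == "node") {
      v <- as.numeric(strsplit(line, ",")[[1]])
      nodes[[length(nodes) + 1L]] <- v[2:4]
    } else if (mode == "elem") {
      v <- as.integer(strsplit(line, ",")[[1]])
      elems[[length(elems) + 1L]] <- v[2:9]
      elset <- c(elset, current_set)
    }
  }
  list(nodes = do.call(rbind, nodes), elements = do.call(rbind, elems),
       elset = elset)
}

export_vtk <- function(mesh, solution, path) {
  coords <- mesh_node_coords(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "trabevalid voxel micro-FE mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", mesh$n_nodes), con)
  writeLines(sprintf("%.9g %.9g %.9g", coords[, 1], coords[, 2], coords[, 3]), con)
  nel <- mesh$n_elements
  writeLines(sprintf("CELLS %d %d", nel, 9L * nel), con)
  writeLines(paste(8L, apply(mesh$elem_nodes, 1, paste, collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", nel), con)
  writeLines(as.character(rep(12L, nel)), con)
  writeLines(sprintf("CELL_DATA %d", nel), con)
  writeLines(c("SCALARS material int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$mat), con)
  if (!is.null(solution)) {
    writeLines(c("SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", solution$von_mises), con)
    disp <- solution$displacements[seq_len(mesh$n_nodes), , drop = FALSE]
    lay <- solution$layout
    if (length(lay$dup_of)) {
      dup_rows <- mesh$n_nodes + seq_along(lay$dup_of)
      disp[lay$dup_of, ] <- (disp[lay$dup_of, , drop = FALSE] +
        solution$displacements[dup_rows, , drop = FALSE]) / 2
    }
    writeLines(sprintf("POINT_DATA %d", mesh$n_nodes), con)
    writeLines("VECTORS displacement double", con)
    writeLines(sprintf("%.9g %.9g %.9g", disp[, 1], disp[, 2], disp[, 3]), con)
  }
}
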