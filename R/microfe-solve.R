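#' Cement-bone interface model
#'
#' `"tied"` bonds the two materials rigidly (shared mesh nodes). The
#' `"frictionless_penalty"` model duplicates the nodes on cement-bone
#' interface faces and couples only the face-normal displacement component of
#' each duplicated pair through penalty springs, leaving tangential sliding
#' free -- a linearization of small-sliding frictionless contact.
#'
#' @param kind `"tied"` or `"frictionless_penalty"`.
#' @param penalty_stiffness Penalty spring stiffness per interface face,
#'   N/mm; defaults to `100 * E_cement * h` at solve time.
#' @return An `interface_model` object.
#' @export
interface_model <- function(kind = c("tied", "frictionless_penalty"),
                            penalty_stiffness = NULL) {
  kind <- match.arg(kind)
  if (kind == "frictionless_penalty" && !is.null(penalty_stiffness) &&
      (!is.finite(penalty_stiffness) || penalty_stiffness <= 0))
    stopf("penalty_stiffness must be positive")
  structure(list(kind = kind, penalty_stiffness = penalty_stiffness),
            class = "interface_model")
}

#' Solver options
#'
#' @param tolerance Relative residual tolerance of the preconditioned
#'   conjugate gradient solver.
#' @param max_iterations Iteration cap.
#' @return A `solver_options` object.
#' @export
solver_options <- function(tolerance = 1e-8, max_iterations = 20000L) {
  structure(list(tolerance = tolerance, max_iterations = as.integer(max_iterations)),
            class = "solver_options")
}

# Internal DOF layout: tied reuses the mesh nodes; frictionless duplicates
# nodes touched by both materials (cement side gets new ids) and builds the
# penalty pairs from the interface faces.
build_layout <- function(mesh, interface, h_mm) {
  nn <- mesh$n_nodes
  if (interface$kind == "tied") {
    return(list(elem_nodes = mesh$elem_nodes, n_nodes = nn,
                orig_node = seq_len(nn), dup_of = integer(0),
                pen_a = integer(0), pen_b = integer(0), pen_k = numeric(0)))
  }
  bone_touch <- logical(nn)
  cem_touch <- logical(nn)
  bone_touch[unique(as.vector(mesh$elem_nodes[mesh$mat == 1L, , drop = FALSE])) + 1L] <- TRUE
  cem_touch[unique(as.vector(mesh$elem_nodes[mesh$mat == 2L, , drop = FALSE])) + 1L] <- TRUE
  dup <- which(bone_touch & cem_touch)
  cem_id <- seq_len(nn)            # 1-based ids of the cement-side instance
  cem_id[dup] <- nn + seq_along(dup)
  elem_nodes <- mesh$elem_nodes
  cem_rows <- mesh$mat == 2L
  elem_nodes[cem_rows, ] <- cem_id[elem_nodes[cem_rows, ] + 1L] - 1L
  penalty <- interface$penalty_stiffness %||% (100 * mesh$materials$cement$E * h_mm)
  corn <- mesh$interface$corners
  if (nrow(corn)) {
    node_of_key <- match(as.vector(corn), mesh$node_key)
    if (anyNA(node_of_key))
      stopf("interface face corner not present in the mesh node set")
    n1 <- matrix(node_of_key, nrow(corn), 4L)      # bone-side instance, 1-based
    n2 <- matrix(cem_id[node_of_key], nrow(corn), 4L)
    ax <- rep(mesh$interface$axis, 4L)
    dof_a <- 3L * (as.vector(n1) - 1L) + ax
    dof_b <- 3L * (as.vector(n2) - 1L) + ax
    k <- rep(penalty / 4, length(dof_a))
    # aggregate coincident pairs (a corner shared by several interface faces)
    key <- paste(dof_a, dof_b)
    agg <- rowsum(k, key)
    first <- which(!duplicated(key))
    sel <- first[match(rownames(agg), key[first])]
    pen_a <- dof_a[sel]; pen_b <- dof_b[sel]; pen_k <- as.numeric(agg)
  } else {
    pen_a <- integer(0); pen_b <- integer(0); pen_k <- numeric(0)
  }
  orig_node <- c(seq_len(nn), dup)   # grid-node id of each layout node
  list(elem_nodes = elem_nodes, n_nodes = nn + length(dup),
       orig_node = orig_node, dup_of = dup,
       pen_a = as.integer(pen_a - 1L), pen_b = as.integer(pen_b - 1L),
       pen_k = pen_k)
}

# Dirichlet constraints for the end-face nodes. Returns dof indices (1-based)
# and values. bc_mode "clamped" prescribes all three components on both end
# faces; "axial" prescribes only z plus minimal lateral rigid-body pins on
# the bottom face (verification mode: consistent with uniform uniaxial
# stress fields).
end_constraints <- function(mesh, layout, bcs, bc_mode) {
  gnx <- mesh$dims[1] + 1L; gny <- mesh$dims[2] + 1L; gnz <- mesh$dims[3] + 1L
  kidx <- mesh$node_key %/% (gnx * gny)
  bottom_nodes <- which(kidx == 0L)
  top_nodes <- which(kidx == gnz - 1L)
  if (!length(bottom_nodes) || !length(top_nodes))
    stopf("mesh has no nodes on an end plane; cannot apply end displacements")
  expand_instances <- function(nodes) {
    if (!length(layout$dup_of)) return(nodes)
    more <- (mesh$n_nodes + seq_along(layout$dup_of))[layout$dup_of %in% nodes]
    c(nodes, more)
  }
  bottom_all <- expand_instances(bottom_nodes)
  top_all <- expand_instances(top_nodes)
  dofs <- integer(0); vals <- numeric(0)
  add <- function(nodes, comps, values) {
    for (c_i in seq_along(comps)) {
      dofs <<- c(dofs, 3L * (nodes - 1L) + comps[c_i])
      vals <<- c(vals, rep(values[c_i], length(nodes)))
    }
  }
  if (bc_mode == "clamped") {
    add(bottom_all, 1:3, bcs$u_bottom)
    add(top_all, 1:3, bcs$u_top)
  } else if (bc_mode == "axial") {
    add(bottom_all, 3L, bcs$u_bottom[3])
    add(top_all, 3L, bcs$u_top[3])
    # lateral rigid-body pins on the bottom face, consistent with symmetric
    # lateral contraction about the pin point
    ij <- key_to_ijk(mesh$node_key[bottom_nodes], gnx, gny)
    o <- order(ij[, 2], ij[, 1])
    n1 <- bottom_nodes[o[1]]
    add(n1, 1:2, c(0, 0))
    same_j <- which(ij[, 2] == ij[o[1], 2] & bottom_nodes != n1)
    if (length(same_j)) {
      pick <- same_j[which.max(abs(ij[same_j, 1] - ij[o[1], 1]))]
      add(bottom_nodes[pick], 2L, 0)
    } else {
      add(setdiff(bottom_nodes, n1)[1], 2L, 0)
    }
  } else stopf("unknown bc_mode '%s'", bc_mode)
  keep <- !duplicated(dofs)
  list(dofs = dofs[keep], values = vals[keep],
       bottom_nodes = bottom_all, top_nodes = top_all)
}

#' Solve the voxel micro-FE compression problem
#'
#' Imposes the end displacements as Dirichlet data, solves the two-material
#' linear elastic system with a matrix-free Jacobi-preconditioned conjugate
#' gradient method, and recovers element centroid stresses, end reactions and
#' the apparent stiffness.
#'
#' @param mesh A [build_mesh()] result.
#' @param bcs [build_boundary_conditions()] displacements of the specimen
#'   ends (may be `NULL` when `constraints` is given).
#' @param interface An [interface_model()].
#' @param opts [solver_options()].
#' @param bc_mode `"clamped"` (all three components prescribed on the end
#'   faces, the default) or `"axial"` (z only plus minimal lateral pins;
#'   verification problems).
#' @param constraints Optional data frame with columns `node` (1-based mesh
#'   node), `comp` (1-3) and `value` (mm) replacing the end-face constraint
#'   construction entirely (e.g. for patch tests).
#' @param x0 Optional initial displacement guess (length `3 * n` layout DOFs)
#'   for warm starts.
#' @return An `fe_solution` with nodal displacements, element centroid stress
#'   tensors and von Mises stresses (MPa), end reactions (N), apparent
#'   stiffness (N/mm) and solver diagnostics.
#' @export
solve_microfe <- function(mesh, bcs = NULL, interface = interface_model("tied"),
                          opts = solver_options(), bc_mode = "clamped",
                          constraints = NULL, x0 = NULL) {
  stopifnot(inherits(mesh, "voxel_mesh"), inherits(interface, "interface_model"),
            inherits(opts, "solver_options"))
  h_mm <- vox_mm(mesh$voxel_size)
  layout <- build_layout(mesh, interface, h_mm)
  templates <- list(element_stiffness(mesh$materials$bone, mesh$voxel_size),
                    element_stiffness(mesh$materials$cement, mesh$voxel_size))
  tmpl <- mesh$mat - 1L
  ndof <- 3L * layout$n_nodes
  if (!is.null(constraints)) {
    cdofs <- 3L * (as.integer(constraints$node) - 1L) + as.integer(constraints$comp)
    cvals <- as.numeric(constraints$value)
    ends <- NULL
  } else {
    if (is.null(bcs)) stopf("either bcs or constraints must be supplied")
    ends <- end_constraints(mesh, layout, bcs, bc_mode)
    cdofs <- ends$dofs
    cvals <- ends$values
  }
  fixed <- integer(ndof)
  fixed[cdofs] <- 1L
  u0 <- numeric(ndof)
  u0[cdofs] <- cvals
  en <- layout$elem_nodes
  storage.mode(en) <- "integer"
  dg <- .hex_diag(en, tmpl, templates, layout$pen_a, layout$pen_b, layout$pen_k, ndof)
  b <- -.hex_matvec(en, tmpl, templates, layout$pen_a, layout$pen_b, layout$pen_k,
                    fixed, u0, FALSE)
  b[cdofs] <- 0
  if (is.null(x0) && !is.null(ends) && bc_mode == "clamped") {
    # affine interpolation between the end displacements: satisfies the
    # constraints exactly and captures the bulk response, leaving only the
    # strut-scale deviation to the iteration
    gnz <- mesh$dims[3] + 1L
    kfrac <- (mesh$node_key %/% ((mesh$dims[1] + 1L) * (mesh$dims[2] + 1L))) / (gnz - 1L)
    kfrac <- kfrac[layout$orig_node]
    x0 <- as.vector(t(outer(1 - kfrac, bcs$u_bottom) + outer(kfrac, bcs$u_top)))
  }
  start <- numeric(ndof)
  if (!is.null(x0)) {
    if (length(x0) != ndof) stopf("x0 has wrong length")
    start <- x0 - u0
    start[cdofs] <- 0
  }
  sol <- .hex_pcg(en, tmpl, templates, layout$pen_a, layout$pen_b, layout$pen_k,
                  fixed, b, start, dg, opts$tolerance, opts$max_iterations)
  if (!sol$converged)
    stopf("PCG did not converge in %d iterations (relative residual %.3e > %.1e)",
          sol$iterations, sol$relres, opts$tolerance)
  u <- sol$x + u0
  f <- .hex_matvec(en, tmpl, templates, layout$pen_a, layout$pen_b, layout$pen_k,
                   fixed, u, FALSE)
  reactions <- list(top = c(NA_real_, NA_real_, NA_real_),
                    bottom = c(NA_real_, NA_real_, NA_real_))
  if (!is.null(ends)) {
    sum_nodes <- function(nodes) {
      c(sum(f[3L * (nodes - 1L) + 1L]), sum(f[3L * (nodes - 1L) + 2L]),
        sum(f[3L * (nodes - 1L) + 3L]))
    }
    reactions$top <- sum_nodes(ends$top_nodes)
    reactions$bottom <- sum_nodes(ends$bottom_nodes)
  }
  # centroid stress: strain from the centroid strain-displacement matrix,
  # equal to the average over the 2x2x2 Gauss points by symmetry
  B0 <- hex_B(0, 0, 0, h_mm)
  dofmat <- matrix(0L, nrow(en), 24L)
  for (a in 1:8) dofmat[, (3 * a - 2):(3 * a)] <-
    cbind(3L * en[, a] + 1L, 3L * en[, a] + 2L, 3L * en[, a] + 3L)
  Ue <- matrix(u[dofmat], nrow(en), 24L)
  Eps <- Ue %*% t(B0)
  stress <- matrix(0, nrow(en), 6L)
  for (m in 1:2) {
    rows <- mesh$mat == m
    if (any(rows)) {
      Dm <- elasticity_matrix(if (m == 1L) mesh$materials$bone else mesh$materials$cement)
      stress[rows, ] <- Eps[rows, , drop = FALSE] %*% t(Dm)
    }
  }
  colnames(stress) <- c("sxx", "syy", "szz", "sxy", "syz", "szx")
  vm <- von_mises(stress)
  interior <- mesh$vox[, 3] > 0L & mesh$vox[, 3] < mesh$dims[3] - 1L
  max_vm <- if (any(interior)) max(vm[interior]) else max(vm)
  stiffness <- NA_real_
  stiffness_energy <- NA_real_
  if (!is.null(bcs)) {
    urel <- bcs$u_top[3] - bcs$u_bottom[3]
    if (abs(urel) > 0) {
      stiffness <- abs(reactions$top[3]) / abs(urel)
      # work identity: for rigid opposed end displacements the strain energy
      # is U = k * urel^2 / 2; variational, so far less sensitive to the
      # remaining iteration residual than the reaction sum
      stiffness_energy <- sum(u * f) / urel^2
    }
  }
  structure(list(
    u = u, displacements = matrix(u, ncol = 3, byrow = TRUE),
    layout = layout, mesh = mesh, bcs = bcs, interface = interface,
    reactions = reactions, stress = stress, von_mises = vm,
    max_von_mises = max_vm, apparent_stiffness = stiffness,
    stiffness_energy = stiffness_energy,
    diagnostics = list(iterations = sol$iterations, relres = sol$relres,
                       converged = sol$converged, n_dof = ndof)),
    class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("<fe_solution> %d DOF, %d PCG iterations (relres %.2e)\n",
              x$diagnostics$n_dof, x$diagnostics$iterations, x$diagnostics$relres))
  if (is.finite(x$apparent_stiffness))
    cat(sprintf("  apparent stiffness %.4g N/mm, max interior von Mises %.4g MPa\n",
                x$apparent_stiffness, x$max_von_mises))
  cat(sprintf("  reactions z: top %.6g N, bottom %.6g N\n",
              x$reactions$top[3], x$reactions$bottom[3]))
  invisible(x)
}

#' Von Mises equivalent stress
#'
#' `sqrt(0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2) +
#' 3 * (sxy^2 + syz^2 + szx^2))` applied to stress 6-vectors
#' `(sxx, syy, szz, sxy, syz, szx)`.
#'
#' @param stress Numeric length-6 vector or n x 6 matrix, MPa.
#' @return Von Mises stress(es), MPa.
#' @export
von_mises <- function(stress) {
  if (is.null(dim(stress))) {
    if (length(stress) %% 6L != 0L) stopf("stress must have 6 components")
    stress <- matrix(stress, ncol = 6, byrow = TRUE)
  }
  if (ncol(stress) != 6L) stopf("stress must have 6 components")
  if (!all(is.finite(stress))) stopf("stress tensor must be finite")
  sqrt(0.5 * ((stress[, 1] - stress[, 2])^2 + (stress[, 2] - stress[, 3])^2 +
              (stress[, 3] - stress[, 1])^2) +
       3 * (stress[, 4]^2 + stress[, 5]^2 + stress[, 6]^2))
}

#' Apparent specimen stiffness
#'
#' Axial reaction magnitude divided by the relative axial end displacement.
#'
#' @param solution An [solve_microfe()] result.
#' @param bcs Boundary conditions (defaults to those of the solution).
#' @return Stiffness, N/mm.
#' @export
apparent_stiffness <- function(solution, bcs = solution$bcs) {
  stopifnot(inherits(solution, "fe_solution"))
  if (is.null(bcs)) stopf("no boundary conditions associated with the solution")
  urel <- bcs$u_top[3] - bcs$u_bottom[3]
  if (urel == 0) stopf("zero relative axial end displacement: stiffness undefined")
  abs(solution$reactions$top[3]) / abs(urel)
}

#' Nodal displacement field on the full node grid
#'
#' Scatters the solved mesh-node displacements onto the complete
#' `(nx + 1) x (ny + 1) x (nz + 1)` node grid of the source label volume
#' (zero away from the mesh; duplicated interface instances averaged), the
#' form consumed by [warp_labels()].
#'
#' @param solution An [solve_microfe()] result.
#' @param scale Scalar multiplier applied to the field (linear elasticity).
#' @return List of arrays `ux`, `uy`, `uz` (mm) over the node grid.
#' @export
solution_field <- function(solution, scale = 1) {
  mesh <- solution$mesh
  gdim <- mesh$dims + 1L
  disp <- solution$displacements * scale
  nn <- mesh$n_nodes
  vals <- disp[seq_len(nn), , drop = FALSE]
  lay <- solution$layout
  if (length(lay$dup_of)) {
    dup_rows <- nn + seq_along(lay$dup_of)
    vals[lay$dup_of, ] <- (vals[lay$dup_of, , drop = FALSE] +
                           disp[dup_rows, , drop = FALSE]) / 2
  }
  ux <- array(0, gdim); uy <- array(0, gdim); uz <- array(0, gdim)
  pos <- mesh$node_key + 1
  ux[pos] <- vals[, 1]; uy[pos] <- vals[, 2]; uz[pos] <- vals[, 3]
  list(ux = ux, uy = uy, uz = uz)
}
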