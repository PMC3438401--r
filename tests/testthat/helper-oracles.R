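# Independent oracles and small fixtures shared across test files.

block_label <- function(nx, ny, nz, vox_um, code = 1L) {
  label_volume(array(code, dim = c(nx, ny, nz)), vox_um)
}

# small foam parameters for fast generator tests
small_foam_params <- function(seed = 42L) {
  foam_params(cylinder_diameter = 3, cylinder_height = 6,
              cement_cap_depth_range = c(0.5, 1.5), voxel_size = 25,
              seed = seed)
}

measured_porosity <- function(foam) {
  geo <- attr(foam, "specimen")
  cyl <- trabevalid:::cylinder_mask(dim(foam$data), foam$voxel_size / 1000,
                                    foam$origin, geo$center[1], geo$center[2],
                                    geo$radius)
  1 - sum(foam$data[cyl] > 0L) / sum(cyl)
}

# --- element stiffness oracle ----------------------------------------------
# Fine-quadrature (4x4x4 Gauss) numerical integration of B^T D B with shape
# function gradients obtained by central finite differences: independent of
# the analytic strain-displacement construction in the package.

gauss4 <- list(x = c(-0.8611363115940526, -0.3399810435848563,
                     0.3399810435848563, 0.8611363115940526),
               w = c(0.3478548451374538, 0.6521451548625461,
                     0.6521451548625461, 0.3478548451374538))

shape_fun <- function(xi) {
  s <- cbind(c(-1, 1, 1, -1, -1, 1, 1, -1),
             c(-1, -1, 1, 1, -1, -1, 1, 1),
             c(-1, -1, -1, -1, 1, 1, 1, 1))
  (1 + xi[1] * s[, 1]) * (1 + xi[2] * s[, 2]) * (1 + xi[3] * s[, 3]) / 8
}

shape_grad_fd <- function(xi, eps = 1e-6) {
  g <- matrix(0, 8, 3)
  for (a in 1:3) {
    e <- numeric(3); e[a] <- eps
    g[, a] <- (shape_fun(xi + e) - shape_fun(xi - e)) / (2 * eps)
  }
  g
}

element_stiffness_oracle <- function(material, h_um) {
  h <- h_um / 1000
  lam <- material$E * material$nu / ((1 + material$nu) * (1 - 2 * material$nu))
  mu <- material$E / (2 * (1 + material$nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  D[4, 4] <- D[5, 5] <- D[6, 6] <- mu
  K <- matrix(0, 24, 24)
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    g <- shape_grad_fd(c(gauss4$x[i], gauss4$x[j], gauss4$x[k])) * (2 / h)
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      ix <- 3 * (a - 1) + 1
      B[1, ix] <- g[a, 1]; B[2, ix + 1] <- g[a, 2]; B[3, ix + 2] <- g[a, 3]
      B[4, ix] <- g[a, 2]; B[4, ix + 1] <- g[a, 1]
      B[5, ix + 1] <- g[a, 3]; B[5, ix + 2] <- g[a, 2]
      B[6, ix] <- g[a, 3]; B[6, ix + 2] <- g[a, 1]
    }
    w <- gauss4$w[i] * gauss4$w[j] * gauss4$w[k] * (h / 2)^3
    K <- K + w * t(B) %*% D %*% B
  }
  K
}

# --- dense direct-solve oracle ----------------------------------------------
# Assemble the full stiffness matrix and solve with base::solve (LU).

dense_solve_oracle <- function(mesh, constrained_dofs, values) {
  nd <- 3L * mesh$n_nodes
  K <- matrix(0, nd, nd)
  Ks <- list(element_stiffness(mesh$materials$bone, mesh$voxel_size),
             element_stiffness(mesh$materials$cement, mesh$voxel_size))
  for (e in seq_len(mesh$n_elements)) {
    nod <- mesh$elem_nodes[e, ]
    dofs <- as.vector(rbind(3L * nod + 1L, 3L * nod + 2L, 3L * nod + 3L))
    K[dofs, dofs] <- K[dofs, dofs] + Ks[[mesh$mat[e]]]
  }
  u <- numeric(nd)
  u[constrained_dofs] <- values
  free <- setdiff(seq_len(nd), constrained_dofs)
  u[free] <- solve(K[free, free], -K[free, constrained_dofs, drop = FALSE] %*% values)
  u
}

# --- metric oracle -----------------------------------------------------------
# Naive per-pixel loop implementing the FP/FN definitions directly.

compare_slices_oracle <- function(fe, uct, region) {
  fp <- 0L; fn <- 0L; match_solid <- 0L; denom <- 0L
  for (i in seq_len(nrow(fe))) for (j in seq_len(ncol(fe))) {
    if (!region[i, j] || fe[i, j] == 3L || uct[i, j] == 3L) next
    fes <- fe[i, j] %in% 1:2
    ucs <- uct[i, j] %in% 1:2
    if (ucs) denom <- denom + 1L
    if (fes && !ucs) fp <- fp + 1L
    if (!fes && ucs) fn <- fn + 1L
    if (fes && ucs) match_solid <- match_solid + 1L
  }
  list(fp = fp, fn = fn, match_solid = match_solid, denom = denom,
       total_pct = 100 * (fp + fn) / denom)
}

# --- threshold oracle --------------------------------------------------------
# Brute-force scan of the three-class between-class variance over all bin
# pairs of a fixed histogram (direct definition, no cumulative trick).

auto_thresholds_oracle <- function(v, n_bins = 64L) {
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  best <- -Inf; bi <- c(NA, NA)
  for (i in 1:(n_bins - 2L)) for (j in (i + 1L):(n_bins - 1L)) {
    cls <- (bin > i) + (bin > j)
    sigma <- 0
    for (cl in 0:2) {
      sel <- cls == cl
      if (any(sel)) sigma <- sigma + sum(sel) / length(v) * (mean(mids[bin[sel]]) - mean(mids[bin]))^2
    }
    if (sigma > best) { best <- sigma; bi <- c(i, j) }
  }
  c(edges[bi[1] + 1L], edges[bi[2] + 1L])
}

# --- local thickness oracle --------------------------------------------------
# Distance-transform-based: thickness at a strut centreline point is twice the
# largest Euclidean distance to background over the point's 3^3 voxel
# neighbourhood (recovers the medial value despite voxel snapping), plus a
# constant discretization correction of 1.25 voxels on the diameter. The
# correction was calibrated on straight cylinders of known thickness
# (0.15-0.3 mm) rasterized with the same centreline-stamping convention, where
# the raw estimate reads 1.2-1.3 voxels low across the whole range;
# thickness_oracle_self_check() re-verifies it on one analytic cylinder.

local_thickness_at_points <- function(label, points, bias_voxels = 1.25) {
  d <- dim(label$data)
  vx <- label$voxel_size / 1000
  bg <- label$data == 0L
  a <- array(sqrt(trabevalid:::.edt3d(as.vector(bg), as.integer(d), FALSE)$dist2), d)
  idx <- round(sweep(points, 2, label$origin, `-`) / vx + 0.5)
  idx <- pmin(pmax(idx, 1), matrix(rep(d, each = nrow(points)), ncol = 3))
  nb <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    max(a[max(1, i - 1):min(d[1], i + 1),
          max(1, j - 1):min(d[2], j + 1),
          max(1, k - 1):min(d[3], k + 1)])
  }, numeric(1))
  2 * nb * vx + bias_voxels * vx
}

# one axis-tilted analytic cylinder of known 0.2 mm thickness, stamped the
# way the generator stamps struts: the corrected oracle must recover it to
# within half a voxel
thickness_oracle_self_check <- function() {
  vx <- 0.025
  g <- as.integer(c(80, 80, 80))
  dirv <- c(1, 2, 5) / sqrt(30)
  tt <- seq(-1.3, 1.3, by = vx)
  pts <- cbind(1 + tt * dirv[1], 1 + tt * dirv[2], 1 + tt * dirv[3])
  r_stamp <- max(0.1 - vx / 2, vx / 2)
  q <- trabevalid:::.stamp_struts(pts, rep(r_stamp, nrow(pts)), g, vx, c(0, 0, 0))
  lab <- label_volume(array(as.integer(q <= 1), dim = g), 25)
  mid <- pts[abs(tt) < 0.6, , drop = FALSE]
  median(local_thickness_at_points(lab, mid))
}
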