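#' Isotropic elastic material
#'
#' Linear-elastic material assigned to one or more element region tags.
#' Units are MPa throughout (mm-N-MPa system), so specific tension in
#' N mm^-2 and stresses share a unit. Defaults used for pharyngeal jaw
#' models: bone 3670 MPa (the low end of the published fish-bone range,
#' appropriate for juveniles), teeth 70000 MPa, Poisson's ratio 0.3.
#'
#' @param name label.
#' @param youngs_modulus Young's modulus (MPa), > 0.
#' @param poisson_ratio Poisson's ratio, in \[0, 0.5).
#' @param region_tags integer element tags covered by this material.
#' @return an object of class `elastic_material`.
#' @export
elastic_material <- function(name, youngs_modulus, poisson_ratio = 0.3,
                             region_tags) {
  if (!is.finite(youngs_modulus) || youngs_modulus <= 0)
    stop("'youngs_modulus' must be > 0 (MPa)")
  if (!is.finite(poisson_ratio) || poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("'poisson_ratio' must be in [0, 0.5)")
  structure(list(name = name, youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 region_tags = as.integer(region_tags)),
            class = "elastic_material")
}

#' Default two-material table for jaw models
#'
#' @param bone_tags,tooth_tags region tags covered by bone and teeth.
#' @param bone_modulus,tooth_modulus Young's moduli (MPa).
#' @param poisson_ratio shared Poisson's ratio.
#' @return list of [elastic_material()] objects.
#' @export
default_materials <- function(bone_tags = c(1L, 3L), tooth_tags = 2L,
                              bone_modulus = 3670, tooth_modulus = 70000,
                              poisson_ratio = 0.3) {
  list(elastic_material("bone", bone_modulus, poisson_ratio, bone_tags),
       elastic_material("tooth", tooth_modulus, poisson_ratio, tooth_tags))
}

# 6x6 isotropic elasticity matrix, Voigt order (xx, yy, zz, xy, yz, zx)
# with engineering shear strains.
iso_elasticity_matrix <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3L), rep(mu, 3L)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

# Shape-function gradients and volume of one TET4.
# coords: 4x3 node positions. Returns list(grads = 4x3, volume).
tet_shape_gradients <- function(coords) {
  A <- t(coords[2:4, , drop = FALSE] - rep(coords[1L, ], each = 3L))
  detA <- det(A)
  if (detA <= 0) stop("inverted element (non-positive volume)")
  gi <- solve(A)               # rows: grad of barycentric coords 2..4
  grads <- rbind(-colSums(gi), gi)
  list(grads = grads, volume = detA / 6)
}

# 6x12 strain-displacement matrix from shape gradients.
tet_b_matrix <- function(grads) {
  B <- matrix(0, 6L, 12L)
  for (i in 1:4) {
    c0 <- 3L * (i - 1L)
    g <- grads[i, ]
    B[1L, c0 + 1L] <- g[1L]
    B[2L, c0 + 2L] <- g[2L]
    B[3L, c0 + 3L] <- g[3L]
    B[4L, c0 + 1L] <- g[2L]; B[4L, c0 + 2L] <- g[1L]
    B[5L, c0 + 2L] <- g[3L]; B[5L, c0 + 3L] <- g[2L]
    B[6L, c0 + 1L] <- g[3L]; B[6L, c0 + 3L] <- g[1L]
  }
  B
}

#' Stiffness matrix of one constant-strain tetrahedron
#'
#' 12x12 symmetric positive-semidefinite stiffness `V * B' D B` of a
#' 4-node tetrahedron, with exactly six rigid-body zero-energy modes.
#'
#' @param coords 4x3 matrix of node positions (mm) in positive-volume
#'   order.
#' @param material an [elastic_material()], or a list with
#'   `youngs_modulus` and `poisson_ratio`.
#' @return 12x12 numeric matrix (N/mm), DOFs ordered (x1,y1,z1,...,z4).
#' @export
element_stiffness <- function(coords, material) {
  sg <- tet_shape_gradients(as.matrix(coords))
  B <- tet_b_matrix(sg$grads)
  D <- iso_elasticity_matrix(material$youngs_modulus, material$poisson_ratio)
  Ke <- sg$volume * crossprod(B, D %*% B)
  (Ke + t(Ke)) / 2
}

# Map each element to its material, erroring on gaps or overlaps.
material_by_element <- function(mesh, materials) {
  if (inherits(materials, "elastic_material")) materials <- list(materials)
  tag_owner <- integer(0)
  for (i in seq_along(materials)) {
    for (tg in materials[[i]]$region_tags) {
      key <- as.character(tg)
      if (!is.null(tag_owner[key]) && !is.na(tag_owner[key]))
        stop(sprintf("region tag %d covered by more than one material", tg))
      tag_owner[key] <- i
    }
  }
  idx <- tag_owner[as.character(mesh$element_region)]
  if (anyNA(idx)) {
    missing <- unique(mesh$element_region[is.na(idx)])
    stop(sprintf("no material covers region tag(s) %s",
                 paste(missing, collapse = ", ")))
  }
  unname(idx)
}

#' Assemble the global stiffness matrix
#'
#' Scatter-adds every element stiffness into the sparse symmetric 3N x 3N
#' global matrix of the equilibrium system `K d = P`.
#'
#' @param mesh a [tet_mesh()].
#' @param materials list of [elastic_material()] covering every region tag
#'   exactly once.
#' @return sparse symmetric `Matrix` of size 3N x 3N (N/mm).
#' @export
assemble_global <- function(mesh, materials) {
  m <- nrow(mesh$tets); n <- nrow(mesh$nodes)
  mat_idx <- material_by_element(mesh, materials)
  if (inherits(materials, "elastic_material")) materials <- list(materials)
  Ds <- lapply(materials, function(mt)
    iso_elasticity_matrix(mt$youngs_modulus, mt$poisson_ratio))
  ii <- integer(144L * m); jj <- integer(144L * m); xx <- numeric(144L * m)
  pos <- 0L
  for (e in seq_len(m)) {
    tet <- mesh$tets[e, ]
    sg <- tet_shape_gradients(mesh$nodes[tet, , drop = FALSE])
    B <- tet_b_matrix(sg$grads)
    Ke <- sg$volume * crossprod(B, Ds[[mat_idx[e]]] %*% B)
    dofs <- as.vector(rbind(3L * tet - 2L, 3L * tet - 1L, 3L * tet))
    idx <- pos + seq_len(144L)
    ii[idx] <- rep(dofs, times = 12L)
    jj[idx] <- rep(dofs, each = 12L)
    xx[idx] <- as.vector(Ke)
    pos <- pos + 144L
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3L * n, 3L * n))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Fixed-node constraint set
#'
#' Nodes with all three translational freedoms constrained — in jaw models,
#' the nodes shared with the neurocranium at the contact patch. Optionally
#' carries prescribed non-zero displacements (used e.g. for patch tests);
#' the default is fully fixed (zero).
#'
#' @param fixed_nodes integer node indices.
#' @param prescribed optional numeric length(fixed_nodes) x 3 matrix of
#'   prescribed displacements (mm); default all zero.
#' @return an object of class `constraint_set`.
#' @export
constraint_set <- function(fixed_nodes, prescribed = NULL) {
  fixed_nodes <- as.integer(fixed_nodes)
  if (!length(fixed_nodes))
    stop("empty constraint set: the static system would retain rigid-body modes")
  o <- order(fixed_nodes)
  fixed_nodes <- fixed_nodes[o]
  if (anyDuplicated(fixed_nodes)) stop("duplicate nodes in constraint set")
  if (!is.null(prescribed)) {
    prescribed <- as.matrix(prescribed)
    if (nrow(prescribed) != length(fixed_nodes) || ncol(prescribed) != 3L)
      stop("'prescribed' must be a length(fixed_nodes) x 3 matrix")
    prescribed <- prescribed[o, , drop = FALSE]
  }
  structure(list(fixed_nodes = fixed_nodes, prescribed = prescribed),
            class = "constraint_set")
}

#' Factorize the constrained stiffness system
#'
#' Eliminates the constrained rows/columns and Cholesky-factorizes the
#' reduced matrix once, for reuse across load cases (linear load
#' combinations, sliding-removal scans).
#'
#' @param K global stiffness from [assemble_global()].
#' @param constraints a [constraint_set()].
#' @return an object of class `fe_factor`.
#' @export
fe_factorize <- function(K, constraints) {
  stopifnot(inherits(constraints, "constraint_set"))
  n_dof <- nrow(K)
  fixed_dofs <- as.vector(rbind(3L * constraints$fixed_nodes - 2L,
                                3L * constraints$fixed_nodes - 1L,
                                3L * constraints$fixed_nodes))
  free <- setdiff(seq_len(n_dof), fixed_dofs)
  Kff <- K[free, free, drop = FALSE]
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE),
                 error = function(e)
                   stop("singular reduced system: constraints do not remove all rigid-body modes"),
                 warning = function(w)
                   stop("singular reduced system: constraints do not remove all rigid-body modes"))
  structure(list(K = K, chol = ch, free = free, fixed_dofs = fixed_dofs,
                 constraints = constraints, n_dof = n_dof),
            class = "fe_factor")
}

#' Solve the linear-static equilibrium system
#'
#' Solves `K d = P` with the constrained freedoms eliminated
#' (row/column reduction, so reactions are exact), then recovers reaction
#' forces at the fixed nodes as `(K d - P)` restricted to the fixed
#' freedoms. Displacements at fixed nodes equal their prescribed values
#' (zero by default) exactly.
#'
#' @param K global stiffness, or an [fe_factorize()] result (preferred when
#'   solving several load cases on one mesh).
#' @param loads numeric n_nodes x 3 matrix of applied nodal forces (N),
#'   e.g. from [sum_muscle_loads()].
#' @param constraints a [constraint_set()]; ignored (taken from the factor)
#'   when `K` is an `fe_factor`.
#' @param tol admissible relative residual of the reduced solve.
#' @return an object of class `solution_field`: `displacements`
#'   (n x 3, mm), `reactions` (n x 3, N; non-zero only at fixed nodes),
#'   `fixed_nodes`, `residual` (relative).
#' @export
solve_linear_static <- function(K, loads, constraints = NULL, tol = 1e-8) {
  fac <- if (inherits(K, "fe_factor")) K else fe_factorize(K, constraints)
  loads <- as.matrix(loads)
  if (any(!is.finite(loads))) stop("non-finite loads")
  P <- as.vector(t(loads))
  if (length(P) != fac$n_dof) stop("loads do not match the mesh size")
  d <- numeric(fac$n_dof)
  if (!is.null(fac$constraints$prescribed))
    d[fac$fixed_dofs] <- as.vector(t(fac$constraints$prescribed))
  rhs <- P[fac$free] - as.vector(fac$K[fac$free, fac$fixed_dofs, drop = FALSE] %*%
                                   d[fac$fixed_dofs])
  d[fac$free] <- as.vector(Matrix::solve(fac$chol, rhs))
  res <- sqrt(sum((as.vector(fac$K[fac$free, , drop = FALSE] %*% d) - P[fac$free])^2))
  scale <- max(sqrt(sum(rhs^2)), .Machine$double.eps)
  residual <- res / scale
  if (residual > tol && sqrt(sum(rhs^2)) > 0)
    warning(sprintf("solver residual %.2e exceeds tolerance %.2e", residual, tol))
  r <- numeric(fac$n_dof)
  r[fac$fixed_dofs] <- as.vector(fac$K[fac$fixed_dofs, , drop = FALSE] %*% d) -
    P[fac$fixed_dofs]
  n <- fac$n_dof / 3L
  structure(list(displacements = matrix(d, n, 3L, byrow = TRUE),
                 reactions = matrix(r, n, 3L, byrow = TRUE),
                 fixed_nodes = fac$constraints$fixed_nodes,
                 residual = residual),
            class = "solution_field")
}

#' Recover element stresses from a displacement solution
#'
#' Constant stress per TET4 from the element displacement gradient:
#' the stress tensor in Voigt order, the von Mises invariant, and
#' (optionally) the principal values/directions from a symmetric
#' eigendecomposition.
#'
#' @param mesh a [tet_mesh()].
#' @param materials material table as in [assemble_global()].
#' @param solution a `solution_field` from [solve_linear_static()].
#' @param principal compute principal values and directions (default TRUE).
#' @return an object of class `stress_field`: `tensor` (m x 6 matrix,
#'   columns xx, yy, zz, xy, yz, zx, MPa), `von_mises` (length m, MPa),
#'   `principal_values` (m x 3, sorted descending), `principal_directions`
#'   (list of 3x3 orthonormal matrices, columns matching the values).
#' @export
recover_stresses <- function(mesh, materials, solution, principal = TRUE) {
  if (nrow(solution$displacements) != nrow(mesh$nodes))
    stop("solution does not match the mesh")
  m <- nrow(mesh$tets)
  mat_idx <- material_by_element(mesh, materials)
  if (inherits(materials, "elastic_material")) materials <- list(materials)
  Ds <- lapply(materials, function(mt)
    iso_elasticity_matrix(mt$youngs_modulus, mt$poisson_ratio))
  tensor <- matrix(0, m, 6L,
                   dimnames = list(NULL, c("xx", "yy", "zz", "xy", "yz", "zx")))
  for (e in seq_len(m)) {
    tet <- mesh$tets[e, ]
    sg <- tet_shape_gradients(mesh$nodes[tet, , drop = FALSE])
    B <- tet_b_matrix(sg$grads)
    de <- as.vector(t(solution$displacements[tet, , drop = FALSE]))
    tensor[e, ] <- Ds[[mat_idx[e]]] %*% (B %*% de)
  }
  vm <- sqrt(0.5 * ((tensor[, 1L] - tensor[, 2L])^2 +
                    (tensor[, 2L] - tensor[, 3L])^2 +
                    (tensor[, 3L] - tensor[, 1L])^2 +
                    6 * (tensor[, 4L]^2 + tensor[, 5L]^2 + tensor[, 6L]^2)))
  out <- list(tensor = tensor, von_mises = vm,
              principal_values = NULL, principal_directions = NULL)
  if (principal) {
    pv <- matrix(0, m, 3L)
    pd <- vector("list", m)
    for (e in seq_len(m)) {
      S <- matrix(c(tensor[e, 1L], tensor[e, 4L], tensor[e, 6L],
                    tensor[e, 4L], tensor[e, 2L], tensor[e, 5L],
                    tensor[e, 6L], tensor[e, 5L], tensor[e, 3L]), 3L, 3L)
      eig <- eigen(S, symmetric = TRUE)   # values already sorted descending
      pv[e, ] <- eig$values
      pd[[e]] <- eig$vectors
    }
    out$principal_values <- pv
    out$principal_directions <- pd
  }
  structure(out, class = "stress_field")
}

#' Resultant reaction force over a node subset
#'
#' Vector sum of the reaction forces over a subset of the fixed nodes
#' (e.g. the neurocranium contact patch); optionally its signed component
#' along a given direction.
#'
#' @param solution a `solution_field`.
#' @param subset integer node indices, all of which must be constrained.
#' @param direction optional unit 3-vector to project onto.
#' @return numeric 3-vector (N), or a scalar when `direction` is given.
#' @export
reaction_resultant <- function(solution, subset, direction = NULL) {
  subset <- as.integer(subset)
  if (!all(subset %in% solution$fixed_nodes))
    stop("subset contains unconstrained nodes")
  res <- colSums(solution$reactions[subset, , drop = FALSE])
  if (is.null(direction)) return(res)
  sum(res * direction / sqrt(sum(direction^2)))
}

#' Net force balance of a solved case
#'
#' Sum of all applied nodal loads plus all reactions; zero (to solver
#' tolerance) for any well-posed static case, mirroring the modeling
#' requirement that the whole model carries no net force.
#'
#' @param solution a `solution_field`.
#' @param loads the applied n x 3 load matrix of the solved case.
#' @return list with `net` (3-vector, N), `magnitude` (N) and `relative`
#'   (magnitude / total applied load magnitude).
#' @export
force_balance <- function(solution, loads) {
  net <- colSums(loads) + colSums(solution$reactions)
  total <- sum(sqrt(rowSums(loads^2)))
  list(net = net, magnitude = sqrt(sum(net^2)),
       relative = sqrt(sum(net^2)) / max(total, .Machine$double.eps))
}

#' Export a solved case to a legacy VTK file
#'
#' Writes the mesh with displacements as point data and von Mises /
#' principal stresses as cell data, for inspection in ParaView-class
#' viewers.
#'
#' @param mesh a [tet_mesh()].
#' @param path output `.vtk` file.
#' @param solution optional `solution_field`.
#' @param stresses optional `stress_field`.
#' @return invisibly, `path`.
#' @export
write_results_vtk <- function(mesh, path, solution = NULL, stresses = NULL) {
  cd <- NULL
  if (!is.null(stresses)) {
    cd <- list(von_mises = stresses$von_mises)
    if (!is.null(stresses$principal_values)) {
      cd$principal_1 <- stresses$principal_values[, 1L]
      cd$principal_3 <- stresses$principal_values[, 3L]
    }
  }
  write_mesh(mesh, path, format = "vtk", cell_data = cd)
  if (!is.null(solution)) {
    con <- file(path, "a"); on.exit(close(con))
    if (!length(mesh$node_sets))
      writeLines(sprintf("POINT_DATA %d", nrow(mesh$nodes)), con)
    writeLines("VECTORS displacement double", con)
    writeLines(apply(solution$displacements, 1L,
                     function(p) paste(num_fmt(p), collapse = " ")), con)
  }
  invisible(path)
}
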