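test_that("element stiffness is symmetric PSD with six rigid-body modes", {
  set.seed(3)
  mat <- elastic_material("bone", 3670, 0.3, 1L)
  for (i in 1:5) {
    coords <- canonical_simplex()$nodes + matrix(stats::rnorm(12, sd = 0.2), 4, 3)
    if (det(rbind(coords[2, ] - coords[1, ], coords[3, ] - coords[1, ],
                  coords[4, ] - coords[1, ])) <= 0) next
    Ke <- element_stiffness(coords, mat)
    expect_lt(max(abs(Ke - t(Ke))), 1e-12 * max(abs(Ke)))
    ev <- eigen(Ke, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6L)
    expect_gt(min(ev), -1e-9 * max(ev))
    # rigid translation produces zero strain energy
    for (ax in 1:3) {
      u <- rep(0, 12); u[seq(ax, 12, by = 3)] <- 1
      expect_lt(abs(t(u) %*% Ke %*% u), 1e-9 * max(abs(Ke)))
    }
  }
  expect_error(element_stiffness(canonical_simplex()$nodes[c(1, 3, 2, 4), ], mat),
               "inverted")
})

test_that("element stiffness matches an independent B'DB V evaluation", {
  # canonical simplex, E = 1 MPa, nu = 0: analytic shape gradients are
  # grad N1 = (-1,-1,-1), grad N2 = e_x, grad N3 = e_y, grad N4 = e_z.
  grads <- rbind(c(-1, -1, -1), diag(3))
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    g <- grads[i, ]; c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- g[1]; B[2, c0 + 2] <- g[2]; B[3, c0 + 3] <- g[3]
    B[4, c0 + 1] <- g[2]; B[4, c0 + 2] <- g[1]
    B[5, c0 + 2] <- g[3]; B[5, c0 + 3] <- g[2]
    B[6, c0 + 1] <- g[3]; B[6, c0 + 3] <- g[1]
  }
  D <- diag(c(1, 1, 1, 0.5, 0.5, 0.5))  # isotropic, E = 1, nu = 0
  oracle <- (1 / 6) * t(B) %*% D %*% B
  Ke <- element_stiffness(canonical_simplex()$nodes,
                          elastic_material("unit", 1, 0, 1L))
  expect_equal(as.matrix(Ke), oracle, tolerance = 1e-12)
})

test_that("global assembly scatters element matrices correctly", {
  simplex <- canonical_simplex()
  mat <- elastic_material("bone", 3670, 0.3, 1L)
  K <- assemble_global(simplex, mat)
  expect_equal(as.matrix(K), element_stiffness(simplex$nodes, mat),
               tolerance = 1e-12, ignore_attr = TRUE)

  # two disconnected tets give a block-diagonal matrix
  two <- tet_mesh(rbind(simplex$nodes, simplex$nodes + 10),
                  rbind(1:4, 5:8), watertight = FALSE)
  K2 <- as.matrix(assemble_global(two, mat))
  expect_equal(K2[1:12, 13:24], matrix(0, 12, 12), ignore_attr = TRUE)
  expect_equal(K2[1:12, 1:12], K2[13:24, 13:24])

  # tooth vs bone: identical geometry, stiffness scales with the modulus
  Kb <- assemble_global(simplex, elastic_material("bone", 3670, 0.3, 1L))
  Kt <- assemble_global(simplex, elastic_material("tooth", 70000, 0.3, 1L))
  expect_equal(as.matrix(Kt), as.matrix(Kb) * (70000 / 3670), tolerance = 1e-12)

  expect_error(assemble_global(simplex, elastic_material("x", 1, 0.3, 2L)),
               "no material covers")
  expect_error(assemble_global(simplex, list(
    elastic_material("a", 1, 0.3, 1L), elastic_material("b", 2, 0.3, 1L))),
    "more than one material")
})

test_that("the solver reproduces the uniaxial bar closed form", {
  bar <- make_bar(length = 10, cross_section = 1, resolution = 4)
  mat <- elastic_material("bone", 3670, 0, 1L)
  K <- assemble_global(bar, mat)
  cs <- constraint_set(region_node_set(bar, "fixed_end"))
  P <- end_face_loads(bar, "load_end", 1, c(1, 0, 0), weighting = "area")
  sol <- solve_linear_static(K, P, cs)
  tip <- mean(sol$displacements[region_node_set(bar, "load_end"), 1])
  expect_equal(tip, 10 / 3670, tolerance = 1e-10)  # delta = FL/(EA)
  # displacements at fixed nodes are exactly zero
  expect_identical(max(abs(sol$displacements[region_node_set(bar, "fixed_end"), ])), 0)

  # element stress sigma = F/A = 1 MPa axially, von Mises 1 MPa
  st <- recover_stresses(bar, mat, sol, principal = FALSE)
  expect_equal(st$tensor[, "xx"], rep(1, nrow(bar$tets)), tolerance = 1e-8)
  expect_equal(st$von_mises, rep(1, nrow(bar$tets)), tolerance = 1e-8)

  # reactions oppose the load: resultant (-1, 0, 0) N
  expect_equal(reaction_resultant(sol, region_node_set(bar, "fixed_end")),
               c(-1, 0, 0), tolerance = 1e-8)
  expect_equal(reaction_resultant(sol, region_node_set(bar, "fixed_end"),
                                  direction = c(0, 0, 1)), 0, tolerance = 1e-8)
  expect_error(reaction_resultant(sol, c(1L, region_node_set(bar, "load_end")[1])),
               "unconstrained")

  # zero loads give zero displacements and reactions; doubling is linear
  sol0 <- solve_linear_static(K, P * 0, cs)
  expect_equal(max(abs(sol0$displacements)), 0)
  expect_equal(max(abs(sol0$reactions)), 0)
  sol2 <- solve_linear_static(K, P * 2, cs)
  expect_equal(sol2$displacements, sol$displacements * 2, tolerance = 1e-12)
})

test_that("a uniform-strain patch test is reproduced exactly", {
  jaw <- small_jaw()
  mesh <- jaw$mesh
  mat <- elastic_material("one", 3670, 0.3, c(1L, 2L, 3L))
  # symmetric displacement-gradient tensor of a uniform strain state
  eps <- matrix(c(1e-3, 2e-4, 1.5e-4,
                  2e-4, -5e-4, 3e-4,
                  1.5e-4, 3e-4, 4e-4), 3, 3)
  boundary <- sort(unique(as.vector(boundary_facets(mesh))))
  presc <- mesh$nodes[boundary, ] %*% eps
  K <- assemble_global(mesh, mat)
  sol <- solve_linear_static(K, matrix(0, nrow(mesh$nodes), 3),
                             constraint_set(boundary, prescribed = presc))
  st <- recover_stresses(mesh, mat, sol, principal = FALSE)
  D <- devFEA:::iso_elasticity_matrix(3670, 0.3)
  voigt <- c(eps[1, 1], eps[2, 2], eps[3, 3],
             2 * eps[1, 2], 2 * eps[2, 3], 2 * eps[3, 1])
  expected <- as.numeric(D %*% voigt)
  for (k in 1:6)
    expect_equal(st$tensor[, k], rep(expected[k], nrow(mesh$tets)),
                 tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("hydrostatic strain has zero von Mises stress", {
  jaw <- small_jaw()
  sol <- list(displacements = jaw$mesh$nodes * 1e-3)  # uniform volumetric strain
  st <- recover_stresses(jaw$mesh, jaw$materials, sol, principal = FALSE)
  expect_lt(max(st$von_mises), 1e-8 * max(abs(st$tensor)))
})

test_that("principal stresses match a brute-force eigendecomposition", {
  jaw <- small_jaw()
  stage <- small_jaw_stage()
  K <- assemble_global(jaw$mesh, jaw$materials)
  cs <- constraint_set(region_node_set(jaw$mesh, "contact_neurocranium"))
  P <- sum_muscle_loads(stage_muscle_loads(stage), nrow(jaw$mesh$nodes))
  sol <- solve_linear_static(K, P, cs)
  st <- recover_stresses(jaw$mesh, jaw$materials, sol, principal = TRUE)
  set.seed(11)
  for (e in sample(nrow(jaw$mesh$tets), 25)) {
    S <- matrix(c(st$tensor[e, "xx"], st$tensor[e, "xy"], st$tensor[e, "zx"],
                  st$tensor[e, "xy"], st$tensor[e, "yy"], st$tensor[e, "yz"],
                  st$tensor[e, "zx"], st$tensor[e, "yz"], st$tensor[e, "zz"]),
                3, 3)
    ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    expect_equal(st$principal_values[e, ], ev, tolerance = 1e-10)
    expect_true(all(diff(st$principal_values[e, ]) <= 1e-12))
    V <- st$principal_directions[[e]]
    expect_equal(crossprod(V), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_true(all(st$von_mises >= 0))
})

test_that("global equilibrium holds for a solved phantom case", {
  jaw <- small_jaw()
  stage <- small_jaw_stage()
  K <- assemble_global(jaw$mesh, jaw$materials)
  cs <- constraint_set(region_node_set(jaw$mesh, "contact_neurocranium"))
  P <- sum_muscle_loads(stage_muscle_loads(stage), nrow(jaw$mesh$nodes))
  sol <- solve_linear_static(K, P, cs)
  bal <- force_balance(sol, P)
  expect_lt(bal$relative, 1e-8)
})

test_that("symmetric loads on the symmetric phantom give mirror fields", {
  jaw <- small_jaw()
  stage <- small_jaw_stage()
  K <- assemble_global(jaw$mesh, jaw$materials)
  cs <- constraint_set(region_node_set(jaw$mesh, "contact_neurocranium"))
  P <- sum_muscle_loads(stage_muscle_loads(stage), nrow(jaw$mesh$nodes))
  sol <- solve_linear_static(K, P, cs)
  st <- recover_stresses(jaw$mesh, jaw$materials, sol, principal = FALSE)

  # match mirror node pairs by reflected coordinates
  refl <- jaw$mesh$nodes
  refl[, 1] <- -refl[, 1]
  key <- function(M) paste(round(M[, 1], 9), round(M[, 2], 9), round(M[, 3], 9))
  node_map <- match(key(refl), key(jaw$mesh$nodes))
  expect_false(anyNA(node_map))
  u <- sol$displacements
  mirrored <- u[node_map, ]
  mirrored[, 1] <- -mirrored[, 1]
  scale <- max(abs(u))
  expect_lt(max(abs(u - mirrored)), 1e-8 * scale)

  # element von Mises matches across mirrored centroids
  cen <- (jaw$mesh$nodes[jaw$mesh$tets[, 1], ] + jaw$mesh$nodes[jaw$mesh$tets[, 2], ] +
            jaw$mesh$nodes[jaw$mesh$tets[, 3], ] + jaw$mesh$nodes[jaw$mesh$tets[, 4], ]) / 4
  cen_refl <- cen
  cen_refl[, 1] <- -cen_refl[, 1]
  el_map <- match(key(cen_refl), key(cen))
  expect_false(anyNA(el_map))
  expect_lt(max(abs(st$von_mises - st$von_mises[el_map])),
            1e-8 * max(st$von_mises))
})

test_that("ill-posed systems and bad inputs are rejected", {
  bar <- make_bar(2, 1, 1)
  mat <- elastic_material("bone", 3670, 0.3, 1L)
  K <- assemble_global(bar, mat)
  expect_error(constraint_set(integer(0)), "rigid-body")
  # a single fixed node leaves rotational rigid modes about it
  expect_error(
    solve_linear_static(K, matrix(0, nrow(bar$nodes), 3),
                        constraint_set(1L)),
    "singular|rigid-body")
  cs <- constraint_set(region_node_set(bar, "fixed_end"))
  P <- matrix(0, nrow(bar$nodes), 3)
  P[1, 1] <- NaN
  expect_error(solve_linear_static(K, P, cs), "non-finite")
})
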