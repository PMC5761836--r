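test_that("attachment centroids are unweighted node means", {
  mesh <- tet_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                   rbind(1:4), node_sets = list(pair = c(1L, 2L), single = 3L),
                   watertight = FALSE)
  expect_equal(attachment_centroid(mesh, "pair"), c(1, 0, 0))
  expect_equal(attachment_centroid(mesh, "single"), c(0, 1, 0))

  # brute-force mean over the generator's planted patch nodes
  jaw <- small_jaw()$mesh
  ids <- jaw$node_sets$insertion_levator_externus_4_right
  expect_equal(attachment_centroid(jaw, "insertion_levator_externus_4_right"),
               colMeans(jaw$nodes[ids, ]))
  box_lo <- apply(jaw$nodes[ids, ], 2, min)
  box_hi <- apply(jaw$nodes[ids, ], 2, max)
  cen <- attachment_centroid(jaw, "insertion_levator_externus_4_right")
  expect_true(all(cen >= box_lo & cen <= box_hi))
})

test_that("muscle direction points from insertion toward origin", {
  mesh <- tet_mesh(rbind(c(1, 1, 0), c(2, 1, 0), c(1, 2, 0), c(1, 1, 1)),
                   rbind(1:4), node_sets = list(ins = 1L, org = 4L),
                   watertight = FALSE)
  m_set <- muscle_definition("a", "median", "ins", origin_set = "org", pcsa = 1)
  expect_equal(muscle_direction(mesh, m_set), c(0, 0, 1))
  m_pt <- muscle_definition("b", "median", "ins", origin_point = c(1, 1, 1),
                            pcsa = 1)
  expect_equal(muscle_direction(mesh, m_pt), c(0, 0, 1))
  m_bad <- muscle_definition("c", "median", "ins", origin_point = c(1, 1, 0),
                             pcsa = 1)
  expect_error(muscle_direction(mesh, m_bad), "coincide")
})

test_that("force magnitude is (pair-averaged) PCSA times specific tension", {
  m1 <- muscle_definition("m", "left", "ins", origin_point = c(0, 0, 1),
                          pcsa = 0.04)
  expect_equal(muscle_force_magnitude(m1), 0.1)
  a <- muscle_definition("p", "left", "ins", origin_point = c(0, 0, 1),
                         pcsa = 0.03)
  b <- muscle_definition("p", "right", "ins", origin_point = c(0, 0, 1),
                         pcsa = 0.05)
  expect_equal(muscle_force_magnitude(a, b), 0.1)
  b$specific_tension <- 3
  expect_error(muscle_force_magnitude(a, b), "mismatched")
  expect_error(muscle_definition("z", "left", "ins",
                                 origin_point = c(0, 0, 1), pcsa = 0),
               "pcsa")
})

test_that("nodal distribution divides the total equally and conserves it", {
  mesh <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                   rbind(1:4), node_sets = list(ins = c(1L, 2L, 3L)),
                   watertight = FALSE)
  m <- muscle_definition("m", "median", "ins", origin_point = c(1, 1, 9),
                         pcsa = 0.4)
  ld <- distribute_nodal_forces(mesh, m)
  expect_s3_class(ld, "muscle_load")
  expect_equal(ld$total_force, 1.0)
  # all nodal forces are the same vector and sum to total x direction
  expect_equal(ld$nodal_forces[1, ], ld$nodal_forces[2, ])
  expect_lt(max(abs(colSums(ld$nodal_forces) -
                      ld$total_force * ld$unit_direction)), 1e-12)
  # a single-node insertion carries the whole force
  mesh1 <- tet_mesh(mesh$nodes, mesh$tets, node_sets = list(ins = 2L),
                    watertight = FALSE)
  ld1 <- distribute_nodal_forces(mesh1, m, magnitude = 1)
  expect_equal(sqrt(sum(ld1$nodal_forces[1, ]^2)), 1)
})

test_that("conservation holds across generator muscles", {
  stage <- small_jaw_stage()
  for (ld in stage_muscle_loads(stage)) {
    expect_lt(max(abs(colSums(ld$nodal_forces) -
                        ld$total_force * ld$unit_direction)), 1e-12)
    expect_equal(max(ld$nodal_forces) , max(ld$nodal_forces[1, ]))
  }
})

test_that("orientation angles reproduce the axis-endpoint conventions", {
  fr <- anatomical_frame()
  dorsal <- orientation_angles(c(0, 0, 1), fr, "right")
  expect_equal(dorsal[["rca"]], 90)
  expect_equal(dorsal[["mla"]], 90)
  rostral <- orientation_angles(c(0, 1, 0), fr, "right")
  expect_equal(rostral[["mla"]], 0)
  expect_equal(rostral[["dva"]], 90)
  caudal <- orientation_angles(c(0, -1, 0), fr, "right")
  expect_equal(caudal[["mla"]], 180)
  expect_equal(caudal[["dva"]], -90)
  lateral <- orientation_angles(c(1, 0, 0), fr, "right")
  expect_equal(lateral[["rca"]], 0)
  expect_equal(lateral[["dva"]], 0)
  expect_error(orientation_angles(c(0, 0, 0), fr), "zero")
})

test_that("orientation angles are scale invariant", {
  fr <- anatomical_frame()
  set.seed(7)
  for (i in 1:20) {
    v <- stats::rnorm(3)
    expect_equal(orientation_angles(v, fr, "right"),
                 orientation_angles(v * stats::runif(1, 0.1, 50), fr, "right"))
  }
})

test_that("mirrored muscle pairs agree after outward-lateral folding", {
  jaw <- small_jaw()
  stage <- small_jaw_stage()
  names_all <- vapply(jaw$muscles, function(m) m$name, "")
  for (nm in unique(names_all)) {
    pair <- jaw$muscles[names_all == nm]
    tri <- lapply(pair, function(m)
      orientation_angles(muscle_direction(jaw$mesh, m), stage$frame, m$side))
    expect_equal(tri[[1]], tri[[2]], tolerance = 1e-9)
    avg <- pair_average_angles(tri[[1]], tri[[2]])
    expect_equal(avg, tri[[1]], tolerance = 1e-9)
  }
  # plain arithmetic averaging
  expect_equal(pair_average_angles(c(rca = 40, mla = 10, dva = 0),
                                   c(rca = 60, mla = 30, dva = 10)),
               c(rca = 50, mla = 20, dva = 5))
})

test_that("muscle configurations round trip through YAML and JSON", {
  muscles <- small_jaw()$muscles
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_muscle_config(muscles, path)
    back <- read_muscle_config(path)
    expect_equal(length(back), length(muscles))
    expect_equal(vapply(back, function(m) m$pcsa, 1),
                 vapply(muscles, function(m) m$pcsa, 1))
    expect_equal(back[[1]]$origin_point, muscles[[1]]$origin_point)
    expect_identical(back[[3]]$side, muscles[[3]]$side)
  }
})

test_that("the shipped muscle template lists the full adductor inventory", {
  tmpl <- yaml::read_yaml(system.file("extdata", "muscles_template.yaml",
                                      package = "devFEA"))
  expect_length(tmpl$muscles, 16L)
  sides <- vapply(tmpl$muscles, function(m) m$side, "")
  expect_equal(sum(sides == "median"), 2L)
  expect_equal(sum(sides %in% c("left", "right")), 14L)
})
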