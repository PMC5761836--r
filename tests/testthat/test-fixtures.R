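test_that("the bar phantom has exact prism volume and end-face node sets", {
  bar <- make_bar(length = 10, cross_section = 1, resolution = 4)
  expect_equal(sum(element_volumes(bar)), 10)
  expect_identical(nrow(validate_mesh(bar)), 0L)
  fixed <- region_node_set(bar, "fixed_end")
  loaded <- region_node_set(bar, "load_end")
  expect_length(intersect(fixed, loaded), 0)
  expect_true(all(bar$nodes[fixed, 1] == 0))
  expect_true(all(bar$nodes[loaded, 1] == 10))
  # the sets cover the end faces completely
  expect_identical(fixed, which(bar$nodes[, 1] == 0))
  expect_identical(loaded, which(bar$nodes[, 1] == 10))
  expect_error(make_bar(resolution = 0), "resolution")
})

test_that("the jaw phantom is valid, symmetric and carries its label plan", {
  jaw <- small_jaw()
  mesh <- jaw$mesh
  expect_identical(nrow(validate_mesh(mesh)), 0L)
  expect_setequal(unique(mesh$element_region), c(1L, 2L, 3L))
  expect_true(all(c("contact_neurocranium",
                    "insertion_levator_externus_4_left",
                    "insertion_levator_externus_4_right",
                    "insertion_retractor_dorsalis_left") %in%
                    names(mesh$node_sets)))

  # nearest-neighbour mirror oracle: reflecting across the midsagittal
  # plane maps the node cloud onto itself
  refl <- mesh$nodes
  refl[, 1] <- -refl[, 1]
  key <- function(M) paste(round(M[, 1], 9), round(M[, 2], 9), round(M[, 3], 9))
  map <- match(key(refl), key(mesh$nodes))
  expect_false(anyNA(map))
  expect_lt(max(abs(refl - mesh$nodes[map, ])), 1e-9)

  # the bridge is thinner than the lobes: smaller transverse cross-section
  cen_z <- (mesh$nodes[mesh$tets[, 1], 3] + mesh$nodes[mesh$tets[, 2], 3] +
              mesh$nodes[mesh$tets[, 3], 3] + mesh$nodes[mesh$tets[, 4], 3]) / 4
  vols <- element_volumes(mesh)
  bridge_depth <- diff(range(cen_z[mesh$element_region == 3L]))
  lobe_depth <- diff(range(cen_z[mesh$element_region == 1L]))
  expect_lt(bridge_depth, lobe_depth)
  # bridge cross-sectional area (volume / x-width) below lobe value
  expect_lt(sum(vols[mesh$element_region == 3L]) / 0.4,
            sum(vols[mesh$element_region %in% c(1L, 2L)]) / 0.8)
})

test_that("phantom generation is bit-reproducible for a given spec", {
  a <- make_jaw_phantom(phantom_spec("jaw", resolution = 1, jitter = 0.05,
                                     seed = 99))
  b <- make_jaw_phantom(phantom_spec("jaw", resolution = 1, jitter = 0.05,
                                     seed = 99))
  expect_identical(a$mesh, b$mesh)
  c <- make_jaw_phantom(phantom_spec("jaw", resolution = 1, jitter = 0.05,
                                     seed = 100))
  expect_false(identical(a$mesh$nodes, c$mesh$nodes))
  expect_identical(nrow(validate_mesh(a$mesh)), 0L)
})

test_that("growth series scales volumes and PCSA with the given factors", {
  series <- make_growth_series(phantom_spec("jaw", resolution = 1), stages = 3)
  vols <- vapply(series, function(s) sum(element_volumes(s$mesh)), 1)
  expect_equal(vols[2] / vols[1], 1.26^3, tolerance = 1e-10)
  expect_equal(vols[3] / vols[2], 1.26^3, tolerance = 1e-10)
  # PCSA scales with the transverse cross-section: factor 1.26^2 per stage
  p1 <- vapply(series[[1]]$muscles, function(m) m$pcsa, 1)
  p2 <- vapply(series[[2]]$muscles, function(m) m$pcsa, 1)
  expect_equal(p2 / p1, rep(1.26^2, length(p1)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # identical factors give identical stages
  flat <- make_growth_series(phantom_spec("jaw", resolution = 1), stages = 3,
                             growth = c(1, 1, 1))
  expect_equal(flat[[1]]$mesh, flat[[3]]$mesh)
  expect_error(make_growth_series(phantom_spec("jaw", resolution = 1),
                                  stages = 1), "stages")
  expect_error(make_growth_series(phantom_spec("jaw", resolution = 1),
                                  stages = 2, growth = c(1, -1, 1)), "> 0")
})

test_that("isotropic growth leaves muscle angles unchanged", {
  series <- make_growth_series(phantom_spec("jaw", resolution = 1), stages = 3)
  tabs <- lapply(series, function(s) stage_angle_table(as_stage_spec(s)))
  expect_equal(tabs[[1]], tabs[[2]], tolerance = 1e-9)
  expect_equal(tabs[[1]], tabs[[3]], tolerance = 1e-9)
})

test_that("anisotropic dorsal growth shifts muscle angles dorsally", {
  series <- make_growth_series(phantom_spec("jaw", resolution = 1), stages = 4,
                               growth = c(1.1, 1.1, 1.4))
  tabs <- lapply(series, function(s) stage_angle_table(as_stage_spec(s)))
  # MLA approaches 90 degrees (pure dorsal) monotonically for every muscle
  for (m in seq_len(nrow(tabs[[1]]))) {
    dist90 <- vapply(tabs, function(t) abs(t$mla[m] - 90), 1)
    expect_true(all(diff(dist90) < 0))
  }
})

test_that("all phantoms in a small test matrix validate cleanly", {
  for (scale in c(0.7, 1, 1.3)) {
    ph <- make_jaw_phantom(phantom_spec("jaw", scale = scale, resolution = 1))
    expect_identical(nrow(validate_mesh(ph$mesh)), 0L)
  }
})
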