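## Deterministic synthetic phantoms: structured tetrahedral subdivision of
## primitive blocks. Every hexahedral cell is split into the six Freudenthal
## tetrahedra sharing the cell's main diagonal, which is conforming across
## neighbouring cells and needs no meshing library.

# Local corner numbering of a cell at lattice position (i,j,k):
# 1=(i,j,k) 2=(i+1,j,k) 3=(i+1,j+1,k) 4=(i,j+1,k)
# 5=(i,j,k+1) 6=(i+1,j,k+1) 7=(i+1,j+1,k+1) 8=(i,j+1,k+1)
FREUDENTHAL_TETS <- matrix(c(1L, 2L, 3L, 7L,
                             1L, 2L, 7L, 6L,
                             1L, 4L, 7L, 3L,
                             1L, 4L, 8L, 7L,
                             1L, 5L, 6L, 7L,
                             1L, 5L, 7L, 8L), ncol = 4L, byrow = TRUE)

CELL_CORNERS <- matrix(c(0L, 0L, 0L,  1L, 0L, 0L,  1L, 1L, 0L,  0L, 1L, 0L,
                         0L, 0L, 1L,  1L, 0L, 1L,  1L, 1L, 1L,  0L, 1L, 1L),
                       ncol = 3L, byrow = TRUE)

# cells: integer matrix (i, j, k) of lattice cell positions; region: tag per
# cell; spacing: 3-vector of cell sizes (mm). Lattice node (i,j,k) sits at
# origin + (i,j,k)*spacing.
lattice_to_mesh <- function(cells, region, spacing, origin = c(0, 0, 0)) {
  nc <- nrow(cells)
  corners <- matrix(0L, 8L * nc, 3L)
  for (c8 in 1:8)
    corners[seq(c8, by = 8L, length.out = nc), ] <-
      cells + rep(CELL_CORNERS[c8, ], each = nc)
  key <- paste(corners[, 1L], corners[, 2L], corners[, 3L], sep = ",")
  uniq <- !duplicated(key)
  node_lattice <- corners[uniq, , drop = FALSE]
  id <- match(key, key[uniq])
  corner_ids <- matrix(id, ncol = 8L, byrow = TRUE)
  tets <- matrix(0L, 6L * nc, 4L)
  for (t6 in 1:6)
    tets[seq(t6, by = 6L, length.out = nc), ] <-
      matrix(corner_ids[, FREUDENTHAL_TETS[t6, ]], ncol = 4L)
  nodes <- sweep(node_lattice %*% diag(spacing), 2L, origin, `+`)
  region <- rep_len(region, nc)
  list(nodes = nodes, tets = tets, lattice = node_lattice,
       element_region = rep(region, each = 6L))
}

#' Phantom specification
#'
#' Parameters for the synthetic phantom generators. `scale` sets the
#' overall size in mm (the default jaw phantom spans 1.2 x 0.8 x 0.4 mm,
#' the size class of a larval pharyngeal jaw); `resolution` multiplies the
#' structured subdivision (the default jaw phantom has 13824 elements at
#' `resolution = 2`). `growth_factor` is the per-stage, per-axis scale
#' triple of the growth series; 1.26 per axis doubles volume per stage.
#' `jitter` optionally perturbs interior nodes by a uniform fraction of the
#' cell size (mirrored so bilateral symmetry is preserved), seeded by
#' `seed`; it defaults to 0 so phantoms are bit-reproducible.
#'
#' @param kind `"jaw"` or `"bar"`.
#' @param scale overall size factor (mm per base unit).
#' @param resolution structured-subdivision multiplier (>= 1).
#' @param growth_factor per-stage per-axis scale triple (> 0).
#' @param seed integer seed for the jitter stream.
#' @param jitter interior-node perturbation as a fraction of cell size,
#'   in \[0, 0.3).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("jaw", "bar"), scale = 1, resolution = 2L,
                         growth_factor = c(1.26, 1.26, 1.26), seed = 1L,
                         jitter = 0) {
  kind <- match.arg(kind)
  resolution <- as.integer(resolution)
  if (resolution < 1L) stop("'resolution' must be >= 1")
  if (scale <= 0) stop("'scale' must be > 0")
  if (length(growth_factor) != 3L || any(growth_factor <= 0))
    stop("'growth_factor' must be a positive 3-vector")
  if (jitter < 0 || jitter >= 0.3) stop("'jitter' must be in [0, 0.3)")
  structure(list(kind = kind, scale = scale, resolution = resolution,
                 growth_factor = as.numeric(growth_factor),
                 seed = as.integer(seed), jitter = jitter),
            class = "phantom_spec")
}

#' Structured bar phantom
#'
#' Axis-aligned prism of TET4 elements along +x with square cross-section,
#' for analytic elasticity validation. Node sets `"fixed_end"` (x = 0) and
#' `"load_end"` (x = length) partition the two end faces.
#'
#' @param length bar length (mm).
#' @param cross_section cross-sectional area (mm^2); the section is square.
#' @param resolution cells across one edge of the cross-section (>= 1).
#' @return a [tet_mesh()] with region tag 1.
#' @export
make_bar <- function(length = 10, cross_section = 1, resolution = 4L) {
  resolution <- as.integer(resolution)
  if (resolution < 1L) stop("'resolution' must be >= 1")
  if (length <= 0 || cross_section <= 0) stop("bar dimensions must be > 0")
  side <- sqrt(cross_section)
  h <- side / resolution
  nx <- max(1L, as.integer(round(length / h)))
  hx <- length / nx
  cells <- as.matrix(expand.grid(i = seq_len(nx) - 1L,
                                 j = seq_len(resolution) - 1L,
                                 k = seq_len(resolution) - 1L))
  lm <- lattice_to_mesh(cells, 1L, c(hx, h, h))
  fixed <- which(lm$lattice[, 1L] == 0L)
  loaded <- which(lm$lattice[, 1L] == nx)
  tet_mesh(lm$nodes, lm$tets, lm$element_region,
           node_sets = list(fixed_end = fixed, load_end = loaded))
}

#' Nodal loads on an end face
#'
#' Builds an applied-load matrix putting a total force on the nodes of a
#' boundary node set, either divided equally (the muscle-load convention)
#' or weighted by the tributary facet area of each node (consistent with a
#' uniform traction, used for analytic validation).
#'
#' @param mesh a [tet_mesh()].
#' @param set_name node-set name covering a boundary face.
#' @param total_force total force magnitude (N).
#' @param direction force direction 3-vector (normalised internally).
#' @param weighting `"equal"` or `"area"`.
#' @return n_nodes x 3 load matrix (N).
#' @export
end_face_loads <- function(mesh, set_name, total_force, direction,
                           weighting = c("equal", "area")) {
  weighting <- match.arg(weighting)
  ids <- region_node_set(mesh, set_name)
  dir <- direction / sqrt(sum(direction^2))
  P <- matrix(0, nrow(mesh$nodes), 3L)
  if (weighting == "equal") {
    w <- rep(1 / length(ids), length(ids))
  } else {
    bf <- boundary_facets(mesh)
    on_face <- matrix(bf %in% ids, ncol = 3L)
    bf <- bf[rowSums(on_face) == 3L, , drop = FALSE]
    if (!nrow(bf)) stop(sprintf("node set '%s' spans no boundary facet", set_name))
    w <- numeric(length(ids))
    for (f in seq_len(nrow(bf))) {
      p <- mesh$nodes[bf[f, ], , drop = FALSE]
      a2 <- crossprod_3(p[2L, ] - p[1L, ], p[3L, ] - p[1L, ])
      area <- sqrt(sum(a2^2)) / 2
      w[match(bf[f, ], ids)] <- w[match(bf[f, ], ids)] + area / 3
    }
    w <- w / sum(w)
  }
  P[ids, ] <- total_force * outer(w, dir)
  P
}

crossprod_3 <- function(a, b)
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])

#' Paired-lobe jaw phantom
#'
#' Bilaterally symmetric phantom emulating a larval upper pharyngeal jaw:
#' two lobes joined by a thinner midline bridge (the engineered weak zone),
#' tooth-cap elements on the ventral occlusal band of each lobe, a dorsal
#' `contact_neurocranium` node set on the bridge roof, and three bilateral
#' muscle insertion patches with explicit dorsal origin points (emulating
#' neurocranial origins). Region tags: 1 bone lobes, 2 tooth caps,
#' 3 bridge (bone).
#'
#' The accompanying muscles carry placeholder PCSAs sized so that
#' full-contraction loads total ~0.2 N and the forces transmitted to the
#' contact patch fall in the 0.01-0.1 N range of larval jaws. The levator
#' externus 4 and levator posterior pairs pull dorso-rostrally (the biting
#' sling, transmitted from the lower jaw); the retractor dorsalis pair
#' pulls dorso-caudally and is the designated reduction pair for
#' anterior-posterior sliding removal.
#'
#' The phantom is constructed as a half-domain (x >= 0) and mirrored, so
#' the node positions and the tetrahedral connectivity are exactly
#' bilaterally symmetric.
#'
#' @param spec a [phantom_spec()] with `kind = "jaw"`.
#' @return list with `mesh` ([tet_mesh()]), `muscles` (list of
#'   [muscle_definition()]), `materials` (list of [elastic_material()]),
#'   `contact_set`, `reduction_muscle`, `biting_muscles`.
#' @export
make_jaw_phantom <- function(spec = phantom_spec("jaw")) {
  stopifnot(inherits(spec, "phantom_spec"))
  r <- spec$resolution
  if (r < 1L) stop("resolution too coarse to realize the bridge")
  s <- spec$scale
  h <- 0.1 * s / r   # lattice spacing (mm)

  # half domain x >= 0, lattice cells (u, j, k); u in 0 .. 6r-1
  grid <- as.matrix(expand.grid(u = 0:(6L * r - 1L), j = 0:(8L * r - 1L),
                                k = 0:(4L * r - 1L)))
  u <- grid[, 1L]; j <- grid[, 2L]; k <- grid[, 3L]
  lobe <- u >= 2L * r
  bridge <- u < 2L * r & j >= 2L * r & j < 6L * r & k >= 2L * r
  tooth <- lobe & k < r & j >= 2L * r & j < 6L * r
  keep <- lobe | bridge
  region <- ifelse(bridge, 3L, ifelse(tooth, 2L, 1L))[keep]
  lm <- lattice_to_mesh(grid[keep, , drop = FALSE], region, c(h, h, h))

  nodes <- lm$nodes; tets <- lm$tets; lat <- lm$lattice
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    bf <- boundary_facets(tet_mesh(nodes, tets, lm$element_region))
    interior <- setdiff(seq_len(nrow(nodes)), unique(as.vector(bf)))
    interior <- interior[lat[interior, 1L] > 0L]   # keep the midplane exact
    if (length(interior))
      nodes[interior, ] <- nodes[interior, ] +
        matrix(stats::runif(3L * length(interior), -1, 1), ncol = 3L) *
        (spec$jitter * h)
  }

  # mirror across the midsagittal plane x = 0; x = 0 nodes are shared
  off_plane <- which(lat[, 1L] > 0L)
  mirror_id <- integer(nrow(nodes))
  mirror_id[-off_plane] <- seq_len(nrow(nodes))[-off_plane]
  mirror_id[off_plane] <- nrow(nodes) + seq_along(off_plane)
  mnodes <- nodes[off_plane, , drop = FALSE]
  mnodes[, 1L] <- -mnodes[, 1L]
  nodes <- rbind(nodes, mnodes)
  mtets <- matrix(mirror_id[tets], ncol = 4L)[, c(1L, 3L, 2L, 4L), drop = FALSE]
  tets <- rbind(tets, mtets)
  element_region <- c(lm$element_region, lm$element_region)
  lat <- rbind(lat, cbind(-lat[off_plane, 1L], lat[off_plane, 2:3, drop = FALSE]))

  gx <- lat[, 1L]; gy <- lat[, 2L]; gz <- lat[, 3L]
  sets <- list(
    contact_neurocranium = which(gz == 4L * r & abs(gx) <= 2L * r &
                                   gy >= 2L * r & gy <= 6L * r),
    insertion_levator_externus_4_right = which(gx == 6L * r & gz <= 2L * r &
                                                 gy >= 3L * r & gy <= 5L * r),
    insertion_levator_externus_4_left = which(gx == -6L * r & gz <= 2L * r &
                                                gy >= 3L * r & gy <= 5L * r),
    insertion_levator_posterior_right = which(gx == 6L * r & gz <= 2L * r &
                                                gy <= 2L * r),
    insertion_levator_posterior_left = which(gx == -6L * r & gz <= 2L * r &
                                               gy <= 2L * r),
    insertion_retractor_dorsalis_right = which(gy == 0L & gz >= r & gz <= 3L * r &
                                                 gx >= 3L * r & gx <= 5L * r),
    insertion_retractor_dorsalis_left = which(gy == 0L & gz >= r & gz <= 3L * r &
                                                gx <= -3L * r & gx >= -5L * r))

  mesh <- tet_mesh(nodes, tets, element_region, node_sets = sets)

  mk <- function(name, side, origin, pcsa) {
    sgn <- if (side == "left") -1 else 1
    muscle_definition(name = name, side = side,
                      insertion_set = sprintf("insertion_%s_%s", name, side),
                      origin_point = c(sgn * origin[1L], origin[2L], origin[3L]) * s,
                      pcsa = pcsa)
  }
  muscles <- list(
    mk("levator_externus_4", "right", c(0.5, 0.9, 1.0), 0.012),
    mk("levator_externus_4", "left", c(0.5, 0.9, 1.0), 0.012),
    mk("levator_posterior", "right", c(0.55, 0.35, 0.95), 0.010),
    mk("levator_posterior", "left", c(0.55, 0.35, 0.95), 0.010),
    mk("retractor_dorsalis", "right", c(0.4, -0.7, 0.8), 0.016),
    mk("retractor_dorsalis", "left", c(0.4, -0.7, 0.8), 0.016))

  list(mesh = mesh, muscles = muscles, materials = default_materials(),
       contact_set = "contact_neurocranium",
       reduction_muscle = "retractor_dorsalis",
       biting_muscles = c("levator_externus_4", "levator_posterior"))
}

#' Allometric growth series of jaw phantoms
#'
#' Stage k of the series is the stage-1 phantom with node coordinates and
#' muscle origin points scaled by the cumulative per-axis growth factors,
#' and each muscle's PCSA scaled by the product of the two factors
#' transverse to its line of action (cross-sectional area grows with the
#' transverse section; the transverse axes are those orthogonal to the
#' dominant component of the base-stage pull direction). The default
#' isotropic factor 1.26 per axis doubles volume per stage. Deterministic
#' given the spec.
#'
#' @param spec a [phantom_spec()].
#' @param stages number of stages (>= 2).
#' @param growth per-stage per-axis scale triple, or a list of one triple
#'   per transition; defaults to `spec$growth_factor`.
#' @return list of stages, each a [make_jaw_phantom()]-shaped list plus
#'   `label`.
#' @export
make_growth_series <- function(spec = phantom_spec("jaw"), stages = 3L,
                               growth = NULL) {
  stages <- as.integer(stages)
  if (stages < 2L) stop("'stages' must be >= 2")
  if (is.null(growth)) growth <- spec$growth_factor
  if (!is.list(growth)) growth <- rep(list(as.numeric(growth)), stages - 1L)
  if (length(growth) != stages - 1L)
    stop("'growth' must give one scale triple per stage transition")
  if (any(unlist(growth) <= 0)) stop("growth factors must be > 0")

  base <- make_jaw_phantom(spec)
  base_dirs <- lapply(base$muscles, function(m) muscle_direction(base$mesh, m))
  dominant <- vapply(base_dirs, function(d) which.max(abs(d)), 1L)

  out <- vector("list", stages)
  cum <- c(1, 1, 1)
  for (k in seq_len(stages)) {
    if (k > 1L) cum <- cum * growth[[k - 1L]]
    st <- base
    st$mesh$nodes <- base$mesh$nodes %*% diag(cum)
    st$muscles <- lapply(seq_along(base$muscles), function(i) {
      m <- base$muscles[[i]]
      m$origin_point <- m$origin_point * cum
      m$pcsa <- m$pcsa * prod(cum[-dominant[i]])
      m
    })
    st$label <- sprintf("stage %d", k)
    out[[k]] <- st
  }
  out
}
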