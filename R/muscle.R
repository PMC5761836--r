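#' Muscle definition
#'
#' A muscle acting on the structural mesh: its insertion node set, its
#' origin (a node set on the same mesh or an explicit point, e.g. on the
#' unmeshed neurocranium), its physiological cross-sectional area (PCSA)
#' and specific tension. Maximal isometric force is PCSA x specific
#' tension; the default specific tension of 2.5 N mm^-2 is the literature
#' value for pharyngeal jaw muscles.
#'
#' @param name muscle name (pairs share a name and differ in `side`).
#' @param side `"left"`, `"right"` or `"median"`.
#' @param insertion_set node-set name on the structural mesh.
#' @param origin_set node-set name, or `NULL` when `origin_point` is given.
#' @param origin_point explicit origin coordinates (mm), or `NULL`.
#' @param pcsa physiological cross-sectional area (mm^2), > 0.
#' @param specific_tension force per unit PCSA (N mm^-2), > 0.
#' @return an object of class `muscle_definition`.
#' @export
muscle_definition <- function(name, side = c("right", "left", "median"),
                              insertion_set, origin_set = NULL,
                              origin_point = NULL, pcsa,
                              specific_tension = 2.5) {
  side <- match.arg(side)
  if (!is.character(insertion_set) || !nzchar(insertion_set))
    stop("'insertion_set' must be a node-set name")
  if (is.null(origin_set) == is.null(origin_point))
    stop("give exactly one of 'origin_set' or 'origin_point'")
  if (!is.null(origin_point) && length(origin_point) != 3L)
    stop("'origin_point' must be a 3-vector (mm)")
  pcsa <- as.numeric(pcsa)
  if (!is.finite(pcsa) || pcsa <= 0) stop("'pcsa' must be > 0")
  if (!is.finite(specific_tension) || specific_tension <= 0)
    stop("'specific_tension' must be > 0")
  structure(list(name = name, side = side, insertion_set = insertion_set,
                 origin_set = origin_set,
                 origin_point = if (!is.null(origin_point)) as.numeric(origin_point),
                 pcsa = pcsa, specific_tension = specific_tension),
            class = "muscle_definition")
}

#' @export
print.muscle_definition <- function(x, ...) {
  org <- if (is.null(x$origin_set))
    sprintf("point (%s) mm", paste(signif(x$origin_point, 4), collapse = ", "))
  else sprintf("set '%s'", x$origin_set)
  cat(sprintf("muscle '%s' (%s): insertion '%s' -> origin %s, PCSA %g mm^2, tension %g N/mm^2\n",
              x$name, x$side, x$insertion_set, org, x$pcsa, x$specific_tension))
  invisible(x)
}

#' Centroid of an attachment area
#'
#' Unweighted arithmetic mean of the member node coordinates of a named
#' node set (the averaged nodal coordinates of an insertion or origin
#' area).
#'
#' @param mesh a [tet_mesh()].
#' @param set_name node-set name or integer region tag.
#' @return numeric 3-vector (mm).
#' @export
attachment_centroid <- function(mesh, set_name) {
  ids <- region_node_set(mesh, set_name)
  if (!length(ids)) stop(sprintf("node set '%s' is empty", set_name))
  colMeans(mesh$nodes[ids, , drop = FALSE])
}

#' Muscle line of action
#'
#' Unit vector from the insertion centroid toward the origin centroid (or
#' explicit origin point) — the direction in which the muscle pulls the
#' structure.
#'
#' @param mesh a [tet_mesh()].
#' @param muscle a [muscle_definition()].
#' @return unit 3-vector.
#' @export
muscle_direction <- function(mesh, muscle) {
  ins <- attachment_centroid(mesh, muscle$insertion_set)
  org <- if (is.null(muscle$origin_set)) muscle$origin_point
  else attachment_centroid(mesh, muscle$origin_set)
  v <- org - ins
  len <- sqrt(sum(v^2))
  if (len < 1e-12)
    stop(sprintf("muscle '%s': insertion and origin centroids coincide", muscle$name))
  v / len
}

#' Muscle force magnitude from PCSA and specific tension
#'
#' For a single muscle, force = PCSA x specific tension. For a bilateral
#' pair, the PCSA is averaged between the left and right sides and the
#' averaged magnitude applies to each side.
#'
#' @param muscle a [muscle_definition()].
#' @param partner optional contralateral [muscle_definition()] of the pair.
#' @return force magnitude (N) applied per side.
#' @export
muscle_force_magnitude <- function(muscle, partner = NULL) {
  if (is.null(partner)) return(muscle$pcsa * muscle$specific_tension)
  if (abs(muscle$specific_tension - partner$specific_tension) > 1e-12)
    stop(sprintf("pair '%s': mismatched specific tension", muscle$name))
  mean(c(muscle$pcsa, partner$pcsa)) * muscle$specific_tension
}

#' Distribute a muscle force over its insertion nodes
#'
#' The total magnitude is divided equally among the insertion nodes, each
#' receiving (total / n) along the insertion-to-origin unit direction — so
#' a muscle producing 100 uN spread across 200 nodes puts 0.5 uN on each.
#' The nodal forces sum to the total force vector exactly.
#'
#' @param mesh a [tet_mesh()].
#' @param muscle a [muscle_definition()].
#' @param magnitude total force (N); defaults to
#'   [muscle_force_magnitude()] of `muscle` alone (pass the pair-averaged
#'   value when working with bilateral pairs).
#' @return an object of class `muscle_load`: list with `muscle`,
#'   `unit_direction`, `total_force` (N), `nodes` (insertion node indices)
#'   and `nodal_forces` (one identical force 3-vector per node, N).
#' @export
distribute_nodal_forces <- function(mesh, muscle, magnitude = NULL) {
  ids <- region_node_set(mesh, muscle$insertion_set)
  if (!length(ids)) stop(sprintf("muscle '%s': empty insertion set", muscle$name))
  if (is.null(magnitude)) magnitude <- muscle_force_magnitude(muscle)
  dir <- muscle_direction(mesh, muscle)
  per_node <- (magnitude / length(ids)) * dir
  structure(list(muscle = muscle, unit_direction = dir,
                 total_force = magnitude, nodes = ids,
                 nodal_forces = matrix(per_node, nrow = length(ids), ncol = 3L,
                                       byrow = TRUE)),
            class = "muscle_load")
}

#' Sum muscle loads into a nodal load table
#'
#' Accumulates a list of `muscle_load` objects (optionally scaled per
#' muscle) into an n_nodes x 3 applied-force matrix, the right-hand side
#' of the linear-static system.
#'
#' @param loads list of `muscle_load` objects.
#' @param n_nodes number of mesh nodes.
#' @param scale named numeric vector of per-muscle multipliers, matched by
#'   muscle name (default 1 for every muscle).
#' @return numeric n_nodes x 3 matrix of applied nodal forces (N).
#' @export
sum_muscle_loads <- function(loads, n_nodes, scale = NULL) {
  P <- matrix(0, n_nodes, 3L)
  for (ld in loads) {
    s <- 1
    if (!is.null(scale) && ld$muscle$name %in% names(scale))
      s <- scale[[ld$muscle$name]]
    P[ld$nodes, ] <- P[ld$nodes, ] + s * ld$nodal_forces
  }
  P
}

#' Three-axis muscle orientation angles
#'
#' Expresses a pull direction in the rotational-angle conventions used for
#' ontogenetic muscle comparisons. With l, r, d the outward-lateral,
#' rostral and dorsal components of the unit direction:
#'
#' * RCA (rostro-caudal axis) = atan2(|d|, |l|), from 0 (lateral) to 90
#'   degrees (dorsal);
#' * MLA (medio-lateral axis) = atan2(d, r), 0 rostral, 90 dorsal, 180
#'   caudal (ventral-pointing vectors give negative values);
#' * DVA (dorso-ventral axis) = atan2(r, |l|), +90 rostral, 0 lateral,
#'   -90 caudal.
#'
#' The outward lateral component is +lateral for right/median structures
#' and -lateral for left ones, which folds the left/right mirroring into
#' the angles: a perfectly mirrored pair yields identical triples.
#'
#' @param direction 3-vector (any positive length; normalised internally).
#' @param frame an [anatomical_frame()].
#' @param side `"right"`, `"left"` or `"median"`.
#' @return named numeric vector `c(rca, mla, dva)` in degrees.
#' @export
orientation_angles <- function(direction, frame = anatomical_frame(),
                               side = c("right", "left", "median")) {
  side <- match.arg(side)
  len <- sqrt(sum(direction^2))
  if (len < 1e-12) stop("zero-length direction")
  u <- direction / len
  lat <- sum(u * frame$lateral) * if (side == "left") -1 else 1
  ros <- sum(u * frame$rostral)
  dor <- sum(u * frame$dorsal)
  deg <- 180 / pi
  c(rca = atan2(abs(dor), abs(lat)) * deg,
    mla = atan2(dor, ros) * deg,
    dva = atan2(ros, abs(lat)) * deg)
}

#' Average the orientation angles of a bilateral pair
#'
#' Component-wise arithmetic mean of two angle triples; the left/right
#' mirroring is already folded into the outward-lateral convention of
#' [orientation_angles()], so a perfectly mirrored pair averages to either
#' side's triple.
#'
#' @param left,right named angle triples `c(rca, mla, dva)` (degrees).
#' @return named angle triple (degrees).
#' @export
pair_average_angles <- function(left, right) {
  (left[c("rca", "mla", "dva")] + right[c("rca", "mla", "dva")]) / 2
}

#' Read and write muscle configuration files
#'
#' Muscle inventories travel as YAML or JSON: a list of entries with the
#' [muscle_definition()] fields (`name`, `side`, `insertion_set`, one of
#' `origin_set`/`origin_point`, `pcsa`, `specific_tension`). A template
#' with the full bilateral adductor inventory ships in
#' `system.file("extdata", "muscles_template.yaml", package = "devFEA")`.
#'
#' @param path file to read or write (`.yaml`/`.yml` or `.json`).
#' @return `read_muscle_config()`: list of [muscle_definition()] objects.
#' @export
read_muscle_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  else stop(sprintf("unsupported muscle config extension '.%s'", ext))
  if (!is.null(raw$muscles)) raw <- raw$muscles
  lapply(raw, function(m)
    muscle_definition(name = m$name, side = m$side %||% "median",
                      insertion_set = m$insertion_set,
                      origin_set = m$origin_set,
                      origin_point = if (!is.null(m$origin_point)) unlist(m$origin_point),
                      pcsa = m$pcsa,
                      specific_tension = m$specific_tension %||% 2.5))
}

#' @rdname read_muscle_config
#' @param muscles list of [muscle_definition()] objects.
#' @export
write_muscle_config <- function(muscles, path) {
  entries <- lapply(muscles, function(m)
    Filter(Negate(is.null),
           list(name = m$name, side = m$side, insertion_set = m$insertion_set,
                origin_set = m$origin_set, origin_point = m$origin_point,
                pcsa = m$pcsa, specific_tension = m$specific_tension)))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(list(muscles = entries), path)
  else if (ext == "json")
    jsonlite::write_json(list(muscles = entries), path, auto_unbox = TRUE,
                         digits = NA)
  else stop(sprintf("unsupported muscle config extension '.%s'", ext))
  invisible(path)
}
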