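#' Stage specification
#'
#' Bundles one developmental stage for the two-step analysis: the labeled
#' mesh, its muscle inventory, the fixed neurocranium contact set, the
#' material table, the muscle pair rescaled to remove anterior-posterior
#' sliding, and the muscles whose transmitted force constitutes the bite.
#'
#' @param label stage label (e.g. `"6 dpf"`); must be unique in a series.
#' @param mesh a [tet_mesh()].
#' @param muscles list of [muscle_definition()].
#' @param contact_set node-set name of the fixed contact patch.
#' @param materials list of [elastic_material()].
#' @param reduction_muscle name of the muscle pair used for sliding
#'   removal.
#' @param biting_muscles character vector of muscle names whose load
#'   resultant is reported as bite force.
#' @param frame an [anatomical_frame()]; the rostral axis is the
#'   anterior-posterior direction.
#' @return an object of class `stage_spec`.
#' @export
stage_spec <- function(label, mesh, muscles, contact_set, materials,
                       reduction_muscle,
                       biting_muscles = c("levator_externus_4",
                                          "levator_posterior"),
                       frame = anatomical_frame()) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (!length(region_node_set(mesh, contact_set)))
    stop("contact set is empty")
  names_all <- vapply(muscles, function(m) m$name, "")
  if (!reduction_muscle %in% names_all)
    stop(sprintf("reduction muscle '%s' is not in the muscle list", reduction_muscle))
  if (!all(biting_muscles %in% names_all))
    stop("some biting muscles are not in the muscle list")
  structure(list(label = label, mesh = mesh, muscles = muscles,
                 contact_set = contact_set, materials = materials,
                 reduction_muscle = reduction_muscle,
                 biting_muscles = biting_muscles, frame = frame),
            class = "stage_spec")
}

#' @rdname stage_spec
#' @param phantom a [make_jaw_phantom()] result (or one stage of
#'   [make_growth_series()]).
#' @export
as_stage_spec <- function(phantom, label = phantom$label %||% "stage 1") {
  stage_spec(label = label, mesh = phantom$mesh, muscles = phantom$muscles,
             contact_set = phantom$contact_set, materials = phantom$materials,
             reduction_muscle = phantom$reduction_muscle,
             biting_muscles = phantom$biting_muscles)
}

#' Build the muscle load set of a stage
#'
#' Distributes every muscle over its insertion nodes with pair-averaged
#' force magnitudes: the PCSA of each left/right pair is averaged and the
#' averaged magnitude applied per side; median muscles use their own PCSA.
#'
#' @param stage a [stage_spec()].
#' @return named list of `muscle_load` objects (names `<muscle>_<side>`).
#' @export
stage_muscle_loads <- function(stage) {
  names_all <- vapply(stage$muscles, function(m) m$name, "")
  loads <- list()
  for (i in seq_along(stage$muscles)) {
    m <- stage$muscles[[i]]
    partner_idx <- which(names_all == m$name & seq_along(names_all) != i)
    mag <- if (length(partner_idx) == 1L)
      muscle_force_magnitude(m, stage$muscles[[partner_idx]])
    else muscle_force_magnitude(m)
    loads[[paste(m$name, m$side, sep = "_")]] <-
      distribute_nodal_forces(stage$mesh, m, magnitude = mag)
  }
  loads
}

# Elements within `rings` rings of a node set: ring 0 = elements touching
# the set, each further ring adds elements sharing a node with the previous.
elements_near_nodes <- function(mesh, node_ids, rings = 1L) {
  touch <- function(ids)
    which(rowSums(matrix(mesh$tets %in% ids, ncol = 4L)) > 0L)
  elems <- touch(node_ids)
  for (i in seq_len(rings)) {
    nodes <- unique(as.vector(mesh$tets[elems, , drop = FALSE]))
    elems <- touch(nodes)
  }
  elems
}

#' Von Mises hotspot outside the load and contact zones
#'
#' Maximum per-element von Mises stress, excluding elements within one
#' ring of the insertion and contact node sets — a reproducible rule
#' standing in for case-by-case visual outlier screening: stresses right
#' under applied nodal forces or fixed nodes are artifacts of discrete
#' load/constraint application.
#'
#' @param mesh a [tet_mesh()].
#' @param von_mises per-element von Mises stress (MPa).
#' @param exclude_sets character vector of node-set names to exclude
#'   around.
#' @param rings number of element rings to exclude (default 1).
#' @return list with `element` (index) and `von_mises` (MPa).
#' @export
stress_hotspot <- function(mesh, von_mises, exclude_sets, rings = 1L) {
  excl <- integer(0)
  for (s in exclude_sets)
    excl <- union(excl, elements_near_nodes(mesh, region_node_set(mesh, s), rings))
  keep <- setdiff(seq_along(von_mises), excl)
  if (!length(keep)) stop("hotspot exclusion removed every element")
  e <- keep[which.max(von_mises[keep])]
  list(element = e, von_mises = von_mises[e])
}

#' Literal reduction-factor arithmetic
#'
#' The printed reduction relation `X = (F_total - F_old) / F_old`, applied
#' to the signed anterior-posterior force components: `F_total` from all
#' muscles, `F_old` from the pair to be reduced. `X` must lie in \[0, 1\]
#' to be a feasible reduction; values outside are flagged infeasible
#' rather than clamped.
#'
#' @param f_total_ap signed anterior-posterior component of all muscle
#'   forces (N).
#' @param f_old_ap signed anterior-posterior component of the reduction
#'   pair (N); must be non-zero.
#' @return an object of class `reduction_result` with `x_factor`,
#'   `feasible`, `f_total_ap`, `f_old_ap`.
#' @export
reduction_factor <- function(f_total_ap, f_old_ap) {
  if (!is.finite(f_old_ap) || f_old_ap == 0)
    stop("'f_old_ap' must be non-zero")
  x <- (f_total_ap - f_old_ap) / f_old_ap
  structure(list(x_factor = x, feasible = x >= 0 && x <= 1,
                 f_total_ap = f_total_ap, f_old_ap = f_old_ap,
                 scale = NA_real_, residual_ap_after = NA_real_),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("reduction factor X = %.6g (%s)\n", x$x_factor,
              if (x$feasible) "feasible" else "infeasible: outside [0, 1]"))
  cat(sprintf("  F_total AP = %.6g N, F_old AP = %.6g N\n",
              x$f_total_ap, x$f_old_ap))
  if (is.finite(x$scale))
    cat(sprintf("  applied pair scale s* = %.6g, residual AP after = %.3g N\n",
                x$scale, x$residual_ap_after))
  invisible(x)
}

#' Remove anterior-posterior sliding by rescaling one muscle pair
#'
#' The full-contraction solution leaves a net anterior-posterior (AP,
#' rostral-axis) reaction at the contact patch — sliding of the jaw along
#' the neurocranium. Because the system is linear, the net AP reaction is
#' affine in the scale `s` applied to the chosen pair; two solves (the
#' model without the pair, and the pair alone) give the closed-form scale
#' `s* = -AP_without_pair / AP_pair_unit` that zeroes it. The reduced case
#' is then solved at `s*` and the residual AP reaction verified.
#'
#' The literal printed reduction factor `X = (F_total - F_old)/F_old` is
#' computed alongside from the applied AP components and reported with the
#' discrepancy `s* + X` (global equilibrium makes the two identical up to
#' solver tolerance, with opposite sign conventions).
#'
#' @param stage a [stage_spec()].
#' @param pair muscle name to rescale; default the stage's
#'   `reduction_muscle`.
#' @param factor optional [fe_factorize()] result to reuse.
#' @param loads optional [stage_muscle_loads()] result to reuse.
#' @return list with `reduction` (a `reduction_result` carrying the
#'   applied scale `s*` and AP residual), `solution` (the reduced-case
#'   `solution_field`), `loads` (the reduced n x 3 load matrix).
#' @export
zero_ap_sliding <- function(stage, pair = stage$reduction_muscle,
                            factor = NULL, loads = NULL) {
  if (is.null(loads)) loads <- stage_muscle_loads(stage)
  is_pair <- vapply(loads, function(ld) ld$muscle$name == pair, TRUE)
  if (!any(is_pair)) stop(sprintf("muscle '%s' not found", pair))
  n <- nrow(stage$mesh$nodes)
  ap <- stage$frame$rostral
  P_pair <- sum_muscle_loads(loads[is_pair], n)
  P_rest <- sum_muscle_loads(loads[!is_pair], n)
  total_mag <- sum(sqrt(rowSums((P_pair + P_rest)^2)))

  if (is.null(factor)) {
    K <- assemble_global(stage$mesh, stage$materials)
    factor <- fe_factorize(K, constraint_set(region_node_set(stage$mesh,
                                                             stage$contact_set)))
  }
  ap_reaction <- function(P) {
    sol <- solve_linear_static(factor, P)
    sum(colSums(sol$reactions) * ap)
  }
  r_rest <- ap_reaction(P_rest)
  r_pair <- ap_reaction(P_pair)
  if (abs(r_pair) <= 1e-12 * max(total_mag, .Machine$double.eps))
    stop(sprintf("pair '%s' contributes no anterior-posterior component", pair))
  s_star <- -r_rest / r_pair

  f_old_ap <- sum(colSums(P_pair) * ap)
  f_total_ap <- sum(colSums(P_pair + P_rest) * ap)
  red <- reduction_factor(f_total_ap, f_old_ap)

  P_red <- P_rest + s_star * P_pair
  sol <- solve_linear_static(factor, P_red)
  red$scale <- s_star
  red$residual_ap_after <- abs(sum(colSums(sol$reactions) * ap))
  red$discrepancy <- s_star + red$x_factor
  list(reduction = red, solution = sol, loads = P_red)
}

#' Force normal to the neurocranium contact patch
#'
#' The force the structure exerts on the neurocranium — the negative of
#' the resultant reaction over the contact node set — projected on the
#' mean outward normal of the contact surface (area-weighted over the
#' boundary facets whose nodes all belong to the set). Positive values
#' are compression against the neurocranium. The dorsal-axis projection
#' is reported alongside, since a single global axis and the local patch
#' normal coincide only for a flat dorsal patch.
#'
#' @param stage a [stage_spec()].
#' @param solution a `solution_field` of the (typically reduced) case.
#' @return list with `normal_force` (N, along the outward patch normal;
#'   positive = compression), `dorsal_force` (N), `patch_normal` (unit
#'   3-vector), `reaction` (reaction resultant on the structure,
#'   3-vector, N).
#' @export
neurocranium_normal_force <- function(stage, solution) {
  ids <- region_node_set(stage$mesh, stage$contact_set)
  bf <- boundary_facets(stage$mesh)
  on_patch <- matrix(bf %in% ids, ncol = 3L)
  bf <- bf[rowSums(on_patch) == 3L, , drop = FALSE]
  if (!nrow(bf)) stop("contact patch spans no boundary facet")
  nrm <- c(0, 0, 0)
  for (f in seq_len(nrow(bf))) {
    p <- stage$mesh$nodes[bf[f, ], , drop = FALSE]
    nrm <- nrm + crossprod_3(p[2L, ] - p[1L, ], p[3L, ] - p[1L, ]) / 2
  }
  len <- sqrt(sum(nrm^2))
  if (len < 1e-12) stop("contact patch has a degenerate (zero-area) mean normal")
  nrm <- nrm / len
  res <- reaction_resultant(solution, ids)
  list(normal_force = sum(-res * nrm),
       dorsal_force = sum(-res * stage$frame$dorsal),
       patch_normal = nrm, reaction = res)
}

#' Bite force of a stage
#'
#' Magnitude of the vector resultant of the unreduced biting-muscle loads
#' (both sides) — the adduction force the muscle sling transmits from the
#' lower jaw. By construction it uses full muscle forces: bite benefits
#' from shearing and needs no static compression, so no sliding reduction
#' applies.
#'
#' @param stage a [stage_spec()].
#' @param loads optional [stage_muscle_loads()] result to reuse.
#' @return bite force magnitude (N), with the resultant vector as
#'   attribute `"vector"`.
#' @export
bite_force <- function(stage, loads = NULL) {
  if (is.null(loads)) loads <- stage_muscle_loads(stage)
  sel <- vapply(loads, function(ld) ld$muscle$name %in% stage$biting_muscles, TRUE)
  if (!any(sel)) stop("biting muscle list matches no loads")
  v <- c(0, 0, 0)
  for (ld in loads[sel]) v <- v + ld$total_force * ld$unit_direction
  structure(sqrt(sum(v^2)), vector = v)
}

#' Orientation-angle table of a stage
#'
#' Per-muscle angle triples in the three-axis convention, computed per
#' side with the outward-lateral convention and then averaged between the
#' members of each pair.
#'
#' @param stage a [stage_spec()].
#' @return data.frame with columns `muscle`, `rca`, `mla`, `dva`
#'   (degrees).
#' @export
stage_angle_table <- function(stage) {
  names_all <- vapply(stage$muscles, function(m) m$name, "")
  out <- list()
  for (nm in unique(names_all)) {
    members <- stage$muscles[names_all == nm]
    triples <- lapply(members, function(m)
      orientation_angles(muscle_direction(stage$mesh, m), stage$frame, m$side))
    tri <- if (length(triples) == 2L)
      pair_average_angles(triples[[1L]], triples[[2L]])
    else triples[[1L]]
    out[[nm]] <- data.frame(muscle = nm, rca = tri[["rca"]], mla = tri[["mla"]],
                            dva = tri[["dva"]])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the two-step analysis of one stage
#'
#' Step one solves full contraction (all muscles at full force acting
#' simultaneously) and records the neurocranium reaction, the bite force,
#' the force balance and the von Mises hotspot outside the load/contact
#' zones. Step two removes anterior-posterior sliding by rescaling the
#' reduction pair ([zero_ap_sliding()]) and records the force normal to
#' the neurocranium in the reduced, purely compressive case. Muscle
#' orientation angles are reported pair-averaged.
#'
#' @param stage a [stage_spec()].
#' @param reduce run the sliding-removal step (default TRUE).
#' @return an object of class `stage_report`.
#' @export
run_stage <- function(stage, reduce = TRUE) {
  loads <- stage_muscle_loads(stage)
  K <- assemble_global(stage$mesh, stage$materials)
  fac <- fe_factorize(K, constraint_set(region_node_set(stage$mesh,
                                                        stage$contact_set)))
  P <- sum_muscle_loads(loads, nrow(stage$mesh$nodes))
  sol <- solve_linear_static(fac, P)
  stresses <- recover_stresses(stage$mesh, stage$materials, sol,
                               principal = FALSE)
  insertion_sets <- vapply(stage$muscles, function(m) m$insertion_set, "")
  hot <- stress_hotspot(stage$mesh, stresses$von_mises,
                        c(stage$contact_set, unique(insertion_sets)))
  bal <- force_balance(sol, P)
  neuro <- reaction_resultant(sol, region_node_set(stage$mesh, stage$contact_set))
  bf <- bite_force(stage, loads)

  report <- list(
    label = stage$label,
    full_contraction = list(
      neurocranium_force = neuro,
      neurocranium_force_magnitude = sqrt(sum(neuro^2)),
      bite_force = as.numeric(bf),
      bite_force_vector = attr(bf, "vector"),
      hotspot = hot,
      balance = bal),
    reduced = NULL,
    angles = stage_angle_table(stage))

  if (reduce) {
    za <- zero_ap_sliding(stage, factor = fac, loads = loads)
    nn <- neurocranium_normal_force(stage, za$solution)
    report$reduced <- list(reduction = za$reduction,
                           normal_force = nn$normal_force,
                           dorsal_force = nn$dorsal_force,
                           patch_normal = nn$patch_normal)
  }
  structure(report, class = "stage_report",
            solution = sol, stresses = stresses, factor = fac, loads = P)
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("stage report '%s'\n", x$label))
  fc <- x$full_contraction
  cat(sprintf("  full contraction: |neurocranium force| %.4g N, bite force %.4g N\n",
              fc$neurocranium_force_magnitude, fc$bite_force))
  cat(sprintf("  hotspot: element %d, von Mises %.4g MPa (balance %.2e relative)\n",
              fc$hotspot$element, fc$hotspot$von_mises, fc$balance$relative))
  if (!is.null(x$reduced))
    cat(sprintf("  reduced: normal force %.4g N (pair scale %.4g, residual AP %.2e N)\n",
                x$reduced$normal_force, x$reduced$reduction$scale,
                x$reduced$reduction$residual_ap_after))
  invisible(x)
}

#' Compare stage reports across an ontogenetic series
#'
#' Percent changes between consecutive stages are later/earlier ratios
#' times 100 (so an "increase of 337%" means the later value is 3.37x the
#' earlier one — the ratio convention, not (later-earlier)/earlier), for
#' bite force, neurocranium force magnitudes and the hotspot stress.
#' Angle changes are later-minus-earlier differences per muscle and axis.
#'
#' @param reports list of `stage_report` objects in chronological order.
#' @return an object of class `ontogeny_series`: `stages` (metric table),
#'   `percent_changes`, `angle_changes`.
#' @export
compare_ontogeny <- function(reports) {
  if (length(reports) < 2L) stop("need at least two stages")
  labels <- vapply(reports, function(r) r$label, "")
  if (anyDuplicated(labels)) stop("duplicate stage labels")
  metric <- function(r) c(
    bite_force = r$full_contraction$bite_force,
    neurocranium_force = r$full_contraction$neurocranium_force_magnitude,
    normal_force = if (!is.null(r$reduced)) r$reduced$normal_force else NA_real_,
    max_von_mises = r$full_contraction$hotspot$von_mises)
  tab <- t(vapply(reports, metric, numeric(4L)))
  stages <- data.frame(label = labels, tab)

  pc <- list()
  for (k in 2:length(reports)) {
    ratio <- 100 * tab[k, ] / tab[k - 1L, ]
    pc[[k - 1L]] <- data.frame(from = labels[k - 1L], to = labels[k],
                               metric = colnames(tab), percent = unname(ratio))
  }
  percent_changes <- do.call(rbind, pc)
  rownames(percent_changes) <- NULL

  ac <- list()
  for (k in 2:length(reports)) {
    a0 <- reports[[k - 1L]]$angles; a1 <- reports[[k]]$angles
    mm <- merge(a0, a1, by = "muscle", suffixes = c("_from", "_to"))
    ac[[k - 1L]] <- data.frame(from = labels[k - 1L], to = labels[k],
                               muscle = mm$muscle,
                               d_rca = mm$rca_to - mm$rca_from,
                               d_mla = mm$mla_to - mm$mla_from,
                               d_dva = mm$dva_to - mm$dva_from)
  }
  angle_changes <- do.call(rbind, ac)
  rownames(angle_changes) <- NULL

  structure(list(stages = stages, percent_changes = percent_changes,
                 angle_changes = angle_changes),
            class = "ontogeny_series")
}

#' @export
print.ontogeny_series <- function(x, ...) {
  cat("ontogeny series\n")
  print(x$stages)
  cat("percent changes (100 x later/earlier):\n")
  print(x$percent_changes)
  invisible(x)
}

#' Write a stage report to disk
#'
#' Writes `<label>.json` (forces, reduction factors, hotspot, angles),
#' `<label>_angles.csv` (the pair-averaged angle table) and, when the
#' solved fields are attached, `<label>.vtk` with displacements and von
#' Mises stress.
#'
#' @param report a `stage_report`.
#' @param dir output directory (created if needed).
#' @param mesh the stage mesh (required for the VTK export).
#' @return invisibly, the JSON path.
#' @export
write_stage_report <- function(report, dir, mesh = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slug <- gsub("[^A-Za-z0-9_.-]+", "_", report$label)
  js <- list(
    stage_label = report$label,
    forces = list(
      bite_force = report$full_contraction$bite_force,
      neurocranium_force = report$full_contraction$neurocranium_force_magnitude,
      normal_force = report$reduced$normal_force),
    x_factor = report$reduced$reduction$x_factor,
    pair_scale = report$reduced$reduction$scale,
    hotspot = report$full_contraction$hotspot,
    balance_relative = report$full_contraction$balance$relative,
    angles = report$angles)
  path <- file.path(dir, paste0(slug, ".json"))
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$angles, file.path(dir, paste0(slug, "_angles.csv")),
                   row.names = FALSE)
  if (!is.null(mesh) && !is.null(attr(report, "solution")))
    write_results_vtk(mesh, file.path(dir, paste0(slug, ".vtk")),
                      solution = attr(report, "solution"),
                      stresses = attr(report, "stresses"))
  invisible(path)
}
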