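#' Labeled tetrahedral mesh
#'
#' `tet_mesh()` builds the central mesh container: node coordinates (mm),
#' 4-node tetrahedra, an integer region tag per element, and named node
#' sets (muscle attachments, the neurocranium contact patch, ...).
#' Node indices are 1-based throughout the package; file readers translate
#' 0-based dialects on ingest.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in mm.
#' @param tets integer matrix, one row per element, four 1-based node
#'   indices per row in positive-volume order.
#' @param element_region integer vector of region tags, one per element.
#' @param node_sets named list of integer vectors of node indices.
#' @param watertight logical; whether the boundary surface is expected to
#'   form a closed 2-manifold (checked by [validate_mesh()]).
#' @return an object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, element_region = NULL, node_sets = list(),
                     watertight = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("'nodes' must have 3 columns (x, y, z in mm)")
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(tets) != 4L) stop("'tets' must have 4 columns (non-tetrahedral cells)")
  n <- nrow(nodes)
  if (any(tets < 1L | tets > n)) stop("dangling node references in 'tets'")
  if (is.null(element_region)) element_region <- rep(1L, nrow(tets))
  element_region <- as.integer(element_region)
  if (length(element_region) != nrow(tets))
    stop("'element_region' must have one tag per element")
  if (!is.list(node_sets)) stop("'node_sets' must be a named list")
  if (length(node_sets) && (is.null(names(node_sets)) || any(!nzchar(names(node_sets)))))
    stop("every node set must be named")
  node_sets <- lapply(node_sets, function(s) {
    s <- sort(unique(as.integer(s)))
    if (length(s) && (min(s) < 1L || max(s) > n))
      stop("node set references a node index out of range")
    s
  })
  structure(
    list(nodes = nodes, tets = tets, element_region = element_region,
         node_sets = node_sets, watertight = isTRUE(watertight)),
    class = "tet_mesh"
  )
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d TET4 elements, %d region tag(s), %d node set(s)\n",
              nrow(x$nodes), nrow(x$tets),
              length(unique(x$element_region)), length(x$node_sets)))
  if (length(x$node_sets))
    cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  invisible(x)
}

#' Signed and absolute element volumes
#'
#' Volume of each tetrahedron, `det([p2-p1, p3-p1, p4-p1]) / 6` (mm^3).
#' `element_volumes()` returns absolute volumes; `signed_volumes()` keeps
#' the sign carried by the node ordering (negative = inverted element).
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector, one volume per element (mm^3).
#' @export
element_volumes <- function(mesh) abs(signed_volumes(mesh))

#' @rdname element_volumes
#' @export
signed_volumes <- function(mesh) {
  p <- mesh$nodes
  t1 <- mesh$tets[, 1L]; t2 <- mesh$tets[, 2L]
  t3 <- mesh$tets[, 3L]; t4 <- mesh$tets[, 4L]
  ax <- p[t2, 1L] - p[t1, 1L]; ay <- p[t2, 2L] - p[t1, 2L]; az <- p[t2, 3L] - p[t1, 3L]
  bx <- p[t3, 1L] - p[t1, 1L]; by <- p[t3, 2L] - p[t1, 2L]; bz <- p[t3, 3L] - p[t1, 3L]
  cx <- p[t4, 1L] - p[t1, 1L]; cy <- p[t4, 2L] - p[t1, 2L]; cz <- p[t4, 3L] - p[t1, 3L]
  (ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) + az * (bx * cy - by * cx)) / 6
}

# Outward-oriented faces of each tet, assuming positive node ordering.
# Returns a (4M x 3) integer matrix; rows 4e-3 .. 4e belong to element e.
tet_faces <- function(tets) {
  a <- tets[, 1L]; b <- tets[, 2L]; c <- tets[, 3L]; d <- tets[, 4L]
  m <- nrow(tets)
  out <- matrix(0L, 4L * m, 3L)
  idx <- seq_len(m)
  out[4L * idx - 3L, ] <- cbind(a, c, b)
  out[4L * idx - 2L, ] <- cbind(a, b, d)
  out[4L * idx - 1L, ] <- cbind(a, d, c)
  out[4L * idx, ]      <- cbind(b, c, d)
  out
}

facet_key <- function(faces) {
  srt <- t(apply(faces, 1L, sort))
  paste(srt[, 1L], srt[, 2L], srt[, 3L], sep = "-")
}

#' Boundary facets of a tetrahedral mesh
#'
#' Facets incident to exactly one tetrahedron, oriented outward (normals
#' point away from the mesh interior when elements are positively ordered).
#'
#' @param mesh a [tet_mesh()].
#' @return integer matrix with one boundary triangle (3 node indices) per
#'   row; attribute `"element"` gives the owning element of each facet.
#' @export
boundary_facets <- function(mesh) {
  faces <- tet_faces(mesh$tets)
  key <- facet_key(faces)
  cnt <- table(key)
  keep <- cnt[key] == 1L
  out <- faces[keep, , drop = FALSE]
  attr(out, "element") <- rep(seq_len(nrow(mesh$tets)), each = 4L)[keep]
  out
}

# TRUE when every edge of a triangle soup is used by exactly two triangles
# (a closed 2-manifold without border).
surface_is_closed <- function(facets) {
  if (!nrow(facets)) return(FALSE)
  e <- rbind(facets[, c(1L, 2L)], facets[, c(2L, 3L)], facets[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]), sep = "-")
  all(table(key) == 2L)
}

#' Validate a tetrahedral mesh
#'
#' Reporting-only check of the mesh invariants: in-range connectivity,
#' strictly positive element volumes, duplicate nodes within `tol`, and a
#' closed boundary surface when the mesh is flagged watertight. The mesh is
#' never repaired; each violation is itemised with the offending indices.
#'
#' @param mesh a [tet_mesh()].
#' @param tol duplicate-node tolerance (mm).
#' @param facets optional boundary-facet matrix to check instead of the one
#'   extracted from `mesh` (useful to audit an externally edited surface).
#' @return data.frame with columns `type`, `index`, `detail`; zero rows iff
#'   all invariants hold.
#' @export
validate_mesh <- function(mesh, tol = 1e-9, facets = NULL) {
  bad <- list()
  rep_row <- function(type, index, detail)
    data.frame(type = type, index = index, detail = detail,
               stringsAsFactors = FALSE)

  sv <- signed_volumes(mesh)
  inv <- which(sv <= 0)
  if (length(inv))
    bad[[length(bad) + 1L]] <- rep_row("inverted_element", inv,
                                       sprintf("signed volume %.3g mm^3", sv[inv]))

  # duplicate nodes within tolerance: grid hash on tol-sized cells
  if (nrow(mesh$nodes) > 1L) {
    key <- apply(round(mesh$nodes / max(tol, .Machine$double.xmin)), 1L,
                 paste, collapse = ",")
    dup <- which(duplicated(key))
    if (length(dup))
      bad[[length(bad) + 1L]] <- rep_row("duplicate_node", dup,
                                         sprintf("within %g mm of an earlier node", tol))
  }

  if (mesh$watertight) {
    f <- if (is.null(facets)) boundary_facets(mesh) else facets
    if (!surface_is_closed(f))
      bad[[length(bad) + 1L]] <- rep_row("open_surface", NA_integer_,
                                         "boundary surface is not a closed 2-manifold")
  }

  if (length(bad)) do.call(rbind, bad)
  else data.frame(type = character(), index = integer(), detail = character(),
                  stringsAsFactors = FALSE)
}

#' Nodes of a region or named node set
#'
#' Resolves a selector to node indices: an integer selects all nodes used
#' by elements carrying that region tag; a character string selects a named
#' node set. Ordering is ascending (deterministic).
#'
#' @param mesh a [tet_mesh()].
#' @param selector integer region tag or node-set name.
#' @return sorted integer vector of node indices.
#' @export
region_node_set <- function(mesh, selector) {
  if (is.character(selector)) {
    if (!selector %in% names(mesh$node_sets))
      stop(sprintf("unknown node set '%s'", selector))
    return(mesh$node_sets[[selector]])
  }
  selector <- as.integer(selector)
  if (!selector %in% mesh$element_region)
    stop(sprintf("unknown region tag %d", selector))
  sort(unique(as.vector(mesh$tets[mesh$element_region == selector, ])))
}

#' Anatomical reference frame
#'
#' Orthonormal direction triple fixing the anatomical axes used for muscle
#' orientation angles. The canonical frame is +x = lateral (right),
#' +y = rostral, +z = dorsal; left-side structures use -x as their outward
#' lateral direction (see [orientation_angles()]).
#'
#' @param lateral,rostral,dorsal unit 3-vectors; must be mutually
#'   orthogonal.
#' @return an object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(lateral = c(1, 0, 0), rostral = c(0, 1, 0),
                             dorsal = c(0, 0, 1)) {
  m <- rbind(lateral = lateral, rostral = rostral, dorsal = dorsal)
  if (max(abs(m %*% t(m) - diag(3))) > 1e-10)
    stop("frame axes must be mutually orthogonal unit vectors")
  structure(list(lateral = as.numeric(lateral), rostral = as.numeric(rostral),
                 dorsal = as.numeric(dorsal)), class = "anatomical_frame")
}
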