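#' Read a labeled tetrahedral mesh
#'
#' Reads a tetrahedral mesh with region tags and named node sets from one of
#' three plain-text dialects:
#'
#' * `vtk` — legacy ASCII VTK unstructured grid. Cells must all be type 10
#'   (tetrahedra). Region tags come from the `region` CELL_DATA scalar; node
#'   sets from 0/1 POINT_DATA scalars named `nset_<name>`. Additional
#'   CELL_DATA scalars are attached as the `"cell_data"` attribute.
#' * `msh` — Gmsh MSH 4.1 ASCII. Elements must be type 4 (TET4); the entity
#'   tag of each element block is the region tag. Node sets travel as
#'   `$NodeData` views named `nset:<name>` with value 1 on members.
#' * `inp` — minimal Abaqus INP: `*NODE`, `*ELEMENT, TYPE=C3D4,
#'   ELSET=REGION_<tag>`, `*NSET, NSET=<name>` cards.
#'
#' External files use each dialect's native indexing (0-based for VTK,
#' 1-based for MSH/INP); the returned mesh is always 1-based.
#'
#' @param path file to read.
#' @param format one of `"auto"` (from extension), `"vtk"`, `"msh"`, `"inp"`.
#' @return a [tet_mesh()], possibly with a `"cell_data"` attribute (named
#'   list of per-element numeric vectors).
#' @export
read_mesh <- function(path, format = c("auto", "vtk", "msh", "inp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") format <- guess_mesh_format(path)
  switch(format,
         vtk = read_mesh_vtk(path),
         msh = read_mesh_msh(path),
         inp = read_mesh_inp(path))
}

#' Write a labeled tetrahedral mesh
#'
#' Inverse of [read_mesh()]. Coordinates are written with 17 significant
#' digits so that a read/write round trip preserves them to better than
#' 1e-12 mm.
#'
#' @param mesh a [tet_mesh()].
#' @param path output file.
#' @param format `"auto"`, `"vtk"`, `"msh"` or `"inp"`.
#' @param cell_data optional named list of per-element numeric vectors
#'   (e.g. von Mises stress) stored as CELL_DATA (VTK) or `$ElementData`
#'   (MSH); not representable in INP and rejected there.
#' @return invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "vtk", "msh", "inp"),
                       cell_data = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_mesh_format(path)
  if (!is.null(cell_data)) {
    if (!is.list(cell_data) || is.null(names(cell_data)))
      stop("'cell_data' must be a named list of per-element vectors")
    nbad <- vapply(cell_data, length, 1L) != nrow(mesh$tets)
    if (any(nbad))
      stop(sprintf("cell_data length mismatch: %s",
                   paste(names(cell_data)[nbad], collapse = ", ")))
  }
  switch(format,
         vtk = write_mesh_vtk(mesh, path, cell_data),
         msh = write_mesh_msh(mesh, path, cell_data),
         inp = write_mesh_inp(mesh, path, cell_data))
  invisible(path)
}

guess_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("vtk", "msh", "inp")) ext
  else stop(sprintf("cannot guess mesh format from extension '.%s'", ext))
}

num_fmt <- function(x) sprintf("%.17g", x)

## ---- legacy VTK unstructured grid ----------------------------------------

write_mesh_vtk <- function(mesh, path, cell_data) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  con <- file(path, "w"); on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "tet_mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  wl(apply(mesh$nodes, 1L, function(p) paste(num_fmt(p), collapse = " ")))
  wl(sprintf("CELLS %d %d", m, 5L * m))
  wl(paste(4L, mesh$tets[, 1L] - 1L, mesh$tets[, 2L] - 1L,
           mesh$tets[, 3L] - 1L, mesh$tets[, 4L] - 1L))
  wl(sprintf("CELL_TYPES %d", m))
  wl(as.character(rep(10L, m)))
  wl(sprintf("CELL_DATA %d", m))
  wl("SCALARS region int 1", "LOOKUP_TABLE default")
  wl(as.character(mesh$element_region))
  for (nm in names(cell_data)) {
    wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
    wl(num_fmt(cell_data[[nm]]))
  }
  if (length(mesh$node_sets)) {
    wl(sprintf("POINT_DATA %d", n))
    for (nm in names(mesh$node_sets)) {
      member <- integer(n); member[mesh$node_sets[[nm]]] <- 1L
      wl(sprintf("SCALARS nset_%s int 1", nm), "LOOKUP_TABLE default")
      wl(as.character(member))
    }
  }
}

read_mesh_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks_of <- function(s) scan(text = s, what = "", quiet = TRUE)
  find <- function(pat) grep(pat, lines, ignore.case = TRUE)
  i <- find("^POINTS\\b")
  if (!length(i)) stop("unreadable VTK file: no POINTS section")
  n <- as.integer(toks_of(lines[i[1L]])[2L])
  # numeric stream after POINTS: 3n coordinates
  stream <- function(start, count) {
    vals <- numeric(0); j <- start
    while (length(vals) < count && j <= length(lines)) {
      vals <- c(vals, suppressWarnings(as.numeric(toks_of(lines[j]))))
      j <- j + 1L
    }
    if (length(vals) < count || anyNA(vals)) stop("unreadable VTK file: truncated data")
    list(vals = vals[seq_len(count)], next_line = j)
  }
  pts <- stream(i[1L] + 1L, 3L * n)
  nodes <- matrix(pts$vals, ncol = 3L, byrow = TRUE)
  i <- find("^CELLS\\b")
  if (!length(i)) stop("unreadable VTK file: no CELLS section")
  hdr <- toks_of(lines[i[1L]])
  m <- as.integer(hdr[2L]); total <- as.integer(hdr[3L])
  cs <- stream(i[1L] + 1L, total)
  # parse the connectivity stream cell by cell
  vals <- as.integer(cs$vals)
  cells <- vector("list", m); pos <- 1L
  for (k in seq_len(m)) {
    np <- vals[pos]
    cells[[k]] <- vals[(pos + 1L):(pos + np)]
    pos <- pos + np + 1L
  }
  i <- find("^CELL_TYPES\\b")
  ct <- stream(i[1L] + 1L, m)
  types <- as.integer(ct$vals)
  if (any(types != 10L))
    stop("non-tetrahedral cells in VTK file (CELL_TYPES other than 10)")
  tets <- do.call(rbind, cells) + 1L
  region <- rep(1L, m); node_sets <- list(); cell_data <- list()
  # scalar sections
  ci <- find("^CELL_DATA\\b"); pi <- find("^POINT_DATA\\b")
  read_scalars <- function(start, stop_at, count) {
    out <- list(); j <- start
    while (j <= length(lines) && !(j %in% stop_at)) {
      if (grepl("^SCALARS\\b", lines[j], ignore.case = TRUE)) {
        nm <- toks_of(lines[j])[2L]
        j <- j + 1L
        if (j <= length(lines) && grepl("^LOOKUP_TABLE", lines[j], ignore.case = TRUE))
          j <- j + 1L
        s <- stream(j, count)
        out[[nm]] <- s$vals
        j <- s$next_line
      } else j <- j + 1L
    }
    out
  }
  if (length(ci)) {
    cd <- read_scalars(ci[1L] + 1L, pi, m)
    if (!is.null(cd$region)) region <- as.integer(cd$region)
    cell_data <- cd[setdiff(names(cd), "region")]
  }
  if (length(pi)) {
    pd <- read_scalars(pi[1L] + 1L, ci[ci > pi[1L]], n)
    for (nm in names(pd)) {
      if (startsWith(nm, "nset_"))
        node_sets[[sub("^nset_", "", nm)]] <- which(pd[[nm]] != 0)
    }
  }
  mesh <- tet_mesh(nodes, tets, region, node_sets)
  if (length(cell_data)) attr(mesh, "cell_data") <- cell_data
  mesh
}

## ---- Gmsh MSH 4.1 ---------------------------------------------------------

write_mesh_msh <- function(mesh, path, cell_data) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  regions <- sort(unique(mesh$element_region))
  con <- file(path, "w"); on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  # one discrete volume entity per region tag
  wl("$Entities", sprintf("0 0 0 %d", length(regions)))
  bb <- apply(mesh$nodes, 2L, range)
  for (r in regions)
    wl(paste(r, num_fmt(bb[1L, 1L]), num_fmt(bb[1L, 2L]), num_fmt(bb[1L, 3L]),
             num_fmt(bb[2L, 1L]), num_fmt(bb[2L, 2L]), num_fmt(bb[2L, 3L]),
             "1", r, "0"))
  wl("$EndEntities")
  wl("$Nodes", sprintf("1 %d 1 %d", n, n),
     sprintf("3 %d 0 %d", regions[1L], n))
  wl(as.character(seq_len(n)))
  wl(apply(mesh$nodes, 1L, function(p) paste(num_fmt(p), collapse = " ")))
  wl("$EndNodes")
  # one block per run of consecutive identical tags, preserving element order
  runs <- rle(mesh$element_region)
  wl("$Elements",
     sprintf("%d %d 1 %d", length(runs$lengths), m, m))
  eid <- 0L
  for (b in seq_along(runs$lengths)) {
    rows <- eid + seq_len(runs$lengths[b])
    wl(sprintf("3 %d 4 %d", runs$values[b], length(rows)))
    wl(paste(rows,
             mesh$tets[rows, 1L], mesh$tets[rows, 2L],
             mesh$tets[rows, 3L], mesh$tets[rows, 4L]))
    eid <- eid + length(rows)
  }
  wl("$EndElements")
  for (nm in names(mesh$node_sets)) {
    ids <- mesh$node_sets[[nm]]
    wl("$NodeData", "1", sprintf("\"nset:%s\"", nm), "1", "0", "3", "0", "1",
       as.character(length(ids)))
    wl(paste(ids, "1"))
    wl("$EndNodeData")
  }
  for (nm in names(cell_data)) {
    wl("$ElementData", "1", sprintf("\"%s\"", nm), "1", "0", "3", "0", "1",
       as.character(m))
    wl(paste(seq_len(m), num_fmt(cell_data[[nm]])))
    wl("$EndElementData")
  }
}

read_mesh_msh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- function(name) {
    s <- which(lines == paste0("$", name))
    e <- which(lines == paste0("$End", name))
    if (!length(s)) return(NULL)
    Map(function(a, b) lines[(a + 1L):(b - 1L)], s, e)
  }
  fmt <- section("MeshFormat")
  if (is.null(fmt)) stop("unreadable MSH file: no $MeshFormat")
  ver <- scan(text = fmt[[1L]][1L], quiet = TRUE)[1L]
  if (ver < 4) stop(sprintf("unsupported MSH version %s (need 4.1)", ver))

  nod <- section("Nodes")[[1L]]
  hdr <- scan(text = nod[1L], quiet = TRUE)
  n_blocks <- hdr[1L]; n_nodes <- hdr[2L]
  tag <- integer(n_nodes); coord <- matrix(0, n_nodes, 3L)
  j <- 2L; k <- 0L
  for (b in seq_len(n_blocks)) {
    bh <- scan(text = nod[j], quiet = TRUE); nb <- bh[4L]; j <- j + 1L
    if (nb == 0) next
    tg <- as.integer(scan(text = paste(nod[j:(j + nb - 1L)], collapse = " "),
                          quiet = TRUE))
    j <- j + nb
    xyz <- scan(text = paste(nod[j:(j + nb - 1L)], collapse = " "), quiet = TRUE)
    j <- j + nb
    tag[k + seq_len(nb)] <- tg
    coord[k + seq_len(nb), ] <- matrix(xyz, ncol = 3L, byrow = TRUE)
    k <- k + nb
  }
  remap <- integer(max(tag)); remap[tag] <- seq_len(n_nodes)

  ele <- section("Elements")[[1L]]
  hdr <- scan(text = ele[1L], quiet = TRUE)
  e_blocks <- hdr[1L]
  tets <- NULL; region <- integer(0)
  j <- 2L
  for (b in seq_len(e_blocks)) {
    bh <- scan(text = ele[j], quiet = TRUE)
    ent <- as.integer(bh[2L]); etype <- as.integer(bh[3L]); nb <- bh[4L]
    j <- j + 1L
    if (nb == 0) next
    if (etype != 4L)
      stop(sprintf("non-tetrahedral cells in MSH file (element type %d)", etype))
    dat <- matrix(as.integer(scan(text = paste(ele[j:(j + nb - 1L)], collapse = " "),
                                  quiet = TRUE)), ncol = 5L, byrow = TRUE)
    j <- j + nb
    tets <- rbind(tets, matrix(remap[dat[, 2:5]], ncol = 4L))
    region <- c(region, rep(ent, nb))
  }

  node_sets <- list()
  for (nd in section("NodeData") %||% list()) {
    nm <- sub('^"(.*)"$', "\\1", nd[2L])
    if (!startsWith(nm, "nset:")) next
    nv <- as.integer(scan(text = nd[8L], quiet = TRUE)[1L])
    if (nv > 0) {
      dat <- matrix(scan(text = paste(nd[8L + seq_len(nv)], collapse = " "),
                         quiet = TRUE), ncol = 2L, byrow = TRUE)
      node_sets[[sub("^nset:", "", nm)]] <- remap[as.integer(dat[, 1L])]
    }
  }
  cell_data <- list()
  for (ed in section("ElementData") %||% list()) {
    nm <- sub('^"(.*)"$', "\\1", ed[2L])
    nv <- as.integer(scan(text = ed[8L], quiet = TRUE)[1L])
    if (nv > 0) {
      dat <- matrix(scan(text = paste(ed[8L + seq_len(nv)], collapse = " "),
                         quiet = TRUE), ncol = 2L, byrow = TRUE)
      cell_data[[nm]] <- dat[order(dat[, 1L]), 2L]
    }
  }
  mesh <- tet_mesh(coord, tets, region, node_sets)
  if (length(cell_data)) attr(mesh, "cell_data") <- cell_data
  mesh
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- minimal Abaqus INP ---------------------------------------------------

write_mesh_inp <- function(mesh, path, cell_data) {
  if (!is.null(cell_data) && length(cell_data))
    stop("per-element fields cannot be stored in INP; use VTK or MSH")
  con <- file(path, "w"); on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("*HEADING", "tet_mesh export", "*NODE")
  wl(paste(seq_len(nrow(mesh$nodes)),
           num_fmt(mesh$nodes[, 1L]), num_fmt(mesh$nodes[, 2L]),
           num_fmt(mesh$nodes[, 3L]), sep = ", "))
  runs <- rle(mesh$element_region)
  eid <- 0L
  for (b in seq_along(runs$lengths)) {
    rows <- eid + seq_len(runs$lengths[b])
    wl(sprintf("*ELEMENT, TYPE=C3D4, ELSET=REGION_%d", runs$values[b]))
    wl(paste(rows, mesh$tets[rows, 1L], mesh$tets[rows, 2L],
             mesh$tets[rows, 3L], mesh$tets[rows, 4L], sep = ", "))
    eid <- eid + length(rows)
  }
  for (nm in names(mesh$node_sets)) {
    wl(sprintf("*NSET, NSET=%s", nm))
    ids <- mesh$node_sets[[nm]]
    for (chunk in split(ids, ceiling(seq_along(ids) / 16)))
      wl(paste(chunk, collapse = ", "))
  }
}

read_mesh_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_kw <- startsWith(trimws(lines), "*")
  kw_at <- which(is_kw)
  block_end <- c(kw_at[-1L] - 1L, length(lines))
  nodes <- NULL; node_id <- integer(0)
  elems <- list(); eregion <- list(); node_sets <- list()
  next_region <- 1L
  for (k in seq_along(kw_at)) {
    kw_raw <- trimws(lines[kw_at[k]])
    kw <- toupper(kw_raw)
    body <- if (block_end[k] > kw_at[k])
      lines[(kw_at[k] + 1L):block_end[k]] else character(0)
    body <- body[!startsWith(trimws(body), "*")]
    if (startsWith(kw, "*NODE") && !startsWith(kw, "*NODESET")) {
      dat <- matrix(scan(text = paste(gsub(",", " ", body), collapse = " "),
                         quiet = TRUE), ncol = 4L, byrow = TRUE)
      node_id <- as.integer(dat[, 1L])
      nodes <- dat[, 2:4, drop = FALSE]
    } else if (startsWith(kw, "*ELEMENT")) {
      type <- sub(".*TYPE=([A-Z0-9]+).*", "\\1", kw)
      if (type != "C3D4")
        stop(sprintf("non-tetrahedral cells in INP file (TYPE=%s)", type))
      elset <- if (grepl("ELSET=", kw)) sub(".*ELSET=([^, ]+).*", "\\1", kw) else ""
      tag <- if (grepl("^REGION_[0-9]+$", elset))
        as.integer(sub("REGION_", "", elset))
      else { t <- next_region; next_region <- next_region + 1L; t }
      dat <- matrix(as.integer(scan(text = paste(gsub(",", " ", body), collapse = " "),
                                    quiet = TRUE)), ncol = 5L, byrow = TRUE)
      elems[[length(elems) + 1L]] <- dat[, 2:5, drop = FALSE]
      eregion[[length(eregion) + 1L]] <- rep(tag, nrow(dat))
    } else if (startsWith(kw, "*NSET")) {
      nm <- sub(".*NSET=([^, ]+).*", "\\1", kw_raw, ignore.case = TRUE)
      ids <- as.integer(scan(text = paste(gsub(",", " ", body), collapse = " "),
                             quiet = TRUE))
      node_sets[[nm]] <- ids
    }
  }
  if (is.null(nodes)) stop("unreadable INP file: no *NODE card")
  if (!length(elems)) stop("unreadable INP file: no *ELEMENT card")
  remap <- integer(max(node_id)); remap[node_id] <- seq_along(node_id)
  tets <- matrix(remap[do.call(rbind, elems)], ncol = 4L)
  node_sets <- lapply(node_sets, function(s) remap[s])
  tet_mesh(nodes, tets, unlist(eregion), node_sets)
}
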