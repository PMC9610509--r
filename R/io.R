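# Mesh and field I/O.
#
# Formats:
#  * "msh"  gmsh ASCII v2.2 with physical groups: full round trip of nodes,
#           connectivity, material labels and surface-patch labels.
#  * "vtk"  legacy VTK unstructured grid (tets + boundary tris, cell region
#           ids); patch/material names are appended as trailing comment
#           lines that this package's reader restores and other readers
#           ignore.
#  * "stl"  ASCII STL of the boundary surface only; volume, materials and
#           patch labels are dropped (reported, not silent).
#
# gmsh orders tet10 nodes as VTK except positions 9 and 10 are swapped.

GMSH_TET10_PERM <- c(1:8, 10L, 9L)

infer_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("msh", "vtk", "stl")))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("msh", "vtk", "stl"))
    stop("unsupported mesh format: '", ext, "' (use msh, vtk or stl)")
  ext
}

#' Write a labeled mesh to disk
#'
#' @param mesh a `labeled_mesh`.
#' @param path output file path; the extension selects the format unless
#'   `format` is given.
#' @param format `"msh"` (gmsh v2.2, full label round trip), `"vtk"`
#'   (legacy unstructured grid) or `"stl"` (boundary surface only).
#' @return invisibly `path`.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  format <- infer_format(path, format)
  switch(format,
         msh = write_msh(mesh, path),
         vtk = write_vtk_mesh(mesh, path),
         stl = write_stl(mesh, path))
  invisible(path)
}

#' Read a labeled mesh
#'
#' @param path file path (`.msh` or `.vtk`; `.stl` yields a surface-only
#'   triangle soup with a warning since labels and volume cannot be
#'   recovered).
#' @param format optional explicit format.
#' @return a `labeled_mesh` (or an `stl_surface` list for STL input).
#' @export
read_mesh <- function(path, format = NULL) {
  format <- infer_format(path, format)
  switch(format,
         msh = read_msh(path),
         vtk = read_vtk_mesh(path),
         stl = read_stl(path))
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

# ---- gmsh v2.2 -------------------------------------------------------------

write_msh <- function(mesh, path) {
  patches <- patch_names(mesh)
  mats <- sort(unique(mesh$elem_label))
  surf_id <- setNames(seq_along(patches), patches)
  vol_id <- setNames(length(patches) + seq_along(mats), mats)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  wl("$PhysicalNames", as.character(length(patches) + length(mats)))
  wl(sprintf("2 %d \"%s\"", surf_id, patches))
  wl(sprintf("3 %d \"%s\"", vol_id, mats))
  wl("$EndPhysicalNames")
  wl("$Nodes", as.character(nrow(mesh$nodes)))
  wl(paste(seq_len(nrow(mesh$nodes)),
           fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
           fmt_num(mesh$nodes[, 3])))
  wl("$EndNodes")
  tri_type <- if (ncol(mesh$facets) == 6L) 9L else 2L
  tet_type <- if (ncol(mesh$elems) == 10L) 11L else 4L
  ee <- mesh$elems
  if (tet_type == 11L) ee <- ee[, GMSH_TET10_PERM, drop = FALSE]
  nf <- nrow(mesh$facets); ne <- nrow(ee)
  wl("$Elements", as.character(nf + ne))
  wl(paste(seq_len(nf), tri_type, 2L,
           surf_id[mesh$facet_patch], surf_id[mesh$facet_patch],
           apply(mesh$facets, 1, paste, collapse = " ")))
  wl(paste(nf + seq_len(ne), tet_type, 2L,
           vol_id[mesh$elem_label], vol_id[mesh$elem_label],
           apply(ee, 1, paste, collapse = " ")))
  wl("$EndElements")
  invisible(path)
}

msh_section <- function(lines, name) {
  i0 <- which(lines == paste0("$", name))
  i1 <- which(lines == paste0("$End", name))
  if (!length(i0) || !length(i1)) return(NULL)
  lines[(i0[1] + 1L):(i1[1] - 1L)]
}

read_msh <- function(path) {
  lines <- readLines(path)
  nd <- msh_section(lines, "Nodes")
  if (is.null(nd)) stop("not a gmsh v2 file (no $Nodes): ", path)
  ntab <- read.table(text = nd[-1L])
  nodes <- as.matrix(ntab[order(ntab[[1]]), 2:4])
  dimnames(nodes) <- NULL

  phys <- msh_section(lines, "PhysicalNames")
  pname <- character(0)
  if (!is.null(phys) && length(phys) > 1L) {
    pp <- phys[-1L]
    id <- as.integer(sub("^\\s*\\d+\\s+(\\d+)\\s+.*$", "\\1", pp))
    nm <- sub('^[^"]*"(.*)"\\s*$', "\\1", pp)
    pname <- setNames(nm, id)
  }

  el <- msh_section(lines, "Elements")[-1L]
  sp <- strsplit(trimws(el), "\\s+")
  type <- vapply(sp, function(x) as.integer(x[2]), 1L)
  ntag <- vapply(sp, function(x) as.integer(x[3]), 1L)
  phys_id <- vapply(sp, function(x)
    if (as.integer(x[3]) >= 1L) as.integer(x[4]) else NA_integer_, 1L)
  conn <- function(x) as.integer(x[-(1:(3 + as.integer(x[3])))])

  tet_rows <- type %in% c(4L, 11L)
  tri_rows <- type %in% c(2L, 9L)
  if (!any(tet_rows)) stop("no tetrahedra found in ", path)
  order_ <- if (any(type == 11L)) 2L else 1L
  elems <- do.call(rbind, lapply(sp[tet_rows], conn))
  if (order_ == 2L) elems <- elems[, GMSH_TET10_PERM, drop = FALSE]

  lab_of <- function(ids, fallback) {
    out <- unname(pname[as.character(ids)])
    out[is.na(out)] <- fallback
    out
  }
  elem_label <- lab_of(phys_id[tet_rows], "base")

  if (any(tri_rows)) {
    facets <- do.call(rbind, lapply(sp[tri_rows], conn))
    facet_patch <- lab_of(phys_id[tri_rows], "free")
  } else {
    bf <- boundary_faces(elems[, 1:4, drop = FALSE])
    facets <- bf$faces
    facet_patch <- rep("free", nrow(facets))
    if (order_ == 2L) {
      # rebuild midedge columns from the tet10 edge map
      i <- as.vector(elems[, 1:4][, TET_EDGES[, 1]])
      j <- as.vector(elems[, 1:4][, TET_EDGES[, 2]])
      mid <- as.vector(elems[, 5:10])
      emap <- setNames(mid, edge_pair_key(i, j))
      fmid <- function(a, b) unname(emap[edge_pair_key(facets[, a], facets[, b])])
      facets <- cbind(facets, fmid(1, 2), fmid(2, 3), fmid(3, 1))
    }
  }
  if (!length(pname))
    warning("mesh file has no physical names; patch/material labels missing",
            " (patches set to 'free', materials to 'base')")
  labeled_mesh(nodes, elems, elem_label, facets, facet_patch, order = order_)
}

# ---- legacy VTK ------------------------------------------------------------

write_vtk_mesh <- function(mesh, path, point_data = NULL, field_data = NULL) {
  patches <- patch_names(mesh)
  mats <- sort(unique(mesh$elem_label))
  surf_id <- setNames(seq_along(patches), patches)
  vol_id <- setNames(length(patches) + seq_along(mats), mats)
  tet_np <- ncol(mesh$elems); tri_np <- ncol(mesh$facets)
  tet_vtk <- if (tet_np == 10L) 24L else 10L
  tri_vtk <- if (tri_np == 6L) 22L else 5L
  ne <- nrow(mesh$elems); nf <- nrow(mesh$facets)

  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "rcdlife labeled mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", nrow(mesh$nodes)))
  wl(paste(fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
           fmt_num(mesh$nodes[, 3])))
  ncell <- ne + nf
  sz <- ne * (tet_np + 1L) + nf * (tri_np + 1L)
  wl(sprintf("CELLS %d %d", ncell, sz))
  wl(paste(tet_np, apply(mesh$elems - 1L, 1, paste, collapse = " ")))
  wl(paste(tri_np, apply(mesh$facets - 1L, 1, paste, collapse = " ")))
  wl(sprintf("CELL_TYPES %d", ncell))
  wl(as.character(c(rep(tet_vtk, ne), rep(tri_vtk, nf))))
  wl(sprintf("CELL_DATA %d", ncell))
  wl("SCALARS region_id int 1", "LOOKUP_TABLE default")
  wl(as.character(c(vol_id[mesh$elem_label], surf_id[mesh$facet_patch])))
  if (!is.null(point_data) && length(point_data)) {
    wl(sprintf("POINT_DATA %d", nrow(mesh$nodes)))
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3L) {
        wl(sprintf("VECTORS %s double", nm))
        wl(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])))
      } else {
        wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
        wl(fmt_num(as.numeric(v)))
      }
    }
  }
  if (!is.null(field_data) && length(field_data)) {
    wl(sprintf("FIELD rcdlife %d", length(field_data)))
    for (nm in names(field_data)) {
      v <- as.numeric(field_data[[nm]])
      wl(sprintf("%s 1 %d double", nm, length(v)),
         paste(fmt_num(v), collapse = " "))
    }
  }
  # name tables (restored by read_mesh; ignored by other legacy readers)
  wl(sprintf("# rcdlife_region 2 %d %s", surf_id, patches))
  wl(sprintf("# rcdlife_region 3 %d %s", vol_id, mats))
  invisible(path)
}

read_vtk_mesh <- function(path) {
  lines <- readLines(path)
  toks_at <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
  ip <- grep("^POINTS ", lines)[1]
  np <- as.integer(toks_at(ip)[2])
  pts <- scan(text = lines[(ip + 1):length(lines)], n = 3 * np, quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS ", lines)[1]
  ncell <- as.integer(toks_at(ic)[2])
  # cells are written one per line
  cell_lines <- lines[ic + seq_len(ncell)]
  cells <- lapply(strsplit(trimws(cell_lines), "\\s+"), as.integer)
  it <- grep("^CELL_TYPES ", lines)[1]
  types <- as.integer(unlist(strsplit(trimws(
    lines[it + seq_len(ncell)]), "\\s+")))
  ird <- grep("^SCALARS region_id", lines)
  region <- if (length(ird))
    as.integer(unlist(strsplit(trimws(
      lines[ird[1] + 1L + seq_len(ncell)]), "\\s+")))
  else rep(NA_integer_, ncell)

  name_lines <- grep("^# rcdlife_region ", lines, value = TRUE)
  pname <- character(0)
  if (length(name_lines)) {
    parts <- strsplit(name_lines, "\\s+")
    ids <- vapply(parts, function(x) x[4], "")
    nms <- vapply(parts, function(x) paste(x[-(1:4)], collapse = " "), "")
    pname <- setNames(nms, ids)
  }
  is_tet <- types %in% c(10L, 24L)
  is_tri <- types %in% c(5L, 22L)
  if (!any(is_tet)) stop("no tetrahedra in VTK file: ", path)
  order_ <- if (any(types == 24L)) 2L else 1L
  elems <- do.call(rbind, lapply(cells[is_tet], function(x) x[-1L] + 1L))
  lab_of <- function(ids, fallback) {
    out <- unname(pname[as.character(ids)])
    out[is.na(out)] <- fallback
    out
  }
  elem_label <- lab_of(region[is_tet], "base")
  if (any(is_tri)) {
    facets <- do.call(rbind, lapply(cells[is_tri], function(x) x[-1L] + 1L))
    facet_patch <- lab_of(region[is_tri], "free")
  } else {
    bf <- boundary_faces(elems[, 1:4, drop = FALSE])
    facets <- bf$faces
    facet_patch <- rep("free", nrow(facets))
    if (order_ == 2L) {
      i <- as.vector(elems[, 1:4][, TET_EDGES[, 1]])
      j <- as.vector(elems[, 1:4][, TET_EDGES[, 2]])
      emap <- setNames(as.vector(elems[, 5:10]), edge_pair_key(i, j))
      fmid <- function(a, b) unname(emap[edge_pair_key(facets[, a], facets[, b])])
      facets <- cbind(facets, fmid(1, 2), fmid(2, 3), fmid(3, 1))
    }
  }
  if (!length(pname))
    warning("VTK mesh has no rcdlife name table; labels missing ",
            "(patches set to 'free', materials to 'base')")
  labeled_mesh(nodes, elems, elem_label, facets, facet_patch, order = order_)
}

#' Write displacement/stress/life fields on a mesh to legacy VTK
#'
#' Writes the volume mesh together with named nodal fields (scalars or
#' 3-column vectors). Normalized fields intended for isoline plots carry
#' the standard 10 percent contour levels as VTK FIELD metadata.
#'
#' @param mesh a `labeled_mesh`.
#' @param path output `.vtk` path.
#' @param point_data named list of per-node numeric vectors or n x 3
#'   matrices.
#' @param contour_levels optional numeric vector of normalized contour
#'   levels recorded as field metadata (default `seq(0.1, 1, 0.1)`).
#' @return invisibly `path`.
#' @export
write_vtk_fields <- function(mesh, path, point_data,
                             contour_levels = seq(0.1, 1, by = 0.1)) {
  write_vtk_mesh(mesh, path, point_data = point_data,
                 field_data = list(isoline_levels = contour_levels))
}

# ---- STL -------------------------------------------------------------------

write_stl <- function(mesh, path) {
  warning("STL is surface-only: volume elements, material labels and ",
          "patch labels are not representable and were dropped")
  g <- facet_geometry(mesh$nodes, mesh$facets)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid rcdlife", con)
  f <- mesh$facets
  v1 <- mesh$nodes[f[, 1], , drop = FALSE]
  v2 <- mesh$nodes[f[, 2], , drop = FALSE]
  v3 <- mesh$nodes[f[, 3], , drop = FALSE]
  block <- paste0("facet normal ", g$normal[, 1], " ", g$normal[, 2], " ",
                  g$normal[, 3], "\n outer loop\n  vertex ",
                  v1[, 1], " ", v1[, 2], " ", v1[, 3], "\n  vertex ",
                  v2[, 1], " ", v2[, 2], " ", v2[, 3], "\n  vertex ",
                  v3[, 1], " ", v3[, 2], " ", v3[, 3],
                  "\n endloop\nendfacet")
  writeLines(block, con)
  writeLines("endsolid rcdlife", con)
  invisible(path)
}

read_stl <- function(path) {
  warning("STL input is a surface-only triangle soup; no volume mesh or ",
          "labels can be recovered")
  lines <- readLines(path)
  vl <- grep("^\\s*vertex ", lines, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(x) as.numeric(x[2:4])))
  nv <- nrow(xyz)
  structure(list(vertices = xyz,
                 faces = matrix(seq_len(nv), ncol = 3, byrow = TRUE)),
            class = "stl_surface")
}
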