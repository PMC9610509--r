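#' @importFrom stats optim setNames aggregate
#' @importFrom utils head tail write.csv
NULL

# Canonical node ordering (VTK convention):
#   tet4 : v1 v2 v3 v4 (positive volume)
#   tet10: v1..v4, then midedge (1,2) (2,3) (3,1) (1,4) (2,4) (3,4)
#          [VTK edges 01,12,20,03,13,23]
#   tri6 : v1 v2 v3, then midedge (1,2) (2,3) (3,1)

#' Construct a labeled tetrahedral mesh
#'
#' A `labeled_mesh` bundles a tetrahedral volume mesh (linear tet4 or
#' quadratic tet10) with a per-element material label and a table of
#' boundary facets, each carrying exactly one named surface-patch label
#' (occlusal blocks, intaglio segments, border seal, retention zones,
#' cutouts, free surface). All coordinates are millimetres.
#'
#' @param nodes numeric matrix (n x 3) of node coordinates in mm.
#' @param elems integer matrix (ne x 4 or ne x 10) of tetrahedra.
#' @param elem_label character vector of per-element material labels
#'   (e.g. `"base"`, `"tooth"`).
#' @param facets integer matrix (nf x 3 or nf x 6) of outward-oriented
#'   boundary triangles.
#' @param facet_patch character vector of per-facet patch names.
#' @param order element order, 1 (tet4) or 2 (tet10).
#' @param mesh_size nominal element size in mm (metadata).
#' @param node_meta optional data.frame of per-node generator metadata.
#' @return an object of class `labeled_mesh`.
#' @export
labeled_mesh <- function(nodes, elems, elem_label, facets, facet_patch,
                         order = 1L, mesh_size = NA_real_, node_meta = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  facets <- as.matrix(facets)
  storage.mode(facets) <- "integer"
  stopifnot(ncol(nodes) == 3,
            ncol(elems) %in% c(4L, 10L),
            ncol(facets) %in% c(3L, 6L),
            length(elem_label) == nrow(elems),
            length(facet_patch) == nrow(facets))
  structure(list(
    nodes = nodes,
    elems = elems,
    elem_label = as.character(elem_label),
    facets = facets,
    facet_patch = as.character(facet_patch),
    order = as.integer(order),
    mesh_size = as.numeric(mesh_size),
    node_meta = node_meta
  ), class = "labeled_mesh")
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("<labeled_mesh> tet%d: %d nodes, %d elements, %d boundary facets\n",
              if (x$order == 2L) 10L else 4L,
              nrow(x$nodes), nrow(x$elems), nrow(x$facets)))
  cat("  materials:", paste(sprintf("%s (%d)", names(table(x$elem_label)),
                                    table(x$elem_label)), collapse = ", "), "\n")
  pn <- patch_names(x)
  cat("  patches:", length(pn), "\n")
  invisible(x)
}

#' Patch names present in a mesh
#' @param mesh a `labeled_mesh`.
#' @return sorted character vector of boundary patch names.
#' @export
patch_names <- function(mesh) sort(unique(mesh$facet_patch))

tet_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 2], , drop = FALSE] - a
  c_ <- nodes[elems[, 3], , drop = FALSE] - a
  d <- nodes[elems[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

# vectorized facet corner geometry: list(area, normal [outward unit], centroid)
facet_geometry <- function(nodes, facets) {
  a <- nodes[facets[, 1], , drop = FALSE]
  b <- nodes[facets[, 2], , drop = FALSE]
  c_ <- nodes[facets[, 3], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  twoA <- sqrt(rowSums(nrm^2))
  list(area = twoA / 2,
       normal = nrm / pmax(twoA, .Machine$double.eps),
       centroid = (a + b + c_) / 3)
}

#' Area of a named boundary patch
#'
#' Sums the (straight-facet) triangle areas of all boundary facets carrying
#' the given patch label.
#'
#' @param mesh a `labeled_mesh`.
#' @param patch patch name (see [patch_names()]).
#' @return area in mm^2.
#' @export
patch_area <- function(mesh, patch) {
  idx <- mesh$facet_patch == patch
  if (!any(idx)) stop("unknown patch name: ", patch)
  sum(facet_geometry(mesh$nodes, mesh$facets[idx, , drop = FALSE])$area)
}

#' Projected (horizontal-plane) area of a boundary patch
#'
#' Computes S0 = sum over facets of area x |vertical component of the unit
#' normal|, i.e. the projection of the patch onto the horizontal plane.
#' For a horizontal patch S0 equals the true area; for a vertical one it
#' is zero.
#'
#' @inheritParams patch_area
#' @return projected area S0 in mm^2.
#' @export
projected_area <- function(mesh, patch) {
  idx <- mesh$facet_patch == patch
  if (!any(idx)) stop("unknown patch name: ", patch)
  g <- facet_geometry(mesh$nodes, mesh$facets[idx, , drop = FALSE])
  sum(g$area * abs(g$normal[, 3]))
}

# ---- boundary extraction ---------------------------------------------------

# outward-oriented corner faces of positive tets (VTK tet: faces acb, abd, bcd, adc)
tet_corner_faces <- function(elems) {
  a <- elems[, 1]; b <- elems[, 2]; c_ <- elems[, 3]; d <- elems[, 4]
  rbind(cbind(a, c_, b), cbind(a, b, d), cbind(b, c_, d), cbind(a, d, c_))
}

face_key <- function(faces) {
  s <- t(apply(faces, 1, sort))
  paste(s[, 1], s[, 2], s[, 3], sep = "_")
}

# boundary faces (occurring once over all tets), outward-oriented,
# with the owning element index attached
boundary_faces <- function(elems) {
  faces <- tet_corner_faces(elems)
  eid <- rep(seq_len(nrow(elems)), 4L)
  key <- face_key(faces)
  tab <- table(key)
  single <- names(tab)[tab == 1L]
  keep <- key %in% single
  list(faces = faces[keep, , drop = FALSE], elem = eid[keep])
}

# ---- quadratic conversion --------------------------------------------------

edge_pair_key <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  paste(lo, hi, sep = "_")
}

TET_EDGES <- cbind(c(1L, 2L, 3L, 1L, 2L, 3L),
                   c(2L, 3L, 1L, 4L, 4L, 4L))

#' Convert a linear tet4 mesh to quadratic tet10
#'
#' Inserts shared midedge nodes (straight-edge midpoints) and upgrades
#' boundary facets to six-node triangles.
#'
#' @param mesh a tet4 `labeled_mesh`.
#' @return a tet10 `labeled_mesh`.
#' @export
as_tet10 <- function(mesh) {
  if (mesh$order == 2L) return(mesh)
  elems <- mesh$elems
  ne <- nrow(elems)
  # all element edges
  i <- as.vector(elems[, TET_EDGES[, 1]])
  j <- as.vector(elems[, TET_EDGES[, 2]])
  key <- edge_pair_key(i, j)
  ukey <- unique(key)
  mid_id <- nrow(mesh$nodes) + match(key, ukey)
  ulo <- as.integer(sub("_.*", "", ukey))
  uhi <- as.integer(sub(".*_", "", ukey))
  mid_xyz <- (mesh$nodes[ulo, , drop = FALSE] + mesh$nodes[uhi, , drop = FALSE]) / 2
  elems10 <- cbind(elems, matrix(mid_id, nrow = ne, ncol = 6L))
  # facets: midedge lookup for (1,2),(2,3),(3,1)
  f <- mesh$facets
  fmid <- function(a, b) {
    k <- edge_pair_key(f[, a], f[, b])
    nrow(mesh$nodes) + match(k, ukey)
  }
  facets6 <- cbind(f, fmid(1, 2), fmid(2, 3), fmid(3, 1))
  nm <- mesh$node_meta
  if (!is.null(nm)) {
    pad <- nm[rep(NA_integer_, length(ukey)), , drop = FALSE]
    nm <- rbind(nm, pad)
  }
  labeled_mesh(rbind(mesh$nodes, mid_xyz), elems10, mesh$elem_label,
               facets6, mesh$facet_patch, order = 2L,
               mesh_size = mesh$mesh_size, node_meta = nm)
}

#' Validate mesh invariants
#'
#' Checks strictly positive element volumes (no inverted elements), that
#' every boundary facet carries exactly one patch label, and that facet
#' corner triangles match the tet boundary (watertight labeling).
#'
#' @param mesh a `labeled_mesh`.
#' @param context optional string naming the offending input in errors.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_mesh <- function(mesh, context = NULL) {
  where <- if (is.null(context)) "" else paste0(" (", context, ")")
  vol <- tet_volumes(mesh$nodes, mesh$elems)
  if (any(!is.finite(vol)) || any(vol <= 0))
    stop("mesh has non-positive element volumes", where,
         "; smallest = ", format(min(vol)))
  bf <- boundary_faces(mesh$elems)
  if (nrow(bf$faces) != nrow(mesh$facets))
    stop("boundary facet table does not cover the mesh boundary", where,
         ": ", nrow(mesh$facets), " labeled vs ",
         nrow(bf$faces), " geometric facets")
  if (!setequal(face_key(bf$faces), face_key(mesh$facets[, 1:3, drop = FALSE])))
    stop("labeled facets do not match mesh boundary", where)
  if (anyNA(mesh$facet_patch) || any(mesh$facet_patch == ""))
    stop("boundary facets with missing patch label", where)
  invisible(TRUE)
}

# ---- structured box mesh (verification geometries) -------------------------

#' Structured tetrahedral box mesh
#'
#' A rectangular block meshed by Freudenthal subdivision of a structured
#' hexahedral grid, used for verification problems (patch tests, cantilever
#' beams, foundation blocks). Face patches are labeled `xmin`, `xmax`,
#' `ymin`, `ymax`, `zmin`, `zmax`.
#'
#' @param lengths numeric length-3: box dimensions in mm.
#' @param n integer length-3: number of elements per direction.
#' @param order element order 1 or 2.
#' @param origin numeric length-3 lower corner (default 0,0,0).
#' @return a `labeled_mesh` with material label `"base"`.
#' @export
mesh_box <- function(lengths = c(1, 1, 1), n = c(2, 2, 2), order = 1L,
                     origin = c(0, 0, 0)) {
  n <- as.integer(n)
  stopifnot(all(n >= 1), all(lengths > 0))
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  xs <- seq(origin[1], origin[1] + lengths[1], length.out = nx + 1)
  ys <- seq(origin[2], origin[2] + lengths[2], length.out = ny + 1)
  zs <- seq(origin[3], origin[3] + lengths[3], length.out = nz + 1)
  nid <- array(seq_len((nx + 1) * (ny + 1) * (nz + 1)),
               dim = c(nx + 1, ny + 1, nz + 1))
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  colnames(nodes) <- NULL

  hexes <- vector("list", nx * ny * nz)
  h <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    h <- h + 1L
    hexes[[h]] <- c(nid[i, j, k], nid[i + 1, j, k], nid[i + 1, j + 1, k],
                    nid[i, j + 1, k], nid[i, j, k + 1], nid[i + 1, j, k + 1],
                    nid[i + 1, j + 1, k + 1], nid[i, j + 1, k + 1])
  }
  elems <- split_hexes(do.call(rbind, hexes))

  # label boundary facets by outer box face
  bf <- boundary_faces(elems)
  g <- facet_geometry(nodes, bf$faces)
  lab <- character(nrow(bf$faces))
  tol <- 1e-9 * max(lengths)
  cx <- g$centroid
  lab[abs(cx[, 1] - xs[1]) < tol] <- "xmin"
  lab[abs(cx[, 1] - xs[nx + 1]) < tol] <- "xmax"
  lab[abs(cx[, 2] - ys[1]) < tol] <- "ymin"
  lab[abs(cx[, 2] - ys[ny + 1]) < tol] <- "ymax"
  lab[abs(cx[, 3] - zs[1]) < tol] <- "zmin"
  lab[abs(cx[, 3] - zs[nz + 1]) < tol] <- "zmax"
  m <- labeled_mesh(nodes, elems, rep("base", nrow(elems)), bf$faces, lab,
                    order = 1L, mesh_size = max(lengths / n))
  if (order == 2L) m <- as_tet10(m) else m
}

# Freudenthal 6-tet subdivision of hexes (rows: v0..v7, VTK hex ordering).
# All hexes split along the v0-v6 diagonal; conforming on structured grids.
split_hexes <- function(hx) {
  pat <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
               c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  out <- matrix(0L, nrow = 6L * nrow(hx), ncol = 4L)
  for (t in 1:6) {
    out[seq(t, by = 6L, length.out = nrow(hx)), ] <- hx[, pat[t, ], drop = FALSE]
  }
  out
}
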