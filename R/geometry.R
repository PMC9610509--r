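# Parametric mandibular denture-base generator.
#
# The base is a horseshoe: an elliptical arch centerline swept with a
# cross-section that carries an alveolar-ridge saddle on the intaglio side
# and drops to flange depth at the edges. Tooth blocks (I incisors,
# II canines, III premolars, IV molars, per side) are conforming prism
# columns bonded node-to-node on top of the base (ideal adhesion, no
# contact interface). Technological cutouts for strands are element-removal
# notches at the anterior midline and between blocks II and III on the
# vestibular edge. The mesh is generated for one side and mirrored about
# the midsagittal plane, so mirror symmetry is exact by construction.

#' Arch parameters for the synthetic denture-base geometry
#'
#' All lengths in mm. Defaults produce a mandibular full-arch base whose
#' occlusal block areas give single-block pressures of roughly 1-10 MPa at
#' a 100 N total load.
#'
#' @param arch_width overall outer width of the horseshoe.
#' @param arch_depth overall outer front-to-back extent.
#' @param section_width width of the swept cross-section (base plate width).
#' @param base_thickness plate thickness above the ridge crest.
#' @param ridge_height height of the alveolar-ridge saddle in the intaglio.
#' @param flange_height total section height at the vestibular/oral edges
#'   (must be >= base_thickness).
#' @param tooth_height height of the artificial tooth blocks.
#' @param tooth_band_width nominal width of the tooth band across the section.
#' @param cutout_depth,cutout_width depth (into the section) and arc width
#'   of the technological cutouts for strands.
#' @param seal_band_width width of the peripheral border-seal band on the
#'   intaglio surface.
#' @param retention_ellipse_axes length-2, semi-axes (arc, cross) of the two
#'   posterior retention zones.
#' @param block_footprints named numeric (I..IV), nominal per-side occlusal
#'   areas in mm^2.
#' @param mesh_size nominal element edge length.
#' @param element_order 1 (tet4) or 2 (tet10, default).
#' @param arch_angle_deg half-arch sweep angle in degrees.
#' @return an object of class `arch_parameters`.
#' @export
arch_parameters <- function(arch_width = 54, arch_depth = 43,
                            section_width = 10, base_thickness = 3,
                            ridge_height = 2, flange_height = 6,
                            tooth_height = 6, tooth_band_width = 6,
                            cutout_depth = 3, cutout_width = 2.2,
                            seal_band_width = 2,
                            retention_ellipse_axes = c(5, 3),
                            block_footprints = c(I = 60, II = 25,
                                                 III = 50, IV = 100),
                            mesh_size = 2.2, element_order = 2L,
                            arch_angle_deg = 130) {
  p <- list(arch_width = arch_width, arch_depth = arch_depth,
            section_width = section_width, base_thickness = base_thickness,
            ridge_height = ridge_height, flange_height = flange_height,
            tooth_height = tooth_height, tooth_band_width = tooth_band_width,
            cutout_depth = cutout_depth, cutout_width = cutout_width,
            seal_band_width = seal_band_width,
            retention_ellipse_axes = retention_ellipse_axes,
            block_footprints = block_footprints,
            mesh_size = mesh_size, element_order = as.integer(element_order),
            arch_angle_deg = arch_angle_deg)
  for (nm in c("arch_width", "arch_depth", "section_width", "base_thickness",
               "flange_height", "tooth_height", "tooth_band_width",
               "cutout_depth", "cutout_width", "seal_band_width",
               "mesh_size"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0)
      stop("arch parameter '", nm, "' must be a positive scalar")
  if (!is.numeric(ridge_height) || ridge_height < 0)
    stop("arch parameter 'ridge_height' must be >= 0")
  if (flange_height < base_thickness)
    stop("arch parameter 'flange_height' must be >= base_thickness")
  if (length(retention_ellipse_axes) != 2 || any(retention_ellipse_axes <= 0))
    stop("arch parameter 'retention_ellipse_axes' must be two positive lengths")
  if (!all(c("I", "II", "III", "IV") %in% names(block_footprints)) ||
      any(block_footprints <= 0))
    stop("arch parameter 'block_footprints' must name positive areas I..IV")
  if (!p$element_order %in% c(1L, 2L))
    stop("arch parameter 'element_order' must be 1 or 2")
  if (arch_angle_deg <= 45 || arch_angle_deg >= 170)
    stop("arch parameter 'arch_angle_deg' out of range (45, 170)")
  if (arch_depth <= section_width || arch_width <= 2 * section_width)
    stop("arch parameters 'arch_width'/'arch_depth' too small for 'section_width'")
  if (cutout_depth >= 0.6 * section_width)
    stop("arch parameter 'cutout_depth' too large for 'section_width'")
  structure(p, class = "arch_parameters")
}

BLOCKS <- c("I", "II", "III", "IV")

#' Tooth-arrangement specification
#'
#' Deviations of the tooth blocks from the normal arrangement: in-plane
#' displacement (vestibular-oral along the local outward normal, and
#' anteroposterior along +y = anterior) and inclination about the block's
#' mesio-distal axis. A zero spec reproduces the normal arrangement exactly.
#'
#' @param disp_vo named numeric (subset of I..IV): vestibular (+) / oral (-)
#'   displacement, mm.
#' @param disp_ap named numeric: anterior (+) / posterior (-) displacement, mm.
#' @param incl_deg named numeric: inclination about the mesio-distal axis,
#'   degrees (positive tilts the occlusal surface vestibularly).
#' @param side `"both"` (symmetric), `"left"` or `"right"`.
#' @param limits length-2 named numeric `c(disp = , incl = )`: admissible
#'   magnitude bounds.
#' @return an object of class `arrangement_spec`.
#' @export
arrangement_spec <- function(disp_vo = NULL, disp_ap = NULL, incl_deg = NULL,
                             side = "both", limits = c(disp = 5, incl = 30)) {
  full <- function(x) {
    v <- setNames(numeric(4), BLOCKS)
    if (!is.null(x)) {
      if (is.null(names(x)) || !all(names(x) %in% BLOCKS))
        stop("arrangement entries must be named with blocks I..IV")
      v[names(x)] <- x
    }
    v
  }
  side <- match.arg(side, c("both", "left", "right"))
  a <- structure(list(disp_vo = full(disp_vo), disp_ap = full(disp_ap),
                      incl_deg = full(incl_deg), side = side,
                      limits = limits), class = "arrangement_spec")
  if (any(abs(c(a$disp_vo, a$disp_ap)) > limits[["disp"]]))
    stop("arrangement displacement exceeds limit of ", limits[["disp"]], " mm")
  if (any(abs(a$incl_deg) > limits[["incl"]]))
    stop("arrangement inclination exceeds limit of ", limits[["incl"]], " deg")
  a
}

is_zero_arrangement <- function(a) {
  all(a$disp_vo == 0) && all(a$disp_ap == 0) && all(a$incl_deg == 0)
}

# ---- derived layout --------------------------------------------------------

# arc-length parametrization of the elliptical centerline (right half)
denture_layout <- function(p) {
  phimax <- p$arch_angle_deg * pi / 180
  A <- (p$arch_width - p$section_width) / 2
  B <- (p$arch_depth - p$section_width) / (1 - cos(phimax))
  w <- p$section_width
  kmax <- max(B / A^2, A / B^2)
  if (kmax * w / 2 >= 0.9)
    stop("arch parameters 'arch_width'/'arch_depth' give a centerline too ",
         "curved for 'section_width' (self-intersecting sweep)")
  # arc length s(phi) on a fine grid
  phi_g <- seq(0, phimax, length.out = 2001)
  sp <- sqrt(A^2 * cos(phi_g)^2 + B^2 * sin(phi_g)^2)
  s_g <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * diff(phi_g)))
  half_len <- s_g[length(s_g)]
  phi_of_s <- stats::approxfun(s_g, phi_g, rule = 2)

  n_half <- max(12L, ceiling(half_len / p$mesh_size))
  n_w <- max(4L, ceiling(w / p$mesh_size))
  n_zb <- max(2L, ceiling(p$base_thickness / p$mesh_size))
  n_zt <- max(2L, ceiling(p$tooth_height / p$mesh_size))
  ds <- half_len / n_half
  du <- w / n_w
  u_cell <- -w / 2 + (seq_len(n_w) - 0.5) * du     # cell centers across width
  s_cell <- (seq_len(n_half) - 0.5) * ds           # cell centers along arc

  # tooth band columns (across width)
  j_tooth <- which(abs(u_cell) <= p$tooth_band_width / 2)
  if (length(j_tooth) < 1)
    stop("arch parameter 'tooth_band_width' too narrow for 'mesh_size'")
  band_w <- length(j_tooth) * du

  # sequential block layout in arc length
  L <- p$block_footprints[BLOCKS] / p$tooth_band_width
  gap <- max(1.2, 0.55 * p$mesh_size)
  start <- max(p$cutout_width / 2 + 0.5, 1.2)
  iv <- list(); a <- start
  for (b in BLOCKS) {
    iv[[b]] <- c(a, a + L[[b]])
    a <- a + L[[b]] + gap
  }
  if (iv[["IV"]][2] > half_len - 0.3)
    stop("arch parameter 'block_footprints' too large for the arch length (",
         round(half_len, 1), " mm per side)")
  block_cols <- list()
  prev_max <- 0L
  for (b in BLOCKS) {
    cols <- which(s_cell >= iv[[b]][1] & s_cell < iv[[b]][2])
    if (length(cols) < 1)
      stop("arch parameter 'mesh_size' too coarse to resolve block ", b,
           " ('block_footprints')")
    # keep at least one free column between consecutive blocks
    if (length(block_cols) && min(cols) <= prev_max + 1L)
      cols <- cols[cols > prev_max + 1L]
    if (length(cols) < 1)
      stop("arch parameter 'mesh_size' too coarse to separate block ", b)
    block_cols[[b]] <- cols
    prev_max <- max(cols)
  }

  # cutout (notch) columns: anterior midline + lateral in the II-III gap
  j_notch <- which(u_cell > w / 2 - p$cutout_depth)
  i_notch_ant <- unique(c(1L, which(s_cell < p$cutout_width / 2)))
  free_cols <- setdiff(seq_len(n_half), unlist(block_cols))
  lat_target <- (iv[["II"]][2] + iv[["III"]][1]) / 2
  cand <- free_cols[abs(s_cell[free_cols] - lat_target) <= 1.5 * ds]
  i_notch_lat <- if (length(cand))
    cand[which.min(abs(s_cell[cand] - lat_target))] else integer(0)
  i_notch <- setdiff(unique(c(i_notch_ant, i_notch_lat)), unlist(block_cols))
  n_cut <- max(1L, floor(n_zb / 2))
  k_notch <- seq(n_zb - n_cut + 1L, n_zb)  # top base layers (cells, 1-based)

  # retention zone center (arc length), on the intaglio under the molars
  s_ret <- 0.82 * half_len

  list(p = p, A = A, B = B, phimax = phimax, half_len = half_len,
       phi_of_s = phi_of_s, n_half = n_half, n_w = n_w, n_zb = n_zb,
       n_zt = n_zt, ds = ds, du = du, u_cell = u_cell, s_cell = s_cell,
       j_tooth = j_tooth, band_w = band_w, block_cols = block_cols,
       i_notch = i_notch, j_notch = j_notch, k_notch = k_notch,
       s_ret = s_ret,
       z_top = p$ridge_height + p$base_thickness)
}

# cross-section profile: intaglio height as a function of u
intaglio_z <- function(u, p) {
  bump <- 0.5 * (1 + cos(2 * pi * u / p$section_width))
  z_top <- p$ridge_height + p$base_thickness
  bump * p$ridge_height + (1 - bump) * (z_top - p$flange_height)
}

# ---- generator -------------------------------------------------------------

#' Generate a labeled synthetic denture-base mesh
#'
#' Builds the parametric horseshoe base with conforming tooth blocks,
#' mirrors it about the midsagittal plane (x = 0) and labels the boundary:
#' 8 occlusal patches (blocks I-IV x left/right), 8 intaglio mucosa-contact
#' segments (4 per side), one peripheral `border_seal` band, two posterior
#' `retention_{left,right}` ellipses, `cutout` faces exposed by the strand
#' notches, and `free` surface elsewhere. Tooth elements carry the label
#' `"tooth"`, the rest `"base"`.
#'
#' @param params an [arch_parameters()] object.
#' @param arrangement an [arrangement_spec()]; the zero spec (default) gives
#'   the normal arrangement.
#' @param seed integer; recorded with the mesh and reserved for stochastic
#'   mesh jitter (the current generator is fully deterministic).
#' @return a `labeled_mesh` (tet4 or tet10 per `params$element_order`).
#' @export
generate_denture <- function(params = arch_parameters(),
                             arrangement = arrangement_spec(),
                             seed = 1L) {
  stopifnot(inherits(params, "arch_parameters"),
            inherits(arrangement, "arrangement_spec"))
  ly <- denture_layout(params)
  p <- params

  n_half <- ly$n_half; n_w <- ly$n_w; n_zb <- ly$n_zb; n_zt <- ly$n_zt

  # kept cells of the right half: (i, j, k) 1-based cell indices
  tooth_cells <- new.env(hash = TRUE)
  for (b in BLOCKS) for (i in ly$block_cols[[b]]) for (j in ly$j_tooth)
    for (k in (n_zb + 1):(n_zb + n_zt))
      assign(sprintf("%d_%d_%d", i, j, k), b, envir = tooth_cells)
  removed <- new.env(hash = TRUE)
  for (i in ly$i_notch) for (j in ly$j_notch) for (k in ly$k_notch)
    assign(sprintf("%d_%d_%d", i, j, k), TRUE, envir = removed)

  cell_state <- function(i, j, k) {
    if (i < 1 || i > n_half || j < 1 || j > n_w || k < 1) return("void")
    key <- sprintf("%d_%d_%d", i, j, k)
    if (k <= n_zb)
      return(if (exists(key, envir = removed, inherits = FALSE))
        "removed" else "base")
    if (exists(key, envir = tooth_cells, inherits = FALSE)) "tooth" else "void"
  }

  # node dictionary (created on demand, deterministic order)
  node_env <- new.env(hash = TRUE)
  node_xyz <- list(); node_ijk <- list()
  n_nodes <- 0L
  node_id <- function(i, j, k) {
    key <- sprintf("%d_%d_%d", i, j, k)
    id <- node_env[[key]]
    if (!is.null(id)) return(id)
    n_nodes <<- n_nodes + 1L
    node_env[[key]] <- n_nodes
    s <- (i - 1L) * ly$ds
    phi <- ly$phi_of_s(s)
    u <- -p$section_width / 2 + (j - 1L) * ly$du
    nvec <- c(sin(phi) / ly$A, cos(phi) / ly$B)
    nvec <- nvec / sqrt(sum(nvec^2))
    cx <- ly$A * sin(phi); cy <- ly$B * cos(phi)
    zb <- intaglio_z(u, p)
    z <- if (k <= n_zb + 1L) zb + (k - 1L) / n_zb * (ly$z_top - zb)
         else ly$z_top + (k - 1L - n_zb) / n_zt * p$tooth_height
    node_xyz[[n_nodes]] <<- c(cx + u * nvec[1], cy + u * nvec[2], z)
    node_ijk[[n_nodes]] <<- c(i, j, k)
    n_nodes
  }

  # enumerate kept cells (fixed order), build hex connectivity + face labels
  hex_list <- list(); hex_mat_lab <- character(0); hex_block <- character(0)
  label_quads <- list(); label_names <- character(0)
  nb_off <- list(iminus = c(-1L, 0L, 0L), iplus = c(1L, 0L, 0L),
                 jminus = c(0L, -1L, 0L), jplus = c(0L, 1L, 0L),
                 kminus = c(0L, 0L, -1L), kplus = c(0L, 0L, 1L))
  # local hex node offsets, VTK ordering v0..v7 (i,j bottom loop, then top)
  voff <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L),
                c(0L, 0L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 1L, 1L))
  face_v <- list(iminus = c(1L, 4L, 8L, 5L), iplus = c(2L, 3L, 7L, 6L),
                 jminus = c(1L, 2L, 6L, 5L), jplus = c(4L, 3L, 7L, 8L),
                 kminus = c(1L, 2L, 3L, 4L), kplus = c(5L, 6L, 7L, 8L))
  seal_u <- p$section_width / 2 - p$seal_band_width
  ret_a <- p$retention_ellipse_axes[1]; ret_b <- p$retention_ellipse_axes[2]

  classify_face <- function(i, j, k, fname, state) {
    sc <- ly$s_cell[i]; uc <- ly$u_cell[j]
    if (fname == "kminus" && k == 1L) {
      if (abs(uc) > seal_u) return("border_seal")
      if (((sc - ly$s_ret) / ret_a)^2 + (uc / ret_b)^2 <= 1)
        return("retention_right")
      q <- min(4L, floor(4 * sc / ly$half_len) + 1L)
      return(sprintf("intaglio_seg_%d_right", q))
    }
    if (fname == "kplus" && state == "tooth" && k == n_zb + n_zt) {
      b <- tooth_cells[[sprintf("%d_%d_%d", i, j, k)]]
      return(sprintf("occlusal_%s_right", b))
    }
    "free"
  }

  nq <- 0L
  for (k in seq_len(n_zb + n_zt)) for (j in seq_len(n_w)) for (i in seq_len(n_half)) {
    st <- cell_state(i, j, k)
    if (st %in% c("void", "removed")) next
    vids <- integer(8)
    for (v in 1:8)
      vids[v] <- node_id(i + voff[v, 1], j + voff[v, 2], k + voff[v, 3])
    hex_list[[length(hex_list) + 1L]] <- vids
    hex_mat_lab <- c(hex_mat_lab, if (st == "tooth") "tooth" else "base")
    for (fname in names(nb_off)) {
      o <- nb_off[[fname]]
      nst <- cell_state(i + o[1], j + o[2], k + o[3])
      if (nst %in% c("base", "tooth")) next        # interior
      if (fname == "iminus" && i == 1L) next       # midsagittal, interior after mirror
      lab <- if (nst == "removed") "cutout" else classify_face(i, j, k, fname, st)
      nq <- nq + 1L
      label_quads[[nq]] <- vids[face_v[[fname]]]
      label_names[nq] <- lab
    }
  }

  nodes <- do.call(rbind, node_xyz)
  ijk <- do.call(rbind, node_ijk)
  hexes <- do.call(rbind, hex_list)
  elems <- split_hexes(hexes)
  elem_label <- rep(hex_mat_lab, each = 6L)

  # ---- mirror about x = 0 --------------------------------------------------
  on_plane <- ijk[, 1] == 1L           # arc node index 1 sits at phi = 0
  mirror_map <- integer(n_nodes)
  mirror_map[on_plane] <- which(on_plane)
  off <- which(!on_plane)
  mirror_map[off] <- n_nodes + seq_along(off)
  nodes_m <- nodes[off, , drop = FALSE]
  nodes_m[, 1] <- -nodes_m[, 1]
  all_nodes <- rbind(nodes, nodes_m)
  side <- c(ifelse(on_plane, "mid", "right"), rep("left", length(off)))
  ijk_all <- rbind(ijk, ijk[off, , drop = FALSE])

  elems_m <- matrix(mirror_map[elems], ncol = 4L)
  elems_m <- elems_m[, c(1L, 2L, 4L, 3L), drop = FALSE]  # restore orientation
  all_elems <- rbind(elems, elems_m)
  all_elab <- c(elem_label, elem_label)

  quads <- do.call(rbind, label_quads)
  quads_m <- matrix(mirror_map[quads], ncol = 4L)
  all_quads <- rbind(quads, quads_m)
  all_qlab <- c(label_names,
                sub("_right$", "_left", label_names))

  # ---- per-node generator metadata (for arrangement + diagnostics) ---------
  s_node <- (ijk_all[, 1] - 1L) * ly$ds
  phi_node <- ly$phi_of_s(s_node)
  sgn <- ifelse(side == "left", -1, 1)
  nx_ <- sin(phi_node) / ly$A; ny_ <- cos(phi_node) / ly$B
  nn <- sqrt(nx_^2 + ny_^2)
  block_of_node <- rep(NA_character_, nrow(all_nodes))
  for (b in BLOCKS) {
    rng <- range(ly$block_cols[[b]])
    in_b <- ijk_all[, 1] >= rng[1] & ijk_all[, 1] <= rng[2] + 1L &
            ijk_all[, 3] > n_zb + 1L
    block_of_node[in_b] <- b
  }
  meta <- data.frame(i = ijk_all[, 1], j = ijk_all[, 2], k = ijk_all[, 3],
                     side = side, s = s_node,
                     nx = sgn * nx_ / nn, ny = ny_ / nn,
                     block = block_of_node, stringsAsFactors = FALSE)

  # ---- arrangement ---------------------------------------------------------
  if (!is_zero_arrangement(arrangement))
    all_nodes <- apply_arrangement(all_nodes, meta, arrangement, p, ly)

  # ---- boundary facets + labels --------------------------------------------
  bf <- boundary_faces(all_elems)
  qtrip <- rbind(all_quads[, c(1, 2, 3)], all_quads[, c(1, 2, 4)],
                 all_quads[, c(1, 3, 4)], all_quads[, c(2, 3, 4)])
  qlab4 <- rep(all_qlab, 4L)
  lut <- setNames(qlab4, face_key(qtrip))
  patch <- unname(lut[face_key(bf$faces)])
  if (anyNA(patch))
    stop("internal error: ", sum(is.na(patch)), " unlabeled boundary facets")

  m <- labeled_mesh(all_nodes, all_elems, all_elab, bf$faces, patch,
                    order = 1L, mesh_size = p$mesh_size, node_meta = meta)
  validate_mesh(m, context = "generate_denture")
  if (p$element_order == 2L) m <- as_tet10(m)
  attr(m, "params") <- params
  attr(m, "arrangement") <- arrangement
  attr(m, "seed") <- as.integer(seed)
  attr(m, "layout") <- ly[c("half_len", "n_half", "n_w", "n_zb", "n_zt",
                            "band_w", "z_top")]
  m
}

# blend tooth-block nodes towards the displaced/inclined position; the
# blend factor grows linearly from 0 at the base interface to 1 at the
# occlusal surface, keeping the mesh conforming (bonded teeth).
apply_arrangement <- function(nodes, meta, arr, p, ly) {
  z_top <- ly$z_top
  lam <- pmin(1, pmax(0, (nodes[, 3] - z_top) / p$tooth_height))
  sides <- if (arr$side == "both") c("left", "right") else arr$side
  for (b in BLOCKS) {
    vo <- arr$disp_vo[[b]]; ap <- arr$disp_ap[[b]]; th <- arr$incl_deg[[b]]
    if (vo == 0 && ap == 0 && th == 0) next
    for (sd in sides) {
      idx <- which(!is.na(meta$block) & meta$block == b & meta$side == sd)
      if (!length(idx)) next
      target <- nodes[idx, , drop = FALSE]
      if (th != 0) {
        sc <- mean(range(meta$s[idx]))
        phi_c <- ly$phi_of_s(sc)
        sgn <- if (sd == "left") -1 else 1
        tx <- ly$A * cos(phi_c); ty <- -ly$B * sin(phi_c)
        tv <- c(sgn * tx, ty, 0) / sqrt(tx^2 + ty^2)   # mesio-distal axis
        p0 <- c(sgn * ly$A * sin(phi_c), ly$B * cos(phi_c), z_top)
        ang <- sgn * th * pi / 180
        K <- rbind(c(0, -tv[3], tv[2]), c(tv[3], 0, -tv[1]),
                   c(-tv[2], tv[1], 0))
        R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
        target <- sweep(sweep(target, 2, p0) %*% t(R), 2, p0, `+`)
      }
      if (vo != 0 || ap != 0) {
        d <- cbind(vo * meta$nx[idx], vo * meta$ny[idx] + ap, 0)
        target <- target + d
      }
      nodes[idx, ] <- nodes[idx, , drop = FALSE] +
        lam[idx] * (target - nodes[idx, , drop = FALSE])
    }
  }
  nodes
}
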