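# Mucosa/seal/retention boundary model and occlusal load cases.
#
# The mucosa under the denture base is a Winkler elastic foundation:
# support traction proportional to local normal displacement, with an
# independent stiffness per intaglio segment (four per side). The border
# seal adds a weaker normal stiffness along the periphery; the posterior
# retention zones act as tangential springs (friction-like forces opposing
# local displacement). An optional linear compliance law c(u_n) = c0 +
# c1 * u_n makes the segment stiffness displacement-dependent (solved by
# secant fixed-point iteration); the default is the pure linear model.

#' Elastic-foundation specification
#'
#' @param k_segments named numeric of per-segment normal stiffnesses in
#'   MPa/mm: names `"1".."4"` (applied to both sides) or
#'   `"1_left".."4_right"` for asymmetric specs.
#' @param k_seal border-seal normal stiffness, MPa/mm.
#' @param k_retention retention-zone tangential stiffness, MPa/mm.
#' @param c1 slope of the compliance law `c(u_n) = c0 + c1 u_n` in
#'   (mm/MPa)/mm, with `c0 = 1/k_segment`; `c1 = 0` (default) is the
#'   linear model.
#' @param patches optional data.frame (`patch`, `k_n`, `k_t`) overriding
#'   name-based resolution for non-denture geometries.
#' @return an object of class `foundation_spec`.
#' @export
foundation_spec <- function(k_segments = c(`1` = 3, `2` = 3, `3` = 3, `4` = 3),
                            k_seal = 1, k_retention = 2, c1 = 0,
                            patches = NULL) {
  if (is.null(patches)) {
    if (is.null(names(k_segments)))
      stop("k_segments must be named ('1'..'4' or '1_left'..'4_right')")
    if (any(k_segments < 0) || k_seal < 0 || k_retention < 0)
      stop("foundation stiffnesses must be >= 0")
    if (all(k_segments == 0) && k_seal == 0)
      stop("at least one foundation patch needs positive normal stiffness")
  }
  if (c1 < 0) stop("compliance slope c1 must be >= 0")
  structure(list(k_segments = k_segments, k_seal = k_seal,
                 k_retention = k_retention, c1 = c1, patches = patches),
            class = "foundation_spec")
}

segment_stiffness <- function(spec, q, side) {
  ks <- spec$k_segments
  key <- paste0(q, "_", side)
  if (key %in% names(ks)) return(ks[[key]])
  if (as.character(q) %in% names(ks)) return(ks[[as.character(q)]])
  stop("foundation_spec has no stiffness for intaglio segment ", key)
}

# expand a foundation_spec against the patches present in a mesh
resolve_foundation <- function(spec, mesh) {
  stopifnot(inherits(spec, "foundation_spec"))
  if (!is.null(spec$patches)) {
    tab <- spec$patches
    stopifnot(all(c("patch", "k_n", "k_t") %in% names(tab)))
    return(tab)
  }
  pn <- patch_names(mesh)
  rows <- list()
  for (p in grep("^intaglio_seg_", pn, value = TRUE)) {
    mm <- regmatches(p, regexec("^intaglio_seg_([1-4])_(left|right)$", p))[[1]]
    rows[[p]] <- data.frame(patch = p,
                            k_n = segment_stiffness(spec, mm[2], mm[3]),
                            k_t = 0)
  }
  if ("border_seal" %in% pn)
    rows[["border_seal"]] <- data.frame(patch = "border_seal",
                                        k_n = spec$k_seal, k_t = 0)
  for (p in grep("^retention_", pn, value = TRUE))
    rows[[p]] <- data.frame(patch = p, k_n = 0, k_t = spec$k_retention)
  if (!length(rows))
    stop("mesh has no foundation patches (intaglio/seal/retention)")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (all(tab$k_n == 0))
    stop("foundation has no positive normal stiffness on any patch")
  tab
}

#' Per-block occlusal pressure
#'
#' `P_k = F0 / S_k`: the pressure on a tooth block is the applied force
#' divided by its (projected) mastication surface area. At the 100 N
#' reference load the default block areas give pressures of about
#' 1-10 MPa.
#'
#' @param F0 total force on the block, N.
#' @param S_k block surface area, mm^2 (> 0).
#' @return pressure in MPa.
#' @export
block_pressure <- function(F0, S_k) {
  if (any(S_k <= 0)) stop("block area S_k must be positive")
  F0 / S_k
}

#' Occlusal load case
#'
#' @param blocks subset of `c("I","II","III","IV")` (ignored for
#'   `"uniform-all"`).
#' @param sidedness `"symmetric"` (both sides share F0),
#'   `"asymmetric-left"`/`"asymmetric-right"` (one side carries all of F0)
#'   or `"uniform-all"` (F0 spread over all eight blocks).
#' @param F0 total vertical force, N (default 100, the average muscular
#'   compression force of a human jaw).
#' @return an object of class `load_case`.
#' @export
load_case <- function(blocks = "I",
                      sidedness = c("symmetric", "asymmetric-left",
                                    "asymmetric-right", "uniform-all"),
                      F0 = 100) {
  sidedness <- match.arg(sidedness)
  if (sidedness == "uniform-all") blocks <- BLOCKS
  if (!length(blocks) || !all(blocks %in% BLOCKS))
    stop("blocks must be a non-empty subset of I..IV")
  if (F0 <= 0) stop("total force F0 must be positive")
  structure(list(blocks = blocks, sidedness = sidedness, F0 = F0),
            class = "load_case")
}

case_patches <- function(case) {
  sides <- switch(case$sidedness,
                  symmetric = c("left", "right"),
                  `uniform-all` = c("left", "right"),
                  `asymmetric-left` = "left",
                  `asymmetric-right` = "right")
  as.vector(outer(case$blocks, sides,
                  function(b, s) sprintf("occlusal_%s_%s", b, s)))
}

#' Build the nodal load vector for a load case
#'
#' Applies a uniform vertical pressure over the selected occlusal patches,
#' scaled by the per-facet vertical projection so that the integrated
#' vertical force equals `F0` exactly regardless of surface curvature
#' (the flat-surface equivalence `F = int P sin(beta) dS = F0`). The load
#' acts downward (-z, biting onto the mandibular denture).
#'
#' @param case a [load_case()].
#' @param mesh a `labeled_mesh` with occlusal patches.
#' @return a length-`3n` dof load vector (N) with attributes
#'   `total_force` (3-vector), `pressure` (MPa) and `patches`.
#' @export
build_load_case <- function(case, mesh) {
  stopifnot(inherits(case, "load_case"))
  patches <- case_patches(case)
  missing <- setdiff(patches, patch_names(mesh))
  if (length(missing))
    stop("load case targets missing patch(es): ",
         paste(missing, collapse = ", "))
  S0 <- sum(vapply(patches, function(p) projected_area(mesh, p), 0))
  if (S0 <= 0) stop("selected occlusal patches have zero projected area")
  P <- case$F0 / S0
  if (P < 0.1 || P > 20)
    warning(sprintf("occlusal pressure %.3g MPa outside plausible 0.1-20 MPa",
                    P))
  f <- numeric(3L * nrow(mesh$nodes))
  for (fi in which(mesh$facet_patch %in% patches)) {
    fn <- mesh$facets[fi, ]
    fm <- facet_mass(mesh$nodes[fn, , drop = FALSE])
    w <- rowSums(fm$M) * abs(fm$normal[3])   # int N_i |n_z| dS
    f[3L * fn] <- f[3L * fn] - P * w
  }
  attr(f, "total_force") <- c(Fx = 0, Fy = 0, Fz = sum(f[seq(3, length(f), 3)]))
  attr(f, "pressure") <- P
  attr(f, "patches") <- patches
  f
}

#' Best-fit rigid-body motion of a displacement field
#'
#' Least-squares fit of `u = t + omega x x` over the base-material nodes.
#' With the denture axes (x transverse, y anteroposterior, z vertical),
#' pitch is the rotation about x, roll about y and yaw about z, in
#' degrees. Also reports the vertical displacement range (max - min of
#' u_z) over the fitted nodes and the RMS fit residual.
#'
#' @param u a `displacement_field`.
#' @param mesh the `labeled_mesh`.
#' @param nodes optional node subset (default: all nodes of elements
#'   labeled `"base"`).
#' @return list with `pitch`, `roll`, `yaw` (deg), `translation` (mm),
#'   `range_z` (mm), `residual` (mm RMS).
#' @export
rigid_motion_metrics <- function(u, mesh, nodes = NULL) {
  if (is.null(nodes))
    nodes <- sort(unique(as.vector(mesh$elems[mesh$elem_label == "base", ])))
  X <- mesh$nodes[nodes, , drop = FALSE]
  U <- unclass(u)[nodes, , drop = FALSE]
  m <- nrow(X)
  # u = t + omega x x  ->  rows [I | -skew(x)] [t; omega]
  A <- matrix(0, 3 * m, 6)
  A[seq(1, 3 * m, 3), 1] <- 1
  A[seq(2, 3 * m, 3), 2] <- 1
  A[seq(3, 3 * m, 3), 3] <- 1
  A[seq(1, 3 * m, 3), 5] <- X[, 3];  A[seq(1, 3 * m, 3), 6] <- -X[, 2]
  A[seq(2, 3 * m, 3), 4] <- -X[, 3]; A[seq(2, 3 * m, 3), 6] <- X[, 1]
  A[seq(3, 3 * m, 3), 4] <- X[, 2];  A[seq(3, 3 * m, 3), 5] <- -X[, 1]
  b <- as.vector(t(U))
  fit <- qr.solve(A, b)
  res <- sqrt(mean((A %*% fit - b)^2))
  omega <- fit[4:6] * 180 / pi
  list(pitch = omega[1], roll = omega[2], yaw = omega[3],
       translation = fit[1:3], range_z = diff(range(U[, 3])),
       residual = res)
}

# ---- static solve (with optional displacement-dependent compliance) --------

# mean normal displacement of a patch, area-weighted over facets
patch_mean_normal_disp <- function(u, mesh, patch) {
  idx <- which(mesh$facet_patch == patch)
  tot <- 0; areas <- 0
  U <- unclass(u)
  for (fi in idx) {
    fn <- mesh$facets[fi, 1:3]
    fm <- facet_mass(mesh$nodes[mesh$facets[fi, ], , drop = FALSE])
    un <- mean(U[fn, , drop = FALSE] %*% fm$normal)
    tot <- tot + un * fm$area
    areas <- areas + fm$area
  }
  tot / areas
}

#' Solve a static load case on a denture mesh
#'
#' Assembles, solves and (when the foundation carries a displacement-
#' dependent compliance law, `c1 > 0`) performs a secant fixed-point
#' iteration: solve, update each segment stiffness from
#' `k = 1 / (c0 + c1 |u_n|)`, re-solve, up to `max_iter` passes.
#'
#' @param mesh a `labeled_mesh`.
#' @param materials a [material_set()].
#' @param foundation a [foundation_spec()].
#' @param load a [load_case()] or a precomputed dof load vector.
#' @param max_iter compliance-iteration cap (default 5).
#' @param system optional pre-assembled `fem_system` to reuse.
#' @return list with `u` (displacement field), `system`, `f`, and
#'   `iterations`.
#' @export
solve_static <- function(mesh, materials, foundation, load, max_iter = 5,
                         system = NULL) {
  f <- if (inherits(load, "load_case")) build_load_case(load, mesh) else load
  if (is.null(system))
    system <- assemble_system(mesh, materials, foundation)
  u <- solve_system(system, f)
  iters <- 1L
  if (foundation$c1 > 0) {
    tab0 <- system$foundation$tab
    seg_rows <- grep("^intaglio_seg_", tab0$patch)
    c0 <- 1 / tab0$k_n[seg_rows]
    for (it in seq_len(max_iter - 1L)) {
      un <- vapply(tab0$patch[seg_rows],
                   function(p) abs(patch_mean_normal_disp(u, mesh, p)), 0)
      k_new <- 1 / (c0 + foundation$c1 * un)
      if (max(abs(k_new - tab0$k_n[seg_rows]) / tab0$k_n[seg_rows]) < 1e-4)
        break
      tab0$k_n[seg_rows] <- k_new
      system <- update_foundation(system, tab0)
      u <- solve_system(system, f)
      iters <- iters + 1L
    }
  }
  list(u = u, system = system, f = f, iterations = iters)
}

# rebuild K from cached bulk + unit foundation matrices with a new table
update_foundation <- function(system, tab) {
  K_found <- 0 * system$K_found
  for (r in seq_len(nrow(tab))) {
    un <- system$foundation$units[[tab$patch[r]]]
    if (tab$k_n[r] > 0) K_found <- K_found + tab$k_n[r] * un$Kn
    if (tab$k_t[r] > 0) K_found <- K_found + tab$k_t[r] * un$Kt
  }
  system$K_found <- K_found
  system$K <- system$K_bulk + K_found
  system$foundation$tab <- tab
  system
}

#' Calibrate segment stiffnesses to null pitch and roll
#'
#' Adjusts the four per-segment stiffness multipliers (applied to both
#' sides, preserving left-right symmetry) so that the uniform all-teeth
#' load case produces vanishing pitch and roll and a vertical displacement
#' range at or below `target_range`. Derivative-free Nelder-Mead on the
#' log-multipliers, bounded to 1e-2..1e2 times the initial stiffness;
#' deterministic for fixed inputs. If the initial spec already meets the
#' tolerances it is returned unchanged.
#'
#' @param mesh a symmetric `labeled_mesh`.
#' @param materials a [material_set()].
#' @param initial starting [foundation_spec()].
#' @param case the balancing load case (default uniform-all at 100 N).
#' @param target_range admissible vertical displacement range, mm
#'   (default 0.02).
#' @param tol_angle admissible |pitch| and |roll|, degrees (default 0.01).
#' @param maxit Nelder-Mead iteration cap.
#' @return a calibrated `foundation_spec` with a `report` attribute
#'   (metrics before/after, multipliers, objective evaluations).
#' @export
calibrate_foundation <- function(mesh, materials, initial,
                                 case = load_case(sidedness = "uniform-all"),
                                 target_range = 0.02, tol_angle = 0.01,
                                 maxit = 120) {
  stopifnot(inherits(initial, "foundation_spec"))
  if (!is.null(initial$patches))
    stop("calibration requires a segment-based foundation_spec")
  system <- assemble_system(mesh, materials, initial)
  f <- build_load_case(case, mesh)
  tab0 <- system$foundation$tab
  seg_q <- as.integer(sub("^intaglio_seg_([1-4])_.*$", "\\1",
                          tab0$patch[grep("^intaglio_seg_", tab0$patch)]))
  seg_rows <- grep("^intaglio_seg_", tab0$patch)
  k0 <- tab0$k_n[seg_rows]

  metrics_of <- function(logm) {
    m <- 10^pmin(pmax(logm, -2), 2)
    tab <- tab0
    tab$k_n[seg_rows] <- k0 * m[seg_q]
    sys2 <- update_foundation(system, tab)
    u <- solve_system(sys2, f)
    rigid_motion_metrics(u, mesh)
  }
  nev <- 0L
  objective <- function(logm) {
    nev <<- nev + 1L
    mt <- metrics_of(logm)
    mt$pitch^2 + mt$roll^2 +
      100 * max(0, mt$range_z / target_range - 0.95)^2
  }
  before <- metrics_of(rep(0, 4))
  if (abs(before$pitch) < tol_angle && abs(before$roll) < tol_angle &&
      before$range_z <= target_range) {
    attr(initial, "report") <- list(before = before, after = before,
                                    multipliers = rep(1, 4),
                                    evaluations = 1L, converged = TRUE)
    return(initial)
  }
  opt <- stats::optim(rep(0, 4), objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  logm <- pmin(pmax(opt$par, -2), 2)
  after <- metrics_of(logm)
  if (abs(after$pitch) > tol_angle || abs(after$roll) > tol_angle ||
      after$range_z > target_range)
    stop(sprintf(paste0("foundation calibration infeasible within bounds: ",
                        "pitch %.4g deg, roll %.4g deg, range %.4g mm"),
                 after$pitch, after$roll, after$range_z))
  m <- 10^logm
  ks <- initial$k_segments
  if (all(as.character(1:4) %in% names(ks))) {
    ks[as.character(1:4)] <- ks[as.character(1:4)] * m
  } else {
    for (q in 1:4) for (sd in c("left", "right")) {
      key <- paste0(q, "_", sd)
      if (key %in% names(ks)) ks[[key]] <- ks[[key]] * m[q]
    }
  }
  out <- foundation_spec(k_segments = ks, k_seal = initial$k_seal,
                         k_retention = initial$k_retention, c1 = initial$c1)
  attr(out, "report") <- list(before = before, after = after,
                              multipliers = m, evaluations = nev,
                              converged = TRUE)
  out
}
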