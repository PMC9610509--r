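# Small-strain isotropic linear elasticity on tet4/tet10 meshes with
# elastic-foundation (Robin) boundary terms. Units: mm-N-MPa.
#
# Elements are straight-sided, so the isoparametric map of a tet10 is
# affine: the Jacobian is constant per element and strains are linear
# within it. Stiffness integration uses the 4-point degree-2 rule (exact
# for tet10), facet mass matrices the 7-point degree-5 triangle rule.

TET4_QP <- list(points = matrix(c(0.25, 0.25, 0.25), 1, 3),
                weights = 1 / 6)
.a <- 0.5854101966249685; .b <- 0.1381966011250105
TET10_QP <- list(points = rbind(c(.a, .b, .b), c(.b, .a, .b),
                                c(.b, .b, .a), c(.b, .b, .b)),
                 weights = rep(1 / 24, 4))
rm(.a, .b)

TRI7_QP <- local({
  a1 <- 0.059715871789770; b1 <- 0.470142064105115
  a2 <- 0.797426985353087; b2 <- 0.101286507323456
  pts <- rbind(c(1 / 3, 1 / 3),
               c(a1, b1), c(b1, a1), c(b1, b1),
               c(a2, b2), c(b2, a2), c(b2, b2))
  w <- c(0.225, rep(0.132394152788506, 3), rep(0.125939180544827, 3))
  list(points = pts, weights = w)  # weights sum to 1 (times area)
})

# reference-coordinate shape gradients
tet4_dN <- function() rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

tet10_dN <- function(r, s, t) {
  L <- c(1 - r - s - t, r, s, t)
  dL <- rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  dN <- matrix(0, 10, 3)
  for (i in 1:4) dN[i, ] <- (4 * L[i] - 1) * dL[i, ]
  for (e in 1:6) {
    i <- TET_EDGES[e, 1]; j <- TET_EDGES[e, 2]
    dN[4 + e, ] <- 4 * (L[i] * dL[j, ] + L[j] * dL[i, ])
  }
  dN
}

# corner reference coordinates (r,s,t) of the tet
TET_CORNER_REF <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

strain_B <- function(dNxyz) {
  n <- nrow(dNxyz)
  B <- matrix(0, 6, 3 * n)
  ix <- 3 * seq_len(n) - 2
  B[1, ix] <- dNxyz[, 1]
  B[2, ix + 1] <- dNxyz[, 2]
  B[3, ix + 2] <- dNxyz[, 3]
  B[4, ix] <- dNxyz[, 2]; B[4, ix + 1] <- dNxyz[, 1]
  B[5, ix + 1] <- dNxyz[, 3]; B[5, ix + 2] <- dNxyz[, 2]
  B[6, ix] <- dNxyz[, 3]; B[6, ix + 2] <- dNxyz[, 1]
  B
}

# element stiffness; xe is (nn x 3) node coordinates
element_stiffness <- function(xe, D) {
  nn <- nrow(xe)
  if (nn == 4L) {
    J <- t(xe[2:4, , drop = FALSE] -
             matrix(xe[1, ], 3, 3, byrow = TRUE))      # dx/dxi
    detJ <- det(J)
    dNxyz <- tet4_dN() %*% solve(J)
    B <- strain_B(dNxyz)
    return((detJ / 6) * crossprod(B, D %*% B))
  }
  # tet10, straight-sided: constant Jacobian from corners
  J <- t(xe[2:4, , drop = FALSE] - matrix(xe[1, ], 3, 3, byrow = TRUE))
  detJ <- det(J)
  Jinv <- solve(J)
  Ke <- matrix(0, 30, 30)
  qp <- TET10_QP
  for (q in seq_along(qp$weights)) {
    dN <- tet10_dN(qp$points[q, 1], qp$points[q, 2], qp$points[q, 3]) %*% Jinv
    B <- strain_B(dN)
    Ke <- Ke + (qp$weights[q] * detJ) * crossprod(B, D %*% B)
  }
  Ke
}

elem_dofs <- function(enodes) {
  as.vector(rbind(3 * enodes - 2, 3 * enodes - 1, 3 * enodes))
}

assemble_bulk <- function(mesh, materials) {
  labs <- unique(mesh$elem_label)
  missing <- setdiff(labs, names(materials$E))
  if (length(missing))
    stop("no material constants for element label(s): ",
         paste(missing, collapse = ", "))
  Dm <- lapply(setNames(labs, labs),
               function(l) elastic_D(materials$E[[l]], materials$nu[[l]]))
  ne <- nrow(mesh$elems)
  nn <- ncol(mesh$elems)
  nd <- 3L * nn
  blk <- nd * nd
  ii <- integer(ne * blk); jj <- integer(ne * blk); vv <- numeric(ne * blk)
  for (e in seq_len(ne)) {
    en <- mesh$elems[e, ]
    Ke <- element_stiffness(mesh$nodes[en, , drop = FALSE],
                            Dm[[mesh$elem_label[e]]])
    dofs <- elem_dofs(en)
    sl <- (e - 1L) * blk + seq_len(blk)
    ii[sl] <- rep(dofs, times = nd)
    jj[sl] <- rep(dofs, each = nd)
    vv[sl] <- Ke
  }
  ndof <- 3L * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(ndof, ndof))
}

# facet shape-function mass matrix ∫ Ni Nj dS (straight facets)
facet_mass <- function(xe) {
  nn <- nrow(xe)
  u <- xe[2, ] - xe[1, ]; v <- xe[3, ] - xe[1, ]
  nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
  A <- sqrt(sum(nrm^2)) / 2
  if (nn == 3L) {
    M <- matrix(A / 12, 3, 3); diag(M) <- A / 6
    return(list(M = M, normal = nrm / (2 * A), area = A))
  }
  M <- matrix(0, 6, 6)
  for (q in seq_along(TRI7_QP$weights)) {
    xi <- TRI7_QP$points[q, 1]; eta <- TRI7_QP$points[q, 2]
    L <- c(1 - xi - eta, xi, eta)
    N <- c(L * (2 * L - 1), 4 * L[1] * L[2], 4 * L[2] * L[3], 4 * L[3] * L[1])
    M <- M + (TRI7_QP$weights[q] * A) * tcrossprod(N)
  }
  list(M = M, normal = nrm / (2 * A), area = A)
}

# per-patch unit foundation matrices (k = 1 MPa/mm); Kn couples normal
# displacement, Kt the tangential components
foundation_unit_matrices <- function(mesh, patches) {
  ndof <- 3L * nrow(mesh$nodes)
  out <- list()
  for (p in patches) {
    idx <- which(mesh$facet_patch == p)
    if (!length(idx)) stop("foundation patch not present in mesh: ", p)
    trip_n <- list(); trip_t <- list()
    for (fi in idx) {
      fn <- mesh$facets[fi, ]
      fm <- facet_mass(mesh$nodes[fn, , drop = FALSE])
      nvec <- fm$normal
      Pn <- tcrossprod(nvec)           # n n^T
      Pt <- diag(3) - Pn
      Kn <- kronecker(fm$M, Pn)
      Kt <- kronecker(fm$M, Pt)
      dofs <- elem_dofs(fn)
      nd <- length(dofs)
      ij <- list(i = rep(dofs, times = nd), j = rep(dofs, each = nd))
      trip_n[[length(trip_n) + 1L]] <- c(ij, list(x = as.vector(Kn)))
      trip_t[[length(trip_t) + 1L]] <- c(ij, list(x = as.vector(Kt)))
    }
    cat_trip <- function(tr) Matrix::sparseMatrix(
      i = unlist(lapply(tr, `[[`, "i")),
      j = unlist(lapply(tr, `[[`, "j")),
      x = unlist(lapply(tr, `[[`, "x")),
      dims = c(ndof, ndof))
    out[[p]] <- list(Kn = cat_trip(trip_n), Kt = cat_trip(trip_t))
  }
  out
}

#' Assemble the linear-elastic system with foundation boundary terms
#'
#' Builds the sparse symmetric stiffness matrix of the mesh plus Winkler
#' elastic-foundation (Robin) terms on the patches named by the foundation
#' spec. The foundation terms remove the rigid-body singularity; a model
#' with neither foundation patches nor fixed supports is rejected.
#'
#' @param mesh a `labeled_mesh`.
#' @param materials a [material_set()].
#' @param foundation a [foundation_spec()] or `NULL`.
#' @param dirichlet optional list of fixed-support sets, each
#'   `list(nodes = <node ids>, comps = <subset of 1:3>)` (homogeneous).
#' @return a `fem_system` (stiffness, foundation pieces, constraint mask).
#' @export
assemble_system <- function(mesh, materials, foundation = NULL,
                            dirichlet = NULL) {
  stopifnot(inherits(mesh, "labeled_mesh"), inherits(materials, "material_set"))
  K_bulk <- assemble_bulk(mesh, materials)
  ndof <- 3L * nrow(mesh$nodes)
  fixed <- rep(FALSE, ndof)
  if (!is.null(dirichlet)) {
    if (!is.null(dirichlet$nodes)) dirichlet <- list(dirichlet)
    for (d in dirichlet)
      for (cc in d$comps) fixed[3L * (d$nodes - 1L) + cc] <- TRUE
  }
  fnd <- NULL
  K_found <- NULL
  if (!is.null(foundation)) {
    tab <- resolve_foundation(foundation, mesh)
    units <- foundation_unit_matrices(mesh, tab$patch)
    K_found <- Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(ndof, ndof))
    for (r in seq_len(nrow(tab))) {
      u <- units[[tab$patch[r]]]
      if (tab$k_n[r] > 0) K_found <- K_found + tab$k_n[r] * u$Kn
      if (tab$k_t[r] > 0) K_found <- K_found + tab$k_t[r] * u$Kt
    }
    fnd <- list(tab = tab, units = units)
  }
  if (is.null(K_found) && !any(fixed))
    stop("unconstrained model: no foundation patches and no fixed supports")
  K <- if (is.null(K_found)) K_bulk else K_bulk + K_found
  structure(list(K = K, K_bulk = K_bulk, K_found = K_found,
                 foundation = fnd, fixed = fixed, mesh = mesh,
                 materials = materials, ndof = ndof),
            class = "fem_system")
}

#' Solve an assembled system for a nodal displacement field
#'
#' Sparse Cholesky factorization with one step of iterative refinement;
#' the relative residual is checked against 1e-8. Deterministic for fixed
#' inputs.
#'
#' @param system a `fem_system` from [assemble_system()].
#' @param f load: either a length-`3n` dof vector or an `n x 3` matrix of
#'   nodal forces in N.
#' @return a `displacement_field`: `n x 3` matrix of displacements (mm)
#'   with the relative residual in `attr(, "residual")`.
#' @export
solve_system <- function(system, f) {
  solve_factored(factor_system(system), system, f)
}

# sparse Cholesky factorization of the constrained system (reusable
# across load cases)
factor_system <- function(system) {
  free <- !system$fixed
  Kff <- Matrix::forceSymmetric(system$K[free, free, drop = FALSE])
  ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE),
                 error = function(e)
                   stop("factorization failure (singular or indefinite ",
                        "system; condition estimate ",
                        format(tryCatch(Matrix::condest(Kff)$est,
                                        error = function(e2) NA)),
                        "): ", conditionMessage(e)))
  list(ch = ch, Kff = Kff, free = free)
}

solve_factored <- function(fct, system, f) {
  if (is.matrix(f)) f <- as.vector(t(f))
  stopifnot(length(f) == system$ndof)
  free <- fct$free
  uf <- Matrix::solve(fct$ch, f[free])
  r <- f[free] - fct$Kff %*% uf
  uf <- uf + Matrix::solve(fct$ch, r)             # one refinement step
  res <- as.numeric(sqrt(sum((f[free] - fct$Kff %*% uf)^2)) /
                      max(sqrt(sum(f[free]^2)), .Machine$double.eps))
  if (sum(f[free]^2) > 0 && (!is.finite(res) || res > 1e-8))
    stop("solver did not converge: relative residual ", format(res))
  u <- numeric(system$ndof)
  u[free] <- as.numeric(uf)
  U <- matrix(u, ncol = 3, byrow = TRUE)
  attr(U, "residual") <- res
  class(U) <- c("displacement_field", class(U))
  U
}

#' von Mises equivalent stress
#'
#' Second-deviatoric-invariant form. Accepts a length-6 Voigt vector
#' `(xx, yy, zz, xy, yz, zx)` or an `n x 6` matrix of such rows.
#'
#' @param tensor stress tensor(s), Voigt notation, MPa.
#' @return nonnegative equivalent stress(es), MPa.
#' @export
von_mises <- function(tensor) {
  t <- if (is.matrix(tensor)) tensor else matrix(tensor, nrow = 1)
  out <- sqrt(0.5 * ((t[, 1] - t[, 2])^2 + (t[, 2] - t[, 3])^2 +
                       (t[, 3] - t[, 1])^2) +
                3 * (t[, 4]^2 + t[, 5]^2 + t[, 6]^2))
  if (is.matrix(tensor)) out else as.numeric(out)
}

#' Principal stresses of symmetric stress tensors
#'
#' Eigendecomposition of each 3x3 tensor; values sorted descending
#' (`s1 >= s2 >= s3`).
#'
#' @param tensor length-6 Voigt vector or `n x 6` matrix
#'   `(xx, yy, zz, xy, yz, zx)`.
#' @param vectors if `TRUE` (single tensor only) also return the
#'   orthonormal principal directions.
#' @return `n x 3` matrix (or length-3 vector) of principal stresses; with
#'   `vectors = TRUE`, a list with `values` and `vectors`.
#' @export
principal_stresses <- function(tensor, vectors = FALSE) {
  single <- !is.matrix(tensor)
  t <- if (single) matrix(tensor, nrow = 1) else tensor
  if (vectors) {
    if (!single) stop("vectors = TRUE requires a single tensor")
    S <- matrix(c(t[1, 1], t[1, 4], t[1, 6],
                  t[1, 4], t[1, 2], t[1, 5],
                  t[1, 6], t[1, 5], t[1, 3]), 3, 3)
    e <- eigen(S, symmetric = TRUE)
    return(list(values = e$values, vectors = e$vectors))
  }
  out <- matrix(0, nrow(t), 3)
  for (i in seq_len(nrow(t))) {
    S <- matrix(c(t[i, 1], t[i, 4], t[i, 6],
                  t[i, 4], t[i, 2], t[i, 5],
                  t[i, 6], t[i, 5], t[i, 3]), 3, 3)
    out[i, ] <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  }
  colnames(out) <- c("s1", "s2", "s3")
  if (single) out[1, ] else out
}

#' Recover the stress field from a displacement solution
#'
#' Element stresses are evaluated from the strain-displacement operator
#' (constant per tet4; linear within a straight-sided tet10, evaluated at
#' the element nodes). Nodal stresses are the arithmetic average over
#' adjacent elements. Both the raw element maxima and the (smoother)
#' nodal-averaged field are reported.
#'
#' @param u a `displacement_field`.
#' @param mesh the `labeled_mesh` that produced it.
#' @param materials the [material_set()] used.
#' @return a `stress_field`: list with `element` (ne x 6 centroid Voigt
#'   stresses), `nodal` (data.frame: Voigt components, `von_mises`,
#'   `s1`, `s2`, `s3`), `max_raw_mises`, `max_nodal_mises`.
#' @export
recover_stress <- function(u, mesh, materials) {
  labs <- unique(mesh$elem_label)
  Dm <- lapply(setNames(labs, labs),
               function(l) elastic_D(materials$E[[l]], materials$nu[[l]]))
  nn <- ncol(mesh$elems)
  ne <- nrow(mesh$elems)
  nnod <- nrow(mesh$nodes)
  acc <- matrix(0, nnod, 6)
  cnt <- numeric(nnod)
  elem_sig <- matrix(0, ne, 6)
  uv <- as.vector(t(unclass(u)))
  for (e in seq_len(ne)) {
    en <- mesh$elems[e, ]
    xe <- mesh$nodes[en, , drop = FALSE]
    D <- Dm[[mesh$elem_label[e]]]
    ue <- uv[elem_dofs(en)]
    J <- t(xe[2:4, , drop = FALSE] - matrix(xe[1, ], 3, 3, byrow = TRUE))
    Jinv <- solve(J)
    if (nn == 4L) {
      sig <- as.numeric(D %*% (strain_B(tet4_dN() %*% Jinv) %*% ue))
      elem_sig[e, ] <- sig
      acc[en, ] <- acc[en, , drop = FALSE] + rep(sig, each = 4)
      cnt[en] <- cnt[en] + 1
    } else {
      sc <- matrix(0, 4, 6)
      for (cc in 1:4) {
        dN <- tet10_dN(TET_CORNER_REF[cc, 1], TET_CORNER_REF[cc, 2],
                       TET_CORNER_REF[cc, 3]) %*% Jinv
        sc[cc, ] <- as.numeric(D %*% (strain_B(dN) %*% ue))
      }
      elem_sig[e, ] <- colMeans(sc)
      # strains are linear: midedge values are endpoint averages
      sm <- (sc[TET_EDGES[, 1], , drop = FALSE] +
               sc[TET_EDGES[, 2], , drop = FALSE]) / 2
      snode <- rbind(sc, sm)
      acc[en, ] <- acc[en, , drop = FALSE] + snode
      cnt[en] <- cnt[en] + 1
    }
  }
  nodal <- acc / pmax(cnt, 1)
  vm <- von_mises(nodal)
  pr <- principal_stresses(nodal)
  nodal_df <- data.frame(sxx = nodal[, 1], syy = nodal[, 2], szz = nodal[, 3],
                         sxy = nodal[, 4], syz = nodal[, 5], szx = nodal[, 6],
                         von_mises = vm, s1 = pr[, 1], s2 = pr[, 2],
                         s3 = pr[, 3])
  structure(list(element = elem_sig, nodal = nodal_df,
                 max_raw_mises = max(von_mises(elem_sig)),
                 max_nodal_mises = max(vm)),
            class = "stress_field")
}

#' Total foundation reaction force
#'
#' Integrates the elastic-foundation tractions over all foundation patches
#' (the force exerted by the supporting tissues on the denture). By global
#' equilibrium it balances the applied load to solver precision.
#'
#' @param u a `displacement_field`.
#' @param system the `fem_system` used to solve it (must carry foundation
#'   terms).
#' @return length-3 numeric `c(Fx, Fy, Fz)` in N.
#' @export
reaction_sum <- function(u, system) {
  if (is.null(system$K_found)) stop("system has no foundation terms")
  r <- -as.numeric(system$K_found %*% as.vector(t(unclass(u))))
  R <- matrix(r, ncol = 3, byrow = TRUE)
  setNames(colSums(R), c("Fx", "Fy", "Fz"))
}
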