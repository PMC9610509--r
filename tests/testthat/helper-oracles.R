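# Independent numerical oracles, deliberately implemented along different
# routes than the package internals.

# --- brute-force element stiffness -----------------------------------------
# Shape-function derivatives by central finite differences (exact for the
# quadratic tet10 basis up to roundoff) and Duffy-transformed tensor-product
# Gauss quadrature on the collapsed cube, instead of the analytic gradients
# and the 4-point simplex rule used by the package.

shape_values <- function(nn, r, s, t) {
  L <- c(1 - r - s - t, r, s, t)
  if (nn == 4L) return(L)
  edges <- cbind(c(1, 2, 3, 1, 2, 3), c(2, 3, 1, 4, 4, 4))
  c(L * (2 * L - 1),
    vapply(1:6, function(e) 4 * L[edges[e, 1]] * L[edges[e, 2]], 0))
}

shape_grads_fd <- function(nn, r, s, t, h = 1e-4) {
  g <- matrix(0, nn, 3)
  pt <- c(r, s, t)
  for (d in 1:3) {
    hi <- pt; lo <- pt
    hi[d] <- hi[d] + h; lo[d] <- lo[d] - h
    g[, d] <- (shape_values(nn, hi[1], hi[2], hi[3]) -
                 shape_values(nn, lo[1], lo[2], lo[3])) / (2 * h)
  }
  g
}

gauss_legendre_01 <- function(n) {
  # Golub-Welsch on [0, 1]
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = (e$values + 1) / 2, w = e$vectors[1, ]^2)
}

oracle_element_stiffness <- function(xe, E, nu, ngauss = 6) {
  nn <- nrow(xe)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam; diag(D)[1:3] <- lam + 2 * mu; diag(D)[4:6] <- mu
  gl <- gauss_legendre_01(ngauss)
  Ke <- matrix(0, 3 * nn, 3 * nn)
  for (a in seq_len(ngauss)) for (b in seq_len(ngauss)) for (cc in seq_len(ngauss)) {
    xi <- gl$x[a]; eta <- gl$x[b]; zeta <- gl$x[cc]
    r <- xi; s <- eta * (1 - xi); t <- zeta * (1 - xi) * (1 - eta)
    duffy <- (1 - xi)^2 * (1 - eta)
    dN <- shape_grads_fd(nn, r, s, t)
    J <- t(xe) %*% dN                      # 3x3: dx/dxi
    dNx <- dN %*% solve(J)
    B <- matrix(0, 6, 3 * nn)
    ix <- 3 * seq_len(nn) - 2
    B[1, ix] <- dNx[, 1]; B[2, ix + 1] <- dNx[, 2]; B[3, ix + 2] <- dNx[, 3]
    B[4, ix] <- dNx[, 2]; B[4, ix + 1] <- dNx[, 1]
    B[5, ix + 1] <- dNx[, 3]; B[5, ix + 2] <- dNx[, 2]
    B[6, ix] <- dNx[, 3]; B[6, ix + 2] <- dNx[, 1]
    w <- gl$w[a] * gl$w[b] * gl$w[cc] * duffy * det(J)
    Ke <- Ke + w * crossprod(B, D %*% B)
  }
  Ke
}

# --- closed-form eigenvalues of a symmetric 3x3 tensor ----------------------
# trigonometric solution of the characteristic cubic
oracle_principal <- function(v) {       # v = (xx, yy, zz, xy, yz, zx)
  A <- matrix(c(v[1], v[4], v[6],
                v[4], v[2], v[5],
                v[6], v[5], v[3]), 3, 3)
  q <- sum(diag(A)) / 3
  B <- A - q * diag(3)
  p <- sqrt(sum(B^2) / 6)
  if (p < 1e-300) return(rep(q, 3))
  detB <- det(B / p)
  phi <- acos(pmin(pmax(detB / 2, -1), 1)) / 3
  eig <- q + 2 * p * cos(phi + c(0, -2, 2) * pi / 3)
  sort(eig, decreasing = TRUE)
}

# --- uniform surface traction on a box face ---------------------------------
# consistent nodal forces for pressure p acting along `dir` on patch `face`
face_traction <- function(mesh, face, p, dir = c(0, 0, 1)) {
  f <- numeric(3 * nrow(mesh$nodes))
  for (fi in which(mesh$facet_patch == face)) {
    fn <- mesh$facets[fi, ]
    fm <- rcdlife:::facet_mass(mesh$nodes[fn, , drop = FALSE])
    w <- rowSums(fm$M)
    for (d in 1:3) f[3 * (fn - 1) + d] <- f[3 * (fn - 1) + d] + p * dir[d] * w
  }
  f
}

box_roller_bc <- function(mesh) {
  tol <- 1e-9
  nmin <- function(d) which(abs(mesh$nodes[, d] - min(mesh$nodes[, d])) < tol)
  list(list(nodes = nmin(1), comps = 1L),
       list(nodes = nmin(2), comps = 2L),
       list(nodes = nmin(3), comps = 3L))
}
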