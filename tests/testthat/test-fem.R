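# Solver verification: patch tests, beam theory, element oracles,
# invariant stress measures, equilibrium.

test_that("uniform-traction patch test is exact for tet4 and tet10", {
  for (ord in c(1L, 2L)) {
    b <- mesh_box(c(1, 1, 1), n = c(2, 2, 2), order = ord)
    mats <- material_set(E = c(base = 1000), nu = 0.3)
    sys <- assemble_system(b, mats, dirichlet = box_roller_bc(b))
    sig <- 2.5
    f <- face_traction(b, "zmax", sig, dir = c(0, 0, 1))
    u <- solve_system(sys, f)
    st <- recover_stress(u, b, mats)
    # recovered stress equals the applied uniaxial state everywhere
    expect_lt(max(abs(st$nodal$szz - sig)), 1e-9 * sig)
    expect_lt(max(abs(st$nodal$sxx)), 1e-9 * sig)
    expect_lt(max(abs(st$nodal$sxy)), 1e-9 * sig)
    expect_equal(st$max_nodal_mises, sig, tolerance = 1e-9)
    expect_equal(st$max_raw_mises, sig, tolerance = 1e-9)
  }
})

test_that("hydrostatic compression has zero deviatoric stress", {
  b <- mesh_box(c(1, 1, 1), n = c(2, 2, 2), order = 2L)
  mats <- material_set(E = c(base = 1000), nu = 0.3)
  sys <- assemble_system(b, mats, dirichlet = box_roller_bc(b))
  p <- 4
  f <- face_traction(b, "zmax", -p, c(0, 0, 1)) +
    face_traction(b, "xmax", -p, c(1, 0, 0)) +
    face_traction(b, "ymax", -p, c(0, 1, 0))
  st <- recover_stress(solve_system(sys, f), b, mats)
  expect_lt(max(st$nodal$von_mises), 1e-9 * p)
  expect_equal(max(abs(st$nodal$szz + p)), 0, tolerance = 1e-9)
})

test_that("tet10 cantilever matches Euler-Bernoulli within 2 percent", {
  L <- 20; h <- 2; E <- 1000; nu <- 0.3; F <- 4
  b <- mesh_box(c(L, h, h), n = c(20, 2, 2), order = 2L)
  mats <- material_set(E = c(base = E), nu = nu)
  tol <- 1e-9
  clamp <- which(abs(b$nodes[, 1]) < tol)
  sys <- assemble_system(b, mats,
                         dirichlet = list(nodes = clamp, comps = 1:3))
  f <- face_traction(b, "xmax", F / (h * h), dir = c(0, 0, 1))
  u <- solve_system(sys, f)
  tip <- mean(unclass(u)[abs(b$nodes[, 1] - L) < tol, 3])
  defl_eb <- F * L^3 / (3 * E * (h * h^3 / 12))
  expect_equal(tip, defl_eb, tolerance = 0.02)
})

test_that("probe displacement Cauchy-converges under refinement", {
  L <- 20; h <- 2; E <- 1000; F <- 4
  defl <- vapply(list(c(5, 1, 1), c(10, 2, 2), c(20, 3, 3)), function(n) {
    b <- mesh_box(c(L, h, h), n = n, order = 2L)
    mats <- material_set(E = c(base = E), nu = 0.3)
    clamp <- which(abs(b$nodes[, 1]) < 1e-9)
    sys <- assemble_system(b, mats,
                           dirichlet = list(nodes = clamp, comps = 1:3))
    f <- face_traction(b, "xmax", F / (h * h), dir = c(0, 0, 1))
    u <- solve_system(sys, f)
    mean(unclass(u)[abs(b$nodes[, 1] - L) < 1e-9, 3])
  }, 0)
  expect_lt(abs(defl[3] - defl[2]), abs(defl[2] - defl[1]))
})

test_that("a block on a uniform foundation settles by p over k", {
  k <- 5; p <- 3; E <- 1000; L <- 1
  fnd <- foundation_spec(patches = data.frame(
    patch = "zmin", k_n = k, k_t = 2))
  b <- mesh_box(c(2, 2, L), n = c(2, 2, 1), order = 1L)
  mats <- material_set(E = c(base = E), nu = 0)   # 1D column state
  sys <- assemble_system(b, mats, fnd)
  f <- face_traction(b, "zmax", -p, dir = c(0, 0, 1))
  u <- solve_system(sys, f)
  uz <- unclass(u)[, 3]
  bot <- abs(b$nodes[, 3]) < 1e-9
  top <- abs(b$nodes[, 3] - L) < 1e-9
  # foundation interface settles by exactly p/k; the column above adds
  # its own uniform compression p L / E
  expect_lt(max(abs(uz[bot] + p / k)), 1e-8)
  expect_lt(max(abs(uz[top] + p / k + p * L / E)), 1e-8)
  expect_lt(max(abs(unclass(u)[, 1:2])), 1e-8)
  st <- recover_stress(u, b, mats)
  expect_lt(max(abs(st$nodal$szz + p)), 1e-8)
  # reactions balance the applied load
  expect_equal(reaction_sum(u, sys)[["Fz"]], p * 4, tolerance = 1e-8)
})

test_that("zero load and linearity behave as a linear operator", {
  sys <- fast_system()
  m <- fast_mesh()
  u0 <- solve_system(sys, numeric(sys$ndof))
  expect_equal(max(abs(unclass(u0))), 0)
  f <- build_load_case(load_case("II", "asymmetric-right"), m)
  u1 <- solve_system(sys, f)
  u2 <- solve_system(sys, 2 * f)
  expect_equal(unclass(u2), 2 * unclass(u1), tolerance = 1e-9)
  # reactions scale with the load factor
  expect_equal(reaction_sum(u2, sys), 2 * reaction_sum(u1, sys),
               tolerance = 1e-9)
})

test_that("an unconstrained model is rejected explicitly", {
  b <- mesh_box(c(1, 1, 1), n = c(1, 1, 1))
  expect_error(assemble_system(b, material_set(E = c(base = 1000))),
               "unconstrained")
  expect_error(assemble_system(fast_mesh(),
                               material_set(E = c(nothing = 1))),
               "material")
})

test_that("single-element stiffness matches the brute-force oracle", {
  set.seed(11)
  E <- 1700; nu <- 0.33
  D <- rcdlife:::elastic_D(E, nu)
  for (rep in 1:3) {
    x4 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) +
      0.15 * matrix(runif(12, -1, 1), 4, 3)
    Ke <- rcdlife:::element_stiffness(x4, D)
    Ko <- oracle_element_stiffness(x4, E, nu)
    expect_lt(max(abs(Ke - Ko)) / max(abs(Ko)), 1e-9)
    # straight-sided tet10 on the same corners
    mids <- (x4[rcdlife:::TET_EDGES[, 1], ] +
               x4[rcdlife:::TET_EDGES[, 2], ]) / 2
    x10 <- rbind(x4, mids)
    Ke10 <- rcdlife:::element_stiffness(x10, D)
    Ko10 <- oracle_element_stiffness(x10, E, nu)
    expect_lt(max(abs(Ke10 - Ko10)) / max(abs(Ko10)), 1e-9)
  }
})

test_that("stress recovery matches a hand-assembled B-matrix product", {
  set.seed(3)
  x4 <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0.1, 0.9, 0), c(0.2, 0.1, 1.1))
  bf <- rcdlife:::boundary_faces(matrix(1:4, 1, 4))
  m <- labeled_mesh(x4, matrix(1:4, 1, 4), "base", bf$faces,
                    rep("free", 4))
  mats <- material_set(E = c(base = 900), nu = 0.28)
  U <- matrix(rnorm(12, sd = 0.01), 4, 3)
  st <- recover_stress(structure(U, class = "displacement_field"), m, mats)
  # oracle: finite-difference shape gradients, independent B assembly
  dN <- shape_grads_fd(4L, 0.25, 0.25, 0.25)
  J <- t(x4) %*% dN
  dNx <- dN %*% solve(J)
  eps <- c(sum(dNx[, 1] * U[, 1]), sum(dNx[, 2] * U[, 2]),
           sum(dNx[, 3] * U[, 3]),
           sum(dNx[, 2] * U[, 1] + dNx[, 1] * U[, 2]),
           sum(dNx[, 3] * U[, 2] + dNx[, 2] * U[, 3]),
           sum(dNx[, 3] * U[, 1] + dNx[, 1] * U[, 3]))
  sig <- as.numeric(rcdlife:::elastic_D(900, 0.28) %*% eps)
  expect_equal(as.numeric(st$element[1, ]), sig, tolerance = 1e-9)
  expect_equal(as.numeric(unlist(st$nodal[1, 1:6])), sig, tolerance = 1e-9)
})

test_that("von Mises follows its closed forms", {
  s <- 7.3; tau <- 2.4
  expect_equal(von_mises(c(s, 0, 0, 0, 0, 0)), s)
  expect_equal(von_mises(c(-s, -s, -s, 0, 0, 0)), 0)
  expect_equal(von_mises(c(0, 0, 0, tau, 0, 0)), sqrt(3) * tau)
  expect_gte(min(von_mises(matrix(rnorm(60), 10, 6))), 0)
})

test_that("principal stresses match the closed-form eigensolution", {
  expect_equal(principal_stresses(c(1, 5, 3, 0, 0, 0)), c(5, 3, 1),
               ignore_attr = TRUE)
  tau <- 4.2
  expect_equal(principal_stresses(c(0, 0, 0, tau, 0, 0)), c(tau, 0, -tau),
               ignore_attr = TRUE, tolerance = 1e-12)
  set.seed(99)
  Ts <- matrix(rnorm(600, sd = 10), 100, 6)
  P <- principal_stresses(Ts)
  expect_true(all(P[, 1] >= P[, 2] & P[, 2] >= P[, 3]))
  for (i in seq_len(100))
    expect_equal(as.numeric(P[i, ]), oracle_principal(Ts[i, ]),
                 tolerance = 1e-9)
  # orthonormal principal directions on request
  pv <- principal_stresses(Ts[1, ], vectors = TRUE)
  expect_equal(crossprod(pv$vectors), diag(3), tolerance = 1e-12)
})

test_that("foundation reactions balance any applied load to 0.1 percent", {
  m <- fast_mesh()
  sys <- fast_system()
  for (cs in list(load_case("I", "symmetric", 100),
                  load_case("III", "asymmetric-left", 100),
                  load_case(sidedness = "uniform-all", F0 = 100))) {
    f <- build_load_case(cs, m)
    u <- solve_system(sys, f)
    r <- reaction_sum(u, sys)
    expect_equal(r[["Fz"]], 100, tolerance = 1e-3)
    expect_lt(abs(r[["Fx"]]) + abs(r[["Fy"]]), 0.1)
  }
})

test_that("symmetric geometry and load give a mirror-symmetric stress field", {
  m <- fast_mesh()
  mats <- material_set()
  sys <- fast_system()
  f <- build_load_case(load_case("II", "symmetric"), m)
  st <- recover_stress(solve_system(sys, f), m, mats)
  vm <- st$nodal$von_mises
  key <- function(x) paste(round(x[, 1], 6), round(x[, 2], 6),
                           round(x[, 3], 6))
  refl <- m$nodes
  refl[, 1] <- -refl[, 1]
  mirror <- match(key(refl), key(m$nodes))
  expect_false(anyNA(mirror))
  rel <- abs(vm - vm[mirror]) / max(vm)
  expect_lt(max(rel), 0.02)
})
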