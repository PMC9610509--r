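# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# coarse tet4 arch: fast geometry for solver-level tests
fast_params <- function(...) {
  arch_parameters(mesh_size = 3, element_order = 1L, ...)
}

fast_mesh <- function() cache_fixture("fast_mesh", generate_denture(fast_params()))

fast_system <- function() cache_fixture("fast_system", {
  assemble_system(fast_mesh(), material_set(), foundation_spec())
})

# calibrated foundation on the coarse arch
fast_calibrated <- function() cache_fixture("fast_calibrated", {
  calibrate_foundation(fast_mesh(), material_set(), foundation_spec())
})

# UV-triangulated hemisphere (z >= 0) of radius r; returns a minimal
# labeled_mesh-like object whose boundary is the hemisphere patch, for
# the closed-form area/projection oracles
hemisphere_surface <- function(r = 1, n_theta = 48, n_phi = 96) {
  th <- seq(0, pi / 2, length.out = n_theta + 1)     # polar, 0 = pole
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  # pole point + rings
  nodes <- rbind(c(0, 0, r))
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 0L
  for (i in seq_len(n_theta)) {
    ring <- cbind(r * sin(th[i + 1]) * cos(ph),
                  r * sin(th[i + 1]) * sin(ph),
                  r * cos(th[i + 1]))
    nodes <- rbind(nodes, ring)
  }
  tris <- list()
  for (j in seq_len(n_phi))  # cap fan
    tris[[length(tris) + 1L]] <- c(1L, idx(1, j), idx(1, j + 1))
  if (n_theta > 1) for (i in seq_len(n_theta - 1)) for (j in seq_len(n_phi)) {
    a <- idx(i, j); b <- idx(i, j + 1); c <- idx(i + 1, j); d <- idx(i + 1, j + 1)
    tris[[length(tris) + 1L]] <- c(a, b, d)
    tris[[length(tris) + 1L]] <- c(a, d, c)
  }
  facets <- do.call(rbind, tris)
  structure(list(nodes = nodes, facets = facets,
                 facet_patch = rep("hemisphere", nrow(facets))),
            class = "labeled_mesh")
}

# minimal fake mesh holding one labeled surface patch (planar or warped
# quad split into two triangles); enough surface for load-building tests
patch_only_mesh <- function(corners, patch = "occlusal_I_right") {
  facets <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  structure(list(nodes = corners, facets = facets,
                 facet_patch = rep(patch, 2)),
            class = "labeled_mesh")
}
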